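# Pruning-based benchmark harness: recreate the placement accuracy loop
# (Pruning -> Damage -> Placement -> Assessment) on synthetic data. Damage
# is injected after alignment (reads inherit the source's alignment
# columns), so alignment error never confounds the measured placement error.

#' Prune a random subtree to create a placement scenario
#'
#' Selects (uniformly at random) an edge whose removal leaves at least
#' `min_remaining_taxa` tips and removes at most a fraction
#' `max_removed_frac` of tips, then prunes the subtree below it. The
#' attachment node is suppressed and its two remaining incident edges merge;
#' the merged edge is the scenario's true placement edge. The pruned
#' sequences become the aligned query set.
#'
#' @param tree a [reference_tree()] or `phylo` whose tips match `msa` ids.
#' @param msa the alignment ([as_alignment()]) for all tips.
#' @param min_remaining_taxa minimum tips that must remain (default 4).
#' @param max_removed_frac maximum fraction of tips removable (default 0.25;
#'   at least one tip is always allowed).
#' @param tips optional character vector naming the exact clade to prune
#'   (must correspond to one edge); bypasses the random choice.
#' @return an object of class `pruning_scenario`: list with `pruned_tree`,
#'   `reference_msa`, `query_records`, `true_edge`, and `pruned_tips`.
#' @export
prune_random_subtree <- function(tree, msa, min_remaining_taxa = 4,
                                 max_removed_frac = 0.25, tips = NULL) {
  phy <- if (inherits(tree, "reference_tree")) tree$phylo else tree
  stopifnot(inherits(phy, "phylo"))
  msa <- as_alignment(msa)
  if (!setequal(phy$tip.label, msa$id)) {
    stop("tree tip labels and alignment ids do not match")
  }
  n <- length(phy$tip.label)
  root <- n + 1L
  desc <- phangorn::Descendants(phy, type = "tips")
  clade_tips <- lapply(desc, function(d) phy$tip.label[d])
  clade_size <- lengths(desc)
  parent <- phy$edge[, 1]
  child <- phy$edge[, 2]
  n_children <- tabulate(parent, nbins = n + phy$Nnode)
  max_removed <- max(1L, floor(max_removed_frac * n))
  eligible <- which(parent != root &
                    n_children[parent] == 2L &
                    clade_size[child] <= max_removed &
                    (n - clade_size[child]) >= min_remaining_taxa)
  if (!is.null(tips)) {
    hit <- which(vapply(child, function(ch) setequal(clade_tips[[ch]], tips),
                        logical(1)))
    if (length(hit) != 1) {
      stop("'tips' does not correspond to exactly one edge")
    }
    if (!hit %in% eligible) {
      stop("requested clade is not prunable under the constraints")
    }
    row <- hit
  } else {
    if (length(eligible) == 0) {
      stop("no prunable edge satisfies the constraints")
    }
    row <- eligible[sample.int(length(eligible), 1)]
  }
  pruned_tips <- clade_tips[[child[row]]]
  p <- parent[row]
  siblings <- child[parent == p & child != child[row]]
  sibling_tips <- clade_tips[[siblings[1]]]

  pruned_phy <- ape::drop.tip(phy, pruned_tips)
  ptree <- reference_tree(pruned_phy)
  pdesc <- phangorn::Descendants(pruned_phy, type = "tips")
  true_row <- which(vapply(pruned_phy$edge[, 2], function(ch) {
    setequal(pruned_phy$tip.label[pdesc[[ch]]], sibling_tips)
  }, logical(1)))
  stopifnot(length(true_row) == 1)

  structure(list(
    pruned_tree = ptree,
    reference_msa = msa[msa$id %in% setdiff(phy$tip.label, pruned_tips), ,
                        drop = FALSE],
    query_records = msa[msa$id %in% pruned_tips, , drop = FALSE],
    true_edge = ptree$edge_num[true_row],
    pruned_tips = pruned_tips),
    class = "pruning_scenario")
}

#' @export
print.pruning_scenario <- function(x, ...) {
  cat("Pruning scenario:", length(x$pruned_tips), "tip(s) pruned (",
      paste(utils::head(x$pruned_tips, 5), collapse = ", "),
      if (length(x$pruned_tips) > 5) ", ..." else "",
      "), true edge", x$true_edge, "\n")
  invisible(x)
}

#' Distance-based naive placer
#'
#' A deliberately simple placement method used so the benchmark loop runs
#' with no external placement tool: it is a benchmark stand-in, not a
#' scientific method. Each aligned query is compared to every reference
#' sequence by normalized Hamming distance over the columns where both are
#' non-gap; the candidate edges are the pendant edges of the `top_k` closest
#' leaves, and the LWR of each candidate is the softmax of the negative
#' distances. Ties are broken deterministically toward the lowest edge
#' number. Queries sharing no non-gap column with any reference are skipped
#' with a warning (they would be unalignable, mirroring premasking).
#'
#' @param query_records aligned query records (damage output in aligned
#'   mode), same column count as `reference_msa`.
#' @param reference_msa the reference alignment.
#' @param pruned_tree the [reference_tree()] to place onto.
#' @param top_k number of candidate leaves (default 3).
#' @return a [placement_set()] (skipped queries are absent).
#' @export
naive_placer <- function(query_records, reference_msa, pruned_tree,
                         top_k = 3) {
  reference_msa <- as_alignment(reference_msa)
  query_records <- validate_records(query_records)
  stopifnot(inherits(pruned_tree, "reference_tree"), top_k >= 1)
  ncol_ref <- nchar(reference_msa$residues[1])
  if (any(nchar(query_records$residues) != ncol_ref)) {
    stop("queries must be aligned to the reference columns")
  }
  ref_mat <- toupper(do.call(rbind,
                             strsplit(reference_msa$residues, "", fixed = TRUE)))
  ref_ng <- !is_gap(ref_mat)
  phy <- pruned_tree$phylo
  pendant <- vapply(reference_msa$id, function(id) {
    tip <- match(id, phy$tip.label)
    if (is.na(tip)) stop("reference sequence '", id, "' is not a tree tip")
    pruned_tree$edge_num[which(phy$edge[, 2] == tip)]
  }, integer(1))

  out <- list()
  for (qi in seq_len(nrow(query_records))) {
    q <- toupper(strsplit(query_records$residues[qi], "", fixed = TRUE)[[1]])
    q_ng <- !is_gap(q)
    dist <- rep(NA_real_, nrow(ref_mat))
    for (ri in seq_len(nrow(ref_mat))) {
      both <- q_ng & ref_ng[ri, ]
      if (any(both)) dist[ri] <- mean(q[both] != ref_mat[ri, both])
    }
    if (all(is.na(dist))) {
      warning("query '", query_records$id[qi],
              "' shares no non-gap column with the reference; skipped")
      next
    }
    ok <- which(!is.na(dist))
    ord <- ok[order(dist[ok], pendant[ok])]
    sel <- ord[seq_len(min(top_k, length(ord)))]
    w <- exp(-dist[sel])
    rows <- data.frame(edge_num = unname(pendant[sel]), lwr = w / sum(w))
    rows <- rows[order(-rows$lwr, rows$edge_num), , drop = FALSE]
    rownames(rows) <- NULL
    out[[query_records$id[qi]]] <- rows
  }
  placement_set(out)
}

#' Damage parameter grid
#'
#' Cartesian product of candidate values for the four damage parameters,
#' for grid searches over the damage parameter space.
#'
#' @param nu,lam,delta_ss,delta_ds numeric vectors of values.
#' @return data.frame with one row per grid point.
#' @export
damage_grid <- function(nu, lam, delta_ss, delta_ds) {
  expand.grid(nu = nu, lam = lam, delta_ss = delta_ss, delta_ds = delta_ds,
              KEEP.OUT.ATTRS = FALSE)
}

#' Run the full pruning/damage/placement/assessment experiment
#'
#' The benchmark loop: for each of `n_prunings` independent random prunings,
#' and for each damage-parameter grid point, the pruned (still aligned)
#' query sequences are damaged with [simulate_damage()] (aligned mode,
#' premasked against the remaining reference alignment), placed with the
#' [naive_placer()] (or a caller-supplied placer, e.g. one ingesting an
#' external tool's jplace output), and assessed against the scenario's true
#' edge. The stage order is exactly Pruning -> Damage -> Placement ->
#' Assessment; alignment is an identity step because damage preserves
#' the source columns.
#'
#' @param msa alignment for all tips.
#' @param tree matching [reference_tree()] or `phylo`.
#' @param grid data.frame of damage parameter combinations
#'   (see [damage_grid()]).
#' @param filters a [read_filters()] object.
#' @param n_prunings number of independent prunings (default 10).
#' @param seed optional integer seed; the run is deterministic given
#'   (inputs, seed).
#' @param top_k candidate count for the naive placer.
#' @param min_remaining_taxa pruning constraint (default 4).
#' @param placer placement function with the signature of [naive_placer()].
#' @return data.frame with one row per pruning x grid point x read:
#'   `pruning`, `nu`, `lam`, `delta_ss`, `delta_ds`, `read_id`, `nd`, `end`,
#'   `normalized_end`.
#' @export
run_experiment <- function(msa, tree, grid, filters = read_filters(),
                           n_prunings = 10, seed = NULL, top_k = 3,
                           min_remaining_taxa = 4, placer = naive_placer) {
  msa <- as_alignment(msa)
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(c("nu", "lam", "delta_ss", "delta_ds") %in% names(grid)))
  results <- list()
  for (p in seq_len(n_prunings)) {
    scen <- prune_random_subtree(tree, msa,
                                 min_remaining_taxa = min_remaining_taxa)
    for (g in seq_len(nrow(grid))) {
      params <- damage_params(grid$nu[g], grid$lam[g],
                              grid$delta_ss[g], grid$delta_ds[g])
      sim <- simulate_damage(scen$query_records, params, filters,
                             aligned = TRUE, reference = scen$reference_msa)
      ps <- placer(sim$records, scen$reference_msa, scen$pruned_tree,
                   top_k = top_k)
      if (length(ps) == 0) next
      truth <- stats::setNames(rep(scen$true_edge, length(ps)), names(ps))
      rec <- assess_placements(ps, truth, scen$pruned_tree)$records
      results[[length(results) + 1]] <- cbind(
        data.frame(pruning = p, nu = grid$nu[g], lam = grid$lam[g],
                   delta_ss = grid$delta_ss[g], delta_ds = grid$delta_ds[g]),
        rec)
    }
  }
  do.call(rbind, c(results, make.row.names = FALSE))
}
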