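# Synthetic fixtures: random sequences with controlled GC content, random
# trees, and tree-evolved alignments. Every test input of the package is
# generated by these functions; nothing is downloaded.

#' Random nucleotide sequence with controlled GC content
#'
#' Each site is independently G or C with probability `gc` (split evenly
#' between the two), otherwise A or T (split evenly). Only G/C sites are
#' eligible for deamination damage, so `gc` directly controls how much
#' misincorporation a damage simulation can introduce.
#'
#' @param length sequence length.
#' @param gc GC fraction in `[0, 1]`.
#' @param id record id (default "random").
#' @return a one-row sequence record set.
#' @export
random_sequence <- function(length, gc, id = "random") {
  stopifnot(length >= 1, gc >= 0, gc <= 1)
  bases <- sample(c("G", "C", "A", "T"), size = length, replace = TRUE,
                  prob = c(gc / 2, gc / 2, (1 - gc) / 2, (1 - gc) / 2))
  seq_records(id, paste(bases, collapse = ""))
}

#' Random reference tree
#'
#' A random unrooted topology from [ape::rtree()] with independent
#' exponential branch lengths (mean `mean_branch_length` expected
#' substitutions per site), with edges numbered by the package's postorder
#' convention (`2 n - 3` edges for `n` tips).
#'
#' @param n_taxa number of tips (>= 3).
#' @param mean_branch_length mean branch length (default 0.1).
#' @return a [reference_tree()], tips labelled `t1..tn`.
#' @export
random_tree <- function(n_taxa, mean_branch_length = 0.1) {
  stopifnot(n_taxa >= 3, mean_branch_length > 0)
  phy <- ape::rtree(n_taxa, rooted = FALSE,
                    br = function(n) stats::rexp(n, 1 / mean_branch_length))
  reference_tree(phy)
}

#' Evolve an alignment down a tree
#'
#' Simulates sequences for every tip under the one-parameter equal-rates
#' (Jukes-Cantor) substitution model, starting from a given root sequence,
#' with no indels: the alignment has exactly the root's length, and for two
#' tips separated by total path length `t` the expected fraction of
#' differing sites is `(3/4) (1 - exp(-4 t r / 3))` at rate `r`.
#'
#' @param tree a [reference_tree()] or `phylo`.
#' @param root_sequence root sequence string (A/C/G/T).
#' @param rate substitution rate multiplier (>= 0).
#' @return an alignment (sequence records, one per tip, in tip-label order).
#' @export
evolve_alignment <- function(tree, root_sequence, rate = 1) {
  phy <- if (inherits(tree, "reference_tree")) tree$phylo else tree
  stopifnot(inherits(phy, "phylo"), rate >= 0)
  root_chars <- tolower(strsplit(root_sequence, "", fixed = TRUE)[[1]])
  stopifnot(all(root_chars %in% c("a", "c", "g", "t")))
  if (rate == 0) {
    return(seq_records(phy$tip.label,
                       rep(toupper(root_sequence), length(phy$tip.label))))
  }
  sim <- phangorn::simSeq(phy, l = length(root_chars), rootseq = root_chars,
                          type = "DNA", rate = rate)
  mat <- toupper(as.character(sim))
  seqs <- apply(mat, 1, paste, collapse = "")
  seq_records(rownames(mat), unname(seqs))[match(phy$tip.label, rownames(mat)), ]
}

#' Generate a complete synthetic scenario fixture
#'
#' Builds a random tree and a tree-evolved alignment from a random root
#' sequence with the requested GC content. This is the package's stand-in
#' for an empirical reference MSA + tree pair; it is fully reproducible
#' from its arguments and seed.
#'
#' @param n_taxa number of tips (>= 4).
#' @param alignment_length number of columns (>= 1).
#' @param gc_content root GC fraction.
#' @param rate substitution rate multiplier.
#' @param seed optional integer seed.
#' @param mean_branch_length mean branch length (default 0.1).
#' @return list with `tree` (a [reference_tree()]), `alignment` (sequence
#'   records), and `root` (the root record).
#' @export
make_fixture <- function(n_taxa, alignment_length, gc_content = 0.4,
                         rate = 1, seed = NULL, mean_branch_length = 0.1) {
  stopifnot(n_taxa >= 4, alignment_length >= 1)
  if (!is.null(seed)) set.seed(seed)
  root <- random_sequence(alignment_length, gc_content, id = "root")
  tree <- random_tree(n_taxa, mean_branch_length)
  alignment <- evolve_alignment(tree, root$residues, rate = rate)
  list(tree = tree, alignment = alignment, root = root)
}
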