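# Placement accuracy metrics: topological node distance between edges,
# expected node distance (eND), and per-read assessment against a truth map.

# Internal: adjacency BFS over the edge graph. Two edges are at distance 1
# when they share a node; the distance between an edge and itself is 0.
# Returns the distance from `from_row` to every edge row.
edge_bfs <- function(edge_matrix, from_row) {
  n_edge <- nrow(edge_matrix)
  # incidence: node id -> edge rows touching it
  nodes <- as.vector(edge_matrix)
  rows <- rep(seq_len(n_edge), 2)
  incidence <- split(rows, nodes)
  dist <- rep(NA_integer_, n_edge)
  dist[from_row] <- 0L
  frontier <- from_row
  while (length(frontier) > 0) {
    nbr <- unique(unlist(incidence[as.character(edge_matrix[frontier, ])],
                         use.names = FALSE))
    nbr <- nbr[is.na(dist[nbr])]
    if (length(nbr) == 0) break
    dist[nbr] <- dist[frontier[1]] + 1L
    frontier <- nbr
  }
  dist
}

#' Topological distance from one edge to all edges
#'
#' Breadth-first search over the edge-adjacency graph of the tree: two
#' edges sharing a node are at distance 1, an edge is at distance 0 from
#' itself.
#'
#' @param tree a [reference_tree()].
#' @param from_edge an edge number in the tree.
#' @return named integer vector of distances, names are edge numbers.
#' @export
edge_distances <- function(tree, from_edge) {
  stopifnot(inherits(tree, "reference_tree"))
  row <- match(as.integer(from_edge), tree$edge_num)
  if (is.na(row)) stop("unknown edge_num: ", from_edge)
  dist <- edge_bfs(tree$phylo$edge, row)
  stats::setNames(dist, tree$edge_num)
}

#' Node distance between two edges
#'
#' The topological placement error: the shortest-path length between two
#' edges in the edge-adjacency graph (edges sharing a node are at distance
#' 1). Zero when the edges coincide; symmetric; satisfies the triangle
#' inequality.
#'
#' @param tree a [reference_tree()].
#' @param edge_a,edge_b edge numbers present in the tree.
#' @return non-negative integer distance.
#' @examples
#' tr <- parse_newick_edges("((A,B),(C,D));")
#' node_distance(tr, tr$edge_num[1], tr$edge_num[1])  # 0
#' @export
node_distance <- function(tree, edge_a, edge_b) {
  d <- edge_distances(tree, edge_a)
  if (!as.character(edge_b) %in% names(d)) {
    stop("unknown edge_num: ", edge_b)
  }
  unname(d[as.character(edge_b)])
}

#' Expected node distance of one read
#'
#' The LWR-weighted placement error: the sum over all reported placements of
#' the likelihood weight ratio times the node distance to the true edge.
#' LWR values are used as given, without renormalization.
#'
#' @param placements data.frame with columns `edge_num` and `lwr` (one
#'   read's placements).
#' @param true_edge the true edge number.
#' @param tree a [reference_tree()].
#' @param strict error when the LWRs sum to more than `1 + 1e-6`.
#' @return non-negative real.
#' @export
expected_node_distance <- function(placements, true_edge, tree,
                                   strict = FALSE) {
  if (!is.data.frame(placements) || nrow(placements) == 0) {
    stop("at least one placement row is required")
  }
  if (strict && sum(placements$lwr) > 1 + 1e-6) {
    stop("LWRs sum to ", sum(placements$lwr), " > 1")
  }
  d <- edge_distances(tree, true_edge)
  key <- as.character(placements$edge_num)
  if (any(!key %in% names(d))) {
    stop("placement references unknown edge_num(s): ",
         paste(placements$edge_num[!key %in% names(d)], collapse = ", "))
  }
  sum(placements$lwr * d[key])
}

# Internal: best placement row — highest lwr, ties broken by lowest edge_num.
best_placement <- function(placements) {
  ord <- order(-placements$lwr, placements$edge_num)
  placements[ord[1], , drop = FALSE]
}

#' Assess a placement set against known true edges
#'
#' Computes per-read accuracy records: `nd`, the node distance of the best
#' placement (highest LWR, ties broken deterministically toward the lowest
#' edge number); `end`, the expected node distance; and `normalized_end`,
#' the eND divided by the tree's tip count (so errors are comparable across
#' trees of different size).
#'
#' @param placements a [placement_set()].
#' @param truth named integer vector (`read_id -> true edge_num`) or a
#'   data.frame with columns `read_id` and `true_edge_num`.
#' @param tree a [reference_tree()].
#' @return list with `records` (data.frame `read_id`, `nd`, `end`,
#'   `normalized_end`) and `summary` (mean and median of each column).
#' @export
assess_placements <- function(placements, truth, tree) {
  stopifnot(inherits(placements, "placement_set"),
            inherits(tree, "reference_tree"))
  if (is.data.frame(truth)) {
    truth <- stats::setNames(as.integer(truth$true_edge_num), truth$read_id)
  }
  ids <- names(placements)
  missing <- setdiff(ids, names(truth))
  if (length(missing) > 0) {
    stop("read(s) without a truth entry: ", paste(missing, collapse = ", "))
  }
  ntip <- tip_count(tree)
  dist_cache <- list()
  records <- do.call(rbind, lapply(ids, function(id) {
    te <- as.character(truth[[id]])
    if (is.null(dist_cache[[te]])) {
      dist_cache[[te]] <<- edge_distances(tree, truth[[id]])
    }
    d <- dist_cache[[te]]
    p <- placements[[id]]
    nd <- unname(d[as.character(best_placement(p)$edge_num)])
    e <- sum(p$lwr * d[as.character(p$edge_num)])
    data.frame(read_id = id, nd = nd, end = e,
               normalized_end = e / ntip, stringsAsFactors = FALSE)
  }))
  summary <- data.frame(
    metric = c("nd", "end", "normalized_end"),
    mean = c(mean(records$nd), mean(records$end),
             mean(records$normalized_end)),
    median = c(stats::median(records$nd), stats::median(records$end),
               stats::median(records$normalized_end)))
  list(records = records, summary = summary)
}
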