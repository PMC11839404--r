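# Independent line-graph oracle for edge-to-edge topological distances:
# build the adjacency-of-edges graph with igraph and take shortest paths.
line_graph_distances <- function(tree) {
  e <- tree$phylo$edge
  n <- nrow(e)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  pairs <- which(outer(seq_len(n), seq_len(n), Vectorize(
    function(i, j) i < j && length(intersect(e[i, ], e[j, ])) > 0)),
    arr.ind = TRUE)
  g <- igraph::add_edges(g, rbind(pairs[, 1], pairs[, 2]))
  igraph::distances(g)
}
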