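#' Reference tree with numbered edges
#'
#' Wraps an [ape::phylo] tree together with an integer edge number for every
#' edge, as used by the jplace placement format. `edge_num[i]` is the number
#' of the i-th row of `phylo$edge`.
#'
#' When no numbering is supplied, edges are numbered `0..E-1` in postorder of
#' the (arbitrarily rooted) tree, i.e. in the row order of
#' `reorder(phylo, "postorder")`. This convention is deterministic for a given
#' Newick string, so truth tables and placements generated by this package
#' always agree.
#'
#' @param phylo an `ape::phylo` tree.
#' @param edge_num optional integer vector of unique edge numbers, parallel
#'   to the rows of `phylo$edge`.
#' @return an object of class `reference_tree`: a list with elements `phylo`
#'   and `edge_num`.
#' @export
reference_tree <- function(phylo, edge_num = NULL) {
  if (!inherits(phylo, "phylo")) stop("'phylo' must be an ape phylo tree")
  n_edge <- nrow(phylo$edge)
  if (is.null(edge_num)) {
    po <- stats::reorder(phylo, "postorder")
    key <- function(e) paste(e[, 1], e[, 2])
    rank <- match(key(phylo$edge), key(po$edge))
    edge_num <- rank - 1L
  }
  edge_num <- as.integer(edge_num)
  if (length(edge_num) != n_edge) {
    stop("'edge_num' must have one entry per edge (", n_edge, ")")
  }
  if (anyDuplicated(edge_num)) stop("edge numbers must be unique")
  structure(list(phylo = phylo, edge_num = edge_num),
            class = "reference_tree")
}

#' @export
print.reference_tree <- function(x, ...) {
  cat("Reference tree:", length(x$phylo$tip.label), "tips,",
      nrow(x$phylo$edge), "numbered edges\n")
  invisible(x)
}

#' Number of tips in a reference tree
#' @param tree a [reference_tree()].
#' @return integer tip count.
#' @export
tip_count <- function(tree) {
  stopifnot(inherits(tree, "reference_tree"))
  length(tree$phylo$tip.label)
}

# Internal: scan for unbalanced parentheses, reporting the 1-based position.
check_newick_balance <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop("malformed Newick: unmatched ')' at position ", i)
      }
    }
  }
  if (depth != 0L) {
    stop("malformed Newick: ", depth, " unclosed '(' at end of string")
  }
  invisible(TRUE)
}

# Marker used to smuggle {N} jplace edge annotations through ape's parser
# by temporarily appending them to node labels.
EDGE_TAG <- "@@"

#' Parse a Newick string with optional jplace edge numbers
#'
#' Accepts plain Newick or the jplace dialect in which every branch carries a
#' `{N}` edge-number annotation after its branch length (e.g. `A:0.1{0}`).
#' When annotations are absent, edges are numbered deterministically in
#' postorder (see [reference_tree()]).
#'
#' @param text a Newick string.
#' @return a [reference_tree()].
#' @examples
#' parse_newick_edges("((A,B),(C,D));")
#' parse_newick_edges("((A:1{0},B:1{1}):1{2},C:1{3}):0{4};")
#' @export
parse_newick_edges <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  check_newick_balance(text)
  has_ann <- grepl("\\{\\d+\\}", text)
  parse_text <- text
  if (has_ann) {
    parse_text <- gsub("([^,():{}]*?)(:[^,():{}]*)?\\{(\\d+)\\}",
                       paste0("\\1", EDGE_TAG, "\\3\\2"), text, perl = TRUE)
  }
  phy <- tryCatch(ape::read.tree(text = parse_text),
                  error = function(e) NULL, warning = function(w) NULL)
  if (is.null(phy)) stop("malformed Newick: failed to parse tree text")
  if (!has_ann) return(reference_tree(phy))

  n_tip <- length(phy$tip.label)
  n_node <- phy$Nnode
  labels <- c(phy$tip.label,
              if (is.null(phy$node.label)) rep("", n_node) else phy$node.label)
  ann <- rep(NA_integer_, n_tip + n_node)
  tagged <- grepl(paste0(EDGE_TAG, "\\d+$"), labels)
  ann[tagged] <- as.integer(sub(paste0(".*", EDGE_TAG, "(\\d+)$"), "\\1",
                                labels[tagged]))
  clean <- sub(paste0(EDGE_TAG, "\\d+$"), "", labels)
  phy$tip.label <- clean[seq_len(n_tip)]
  if (!is.null(phy$node.label)) {
    phy$node.label <- clean[n_tip + seq_len(n_node)]
  }
  edge_num <- ann[phy$edge[, 2]]
  if (anyNA(edge_num)) {
    stop("jplace Newick: ", sum(is.na(edge_num)),
         " edge(s) lack a {N} edge-number annotation")
  }
  reference_tree(phy, edge_num)
}

#' Serialize a reference tree to jplace-style Newick
#'
#' Writes the tree with each edge's number in braces after its branch length,
#' the dialect used inside jplace files. Reparsing with
#' [parse_newick_edges()] preserves edge numbers.
#'
#' @param tree a [reference_tree()].
#' @return a single Newick string.
#' @export
write_newick_edges <- function(tree) {
  stopifnot(inherits(tree, "reference_tree"))
  phy <- tree$phylo
  n_tip <- length(phy$tip.label)
  n_node <- phy$Nnode
  labels <- c(phy$tip.label,
              if (is.null(phy$node.label)) rep("", n_node) else phy$node.label)
  for (i in seq_len(nrow(phy$edge))) {
    child <- phy$edge[i, 2]
    labels[child] <- paste0(labels[child], EDGE_TAG, tree$edge_num[i])
  }
  phy$tip.label <- labels[seq_len(n_tip)]
  phy$node.label <- labels[n_tip + seq_len(n_node)]
  text <- ape::write.tree(phy)
  gsub(paste0("([^,():{}]*?)", EDGE_TAG, "(\\d+)(:[0-9.eE+-]+)?"),
       "\\1\\3{\\2}", text, perl = TRUE)
}
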