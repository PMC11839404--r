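#' Construct a placement set
#'
#' A placement set maps each query id to a data.frame of
#' `(edge_num, lwr)` rows: the branches a placement tool proposed for that
#' query and the likelihood weight ratio (LWR) of each. Row order is
#' preserved as given.
#'
#' @param placements named list of data.frames with columns `edge_num`
#'   (integer >= 0) and `lwr` (in `[0, 1]`).
#' @return an object of class `placement_set`.
#' @export
placement_set <- function(placements) {
  if (length(placements) == 0) {
    return(structure(stats::setNames(list(), character()),
                     class = "placement_set"))
  }
  if (is.null(names(placements)) || any(!nzchar(names(placements)))) {
    stop("placements must be a named list (one entry per query id)")
  }
  for (id in names(placements)) {
    p <- placements[[id]]
    if (!is.data.frame(p) || !all(c("edge_num", "lwr") %in% names(p))) {
      stop("placement entry for '", id,
           "' must be a data.frame with columns edge_num and lwr")
    }
    if (nrow(p) == 0) stop("query '", id, "' has zero placement rows")
    if (any(p$lwr < 0 | p$lwr > 1)) {
      stop("query '", id, "' has like_weight_ratio outside [0, 1]")
    }
    if (any(p$edge_num < 0 | p$edge_num != floor(p$edge_num))) {
      stop("query '", id, "' has a non-integer or negative edge_num")
    }
  }
  structure(placements, class = "placement_set")
}

#' @export
print.placement_set <- function(x, ...) {
  cat("Placement set:", length(x), "queries,",
      sum(vapply(x, nrow, 0L)), "placement rows\n")
  invisible(x)
}

#' Parse a jplace placement file
#'
#' Reads the jplace JSON interchange format (version 3 key layout): the
#' `tree` string with `{N}` edge numbers, the `fields` vector naming the
#' per-placement columns, and the `placements` array. Only `edge_num` and
#' `like_weight_ratio` are consumed; both the `n` and `nm` query-naming
#' styles are accepted, and `nm` multiplicities are ignored (treated as 1).
#'
#' @param path path to a jplace file, or a jplace JSON string.
#' @return a list with elements `tree` (a [reference_tree()]) and
#'   `placements` (a [placement_set()]).
#' @export
parse_jplace <- function(path) {
  text <- if (length(path) == 1 && !grepl("[{\n]", path)) {
    paste(readLines(path, warn = FALSE), collapse = "\n")
  } else {
    paste(path, collapse = "\n")
  }
  doc <- jsonlite::fromJSON(text, simplifyVector = FALSE)
  for (key in c("tree", "placements", "fields")) {
    if (is.null(doc[[key]])) stop("jplace is missing required field '", key, "'")
  }
  fields <- unlist(doc$fields)
  for (key in c("edge_num", "like_weight_ratio")) {
    if (!key %in% fields) {
      stop("jplace 'fields' is missing required field '", key, "'")
    }
  }
  i_edge <- match("edge_num", fields)
  i_lwr <- match("like_weight_ratio", fields)

  tree <- parse_newick_edges(doc$tree)

  placements <- list()
  for (entry in doc$placements) {
    ids <- if (!is.null(entry$n)) {
      unlist(entry$n)
    } else if (!is.null(entry$nm)) {
      vapply(entry$nm, function(x) as.character(x[[1]]), "")
    } else {
      stop("jplace placement entry lacks both 'n' and 'nm' name fields")
    }
    rows <- do.call(rbind, lapply(entry$p, function(p) {
      data.frame(edge_num = as.integer(p[[i_edge]]),
                 lwr = as.numeric(p[[i_lwr]]))
    }))
    unknown <- setdiff(rows$edge_num, tree$edge_num)
    if (length(unknown) > 0) {
      stop("jplace references edge_num(s) absent from the tree: ",
           paste(unknown, collapse = ", "))
    }
    for (id in ids) placements[[id]] <- rows
  }
  list(tree = tree, placements = placement_set(placements))
}

#' Write a placement set to a jplace file
#'
#' Emits a minimal version-3 jplace document with `edge_num` and
#' `like_weight_ratio` fields; round-trips through [parse_jplace()].
#'
#' @param placements a [placement_set()].
#' @param tree the [reference_tree()] the placements refer to.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_jplace <- function(placements, tree, path) {
  stopifnot(inherits(placements, "placement_set"),
            inherits(tree, "reference_tree"))
  entries <- lapply(names(placements), function(id) {
    p <- placements[[id]]
    list(p = lapply(seq_len(nrow(p)),
                    function(i) list(p$edge_num[i], p$lwr[i])),
         n = list(id))
  })
  doc <- list(version = 3,
              tree = write_newick_edges(tree),
              fields = list("edge_num", "like_weight_ratio"),
              placements = entries,
              metadata = list(invocation = "paleoplace"))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
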