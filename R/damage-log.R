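#' Tabulate the damage log
#'
#' Builds the damage-log table: one summary row per read followed by one row
#' per damage event on that read. Event columns (`event_position`,
#' `event_kind`, `event_region`) are `NA` on summary rows; read-level columns
#' are repeated on event rows. The total row count is therefore the number
#' of reads plus the total number of events. Coordinates are 1-based
#' inclusive; `event_position` indexes the read's residue string.
#'
#' @param reads list of damaged reads.
#' @return a data.frame with columns `read_id`, `source_id`, `start`, `end`,
#'   `overhang_side`, `overhang_length`, `event_position`, `event_kind`,
#'   `event_region`.
#' @export
damage_log_table <- function(reads) {
  rows <- lapply(reads, function(r) {
    base <- data.frame(read_id = r$read_id, source_id = r$source_id,
                       start = r$start, end = r$end,
                       overhang_side = r$overhang_side,
                       overhang_length = r$overhang_length,
                       stringsAsFactors = FALSE)
    summary_row <- cbind(base, data.frame(event_position = NA_integer_,
                                          event_kind = NA_character_,
                                          event_region = NA_character_))
    if (nrow(r$events) == 0) return(summary_row)
    event_rows <- cbind(base[rep(1, nrow(r$events)), , drop = FALSE],
                        data.frame(event_position = r$events$position,
                                   event_kind = r$events$kind,
                                   event_region = r$events$region))
    rbind(summary_row, event_rows)
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  if (is.null(out)) {
    out <- data.frame(read_id = character(), source_id = character(),
                      start = integer(), end = integer(),
                      overhang_side = character(), overhang_length = integer(),
                      event_position = integer(), event_kind = character(),
                      event_region = character(), stringsAsFactors = FALSE)
  }
  out
}

#' Write the TSV damage log
#'
#' Tab-separated, UTF-8, `\n` line endings, one header row; optional leading
#' `#` comment lines (used by the command-line tool to record version,
#' parameters, and seed).
#'
#' @param reads list of damaged reads (or a pre-built [damage_log_table()]).
#' @param path output path.
#' @param comments optional character vector written as leading `# ` lines.
#' @return `path`, invisibly.
#' @export
write_damage_log <- function(reads, path, comments = NULL) {
  tab <- if (is.data.frame(reads)) reads else damage_log_table(reads)
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (!is.null(comments)) {
    writeLines(paste0("# ", comments), con, sep = "\n")
  }
  utils::write.table(tab, con, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

#' Read a TSV damage log
#'
#' @param path path written by [write_damage_log()].
#' @return the damage-log data.frame (empty event fields read back as `NA`).
#' @export
read_damage_log <- function(path) {
  out <- utils::read.delim(path, sep = "\t", comment.char = "#",
                           na.strings = "", stringsAsFactors = FALSE)
  out$event_kind <- as.character(out$event_kind)
  out$event_region <- as.character(out$event_region)
  out
}
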