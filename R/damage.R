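#' Briggs-model damage parameters
#'
#' The four probabilities of the Briggs model of post-mortem DNA damage:
#'
#' * `nu` — probability of a backbone nick at each junction between two
#'   consecutive (non-gap) residues; controls fragmentation and hence read
#'   length.
#' * `lam` — success probability of the geometric distribution the
#'   single-stranded overhang length is drawn from (support `0, 1, 2, ...`;
#'   `lam = 1` always gives a zero-length overhang, i.e. no overhang damage).
#' * `delta_ss` — per-base deamination probability inside the single-stranded
#'   overhang.
#' * `delta_ds` — per-base deamination probability in the double-stranded
#'   (protected) remainder of the read.
#'
#' @param nu nick probability in `[0, 1]`.
#' @param lam geometric overhang parameter in `(0, 1]`.
#' @param delta_ss single-stranded deamination probability in `[0, 1]`.
#' @param delta_ds double-stranded deamination probability in `[0, 1]`.
#' @return an object of class `damage_params`.
#' @examples
#' damage_params(nu = 0.025, lam = 0.15, delta_ss = 0.65, delta_ds = 0.015)
#' @export
damage_params <- function(nu, lam, delta_ss, delta_ds) {
  if (!is.numeric(nu) || nu < 0 || nu > 1) stop("'nu' must be in [0, 1]")
  if (!is.numeric(lam) || lam <= 0 || lam > 1) stop("'lam' must be in (0, 1]")
  if (!is.numeric(delta_ss) || delta_ss < 0 || delta_ss > 1) {
    stop("'delta_ss' must be in [0, 1]")
  }
  if (!is.numeric(delta_ds) || delta_ds < 0 || delta_ds > 1) {
    stop("'delta_ds' must be in [0, 1]")
  }
  structure(list(nu = nu, lam = lam, delta_ss = delta_ss,
                 delta_ds = delta_ds),
            class = "damage_params")
}

#' @export
print.damage_params <- function(x, ...) {
  cat(sprintf("Briggs damage parameters: nu=%g lam=%g delta_ss=%g delta_ds=%g\n",
              x$nu, x$lam, x$delta_ss, x$delta_ds))
  invisible(x)
}

#' Read filter settings
#'
#' Filters applied to simulated reads: a minimum read length counted over
#' non-gap sites only (default 15 bp, mimicking the pre-filtering step of
#' typical ancient-DNA analyses), a minimum number of surviving reads per
#' source sequence (default 10; the simulator repeats damage passes,
#' accumulating reads, until this count is reached), and an optional maximum
#' read count applied by uniform downsampling. `max_accumulation_passes`
#' bounds the accumulation loop so it terminates even when a source can
#' never yield enough surviving reads.
#'
#' @param min_length minimum non-gap read length in bp (default 15).
#' @param min_reads minimum surviving reads per source sequence (default 10).
#' @param max_reads optional cap on reads per source (uniform downsampling).
#' @param max_accumulation_passes safety bound on damage passes (default 1000).
#' @return an object of class `read_filters`.
#' @export
read_filters <- function(min_length = 15, min_reads = 10, max_reads = NULL,
                         max_accumulation_passes = 1000) {
  stopifnot(min_length >= 0, min_reads >= 0, max_accumulation_passes >= 1)
  if (!is.null(max_reads)) {
    stopifnot(max_reads >= 1)
    if (min_reads > max_reads) stop("min_reads must be <= max_reads")
  }
  structure(list(min_length = as.integer(min_length),
                 min_reads = as.integer(min_reads),
                 max_reads = if (is.null(max_reads)) NULL else as.integer(max_reads),
                 max_accumulation_passes = as.integer(max_accumulation_passes)),
            class = "read_filters")
}

#' Disable all read filters
#'
#' Convenience constructor for the unfiltered setting (single damage pass,
#' every fragment kept).
#' @return a `read_filters` object with all thresholds off.
#' @export
no_filters <- function() read_filters(min_length = 0, min_reads = 0)

#' Mark nick positions along a sequence
#'
#' Step 1 of the damage simulation: each junction between two consecutive
#' non-gap residues is nicked independently with probability `nu`, scanning
#' left to right. Junction `i` sits after the i-th non-gap residue; gap
#' columns are not physical nucleotides and carry no junctions.
#'
#' @param residues a single sequence string (gaps allowed).
#' @param nu nick probability per junction.
#' @return strictly increasing integer vector of nicked junction indices
#'   (1-based: junction `i` is after the i-th non-gap residue).
#' @export
mark_nicks <- function(residues, nu) {
  stopifnot(is.character(residues), length(residues) == 1)
  if (nu < 0 || nu > 1) stop("'nu' must be in [0, 1]")
  n_res <- sum(!is_gap(strsplit(residues, "", fixed = TRUE)[[1]]))
  n_junction <- max(n_res - 1L, 0L)
  if (n_junction == 0L || nu == 0) return(integer())
  which(stats::runif(n_junction) < nu)
}

#' Break a sequence into fragments at nick points
#'
#' Step 2 of the damage simulation. Fragments are contiguous, ordered, and
#' jointly cover the whole string; gap columns following a nicked junction
#' travel with the preceding fragment (the next fragment starts at the next
#' non-gap residue).
#'
#' @param residues a single sequence string.
#' @param nicks junction indices from [mark_nicks()].
#' @return data.frame with columns `start`, `end`: 1-based inclusive
#'   coordinates into `residues`.
#' @export
fragment_at_nicks <- function(residues, nicks) {
  stopifnot(is.character(residues), length(residues) == 1)
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  nongap <- which(!is_gap(chars))
  nicks <- sort(unique(as.integer(nicks)))
  if (length(nicks) > 0 &&
      (min(nicks) < 1 || max(nicks) > length(nongap) - 1)) {
    stop("nick junction index out of range")
  }
  starts <- c(1L, nongap[nicks + 1L])
  ends <- c(starts[-1L] - 1L, nchar(residues))
  data.frame(start = starts, end = ends)
}

#' Sample overhang side and length
#'
#' Step 3 of the damage simulation. Each read receives a single-stranded
#' overhang on exactly one end: the 5' side with probability 0.5, else the
#' 3' side. The overhang length is geometric with success probability `lam`,
#' counting failures before the first success, so zero-length overhangs are
#' possible and `lam = 1` gives length 0 always. Lengths are capped at the
#' read's non-gap length when the overhang is applied, not here.
#'
#' Draw order per overhang is side then length, so single draws interleave
#' reproducibly inside [damage_sequence()].
#'
#' @param lam geometric success probability in `(0, 1]`.
#' @param n number of overhangs to sample (default 1).
#' @return data.frame with columns `side` (`"five_prime"`/`"three_prime"`)
#'   and `length` (integer >= 0).
#' @export
sample_overhang <- function(lam, n = 1) {
  if (!is.numeric(lam) || lam <= 0 || lam > 1) stop("'lam' must be in (0, 1]")
  side <- character(n)
  len <- integer(n)
  for (i in seq_len(n)) {
    side[i] <- if (stats::runif(1) < 0.5) "five_prime" else "three_prime"
    len[i] <- stats::rgeom(1, lam)
  }
  data.frame(side = side, length = len)
}

# Shared empty events table (avoids repeated data.frame() allocation in the
# per-fragment hot path).
EMPTY_EVENTS <- data.frame(position = integer(), kind = character(),
                           region = character(), stringsAsFactors = FALSE)

# Internal fast path of apply_deamination operating on a character vector.
deaminate_chars <- function(chars, side, overhang_length,
                            delta_ss, delta_ds) {
  nongap <- which(!is_gap(chars))
  L <- min(as.integer(overhang_length), length(nongap))
  overhang_pos <- if (L == 0L) {
    integer()
  } else if (side == "five_prime") {
    nongap[seq_len(L)]
  } else {
    nongap[seq.int(length(nongap) - L + 1L, length(nongap))]
  }
  eligible_chars <- if (side == "five_prime") c("C", "c") else c("G", "g")
  eligible <- which(chars %in% eligible_chars)
  events <- EMPTY_EVENTS
  if (length(eligible) > 0) {
    in_ss <- eligible %in% overhang_pos
    p <- ifelse(in_ss, delta_ss, delta_ds)
    flip <- stats::runif(length(eligible)) < p
    if (any(flip)) {
      pos <- eligible[flip]
      chars[pos] <- chartr("CcGg", "TtAa", chars[pos])
      events <- list(
        position = pos,
        kind = rep(if (side == "five_prime") "C_to_T" else "G_to_A",
                   length(pos)),
        region = ifelse(in_ss[flip], "single_stranded", "double_stranded"))
      class(events) <- "data.frame"
      attr(events, "row.names") <- .set_row_names(length(pos))
    }
  }
  list(chars = chars, events = events)
}

#' Apply deamination damage to one fragment
#'
#' Step 4 of the damage simulation. On a read with a 5' overhang only
#' C -> T substitutions can occur (cytosine deamination read directly);
#' on a read with a 3' overhang only G -> A substitutions occur (the
#' library-preparation complement of deamination in the overhang). Eligible
#' bases inside the overhang flip with probability `delta_ss`, eligible
#' bases elsewhere in the read with probability `delta_ds`. The overhang
#' spans the first (5') or last (3') `L` *non-gap* residues. Gap columns and
#' ambiguity codes are never altered; eligibility is case-insensitive and
#' case is preserved (`c` flips to `t`). Draws are made left to right over
#' the eligible bases.
#'
#' @param residues fragment string (gaps allowed).
#' @param side `"five_prime"` or `"three_prime"`.
#' @param overhang_length non-negative integer; capped at the non-gap length.
#' @param delta_ss,delta_ds deamination probabilities.
#' @return list with `residues` (damaged string) and `events` (data.frame
#'   `position` (1-based index into the fragment string), `kind`
#'   (`"C_to_T"`/`"G_to_A"`), `region` (`"single_stranded"`/`"double_stranded"`)).
#' @export
apply_deamination <- function(residues, side, overhang_length,
                              delta_ss, delta_ds) {
  stopifnot(is.character(residues), length(residues) == 1)
  side <- match.arg(side, c("five_prime", "three_prime"))
  if (overhang_length < 0) stop("'overhang_length' must be >= 0")
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  dd <- deaminate_chars(chars, side, overhang_length, delta_ss, delta_ds)
  list(residues = paste(dd$chars, collapse = ""), events = dd$events)
}

# Internal: construct one damaged read record.
new_damaged_read <- function(read_id, source_id, start, end, residues,
                             overhang_side, overhang_length, events) {
  structure(list(read_id = read_id, source_id = source_id,
                 start = as.integer(start), end = as.integer(end),
                 residues = residues, overhang_side = overhang_side,
                 overhang_length = as.integer(overhang_length),
                 events = events),
            class = "damaged_read")
}

#' @export
print.damaged_read <- function(x, ...) {
  cat(sprintf("<damaged_read %s [%d,%d] of %s; overhang %s L=%d; %d event(s)>\n",
              x$read_id, x$start, x$end, x$source_id, x$overhang_side,
              x$overhang_length, nrow(x$events)))
  invisible(x)
}

#' Run one damage pass over a source sequence
#'
#' Composes the model steps on a single source sequence: mark nicks,
#' fragment at the nick points, then per fragment sample an overhang
#' (side, then length) and apply deamination. Every read keeps its source
#' coordinates and any internal gap columns, so reads from aligned sources
#' stay in alignment.
#'
#' The RNG draw order is fixed and documented: nicks left to right, then per
#' fragment its overhang side, its overhang length, and its deamination
#' draws left to right. Given a seeded RNG the output is reproducible.
#'
#' @param record a one-row sequence record set (see [seq_records()]).
#' @param params a [damage_params()] object.
#' @param pass pass number used in read ids (`<source_id>/<pass>/<ordinal>`).
#' @return list of damaged reads.
#' @export
damage_sequence <- function(record, params, pass = 1L) {
  record <- validate_records(record)
  if (nrow(record) != 1) stop("'record' must contain exactly one sequence")
  if (!nzchar(record$residues)) stop("empty sequence: ", record$id)
  stopifnot(inherits(params, "damage_params"))
  residues <- record$residues
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  frags <- fragment_at_nicks(residues, mark_nicks(residues, params$nu))
  reads <- vector("list", nrow(frags))
  for (i in seq_len(nrow(frags))) {
    # draw order per fragment: overhang side, overhang length, deamination
    side <- if (stats::runif(1) < 0.5) "five_prime" else "three_prime"
    len <- stats::rgeom(1, params$lam)
    dd <- deaminate_chars(chars[frags$start[i]:frags$end[i]], side, len,
                          params$delta_ss, params$delta_ds)
    reads[[i]] <- new_damaged_read(
      read_id = paste(record$id, pass, i, sep = "/"),
      source_id = record$id,
      start = frags$start[i], end = frags$end[i],
      residues = paste(dd$chars, collapse = ""),
      overhang_side = side, overhang_length = len,
      events = dd$events)
  }
  reads
}

#' Non-gap length of a damaged read
#' @param read a damaged read.
#' @return integer count of non-gap sites.
#' @export
nongap_length <- function(read) {
  sum(!is_gap(strsplit(read$residues, "", fixed = TRUE)[[1]]))
}

#' Filter simulated reads
#'
#' Applies, in order: (a) unconditional removal of reads consisting entirely
#' of gap and/or ambiguity characters; (b) removal of reads whose non-gap
#' length is below `min_length`; (c) premasking — when a reference alignment
#' is supplied, removal of reads that share no alignment column in which both
#' the read and at least one reference sequence have a non-gap character
#' (such reads would be unalignable and unplaceable by any method); and
#' (d) if `max_reads` is set and `downsample = TRUE`, uniform downsampling
#' without replacement to `max_reads`.
#'
#' @param reads list of damaged reads from one source sequence.
#' @param filters a [read_filters()] object.
#' @param reference optional reference alignment ([as_alignment()]) whose
#'   columns match the read coordinates.
#' @param downsample apply the `max_reads` cap (default TRUE).
#' @return filtered list of damaged reads.
#' @export
filter_reads <- function(reads, filters, reference = NULL, downsample = TRUE) {
  stopifnot(inherits(filters, "read_filters"))
  ref_mask <- NULL
  if (!is.null(reference)) {
    reference <- as_alignment(reference)
    cols <- do.call(rbind, strsplit(reference$residues, "", fixed = TRUE))
    ref_mask <- apply(!is_gap(cols), 2, any)
  }
  keep <- vapply(reads, function(r) {
    chars <- strsplit(r$residues, "", fixed = TRUE)[[1]]
    informative <- is_unambig(chars)
    if (!any(informative)) return(FALSE)  # all-gap / all-ambiguous
    nongap <- !is_gap(chars)
    if (sum(nongap) < filters$min_length) return(FALSE)
    if (!is.null(ref_mask)) {
      cols <- seq.int(r$start, r$end)
      if (!any(nongap & ref_mask[cols])) return(FALSE)  # premask
    }
    TRUE
  }, logical(1))
  out <- reads[keep]
  if (downsample && !is.null(filters$max_reads) &&
      length(out) > filters$max_reads) {
    out <- out[sort(sample.int(length(out), filters$max_reads))]
  }
  out
}

#' Simulate ancient-DNA damage over a set of sequences
#'
#' The full simulation loop. For each source sequence, damage passes
#' ([damage_sequence()] followed by [filter_reads()]) repeat, accumulating
#' surviving reads, until at least `min_reads` survive or
#' `max_accumulation_passes` is reached; reads are then downsampled to
#' `max_reads` if set. Reaching the pass bound with zero survivors is an
#' error naming the source sequence; reaching it with some survivors returns
#' them with a warning.
#'
#' @param records sequence records to damage.
#' @param params a [damage_params()] object.
#' @param filters a [read_filters()] object (default: paper-style filters,
#'   min length 15 bp and min count 10).
#' @param aligned keep reads aligned to source columns in the output records
#'   (gap-padded to full source length); otherwise gaps are stripped.
#' @param reference optional reference alignment for premasking.
#' @param seed optional integer seed; same seed, same inputs give
#'   byte-identical outputs.
#' @return list with `reads` (list of damaged reads), `records`
#'   (the reads as writable sequence records, see `aligned`), and `log`
#'   (the damage-log data.frame, see [write_damage_log()]).
#' @export
simulate_damage <- function(records, params, filters = read_filters(),
                            aligned = TRUE, reference = NULL, seed = NULL) {
  records <- validate_records(records)
  stopifnot(inherits(params, "damage_params"),
            inherits(filters, "read_filters"))
  if (!is.null(seed)) set.seed(seed)
  all_reads <- list()
  for (i in seq_len(nrow(records))) {
    rec <- records[i, , drop = FALSE]
    acc <- list()
    pass <- 0L
    repeat {
      pass <- pass + 1L
      reads <- damage_sequence(rec, params, pass = pass)
      acc <- c(acc, filter_reads(reads, filters, reference,
                                 downsample = FALSE))
      if (length(acc) >= filters$min_reads) break
      if (pass >= filters$max_accumulation_passes) {
        if (length(acc) == 0) {
          stop("no read from source '", rec$id, "' survived filtering after ",
               pass, " accumulation passes")
        }
        warning("source '", rec$id, "': accumulation bound reached with ",
                length(acc), " < ", filters$min_reads, " surviving reads")
        break
      }
    }
    if (!is.null(filters$max_reads) && length(acc) > filters$max_reads) {
      acc <- acc[sort(sample.int(length(acc), filters$max_reads))]
    }
    all_reads <- c(all_reads, acc)
  }
  list(reads = all_reads,
       records = reads_as_records(all_reads, records, aligned = aligned),
       log = damage_log_table(all_reads))
}

#' Convert damaged reads to writable sequence records
#'
#' In aligned mode each read is padded with gap characters to the full
#' length of its source sequence, at its original coordinates, so alignment
#' column indices are preserved. In unaligned mode gaps are stripped.
#'
#' @param reads list of damaged reads.
#' @param sources the source sequence records (for lengths in aligned mode).
#' @param aligned logical.
#' @return sequence records (see [seq_records()]).
#' @export
reads_as_records <- function(reads, sources, aligned = TRUE) {
  if (length(reads) == 0) {
    return(data.frame(id = character(), desc = character(),
                      residues = character(), stringsAsFactors = FALSE))
  }
  sources <- validate_records(sources)
  src_len <- stats::setNames(nchar(sources$residues), sources$id)
  residues <- vapply(reads, function(r) {
    if (aligned) {
      total <- src_len[[r$source_id]]
      paste0(strrep(GAP_CHAR, r$start - 1L), r$residues,
             strrep(GAP_CHAR, total - r$end))
    } else {
      gsub(GAP_CHAR, "", r$residues, fixed = TRUE)
    }
  }, character(1))
  seq_records(vapply(reads, `[[`, "", "read_id"), residues)
}
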