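# Shared helpers: all fixtures are generated in code, nothing is stored.

tmp_fasta <- function(records, ...) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  write_fasta(records, path, ...)
  path
}

# Chi-square goodness of fit of non-negative counts x against the geometric
# law P(L = k) = (1 - lam)^k * lam, pooling tail bins to expected count >= 5.
geom0_chisq_p <- function(x, lam) {
  n <- length(x)
  kmax <- max(x)
  probs <- (1 - lam)^(0:kmax) * lam
  probs <- c(probs, 1 - sum(probs))          # tail bin
  obs <- c(tabulate(x + 1L, nbins = kmax + 1L), sum(x > kmax))
  # pool from the right until expected counts are all >= 5 (probs decrease,
  # so it suffices that the last two bins clear the threshold)
  while (length(probs) > 2 &&
         (n * probs[length(probs)] < 5 || n * probs[length(probs) - 1] < 5)) {
    k <- length(probs)
    probs[k - 1] <- probs[k - 1] + probs[k]
    obs[k - 1] <- obs[k - 1] + obs[k]
    probs <- probs[-k]; obs <- obs[-k]
  }
  stats::chisq.test(obs, p = probs / sum(probs))$p.value
}

# A fixed small MSA + unrooted tree pair used by harness tests.
harness_fixture <- function(n_taxa = 32, len = 2000, seed = 1) {
  make_fixture(n_taxa, len, gc_content = 0.4, rate = 1, seed = seed)
}

# Build a damaged_read-shaped object directly (for metric unit tests).
fake_read <- function(id, residues, events = NULL, start = 1) {
  if (is.null(events)) {
    events <- data.frame(position = integer(), kind = character(),
                         region = character())
  }
  structure(list(read_id = id, source_id = "src", start = start,
                 end = start + nchar(residues) - 1L, residues = residues,
                 overhang_side = "five_prime", overhang_length = 0L,
                 events = events),
            class = "damaged_read")
}
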