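test_that("nick marking hits the degenerate endpoints of the rate", {
  set.seed(1)
  expect_equal(mark_nicks("ACGTACGT", 0), integer())
  expect_equal(mark_nicks("ACGTA", 1), 1:4)
  expect_equal(mark_nicks("A", 0.5), integer())    # no junction to nick
})

test_that("nick count recovers the binomial mean", {
  set.seed(11)
  n_junction <- 1000 - 1
  nu <- 0.02
  counts <- replicate(1000, length(mark_nicks(strrep("A", 1000), nu)))
  se <- sqrt(n_junction * nu * (1 - nu) / 1000)
  expect_lt(abs(mean(counts) - n_junction * nu), 3 * se)
})

test_that("junctions exist only between non-gap residues", {
  set.seed(3)
  # 4 non-gap residues -> 3 junctions, whatever the gaps do
  expect_equal(mark_nicks("A--C-G-T--", 1), 1:3)
})

test_that("fragmentation cuts at nicks and conserves the sequence", {
  expect_equal(fragment_at_nicks("ACGTAC", integer()),
               data.frame(start = 1L, end = 6L))
  fr <- fragment_at_nicks("ACGTAC", c(2, 4))
  expect_equal(substring("ACGTAC", fr$start, fr$end), c("AC", "GT", "AC"))
  # gap columns after a nick stay with the preceding fragment
  fr2 <- fragment_at_nicks("A-C-GT", 1)
  expect_equal(substring("A-C-GT", fr2$start, fr2$end), c("A-", "C-GT"))
  # conservation for random nick sets
  set.seed(4)
  s <- paste(sample(c("A", "C", "G", "T", "-"), 200, TRUE), collapse = "")
  n_res <- sum(strsplit(s, "")[[1]] != "-")
  for (i in 1:20) {
    nicks <- sort(sample(n_res - 1, sample(0:10, 1)))
    fr <- fragment_at_nicks(s, nicks)
    expect_equal(paste(substring(s, fr$start, fr$end), collapse = ""), s)
    expect_true(all(fr$start[-1] == fr$end[-nrow(fr)] + 1))
  }
})

test_that("overhang sampling matches the zero-indexed geometric law", {
  expect_error(sample_overhang(0), "lam")
  expect_error(sample_overhang(1.5), "lam")
  set.seed(5)
  expect_true(all(sample_overhang(1, 200)$length == 0))
  oh <- sample_overhang(0.5, 1e5)
  mean_se <- sqrt((1 - 0.5) / 0.5^2 / 1e5)
  expect_lt(abs(mean(oh$length) - (1 - 0.5) / 0.5), 3 * mean_se)
  # both sides drawn 50/50
  p5 <- mean(oh$side == "five_prime")
  expect_lt(abs(p5 - 0.5), 3 * sqrt(0.25 / 1e5))
  # full goodness of fit against P(L = k) = (1 - lam)^k lam
  expect_gt(geom0_chisq_p(oh$length, 0.5), 0.001)
})

test_that("deamination respects side, region, and eligibility", {
  set.seed(6)
  none <- apply_deamination("CCGG", "five_prime", 2, 0, 0)
  expect_equal(none$residues, "CCGG")
  expect_equal(nrow(none$events), 0)

  ss_only <- apply_deamination("CCCC", "five_prime", 2, 1, 0)
  expect_equal(ss_only$residues, "TTCC")
  expect_equal(ss_only$events$position, c(1L, 2L))
  expect_equal(unique(ss_only$events$region), "single_stranded")

  # a 5'-overhang read can only take C->T damage; G is never altered
  expect_equal(apply_deamination("ACGT", "five_prime", 4, 1, 1)$residues,
               "ATGT")
  # mirror: 3' overhang, G->A only, overhang counted from the right
  expect_equal(apply_deamination("GGGG", "three_prime", 1, 1, 0)$residues,
               "GGGA")
  # gaps and ambiguity codes are never altered; case is preserved
  lc <- apply_deamination("c-Ng", "five_prime", 4, 1, 1)
  expect_equal(lc$residues, "t-Ng")
  expect_error(apply_deamination("ACGT", "five_prime", -1, 0, 0), ">= 0")
})

test_that("deamination rates are recovered in both regions", {
  set.seed(7)
  n <- 1e5
  dss <- 0.65
  dds <- 0.015
  # half the bases inside a 5' overhang, half outside
  res <- apply_deamination(strrep("C", n), "five_prime", n / 2, dss, dds)
  chars <- strsplit(res$residues, "")[[1]]
  ss_rate <- mean(chars[1:(n / 2)] == "T")
  ds_rate <- mean(chars[(n / 2 + 1):n] == "T")
  expect_lt(abs(ss_rate - dss), 3 * sqrt(dss * (1 - dss) / (n / 2)))
  expect_lt(abs(ds_rate - dds), 3 * sqrt(dds * (1 - dds) / (n / 2)))
})

test_that("a damage pass conserves everything outside its recorded events", {
  set.seed(8)
  src <- random_sequence(5000, 0.5, id = "src")
  reads <- damage_sequence(src, damage_params(0.01, 0.3, 0.8, 0.05))
  expect_gt(length(reads), 1)
  # reverting the recorded events must restore the source exactly
  restored <- vapply(reads, function(r) {
    chars <- strsplit(r$residues, "")[[1]]
    if (nrow(r$events) > 0) {
      chars[r$events$position] <- chartr("TtAa", "CcGg",
                                         chars[r$events$position])
    }
    paste(chars, collapse = "")
  }, "")
  expect_equal(paste(restored, collapse = ""), src$residues)
  # single-damage-type invariant and source-eligibility of events
  for (r in reads) {
    expect_lte(nongap_length(r), nchar(src$residues))
    expect_lte(length(unique(r$events$kind)), 1)
    if (nrow(r$events) > 0) {
      src_chars <- strsplit(substr(src$residues, r$start, r$end), "")[[1]]
      expected <- if (r$overhang_side == "five_prime") c("C", "c") else c("G", "g")
      expect_true(all(src_chars[r$events$position] %in% expected))
    }
  }
})

test_that("the no-damage setting is the identity", {
  src <- seq_records("s", "ACGT-acgtNRY")
  reads <- damage_sequence(src, damage_params(0, 1, 0, 0))
  expect_length(reads, 1)
  expect_equal(reads[[1]]$residues, src$residues)
  expect_equal(nrow(reads[[1]]$events), 0)
  sim <- simulate_damage(src, damage_params(0, 1, 0, 0), no_filters())
  expect_equal(sim$records$residues, src$residues)
})

test_that("interior fragment lengths follow the shifted geometric law", {
  set.seed(9)
  nu <- 0.02
  reads <- damage_sequence(random_sequence(4e5, 0.5, id = "s"),
                           damage_params(nu, 1, 0, 0))
  lens <- vapply(reads, nongap_length, 0L)
  interior <- lens[c(-1, -length(lens))]
  # K - 1 is geometric on {0, 1, ...} with success probability nu
  expect_gt(geom0_chisq_p(interior - 1L, nu), 0.001)
})

test_that("read filters drop uninformative and short reads and premask", {
  f <- read_filters(min_length = 3, min_reads = 0)
  reads <- list(fake_read("allgap", "---N--"),
                fake_read("short", "A--C"),
                fake_read("ok", "AC-GT"))
  kept <- filter_reads(reads, f)
  expect_equal(vapply(kept, `[[`, "", "read_id"), "ok")

  # premasking: read overlaps reference non-gap columns or is dropped
  ref <- seq_records(c("r1", "r2"), c("AAAA----", "-AAA----"))
  reads2 <- list(fake_read("inside", "GGG", start = 1),
                 fake_read("outside", "GGG", start = 6))
  kept2 <- filter_reads(reads2, read_filters(0, 0), reference = ref)
  expect_equal(vapply(kept2, `[[`, "", "read_id"), "inside")
})

test_that("downsampling is uniform without replacement", {
  reads <- lapply(1:50, function(i) fake_read(paste0("r", i), "ACGT"))
  f <- read_filters(min_length = 0, min_reads = 0, max_reads = 10)
  set.seed(10)
  reps <- 5000
  counts <- integer(50)
  for (i in seq_len(reps)) {
    kept <- filter_reads(reads, f)
    expect_length(kept, 10)
    idx <- as.integer(sub("r", "", vapply(kept, `[[`, "", "read_id")))
    counts[idx] <- counts[idx] + 1L
  }
  # each read retained with probability 10/50
  p <- stats::chisq.test(counts, p = rep(1 / 50, 50))$p.value
  expect_gt(p, 0.001)
})

test_that("simulation honors default count and length thresholds", {
  set.seed(12)
  src <- random_sequence(2000, 0.4, id = "s")
  sim <- simulate_damage(src, damage_params(0.001, 1, 0, 0), read_filters())
  expect_gte(length(sim$reads), 10)
  expect_true(all(vapply(sim$reads, nongap_length, 0L) >= 15))
})

test_that("simulation is byte-identical under a fixed seed", {
  src <- random_sequence(3000, 0.4, id = "s")
  fa <- replicate(2, withr::local_tempfile(fileext = ".fasta"))
  lg <- replicate(2, withr::local_tempfile(fileext = ".tsv"))
  for (i in 1:2) {
    sim <- simulate_damage(src, damage_params(0.02, 0.3, 0.6, 0.02),
                           read_filters(), seed = 99)
    write_fasta(sim$records, fa[i])
    write_damage_log(sim$log, lg[i])
  }
  expect_equal(unname(tools::md5sum(fa[1])), unname(tools::md5sum(fa[2])))
  expect_equal(unname(tools::md5sum(lg[1])), unname(tools::md5sum(lg[2])))
})

test_that("accumulation failure names the offending source", {
  src <- seq_records("tiny", "ACGT")  # can never reach min_length 15
  expect_error(
    simulate_damage(src, damage_params(0, 1, 0, 0),
                    read_filters(min_length = 15, min_reads = 1,
                                 max_accumulation_passes = 3)),
    "tiny")
})

test_that("aligned output preserves source columns; unaligned strips gaps", {
  src <- seq_records("s", "AC--GTACGT")
  p <- damage_params(0, 1, 0, 0)
  aligned <- simulate_damage(src, p, no_filters(), aligned = TRUE)
  expect_equal(nchar(aligned$records$residues), nchar(src$residues))
  unaligned <- simulate_damage(src, p, no_filters(), aligned = FALSE)
  expect_false(grepl("-", unaligned$records$residues))
})
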