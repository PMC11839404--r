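test_that("pruning a quartet leaf merges the sibling branch as truth", {
  tree <- parse_newick_edges("((A,B),(C,D));")
  msa <- as_alignment(seq_records(c("A", "B", "C", "D"),
                                  c("ACGTA", "ACGTT", "ACCTA", "ACCTT")))
  scen <- prune_random_subtree(tree, msa, min_remaining_taxa = 3, tips = "D")
  expect_equal(sort(scen$pruned_tips), "D")
  expect_equal(length(scen$pruned_tree$phylo$tip.label), 3)
  expect_equal(scen$query_records$id, "D")
  # tip conservation: removed + remaining partition the original tips
  expect_setequal(c(scen$pruned_tips, scen$reference_msa$id),
                  c("A", "B", "C", "D"))
  # the true edge is the merged branch formerly leading toward C
  pt <- scen$pruned_tree
  c_edge <- pt$edge_num[which(pt$phylo$edge[, 2] ==
                              match("C", pt$phylo$tip.label))]
  expect_equal(scen$true_edge, c_edge)
})

test_that("pruning errors when constraints leave no eligible edge", {
  tree <- parse_newick_edges("((A,B),(C,D));")
  msa <- as_alignment(seq_records(c("A", "B", "C", "D"),
                                  rep("ACGT", 4)))
  expect_error(prune_random_subtree(tree, msa, min_remaining_taxa = 4),
               "no prunable edge")
})

test_that("eligible subtrees are chosen uniformly", {
  set.seed(30)
  fx <- make_fixture(10, 50, seed = 77)
  phy <- fx$tree$phylo
  # independent enumeration of eligible clades: <= 2 tips removed (25% of
  # 10, floored), >= 4 remaining, binary parent that is not the root
  n <- 10
  desc <- lapply(seq_len(n + phy$Nnode), function(nd) {
    if (nd <= n) nd else unlist(phangorn::Descendants(phy, nd, "tips"))
  })
  parent_of <- function(nd) phy$edge[phy$edge[, 2] == nd, 1]
  eligible <- Filter(function(nd) {
    p <- parent_of(nd)
    length(p) == 1 && p != n + 1 &&
      sum(phy$edge[, 1] == p) == 2 && length(desc[[nd]]) <= 2
  }, seq_len(n + phy$Nnode)[-(n + 1)])
  keys <- vapply(eligible,
                 function(nd) paste(sort(phy$tip.label[desc[[nd]]]),
                                    collapse = "+"), "")
  reps <- 3000
  seen <- vapply(seq_len(reps), function(i) {
    scen <- prune_random_subtree(fx$tree, fx$alignment)
    paste(sort(scen$pruned_tips), collapse = "+")
  }, "")
  expect_setequal(unique(seen), keys)
  counts <- table(factor(seen, levels = keys))
  p <- stats::chisq.test(counts, p = rep(1 / length(keys), length(keys)))$p.value
  expect_gt(p, 0.001)
})

test_that("the naive placer recovers an identical leaf and normalizes LWR", {
  fx <- make_fixture(12, 300, seed = 41)
  scen <- prune_random_subtree(fx$tree, fx$alignment, tips = NULL)
  ref <- scen$reference_msa
  # a query that IS a reference sequence places on that leaf's pendant edge
  q <- seq_records("copycat", ref$residues[3])
  ps <- naive_placer(q, ref, scen$pruned_tree)
  pt <- scen$pruned_tree
  expected_edge <- pt$edge_num[which(pt$phylo$edge[, 2] ==
                                     match(ref$id[3], pt$phylo$tip.label))]
  expect_equal(ps[["copycat"]]$edge_num[1], expected_edge)
  expect_equal(sum(ps[["copycat"]]$lwr), 1)
  expect_equal(nrow(ps[["copycat"]]), 3)
})

test_that("the naive placer breaks exact ties toward the lowest edge number", {
  tree <- parse_newick_edges("((A:1,B:1):1,(C:1,D:1):1);")
  msa <- as_alignment(seq_records(c("A", "B", "C", "D"),
                                  c("AAAA", "AAAA", "CCCC", "GGGG")))
  scen <- list()  # place on the full tree directly
  q <- seq_records("q", "AAAT")  # equidistant to A and B
  ps <- naive_placer(q, msa, tree, top_k = 2)
  pa <- tree$edge_num[which(tree$phylo$edge[, 2] == 1)]
  pb <- tree$edge_num[which(tree$phylo$edge[, 2] == 2)]
  expect_equal(ps[["q"]]$edge_num[1], min(pa, pb))
})

test_that("queries with no reference overlap are skipped with a warning", {
  msa <- as_alignment(seq_records(c("A", "B", "C"),
                                  c("ACGT----", "AGGT----", "ACTT----")))
  tree <- parse_newick_edges("(A,B,C);")
  q <- seq_records("ghost", "----ACGT")
  expect_warning(ps <- naive_placer(q, msa, tree), "ghost")
  expect_length(ps, 0)
})

test_that("the experiment table is one row per pruning x grid point x read", {
  fx <- harness_fixture(16, 400, seed = 2)
  grid <- damage_grid(nu = c(0, 0.02), lam = 1, delta_ss = 0, delta_ds = 0)
  res <- run_experiment(fx$alignment, fx$tree, grid, read_filters(),
                        n_prunings = 3, seed = 7)
  expect_true(all(c("pruning", "nu", "lam", "delta_ss", "delta_ds",
                    "read_id", "nd", "end", "normalized_end") %in% names(res)))
  expect_setequal(unique(res$pruning), 1:3)
  # every (pruning, grid point) cell is present, with >= 10 reads per query
  cells <- unique(res[c("pruning", "nu")])
  expect_equal(nrow(cells), 3 * 2)
  for (i in seq_len(nrow(cells))) {
    cell <- res[res$pruning == cells$pruning[i] & res$nu == cells$nu[i], ]
    n_queries <- length(unique(sub("/[0-9]+/[0-9]+$", "", cell$read_id)))
    expect_gte(nrow(cell), 10 * n_queries)
  }
})

test_that("the experiment is deterministic given a seed", {
  fx <- harness_fixture(12, 300, seed = 3)
  grid <- damage_grid(0.01, 0.3, 0.5, 0.01)
  r1 <- run_experiment(fx$alignment, fx$tree, grid, n_prunings = 2, seed = 5)
  r2 <- run_experiment(fx$alignment, fx$tree, grid, n_prunings = 2, seed = 5)
  expect_identical(r1, r2)
})
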