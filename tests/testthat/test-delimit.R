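test_that("gap_report tabulates sorted distances and the histogram", {
  d3 <- matrix(0.1, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(d3) <- 0
  rep3 <- gap_report(d3, n_bins = 10)
  expect_equal(rep3$distances, rep(0.1, 3))
  expect_equal(sum(rep3$histogram$counts), 3)
  expect_equal(sum(rep3$histogram$counts > 0), 1)

  d2 <- matrix(c(0, 0.05, 0.05, 0), 2, 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  expect_length(gap_report(d2)$distances, 1)
})

test_that("a two-species simulation produces a bimodal gap report", {
  sim <- simulate_species_sequences(2, 6, L = 600, intra = 0.008,
                                    inter = 0.09, seed = 3)
  dm <- distance_matrix(sim$records, "K2P")
  rep <- gap_report(dm, n_bins = 20, prior_P = 0.01)
  expect_false(is.null(rep$gap_interval))
  # an empty histogram bin range sits between the modes
  mids <- (rep$histogram$breaks[-1] + rep$histogram$breaks[-21]) / 2
  inside <- mids > rep$gap_interval[1] & mids < rep$gap_interval[2]
  expect_true(any(rep$histogram$counts[inside] == 0))
  # histogram counts conserve the number of pairs
  expect_equal(sum(rep$histogram$counts), choose(12, 2))
})

test_that("detect_gap finds the first qualifying interval above the prior", {
  d <- sort(c(seq(0.001, 0.01, by = 0.001), seq(0.08, 0.10, by = 0.005)))
  thr <- detect_gap(d, prior_P = 0.005, X = 1.5)
  expect_gt(thr, 0.01)
  expect_lt(thr, 0.08)

  # uniform grid: no interval stands out
  expect_true(is.na(detect_gap(seq(0.001, 0.02, by = 0.001),
                               prior_P = 0.005, X = 1.5)))
  # nothing to scan above the prior
  expect_true(is.na(detect_gap(c(0.001, 0.002, 0.003), prior_P = 0.1)))
  expect_error(detect_gap(c(0.05, 0.01), prior_P = 0.01), "sorted")
})

test_that("single linkage equals the connected components of the gap graph", {
  all0 <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  expect_equal(single_linkage_partition(all0, 0.01)$n_groups, 1)

  # two tight pairs
  labels <- c("a1", "a2", "b1", "b2")
  d <- matrix(0.09, 4, 4, dimnames = list(labels, labels))
  diag(d) <- 0
  d["a1", "a2"] <- d["a2", "a1"] <- 0.005
  d["b1", "b2"] <- d["b2", "b1"] <- 0.005
  part <- single_linkage_partition(d, 0.05)
  expect_equal(part$n_groups, 2)
  expect_equal(part$assignment[["a1"]], part$assignment[["a2"]])
  expect_false(part$assignment[["a1"]] == part$assignment[["b1"]])

  # threshold below every distance: all singletons
  expect_equal(single_linkage_partition(d, 0.001)$n_groups, 4)
})

test_that("single linkage matches the transitive-closure oracle", {
  for (seed in 1:12) {
    n <- sample(3:7, 1)
    dm <- random_dist_matrix(n, seed = seed)
    for (thr in c(0.02, 0.05, 0.1, 0.15, 0.25)) {
      part <- single_linkage_partition(dm, thr)
      expect_equal(part$assignment, oracle_single_linkage(dm, thr))
    }
  }
})

test_that("group count is non-increasing in the linkage threshold", {
  dm <- random_dist_matrix(7, seed = 21)
  thresholds <- seq(0.01, 0.25, by = 0.01)
  ng <- vapply(thresholds,
               function(t) single_linkage_partition(dm, t)$n_groups, 0L)
  expect_true(all(diff(ng) <= 0))
})

test_that("recursion resolves nested divergences the first pass misses", {
  # Three species. A and B are tight (intra <= 0.008) and diverge at ~0.04;
  # C is internally variable (intra 0.015-0.035), which fills the pooled
  # distance distribution below the A|B divergence so the first pass can
  # only split at the larger gap (~0.04 vs ~0.12); the A|B split is then
  # found by recursion inside the A+B group.
  set.seed(107)
  labels <- c(paste0("a", 1:4), paste0("b", 1:4), paste0("c", 1:5))
  n <- length(labels)
  dm <- matrix(0, n, n, dimnames = list(labels, labels))
  fill <- function(g1, g2, lo, hi) {
    for (i in g1) for (j in g2) {
      if (i < j) dm[i, j] <<- dm[j, i] <<- stats::runif(1, lo, hi)
    }
  }
  a <- 1:4; b <- 5:8; cc <- 9:13
  fill(a, a, 0.002, 0.008); fill(b, b, 0.002, 0.008)
  fill(a, b, 0.038, 0.042)
  fill(a, cc, 0.11, 0.125); fill(b, cc, 0.11, 0.125)
  # C's intraspecific distances climb evenly to just below the A|B
  # divergence, so the pooled distribution has no gap before ~0.04
  cvals <- seq(0.004, 0.034, length.out = 10)
  k <- 0
  for (i in cc) for (j in cc) {
    if (i < j) { k <- k + 1; dm[i, j] <- dm[j, i] <- cvals[k] }
  }
  first_pass <- recursive_delimit(dm, prior_P = 0.01, max_depth = 1)
  expect_equal(first_pass$n_groups, 2)
  part <- recursive_delimit(dm, prior_P = 0.01)
  expect_equal(part$n_groups, 3)

  # single species: one group at every prior
  one <- simulate_species_sequences(1, 8, L = 600, intra = 0.005,
                                    inter = 0.5, seed = 19)
  dmo <- distance_matrix(one$records, "K2P")
  for (p in c(0.005, 0.01, 0.05)) {
    expect_equal(recursive_delimit(dmo, p)$n_groups, 1)
  }

  # clear two-species gap: identical at depth 1 and depth 10
  two <- simulate_species_sequences(2, 6, L = 600, intra = 0.005,
                                    inter = 0.08, seed = 20)
  dmt <- distance_matrix(two$records, "K2P")
  p1 <- recursive_delimit(dmt, 0.01, max_depth = 1)
  p10 <- recursive_delimit(dmt, 0.01, max_depth = 10)
  expect_equal(p1$assignment, p10$assignment)
  expect_equal(p1$n_groups, 2)
})

test_that("partition group ids are the lexicographically smallest member", {
  sim <- simulate_species_sequences(2, 4, L = 400, intra = 0.005,
                                    inter = 0.08, seed = 23)
  dm <- distance_matrix(sim$records, "K2P")
  part <- recursive_delimit(dm, 0.01)
  for (g in unique(part$assignment)) {
    expect_equal(g, min(names(part$assignment)[part$assignment == g]))
  }
})

test_that("the prior sweep recovers four species at compatible priors", {
  sim <- simulate_species_sequences(4, 8, L = 600, intra = 0.005,
                                    inter = 0.08, seed = 41)
  dm <- distance_matrix(sim$records, "K2P")
  sweep <- prior_sweep(dm)
  expect_equal(nrow(sweep$summary), 10)
  expect_true(all(diff(sweep$summary$prior_P) > 0))
  compatible <- sweep$summary$prior_P >= 0.005 & sweep$summary$prior_P <= 0.03
  expect_true(all(sweep$summary$n_groups[compatible] == 4))
  # a prior above the largest distance collapses everything into one group
  expect_equal(recursive_delimit(dm, max(dm) * 1.1)$n_groups, 1)
})

test_that("partition and sweep TSV writers emit well-formed tables", {
  sim <- simulate_species_sequences(2, 4, L = 400, intra = 0.005,
                                    inter = 0.08, seed = 6)
  dm <- distance_matrix(sim$records, "K2P")
  part <- recursive_delimit(dm, 0.01)
  p1 <- withr::local_tempfile(fileext = ".tsv")
  write_partition(part, p1)
  tab <- read.delim(p1)
  expect_equal(nrow(tab), 8)
  expect_named(tab, c("specimen_id", "group_id", "prior_P", "threshold"))

  sw <- prior_sweep(dm, n_steps = 4)
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_sweep(sw, p2)
  expect_equal(nrow(read.delim(p2)), 4)
})
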