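test_that("hit tables are schema- and range-checked on read", {
  hits <- do.call(rbind, lapply(1:5, function(i)
    toy_hit(paste("Salicornia sp", i), bitscore = 1000 - i)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_hit_table(hits, path)
  expect_equal(nrow(read_hit_table(path)), 5)

  bad <- hits; bad$pident[1] <- 101
  write_hit_table(bad, path)
  expect_error(read_hit_table(path), "pident")

  write_hit_table(hits[, setdiff(names(hits), "family")], path)
  expect_error(read_hit_table(path), "schema")

  write_hit_table(hits[0, ], path)
  expect_warning(empty <- read_hit_table(path), "empty")
  expect_equal(nrow(empty), 0)
})

test_that("the weighted score re-weights by coverage over identity", {
  expect_equal(weighted_score(200, 100, 100), 200)
  expect_equal(weighted_score(200, 98, 96), 204.1667, tolerance = 1e-4)
  expect_equal(weighted_score(0, 50, 99), 0)
  expect_error(weighted_score(100, 90, 0), "identity")
  # neutral exactly when cover equals identity
  for (v in c(80, 90.5, 100)) expect_equal(weighted_score(150, v, v), 150)
})

test_that("identity tiers follow the upper-bound-wins boundaries", {
  expect_equal(identity_tier(96), "High")
  expect_equal(identity_tier(95), "High")
  expect_equal(identity_tier(94.99), "Medium")
  expect_equal(identity_tier(90), "Medium")
  expect_equal(identity_tier(88), "Low")
})

test_that("candidate sets truncate and re-rank per method", {
  hits <- do.call(rbind, lapply(1:3, function(i)
    toy_hit(paste("Salicornia sp", i), bitscore = 900 + i)))
  cs <- candidate_set(hits, "simple")
  expect_equal(nrow(cs), 3)
  expect_equal(cs$bitscore, c(903, 902, 901))
  expect_equal(cs$score, cs$bitscore)

  many <- do.call(rbind, lapply(1:150, function(i)
    toy_hit(paste("Salicornia sp", i), bitscore = 1000 - i)))
  expect_equal(nrow(candidate_set(many, "optimized")), 100)
  expect_equal(nrow(candidate_set(many, "simple")), 10)

  # equal max_score: optimized re-ranks by weighted score, tie-break after
  tie <- rbind(toy_hit("Salicornia alpha", bitscore = 500, qcovs = 100,
                       pident = 99),
               toy_hit("Salicornia beta", bitscore = 500, qcovs = 100,
                       pident = 90))
  cso <- candidate_set(tie, "optimized")
  expect_equal(cso$species[1], "Salicornia beta")  # 500*100/90 > 500*100/99
  expect_gt(cso$score[1], cso$score[2])
})

test_that("the 1% deviation set uses the active ranking score", {
  cands <- rbind(toy_hit("Salicornia alpha"), toy_hit("Salicornia beta"),
                 toy_hit("Salicornia gamma"))
  cands$score <- c(204.2, 203.0, 200.0)
  expect_equal(species_within_deviation(cands),
               c("Salicornia alpha", "Salicornia beta"))
  one <- toy_hit("Salicornia alpha"); one$score <- 100
  expect_equal(species_within_deviation(one), "Salicornia alpha")
})

test_that("the decision ladder reproduces hand-derived assignments", {
  for (case in ladder_cases) {
    for (method in c("simple", "optimized")) {
      a <- assign_taxon("q1", case$hits, method, synonym_groups = syn6)
      expect_equal(a$rank, case$rank, label = paste(case$name, method))
      expect_equal(a$taxon, case$taxon, label = paste(case$name, method))
      if (a$rank == "species") expect_equal(a$n_candidate_species, 1L)
    }
  }
})

test_that("an empty hit list yields an explicit unassigned record", {
  a <- assign_taxon("qx", toy_hit("x")[0, ], "simple")
  expect_equal(a$rank, "unassigned")
  expect_equal(a$n_candidate_species, 0L)
})

test_that("simple and optimized agree when cover equals identity, <=10 hits", {
  set.seed(77)
  for (i in 1:10) {
    n <- sample(2:10, 1)
    v <- round(stats::runif(n, 85, 100), 1)
    hits <- do.call(rbind, lapply(seq_len(n), function(j)
      toy_hit(paste("Salicornia sp", sample(1:4, 1)),
              bitscore = round(stats::runif(1, 500, 1000), 1),
              qcovs = v[j], pident = v[j])))
    a1 <- assign_taxon("q1", hits, "simple", syn6)
    a2 <- assign_taxon("q1", hits, "optimized", syn6)
    expect_equal(a1$rank, a2$rank)
    expect_equal(a1$taxon, a2$taxon)
  }
})

test_that("noise-free synthetic hit tables recover the truth exactly", {
  sim <- simulate_species_sequences(4, 8, seed = 51)
  ht <- simulate_hit_table(sim$truth, score_noise_sd = 0, decoy_rate = 0,
                           seed = 51)
  for (method in c("simple", "optimized")) {
    asg <- assign_all(ht, method)
    expect_true(all(asg$rank == "species"))
    expect_equal(asg$taxon,
                 unname(paste("Salicornia",
                              sim$truth$species[asg$query_id])))
  }
})

test_that("near-top synonym-group decoys produce species_group calls", {
  truth <- list(species = setNames(rep("persica", 6), paste0("q", 1:6)))
  names(truth$species) <- paste0("q", 1:6)
  ht <- simulate_hit_table(truth, decoy_rate = 0.999, seed = 5,
                           species_names = c(persica = "Salicornia persica"),
                           synonym_groups = syn6)
  asg <- assign_all(ht, "optimized", syn6)
  expect_true(all(asg$rank == "species_group"))
  expect_true(all(asg$taxon == "S. europaea complex"))
})

test_that("combination consensus picks the most specific majority rank", {
  asg <- rbind(
    assign_taxon("q1", toy_hit("Salicornia bigelovii", pident = 93), "simple"),
    assign_taxon("q1", toy_hit("Salicornia bigelovii", pident = 99), "simple"))
  asg$marker <- c("matK", "rbcL")  # genus call + species call, same genus
  expect_equal(asg$rank, c("genus", "species"))
  cons <- combine_assignments(asg, "core")
  expect_equal(cons$rank, "genus")
  expect_equal(cons$taxon, "Salicornia")

  # both species-level and agreeing: species wins
  asg2 <- rbind(
    assign_taxon("q1", toy_hit("Salicornia bigelovii", pident = 99), "simple"),
    assign_taxon("q1", toy_hit("Salicornia bigelovii", pident = 98), "simple"))
  asg2$marker <- c("matK", "rbcL")
  cons2 <- combine_assignments(asg2, "core")
  expect_equal(cons2$rank, "species")
  expect_equal(cons2$taxon, "Salicornia bigelovii")

  # species-level disagreement between the two members: no strict majority
  # at species, consensus degrades to the shared genus
  asg3 <- rbind(
    assign_taxon("q1", toy_hit("Salicornia bigelovii", pident = 99), "simple"),
    assign_taxon("q1", toy_hit("Salicornia rubra", pident = 99), "simple"))
  asg3$marker <- c("matK", "rbcL")
  cons3 <- combine_assignments(asg3, "core")
  expect_equal(cons3$rank, "genus")
  expect_equal(cons3$taxon, "Salicornia")
})

test_that("efficiency percentages sum to 100 within each label", {
  sim <- simulate_species_sequences(3, 5, seed = 12)
  ht <- simulate_hit_table(sim$truth, decoy_rate = 0.5, seed = 12,
                           synonym_groups = syn6)
  asg <- assign_all(ht, "optimized", syn6)
  eff <- summarize_efficiency(asg)
  for (lab in unique(eff$label)) {
    expect_equal(sum(eff$percent[eff$label == lab]), 100, tolerance = 0.01)
  }
  expect_equal(nrow(summarize_efficiency(asg[0, ])), 0)

  ten <- do.call(rbind, lapply(1:10, function(i)
    assign_taxon(paste0("q", i), toy_hit("Salicornia bigelovii"), "simple")))
  ten$marker <- "rbcL"
  eff10 <- summarize_efficiency(ten)
  expect_equal(eff10$percent[eff10$rank == "species"], 100)
})
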