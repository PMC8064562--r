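test_that("ESRI ASCII grids round-trip exactly, nodata included", {
  m <- matrix(c(1.5, 2.25, NA, -3.125), 2, 2)
  g <- env_grid(m, xllcorner = 10, yllcorner = 20, cellsize = 0.5,
                name = "bio01")
  path <- withr::local_tempfile(fileext = ".asc")
  write_esri_ascii(g, path)
  back <- read_esri_ascii(path, name = "bio01")
  expect_equal(back$values, g$values)
  expect_equal(back$xllcorner, 10)
  expect_equal(back$cellsize, 0.5)
  # second write is byte-identical (stable formatting)
  path2 <- withr::local_tempfile(fileext = ".asc")
  write_esri_ascii(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("value-count mismatches are format errors", {
  path <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("ncols 2", "nrows 2", "xllcorner 0", "yllcorner 0",
               "cellsize 1", "NODATA_value -9999", "1 2 3"), path)
  expect_error(read_esri_ascii(path), "format error")
})

test_that("extraction uses half-open cells and drops nodata/outside points", {
  m <- matrix(1:4, 2, 2, byrow = TRUE)  # row 1 (north): 1 2; row 2: 3 4
  g <- env_grid(m, xllcorner = 0, yllcorner = 0, cellsize = 1, name = "v1")
  occ <- data.frame(lon = c(0.5, 1.5, 0.5, 1.0, 2.5),
                    lat = c(1.5, 0.5, 0.5, 1.0, 0.5))
  out <- extract_env(occ, list(g))
  # cell centers: (0.5,1.5)->1, (1.5,0.5)->4, (0.5,0.5)->3
  expect_equal(unname(out$env[1:3, 1]), c(1, 4, 3))
  # shared-edge point (1,1) goes to the higher-index (east/north) cell: 2
  expect_equal(unname(out$env[4, 1]), 2)
  expect_equal(out$dropped$reason, "outside extent")

  gn <- g; gn$values[1, 1] <- NA
  out2 <- extract_env(data.frame(lon = 0.5, lat = 1.5), list(gn))
  expect_equal(nrow(out2$env), 0)
  expect_equal(out2$dropped$reason, "nodata cell")

  g2 <- env_grid(m, xllcorner = 5, yllcorner = 0, cellsize = 1)
  expect_error(extract_env(occ, list(g, g2)), "mismatched extents")
})

test_that("reverse jackknife flags the planted extreme only", {
  flags <- reverse_jackknife_outliers(c(1, 2, 3, 4, 100))
  expect_equal(which(flags), 5L)
  expect_equal(sum(reverse_jackknife_outliers(c(1, 2, 3, 4, 5))), 0)
  expect_equal(sum(reverse_jackknife_outliers(rep(7, 6))), 0)
  expect_error(reverse_jackknife_outliers(1:4), "5")
  # low-end extreme, order-independence
  v <- c(500, 10, 11, 12, 13, 14)
  expect_equal(which(reverse_jackknife_outliers(v)), 1L)
  expect_equal(sum(reverse_jackknife_outliers(sample(v))), 1)
})

test_that("occurrence cleaning applies the 3-of-19 variable rule", {
  # evenly spaced benign values (no natural outliers), planted extremes
  n <- 30
  env <- matrix(rep(seq(0, 2.9, by = 0.1), 19), n, 19,
                dimnames = list(NULL, sprintf("bio%02d", 1:19)))
  env[1, 1:3] <- 60    # outlying in exactly 3 variables
  env[2, 4:5] <- 60    # outlying in exactly 2
  cl <- clean_occurrences(env)
  expect_equal(cl$n_flagged[1], 3)
  expect_equal(cl$n_flagged[2], 2)
  expect_false(cl$keep[1])
  expect_true(cl$keep[2])
  expect_true(all(cl$keep[-1]))
})

test_that("train/test splits are sized, disjoint and reproducible", {
  s <- split_train_test(100, 0.25, seed = 3)
  expect_length(s$test, 25)
  expect_length(s$train, 75)
  expect_length(intersect(s$train, s$test), 0)
  expect_length(split_train_test(5, 0.25, seed = 1)$test, 1)
  expect_identical(split_train_test(50, 0.25, seed = 7),
                   split_train_test(50, 0.25, seed = 7))
  expect_error(split_train_test(10, 0), "test_fraction")
  expect_error(split_train_test(10, 1.2), "test_fraction")
})

test_that("maxent activates an informative variable with the right sign", {
  set.seed(5)
  bg <- cbind(v1 = stats::rnorm(2000), v2 = stats::rnorm(2000))
  # presences concentrated at high v1
  pres <- cbind(v1 = stats::rnorm(200, 2), v2 = stats::rnorm(200))
  m <- fit_maxent(pres, bg, beta = 0.5)
  expect_gt(m$lambda[["v1:l"]], 0)
  expect_equal(sum(m$background_raw), 1, tolerance = 1e-6)
  # presences distributed as the background: everything shrinks to zero
  m0 <- fit_maxent(bg[1:200, ], bg, beta = 1)
  expect_true(all(abs(m0$lambda) < 0.05))
  # penalty dominance drives the weights exactly to zero
  mb <- fit_maxent(pres, bg, beta = 1e6)
  expect_true(all(mb$lambda == 0))
})

test_that("suitability predictions normalize and preserve ranking", {
  land <- simulate_landscape(n_vars = 2, nrows = 20, ncols = 20,
                             coeffs = c(4, 0), n_presence = 60, seed = 13)
  ext <- extract_env(land$occurrences, land$grids)
  bg <- sample_background(land$grids, seed = 1)
  m <- fit_maxent(ext$env, bg, beta = 0.5)
  pred <- predict_suitability(m, land$grids)
  v <- pred$raw$values
  expect_true(all(is.na(v[1, ])))  # nodata ring propagates
  # background raw scores sum to one; grid raw values are the same scores
  expect_equal(sum(m$background_raw), 1, tolerance = 1e-6)
  expect_equal(sum(v, na.rm = TRUE), 1, tolerance = 1e-6)
  cum <- pred$cumulative$values
  expect_true(all(cum >= 0 & cum <= 100, na.rm = TRUE))
  # a uniform model scores every valid cell equally
  mu <- fit_maxent(ext$env, bg, beta = 1e6)
  pu <- predict_suitability(mu, land$grids)
  vals <- pu$raw$values[!is.na(pu$raw$values)]
  expect_equal(max(vals) - min(vals), 0, tolerance = 1e-12)
  # a monotone single-variable model ranks cells like the variable itself
  m1 <- fit_maxent(ext$env[, 1, drop = FALSE], bg[, 1, drop = FALSE],
                   beta = 0.5, quadratic = FALSE)
  sc <- maxent_scores(m1, bg[, 1, drop = FALSE])
  expect_equal(order(sc), order(bg[, 1]))
})

test_that("AUC follows the rank/tie convention and bands", {
  expect_equal(auc(c(5, 6), c(1, 2, 3)), 1)
  expect_equal(auc(rep(1, 5), rep(1, 10)), 0.5)
  expect_equal(auc(c(2), c(1, 3)), 0.5)
  expect_equal(interpret_auc(0.49), "random")
  expect_equal(interpret_auc(0.6), "poor")
  expect_equal(interpret_auc(0.85), "moderate")
  expect_equal(interpret_auc(0.994), "good")
})

test_that("jackknife importance ranks the informative variable first", {
  land <- simulate_landscape(n_vars = 4, nrows = 30, ncols = 30,
                             coeffs = c(5, 0, 0, 0), n_presence = 100,
                             seed = 21)
  ext <- extract_env(land$occurrences, land$grids)
  sp <- split_train_test(nrow(ext$env), 0.25, seed = 2)
  bg <- sample_background(land$grids, seed = 1)
  jk <- jackknife_importance(ext$env[sp$train, ], ext$env[sp$test, ], bg)
  expect_equal(jk$variable[1], "bio01")
  expect_equal(nrow(jk), 4)
  expect_equal(jk$rank, 1:4)

  # duplicated variable: symmetric with-only AUCs
  env2 <- cbind(ext$env, bio01b = ext$env[, "bio01"])
  bg2 <- cbind(bg, bio01b = bg[, "bio01"])
  jk2 <- jackknife_importance(env2[sp$train, ], env2[sp$test, ], bg2)
  a <- jk2$auc_only[jk2$variable == "bio01"]
  b <- jk2$auc_only[jk2$variable == "bio01b"]
  expect_equal(a, b, tolerance = 1e-6)
})

test_that("evaluation bands are consistent with the test AUC", {
  land <- simulate_landscape(n_vars = 2, nrows = 20, ncols = 20,
                             coeffs = c(5, 0), n_presence = 60, seed = 3)
  ext <- extract_env(land$occurrences, land$grids)
  sp <- split_train_test(nrow(ext$env), 0.25, seed = 4)
  bg <- sample_background(land$grids, seed = 1)
  m <- fit_maxent(ext$env[sp$train, ], bg)
  ev <- evaluate_sdm(m, ext$env[sp$train, ], ext$env[sp$test, ], bg, 0.25)
  expect_equal(ev$band, interpret_auc(ev$test_auc))
  expect_equal(ev$test_fraction, 0.25)
})

test_that("linear-only fits recover the generating coefficient ranking", {
  rhos <- vapply(1:20, function(s) {
    coeffs <- seq(-2, 2, length.out = 8)
    land <- simulate_landscape(n_vars = 8, nrows = 60, ncols = 60,
                               coeffs = coeffs, n_presence = 200, seed = s)
    ext <- extract_env(land$occurrences, land$grids)
    bg <- sample_background(land$grids, seed = 1)
    m <- fit_maxent(ext$env, bg, beta = 0.1, quadratic = FALSE)
    stats::cor(m$lambda, coeffs, method = "spearman")
  }, 0)
  expect_gte(mean(rhos), 0.9)
  expect_true(all(rhos > 0.7))
})
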