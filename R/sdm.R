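# Presence-only niche modeling: reverse-jackknife record cleaning, an
# L1-regularized maximum-entropy model over background cells with linear +
# quadratic features, suitability prediction, AUC validation and jackknife
# variable importance.

#' Reverse-jackknife outlier flags for a vector of environmental values
#'
#' Chapman-style univariate gap rule. With the values sorted, the critical
#' threshold is `t = (0.95 * sqrt(n) + 0.2) * (range / 50)`. Walking inward
#' from each extreme, a value is flagged while the gap separating it from
#' the remaining body exceeds `t` AND exceeds `rel_width` times the mean of
#' the remaining consecutive gaps -- an extreme must stand out both on the
#' variable's absolute scale and relative to the local spacing of the data.
#'
#' @param values Numeric vector, at least 5 finite values.
#' @param rel_width Relative-width multiplier, default 1.5.
#' @return Logical vector, `TRUE` where the value is an outlier.
#' @export
reverse_jackknife_outliers <- function(values, rel_width = 1.5) {
  stopifnot(sum(is.finite(values)) >= 5)
  n <- length(values)
  ord <- order(values)
  x <- values[ord]
  rng <- x[n] - x[1]
  flag_sorted <- rep(FALSE, n)
  if (rng > 0) {
    crit <- (0.95 * sqrt(n) + 0.2) * (rng / 50)
    gaps <- diff(x)
    lo <- 1; hi <- n
    is_gap <- function(g, others) {
      g > crit && g > rel_width * mean(others)
    }
    repeat {
      moved <- FALSE
      if (hi - lo >= 2) {
        g <- gaps[lo]
        if (is_gap(g, gaps[(lo + 1):(hi - 1)])) {
          flag_sorted[lo] <- TRUE; lo <- lo + 1; moved <- TRUE
        }
      }
      if (hi - lo >= 2) {
        g <- gaps[hi - 1]
        if (is_gap(g, gaps[lo:(hi - 2)])) {
          flag_sorted[hi] <- TRUE; hi <- hi - 1; moved <- TRUE
        }
      }
      if (!moved) break
    }
  }
  out <- logical(n)
  out[ord] <- flag_sorted
  out
}

#' Clean occurrence records by multivariate outlier agreement
#'
#' A record is removed when [reverse_jackknife_outliers()] flags it in at
#' least `min_flagged_vars` environmental variables (default 3 of the 19
#' bioclimatic layers).
#'
#' @param env Occurrence x variable matrix ([extract_env()]).
#' @param min_flagged_vars Removal threshold, default 3.
#' @param rel_width Passed to [reverse_jackknife_outliers()].
#' @return List with `keep` (logical per record), `n_flagged` (integer per
#'   record) and `flags` (record x variable logical matrix).
#' @export
clean_occurrences <- function(env, min_flagged_vars = 3, rel_width = 1.5) {
  flags <- apply(env, 2, reverse_jackknife_outliers, rel_width = rel_width)
  if (is.null(dim(flags))) flags <- matrix(flags, nrow = nrow(env))
  n_flagged <- rowSums(flags)
  list(keep = n_flagged < min_flagged_vars, n_flagged = n_flagged,
       flags = flags)
}

#' Random train/test split of occurrence records
#'
#' @param n Number of occurrences (or a data frame / matrix whose rows are
#'   split).
#' @param test_fraction Fraction held out, default 0.25.
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `test`
#'   (`length(test) = round(n * test_fraction)`, at least 1).
#' @export
split_train_test <- function(n, test_fraction = 0.25, seed = 1) {
  if (!is.numeric(n) || length(n) != 1) n <- nrow(n)
  stopifnot(n >= 4)
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop("test_fraction must be in (0, 1)", call. = FALSE)
  }
  n_test <- max(1L, round(n * test_fraction))
  set.seed(seed)
  test <- sort(sample.int(n, n_test))
  list(train = setdiff(seq_len(n), test), test = test)
}

#' Sample background cells from a grid stack
#'
#' Uniform sample (without replacement) of valid (non-nodata) cells; all
#' cells are used when fewer than `n` are valid.
#'
#' @param grids List of `env_grid` sharing an extent.
#' @param n Background size, default 10000.
#' @param seed Integer seed.
#' @return Matrix of background cell values (cells x variables), with the
#'   cell centers as attributes `lon`/`lat`.
#' @export
sample_background <- function(grids, n = 10000, seed = 1) {
  ref <- .check_shared_extent(grids)
  vals <- vapply(grids, function(g) as.vector(t(g$values)), # row-major
                 numeric(ref$nrows * ref$ncols))
  colnames(vals) <- vapply(grids, `[[`, "", "name")
  valid <- which(stats::complete.cases(vals))
  if (length(valid) > n) {
    set.seed(seed)
    valid <- sort(sample(valid, n))
  }
  out <- vals[valid, , drop = FALSE]
  # cell centers (values were flattened row-major, north row first)
  row <- (valid - 1) %/% ref$ncols + 1
  col <- (valid - 1) %% ref$ncols + 1
  attr(out, "lon") <- ref$xllcorner + (col - 0.5) * ref$cellsize
  attr(out, "lat") <- ref$yllcorner + (ref$nrows - row + 0.5) * ref$cellsize
  out
}

# build the standardized feature matrix for raw variable values
.maxent_features <- function(env, spec) {
  env <- as.matrix(env)[, spec$variables, drop = FALSE]
  feats <- env
  if (spec$quadratic) feats <- cbind(feats, env^2)
  colnames(feats) <- spec$feature_names
  scale(feats, center = spec$center, scale = spec$scale)
}

.maxent_feature_spec <- function(background, quadratic = TRUE) {
  background <- as.matrix(background)
  vars <- colnames(background)
  if (is.null(vars)) vars <- paste0("v", seq_len(ncol(background)))
  colnames(background) <- vars
  feature_names <- if (quadratic) c(paste0(vars, ":l"), paste0(vars, ":q"))
                   else paste0(vars, ":l")
  raw <- background
  feats <- if (quadratic) cbind(raw, raw^2) else raw
  center <- colMeans(feats)
  scale <- apply(feats, 2, stats::sd)
  scale[scale == 0 | !is.finite(scale)] <- 1   # constant feature: inert
  list(variables = vars, quadratic = quadratic,
       feature_names = feature_names, center = center, scale = scale)
}

# negative penalized log-likelihood and gradient on the (a, b) split,
# lambda = a - b, both >= 0
.maxent_objective <- function(Fp_means, Fb, beta) {
  p <- length(Fp_means)
  list(
    fn = function(ab) {
      lambda <- ab[1:p] - ab[(p + 1):(2 * p)]
      eta <- drop(Fb %*% lambda)
      mx <- max(eta)
      logZ <- mx + log(sum(exp(eta - mx)))
      -(sum(Fp_means * lambda) - logZ) + sum(beta * ab)
    },
    gr = function(ab) {
      lambda <- ab[1:p] - ab[(p + 1):(2 * p)]
      eta <- drop(Fb %*% lambda)
      mx <- max(eta)
      w <- exp(eta - mx)
      w <- w / sum(w)
      g <- -(Fp_means - drop(crossprod(Fb, w)))
      c(g + beta, -g + beta)
    })
}

#' Fit a maximum-entropy niche model
#'
#' Maximizes the mean presence log-likelihood
#' `mean_p [lambda . f(x)] - log sum_b exp(lambda . f(x))` minus an L1
#' penalty `sum_j beta_j |lambda_j|`, over linear (+ optional quadratic)
#' features standardized on the background mean/sd. The problem is convex;
#' it is solved by L-BFGS-B on the positive/negative split of `lambda`,
#' which handles the penalty exactly (large `beta` drives weights to 0).
#'
#' @param presence_env Presence cell values (points x variables).
#' @param background_env Background cell values ([sample_background()]).
#' @param beta L1 regularization weight per feature (scalar or vector),
#'   default 1.
#' @param quadratic Include quadratic features (default TRUE).
#' @param max_iter Iteration cap, default 500.
#' @param tol Convergence tolerance on the objective, default 1e-6.
#' @param init Optional warm-start weight vector (named by feature).
#' @return A `maxent_model`: feature spec, `lambda`, `beta`, `logZ`, the
#'   background reference scores and convergence info.
#' @export
fit_maxent <- function(presence_env, background_env, beta = 1,
                       quadratic = TRUE, max_iter = 500, tol = 1e-6,
                       init = NULL) {
  presence_env <- as.matrix(presence_env)
  stopifnot(nrow(presence_env) >= 2)
  spec <- .maxent_feature_spec(background_env, quadratic)
  Fb <- .maxent_features(background_env, spec)
  Fp <- .maxent_features(presence_env, spec)
  p <- ncol(Fb)
  beta <- rep_len(beta, p)
  obj <- .maxent_objective(colMeans(Fp), Fb, beta)
  ab0 <- numeric(2 * p)
  if (!is.null(init)) {
    lam0 <- rep(0, p)
    names(lam0) <- spec$feature_names
    common <- intersect(names(init), spec$feature_names)
    lam0[common] <- init[common]
    ab0 <- c(pmax(lam0, 0), pmax(-lam0, 0))
  }
  fit <- stats::optim(ab0, obj$fn, obj$gr, method = "L-BFGS-B",
                      lower = 0,
                      control = list(maxit = max_iter,
                                     factr = tol / .Machine$double.eps))
  if (fit$convergence != 0) {
    gnorm <- sqrt(sum(pmin(obj$gr(fit$par), 0)^2))
    warning("maxent fit did not converge (code ", fit$convergence,
            "); projected gradient norm ", format(gnorm), call. = FALSE)
  }
  lambda <- fit$par[1:p] - fit$par[(p + 1):(2 * p)]
  names(lambda) <- spec$feature_names
  eta_b <- drop(Fb %*% lambda)
  mx <- max(eta_b)
  logZ <- mx + log(sum(exp(eta_b - mx)))
  raw_b <- exp(eta_b - logZ)
  model <- structure(list(spec = spec, lambda = lambda, beta = beta,
                          logZ = logZ, background_raw = raw_b,
                          objective = fit$value,
                          converged = fit$convergence == 0),
                     class = "maxent_model")
  stopifnot(abs(sum(raw_b) - 1) < 1e-6)  # normalization invariant
  model
}

#' @export
print.maxent_model <- function(x, ...) {
  active <- sum(x$lambda != 0)
  cat("maxent_model:", length(x$spec$variables), "variables,",
      length(x$lambda), "features,", active, "active; converged:",
      x$converged, "\n")
  invisible(x)
}

#' Score cells under a fitted maxent model
#'
#' @param model A `maxent_model`.
#' @param env Cell values (points x variables; variable names must match
#'   the training variables).
#' @return Numeric vector of raw suitabilities `exp(lambda . f(x)) / Z`
#'   (the background reference sums to 1).
#' @export
maxent_scores <- function(model, env) {
  env <- as.matrix(env)
  missing <- setdiff(model$spec$variables, colnames(env))
  if (length(missing) > 0) {
    stop("unseen variable(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  Fx <- .maxent_features(env, model$spec)
  exp(drop(Fx %*% model$lambda) - model$logZ)
}

#' Predict suitability over environmental grids
#'
#' @param model A `maxent_model`.
#' @param grids List of `env_grid` covering the training variables.
#' @return List of two `env_grid`s: `raw` (relative occurrence rate; sums
#'   to 1 over the background reference) and `cumulative` (the raw-score
#'   cumulative transform on a 0-100 scale). Nodata is propagated.
#' @export
predict_suitability <- function(model, grids) {
  ref <- .check_shared_extent(grids)
  vals <- vapply(grids, function(g) as.vector(t(g$values)),
                 numeric(ref$nrows * ref$ncols))
  colnames(vals) <- vapply(grids, `[[`, "", "name")
  ok <- stats::complete.cases(vals)
  raw <- rep(NA_real_, nrow(vals))
  raw[ok] <- maxent_scores(model, vals[ok, , drop = FALSE])
  # cumulative: percent of background probability mass at or below the score
  bg <- sort(model$background_raw)
  cum_at <- cumsum(bg)
  cum <- rep(NA_real_, length(raw))
  pos <- findInterval(raw[ok], bg)
  cum[ok] <- 100 * ifelse(pos == 0, 0, cum_at[pmax(pos, 1)])
  to_grid <- function(v, nm) {
    env_grid(matrix(v, ref$nrows, ref$ncols, byrow = TRUE),
             ref$xllcorner, ref$yllcorner, ref$cellsize,
             ref$nodata_value, nm)
  }
  list(raw = to_grid(raw, "suitability_raw"),
       cumulative = to_grid(cum, "suitability_cumulative"))
}

#' Rank-based AUC of presence scores against background scores
#'
#' The probability that a random presence outscores a random background
#' cell, with ties counting one half (the Mann-Whitney statistic).
#'
#' @param presence_scores,background_scores Numeric score vectors.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(presence_scores, background_scores) {
  n1 <- length(presence_scores); n0 <- length(background_scores)
  stopifnot(n1 >= 1, n0 >= 2)
  r <- rank(c(presence_scores, background_scores), ties.method = "average")
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Interpret an AUC value
#'
#' Bands: below 0.5 random; 0.5-0.7 poor; 0.7-0.9 moderate; 0.9 and above
#' good discrimination.
#'
#' @param auc_value AUC in `[0, 1]`.
#' @return `"random"`, `"poor"`, `"moderate"` or `"good"`.
#' @export
interpret_auc <- function(auc_value) {
  ifelse(auc_value < 0.5, "random",
         ifelse(auc_value < 0.7, "poor",
                ifelse(auc_value < 0.9, "moderate", "good")))
}

#' Train/test AUC evaluation of a fitted model
#'
#' @param model A `maxent_model`.
#' @param train_env,test_env Presence cell values for the training and
#'   held-out points.
#' @param background_env Background cell values.
#' @param test_fraction Recorded in the result.
#' @return List with `train_auc`, `test_auc`, `band`, `test_fraction`.
#' @export
evaluate_sdm <- function(model, train_env, test_env, background_env,
                         test_fraction = NA_real_) {
  bg <- maxent_scores(model, background_env)
  train_auc <- auc(maxent_scores(model, train_env), bg)
  test_auc <- auc(maxent_scores(model, test_env), bg)
  list(train_auc = train_auc, test_auc = test_auc,
       band = interpret_auc(test_auc), test_fraction = test_fraction)
}

#' Jackknife variable importance
#'
#' For each variable, fits a model with that variable alone and a model
#' with it excluded (warm-started from the full fit), and evaluates the
#' held-out AUC of each. Variables are ranked by the with-only AUC.
#'
#' @param train_env,test_env,background_env Cell-value matrices as in
#'   [evaluate_sdm()].
#' @param beta,quadratic,max_iter,tol Passed to [fit_maxent()].
#' @param full_model Optional pre-fitted full model reused for warm starts.
#' @return Data frame with one row per variable: `variable`, `auc_only`,
#'   `auc_without`, `rank` (1 = most important by `auc_only`).
#' @export
jackknife_importance <- function(train_env, test_env, background_env,
                                 beta = 1, quadratic = TRUE, max_iter = 500,
                                 tol = 1e-6, full_model = NULL) {
  train_env <- as.matrix(train_env)
  vars <- colnames(train_env)
  stopifnot(length(vars) >= 2)
  if (is.null(full_model)) {
    full_model <- fit_maxent(train_env, background_env, beta = beta,
                             quadratic = quadratic, max_iter = max_iter,
                             tol = tol)
  }
  bg_all <- as.matrix(background_env)
  auc_of <- function(cols) {
    m <- fit_maxent(train_env[, cols, drop = FALSE],
                    bg_all[, cols, drop = FALSE], beta = beta,
                    quadratic = quadratic, max_iter = max_iter, tol = tol,
                    init = full_model$lambda)
    bg_scores <- maxent_scores(m, bg_all[, cols, drop = FALSE])
    auc(maxent_scores(m, test_env[, cols, drop = FALSE]), bg_scores)
  }
  auc_only <- vapply(vars, function(v) auc_of(v), 0)
  auc_without <- vapply(vars, function(v) auc_of(setdiff(vars, v)), 0)
  out <- data.frame(variable = vars, auc_only = auc_only,
                    auc_without = auc_without, stringsAsFactors = FALSE)
  out$rank <- rank(-out$auc_only, ties.method = "first")
  rownames(out) <- NULL
  out[order(out$rank), ]
}
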