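# One-level AMOVA from a distance matrix, Fst with a permutation test,
# and Nei's standard genetic distance between populations.

# AMOVA/Fst core on a squared-distance matrix and integer population labels
.fst_components <- function(d2, pop) {
  N <- nrow(d2)
  pops <- unique(pop)
  P <- length(pops)
  SSD_total <- sum(d2) / 2 / N
  SSD_within <- 0
  sizes <- numeric(P)
  for (k in seq_len(P)) {
    idx <- which(pop == pops[k])
    sizes[k] <- length(idx)
    if (length(idx) > 1) {
      SSD_within <- SSD_within + sum(d2[idx, idx]) / 2 / length(idx)
    }
  }
  SSD_among <- SSD_total - SSD_within
  df_among <- P - 1
  df_within <- N - P
  sigma2_w <- SSD_within / df_within
  n_bar <- (N - sum(sizes^2) / N) / (P - 1)
  sigma2_a <- (SSD_among / df_among - sigma2_w) / n_bar
  list(SSD_total = SSD_total, SSD_among = SSD_among,
       SSD_within = SSD_within, df_among = df_among, df_within = df_within,
       sigma2_a = sigma2_a, sigma2_w = sigma2_w)
}

.fst_from_components <- function(comp) {
  a <- max(comp$sigma2_a, 0)
  w <- comp$sigma2_w
  if (a + w <= 0) return(0)   # degenerate: no molecular variance at all
  a / (a + w)
}

# unclamped variance-component ratio, the permutation test statistic;
# clamping would pile tied zeros under the null and bias p upward
.fst_raw_stat <- function(comp) {
  denom <- comp$sigma2_a + comp$sigma2_w
  if (denom <= 0) return(0)
  comp$sigma2_a / denom
}

.check_pops <- function(dm, pops) {
  labels <- rownames(dm)
  if (!all(labels %in% names(pops))) {
    stop("population map must cover every specimen in the matrix",
         call. = FALSE)
  }
  pop <- as.character(pops[labels])
  if (length(unique(pop)) < 2) stop("need at least 2 populations",
                                    call. = FALSE)
  if (nrow(dm) - length(unique(pop)) < 1) {
    stop("within-population degrees of freedom are zero", call. = FALSE)
  }
  pop
}

#' One-level analysis of molecular variance (AMOVA)
#'
#' Partitions squared pairwise molecular distances into among- and
#' within-population components: `SSD_total = sum_{i<j} d_ij^2 / N`,
#' `SSD_within = sum_p sum_{i<j in p} d_ij^2 / n_p`, with
#' `sigma2_w = SSD_within / (N - P)` and
#' `sigma2_a = (SSD_among/(P-1) - sigma2_w) / n_bar` where
#' `n_bar = (N - sum n_p^2 / N) / (P - 1)`. Fst is
#' `sigma2_a / (sigma2_a + sigma2_w)`, reported clamped to `[0, 1]` with
#' the raw among-population component preserved.
#'
#' @param dm Distance matrix with specimen labels.
#' @param pops Named character vector: specimen -> population label.
#' @return An `amova_result` list: degrees of freedom, sums of squares,
#'   variance components (`sigma2_a` clamped, `raw_sigma2_a` unclamped),
#'   `pct_among`/`pct_within` and `Fst`.
#' @export
amova_one_level <- function(dm, pops) {
  pop <- .check_pops(dm, pops)
  comp <- .fst_components(unclass(dm)^2, pop)
  a <- max(comp$sigma2_a, 0)
  w <- comp$sigma2_w
  total <- a + w
  pct_among <- if (total > 0) 100 * a / total else 0
  structure(list(
    df_among = comp$df_among, df_within = comp$df_within,
    SSD_among = comp$SSD_among, SSD_within = comp$SSD_within,
    SSD_total = comp$SSD_total,
    sigma2_a = a, sigma2_w = w, raw_sigma2_a = comp$sigma2_a,
    pct_among = pct_among, pct_within = 100 - pct_among,
    Fst = .fst_from_components(comp)
  ), class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat("One-level AMOVA\n")
  tab <- data.frame(
    source = c("Among populations", "Within populations"),
    df = c(x$df_among, x$df_within),
    SSD = c(x$SSD_among, x$SSD_within),
    sigma2 = c(x$sigma2_a, x$sigma2_w),
    pct = c(x$pct_among, x$pct_within))
  print(tab, row.names = FALSE)
  cat("Fst =", format(x$Fst), "\n")
  invisible(x)
}

#' Write an AMOVA table as TSV
#' @param amova An `amova_result`.
#' @param path Output path.
#' @export
write_amova <- function(amova, path) {
  df <- data.frame(
    source = c("among", "within", "total"),
    df = c(amova$df_among, amova$df_within,
           amova$df_among + amova$df_within),
    SSD = c(amova$SSD_among, amova$SSD_within, amova$SSD_total),
    sigma2 = c(amova$sigma2_a, amova$sigma2_w, NA),
    percent = c(amova$pct_among, amova$pct_within, NA))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Permutation test for Fst
#'
#' Permutes specimens among populations (preserving population sizes) and
#' reports `p = (1 + #\{perm Fst >= observed\}) / (n_perm + 1)`. The test
#' statistic is the unclamped variance-component ratio: clamping negative
#' among-population components to zero would tie a large fraction of null
#' permutations with a zero observed value and push p to 1, destroying the
#' uniform null distribution the test relies on.
#'
#' @param dm Distance matrix.
#' @param pops Named population map.
#' @param n_perm Number of permutations, default 1023.
#' @param seed Integer seed for reproducibility.
#' @return List with `p_value`, `observed` (clamped Fst as reported by
#'   [amova_one_level()]), `observed_raw` (the test statistic), `n_perm`,
#'   `seed`.
#' @export
fst_permutation_test <- function(dm, pops, n_perm = 1023, seed = 1) {
  pop <- .check_pops(dm, pops)
  d2 <- unclass(dm)^2
  comp <- .fst_components(d2, pop)
  observed_raw <- .fst_raw_stat(comp)
  set.seed(seed)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    perm <- sample(pop)
    if (.fst_raw_stat(.fst_components(d2, perm)) >= observed_raw) {
      hits <- hits + 1L
    }
  }
  list(p_value = (1 + hits) / (n_perm + 1),
       observed = .fst_from_components(comp),
       observed_raw = observed_raw, n_perm = n_perm, seed = seed)
}

#' Haplotype frequency vectors per population
#'
#' Collapses identical sequences (exact match after stripping gap
#' characters) to haplotypes and returns per-population frequencies over
#' the union haplotype index.
#'
#' @param records Sequence record data frame.
#' @param pops Named character vector: sample_id -> population.
#' @param strip_gaps Remove `-` before comparing (default TRUE).
#' @return Matrix with one row per population (rownames) and one column per
#'   haplotype; rows sum to 1.
#' @export
haplotype_frequencies <- function(records, pops, strip_gaps = TRUE) {
  seqs <- records$seq
  if (strip_gaps) seqs <- gsub("-", "", seqs, fixed = TRUE)
  pop <- as.character(pops[records$sample_id])
  if (anyNA(pop)) stop("population map must cover every record", call. = FALSE)
  haps <- unique(seqs)
  pop_levels <- unique(pop)
  freq <- matrix(0, length(pop_levels), length(haps),
                 dimnames = list(pop_levels,
                                 paste0("hap", seq_along(haps))))
  for (p in pop_levels) {
    idx <- pop == p
    if (!any(idx)) stop("empty population: ", p, call. = FALSE)
    counts <- table(factor(match(seqs[idx], haps),
                           levels = seq_along(haps)))
    freq[p, ] <- as.numeric(counts) / sum(counts)
  }
  freq
}

#' Nei's standard genetic distance between two frequency vectors
#'
#' `I = sum(x*y) / sqrt(sum(x^2) * sum(y^2))`, `D = -log(I)`; populations
#' sharing no haplotype have `I = 0` and `D = Inf`.
#'
#' @param freq_x,freq_y Haplotype frequency vectors over a shared index,
#'   each summing to 1.
#' @return Nei's D (nonnegative, possibly `Inf`).
#' @export
nei_distance <- function(freq_x, freq_y) {
  if (any(freq_x < 0) || any(freq_y < 0)) {
    stop("negative haplotype frequency", call. = FALSE)
  }
  if (abs(sum(freq_x) - 1) > 1e-9 || abs(sum(freq_y) - 1) > 1e-9) {
    stop("frequency vectors must each sum to 1", call. = FALSE)
  }
  I <- sum(freq_x * freq_y) / sqrt(sum(freq_x^2) * sum(freq_y^2))
  if (I <= 0) return(Inf)
  max(-log(I), 0)  # guard against -0 from rounding when I is 1 + eps
}

#' Pairwise Nei distance matrix between populations
#'
#' @param freq Frequency matrix from [haplotype_frequencies()].
#' @return Symmetric matrix of Nei's D with population labels.
#' @export
nei_matrix <- function(freq) {
  pops <- rownames(freq)
  n <- length(pops)
  D <- matrix(0, n, n, dimnames = list(pops, pops))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        D[i, j] <- D[j, i] <- nei_distance(freq[i, ], freq[j, ])
      }
    }
  }
  D
}
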