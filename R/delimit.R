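# Automatic barcode-gap discovery: find the gap between intra- and
# inter-specific pairwise distances, partition specimens by single linkage
# below it, recurse within groups, and sweep the prior divergence.

#' Histogram and ranked-distance report for a distance matrix
#'
#' @param dm Distance matrix ([distance_matrix()]).
#' @param n_bins Number of equal-width histogram bins over `[0, max]`.
#' @param prior_P,X Optional: when `prior_P` is given the detected gap
#'   interval under [detect_gap()] is included.
#' @return List with `distances` (sorted ascending), `histogram`
#'   (`breaks`, `counts`), `ranked` (rank/distance data frame) and
#'   `gap_interval` (`c(lo, hi)` or `NULL`).
#' @export
gap_report <- function(dm, n_bins = 20, prior_P = NULL, X = 1.5) {
  d <- pairwise_distances(dm, sorted = TRUE)
  upper <- max(d, .Machine$double.eps)
  breaks <- seq(0, upper, length.out = n_bins + 1)
  counts <- graphics::hist(d, breaks = breaks, plot = FALSE,
                           include.lowest = TRUE, right = TRUE)$counts
  gap_int <- NULL
  if (!is.null(prior_P)) {
    thr <- detect_gap(d, prior_P, X)
    if (!is.na(thr)) {
      below <- max(d[d < thr]); above <- min(d[d >= thr])
      gap_int <- c(below, above)
    }
  }
  list(distances = d,
       histogram = list(breaks = breaks, counts = counts),
       ranked = data.frame(rank = seq_along(d), distance = d),
       gap_interval = gap_int)
}

#' Detect the barcode gap in a sorted distance vector
#'
#' Scans the intervals between consecutive distinct ranked distances (exact
#' ties collapse to one value, so a run of identical distances cannot mimic
#' an empty region): an interval starting at distance `d` with width `w` is
#' a gap when (a) its midpoint exceeds the prior maximal intraspecific
#' divergence `prior_P`, and (b) `w` exceeds `X` times the larger of the
#' local divergence `d` and the mean width of the preceding `W` intervals.
#' The divergence floor makes detection scale-aware: an interspecific gap
#' must dwarf the divergence level at which it opens, so small irregular
#' spacings inside the intraspecific cloud (where corrected distances
#' cluster tightly) never qualify. The first qualifying interval's midpoint
#' is returned; absence of a gap is a valid outcome (`NA`).
#'
#' @param sorted_distances Pairwise distances sorted ascending.
#' @param prior_P Prior maximal intraspecific divergence (> 0).
#' @param X Relative gap width (> 0), default 1.5.
#' @param W Sliding window of preceding intervals, default 10.
#' @return The gap threshold (interval midpoint) or `NA_real_`.
#' @export
detect_gap <- function(sorted_distances, prior_P, X = 1.5, W = 10) {
  stopifnot(prior_P > 0, X > 0, W >= 3)
  if (is.unsorted(sorted_distances)) {
    stop("distances must be sorted ascending", call. = FALSE)
  }
  d <- unique(sorted_distances)
  M <- length(d)
  if (M < 2) return(NA_real_)
  w <- diff(d)
  for (i in seq_len(M - 1)) {
    mid <- (d[i] + d[i + 1]) / 2
    if (mid <= prior_P) next
    prev_mean <- if (i > 1) mean(w[max(1, i - W):(i - 1)]) else 0
    if (w[i] > X * max(d[i], prev_mean)) return(mid)
  }
  NA_real_
}

# connected components of the graph joining pairs with d < threshold
.components_below <- function(dm, threshold) {
  n <- nrow(dm)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (dm[i, j] < threshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  vapply(seq_len(n), find, 1L)
}

#' Partition specimens by single linkage below a threshold
#'
#' Groups are the connected components of the graph joining specimen pairs
#' with distance strictly below `threshold`. Group ids are the
#' lexicographically smallest member label, making partitions deterministic.
#'
#' @param dm Distance matrix.
#' @param threshold Linkage threshold (> 0).
#' @param prior_P Optional prior recorded in the result.
#' @return A `partition` object: list with `assignment` (named character,
#'   specimen -> group id), `prior_P`, `threshold`, `n_groups`.
#' @export
single_linkage_partition <- function(dm, threshold, prior_P = NA_real_) {
  stopifnot(threshold > 0)
  labels <- rownames(dm)
  comp <- .components_below(unclass(dm), threshold)
  groups <- split(labels, comp)
  ids <- vapply(groups, function(g) min(g), "")
  assignment <- stats::setNames(rep(ids, lengths(groups)), unlist(groups))
  assignment <- assignment[labels]
  structure(list(assignment = assignment, prior_P = prior_P,
                 threshold = threshold,
                 n_groups = length(unique(assignment))),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat("Partition:", x$n_groups, "group(s); prior_P =", format(x$prior_P),
      "; threshold =", format(x$threshold), "\n")
  invisible(x)
}

#' Recursive barcode-gap delimitation
#'
#' Applies [detect_gap()] + [single_linkage_partition()], then re-applies
#' the procedure within each resulting group of at least `min_size`
#' specimens using that group's sub-matrix, until no gap is found, groups
#' fall below `min_size`, or `max_depth` is reached.
#'
#' @param dm Distance matrix.
#' @param prior_P Prior maximal intraspecific divergence.
#' @param X Relative gap width, default 1.5.
#' @param W Gap-detection window, default 10.
#' @param min_size Minimum group size eligible for further splitting
#'   (default 4, preventing spurious splits of pairs).
#' @param max_depth Recursion limit, default 10.
#' @return A `partition` object; `threshold` is the first-level gap (`NA`
#'   when no gap was found at the top level).
#' @export
recursive_delimit <- function(dm, prior_P, X = 1.5, W = 10, min_size = 4,
                              max_depth = 10) {
  labels <- rownames(dm)
  top_threshold <- NA_real_
  split_group <- function(idx, depth) {
    too_small <- length(idx) < 2 || (depth > 1 && length(idx) < min_size)
    if (too_small || depth > max_depth) return(list(idx))
    sub <- unclass(dm)[idx, idx, drop = FALSE]
    thr <- detect_gap(sort(sub[lower.tri(sub)]), prior_P, X, W)
    if (is.na(thr)) return(list(idx))
    if (depth == 1 && is.na(top_threshold)) top_threshold <<- thr
    comp <- .components_below(sub, thr)
    if (length(unique(comp)) == 1) return(list(idx))
    out <- list()
    for (g in unique(comp)) {
      sub_idx <- idx[comp == g]
      out <- c(out, split_group(sub_idx, depth + 1))
    }
    out
  }
  groups <- split_group(seq_along(labels), 1)
  ids <- vapply(groups, function(g) min(labels[g]), "")
  assignment <- stats::setNames(rep(NA_character_, length(labels)), labels)
  for (k in seq_along(groups)) assignment[labels[groups[[k]]]] <- ids[k]
  structure(list(assignment = assignment, prior_P = prior_P,
                 threshold = top_threshold,
                 n_groups = length(unique(assignment))),
            class = "partition")
}

#' Sweep the prior intraspecific divergence
#'
#' Runs [recursive_delimit()] at `n_steps` log-spaced priors between
#' `P_min` and `P_max` (inclusive) and tabulates the number of groups per
#' prior (the "automatic partition" summary).
#'
#' @param dm Distance matrix.
#' @param P_min,P_max Prior range, defaults 0.001 and 0.100 (the standard
#'   barcode-gap survey range).
#' @param n_steps Number of priors, default 10.
#' @param X,W,min_size,max_depth Passed to [recursive_delimit()].
#' @return A `sweep_result`: list with `partitions` (list of `partition`),
#'   `summary` (data frame prior_P / n_groups / threshold) and `X`.
#' @export
prior_sweep <- function(dm, P_min = 0.001, P_max = 0.100, n_steps = 10,
                        X = 1.5, W = 10, min_size = 4, max_depth = 10) {
  stopifnot(P_min > 0, P_min < P_max)
  priors <- exp(seq(log(P_min), log(P_max), length.out = n_steps))
  partitions <- lapply(priors, function(p)
    recursive_delimit(dm, p, X = X, W = W, min_size = min_size,
                      max_depth = max_depth))
  summary <- data.frame(
    prior_P = priors,
    n_groups = vapply(partitions, `[[`, 0L, "n_groups"),
    threshold = vapply(partitions, `[[`, 0, "threshold")
  )
  structure(list(partitions = partitions, summary = summary, X = X),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("Barcode-gap prior sweep (X =", x$X, ")\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Write a partition as TSV (specimen_id, group_id, prior_P, threshold)
#' @param partition A `partition` object.
#' @param path Output TSV path.
#' @export
write_partition <- function(partition, path) {
  df <- data.frame(specimen_id = names(partition$assignment),
                   group_id = unname(partition$assignment),
                   prior_P = partition$prior_P,
                   threshold = partition$threshold)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a prior-sweep summary as TSV
#' @param sweep A `sweep_result` object.
#' @param path Output TSV path.
#' @export
write_sweep <- function(sweep, path) {
  utils::write.table(sweep$summary, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
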