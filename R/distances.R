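# Pairwise evolutionary distances with pairwise deletion, and a
# neighbor-joining tree on the resulting matrix.

# integer coding: A=1, C=2, G=3, T=4, anything else NA (excluded pairwise)
.encode_seq <- function(seq) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  match(chars, c("A", "C", "G", "T"))
}

.seq_matrix <- function(seqs) {
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1) {
    stop("sequences must be pre-aligned to equal length", call. = FALSE)
  }
  do.call(rbind, lapply(seqs, .encode_seq))
}

#' Count shared-site substitution patterns between two aligned sequences
#'
#' Sites where either sequence carries a gap or an ambiguity code are
#' excluded (pairwise deletion). Transitions are purine-purine (A<->G) or
#' pyrimidine-pyrimidine (C<->T) differences; all other differences are
#' transversions.
#'
#' @param a,b Aligned sequences of equal length (strings).
#' @return List with `n` (compared sites), `P` (transition proportion) and
#'   `Q` (transversion proportion).
#' @export
count_site_patterns <- function(a, b) {
  ca <- .encode_seq(a); cb <- .encode_seq(b)
  if (length(ca) != length(cb)) {
    stop("sequences differ in length; alignment required", call. = FALSE)
  }
  ok <- !is.na(ca) & !is.na(cb)
  n <- sum(ok)
  if (n == 0) stop("zero comparable sites between the two sequences",
                   call. = FALSE)
  ca <- ca[ok]; cb <- cb[ok]
  diff <- ca != cb
  purine_a <- ca == 1L | ca == 3L
  purine_b <- cb == 1L | cb == 3L
  ts <- sum(diff & (purine_a == purine_b))
  tv <- sum(diff & (purine_a != purine_b))
  list(n = n, P = ts / n, Q = tv / n)
}

#' Kimura two-parameter distance
#'
#' `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)` from transition (P) and
#' transversion (Q) proportions.
#'
#' @param counts List with elements `P` and `Q`, as returned by
#'   [count_site_patterns()], or a transition proportion (then `Q` must be
#'   given).
#' @param Q Transversion proportion when `counts` is numeric.
#' @return The K2P distance.
#' @export
k2p <- function(counts, Q = NULL) {
  if (is.list(counts)) { P <- counts$P; Q <- counts$Q } else P <- counts
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    stop("K2P saturation: P=", format(P), ", Q=", format(Q), call. = FALSE)
  }
  -0.5 * log(w1) - 0.25 * log(w2)
}

#' Jukes-Cantor (JC69) distance
#'
#' `d = -3/4 log(1 - 4p/3)` from the mismatch proportion `p` (`p < 0.75`).
#'
#' @param p Proportion of mismatching sites.
#' @return The JC69 distance.
#' @export
jc69 <- function(p) {
  if (p >= 0.75) stop("JC69 saturation: p=", format(p), call. = FALSE)
  -0.75 * log(1 - 4 * p / 3)
}

.pair_distance <- function(n, P, Q, model) {
  switch(model,
    p = P + Q,
    JC69 = jc69(P + Q),
    K2P = k2p(list(P = P, Q = Q)))
}

#' Pairwise distance matrix under a named model
#'
#' Computes all pairwise distances between pre-aligned records of one marker
#' under `"p"` (uncorrected, the "simple" distance), `"JC69"` or `"K2P"`,
#' with pairwise deletion of gap/ambiguous sites. Saturated pairs abort with
#' an error naming them, so downstream partitions are never built on partial
#' matrices.
#'
#' @param records Sequence record data frame (single marker, aligned) or a
#'   named character vector of sequences.
#' @param model One of `"K2P"`, `"JC69"`, `"p"` (alias `"simple"`).
#' @return A symmetric numeric matrix with specimen labels as dimnames and
#'   attributes `model`; class `"barcode_dist"`.
#' @export
distance_matrix <- function(records, model = c("K2P", "JC69", "p", "simple")) {
  model <- match.arg(model)
  if (model == "simple") model <- "p"
  if (is.data.frame(records)) {
    if (length(unique(records$marker)) > 1) {
      stop("distance_matrix needs records of a single marker", call. = FALSE)
    }
    seqs <- stats::setNames(records$seq, records$sample_id)
  } else {
    seqs <- records
  }
  if (length(seqs) < 2) stop("need at least two records", call. = FALSE)
  labels <- names(seqs)
  if (is.null(labels) || anyDuplicated(labels)) {
    stop("records need unique specimen labels", call. = FALSE)
  }
  m <- .seq_matrix(seqs)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  purine <- m == 1L | m == 3L
  valid <- !is.na(m)
  saturated <- character(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- valid[i, ] & valid[j, ]
      nn <- sum(ok)
      if (nn == 0) {
        stop("zero comparable sites between ", labels[i], " and ", labels[j],
             call. = FALSE)
      }
      diff <- ok & (m[i, ] != m[j, ])
      ts <- sum(diff & (purine[i, ] == purine[j, ]))
      tv <- sum(diff) - ts
      val <- tryCatch(.pair_distance(nn, ts / nn, tv / nn, model),
                      error = function(e) NA_real_)
      if (is.na(val)) {
        saturated <- c(saturated, paste0(labels[i], "/", labels[j]))
      } else {
        d[i, j] <- d[j, i] <- val
      }
    }
  }
  if (length(saturated) > 0) {
    stop("saturated pair(s) under model ", model, ": ",
         paste(saturated, collapse = ", "), call. = FALSE)
  }
  structure(d, model = model, class = c("barcode_dist", "matrix", "array"))
}

#' Lower-triangle distances of a distance matrix
#' @param dm Matrix from [distance_matrix()].
#' @param sorted Sort ascending?
#' @return Numeric vector of the N(N-1)/2 pairwise distances.
#' @export
pairwise_distances <- function(dm, sorted = FALSE) {
  v <- dm[lower.tri(dm)]
  if (sorted) sort(v) else v
}

#' Write / read a labeled square distance matrix as CSV
#' @param dm Distance matrix.
#' @param path CSV path.
#' @return `path` (write) or the matrix (read).
#' @export
write_distance_matrix <- function(dm, path) {
  df <- data.frame(label = rownames(dm), as.data.frame(unclass(dm)[, ,
                   drop = FALSE]), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$label
  storage.mode(m) <- "double"
  m
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor-joining agglomeration (via [ape::nj()]); negative
#' branch lengths are clamped to zero with the deficit moved to the sister
#' edge, preserving tip-to-tip path lengths through the parent node.
#'
#' @param dm Distance matrix with at least 3 taxa.
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(dm) {
  if (nrow(dm) < 3) stop("neighbor joining needs at least 3 taxa",
                         call. = FALSE)
  tree <- ape::nj(stats::as.dist(unclass(dm)))
  neg <- which(tree$edge.length < 0)
  for (i in neg) {
    parent <- tree$edge[i, 1]
    sibs <- setdiff(which(tree$edge[, 1] == parent), i)
    deficit <- tree$edge.length[i]
    tree$edge.length[i] <- 0
    if (length(sibs) > 0) {
      tree$edge.length[sibs[1]] <- tree$edge.length[sibs[1]] + deficit
    }
  }
  tree
}

#' Write a tree in newick format with 6-decimal branch lengths
#' @param tree A `phylo` object.
#' @param path Output path.
#' @export
write_newick <- function(tree, path) {
  tree$edge.length <- round(tree$edge.length, 6)
  ape::write.tree(tree, file = path)
  invisible(path)
}
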