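# Independent brute-force oracles, written directly from first principles
# and kept free of the package's internal code paths.

# per-site pairwise distance oracle: explicit character loop
oracle_pair_distance <- function(a, b, model) {
  ca <- strsplit(toupper(a), "")[[1]]
  cb <- strsplit(toupper(b), "")[[1]]
  ts <- 0; tv <- 0; n <- 0
  purine <- function(x) x == "A" || x == "G"
  for (k in seq_along(ca)) {
    x <- ca[k]; y <- cb[k]
    if (!(x %in% c("A", "C", "G", "T")) || !(y %in% c("A", "C", "G", "T"))) next
    n <- n + 1
    if (x != y) {
      if (purine(x) == purine(y)) ts <- ts + 1 else tv <- tv + 1
    }
  }
  P <- ts / n; Q <- tv / n; p <- P + Q
  switch(model,
         p = p,
         JC69 = -0.75 * log(1 - 4 * p / 3),
         K2P = -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q))
}

# transitive-closure single-linkage oracle: repeatedly merge any two groups
# containing a pair closer than the threshold, until stable
oracle_single_linkage <- function(dm, threshold) {
  labels <- rownames(dm)
  groups <- as.list(labels)
  repeat {
    merged <- FALSE
    for (i in seq_along(groups)) {
      for (j in seq_along(groups)) {
        if (j <= i) next
        close <- any(dm[groups[[i]], groups[[j]], drop = FALSE] < threshold)
        if (close) {
          groups[[i]] <- c(groups[[i]], groups[[j]])
          groups[[j]] <- NULL
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  # canonical form: membership keyed by smallest member
  assignment <- character(length(labels))
  names(assignment) <- labels
  for (g in groups) assignment[g] <- min(g)
  assignment
}

# AMOVA brute force: the squared-distance decomposition transcribed with
# explicit double loops
oracle_amova <- function(dm, pops) {
  labels <- rownames(dm)
  pop <- as.character(pops[labels])
  N <- length(labels)
  P <- length(unique(pop))
  sst <- 0
  for (i in seq_len(N - 1)) for (j in (i + 1):N) sst <- sst + dm[i, j]^2
  sst <- sst / N
  ssw <- 0
  for (p in unique(pop)) {
    idx <- which(pop == p)
    np <- length(idx)
    acc <- 0
    if (np > 1) {
      for (a in seq_len(np - 1)) for (b in (a + 1):np) {
        acc <- acc + dm[idx[a], idx[b]]^2
      }
    }
    ssw <- ssw + acc / np
  }
  ssa <- sst - ssw
  df_a <- P - 1
  df_w <- N - P
  s2w <- ssw / df_w
  sizes <- table(pop)
  nbar <- (N - sum(sizes^2) / N) / (P - 1)
  s2a <- (ssa / df_a - s2w) / nbar
  a <- max(s2a, 0)
  fst <- if (a + s2w <= 0) 0 else a / (a + s2w)
  list(SSD_total = sst, SSD_among = ssa, SSD_within = ssw,
       sigma2_a = s2a, sigma2_w = s2w, Fst = fst)
}

# random symmetric distance matrix with zero diagonal
random_dist_matrix <- function(n, seed) {
  set.seed(seed)
  labels <- sprintf("t%02d", seq_len(n))
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  vals <- round(stats::runif(n * (n - 1) / 2, 0.001, 0.2), 3)
  m[lower.tri(m)] <- vals
  m + t(m)
}

# hit-table row constructor for enumerated assignment cases
toy_hit <- function(species, genus = "Salicornia", family = "Amaranthaceae",
                    bitscore = 1000, qcovs = 100, pident = 99) {
  data.frame(qseqid = "q1", sseqid = paste0(gsub(" ", "_", species), "_1"),
             species = species, genus = genus, family = family,
             bitscore = bitscore, qcovs = qcovs, pident = pident,
             stringsAsFactors = FALSE)
}
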