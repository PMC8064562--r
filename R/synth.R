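# Seeded synthetic-data generators with known truth for every pipeline
# stage: multi-species barcode sequence sets, population haplotype
# structures, BLAST-style hit tables, and environmental landscapes with
# occurrence samples.

.bases <- c("A", "C", "G", "T")
# transition partner of each base (A<->G, C<->T); columns = transversions
.transition <- c(A = "G", C = "T", G = "A", T = "C")
.transversions <- list(A = c("C", "T"), C = c("A", "G"),
                       G = c("C", "T"), T = c("A", "G"))

# mutate a character-vector sequence with expected per-site substitutions
# `rate`; transitions drawn with odds kappa : 1 over transversions
.mutate_seq <- function(seq, rate, kappa) {
  L <- length(seq)
  n_mut <- stats::rpois(1, L * rate)
  if (n_mut == 0) return(seq)
  sites <- sample.int(L, min(n_mut, L))
  for (s in sites) {
    base <- seq[s]
    if (stats::runif(1) < kappa / (kappa + 1)) {
      seq[s] <- .transition[[base]]
    } else {
      seq[s] <- sample(.transversions[[base]], 1)
    }
  }
  seq
}

#' Simulate a multi-species barcode sequence set with known truth
#'
#' A random root sequence spawns `k` species ancestors (expected per-site
#' substitutions `inter / 2` each), and each ancestor spawns `n_per`
#' individuals (expected `intra / 2` each), so expected pairwise divergence
#' is about `intra` within and `inter` between species. Substitution counts
#' are Poisson; transitions are favored over transversions with odds
#' `kappa : 1`. Deterministic under `seed`.
#'
#' @param k Number of species.
#' @param n_per Individuals per species.
#' @param L Sequence length (>= 200).
#' @param intra,inter Expected intra-/inter-specific divergence
#'   (`inter > 2 * intra` guarantees a barcode gap by construction;
#'   `intra = 0` is allowed).
#' @param kappa Transition/transversion odds, default 2.
#' @param seed Integer seed.
#' @param marker Marker label for the records, default `"rbcL"`.
#' @param sites Optional site ids recycled over specimens.
#' @return List with `records` (sequence data frame) and `truth` (list:
#'   `species` named vector specimen -> true species, and `params`).
#' @export
simulate_species_sequences <- function(k, n_per, L = 600, intra = 0.005,
                                       inter = 0.08, kappa = 2, seed = 1,
                                       marker = "rbcL", sites = NULL) {
  stopifnot(k >= 1, n_per >= 1, L >= 200)
  if (inter <= 2 * intra) {
    stop("need inter > 2 * intra for a barcode gap by construction",
         call. = FALSE)
  }
  set.seed(seed)
  root <- sample(.bases, L, replace = TRUE)
  ids <- character(0); species <- character(0); seqs <- character(0)
  for (s in seq_len(k)) {
    anc <- .mutate_seq(root, inter / 2, kappa)
    sp <- sprintf("species_%02d", s)
    for (i in seq_len(n_per)) {
      ids <- c(ids, sprintf("sp%02d_i%02d", s, i))
      species <- c(species, sp)
      seqs <- c(seqs, paste(.mutate_seq(anc, intra / 2, kappa),
                            collapse = ""))
    }
  }
  if (is.null(sites)) sites <- paste0("site", seq_len(min(26, k * n_per)))
  records <- data.frame(sample_id = ids,
                        site_id = rep_len(sites, length(ids)),
                        marker = marker, seq = seqs,
                        stringsAsFactors = FALSE)
  truth <- list(species = stats::setNames(species, ids),
                params = list(k = k, n_per = n_per, L = L, intra = intra,
                              inter = inter, kappa = kappa, seed = seed))
  list(records = records, truth = truth)
}

#' Simulate population haplotype structure
#'
#' Each population draws haplotypes either from its own private pool
#' (probability `1 - migration_mix`) or from a pool shared by all
#' populations (probability `migration_mix`), so downstream Fst decreases
#' monotonically in `migration_mix`: 0 gives fully differentiated
#' populations (Fst = 1 with the default single-haplotype private pools),
#' 1 gives one panmictic pool (Fst near 0).
#'
#' @param n_pops Number of populations.
#' @param n_per Individuals per population.
#' @param migration_mix Blending proportion in `[0, 1]`.
#' @param seed Integer seed.
#' @param L Sequence length, default 300.
#' @param pool_divergence Expected divergence between pool haplotypes,
#'   default 0.05.
#' @param private_pool_size,shared_pool_size Haplotypes per private pool
#'   (default 1) and in the shared pool (default 4).
#' @param marker Marker label, default `"ITS2"`.
#' @return List with `records`, `pops` (named vector specimen ->
#'   population) and `descriptor` (generating parameters).
#' @export
simulate_population_structure <- function(n_pops, n_per, migration_mix,
                                          seed = 1, L = 300,
                                          pool_divergence = 0.05,
                                          private_pool_size = 1,
                                          shared_pool_size = 4,
                                          marker = "ITS2") {
  stopifnot(n_pops >= 2, n_per >= 1,
            migration_mix >= 0, migration_mix <= 1)
  set.seed(seed)
  root <- sample(.bases, L, replace = TRUE)
  new_hap <- function() paste(.mutate_seq(root, pool_divergence / 2, 2),
                              collapse = "")
  shared <- replicate(shared_pool_size, new_hap())
  private <- lapply(seq_len(n_pops), function(i)
    replicate(private_pool_size, new_hap()))
  ids <- character(0); pop <- character(0); seqs <- character(0)
  for (p in seq_len(n_pops)) {
    for (i in seq_len(n_per)) {
      ids <- c(ids, sprintf("pop%02d_i%02d", p, i))
      pop <- c(pop, sprintf("pop%02d", p))
      from_shared <- stats::runif(1) < migration_mix
      pool <- if (from_shared) shared else private[[p]]
      seqs <- c(seqs, sample(pool, 1))
    }
  }
  records <- data.frame(sample_id = ids, site_id = pop, marker = marker,
                        seq = seqs, stringsAsFactors = FALSE)
  list(records = records, pops = stats::setNames(pop, ids),
       descriptor = list(n_pops = n_pops, n_per = n_per,
                         migration_mix = migration_mix, seed = seed,
                         L = L, pool_divergence = pool_divergence))
}

#' Simulate a BLAST-style hit table from a species truth
#'
#' Each query receives a top hit on its true species (identity near 100,
#' full coverage) plus congeneric and confamilial decoys at lower scores.
#' With probability `decoy_rate` a query additionally receives a
#' near-top congeneric decoy within 1% of the best score (drawn from the
#' query species' synonym group when `synonym_groups` covers it),
#' exercising the species-group and genus branches of the assignment
#' ladder. Deterministic under `seed`.
#'
#' @param truth Truth list from [simulate_species_sequences()] (or any list
#'   with a named `species` vector).
#' @param score_noise_sd Gaussian noise added to bit scores, default 0.
#' @param decoy_rate Probability of a near-top decoy per query, in `[0, 1)`.
#' @param seed Integer seed.
#' @param genus,family Taxonomy applied to true species, defaults
#'   Salicornia / Amaranthaceae.
#' @param species_names Optional mapping from truth labels to binomials;
#'   defaults to `"Salicornia <label>"`.
#' @param synonym_groups Optional species -> group map for near-top decoys.
#' @param marker Marker label column, default `"rbcL"`.
#' @return Hit table data frame (extended outfmt-6 columns plus `marker`).
#' @export
simulate_hit_table <- function(truth, score_noise_sd = 0, decoy_rate = 0,
                               seed = 1, genus = "Salicornia",
                               family = "Amaranthaceae",
                               species_names = NULL,
                               synonym_groups = NULL, marker = "rbcL") {
  stopifnot(score_noise_sd >= 0, decoy_rate >= 0, decoy_rate < 1)
  set.seed(seed)
  labels <- truth$species
  true_sp <- sort(unique(labels))
  if (is.null(species_names)) {
    species_names <- stats::setNames(paste(genus, true_sp), true_sp)
  }
  decoy_congeneric <- paste(genus, c("decoya", "decoyb"))
  decoy_confamilial <- data.frame(
    species = c("Halocnemum strobilaceum", "Suaeda maritima"),
    genus = c("Halocnemum", "Suaeda"), family = family,
    stringsAsFactors = FALSE)
  rows <- list()
  for (q in names(labels)) {
    sp <- species_names[[labels[[q]]]]
    base <- 1000
    noise <- function() if (score_noise_sd > 0)
      stats::rnorm(1, 0, score_noise_sd) else 0
    hit <- function(species, genus, family, score, pident, qcovs = 100) {
      data.frame(qseqid = q, sseqid = paste0(gsub(" ", "_", species), "_acc"),
                 species = species, genus = genus, family = family,
                 bitscore = round(pmax(score, 1), 1), qcovs = qcovs,
                 pident = round(pident, 2), marker = marker,
                 stringsAsFactors = FALSE)
    }
    qrows <- list(hit(sp, genus, family, base + noise(), 99.5))
    if (stats::runif(1) < decoy_rate) {
      pool <- NULL
      if (!is.null(synonym_groups) && sp %in% names(synonym_groups)) {
        grp <- synonym_groups[[sp]]
        pool <- setdiff(names(synonym_groups)[synonym_groups == grp], sp)
      }
      if (length(pool) == 0) pool <- decoy_congeneric
      near <- sample(pool, 1)
      qrows <- c(qrows, list(hit(near, genus, family,
                                 base * 0.995 + noise(), 99.0)))
    }
    qrows <- c(qrows,
               list(hit(decoy_congeneric[1], genus, family,
                        base * 0.90 + noise(), 93.0),
                    hit(decoy_congeneric[2], genus, family,
                        base * 0.88 + noise(), 92.0),
                    hit(decoy_confamilial$species[1],
                        decoy_confamilial$genus[1],
                        decoy_confamilial$family[1],
                        base * 0.75 + noise(), 85.0),
                    hit(decoy_confamilial$species[2],
                        decoy_confamilial$genus[2],
                        decoy_confamilial$family[2],
                        base * 0.72 + noise(), 84.0)))
    rows <- c(rows, qrows)
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

# separable Gaussian smoothing of a matrix (reflected edges via kernel
# renormalization through banded smoother matrices)
.smooth_matrix <- function(m, sigma) {
  smoother <- function(n) {
    idx <- seq_len(n)
    K <- exp(-0.5 * outer(idx, idx, "-")^2 / sigma^2)
    K / rowSums(K)
  }
  Kr <- smoother(nrow(m))
  Kc <- smoother(ncol(m))
  Kr %*% m %*% t(Kc)
}

#' Simulate an environmental landscape with occurrences
#'
#' Generates `n_vars` smooth random fields (seeded Gaussian noise with
#' distance-kernel smoothing, kernel width 1/10 of the grid extent by
#' default), standardizes them over cells, and samples presences without
#' replacement with probability proportional to the true suitability
#' `exp(coeffs . z)`. A one-cell nodata border ring exercises masking.
#'
#' @param n_vars Number of environmental variables, default 19 (the
#'   standard bioclimatic set size).
#' @param nrows,ncols Grid dimensions, default 60 x 60.
#' @param coeffs Generating coefficient vector (length `n_vars`; zeros are
#'   noise variables).
#' @param n_presence Number of occurrence points, default 200.
#' @param seed Integer seed.
#' @param cellsize Degrees per cell, default 0.05.
#' @param xllcorner,yllcorner Grid origin, default 0/0.
#' @param smooth_frac Smoothing kernel width as a fraction of the grid
#'   extent, default 0.1.
#' @return List with `grids` (named list of `env_grid`, `bio01`...),
#'   `occurrences` (lon/lat data frame) and `truth` (list: `coeffs`,
#'   `suitability` grid, `seed`).
#' @export
simulate_landscape <- function(n_vars = 19, nrows = 60, ncols = 60,
                               coeffs = c(5, rep(0, n_vars - 1)),
                               n_presence = 200, seed = 1, cellsize = 0.05,
                               xllcorner = 0, yllcorner = 0,
                               smooth_frac = 0.1) {
  stopifnot(length(coeffs) == n_vars, nrows >= 10, ncols >= 10)
  set.seed(seed)
  sigma <- smooth_frac * max(nrows, ncols)
  names <- sprintf("bio%02d", seq_len(n_vars))
  border <- function(m) {
    m[c(1, nrow(m)), ] <- NA; m[, c(1, ncol(m))] <- NA; m
  }
  z <- vector("list", n_vars)
  grids <- vector("list", n_vars)
  for (k in seq_len(n_vars)) {
    field <- .smooth_matrix(matrix(stats::rnorm(nrows * ncols), nrows),
                            sigma)
    field <- (field - mean(field)) / stats::sd(field)
    z[[k]] <- field
    grids[[k]] <- env_grid(border(field), xllcorner, yllcorner, cellsize,
                           name = names[k])
  }
  names(grids) <- names
  eta <- Reduce(`+`, Map(function(zz, cc) cc * zz, z, as.list(coeffs)))
  suit <- exp(eta - max(eta))
  valid <- border(matrix(1, nrows, ncols))
  cells <- which(!is.na(valid))
  stopifnot(n_presence <= length(cells))
  picked <- sample(cells, n_presence, prob = suit[cells])
  row <- (picked - 1) %% nrows + 1
  col <- (picked - 1) %/% nrows + 1
  jit_x <- stats::runif(n_presence, -0.4, 0.4)
  jit_y <- stats::runif(n_presence, -0.4, 0.4)
  occurrences <- data.frame(
    lon = xllcorner + (col - 0.5 + jit_x) * cellsize,
    lat = yllcorner + (nrows - row + 0.5 + jit_y) * cellsize)
  truth <- list(coeffs = stats::setNames(coeffs, names),
                suitability = env_grid(border(suit / sum(suit)), xllcorner,
                                       yllcorner, cellsize,
                                       name = "true_suitability"),
                seed = seed)
  list(grids = grids, occurrences = occurrences, truth = truth)
}
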