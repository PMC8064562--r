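# One-command orchestration of the pipeline stages with a single config
# file, per-stage seeds derived from one top-level seed, and a manifest of
# outputs with checksums. Reruns with the same config and seed overwrite
# the run directory with byte-identical files.

.stage_names <- c("simulate", "distance", "delimit", "assign", "popgen",
                  "sdm")

.default_config <- function() {
  list(
    seed = 1,
    distance = list(model = "K2P"),
    simulate = list(
      sequences = list(k_species = 4, n_per = 8, length = 600,
                       intra = 0.005, inter = 0.08, kappa = 2,
                       markers = c("rbcL", "matK", "trnH-psbA", "ITS2",
                                   "ycf")),
      popgen = list(n_pops = 4, n_per = 6, migration_mix = 0.3),
      hits = list(score_noise_sd = 0, decoy_rate = 0.2),
      landscape = list(n_vars = 19, nrows = 60, ncols = 60,
                       dominant_coeff = 5, n_presence = 200)),
    delimit = list(P_min = 0.001, P_max = 0.100, n_steps = 10, X = 1.5,
                   W = 10, report_prior = 0.01),
    assign = list(method = "optimized", deviation = 0.01),
    popgen = list(n_perm = 1023),
    sdm = list(test_fraction = 0.25, beta = 1, background = 10000,
               min_flagged_vars = 3, jackknife = TRUE)
  )
}

.merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- .merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Read and validate a pipeline run configuration
#'
#' YAML with per-stage sections; omitted settings take the package
#' defaults, which follow the standard study settings (gap width X = 1.5,
#' prior range 0.001-0.100, 1023 permutations, 25% test split, minimum 3
#' flagged variables, GC threshold 0.65).
#'
#' @param path YAML path, or a pre-parsed list.
#' @return Validated config list.
#' @export
read_run_config <- function(path) {
  override <- if (is.character(path)) yaml::read_yaml(path) else path
  config <- .merge_config(.default_config(), override)
  stopifnot(config$delimit$P_min > 0,
            config$delimit$P_min < config$delimit$P_max,
            config$delimit$X > 0,
            config$sdm$test_fraction > 0, config$sdm$test_fraction < 1,
            config$popgen$n_perm >= 1)
  config
}

# every source of randomness flows from the one top-level seed through
# fixed per-purpose offsets
.stage_seed <- function(config, purpose) {
  offsets <- c(sequences = 11, popgen = 23, hits = 37, landscape = 53,
               split = 71, background = 89, fst = 97)
  as.integer((config$seed + offsets[[purpose]]) %% .Machine$integer.max)
}

.out <- function(outdir, ...) file.path(outdir, ...)

#' Run one pipeline stage
#'
#' Stages: `simulate` (synthetic sequences, population structure, hit
#' table, landscape), `distance` (per-marker distance matrices and NJ
#' trees), `delimit` (prior sweep + reported partition), `assign`
#' (taxonomic assignments and efficiency summary), `popgen` (AMOVA, Fst
#' permutation test, Nei matrix), `sdm` (cleaning, maxent fit, suitability
#' rasters, AUC evaluation, jackknife). Missing inputs raise an error
#' naming the producing stage.
#'
#' @param name Stage name.
#' @param config Config list ([read_run_config()]).
#' @param outdir Run directory.
#' @return Character vector of the files the stage wrote (relative paths).
#' @export
run_stage <- function(name, config, outdir) {
  name <- match.arg(name, .stage_names)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fn <- switch(name,
    simulate = .stage_simulate, distance = .stage_distance,
    delimit = .stage_delimit, assign = .stage_assign,
    popgen = .stage_popgen, sdm = .stage_sdm)
  fn(config, outdir)
}

.require_input <- function(path, producer) {
  if (!file.exists(path)) {
    stop("missing input '", path, "': run the '", producer,
         "' stage first", call. = FALSE)
  }
  path
}

.stage_simulate <- function(config, outdir) {
  sc <- config$simulate
  dir.create(.out(outdir, "sequences"), showWarnings = FALSE)
  dir.create(.out(outdir, "grids"), showWarnings = FALSE)
  files <- character(0)
  sites <- read_sample_table()
  truth <- NULL
  markers <- sc$sequences$markers
  for (i in seq_along(markers)) {
    sim <- simulate_species_sequences(
      k = sc$sequences$k_species, n_per = sc$sequences$n_per,
      L = sc$sequences$length, intra = sc$sequences$intra,
      inter = sc$sequences$inter, kappa = sc$sequences$kappa,
      seed = .stage_seed(config, "sequences") + i,
      marker = markers[i], sites = paste0("site", sites$site_no))
    if (is.null(truth)) truth <- sim$truth
    f <- .out(outdir, "sequences", paste0(markers[i], ".fasta"))
    write_fasta(sim$records, f)
    files <- c(files, f)
  }
  jsonlite::write_json(
    list(species = as.list(truth$species), params = truth$params),
    .out(outdir, "species_truth.json"), auto_unbox = TRUE, digits = NA)
  files <- c(files, .out(outdir, "species_truth.json"))

  pg <- simulate_population_structure(
    n_pops = sc$popgen$n_pops, n_per = sc$popgen$n_per,
    migration_mix = sc$popgen$migration_mix,
    seed = .stage_seed(config, "popgen"))
  write_fasta(pg$records, .out(outdir, "popgen.fasta"))
  utils::write.csv(data.frame(specimen_id = names(pg$pops),
                              population = unname(pg$pops)),
                   .out(outdir, "populations.csv"), row.names = FALSE,
                   quote = FALSE)
  files <- c(files, .out(outdir, "popgen.fasta"),
             .out(outdir, "populations.csv"))

  syn <- read_synonym_groups()
  tabs <- lapply(seq_along(markers), function(i) {
    sim <- simulate_species_sequences(
      k = sc$sequences$k_species, n_per = sc$sequences$n_per,
      L = sc$sequences$length, intra = sc$sequences$intra,
      inter = sc$sequences$inter, kappa = sc$sequences$kappa,
      seed = .stage_seed(config, "sequences") + i, marker = markers[i])
    simulate_hit_table(sim$truth,
                       score_noise_sd = sc$hits$score_noise_sd,
                       decoy_rate = sc$hits$decoy_rate,
                       seed = .stage_seed(config, "hits") + i,
                       synonym_groups = syn, marker = markers[i])
  })
  write_hit_table(do.call(rbind, tabs), .out(outdir, "hits.tsv"))
  files <- c(files, .out(outdir, "hits.tsv"))

  lc <- sc$landscape
  land <- simulate_landscape(
    n_vars = lc$n_vars, nrows = lc$nrows, ncols = lc$ncols,
    coeffs = c(lc$dominant_coeff, rep(0, lc$n_vars - 1)),
    n_presence = lc$n_presence, seed = .stage_seed(config, "landscape"))
  for (g in land$grids) {
    f <- .out(outdir, "grids", paste0(g$name, ".asc"))
    write_esri_ascii(g, f)
    files <- c(files, f)
  }
  utils::write.csv(land$occurrences, .out(outdir, "occurrences.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(as.list(land$truth$coeffs),
                       .out(outdir, "landscape_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  files <- c(files, .out(outdir, "occurrences.csv"),
             .out(outdir, "landscape_truth.json"))
  files
}

.pipeline_markers <- function(config, outdir) {
  markers <- config$simulate$sequences$markers
  for (m in markers) {
    .require_input(.out(outdir, "sequences", paste0(m, ".fasta")),
                   "simulate")
  }
  markers
}

.stage_distance <- function(config, outdir) {
  markers <- .pipeline_markers(config, outdir)
  dir.create(.out(outdir, "distance"), showWarnings = FALSE)
  files <- character(0)
  for (m in markers) {
    records <- read_fasta(.out(outdir, "sequences", paste0(m, ".fasta")))
    dm <- distance_matrix(records, config$distance$model)
    f <- .out(outdir, "distance", paste0(m, ".csv"))
    write_distance_matrix(dm, f)
    files <- c(files, f)
    if (nrow(dm) >= 3) {
      fn <- .out(outdir, "distance", paste0(m, ".nwk"))
      write_newick(nj_tree(dm), fn)
      files <- c(files, fn)
    }
  }
  files
}

.stage_delimit <- function(config, outdir) {
  markers <- .pipeline_markers(config, outdir)
  dc <- config$delimit
  dir.create(.out(outdir, "delimit"), showWarnings = FALSE)
  files <- character(0)
  for (m in markers) {
    records <- read_fasta(.out(outdir, "sequences", paste0(m, ".fasta")))
    dm <- distance_matrix(records, config$distance$model)
    sweep <- prior_sweep(dm, P_min = dc$P_min, P_max = dc$P_max,
                         n_steps = dc$n_steps, X = dc$X, W = dc$W)
    f1 <- .out(outdir, "delimit", paste0(m, "_sweep.tsv"))
    write_sweep(sweep, f1)
    part <- recursive_delimit(dm, dc$report_prior, X = dc$X, W = dc$W)
    f2 <- .out(outdir, "delimit", paste0(m, "_partition.tsv"))
    write_partition(part, f2)
    files <- c(files, f1, f2)
  }
  files
}

.stage_assign <- function(config, outdir) {
  hits <- read_hit_table(.require_input(.out(outdir, "hits.tsv"),
                                        "simulate"))
  syn <- read_synonym_groups()
  method <- config$assign$method
  deviation <- config$assign$deviation
  per_marker <- do.call(rbind, lapply(split(hits, hits$marker), function(h)
    assign_all(h, method, syn, deviation)))
  combos <- c("core", "coding", "non-coding", "cpDNA", "total")
  combos <- combos[vapply(combos, function(cb)
    all(combination_members(cb) %in% hits$marker), TRUE)]
  combined <- do.call(rbind, lapply(combos, function(cb)
    combine_assignments(per_marker, cb, syn)))
  all_assign <- rbind(per_marker, combined)
  dir.create(.out(outdir, "assign"), showWarnings = FALSE)
  f1 <- .out(outdir, "assign", "assignments.tsv")
  utils::write.table(all_assign, f1, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  f2 <- .out(outdir, "assign", "efficiency.csv")
  utils::write.csv(summarize_efficiency(all_assign), f2, row.names = FALSE,
                   quote = FALSE)
  c(f1, f2)
}

.stage_popgen <- function(config, outdir) {
  records <- read_fasta(.require_input(.out(outdir, "popgen.fasta"),
                                       "simulate"))
  popmap <- utils::read.csv(.require_input(.out(outdir, "populations.csv"),
                                           "simulate"),
                            stringsAsFactors = FALSE)
  pops <- stats::setNames(popmap$population, popmap$specimen_id)
  dm <- distance_matrix(records, "p")
  amova <- amova_one_level(dm, pops)
  test <- fst_permutation_test(dm, pops, n_perm = config$popgen$n_perm,
                               seed = .stage_seed(config, "fst"))
  freq <- haplotype_frequencies(records, pops)
  dir.create(.out(outdir, "popgen"), showWarnings = FALSE)
  f1 <- .out(outdir, "popgen", "amova.tsv")
  write_amova(amova, f1)
  f2 <- .out(outdir, "popgen", "fst_test.json")
  jsonlite::write_json(test, f2, auto_unbox = TRUE, digits = NA)
  f3 <- .out(outdir, "popgen", "nei_matrix.csv")
  write_distance_matrix(nei_matrix(freq), f3)
  c(f1, f2, f3)
}

.stage_sdm <- function(config, outdir) {
  sc <- config$sdm
  grid_files <- sort(list.files(.out(outdir, "grids"),
                                pattern = "\\.asc$", full.names = TRUE))
  if (length(grid_files) == 0) {
    stop("missing input '", .out(outdir, "grids"),
         "': run the 'simulate' stage first", call. = FALSE)
  }
  occ <- utils::read.csv(.require_input(.out(outdir, "occurrences.csv"),
                                        "simulate"),
                         stringsAsFactors = FALSE)
  grids <- lapply(grid_files, read_esri_ascii)
  ext <- extract_env(occ, grids)
  cleaning <- clean_occurrences(ext$env,
                                min_flagged_vars = sc$min_flagged_vars)
  env <- ext$env[cleaning$keep, , drop = FALSE]
  split <- split_train_test(nrow(env), sc$test_fraction,
                            seed = .stage_seed(config, "split"))
  background <- sample_background(grids, sc$background,
                                  seed = .stage_seed(config, "background"))
  model <- fit_maxent(env[split$train, , drop = FALSE], background,
                      beta = sc$beta)
  eval <- evaluate_sdm(model, env[split$train, , drop = FALSE],
                       env[split$test, , drop = FALSE], background,
                       test_fraction = sc$test_fraction)
  pred <- predict_suitability(model, grids)
  dir.create(.out(outdir, "sdm"), showWarnings = FALSE)
  files <- character(0)
  f <- .out(outdir, "sdm", "cleaning.csv")
  utils::write.csv(data.frame(lon = ext$occurrences$lon,
                              lat = ext$occurrences$lat,
                              n_flagged = cleaning$n_flagged,
                              kept = cleaning$keep),
                   f, row.names = FALSE, quote = FALSE)
  files <- c(files, f)
  for (nm in c("raw", "cumulative")) {
    f <- .out(outdir, "sdm", paste0("suitability_", nm, ".asc"))
    write_esri_ascii(pred[[nm]], f)
    files <- c(files, f)
  }
  f <- .out(outdir, "sdm", "evaluation.json")
  jsonlite::write_json(eval, f, auto_unbox = TRUE, digits = NA)
  files <- c(files, f)
  if (isTRUE(sc$jackknife)) {
    jk <- jackknife_importance(env[split$train, , drop = FALSE],
                               env[split$test, , drop = FALSE],
                               background, beta = sc$beta,
                               full_model = model)
    f <- .out(outdir, "sdm", "jackknife.csv")
    utils::write.csv(jk, f, row.names = FALSE, quote = FALSE)
    files <- c(files, f)
  }
  files
}

#' Run the full pipeline
#'
#' Executes all stages in order under one run directory and writes a
#' `manifest.json` recording the config, per-stage seeds, output files and
#' their MD5 checksums. A rerun with the same config and seed reproduces
#' every file byte-identically.
#'
#' @param config YAML path or config list ([read_run_config()]).
#' @param outdir Run directory.
#' @param seed Optional override of the config's top-level seed.
#' @param stages Stages to run, default all.
#' @return The manifest (invisibly), also written as JSON.
#' @export
run_pipeline <- function(config, outdir, seed = NULL,
                         stages = .stage_names) {
  config <- read_run_config(config)
  if (!is.null(seed)) config$seed <- seed
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version =
                     as.character(utils::packageVersion("barcodiv")),
                   seed = config$seed, config = config,
                   stages = list())
  for (st in stages) {
    files <- run_stage(st, config, outdir)
    rel <- sub(paste0("^", gsub("([][{}()+*^$\\\\.|?])", "\\\\\\1", outdir),
                      "/?"), "", files)
    checksums <- as.list(unname(tools::md5sum(files)))
    names(checksums) <- rel
    manifest$stages[[st]] <- list(n_outputs = length(files),
                                  outputs = checksums)
  }
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
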