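# Weighted BLAST-hit classification: rescoring, identity tiers,
# 1%-deviation candidate counting, the rank-assignment ladder, and
# discrimination-efficiency summaries.

.hit_columns <- c("qseqid", "sseqid", "species", "genus", "family",
                  "bitscore", "qcovs", "pident")

.rank_levels <- c("species", "species_group", "genus", "family", "unassigned")

#' Read an extended outfmt-6 hit table
#'
#' Tab-separated with header; required columns: `qseqid, sseqid, species,
#' genus, family, bitscore, qcovs, pident` (an offline stand-in for
#' NCBI/BOLD query results, carrying taxonomy alongside the usual BLAST
#' tabular fields). An optional `marker` column is preserved.
#'
#' @param path TSV path.
#' @return Data frame of typed hit records.
#' @export
read_hit_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(tab) == 0) {
    warning("empty hit table: ", path, call. = FALSE)
  }
  missing <- setdiff(.hit_columns, names(tab))
  if (length(missing) > 0) {
    stop("hit table schema error, missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(tab) > 0) {
    if (any(tab$pident <= 0 | tab$pident > 100)) {
      stop("pident outside (0, 100]", call. = FALSE)
    }
    if (any(tab$qcovs < 0 | tab$qcovs > 100)) {
      stop("qcovs outside [0, 100]", call. = FALSE)
    }
    if (any(tab$bitscore < 0)) stop("negative bitscore", call. = FALSE)
  }
  tab
}

#' Write a hit table TSV
#' @param hits Hit data frame.
#' @param path Output path.
#' @export
write_hit_table <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Identity-weighted hit score
#'
#' `max_score * (query_cover / identity)`: hits covering the full query at
#' modest identity are up-weighted relative to short perfect matches.
#'
#' @param max_score Bit score (nonnegative).
#' @param query_cover Query coverage percent in `[0, 100]`.
#' @param identity Percent identity in `(0, 100]`.
#' @return The weighted score.
#' @export
weighted_score <- function(max_score, query_cover, identity) {
  if (any(identity <= 0)) stop("identity must be > 0", call. = FALSE)
  max_score * (query_cover / identity)
}

#' Identity tier of a percent identity
#'
#' High for identity >= 95, Medium for 90 <= identity < 95, Low below 90.
#' The published tier boundaries overlap at 90 and 95; the upper bound wins
#' here (95 is High, 90 is Medium).
#'
#' @param identity Percent identity in `(0, 100]`.
#' @return `"High"`, `"Medium"` or `"Low"`.
#' @export
identity_tier <- function(identity) {
  ifelse(identity >= 95, "High", ifelse(identity >= 90, "Medium", "Low"))
}

#' Ordered candidate hits for one query
#'
#' The simple method keeps the top 10 hits by bit score; the optimized
#' method keeps the top 100 by bit score and re-ranks them by
#' [weighted_score()]. Ties break by identity (descending) then subject
#' species name (ascending), keeping the ordering stable.
#'
#' @param hits Hit rows for a single query.
#' @param method `"simple"` or `"optimized"`.
#' @return The candidate rows, ordered, with a `score` column holding the
#'   active method's ranking score.
#' @export
candidate_set <- function(hits, method = c("simple", "optimized")) {
  method <- match.arg(method)
  stopifnot(nrow(hits) >= 1)
  ord <- order(-hits$bitscore, -hits$pident, hits$species)
  hits <- hits[ord, , drop = FALSE]
  if (method == "simple") {
    out <- utils::head(hits, 10)
    out$score <- out$bitscore
  } else {
    out <- utils::head(hits, 100)
    out$score <- weighted_score(out$bitscore, out$qcovs, out$pident)
    out <- out[order(-out$score, -out$pident, out$species), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Species within a score deviation of the best candidate
#'
#' Distinct subject species whose ranking score is at least
#' `(1 - deviation)` times the best score.
#'
#' @param candidates Ordered candidates from [candidate_set()].
#' @param deviation Relative deviation, default 0.01 (1%).
#' @return Character vector of species names.
#' @export
species_within_deviation <- function(candidates, deviation = 0.01) {
  S <- candidates$score[1]
  if (!is.finite(S) || S <= 0) {
    stop("best candidate score must be positive", call. = FALSE)
  }
  unique(candidates$species[candidates$score >= (1 - deviation) * S])
}

#' Rank-level taxonomic assignment for one query
#'
#' Applies the tiered decision ladder to the candidate hits: (1) High
#' identity with a single species inside the deviation set assigns the
#' species; (2) a deviation set confined to one synonym group at
#' High/Medium identity assigns the species group; (3) one genus at
#' High/Medium assigns the genus; (4) one family at High/Medium assigns
#' the family; (5) otherwise the query is unassigned, except that at Low
#' identity a unanimous family still assigns the family.
#'
#' @param query_id Query identifier.
#' @param hits Hit rows for this query (possibly empty).
#' @param method `"simple"` or `"optimized"`.
#' @param synonym_groups Named character vector species -> group label
#'   (see [read_synonym_groups()]), or `NULL`.
#' @param deviation Relative score deviation, default 0.01.
#' @return One-row data frame: `query_id, rank, taxon, tier,
#'   n_candidate_species, method`, plus `genus`/`family` of the best
#'   candidate (used for combination consensus).
#' @export
assign_taxon <- function(query_id, hits, method = c("simple", "optimized"),
                         synonym_groups = NULL, deviation = 0.01) {
  method <- match.arg(method)
  if (is.null(hits) || nrow(hits) == 0) {
    return(data.frame(query_id = query_id, rank = "unassigned",
                      taxon = NA_character_, tier = NA_character_,
                      n_candidate_species = 0L, method = method,
                      genus = NA_character_, family = NA_character_,
                      stringsAsFactors = FALSE))
  }
  cands <- candidate_set(hits, method)
  tier <- identity_tier(cands$pident[1])
  devset <- species_within_deviation(cands, deviation)
  # taxonomy of the deviation-set species (first occurrence in candidates)
  idx <- match(devset, cands$species)
  genera <- unique(cands$genus[idx])
  families <- unique(cands$family[idx])
  best_genus <- cands$genus[1]; best_family <- cands$family[1]
  res <- function(rank, taxon) {
    data.frame(query_id = query_id, rank = rank, taxon = taxon, tier = tier,
               n_candidate_species = length(devset), method = method,
               genus = best_genus, family = best_family,
               stringsAsFactors = FALSE)
  }
  high_med <- tier %in% c("High", "Medium")
  if (tier == "High" && length(devset) == 1) {
    return(res("species", devset))
  }
  if (high_med && !is.null(synonym_groups)) {
    groups <- unname(synonym_groups[devset])
    if (!anyNA(groups) && length(unique(groups)) == 1) {
      return(res("species_group", groups[1]))
    }
  }
  if (high_med && length(genera) == 1) return(res("genus", genera))
  if (length(families) == 1) {
    if (high_med) return(res("family", families))
    # Low tier: family allowed only when unanimous across all candidates
    if (length(unique(cands$family)) == 1) return(res("family", families))
  }
  res("unassigned", NA_character_)
}

#' Assign every query in a hit table
#'
#' @param hit_table Hit data frame ([read_hit_table()]); an optional
#'   `marker` column is carried into the result.
#' @param method,synonym_groups,deviation See [assign_taxon()].
#' @return Data frame of assignments, one row per query.
#' @export
assign_all <- function(hit_table, method = c("simple", "optimized"),
                       synonym_groups = NULL, deviation = 0.01) {
  method <- match.arg(method)
  if (nrow(hit_table) == 0) {
    out <- assign_taxon("none", hit_table[0, ], method)[0, ]
    return(out)
  }
  pieces <- lapply(split(hit_table, hit_table$qseqid), function(h) {
    a <- assign_taxon(h$qseqid[1], h, method, synonym_groups, deviation)
    if ("marker" %in% names(h)) a$marker <- h$marker[1]
    a
  })
  out <- do.call(rbind, c(pieces, make.row.names = FALSE))
  out[order(out$query_id), , drop = FALSE]
}

# project an assignment onto a coarser rank; NA when not defined
.project_rank <- function(assignment, rank, synonym_groups = NULL) {
  r <- assignment$rank
  depth <- match(r, .rank_levels)
  target <- match(rank, .rank_levels)
  if (is.na(depth) || depth > 4 || target < depth) return(NA_character_)
  switch(rank,
    species = assignment$taxon,
    species_group = {
      if (r == "species_group") assignment$taxon
      else if (!is.null(synonym_groups)) unname(synonym_groups[assignment$taxon])
      else NA_character_
    },
    genus = if (r == "genus") assignment$taxon else assignment$genus,
    family = if (r == "family") assignment$taxon else assignment$family)
}

#' Consensus assignment across the member markers of a combination
#'
#' For each query, scans ranks from most to least specific and returns the
#' first rank at which a strict majority of the combination's member-marker
#' assignments project to the same taxon; the query is unassigned when no
#' rank reaches a majority. Markers without an assignment still count in
#' the denominator.
#'
#' @param assignments Per-marker assignment data frame (from [assign_all()]
#'   with a `marker` column).
#' @param combination_label Combination label, e.g. `"core"`.
#' @param synonym_groups Optional species -> group mapping used when
#'   projecting species-level calls onto the species-group rank.
#' @return Assignment data frame labeled with the combination.
#' @export
combine_assignments <- function(assignments, combination_label,
                                synonym_groups = NULL) {
  members <- combination_members(combination_label)
  sub <- assignments[assignments$marker %in% members, , drop = FALSE]
  queries <- sort(unique(sub$query_id))
  n_members <- length(members)
  if (length(queries) == 0) {
    out <- assignments[0, , drop = FALSE]
    if (!"marker" %in% names(out)) out$marker <- character(0)
    return(out)
  }
  pieces <- lapply(queries, function(q) {
    rows <- sub[sub$query_id == q, , drop = FALSE]
    out <- data.frame(query_id = q, rank = "unassigned",
                      taxon = NA_character_, tier = NA_character_,
                      n_candidate_species = NA_integer_,
                      method = rows$method[1], genus = NA_character_,
                      family = NA_character_, marker = combination_label,
                      stringsAsFactors = FALSE)
    for (rank in .rank_levels[1:4]) {
      votes <- vapply(seq_len(nrow(rows)), function(i)
        .project_rank(rows[i, ], rank, synonym_groups), "")
      votes <- votes[!is.na(votes)]
      if (length(votes) == 0) next
      tally <- sort(table(votes), decreasing = TRUE)
      if (tally[1] * 2 > n_members &&
          sum(tally == tally[1]) == 1) {
        out$rank <- rank
        out$taxon <- names(tally)[1]
        break
      }
    }
    out
  })
  do.call(rbind, c(pieces, make.row.names = FALSE))
}

#' Discrimination-efficiency summary
#'
#' Percentage of queries assigned at each rank, per marker or combination
#' label. Percentages sum to 100 within each label.
#'
#' @param assignments Assignment data frame carrying a `marker` column.
#' @return Data frame `label` x `rank` -> `percent`.
#' @export
summarize_efficiency <- function(assignments) {
  if (nrow(assignments) == 0) {
    return(data.frame(label = character(), rank = character(),
                      percent = numeric(), stringsAsFactors = FALSE))
  }
  if (!"marker" %in% names(assignments)) {
    stop("assignments need a 'marker' label column", call. = FALSE)
  }
  pieces <- lapply(split(assignments, assignments$marker), function(a) {
    counts <- table(factor(a$rank, levels = .rank_levels))
    data.frame(label = a$marker[1], rank = names(counts),
               percent = 100 * as.numeric(counts) / nrow(a),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(pieces, make.row.names = FALSE))
}
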