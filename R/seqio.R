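#' @import stats
#' @import utils
NULL

# IUPAC nucleotide alphabet, gaps included
.iupac_alphabet <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
                     "B", "D", "H", "V", "N", "-")

.validate_alphabet <- function(seqs, ids) {
  for (i in seq_along(seqs)) {
    chars <- unique(strsplit(seqs[[i]], "", fixed = TRUE)[[1]])
    bad <- setdiff(chars, .iupac_alphabet)
    if (length(bad) > 0) {
      stop("alphabet error in record '", ids[[i]], "': illegal character(s) ",
           paste(sQuote(bad), collapse = ", "), call. = FALSE)
    }
  }
  invisible(TRUE)
}

.validate_records <- function(records) {
  stopifnot(is.data.frame(records))
  need <- c("sample_id", "site_id", "marker", "seq")
  missing <- setdiff(need, names(records))
  if (length(missing) > 0) {
    stop("records are missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(!nzchar(records$seq))) stop("empty sequence in records", call. = FALSE)
  unknown <- setdiff(unique(records$marker), known_marker_labels())
  if (length(unknown) > 0) {
    stop("marker(s) not in the registry: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  invisible(records)
}

#' Read barcode sequences from a FASTA file
#'
#' Headers must follow the grammar `sample_id|site_id|marker` (three fields
#' separated by `|`). Sequences are uppercased and checked against the IUPAC
#' nucleotide alphabet (gaps `-` and ambiguity codes allowed).
#'
#' @param path Path to a FASTA file.
#' @return A data frame of sequence records with columns `sample_id`,
#'   `site_id`, `marker`, `seq`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) {
    return(data.frame(sample_id = character(), site_id = character(),
                      marker = character(), seq = character(),
                      stringsAsFactors = FALSE))
  }
  headers <- names(set)
  fields <- strsplit(headers, "|", fixed = TRUE)
  n_fields <- lengths(fields)
  if (any(n_fields != 3)) {
    bad <- which(n_fields != 3)[1]
    stop("parse error in FASTA header ", bad, " ('", headers[bad],
         "'): expected sample_id|site_id|marker", call. = FALSE)
  }
  seqs <- toupper(as.character(set))
  records <- data.frame(
    sample_id = vapply(fields, `[[`, "", 1L),
    site_id   = vapply(fields, `[[`, "", 2L),
    marker    = vapply(fields, `[[`, "", 3L),
    seq       = unname(seqs),
    stringsAsFactors = FALSE
  )
  .validate_alphabet(records$seq, records$sample_id)
  .validate_records(records)
  records
}

#' Write barcode sequence records to FASTA
#'
#' Headers are written as `sample_id|site_id|marker`; sequence lines are
#' wrapped at 60 columns. `read_fasta(write_fasta(x))` is the identity.
#'
#' @param records A record data frame as returned by [read_fasta()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  .validate_records(records)
  set <- Biostrings::BStringSet(records$seq)
  names(set) <- paste(records$sample_id, records$site_id, records$marker,
                      sep = "|")
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Convert degree/minute/second coordinates to decimal degrees
#'
#' @param degrees,minutes,seconds Numeric DMS components (`0 <= minutes < 60`,
#'   `0 <= seconds < 60`).
#' @param hemisphere_sign `+1`/`-1`, or one of `"+", "-", "N", "S", "E", "W"`
#'   (south and west are negative).
#' @return Decimal degrees, signed.
#' @export
dms_to_decimal <- function(degrees, minutes, seconds, hemisphere_sign = 1) {
  if (is.character(hemisphere_sign)) {
    hemisphere_sign <- switch(hemisphere_sign,
      "+" = 1, "N" = 1, "E" = 1, "-" = -1, "S" = -1, "W" = -1,
      stop("unknown hemisphere: '", hemisphere_sign, "'", call. = FALSE))
  }
  if (any(minutes < 0 | minutes >= 60)) {
    stop("minutes out of range [0, 60)", call. = FALSE)
  }
  if (any(seconds < 0 | seconds >= 60)) {
    stop("seconds out of range [0, 60)", call. = FALSE)
  }
  hemisphere_sign * (degrees + minutes / 60 + seconds / 3600)
}

#' Parse a DMS string such as "50° 49' 26.511''" to decimal degrees
#'
#' The first three numeric tokens are taken as degrees, minutes and seconds;
#' any separators are accepted. Strings whose minutes or seconds fall outside
#' `[0, 60)` (transcription defects) yield `NA` with a warning rather than an
#' error, so a metadata table with one bad coordinate still loads.
#'
#' @param x Character vector of DMS strings.
#' @param hemisphere_sign Sign(s), recycled; see [dms_to_decimal()].
#' @return Numeric vector of decimal degrees (`NA` where unparseable).
#' @export
parse_dms <- function(x, hemisphere_sign = 1) {
  sign <- rep_len(hemisphere_sign, length(x))
  out <- rep(NA_real_, length(x))
  for (i in seq_along(x)) {
    tokens <- regmatches(x[i], gregexpr("[0-9]+\\.?[0-9]*", x[i]))[[1]]
    if (length(tokens) < 3) {
      warning("cannot parse DMS string: '", x[i], "'", call. = FALSE)
      next
    }
    d <- as.numeric(tokens[1]); m <- as.numeric(tokens[2])
    s <- as.numeric(tokens[3])
    if (m < 0 || m >= 60 || s < 0 || s >= 60) {
      warning("DMS components out of range in '", x[i], "'", call. = FALSE)
      next
    }
    out[i] <- dms_to_decimal(d, m, s, sign[i])
  }
  out
}

#' Read the collection-site metadata table
#'
#' Expects a CSV with header `site_no,province,site_name,lon_dms,lat_dms`.
#' DMS strings are converted to decimal degrees (`lon_dd`, `lat_dd`);
#' unparseable coordinates become `NA` with a warning.
#'
#' @param path CSV path. Defaults to the packaged site table of the 26
#'   Iranian *Salicornia* collection sites.
#' @return Data frame with the original columns plus `lon_dd` and `lat_dd`.
#' @export
read_sample_table <- function(path = system.file("extdata",
                                                 "salicornia_sites.csv",
                                                 package = "barcodiv")) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  need <- c("site_no", "province", "site_name", "lon_dms", "lat_dms")
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0) {
    stop("site table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(tab$site_no)) stop("duplicate site_no", call. = FALSE)
  tab$lon_dd <- parse_dms(tab$lon_dms)
  tab$lat_dd <- parse_dms(tab$lat_dms)
  ok_lon <- is.na(tab$lon_dd) | (tab$lon_dd >= -180 & tab$lon_dd <= 180)
  ok_lat <- is.na(tab$lat_dd) | (tab$lat_dd >= -90 & tab$lat_dd <= 90)
  if (!all(ok_lon) || !all(ok_lat)) {
    stop("coordinates outside valid ranges", call. = FALSE)
  }
  tab
}

#' GC content of a nucleotide sequence
#'
#' Computed as (G+C)/(A+C+G+T); gaps, N and other ambiguity codes are
#' excluded from both numerator and denominator.
#'
#' @param seq A single sequence string.
#' @return Fraction in `[0, 1]`.
#' @export
gc_content <- function(seq) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  gc <- sum(chars == "G" | chars == "C")
  at <- sum(chars == "A" | chars == "T")
  if (gc + at == 0) {
    stop("GC content undefined: no unambiguous bases", call. = FALSE)
  }
  gc / (gc + at)
}

#' Flag high-GC records
#'
#' Records whose GC content strictly exceeds `threshold` are returned;
#' the field convention treats such amplicons as candidates for cloning
#' before sequencing. The boundary value itself is not flagged.
#'
#' @param records Sequence record data frame.
#' @param threshold GC fraction in (0, 1); default 0.65.
#' @return The flagged subset of `records` with an added `gc` column.
#' @export
flag_high_gc <- function(records, threshold = 0.65) {
  stopifnot(threshold > 0, threshold < 1)
  if (nrow(records) == 0) {
    records$gc <- numeric(0)
    return(records)
  }
  records$gc <- vapply(records$seq, gc_content, 0, USE.NAMES = FALSE)
  records[records$gc > threshold, , drop = FALSE]
}

#' Concatenate per-marker sequences into a combination record
#'
#' Member markers are concatenated in a fixed canonical order (alphabetical
#' by marker name); samples missing any member marker are excluded and
#' listed in the report.
#'
#' @param records Record data frame covering one or more markers.
#' @param combination_label A label registered in the marker registry,
#'   e.g. `"core"` (matK+rbcL) or `"total"`.
#' @return List with `records` (one concatenated record per complete sample)
#'   and `excluded` (data frame of sample_id and the markers it lacks).
#' @export
concatenate_markers <- function(records, combination_label) {
  .validate_records(records)
  members <- sort(combination_members(combination_label))
  samples <- unique(records$sample_id)
  out <- list(); excluded <- list()
  for (s in samples) {
    sub <- records[records$sample_id == s, , drop = FALSE]
    missing <- setdiff(members, sub$marker)
    if (length(missing) > 0) {
      excluded[[s]] <- data.frame(sample_id = s,
                                  missing = paste(missing, collapse = ";"),
                                  stringsAsFactors = FALSE)
      next
    }
    parts <- vapply(members, function(m) {
      hit <- sub$seq[sub$marker == m]
      if (length(hit) > 1) {
        stop("sample '", s, "' has multiple records for marker ", m,
             call. = FALSE)
      }
      hit
    }, "")
    out[[s]] <- data.frame(sample_id = s, site_id = sub$site_id[1],
                           marker = combination_label,
                           seq = paste(parts, collapse = ""),
                           stringsAsFactors = FALSE)
  }
  list(
    records = if (length(out)) do.call(rbind, c(out, make.row.names = FALSE))
              else data.frame(sample_id = character(), site_id = character(),
                              marker = character(), seq = character()),
    excluded = if (length(excluded))
                 do.call(rbind, c(excluded, make.row.names = FALSE))
               else data.frame(sample_id = character(), missing = character())
  )
}

#' Read species synonym groups
#'
#' A two-column CSV (`species,group`) mapping species names to a
#' species-group label (e.g. the *S. europaea* complex). Each species may
#' appear in at most one group.
#'
#' @param path CSV path; defaults to the packaged group seeded with the six
#'   names of the *S. europaea* complex.
#' @return Named character vector: species name -> group label.
#' @export
read_synonym_groups <- function(path = system.file("extdata",
                                                   "synonym_groups.csv",
                                                   package = "barcodiv")) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("species", "group") %in% names(tab))) {
    stop("synonym group file needs columns species,group", call. = FALSE)
  }
  if (anyDuplicated(tab$species)) {
    stop("species assigned to more than one group", call. = FALSE)
  }
  stats::setNames(tab$group, tab$species)
}
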