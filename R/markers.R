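#' Barcode marker registry
#'
#' The five barcode regions handled by the package and their genomic
#' provenance: three plastid coding regions (rbcL, matK, ycf), one plastid
#' intergenic spacer (trnH-psbA) and the nuclear internal transcribed
#' spacer ITS2.
#'
#' @return A data frame with columns `marker`, `genome`
#'   (`"plastid"`/`"nuclear"`) and `coding` (logical).
#' @export
marker_registry <- function() {
  data.frame(
    marker = c("rbcL", "matK", "ycf", "trnH-psbA", "ITS2"),
    genome = c("plastid", "plastid", "plastid", "plastid", "nuclear"),
    coding = c(TRUE, TRUE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

# combination labels -> member markers
.marker_combinations <- list(
  "core"       = c("matK", "rbcL"),
  "coding"     = c("matK", "rbcL", "ycf"),
  "non-coding" = c("trnH-psbA", "ITS2"),
  "cpDNA"      = c("matK", "rbcL", "ycf", "trnH-psbA"),
  "total"      = c("rbcL", "matK", "ycf", "trnH-psbA", "ITS2")
)

#' Member markers of a combination label
#'
#' @param label A combination label: one of `"core"`, `"coding"`,
#'   `"non-coding"`, `"cpDNA"`, `"total"`, or a single marker name.
#' @return Character vector of member marker names.
#' @export
combination_members <- function(label) {
  if (label %in% marker_registry()$marker) return(label)
  members <- .marker_combinations[[label]]
  if (is.null(members)) {
    stop("unknown marker or combination label: '", label, "'", call. = FALSE)
  }
  members
}

#' All labels accepted as a record's `marker` field
#' @return Character vector of single markers plus combination labels.
#' @export
known_marker_labels <- function() {
  c(marker_registry()$marker, names(.marker_combinations))
}
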