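# ESRI ASCII grid IO and occurrence-by-grid value extraction.

#' Construct an environmental grid
#'
#' @param values Numeric matrix, `nrows x ncols`, row 1 = northernmost row;
#'   `NA` marks nodata cells.
#' @param xllcorner,yllcorner Lower-left corner in decimal degrees.
#' @param cellsize Cell size in degrees (> 0).
#' @param nodata_value Sentinel written for `NA` cells (default -9999).
#' @param name Variable label.
#' @return An `env_grid` object.
#' @export
env_grid <- function(values, xllcorner = 0, yllcorner = 0, cellsize = 1,
                     nodata_value = -9999, name = "env") {
  stopifnot(is.matrix(values), cellsize > 0)
  structure(list(ncols = ncol(values), nrows = nrow(values),
                 xllcorner = xllcorner, yllcorner = yllcorner,
                 cellsize = cellsize, nodata_value = nodata_value,
                 values = values, name = name),
            class = "env_grid")
}

#' @export
print.env_grid <- function(x, ...) {
  cat("env_grid '", x$name, "': ", x$nrows, " x ", x$ncols,
      " cells, cellsize ", x$cellsize, ", ",
      sum(is.na(x$values)), " nodata\n", sep = "")
  invisible(x)
}

# exact double round-trip through text
.fmt_grid_value <- function(x) sprintf("%.17g", x)

#' Read an ESRI ASCII grid (.asc)
#'
#' Six-line header (`ncols, nrows, xllcorner, yllcorner, cellsize,
#' NODATA_value`) followed by row-major values, north row first. Nodata
#' cells become `NA`; the sentinel is preserved for writing.
#'
#' @param path `.asc` path.
#' @param name Variable label; defaults to the file name.
#' @return An `env_grid`.
#' @export
read_esri_ascii <- function(path, name = sub("\\.asc$", "", basename(path))) {
  lines <- readLines(path)
  if (length(lines) < 7) stop("ESRI ASCII format error: too few lines",
                              call. = FALSE)
  header <- list()
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) != 2) {
      stop("ESRI ASCII header error on line ", i, call. = FALSE)
    }
    header[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!all(need %in% names(header))) {
    stop("ESRI ASCII header missing keys: ",
         paste(setdiff(need, names(header)), collapse = ", "), call. = FALSE)
  }
  vals <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  nc <- header$ncols; nr <- header$nrows
  if (length(vals) != nc * nr) {
    stop("ESRI ASCII format error: expected ", nc * nr, " values, found ",
         length(vals), call. = FALSE)
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == header$nodata_value] <- NA
  env_grid(m, header$xllcorner, header$yllcorner, header$cellsize,
           header$nodata_value, name)
}

#' Write an ESRI ASCII grid (.asc)
#'
#' Values are written with enough digits that reading the file back
#' reproduces the doubles exactly; nodata cells are written as the grid's
#' sentinel token.
#'
#' @param grid An `env_grid`.
#' @param path Output path.
#' @export
write_esri_ascii <- function(grid, path) {
  stopifnot(inherits(grid, "env_grid"))
  header <- c(
    paste("ncols", grid$ncols),
    paste("nrows", grid$nrows),
    paste("xllcorner", .fmt_grid_value(grid$xllcorner)),
    paste("yllcorner", .fmt_grid_value(grid$yllcorner)),
    paste("cellsize", .fmt_grid_value(grid$cellsize)),
    paste("NODATA_value", .fmt_grid_value(grid$nodata_value)))
  m <- grid$values
  rows <- vapply(seq_len(nrow(m)), function(i) {
    v <- m[i, ]
    out <- .fmt_grid_value(v)
    out[is.na(v)] <- .fmt_grid_value(grid$nodata_value)
    paste(out, collapse = " ")
  }, "")
  writeLines(c(header, rows), path)
  invisible(path)
}

.check_shared_extent <- function(grids) {
  ref <- grids[[1]]
  for (g in grids[-1]) {
    same <- g$ncols == ref$ncols && g$nrows == ref$nrows &&
      isTRUE(all.equal(g$xllcorner, ref$xllcorner)) &&
      isTRUE(all.equal(g$yllcorner, ref$yllcorner)) &&
      isTRUE(all.equal(g$cellsize, ref$cellsize))
    if (!same) stop("grids have mismatched extents/cellsizes", call. = FALSE)
  }
  ref
}

# point -> (row, col) in matrix coordinates; NA when outside the extent.
# Half-open cell intervals with origin at the lower-left corner: a point on
# a shared edge belongs to the higher-index (east/north) cell.
.cell_index <- function(grid, lon, lat) {
  col <- floor((lon - grid$xllcorner) / grid$cellsize) + 1
  row_from_bottom <- floor((lat - grid$yllcorner) / grid$cellsize) + 1
  inside <- col >= 1 & col <= grid$ncols &
    row_from_bottom >= 1 & row_from_bottom <= grid$nrows
  row <- grid$nrows - row_from_bottom + 1
  list(row = ifelse(inside, row, NA), col = ifelse(inside, col, NA),
       inside = inside)
}

#' Extract environmental values at occurrence points
#'
#' Nearest-cell lookup for each occurrence in each grid. Occurrences
#' outside the shared extent, or landing on a nodata cell in any grid, are
#' dropped and reported.
#'
#' @param occurrences Data frame with `lon` and `lat` (decimal degrees).
#' @param grids List of `env_grid` objects sharing extent and cellsize.
#' @return List with `env` (occurrence x variable matrix for the retained
#'   points), `occurrences` (retained rows) and `dropped` (data frame of
#'   dropped rows with a `reason`).
#' @export
extract_env <- function(occurrences, grids) {
  stopifnot(all(c("lon", "lat") %in% names(occurrences)))
  ref <- .check_shared_extent(grids)
  idx <- .cell_index(ref, occurrences$lon, occurrences$lat)
  n <- nrow(occurrences)
  env <- matrix(NA_real_, n, length(grids),
                dimnames = list(NULL, vapply(grids, `[[`, "", "name")))
  for (k in seq_along(grids)) {
    m <- grids[[k]]$values
    ok <- idx$inside
    env[ok, k] <- m[cbind(idx$row[ok], idx$col[ok])]
  }
  reason <- rep(NA_character_, n)
  reason[!idx$inside] <- "outside extent"
  nodata <- idx$inside & apply(env, 1, anyNA)
  reason[nodata] <- "nodata cell"
  keep <- is.na(reason)
  dropped <- occurrences[!keep, , drop = FALSE]
  if (nrow(dropped) > 0) dropped$reason <- reason[!keep]
  list(env = env[keep, , drop = FALSE],
       occurrences = occurrences[keep, , drop = FALSE],
       dropped = dropped)
}
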