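# Categorical land-use raster: integer class codes on a regular grid in
# metric coordinates. Stored row 1 = top (north), as in the ESRI ASCII
# format itself.

#' Construct a land-use grid
#'
#' @param codes Integer matrix of class codes (1..n_classes), `NA` = NODATA.
#'   Row 1 is the northernmost row.
#' @param cellsize Cell edge length in metres (> 0).
#' @param xll,yll Coordinates of the lower-left corner of the grid (m).
#' @param classes Named integer vector of admissible codes; default the
#'   seven land-use categories used throughout the package.
#' @return Object of class `landuse_grid`.
#' @export
landuse_grid <- function(codes, cellsize, xll = 0, yll = 0,
                         classes = landuse_classes()) {
  stopifnot(is.matrix(codes), cellsize > 0)
  bad <- setdiff(unique(codes[!is.na(codes)]), classes)
  if (length(bad)) abort(paste("unknown land-use code(s):",
                               paste(bad, collapse = ", ")))
  structure(list(codes = codes, cellsize = cellsize, xll = xll, yll = yll,
                 classes = classes),
            class = "landuse_grid")
}

#' The seven land-use categories
#'
#' Cultivated land, forest land, grass/shrubland, construction land, water
#' area, wetland, and bare land, coded 1..7.
#' @return Named integer vector.
#' @export
landuse_classes <- function() {
  c(cultivated = 1L, forest = 2L, grass = 3L, construction = 4L,
    water = 5L, wetland = 6L, bare = 7L)
}

#' @export
print.landuse_grid <- function(x, ...) {
  cat("<landuse_grid>", nrow(x$codes), "x", ncol(x$codes),
      "cells,", x$cellsize, "m cells, origin (", x$xll, ",", x$yll, ")\n")
  invisible(x)
}

#' Read / write ESRI ASCII grids
#'
#' Minimal reader for the plain-text `.asc` raster format (header lines
#' `ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`, optional
#' `NODATA_value`, then `nrows` rows of values, northernmost first).
#'
#' @param path File path.
#' @return [read_landuse_asc()]: a `landuse_grid`.
#' @export
read_landuse_asc <- function(path) {
  lines <- readLines(path)
  hdr <- list(); i <- 1
  repeat {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    key <- tolower(parts[1])
    if (!key %in% c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
                    "nodata_value")) break
    hdr[[key]] <- as.numeric(parts[2]); i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    abort(paste("invalid ESRI ASCII header; need", paste(need, collapse = ", ")))
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    abort("ESRI ASCII body does not match ncols x nrows")
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  landuse_grid(m, cellsize = hdr$cellsize, xll = hdr$xllcorner,
               yll = hdr$yllcorner)
}

#' @rdname read_landuse_asc
#' @param grid A `landuse_grid`.
#' @export
write_landuse_asc <- function(grid, path) {
  m <- grid$codes
  m[is.na(m)] <- -9999
  hdr <- c(paste("ncols", ncol(m)), paste("nrows", nrow(m)),
           paste("xllcorner", grid$xll), paste("yllcorner", grid$yll),
           paste("cellsize", grid$cellsize), "NODATA_value -9999")
  body <- apply(m, 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

# cell-centre coordinates; row r counts from the top
cell_centres <- function(grid) {
  nr <- nrow(grid$codes); nc <- ncol(grid$codes); cs <- grid$cellsize
  list(x = grid$xll + (seq_len(nc) - 0.5) * cs,
       y = grid$yll + (nr - seq_len(nr) + 0.5) * cs)
}
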