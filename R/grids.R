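#' ESRI ASCII raster grids
#'
#' Minimal reader/writer for the ESRI ASCII grid interchange format: a
#' six-line header (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`,
#' `NODATA_value`) followed by `nrows` rows of values in row-major order
#' starting at the north-west corner. Values equal to the NODATA sentinel are
#' stored as `NA`.
#'
#' @param path file path.
#' @return `read_ascii_grid()` returns an `ascii_grid`: a list with `data`
#'   (numeric matrix, row 1 = northernmost), `xllcorner`, `yllcorner`,
#'   `cellsize`, `nodata`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  for (i in 1:6) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    hdr[[tolower(kv[1L])]] <- as.numeric(kv[2L])
  }
  vals <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == hdr$nodata_value] <- NA
  ascii_grid(m, xllcorner = hdr$xllcorner, yllcorner = hdr$yllcorner,
             cellsize = hdr$cellsize, nodata = hdr$nodata_value)
}

#' @rdname read_ascii_grid
#' @param data numeric matrix (row 1 = northernmost row).
#' @param xllcorner,yllcorner lower-left corner coordinates.
#' @param cellsize cell size.
#' @param nodata NODATA sentinel written on output.
#' @export
ascii_grid <- function(data, xllcorner = 0, yllcorner = 0, cellsize = 1,
                       nodata = -9999) {
  if (!is.matrix(data)) abort("data must be a matrix.",
                              class = "comdemog_config_error")
  structure(list(data = data, xllcorner = xllcorner, yllcorner = yllcorner,
                 cellsize = cellsize, nodata = nodata),
            class = "ascii_grid")
}

#' @rdname read_ascii_grid
#' @param grid an `ascii_grid`.
#' @export
write_ascii_grid <- function(grid, path) {
  m <- grid$data
  m[is.na(m)] <- grid$nodata
  hdr <- c(
    paste("ncols", ncol(m)),
    paste("nrows", nrow(m)),
    paste("xllcorner", format(grid$xllcorner, scientific = FALSE)),
    paste("yllcorner", format(grid$yllcorner, scientific = FALSE)),
    paste("cellsize", format(grid$cellsize, scientific = FALSE)),
    paste("NODATA_value", format(grid$nodata, scientific = FALSE))
  )
  rows <- apply(m, 1L, function(r) paste(format(r, trim = TRUE,
                                                digits = 15), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @export
print.ascii_grid <- function(x, ...) {
  cat(sprintf("<ascii_grid> %d x %d cells (cellsize %g), %d NODATA\n",
              nrow(x$data), ncol(x$data), x$cellsize, sum(is.na(x$data))))
  invisible(x)
}

same_geometry <- function(a, b) {
  identical(dim(a$data), dim(b$data)) &&
    isTRUE(all.equal(c(a$xllcorner, a$yllcorner, a$cellsize),
                     c(b$xllcorner, b$yllcorner, b$cellsize)))
}
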