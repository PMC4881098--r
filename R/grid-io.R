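#' Construct a DEMGrid
#'
#' @param values numeric matrix of elevations (row 1 = northernmost row);
#'   \code{NA} marks nodata.
#' @param cellSize cell edge in meters (default 100, the resolution used for
#'   the terrain indices).
#' @param origin map coordinates of the top-left grid corner,
#'   \code{c(xmin, ymax)}.
#' @param nodata sentinel written to disk for \code{NA} cells.
#' @param crs free-text projected-CRS note.
#' @return a [DEMGrid-class].
#' @examples
#' dem <- DEMGrid(matrix(1000, 4, 4))
#' dim(dem)
#' @export
DEMGrid <- function(values, cellSize = 100, origin = c(0, nrow(values) * cellSize),
                    nodata = -9999, crs = "local projected CRS (meters)") {
  new("DEMGrid", values = values, cellSize = cellSize,
      origin = as.numeric(origin), nodata = nodata, crs = crs)
}

#' Construct a ResidentialMask aligned to a DEM
#'
#' @param mask logical or 0/1 matrix (1 = residential).
#' @param dem the [DEMGrid-class] the mask annotates; geometry is copied.
#' @return a [ResidentialMask-class].
#' @export
ResidentialMask <- function(mask, dem) {
  m <- mask
  storage.mode(m) <- "double"
  if (!all(dim(m) == dim(dem@values)))
    .dataError("residential mask (%d x %d) does not match DEM (%d x %d)",
               nrow(m), ncol(m), nrow(dem@values), ncol(dem@values))
  new("ResidentialMask", values = m, cellSize = dem@cellSize,
      origin = dem@origin, nodata = dem@nodata, crs = dem@crs)
}

#' Read and write ESRI ASCII grids
#'
#' Plain-text raster exchange format: a six-line header (ncols, nrows,
#' xllcorner, yllcorner, cellsize, NODATA_value) followed by rows of values
#' from north to south. Cells equal to the nodata sentinel become \code{NA}.
#'
#' @param path file path.
#' @param crs CRS note to attach on read (the format itself carries none).
#' @return \code{readAsciiGrid} returns a [DEMGrid-class];
#'   \code{writeAsciiGrid} returns \code{path} invisibly.
#' @examples
#' f <- tempfile(fileext = ".asc")
#' writeAsciiGrid(DEMGrid(matrix(1:6, 2, 3)), f)
#' readAsciiGrid(f)
#' @export
readAsciiGrid <- function(path, crs = "local projected CRS (meters)") {
  if (!file.exists(path)) .configError("raster file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 0L
  while (i < length(lines)) {
    parts <- strsplit(trimws(lines[i + 1L]), "\\s+")[[1]]
    if (length(parts) == 2L && grepl("^[A-Za-z_]", parts[1])) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
      i <- i + 1L
    } else break
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    .dataError("malformed ESRI ASCII header in %s", path)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(text = paste(lines[-seq_len(i)], collapse = "\n"),
               quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc)
    .dataError("expected %d values in %s, found %d", nr * nc, path,
               length(vals))
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  DEMGrid(m, cellSize = hdr$cellsize,
          origin = c(hdr$xllcorner, hdr$yllcorner + nr * hdr$cellsize),
          nodata = nodata, crs = crs)
}

#' @param grid a [DEMGrid-class] (or [ResidentialMask-class]) to write.
#' @rdname readAsciiGrid
#' @export
writeAsciiGrid <- function(grid, path) {
  v <- grid@values
  nr <- nrow(v); nc <- ncol(v)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", nc),
    sprintf("nrows %d", nr),
    sprintf("xllcorner %.10g", grid@origin[1]),
    sprintf("yllcorner %.10g", grid@origin[2] - nr * grid@cellSize),
    sprintf("cellsize %.10g", grid@cellSize),
    sprintf("NODATA_value %.10g", grid@nodata)
  ), con)
  v[is.na(v)] <- grid@nodata
  writeLines(apply(v, 1L, function(r)
    paste(formatC(r, format = "g", digits = 10), collapse = " ")), con)
  invisible(path)
}
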