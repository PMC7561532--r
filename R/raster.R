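#' Lightweight in-memory raster
#'
#' A minimal regular-grid raster: a numeric matrix with an origin and a
#' square cell size in projected meters. Row 1 is the northernmost row
#' (map orientation), column 1 the westernmost column. Cell centers are at
#' `xll + (col - 0.5) * cell` and `yll + (nrow - row + 0.5) * cell`.
#'
#' @param values numeric or integer matrix.
#' @param xll,yll coordinates (m) of the lower-left corner of the grid.
#' @param cell cell size (m), strictly positive.
#' @param categories optional character vector naming integer codes
#'   (for categorical rasters such as land cover).
#' @return an object of class `grid_raster`.
#' @export
grid_raster <- function(values, xll = 0, yll = 0, cell, categories = NULL) {
  stopifnot(is.matrix(values))
  if (!is.numeric(cell) || length(cell) != 1L || !is.finite(cell) || cell <= 0) {
    stop("invalid-spec: cell size must be a positive number", call. = FALSE)
  }
  structure(
    list(values = values, xll = xll, yll = yll, cell = cell,
         categories = categories),
    class = "grid_raster"
  )
}

#' @export
print.grid_raster <- function(x, ...) {
  cat(sprintf("<grid_raster> %d x %d cells of %g m, origin (%g, %g)\n",
              nrow(x$values), ncol(x$values), x$cell, x$xll, x$yll))
  if (!is.null(x$categories)) {
    cat("categories:", paste(x$categories, collapse = ", "), "\n")
  }
  invisible(x)
}

raster_extent <- function(r) {
  c(xmin = r$xll, xmax = r$xll + ncol(r$values) * r$cell,
    ymin = r$yll, ymax = r$yll + nrow(r$values) * r$cell)
}

raster_in_bounds <- function(r, x, y) {
  e <- raster_extent(r)
  x >= e["xmin"] & x <= e["xmax"] & y >= e["ymin"] & y <= e["ymax"]
}

# Row/col of the cell containing each point. Points on the east/north
# boundary are assigned to the last cell.
raster_rowcol <- function(r, x, y) {
  nx <- ncol(r$values); ny <- nrow(r$values)
  col <- pmin(pmax(floor((x - r$xll) / r$cell) + 1, 1), nx)
  row <- pmin(pmax(ny - floor((y - r$yll) / r$cell), 1), ny)
  cbind(row = row, col = col)
}

#' Extract raster values at point locations
#'
#' @param r a [grid_raster()].
#' @param x,y point coordinates (m); vectors of equal length.
#' @return vector of cell values at the containing cells.
#' @export
raster_extract <- function(r, x, y) {
  ok <- raster_in_bounds(r, x, y)
  if (any(!ok)) {
    i <- which(!ok)[1]
    stop(sprintf("point (%g, %g) is outside the raster extent", x[i], y[i]),
         call. = FALSE)
  }
  rc <- raster_rowcol(r, x, y)
  r$values[cbind(rc[, "row"], rc[, "col"])]
}

# Values (and optionally coordinates) of cells whose CENTERS fall within
# `radius` of (x0, y0). Circles reaching past the raster edge are clipped;
# the coverage fraction (cells available / cells expected for a full
# circle) is attached as an attribute.
raster_circle_values <- function(r, x0, y0, radius, coords = FALSE) {
  cell <- r$cell
  nx <- ncol(r$values); ny <- nrow(r$values)
  jmin <- max(1L, floor((x0 - radius - r$xll) / cell - 0.5) + 1L)
  jmax <- min(nx, ceiling((x0 + radius - r$xll) / cell + 0.5))
  # y center of row i is yll + (ny - i + 0.5)*cell; invert for row range
  imin <- max(1L, floor(ny - (y0 + radius - r$yll) / cell + 0.5))
  imax <- min(ny, ceiling(ny - (y0 - radius - r$yll) / cell + 0.5))
  if (jmin > jmax || imin > imax) {
    out <- r$values[0]
    attr(out, "coverage") <- 0
    return(out)
  }
  jj <- jmin:jmax; ii <- imin:imax
  xc <- r$xll + (jj - 0.5) * cell
  yc <- r$yll + (ny - ii + 0.5) * cell
  dx2 <- outer(rep(1, length(ii)), (xc - x0)^2)
  dy2 <- outer((yc - y0)^2, rep(1, length(jj)))
  inside <- (dx2 + dy2) <= radius^2
  vals <- r$values[ii, jj, drop = FALSE][inside]
  n_expected <- sum_circle_cells(cell, radius)
  attr(vals, "coverage") <- length(vals) / n_expected
  if (coords) {
    attr(vals, "x") <- outer(rep(1, length(ii)), xc)[inside]
    attr(vals, "y") <- outer(yc, rep(1, length(jj)))[inside]
  }
  vals
}

# Number of cell centers of an infinite grid (aligned at half-cells) that a
# circle of `radius` would cover; used as the clipped-circle denominator.
sum_circle_cells <- function(cell, radius) {
  k <- ceiling(radius / cell) + 1L
  offs <- (-k:k + 0)
  xs <- offs * cell
  sum(outer(xs^2, xs^2, "+") <= radius^2)
}

#' Write a raster as an ESRI ASCII grid
#'
#' Plain-text interchange format readable by standard GIS software.
#'
#' @param r a [grid_raster()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(r, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(r$values)),
    sprintf("nrows %d", nrow(r$values)),
    sprintf("xllcorner %.10g", r$xll),
    sprintf("yllcorner %.10g", r$yll),
    sprintf("cellsize %.10g", r$cell),
    "NODATA_value -9999"
  ), con)
  write.table(r$values, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path file path.
#' @param categories optional category names for integer-coded rasters.
#' @return a [grid_raster()].
#' @export
read_ascii_grid <- function(path, categories = NULL) {
  hdr <- readLines(path, n = 6)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  h <- setNames(as.numeric(kv[, 2]), tolower(kv[, 1]))
  vals <- as.matrix(read.table(path, skip = 6))
  dimnames(vals) <- NULL
  vals[vals == h[["nodata_value"]]] <- NA
  stopifnot(nrow(vals) == h[["nrows"]], ncol(vals) == h[["ncols"]])
  grid_raster(vals, xll = h[["xllcorner"]], yll = h[["yllcorner"]],
              cell = h[["cellsize"]], categories = categories)
}
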