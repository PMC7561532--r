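# Land-cover class codes used throughout the package.
LC_FOREST <- 1L; LC_OPEN <- 2L; LC_WETLAND <- 3L; LC_ANTHRO <- 4L
LC_CLASSES <- c("forest", "open", "wetland", "anthropogenic")

#' Reclassify a raw land-cover raster into the four analysis classes
#'
#' Collapses a many-class inventory raster into
#' forest / open / wetland / anthropogenic.
#'
#' @param r a categorical [grid_raster()] with integer codes.
#' @param mapping named character vector: names are raw codes (as
#'   character), values are one of `"forest"`, `"open"`, `"wetland"`,
#'   `"anthropogenic"`.
#' @return a [grid_raster()] coded 1..4 with `categories` set.
#' @export
reclass_landcover <- function(r, mapping) {
  stopifnot(inherits(r, "grid_raster"))
  raw <- unique(as.vector(r$values))
  raw <- raw[!is.na(raw)]
  missing_codes <- setdiff(as.character(raw), names(mapping))
  if (length(missing_codes)) {
    stop("unmapped land-cover codes: ", paste(missing_codes, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(mapping), LC_CLASSES)
  if (length(bad)) {
    stop("mapping targets must be one of ", paste(LC_CLASSES, collapse = ", "),
         call. = FALSE)
  }
  code <- setNames(match(mapping, LC_CLASSES), names(mapping))
  vals <- matrix(code[as.character(r$values)], nrow(r$values), ncol(r$values))
  grid_raster(vals, xll = r$xll, yll = r$yll, cell = r$cell,
              categories = LC_CLASSES)
}

#' Focal class proportion around a point
#'
#' Fraction of raster cells whose centers lie within `radius` of the point
#' that belong to `class`. Circles reaching past the raster edge are
#' clipped and the proportion is computed over the available cells.
#'
#' @param r categorical [grid_raster()] coded 1..4.
#' @param class class name (`"forest"`, ...) or integer code.
#' @param radius radius in meters.
#' @param x,y point coordinates (m).
#' @return proportion in `[0, 1]`.
#' @export
focal_proportion <- function(r, class, radius, x, y) {
  code <- if (is.character(class)) match(class, LC_CLASSES) else as.integer(class)
  stopifnot(!is.na(code))
  vals <- raster_circle_values(r, x, y, radius)
  if (length(vals) == 0) stop("no raster cells within radius", call. = FALSE)
  mean(vals == code)
}

#' Forest-open edge density around a point
#'
#' Total length of boundaries shared between a forest cell and an open
#' cell (other class adjacencies are ignored) whose midpoints lie within
#' `radius` of the point, divided by the circle area `pi * radius^2`.
#'
#' @param r categorical [grid_raster()] coded 1..4.
#' @param x,y point coordinates (m).
#' @param radius radius in meters (default 50).
#' @return edge density in meters of boundary per square meter.
#' @export
edge_density <- function(r, x, y, radius = 50) {
  cell <- r$cell
  nx <- ncol(r$values); ny <- nrow(r$values)
  jmin <- max(1L, floor((x - radius - r$xll) / cell)); jmax <- min(nx, ceiling((x + radius - r$xll) / cell) + 1L)
  imin <- max(1L, floor(ny - (y + radius - r$yll) / cell)); imax <- min(ny, ceiling(ny - (y - radius - r$yll) / cell) + 1L)
  if (jmin > jmax || imin > imax) return(0)
  ii <- imin:imax; jj <- jmin:jmax
  w <- r$values[ii, jj, drop = FALSE]
  xc <- r$xll + (jj - 0.5) * cell
  yc <- r$yll + (ny - ii + 0.5) * cell
  total <- 0
  ni <- length(ii); nj <- length(jj)
  if (ni >= 2) {  # vertical neighbors -> horizontal shared edges
    a <- w[-ni, , drop = FALSE]; b <- w[-1, , drop = FALSE]
    is_edge <- (a == LC_FOREST & b == LC_OPEN) | (a == LC_OPEN & b == LC_FOREST)
    mx <- matrix(xc, ni - 1, nj, byrow = TRUE)
    my <- matrix((yc[-ni] + yc[-1]) / 2, ni - 1, nj)
    total <- total + cell * sum(is_edge & ((mx - x)^2 + (my - y)^2 <= radius^2))
  }
  if (nj >= 2) {  # horizontal neighbors -> vertical shared edges
    a <- w[, -nj, drop = FALSE]; b <- w[, -1, drop = FALSE]
    is_edge <- (a == LC_FOREST & b == LC_OPEN) | (a == LC_OPEN & b == LC_FOREST)
    mx <- matrix((xc[-nj] + xc[-1]) / 2, ni, nj - 1, byrow = TRUE)
    my <- matrix(yc, ni, nj - 1)
    total <- total + cell * sum(is_edge & ((mx - x)^2 + (my - y)^2 <= radius^2))
  }
  total / (pi * radius^2)
}

#' Simpson diversity of forest, open, and wetland around a point
#'
#' `1 - sum(p_i^2)` where `p_i` are the proportions of forest, open and
#' wetland among cells of those three classes within `radius`
#' (anthropogenic cells are excluded from the denominator).
#'
#' @param r categorical [grid_raster()] coded 1..4.
#' @param x,y point coordinates (m).
#' @param radius radius in meters (default 500).
#' @return diversity in `[0, 2/3]` for three classes.
#' @export
simpson_diversity <- function(r, x, y, radius = 500) {
  vals <- raster_circle_values(r, x, y, radius)
  vals <- vals[vals %in% c(LC_FOREST, LC_OPEN, LC_WETLAND)]
  if (length(vals) == 0) return(0)
  p <- tabulate(vals, nbins = 3) / length(vals)
  1 - sum(p^2)
}

#' Slope raster from a DEM
#'
#' Horn's 3x3 finite-difference gradient; slope is `atan(|grad z|)` in
#' radians. Grid borders use edge replication.
#'
#' @param dem a [grid_raster()] of elevations (m).
#' @return a [grid_raster()] of slopes (radians).
#' @export
slope_from_dem <- function(dem) {
  z <- dem$values
  ny <- nrow(z); nx <- ncol(z)
  zp <- z[c(1, seq_len(ny), ny), c(1, seq_len(nx), nx)]  # replicate edges
  i <- 2:(ny + 1); j <- 2:(nx + 1)
  z1 <- zp[i - 1, j - 1]; z2 <- zp[i - 1, j]; z3 <- zp[i - 1, j + 1]
  z4 <- zp[i,     j - 1];                      z6 <- zp[i,     j + 1]
  z7 <- zp[i + 1, j - 1]; z8 <- zp[i + 1, j]; z9 <- zp[i + 1, j + 1]
  gx <- ((z3 + 2 * z6 + z9) - (z1 + 2 * z4 + z7)) / (8 * dem$cell)
  gy <- ((z1 + 2 * z2 + z3) - (z7 + 2 * z8 + z9)) / (8 * dem$cell)
  grid_raster(atan(sqrt(gx^2 + gy^2)), xll = dem$xll, yll = dem$yll,
              cell = dem$cell)
}

#' Linear-corridor density around a point
#'
#' Total length (km) of corridor line segments clipped to the circle of
#' the given radius; the unit is kilometers per circle, not per area,
#' so local (100 m) and landscape (500 m) scales stay comparable.
#'
#' @param lines data.frame with columns `x0, y0, x1, y1` (m).
#' @param x,y circle center (m).
#' @param radius circle radius (m).
#' @return clipped corridor length in km.
#' @export
corridor_density <- function(lines, x, y, radius) {
  if (is.null(lines) || nrow(lines) == 0) return(0)
  dx <- lines$x1 - lines$x0; dy <- lines$y1 - lines$y0
  fx <- lines$x0 - x; fy <- lines$y0 - y
  a <- dx^2 + dy^2
  b <- 2 * (fx * dx + fy * dy)
  cc <- fx^2 + fy^2 - radius^2
  disc <- b^2 - 4 * a * cc
  len <- numeric(nrow(lines))
  ok <- disc > 0 & a > 0
  if (any(ok)) {
    sq <- sqrt(disc[ok])
    t1 <- pmax((-b[ok] - sq) / (2 * a[ok]), 0)
    t2 <- pmin((-b[ok] + sq) / (2 * a[ok]), 1)
    len[ok] <- pmax(t2 - t1, 0) * sqrt(a[ok])
  }
  sum(len) / 1000
}

#' Sample the nine-step-selection covariates at points
#'
#' Evaluates the global-model covariates at each point of a landscape
#' stack: local (10 m cell) binary forest and open indicators, 500 m
#' focal forest and open proportions, 50 m forest-open edge density,
#' 500 m Simpson heterogeneity of forest/open/wetland, corridor density
#' within 100 m and 500 m (km per circle), elevation in hectometers, and
#' slope in radians.
#'
#' @param stack a `landscape_stack` from [make_landscape()] (or assembled
#'   from read rasters: elements `landcover`, `dem`, `slope`, `corridors`).
#' @param x,y point coordinates (m), equal-length vectors.
#' @return data.frame with one row per point and columns `forest10`,
#'   `open10`, `forest500`, `open500`, `edge50`, `simpson500`,
#'   `corridor100`, `corridor500`, `elev100`, `slope`.
#' @export
sample_covariates <- function(stack, x, y) {
  lc <- stack$landcover
  if (!all(raster_in_bounds(lc, x, y))) {
    i <- which(!raster_in_bounds(lc, x, y))[1]
    stop(sprintf("point (%g, %g) outside the landscape", x[i], y[i]),
         call. = FALSE)
  }
  local_code <- raster_extract(lc, x, y)
  n <- length(x)
  f500 <- o500 <- e50 <- s500 <- c100 <- c500 <- numeric(n)
  for (i in seq_len(n)) {
    vals <- raster_circle_values(lc, x[i], y[i], 500)
    f500[i] <- mean(vals == LC_FOREST)
    o500[i] <- mean(vals == LC_OPEN)
    three <- vals[vals %in% c(LC_FOREST, LC_OPEN, LC_WETLAND)]
    s500[i] <- if (length(three)) 1 - sum((tabulate(three, 3) / length(three))^2) else 0
    e50[i] <- edge_density(lc, x[i], y[i], 50)
    c100[i] <- corridor_density(stack$corridors, x[i], y[i], 100)
    c500[i] <- corridor_density(stack$corridors, x[i], y[i], 500)
  }
  data.frame(
    forest10 = as.numeric(local_code == LC_FOREST),
    open10 = as.numeric(local_code == LC_OPEN),
    forest500 = f500, open500 = o500,
    edge50 = e50, simpson500 = s500,
    corridor100 = c100, corridor500 = c500,
    elev100 = raster_extract(stack$dem, x, y) / 100,
    slope = raster_extract(stack$slope, x, y)
  )
}
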