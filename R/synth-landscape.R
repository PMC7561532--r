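#' Specify a synthetic landscape
#'
#' Parameters of the synthetic study landscape: a categorical land-cover
#' raster (forest / open / wetland / anthropogenic), a digital elevation
#' model with a one-sided high plateau, and sparse straight linear
#' corridors (roads / trails / utility lines). Defaults emulate a
#' maritime highland park: a ~26 km2 window with relief spanning
#' lowlands to a plateau above 300 m and forest-dominated cover.
#'
#' @param size grid size in cells (square grid).
#' @param cell cell size in meters.
#' @param proportions named proportions for classes
#'   `forest`, `open`, `wetland`, `anthropogenic`; must sum to 1.
#' @param relief relief amplitude (m): DEM spans `[0, relief]`.
#' @param plateau_threshold elevation (m) separating the low/high season
#'   rule regimes.
#' @param n_corridors number of straight linear corridors.
#' @param patch_scale land-cover patch autocorrelation scale, in cells.
#' @param seed integer seed; identical seed gives identical landscapes.
#' @return an object of class `landscape_spec`.
#' @export
landscape_spec <- function(size = 256, cell = 20,
                           proportions = c(forest = 0.55, open = 0.25,
                                           wetland = 0.15, anthropogenic = 0.05),
                           relief = 450, plateau_threshold = 300,
                           n_corridors = 6, patch_scale = 8, seed = 1L) {
  if (!is_count(size) || !(is.numeric(cell) && length(cell) == 1 &&
                           is.finite(cell) && cell > 0)) {
    stop("invalid-spec: grid size and cell size must be positive", call. = FALSE)
  }
  cls <- c("forest", "open", "wetland", "anthropogenic")
  if (!all(cls %in% names(proportions)) ||
      abs(sum(proportions) - 1) > 1e-8 || any(proportions < 0)) {
    stop("invalid-spec: class proportions must be named and sum to 1",
         call. = FALSE)
  }
  structure(list(size = as.integer(size), cell = cell,
                 proportions = proportions[cls], relief = relief,
                 plateau_threshold = plateau_threshold,
                 n_corridors = n_corridors, patch_scale = patch_scale,
                 seed = as.integer(seed)),
            class = "landscape_spec")
}

# Smoothed Gaussian random field: white noise convolved with a separable
# Gaussian kernel (circular edges). Thresholding such a field gives
# contiguous patches with controllable class proportions.
smooth_field <- function(n, range_cells) {
  z <- matrix(rnorm(n * n), n, n)
  half <- min(max(1L, ceiling(3 * range_cells)), (n - 1) %/% 2)
  k <- stats::dnorm(seq(-half, half), sd = range_cells)
  k <- k / sum(k)
  z <- apply(z, 2, function(col) stats::filter(col, k, circular = TRUE))
  z <- t(apply(t(z), 2, function(col) stats::filter(col, k, circular = TRUE)))
  matrix(as.numeric(z), n, n)
}

# Exact-proportion classification of a continuous field by rank.
classify_by_rank <- function(field, proportions) {
  n <- length(field)
  counts <- diff(round(c(0, cumsum(proportions)) * n))
  code <- integer(n)
  ord <- order(field, stats::runif(n))  # random tie-break, seeded upstream
  code[ord] <- rep.int(seq_along(proportions), counts)
  matrix(code, nrow(field), ncol(field))
}

#' Generate a synthetic landscape stack
#'
#' Builds co-registered rasters (categorical land cover, DEM, slope) and a
#' linear-corridor layer from a [landscape_spec()]. Land cover is a
#' rank-thresholded smoothed Gaussian random field, giving contiguous
#' patches whose class frequencies match the requested proportions almost
#' exactly. The DEM mixes a low-frequency random field with a sigmoid
#' plateau along the x-axis and is rescaled to `[0, relief]`. Corridors
#' are random straight chords of the study window.
#'
#' @param spec a [landscape_spec()].
#' @return an object of class `landscape_stack`: list with elements
#'   `landcover`, `dem`, `slope` ([grid_raster()]s), `corridors`
#'   (data.frame `id, x0, y0, x1, y1`), and `spec`.
#' @export
make_landscape <- function(spec) {
  stopifnot(inherits(spec, "landscape_spec"))
  with_seed(spec$seed, {
    n <- spec$size
    lc_field <- smooth_field(n, spec$patch_scale)
    lc <- classify_by_rank(lc_field, spec$proportions)
    landcover <- grid_raster(lc, cell = spec$cell,
                             categories = names(spec$proportions))

    if (spec$relief > 0) {
      base <- smooth_field(n, max(spec$patch_scale * 4, 16))
      base <- (base - min(base)) / max(diff(range(base)), .Machine$double.eps)
      xs <- (seq_len(n) - 0.5) / n
      plateau <- 1 / (1 + exp(-(xs - 0.55) / 0.06))
      dem_raw <- 0.72 * matrix(plateau, n, n, byrow = TRUE) + 0.28 * base
      dem_raw <- (dem_raw - min(dem_raw)) / diff(range(dem_raw))
      demv <- dem_raw * spec$relief
    } else {
      demv <- matrix(0, n, n)
    }
    dem <- grid_raster(demv, cell = spec$cell)

    corridors <- make_corridors(spec$n_corridors, n * spec$cell)

    structure(list(landcover = landcover, dem = dem,
                   slope = slope_from_dem(dem), corridors = corridors,
                   spec = spec),
              class = "landscape_stack")
  })
}

# Random straight chords of the [0, L]^2 window: a random interior point
# and direction, extended to the window boundary on both sides.
make_corridors <- function(n_corridors, L) {
  if (n_corridors == 0) {
    return(data.frame(id = integer(), x0 = numeric(), y0 = numeric(),
                      x1 = numeric(), y1 = numeric()))
  }
  out <- lapply(seq_len(n_corridors), function(i) {
    px <- runif(1, 0.1 * L, 0.9 * L); py <- runif(1, 0.1 * L, 0.9 * L)
    th <- runif(1, 0, pi)
    dx <- cos(th); dy <- sin(th)
    tx <- if (abs(dx) > 1e-12) sort(c((0 - px) / dx, (L - px) / dx)) else c(-Inf, Inf)
    ty <- if (abs(dy) > 1e-12) sort(c((0 - py) / dy, (L - py) / dy)) else c(-Inf, Inf)
    tmin <- max(tx[1], ty[1]); tmax <- min(tx[2], ty[2])
    data.frame(id = i, x0 = px + dx * tmin, y0 = py + dy * tmin,
               x1 = px + dx * tmax, y1 = py + dy * tmax)
  })
  do.call(rbind, out)
}

#' @export
print.landscape_stack <- function(x, ...) {
  cat(sprintf("<landscape_stack> %d x %d cells of %g m (%.1f km2), %d corridors\n",
              nrow(x$landcover$values), ncol(x$landcover$values),
              x$landcover$cell,
              prod(dim(x$landcover$values)) * x$landcover$cell^2 / 1e6,
              length(unique(x$corridors$id))))
  invisible(x)
}

#' Write linear features as GeoJSON
#'
#' @param lines data.frame with columns `id, x0, y0, x1, y1`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_lines_geojson <- function(lines, path) {
  feats <- lapply(seq_len(nrow(lines)), function(i) {
    list(type = "Feature",
         properties = list(id = lines$id[i]),
         geometry = list(type = "LineString",
                         coordinates = list(c(lines$x0[i], lines$y0[i]),
                                            c(lines$x1[i], lines$y1[i]))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read linear features from GeoJSON
#'
#' Reads LineString features; multi-vertex lines are decomposed into
#' their component segments.
#'
#' @param path GeoJSON file path.
#' @return data.frame with columns `id, x0, y0, x1, y1`.
#' @export
read_lines_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  segs <- list()
  for (f in gj$features) {
    cc <- f$geometry$coordinates
    id <- f$properties$id %||% length(segs) + 1L
    for (k in seq_len(length(cc) - 1)) {
      segs[[length(segs) + 1L]] <- data.frame(
        id = id,
        x0 = as.numeric(cc[[k]][[1]]), y0 = as.numeric(cc[[k]][[2]]),
        x1 = as.numeric(cc[[k + 1]][[1]]), y1 = as.numeric(cc[[k + 1]][[2]]))
    }
  }
  do.call(rbind, segs)
}
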