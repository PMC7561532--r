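# ---- planar geometry helpers ----------------------------------------------

# Signed area of a polygon (shoelace); vertices as a 2-column matrix.
signed_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2
}

polygon_area <- function(p) abs(signed_area(p))

# Counter-clockwise convex hull vertices of a point matrix.
convex_hull <- function(p) {
  h <- chull(p[, 1], p[, 2])
  v <- p[h, , drop = FALSE]
  if (nrow(v) >= 3 && signed_area(v) < 0) v <- v[rev(seq_len(nrow(v))), ,
                                                 drop = FALSE]
  v
}

# Is each point inside (or on, within eps) a convex CCW polygon?
# Degenerate (collinear) hulls are treated as segments.
points_in_hull <- function(px, py, hull, eps = 1e-9) {
  n <- nrow(hull)
  if (n == 1) {
    return(abs(px - hull[1, 1]) <= eps & abs(py - hull[1, 2]) <= eps)
  }
  if (n == 2 || polygon_area(hull) <= eps) {
    # distance to the spanning segment of the degenerate hull
    a <- hull[which.min(hull[, 1] + hull[, 2] * 1e-7), , drop = FALSE]
    b <- hull[which.max(hull[, 1] + hull[, 2] * 1e-7), , drop = FALSE]
    ab <- c(b) - c(a)
    L2 <- sum(ab^2)
    if (L2 == 0) {
      return(abs(px - a[1]) <= eps & abs(py - a[2]) <= eps)
    }
    t <- ((px - a[1]) * ab[1] + (py - a[2]) * ab[2]) / L2
    t <- pmin(pmax(t, 0), 1)
    dx <- px - (a[1] + t * ab[1]); dy <- py - (a[2] + t * ab[2])
    return(dx^2 + dy^2 <= eps)
  }
  inside <- rep(TRUE, length(px))
  scale <- sqrt(polygon_area(hull))
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    cr <- (hull[j, 1] - hull[i, 1]) * (py - hull[i, 2]) -
      (hull[j, 2] - hull[i, 2]) * (px - hull[i, 1])
    inside <- inside & (cr >= -eps * scale)
  }
  inside
}

# Exact area of the union of convex polygons by vertical slab
# decomposition: slabs are delimited by all vertex x-coordinates and all
# pairwise edge-crossing x-coordinates; within a slab every polygon
# contributes one y-interval with linear bounds, so the union length at
# the slab midpoint integrates exactly.
union_area_convex <- function(hulls, eps = 1e-12) {
  hulls <- Filter(function(h) nrow(h) >= 3 && polygon_area(h) > eps, hulls)
  if (length(hulls) == 0) return(0)
  edges <- do.call(rbind, lapply(seq_along(hulls), function(k) {
    h <- hulls[[k]]
    n <- nrow(h)
    cbind(hull = k, x1 = h[, 1], y1 = h[, 2],
          x2 = h[c(2:n, 1), 1], y2 = h[c(2:n, 1), 2])
  }))
  xs <- c(edges[, "x1"], edges[, "x2"])
  # pairwise edge intersections (chunked to bound memory)
  E <- nrow(edges)
  chunk <- max(1L, floor(2e6 / E))
  for (s in seq(1, E, by = chunk)) {
    ii <- s:min(s + chunk - 1, E)
    a <- edges[ii, , drop = FALSE]
    dx1 <- a[, "x2"] - a[, "x1"]; dy1 <- a[, "y2"] - a[, "y1"]
    dx2 <- edges[, "x2"] - edges[, "x1"]; dy2 <- edges[, "y2"] - edges[, "y1"]
    # solve a + t*(d1) = b + u*(d2) for each pair (outer products)
    den <- outer(dx1, dy2) - outer(dy1, dx2)
    bx <- outer(-a[, "x1"], edges[, "x1"], `+`)
    by <- outer(-a[, "y1"], edges[, "y1"], `+`)
    t <- (bx * rep(dy2, each = length(ii)) - by * rep(dx2, each = length(ii))) / den
    u <- (bx * matrix(dy1, length(ii), E) - by * matrix(dx1, length(ii), E)) /
      den
    ok <- is.finite(t) & is.finite(u) & t > 0 & t < 1 & u > 0 & u < 1
    if (any(ok)) {
      ti <- t[ok]
      xi <- matrix(a[, "x1"], length(ii), E)[ok] +
        ti * matrix(dx1, length(ii), E)[ok]
      xs <- c(xs, xi)
    }
  }
  xs <- sort(unique(xs))
  area <- 0
  for (k in seq_len(length(xs) - 1)) {
    w <- xs[k + 1] - xs[k]
    if (w <= eps) next
    xm <- (xs[k] + xs[k + 1]) / 2
    span <- (pmin(edges[, "x1"], edges[, "x2"]) <= xm) &
      (pmax(edges[, "x1"], edges[, "x2"]) >= xm) &
      (abs(edges[, "x2"] - edges[, "x1"]) > eps)
    if (!any(span)) next
    e <- edges[span, , drop = FALSE]
    yy <- e[, "y1"] + (e[, "y2"] - e[, "y1"]) *
      (xm - e[, "x1"]) / (e[, "x2"] - e[, "x1"])
    lo <- tapply(yy, e[, "hull"], min)
    hi <- tapply(yy, e[, "hull"], max)
    o <- order(lo)
    lo <- lo[o]; hi <- hi[o]
    len <- 0; cur_lo <- lo[1]; cur_hi <- hi[1]
    if (length(lo) > 1) for (m in 2:length(lo)) {
      if (lo[m] > cur_hi) {
        len <- len + (cur_hi - cur_lo)
        cur_lo <- lo[m]; cur_hi <- hi[m]
      } else cur_hi <- max(cur_hi, hi[m])
    }
    len <- len + (cur_hi - cur_lo)
    area <- area + w * len
  }
  as.numeric(area)
}

# ---- home-range estimators --------------------------------------------------

#' Adaptive sphere-of-influence parameter
#'
#' The adaptive LoCoH tuning parameter `a`: the maximum distance between
#' any two locations in the data set. Computed on the convex hull, which
#' carries the diameter, so it is exact and fast for large point sets.
#'
#' @param points 2-column matrix or data.frame of coordinates (m).
#' @return maximum pairwise distance (m).
#' @export
adaptive_a <- function(points) {
  p <- as.matrix(points)[, 1:2, drop = FALSE]
  if (nrow(p) < 2) stop("need at least 2 points", call. = FALSE)
  u <- unique(p)
  if (nrow(u) == 1) return(0)
  h <- if (nrow(u) > 3) u[chull(u[, 1], u[, 2]), , drop = FALSE] else u
  max(stats::dist(h))
}

new_homerange <- function(method, isopleth, hulls, area_m2, n, id = NA,
                          scope = "all", log = NULL) {
  structure(list(id = id, method = method, isopleth = isopleth,
                 scope = scope, hulls = hulls,
                 area_km2 = area_m2 / 1e6, n = n, log = log),
            class = "homerange")
}

#' @export
print.homerange <- function(x, ...) {
  cat(sprintf("<homerange> %s %g%% (%s, %s): %.6g km2 from %d locations\n",
              x$method, x$isopleth, x$id, x$scope, x$area_km2, x$n))
  invisible(x)
}

#' Adaptive local convex hull (a-LoCoH) home range
#'
#' For every location, a local hull is built from the location and its
#' nearest neighbors added in ascending distance while the cumulative
#' sum of distances stays within the sphere of influence `a`. Hulls are
#' sorted by ascending area (ties: fewer vertices, then construction
#' order) and unioned until at least `isopleth` percent of the locations
#' are covered (boundary counts as covered). Duplicate locations are
#' deduplicated before hull construction but all locations count toward
#' the isopleth.
#'
#' @param points 2-column matrix or data.frame of coordinates (m).
#' @param a sphere-of-influence (m), see [adaptive_a()].
#' @param isopleth percent of locations to cover (default 95).
#' @param id,scope labels carried into the result.
#' @return a `homerange` object (multipart polygon: the component
#'   hulls, whose overlap-corrected union area is reported).
#' @export
alocoh <- function(points, a, isopleth = 95, id = NA, scope = "all") {
  p <- as.matrix(points)[, 1:2, drop = FALSE]
  storage.mode(p) <- "double"
  if (nrow(p) < 3) stop("need at least 3 points", call. = FALSE)
  u <- unique(p)
  if (nrow(u) < 3 ||
      all(abs((u[, 1] - u[1, 1]) * (u[2, 2] - u[1, 2]) -
              (u[, 2] - u[1, 2]) * (u[2, 1] - u[1, 1])) < 1e-9)) {
    stop("degenerate geometry: all points are collinear", call. = FALSE)
  }
  nu <- nrow(u)
  hulls <- vector("list", nu)
  areas <- numeric(nu); nvert <- integer(nu)
  for (i in seq_len(nu)) {
    d <- sqrt((u[, 1] - u[i, 1])^2 + (u[, 2] - u[i, 2])^2)
    o <- order(d)
    keep <- o[cumsum(d[o]) <= a]
    if (!i %in% keep) keep <- c(i, keep)
    sub <- u[keep, , drop = FALSE]
    h <- if (nrow(sub) >= 3) convex_hull(sub) else sub
    hulls[[i]] <- h
    areas[i] <- if (nrow(h) >= 3) polygon_area(h) else 0
    nvert[i] <- nrow(h)
  }
  # degenerate (zero-area) local hulls cannot contribute area and must
  # not satisfy the isopleth; they are excluded from the accumulation
  proper <- which(areas > 0)
  o <- proper[order(areas[proper], nvert[proper], proper)]
  need <- isopleth / 100 * nrow(p)
  covered <- rep(FALSE, nrow(p))
  used <- integer()
  for (i in o) {
    used <- c(used, i)
    covered <- covered | points_in_hull(p[, 1], p[, 2], hulls[[i]])
    if (sum(covered) >= need - 1e-9) break
  }
  sel <- hulls[used]
  new_homerange("aLoCoH", isopleth, sel, union_area_convex(sel),
                nrow(p), id = id, scope = scope,
                log = list(a = a, n_hulls = length(sel),
                           n_degenerate = nu - length(proper),
                           coverage = sum(covered) / nrow(p)))
}

#' Minimum convex polygon home range
#'
#' Removes the `(100 - isopleth)` percent of locations farthest from the
#' arithmetic-mean centroid and returns the convex hull and area of the
#' remainder.
#'
#' @param points 2-column matrix or data.frame of coordinates (m).
#' @param isopleth percent of locations retained (default 95).
#' @param id,scope labels carried into the result.
#' @return a `homerange` object.
#' @export
mcp <- function(points, isopleth = 95, id = NA, scope = "all") {
  p <- as.matrix(points)[, 1:2, drop = FALSE]
  storage.mode(p) <- "double"
  if (nrow(p) < 3) stop("need at least 3 points", call. = FALSE)
  ctr <- colMeans(p)
  d <- sqrt((p[, 1] - ctr[1])^2 + (p[, 2] - ctr[2])^2)
  keep <- order(d)[seq_len(ceiling(isopleth / 100 * nrow(p)))]
  sub <- p[keep, , drop = FALSE]
  if (nrow(unique(sub)) < 3) {
    stop("degenerate geometry: fewer than 3 distinct retained points",
         call. = FALSE)
  }
  h <- convex_hull(sub)
  a <- polygon_area(h)
  if (a <= 0) stop("degenerate geometry: retained points are collinear",
                   call. = FALSE)
  new_homerange("MCP", isopleth, list(h), a, nrow(p), id = id, scope = scope)
}

#' Seasonal and full-period home ranges
#'
#' Computes 95% a-LoCoH and 95% MCP ranges per animal for the full
#' monitoring period and for each season partition, skipping partitions
#' with fewer than `min_locs` locations (logged in the result).
#'
#' @param fixes fix data.frame with `id, x, y` and a `season` column
#'   (see [assign_temporal()]).
#' @param isopleth isopleth percent (default 95).
#' @param min_locs minimum locations per partition (default 30).
#' @return list with `ranges` (list of `homerange`) and `skipped`
#'   (data.frame of skipped partitions with reasons).
#' @export
seasonal_ranges <- function(fixes, isopleth = 95, min_locs = 30) {
  f <- fixes[!is.na(fixes$x), , drop = FALSE]
  ranges <- list()
  skipped <- data.frame(id = character(), scope = character(),
                        n = integer(), reason = character())
  for (animal in unique(f$id)) {
    fa <- f[f$id == animal, , drop = FALSE]
    parts <- list(all = fa,
                  snow = fa[fa$season == "snow", , drop = FALSE],
                  snow_free = fa[fa$season == "snow_free", , drop = FALSE])
    for (scope in names(parts)) {
      pp <- parts[[scope]]
      if (nrow(pp) < min_locs) {
        skipped <- rbind(skipped, data.frame(
          id = animal, scope = scope, n = nrow(pp),
          reason = sprintf("fewer than %d locations", min_locs)))
        next
      }
      pts <- cbind(pp$x, pp$y)
      a <- adaptive_a(pts)
      ranges[[length(ranges) + 1]] <- alocoh(pts, a, isopleth, id = animal,
                                             scope = scope)
      ranges[[length(ranges) + 1]] <- mcp(pts, isopleth, id = animal,
                                          scope = scope)
    }
  }
  list(ranges = ranges, skipped = skipped)
}

#' Summary table of home ranges
#'
#' @param ranges list of `homerange` objects (or the `$ranges` element
#'   of [seasonal_ranges()]).
#' @return data.frame `id, method, scope, isopleth, area_km2, n`.
#' @export
homerange_summary <- function(ranges) {
  if (!is.null(ranges$ranges)) ranges <- ranges$ranges
  do.call(rbind, lapply(ranges, function(r) {
    data.frame(id = r$id, method = r$method, scope = r$scope,
               isopleth = r$isopleth, area_km2 = r$area_km2, n = r$n)
  }))
}

#' Write home-range polygons as GeoJSON
#'
#' Each component hull becomes one polygon of a MultiPolygon feature.
#'
#' @param ranges list of `homerange` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_homeranges_geojson <- function(ranges, path) {
  if (!is.null(ranges$ranges)) ranges <- ranges$ranges
  feats <- lapply(ranges, function(r) {
    polys <- lapply(r$hulls, function(h) {
      ring <- rbind(h, h[1, , drop = FALSE])
      list(lapply(seq_len(nrow(ring)), function(i) as.numeric(ring[i, ])))
    })
    list(type = "Feature",
         properties = list(id = r$id, method = r$method, scope = r$scope,
                           isopleth = r$isopleth, area_km2 = r$area_km2,
                           n = r$n),
         geometry = list(type = "MultiPolygon", coordinates = polys))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
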