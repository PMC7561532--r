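#' Specify a synthetic movement track
#'
#' Ground-truth parameters for an HMM-driven, optionally selection-biased
#' movement track. Defaults follow a three-state carnivore model:
#' encamped (short steps, weakly concentrated turns), foraging
#' (intermediate steps, weakly concentrated turns) and traveling (long
#' steps, directionally persistent), with state mean step lengths of
#' 7, 198 and 1426 m on a 2-h fix schedule.
#'
#' @param step_mean per-state mean step length (m), strictly increasing.
#' @param step_sd per-state step-length SD (m).
#' @param turn_m per-state wrapped-Cauchy turn-angle location (radians).
#' @param turn_rho per-state wrapped-Cauchy concentration in `[0, 1)`.
#' @param transition state transition matrix (rows sum to 1).
#' @param fix_interval_h fix interval in hours.
#' @param duration_days track duration in days.
#' @param missingness expected fraction of missing fixes, in `[0, 0.25]`.
#' @param beta named numeric vector of selection coefficients on
#'   covariates (names from [sample_covariates()] columns); `NULL` or all
#'   zero means no habitat selection.
#' @param n_candidates number of candidate endpoints per step used by the
#'   importance-sampling selection scheme.
#' @param start numeric `c(x, y)` start location (m); `NULL` centers the
#'   track in the landscape.
#' @param start_state initial behavioral state (index or state name);
#'   `NULL` draws it uniformly.
#' @param start_time POSIXct UTC time of the first fix.
#' @param states optional state names.
#' @param seed integer seed.
#' @return an object of class `track_spec`.
#' @export
track_spec <- function(step_mean = c(7, 198, 1426),
                       step_sd = c(6, 160, 1100),
                       turn_m = c(0, 0, 0),
                       turn_rho = c(0.1, 0.3, 0.8),
                       transition = NULL,
                       fix_interval_h = 2, duration_days = 30,
                       missingness = 0.085,
                       beta = NULL, n_candidates = 50,
                       start = NULL, start_state = NULL,
                       start_time = as.POSIXct("2014-06-01 00:00:00", tz = "UTC"),
                       states = NULL, seed = 1L) {
  N <- length(step_mean)
  if (is.null(transition)) {
    transition <- matrix(0.2 / (N - 1), N, N); diag(transition) <- 0.8
  }
  stopifnot(length(step_sd) == N, length(turn_m) == N, length(turn_rho) == N,
            nrow(transition) == N, ncol(transition) == N)
  if (any(diff(step_mean) <= 0)) {
    stop("invalid-spec: step means must be strictly increasing across states",
         call. = FALSE)
  }
  if (any(abs(rowSums(transition) - 1) > 1e-8) || any(transition < 0)) {
    stop("invalid-spec: transition matrix rows must sum to 1", call. = FALSE)
  }
  if (missingness < 0 || missingness > 0.25) {
    stop("invalid-spec: missingness must be in [0, 0.25]", call. = FALSE)
  }
  if (any(turn_rho < 0 | turn_rho >= 1)) {
    stop("invalid-spec: turn_rho must be in [0, 1)", call. = FALSE)
  }
  if (is.null(states)) {
    states <- if (N == 3) c("encamped", "foraging", "traveling")
              else paste0("state", seq_len(N))
  }
  structure(list(step_mean = step_mean, step_sd = step_sd, turn_m = turn_m,
                 turn_rho = turn_rho, transition = transition,
                 fix_interval_h = fix_interval_h,
                 duration_days = duration_days, missingness = missingness,
                 beta = beta, n_candidates = n_candidates, start = start,
                 start_state = start_state,
                 start_time = start_time, states = states,
                 seed = as.integer(seed)),
            class = "track_spec")
}

# Fold a coordinate into [lo, hi] by reflection (triangle wave).
reflect_coord <- function(v, lo, hi) {
  w <- hi - lo
  u <- (v - lo) %% (2 * w)
  lo + ifelse(u > w, 2 * w - u, u)
}

# Evaluate only the named covariates at points; cheap point lookups are
# vectorized, focal metrics loop over points.
covariate_at <- function(stack, x, y, vars) {
  out <- matrix(NA_real_, length(x), length(vars),
                dimnames = list(NULL, vars))
  for (v in vars) {
    out[, v] <- switch(v,
      forest10 = as.numeric(raster_extract(stack$landcover, x, y) == LC_FOREST),
      open10 = as.numeric(raster_extract(stack$landcover, x, y) == LC_OPEN),
      elev100 = raster_extract(stack$dem, x, y) / 100,
      slope = raster_extract(stack$slope, x, y),
      forest500 = vapply(seq_along(x), function(i)
        focal_proportion(stack$landcover, LC_FOREST, 500, x[i], y[i]), 0),
      open500 = vapply(seq_along(x), function(i)
        focal_proportion(stack$landcover, LC_OPEN, 500, x[i], y[i]), 0),
      edge50 = vapply(seq_along(x), function(i)
        edge_density(stack$landcover, x[i], y[i], 50), 0),
      simpson500 = vapply(seq_along(x), function(i)
        simpson_diversity(stack$landcover, x[i], y[i], 500), 0),
      corridor100 = vapply(seq_along(x), function(i)
        corridor_density(stack$corridors, x[i], y[i], 100), 0),
      corridor500 = vapply(seq_along(x), function(i)
        corridor_density(stack$corridors, x[i], y[i], 500), 0),
      stop("unknown covariate: ", v, call. = FALSE)
    )
  }
  out
}

#' Simulate a movement track over a landscape
#'
#' Generates a track from the hidden-Markov movement model of a
#' [track_spec()]: at each step the behavioral state follows the Markov
#' chain, the step length is gamma and the turning angle wrapped Cauchy
#' for that state. When selection coefficients are set, each step draws
#' `n_candidates` candidate endpoints from the movement kernel and picks
#' one with probability proportional to `exp(beta' z)` of the candidate's
#' covariates (importance-sampling step-selection scheme); the chosen
#' endpoint then defines the realized bearing. Steps that would leave the
#' landscape are reflected at the boundary.
#'
#' @param spec a [track_spec()].
#' @param landscape a `landscape_stack` from [make_landscape()].
#' @param id animal identifier for the output fixes.
#' @return list with `fixes` (data.frame `id, time, x, y, source,
#'   missing`) and `states` (integer ground-truth state per fix; state of
#'   a fix is the state that generated the step ending at it, with the
#'   initial state repeated for the first fix).
#' @export
simulate_track <- function(spec, landscape, id = "A01") {
  stopifnot(inherits(spec, "track_spec"), inherits(landscape, "landscape_stack"))
  ext <- raster_extent(landscape$landcover)
  N <- length(spec$step_mean)
  n_steps <- round(spec$duration_days * 24 / spec$fix_interval_h)
  sel_vars <- names(spec$beta)[!is.na(spec$beta) & spec$beta != 0]
  use_selection <- length(sel_vars) > 0

  with_seed(spec$seed, {
    x <- numeric(n_steps + 1); y <- numeric(n_steps + 1)
    st <- integer(n_steps + 1)
    if (is.null(spec$start)) {
      x[1] <- mean(ext[c("xmin", "xmax")]); y[1] <- mean(ext[c("ymin", "ymax")])
    } else {
      x[1] <- spec$start[1]; y[1] <- spec$start[2]
    }
    st[1] <- if (is.null(spec$start_state)) sample.int(N, 1) else {
      s0 <- spec$start_state
      if (is.character(s0)) s0 <- match(s0, spec$states)
      stopifnot(!is.na(s0), s0 >= 1, s0 <= N)
      as.integer(s0)
    }
    bearing <- runif(1, -pi, pi)
    M <- if (use_selection) spec$n_candidates else 1L
    for (t in seq_len(n_steps)) {
      s <- if (t == 1) st[1] else sample.int(N, 1, prob = spec$transition[st[t], ])
      st[t + 1] <- s
      turns <- rwrappedcauchy(M, spec$turn_m[s], spec$turn_rho[s])
      lens <- rgamma_ms(M, spec$step_mean[s], spec$step_sd[s])
      brg <- wrap_angle(bearing + turns)
      cx <- reflect_coord(x[t] + lens * cos(brg), ext["xmin"], ext["xmax"])
      cy <- reflect_coord(y[t] + lens * sin(brg), ext["ymin"], ext["ymax"])
      pick <- 1L
      if (use_selection) {
        z <- covariate_at(landscape, cx, cy, sel_vars)
        lp <- as.vector(z %*% spec$beta[sel_vars])
        w <- exp(lp - max(lp))
        pick <- sample.int(M, 1, prob = w)
      }
      x[t + 1] <- cx[pick]; y[t + 1] <- cy[pick]
      dx <- x[t + 1] - x[t]; dy <- y[t + 1] - y[t]
      if (dx != 0 || dy != 0) bearing <- atan2(dy, dx)
    }
    times <- spec$start_time + (0:n_steps) * spec$fix_interval_h * 3600
    fixes <- data.frame(id = id, time = times, x = x, y = y,
                        source = "observed", missing = FALSE,
                        stringsAsFactors = FALSE)
    st[1] <- st[2]  # first fix carries the initial step's state
    list(fixes = fixes, states = st)
  })
}

#' Introduce missing fixes into a track
#'
#' Marks fixes missing at random at the requested rate, never allowing
#' more than `max_gap` consecutive missing fixes. Missing fixes keep
#' their row with `NA` coordinates and `missing = TRUE`.
#'
#' @param fixes fix data.frame (`id, time, x, y, ...`).
#' @param rate expected missingness in `[0, 0.25]`.
#' @param max_gap maximum run of consecutive missing fixes.
#' @param seed integer seed.
#' @return the fix data.frame with gaps marked.
#' @export
drop_fixes <- function(fixes, rate, max_gap = 4, seed = 1L) {
  if (rate < 0 || rate > 0.25) {
    stop("invalid-spec: missingness rate must be in [0, 0.25]", call. = FALSE)
  }
  if (rate == 0) return(fixes)
  n <- nrow(fixes)
  with_seed(seed, {
    miss <- runif(n) < rate
    miss[c(1, n)] <- FALSE  # keep endpoints so the span is preserved
    # break any run longer than max_gap by re-observing every
    # (max_gap + 1)-th fix inside the run
    r <- rle(miss)
    pos <- cumsum(c(1, r$lengths[-length(r$lengths)]))
    for (k in which(r$values & r$lengths > max_gap)) {
      idx <- pos[k] + seq_len(r$lengths[k]) - 1
      keep <- idx[seq_along(idx) %% (max_gap + 1) == 0]
      miss[keep] <- FALSE
    }
    fixes$missing <- miss
    fixes$x[miss] <- NA_real_
    fixes$y[miss] <- NA_real_
    fixes
  })
}
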