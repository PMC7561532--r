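# Integrated Ornstein-Uhlenbeck (CTCRW) discrete-time system matrices
# for a time step of dt hours. The state is (position, velocity); sigma
# is the stationary velocity SD (m/h) and beta the velocity
# autocorrelation rate (1/h).
ctcrw_system <- function(dt, beta, sigma) {
  phi <- exp(-beta * dt)
  F <- matrix(c(1, 0, (1 - phi) / beta, phi), 2, 2)
  q11 <- sigma^2 / beta^2 * (2 * beta * dt - 3 + 4 * phi - phi^2)
  q12 <- sigma^2 / beta * (1 - phi)^2
  q22 <- sigma^2 * (1 - phi^2)
  Q <- matrix(c(q11, q12, q12, q22), 2, 2)
  list(F = F, Q = Q)
}

# Kalman filter for one axis over slot times (hours). z may contain NA
# (missing slots: predict only). Returns the log-likelihood and, when
# `keep = TRUE`, the filtered/predicted moments needed by the smoother.
ctcrw_kalman <- function(times, z, beta, sigma, tau,
                         prior_mean, prior_var = 1e8, keep = FALSE) {
  n <- length(times)
  m <- c(prior_mean, 0)
  P <- diag(c(prior_var, sigma^2))
  ll <- 0
  if (keep) {
    mp <- matrix(NA_real_, n, 2); Pp <- array(NA_real_, c(n, 2, 2))
    mf <- matrix(NA_real_, n, 2); Pf <- array(NA_real_, c(n, 2, 2))
    Fs <- array(NA_real_, c(n, 2, 2))
  }
  for (k in seq_len(n)) {
    if (k > 1) {
      sys <- ctcrw_system(times[k] - times[k - 1], beta, sigma)
      m <- as.vector(sys$F %*% m)
      P <- sys$F %*% P %*% t(sys$F) + sys$Q
      if (keep) Fs[k, , ] <- sys$F
    }
    if (keep) { mp[k, ] <- m; Pp[k, , ] <- P }
    if (!is.na(z[k])) {
      S <- P[1, 1] + tau^2
      v <- z[k] - m[1]
      ll <- ll - 0.5 * (log(2 * pi * S) + v^2 / S)
      K <- P[, 1] / S
      m <- m + K * v
      P <- P - K %o% P[1, ]
      P <- (P + t(P)) / 2
    }
    if (keep) { mf[k, ] <- m; Pf[k, , ] <- P }
  }
  out <- list(loglik = ll)
  if (keep) out <- c(out, list(mp = mp, Pp = Pp, mf = mf, Pf = Pf, Fs = Fs))
  out
}

# Rauch-Tung-Striebel smoother on the stored filter pass.
ctcrw_smooth <- function(kf) {
  n <- nrow(kf$mf)
  ms <- kf$mf; Ps <- kf$Pf
  if (n > 1) for (k in (n - 1):1) {
    F <- kf$Fs[k + 1, , ]
    Ppred <- kf$Pp[k + 1, , ]
    G <- kf$Pf[k, , ] %*% t(F) %*% solve(Ppred)
    ms[k, ] <- kf$mf[k, ] + as.vector(G %*% (ms[k + 1, ] - kf$mp[k + 1, ]))
    Ps[k, , ] <- kf$Pf[k, , ] + G %*% (Ps[k + 1, , ] - Ppred) %*% t(G)
  }
  list(mean = ms, var = Ps)
}

#' CTCRW log-likelihood of one coordinate series
#'
#' Exact Gaussian likelihood of observed positions under the integrated
#' Ornstein-Uhlenbeck velocity model, evaluated by Kalman filtering.
#' Exposed for validation against the direct multivariate-normal
#' density.
#'
#' @param times_h observation times (hours, increasing).
#' @param z positions (m); `NA` for missing slots.
#' @param beta velocity autocorrelation rate (1/h).
#' @param sigma stationary velocity SD (m/h).
#' @param tau measurement noise SD (m).
#' @param prior_mean,prior_var Gaussian prior on the initial position.
#' @return log-likelihood.
#' @export
ctcrw_loglik <- function(times_h, z, beta, sigma, tau,
                         prior_mean = z[which(!is.na(z))[1]],
                         prior_var = 1e8) {
  ctcrw_kalman(times_h, z, beta, sigma, tau, prior_mean, prior_var)$loglik
}

#' Fit a continuous-time correlated random walk to a burst
#'
#' Maximum likelihood for the integrated Ornstein-Uhlenbeck state-space
#' model over the burst's observed slots, x and y treated as independent
#' with shared parameters. The measurement noise SD is bounded below at
#' `tau_floor` (GPS jitter of stationary collars). A small multistart
#' over the autocorrelation rate guards against local optima; an
#' estimate at the upper rate bound (no velocity persistence) is
#' flagged.
#'
#' @param burst a `burst` from [extract_bursts()].
#' @param tau_floor lower bound (m) for measurement noise SD.
#' @param beta_bounds bounds (1/h) for the autocorrelation rate.
#' @param min_obs minimum number of observed fixes.
#' @return object of class `ctcrw_params`: list with `beta`, `sigma`,
#'   `tau`, `loglik`, `beta_at_bound`, `convergence`.
#' @export
fit_ctcrw <- function(burst, tau_floor = 1, beta_bounds = c(1e-3, 50),
                      min_obs = 20) {
  obs <- burst[burst$observed, , drop = FALSE]
  if (nrow(obs) < min_obs) {
    stop("need at least ", min_obs, " observed fixes to fit the CTCRW",
         call. = FALSE)
  }
  t_h <- as.numeric(difftime(burst$time, burst$time[1], units = "hours"))
  zx <- ifelse(burst$observed, burst$x, NA_real_)
  zy <- ifelse(burst$observed, burst$y, NA_real_)
  # data-scale starting values: rms displacement speed
  dt <- diff(t_h[burst$observed])
  spd <- sqrt(diff(obs$x)^2 + diff(obs$y)^2) / pmax(dt, 1e-6)
  sig0 <- max(stats::median(spd), 1)
  negll <- function(p) {
    beta <- exp(p[1]); sigma <- exp(p[2]); tau <- tau_floor + exp(p[3])
    ll <- .ctcrw_loglik_cpp(t_h, zx, beta, sigma, tau, obs$x[1], 1e8) +
      .ctcrw_loglik_cpp(t_h, zy, beta, sigma, tau, obs$y[1], 1e8)
    if (!is.finite(ll)) 1e300 else -ll
  }
  starts <- list(c(log(0.2), log(sig0), log(10)),
                 c(log(2), log(sig0), log(10)))
  best <- NULL
  fails <- character()
  for (s in starts) {
    o <- tryCatch(
      optim(s, negll, method = "L-BFGS-B",
            lower = c(log(beta_bounds[1]), log(1e-3), log(1e-6)),
            upper = c(log(beta_bounds[2]), log(1e6), log(1e6))),
      error = function(e) conditionMessage(e))
    if (is.character(o)) { fails <- c(fails, o); next }
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best)) {
    stop("CTCRW optimization failed from all starts: ",
         paste(unique(fails), collapse = "; "), call. = FALSE)
  }
  beta <- exp(best$par[1])
  sigma <- exp(best$par[2])
  tau <- tau_floor + exp(best$par[3])
  at_bound <- beta >= beta_bounds[2] * 0.99
  # degenerate persistence: either the rate hit its bound or the fitted
  # per-slot displacement scale is below the measurement noise (the
  # track is indistinguishable from stationary jitter, and the rate is
  # then unidentified)
  med_dt <- stats::median(dt)
  no_persistence <- at_bound || (sigma * med_dt < tau)
  if (no_persistence) {
    warning("no detectable velocity persistence ",
            "(white-noise-like track); rate parameter unreliable")
  }
  structure(list(beta = beta, sigma = sigma, tau = tau,
                 loglik = -best$value, beta_at_bound = at_bound,
                 no_persistence = no_persistence,
                 convergence = best$convergence),
            class = "ctcrw_params")
}

#' @export
print.ctcrw_params <- function(x, ...) {
  cat(sprintf(
    "<ctcrw_params> beta %.3g /h, sigma %.3g m/h, tau %.3g m, loglik %.2f\n",
    x$beta, x$sigma, x$tau, x$loglik))
  invisible(x)
}

#' Impute missing burst slots from the CTCRW smoothing distribution
#'
#' Fills each missing slot with one draw from the marginal Kalman
#' smoothing distribution at that slot (single imputation). Observed
#' fixes are unchanged; imputed fixes get `source = "imputed"`.
#'
#' @param burst a `burst` from [extract_bursts()].
#' @param params a `ctcrw_params` from [fit_ctcrw()].
#' @param seed integer seed (the draw is deterministic given the seed).
#' @return the burst with missing slots filled.
#' @export
impute_missing <- function(burst, params, seed = 1L) {
  miss <- !burst$observed
  if (!any(miss)) return(burst)
  t_h <- as.numeric(difftime(burst$time, burst$time[1], units = "hours"))
  with_seed(seed, {
    for (axis in c("x", "y")) {
      z <- ifelse(burst$observed, burst[[axis]], NA_real_)
      kf <- ctcrw_kalman(t_h, z, params$beta, params$sigma, params$tau,
                         z[which(!is.na(z))[1]], keep = TRUE)
      sm <- ctcrw_smooth(kf)
      sdv <- sqrt(pmax(sm$var[miss, 1, 1], 0))
      burst[[axis]][miss] <- rnorm(sum(miss), sm$mean[miss, 1], sdv)
    }
    burst$source[miss] <- "imputed"
    burst
  })
}

#' Smoothing distribution at burst slots
#'
#' Marginal smoothing means and SDs of the position at every slot, per
#' axis; used for imputation diagnostics.
#'
#' @param burst a `burst`.
#' @param params a `ctcrw_params`.
#' @return data.frame with columns `slot, mean_x, sd_x, mean_y, sd_y`.
#' @export
ctcrw_smooth_positions <- function(burst, params) {
  t_h <- as.numeric(difftime(burst$time, burst$time[1], units = "hours"))
  out <- data.frame(slot = burst$slot)
  for (axis in c("x", "y")) {
    z <- ifelse(burst$observed, burst[[axis]], NA_real_)
    kf <- ctcrw_kalman(t_h, z, params$beta, params$sigma, params$tau,
                       z[which(!is.na(z))[1]], keep = TRUE)
    sm <- ctcrw_smooth(kf)
    out[[paste0("mean_", axis)]] <- sm$mean[, 1]
    out[[paste0("sd_", axis)]] <- sqrt(pmax(sm$var[, 1, 1], 0))
  }
  out
}
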