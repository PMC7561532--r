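#' Gamma log-density parameterized by mean and SD
#'
#' Shape is `(mean/sd)^2` and scale `sd^2/mean`. Non-finite log
#' densities (the degenerate x = 0 endpoint) are clamped to +/- 1e30 so
#' optimizers never see infinities.
#'
#' @param x step length (m), `>= 0`.
#' @param mean,sd gamma mean and SD (m), `> 0`.
#' @return log density.
#' @export
gamma_logpdf <- function(x, mean, sd) {
  stopifnot(all(mean > 0), all(sd > 0))
  shape <- (mean / sd)^2
  out <- dgamma(x, shape = shape, scale = sd^2 / mean, log = TRUE)
  out[out == -Inf] <- -1e30
  out[out == Inf] <- 1e30
  out
}

#' Wrapped Cauchy log-density
#'
#' `log((1/2pi) * (1 - rho^2) / (1 + rho^2 - 2 rho cos(theta - m)))`.
#'
#' @param theta angle (radians) in `(-pi, pi]`.
#' @param m location (radians).
#' @param rho concentration in `[0, 1)`.
#' @return log density.
#' @export
wrapped_cauchy_logpdf <- function(theta, m = 0, rho = 0) {
  if (any(rho < 0 | rho >= 1)) {
    stop("rho must be in [0, 1)", call. = FALSE)
  }
  log1p(-rho^2) - log(2 * pi) - log(1 + rho^2 - 2 * rho * cos(theta - m))
}

# ---- movement model object --------------------------------------------------

new_movement_model <- function(mean, sd, turn_m, turn_rho, Gamma, delta,
                               loglik = NA_real_, extra = list()) {
  N <- length(mean)
  stopifnot(length(sd) == N, length(turn_m) == N, length(turn_rho) == N,
            all(dim(Gamma) == N), length(delta) == N)
  k <- 4 * N + N * (N - 1) + (N - 1)
  structure(c(list(N = N, mean = mean, sd = sd, turn_m = turn_m,
                   turn_rho = turn_rho, Gamma = Gamma, delta = delta,
                   loglik = loglik, k = k), extra),
            class = "movement_model")
}

#' @export
print.movement_model <- function(x, ...) {
  cat(sprintf("<movement_model> %d states, loglik %.3f, k = %d, AIC %.2f\n",
              x$N, x$loglik, x$k, aic(x)))
  tab <- data.frame(state = seq_len(x$N),
                    step_mean = round(x$mean, 1), step_sd = round(x$sd, 1),
                    turn_loc = round(x$turn_m, 2),
                    turn_rho = round(x$turn_rho, 3))
  print(tab, row.names = FALSE)
  invisible(x)
}

# Reorder states by ascending step-length mean (canonical labeling).
canonicalize_model <- function(m) {
  o <- order(m$mean)
  m$mean <- m$mean[o]; m$sd <- m$sd[o]
  m$turn_m <- m$turn_m[o]; m$turn_rho <- m$turn_rho[o]
  m$Gamma <- m$Gamma[o, o, drop = FALSE]
  m$delta <- m$delta[o]
  m
}

# ---- emission matrix and observation preparation ---------------------------

# Accept a single step data.frame or a list of them (one per burst).
as_step_list <- function(steps) {
  if (is.data.frame(steps)) list(steps) else steps
}

# T x N matrix of log emission densities for one burst's steps.
# Missing lengths contribute nothing (row of zeros: transition only);
# missing turning angles contribute the step-length term only.
emission_logmat <- function(steps, mean, sd, turn_m, turn_rho,
                            step_floor = 1) {
  Tn <- nrow(steps); N <- length(mean)
  len <- pmax(steps$length, step_floor)
  logB <- matrix(0, Tn, N)
  has_len <- !is.na(len)
  has_turn <- !is.na(steps$turn)
  for (j in seq_len(N)) {
    col <- numeric(Tn)
    col[has_len] <- gamma_logpdf(len[has_len], mean[j], sd[j])
    col[has_turn] <- col[has_turn] +
      wrapped_cauchy_logpdf(steps$turn[has_turn], turn_m[j], turn_rho[j])
    logB[, j] <- col
  }
  logB
}

#' Forward-algorithm log-likelihood of a movement model
#'
#' Scaled forward recursion over the step series; multiple bursts are
#' independent sequences whose log-likelihoods sum. Steps with missing
#' length contribute transitions only; steps with missing turning angle
#' contribute the step-length term only.
#'
#' @param model a `movement_model`.
#' @param steps a step data.frame from [steps_from_burst()] or a list of
#'   them (one per burst).
#' @param step_floor floor (m) applied to step lengths before the gamma
#'   density (GPS noise scale), default 1.
#' @return total log-likelihood.
#' @export
forward_loglik <- function(model, steps, step_floor = 1) {
  sl <- as_step_list(steps)
  sum(vapply(sl, function(s) {
    logB <- emission_logmat(s, model$mean, model$sd, model$turn_m,
                            model$turn_rho, step_floor)
    .hmm_forward_cpp(logB, model$Gamma, model$delta)
  }, 0))
}

# ---- working-scale parameter transforms ------------------------------------

model_to_working <- function(m) {
  N <- m$N
  g <- as.vector(vapply(seq_len(N), function(i) {
    log(m$Gamma[i, -i] / m$Gamma[i, i])
  }, numeric(N - 1)))
  d <- log(m$delta[-1] / m$delta[1])
  c(log(m$mean), log(m$sd), m$turn_m, stats::qlogis(m$turn_rho), g, d)
}

working_to_model <- function(w, N) {
  mean <- exp(w[1:N]); sd <- exp(w[N + 1:N])
  turn_m <- wrap_angle(w[2 * N + 1:N])
  turn_rho <- stats::plogis(w[3 * N + 1:N])
  Gamma <- matrix(0, N, N)
  idx <- 4 * N
  for (i in seq_len(N)) {
    off <- exp(w[idx + seq_len(N - 1)])
    idx <- idx + N - 1
    row <- numeric(N); row[i] <- 1; row[-i] <- off
    Gamma[i, ] <- row / sum(row)
  }
  dfree <- exp(c(0, w[idx + seq_len(N - 1)]))
  delta <- dfree / sum(dfree)
  new_movement_model(mean, sd, turn_m, turn_rho, Gamma, delta)
}

default_start <- function(N, means = NULL, rho = 0.4) {
  if (is.null(means)) {
    means <- switch(as.character(N), "2" = c(20, 800),
                    "3" = c(7, 200, 1400), "4" = c(7, 100, 400, 1400),
                    stop("N must be 2, 3, or 4"))
  }
  Gamma <- matrix(0.2 / (N - 1), N, N); diag(Gamma) <- 0.8
  new_movement_model(means, means, rep(0, N), rep(rho, N), Gamma,
                     rep(1 / N, N))
}

# ---- fitting ----------------------------------------------------------------

# Log emission matrix from precomputed observation pieces.
hmm_emis <- function(o, m, N) {
  Tn <- length(o$len)
  logB <- matrix(0, Tn, N)
  for (j in seq_len(N)) {
    col <- numeric(Tn)
    col[o$has_len] <- gamma_logpdf(o$len[o$has_len], m$mean[j], m$sd[j])
    col[o$has_turn] <- col[o$has_turn] +
      wrapped_cauchy_logpdf(o$turn[o$has_turn], m$turn_m[j], m$turn_rho[j])
    logB[, j] <- col
  }
  logB
}

hmm_negll <- function(w, obs, N) {
  m <- working_to_model(w, N)
  ll <- 0
  for (o in obs) ll <- ll + .hmm_forward_cpp(hmm_emis(o, m, N), m$Gamma,
                                             m$delta)
  if (!is.finite(ll)) 1e300 else -ll
}

# Analytic score via the Fisher identity: the gradient of the marginal
# log-likelihood equals the posterior-weighted complete-data score, with
# posteriors and expected transition counts from the forward-backward
# pass. Chain-ruled onto the working scale (log means/SDs, logit
# concentrations, multinomial-logit transition rows and initial law).
hmm_negll_grad <- function(w, obs, N) {
  m <- working_to_model(w, N)
  g_mu <- g_sd <- g_m <- g_rho <- numeric(N)
  g_gamma <- matrix(0, N, N)
  g_delta <- numeric(N)
  for (o in obs) {
    fb <- .hmm_fb_cpp(hmm_emis(o, m, N), m$Gamma, m$delta)
    if (!is.finite(fb$loglik)) return(rep(0, length(w)))
    post <- fb$post
    for (j in seq_len(N)) {
      k <- (m$mean[j] / m$sd[j])^2
      th <- m$sd[j]^2 / m$mean[j]
      x <- o$len[o$has_len]
      pw <- post[o$has_len, j]
      A <- -log(th) - digamma(k) + log(x)
      g_mu[j] <- g_mu[j] + sum(pw * (2 * k * A + k - x / th))
      g_sd[j] <- g_sd[j] + sum(pw * (-2 * k * A - 2 * k + 2 * x / th))
      tt <- o$turn[o$has_turn]
      pt <- post[o$has_turn, j]
      rho <- m$turn_rho[j]
      D <- 1 + rho^2 - 2 * rho * cos(tt - m$turn_m[j])
      g_m[j] <- g_m[j] + sum(pt * 2 * rho * sin(tt - m$turn_m[j]) / D)
      dr <- -2 * rho / (1 - rho^2) - (2 * rho - 2 * cos(tt - m$turn_m[j])) / D
      g_rho[j] <- g_rho[j] + sum(pt * dr) * rho * (1 - rho)
    }
    xi <- fb$xi
    rs <- rowSums(xi)
    g_gamma <- g_gamma + (xi - rs * m$Gamma)
    g_delta <- g_delta + (fb$post1 - m$delta)
  }
  gG <- as.vector(vapply(seq_len(N), function(i) g_gamma[i, -i],
                         numeric(N - 1)))
  -c(g_mu, g_sd, g_m, g_rho, gG, g_delta[-1])
}

# Precompute the observation pieces used by the likelihood/score.
hmm_obs <- function(sl, step_floor) {
  lapply(sl, function(s) {
    list(len = pmax(s$length, step_floor), turn = s$turn,
         has_len = !is.na(s$length), has_turn = !is.na(s$turn))
  })
}

#' Fit a hidden Markov movement model by direct likelihood maximization
#'
#' Bounded quasi-Newton (`optim` L-BFGS-B) on working-scale parameters:
#' log step-length means and SDs, turn-angle locations, logit
#' concentrations, multinomial-logit transition rows, and logit initial
#' distribution. The fitted model is canonicalized with states ordered
#' by ascending step-length mean.
#'
#' @param steps step data.frame or list of step data.frames.
#' @param N number of states (2, 3 or 4).
#' @param start a `movement_model`-like starting point (see
#'   [multistart_fit()] for grids); `NULL` uses scale-spanning defaults.
#' @param step_floor step-length floor (m) before the gamma density.
#' @param control passed to [stats::optim()].
#' @return fitted `movement_model` with `loglik`, `k`, `convergence` and
#'   the starting values under `$start`.
#' @export
fit_hmm <- function(steps, N, start = NULL, step_floor = 1,
                    control = list(maxit = 300)) {
  if (!N %in% 2:4) stop("N must be 2, 3, or 4", call. = FALSE)
  sl <- as_step_list(steps)
  if (is.null(start)) start <- default_start(N)
  w0 <- model_to_working(start)
  npar <- length(w0)
  lower <- c(rep(log(0.1), N), rep(log(0.1), N), rep(-2 * pi, N),
             rep(-10, N), rep(-20, (N - 1) * N), rep(-20, N - 1))
  upper <- c(rep(log(1e5), N), rep(log(1e5), N), rep(2 * pi, N),
             rep(10, N), rep(20, (N - 1) * N), rep(20, N - 1))
  obs <- hmm_obs(sl, step_floor)
  opt <- tryCatch(
    optim(w0, hmm_negll, gr = hmm_negll_grad, method = "L-BFGS-B",
          lower = lower, upper = upper, control = control,
          obs = obs, N = N),
    error = function(e) {
      stop("HMM optimizer failed: ", conditionMessage(e),
           " (start retained in condition)", call. = FALSE)
    })
  fit <- working_to_model(opt$par, N)
  fit$loglik <- -opt$value
  fit$convergence <- opt$convergence
  fit$start <- list(mean = start$mean, sd = start$sd,
                    turn_rho = start$turn_rho)
  fit$step_floor <- step_floor
  canonicalize_model(fit)
}

#' Build the default multistart grid
#'
#' Step-length mean candidates crossed over states respecting the
#' ascending-order constraint, combined with low and high turn-angle
#' concentration levels. Means span the encamped-to-traveling scales.
#'
#' @param N number of states.
#' @param means candidate step-length means (m).
#' @param rhos candidate turn concentrations.
#' @return list of `movement_model` starting points.
#' @export
start_grid <- function(N, means = c(5, 50, 200, 500, 1500),
                       rhos = c(0.2, 0.7)) {
  means <- sort(means)
  combs <- if (length(means) >= N) {
    utils::combn(means, N, simplify = FALSE)
  } else {
    # fewer candidates than states: one geometric ladder spanning them
    list(exp(seq(log(min(means)), log(max(means)), length.out = N)))
  }
  out <- list()
  for (cm in combs) for (r in rhos) {
    out[[length(out) + 1]] <- default_start(N, means = cm, rho = r)
  }
  out
}

#' Multistart HMM fit
#'
#' Runs [fit_hmm()] from every start in the grid and keeps the fit with
#' the highest log-likelihood (ties broken by grid order). The grid and
#' each start's result are recorded under `$multistart`.
#'
#' @param steps step data.frame or list of step data.frames.
#' @param N number of states.
#' @param grid list of starting models, e.g. from [start_grid()].
#' @param ... passed to [fit_hmm()].
#' @return best fitted `movement_model`.
#' @export
multistart_fit <- function(steps, N, grid = start_grid(N), ...) {
  if (length(grid) == 0) stop("empty start grid", call. = FALSE)
  fits <- list(); errs <- character()
  for (g in grid) {
    f <- tryCatch(fit_hmm(steps, N, start = g, ...),
                  error = function(e) conditionMessage(e))
    if (is.character(f)) errs <- c(errs, f) else fits[[length(fits) + 1]] <- f
  }
  if (length(fits) == 0) {
    stop("all multistart fits failed: ", paste(unique(errs), collapse = "; "),
         call. = FALSE)
  }
  lls <- vapply(fits, `[[`, 0, "loglik")
  best <- fits[[which.max(lls)]]  # which.max takes the first maximum
  best$multistart <- list(
    n_starts = length(grid), n_failed = length(errs),
    logliks = lls,
    starts = lapply(grid, function(g) list(mean = g$mean,
                                           turn_rho = g$turn_rho)))
  best
}

# ---- decoding ---------------------------------------------------------------

#' Viterbi decoding of the most probable state path
#'
#' @param model fitted `movement_model`.
#' @param steps step data.frame or list of step data.frames.
#' @param step_floor step-length floor (m), as used in fitting.
#' @return integer state path (concatenated over bursts, in input order).
#' @export
viterbi <- function(model, steps, step_floor = 1) {
  sl <- as_step_list(steps)
  unlist(lapply(sl, function(s) {
    logB <- emission_logmat(s, model$mean, model$sd, model$turn_m,
                            model$turn_rho, step_floor)
    Tn <- nrow(logB); N <- ncol(logB)
    if (Tn == 0) return(integer())
    lG <- log(model$Gamma)
    phi <- log(model$delta) + logB[1, ]
    back <- matrix(0L, Tn, N)
    if (Tn > 1) for (t in 2:Tn) {
      cand <- phi + lG  # N x N: previous state i -> state j
      back[t, ] <- max.col(t(cand), ties.method = "first")
      phi <- cand[cbind(back[t, ], seq_len(N))] + logB[t, ]
    }
    path <- integer(Tn)
    path[Tn] <- which.max(phi)
    if (Tn > 1) for (t in (Tn - 1):1) path[t] <- back[t + 1, path[t + 1]]
    path
  }))
}

#' Forward-backward state posteriors
#'
#' Smoothing probabilities of each state at each step, the per-step
#' maximum posterior, and the Viterbi path, bundled as a `decoding`.
#'
#' @param model fitted `movement_model`.
#' @param steps step data.frame or list of step data.frames.
#' @param step_floor step-length floor (m).
#' @return object of class `decoding`: list with `posterior` (matrix,
#'   rows sum to 1), `max_posterior`, `viterbi`, `loglik`.
#' @export
state_posteriors <- function(model, steps, step_floor = 1) {
  sl <- as_step_list(steps)
  posts <- list(); ll <- 0
  for (s in sl) {
    logB <- emission_logmat(s, model$mean, model$sd, model$turn_m,
                            model$turn_rho, step_floor)
    Tn <- nrow(logB); N <- ncol(logB)
    B <- exp(logB - apply(logB, 1, max))
    alpha <- matrix(0, Tn, N); cvec <- numeric(Tn)
    a <- model$delta * B[1, ]
    cvec[1] <- sum(a); alpha[1, ] <- a / cvec[1]
    if (Tn > 1) for (t in 2:Tn) {
      a <- (alpha[t - 1, ] %*% model$Gamma) * B[t, ]
      cvec[t] <- sum(a); alpha[t, ] <- a / cvec[t]
    }
    beta <- matrix(0, Tn, N)
    beta[Tn, ] <- 1
    if (Tn > 1) for (t in (Tn - 1):1) {
      beta[t, ] <- as.vector(model$Gamma %*% (B[t + 1, ] * beta[t + 1, ])) /
        cvec[t + 1]
    }
    p <- alpha * beta
    p <- p / rowSums(p)
    posts[[length(posts) + 1]] <- p
    ll <- ll + sum(log(cvec)) + sum(apply(logB, 1, max))
  }
  posterior <- do.call(rbind, posts)
  structure(list(posterior = posterior,
                 max_posterior = apply(posterior, 1, max),
                 viterbi = viterbi(model, steps, step_floor),
                 loglik = ll),
            class = "decoding")
}

#' Predictive-power index of a decoding
#'
#' Mean over steps of the posterior probability of the most likely state;
#' a model is considered strongly predictive when this exceeds 0.85.
#'
#' @param decoding a `decoding` from [state_posteriors()].
#' @return scalar in `[1/N, 1]`.
#' @export
predictive_power <- function(decoding) mean(decoding$max_posterior)

#' Akaike information criterion of a movement model
#'
#' `-2 loglik + 2 k` with `k = 4N` emission parameters plus `N(N-1)`
#' transition and `N-1` initial-distribution parameters.
#'
#' @param model fitted `movement_model`.
#' @return AIC value.
#' @export
aic <- function(model) -2 * model$loglik + 2 * model$k

#' Select among candidate movement models by sequential criteria
#'
#' Three sequential criteria: (1) biological plausibility — state
#' step-length means ordered and separated by at least `mean_ratio`;
#' (2) predictive power — mean maximum posterior above
#' `pred_threshold`; (3) minimum AIC among the survivors.
#'
#' @param candidates list of fitted `movement_model`s (e.g. N = 2, 3, 4).
#' @param decodings list of matching `decoding`s.
#' @param mean_ratio minimum ratio between successive state means.
#' @param pred_threshold predictive-power threshold (default 0.85).
#' @return list with `model` (the chosen one) and `report` (data.frame
#'   of criteria per candidate). Errors with the report attached if no
#'   candidate passes.
#' @export
select_model <- function(candidates, decodings, mean_ratio = 3,
                         pred_threshold = 0.85) {
  stopifnot(length(candidates) == length(decodings))
  report <- do.call(rbind, lapply(seq_along(candidates), function(i) {
    m <- candidates[[i]]
    plaus <- all(diff(m$mean) > 0) &&
      all(m$mean[-1] / m$mean[-m$N] >= mean_ratio)
    pp <- predictive_power(decodings[[i]])
    data.frame(N = m$N, loglik = m$loglik, k = m$k, aic = aic(m),
               plausible = plaus, predictive_power = pp,
               strongly_predictive = pp > pred_threshold)
  }))
  report$passes <- report$plausible & report$strongly_predictive
  surv <- which(report$passes)
  if (length(surv) == 0) {
    e <- simpleError("no candidate model passes the sequential criteria")
    e$report <- report
    stop(e)
  }
  best <- surv[which.min(report$aic[surv])]
  list(model = candidates[[best]], report = report)
}

#' Serialize a movement model to JSON
#'
#' @param model a `movement_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_movement_model <- function(model, path) {
  obj <- list(N = model$N, mean = model$mean, sd = model$sd,
              turn_m = model$turn_m, turn_rho = model$turn_rho,
              Gamma = model$Gamma, delta = model$delta,
              loglik = model$loglik, k = model$k,
              multistart = model$multistart)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}
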