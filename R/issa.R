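#' Pooled empirical step-length and turn-angle distributions
#'
#' Availability distributions for random-step generation: the pooled
#' observed step lengths and turning angles across all animals' steps
#' (empirical resampling, no parametric fit).
#'
#' @param steps step data.frame or list of step data.frames.
#' @return list with numeric vectors `lengths` and `turns`.
#' @export
empirical_distributions <- function(steps) {
  sl <- as_step_list(steps)
  lengths <- unlist(lapply(sl, function(s) s$length))
  turns <- unlist(lapply(sl, function(s) s$turn))
  list(lengths = lengths[!is.na(lengths)], turns = turns[!is.na(turns)])
}

#' Generate random candidate steps for one stratum
#'
#' Draws `n` independent (length, turn angle) pairs by resampling the
#' pooled empirical distributions, places endpoints from the stratum's
#' start point and previous absolute bearing, and redraws candidates
#' falling outside the landscape (up to `max_attempts` per candidate).
#'
#' @param x0,y0 stratum start point (m).
#' @param prev_bearing absolute bearing (radians, counterclockwise from
#'   east) of the incoming step.
#' @param distributions list from [empirical_distributions()].
#' @param n number of random steps (default 10).
#' @param extent landscape extent `c(xmin, xmax, ymin, ymax)`; `NULL`
#'   disables the bounds check.
#' @param seed integer seed.
#' @param max_attempts redraw budget per candidate.
#' @return data.frame `x, y, length, turn` with `n` rows.
#' @export
generate_random_steps <- function(x0, y0, prev_bearing, distributions,
                                  n = 10, extent = NULL, seed = 1L,
                                  max_attempts = 100) {
  if (length(distributions$lengths) == 0 || length(distributions$turns) == 0) {
    stop("empty empirical distributions", call. = FALSE)
  }
  if (!is.null(extent) &&
      (x0 < extent[1] || x0 > extent[2] || y0 < extent[3] || y0 > extent[4])) {
    stop("stratum start point outside the landscape", call. = FALSE)
  }
  with_seed(seed, {
    out <- data.frame(x = numeric(n), y = numeric(n),
                      length = numeric(n), turn = numeric(n))
    for (i in seq_len(n)) {
      ok <- FALSE
      for (att in seq_len(max_attempts)) {
        len <- sample(distributions$lengths, 1)
        trn <- sample(distributions$turns, 1)
        brg <- prev_bearing + trn
        x <- x0 + len * cos(brg); y <- y0 + len * sin(brg)
        if (is.null(extent) ||
            (x >= extent[1] && x <= extent[2] &&
             y >= extent[3] && y <= extent[4])) {
          out[i, ] <- c(x, y, len, trn)
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("could not place a random step inside the landscape ",
                    "after ", max_attempts, " attempts", call. = FALSE)
    }
    out
  })
}

#' Build used/available step strata with covariates
#'
#' One stratum per usable decoded step: the used step plus `n_random`
#' random steps, each characterized by the landscape covariates at its
#' endpoint, the natural log of its step length, and the cosine of its
#' turning angle. Strata are dropped (and logged) when the used step has
#' no defined turning angle or length, or touches an imputed fix.
#'
#' @param steps decoded step data.frame with columns from
#'   [steps_from_burst()] plus `behavior`, `season`, `light`.
#' @param stack a `landscape_stack`.
#' @param distributions list from [empirical_distributions()].
#' @param n_random random steps per stratum (default 10).
#' @param seed integer seed.
#' @param ln_floor floor (m) for step length before the log.
#' @param covariates landscape covariates to sample at candidate
#'   endpoints; `NULL` means the full set of [sample_covariates()]
#'   columns. Restricting the set speeds up large simulation studies.
#' @return long-format data.frame: `stratum, case, season, light,
#'   behavior, x, y, ln_sl, cos_ta` plus the covariate columns of
#'   [sample_covariates()].
#' @export
make_strata <- function(steps, stack, distributions, n_random = 10,
                        seed = 1L, ln_floor = 1, covariates = NULL) {
  ext <- raster_extent(stack$landcover)
  usable <- !is.na(steps$turn) & !is.na(steps$length) & !steps$imputed &
    raster_in_bounds(stack$landcover, steps$x1, steps$y1)
  s <- steps[usable, , drop = FALSE]
  if (nrow(s) == 0) return(NULL)
  prev_bearing <- s$bearing - s$turn
  rows <- vector("list", nrow(s))
  for (i in seq_len(nrow(s))) {
    rnd <- generate_random_steps(s$x0[i], s$y0[i], prev_bearing[i],
                                 distributions, n = n_random, extent = ext,
                                 seed = stage_seed(seed, paste0("stratum", i)))
    rows[[i]] <- data.frame(
      stratum = i,
      case = c(1L, rep(0L, n_random)),
      season = s$season[i], light = s$light[i], behavior = s$behavior[i],
      x = c(s$x1[i], rnd$x), y = c(s$y1[i], rnd$y),
      length = c(s$length[i], rnd$length),
      turn = c(s$turn[i], rnd$turn))
  }
  long <- do.call(rbind, rows)
  long$ln_sl <- log(pmax(long$length, ln_floor))
  long$cos_ta <- cos(long$turn)
  if (is.null(covariates)) {
    cbind(long, sample_covariates(stack, long$x, long$y))
  } else {
    cbind(long, as.data.frame(covariate_at(stack, long$x, long$y,
                                           covariates)))
  }
}

#' Partition strata into season x light x behavior datasets
#'
#' @param strata long-format strata from [make_strata()].
#' @return named list of data.frames keyed `"season.light.behavior"`;
#'   all 2 x 3 x 3 combinations are present (possibly empty).
#' @export
partition_steps <- function(strata) {
  seasons <- c("snow", "snow_free")
  lights <- c("diurnal", "crepuscular", "nocturnal")
  behaviors <- sort(unique(as.character(strata$behavior)))
  if (length(behaviors) == 0) behaviors <- c("encamped", "foraging", "traveling")
  out <- list()
  for (se in seasons) for (li in lights) for (be in behaviors) {
    key <- paste(se, li, be, sep = ".")
    out[[key]] <- strata[strata$season == se & strata$light == li &
                           strata$behavior == be, , drop = FALSE]
  }
  out
}

# Default covariate list of the global selection model.
issa_covariates <- function() {
  c("forest10", "open10", "forest500", "open500", "edge50", "simpson500",
    "corridor100", "corridor500", "elev100", "slope", "ln_sl", "cos_ta")
}

#' Conditional logistic regression on step strata
#'
#' Maximizes the stratified conditional-logistic partial likelihood (a
#' softmax over the candidates of each stratum with the used candidate
#' in the numerator) by Newton-Raphson on the analytic gradient and
#' Hessian, with step-halving and a 1e-8 ridge on the Hessian diagonal.
#' Standard errors come from the inverse observed information.
#' Covariates with no within-stratum contrast anywhere are an error;
#' coefficients walked beyond `sep_bound` are flagged as separated with
#' an infinite-SE marker.
#'
#' @param data long-format strata (one dataset from [partition_steps()]).
#' @param covariates covariate column names; default [issa_covariates()].
#' @param min_strata minimum number of complete strata (default 20).
#' @param max_iter,tol Newton iteration controls.
#' @param sep_bound coefficient magnitude treated as separation.
#' @return object of class `selection_fit`: `beta`, `se`, `loglik`,
#'   `loglik_null`, `n_strata`, `significant`, `vif`, `separated`,
#'   `converged`, `key`.
#' @export
fit_clogit <- function(data, covariates = issa_covariates(),
                       min_strata = 20, max_iter = 50, tol = 1e-10,
                       sep_bound = 15) {
  cc <- complete.cases(data[, covariates, drop = FALSE])
  data <- data[cc, , drop = FALSE]
  # keep only strata with exactly one used candidate
  used_per <- tapply(data$case, data$stratum, sum)
  keep <- names(used_per)[used_per == 1]
  data <- data[as.character(data$stratum) %in% keep, , drop = FALSE]
  ns <- length(unique(data$stratum))
  if (ns < min_strata) {
    stop("too few strata (", ns, " < ", min_strata, ")", call. = FALSE)
  }
  X <- as.matrix(data[, covariates, drop = FALSE])
  stratum <- factor(data$stratum)
  case <- data$case == 1
  # within-stratum contrast check
  ctr <- rowsum(X, stratum) / as.vector(table(stratum))
  Xc <- X - ctr[as.integer(stratum), , drop = FALSE]
  no_contrast <- colSums(Xc^2) == 0
  if (any(no_contrast)) {
    stop("no within-stratum contrast for covariate(s): ",
         paste(covariates[no_contrast], collapse = ", "), call. = FALSE)
  }
  p <- ncol(X)
  beta <- numeric(p)
  loglik <- function(b) {
    eta <- as.vector(X %*% b)
    eta_max <- tapply(eta, stratum, max)[stratum]
    w <- exp(eta - as.numeric(eta_max))
    denom <- rowsum(w, stratum)
    sum(eta[case]) - sum(as.numeric(eta_max[case])) - sum(log(denom))
  }
  ll <- loglik(beta)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- as.vector(X %*% beta)
    eta_max <- as.numeric(tapply(eta, stratum, max)[stratum])
    w <- exp(eta - eta_max)
    denom <- as.numeric(rowsum(w, stratum)[stratum])
    prob <- w / denom
    M <- rowsum(prob * X, stratum)             # per-stratum mean covariate
    grad <- colSums(X[case, , drop = FALSE]) - colSums(M)
    info <- t(X) %*% (prob * X) - t(M) %*% M   # observed information
    info_r <- info + diag(1e-8, p)
    step <- tryCatch(solve(info_r, grad), error = function(e) {
      ev <- eigen(info_r, symmetric = TRUE)
      bad <- covariates[abs(ev$vectors[, p]) > 0.5]
      stop("singular information matrix; near-collinear column(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    })
    # step-halving: partial likelihood must not decrease
    lam <- 1
    repeat {
      cand <- beta + lam * step
      ll_new <- loglik(cand)
      if (ll_new >= ll - 1e-12 || lam < 1e-6) break
      lam <- lam / 2
    }
    beta <- cand
    if (abs(ll_new - ll) < tol && sqrt(sum(grad^2)) < 1e-6) {
      ll <- ll_new; converged <- TRUE; break
    }
    ll <- ll_new
  }
  separated <- abs(beta) > sep_bound
  eta <- as.vector(X %*% beta)
  eta_max <- as.numeric(tapply(eta, stratum, max)[stratum])
  w <- exp(eta - eta_max)
  prob <- w / as.numeric(rowsum(w, stratum)[stratum])
  M <- rowsum(prob * X, stratum)
  info <- t(X) %*% (prob * X) - t(M) %*% M
  vcov <- tryCatch(solve(info + diag(1e-8, ncol(X))),
                   error = function(e) matrix(NA_real_, p, p))
  se <- sqrt(pmax(diag(vcov), 0))
  se[separated] <- Inf
  names(beta) <- names(se) <- covariates
  m_per <- as.vector(table(stratum))
  fit <- structure(list(
    beta = beta, se = se, loglik = ll,
    loglik_null = -sum(log(m_per)),
    n_strata = ns, vif = vif(data, covariates),
    separated = separated, converged = converged,
    iterations = it, key = attr(data, "key")),
    class = "selection_fit")
  fit$significant <- significance_flags(fit)
  fit
}

#' @export
print.selection_fit <- function(x, ...) {
  cat(sprintf("<selection_fit> %d strata, log partial likelihood %.3f\n",
              x$n_strata, x$loglik))
  tab <- data.frame(beta = round(x$beta, 3), se = round(x$se, 3),
                    significant = x$significant, vif = round(x$vif, 2))
  print(tab)
  invisible(x)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` from ordinary least squares of covariate
#' `j` on the other covariates over all candidate rows. Perfectly
#' collinear covariates return values above the 1e6 sentinel.
#'
#' @param data long-format strata rows.
#' @param covariates covariate column names.
#' @return named numeric vector of VIFs.
#' @export
vif <- function(data, covariates = issa_covariates()) {
  X <- as.matrix(data[, covariates, drop = FALSE])
  out <- setNames(numeric(length(covariates)), covariates)
  for (j in seq_along(covariates)) {
    yj <- X[, j]
    others <- X[, -j, drop = FALSE]
    if (stats::var(yj) == 0) { out[j] <- 1; next }
    fit <- stats::lm.fit(cbind(1, others), yj)
    r2 <- 1 - sum(fit$residuals^2) / sum((yj - mean(yj))^2)
    out[j] <- 1 / max(1 - r2, 1e-12)
  }
  out
}

#' Significance flags by the twice-standard-error rule
#'
#' A coefficient is flagged significant iff `2 * SE < |beta|`
#' (strict inequality).
#'
#' @param fit a `selection_fit` (or any list with `beta` and `se`).
#' @return named logical vector.
#' @export
significance_flags <- function(fit) {
  flags <- 2 * fit$se < abs(fit$beta)
  flags[!is.finite(fit$se)] <- FALSE
  flags
}

#' Fit the global selection model across all temporal-behavior datasets
#'
#' Runs [fit_clogit()] independently on each season x light x behavior
#' dataset with enough strata; smaller datasets are skipped with a
#' logged reason.
#'
#' @param strata long-format strata from [make_strata()].
#' @param covariates covariate list, default [issa_covariates()].
#' @param min_strata minimum strata per dataset.
#' @return list with `fits` (named list of `selection_fit`) and
#'   `skipped` (data.frame with reasons).
#' @export
fit_issa <- function(strata, covariates = issa_covariates(),
                     min_strata = 20) {
  parts <- partition_steps(strata)
  fits <- list()
  skipped <- data.frame(key = character(), n_strata = integer(),
                        reason = character())
  for (key in names(parts)) {
    d <- parts[[key]]
    ns <- length(unique(d$stratum))
    attr(d, "key") <- key
    f <- tryCatch(fit_clogit(d, covariates, min_strata = min_strata),
                  error = function(e) conditionMessage(e))
    if (is.character(f)) {
      skipped <- rbind(skipped,
                       data.frame(key = key, n_strata = ns, reason = f))
    } else {
      fits[[key]] <- f
    }
  }
  list(fits = fits, skipped = skipped)
}

#' Long-format results table of selection fits
#'
#' @param issa_fits result of [fit_issa()].
#' @return data.frame `key, covariate, beta, se, significant, vif,
#'   n_strata`.
#' @export
issa_results_table <- function(issa_fits) {
  do.call(rbind, lapply(names(issa_fits$fits), function(key) {
    f <- issa_fits$fits[[key]]
    data.frame(key = key, covariate = names(f$beta), beta = f$beta,
               se = f$se, significant = f$significant, vif = f$vif,
               n_strata = f$n_strata, row.names = NULL)
  }))
}

#' Wide-format coefficient table of selection fits
#'
#' Reshapes the selection results into the familiar report layout: one
#' row per covariate, one column per season x light x behavior dataset,
#' cells formatted as `beta (SE)` with significant coefficients
#' (2 x SE < |beta|) marked by an asterisk.
#'
#' @param issa_fits result of [fit_issa()].
#' @param digits decimals for the formatted cells.
#' @return data.frame with a `covariate` column and one column per
#'   fitted dataset.
#' @export
issa_wide_table <- function(issa_fits, digits = 2) {
  keys <- names(issa_fits$fits)
  if (length(keys) == 0) return(NULL)
  covs <- names(issa_fits$fits[[1]]$beta)
  out <- data.frame(covariate = covs, stringsAsFactors = FALSE)
  for (key in keys) {
    f <- issa_fits$fits[[key]]
    cell <- sprintf(paste0("%.", digits, "f (%.", digits, "f)"),
                    f$beta[covs], f$se[covs])
    cell[f$significant[covs]] <- paste0(cell[f$significant[covs]], "*")
    out[[key]] <- cell
  }
  out
}
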