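# Minimal strata builder: k strata, m candidates each, covariates given
# as a list of vectors/matrices.
toy_strata <- function(X, case_idx) {
  k <- length(X)
  do.call(rbind, lapply(seq_len(k), function(s) {
    m <- nrow(X[[s]])
    d <- as.data.frame(X[[s]])
    d$stratum <- s
    d$case <- as.integer(seq_len(m) == case_idx[s])
    d
  }))
}

# Direct partial likelihood for one coefficient vector (oracle).
partial_ll <- function(data, covariates, beta) {
  eta <- as.matrix(data[, covariates, drop = FALSE]) %*% beta
  sum(tapply(seq_len(nrow(data)), data$stratum, function(i) {
    eta[i][data$case[i] == 1] - log(sum(exp(eta[i])))
  }))
}

test_that("pooled empirical distributions conserve the sample", {
  a <- data.frame(length = 1:5, turn = c(NA, 0.1, -0.2, 0.3, 0))
  b <- data.frame(length = c(10, 20), turn = c(NA, 0.5))
  d <- empirical_distributions(list(a, b))
  expect_equal(sort(d$lengths), sort(c(1:5, 10, 20)))
  expect_length(d$turns, 5)
  expect_equal(empirical_distributions(a)$lengths, 1:5)
})

test_that("resampled step lengths reproduce the pooled distribution", {
  set.seed(1)
  pool <- data.frame(length = rgamma(2000, 2, 0.01),
                     turn = runif(2000, -pi, pi))
  d <- empirical_distributions(pool)
  rs <- generate_random_steps(0, 0, 0, d, n = 10, seed = 3)
  expect_equal(nrow(rs), 10)
  expect_true(all(rs$length %in% d$lengths))
  expect_true(all(rs$turn %in% d$turns))

  draws <- replicate(1000, NULL)
  set.seed(9)
  big <- sample(d$lengths, 1e4, replace = TRUE)
  ks <- suppressWarnings(stats::ks.test(big, d$lengths))
  expect_lt(unname(ks$statistic), 0.02)
})

test_that("random steps stay in bounds and degenerate distributions coincide", {
  d0 <- list(lengths = rep(100, 5), turns = rep(0.2, 5))
  rs <- generate_random_steps(0, 0, pi / 4, d0, n = 10, seed = 1)
  expect_equal(length(unique(round(rs$x, 9))), 1)
  expect_equal(length(unique(round(rs$y, 9))), 1)

  d <- list(lengths = rep(500, 10), turns = seq(-pi, pi, length.out = 10))
  ext <- c(0, 1000, 0, 1000)
  rs <- generate_random_steps(500, 500, 0, d, n = 10, extent = ext, seed = 2)
  expect_true(all(rs$x >= 0 & rs$x <= 1000 & rs$y >= 0 & rs$y <= 1000))
  expect_error(generate_random_steps(-10, 500, 0, d, extent = ext),
               "outside")
  # impossible placement exhausts the redraw budget
  dfar <- list(lengths = rep(1e6, 3), turns = c(0, 1, 2))
  expect_error(generate_random_steps(500, 500, 0, dfar, extent = ext,
                                     max_attempts = 20), "attempts")
})

test_that("partitioning yields the full season x light x behavior grid", {
  set.seed(2)
  strata <- data.frame(
    stratum = rep(1:60, each = 2), case = rep(c(1, 0), 60),
    season = rep(sample(c("snow", "snow_free"), 60, TRUE), each = 2),
    light = rep(sample(c("diurnal", "crepuscular", "nocturnal"), 60, TRUE),
                each = 2),
    behavior = rep(sample(c("encamped", "foraging", "traveling"), 60, TRUE),
                   each = 2))
  parts <- partition_steps(strata)
  expect_length(parts, 18)
  expect_equal(sum(vapply(parts, nrow, 0L)), nrow(strata))

  one <- strata
  one$season <- "snow_free"; one$light <- "diurnal"; one$behavior <- "traveling"
  parts1 <- partition_steps(one)
  expect_equal(sum(vapply(parts1, nrow, 0L) > 0), 1)
})

test_that("the conditional-logistic MLE matches brute-force maximization on a toy", {
  set.seed(3)
  X <- lapply(1:5, function(s) matrix(rbinom(6, 1, 0.5), ncol = 1,
                                      dimnames = list(NULL, "z")))
  case_idx <- sample(1:6, 5, replace = TRUE)
  data <- toy_strata(X, case_idx)
  # ensure the used candidate differs within strata (no separation)
  data$z[data$case == 1] <- c(1, 0, 1, 0, 1)
  fit <- fit_clogit(data, covariates = "z", min_strata = 1)
  # brute-force oracle: one-dimensional maximization of the partial lik
  oracle <- stats::optimize(function(b) partial_ll(data, "z", b),
                            c(-10, 10), maximum = TRUE)
  expect_equal(unname(fit$beta), oracle$maximum, tolerance = 1e-4)
  expect_equal(fit$loglik, oracle$objective, tolerance = 1e-6)
  expect_gte(fit$loglik, partial_ll(data, "z", unname(fit$beta) + 0.01))
})

test_that("the in-package fit agrees with the survival package on shared data", {
  skip_if_not_installed("survival")
  withr::local_package("survival")  # clogit builds an unqualified coxph call
  set.seed(4)
  n_str <- 40
  rows <- lapply(seq_len(n_str), function(s) {
    m <- 11
    d <- data.frame(z1 = rnorm(m), z2 = rbinom(m, 1, 0.4))
    eta <- 0.8 * d$z1 - 0.5 * d$z2
    pick <- sample(m, 1, prob = exp(eta))
    d$stratum <- s
    d$case <- as.integer(seq_len(m) == pick)
    d
  })
  data <- do.call(rbind, rows)
  fit <- fit_clogit(data, covariates = c("z1", "z2"), min_strata = 5)
  ref <- survival::clogit(case ~ z1 + z2 + strata(stratum), data = data)
  expect_equal(unname(fit$beta), unname(coef(ref)), tolerance = 1e-5)
  expect_equal(unname(fit$se),
               unname(sqrt(diag(vcov(ref)))), tolerance = 1e-4)
})

test_that("the null partial likelihood and Newton monotonicity hold", {
  set.seed(5)
  n_str <- 25
  rows <- lapply(seq_len(n_str), function(s) {
    d <- data.frame(z = rnorm(11))
    d$stratum <- s
    d$case <- as.integer(seq_len(11) == sample(11, 1))
    d
  })
  data <- do.call(rbind, rows)
  expect_equal(partial_ll(data, "z", 0), n_str * log(1 / 11))
  fit <- fit_clogit(data, covariates = "z", min_strata = 5)
  expect_equal(fit$loglik_null, n_str * log(1 / 11))
  expect_gte(fit$loglik, fit$loglik_null - 1e-12)
})

test_that("candidate order within strata does not change the estimate", {
  set.seed(6)
  rows <- lapply(1:30, function(s) {
    d <- data.frame(z1 = rnorm(11), z2 = rnorm(11))
    eta <- 1 * d$z1
    d$stratum <- s
    d$case <- as.integer(seq_len(11) == sample(11, 1, prob = exp(eta)))
    d
  })
  data <- do.call(rbind, rows)
  fit1 <- fit_clogit(data, covariates = c("z1", "z2"), min_strata = 5)
  set.seed(7)
  shuffled <- do.call(rbind, lapply(split(data, data$stratum),
                                    function(d) d[sample(nrow(d)), ]))
  fit2 <- fit_clogit(shuffled, covariates = c("z1", "z2"), min_strata = 5)
  expect_equal(fit1$beta, fit2$beta, tolerance = 1e-8)
})

test_that("covariates without within-stratum contrast are refused by name", {
  set.seed(8)
  rows <- lapply(1:25, function(s) {
    d <- data.frame(z = rnorm(11), flat = s * 1.0)  # constant within stratum
    d$stratum <- s
    d$case <- as.integer(seq_len(11) == 1)
    d
  })
  data <- do.call(rbind, rows)
  expect_error(fit_clogit(data, covariates = c("z", "flat"), min_strata = 5),
               "flat")
  expect_error(fit_clogit(data[data$stratum <= 3, ], covariates = "z",
                          min_strata = 20), "too few strata")
})

test_that("variance inflation factors follow the 1/(1-R2) closed form", {
  # orthogonal design
  X <- data.frame(a = rep(c(-1, 1), 20), b = rep(c(-1, -1, 1, 1), 10))
  expect_true(all(abs(vif(X, c("a", "b")) - 1) < 1e-10))

  # exact R^2 = 0.75 construction: y = x + e with var(e) = var(x)/3
  x1 <- rep(c(-3, -1, 1, 3), 10)
  e <- rep(c(1, -1, -1, 1), 10) * sqrt(5 / 3)
  X2 <- data.frame(x1 = x1, x2 = x1 + e)
  v <- vif(X2, c("x1", "x2"))
  expect_equal(unname(v["x2"]), 4, tolerance = 1e-9)

  # perfect collinearity reports the sentinel
  X3 <- data.frame(u = rnorm(40))
  X3$v <- X3$u
  expect_true(all(vif(X3, c("u", "v")) > 1e6))
})

test_that("significance follows the strict twice-standard-error rule", {
  fit <- list(beta = c(a = 0.92, b = 0.44, c = -0.8),
              se = c(a = 0.34, b = 0.37, c = 0.4))
  flags <- significance_flags(fit)
  expect_true(flags[["a"]])    # 0.68 < 0.92
  expect_false(flags[["b"]])   # 0.74 > 0.44
  expect_false(flags[["c"]])   # exactly 2 SE: strict inequality fails
  inf_fit <- list(beta = c(a = 20), se = c(a = Inf))
  expect_false(significance_flags(inf_fit)[["a"]])
})

test_that("known selection against a landscape covariate is recovered end to end", {
  st <- test_landscape(seed = 21)
  ts <- track_spec(step_mean = 150, step_sd = 100, turn_m = 0,
                   turn_rho = 0.2, transition = matrix(1, 1, 1),
                   duration_days = 30, missingness = 0,
                   beta = c(forest10 = 1.0), seed = 31)
  sim <- simulate_track(ts, st)
  s <- steps_from_burst(make_burst(sim$fixes$x, sim$fixes$y))
  s$behavior <- "traveling"; s$season <- "snow_free"; s$light <- "diurnal"
  d <- empirical_distributions(s)
  strata <- make_strata(s, st, d, n_random = 10, seed = 5,
                        covariates = "forest10")
  fit <- fit_clogit(strata, covariates = c("forest10", "ln_sl", "cos_ta"))
  expect_lt(abs(fit$beta[["forest10"]] - 1.0), 2 * fit$se[["forest10"]])
})

test_that("the wide coefficient table formats one column per dataset", {
  set.seed(11)
  strata <- do.call(rbind, lapply(1:50, function(s) {
    d <- data.frame(z = rnorm(11), ln_sl = rnorm(11), cos_ta = rnorm(11))
    d$stratum <- s
    d$case <- as.integer(seq_len(11) == sample(11, 1, prob = exp(d$z)))
    d$season <- "snow_free"
    d$light <- if (s %% 2) "diurnal" else "nocturnal"
    d$behavior <- "traveling"
    d
  }))
  fits <- fit_issa(strata, covariates = c("z", "ln_sl", "cos_ta"),
                   min_strata = 10)
  wide <- issa_wide_table(fits)
  expect_equal(wide$covariate, c("z", "ln_sl", "cos_ta"))
  expect_equal(ncol(wide), 1 + length(fits$fits))
  # cells carry the beta (SE) format, starred when significant
  f1 <- fits$fits[[1]]
  expect_match(wide[[2]][1], "^-?\\d+\\.\\d+ \\(\\d+\\.\\d+\\)\\*?$")
  if (f1$significant[["z"]]) expect_match(wide[[2]][1], "\\*$")
})
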