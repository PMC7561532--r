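test_that("emission densities have the stated closed forms and normalize", {
  # mean = sd is the exponential: density 1/mu at zero
  expect_equal(gamma_logpdf(0, 100, 100), log(1 / 100))
  # quadrature oracle: density integrates to one
  for (p in list(c(7, 6), c(198, 160), c(1426, 1100))) {
    q <- stats::integrate(function(x) exp(gamma_logpdf(x, p[1], p[2])),
                          0, Inf, rel.tol = 1e-9)
    expect_lt(abs(q$value - 1), 1e-6)
  }
  # sampling oracle at the foraging scale
  set.seed(1)
  draws <- carnmove:::rgamma_ms(1e5, 198, 160)
  expect_lt(abs(mean(draws) - 198), 3 * 160 / sqrt(1e5))

  # wrapped Cauchy: uniform limit, normalization, mode at the location
  expect_equal(exp(wrapped_cauchy_logpdf(1.3, 0, 0)), 1 / (2 * pi))
  for (rho in c(0.2, 0.8)) {
    q <- stats::integrate(function(th) exp(wrapped_cauchy_logpdf(th, 0.5, rho)),
                          -pi, pi, rel.tol = 1e-9)
    expect_lt(abs(q$value - 1), 1e-6)
  }
  th <- seq(-pi, pi, length.out = 721)
  dens <- wrapped_cauchy_logpdf(th, 0.7, 0.8)
  expect_equal(th[which.max(dens)], 0.7, tolerance = 0.01)
  expect_error(wrapped_cauchy_logpdf(0, 0, 1), "rho")
})

test_that("the forward likelihood reduces to summed emissions for one state", {
  set.seed(2)
  s <- data.frame(length = rgamma(20, 2, 0.01), turn = runif(20, -pi, pi),
                  imputed = FALSE)
  s$turn[1] <- NA
  m <- toy_model(1)
  direct <- sum(gamma_logpdf(pmax(s$length, 1), m$mean, m$sd)) +
    sum(wrapped_cauchy_logpdf(s$turn[-1], m$turn_m, m$turn_rho))
  expect_equal(forward_loglik(m, s), direct, tolerance = 1e-10)
})

test_that("forward, Viterbi and posteriors agree with exhaustive path enumeration", {
  for (N in 2:3) {
    set.seed(N)
    Tn <- if (N == 2) 6 else 7
    m <- toy_model(N)
    s <- data.frame(length = rgamma(Tn, 1.5, 0.005),
                    turn = runif(Tn, -pi, pi), imputed = FALSE)
    s$turn[1] <- NA
    s$length[3] <- NA  # missing-length slot handled as transition-only
    logB <- carnmove:::emission_logmat(s, m$mean, m$sd, m$turn_m,
                                       m$turn_rho, 1)
    expect_equal(forward_loglik(m, s), enum_forward(logB, m$Gamma, m$delta),
                 tolerance = 1e-8)
    expect_equal(viterbi(m, s),
                 as.integer(enum_viterbi(logB, m$Gamma, m$delta)))
    dec <- state_posteriors(m, s)
    expect_equal(dec$posterior, enum_posteriors(logB, m$Gamma, m$delta),
                 tolerance = 1e-8)
    expect_true(all(abs(rowSums(dec$posterior) - 1) < 1e-10))
  }
})

test_that("multiple bursts contribute additively to the likelihood", {
  set.seed(5)
  mk <- function(n) {
    s <- data.frame(length = rgamma(n, 2, 0.01), turn = runif(n, -pi, pi),
                    imputed = FALSE)
    s$turn[1] <- NA
    s
  }
  m <- toy_model(2)
  a <- mk(10); b <- mk(15)
  expect_equal(forward_loglik(m, list(a, b)),
               forward_loglik(m, a) + forward_loglik(m, b),
               tolerance = 1e-10)
})

test_that("the likelihood is invariant to state relabeling", {
  set.seed(6)
  s <- data.frame(length = rgamma(50, 2, 0.01), turn = runif(50, -pi, -pi + 2),
                  imputed = FALSE)
  s$turn[1] <- NA
  m <- toy_model(3)
  perm <- c(3, 1, 2)
  mp <- carnmove:::new_movement_model(
    m$mean[perm], m$sd[perm], m$turn_m[perm], m$turn_rho[perm],
    m$Gamma[perm, perm], m$delta[perm])
  expect_equal(forward_loglik(m, s), forward_loglik(mp, s),
               tolerance = 1e-10)
})

test_that("two-state parameters are recovered from simulated data", {
  sim <- sim_hmm_steps(3000, mean = c(10, 1000), sd = c(8, 700),
                       rho = c(0.2, 0.7), seed = 31)
  fit <- fit_hmm(sim$steps, 2, start = carnmove:::default_start(2))
  expect_true(all(abs(fit$mean - c(10, 1000)) / c(10, 1000) < 0.10))
  truth_Gamma <- matrix(c(0.8, 0.2, 0.2, 0.8), 2, 2)
  expect_true(all(abs(fit$Gamma - truth_Gamma) < 0.05))
  # ML property: fitted likelihood is at least the truth's likelihood
  truth <- carnmove:::new_movement_model(c(10, 1000), c(8, 700), c(0, 0),
                                         c(0.2, 0.7), truth_Gamma,
                                         c(0.5, 0.5))
  expect_gte(fit$loglik + 1e-6, forward_loglik(truth, sim$steps))
})

test_that("refitting from a fitted optimum is a fixed point", {
  sim <- sim_hmm_steps(800, mean = c(20, 800), sd = c(15, 500),
                       rho = c(0.2, 0.7), seed = 7)
  ctl <- list(maxit = 1000, factr = 1, pgtol = 1e-5)
  fit <- fit_hmm(sim$steps, 2, start = carnmove:::default_start(2),
                 control = ctl)
  refit <- fit_hmm(sim$steps, 2, start = fit, control = ctl)
  expect_equal(refit$loglik, fit$loglik, tolerance = 1e-6)
  expect_equal(refit$mean, fit$mean, tolerance = 1e-6)
  expect_equal(refit$Gamma, fit$Gamma, tolerance = 1e-6)
})

test_that("multistart fitting maximizes over the grid deterministically", {
  sim <- sim_hmm_steps(600, mean = c(15, 900), sd = c(10, 600),
                       rho = c(0.2, 0.7), seed = 8)
  g1 <- list(carnmove:::default_start(2, c(20, 800), 0.4))
  single <- fit_hmm(sim$steps, 2, start = g1[[1]])
  ms <- multistart_fit(sim$steps, 2, grid = g1)
  expect_equal(ms$loglik, single$loglik)
  expect_equal(ms$mean, single$mean)

  # a deliberately bad start cannot win
  grid <- list(carnmove:::default_start(2, c(20, 800), 0.4),
               carnmove:::default_start(2, c(5000, 20000), 0.05))
  ms2 <- multistart_fit(sim$steps, 2, grid = grid)
  fits <- lapply(grid, function(g) fit_hmm(sim$steps, 2, start = g))
  expect_gte(ms2$loglik, max(vapply(fits, `[[`, 0, "loglik")) - 1e-8)
  # same winner under a reordered grid (tie to first in grid order)
  ms3 <- multistart_fit(sim$steps, 2, grid = rev(grid))
  expect_equal(ms3$mean, ms2$mean, tolerance = 1e-5)
  expect_error(multistart_fit(sim$steps, 2, grid = list()), "empty")
})

test_that("decoding summaries behave at the degenerate ends", {
  set.seed(9)
  s <- data.frame(length = rgamma(15, 2, 0.01), turn = runif(15, -pi, pi),
                  imputed = FALSE)
  s$turn[1] <- NA
  m1 <- toy_model(1)
  expect_equal(viterbi(m1, s), rep(1L, 15))
  dec <- state_posteriors(m1, s)
  expect_equal(dec$max_posterior, rep(1, 15))
  expect_equal(predictive_power(dec), 1)

  # uniform-posterior degenerate two-state decoding
  fake <- structure(list(max_posterior = rep(0.5, 10)), class = "decoding")
  expect_equal(predictive_power(fake), 0.5)
})

test_that("AIC follows the formula with the documented parameter count", {
  m <- toy_model(3)
  expect_equal(m$k, 20)  # 12 emission + 6 transition + 2 initial
  m$loglik <- -100
  m$k <- 10
  expect_equal(aic(m), 220)
  expect_equal(toy_model(2)$k, 11)
  expect_equal(toy_model(4)$k, 31)
})

test_that("model selection applies the three sequential criteria", {
  mk <- function(N, means, ll) {
    m <- toy_model(N)
    m$mean <- means
    m$loglik <- ll
    m
  }
  dk <- function(pp) structure(list(max_posterior = pp), class = "decoding")

  # only the middle candidate is plausible and predictive
  cands <- list(mk(2, c(100, 150), -10),           # means too close
                mk(3, c(7, 200, 1400), -12),
                mk(4, c(7, 15, 200, 1400), -5))    # 15/7 < 3x apart
  decs <- list(dk(rep(0.99, 10)), dk(rep(0.95, 10)), dk(rep(0.99, 10)))
  sel <- select_model(cands, decs)
  expect_equal(sel$model$N, 3)
  expect_equal(sum(sel$report$passes), 1)

  # all pass: minimum AIC wins
  cands <- list(mk(2, c(10, 500), -10), mk(2, c(10, 500), -1),
                mk(2, c(10, 500), -20))
  decs <- list(dk(rep(0.9, 5)), dk(rep(0.9, 5)), dk(rep(0.9, 5)))
  sel <- select_model(cands, decs)
  expect_equal(sel$model$loglik, -1)

  # weak prediction fails the second criterion
  decs_weak <- list(dk(rep(0.5, 5)), dk(rep(0.5, 5)), dk(rep(0.5, 5)))
  err <- tryCatch(select_model(cands, decs_weak), error = function(e) e)
  expect_s3_class(err, "error")
  expect_s3_class(err$report, "data.frame")
})

test_that("movement models serialize to JSON and stay numerically intact", {
  m <- toy_model(3)
  m$loglik <- -123.456
  p <- withr::local_tempfile(fileext = ".json")
  write_movement_model(m, p)
  back <- jsonlite::read_json(p, simplifyVector = TRUE)
  expect_equal(back$mean, m$mean)
  expect_equal(matrix(unlist(back$Gamma), 3, 3, byrow = TRUE), m$Gamma,
               tolerance = 1e-12)
  expect_equal(back$loglik, m$loglik)
})
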