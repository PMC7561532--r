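test_that("speed screening keeps plausible tracks and removes impossible fixes", {
  # two fixes 1 km apart over 2 h: 0.5 km/h, nothing to do
  f <- make_fixes(c(0, 2), c(0, 1000), c(0, 0))
  out <- filter_speed(f)
  expect_equal(nrow(out$fixes), 2)
  expect_equal(nrow(out$removed), 0)

  # a fix displaced 120 km from both neighbors at 2-h spacing (60 km/h)
  f <- make_fixes(c(0, 2, 4), c(0, 120e3, 0), c(0, 0, 0))
  out <- filter_speed(f)
  expect_equal(nrow(out$removed), 1)
  expect_equal(out$removed$x, 120e3)
})

test_that("iterated removal matches the minimal removal set on a planted-outlier toy", {
  set.seed(7)
  x <- cumsum(rnorm(10, 0, 300)); y <- cumsum(rnorm(10, 0, 300))
  x[4] <- x[4] + 150e3; y[8] <- y[8] - 200e3
  f <- make_fixes(seq(0, 18, by = 2), x, y)
  out <- filter_speed(f)
  expect_equal(nrow(out$removed), 2)
  expect_setequal(out$removed$x, c(x[4], x[8]))

  # exhaustive-removal oracle: no smaller subset fixes the track
  ok_after_removing <- function(idx) {
    g <- f[-idx, , drop = FALSE]
    v <- carnmove:::consecutive_speeds(g$time, g$x, g$y)
    all(v <= 50)
  }
  expect_false(any(vapply(1:10, ok_after_removing, TRUE)))
  expect_true(ok_after_removing(c(4, 8)))
})

test_that("speed screening never removes fixes from a track within the speed limit", {
  for (s in 1:5) {
    set.seed(s)
    n <- 30
    # max speed 2 km over 2 h = 1 km/h
    f <- make_fixes(seq(0, by = 2, length.out = n),
                    cumsum(runif(n, -2000, 2000)),
                    cumsum(runif(n, -2000, 2000)))
    expect_equal(nrow(filter_speed(f)$removed), 0)
  }
})

test_that("speeds between flag and removal thresholds are flagged, not removed", {
  # 30 km in 2 h = 15 km/h: improbable but possible
  f <- make_fixes(c(0, 2, 4), c(0, 30e3, 31e3), c(0, 0, 0))
  out <- filter_speed(f)
  expect_equal(nrow(out$removed), 0)
  expect_true(any(out$fixes$speed_flag))
})

test_that("single-fix animals pass through speed screening with a warning", {
  f <- make_fixes(0, 5, 5)
  expect_warning(out <- filter_speed(f), "fewer than 2")
  expect_equal(nrow(out$fixes), 1)
})

test_that("rarefaction is the identity on already-regular data and thins dense data", {
  f <- make_fixes(seq(0, 48, by = 2), seq(0, 48, by = 2) * 10, 0)
  expect_equal(rarefy(f, 2)$time, f$time)

  dense <- make_fixes(seq(0, 24, by = 0.25), seq_len(97), 0)
  out <- rarefy(dense, 2)
  expect_equal(as.numeric(diff(out$time), units = "hours"),
               rep(2, nrow(out) - 1))
  expect_equal(out$x, dense$x[seq(1, 97, by = 8)])
})

test_that("7-h rarefaction of a mixed schedule matches the exhaustive longest-subsequence oracle", {
  # mixed 2/6-h schedule with an embedded 7-h-compatible chain
  hours <- sort(unique(c(seq(0, 40, by = 2), seq(48, 60, by = 6),
                         seq(0, 63, by = 7))))
  hours <- hours[seq_len(min(30, length(hours)))]
  f <- make_fixes(hours, hours * 100, 0)
  out <- rarefy(f, 7)
  gaps <- as.numeric(diff(out$time), units = "hours")
  # all gaps between consecutive retained fixes round to 7 h at 15 min,
  # except across data holes where the chain restarts
  expect_true(all(abs(gaps - 7) <= 0.125 | gaps > 7.125))

  # dynamic-programming oracle: longest subsequence from the first fix
  # whose successive gaps all round to 7 h
  n <- length(hours)
  best_len <- integer(n); best_len[1] <- 1
  for (i in 2:n) {
    best_len[i] <- 1
    for (j in 1:(i - 1)) {
      if (best_len[j] > 0 && abs(hours[i] - hours[j] - 7) <= 0.125) {
        best_len[i] <- max(best_len[i], best_len[j] + 1)
      }
    }
  }
  kept_chain <- sum(abs(gaps - 7) <= 0.125) + 1
  expect_equal(kept_chain, max(best_len))
})

test_that("rarefaction and burst extraction are idempotent", {
  st <- test_landscape()
  f <- simulate_track(track_spec(duration_days = 12, missingness = 0.08,
                                 seed = 3), st)$fixes
  f <- drop_fixes(f, 0.08, seed = 4)
  r1 <- rarefy(f, 2)
  expect_equal(rarefy(r1, 2)$time, r1$time)
  b1 <- extract_bursts(r1)
  flat <- do.call(rbind, lapply(b1, function(b) {
    data.frame(id = attr(b, "id"), time = b$time, x = b$x, y = b$y,
               source = b$source, missing = !b$observed)
  }))
  b2 <- extract_bursts(flat)
  expect_equal(length(b2), length(b1))
  expect_equal(b2[[1]]$x, b1[[1]]$x)
})

test_that("burst extraction enforces the 8-day and 4-missed-fix rules", {
  # 10 complete days -> one burst of 10 days
  n <- 10 * 12 + 1
  f <- make_fixes(seq(0, by = 2, length.out = n), seq_len(n), 0)
  b <- extract_bursts(f)
  expect_length(b, 1)
  expect_equal(as.numeric(difftime(max(b[[1]]$time), min(b[[1]]$time),
                                   units = "days")), 10)

  # 20 days with a 12-h hole (6 missing slots) at day 10 -> two halves
  hrs <- seq(0, by = 2, length.out = 20 * 12 + 1)
  keep <- !(hrs > 240 & hrs < 252)
  f <- make_fixes(hrs[keep], seq_along(hrs[keep]), 0)
  b <- extract_bursts(f)
  expect_length(b, 2)
  spans <- vapply(b, function(bb)
    as.numeric(difftime(max(bb$time), min(bb$time), units = "days")), 0)
  expect_true(all(spans >= 8))

  # 7 complete days -> nothing
  n <- 7 * 12 + 1
  f <- make_fixes(seq(0, by = 2, length.out = n), seq_len(n), 0)
  expect_length(extract_bursts(f), 0)

  # gaps of up to 4 missing slots stay within one burst
  hrs <- seq(0, by = 2, length.out = 10 * 12 + 1)
  keep <- !(hrs %in% c(50, 52, 54, 56))  # 4 consecutive missing
  f <- make_fixes(hrs[keep], seq_along(hrs[keep]), 0)
  b <- extract_bursts(f)
  expect_length(b, 1)
  expect_equal(sum(!b[[1]]$observed), 4)
})

test_that("the sum of burst durations never exceeds the monitored span", {
  st <- test_landscape()
  f <- simulate_track(track_spec(duration_days = 25, missingness = 0.1,
                                 seed = 9), st)$fixes
  f <- drop_fixes(f, 0.1, seed = 10)
  b <- extract_bursts(rarefy(f, 2))
  span <- as.numeric(difftime(max(f$time), min(f$time), units = "days"))
  total <- sum(vapply(b, function(bb)
    as.numeric(difftime(max(bb$time), min(bb$time), units = "days")), 0))
  expect_lte(total, span + 1e-9)
})

test_that("step geometry follows the stated conventions", {
  # collinear km-spaced fixes: 1000 m steps, zero turning angle
  b <- make_burst(c(0, 1000, 2000), c(0, 0, 0))
  s <- steps_from_burst(b)
  expect_equal(s$length, c(1000, 1000))
  expect_true(is.na(s$turn[1]))
  expect_equal(s$turn[2], 0)

  # east then north: left turn of +pi/2
  b <- make_burst(c(0, 1000, 1000), c(0, 0, 1000))
  s <- steps_from_burst(b)
  expect_equal(s$turn[2], pi / 2)

  # turning angle after a zero-length step is undefined
  b <- make_burst(c(0, 1000, 1000, 2000), c(0, 0, 0, 0))
  s <- steps_from_burst(b)
  expect_equal(s$length[2], 0)
  expect_true(is.na(s$turn[3]))

  # imputed involvement flags both adjacent steps
  b <- make_burst(c(0, 1000, 2000), c(0, 0, 0))
  b$source[2] <- "imputed"
  s <- steps_from_burst(b)
  expect_true(all(s$imputed))
})

test_that("turning angles agree with an independent complex-argument computation", {
  set.seed(3)
  x <- cumsum(rnorm(50, 0, 200)); y <- cumsum(rnorm(50, 0, 200))
  s <- steps_from_burst(make_burst(x, y))
  z <- complex(real = diff(x), imaginary = diff(y))
  oracle <- Arg(z[-1] / z[-length(z)])
  expect_equal(s$turn[-1], oracle, tolerance = 1e-12)
})

test_that("net squared displacement starts at zero and measures squared distance", {
  f <- make_fixes(c(0, 2), c(0, 0), c(0, 3000))
  nsd <- net_squared_displacement(f)
  expect_equal(nsd$nsd, c(0, 9e6))
  expect_error(net_squared_displacement(f[0, ]), "at least one")
})

test_that("a transient's NSD shows a strong monotone trend", {
  set.seed(11)
  n <- 200
  # directed dispersal with noise (simulation oracle for transience)
  x <- cumsum(rnorm(n, 300, 200)); y <- cumsum(rnorm(n, 150, 200))
  f <- make_fixes(seq(0, by = 2, length.out = n), x, y)
  nsd <- net_squared_displacement(f)
  rho <- stats::cor(seq_len(n), nsd$nsd, method = "spearman")
  expect_gt(rho, 0.9)
})
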