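# Shared fixture builders and independent oracles. Oracles here are
# deliberately naive (enumeration, brute force) and never call the code
# paths they check.

t0_utc <- as.POSIXct("2014-06-01 00:00:00", tz = "UTC")

# Build a burst object directly from coordinates.
make_burst <- function(x, y, interval_h = 2, start = t0_utc,
                       observed = rep(TRUE, length(x)), id = "T01") {
  b <- data.frame(slot = seq_along(x) - 1,
                  time = start + (seq_along(x) - 1) * interval_h * 3600,
                  x = x, y = y, observed = observed,
                  source = ifelse(observed, "observed", "missing"),
                  stringsAsFactors = FALSE)
  b$x[!observed] <- NA_real_
  b$y[!observed] <- NA_real_
  attr(b, "id") <- id
  attr(b, "interval_h") <- interval_h
  class(b) <- c("burst", "data.frame")
  b
}

# Build a fix table from times (hours offset) and coordinates.
make_fixes <- function(hours, x, y, id = "T01", start = t0_utc) {
  data.frame(id = id, time = start + hours * 3600, x = x, y = y,
             source = "observed", missing = FALSE,
             stringsAsFactors = FALSE)
}

# Direct simulation from the HMM generative model (Markov chain +
# gamma/wrapped-Cauchy emissions), independent of simulate_track's
# spatial bookkeeping.
sim_hmm_steps <- function(n, mean, sd, rho, m = rep(0, length(mean)),
                          Gamma = NULL, delta = NULL, seed = 1) {
  N <- length(mean)
  if (is.null(Gamma)) {
    Gamma <- matrix(0.2 / (N - 1), N, N); diag(Gamma) <- 0.8
  }
  if (is.null(delta)) delta <- rep(1 / N, N)
  set.seed(seed)
  st <- integer(n)
  st[1] <- sample.int(N, 1, prob = delta)
  for (t in 2:n) st[t] <- sample.int(N, 1, prob = Gamma[st[t - 1], ])
  len <- rgamma(n, shape = (mean[st] / sd[st])^2,
                scale = sd[st]^2 / mean[st])
  turn <- vapply(seq_len(n), function(t) rwrappedcauchy(1, m[st[t]],
                                                        rho[st[t]]), 0)
  steps <- data.frame(length = len, turn = turn, imputed = FALSE)
  steps$turn[1] <- NA  # first step has no defined turning angle
  list(steps = steps, states = st)
}

# Exhaustive-path HMM oracles (N^T enumeration).
enum_paths <- function(N, T) {
  as.matrix(expand.grid(rep(list(seq_len(N)), T)))
}

enum_logjoint <- function(logB, Gamma, delta) {
  N <- ncol(logB); T <- nrow(logB)
  paths <- enum_paths(N, T)
  lp <- numeric(nrow(paths))
  for (r in seq_len(nrow(paths))) {
    p <- paths[r, ]
    v <- log(delta[p[1]]) + logB[1, p[1]]
    if (T > 1) for (t in 2:T) {
      v <- v + log(Gamma[p[t - 1], p[t]]) + logB[t, p[t]]
    }
    lp[r] <- v
  }
  list(paths = paths, logp = lp)
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

enum_forward <- function(logB, Gamma, delta) {
  logsumexp(enum_logjoint(logB, Gamma, delta)$logp)
}

enum_viterbi <- function(logB, Gamma, delta) {
  e <- enum_logjoint(logB, Gamma, delta)
  e$paths[which.max(e$logp), ]
}

enum_posteriors <- function(logB, Gamma, delta) {
  e <- enum_logjoint(logB, Gamma, delta)
  w <- exp(e$logp - logsumexp(e$logp))
  T <- ncol(e$paths); N <- ncol(logB)
  out <- matrix(0, T, N)
  for (t in seq_len(T)) for (j in seq_len(N)) {
    out[t, j] <- sum(w[e$paths[, t] == j])
  }
  out
}

# A small well-conditioned test model.
toy_model <- function(N = 2) {
  if (N == 1) {
    Gamma <- matrix(1, 1, 1)
  } else {
    Gamma <- matrix(0.2 / (N - 1), N, N); diag(Gamma) <- 0.8
  }
  carnmove:::new_movement_model(
    mean = c(20, 300, 1200, 2500)[seq_len(N)],
    sd = c(15, 200, 900, 1500)[seq_len(N)],
    turn_m = rep(0, N),
    turn_rho = seq(0.1, 0.7, length.out = N),
    Gamma = Gamma, delta = rep(1 / N, N))
}

# Published per-behavior location counts by season and light period
# (behavior columns: encamped, foraging, traveling); the worked-example
# input for the time-budget module.
budget_counts <- function() {
  list(
    snow_free = rbind(diurnal = c(1032, 1165, 1065),
                      crepuscular = c(658, 826, 1100),
                      nocturnal = c(698, 596, 645)),
    snow = rbind(diurnal = c(274, 258, 333),
                 crepuscular = c(295, 189, 214),
                 nocturnal = c(251, 130, 125)))
}

budget_published_proportions <- function() {
  list(
    snow_free = rbind(diurnal = c(0.32, 0.36, 0.33),
                      crepuscular = c(0.25, 0.32, 0.43),
                      nocturnal = c(0.36, 0.31, 0.33)),
    snow = rbind(diurnal = c(0.32, 0.30, 0.38),
                 crepuscular = c(0.42, 0.27, 0.31),
                 nocturnal = c(0.50, 0.26, 0.25)))
}

# Simple landscape used across tests.
test_landscape <- function(size = 96, cell = 30, seed = 11, ...) {
  make_landscape(landscape_spec(size = size, cell = cell, seed = seed, ...))
}

# Independent oracle: joint Gaussian density of the observed positions
# under the integrated OU model, built from the state-space recursions
# as one big multivariate normal (no Kalman filtering involved).
direct_ou_loglik <- function(times, z, beta, sigma, tau, prior_mean,
                             prior_var) {
  n <- length(times)
  sys <- function(dt) {
    phi <- exp(-beta * dt)
    list(F = matrix(c(1, 0, (1 - phi) / beta, phi), 2, 2),
         Q = matrix(c(sigma^2 / beta^2 * (2 * beta * dt - 3 + 4 * phi - phi^2),
                      sigma^2 / beta * (1 - phi)^2,
                      sigma^2 / beta * (1 - phi)^2,
                      sigma^2 * (1 - phi^2)), 2, 2))
  }
  V <- vector("list", n)   # Var(s_k)
  V[[1]] <- diag(c(prior_var, sigma^2))
  Fs <- vector("list", n)
  for (k in 2:n) {
    s <- sys(times[k] - times[k - 1])
    Fs[[k]] <- s$F
    V[[k]] <- s$F %*% V[[k - 1]] %*% t(s$F) + s$Q
  }
  C <- matrix(0, n, n)
  for (i in 1:n) {
    C[i, i] <- V[[i]][1, 1] + tau^2
    if (i < n) {
      Cik <- V[[i]]
      for (l in (i + 1):n) {
        Cik <- Cik %*% t(Fs[[l]])
        C[i, l] <- C[l, i] <- Cik[1, 1]
      }
    }
  }
  mu <- rep(prior_mean, n)
  r <- z - mu
  -0.5 * (n * log(2 * pi) + determinant(C)$modulus[1] +
            sum(r * solve(C, r)))
}


# Simulate an integrated-OU track (positions only) on a regular grid;
# generator independent of the package's filtering code.
sim_ou_positions <- function(n, dt, beta, sigma, tau, seed) {
  set.seed(seed)
  x <- 0; v <- rnorm(1, 0, sigma)
  phi <- exp(-beta * dt)
  Q <- matrix(c(sigma^2 / beta^2 * (2 * beta * dt - 3 + 4 * phi - phi^2),
                sigma^2 / beta * (1 - phi)^2,
                sigma^2 / beta * (1 - phi)^2,
                sigma^2 * (1 - phi^2)), 2, 2)
  L <- chol(Q)
  out <- numeric(n)
  out[1] <- x
  for (k in 2:n) {
    e <- as.vector(t(L) %*% rnorm(2))
    xn <- x + v * (1 - phi) / beta + e[1]
    v <- v * phi + e[2]
    x <- xn
    out[k] <- x
  }
  out + rnorm(n, 0, tau)
}
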