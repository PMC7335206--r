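# Shared fixtures and independent oracles for the test suite.
# Oracles deliberately avoid the package's spectral-propagator code path:
# the likelihood oracle uses scaling-and-squaring matrix exponentials
# (Matrix::expm) and the Viterbi oracle enumerates all state sequences.

channels3 <- c("D", "A1", "A2")

# brute-force log-likelihood via Matrix::expm, with renormalization
oracle_loglik <- function(photons, model) {
  chan <- match(photons$channel, model$channels)
  v <- model$p0 * model$emission[, chan[1]]
  logL <- 0
  s <- sum(v)
  v <- v / s
  logL <- logL + log(s)
  if (nrow(photons) > 1) {
    for (i in 2:nrow(photons)) {
      P <- as.matrix(Matrix::expm(model$K * (photons$time[i] - photons$time[i - 1])))
      v <- as.numeric(P %*% v) * model$emission[, chan[i]]
      s <- sum(v)
      v <- v / s
      logL <- logL + log(s)
    }
  }
  logL
}

# exhaustive most-likely-state-sequence search (all ns^N sequences)
oracle_viterbi <- function(photons, model) {
  ns <- length(model$states)
  N <- nrow(photons)
  chan <- match(photons$channel, model$channels)
  Ps <- lapply(seq_len(max(N - 1, 0)), function(i) {
    as.matrix(Matrix::expm(model$K * (photons$time[i + 1] - photons$time[i])))
  })
  best <- -Inf
  best_path <- NULL
  grid <- expand.grid(rep(list(seq_len(ns)), N))
  for (r in seq_len(nrow(grid))) {
    path <- as.integer(grid[r, ])
    lp <- log(model$p0[path[1]]) + log(model$emission[path[1], chan[1]])
    if (N > 1) {
      for (i in 2:N) {
        lp <- lp + log(Ps[[i - 1]][path[i], path[i - 1]]) +
          log(model$emission[path[i], chan[i]])
      }
    }
    if (lp > best) {
      best <- lp
      best_path <- path
    }
  }
  list(path = best_path, logprob = best)
}

# random valid kinetic models for property-style loops
random_linear_model <- function(ns, colors = 3, rate_scale = 1e3) {
  fwd <- runif(ns - 1, 0.2, 1) * rate_scale
  bwd <- runif(ns - 1, 0.2, 1) * rate_scale
  if (colors == 3) {
    e1 <- runif(ns, 0.05, 0.5)
    e2 <- runif(ns, 0.05, 0.9 - e1)
    build_linear_n_state(fwd, bwd, e1, e2)
  } else {
    build_linear_n_state(fwd, bwd, runif(ns, 0.05, 0.95))
  }
}

random_photons <- function(N, model, span = 5e-3) {
  times <- sort(runif(N, 0, span))
  tibble::tibble(time = times, channel = recolor(times, model))
}

# every model family at generic parameter values, for oracle sweeps
all_family_models <- function(n = 80) {
  list(
    folding_2c = build_folding_2c(1.2e3, 0.8e3, 0.8, 0.3),
    folding_3c = build_folding_3c(1.2e3, 0.8e3, c(0.55, 0.25), c(0.25, 0.2)),
    folding_2c_blink = build_folding_2c_blink(1.2e3, 0.8e3, 0.8, 0.3, 0.05,
                                              k_b = 150, k_d0 = 60, n = n),
    folding_3c_blink = {
      tied <- apply_tying(list(eps1_F = 0.55, eps2_F = 0.25, eps1_U = 0.25,
                               eps2_U = 0.2, epsDA1_F = 0.7, epsDA1_U = 0.4,
                               epsDA2_F = 0.45, epsDA2_U = 0.3),
                          "folding_global_blink", l12 = 0.23)
      build_folding_3c_blink(1.2e3, 0.8e3, tied$eps1_3c, tied$eps2_3c,
                             kb1 = 150, kd10 = 60, kb2 = 120, kd20 = 40, n = n)
    },
    binding_3cDA1 = build_binding_3cDA1(2e3, 1e3, 0.85, 3, 2,
                                        c(0.5, 0.3, 0.45), c(0.2, 0.05, 0.03)),
    binding_3cDA1_blink = {
      tied <- apply_tying(list(eps1_Bbb = 0.5, eps2_Bbb = 0.2, eps1_Ubb = 0.3,
                               eps2_Ubb = 0.05, eps1_Bbd = 0.45,
                               epsDA2_B = 0.55, epsDA2_U = 0.04),
                          "binding_global_blink")
      build_binding_3cDA1_blink(2e3, 1e3, 0.85, 3, 2, kb1 = 150, kd10 = 60,
                                kb2 = 120, kd20 = 40, tied$eps1_3c,
                                tied$eps2_3c, n = n)
    },
    binding_DA2 = build_binding_DA2(2e3, 1e3, 0.85, 3, 2, 0.55, 0.04),
    binding_DA2_blink = build_binding_DA2(2e3, 1e3, 0.85, 3, 2, 0.55, 0.04,
                                          with_blinking = TRUE, kb2 = 120,
                                          kd20 = 40, n = n)
  )
}

# all color sequences of length N over the model's channels
all_sequences <- function(N, channels) {
  grid <- expand.grid(rep(list(channels), N), stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(i) unname(unlist(grid[i, ])))
}

# forward-distort ideal count rates exactly as the correction chain inverts:
# ideal -> + direct excitation -> + leak -> + background; returns raw
# fractions and the total rate (per ms)
forward_distort_rates <- function(E, factors, n_total = 100) {
  g1 <- factors$gamma1
  g2 <- factors$gamma2
  x1 <- g1 * (1 - E[["E12"]]) * E[["E1"]] / (1 - E[["E1"]])
  x2 <- g2 * (E[["E12"]] * E[["E1"]] / (1 - E[["E1"]]) + E[["E2"]] / (1 - E[["E2"]]))
  nD <- 1
  nA1 <- x1
  nA2 <- x2
  kex <- nA1 / g1 + nA2 / g2 + nD
  nA1 <- nA1 + g1 * kex * factors$f1dir * (1 - E[["E12"]])
  nA2 <- nA2 + g2 * kex * (factors$f1dir * E[["E12"]] + factors$f2dir)
  A1 <- (1 - factors$l12) * nA1 + factors$l1 * nD
  A2 <- factors$l12 * nA1 + nA2 + factors$l2 * nD
  D <- (1 - factors$l1 - factors$l2) * nD
  sc <- n_total / (A1 + A2 + D)
  D <- D * sc + factors$b_D
  A1 <- A1 * sc + factors$b_A1
  A2 <- A2 * sc + factors$b_A2
  n <- D + A1 + A2
  list(eps1 = A1 / n, eps2 = A2 / n, n = n)
}
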