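test_that("hand-computable likelihood values are reproduced", {
  # single acceptor photon, 2 states: L = eps_F p_F + eps_U (1 - p_F)
  m <- build_folding_2c(1.5e3, 1e3, 0.8, 0.4)  # p_F = 0.6
  ph <- tibble::tibble(time = 1e-3, channel = "A1")
  expect_equal(segment_loglik(ph, m)$loglik, log(0.8 * 0.6 + 0.4 * 0.4),
               tolerance = 1e-12)

  # indistinguishable states: i.i.d. coin, L = 0.5^N regardless of K
  m2 <- build_folding_2c(3e3, 0.5e3, 0.5, 0.5)
  ph4 <- tibble::tibble(time = c(1, 2, 5, 9) * 1e-3,
                        channel = c("A1", "D", "A1", "A1"))
  expect_equal(segment_loglik(ph4, m2)$loglik, 4 * log(0.5), tolerance = 1e-12)

  # empty trajectory: ln L = 0
  expect_equal(segment_loglik(ph4[0, ], m2)$loglik, 0)

  # incompatible channels error
  ph_a2 <- tibble::tibble(time = 1e-3, channel = "A2")
  expect_error(segment_loglik(ph_a2, m2), "A2")
})

test_that("spectral evaluation matches the matrix-exponential oracle", {
  skip_if_not_installed("Matrix")
  set.seed(7)
  m3 <- random_linear_model(3)
  ph <- random_photons(5, m3)
  expect_equal(segment_loglik(ph, m3)$loglik, oracle_loglik(ph, m3),
               tolerance = 1e-10)

  # all families, 1000-photon trajectories
  for (m in all_family_models()) {
    ph <- random_photons(1000, m, span = 0.5)
    expect_equal(segment_loglik(ph, m)$loglik, oracle_loglik(ph, m),
                 tolerance = 1e-8)
  }
})

test_that("likelihood is normalized over all color sequences", {
  set.seed(21)
  for (rep in 1:3) {
    m2 <- random_linear_model(2, colors = 2)
    times <- sort(runif(5, 0, 3e-3))
    tot <- sum(vapply(all_sequences(5, m2$channels), function(sq) {
      exp(segment_loglik(tibble::tibble(time = times, channel = sq), m2)$loglik)
    }, numeric(1)))
    expect_equal(tot, 1, tolerance = 1e-10)
  }
  m3 <- random_linear_model(3, colors = 3)
  times <- sort(runif(4, 0, 3e-3))
  tot <- sum(vapply(all_sequences(4, m3$channels), function(sq) {
    exp(segment_loglik(tibble::tibble(time = times, channel = sq), m3)$loglik)
  }, numeric(1)))
  expect_equal(tot, 1, tolerance = 1e-10)
})

test_that("long gaps factorize the likelihood into stationary terms", {
  m <- build_folding_3c(1e3, 0.7e3, c(0.55, 0.25), c(0.25, 0.2))
  # gaps with dt * k >= 40: photons decouple
  times <- cumsum(rep(0.05, 12))  # dt * k = 50
  set.seed(3)
  chans <- sample(m$channels, 12, replace = TRUE)
  ph <- tibble::tibble(time = times, channel = chans)
  indep <- sum(log(vapply(chans, function(c) {
    sum(m$emission[, c] * m$p0)
  }, numeric(1))))
  expect_equal(segment_loglik(ph, m)$loglik, indep, tolerance = 1e-10)
})

test_that("renormalized recursion equals the naive product on short data", {
  m <- build_folding_3c(1.5e3, 1e3, c(0.5, 0.2), c(0.25, 0.3))
  set.seed(5)
  ph <- random_photons(40, m)
  chan <- match(ph$channel, m$channels)
  sp <- eigen(m$K)
  v <- m$p0 * m$emission[, chan[1]]
  for (i in 2:40) {
    P <- Re(sp$vectors %*% diag(exp(sp$values * (ph$time[i] - ph$time[i - 1]))) %*%
              solve(sp$vectors))
    v <- as.numeric(P %*% v) * m$emission[, chan[i]]
  }
  expect_equal(segment_loglik(ph, m)$loglik, log(sum(v)), tolerance = 1e-10)
})

test_that("chunked partial products are split-invariant", {
  m <- all_family_models()$binding_3cDA1
  set.seed(9)
  ph <- random_photons(300, m, span = 0.1)
  ref <- segment_loglik(ph, m)$loglik
  expect_equal(partial_products(ph, m, 1)$loglik, ref, tolerance = 1e-9)
  expect_equal(partial_products(ph, m, nrow(ph))$loglik, ref, tolerance = 1e-9)
  for (nc in c(2, 7, 33)) {
    expect_equal(partial_products(ph, m, nc)$loglik, ref, tolerance = 1e-9)
  }
})

test_that("global likelihood sums classes and is order-invariant", {
  model3c <- build_folding_3c(2e3, 1e3, c(0.55, 0.25), c(0.25, 0.2))
  d <- simulate_photons(model3c, 60, 0.05, n_trajectories = 2, class = "3c",
                        seed = 14)
  par <- list(k = 3e3, p_F = 2 / 3, eps1_F = 0.55, eps2_F = 0.25,
              eps1_U = 0.25, eps2_U = 0.2)
  # one segment: equals segment_loglik
  one <- d$photons[d$photons$trajectory_id == d$photons$trajectory_id[1], ]
  d1 <- fret_data(one, kind = "folding")
  expect_equal(global_loglik(d1, par, "folding_3c")$loglik,
               segment_loglik(one, model3c)$loglik)
  # permuting trajectory order leaves the sum unchanged
  perm <- fret_data(d$photons[rev(seq_len(nrow(d$photons))), ] |>
                      dplyr::arrange(factor(trajectory_id,
                                            levels = rev(unique(trajectory_id))),
                                     time),
                    kind = "folding")
  expect_equal(global_loglik(perm, par, "folding_3c")$loglik,
               global_loglik(d, par, "folding_3c")$loglik)
  # class not covered by the family errors
  expect_error(global_loglik(d, par, "folding_2c"), "3c")
})

test_that("blinking family with vanishing dark rates matches its no-blink limit", {
  model3c <- build_folding_3c(2e3, 1e3, c(0.55, 0.25), c(0.25, 0.2))
  da1 <- build_folding_2c(2e3, 1e3, 0.7, 0.4, "A1")
  d3 <- simulate_photons(model3c, 70, 0.04, class = "3c", seed = 31)
  dda1 <- simulate_photons(da1, 50, 0.04, class = "DA1", seed = 32,
                           id_prefix = "da1_")
  dda1$photons$channel[dda1$photons$channel == "A1"] <-
    sample(c("A1", "A2"), sum(dda1$photons$channel == "A1"), TRUE, c(0.8, 0.2))
  da2 <- build_folding_2c(2e3, 1e3, 0.45, 0.3, "A2")
  dda2 <- simulate_photons(da2, 50, 0.04, class = "DA2", seed = 33,
                           id_prefix = "da2_")
  all <- fret_data(dplyr::bind_rows(d3$photons, dda1$photons, dda2$photons),
                   kind = "folding")
  base <- list(k = 3e3, p_F = 2 / 3, eps1_F = 0.55, eps2_F = 0.25,
               eps1_U = 0.25, eps2_U = 0.2, epsDA1_F = 0.7, epsDA1_U = 0.4,
               epsDA2_F = 0.45, epsDA2_U = 0.3)
  plain <- global_loglik(all, base, "folding_global")
  blink0 <- global_loglik(all, c(base, list(kb1 = 100, kd10 = 0, kb2 = 100,
                                            kd20 = 0)),
                          "folding_global_blink")
  expect_equal(blink0$loglik, plain$loglik, tolerance = 1e-10)
  expect_equal(plain$n_photons, nrow(all$photons))
})
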