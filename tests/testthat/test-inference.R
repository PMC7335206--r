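test_that("simulated kinetics are recovered within their uncertainties", {
  set.seed(101)
  k <- 1e3   # 1 per ms
  pF <- 0.6
  model <- build_folding_3c(k * pF, k * (1 - pF), c(0.55, 0.25), c(0.25, 0.2))
  d <- simulate_photons(model, 80, 0.5, class = "3c", seed = 102)  # ~4e4 photons
  init <- list(k = 2e3, p_F = 0.5, eps1_F = 0.5, eps2_F = 0.3,
               eps1_U = 0.3, eps2_U = 0.25)
  fit <- fit_ml(d, "folding_3c", init)
  expect_true(fit$converged)
  # maximization: at least as good as the truth
  truth <- list(k = k, p_F = pF, eps1_F = 0.55, eps2_F = 0.25,
                eps1_U = 0.25, eps2_U = 0.2)
  expect_gte(fit$max_loglik, global_loglik(d, truth, "folding_3c")$loglik - 1e-6)
  fit <- error_bars(d, NULL, fit)
  expect_true(all(is.finite(fit$std_devs)))
  expect_lt(abs(fit$estimates[["k"]] - k), 3 * fit$std_devs[["k"]])
  expect_lt(abs(fit$estimates[["p_F"]] - pF), 3 * fit$std_devs[["p_F"]])
  # optimum value is transform-independent: re-evaluating the likelihood at
  # the natural-unit estimates reproduces max_loglik
  expect_equal(global_loglik(d, as.list(fit$estimates), "folding_3c")$loglik,
               fit$max_loglik, tolerance = 1e-9)
  # tidy/glance accessors
  td <- tidy(fit)
  expect_equal(names(td), c("term", "estimate", "std.error"))
  expect_equal(nrow(td), 6)
  expect_true(glance(fit)$converged)
})

test_that("initialization at the truth can only improve the likelihood", {
  model <- build_folding_2c(1.5e3, 1e3, 0.8, 0.3)
  d <- simulate_photons(model, 60, 0.2, class = "DA1", seed = 44)
  truth <- list(k = 2.5e3, p_F = 0.6, eps_F = 0.8, eps_U = 0.3)
  fit <- fit_ml(d, "folding_2c", truth, options = list(restarts = 1))
  expect_gte(fit$max_loglik, global_loglik(d, truth, "folding_2c")$loglik - 1e-9)
})

test_that("degenerate one-color data pushes fractions to a flagged boundary", {
  ph <- tibble::tibble(trajectory_id = "t", class = "DA1",
                       time = sort(runif(300, 0, 0.01)),
                       channel = rep("A1", 300))
  d <- fret_data(ph, kind = "folding")
  fit <- fit_ml(d, "folding_2c",
                list(k = 1e3, p_F = 0.5, eps_F = 0.9, eps_U = 0.8),
                options = list(restarts = 1, maxit = 2000))
  expect_true(any(fit$boundary[c("eps_F", "eps_U")]))
  expect_true(all(is.na(fit$std_devs[fit$boundary])))
})

test_that("curvature uncertainties match the binomial closed form", {
  # no dynamics, indistinguishable states: eps from N two-color photons is a
  # binomial proportion with sd sqrt(eps (1 - eps) / N)
  set.seed(55)
  N <- 5000
  eps_true <- 0.35
  ph <- tibble::tibble(trajectory_id = "t", class = "DA1",
                       time = sort(runif(N, 0, 0.05)),
                       channel = sample(c("A1", "D"), N, TRUE,
                                        c(eps_true, 1 - eps_true)))
  d <- fret_data(ph, kind = "folding")
  fam <- fret_family("static_2c")
  fit <- fit_ml(d, fam, list(eps = 0.5), options = list(restarts = 1))
  fit <- error_bars(d, fam, fit)
  eps_hat <- mean(ph$channel == "A1")
  expect_equal(fit$estimates[["eps"]], eps_hat, tolerance = 1e-4)
  sd_ref <- sqrt(eps_hat * (1 - eps_hat) / N)
  expect_lt(abs(fit$std_devs[["eps"]] / sd_ref - 1), 0.05)

  # Fisher scaling: doubling the data shrinks sd(k) by ~1/sqrt(2)
  model <- build_folding_3c(1.5e3, 1e3, c(0.55, 0.25), c(0.25, 0.2))
  d1 <- simulate_photons(model, 80, 0.25, class = "3c", seed = 66)
  d2big <- simulate_photons(model, 80, 0.5, class = "3c", seed = 66)
  init <- list(k = 2.5e3, p_F = 0.6, eps1_F = 0.55, eps2_F = 0.25,
               eps1_U = 0.25, eps2_U = 0.2)
  f1 <- error_bars(d1, NULL, fit_ml(d1, "folding_3c", init,
                                    options = list(restarts = 1)))
  f2 <- error_bars(d2big, NULL, fit_ml(d2big, "folding_3c", init,
                                       options = list(restarts = 1)))
  ratio <- f2$std_devs[["k"]] / f1$std_devs[["k"]]
  expect_lt(abs(ratio - 1 / sqrt(2)), 0.25)
})

test_that("flat directions are flagged rather than propagated as NaN", {
  # two exchangeable states with identical fractions leave k nearly flat
  ph <- tibble::tibble(trajectory_id = "t", class = "DA1",
                       time = sort(runif(400, 0, 0.01)),
                       channel = sample(c("A1", "D"), 400, TRUE))
  d <- fret_data(ph, kind = "folding")
  fit <- fit_ml(d, "folding_2c",
                list(k = 1e3, p_F = 0.5, eps_F = 0.5, eps_U = 0.5),
                options = list(restarts = 1, maxit = 3000))
  fit$converged <- TRUE  # force error-bar computation on the stalled fit
  out <- error_bars(d, NULL, fit)
  expect_false(any(is.nan(out$std_devs)))
})

test_that("BIC ranking penalizes parameters and respects the data", {
  f1 <- structure(list(max_loglik = -1000, bic = 2000 + 14 * log(5000),
                       n_photons = 5000,
                       family = fret_family("folding_global_blink")),
                  class = "fret_fit")
  f2 <- structure(list(max_loglik = -1000, bic = 2000 + 16 * log(5000),
                       n_photons = 5000,
                       family = fret_family("binding_global_blink")),
                  class = "fret_fit")
  tab <- compare_bic(list(f1, f2))
  expect_equal(tab$model[1], "folding_global_blink")  # smaller P wins
  expect_equal(tab$delta_bic[1], 0)
  expect_equal(nrow(compare_bic(f1)), 1)
  f3 <- f2
  f3$n_photons <- 4999
  expect_error(compare_bic(list(f1, f3)), "different data")
})
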