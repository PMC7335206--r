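alpha3d_factors <- function(n = NULL) {
  correction_factors(b_D = 1, b_A1 = 0.8, b_A2 = 0.6,
                     l1 = 0.051, l2 = 0.001, l12 = 0.23,
                     f1dir = 0.067, f2dir = 0.072,
                     gamma1 = 1.51, gamma2 = 0.75, n = n)
}

test_that("background correction matches the subtraction formulas", {
  f <- correction_factors(b_A = 1, b_D = 1, n = 102)
  expect_equal(correct_background(0.5, f, "2c"), 0.5)
  f0 <- correction_factors(n = 90)
  expect_equal(correct_background(0.37, f0, "2c"), 0.37)  # zero background: identity
  f3 <- correction_factors(b_D = 10, b_A1 = 10, b_A2 = 10, n = 90)
  out <- correct_background(list(eps1 = 1 / 3, eps2 = 1 / 3), f3, "3c")
  expect_equal(out$eps1, 1 / 3)
  expect_equal(out$eps2, 1 / 3)
  expect_error(correct_background(0.5, correction_factors(b_A = 60, b_D = 50,
                                                          n = 100), "2c"),
               "background")
})

test_that("donor-leak correction inverts the forward leak model exactly", {
  f <- correction_factors(l = 0.07)
  expect_equal(correct_donor_leak(0.07, f, "2c"), 0)  # pure-donor corrects to 0
  expect_equal(correct_donor_leak(0.5, correction_factors(), "2c"), 0.5)

  # three-color with the folding coefficients: distort ideal rates by the
  # forward leak model, correct, recover to 1e-12
  f3 <- alpha3d_factors()
  ideal <- list(nD = 0.45, nA1 = 0.35, nA2 = 0.2)
  A1 <- (1 - f3$l12) * ideal$nA1 + f3$l1 * ideal$nD
  A2 <- f3$l12 * ideal$nA1 + ideal$nA2 + f3$l2 * ideal$nD
  D <- (1 - f3$l1 - f3$l2) * ideal$nD
  tot <- A1 + A2 + D
  out <- correct_donor_leak(list(eps1 = A1 / tot, eps2 = A2 / tot), f3, "3c")
  # corrected fractions are over the corrected total
  tot_c <- with(ideal, nD + nA1 + nA2)
  expect_equal(out$eps1, ideal$nA1 / tot_c, tolerance = 1e-12)
  expect_equal(out$eps2, ideal$nA2 / tot_c, tolerance = 1e-12)
  expect_error(correct_donor_leak(list(eps1 = 0.3, eps2 = 0.3),
                                  correction_factors(l1 = 0.6, l2 = 0.5),
                                  "3c"),
               "positive")
})

test_that("direct-excitation correction inverts its forward model", {
  # 2c round trip: n_A -> n_A + (n_A + gamma n_D) f
  f <- correction_factors(fdir = 0.06, gamma = 1.3)
  epsc <- 0.42
  nD <- 1 - epsc
  nA <- epsc + (epsc + 1.3 * (1 - epsc)) * 0.06
  eps_raw <- nA / (nA + nD)
  expect_equal(correct_direct_excitation(eps_raw, f, mode = "2c"), epsc,
               tolerance = 1e-12)
  expect_equal(correct_direct_excitation(0.42, correction_factors(), mode = "2c"),
               0.42)
})

test_that("fraction/efficiency conversions agree across all three anchors", {
  fr <- fractions_from_efficiencies(0.8, 0.2, 0.5)
  expect_equal(fr$eps1, 8 / 21, tolerance = 1e-12)
  expect_equal(fr$eps2, 9 / 21, tolerance = 1e-12)
  e12 <- efficiencies_from_fractions(fr$eps1, fr$eps2, 1, 1, "E12", 0.5)
  expect_equal(c(e12$E1, e12$E2), c(0.8, 0.2), tolerance = 1e-12)
  e1 <- efficiencies_from_fractions(fr$eps1, fr$eps2, 1, 1, "E1", 0.8)
  expect_equal(c(e1$E2, e1$E12), c(0.2, 0.5), tolerance = 1e-12)
  e2 <- efficiencies_from_fractions(fr$eps1, fr$eps2, 1, 1, "E2", 0.2)
  expect_equal(c(e2$E1, e2$E12), c(0.8, 0.5), tolerance = 1e-12)

  expect_equal(fractions_from_efficiencies(0, 0, 0)$eps1, 0)
  expect_error(fractions_from_efficiencies(1, 0.2, 0.5), "< 1")

  # random triplets round-trip through every anchor
  set.seed(8)
  for (i in 1:50) {
    E <- c(E1 = runif(1, 0.05, 0.9), E2 = runif(1, 0.05, 0.9),
           E12 = runif(1, 0.05, 0.9))
    g1 <- runif(1, 0.5, 2)
    g2 <- runif(1, 0.5, 2)
    fr <- fractions_from_efficiencies(E[1], E[2], E[3], g1, g2)
    for (a in c("E12", "E1", "E2")) {
      got <- efficiencies_from_fractions(fr$eps1, fr$eps2, g1, g2, a,
                                         unname(E[a]))
      expect_equal(c(got$E1, got$E2, got$E12), unname(E), tolerance = 1e-10)
    }
  }
})

test_that("two-color efficiency formula is exact, monotone, and gamma-aware", {
  expect_equal(two_color_E(0.6, 1), 0.6)
  expect_equal(two_color_E(0, 2), 0)
  expect_equal(two_color_E(1, 2), 1)
  expect_equal(two_color_E(0.6, 1.51), 0.6 / (0.6 + 1.51 * 0.4),
               tolerance = 1e-12)
  eps <- seq(0.01, 0.99, by = 0.01)
  expect_true(all(diff(two_color_E(eps, 0.75)) > 0))
  expect_true(all(diff(two_color_E(eps, 1.51)) > 0))
})

test_that("iterative conversion recovers the generating triplet", {
  f <- alpha3d_factors()
  E <- c(E1 = 0.6, E2 = 0.35, E12 = 0.45)
  raw <- forward_distort_rates(E, f, n_total = 100)
  f$n <- raw$n
  res <- correct_fractions_3c(raw$eps1, raw$eps2, f, "E2", E[["E2"]])
  expect_equal(res$efficiencies$E1, E[["E1"]], tolerance = 1e-8)
  expect_equal(res$efficiencies$E12, E[["E12"]], tolerance = 1e-8)
  expect_lte(res$iterations, 100)

  # no direct excitation: converges immediately to the non-iterative result
  f0 <- correction_factors(gamma1 = 1.51, gamma2 = 0.75)
  fr <- fractions_from_efficiencies(E[1], E[2], E[3], 1.51, 0.75)
  r0 <- iterate_3c_conversion(fr$eps1, fr$eps2, f0, "E2", E[["E2"]])
  expect_equal(r0$iterations, 1)
  expect_equal(r0$efficiencies$E1, E[["E1"]], tolerance = 1e-10)
})

test_that("anchor conditioning degrades as the anchored pathway weakens", {
  # sensitivity of E2 to eps under the E1 anchor grows as E2 -> 0: the
  # E1-anchored route becomes ill-conditioned exactly when E2 is low
  g1 <- 1.51
  g2 <- 0.75
  sens <- vapply(c(0.3, 0.15, 0.05, 0.02), function(E2) {
    E <- c(E1 = 0.6, E2 = E2, E12 = 0.45)
    fr <- fractions_from_efficiencies(E[1], E[2], E[3], g1, g2)
    h <- 1e-6
    a <- efficiencies_from_fractions(fr$eps1, fr$eps2 + h, g1, g2, "E1", 0.6)$E2
    b <- efficiencies_from_fractions(fr$eps1, fr$eps2 - h, g1, g2, "E1", 0.6)$E2
    abs(a - b) / (2 * h) / E2  # relative sensitivity
  }, numeric(1))
  expect_true(all(diff(sens) > 0))
})

test_that("correction factors are estimable from calibration data", {
  # donor-only rates (5.1, 0.1, 94.8) per ms give l1 = 0.051
  f <- estimate_correction_factors(donly_rates = list(n_A10 = 5.1, n_A20 = 0.1,
                                                      n_D0 = 94.8))
  expect_equal(f$l1, 0.051)
  expect_equal(f$l2, 0.001)
  # l12 from DA1-segment fractions per its count-rate definition
  fl <- estimate_correction_factors(
    da1_fractions = list(eps1 = 0.60, eps2 = 0.20, n = 100),
    backgrounds = list(b_A1 = 1, b_A2 = 1))
  expect_equal(fl$l12, (100 * 0.20 - 1) / (100 * 0.8 - 2), tolerance = 1e-12)
  # no acceptor signal after donor bleaching: f_dir = 0
  f2 <- estimate_correction_factors(prepost = list(n_A_pre = 40, n_D_pre = 60,
                                                   n_A_post = 0))
  expect_equal(f2$fdir, 0)
  # synthetic acceptor-bleach step with known gamma recovers it exactly
  gam <- 1.51
  nD_pre <- 50
  nA_pre <- 45
  dD <- 30
  f3 <- estimate_correction_factors(gamma_pairs = list(
    n_A_pre = nA_pre, n_A_post = nA_pre - gam * dD,
    n_D_pre = nD_pre, n_D_post = nD_pre + dD))
  expect_equal(f3$gamma, gam, tolerance = 1e-12)
  expect_error(estimate_correction_factors(donly_rates = list(n_A0 = 0, n_D0 = 0)),
               "zero")
})

test_that("out-of-range corrected fractions are clipped with a warning", {
  f <- correction_factors(b_A = 5, b_D = 0, n = 100)
  expect_warning(out <- correct_background(0.04, f, "2c"), "clipped")
  expect_equal(out, 0)
})
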