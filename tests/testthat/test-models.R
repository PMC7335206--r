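model_invariants <- function(m) {
  expect_lt(max(abs(colSums(m$K))), 1e-9 * max(1, max(abs(m$K))))
  offdiag <- m$K - diag(diag(m$K), nrow(m$K))
  expect_true(all(offdiag >= 0))
  expect_true(all(m$p0 >= 0))
  expect_equal(sum(m$p0), 1, tolerance = 1e-10)
  expect_true(all(m$emission >= -1e-12 & m$emission <= 1 + 1e-12))
  expect_equal(unname(rowSums(m$emission)), rep(1, nrow(m$K)), tolerance = 1e-10)
}

test_that("two-state folding builders match the two-state rate algebra", {
  m <- build_folding_2c(1e3, 1e3, 0.8, 0.3)
  expect_equal(unname(m$p0), c(0.5, 0.5))
  m <- build_folding_2c(2e3, 1e3, 0.8, 0.3)
  expect_equal(unname(m$p0[1]), 2 / 3)
  expect_equal(unname(m$K), matrix(c(-1e3, 1e3, 2e3, -2e3), 2, 2))
  model_invariants(m)
  expect_lt(max(abs(m$K %*% m$p0)), 1e-9)
  expect_error(build_folding_2c(-1, 1, 0.5, 0.5), "rates")

  m3 <- build_folding_3c(2e3, 1e3, c(0.3, 0.1), c(0.5, 0.2))
  expect_equal(unname(m3$emission[, "D"]), c(0.2, 0.7))
  model_invariants(m3)
  # eps1 + eps2 = 0 everywhere => donor matrix is the identity
  m0 <- build_folding_3c(1e3, 1e3, c(0, 0), c(0, 0))
  expect_equal(unname(m0$emission[, "D"]), c(1, 1))
  expect_error(build_folding_3c(1e3, 1e3, c(0.6, 0.1), c(0.5, 0.2)), "> 1")
})

test_that("three-state binding generator has the incomplete-labeling structure", {
  # k_B = k_U, phi = 0.5 gives p0 = (0.25, 0.5, 0.25)
  m <- build_binding_3cDA1(1e3, 1e3, 0.5, 3, 2, c(0.5, 0.3, 0.45),
                           c(0.2, 0.05, 0.03))
  expect_equal(unname(m$p0), c(0.25, 0.5, 0.25))
  model_invariants(m)
  # phi = 1, no bleaching: third state unreachable from state 1
  m1 <- build_binding_3cDA1(1e3, 1e3, 1, 3, 0, c(0.5, 0.3, 0.45),
                            c(0.2, 0.05, 0.03))
  expect_equal(m1$K[3, 1], 0)
  expect_equal(m1$K[3, 2], 0)
  expect_lt(max(abs(colSums(m1$K))), 1e-9)
  expect_error(build_binding_3cDA1(1e3, 1e3, 1.2, 3, 2,
                                   c(0.5, 0.3, 0.45), c(0.2, 0.05, 0.03)),
               "phi")
})

test_that("blinking builders scale dark rates with count rate and reduce cleanly", {
  # n = n0 leaves k_d at its reference value
  m <- build_folding_2c_blink(1e3, 1e3, 0.8, 0.3, 0.05, k_b = 100, k_d0 = 60,
                              n = 100)
  expect_equal(m$K[3, 1], 60)
  m2 <- build_folding_2c_blink(1e3, 1e3, 0.8, 0.3, 0.05, k_b = 100, k_d0 = 60,
                               n = 50)
  expect_equal(m2$K[3, 1], 30)
  model_invariants(m)
  expect_lt(max(abs(m$K %*% m$p0)), 1e-9)

  # k_d0 = 0: bright block reduces to the two-state dynamics, p_b = 1
  m0 <- build_folding_2c_blink(2e3, 1e3, 0.8, 0.3, 0.05, k_b = 100, k_d0 = 0,
                               n = 80)
  expect_equal(unname(m0$p0), c(2 / 3, 1 / 3, 0, 0))
  expect_equal(unname(m0$K[1:2, 1:2]),
               unname(build_folding_2c(2e3, 1e3, 0.8, 0.3)$K))

  # eight states for the fully blinking three-color models
  fam8 <- all_family_models()
  expect_equal(length(fam8$folding_3c_blink$states), 8)
  expect_equal(length(fam8$binding_3cDA1_blink$states), 8)
  for (m in fam8) model_invariants(m)
  # folding models are stationary; binding ones need not be
  expect_lt(max(abs(fam8$folding_3c_blink$K %*% fam8$folding_3c_blink$p0)), 1e-7)

  # dark rates -> 0 confines dynamics to the bright-bright block
  tied <- apply_tying(list(eps1_F = 0.55, eps2_F = 0.25, eps1_U = 0.25,
                           eps2_U = 0.2, epsDA1_F = 0.7, epsDA1_U = 0.4,
                           epsDA2_F = 0.45, epsDA2_U = 0.3),
                      "folding_global_blink")
  mb <- build_folding_3c_blink(2e3, 1e3, tied$eps1_3c, tied$eps2_3c,
                               kb1 = 100, kd10 = 0, kb2 = 100, kd20 = 0, n = 80)
  expect_equal(unname(mb$p0[1:2]), c(2 / 3, 1 / 3))
  expect_equal(unname(mb$K[1:2, 1:2]),
               unname(build_folding_3c(2e3, 1e3, c(0.55, 0.25),
                                       c(0.25, 0.2))$K))
})

test_that("DA2 binding model ties dark-state fractions to the unbound state", {
  m <- build_binding_DA2(2e3, 1e3, 0.85, 3, 2, 0.55, 0.04)
  expect_equal(unname(m$emission[, "A2"]), c(0.55, 0.04, 0.04))
  model_invariants(m)
  mb <- build_binding_DA2(2e3, 1e3, 0.85, 3, 2, 0.55, 0.04,
                          with_blinking = TRUE, kb2 = 100, kd20 = 40, n = 80)
  expect_equal(unname(mb$emission[, "A2"]), c(0.55, 0.04, 0.04, 0.04))
  model_invariants(mb)
  # kd2 = 0: fourth state unpopulated
  m0 <- build_binding_DA2(2e3, 1e3, 0.85, 3, 2, 0.55, 0.04,
                          with_blinking = TRUE, kb2 = 100, kd20 = 0, n = 80)
  expect_equal(unname(m0$p0[4]), 0)
})

test_that("linear chain builder reduces, symmetrizes, and solves p_eq", {
  m2 <- build_linear_n_state(2e3, 1e3, c(0.8, 0.3))
  ref <- build_folding_2c(1e3, 2e3, 0.8, 0.3)  # fwd 1->2 is k12; F state first
  expect_equal(unname(m2$p0), c(1 / 3, 2 / 3))
  expect_lt(max(abs(m2$K %*% m2$p0)), 1e-9)
  expect_equal(sort(unname(m2$p0)), sort(unname(ref$p0)))

  m3 <- build_linear_n_state(c(1e3, 1e3), c(1e3, 1e3), c(0.8, 0.5, 0.2))
  expect_equal(unname(m3$p0), rep(1 / 3, 3), tolerance = 1e-12)

  set.seed(42)
  for (i in 1:5) {
    m <- random_linear_model(sample(2:5, 1), colors = sample(2:3, 1))
    model_invariants(m)
    expect_lt(max(abs(m$K %*% m$p0)), 1e-8)
  }
  expect_error(build_linear_n_state(c(1e3, 0), c(1e3, 1e3), c(0.1, 0.5, 0.9)),
               "disconnected")
})

test_that("parameter counts match the model structure after tying", {
  expect_equal(count_free_parameters("folding_global_blink"), 14)
  expect_equal(count_free_parameters("binding_global_blink"), 16)
  expect_equal(count_free_parameters("binding_global"), 12)
  expect_equal(independent_fractions("binding_global"), 5)
  expect_equal(count_free_parameters("folding_global"), 10)
  expect_equal(count_free_parameters("linear_2c", n_states = 3), 7)
  expect_error(count_free_parameters("no_such_family"), "unknown")
})

test_that("apply_tying implements the documented relations", {
  # unbound-state ratio: eps2_Bd = eps1_Bd * (eps2_U / eps1_U)
  p <- apply_tying(list(eps1_Bd = 0.6, eps1_U = 0.3, eps2_U = 0.03),
                   "binding_global")
  expect_equal(p$eps2_Bd, 0.06)
  # and the converse direction reproduces the ratio identity
  p2 <- apply_tying(list(eps1_Bd = 0.6, eps2_Bd = 0.06, eps1_U = 0.3),
                    "binding_global")
  expect_equal(p2$eps2_U / p2$eps1_U, p2$eps2_Bd / p2$eps1_Bd)
  expect_error(apply_tying(list(eps1_Bd = 0.6, eps2_Bd = 0.06, eps1_U = 0),
                           "binding_global"), "eps1_U")

  # folding: A2-dark fractions come from the DA1 fraction split by l12,
  # A1-dark from the DA2 fraction; dark-dark emits donor only
  tied <- apply_tying(list(eps1_F = 0.55, eps2_F = 0.25, eps1_U = 0.25,
                           eps2_U = 0.2, epsDA1_F = 0.7, epsDA1_U = 0.4,
                           epsDA2_F = 0.45, epsDA2_U = 0.3),
                      "folding_global_blink", l12 = 0.2)
  expect_length(tied$eps1_3c, 8)
  expect_equal(tied$eps1_3c[3], 0.7 * 0.8)   # Fbd
  expect_equal(tied$eps2_3c[3], 0.7 * 0.2)
  expect_equal(tied$eps2_3c[5], 0.45)        # Fdb
  expect_equal(tied$eps1_3c[5], 0)
  expect_equal(tied$eps1_3c[7] + tied$eps2_3c[7], 0)  # Fdd
  # total parameter budget: 8 free fractions feed all 16 diagonal entries
  expect_equal(count_free_parameters("folding_global_blink"), 14)

  # identity when the family has no tying
  p0 <- list(k = 1e3, p_F = 0.5, eps_F = 0.8, eps_U = 0.3)
  expect_identical(apply_tying(p0, "folding_2c"), p0)
})
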