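# Kinetic model construction.
#
# Conventions: K[i, j] is the rate from state j to state i, so columns sum to
# zero and populations are column vectors. Emission is stored as an
# n_states x n_channels matrix `emission` whose column for channel c is the
# diagonal of the photon color matrix F(c); rows sum to 1 (the donor column
# is the complement of the acceptor fractions), which guarantees
# sum_c F(c) = I and hence a normalized photon-color likelihood.

#' Construct a kinetic/emission model
#'
#' Low-level constructor; the `build_*` helpers are the intended entry
#' points. Validates generator and emission structure.
#'
#' @param K Square rate generator (per second), columns summing to zero.
#' @param emission `n_states x n_channels` matrix of per-state emission
#'   fractions; rows must sum to 1 and entries lie in `[0, 1]`. Column names
#'   are the detection channels.
#' @param p0 Initial population vector (the model family's equilibrium vector;
#'   model family; for the binding families with photobleaching it is not the
#'   stationary vector of `K`).
#' @param states Character state labels.
#' @param family Family tag carried along for reporting.
#' @return A `fret_model` object.
#' @export
fret_model <- function(K, emission, p0, states, family = "custom") {
  K <- as.matrix(K)
  emission <- as.matrix(emission)
  ns <- nrow(K)
  stopifnot(ncol(K) == ns, nrow(emission) == ns, length(p0) == ns,
            length(states) == ns)
  offdiag <- K - diag(diag(K), ns)
  if (any(offdiag < 0)) stop("negative off-diagonal rate in K", call. = FALSE)
  cs <- colSums(K)
  if (any(abs(cs) > 1e-8 * max(1, max(abs(K))))) {
    stop("columns of K must sum to zero", call. = FALSE)
  }
  if (any(p0 < -1e-12) || abs(sum(p0) - 1) > 1e-8) {
    stop("p0 must be a probability vector", call. = FALSE)
  }
  if (any(emission < -1e-12) || any(emission > 1 + 1e-12)) {
    stop("emission fractions must lie in [0, 1] (donor complement >= 0)", call. = FALSE)
  }
  if (any(abs(rowSums(emission) - 1) > 1e-10)) {
    stop("emission rows must sum to 1 across channels", call. = FALSE)
  }
  dimnames(K) <- list(states, states)
  rownames(emission) <- states
  structure(list(K = K, emission = emission, p0 = setNames(as.numeric(p0), states),
                 states = states, channels = colnames(emission), family = family),
            class = "fret_model")
}

#' @export
print.fret_model <- function(x, ...) {
  cat("<fret_model> family ", x$family, ": ", length(x$states), " states (",
      paste(x$states, collapse = ", "), "), channels ",
      paste(x$channels, collapse = "/"), "\n", sep = "")
  invisible(x)
}

# emission matrix for a 2-color model: acceptor fractions eps, acceptor
# channel name given (A1 or A2)
emission_2c <- function(eps, acceptor = "A1") {
  m <- cbind(D = 1 - eps, a = eps)
  colnames(m) <- c("D", acceptor)
  m
}

emission_3c <- function(eps1, eps2) {
  if (any(eps1 + eps2 > 1 + 1e-12)) {
    stop("eps1 + eps2 > 1 in at least one state", call. = FALSE)
  }
  cbind(D = 1 - eps1 - eps2, A1 = eps1, A2 = eps2)
}

check_rates <- function(...) {
  r <- c(...)
  if (any(!is.finite(r)) || any(r < 0)) stop("rates must be finite and >= 0", call. = FALSE)
  invisible(r)
}

#' Two-state folding model for two-color segments
#'
#' `K = [[-k_U, k_F], [k_U, -k_F]]`, acceptor fractions `Diag(eps_F, eps_U)`,
#' and the equilibrium populations `(p_F, 1 - p_F)` with
#' `p_F = k_F / (k_F + k_U)`.
#'
#' @param k_F,k_U Folding and unfolding rate coefficients (per second).
#' @param eps_F,eps_U Acceptor fractions of the folded and unfolded states.
#' @param acceptor Acceptor channel label for the merged two-color photons
#'   (`"A1"` for DA1 segments, `"A2"` for DA2 segments).
#' @return A `fret_model` with 2 states.
#' @export
build_folding_2c <- function(k_F, k_U, eps_F, eps_U, acceptor = "A1") {
  check_rates(k_F, k_U)
  K <- matrix(c(-k_U, k_U, k_F, -k_F), 2, 2)
  p_F <- k_F / (k_F + k_U)
  fret_model(K, emission_2c(c(eps_F, eps_U), acceptor), c(p_F, 1 - p_F),
             c("F", "U"), "folding_2c")
}

#' Two-state folding model for three-color segments
#'
#' Same generator and populations as [build_folding_2c()]; the photon color
#' matrices are `F(A1) = E1`, `F(A2) = E2`, `F(D) = I - E1 - E2` with
#' per-state fractions on the diagonals.
#'
#' @inheritParams build_folding_2c
#' @param eps1,eps2 Length-2 vectors of A1 and A2 fractions for states
#'   `(F, U)`; `eps1 + eps2 <= 1` per state.
#' @export
build_folding_3c <- function(k_F, k_U, eps1, eps2) {
  check_rates(k_F, k_U)
  stopifnot(length(eps1) == 2, length(eps2) == 2)
  K <- matrix(c(-k_U, k_U, k_F, -k_F), 2, 2)
  p_F <- k_F / (k_F + k_U)
  fret_model(K, emission_3c(eps1, eps2), c(p_F, 1 - p_F), c("F", "U"), "folding_3c")
}

#' Three-state binding model for 3-color/DA1 segments
#'
#' Binding with incomplete A2 labeling and slow A2 photobleaching/blinking:
#' states are bound with active A2 (`Bb`), unbound (`U`), and bound with
#' inactive or unlabeled A2 (`Bd`). The initial populations are
#' `(phi * p_B, 1 - p_B, (1 - phi) * p_B)`; because photobleaching is
#' irreversible this vector is deliberately not the stationary vector of `K`.
#'
#' @param k_B,k_U Binding and unbinding rate coefficients (per second).
#' @param phi Fraction of molecules with active A2, in `[0, 1]`.
#' @param kb2p,kd2p Recovery and bleaching/slow-blinking rates of A2
#'   (the primed rates), per second.
#' @param eps1,eps2 Length-3 vectors of A1/A2 fractions for `(Bb, U, Bd)`.
#' @export
build_binding_3cDA1 <- function(k_B, k_U, phi, kb2p, kd2p, eps1, eps2) {
  check_rates(k_B, k_U, kb2p, kd2p)
  if (phi < 0 || phi > 1) stop("phi must lie in [0, 1]", call. = FALSE)
  stopifnot(length(eps1) == 3, length(eps2) == 3)
  p_B <- k_B / (k_B + k_U)
  K <- matrix(c(
    -k_U - kd2p, k_U,  kd2p,
    phi * k_B,   -k_B, (1 - phi) * k_B,
    kb2p,        k_U,  -k_U - kb2p
  ), 3, 3)
  p0 <- c(phi * p_B, 1 - p_B, (1 - phi) * p_B)
  fret_model(K, emission_3c(eps1, eps2), p0, c("Bb", "U", "Bd"), "binding_3cDA1")
}

#' Two-state folding with acceptor blinking, two-color segments
#'
#' Four states: (F, U) x (acceptor bright, dark). The dark-entry rate scales
#' with the trajectory's photon count rate, `k_d = k_d0 * (n / n0)` with the
#' reference rate `n0 = 100` photons/ms, because dark-state entry is driven
#' by excitation; the recovery rate `k_b` is intensity-independent.
#'
#' @inheritParams build_folding_2c
#' @param eps_d Acceptor fraction in the dark state (leak/background level).
#' @param k_b,k_d0 Dark-to-bright rate and reference bright-to-dark rate
#'   (per second).
#' @param n Trajectory mean photon count rate (photons per ms).
#' @param n0 Reference count rate (photons per ms).
#' @export
build_folding_2c_blink <- function(k_F, k_U, eps_F, eps_U, eps_d,
                                   k_b, k_d0, n, n0 = fret_n0,
                                   acceptor = "A1") {
  check_rates(k_F, k_U, k_b, k_d0)
  k_d <- k_d0 * (n / n0)
  p_F <- k_F / (k_F + k_U)
  p_b <- if (k_b + k_d > 0) k_b / (k_b + k_d) else 1
  K <- matrix(c(
    -k_U - k_d, k_U,        k_d,        0,
    k_F,        -k_F - k_d, 0,          k_d,
    k_b,        0,          -k_U - k_b, k_U,
    0,          k_b,        k_F,        -k_F - k_b
  ), 4, 4)
  p0 <- c(p_F * p_b, (1 - p_F) * p_b, p_F * (1 - p_b), (1 - p_F) * (1 - p_b))
  fret_model(K, emission_2c(c(eps_F, eps_U, eps_d, eps_d), acceptor), p0,
             c("Fb", "Ub", "Fd", "Ud"), "folding_2c_blink")
}

# state labels for the 8-state folding-blink model, order (S fastest, then
# A2 photophysical state k, then A1 photophysical state j): Sjk
folding_blink_states <- c("Fbb", "Ubb", "Fbd", "Ubd", "Fdb", "Udb", "Fdd", "Udd")

#' Two-state folding with blinking of both acceptors, three-color segments
#'
#' Eight states `(S, j, k)` with `S` the conformational state and `j`, `k`
#' the bright/dark photophysical states of A1 and A2, in the order
#' `Fbb, Ubb, Fbd, Ubd, Fdb, Udb, Fdd, Udd`. Dark-entry rates scale with the
#' trajectory count rate: `k_dI = k_dI0 * (n / n0)`.
#' Populations factorize, `p_Sjk = p_S * p_j1 * p_k2`.
#'
#' @inheritParams build_folding_2c_blink
#' @param eps1,eps2 Length-8 vectors of A1/A2 fractions in the state order
#'   above (typically produced by [apply_tying()]).
#' @param kb1,kd10,kb2,kd20 Blinking rates of A1 and A2 (per second);
#'   `kd10`/`kd20` are at the reference count rate.
#' @export
build_folding_3c_blink <- function(k_F, k_U, eps1, eps2, kb1, kd10, kb2, kd20,
                                   n, n0 = fret_n0) {
  check_rates(k_F, k_U, kb1, kd10, kb2, kd20)
  stopifnot(length(eps1) == 8, length(eps2) == 8)
  kd1 <- kd10 * (n / n0)
  kd2 <- kd20 * (n / n0)
  ns <- 8
  K <- matrix(0, ns, ns)
  # conformational exchange within each photophysical block
  for (b in c(0, 2, 4, 6)) {
    K[b + 1, b + 2] <- k_F
    K[b + 2, b + 1] <- k_U
  }
  # A2 blinking couples (1,3),(2,4),(5,7),(6,8)
  for (p in list(c(1, 3), c(2, 4), c(5, 7), c(6, 8))) {
    K[p[2], p[1]] <- kd2
    K[p[1], p[2]] <- kb2
  }
  # A1 blinking couples (1,5),(2,6),(3,7),(4,8)
  for (p in list(c(1, 5), c(2, 6), c(3, 7), c(4, 8))) {
    K[p[2], p[1]] <- kd1
    K[p[1], p[2]] <- kb1
  }
  diag(K) <- -colSums(K)
  p_F <- k_F / (k_F + k_U)
  p_b1 <- if (kb1 + kd1 > 0) kb1 / (kb1 + kd1) else 1
  p_b2 <- if (kb2 + kd2 > 0) kb2 / (kb2 + kd2) else 1
  pS <- c(F = p_F, U = 1 - p_F)
  pj <- c(b = p_b1, d = 1 - p_b1)
  pk <- c(b = p_b2, d = 1 - p_b2)
  p0 <- vapply(folding_blink_states, function(s) {
    pS[[substr(s, 1, 1)]] * pj[[substr(s, 2, 2)]] * pk[[substr(s, 3, 3)]]
  }, numeric(1))
  fret_model(K, emission_3c(eps1, eps2), p0, folding_blink_states, "folding_3c_blink")
}

binding_blink_states <- c("Bbb", "Ubb", "Bbx", "Bbd", "Bdb", "Udb", "Bdx", "Bdd")

#' Two-state binding with acceptor blinking, 3-color/DA1 segments
#'
#' Eight states: the three states of [build_binding_3cDA1()] plus a fast
#' A2-dark state, replicated for A1 bright/dark. State order
#' `Bbb, Ubb, Bbx, Bbd, Bdb, Udb, Bdx, Bdd`, where `x` marks the
#' bleached/unlabeled-A2 state and `d` the fast A2 dark state.
#' The initial vector is the factorized product form; with irreversible A2
#' photobleaching (`phi' < phi`) it is not stationary.
#'
#' @inheritParams build_binding_3cDA1
#' @inheritParams build_folding_3c_blink
#' @param eps1,eps2 Length-8 vectors in the state order above (from
#'   [apply_tying()]).
#' @export
build_binding_3cDA1_blink <- function(k_B, k_U, phi, kb2p, kd2p,
                                      kb1, kd10, kb2, kd20, eps1, eps2,
                                      n, n0 = fret_n0) {
  check_rates(k_B, k_U, kb2p, kd2p, kb1, kd10, kb2, kd20)
  if (phi < 0 || phi > 1) stop("phi must lie in [0, 1]", call. = FALSE)
  stopifnot(length(eps1) == 8, length(eps2) == 8)
  kd1 <- kd10 * (n / n0)
  kd2 <- kd20 * (n / n0)
  p_b1 <- if (kb1 + kd1 > 0) kb1 / (kb1 + kd1) else 1
  p_b2 <- if (kb2 + kd2 > 0) kb2 / (kb2 + kd2) else 1
  p_d2 <- 1 - p_b2
  p_B <- k_B / (k_B + k_U)
  p_U <- 1 - p_B
  # build explicitly (column convention: K[i,j] = rate j -> i)
  K <- matrix(0, 8, 8)
  # columns 1..4: A1-bright half
  K[2, 1] <- k_U; K[3, 1] <- kd2p; K[4, 1] <- kd2; K[5, 1] <- kd1
  K[1, 2] <- phi * p_b2 * k_B; K[3, 2] <- (1 - phi) * k_B; K[4, 2] <- phi * p_d2 * k_B
  K[6, 2] <- kd1
  K[1, 3] <- kb2p; K[2, 3] <- k_U; K[7, 3] <- kd1
  K[1, 4] <- kb2; K[2, 4] <- k_U; K[8, 4] <- kd1
  # columns 5..8: A1-dark half (replica, plus recovery kb1 back)
  K[6, 5] <- k_U; K[7, 5] <- kd2p; K[8, 5] <- kd2; K[1, 5] <- kb1
  K[5, 6] <- phi * p_b2 * k_B; K[7, 6] <- (1 - phi) * k_B; K[8, 6] <- phi * p_d2 * k_B
  K[2, 6] <- kb1
  K[5, 7] <- kb2p; K[6, 7] <- k_U; K[3, 7] <- kb1
  K[5, 8] <- kb2; K[6, 8] <- k_U; K[4, 8] <- kb1
  diag(K) <- -colSums(K)
  p0 <- c(p_B * p_b1 * p_b2 * phi, p_U * p_b1, p_B * p_b1 * (1 - phi),
          p_B * p_b1 * p_d2 * phi, p_B * (1 - p_b1) * p_b2 * phi,
          p_U * (1 - p_b1), p_B * (1 - p_b1) * (1 - phi),
          p_B * (1 - p_b1) * p_d2 * phi)
  fret_model(K, emission_3c(eps1, eps2), p0, binding_blink_states, "binding_3cDA1_blink")
}

#' Binding model for DA2 segments
#'
#' Without blinking: the three-state generator of [build_binding_3cDA1()]
#' with scalar acceptor fractions `Diag(eps_Bb, eps_U, eps_Bd)` and the
#' constraint `eps_Bd = eps_U` (a bound state with inactive A2 is
#' indistinguishable from the unbound state). With blinking: the four-state
#' model with an extra fast A2-dark state whose fraction is also tied to
#' `eps_U`.
#'
#' @inheritParams build_binding_3cDA1
#' @param eps_Bb,eps_U A2 fractions (DA2 convention: A2 photons over all
#'   photons with D and A1 merged) of the bound-bright and unbound states.
#' @param with_blinking Add the fast A2 dark state.
#' @param kb2,kd20 Fast A2 blinking rates (per second; `kd20` at the
#'   reference count rate), used when `with_blinking = TRUE`.
#' @inheritParams build_folding_2c_blink
#' @export
build_binding_DA2 <- function(k_B, k_U, phi, kb2p, kd2p, eps_Bb, eps_U,
                              with_blinking = FALSE, kb2 = 0, kd20 = 0,
                              n = fret_n0, n0 = fret_n0) {
  check_rates(k_B, k_U, kb2p, kd2p)
  if (phi < 0 || phi > 1) stop("phi must lie in [0, 1]", call. = FALSE)
  p_B <- k_B / (k_B + k_U)
  if (!with_blinking) {
    K <- matrix(c(
      -k_U - kd2p, k_U,  kd2p,
      phi * k_B,   -k_B, (1 - phi) * k_B,
      kb2p,        k_U,  -k_U - kb2p
    ), 3, 3)
    p0 <- c(phi * p_B, 1 - p_B, (1 - phi) * p_B)
    return(fret_model(K, emission_2c(c(eps_Bb, eps_U, eps_U), "A2"), p0,
                      c("Bb", "U", "Bx"), "binding_DA2"))
  }
  check_rates(kb2, kd20)
  kd2 <- kd20 * (n / n0)
  p_b2 <- if (kb2 + kd2 > 0) kb2 / (kb2 + kd2) else 1
  p_d2 <- 1 - p_b2
  K <- matrix(0, 4, 4)
  K[2, 1] <- k_U; K[3, 1] <- kd2p; K[4, 1] <- kd2
  K[1, 2] <- phi * p_b2 * k_B; K[3, 2] <- (1 - phi) * k_B; K[4, 2] <- phi * p_d2 * k_B
  K[1, 3] <- kb2p; K[2, 3] <- k_U
  K[1, 4] <- kb2; K[2, 4] <- k_U
  diag(K) <- -colSums(K)
  p0 <- c(p_B * p_b2 * phi, 1 - p_B, p_B * (1 - phi), p_B * p_d2 * phi)
  fret_model(K, emission_2c(c(eps_Bb, eps_U, eps_U, eps_U), "A2"), p0,
             c("Bb", "U", "Bx", "Bd"), "binding_DA2_blink")
}

#' N-state linear (chain) model
#'
#' Tridiagonal generator for a linear kinetic scheme
#' `1 <-> 2 <-> ... <-> n`. The equilibrium vector is the null vector of `K`
#' normalized to sum 1.
#'
#' @param rates_fwd,rates_bwd Length `n - 1` vectors of forward
#'   (`i -> i + 1`) and backward (`i + 1 -> i`) rates, per second; every
#'   adjacent pair must be connected (`rates_fwd[i] + rates_bwd[i] > 0` and
#'   reachability in both directions requires both positive).
#' @param eps1 Per-state acceptor fractions (length `n`). With `eps2 = NULL`
#'   a two-color model is built.
#' @param eps2 Optional per-state A2 fractions for a three-color model.
#' @param acceptor Acceptor channel for the two-color case.
#' @export
build_linear_n_state <- function(rates_fwd, rates_bwd, eps1, eps2 = NULL,
                                 acceptor = "A1") {
  n <- length(eps1)
  if (n < 2) stop("need at least 2 states", call. = FALSE)
  stopifnot(length(rates_fwd) == n - 1, length(rates_bwd) == n - 1)
  check_rates(rates_fwd, rates_bwd)
  if (any(rates_fwd == 0) || any(rates_bwd == 0)) {
    stop("disconnected chain: a forward/backward rate is zero", call. = FALSE)
  }
  K <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    K[i + 1, i] <- rates_fwd[i]
    K[i, i + 1] <- rates_bwd[i]
  }
  diag(K) <- -colSums(K)
  p0 <- stationary_vector(K)
  emission <- if (is.null(eps2)) emission_2c(eps1, acceptor) else emission_3c(eps1, eps2)
  fret_model(K, emission, p0, paste0("S", seq_len(n)), paste0("linear_", n, "state"))
}

#' Stationary distribution of a rate generator
#'
#' Solves `K p = 0`, `sum(p) = 1` by replacing one balance equation with the
#' normalization constraint.
#'
#' @param K Rate generator with columns summing to zero.
#' @return Probability vector.
#' @export
stationary_vector <- function(K) {
  n <- nrow(K)
  A <- rbind(K[-1, , drop = FALSE], rep(1, n))
  b <- c(rep(0, n - 1), 1)
  p <- qr.solve(A, b)
  if (any(p < -1e-10)) stop("no nonnegative stationary vector", call. = FALSE)
  p <- pmax(p, 0)
  p / sum(p)
}
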