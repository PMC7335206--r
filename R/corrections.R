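# Correction of acceptor count fractions (background, cross-talk, direct
# excitation) and conversion between fractions and the three FRET
# efficiencies. The correction order is fixed: background, then donor/A1
# leak, then direct acceptor excitation — each formula expects the output of
# the previous step.

#' Bundle per-dataset correction factors
#'
#' @param b_D,b_A1,b_A2,b_A Background count rates (photons per ms) in the
#'   donor, A1, A2 (three-color) or merged acceptor (two-color) channels.
#' @param l Donor leak fraction into the acceptor channel (two-color).
#' @param l1,l2 Donor leak fractions into the A1 and A2 channels.
#' @param l12 A1 leak fraction into the A2 channel.
#' @param f1dir,f2dir,fdir Direct-excitation fractions of A1, A2 (or the
#'   single two-color acceptor).
#' @param gamma1,gamma2,gamma Detection-efficiency x quantum-yield ratios.
#' @param n Total mean count rate (photons per ms).
#' @return A `fret_corrections` list.
#' @export
correction_factors <- function(b_D = 0, b_A1 = 0, b_A2 = 0, b_A = 0,
                               l = 0, l1 = 0, l2 = 0, l12 = 0,
                               f1dir = 0, f2dir = 0, fdir = 0,
                               gamma1 = 1, gamma2 = 1, gamma = 1, n = NULL) {
  fr <- c(l, l1, l2, l12, f1dir, f2dir, fdir)
  if (any(fr < 0 | fr >= 1)) stop("leak/direct fractions must lie in [0, 1)", call. = FALSE)
  if (any(c(gamma1, gamma2, gamma) <= 0)) stop("gamma factors must be positive", call. = FALSE)
  if (any(c(b_D, b_A1, b_A2, b_A) < 0)) stop("backgrounds must be >= 0", call. = FALSE)
  structure(list(b_D = b_D, b_A1 = b_A1, b_A2 = b_A2, b_A = b_A,
                 l = l, l1 = l1, l2 = l2, l12 = l12,
                 f1dir = f1dir, f2dir = f2dir, fdir = fdir,
                 gamma1 = gamma1, gamma2 = gamma2, gamma = gamma, n = n),
            class = "fret_corrections")
}

#' Background correction of acceptor fractions
#'
#' Subtracts the per-channel background count rates. Two-color:
#' `eps_c = (eps n - b_A) / (n - b_A - b_D)`; three-color analogously with
#' both acceptor channels.
#'
#' @param eps For `mode = "2c"` a numeric vector of acceptor fractions; for
#'   `"3c"` a list/data frame with `eps1`, `eps2`.
#' @param factors A [correction_factors()] (needs `n` and backgrounds).
#' @param mode `"2c"` or `"3c"`.
#' @param clip Clip slightly negative corrected fractions to zero (with a
#'   warning) rather than returning them.
#' @return Corrected fractions, same shape as the input.
#' @export
correct_background <- function(eps, factors, mode = c("2c", "3c"), clip = TRUE) {
  mode <- match.arg(mode)
  n <- factors$n
  if (is.null(n)) stop("factors$n (total count rate) required", call. = FALSE)
  if (mode == "2c") {
    den <- n - factors$b_A - factors$b_D
    if (den <= 0) stop("count rate does not exceed total background", call. = FALSE)
    out <- (eps * n - factors$b_A) / den
    return(clip01(out, clip))
  }
  den <- n - factors$b_D - factors$b_A1 - factors$b_A2
  if (den <= 0) stop("count rate does not exceed total background", call. = FALSE)
  list(eps1 = clip01((eps$eps1 * n - factors$b_A1) / den, clip),
       eps2 = clip01((eps$eps2 * n - factors$b_A2) / den, clip))
}

clip01 <- function(x, clip) {
  if (clip && any(x < 0)) {
    warning("corrected fraction(s) below 0 clipped to 0", call. = FALSE)
    x <- pmax(x, 0)
  }
  x
}

#' Donor (and A1) leak correction
#'
#' Two-color: `eps_c = (eps - l) / (1 - l)`. Three-color: inverts the leak
#' model `n_A1 = (1 - l12) n_A1c + l1 n_Dc`, `n_A2 = l12 n_A1c + n_A2c +
#' l2 n_Dc`, `n_D = (1 - l1 - l2) n_Dc`. Inputs are background-corrected
#' fractions.
#'
#' @inheritParams correct_background
#' @export
correct_donor_leak <- function(eps, factors, mode = c("2c", "3c"), clip = TRUE) {
  mode <- match.arg(mode)
  if (mode == "2c") {
    return(clip01((eps - factors$l) / (1 - factors$l), clip))
  }
  l1 <- factors$l1
  l2 <- factors$l2
  l12 <- factors$l12
  den <- (1 - l1 - l2) * (1 - l12)
  if (den <= 0) stop("1 - l1 - l2 (or 1 - l12) must be positive", call. = FALSE)
  e1 <- eps$eps1
  e2 <- eps$eps2
  list(eps1 = clip01((e1 * (1 - l2) - (1 - e2) * l1) / den, clip),
       eps2 = clip01((e1 * (l2 - l12) + e2 * (1 - l1 - l12) + (l1 + l2) * l12 - l2) / den,
                     clip))
}

#' Direct-acceptor-excitation correction
#'
#' Two-color: `eps_c = (eps - f gamma (1 - eps)) / (1 + f (1 - gamma)(1 - eps))`.
#' Three-color: removes the direct-excitation count rates of A1 (attenuated
#' by transfer to A2, factor `1 - E12`) and A2 (direct plus transfer from
#' directly excited A1), which requires the true efficiencies; supply them
#' via `efficiencies` (or use [iterate_3c_conversion()] when only an anchor
#' efficiency is known). Inputs are background- and leak-corrected fractions.
#'
#' @inheritParams correct_background
#' @param efficiencies For `"3c"`: list/vector with `E1`, `E2`, `E12`.
#' @export
correct_direct_excitation <- function(eps, factors, efficiencies = NULL,
                                      mode = c("2c", "3c"), clip = TRUE) {
  mode <- match.arg(mode)
  if (mode == "2c") {
    f <- factors$fdir
    g <- factors$gamma
    return(clip01((eps - f * g * (1 - eps)) / (1 + f * (1 - g) * (1 - eps)), clip))
  }
  if (is.null(efficiencies)) stop("3c mode needs E1, E2, E12", call. = FALSE)
  E1 <- efficiencies[["E1"]]
  E2 <- efficiencies[["E2"]]
  E12 <- efficiencies[["E12"]]
  f1 <- factors$f1dir
  f2 <- factors$f2dir
  g1 <- factors$gamma1
  g2 <- factors$gamma2
  e1 <- eps$eps1
  e2 <- eps$eps2
  Z <- (1 - e1 - e2) * (1 + E1 / (1 - E1) + E2 / (1 - E2))
  den <- 1 - (f1 * g1 + f2 * g2 + f1 * (g2 - g1) * E12) * Z
  if (any(den <= 0)) stop("direct-excitation correction denominator <= 0", call. = FALSE)
  list(eps1 = clip01((e1 - f1 * g1 * (1 - E12) * Z) / den, clip),
       eps2 = clip01((e2 - (f2 + f1 * E12) * g2 * Z) / den, clip))
}

#' Convert corrected acceptor fractions to the three FRET efficiencies
#'
#' The two count-rate ratio relations
#' `n_A1 / (gamma1 n_D) = (1 - E12) E1 / (1 - E1)` and
#' `n_A2 / (gamma2 n_D) = E12 E1 / (1 - E1) + E2 / (1 - E2)` determine only
#' two of the three efficiencies, so one must be anchored from two-color
#' segments (or alternating excitation): anchoring `E12`, `E1` or `E2`
#' solves for the remaining pair. The anchor choice drives accuracy — anchor
#' with the efficiency that is measured well (use `E2` when `E2` is low).
#'
#' @param eps1,eps2 Corrected three-color acceptor fractions
#'   (`eps1 + eps2 < 1`).
#' @param gamma1,gamma2 Gamma factors.
#' @param anchor Which efficiency is known: `"E12"`, `"E1"` or `"E2"`.
#' @param anchor_value Its value, in `[0, 1)`.
#' @return A tibble with `E1`, `E2`, `E12`, `anchor`.
#' @export
efficiencies_from_fractions <- function(eps1, eps2, gamma1 = 1, gamma2 = 1,
                                        anchor = c("E12", "E1", "E2"),
                                        anchor_value) {
  anchor <- match.arg(anchor)
  if (any(eps1 + eps2 >= 1)) stop("eps1 + eps2 must be < 1", call. = FALSE)
  if (any(anchor_value < 0 | anchor_value >= 1)) {
    stop("anchor efficiency must lie in [0, 1)", call. = FALSE)
  }
  d <- 1 - eps1 - eps2
  r1 <- eps1 / gamma1
  r2 <- eps2 / gamma2
  if (anchor == "E12") {
    E12 <- anchor_value
    E1 <- 1 / (1 + gamma1 * d * (1 - E12) / eps1)
    inner <- r2 - r1 * E12 / (1 - E12)
    if (any(inner == 0)) stop("ill-conditioned anchor E12: zero inner term", call. = FALSE)
    E2 <- 1 / (1 + d / inner)
  } else if (anchor == "E1") {
    E1 <- anchor_value
    inner <- (r1 + r2) / d - E1 / (1 - E1)
    if (any(inner == 0 | E1 == 0)) stop("ill-conditioned anchor E1", call. = FALSE)
    E2 <- 1 / (1 + 1 / inner)
    E12 <- 1 - r1 * (1 - E1) / (d * E1)
  } else {
    E2 <- anchor_value
    inner <- (r1 + r2) / d - E2 / (1 - E2)
    if (any(inner == 0)) stop("ill-conditioned anchor E2", call. = FALSE)
    E1 <- 1 / (1 + 1 / inner)
    inner12 <- r2 - d * E2 / (1 - E2)
    if (any(inner12 == 0)) stop("ill-conditioned anchor E2: zero A1->A2 term", call. = FALSE)
    E12 <- 1 / (1 + r1 / inner12)
  }
  tibble::tibble(E1 = unname(E1), E2 = unname(E2), E12 = unname(E12),
                 anchor = anchor)
}

#' Ideal acceptor fractions from a FRET efficiency triplet
#'
#' Forward direction of the count-rate relations (the inverse of every
#' anchored conversion): with the donor count rate as the unit,
#' `n_A1 = gamma1 (1 - E12) E1 / (1 - E1)` and
#' `n_A2 = gamma2 (E12 E1 / (1 - E1) + E2 / (1 - E2))`, normalized to
#' fractions.
#'
#' @param E1,E2,E12 Efficiencies (`E1, E2 < 1`).
#' @inheritParams efficiencies_from_fractions
#' @return A tibble with `eps1`, `eps2`.
#' @export
fractions_from_efficiencies <- function(E1, E2, E12, gamma1 = 1, gamma2 = 1) {
  if (any(E1 >= 1 | E2 >= 1)) stop("E1 and E2 must be < 1 (infinite count-rate ratio)",
                                   call. = FALSE)
  x1 <- gamma1 * (1 - E12) * E1 / (1 - E1)
  x2 <- gamma2 * (E12 * E1 / (1 - E1) + E2 / (1 - E2))
  tot <- 1 + x1 + x2
  tibble::tibble(eps1 = unname(x1 / tot), eps2 = unname(x2 / tot))
}

#' Two-color FRET efficiency from an acceptor fraction
#'
#' `E = eps / (eps + gamma (1 - eps))`; the identity when `gamma = 1`.
#'
#' @param eps Corrected acceptor fraction(s) in `[0, 1]`.
#' @param gamma Gamma factor.
#' @export
two_color_E <- function(eps, gamma = 1) {
  stopifnot(all(eps >= 0 & eps <= 1))
  eps / (eps + gamma * (1 - eps))
}

#' Iterative direct-excitation correction and conversion
#'
#' The three-color direct-excitation correction needs the true efficiencies,
#' which are themselves computed from the corrected fractions. Starting from
#' the uncorrected (background- and leak-corrected) fractions, this
#' alternates the anchored conversion and the direct-excitation correction
#' until the efficiencies stop changing. Since the direct-excitation
#' fractions are small the iteration converges in a handful of steps.
#'
#' @param eps1,eps2 Background- and leak-corrected three-color fractions.
#' @param factors A [correction_factors()] with `f1dir`, `f2dir`, gammas.
#' @inheritParams efficiencies_from_fractions
#' @param tol Convergence tolerance on the maximum absolute change.
#' @param max_iter Iteration cap; exceeding it is an error.
#' @return A list with `fractions` (tibble `eps1`, `eps2`), `efficiencies`
#'   (tibble `E1`, `E2`, `E12`, `anchor`), `iterations`.
#' @export
iterate_3c_conversion <- function(eps1, eps2, factors,
                                  anchor = c("E12", "E1", "E2"), anchor_value,
                                  tol = 1e-8, max_iter = 100) {
  anchor <- match.arg(anchor)
  g1 <- factors$gamma1
  g2 <- factors$gamma2
  eff <- efficiencies_from_fractions(eps1, eps2, g1, g2, anchor, anchor_value)
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    cor <- correct_direct_excitation(list(eps1 = eps1, eps2 = eps2), factors,
                                     efficiencies = eff, mode = "3c", clip = FALSE)
    eff_new <- efficiencies_from_fractions(cor$eps1, cor$eps2, g1, g2,
                                           anchor, anchor_value)
    delta <- max(abs(c(eff_new$E1 - eff$E1, eff_new$E2 - eff$E2,
                       eff_new$E12 - eff$E12)))
    trace <- c(trace, delta)
    eff <- eff_new
    if (delta < tol) {
      return(list(fractions = tibble::tibble(eps1 = cor$eps1, eps2 = cor$eps2),
                  efficiencies = eff, iterations = it))
    }
  }
  stop("no convergence in ", max_iter, " iterations; last changes: ",
       paste(format(tail(trace, 3), digits = 3), collapse = ", "), call. = FALSE)
}

#' Estimate correction factors from calibration segments
#'
#' Donor-only segments give the leak fractions as the background-corrected
#' mean channel-rate ratios, `l1 = n_A1^0 / (n_A1^0 + n_A2^0 + n_D^0)` (and
#' analogously `l2`, or `l` in two-color). The A1-into-A2 leak comes from
#' DA1-segment fractions, `l12 = (n eps2 - b_A2) / (n eps1 + n eps2 - b_A1 -
#' b_A2)`. Direct-excitation fractions come from count rates before and
#' after donor bleaching, `f_dir = n_A^dir / (n_A + gamma n_D)`; gamma
#' factors from the count-rate changes across acceptor photobleaching,
#' `gamma = -delta n_A / delta n_D`.
#'
#' @param donly_rates Named vector/list of background-corrected mean donor-only
#'   channel rates (`n_D0`, `n_A10`, `n_A20`; or `n_D0`, `n_A0` for 2c).
#' @param da1_fractions Optional list with `eps1`, `eps2`, `n` (and the
#'   backgrounds are taken from `backgrounds`) for `l12`.
#' @param prepost Optional tibble with columns `channel_A`, `channel_D`
#'   rates `pre` and `post` donor bleaching for the direct-excitation
#'   fraction; or for gamma, acceptor-bleach `pre`/`post` pairs via
#'   `gamma_pairs`.
#' @param gamma_pairs Optional tibble with `n_A_pre`, `n_A_post`, `n_D_pre`,
#'   `n_D_post` across an acceptor photobleaching step.
#' @param backgrounds Optional list with `b_A1`, `b_A2` used for `l12`.
#' @param gamma Gamma used in the `f_dir` denominator (default 1).
#' @return A [correction_factors()] with the estimable entries filled.
#' @export
estimate_correction_factors <- function(donly_rates = NULL, da1_fractions = NULL,
                                        prepost = NULL, gamma_pairs = NULL,
                                        backgrounds = list(b_A1 = 0, b_A2 = 0),
                                        gamma = 1) {
  out <- list(l = 0, l1 = 0, l2 = 0, l12 = 0, fdir = 0, f1dir = 0, f2dir = 0,
              gamma1 = 1, gamma2 = 1, gamma = 1)
  if (!is.null(donly_rates)) {
    d <- as.list(donly_rates)
    if (!is.null(d$n_A0)) {
      tot <- d$n_A0 + d$n_D0
      if (tot <= 0) stop("zero donor-only rate", call. = FALSE)
      out$l <- d$n_A0 / tot
    }
    if (!is.null(d$n_A10)) {
      tot <- d$n_A10 + d$n_A20 + d$n_D0
      if (tot <= 0) stop("zero donor-only rate", call. = FALSE)
      out$l1 <- d$n_A10 / tot
      out$l2 <- d$n_A20 / tot
    }
  }
  if (!is.null(da1_fractions)) {
    f <- da1_fractions
    num <- f$n * f$eps2 - backgrounds$b_A2
    den <- f$n * f$eps1 + f$n * f$eps2 - backgrounds$b_A1 - backgrounds$b_A2
    if (den == 0) stop("zero denominator in l12", call. = FALSE)
    out$l12 <- num / den
  }
  if (!is.null(prepost)) {
    den <- prepost$n_A_pre + gamma * prepost$n_D_pre
    if (any(den == 0)) stop("zero denominator in f_dir", call. = FALSE)
    fdir <- prepost$n_A_post / den
    out$fdir <- out$f1dir <- mean(fdir)
    if (!is.null(prepost$n_A2_post)) {
      out$f2dir <- mean(prepost$n_A2_post / den)
    }
  }
  if (!is.null(gamma_pairs)) {
    dD <- gamma_pairs$n_D_post - gamma_pairs$n_D_pre
    if (any(dD == 0)) stop("zero donor-rate change across acceptor bleach", call. = FALSE)
    out$gamma <- out$gamma1 <- mean((gamma_pairs$n_A_pre - gamma_pairs$n_A_post) / dD)
  }
  do.call(correction_factors, out)
}

#' Apply the full correction chain to measured fractions
#'
#' Background, then leak, then (iterative) direct-excitation correction and
#' anchored conversion, in one call.
#'
#' @inheritParams iterate_3c_conversion
#' @param eps1,eps2 Raw three-color acceptor fractions.
#' @export
correct_fractions_3c <- function(eps1, eps2, factors, anchor, anchor_value,
                                 tol = 1e-8, max_iter = 100) {
  bg <- correct_background(list(eps1 = eps1, eps2 = eps2), factors, "3c")
  lk <- correct_donor_leak(bg, factors, "3c")
  iterate_3c_conversion(lk$eps1, lk$eps2, factors, anchor, anchor_value,
                        tol = tol, max_iter = max_iter)
}
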