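# Fit families: the global models the likelihood is maximized under.
#
# A family bundles the free parameter names and their transforms with a
# builder that turns a parameter vector into the per-class kinetic model.
# Rates are optimized on a log scale and fractions on a logit scale; pairs
# of three-color fractions belonging to one state use an additive-logistic
# map so that eps1 + eps2 < 1 is maintained throughout the search.

#' Define a fit family
#'
#' @param name One of `"folding_2c"`, `"folding_3c"`, `"folding_global"`,
#'   `"folding_global_blink"`, `"binding_global"`, `"binding_global_blink"`,
#'   `"linear_2c"`.
#' @param n_states Number of states (linear-chain family only).
#' @param acceptor Acceptor channel of the two-color linear-chain family.
#' @return A `fret_family` object with elements `name`, `kind`, `classes`,
#'   `par_names`, `n_params`, and builder/transform closures.
#' @export
fret_family <- function(name, n_states = 2, acceptor = "A1") {
  par_names <- family_param_names(name, n_states)
  spec <- switch(name,
    static_2c = list(
      # no dynamics: one effective state emitting a binomial photon stream;
      # the baseline for uncertainty calibration
      kind = "folding", classes = c("DA1", "DA2"),
      pairs = list(), rates = character(0), probs = "eps",
      build = function(p, class, n) {
        build_folding_2c(1, 1, p$eps, p$eps,
                         acceptor = if (class == "DA2") "A2" else "A1")
      }
    ),
    folding_2c = list(
      kind = "folding", classes = c("DA1", "DA2"),
      pairs = list(), rates = "k", probs = c("p_F", "eps_F", "eps_U"),
      build = function(p, class, n) {
        build_folding_2c(p$k * p$p_F, p$k * (1 - p$p_F), p$eps_F, p$eps_U,
                         acceptor = if (class == "DA2") "A2" else "A1")
      }
    ),
    folding_3c = list(
      kind = "folding", classes = "3c",
      pairs = list(c("eps1_F", "eps2_F"), c("eps1_U", "eps2_U")),
      rates = "k", probs = "p_F",
      build = function(p, class, n) {
        build_folding_3c(p$k * p$p_F, p$k * (1 - p$p_F),
                         c(p$eps1_F, p$eps1_U), c(p$eps2_F, p$eps2_U))
      }
    ),
    folding_global = list(
      kind = "folding", classes = c("3c", "DA1", "DA2"),
      pairs = list(c("eps1_F", "eps2_F"), c("eps1_U", "eps2_U")),
      rates = "k",
      probs = c("p_F", "epsDA1_F", "epsDA1_U", "epsDA2_F", "epsDA2_U"),
      build = function(p, class, n) {
        k_F <- p$k * p$p_F
        k_U <- p$k * (1 - p$p_F)
        switch(class,
          "3c" = build_folding_3c(k_F, k_U, c(p$eps1_F, p$eps1_U),
                                  c(p$eps2_F, p$eps2_U)),
          "DA1" = build_folding_2c(k_F, k_U, p$epsDA1_F, p$epsDA1_U, "A1"),
          "DA2" = build_folding_2c(k_F, k_U, p$epsDA2_F, p$epsDA2_U, "A2"))
      }
    ),
    folding_global_blink = list(
      kind = "folding", classes = c("3c", "DA1", "DA2"),
      pairs = list(c("eps1_F", "eps2_F"), c("eps1_U", "eps2_U")),
      rates = c("k", "kb1", "kd10", "kb2", "kd20"),
      probs = c("p_F", "epsDA1_F", "epsDA1_U", "epsDA2_F", "epsDA2_U"),
      build = function(p, class, n, l12 = 0) {
        k_F <- p$k * p$p_F
        k_U <- p$k * (1 - p$p_F)
        switch(class,
          "3c" = {
            pt <- apply_tying(p, "folding_global_blink", l12 = l12)
            build_folding_3c_blink(k_F, k_U, pt$eps1_3c, pt$eps2_3c,
                                   p$kb1, p$kd10, p$kb2, p$kd20, n = n)
          },
          "DA1" = build_folding_2c_blink(k_F, k_U, p$epsDA1_F, p$epsDA1_U, 0,
                                         p$kb1, p$kd10, n = n, acceptor = "A1"),
          "DA2" = build_folding_2c_blink(k_F, k_U, p$epsDA2_F, p$epsDA2_U, 0,
                                         p$kb2, p$kd20, n = n, acceptor = "A2"))
      }
    ),
    binding_global = list(
      kind = "binding", classes = c("3c/DA1", "DA2"),
      pairs = list(c("eps1_Bb", "eps2_Bb"), c("eps1_Bd", "eps2_Bd")),
      rates = c("k_B", "k_U", "kb2p", "kd2p"),
      probs = c("eps1_U", "epsDA2_B", "epsDA2_U", "phi"),
      build = function(p, class, n) {
        pt <- apply_tying(p, "binding_global")
        switch(class,
          "3c/DA1" = build_binding_3cDA1(
            p$k_B, p$k_U, p$phi, p$kb2p, p$kd2p,
            c(pt$eps1_Bb, pt$eps1_U, pt$eps1_Bd),
            c(pt$eps2_Bb, pt$eps2_U, pt$eps2_Bd)),
          "DA2" = build_binding_DA2(p$k_B, p$k_U, p$phi, p$kb2p, p$kd2p,
                                    p$epsDA2_B, p$epsDA2_U))
      }
    ),
    binding_global_blink = list(
      kind = "binding", classes = c("3c/DA1", "DA2"),
      pairs = list(c("eps1_Bbb", "eps2_Bbb"), c("eps1_Ubb", "eps2_Ubb")),
      rates = c("k_B", "k_U", "kb1", "kd10", "kb2", "kd20", "kb2p", "kd2p"),
      probs = c("eps1_Bbd", "epsDA2_B", "epsDA2_U", "phi"),
      build = function(p, class, n) {
        pt <- apply_tying(p, "binding_global_blink")
        switch(class,
          "3c/DA1" = build_binding_3cDA1_blink(
            p$k_B, p$k_U, p$phi, p$kb2p, p$kd2p,
            p$kb1, p$kd10, p$kb2, p$kd20,
            pt$eps1_3c, pt$eps2_3c, n = n),
          "DA2" = build_binding_DA2(p$k_B, p$k_U, p$phi, p$kb2p, p$kd2p,
                                    p$epsDA2_B, p$epsDA2_U,
                                    with_blinking = TRUE,
                                    kb2 = p$kb2, kd20 = p$kd20, n = n))
      }
    ),
    linear_2c = list(
      kind = "folding", classes = c("DA1", "DA2"),
      pairs = list(),
      rates = c(paste0("k", seq_len(n_states - 1), seq_len(n_states - 1) + 1),
                paste0("k", seq_len(n_states - 1) + 1, seq_len(n_states - 1))),
      probs = paste0("eps", seq_len(n_states)),
      build = function(p, class, n) {
        fwd <- unlist(p[paste0("k", seq_len(n_states - 1), seq_len(n_states - 1) + 1)])
        bwd <- unlist(p[paste0("k", seq_len(n_states - 1) + 1, seq_len(n_states - 1))])
        eps <- unlist(p[paste0("eps", seq_len(n_states))])
        build_linear_n_state(fwd, bwd, eps,
                             acceptor = if (class == "DA2") "A2" else "A1")
      }
    ),
    stop("unknown model family: ", name, call. = FALSE)
  )
  structure(list(name = name, kind = spec$kind, classes = spec$classes,
                 par_names = par_names, n_params = length(par_names),
                 n_states = n_states,
                 pairs = spec$pairs, rates = spec$rates, probs = spec$probs,
                 build = spec$build),
            class = "fret_family")
}

#' @export
print.fret_family <- function(x, ...) {
  cat("<fret_family> ", x$name, " (", x$kind, "): ", x$n_params,
      " free parameters\n  ", paste(x$par_names, collapse = ", "), "\n", sep = "")
  invisible(x)
}

as_family <- function(family, ...) {
  if (inherits(family, "fret_family")) family else fret_family(family, ...)
}

# ---- coordinate transforms --------------------------------------------------

family_transform <- function(fam, par) {
  par <- unlist(par)[fam$par_names]
  eta <- setNames(numeric(fam$n_params), fam$par_names)
  for (nm in fam$rates) eta[nm] <- log(par[nm])
  for (nm in fam$probs) eta[nm] <- qlogis(par[nm])
  for (pr in fam$pairs) {
    a <- par[pr[1]]
    b <- par[pr[2]]
    d <- 1 - a - b
    eta[pr[1]] <- log(a / d)
    eta[pr[2]] <- log(b / d)
  }
  eta
}

family_untransform <- function(fam, eta) {
  par <- setNames(numeric(fam$n_params), fam$par_names)
  for (nm in fam$rates) par[nm] <- exp(eta[nm])
  for (nm in fam$probs) par[nm] <- plogis(eta[nm])
  for (pr in fam$pairs) {
    e1 <- exp(eta[pr[1]])
    e2 <- exp(eta[pr[2]])
    par[pr[1]] <- e1 / (1 + e1 + e2)
    par[pr[2]] <- e2 / (1 + e1 + e2)
  }
  par
}

# ---- global likelihood ------------------------------------------------------

# merge channels of two-color segments before likelihood evaluation
merge_for_class <- function(photons, class) {
  switch(class,
    DA1 = combine_channels(photons, "DA1-merge"),
    DA2 = combine_channels(photons, "DA2-merge"),
    photons)
}

#' Global log-likelihood of a dataset under a model family
#'
#' Sums segment log-likelihoods over all analyzable trajectories: folding
#' datasets combine the three-color, DA1 and DA2 segment classes
#' (`L = L_3c * L_DA1 * L_DA2`), binding datasets the 3-color/DA1 and DA2
#' classes. Two-color segments have their channels merged first; donor-only
#' segments are excluded. For blinking families the dark-entry rates are
#' scaled by each trajectory's own count rate.
#'
#' @param data A [fret_data()].
#' @param params Named list/vector of the family's free parameters.
#' @param family A [fret_family()] or family name.
#' @return A `fret_loglik` list with a `by_class` subtotal tibble.
#' @export
global_loglik <- function(data, params, family) {
  fam <- as_family(family)
  stopifnot(inherits(data, "fret_data"))
  params <- as.list(unlist(params))
  rates <- trajectory_rates(data$photons)
  rates <- rates[rates$class != "Donly", ]
  bad <- setdiff(unique(rates$class), fam$classes)
  if (length(bad) > 0) {
    stop("segment class(es) ", paste(bad, collapse = ", "),
         " not covered by family ", fam$name, call. = FALSE)
  }
  total <- 0
  n_tot <- 0L
  by_class <- list()
  for (i in seq_len(nrow(rates))) {
    cls <- rates$class[i]
    ph <- data$photons[data$photons$trajectory_id == rates$trajectory_id[i], ]
    ph <- merge_for_class(ph, cls)
    model <- fam$build(params, cls, rates$rate_ms[i])
    ll <- segment_loglik(ph, model)
    total <- total + ll$loglik
    n_tot <- n_tot + ll$n_photons
    by_class[[cls]] <- (by_class[[cls]] %||% 0) + ll$loglik
  }
  structure(list(loglik = total, n_photons = n_tot,
                 by_class = tibble::tibble(class = names(by_class),
                                           loglik = unlist(by_class))),
            class = "fret_loglik")
}

`%||%` <- function(x, y) if (is.null(x)) y else x
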