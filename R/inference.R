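# Maximum-likelihood fitting, curvature-based uncertainties, and BIC.

# Pre-split a dataset into plain per-segment records so the optimizer's
# objective avoids tibble overhead in the hot loop.
prepare_segments <- function(data, fam) {
  rates <- trajectory_rates(data$photons)
  rates <- rates[rates$class != "Donly", ]
  bad <- setdiff(unique(rates$class), fam$classes)
  if (length(bad) > 0) {
    stop("segment class(es) ", paste(bad, collapse = ", "),
         " not covered by family ", fam$name, call. = FALSE)
  }
  purrr::map(seq_len(nrow(rates)), function(i) {
    ph <- data$photons[data$photons$trajectory_id == rates$trajectory_id[i], ]
    ph <- merge_for_class(ph, rates$class[i])
    list(class = rates$class[i], time = ph$time, channel = ph$channel,
         n = ifelse(is.na(rates$rate_ms[i]), fret_n0, rates$rate_ms[i]))
  })
}

make_objective <- function(segments, fam) {
  # channel index per segment is fixed by the class's channel set
  segments <- purrr::map(segments, function(s) {
    probe <- fam$build(as.list(family_untransform(fam, setNames(rep(0, fam$n_params),
                                                                fam$par_names))),
                       s$class, s$n %||% 100)
    s$chan <- match(s$channel, probe$channels) - 1L
    if (anyNA(s$chan)) stop("channel labels incompatible with class ", s$class,
                            call. = FALSE)
    s
  })
  n_eval <- 0L
  obj <- function(eta) {
    n_eval <<- n_eval + 1L
    par <- as.list(family_untransform(fam, setNames(eta, fam$par_names)))
    tot <- 0
    for (s in segments) {
      model <- tryCatch(fam$build(par, s$class, s$n), error = function(e) NULL)
      if (is.null(model)) return(1e10)
      ll <- tryCatch(cpp_segment_loglik(s$time, s$chan, model$K,
                                        model$emission, model$p0)$loglik,
                     error = function(e) NA_real_)
      if (!is.finite(ll)) return(1e10)
      tot <- tot + ll
    }
    -tot
  }
  list(obj = obj, evals = function() n_eval,
       n_photons = sum(purrr::map_int(segments, ~ length(.x$time))))
}

#' Maximize the global likelihood of a dataset
#'
#' Derivative-free Nelder-Mead optimization in transformed coordinates: log
#' for rates, logit for lone fractions, and an additive-logistic map for
#' per-state three-color fraction pairs (keeping `eps1 + eps2 < 1`). The
#' restart policy runs three searches (the initial point and two copies
#' shifted by +/-20% in transformed space) and keeps the best.
#'
#' @param data A [fret_data()].
#' @param family A [fret_family()] or family name.
#' @param init Named list of starting values (natural units).
#' @param options List overriding `restarts` (3), `maxit` (5e4), `reltol`
#'   (1e-8), `perturb` (0.2).
#' @return A `fret_fit` with `estimates`, `std_devs` (filled by
#'   [error_bars()]), `max_loglik`, `bic`, `n_photons`, `n_evaluations`,
#'   `converged`, `boundary`, and the transform record `eta`.
#' @export
fit_ml <- function(data, family, init, options = list()) {
  fam <- as_family(family)
  opt <- modifyList(list(restarts = 3, maxit = 5e4, reltol = 1e-8,
                         perturb = 0.2), options)
  init <- unlist(init)[fam$par_names]
  if (anyNA(init)) stop("init must name every free parameter of ", fam$name,
                        call. = FALSE)
  segments <- prepare_segments(data, fam)
  if (length(segments) == 0) stop("no analyzable segments", call. = FALSE)
  ob <- make_objective(segments, fam)
  eta0 <- family_transform(fam, init)
  f0 <- ob$obj(eta0)
  starts <- list(eta0)
  if (opt$restarts >= 2) starts <- c(starts, list(eta0 + opt$perturb * pmax(abs(eta0), 1)))
  if (opt$restarts >= 3) starts <- c(starts, list(eta0 - opt$perturb * pmax(abs(eta0), 1)))
  runs <- purrr::map(starts[seq_len(min(opt$restarts, length(starts)))], function(s) {
    if (length(s) == 1) {
      # Nelder-Mead is unreliable in one dimension; bracketed Brent instead
      optim(s, ob$obj, method = "Brent", lower = s - 30, upper = s + 30,
            control = list(maxit = opt$maxit))
    } else {
      optim(s, ob$obj, method = "Nelder-Mead",
            control = list(maxit = opt$maxit, reltol = opt$reltol))
    }
  })
  best <- runs[[which.min(purrr::map_dbl(runs, "value"))]]
  improved <- best$value <= f0 + 1e-9
  est <- family_untransform(fam, setNames(best$par, fam$par_names))
  boundary <- fam$par_names %in% c(fam$probs, unlist(fam$pairs)) &
    (est < 1e-6 | est > 1 - 1e-6)
  bic <- 2 * best$value + fam$n_params * log(ob$n_photons)
  structure(list(
    estimates = est,
    std_devs = setNames(rep(NA_real_, fam$n_params), fam$par_names),
    max_loglik = -best$value,
    bic = bic,
    n_photons = ob$n_photons,
    n_evaluations = ob$evals(),
    converged = improved && best$convergence == 0,
    boundary = setNames(boundary, fam$par_names),
    eta = setNames(best$par, fam$par_names),
    family = fam,
    options = opt
  ), class = "fret_fit")
}

#' @export
print.fret_fit <- function(x, ...) {
  cat("<fret_fit> ", x$family$name, ": ln L = ",
      format(x$max_loglik, digits = 10), ", BIC = ", format(x$bic, digits = 8),
      ", N = ", x$n_photons, " photons, converged: ", x$converged, "\n", sep = "")
  print(tidy(x), n = Inf)
  invisible(x)
}

#' @export
tidy.fret_fit <- function(x, ...) {
  tibble::tibble(term = names(x$estimates),
                 estimate = unname(x$estimates),
                 std.error = unname(x$std_devs))
}

#' @export
glance.fret_fit <- function(x, ...) {
  tibble::tibble(logLik = x$max_loglik, BIC = x$bic,
                 n_photons = x$n_photons, n_params = x$family$n_params,
                 n_evaluations = x$n_evaluations, converged = x$converged)
}

#' Curvature-based standard deviations
#'
#' Central finite-difference Hessian of the negative log-likelihood at the
#' maximum, in transformed coordinates (step 1e-4, Richardson-refined
#' diagonal at 5e-5), inverted to the covariance and mapped back to natural
#' units by the delta method. Parameters whose curvature is not positive
#' definite (flat directions, boundary estimates) keep `NA` standard
#' deviations rather than propagating NaN.
#'
#' @inheritParams fit_ml
#' @param fit A converged [fit_ml()] result.
#' @return The fit, with `std_devs` (and `vcov_eta`) filled in.
#' @export
error_bars <- function(data, family, fit) {
  fam <- if (missing(family) || is.null(family)) fit$family else as_family(family)
  if (!fit$converged) stop("fit did not converge; refusing error bars", call. = FALSE)
  segments <- prepare_segments(data, fam)
  ob <- make_objective(segments, fam)
  eta <- fit$eta
  P <- length(eta)
  h <- 1e-4
  f0 <- ob$obj(eta)
  H <- matrix(NA_real_, P, P)
  step <- function(i, s) {
    e <- eta
    e[i] <- e[i] + s
    e
  }
  for (i in seq_len(P)) {
    d1 <- (ob$obj(step(i, h)) - 2 * f0 + ob$obj(step(i, -h))) / h^2
    h2 <- h / 2
    d2 <- (ob$obj(step(i, h2)) - 2 * f0 + ob$obj(step(i, -h2))) / h2^2
    H[i, i] <- (4 * d2 - d1) / 3  # Richardson refinement
    if (i > 1) {
      for (j in seq_len(i - 1)) {
        epp <- step(i, h); epp[j] <- epp[j] + h
        epm <- step(i, h); epm[j] <- epm[j] - h
        emp <- step(i, -h); emp[j] <- emp[j] + h
        emm <- step(i, -h); emm[j] <- emm[j] - h
        H[i, j] <- H[j, i] <-
          (ob$obj(epp) - ob$obj(epm) - ob$obj(emp) + ob$obj(emm)) / (4 * h^2)
      }
    }
  }
  sd_eta <- rep(NA_real_, P)
  Sigma <- tryCatch(solve(H), error = function(e) NULL)
  usable <- !is.null(Sigma) && all(is.finite(Sigma))
  if (usable && any(diag(Sigma) <= 0)) {
    # keep only parameters with positive marginal curvature-variance
    ok <- diag(Sigma) > 0
  } else if (usable) {
    ok <- rep(TRUE, P)
  } else {
    ok <- rep(FALSE, P)
  }
  sds <- setNames(rep(NA_real_, P), names(eta))
  if (any(ok)) {
    # delta method: numeric Jacobian of the inverse transform
    J <- matrix(0, P, P)
    hj <- 1e-6
    for (j in seq_len(P)) {
      J[, j] <- (family_untransform(fam, step(j, hj)) -
                 family_untransform(fam, step(j, -hj))) / (2 * hj)
    }
    V <- J %*% Sigma %*% t(J)
    d <- diag(V)
    sds[ok & d > 0] <- sqrt(d[ok & d > 0])
  }
  sds[fit$boundary] <- NA_real_
  fit$std_devs <- sds
  fit$vcov_eta <- if (usable) Sigma else NULL
  fit
}

#' Delta-method uncertainty of a derived quantity
#'
#' Propagates the curvature covariance of a fit (from [error_bars()]) to a
#' scalar function of the natural-unit parameters, e.g. a state population
#' computed from fitted rates.
#'
#' @param fit A [fit_ml()] result with `vcov_eta` (run [error_bars()] first).
#' @param fun Function of a named parameter vector returning a scalar.
#' @return A list with `value` and `sd` (`NA` when the covariance is
#'   unavailable).
#' @export
delta_method_sd <- function(fit, fun) {
  value <- fun(fit$estimates)
  if (is.null(fit$vcov_eta)) return(list(value = value, sd = NA_real_))
  fam <- fit$family
  eta <- fit$eta
  h <- 1e-6
  g <- vapply(seq_along(eta), function(j) {
    ep <- eta
    ep[j] <- ep[j] + h
    em <- eta
    em[j] <- em[j] - h
    (fun(family_untransform(fam, ep)) - fun(family_untransform(fam, em))) / (2 * h)
  }, numeric(1))
  v <- as.numeric(t(g) %*% fit$vcov_eta %*% g)
  list(value = value, sd = if (v > 0) sqrt(v) else NA_real_)
}

#' Rank fitted models by BIC
#'
#' `BIC = -2 ln L + P ln N` with `N` the total photon count (the likelihood's
#' observation units) and `P` the family's free-parameter count. Smaller is
#' better. Statistical state-count selection deserves caution: measurement
#' heterogeneity and impurities can mimic extra states, so prior knowledge
#' should temper what BIC alone suggests.
#'
#' @param fits A list of `fret_fit` objects fitted to the same data.
#' @param data Optional dataset; when given, each fit's photon count is
#'   checked against it.
#' @return A tibble ranked by ascending BIC with `delta_bic` relative to the
#'   best model.
#' @export
compare_bic <- function(fits, data = NULL) {
  if (inherits(fits, "fret_fit")) fits <- list(fits)
  n <- unique(purrr::map_dbl(fits, "n_photons"))
  if (length(n) > 1) stop("fits were computed on different data", call. = FALSE)
  if (!is.null(data)) {
    rates <- trajectory_rates(data$photons)
    n_data <- sum(rates$n_photons[rates$class != "Donly"])
    if (n_data != n) stop("fits do not match the supplied data", call. = FALSE)
  }
  out <- purrr::map_dfr(fits, function(f) {
    tibble::tibble(model = f$family$name,
                   n_states = f$family$n_states,
                   n_params = f$family$n_params,
                   logLik = f$max_loglik, bic = f$bic)
  })
  out <- dplyr::arrange(out, .data$bic)
  dplyr::mutate(out, delta_bic = .data$bic - .data$bic[1])
}
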