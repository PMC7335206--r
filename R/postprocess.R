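# Photon-level state assignment, correlation analysis, and acceptor-fraction
# histograms.

#' Most probable state sequence at the single-photon level
#'
#' Viterbi decoding adapted to photon trajectories: maximizes over state
#' sequences the product of per-gap propagator entries and per-photon
#' emission factors (the single-path integrand of the likelihood), by
#' dynamic programming in the log domain with backtracking. Ties break
#' toward the lower state index.
#'
#' @param photons Photon table of a single trajectory.
#' @param model A [fret_model()] compatible with the trajectory's channels.
#' @return A tibble with `time`, `channel`, `state`, `label`; the path
#'   log-probability is in attribute `"logprob"`.
#' @export
viterbi_states <- function(photons, model) {
  photons <- tibble::as_tibble(photons)
  if (nrow(photons) == 0) {
    out <- tibble::tibble(time = double(), channel = character(),
                          state = integer(), label = character())
    attr(out, "logprob") <- 0
    return(out)
  }
  chan <- match(photons$channel, model$channels)
  if (anyNA(chan)) stop("photon channels incompatible with model", call. = FALSE)
  res <- cpp_viterbi(photons$time, chan - 1L, model$K, model$emission, model$p0)
  out <- tibble::tibble(time = photons$time, channel = photons$channel,
                        state = as.integer(res$path),
                        label = model$states[res$path])
  attr(out, "logprob") <- res$logprob
  out
}

#' Cross-correlation of binned channel counts
#'
#' For each qualifying segment computes
#' `C(tau) = <N_a(t + tau) N_b(t)> / (<N_a><N_b>) - 1` on binned counts and
#' averages the curves over segments (trajectories) longer than
#' `min_segment`. For a two-state system the donor-acceptor cross-correlation
#' decays as a single exponential with the relaxation rate.
#'
#' @param photons Photon table (or [fret_data()]).
#' @param pair Length-2 channel pair `c(alpha, beta)`.
#' @param bin_time Count bin width in seconds (default 10 us).
#' @param n_lags Number of lag bins.
#' @param min_segment Minimum segment span in seconds (default 10 ms).
#' @return A `fret_corr` tibble with `tau`, `correlation`, `n_segments`.
#' @export
cross_correlation <- function(photons, pair = c("A1", "D"), bin_time = 1e-5,
                              n_lags = 50, min_segment = 0.01) {
  if (inherits(photons, "fret_data")) photons <- photons$photons
  stopifnot(bin_time > 0, length(pair) == 2, all(pair %in% fret_channels))
  binned <- bin_trajectory(photons, bin_time)
  curves <- binned |>
    dplyr::group_by(.data$trajectory_id) |>
    dplyr::group_split() |>
    purrr::keep(~ (max(.x$bin) - min(.x$bin) + 1) * bin_time >= min_segment) |>
    purrr::map(function(tr) {
      nb <- max(tr$bin) - min(tr$bin) + 1L
      a <- b <- numeric(nb)
      a[tr$bin - min(tr$bin) + 1L] <- tr[[pair[1]]]
      b[tr$bin - min(tr$bin) + 1L] <- tr[[pair[2]]]
      ma <- mean(a)
      mb <- mean(b)
      if (ma == 0 || mb == 0) return(NULL)
      purrr::map_dbl(seq_len(min(n_lags, nb - 1L)), function(k) {
        mean(a[(k + 1):nb] * b[1:(nb - k)]) / (ma * mb) - 1
      })
    }) |>
    purrr::compact()
  if (length(curves) == 0) {
    stop("no segment longer than ", min_segment, " s with counts in both channels",
         call. = FALSE)
  }
  len <- min(lengths(curves))
  cc <- rowMeans(do.call(cbind, purrr::map(curves, ~ .x[seq_len(len)])))
  out <- tibble::tibble(tau = bin_time * seq_len(len), correlation = cc,
                        n_segments = length(curves))
  class(out) <- c("fret_corr", class(out))
  out
}

#' Per-bin acceptor fractions for histogramming
#'
#' Bins each trajectory (default 1 ms) and computes the uncorrected acceptor
#' fractions per bin: `eps1`, `eps2` for three-color classes and `eps` for
#' merged two-color classes. Bins with fewer than `min_photons` photons are
#' dropped (boundary bins at segment edges otherwise distort the histogram).
#'
#' @param data A [fret_data()] or photon table.
#' @param bin_time Bin width in seconds.
#' @param min_photons Minimum photons per retained bin.
#' @return A `fret_fractions` tibble with one row per retained bin:
#'   `trajectory_id`, `class`, `bin`, `n`, and `eps1`/`eps2`/`eps` (NA where
#'   not applicable).
#' @export
fraction_histograms <- function(data, bin_time = 1e-3, min_photons = 20) {
  photons <- if (inherits(data, "fret_data")) data$photons else tibble::as_tibble(data)
  stopifnot(bin_time > 0)
  if (nrow(photons) == 0) {
    out <- tibble::tibble(trajectory_id = character(), class = character(),
                          bin = integer(), n = integer(),
                          eps1 = double(), eps2 = double(), eps = double())
    class(out) <- c("fret_fractions", class(out))
    return(out)
  }
  merged <- photons |>
    dplyr::group_by(.data$trajectory_id) |>
    dplyr::group_split() |>
    purrr::map(~ merge_for_class(.x, .x$class[1])) |>
    dplyr::bind_rows()
  out <- bin_trajectory(merged, bin_time) |>
    dplyr::filter(.data$n >= min_photons) |>
    dplyr::mutate(
      eps1 = dplyr::if_else(.data$class %in% c("3c", "3c/DA1"),
                            .data$A1 / .data$n, NA_real_),
      eps2 = dplyr::if_else(.data$class %in% c("3c", "3c/DA1"),
                            .data$A2 / .data$n, NA_real_),
      eps = dplyr::case_when(
        .data$class == "DA1" ~ .data$A1 / .data$n,
        .data$class == "DA2" ~ .data$A2 / .data$n,
        TRUE ~ NA_real_
      )
    ) |>
    dplyr::select("trajectory_id", "class", "bin", "n", "eps1", "eps2", "eps")
  class(out) <- c("fret_fractions", class(out))
  out
}

#' Recoloring self-consistency check
#'
#' Recolors the dataset's arrival times under a fitted model (or an explicit
#' model per class) and compares the per-bin acceptor-fraction histograms of
#' the data and the recolored copy with a chi-squared test on pooled counts.
#' Under the generating model the histograms agree; a wrong relaxation rate
#' shows up as excess (slow exchange) or missing (fast exchange) bimodality.
#'
#' @param data A [fret_data()].
#' @param fit A converged [fit_ml()] result (or a named list of
#'   [fret_model()]s keyed by class).
#' @param seed Integer seed for the recoloring.
#' @param bin_time,min_photons,breaks Histogram controls.
#' @return A list with `observed` and `recolored` fraction tables and a
#'   `chisq` tibble (statistic, df, p.value per fraction).
#' @export
recolor_check <- function(data, fit, seed = NULL, bin_time = 1e-3,
                          min_photons = 20, breaks = seq(0, 1, by = 0.05)) {
  stopifnot(inherits(data, "fret_data"))
  if (!is.null(seed)) set.seed(seed)
  if (inherits(fit, "fret_fit")) {
    if (!fit$converged) stop("fit did not converge", call. = FALSE)
    fam <- fit$family
    params <- as.list(fit$estimates)
    model_for <- function(class, n) fam$build(params, class, n)
  } else {
    model_for <- function(class, n) fit[[class]]
  }
  rates <- trajectory_rates(data$photons)
  reco <- data$photons |>
    dplyr::group_by(.data$trajectory_id) |>
    dplyr::group_split() |>
    purrr::map(function(tr) {
      cls <- tr$class[1]
      if (cls == "Donly") return(tr)
      n <- rates$rate_ms[rates$trajectory_id == tr$trajectory_id[1]]
      model <- model_for(cls, ifelse(is.na(n), fret_n0, n))
      mg <- merge_for_class(tr, cls)
      mg$channel <- recolor(mg$time, model)
      # restore the original class label; channels already in merged space
      mg
    }) |>
    dplyr::bind_rows()
  obs <- fraction_histograms(data, bin_time, min_photons)
  sim <- fraction_histograms(fret_data(reco, kind = data$kind), bin_time, min_photons)
  chisq <- purrr::map_dfr(c("eps1", "eps2", "eps"), function(col) {
    o <- obs[[col]][!is.na(obs[[col]])]
    s <- sim[[col]][!is.na(sim[[col]])]
    if (length(o) == 0 || length(s) == 0) return(NULL)
    co <- table(cut(o, breaks, include.lowest = TRUE))
    cs <- table(cut(s, breaks, include.lowest = TRUE))
    keep <- co + cs > 0
    ct <- suppressWarnings(stats::chisq.test(rbind(co[keep], cs[keep])))
    tibble::tibble(fraction = col, statistic = unname(ct$statistic),
                   df = unname(ct$parameter), p.value = ct$p.value)
  })
  list(observed = obs, recolored = sim, chisq = chisq)
}
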