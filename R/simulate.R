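# Generative photon simulator and recoloring engine. Arrival times are a
# homogeneous Poisson process (recoloring of experimental trajectories
# preserves their arrival times, so a homogeneous process is the minimal
# faithful generative stand-in); colors are drawn from an exact
# continuous-time Markov state path. All randomness goes through R's RNG, so
# set.seed() (or the `seed` arguments) makes everything reproducible.

#' Sample a state path of a kinetic model
#'
#' Exact Gillespie realization: exponential dwells with the state's total
#' exit rate, jumps proportional to the column rates of `K`. A state with no
#' exit rate (photobleached/absorbing) is held forever.
#'
#' @param model A [fret_model()].
#' @param duration Path length in seconds.
#' @param seed Optional integer seed.
#' @return A tibble with `time` (entry time, s), `state` (index), `label`.
#' @export
simulate_state_path <- function(model, duration, seed = NULL) {
  stopifnot(duration > 0)
  if (!is.null(seed)) set.seed(seed)
  res <- cpp_state_path(model$K, model$p0, duration)
  tibble::tibble(time = res$time, state = res$state,
                 label = model$states[res$state])
}

#' Recolor photon arrival times under a kinetic/emission model
#'
#' Draws a state path over the span of the arrival times, then draws each
#' photon's detection channel from its state's emission fractions. The
#' arrival times are preserved; only the colors are new. Recoloring
#' experimental or simulated trajectories under fitted parameters is the
#' standard way to validate a model against the data that produced it.
#'
#' @param times Sorted photon arrival times (seconds).
#' @param model A [fret_model()].
#' @param seed Optional integer seed.
#' @return Character vector of channel labels, one per photon.
#' @export
recolor <- function(times, model, seed = NULL) {
  if (is.unsorted(times, strictly = FALSE)) stop("times must be sorted", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (length(times) == 0) return(character(0))
  code <- cpp_recolor(times, model$K, model$emission, model$p0)
  model$channels[code + 1L]
}

#' Simulate photon trajectories
#'
#' Homogeneous Poisson arrivals at `rate_ms` photons per ms over `duration`
#' seconds, colored by [recolor()] under `model`, optionally corrupted by
#' the forward distortion model (the exact inverse, in expectation, of the
#' correction chain): direct-excitation acceptor photons are added as
#' independent Poisson streams, then donor/A1 photons are misassigned with
#' the leak probabilities (`l1`, `l2`, `l12`), then background photons are
#' added per channel.
#'
#' @param model A [fret_model()] (its channels decide 2c vs 3c).
#' @param rate_ms Mean photon count rate (photons per ms).
#' @param duration Trajectory duration (seconds).
#' @param n_trajectories Number of trajectories.
#' @param class Segment class label for the output.
#' @param distortion Optional [correction_factors()]; `NULL` leaves the
#'   photons ideal. Three-color direct excitation additionally needs
#'   `efficiencies = c(E1=, E2=, E12=)`.
#' @param efficiencies True efficiency triplet used by the three-color
#'   direct-excitation forward model.
#' @param kind Experiment kind of the returned dataset.
#' @param seed Optional integer seed.
#' @param id_prefix Trajectory id prefix.
#' @return A [fret_data()].
#' @export
simulate_photons <- function(model, rate_ms, duration, n_trajectories = 1,
                             class = "3c", distortion = NULL,
                             efficiencies = NULL,
                             kind = c("folding", "binding"),
                             seed = NULL, id_prefix = "sim") {
  kind <- match.arg(kind)
  if (!is.null(seed)) set.seed(seed)
  rate_s <- rate_ms * 1e3
  trajs <- purrr::map(seq_len(n_trajectories), function(i) {
    N <- rpois(1, rate_s * duration)
    times <- untie_times(sort(runif(N, 0, duration)))
    channel <- recolor(times, model)
    ph <- tibble::tibble(time = times, channel = channel)
    if (!is.null(distortion)) {
      ph <- distort_photons(ph, model, rate_s, duration, distortion, efficiencies)
    }
    ph$trajectory_id <- sprintf("%s%03d", id_prefix, i)
    ph$class <- class
    ph[, c("trajectory_id", "class", "time", "channel")]
  })
  fret_data(dplyr::bind_rows(trajs), corrections = distortion, kind = kind)
}

# forward corruption: direct excitation -> leak -> background
distort_photons <- function(ph, model, rate_s, duration, factors, efficiencies) {
  three_color <- length(model$channels) == 3
  # mean ideal channel rates from the initial populations
  shares <- as.numeric(crossprod(model$p0, model$emission))
  names(shares) <- model$channels
  if (three_color) {
    if (is.null(efficiencies)) {
      if (factors$f1dir > 0 || factors$f2dir > 0) {
        stop("three-color direct excitation needs the true efficiencies", call. = FALSE)
      }
      efficiencies <- c(E1 = 0, E2 = 0, E12 = 0)
    }
    nD <- rate_s * shares[["D"]]
    nA1 <- rate_s * shares[["A1"]]
    nA2 <- rate_s * shares[["A2"]]
    kex <- nA1 / factors$gamma1 + nA2 / factors$gamma2 + nD
    dir1 <- factors$gamma1 * kex * factors$f1dir * (1 - efficiencies[["E12"]])
    dir2 <- factors$gamma2 * kex *
      (factors$f1dir * efficiencies[["E12"]] + factors$f2dir)
    ph <- add_poisson_photons(ph, dir1, duration, "A1")
    ph <- add_poisson_photons(ph, dir2, duration, "A2")
    # leak: D -> A1 (l1), D -> A2 (l2); A1 -> A2 (l12)
    u <- runif(nrow(ph))
    isD <- ph$channel == "D"
    ph$channel[isD & u < factors$l1] <- "A1"
    ph$channel[isD & u >= factors$l1 & u < factors$l1 + factors$l2] <- "A2"
    isA1 <- !isD & ph$channel == "A1"
    ph$channel[isA1 & u < factors$l12] <- "A2"
    ph <- add_poisson_photons(ph, factors$b_A1 * 1e3, duration, "A1")
    ph <- add_poisson_photons(ph, factors$b_A2 * 1e3, duration, "A2")
    ph <- add_poisson_photons(ph, factors$b_D * 1e3, duration, "D")
  } else {
    acceptor <- setdiff(model$channels, "D")
    nD <- rate_s * shares[["D"]]
    nA <- rate_s * shares[[acceptor]]
    dirA <- (nA + factors$gamma * nD) * factors$fdir
    ph <- add_poisson_photons(ph, dirA, duration, acceptor)
    u <- runif(nrow(ph))
    ph$channel[ph$channel == "D" & u < factors$l] <- acceptor
    ph <- add_poisson_photons(ph, factors$b_A * 1e3, duration, acceptor)
    ph <- add_poisson_photons(ph, factors$b_D * 1e3, duration, "D")
  }
  ph <- ph[order(ph$time), ]
  ph$time <- untie_times(ph$time)
  ph
}

# runif has 32-bit resolution, so sorted draws can tie at realistic photon
# counts; nudge ties upward by femtoseconds (far below any physical scale)
untie_times <- function(times) {
  while (length(times) > 1 && any(diff(times) <= 0)) {
    i <- which(diff(times) <= 0) + 1L
    times[i] <- times[i - 1L] + 1e-15 * (1 + abs(times[i - 1L]))
    times <- sort(times)
  }
  times
}

add_poisson_photons <- function(ph, rate_s, duration, channel) {
  if (rate_s <= 0) return(ph)
  N <- rpois(1, rate_s * duration)
  if (N == 0) return(ph)
  dplyr::bind_rows(ph, tibble::tibble(time = runif(N, 0, duration),
                                      channel = channel))
}

#' Benchmark datasets sweeping the relaxation rate
#'
#' Emits simulated datasets mimicking the recoloring benchmark designs:
#' two-state folding at ~80 photons/ms with folded populations
#' `{0.3, 0.47, 0.63}`, or two-state binding at ~65 photons/ms with bound
#' fractions `{0.3, 0.5, 0.7}`, sweeping the relaxation rate over
#' `k_over_n` (relative to the count rate) with five replicate seeds per
#' grid point.
#'
#' @param config `"folding"` or `"binding"`.
#' @param k_over_n Relaxation rates as multiples of the photon count rate
#'   (rates and count rate on the same per-ms scale).
#' @param p_grid Folded (or bound) populations; defaults per config.
#' @param rate_ms Count rate (photons per ms); default 80 (folding) or
#'   65 (binding).
#' @param n_photons Target photons per dataset.
#' @param n_seeds Replicates per grid point.
#' @param seed Base seed; replicate seeds derive from it deterministically.
#' @param eps Per-state emission fractions of the simulated reporter
#'   (three-color: lists `eps1`, `eps2` of per-state values).
#' @return A tibble with the grid and a `data` list-column of [fret_data()].
#' @export
make_benchmark <- function(config = c("folding", "binding"),
                           k_over_n = c(0.01, 0.1, 0.5, 1),
                           p_grid = NULL, rate_ms = NULL,
                           n_photons = 3e5, n_seeds = 5, seed = 1,
                           eps = list(eps1 = c(0.55, 0.25), eps2 = c(0.25, 0.2))) {
  config <- match.arg(config)
  p_grid <- p_grid %||% if (config == "folding") c(0.3, 0.47, 0.63) else c(0.3, 0.5, 0.7)
  rate_ms <- rate_ms %||% if (config == "folding") 80 else 65
  duration <- n_photons / (rate_ms * 1e3)
  grid <- tidyr::expand_grid(p = p_grid, k_over_n = k_over_n,
                             replicate = seq_len(n_seeds))
  grid$seed <- seed + 7919L * seq_len(nrow(grid))
  grid$data <- purrr::pmap(grid, function(p, k_over_n, replicate, seed) {
    k <- k_over_n * rate_ms * 1e3  # per second
    prefix <- sprintf("bm_p%02.0f_k%03.0f_r%d_", 100 * p, 100 * k_over_n, replicate)
    if (config == "folding") {
      model <- build_folding_3c(k * p, k * (1 - p), eps$eps1, eps$eps2)
      simulate_photons(model, rate_ms, duration, class = "3c", seed = seed,
                       id_prefix = prefix)
    } else {
      model <- build_binding_3cDA1(k * p, k * (1 - p), phi = 0.9,
                                   kb2p = 2, kd2p = 1,
                                   eps1 = c(0.55, 0.25, 0.6),
                                   eps2 = c(0.25, 0.05, 0.02))
      simulate_photons(model, rate_ms, duration, class = "3c/DA1",
                       kind = "binding", seed = seed, id_prefix = prefix)
    }
  })
  grid
}
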