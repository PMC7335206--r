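# ggplot2 displays for the result types.

#' @export
autoplot.fret_fractions <- function(object, binwidth = 0.02, ...) {
  long <- object |>
    tidyr::pivot_longer(cols = c("eps1", "eps2", "eps"),
                        names_to = "fraction", values_to = "value") |>
    dplyr::filter(!is.na(.data$value))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "grey35", colour = "white", linewidth = 0.1) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$class),
                        cols = ggplot2::vars(.data$fraction),
                        scales = "free_y") +
    ggplot2::labs(x = "acceptor photon fraction", y = "bins") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.fret_corr <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$tau, y = .data$correlation)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(tau ~ "(s)"), y = expression(C(tau))) +
    ggplot2::theme_minimal()
}

#' Plot a state path over a binned trajectory
#'
#' Overlays a Viterbi (or simulated) state path on the binned per-channel
#' count trace of a trajectory.
#'
#' @param photons Photon table of one trajectory.
#' @param states Output of [viterbi_states()] for the same photons.
#' @param bin_time Count bin width (s).
#' @export
plot_state_path <- function(photons, states, bin_time = 1e-3) {
  binned <- bin_trajectory(photons, bin_time) |>
    tidyr::pivot_longer(cols = dplyr::any_of(fret_channels),
                        names_to = "channel", values_to = "counts")
  ggplot2::ggplot() +
    ggplot2::geom_step(data = binned,
                       ggplot2::aes(x = .data$t_mid, y = .data$counts,
                                    colour = .data$channel)) +
    ggplot2::geom_rug(data = states,
                      ggplot2::aes(x = .data$time, colour = .data$label),
                      sides = "t", length = ggplot2::unit(0.03, "npc")) +
    ggplot2::scale_colour_brewer(palette = "Dark2") +
    ggplot2::labs(x = "time (s)", y = sprintf("counts / %g ms", bin_time * 1e3)) +
    ggplot2::theme_minimal()
}

#' Plot parameter recovery across a benchmark grid
#'
#' @param results Tibble with columns `k_over_n`, `p`, `estimate`, `truth`,
#'   and `parameter`.
#' @export
plot_recovery <- function(results) {
  ggplot2::ggplot(results,
                  ggplot2::aes(x = .data$k_over_n, y = .data$estimate,
                               colour = factor(.data$p))) +
    ggplot2::geom_point(position = ggplot2::position_jitter(width = 0.02, height = 0)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$truth), linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(ggplot2::vars(.data$parameter), scales = "free_y") +
    ggplot2::labs(x = "relaxation rate / count rate", colour = "population") +
    ggplot2::theme_minimal()
}
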