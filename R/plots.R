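#' Plot a family of scaled population trajectories
#'
#' Draws \eqn{f(s) = N(s)/N_{eq}} for several initial conditions `f0` at a
#' common `n_ratio`. Super-critical starts (`f0 > n_ratio`) are drawn up to
#' just below their blow-up time.
#'
#' @param f0_set numeric vector of initial scaled populations.
#' @param n_ratio dimensionless ratio \eqn{\gamma / k_E}.
#' @param s_max right edge of the scaled-time axis.
#' @param n_points grid resolution per curve.
#' @return A ggplot object.
#' @examples
#' plot_population_trajectories(c(0, 0.5, 1, 2, 3.3, 3.5), n_ratio = 3.3)
#' @export
plot_population_trajectories <- function(f0_set, n_ratio, s_max = 4,
                                         n_points = 200) {
  dat <- purrr::map_dfr(f0_set, function(f0) {
    s_top <- if (f0 > n_ratio) {
      min(s_max, 0.98 * divergence_time(f0, n_ratio))
    } else s_max
    population_trajectory(f0, n_ratio, seq(0, s_top, length.out = n_points)) |>
      dplyr::mutate(f0 = f0)
  })
  ggplot2::ggplot(dat, ggplot2::aes(.data$s, .data$f,
                                    colour = factor(.data$f0))) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = c(1, n_ratio), linetype = "dashed",
                        linewidth = 0.3) +
    ggplot2::labs(x = expression(s == k[E] * t ~ "(time in units of" ~ tau[E] * ")"),
                  y = expression(f == N / N[eq]),
                  colour = expression(f[0])) +
    ggplot2::coord_cartesian(ylim = c(0, n_ratio * 1.5)) +
    ggplot2::theme_minimal()
}

#' Plot the equilibrium genotype distribution against the invariant
#'
#' Equilibrium probabilities of the three genotype subgroups as functions of
#' the conserved difference \eqn{\Delta P_0 \in [-1, 1]}.
#'
#' @param n_points grid resolution.
#' @return A ggplot object.
#' @export
plot_equilibrium_distribution <- function(n_points = 201) {
  dat <- equilibrium_distribution(seq(-1, 1, length.out = n_points)) |>
    tidyr::pivot_longer(c("P_N", "P_S", "P_NS"),
                        names_to = "subgroup", values_to = "probability")
  ggplot2::ggplot(dat, ggplot2::aes(.data$delta_P0, .data$probability,
                                    colour = .data$subgroup)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(Delta * P[0]), y = "equilibrium probability",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot genotype dilution across immigration cycles
#'
#' Equilibrium subgroup probabilities after `j` cycles at immigration
#' fraction `chi` (resident homozygotes decay as \eqn{(1-\chi)^{2j}}).
#'
#' @param chi immigration fraction per cycle.
#' @param j_max largest cycle number shown.
#' @return A ggplot object.
#' @export
plot_cycle_dilution <- function(chi = 2 / 30, j_max = 60) {
  dat <- subgroup_probs_after_cycles(0:j_max, chi) |>
    tidyr::pivot_longer(c("P_N", "P_S", "P_NS"),
                        names_to = "subgroup", values_to = "probability")
  ggplot2::ggplot(dat, ggplot2::aes(.data$j, .data$probability,
                                    colour = .data$subgroup)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "immigration cycle j", y = "equilibrium probability",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the dilution-time curves
#'
#' Total time \eqn{T_f(\chi) = J_f(\chi)\,\Delta t} to reach the target
#' immigrant-homozygote probability, one curve per inter-cycle interval.
#'
#' @inheritParams dilution_time_curve
#' @param what `"T_f"` (years) or `"J_f"` (cycle count) on the y axis.
#' @return A ggplot object.
#' @export
plot_dilution_time <- function(P_Sf = 0.990,
                               chi_grid = seq(0.005, 0.09, length.out = 120),
                               delta_t = c(50, 100, 150),
                               what = c("T_f", "J_f")) {
  what <- match.arg(what)
  dat <- dilution_time_curve(P_Sf, chi_grid, delta_t)
  if (what == "J_f") {
    dat <- dplyr::distinct(dat, .data$chi, .data$J_f)
    p <- ggplot2::ggplot(dat, ggplot2::aes(.data$chi, .data$J_f)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = expression(chi), y = expression(J[f]))
  } else {
    p <- ggplot2::ggplot(dat, ggplot2::aes(.data$chi, .data$T_f,
                                           colour = factor(.data$delta_t))) +
      ggplot2::geom_line() +
      ggplot2::labs(x = expression(chi), y = expression(T[f] ~ "(years)"),
                    colour = expression(Delta * t ~ "(yr)"))
  }
  p + ggplot2::theme_minimal()
}

#' Plot a simulated ensemble against the closed forms
#'
#' Ensemble-mean genotype probabilities at each sample time (points) over the
#' analytic prediction (lines).
#'
#' @param object an `nd_sim` object.
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.nd_sim <- function(object, ...) {
  tr <- object$trajectory
  sim_long <- tr |>
    dplyr::select("time", "locus", P_N = "P_N_hat", P_S = "P_S_hat",
                  P_NS = "P_NS_hat") |>
    tidyr::pivot_longer(c("P_N", "P_S", "P_NS"),
                        names_to = "subgroup", values_to = "probability")
  ana_long <- tr |>
    dplyr::select("time", "P_N", "P_S", "P_NS") |>
    dplyr::distinct() |>
    tidyr::pivot_longer(c("P_N", "P_S", "P_NS"),
                        names_to = "subgroup", values_to = "probability")
  ggplot2::ggplot(sim_long, ggplot2::aes(.data$time, .data$probability,
                                         colour = .data$subgroup)) +
    ggplot2::geom_line(data = ana_long, linewidth = 0.4) +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "time (years)", y = "ensemble-mean probability",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
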