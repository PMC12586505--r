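#' Regenerate the model's standard figures as CSV + plot files
#'
#' Writes, for each requested figure, the plotted curves as a CSV file (the
#' tested artifact) and a PDF rendering (a convenience):
#' \describe{
#'   \item{1}{scaled population trajectories \eqn{f(s)} for
#'     `f0` in \{0, 0.5, 1, 2, 3.3, 3.5\} at `n_ratio = 3.3` (the `f0` set is
#'     a representative choice covering both convergent and divergent
#'     starts).}
#'   \item{2}{equilibrium genotype distribution over
#'     \eqn{\Delta P_0 \in [-1, 1]}.}
#'   \item{3}{equilibrium subgroup probabilities across immigration cycles at
#'     `chi = 2/30`, \eqn{\Delta P_{0,0} = 1}.}
#'   \item{4}{cycle count \eqn{J_f(\chi)} for targets
#'     `P_Sf` in \{0.990, 0.995, 0.999\}.}
#'   \item{5}{total time \eqn{T_f(\chi)} for `P_Sf = 0.990` at
#'     `delta_t` in \{50, 100, 150\} years.}
#' }
#'
#' @param which integer vector of figure ids within 1..5.
#' @param outdir output directory (created if missing).
#' @return Invisibly, a character vector of the files written.
#' @examples
#' \dontrun{
#' regenerate_figures(1:5, tempdir())
#' }
#' @export
regenerate_figures <- function(which = 1:5, outdir = ".") {
  stopifnot(all(which %in% 1:5))
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  written <- character()
  emit <- function(id, dat, plot) {
    csv <- file.path(outdir, sprintf("fig%d.csv", id))
    pdf_file <- file.path(outdir, sprintf("fig%d.pdf", id))
    readr::write_csv(dat, csv)
    ggplot2::ggsave(pdf_file, plot, width = 6, height = 4)
    c(csv, pdf_file)
  }
  for (id in which) {
    files <- switch(
      as.character(id),
      "1" = {
        f0_set <- c(0, 0.5, 1, 2, 3.3, 3.5)
        dat <- purrr::map_dfr(f0_set, function(f0) {
          s_top <- if (f0 > 3.3) 0.98 * divergence_time(f0, 3.3) else 4
          population_trajectory(f0, 3.3, seq(0, s_top, length.out = 200)) |>
            dplyr::mutate(f0 = f0, .before = 1)
        })
        emit(1, dat, plot_population_trajectories(f0_set, 3.3))
      },
      "2" = {
        dat <- equilibrium_distribution(seq(-1, 1, length.out = 201))
        emit(2, dat, plot_equilibrium_distribution())
      },
      "3" = {
        dat <- subgroup_probs_after_cycles(0:60, chi = 2 / 30) |>
          dplyr::left_join(allele_frequencies(0:60, chi = 2 / 30), by = "j") |>
          dplyr::rename(p = "p_sapiens", q = "q_neanderthal")
        emit(3, dat, plot_cycle_dilution(chi = 2 / 30, j_max = 60))
      },
      "4" = {
        chi_grid <- seq(0.005, 0.09, length.out = 120)
        dat <- purrr::map_dfr(c(0.990, 0.995, 0.999), function(ps) {
          tibble::tibble(P_Sf = ps, chi = chi_grid,
                         J_f = vapply(chi_grid, cycles_to_target,
                                      numeric(1), P_Sf = ps))
        })
        pl <- ggplot2::ggplot(dat, ggplot2::aes(.data$chi, .data$J_f,
                                                colour = factor(.data$P_Sf))) +
          ggplot2::geom_line() +
          ggplot2::labs(x = expression(chi), y = expression(J[f]),
                        colour = expression(P[paste(S, ",", f)])) +
          ggplot2::theme_minimal()
        emit(4, dat, pl)
      },
      "5" = {
        dat <- dilution_time_curve(0.990, seq(0.005, 0.09, length.out = 120),
                                   c(50, 100, 150))
        emit(5, dat, plot_dilution_time())
      }
    )
    written <- c(written, files)
  }
  invisible(written)
}
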