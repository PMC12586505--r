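#' Immigration-cycle schedule
#'
#' Packages the per-cycle immigration fraction \eqn{\chi = \delta/N_{eq}}, the
#' mean inter-cycle interval \eqn{\Delta t}, and the pre-immigration
#' \eqn{\Delta P_{0,0}} (1 for an initially pure resident population). Two
#' advisories are attached as warnings: the perturbative treatment assumes
#' small per-cycle fractions (`chi > 2/30` is flagged), and the
#' equilibrium-between-cycles approximation needs \eqn{\Delta t / \tau_E > 2}.
#'
#' @param chi immigration fraction per cycle, in `(0, 1)`.
#' @param delta_t mean interval between cycles (years), `> 0`.
#' @param delta_P00 initial \eqn{\Delta P_0} before any cycle, in `[-1, 1]`.
#' @param tau_E exit mean lifetime (years) used for the `delta_t` advisory;
#'   `NULL` skips the check.
#' @return A one-row tibble with columns `chi`, `delta_t`, `delta_P00`.
#' @examples
#' cycle_schedule(chi = 0.02, delta_t = 100, tau_E = 24)
#' @export
cycle_schedule <- function(chi, delta_t, delta_P00 = 1, tau_E = NULL) {
  stopifnot(is.numeric(chi), is.numeric(delta_t), is.numeric(delta_P00),
            length(chi) == 1L, length(delta_t) == 1L,
            length(delta_P00) == 1L)
  if (chi <= 0 || chi >= 1) stop("chi must lie in (0, 1)", call. = FALSE)
  if (delta_t <= 0) stop("delta_t must be positive", call. = FALSE)
  if (abs(delta_P00) > 1) stop("|delta_P00| must not exceed 1", call. = FALSE)
  if (chi > 2 / 30) {
    warning("chi = ", format(chi, digits = 4), " > 2/30: the model assumes ",
            "small per-cycle genetic perturbations", call. = FALSE)
  }
  if (!is.null(tau_E) && delta_t / tau_E <= 2) {
    warning("delta_t/tau_E = ", format(delta_t / tau_E, digits = 4),
            " <= 2: the equilibrium-between-cycles approximation needs ",
            "delta_t > 2 tau_E", call. = FALSE)
  }
  tibble::tibble(chi = chi, delta_t = delta_t, delta_P00 = delta_P00)
}

check_chi <- function(chi, allow_zero = TRUE) {
  stopifnot(is.numeric(chi), length(chi) == 1L)
  lo <- if (allow_zero) 0 else .Machine$double.xmin
  if (chi < lo - 1e-15 || chi >= 1) {
    stop("chi must lie in [", if (allow_zero) "0" else ">0", ", 1)",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Apply one immigration cycle to an equilibrated distribution
#'
#' A cycle instantaneously replaces a fraction `chi` of the stationary
#' population with immigrant homozygotes:
#' \deqn{P_{S,j}(0) = P_{S,j-1}(\infty) + \chi - P_{S,j-1}(\infty)\,\chi,
#'       \qquad P_{N,j}(0) = P_{N,j-1}(\infty)(1 - \chi),}
#' with the heterozygotes likewise scaled by \eqn{(1 - \chi)}. The implied
#' update of the invariant is
#' \eqn{\Delta P_{0,j} = \Delta P_{0,j-1}(1 - \chi) - \chi}.
#'
#' @param prev_eq the pre-cycle (equilibrated) genotype distribution; length-3
#'   numeric `(P_N, P_S, P_NS)` or a one-row data frame.
#' @param chi immigration fraction, in `[0, 1)`.
#' @return A one-row tibble with columns `P_N`, `P_S`, `P_NS`: the
#'   post-replacement initial distribution of the new cycle.
#' @examples
#' apply_cycle(c(1, 0, 0), chi = 2 / 30)
#' @export
apply_cycle <- function(prev_eq, chi) {
  prev_eq <- as_genotype_dist(prev_eq)
  check_chi(chi)
  tibble::tibble(
    P_N = prev_eq$P_N * (1 - chi),
    P_S = prev_eq$P_S + chi - prev_eq$P_S * chi,
    P_NS = prev_eq$P_NS * (1 - chi)
  )
}

#' Conserved difference after j immigration cycles
#'
#' Closed-form iteration of the per-cycle update:
#' \deqn{\Delta P_{0,j} = (1 - \chi)^j (1 + \Delta P_{0,0}) - 1,}
#' monotonically decreasing in `j` towards \eqn{-1} (complete dilution).
#'
#' @param j number of completed cycles (non-negative integer; vectorised).
#' @param chi immigration fraction, in `[0, 1)`.
#' @param delta_P00 value of \eqn{\Delta P_0} before any cycle (default 1:
#'   pure resident homozygote start).
#' @return Numeric vector of \eqn{\Delta P_{0,j}}.
#' @examples
#' delta_p_after_cycles(0:10, chi = 2 / 30)
#' @export
delta_p_after_cycles <- function(j, chi, delta_P00 = 1) {
  stopifnot(is.numeric(j), is.numeric(delta_P00), length(delta_P00) == 1L)
  if (any(j < 0) || any(j != floor(j))) {
    stop("j must contain non-negative integers", call. = FALSE)
  }
  check_chi(chi)
  if (abs(delta_P00) > 1) stop("|delta_P00| must not exceed 1", call. = FALSE)
  (1 - chi)^j * (1 + delta_P00) - 1
}

#' Equilibrium subgroup probabilities after j immigration cycles
#'
#' Closed forms for an initially pure resident population
#' (\eqn{\Delta P_{0,0} = 1}):
#' \deqn{P_{N,j}(\infty) = (1 - \chi)^{2j},\qquad
#'       P_{S,j}(\infty) = \left[(1 - \chi)^j - 1\right]^2,\qquad
#'       P_{NS,j}(\infty) = \frac{1 - \left[2 (1 - \chi)^j - 1\right]^2}{2}.}
#'
#' @inheritParams delta_p_after_cycles
#' @return A tibble with columns `j`, `P_N`, `P_S`, `P_NS`.
#' @examples
#' subgroup_probs_after_cycles(0:20, chi = 2 / 30)
#' @export
subgroup_probs_after_cycles <- function(j, chi) {
  stopifnot(is.numeric(j))
  if (any(j < 0) || any(j != floor(j))) {
    stop("j must contain non-negative integers", call. = FALSE)
  }
  check_chi(chi)
  w <- (1 - chi)^j
  tibble::tibble(
    j = j,
    P_N = w^2,
    P_S = (w - 1)^2,
    P_NS = (1 - (2 * w - 1)^2) / 2
  )
}

#' Allele frequencies after j immigration cycles
#'
#' The immigrant (`p`) and resident (`q`) allele frequencies carried by the
#' equilibrium genotype distribution,
#' \deqn{p_j = P_{S,j}(\infty) + \tfrac12 P_{NS,j}(\infty) = 1 - (1-\chi)^j,
#'       \qquad q_j = (1-\chi)^j,}
#' which coincide with the allele-frequency recursion of the classical
#' continent-island model with per-cycle migration fraction \eqn{\chi}.
#'
#' @inheritParams subgroup_probs_after_cycles
#' @return A tibble with columns `j`, `p_sapiens`, `q_neanderthal`.
#' @examples
#' allele_frequencies(0:10, chi = 0.02)
#' @export
allele_frequencies <- function(j, chi) {
  stopifnot(is.numeric(j))
  if (any(j < 0) || any(j != floor(j))) {
    stop("j must contain non-negative integers", call. = FALSE)
  }
  check_chi(chi)
  q <- (1 - chi)^j
  tibble::tibble(j = j, p_sapiens = 1 - q, q_neanderthal = q)
}

#' Number of immigration cycles to reach a dilution target
#'
#' Inverts the immigrant-homozygote closed form for the cycle count needed to
#' reach a final probability \eqn{P_{S,f}}:
#' \deqn{J_f = \frac{\ln\left(1 - \sqrt{P_{S,f}}\right)}{\ln(1 - \chi)}.}
#' `J_f` is returned as a real number (the underlying curve is continuous);
#' use [whole_cycles()] for the smallest integer schedule reaching the target.
#'
#' @param P_Sf target final immigrant-homozygote probability, in `(0, 1)`.
#' @param chi immigration fraction per cycle, in `(0, 1)`.
#' @return Real-valued cycle count \eqn{J_f}.
#' @examples
#' cycles_to_target(0.990, chi = 2 / 30) # about 76.8
#' @export
cycles_to_target <- function(P_Sf, chi) {
  stopifnot(is.numeric(P_Sf), length(P_Sf) == 1L)
  if (P_Sf <= 0 || P_Sf >= 1) {
    stop("P_Sf must lie strictly inside (0, 1): the cycle count has a log ",
         "singularity at the endpoints", call. = FALSE)
  }
  check_chi(chi, allow_zero = FALSE)
  log(1 - sqrt(P_Sf)) / log(1 - chi)
}

#' @rdname cycles_to_target
#' @return `whole_cycles()`: the ceiling of \eqn{J_f}, i.e. the smallest
#'   integer number of cycles whose equilibrium \eqn{P_{S,j}(\infty)} meets or
#'   exceeds `P_Sf`.
#' @export
whole_cycles <- function(P_Sf, chi) {
  ceiling(cycles_to_target(P_Sf, chi))
}

#' Total dilution time
#'
#' Total time to reach the dilution target, \eqn{T_f(\chi) = J_f(\chi)\,
#' \Delta t}, with \eqn{J_f} from [cycles_to_target()].
#'
#' @inheritParams cycles_to_target
#' @param delta_t mean interval between immigration cycles (years), `> 0`.
#' @return Total time \eqn{T_f} in years.
#' @examples
#' total_time(0.990, chi = 0.02, delta_t = 100) # about 26,200 years
#' @export
total_time <- function(P_Sf, chi, delta_t) {
  stopifnot(is.numeric(delta_t), length(delta_t) == 1L)
  if (delta_t <= 0) stop("delta_t must be positive", call. = FALSE)
  cycles_to_target(P_Sf, chi) * delta_t
}

#' Immigration fraction needed to dilute within a given time
#'
#' Closed-form inversion of the dilution-time relation: the \eqn{\chi} for
#' which \eqn{T_f(\chi) = J_f(\chi)\,\Delta t} equals the requested total
#' time,
#' \deqn{\chi = 1 - \left(1 - \sqrt{P_{S,f}}\right)^{\Delta t / T_f}.}
#'
#' @inheritParams total_time
#' @param T_f requested total dilution time (years), `> 0`.
#' @return The immigration fraction \eqn{\chi} in `(0, 1)`.
#' @examples
#' chi_for_time(0.990, delta_t = 50, T_f = 30000) # about 0.0088
#' @export
chi_for_time <- function(P_Sf, delta_t, T_f) {
  stopifnot(is.numeric(P_Sf), is.numeric(delta_t), is.numeric(T_f),
            length(P_Sf) == 1L, length(delta_t) == 1L, length(T_f) == 1L)
  if (P_Sf <= 0 || P_Sf >= 1) {
    stop("P_Sf must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (delta_t <= 0 || T_f <= 0) {
    stop("delta_t and T_f must be positive", call. = FALSE)
  }
  1 - (1 - sqrt(P_Sf))^(delta_t / T_f)
}

#' Dilution-time curve over an immigration-fraction grid
#'
#' Tabulates \eqn{J_f(\chi)} and \eqn{T_f(\chi) = J_f(\chi)\,\Delta t} over a
#' grid of immigration fractions, one row per (`chi`, `delta_t`) pair.
#'
#' @inheritParams cycles_to_target
#' @param chi_grid numeric vector of immigration fractions in `(0, 1)`.
#' @param delta_t numeric vector of inter-cycle intervals (years).
#' @return A tibble with columns `chi`, `delta_t`, `J_f`, `T_f`.
#' @examples
#' dilution_time_curve(0.990, seq(0.005, 0.08, by = 0.005), c(50, 100, 150))
#' @export
dilution_time_curve <- function(P_Sf, chi_grid, delta_t) {
  stopifnot(is.numeric(chi_grid), is.numeric(delta_t))
  J <- vapply(chi_grid, function(ch) cycles_to_target(P_Sf, ch), numeric(1))
  tidyr::expand_grid(
    tibble::tibble(chi = chi_grid, J_f = J),
    delta_t = delta_t
  ) |>
    dplyr::mutate(T_f = .data$J_f * .data$delta_t) |>
    dplyr::select("chi", "delta_t", "J_f", "T_f")
}
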