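#' Demographic parameters of the reference tribe
#'
#' Bundles the rate constants of the mean-field population model
#' \eqn{\dot N = (k/4) N^2 - k_E N - \gamma (N - N_{eq})} together with the
#' derived quantities used throughout the package: the stable equilibrium
#' population \eqn{N_{eq} = 4 k_E / k}, the unstable equilibrium
#' \eqn{N' = 4\gamma/k}, the dimensionless migration/exit ratio
#' \eqn{n = \gamma / k_E}, and the exit mean lifetime \eqn{\tau_E = 1/k_E}.
#'
#' The reproductive term \eqn{(k/4) N^2} counts possible female-male couples
#' under exact sex equality; the exit term \eqn{k_E N} lumps death, ageing out
#' of reproduction and loss of fertility; the migration term restores the
#' population towards \eqn{N_{eq}}. The stable-equilibrium regime of the model
#' requires \eqn{n > 1}; a value of 1 or below is accepted but flagged with a
#' warning, since then \eqn{N_{eq}} no longer is the stable root.
#'
#' @param k reproductive rate constant (per pair per year), `>= 0`.
#' @param k_E exit rate constant (per year), `> 0`.
#' @param gamma migration rate constant (per year), `>= 0`.
#' @return A one-row tibble of class `nd_demography` with columns `k`, `k_E`,
#'   `gamma`, `N_eq`, `N_unstable`, `n_ratio`, `tau_E`.
#' @examples
#' demographic_params(k = 0.04, k_E = 1, gamma = 3.3)
#' @export
demographic_params <- function(k, k_E, gamma) {
  stopifnot(is.numeric(k), is.numeric(k_E), is.numeric(gamma),
            length(k) == 1L, length(k_E) == 1L, length(gamma) == 1L)
  if (k < 0 || k_E < 0 || gamma < 0) {
    stop("rate constants k, k_E, gamma must be non-negative", call. = FALSE)
  }
  if (k_E <= 0) stop("k_E must be positive (tau_E = 1/k_E)", call. = FALSE)
  n_ratio <- gamma / k_E
  if (n_ratio <= 1) {
    warning("n_ratio = gamma/k_E <= 1: N_eq is not the stable equilibrium ",
            "in this regime", call. = FALSE)
  }
  out <- tibble::tibble(
    k = k, k_E = k_E, gamma = gamma,
    N_eq = equilibrium_population(k, k_E),
    N_unstable = 4 * gamma / k,
    n_ratio = n_ratio,
    tau_E = 1 / k_E
  )
  class(out) <- c("nd_demography", class(out))
  out
}

#' Stable equilibrium reproductive population
#'
#' The stationary condition \eqn{(k/4) N_{eq}^2 - k_E N_{eq} = 0} of the
#' mean-field demographic equation gives \eqn{N_{eq} = 4 k_E / k}.
#'
#' @param k reproductive rate constant (per pair per year), `> 0`.
#' @param k_E exit rate constant (per year), `>= 0`.
#' @return The equilibrium expected reproductive population (individuals).
#' @examples
#' equilibrium_population(k = 0.04, k_E = 1) # 100
#' @export
equilibrium_population <- function(k, k_E) {
  stopifnot(is.numeric(k), is.numeric(k_E), length(k) == 1L, length(k_E) == 1L)
  if (k <= 0) stop("k must be positive: no finite equilibrium for k = 0",
                   call. = FALSE)
  if (k_E < 0) stop("k_E must be non-negative", call. = FALSE)
  4 * k_E / k
}

#' Closed-form dimensionless population trajectory
#'
#' Solves \eqn{df/ds = (f - 1)(f - n)} for the scaled population
#' \eqn{f = N/N_{eq}} against the scaled time \eqn{s = k_E t}. For
#' \eqn{n \ne 1} the solution is
#' \deqn{f(s) = \frac{n (f_0 - 1) - (f_0 - n) e^{(n-1)s}}
#'                   {f_0 - 1 - (f_0 - n) e^{(n-1)s}},}
#' and for the degenerate \eqn{n = 1} case the analytic limit
#' \eqn{f(s) = 1 + (f_0 - 1)/(1 - (f_0 - 1)s)} (solution of
#' \eqn{df/ds = (f-1)^2}) is used. Trajectories with \eqn{0 \le f_0 < n}
#' converge to the stable root \eqn{f = 1}; trajectories started above the
#' unstable root (\eqn{f_0 > n}) blow up at the finite time returned by
#' [divergence_time()], and requesting such an `s` is an error.
#'
#' @param f0 initial scaled population \eqn{N(0)/N_{eq}}, `>= 0`.
#' @param n_ratio dimensionless ratio \eqn{\gamma/k_E}, `> 0`.
#' @param s_grid numeric vector of scaled times, all `>= 0`.
#' @return A tibble with columns `s` and `f`.
#' @examples
#' population_trajectory(0.5, 3.3, seq(0, 5, by = 0.5))
#' @seealso [divergence_time()], [trajectory_ode()]
#' @export
population_trajectory <- function(f0, n_ratio, s_grid) {
  check_trajectory_args(f0, n_ratio, s_grid)
  n <- n_ratio
  if (abs(n - 1) < 1e-12) {
    f <- 1 + (f0 - 1) / (1 - (f0 - 1) * s_grid)
  } else {
    e <- exp((n - 1) * s_grid)
    f <- (n * (f0 - 1) - (f0 - n) * e) / (f0 - 1 - (f0 - n) * e)
  }
  # pin the two stationary roots to machine-exact constants
  if (f0 == 1) f <- rep(1, length(s_grid))
  if (f0 == n) f <- rep(n, length(s_grid))
  tibble::tibble(s = s_grid, f = f)
}

#' Finite blow-up time of a super-critical trajectory
#'
#' A trajectory started above the unstable equilibrium (\eqn{f_0 > n > 1})
#' diverges at the finite scaled time
#' \deqn{s^* = \frac{1}{n - 1}\,\ln\frac{f_0 - 1}{f_0 - n},}
#' with the \eqn{n = 1} limit \eqn{s^* = 1/(f_0 - 1)}. Convergent initial
#' conditions (\eqn{0 \le f_0 \le n}) have no divergence and raise an error.
#'
#' @inheritParams population_trajectory
#' @return The critical scaled time \eqn{s^*} (dimensionless, positive).
#' @examples
#' divergence_time(4, 3.3)
#' @export
divergence_time <- function(f0, n_ratio) {
  stopifnot(is.numeric(f0), is.numeric(n_ratio),
            length(f0) == 1L, length(n_ratio) == 1L)
  if (n_ratio < 1) {
    stop("divergence requires n_ratio >= 1 (model regime)", call. = FALSE)
  }
  if (f0 <= n_ratio) {
    stop("f0 = ", f0, " is at or below n_ratio = ", n_ratio,
         ": the trajectory converges, no divergence time exists",
         call. = FALSE)
  }
  if (abs(n_ratio - 1) < 1e-12) return(1 / (f0 - 1))
  log((f0 - 1) / (f0 - n_ratio)) / (n_ratio - 1)
}

#' Numeric-integration oracle for the population trajectory
#'
#' Integrates \eqn{df/ds = (f - 1)(f - n)} with `deSolve::lsoda` at tight
#' tolerances. This is an independent cross-check of the closed form in
#' [population_trajectory()]; the two agree to better than `1e-8` on the
#' convergent regime.
#'
#' @inheritParams population_trajectory
#' @return A tibble with columns `s` and `f`.
#' @export
trajectory_ode <- function(f0, n_ratio, s_grid) {
  check_trajectory_args(f0, n_ratio, s_grid)
  times <- sort(unique(c(0, s_grid)))
  sol <- deSolve::ode(
    y = c(f = f0), times = times,
    func = function(s, y, p) list((y[1] - 1) * (y[1] - p)),
    parms = n_ratio, method = "lsoda", rtol = 1e-12, atol = 1e-12
  )
  tibble::tibble(s = s_grid, f = unname(sol[match(s_grid, times), "f"]))
}

check_trajectory_args <- function(f0, n_ratio, s_grid) {
  stopifnot(is.numeric(f0), is.numeric(n_ratio), is.numeric(s_grid),
            length(f0) == 1L, length(n_ratio) == 1L)
  if (f0 < 0) stop("f0 must be non-negative", call. = FALSE)
  if (n_ratio <= 0) stop("n_ratio must be positive", call. = FALSE)
  if (any(s_grid < 0)) stop("s values must be non-negative", call. = FALSE)
  if (f0 > n_ratio && n_ratio >= 1) {
    s_crit <- divergence_time(f0, n_ratio)
    if (any(s_grid >= s_crit)) {
      stop("trajectory with f0 = ", f0, " > n_ratio = ", n_ratio,
           " diverges at s = ", format(s_crit, digits = 10),
           "; requested s values must stay strictly below it", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Exit mean lifetime implied by stationarity
#'
#' At demographic stationarity the per-reproductive-individual recruitment
#' rate balances the exit rate \eqn{k_E}: one surviving recruit per couple
#' every `interval / survival` years, shared over the two parents, so
#' \deqn{\tau_E = \frac{2\,\mathrm{interval}}{\mathrm{survival}}.}
#' With the extant hunter-gatherer values (mean inter-birth interval per woman
#' of 4-8 years, survival to reproductive age about 0.5) the midpoint interval
#' of 6 years gives \eqn{\tau_E = 24} years.
#'
#' @param mean_birth_interval mean time between successive live births per
#'   woman (years), `> 0`.
#' @param survival_to_reproduction probability of surviving to reproductive
#'   age, in `(0, 1]`.
#' @return The exit mean lifetime \eqn{\tau_E} in years.
#' @examples
#' calibrate_tau_e(6, 0.5) # 24
#' @export
calibrate_tau_e <- function(mean_birth_interval, survival_to_reproduction) {
  stopifnot(is.numeric(mean_birth_interval),
            is.numeric(survival_to_reproduction),
            length(mean_birth_interval) == 1L,
            length(survival_to_reproduction) == 1L)
  if (mean_birth_interval <= 0) {
    stop("mean_birth_interval must be positive", call. = FALSE)
  }
  if (survival_to_reproduction <= 0 || survival_to_reproduction > 1) {
    stop("survival_to_reproduction must be in (0, 1]", call. = FALSE)
  }
  2 * mean_birth_interval / survival_to_reproduction
}
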