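#' Genotype-subgroup distribution at a single autosomal locus
#'
#' Validates and packages the probabilities of the three genotype subgroups
#' within the stationary expected population: resident (Neanderthal)
#' homozygotes `P_N`, immigrant (H. sapiens) homozygotes `P_S`, and
#' heterozygotes `P_NS`. The three must be non-negative and sum to 1;
#' deviations of the sum below `1e-9` are renormalised silently, larger ones
#' are an error.
#'
#' @param P_N,P_S,P_NS subgroup probabilities.
#' @return A one-row tibble with columns `P_N`, `P_S`, `P_NS` (exact sum 1).
#' @examples
#' genotype_distribution(1, 0, 0)
#' genotype_distribution(0.25, 0.25, 0.5)
#' @export
genotype_distribution <- function(P_N, P_S, P_NS) {
  stopifnot(is.numeric(P_N), is.numeric(P_S), is.numeric(P_NS),
            length(P_N) == 1L, length(P_S) == 1L, length(P_NS) == 1L)
  p <- c(P_N, P_S, P_NS)
  if (any(p < -1e-12) || any(p > 1 + 1e-12)) {
    stop("genotype probabilities must lie in [0, 1]", call. = FALSE)
  }
  p <- pmin(pmax(p, 0), 1)
  dev <- abs(sum(p) - 1)
  if (dev > 1e-9) {
    stop("genotype probabilities sum to ", format(sum(p), digits = 12),
         ", not 1 (deviation ", format(dev, digits = 3), " > 1e-9)",
         call. = FALSE)
  }
  p <- p / sum(p)
  tibble::tibble(P_N = p[1], P_S = p[2], P_NS = p[3])
}

as_genotype_dist <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("P_N", "P_S", "P_NS") %in% names(x)), nrow(x) == 1L)
    genotype_distribution(x$P_N, x$P_S, x$P_NS)
  } else if (is.numeric(x) && length(x) == 3L) {
    genotype_distribution(x[1], x[2], x[3])
  } else {
    stop("expected a genotype distribution (3 probabilities or a one-row ",
         "data frame with P_N, P_S, P_NS)", call. = FALSE)
  }
}

#' Closed-form genotype-subgroup trajectory
#'
#' Time evolution of the three subgroup probabilities within a stationary
#' expected population. The difference \eqn{\Delta P_0 = P_N(0) - P_S(0)} is a
#' dynamical invariant, and the homozygote total \eqn{Z = P_N + P_S} relaxes
#' exponentially,
#' \deqn{Z(t) = \left[Z(0) - \tfrac{\Delta P_0^2 + 1}{2}\right] e^{-k_E t}
#'       + \tfrac{\Delta P_0^2 + 1}{2},}
#' from which \eqn{P_N = (Z + \Delta P_0)/2}, \eqn{P_S = (Z - \Delta P_0)/2}
#' and \eqn{P_{NS} = 1 - Z}. The relaxation time constant is the exit mean
#' lifetime \eqn{\tau_E = 1/k_E}; equilibrium is essentially reached for
#' \eqn{t > 2\tau_E}.
#'
#' @param init initial genotype distribution: a length-3 numeric
#'   `(P_N, P_S, P_NS)` or a one-row data frame as returned by
#'   [genotype_distribution()].
#' @param k_E exit rate constant (per year), `> 0`.
#' @param t_grid numeric vector of times (years), all `>= 0`.
#' @return A tibble with columns `t`, `P_N`, `P_S`, `P_NS`.
#' @examples
#' genotype_trajectory(c(0.5, 0.5, 0), k_E = 1 / 24, t_grid = c(0, 24, 48))
#' @seealso [equilibrium_distribution()], [genotype_ode()]
#' @export
genotype_trajectory <- function(init, k_E, t_grid) {
  init <- as_genotype_dist(init)
  stopifnot(is.numeric(k_E), length(k_E) == 1L, is.numeric(t_grid))
  if (k_E <= 0) stop("k_E must be positive (no relaxation for k_E = 0)",
                     call. = FALSE)
  if (any(t_grid < 0)) stop("t values must be non-negative", call. = FALSE)
  dP0 <- init$P_N - init$P_S
  Z0 <- init$P_N + init$P_S
  A <- Z0 - (dP0^2 + 1) / 2
  decay <- exp(-k_E * t_grid)
  P_N <- A * decay / 2 + (dP0 + 1)^2 / 4
  P_S <- A * decay / 2 + (dP0 - 1)^2 / 4
  tibble::tibble(t = t_grid, P_N = P_N, P_S = P_S, P_NS = 1 - P_N - P_S)
}

#' Equilibrium genotype-subgroup distribution
#'
#' The \eqn{t \to \infty} limit of the genotype trajectory is fully determined
#' by the conserved difference \eqn{\Delta P_0}:
#' \deqn{P_N(\infty) = \frac{(\Delta P_0 + 1)^2}{4},\quad
#'       P_S(\infty) = \frac{(\Delta P_0 - 1)^2}{4},\quad
#'       P_{NS}(\infty) = \frac{1 - \Delta P_0^2}{2}.}
#' These are Hardy-Weinberg proportions for allele frequencies
#' \eqn{(1 \pm \Delta P_0)/2}, so \eqn{P_{NS}(\infty)^2 =
#' 4 P_N(\infty) P_S(\infty)} identically.
#'
#' @param delta_P0 conserved difference \eqn{P_N(0) - P_S(0)}, in
#'   \eqn{[-1, 1]}; vectorised.
#' @return A tibble with columns `delta_P0`, `P_N`, `P_S`, `P_NS`.
#' @examples
#' equilibrium_distribution(0)   # (0.25, 0.25, 0.5)
#' equilibrium_distribution(1)   # (1, 0, 0)
#' @export
equilibrium_distribution <- function(delta_P0) {
  stopifnot(is.numeric(delta_P0))
  if (any(abs(delta_P0) > 1 + 1e-12)) {
    stop("|delta_P0| must not exceed 1", call. = FALSE)
  }
  delta_P0 <- pmin(pmax(delta_P0, -1), 1)
  tibble::tibble(
    delta_P0 = delta_P0,
    P_N = (delta_P0 + 1)^2 / 4,
    P_S = (delta_P0 - 1)^2 / 4,
    P_NS = (1 - delta_P0^2) / 2
  )
}

#' Numeric-integration oracle for the genotype trajectory
#'
#' Integrates the coupled subgroup rate equations
#' \deqn{\dot P_N = \dot P_S = k_E\left\{\tfrac14\left[1 - (P_N + P_S)\right]^2
#'       - P_N P_S\right\},\qquad \dot P_{NS} = -(\dot P_N + \dot P_S),}
#' with `deSolve::lsoda` at tight tolerances, as an independent cross-check of
#' the closed forms in [genotype_trajectory()] (agreement better than `1e-8`).
#'
#' @inheritParams genotype_trajectory
#' @return A tibble with columns `t`, `P_N`, `P_S`, `P_NS`.
#' @export
genotype_ode <- function(init, k_E, t_grid) {
  init <- as_genotype_dist(init)
  stopifnot(is.numeric(k_E), length(k_E) == 1L, is.numeric(t_grid))
  if (k_E <= 0) stop("k_E must be positive", call. = FALSE)
  if (any(t_grid < 0)) stop("t values must be non-negative", call. = FALSE)
  times <- sort(unique(c(0, t_grid)))
  rhs <- function(t, y, p) {
    common <- p * ((1 - (y[1] + y[2]))^2 / 4 - y[1] * y[2])
    list(c(common, common, -2 * common))
  }
  sol <- deSolve::ode(
    y = c(P_N = init$P_N, P_S = init$P_S, P_NS = init$P_NS),
    times = times, func = rhs, parms = k_E,
    method = "lsoda", rtol = 1e-12, atol = 1e-12
  )
  idx <- match(t_grid, times)
  tibble::tibble(t = t_grid,
                 P_N = unname(sol[idx, "P_N"]),
                 P_S = unname(sol[idx, "P_S"]),
                 P_NS = unname(sol[idx, "P_NS"]))
}
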