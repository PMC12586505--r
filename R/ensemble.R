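#' Binomial law of immigrant-homozygote counts in one tribe
#'
#' In a single reference tribe of `N_eq` reproductive individuals, the number
#' of immigrant homozygotes \eqn{k_S} at a locus with final probability
#' \eqn{P_{S,f}} is binomial,
#' \deqn{P_{k_S} = \binom{N_{eq}}{k_S} P_{S,f}^{k_S} (1-P_{S,f})^{N_{eq}-k_S},}
#' with mean \eqn{N_{eq} P_{S,f}} and variance
#' \eqn{N_{eq} P_{S,f}(1 - P_{S,f})}. This across-tribe dispersion is the
#' model's genetic-drift proxy.
#'
#' @param N_eq reproductive individuals per tribe (positive integer).
#' @param P_Sf immigrant-homozygote probability, in `[0, 1]`.
#' @return A tibble with columns `k_S` (0..`N_eq`) and `prob`.
#' @examples
#' tribe_homozygote_pmf(10, 0.9)
#' @export
tribe_homozygote_pmf <- function(N_eq, P_Sf) {
  check_count(N_eq, "N_eq")
  check_prob(P_Sf, "P_Sf")
  k <- 0:N_eq
  tibble::tibble(k_S = k, prob = dbinom(k, N_eq, P_Sf))
}

#' Standard deviation of the within-tribe immigrant fraction
#'
#' \deqn{\mathrm{sd}(k_S / N_{eq}) = \sqrt{P_{S,f}(1 - P_{S,f})} / \sqrt{N_{eq}},}
#' vanishing as \eqn{N_{eq} \to \infty} or \eqn{P_{S,f} \to 0, 1}.
#'
#' @inheritParams tribe_homozygote_pmf
#' @return The dimensionless standard deviation of \eqn{k_S/N_{eq}}.
#' @examples
#' tribe_fraction_sd(100, 0.99) # about 0.00995
#' @export
tribe_fraction_sd <- function(N_eq, P_Sf) {
  check_count(N_eq, "N_eq")
  check_prob(P_Sf, "P_Sf")
  sqrt(P_Sf * (1 - P_Sf)) / sqrt(N_eq)
}

#' Finite-ensemble confidence interval for the estimated probability
#'
#' The ensemble estimator \eqn{\hat P_{S,f}} (mean immigrant-homozygote
#' fraction over `M` tribes of `N_eq` individuals) has standard deviation
#' \eqn{\sigma = \sqrt{P_{S,f}(1-P_{S,f})}/\sqrt{N_{eq} M}}. Assuming
#' Gaussian-like statistics, the 95 per cent band is reported with the
#' conventional 2-sigma half-width (exactly \eqn{2\sigma}, not
#' \eqn{1.96\sigma}).
#'
#' @inheritParams tribe_homozygote_pmf
#' @param M number of tribes in the ensemble (positive integer).
#' @return A one-row tibble with columns `P_Sf`, `sigma`, `lower`, `upper`.
#' @examples
#' ensemble_estimate_ci(0.990, N_eq = 100, M = 10) # (0.984, 0.996)
#' @export
ensemble_estimate_ci <- function(P_Sf, N_eq, M) {
  check_prob(P_Sf, "P_Sf")
  check_count(N_eq, "N_eq")
  check_count(M, "M")
  sigma <- sqrt(P_Sf * (1 - P_Sf)) / sqrt(N_eq * M)
  tibble::tibble(P_Sf = P_Sf, sigma = sigma,
                 lower = P_Sf - 2 * sigma, upper = P_Sf + 2 * sigma)
}

#' Multinomial law of the three genotype counts in one tribe
#'
#' Joint probability of finding `(k_S, k_N, k_NS)` immigrant homozygotes,
#' resident homozygotes and heterozygotes in a tribe of `N_eq` individuals,
#' \deqn{P(k_S, k_N, k_{NS}) = \frac{N_{eq}!}{k_S!\,k_N!\,k_{NS}!}
#'       P_{S}^{k_S} P_{N}^{k_N} P_{NS}^{k_{NS}},}
#' evaluated in log space so that `N_eq` up to `1e4` is exact to better than
#' `1e-12` relative. Marginalising over `k_N`, `k_NS` recovers the binomial
#' law of [tribe_homozygote_pmf()].
#'
#' @inheritParams tribe_homozygote_pmf
#' @param dist genotype distribution (length-3 `(P_N, P_S, P_NS)` or a
#'   one-row data frame).
#' @return A tibble with one row per composition `k_S + k_N + k_NS = N_eq`
#'   and columns `k_S`, `k_N`, `k_NS`, `prob`.
#' @examples
#' tribe_genotype_pmf(2, c(0.25, 0.25, 0.5))
#' @export
tribe_genotype_pmf <- function(N_eq, dist) {
  check_count(N_eq, "N_eq")
  dist <- as_genotype_dist(dist)
  p <- c(dist$P_S, dist$P_N, dist$P_NS)
  comp <- tidyr::expand_grid(k_S = 0:N_eq, k_N = 0:N_eq) |>
    dplyr::filter(.data$k_S + .data$k_N <= N_eq) |>
    dplyr::mutate(k_NS = N_eq - .data$k_S - .data$k_N)
  # log-space multinomial: lgamma-based, robust to large N_eq
  logp <- ifelse(p > 0, log(p), -Inf)
  term <- function(k, lp) ifelse(k == 0, 0, k * lp)
  lpr <- lgamma(N_eq + 1) -
    lgamma(comp$k_S + 1) - lgamma(comp$k_N + 1) - lgamma(comp$k_NS + 1) +
    term(comp$k_S, logp[1]) + term(comp$k_N, logp[2]) +
    term(comp$k_NS, logp[3])
  dplyr::mutate(comp, prob = exp(lpr))
}

#' @rdname tribe_genotype_pmf
#' @param k_S,k_N,k_NS a single genotype composition with
#'   `k_S + k_N + k_NS = N_eq`; vectorised.
#' @return `tribe_genotype_prob()`: the probability of the given
#'   composition(s), evaluated in log space.
#' @export
tribe_genotype_prob <- function(N_eq, dist, k_S, k_N, k_NS) {
  check_count(N_eq, "N_eq")
  dist <- as_genotype_dist(dist)
  stopifnot(length(k_S) == length(k_N), length(k_N) == length(k_NS))
  if (any(k_S < 0 | k_N < 0 | k_NS < 0) ||
      any(k_S + k_N + k_NS != N_eq)) {
    stop("counts must be non-negative and sum to N_eq", call. = FALSE)
  }
  p <- c(dist$P_S, dist$P_N, dist$P_NS)
  logp <- ifelse(p > 0, log(p), -Inf)
  term <- function(k, lp) ifelse(k == 0, 0, k * lp)
  exp(lgamma(N_eq + 1) -
        lgamma(k_S + 1) - lgamma(k_N + 1) - lgamma(k_NS + 1) +
        term(k_S, logp[1]) + term(k_N, logp[2]) + term(k_NS, logp[3]))
}

#' Multi-locus immigrant-homozygosity moments
#'
#' For `n_loci` statistically independent loci, each with the same final
#' immigrant-homozygote probability `P_Sf`, the number of loci at which an
#' individual is immigrant homozygote is binomial with
#' \deqn{\langle n_S \rangle = n P_{S,f},\qquad
#'       \sigma^2_{n_S} = n P_{S,f}(1 - P_{S,f}).}
#'
#' @param n_loci number of independent loci (positive integer).
#' @inheritParams tribe_homozygote_pmf
#' @return A one-row tibble with columns `n_loci`, `P_Sf`, `mean_nS`,
#'   `var_nS`.
#' @examples
#' multilocus_homozygosity_stats(10, 0.99)
#' @export
multilocus_homozygosity_stats <- function(n_loci, P_Sf) {
  check_count(n_loci, "n_loci")
  check_prob(P_Sf, "P_Sf")
  tibble::tibble(n_loci = n_loci, P_Sf = P_Sf,
                 mean_nS = n_loci * P_Sf,
                 var_nS = n_loci * P_Sf * (1 - P_Sf))
}

#' Resident-allele carrier statistics across independent loci
#'
#' An individual carries at least one resident (Neanderthal) allele among
#' `n_loci` independent loci with probability \eqn{1 - P_{S,f}^n}. In a tribe
#' of `N_eq` individuals the carrier fraction \eqn{k/N_{eq}} then has
#' \deqn{\frac{\langle k \rangle}{N_{eq}} = 1 - P_{S,f}^n, \qquad
#'       \frac{\sigma_k}{N_{eq}} =
#'       \frac{\sqrt{(1 - P_{S,f}^n)\,P_{S,f}^n}}{\sqrt{N_{eq}}},}
#' and the ensemble mean over `M` tribes has standard deviation
#' \eqn{\sigma_k / (N_{eq}\sqrt{M})}.
#'
#' @inheritParams multilocus_homozygosity_stats
#' @inheritParams ensemble_estimate_ci
#' @return A one-row tibble with columns `n_loci`, `P_Sf`, `N_eq`, `M`,
#'   `carrier_prob`, `mean_frac`, `sd_frac`, `ensemble_sd`.
#' @examples
#' carrier_stats(n_loci = 10, P_Sf = 0.99, N_eq = 100, M = 10)
#' @export
carrier_stats <- function(n_loci, P_Sf, N_eq, M = 1) {
  check_count(n_loci, "n_loci")
  check_prob(P_Sf, "P_Sf")
  check_count(N_eq, "N_eq")
  check_count(M, "M")
  psn <- P_Sf^n_loci
  carrier <- 1 - psn
  sd_frac <- sqrt(carrier * psn) / sqrt(N_eq)
  tibble::tibble(
    n_loci = n_loci, P_Sf = P_Sf, N_eq = N_eq, M = M,
    carrier_prob = carrier,
    mean_frac = carrier,
    sd_frac = sd_frac,
    ensemble_sd = sd_frac / sqrt(M)
  )
}

#' Locus count maximising the carrier-fraction noise
#'
#' The across-tribe standard deviation of the carrier fraction peaks in the
#' locus count where \eqn{P_{S,f}^n = 1/2}, i.e. at the real-valued
#' \deqn{n^* = \frac{\ln(1/2)}{\ln P_{S,f}}.}
#' Integer reporting (floor/ceiling) is left to the caller.
#'
#' @param P_Sf immigrant-homozygote probability, strictly inside `(0, 1)`.
#' @return The real-valued maximising locus count \eqn{n^*}.
#' @examples
#' carrier_sd_maximizer(0.99) # about 69
#' @export
carrier_sd_maximizer <- function(P_Sf) {
  stopifnot(is.numeric(P_Sf), length(P_Sf) == 1L)
  if (P_Sf <= 0 || P_Sf >= 1) {
    stop("P_Sf must lie strictly inside (0, 1)", call. = FALSE)
  }
  log(0.5) / log(P_Sf)
}

check_count <- function(x, name) {
  stopifnot(is.numeric(x), length(x) == 1L)
  if (x < 1 || x != floor(x)) {
    stop(name, " must be a positive integer", call. = FALSE)
  }
  invisible(TRUE)
}

check_prob <- function(x, name) {
  stopifnot(is.numeric(x), length(x) == 1L)
  if (x < 0 || x > 1) stop(name, " must lie in [0, 1]", call. = FALSE)
  invisible(TRUE)
}
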