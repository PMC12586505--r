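#' Configuration for the tribe-ensemble simulator
#'
#' Collects every knob of the forward-time Monte Carlo model: `M` independent
#' tribes of `N_eq` reproductive individuals each, held at constant size
#' (stationary expected population). Per time step of length `step` years,
#' each individual exits with probability `step / tau_E` and is replaced by
#' the Mendelian offspring of a uniformly random ordered pair of distinct
#' remaining individuals; each individual is also exchanged with the
#' surrounding environment with probability `gamma * step`, where
#' `gamma = n_ratio / tau_E` is the migration rate constant of the
#' demographic model. Every `delta_t` years an immigration cycle replaces a
#' fraction `chi` of each tribe with immigrant homozygotes (at all loci).
#'
#' The environment (`bath`) realises the model's assumption that migration
#' does not alter the genotype distribution of the expected population:
#' `"reference"` (default) draws exchanged individuals from the analytic
#' expected-population trajectory, i.e. the tribe is embedded in an infinite
#' metapopulation already following the mean-field dynamics; `"ensemble"`
#' draws from the current mean of the simulated tribes (self-consistent
#' mean-field coupling); `"none"` isolates the tribes, which then accumulate
#' unchecked genetic drift (useful to demonstrate what the exchange term
#' suppresses).
#'
#' `immigration = "binomial"` (default) draws a Binomial(`N_eq`, `chi`) number
#' of immigrants per tribe per cycle, matching the interpretation of `chi` as
#' an ensemble-average fraction with tribe-to-tribe variation;
#' `"exact"` replaces `round(chi * N_eq)` individuals in every tribe.
#'
#' @param N_eq reproductive individuals per tribe, `>= 2`.
#' @param M number of tribes, `>= 1`.
#' @param tau_E exit mean lifetime (years).
#' @param chi per-cycle immigration fraction, in `[0, 1]`.
#' @param delta_t inter-cycle interval (years).
#' @param n_cycles number of immigration cycles.
#' @param seed RNG seed (mandatory, for reproducibility).
#' @param step event-time discretisation (years); must satisfy
#'   `step <= tau_E / 20`. Default `tau_E / 24`.
#' @param n_loci number of independently simulated loci.
#' @param n_ratio dimensionless migration/exit ratio \eqn{\gamma/k_E}
#'   setting the environment-exchange rate (default 3.3).
#' @param bath environment model: `"reference"`, `"ensemble"` or `"none"`.
#' @param immigration immigrant-number model: `"binomial"` or `"exact"`.
#' @return A list of class `nd_sim_config`.
#' @examples
#' sim_config(N_eq = 50, M = 20, tau_E = 24, chi = 2 / 30, delta_t = 100,
#'            n_cycles = 5, seed = 1)
#' @export
sim_config <- function(N_eq, M, tau_E, chi, delta_t, n_cycles, seed,
                       step = tau_E / 24, n_loci = 1, n_ratio = 3.3,
                       bath = c("reference", "ensemble", "none"),
                       immigration = c("binomial", "exact")) {
  bath <- match.arg(bath)
  immigration <- match.arg(immigration)
  stopifnot(is.numeric(N_eq), is.numeric(M), is.numeric(tau_E),
            is.numeric(chi), is.numeric(delta_t), is.numeric(n_cycles),
            is.numeric(step), is.numeric(n_loci), is.numeric(n_ratio))
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L) {
    stop("a numeric RNG seed is mandatory", call. = FALSE)
  }
  if (N_eq < 2 || N_eq != floor(N_eq)) {
    stop("N_eq must be an integer >= 2", call. = FALSE)
  }
  if (M < 1 || M != floor(M)) stop("M must be an integer >= 1", call. = FALSE)
  if (tau_E <= 0) stop("tau_E must be positive", call. = FALSE)
  if (chi < 0 || chi > 1) stop("chi must lie in [0, 1]", call. = FALSE)
  if (delta_t <= 0) stop("delta_t must be positive", call. = FALSE)
  if (n_cycles < 0 || n_cycles != floor(n_cycles)) {
    stop("n_cycles must be a non-negative integer", call. = FALSE)
  }
  if (step <= 0 || step > tau_E / 20) {
    stop("step must satisfy 0 < step <= tau_E / 20 (discretisation error ",
         "on the exit process)", call. = FALSE)
  }
  if (n_loci < 1 || n_loci != floor(n_loci)) {
    stop("n_loci must be a positive integer", call. = FALSE)
  }
  if (n_ratio < 0) stop("n_ratio must be non-negative", call. = FALSE)
  structure(
    list(N_eq = as.integer(N_eq), M = as.integer(M), tau_E = tau_E,
         chi = chi, delta_t = delta_t, n_cycles = as.integer(n_cycles),
         seed = as.integer(seed), step = step, n_loci = as.integer(n_loci),
         n_ratio = n_ratio, bath = bath, immigration = immigration),
    class = "nd_sim_config"
  )
}

# analytic within-cycle relaxation evaluated at the ends of the n_steps steps
bath_trajectory <- function(init, tau_E, step, n_steps) {
  tr <- genotype_trajectory(init, k_E = 1 / tau_E,
                            t_grid = step * seq_len(n_steps))
  as.matrix(tr[, c("P_N", "P_S", "P_NS")])
}

# per-cycle post-immigration initial distributions from the exact recursion
cycle_init_table <- function(chi, n_cycles, delta_P00 = 1) {
  eq <- equilibrium_distribution(delta_P00)[, c("P_N", "P_S", "P_NS")]
  inits <- vector("list", n_cycles)
  for (j in seq_len(n_cycles)) {
    inits[[j]] <- apply_cycle(eq, chi)
    dP <- inits[[j]]$P_N - inits[[j]]$P_S
    eq <- equilibrium_distribution(dP)[, c("P_N", "P_S", "P_NS")]
  }
  inits
}

counts_tibble <- function(counts_by_locus, cycle, time) {
  purrr::imap_dfr(counts_by_locus, function(cnt, locus) {
    tibble::tibble(cycle = cycle, time = time, locus = as.integer(locus),
                   tribe = seq_len(nrow(cnt)),
                   k_N = cnt[, 1], k_S = cnt[, 2], k_NS = cnt[, 3])
  })
}

#' Simulate an ensemble of finite tribes through immigration cycles
#'
#' Runs the forward-time Monte Carlo model described in [sim_config()]: all
#' tribes start as pure resident homozygotes; each immigration cycle replaces
#' a fraction `chi` of every tribe with immigrant homozygotes, followed by
#' `delta_t` years of exit/Mendelian-replacement relaxation (plus environment
#' exchange). Per-tribe genotype counts are recorded at the end of every
#' cycle, together with the closed-form equilibrium prediction for that
#' cycle.
#'
#' @param config an [sim_config()] object.
#' @return An object of class `nd_sim`: a list with elements
#'   \describe{
#'     \item{trajectory}{tibble of ensemble means per cycle end and locus
#'       (`cycle`, `time`, `locus`, `P_N_hat`, `P_S_hat`, `P_NS_hat`) joined
#'       with the analytic closed forms (`P_N`, `P_S`, `P_NS`).}
#'     \item{counts}{tibble of per-tribe genotype counts at each cycle end.}
#'     \item{final}{tibble of per-tribe counts after the last cycle.}
#'     \item{config}{the configuration.}
#'   }
#' @examples
#' cfg <- sim_config(N_eq = 30, M = 20, tau_E = 24, chi = 2 / 30,
#'                   delta_t = 100, n_cycles = 3, seed = 1)
#' sim <- simulate_ensemble(cfg)
#' tidy(sim)
#' @seealso [relaxation_experiment()], [subgroup_probs_after_cycles()]
#' @export
simulate_ensemble <- function(config) {
  stopifnot(inherits(config, "nd_sim_config"))
  set.seed(config$seed)
  N <- config$N_eq
  M <- config$M
  p_exit <- config$step / config$tau_E
  p_mig <- config$n_ratio / config$tau_E * config$step
  n_steps <- max(1L, as.integer(round(config$delta_t / config$step)))
  bath_mode <- switch(config$bath, none = 0L, reference = 1L, ensemble = 2L)
  empty_bath <- matrix(0, 1, 3)

  counts <- replicate(config$n_loci,
                      cbind(rep(N, M), rep(0L, M), rep(0L, M)),
                      simplify = FALSE)
  inits <- if (config$chi > 0 && config$chi < 1) {
    cycle_init_table(config$chi, config$n_cycles)
  } else NULL

  traj <- list()
  count_rows <- list()
  closed <- subgroup_probs_after_cycles(seq_len(max(config$n_cycles, 1)),
                                        chi = min(max(config$chi, 0), 1 - 1e-15))
  for (j in seq_len(config$n_cycles)) {
    n_imm <- switch(config$immigration,
                    binomial = stats::rbinom(M, N, config$chi),
                    exact = rep(as.integer(round(config$chi * N)), M))
    bath <- if (bath_mode == 1L) {
      if (!is.null(inits)) {
        bath_trajectory(inits[[j]], config$tau_E, config$step, n_steps)
      } else {
        # chi = 0 or 1: expected distribution is constant
        p <- if (config$chi >= 1) c(0, 1, 0) else c(1, 0, 0)
        matrix(p, n_steps, 3, byrow = TRUE)
      }
    } else empty_bath
    for (l in seq_len(config$n_loci)) {
      counts[[l]] <- .immigration_replace(counts[[l]], as.integer(n_imm))
      counts[[l]] <- .moran_advance(counts[[l]], n_steps, p_exit, p_mig,
                                    bath, bath_mode)
    }
    t_end <- j * config$delta_t
    count_rows[[j]] <- counts_tibble(counts, j, t_end)
    means <- purrr::imap_dfr(counts, function(cnt, locus) {
      tibble::tibble(cycle = j, time = t_end, locus = as.integer(locus),
                     P_N_hat = mean(cnt[, 1]) / N,
                     P_S_hat = mean(cnt[, 2]) / N,
                     P_NS_hat = mean(cnt[, 3]) / N)
    })
    traj[[j]] <- means
  }

  trajectory <- dplyr::bind_rows(traj)
  if (nrow(trajectory) > 0) {
    trajectory <- dplyr::left_join(
      trajectory, dplyr::rename(closed, cycle = "j"), by = "cycle"
    )
  }
  all_counts <- dplyr::bind_rows(count_rows)
  final <- if (nrow(all_counts) > 0) {
    dplyr::filter(all_counts, .data$cycle == max(.data$cycle))
  } else {
    counts_tibble(counts, 0L, 0)
  }
  structure(
    list(trajectory = trajectory, counts = all_counts, final = final,
         config = config),
    class = "nd_sim"
  )
}

#' Relaxation of an arbitrary initial genotype mixture (no immigration)
#'
#' Initialises every tribe as an independent multinomial sample of `N_eq`
#' individuals from `init`, runs the exit/Mendelian-replacement dynamics with
#' no immigration, and records per-tribe counts and ensemble means at the
#' requested times. The ensemble means are joined with the closed-form
#' relaxation trajectory for direct comparison.
#'
#' @param config an [sim_config()] object (`chi` is ignored; no cycles run).
#' @param init initial genotype distribution (length-3 numeric or a one-row
#'   data frame).
#' @param t_grid sampling times in years (default `c(0.5, 1, 2, 4) * tau_E`).
#' @return An `nd_sim` object; `trajectory` has one row per sample time and
#'   locus with ensemble means and analytic values.
#' @examples
#' cfg <- sim_config(N_eq = 30, M = 50, tau_E = 24, chi = 0, delta_t = 100,
#'                   n_cycles = 0, seed = 1)
#' relaxation_experiment(cfg, init = c(0, 0, 1))
#' @export
relaxation_experiment <- function(config, init,
                                  t_grid = c(0.5, 1, 2, 4) * config$tau_E) {
  stopifnot(inherits(config, "nd_sim_config"))
  init <- as_genotype_dist(init)
  stopifnot(is.numeric(t_grid), all(t_grid >= 0))
  set.seed(config$seed)
  N <- config$N_eq
  M <- config$M
  p_exit <- config$step / config$tau_E
  p_mig <- config$n_ratio / config$tau_E * config$step
  bath_mode <- switch(config$bath, none = 0L, reference = 1L, ensemble = 2L)

  p0 <- c(init$P_N, init$P_S, init$P_NS)
  counts <- replicate(
    config$n_loci,
    t(stats::rmultinom(M, N, p0)),
    simplify = FALSE
  )

  t_grid <- sort(unique(t_grid))
  steps_at <- as.integer(round(t_grid / config$step))
  traj <- list()
  count_rows <- list()
  done <- 0L
  for (i in seq_along(steps_at)) {
    n_steps <- steps_at[i] - done
    if (n_steps > 0) {
      bath <- if (bath_mode == 1L) {
        tr <- genotype_trajectory(
          init, k_E = 1 / config$tau_E,
          t_grid = config$step * (done + seq_len(n_steps))
        )
        as.matrix(tr[, c("P_N", "P_S", "P_NS")])
      } else matrix(0, 1, 3)
      for (l in seq_len(config$n_loci)) {
        counts[[l]] <- .moran_advance(counts[[l]], n_steps, p_exit, p_mig,
                                      bath, bath_mode)
      }
      done <- steps_at[i]
    }
    t_i <- t_grid[i]
    count_rows[[i]] <- counts_tibble(counts, i, t_i)
    traj[[i]] <- purrr::imap_dfr(counts, function(cnt, locus) {
      tibble::tibble(cycle = i, time = t_i, locus = as.integer(locus),
                     P_N_hat = mean(cnt[, 1]) / N,
                     P_S_hat = mean(cnt[, 2]) / N,
                     P_NS_hat = mean(cnt[, 3]) / N)
    })
  }
  trajectory <- dplyr::bind_rows(traj)
  analytic <- genotype_trajectory(init, k_E = 1 / config$tau_E,
                                  t_grid = t_grid) |>
    dplyr::rename(time = "t")
  trajectory <- dplyr::left_join(trajectory, analytic, by = "time")
  all_counts <- dplyr::bind_rows(count_rows)
  structure(
    list(trajectory = trajectory,
         counts = all_counts,
         final = dplyr::filter(all_counts, .data$time == max(.data$time)),
         config = config),
    class = "nd_sim"
  )
}

#' @export
print.nd_sim <- function(x, ...) {
  cfg <- x$config
  cat("Tribe-ensemble simulation (", cfg$M, " tribes x ", cfg$N_eq,
      " individuals, ", cfg$n_loci, " locus/loci)\n", sep = "")
  cat("  tau_E = ", cfg$tau_E, " yr, chi = ", format(cfg$chi, digits = 4),
      ", delta_t = ", cfg$delta_t, " yr, cycles = ", cfg$n_cycles,
      ", bath = ", cfg$bath, ", seed = ", cfg$seed, "\n", sep = "")
  if (nrow(x$trajectory) > 0) {
    last <- dplyr::slice_tail(x$trajectory, n = 1)
    cat("  final ensemble means: P_N = ",
        format(last$P_N_hat, digits = 4), ", P_S = ",
        format(last$P_S_hat, digits = 4), ", P_NS = ",
        format(last$P_NS_hat, digits = 4), "\n", sep = "")
  }
  invisible(x)
}

#' Tidy the simulated trajectory
#'
#' @param x an `nd_sim` object.
#' @param ... unused.
#' @return The trajectory tibble: ensemble-mean genotype probabilities per
#'   sample time and locus alongside the analytic prediction.
#' @exportS3Method generics::tidy
tidy.nd_sim <- function(x, ...) x$trajectory

#' One-row summary of a simulation
#'
#' @param x an `nd_sim` object.
#' @param ... unused.
#' @return A one-row tibble: configuration, final ensemble means, their
#'   across-tribe standard deviations, and the analytic prediction.
#' @exportS3Method generics::glance
glance.nd_sim <- function(x, ...) {
  cfg <- x$config
  fin <- x$final
  N <- cfg$N_eq
  last <- dplyr::slice_tail(x$trajectory, n = 1)
  if (nrow(last) == 0) {
    last <- tibble::tibble(P_N = NA_real_, P_S = NA_real_, P_NS = NA_real_)
  }
  tibble::tibble(
    N_eq = cfg$N_eq, M = cfg$M, n_loci = cfg$n_loci, chi = cfg$chi,
    delta_t = cfg$delta_t, n_cycles = cfg$n_cycles, seed = cfg$seed,
    P_N_hat = mean(fin$k_N) / N,
    P_S_hat = mean(fin$k_S) / N,
    P_NS_hat = mean(fin$k_NS) / N,
    sd_frac_S = stats::sd(fin$k_S / N),
    P_N = last$P_N, P_S = last$P_S, P_NS = last$P_NS
  )
}
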