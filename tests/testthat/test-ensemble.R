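test_that("within-tribe homozygote counts follow the binomial law", {
  pmf <- tribe_homozygote_pmf(2, 0.5)
  expect_equal(pmf$prob, c(0.25, 0.5, 0.25))
  # point mass at full dilution
  pm <- tribe_homozygote_pmf(10, 1)
  expect_equal(pm$prob, c(rep(0, 10), 1))
  # pmf normalisation and closed-form moments for a range of sizes
  for (N_eq in c(5, 50, 200)) {
    for (P_Sf in c(0.1, 0.5, 0.99)) {
      pmf <- tribe_homozygote_pmf(N_eq, P_Sf)
      expect_equal(sum(pmf$prob), 1, tolerance = 1e-10)
      m <- sum(pmf$k_S * pmf$prob)
      v <- sum((pmf$k_S - m)^2 * pmf$prob)
      expect_equal(m, N_eq * P_Sf, tolerance = 1e-9)
      expect_equal(v, N_eq * P_Sf * (1 - P_Sf), tolerance = 1e-9)
    }
  }
})

test_that("tribe fraction noise scales as a root-N binomial sd", {
  expect_equal(tribe_fraction_sd(100, 0.99), sqrt(0.99 * 0.01) / 10)
  expect_equal(tribe_fraction_sd(100, 0.99), 0.0099499, tolerance = 1e-5)
  expect_equal(tribe_fraction_sd(100, 0), 0)
  expect_equal(tribe_fraction_sd(100, 1), 0)
  expect_equal(tribe_fraction_sd(200, 0.7) * sqrt(2), tribe_fraction_sd(100, 0.7))
})

test_that("finite-ensemble interval uses the 2-sigma Gaussian convention", {
  ci <- ensemble_estimate_ci(0.990, 100, 10)
  expect_equal(ci$sigma, sqrt(0.99 * 0.01) / sqrt(1000))
  expect_equal(round(ci$lower, 3), 0.984)
  expect_equal(round(ci$upper, 3), 0.996)
  expect_equal(ci$upper - ci$P_Sf, 2 * ci$sigma)  # exactly 2 sigma, not 1.96
  # degenerate and asymptotic limits
  ci1 <- ensemble_estimate_ci(1, 100, 10)
  expect_equal(c(ci1$lower, ci1$upper), c(1, 1))
  ciM <- ensemble_estimate_ci(0.9, 100, 10^8)
  expect_lt(ciM$upper - ciM$lower, 1e-4)
})

test_that("multinomial genotype pmf is exact and marginalises to the
           binomial", {
  # two-individual tribe at the symmetric equilibrium
  pmf <- tribe_genotype_pmf(2, c(0.25, 0.25, 0.5))
  expect_equal(sum(pmf$prob), 1, tolerance = 1e-12)
  expect_equal(pmf$prob[pmf$k_NS == 2], 0.25)
  # point mass for a pure resident tribe
  pure <- tribe_genotype_pmf(4, c(1, 0, 0))
  expect_equal(pure$prob[pure$k_N == 4], 1)
  expect_equal(sum(pure$prob), 1)
  # agreement with dmultinom and the binomial marginal, N_eq <= 50
  set.seed(1)
  for (N_eq in c(10, 50)) {
    dist <- c(0.2, 0.5, 0.3)
    pmf <- tribe_genotype_pmf(N_eq, dist)
    idx <- sample(nrow(pmf), 25)
    for (i in idx) {
      expect_equal(pmf$prob[i],
                   dmultinom(c(pmf$k_S[i], pmf$k_N[i], pmf$k_NS[i]),
                             prob = c(dist[2], dist[1], dist[3])),
                   tolerance = 1e-12)
    }
    marg <- vapply(0:N_eq,
                   function(k) sum(pmf$prob[pmf$k_S == k]), numeric(1))
    expect_equal(marg, tribe_homozygote_pmf(N_eq, dist[2])$prob,
                 tolerance = 1e-12)
  }
})

test_that("log-space evaluation survives large tribes", {
  # pointwise probabilities at N_eq = 10^4 against dmultinom
  N_eq <- 10000
  dist <- c(0.3, 0.6, 0.1)  # (P_N, P_S, P_NS)
  cases <- rbind(c(6000, 3000, 1000), c(5900, 3100, 1000),
                 c(6500, 2500, 1000), c(10000, 0, 0))
  for (i in seq_len(nrow(cases))) {
    k <- cases[i, ]
    # lgamma at N_eq = 1e4 carries ~1e-11 relative rounding in the exponent,
    # so agreement with dmultinom is checked at 1e-8 relative
    expect_equal(tribe_genotype_prob(N_eq, dist, k[1], k[2], k[3]),
                 dmultinom(k, prob = c(0.6, 0.3, 0.1)),
                 tolerance = 1e-8)
  }
  # the enumerated pmf still normalises at a few hundred individuals
  pmf <- tribe_genotype_pmf(300, dist)
  expect_equal(sum(pmf$prob), 1, tolerance = 1e-10)
})

test_that("multi-locus homozygosity moments are binomial across loci", {
  st <- multilocus_homozygosity_stats(10, 0.99)
  expect_equal(st$mean_nS, 9.9)
  expect_equal(st$var_nS, 0.099)
  full <- multilocus_homozygosity_stats(7, 1)
  expect_equal(c(full$mean_nS, full$var_nS), c(7, 0))
  one <- multilocus_homozygosity_stats(1, 0.3)
  expect_equal(c(one$mean_nS, one$var_nS), c(0.3, 0.3 * 0.7))
})

test_that("carrier statistics reproduce the printed multi-locus regime", {
  cs <- carrier_stats(n_loci = 10, P_Sf = 0.99, N_eq = 100, M = 10)
  expect_equal(cs$carrier_prob, 1 - 0.99^10)
  expect_equal(cs$mean_frac, 0.0956, tolerance = 1e-3)
  expect_equal(cs$sd_frac, 0.0294, tolerance = 1e-3)
  expect_equal(cs$ensemble_sd, 0.0093, tolerance = 1e-2)
  expect_equal(cs$ensemble_sd, cs$sd_frac / sqrt(10))
  none <- carrier_stats(5, 1, 100)
  expect_equal(c(none$carrier_prob, none$mean_frac, none$sd_frac), c(0, 0, 0))
  # mean carrier fraction rises with locus count, falls with P_Sf (as the
  # formula 1 - P_Sf^n dictates)
  fr_n <- vapply(1:20, function(n) carrier_stats(n, 0.9, 100)$mean_frac,
                 numeric(1))
  expect_true(all(diff(fr_n) > 0))
  fr_p <- vapply(c(0.5, 0.7, 0.9, 0.99),
                 function(p) carrier_stats(10, p, 100)$mean_frac, numeric(1))
  expect_true(all(diff(fr_p) < 0))
})

test_that("carrier-noise maximum sits where the n-locus homozygosity is
           one half", {
  expect_equal(carrier_sd_maximizer(0.5), 1)
  nstar <- carrier_sd_maximizer(0.99)
  expect_equal(nstar, 68.97, tolerance = 1e-3)
  # brute-force scan of the sd formula over integer locus counts
  sd_at <- function(n) carrier_stats(n, 0.99, 100)$sd_frac
  scan <- vapply(1:500, sd_at, numeric(1))
  expect_equal(which.max(scan), 69)
  best <- max(sd_at(floor(nstar)), sd_at(ceiling(nstar)))
  expect_true(all(scan <= best + 1e-15))
  expect_error(carrier_sd_maximizer(1), "strictly inside")
})
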