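test_that("one cycle perturbs the distribution as a partial replacement", {
  ini <- apply_cycle(c(1, 0, 0), chi = 2 / 30)
  expect_equal(ini$P_N - ini$P_S, 26 / 30)  # (1)(1 - chi) - chi
  expect_distribution(ini)
  # chi = 0 is the identity
  d <- genotype_distribution(0.3, 0.2, 0.5)
  expect_equal(apply_cycle(d, 0), d)
  # an all-immigrant population cannot be diluted further
  expect_equal(apply_cycle(c(0, 1, 0), 0.4),
               genotype_distribution(0, 1, 0))
  expect_error(apply_cycle(c(1, 0, 0), 1), "chi")
})

test_that("closed-form invariant recursion matches explicit iteration", {
  for (chi in c(0.005, 2 / 30, 0.2)) {
    dp <- 1
    for (j in 1:12) {
      dp <- dp * (1 - chi) - chi
      expect_lt(abs(delta_p_after_cycles(j, chi) - dp), 1e-14)
    }
  }
  expect_equal(delta_p_after_cycles(0, 0.1, delta_P00 = 0.5), 0.5)
  expect_equal(delta_p_after_cycles(10, 2 / 30), 2 * (28 / 30)^10 - 1)
  expect_equal(delta_p_after_cycles(10, 2 / 30), 0.00322365, tolerance = 1e-6)
  # limit: complete dilution
  expect_equal(delta_p_after_cycles(5000, 0.05), -1)
})

test_that("cycle-schedule advisories fire for out-of-regime parameters", {
  expect_silent(cycle_schedule(chi = 0.02, delta_t = 100, tau_E = 24))
  expect_warning(cycle_schedule(chi = 0.2, delta_t = 100, tau_E = 24),
                 "small per-cycle")
  expect_warning(cycle_schedule(chi = 0.02, delta_t = 40, tau_E = 24),
                 "2 tau_E")
  expect_error(cycle_schedule(chi = 0, delta_t = 100), "chi")
})

test_that("subgroup closed forms equal the j-fold cycle composition", {
  for (chi in c(0.005, 2 / 30, 0.2)) {
    probs <- subgroup_probs_after_cycles(0:50, chi)
    expect_distribution(probs)
    for (j in c(0, 1, 2, 5, 10, 25, 50)) {
      it <- iterate_cycles(j, chi)
      row <- probs[probs$j == j, ]
      expect_lt(abs(row$P_N - it$P_N), 1e-12)
      expect_lt(abs(row$P_S - it$P_S), 1e-12)
      expect_lt(abs(row$P_NS - it$P_NS), 1e-12)
    }
  }
  # frozen anchors
  p10 <- subgroup_probs_after_cycles(10, 2 / 30)
  expect_equal(p10$P_N, (28 / 30)^20)
  expect_equal(p10$P_N, 0.25161, tolerance = 1e-4)
  p0 <- subgroup_probs_after_cycles(0, 0.05)
  expect_equal(c(p0$P_N, p0$P_S, p0$P_NS), c(1, 0, 0))
})

test_that("monotone dilution: resident loss, immigrant gain, heterozygote
           unimodality", {
  for (chi in c(0.01, 2 / 30)) {
    probs <- subgroup_probs_after_cycles(0:200, chi)
    expect_true(all(diff(probs$P_N) < 0))
    expect_true(all(diff(probs$P_S) > 0))
    d <- diff(probs$P_NS)
    turn <- which(d < 0)[1]
    expect_true(all(d[seq_len(turn - 1)] > 0))
    expect_true(all(d[turn:length(d)] < 0))
  }
  # resident homozygotes also decrease with chi at fixed j
  pj <- vapply(c(0.01, 0.05, 0.1, 0.3),
               function(ch) subgroup_probs_after_cycles(8, ch)$P_N,
               numeric(1))
  expect_true(all(diff(pj) < 0))
})

test_that("allele frequencies recover the continent-island recursion", {
  for (chi in c(0.005, 2 / 30, 0.2)) {
    j <- 0:50
    af <- allele_frequencies(j, chi)
    probs <- subgroup_probs_after_cycles(j, chi)
    expect_equal(af$q_neanderthal, (1 - chi)^j, tolerance = 1e-15)
    expect_equal(af$p_sapiens + af$q_neanderthal, rep(1, length(j)))
    # allele frequency extracted from the genotype closed forms
    expect_equal(af$p_sapiens, probs$P_S + probs$P_NS / 2, tolerance = 1e-12)
    expect_equal(af$q_neanderthal, probs$P_N + probs$P_NS / 2,
                 tolerance = 1e-12)
  }
  one <- allele_frequencies(1, 0.5)
  expect_equal(c(one$p_sapiens, one$q_neanderthal), c(0.5, 0.5))
})

test_that("cycle count to a dilution target matches bracketing iteration", {
  # oracle: smallest integer j whose closed-form P_S reaches the target
  smallest_j <- function(P_Sf, chi) {
    j <- 0
    while (subgroup_probs_after_cycles(j, chi)$P_S < P_Sf) j <- j + 1
    j
  }
  for (case in list(c(0.990, 2 / 30), c(0.990, 0.02), c(0.95, 0.05))) {
    Jf <- cycles_to_target(case[1], case[2])
    expect_equal(ceiling(Jf), smallest_j(case[1], case[2]))
    expect_equal(whole_cycles(case[1], case[2]), ceiling(Jf))
  }
  expect_equal(cycles_to_target(0.990, 2 / 30), 76.7588, tolerance = 1e-4)
  expect_equal(cycles_to_target(0.990, 0.02), 262.1336, tolerance = 1e-4)
  # one cycle suffices exactly when P_Sf = chi^2
  expect_equal(cycles_to_target(0.3^2, 0.3), 1)
  # strictly decreasing in chi
  grid <- vapply(seq(0.01, 0.2, by = 0.01), cycles_to_target,
                 numeric(1), P_Sf = 0.99)
  expect_true(all(diff(grid) < 0))
  expect_error(cycles_to_target(1, 0.1), "singular")
})

test_that("total dilution time scales linearly and inverts exactly", {
  expect_equal(total_time(0.990, 0.02, 100), 26213.36, tolerance = 1e-5)
  expect_equal(total_time(0.990, 0.02, 200),
               2 * total_time(0.990, 0.02, 100))
  # chi -> 1 collapses the dilution time
  expect_lt(total_time(0.990, 0.9999, 50), 50 * 1.01)
  # closed-form inversion round-trips on a grid
  for (P_Sf in c(0.9, 0.990, 0.999)) {
    for (chi in c(0.008, 0.03, 0.08)) {
      for (dt in c(50, 150)) {
        Tf <- total_time(P_Sf, chi, dt)
        expect_equal(chi_for_time(P_Sf, dt, Tf), chi, tolerance = 1e-9)
      }
    }
  }
  expect_equal(chi_for_time(0.990, 50, 30000), 0.0088, tolerance = 1e-2)
  # T_f = delta_t means a single cycle: chi = 1 - (1 - sqrt(P_Sf))
  expect_equal(chi_for_time(0.990, 75, 75), sqrt(0.990))
})

test_that("dilution-time curves are strictly decreasing in chi", {
  curve <- dilution_time_curve(0.990, seq(0.005, 0.09, by = 0.005),
                               c(50, 100, 150))
  expect_named(curve, c("chi", "delta_t", "J_f", "T_f"))
  for (dt in c(50, 100, 150)) {
    Tf <- curve$T_f[curve$delta_t == dt]
    expect_true(all(diff(Tf) < 0))
  }
})
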