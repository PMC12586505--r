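# Independent oracles used across test files.

# explicit j-fold composition: immigration perturbation followed by
# relaxation to equilibrium, starting from a pure resident population
iterate_cycles <- function(j, chi, delta_P00 = 1) {
  eq <- equilibrium_distribution(delta_P00)[, c("P_N", "P_S", "P_NS")]
  for (i in seq_len(j)) {
    ini <- apply_cycle(eq, chi)
    eq <- equilibrium_distribution(ini$P_N - ini$P_S)[, c("P_N", "P_S", "P_NS")]
  }
  eq
}

# crude fixed-step RK4 for df/ds = (f-1)(f-n); independent of deSolve
rk4_trajectory <- function(f0, n_ratio, s_end, n_steps = 20000) {
  h <- s_end / n_steps
  f <- f0
  rhs <- function(f) (f - 1) * (f - n_ratio)
  for (i in seq_len(n_steps)) {
    k1 <- rhs(f); k2 <- rhs(f + h * k1 / 2)
    k3 <- rhs(f + h * k2 / 2); k4 <- rhs(f + h * k3)
    f <- f + h * (k1 + 2 * k2 + 2 * k3 + k4) / 6
  }
  f
}

expect_distribution <- function(d, tol = 1e-12) {
  expect_true(all(d$P_N >= -tol & d$P_N <= 1 + tol))
  expect_true(all(d$P_S >= -tol & d$P_S <= 1 + tol))
  expect_true(all(d$P_NS >= -tol & d$P_NS <= 1 + tol))
  expect_equal(d$P_N + d$P_S + d$P_NS, rep(1, nrow(d)), tolerance = tol)
}
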