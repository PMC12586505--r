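// Forward-time core of the tribe-ensemble simulator.
//
// Genotype codes: 0 = resident homozygote (N), 1 = immigrant homozygote (S),
// 2 = heterozygote (NS). Each tribe holds a fixed number of reproductive
// individuals (stationary expected population); per step each individual
// exits with probability p_exit and is replaced by the Mendelian offspring
// of a uniformly random ordered pair of distinct remaining individuals.
// Optionally, each individual is exchanged with the environment with
// probability p_mig; the environment carries either a supplied reference
// genotype distribution (one row per step) or the current ensemble mean.
//
// Uses R's RNG stream, so results are reproducible under set.seed().

#include <Rcpp.h>
using namespace Rcpp;

// draw one genotype index proportional to the three counts
static inline int pick3(const int c[3]) {
  double tot = c[0] + c[1] + c[2];
  double u = unif_rand() * tot;
  if (u < c[0]) return 0;
  if (u < c[0] + c[1]) return 1;
  return 2;
}

// random allele carried by a parent of the given genotype (0 = N, 1 = S)
static inline int allele(int g) {
  if (g == 0) return 0;
  if (g == 1) return 1;
  return unif_rand() < 0.5 ? 0 : 1;
}

// draw one genotype from a probability distribution
static inline int pick3p(const double p[3]) {
  double u = unif_rand();
  if (u < p[0]) return 0;
  if (u < p[0] + p[1]) return 1;
  return 2;
}

// [[Rcpp::export(name = ".moran_advance")]]
IntegerMatrix moran_advance(IntegerMatrix counts, int n_steps,
                            double p_exit, double p_mig,
                            NumericMatrix bath, int bath_mode) {
  const int M = counts.nrow();
  IntegerMatrix st = clone(counts);

  for (int step = 0; step < n_steps; ++step) {
    // --- exit + Mendelian replacement, tribe by tribe ---
    for (int l = 0; l < M; ++l) {
      int c[3] = { st(l, 0), st(l, 1), st(l, 2) };
      int N = c[0] + c[1] + c[2];
      int d = (int) R::rbinom((double) N, p_exit);
      if (d > N - 2) d = N - 2;  // keep at least one mating pair
      if (d <= 0) continue;
      // exits: without replacement from current composition
      for (int i = 0; i < d; ++i) {
        int g = pick3(c);
        c[g] -= 1;
      }
      // births: ordered pair of distinct individuals from the remaining pool
      int born[3] = { 0, 0, 0 };
      for (int i = 0; i < d; ++i) {
        int g1 = pick3(c);
        c[g1] -= 1;
        int g2 = pick3(c);
        c[g1] += 1;
        int a = allele(g1) + allele(g2);
        born[a == 0 ? 0 : (a == 2 ? 1 : 2)] += 1;
      }
      st(l, 0) = c[0] + born[0];
      st(l, 1) = c[1] + born[1];
      st(l, 2) = c[2] + born[2];
    }

    // --- environment exchange ---
    if (bath_mode > 0 && p_mig > 0) {
      double pb[3];
      if (bath_mode == 1) {          // reference trajectory
        pb[0] = bath(step, 0);
        pb[1] = bath(step, 1);
        pb[2] = bath(step, 2);
      } else {                       // self-consistent ensemble mean
        double tot = 0, s0 = 0, s1 = 0, s2 = 0;
        for (int l = 0; l < M; ++l) {
          s0 += st(l, 0); s1 += st(l, 1); s2 += st(l, 2);
        }
        tot = s0 + s1 + s2;
        pb[0] = s0 / tot; pb[1] = s1 / tot; pb[2] = s2 / tot;
      }
      for (int l = 0; l < M; ++l) {
        int c[3] = { st(l, 0), st(l, 1), st(l, 2) };
        int N = c[0] + c[1] + c[2];
        int b = (int) R::rbinom((double) N, p_mig);
        for (int i = 0; i < b; ++i) {
          int g_out = pick3(c);
          c[g_out] -= 1;
          c[pick3p(pb)] += 1;
        }
        st(l, 0) = c[0]; st(l, 1) = c[1]; st(l, 2) = c[2];
      }
    }
  }
  return st;
}

// Replace n_repl uniformly chosen individuals per tribe with immigrant
// homozygotes (one immigration cycle). n_repl is a length-M integer vector.
// [[Rcpp::export(name = ".immigration_replace")]]
IntegerMatrix immigration_replace(IntegerMatrix counts, IntegerVector n_repl) {
  const int M = counts.nrow();
  IntegerMatrix st = clone(counts);
  for (int l = 0; l < M; ++l) {
    int c[3] = { st(l, 0), st(l, 1), st(l, 2) };
    int r = n_repl[l];
    for (int i = 0; i < r; ++i) {
      int g = pick3(c);
      c[g] -= 1;
    }
    st(l, 0) = c[0];
    st(l, 1) = c[1] + r;
    st(l, 2) = c[2];
  }
  return st;
}
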