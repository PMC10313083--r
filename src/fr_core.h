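#pragma once

// keep Armadillo quiet about ill-conditioned solves; they are detected and
// handled by a least-squares fallback in pair_stationary()
#define ARMA_WARN_LEVEL 1
#include <RcppArmadillo.h>
#include <cstdint>
#include <string>

// Core representation of deterministic memory-(m1,m2) strategies for the
// iterated donation game.
//
// A strategy at memory capacity m (0..3) is a lookup table over the
// 2^(2m) joint history profiles (a_m..a_1, b_m..b_1), where a_t is the
// focal player's action t rounds ago and b_t the co-player's.
//
// Bit conventions (fixed package-wide):
//   * action C = 1, D = 0;
//   * profile index i = (A << m) | B, with A the own-history bits and B
//     the co-player-history bits; the most recent round sits in bit 0
//     (a_1 = bit 0 of A, a_2 = bit 1, ...);
//   * table bit i of `bits` is the prescribed action at profile i.

namespace fr {

struct Strat {
  int m;          // memory capacity, 0..3
  uint64_t bits;  // 2^(2m) table bits

  Strat() : m(0), bits(0) {}
  Strat(int m_, uint64_t bits_) : m(m_), bits(bits_) {}
};

inline int n_profiles(int m) { return 1 << (2 * m); }

inline int act(const Strat& s, uint64_t A, uint64_t B) {
  return static_cast<int>((s.bits >> ((A << s.m) | B)) & 1ULL);
}

// Deepest own-/co-player-history round the prescription depends on.
void memory_lengths(const Strat& s, int& m1, int& m2);

// Re-index a table to capacity m_target; valid whenever
// m_target >= max(m1, m2) of s (lift or canonical shrink).
Strat reindex(const Strat& s, int m_target);

// Stationary distribution of the pair Markov chain of p vs q at common
// capacity max(1, p.m, q.m), under implementation error e > 0.
arma::vec pair_stationary(const Strat& p, const Strat& q, double e, int& m_out);

// Cooperation levels gamma_{p,q} and gamma_{q,p} from the stationary
// distribution.
void pair_coop(const Strat& p, const Strat& q, double e,
               double& gpq, double& gqp);

double self_coop(const Strat& s, double e);

// Rivalry: no negative cycle in the full-memory rivalry graph (e = 0).
bool is_rival(const Strat& s);

inline bool is_efficient(const Strat& s, double e = 1e-4,
                         double threshold = 0.99) {
  return self_coop(s, e) > threshold;
}

// Reporting label: 0 = other, 1 = non-FR efficient, 2 = non-FR rival, 3 = FR.
int class_label(const Strat& s, double e_eff = 1e-4, double threshold = 0.99);

// Fixation probability of a single Y mutant in a homogeneous group of N
// X-players under the Fermi pairwise-comparison process (log-sum-exp form).
double fixation_rho(double piXX, double piXY, double piYX, double piYY,
                    int N, double sigma_in);

double fermi(double pi_x, double pi_y, double sigma);

}  // namespace fr
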