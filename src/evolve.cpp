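#include "fr_core.h"
#include <unordered_map>

// Small-mutation-limit evolutionary Monte Carlo.  All strategies inside a
// run are represented at the run's memory capacity m (>= 1), so the table
// bits are a unique key for caching.  RNG draws go through R's generator
// (unif_rand), so runs are reproducible via set.seed() on the R side.

namespace {

using fr::Strat;

struct StratProps {
  double gamma;   // self-cooperation gamma_pp at the run's error rate
  double pi;      // self-payoff (b - 1) * gamma
  int label;      // 0 other, 1 non-FR efficient, 2 non-FR rival, 3 FR
  int m1, m2;     // exact memory lengths
};

struct RunCtx {
  int m;          // capacity (>= 1)
  double b, e;
  std::unordered_map<uint64_t, StratProps> props;

  const StratProps& get(const Strat& s) {
    auto it = props.find(s.bits);
    if (it != props.end()) return it->second;
    StratProps p;
    p.gamma = fr::self_coop(s, e);
    p.pi = (b - 1.0) * p.gamma;
    p.label = fr::class_label(s);
    fr::memory_lengths(s, p.m1, p.m2);
    return props.emplace(s.bits, p).first->second;
  }
};

// Two-step mutant sampler: (m1, m2) uniform on {0,..,m}^2, then a uniform
// table from the exact class S(m1, m2) by rejection; returned at capacity
// m_cap.
Strat sample_mutant_strat(int m, int m_cap) {
  int m1 = static_cast<int>(unif_rand() * (m + 1));
  if (m1 > m) m1 = m;
  int m2 = static_cast<int>(unif_rand() * (m + 1));
  if (m2 > m) m2 = m;
  const int L = 1 << (m1 + m2);
  const uint64_t mask1 = (m1 == 0) ? 0ULL : ((1ULL << m1) - 1);
  const uint64_t mask2 = (m2 == 0) ? 0ULL : ((1ULL << m2) - 1);
  for (int tries = 0; tries < 10000; ++tries) {
    uint64_t t = 0;
    for (int h = 0; h < L; ++h)
      if (unif_rand() < 0.5) t |= (1ULL << h);
    // exact-memory check on the class table
    bool ok = true;
    if (m1 > 0) {
      const uint64_t flip = 1ULL << (m2 + m1 - 1);
      bool dep = false;
      for (int h = 0; h < L && !dep; ++h)
        if (!(h & flip))
          dep = ((t >> h) & 1ULL) != ((t >> (h | flip)) & 1ULL);
      ok = dep;
    }
    if (ok && m2 > 0) {
      const uint64_t flip = 1ULL << (m2 - 1);
      bool dep = false;
      for (int h = 0; h < L && !dep; ++h)
        if (!(h & flip))
          dep = ((t >> h) & 1ULL) != ((t >> (h | flip)) & 1ULL);
      ok = dep;
    }
    if (!ok) continue;
    // embed into the full square table at capacity m_cap
    Strat s(m_cap, 0ULL);
    const int n = fr::n_profiles(m_cap);
    const uint64_t maskM = (1ULL << m_cap) - 1;
    for (int i = 0; i < n; ++i) {
      const uint64_t A = (static_cast<uint64_t>(i) >> m_cap) & maskM;
      const uint64_t B = static_cast<uint64_t>(i) & maskM;
      const uint64_t h = ((A & mask1) << m2) | (B & mask2);
      if ((t >> h) & 1ULL) s.bits |= (1ULL << i);
    }
    return s;
  }
  Rcpp::stop("mutant rejection sampling exceeded retry cap");
}

struct SeriesAcc {
  std::vector<double> t, coop, fr_, eff, riv, mm1, mm2;
  void push(double tt, double c, double f, double ef, double rv, double a1,
            double a2) {
    t.push_back(tt);
    coop.push_back(c);
    fr_.push_back(f);
    eff.push_back(ef);
    riv.push_back(rv);
    mm1.push_back(a1);
    mm2.push_back(a2);
  }
  Rcpp::DataFrame df() const {
    return Rcpp::DataFrame::create(
        Rcpp::Named("t") = t, Rcpp::Named("cooperation") = coop,
        Rcpp::Named("frac_fr") = fr_, Rcpp::Named("frac_eff") = eff,
        Rcpp::Named("frac_rival") = riv, Rcpp::Named("mean_m1") = mm1,
        Rcpp::Named("mean_m2") = mm2);
  }
};

}  // namespace

// [[Rcpp::export]]
Rcpp::List run_well_mixed_cpp(int N, double b, double e, int m,
                              double sigma_in, double steps, double burn_in,
                              double thin) {
  if (N < 2) Rcpp::stop("N must be >= 2");
  if (m < 1 || m > 3) Rcpp::stop("m must be in 1..3");
  const int mc = m;
  RunCtx ctx;
  ctx.m = mc;
  ctx.b = b;
  ctx.e = e;

  // pair-payoff cache, worthwhile only when the strategy space is small
  const bool cache_pairs = (m <= 1);
  std::unordered_map<uint64_t, std::pair<double, double>> pair_cache;

  Strat X = sample_mutant_strat(m, mc);
  double piXX = ctx.get(X).pi;

  double sum_coop = 0, sum_m1 = 0, sum_m2 = 0;
  double cnt = 0;
  double n_fr = 0, n_eff = 0, n_riv = 0;
  SeriesAcc series;

  const long long n_steps = static_cast<long long>(steps);
  const long long n_burn = static_cast<long long>(burn_in);
  const long long n_thin = static_cast<long long>(thin);
  for (long long t = 1; t <= n_steps; ++t) {
    Strat Y = sample_mutant_strat(m, mc);
    double gXY, gYX;
    if (cache_pairs) {
      const uint64_t key = (X.bits << 32) | Y.bits;
      auto it = pair_cache.find(key);
      if (it == pair_cache.end()) {
        fr::pair_coop(X, Y, e, gXY, gYX);
        pair_cache.emplace(key, std::make_pair(gXY, gYX));
      } else {
        gXY = it->second.first;
        gYX = it->second.second;
      }
    } else {
      fr::pair_coop(X, Y, e, gXY, gYX);
    }
    const double piXY = b * gYX - gXY;
    const double piYX = b * gXY - gYX;
    const double piYY = ctx.get(Y).pi;
    const double rho = fr::fixation_rho(piXX, piXY, piYX, piYY, N, sigma_in);
    if (unif_rand() < rho) {
      X = Y;
      piXX = piYY;
    }
    if (t > n_burn) {
      const StratProps& pr = ctx.get(X);
      sum_coop += pr.gamma;
      sum_m1 += pr.m1;
      sum_m2 += pr.m2;
      if (pr.label == 3) n_fr += 1;
      else if (pr.label == 1) n_eff += 1;
      else if (pr.label == 2) n_riv += 1;
      cnt += 1;
      if (n_thin > 0 && t % n_thin == 0)
        series.push(static_cast<double>(t), pr.gamma, pr.label == 3,
                    pr.label == 1, pr.label == 2, pr.m1, pr.m2);
    }
    if ((t & 4095) == 0) Rcpp::checkUserInterrupt();
  }

  return Rcpp::List::create(
      Rcpp::Named("mean_cooperation") = sum_coop / cnt,
      Rcpp::Named("frac_fr") = n_fr / cnt,
      Rcpp::Named("frac_eff") = n_eff / cnt,
      Rcpp::Named("frac_rival") = n_riv / cnt,
      Rcpp::Named("mean_m1") = sum_m1 / cnt,
      Rcpp::Named("mean_m2") = sum_m2 / cnt,
      Rcpp::Named("series") = series.df());
}

// [[Rcpp::export]]
Rcpp::List run_group_structured_cpp(int M, int N, double b, double e, int m,
                                    double sigma_in, double sigma_out,
                                    double r, double steps, double burn_in,
                                    double thin) {
  if (M < 2) Rcpp::stop("M must be >= 2");
  if (N < 2) Rcpp::stop("N must be >= 2");
  if (m < 1 || m > 3) Rcpp::stop("m must be in 1..3");
  if (r < 0 || r > 1) Rcpp::stop("r must be in [0, 1]");
  const int mc = m;
  RunCtx ctx;
  ctx.m = mc;
  ctx.b = b;
  ctx.e = e;

  // resident-resident pair payoffs recur constantly: cache them
  struct PairHash {
    size_t operator()(const std::pair<uint64_t, uint64_t>& k) const {
      return std::hash<uint64_t>()(k.first * 0x9E3779B97F4A7C15ULL ^ k.second);
    }
  };
  std::unordered_map<std::pair<uint64_t, uint64_t>, std::pair<double, double>,
                     PairHash> pair_cache;
  auto pair_payoffs = [&](const Strat& X, const Strat& Y, double& piXY,
                          double& piYX) {
    const auto key = std::make_pair(X.bits, Y.bits);
    auto it = pair_cache.find(key);
    double gXY, gYX;
    if (it == pair_cache.end()) {
      fr::pair_coop(X, Y, e, gXY, gYX);
      pair_cache.emplace(key, std::make_pair(gXY, gYX));
    } else {
      gXY = it->second.first;
      gYX = it->second.second;
    }
    piXY = b * gYX - gXY;
    piYX = b * gXY - gYX;
  };

  std::vector<Strat> res(M);
  // streaming aggregates over groups, updated on each replacement
  double agg_coop = 0, agg_m1 = 0, agg_m2 = 0;
  double agg_fr = 0, agg_eff = 0, agg_riv = 0;
  auto label_add = [&](int lab, double sgn) {
    if (lab == 3) agg_fr += sgn;
    else if (lab == 1) agg_eff += sgn;
    else if (lab == 2) agg_riv += sgn;
  };
  for (int g = 0; g < M; ++g) {
    res[g] = sample_mutant_strat(m, mc);
    const StratProps& pr = ctx.get(res[g]);
    agg_coop += pr.gamma;
    agg_m1 += pr.m1;
    agg_m2 += pr.m2;
    label_add(pr.label, 1);
  }
  auto replace_group = [&](int g, const Strat& Y) {
    const StratProps& old = ctx.get(res[g]);
    agg_coop -= old.gamma;
    agg_m1 -= old.m1;
    agg_m2 -= old.m2;
    label_add(old.label, -1);
    res[g] = Y;
    const StratProps& nw = ctx.get(Y);
    agg_coop += nw.gamma;
    agg_m1 += nw.m1;
    agg_m2 += nw.m2;
    label_add(nw.label, 1);
  };

  double sum_coop = 0, sum_m1 = 0, sum_m2 = 0;
  double sum_fr = 0, sum_eff = 0, sum_riv = 0;
  double cnt = 0;
  SeriesAcc series;

  const long long n_steps = static_cast<long long>(steps);
  const long long n_burn = static_cast<long long>(burn_in);
  const long long n_thin = static_cast<long long>(thin);
  for (long long t = 1; t <= n_steps; ++t) {
    const int g = std::min(static_cast<int>(unif_rand() * M), M - 1);
    const Strat X = res[g];
    if (unif_rand() < r) {
      // mutation: a mutant lineage appears in the focal group
      Strat Y = sample_mutant_strat(m, mc);
      double piXY, piYX;
      double gXY, gYX;
      fr::pair_coop(X, Y, e, gXY, gYX);  // mutants are fresh; no caching
      piXY = b * gYX - gXY;
      piYX = b * gXY - gYX;
      const double rho = fr::fixation_rho(ctx.get(X).pi, piXY, piYX,
                                          ctx.get(Y).pi, N, sigma_in);
      if (unif_rand() < rho) replace_group(g, Y);
    } else {
      // out-group imitation from a random other group
      int h = std::min(static_cast<int>(unif_rand() * (M - 1)), M - 2);
      if (h >= g) ++h;
      const Strat Y = res[h];
      if (Y.bits != X.bits) {
        const double piX = ctx.get(X).pi;
        const double piY = ctx.get(Y).pi;
        double piXY, piYX;
        pair_payoffs(X, Y, piXY, piYX);
        const double T = fr::fermi(piX, piY, sigma_out) *
                         fr::fixation_rho(piX, piXY, piYX, piY, N, sigma_in);
        if (unif_rand() < T) replace_group(g, Y);
      }
    }
    if (t > n_burn) {
      sum_coop += agg_coop / M;
      sum_m1 += agg_m1 / M;
      sum_m2 += agg_m2 / M;
      sum_fr += agg_fr / M;
      sum_eff += agg_eff / M;
      sum_riv += agg_riv / M;
      cnt += 1;
      if (n_thin > 0 && t % n_thin == 0)
        series.push(static_cast<double>(t), agg_coop / M, agg_fr / M,
                    agg_eff / M, agg_riv / M, agg_m1 / M, agg_m2 / M);
    }
    if ((t & 4095) == 0) Rcpp::checkUserInterrupt();
  }

  return Rcpp::List::create(
      Rcpp::Named("mean_cooperation") = sum_coop / cnt,
      Rcpp::Named("frac_fr") = sum_fr / cnt,
      Rcpp::Named("frac_eff") = sum_eff / cnt,
      Rcpp::Named("frac_rival") = sum_riv / cnt,
      Rcpp::Named("mean_m1") = sum_m1 / cnt,
      Rcpp::Named("mean_m2") = sum_m2 / cnt,
      Rcpp::Named("series") = series.df());
}

// [[Rcpp::export]]
Rcpp::IntegerMatrix sample_mutants_cpp(int m, int n) {
  if (m < 1 || m > 3) Rcpp::stop("m must be in 1..3");
  Rcpp::IntegerMatrix out(n, fr::n_profiles(m));
  for (int k = 0; k < n; ++k) {
    Strat s = sample_mutant_strat(m, m);
    for (int i = 0; i < fr::n_profiles(m); ++i)
      out(k, i) = static_cast<int>((s.bits >> i) & 1ULL);
  }
  return out;
}
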