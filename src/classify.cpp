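#include "fr_core.h"

namespace fr {

// Rivalry test at e = 0.  Nodes are the full-memory joint states of the
// strategy's capacity (at least 1); from each node the focal action is the
// deterministic prescription while the co-player's action is free, giving
// two outgoing edges.  Edge weight is the focal-minus-co-player payoff
// difference of the new round, normalized to {-1, 0, +1} (the sign is
// independent of b and c).  The strategy is a rival iff the graph has no
// negative-weight cycle, checked by Floyd-Warshall over shortest walks
// with early exit on a negative diagonal.
bool is_rival(const Strat& s0) {
  const Strat s = (s0.m == 0) ? reindex(s0, 1) : s0;
  const int m = s.m;
  const int n = n_profiles(m);
  const uint64_t mask = (1ULL << m) - 1;
  const int INF = 1 << 28;
  std::vector<int> d(static_cast<size_t>(n) * n, INF);
  for (int i = 0; i < n; ++i) {
    const uint64_t A = (static_cast<uint64_t>(i) >> m) & mask;
    const uint64_t B = static_cast<uint64_t>(i) & mask;
    const int ap = act(s, A, B);
    const uint64_t A2 = ((A << 1) | static_cast<uint64_t>(ap)) & mask;
    for (int bp = 0; bp <= 1; ++bp) {
      const uint64_t B2 = ((B << 1) | static_cast<uint64_t>(bp)) & mask;
      const int j = static_cast<int>((A2 << m) | B2);
      const int w = (ap == bp) ? 0 : (ap == 1 ? -1 : 1);
      int& ref = d[static_cast<size_t>(i) * n + j];
      if (w < ref) ref = w;
    }
  }
  for (int k = 0; k < n; ++k) {
    for (int i = 0; i < n; ++i) {
      const int dik = d[static_cast<size_t>(i) * n + k];
      if (dik >= INF) continue;
      const int* dk = &d[static_cast<size_t>(k) * n];
      int* di = &d[static_cast<size_t>(i) * n];
      for (int j = 0; j < n; ++j) {
        if (dk[j] >= INF) continue;
        const int via = dik + dk[j];
        if (via < di[j]) di[j] = via;
      }
    }
    for (int i = 0; i < n; ++i)
      if (d[static_cast<size_t>(i) * n + i] < 0) return false;
  }
  return true;
}

int class_label(const Strat& s, double e_eff, double threshold) {
  const bool eff = is_efficient(s, e_eff, threshold);
  const bool riv = is_rival(s);
  if (eff && riv) return 3;
  if (riv) return 2;
  if (eff) return 1;
  return 0;
}

}  // namespace fr

// ---------------------------------------------------------------------------

static fr::Strat strat_in(const Rcpp::IntegerVector& table) {
  const int n = table.size();
  int m = -1;
  for (int k = 0; k <= 3; ++k)
    if (n == (1 << (2 * k))) m = k;
  if (m < 0) Rcpp::stop("invalid strategy table length");
  fr::Strat s(m, 0ULL);
  for (int i = 0; i < n; ++i)
    if (table[i] == 1) s.bits |= (1ULL << i);
  return s;
}

// [[Rcpp::export]]
bool is_rival_cpp(Rcpp::IntegerVector table) {
  return fr::is_rival(strat_in(table));
}

// [[Rcpp::export]]
bool is_efficient_cpp(Rcpp::IntegerVector table, double e, double threshold) {
  return fr::is_efficient(strat_in(table), e, threshold);
}

// [[Rcpp::export]]
int class_label_cpp(Rcpp::IntegerVector table, double e, double threshold) {
  return fr::class_label(strat_in(table), e, threshold);
}

// --- exact-memory class machinery ------------------------------------------
//
// A class table for the exact-memory class (m1, m2) assigns an action to
// each of the 2^(m1+m2) short histories h = (A1 << m2) | B1 (A1: m1 own
// bits, B1: m2 co-player bits; most recent round in bit 0).  Its exact
// memory is (m1, m2) iff it depends on a_{m1} (when m1 > 0) and on
// b_{m2} (when m2 > 0).

static bool exact_memory_class_table(uint64_t t, int m1, int m2) {
  const int L = 1 << (m1 + m2);
  if (m1 > 0) {
    const uint64_t flip = 1ULL << (m2 + m1 - 1);
    bool dep = false;
    for (int h = 0; h < L && !dep; ++h) {
      if (h & flip) continue;
      dep = ((t >> h) & 1ULL) != ((t >> (h | flip)) & 1ULL);
    }
    if (!dep) return false;
  }
  if (m2 > 0) {
    const uint64_t flip = 1ULL << (m2 - 1);
    bool dep = false;
    for (int h = 0; h < L && !dep; ++h) {
      if (h & flip) continue;
      dep = ((t >> h) & 1ULL) != ((t >> (h | flip)) & 1ULL);
    }
    if (!dep) return false;
  }
  return true;
}

// Embed a class table into a full square table at capacity max(m1, m2, 1).
static fr::Strat embed_class_table(uint64_t t, int m1, int m2) {
  const int M = std::max(1, std::max(m1, m2));
  const uint64_t mask1 = (m1 == 0) ? 0ULL : ((1ULL << m1) - 1);
  const uint64_t mask2 = (m2 == 0) ? 0ULL : ((1ULL << m2) - 1);
  const uint64_t maskM = (1ULL << M) - 1;
  fr::Strat s(M, 0ULL);
  const int n = fr::n_profiles(M);
  for (int i = 0; i < n; ++i) {
    const uint64_t A = (static_cast<uint64_t>(i) >> M) & maskM;
    const uint64_t B = static_cast<uint64_t>(i) & maskM;
    const uint64_t h = ((A & mask1) << m2) | (B & mask2);
    if ((t >> h) & 1ULL) s.bits |= (1ULL << i);
  }
  return s;
}

// [[Rcpp::export]]
Rcpp::List enumerate_class_cpp(int m1, int m2) {
  if (m1 < 0 || m2 < 0 || m1 > 3 || m2 > 3) Rcpp::stop("m1, m2 must be in 0..3");
  if (m1 + m2 > 4)
    Rcpp::stop("exhaustive enumeration is limited to m1 + m2 <= 4 "
               "(use sampling for larger classes)");
  const int L = 1 << (m1 + m2);
  const uint64_t total = 1ULL << L;
  std::vector<double> keep;
  for (uint64_t t = 0; t < total; ++t)
    if (exact_memory_class_table(t, m1, m2)) keep.push_back(static_cast<double>(t));
  const int M = std::max(1, std::max(m1, m2));
  Rcpp::IntegerMatrix tables(static_cast<int>(keep.size()), fr::n_profiles(M));
  for (size_t k = 0; k < keep.size(); ++k) {
    fr::Strat s = embed_class_table(static_cast<uint64_t>(keep[k]), m1, m2);
    for (int i = 0; i < fr::n_profiles(M); ++i)
      tables(static_cast<int>(k), i) = static_cast<int>((s.bits >> i) & 1ULL);
  }
  return Rcpp::List::create(Rcpp::Named("m_cap") = M,
                            Rcpp::Named("tables") = tables);
}

// Exhaustive census of one exact-memory class: counts of efficient, rival
// and FR strategies (and their class tables for the FRs).
// [[Rcpp::export]]
Rcpp::List census_exhaustive_cpp(int m1, int m2, double e_eff,
                                 double threshold) {
  if (m1 < 0 || m2 < 0 || m1 > 3 || m2 > 3) Rcpp::stop("m1, m2 must be in 0..3");
  if (m1 + m2 > 4) Rcpp::stop("class too large for exhaustive census");
  const int L = 1 << (m1 + m2);
  const uint64_t total = 1ULL << L;
  long n_total = 0, n_eff = 0, n_riv = 0, n_fr = 0;
  std::vector<double> fr_tables;
  for (uint64_t t = 0; t < total; ++t) {
    if (!exact_memory_class_table(t, m1, m2)) continue;
    ++n_total;
    fr::Strat s = embed_class_table(t, m1, m2);
    const bool eff = fr::is_efficient(s, e_eff, threshold);
    const bool riv = fr::is_rival(s);
    if (eff) ++n_eff;
    if (riv) ++n_riv;
    if (eff && riv) {
      ++n_fr;
      fr_tables.push_back(static_cast<double>(t));
    }
    if ((t & 0xFFFULL) == 0) Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(
      Rcpp::Named("n_total") = static_cast<double>(n_total),
      Rcpp::Named("n_efficient") = static_cast<double>(n_eff),
      Rcpp::Named("n_rival") = static_cast<double>(n_riv),
      Rcpp::Named("n_fr") = static_cast<double>(n_fr),
      Rcpp::Named("fr_class_tables") = Rcpp::wrap(fr_tables));
}

// Draw a uniform class table with exact memory (m1, m2) by rejection.
static uint64_t sample_exact_class_table(int m1, int m2, int max_tries) {
  const int L = 1 << (m1 + m2);
  for (int tries = 0; tries < max_tries; ++tries) {
    uint64_t t = 0;
    for (int h = 0; h < L; ++h)
      if (unif_rand() < 0.5) t |= (1ULL << h);
    if (exact_memory_class_table(t, m1, m2)) return t;
  }
  Rcpp::stop("rejection sampling failed to hit the exact-memory class");
}

// Monte Carlo census of one class from n_samples uniform exact-class draws.
// [[Rcpp::export]]
Rcpp::List census_sample_cpp(int m1, int m2, int n_samples, double e_eff,
                             double threshold) {
  if (m1 < 0 || m2 < 0 || m1 > 3 || m2 > 3) Rcpp::stop("m1, m2 must be in 0..3");
  long n_eff = 0, n_riv = 0, n_fr = 0;
  for (int k = 0; k < n_samples; ++k) {
    const uint64_t t = sample_exact_class_table(m1, m2, 10000);
    fr::Strat s = embed_class_table(t, m1, m2);
    const bool eff = fr::is_efficient(s, e_eff, threshold);
    const bool riv = fr::is_rival(s);
    if (eff) ++n_eff;
    if (riv) ++n_riv;
    if (eff && riv) ++n_fr;
    if ((k & 0xFF) == 0) Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(
      Rcpp::Named("n_efficient") = static_cast<double>(n_eff),
      Rcpp::Named("n_rival") = static_cast<double>(n_riv),
      Rcpp::Named("n_fr") = static_cast<double>(n_fr));
}

// [[Rcpp::export]]
Rcpp::IntegerVector embed_class_table_cpp(double class_table, int m1, int m2) {
  fr::Strat s = embed_class_table(static_cast<uint64_t>(class_table), m1, m2);
  Rcpp::IntegerVector out(fr::n_profiles(s.m));
  for (int i = 0; i < fr::n_profiles(s.m); ++i)
    out[i] = static_cast<int>((s.bits >> i) & 1ULL);
  return out;
}
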