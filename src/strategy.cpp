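#include "fr_core.h"

namespace fr {

void memory_lengths(const Strat& s, int& m1, int& m2) {
  const int m = s.m;
  const int n = n_profiles(m);
  m1 = 0;
  m2 = 0;
  // m1 = deepest own round the table depends on.  Testing dependence on
  // a_d for the largest d first reproduces the wildcard cascade: once the
  // table is known to be independent of all rounds deeper than d, the
  // wildcarded prescriptions p_{*..*a_d..} are well defined and differ in
  // a_d iff some pair of profiles differing only in a_d differ.
  for (int d = m; d >= 1 && m1 == 0; --d) {
    const uint64_t flip = 1ULL << (m + d - 1);  // a_d lives in A's bit d-1
    for (int i = 0; i < n; ++i) {
      if (i & flip) continue;
      if (((s.bits >> i) & 1ULL) != ((s.bits >> (i | flip)) & 1ULL)) {
        m1 = d;
        break;
      }
    }
  }
  for (int d = m; d >= 1 && m2 == 0; --d) {
    const uint64_t flip = 1ULL << (d - 1);  // b_d lives in B's bit d-1
    for (int i = 0; i < n; ++i) {
      if (i & flip) continue;
      if (((s.bits >> i) & 1ULL) != ((s.bits >> (i | flip)) & 1ULL)) {
        m2 = d;
        break;
      }
    }
  }
}

Strat reindex(const Strat& s, int m_target) {
  if (m_target == s.m) return s;
  int m1, m2;
  memory_lengths(s, m1, m2);
  const int m_min = std::max(m1, m2);
  if (m_target < m_min)
    Rcpp::stop("cannot represent a memory-(%d,%d) strategy at capacity %d",
               m1, m2, m_target);
  const int M = m_target;
  const uint64_t mask_src = (s.m == 0) ? 0ULL : ((1ULL << s.m) - 1);
  const uint64_t mask_tgt = (1ULL << M) - 1;
  Strat out(M, 0ULL);
  const int n = n_profiles(M);
  for (int i = 0; i < n; ++i) {
    uint64_t A = (static_cast<uint64_t>(i) >> M) & mask_tgt;
    uint64_t B = static_cast<uint64_t>(i) & mask_tgt;
    // when shrinking, bits beyond s.m are dropped; legal because the
    // prescription does not depend on them (checked above)
    if (act(s, A & mask_src, B & mask_src))
      out.bits |= (1ULL << i);
  }
  return out;
}

}  // namespace fr

// ---------------------------------------------------------------------------
// R interface helpers: strategies cross the boundary as integer 0/1 tables.

static fr::Strat strat_from_table(const Rcpp::IntegerVector& table) {
  const int n = table.size();
  int m = -1;
  for (int k = 0; k <= 3; ++k)
    if (n == (1 << (2 * k))) m = k;
  if (m < 0)
    Rcpp::stop("strategy table must have length 2^(2*m_cap) with m_cap in 0..3");
  fr::Strat s(m, 0ULL);
  for (int i = 0; i < n; ++i) {
    if (table[i] != 0 && table[i] != 1)
      Rcpp::stop("strategy tables must be deterministic (entries 0 or 1)");
    if (table[i] == 1) s.bits |= (1ULL << i);
  }
  return s;
}

static Rcpp::IntegerVector table_from_strat(const fr::Strat& s) {
  const int n = fr::n_profiles(s.m);
  Rcpp::IntegerVector table(n);
  for (int i = 0; i < n; ++i)
    table[i] = static_cast<int>((s.bits >> i) & 1ULL);
  return table;
}

// [[Rcpp::export]]
Rcpp::IntegerVector memory_lengths_cpp(Rcpp::IntegerVector table) {
  fr::Strat s = strat_from_table(table);
  int m1, m2;
  fr::memory_lengths(s, m1, m2);
  return Rcpp::IntegerVector::create(Rcpp::Named("m1") = m1,
                                     Rcpp::Named("m2") = m2);
}

// [[Rcpp::export]]
Rcpp::IntegerVector reindex_cpp(Rcpp::IntegerVector table, int m_target) {
  if (m_target < 0 || m_target > 3)
    Rcpp::stop("m_target must be in 0..3");
  return table_from_strat(fr::reindex(strat_from_table(table), m_target));
}
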