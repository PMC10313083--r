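#include "fr_core.h"

namespace fr {

// Build the row-stochastic transition matrix of the pair chain of p vs q
// at common capacity m (both already reindexed).  Each state (A, B) has
// four successors given by the players' effective actions; q reads the
// index-swapped profile (B, A).
static arma::mat transition(const Strat& p, const Strat& q, double e) {
  const int m = p.m;
  const int n = n_profiles(m);
  const uint64_t mask = (1ULL << m) - 1;
  arma::mat T(n, n, arma::fill::zeros);
  for (int i = 0; i < n; ++i) {
    const uint64_t A = (static_cast<uint64_t>(i) >> m) & mask;
    const uint64_t B = static_cast<uint64_t>(i) & mask;
    const double cp = (1.0 - e) * act(p, A, B) + e * (1 - act(p, A, B));
    const double cq = (1.0 - e) * act(q, B, A) + e * (1 - act(q, B, A));
    for (int ap = 0; ap <= 1; ++ap) {
      const double wa = ap ? cp : 1.0 - cp;
      const uint64_t A2 = ((A << 1) | static_cast<uint64_t>(ap)) & mask;
      for (int bp = 0; bp <= 1; ++bp) {
        const double wb = bp ? cq : 1.0 - cq;
        const uint64_t B2 = ((B << 1) | static_cast<uint64_t>(bp)) & mask;
        T(i, static_cast<int>((A2 << m) | B2)) += wa * wb;
      }
    }
  }
  return T;
}

arma::vec pair_stationary(const Strat& p, const Strat& q, double e,
                          int& m_out) {
  const int m = std::max(1, std::max(p.m, q.m));
  m_out = m;
  const Strat pl = reindex(p, m);
  const Strat ql = reindex(q, m);
  const int n = n_profiles(m);
  const arma::mat T = transition(pl, ql, e);
  arma::mat A = T.t() - arma::eye(n, n);
  A.row(n - 1).ones();  // replace one equation by the normalization
  arma::vec rhs(n, arma::fill::zeros);
  rhs(n - 1) = 1.0;
  arma::vec v;
  bool ok = arma::solve(v, A, rhs) && v.is_finite();
  if (ok) {
    // the system can be ill-conditioned for tiny e; accept the LU solution
    // only if it actually satisfies v T = v
    const double resid = arma::norm(T.t() * v - v, "inf");
    ok = resid < 1e-9 && v.min() > -1e-9;
  }
  if (!ok) {
    // least-squares on the full stacked system [T' - I; 1'] v = [0; 1]
    arma::mat B(n + 1, n);
    B.rows(0, n - 1) = T.t() - arma::eye(n, n);
    B.row(n).ones();
    arma::vec c(n + 1, arma::fill::zeros);
    c(n) = 1.0;
    if (!arma::solve(v, B, c) || !v.is_finite())
      Rcpp::stop("stationary-distribution solve failed (e = %g)", e);
  }
  v.clamp(0.0, arma::datum::inf);
  v /= arma::accu(v);
  return v;
}

void pair_coop(const Strat& p, const Strat& q, double e,
               double& gpq, double& gqp) {
  int m;
  arma::vec v = pair_stationary(p, q, e, m);
  const int n = n_profiles(m);
  gpq = 0.0;
  gqp = 0.0;
  for (int i = 0; i < n; ++i) {
    if ((i >> m) & 1) gpq += v(i);  // focal's last action was C
    if (i & 1) gqp += v(i);         // co-player's last action was C
  }
}

double self_coop(const Strat& s, double e) {
  double g, g2;
  pair_coop(s, s, e, g, g2);
  return g;
}

double fermi(double pi_x, double pi_y, double sigma) {
  double z = sigma * (pi_x - pi_y);
  if (z > 700.0) z = 700.0;
  if (z < -700.0) z = -700.0;
  return 1.0 / (1.0 + std::exp(z));
}

double fixation_rho(double piXX, double piXY, double piYX, double piYY,
                    int N, double sigma_in) {
  // rho = 1 / sum_{j=0}^{N-1} exp(L_j), computed as exp(-logsumexp)
  double lmax = 0.0;  // L_0 = 0
  std::vector<double> L(N);
  for (int j = 0; j < N; ++j) {
    L[j] = sigma_in * j *
           ((2.0 * N - j - 3.0) * piXX + (j + 1.0) * piXY -
            (2.0 * N - j - 1.0) * piYX - (j - 1.0) * piYY) /
           (2.0 * (N - 1.0));
    if (L[j] > lmax) lmax = L[j];
  }
  double s = 0.0;
  for (int j = 0; j < N; ++j) s += std::exp(L[j] - lmax);
  return std::exp(-(lmax + std::log(s)));
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
Rcpp::NumericMatrix transition_matrix_cpp(Rcpp::IntegerVector p,
                                          Rcpp::IntegerVector q, double e) {
  fr::Strat sp = strat_in(p), sq = strat_in(q);
  const int m = std::max(1, std::max(sp.m, sq.m));
  arma::mat T = [&]() {
    fr::Strat pl = fr::reindex(sp, m), ql = fr::reindex(sq, m);
    const int n = fr::n_profiles(m);
    arma::mat out(n, n, arma::fill::zeros);
    const uint64_t mask = (1ULL << m) - 1;
    for (int i = 0; i < n; ++i) {
      const uint64_t A = (static_cast<uint64_t>(i) >> m) & mask;
      const uint64_t B = static_cast<uint64_t>(i) & mask;
      const double cp = (1.0 - e) * fr::act(pl, A, B) + e * (1 - fr::act(pl, A, B));
      const double cq = (1.0 - e) * fr::act(ql, B, A) + e * (1 - fr::act(ql, B, A));
      for (int ap = 0; ap <= 1; ++ap)
        for (int bp = 0; bp <= 1; ++bp) {
          const uint64_t A2 = ((A << 1) | static_cast<uint64_t>(ap)) & mask;
          const uint64_t B2 = ((B << 1) | static_cast<uint64_t>(bp)) & mask;
          out(i, static_cast<int>((A2 << m) | B2)) +=
              (ap ? cp : 1.0 - cp) * (bp ? cq : 1.0 - cq);
        }
    }
    return out;
  }();
  return Rcpp::wrap(T);
}

// [[Rcpp::export]]
Rcpp::List pair_stationary_cpp(Rcpp::IntegerVector p, Rcpp::IntegerVector q,
                               double e) {
  int m;
  arma::vec v = fr::pair_stationary(strat_in(p), strat_in(q), e, m);
  double gpq, gqp;
  fr::pair_coop(strat_in(p), strat_in(q), e, gpq, gqp);
  return Rcpp::List::create(Rcpp::Named("v") = Rcpp::wrap(v),
                            Rcpp::Named("m") = m,
                            Rcpp::Named("gamma_pq") = gpq,
                            Rcpp::Named("gamma_qp") = gqp);
}

// [[Rcpp::export]]
double fermi_cpp(double pi_x, double pi_y, double sigma) {
  return fr::fermi(pi_x, pi_y, sigma);
}

// [[Rcpp::export]]
double fixation_rho_cpp(double piXX, double piXY, double piYX, double piYY,
                        int N, double sigma_in) {
  if (N < 2) Rcpp::stop("N must be >= 2");
  return fr::fixation_rho(piXX, piXY, piYX, piYY, N, sigma_in);
}
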