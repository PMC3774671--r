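#include <Rcpp.h>
using namespace Rcpp;

// Binomial admixture model EM with SQUAREM extrapolation.
// g: N x M dosages (0/1/2, NA missing); Q: N x K row-stochastic; P: K x M.
//
// One pass computes the log-likelihood at the current parameters and the
// plain EM update. Squared extrapolation (SQUAREM) is applied over pairs of
// EM steps with a monotonicity guard: an extrapolated state is accepted
// only if its likelihood does not fall below the single-EM-step state, so
// the reported trace is non-decreasing (asserted).

static double em_pass(const NumericMatrix& g,
                      const NumericMatrix& Q, const NumericMatrix& P,
                      NumericMatrix& Qout, NumericMatrix& Pout,
                      const std::vector<double>& nobs, bool update) {
  const int n = g.nrow(), m = g.ncol(), K = Q.ncol();
  double ll = 0.0;
  NumericMatrix Pnum(K, m), Pden(K, m);
  if (update) {
    std::fill(Qout.begin(), Qout.end(), 0.0);
  }
  std::vector<double> fk(K);
  for (int j = 0; j < m; ++j) {
    for (int i = 0; i < n; ++i) {
      double gij = g(i, j);
      if (NumericMatrix::is_na(gij)) continue;
      double f = 0.0;
      for (int k = 0; k < K; ++k) {
        fk[k] = Q(i, k) * P(k, j);
        f += fk[k];
      }
      ll += gij * std::log(f) + (2.0 - gij) * std::log(1.0 - f);
      if (!update) continue;
      double a = gij / f;                 // A1-allele responsibility scale
      double b = (2.0 - gij) / (1.0 - f); // A2-allele responsibility scale
      for (int k = 0; k < K; ++k) {
        double ra = fk[k] * a;                 // E[A1 copies from cluster k]
        double rb = (Q(i, k) - fk[k]) * b;     // E[A2 copies from cluster k]
        Qout(i, k) += ra + rb;
        Pnum(k, j) += ra;
        Pden(k, j) += ra + rb;
      }
    }
  }
  if (update) {
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int k = 0; k < K; ++k) {
        double v = Qout(i, k) / (2.0 * nobs[i]);
        if (v < 1e-12) v = 1e-12;
        Qout(i, k) = v;
        s += v;
      }
      for (int k = 0; k < K; ++k) Qout(i, k) /= s;
    }
    for (int k = 0; k < K; ++k)
      for (int j = 0; j < m; ++j) {
        double v = Pden(k, j) > 0 ? Pnum(k, j) / Pden(k, j) : P(k, j);
        if (v < 1e-6) v = 1e-6;
        if (v > 1.0 - 1e-6) v = 1.0 - 1e-6;
        Pout(k, j) = v;
      }
  }
  return ll;
}

static void project(NumericMatrix& Q, NumericMatrix& P) {
  const int n = Q.nrow(), K = Q.ncol(), m = P.ncol();
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int k = 0; k < K; ++k) {
      if (Q(i, k) < 1e-12) Q(i, k) = 1e-12;
      s += Q(i, k);
    }
    for (int k = 0; k < K; ++k) Q(i, k) /= s;
  }
  for (int k = 0; k < K; ++k)
    for (int j = 0; j < m; ++j) {
      if (P(k, j) < 1e-6) P(k, j) = 1e-6;
      if (P(k, j) > 1.0 - 1e-6) P(k, j) = 1.0 - 1e-6;
    }
}

// [[Rcpp::export(name = ".admix_em_cpp")]]
List admix_em_cpp(NumericMatrix g, NumericMatrix Q0, NumericMatrix P0,
                  int max_iter, double tol) {
  const int n = g.nrow(), m = g.ncol(), K = Q0.ncol();
  NumericMatrix Q(clone(Q0)), P(clone(P0));
  NumericMatrix Q1(n, K), P1(K, m), Q2(n, K), P2(K, m);
  NumericMatrix Qs(n, K), Ps(K, m), Qt(n, K), Pt(K, m);
  std::vector<double> nobs(n, 0.0);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j)
      if (!NumericMatrix::is_na(g(i, j))) nobs[i] += 1.0;

  std::vector<double> trace;
  double prev = R_NegInf;
  bool converged = false;
  int passes = 0;
  auto record = [&](double ll) {
    if (ll + 1e-8 < prev)
      stop("EM decreased the likelihood; this is a bug");
    trace.push_back(ll);
    if (R_finite(prev) && ll - prev < tol) converged = true;
    prev = ll;
  };

  int cycles = 0;
  while (cycles < max_iter && !converged) {
    ++cycles;
    // theta0 -> theta1 -> theta2 (two plain EM steps)
    double ll0 = em_pass(g, Q, P, Q1, P1, nobs, true); ++passes;
    record(ll0);
    if (converged) break;
    double ll1 = em_pass(g, Q1, P1, Q2, P2, nobs, true); ++passes;
    record(ll1);
    if (converged) { Q = Q1; P = P1; break; }
    // SQUAREM: theta_sq = theta0 - 2a r + a^2 v, a = -||r||/||v|| in [-1000,-1]
    double rr = 0.0, vv = 0.0;
    for (int t = 0; t < n * K; ++t) {
      double r = Q1[t] - Q[t], v = Q2[t] - 2.0 * Q1[t] + Q[t];
      rr += r * r; vv += v * v;
    }
    for (int t = 0; t < K * m; ++t) {
      double r = P1[t] - P[t], v = P2[t] - 2.0 * P1[t] + P[t];
      rr += r * r; vv += v * v;
    }
    double alpha = vv > 0 ? -std::sqrt(rr / vv) : -1.0;
    if (alpha > -1.0) alpha = -1.0;
    if (alpha < -1000.0) alpha = -1000.0;
    bool accepted = false;
    if (alpha < -1.0) {
      for (int t = 0; t < n * K; ++t) {
        double r = Q1[t] - Q[t], v = Q2[t] - 2.0 * Q1[t] + Q[t];
        Qs[t] = Q[t] - 2.0 * alpha * r + alpha * alpha * v;
      }
      for (int t = 0; t < K * m; ++t) {
        double r = P1[t] - P[t], v = P2[t] - 2.0 * P1[t] + P[t];
        Ps[t] = P[t] - 2.0 * alpha * r + alpha * alpha * v;
      }
      project(Qs, Ps);
      double lls = em_pass(g, Qs, Ps, Qt, Pt, nobs, false); ++passes;
      if (lls >= ll1) {          // guard: never worse than one EM step
        Q = Qs; P = Ps;
        accepted = true;
      }
    }
    if (!accepted) { Q = Q2; P = P2; }
  }
  return List::create(_["Q"] = Q, _["P"] = P,
                      _["trace"] = NumericVector(trace.begin(), trace.end()),
                      _["converged"] = converged,
                      _["passes"] = passes);
}
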