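#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Gaussian (RBF) Gram matrix K[i, j] = exp(-gamma * ||X[i,] - Y[j,]||^2)
// [[Rcpp::export]]
NumericMatrix rbf_gram_cpp(NumericMatrix X, NumericMatrix Y, double gamma) {
  int n = X.nrow(), m = Y.nrow(), k = X.ncol();
  NumericMatrix K(n, m);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      double d2 = 0.0;
      for (int c = 0; c < k; ++c) {
        double d = X(i, c) - Y(j, c);
        d2 += d * d;
      }
      K(i, j) = std::exp(-gamma * d2);
    }
  }
  return K;
}

// epsilon-SVR dual in the beta = alpha - alpha* parameterization:
//   maximize  W(beta) = y'beta - eps * sum|beta| - 0.5 * beta' K beta
//   subject to sum(beta) = 0,  -C <= beta_i <= C
// SMO with exact pair subproblems: the gain along (e_i - e_j) is piecewise
// concave quadratic; its maximum is found by evaluating box endpoints, sign
// breakpoints and the per-sign stationary points. Pair selection anchors on
// the maximal KKT violators and picks the partner with the largest exact
// gain. Convergence is declared when the duality gap (with the bias chosen
// to minimize the primal exactly) drops below `tol`.
// [[Rcpp::export]]
List smo_svr_cpp(NumericMatrix K, NumericVector y, double C, double eps,
                 double tol, int max_iter) {
  int n = y.size();
  std::vector<double> beta(n, 0.0), f(n, 0.0); // f = K beta

  auto dual_obj = [&]() {
    double d = 0.0;
    for (int i = 0; i < n; ++i)
      d += y[i] * beta[i] - eps * std::fabs(beta[i]) - 0.5 * beta[i] * f[i];
    return d;
  };

  // exact gain of moving beta_i += t, beta_j -= t
  auto pair_gain = [&](int i, int j, double &t_out) {
    double gi = y[i] - f[i], gj = y[j] - f[j];
    double a = K(i, i) + K(j, j) - 2.0 * K(i, j);
    double tlo = std::max(-C - beta[i], beta[j] - C);
    double thi = std::min(C - beta[i], beta[j] + C);
    if (thi <= tlo) { t_out = 0.0; return 0.0; }
    double cand[8];
    int nc = 0;
    cand[nc++] = tlo; cand[nc++] = thi;
    cand[nc++] = -beta[i]; cand[nc++] = beta[j];
    if (a > 1e-14) {
      for (int si = -1; si <= 1; si += 2)
        for (int sj = -1; sj <= 1; sj += 2)
          cand[nc++] = (gi - gj - eps * si + eps * sj) / a;
    }
    double best_t = 0.0, best_g = 0.0;
    for (int c = 0; c < nc; ++c) {
      double t = std::min(std::max(cand[c], tlo), thi);
      double g = (gi - gj) * t - 0.5 * a * t * t
        - eps * (std::fabs(beta[i] + t) - std::fabs(beta[i]))
        - eps * (std::fabs(beta[j] - t) - std::fabs(beta[j]));
      if (g > best_g) { best_g = g; best_t = t; }
    }
    t_out = best_t;
    return best_g;
  };

  // duality gap with the primal-optimal bias: minimize over b the
  // piecewise-linear sum of tube violations (optimum at a breakpoint)
  std::vector<double> bp(2 * n);
  auto gap_now = [&](double &b_out) {
    double quad = 0.0;
    for (int i = 0; i < n; ++i) quad += 0.5 * beta[i] * f[i];
    for (int i = 0; i < n; ++i) {
      double r = y[i] - f[i];
      bp[2 * i] = r - eps;
      bp[2 * i + 1] = r + eps;
    }
    double best_slack = R_PosInf;
    std::vector<double> sl(2 * n);
    for (int c = 0; c < 2 * n; ++c) {
      double b = bp[c], s = 0.0;
      for (int i = 0; i < n; ++i) {
        double v = std::fabs(y[i] - f[i] - b) - eps;
        if (v > 0.0) s += v;
      }
      sl[c] = s;
      if (s < best_slack) best_slack = s;
    }
    // the minimizing set is an interval; report its midpoint
    double blo = R_PosInf, bhi = R_NegInf;
    for (int c = 0; c < 2 * n; ++c) {
      if (sl[c] <= best_slack + 1e-12 * (1.0 + best_slack)) {
        blo = std::min(blo, bp[c]);
        bhi = std::max(bhi, bp[c]);
      }
    }
    b_out = 0.5 * (blo + bhi);
    double primal = quad + C * best_slack;
    return primal - dual_obj();
  };

  double snap = 1e-12 * std::max(1.0, C);
  int it = 0, check_every = 32;
  bool converged = false;
  double gap = R_PosInf, b = 0.0;
  gap = gap_now(b);
  if (gap < tol) converged = true;

  while (!converged && it < max_iter) {
    // anchors: maximal up- and down-violators
    int ai = -1, aj = -1;
    double max_up = -R_PosInf, max_dn = -R_PosInf;
    for (int i = 0; i < n; ++i) {
      double g = y[i] - f[i];
      if (beta[i] < C - snap) {
        double up = (beta[i] >= 0.0) ? g - eps : g + eps;
        if (up > max_up) { max_up = up; ai = i; }
      }
      if (beta[i] > -C + snap) {
        double dn = (beta[i] <= 0.0) ? -g - eps : -g + eps;
        if (dn > max_dn) { max_dn = dn; aj = i; }
      }
    }
    if (ai < 0 || aj < 0 || max_up + max_dn < 1e-12) {
      // pairwise KKT satisfied: dual optimum
      gap = gap_now(b);
      converged = true;
      break;
    }

    // best partner for each anchor by exact gain
    double best_g = 0.0, best_t = 0.0;
    int bi = -1, bj = -1;
    for (int j = 0; j < n; ++j) {
      if (j != ai) {
        double t, g = pair_gain(ai, j, t);
        if (g > best_g) { best_g = g; best_t = t; bi = ai; bj = j; }
      }
      if (j != aj) {
        double t, g = pair_gain(j, aj, t);
        if (g > best_g) { best_g = g; best_t = t; bi = j; bj = aj; }
      }
    }
    if (bi < 0 || best_g <= 0.0) {
      gap = gap_now(b);
      converged = true;
      break;
    }

    // land exactly on a bound or sign breakpoint when the step is within
    // rounding of one, so near-glued coordinates cannot stall the sweep
    {
      double marks[4] = {-C - beta[bi], C - beta[bi], -beta[bi], beta[bj]};
      for (double mk : marks) {
        if (std::fabs(best_t - mk) < snap) { best_t = mk; break; }
      }
      double bj_marks[2] = {beta[bj] - C, beta[bj] + C};
      for (double mk : bj_marks) {
        if (std::fabs(best_t - mk) < snap) { best_t = mk; break; }
      }
    }
    beta[bi] += best_t;
    beta[bj] -= best_t;
    for (int m = 0; m < n; ++m) f[m] += best_t * (K(bi, m) - K(bj, m));
    ++it;

    if (it % check_every == 0) {
      // refresh f = K beta to purge accumulated incremental rounding
      if (it % (check_every * 32) == 0) {
        for (int m = 0; m < n; ++m) {
          double acc = 0.0;
          for (int i2 = 0; i2 < n; ++i2) acc += K(i2, m) * beta[i2];
          f[m] = acc;
        }
      }
      gap = gap_now(b);
      if (gap < tol) { converged = true; break; }
    }
  }
  if (!converged) gap = gap_now(b);

  // bias from free support vectors when available, else the primal-optimal b
  double sv_tol = 1e-8 * C;
  double bsum = 0.0;
  int nfree = 0;
  for (int i = 0; i < n; ++i) {
    double ab = std::fabs(beta[i]);
    if (ab > sv_tol && ab < C * (1.0 - 1e-8)) {
      bsum += y[i] - f[i] - (beta[i] > 0 ? eps : -eps);
      ++nfree;
    }
  }
  if (nfree > 0) b = bsum / nfree;

  return List::create(
    _["beta"] = NumericVector(beta.begin(), beta.end()),
    _["b"] = b,
    _["objective"] = dual_obj(),
    _["gap"] = gap,
    _["iterations"] = it,
    _["converged"] = converged
  );
}
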