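#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// EM kernel for the VAF mixture model. Mirrors the plain-R engine in
// R/em.R step for step (the test suite asserts agreement): beta-binomial
// true-clone likelihoods with moment-matched pseudo-counts, a binomial
// sequencing-error likelihood for zero-centroid clusters, context-dependent
// priors keyed on (alt == 0?, centroid == 0?), per-sample posteriors
// multiplied across samples, hard or fuzzy membership, weighted-mean
// centroid updates with empty-cluster dropping, and the three-part
// stopping rule.

static inline double clamp_mu(double mu) {
  const double eps = 1e-6;
  if (mu < eps) return eps;
  if (mu > 1.0 - eps) return 1.0 - eps;
  return mu;
}

// [[Rcpp::export]]
List cpp_run_em(IntegerMatrix alt, IntegerMatrix total, NumericMatrix vaf,
                NumericMatrix mu0, NumericVector pse, double fp_prior,
                double tn_prior_total, double c_scale, bool hard,
                int max_iter, int min_iter) {
  const int m = alt.nrow();
  const int n = alt.ncol();
  int K = mu0.ncol();  // k true clusters + FV (last column, fixed at 0)

  // centroids, column-major m x K, true columns clamped
  std::vector<double> mu(m * K);
  for (int y = 0; y < K; ++y)
    for (int i = 0; i < m; ++i)
      mu[y * m + i] = (y == K - 1) ? 0.0 : clamp_mu(mu0(i, y));

  // per (i,j) precomputations: the binomial error loglik and the
  // mu-independent part of the beta-binomial loglik,
  // lchoose(n,a) + lgamma(n*c) - lgamma(n + n*c)   (alpha + beta = n*c)
  std::vector<double> base(m * n), lbin(m * n);
  std::vector<int> udepth;      // distinct positive depths
  std::vector<int> uidx(m * n); // (i,j) -> index into udepth
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < m; ++i) {
      int nt = total(i, j), na = alt(i, j);
      if (nt > 0) {
        base[j * m + i] = R::lchoose(nt, na) +
          R::lgammafn(nt * c_scale) - R::lgammafn(nt + nt * c_scale);
        lbin[j * m + i] = R::dbinom(na, nt, pse[j], 1);
        int ui = -1;
        for (size_t q = 0; q < udepth.size(); ++q)
          if (udepth[q] == nt) { ui = (int)q; break; }
        if (ui < 0) { udepth.push_back(nt); ui = (int)udepth.size() - 1; }
        uidx[j * m + i] = ui;
      } else {
        base[j * m + i] = 0.0;
        lbin[j * m + i] = 0.0;
        uidx[j * m + i] = -1;
      }
    }
  std::vector<double> lgab(udepth.size());

  std::vector<double> lognum(n * K), Lam(n * K), The(n * K);
  std::vector<double> prev_mu, prev_the;
  double prev_obj = NA_REAL;
  std::vector<double> trace;
  bool converged = false, aborted = false;
  int it = 0;

  auto e_step = [&](double &obj_out) {
    std::fill(lognum.begin(), lognum.end(), 0.0);
    for (int i = 0; i < m; ++i) {
      // context priors for this sample; zero-centroid set is the FV column
      // plus any true column clamped-to-zero (cannot occur after clamping,
      // but count defensively)
      int nzero = 0;
      for (int y = 0; y < K; ++y) if (mu[y * m + i] == 0.0) ++nzero;
      int nz = K - nzero;
      double lp_pos_zero = std::log(fp_prior);
      double lp_pos_true = std::log((1.0 - nzero * fp_prior) / nz);
      double lp_zero_zero = std::log(tn_prior_total / nzero);
      double lp_zero_true = std::log((1.0 - tn_prior_total) / nz);
      for (int y = 0; y < K; ++y) {
        double muy = mu[y * m + i];
        bool iszero = (muy == 0.0);
        if (!iszero) {
          // per distinct depth: lgamma(alpha) + lgamma(beta)
          for (size_t q = 0; q < udepth.size(); ++q) {
            double ab = udepth[q] * c_scale;
            lgab[q] = R::lgammafn(muy * ab) + R::lgammafn((1.0 - muy) * ab);
          }
        }
        for (int j = 0; j < n; ++j) {
          int nt = total(i, j), na = alt(i, j);
          double ll = 0.0;
          if (nt > 0) {
            if (iszero) {
              ll = lbin[j * m + i];
            } else {
              double ab = nt * c_scale;
              double al = muy * ab;
              ll = base[j * m + i] + R::lgammafn(na + al) +
                R::lgammafn(nt - na + ab - al) - lgab[uidx[j * m + i]];
            }
          }
          double lp = (na == 0) ? (iszero ? lp_zero_zero : lp_zero_true)
                                : (iszero ? lp_pos_zero : lp_pos_true);
          lognum[y * n + j] += ll + lp;
        }
      }
    }
    // row softmax + objective
    double obj = 0.0;
    for (int j = 0; j < n; ++j) {
      double mx = -INFINITY;
      for (int y = 0; y < K; ++y) mx = std::max(mx, lognum[y * n + j]);
      double sw = 0.0;
      for (int y = 0; y < K; ++y) sw += std::exp(lognum[y * n + j] - mx);
      if (!std::isfinite(mx) || sw == 0.0) {
        for (int y = 0; y < K; ++y) Lam[y * n + j] = 1.0 / K;
      } else {
        for (int y = 0; y < K; ++y)
          Lam[y * n + j] = std::exp(lognum[y * n + j] - mx) / sw;
        obj += mx + std::log(sw);
      }
    }
    obj_out = obj;
    // membership
    if (hard) {
      for (int j = 0; j < n; ++j) {
        int best = 0;
        double bv = Lam[j];
        for (int y = 1; y < K; ++y)
          if (Lam[y * n + j] > bv) { bv = Lam[y * n + j]; best = y; }
        for (int y = 0; y < K; ++y) The[y * n + j] = (y == best) ? 1.0 : 0.0;
      }
    } else {
      std::copy(Lam.begin(), Lam.end(), The.begin());
    }
  };

  while (it < max_iter) {
    ++it;
    double obj;
    e_step(obj);
    trace.push_back(obj);

    // M step with empty-cluster dropping
    std::vector<double> w(K - 1, 0.0);
    for (int y = 0; y < K - 1; ++y)
      for (int j = 0; j < n; ++j) w[y] += The[y * n + j];
    int keepn = 0;
    for (int y = 0; y < K - 1; ++y) if (w[y] >= 1e-12) ++keepn;
    if (keepn == 0) { aborted = true; break; }
    bool dropped = (keepn < K - 1);

    int Knew = keepn + 1;
    std::vector<double> mu_new(m * Knew, 0.0), the_new;
    if (dropped) the_new.assign(n * Knew, 0.0);
    int yy = 0;
    for (int y = 0; y < K - 1; ++y) {
      if (w[y] < 1e-12) continue;
      for (int i = 0; i < m; ++i) {
        double num = 0.0;
        for (int j = 0; j < n; ++j) num += vaf(i, j) * The[y * n + j];
        mu_new[yy * m + i] = clamp_mu(num / w[y]);
      }
      if (dropped)
        for (int j = 0; j < n; ++j) the_new[yy * n + j] = The[y * n + j];
      ++yy;
    }
    if (dropped) {
      for (int j = 0; j < n; ++j)
        the_new[(Knew - 1) * n + j] = The[(K - 1) * n + j];
    }

    // exact fixed point: if neither the centroids nor the membership moved
    // at all, every later iterate is identical and the stopping rule would
    // fire unchanged at the iteration floor - skip the no-op iterations
    bool fixed_point = false;
    if (!dropped && prev_mu.size() == mu_new.size() &&
        prev_the.size() == The.size()) {
      fixed_point = true;
      for (size_t q = 0; q < mu_new.size() && fixed_point; ++q)
        if (mu_new[q] != prev_mu[q]) fixed_point = false;
      for (size_t q = 0; q < The.size() && fixed_point; ++q)
        if (The[q] != prev_the[q]) fixed_point = false;
    }

    // convergence: > min_iter iterations AND (obj gap < 1% OR all centroid
    // moves < 0.01 OR unchanged membership)
    bool stop = fixed_point;
    if (it > min_iter && !std::isnan(prev_obj)) {
      bool b1 = std::fabs(obj - prev_obj) < 0.01 * std::fabs(prev_obj);
      bool b2 = false, b3 = false;
      if (!dropped && prev_mu.size() == mu_new.size()) {
        double mv = 0.0;
        for (size_t q = 0; q < mu_new.size(); ++q)
          mv = std::max(mv, std::fabs(mu_new[q] - prev_mu[q]));
        b2 = (mv < 0.01);
      }
      const std::vector<double> &the_cur = dropped ? the_new : The;
      if (prev_the.size() == the_cur.size()) {
        double tv = 0.0;
        for (size_t q = 0; q < the_cur.size(); ++q)
          tv = std::max(tv, std::fabs(the_cur[q] - prev_the[q]));
        b3 = (tv < 1e-12);
      }
      stop = b1 || b2 || b3;
    }

    prev_obj = obj;
    prev_mu = mu_new;
    prev_the = dropped ? the_new : The;
    mu = std::move(mu_new);
    if (dropped) {
      K = Knew;
      lognum.assign(n * K, 0.0);
      Lam.assign(n * K, 0.0);
      The.assign(n * K, 0.0);
    }
    if (stop) { converged = true; break; }
  }

  if (aborted) return List::create(Named("aborted") = true);

  // refresh the posterior at the final centroids
  double obj_final;
  e_step(obj_final);
  trace.push_back(obj_final);

  NumericMatrix mu_out(m, K), Lam_out(n, K), The_out(n, K);
  for (int y = 0; y < K; ++y) {
    for (int i = 0; i < m; ++i) mu_out(i, y) = mu[y * m + i];
    for (int j = 0; j < n; ++j) {
      Lam_out(j, y) = Lam[y * n + j];
      The_out(j, y) = The[y * n + j];
    }
  }
  return List::create(
      Named("mu") = mu_out, Named("Lambda") = Lam_out,
      Named("Theta") = The_out, Named("objective") = obj_final,
      Named("objective_trace") = NumericVector(trace.begin(), trace.end()),
      Named("n_iter") = it, Named("converged") = converged,
      Named("aborted") = false);
}
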