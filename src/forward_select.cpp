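// Forward-selection workhorses shared by the LIMITS gLV estimator and the
// sparse linear-Gaussian DBN. Both refit inside every leave-one-out
// omission, so the inner loops live here.
//
// LIMITS evaluates candidates through precomputed per-split Gram matrices:
// the design (taxa abundances at interval starts) is shared by all taxa,
// so the train/test cross-products are built once per bootstrap split and
// every candidate model reduces to a small normal-equations solve.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static bool ols(const mat& X, const vec& y, vec& coef) {
  bool ok = solve(coef, X, y, solve_opts::no_approx);
  if (!ok) {
    mat Xp;
    if (!pinv(Xp, X)) return false;
    coef = Xp * y;
  }
  return true;
}

// LIMITS fit for all taxa at once. Yt: pairs x covariates (abundances at
// interval starts + trailing ones column); F: taxa x pairs response matrix
// of log-rates; splits: pairs x nboot 0/1 train membership (drawn in R so
// R's RNG governs reproducibility); thresh: minimal relative out-of-bag
// error improvement. The model for taxon i always contains the trailing
// (growth rate) column and its own self-interaction column. Returns the
// taxa x covariates coefficient matrix of per-entry bootstrap medians.
//
// Candidate models are scored through the train/test Gram matrices with a
// bordered Cholesky factorization of the active set, so adding and
// testing one covariate costs O(k^2) instead of a fresh O(k^3) solve.
// [[Rcpp::export]]
arma::mat cpp_limits_fit(const arma::mat& Yt, const arma::mat& F,
                         const arma::imat& splits, double thresh) {
  const uword q = Yt.n_cols, n = F.n_rows;
  const uword nboot = splits.n_cols;
  const uword growth = q - 1;
  cube boots(q, nboot, n, fill::zeros);

  std::vector<double> L(q * q), z(q), wCand(q), wBest(q), coef(q + 1);
  std::vector<uword> act;

  for (uword b = 0; b < nboot; ++b) {
    uvec train = find(splits.col(b) == 1);
    uvec test  = find(splits.col(b) == 0);
    if (train.n_elem < 2 || test.n_elem < 1) continue;
    const mat Xtr = Yt.rows(train), Xte = Yt.rows(test);
    const mat Gtr = Xtr.t() * Xtr;        // q x q, shared by all taxa
    const mat Gte = Xte.t() * Xte;
    const mat Gall = Yt.t() * Yt;
    const double nte = (double)test.n_elem;
    const uword maxK = std::min<uword>(q, train.n_elem);

    for (uword i = 0; i < n; ++i) {
      vec fall = F.row(i).t();
      const vec gtr = Xtr.t() * fall.elem(train);
      const vec gte = Xte.t() * fall.elem(test);
      const double yTy = dot(fall.elem(test), fall.elem(test));

      act.clear();
      std::vector<bool> inact(q, false);

      // forward substitution: w = L^{-1} Gtr(act, c); border depth d
      auto border = [&](uword c, uword k, double* w,
                        double& d, double& zc) -> bool {
        for (uword r = 0; r < k; ++r) {
          double s = Gtr(act[r], c);
          for (uword j = 0; j < r; ++j) s -= L[r * q + j] * w[j];
          w[r] = s / L[r * q + r];
        }
        double d2 = Gtr(c, c);
        for (uword r = 0; r < k; ++r) d2 -= w[r] * w[r];
        if (!(d2 > 1e-12 * (std::abs(Gtr(c, c)) + 1e-30))) return false;
        d = std::sqrt(d2);
        double s = gtr(c);
        for (uword r = 0; r < k; ++r) s -= w[r] * z[r];
        zc = s / d;
        return true;
      };
      auto commit = [&](uword c, const double* w, double d, double zc) {
        uword k = act.size();
        for (uword j = 0; j < k; ++j) L[k * q + j] = w[j];
        L[k * q + k] = d;
        z[k] = zc;
        act.push_back(c);
        inact[c] = true;
      };
      // back substitution over the bordered factor (active set + cand c)
      auto solveBordered = [&](const double* w, double d, double zc,
                               uword k, double* cf) {
        cf[k] = zc / d;
        for (sword r = (sword)k - 1; r >= 0; --r) {
          double s = z[r] - w[r] * cf[k];
          for (uword j = r + 1; j < k; ++j) s -= L[j * q + r] * cf[j];
          cf[r] = s / L[r * q + r];
        }
      };
      auto solveCurrent = [&](uword k, double* cf) {
        for (sword r = (sword)k - 1; r >= 0; --r) {
          double s = z[r];
          for (uword j = r + 1; j < k; ++j) s -= L[j * q + r] * cf[j];
          cf[r] = s / L[r * q + r];
        }
      };
      // out-of-bag MSE of coefficients cf over act (+ optional cand c)
      auto testErr = [&](uword k1, const double* cf, uword cand) {
        double lin = 0, quad = 0;
        for (uword r = 0; r < k1; ++r) {
          uword ar = (r < act.size()) ? act[r] : cand;
          lin += cf[r] * gte(ar);
          quad += cf[r] * cf[r] * Gte(ar, ar);
          for (uword j = 0; j < r; ++j) {
            uword aj = (j < act.size()) ? act[j] : cand;
            quad += 2.0 * cf[r] * cf[j] * Gte(ar, aj);
          }
        }
        return (yTy - 2.0 * lin + quad) / nte;
      };

      // seed the always-included covariates: growth rate, self-interaction
      double d, zc;
      bool ok = border(growth, 0, wCand.data(), d, zc);
      if (ok) commit(growth, wCand.data(), d, zc);
      if (ok && i != growth) {
        ok = border(i, act.size(), wCand.data(), d, zc);
        if (ok) commit(i, wCand.data(), d, zc);
      }
      if (!ok) continue;
      solveCurrent(act.size(), coef.data());
      double e0 = testErr(act.size(), coef.data(), q);

      while (act.size() < maxK) {
        if (e0 <= 0) break;
        double best = datum::inf, bestD = 0, bestZc = 0;
        uword bestc = q;
        const uword k = act.size();
        for (uword c = 0; c < q; ++c) {
          if (inact[c]) continue;
          double dc, zcc;
          if (!border(c, k, wCand.data(), dc, zcc)) continue;
          solveBordered(wCand.data(), dc, zcc, k, coef.data());
          double e = testErr(k + 1, coef.data(), c);
          if (e < best) {
            best = e; bestc = c; bestD = dc; bestZc = zcc;
            std::copy(wCand.begin(), wCand.begin() + k, wBest.begin());
          }
        }
        if (bestc == q) break;
        if ((e0 - best) / e0 < thresh) break;
        commit(bestc, wBest.data(), bestD, bestZc);
        e0 = best;
      }
      // the split only drives selection; the repetition's coefficients are
      // re-estimated on all pairs over the selected support, which keeps
      // the per-coordinate bootstrap medians jointly coherent
      uvec actv(act);
      vec gall = Yt.t() * fall;
      vec cfAll;
      mat Ga = Gall.submat(actv, actv);
      if (!solve(cfAll, Ga, gall.elem(actv), solve_opts::no_approx)) {
        mat Gp;
        if (!pinv(Gp, Ga)) continue;
        cfAll = Gp * gall.elem(actv);
      }
      for (uword k = 0; k < actv.n_elem; ++k) boots(actv(k), b, i) = cfAll(k);
    }
  }
  mat out(n, q, fill::zeros);
  for (uword i = 0; i < n; ++i)
    out.row(i) = median(boots.slice(i), 1).t();
  return out;
}

// Greedy forward parent selection for one DBN child node, scored by BIC
// (n log(rss/n) + k log n). X column 0 must be the intercept, which is
// always included and does not count against max_parents.
// [[Rcpp::export]]
Rcpp::List cpp_greedy_bic(const arma::mat& X, const arma::vec& y,
                          int max_parents) {
  const uword n = X.n_rows, q = X.n_cols;
  std::vector<uword> active;
  active.push_back(0);
  // floor the RSS at the numerical-noise scale of the response so that an
  // already-perfect fit (e.g. a constant child) cannot "improve" through
  // floating-point dust and recruit collinear parents
  const double rssFloor = 1e-20 * std::max(1.0, dot(y, y));
  auto bicOf = [&](const uvec& act, vec& coef) -> double {
    if (!ols(X.cols(act), y, coef)) return datum::inf;
    vec r = y - X.cols(act) * coef;
    double rss = std::max(dot(r, r), rssFloor);
    return n * std::log(rss / n) + act.n_elem * std::log((double)n);
  };
  uvec act(active);
  vec coef;
  double bic = bicOf(act, coef);
  std::vector<bool> inact(q, false);
  inact[0] = true;

  while ((int)active.size() - 1 < max_parents &&
         active.size() < std::min<uword>(q, n)) {
    double best = bic;
    uword bestc = q;
    vec bestCoef;
    for (uword c = 1; c < q; ++c) {
      if (inact[c]) continue;
      std::vector<uword> tryA = active;
      tryA.push_back(c);
      uvec ta(tryA);
      vec cf;
      double b = bicOf(ta, cf);
      if (b < best) { best = b; bestc = c; bestCoef = cf; }
    }
    if (bestc == q) break;
    active.push_back(bestc);
    inact[bestc] = true;
    bic = best;
    coef = bestCoef;
    act = uvec(active);
  }
  vec full(q, fill::zeros);
  for (uword k = 0; k < act.n_elem; ++k) full(act(k)) = coef(k);
  vec r = y - X.cols(act) * coef;
  double sigma2 = dot(r, r) / std::max<double>(1.0, n - act.n_elem);
  return Rcpp::List::create(
    Rcpp::Named("coef") = full,
    Rcpp::Named("selected") = Rcpp::IntegerVector(act.begin(), act.end()),
    Rcpp::Named("sigma2") = sigma2);
}
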