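#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Artificial-centering hit-and-run chain inside a box-bounded affine
// polytope. Warm-up columns are feasible extreme points (FVA solutions);
// directions are projected warm-up-minus-center differences, so the chain
// stays in the steady-state null space; drift is removed at collection time
// by the projection matrix `proj` (I - V1 V1^T from the SVD of S).
// Uses R's RNG (unif_rand) so runs are reproducible under set.seed().

// [[Rcpp::export]]
arma::mat achr_sample(const arma::mat& warmup, const arma::vec& lb,
                      const arma::vec& ub, int n_samples, int thinning,
                      const arma::mat& proj) {
  const int n = lb.n_elem;
  const int nw = warmup.n_cols;
  const double dir_tol = 1e-9;

  arma::vec center = arma::mean(warmup, 1);
  arma::vec x = proj * warmup.col(0);
  double k = nw;

  arma::mat out(n_samples, n);
  int collected = 0;
  long step = 0;
  int stuck = 0;

  while (collected < n_samples) {
    int j = (int)std::floor(unif_rand() * nw);
    if (j >= nw) j = nw - 1;
    arma::vec dir = proj * (warmup.col(j) - center);
    double dn = arma::norm(dir);
    if (dn < 1e-12) {
      if (++stuck > 1000) { // degenerate polytope: emit current point
        out.row(collected++) = x.t();
        stuck = 0;
      }
      continue;
    }
    dir /= dn;

    double tmin = -std::numeric_limits<double>::infinity();
    double tmax = std::numeric_limits<double>::infinity();
    for (int i = 0; i < n; ++i) {
      double d = dir(i);
      if (std::fabs(d) < dir_tol) continue;
      double a = (lb(i) - x(i)) / d;
      double b = (ub(i) - x(i)) / d;
      double lo = a < b ? a : b;
      double hi = a < b ? b : a;
      if (lo > tmin) tmin = lo;
      if (hi < tmax) tmax = hi;
    }
    if (!std::isfinite(tmin) || !std::isfinite(tmax) || tmax < tmin) {
      if (++stuck > 1000) {
        out.row(collected++) = x.t();
        stuck = 0;
      }
      continue;
    }
    stuck = 0;
    double lambda = tmin + unif_rand() * (tmax - tmin);
    x += lambda * dir;
    center = (center * k + x) / (k + 1.0);
    k += 1.0;

    if (++step % thinning == 0) {
      x = proj * x;
      out.row(collected++) = x.t();
    }
  }
  return out;
}
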