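#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Overdamped (Brownian) Euler-Maruyama integration of the 1-D gap coordinate
// on U(g) = -kT * log sum_i exp(log_w[i] - (g - c[i])^2 / (2 s[i]^2)).
// Uses R's RNG so set.seed() on the R side gives full reproducibility.
// Records g at steps 0, stride, 2*stride, ...
// [[Rcpp::export]]
NumericVector langevin_gap_cpp(NumericVector centers, NumericVector log_w,
                               NumericVector widths, double kT, double x0,
                               double n_steps_d, double dt, double friction,
                               int stride, double bound) {
  const R_xlen_t n_steps = (R_xlen_t)n_steps_d;
  const int K = centers.size();
  const R_xlen_t n_out = (n_steps - 1) / stride + 1;
  NumericVector out(n_out);
  const double noise = std::sqrt(2.0 * kT * dt / friction);
  double g = x0;
  out[0] = g;
  R_xlen_t j = 1;
  for (R_xlen_t t = 1; t < n_steps; ++t) {
    // mixture-weighted gradient, shifted by the max exponent for stability
    double amax = R_NegInf;
    for (int i = 0; i < K; ++i) {
      double d = (g - centers[i]) / widths[i];
      double a = log_w[i] - 0.5 * d * d;
      if (a > amax) amax = a;
    }
    double num = 0.0, den = 0.0;
    for (int i = 0; i < K; ++i) {
      double d = (g - centers[i]) / widths[i];
      double p = std::exp(log_w[i] - 0.5 * d * d - amax);
      den += p;
      num += p * (g - centers[i]) / (widths[i] * widths[i]);
    }
    double gradU = kT * num / den;
    g += -dt * gradU / friction + noise * norm_rand();
    if (!std::isfinite(g) || std::fabs(g) > bound) {
      stop("gap coordinate diverged (|g| > %g) at step %td; use a smaller dt",
           bound, (ptrdiff_t)t);
    }
    if (t % stride == 0) out[j++] = g;
  }
  return out;
}

// Sample a discrete Markov chain from row-stochastic T (1-based states on the
// R side; 0-based internally). cumT holds row-wise cumulative probabilities.
// [[Rcpp::export]]
IntegerVector sample_chain_cpp(NumericMatrix cumT, int n_steps, int init) {
  const int k = cumT.nrow();
  IntegerVector out(n_steps);
  int s = init - 1;
  out[0] = s + 1;
  for (int t = 1; t < n_steps; ++t) {
    double u = unif_rand();
    int nxt = k - 1;
    for (int j = 0; j < k; ++j) {
      if (u <= cumT(s, j)) { nxt = j; break; }
    }
    s = nxt;
    out[t] = s + 1;
  }
  return out;
}

static double kabsch_rmsd_centered(const arma::mat& Xc, const arma::mat& Yc) {
  // Xc, Yc: N x 3, already centered. Minimized RMSD via SVD of the 3x3
  // cross-covariance, sign-correcting the smallest singular value so a
  // reflection is never used.
  const double N = (double)Xc.n_rows;
  arma::mat H = Xc.t() * Yc;
  arma::mat U, V;
  arma::vec s;
  arma::svd(U, s, V, H);
  double sgn = (arma::det(V * U.t()) < 0.0) ? -1.0 : 1.0;
  double trace = s(0) + s(1) + sgn * s(2);
  double e0 = arma::accu(Xc % Xc) + arma::accu(Yc % Yc);
  double msd = (e0 - 2.0 * trace) / N;
  return std::sqrt(std::max(msd, 0.0));
}

// Pairwise minimized RMSD between every frame of `coords` (N*3*F cube flattened
// as an (F) list is avoided: coords is n_beads x 3 x n_frames) and every frame
// of `refs` (n_beads x 3 x n_refs). Returns n_frames x n_refs matrix.
// [[Rcpp::export]]
NumericMatrix rmsd_to_refs_cpp(arma::cube coords, arma::cube refs) {
  const int F = coords.n_slices, R = refs.n_slices;
  NumericMatrix out(F, R);
  std::vector<arma::mat> refc(R);
  for (int r = 0; r < R; ++r) {
    arma::mat Y = refs.slice(r);
    Y.each_row() -= arma::mean(Y, 0);
    refc[r] = Y;
  }
  for (int f = 0; f < F; ++f) {
    arma::mat X = coords.slice(f);
    X.each_row() -= arma::mean(X, 0);
    for (int r = 0; r < R; ++r) out(f, r) = kabsch_rmsd_centered(X, refc[r]);
  }
  return out;
}

// Symmetric all-vs-all minimized RMSD matrix for one set of frames.
// [[Rcpp::export]]
NumericMatrix rmsd_matrix_cpp(arma::cube coords) {
  const int F = coords.n_slices;
  NumericMatrix out(F, F);
  std::vector<arma::mat> cc(F);
  for (int f = 0; f < F; ++f) {
    arma::mat X = coords.slice(f);
    X.each_row() -= arma::mean(X, 0);
    cc[f] = X;
  }
  for (int i = 0; i < F; ++i) {
    for (int j = i + 1; j < F; ++j) {
      double v = kabsch_rmsd_centered(cc[i], cc[j]);
      out(i, j) = v;
      out(j, i) = v;
    }
  }
  return out;
}
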