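// Gaussian CMI2 kernel for the multi-order pruning loop.
// Everything operates on a precomputed gene-gene covariance matrix; the
// pruning pass calls max_cmi2_cpp once per edge per order, enumerating
// all conditioning subsets of the common neighbours in-place.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static double subdet(const mat &S, const uvec &idx) {
  if (idx.n_elem == 0) return 1.0;
  return det(S.submat(idx, idx));
}

// E_z KL( theta(y|z) || q_{x->y}(y|z) ), closed form; 0 for empty z.
static double kl_dir(const mat &S, uword x, uword y, const uvec &z) {
  if (z.n_elem == 0) return 0.0;
  const mat Szz = S.submat(z, z);
  const double syy = S(y, y);
  vec alpha = solve(Szz, vec(S.submat(z, uvec{y})), solve_opts::no_approx);
  double v1 = syy - dot(vec(S.submat(z, uvec{y})), alpha);
  uvec w(z.n_elem + 1);
  w(0) = x;
  w.subvec(1, z.n_elem) = z;
  vec beta = solve(S.submat(w, w), vec(S.submat(w, uvec{y})),
                   solve_opts::no_approx);
  double a = beta(0);
  vec b = beta.subvec(1, z.n_elem);
  double s2 = syy - dot(vec(S.submat(w, uvec{y})), beta);
  double v2 = s2 + a * a * S(x, x);
  if (v1 <= 0.0 || v2 <= 0.0)
    Rcpp::stop("singular conditional variance in CMI2 kernel");
  vec d = alpha - b;
  double quad = as_scalar(d.t() * Szz * d);
  double kl = 0.5 * (std::log(v2 / v1) + v1 / v2 + quad / v2 - 1.0);
  return kl > 0.0 ? kl : 0.0;
}

// total, cmi, kl_xy, kl_yx for 0-based x, y, conditioning set z
static vec cmi2_parts(const mat &S, uword x, uword y, const uvec &z,
                      bool inclusive) {
  uvec xz(z.n_elem + 1), yz(z.n_elem + 1), xyz(z.n_elem + 2);
  xz(0) = x;
  yz(0) = y;
  xyz(0) = x;
  xyz(1) = y;
  for (uword k = 0; k < z.n_elem; ++k) {
    xz(k + 1) = z(k);
    yz(k + 1) = z(k);
    xyz(k + 2) = z(k);
  }
  double num = subdet(S, xz) * subdet(S, yz);
  double den = subdet(S, z) * subdet(S, xyz);
  if (!std::isfinite(num) || !std::isfinite(den) || num <= 0.0 || den <= 0.0)
    Rcpp::stop("singular covariance submatrix in CMI2 kernel");
  double ci = 0.5 * std::log(num / den);
  if (ci < 0.0) ci = 0.0;
  double kxy = 0.0, kyx = 0.0;
  if (inclusive) {
    kxy = kl_dir(S, x, y, z);
    kyx = kl_dir(S, y, x, z);
  }
  vec out(4);
  out(0) = ci + 0.5 * (kxy + kyx);
  out(1) = ci;
  out(2) = kxy;
  out(3) = kyx;
  return out;
}

// [[Rcpp::export]]
Rcpp::NumericVector cmi2_parts_cpp(const arma::mat &cov, int x, int y,
                                   Rcpp::IntegerVector S, bool inclusive) {
  uvec z(S.size());
  for (int k = 0; k < S.size(); ++k) z(k) = (uword)(S[k] - 1);
  vec out = cmi2_parts(cov, (uword)(x - 1), (uword)(y - 1), z, inclusive);
  return Rcpp::NumericVector(out.begin(), out.end());
}

// Max CMI2 total over all C(|neighbors|, order) conditioning subsets.
// [[Rcpp::export]]
double max_cmi2_cpp(const arma::mat &cov, int x, int y,
                    Rcpp::IntegerVector neighbors, int order,
                    bool inclusive) {
  const int m = neighbors.size();
  if (order < 1 || order > m)
    Rcpp::stop("'order' must lie in 1..length(neighbors)");
  std::vector<uword> nb(m);
  for (int k = 0; k < m; ++k) nb[k] = (uword)(neighbors[k] - 1);
  std::vector<int> comb(order);
  for (int k = 0; k < order; ++k) comb[k] = k;
  uvec z(order);
  double best = -datum::inf;
  for (;;) {
    for (int k = 0; k < order; ++k) z(k) = nb[comb[k]];
    vec parts = cmi2_parts(cov, (uword)(x - 1), (uword)(y - 1), z, inclusive);
    if (parts(0) > best) best = parts(0);
    // advance to the next combination in lexicographic order
    int i = order - 1;
    while (i >= 0 && comb[i] == m - order + i) --i;
    if (i < 0) break;
    ++comb[i];
    for (int k = i + 1; k < order; ++k) comb[k] = comb[k - 1] + 1;
  }
  return best;
}
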