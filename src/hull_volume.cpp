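// Convex-hull volume and the soft minimal-volume-enclosing-simplex objective.
//
// No qhull binding is available, so hull volume is computed with an
// incremental beneath-beyond algorithm: maintain the facet set of the hull of
// the points processed so far; for each new point outside the current hull,
// delete the visible facets and cone the horizon ridges to the new point.
// Volume is then the sum of simplex volumes from an interior point to each
// facet (the hull is star-shaped from any interior point).  Intended for the
// low-dimensional fitting spaces used here (m = k - 1, k <= 8).

#include <RcppArmadillo.h>
#include <map>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Facet {
  uvec verts;   // d vertex indices into the point matrix
  vec normal;   // outward unit normal
  double offset; // normal . x == offset on the facet plane
};

// Outward-oriented facet through the d points P.rows(idx); "outward" means
// the interior point lies on the negative side.
bool make_facet(const mat& P, const uvec& idx, const vec& interior, Facet& out) {
  const uword d = P.n_cols;
  mat E(d - 1, d);
  for (uword i = 1; i < d; ++i) E.row(i - 1) = P.row(idx(i)) - P.row(idx(0));
  mat U, V;
  vec s;
  if (!svd(U, s, V, E)) return false;
  vec n = V.col(d - 1); // null direction of the (d-1) x d edge matrix
  double off = dot(n, P.row(idx(0)).t());
  double side = dot(n, interior) - off;
  if (side > 0) { n = -n; off = -off; }
  out.verts = idx;
  out.normal = n;
  out.offset = off;
  return true;
}

} // namespace

// Volume of the convex hull of an n x d point set (d >= 2).  Returns 0 when
// the points are degenerate (affine rank < d).
// [[Rcpp::export]]
double cpp_hull_volume(const arma::mat& pts) {
  const uword n = pts.n_rows, d = pts.n_cols;
  if (d < 2) Rcpp::stop("cpp_hull_volume requires dimension >= 2");
  if (n < d + 1) return 0.0;

  const double scale = std::max(1.0, arma::abs(pts).max());
  const double eps = 1e-9 * scale;

  // Initial affinely independent d+1 points by greedy Gram-Schmidt residuals.
  std::vector<uword> init;
  init.push_back(pts.col(0).index_max()); // deterministic extreme start
  mat basis(d, 0);
  while (init.size() < d + 1) {
    const vec p0 = pts.row(init[0]).t();
    double best = -1.0;
    uword best_i = 0;
    for (uword i = 0; i < n; ++i) {
      vec r = pts.row(i).t() - p0;
      if (basis.n_cols > 0) r -= basis * (basis.t() * r);
      double nr = norm(r);
      if (nr > best) { best = nr; best_i = i; }
    }
    if (best < eps) return 0.0; // affine rank deficient
    vec r = pts.row(best_i).t() - pts.row(init[0]).t();
    if (basis.n_cols > 0) r -= basis * (basis.t() * r);
    basis.insert_cols(basis.n_cols, r / norm(r));
    init.push_back(best_i);
  }

  vec interior = zeros<vec>(d);
  for (uword j = 0; j <= d; ++j) interior += pts.row(init[j]).t();
  interior /= double(d + 1);

  std::vector<Facet> facets;
  for (uword leave = 0; leave <= d; ++leave) {
    uvec idx(d);
    uword c = 0;
    for (uword j = 0; j <= d; ++j) if (j != leave) idx(c++) = init[j];
    Facet f;
    if (!make_facet(pts, idx, interior, f)) return 0.0;
    facets.push_back(f);
  }

  std::vector<bool> used(n, false);
  for (uword j = 0; j <= d; ++j) used[init[j]] = true;

  for (uword i = 0; i < n; ++i) {
    if (used[i]) continue;
    const vec p = pts.row(i).t();

    std::vector<uword> visible;
    for (uword f = 0; f < facets.size(); ++f)
      if (dot(facets[f].normal, p) - facets[f].offset > eps) visible.push_back(f);
    if (visible.empty()) continue; // inside current hull

    // Ridges of visible facets; a ridge on the horizon belongs to exactly one
    // visible facet (its other facet is hidden).
    std::map<std::vector<uword>, int> ridge_count;
    std::map<std::vector<uword>, std::vector<uword>> ridge_verts;
    for (uword vf : visible) {
      const uvec& vv = facets[vf].verts;
      for (uword leave = 0; leave < d; ++leave) {
        std::vector<uword> key;
        for (uword j = 0; j < d; ++j) if (j != leave) key.push_back(vv(j));
        std::sort(key.begin(), key.end());
        ridge_count[key]++;
        ridge_verts[key] = key;
      }
    }

    std::vector<Facet> fresh;
    for (auto& kv : ridge_count) {
      if (kv.second != 1) continue; // interior ridge between two visible facets
      const std::vector<uword>& rv = ridge_verts[kv.first];
      uvec idx(d);
      for (uword j = 0; j + 1 < d; ++j) idx(j) = rv[j];
      idx(d - 1) = i;
      Facet f;
      if (make_facet(pts, idx, interior, f)) fresh.push_back(f);
    }

    std::vector<Facet> kept;
    kept.reserve(facets.size());
    std::vector<bool> is_vis(facets.size(), false);
    for (uword vf : visible) is_vis[vf] = true;
    for (uword f = 0; f < facets.size(); ++f)
      if (!is_vis[f]) kept.push_back(facets[f]);
    for (auto& f : fresh) kept.push_back(f);
    facets.swap(kept);
    used[i] = true;
  }

  // Star decomposition from the interior point.
  double lfac = std::lgamma(double(d) + 1.0);
  double vol = 0.0;
  mat M(d, d);
  for (auto& f : facets) {
    for (uword j = 0; j < d; ++j) M.col(j) = pts.row(f.verts(j)).t() - interior;
    double val, sign;
    log_det(val, sign, M);
    if (std::isfinite(val)) vol += std::exp(val - lfac);
  }
  return vol;
}

// Objective of the soft minimal-volume enclosing simplex: log simplex volume
// plus lambda times the summed negative barycentric slack of points lying
// outside.  `par` stacks the k x m archetype matrix column-major; `Xt1` is the
// (m+1) x n matrix rbind(t(scores), 1).
// [[Rcpp::export]]
double cpp_simplex_objective(const arma::vec& par, const arma::mat& Xt1,
                             int k, int m, double lambda) {
  mat A(par.memptr(), k, m); // k = m + 1 archetypes in m dims
  mat T(m + 1, k);
  T.rows(0, m - 1) = A.t();
  T.row(m).ones();

  mat Ti;
  if (!inv(Ti, T)) return 1e10;

  // penalty: total negative barycentric slack, accumulated column by column
  // (w = Ti * x per point) without materializing the k x n weight matrix
  const uword n = Xt1.n_cols;
  const double* ti = Ti.memptr();
  const double* xp = Xt1.memptr();
  double pen = 0.0;
  for (uword j = 0; j < n; ++j) {
    const double* x = xp + j * (m + 1);
    for (int r = 0; r < k; ++r) {
      double w = 0.0;
      for (int c = 0; c <= m; ++c) w += ti[r + c * k] * x[c];
      if (w < 0.0) pen -= w;
    }
  }

  mat M(m, m);
  for (int j = 1; j < k; ++j) M.col(j - 1) = (A.row(j) - A.row(0)).t();
  double val, sign;
  log_det(val, sign, M);
  if (!std::isfinite(val)) return 1e10;
  double logvol = val - std::lgamma(double(m) + 1.0);
  return logvol + lambda * pen;
}

// Barycentric coordinates of each row of `points` with respect to the k = m+1
// archetype rows of `A`.  Returns an n x k matrix.
// [[Rcpp::export]]
arma::mat cpp_barycentric(const arma::mat& points, const arma::mat& A) {
  const uword m = A.n_cols, k = A.n_rows;
  mat T(m + 1, k);
  T.rows(0, m - 1) = A.t();
  T.row(m).ones();
  mat B(m + 1, points.n_rows);
  B.rows(0, m - 1) = points.t();
  B.row(m).ones();
  mat W;
  if (!solve(W, T, B, solve_opts::no_approx))
    Rcpp::stop("degenerate simplex: barycentric system is singular");
  return W.t();
}
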