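// Spatial search kernels: uniform-grid kNN / NN / radius clustering,
// PCA surface normals, and RANSAC scoring loops for planes and cylinders.
// Brute force would be O(N^2) on clouds of 1e5+ points; the grid keeps
// every query local.
#include <RcppArmadillo.h>
#include <unordered_map>
#include <queue>
#include <vector>
#include <cmath>
#include <cstdint>

// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct Grid {
  double h;
  double minx, miny, minz;
  std::unordered_map<std::int64_t, std::vector<int> > cells;
  const arma::mat* pts; // N x 3

  static std::int64_t key(int ix, int iy, int iz) {
    const std::int64_t OFF = 1 << 20;
    return ((std::int64_t)(ix + OFF) << 42) |
           ((std::int64_t)(iy + OFF) << 21) |
           (std::int64_t)(iz + OFF);
  }

  void cell_of(double x, double y, double z, int& ix, int& iy, int& iz) const {
    ix = (int)std::floor((x - minx) / h);
    iy = (int)std::floor((y - miny) / h);
    iz = (int)std::floor((z - minz) / h);
  }

  void build(const arma::mat& P, double cell) {
    pts = &P;
    h = cell;
    minx = P.col(0).min(); miny = P.col(1).min(); minz = P.col(2).min();
    cells.reserve(P.n_rows);
    for (arma::uword i = 0; i < P.n_rows; ++i) {
      int ix, iy, iz;
      cell_of(P(i, 0), P(i, 1), P(i, 2), ix, iy, iz);
      cells[key(ix, iy, iz)].push_back((int)i);
    }
  }

  // k nearest neighbors of query q (exact), excluding index `self` if >= 0.
  // Returns pairs (squared distance, index), sorted ascending.
  std::vector<std::pair<double,int> > knn(const arma::rowvec& q, int k,
                                          int self) const {
    const arma::mat& P = *pts;
    int qx, qy, qz;
    cell_of(q(0), q(1), q(2), qx, qy, qz);
    // max-heap on squared distance
    std::priority_queue<std::pair<double,int> > heap;
    int max_ring = 2;
    {
      // enough rings to cover the whole cloud in the worst case
      double ex = std::max(std::fabs(P.col(0).max() - minx), std::fabs(q(0) - minx));
      double ey = std::max(std::fabs(P.col(1).max() - miny), std::fabs(q(1) - miny));
      double ez = std::max(std::fabs(P.col(2).max() - minz), std::fabs(q(2) - minz));
      max_ring = (int)(std::max(ex, std::max(ey, ez)) / h) + 2;
    }
    for (int ring = 0; ring <= max_ring; ++ring) {
      for (int ix = qx - ring; ix <= qx + ring; ++ix)
        for (int iy = qy - ring; iy <= qy + ring; ++iy)
          for (int iz = qz - ring; iz <= qz + ring; ++iz) {
            int cheb = std::max(std::abs(ix - qx),
                       std::max(std::abs(iy - qy), std::abs(iz - qz)));
            if (cheb != ring) continue; // shell only
            auto it = cells.find(key(ix, iy, iz));
            if (it == cells.end()) continue;
            for (int j : it->second) {
              if (j == self) continue;
              double dx = P(j, 0) - q(0), dy = P(j, 1) - q(1), dz = P(j, 2) - q(2);
              double d2 = dx * dx + dy * dy + dz * dz;
              if ((int)heap.size() < k) heap.push(std::make_pair(d2, j));
              else if (d2 < heap.top().first) { heap.pop(); heap.push(std::make_pair(d2, j)); }
            }
          }
      if ((int)heap.size() == k) {
        double worst = std::sqrt(heap.top().first);
        if (worst <= (double)ring * h) break; // unvisited cells cannot beat it
      }
    }
    std::vector<std::pair<double,int> > out;
    out.reserve(heap.size());
    while (!heap.empty()) { out.push_back(heap.top()); heap.pop(); }
    std::reverse(out.begin(), out.end());
    return out;
  }
};

double pick_cell(const arma::mat& P, double fallback) {
  if (P.n_rows < 2) return fallback;
  double vx = P.col(0).max() - P.col(0).min();
  double vy = P.col(1).max() - P.col(1).min();
  double vz = P.col(2).max() - P.col(2).min();
  double vol = std::max(vx, 1e-6) * std::max(vy, 1e-6) * std::max(vz, 1e-6);
  double h = std::cbrt(vol * 4.0 / (double)P.n_rows); // ~4 pts per occupied cell
  if (!(h > 0.0) || !std::isfinite(h)) h = fallback;
  return std::max(h, 1e-9);
}

} // namespace

//' @noRd
// [[Rcpp::export]]
NumericVector cpp_knn_mean_dist(const arma::mat& P, int k) {
  Grid g;
  g.build(P, pick_cell(P, 0.01));
  int n = (int)P.n_rows;
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    arma::rowvec q = P.row(i);
    std::vector<std::pair<double,int> > nb = g.knn(q, k, i);
    double s = 0.0;
    for (size_t j = 0; j < nb.size(); ++j) s += std::sqrt(nb[j].first);
    out[i] = nb.empty() ? NA_REAL : s / (double)nb.size();
  }
  return out;
}

//' @noRd
// [[Rcpp::export]]
List cpp_nn(const arma::mat& Q, const arma::mat& X) {
  Grid g;
  g.build(X, pick_cell(X, 0.01));
  int n = (int)Q.n_rows;
  IntegerVector idx(n);
  NumericVector dist(n);
  for (int i = 0; i < n; ++i) {
    arma::rowvec q = Q.row(i);
    std::vector<std::pair<double,int> > nb = g.knn(q, 1, -1);
    idx[i] = nb[0].second + 1; // 1-based
    dist[i] = std::sqrt(nb[0].first);
  }
  return List::create(_["idx"] = idx, _["dist"] = dist);
}

//' @noRd
// [[Rcpp::export]]
IntegerVector cpp_radius_cluster(const arma::mat& P, double tol) {
  int n = (int)P.n_rows;
  Grid g;
  g.build(P, tol);
  IntegerVector comp(n, 0);
  double tol2 = tol * tol;
  int cur = 0;
  std::vector<int> stack;
  for (int s = 0; s < n; ++s) {
    if (comp[s] != 0) continue;
    ++cur;
    comp[s] = cur;
    stack.push_back(s);
    while (!stack.empty()) {
      int i = stack.back(); stack.pop_back();
      int cx, cy, cz;
      g.cell_of(P(i, 0), P(i, 1), P(i, 2), cx, cy, cz);
      for (int ix = cx - 1; ix <= cx + 1; ++ix)
        for (int iy = cy - 1; iy <= cy + 1; ++iy)
          for (int iz = cz - 1; iz <= cz + 1; ++iz) {
            auto it = g.cells.find(Grid::key(ix, iy, iz));
            if (it == g.cells.end()) continue;
            for (int j : it->second) {
              if (comp[j] != 0) continue;
              double dx = P(j, 0) - P(i, 0), dy = P(j, 1) - P(i, 1),
                     dz = P(j, 2) - P(i, 2);
              if (dx * dx + dy * dy + dz * dz <= tol2) {
                comp[j] = cur;
                stack.push_back(j);
              }
            }
          }
    }
  }
  return comp;
}

//' @noRd
// [[Rcpp::export]]
arma::mat cpp_pca_normals(const arma::mat& P, int k) {
  Grid g;
  g.build(P, pick_cell(P, 0.01));
  int n = (int)P.n_rows;
  arma::mat N(n, 3, arma::fill::zeros);
  for (int i = 0; i < n; ++i) {
    arma::rowvec q = P.row(i);
    std::vector<std::pair<double,int> > nb = g.knn(q, k, i);
    if ((int)nb.size() < 3) { N(i, 2) = 1.0; continue; }
    arma::mat M((int)nb.size() + 1, 3);
    M.row(0) = q;
    for (size_t j = 0; j < nb.size(); ++j) M.row((arma::uword)j + 1) = P.row(nb[j].second);
    arma::rowvec mu = arma::mean(M, 0);
    M.each_row() -= mu;
    arma::mat C = M.t() * M;
    arma::vec eigval;
    arma::mat eigvec;
    if (!arma::eig_sym(eigval, eigvec, C)) { N(i, 2) = 1.0; continue; }
    N.row(i) = eigvec.col(0).t(); // smallest eigenvalue -> surface normal
  }
  return N;
}

// Score RANSAC plane hypotheses. samples: m x 3 matrix of 1-based point
// indices. Returns best (normal, offset, inlier count) by inlier count.
//' @noRd
// [[Rcpp::export]]
List cpp_ransac_plane(const arma::mat& P, const arma::imat& samples,
                      double thresh) {
  int m = (int)samples.n_rows;
  int n = (int)P.n_rows;
  double best_n1 = 0, best_n2 = 0, best_n3 = 1, best_d = 0;
  int best_count = -1;
  for (int s = 0; s < m; ++s) {
    arma::rowvec p1 = P.row(samples(s, 0) - 1);
    arma::rowvec p2 = P.row(samples(s, 1) - 1);
    arma::rowvec p3 = P.row(samples(s, 2) - 1);
    arma::rowvec u = p2 - p1, v = p3 - p1;
    double nx = u(1) * v(2) - u(2) * v(1);
    double ny = u(2) * v(0) - u(0) * v(2);
    double nz = u(0) * v(1) - u(1) * v(0);
    double nrm = std::sqrt(nx * nx + ny * ny + nz * nz);
    if (nrm < 1e-12) continue;
    nx /= nrm; ny /= nrm; nz /= nrm;
    double d = -(nx * p1(0) + ny * p1(1) + nz * p1(2));
    int count = 0;
    for (int i = 0; i < n; ++i) {
      double r = nx * P(i, 0) + ny * P(i, 1) + nz * P(i, 2) + d;
      if (std::fabs(r) <= thresh) ++count;
    }
    if (count > best_count) {
      best_count = count;
      best_n1 = nx; best_n2 = ny; best_n3 = nz; best_d = d;
    }
  }
  return List::create(_["normal"] = NumericVector::create(best_n1, best_n2, best_n3),
                      _["offset"] = best_d, _["count"] = best_count);
}

// Score two-point-plus-normals cylinder hypotheses.
// P: n x 3 points, Nrm: n x 3 unit normals, pairs: m x 2 (1-based).
// prior: length-3 axis prior or length-0; cos_max_dev: min |cos| to prior.
// Returns the hypothesis with most inliers of |radial dist - r| <= thresh.
//' @noRd
// [[Rcpp::export]]
List cpp_ransac_cylinder(const arma::mat& P, const arma::mat& Nrm,
                         const arma::imat& pairs, double thresh,
                         const arma::vec& prior, double cos_max_dev,
                         double rmin, double rmax) {
  int m = (int)pairs.n_rows;
  int n = (int)P.n_rows;
  bool has_prior = prior.n_elem == 3;
  arma::vec best_a(3, arma::fill::zeros), best_d(3, arma::fill::zeros);
  double best_r = -1;
  int best_count = -1;
  for (int s = 0; s < m; ++s) {
    arma::vec p1 = P.row(pairs(s, 0) - 1).t();
    arma::vec p2 = P.row(pairs(s, 1) - 1).t();
    arma::vec n1 = Nrm.row(pairs(s, 0) - 1).t();
    arma::vec n2 = Nrm.row(pairs(s, 1) - 1).t();
    arma::vec d = arma::cross(n1, n2);
    double dn = arma::norm(d);
    if (dn < 1e-8) continue; // parallel normals: axis undetermined
    d /= dn;
    if (has_prior && std::fabs(arma::dot(d, prior)) < cos_max_dev) continue;
    // intersect the two normal lines in the plane orthogonal to d:
    // solve p1p + s*n1p = p2p + t*n2p with *p = projection onto that plane.
    arma::vec n1p = n1 - arma::dot(n1, d) * d;
    arma::vec n2p = n2 - arma::dot(n2, d) * d;
    arma::vec dp = (p2 - arma::dot(p2, d) * d) - (p1 - arma::dot(p1, d) * d);
    // 2x2 system in an orthonormal basis (e1, e2) of the plane
    arma::vec e1 = n1p;
    double e1n = arma::norm(e1);
    if (e1n < 1e-10) continue;
    e1 /= e1n;
    arma::vec e2 = arma::cross(d, e1);
    double a11 = arma::dot(n1p, e1), a12 = -arma::dot(n2p, e1);
    double a21 = arma::dot(n1p, e2), a22 = -arma::dot(n2p, e2);
    double b1 = arma::dot(dp, e1), b2 = arma::dot(dp, e2);
    double det = a11 * a22 - a12 * a21;
    if (std::fabs(det) < 1e-12) continue;
    double sl = (b1 * a22 - b2 * a12) / det;
    arma::vec axis_pt = p1 + sl * n1;
    arma::vec v1 = p1 - axis_pt;
    v1 -= arma::dot(v1, d) * d;
    double r = arma::norm(v1);
    if (r < rmin || r > rmax) continue;
    int count = 0;
    for (int i = 0; i < n; ++i) {
      double wx = P(i, 0) - axis_pt(0), wy = P(i, 1) - axis_pt(1),
             wz = P(i, 2) - axis_pt(2);
      double t = wx * d(0) + wy * d(1) + wz * d(2);
      double rx = wx - t * d(0), ry = wy - t * d(1), rz = wz - t * d(2);
      double dist = std::sqrt(rx * rx + ry * ry + rz * rz);
      if (std::fabs(dist - r) <= thresh) ++count;
    }
    if (count > best_count) {
      best_count = count;
      best_a = axis_pt; best_d = d; best_r = r;
    }
  }
  return List::create(_["axis_point"] = NumericVector::create(best_a(0), best_a(1), best_a(2)),
                      _["axis_dir"] = NumericVector::create(best_d(0), best_d(1), best_d(2)),
                      _["radius"] = best_r, _["count"] = best_count);
}
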