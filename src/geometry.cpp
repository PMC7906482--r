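// Low-level geometry kernels: neighbor search, normals, FPFH descriptors,
// 1-D SOM chain training, nearest-neighbor queries. Coordinates in meters.
#include <Rcpp.h>
#include <unordered_map>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

namespace {

// pack 3 signed cell coordinates into one 64-bit key (21 bits each)
inline long long cell_key(long ix, long iy, long iz) {
  const long long off = 1LL << 20;
  return ((ix + off) << 42) | ((iy + off) << 21) | (iz + off);
}

struct Grid {
  std::unordered_map<long long, std::vector<int> > cells;
  double cs; // cell size
  const NumericMatrix& pts;
  Grid(const NumericMatrix& p, double cell_size) : cs(cell_size), pts(p) {
    for (int i = 0; i < p.nrow(); ++i) {
      long ix = (long)std::floor(p(i, 0) / cs);
      long iy = (long)std::floor(p(i, 1) / cs);
      long iz = (long)std::floor(p(i, 2) / cs);
      cells[cell_key(ix, iy, iz)].push_back(i);
    }
  }
  // indices within radius r of point (x,y,z); r must be <= cs
  void query(double x, double y, double z, double r, std::vector<int>& out) const {
    out.clear();
    double r2 = r * r;
    long ix = (long)std::floor(x / cs), iy = (long)std::floor(y / cs),
         iz = (long)std::floor(z / cs);
    for (long dx = -1; dx <= 1; ++dx)
      for (long dy = -1; dy <= 1; ++dy)
        for (long dz = -1; dz <= 1; ++dz) {
          auto it = cells.find(cell_key(ix + dx, iy + dy, iz + dz));
          if (it == cells.end()) continue;
          for (int j : it->second) {
            double ddx = pts(j, 0) - x, ddy = pts(j, 1) - y, ddz = pts(j, 2) - z;
            if (ddx * ddx + ddy * ddy + ddz * ddz <= r2) out.push_back(j);
          }
        }
  }
};

// eigen decomposition of a symmetric 3x3 matrix by cyclic Jacobi.
// a is overwritten; v receives eigenvectors (columns); d eigenvalues.
void eigen_sym3(double a[3][3], double v[3][3], double d[3]) {
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) v[i][j] = (i == j) ? 1.0 : 0.0;
  for (int sweep = 0; sweep < 50; ++sweep) {
    double off = std::fabs(a[0][1]) + std::fabs(a[0][2]) + std::fabs(a[1][2]);
    if (off < 1e-18) break;
    for (int p = 0; p < 2; ++p)
      for (int q = p + 1; q < 3; ++q) {
        if (std::fabs(a[p][q]) < 1e-30) continue;
        double theta = (a[q][q] - a[p][p]) / (2.0 * a[p][q]);
        double t = (theta >= 0 ? 1.0 : -1.0) /
                   (std::fabs(theta) + std::sqrt(theta * theta + 1.0));
        double c = 1.0 / std::sqrt(t * t + 1.0), s = t * c;
        for (int k = 0; k < 3; ++k) {
          double akp = a[k][p], akq = a[k][q];
          a[k][p] = c * akp - s * akq;
          a[k][q] = s * akp + c * akq;
        }
        for (int k = 0; k < 3; ++k) {
          double apk = a[p][k], aqk = a[q][k];
          a[p][k] = c * apk - s * aqk;
          a[q][k] = s * apk + c * aqk;
        }
        for (int k = 0; k < 3; ++k) {
          double vkp = v[k][p], vkq = v[k][q];
          v[k][p] = c * vkp - s * vkq;
          v[k][q] = s * vkp + c * vkq;
        }
      }
  }
  for (int i = 0; i < 3; ++i) d[i] = a[i][i];
}

} // namespace

// [[Rcpp::export]]
List cpp_radius_neighbors(NumericMatrix pts, double radius) {
  Grid g(pts, radius);
  int n = pts.nrow();
  List out(n);
  std::vector<int> buf;
  for (int i = 0; i < n; ++i) {
    g.query(pts(i, 0), pts(i, 1), pts(i, 2), radius, buf);
    IntegerVector v(buf.size() > 0 ? buf.size() - 1 : 0);
    int k = 0;
    for (int j : buf)
      if (j != i) v[k++] = j + 1; // 1-based, self excluded
    if (k < v.size()) v = IntegerVector(v.begin(), v.begin() + k);
    out[i] = v;
  }
  return out;
}

// k nearest neighbors of each query row among data rows (brute force).
// [[Rcpp::export]]
List cpp_knn(NumericMatrix query, NumericMatrix data, int k) {
  int nq = query.nrow(), nd = data.nrow();
  if (k > nd) k = nd;
  IntegerMatrix idx(nq, k);
  NumericMatrix dist(nq, k);
  std::vector<std::pair<double, int> > d(nd);
  for (int i = 0; i < nq; ++i) {
    for (int j = 0; j < nd; ++j) {
      double dx = query(i, 0) - data(j, 0), dy = query(i, 1) - data(j, 1),
             dz = query(i, 2) - data(j, 2);
      d[j] = std::make_pair(dx * dx + dy * dy + dz * dz, j);
    }
    std::partial_sort(d.begin(), d.begin() + k, d.end());
    for (int j = 0; j < k; ++j) {
      idx(i, j) = d[j].second + 1;
      dist(i, j) = std::sqrt(d[j].first);
    }
  }
  return List::create(_["idx"] = idx, _["dist"] = dist);
}

// distance from each query point to its nearest data point (plus the index)
// [[Rcpp::export]]
List cpp_nn1(NumericMatrix query, NumericMatrix data) {
  int nq = query.nrow(), nd = data.nrow();
  IntegerVector idx(nq);
  NumericVector dist(nq);
  for (int i = 0; i < nq; ++i) {
    double best = std::numeric_limits<double>::max();
    int bi = 0;
    for (int j = 0; j < nd; ++j) {
      double dx = query(i, 0) - data(j, 0), dy = query(i, 1) - data(j, 1),
             dz = query(i, 2) - data(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) { best = d2; bi = j; }
    }
    idx[i] = bi + 1;
    dist[i] = std::sqrt(best);
  }
  return List::create(_["idx"] = idx, _["dist"] = dist);
}

// unit surface normals from the covariance of the radius neighborhood;
// sign made canonical (first nonzero of (z,y,x) component positive)
// [[Rcpp::export]]
NumericMatrix cpp_normals(NumericMatrix pts, List nbrs) {
  int n = pts.nrow();
  NumericMatrix nrm(n, 3);
  for (int i = 0; i < n; ++i) {
    IntegerVector nb = nbrs[i];
    int m = nb.size() + 1;
    double mean[3] = {pts(i, 0), pts(i, 1), pts(i, 2)};
    for (int t = 0; t < nb.size(); ++t)
      for (int c = 0; c < 3; ++c) mean[c] += pts(nb[t] - 1, c);
    for (int c = 0; c < 3; ++c) mean[c] /= m;
    double cov[3][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}};
    for (int t = -1; t < nb.size(); ++t) {
      int j = (t < 0) ? i : nb[t] - 1;
      double dx[3] = {pts(j, 0) - mean[0], pts(j, 1) - mean[1], pts(j, 2) - mean[2]};
      for (int a = 0; a < 3; ++a)
        for (int b = 0; b < 3; ++b) cov[a][b] += dx[a] * dx[b];
    }
    double v[3][3], d[3];
    eigen_sym3(cov, v, d);
    int k = 0;
    if (d[1] < d[k]) k = 1;
    if (d[2] < d[k]) k = 2;
    double nx = v[0][k], ny = v[1][k], nz = v[2][k];
    double len = std::sqrt(nx * nx + ny * ny + nz * nz);
    if (len < 1e-300) { nx = 0; ny = 0; nz = 1; len = 1; }
    nx /= len; ny /= len; nz /= len;
    const double tol = 1e-12;
    bool flip = (nz < -tol) ||
                (std::fabs(nz) <= tol && (ny < -tol ||
                 (std::fabs(ny) <= tol && nx < 0)));
    if (flip) { nx = -nx; ny = -ny; nz = -nz; }
    nrm(i, 0) = nx; nrm(i, 1) = ny; nrm(i, 2) = nz;
  }
  return nrm;
}

namespace {

// simplified point feature (Darboux frame angles) between source s and target t
inline void pair_features(const double* ps, const double* ns, const double* pt,
                          const double* nt, double& f_alpha, double& f_phi,
                          double& f_theta, bool& ok) {
  double d[3] = {pt[0] - ps[0], pt[1] - ps[1], pt[2] - ps[2]};
  double dn = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
  if (dn < 1e-12) { ok = false; return; }
  for (int c = 0; c < 3; ++c) d[c] /= dn;
  const double* u = ns;
  double v[3] = {d[1] * u[2] - d[2] * u[1], d[2] * u[0] - d[0] * u[2],
                 d[0] * u[1] - d[1] * u[0]};
  double vn = std::sqrt(v[0] * v[0] + v[1] * v[1] + v[2] * v[2]);
  if (vn < 1e-12) { ok = false; return; } // d parallel to normal
  for (int c = 0; c < 3; ++c) v[c] /= vn;
  double w[3] = {u[1] * v[2] - u[2] * v[1], u[2] * v[0] - u[0] * v[2],
                 u[0] * v[1] - u[1] * v[0]};
  f_alpha = v[0] * nt[0] + v[1] * nt[1] + v[2] * nt[2];
  f_phi = u[0] * d[0] + u[1] * d[1] + u[2] * d[2];
  f_theta = std::atan2(w[0] * nt[0] + w[1] * nt[1] + w[2] * nt[2],
                       u[0] * nt[0] + u[1] * nt[1] + u[2] * nt[2]);
  ok = true;
}

inline int bin11(double x, double lo, double hi) {
  int b = (int)std::floor((x - lo) / (hi - lo) * 11.0);
  if (b < 0) b = 0;
  if (b > 10) b = 10;
  return b;
}

} // namespace

// 33-bin fast point feature histograms (11 bins per angular feature).
// Points with fewer than kmin neighbors get a zero histogram and flag TRUE.
// [[Rcpp::export]]
List cpp_fpfh(NumericMatrix pts, NumericMatrix normals, List nbrs, int kmin) {
  const double PI = 3.14159265358979323846;
  int n = pts.nrow();
  NumericMatrix spfh(n, 33);
  LogicalVector flagged(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector nb = nbrs[i];
    if (nb.size() < kmin) { flagged[i] = true; continue; }
    double ps[3] = {pts(i, 0), pts(i, 1), pts(i, 2)};
    double ns[3] = {normals(i, 0), normals(i, 1), normals(i, 2)};
    int cnt = 0;
    for (int t = 0; t < nb.size(); ++t) {
      int j = nb[t] - 1;
      double pt[3] = {pts(j, 0), pts(j, 1), pts(j, 2)};
      double nt[3] = {normals(j, 0), normals(j, 1), normals(j, 2)};
      double fa, fp, ft;
      bool ok;
      pair_features(ps, ns, pt, nt, fa, fp, ft, ok);
      if (!ok) continue;
      spfh(i, bin11(fa, -1.0, 1.0)) += 1.0;
      spfh(i, 11 + bin11(fp, -1.0, 1.0)) += 1.0;
      spfh(i, 22 + bin11(ft, -PI, PI)) += 1.0;
      ++cnt;
    }
    if (cnt == 0) { flagged[i] = true; continue; }
    for (int blk = 0; blk < 3; ++blk) {
      double s = 0;
      for (int b = 0; b < 11; ++b) s += spfh(i, blk * 11 + b);
      if (s > 0)
        for (int b = 0; b < 11; ++b) spfh(i, blk * 11 + b) /= s;
    }
  }
  // FPFH = own SPFH + distance-weighted mean of neighbors' SPFHs
  NumericMatrix fpfh(n, 33);
  for (int i = 0; i < n; ++i) {
    if (flagged[i]) continue;
    for (int b = 0; b < 33; ++b) fpfh(i, b) = spfh(i, b);
    IntegerVector nb = nbrs[i];
    int k = 0;
    std::vector<double> wsum(33, 0.0);
    for (int t = 0; t < nb.size(); ++t) {
      int j = nb[t] - 1;
      if (flagged[j]) continue;
      double dx = pts(i, 0) - pts(j, 0), dy = pts(i, 1) - pts(j, 1),
             dz = pts(i, 2) - pts(j, 2);
      double w = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (w < 1e-12) continue;
      for (int b = 0; b < 33; ++b) wsum[b] += spfh(j, b) / w;
      ++k;
    }
    if (k > 0)
      for (int b = 0; b < 33; ++b) fpfh(i, b) += wsum[b] / k;
    for (int blk = 0; blk < 3; ++blk) {
      double s = 0;
      for (int b = 0; b < 11; ++b) s += fpfh(i, blk * 11 + b);
      if (s > 0)
        for (int b = 0; b < 11; ++b) fpfh(i, blk * 11 + b) /= s;
    }
  }
  return List::create(_["fpfh"] = fpfh, _["flagged"] = flagged);
}

// Online 1-D SOM: alternates best-matching-unit selection and
// Gaussian-neighborhood-weighted updates over shuffled samples.
// Uses the R RNG, so results are reproducible under set.seed().
// [[Rcpp::export]]
NumericMatrix cpp_som_chain(NumericMatrix pts, NumericMatrix init, int epochs,
                            double eta0, double eta1, double conv_tol) {
  int m = pts.nrow(), n = init.nrow();
  NumericMatrix w = clone(init);
  std::vector<double> prev(3 * n);
  for (int e = 0; e < epochs; ++e) {
    double frac = (epochs > 1) ? (double)e / (epochs - 1) : 1.0;
    double eta = eta0 + (eta1 - eta0) * frac;
    double sigma0 = std::max(n / 2.0, 0.5);
    double sigma = sigma0 + (0.5 - sigma0) * frac;
    for (int u = 0; u < n; ++u)
      for (int c = 0; c < 3; ++c) prev[3 * u + c] = w(u, c);
    IntegerVector ord = sample(m, m, false); // R RNG
    for (int t = 0; t < m; ++t) {
      int i = ord[t] - 1;
      double x[3] = {pts(i, 0), pts(i, 1), pts(i, 2)};
      int bmu = 0;
      double best = std::numeric_limits<double>::max();
      for (int u = 0; u < n; ++u) {
        double dx = x[0] - w(u, 0), dy = x[1] - w(u, 1), dz = x[2] - w(u, 2);
        double d2 = dx * dx + dy * dy + dz * dz;
        if (d2 < best) { best = d2; bmu = u; }
      }
      for (int u = 0; u < n; ++u) {
        double du = u - bmu;
        double beta = std::exp(-du * du / (2.0 * sigma * sigma));
        if (beta < 1e-6) continue;
        for (int c = 0; c < 3; ++c) w(u, c) += eta * beta * (x[c] - w(u, c));
      }
    }
    double move = 0;
    for (int u = 0; u < n; ++u)
      for (int c = 0; c < 3; ++c)
        move = std::max(move, std::fabs(w(u, c) - prev[3 * u + c]));
    if (move < conv_tol) break;
  }
  return w;
}
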