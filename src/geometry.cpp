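// Low-level geometric kernels: 3D nearest-neighbour search (kd-tree),
// fixed-radius neighbour lists (uniform grid hash), and voxel volume of a
// watertight triangle mesh by vertical-ray parity counting.
#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

namespace {

struct KDTree {
  // points stored as flat array of 3 doubles, tree over permutation idx
  const double *pts;
  int n;
  std::vector<int> idx;

  KDTree(const double *p, int n_) : pts(p), n(n_), idx(n_) {
    for (int i = 0; i < n; ++i) idx[i] = i;
    build(0, n, 0);
  }

  inline double coord(int i, int d) const { return pts[3 * i + d]; }

  void build(int lo, int hi, int depth) {
    if (hi - lo <= 1) return;
    int mid = (lo + hi) / 2;
    int d = depth % 3;
    std::nth_element(idx.begin() + lo, idx.begin() + mid, idx.begin() + hi,
                     [&](int a, int b) { return coord(a, d) < coord(b, d); });
    build(lo, mid, depth + 1);
    build(mid + 1, hi, depth + 1);
  }

  void nearest(const double *q, int lo, int hi, int depth, int &best,
               double &bestd2) const {
    if (hi <= lo) return;
    int mid = (lo + hi) / 2;
    int d = depth % 3;
    int p = idx[mid];
    double dx = q[0] - coord(p, 0), dy = q[1] - coord(p, 1),
           dz = q[2] - coord(p, 2);
    double d2 = dx * dx + dy * dy + dz * dz;
    if (d2 < bestd2) {
      bestd2 = d2;
      best = p;
    }
    double delta = q[d] - coord(p, d);
    if (delta < 0) {
      nearest(q, lo, mid, depth + 1, best, bestd2);
      if (delta * delta < bestd2) nearest(q, mid + 1, hi, depth + 1, best, bestd2);
    } else {
      nearest(q, mid + 1, hi, depth + 1, best, bestd2);
      if (delta * delta < bestd2) nearest(q, lo, mid, depth + 1, best, bestd2);
    }
  }

  int query(const double *q, double &dist) const {
    int best = -1;
    double bestd2 = R_PosInf;
    nearest(q, 0, n, 0, best, bestd2);
    dist = std::sqrt(bestd2);
    return best;
  }
};

}  // namespace

// [[Rcpp::export]]
List cpp_nearest(NumericMatrix query, NumericMatrix target) {
  if (target.nrow() < 1) stop("empty target cloud");
  int nq = query.nrow(), nt = target.nrow();
  // column-major R matrix -> flat xyz triplets
  std::vector<double> tp(3 * nt), qp(3 * nq);
  for (int i = 0; i < nt; ++i)
    for (int d = 0; d < 3; ++d) tp[3 * i + d] = target(i, d);
  for (int i = 0; i < nq; ++i)
    for (int d = 0; d < 3; ++d) qp[3 * i + d] = query(i, d);
  KDTree tree(tp.data(), nt);
  IntegerVector idx(nq);
  NumericVector dist(nq);
  for (int i = 0; i < nq; ++i) {
    double d;
    idx[i] = tree.query(&qp[3 * i], d) + 1;
    dist[i] = d;
  }
  return List::create(_["index"] = idx, _["dist"] = dist);
}

// [[Rcpp::export]]
List cpp_radius_neighbors(NumericMatrix pts, double eps) {
  int n = pts.nrow();
  double inv = 1.0 / eps;
  auto key = [&](long long cx, long long cy, long long cz) {
    return ((cx * 73856093LL) ^ (cy * 19349663LL) ^ (cz * 83492791LL));
  };
  std::unordered_map<long long, std::vector<int> > grid;
  std::vector<long long> cx(n), cy(n), cz(n);
  for (int i = 0; i < n; ++i) {
    cx[i] = (long long)std::floor(pts(i, 0) * inv);
    cy[i] = (long long)std::floor(pts(i, 1) * inv);
    cz[i] = (long long)std::floor(pts(i, 2) * inv);
    grid[key(cx[i], cy[i], cz[i])].push_back(i);
  }
  double eps2 = eps * eps;
  List out(n);
  std::vector<int> nb;
  for (int i = 0; i < n; ++i) {
    nb.clear();
    for (long long ax = cx[i] - 1; ax <= cx[i] + 1; ++ax)
      for (long long ay = cy[i] - 1; ay <= cy[i] + 1; ++ay)
        for (long long az = cz[i] - 1; az <= cz[i] + 1; ++az) {
          auto it = grid.find(key(ax, ay, az));
          if (it == grid.end()) continue;
          for (int j : it->second) {
            // hash collisions put unrelated cells in one bucket; recheck cell
            if (cx[j] < cx[i] - 1 || cx[j] > cx[i] + 1 || cy[j] < cy[i] - 1 ||
                cy[j] > cy[i] + 1 || cz[j] < cz[i] - 1 || cz[j] > cz[i] + 1)
              continue;
            double dx = pts(i, 0) - pts(j, 0), dy = pts(i, 1) - pts(j, 1),
                   dz = pts(i, 2) - pts(j, 2);
            if (dx * dx + dy * dy + dz * dz <= eps2) nb.push_back(j + 1);
          }
        }
    out[i] = IntegerVector(nb.begin(), nb.end());
  }
  return out;
}

// Volume by parity counting of voxel centres along vertical rays.
// Column centres are jittered by an irrational sub-voxel offset so rays do
// not pass exactly through mesh vertices/edges of regularly gridded meshes.
// [[Rcpp::export]]
List cpp_voxel_volume(NumericMatrix v, IntegerMatrix f, double pitch) {
  int nv = v.nrow(), nf = f.nrow();
  if (nv < 4 || nf < 4) stop("mesh too small for volume estimation");
  double xmin = R_PosInf, xmax = R_NegInf, ymin = R_PosInf, ymax = R_NegInf,
         zmin = R_PosInf, zmax = R_NegInf;
  for (int i = 0; i < nv; ++i) {
    xmin = std::min(xmin, v(i, 0)); xmax = std::max(xmax, v(i, 0));
    ymin = std::min(ymin, v(i, 1)); ymax = std::max(ymax, v(i, 1));
    zmin = std::min(zmin, v(i, 2)); zmax = std::max(zmax, v(i, 2));
  }
  const double jx = 0.2137 * pitch * 1e-2, jy = 0.3571 * pitch * 1e-2;
  int nx = (int)std::ceil((xmax - xmin) / pitch) + 1;
  int ny = (int)std::ceil((ymax - ymin) / pitch) + 1;
  if ((double)nx * ny > 4e7) stop("voxel pitch too fine for mesh extent");
  std::vector<std::vector<int> > cells((size_t)nx * ny);
  for (int t = 0; t < nf; ++t) {
    double tx0 = R_PosInf, tx1 = R_NegInf, ty0 = R_PosInf, ty1 = R_NegInf;
    for (int k = 0; k < 3; ++k) {
      int p = f(t, k) - 1;
      tx0 = std::min(tx0, v(p, 0)); tx1 = std::max(tx1, v(p, 0));
      ty0 = std::min(ty0, v(p, 1)); ty1 = std::max(ty1, v(p, 1));
    }
    int i0 = std::max(0, (int)std::floor((tx0 - xmin - jx) / pitch - 0.5));
    int i1 = std::min(nx - 1, (int)std::ceil((tx1 - xmin - jx) / pitch - 0.5));
    int j0 = std::max(0, (int)std::floor((ty0 - ymin - jy) / pitch - 0.5));
    int j1 = std::min(ny - 1, (int)std::ceil((ty1 - ymin - jy) / pitch - 0.5));
    for (int i = i0; i <= i1; ++i)
      for (int j = j0; j <= j1; ++j) cells[(size_t)i * ny + j].push_back(t);
  }
  long long count = 0;
  std::vector<double> cross;
  for (int i = 0; i < nx; ++i) {
    double x = xmin + (i + 0.5) * pitch + jx;
    for (int j = 0; j < ny; ++j) {
      const std::vector<int> &cand = cells[(size_t)i * ny + j];
      if (cand.empty()) continue;
      double y = ymin + (j + 0.5) * pitch + jy;
      cross.clear();
      for (int t : cand) {
        int a = f(t, 0) - 1, b = f(t, 1) - 1, c = f(t, 2) - 1;
        double ax = v(a, 0) - x, ay = v(a, 1) - y;
        double bx = v(b, 0) - x, by = v(b, 1) - y;
        double cxp = v(c, 0) - x, cyp = v(c, 1) - y;
        double d1 = ax * by - ay * bx;
        double d2 = bx * cyp - by * cxp;
        double d3 = cxp * ay - cyp * ax;
        bool pos = d1 > 0 && d2 > 0 && d3 > 0;
        bool neg = d1 < 0 && d2 < 0 && d3 < 0;
        if (!pos && !neg) continue;
        double area = d1 + d2 + d3;
        double w1 = d2 / area, w2 = d3 / area, w3 = d1 / area;
        cross.push_back(w1 * v(a, 2) + w2 * v(b, 2) + w3 * v(c, 2));
      }
      if (cross.size() < 2) continue;
      std::sort(cross.begin(), cross.end());
      // collapse duplicate hits at shared edges
      std::vector<double> uq;
      for (double zc : cross)
        if (uq.empty() || zc - uq.back() > 1e-9) uq.push_back(zc);
      size_t m = uq.size() - (uq.size() % 2);
      for (size_t k = 0; k + 1 < m; k += 2) {
        int jlo = (int)std::ceil((uq[k] - zmin) / pitch - 0.5);
        int jhi = (int)std::floor((uq[k + 1] - zmin) / pitch - 0.5);
        if (jhi >= jlo) count += (jhi - jlo + 1);
      }
    }
  }
  double vol = (double)count * pitch * pitch * pitch;
  return List::create(_["volume"] = vol, _["voxels"] = (double)count);
}
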