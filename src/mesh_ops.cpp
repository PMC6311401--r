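#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>
#include <algorithm>
using namespace Rcpp;

// Closest point on triangle abc to p (Ericson, Real-Time Collision Detection).
static inline void closest_pt_tri(const double *p, const double *a,
                                  const double *b, const double *c,
                                  double *out) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) {
    ab[i] = b[i] - a[i];
    ac[i] = c[i] - a[i];
    ap[i] = p[i] - a[i];
  }
  double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  if (d1 <= 0.0 && d2 <= 0.0) { for (int i = 0; i < 3; ++i) out[i] = a[i]; return; }

  double bp[3];
  for (int i = 0; i < 3; ++i) bp[i] = p[i] - b[i];
  double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
  double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
  if (d3 >= 0.0 && d4 <= d3) { for (int i = 0; i < 3; ++i) out[i] = b[i]; return; }

  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + v * ab[i];
    return;
  }

  double cp[3];
  for (int i = 0; i < 3; ++i) cp[i] = p[i] - c[i];
  double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
  double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
  if (d6 >= 0.0 && d5 <= d6) { for (int i = 0; i < 3; ++i) out[i] = c[i]; return; }

  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + w * ac[i];
    return;
  }

  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int i = 0; i < 3; ++i) out[i] = b[i] + w * (c[i] - b[i]);
    return;
  }

  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int i = 0; i < 3; ++i) out[i] = a[i] + ab[i] * v + ac[i] * w;
}

static inline double sqdist3(const double *a, const double *b) {
  double s = 0.0;
  for (int i = 0; i < 3; ++i) { double d = a[i] - b[i]; s += d * d; }
  return s;
}

static inline int64_t cell_key(int ix, int iy, int iz) {
  return (((int64_t)(ix + 1) & 0x1FFFFF) << 42) |
         (((int64_t)(iy + 1) & 0x1FFFFF) << 21) |
         ((int64_t)(iz + 1) & 0x1FFFFF);
}

struct MeshIndex {
  int nf;
  std::vector<double> tri;              // 9 doubles per triangle
  double lo[3], hi[3];
  double cell;
  int max_shell;
  std::unordered_map<int64_t, std::vector<int> > grid;
};

static MeshIndex *build_index(NumericMatrix V, IntegerMatrix F) {
  const int nf = F.nrow();
  if (nf == 0) stop("mesh has no faces");
  MeshIndex *mi = new MeshIndex();
  mi->nf = nf;
  std::vector<double> &tri = mi->tri;
  tri.resize(9 * (size_t)nf);
  double *lo = mi->lo, *hi = mi->hi;
  lo[0] = lo[1] = lo[2] = R_PosInf;
  hi[0] = hi[1] = hi[2] = R_NegInf;
  double mean_ext = 0.0;
  for (int f = 0; f < nf; ++f) {
    for (int k = 0; k < 3; ++k) {
      int vi = F(f, k) - 1;
      for (int d = 0; d < 3; ++d) tri[9 * (size_t)f + 3 * k + d] = V(vi, d);
    }
    for (int d = 0; d < 3; ++d) {
      double a = tri[9 * (size_t)f + d], b = tri[9 * (size_t)f + 3 + d],
             c = tri[9 * (size_t)f + 6 + d];
      double mn = std::min(a, std::min(b, c)), mx = std::max(a, std::max(b, c));
      if (mn < lo[d]) lo[d] = mn;
      if (mx > hi[d]) hi[d] = mx;
      mean_ext += (mx - mn);
    }
  }
  mean_ext /= (3.0 * nf);
  double diag = 0.0;
  for (int d = 0; d < 3; ++d) diag = std::max(diag, hi[d] - lo[d]);
  double cell = std::max(2.0 * mean_ext, diag / 64.0);
  if (cell <= 0.0) cell = 1.0;
  mi->cell = cell;

  mi->grid.reserve((size_t)nf * 2);
  for (int f = 0; f < nf; ++f) {
    int c0[3], c1[3];
    for (int d = 0; d < 3; ++d) {
      double a = tri[9 * (size_t)f + d], b = tri[9 * (size_t)f + 3 + d],
             c = tri[9 * (size_t)f + 6 + d];
      double mn = std::min(a, std::min(b, c)), mx = std::max(a, std::max(b, c));
      c0[d] = (int)std::floor((mn - lo[d]) / cell);
      c1[d] = (int)std::floor((mx - lo[d]) / cell);
    }
    for (int ix = c0[0]; ix <= c1[0]; ++ix)
      for (int iy = c0[1]; iy <= c1[1]; ++iy)
        for (int iz = c0[2]; iz <= c1[2]; ++iz)
          mi->grid[cell_key(ix, iy, iz)].push_back(f);
  }

  int max_shell = 3;
  for (int d = 0; d < 3; ++d) {
    int n = (int)std::ceil((hi[d] - lo[d]) / cell) + 2;
    if (n > max_shell) max_shell = n;
  }
  mi->max_shell = max_shell;
  return mi;
}

// [[Rcpp::export(name = ".cpp_mesh_index")]]
SEXP cpp_mesh_index(NumericMatrix V, IntegerMatrix F) {
  XPtr<MeshIndex> ptr(build_index(V, F), true);
  return ptr;
}

static List query_index(MeshIndex *mi, NumericMatrix Q) {
  const int nf = mi->nf, nq = Q.nrow();
  const std::vector<double> &tri = mi->tri;
  const double *lo = mi->lo;
  const double cell = mi->cell;
  const int max_shell = mi->max_shell;
  const std::unordered_map<int64_t, std::vector<int> > &grid = mi->grid;

  NumericMatrix P(nq, 3);
  NumericVector dist(nq);
  IntegerVector face(nq);
  std::vector<int> stamp((size_t)nf, -1);

  for (int q = 0; q < nq; ++q) {
    double p[3] = {Q(q, 0), Q(q, 1), Q(q, 2)};
    int cq[3];
    bool clamped = false;
    for (int d = 0; d < 3; ++d) {
      cq[d] = (int)std::floor((p[d] - lo[d]) / cell);
      int hi_cell = (int)std::floor((mi->hi[d] - lo[d]) / cell);
      if (cq[d] < 0) { cq[d] = 0; clamped = true; }
      if (cq[d] > hi_cell) { cq[d] = hi_cell; clamped = true; }
    }
    double best = R_PosInf, bestpt[3] = {0, 0, 0};
    int bestf = -1;
    for (int r = 0; r <= max_shell + 1; ++r) {
      // visit only cells at Chebyshev distance exactly r
      for (int dx = -r; dx <= r; ++dx) {
        int ix = cq[0] + dx;
        bool face_x = (std::abs(dx) == r);
        for (int dy = -r; dy <= r; ++dy) {
          int iy = cq[1] + dy;
          bool face_xy = face_x || (std::abs(dy) == r);
          int zstep = face_xy ? 1 : 2 * r;
          if (!face_xy && r == 0) zstep = 1;
          for (int dz = -r; dz <= r; dz += zstep) {
            int iz = cq[2] + dz;
            // prune cells that cannot beat the current best
            if (bestf >= 0) {
              double dd = 0.0;
              int ci[3] = {ix, iy, iz};
              for (int d = 0; d < 3; ++d) {
                double c0 = lo[d] + ci[d] * cell;
                double gap = (p[d] < c0) ? (c0 - p[d])
                             : (p[d] > c0 + cell ? p[d] - c0 - cell : 0.0);
                dd += gap * gap;
              }
              if (dd >= best) continue;
            }
            std::unordered_map<int64_t, std::vector<int> >::const_iterator it =
                grid.find(cell_key(ix, iy, iz));
            if (it == grid.end()) continue;
            const std::vector<int> &ids = it->second;
            for (size_t m = 0; m < ids.size(); ++m) {
              int f = ids[m];
              if (stamp[f] == q) continue;
              stamp[f] = q;
              double cpt[3];
              closest_pt_tri(p, &tri[9 * (size_t)f], &tri[9 * (size_t)f + 3],
                             &tri[9 * (size_t)f + 6], cpt);
              double d2 = sqdist3(p, cpt);
              if (d2 < best) {
                best = d2;
                bestf = f;
                for (int d = 0; d < 3; ++d) bestpt[d] = cpt[d];
              }
            }
          }
        }
      }
      // cells on shell r+1 are at Euclidean distance >= r*cell from the
      // search center; when the center was clamped into the grid, give up
      // one shell of slack
      double rsafe = clamped ? (double)(r - 1) : (double)r;
      if (rsafe < 0.0) rsafe = 0.0;
      if (bestf >= 0 && best <= rsafe * cell * rsafe * cell) break;
    }
    for (int d = 0; d < 3; ++d) P(q, d) = bestpt[d];
    dist[q] = std::sqrt(best);
    face[q] = bestf + 1;
  }
  return List::create(Named("points") = P, Named("dist") = dist,
                      Named("face") = face);
}

// [[Rcpp::export(name = ".cpp_closest_points_indexed")]]
List cpp_closest_points_indexed(SEXP index, NumericMatrix Q) {
  XPtr<MeshIndex> ptr(index);
  return query_index(ptr.get(), Q);
}

// [[Rcpp::export(name = ".cpp_closest_points")]]
List cpp_closest_points(NumericMatrix V, IntegerMatrix F, NumericMatrix Q) {
  MeshIndex *mi = build_index(V, F);
  List out = query_index(mi, Q);
  delete mi;
  return out;
}

// Parity (ray-casting) inside test on a regular voxel grid.  origin is the
// lower corner of the grid; voxel centers sit at origin + (i - 0.5) * spacing.
// [[Rcpp::export(name = ".cpp_voxel_inside")]]
LogicalVector cpp_voxel_inside(NumericMatrix V, IntegerMatrix F,
                               NumericVector origin, NumericVector spacing,
                               IntegerVector dims) {
  const int nf = F.nrow();
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  LogicalVector out((R_xlen_t)nx * ny * nz);

  // bucket triangles over (x, y) columns
  std::vector<std::vector<int> > cols((size_t)nx * ny);
  const double eps = 1e-7 * (spacing[0] + spacing[1]);
  for (int f = 0; f < nf; ++f) {
    double xs[3], ys[3];
    for (int k = 0; k < 3; ++k) {
      xs[k] = V(F(f, k) - 1, 0);
      ys[k] = V(F(f, k) - 1, 1);
    }
    double xmn = std::min(xs[0], std::min(xs[1], xs[2]));
    double xmx = std::max(xs[0], std::max(xs[1], xs[2]));
    double ymn = std::min(ys[0], std::min(ys[1], ys[2]));
    double ymx = std::max(ys[0], std::max(ys[1], ys[2]));
    int i0 = std::max(0, (int)std::floor((xmn - origin[0]) / spacing[0] - 0.5));
    int i1 = std::min(nx - 1, (int)std::ceil((xmx - origin[0]) / spacing[0]));
    int j0 = std::max(0, (int)std::floor((ymn - origin[1]) / spacing[1] - 0.5));
    int j1 = std::min(ny - 1, (int)std::ceil((ymx - origin[1]) / spacing[1]));
    for (int i = i0; i <= i1; ++i)
      for (int j = j0; j <= j1; ++j)
        cols[(size_t)j * nx + i].push_back(f);
  }

  std::vector<double> zhits;
  for (int j = 0; j < ny; ++j) {
    double py = origin[1] + (j + 0.5) * spacing[1] + eps * 0.618;
    for (int i = 0; i < nx; ++i) {
      const std::vector<int> &ids = cols[(size_t)j * nx + i];
      if (ids.empty()) continue;
      double px = origin[0] + (i + 0.5) * spacing[0] + eps;
      zhits.clear();
      for (size_t m = 0; m < ids.size(); ++m) {
        int f = ids[m];
        double a[3], b[3], c[3];
        for (int d = 0; d < 3; ++d) {
          a[d] = V(F(f, 0) - 1, d);
          b[d] = V(F(f, 1) - 1, d);
          c[d] = V(F(f, 2) - 1, d);
        }
        double e1x = b[0] - a[0], e1y = b[1] - a[1];
        double e2x = c[0] - a[0], e2y = c[1] - a[1];
        double det = e1x * e2y - e1y * e2x;
        if (std::fabs(det) < 1e-14) continue;  // vertical triangle: generic ray misses
        double qx = px - a[0], qy = py - a[1];
        double u = (qx * e2y - qy * e2x) / det;
        double v = (e1x * qy - e1y * qx) / det;
        if (u < 0.0 || v < 0.0 || u + v > 1.0) continue;
        zhits.push_back(a[2] + u * (b[2] - a[2]) + v * (c[2] - a[2]));
      }
      if (zhits.size() < 2) continue;
      std::sort(zhits.begin(), zhits.end());
      size_t np = zhits.size() / 2;
      for (size_t m = 0; m < np; ++m) {
        double z0 = zhits[2 * m], z1 = zhits[2 * m + 1];
        int k0 = std::max(0, (int)std::ceil((z0 - origin[2]) / spacing[2] - 0.5));
        int k1 = std::min(nz - 1, (int)std::floor((z1 - origin[2]) / spacing[2] - 0.5));
        for (int k = k0; k <= k1; ++k) {
          double zc = origin[2] + (k + 0.5) * spacing[2];
          if (zc > z0 && zc < z1)
            out[(R_xlen_t)k * nx * ny + (R_xlen_t)j * nx + i] = true;
        }
      }
    }
  }
  return out;
}
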