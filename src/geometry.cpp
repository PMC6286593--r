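// Geometry kernels: nearest-neighbour queries, point-to-mesh distances,
// column-wise ray/mesh intersection (voxelization, height maps),
// moving-least-squares height fields and height-map visibility.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <limits>
using namespace Rcpp;

static inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}

// Closest-point distance^2 from p to triangle (a,b,c), Ericson's region test.
static double triPointDist2(const double* p, const double* a,
                            const double* b, const double* c) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) {
    ab[i] = b[i] - a[i]; ac[i] = c[i] - a[i]; ap[i] = p[i] - a[i];
  }
  double d1 = dot3(ab, ap), d2 = dot3(ac, ap);
  if (d1 <= 0.0 && d2 <= 0.0) return dot3(ap, ap);

  double bp[3];
  for (int i = 0; i < 3; ++i) bp[i] = p[i] - b[i];
  double d3 = dot3(ab, bp), d4 = dot3(ac, bp);
  if (d3 >= 0.0 && d4 <= d3) return dot3(bp, bp);

  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3), q[3];
    for (int i = 0; i < 3; ++i) q[i] = a[i] + v * ab[i] - p[i];
    return dot3(q, q);
  }

  double cp[3];
  for (int i = 0; i < 3; ++i) cp[i] = p[i] - c[i];
  double d5 = dot3(ab, cp), d6 = dot3(ac, cp);
  if (d6 >= 0.0 && d5 <= d6) return dot3(cp, cp);

  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6), q[3];
    for (int i = 0; i < 3; ++i) q[i] = a[i] + w * ac[i] - p[i];
    return dot3(q, q);
  }

  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6)), q[3];
    for (int i = 0; i < 3; ++i) q[i] = b[i] + w * (c[i] - b[i]) - p[i];
    return dot3(q, q);
  }

  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom, q[3];
  for (int i = 0; i < 3; ++i) q[i] = a[i] + ab[i] * v + ac[i] * w - p[i];
  return dot3(q, q);
}

// Uniform 3D grid over triangle AABBs; supports nearest-triangle queries with
// expanding-shell search and an exact termination bound.
struct TriGrid {
  const double* V; const int* F; int nf;
  double lo[3], hi[3], cs[3];
  int nc[3];
  std::vector< std::vector<int> > cells;
  std::vector<int> stamp;
  int stampVal;

  TriGrid(const NumericMatrix& Vm, const IntegerMatrix& Fm,
          std::vector<double>& vbuf, std::vector<int>& fbuf) {
    int nv = Vm.nrow(); nf = Fm.nrow();
    vbuf.resize(3 * nv); fbuf.resize(3 * nf);
    for (int i = 0; i < nv; ++i)
      for (int j = 0; j < 3; ++j) vbuf[3 * i + j] = Vm(i, j);
    for (int i = 0; i < nf; ++i)
      for (int j = 0; j < 3; ++j) fbuf[3 * i + j] = Fm(i, j) - 1; // 1- to 0-based
    V = vbuf.data(); F = fbuf.data();
    for (int j = 0; j < 3; ++j) {
      lo[j] = std::numeric_limits<double>::infinity();
      hi[j] = -std::numeric_limits<double>::infinity();
    }
    for (int i = 0; i < nv; ++i)
      for (int j = 0; j < 3; ++j) {
        lo[j] = std::min(lo[j], vbuf[3 * i + j]);
        hi[j] = std::max(hi[j], vbuf[3 * i + j]);
      }
    int target = std::max(1, (int)std::floor(std::cbrt((double)nf)));
    for (int j = 0; j < 3; ++j) {
      double ext = std::max(hi[j] - lo[j], 1e-9);
      nc[j] = std::min(target, 64);
      cs[j] = ext / nc[j] * (1.0 + 1e-12);
    }
    cells.assign((size_t)nc[0] * nc[1] * nc[2], std::vector<int>());
    for (int t = 0; t < nf; ++t) {
      double tlo[3], thi[3];
      for (int j = 0; j < 3; ++j) {
        tlo[j] = std::numeric_limits<double>::infinity();
        thi[j] = -std::numeric_limits<double>::infinity();
      }
      for (int k = 0; k < 3; ++k) {
        const double* v = V + 3 * F[3 * t + k];
        for (int j = 0; j < 3; ++j) {
          tlo[j] = std::min(tlo[j], v[j]); thi[j] = std::max(thi[j], v[j]);
        }
      }
      int i0[3], i1[3];
      for (int j = 0; j < 3; ++j) {
        i0[j] = std::max(0, std::min(nc[j] - 1, (int)((tlo[j] - lo[j]) / cs[j])));
        i1[j] = std::max(0, std::min(nc[j] - 1, (int)((thi[j] - lo[j]) / cs[j])));
      }
      for (int ix = i0[0]; ix <= i1[0]; ++ix)
        for (int iy = i0[1]; iy <= i1[1]; ++iy)
          for (int iz = i0[2]; iz <= i1[2]; ++iz)
            cells[(size_t)ix + nc[0] * ((size_t)iy + nc[1] * iz)].push_back(t);
    }
    stamp.assign(nf, -1);
    stampVal = 0;
  }

  double nearestDist2(const double p[3]) {
    ++stampVal;
    int c[3];
    for (int j = 0; j < 3; ++j)
      c[j] = std::max(0, std::min(nc[j] - 1, (int)((p[j] - lo[j]) / cs[j])));
    double best = std::numeric_limits<double>::infinity();
    int smax = 0;
    for (int j = 0; j < 3; ++j) smax = std::max(smax, nc[j]);
    for (int s = 0; s <= smax; ++s) {
      int a0[3], a1[3];
      for (int j = 0; j < 3; ++j) {
        a0[j] = std::max(0, c[j] - s); a1[j] = std::min(nc[j] - 1, c[j] + s);
      }
      for (int ix = a0[0]; ix <= a1[0]; ++ix)
        for (int iy = a0[1]; iy <= a1[1]; ++iy)
          for (int iz = a0[2]; iz <= a1[2]; ++iz) {
            // only new shell cells
            if (s > 0 &&
                ix > c[0] - s && ix < c[0] + s &&
                iy > c[1] - s && iy < c[1] + s &&
                iz > c[2] - s && iz < c[2] + s) continue;
            const std::vector<int>& lst =
              cells[(size_t)ix + nc[0] * ((size_t)iy + nc[1] * iz)];
            for (size_t q = 0; q < lst.size(); ++q) {
              int t = lst[q];
              if (stamp[t] == stampVal) continue;
              stamp[t] = stampVal;
              double d2 = triPointDist2(p, V + 3 * F[3 * t], V + 3 * F[3 * t + 1],
                                        V + 3 * F[3 * t + 2]);
              if (d2 < best) best = d2;
            }
          }
      // geometric bound: triangles not yet examined lie outside the block
      double boxlo[3], boxhi[3], dout = std::numeric_limits<double>::infinity();
      bool inside = true;
      for (int j = 0; j < 3; ++j) {
        boxlo[j] = lo[j] + (c[j] - s) * cs[j];
        boxhi[j] = lo[j] + (c[j] + s + 1) * cs[j];
        if (p[j] < boxlo[j] || p[j] > boxhi[j]) inside = false;
        dout = std::min(dout, std::min(p[j] - boxlo[j], boxhi[j] - p[j]));
      }
      if (inside && best <= dout * dout) break;
      if (a0[0] == 0 && a0[1] == 0 && a0[2] == 0 &&
          a1[0] == nc[0] - 1 && a1[1] == nc[1] - 1 && a1[2] == nc[2] - 1) break;
    }
    return best;
  }
};

// [[Rcpp::export]]
NumericVector cpp_point_mesh_dist(NumericMatrix P, NumericMatrix V,
                                  IntegerMatrix F) {
  std::vector<double> vbuf; std::vector<int> fbuf;
  TriGrid grid(V, F, vbuf, fbuf);
  int n = P.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double p[3] = { P(i, 0), P(i, 1), P(i, 2) };
    out[i] = std::sqrt(grid.nearestDist2(p));
  }
  return out;
}

// Brute-force k nearest neighbours (excluding self when self = true).
// [[Rcpp::export]]
List cpp_knn(NumericMatrix X, int k, bool exclude_self) {
  int n = X.nrow();
  IntegerMatrix idx(n, k);
  NumericMatrix dst(n, k);
  std::vector< std::pair<double, int> > d(n);
  for (int i = 0; i < n; ++i) {
    double xi = X(i, 0), yi = X(i, 1), zi = X(i, 2);
    for (int j = 0; j < n; ++j) {
      double dx = X(j, 0) - xi, dy = X(j, 1) - yi, dz = X(j, 2) - zi;
      double dd = dx * dx + dy * dy + dz * dz;
      if (exclude_self && j == i) dd = std::numeric_limits<double>::infinity();
      d[j] = std::make_pair(dd, j);
    }
    std::partial_sort(d.begin(), d.begin() + k, d.end());
    for (int q = 0; q < k; ++q) {
      idx(i, q) = d[q].second + 1;
      dst(i, q) = std::sqrt(d[q].first);
    }
  }
  return List::create(_["idx"] = idx, _["dist"] = dst);
}

// ---- column-wise ray intersection along +z -------------------------------

struct ColumnCaster {
  std::vector<double> vx, vy, vz;
  std::vector<int> fa, fb, fc;
  std::vector<char> sel;
  double lox, loy, hix, hiy, csx, csy;
  int ncx, ncy;
  std::vector< std::vector<int> > bins;
  double jx, jy;   // deterministic jitter unit

  ColumnCaster(const NumericMatrix& V, const IntegerMatrix& F,
               const LogicalVector& faceSel, double jitter_scale) {
    int nv = V.nrow(), nf = F.nrow();
    vx.resize(nv); vy.resize(nv); vz.resize(nv);
    for (int i = 0; i < nv; ++i) { vx[i] = V(i,0); vy[i] = V(i,1); vz[i] = V(i,2); }
    fa.resize(nf); fb.resize(nf); fc.resize(nf); sel.resize(nf);
    for (int i = 0; i < nf; ++i) {
      fa[i] = F(i,0) - 1; fb[i] = F(i,1) - 1; fc[i] = F(i,2) - 1;
      sel[i] = (faceSel.size() == 0) ? 1 : (faceSel[i] ? 1 : 0);
    }
    lox = *std::min_element(vx.begin(), vx.end());
    hix = *std::max_element(vx.begin(), vx.end());
    loy = *std::min_element(vy.begin(), vy.end());
    hiy = *std::max_element(vy.begin(), vy.end());
    int target = std::max(1, (int)std::sqrt((double)nf / 2.0));
    ncx = std::min(target, 512); ncy = std::min(target, 512);
    csx = std::max(hix - lox, 1e-9) / ncx * (1 + 1e-12);
    csy = std::max(hiy - loy, 1e-9) / ncy * (1 + 1e-12);
    bins.assign((size_t)ncx * ncy, std::vector<int>());
    for (int t = 0; t < nf; ++t) {
      if (!sel[t]) continue;
      double x0 = std::min(vx[fa[t]], std::min(vx[fb[t]], vx[fc[t]]));
      double x1 = std::max(vx[fa[t]], std::max(vx[fb[t]], vx[fc[t]]));
      double y0 = std::min(vy[fa[t]], std::min(vy[fb[t]], vy[fc[t]]));
      double y1 = std::max(vy[fa[t]], std::max(vy[fb[t]], vy[fc[t]]));
      int i0 = std::max(0, std::min(ncx - 1, (int)((x0 - lox) / csx)));
      int i1 = std::max(0, std::min(ncx - 1, (int)((x1 - lox) / csx)));
      int j0 = std::max(0, std::min(ncy - 1, (int)((y0 - loy) / csy)));
      int j1 = std::max(0, std::min(ncy - 1, (int)((y1 - loy) / csy)));
      for (int ix = i0; ix <= i1; ++ix)
        for (int iy = j0; iy <= j1; ++iy)
          bins[(size_t)ix + ncx * (size_t)iy].push_back(t);
    }
    jx = jitter_scale; jy = 0.7 * jitter_scale;
  }

  // all z intersections of the vertical line at (x,y); returns false if a
  // degenerate (edge/vertex) hit was found and the caller must jitter
  bool hitsAt(double x, double y, std::vector<double>& out) const {
    out.clear();
    if (x < lox - 1e-9 || x > hix + 1e-9 || y < loy - 1e-9 || y > hiy + 1e-9)
      return true;
    int ix = std::max(0, std::min(ncx - 1, (int)((x - lox) / csx)));
    int iy = std::max(0, std::min(ncy - 1, (int)((y - loy) / csy)));
    const std::vector<int>& lst = bins[(size_t)ix + ncx * (size_t)iy];
    for (size_t q = 0; q < lst.size(); ++q) {
      int t = lst[q];
      double ax = vx[fa[t]], ay = vy[fa[t]], az = vz[fa[t]];
      double bx = vx[fb[t]], by = vy[fb[t]], bz = vz[fb[t]];
      double cx = vx[fc[t]], cy = vy[fc[t]], cz = vz[fc[t]];
      double d = (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
      double scale = std::max({ std::fabs(bx - ax) + std::fabs(by - ay),
                                std::fabs(cx - ax) + std::fabs(cy - ay), 1e-30 });
      if (std::fabs(d) < 1e-14 * scale * scale) continue; // vertical triangle: zero xy area
      double w0 = (bx - x) * (cy - y) - (by - y) * (cx - x);
      double w1 = (cx - x) * (ay - y) - (cy - y) * (ax - x);
      double w2 = (ax - x) * (by - y) - (ay - y) * (bx - x);
      double eps = 1e-12 * std::fabs(d);
      if (d < 0) { w0 = -w0; w1 = -w1; w2 = -w2; d = -d; }
      if (w0 < -eps || w1 < -eps || w2 < -eps) continue;       // outside
      if (w0 < eps || w1 < eps || w2 < eps) return false;      // edge/vertex hit
      out.push_back((w0 * az + w1 * bz + w2 * cz) / d);
    }
    std::sort(out.begin(), out.end());
    return true;
  }

  // jitter until non-degenerate, deterministically nudging towards the mesh
  // interior so rays on the outer boundary are not pushed off the mesh
  // (a clean off-mesh miss would be accepted as "no hits")
  void robustHits(double x, double y, std::vector<double>& out) const {
    double dirx = (x <= 0.5 * (lox + hix)) ? 1.0 : -1.0;
    double diry = (y <= 0.5 * (loy + hiy)) ? 1.0 : -1.0;
    for (int k = 0; k < 96; ++k) {
      if (hitsAt(x + dirx * k * jx, y + diry * k * jy, out)) return;
    }
    Rcpp::stop("ray caster: could not resolve degenerate column hit");
  }
};

// Binary occupancy by z-parity at voxel centers.
// [[Rcpp::export]]
IntegerVector cpp_voxelize(NumericMatrix V, IntegerMatrix F,
                           NumericVector origin, NumericVector spacing,
                           IntegerVector dims) {
  LogicalVector noSel(0);
  ColumnCaster cc(V, F, noSel, 1e-4 * spacing[0]);
  int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector out((R_xlen_t)nx * ny * nz);
  std::vector<double> hits;
  for (int iy = 0; iy < ny; ++iy) {
    double y = origin[1] + iy * spacing[1];
    for (int ix = 0; ix < nx; ++ix) {
      double x = origin[0] + ix * spacing[0];
      cc.robustHits(x, y, hits);
      if (hits.empty()) continue;
      size_t h = 0;
      int nh = (int)hits.size();
      for (int iz = 0; iz < nz; ++iz) {
        double z = origin[2] + iz * spacing[2];
        while (h < hits.size() && hits[h] <= z) ++h;
        // crossings strictly above z: nh - h; odd -> inside
        if (((nh - (int)h) & 1) == 1)
          out[(R_xlen_t)ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz)] = 1;
      }
    }
  }
  return out;
}

// Highest z intersection of vertical lines through (xs, ys) with (a subset of)
// the mesh faces. Returns NaN where the line misses.
// [[Rcpp::export]]
List cpp_mesh_z_at(NumericMatrix V, IntegerMatrix F,
                   NumericVector xs, NumericVector ys,
                   LogicalVector faceSel, double jitter) {
  ColumnCaster cc(V, F, faceSel, jitter);
  int n = xs.size();
  NumericVector zmax(n), zmin(n);
  IntegerVector nhit(n);
  std::vector<double> hits;
  for (int i = 0; i < n; ++i) {
    cc.robustHits(xs[i], ys[i], hits);
    nhit[i] = (int)hits.size();
    if (hits.empty()) {
      zmax[i] = NA_REAL; zmin[i] = NA_REAL;
    } else {
      zmin[i] = hits.front(); zmax[i] = hits.back();
    }
  }
  return List::create(_["zmax"] = zmax, _["zmin"] = zmin, _["n"] = nhit);
}

// ---- moving-least-squares height field -----------------------------------

// [[Rcpp::export]]
List cpp_mls_heightfield(NumericVector px, NumericVector py, NumericVector ph,
                         double x0, double y0, double dx, int nx, int ny,
                         double radius, double tau) {
  int np = px.size();
  double cell = radius;
  double lox = x0 - dx, loy = y0 - dx;
  int bnx = std::max(1, (int)std::ceil((nx * dx + 2 * dx) / cell));
  int bny = std::max(1, (int)std::ceil((ny * dx + 2 * dx) / cell));
  std::vector< std::vector<int> > bins((size_t)bnx * bny);
  for (int i = 0; i < np; ++i) {
    int bx = (int)((px[i] - lox) / cell), by = (int)((py[i] - loy) / cell);
    if (bx < 0 || bx >= bnx || by < 0 || by >= bny) continue;
    bins[(size_t)bx + bnx * (size_t)by].push_back(i);
  }
  NumericMatrix z(nx, ny);
  IntegerMatrix cnt(nx, ny);
  double r2 = radius * radius, inv2t2 = 1.0 / (2.0 * tau * tau);
  for (int iy = 0; iy < ny; ++iy) {
    double gy = y0 + iy * dx;
    for (int ix = 0; ix < nx; ++ix) {
      double gx = x0 + ix * dx;
      int bx = (int)((gx - lox) / cell), by = (int)((gy - loy) / cell);
      double sw = 0.0, swz = 0.0;
      int n = 0;
      for (int ox = -1; ox <= 1; ++ox)
        for (int oy = -1; oy <= 1; ++oy) {
          int cx = bx + ox, cy = by + oy;
          if (cx < 0 || cx >= bnx || cy < 0 || cy >= bny) continue;
          const std::vector<int>& lst = bins[(size_t)cx + bnx * (size_t)cy];
          for (size_t q = 0; q < lst.size(); ++q) {
            int i = lst[q];
            double ddx = px[i] - gx, ddy = py[i] - gy;
            double d2 = ddx * ddx + ddy * ddy;
            if (d2 > r2) continue;
            double w = std::exp(-d2 * inv2t2);
            sw += w; swz += w * ph[i]; ++n;
          }
        }
      if (n == 0) { z(ix, iy) = NA_REAL; cnt(ix, iy) = 0; }
      else { z(ix, iy) = swz / sw; cnt(ix, iy) = n; }
    }
  }
  return List::create(_["z"] = z, _["n"] = cnt);
}

// ---- visibility on a height map ------------------------------------------

static inline double bilinH(const double* H, int nx, int ny,
                            double x0, double y0, double dx, double dy,
                            double x, double y) {
  double fx = (x - x0) / dx, fy = (y - y0) / dy;
  if (fx < 0 || fy < 0 || fx > nx - 1 || fy > ny - 1)
    return -std::numeric_limits<double>::infinity();
  int ix = std::min((int)fx, nx - 2), iy = std::min((int)fy, ny - 2);
  if (nx == 1 || ny == 1) return H[0];
  double tx = fx - ix, ty = fy - iy;
  double h00 = H[ix + nx * iy], h10 = H[ix + 1 + nx * iy];
  double h01 = H[ix + nx * (iy + 1)], h11 = H[ix + 1 + nx * (iy + 1)];
  return (1 - tx) * (1 - ty) * h00 + tx * (1 - ty) * h10 +
         (1 - tx) * ty * h01 + tx * ty * h11;
}

// [[Rcpp::export]]
LogicalVector cpp_visible_from(NumericMatrix H, double x0, double y0,
                               double dx, double dy,
                               NumericVector px, NumericVector py,
                               NumericVector pz, NumericVector vp,
                               double step, double eps) {
  int n = px.size(), nx = H.nrow(), ny = H.ncol();
  const double* Hp = H.begin();
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) {
    double rx = vp[0] - px[i], ry = vp[1] - py[i], rz = vp[2] - pz[i];
    double L = std::sqrt(rx * rx + ry * ry + rz * rz);
    bool vis = true;
    if (L > step) {
      double ux = rx / L, uy = ry / L, uz = rz / L;
      for (double t = step; t < L - 0.5 * step; t += step) {
        double sx = px[i] + t * ux, sy = py[i] + t * uy, sz = pz[i] + t * uz;
        double h = bilinH(Hp, nx, ny, x0, y0, dx, dy, sx, sy);
        if (h > sz + eps) { vis = false; break; }
      }
    }
    out[i] = vis;
  }
  return out;
}
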