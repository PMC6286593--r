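// Broad-beam electron dose kernel: radiological depth by ray marching with
// trilinear density sampling, flat-field lateral profile with Gaussian
// penumbra and low-level scatter tail, depth dose by table lookup, and an
// air-gap inverse-square factor relative to the calibration geometry.
#include <Rcpp.h>
#include <cmath>
#include <limits>
#include <algorithm>
using namespace Rcpp;

// trilinear sample, voxel-center convention; outside [-0.5, n-0.5] -> fill
static double trilin(const double* v, int nx, int ny, int nz,
                     const double* o, const double* s,
                     double x, double y, double z, double fill) {
  double fx = (x - o[0]) / s[0], fy = (y - o[1]) / s[1], fz = (z - o[2]) / s[2];
  if (fx < -0.5 || fy < -0.5 || fz < -0.5 ||
      fx > nx - 0.5 || fy > ny - 0.5 || fz > nz - 0.5) return fill;
  fx = std::min(std::max(fx, 0.0), nx - 1.0);
  fy = std::min(std::max(fy, 0.0), ny - 1.0);
  fz = std::min(std::max(fz, 0.0), nz - 1.0);
  int ix = std::min((int)fx, std::max(nx - 2, 0));
  int iy = std::min((int)fy, std::max(ny - 2, 0));
  int iz = std::min((int)fz, std::max(nz - 2, 0));
  double tx = fx - ix, ty = fy - iy, tz = fz - iz;
  int sx = (nx > 1) ? 1 : 0, sy = (ny > 1) ? nx : 0, sz2 = (nz > 1) ? nx * ny : 0;
  const double* b = v + ix + (R_xlen_t)nx * iy + (R_xlen_t)nx * ny * iz;
  double c00 = b[0] * (1 - tx) + b[sx] * tx;
  double c10 = b[sy] * (1 - tx) + b[sy + sx] * tx;
  double c01 = b[sz2] * (1 - tx) + b[sz2 + sx] * tx;
  double c11 = b[sy + sz2] * (1 - tx) + b[sy + sz2 + sx] * tx;
  double c0 = c00 * (1 - ty) + c10 * ty;
  double c1 = c01 * (1 - ty) + c11 * ty;
  return c0 * (1 - tz) + c1 * tz;
}

struct Marcher {
  const double* dens; int nx, ny, nz;
  const double* o; const double* s;
  double step, tissue_thresh;

  // march from `entry` to `entry + L*a`, accumulating water-equivalent depth
  // and tissue (non-air) path length
  void march(const double* entry, const double* a, double L,
             double& rad, double& tissue) const {
    rad = 0.0; tissue = 0.0;
    if (L <= 0) return;
    int n = (int)std::floor(L / step);
    double rem = L - n * step;
    for (int i = 0; i < n; ++i) {
      double t = (i + 0.5) * step;
      double d = trilin(dens, nx, ny, nz, o, s,
                        entry[0] + t * a[0], entry[1] + t * a[1],
                        entry[2] + t * a[2], 0.0);
      rad += d * step;
      if (d > tissue_thresh) tissue += step;
    }
    if (rem > 1e-12) {
      double t = n * step + 0.5 * rem;
      double d = trilin(dens, nx, ny, nz, o, s,
                        entry[0] + t * a[0], entry[1] + t * a[1],
                        entry[2] + t * a[2], 0.0);
      rad += d * rem;
      if (d > tissue_thresh) tissue += rem;
    }
  }
};

static inline double pddLookup(const double* tab, int ntab, double x0,
                               double dx, double d) {
  double f = (d - x0) / dx;
  if (f <= 0) return tab[0];
  if (f >= ntab - 1) return tab[ntab - 1];
  int i = (int)f;
  double t = f - i;
  return tab[i] * (1 - t) + tab[i + 1] * t;
}

// [[Rcpp::export]]
NumericVector cpp_dose(NumericVector dens, IntegerVector ddims,
                       NumericVector dorigin, NumericVector dspacing,
                       NumericVector gorigin, NumericVector gspacing,
                       IntegerVector gdims,
                       NumericVector e, NumericVector a, NumericVector npl,
                       double r_app, double ssd,
                       double pdd_x0, double pdd_dx, NumericVector pdd,
                       double sigma_pen, double scat_amp, double scat_sigma,
                       double lat_cut, double step, double tissue_thresh) {
  Marcher m;
  m.dens = dens.begin();
  m.nx = ddims[0]; m.ny = ddims[1]; m.nz = ddims[2];
  m.o = dorigin.begin(); m.s = dspacing.begin();
  m.step = step; m.tissue_thresh = tissue_thresh;

  int nx = gdims[0], ny = gdims[1], nz = gdims[2];
  NumericVector out((R_xlen_t)nx * ny * nz);
  double src[3];
  for (int j = 0; j < 3; ++j) src[j] = e[j] - ssd * a[j];
  double an = a[0] * npl[0] + a[1] * npl[1] + a[2] * npl[2];
  if (std::fabs(an) < 1e-9)
    stop("beam axis is parallel to the applicator end plane");

  const double* tab = pdd.begin();
  int ntab = pdd.size();
  R_xlen_t q = 0;
  for (int iz = 0; iz < nz; ++iz) {
    double z = gorigin[2] + iz * gspacing[2];
    for (int iy = 0; iy < ny; ++iy) {
      double y = gorigin[1] + iy * gspacing[1];
      for (int ix = 0; ix < nx; ++ix, ++q) {
        double x = gorigin[0] + ix * gspacing[0];
        double w[3] = { x - src[0], y - src[1], z - src[2] };
        double dsrc = w[0] * a[0] + w[1] * a[1] + w[2] * a[2];
        if (dsrc < 1e-6) { out[q] = 0.0; continue; }
        double l0 = w[0] - dsrc * a[0], l1 = w[1] - dsrc * a[1],
               l2 = w[2] - dsrc * a[2];
        double lat = std::sqrt(l0 * l0 + l1 * l1 + l2 * l2) * (ssd / dsrc);
        double delta = lat - r_app;
        if (delta > lat_cut) { out[q] = 0.0; continue; }
        double prof = 1.0;
        if (delta > 0) {
          double g1 = std::exp(-0.5 * (delta / sigma_pen) * (delta / sigma_pen));
          double g2 = scat_amp *
            std::exp(-0.5 * (delta / scat_sigma) * (delta / scat_sigma));
          prof = std::max(g1, g2);
        }
        double p[3] = { x, y, z };
        double pe[3] = { p[0] - e[0], p[1] - e[1], p[2] - e[2] };
        double u = (pe[0] * npl[0] + pe[1] * npl[1] + pe[2] * npl[2]) / an;
        double rad = 0.0, tissue = 0.0;
        if (u > 0) {
          double entry[3] = { p[0] - u * a[0], p[1] - u * a[1], p[2] - u * a[2] };
          m.march(entry, a.begin(), u, rad, tissue);
        } else {
          u = 0.0;
        }
        double isf = (ssd + tissue) / (ssd + u);
        out[q] = 100.0 * pddLookup(tab, ntab, pdd_x0, pdd_dx, rad) *
                 prof * isf * isf;
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_raddepth(NumericVector dens, IntegerVector ddims,
                           NumericVector dorigin, NumericVector dspacing,
                           NumericVector e, NumericVector a, NumericVector npl,
                           NumericVector p, double step, double tissue_thresh) {
  Marcher m;
  m.dens = dens.begin();
  m.nx = ddims[0]; m.ny = ddims[1]; m.nz = ddims[2];
  m.o = dorigin.begin(); m.s = dspacing.begin();
  m.step = step; m.tissue_thresh = tissue_thresh;
  double an = a[0] * npl[0] + a[1] * npl[1] + a[2] * npl[2];
  if (std::fabs(an) < 1e-9)
    stop("beam axis is parallel to the applicator end plane");
  double pe[3] = { p[0] - e[0], p[1] - e[1], p[2] - e[2] };
  double u = (pe[0] * npl[0] + pe[1] * npl[1] + pe[2] * npl[2]) / an;
  double rad = 0.0, tissue = 0.0;
  if (u > 0) {
    double entry[3] = { p[0] - u * a[0], p[1] - u * a[1], p[2] - u * a[2] };
    m.march(entry, a.begin(), u, rad, tissue);
  }
  return NumericVector::create(rad, tissue, std::max(u, 0.0));
}

// [[Rcpp::export]]
NumericVector cpp_resample(NumericVector v, IntegerVector dims,
                           NumericVector origin, NumericVector spacing,
                           NumericVector torigin, NumericVector tspacing,
                           IntegerVector tdims, int mode, double fill) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int tx = tdims[0], ty = tdims[1], tz = tdims[2];
  NumericVector out((R_xlen_t)tx * ty * tz);
  const double* vp = v.begin();
  R_xlen_t q = 0;
  for (int iz = 0; iz < tz; ++iz) {
    double z = torigin[2] + iz * tspacing[2];
    for (int iy = 0; iy < ty; ++iy) {
      double y = torigin[1] + iy * tspacing[1];
      for (int ix = 0; ix < tx; ++ix, ++q) {
        double x = torigin[0] + ix * tspacing[0];
        if (mode == 0) {
          out[q] = trilin(vp, nx, ny, nz, origin.begin(), spacing.begin(),
                          x, y, z, fill);
        } else {
          double fx = (x - origin[0]) / spacing[0];
          double fy = (y - origin[1]) / spacing[1];
          double fz = (z - origin[2]) / spacing[2];
          int jx = (int)std::floor(fx + 0.5), jy = (int)std::floor(fy + 0.5),
              jz = (int)std::floor(fz + 0.5);
          if (jx < 0 || jy < 0 || jz < 0 || jx >= nx || jy >= ny || jz >= nz)
            out[q] = fill;
          else
            out[q] = vp[jx + (R_xlen_t)nx * jy + (R_xlen_t)nx * ny * jz];
        }
      }
    }
  }
  return out;
}

// gamma index; offsets are candidate displacements (mm) with squared radii.
// When sorted_break is true, `offs` must be sorted by increasing radius and
// the search stops once the distance term alone exceeds the current best.
// [[Rcpp::export]]
NumericVector cpp_gamma(NumericVector refv, IntegerVector rdims,
                        NumericVector rorigin, NumericVector rspacing,
                        NumericVector evalv, IntegerVector edims,
                        NumericVector eorigin, NumericVector espacing,
                        IntegerVector evalIdx, NumericMatrix offs,
                        NumericVector offr2, double dd_abs, double dta,
                        bool sorted_break) {
  int nx = rdims[0], ny = rdims[1];
  int noff = offs.nrow();
  int nq = evalIdx.size();
  NumericVector out(nq);
  double dta2 = dta * dta, dd2 = dd_abs * dd_abs;
  const double* ev = evalv.begin();
  for (int i = 0; i < nq; ++i) {
    R_xlen_t idx = evalIdx[i];
    int ix = (int)(idx % nx);
    int iy = (int)((idx / nx) % ny);
    int iz = (int)(idx / ((R_xlen_t)nx * ny));
    double x = rorigin[0] + ix * rspacing[0];
    double y = rorigin[1] + iy * rspacing[1];
    double z = rorigin[2] + iz * rspacing[2];
    double Dr = refv[idx];
    double best = std::numeric_limits<double>::infinity();
    bool any = false;
    for (int k = 0; k < noff; ++k) {
      double r2 = offr2[k];
      if (sorted_break && any && r2 / dta2 >= best) break;
      double De = trilin(ev, edims[0], edims[1], edims[2],
                         eorigin.begin(), espacing.begin(),
                         x + offs(k, 0), y + offs(k, 1), z + offs(k, 2),
                         NA_REAL);
      if (ISNAN(De)) continue;
      double dd = De - Dr;
      double g2 = dd * dd / dd2 + r2 / dta2;
      if (g2 < best) { best = g2; any = true; }
    }
    out[i] = any ? std::sqrt(best) : NA_REAL;
  }
  return out;
}
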