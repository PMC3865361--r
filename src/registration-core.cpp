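// Inner loop of featurelet registration: metric evaluation of a moving patch
// against the fixed image sampled at (sub)voxel translations, exhaustive
// integer-translation scan over the search region, and regular-step
// gradient-descent subvoxel refinement.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// trilinear clamp-to-edge sample at 0-based continuous coordinates
static double sample3(const double* f, int nx, int ny, int nz,
                      double x, double y, double z) {
  x = clampd(x, 0.0, nx - 1.0);
  y = clampd(y, 0.0, ny - 1.0);
  z = clampd(z, 0.0, nz - 1.0);
  int x0 = (int)std::floor(x); if (x0 > nx - 2) x0 = nx - 2; if (x0 < 0) x0 = 0;
  int y0 = (int)std::floor(y); if (y0 > ny - 2) y0 = ny - 2; if (y0 < 0) y0 = 0;
  int z0 = (int)std::floor(z); if (z0 > nz - 2) z0 = nz - 2; if (z0 < 0) z0 = 0;
  int x1 = x0 + 1; if (x1 > nx - 1) x1 = nx - 1;
  int y1 = y0 + 1; if (y1 > ny - 1) y1 = ny - 1;
  int z1 = z0 + 1; if (z1 > nz - 1) z1 = nz - 1;
  double wx = clampd(x - x0, 0.0, 1.0);
  double wy = clampd(y - y0, 0.0, 1.0);
  double wz = clampd(z - z0, 0.0, 1.0);
  const size_t sxy = (size_t)nx * ny;
  #define F(i, j, k) f[(size_t)(i) + (size_t)nx * (j) + sxy * (k)]
  double c00 = F(x0, y0, z0) * (1 - wx) + F(x1, y0, z0) * wx;
  double c10 = F(x0, y1, z0) * (1 - wx) + F(x1, y1, z0) * wx;
  double c01 = F(x0, y0, z1) * (1 - wx) + F(x1, y0, z1) * wx;
  double c11 = F(x0, y1, z1) * (1 - wx) + F(x1, y1, z1) * wx;
  #undef F
  double c0 = c00 * (1 - wy) + c10 * wy;
  double c1 = c01 * (1 - wy) + c11 * wy;
  return c0 * (1 - wz) + c1 * wz;
}

struct MetricCtx {
  const double* fixed;
  int nx, ny, nz;
  const double* patch;
  int px, py, pz;
  int bx, by, bz;           // 0-based moving-box low corner (shared grid)
  int metric;               // 0 = NC, 1 = MI
  int bins;
  std::vector<double> buf;  // sampled fixed values
  std::vector<int> ja, jb, jab;
};

// fill ctx.buf with fixed image sampled at box + tau (trilinear, clamp)
static void sample_patch(MetricCtx& c, double tx, double ty, double tz) {
  size_t m = 0;
  bool integral = (tx == std::floor(tx) && ty == std::floor(ty) && tz == std::floor(tz));
  if (integral) {
    int ox = c.bx + (int)tx, oy = c.by + (int)ty, oz = c.bz + (int)tz;
    // in-bounds fast path; fall back to clamped sampling otherwise
    if (ox >= 0 && oy >= 0 && oz >= 0 && ox + c.px <= c.nx &&
        oy + c.py <= c.ny && oz + c.pz <= c.nz) {
      const size_t sxy = (size_t)c.nx * c.ny;
      for (int k = 0; k < c.pz; ++k)
        for (int j = 0; j < c.py; ++j) {
          const double* row = c.fixed + (size_t)(ox) + (size_t)c.nx * (oy + j) + sxy * (oz + k);
          for (int i = 0; i < c.px; ++i) c.buf[m++] = row[i];
        }
      return;
    }
  }
  // constant-fractional-offset fast path: the whole patch shares one set of
  // trilinear corner weights, so precompute them and walk row pointers
  double fx = std::floor(tx), fy = std::floor(ty), fz = std::floor(tz);
  int x0 = c.bx + (int)fx, y0 = c.by + (int)fy, z0 = c.bz + (int)fz;
  if (x0 >= 0 && y0 >= 0 && z0 >= 0 && x0 + c.px + 1 <= c.nx &&
      y0 + c.py + 1 <= c.ny && z0 + c.pz + 1 <= c.nz) {
    double wx = tx - fx, wy = ty - fy, wz = tz - fz;
    double w000 = (1 - wx) * (1 - wy) * (1 - wz), w100 = wx * (1 - wy) * (1 - wz);
    double w010 = (1 - wx) * wy * (1 - wz),       w110 = wx * wy * (1 - wz);
    double w001 = (1 - wx) * (1 - wy) * wz,       w101 = wx * (1 - wy) * wz;
    double w011 = (1 - wx) * wy * wz,             w111 = wx * wy * wz;
    const size_t sxy = (size_t)c.nx * c.ny;
    for (int k = 0; k < c.pz; ++k)
      for (int j = 0; j < c.py; ++j) {
        const double* p00 = c.fixed + (size_t)x0 + (size_t)c.nx * (y0 + j) + sxy * (z0 + k);
        const double* p10 = p00 + c.nx;
        const double* p01 = p00 + sxy;
        const double* p11 = p01 + c.nx;
        for (int i = 0; i < c.px; ++i)
          c.buf[m++] = w000 * p00[i] + w100 * p00[i + 1] +
                       w010 * p10[i] + w110 * p10[i + 1] +
                       w001 * p01[i] + w101 * p01[i + 1] +
                       w011 * p11[i] + w111 * p11[i + 1];
      }
    return;
  }
  for (int k = 0; k < c.pz; ++k)
    for (int j = 0; j < c.py; ++j)
      for (int i = 0; i < c.px; ++i)
        c.buf[m++] = sample3(c.fixed, c.nx, c.ny, c.nz,
                             c.bx + i + tx, c.by + j + ty, c.bz + k + tz);
}

static double eval_nc(const MetricCtx& c) {
  const size_t n = c.buf.size();
  double sa = 0, sb = 0;
  for (size_t i = 0; i < n; ++i) { sa += c.patch[i]; sb += c.buf[i]; }
  double ma = sa / n, mb = sb / n;
  double saa = 0, sbb = 0, sab = 0;
  for (size_t i = 0; i < n; ++i) {
    double da = c.patch[i] - ma, db = c.buf[i] - mb;
    saa += da * da; sbb += db * db; sab += da * db;
  }
  if (saa <= 0.0 || sbb <= 0.0) return 0.0;
  return sab / std::sqrt(saa * sbb);
}

static double eval_mi(MetricCtx& c) {
  const size_t n = c.buf.size();
  const int B = c.bins;
  double alo = c.patch[0], ahi = c.patch[0], blo = c.buf[0], bhi = c.buf[0];
  for (size_t i = 1; i < n; ++i) {
    if (c.patch[i] < alo) alo = c.patch[i];
    if (c.patch[i] > ahi) ahi = c.patch[i];
    if (c.buf[i] < blo) blo = c.buf[i];
    if (c.buf[i] > bhi) bhi = c.buf[i];
  }
  std::fill(c.ja.begin(), c.ja.end(), 0);
  std::fill(c.jb.begin(), c.jb.end(), 0);
  std::fill(c.jab.begin(), c.jab.end(), 0);
  double ra = ahi - alo, rb = bhi - blo;
  for (size_t i = 0; i < n; ++i) {
    int ia = (ra > 0) ? (int)((c.patch[i] - alo) / ra * B) : 0;
    int ib = (rb > 0) ? (int)((c.buf[i] - blo) / rb * B) : 0;
    if (ia >= B) ia = B - 1;
    if (ib >= B) ib = B - 1;
    c.ja[ia]++; c.jb[ib]++; c.jab[ia + B * ib]++;
  }
  double ha = 0, hb = 0, hab = 0;
  for (int i = 0; i < B; ++i) {
    if (c.ja[i]) { double p = (double)c.ja[i] / n; ha -= p * std::log(p); }
    if (c.jb[i]) { double p = (double)c.jb[i] / n; hb -= p * std::log(p); }
  }
  for (int i = 0; i < B * B; ++i)
    if (c.jab[i]) { double p = (double)c.jab[i] / n; hab -= p * std::log(p); }
  double mi = ha + hb - hab;
  return mi > 0 ? mi : 0.0;
}

static double metric_at(MetricCtx& c, double tx, double ty, double tz) {
  sample_patch(c, tx, ty, tz);
  return (c.metric == 0) ? eval_nc(c) : eval_mi(c);
}

static MetricCtx make_ctx(NumericVector fixed, IntegerVector fdim,
                          NumericVector patch, IntegerVector pdim,
                          IntegerVector box_lo, int metric, int bins) {
  MetricCtx c;
  c.fixed = REAL(fixed);
  c.nx = fdim[0]; c.ny = fdim[1]; c.nz = fdim[2];
  c.patch = REAL(patch);
  c.px = pdim[0]; c.py = pdim[1]; c.pz = pdim[2];
  c.bx = box_lo[0]; c.by = box_lo[1]; c.bz = box_lo[2];
  c.metric = metric; c.bins = bins;
  c.buf.resize((size_t)c.px * c.py * c.pz);
  c.ja.resize(bins); c.jb.resize(bins); c.jab.resize((size_t)bins * bins);
  return c;
}

// [[Rcpp::export]]
double fl_metric_cpp(NumericVector fixed, IntegerVector fdim,
                     NumericVector patch, IntegerVector pdim,
                     IntegerVector box_lo, NumericVector tau,
                     int metric, int bins) {
  MetricCtx c = make_ctx(fixed, fdim, patch, pdim, box_lo, metric, bins);
  return metric_at(c, tau[0], tau[1], tau[2]);
}

// [[Rcpp::export]]
List fl_register_cpp(NumericVector fixed, IntegerVector fdim,
                     NumericVector patch, IntegerVector pdim,
                     IntegerVector box_lo,
                     NumericVector tau_lo, NumericVector tau_hi,
                     int metric, int bins,
                     double max_step, double min_step, int max_iter,
                     double relax, double probe, bool global_init) {
  MetricCtx c = make_ctx(fixed, fdim, patch, pdim, box_lo, metric, bins);
  double tlo[3] = { tau_lo[0], tau_lo[1], tau_lo[2] };
  double thi[3] = { tau_hi[0], tau_hi[1], tau_hi[2] };
  double tau[3] = { clampd(0.0, tlo[0], thi[0]),
                    clampd(0.0, tlo[1], thi[1]),
                    clampd(0.0, tlo[2], thi[2]) };
  double scan_best = R_NegInf;
  double scan_tau[3] = { tau[0], tau[1], tau[2] };

  if (global_init) {
    for (int tz = (int)std::ceil(tlo[2]); tz <= (int)std::floor(thi[2]); ++tz)
      for (int ty = (int)std::ceil(tlo[1]); ty <= (int)std::floor(thi[1]); ++ty)
        for (int tx = (int)std::ceil(tlo[0]); tx <= (int)std::floor(thi[0]); ++tx) {
          double m = metric_at(c, tx, ty, tz);
          if (m > scan_best) {
            scan_best = m;
            scan_tau[0] = tx; scan_tau[1] = ty; scan_tau[2] = tz;
          }
        }
    if (R_finite(scan_best)) {
      tau[0] = scan_tau[0]; tau[1] = scan_tau[1]; tau[2] = scan_tau[2];
    }
  }

  double best = metric_at(c, tau[0], tau[1], tau[2]);
  double best_tau[3] = { tau[0], tau[1], tau[2] };
  double step = max_step;
  double gprev[3] = { 0, 0, 0 };
  bool have_prev = false, converged = false;
  int iter = 0;

  while (iter < max_iter) {
    ++iter;
    double g[3];
    for (int a = 0; a < 3; ++a) {
      double tp[3] = { tau[0], tau[1], tau[2] };
      double tm[3] = { tau[0], tau[1], tau[2] };
      tp[a] = clampd(tau[a] + probe, tlo[a], thi[a]);
      tm[a] = clampd(tau[a] - probe, tlo[a], thi[a]);
      double denom = tp[a] - tm[a];
      g[a] = (denom > 0)
        ? (metric_at(c, tp[0], tp[1], tp[2]) - metric_at(c, tm[0], tm[1], tm[2])) / denom
        : 0.0;
    }
    double gn = std::sqrt(g[0] * g[0] + g[1] * g[1] + g[2] * g[2]);
    if (gn < 1e-12) { converged = true; break; }
    if (have_prev &&
        g[0] * gprev[0] + g[1] * gprev[1] + g[2] * gprev[2] < 0.0)
      step *= relax;
    if (step < min_step) { converged = true; break; }
    double moved = 0.0;
    for (int a = 0; a < 3; ++a) {
      double nt = clampd(tau[a] + step * g[a] / gn, tlo[a], thi[a]);
      moved += std::fabs(nt - tau[a]);
      tau[a] = nt;
    }
    if (moved == 0.0) {
      // every component clamped at the feasible boundary: the step cannot
      // make progress, so relax it as if the gradient had reversed
      step *= relax;
      continue;
    }
    double m = metric_at(c, tau[0], tau[1], tau[2]);
    if (m > best) {
      best = m;
      best_tau[0] = tau[0]; best_tau[1] = tau[1]; best_tau[2] = tau[2];
    }
    gprev[0] = g[0]; gprev[1] = g[1]; gprev[2] = g[2];
    have_prev = true;
  }

  return List::create(
    _["displacement"] = NumericVector::create(best_tau[0], best_tau[1], best_tau[2]),
    _["merit"] = best,
    _["converged"] = converged,
    _["iterations"] = iter,
    _["scan_merit"] = global_init ? scan_best : NA_REAL,
    _["scan_displacement"] = NumericVector::create(scan_tau[0], scan_tau[1], scan_tau[2]));
}
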