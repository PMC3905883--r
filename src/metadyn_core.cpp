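// Hot loops of the metadynamics engine: BAOAB Langevin stepping on a
// tabulated potential gradient with on-the-fly Gaussian hill deposition on
// a bias grid, and exact (untruncated) summation of Gaussian hills onto a
// rectangular free-energy grid.
//
// Units: nm / dimensionless CVs, kJ/mol, ps, amu.  RNG comes from R's
// generator, so set.seed() in R makes runs bit-reproducible.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double KB = 0.008314463; // kJ/(mol K)

// Linear interpolation helpers on a uniform grid -------------------------

struct Axis {
  double lo, hi, step;
  int n;
};

static inline void locate(const Axis &ax, double x, int &i0, double &w) {
  double t = (x - ax.lo) / ax.step;
  i0 = (int)std::floor(t);
  if (i0 < 0) { i0 = 0; w = 0.0; return; }
  if (i0 >= ax.n - 1) { i0 = ax.n - 2; w = 1.0; return; }
  w = t - i0;
}

// [[Rcpp::export(name = ".metadyn_core")]]
List metadyn_core(NumericVector xmin, NumericVector xmax,
                  IntegerVector ngrid, NumericMatrix ugrad,
                  NumericVector x0, NumericVector mass, double dt, double friction,
                  double temperature, int n_steps, int pace_steps,
                  int record_stride, double w0, NumericVector widths,
                  bool well_tempered, double bias_factor,
                  double hill_cutoff_sigmas) {
  const int d = xmin.size();
  if (d < 1 || d > 2) stop("only 1 or 2 collective variables supported");

  Axis ax[2];
  long ntot = 1;
  for (int k = 0; k < d; ++k) {
    ax[k].lo = xmin[k]; ax[k].hi = xmax[k]; ax[k].n = ngrid[k];
    ax[k].step = (xmax[k] - xmin[k]) / (ngrid[k] - 1);
    ntot *= ngrid[k];
  }
  if (ugrad.nrow() != ntot || ugrad.ncol() != d)
    stop("gradient table has wrong dimensions");

  // bias value and gradient tables
  std::vector<double> vb(ntot, 0.0);
  std::vector<std::vector<double>> gb(d, std::vector<double>(ntot, 0.0));

  const int nx = ax[0].n;

  // interpolate a table at x (linear / bilinear)
  auto interp = [&](const double *tab, const double *x) -> double {
    int i0; double wx;
    locate(ax[0], x[0], i0, wx);
    if (d == 1)
      return tab[i0] * (1 - wx) + tab[i0 + 1] * wx;
    int j0; double wy;
    locate(ax[1], x[1], j0, wy);
    const double *c0 = tab + (long)j0 * nx, *c1 = tab + (long)(j0 + 1) * nx;
    double a = c0[i0] * (1 - wx) + c0[i0 + 1] * wx;
    double b = c1[i0] * (1 - wx) + c1[i0 + 1] * wx;
    return a * (1 - wy) + b * wy;
  };

  // deposit one Gaussian hill on the bias tables (truncated window)
  auto deposit = [&](const double *c, double h) {
    int lo[2] = {0, 0}, hi[2] = {0, 0};
    for (int k = 0; k < d; ++k) {
      double r = hill_cutoff_sigmas * widths[k];
      lo[k] = std::max(0, (int)std::floor((c[k] - r - ax[k].lo) / ax[k].step));
      hi[k] = std::min(ax[k].n - 1,
                       (int)std::ceil((c[k] + r - ax[k].lo) / ax[k].step));
    }
    if (d == 1) {
      for (int i = lo[0]; i <= hi[0]; ++i) {
        double dx = (ax[0].lo + i * ax[0].step - c[0]) / widths[0];
        double e = h * std::exp(-0.5 * dx * dx);
        vb[i] += e;
        gb[0][i] += -dx / widths[0] * e;
      }
    } else {
      std::vector<double> ex(hi[0] - lo[0] + 1), dxs(hi[0] - lo[0] + 1);
      for (int i = lo[0]; i <= hi[0]; ++i) {
        double dx = (ax[0].lo + i * ax[0].step - c[0]) / widths[0];
        dxs[i - lo[0]] = dx;
        ex[i - lo[0]] = std::exp(-0.5 * dx * dx);
      }
      for (int j = lo[1]; j <= hi[1]; ++j) {
        double dy = (ax[1].lo + j * ax[1].step - c[1]) / widths[1];
        double ey = h * std::exp(-0.5 * dy * dy);
        long off = (long)j * nx;
        for (int i = lo[0]; i <= hi[0]; ++i) {
          double e = ey * ex[i - lo[0]];
          vb[off + i] += e;
          gb[0][off + i] += -dxs[i - lo[0]] / widths[0] * e;
          gb[1][off + i] += -dy / widths[1] * e;
        }
      }
    }
  };

  std::vector<const double *> ucol(d);
  for (int k = 0; k < d; ++k) ucol[k] = &ugrad(0, k);

  auto force = [&](const double *x, double *f) {
    for (int k = 0; k < d; ++k)
      f[k] = -interp(ucol[k], x) - interp(gb[k].data(), x);
  };

  // BAOAB constants (per-CV masses allow per-CV relaxation timescales)
  const double c1 = std::exp(-friction * dt);
  double c2[2] = {0, 0};
  for (int k = 0; k < d; ++k)
    c2[k] = std::sqrt(KB * temperature * (1.0 - c1 * c1) / mass[k]);

  double x[2] = {0, 0}, v[2] = {0, 0}, f[2] = {0, 0};
  for (int k = 0; k < d; ++k) x[k] = x0[k];
  force(x, f);

  const int n_hills = n_steps / pace_steps;
  const int n_rec = n_steps / record_stride;
  NumericMatrix hills(n_hills, 2 * d + 3); // time, centers, sigmas, h, biasf
  NumericMatrix colvar(n_rec, d + 1);
  int ih = 0, ir = 0;

  auto reflect = [&](int k) {
    // reflecting walls at the domain boundary
    for (int guard = 0; guard < 64; ++guard) {
      if (x[k] < ax[k].lo) { x[k] = 2 * ax[k].lo - x[k]; v[k] = -v[k]; }
      else if (x[k] > ax[k].hi) { x[k] = 2 * ax[k].hi - x[k]; v[k] = -v[k]; }
      else return;
    }
    stop("particle escaped the domain (unstable integration step?)");
  };

  for (int step = 0; step < n_steps; ++step) {
    for (int k = 0; k < d; ++k) {           // B
      v[k] += 0.5 * dt * f[k] / mass[k];
      x[k] += 0.5 * dt * v[k];              // A
      reflect(k);
    }
    for (int k = 0; k < d; ++k) {           // O
      v[k] = c1 * v[k] + c2[k] * norm_rand();
      x[k] += 0.5 * dt * v[k];              // A
      reflect(k);
    }
    force(x, f);
    for (int k = 0; k < d; ++k)             // B
      v[k] += 0.5 * dt * f[k] / mass[k];

    if (!std::isfinite(x[0]) || (d == 2 && !std::isfinite(x[1])))
      stop("NaN encountered in the trajectory at step %d", step + 1);

    double t = (step + 1) * dt;
    if ((step + 1) % pace_steps == 0 && ih < n_hills) {
      double h = w0;
      if (well_tempered)
        h = w0 * std::exp(-interp(vb.data(), x) /
                          (KB * (bias_factor - 1.0) * temperature));
      if (h > 0) deposit(x, h);
      hills(ih, 0) = t;
      for (int k = 0; k < d; ++k) {
        hills(ih, 1 + k) = x[k];
        hills(ih, 1 + d + k) = widths[k];
      }
      hills(ih, 1 + 2 * d) = h;
      hills(ih, 2 + 2 * d) = well_tempered ? bias_factor : 1.0;
      ++ih;
    }
    if ((step + 1) % record_stride == 0 && ir < n_rec) {
      colvar(ir, 0) = t;
      for (int k = 0; k < d; ++k) colvar(ir, 1 + k) = x[k];
      ++ir;
    }
  }

  NumericVector bias_final(vb.begin(), vb.end());
  return List::create(_["hills"] = hills, _["colvar"] = colvar,
                      _["bias_grid"] = bias_final,
                      _["x_final"] = NumericVector(x, x + d));
}

// Exact Gaussian hill summation on a grid (no tail truncation).  The
// per-hill outer product is factorized per dimension.
// [[Rcpp::export(name = ".sum_hills_grid")]]
NumericVector sum_hills_grid(NumericMatrix centers, NumericMatrix sigmas,
                             NumericVector heights, List axes) {
  const int d = centers.ncol();
  const int nh = centers.nrow();
  if (d < 1 || d > 2) stop("only 1 or 2 CVs supported");
  NumericVector ax1 = axes[0];
  const int nx = ax1.size();
  if (d == 1) {
    NumericVector out(nx);
    for (int h = 0; h < nh; ++h) {
      double c = centers(h, 0), s = sigmas(h, 0), w = heights[h];
      for (int i = 0; i < nx; ++i) {
        double u = (ax1[i] - c) / s;
        out[i] += w * std::exp(-0.5 * u * u);
      }
    }
    return out;
  }
  NumericVector ax2 = axes[1];
  const int ny = ax2.size();
  NumericVector out((long)nx * ny);
  std::vector<double> ex(nx), ey(ny);
  for (int h = 0; h < nh; ++h) {
    double cx = centers(h, 0), sx = sigmas(h, 0);
    double cy = centers(h, 1), sy = sigmas(h, 1);
    double w = heights[h];
    for (int i = 0; i < nx; ++i) {
      double u = (ax1[i] - cx) / sx;
      ex[i] = std::exp(-0.5 * u * u);
    }
    for (int j = 0; j < ny; ++j) {
      double u = (ax2[j] - cy) / sy;
      ey[j] = w * std::exp(-0.5 * u * u);
    }
    for (int j = 0; j < ny; ++j) {
      double e = ey[j];
      long off = (long)j * nx;
      for (int i = 0; i < nx; ++i) out[off + i] += e * ex[i];
    }
  }
  return out;
}
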