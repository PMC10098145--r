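#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Staggered-grid FDTD for linear lossless acoustics in heterogeneous 2-D media,
// first-order coupled pressure / particle-velocity form with a split-field PML.
//
//   dv/dt = -grad(p) / rho           (v on cell faces, half-integer time steps)
//   dp/dt = -rho c^2 div(v)          (p at cell centres, integer time steps,
//                                     p = px + py inside the PML)
//
// Initial condition: p(0) = p0, v(0) = 0; the first velocity update uses dt/2
// so the leapfrog recursion is the symmetric second-order one (this makes the
// discrete propagator exactly reciprocal under compressibility weighting).
//
// Fields are stored column-major like R matrices: index i (0..nx-1) is the
// first/"x" axis, j (0..ny-1) the second/"y" axis, linear index i + nx*j.
// vx lives on interior x-faces ((nx-1) x ny), vy on interior y-faces
// (nx x (ny-1)); the outermost boundary is rigid, behind the PML.

static inline double pml_profile(double pos, double n, double pml, double smax) {
  // pos: distance of the stagger point from the domain edge, in cells
  if (pml <= 0.0) return 0.0;
  double d = 0.0;
  if (pos < pml) d = (pml - pos) / pml;
  else if (pos > n - pml) d = (pos - (n - pml)) / pml;
  if (d <= 0.0) return 0.0;
  double d2 = d * d;
  return smax * d2 * d2; // polynomial profile of order 4
}

// [[Rcpp::export]]
List fdtd_run(NumericMatrix sound_speed, NumericMatrix density, NumericMatrix p0,
              double dx, double dt, int nt, int pml_cells,
              List sensor_cells, List sensor_weights, int record_every) {
  const int nx = sound_speed.nrow(), ny = sound_speed.ncol();
  if (density.nrow() != nx || density.ncol() != ny || p0.nrow() != nx || p0.ncol() != ny)
    stop("field shapes do not match");
  if (nt < 1) stop("nt must be >= 1");
  const int ncell = nx * ny;

  double cmax = 0.0;
  for (int k = 0; k < ncell; ++k) cmax = std::max(cmax, sound_speed[k]);
  // sigma_max for ~1e-5 round-trip reflection through the polynomial layer
  const double smax = (pml_cells > 0)
    ? -(4.0 + 1.0) * cmax * std::log(1e-5) / (2.0 * pml_cells * dx)
    : 0.0;

  // damping coefficients per x-index (cell centres and x-faces) and per y-index
  std::vector<double> cpx(nx), epx(nx), cpy(ny), epy(ny);
  std::vector<double> cfx(nx - 1), efx(nx - 1), cfy(ny - 1), efy(ny - 1);
  const double r = dt / dx;
  for (int i = 0; i < nx; ++i) {
    double a = 0.5 * dt * pml_profile(i + 0.5, nx, pml_cells, smax);
    cpx[i] = (1.0 - a) / (1.0 + a);
    epx[i] = r / (1.0 + a);
  }
  for (int j = 0; j < ny; ++j) {
    double a = 0.5 * dt * pml_profile(j + 0.5, ny, pml_cells, smax);
    cpy[j] = (1.0 - a) / (1.0 + a);
    epy[j] = r / (1.0 + a);
  }
  for (int i = 0; i < nx - 1; ++i) {
    double a = 0.5 * dt * pml_profile(i + 1.0, nx, pml_cells, smax);
    cfx[i] = (1.0 - a) / (1.0 + a);
    efx[i] = r / (1.0 + a);
  }
  for (int j = 0; j < ny - 1; ++j) {
    double a = 0.5 * dt * pml_profile(j + 1.0, ny, pml_cells, smax);
    cfy[j] = (1.0 - a) / (1.0 + a);
    efy[j] = r / (1.0 + a);
  }

  // material coefficients: kappa = rho c^2 at centres, 1/rho averaged to faces
  std::vector<double> kappa(ncell), irhox((nx - 1) * ny), irhoy(nx * (ny - 1));
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      int k = i + nx * j;
      kappa[k] = density[k] * sound_speed[k] * sound_speed[k];
    }
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx - 1; ++i)
      irhox[i + (nx - 1) * j] = 2.0 / (density[i + nx * j] + density[i + 1 + nx * j]);
  for (int j = 0; j < ny - 1; ++j)
    for (int i = 0; i < nx; ++i)
      irhoy[i + nx * j] = 2.0 / (density[i + nx * j] + density[i + nx * (j + 1)]);

  // state: split pressure px/py, velocities
  std::vector<double> px(ncell), py(ncell), vx((nx - 1) * ny, 0.0), vy(nx * (ny - 1), 0.0);
  for (int k = 0; k < ncell; ++k) { px[k] = 0.5 * p0[k]; py[k] = 0.5 * p0[k]; }

  // sensors: list of 0-based linear cell indices + weights
  const int ns = sensor_cells.size();
  std::vector<std::vector<int> > sidx(ns);
  std::vector<std::vector<double> > swgt(ns);
  for (int s = 0; s < ns; ++s) {
    IntegerVector ic = sensor_cells[s];
    NumericVector wc = sensor_weights[s];
    if (ic.size() != wc.size()) stop("sensor cells/weights length mismatch");
    sidx[s].assign(ic.begin(), ic.end());
    swgt[s].assign(wc.begin(), wc.end());
    for (size_t q = 0; q < sidx[s].size(); ++q)
      if (sidx[s][q] < 0 || sidx[s][q] >= ncell) stop("sensor cell index out of range");
  }

  NumericMatrix traces(nt, ns);
  List fields;
  IntegerVector field_steps;
  std::vector<NumericMatrix> snaps;
  std::vector<int> snap_steps;

  // record step 0 (the initial pressure itself)
  for (int s = 0; s < ns; ++s) {
    double acc = 0.0;
    for (size_t q = 0; q < sidx[s].size(); ++q)
      acc += swgt[s][q] * (px[sidx[s][q]] + py[sidx[s][q]]);
    traces(0, s) = acc;
  }
  if (record_every > 0) {
    NumericMatrix f(nx, ny);
    for (int k = 0; k < ncell; ++k) f[k] = px[k] + py[k];
    snaps.push_back(f); snap_steps.push_back(0);
  }

  // 4th-order staggered differences with dispersion-matched coefficients:
  // c2 = (CFL^2 - 1)/24 cancels the leading (cubic) dispersion of the
  // leapfrog time integration at the operating Courant number, so the
  // numerical front stays sharp (c2 = -1/24 recovers the standard stencil
  // as CFL -> 0). Out-of-range samples are taken as zero, so divergence is
  // exactly the negative adjoint of the gradient and the propagator stays
  // reciprocal.
  // dispersion-matched 6-point staggered differences: the coefficients of
  // sin((2j-1)k dx/2) are solved so the semi-discrete dispersion matches the
  // leapfrog time integration through (k dx)^5 at the operating Courant
  // number (as CFL -> 0 they reduce to the standard 6th-order stencil).
  // Out-of-range samples are taken as zero, so divergence stays exactly the
  // negative adjoint of the gradient and the propagator stays reciprocal.
  // q is clamped at the scheme's stability range so that an over-large time
  // step keeps a sane stencil and surfaces as leapfrog instability (caught
  // by the non-finite field check) instead of degenerate coefficients
  const double q = std::min((cmax * dt / dx) * (cmax * dt / dx), 0.36);
  const double c3 = (q - 1.0) * (q - 9.0) / 1920.0;
  const double c2 = (q - 1.0) / 24.0 - 5.0 * c3;
  const double c1 = 1.0 - 3.0 * c2 - 5.0 * c3;
  std::vector<double> pt(ncell); // total pressure, rebuilt each step
  const int fnx = nx - 1;
  for (int n = 1; n < nt; ++n) {
    const double half = (n == 1) ? 0.5 : 1.0; // leapfrog initialization
    for (int k = 0; k < ncell; ++k) pt[k] = px[k] + py[k];
    // velocity updates
    for (int j = 0; j < ny; ++j) {
      const int off = nx * j, foff = fnx * j;
      for (int i = 0; i < fnx; ++i) {
        const int k = i + off, f = i + foff;
        double g = c1 * (pt[k + 1] - pt[k]);
        g += c2 * ((i + 2 < nx ? pt[k + 2] : 0.0) - (i - 1 >= 0 ? pt[k - 1] : 0.0));
        g += c3 * ((i + 3 < nx ? pt[k + 3] : 0.0) - (i - 2 >= 0 ? pt[k - 2] : 0.0));
        vx[f] = cfx[i] * vx[f] - half * efx[i] * irhox[f] * g;
      }
    }
    for (int j = 0; j < ny - 1; ++j) {
      const int off = nx * j;
      for (int i = 0; i < nx; ++i) {
        const int k = i + off;
        double g = c1 * (pt[k + nx] - pt[k]);
        g += c2 * ((j + 2 < ny ? pt[k + 2 * nx] : 0.0) - (j - 1 >= 0 ? pt[k - nx] : 0.0));
        g += c3 * ((j + 3 < ny ? pt[k + 3 * nx] : 0.0) - (j - 2 >= 0 ? pt[k - 2 * nx] : 0.0));
        vy[k] = cfy[j] * vy[k] - half * efy[j] * irhoy[k] * g;
      }
    }
    // pressure updates (divergence = negative adjoint of the gradient)
    for (int j = 0; j < ny; ++j) {
      const int off = nx * j, foff = fnx * j;
      for (int i = 0; i < nx; ++i) {
        const int k = i + off;
        double dvx = c1 * ((i < fnx ? vx[i + foff] : 0.0) - (i - 1 >= 0 ? vx[i - 1 + foff] : 0.0));
        dvx += c2 * ((i + 1 < fnx ? vx[i + 1 + foff] : 0.0) - (i - 2 >= 0 ? vx[i - 2 + foff] : 0.0));
        dvx += c3 * ((i + 2 < fnx ? vx[i + 2 + foff] : 0.0) - (i - 3 >= 0 ? vx[i - 3 + foff] : 0.0));
        px[k] = cpx[i] * px[k] - epx[i] * kappa[k] * dvx;
        double dvy = c1 * ((j < ny - 1 ? vy[k] : 0.0) - (j - 1 >= 0 ? vy[k - nx] : 0.0));
        dvy += c2 * ((j + 1 < ny - 1 ? vy[k + nx] : 0.0) - (j - 2 >= 0 ? vy[k - 2 * nx] : 0.0));
        dvy += c3 * ((j + 2 < ny - 1 ? vy[k + 2 * nx] : 0.0) - (j - 3 >= 0 ? vy[k - 3 * nx] : 0.0));
        py[k] = cpy[j] * py[k] - epy[j] * kappa[k] * dvy;
      }
    }
    for (int s = 0; s < ns; ++s) {
      double acc = 0.0;
      for (size_t q = 0; q < sidx[s].size(); ++q)
        acc += swgt[s][q] * (px[sidx[s][q]] + py[sidx[s][q]]);
      traces(n, s) = acc;
    }
    if (record_every > 0 && n % record_every == 0) {
      NumericMatrix f(nx, ny);
      for (int k = 0; k < ncell; ++k) f[k] = px[k] + py[k];
      snaps.push_back(f); snap_steps.push_back(n);
    }
    if (n % 200 == 0) {
      const double probe = px[ncell / 2] + py[ncell / 2] + px[0] + px[ncell - 1];
      if (!R_finite(probe)) {
        // locate a non-finite cell for the error message
        for (int k = 0; k < ncell; ++k)
          if (!R_finite(px[k] + py[k]))
            stop("numerical-failure: non-finite pressure at step %d (cell %d); time step too large for this medium", n, k + 1);
        stop("numerical-failure: non-finite field at step %d", n);
      }
      Rcpp::checkUserInterrupt();
    }
  }
  // final finite check on the recorded traces
  for (int s = 0; s < ns; ++s)
    for (int n = 0; n < nt; ++n)
      if (!R_finite(traces(n, s)))
        stop("numerical-failure: non-finite trace sample at step %d; time step too large for this medium", n);

  if (record_every > 0) {
    fields = List(snaps.size());
    field_steps = IntegerVector(snap_steps.size());
    for (size_t q = 0; q < snaps.size(); ++q) { fields[q] = snaps[q]; field_steps[q] = snap_steps[q]; }
  }
  return List::create(_["traces"] = traces, _["fields"] = fields,
                      _["field_steps"] = field_steps);
}
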