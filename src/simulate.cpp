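#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// periodic wrap into [0, L)
static inline double wrapL(double v, double L) {
  double r = v - L * std::floor(v / L);
  if (r >= L) r -= L;
  if (r < 0.0) r += L;
  return r;
}

// Brownian dynamics of one fluorescent species sampled by a scanned line.
//
// Particles live on a strip [0, field_um) x [-strip_um/2, strip_um/2); x is
// the scan axis. Between successive lines each mobile particle takes a
// Gaussian step of variance 2*D*dt per axis plus an optional drift v*dt in x.
// Detection is a 2D Gaussian PSF exp(-2*((x-xc)^2+y^2)/w0^2) with amplitude
// `brightness` counts per sampling per molecule at the PSF centre.
//
// Boundaries: periodic in y always; periodic in x unless a barrier is
// present, in which case the field ends are reflecting walls so that an
// impermeable barrier genuinely partitions the field. A step attempting to
// cross the barrier plane is transmitted with probability cross_prob and
// specularly reflected otherwise.
//
// Uses the R RNG, so results are reproducible under set.seed(). Returns the
// n_lines x n_pixels matrix of *expected* counts (Poisson sampling is done
// in R) and, optionally, the unwrapped trajectories for diagnostics.
// [[Rcpp::export]]
List sim_species_carpet(int n_lines, int n_pixels, double pixel_um,
                        double field_um, double strip_um,
                        double D, double vel, double brightness,
                        double waist_um, double dt,
                        bool has_barrier, double barrier_x_um,
                        double cross_prob,
                        NumericVector x0, NumericVector y0,
                        LogicalVector mobile, bool keep_traj) {
  const int np = x0.size();
  NumericMatrix carpet(n_lines, n_pixels);
  NumericMatrix traj_x, traj_y, pos_x;
  if (keep_traj) {
    traj_x = NumericMatrix(n_lines, np);   // unwrapped (free-step) coords
    traj_y = NumericMatrix(n_lines, np);
    pos_x = NumericMatrix(n_lines, np);    // actual in-field positions
  }
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> y(y0.begin(), y0.end());
  // unwrapped coordinates for displacement statistics
  std::vector<double> xu(x0.begin(), x0.end());
  std::vector<double> yu(y0.begin(), y0.end());
  const double sig = std::sqrt(2.0 * D * dt);
  const double w2 = waist_um * waist_um;
  const double cutoff = 2.5 * waist_um;          // exp(-12.5) ~ 4e-6 tail
  const int hw = (int)std::ceil(cutoff / pixel_um) + 1;
  const double half_strip = strip_um / 2.0;
  // pixel-index wraparound is only meaningful when the particle field is
  // exactly the scanned ring (periodic BC, field == n_pixels * pixel)
  const bool wrap_px = !has_barrier &&
    std::fabs(field_um - n_pixels * pixel_um) < 1e-9 * field_um;

  for (int t = 0; t < n_lines; ++t) {
    if (t > 0) {
      for (int i = 0; i < np; ++i) {
        if (!mobile[i]) continue;
        double dx = sig * norm_rand() + vel * dt;
        double dy = sig * norm_rand();
        double nx = x[i] + dx;
        if (has_barrier) {
          // barrier bounce (Bernoulli transmission), then reflecting walls
          if ((x[i] - barrier_x_um) * (nx - barrier_x_um) < 0.0) {
            if (unif_rand() >= cross_prob) nx = 2.0 * barrier_x_um - nx;
          }
          if (nx < 0.0) nx = -nx;
          if (nx >= field_um) nx = 2.0 * field_um - nx;
          if (nx < 0.0) nx = 0.0;                 // pathological large step
        } else {
          nx = wrapL(nx, field_um);
        }
        double ny = wrapL(y[i] + dy + half_strip, strip_um) - half_strip;
        x[i] = nx; y[i] = ny;
        xu[i] += dx; yu[i] += dy;
      }
    }
    if (keep_traj) {
      for (int i = 0; i < np; ++i) {
        traj_x(t, i) = xu[i]; traj_y(t, i) = yu[i]; pos_x(t, i) = x[i];
      }
    }
    if (brightness <= 0.0) continue;
    for (int i = 0; i < np; ++i) {
      double ay = std::fabs(y[i]);
      if (strip_um - ay < ay) ay = strip_um - ay;  // min-image in y
      if (ay > cutoff) continue;
      const double amp = brightness * std::exp(-2.0 * ay * ay / w2);
      const int jc = (int)std::floor(x[i] / pixel_um);
      for (int j = jc - hw; j <= jc + hw; ++j) {
        int jj = j;
        double xc = (j + 0.5) * pixel_um;
        if (wrap_px) {
          jj = j % n_pixels; if (jj < 0) jj += n_pixels;
        } else {
          if (jj < 0 || jj >= n_pixels) continue;
        }
        double d = x[i] - xc;
        carpet(t, jj) += amp * std::exp(-2.0 * d * d / w2);
      }
    }
  }
  List out = List::create(_["expected"] = carpet);
  if (keep_traj) {
    out["traj_x"] = traj_x; out["traj_y"] = traj_y; out["pos_x"] = pos_x;
  }
  return out;
}

// Brownian dynamics of one species in the 2D image plane, rendered frame by
// frame. Periodic boundaries on both axes; x runs along columns, y along
// rows. Returns expected counts as an (n_frames * rows * cols) vector in
// frame-major order (dim attribute is attached in R).
// [[Rcpp::export]]
NumericVector sim_species_frames(int n_frames, int rows, int cols,
                                 double px_um, double D, double brightness,
                                 double waist_um, double dt,
                                 NumericVector x0, NumericVector y0) {
  const int np = x0.size();
  const double lx = cols * px_um, ly = rows * px_um;
  NumericVector out(static_cast<R_xlen_t>(n_frames) * rows * cols);
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> y(y0.begin(), y0.end());
  const double sig = std::sqrt(2.0 * D * dt);
  const double w2 = waist_um * waist_um;
  const double cutoff = 2.5 * waist_um;
  const int hw = (int)std::ceil(cutoff / px_um) + 1;

  for (int t = 0; t < n_frames; ++t) {
    if (t > 0) {
      for (int i = 0; i < np; ++i) {
        x[i] = wrapL(x[i] + sig * norm_rand(), lx);
        y[i] = wrapL(y[i] + sig * norm_rand(), ly);
      }
    }
    const R_xlen_t base = static_cast<R_xlen_t>(t) * rows * cols;
    for (int i = 0; i < np; ++i) {
      const int rc = (int)std::floor(y[i] / px_um);
      const int cc = (int)std::floor(x[i] / px_um);
      for (int r = rc - hw; r <= rc + hw; ++r) {
        int rr = r % rows; if (rr < 0) rr += rows;
        double dy = y[i] - (r + 0.5) * px_um;
        double gy = std::exp(-2.0 * dy * dy / w2);
        if (gy < 1e-8) continue;
        for (int c = cc - hw; c <= cc + hw; ++c) {
          int cc2 = c % cols; if (cc2 < 0) cc2 += cols;
          double dx = x[i] - (c + 0.5) * px_um;
          out[base + rr + static_cast<R_xlen_t>(cc2) * rows] +=
            brightness * gy * std::exp(-2.0 * dx * dx / w2);
        }
      }
    }
  }
  return out;
}
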