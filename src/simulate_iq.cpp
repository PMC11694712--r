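#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Slow-time HPRF pulsed-Doppler ensemble on a beamformed
// (gate-depth x lateral x elevation) grid.
//
// Per pulse, each scatterer contributes
//   amplitude * two-way beam amplitude * range-gate window * exp(i 4 pi f0 z / c)
// into every gate-depth bin whose depth is congruent to the scatterer depth
// modulo the range-ambiguity spacing c / (2 PRF): echoes from depths
// separated by that spacing arrive in the same receive gate and sum.
//
// The two-way amplitude is transmit x receive: the single broad transmit
// beam (one-way Gaussian-beam profile) is fixed on the axis (x = y = 0),
// while receive beamforming focuses dynamically at every depth, giving a
// diffraction-limited receive profile of 1/e radius z*lambda/(pi*w_a)
// translated to each lateral/elevation grid point. A jet displaced beyond
// the transmit beam width is therefore captured incompletely, as in vivo,
// while the receive resolution stays sharp.
//
// Blood scatterers are advected by the jet field (elliptical-cylinder core,
// top-hat or parabolic profile, within-beat orifice-area modulation,
// sinusoidal lateral excursion) with per-pulse Euler steps and are recycled
// through the core slab so the seeded density is stationary; tissue clutter
// drifts quasi-statically; reflectors are fixed.

static inline double beam_w(double w0, double zw, double zR, double z) {
  double t = (z - zw) / zR;
  return w0 * std::sqrt(1.0 + t * t);
}

// [[Rcpp::export]]
ComplexVector cpp_simulate_iq(
    NumericMatrix pos0, NumericVector amp, IntegerVector cls,
    NumericMatrix drift,
    NumericVector jet_u, NumericVector e1, NumericVector e2,
    NumericVector orifice_center,
    double core_length, double a0, double b0, int parabolic,
    NumericVector speed_t, NumericVector gmod_t, NumericVector exc_t,
    NumericVector gx, NumericVector gy, NumericVector gz,
    double w0x, double zwx, double zRx,
    double w0y, double zwy, double zRy,
    double krx_x, double krx_y,
    double f0_hz, double prf_hz, double c_ms, double gate_sigma_mm,
    int n_frames, double ramp_mm, NumericMatrix respawn,
    NumericVector coh_phase, double coh_omega) {

  const int ns = pos0.nrow();
  const int nx = gx.size(), ny = gy.size(), nz = gz.size();
  const int nt = n_frames;
  ComplexVector out(static_cast<R_xlen_t>(nz) * nx * ny * nt);
  std::vector<double> px(ns), py(ns), pz(ns);
  for (int s = 0; s < ns; ++s) {
    px[s] = pos0(s, 0); py[s] = pos0(s, 1); pz[s] = pos0(s, 2);
  }
  const double dt = 1.0 / prf_hz;
  const double amb_mm = c_ms * 1000.0 / (2.0 * prf_hz); // ambiguity spacing
  const double phase_k = 4.0 * M_PI * f0_hz * 1e-3 / c_ms; // per mm depth
  const double gate_cut = 4.0 * gate_sigma_mm;
  const double inv2sg2 = 1.0 / (2.0 * gate_sigma_mm * gate_sigma_mm);

  std::vector<double> bx2(nx), by2(ny), gw(nz);
  std::vector<int> gidx(nz);
  const int n_respawn = respawn.nrow();
  int respawn_i = 0;

  for (int t = 0; t < nt; ++t) {
    const double sp = speed_t[t];
    const double g = gmod_t[t];
    const double a = a0 * g, b = b0 * g;
    const double cx = orifice_center[0] + exc_t[t];
    const double cy = orifice_center[1];
    const double cz = orifice_center[2];
    R_xlen_t off_t = static_cast<R_xlen_t>(t) * nz * nx * ny;

    for (int s = 0; s < ns; ++s) {
      // ---- advect ----
      // Scattering amplitude of blood tapers over the first/last ramp_mm
      // of the core so scatterers materialize and recycle at zero
      // amplitude: without the taper the recycling jump is an amplitude
      // step inside the sensed gate and raises a broadband pedestal.
      double taper = 1.0;
      if (cls[s] == 0) { // blood
        double dx = px[s] - cx, dy = py[s] - cy, dz = pz[s] - cz;
        double sax = dx * jet_u[0] + dy * jet_u[1] + dz * jet_u[2];
        if (sax >= 0.0 && sax <= core_length) {
          double rx = dx - sax * jet_u[0], ry = dy - sax * jet_u[1],
                 rz = dz - sax * jet_u[2];
          double c1 = (rx * e1[0] + ry * e1[1] + rz * e1[2]) / a;
          double c2 = (rx * e2[0] + ry * e2[1] + rz * e2[2]) / b;
          double r2 = c1 * c1 + c2 * c2;
          if (r2 <= 1.0) {
            double sax2 = sax;
            if (sp != 0.0) {
              double v = parabolic ? 2.0 * sp * (1.0 - r2) : sp; // m/s
              double step = v * dt * 1000.0;                     // mm
              px[s] += step * jet_u[0];
              py[s] += step * jet_u[1];
              pz[s] += step * jet_u[2];
              // recycle through the core slab; the re-entering scatterer
              // is new blood through the orifice and takes a fresh random
              // radial position (otherwise the lateral speckle pattern of
              // the whole recording would be a single frozen draw)
              sax2 = sax + step;
              if (sax2 > core_length) {
                sax2 -= core_length;
                double rc1 = 0.0, rc2 = 0.0;
                if (n_respawn > 0) {
                  rc1 = respawn(respawn_i, 0);
                  rc2 = respawn(respawn_i, 1);
                  respawn_i = (respawn_i + 1) % n_respawn;
                }
                double ra = rc1 * a, rb = rc2 * b;
                px[s] = cx + sax2 * jet_u[0] + ra * e1[0] + rb * e2[0];
                py[s] = cy + sax2 * jet_u[1] + ra * e1[1] + rb * e2[1];
                pz[s] = cz + sax2 * jet_u[2] + ra * e1[2] + rb * e2[2];
              }
            }
            if (ramp_mm > 0.0) {
              double t1 = sax2 / ramp_mm;
              double t2 = (core_length - sax2) / ramp_mm;
              taper = std::max(0.0, std::min(1.0, std::min(t1, t2)));
            }
          }
        }
      } else if (cls[s] == 1) { // quasi-static clutter drift
        px[s] += drift(s, 0) * dt * 1000.0;
        py[s] += drift(s, 1) * dt * 1000.0;
        pz[s] += drift(s, 2) * dt * 1000.0;
      }
      // blood speckle coherence: smooth unit-power amplitude modulation
      // with a random per-scatterer phase, emulating the decorrelation of
      // real blood echoes that the laminar mean-flow advection lacks
      if (cls[s] == 0 && coh_omega > 0.0)
        taper *= M_SQRT2 * std::cos(coh_omega * t * dt + coh_phase[s]);

      const double z = pz[s];
      if (z <= 0.5 || taper == 0.0) continue;

      // ---- one-way transmit envelope: cheap early skip ----
      double wx = beam_w(w0x, zwx, zRx, z), wy = beam_w(w0y, zwy, zRy, z);
      double tx = std::sqrt((w0x / wx) * (w0y / wy)) *
        std::exp(-px[s] * px[s] / (wx * wx) - py[s] * py[s] / (wy * wy));
      double as = amp[s] * tx * taper;
      if (std::fabs(as) < 1e-9) continue;

      // ---- range gate (with ambiguity wrap) ----
      int nhit = 0;
      for (int k = 0; k < nz; ++k) {
        double d = z - gz[k];
        d -= amb_mm * std::round(d / amb_mm);
        if (std::fabs(d) < gate_cut) {
          gidx[nhit] = k;
          gw[nhit] = std::exp(-d * d * inv2sg2);
          ++nhit;
        }
      }
      if (nhit == 0) continue;

      // ---- dynamically focused receive sensitivity per grid axis ----
      double wrx = krx_x * z, wry = krx_y * z;
      double mxx = 0.0, mxy = 0.0;
      for (int i = 0; i < nx; ++i) {
        double dx = px[s] - gx[i];
        bx2[i] = std::exp(-dx * dx / (wrx * wrx));
        if (bx2[i] > mxx) mxx = bx2[i];
      }
      for (int j = 0; j < ny; ++j) {
        double dy = py[s] - gy[j];
        by2[j] = std::exp(-dy * dy / (wry * wry));
        if (by2[j] > mxy) mxy = by2[j];
      }
      if (std::fabs(as) * mxx * mxy < 1e-9) continue;

      double ph = phase_k * z;
      double re = as * std::cos(ph), im = as * std::sin(ph);

      for (int j = 0; j < ny; ++j) {
        double bj = by2[j];
        if (bj * mxx * std::fabs(as) < 1e-10) continue;
        R_xlen_t off_j = off_t + static_cast<R_xlen_t>(j) * nz * nx;
        for (int i = 0; i < nx; ++i) {
          double w2 = bj * bx2[i];
          if (w2 * std::fabs(as) < 1e-10) continue;
          double cre = re * w2, cim = im * w2;
          R_xlen_t off_i = off_j + static_cast<R_xlen_t>(i) * nz;
          for (int h = 0; h < nhit; ++h) {
            Rcomplex &o = out[off_i + gidx[h]];
            o.r += cre * gw[h];
            o.i += cim * gw[h];
          }
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(nz, nx, ny, nt);
  return out;
}

// Synthetic power-Doppler model image for ellipse segmentation: indicator
// of a rotated ellipse, weighted by the fixed transmit-beam power envelope
// exp(-2 x^2/env_wx^2 - 2 y^2/env_wy^2) (disabled when env_wx <= 0),
// rendered on a fine grid and blurred with the separable Gaussian receive
// power PSF, evaluated at the image pixel grid.
// [[Rcpp::export]]
NumericMatrix cpp_ellipse_model_image(
    double cx, double cy, double a, double b, double rot_deg,
    NumericVector gx, NumericVector gy,
    double sx, double sy, double fine_step,
    double env_wx, double env_wy) {
  const int nx = gx.size(), ny = gy.size();
  double x0 = gx[0] - 3.0 * sx, x1 = gx[nx - 1] + 3.0 * sx;
  double y0 = gy[0] - 3.0 * sy, y1 = gy[ny - 1] + 3.0 * sy;
  int nfx = std::max(2, (int)std::ceil((x1 - x0) / fine_step) + 1);
  int nfy = std::max(2, (int)std::ceil((y1 - y0) / fine_step) + 1);
  double th = rot_deg * M_PI / 180.0, ct = std::cos(th), st = std::sin(th);

  // transmit-weighted indicator on fine grid
  NumericMatrix ind(nfx, nfy);
  for (int j = 0; j < nfy; ++j) {
    double ya = y0 + j * fine_step;
    double v = ya - cy;
    for (int i = 0; i < nfx; ++i) {
      double xa = x0 + i * fine_step;
      double u = xa - cx;
      double ua = (ct * u + st * v) / a, vb = (-st * u + ct * v) / b;
      if (ua * ua + vb * vb <= 1.0) {
        double w = 1.0;
        if (env_wx > 0.0)
          w = std::exp(-2.0 * xa * xa / (env_wx * env_wx)
                       - 2.0 * ya * ya / (env_wy * env_wy));
        ind(i, j) = w;
      }
    }
  }
  // separable Gaussian blur sampled at pixel centres
  NumericMatrix Kx(nx, nfx), Ky(ny, nfy);
  for (int p = 0; p < nx; ++p)
    for (int i = 0; i < nfx; ++i) {
      double d = gx[p] - (x0 + i * fine_step);
      Kx(p, i) = std::exp(-d * d / (2.0 * sx * sx));
    }
  for (int q = 0; q < ny; ++q)
    for (int j = 0; j < nfy; ++j) {
      double d = gy[q] - (y0 + j * fine_step);
      Ky(q, j) = std::exp(-d * d / (2.0 * sy * sy));
    }
  NumericMatrix out(nx, ny);
  std::vector<double> tmp(nfy);
  for (int p = 0; p < nx; ++p) {
    for (int j = 0; j < nfy; ++j) {
      double acc = 0.0;
      for (int i = 0; i < nfx; ++i) acc += Kx(p, i) * ind(i, j);
      tmp[j] = acc;
    }
    for (int q = 0; q < ny; ++q) {
      double acc = 0.0;
      for (int j = 0; j < nfy; ++j) acc += Ky(q, j) * tmp[j];
      out(p, q) = acc;
    }
  }
  return out;
}
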