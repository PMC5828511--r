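#include <Rcpp.h>
using namespace Rcpp;

// Correlated-random-walk flight simulator with optional crossing-triggered
// augmentations. One Euler-Maruyama step of
//   tau * dv = (-v + eta*xi + b*w_c + a*w_u) dt
// per sample, reflecting boundaries, concentration read from a Gaussian
// plume. Modes:
//   0 = base walker (w_c -> tunnel centerline)
//   1 = surge-cast / synthetic-effects: additive upwind alpha-function surge
//       of amplitude (A0 + conc_gain*c_peak) * hist(n) triggered at the
//       concentration peak of each plume crossing; hist(n) = rho for n >= 3
//       (step) or rho^(n-1) (smooth)
//   2 = centerline-inferring: w_c -> MAP centerline estimate of a 2D
//       Gaussian belief (diagonal covariance) updated at each crossing peak,
//       with continuous upwind drive k = k_star / |K|
//
// RNG contract: exactly 3 standard normals drawn per step via Rcpp::rnorm,
// matching an R reference stepper drawing rnorm(3) per step.

static inline double plume_conc(double x, double y, double z,
                                double yc, double zc, double sigma0,
                                double widen, double cmax) {
  double sig = sigma0 + widen * x;
  double r2 = (y - yc) * (y - yc) + (z - zc) * (z - zc);
  return cmax * std::exp(-r2 / (2.0 * sig * sig));
}

static inline void reflect(double &p, double &v, double lo, double hi) {
  // positions can overshoot by at most a few mm per step; loop for safety
  for (int it = 0; it < 8 && (p < lo || p > hi); ++it) {
    if (p < lo) { p = 2.0 * lo - p; v = -v; }
    if (p > hi) { p = 2.0 * hi - p; v = -v; }
  }
  if (p < lo) p = lo;
  if (p > hi) p = hi;
}

// [[Rcpp::export]]
List sim_walker_cpp(int n_steps, double dt,
                    double tau, double eta, double b,
                    NumericVector start, NumericVector v0,
                    NumericVector extent,
                    NumericVector plume_par,  // yc, zc, sigma0, widen, cmax
                    double detect_threshold,
                    int mode,
                    double A0, double conc_gain, double rho, int smooth_decay,
                    double surge_threshold, double tau_s,
                    double k_star, double Ks_var, double K0_var,
                    double tau_m) {
  const double Lx = extent[0], Ly = extent[1], Lz = extent[2];
  const double yc = plume_par[0], zc = plume_par[1], sigma0 = plume_par[2],
               widen = plume_par[3], cmax = plume_par[4];
  const int n = n_steps + 1;

  NumericMatrix pos(n, 3), vel(n, 3);
  NumericVector conc(n);
  std::vector<int> trig_idx;
  std::vector<double> trig_amp_v;

  double x = start[0], y = start[1], z = start[2];
  double vx = v0[0], vy = v0[1], vz = v0[2];

  // active surge kernels (time, amplitude); pruned once negligible
  const int MAXK = 64;
  double trig_t[MAXK], trig_a[MAXK];
  int n_trig = 0;

  // crossing bookkeeping
  bool in_exc = false, peaked = false;
  double prev_c = 0.0;
  int crossing_count = 0;

  // centerline belief state (diagonal covariance)
  double bm_y = 0.0, bm_z = 0.0, bv_y = K0_var, bv_z = K0_var;

  pos(0, 0) = x; pos(0, 1) = y; pos(0, 2) = z;
  vel(0, 0) = vx; vel(0, 1) = vy; vel(0, 2) = vz;
  conc[0] = plume_conc(x, y, z, yc, zc, sigma0, widen, cmax);
  prev_c = conc[0];
  in_exc = conc[0] >= detect_threshold;

  for (int i = 1; i < n; ++i) {
    // crosswind bias target: tunnel centerline or belief MAP
    double ty = 0.0, tz = 0.0;
    if (mode == 2) { ty = bm_y; tz = bm_z; }
    double dy = ty - y, dz = tz - z;
    double dn = std::sqrt(dy * dy + dz * dz);
    double wcy = 0.0, wcz = 0.0;
    if (dn > 1e-12) { wcy = dy / dn; wcz = dz / dn; }

    // upwind drive amplitude
    double amp = 0.0;
    if (mode == 1) {
      double tprev = (i - 1) * dt;  // kernels evaluated at current step time
      int keep = 0;
      for (int k = 0; k < n_trig; ++k) {
        double s = (tprev - trig_t[k]) / tau_s;
        if (s <= 12.0) {  // kernel negligible beyond ~12 timescales
          trig_t[keep] = trig_t[k]; trig_a[keep] = trig_a[k]; ++keep;
          if (s >= 0.0) amp += trig_a[k] * s * std::exp(1.0 - s);
        }
      }
      n_trig = keep;
    } else if (mode == 2) {
      amp = k_star / (bv_y * bv_z);
    }

    NumericVector xi = rnorm(3);
    double f = dt / tau;
    vx += f * (-vx + eta * xi[0] - amp);  // w_u = (-1, 0, 0)
    vy += f * (-vy + eta * xi[1] + b * wcy);
    vz += f * (-vz + eta * xi[2] + b * wcz);

    x += vx * dt; y += vy * dt; z += vz * dt;
    reflect(x, vx, 0.0, Lx);
    reflect(y, vy, -Ly / 2.0, Ly / 2.0);
    reflect(z, vz, -Lz / 2.0, Lz / 2.0);

    double c = plume_conc(x, y, z, yc, zc, sigma0, widen, cmax);
    pos(i, 0) = x; pos(i, 1) = y; pos(i, 2) = z;
    vel(i, 0) = vx; vel(i, 1) = vy; vel(i, 2) = vz;
    conc[i] = c;

    // belief memory decay (continuous, every step)
    if (mode == 2 && tau_m > 0.0) {
      double g = std::exp(-dt / tau_m);
      bm_y *= g; bm_z *= g;
      bv_y = K0_var + (bv_y - K0_var) * g;
      bv_z = K0_var + (bv_z - K0_var) * g;
    }

    // online crossing-peak detection on the experienced concentration
    if (!in_exc) {
      if (c >= detect_threshold) { in_exc = true; peaked = false; }
    } else if (c < detect_threshold) {
      in_exc = false; peaked = false;
    }
    if (in_exc && !peaked && c < prev_c && prev_c >= detect_threshold) {
      // previous sample was the excursion's concentration peak
      peaked = true;
      ++crossing_count;
      double c_peak = prev_c;
      if (mode == 1 && c_peak >= surge_threshold) {
        double hist = 1.0;
        if (smooth_decay) hist = std::pow(rho, crossing_count - 1);
        else if (crossing_count >= 3) hist = rho;
        double A = (A0 + conc_gain * c_peak) * hist;
        if (A > 0.0 && n_trig < MAXK) {
          trig_t[n_trig] = (i - 1) * dt;
          trig_a[n_trig] = A;
          ++n_trig;
        }
        trig_idx.push_back(i - 1);
        trig_amp_v.push_back(A);
      } else if (mode == 2) {
        double oy = pos(i - 1, 1), oz = pos(i - 1, 2);
        double pvy = 1.0 / (1.0 / bv_y + 1.0 / Ks_var);
        double pvz = 1.0 / (1.0 / bv_z + 1.0 / Ks_var);
        bm_y = pvy * (bm_y / bv_y + oy / Ks_var);
        bm_z = pvz * (bm_z / bv_z + oz / Ks_var);
        bv_y = pvy; bv_z = pvz;
        trig_idx.push_back(i - 1);
        trig_amp_v.push_back(k_star / (bv_y * bv_z));
      } else {
        trig_idx.push_back(i - 1);
        trig_amp_v.push_back(0.0);
      }
    }
    prev_c = c;
  }

  return List::create(
      _["positions"] = pos, _["velocities"] = vel, _["concentrations"] = conc,
      _["trigger_index"] = wrap(trig_idx),
      _["trigger_amplitude"] = wrap(trig_amp_v),
      _["n_crossings_online"] = crossing_count);
}
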