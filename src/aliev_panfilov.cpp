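#include <Rcpp.h>
using namespace Rcpp;

// Two-variable Aliev-Panfilov excitation/recovery kinetics on a regular 2-D
// sheet, explicit Euler, 5-point Laplacian, no-flux boundaries.
//
//   dV/dt = ( -k V (V - a(t)) (V - 1) - V r ) / tau + D lap(V)
//   dr/dt = ( (eps0 + mu1 r / (V + mu2)) * (-r - k V (V - a(t) - 1)) ) / tau
//
// tau (ms per dimensionless time unit) maps the dimensionless kinetics onto
// millisecond time; a(t) = a * (1 + a_mod_amp * sin(2 pi t / a_mod_period))
// provides the meander control. A periodic stimulus current is injected on
// stim_nodes (0-based linear indices, column-major) during its duty windows.
//
// Frames of V are recorded every record_every steps (including step 0).
// [[Rcpp::export(name = ".ap_run")]]
List ap_run(int nx, int ny, double h, double D, double dt, int n_steps,
            int record_every,
            double k, double a, double eps0, double mu1, double mu2,
            double tau,
            NumericVector V0, NumericVector r0,
            double a_mod_amp, double a_mod_period,
            IntegerVector stim_nodes, double stim_period, double stim_start,
            double stim_dur, double stim_amp, double t0) {
  const int n = nx * ny;
  if (V0.size() != n || r0.size() != n)
    stop("state size mismatch");
  std::vector<double> V(V0.begin(), V0.end());
  std::vector<double> r(r0.begin(), r0.end());
  std::vector<double> Vn(n);

  const int n_frames = n_steps / record_every + 1;
  NumericVector movie((R_xlen_t)n * n_frames);
  NumericVector frame_t(n_frames);

  const double alpha = D * dt / (h * h);
  int frame = 0;
  // record initial state
  for (int i = 0; i < n; ++i) movie[i] = V[i];
  frame_t[0] = t0;
  frame = 1;

  for (int step = 1; step <= n_steps; ++step) {
    const double t = t0 + step * dt;
    double at = a;
    if (a_mod_amp != 0.0 && a_mod_period > 0.0)
      at = a * (1.0 + a_mod_amp * std::sin(2.0 * M_PI * t / a_mod_period));

    double since_onset = 0.0;
    if (t >= stim_start && stim_period > 0.0) {
      const double el = t - stim_start;
      since_onset = el - std::floor(el / stim_period) * stim_period;
    }
    const bool stim_on =
      stim_nodes.size() > 0 && t >= stim_start && stim_period > 0.0 &&
      since_onset < stim_dur;

    for (int j = 0; j < ny; ++j) {
      const int jm = (j == 0) ? 1 : j - 1;
      const int jp = (j == ny - 1) ? ny - 2 : j + 1;
      for (int i = 0; i < nx; ++i) {
        const int im = (i == 0) ? 1 : i - 1;
        const int ip = (i == nx - 1) ? nx - 2 : i + 1;
        const int idx = i + nx * j;
        const double v = V[idx];
        const double lap = V[im + nx * j] + V[ip + nx * j] +
                           V[i + nx * jm] + V[i + nx * jp] - 4.0 * v;
        const double rv = r[idx];
        const double dv = (-k * v * (v - at) * (v - 1.0) - v * rv) / tau;
        const double dr = ((eps0 + mu1 * rv / (v + mu2)) *
                           (-rv - k * v * (v - at - 1.0))) / tau;
        Vn[idx] = v + dt * dv + alpha * lap;
        r[idx] = rv + dt * dr;
      }
    }
    if (stim_on) {
      for (int s = 0; s < stim_nodes.size(); ++s) {
        const int idx = stim_nodes[s];
        Vn[idx] += stim_amp * dt;
        if (Vn[idx] > 1.0) Vn[idx] = 1.0;
      }
    }
    std::swap(V, Vn);

    if (step % 500 == 0) {
      double chk = 0.0;
      for (int i = 0; i < n; ++i) chk += V[i];
      if (!std::isfinite(chk))
        stop("simulation went non-finite at step %d (t = %.1f ms)", step, t);
    }
    if (step % record_every == 0) {
      const R_xlen_t off = (R_xlen_t)n * frame;
      for (int i = 0; i < n; ++i) movie[off + i] = V[i];
      frame_t[frame] = t;
      ++frame;
    }
  }

  return List::create(_["movie"] = movie, _["frame_t"] = frame_t,
                      _["V"] = NumericVector(V.begin(), V.end()),
                      _["r"] = NumericVector(r.begin(), r.end()),
                      _["n_frames"] = n_frames);
}

// 1-D cable with the same kinetics; used as an independent conduction-velocity
// oracle. Returns activation times (first upward crossing of V = 0.5) per node.
// [[Rcpp::export(name = ".ap_run_cable")]]
NumericVector ap_run_cable(int nx, double h, double D, double dt, int n_steps,
                           double k, double a, double eps0, double mu1,
                           double mu2, double tau,
                           int stim_width, double stim_amp, double stim_dur) {
  std::vector<double> V(nx, 0.0), r(nx, 0.0), Vn(nx);
  NumericVector act(nx, NA_REAL);
  const double alpha = D * dt / (h * h);
  for (int step = 1; step <= n_steps; ++step) {
    const double t = step * dt;
    for (int i = 0; i < nx; ++i) {
      const int im = (i == 0) ? 1 : i - 1;
      const int ip = (i == nx - 1) ? nx - 2 : i + 1;
      const double v = V[i];
      const double lap = V[im] + V[ip] - 2.0 * v;
      const double rv = r[i];
      const double dv = (-k * v * (v - a) * (v - 1.0) - v * rv) / tau;
      const double dr = ((eps0 + mu1 * rv / (v + mu2)) *
                         (-rv - k * v * (v - a - 1.0))) / tau;
      Vn[i] = v + dt * dv + alpha * lap;
      r[i] = rv + dt * dr;
    }
    if (t < stim_dur)
      for (int i = 0; i < stim_width && i < nx; ++i) {
        Vn[i] += stim_amp * dt;
        if (Vn[i] > 1.0) Vn[i] = 1.0;
      }
    for (int i = 0; i < nx; ++i) {
      if (ISNA(act[i]) && Vn[i] >= 0.5 && V[i] < 0.5) act[i] = t;
      V[i] = Vn[i];
    }
  }
  return act;
}
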