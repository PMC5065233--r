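#include <Rcpp.h>
using namespace Rcpp;

// Shared numerical kernels. All stochastic draws go through R's RNG so that
// set.seed() in R controls every trajectory.

static inline double hill(double u, double n) {
  if (u <= 0.0) return 0.0;
  double p = (n == 2.0) ? u * u : ((n == 1.0) ? u : std::pow(u, n));
  return p / (1.0 + p);
}

// Euler-Maruyama ensemble for the 1-D units (simple regulated / bistable
// autoactivation). One column per unit, one row per realization; units of a
// realization share the signal x[i] (plus any extrinsic offset already folded
// into xeff) but draw independent Wiener increments.
//
// kind: 0 = simple (signal in the Hill argument), 1 = bistable (additive
// signal, autoactivation Hill on y scaled by omega).
// eps12: length-2 cross-talk strengths (eps1, eps2); only honoured for
// kind = 1 and N = 2 (unit 1's Hill argument is y1 + eps2*y2, unit 2's is
// y2 + eps1*y1).
// Returns list(avg = window-averaged states, last = final states).
// offset: per-realization constant additive drift term (shared extrinsic
// production offset).
// [[Rcpp::export(name = ".em_ensemble_1d")]]
List em_ensemble_1d(int kind, NumericVector xeff, NumericVector offset,
                    NumericVector omega, NumericVector eps12, double alpha0,
                    double alpha, double n, double K, double dt, int nsteps,
                    double window_frac, NumericMatrix y0) {
  int R = xeff.size(), N = omega.size();
  NumericMatrix y(R, N), avg(R, N);
  for (int j = 0; j < N; ++j)
    for (int i = 0; i < R; ++i) y(i, j) = y0(i, j);
  int w0 = nsteps - (int)std::floor(window_frac * nsteps);
  if (w0 < 0) w0 = 0;
  int nw = nsteps - w0;
  double sdt = std::sqrt(dt);
  bool xtalk = (kind == 1 && N == 2 &&
                (eps12[0] != 0.0 || eps12[1] != 0.0));
  for (int s = 0; s < nsteps; ++s) {
    for (int j = 0; j < N; ++j) {
      double om = omega[j];
      for (int i = 0; i < R; ++i) {
        double yi = y(i, j), prod, drift;
        if (kind == 0) {
          // production set by the signal; omega scales the signal's
          // dissociation constant (heterogeneous input threshold)
          double xi = xeff[i];
          prod = alpha0 + alpha * hill(xi / om, n);
          drift = prod - yi + offset[i];
        } else {
          double arg = yi;
          if (xtalk) arg += (j == 0 ? eps12[1] * y(i, 1) : eps12[0] * y(i, 0));
          prod = alpha0 + alpha * hill(arg / om, n);
          drift = prod - yi + xeff[i] + offset[i];
        }
        double q2 = (prod + yi) / K;
        double yn = yi + drift * dt +
          ((q2 > 0.0) ? std::sqrt(q2) * sdt * R::norm_rand() : 0.0);
        if (yn < 0.0) yn = 0.0;
        if (!std::isfinite(yn))
          stop("Euler-Maruyama step diverged (dt too large?)");
        y(i, j) = yn;
        if (s >= w0) avg(i, j) += yn;
      }
    }
  }
  if (nw > 0)
    for (int j = 0; j < N; ++j)
      for (int i = 0; i < R; ++i) avg(i, j) /= nw;
  return List::create(_["avg"] = avg, _["last"] = y);
}

// Euler-Maruyama ensemble for the excitable (competence-like) two-variable
// unit. The signal is a pulse of amplitude x[i] on dz during the first
// pulse_steps steps; additive noise of constant amplitude q acts on z only.
// Records the running maximum of y after the pulse (excursion detector).
// [[Rcpp::export(name = ".em_ensemble_excitable")]]
List em_ensemble_excitable(NumericVector x, int N, double alpha0,
                           double alpha, double beta, double sigma,
                           double n, double m, double K, double dt,
                           int nsteps, int pulse_steps,
                           double y_rest, double z_rest) {
  int R = x.size();
  NumericMatrix ymax(R, N), ylast(R, N), zlast(R, N);
  double q = std::sqrt((beta + 1.0) / K), sdt = std::sqrt(dt);
  for (int j = 0; j < N; ++j) {
    std::vector<double> y(R, y_rest), z(R, z_rest);
    for (int s = 0; s < nsteps; ++s) {
      bool on = s < pulse_steps;
      for (int i = 0; i < R; ++i) {
        double yi = y[i], zi = z[i];
        double den = 1.0 + yi + zi;
        double u = sigma * yi;               // (sigma*y)^n positive feedback
        double v = sigma * std::pow(yi, m);  // sigma*y^m repression
        double dy = alpha0 + alpha * hill(u, n) - yi / den;
        double dz = beta / (1.0 + v) - zi / den + (on ? x[i] : 0.0) ;
        double yn = yi + dy * dt;
        double zn = zi + dz * dt + q * sdt * R::norm_rand();
        if (yn < 0.0) yn = 0.0;
        if (zn < 0.0) zn = 0.0;
        if (!std::isfinite(yn) || !std::isfinite(zn))
          stop("Euler-Maruyama step diverged (dt too large?)");
        y[i] = yn; z[i] = zn;
        if (s >= pulse_steps && yn > ymax(i, j)) ymax(i, j) = yn;
      }
    }
    for (int i = 0; i < R; ++i) { ylast(i, j) = y[i]; zlast(i, j) = z[i]; }
  }
  return List::create(_["ymax"] = ymax, _["ylast"] = ylast,
                      _["zlast"] = zlast);
}

// Inverse-CDF draws from stationary densities tabulated as
// log w(y; x) = K*(A0(y) + x*B0(y)) - logq2K(y) on the grid (bistable form,
// where the signal enters the potential linearly). One draw per element of x.
// [[Rcpp::export(name = ".fp_sample_linear")]]
NumericVector fp_sample_linear(NumericVector x, double K, NumericVector grid,
                               NumericVector A0, NumericVector B0,
                               NumericVector logq2K, NumericVector u) {
  int R = x.size(), M = grid.size();
  NumericVector out(R);
  std::vector<double> w(M);
  for (int i = 0; i < R; ++i) {
    double mx = -1e300;
    for (int k = 0; k < M; ++k) {
      w[k] = K * (A0[k] + x[i] * B0[k]) - logq2K[k];
      if (w[k] > mx) mx = w[k];
    }
    double tot = 0.0;
    for (int k = 0; k < M; ++k) { w[k] = std::exp(w[k] - mx); tot += w[k]; }
    double target = u[i] * tot, c = 0.0;
    int k = 0;
    for (; k < M - 1; ++k) { c += w[k]; if (c >= target) break; }
    out[i] = grid[k];
  }
  return out;
}

// Same draw scheme for the simple regulated unit, whose stationary potential
// has the closed form psi(y) = 2K*(2c*log((c+y)/c) - y) with production
// c = alpha0 + alpha*hill(x).  cvec holds c per realization.
// [[Rcpp::export(name = ".fp_sample_simple")]]
NumericVector fp_sample_simple(NumericVector cvec, double K,
                               NumericVector grid, NumericVector u) {
  int R = cvec.size(), M = grid.size();
  NumericVector out(R);
  std::vector<double> w(M);
  for (int i = 0; i < R; ++i) {
    double c = cvec[i], mx = -1e300;
    for (int k = 0; k < M; ++k) {
      double y = grid[k];
      double psi = 2.0 * K * (2.0 * c * std::log((c + y) / c) - y);
      w[k] = psi - std::log((c + y) / K);
      if (w[k] > mx) mx = w[k];
    }
    double tot = 0.0;
    for (int k = 0; k < M; ++k) { w[k] = std::exp(w[k] - mx); tot += w[k]; }
    double target = u[i] * tot, c2 = 0.0;
    int k = 0;
    for (; k < M - 1; ++k) { c2 += w[k]; if (c2 >= target) break; }
    out[i] = grid[k];
  }
  return out;
}
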