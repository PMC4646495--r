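#include <Rcpp.h>
using namespace Rcpp;

// Closed-loop tick integrator for the virtual-teacher dyad.
//
// The VT (x, dx) is advanced by classical RK4 with the partner observation
// held constant within each step (zero-order hold). The partner is either a
// scripted trace, a phase-level surrogate integrating its own phase under
// the HKB relative-phase flow (Euler-Maruyama), or a second limb-level
// oscillator with its own HKB coupling. Both sides read each other through a
// configurable loop delay (default one tick, i.e. 2 ms at 500 Hz); the
// surrogate additionally reads the VT through its perceptual delay buffer.
//
// RNG: exactly one N(0,1) draw per tick when the partner is the surrogate,
// none otherwise, so R-side seeding reproduces sample paths and the pure-R
// reference engine consumes the identical stream.

// Wrap to (-pi, pi], matching the R-side wrap_angle().
static inline double wrap_pi(double a) {
  return a - 2.0 * M_PI * std::ceil((a - M_PI) / (2.0 * M_PI));
}

struct VTP {
  double alpha, beta, gamma, omega, A, B, mu;
};

static inline double vt_acc(const VTP &p, double x, double dx,
                            double y, double dy,
                            double C, double A, double B, double psi) {
  double intrinsic = -(p.alpha * dx * dx * dx + p.beta * x * x * dx -
                       p.gamma * dx) - p.omega * p.omega * x;
  double d = x - p.mu * y;
  double hkb = (A + B * d * d) * (dx - p.mu * dy);
  double intent = C * ((dx - dy) * std::cos(psi) +
                       p.omega * y * std::sin(psi));
  return intrinsic + hkb + intent;
}

static inline void rk4(const VTP &p, double &x, double &dx, double y,
                       double dy, double C, double A, double B, double psi,
                       double dt) {
  double k1x = dx, k1v = vt_acc(p, x, dx, y, dy, C, A, B, psi);
  double k2x = dx + 0.5 * dt * k1v;
  double k2v = vt_acc(p, x + 0.5 * dt * k1x, dx + 0.5 * dt * k1v,
                      y, dy, C, A, B, psi);
  double k3x = dx + 0.5 * dt * k2v;
  double k3v = vt_acc(p, x + 0.5 * dt * k2x, dx + 0.5 * dt * k2v,
                      y, dy, C, A, B, psi);
  double k4x = dx + dt * k3v;
  double k4v = vt_acc(p, x + dt * k3x, dx + dt * k3v,
                      y, dy, C, A, B, psi);
  x += dt / 6.0 * (k1x + 2 * k2x + 2 * k3x + k4x);
  dx += dt / 6.0 * (k1v + 2 * k2v + 2 * k3v + k4v);
}

// [[Rcpp::export(name = ".dyad_loop_cpp")]]
List dyad_loop_cpp(int n, double dt, List vt, NumericVector C,
                   NumericVector A, NumericVector B, NumericVector psi,
                   LogicalVector visible, std::string partner_kind,
                   List partner, double x0, double dx0, int delay_ticks,
                   double theta0) {
  VTP p;
  p.alpha = vt["alpha"]; p.beta = vt["beta"]; p.gamma = vt["gamma"];
  p.omega = vt["omega"]; p.A = vt["A"]; p.B = vt["B"]; p.mu = vt["mu"];

  NumericVector X(n), DX(n), Y(n), DY(n), PHI(n, NA_REAL);
  X[0] = x0; DX[0] = dx0;

  bool surrogate = partner_kind == "surrogate";
  bool limb = partner_kind == "limb";

  // surrogate parameters
  double sa = 0, sb = 0, sc = 0, spsi = 0, ssig = 0, samp = 1,
         somh = 2 * M_PI, sdel = 0;
  int d_per = 0;
  // limb partner parameters
  VTP ph; double Ah = 0, Bh = 0;
  double theta_y = theta0, yy = 0, ydy = 0;

  if (surrogate) {
    List sp = partner["params"];
    sa = sp["a"]; sb = sp["b"]; sc = sp["c"]; spsi = sp["psi_intent"];
    ssig = sp["sigma"]; samp = sp["amplitude"]; somh = sp["omega_h"];
    sdel = sp["delay_s"];
    d_per = (int) std::lround(sdel / dt);
    Y[0] = samp * std::cos(theta_y);
    DY[0] = -samp * somh * std::sin(theta_y);
  } else if (limb) {
    List lp = partner["params"];
    ph.alpha = lp["alpha"]; ph.beta = lp["beta"]; ph.gamma = lp["gamma"];
    ph.omega = lp["omega"]; ph.mu = 1; ph.A = 0; ph.B = 0;
    Ah = partner["A_h"]; Bh = partner["B_h"];
    yy = std::cos(theta0); ydy = -ph.omega * std::sin(theta0);
    Y[0] = yy; DY[0] = ydy;
  } else {
    NumericVector ys = partner["y"], dys = partner["dy"];
    if (ys.size() < n) stop("scripted trace shorter than trial");
    for (int i = 0; i < n; ++i) { Y[i] = ys[i]; DY[i] = dys[i]; }
  }

  double sqdt = std::sqrt(dt);
  RNGScope scope;

  for (int i = 1; i < n; ++i) {
    int j = i - delay_ticks;            // partner sample seen by the VT
    double oy = j >= 0 ? Y[j] : 0.0, ody = j >= 0 ? DY[j] : 0.0;
    double x = X[i - 1], dx = DX[i - 1];
    rk4(p, x, dx, oy, ody, C[i - 1], A[i - 1], B[i - 1], psi[i - 1], dt);
    if (!std::isfinite(x) || !std::isfinite(dx)) {
      stop("integration failure at t = %f s: non-finite state", (i - 1) * dt);
    }
    X[i] = x; DX[i] = dx;

    if (surrogate) {
      int k = i - delay_ticks - d_per;  // VT sample seen by the surrogate
      double drift = somh;
      if (visible[i - 1] && k >= 0) {
        // delayed VT phase, extrapolated over the known delay
        double th_x = std::atan2(-DX[k] / somh, X[k]) +
                      somh * (sdel + delay_ticks * dt);
        double phih = wrap_pi(theta_y - th_x);
        drift += -sa * std::sin(phih) - 2 * sb * std::sin(2 * phih) +
                 sc * std::sin(spsi - phih);
      }
      theta_y += drift * dt + ssig * sqdt * norm_rand();
      Y[i] = samp * std::cos(theta_y);
      DY[i] = -samp * drift * std::sin(theta_y);
      double th_now = std::atan2(-DX[i] / somh, X[i]);
      PHI[i] = wrap_pi(theta_y - th_now);
    } else if (limb) {
      int k = i - delay_ticks;
      double ox = k >= 0 ? X[k] : 0.0, odx = k >= 0 ? DX[k] : 0.0;
      double Ause = visible[i - 1] ? Ah : 0.0;
      double Buse = visible[i - 1] ? Bh : 0.0;
      rk4(ph, yy, ydy, ox, odx, 0.0, Ause, Buse, 0.0, dt);
      if (!std::isfinite(yy) || !std::isfinite(ydy)) {
        stop("integration failure at t = %f s: non-finite partner state",
             (i - 1) * dt);
      }
      Y[i] = yy; DY[i] = ydy;
    }
  }

  return List::create(_["x"] = X, _["dx"] = DX, _["y"] = Y, _["dy"] = DY,
                      _["phi"] = PHI);
}
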