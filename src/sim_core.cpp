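#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Forward-Euler integration of the double inverted pendulum stance model
// with ring-buffer delay lines for the intermittent and reflexive
// controllers. All randomness (the torque-noise series) is drawn in R and
// passed in, so reproducibility is governed entirely by R's RNG.
//
// Conventions: theta_a is the forward tilt of the LE (leg) link from
// vertical, theta_h the forward rotation of the HAT link relative to the
// LE link; positive torques accelerate the corresponding angle forward.
// Active and reflexive torques are applied as negative (restoring)
// feedback of the delayed CoM tilt state.

struct Body {
  double m1, m2, l1, c1, c2, I1, I2, g;
};

static inline void dynamics(const Body& b, double th_a, double th_h,
                            double om_a, double om_h,
                            double& M11, double& M12, double& M22,
                            double& C1, double& C2,
                            double& G1, double& G2) {
  const double ch = std::cos(th_h), sh = std::sin(th_h);
  const double s1 = std::sin(th_a), s12 = std::sin(th_a + th_h);
  M11 = b.I1 + b.m1 * b.c1 * b.c1 + b.I2 +
        b.m2 * (b.l1 * b.l1 + b.c2 * b.c2 + 2.0 * b.l1 * b.c2 * ch);
  M12 = b.I2 + b.m2 * (b.c2 * b.c2 + b.l1 * b.c2 * ch);
  M22 = b.I2 + b.m2 * b.c2 * b.c2;
  C1 = -b.m2 * b.l1 * b.c2 * sh * (2.0 * om_a * om_h + om_h * om_h);
  C2 = b.m2 * b.l1 * b.c2 * sh * om_a * om_a;
  // G enters the left-hand side M*acc + C + G = T; it is negative for a
  // forward tilt, i.e. gravity topples the pendulum forward.
  G1 = -b.g * ((b.m1 * b.c1 + b.m2 * b.l1) * s1 + b.m2 * b.c2 * s12);
  G2 = -b.g * b.m2 * b.c2 * s12;
}

// [[Rcpp::export(.sim_core)]]
List sim_core(List body, NumericVector passive, NumericVector ctrl,
              NumericVector reflex, NumericMatrix pert_segments,
              NumericVector pert_times, NumericMatrix noise,
              double dt, double t_start, double t_end,
              NumericVector init, NumericVector region,
              double fall_limit) {
  Body b;
  b.m1 = as<double>(body["m_le"]);  b.m2 = as<double>(body["m_hat"]);
  b.l1 = as<double>(body["l_le"]);
  b.c1 = as<double>(body["c_le"]); b.c2 = as<double>(body["c_hat"]);
  b.I1 = as<double>(body["i_le"]); b.I2 = as<double>(body["i_hat"]);
  b.g  = as<double>(body["g"]);

  const double K_a = passive[0], B_a = passive[1];
  const double K_h = passive[2], B_h = passive[3];
  const double P = ctrl[0], D = ctrl[1];
  const int nd = (int)ctrl[2];          // intermittent delay, in steps
  const bool has_reflex = reflex[0] > 0.5;
  const double Pr = reflex[1], Dr = reflex[2];
  const int ndr = (int)reflex[3];       // reflex delay, in steps
  const double t_on = reflex[4], t_off = reflex[5];
  const double slope1 = region[0], slope2 = region[1];
  const bool slope2_inf = !std::isfinite(slope2);

  const int n = (int)std::llround((t_end - t_start) / dt) + 1;
  const int n_pert = pert_times.size();

  NumericVector t(n), th_a(n), th_h(n), om_a(n), om_h(n);
  NumericVector th_com(n), om_com(n), com_x(n), com_y(n);
  NumericVector tp_a(n), tp_h(n), ta_a(n), tr_a(n);
  NumericVector tq_a(n), tq_h(n), tn_a(n), tn_h(n);
  IntegerVector mode(n);
  bool fallen = false;
  int n_used = n;

  double xa = init[0], xh = init[1], va = init[2], vh = init[3];

  for (int i = 0; i < n; ++i) {
    const double ti = t_start + i * dt;
    t[i] = ti; th_a[i] = xa; th_h[i] = xh; om_a[i] = va; om_h[i] = vh;

    // CoM kinematics of the two moving links (foot excluded)
    const double s1 = std::sin(xa), c1 = std::cos(xa);
    const double s12 = std::sin(xa + xh), c12 = std::cos(xa + xh);
    const double x1 = b.c1 * s1, y1 = b.c1 * c1;
    const double x2 = b.l1 * s1 + b.c2 * s12;
    const double y2 = b.l1 * c1 + b.c2 * c12;
    const double mtot = b.m1 + b.m2;
    const double xc = (b.m1 * x1 + b.m2 * x2) / mtot;
    const double yc = (b.m1 * y1 + b.m2 * y2) / mtot;
    const double vx1 = b.c1 * c1 * va, vy1 = -b.c1 * s1 * va;
    const double vx2 = b.l1 * c1 * va + b.c2 * c12 * (va + vh);
    const double vy2 = -b.l1 * s1 * va - b.c2 * s12 * (va + vh);
    const double vxc = (b.m1 * vx1 + b.m2 * vx2) / mtot;
    const double vyc = (b.m1 * vy1 + b.m2 * vy2) / mtot;
    com_x[i] = xc; com_y[i] = yc;
    th_com[i] = std::atan2(xc, yc);
    om_com[i] = (vxc * yc - xc * vyc) / (xc * xc + yc * yc);

    // support-surface acceleration at ti (piecewise constant per event)
    double alpha = 0.0;
    bool reflex_window = false;
    for (int k = 0; k < n_pert; ++k) {
      const double tr = ti - pert_times[k];
      if (tr < -1e-12) break;
      for (int s = 0; s < pert_segments.nrow(); ++s) {
        if (tr >= pert_segments(s, 0) - 1e-12 && tr < pert_segments(s, 1) - 1e-12)
          alpha = pert_segments(s, 2);
      }
      if (has_reflex && tr >= t_on - 1e-12 && tr < t_off - 1e-12)
        reflex_window = true;
    }

    // delayed CoM state (earliest stored sample during warm-up)
    const int id = i - nd >= 0 ? i - nd : 0;
    const int idr = i - ndr >= 0 ? i - ndr : 0;

    double tau_act = 0.0, tau_rfx = 0.0;
    int m = 0; // OFF
    if (reflex_window) {
      m = 2;
      tau_rfx = -(Pr * th_com[idr] + Dr * om_com[idr]);
    } else {
      const double thd = th_com[id], omd = om_com[id];
      const double g1 = omd - slope1 * thd;
      const double g2 = slope2_inf ? thd : (omd - slope2 * thd);
      const bool off = g1 * g2 <= 0.0;
      if (!off) {
        m = 1;
        tau_act = -(P * thd + D * omd);
      }
    }
    mode[i] = m;

    // torque components
    const double tpa = -(K_a * xa + B_a * va);
    const double tph = -(K_h * xh + B_h * vh);
    double tqa = 0.0, tqh = 0.0;
    if (alpha != 0.0) {
      tqa = -alpha * (b.m1 * b.c1 * c1 + b.m2 * (b.l1 * c1 + b.c2 * c12));
      tqh = -alpha * b.m2 * b.c2 * c12;
    }
    const double tna = noise(i, 0), tnh = noise(i, 1);
    tp_a[i] = tpa; tp_h[i] = tph; ta_a[i] = tau_act; tr_a[i] = tau_rfx;
    tq_a[i] = tqa; tq_h[i] = tqh; tn_a[i] = tna; tn_h[i] = tnh;

    if (std::fabs(th_com[i]) > fall_limit) { fallen = true; n_used = i + 1; break; }
    if (i == n - 1) break;

    // equations of motion and Euler step
    double M11, M12, M22, C1, C2, G1, G2;
    dynamics(b, xa, xh, va, vh, M11, M12, M22, C1, C2, G1, G2);
    const double Ta = tpa + tau_act + tau_rfx + tqa + tna - C1 - G1;
    const double Th = tph + tqh + tnh - C2 - G2;
    const double det = M11 * M22 - M12 * M12;
    const double acc_a = (M22 * Ta - M12 * Th) / det;
    const double acc_h = (M11 * Th - M12 * Ta) / det;
    xa += dt * va; xh += dt * vh;
    va += dt * acc_a; vh += dt * acc_h;
    if (!std::isfinite(xa) || !std::isfinite(xh)) { fallen = true; n_used = i + 1; break; }
  }

  Range r(0, n_used - 1);
  return List::create(
    _["t"] = t[r], _["theta_a"] = th_a[r], _["theta_h"] = th_h[r],
    _["omega_a"] = om_a[r], _["omega_h"] = om_h[r],
    _["theta_com"] = th_com[r], _["omega_com"] = om_com[r],
    _["com_x"] = com_x[r], _["com_y"] = com_y[r],
    _["tau_pass_a"] = tp_a[r], _["tau_pass_h"] = tp_h[r],
    _["tau_act_a"] = ta_a[r], _["tau_reflex_a"] = tr_a[r],
    _["tau_pert_a"] = tq_a[r], _["tau_pert_h"] = tq_h[r],
    _["tau_noise_a"] = tn_a[r], _["tau_noise_h"] = tn_h[r],
    _["control_mode"] = mode[r], _["fallen"] = fallen);
}
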