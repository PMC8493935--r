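#include <Rcpp.h>
using namespace Rcpp;

// Wrap an angle to (-pi, pi]; identical arithmetic to the R helper
// (floored modulo), so R and C++ paths agree bitwise.
inline double wrap_pi(double a) {
  double s = a + M_PI;
  double w = s - 2.0 * M_PI * std::floor(s / (2.0 * M_PI));
  w -= M_PI;                 // now in [-pi, pi)
  if (w == -M_PI) w = M_PI;  // closed at +pi, open at -pi
  return w;
}

// Heading angular acceleration: damping, goal attraction with a
// distance-decaying gain floored at c2, and per-obstacle repulsion decaying
// exponentially in both angular offset and distance.
inline double heading_accel(double phi, double phi_dot,
                            double theta_g, double d_g,
                            const NumericVector &theta_o,
                            const NumericVector &d_o,
                            double beta, double gamma, double eps,
                            double c1, double c2, double c3, double c4) {
  double dg_ang = wrap_pi(phi - theta_g);
  double acc = -beta * phi_dot - gamma * dg_ang * (std::exp(-c1 * d_g) + c2);
  const int n = theta_o.size();
  for (int i = 0; i < n; ++i) {
    double da = wrap_pi(phi - theta_o[i]);
    acc += eps * da * std::exp(-c3 * std::fabs(da)) * std::exp(-c4 * d_o[i]);
  }
  return acc;
}

// [[Rcpp::export(name = ".simulate_dpmp_cpp")]]
List simulate_dpmp_cpp(double x0, double y0, double phi0, double phi_dot0,
                       double speed, double tx, double ty,
                       NumericVector ox, NumericVector oy, NumericVector orad,
                       double target_radius, double agent_radius,
                       double beta, double gamma, double eps,
                       double c1, double c2, double c3, double c4,
                       double dt, int n_max,
                       double max_turn_rate, double max_turn_accel) {
  // max_turn_rate / max_turn_accel: pass R_PosInf for uncapped (continuous mode)
  const int n_obs = ox.size();
  NumericVector t(n_max + 1), x(n_max + 1), y(n_max + 1), phi(n_max + 1);
  NumericVector theta_o(n_obs), d_o(n_obs);

  double cx = x0, cy = y0, cphi = wrap_pi(phi0), cdot = phi_dot0;
  t[0] = 0.0; x[0] = cx; y[0] = cy; phi[0] = cphi;
  std::string outcome = "timed_out";
  int last = 0;

  for (int k = 1; k <= n_max; ++k) {
    double dxg = tx - cx, dyg = ty - cy;
    double d_g = std::sqrt(dxg * dxg + dyg * dyg);
    if (d_g == 0.0)
      stop("agent coincides with target at step %d", k - 1);
    double theta_g = std::atan2(dyg, dxg);
    for (int i = 0; i < n_obs; ++i) {
      double dxo = ox[i] - cx, dyo = oy[i] - cy;
      double di = std::sqrt(dxo * dxo + dyo * dyo);
      if (di == 0.0)
        stop("agent coincides with obstacle %d at step %d", i + 1, k - 1);
      theta_o[i] = std::atan2(dyo, dxo);
      d_o[i] = di;
    }
    double acc = heading_accel(cphi, cdot, theta_g, d_g, theta_o, d_o,
                               beta, gamma, eps, c1, c2, c3, c4);
    if (acc > max_turn_accel) acc = max_turn_accel;
    if (acc < -max_turn_accel) acc = -max_turn_accel;
    cdot += acc * dt;
    if (cdot > max_turn_rate) cdot = max_turn_rate;
    if (cdot < -max_turn_rate) cdot = -max_turn_rate;
    cphi = wrap_pi(cphi + cdot * dt);
    cx += speed * std::cos(cphi) * dt;
    cy += speed * std::sin(cphi) * dt;

    if (!std::isfinite(cx) || !std::isfinite(cy) || !std::isfinite(cphi) ||
        !std::isfinite(cdot))
      stop("non-finite state at step %d (parameter blow-up)", k);

    t[k] = k * dt; x[k] = cx; y[k] = cy; phi[k] = cphi;
    last = k;

    bool hit = false;
    for (int i = 0; i < n_obs; ++i) {
      double dxo = ox[i] - cx, dyo = oy[i] - cy;
      if (std::sqrt(dxo * dxo + dyo * dyo) < orad[i] + agent_radius) {
        hit = true; break;
      }
    }
    if (hit) { outcome = "hit_obstacle"; break; }
    double dxg2 = tx - cx, dyg2 = ty - cy;
    if (std::sqrt(dxg2 * dxg2 + dyg2 * dyg2) < target_radius + agent_radius) {
      outcome = "reached_target"; break;
    }
  }

  IntegerVector idx = seq(0, last);
  return List::create(_["t"] = t[idx], _["x"] = x[idx], _["y"] = y[idx],
                      _["phi"] = phi[idx], _["outcome"] = outcome,
                      _["phi_dot_final"] = cdot);
}

// Classic DTW with Euclidean local cost, symmetric step pattern
// (match / insert / delete), boundary anchored; returns the accumulated
// cost along the optimal warping path.
// [[Rcpp::export(name = ".dtw_cpp")]]
double dtw_cpp(NumericMatrix a, NumericMatrix b) {
  const int n = a.nrow(), m = b.nrow(), d = a.ncol();
  if (n < 1 || m < 1) stop("empty sequence");
  if (b.ncol() != d) stop("dimension mismatch");
  std::vector<double> prev(m), cur(m);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      double cost = 0.0;
      for (int k = 0; k < d; ++k) {
        double diff = a(i, k) - b(j, k);
        cost += diff * diff;
      }
      cost = std::sqrt(cost);
      double best;
      if (i == 0 && j == 0) best = 0.0;
      else if (i == 0) best = cur[j - 1];
      else if (j == 0) best = prev[j];
      else best = std::min(prev[j], std::min(cur[j - 1], prev[j - 1]));
      cur[j] = cost + best;
    }
    std::swap(prev, cur);
  }
  return prev[m - 1];
}
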