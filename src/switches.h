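#ifndef STEMDISH_SWITCHES_H
#define STEMDISH_SWITCHES_H

#include <cmath>
#include <vector>

namespace stemdish {

inline double powh(double v, double n) {
  if (n == 4.0) { double v2 = v * v; return v2 * v2; }
  if (n == 2.0) return v * v;
  if (n == 1.0) return v;
  return std::pow(v, n);
}

// Generic two-variable regulatory switch
//   dx/dt = (ax + ex) x^n/(b^n + x^n) + ix b^n/(b^n + y^n) - g x
//   dy/dt = (ay + ey) y^n/(b^n + y^n) + iy b^n/(b^n + x^n) - g y
// ax = ay = 0 gives the mutual-repression bistable circuit (stem cells,
// signalling species); nonzero a gives the self-activating tristable one
// (progenitors), with e the additive signal-effect increment.
struct Switch {
  double ax, ay, ex, ey, ix, iy, hn, gamma, bn;
  Switch() : ax(0), ay(0), ex(0), ey(0), ix(0), iy(0), hn(1), gamma(1), bn(1) {}
  Switch(double ax_, double ay_, double ex_, double ey_,
         double ix_, double iy_, double beta, double hn_, double g)
      : ax(ax_), ay(ay_), ex(ex_), ey(ey_), ix(ix_), iy(iy_),
        hn(hn_), gamma(g), bn(powh(beta, hn_)) {}

  inline void drift(double x, double y, double &fx, double &fy) const {
    double xn = powh(x, hn), yn = powh(y, hn);
    fx = (ax + ex) * (xn / (bn + xn)) + ix * (bn / (bn + yn)) - gamma * x;
    fy = (ay + ey) * (yn / (bn + yn)) + iy * (bn / (bn + xn)) - gamma * y;
  }
};

struct Attractor { double x, y; int label; };

inline void rk4_step(const Switch &sw, double &x, double &y, double dt) {
  double k1x, k1y, k2x, k2y, k3x, k3y, k4x, k4y;
  sw.drift(x, y, k1x, k1y);
  sw.drift(x + 0.5 * dt * k1x, y + 0.5 * dt * k1y, k2x, k2y);
  sw.drift(x + 0.5 * dt * k2x, y + 0.5 * dt * k2y, k3x, k3y);
  sw.drift(x + dt * k3x, y + dt * k3y, k4x, k4y);
  x += dt / 6.0 * (k1x + 2 * k2x + 2 * k3x + k4x);
  y += dt / 6.0 * (k1y + 2 * k2y + 2 * k3y + k4y);
  if (x < 0) x = 0;
  if (y < 0) y = 0;
}

// Integrate until captured within capture_r of a stable fixed point or the
// drift speed falls below speed_tol; ties / non-convergence -> tie_label.
inline int classify_point(const Switch &sw, double x, double y,
                          const std::vector<Attractor> &att,
                          double dt, long max_steps, double speed_tol,
                          double capture_r, int tie_label) {
  const double cr2 = capture_r * capture_r;
  const double st2 = speed_tol * speed_tol;
  for (long s = 0; s < max_steps; ++s) {
    for (size_t a = 0; a < att.size(); ++a) {
      double ddx = x - att[a].x, ddy = y - att[a].y;
      if (ddx * ddx + ddy * ddy <= cr2) return att[a].label;
    }
    double fx, fy;
    sw.drift(x, y, fx, fy);
    if (fx * fx + fy * fy < st2) {
      int best = -1; double bd = cr2;
      for (size_t a = 0; a < att.size(); ++a) {
        double ddx = x - att[a].x, ddy = y - att[a].y, d2 = ddx * ddx + ddy * ddy;
        if (d2 <= bd) { bd = d2; best = (int)a; }
      }
      return best >= 0 ? att[best].label : tie_label;
    }
    rk4_step(sw, x, y, dt);
  }
  return tie_label;
}

// Stable fixed points by forward integration from a coarse seed grid,
// clustering converged endpoints.  Labels are left at 0 for the caller.
inline std::vector<Attractor> find_attractors(const Switch &sw, double xmax,
                                              double dt = 0.05,
                                              long max_steps = 200000,
                                              double cluster_tol = 2.0) {
  std::vector<Attractor> out;
  const int k = 7;
  for (int i = 0; i < k; ++i) {
    for (int j = 0; j < k; ++j) {
      double x = xmax * i / (k - 1.0), y = xmax * j / (k - 1.0);
      bool conv = false;
      for (long s = 0; s < max_steps; ++s) {
        double fx, fy;
        sw.drift(x, y, fx, fy);
        if (fx * fx + fy * fy < 1e-16) { conv = true; break; }
        rk4_step(sw, x, y, dt);
      }
      if (!conv) continue;
      bool merged = false;
      for (size_t a = 0; a < out.size(); ++a) {
        double ddx = x - out[a].x, ddy = y - out[a].y;
        if (ddx * ddx + ddy * ddy < cluster_tol * cluster_tol) { merged = true; break; }
      }
      if (!merged) out.push_back({x, y, 0});
    }
  }
  return out;
}

// Fate codes shared with the dish occupancy encoding: 1 S, 2 P, 3 A, 4 B.
inline void label_stem(std::vector<Attractor> &att) {
  for (size_t a = 0; a < att.size(); ++a)
    att[a].label = (att[a].x > att[a].y) ? 1 : 2;
}

inline void label_progenitor(std::vector<Attractor> &att) {
  for (size_t a = 0; a < att.size(); ++a) {
    if (att[a].x > 2.0 * att[a].y + 1.0) att[a].label = 3;
    else if (att[a].y > 2.0 * att[a].x + 1.0) att[a].label = 4;
    else att[a].label = 2;
  }
}

// Nearest-grid-point basin map on [0, xmax]^2 with the given step.
inline std::vector<signed char> build_map(const Switch &sw,
                                          const std::vector<Attractor> &att,
                                          double xmax, double step,
                                          int tie_label,
                                          double dt = 0.05,
                                          long max_steps = 100000,
                                          double speed_tol = 1e-6,
                                          double capture_r = 1.0) {
  int m = (int)std::floor(xmax / step + 1e-9) + 1;
  std::vector<signed char> map((size_t)m * m);
  for (int j = 0; j < m; ++j) {
    for (int i = 0; i < m; ++i) {
      map[(size_t)i + (size_t)m * j] = (signed char)classify_point(
          sw, i * step, j * step, att, dt, max_steps, speed_tol, capture_r,
          tie_label);
    }
  }
  return map;
}

} // namespace stemdish

#endif
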