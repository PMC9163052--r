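#include <Rcpp.h>
#include "switches.h"

using namespace Rcpp;
using namespace stemdish;

static Switch switch_from_list(const List &p) {
  return Switch(as<double>(p["ax"]), as<double>(p["ay"]),
                as<double>(p["ex"]), as<double>(p["ey"]),
                as<double>(p["ix"]), as<double>(p["iy"]),
                as<double>(p["beta"]), as<double>(p["hill_n"]),
                as<double>(p["gamma"]));
}

// [[Rcpp::export]]
NumericMatrix cpp_drift(List p, NumericVector x, NumericVector y) {
  Switch sw = switch_from_list(p);
  int n = x.size();
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    double fx, fy;
    sw.drift(x[i], y[i], fx, fy);
    out(i, 0) = fx;
    out(i, 1) = fy;
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_find_attractors(List p, double xmax) {
  Switch sw = switch_from_list(p);
  std::vector<Attractor> att = find_attractors(sw, xmax);
  NumericMatrix out(att.size(), 2);
  for (size_t a = 0; a < att.size(); ++a) {
    out(a, 0) = att[a].x;
    out(a, 1) = att[a].y;
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_classify(List p, NumericVector x, NumericVector y,
                           NumericMatrix attractors, IntegerVector labels,
                           double dt, double max_steps, double speed_tol,
                           double capture_r, int tie_label) {
  Switch sw = switch_from_list(p);
  std::vector<Attractor> att(attractors.nrow());
  for (int a = 0; a < attractors.nrow(); ++a)
    att[a] = {attractors(a, 0), attractors(a, 1), labels[a]};
  int n = x.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = classify_point(sw, x[i], y[i], att, dt, (long)max_steps,
                            speed_tol, capture_r, tie_label);
  return out;
}

// [[Rcpp::export]]
IntegerMatrix cpp_basin_map(List p, NumericMatrix attractors,
                            IntegerVector labels, double xmax, double step,
                            int tie_label) {
  Switch sw = switch_from_list(p);
  std::vector<Attractor> att(attractors.nrow());
  for (int a = 0; a < attractors.nrow(); ++a)
    att[a] = {attractors(a, 0), attractors(a, 1), labels[a]};
  std::vector<signed char> map = build_map(sw, att, xmax, step, tie_label);
  int m = (int)std::floor(xmax / step + 1e-9) + 1;
  IntegerMatrix out(m, m); // rows index x, cols index y
  for (int j = 0; j < m; ++j)
    for (int i = 0; i < m; ++i)
      out(i, j) = map[(size_t)i + (size_t)m * j];
  return out;
}
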