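// Exact Gillespie simulation of the 24-channel lattice model: per-cell
// determinant kinetics (Hill production, linear degradation), division with
// binomial partitioning and basin-lookup fate calling, S/P interconversion,
// death, movement to random empty meshes, and per-mesh signal production,
// decay and diffusion.  Propensities are kept per channel per mesh and
// updated incrementally after each event; channel totals are refreshed from
// scratch periodically to control floating-point drift.

#include <Rcpp.h>
#include "switches.h"
#include <map>
#include <cmath>

using namespace Rcpp;
using namespace stemdish;

namespace {

// channel indices (Table rows 1..24, zero-based)
enum {
  CH_SX_PROD = 0, CH_SX_DEG, CH_SY_PROD, CH_SY_DEG,
  CH_S_DIV, CH_S_DEATH, CH_S_TRANS, CH_S_MOVE,
  CH_PX_PROD, CH_PX_DEG, CH_PY_PROD, CH_PY_DEG,
  CH_P_DIV, CH_P_DEATH, CH_P_TRANS, CH_P_MOVE,
  CH_A_DEATH, CH_B_DEATH,
  CH_S1_PROD, CH_S1_DEG, CH_S2_PROD, CH_S2_DEG,
  CH_S1_DIFF, CH_S2_DIFF
};

struct ProgMap {
  std::vector<signed char> map;
  std::vector<int> plist; // grid indices labelled P, for determinant resampling
};

struct StemMapCache {
  std::vector<signed char> map;
  std::vector<int> slist;
};

// Session-wide caches: the fate maps depend only on switch parameters and
// the (quantised) signal-effect increments, so they are shared across
// runs instead of being rebuilt per simulation.
static std::map<std::string, ProgMap> g_progCache;
static std::map<std::string, StemMapCache> g_stemCache;

struct Engine {
  int H, W, N;
  std::vector<signed char> valid, occ;
  std::vector<int> xs, ys, divc, s1, s2;
  std::vector<std::vector<int> > nb4, nb8;

  double r_s, gamma_s, w_p, m_s, r_p, gamma_p, w_s, m_p, gamma_A, gamma_B;
  double iota_x0, iota_y, gamma_det_s, stem_bn, stem_hn;
  double alpha_x, alpha_y, iota_xp, iota_yp, gamma_det_p, prog_bn, prog_hn;
  double eps_a, eps_b;
  double alpha_s1, alpha_s2, sig_bn, sig_hn, k_sig, Dh2;
  bool signals_on, diff_scale, diff_weighted;
  double n0;
  int eps_levels;
  double prog_step, prog_max, stem_step, stem_max;
  double cls_dt, speed_tol, capture_r;
  long cls_steps;

  std::vector<double> prop; // 24 * N, channel-major
  std::vector<double> fen;  // 24 Fenwick trees (size N+1 each) over prop
  int fenN;
  double T[24], G;

  // Fenwick prefix-sum trees give O(log N) site selection within a
  // channel; the selection loop dominates runtime at acceptance scale.
  inline void fenAdd(int c, int i, double d) {
    double *f = &fen[(size_t)c * (fenN + 1)];
    for (int k = i + 1; k <= fenN; k += k & -k) f[k] += d;
  }
  inline int fenSearch(int c, double v) const {
    const double *f = &fen[(size_t)c * (fenN + 1)];
    int pos = 0, mask = 1;
    while ((mask << 1) <= fenN) mask <<= 1;
    for (; mask > 0; mask >>= 1) {
      int nxt = pos + mask;
      if (nxt <= fenN && f[nxt] < v) { pos = nxt; v -= f[nxt]; }
    }
    return pos; // 0-based mesh index, may equal N on fp drift
  }
  void fenRebuild() {
    std::fill(fen.begin(), fen.end(), 0.0);
    for (int c = 0; c < 24; ++c)
      for (int m = 0; m < N; ++m)
        if (prop[(size_t)c * N + m] != 0)
          fenAdd(c, m, prop[(size_t)c * N + m]);
  }

  long cntS, cntP, cntA, cntB;
  double sumDivP;
  int emptyCount;
  bool moveOpen;

  int stemM, progM;
  const std::vector<signed char> *stemMap;
  const std::vector<int> *stemSList;
  std::map<int, const ProgMap *> progCache;
  long progMapsBuilt;

  double ecount[24];
  long cSS, cSP, cPP, dPP, dPA, dPB, dAB, dAA, dBB;
  long noopMove, noopDiff;
  double expS, expP, expA, expB;

  // -- propensity plumbing ------------------------------------------------
  inline void setp(int c, int m, double v) {
    if (v < 0) {
      if (v < -1e-9) stop("negative propensity (channel %d)", c + 1);
      v = 0;
    }
    double d = v - prop[(size_t)c * N + m];
    if (d == 0) return;
    prop[(size_t)c * N + m] = v;
    fenAdd(c, m, d);
    T[c] += d;
    G += d;
  }

  inline double hillRep(double bn, double hn, double v) const {
    return bn / (bn + powh(v, hn));
  }
  inline double hillAct(double bn, double hn, double v) const {
    double vn = powh(v, hn);
    return vn / (bn + vn);
  }
  inline double epsOf(int s) const {
    if (!signals_on) return 0.0;
    return s <= eps_b ? eps_a * s / eps_b : eps_a;
  }
  inline double iotaN() const {
    double n = (double)(cntS + cntP);
    double excess = n > n0 ? n - n0 : 0.0;
    return iota_x0 * n0 / (n0 + excess);
  }
  inline bool hasEmpty8(int m) const {
    const std::vector<int> &nb = nb8[m];
    for (size_t k = 0; k < nb.size(); ++k)
      if (occ[nb[k]] == 0) return true;
    return false;
  }

  void recompCell(int m) {
    signed char o = occ[m];
    if (o == 1) {
      setp(CH_SX_PROD, m, iotaN() * hillRep(stem_bn, stem_hn, ys[m]));
      setp(CH_SX_DEG, m, gamma_det_s * xs[m]);
      setp(CH_SY_PROD, m, iota_y * hillRep(stem_bn, stem_hn, xs[m]));
      setp(CH_SY_DEG, m, gamma_det_s * ys[m]);
      setp(CH_S_DIV, m, hasEmpty8(m) ? r_s : 0.0);
      setp(CH_S_DEATH, m, gamma_s);
      setp(CH_S_TRANS, m, w_p);
      setp(CH_S_MOVE, m, moveOpen ? m_s : 0.0);
    } else {
      for (int c = CH_SX_PROD; c <= CH_S_MOVE; ++c) setp(c, m, 0.0);
    }
    if (o == 2) {
      setp(CH_PX_PROD, m,
           (alpha_x + epsOf(s1[m])) * hillAct(prog_bn, prog_hn, xs[m]) +
               iota_xp * hillRep(prog_bn, prog_hn, ys[m]));
      setp(CH_PX_DEG, m, gamma_det_p * xs[m]);
      setp(CH_PY_PROD, m,
           (alpha_y + epsOf(s2[m])) * hillAct(prog_bn, prog_hn, ys[m]) +
               iota_yp * hillRep(prog_bn, prog_hn, xs[m]));
      setp(CH_PY_DEG, m, gamma_det_p * ys[m]);
      setp(CH_P_DIV, m, hasEmpty8(m) ? r_p : 0.0);
      setp(CH_P_DEATH, m, gamma_p);
      setp(CH_P_TRANS, m, w_s);
      setp(CH_P_MOVE, m, moveOpen ? m_p : 0.0);
    } else {
      for (int c = CH_PX_PROD; c <= CH_P_MOVE; ++c) setp(c, m, 0.0);
    }
    setp(CH_A_DEATH, m, o == 3 ? gamma_A : 0.0);
    setp(CH_B_DEATH, m, o == 4 ? gamma_B : 0.0);
    setp(CH_S1_PROD, m, (signals_on && o == 3)
                            ? alpha_s1 * hillRep(sig_bn, sig_hn, s2[m])
                            : 0.0);
    setp(CH_S2_PROD, m, (signals_on && o == 4)
                            ? alpha_s2 * hillRep(sig_bn, sig_hn, s1[m])
                            : 0.0);
  }

  void recompSig(int m) {
    signed char o = occ[m];
    setp(CH_S1_DEG, m, k_sig * s1[m]);
    setp(CH_S2_DEG, m, k_sig * s2[m]);
    setp(CH_S1_DIFF, m, (signals_on && s1[m] > 0)
                            ? (diff_scale ? Dh2 * s1[m] : Dh2)
                            : 0.0);
    setp(CH_S2_DIFF, m, (signals_on && s2[m] > 0)
                            ? (diff_scale ? Dh2 * s2[m] : Dh2)
                            : 0.0);
    setp(CH_S1_PROD, m, (signals_on && o == 3)
                            ? alpha_s1 * hillRep(sig_bn, sig_hn, s2[m])
                            : 0.0);
    setp(CH_S2_PROD, m, (signals_on && o == 4)
                            ? alpha_s2 * hillRep(sig_bn, sig_hn, s1[m])
                            : 0.0);
    if (o == 2) { // local epsilon feeds the determinant production channels
      setp(CH_PX_PROD, m,
           (alpha_x + epsOf(s1[m])) * hillAct(prog_bn, prog_hn, xs[m]) +
               iota_xp * hillRep(prog_bn, prog_hn, ys[m]));
      setp(CH_PY_PROD, m,
           (alpha_y + epsOf(s2[m])) * hillAct(prog_bn, prog_hn, ys[m]) +
               iota_yp * hillRep(prog_bn, prog_hn, xs[m]));
    }
  }

  void gatingUpdate(int m) { // occupancy at m changed; neighbours' division gate
    const std::vector<int> &nb = nb8[m];
    for (size_t k = 0; k < nb.size(); ++k) {
      int q = nb[k];
      if (occ[q] == 1) setp(CH_S_DIV, q, hasEmpty8(q) ? r_s : 0.0);
      else if (occ[q] == 2) setp(CH_P_DIV, q, hasEmpty8(q) ? r_p : 0.0);
    }
  }

  void iotaAll() { // dividing-cell census changed; refresh channel 1 for all S
    double v = iotaN();
    for (int m = 0; m < N; ++m)
      if (occ[m] == 1) setp(CH_SX_PROD, m, v * hillRep(stem_bn, stem_hn, ys[m]));
  }

  void refreshMoveGate() {
    bool open = emptyCount > 0;
    if (open == moveOpen) return;
    moveOpen = open;
    for (int m = 0; m < N; ++m) {
      if (occ[m] == 1) setp(CH_S_MOVE, m, moveOpen ? m_s : 0.0);
      else if (occ[m] == 2) setp(CH_P_MOVE, m, moveOpen ? m_p : 0.0);
    }
  }

  void refreshTotals() {
    G = 0;
    for (int c = 0; c < 24; ++c) {
      double s = 0;
      const double *pc = &prop[(size_t)c * N];
      for (int m = 0; m < N; ++m) s += pc[m];
      T[c] = s;
      G += s;
    }
    fenRebuild();
  }

  void initProp() {
    std::fill(prop.begin(), prop.end(), 0.0);
    for (int c = 0; c < 24; ++c) T[c] = 0;
    G = 0;
    emptyCount = 0;
    for (int m = 0; m < N; ++m)
      if (valid[m] && occ[m] == 0) ++emptyCount;
    moveOpen = emptyCount > 0;
    for (int m = 0; m < N; ++m) {
      if (!valid[m]) continue;
      recompCell(m);
      recompSig(m);
    }
    refreshTotals();
  }

  // -- fate maps ----------------------------------------------------------
  Switch stemSwitch() const {
    return Switch(0, 0, 0, 0, iota_x0, iota_y,
                  std::pow(stem_bn, 1.0 / stem_hn), stem_hn, gamma_det_s);
  }
  Switch progSwitch(double ex, double ey) const {
    return Switch(alpha_x, alpha_y, ex, ey, iota_xp, iota_yp,
                  std::pow(prog_bn, 1.0 / prog_hn), prog_hn, gamma_det_p);
  }

  std::string mapKeyBase() const {
    char buf[256];
    snprintf(buf, sizeof(buf), "%g|%g|%g|%g|%g|%g|%g|%g|%g|%g|%g|%ld",
             alpha_x, alpha_y, iota_xp, iota_yp, prog_bn, prog_hn,
             gamma_det_p, prog_step, prog_max, cls_dt, capture_r, cls_steps);
    return std::string(buf);
  }

  void buildStemMap() {
    char buf[256];
    snprintf(buf, sizeof(buf), "stem|%g|%g|%g|%g|%g|%g|%g",
             iota_x0, iota_y, stem_bn, stem_hn, gamma_det_s, stem_max,
             stem_step);
    std::string key(buf);
    stemM = (int)std::floor(stem_max / stem_step + 1e-9) + 1;
    std::map<std::string, StemMapCache>::iterator it = g_stemCache.find(key);
    if (it == g_stemCache.end()) {
      Switch sw = stemSwitch();
      std::vector<Attractor> att = find_attractors(sw, stem_max);
      label_stem(att);
      StemMapCache c;
      c.map = build_map(sw, att, stem_max, stem_step, 2, cls_dt, cls_steps,
                        speed_tol, capture_r);
      for (size_t i = 0; i < c.map.size(); ++i)
        if (c.map[i] == 1) c.slist.push_back((int)i);
      if (c.slist.empty())
        stop("stem switch has no S basin at these parameters");
      it = g_stemCache.insert(std::make_pair(key, c)).first;
    }
    stemMap = &it->second.map;
    stemSList = &it->second.slist;
  }

  inline int epsLevel(int s) const {
    if (!signals_on) return 0;
    double f = s >= eps_b ? 1.0 : (double)s / eps_b;
    return (int)std::floor(f * (eps_levels - 1) + 0.5);
  }

  const ProgMap &progMapFor(int l1, int l2) {
    int key = l1 * eps_levels + l2;
    std::map<int, const ProgMap *>::iterator it = progCache.find(key);
    if (it != progCache.end()) return *it->second;
    double ex = eps_a * l1 / (eps_levels - 1.0);
    double ey = eps_a * l2 / (eps_levels - 1.0);
    char buf[64];
    snprintf(buf, sizeof(buf), "|%g|%g", ex, ey);
    std::string gkey = mapKeyBase() + buf;
    std::map<std::string, ProgMap>::iterator git = g_progCache.find(gkey);
    if (git == g_progCache.end()) {
      Switch sw = progSwitch(ex, ey);
      std::vector<Attractor> att = find_attractors(sw, prog_max);
      label_progenitor(att);
      ProgMap pm;
      pm.map = build_map(sw, att, prog_max, prog_step, 2, cls_dt, cls_steps,
                         speed_tol, capture_r);
      for (size_t i = 0; i < pm.map.size(); ++i)
        if (pm.map[i] == 2) pm.plist.push_back((int)i);
      git = g_progCache.insert(std::make_pair(gkey, pm)).first;
      ++progMapsBuilt;
    }
    progCache.insert(std::make_pair(key, &git->second));
    return git->second;
  }

  inline int stemLookup(int x, int y) const {
    int i = (int)std::floor(std::min((double)x, stem_max) / stem_step + 0.5);
    int j = (int)std::floor(std::min((double)y, stem_max) / stem_step + 0.5);
    return (*stemMap)[(size_t)i + (size_t)stemM * j];
  }
  inline int progLookup(const ProgMap &pm, int x, int y) const {
    int i = (int)std::floor(std::min((double)x, prog_max) / prog_step + 0.5);
    int j = (int)std::floor(std::min((double)y, prog_max) / prog_step + 0.5);
    return pm.map[(size_t)i + (size_t)progM * j];
  }

  void sampleStemS(int &x, int &y) {
    const std::vector<int> &sl = *stemSList;
    int idx = sl[(int)(unif_rand() * sl.size()) % sl.size()];
    x = (int)std::floor((idx % stemM) * stem_step + 0.5);
    y = (int)std::floor((idx / stemM) * stem_step + 0.5);
  }
  void sampleProgP(int mesh, int &x, int &y) {
    const ProgMap *pm = &progMapFor(epsLevel(s1[mesh]), epsLevel(s2[mesh]));
    if (pm->plist.empty()) pm = &progMapFor(0, 0);
    if (pm->plist.empty()) stop("progenitor switch has no P basin");
    int idx = pm->plist[(int)(unif_rand() * pm->plist.size()) % pm->plist.size()];
    x = (int)std::floor((idx % progM) * prog_step + 0.5);
    y = (int)std::floor((idx / progM) * prog_step + 0.5);
  }

  // -- events -------------------------------------------------------------
  void clearMesh(int m) {
    occ[m] = 0;
    xs[m] = ys[m] = divc[m] = 0;
  }

  void applyDeath(int m) {
    signed char o = occ[m];
    if (o == 1) --cntS;
    else if (o == 2) { --cntP; sumDivP -= divc[m]; }
    else if (o == 3) --cntA;
    else if (o == 4) --cntB;
    clearMesh(m);
    ++emptyCount;
    refreshMoveGate();
    recompCell(m);
    gatingUpdate(m);
    if (o == 1 || o == 2) iotaAll();
  }

  // S <-> P flip; determinants resample from the target system's basin.
  // The division counter travels with the lineage (it is not reset):
  // resetting it would let the transformation churn (w_s per P cell far
  // exceeds the space-gated division rate) wipe counters faster than
  // divisions accumulate, and the mean-division termination metric could
  // never be reached.
  void applyTransform(int m) {
    if (occ[m] == 1) { // S -> P
      --cntS; ++cntP; sumDivP += divc[m];
      occ[m] = 2;
      sampleProgP(m, xs[m], ys[m]);
    } else { // P -> S
      --cntP; sumDivP -= divc[m]; ++cntS;
      occ[m] = 1;
      sampleStemS(xs[m], ys[m]);
    }
    recompCell(m);
  }

  void applyMove(int m) {
    if (emptyCount <= 0) { ++noopMove; return; }
    int r = (int)(unif_rand() * emptyCount) % emptyCount, e = -1;
    for (int q = 0; q < N; ++q) {
      if (valid[q] && occ[q] == 0 && r-- == 0) { e = q; break; }
    }
    if (e < 0) { ++noopMove; return; }
    occ[e] = occ[m]; xs[e] = xs[m]; ys[e] = ys[m]; divc[e] = divc[m];
    clearMesh(m);
    recompCell(m); recompCell(e);
    gatingUpdate(m); gatingUpdate(e);
  }

  void applyDivision(int m, bool stem_mother) {
    int cand[8], nc = 0;
    const std::vector<int> &nb = nb8[m];
    for (size_t k = 0; k < nb.size(); ++k)
      if (occ[nb[k]] == 0) cand[nc++] = nb[k];
    if (nc == 0) return; // channel is gated; defensive
    int e = cand[(int)(unif_rand() * nc) % nc];
    int mx = xs[m], my = ys[m], divm = divc[m];
    int dx[2], dy[2], lab[2], meshes[2] = {m, e};
    dx[0] = (int)R::rbinom(mx, 0.5); dx[1] = mx - dx[0];
    dy[0] = (int)R::rbinom(my, 0.5); dy[1] = my - dy[0];
    if (stem_mother) --cntS; else { --cntP; sumDivP -= divm; }
    for (int d = 0; d < 2; ++d) {
      int mm = meshes[d];
      if (stem_mother) {
        lab[d] = stemLookup(dx[d], dy[d]);
        occ[mm] = (signed char)lab[d];
        if (lab[d] == 2) { // new system: resample from the local P basin
          sampleProgP(mm, xs[mm] = 0, ys[mm] = 0);
          ++cntP; sumDivP += divm;
        } else {
          xs[mm] = dx[d]; ys[mm] = dy[d];
          ++cntS;
        }
        divc[mm] = divm;
      } else {
        const ProgMap &pm = progMapFor(epsLevel(s1[mm]), epsLevel(s2[mm]));
        lab[d] = progLookup(pm, dx[d], dy[d]);
        occ[mm] = (signed char)lab[d];
        if (lab[d] == 2) {
          xs[mm] = dx[d]; ys[mm] = dy[d]; divc[mm] = divm + 1;
          ++cntP; sumDivP += divm + 1;
        } else {
          xs[mm] = ys[mm] = 0; divc[mm] = 0;
          if (lab[d] == 3) ++cntA; else ++cntB;
        }
      }
    }
    if (stem_mother) {
      int nP = (lab[0] == 2) + (lab[1] == 2);
      if (nP == 0) ++cSS; else if (nP == 1) ++cSP; else ++cPP;
    } else {
      int a = std::min(lab[0], lab[1]), b = std::max(lab[0], lab[1]);
      if (a == 2 && b == 2) ++dPP;
      else if (a == 2 && b == 3) ++dPA;
      else if (a == 2 && b == 4) ++dPB;
      else if (a == 3 && b == 4) ++dAB;
      else if (a == 3) ++dAA;
      else ++dBB;
    }
    --emptyCount;
    refreshMoveGate();
    iotaAll();
    recompCell(m); recompCell(e);
    gatingUpdate(m); gatingUpdate(e);
  }

  int diffuseTarget(int m, const std::vector<int> &scnt) {
    const std::vector<int> &nb = nb4[m];
    if (nb.empty()) return -1;
    if (!diff_weighted) return nb[(int)(unif_rand() * nb.size()) % nb.size()];
    double tot = 0;
    for (size_t k = 0; k < nb.size(); ++k) tot += 1.0 + scnt[nb[k]];
    double u = unif_rand() * tot, acc = 0;
    for (size_t k = 0; k < nb.size(); ++k) {
      acc += 1.0 + scnt[nb[k]];
      if (u <= acc) return nb[k];
    }
    return nb[nb.size() - 1];
  }

  void applyEvent(int c, int m) {
    switch (c) {
    case CH_SX_PROD: ++xs[m];
      setp(CH_SX_DEG, m, gamma_det_s * xs[m]);
      setp(CH_SY_PROD, m, iota_y * hillRep(stem_bn, stem_hn, xs[m]));
      break;
    case CH_SX_DEG: --xs[m];
      setp(CH_SX_DEG, m, gamma_det_s * xs[m]);
      setp(CH_SY_PROD, m, iota_y * hillRep(stem_bn, stem_hn, xs[m]));
      break;
    case CH_SY_PROD: ++ys[m];
      setp(CH_SY_DEG, m, gamma_det_s * ys[m]);
      setp(CH_SX_PROD, m, iotaN() * hillRep(stem_bn, stem_hn, ys[m]));
      break;
    case CH_SY_DEG: --ys[m];
      setp(CH_SY_DEG, m, gamma_det_s * ys[m]);
      setp(CH_SX_PROD, m, iotaN() * hillRep(stem_bn, stem_hn, ys[m]));
      break;
    case CH_S_DIV: applyDivision(m, true); break;
    case CH_S_DEATH: applyDeath(m); break;
    case CH_S_TRANS: applyTransform(m); break;
    case CH_S_MOVE: applyMove(m); break;
    case CH_PX_PROD: ++xs[m]; progDetChans(m); break;
    case CH_PX_DEG: --xs[m]; progDetChans(m); break;
    case CH_PY_PROD: ++ys[m]; progDetChans(m); break;
    case CH_PY_DEG: --ys[m]; progDetChans(m); break;
    case CH_P_DIV: applyDivision(m, false); break;
    case CH_P_DEATH: applyDeath(m); break;
    case CH_P_TRANS: applyTransform(m); break;
    case CH_P_MOVE: applyMove(m); break;
    case CH_A_DEATH: applyDeath(m); break;
    case CH_B_DEATH: applyDeath(m); break;
    case CH_S1_PROD: ++s1[m]; recompSig(m); break;
    case CH_S1_DEG: --s1[m]; recompSig(m); break;
    case CH_S2_PROD: ++s2[m]; recompSig(m); break;
    case CH_S2_DEG: --s2[m]; recompSig(m); break;
    case CH_S1_DIFF: {
      int t = diffuseTarget(m, s1);
      if (t < 0) { ++noopDiff; break; }
      --s1[m]; ++s1[t];
      recompSig(m); recompSig(t);
      break;
    }
    case CH_S2_DIFF: {
      int t = diffuseTarget(m, s2);
      if (t < 0) { ++noopDiff; break; }
      --s2[m]; ++s2[t];
      recompSig(m); recompSig(t);
      break;
    }
    }
  }

  void progDetChans(int m) { // x/y of a P cell changed
    setp(CH_PX_PROD, m,
         (alpha_x + epsOf(s1[m])) * hillAct(prog_bn, prog_hn, xs[m]) +
             iota_xp * hillRep(prog_bn, prog_hn, ys[m]));
    setp(CH_PX_DEG, m, gamma_det_p * xs[m]);
    setp(CH_PY_PROD, m,
         (alpha_y + epsOf(s2[m])) * hillAct(prog_bn, prog_hn, ys[m]) +
             iota_yp * hillRep(prog_bn, prog_hn, xs[m]));
    setp(CH_PY_DEG, m, gamma_det_p * ys[m]);
  }

  void applyInjury(const IntegerVector &meshes) {
    for (int k = 0; k < meshes.size(); ++k) {
      int m = meshes[k];
      if (m < 0 || m >= N || !valid[m] || occ[m] == 0) continue;
      signed char o = occ[m];
      if (o == 1) --cntS;
      else if (o == 2) { --cntP; sumDivP -= divc[m]; }
      else if (o == 3) --cntA;
      else --cntB;
      clearMesh(m);
    }
    initProp(); // full rebuild: occupancy changed over a whole region
  }
};

} // namespace

// [[Rcpp::export]]
List cpp_simulate(List dish, List cfg, List injuries) {
  Engine E;
  E.H = as<int>(dish["height"]); E.W = as<int>(dish["width"]);
  E.N = E.H * E.W;
  IntegerVector v = dish["valid"], o = dish["occ"], x = dish["x"],
                y = dish["y"], dv = dish["div"], a1 = dish["s1"],
                a2 = dish["s2"];
  E.valid.assign(E.N, 0); E.occ.assign(E.N, 0);
  E.xs.assign(E.N, 0); E.ys.assign(E.N, 0); E.divc.assign(E.N, 0);
  E.s1.assign(E.N, 0); E.s2.assign(E.N, 0);
  for (int m = 0; m < E.N; ++m) {
    E.valid[m] = (signed char)v[m];
    E.occ[m] = (signed char)o[m];
    E.xs[m] = x[m]; E.ys[m] = y[m]; E.divc[m] = dv[m];
    E.s1[m] = a1[m]; E.s2[m] = a2[m];
  }

  // neighbour lists (4-adjacency for diffusion, 8 for daughter placement)
  E.nb4.resize(E.N); E.nb8.resize(E.N);
  for (int c = 0; c < E.W; ++c) {
    for (int r = 0; r < E.H; ++r) {
      int m = r + E.H * c;
      if (!E.valid[m]) continue;
      for (int dc = -1; dc <= 1; ++dc) {
        for (int dr = -1; dr <= 1; ++dr) {
          if (dr == 0 && dc == 0) continue;
          int rr = r + dr, cc = c + dc;
          if (rr < 0 || rr >= E.H || cc < 0 || cc >= E.W) continue;
          int q = rr + E.H * cc;
          if (!E.valid[q]) continue;
          E.nb8[m].push_back(q);
          if (dr == 0 || dc == 0) E.nb4[m].push_back(q);
        }
      }
    }
  }

  E.r_s = as<double>(cfg["r_s"]); E.gamma_s = as<double>(cfg["gamma_s"]);
  E.w_p = as<double>(cfg["w_p"]); E.m_s = as<double>(cfg["m_s"]);
  E.r_p = as<double>(cfg["r_p"]); E.gamma_p = as<double>(cfg["gamma_p"]);
  E.w_s = as<double>(cfg["w_s"]); E.m_p = as<double>(cfg["m_p"]);
  E.gamma_A = as<double>(cfg["gamma_A"]); E.gamma_B = as<double>(cfg["gamma_B"]);
  E.iota_x0 = as<double>(cfg["iota_xs"]); E.iota_y = as<double>(cfg["iota_ys"]);
  E.gamma_det_s = as<double>(cfg["gamma_det_s"]);
  E.stem_hn = as<double>(cfg["hill_s"]);
  E.stem_bn = powh(as<double>(cfg["beta_s"]), E.stem_hn);
  E.alpha_x = as<double>(cfg["alpha_xp"]); E.alpha_y = as<double>(cfg["alpha_yp"]);
  E.iota_xp = as<double>(cfg["iota_xp"]); E.iota_yp = as<double>(cfg["iota_yp"]);
  E.gamma_det_p = as<double>(cfg["gamma_det_p"]);
  E.prog_hn = as<double>(cfg["hill_p"]);
  E.prog_bn = powh(as<double>(cfg["beta_p"]), E.prog_hn);
  E.eps_a = as<double>(cfg["eps_a"]); E.eps_b = as<double>(cfg["eps_b"]);
  E.alpha_s1 = as<double>(cfg["alpha_s1"]); E.alpha_s2 = as<double>(cfg["alpha_s2"]);
  E.sig_hn = as<double>(cfg["hill_sig"]);
  E.sig_bn = powh(as<double>(cfg["beta_sig"]), E.sig_hn);
  E.k_sig = as<double>(cfg["k_sig"]);
  double h = as<double>(cfg["h"]);
  E.Dh2 = as<double>(cfg["D"]) / (h * h);
  E.signals_on = as<bool>(cfg["signals_on"]);
  E.diff_scale = as<bool>(cfg["diffusion_scales_with_count"]);
  E.diff_weighted = as<std::string>(cfg["diffusion_neighbor_rule"]) == "weighted";
  E.eps_levels = as<int>(cfg["eps_levels"]);
  E.prog_step = as<double>(cfg["prog_map_step"]);
  E.prog_max = as<double>(cfg["prog_map_max"]);
  E.stem_step = as<double>(cfg["stem_map_step"]);
  E.stem_max = as<double>(cfg["stem_map_max"]);
  E.cls_dt = as<double>(cfg["classify_dt"]);
  E.cls_steps = (long)as<double>(cfg["classify_max_steps"]);
  E.speed_tol = as<double>(cfg["classify_speed_tol"]);
  E.capture_r = as<double>(cfg["classify_capture_r"]);
  double term_div = as<double>(cfg["termination_divisions"]);
  int n_shots = as<int>(cfg["n_shots"]);
  double max_time = as<double>(cfg["max_time"]);
  double max_events = as<double>(cfg["max_events"]);
  long log_max = (long)as<double>(cfg["log_max"]);

  E.cntS = E.cntP = E.cntA = E.cntB = 0;
  E.sumDivP = 0;
  for (int m = 0; m < E.N; ++m) {
    if (E.occ[m] == 1) ++E.cntS;
    else if (E.occ[m] == 2) { ++E.cntP; E.sumDivP += E.divc[m]; }
    else if (E.occ[m] == 3) ++E.cntA;
    else if (E.occ[m] == 4) ++E.cntB;
  }
  double cfg_n0 = as<double>(cfg["iota_n0"]);
  E.n0 = cfg_n0 > 0 ? cfg_n0 : (double)(E.cntS + E.cntP);
  if (E.n0 <= 0) E.n0 = 1;

  E.progM = (int)std::floor(E.prog_max / E.prog_step + 1e-9) + 1;
  E.progMapsBuilt = 0;
  E.buildStemMap();

  E.prop.assign((size_t)24 * E.N, 0.0);
  E.fenN = E.N;
  E.fen.assign((size_t)24 * (E.N + 1), 0.0);
  E.initProp();
  NumericVector T0(24);
  for (int c = 0; c < 24; ++c) T0[c] = E.T[c];
  double G0 = E.G;

  for (int c = 0; c < 24; ++c) E.ecount[c] = 0;
  E.cSS = E.cSP = E.cPP = 0;
  E.dPP = E.dPA = E.dPB = E.dAB = E.dAA = E.dBB = 0;
  E.noopMove = E.noopDiff = 0;
  E.expS = E.expP = E.expA = E.expB = 0;

  // injuries: fire once when the mean P division count crosses the trigger
  int nInj = injuries.size();
  std::vector<bool> fired(nInj, false);
  std::vector<double> triggers(nInj);
  for (int k = 0; k < nInj; ++k)
    triggers[k] = as<double>(as<List>(injuries[k])["trigger"]);

  bool had_dividing = (E.cntS + E.cntP) > 0;

  // snapshot ring with dt doubling; thinned to n_shots in R
  std::vector<double> snapT;
  std::vector<std::vector<signed char> > snapOcc;
  std::vector<double> snapS, snapP, snapA, snapB, snapDiv;
  double snap_dt = as<double>(cfg["snapshot_dt0"]);
  size_t snapCap = (size_t)(2 * n_shots + 2);
  double nextSnap = 0.0;

  std::vector<double> logT; std::vector<int> logC, logM;

  double t = 0;
  double nEvents = 0;
  std::string status = "running";

  #define TAKE_SNAP(tt)                                               \
    do {                                                              \
      snapT.push_back(tt);                                            \
      snapOcc.push_back(std::vector<signed char>(E.occ));             \
      snapS.push_back((double)E.cntS); snapP.push_back((double)E.cntP); \
      snapA.push_back((double)E.cntA); snapB.push_back((double)E.cntB); \
      snapDiv.push_back(E.cntP > 0 ? E.sumDivP / E.cntP : NA_REAL);   \
    } while (0)

  TAKE_SNAP(0.0);
  nextSnap = snap_dt;

  while (true) {
    if (E.G <= 1e-12) { status = had_dividing && (E.cntS + E.cntP) == 0 ? "extinct" : "exhausted"; break; }
    double dt = exp_rand() / E.G;
    double tn = t + dt;
    if (tn > max_time) {
      // hold state to the horizon; snapshots on the way out
      while (nextSnap <= max_time) {
        TAKE_SNAP(nextSnap);
        nextSnap += snap_dt;
        if (snapT.size() >= snapCap) {
          std::vector<double> t2; std::vector<std::vector<signed char> > o2;
          std::vector<double> s2v, p2, a2v, b2, d2;
          for (size_t i = 0; i < snapT.size(); i += 2) {
            t2.push_back(snapT[i]); o2.push_back(snapOcc[i]);
            s2v.push_back(snapS[i]); p2.push_back(snapP[i]);
            a2v.push_back(snapA[i]); b2.push_back(snapB[i]); d2.push_back(snapDiv[i]);
          }
          snapT.swap(t2); snapOcc.swap(o2); snapS.swap(s2v); snapP.swap(p2);
          snapA.swap(a2v); snapB.swap(b2); snapDiv.swap(d2);
          snap_dt *= 2; nextSnap = snapT.back() + snap_dt;
        }
      }
      double hold = max_time - t;
      E.expS += E.cntS * hold; E.expP += E.cntP * hold;
      E.expA += E.cntA * hold; E.expB += E.cntB * hold;
      t = max_time;
      status = "max_time";
      break;
    }
    E.expS += E.cntS * dt; E.expP += E.cntP * dt;
    E.expA += E.cntA * dt; E.expB += E.cntB * dt;
    while (nextSnap <= tn) {
      TAKE_SNAP(nextSnap);
      nextSnap += snap_dt;
      if (snapT.size() >= snapCap) {
        std::vector<double> t2; std::vector<std::vector<signed char> > o2;
        std::vector<double> s2v, p2, a2v, b2, d2;
        for (size_t i = 0; i < snapT.size(); i += 2) {
          t2.push_back(snapT[i]); o2.push_back(snapOcc[i]);
          s2v.push_back(snapS[i]); p2.push_back(snapP[i]);
          a2v.push_back(snapA[i]); b2.push_back(snapB[i]); d2.push_back(snapDiv[i]);
        }
        snapT.swap(t2); snapOcc.swap(o2); snapS.swap(s2v); snapP.swap(p2);
        snapA.swap(a2v); snapB.swap(b2); snapDiv.swap(d2);
        snap_dt *= 2; nextSnap = snapT.back() + snap_dt;
      }
    }
    t = tn;

    // channel, then site within channel
    double u = unif_rand() * E.G;
    int c = 0; double acc = 0;
    for (; c < 24; ++c) {
      if (u < acc + E.T[c]) break;
      acc += E.T[c];
    }
    if (c == 24) {
      E.refreshTotals();
      continue;
    }
    double vv = u - acc;
    const double *pc = &E.prop[(size_t)c * E.N];
    int m = E.fenSearch(c, vv);
    if (m >= E.N || pc[m] <= 0) { // fp drift: fall back to a clean state
      m = -1;
      for (int i = E.N - 1; i >= 0; --i)
        if (pc[i] > 0) { m = i; break; }
      if (m < 0) { E.refreshTotals(); continue; }
    }

    if (log_max > 0 && (long)logT.size() < log_max) {
      logT.push_back(t); logC.push_back(c + 1); logM.push_back(m + 1);
    }
    E.applyEvent(c, m);
    E.ecount[c] += 1;
    nEvents += 1;

    if (((long)nEvents & 0xFFFF) == 0) E.refreshTotals();

    double meanDiv = E.cntP > 0 ? E.sumDivP / E.cntP : 0.0;
    for (int k = 0; k < nInj; ++k) {
      if (!fired[k] && meanDiv >= triggers[k]) {
        fired[k] = true;
        E.applyInjury(as<IntegerVector>(as<List>(injuries[k])["meshes"]));
        meanDiv = E.cntP > 0 ? E.sumDivP / E.cntP : 0.0;
      }
    }
    if (E.cntP > 0 && meanDiv >= term_div) { status = "divisions"; break; }
    if (had_dividing && E.cntS + E.cntP == 0) { status = "extinct"; break; }
    if (nEvents >= max_events) { status = "max_events"; break; }
  }
  TAKE_SNAP(t); // final state

  #undef TAKE_SNAP

  int nsnap = (int)snapT.size();
  IntegerMatrix snaps(E.N, nsnap);
  for (int k = 0; k < nsnap; ++k)
    for (int m = 0; m < E.N; ++m) snaps(m, k) = snapOcc[k][m];

  IntegerVector occF(E.N), xF(E.N), yF(E.N), dF(E.N), s1F(E.N), s2F(E.N);
  for (int m = 0; m < E.N; ++m) {
    occF[m] = E.occ[m]; xF[m] = E.xs[m]; yF[m] = E.ys[m];
    dF[m] = E.divc[m]; s1F[m] = E.s1[m]; s2F[m] = E.s2[m];
  }

  NumericVector ec(24);
  for (int c = 0; c < 24; ++c) ec[c] = E.ecount[c];

  return List::create(
      _["status"] = status,
      _["t_end"] = t,
      _["n_events"] = nEvents,
      _["mean_divisions"] = E.cntP > 0 ? E.sumDivP / E.cntP : NA_REAL,
      _["snap_times"] = snapT,
      _["snapshots"] = snaps,
      _["snap_counts"] = DataFrame::create(
          _["time"] = snapT, _["n_S"] = snapS, _["n_P"] = snapP,
          _["n_A"] = snapA, _["n_B"] = snapB, _["mean_div"] = snapDiv),
      _["final"] = List::create(_["occ"] = occF, _["x"] = xF, _["y"] = yF,
                                _["div"] = dF, _["s1"] = s1F, _["s2"] = s2F),
      _["event_counts"] = ec,
      _["division_outcomes"] = NumericVector::create(
          _["S_SS"] = (double)E.cSS, _["S_SP"] = (double)E.cSP,
          _["S_PP"] = (double)E.cPP, _["P_PP"] = (double)E.dPP,
          _["P_PA"] = (double)E.dPA, _["P_PB"] = (double)E.dPB,
          _["P_AB"] = (double)E.dAB, _["P_AA"] = (double)E.dAA,
          _["P_BB"] = (double)E.dBB),
      _["exposure"] = NumericVector::create(
          _["S"] = E.expS, _["P"] = E.expP, _["A"] = E.expA, _["B"] = E.expB),
      _["noop"] = NumericVector::create(_["move"] = (double)E.noopMove,
                                        _["diffusion"] = (double)E.noopDiff),
      _["initial_total"] = G0,
      _["initial_channel_totals"] = T0,
      _["injury_fired"] = LogicalVector(fired.begin(), fired.end()),
      _["event_log"] = DataFrame::create(_["time"] = logT, _["channel"] = logC,
                                         _["mesh"] = logM),
      _["prog_maps_built"] = (int)E.progMapsBuilt);
}
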