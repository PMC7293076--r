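// Simulation core: 2D arena, differential-drive hunters, ray sensors,
// sigmoid MLP controllers, timed capture rule.  This is the fast path used
// by runTrial(); every operation here also has a pure-R reference
// implementation in R/ and the two are property-tested for agreement.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const int N_IN = 49;    // 12 proximity + 12 camera rays x 3 + bias
static const int N_HID = 8;
static const int N_GENES = 410; // 49*8 + 9*2

struct Params {
  double W, H;
  int nBoars, nStags, trialSteps, captureSteps;
  double robotR, preyR, wheelMax, axle, proxRange;
  double payBoar, payStag, paySolo;
  double diag;
};

static Params getParams(const List& cfg) {
  Params p;
  p.W = as<double>(cfg["arena_width"]);
  p.H = as<double>(cfg["arena_height"]);
  p.nBoars = as<int>(cfg["n_boars"]);
  p.nStags = as<int>(cfg["n_stags"]);
  p.trialSteps = as<int>(cfg["trial_steps"]);
  p.captureSteps = as<int>(cfg["capture_steps"]);
  p.robotR = as<double>(cfg["robot_radius"]);
  p.preyR = as<double>(cfg["prey_radius"]);
  p.wheelMax = as<double>(cfg["wheel_speed_max"]);
  p.axle = as<double>(cfg["axle_length"]);
  p.proxRange = as<double>(cfg["prox_range"]);
  p.payBoar = as<double>(cfg["boar_coop"]);
  p.payStag = as<double>(cfg["stag_coop"]);
  p.paySolo = as<double>(cfg["solo"]);
  p.diag = std::sqrt(p.W * p.W + p.H * p.H);
  return p;
}

struct World {
  double rx[2], ry[2], rth[2];
  std::vector<double> px, py;
  std::vector<int> kind;   // 0 = boar, 1 = stag
  std::vector<int> cnt;    // consecutive >=1-hunter contact steps
  std::vector<int> sA, sB; // step index where current contact streak began, -1 if none
  int step;
  double rew[2];
  std::vector<int> evStep, evKind, evFirst; // first: 0 = A, 1 = B
  std::vector<int> evCoop;
  long touch[2][2];        // contact-streak onsets: [robot][prey kind]
};

// Ray direction tables (relative to heading, rotated at use time).
// Proximity rays: 30-degree increments starting at the heading.
// Camera rays: centers of 12 equal 7.5-degree sectors spanning heading +/- 45.
struct RayTables {
  double prx[12], pry[12], cmx[12], cmy[12];
  RayTables() {
    for (int k = 0; k < 12; k++) {
      double a = k * 30.0 * M_PI / 180.0;
      prx[k] = std::cos(a); pry[k] = std::sin(a);
      double b = (-45.0 + 3.75 + 7.5 * k) * M_PI / 180.0;
      cmx[k] = std::cos(b); cmy[k] = std::sin(b);
    }
  }
};
static const RayTables RAYS;

// First non-negative ray parameter t with origin->(dx,dy) hitting the circle
// centred at (cx,cy) relative to the origin, radius r. Returns -1 on miss.
// An origin inside the circle reports t = 0 (contact).
static inline double rayCircle(double cx, double cy, double c2, double r2,
                               double dx, double dy) {
  double b = cx * dx + cy * dy;
  if (b < 0.0) return (c2 < r2) ? 0.0 : -1.0;
  double disc = b * b - c2 + r2;
  if (disc < 0.0) return -1.0;
  double s = std::sqrt(disc);
  double t = b - s;
  if (t >= 0.0) return t;
  if (c2 < r2) return 0.0;
  return -1.0;
}

// Fill the 49 input activations for robot ri from the current (pre-step)
// state. Also exports cos/sin of the heading so the actuation step can reuse
// them (the displacement uses the pre-step heading).
static void sense(const World& w, const Params& p, int ri, double* in,
                  double* cthOut, double* sthOut) {
  const double x = w.rx[ri], y = w.ry[ri], th = w.rth[ri];
  const double cth = std::cos(th), sth = std::sin(th);
  *cthOut = cth; *sthOut = sth;
  const int oi = 1 - ri;
  const int n = (int)w.px.size();
  // Obstacle circles: other robot first (type hunter), then prey.
  // Types: 1 hunter, 2 boar, 3 stag (two-bit code b1 = t>>1, b2 = t&1).
  // Scratch buffers are reused across calls to keep the hot loop
  // allocation-free.
  const int m = n + 1;
  static thread_local std::vector<double> CX, CY, C2, CR, R2, UX, UY, CHW, CONE;
  static thread_local std::vector<int> CT;
  static thread_local std::vector<char> NEAR;
  if ((int)CX.size() != m) {
    CX.resize(m); CY.resize(m); C2.resize(m); CR.resize(m); R2.resize(m);
    UX.resize(m); UY.resize(m); CHW.resize(m); CONE.resize(m);
    CT.resize(m); NEAR.resize(m);
  }
  CX[0] = w.rx[oi] - x; CY[0] = w.ry[oi] - y; CR[0] = p.robotR; CT[0] = 1;
  for (int j = 0; j < n; j++) {
    CX[j + 1] = w.px[j] - x; CY[j + 1] = w.py[j] - y;
    CR[j + 1] = p.preyR; CT[j + 1] = 2 + w.kind[j];
  }
  // Conservative camera cone cull: a circle whose angular interval
  // (bearing +/- half-width) lies beyond the outermost camera rays, by
  // more than a safety margin, cannot intersect any camera ray and is
  // skipped wholesale; boundary cases fall through to the exact test so
  // results match the R reference bit for bit.
  const double cosExtreme = 0.75183980747897738; // cos(41.25 deg)
  const double sinExtreme = 0.65934581510006886; // sin(41.25 deg)
  for (int j = 0; j < m; j++) {
    C2[j] = CX[j] * CX[j] + CY[j] * CY[j];
    double reach = p.proxRange + p.robotR + CR[j];
    NEAR[j] = (C2[j] <= reach * reach) ? 1 : 0;
    double r2 = CR[j] * CR[j];
    R2[j] = r2;
    if (C2[j] <= r2) {
      CHW[j] = -2.0; CONE[j] = -2.0; UX[j] = 0.0; UY[j] = 0.0;  // inside
    } else {
      double inv = 1.0 / std::sqrt(C2[j]);
      UX[j] = CX[j] * inv; UY[j] = CY[j] * inv;
      double coshw = std::sqrt(1.0 - r2 / C2[j]);
      double sinhw = CR[j] * inv;
      CHW[j] = coshw - 1e-6;
      CONE[j] = cosExtreme * coshw - sinExtreme * sinhw - 1e-6;
    }
  }
  // Rotate the fixed ray tables into world frame once.
  double PRX[12], PRY[12], CMX[12], CMY[12];
  for (int k = 0; k < 12; k++) {
    PRX[k] = cth * RAYS.prx[k] - sth * RAYS.pry[k];
    PRY[k] = sth * RAYS.prx[k] + cth * RAYS.pry[k];
    CMX[k] = cth * RAYS.cmx[k] - sth * RAYS.cmy[k];
    CMY[k] = sth * RAYS.cmx[k] + cth * RAYS.cmy[k];
  }
  // Proximity: rays from the body surface, activation 1 - d/range.
  // Walls can only register when the robot is within sensing reach of one;
  // otherwise the wall distance exceeds the range on every ray and the
  // activation is 0 regardless, so the ray-wall work is skipped.
  double PT[12];
  double wallReach = p.proxRange + p.robotR;
  bool wallNear = x <= wallReach || p.W - x <= wallReach ||
                  y <= wallReach || p.H - y <= wallReach;
  if (wallNear) {
    for (int k = 0; k < 12; k++) {
      double dx = PRX[k], dy = PRY[k];
      double t = 1e300;
      if (dx > 1e-300)       { double tw = (p.W - x) / dx; if (tw < t) t = tw; }
      else if (dx < -1e-300) { double tw = (0.0 - x) / dx; if (tw < t) t = tw; }
      if (dy > 1e-300)       { double tw = (p.H - y) / dy; if (tw < t) t = tw; }
      else if (dy < -1e-300) { double tw = (0.0 - y) / dy; if (tw < t) t = tw; }
      PT[k] = t;
    }
  } else {
    for (int k = 0; k < 12; k++) PT[k] = 1e300;
  }
  for (int j = 0; j < m; j++) {
    if (!NEAR[j]) continue;
    for (int k = 0; k < 12; k++) {
      if (PRX[k] * UX[j] + PRY[k] * UY[j] < CHW[j]) continue;
      double tc = rayCircle(CX[j], CY[j], C2[j], R2[j], PRX[k], PRY[k]);
      if (tc >= 0.0 && tc < PT[k]) PT[k] = tc;
    }
  }
  for (int k = 0; k < 12; k++) {
    double d = PT[k] - p.robotR;
    if (d < 0.0) d = 0.0;
    in[k] = (d <= p.proxRange) ? 1.0 - d / p.proxRange : 0.0;
  }
  // Camera: nearest agent per ray, walls invisible, unlimited range,
  // proximity 1 - d/diag with d from the robot centre to the agent surface.
  double BT[12]; int TY[12];
  for (int k = 0; k < 12; k++) { BT[k] = 1e300; TY[k] = 0; }
  for (int j = 0; j < m; j++) {
    if (UX[j] * cth + UY[j] * sth < CONE[j]) continue;  // outside camera cone
    for (int k = 0; k < 12; k++) {
      if (CMX[k] * UX[j] + CMY[k] * UY[j] < CHW[j]) continue;
      double tc = rayCircle(CX[j], CY[j], C2[j], R2[j], CMX[k], CMY[k]);
      if (tc >= 0.0 && tc < BT[k]) { BT[k] = tc; TY[k] = CT[j]; }
    }
  }
  for (int k = 0; k < 12; k++) {
    double* slot = in + 12 + 3 * k;
    if (TY[k] == 0) {
      slot[0] = 0.0; slot[1] = 0.0; slot[2] = 0.0;
    } else {
      slot[0] = (TY[k] >> 1) & 1;
      slot[1] = TY[k] & 1;
      double a = 1.0 - BT[k] / p.diag;
      slot[2] = (a < 0.0) ? 0.0 : a;
    }
  }
  in[48] = 1.0;
}

// Sigmoid MLP, gene layout: genes[(i*8)+j] = input i -> hidden j (i in 0..48),
// genes[392 + h*2 + o] = hidden h -> output o (h = 8 is the hidden-layer bias).
// Two-way unrolled accumulation (even/odd inputs) to break the
// floating-point dependency chain; the R reference reproduces the same
// summation order exactly.
__attribute__((target_clones("arch=haswell","default")))
static void mlp(const double* g, const double* in, double* out) {
  double a0[N_HID], a1[N_HID];
  for (int j = 0; j < N_HID; j++) { a0[j] = 0.0; a1[j] = 0.0; }
  int i = 0;
  for (; i + 1 < N_IN; i += 2) {
    const double v0 = in[i], v1 = in[i + 1];
    const double* r0 = g + i * N_HID;
    for (int j = 0; j < N_HID; j++) {
      a0[j] += v0 * r0[j];
      a1[j] += v1 * r0[j + N_HID];
    }
  }
  for (; i < N_IN; i++) {
    const double v = in[i];
    const double* row = g + i * N_HID;
    for (int j = 0; j < N_HID; j++) a0[j] += v * row[j];
  }
  double h[N_HID];
  for (int j = 0; j < N_HID; j++) h[j] = a0[j] + a1[j];
  for (int j = 0; j < N_HID; j++) h[j] = 1.0 / (1.0 + std::exp(-h[j]));
  for (int o = 0; o < 2; o++) {
    double s = 0.0;
    for (int j = 0; j < N_HID; j++) s += h[j] * g[392 + j * 2 + o];
    s += g[392 + 8 * 2 + o]; // hidden-layer bias weight
    out[o] = 1.0 / (1.0 + std::exp(-s));
  }
}

static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Differential-drive update: command c in [0,1] -> wheel velocity (2c-1)*vmax;
// displacement along the old heading, then the heading update.
static inline void actuate(World& w, const Params& p, int ri,
                           double cl, double cr, double cth, double sth) {
  double vl = (2.0 * cl - 1.0) * p.wheelMax;
  double vr = (2.0 * cr - 1.0) * p.wheelMax;
  double lin = 0.5 * (vl + vr);
  w.rx[ri] = clampd(w.rx[ri] + lin * cth, p.robotR, p.W - p.robotR);
  w.ry[ri] = clampd(w.ry[ri] + lin * sth, p.robotR, p.H - p.robotR);
  w.rth[ri] += (vr - vl) / p.axle;
  if (w.rth[ri] > M_PI) w.rth[ri] -= 2.0 * M_PI;
  else if (w.rth[ri] < -M_PI) w.rth[ri] += 2.0 * M_PI;
}

static inline void pushApart(World& w, const Params& p) {
  double dx = w.rx[1] - w.rx[0], dy = w.ry[1] - w.ry[0];
  double d2 = dx * dx + dy * dy, lim = 2.0 * p.robotR;
  if (d2 >= lim * lim) return;
  double d = std::sqrt(d2), ux, uy;
  if (d < 1e-9) { ux = 1.0; uy = 0.0; d = 0.0; } else { ux = dx / d; uy = dy / d; }
  double half = 0.5 * (lim - d);
  w.rx[0] = clampd(w.rx[0] - half * ux, p.robotR, p.W - p.robotR);
  w.ry[0] = clampd(w.ry[0] - half * uy, p.robotR, p.H - p.robotR);
  w.rx[1] = clampd(w.rx[1] + half * ux, p.robotR, p.W - p.robotR);
  w.ry[1] = clampd(w.ry[1] + half * uy, p.robotR, p.H - p.robotR);
}

static inline void respawn(World& w, const Params& p, int i) {
  w.px[i] = p.preyR + unif_rand() * (p.W - 2.0 * p.preyR);
  w.py[i] = p.preyR + unif_rand() * (p.H - 2.0 * p.preyR);
  w.cnt[i] = 0; w.sA[i] = -1; w.sB[i] = -1;
}

// Contact bookkeeping and the timed capture/payoff rule for one step.
static void updateCaptures(World& w, const Params& p) {
  const double lim = p.robotR + p.preyR, lim2 = lim * lim;
  const int n = (int)w.px.size();
  for (int i = 0; i < n; i++) {
    double ax = w.rx[0] - w.px[i], ay = w.ry[0] - w.py[i];
    double bx = w.rx[1] - w.px[i], by = w.ry[1] - w.py[i];
    bool cA = ax * ax + ay * ay <= lim2;
    bool cB = bx * bx + by * by <= lim2;
    if (cA) { if (w.sA[i] < 0) { w.sA[i] = w.step; w.touch[0][w.kind[i]]++; } }
    else w.sA[i] = -1;
    if (cB) { if (w.sB[i] < 0) { w.sB[i] = w.step; w.touch[1][w.kind[i]]++; } }
    else w.sB[i] = -1;
    if (cA || cB) w.cnt[i]++; else w.cnt[i] = 0;
    if (w.cnt[i] >= p.captureSteps) {
      bool coop = cA && cB;
      int first;
      if (coop) first = (w.sA[i] <= w.sB[i]) ? 0 : 1;
      else first = cA ? 0 : 1;
      if (coop) {
        double pay = (w.kind[i] == 0) ? p.payBoar : p.payStag;
        w.rew[0] += pay; w.rew[1] += pay;
      } else {
        w.rew[0] += (first == 0) ? p.paySolo : 0.0;
        w.rew[1] += (first == 1) ? p.paySolo : 0.0;
      }
      w.evStep.push_back(w.step); w.evKind.push_back(w.kind[i]);
      w.evCoop.push_back(coop ? 1 : 0); w.evFirst.push_back(first);
      respawn(w, p, i);
    }
  }
}

static void stepCore(World& w, const Params& p,
                     const double* cA, const double* cB,
                     const double* trig) {
  actuate(w, p, 0, cA[0], cA[1], trig[0], trig[1]);
  actuate(w, p, 1, cB[0], cB[1], trig[2], trig[3]);
  pushApart(w, p);
  updateCaptures(w, p);
  w.step++;
}

static void initWorldCore(World& w, const Params& p) {
  w.rx[0] = p.W / 2.0 - 1.5 * p.robotR;
  w.rx[1] = p.W / 2.0 + 1.5 * p.robotR;
  w.ry[0] = w.ry[1] = p.H - 2.0 * p.robotR;
  w.rth[0] = w.rth[1] = -M_PI / 2.0;
  int n = p.nBoars + p.nStags;
  w.px.resize(n); w.py.resize(n); w.kind.resize(n);
  w.cnt.assign(n, 0); w.sA.assign(n, -1); w.sB.assign(n, -1);
  for (int i = 0; i < n; i++) {
    w.kind[i] = (i < p.nBoars) ? 0 : 1;
    w.px[i] = p.preyR + unif_rand() * (p.W - 2.0 * p.preyR);
    w.py[i] = p.preyR + unif_rand() * (p.H - 2.0 * p.preyR);
  }
  w.step = 0; w.rew[0] = w.rew[1] = 0.0;
  w.touch[0][0] = w.touch[0][1] = w.touch[1][0] = w.touch[1][1] = 0;
}

static List worldToList(const World& w) {
  return List::create(
    _["rx"] = NumericVector(w.rx, w.rx + 2),
    _["ry"] = NumericVector(w.ry, w.ry + 2),
    _["rth"] = NumericVector(w.rth, w.rth + 2),
    _["px"] = wrap(w.px), _["py"] = wrap(w.py),
    _["kind"] = wrap(w.kind), _["counter"] = wrap(w.cnt),
    _["streak_a"] = wrap(w.sA), _["streak_b"] = wrap(w.sB),
    _["step"] = w.step,
    _["rewards"] = NumericVector(w.rew, w.rew + 2),
    _["ev_step"] = wrap(w.evStep), _["ev_kind"] = wrap(w.evKind),
    _["ev_coop"] = wrap(w.evCoop), _["ev_first"] = wrap(w.evFirst),
    _["touches"] = IntegerVector::create(
        (int)w.touch[0][0], (int)w.touch[1][0],
        (int)w.touch[0][1], (int)w.touch[1][1]));
}

static void worldFromList(const List& st, World& w) {
  NumericVector rx = st["rx"], ry = st["ry"], rth = st["rth"];
  for (int i = 0; i < 2; i++) { w.rx[i] = rx[i]; w.ry[i] = ry[i]; w.rth[i] = rth[i]; }
  w.px = as<std::vector<double> >(st["px"]);
  w.py = as<std::vector<double> >(st["py"]);
  w.kind = as<std::vector<int> >(st["kind"]);
  w.cnt = as<std::vector<int> >(st["counter"]);
  w.sA = as<std::vector<int> >(st["streak_a"]);
  w.sB = as<std::vector<int> >(st["streak_b"]);
  w.step = as<int>(st["step"]);
  NumericVector rw = st["rewards"];
  w.rew[0] = rw[0]; w.rew[1] = rw[1];
  w.evStep = as<std::vector<int> >(st["ev_step"]);
  w.evKind = as<std::vector<int> >(st["ev_kind"]);
  w.evCoop = as<std::vector<int> >(st["ev_coop"]);
  w.evFirst = as<std::vector<int> >(st["ev_first"]);
  IntegerVector tc = st["touches"];
  w.touch[0][0] = tc[0]; w.touch[1][0] = tc[1];
  w.touch[0][1] = tc[2]; w.touch[1][1] = tc[3];
}

// [[Rcpp::export]]
List cppInitWorld(List cfg) {
  Params p = getParams(cfg);
  World w;
  initWorldCore(w, p);
  return worldToList(w);
}

// [[Rcpp::export]]
List cppStepWorld(List state, NumericVector commandsA, NumericVector commandsB,
                  List cfg) {
  Params p = getParams(cfg);
  World w;
  worldFromList(state, w);
  double cA[2] = { commandsA[0], commandsA[1] };
  double cB[2] = { commandsB[0], commandsB[1] };
  double trig[4] = { std::cos(w.rth[0]), std::sin(w.rth[0]),
                     std::cos(w.rth[1]), std::sin(w.rth[1]) };
  stepCore(w, p, cA, cB, trig);
  return worldToList(w);
}

// [[Rcpp::export]]
NumericVector cppSense(List state, int robot, List cfg) {
  Params p = getParams(cfg);
  World w;
  worldFromList(state, w);
  NumericVector out(N_IN);
  double in[N_IN], c0, s0;
  sense(w, p, robot - 1, in, &c0, &s0);
  for (int i = 0; i < N_IN; i++) out[i] = in[i];
  return out;
}

// [[Rcpp::export]]
NumericVector cppMlpForward(NumericVector genes, NumericVector inputs) {
  if (genes.size() != N_GENES) stop("gene vector must have length 410");
  if (inputs.size() != N_IN) stop("input vector must have length 49");
  double out[2];
  mlp(REAL(genes), REAL(inputs), out);
  return NumericVector::create(out[0], out[1]);
}

// Run a whole trial: sense -> MLP -> step, trialSteps times. Sensing always
// uses the pre-step snapshot; both robots are updated synchronously.
// [[Rcpp::export]]
List cppRunTrial(NumericVector weightsA, NumericVector weightsB, List cfg,
                 bool recordTrajectory = false) {
  if (weightsA.size() != N_GENES || weightsB.size() != N_GENES)
    stop("gene vector must have length 410");
  Params p = getParams(cfg);
  World w;
  initWorldCore(w, p);
  const double* gA = REAL(weightsA);
  const double* gB = REAL(weightsB);
  double inA[N_IN], inB[N_IN], cA[2], cB[2];
  NumericMatrix traj;
  if (recordTrajectory) traj = NumericMatrix(p.trialSteps, 6);
  double trig[4];
  for (int s = 0; s < p.trialSteps; s++) {
    sense(w, p, 0, inA, trig, trig + 1); mlp(gA, inA, cA);
    sense(w, p, 1, inB, trig + 2, trig + 3); mlp(gB, inB, cB);
    stepCore(w, p, cA, cB, trig);
    if (recordTrajectory) {
      traj(s, 0) = w.rx[0]; traj(s, 1) = w.ry[0]; traj(s, 2) = w.rth[0];
      traj(s, 3) = w.rx[1]; traj(s, 4) = w.ry[1]; traj(s, 5) = w.rth[1];
    }
  }
  List out = List::create(
    _["rewards"] = NumericVector(w.rew, w.rew + 2),
    _["ev_step"] = wrap(w.evStep), _["ev_kind"] = wrap(w.evKind),
    _["ev_coop"] = wrap(w.evCoop), _["ev_first"] = wrap(w.evFirst),
    _["touches"] = IntegerVector::create(
        (int)w.touch[0][0], (int)w.touch[1][0],
        (int)w.touch[0][1], (int)w.touch[1][1]),
    _["steps_run"] = p.trialSteps,
    _["final_state"] = worldToList(w));
  if (recordTrajectory) out["trajectory"] = traj;
  return out;
}
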