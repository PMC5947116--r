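// Core numerics: rate-expression evaluation, membrane RHS, fixed-step Heun
// (deterministic and stochastic), adaptive Dormand-Prince with spike-event
// localisation / Poincare-section recording, and DPSS taper construction.
//
// Gating-rate expressions arrive from R as flat bytecode vectors compiled
// from the kinetics definition file; see R/kinetics.R for the compiler.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Rate-expression bytecode VM
//
// opcodes (encoded as doubles): 0 PUSH_CONST c, 1 PUSH_X, 2 ADD, 3 SUB,
// 4 MUL, 5 DIV, 6 NEG, 7 EXP.  x is V (mV) for voltage-dependent rates and
// time-since-spike (ms) for the AHP opening rate.
// ---------------------------------------------------------------------------

static const double TSS_NONE = 1e9; // "no spike yet" sentinel for t_since_spike

static double eval_code(const std::vector<double>& code, double x) {
  double st[32];
  int sp = 0;
  size_t i = 0, n = code.size();
  while (i < n) {
    int op = (int) code[i++];
    switch (op) {
    case 0: st[sp++] = code[i++]; break;
    case 1: st[sp++] = x; break;
    case 2: sp--; st[sp - 1] += st[sp]; break;
    case 3: sp--; st[sp - 1] -= st[sp]; break;
    case 4: sp--; st[sp - 1] *= st[sp]; break;
    case 5: sp--; st[sp - 1] /= st[sp]; break;
    case 6: st[sp - 1] = -st[sp - 1]; break;
    case 7: st[sp - 1] = std::exp(st[sp - 1]); break;
    }
  }
  double v = st[0];
  // removable singularity of linear-over-exponential forms (0/0): nudge x
  if (!std::isfinite(v)) {
    i = 0; sp = 0;
    double xx = x + 1e-8;
    while (i < n) {
      int op = (int) code[i++];
      switch (op) {
      case 0: st[sp++] = code[i++]; break;
      case 1: st[sp++] = xx; break;
      case 2: sp--; st[sp - 1] += st[sp]; break;
      case 3: sp--; st[sp - 1] -= st[sp]; break;
      case 4: sp--; st[sp - 1] *= st[sp]; break;
      case 5: sp--; st[sp - 1] /= st[sp]; break;
      case 6: st[sp - 1] = -st[sp - 1]; break;
      case 7: st[sp - 1] = std::exp(st[sp - 1]); break;
      }
    }
    v = st[0];
  }
  return v;
}

// ---------------------------------------------------------------------------
// Model representation
// ---------------------------------------------------------------------------

struct Gate {
  std::vector<double> alpha, beta;
  bool ahp;    // alpha is a function of time-since-spike, not V
  bool frozen; // derivative forced to zero (fast-slow freezing, AHP clamping)
  bool tab;    // voltage rates pre-tabulated (fixed-step batch work)
  std::vector<double> atab, btab;
};

// rate-table grid: covers the admissible voltage range of the integrators
static const double TAB_V0 = -150.0, TAB_V1 = 100.0, TAB_DV = 0.02;

struct Chan {
  double g, E;
  std::vector<int> gidx; // 0-based gate indices
  std::vector<int> expo;
};

struct Model {
  double C, Iapp, sigma, thr, refract;
  std::vector<Gate> gates;
  std::vector<Chan> chans;
};

static Model parse_model(const List& m) {
  Model mod;
  mod.C = as<double>(m["C"]);
  mod.Iapp = as<double>(m["Iapp"]);
  mod.sigma = as<double>(m["sigma"]);
  mod.thr = as<double>(m["spike_threshold"]);
  mod.refract = as<double>(m["refract"]);
  bool tabulate = m.containsElementNamed("tabulate") && as<bool>(m["tabulate"]);
  List gl = m["gates"];
  for (int i = 0; i < gl.size(); ++i) {
    List g = gl[i];
    Gate gt;
    NumericVector a = g["alpha"], b = g["beta"];
    gt.alpha.assign(a.begin(), a.end());
    gt.beta.assign(b.begin(), b.end());
    gt.ahp = as<bool>(g["ahp"]);
    gt.frozen = as<bool>(g["frozen"]);
    gt.tab = tabulate && !gt.ahp && !gt.frozen;
    if (gt.tab) {
      int n = (int) ((TAB_V1 - TAB_V0) / TAB_DV) + 2;
      gt.atab.resize(n);
      gt.btab.resize(n);
      for (int j = 0; j < n; ++j) {
        double v = TAB_V0 + j * TAB_DV;
        gt.atab[j] = eval_code(gt.alpha, v);
        gt.btab[j] = eval_code(gt.beta, v);
      }
    }
    mod.gates.push_back(gt);
  }
  List cl = m["channels"];
  for (int i = 0; i < cl.size(); ++i) {
    List c = cl[i];
    Chan ch;
    ch.g = as<double>(c["g"]);
    ch.E = as<double>(c["E"]);
    IntegerVector gi = c["gidx"], ex = c["expo"];
    for (int k = 0; k < gi.size(); ++k) {
      ch.gidx.push_back(gi[k] - 1);
      ch.expo.push_back(ex[k]);
    }
    mod.chans.push_back(ch);
  }
  return mod;
}

// y = (V, x_1, ..., x_ng); returns dy, ionic current sum optional
static void rhs(const Model& mod, const double* y, double tss, double* dy) {
  double V = y[0];
  double Isum = 0.0;
  for (size_t c = 0; c < mod.chans.size(); ++c) {
    const Chan& ch = mod.chans[c];
    if (ch.g == 0.0) continue;
    double psi = 1.0;
    for (size_t k = 0; k < ch.gidx.size(); ++k) {
      double xv = y[1 + ch.gidx[k]];
      for (int e = 0; e < ch.expo[k]; ++e) psi *= xv;
    }
    Isum += ch.g * psi * (V - ch.E);
  }
  dy[0] = (mod.Iapp - Isum) / mod.C;
  for (size_t i = 0; i < mod.gates.size(); ++i) {
    const Gate& g = mod.gates[i];
    if (g.frozen) { dy[1 + i] = 0.0; continue; }
    double a, b;
    if (g.tab) {
      double u = (V - TAB_V0) / TAB_DV;
      int n = (int) g.atab.size();
      if (u < 0.0) u = 0.0;
      if (u > n - 2) u = n - 2;
      int j = (int) u;
      double w = u - j;
      a = g.atab[j] + w * (g.atab[j + 1] - g.atab[j]);
      b = g.btab[j] + w * (g.btab[j + 1] - g.btab[j]);
    } else {
      double xarg = g.ahp ? tss : V;
      a = eval_code(g.alpha, xarg);
      b = eval_code(g.beta, xarg);
    }
    dy[1 + i] = a * (1.0 - y[1 + i]) - b * y[1 + i];
  }
}

// [[Rcpp::export]]
NumericVector rhs_cpp(List model, NumericVector y, double tss) {
  Model mod = parse_model(model);
  int n = y.size();
  NumericVector dy(n);
  rhs(mod, y.begin(), tss, dy.begin());
  return dy;
}

// [[Rcpp::export]]
double eval_rate_cpp(NumericVector code, double x) {
  std::vector<double> c(code.begin(), code.end());
  return eval_code(c, x);
}

// ---------------------------------------------------------------------------
// Fixed-step Heun (deterministic when sigma = 0; stochastic Heun otherwise).
// Additive white noise enters the V equation only; the same Wiener increment
// is used in the predictor and corrector stages.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List heun_cpp(List model, NumericVector y0, double tss0, double duration,
              double dt, int stride) {
  Model mod = parse_model(model);
  int n = y0.size();
  long nstep = (long) std::floor(duration / dt + 0.5);
  long nrec = nstep / stride + 1;
  NumericVector tr(nrec);
  NumericMatrix yr(nrec, n);
  std::vector<double> spikes;
  std::vector<double> y(y0.begin(), y0.end()), yp(n), f0(n), f1(n);
  double tss = tss0;
  double t = 0.0;
  double noise_scale = mod.sigma / mod.C;
  bool stochastic = mod.sigma > 0.0;
  bool diverged = false;
  long irec = 0;
  tr[irec] = 0.0;
  for (int j = 0; j < n; ++j) yr(irec, j) = y[j];
  irec++;
  double last_spike = -TSS_NONE;
  double sqdt = std::sqrt(dt);

  for (long i = 0; i < nstep; ++i) {
    double w = stochastic ? noise_scale * sqdt * R::norm_rand() : 0.0;
    rhs(mod, y.data(), tss, f0.data());
    for (int j = 0; j < n; ++j) yp[j] = y[j] + dt * f0[j];
    yp[0] += w;
    rhs(mod, yp.data(), tss + dt, f1.data());
    double Vold = y[0];
    for (int j = 0; j < n; ++j) y[j] += 0.5 * dt * (f0[j] + f1[j]);
    y[0] += w;
    // numerical guard: the exact flow keeps gating fractions in [0,1]
    for (int j = 1; j < n; ++j) {
      if (y[j] < 0.0) y[j] = 0.0;
      else if (y[j] > 1.0) y[j] = 1.0;
    }
    t = (i + 1) * dt;
    tss += dt;
    // upward threshold crossing -> spike event (linear interpolation)
    if (Vold < mod.thr && y[0] >= mod.thr) {
      double frac = (mod.thr - Vold) / (y[0] - Vold);
      double tspike = t - dt + frac * dt;
      if (tspike - last_spike >= mod.refract) {
        spikes.push_back(tspike);
        last_spike = tspike;
        tss = t - tspike;
      }
    }
    if (!std::isfinite(y[0]) || std::fabs(y[0]) > 200.0) {
      diverged = true;
      break;
    }
    if ((i + 1) % stride == 0 && irec < nrec) {
      tr[irec] = t;
      for (int j = 0; j < n; ++j) yr(irec, j) = y[j];
      irec++;
    }
  }
  if (irec < nrec) { // diverged early: truncate records
    tr = NumericVector(tr.begin(), tr.begin() + irec);
    NumericMatrix yr2(irec, n);
    for (long r = 0; r < irec; ++r)
      for (int j = 0; j < n; ++j) yr2(r, j) = yr(r, j);
    yr = yr2;
  }
  return List::create(_["t"] = tr, _["y"] = yr,
                      _["spikes"] = NumericVector(spikes.begin(), spikes.end()),
                      _["y_end"] = NumericVector(y.begin(), y.end()),
                      _["tss_end"] = tss, _["diverged"] = diverged);
}

// ---------------------------------------------------------------------------
// Adaptive Dormand-Prince 5(4) with event localisation at upward crossings
// of the spike threshold (the Poincare section V = 0 in default use).
// ---------------------------------------------------------------------------

static const double DP_C[7] = {0.0, 1.0 / 5, 3.0 / 10, 4.0 / 5, 8.0 / 9, 1.0, 1.0};
static const double DP_A[7][6] = {
  {0, 0, 0, 0, 0, 0},
  {1.0 / 5, 0, 0, 0, 0, 0},
  {3.0 / 40, 9.0 / 40, 0, 0, 0, 0},
  {44.0 / 45, -56.0 / 15, 32.0 / 9, 0, 0, 0},
  {19372.0 / 6561, -25360.0 / 2187, 64448.0 / 6561, -212.0 / 729, 0, 0},
  {9017.0 / 3168, -355.0 / 33, 46732.0 / 5247, 49.0 / 176, -5103.0 / 18656, 0},
  {35.0 / 384, 0, 500.0 / 1113, 125.0 / 192, -2187.0 / 6784, 11.0 / 84}};
static const double DP_B5[7] = {35.0 / 384, 0, 500.0 / 1113, 125.0 / 192,
                                -2187.0 / 6784, 11.0 / 84, 0};
static const double DP_B4[7] = {5179.0 / 57600, 0, 7571.0 / 16695, 393.0 / 640,
                                -92097.0 / 339200, 187.0 / 2100, 1.0 / 40};

// single DP step of size h from (y, tss); writes y5 (5th order) and err norm
static double dp_step(const Model& mod, const std::vector<double>& y,
                      double tss, double h, std::vector<double>& y5,
                      double rtol, double atol) {
  int n = (int) y.size();
  static thread_local std::vector<double> k[7], ytmp;
  for (int s = 0; s < 7; ++s) k[s].resize(n);
  ytmp.resize(n);
  rhs(mod, y.data(), tss, k[0].data());
  for (int s = 1; s < 7; ++s) {
    for (int j = 0; j < n; ++j) {
      double acc = 0.0;
      for (int q = 0; q < s; ++q) acc += DP_A[s][q] * k[q][j];
      ytmp[j] = y[j] + h * acc;
    }
    rhs(mod, ytmp.data(), tss + DP_C[s] * h, k[s].data());
  }
  double err = 0.0;
  for (int j = 0; j < n; ++j) {
    double s5 = 0.0, s4 = 0.0;
    for (int s = 0; s < 7; ++s) {
      s5 += DP_B5[s] * k[s][j];
      s4 += DP_B4[s] * k[s][j];
    }
    y5[j] = y[j] + h * s5;
    double sc = atol + rtol * std::max(std::fabs(y[j]), std::fabs(y5[j]));
    double e = h * (s5 - s4) / sc;
    err += e * e;
  }
  return std::sqrt(err / n);
}

// [[Rcpp::export]]
List dopri_cpp(List model, NumericVector y0, double tss0, double duration,
               double rtol, double atol, int max_crossings, bool record,
               double hmax, double record_dt) {
  Model mod = parse_model(model);
  int n = y0.size();
  std::vector<double> y(y0.begin(), y0.end()), ynew(n), ytry(n);
  double t = 0.0, tss = tss0;
  double h = 1e-3;
  std::vector<double> rec_t, rec_flat, spikes, cross_t, cross_flat, cross_isi;
  double last_spike = -TSS_NONE;
  bool failed = false;
  double next_rec = 0.0;
  if (record) {
    rec_t.push_back(t);
    for (int j = 0; j < n; ++j) rec_flat.push_back(y[j]);
    next_rec = record_dt;
  }
  long iter = 0;
  while (t < duration) {
    if (++iter > 100000000L) { failed = true; break; }
    if (h > hmax) h = hmax;
    if (t + h > duration) h = duration - t;
    double err = dp_step(mod, y, tss, h, ynew, rtol, atol);
    if (err > 1.0) {
      h *= std::max(0.2, 0.9 * std::pow(err, -0.2));
      if (h < 1e-12) { failed = true; break; }
      continue;
    }
    // accepted; check for upward threshold crossing within the step
    double Vold = y[0], Vnew = ynew[0];
    bool crossed = (Vold < mod.thr && Vnew >= mod.thr);
    if (crossed && (t + h) - last_spike >= mod.refract) {
      // bisection on sub-step size for the crossing time
      double lo = 0.0, hi = h;
      std::vector<double> ycr(ynew);
      for (int it = 0; it < 80 && (hi - lo) > 1e-14 * std::max(1.0, h); ++it) {
        double mid = 0.5 * (lo + hi);
        dp_step(mod, y, tss, mid, ytry, rtol, atol);
        if (ytry[0] >= mod.thr) { hi = mid; ycr = ytry; }
        else lo = mid;
      }
      double tcr = t + hi;
      spikes.push_back(tcr);
      cross_t.push_back(tcr);
      cross_isi.push_back(tss + hi); // time since previous spike at crossing
      for (int j = 0; j < n; ++j) cross_flat.push_back(ycr[j]);
      last_spike = tcr;
      // resume from the crossing with the spike clock reset
      t = tcr;
      y = ycr;
      tss = 0.0;
      if (record && t >= next_rec) {
        rec_t.push_back(t);
        for (int j = 0; j < n; ++j) rec_flat.push_back(y[j]);
        while (next_rec <= t) next_rec += record_dt;
      }
      if (max_crossings > 0 && (int) cross_t.size() >= max_crossings) break;
      h = std::min(h, 1e-2);
      continue;
    }
    t += h;
    tss += h;
    y = ynew;
    for (int j = 1; j < n; ++j) {
      if (y[j] < 0.0) y[j] = 0.0;
      else if (y[j] > 1.0) y[j] = 1.0;
    }
    if (!std::isfinite(y[0]) || std::fabs(y[0]) > 200.0) { failed = true; break; }
    if (record && t >= next_rec) {
      rec_t.push_back(t);
      for (int j = 0; j < n; ++j) rec_flat.push_back(y[j]);
      while (next_rec <= t) next_rec += record_dt;
    }
    h *= std::min(5.0, std::max(0.2, 0.9 * std::pow(std::max(err, 1e-10), -0.2)));
  }
  int ncr = (int) cross_t.size();
  NumericMatrix cross(ncr, n);
  for (int r = 0; r < ncr; ++r)
    for (int j = 0; j < n; ++j) cross(r, j) = cross_flat[(size_t) r * n + j];
  List out = List::create(
      _["spikes"] = NumericVector(spikes.begin(), spikes.end()),
      _["cross_t"] = NumericVector(cross_t.begin(), cross_t.end()),
      _["cross_y"] = cross,
      _["cross_isi"] = NumericVector(cross_isi.begin(), cross_isi.end()),
      _["y_end"] = NumericVector(y.begin(), y.end()), _["t_end"] = t,
      _["tss_end"] = tss, _["failed"] = failed);
  if (record) {
    int nr = (int) rec_t.size();
    NumericMatrix yr(nr, n);
    for (int r = 0; r < nr; ++r)
      for (int j = 0; j < n; ++j) yr(r, j) = rec_flat[(size_t) r * n + j];
    out["t"] = NumericVector(rec_t.begin(), rec_t.end());
    out["y"] = yr;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Discrete prolate spheroidal sequences via the symmetric tridiagonal
// commuting matrix (Slepian): Sturm-sequence bisection for the K largest
// eigenvalues, inverse iteration for eigenvectors.
// ---------------------------------------------------------------------------

// count of eigenvalues of tridiag(d, e) strictly greater than x
static int sturm_count_gt(const std::vector<double>& d,
                          const std::vector<double>& e, double x) {
  int n = (int) d.size(), cnt = 0;
  double q = d[0] - x;
  if (q > 0) cnt++;
  for (int i = 1; i < n; ++i) {
    double denom = (q == 0.0) ? 1e-300 : q;
    q = d[i] - x - e[i - 1] * e[i - 1] / denom;
    if (q > 0) cnt++;
  }
  return cnt;
}

// solve (T - mu I) z = b in place, tridiagonal with partial pivoting
static void trisolve_shift(const std::vector<double>& d,
                           const std::vector<double>& e, double mu,
                           std::vector<double>& z) {
  int n = (int) d.size();
  std::vector<double> a(n), b(n - 1), c(n - 1), cc(n, 0.0);
  for (int i = 0; i < n; ++i) a[i] = d[i] - mu;
  for (int i = 0; i < n - 1; ++i) { b[i] = e[i]; c[i] = e[i]; }
  // forward elimination with partial pivoting (fill-in one extra diagonal)
  for (int i = 0; i < n - 1; ++i) {
    if (std::fabs(c[i]) > std::fabs(a[i])) {
      std::swap(a[i], c[i]);
      double t1 = b[i]; b[i] = a[i + 1]; a[i + 1] = t1;
      double t2 = cc[i]; cc[i] = (i + 1 < n - 1) ? b[i + 1] : 0.0;
      if (i + 1 < n - 1) b[i + 1] = t2;
      std::swap(z[i], z[i + 1]);
    }
    double m = (a[i] == 0.0) ? 0.0 : c[i] / a[i];
    a[i + 1] -= m * b[i];
    if (i + 1 < n - 1) b[i + 1] -= m * cc[i];
    z[i + 1] -= m * z[i];
  }
  // back substitution
  for (int i = n - 1; i >= 0; --i) {
    double s = z[i];
    if (i + 1 < n) s -= b[i] * z[i + 1];
    if (i + 2 < n) s -= cc[i] * z[i + 2];
    z[i] = s / (a[i] == 0.0 ? 1e-300 : a[i]);
  }
}

// [[Rcpp::export]]
NumericMatrix dpss_cpp(int N, double NW, int K) {
  double W = NW / N;
  std::vector<double> d(N), e(N - 1);
  double c2w = std::cos(2.0 * M_PI * W);
  for (int i = 0; i < N; ++i) {
    double v = (N - 1 - 2.0 * i) / 2.0;
    d[i] = v * v * c2w;
  }
  for (int i = 0; i < N - 1; ++i) e[i] = (i + 1.0) * (N - 1.0 - i) / 2.0;
  // Gershgorin bounds
  double lo = d[0], hi = d[0];
  for (int i = 0; i < N; ++i) {
    double r = 0.0;
    if (i > 0) r += std::fabs(e[i - 1]);
    if (i < N - 1) r += std::fabs(e[i]);
    lo = std::min(lo, d[i] - r);
    hi = std::max(hi, d[i] + r);
  }
  NumericMatrix tapers(N, K);
  std::vector<std::vector<double> > found;
  for (int k = 0; k < K; ++k) {
    // k-th largest eigenvalue by bisection
    double a = lo, b = hi;
    for (int it = 0; it < 200 && (b - a) > 1e-12 * std::max(1.0, std::fabs(b)); ++it) {
      double mid = 0.5 * (a + b);
      if (sturm_count_gt(d, e, mid) >= k + 1) a = mid;
      else b = mid;
    }
    double mu = 0.5 * (a + b);
    // inverse iteration
    std::vector<double> z(N);
    for (int i = 0; i < N; ++i) z[i] = std::sin((k + 1) * M_PI * (i + 1.0) / (N + 1.0));
    double shift = mu * (1.0 + 1e-10) + 1e-10;
    for (int it = 0; it < 6; ++it) {
      trisolve_shift(d, e, shift, z);
      // orthogonalise against previously found vectors
      for (size_t p = 0; p < found.size(); ++p) {
        double dot = 0.0;
        for (int i = 0; i < N; ++i) dot += z[i] * found[p][i];
        for (int i = 0; i < N; ++i) z[i] -= dot * found[p][i];
      }
      double nrm = 0.0;
      for (int i = 0; i < N; ++i) nrm += z[i] * z[i];
      nrm = std::sqrt(nrm);
      for (int i = 0; i < N; ++i) z[i] /= (nrm == 0.0 ? 1.0 : nrm);
    }
    // sign convention: symmetric tapers have positive mean, antisymmetric
    // tapers a positive initial lobe
    double mean = 0.0, slope = 0.0;
    for (int i = 0; i < N; ++i) {
      mean += z[i];
      slope += (N - 1 - 2.0 * i) * z[i];
    }
    double flip = (std::fabs(mean) > 1e-7 * N) ? ((mean > 0) ? 1.0 : -1.0)
                                               : ((slope > 0) ? 1.0 : -1.0);
    for (int i = 0; i < N; ++i) z[i] *= flip;
    for (int i = 0; i < N; ++i) tapers(i, k) = z[i];
    found.push_back(z);
  }
  return tapers;
}
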