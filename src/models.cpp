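// Kinetic right-hand sides for the coupled clock/cell-cycle models and the
// Euler-Maruyama chemical-Langevin integrator.  Parameter vectors arrive as
// dense doubles in the fixed order defined by cl_param_names() on the R side;
// the enum below must stay in sync with that ordering.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

enum par {
  VBP, VSP, KAB, HAB, KIP, HIP, VMP, KMP, KSP, K1, K2, VDPC, VDPN, KDP,
  VBB, VSB, KIB, HIB, DMB, KSB, DB,
  VBR, VSR, KAR, HAR, KIR, HIR, DMR, KSR, DR, KC2, HC2,
  KSB0,
  VBW, VSW, KAW, HAW, DMW, KSW, DW,
  VSC, VDC, KDC, KDL,
  VB1, VS1, KAM, HAM, KCB, HCB, V2, KWEE, K2G,
  VS3, KA3, HA3, V4, K4,
  VD0, DDD, VE, KDE, DE, VA, KEA, DA, BCB, KACB,
  VP, DP21, KREV, HREV, KP21,
  KBP,
  C1, C2, SCL, SCC,
  N_PAR
};

static inline double hact(double x, double K, double h) {
  if (x <= 0.0) return 0.0;
  double xn = std::pow(x, h);
  return xn / (std::pow(K, h) + xn);
}
static inline double hrep(double x, double K, double h) {
  if (x <= 0.0) return 1.0;
  double Kn = std::pow(K, h);
  return Kn / (Kn + std::pow(x, h));
}
static inline double mm(double v, double x, double K) {
  return v * x / (K + x);
}

int n_species_for(int model) {
  switch (model) {
  case 1: return 9;
  case 2: return 12;
  case 3: return 16;
  default: stop("unknown model id %d", model);
  }
  return 0;
}

// production/degradation decomposition of dX/dt; both components are
// nonnegative for nonnegative states, as required by the CLE noise term.
static void model_rhs(int model, const double* p, const double* x,
                      double* prod, double* deg) {
  const double s1 = p[SCL], s2 = p[SCC];
  const double c1 = p[C1], c2 = p[C2];

  // --- circadian clock ---
  const double Mp = x[0], Pc = x[1], Pn = x[2];
  double B;
  if (model == 1) {
    B = x[3];
  } else {
    B = x[4];
  }
  prod[0] = s1 * (p[VBP] + p[VSP] * hact(B, p[KAB], p[HAB])) *
            hrep(Pn, p[KIP], p[HIP]);
  deg[0]  = s1 * mm(p[VMP], Mp, p[KMP]);
  prod[1] = s1 * (p[KSP] * Mp + p[K2] * Pn);
  deg[1]  = s1 * (p[K1] * Pc + mm(p[VDPC], Pc, p[KDP]));
  prod[2] = s1 * p[K1] * Pc;
  deg[2]  = s1 * (p[K2] * Pn + mm(p[VDPN], Pn, p[KDP]));

  int iw;  // index of Wee1 mRNA
  if (model == 1) {
    // constitutive BMAL1-CLOCK: constant level, no secondary loop
    prod[3] = s1 * p[KSB0];
    deg[3]  = s1 * p[DB] * B;
    iw = 4;
  } else {
    const double Mb = x[3], Mr = x[5], R = x[6];
    const double MPF = (model == 2) ? x[10] : x[13];
    prod[3] = s1 * (p[VBB] + p[VSB] * hrep(R, p[KIB], p[HIB]));
    deg[3]  = s1 * p[DMB] * Mb;
    prod[4] = s1 * p[KSB] * Mb;
    deg[4]  = s1 * (p[DB] * B + p[KBP] * B * Pn);
    double rev_gate = 1.0;
    if (c2 > 0.0 && MPF > 0.0)
      rev_gate = 1.0 / (1.0 + c2 * std::pow(MPF / p[KC2], p[HC2]));
    prod[5] = s1 * (p[VBR] + p[VSR] * hact(B, p[KAR], p[HAR])) *
              hrep(Pn, p[KIR], p[HIR]) * rev_gate;
    deg[5]  = s1 * p[DMR] * Mr;
    prod[6] = s1 * p[KSR] * Mr;
    deg[6]  = s1 * p[DR] * R;
    iw = 7;
  }

  // --- Wee1 branch (forward coupling) ---
  const double Mw = x[iw], W = x[iw + 1];
  prod[iw]     = s2 * (p[VBW] + c1 * p[VSW] * hact(B, p[KAW], p[HAW]));
  deg[iw]      = s2 * p[DMW] * Mw;
  prod[iw + 1] = s2 * p[KSW] * Mw;
  deg[iw + 1]  = s2 * p[DW] * W;

  // --- cell cycle core: cyclin / MPF / APC relaxation oscillator ---
  int ic;       // index of cyclin B
  double pf = 1.0, cb_drive = 1.0;
  if (model == 3) {
    const double D = x[9], E = x[10], A = x[11], P21 = x[15], R = x[6];
    pf = 1.0 / (1.0 + P21 / p[KP21]);
    prod[9]  = s2 * p[VD0];
    deg[9]   = s2 * p[DDD] * D;
    prod[10] = s2 * p[VE] * hact(D, p[KDE], 2.0) * pf;
    deg[10]  = s2 * p[DE] * E;
    prod[11] = s2 * p[VA] * hact(E, p[KEA], 2.0) * pf;
    deg[11]  = s2 * p[DA] * A;
    double p21_gate = 1.0;
    if (c1 > 0.0 && R > 0.0)
      p21_gate = 1.0 / (1.0 + c1 * std::pow(R / p[KREV], p[HREV]));
    prod[15] = s2 * p[VP] * p21_gate;
    deg[15]  = s2 * p[DP21] * P21;
    cb_drive = p[BCB] + (1.0 - p[BCB]) * hact(A, p[KACB], 2.0);
    ic = 12;
  } else {
    ic = iw + 2;
  }
  const double Cb = x[ic], M = x[ic + 1], X = x[ic + 2];
  prod[ic] = s2 * p[VSC] * cb_drive;
  deg[ic]  = s2 * (p[VDC] * X * Cb / (p[KDC] + Cb) + p[KDL] * Cb);
  double act = (p[VB1] + p[VS1] * hact(M, p[KAM], p[HAM])) *
               hact(Cb, p[KCB], p[HCB]) * pf;
  // activation fills the inactive pool (1 - M); an excursion past 1 acts as
  // an extra degradation flux so both components stay nonnegative
  prod[ic + 1] = s2 * act * std::max(1.0 - M, 0.0);
  deg[ic + 1]  = s2 * ((p[V2] + p[KWEE] * W) * M / (p[K2G] + M) +
                       act * std::max(M - 1.0, 0.0));
  double r3 = p[VS3] * hact(M, p[KA3], p[HA3]);
  prod[ic + 2] = s2 * r3 * std::max(1.0 - X, 0.0);
  deg[ic + 2]  = s2 * (mm(p[V4], X, p[K4]) + r3 * std::max(X - 1.0, 0.0));
}

static void check_inputs(int model, const NumericVector& params,
                         const NumericVector& state) {
  if (params.size() != N_PAR)
    stop("parameter vector has length %d, expected %d",
         (int)params.size(), (int)N_PAR);
  int ns = n_species_for(model);
  if (state.size() != ns)
    stop("state has length %d but model %d has %d species",
         (int)state.size(), model, ns);
  for (int i = 0; i < ns; ++i)
    if (!std::isfinite(state[i]))
      stop("non-finite value in state (species %d)", i + 1);
}

// [[Rcpp::export]]
List cl_rhs_cpp(int model, NumericVector params, NumericVector state) {
  check_inputs(model, params, state);
  int ns = n_species_for(model);
  NumericVector prod(ns), deg(ns);
  model_rhs(model, params.begin(), state.begin(), prod.begin(), deg.begin());
  return List::create(_["production"] = prod, _["degradation"] = deg);
}

static inline void em_step(int model, const double* p, double* x, double dt,
                           double sqdt, int noise_mode, const double* sigma,
                           double inv_sqrt_omega, const double* gmult,
                           int ns, double* prod, double* deg) {
  model_rhs(model, p, x, prod, deg);
  if (noise_mode == 0) {
    for (int i = 0; i < ns; ++i) x[i] += (prod[i] - deg[i]) * dt;
  } else if (noise_mode == 1) {
    for (int i = 0; i < ns; ++i)
      x[i] += (prod[i] - deg[i]) * dt + sigma[i] * gmult[i] * sqdt * norm_rand();
  } else {
    for (int i = 0; i < ns; ++i) {
      double g = std::sqrt(prod[i] + deg[i]) * inv_sqrt_omega * gmult[i];
      x[i] += (prod[i] - deg[i]) * dt + g * sqdt * norm_rand();
    }
  }
  for (int i = 0; i < ns; ++i) if (x[i] < 0.0) x[i] = 0.0;
}

static void check_overflow(const double* x, int ns, double t) {
  for (int i = 0; i < ns; ++i)
    if (!std::isfinite(x[i]) || std::fabs(x[i]) > 1e9)
      stop("integration diverged: species %d at t = %.3f h", i + 1, t);
}

// [[Rcpp::export]]
NumericMatrix cl_integrate_cpp(int model, NumericVector params,
                               NumericVector state0, double dt, int n_steps,
                               int record_every, int noise_mode,
                               NumericVector sigma, double omega,
                               NumericVector gmult) {
  check_inputs(model, params, state0);
  int ns = n_species_for(model);
  if (sigma.size() != ns || gmult.size() != ns)
    stop("sigma/gmult must have one entry per species");
  int nrec = n_steps / record_every;
  NumericMatrix out(nrec + 1, ns);
  std::vector<double> x(state0.begin(), state0.end());
  std::vector<double> prod(ns), deg(ns);
  double sqdt = std::sqrt(dt);
  double isw = (omega > 0.0) ? 1.0 / std::sqrt(omega) : 0.0;
  RNGScope rng;
  for (int i = 0; i < ns; ++i) out(0, i) = x[i];
  int row = 1;
  for (int s = 1; s <= n_steps; ++s) {
    em_step(model, params.begin(), x.data(), dt, sqdt, noise_mode,
            sigma.begin(), isw, gmult.begin(), ns, prod.data(), deg.data());
    if (s % record_every == 0) {
      check_overflow(x.data(), ns, s * dt);
      for (int i = 0; i < ns; ++i) out(row, i) = x[i];
      ++row;
    }
  }
  return out;
}

// Integrate one cell from birth until its division event (latched M phase,
// then a downward crossing of th_div) or until t_max (censored).
// [[Rcpp::export]]
List cl_simulate_cell_cpp(int model, NumericVector params,
                          NumericVector state0, double dt, double t_max,
                          int mpf_index, double th_s, double th_m,
                          double th_div, int noise_mode, NumericVector sigma,
                          double omega, NumericVector gmult, int record_every,
                          bool record_states) {
  check_inputs(model, params, state0);
  int ns = n_species_for(model);
  int im = mpf_index - 1;
  if (im < 0 || im >= ns) stop("bad MPF index");
  int n_steps = (int)std::ceil(t_max / dt);
  int nrec = n_steps / record_every;
  std::vector<double> x(state0.begin(), state0.end());
  std::vector<double> prod(ns), deg(ns);
  IntegerVector phase_rec(nrec + 1);
  NumericMatrix states;
  if (record_states) states = NumericMatrix(nrec + 1, ns);
  double sqdt = std::sqrt(dt);
  double isw = (omega > 0.0) ? 1.0 / std::sqrt(omega) : 0.0;
  RNGScope rng;

  bool latched = false, divided = false;
  double t_div = NA_REAL, t_enter_s = NA_REAL, t_enter_m = NA_REAL;
  int phase = (x[im] >= th_m) ? 3 : (x[im] >= th_s ? 2 : 1);
  if (phase == 3) { latched = true; t_enter_m = 0.0; }
  phase_rec[0] = phase;
  if (record_states) for (int i = 0; i < ns; ++i) states(0, i) = x[i];
  int row = 1, steps_done = 0;

  for (int s = 1; s <= n_steps; ++s) {
    em_step(model, params.begin(), x.data(), dt, sqdt, noise_mode,
            sigma.begin(), isw, gmult.begin(), ns, prod.data(), deg.data());
    double t = s * dt, mpf = x[im];
    if (!latched) {
      if (ISNA(t_enter_s) && mpf >= th_s) t_enter_s = t;
      if (mpf >= th_m) { latched = true; t_enter_m = t; }
    } else if (mpf < th_div) {
      divided = true;
      t_div = t;
    }
    phase = latched ? 3 : (mpf >= th_s ? 2 : 1);
    if (s % record_every == 0) {
      check_overflow(x.data(), ns, t);
      phase_rec[row] = phase;
      if (record_states) for (int i = 0; i < ns; ++i) states(row, i) = x[i];
      ++row;
    }
    steps_done = s;
    if (divided) break;
  }
  int used = steps_done / record_every + 1;
  List out = List::create(
    _["divided"] = divided,
    _["t_div"] = t_div,
    _["t_enter_s"] = t_enter_s,
    _["t_enter_m"] = t_enter_m,
    _["t_end"] = divided ? t_div : (double)n_steps * dt,
    _["state_end"] = NumericVector(x.begin(), x.end()),
    _["phase"] = phase_rec[Range(0, used - 1)],
    _["record_dt"] = dt * record_every);
  if (record_states)
    out["states"] = states(Range(0, used - 1), _);
  return out;
}
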