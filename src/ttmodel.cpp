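// Human ventricular epicardial myocyte model (ten Tusscher et al. 2004
// formulation) with scalable maximal conductances, plus the fixed-step
// integrator (Rush-Larsen for Hodgkin-Huxley gates, forward Euler for Vm and
// concentrations) and the pacing inner loops.  All voltages mV, times ms,
// concentrations mM, currents pA/pF.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// physical constants
static const double Rgas = 8314.472;    // J/(kmol K)
static const double Temp = 310.0;       // K
static const double Frdy = 96485.3415;  // C/mol
// cell geometry (reference model values)
static const double CAPwc = 0.185;      // whole-cell capacitance scaling
static const double Vc    = 0.016404;   // cytoplasmic volume
static const double Vsr   = 0.001094;   // SR volume
// cytosolic / SR calcium buffering
static const double Bufc = 0.15,  Kbufc = 0.001;
static const double Bufsr = 10.0, Kbufsr = 0.3;
// fixed current parameters
static const double Kup  = 0.00025;
static const double KpCa = 0.0005;
static const double KmK  = 1.0,  KmNa = 40.0;
static const double KmNai = 87.5, KmCa = 1.38, ksat = 0.1;
static const double gam_naca = 0.35, alpha_naca = 2.5;
static const double pKNa = 0.03;

// state vector layout (17 variables)
enum { iV = 0, iM, iH, iJ, iD, iF, iFCA, iR, iS, iXR1, iXR2, iXS, iG,
       iCAI, iCASR, iNAI, iKI, NSTATE };
static const char* STATE_NAMES[NSTATE] = {
  "Vm", "m", "h", "j", "d", "f", "fCa", "r", "s", "xr1", "xr2", "xs", "g",
  "Ca_i", "Ca_SR", "Na_i", "K_i" };

// parameter vector layout (order fixed; mirrored in R/conductances.R)
enum { pGKS = 0, pGKR, pGK1, pGNA, pGBNA, pGCAL, pGBCA, pGTO, pGPCA, pGPK,
       pPNAK, pKNACA, pVMAXUP, pVLEAK, pAREL, pBREL, pCREL,
       pNAO, pCAO, pKO, NPAR };

// the 12 membrane currents, Eq.-2 order, plus their sum
struct Currents {
  double INa, IK1, Ito, IKr, IKs, ICaL, INaCa, INaK, IpCa, IpK, IbCa, IbNa;
  double Iion;
};

static inline void compute_currents(const double* s, const double* p,
                                    Currents& c) {
  const double V = s[iV];
  const double cai = s[iCAI], nai = s[iNAI], ki = s[iKI];
  const double Nao = p[pNAO], Cao = p[pCAO], Ko = p[pKO];
  const double rtf = Rgas * Temp / Frdy;
  const double EK  = rtf * log(Ko / ki);
  const double ENa = rtf * log(Nao / nai);
  const double EKs = rtf * log((Ko + pKNa * Nao) / (ki + pKNa * nai));
  const double ECa = 0.5 * rtf * log(Cao / cai);
  const double vfrt = V / rtf;

  c.INa = p[pGNA] * s[iM] * s[iM] * s[iM] * s[iH] * s[iJ] * (V - ENa);

  const double ak1 = 0.1 / (1.0 + exp(0.06 * (V - EK - 200.0)));
  const double bk1 = (3.0 * exp(0.0002 * (V - EK + 100.0)) +
                      exp(0.1 * (V - EK - 10.0))) /
                     (1.0 + exp(-0.5 * (V - EK)));
  c.IK1 = p[pGK1] * sqrt(Ko / 5.4) * ak1 / (ak1 + bk1) * (V - EK);

  c.Ito = p[pGTO] * s[iR] * s[iS] * (V - EK);
  c.IKr = p[pGKR] * sqrt(Ko / 5.4) * s[iXR1] * s[iXR2] * (V - EK);
  c.IKs = p[pGKS] * s[iXS] * s[iXS] * (V - EKs);

  // L-type Ca current (GHK-type driving force); series expansion near Vm = 0
  const double z = 2.0 * vfrt;
  double drive;
  if (fabs(z) < 1e-5) {
    // limit of V*(cai*e^z - 0.341*Cao)/(e^z - 1) as Vm -> 0
    drive = (rtf / 2.0) * (cai - 0.341 * Cao);
  } else {
    drive = V * (cai * exp(z) - 0.341 * Cao) / (exp(z) - 1.0);
  }
  c.ICaL = p[pGCAL] * s[iD] * s[iF] * s[iFCA] * 4.0 * Frdy / rtf * drive;

  c.INaCa = p[pKNACA] *
            (exp(gam_naca * vfrt) * nai * nai * nai * Cao -
             exp((gam_naca - 1.0) * vfrt) * Nao * Nao * Nao * cai * alpha_naca) /
            ((KmNai * KmNai * KmNai + Nao * Nao * Nao) * (KmCa + Cao) *
             (1.0 + ksat * exp((gam_naca - 1.0) * vfrt)));

  c.INaK = p[pPNAK] * Ko * nai / ((Ko + KmK) * (nai + KmNa)) /
           (1.0 + 0.1245 * exp(-0.1 * vfrt) + 0.0353 * exp(-vfrt));

  c.IpCa = p[pGPCA] * cai / (KpCa + cai);
  c.IpK  = p[pGPK] * (V - EK) / (1.0 + exp((25.0 - V) / 5.98));
  c.IbCa = p[pGBCA] * (V - ECa);
  c.IbNa = p[pGBNA] * (V - ENa);

  c.Iion = c.INa + c.IK1 + c.Ito + c.IKr + c.IKs + c.ICaL + c.INaCa +
           c.INaK + c.IpCa + c.IpK + c.IbCa + c.IbNa;
}

// Rush-Larsen update helper
static inline double rl(double x, double xinf, double tau, double dt) {
  return xinf - (xinf - x) * exp(-dt / tau);
}

// advance the state one dt in place; returns -1 on success, else the index of
// the first non-finite state variable
static inline int step_once(double* s, const double* p, double dt,
                            double istim) {
  Currents c;
  compute_currents(s, p, c);
  const double V = s[iV];
  const double cai = s[iCAI], casr = s[iCASR];

  // --- gate kinetics ---
  double minf = 1.0 / pow(1.0 + exp((-56.86 - V) / 9.03), 2.0);
  double am = 1.0 / (1.0 + exp((-60.0 - V) / 5.0));
  double bm = 0.1 / (1.0 + exp((V + 35.0) / 5.0)) +
              0.1 / (1.0 + exp((V - 50.0) / 200.0));
  double taum = am * bm;

  double hinf = 1.0 / pow(1.0 + exp((V + 71.55) / 7.43), 2.0);
  double tauh;
  if (V >= -40.0) {
    tauh = 1.0 / (0.77 / (0.13 * (1.0 + exp(-(V + 10.66) / 11.1))));
  } else {
    double ah = 0.057 * exp(-(V + 80.0) / 6.8);
    double bh = 2.7 * exp(0.079 * V) + 3.1e5 * exp(0.3485 * V);
    tauh = 1.0 / (ah + bh);
  }

  double jinf = hinf;
  double tauj;
  if (V >= -40.0) {
    double bj = 0.6 * exp(0.057 * V) / (1.0 + exp(-0.1 * (V + 32.0)));
    tauj = 1.0 / bj;
  } else {
    double aj = (-2.5428e4 * exp(0.2444 * V) - 6.948e-6 * exp(-0.04391 * V)) *
                (V + 37.78) / (1.0 + exp(0.311 * (V + 79.23)));
    double bj = 0.02424 * exp(-0.01052 * V) /
                (1.0 + exp(-0.1378 * (V + 40.14)));
    tauj = 1.0 / (aj + bj);
  }

  double dinf = 1.0 / (1.0 + exp((-5.0 - V) / 7.5));
  double ad = 1.4 / (1.0 + exp((-35.0 - V) / 13.0)) + 0.25;
  double bd = 1.4 / (1.0 + exp((V + 5.0) / 5.0));
  double cd = 1.0 / (1.0 + exp((50.0 - V) / 20.0));
  double taud = ad * bd + cd;

  double finf = 1.0 / (1.0 + exp((V + 20.0) / 7.0));
  double tauf = 1125.0 * exp(-pow(V + 27.0, 2.0) / 240.0) + 80.0 +
                165.0 / (1.0 + exp((25.0 - V) / 10.0));

  double afca = 1.0 / (1.0 + pow(cai / 0.000325, 8.0));
  double bfca = 0.1 / (1.0 + exp((cai - 0.0005) / 0.0001));
  double cfca = 0.2 / (1.0 + exp((cai - 0.00075) / 0.0008));
  double fcainf = (afca + bfca + cfca + 0.23) / 1.46;
  const double taufca = 2.0;

  double rinf = 1.0 / (1.0 + exp((20.0 - V) / 6.0));
  double taur = 9.5 * exp(-pow(V + 40.0, 2.0) / 1800.0) + 0.8;
  // epicardial s gate
  double sinf = 1.0 / (1.0 + exp((V + 20.0) / 5.0));
  double taus = 85.0 * exp(-pow(V + 45.0, 2.0) / 320.0) +
                5.0 / (1.0 + exp((V - 20.0) / 5.0)) + 3.0;

  double xr1inf = 1.0 / (1.0 + exp((-26.0 - V) / 7.0));
  double axr1 = 450.0 / (1.0 + exp((-45.0 - V) / 10.0));
  double bxr1 = 6.0 / (1.0 + exp((V + 30.0) / 11.5));
  double tauxr1 = axr1 * bxr1;

  double xr2inf = 1.0 / (1.0 + exp((V + 88.0) / 24.0));
  double axr2 = 3.0 / (1.0 + exp((-60.0 - V) / 20.0));
  double bxr2 = 1.12 / (1.0 + exp((V - 60.0) / 20.0));
  double tauxr2 = axr2 * bxr2;

  double xsinf = 1.0 / (1.0 + exp((-5.0 - V) / 14.0));
  double axs = 1100.0 / sqrt(1.0 + exp((-10.0 - V) / 6.0));
  double bxs = 1.0 / (1.0 + exp((V - 60.0) / 20.0));
  double tauxs = axs * bxs;

  // SR release gate steady state
  double ginf = (cai < 0.00035)
                    ? 1.0 / (1.0 + pow(cai / 0.00035, 6.0))
                    : 1.0 / (1.0 + pow(cai / 0.00035, 16.0));
  const double taug = 2.0;

  // --- calcium handling fluxes ---
  double Irel = (p[pAREL] * casr * casr / (p[pBREL] * p[pBREL] + casr * casr) +
                 p[pCREL]) * s[iD] * s[iG];
  double Ileak = p[pVLEAK] * (casr - cai);
  double Iup = p[pVMAXUP] / (1.0 + Kup * Kup / (cai * cai));

  double caibuf = 1.0 / (1.0 + Bufc * Kbufc / pow(cai + Kbufc, 2.0));
  double casrbuf = 1.0 / (1.0 + Bufsr * Kbufsr / pow(casr + Kbufsr, 2.0));

  double dcai = caibuf * (Ileak - Iup + Irel -
                          (c.ICaL + c.IbCa + c.IpCa - 2.0 * c.INaCa) *
                              CAPwc / (2.0 * Vc * Frdy));
  double dcasr = casrbuf * Vc / Vsr * (Iup - Irel - Ileak);
  double dnai = -(c.INa + c.IbNa + 3.0 * c.INaK + 3.0 * c.INaCa) *
                CAPwc / (Vc * Frdy);
  double dki = -(c.IK1 + c.Ito + c.IKr + c.IKs + c.IpK - 2.0 * c.INaK +
                 istim) * CAPwc / (Vc * Frdy);

  // --- update (Rush-Larsen gates, forward Euler otherwise) ---
  s[iM]   = rl(s[iM], minf, taum, dt);
  s[iH]   = rl(s[iH], hinf, tauh, dt);
  s[iJ]   = rl(s[iJ], jinf, tauj, dt);
  s[iD]   = rl(s[iD], dinf, taud, dt);
  s[iF]   = rl(s[iF], finf, tauf, dt);
  // voltage-conditional freeze of the Ca-dependent gates
  if (!(fcainf > s[iFCA] && V > -60.0))
    s[iFCA] = rl(s[iFCA], fcainf, taufca, dt);
  if (!(ginf > s[iG] && V > -60.0))
    s[iG] = rl(s[iG], ginf, taug, dt);
  s[iR]   = rl(s[iR], rinf, taur, dt);
  s[iS]   = rl(s[iS], sinf, taus, dt);
  s[iXR1] = rl(s[iXR1], xr1inf, tauxr1, dt);
  s[iXR2] = rl(s[iXR2], xr2inf, tauxr2, dt);
  s[iXS]  = rl(s[iXS], xsinf, tauxs, dt);

  s[iCAI]  += dt * dcai;
  s[iCASR] += dt * dcasr;
  s[iNAI]  += dt * dnai;
  s[iKI]   += dt * dki;
  s[iV]    += dt * (-(c.Iion + istim));

  for (int k = 0; k < NSTATE; ++k)
    if (!std::isfinite(s[k])) return k;
  return -1;
}

static void check_lengths(const NumericVector& state,
                          const NumericVector& params) {
  if (state.size() != NSTATE)
    stop("state must have %d elements", NSTATE);
  if (params.size() != NPAR)
    stop("params must have %d elements", NPAR);
}

// [[Rcpp::export]]
NumericVector tt_currents_cpp(NumericVector state, NumericVector params) {
  check_lengths(state, params);
  Currents c;
  compute_currents(REAL(state), REAL(params), c);
  NumericVector out = NumericVector::create(
      _["I_Na"] = c.INa, _["I_K1"] = c.IK1, _["I_to"] = c.Ito,
      _["I_Kr"] = c.IKr, _["I_Ks"] = c.IKs, _["I_CaL"] = c.ICaL,
      _["I_NaCa"] = c.INaCa, _["I_NaK"] = c.INaK, _["I_pCa"] = c.IpCa,
      _["I_pK"] = c.IpK, _["I_bCa"] = c.IbCa, _["I_bNa"] = c.IbNa,
      _["I_ion"] = c.Iion);
  return out;
}

// [[Rcpp::export]]
NumericVector tt_integrate_cpp(NumericVector state, NumericVector params,
                               double duration, double dt, double istim) {
  check_lengths(state, params);
  NumericVector out = clone(state);
  double* s = REAL(out);
  const double* p = REAL(params);
  long nsteps = (long)(duration / dt + 0.5);
  for (long k = 0; k < nsteps; ++k) {
    int bad = step_once(s, p, dt, istim);
    if (bad >= 0)
      stop("numerical failure: state variable '%s' became non-finite at t = %g ms",
           STATE_NAMES[bad], (k + 1) * dt);
  }
  return out;
}

// analyze one beat's Vm samples (step-boundary resolution) for the per-beat
// record: upstroke time (max dVm/dt), peak, pre-stimulus rest, APD90 with
// linearly interpolated 90%-repolarization crossing
static void analyze_beat(const std::vector<double>& v, double dt,
                         double t0, double* rec) {
  const int n = (int)v.size();  // n = nsteps+1 samples
  double rest = v[0];
  int kpk = 0;
  double peak = v[0];
  double maxdv = -1e300;
  int kup = 0;
  for (int k = 0; k + 1 < n; ++k) {
    double dv = (v[k + 1] - v[k]) / dt;
    if (dv > maxdv) { maxdv = dv; kup = k; }
    if (v[k + 1] > peak) { peak = v[k + 1]; kpk = k + 1; }
  }
  double t_up = t0 + kup * dt;
  double thr = rest + 0.1 * (peak - rest);
  double apd = NA_REAL;
  for (int k = kpk; k + 1 < n; ++k) {
    if (v[k] > thr && v[k + 1] <= thr) {
      double tc = t0 + dt * (k + (v[k] - thr) / (v[k] - v[k + 1]));
      apd = tc - t_up;
      break;
    }
  }
  double capture = (peak > 0.0) ? 1.0 : 0.0;
  rec[0] = t0;        // stimulus time
  rec[1] = t_up;      // time of maximum upstroke
  rec[2] = peak;      // peak Vm
  rec[3] = rest;      // pre-stimulus Vm
  rec[4] = apd;       // APD90 (NA if no repolarization crossing in window)
  rec[5] = capture;
}

// [[Rcpp::export]]
List tt_pace_cpp(NumericVector state, NumericVector params, double cl,
                 int nbeats, double dt, double stim_amp, double stim_dur,
                 double trace_dt, double t_start) {
  check_lengths(state, params);
  NumericVector st = clone(state);
  double* s = REAL(st);
  const double* p = REAL(params);
  const long nsteps = (long)(cl / dt + 0.5);
  const bool keep_trace = trace_dt > 0;
  const long thin = keep_trace ? std::max(1L, (long)(trace_dt / dt + 0.5)) : 0;

  NumericMatrix beats(nbeats, 6);
  std::vector<double> vbuf((size_t)nsteps + 1);
  std::vector<double> tr_t, tr_v;
  if (keep_trace) {
    tr_t.reserve((size_t)(nbeats * nsteps / thin + nbeats + 1));
    tr_v.reserve(tr_t.capacity());
  }

  for (int b = 0; b < nbeats; ++b) {
    double t0 = t_start + (double)b * cl;
    vbuf[0] = s[iV];
    if (keep_trace) { tr_t.push_back(t0); tr_v.push_back(s[iV]); }
    for (long k = 0; k < nsteps; ++k) {
      double tloc = k * dt;
      double istim = (tloc < stim_dur) ? stim_amp : 0.0;
      int bad = step_once(s, p, dt, istim);
      if (bad >= 0)
        stop("numerical failure: state variable '%s' became non-finite at "
             "beat %d, t = %g ms", STATE_NAMES[bad], b + 1, t0 + (k + 1) * dt);
      vbuf[(size_t)k + 1] = s[iV];
      if (keep_trace && ((k + 1) % thin == 0)) {
        tr_t.push_back(t0 + (k + 1) * dt);
        tr_v.push_back(s[iV]);
      }
    }
    double rec[6];
    analyze_beat(vbuf, dt, t0, rec);
    for (int c2 = 0; c2 < 6; ++c2) beats(b, c2) = rec[c2];
  }
  colnames(beats) = CharacterVector::create(
      "stim_time", "t_upstroke", "peak_vm", "rest_vm", "apd90", "capture");
  List out = List::create(_["state"] = st, _["beats"] = beats);
  if (keep_trace) {
    out["trace_t"] = NumericVector(tr_t.begin(), tr_t.end());
    out["trace_vm"] = NumericVector(tr_v.begin(), tr_v.end());
  }
  return out;
}

// pre-pace at a fixed cycle length until the state sampled at stimulus times
// stops changing (max relative change < tol), capped at max_beats
// [[Rcpp::export]]
List tt_prepace_cpp(NumericVector state, NumericVector params, double cl,
                    int max_beats, double tol, double dt, double stim_amp,
                    double stim_dur) {
  check_lengths(state, params);
  NumericVector st = clone(state);
  double* s = REAL(st);
  const double* p = REAL(params);
  const long nsteps = (long)(cl / dt + 0.5);
  double prev[NSTATE];
  double relchg = R_PosInf;
  int b = 0;
  for (; b < max_beats; ++b) {
    for (int k = 0; k < NSTATE; ++k) prev[k] = s[k];
    for (long k = 0; k < nsteps; ++k) {
      double tloc = k * dt;
      double istim = (tloc < stim_dur) ? stim_amp : 0.0;
      int bad = step_once(s, p, dt, istim);
      if (bad >= 0)
        stop("numerical failure during pre-pacing: state variable '%s' "
             "became non-finite at beat %d", STATE_NAMES[bad], b + 1);
    }
    relchg = 0.0;
    for (int k = 0; k < NSTATE; ++k) {
      double d = fabs(s[k] - prev[k]) / std::max(fabs(prev[k]), 1e-6);
      if (d > relchg) relchg = d;
    }
    if (relchg < tol) { ++b; break; }
  }
  return List::create(_["state"] = st, _["beats_used"] = b,
                      _["converged"] = (relchg < tol),
                      _["max_rel_change"] = relchg);
}
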