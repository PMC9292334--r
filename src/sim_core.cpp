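// Mixed-layer box-model core: right-hand side and fixed-step RK4 integrator.
//
// State layout (length 37):
//   0        n          dissolved macronutrient (carbon-equivalent units)
//   1..5     d[e]       dissolved metal, element order Fe Zn Cu Co Mn
//   6..7     pc[g]      phytoplankton carbon, group order nano diatom
//   8..17    pm[g*5+e]  phytoplankton metal content
//   18       zc         microzooplankton carbon
//   19       poc        particulate organic carbon
//   20..24   pom[e]     particulate metal
//   25..26   cumulative boundary C fluxes (in = sources+mixing, out = export)
//   27..31   cumulative boundary metal influx per element
//   32..36   cumulative boundary metal outflux per element
// The cumulative entries are integrated by the same RK4 pass as the pools so
// the budget check compares two independently coded routes to the same mass.

#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

static const int NE = 5;   // elements
static const int NG = 2;   // phytoplankton groups
static const int NST = 37; // state length
static const int IX_N = 0, IX_D = 1, IX_PC = 6, IX_PM = 8, IX_ZC = 18,
                 IX_POC = 19, IX_POM = 20, IX_CIN_C = 25, IX_COUT_C = 26,
                 IX_CIN_M = 27, IX_COUT_M = 32;
// diagnostics: sst zoo_b npp grazing_c recycle_c egest_c export_c +
// per-element recycle_m, recycle_stoich, fq, prey_q, export_m
static const int NDIAG = 7 + 5 * NE;

struct Pars {
  double mu_max[NG], k_n[NG], q10, t_ref;
  double v_max[NG][NE], k_up[NE], q_max[NG][NE];
  double q_zoo[NE], ae_max[NE], ae_shape[NE];
  double g_max, k_g, pref[3];
  double ae_c, sigma, m_z, m_p, l_sink, l_rem;
  double n_deep, d_deep[NE], s_n, s_d[NE], fe_q_min;
  bool has_fq_fixed;
  double fq_fixed[NE];
};

static Pars parse_pars(const List& pl, const Nullable<NumericVector>& fq_fixed) {
  Pars p;
  NumericVector v;
  v = pl["mu_max"];  for (int g = 0; g < NG; ++g) p.mu_max[g] = v[g];
  v = pl["k_n"];     for (int g = 0; g < NG; ++g) p.k_n[g] = v[g];
  p.q10 = as<double>(pl["q10"]); p.t_ref = as<double>(pl["t_ref"]);
  v = pl["v_max"];
  for (int g = 0; g < NG; ++g)
    for (int e = 0; e < NE; ++e) p.v_max[g][e] = v[g * NE + e];
  v = pl["q_max"];
  for (int g = 0; g < NG; ++g)
    for (int e = 0; e < NE; ++e) p.q_max[g][e] = v[g * NE + e];
  v = pl["k_up"];   for (int e = 0; e < NE; ++e) p.k_up[e] = v[e];
  v = pl["q_zoo"];  for (int e = 0; e < NE; ++e) p.q_zoo[e] = v[e];
  v = pl["ae_max"]; for (int e = 0; e < NE; ++e) p.ae_max[e] = v[e];
  v = pl["ae_shape"]; for (int e = 0; e < NE; ++e) p.ae_shape[e] = v[e];
  p.g_max = as<double>(pl["g_max"]); p.k_g = as<double>(pl["k_g"]);
  v = pl["pref"]; for (int i = 0; i < 3; ++i) p.pref[i] = v[i];
  p.ae_c = as<double>(pl["ae_c"]); p.sigma = as<double>(pl["sigma_diss"]);
  p.m_z = as<double>(pl["m_z"]); p.m_p = as<double>(pl["m_p"]);
  p.l_sink = as<double>(pl["lambda_sink"]);
  p.l_rem = as<double>(pl["lambda_rem"]);
  p.n_deep = as<double>(pl["n_deep"]);
  v = pl["d_deep"]; for (int e = 0; e < NE; ++e) p.d_deep[e] = v[e];
  p.s_n = as<double>(pl["source_n"]);
  v = pl["source_d"]; for (int e = 0; e < NE; ++e) p.s_d[e] = v[e];
  p.fe_q_min = as<double>(pl["fe_q_min"]);
  p.has_fq_fixed = fq_fixed.isNotNull();
  if (p.has_fq_fixed) {
    NumericVector f(fq_fixed);
    if (f.size() != NE) stop("fq_fixed must have length 5");
    for (int e = 0; e < NE; ++e) p.fq_fixed[e] = f[e];
  }
  return p;
}

struct Forcing {
  std::vector<double> time, temp, kappa;
  double temp_amp, temp_period;
  double interp(const std::vector<double>& val, double t) const {
    const std::vector<double>& tt = time;
    if (t <= tt.front()) return val.front();
    if (t >= tt.back()) return val.back();
    size_t i = std::upper_bound(tt.begin(), tt.end(), t) - tt.begin();
    if (val[i - 1] == val[i]) return val[i];  // constant segments stay exact
    double w = (t - tt[i - 1]) / (tt[i] - tt[i - 1]);
    return (1.0 - w) * val[i - 1] + w * val[i];
  }
  double temperature(double t) const {
    double T = interp(temp, t);
    if (temp_amp != 0.0)
      T += temp_amp * std::sin(2.0 * M_PI * t / temp_period);
    return T;
  }
  double mixing(double t) const { return interp(kappa, t); }
};

static Forcing parse_forcing(const List& fl) {
  Forcing f;
  NumericVector t = fl["time"], T = fl["temp"], k = fl["kappa"];
  if (t.size() != T.size() || t.size() != k.size() || t.size() < 1)
    stop("forcing vectors time/temp/kappa must have equal positive length");
  f.time = as<std::vector<double> >(t);
  f.temp = as<std::vector<double> >(T);
  f.kappa = as<std::vector<double> >(k);
  f.temp_amp = fl.containsElementNamed("temp_amp") ?
    as<double>(fl["temp_amp"]) : 0.0;
  f.temp_period = fl.containsElementNamed("temp_period") ?
    as<double>(fl["temp_period"]) : 360.0;
  return f;
}

static inline double clamp01(double x) {
  return x < 0.0 ? 0.0 : (x > 1.0 ? 1.0 : x);
}

// Right-hand side; diag may be NULL when diagnostics are not needed.
static void deriv(const double* y, const Pars& p, double T, double kap,
                  double* dy, double* diag) {
  for (int i = 0; i < NST; ++i) dy[i] = 0.0;

  const double n = y[IX_N], zc = y[IX_ZC], poc = y[IX_POC];
  const double* d = y + IX_D;
  const double* pc = y + IX_PC;
  const double* pom = y + IX_POM;

  const double tf = std::pow(p.q10, (T - p.t_ref) / 10.0);

  // phytoplankton quotas
  double quota[NG][NE];
  for (int g = 0; g < NG; ++g)
    for (int e = 0; e < NE; ++e)
      quota[g][e] = pc[g] > 0.0 ? y[IX_PM + g * NE + e] / pc[g] : 0.0;

  // growth: macronutrient Michaelis-Menten and Droop Fe limitation
  double mu[NG], npp = 0.0;
  for (int g = 0; g < NG; ++g) {
    double lim_n = n / (n + p.k_n[g]);
    double fe_lim = 1.0;
    if (pc[g] > 0.0)
      fe_lim = clamp01((quota[g][0] - p.fe_q_min) /
                       (p.q_max[g][0] - p.fe_q_min));
    mu[g] = p.mu_max[g] * tf * std::min(lim_n, fe_lim);
    npp += mu[g] * pc[g];
    dy[IX_PC + g] += mu[g] * pc[g];
  }
  dy[IX_N] -= npp;

  // metal uptake (quota-regulated)
  for (int g = 0; g < NG; ++g) {
    for (int e = 0; e < NE; ++e) {
      double head = 1.0 - quota[g][e] / p.q_max[g][e];
      if (head < 0.0) head = 0.0;
      double v = p.v_max[g][e] * d[e] / (d[e] + p.k_up[e]) * head;
      double flux = v * pc[g];
      dy[IX_D + e] -= flux;
      dy[IX_PM + g * NE + e] += flux;
    }
  }

  // multi-prey grazing (nano, diatom, particles)
  double F[3] = { pc[0], pc[1], poc };
  double avail = 0.0;
  for (int i = 0; i < 3; ++i) avail += p.pref[i] * F[i];
  double gr[3] = { 0.0, 0.0, 0.0 };
  if (avail > 0.0 && zc > 0.0) {
    double denom = p.k_g + avail;
    for (int i = 0; i < 3; ++i)
      gr[i] = p.g_max * tf * zc * p.pref[i] * F[i] / denom;
  }
  double ic = gr[0] + gr[1] + gr[2];
  dy[IX_PC + 0] -= gr[0];
  dy[IX_PC + 1] -= gr[1];
  dy[IX_POC] -= gr[2];

  // prey quotas seen by the grazer
  double pq[3][NE];
  for (int e = 0; e < NE; ++e) {
    pq[0][e] = quota[0][e];
    pq[1][e] = quota[1][e];
    pq[2][e] = poc > 0.0 ? pom[e] / poc : 0.0;
  }
  for (int g = 0; g < NG; ++g)
    for (int e = 0; e < NE; ++e)
      dy[IX_PM + g * NE + e] -= gr[g] * pq[g][e];
  for (int e = 0; e < NE; ++e) dy[IX_POM + e] -= gr[2] * pq[2][e];

  // zooplankton carbon budget
  double growth_c = p.ae_c * ic;
  double rec_c = p.sigma * (1.0 - p.ae_c) * ic;
  double eg_c = (1.0 - p.sigma) * (1.0 - p.ae_c) * ic;
  double mort_c = p.m_z * tf * zc * zc;  // metabolic (Q10-scaled) closure
  dy[IX_ZC] += growth_c - mort_c;
  dy[IX_N] += rec_c + p.sigma * mort_c;
  dy[IX_POC] += eg_c + (1.0 - p.sigma) * mort_c;

  // per-element zooplankton metal budget with fixed body stoichiometry.
  // The recycling-flux diagnostic is the GROSS dissolved excretion
  // sigma * (I_m - assimilated); the shortfall ladder that keeps the
  // zooplankton quota exactly fixed (excretion first, floored at 0, then
  // egestion, then the ambient dissolved pool) only affects the NET fluxes
  // entering the pools.
  double rec_m[NE], fq_live[NE];
  for (int e = 0; e < NE; ++e) {
    double im = gr[0] * pq[0][e] + gr[1] * pq[1][e] + gr[2] * pq[2][e];
    double rec_gross = 0.0, rec_net = 0.0, eg_net = 0.0, draw_diss = 0.0;
    fq_live[e] = NA_REAL;
    if (ic > 0.0) {
      double mc_prey = im / ic;
      if (mc_prey > 0.0) fq_live[e] = p.q_zoo[e] / mc_prey;
      double fq_eff = p.has_fq_fixed ? p.fq_fixed[e] : fq_live[e];
      double ae = 0.0;
      if (R_finite(fq_eff) && fq_eff > 0.0)
        ae = p.ae_max[e] *
          std::pow(std::min(fq_eff, 1.0 / fq_eff), p.ae_shape[e]);
      double demand = growth_c * p.q_zoo[e];
      double assim = std::min(ae * im, demand);
      double unassim = im - assim;
      rec_gross = p.sigma * unassim;
      rec_net = rec_gross;
      eg_net = (1.0 - p.sigma) * unassim;
      double shortfall = demand - assim;
      double take = std::min(shortfall, rec_net);
      rec_net -= take; shortfall -= take;
      take = std::min(shortfall, eg_net);
      eg_net -= take; shortfall -= take;
      draw_diss = shortfall;
    }
    dy[IX_D + e] += rec_net - draw_diss + p.sigma * p.q_zoo[e] * mort_c;
    dy[IX_POM + e] += eg_net + (1.0 - p.sigma) * p.q_zoo[e] * mort_c;
    rec_m[e] = rec_gross;
  }

  // phytoplankton mortality to particles
  for (int g = 0; g < NG; ++g) {
    dy[IX_PC + g] -= p.m_p * pc[g];
    dy[IX_POC] += p.m_p * pc[g];
    for (int e = 0; e < NE; ++e) {
      dy[IX_PM + g * NE + e] -= p.m_p * y[IX_PM + g * NE + e];
      dy[IX_POM + e] += p.m_p * y[IX_PM + g * NE + e];
    }
  }

  // particle remineralization and sinking export
  dy[IX_N] += p.l_rem * poc;
  dy[IX_POC] -= (p.l_rem + p.l_sink) * poc;
  for (int e = 0; e < NE; ++e) {
    dy[IX_D + e] += p.l_rem * pom[e];
    dy[IX_POM + e] -= (p.l_rem + p.l_sink) * pom[e];
  }

  // boundary exchange: deep mixing and constant external sources
  double mix_n = kap * (p.n_deep - n);
  dy[IX_N] += mix_n + p.s_n;
  dy[IX_CIN_C] = mix_n + p.s_n;
  dy[IX_COUT_C] = p.l_sink * poc;
  for (int e = 0; e < NE; ++e) {
    double mix_d = kap * (p.d_deep[e] - d[e]);
    dy[IX_D + e] += mix_d + p.s_d[e];
    dy[IX_CIN_M + e] = mix_d + p.s_d[e];
    dy[IX_COUT_M + e] = p.l_sink * pom[e];
  }

  if (diag) {
    diag[0] = T;
    diag[1] = zc;
    diag[2] = npp;
    diag[3] = ic;
    diag[4] = rec_c;
    diag[5] = eg_c;
    diag[6] = p.l_sink * poc;
    for (int e = 0; e < NE; ++e) {
      diag[7 + e] = rec_m[e];
      diag[7 + NE + e] = rec_c > 0.0 ? rec_m[e] / rec_c : NA_REAL;
      diag[7 + 2 * NE + e] = fq_live[e];
      diag[7 + 3 * NE + e] = p.pref[0] * y[IX_PM + e] +
        p.pref[1] * y[IX_PM + NE + e] + p.pref[2] * pom[e];
      diag[7 + 4 * NE + e] = p.l_sink * pom[e];
    }
  }
}

static const char* pool_name(int i) {
  static const char* el[NE] = { "Fe", "Zn", "Cu", "Co", "Mn" };
  static std::string buf;
  if (i == IX_N) return "n";
  if (i >= IX_D && i < IX_D + NE) { buf = std::string("d.") + el[i - IX_D]; return buf.c_str(); }
  if (i == IX_PC) return "pc.nano";
  if (i == IX_PC + 1) return "pc.diatom";
  if (i >= IX_PM && i < IX_PM + NG * NE) {
    int g = (i - IX_PM) / NE, e = (i - IX_PM) % NE;
    buf = std::string("pm.") + (g == 0 ? "nano." : "diatom.") + el[e];
    return buf.c_str();
  }
  if (i == IX_ZC) return "zc";
  if (i == IX_POC) return "poc";
  if (i >= IX_POM && i < IX_POM + NE) { buf = std::string("pom.") + el[i - IX_POM]; return buf.c_str(); }
  return "cumulative";
}

static void rk4_step(double* y, double t, double dt, const Pars& p,
                     const Forcing& f) {
  double k1[NST], k2[NST], k3[NST], k4[NST], tmp[NST];
  deriv(y, p, f.temperature(t), f.mixing(t), k1, NULL);
  for (int i = 0; i < NST; ++i) tmp[i] = y[i] + 0.5 * dt * k1[i];
  double Th = f.temperature(t + 0.5 * dt), kh = f.mixing(t + 0.5 * dt);
  deriv(tmp, p, Th, kh, k2, NULL);
  for (int i = 0; i < NST; ++i) tmp[i] = y[i] + 0.5 * dt * k2[i];
  deriv(tmp, p, Th, kh, k3, NULL);
  for (int i = 0; i < NST; ++i) tmp[i] = y[i] + dt * k3[i];
  deriv(tmp, p, f.temperature(t + dt), f.mixing(t + dt), k4, NULL);
  for (int i = 0; i < NST; ++i)
    y[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
}

// [[Rcpp::export]]
List sim_core(NumericVector y0, List pars, List forcing, double t0,
              double t_end, double dt, double save_every,
              Nullable<NumericVector> fq_fixed) {
  if (y0.size() != NST) stop("state vector must have length %d", NST);
  if (dt <= 0.0) stop("dt must be > 0");
  Pars p = parse_pars(pars, fq_fixed);
  Forcing f = parse_forcing(forcing);

  long nstep = (long)std::llround((t_end - t0) / dt);
  if (nstep < 0) stop("t_end must be >= t0");
  if (std::fabs(t0 + nstep * dt - t_end) > 1e-6)
    stop("(t_end - t0) must be an integer multiple of dt");
  long ksave = std::max(1L, (long)std::llround(save_every / dt));

  long nsave = nstep / ksave + 1;
  NumericVector time_out(nsave);
  NumericMatrix state_out(nsave, NST);
  NumericMatrix diag_out(nsave, NDIAG);

  double y[NST], dy[NST], dg[NDIAG];
  for (int i = 0; i < NST; ++i) y[i] = y0[i];

  long isave = 0;
  for (long s = 0; s <= nstep; ++s) {
    double t = t0 + s * dt;
    if (s % ksave == 0 && isave < nsave) {
      deriv(y, p, f.temperature(t), f.mixing(t), dy, dg);
      time_out[isave] = t;
      for (int i = 0; i < NST; ++i) state_out(isave, i) = y[i];
      for (int i = 0; i < NDIAG; ++i) diag_out(isave, i) = dg[i];
      ++isave;
    }
    if (s == nstep) break;
    rk4_step(y, t, dt, p, f);
    for (int i = 0; i < IX_CIN_C; ++i) {
      if (!R_finite(y[i]))
        stop("integration failure: pool '%s' is not finite at t = %.3f d",
             pool_name(i), t + dt);
      if (y[i] < 0.0) {
        if (y[i] > -1e-14) y[i] = 0.0;
        else stop("integration failure: pool '%s' went negative (%.3e) at t = %.3f d",
                  pool_name(i), y[i], t + dt);
      }
    }
  }
  return List::create(_["time"] = time_out, _["state"] = state_out,
                      _["diag"] = diag_out);
}

// [[Rcpp::export]]
List deriv_core(NumericVector y, List pars, double temp, double kappa,
                Nullable<NumericVector> fq_fixed) {
  if (y.size() != NST) stop("state vector must have length %d", NST);
  Pars p = parse_pars(pars, fq_fixed);
  NumericVector dy(NST), dg(NDIAG);
  double yy[NST], dd[NST], gg[NDIAG];
  for (int i = 0; i < NST; ++i) yy[i] = y[i];
  deriv(yy, p, temp, kappa, dd, gg);
  for (int i = 0; i < NST; ++i) dy[i] = dd[i];
  for (int i = 0; i < NDIAG; ++i) dg[i] = gg[i];
  return List::create(_["dy"] = dy, _["diag"] = dg);
}
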