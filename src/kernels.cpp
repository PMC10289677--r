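// Hard-sphere crowding kernels: scaled-particle-theory activity coefficients,
// the crowding-adjusted Michaelis parameter, self-consistent binding equilibria,
// and the grid/point evaluations of the pathway and whole-cell models.
//
// Internal unit system: lengths in nm, number densities in molecules * nm^-3
// (1 uM = 6.02214076e-7 nm^-3), rates in s^-1. All conversion from/to uM happens
// at the R boundary.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static const double PI_ = 3.14159265358979323846;

static inline double sph_vol(double r)  { return 4.0 * PI_ / 3.0 * r * r * r; }
static inline double sph_surf(double r) { return 4.0 * PI_ * r * r; }

// ---------------------------------------------------------------------------
// SPT moments and activity coefficient
// ---------------------------------------------------------------------------

struct Moments {
  double m0;   // <<1>>  = sum w_i
  double mr;   // <<r>>  = sum w_i r_i
  double mr2;  // <<r>>_2 = sum w_i r_i^2
  double mS;   // <<S>>  = sum w_i 4 pi r_i^2
  double mV;   // <<V>>  = sum w_i (4 pi / 3) r_i^3
};

static inline Moments compute_moments(const double* w, const double* r, int n) {
  Moments m = {0.0, 0.0, 0.0, 0.0, 0.0};
  for (int i = 0; i < n; ++i) {
    const double wi = w[i], ri = r[i];
    if (wi <= 0.0) continue;
    m.m0  += wi;
    m.mr  += wi * ri;
    m.mr2 += wi * ri * ri;
    m.mV  += wi * sph_vol(ri);
  }
  m.mS = 4.0 * PI_ * m.mr2;
  return m;
}

// ln gamma_i for a probe hard sphere of radius ri in a mixture with moments m.
// SPT insertion work: -ln(1-<<V>>) + first-, second- and third-order terms;
// the third-order term V_i <<r>>_2 <<S>>^2 / (3 (1-<<V>>)^3) equals the SPT
// pressure contribution V_i <<S>>^3/(12 pi (1-<<V>>)^3) identically.
static inline double spt_lngamma(double ri, const Moments& m) {
  const double one = 1.0 - m.mV;
  const double Si = sph_surf(ri), Vi = sph_vol(ri);
  const double t1 = -std::log(one);
  const double t2 = (ri * m.mS + Si * m.mr + Vi * m.m0) / one;
  const double t3 = (ri * ri * m.mS * m.mS + 2.0 * Vi * m.mr * m.mS) /
                    (2.0 * one * one);
  const double t4 = Vi * m.mr2 * m.mS * m.mS / (3.0 * one * one * one);
  return t1 + t2 + t3 + t4;
}

// Crowding-adjusted Michaelis parameter; ed = exp(-g*rho).
static inline double km_star_formula(double K0, double Gamma, double theta,
                                     double ed) {
  return K0 * (Gamma + theta * ed) / ((1.0 + theta) * Gamma * ed);
}

// Exact complex concentration for E + S <-> C with dissociation parameter K:
// C = E_tot * S_free / (S_free + K), S_free = S_tot - C  =>  quadratic in C.
static inline double bind_quad(double Etot, double Stot, double K) {
  if (Etot <= 0.0 || Stot <= 0.0) return 0.0;
  const double b = Etot + Stot + K;
  double disc = b * b - 4.0 * Etot * Stot;
  if (disc < 0.0) disc = 0.0;
  double C = 2.0 * Etot * Stot / (b + std::sqrt(disc)); // stable form
  const double cap = std::min(Etot, Stot);
  if (C < 0.0) C = 0.0;
  if (C > cap) C = cap;
  return C;
}

// ---------------------------------------------------------------------------
// Exported scalar/vector primitives
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cc_lngamma")]]
NumericVector cc_lngamma(NumericVector probe_r, NumericVector w,
                         NumericVector r) {
  const int nmix = w.size(), np = probe_r.size();
  Moments m = compute_moments(nmix ? &w[0] : nullptr,
                              nmix ? &r[0] : nullptr, nmix);
  if (m.mV >= 1.0) stop("mixture over-packed: occupied fraction >= 1");
  NumericVector out(np);
  for (int i = 0; i < np; ++i) out[i] = spt_lngamma(probe_r[i], m);
  return out;
}

// [[Rcpp::export(name = ".cc_km_star_formula")]]
double cc_km_star_formula(double K0, double Gamma, double theta, double ed) {
  return km_star_formula(K0, Gamma, theta, ed);
}

// ---------------------------------------------------------------------------
// General single-reaction self-consistent binding equilibrium
// ---------------------------------------------------------------------------
// Reaction species (substrate, catalyst, complex) plus an inert crowding
// background. n_lump > 1 treats the totals as summed over n_lump identical
// reactions (effective dissociation n_lump * KM*). mode: 0 full,
// 1 diffusion-only (Gamma := 1), 2 transition-only (exp(-g rho) := 1).

// [[Rcpp::export(name = ".cc_binding_solve")]]
List cc_binding_solve(double cat_tot, double sub_tot, double K0, double theta,
                      double r_sub, double r_cat, double r_cpl, double g_sub,
                      double n_lump, NumericVector bg_w, NumericVector bg_r,
                      int mode, double tol, int max_iter) {
  const int nbg = bg_w.size();
  std::vector<double> w(nbg + 3), r(nbg + 3);
  for (int i = 0; i < nbg; ++i) { w[i] = bg_w[i]; r[i] = bg_r[i]; }
  r[nbg] = r_sub; r[nbg + 1] = r_cat; r[nbg + 2] = r_cpl;

  double C = 0.0, Km = K0, Km_prev = -1.0, dKm_prev = 0.0;
  double sf = sub_tot, cf = cat_tot;
  bool conv = false;
  int it = 0;
  double lng_s = 0.0, lng_c = 0.0, lng_x = 0.0, Gamma = 1.0, ed = 1.0, mV = 0.0;

  for (it = 1; it <= max_iter; ++it) {
    w[nbg] = sf; w[nbg + 1] = cf; w[nbg + 2] = C;
    Moments m = compute_moments(w.data(), r.data(), nbg + 3);
    mV = m.mV;
    if (mV >= 1.0) stop("mixture over-packed: occupied fraction >= 1");
    if (mode == 1) {
      Gamma = 1.0; lng_s = lng_c = lng_x = NA_REAL;
    } else {
      lng_s = spt_lngamma(r_sub, m);
      lng_c = spt_lngamma(r_cat, m);
      lng_x = spt_lngamma(r_cpl, m);
      Gamma = std::exp(lng_s + lng_c - lng_x);
    }
    ed = (mode == 2) ? 1.0 : std::exp(-g_sub * mV);
    double Km_new = km_star_formula(K0, Gamma, theta, ed);

    double C_new = bind_quad(cat_tot, sub_tot, n_lump * Km_new);
    // damp the complex update if the KM* iteration starts to oscillate
    if (Km_prev > 0.0) {
      const double dKm = Km_new - Km;
      if (dKm * dKm_prev < 0.0) C_new = 0.5 * (C_new + C);
      dKm_prev = dKm;
    }
    C = C_new;
    sf = sub_tot - C; cf = cat_tot - C;

    const double rel = (Km > 0.0) ? std::fabs(Km_new - Km) / Km_new : 1.0;
    Km_prev = Km; Km = Km_new;
    if (it > 1 && rel < tol) { conv = true; break; }
  }
  // final polish: complex exactly consistent with the converged KM*
  C = bind_quad(cat_tot, sub_tot, n_lump * Km);
  sf = sub_tot - C; cf = cat_tot - C;

  return List::create(
    _["complex"] = C, _["substrate_free"] = sf, _["catalyst_free"] = cf,
    _["km_star"] = Km, _["Gamma"] = Gamma, _["diffusion_factor"] = ed,
    _["gamma_ln_substrate"] = lng_s, _["gamma_ln_catalyst"] = lng_c,
    _["gamma_ln_complex"] = lng_x, _["occupancy"] = mV,
    _["iterations"] = it, _["converged"] = conv);
}

// ---------------------------------------------------------------------------
// Pathway model grid scan
// ---------------------------------------------------------------------------

struct PathPoint {
  double flux, mu, km_norm;
  int iter; bool conv;
};

static PathPoint pathway_point(double rho, double f, double N, double kcat,
                               double K0, double theta, double rs, double rE,
                               bool parallel, double g_s, int mode,
                               double tol, int max_iter) {
  const double Vs = sph_vol(rs), VE = sph_vol(rE);
  const double ns = f * rho / Vs, nE = (1.0 - f) * rho / VE;
  const double rC = std::cbrt(rE * rE * rE + rs * rs * rs);

  double w[3], r[3] = {rs, rE, rC};
  double C = 0.0, sf = ns, Ef = nE;
  double Km = K0, Km_prev = -1.0, dKm_prev = 0.0;
  bool conv = false;
  int it = 0;
  for (it = 1; it <= max_iter; ++it) {
    w[0] = sf; w[1] = Ef; w[2] = C;
    Moments m = compute_moments(w, r, 3);
    double Gamma = 1.0;
    if (mode != 1)
      Gamma = std::exp(spt_lngamma(rs, m) + spt_lngamma(rE, m) -
                       spt_lngamma(rC, m));
    const double ed = (mode == 2) ? 1.0 : std::exp(-g_s * m.mV);
    const double Km_new = km_star_formula(K0, Gamma, theta, ed);
    double C_new = bind_quad(nE, ns, N * Km_new);
    if (Km_prev > 0.0) {
      const double dKm = Km_new - Km;
      if (dKm * dKm_prev < 0.0) C_new = 0.5 * (C_new + C);
      dKm_prev = dKm;
    }
    C = C_new; sf = ns - C; Ef = nE - C;
    const double rel = std::fabs(Km_new - Km) / Km_new;
    Km_prev = Km; Km = Km_new;
    if (it > 1 && rel < tol) { conv = true; break; }
  }
  PathPoint out;
  out.flux = (kcat / N) * ns * nE / (N * Km + ns);   // totals, Eq S8 convention
  out.mu = (rho > 0.0) ? out.flux / rho : NA_REAL;
  if (parallel) out.mu *= N;
  out.km_norm = Km / K0;
  out.iter = it; out.conv = conv;
  return out;
}

// Full scan over (rho, substrate volume share) grids. Returns either the full
// table or the per-rho envelope (max over share) of flux and mu.
// [[Rcpp::export(name = ".cc_pathway_scan")]]
List cc_pathway_scan(NumericVector rho, NumericVector share, double N,
                     double kcat, double K0, double theta, double rs,
                     double rE, bool parallel, double g_s, int mode,
                     double tol, int max_iter, bool full) {
  const int nr = rho.size(), nf = share.size();
  NumericVector env_mu(nr), env_flux(nr), env_share_mu(nr), env_share_flux(nr),
      env_km_mu(nr);
  IntegerVector env_nfail(nr);
  NumericVector tab_flux, tab_mu, tab_km;
  LogicalVector tab_conv;
  if (full) {
    tab_flux = NumericVector(nr * nf); tab_mu = NumericVector(nr * nf);
    tab_km = NumericVector(nr * nf); tab_conv = LogicalVector(nr * nf);
  }
  for (int i = 0; i < nr; ++i) {
    double best_mu = R_NegInf, best_flux = R_NegInf;
    double bsm = NA_REAL, bsf = NA_REAL, bkm = NA_REAL;
    int nfail = 0;
    for (int j = 0; j < nf; ++j) {
      PathPoint p = pathway_point(rho[i], share[j], N, kcat, K0, theta, rs, rE,
                                  parallel, g_s, mode, tol, max_iter);
      if (full) {
        const int k = i * nf + j;
        tab_flux[k] = p.flux; tab_mu[k] = p.mu; tab_km[k] = p.km_norm;
        tab_conv[k] = p.conv;
      }
      if (!p.conv) { ++nfail; continue; } // excluded from envelopes
      if (p.mu > best_mu)   { best_mu = p.mu; bsm = share[j]; bkm = p.km_norm; }
      if (p.flux > best_flux) { best_flux = p.flux; bsf = share[j]; }
    }
    env_mu[i] = best_mu; env_flux[i] = best_flux;
    env_share_mu[i] = bsm; env_share_flux[i] = bsf; env_km_mu[i] = bkm;
    env_nfail[i] = nfail;
  }
  List out = List::create(
    _["rho"] = rho, _["mu"] = env_mu, _["flux"] = env_flux,
    _["share_at_mu"] = env_share_mu, _["share_at_flux"] = env_share_flux,
    _["km_norm_at_mu"] = env_km_mu, _["n_failed"] = env_nfail);
  if (full)
    out["table"] = List::create(_["flux"] = tab_flux, _["mu"] = tab_mu,
                                _["km_norm"] = tab_km, _["converged"] = tab_conv);
  return out;
}

// ---------------------------------------------------------------------------
// Whole-cell model point evaluation
// ---------------------------------------------------------------------------
// Parameter vector layout (all internal units):
//  0 kcatT  1 KMT  2 sext  3 kcatM  4 K0M  5 thetaM  6 kcatR  7 K0R  8 thetaR
//  9 N  10 lT  11 lM  12 lR  13 rs  14 rM  15 rp  16 rR  17 gM  18 gR
// 19 crowding(0/1)  20 max_iter  21 tol  22 n_p_grid

struct WCPar {
  double kcatT, KMT, sext, kcatM, K0M, thetaM, kcatR, K0R, thetaR;
  double N, lT, lM, lR, rs, rM, rp, rR, gM, gR;
  bool crowding; int max_iter; double tol; int npgrid;
  double Vs, VM, Vp, VR, rMs, rRp;
};

static WCPar unpack_par(const NumericVector& v) {
  WCPar P;
  P.kcatT = v[0]; P.KMT = v[1]; P.sext = v[2];
  P.kcatM = v[3]; P.K0M = v[4]; P.thetaM = v[5];
  P.kcatR = v[6]; P.K0R = v[7]; P.thetaR = v[8];
  P.N = v[9]; P.lT = v[10]; P.lM = v[11]; P.lR = v[12];
  P.rs = v[13]; P.rM = v[14]; P.rp = v[15]; P.rR = v[16];
  P.gM = v[17]; P.gR = v[18];
  P.crowding = v[19] != 0.0; P.max_iter = (int)v[20]; P.tol = v[21];
  P.npgrid = (int)v[22];
  P.Vs = sph_vol(P.rs); P.VM = sph_vol(P.rM);
  P.Vp = sph_vol(P.rp); P.VR = sph_vol(P.rR);
  P.rMs = std::cbrt(P.rM * P.rM * P.rM + P.rs * P.rs * P.rs);
  P.rRp = std::cbrt(P.rR * P.rR * P.rR + P.rp * P.rp * P.rp);
  return P;
}

struct WCState {
  double s, p, M, R, T, CM, CR, KmM, KmR, vT, vM, vR, mu, res_s, res_p;
  int iter; bool conv, ok;
};

// Coupled self-consistent binding equilibria of the metabolic and ribosomal
// reactions sharing one crowding background (T excluded). Totals in nm^-3.
static bool wc_equilibrium(double s, double p, double M, double R,
                           const WCPar& P, double& KmM, double& KmR,
                           double& CM, double& CR, int& iters) {
  KmM = P.K0M; KmR = P.K0R; CM = 0.0; CR = 0.0; iters = 0;
  const double rho = s * P.Vs + M * P.VM + p * P.Vp + R * P.VR;
  if (rho >= 1.0) return false;
  if (!P.crowding) {
    CM = bind_quad(M, s, P.N * KmM);
    CR = bind_quad(R, p, KmR);
    iters = 1;
    return true;
  }
  const double edM = std::exp(-P.gM * rho), edR = std::exp(-P.gR * rho);
  double w[6], r[6] = {P.rs, P.rM, P.rMs, P.rp, P.rR, P.rRp};
  double dM_prev = 0.0, dR_prev = 0.0;
  bool started = false;
  for (int it = 1; it <= P.max_iter; ++it) {
    iters = it;
    w[0] = s - CM; w[1] = M - CM; w[2] = CM;
    w[3] = p - CR; w[4] = R - CR; w[5] = CR;
    Moments m = compute_moments(w, r, 6);
    const double lrs = spt_lngamma(P.rs, m), lrM = spt_lngamma(P.rM, m),
                 lrMs = spt_lngamma(P.rMs, m), lrp = spt_lngamma(P.rp, m),
                 lrR = spt_lngamma(P.rR, m), lrRp = spt_lngamma(P.rRp, m);
    const double GammaM = std::exp(lrs + lrM - lrMs);
    const double GammaR = std::exp(lrp + lrR - lrRp);
    const double KmM_new = km_star_formula(P.K0M, GammaM, P.thetaM, edM);
    const double KmR_new = km_star_formula(P.K0R, GammaR, P.thetaR, edR);
    double CM_new = bind_quad(M, s, P.N * KmM_new);
    double CR_new = bind_quad(R, p, KmR_new);
    if (started) {
      const double dM = KmM_new - KmM, dR = KmR_new - KmR;
      if (dM * dM_prev < 0.0) CM_new = 0.5 * (CM_new + CM);
      if (dR * dR_prev < 0.0) CR_new = 0.5 * (CR_new + CR);
      dM_prev = dM; dR_prev = dR;
    } else {
      dM_prev = KmM_new - KmM; dR_prev = KmR_new - KmR;
      started = true;
    }
    const double relM = std::fabs(KmM_new - KmM) / KmM_new;
    const double relR = std::fabs(KmR_new - KmR) / KmR_new;
    CM = CM_new; CR = CR_new; KmM = KmM_new; KmR = KmR_new;
    if (it > 1 && relM < P.tol && relR < P.tol) return true;
  }
  return false;
}

// Evaluate the model at totals (s, p, M) with R fixed by the occupancy
// constraint and T fixed by the substrate balance (closed-form quadratic).
static WCState wc_eval(double s, double p, double M, double rho,
                       const WCPar& P) {
  WCState st; st.ok = false; st.conv = false; st.iter = 0;
  st.s = s; st.p = p; st.M = M;
  st.mu = NA_REAL;
  const double volR = rho - s * P.Vs - M * P.VM - p * P.Vp;
  if (volR < 0.0) return st;
  const double R = volR / P.VR;
  st.R = R;
  double KmM, KmR, CM, CR; int iters;
  st.conv = wc_equilibrium(s, p, M, R, P, KmM, KmR, CM, CR, iters);
  st.iter = iters;
  if (!st.conv) return st;
  st.KmM = KmM; st.KmR = KmR; st.CM = CM; st.CR = CR;
  st.vM = (P.kcatM / P.N) * s * M / (P.N * KmM + s);
  st.vR = P.kcatR * p * R / (KmR + p);
  const double A = P.kcatT * P.sext / (P.sext + P.KMT);
  const double P0 = P.lM * M + P.lR * R;
  // A*lT*T^2 + (A*P0 - vM*lT)*T - (vM*P0 + vR*s) = 0, take positive root
  double T;
  if (A <= 0.0) {
    if (st.vM > 0.0) return st;  // no import possible but pathway consumes
    T = 0.0;
  } else {
    const double a2 = A * P.lT, b = A * P0 - st.vM * P.lT,
                 c = -(st.vM * P0 + st.vR * s);
    if (a2 <= 0.0) {
      T = (b > 0.0) ? (-c / b) : 0.0;
    } else {
      const double disc = b * b - 4.0 * a2 * c;
      T = (-b + std::sqrt(std::max(disc, 0.0))) / (2.0 * a2);
    }
    if (T < 0.0) T = 0.0;
  }
  st.T = T;
  st.vT = A * T;
  const double prot = P.lM * M + P.lR * R + P.lT * T;
  st.mu = (prot > 0.0) ? st.vR / prot : NA_REAL;
  if (!std::isfinite(st.mu)) return st;
  st.res_s = st.vT - st.vM - st.mu * s;
  st.res_p = st.vM - st.vR - st.mu * p;
  st.ok = true;
  return st;
}

// res_p as a function of p at fixed (s, M, rho): used for root bracketing.
static double wc_resp(double s, double M, double p, double rho, const WCPar& P,
                      WCState& st) {
  st = wc_eval(s, p, M, rho, P);
  return st.ok ? st.res_p : NA_REAL;
}

// Find the precursor concentration(s) solving the p balance and return the
// state of the root with the highest growth rate.
static WCState wc_best_p(double s, double M, double rho, const WCPar& P) {
  WCState bad; bad.ok = false; bad.mu = NA_REAL;
  const double volp = rho - s * P.Vs - M * P.VM;
  if (volp <= 0.0) return bad;
  const double pmax = volp / P.Vp;
  const int ng = std::max(P.npgrid, 8);
  const double lo = std::log(pmax) - 18.0, hi = std::log(pmax * (1.0 - 1e-9));
  std::vector<double> lp(ng), fv(ng);
  WCState tmp;
  for (int i = 0; i < ng; ++i) {
    lp[i] = lo + (hi - lo) * i / (ng - 1.0);
    fv[i] = wc_resp(s, M, std::exp(lp[i]), rho, P, tmp);
  }
  WCState best = bad; double best_mu = R_NegInf;
  for (int i = 0; i + 1 < ng; ++i) {
    if (!std::isfinite(fv[i]) || !std::isfinite(fv[i + 1])) continue;
    if (fv[i] == 0.0) {
      wc_resp(s, M, std::exp(lp[i]), rho, P, tmp);
      if (tmp.ok && tmp.mu > best_mu) { best = tmp; best_mu = tmp.mu; }
      continue;
    }
    if (fv[i] * fv[i + 1] > 0.0) continue;
    // Illinois regula falsi on log p
    double a = lp[i], b = lp[i + 1], fa = fv[i], fb = fv[i + 1];
    double c = a, fc = fa;
    WCState stc;
    for (int k = 0; k < 100; ++k) {
      c = (a * fb - b * fa) / (fb - fa);
      if (!std::isfinite(c)) break;
      fc = wc_resp(s, M, std::exp(c), rho, P, stc);
      if (!std::isfinite(fc)) break;
      const double scale = std::max({std::fabs(stc.vM), std::fabs(stc.vR),
                                     std::fabs(stc.mu * stc.p), 1e-300});
      if (std::fabs(fc) <= 1e-11 * scale || std::fabs(b - a) < 1e-14) break;
      if (fa * fc < 0.0) { b = c; fb = fc; fa *= 0.5; }
      else               { a = c; fa = fc; fb *= 0.5; }
      // re-anchor: plain regula falsi step from fresh endpoints
      if (fa * fc < 0.0) { /* handled above */ }
    }
    if (stc.ok && std::isfinite(stc.mu) && stc.mu > best_mu) {
      best = stc; best_mu = stc.mu;
    }
  }
  return best;
}

static inline void softmax_shares(double z1, double z2, double& a_s,
                                  double& a_M) {
  const double zmax = std::max({z1, z2, 0.0});
  const double e1 = std::exp(z1 - zmax), e2 = std::exp(z2 - zmax),
               e3 = std::exp(-zmax);
  const double tot = e1 + e2 + e3;
  a_s = e1 / tot; a_M = e2 / tot;
}

static List wc_state_list(const WCState& st) {
  return List::create(
    _["ok"] = st.ok, _["converged"] = st.conv, _["iterations"] = st.iter,
    _["mu"] = st.mu, _["s"] = st.s, _["p"] = st.p, _["T"] = st.T,
    _["M"] = st.M, _["R"] = st.R, _["complex_M"] = st.CM,
    _["complex_R"] = st.CR, _["km_star_M"] = st.KmM, _["km_star_R"] = st.KmR,
    _["v_T"] = st.vT, _["v_M"] = st.vM, _["v_R"] = st.vR,
    _["res_s"] = st.res_s, _["res_p"] = st.res_p);
}

// Growth rate (internal units) at softmax coordinates; NaN if infeasible.
// [[Rcpp::export(name = ".cc_wc_mu")]]
double cc_wc_mu(double z1, double z2, double rho, NumericVector par) {
  const WCPar P = unpack_par(par);
  double a_s, a_M;
  softmax_shares(z1, z2, a_s, a_M);
  const double s = a_s * rho / P.Vs, M = a_M * rho / P.VM;
  WCState st = wc_best_p(s, M, rho, P);
  return st.ok ? st.mu : NA_REAL;
}

// Full state at softmax coordinates.
// [[Rcpp::export(name = ".cc_wc_state")]]
List cc_wc_state(double z1, double z2, double rho, NumericVector par) {
  const WCPar P = unpack_par(par);
  double a_s, a_M;
  softmax_shares(z1, z2, a_s, a_M);
  const double s = a_s * rho / P.Vs, M = a_M * rho / P.VM;
  WCState st = wc_best_p(s, M, rho, P);
  return wc_state_list(st);
}

// Direct evaluation at given totals (s, p, M) in nm^-3 (R from occupancy,
// T from the substrate balance); used by the R reference path and tests.
// [[Rcpp::export(name = ".cc_wc_eval_spm")]]
List cc_wc_eval_spm(double s, double p, double M, double rho,
                    NumericVector par) {
  const WCPar P = unpack_par(par);
  return wc_state_list(wc_eval(s, p, M, rho, P));
}

// Coupled equilibrium alone at given totals (all five fixed), for testing.
// [[Rcpp::export(name = ".cc_wc_equilibrium")]]
List cc_wc_equilibrium(double s, double p, double M, double R,
                       NumericVector par) {
  const WCPar P = unpack_par(par);
  double KmM, KmR, CM, CR; int iters;
  bool conv = wc_equilibrium(s, p, M, R, P, KmM, KmR, CM, CR, iters);
  return List::create(_["converged"] = conv, _["km_star_M"] = KmM,
                      _["km_star_R"] = KmR, _["complex_M"] = CM,
                      _["complex_R"] = CR, _["iterations"] = iters);
}
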