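// O'Hara-Rudy dynamic (ORd) human ventricular myocyte model, endo/M/epi
// variants, with multiplicative conductance scalings on I_Na, I_NaL, I_CaL,
// I_Kr for drug block.  Hybrid Rush-Larsen / forward-Euler steppers for a
// single cell and for monodomain tissue (sparse diffusion operator supplied
// from R); pure forward Euler available via method = "fe".
//
// All currents are per membrane capacitance (A/F), so dV/dt is in mV/ms and
// the single-cell equations are independent of the tissue C_m.

#include <Rcpp.h>
#include <cmath>
#include <cstring>
using namespace Rcpp;

static const int NSTATE = 41;

// state indices
enum {
  iV = 0, iNai, iNass, iKi, iKss, iCai, iCass, iCansr, iCajsr,
  iM, iHf, iHs, iJ, iHsp, iJp, iML, iHL, iHLp,
  iA, iIF, iIS, iAp, iIFp, iISp,
  iD, iFF, iFS, iFcaf, iFcas, iJca, iNca, iFFp, iFcafp,
  iXrf, iXrs, iXs1, iXs2, iXk1, iJrelnp, iJrelp, iCaMKt
};

// cell types
enum { ENDO = 0, EPI = 1, MCELL = 2 };

// extracellular concentrations and physical constants
static const double nao = 140.0, cao = 1.8, ko = 5.4;
static const double Rgas = 8314.0, Temp = 310.0, Frdy = 96485.0;

// cell geometry
static const double Lcell = 0.01, rad = 0.0011;
static const double vcell = 1000.0 * 3.14 * rad * rad * Lcell;
static const double Ageo = 2.0 * 3.14 * rad * rad + 2.0 * 3.14 * rad * Lcell;
static const double Acap = 2.0 * Ageo;
static const double vmyo = 0.68 * vcell;
static const double vnsr = 0.0552 * vcell;
static const double vjsr = 0.0048 * vcell;
static const double vss  = 0.02 * vcell;

// x / (exp(k*x) - 1), safe near x = 0 (limit 1/k)
static inline double safe_ratio(double x, double k) {
  double kx = k * x;
  if (std::fabs(kx) < 1e-7) return (1.0 - kx / 2.0) / k;
  return x / std::expm1(kx);
}

struct Currents {
  double INa, INaL, Ito, ICaL, ICaNa, ICaK, IKr, IKs, IK1;
  double INaCa_i, INaCa_ss, INaK, INab, IKb, IpCa, ICab;
  double Jrel, Jup, Iion;
};

// Full right-hand side.  Fills derivatives d[] for the forward-Euler
// variables (Vm, concentrations, CaMKt) and steady-state/time-constant pairs
// ss[]/tau[] for every relaxation-form variable (indices iM..iJrelp), which
// the steppers integrate by forward Euler or Rush-Larsen exponential update.
// scal = {sNa, sNaL, sCaL, sKr} in [0,1].
static void ord_rhs(const double *y, int celltype, const double *scal,
                    double Istim, double *d, double *ss, double *tau,
                    Currents &cur) {
  const double v = y[iV];
  const double nai = y[iNai], nass = y[iNass];
  const double ki = y[iKi], kss = y[iKss];
  const double cai = y[iCai], cass = y[iCass];
  const double cansr = y[iCansr], cajsr = y[iCajsr];

  // CaMK
  const double KmCaMK = 0.15, aCaMK = 0.05, bCaMK = 0.00068;
  const double CaMKo = 0.05, KmCaM = 0.0015;
  double CaMKb = CaMKo * (1.0 - y[iCaMKt]) / (1.0 + KmCaM / cass);
  double CaMKa = CaMKb + y[iCaMKt];
  d[iCaMKt] = aCaMK * CaMKb * (CaMKb + y[iCaMKt]) - bCaMK * y[iCaMKt];

  // reversal potentials
  const double rtf = Rgas * Temp / Frdy;
  double ENa = rtf * std::log(nao / nai);
  double EK = rtf * std::log(ko / ki);
  const double PKNa = 0.01833;
  double EKs = rtf * std::log((ko + PKNa * nao) / (ki + PKNa * nai));
  double vfrt = v / rtf;

  // I_Na (fast)
  double mss = 1.0 / (1.0 + std::exp(-(v + 39.57) / 9.871));
  double tm = 1.0 / (6.765 * std::exp((v + 11.64) / 34.77) +
                     8.552 * std::exp(-(v + 77.42) / 5.955));
  ss[iM] = mss; tau[iM] = tm;
  double hss = 1.0 / (1.0 + std::exp((v + 82.90) / 6.086));
  double thf = 1.0 / (1.432e-5 * std::exp(-(v + 1.196) / 6.285) +
                      6.149 * std::exp((v + 0.5096) / 20.27));
  double ths = 1.0 / (0.009794 * std::exp(-(v + 17.95) / 28.05) +
                      0.3343 * std::exp((v + 5.730) / 56.66));
  const double Ahf = 0.99, Ahs = 1.0 - Ahf;
  ss[iHf] = hss; tau[iHf] = thf;
  ss[iHs] = hss; tau[iHs] = ths;
  double h = Ahf * y[iHf] + Ahs * y[iHs];
  double jss = hss;
  double tj = 2.038 + 1.0 / (0.02136 * std::exp(-(v + 100.6) / 8.281) +
                             0.3052 * std::exp((v + 0.9941) / 38.45));
  ss[iJ] = jss; tau[iJ] = tj;
  double hssp = 1.0 / (1.0 + std::exp((v + 89.1) / 6.086));
  double thsp = 3.0 * ths;
  ss[iHsp] = hssp; tau[iHsp] = thsp;
  double hp = Ahf * y[iHf] + Ahs * y[iHsp];
  double tjp = 1.46 * tj;
  ss[iJp] = jss; tau[iJp] = tjp;
  double GNa = 75.0 * scal[0];
  double fINap = 1.0 / (1.0 + KmCaMK / CaMKa);
  cur.INa = GNa * (v - ENa) * y[iM] * y[iM] * y[iM] *
            ((1.0 - fINap) * h * y[iJ] + fINap * hp * y[iJp]);

  // I_NaL (late)
  double mLss = 1.0 / (1.0 + std::exp(-(v + 42.85) / 5.264));
  double tmL = tm;
  ss[iML] = mLss; tau[iML] = tmL;
  double hLss = 1.0 / (1.0 + std::exp((v + 87.61) / 7.488));
  const double thL = 200.0;
  ss[iHL] = hLss; tau[iHL] = thL;
  double hLssp = 1.0 / (1.0 + std::exp((v + 93.81) / 7.488));
  const double thLp = 3.0 * thL;
  ss[iHLp] = hLssp; tau[iHLp] = thLp;
  double GNaL = 0.0075 * scal[1];
  if (celltype == EPI) GNaL *= 0.6;
  double fINaLp = 1.0 / (1.0 + KmCaMK / CaMKa);
  cur.INaL = GNaL * (v - ENa) * y[iML] *
             ((1.0 - fINaLp) * y[iHL] + fINaLp * y[iHLp]);

  // I_to
  double ass = 1.0 / (1.0 + std::exp(-(v - 14.34) / 14.82));
  double ta = 1.0515 / (1.0 / (1.2089 * (1.0 + std::exp(-(v - 18.4099) / 29.3814))) +
                        3.5 / (1.0 + std::exp((v + 100.0) / 29.3814)));
  ss[iA] = ass; tau[iA] = ta;
  double iss = 1.0 / (1.0 + std::exp((v + 43.94) / 5.711));
  double delta_epi = (celltype == EPI)
                         ? 1.0 - 0.95 / (1.0 + std::exp((v + 70.0) / 5.0))
                         : 1.0;
  double tiF = 4.562 + 1.0 / (0.3933 * std::exp(-(v + 100.0) / 100.0) +
                              0.08004 * std::exp((v + 50.0) / 16.59));
  double tiS = 23.62 + 1.0 / (0.001416 * std::exp(-(v + 96.52) / 59.05) +
                              1.780e-8 * std::exp((v + 114.1) / 8.079));
  tiF *= delta_epi;
  tiS *= delta_epi;
  double AiF = 1.0 / (1.0 + std::exp((v - 213.6) / 151.2));
  double AiS = 1.0 - AiF;
  ss[iIF] = iss; tau[iIF] = tiF;
  ss[iIS] = iss; tau[iIS] = tiS;
  double ito_i = AiF * y[iIF] + AiS * y[iIS];
  double assp = 1.0 / (1.0 + std::exp(-(v - 24.34) / 14.82));
  ss[iAp] = assp; tau[iAp] = ta;
  double dti_develop = 1.354 + 1.0e-4 / (std::exp((v - 167.4) / 15.89) +
                                         std::exp(-(v - 12.23) / 0.2154));
  double dti_recover = 1.0 - 0.5 / (1.0 + std::exp((v + 70.0) / 20.0));
  double tiFp = dti_develop * dti_recover * tiF;
  double tiSp = dti_develop * dti_recover * tiS;
  ss[iIFp] = iss; tau[iIFp] = tiFp;
  ss[iISp] = iss; tau[iISp] = tiSp;
  double ito_ip = AiF * y[iIFp] + AiS * y[iISp];
  double Gto = 0.02;
  if (celltype == EPI || celltype == MCELL) Gto *= 4.0;
  double fItop = 1.0 / (1.0 + KmCaMK / CaMKa);
  cur.Ito = Gto * (v - EK) * ((1.0 - fItop) * y[iA] * ito_i +
                              fItop * y[iAp] * ito_ip);

  // I_CaL / I_CaNa / I_CaK
  double dss = 1.0 / (1.0 + std::exp(-(v + 3.940) / 4.230));
  double td = 0.6 + 1.0 / (std::exp(-0.05 * (v + 6.0)) +
                           std::exp(0.09 * (v + 14.0)));
  ss[iD] = dss; tau[iD] = td;
  double fss = 1.0 / (1.0 + std::exp((v + 19.58) / 3.696));
  double tff = 7.0 + 1.0 / (0.0045 * std::exp(-(v + 20.0) / 10.0) +
                            0.0045 * std::exp((v + 20.0) / 10.0));
  double tfs = 1000.0 + 1.0 / (0.000035 * std::exp(-(v + 5.0) / 4.0) +
                               0.000035 * std::exp((v + 5.0) / 6.0));
  const double Aff = 0.6, Afs = 1.0 - Aff;
  ss[iFF] = fss; tau[iFF] = tff;
  ss[iFS] = fss; tau[iFS] = tfs;
  double f = Aff * y[iFF] + Afs * y[iFS];
  double fcass = fss;
  double tfcaf = 7.0 + 1.0 / (0.04 * std::exp(-(v - 4.0) / 7.0) +
                              0.04 * std::exp((v - 4.0) / 7.0));
  double tfcas = 100.0 + 1.0 / (0.00012 * std::exp(-v / 3.0) +
                                0.00012 * std::exp(v / 7.0));
  double Afcaf = 0.3 + 0.6 / (1.0 + std::exp((v - 10.0) / 10.0));
  double Afcas = 1.0 - Afcaf;
  ss[iFcaf] = fcass; tau[iFcaf] = tfcaf;
  ss[iFcas] = fcass; tau[iFcas] = tfcas;
  double fca = Afcaf * y[iFcaf] + Afcas * y[iFcas];
  const double tjca = 75.0;
  ss[iJca] = fcass; tau[iJca] = tjca;
  double tffp = 2.5 * tff;
  ss[iFFp] = fss; tau[iFFp] = tffp;
  double fp = Aff * y[iFFp] + Afs * y[iFS];
  double tfcafp = 2.5 * tfcaf;
  ss[iFcafp] = fcass; tau[iFcafp] = tfcafp;
  double fcap = Afcaf * y[iFcafp] + Afcas * y[iFcas];
  const double Kmn = 0.002, k2n = 1000.0;
  double km2n = y[iJca] * 1.0;
  double t4 = (1.0 + Kmn / cass);
  double anca = 1.0 / (k2n / km2n + t4 * t4 * t4 * t4);
  ss[iNca] = anca * k2n / km2n; tau[iNca] = 1.0 / km2n;
  double PhiCaL = 4.0 * Frdy * (cass * std::exp(2.0 * vfrt) - 0.341 * cao) *
                  safe_ratio(vfrt, 2.0);
  double PhiCaNa = Frdy * (0.75 * nass * std::exp(vfrt) - 0.75 * nao) *
                   safe_ratio(vfrt, 1.0);
  double PhiCaK = Frdy * (0.75 * kss * std::exp(vfrt) - 0.75 * ko) *
                  safe_ratio(vfrt, 1.0);
  double PCa = 0.0001 * scal[2];
  if (celltype == EPI) PCa *= 1.2;
  if (celltype == MCELL) PCa *= 2.5;
  double PCap = 1.1 * PCa;
  double PCaNa = 0.00125 * PCa, PCaK = 3.574e-4 * PCa;
  double PCaNap = 0.00125 * PCap, PCaKp = 3.574e-4 * PCap;
  double fICaLp = 1.0 / (1.0 + KmCaMK / CaMKa);
  double gate_np = y[iD] * (f * (1.0 - y[iNca]) + y[iJca] * fca * y[iNca]);
  double gate_p = y[iD] * (fp * (1.0 - y[iNca]) + y[iJca] * fcap * y[iNca]);
  cur.ICaL = (1.0 - fICaLp) * PCa * PhiCaL * gate_np +
             fICaLp * PCap * PhiCaL * gate_p;
  cur.ICaNa = (1.0 - fICaLp) * PCaNa * PhiCaNa * gate_np +
              fICaLp * PCaNap * PhiCaNa * gate_p;
  cur.ICaK = (1.0 - fICaLp) * PCaK * PhiCaK * gate_np +
             fICaLp * PCaKp * PhiCaK * gate_p;

  // I_Kr
  double xrss = 1.0 / (1.0 + std::exp(-(v + 8.337) / 6.789));
  double txrf = 12.98 + 1.0 / (0.3652 * std::exp((v - 31.66) / 3.869) +
                               4.123e-5 * std::exp(-(v - 47.78) / 20.38));
  double txrs = 1.865 + 1.0 / (0.06629 * std::exp((v - 34.70) / 7.355) +
                               1.128e-5 * std::exp(-(v - 29.74) / 25.94));
  double Axrf = 1.0 / (1.0 + std::exp((v + 54.81) / 38.21));
  double Axrs = 1.0 - Axrf;
  ss[iXrf] = xrss; tau[iXrf] = txrf;
  ss[iXrs] = xrss; tau[iXrs] = txrs;
  double xr = Axrf * y[iXrf] + Axrs * y[iXrs];
  double rkr = 1.0 / (1.0 + std::exp((v + 55.0) / 75.0)) *
               1.0 / (1.0 + std::exp((v - 10.0) / 30.0));
  double GKr = 0.046 * scal[3];
  if (celltype == EPI) GKr *= 1.3;
  if (celltype == MCELL) GKr *= 0.8;
  cur.IKr = GKr * std::sqrt(ko / 5.4) * xr * rkr * (v - EK);

  // I_Ks
  double xs1ss = 1.0 / (1.0 + std::exp(-(v + 11.60) / 8.932));
  double txs1 = 817.3 + 1.0 / (2.326e-4 * std::exp((v + 48.28) / 17.80) +
                               0.001292 * std::exp(-(v + 210.0) / 230.0));
  ss[iXs1] = xs1ss; tau[iXs1] = txs1;
  double xs2ss = xs1ss;
  double txs2 = 1.0 / (0.01 * std::exp((v - 50.0) / 20.0) +
                       0.0193 * std::exp(-(v + 66.54) / 31.0));
  ss[iXs2] = xs2ss; tau[iXs2] = txs2;
  double KsCa = 1.0 + 0.6 / (1.0 + std::pow(3.8e-5 / cai, 1.4));
  double GKs = 0.0034;
  if (celltype == EPI) GKs *= 1.4;
  cur.IKs = GKs * KsCa * y[iXs1] * y[iXs2] * (v - EKs);

  // I_K1
  double xk1ss = 1.0 / (1.0 + std::exp(-(v + 2.5538 * ko + 144.59) /
                                       (1.5692 * ko + 3.8115)));
  double txk1 = 122.2 / (std::exp(-(v + 127.2) / 20.36) +
                         std::exp((v + 236.8) / 69.33));
  ss[iXk1] = xk1ss; tau[iXk1] = txk1;
  double rk1 = 1.0 / (1.0 + std::exp((v + 105.8 - 2.6 * ko) / 9.493));
  double GK1 = 0.1908;
  if (celltype == EPI) GK1 *= 1.2;
  if (celltype == MCELL) GK1 *= 1.3;
  cur.IK1 = GK1 * std::sqrt(ko) * rk1 * y[iXk1] * (v - EK);

  // I_NaCa (myoplasmic and subspace components)
  const double kna1 = 15.0, kna2 = 5.0, kna3 = 88.12, kasymm = 12.5;
  const double wna = 6.0e4, wca = 6.0e4, wnaca = 5.0e3;
  const double kcaon = 1.5e6, kcaoff = 5.0e3;
  const double qna = 0.5224, qca = 0.1670;
  double hca = std::exp(qca * vfrt);
  double hna = std::exp(qna * vfrt);
  double Gncx = 0.0008;
  if (celltype == EPI) Gncx *= 1.1;
  if (celltype == MCELL) Gncx *= 1.4;
  const double KmCaAct = 150.0e-6, zna = 1.0, zca = 2.0;

  double INaCa_out[2];
  for (int comp = 0; comp < 2; ++comp) {
    double na = comp == 0 ? nai : nass;
    double ca = comp == 0 ? cai : cass;
    double h1 = 1.0 + na / kna3 * (1.0 + hna);
    double h2 = (na * hna) / (kna3 * h1);
    double h3 = 1.0 / h1;
    double h4 = 1.0 + na / kna1 * (1.0 + na / kna2);
    double h5 = na * na / (h4 * kna1 * kna2);
    double h6 = 1.0 / h4;
    double h7 = 1.0 + nao / kna3 * (1.0 + 1.0 / hna);
    double h8 = nao / (kna3 * hna * h7);
    double h9 = 1.0 / h7;
    double h10 = kasymm + 1.0 + nao / kna1 * (1.0 + nao / kna2);
    double h11 = nao * nao / (h10 * kna1 * kna2);
    double h12 = 1.0 / h10;
    double k1 = h12 * cao * kcaon;
    double k2 = kcaoff;
    double k3p = h9 * wca;
    double k3pp = h8 * wnaca;
    double k3 = k3p + k3pp;
    double k4p = h3 * wca / hca;
    double k4pp = h2 * wnaca;
    double k4 = k4p + k4pp;
    double k5 = kcaoff;
    double k6 = h6 * ca * kcaon;
    double k7 = h5 * h2 * wna;
    double k8 = h8 * h11 * wna;
    double x1 = k2 * k4 * (k7 + k6) + k5 * k7 * (k2 + k3);
    double x2 = k1 * k7 * (k4 + k5) + k4 * k6 * (k1 + k8);
    double x3 = k1 * k3 * (k7 + k6) + k8 * k6 * (k2 + k3);
    double x4 = k2 * k8 * (k4 + k5) + k3 * k5 * (k1 + k8);
    double s = x1 + x2 + x3 + x4;
    double E1 = x1 / s, E2 = x2 / s, E3 = x3 / s, E4 = x4 / s;
    double allo = 1.0 / (1.0 + (KmCaAct / ca) * (KmCaAct / ca));
    double JncxNa = 3.0 * (E4 * k7 - E1 * k8) + E3 * k4pp - E2 * k3pp;
    double JncxCa = E2 * k2 - E1 * k1;
    double frac = comp == 0 ? 0.8 : 0.2;
    INaCa_out[comp] = frac * Gncx * allo * (zna * JncxNa + zca * JncxCa);
  }
  cur.INaCa_i = INaCa_out[0];
  cur.INaCa_ss = INaCa_out[1];

  // I_NaK
  {
    const double k1p = 949.5, k1m = 182.4, k2p = 687.2, k2m = 39.4;
    const double k3p = 1899.0, k3m = 79300.0, k4p = 639.0, k4m = 40.0;
    const double Knai0 = 9.073, Knao0 = 27.78, delta = -0.1550;
    double Knai = Knai0 * std::exp(delta * vfrt / 3.0);
    double Knao = Knao0 * std::exp((1.0 - delta) * vfrt / 3.0);
    const double Kki = 0.5, Kko = 0.3582;
    const double MgADP = 0.05, MgATP = 9.8, Kmgatp = 1.698e-7;
    const double Hp = 1.0e-7, eP = 4.2, Khp = 1.698e-7;
    const double Knap = 224.0, Kxkur = 292.0;
    double P = eP / (1.0 + Hp / Khp + nai / Knap + ki / Kxkur);
    double t_nai = 1.0 + nai / Knai, t_ki = 1.0 + ki / Kki;
    double t_nao = 1.0 + nao / Knao, t_ko = 1.0 + ko / Kko;
    double denom_i = t_nai * t_nai * t_nai + t_ki * t_ki - 1.0;
    double denom_o = t_nao * t_nao * t_nao + t_ko * t_ko - 1.0;
    double a1 = k1p * std::pow(nai / Knai, 3.0) / denom_i;
    double b1 = k1m * MgADP;
    double a2 = k2p;
    double b2 = k2m * std::pow(nao / Knao, 3.0) / denom_o;
    double a3 = k3p * (ko / Kko) * (ko / Kko) / denom_o;
    double b3 = k3m * P * Hp / (1.0 + MgATP / Kmgatp);
    double a4 = (k4p * MgATP / Kmgatp) / (1.0 + MgATP / Kmgatp);
    double b4 = k4m * (ki / Kki) * (ki / Kki) / denom_i;
    double x1 = a4 * a1 * a2 + b2 * b4 * b3 + a2 * b4 * b3 + b3 * a1 * a2;
    double x2 = b2 * b1 * b4 + a1 * a2 * a3 + a3 * b1 * b4 + a2 * a3 * b4;
    double x3 = a2 * a3 * a4 + b3 * b2 * b1 + b2 * b1 * a4 + a3 * a4 * b1;
    double x4 = b4 * b3 * b2 + a3 * a4 * a1 + b2 * a4 * a1 + b3 * b2 * a1;
    double s = x1 + x2 + x3 + x4;
    double E1 = x1 / s, E2 = x2 / s, E3 = x3 / s, E4 = x4 / s;
    const double zk = 1.0;
    double JnakNa = 3.0 * (E1 * a3 - E2 * b3);
    double JnakK = 2.0 * (E4 * b1 - E3 * a1);
    double Pnak = 30.0;
    if (celltype == EPI) Pnak *= 0.9;
    if (celltype == MCELL) Pnak *= 0.7;
    cur.INaK = Pnak * (zna * JnakNa + zk * JnakK);
  }

  // background and minor currents
  double xkb = 1.0 / (1.0 + std::exp(-(v - 14.48) / 18.34));
  double GKb = 0.003;
  if (celltype == EPI) GKb *= 0.6;
  cur.IKb = GKb * xkb * (v - EK);
  const double PNab = 3.75e-10;
  cur.INab = PNab * Frdy * (nai * std::exp(vfrt) - nao) * safe_ratio(vfrt, 1.0);
  const double PCab = 2.5e-8;
  cur.ICab = PCab * 4.0 * Frdy * (cai * std::exp(2.0 * vfrt) - 0.341 * cao) *
             safe_ratio(vfrt, 2.0);
  const double GpCa = 0.0005;
  cur.IpCa = GpCa * cai / (0.0005 + cai);

  // diffusion fluxes between subspace and myoplasm
  double JdiffNa = (nass - nai) / 2.0;
  double JdiffK = (kss - ki) / 2.0;
  double Jdiff = (cass - cai) / 0.2;

  // SR calcium release
  const double bt = 4.75;
  double a_rel = 0.5 * bt;
  double csqn_gate = 1.0 + std::pow(1.5 / cajsr, 8.0);
  double Jrel_inf = a_rel * (-cur.ICaL) / csqn_gate;
  if (celltype == MCELL) Jrel_inf *= 1.7;
  double tau_rel = bt / (1.0 + 0.0123 / cajsr);
  if (tau_rel < 0.001) tau_rel = 0.001;
  ss[iJrelnp] = Jrel_inf; tau[iJrelnp] = tau_rel;
  double btp = 1.25 * bt;
  double a_relp = 0.5 * btp;
  double Jrel_infp = a_relp * (-cur.ICaL) / csqn_gate;
  if (celltype == MCELL) Jrel_infp *= 1.7;
  double tau_relp = btp / (1.0 + 0.0123 / cajsr);
  if (tau_relp < 0.001) tau_relp = 0.001;
  ss[iJrelp] = Jrel_infp; tau[iJrelp] = tau_relp;
  double fJrelp = 1.0 / (1.0 + KmCaMK / CaMKa);
  cur.Jrel = (1.0 - fJrelp) * y[iJrelnp] + fJrelp * y[iJrelp];

  // SR calcium uptake / leak / translocation
  double Jupnp = 0.004375 * cai / (cai + 0.00092);
  double Jupp = 2.75 * 0.004375 * cai / (cai + 0.00092 - 0.00017);
  if (celltype == EPI) { Jupnp *= 1.3; Jupp *= 1.3; }
  double fJupp = 1.0 / (1.0 + KmCaMK / CaMKa);
  double Jleak = 0.0039375 * cansr / 15.0;
  cur.Jup = (1.0 - fJupp) * Jupnp + fJupp * Jupp - Jleak;
  double Jtr = (cansr - cajsr) / 100.0;

  // ionic concentration balances
  d[iNai] = -(cur.INa + cur.INaL + 3.0 * cur.INaCa_i + 3.0 * cur.INaK +
              cur.INab) * Acap / (Frdy * vmyo) + JdiffNa * vss / vmyo;
  d[iNass] = -(cur.ICaNa + 3.0 * cur.INaCa_ss) * Acap / (Frdy * vss) - JdiffNa;
  d[iKi] = -(cur.Ito + cur.IKr + cur.IKs + cur.IK1 + cur.IKb + Istim -
             2.0 * cur.INaK) * Acap / (Frdy * vmyo) + JdiffK * vss / vmyo;
  d[iKss] = -cur.ICaK * Acap / (Frdy * vss) - JdiffK;

  double cmdnmax = 0.05;
  if (celltype == EPI) cmdnmax *= 1.3;
  const double kmcmdn = 0.00238, trpnmax = 0.07, kmtrpn = 0.0005;
  const double BSRmax = 0.047, KmBSR = 0.00087;
  const double BSLmax = 1.124, KmBSL = 0.0087;
  const double csqnmax = 10.0, kmcsqn = 0.8;
  double t_c1 = kmcmdn + cai, t_c2 = kmtrpn + cai;
  double Bcai = 1.0 / (1.0 + cmdnmax * kmcmdn / (t_c1 * t_c1) +
                       trpnmax * kmtrpn / (t_c2 * t_c2));
  d[iCai] = Bcai * (-(cur.IpCa + cur.ICab - 2.0 * cur.INaCa_i) * Acap /
                        (2.0 * Frdy * vmyo) -
                    cur.Jup * vnsr / vmyo + Jdiff * vss / vmyo);
  double t_s1 = KmBSR + cass, t_s2 = KmBSL + cass;
  double Bcass = 1.0 / (1.0 + BSRmax * KmBSR / (t_s1 * t_s1) +
                        BSLmax * KmBSL / (t_s2 * t_s2));
  d[iCass] = Bcass * (-(cur.ICaL - 2.0 * cur.INaCa_ss) * Acap /
                          (2.0 * Frdy * vss) +
                      cur.Jrel * vjsr / vss - Jdiff);
  d[iCansr] = cur.Jup - Jtr * vjsr / vnsr;
  double t_j = kmcsqn + cajsr;
  double Bcajsr = 1.0 / (1.0 + csqnmax * kmcsqn / (t_j * t_j));
  d[iCajsr] = Bcajsr * (Jtr - cur.Jrel);

  cur.Iion = cur.INa + cur.INaL + cur.Ito + cur.ICaL + cur.ICaNa + cur.ICaK +
             cur.IKr + cur.IKs + cur.IK1 + cur.INaCa_i + cur.INaCa_ss +
             cur.INaK + cur.INab + cur.IKb + cur.IpCa + cur.ICab;
  d[iV] = -(cur.Iion + Istim);
}

// indices integrated in relaxation form (Rush-Larsen eligible)
static inline bool is_relax(int i) { return i >= iM && i <= iJrelp; }

// advance state in place by one step; method 0 = forward Euler, 1 = hybrid
// Rush-Larsen (exponential update for relaxation variables)
static inline void advance(double *y, const double *d, const double *ss,
                           const double *tau, double dt, int method) {
  for (int i = 0; i < NSTATE; ++i) {
    if (is_relax(i)) {
      if (method == 1)
        y[i] = ss[i] - (ss[i] - y[i]) * std::exp(-dt / tau[i]);
      else
        y[i] += dt * (ss[i] - y[i]) / tau[i];
    } else {
      y[i] += dt * d[i];
    }
  }
}

static int decode_method(const std::string &s) {
  if (s == "rl") return 1;
  if (s == "fe") return 0;
  stop("unknown integration method '" + s + "' (expected 'rl' or 'fe')");
  return -1;
}

static int decode_celltype(const std::string &s) {
  if (s == "endo") return ENDO;
  if (s == "epi") return EPI;
  if (s == "M" || s == "m") return MCELL;
  stop("unknown cell type '" + s + "' (expected 'endo', 'M' or 'epi')");
  return -1;
}

static CharacterVector state_names_vec() {
  return CharacterVector::create(
      "v", "nai", "nass", "ki", "kss", "cai", "cass", "cansr", "cajsr",
      "m", "hf", "hs", "j", "hsp", "jp", "mL", "hL", "hLp",
      "a", "iF", "iS", "ap", "iFp", "iSp",
      "d", "ff", "fs", "fcaf", "fcas", "jca", "nca", "ffp", "fcafp",
      "xrf", "xrs", "xs1", "xs2", "xk1", "Jrelnp", "Jrelp", "CaMKt");
}

// [[Rcpp::export]]
CharacterVector ord_state_names() { return state_names_vec(); }

// [[Rcpp::export]]
NumericVector ord_initial_state(std::string cell_type) {
  decode_celltype(cell_type); // validate
  NumericVector y(NSTATE);
  y[iV] = -87.0;
  y[iNai] = 7.0; y[iNass] = 7.0;
  y[iKi] = 145.0; y[iKss] = 145.0;
  y[iCai] = 1.0e-4; y[iCass] = 1.0e-4;
  y[iCansr] = 1.2; y[iCajsr] = 1.2;
  y[iM] = 0.0; y[iHf] = 1.0; y[iHs] = 1.0; y[iJ] = 1.0;
  y[iHsp] = 1.0; y[iJp] = 1.0;
  y[iML] = 0.0; y[iHL] = 1.0; y[iHLp] = 1.0;
  y[iA] = 0.0; y[iIF] = 1.0; y[iIS] = 1.0;
  y[iAp] = 0.0; y[iIFp] = 1.0; y[iISp] = 1.0;
  y[iD] = 0.0; y[iFF] = 1.0; y[iFS] = 1.0;
  y[iFcaf] = 1.0; y[iFcas] = 1.0; y[iJca] = 1.0;
  y[iNca] = 0.0; y[iFFp] = 1.0; y[iFcafp] = 1.0;
  y[iXrf] = 0.0; y[iXrs] = 0.0; y[iXs1] = 0.0; y[iXs2] = 0.0;
  y[iXk1] = 1.0;
  y[iJrelnp] = 0.0; y[iJrelp] = 0.0; y[iCaMKt] = 0.0;
  y.attr("names") = state_names_vec();
  return y;
}

static void check_state(const NumericVector &y) {
  if (y.size() != NSTATE)
    stop("state vector must have %d elements", NSTATE);
  for (int i = 0; i < NSTATE; ++i)
    if (!R_finite(y[i])) stop("non-finite value in state variable '%s'",
                              as<std::string>(as<CharacterVector>(state_names_vec())[i]).c_str());
}

static void get_scalings(const NumericVector &scalings, double *scal) {
  if (scalings.size() != 4)
    stop("scalings must have 4 elements (INa, INaL, ICaL, IKr)");
  for (int i = 0; i < 4; ++i) {
    if (!R_finite(scalings[i]) || scalings[i] < 0.0 || scalings[i] > 1.0)
      stop("channel scalings must lie in [0, 1]");
    scal[i] = scalings[i];
  }
}

// [[Rcpp::export]]
List ord_currents(NumericVector state, std::string cell_type,
                  NumericVector scalings, double stim = 0.0) {
  check_state(state);
  int ct = decode_celltype(cell_type);
  double scal[4];
  get_scalings(scalings, scal);
  double d[NSTATE], ss[NSTATE], tau[NSTATE];
  Currents cur;
  ord_rhs(REAL(state), ct, scal, stim, d, ss, tau, cur);
  return List::create(
      _["INa"] = cur.INa, _["INaL"] = cur.INaL, _["Ito"] = cur.Ito,
      _["ICaL"] = cur.ICaL, _["ICaNa"] = cur.ICaNa, _["ICaK"] = cur.ICaK,
      _["IKr"] = cur.IKr, _["IKs"] = cur.IKs, _["IK1"] = cur.IK1,
      _["INaCa_i"] = cur.INaCa_i, _["INaCa_ss"] = cur.INaCa_ss,
      _["INaK"] = cur.INaK, _["INab"] = cur.INab, _["IKb"] = cur.IKb,
      _["IpCa"] = cur.IpCa, _["ICab"] = cur.ICab,
      _["Iion"] = cur.Iion, _["Istim"] = stim,
      _["dVdt"] = -(cur.Iion + stim));
}

// [[Rcpp::export]]
NumericVector ord_step(NumericVector state, std::string cell_type,
                       NumericVector scalings, double stim, double dt,
                       std::string method = "rl") {
  check_state(state);
  if (dt <= 0.0) stop("dt must be positive");
  int ct = decode_celltype(cell_type);
  int mth = decode_method(method);
  double scal[4];
  get_scalings(scalings, scal);
  double d[NSTATE], ss[NSTATE], tau[NSTATE];
  Currents cur;
  NumericVector out = clone(state);
  ord_rhs(REAL(state), ct, scal, stim, d, ss, tau, cur);
  advance(REAL(out), d, ss, tau, dt, mth);
  for (int i = 0; i < NSTATE; ++i)
    if (!R_finite(out[i]))
      stop("numerical instability after step in state variable '%s'",
           as<std::string>(as<CharacterVector>(state_names_vec())[i]).c_str());
  out.attr("names") = state_names_vec();
  return out;
}

// Paced single-cell run.  Stimulus of stim_amp (A/F) for stim_dur (ms) at the
// start of each of n_beats cycles of length cl (ms).  Records Vm (and Cai) at
// save_stride steps, per-beat APD at `level` repolarization, and stops early
// when successive APDs differ by < tol (if tol > 0).
// [[Rcpp::export]]
List ord_pace(NumericVector state, std::string cell_type,
              NumericVector scalings, double cl, int n_beats, double dt,
              double stim_amp, double stim_dur, int save_stride,
              double tol, double level, bool gate_check,
              std::string method = "rl") {
  check_state(state);
  int ct = decode_celltype(cell_type);
  int mth = decode_method(method);
  double scal[4];
  get_scalings(scalings, scal);
  if (cl <= 0 || dt <= 0 || n_beats < 1) stop("invalid pacing protocol");
  if (stim_dur >= cl) stop("stimulus duration must be shorter than the cycle length");

  double y[NSTATE], d[NSTATE], ssv[NSTATE], tauv[NSTATE];
  std::memcpy(y, REAL(state), sizeof(y));
  Currents cur;

  long steps_per_beat = (long)std::llround(cl / dt);
  long total_steps = steps_per_beat * (long)n_beats;
  long nsave = total_steps / save_stride + 1;
  std::vector<double> t_out; t_out.reserve(nsave);
  std::vector<double> v_out; v_out.reserve(nsave);
  std::vector<double> cai_out; cai_out.reserve(nsave);
  std::vector<double> apd(n_beats, NA_REAL);
  std::vector<double> vpeak_v(n_beats, NA_REAL), vrest_v(n_beats, NA_REAL);
  std::vector<double> tup_v(n_beats, NA_REAL);
  std::vector<double> beat_start(n_beats, NA_REAL);

  // gate variables that must stay in [0,1] (nca is an occupancy fraction)
  static const int gate_idx[] = {iM, iHf, iHs, iJ, iHsp, iJp, iML, iHL, iHLp,
                                 iA, iIF, iIS, iAp, iIFp, iISp, iD, iFF, iFS,
                                 iFcaf, iFcas, iJca, iNca, iFFp, iFcafp,
                                 iXrf, iXrs, iXs1, iXs2, iXk1};
  bool gates_ok = true;

  int beats_run = 0;
  bool converged = false;
  long step = 0;
  for (int b = 0; b < n_beats && !converged; ++b) {
    beats_run = b + 1;
    beat_start[b] = b * cl;
    double vrest = y[iV];
    double vpeak = y[iV];
    double maxdvdt = -1e300;
    double tup = NA_REAL, tcross = NA_REAL;
    bool crossed = false;
    for (long s = 0; s < steps_per_beat; ++s, ++step) {
      double t = b * cl + s * dt;
      double stim = (s * dt < stim_dur) ? stim_amp : 0.0;
      if (step % save_stride == 0) {
        t_out.push_back(t);
        v_out.push_back(y[iV]);
        cai_out.push_back(y[iCai]);
      }
      double vold = y[iV];
      ord_rhs(y, ct, scal, stim, d, ssv, tauv, cur);
      advance(y, d, ssv, tauv, dt, mth);
      if (!R_finite(y[iV]) || std::fabs(y[iV]) > 500.0)
        stop("numerical instability at beat %d, t = %.3f ms", b + 1, t);
      double dvdt = (y[iV] - vold) / dt;
      if (dvdt > maxdvdt) { maxdvdt = dvdt; tup = t + dt; }
      if (y[iV] > vpeak) vpeak = y[iV];
      if (!crossed && y[iV] < vold) {
        double v90 = vpeak - level * (vpeak - vrest);
        if (y[iV] < v90 && vpeak - vrest > 20.0) {
          tcross = t + dt;
          crossed = true;
        }
      }
      if (gate_check && (step % 50 == 0)) {
        for (size_t g = 0; g < sizeof(gate_idx) / sizeof(int); ++g) {
          double gv = y[gate_idx[g]];
          if (gv < -1e-9 || gv > 1.0 + 1e-9) gates_ok = false;
        }
      }
    }
    vrest_v[b] = vrest;
    vpeak_v[b] = vpeak;
    tup_v[b] = tup;
    if (crossed && R_finite(tup)) apd[b] = tcross - tup;
    if (tol > 0 && b >= 1 && R_finite(apd[b]) && R_finite(apd[b - 1]) &&
        std::fabs(apd[b] - apd[b - 1]) < tol)
      converged = true;
  }
  // final sample
  t_out.push_back(beats_run * cl);
  v_out.push_back(y[iV]);
  cai_out.push_back(y[iCai]);

  NumericVector final_state(NSTATE);
  std::memcpy(REAL(final_state), y, sizeof(y));
  final_state.attr("names") = state_names_vec();

  apd.resize(beats_run); vpeak_v.resize(beats_run);
  vrest_v.resize(beats_run); tup_v.resize(beats_run);
  beat_start.resize(beats_run);
  return List::create(
      _["time"] = wrap(t_out), _["vm"] = wrap(v_out),
      _["cai"] = wrap(cai_out),
      _["apd"] = wrap(apd), _["v_peak"] = wrap(vpeak_v),
      _["v_rest"] = wrap(vrest_v), _["t_upstroke"] = wrap(tup_v),
      _["beat_start"] = wrap(beat_start),
      _["beats_run"] = beats_run, _["converged"] = converged,
      _["gates_in_range"] = gates_ok,
      _["final_state"] = final_state);
}

// Monodomain tissue run on an arbitrary mesh.  The diffusion operator
// (including D, zero-flux boundaries, mass lumping) is supplied as a sparse
// N x N matrix in compressed-column form (Li, Lp, Lx).  PMJ stimulation:
// node j with finite pmj_delay[j] receives stim_amp from each pacing time
// + delay until its Vm first exceeds cutoff (latch resets each beat).  With
// use_latch = false the stimulus instead lasts stim_dur ms.
// [[Rcpp::export]]
List ord_tissue_run(NumericMatrix states, IntegerVector cell_types,
                    NumericVector scalings,
                    IntegerVector Li, IntegerVector Lp, NumericVector Lx,
                    double dt, double duration,
                    NumericVector pacing_times, NumericVector pmj_delay,
                    double stim_amp, double cutoff_mV, double stim_dur,
                    bool use_latch, int save_stride,
                    double act_threshold, std::string method = "rl") {
  int N = states.ncol();
  if (states.nrow() != NSTATE) stop("states must be a %d x N matrix", NSTATE);
  if (cell_types.size() != N || pmj_delay.size() != N)
    stop("cell_types and pmj_delay must have one entry per node");
  if ((int)Lp.size() != N + 1) stop("operator dimension mismatch");
  double scal[4];
  get_scalings(scalings, scal);
  int mth = decode_method(method);
  if (dt <= 0 || duration <= 0) stop("invalid dt/duration");

  std::vector<double> Y(states.begin(), states.end()); // column-major, NSTATE*N
  std::vector<double> diff(N), d(NSTATE), ssv(NSTATE), tauv(NSTATE);
  long nsteps = (long)std::llround(duration / dt);
  long nsave = nsteps / save_stride + 1;
  NumericMatrix vm_out(N, (int)nsave);
  std::vector<double> t_out; t_out.reserve(nsave);
  NumericVector act_time(N, NA_REAL);
  std::vector<char> latched(N, 0);
  std::vector<int> beat_of(N, -1);
  Currents cur;
  int np = pacing_times.size();
  int isave = 0;

  for (long s = 0; s <= nsteps; ++s) {
    double t = s * dt;
    if (s % save_stride == 0 && isave < (int)nsave) {
      for (int j = 0; j < N; ++j) vm_out(j, isave) = Y[(size_t)j * NSTATE + iV];
      t_out.push_back(t);
      ++isave;
    }
    if (s == nsteps) break;

    // diffusion term: diff = L %*% Vm
    for (int j = 0; j < N; ++j) diff[j] = 0.0;
    for (int col = 0; col < N; ++col) {
      double vcol = Y[(size_t)col * NSTATE + iV];
      for (int k = Lp[col]; k < Lp[col + 1]; ++k)
        diff[Li[k]] += Lx[k] * vcol;
    }

    for (int j = 0; j < N; ++j) {
      double *y = &Y[(size_t)j * NSTATE];
      // stimulation
      double stim = 0.0;
      if (R_finite(pmj_delay[j])) {
        for (int p = 0; p < np; ++p) {
          double t0 = pacing_times[p] + pmj_delay[j];
          if (use_latch) {
            if (beat_of[j] < p && t >= t0) { beat_of[j] = p; latched[j] = 0; }
            if (beat_of[j] == p && !latched[j] && t >= t0) {
              if (y[iV] > cutoff_mV) latched[j] = 1;
              else stim = stim_amp;
            }
          } else if (t >= t0 && t < t0 + stim_dur) {
            stim = stim_amp;
          }
        }
      }
      double vold = y[iV];
      ord_rhs(y, (int)cell_types[j], scal, stim, d.data(), ssv.data(),
              tauv.data(), cur);
      advance(y, d.data(), ssv.data(), tauv.data(), dt, mth);
      y[iV] += dt * diff[j];
      if (!R_finite(y[iV]) || std::fabs(y[iV]) > 500.0)
        stop("numerical instability at node %d, t = %.3f ms "
             "(check the explicit stability bound dt <= dx^2/(2*d*D))",
             j + 1, t);
      if (!R_finite(act_time[j]) && vold < act_threshold &&
          y[iV] >= act_threshold)
        act_time[j] = t + dt;
    }
  }

  NumericMatrix final_states(NSTATE, N);
  std::copy(Y.begin(), Y.end(), final_states.begin());
  rownames(final_states) = state_names_vec();
  return List::create(_["time"] = wrap(t_out), _["vm"] = vm_out,
                      _["activation_time"] = act_time,
                      _["final_states"] = final_states);
}
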