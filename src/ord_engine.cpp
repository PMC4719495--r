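// Compiled engine for the epicardial ORd human ventricular cell model.
//
// Voltage-dependent gate rates and current helper factors are tabulated over
// membrane potential and linearly interpolated; Hodgkin-Huxley gates advance
// with the Rush-Larsen exponential update and concentrations/Vm with forward
// Euler on a two-level step (fine during stimulus/upstroke and steep
// repolarization, coarse elsewhere). The exact (untabulated) derivative is
// exported separately for cross-checks against adaptive stiff solvers.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// ---- constants (ORd conventions, epicardial variant) ----
static const double nao = 140.0, cao = 1.8, ko = 5.4;
static const double Rgas = 8314.0, Temp = 310.0, Frdy = 96485.0;
static const double FRT = Frdy / (Rgas * Temp);
static const double Lcell = 0.01, rady = 0.0011;
static const double vcell = 1000.0 * 3.14 * rady * rady * Lcell;
static const double Ageo = 2.0 * 3.14 * rady * rady + 2.0 * 3.14 * rady * Lcell;
static const double Acap = 2.0 * Ageo;
static const double vmyo = 0.68 * vcell, vnsr = 0.0552 * vcell;
static const double vjsr = 0.0048 * vcell, vss = 0.02 * vcell;

static const double aCaMK = 0.05, bCaMK = 0.00068, CaMKo = 0.05;
static const double KmCaM = 0.0015, KmCaMK = 0.15;

static const double cmdnmax = 0.05 * 1.3, kmcmdn = 0.00238;
static const double trpnmax = 0.07, kmtrpn = 0.0005;
static const double BSRmax = 0.047, KmBSR = 0.00087;
static const double BSLmax = 1.124, KmBSL = 0.0087;
static const double csqnmax = 10.0, kmcsqn = 0.8;

// baseline maximal conductances/permeabilities, epicardial scalings applied
static const double GNa0 = 75.0, GNaL0 = 0.0075 * 0.6, Gto0 = 0.02 * 4.0;
static const double PCa0 = 0.0001 * 1.2, GKr0 = 0.046 * 1.3;
static const double GKs0 = 0.0034 * 1.4, GK10 = 0.1908 * 1.2;
static const double Gncx0 = 0.0008 * 1.1, Pnak0 = 30.0 * 0.9;
static const double GKb0 = 0.003 * 0.6, PNab0 = 3.75e-10, PCab0 = 2.5e-8;
static const double GpCa0 = 0.0005;

static const int NSTATE = 41, NGATE = 28, NHELP = 14;
// state layout: 0 v,1 nai,2 nass,3 ki,4 kss,5 cai,6 cass,7 cansr,8 cajsr,
// 9..29 gates m..jca, 30 nca, 31 ffp, 32 fcafp, 33..37 xrf..xk1,
// 38 Jrelnp, 39 Jrelp, 40 CaMKt
static const int GIDX[NGATE] = {9,10,11,12,13,14,15,16,17,18,19,20,21,22,23,
                                24,25,26,27,28,29,31,32,33,34,35,36,37};
enum { G_m,G_hf,G_hs,G_j,G_hsp,G_jp,G_mL,G_hL,G_hLp,G_a,G_iF,G_iS,G_ap,
       G_iFp,G_iSp,G_d,G_ff,G_fs,G_fcaf,G_fcas,G_jca,G_ffp,G_fcafp,
       G_xrf,G_xrs,G_xs1,G_xs2,G_xk1 };
enum { H_expv,H_coef1,H_exp2v,H_coef2,H_hca,H_hna,H_Knai,H_Knao,
       H_rkr,H_rk1,H_xkb,H_Afcaf,H_AiF,H_Axrf };

// ---- exact voltage-dependent quantities ----
static void vdep_helpers(double v, double* H) {
  double vfrt = v * FRT;
  double vffrt = Frdy * vfrt;
  double em1 = std::expm1(vfrt);
  double em2 = std::expm1(2.0 * vfrt);
  H[H_expv] = std::exp(vfrt);
  H[H_coef1] = (std::fabs(vfrt) < 1e-8) ? Frdy : vffrt / em1;
  H[H_exp2v] = std::exp(2.0 * vfrt);
  H[H_coef2] = (std::fabs(vfrt) < 1e-8) ? 2.0 * Frdy : 4.0 * vffrt / em2;
  H[H_hca] = std::exp(0.1670 * vfrt);
  H[H_hna] = std::exp(0.5224 * vfrt);
  H[H_Knai] = 9.073 * std::exp(-0.1550 * vfrt / 3.0);
  H[H_Knao] = 27.78 * std::exp((1.0 + 0.1550) * vfrt / 3.0);
  H[H_rkr] = 1.0 / ((1.0 + std::exp((v + 55.0) / 75.0)) *
                    (1.0 + std::exp((v - 10.0) / 30.0)));
  H[H_rk1] = 1.0 / (1.0 + std::exp((v + 105.8 - 2.6 * ko) / 9.493));
  H[H_xkb] = 1.0 / (1.0 + std::exp(-(v - 14.48) / 18.34));
  H[H_Afcaf] = 0.3 + 0.6 / (1.0 + std::exp((v - 10.0) / 10.0));
  H[H_AiF] = 1.0 / (1.0 + std::exp((v - 213.6) / 151.2));
  H[H_Axrf] = 1.0 / (1.0 + std::exp((v + 54.81) / 38.21));
}

static void gate_rates(double v, const double* ktau, double* inf, double* tau) {
  double mtd = ktau[0], mtf = ktau[1], mtj = ktau[2];
  inf[G_m] = 1.0 / (1.0 + std::exp(-(v + 39.57) / 9.871));
  tau[G_m] = 1.0 / (6.765 * std::exp((v + 11.64) / 34.77) +
                    8.552 * std::exp(-(v + 77.42) / 5.955));
  double hss = 1.0 / (1.0 + std::exp((v + 82.90) / 6.086));
  inf[G_hf] = hss;
  tau[G_hf] = 1.0 / (1.432e-5 * std::exp(-(v + 1.196) / 6.285) +
                     6.149 * std::exp((v + 0.5096) / 20.27));
  inf[G_hs] = hss;
  tau[G_hs] = 1.0 / (0.009794 * std::exp(-(v + 17.95) / 28.05) +
                     0.3343 * std::exp((v + 5.730) / 56.66));
  inf[G_j] = hss;
  tau[G_j] = 2.038 + 1.0 / (0.02136 * std::exp(-(v + 100.6) / 8.281) +
                            0.3052 * std::exp((v + 0.9941) / 38.45));
  inf[G_hsp] = 1.0 / (1.0 + std::exp((v + 89.1) / 6.086));
  tau[G_hsp] = 3.0 * tau[G_hs];
  inf[G_jp] = hss;
  tau[G_jp] = 1.46 * tau[G_j];
  inf[G_mL] = 1.0 / (1.0 + std::exp(-(v + 42.85) / 5.264));
  tau[G_mL] = tau[G_m];
  inf[G_hL] = 1.0 / (1.0 + std::exp((v + 87.61) / 7.488));
  tau[G_hL] = 200.0;
  inf[G_hLp] = 1.0 / (1.0 + std::exp((v + 93.81) / 7.488));
  tau[G_hLp] = 600.0;
  inf[G_a] = 1.0 / (1.0 + std::exp(-(v - 14.34) / 14.82));
  tau[G_a] = 1.0515 /
    (1.0 / (1.2089 * (1.0 + std::exp(-(v - 18.4099) / 29.3814))) +
     3.5 / (1.0 + std::exp((v + 100.0) / 29.3814)));
  double iss = 1.0 / (1.0 + std::exp((v + 43.94) / 5.711));
  double depi = 1.0 - 0.95 / (1.0 + std::exp((v + 70.0) / 5.0));
  inf[G_iF] = iss;
  tau[G_iF] = depi * (4.562 + 1.0 / (0.3933 * std::exp(-(v + 100.0) / 100.0) +
                                     0.08004 * std::exp((v + 50.0) / 16.59)));
  inf[G_iS] = iss;
  tau[G_iS] = depi * (23.62 + 1.0 / (0.001416 * std::exp(-(v + 96.52) / 59.05) +
                                     1.780e-8 * std::exp((v + 114.1) / 8.079)));
  inf[G_ap] = 1.0 / (1.0 + std::exp(-(v - 24.34) / 14.82));
  tau[G_ap] = tau[G_a];
  double dti_dev = 1.354 + 1e-4 / (std::exp((v - 167.4) / 15.89) +
                                   std::exp(-(v - 12.23) / 0.2154));
  double dti_rec = 1.0 - 0.5 / (1.0 + std::exp((v + 70.0) / 20.0));
  inf[G_iFp] = iss;
  tau[G_iFp] = dti_dev * dti_rec * tau[G_iF];
  inf[G_iSp] = iss;
  tau[G_iSp] = dti_dev * dti_rec * tau[G_iS];
  inf[G_d] = 1.0 / (1.0 + std::exp(-(v + 3.940) / 4.230));
  tau[G_d] = mtd * (0.6 + 1.0 / (std::exp(-0.05 * (v + 6.0)) +
                                 std::exp(0.09 * (v + 14.0))));
  double fss = 1.0 / (1.0 + std::exp((v + 19.58) / 3.696));
  inf[G_ff] = fss;
  tau[G_ff] = mtf * (7.0 + 1.0 / (0.0045 * std::exp(-(v + 20.0) / 10.0) +
                                  0.0045 * std::exp((v + 20.0) / 10.0)));
  inf[G_fs] = fss;
  tau[G_fs] = mtf * (1000.0 + 1.0 / (3.5e-5 * std::exp(-(v + 5.0) / 4.0) +
                                     3.5e-5 * std::exp((v + 5.0) / 6.0)));
  inf[G_fcaf] = fss;
  tau[G_fcaf] = 7.0 + 1.0 / (0.04 * std::exp(-(v - 4.0) / 7.0) +
                             0.04 * std::exp((v - 4.0) / 7.0));
  inf[G_fcas] = fss;
  tau[G_fcas] = 100.0 + 1.0 / (0.00012 * std::exp(-v / 3.0) +
                               0.00012 * std::exp(v / 7.0));
  inf[G_jca] = fss;
  tau[G_jca] = mtj * 75.0;
  inf[G_ffp] = fss;
  tau[G_ffp] = 2.5 * tau[G_ff];
  inf[G_fcafp] = fss;
  tau[G_fcafp] = 2.5 * tau[G_fcaf];
  double xrss = 1.0 / (1.0 + std::exp(-(v + 8.337) / 6.789));
  inf[G_xrf] = xrss;
  tau[G_xrf] = 12.98 + 1.0 / (0.3652 * std::exp((v - 31.66) / 3.869) +
                              4.123e-5 * std::exp(-(v - 47.78) / 20.38));
  inf[G_xrs] = xrss;
  tau[G_xrs] = 1.865 + 1.0 / (0.06629 * std::exp((v - 34.70) / 7.355) +
                              1.128e-5 * std::exp(-(v - 29.74) / 25.94));
  double xs1ss = 1.0 / (1.0 + std::exp(-(v + 11.60) / 8.932));
  inf[G_xs1] = xs1ss;
  tau[G_xs1] = 817.3 + 1.0 / (2.326e-4 * std::exp((v + 48.28) / 17.80) +
                              0.001292 * std::exp(-(v + 210.0) / 230.0));
  inf[G_xs2] = xs1ss;
  tau[G_xs2] = 1.0 / (0.01 * std::exp((v - 50.0) / 20.0) +
                      0.0193 * std::exp(-(v + 66.54) / 31.0));
  inf[G_xk1] = 1.0 / (1.0 + std::exp(-(v + 2.5538 * ko + 144.59) /
                                     (1.5692 * ko + 3.8115)));
  tau[G_xk1] = 122.2 / (std::exp(-(v + 127.2) / 20.36) +
                        std::exp((v + 236.8) / 69.33));
}

// everything assemble() produces from one state evaluation
struct Out {
  double dconc[9];        // dv, dnai, dnass, dki, dkss, dcai, dcass, dcansr, dcajsr
  double INa, INaL, Ito, ICaL, ICaNa, ICaK, IKr, IKs, IK1;
  double INaCa_i, INaCa_ss, INaK, INab, IKb, IpCa, ICab;
  double Jrel, Jup, Jleak, Jtr, Jdiff;
  double jrel_inf, jrel_tau, jrelp_inf, jrelp_tau;
  double dnca, dCaMKt;
  double scb_rate, srcb_rate, jrel_cyto, jup_cyto, ical_influx_rate;
};

static inline double ncx_flux(double na, double ca, double hca, double hna) {
  const double kna1 = 15.0, kna2 = 5.0, kna3 = 88.12, kasymm = 12.5;
  const double wna = 6.0e4, wca = 6.0e4, wnaca = 5.0e3;
  const double kcaon = 1.5e6, kcaoff = 5.0e3;
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
  double k1 = h12 * cao * kcaon, k2 = kcaoff;
  double k3p = h9 * wca, k3pp = h8 * wnaca, k3 = k3p + k3pp;
  double k4p = h3 * wca / hca, k4pp = h2 * wnaca, k4 = k4p + k4pp;
  double k5 = kcaoff, k6 = h6 * ca * kcaon;
  double k7 = h5 * h2 * wna, k8 = h8 * h11 * wna;
  double x1 = k2 * k4 * (k7 + k6) + k5 * k7 * (k2 + k3);
  double x2 = k1 * k7 * (k4 + k5) + k4 * k6 * (k1 + k8);
  double x3 = k1 * k3 * (k7 + k6) + k8 * k6 * (k2 + k3);
  double x4 = k2 * k8 * (k4 + k5) + k3 * k5 * (k1 + k8);
  double tot = x1 + x2 + x3 + x4;
  double E1 = x1 / tot, E2 = x2 / tot, E3 = x3 / tot, E4 = x4 / tot;
  double r = 150e-6 / ca;
  double allo = 1.0 / (1.0 + r * r);
  double JncxNa = 3.0 * (E4 * k7 - E1 * k8) + E3 * k4pp - E2 * k3pp;
  double JncxCa = E2 * k2 - E1 * k1;
  return allo * (JncxNa + 2.0 * JncxCa);
}

static void assemble(const double* st, const double* H, const double* sc,
                     double istim, Out& o) {
  double v = st[0], nai = st[1], nass = st[2], ki = st[3], kss = st[4];
  double cai = st[5], cass = st[6], cansr = st[7], cajsr = st[8];
  double nca = st[30], Jrelnp = st[38], Jrelp = st[39], CaMKt = st[40];

  double ENa = (1.0 / FRT) * std::log(nao / nai);
  double EK = (1.0 / FRT) * std::log(ko / ki);
  double EKs = (1.0 / FRT) * std::log((ko + 0.01833 * nao) /
                                      (ki + 0.01833 * nai));

  double CaMKb = CaMKo * (1.0 - CaMKt) / (1.0 + KmCaM / cass);
  double CaMKa = CaMKb + CaMKt;
  o.dCaMKt = aCaMK * CaMKb * (CaMKb + CaMKt) - bCaMK * CaMKt;
  double phi = 1.0 / (1.0 + KmCaMK / CaMKa);

  double h = 0.99 * st[10] + 0.01 * st[11];
  double hp = 0.99 * st[10] + 0.01 * st[13];
  double m3 = st[9] * st[9] * st[9];
  o.INa = sc[0] * GNa0 * (v - ENa) * m3 *
    ((1.0 - phi) * h * st[12] + phi * hp * st[14]);

  o.INaL = sc[1] * GNaL0 * (v - ENa) * st[15] *
    ((1.0 - phi) * st[16] + phi * st[17]);

  double AiF = H[H_AiF], AiS = 1.0 - AiF;
  double igate = AiF * st[19] + AiS * st[20];
  double ipgate = AiF * st[22] + AiS * st[23];
  o.Ito = sc[2] * Gto0 * (v - EK) *
    ((1.0 - phi) * st[18] * igate + phi * st[21] * ipgate);

  double f = 0.6 * st[25] + 0.4 * st[26];
  double Afcaf = H[H_Afcaf], Afcas = 1.0 - Afcaf;
  double fca = Afcaf * st[27] + Afcas * st[28];
  double f_p = 0.6 * st[31] + 0.4 * st[26];
  double fca_p = Afcaf * st[32] + Afcas * st[28];
  double PhiCaL = H[H_coef2] * (cass * H[H_exp2v] - 0.341 * cao);
  double PhiCaNa = H[H_coef1] * (0.75 * nass * H[H_expv] - 0.75 * nao);
  double PhiCaK = H[H_coef1] * (0.75 * kss * H[H_expv] - 0.75 * ko);
  double PCa = sc[3] * PCa0, PCap = 1.1 * PCa;
  double gnp = st[24] * (f * (1.0 - nca) + st[29] * fca * nca);
  double gp = st[24] * (f_p * (1.0 - nca) + st[29] * fca_p * nca);
  o.ICaL = (1.0 - phi) * PCa * PhiCaL * gnp + phi * PCap * PhiCaL * gp;
  o.ICaNa = 0.00125 * ((1.0 - phi) * PCa * PhiCaNa * gnp +
                       phi * PCap * PhiCaNa * gp);
  o.ICaK = 3.574e-4 * ((1.0 - phi) * PCa * PhiCaK * gnp +
                       phi * PCap * PhiCaK * gp);
  double km2n = st[29];
  double q = 1.0 + 0.002 / cass;
  double q2 = q * q;
  double anca = 1.0 / (1000.0 / km2n + q2 * q2);
  o.dnca = anca * 1000.0 - nca * km2n;

  double xr = H[H_Axrf] * st[33] + (1.0 - H[H_Axrf]) * st[34];
  o.IKr = sc[4] * GKr0 * std::sqrt(ko / 5.4) * xr * H[H_rkr] * (v - EK);

  double KsCa = 1.0 + 0.6 / (1.0 + std::pow(3.8e-5 / cai, 1.4));
  o.IKs = sc[5] * GKs0 * KsCa * st[35] * st[36] * (v - EKs);

  o.IK1 = sc[6] * GK10 * std::sqrt(ko) * H[H_rk1] * st[37] * (v - EK);

  double Gncx = sc[7] * Gncx0;
  o.INaCa_i = 0.8 * Gncx * ncx_flux(nai, cai, H[H_hca], H[H_hna]);
  o.INaCa_ss = 0.2 * Gncx * ncx_flux(nass, cass, H[H_hca], H[H_hna]);

  {
    const double k1p = 949.5, k1m = 182.4, k2p = 687.2, k2m = 39.4;
    const double k3p = 1899.0, k3m = 79300.0, k4p = 639.0, k4m = 40.0;
    const double Kki = 0.5, Kko = 0.3582, MgADP = 0.05, MgATP = 9.8;
    const double Kmgatp = 1.698e-7, Hconc = 1e-7, eP = 4.2, Khp = 1.698e-7;
    const double Knap = 224.0, Kxkur = 292.0;
    double Knai = H[H_Knai], Knao = H[H_Knao];
    double P = eP / (1.0 + Hconc / Khp + nai / Knap + ki / Kxkur);
    double rni = nai / Knai, rno = nao / Knao;
    double rki = 1.0 + ki / Kki, rko = 1.0 + ko / Kko;
    double d_in = (1.0 + rni) * (1.0 + rni) * (1.0 + rni) + rki * rki - 1.0;
    double d_out = (1.0 + rno) * (1.0 + rno) * (1.0 + rno) + rko * rko - 1.0;
    double a1 = k1p * rni * rni * rni / d_in;
    double b1 = k1m * MgADP;
    double a2 = k2p;
    double b2 = k2m * rno * rno * rno / d_out;
    double a3 = k3p * (ko / Kko) * (ko / Kko) / d_out;
    double b3 = k3m * P * Hconc / (1.0 + MgATP / Kmgatp);
    double a4 = k4p * MgATP / Kmgatp / (1.0 + MgATP / Kmgatp);
    double b4 = k4m * (ki / Kki) * (ki / Kki) / d_in;
    double x1 = a4 * a1 * a2 + b2 * b4 * b3 + a2 * b4 * b3 + b3 * a1 * a2;
    double x2 = b2 * b1 * b4 + a1 * a2 * a3 + a3 * b1 * b4 + a2 * a3 * b4;
    double x3 = a2 * a3 * a4 + b3 * b2 * b1 + b2 * b1 * a4 + a3 * a4 * b1;
    double x4 = b4 * b3 * b2 + a3 * a4 * a1 + b2 * a4 * a1 + b3 * b1 * a1;
    double tot = x1 + x2 + x3 + x4;
    double E1 = x1 / tot, E2 = x2 / tot, E3 = x3 / tot, E4 = x4 / tot;
    double JnakNa = 3.0 * (E1 * a3 - E2 * b3);
    double JnakK = 2.0 * (E4 * b1 - E3 * a1);
    o.INaK = sc[8] * Pnak0 * (JnakNa + JnakK);
  }

  o.IKb = GKb0 * H[H_xkb] * (v - EK);
  o.INab = PNab0 * H[H_coef1] * (nai * H[H_expv] - nao);
  o.ICab = PCab0 * H[H_coef2] * (cai * H[H_exp2v] - 0.341 * cao);
  o.IpCa = GpCa0 * cai / (0.0005 + cai);

  double JdiffNa = (nass - nai) / 2.0;
  double JdiffK = (kss - ki) / 2.0;
  o.Jdiff = (cass - cai) / 0.2;

  const double bt = 4.75;
  double rel_gain = 1.0 / (1.0 + std::pow(1.5 / cajsr, 8.0));
  o.jrel_inf = 0.5 * bt * (-o.ICaL) * rel_gain;
  o.jrel_tau = std::max(bt / (1.0 + 0.0123 / cajsr), 0.001);
  double btp = 1.25 * bt;
  o.jrelp_inf = 0.5 * btp * (-o.ICaL) * rel_gain;
  o.jrelp_tau = std::max(btp / (1.0 + 0.0123 / cajsr), 0.001);
  o.Jrel = sc[9] * ((1.0 - phi) * Jrelnp + phi * Jrelp);

  double Jupnp = 0.004375 * cai / (cai + 0.00092);
  double Jupp = 2.75 * 0.004375 * cai / (cai + 0.00092 - 0.00017);
  o.Jleak = 0.0039375 * cansr / 15.0;
  o.Jup = sc[10] * ((1.0 - phi) * Jupnp + phi * Jupp) - o.Jleak;
  o.Jtr = (cansr - cajsr) / 100.0;

  double AF = Acap / Frdy;
  o.dconc[1] = -(o.INa + o.INaL + 3.0 * o.INaCa_i + 3.0 * o.INaK + o.INab) *
    AF / vmyo + JdiffNa * vss / vmyo;
  o.dconc[2] = -(o.ICaNa + 3.0 * o.INaCa_ss) * AF / vss - JdiffNa;
  o.dconc[3] = -(o.Ito + o.IKr + o.IKs + o.IK1 + o.IKb + istim -
                 2.0 * o.INaK) * AF / vmyo + JdiffK * vss / vmyo;
  o.dconc[4] = -o.ICaK * AF / vss - JdiffK;
  double bc1 = kmcmdn + cai, bc2 = kmtrpn + cai;
  double Bcai = 1.0 / (1.0 + cmdnmax * kmcmdn / (bc1 * bc1) +
                       trpnmax * kmtrpn / (bc2 * bc2));
  o.dconc[5] = Bcai * (-(o.IpCa + o.ICab - 2.0 * o.INaCa_i) * AF /
                       (2.0 * vmyo) - o.Jup * vnsr / vmyo +
                       o.Jdiff * vss / vmyo);
  double bs1 = KmBSR + cass, bs2 = KmBSL + cass;
  double Bcass = 1.0 / (1.0 + BSRmax * KmBSR / (bs1 * bs1) +
                        BSLmax * KmBSL / (bs2 * bs2));
  o.dconc[6] = Bcass * (-(o.ICaL - 2.0 * o.INaCa_ss) * AF / (2.0 * vss) +
                        o.Jrel * vjsr / vss - o.Jdiff);
  o.dconc[7] = o.Jup - o.Jtr * vjsr / vnsr;
  double bj = kmcsqn + cajsr;
  double Bcajsr = 1.0 / (1.0 + csqnmax * kmcsqn / (bj * bj));
  o.dconc[8] = Bcajsr * (o.Jtr - o.Jrel);

  double Iion = o.INa + o.INaL + o.Ito + o.ICaL + o.ICaNa + o.ICaK + o.IKr +
    o.IKs + o.IK1 + o.INaCa_i + o.INaCa_ss + o.INaK + o.INab + o.IKb +
    o.IpCa + o.ICab;
  o.dconc[0] = -(Iion + istim);

  o.jrel_cyto = o.Jrel * vjsr / vmyo;
  o.jup_cyto = o.Jup * vnsr / vmyo;
  o.srcb_rate = o.jup_cyto - o.jrel_cyto;
  o.scb_rate = (-(o.ICaL - 2.0 * o.INaCa_ss) -
                (o.IpCa + o.ICab - 2.0 * o.INaCa_i)) * AF / (2.0 * vmyo);
  o.ical_influx_rate = (o.ICaL < 0.0) ? -o.ICaL * AF / (2.0 * vmyo) : 0.0;
}

// ---- lookup table ----
static const double VMIN = -150.0, VMAX = 100.0, DV = 0.05;
static const int NROW = (int)((VMAX - VMIN) / DV) + 1;

struct Lut {
  std::vector<double> tab;   // row-major: NHELP helpers, NGATE inf, ef, ec
  int ncol;
  Lut(const double* ktau, double dtf, double dtc) {
    ncol = NHELP + 3 * NGATE;
    tab.resize((size_t)NROW * ncol);
    double inf[NGATE], tau[NGATE];
    for (int r = 0; r < NROW; ++r) {
      double v = VMIN + r * DV;
      double* row = &tab[(size_t)r * ncol];
      vdep_helpers(v, row);
      gate_rates(v, ktau, inf, tau);
      for (int g = 0; g < NGATE; ++g) {
        row[NHELP + g] = inf[g];
        row[NHELP + NGATE + g] = std::exp(-dtf / tau[g]);
        row[NHELP + 2 * NGATE + g] = std::exp(-dtc / tau[g]);
      }
    }
  }
  // interpolate helpers + inf + chosen exp set into H (NHELP), inf, e
  inline void lookup(double v, bool fine, double* H, double* inf,
                     double* e) const {
    double x = (v - VMIN) / DV;
    if (x < 0.0) x = 0.0;
    if (x > NROW - 1.001) x = NROW - 1.001;
    int i0 = (int)x;
    double w = x - i0;
    const double* r0 = &tab[(size_t)i0 * ncol];
    const double* r1 = r0 + ncol;
    for (int c = 0; c < NHELP; ++c) H[c] = r0[c] + w * (r1[c] - r0[c]);
    const double* a0 = r0 + NHELP;
    const double* a1 = r1 + NHELP;
    for (int g = 0; g < NGATE; ++g) inf[g] = a0[g] + w * (a1[g] - a0[g]);
    int off = fine ? NHELP + NGATE : NHELP + 2 * NGATE;
    const double* b0 = r0 + off;
    const double* b1 = r1 + off;
    for (int g = 0; g < NGATE; ++g) e[g] = b0[g] + w * (b1[g] - b0[g]);
  }
};

// one integration substep; returns Out for observables
static inline void step_state(double* st, const Lut& lut, const double* sc,
                              double dt, bool fine, double istim, Out& o,
                              bool clamp_v) {
  double H[NHELP], inf[NGATE], e[NGATE];
  lut.lookup(st[0], fine, H, inf, e);
  assemble(st, H, sc, istim, o);
  // concentrations + Vm: forward Euler
  if (!clamp_v) st[0] += dt * o.dconc[0];
  for (int c = 1; c < 9; ++c) st[c] += dt * o.dconc[c];
  // HH gates: Rush-Larsen
  for (int g = 0; g < NGATE; ++g) {
    int i = GIDX[g];
    st[i] = inf[g] + (st[i] - inf[g]) * e[g];
  }
  // release gates: exponential update with state-dependent tau
  st[38] = o.jrel_inf + (st[38] - o.jrel_inf) * std::exp(-dt / o.jrel_tau);
  st[39] = o.jrelp_inf + (st[39] - o.jrelp_inf) * std::exp(-dt / o.jrelp_tau);
  // nca and CaMK trap: Euler (bounded rates)
  st[30] += dt * o.dnca;
  st[40] += dt * o.dCaMKt;
}

static const char* TRACE_COLS[] = {
  "t", "v", "cai", "cass", "cajsr", "cansr", "nai", "ki",
  "jrel", "jup", "ical", "icana", "icak", "inaca_i", "inaca_ss", "inaca",
  "icab", "ipca", "ina", "inal", "ito", "ikr", "iks", "ik1", "inak",
  "ikb", "inab", "istim", "beat"};
static const int NTC = 29;

static const char* BEAT_COLS[] = {
  "beat", "t_stim", "rmp", "peak_v_early", "vmax", "apd90", "apd40",
  "cat_min", "cat_max", "srcb", "scb", "jrel_int", "ical_influx",
  "captured"};
static const int NBC = 14;

// [[Rcpp::export]]
List pace_cpp(NumericVector scaling, NumericVector kinetics,
              NumericVector state, double cl, int n_beats, int record_from,
              double stim_amp, double stim_dur, double dt_fine,
              double dt_coarse, double sample_dt, double fine_win,
              double dvdt_thresh) {
  if (state.size() != NSTATE) stop("state must have length 41");
  if (scaling.size() != 11) stop("scaling must have length 11");
  if (kinetics.size() != 3) stop("kinetics must have length 3");
  int spb = (int)std::lround(cl / sample_dt);
  if (std::fabs(spb * sample_dt - cl) > 1e-9)
    stop("cycle length must be a multiple of sample_dt");
  int nsub_f = (int)std::lround(sample_dt / dt_fine);
  int nsub_c = (int)std::lround(sample_dt / dt_coarse);

  double st[NSTATE];
  for (int i = 0; i < NSTATE; ++i) st[i] = state[i];
  const double* sc = REAL(scaling);
  Lut lut(REAL(kinetics), dt_fine, dt_coarse);

  int n_rec = std::max(0, n_beats - std::max(record_from, 0));
  NumericMatrix trace(n_rec > 0 ? n_rec * spb : 0, NTC);
  NumericMatrix beats(n_beats, NBC);
  Out o;
  {
    double H0[NHELP];
    vdep_helpers(st[0], H0);
    assemble(st, H0, sc, stim_amp, o);
  }
  double lastdv = 0.0;
  int trow = 0;
  bool failed = false;
  int fail_beat = -1;

  for (int b = 0; b < n_beats && !failed; ++b) {
    bool rec = b >= record_from;
    double t_stim = (double)b * cl;
    double rmp = st[0];
    double vmax = st[0], peak_early = st[0];
    double cat_min = st[5], cat_max = st[5];
    double srcb = 0.0, scb = 0.0, jrel_int = 0.0, ical_in = 0.0;
    double apd90 = NA_REAL, apd40 = NA_REAL;
    double t_vmax = -1.0;
    bool done90 = false, done40 = false;
    double vprev = st[0];

    for (int sbin = 0; sbin < spb; ++sbin) {
      double tb = sbin * sample_dt;
      bool fine = (tb < stim_dur + fine_win) || std::fabs(lastdv) > dvdt_thresh;
      double dt = fine ? dt_fine : dt_coarse;
      int nsub = fine ? nsub_f : nsub_c;
      if (rec) {
        trace(trow, 0) = t_stim + tb;
        trace(trow, 1) = st[0];
        trace(trow, 2) = st[5];
        trace(trow, 3) = st[6];
        trace(trow, 4) = st[8];
        trace(trow, 5) = st[7];
        trace(trow, 6) = st[1];
        trace(trow, 7) = st[3];
        trace(trow, 8) = o.jrel_cyto;
        trace(trow, 9) = o.jup_cyto;
        trace(trow, 10) = o.ICaL;
        trace(trow, 11) = o.ICaNa;
        trace(trow, 12) = o.ICaK;
        trace(trow, 13) = o.INaCa_i;
        trace(trow, 14) = o.INaCa_ss;
        trace(trow, 15) = o.INaCa_i + o.INaCa_ss;
        trace(trow, 16) = o.ICab;
        trace(trow, 17) = o.IpCa;
        trace(trow, 18) = o.INa;
        trace(trow, 19) = o.INaL;
        trace(trow, 20) = o.Ito;
        trace(trow, 21) = o.IKr;
        trace(trow, 22) = o.IKs;
        trace(trow, 23) = o.IK1;
        trace(trow, 24) = o.INaK;
        trace(trow, 25) = o.IKb;
        trace(trow, 26) = o.INab;
        trace(trow, 27) = (tb < stim_dur) ? stim_amp : 0.0;
        trace(trow, 28) = b + 1;
        ++trow;
      }
      for (int ssub = 0; ssub < nsub; ++ssub) {
        double tloc = tb + ssub * dt;
        double istim = (tloc < stim_dur) ? stim_amp : 0.0;
        vprev = st[0];
        step_state(st, lut, sc, dt, fine, istim, o, false);
        lastdv = o.dconc[0];
        srcb += o.srcb_rate * dt;
        scb += o.scb_rate * dt;
        jrel_int += o.jrel_cyto * dt;
        ical_in += o.ical_influx_rate * dt;
        double tnew = tloc + dt;
        if (st[0] > vmax) { vmax = st[0]; t_vmax = tnew; }
        if (tnew <= 50.0 && st[0] > peak_early) peak_early = st[0];
        if (st[5] < cat_min) cat_min = st[5];
        if (st[5] > cat_max) cat_max = st[5];
        if (t_vmax >= 0.0 && tnew > t_vmax) {
          double apa = vmax - rmp;
          if (!done90) {
            double v90 = rmp + 0.10 * apa;
            if (vprev >= v90 && st[0] < v90) {
              apd90 = tnew - dt * (v90 - st[0]) / (vprev - st[0]);
              done90 = true;
            }
          }
          if (!done40) {
            double v40 = rmp + 0.60 * apa;
            if (vprev >= v40 && st[0] < v40) {
              apd40 = tnew - dt * (v40 - st[0]) / (vprev - st[0]);
              done40 = true;
            }
          }
        }
      }
    }
    for (int i = 0; i < NSTATE; ++i)
      if (!std::isfinite(st[i])) { failed = true; fail_beat = b + 1; }
    beats(b, 0) = b + 1;
    beats(b, 1) = t_stim;
    beats(b, 2) = rmp;
    beats(b, 3) = peak_early;
    beats(b, 4) = vmax;
    beats(b, 5) = apd90;
    beats(b, 6) = apd40;
    beats(b, 7) = cat_min;
    beats(b, 8) = cat_max;
    beats(b, 9) = srcb;
    beats(b, 10) = scb;
    beats(b, 11) = jrel_int;
    beats(b, 12) = ical_in;
    beats(b, 13) = (peak_early > 0.0) ? 1.0 : 0.0;
  }

  NumericVector fin(NSTATE);
  for (int i = 0; i < NSTATE; ++i) fin[i] = st[i];
  colnames(trace) = CharacterVector(TRACE_COLS, TRACE_COLS + NTC);
  colnames(beats) = CharacterVector(BEAT_COLS, BEAT_COLS + NBC);
  return List::create(_["state"] = fin, _["trace"] = trace,
                      _["beats"] = beats, _["failed"] = failed,
                      _["fail_beat"] = fail_beat);
}

// [[Rcpp::export]]
List clamp_cpp(NumericVector scaling, NumericVector kinetics,
               NumericVector state, NumericVector vm_waveform, double cl,
               int n_beats, int record_from, double dt_fine, double dt_coarse,
               double sample_dt, double fine_win, double dvdt_thresh) {
  if (state.size() != NSTATE) stop("state must have length 41");
  int spb = (int)std::lround(cl / sample_dt);
  if (std::fabs(spb * sample_dt - cl) > 1e-9)
    stop("cycle length must be a multiple of sample_dt");
  if (vm_waveform.size() != spb)
    stop("vm_waveform must have one sample per sample_dt over one beat");
  int nsub_f = (int)std::lround(sample_dt / dt_fine);
  int nsub_c = (int)std::lround(sample_dt / dt_coarse);

  double st[NSTATE];
  for (int i = 0; i < NSTATE; ++i) st[i] = state[i];
  const double* sc = REAL(scaling);
  const double* wf = REAL(vm_waveform);
  Lut lut(REAL(kinetics), dt_fine, dt_coarse);

  int n_rec = std::max(0, n_beats - std::max(record_from, 0));
  NumericMatrix trace(n_rec > 0 ? n_rec * spb : 0, NTC);
  NumericMatrix beats(n_beats, NBC);
  Out o;
  {
    double H0[NHELP];
    st[0] = wf[0];
    vdep_helpers(st[0], H0);
    assemble(st, H0, sc, 0.0, o);
  }
  int trow = 0;
  bool failed = false;
  int fail_beat = -1;

  auto wave_at = [&](double tb) {
    double x = tb / sample_dt;
    int i0 = (int)x;
    double w = x - i0;
    int i1 = (i0 + 1) % spb;
    i0 = i0 % spb;
    return wf[i0] + w * (wf[i1] - wf[i0]);
  };

  for (int b = 0; b < n_beats && !failed; ++b) {
    bool rec = b >= record_from;
    double t_stim = (double)b * cl;
    double rmp = wf[0];
    double vmax = wf[0], cat_min = st[5], cat_max = st[5];
    double srcb = 0.0, scb = 0.0, jrel_int = 0.0, ical_in = 0.0;
    for (int sbin = 0; sbin < spb; ++sbin) {
      double tb = sbin * sample_dt;
      double slope = (wave_at(tb + sample_dt) - wave_at(tb)) / sample_dt;
      bool fine = (tb < fine_win) || std::fabs(slope) > dvdt_thresh;
      double dt = fine ? dt_fine : dt_coarse;
      int nsub = fine ? nsub_f : nsub_c;
      if (rec) {
        st[0] = wave_at(tb);
        trace(trow, 0) = t_stim + tb;
        trace(trow, 1) = st[0];
        trace(trow, 2) = st[5];
        trace(trow, 3) = st[6];
        trace(trow, 4) = st[8];
        trace(trow, 5) = st[7];
        trace(trow, 6) = st[1];
        trace(trow, 7) = st[3];
        trace(trow, 8) = o.jrel_cyto;
        trace(trow, 9) = o.jup_cyto;
        trace(trow, 10) = o.ICaL;
        trace(trow, 11) = o.ICaNa;
        trace(trow, 12) = o.ICaK;
        trace(trow, 13) = o.INaCa_i;
        trace(trow, 14) = o.INaCa_ss;
        trace(trow, 15) = o.INaCa_i + o.INaCa_ss;
        trace(trow, 16) = o.ICab;
        trace(trow, 17) = o.IpCa;
        trace(trow, 18) = o.INa;
        trace(trow, 19) = o.INaL;
        trace(trow, 20) = o.Ito;
        trace(trow, 21) = o.IKr;
        trace(trow, 22) = o.IKs;
        trace(trow, 23) = o.IK1;
        trace(trow, 24) = o.INaK;
        trace(trow, 25) = o.IKb;
        trace(trow, 26) = o.INab;
        trace(trow, 27) = 0.0;
        trace(trow, 28) = b + 1;
        ++trow;
      }
      for (int ssub = 0; ssub < nsub; ++ssub) {
        double tloc = tb + ssub * dt;
        st[0] = wave_at(tloc);
        step_state(st, lut, sc, dt, fine, 0.0, o, true);
        srcb += o.srcb_rate * dt;
        scb += o.scb_rate * dt;
        jrel_int += o.jrel_cyto * dt;
        ical_in += o.ical_influx_rate * dt;
        if (st[0] > vmax) vmax = st[0];
        if (st[5] < cat_min) cat_min = st[5];
        if (st[5] > cat_max) cat_max = st[5];
      }
    }
    for (int i = 0; i < NSTATE; ++i)
      if (!std::isfinite(st[i])) { failed = true; fail_beat = b + 1; }
    beats(b, 0) = b + 1;
    beats(b, 1) = t_stim;
    beats(b, 2) = rmp;
    beats(b, 3) = vmax;
    beats(b, 4) = vmax;
    beats(b, 5) = NA_REAL;
    beats(b, 6) = NA_REAL;
    beats(b, 7) = cat_min;
    beats(b, 8) = cat_max;
    beats(b, 9) = srcb;
    beats(b, 10) = scb;
    beats(b, 11) = jrel_int;
    beats(b, 12) = ical_in;
    beats(b, 13) = 1.0;
  }

  NumericVector fin(NSTATE);
  for (int i = 0; i < NSTATE; ++i) fin[i] = st[i];
  colnames(trace) = CharacterVector(TRACE_COLS, TRACE_COLS + NTC);
  colnames(beats) = CharacterVector(BEAT_COLS, BEAT_COLS + NBC);
  return List::create(_["state"] = fin, _["trace"] = trace,
                      _["beats"] = beats, _["failed"] = failed,
                      _["fail_beat"] = fail_beat);
}

// Exact derivative evaluation (no lookup tables): used by the deSolve
// cross-check route and by unit tests comparing against the plain-R
// transcription.
// [[Rcpp::export]]
List derivs_cpp(NumericVector state, NumericVector scaling,
                NumericVector kinetics, double i_stim) {
  if (state.size() != NSTATE) stop("state must have length 41");
  double st[NSTATE];
  for (int i = 0; i < NSTATE; ++i) st[i] = state[i];
  double H[NHELP], inf[NGATE], tau[NGATE];
  vdep_helpers(st[0], H);
  gate_rates(st[0], REAL(kinetics), inf, tau);
  Out o;
  assemble(st, H, REAL(scaling), i_stim, o);
  NumericVector d(NSTATE);
  for (int c = 0; c < 9; ++c) d[c] = o.dconc[c];
  for (int g = 0; g < NGATE; ++g) {
    int i = GIDX[g];
    d[i] = (inf[g] - st[i]) / tau[g];
  }
  d[30] = o.dnca;
  d[38] = (o.jrel_inf - st[38]) / o.jrel_tau;
  d[39] = (o.jrelp_inf - st[39]) / o.jrelp_tau;
  d[40] = o.dCaMKt;
  NumericVector cur = NumericVector::create(
    _["INa"] = o.INa, _["INaL"] = o.INaL, _["Ito"] = o.Ito,
    _["ICaL"] = o.ICaL, _["ICaNa"] = o.ICaNa, _["ICaK"] = o.ICaK,
    _["IKr"] = o.IKr, _["IKs"] = o.IKs, _["IK1"] = o.IK1,
    _["INaCa_i"] = o.INaCa_i, _["INaCa_ss"] = o.INaCa_ss,
    _["INaK"] = o.INaK, _["INab"] = o.INab, _["IKb"] = o.IKb,
    _["IpCa"] = o.IpCa, _["ICab"] = o.ICab, _["Istim"] = i_stim);
  NumericVector fx = NumericVector::create(
    _["Jrel"] = o.Jrel, _["Jup"] = o.Jup, _["Jleak"] = o.Jleak,
    _["Jtr"] = o.Jtr, _["Jdiff"] = o.Jdiff);
  return List::create(_["dstate"] = d, _["currents"] = cur, _["fluxes"] = fx);
}
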