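// Compiled core: Hodgkin-Huxley type cell vector fields for the
// subthalamo-pallido-thalamic network, conductance-based synaptic gates,
// and a fixed-step RK4 integrator with in-loop spike detection.
//
// State layout of the flat vector y (n = neurons per population):
//   STN  [0,6n):   v | n | h | r | Ca | s
//   GPe  [6n,12n): v | n | h | r | Ca | s
//   GPi  [12n,18n):v | n | h | r | Ca | s
//   Th   [18n,21n):v | h | r
// Each presynaptic neuron carries a single s gate shared by all of its
// efferent targets (the gate depends only on the presynaptic voltage).

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double xinf(double v, double th, double sg) {
  return 1.0 / (1.0 + std::exp(-(v - th) / sg));
}

// Low-threshold gate of the T current as a function of the slow variable r.
// Normalized form anchors b(0) = 0; the printed alternative uses
// exp(theta_b/sigma_b) as the offset instead.
static inline double binf(double r, double th, double sg, bool printed) {
  double off = printed ? std::exp(th / sg) : 1.0 / (1.0 + std::exp(-th / sg));
  return 1.0 / (1.0 + std::exp((r - th) / sg)) - off;
}

// Voltage-dependent time constant; tau1 == 0 collapses to the constant case.
static inline double taux(double v, double t0, double t1, double th, double sg) {
  if (t1 == 0.0) return t0;
  return t0 + t1 / (1.0 + std::exp(-(v - th) / sg));
}

struct BGPar {
  double gL, gNa, gK, gT, gCa, gAHP;
  double EL, ENa, EK, ECa;
  double th_m, sg_m, th_h, sg_h, th_n, sg_n, th_r, sg_r;
  double th_a, sg_a, th_s, sg_s, th_b, sg_b;
  bool use_b;      // STN uses b_inf(r)^2 in I_T; GPe/GPi use r itself
  bool b_printed;  // compatibility switch for the printed offset in b_inf
  double tau0_h, tau1_h, thtau_h, sgtau_h;
  double tau0_n, tau1_n, thtau_n, sgtau_n;
  double tau0_r, tau1_r, thtau_r, sgtau_r;
  double phi_h, phi_n, phi_r;
  double eps, k1, kCa;
  double Cm, Iapp;
  // synaptic output (s gate) of this population
  double alpha, beta, thH, sgH, th_pre;
  bool double_shift;  // H_inf(v - th_pre) with th^H inside H (default)
};

struct ThPar {
  double gL, gNa, gK, gT;
  double EL, ENa, EK, ET;
  double Cm;
};

static double num(const List& p, const char* nm) {
  if (!p.containsElementNamed(nm))
    stop("parameter set is missing '%s'", nm);
  return as<double>(p[nm]);
}

static BGPar bg_par(const List& p) {
  BGPar q;
  q.gL = num(p, "g_L"); q.gNa = num(p, "g_Na"); q.gK = num(p, "g_K");
  q.gT = num(p, "g_T"); q.gCa = num(p, "g_Ca"); q.gAHP = num(p, "g_AHP");
  q.EL = num(p, "E_L"); q.ENa = num(p, "E_Na"); q.EK = num(p, "E_K");
  q.ECa = num(p, "E_Ca");
  q.th_m = num(p, "theta_m"); q.sg_m = num(p, "sigma_m");
  q.th_h = num(p, "theta_h"); q.sg_h = num(p, "sigma_h");
  q.th_n = num(p, "theta_n"); q.sg_n = num(p, "sigma_n");
  q.th_r = num(p, "theta_r"); q.sg_r = num(p, "sigma_r");
  q.th_a = num(p, "theta_a"); q.sg_a = num(p, "sigma_a");
  q.th_s = num(p, "theta_s"); q.sg_s = num(p, "sigma_s");
  q.use_b = as<bool>(p["use_b"]);
  q.th_b = q.use_b ? num(p, "theta_b") : 0.0;
  q.sg_b = q.use_b ? num(p, "sigma_b") : 1.0;
  q.b_printed = p.containsElementNamed("b_form") ?
    (as<std::string>(p["b_form"]) == "printed") : false;
  q.tau0_h = num(p, "tau0_h"); q.tau1_h = num(p, "tau1_h");
  q.thtau_h = num(p, "theta_tau_h"); q.sgtau_h = num(p, "sigma_tau_h");
  q.tau0_n = num(p, "tau0_n"); q.tau1_n = num(p, "tau1_n");
  q.thtau_n = num(p, "theta_tau_n"); q.sgtau_n = num(p, "sigma_tau_n");
  q.tau0_r = num(p, "tau0_r"); q.tau1_r = num(p, "tau1_r");
  q.thtau_r = num(p, "theta_tau_r"); q.sgtau_r = num(p, "sigma_tau_r");
  q.phi_h = num(p, "phi_h"); q.phi_n = num(p, "phi_n"); q.phi_r = num(p, "phi_r");
  q.eps = num(p, "eps"); q.k1 = num(p, "k1"); q.kCa = num(p, "k_Ca");
  q.Cm = num(p, "C_m"); q.Iapp = num(p, "I_app");
  q.alpha = num(p, "alpha"); q.beta = num(p, "beta");
  q.thH = num(p, "theta_H"); q.sgH = num(p, "sigma_H");
  q.th_pre = num(p, "theta_pre");
  q.double_shift = p.containsElementNamed("theta_shift") ?
    (as<std::string>(p["theta_shift"]) == "double") : true;
  return q;
}

static ThPar th_par(const List& p) {
  ThPar q;
  q.gL = num(p, "g_L"); q.gNa = num(p, "g_Na"); q.gK = num(p, "g_K");
  q.gT = num(p, "g_T");
  q.EL = num(p, "E_L"); q.ENa = num(p, "E_Na"); q.EK = num(p, "E_K");
  q.ET = num(p, "E_T");
  q.Cm = num(p, "C_m");
  return q;
}

// dy for one STN/GPe/GPi cell; st = {v, n, h, r, Ca}; cur (length 6, may be
// NULL) receives I_L, I_Na, I_K, I_Ca, I_T, I_AHP.
static inline void bg_deriv(const BGPar& p, const double* st, double isyn,
                            double iapp, double* d, double* cur) {
  double v = st[0], nn = st[1], h = st[2], r = st[3], ca = st[4];
  double minf = xinf(v, p.th_m, p.sg_m);
  double ainf = xinf(v, p.th_a, p.sg_a);
  double sinf = xinf(v, p.th_s, p.sg_s);
  double IL = p.gL * (v - p.EL);
  double INa = p.gNa * minf * minf * minf * h * (v - p.ENa);
  double IK = p.gK * nn * nn * nn * nn * (v - p.EK);
  double ICa = p.gCa * sinf * sinf * (v - p.ECa);
  double tgate;
  if (p.use_b) {
    double b = binf(r, p.th_b, p.sg_b, p.b_printed);
    tgate = b * b;
  } else {
    tgate = r;
  }
  double IT = p.gT * ainf * ainf * ainf * tgate * (v - p.ECa);
  double IAHP = p.gAHP * (v - p.EK) * (ca / (ca + p.k1));
  d[0] = (-IL - INa - IK - ICa - IT - IAHP - isyn + iapp) / p.Cm;
  d[1] = p.phi_n * (xinf(v, p.th_n, p.sg_n) - nn) /
         taux(v, p.tau0_n, p.tau1_n, p.thtau_n, p.sgtau_n);
  d[2] = p.phi_h * (xinf(v, p.th_h, p.sg_h) - h) /
         taux(v, p.tau0_h, p.tau1_h, p.thtau_h, p.sgtau_h);
  d[3] = p.phi_r * (xinf(v, p.th_r, p.sg_r) - r) /
         taux(v, p.tau0_r, p.tau1_r, p.thtau_r, p.sgtau_r);
  d[4] = p.eps * (-ICa - IT - p.kCa * ca);
  if (cur) {
    cur[0] = IL; cur[1] = INa; cur[2] = IK; cur[3] = ICa; cur[4] = IT;
    cur[5] = IAHP;
  }
}

// Thalamic gating functions are fixed closed forms (single parameter set).
static inline void th_deriv(const ThPar& p, const double* st, double igpith,
                            double ismc, double* d, double* cur) {
  double v = st[0], h = st[1], r = st[2];
  double minf = 1.0 / (1.0 + std::exp(-(v + 37.0) / 7.0));
  double pinf = 1.0 / (1.0 + std::exp(-(v + 60.0) / 6.2));
  double hinf = 1.0 / (1.0 + std::exp((v + 41.0) / 4.0));
  double rinf = 1.0 / (1.0 + std::exp((v + 84.0) / 4.0));
  double ah = 0.128 * std::exp(-(v + 46.0) / 18.0);
  double bh = 4.0 / (1.0 + std::exp(-(v + 23.0) / 5.0));
  double tauh = 1.0 / (ah + bh);
  double taur = 28.0 + std::exp(-(v + 25.0) / 10.5);
  double IL = p.gL * (v - p.EL);
  double INa = p.gNa * minf * minf * minf * h * (v - p.ENa);
  double kk = 0.75 * (1.0 - h);
  double IK = p.gK * kk * kk * kk * kk * (v - p.EK);
  double IT = p.gT * pinf * pinf * r * (v - p.ET);
  d[0] = (-IL - INa - IK - IT - igpith + ismc) / p.Cm;
  d[1] = (hinf - h) / tauh;
  d[2] = (rinf - r) / taur;
  if (cur) { cur[0] = IL; cur[1] = INa; cur[2] = IK; cur[3] = IT; }
}

// Synaptic gate: ds/dt = alpha * H_inf(v_pre) * (1 - s) - beta * s.
static inline double s_deriv(const BGPar& p, double vpre, double s) {
  double arg = p.double_shift ? (vpre - p.th_pre) : vpre;
  double H = 1.0 / (1.0 + std::exp(-(arg - p.thH) / p.sgH));
  return p.alpha * H * (1.0 - s) - p.beta * s;
}

// [[Rcpp::export(name = ".bg_cell_deriv_cpp")]]
List bg_cell_deriv_cpp(List params, NumericVector state, double i_syn,
                       double i_app) {
  BGPar p = bg_par(params);
  double d[5], cur[6];
  bg_deriv(p, REAL(state), i_syn, i_app, d, cur);
  NumericVector dv = NumericVector::create(
    _["v"] = d[0], _["n"] = d[1], _["h"] = d[2], _["r"] = d[3], _["Ca"] = d[4]);
  NumericVector cc = NumericVector::create(
    _["I_L"] = cur[0], _["I_Na"] = cur[1], _["I_K"] = cur[2],
    _["I_Ca"] = cur[3], _["I_T"] = cur[4], _["I_AHP"] = cur[5]);
  return List::create(_["deriv"] = dv, _["currents"] = cc);
}

// [[Rcpp::export(name = ".th_cell_deriv_cpp")]]
List th_cell_deriv_cpp(List params, NumericVector state, double i_gpi_th,
                       double i_smc) {
  ThPar p = th_par(params);
  double d[3], cur[4];
  th_deriv(p, REAL(state), i_gpi_th, i_smc, d, cur);
  NumericVector dv = NumericVector::create(
    _["v"] = d[0], _["h"] = d[1], _["r"] = d[2]);
  NumericVector cc = NumericVector::create(
    _["I_L"] = cur[0], _["I_Na"] = cur[1], _["I_K"] = cur[2],
    _["I_T"] = cur[3]);
  return List::create(_["deriv"] = dv, _["currents"] = cc);
}

struct Net {
  int n;
  BGPar stn, gpe, gpi;
  ThPar th;
  // projection conductances / reversals
  double g_gs, E_gs, g_sg, E_sg, g_gg, E_gg, g_sgi, E_sgi, g_ggi, E_ggi,
         g_git, E_git;
  // afferent indices (0-based)
  std::vector<int> stn_gpe1, stn_gpe2;   // GPe neurons inhibiting STN i
  std::vector<int> gpe_stn;              // STN neuron exciting GPe i
  std::vector<int> gpe_gpe1, gpe_gpe2;
  std::vector<int> gpi_stn;
  std::vector<int> gpi_gpe1, gpi_gpe2;
  std::vector<int> th_gpi;
};

// Full network vector field; idbs/ismc are the stimulus currents over the
// current step (piecewise constant on the integration grid).
static void net_deriv(const Net& N, const double* y, double idbs, double ismc,
                      double* dy) {
  const int n = N.n;
  const double* stn = y;            double* dstn = dy;
  const double* gpe = y + 6 * n;    double* dgpe = dy + 6 * n;
  const double* gpi = y + 12 * n;   double* dgpi = dy + 12 * n;
  const double* th = y + 18 * n;    double* dth = dy + 18 * n;
  const double* s_stn = stn + 5 * n;
  const double* s_gpe = gpe + 5 * n;
  const double* s_gpi = gpi + 5 * n;

  double st[5], d[5];
  for (int i = 0; i < n; ++i) {
    // STN i <- GPe (i-1), (i+1)
    double ss = s_gpe[N.stn_gpe1[i]] + s_gpe[N.stn_gpe2[i]];
    double isyn = N.g_gs * (stn[i] - N.E_gs) * ss;
    st[0] = stn[i]; st[1] = stn[n + i]; st[2] = stn[2 * n + i];
    st[3] = stn[3 * n + i]; st[4] = stn[4 * n + i];
    bg_deriv(N.stn, st, isyn, N.stn.Iapp + idbs, d, 0);
    dstn[i] = d[0]; dstn[n + i] = d[1]; dstn[2 * n + i] = d[2];
    dstn[3 * n + i] = d[3]; dstn[4 * n + i] = d[4];
    dstn[5 * n + i] = s_deriv(N.stn, stn[i], s_stn[i]);

    // GPe i <- STN i, GPe (i-1), (i+1)
    double isyn_g = N.g_sg * (gpe[i] - N.E_sg) * s_stn[N.gpe_stn[i]] +
      N.g_gg * (gpe[i] - N.E_gg) * (s_gpe[N.gpe_gpe1[i]] + s_gpe[N.gpe_gpe2[i]]);
    st[0] = gpe[i]; st[1] = gpe[n + i]; st[2] = gpe[2 * n + i];
    st[3] = gpe[3 * n + i]; st[4] = gpe[4 * n + i];
    bg_deriv(N.gpe, st, isyn_g, N.gpe.Iapp, d, 0);
    dgpe[i] = d[0]; dgpe[n + i] = d[1]; dgpe[2 * n + i] = d[2];
    dgpe[3 * n + i] = d[3]; dgpe[4 * n + i] = d[4];
    dgpe[5 * n + i] = s_deriv(N.gpe, gpe[i], s_gpe[i]);

    // GPi i <- STN i, GPe (i-1), (i+1)
    double isyn_gi = N.g_sgi * (gpi[i] - N.E_sgi) * s_stn[N.gpi_stn[i]] +
      N.g_ggi * (gpi[i] - N.E_ggi) * (s_gpe[N.gpi_gpe1[i]] + s_gpe[N.gpi_gpe2[i]]);
    st[0] = gpi[i]; st[1] = gpi[n + i]; st[2] = gpi[2 * n + i];
    st[3] = gpi[3 * n + i]; st[4] = gpi[4 * n + i];
    bg_deriv(N.gpi, st, isyn_gi, N.gpi.Iapp, d, 0);
    dgpi[i] = d[0]; dgpi[n + i] = d[1]; dgpi[2 * n + i] = d[2];
    dgpi[3 * n + i] = d[3]; dgpi[4 * n + i] = d[4];
    dgpi[5 * n + i] = s_deriv(N.gpi, gpi[i], s_gpi[i]);

    // Th i <- GPi i
    double isyn_t = N.g_git * (th[i] - N.E_git) * s_gpi[N.th_gpi[i]];
    double dt3[3];
    double stt[3] = { th[i], th[n + i], th[2 * n + i] };
    th_deriv(N.th, stt, isyn_t, ismc, dt3, 0);
    dth[i] = dt3[0]; dth[n + i] = dt3[1]; dth[2 * n + i] = dt3[2];
  }
}

static std::vector<int> idxvec(const IntegerVector& v) {
  return std::vector<int>(v.begin(), v.end());
}

// Thalamic I_T and GPi->Th synaptic current for diagnostics at record time.
static inline double th_it(const ThPar& p, double v, double r) {
  double pinf = 1.0 / (1.0 + std::exp(-(v + 60.0) / 6.2));
  return p.gT * pinf * pinf * r * (v - p.ET);
}
static inline double bg_it(const BGPar& p, double v, double r) {
  double ainf = xinf(v, p.th_a, p.sg_a);
  double tg = r;
  if (p.use_b) {
    double b = binf(r, p.th_b, p.sg_b, p.b_printed);
    tg = b * b;
  }
  return p.gT * ainf * ainf * ainf * tg * (v - p.ECa);
}

// [[Rcpp::export(name = ".simulate_network_cpp")]]
List simulate_network_cpp(List stn_params, List gpe_params, List gpi_params,
                          List th_params, List syn, List afferents,
                          NumericVector y0, NumericVector i_dbs,
                          NumericVector i_smc, double dt, int nsteps,
                          double spike_threshold, double refractory,
                          int record_every, bool record_currents) {
  Net N;
  N.stn = bg_par(stn_params);
  N.gpe = bg_par(gpe_params);
  N.gpi = bg_par(gpi_params);
  N.th = th_par(th_params);
  N.g_gs = num(syn, "g_gpe_stn"); N.E_gs = num(syn, "E_gpe_stn");
  N.g_sg = num(syn, "g_stn_gpe"); N.E_sg = num(syn, "E_stn_gpe");
  N.g_gg = num(syn, "g_gpe_gpe"); N.E_gg = num(syn, "E_gpe_gpe");
  N.g_sgi = num(syn, "g_stn_gpi"); N.E_sgi = num(syn, "E_stn_gpi");
  N.g_ggi = num(syn, "g_gpe_gpi"); N.E_ggi = num(syn, "E_gpe_gpi");
  N.g_git = num(syn, "g_gpi_th"); N.E_git = num(syn, "E_gpi_th");
  N.stn_gpe1 = idxvec(afferents["stn_gpe1"]);
  N.stn_gpe2 = idxvec(afferents["stn_gpe2"]);
  N.gpe_stn = idxvec(afferents["gpe_stn"]);
  N.gpe_gpe1 = idxvec(afferents["gpe_gpe1"]);
  N.gpe_gpe2 = idxvec(afferents["gpe_gpe2"]);
  N.gpi_stn = idxvec(afferents["gpi_stn"]);
  N.gpi_gpe1 = idxvec(afferents["gpi_gpe1"]);
  N.gpi_gpe2 = idxvec(afferents["gpi_gpe2"]);
  N.th_gpi = idxvec(afferents["th_gpi"]);
  const int n = (int) N.stn_gpe1.size();
  N.n = n;
  const int ny = 21 * n;
  if (y0.size() != ny) stop("state vector has wrong length");
  if (i_dbs.size() < nsteps || i_smc.size() < nsteps)
    stop("stimulus vectors shorter than the number of steps");

  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> k1(ny), k2(ny), k3(ny), k4(ny), tmp(ny);
  std::vector<double> vprev(4 * n);
  std::vector< std::vector<double> > spikes(4 * n);
  std::vector<double> last_spike(4 * n, -1e9);

  // voltage index of neuron j (0..4n-1) in y
  std::vector<int> vidx(4 * n);
  for (int i = 0; i < n; ++i) {
    vidx[i] = i;                  // STN
    vidx[n + i] = 6 * n + i;      // GPe
    vidx[2 * n + i] = 12 * n + i; // GPi
    vidx[3 * n + i] = 18 * n + i; // Th
  }

  const int nrec = record_every > 0 ? nsteps / record_every + 1 : 0;
  NumericMatrix v_stn, v_gpe, v_gpi, v_th, it_stn, it_th, isyn_th;
  NumericVector t_rec;
  if (record_every > 0) {
    v_stn = NumericMatrix(nrec, n); v_gpe = NumericMatrix(nrec, n);
    v_gpi = NumericMatrix(nrec, n); v_th = NumericMatrix(nrec, n);
    t_rec = NumericVector(nrec);
    if (record_currents) {
      it_stn = NumericMatrix(nrec, n);
      it_th = NumericMatrix(nrec, n);
      isyn_th = NumericMatrix(nrec, n);
    }
  }
  int irec = 0;
  const char* popname[4] = { "STN", "GPe", "GPi", "Th" };

  // record initial sample
  if (record_every > 0) {
    t_rec[0] = 0.0;
    for (int i = 0; i < n; ++i) {
      v_stn(0, i) = y[vidx[i]]; v_gpe(0, i) = y[vidx[n + i]];
      v_gpi(0, i) = y[vidx[2 * n + i]]; v_th(0, i) = y[vidx[3 * n + i]];
      if (record_currents) {
        it_stn(0, i) = bg_it(N.stn, y[i], y[3 * n + i]);
        it_th(0, i) = th_it(N.th, y[18 * n + i], y[20 * n + i]);
        isyn_th(0, i) = N.g_git * (y[18 * n + i] - N.E_git) *
          y[12 * n + 5 * n + N.th_gpi[i]];
      }
    }
    irec = 1;
  }

  for (int k = 0; k < nsteps; ++k) {
    double idbs = i_dbs[k], ismc = i_smc[k];
    for (int j = 0; j < 4 * n; ++j) vprev[j] = y[vidx[j]];

    net_deriv(N, y.data(), idbs, ismc, k1.data());
    for (int j = 0; j < ny; ++j) tmp[j] = y[j] + 0.5 * dt * k1[j];
    net_deriv(N, tmp.data(), idbs, ismc, k2.data());
    for (int j = 0; j < ny; ++j) tmp[j] = y[j] + 0.5 * dt * k2[j];
    net_deriv(N, tmp.data(), idbs, ismc, k3.data());
    for (int j = 0; j < ny; ++j) tmp[j] = y[j] + dt * k3[j];
    net_deriv(N, tmp.data(), idbs, ismc, k4.data());
    for (int j = 0; j < ny; ++j)
      y[j] += dt / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);

    double t = (k + 1) * dt;
    for (int j = 0; j < 4 * n; ++j) {
      double v = y[vidx[j]];
      if (!std::isfinite(v))
        stop("state blow-up at t = %.3f ms (%s neuron %d: v is not finite)",
             t, popname[j / n], j % n);
      if (vprev[j] < spike_threshold && v >= spike_threshold &&
          t - last_spike[j] >= refractory) {
        spikes[j].push_back(t);
        last_spike[j] = t;
      }
    }

    if (record_every > 0 && (k + 1) % record_every == 0) {
      t_rec[irec] = t;
      for (int i = 0; i < n; ++i) {
        v_stn(irec, i) = y[i]; v_gpe(irec, i) = y[6 * n + i];
        v_gpi(irec, i) = y[12 * n + i]; v_th(irec, i) = y[18 * n + i];
        if (record_currents) {
          it_stn(irec, i) = bg_it(N.stn, y[i], y[3 * n + i]);
          it_th(irec, i) = th_it(N.th, y[18 * n + i], y[20 * n + i]);
          isyn_th(irec, i) = N.g_git * (y[18 * n + i] - N.E_git) *
            y[17 * n + N.th_gpi[i]];
        }
      }
      ++irec;
    }
  }

  List spk(4);
  for (int pop = 0; pop < 4; ++pop) {
    List ls(n);
    for (int i = 0; i < n; ++i)
      ls[i] = NumericVector(spikes[pop * n + i].begin(),
                            spikes[pop * n + i].end());
    spk[pop] = ls;
  }
  spk.names() = CharacterVector::create("STN", "GPe", "GPi", "Th");

  List out = List::create(_["spikes"] = spk,
                          _["state"] = NumericVector(y.begin(), y.end()));
  if (record_every > 0) {
    out["time"] = t_rec;
    out["v"] = List::create(_["STN"] = v_stn, _["GPe"] = v_gpe,
                            _["GPi"] = v_gpi, _["Th"] = v_th);
    if (record_currents)
      out["currents"] = List::create(_["I_T_STN"] = it_stn,
                                     _["I_T_Th"] = it_th,
                                     _["I_GPi_Th"] = isyn_th);
  }
  return out;
}

// Single STN/GPe/GPi cell driven by an injected-current series (one value per
// step, piecewise constant). Used for current-step and rebound protocols.
// [[Rcpp::export(name = ".simulate_bg_cell_cpp")]]
List simulate_bg_cell_cpp(List params, NumericVector state0,
                          NumericVector i_inj, double dt, int nsteps,
                          double spike_threshold, double refractory,
                          int record_every) {
  BGPar p = bg_par(params);
  if (state0.size() != 5) stop("state0 must be {v, n, h, r, Ca}");
  if (i_inj.size() < nsteps) stop("i_inj shorter than nsteps");
  double y[5], k1[5], k2[5], k3[5], k4[5], tmp[5];
  for (int j = 0; j < 5; ++j) y[j] = state0[j];
  const int nrec = record_every > 0 ? nsteps / record_every + 1 : 0;
  NumericVector vtr(nrec), ittr(nrec), ttr(nrec);
  std::vector<double> spikes;
  double last_spike = -1e9;
  int irec = 0;
  if (record_every > 0) {
    vtr[0] = y[0]; ittr[0] = bg_it(p, y[0], y[3]); ttr[0] = 0.0; irec = 1;
  }
  for (int k = 0; k < nsteps; ++k) {
    double I = i_inj[k];
    double vprev = y[0];
    bg_deriv(p, y, 0.0, I, k1, 0);
    for (int j = 0; j < 5; ++j) tmp[j] = y[j] + 0.5 * dt * k1[j];
    bg_deriv(p, tmp, 0.0, I, k2, 0);
    for (int j = 0; j < 5; ++j) tmp[j] = y[j] + 0.5 * dt * k2[j];
    bg_deriv(p, tmp, 0.0, I, k3, 0);
    for (int j = 0; j < 5; ++j) tmp[j] = y[j] + dt * k3[j];
    bg_deriv(p, tmp, 0.0, I, k4, 0);
    for (int j = 0; j < 5; ++j)
      y[j] += dt / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
    double t = (k + 1) * dt;
    if (!std::isfinite(y[0]))
      stop("state blow-up at t = %.3f ms (single cell)", t);
    if (vprev < spike_threshold && y[0] >= spike_threshold &&
        t - last_spike >= refractory) {
      spikes.push_back(t);
      last_spike = t;
    }
    if (record_every > 0 && (k + 1) % record_every == 0) {
      vtr[irec] = y[0]; ittr[irec] = bg_it(p, y[0], y[3]); ttr[irec] = t;
      ++irec;
    }
  }
  List out = List::create(
    _["spikes"] = NumericVector(spikes.begin(), spikes.end()),
    _["state"] = NumericVector(y, y + 5));
  if (record_every > 0) {
    out["time"] = ttr; out["v"] = vtr; out["I_T"] = ittr;
  }
  return out;
}
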