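#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Five-channel Hodgkin-Huxley-type RGC membrane (Fohlmeister-lineage
// amphibian kinetics at 22 C, no Q10 scaling) on a 1-D cable driven by an
// extracellular potential. Gates: m, h (Na), n (K delayed rectifier),
// a, hA (K A-type), c (Ca L-type); K(Ca) is gated algebraically by [Ca]_i.
//
// Units: mV, ms, mS, uF, uA, mM. mS*mV = uA; uF*mV/ms = uA.

static inline double linexp(double num_scale, double v, double v0, double inv_b) {
  // num_scale*(v-v0) / (exp(inv_b*(v-v0)) - 1), with the removable
  // singularity at v = v0 handled by its limit -num_scale/inv_b.
  double x = inv_b * (v - v0);
  if (std::fabs(x) < 1e-7) return -num_scale / inv_b * (1.0 - 0.5 * x);
  return num_scale * (v - v0) / std::expm1(x);
}

struct Rates { double a[6], b[6]; };  // order: m, h, n, aA, hA, c

static inline Rates fcm_rates(double v) {
  Rates r;
  r.a[0] = linexp(-0.6,   v, -30.0, -0.1);        // alpha_m
  r.b[0] = 20.0 * std::exp(-(v + 55.0) / 18.0);   // beta_m
  r.a[1] = 0.4 * std::exp(-(v + 50.0) / 20.0);    // alpha_h
  r.b[1] = 6.0 / (1.0 + std::exp(-0.1 * (v + 20.0)));
  r.a[2] = linexp(-0.02,  v, -40.0, -0.1);        // alpha_n
  r.b[2] = 0.4 * std::exp(-(v + 50.0) / 80.0);
  r.a[3] = linexp(-0.006, v, -90.0, -0.1);        // alpha_a (A-type act.)
  r.b[3] = 0.1 * std::exp(-(v + 30.0) / 10.0);
  r.a[4] = 0.04 * std::exp(-(v + 70.0) / 20.0);   // alpha_hA
  r.b[4] = 0.6 / (1.0 + std::exp(-0.1 * (v + 40.0)));
  r.a[5] = linexp(-0.3,   v, -13.0, -0.1);        // alpha_c
  r.b[5] = 10.0 * std::exp(-(v + 38.0) / 18.0);
  return r;
}

// [[Rcpp::export(name = ".fcm_rates_cpp")]]
NumericMatrix fcm_rates_cpp(NumericVector v) {
  NumericMatrix out(v.size(), 12);
  CharacterVector nm = CharacterVector::create(
    "alpha_m", "beta_m", "alpha_h", "beta_h", "alpha_n", "beta_n",
    "alpha_a", "beta_a", "alpha_hA", "beta_hA", "alpha_c", "beta_c");
  for (R_xlen_t i = 0; i < v.size(); ++i) {
    Rates r = fcm_rates(v[i]);
    for (int g = 0; g < 6; ++g) { out(i, 2 * g) = r.a[g]; out(i, 2 * g + 1) = r.b[g]; }
  }
  colnames(out) = nm;
  return out;
}

// Precomputed Rush-Larsen tables: per gate, x_inf(V) and exp(-dt/tau(V)).
struct RLTable {
  double vmin, dv_inv;
  int nbin;
  std::vector<double> xinf[6], edt[6];
  void build(double dt, double vmin_, double vmax, double dv) {
    vmin = vmin_; dv_inv = 1.0 / dv;
    nbin = (int)std::ceil((vmax - vmin) / dv) + 1;
    for (int g = 0; g < 6; ++g) { xinf[g].resize(nbin); edt[g].resize(nbin); }
    for (int b = 0; b < nbin; ++b) {
      Rates r = fcm_rates(vmin + b * dv);
      for (int g = 0; g < 6; ++g) {
        double s = r.a[g] + r.b[g];
        xinf[g][b] = r.a[g] / s;
        edt[g][b]  = std::exp(-dt * s);
      }
    }
  }
  inline void lookup(double v, double* xi, double* ed) const {
    double u = (v - vmin) * dv_inv;
    if (u < 0) u = 0;
    if (u > nbin - 1.001) u = nbin - 1.001;
    int b = (int)u;
    double w = u - b;
    for (int g = 0; g < 6; ++g) {
      xi[g] = xinf[g][b] * (1 - w) + xinf[g][b + 1] * w;
      ed[g] = edt[g][b]  * (1 - w) + edt[g][b + 1]  * w;
    }
  }
};

// theta = 1: backward Euler; theta = 0.5: Crank-Nicolson. Conductances and
// reversal drives are frozen at the start of each step (Rush-Larsen gates
// updated first from V^t), the cable tridiagonal system is solved by the
// Thomas algorithm.
//
// gabs: 6 x n matrix of absolute conductances (mS), rows in the order
//       gNa, gK, gKA, gKCa, gCa, gL.
// [[Rcpp::export(name = ".cable_integrate")]]
List cable_integrate(NumericMatrix gabs, NumericVector el,
                     double ena, double ek,
                     NumericVector cm, NumericVector gax,
                     NumericVector ve_unit, NumericVector i_wave, double dt,
                     double v_init, NumericVector gates_init,
                     double ca_rest, double ca_out, double ca_diss,
                     double tau_ca, NumericVector shell_vol_L,
                     double nernst_ca_factor,
                     IntegerVector record_idx, int record_stride,
                     double spike_level, double theta,
                     double i_intra_amp, int i_intra_comp,
                     double i_intra_t0, double i_intra_t1) {
  const int n = gabs.ncol();
  const int nt = i_wave.size();
  const double CA_K = 1e-6 / (2.0 * 96485.33);  // uA -> mmol/ms scale (per liter below)

  std::vector<double> v(n, v_init), vnew(n), ca(n, ca_rest), eca(n);
  std::vector<double> g6[6];
  for (int g = 0; g < 6; ++g) g6[g].assign(n, 0.0);
  std::vector<double> gate[6];
  for (int g = 0; g < 6; ++g) gate[g].assign(n, gates_init[g]);

  RLTable tab;
  tab.build(dt, -150.0, 120.0, 0.01);

  std::vector<double> sub(n), dia(n), sup(n), rhs(n), cp(n), dp(n);
  std::vector<double> ve_now(n, 0.0), ve_old(n, 0.0);

  const int nrec = record_idx.size();
  const int nsteps_rec = nt / record_stride + 1;
  NumericMatrix vrec(nsteps_rec, nrec);
  NumericVector trec(nsteps_rec);
  int irec = 0;

  std::vector<int> cross_comp; std::vector<double> cross_time;
  double xi[6], ed[6];
  bool diverged = false; double t_fail = NA_REAL;

  // record initial state
  for (int q = 0; q < nrec; ++q) vrec(0, q) = v[record_idx[q]];
  trec[0] = 0.0;
  irec = 1;

  for (int s = 0; s < nt; ++s) {
    double t_new = (s + 1) * dt;
    double I_old = (s == 0) ? 0.0 : i_wave[s - 1];
    double I_new = i_wave[s];
    for (int i = 0; i < n; ++i) {
      ve_old[i] = ve_unit[i] * I_old * 1e-3;  // V/A * uA -> mV
      ve_now[i] = ve_unit[i] * I_new * 1e-3;
    }

    // gate update from V^t, then frozen conductances
    for (int i = 0; i < n; ++i) {
      tab.lookup(v[i], xi, ed);
      for (int g = 0; g < 6; ++g)
        gate[g][i] = xi[g] + (gate[g][i] - xi[g]) * ed[g];
      double m = gate[0][i], h = gate[1][i], nn = gate[2][i];
      double aA = gate[3][i], hA = gate[4][i], c = gate[5][i];
      double kca = (ca[i] / ca_diss) * (ca[i] / ca_diss);
      kca = kca / (1.0 + kca);
      g6[0][i] = gabs(0, i) * m * m * m * h;   // Na
      g6[1][i] = gabs(1, i) * nn * nn * nn * nn; // K
      g6[2][i] = gabs(2, i) * aA * aA * aA * hA; // K,A
      g6[3][i] = gabs(3, i) * kca;             // K,Ca
      g6[4][i] = gabs(4, i) * c * c * c;       // Ca
      eca[i] = nernst_ca_factor * std::log(ca_out / ca[i]);
    }

    // assemble tridiagonal theta-system
    for (int i = 0; i < n; ++i) {
      double gl = gabs(5, i);
      double gtot = g6[0][i] + g6[1][i] + g6[2][i] + g6[3][i] + g6[4][i] + gl;
      double edrv = g6[0][i] * ena + (g6[1][i] + g6[2][i] + g6[3][i]) * ek +
                    g6[4][i] * eca[i] + gl * el[i];
      double gl_ax = (i > 0)     ? gax[i - 1] : 0.0;
      double gr_ax = (i < n - 1) ? gax[i]     : 0.0;
      double cdt = cm[i] / dt;
      dia[i] = cdt + theta * (gtot + gl_ax + gr_ax);
      sub[i] = (i > 0)     ? -theta * gax[i - 1] : 0.0;
      sup[i] = (i < n - 1) ? -theta * gax[i]     : 0.0;
      double lap_vo = 0.0, lap_ve = 0.0, lap_ve_old = 0.0;
      if (i > 0) {
        lap_vo     += gax[i - 1] * (v[i - 1] - v[i]);
        lap_ve     += gax[i - 1] * (ve_now[i - 1] - ve_now[i]);
        lap_ve_old += gax[i - 1] * (ve_old[i - 1] - ve_old[i]);
      }
      if (i < n - 1) {
        lap_vo     += gax[i] * (v[i + 1] - v[i]);
        lap_ve     += gax[i] * (ve_now[i + 1] - ve_now[i]);
        lap_ve_old += gax[i] * (ve_old[i + 1] - ve_old[i]);
      }
      rhs[i] = cdt * v[i] + edrv + (1.0 - theta) * (lap_vo - gtot * v[i]) +
               theta * lap_ve + (1.0 - theta) * lap_ve_old;
      if (i == i_intra_comp && t_new > i_intra_t0 && t_new <= i_intra_t1)
        rhs[i] += i_intra_amp;  // intracellular current injection (uA)
    }

    // Thomas solve
    cp[0] = sup[0] / dia[0];
    dp[0] = rhs[0] / dia[0];
    for (int i = 1; i < n; ++i) {
      double m_ = dia[i] - sub[i] * cp[i - 1];
      cp[i] = sup[i] / m_;
      dp[i] = (rhs[i] - sub[i] * dp[i - 1]) / m_;
    }
    vnew[n - 1] = dp[n - 1];
    for (int i = n - 2; i >= 0; --i) vnew[i] = dp[i] - cp[i] * vnew[i + 1];

    // Ca pool update (implicit decay), spike crossings, state swap
    for (int i = 0; i < n; ++i) {
      double ica = g6[4][i] * (vnew[i] - eca[i]);  // uA, inward negative
      double src = -ica * CA_K / shell_vol_L[i];   // mM/ms
      ca[i] = (ca[i] + dt * (src + ca_rest / tau_ca)) / (1.0 + dt / tau_ca);
      if (ca[i] < 1e-12) ca[i] = 1e-12;
      if (v[i] < spike_level && vnew[i] >= spike_level) {
        cross_comp.push_back(i + 1);
        cross_time.push_back(t_new);
      }
      if (!std::isfinite(vnew[i])) { diverged = true; t_fail = t_new; }
      v[i] = vnew[i];
    }
    if (diverged) break;

    if ((s + 1) % record_stride == 0 && irec < nsteps_rec) {
      for (int q = 0; q < nrec; ++q) vrec(irec, q) = v[record_idx[q]];
      trec[irec] = t_new;
      ++irec;
    }
  }

  NumericVector vfinal(n), cafinal(n);
  for (int i = 0; i < n; ++i) { vfinal[i] = v[i]; cafinal[i] = ca[i]; }
  NumericMatrix gfinal(6, n);
  for (int g = 0; g < 6; ++g)
    for (int i = 0; i < n; ++i) gfinal(g, i) = gate[g][i];

  return List::create(
    _["t"] = trec[Range(0, irec - 1)],
    _["v"] = vrec(Range(0, irec - 1), Range(0, std::max(nrec - 1, 0))),
    _["cross_comp"] = wrap(cross_comp),
    _["cross_time"] = wrap(cross_time),
    _["v_final"] = vfinal,
    _["ca_final"] = cafinal,
    _["gates_final"] = gfinal,
    _["diverged"] = diverged,
    _["t_fail"] = t_fail);
}
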