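// Double-cable compartmental integrator.
//
// The model is a list of flat arrays describing one branched-free cable:
// every compartment has an axolemma (intracellular) potential and, where a
// myelin sheath is present, a second periaxonal-layer potential coupled
// through the myelin admittance and drained to bath through a paranodal
// seal. States are ordered along the cable with the periaxonal state
// interleaved after its axolemma state, which makes the implicit system
// pentadiagonal; it is solved with an unpivoted banded LU (the matrix is
// weakly diagonally dominant by construction).
//
// Units: mV, ms, nF, uS, nA. Active compartments use Wang-Buzsaki style
// NaF/KDR kinetics (instantaneous m, exponential h/n updates), linearized
// per step so the potential solve stays linear.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

struct CableModel {
  int ncomp = 0, nstate = 0;
  std::vector<int> si, sp;           // state index of phi_i / phi_p (-1 if none)
  std::vector<double> c_ax, g_pas, e_pas, gna, gk;    // per comp (uS, nF)
  std::vector<double> c_my, g_my, g_seal;             // per comp (0 when no sheath)
  std::vector<int> active;           // 0 passive, 1 active (NaF+KDR)
  std::vector<double> phi_gate;      // per comp temperature-like rate factor
  std::vector<int> ai_a, ai_b;       // intracellular axial pairs (comp ids)
  std::vector<double> ai_g;
  std::vector<int> ap_a, ap_b;       // periaxonal axial pairs
  std::vector<double> ap_g;
  double ena = 55.0, ek = -90.0;
  int inj_comp = 0;
};

CableModel parse_model(const List& m) {
  CableModel M;
  IntegerVector has_peri = m["has_peri"];
  M.ncomp = has_peri.size();
  M.si.resize(M.ncomp); M.sp.resize(M.ncomp);
  int q = 0;
  for (int k = 0; k < M.ncomp; ++k) {
    M.si[k] = q++;
    M.sp[k] = has_peri[k] ? q++ : -1;
  }
  M.nstate = q;
  auto getv = [&](const char* nm) {
    NumericVector v = m[nm];
    return std::vector<double>(v.begin(), v.end());
  };
  M.c_ax = getv("c_ax"); M.g_pas = getv("g_pas"); M.e_pas = getv("e_pas");
  M.gna = getv("gna");   M.gk = getv("gk");
  M.c_my = getv("c_my"); M.g_my = getv("g_my");   M.g_seal = getv("g_seal");
  M.phi_gate = getv("phi_gate");
  IntegerVector act = m["active"];
  M.active.assign(act.begin(), act.end());
  IntegerVector ia = m["axial_i_a"], ib = m["axial_i_b"];
  NumericVector ig = m["axial_i_g"];
  M.ai_a.assign(ia.begin(), ia.end());
  M.ai_b.assign(ib.begin(), ib.end());
  M.ai_g.assign(ig.begin(), ig.end());
  IntegerVector pa = m["axial_p_a"], pb = m["axial_p_b"];
  NumericVector pg = m["axial_p_g"];
  M.ap_a.assign(pa.begin(), pa.end());
  M.ap_b.assign(pb.begin(), pb.end());
  M.ap_g.assign(pg.begin(), pg.end());
  M.ena = as<double>(m["ena"]); M.ek = as<double>(m["ek"]);
  M.inj_comp = as<int>(m["inj_comp"]);
  return M;
}

// ---- Wang-Buzsaki style gating -------------------------------------------
inline double am(double v) {
  double x = v + 35.0;
  if (std::fabs(x) < 1e-6) return 1.0;  // limit of 0.1*x/(1-exp(-x/10))
  return 0.1 * x / (1.0 - std::exp(-x / 10.0));
}
inline double bm(double v) { return 4.0 * std::exp(-(v + 60.0) / 18.0); }
inline double ah(double v) { return 0.07 * std::exp(-(v + 58.0) / 20.0); }
inline double bh(double v) { return 1.0 / (1.0 + std::exp(-(v + 28.0) / 10.0)); }
inline double an(double v) {
  double x = v + 34.0;
  if (std::fabs(x) < 1e-6) return 0.1;
  return 0.01 * x / (1.0 - std::exp(-x / 10.0));
}
inline double bn(double v) { return 0.125 * std::exp(-(v + 44.0) / 80.0); }

inline double minf(double v) { double a = am(v); return a / (a + bm(v)); }

// ---- banded LU, bandwidth 2, no pivoting ---------------------------------
struct Banded {
  int n = 0;
  std::vector<double> l2, l1, d, u1, u2;
  void resize(int nn) {
    n = nn;
    l2.assign(n, 0.0); l1.assign(n, 0.0); d.assign(n, 0.0);
    u1.assign(n, 0.0); u2.assign(n, 0.0);
  }
  void zero() {
    std::fill(l2.begin(), l2.end(), 0.0);
    std::fill(l1.begin(), l1.end(), 0.0);
    std::fill(d.begin(), d.end(), 0.0);
    std::fill(u1.begin(), u1.end(), 0.0);
    std::fill(u2.begin(), u2.end(), 0.0);
  }
  inline void add(int r, int c, double v) {
    int off = c - r;
    if (off == 0) d[r] += v;
    else if (off == 1) u1[r] += v;
    else if (off == 2) u2[r] += v;
    else if (off == -1) l1[r] += v;
    else if (off == -2) l2[r] += v;
    else Rcpp::stop("banded structure violated (offset %d)", off);
  }
  // solve in place: factors overwrite, rhs -> solution
  void solve(std::vector<double>& b) {
    // forward elimination
    for (int i = 0; i < n; ++i) {
      double piv = d[i];
      if (i + 1 < n && l1[i + 1] != 0.0) {
        double f = l1[i + 1] / piv;
        d[i + 1] -= f * u1[i];
        u1[i + 1] -= f * u2[i];
        b[i + 1] -= f * b[i];
        l1[i + 1] = 0.0;
      }
      if (i + 2 < n && l2[i + 2] != 0.0) {
        double f = l2[i + 2] / piv;
        l1[i + 2] -= f * u1[i];
        d[i + 2] -= f * u2[i];
        b[i + 2] -= f * b[i];
        l2[i + 2] = 0.0;
      }
    }
    // back substitution
    for (int i = n - 1; i >= 0; --i) {
      double s = b[i];
      if (i + 1 < n) s -= u1[i] * b[i + 1];
      if (i + 2 < n) s -= u2[i] * b[i + 2];
      b[i] = s / d[i];
    }
  }
};

struct GateState {
  std::vector<double> h, n;
};

inline double vm_of(const CableModel& M, const std::vector<double>& phi, int k) {
  double p = (M.sp[k] >= 0) ? phi[M.sp[k]] : 0.0;
  return phi[M.si[k]] - p;
}

void init_gates(const CableModel& M, const std::vector<double>& phi, GateState& G) {
  G.h.assign(M.ncomp, 0.0);
  G.n.assign(M.ncomp, 0.0);
  for (int k = 0; k < M.ncomp; ++k) {
    if (!M.active[k]) continue;
    double v = vm_of(M, phi, k);
    G.h[k] = ah(v) / (ah(v) + bh(v));
    G.n[k] = an(v) / (an(v) + bn(v));
  }
}

// per-comp ionic linearization at current gate state: G_ion, b_ion
inline void ionic(const CableModel& M, const GateState& G, int k, double vm,
                  double& Gi, double& bi) {
  Gi = M.g_pas[k];
  bi = M.g_pas[k] * M.e_pas[k];
  if (M.active[k]) {
    double m = minf(vm);
    double gna = M.gna[k] * m * m * m * G.h[k];
    double gk = M.gk[k] * G.n[k] * G.n[k] * G.n[k] * G.n[k];
    Gi += gna + gk;
    bi += gna * M.ena + gk * M.ek;
  }
}

}  // namespace

// [[Rcpp::export(name = ".cable_steady_cpp")]]
List cable_steady_cpp(List model, double v_soma, int max_iter = 80,
                      double tol = 1e-8) {
  CableModel M = parse_model(model);
  std::vector<double> phi(M.nstate, v_soma);
  // periaxonal potentials start at 0 (bath)
  for (int k = 0; k < M.ncomp; ++k)
    if (M.sp[k] >= 0) phi[M.sp[k]] = 0.0;
  GateState G;
  Banded A;
  std::vector<double> rhs(M.nstate);
  int soma = M.inj_comp;
  int soma_state = M.si[soma];
  double i_hold = 0.0;
  double err = 1e9;
  int it = 0;
  for (; it < max_iter; ++it) {
    init_gates(M, phi, G);  // gates at their steady state for current Vm
    A.resize(M.nstate);
    std::fill(rhs.begin(), rhs.end(), 0.0);
    // membrane rows (steady: no capacitive terms, theta = 1)
    for (int k = 0; k < M.ncomp; ++k) {
      double vm = vm_of(M, phi, k);
      double Gi, bi;
      ionic(M, G, k, vm, Gi, bi);
      int r = M.si[k];
      if (k == soma) {
        // unknown at soma position is I_hold; phi_soma fixed at v_soma
        A.add(r, r, -1.0);                    // coefficient of I_hold
        rhs[r] += -(Gi * v_soma - bi);        // ionic at the pinned potential
      } else {
        A.add(r, r, Gi);
        rhs[r] += bi;
        if (M.sp[k] >= 0) A.add(r, M.sp[k], -Gi);
      }
      if (M.sp[k] >= 0) {
        int rp = M.sp[k];
        A.add(rp, rp, M.g_my[k] + M.g_seal[k] + Gi);
        A.add(rp, r, -Gi);
        rhs[rp] += -bi;
      }
    }
    // intracellular axial couplings
    for (size_t e = 0; e < M.ai_a.size(); ++e) {
      int a = M.si[M.ai_a[e]], b = M.si[M.ai_b[e]];
      double g = M.ai_g[e];
      for (int pass = 0; pass < 2; ++pass) {
        int r = pass == 0 ? a : b, c = pass == 0 ? b : a;
        if (r == soma_state) continue;  // soma row is the I_hold row; its
                                        // axial balance is absorbed there
        if (c == soma_state) {
          A.add(r, r, g);
          rhs[r] += g * v_soma;
        } else {
          A.add(r, r, g);
          A.add(r, c, -g);
        }
      }
      // soma (I_hold) row: current conservation at the pinned compartment
      if (a == soma_state || b == soma_state) {
        int other = (a == soma_state) ? b : a;
        A.add(soma_state, other, -g);
        rhs[soma_state] += -g * v_soma;
      }
    }
    // periaxonal axial couplings
    for (size_t e = 0; e < M.ap_a.size(); ++e) {
      int a = M.sp[M.ap_a[e]], b = M.sp[M.ap_b[e]];
      double g = M.ap_g[e];
      A.add(a, a, g); A.add(a, b, -g);
      A.add(b, b, g); A.add(b, a, -g);
    }
    std::vector<double> sol = rhs;
    A.solve(sol);
    // sol holds potentials, except soma position holds I_hold
    err = 0.0;
    for (int s = 0; s < M.nstate; ++s) {
      if (s == soma_state) continue;
      err = std::max(err, std::fabs(sol[s] - phi[s]));
      phi[s] = 0.5 * phi[s] + 0.5 * sol[s];
    }
    i_hold = sol[soma_state];
    phi[soma_state] = v_soma;
    if (err < tol) break;
  }
  init_gates(M, phi, G);
  return List::create(_["phi"] = NumericVector(phi.begin(), phi.end()),
                      _["i_hold"] = i_hold, _["iterations"] = it + 1,
                      _["err"] = err,
                      _["h"] = NumericVector(G.h.begin(), G.h.end()),
                      _["n"] = NumericVector(G.n.begin(), G.n.end()));
}

namespace {

// gating rate tables over a fixed voltage grid: x_inf and the exact
// exponential relaxation factor exp(-dt * phi * (alpha + beta)) per gate
struct GateTables {
  double v0 = -120.0, dv = 0.05, inv_dv = 20.0;
  int nv = 0;
  std::vector<double> hinf, hfac, ninf, nfac, minf_t, mfac;
  void build(double dt, double phi, double phi_m, double phi_n,
             double h_shift) {
    nv = static_cast<int>((70.0 - v0) / dv) + 2;
    hinf.resize(nv); hfac.resize(nv); ninf.resize(nv); nfac.resize(nv);
    minf_t.resize(nv); mfac.resize(nv);
    for (int i = 0; i < nv; ++i) {
      double v = v0 + i * dv;
      double a = ah(v - h_shift), b = bh(v - h_shift);
      hinf[i] = a / (a + b);
      hfac[i] = std::exp(-dt * phi * (a + b));
      a = an(v); b = bn(v);
      ninf[i] = a / (a + b);
      nfac[i] = std::exp(-dt * phi_n * (a + b));
      a = am(v); b = bm(v);
      minf_t[i] = a / (a + b);
      mfac[i] = std::exp(-dt * phi_m * (a + b));
    }
  }
  inline void lookup(double v, double& hi, double& hf, double& ni,
                     double& nf, double& mi, double& mf) const {
    double x = (v - v0) * inv_dv;
    if (x < 0) x = 0;
    if (x > nv - 2) x = nv - 2;
    int i = static_cast<int>(x);
    double f = x - i;
    hi = hinf[i] + f * (hinf[i + 1] - hinf[i]);
    hf = hfac[i] + f * (hfac[i + 1] - hfac[i]);
    ni = ninf[i] + f * (ninf[i + 1] - ninf[i]);
    nf = nfac[i] + f * (nfac[i + 1] - nfac[i]);
    mi = minf_t[i] + f * (minf_t[i + 1] - minf_t[i]);
    mf = mfac[i] + f * (mfac[i + 1] - mfac[i]);
  }
};

}  // namespace

// [[Rcpp::export(name = ".cable_integrate_cpp")]]
List cable_integrate_cpp(List model, NumericVector phi0, NumericVector h0,
                         NumericVector n0, double dt, int nsteps,
                         double i_hold, double i_step, double t_on,
                         double t_off, IntegerVector probe_comps,
                         double theta = 0.5, bool record_max = true,
                         double v_abort = 250.0) {
  CableModel M = parse_model(model);
  if (phi0.size() != M.nstate) stop("bad initial state length");
  const int n = M.nstate;
  std::vector<double> phi(phi0.begin(), phi0.end());
  std::vector<double> h(h0.begin(), h0.end()), gn(n0.begin(), n0.end());

  // active compartments must share one gating rate factor for the tables
  double phig = 0.0;
  std::vector<int> act;
  for (int k = 0; k < M.ncomp; ++k)
    if (M.active[k]) {
      act.push_back(k);
      if (phig == 0.0) phig = M.phi_gate[k];
      else if (M.phi_gate[k] != phig) stop("phi_gate must be uniform");
    }
  // per-compartment NaF-activation and KDR rate factors; one table per
  // unique (phi_m, phi_n) pair
  std::vector<double> phim_v(M.ncomp, phig), phin_v(M.ncomp, phig),
      hsh_v(M.ncomp, 0.0);
  auto fill_per_comp = [&](const char* nm, std::vector<double>& dst) {
    if (model.containsElementNamed(nm)) {
      NumericVector pv = model[nm];
      if (pv.size() == M.ncomp) dst.assign(pv.begin(), pv.end());
      else dst.assign(M.ncomp, pv[0]);
    }
  };
  fill_per_comp("phi_m", phim_v);
  fill_per_comp("phi_n", phin_v);
  fill_per_comp("h_shift", hsh_v);
  struct Key { double a, b, c;
               bool operator==(const Key& o) const {
                 return a == o.a && b == o.b && c == o.c; } };
  std::vector<Key> ph_u;
  std::vector<int> tab_of(act.size());
  for (size_t a = 0; a < act.size(); ++a) {
    Key pv{phim_v[act[a]], phin_v[act[a]], hsh_v[act[a]]};
    int j = -1;
    for (size_t u = 0; u < ph_u.size(); ++u)
      if (ph_u[u] == pv) { j = static_cast<int>(u); break; }
    if (j < 0) { ph_u.push_back(pv); j = static_cast<int>(ph_u.size()) - 1; }
    tab_of[a] = j;
  }
  std::vector<GateTables> T(ph_u.size());
  for (size_t u = 0; u < ph_u.size(); ++u)
    T[u].build(dt, phig, ph_u[u].a, ph_u[u].b, ph_u[u].c);

  // ---- static banded operators -------------------------------------------
  // A x' = B x + c0 + step terms;  A holds the theta side with passive
  // ionic conductances, B the (1-theta) side; active-compartment ionic
  // conductances are added per step (single-layer rows: diagonal only).
  std::vector<double> Al2(n, 0), Al1(n, 0), Ad(n, 0), Au1(n, 0), Au2(n, 0);
  std::vector<double> Bl2(n, 0), Bl1(n, 0), Bd(n, 0), Bu1(n, 0), Bu2(n, 0);
  std::vector<double> c0(n, 0);
  auto addA = [&](int r, int c, double v) {
    int off = c - r;
    if (off == 0) Ad[r] += v; else if (off == 1) Au1[r] += v;
    else if (off == 2) Au2[r] += v; else if (off == -1) Al1[r] += v;
    else if (off == -2) Al2[r] += v; else stop("band violated");
  };
  auto addB = [&](int r, int c, double v) {
    int off = c - r;
    if (off == 0) Bd[r] += v; else if (off == 1) Bu1[r] += v;
    else if (off == 2) Bu2[r] += v; else if (off == -1) Bl1[r] += v;
    else if (off == -2) Bl2[r] += v; else stop("band violated");
  };
  const double om = 1.0 - theta;
  for (int k = 0; k < M.ncomp; ++k) {
    int r = M.si[k];
    double cdt = M.c_ax[k] / dt, gp = M.g_pas[k];
    addA(r, r, cdt + theta * gp);
    addB(r, r, cdt - om * gp);
    c0[r] += gp * M.e_pas[k];
    int rp = M.sp[k];
    if (rp >= 0) {
      addA(r, rp, -(cdt + theta * gp));
      addB(r, rp, -(cdt - om * gp));
      double gms = M.g_my[k] + M.g_seal[k];
      addA(rp, rp, M.c_my[k] / dt + theta * gms + cdt + theta * gp);
      addA(rp, r, -(cdt + theta * gp));
      addB(rp, rp, M.c_my[k] / dt - om * gms + cdt - om * gp);
      addB(rp, r, -(cdt - om * gp));
      c0[rp] += -gp * M.e_pas[k];
    }
  }
  for (size_t e = 0; e < M.ai_a.size(); ++e) {
    int a = M.si[M.ai_a[e]], b = M.si[M.ai_b[e]];
    double g = M.ai_g[e];
    addA(a, a, theta * g); addA(a, b, -theta * g);
    addA(b, b, theta * g); addA(b, a, -theta * g);
    addB(a, a, -om * g); addB(a, b, om * g);
    addB(b, b, -om * g); addB(b, a, om * g);
  }
  for (size_t e = 0; e < M.ap_a.size(); ++e) {
    int a = M.sp[M.ap_a[e]], b = M.sp[M.ap_b[e]];
    double g = M.ap_g[e];
    addA(a, a, theta * g); addA(a, b, -theta * g);
    addA(b, b, theta * g); addA(b, a, -theta * g);
    addB(a, a, -om * g); addB(a, b, om * g);
    addB(b, b, -om * g); addB(b, a, om * g);
  }

  int np = probe_comps.size();
  NumericMatrix traces(nsteps + 1, np);
  std::vector<double> vmax(M.ncomp, -1e9);
  // branch-free compartment lists for the running-peak update
  std::vector<int> one_k, one_s, two_k, two_si, two_sp;
  for (int k = 0; k < M.ncomp; ++k) {
    if (M.sp[k] >= 0) {
      two_k.push_back(k); two_si.push_back(M.si[k]); two_sp.push_back(M.sp[k]);
    } else {
      one_k.push_back(k); one_s.push_back(M.si[k]);
    }
  }
  auto record = [&](int row) {
    for (int p = 0; p < np; ++p) {
      int k = probe_comps[p];
      double pp = (M.sp[k] >= 0) ? phi[M.sp[k]] : 0.0;
      traces(row, p) = phi[M.si[k]] - pp;
    }
  };
  record(0);
  const int soma_row = M.si[M.inj_comp];
  const int nact = static_cast<int>(act.size());
  std::vector<int> act_row(nact);
  std::vector<double> act_gna(nact), act_gk(nact);
  for (int a = 0; a < nact; ++a) {
    act_row[a] = M.si[act[a]];
    act_gna[a] = M.gna[act[a]];
    act_gk[a] = M.gk[act[a]];
  }
  std::vector<double> dG(nact), dB(nact);
  std::vector<double> m(nact);
  for (int a = 0; a < nact; ++a) m[a] = minf(phi[act_row[a]]);

  // work arrays for the non-destructive banded LU
  std::vector<double> rhs(n), invd(n), wu1(n), invdB(n), wu1B(n);
  const double ena = M.ena, ek = M.ek;
  double* P = phi.data();
  double* R = rhs.data();

  for (int stp = 0; stp < nsteps; ++stp) {
    double t_mid = (stp + theta) * dt;
    double iinj = i_hold + ((t_mid >= t_on && t_mid < t_off) ? i_step : 0.0);

    // rhs = B * phi + c0
    if (n >= 5) {
      const double *l2 = Bl2.data(), *l1 = Bl1.data(), *d = Bd.data(),
                   *u1 = Bu1.data(), *u2 = Bu2.data(), *cc = c0.data();
      R[0] = d[0] * P[0] + u1[0] * P[1] + u2[0] * P[2] + cc[0];
      R[1] = l1[1] * P[0] + d[1] * P[1] + u1[1] * P[2] + u2[1] * P[3] + cc[1];
      for (int i = 2; i < n - 2; ++i)
        R[i] = l2[i] * P[i - 2] + l1[i] * P[i - 1] + d[i] * P[i] +
               u1[i] * P[i + 1] + u2[i] * P[i + 2] + cc[i];
      int i = n - 2;
      R[i] = l2[i] * P[i - 2] + l1[i] * P[i - 1] + d[i] * P[i] +
             u1[i] * P[i + 1] + cc[i];
      i = n - 1;
      R[i] = l2[i] * P[i - 2] + l1[i] * P[i - 1] + d[i] * P[i] + cc[i];
    } else {
      for (int i = 0; i < n; ++i) {
        double s = c0[i] + Bd[i] * P[i];
        if (i >= 1) s += Bl1[i] * P[i - 1];
        if (i >= 2) s += Bl2[i] * P[i - 2];
        if (i + 1 < n) s += Bu1[i] * P[i + 1];
        if (i + 2 < n) s += Bu2[i] * P[i + 2];
        R[i] = s;
      }
    }
    R[soma_row] += iinj;

    // gating + active ionic linearization (all active rows single-layer)
    for (int a = 0; a < nact; ++a) {
      int r = act_row[a];
      double v = P[r];
      double hi, hf, ni, nf, mi, mf;
      T[tab_of[a]].lookup(v, hi, hf, ni, nf, mi, mf);
      double hh = hi + (h[act[a]] - hi) * hf;
      double nn = ni + (gn[act[a]] - ni) * nf;
      double mm = mi + (m[a] - mi) * mf;
      h[act[a]] = hh; gn[act[a]] = nn; m[a] = mm;
      double n2 = nn * nn;
      double gna = act_gna[a] * mm * mm * mm * hh;
      double gk = act_gk[a] * n2 * n2;
      dG[a] = gna + gk;
      R[r] += -om * dG[a] * v + gna * ena + gk * ek;
      Ad[r] += theta * dG[a];
    }

    // banded LU (non-destructive: Al*/Au* stay pristine except the active
    // diagonal entries restored below). For large systems the
    // factorization is twisted (run from both ends toward the middle):
    // the two elimination recurrences are independent, which hides the
    // division latency that a single-ended sweep serializes on.
    if (n >= 16) {
      const double *l2 = Al2.data(), *l1 = Al1.data(), *d = Ad.data(),
                   *u1 = Au1.data(), *u2 = Au2.data();
      double* id = invd.data();
      double* w1 = wu1.data();
      double* idB = invdB.data();
      double* w1B = wu1B.data();
      const int m = n / 2;          // interface rows are m and m + 1
      // seeds: top rows 0,1 and bottom rows n-1, n-2
      id[0] = 1.0 / d[0];
      w1[0] = u1[0];
      {
        double f = l1[1] * id[0];
        id[1] = 1.0 / (d[1] - f * w1[0]);
        w1[1] = u1[1] - f * u2[0];
        R[1] -= f * R[0];
      }
      idB[n - 1] = 1.0 / d[n - 1];
      w1B[n - 1] = l1[n - 1];
      {
        double f = u1[n - 2] * idB[n - 1];
        idB[n - 2] = 1.0 / (d[n - 2] - f * w1B[n - 1]);
        w1B[n - 2] = l1[n - 2] - f * l2[n - 1];
        R[n - 2] -= f * R[n - 1];
      }
      // interleaved sweeps: top rows 2..m-1, bottom rows n-3..m+2
      {
        int i = 2, j = n - 3;
        for (; i < m; ++i, --j) {
          double lh2 = l2[i] * id[i - 2];
          double lh1 = (l1[i] - lh2 * w1[i - 2]) * id[i - 1];
          id[i] = 1.0 / (d[i] - lh2 * u2[i - 2] - lh1 * w1[i - 1]);
          w1[i] = u1[i] - lh1 * u2[i - 1];
          R[i] -= lh2 * R[i - 2] + lh1 * R[i - 1];
          if (j >= m + 2) {
            double uh2 = u2[j] * idB[j + 2];
            double uh1 = (u1[j] - uh2 * w1B[j + 2]) * idB[j + 1];
            idB[j] = 1.0 / (d[j] - uh2 * l2[j + 2] - uh1 * w1B[j + 1]);
            w1B[j] = l1[j] - uh1 * l2[j + 1];
            R[j] -= uh2 * R[j + 2] + uh1 * R[j + 1];
          }
        }
        for (; j >= m + 2; --j) {
          double uh2 = u2[j] * idB[j + 2];
          double uh1 = (u1[j] - uh2 * w1B[j + 2]) * idB[j + 1];
          idB[j] = 1.0 / (d[j] - uh2 * l2[j + 2] - uh1 * w1B[j + 1]);
          w1B[j] = l1[j] - uh1 * l2[j + 1];
          R[j] -= uh2 * R[j + 2] + uh1 * R[j + 1];
        }
      }
      // 2x2 interface in rows m, m+1
      double am_, bm_, rm_, cm_, dm_, rm1_;
      {
        double lh2 = l2[m] * id[m - 2];
        double lh1 = (l1[m] - lh2 * w1[m - 2]) * id[m - 1];
        double uh2 = u2[m] * idB[m + 2];
        am_ = d[m] - lh2 * u2[m - 2] - lh1 * w1[m - 1] - uh2 * l2[m + 2];
        bm_ = u1[m] - lh1 * u2[m - 1] - uh2 * w1B[m + 2];
        rm_ = R[m] - lh2 * R[m - 2] - lh1 * R[m - 1] - uh2 * R[m + 2];

        double lh2b = l2[m + 1] * id[m - 1];   // col m-1 eliminated above
        double uh2b = u2[m + 1] * idB[m + 3];
        double uh1b = (u1[m + 1] - uh2b * w1B[m + 3]) * idB[m + 2];
        cm_ = l1[m + 1] - lh2b * w1[m - 1] - uh1b * l2[m + 2];
        dm_ = d[m + 1] - lh2b * u2[m - 1] - uh2b * l2[m + 3] -
              uh1b * w1B[m + 2];
        rm1_ = R[m + 1] - lh2b * R[m - 1] - uh2b * R[m + 3] - uh1b * R[m + 2];
      }
      double det = am_ * dm_ - bm_ * cm_;
      double xm = (rm_ * dm_ - bm_ * rm1_) / det;
      double xm1 = (am_ * rm1_ - cm_ * rm_) / det;
      R[m] = xm;
      R[m + 1] = xm1;
      // interleaved back substitution outward from the middle
      {
        int i = m - 1, j = m + 2;
        R[i] = (R[i] - w1[i] * R[i + 1] - u2[i] * R[i + 2]) * id[i];
        R[j] = (R[j] - w1B[j] * R[j - 1] - l2[j] * R[j - 2]) * idB[j];
        --i; ++j;
        for (; i >= 0 && j < n; --i, ++j) {
          R[i] = (R[i] - w1[i] * R[i + 1] - u2[i] * R[i + 2]) * id[i];
          R[j] = (R[j] - w1B[j] * R[j - 1] - l2[j] * R[j - 2]) * idB[j];
        }
        for (; i >= 0; --i)
          R[i] = (R[i] - w1[i] * R[i + 1] - u2[i] * R[i + 2]) * id[i];
        for (; j < n; ++j)
          R[j] = (R[j] - w1B[j] * R[j - 1] - l2[j] * R[j - 2]) * idB[j];
      }
    } else {
      const double *l2 = Al2.data(), *l1 = Al1.data(), *d = Ad.data(),
                   *u1 = Au1.data(), *u2 = Au2.data();
      double* id = invd.data();
      double* w1 = wu1.data();
      id[0] = 1.0 / d[0];
      w1[0] = u1[0];
      if (n > 1) {
        double lh1 = l1[1] * id[0];
        id[1] = 1.0 / (d[1] - lh1 * w1[0]);
        w1[1] = u1[1] - lh1 * u2[0];
        R[1] -= lh1 * R[0];
      }
      for (int i = 2; i < n; ++i) {
        double lh2 = l2[i] * id[i - 2];
        double lh1i = (l1[i] - lh2 * w1[i - 2]) * id[i - 1];
        double dhi = d[i] - lh2 * u2[i - 2] - lh1i * w1[i - 1];
        id[i] = 1.0 / dhi;
        w1[i] = u1[i] - lh1i * u2[i - 1];
        R[i] -= lh2 * R[i - 2] + lh1i * R[i - 1];
      }
      // back substitution
      R[n - 1] *= id[n - 1];
      if (n > 1) R[n - 2] = (R[n - 2] - w1[n - 2] * R[n - 1]) * id[n - 2];
      for (int i = n - 3; i >= 0; --i)
        R[i] = (R[i] - w1[i] * R[i + 1] - u2[i] * R[i + 2]) * id[i];
    }
    for (int a = 0; a < nact; ++a) Ad[act_row[a]] -= theta * dG[a];

    std::swap(phi, rhs);
    P = phi.data();
    R = rhs.data();
    record(stp + 1);
    if (record_max) {
      const double* Q = phi.data();
      double* VM = vmax.data();
      for (size_t j = 0; j < one_k.size(); ++j) {
        double v = Q[one_s[j]];
        if (v > VM[one_k[j]]) VM[one_k[j]] = v;
      }
      for (size_t j = 0; j < two_k.size(); ++j) {
        double v = Q[two_si[j]] - Q[two_sp[j]];
        if (v > VM[two_k[j]]) VM[two_k[j]] = v;
      }
    }
    if ((stp & 255) == 0) {
      for (int s = 0; s < n; ++s)
        if (!(std::fabs(phi[s]) < v_abort))
          stop("cable integration diverged at t=%.3f ms (state %d)",
               (stp + 1) * dt, s + 1);
    }
  }
  return List::create(
      _["traces"] = traces,
      _["vmax"] = NumericVector(vmax.begin(), vmax.end()),
      _["phi"] = NumericVector(phi.begin(), phi.end()),
      _["h"] = NumericVector(h.begin(), h.end()),
      _["n"] = NumericVector(gn.begin(), gn.end()));
}
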