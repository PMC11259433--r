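// Event-driven leaky integrate-and-fire ring-attractor network.
//
// 20,000 LIF neurons (80% E, 20% I) on a ring of preferred directions,
// sparse wrapped-Gaussian connectivity, current-based single-exponential
// AMPA/NMDA/GABA receptor traces, short-term facilitation (u/x) on the
// E->E pathway kept per presynaptic neuron, probabilistic spike
// transmission (one Bernoulli draw per presynaptic spike gates delivery to
// ALL targets and the STP update; the somatic reset still happens), and
// optional per-connection AMPA/NMDA delays via a ring buffer.
//
// Voltages in mV, times in ms. Exponential-Euler updates; synaptic input
// treated as constant within one dt for the membrane update.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <random>

using namespace Rcpp;

namespace {

inline double wrap_deg(double d) {
  d -= 360.0 * std::floor(d / 360.0);  // [0, 360)
  if (d > 180.0) d -= 360.0;
  return d;
}

// wrapped Gaussian on the circle (degrees)
inline double wgauss(double d, double sigma) {
  double s = 0.0;
  for (int k = -3; k <= 3; ++k) {
    double z = (d + 360.0 * k) / sigma;
    s += std::exp(-0.5 * z * z);
  }
  return s;
}

struct RNG {
  std::mt19937_64 g;
  explicit RNG(std::uint64_t seed) : g(seed) {}
  inline double unif() {
    return (g() >> 11) * (1.0 / 9007199254740992.0);
  }
};

// one pathway: sources -> targets, CSR by source, built by thinning
void build_pathway(int n_src, int n_tgt, double k_src, double sigma,
                   RNG& rng, std::vector<int>& ptr, std::vector<int>& idx,
                   long& n_clip) {
  // p(i<-j) = (k_src/n_src) * G(dtheta)/<G> with <G> the mean over the
  // target grid; thinning with geometric jumps under pmax
  std::vector<double> gtab(n_tgt);
  double gmean = 0.0;
  for (int i = 0; i < n_tgt; ++i) {
    double d = wrap_deg(360.0 * i / n_tgt);
    gtab[i] = wgauss(d, sigma);
    gmean += gtab[i];
  }
  gmean /= n_tgt;
  double base = k_src / n_src / gmean;
  double pmax = 0.0;
  std::vector<double> p(n_tgt);
  for (int i = 0; i < n_tgt; ++i) {
    p[i] = base * gtab[i];
    if (p[i] > 1.0) { p[i] = 1.0; ++n_clip; }
    if (p[i] > pmax) pmax = p[i];
  }
  ptr.assign(n_src + 1, 0);
  idx.clear();
  idx.reserve(static_cast<size_t>(k_src) * n_tgt / n_src * n_src + 64);
  double lq = std::log1p(-pmax);  // log(1 - pmax)
  for (int j = 0; j < n_src; ++j) {
    // target i has offset angle 360*(i/n_tgt - j/n_src): equivalently the
    // p-table shifted by j*n_tgt/n_src (real-valued shift; round to the
    // nearest grid point, exact when n_tgt is a multiple of n_src)
    double shift = static_cast<double>(j) * n_tgt / n_src;
    int ishift = static_cast<int>(std::lround(shift));
    double pos = -1.0;
    for (;;) {
      // geometric jump to the next candidate under pmax
      double ujump = rng.unif();
      pos += 1.0 + std::floor(std::log(1.0 - ujump) / lq);
      if (pos >= n_tgt) break;
      int i = static_cast<int>(pos);
      int tgt = i + ishift;
      if (tgt >= n_tgt) tgt -= n_tgt;
      double pp = p[i];
      if (pp >= pmax || rng.unif() * pmax < pp) idx.push_back(tgt);
    }
    ptr[j + 1] = static_cast<int>(idx.size());
  }
}

}  // namespace

// [[Rcpp::export(name = ".ring_connect_cpp")]]
List ring_connect_cpp(int ne, int ni, double ke, double ki,
                      double sigma_ee, double sigma_ei, double sigma_ie,
                      double sigma_ii, int seed) {
  RNG rng(static_cast<std::uint64_t>(seed) * 2654435761u + 1);
  std::vector<int> pee, iee, pei, iei, pie, iie, pii, iii;
  long clip = 0;
  // names: <src><tgt>; E->E, E->I, I->E, I->I
  build_pathway(ne, ne, ke, sigma_ee, rng, pee, iee, clip);
  build_pathway(ne, ni, ke, sigma_ei, rng, pei, iei, clip);
  build_pathway(ni, ne, ki, sigma_ie, rng, pie, iie, clip);
  build_pathway(ni, ni, ki, sigma_ii, rng, pii, iii, clip);
  return List::create(
      _["ee_ptr"] = pee, _["ee_idx"] = iee, _["ei_ptr"] = pei,
      _["ei_idx"] = iei, _["ie_ptr"] = pie, _["ie_idx"] = iie,
      _["ii_ptr"] = pii, _["ii_idx"] = iii, _["n_clipped"] = (double)clip);
}

// [[Rcpp::export(name = ".ring_sim_cpp")]]
List ring_sim_cpp(List par, List conn, double cue_deg,
                  NumericVector p_trans, List delay_spec, int seed,
                  bool record_i = false, bool record_vm = false) {
  const int ne = as<int>(par["NE"]), ni = as<int>(par["NI"]);
  const int n = ne + ni;
  const double dt = as<double>(par["dt"]);
  const double tau_e = as<double>(par["tau_e"]), tau_i = as<double>(par["tau_i"]);
  const double tau_a = as<double>(par["tau_a"]), tau_n = as<double>(par["tau_n"]);
  const double tau_g = as<double>(par["tau_g"]);
  const double tau_d = as<double>(par["tau_d"]), tau_f = as<double>(par["tau_f"]);
  const double U = as<double>(par["U"]);
  const double VT = as<double>(par["VT"]), VR = as<double>(par["VR"]);
  const double g_eea = as<double>(par["g_eea"]), g_een = as<double>(par["g_een"]);
  const double g_eia = as<double>(par["g_eia"]), g_ein = as<double>(par["g_ein"]);
  const double g_ie = as<double>(par["g_ie"]), g_ii = as<double>(par["g_ii"]);
  const double ie_ext = as<double>(par["ie_ext"]), ii_ext = as<double>(par["ii_ext"]);
  const double imax_e = as<double>(par["imax_e"]), eps_e = as<double>(par["eps_e"]);
  const double t_fix = as<double>(par["fixation_ms"]);
  const double t_cue = as<double>(par["cue_ms"]);
  const double t_delay = as<double>(par["delay_ms"]);
  const bool kernel_jump_g = as<bool>(par["kernel_jump_g"]);
  // external Poisson population (correlated-input variant); 0 disables
  const int next_n = par.containsElementNamed("n_ext") ? as<int>(par["n_ext"]) : 0;

  const double T = t_fix + t_cue + t_delay;
  const int nsteps = static_cast<int>(std::lround(T / dt));
  const int cue_on = static_cast<int>(std::lround(t_fix / dt));
  const int cue_off = static_cast<int>(std::lround((t_fix + t_cue) / dt));

  IntegerVector eeptr = conn["ee_ptr"], eeidx = conn["ee_idx"];
  IntegerVector eiptr = conn["ei_ptr"], eiidx = conn["ei_idx"];
  IntegerVector ieptr = conn["ie_ptr"], ieidx = conn["ie_idx"];
  IntegerVector iiptr = conn["ii_ptr"], iiidx = conn["ii_idx"];
  const int *EEp = eeptr.begin(), *EEi = eeidx.begin();
  const int *EIp = eiptr.begin(), *EIi = eiidx.begin();
  const int *IEp = ieptr.begin(), *IEi = ieidx.begin();
  const int *IIp = iiptr.begin(), *IIi = iiidx.begin();

  RNG rng(static_cast<std::uint64_t>(seed) * 6364136223846793005ull + 1442695040888963407ull);

  // receptor jumps: either J = g (per-spike voltage integral g*tau) or
  // J = g/tau (integral g)
  auto J = [&](double g, double tau) { return kernel_jump_g ? g : g / tau; };
  const double j_eea = J(g_eea, tau_a), j_een = J(g_een, tau_n);
  const double j_eia = J(g_eia, tau_a), j_ein = J(g_ein, tau_n);
  const double j_ie = J(g_ie, tau_g), j_ii = J(g_ii, tau_g);

  std::vector<double> V(n), sa(n, 0.0), sn_(n, 0.0), sg(n, 0.0);
  std::vector<double> u(ne, U), x(ne, 1.0);
  for (int i = 0; i < n; ++i) V[i] = VR + (VT - VR) * rng.unif();

  const double de = std::exp(-dt / tau_e), di = std::exp(-dt / tau_i);
  const double da = std::exp(-dt / tau_a), dn = std::exp(-dt / tau_n),
               dg = std::exp(-dt / tau_g);
  const double fd = std::exp(-dt / tau_d), ff = std::exp(-dt / tau_f);

  std::vector<double> cue(ne);
  for (int i = 0; i < ne; ++i) {
    double d = wrap_deg(360.0 * i / ne - cue_deg);
    cue[i] = imax_e * std::exp(-0.5 * (d / eps_e) * (d / eps_e));
  }

  // optional per-connection delays on the excitatory (AMPA+NMDA) pathways
  bool use_delay = false;
  int dmax_steps = 0;
  std::vector<float> dbuf_a, dbuf_n;
  std::vector<uint16_t> ee_del, ei_del;
  if (delay_spec.containsElementNamed("max_ms")) {
    double dmax = as<double>(delay_spec["max_ms"]);
    if (dmax > 0) {
      use_delay = true;
      dmax_steps = static_cast<int>(std::ceil(dmax / dt)) + 1;
      ee_del.resize(eeidx.size());
      ei_del.resize(eiidx.size());
      for (size_t e = 0; e < ee_del.size(); ++e)
        ee_del[e] = static_cast<uint16_t>(rng.unif() * dmax / dt);
      for (size_t e = 0; e < ei_del.size(); ++e)
        ei_del[e] = static_cast<uint16_t>(rng.unif() * dmax / dt);
      dbuf_a.assign(static_cast<size_t>(dmax_steps) * n, 0.0f);
      dbuf_n.assign(static_cast<size_t>(dmax_steps) * n, 0.0f);
    }
  }

  // external Poisson population (structured shared input)
  std::vector<int> xe_ptr, xe_idx;
  double r_ext = 0.0, j_ext_e = 0.0, j_ext_i = 0.0;
  if (next_n > 0) {
    r_ext = as<double>(par["r_ext"]);
    double kext = as<double>(par["k_ext"]);
    double sig_ext = as<double>(par["sigma_ext"]);
    j_ext_e = J(as<double>(par["g_ext_e"]), tau_a);
    j_ext_i = J(as<double>(par["g_ext_i"]), tau_a);
    long clip = 0;
    // one pathway onto the concatenated (E then I) ring: build separately
    // onto E and I with the same in-degree expectation kext
    std::vector<int> pe, ie, pi_, ii_;
    build_pathway(next_n, ne, kext, sig_ext, rng, pe, ie, clip);
    build_pathway(next_n, ni, kext, sig_ext, rng, pi_, ii_, clip);
    xe_ptr.assign(next_n + 1, 0);
    for (int j = 0; j < next_n; ++j) {
      for (int q = pe[j]; q < pe[j + 1]; ++q) xe_idx.push_back(ie[q]);
      for (int q = pi_[j]; q < pi_[j + 1]; ++q) xe_idx.push_back(ne + ii_[q]);
      xe_ptr[j + 1] = static_cast<int>(xe_idx.size());
    }
  }

  std::vector<int> sp_id;  // spikes this step
  sp_id.reserve(1024);
  std::vector<int> ras_id;
  std::vector<double> ras_t;
  ras_id.reserve(1 << 20);
  ras_t.reserve(1 << 20);
  std::vector<int> ras_id_i;
  std::vector<double> ras_t_i;
  long n_e_spikes = 0, n_transmitted = 0;

  // runaway guard: spike counts over a rolling 500 ms
  const int guard_win = static_cast<int>(500.0 / dt);
  long guard_count = 0;
  std::vector<int> guard_hist(guard_win, 0);
  int guard_pos = 0;

  NumericMatrix vm_out;
  if (record_vm) vm_out = NumericMatrix(nsteps / 10 + 1, 6);

  const double p_ext_step = r_ext * dt * 1e-3;  // rext in Hz, dt in ms
  double lq_ext = (next_n > 0 && p_ext_step < 1.0)
                      ? std::log1p(-p_ext_step) : 0.0;

  for (int stp = 0; stp < nsteps; ++stp) {
    double t = stp * dt;
    bool cue_active = (stp >= cue_on && stp < cue_off);

    // delayed deliveries arriving now
    if (use_delay) {
      size_t off = static_cast<size_t>(stp % dmax_steps) * n;
      float* ba = dbuf_a.data() + off;
      float* bn = dbuf_n.data() + off;
      for (int i = 0; i < n; ++i) {
        sa[i] += ba[i]; sn_[i] += bn[i];
        ba[i] = 0.0f; bn[i] = 0.0f;
      }
    }

    // membrane + trace updates, threshold detection
    sp_id.clear();
    for (int i = 0; i < ne; ++i) {
      double inp = sa[i] + sn_[i] + sg[i] + ie_ext;
      if (cue_active) inp += cue[i];
      double v = inp + (V[i] - inp) * de;
      sa[i] *= da; sn_[i] *= dn; sg[i] *= dg;
      u[i] = U + (u[i] - U) * ff;
      x[i] = 1.0 + (x[i] - 1.0) * fd;
      if (v >= VT) { v = VR; sp_id.push_back(i); }
      V[i] = v;
    }
    for (int i = ne; i < n; ++i) {
      double inp = sa[i] + sn_[i] + sg[i] + ii_ext;
      double v = inp + (V[i] - inp) * di;
      sa[i] *= da; sn_[i] *= dn; sg[i] *= dg;
      if (v >= VT) { v = VR; sp_id.push_back(i); }
      V[i] = v;
    }

    // external Poisson spikes (geometric skip over the population)
    if (next_n > 0 && p_ext_step > 0) {
      double pos = -1.0;
      for (;;) {
        pos += 1.0 + std::floor(std::log(1.0 - rng.unif()) / lq_ext);
        if (pos >= next_n) break;
        int j = static_cast<int>(pos);
        for (int q = xe_ptr[j]; q < xe_ptr[j + 1]; ++q) {
          int tgt = xe_idx[q];
          sa[tgt] += (tgt < ne) ? j_ext_e : j_ext_i;
        }
      }
    }

    // spike propagation
    for (int s : sp_id) {
      if (s < ne) {
        ras_id.push_back(s);
        ras_t.push_back(t);
        ++n_e_spikes;
        // one transmission draw per presynaptic spike (per-axon failure)
        if (p_trans[s] < 1.0 && rng.unif() >= p_trans[s]) continue;
        ++n_transmitted;
        // facilitation first, depression uses the updated u
        double uu = u[s] + U * (1.0 - u[s]);
        double w = uu * x[s];
        x[s] *= (1.0 - uu);
        u[s] = uu;
        double wa = j_eea * w, wn = j_een * w;
        if (!use_delay) {
          for (int q = EEp[s]; q < EEp[s + 1]; ++q) {
            int tgt = EEi[q];
            sa[tgt] += wa; sn_[tgt] += wn;
          }
          for (int q = EIp[s]; q < EIp[s + 1]; ++q) {
            int tgt = ne + EIi[q];
            sa[tgt] += j_eia; sn_[tgt] += j_ein;
          }
        } else {
          for (int q = EEp[s]; q < EEp[s + 1]; ++q) {
            int tgt = EEi[q];
            size_t slot = static_cast<size_t>((stp + 1 + ee_del[q]) % dmax_steps) * n + tgt;
            dbuf_a[slot] += static_cast<float>(wa);
            dbuf_n[slot] += static_cast<float>(wn);
          }
          for (int q = EIp[s]; q < EIp[s + 1]; ++q) {
            int tgt = ne + EIi[q];
            size_t slot = static_cast<size_t>((stp + 1 + ei_del[q]) % dmax_steps) * n + tgt;
            dbuf_a[slot] += static_cast<float>(j_eia);
            dbuf_n[slot] += static_cast<float>(j_ein);
          }
        }
      } else {
        if (record_i) {
          ras_id_i.push_back(s);
          ras_t_i.push_back(t);
        }
        int j = s - ne;
        for (int q = IEp[j]; q < IEp[j + 1]; ++q) sg[IEi[q]] += j_ie;
        for (int q = IIp[j]; q < IIp[j + 1]; ++q) sg[ne + IIi[q]] += j_ii;
      }
    }

    // runaway guard
    guard_count += static_cast<long>(sp_id.size()) - guard_hist[guard_pos];
    guard_hist[guard_pos] = static_cast<int>(sp_id.size());
    guard_pos = (guard_pos + 1) % guard_win;
    if (stp >= guard_win) {
      double rate = guard_count / (0.5 * n);  // spikes per 500 ms per neuron -> Hz*?
      // guard_count spikes in 0.5 s over n neurons: mean rate in Hz
      rate = guard_count / (static_cast<double>(n) * 0.5);
      if (rate > 200.0)
        stop("runaway network activity (population mean %.0f Hz sustained 500 ms at t=%.0f ms)",
             rate, t);
    }

    if (record_vm && stp % 10 == 0) {
      int r = stp / 10;
      vm_out(r, 0) = V[0]; vm_out(r, 1) = V[ne / 4]; vm_out(r, 2) = V[ne / 2];
      vm_out(r, 3) = V[ne]; vm_out(r, 4) = sa[ne / 2]; vm_out(r, 5) = sn_[ne / 2];
    }
  }

  List out = List::create(
      _["id"] = IntegerVector(ras_id.begin(), ras_id.end()),
      _["t"] = NumericVector(ras_t.begin(), ras_t.end()),
      _["t_total"] = T, _["u_final"] = NumericVector(u.begin(), u.end()),
      _["x_final"] = NumericVector(x.begin(), x.end()),
      _["n_e_spikes"] = (double)n_e_spikes,
      _["n_transmitted"] = (double)n_transmitted);
  if (record_i) {
    out["id_i"] = IntegerVector(ras_id_i.begin(), ras_id_i.end());
    out["t_i"] = NumericVector(ras_t_i.begin(), ras_t_i.end());
  }
  if (record_vm) out["vm"] = vm_out;
  return out;
}
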