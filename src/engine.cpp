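#include <Rcpp.h>
using namespace Rcpp;

// Fixed-step exponential-Euler integration of the reduced microcircuit.
// Units: time ms, voltage mV, conductance nS, capacitance pF, current pA.
// All randomness comes from R's RNG (norm_rand), so set.seed() on the R side
// makes runs bit-reproducible.  Draw order per step: for each neuron, somatic
// OU deviate then (two-compartment only) apical OU deviate.

static inline double rect_factor(double V, double Vhalf, double k, double fmin) {
  return fmin + (1.0 - fmin) / (1.0 + std::exp(-(V - Vhalf) / k));
}

// [[Rcpp::export(name = ".sim_engine")]]
List sim_engine(List net, double duration, double dt,
                int record_mode, int record_every) {
  const int n = as<int>(net["n"]);
  IntegerVector type = net["type"];          // 0 Pyr, 1 SST, 2 PV, 3 VIP
  LogicalVector two_comp = net["two_comp"];
  NumericVector Cm_s = net["Cm_s"], Cm_a = net["Cm_a"];
  NumericVector gL_s = net["gL_s"], gL_a = net["gL_a"];
  NumericVector EL = net["EL"], Vth = net["Vth"], Vreset = net["Vreset"];
  NumericVector tref = net["tref"], gc = net["gc"];
  NumericVector w_adapt = net["w_adapt"], tau_adapt = net["tau_adapt"];
  NumericVector bap_g = net["bap_g"], bap_tau = net["bap_tau"];
  NumericVector Gt_s = net["Gt_s"], Gt_a = net["Gt_a"];
  const double E_gaba = as<double>(net["E_gaba"]);
  const double Vhalf = as<double>(net["V_half"]);
  const double krect = as<double>(net["k_rect"]);
  const double fmin = as<double>(net["f_min"]);
  NumericVector ou_mean_s = net["ou_mean_s"], ou_sd_s = net["ou_sd_s"];
  NumericVector ou_mean_a = net["ou_mean_a"], ou_sd_a = net["ou_sd_a"];
  const double tau_ou = as<double>(net["tau_ou"]);
  const double E_exc = as<double>(net["E_exc"]);
  List classes = net["classes"];
  List stim = net["stim"];
  IntegerVector pyr_idx = net["pyr_idx"];

  const int nsteps = (int) std::round(duration / dt);
  const int nc = classes.size();

  // per-class constants and state
  std::vector<IntegerVector> cls_ptr(nc), cls_tgt(nc);
  std::vector<double> cls_w(nc), cls_er(nc), cls_ed(nc), cls_norm(nc),
      cls_E(nc);
  std::vector<int> cls_comp(nc);
  std::vector<std::vector<double>> xr(nc), xd(nc);
  for (int c = 0; c < nc; ++c) {
    List cl = classes[c];
    cls_ptr[c] = as<IntegerVector>(cl["ptr"]);
    cls_tgt[c] = as<IntegerVector>(cl["tgt"]);
    cls_w[c] = as<double>(cl["w"]);
    double tr = as<double>(cl["tau_r"]), td = as<double>(cl["tau_d"]);
    if (td <= tr) stop("synapse class %d: tau_d must exceed tau_r", c + 1);
    cls_er[c] = std::exp(-dt / tr);
    cls_ed[c] = std::exp(-dt / td);
    double tpk = tr * td / (td - tr) * std::log(td / tr);
    cls_norm[c] = 1.0 / (std::exp(-tpk / td) - std::exp(-tpk / tr));
    cls_E[c] = as<double>(cl["E_syn"]);
    cls_comp[c] = as<int>(cl["comp"]);   // 0 somatic-basal, 1 apical
    xr[c].assign(n, 0.0);
    xd[c].assign(n, 0.0);
  }

  // stimulus events (sorted by time on the R side)
  IntegerVector st_neuron = stim["neuron"], st_comp = stim["comp"];
  NumericVector st_time = stim["time"], st_w = stim["w"];
  const double st_tr = as<double>(stim["tau_r"]);
  const double st_td = as<double>(stim["tau_d"]);
  const double st_E = as<double>(stim["E_syn"]);
  const int nst = st_neuron.size();
  double st_er = 1.0, st_ed = 1.0, st_norm = 1.0;
  if (nst > 0) {
    st_er = std::exp(-dt / st_tr);
    st_ed = std::exp(-dt / st_td);
    double tpk = st_tr * st_td / (st_td - st_tr) * std::log(st_td / st_tr);
    st_norm = 1.0 / (std::exp(-tpk / st_td) - std::exp(-tpk / st_tr));
  }
  std::vector<double> sxr_s(n, 0.0), sxd_s(n, 0.0), sxr_a(n, 0.0),
      sxd_a(n, 0.0);
  int st_next = 0;

  // state
  std::vector<double> Vs(n), Va(n), w(n, 0.0), refr(n, 0.0);
  std::vector<double> bap(n, 0.0);
  std::vector<double> ou_s(n), ou_a(n);
  for (int i = 0; i < n; ++i) {
    Vs[i] = EL[i];
    Va[i] = EL[i];
    ou_s[i] = ou_mean_s[i];
    ou_a[i] = ou_mean_a[i];
  }
  const double e_ou = std::exp(-dt / tau_ou);
  const double s_ou = std::sqrt(1.0 - e_ou * e_ou);

  // recording
  const int npyr = pyr_idx.size();
  int nrec = 0;
  if (record_mode > 0) nrec = nsteps / record_every;
  NumericVector ax_sum(record_mode == 1 ? nrec : 0);
  NumericMatrix ax_mat(record_mode == 2 ? npyr : 0,
                       record_mode == 2 ? nrec : 0);
  int irec = 0;

  std::vector<int> sp_id;
  std::vector<double> sp_t;
  sp_id.reserve(4096);
  sp_t.reserve(4096);

  std::vector<double> gsum_s(n), gEsum_s(n), gsum_a(n), gEsum_a(n);

  for (int step = 0; step < nsteps; ++step) {
    double t = step * dt;

    // accumulate synaptic conductances (per class decay + sum)
    std::fill(gsum_s.begin(), gsum_s.end(), 0.0);
    std::fill(gEsum_s.begin(), gEsum_s.end(), 0.0);
    std::fill(gsum_a.begin(), gsum_a.end(), 0.0);
    std::fill(gEsum_a.begin(), gEsum_a.end(), 0.0);
    for (int c = 0; c < nc; ++c) {
      double er = cls_er[c], ed = cls_ed[c], nrm = cls_norm[c], E = cls_E[c];
      std::vector<double>& r = xr[c];
      std::vector<double>& d = xd[c];
      if (cls_comp[c] == 0) {
        for (int i = 0; i < n; ++i) {
          r[i] *= er; d[i] *= ed;
          double g = nrm * (d[i] - r[i]);
          if (g != 0.0) { gsum_s[i] += g; gEsum_s[i] += g * E; }
        }
      } else {
        for (int i = 0; i < n; ++i) {
          r[i] *= er; d[i] *= ed;
          double g = nrm * (d[i] - r[i]);
          if (g != 0.0) { gsum_a[i] += g; gEsum_a[i] += g * E; }
        }
      }
    }
    if (nst > 0) {
      while (st_next < nst && st_time[st_next] <= t) {
        int j = st_neuron[st_next];
        if (st_comp[st_next] == 0) {
          sxr_s[j] += st_w[st_next]; sxd_s[j] += st_w[st_next];
        } else {
          sxr_a[j] += st_w[st_next]; sxd_a[j] += st_w[st_next];
        }
        ++st_next;
      }
      for (int i = 0; i < n; ++i) {
        sxr_s[i] *= st_er; sxd_s[i] *= st_ed;
        sxr_a[i] *= st_er; sxd_a[i] *= st_ed;
        double gs = st_norm * (sxd_s[i] - sxr_s[i]);
        if (gs != 0.0) { gsum_s[i] += gs; gEsum_s[i] += gs * st_E; }
        double ga = st_norm * (sxd_a[i] - sxr_a[i]);
        if (ga != 0.0) { gsum_a[i] += ga; gEsum_a[i] += ga * st_E; }
      }
    }

    for (int i = 0; i < n; ++i) {
      // OU background (exact update, clipped at 0 when applied)
      ou_s[i] = ou_mean_s[i] + (ou_s[i] - ou_mean_s[i]) * e_ou +
                ou_sd_s[i] * s_ou * norm_rand();
      double gou_s = ou_s[i] > 0.0 ? ou_s[i] : 0.0;
      double gou_a = 0.0;
      if (two_comp[i]) {
        ou_a[i] = ou_mean_a[i] + (ou_a[i] - ou_mean_a[i]) * e_ou +
                  ou_sd_a[i] * s_ou * norm_rand();
        gou_a = ou_a[i] > 0.0 ? ou_a[i] : 0.0;
      }

      // adaptation decay
      if (tau_adapt[i] > 0.0) w[i] *= std::exp(-dt / tau_adapt[i]);

      double Vs_old = Vs[i], Va_old = Va[i];
      bool refractory = refr[i] > 0.0;

      if (two_comp[i]) {
        // apical compartment (never clamped); bap = spike-triggered
        // back-propagation conductance (excitatory, brief)
        if (bap_tau[i] > 0.0) bap[i] *= std::exp(-dt / bap_tau[i]);
        double rta = rect_factor(Va_old, Vhalf, krect, fmin);
        double gta = Gt_a[i] * rta;
        double gtot_a = gL_a[i] + gsum_a[i] + gou_a + gta + gc[i] + bap[i];
        double num_a = gL_a[i] * EL[i] + gEsum_a[i] + gou_a * E_exc +
                       gta * E_gaba + gc[i] * Vs_old + bap[i] * E_exc;
        double Vinf_a = num_a / gtot_a;
        Va[i] = Vinf_a + (Va_old - Vinf_a) * std::exp(-dt * gtot_a / Cm_a[i]);
      }

      if (refractory) {
        refr[i] -= dt;
        Vs[i] = Vreset[i];
      } else {
        double rts = rect_factor(Vs_old, Vhalf, krect, fmin);
        double gts = Gt_s[i] * rts;
        double gtot_s = gL_s[i] + gsum_s[i] + gou_s + gts;
        double num_s = gL_s[i] * EL[i] + gEsum_s[i] + gou_s * E_exc +
                       gts * E_gaba - w[i];
        if (two_comp[i]) {
          gtot_s += gc[i];
          num_s += gc[i] * Va_old;
        }
        double Vinf_s = num_s / gtot_s;
        Vs[i] = Vinf_s + (Vs_old - Vinf_s) * std::exp(-dt * gtot_s / Cm_s[i]);

        if (!std::isfinite(Vs[i]) || (two_comp[i] && !std::isfinite(Va[i])))
          stop("numeric blow-up at neuron %d, t = %.3f ms", i + 1, t);

        if (Vs[i] >= Vth[i]) {
          double tspike = t + dt;
          sp_id.push_back(i + 1);
          sp_t.push_back(tspike);
          Vs[i] = Vreset[i];
          refr[i] = tref[i];
          w[i] += w_adapt[i];
          if (two_comp[i]) bap[i] += bap_g[i];
          for (int c = 0; c < nc; ++c) {
            int lo = cls_ptr[c][i], hi = cls_ptr[c][i + 1];
            for (int e = lo; e < hi; ++e) {
              int k = cls_tgt[c][e];
              xr[c][k] += cls_w[c];
              xd[c][k] += cls_w[c];
            }
          }
        }
      }
    }

    if (record_mode > 0 && (step + 1) % record_every == 0 && irec < nrec) {
      if (record_mode == 1) {
        double s = 0.0;
        for (int q = 0; q < npyr; ++q) {
          int i = pyr_idx[q];
          s += gc[i] * (Va[i] - Vs[i]);
        }
        ax_sum[irec] = s;
      } else {
        for (int q = 0; q < npyr; ++q) {
          int i = pyr_idx[q];
          ax_mat(q, irec) = gc[i] * (Va[i] - Vs[i]);
        }
      }
      ++irec;
    }
  }

  List out = List::create(
      _["spike_id"] = wrap(sp_id), _["spike_t"] = wrap(sp_t),
      _["nrec"] = nrec);
  if (record_mode == 1) out["axial"] = ax_sum;
  if (record_mode == 2) out["axial"] = ax_mat;
  return out;
}
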