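// Recurrent-network trial engine: a population of two-compartment spike-trace
// neurons sharing an afferent stream, with plastic afferent and recurrent
// synapses under the same rule as the single-neuron engine. Presynaptic pool
// per cell = [afferent units, network cells]; a spike detected at step k
// reaches recurrent targets at step k+1 (one grid step, 0.1 ms).
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double zeta_n(double wabs, double phiz, double tauz) {
  if (wabs < phiz) return 0.0;
  double x = (wabs - phiz) / tauz;
  return x * std::exp(-(x - 1.0));
}

static inline double dexp_norm_n(double tr, double td) {
  double tp = td * tr / (td - tr) * std::log(td / tr);
  return std::exp(-tp / td) - std::exp(-tp / tr);
}

// [[Rcpp::export]]
List sim_network_cpp(IntegerVector sp_step, IntegerVector sp_unit,
                     IntegerVector aff_sign, int n_steps, double dt,
                     NumericMatrix W0, LogicalMatrix mask, int n_exc_cells,
                     NumericVector c_s_vec, NumericVector c_d_vec,
                     List np, List pp, bool plastic,
                     NumericVector kappa0_e, NumericVector kappa0_i,
                     double runaway_cap_hz) {
  const int n_cells = W0.nrow(), n_pre = W0.ncol(), n_aff = aff_sign.size();
  if (n_pre != n_aff + n_cells) stop("W0 must have n_aff + n_cells columns");
  const double g_ls = np["g_ls"], v_ls = np["v_ls"], v_th = np["v_th"],
               v_re = np["v_re"], t_ref = np["t_ref"], g_ld = np["g_ld"],
               v_ld = np["v_ld"], v_er = np["v_er"], v_ir = np["v_ir"],
               gbar_e = np["gbar_e"], gbar_i = np["gbar_i"], rho = np["rho"],
               g_cds = np["g_cds"], g_csdr = np["g_csdr"], m_csd = np["m_csd"];
  const double te_r = np["tau_e_rise"], te_d = np["tau_e_decay"],
               ti_r = np["tau_i_rise"], ti_d = np["tau_i_decay"],
               tc_r = np["tau_csd_rise"], tc_d = np["tau_csd_decay"];
  const double tau_y = pp["tau_y"], tau_ybar = pp["tau_ybar"],
               tau_p = pp["tau_p"], phi_z = pp["phi_zeta"],
               tau_z = pp["tau_zeta"], eta = pp["eta"],
               tau_delta = pp["tau_delta"], t_kappa = pp["t_kappa"];
  const int stride = as<int>(pp["plasticity_stride"]);
  const int kappa_steps = (int)std::lround(t_kappa / dt);
  const int tref_steps = (int)std::lround(t_ref / dt);
  const double de_d = std::exp(-dt / te_d), de_r = std::exp(-dt / te_r),
               di_d = std::exp(-dt / ti_d), di_r = std::exp(-dt / ti_r),
               dc_d = std::exp(-dt / tc_d), dc_r = std::exp(-dt / tc_r);
  const double ne = dexp_norm_n(te_r, te_d), ni = dexp_norm_n(ti_r, ti_d),
               nc = dexp_norm_n(tc_r, tc_d);
  const double sdt = stride * dt, psp_decay = std::exp(-sdt / tau_p),
               y_decay = std::exp(-dt / tau_y);

  // presynaptic Dale sign over the pooled columns
  std::vector<int> pre_sign(n_pre);
  for (int j = 0; j < n_aff; ++j) pre_sign[j] = aff_sign[j];
  for (int j = 0; j < n_cells; ++j) pre_sign[n_aff + j] = j < n_exc_cells ? 1 : -1;

  // per-cell state
  std::vector<double> v_s(n_cells, v_ls), v_d(n_cells, v_ld),
      Y(n_cells, 0.0), Ybar(n_cells, 0.0),
      xe_d(n_cells, 0.0), xe_r(n_cells, 0.0), xi_d(n_cells, 0.0),
      xi_r(n_cells, 0.0), xc_d(n_cells, 0.0), xc_r(n_cells, 0.0),
      kap_e(kappa0_e.begin(), kappa0_e.end()),
      kap_i(kappa0_i.begin(), kappa0_i.end()),
      th_e(n_cells, 0.0), th_i(n_cells, 0.0),
      acc_e(n_cells, 0.0), acc_i(n_cells, 0.0);
  std::vector<int> refrac(n_cells, 0);
  std::vector<double> W(W0.begin(), W0.end()),
      psp(n_cells * (size_t)n_pre, 0.0), dw(n_cells * (size_t)n_pre, 0.0);
  std::vector<double> psp_cnt(n_pre, 0.0); // presynaptic spike counts per stride
  std::vector<char> msk(n_cells * (size_t)n_pre);
  for (size_t i = 0; i < msk.size(); ++i) msk[i] = mask[i] ? 1 : 0;
  for (int c = 0; c < n_cells; ++c)
    for (int j = 0; j < n_pre; ++j) {
      double a = std::fabs(W[c + (size_t)j * n_cells]);
      if (pre_sign[j] > 0) th_e[c] += a; else th_i[c] += a;
    }

  std::vector<int> out_step, out_cell;
  std::vector<char> spiked_prev(n_cells, 0);
  double min_kappa = R_PosInf;
  for (int c = 0; c < n_cells; ++c) {
    if (kap_e[c] < min_kappa) min_kappa = kap_e[c];
    if (kap_i[c] < min_kappa) min_kappa = kap_i[c];
  }
  // runaway detection over 500 ms windows
  const int win_steps = (int)std::lround(500.0 / dt);
  int win_count = 0;
  RNGScope scope;
  const int n_ev = sp_step.size();
  int ev = 0;

  for (int k = 1; k <= n_steps; ++k) {
    std::fill(acc_e.begin(), acc_e.end(), 0.0);
    std::fill(acc_i.begin(), acc_i.end(), 0.0);
    // afferent spikes of this step
    while (ev < n_ev && sp_step[ev] == k) {
      int j = sp_unit[ev] - 1;
      psp_cnt[j] += 1.0;
      if (pre_sign[j] > 0)
        for (int c = 0; c < n_cells; ++c)
          acc_e[c] += kap_e[c] * std::fabs(W[c + (size_t)j * n_cells]);
      else
        for (int c = 0; c < n_cells; ++c)
          acc_i[c] += kap_i[c] * std::fabs(W[c + (size_t)j * n_cells]);
      ++ev;
    }
    // recurrent spikes from the previous step
    for (int s = 0; s < n_cells; ++s) {
      if (!spiked_prev[s]) continue;
      int j = n_aff + s;
      psp_cnt[j] += 1.0;
      if (pre_sign[j] > 0)
        for (int c = 0; c < n_cells; ++c)
          acc_e[c] += kap_e[c] * std::fabs(W[c + (size_t)j * n_cells]);
      else
        for (int c = 0; c < n_cells; ++c)
          acc_i[c] += kap_i[c] * std::fabs(W[c + (size_t)j * n_cells]);
    }
    int spikes_this_step = 0;
    for (int c = 0; c < n_cells; ++c) {
      xe_d[c] = xe_d[c] * de_d + acc_e[c]; xe_r[c] = xe_r[c] * de_r + acc_e[c];
      xi_d[c] = xi_d[c] * di_d + acc_i[c]; xi_r[c] = xi_r[c] * di_r + acc_i[c];
      xc_d[c] *= dc_d; xc_r[c] *= dc_r;
      bool refr_now = refrac[c] > 0;
      double g_e = gbar_e * (xe_d[c] - xe_r[c]) / ne;
      double g_i = gbar_i * (xi_d[c] - xi_r[c]) / ni;
      double gc = refr_now ? (g_csdr + (xc_d[c] - xc_r[c]) / nc) : g_csdr;
      // exponential-Euler membrane update: unconditionally stable for the
      // large conductance transients of small-capacitance inhibitory cells
      double g_tot = g_ld + g_e + g_i + gc;
      double v_inf = (g_ld * v_ld + g_e * v_er + g_i * v_ir + gc * v_s[c]) / g_tot;
      double v_d_new = v_inf + (v_d[c] - v_inf) * std::exp(-dt * g_tot / c_d_vec[c]);
      if (rho > 0) v_d_new += rho * std::sqrt(dt) * R::norm_rand() / c_d_vec[c];
      bool sp = false;
      if (refrac[c] > 0) {
        --refrac[c];
      } else {
        double gs_tot = g_cds + g_ls;
        double vs_inf = (g_cds * v_d[c] + g_ls * v_ls) / gs_tot;
        v_s[c] = vs_inf + (v_s[c] - vs_inf) * std::exp(-dt * gs_tot / c_s_vec[c]);
        if (v_s[c] > v_th) {
          sp = true; v_s[c] = v_re; refrac[c] = tref_steps;
          xc_d[c] += m_csd; xc_r[c] += m_csd;
          out_step.push_back(k); out_cell.push_back(c + 1);
          ++spikes_this_step;
        }
      }
      v_d[c] = v_d_new;
      if (!std::isfinite(v_d[c]) || !std::isfinite(v_s[c]))
        stop("numerical divergence in cell %d at step %d", c + 1, k);
      spiked_prev[c] = sp ? 1 : 0;
      Y[c] = Y[c] * y_decay + (sp ? 1.0 : 0.0);
      Ybar[c] += dt * (Y[c] - Ybar[c]) / tau_ybar;
    }
    win_count += spikes_this_step;
    if (k % win_steps == 0) {
      double pop_rate = win_count / (0.5 * n_cells);
      if (pop_rate > runaway_cap_hz)
        stop("population runaway: mean rate %.1f Hz > cap %.1f Hz at %.0f ms",
             pop_rate, runaway_cap_hz, k * dt);
      win_count = 0;
    }
    if (k % stride == 0) {
      if (plastic) {
        for (int c = 0; c < n_cells; ++c) {
          double e_sig = Y[c] - Ybar[c];
          bool active = std::fabs(e_sig) > 1e-10;
          for (int j = 0; j < n_pre; ++j) {
            size_t idx = c + (size_t)j * n_cells;
            if (!msk[idx]) continue;
            double wj = W[idx];
            double ps = psp[idx] * psp_decay + psp_cnt[j] * wj / tau_p;
            psp[idx] = ps;
            double pi_ij = 0.0;
            if (active) {
              double ep = e_sig * ps;
              if (std::fabs(ep) > 1e-12)
                pi_ij = ep * zeta_n(std::fabs(wj), phi_z, tau_z);
            }
            double d = dw[idx] + sdt * (pi_ij - dw[idx]) / tau_delta;
            double prop = wj + eta * d * sdt;
            if (prop * pre_sign[j] < 0) d = 0.0;
            dw[idx] = d;
            W[idx] = wj + eta * d * sdt;
          }
        }
      }
      std::fill(psp_cnt.begin(), psp_cnt.end(), 0.0);
    }
    if (kappa_steps > 0 && k % kappa_steps == 0 && plastic) {
      for (int c = 0; c < n_cells; ++c) {
        double tse = 0.0, tsi = 0.0;
        for (int j = 0; j < n_pre; ++j) {
          double a = std::fabs(W[c + (size_t)j * n_cells]);
          if (pre_sign[j] > 0) tse += a; else tsi += a;
        }
        if (tse > 0) { kap_e[c] *= th_e[c] / tse; th_e[c] = tse; }
        if (tsi > 0) { kap_i[c] *= th_i[c] / tsi; th_i[c] = tsi; }
        if (kap_e[c] < min_kappa) min_kappa = kap_e[c];
        if (kap_i[c] < min_kappa) min_kappa = kap_i[c];
      }
    }
  }
  NumericMatrix W_out(n_cells, n_pre);
  std::copy(W.begin(), W.end(), W_out.begin());
  return List::create(_["spike_step"] = wrap(out_step),
                      _["spike_cell"] = wrap(out_cell),
                      _["W_final"] = W_out, _["min_kappa"] = min_kappa);
}
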