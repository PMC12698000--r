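// Single-neuron trial engine: forward-Euler membrane integration at dt with
// exponential-integrator updates for the linear filter states, replicating the
// pure-R steppers in R/neuron.R and R/plasticity.R operation-for-operation.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double zeta_c(double wabs, double phiz, double tauz) {
  if (wabs < phiz) return 0.0;
  double x = (wabs - phiz) / tauz;
  return x * std::exp(-(x - 1.0));
}

struct HvaRates { double m_inf, h_inf, tau_m, tau_h; };
static inline HvaRates hva_rates_c(double v) {
  double x = -27.0 - v;
  double ma = (std::fabs(x) < 1e-9) ? 0.055 * 3.8
                                    : 0.055 * x / (std::exp(x / 3.8) - 1.0);
  double mb = 0.94 * std::exp((-75.0 - v) / 17.0);
  double ha = 0.000457 * std::exp((-13.0 - v) / 50.0);
  double hb = 0.0065 / (std::exp((-v - 15.0) / 28.0) + 1.0);
  HvaRates r;
  r.m_inf = ma / (ma + mb); r.tau_m = 1.0 / (ma + mb);
  r.h_inf = ha / (ha + hb); r.tau_h = 1.0 / (ha + hb);
  return r;
}

static inline double dexp_norm(double tr, double td) {
  double tp = td * tr / (td - tr) * std::log(td / tr);
  return std::exp(-tp / td) - std::exp(-tp / tr);
}

// [[Rcpp::export]]
List sim_neuron_cpp(IntegerVector sp_step, IntegerVector sp_unit, int n_steps,
                    double dt, NumericVector w0, IntegerVector sgn,
                    LogicalVector nmda_mask, List np, List pp, int variant,
                    IntegerVector forced_steps, bool plastic, bool kappa_on,
                    int snap_stride, int rec_stride,
                    double kappa0_e = 1.0, double kappa0_i = 1.0) {
  const int n_units = w0.size();
  // neuron parameters
  const double c_s = np["c_s"], g_ls = np["g_ls"], g_lsr = np["g_lsr"],
               v_ls = np["v_ls"], v_th = np["v_th"], v_re = np["v_re"],
               v_peak = np["v_peak"], t_ref = np["t_ref"], c_d = np["c_d"],
               g_ld = np["g_ld"], v_ld = np["v_ld"], v_er = np["v_er"],
               v_ir = np["v_ir"], gbar_e = np["gbar_e"], gbar_i = np["gbar_i"],
               rho = np["rho"], g_cds = np["g_cds"], g_csdr = np["g_csdr"],
               m_csd = np["m_csd"], g_ca = np["g_ca"], v_ca = np["v_ca"],
               gbar_nmda = np["gbar_nmda"], v_nmda = np["v_nmda"],
               mg = np["mg"], f_ca = np["f_ca"];
  const double te_r = np["tau_e_rise"], te_d = np["tau_e_decay"],
               ti_r = np["tau_i_rise"], ti_d = np["tau_i_decay"],
               tc_r = np["tau_csd_rise"], tc_d = np["tau_csd_decay"],
               tn_r = np["tau_nmda_rise"], tn_d = np["tau_nmda_decay"];
  // plasticity parameters
  const double tau_y = pp["tau_y"], tau_ybar = pp["tau_ybar"], c0 = pp["c0"],
               phi_ca = pp["phi_ca"], tau_c = pp["tau_c"],
               tau_cbar = pp["tau_cbar"], tau_p = pp["tau_p"],
               phi_z = pp["phi_zeta"], tau_z = pp["tau_zeta"],
               eta = pp["eta"], tau_delta = pp["tau_delta"],
               t_kappa = pp["t_kappa"];
  const int stride = as<int>(pp["plasticity_stride"]);
  const int kappa_steps = (int)std::lround(t_kappa / dt);
  const int tref_steps = (int)std::lround(t_ref / dt);
  const bool calcium = variant != 0, nmdar = variant == 2;

  // precomputed decay factors and normalizations
  const double de_d = std::exp(-dt / te_d), de_r = std::exp(-dt / te_r),
               di_d = std::exp(-dt / ti_d), di_r = std::exp(-dt / ti_r),
               dc_d = std::exp(-dt / tc_d), dc_r = std::exp(-dt / tc_r),
               dn_d = std::exp(-dt / tn_d), dn_r = std::exp(-dt / tn_r);
  const double ne = dexp_norm(te_r, te_d), ni = dexp_norm(ti_r, ti_d),
               nc = dexp_norm(tc_r, tc_d), nn = dexp_norm(tn_r, tn_d);
  const double sdt = stride * dt, psp_decay = std::exp(-sdt / tau_p),
               y_decay = std::exp(-dt / tau_y);

  // states
  std::vector<double> w(w0.begin(), w0.end()), dw(n_units, 0.0),
      psp(n_units, 0.0), psp_acc(n_units, 0.0);
  double xe_d = 0, xe_r = 0, xi_d = 0, xi_r = 0, xc_d = 0, xc_r = 0,
         xn_d = 0, xn_r = 0;
  double v_s = v_ls, v_d = v_ld;
  int refrac = 0;
  double Y = 0, Ybar = 0;
  double C = c0, Cbar = c0, e_sig = 0;
  double m = 0, h = hva_rates_c(v_ld).h_inf;
  // homeostatic gains, one per synapse class (E / I) so that each class's
  // total displacement-weighted drive is preserved separately
  double kappa_e = kappa0_e, kappa_i = kappa0_i, theta_e = 0.0, theta_i = 0.0;
  for (int i = 0; i < n_units; ++i) {
    if (sgn[i] > 0) theta_e += std::fabs(w[i]); else theta_i += std::fabs(w[i]);
  }

  // output buffers
  std::vector<int> spike_steps;
  int n_snap = snap_stride > 0 ? n_steps / snap_stride : 0;
  NumericMatrix W_snap(snap_stride > 0 ? n_units : 0, n_snap);
  IntegerVector snap_at(n_snap);
  int n_kap = kappa_steps > 0 ? n_steps / kappa_steps : 0;
  NumericVector kappa_series(n_kap), kappa_e_series(n_kap), kappa_i_series(n_kap);
  int n_rec = rec_stride > 0 ? n_steps / rec_stride : 0;
  NumericVector e_rec(n_rec), vs_rec(n_rec), vd_rec(n_rec);

  RNGScope scope;
  const int n_ev = sp_step.size();
  int ev = 0, fp = 0;
  const int n_forced = forced_steps.size();

  for (int k = 1; k <= n_steps; ++k) {
    // 1. gather impulses
    double ae = 0, ai = 0, an = 0;
    while (ev < n_ev && sp_step[ev] == k) {
      int u = sp_unit[ev] - 1;
      if (sgn[u] > 0) {
        double aw = kappa_e * std::fabs(w[u]);
        ae += aw;
        if (nmdar && nmda_mask[u]) an += aw;
      } else ai += kappa_i * std::fabs(w[u]);
      psp_acc[u] += w[u];
      ++ev;
    }
    // 2. conductance filters
    xe_d = xe_d * de_d + ae; xe_r = xe_r * de_r + ae;
    xi_d = xi_d * di_d + ai; xi_r = xi_r * di_r + ai;
    bool refr_now = refrac > 0;
    xc_d *= dc_d; xc_r *= dc_r;
    double g_csd = g_csdr + (xc_d - xc_r) / nc;
    double i_ca = 0, i_nmda = 0, i_ca_total = 0;
    if (calcium) {
      HvaRates r = hva_rates_c(v_d);
      m += dt * (r.m_inf - m) / r.tau_m;
      h += dt * (r.h_inf - h) / r.tau_h;
      if (m < 0) m = 0; else if (m > 1) m = 1;
      if (h < 0) h = 0; else if (h > 1) h = 1;
      i_ca = g_ca * m * m * h * (v_ca - v_d);
      i_ca_total = i_ca;
      if (nmdar) {
        xn_d = xn_d * dn_d + an; xn_r = xn_r * dn_r + an;
        double g_n = gbar_nmda * (xn_d - xn_r) / nn;
        double drive = g_n * (v_nmda - v_d) /
                       (1.0 + mg / 3.57 * std::exp(-0.062 * v_d));
        i_nmda = drive * (1.0 - f_ca);
        i_ca_total += drive * f_ca;
      }
    }
    // 3. dendrite (synchronous Euler: uses pre-update v_s)
    double g_e = gbar_e * (xe_d - xe_r) / ne;
    double g_i = gbar_i * (xi_d - xi_r) / ni;
    double gc = refr_now ? g_csd : g_csdr;
    double dv = (g_ld * (v_ld - v_d) + g_e * (v_er - v_d) + g_i * (v_ir - v_d) +
                 gc * (v_s - v_d) + i_ca + i_nmda) / c_d;
    double v_d_new = v_d + dt * dv;
    if (rho > 0) v_d_new += rho * std::sqrt(dt) * R::norm_rand() / c_d;
    // 4. soma
    bool spiked = false;
    if (refrac > 0) {
      if (calcium) v_s += dt * g_lsr * (v_ls - v_s) / c_s;
      --refrac;
    } else {
      v_s += dt * (g_cds * (v_d - v_s) + g_ls * (v_ls - v_s)) / c_s;
      bool force = false;
      while (fp < n_forced && forced_steps[fp] < k) ++fp;
      if (fp < n_forced && forced_steps[fp] == k) { force = true; ++fp; }
      if (v_s > v_th || force) {
        spiked = true;
        v_s = calcium ? v_peak : v_re;
        refrac = tref_steps;
      }
    }
    v_d = v_d_new;
    if (!std::isfinite(v_d) || !std::isfinite(v_s))
      stop("numerical divergence in membrane potential at step %d", k);
    if (spiked) {
      spike_steps.push_back(k);
      xc_d += m_csd; xc_r += m_csd; // bAP pulse into the coupling filter
    }
    // 5. plasticity traces
    if (calcium) {
      C += dt * (phi_ca * i_ca_total - (C - c0) / tau_c);
      Cbar += dt * (C - Cbar) / tau_cbar;
      e_sig = C - Cbar;
    } else {
      Y = Y * y_decay + (spiked ? 1.0 : 0.0);
      Ybar += dt * (Y - Ybar) / tau_ybar;
      e_sig = Y - Ybar;
    }
    // 6. plasticity substep
    if (k % stride == 0) {
      if (plastic) {
        for (int i = 0; i < n_units; ++i) {
          double ps = psp[i] * psp_decay + psp_acc[i] / tau_p;
          psp[i] = ps; psp_acc[i] = 0.0;
          double pi_i = 0.0;
          double ep = e_sig * ps;
          if (std::fabs(ep) > 1e-12)
            pi_i = ep * zeta_c(std::fabs(w[i]), phi_z, tau_z);
          double d = dw[i] + sdt * (pi_i - dw[i]) / tau_delta;
          double prop = w[i] + eta * d * sdt;
          if (prop * sgn[i] < 0) d = 0.0;
          dw[i] = d;
          w[i] += eta * d * sdt;
        }
      } else {
        for (int i = 0; i < n_units; ++i) psp_acc[i] = 0.0;
      }
    }
    // 7. homeostatic rescale
    if (kappa_steps > 0 && k % kappa_steps == 0) {
      if (kappa_on && plastic) {
        double tse = 0.0, tsi = 0.0;
        for (int i = 0; i < n_units; ++i) {
          if (sgn[i] > 0) tse += std::fabs(w[i]); else tsi += std::fabs(w[i]);
        }
        if (tse > 0) { kappa_e *= theta_e / tse; theta_e = tse; }
        if (tsi > 0) { kappa_i *= theta_i / tsi; theta_i = tsi; }
      }
      kappa_series[k / kappa_steps - 1] = std::min(kappa_e, kappa_i);
      kappa_e_series[k / kappa_steps - 1] = kappa_e;
      kappa_i_series[k / kappa_steps - 1] = kappa_i;
    }
    // 8. recording
    if (snap_stride > 0 && k % snap_stride == 0) {
      int j = k / snap_stride - 1;
      for (int i = 0; i < n_units; ++i) W_snap(i, j) = w[i];
      snap_at[j] = k;
    }
    if (rec_stride > 0 && k % rec_stride == 0) {
      int j = k / rec_stride - 1;
      e_rec[j] = e_sig; vs_rec[j] = v_s; vd_rec[j] = v_d;
    }
  }

  double min_kappa = std::min(kappa0_e, kappa0_i);
  for (int j = 0; j < n_kap; ++j)
    if (kappa_series[j] < min_kappa) min_kappa = kappa_series[j];
  return List::create(
      _["spike_steps"] = wrap(spike_steps), _["w"] = wrap(w),
      _["W_snap"] = W_snap, _["snap_steps"] = snap_at,
      _["kappa_series"] = kappa_series, _["kappa_e_series"] = kappa_e_series,
      _["kappa_i_series"] = kappa_i_series, _["min_kappa"] = min_kappa,
      _["e_rec"] = e_rec, _["vs_rec"] = vs_rec, _["vd_rec"] = vd_rec);
}
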