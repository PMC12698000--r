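# Two-compartment membrane machinery: somatic and dendritic compartments,
# double-exponential conductance channels, HVA-Ca2+ and NMDAR channels, and the
# spike-triggered transient somato-dendritic coupling boost.

#' Default neuron parameters
#'
#' Units: mV, ms, nS, pF, pA throughout, so membrane equations integrate in
#' mV/ms without conversion factors. All values are calibrated defaults chosen
#' within hippocampal/cortical pyramidal-cell literature ranges (provenance
#' "calibrated").
#'
#' Somatic fields: `c_s` capacitance, `g_ls` leak, `g_lsr` refractory leak
#' (calcium variants, >> `g_ls`), `v_ls` leak reversal, `v_th` threshold,
#' `v_re` reset, `v_peak` spike peak (calcium variants), `t_ref` refractory
#' period (ms, within 2-3). Dendritic fields: `c_d`, `g_ld`, `v_ld`, reversals
#' `v_er`/`v_ir`, peak conductances `gbar_e`/`gbar_i`, rise/decay constants per
#' channel, membrane-noise amplitude `rho` (pA sqrt(ms), 0 = off). Coupling:
#' `g_cds` dendrite-to-soma (zeroed during refractoriness), `g_csdr` resting
#' soma-to-dendrite, `m_csd` bAP pulse amplitude, `tau_csd_rise`/`tau_csd_decay`
#' the pulse shape. HVA channel: `g_ca`, `v_ca`. NMDAR: `gbar_nmda`,
#' `tau_nmda_rise`/`tau_nmda_decay` (Q10-corrected), `v_nmda`, `mg`
#' concentration (mM), `f_ca` calcium fraction, `nmda_frac` fraction of
#' excitatory synapses carrying NMDARs.
#'
#' @param variant One of `"spike_trace"`, `"calcium"`, `"calcium_nmdar"`.
#' @param ... Overrides for individual fields.
#' @return A named list of parameters with a `variant` field.
#' @export
neuron_params <- function(variant = c("spike_trace", "calcium", "calcium_nmdar"),
                          ...) {
  variant <- match.arg(variant)
  p <- list(
    variant = variant,
    c_s = 200, g_ls = 10, g_lsr = 250, v_ls = -70, v_th = -59, v_re = -60,
    v_peak = 30, t_ref = 2,
    c_d = 170, g_ld = 10, v_ld = -70, v_er = 0, v_ir = -80,
    gbar_e = 2, gbar_i = 2.5,
    tau_e_rise = 0.5, tau_e_decay = 3, tau_i_rise = 0.5, tau_i_decay = 8,
    rho = 0,
    g_cds = 25, g_csdr = 2,
    m_csd = if (variant == "spike_trace") 0 else 60,
    tau_csd_rise = 0.2, tau_csd_decay = 1.2,
    g_ca = 8, v_ca = 120,
    gbar_nmda = 0.05, tau_nmda_rise = 3.3, tau_nmda_decay = 102.38,
    v_nmda = 0, mg = 1, f_ca = 0.05, nmda_frac = 0.75)
  ov <- list(...)
  unknown <- setdiff(names(ov), names(p))
  if (length(unknown) > 0) stop("unknown neuron parameter(s): ",
                                paste(unknown, collapse = ", "))
  p[names(ov)] <- ov
  stopifnot(p$t_ref >= 2, p$t_ref <= 3, p$v_re < p$v_th, p$v_th < p$v_peak,
            p$tau_e_rise < p$tau_e_decay, p$tau_i_rise < p$tau_i_decay,
            p$v_ir < p$v_ld, p$v_ld < p$v_er,
            p$m_csd >= 0, p$g_csdr >= 0, p$mg >= 0,
            p$f_ca >= 0, p$f_ca <= 1)
  if (variant %in% c("calcium", "calcium_nmdar") && p$g_lsr <= 5 * p$g_ls)
    warning("g_lsr should greatly exceed g_ls in the calcium variants")
  p
}

#' Peak time of a normalized double-exponential filter
#'
#' Closed form `t_peak = tau_d * tau_r / (tau_d - tau_r) * log(tau_d / tau_r)`.
#'
#' @param tau_rise,tau_decay Rise and decay constants, ms (must differ).
#' @return Peak time, ms.
#' @export
double_exp_peak_time <- function(tau_rise, tau_decay) {
  if (tau_rise == tau_decay)
    stop("tau_rise must differ from tau_decay (alpha-function limit unsupported)")
  tau_decay * tau_rise / (tau_decay - tau_rise) * log(tau_decay / tau_rise)
}

# Normalization so a unit impulse drives the filter to peak exactly 1.
double_exp_norm <- function(tau_rise, tau_decay) {
  tp <- double_exp_peak_time(tau_rise, tau_decay)
  exp(-tp / tau_decay) - exp(-tp / tau_rise)
}

#' Initialize a double-exponential conductance state
#'
#' @param tau_rise,tau_decay Filter time constants, ms.
#' @return A `double_exp_state` list with the two exponential states and the
#'   precomputed peak-normalization constant.
#' @export
double_exp_state <- function(tau_rise, tau_decay) {
  list(xi_decay = 0, xi_rise = 0,
       tau_rise = tau_rise, tau_decay = tau_decay,
       norm = double_exp_norm(tau_rise, tau_decay))
}

#' Step a double-exponential conductance filter
#'
#' Both exponentials decay (exact exponential update) and receive the summed
#' impulse input of this step. The filter output
#' `F = (xi_decay - xi_rise) / norm` is normalized so that a single unit
#' impulse peaks at exactly 1, `t_peak` after the impulse. The filter is
#' linear: responses to summed impulse trains superpose.
#'
#' @param state A `double_exp_state`.
#' @param impulse Summed impulse input this step (e.g. `kappa * sum(|w|)` over
#'   arriving spikes, or `m_csd` at a somatic spike).
#' @param dt Step, ms.
#' @return Updated state; read the output with [double_exp_value()].
#' @export
step_conductance <- function(state, impulse, dt) {
  state$xi_decay <- state$xi_decay * exp(-dt / state$tau_decay) + impulse
  state$xi_rise <- state$xi_rise * exp(-dt / state$tau_rise) + impulse
  state
}

#' @rdname step_conductance
#' @export
double_exp_value <- function(state) {
  (state$xi_decay - state$xi_rise) / state$norm
}

#' HVA-Ca2+ channel rate functions
#'
#' Voltage-dependent forward/backward rates of the high-voltage-activated
#' calcium channel with m^2 h kinetics:
#' `m_alpha = 0.055 (-27 - V) / (exp((-27 - V)/3.8) - 1)` (analytic limit
#' `0.055 * 3.8` at `V = -27`), `m_beta = 0.94 exp((-75 - V)/17)`,
#' `h_alpha = 0.000457 exp((-13 - V)/50)`,
#' `h_beta = 0.0065 / (exp((-V - 15)/28) + 1)`, with the derived steady states
#' `x_inf = x_alpha / (x_alpha + x_beta)` and `tau_x = 1 / (x_alpha + x_beta)`.
#'
#' @param v_d Dendritic potential, mV (scalar or vector).
#' @return List with `m_alpha`, `m_beta`, `h_alpha`, `h_beta`, `m_inf`,
#'   `h_inf`, `tau_m`, `tau_h`.
#' @export
hva_rates <- function(v_d) {
  x <- -27 - v_d
  m_alpha <- ifelse(abs(x) < 1e-9, 0.055 * 3.8, 0.055 * x / (exp(x / 3.8) - 1))
  m_beta <- 0.94 * exp((-75 - v_d) / 17)
  h_alpha <- 0.000457 * exp((-13 - v_d) / 50)
  h_beta <- 0.0065 / (exp((-v_d - 15) / 28) + 1)
  list(m_alpha = m_alpha, m_beta = m_beta, h_alpha = h_alpha, h_beta = h_beta,
       m_inf = m_alpha / (m_alpha + m_beta), h_inf = h_alpha / (h_alpha + h_beta),
       tau_m = 1 / (m_alpha + m_beta), tau_h = 1 / (h_alpha + h_beta))
}

#' Step the HVA-Ca2+ gates and read the calcium current
#'
#' Forward-Euler relaxation of the gates towards their voltage-dependent steady
#' states, then `I_Ca = g_ca * m^2 * h * (v_ca - v_d)` (inward/depolarizing for
#' `v_d < v_ca`). Gates leaving `[0, 1]` beyond tolerance are clamped with a
#' warning.
#'
#' @param state List with gates `m`, `h`.
#' @param v_d Dendritic potential, mV.
#' @param dt Step, ms.
#' @param p Neuron parameters (uses `g_ca`, `v_ca`).
#' @return List with updated `m`, `h` and the current `i_ca` (pA).
#' @export
step_hva <- function(state, v_d, dt, p) {
  r <- hva_rates(v_d)
  m <- state$m + dt * (r$m_inf - state$m) / r$tau_m
  h <- state$h + dt * (r$h_inf - state$h) / r$tau_h
  if (m < -1e-6 || m > 1 + 1e-6 || h < -1e-6 || h > 1 + 1e-6)
    warning("HVA gate left [0, 1]; clamping")
  m <- min(max(m, 0), 1); h <- min(max(h, 0), 1)
  list(m = m, h = h, i_ca = p$g_ca * m^2 * h * (p$v_ca - v_d))
}

#' Magnesium-block voltage dependence of the NMDAR
#'
#' `MgB(V) = 1 / (1 + [Mg]/3.57 * exp(-0.062 V))`: fully blocked at
#' hyperpolarization, fully open (`MgB -> 1`) at strong depolarization or
#' `Mg = 0`.
#'
#' @param v Membrane potential, mV.
#' @param mg Magnesium concentration, mM.
#' @return Unblocked fraction in `(0, 1]`.
#' @export
nmda_mgb <- function(v, mg) {
  1 / (1 + mg / 3.57 * exp(-0.062 * v))
}

#' NMDAR currents
#'
#' The NMDAR conductance (a double-exponential filter over the NMDA-carrying
#' excitatory impulses) splits into a nonspecific current and a calcium
#' current: `I_NMDA = g * MgB * (v_nmda - v_d) * (1 - f_ca)` and
#' `I_Ca,nmda = g * MgB * (v_nmda - v_d) * f_ca`, the latter added to the HVA
#' calcium current before integration into the calcium trace.
#'
#' @param v_d Dendritic potential, mV.
#' @param g_nmda Instantaneous NMDAR conductance, nS.
#' @param p Neuron parameters (uses `mg`, `f_ca`, `v_nmda`).
#' @return List with `i_nmda` and `i_ca_nmda` (pA).
#' @export
nmda_currents <- function(v_d, g_nmda, p) {
  drive <- g_nmda * nmda_mgb(v_d, p$mg) * (p$v_nmda - v_d)
  list(i_nmda = drive * (1 - p$f_ca), i_ca_nmda = drive * p$f_ca)
}

#' Step the transient somato-dendritic coupling
#'
#' On every somatic spike both coupling exponentials receive the bAP pulse
#' `m_csd`, so `g_csd = g_csdr + F_csd(t)` rises to `g_csdr + m_csd` at the
#' pulse peak time and relaxes back to the resting value `g_csdr`. The
#' soma-to-dendrite current uses the boosted `g_csd` during refractory states
#' and the resting `g_csdr` otherwise; the dendrite-to-soma conductance
#' `g_cds` is zeroed during refractoriness.
#'
#' @param state A `double_exp_state` for the coupling pulse.
#' @param spiked Logical: somatic spike this step?
#' @param dt Step, ms.
#' @param p Neuron parameters.
#' @return List with updated `state` and the boosted conductance `g_csd`.
#' @export
step_coupling <- function(state, spiked, dt, p) {
  state <- step_conductance(state, if (isTRUE(spiked)) p$m_csd else 0, dt)
  list(state = state, g_csd = p$g_csdr + double_exp_value(state))
}

#' Step the somatic compartment
#'
#' Outside refractoriness `dVs/dt = (g_cds (Vd - Vs) + g_ls (Vls - Vs)) / Cs`.
#' On threshold crossing the spike-trace variant resets to `v_re` and halts
#' integration for `t_ref`; the calcium variants jump to `v_peak` within the
#' step and then hyperpolarize under the strong refractory leak `g_lsr` with
#' all dendritic/synaptic input to the soma gated off.
#'
#' @param state List with `v_s` and `refrac` (remaining refractory steps).
#' @param v_d Dendritic potential, mV.
#' @param dt Step, ms.
#' @param p Neuron parameters.
#' @param force_spike Force a threshold crossing this step (pairing protocols).
#' @return List with updated `v_s`, `refrac`, and `spiked`.
#' @export
step_soma <- function(state, v_d, dt, p, force_spike = FALSE) {
  if (!is.finite(state$v_s)) stop("numerical divergence in v_s")
  calcium <- p$variant != "spike_trace"
  v_s <- state$v_s; refrac <- state$refrac; spiked <- FALSE
  if (refrac > 0L) {
    if (calcium) v_s <- v_s + dt * p$g_lsr * (p$v_ls - v_s) / p$c_s
    refrac <- refrac - 1L
  } else {
    v_s <- v_s + dt * (p$g_cds * (v_d - v_s) + p$g_ls * (p$v_ls - v_s)) / p$c_s
    if (v_s > p$v_th || isTRUE(force_spike)) {
      spiked <- TRUE
      v_s <- if (calcium) p$v_peak else p$v_re
      refrac <- as.integer(round(p$t_ref / dt))
    }
  }
  list(v_s = v_s, refrac = refrac, spiked = spiked)
}

#' Step the dendritic compartment
#'
#' Forward-Euler update of the dendritic potential under leak, excitatory and
#' inhibitory conductances, the somato-dendritic coupling current (boosted
#' `g_csd` while the soma is refractory, resting `g_csdr` otherwise), the HVA
#' calcium current and the NMDAR current when enabled, plus optional Gaussian
#' membrane current noise of amplitude `rho`.
#'
#' @param v_d Dendritic potential, mV.
#' @param v_s Somatic potential, mV.
#' @param refractory Logical: soma currently refractory?
#' @param g_e,g_i Excitatory/inhibitory conductances, nS.
#' @param g_csd Boosted coupling conductance (from [step_coupling()]).
#' @param i_ca HVA calcium current, pA (0 for the spike-trace variant).
#' @param i_nmda NMDAR nonspecific current, pA.
#' @param dt Step, ms.
#' @param p Neuron parameters.
#' @param noise Optional pre-drawn standard-normal deviate for the noise term.
#' @return Updated `v_d`.
#' @export
step_dendrite <- function(v_d, v_s, refractory, g_e, g_i, g_csd,
                          i_ca = 0, i_nmda = 0, dt, p, noise = 0) {
  if (!is.finite(v_d)) stop("numerical divergence in v_d")
  gc <- if (refractory) g_csd else p$g_csdr
  i_csd <- gc * (v_s - v_d)
  dv <- (p$g_ld * (p$v_ld - v_d) + g_e * (p$v_er - v_d) + g_i * (p$v_ir - v_d) +
           i_csd + i_ca + i_nmda) / p$c_d
  v_d + dt * dv + p$rho * sqrt(dt) * noise / p$c_d
}

#' Pure-R reference simulation of a single two-compartment neuron
#'
#' Step-by-step reference implementation of the full closed loop (membrane,
#' channels, traces, plasticity, homeostasis) used to validate the compiled
#' engine on small fixtures. Slow: intended for short toy runs only.
#'
#' @param stream An `input_stream` (see [build_input_stream()]).
#' @param w0 Initial weight vector (length = number of input units).
#' @param np Neuron parameters ([neuron_params()]).
#' @param pp Plasticity parameters ([plasticity_params()]).
#' @param n_steps Number of membrane steps to simulate (defaults to the full
#'   stream).
#' @param record_stride Record membrane/trace series every this many steps.
#' @return List with `spike_steps`, `w`, `kappa_series`, `min_kappa`, and the
#'   recorded series `v_s`, `v_d`, `e`.
#' @export
simulate_neuron_r <- function(stream, w0, np, pp, n_steps = stream$n_steps,
                              record_stride = 10L) {
  dt <- stream$spec$dt
  n_units <- length(w0)
  sgn <- stream$sign
  nmda_mask <- rep(FALSE, n_units)
  if (np$variant == "calcium_nmdar") {
    exc <- which(sgn > 0)
    nmda_mask[sample(exc, round(np$nmda_frac * length(exc)))] <- TRUE
  }
  # states
  w <- w0; dwv <- numeric(n_units); psp <- numeric(n_units)
  se <- double_exp_state(np$tau_e_rise, np$tau_e_decay)
  si <- double_exp_state(np$tau_i_rise, np$tau_i_decay)
  sc <- double_exp_state(np$tau_csd_rise, np$tau_csd_decay)
  sn <- double_exp_state(np$tau_nmda_rise, np$tau_nmda_decay)
  soma <- list(v_s = np$v_ls, refrac = 0L)
  v_d <- np$v_ld
  tr <- list(Y = 0, Ybar = 0, C = pp$c0, Cbar = pp$c0, e = 0)
  hva <- list(m = 0, h = hva_rates(np$v_ld)$h_inf)
  exc_syn <- sgn > 0
  kap_e <- list(kappa = 1, theta = sum(abs(w0[exc_syn])))
  kap_i <- list(kappa = 1, theta = sum(abs(w0[!exc_syn])))
  stride <- pp$plasticity_stride
  kappa_steps <- as.integer(round(pp$t_kappa / dt))
  spike_steps <- integer(0)
  psp_acc <- numeric(n_units)
  nrec <- floor(n_steps / record_stride)
  rec <- list(v_s = numeric(nrec), v_d = numeric(nrec), e = numeric(nrec))
  kappa_series <- numeric(0)
  ev <- 1L # pointer into the sorted event stream
  calcium <- np$variant != "spike_trace"
  for (k in seq_len(n_steps)) {
    ae <- 0; ai <- 0; an <- 0
    while (ev <= length(stream$step) && stream$step[ev] == k) {
      u <- stream$unit[ev]
      if (sgn[u] > 0) {
        aw <- kap_e$kappa * abs(w[u])
        ae <- ae + aw
        if (nmda_mask[u]) an <- an + aw
      } else ai <- ai + kap_i$kappa * abs(w[u])
      psp_acc[u] <- psp_acc[u] + w[u]
      ev <- ev + 1L
    }
    se <- step_conductance(se, ae, dt)
    si <- step_conductance(si, ai, dt)
    refr_now <- soma$refrac > 0L
    cpl <- step_coupling(sc, FALSE, dt, np) # pulse injected at spike below
    sc <- cpl$state
    i_ca <- 0; i_nmda <- 0; i_ca_total <- 0
    if (calcium) {
      hv <- step_hva(hva, v_d, dt, np)
      hva <- list(m = hv$m, h = hv$h)
      i_ca <- hv$i_ca
      i_ca_total <- i_ca
      if (np$variant == "calcium_nmdar") {
        sn <- step_conductance(sn, an, dt)
        g_n <- np$gbar_nmda * double_exp_value(sn)
        nm <- nmda_currents(v_d, g_n, np)
        i_nmda <- nm$i_nmda
        i_ca_total <- i_ca_total + nm$i_ca_nmda
      }
    }
    g_e <- np$gbar_e * double_exp_value(se)
    g_i <- np$gbar_i * double_exp_value(si)
    v_d_new <- step_dendrite(v_d, soma$v_s, refr_now, g_e, g_i, cpl$g_csd,
                             i_ca, i_nmda, dt, np,
                             noise = if (np$rho > 0) stats::rnorm(1) else 0)
    soma <- step_soma(soma, v_d, dt, np)
    v_d <- v_d_new
    if (soma$spiked) {
      spike_steps <- c(spike_steps, k)
      sc <- step_conductance(sc, np$m_csd, 0) # impulse only, no extra decay
    }
    if (calcium) {
      tr2 <- step_calcium_trace(list(C = tr$C, Cbar = tr$Cbar), i_ca_total, dt, pp)
      tr$C <- tr2$C; tr$Cbar <- tr2$Cbar; tr$e <- tr2$e
    } else {
      tr2 <- step_spike_traces(list(Y = tr$Y, Ybar = tr$Ybar), soma$spiked, dt, pp)
      tr$Y <- tr2$Y; tr$Ybar <- tr2$Ybar; tr$e <- tr2$e
    }
    if (k %% stride == 0L) {
      sdt <- stride * dt
      psp <- step_psp(psp, psp_acc, sdt, pp)
      psp_acc[] <- 0
      piv <- plasticity_induction(tr$e, psp, w, pp)
      upd <- step_weight_update(w, dwv, piv, sgn, sdt, pp)
      w <- upd$w; dwv <- upd$dw
    }
    if (k %% kappa_steps == 0L) {
      kap_e <- homeostatic_rescale(w[exc_syn], kap_e)
      kap_i <- homeostatic_rescale(w[!exc_syn], kap_i)
      kappa_series <- c(kappa_series, min(kap_e$kappa, kap_i$kappa))
    }
    if (k %% record_stride == 0L) {
      j <- k %/% record_stride
      rec$v_s[j] <- soma$v_s; rec$v_d[j] <- v_d; rec$e[j] <- tr$e
    }
  }
  list(spike_steps = spike_steps, w = w,
       kappa_series = kappa_series,
       min_kappa = if (length(kappa_series)) min(kappa_series) else 1,
       v_s = rec$v_s, v_d = rec$v_d, e = rec$e)
}
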