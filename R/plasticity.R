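# The self-supervising plasticity rule: excitability traces, PSP traces, the
# alpha-function weight scaling, plasticity induction, eligibility dynamics and
# the Dale-sign clamp. These pure-R steppers define the discretization; the
# Rcpp trial engine replicates them exactly (asserted by tests).

#' Default plasticity parameters
#'
#' Time constants in ms. `tau_y`/`tau_ybar` govern the spike trace and its
#' low-pass average (spike-trace flavor); `c0`, `phi_ca`, `tau_c`, `tau_cbar`
#' the calcium trace flavor; `tau_p` the PSP trace; `phi_zeta`/`tau_zeta` the
#' alpha-function weight scaling; `eta` the learning rate and `tau_delta` the
#' eligibility filter. All values are calibrated defaults (provenance
#' "calibrated"): they reproduce tuning within a handful of pattern
#' presentations at the standard input scale.
#'
#' @param ... Overrides for individual fields.
#' @return A named list of parameters.
#' @export
plasticity_params <- function(...) {
  p <- list(tau_y = 12, tau_ybar = 250,
            c0 = 0.05, phi_ca = 1, tau_c = 12, tau_cbar = 250,
            tau_p = 12,
            phi_zeta = 0.2, tau_zeta = 3,
            eta = 0.5, tau_delta = 20,
            t_kappa = 100, plasticity_stride = 5L,
            drive_ref = sqrt(2 / pi))
  ov <- list(...)
  unknown <- setdiff(names(ov), names(p))
  if (length(unknown) > 0) stop("unknown plasticity parameter(s): ",
                                paste(unknown, collapse = ", "))
  p[names(ov)] <- ov
  stopifnot(p$tau_y > 0, p$tau_ybar > 0, p$tau_c > 0, p$tau_cbar > 0,
            p$tau_p > 0, p$tau_zeta > 0, p$eta > 0, p$tau_delta > 0)
  p
}

#' Step the postsynaptic spike traces
#'
#' `Y` jumps by 1 at each somatic spike and decays exponentially with `tau_y`
#' (exact exponential-integrator update); `Ybar` low-pass filters `Y` with
#' `tau_ybar` (forward Euler). The excitability signal is `e = Y - Ybar`.
#' Traces never feed back into the membrane equations.
#'
#' @param traces List with numeric `Y`, `Ybar`.
#' @param spiked Logical: did the soma spike this step?
#' @param dt Step, ms.
#' @param p Plasticity parameters.
#' @return Updated traces with `e` field.
#' @export
step_spike_traces <- function(traces, spiked, dt, p) {
  Y <- traces$Y * exp(-dt / p$tau_y) + as.numeric(spiked)
  Ybar <- traces$Ybar + dt * (Y - traces$Ybar) / p$tau_ybar
  list(Y = Y, Ybar = Ybar, e = Y - Ybar)
}

#' Step the calcium trace pair
#'
#' `dC/dt = phi_ca * I_Ca - (C - C0)/tau_c` (forward Euler); `Cbar` low-pass
#' filters `C` with `tau_cbar`. The calcium excitability signal is
#' `e_c = C - Cbar`.
#'
#' @param traces List with numeric `C`, `Cbar`.
#' @param i_ca Total calcium current this step (HVA + NMDAR fraction), pA.
#' @param dt Step, ms.
#' @param p Plasticity parameters.
#' @return Updated traces with `e` field.
#' @export
step_calcium_trace <- function(traces, i_ca, dt, p) {
  C <- traces$C + dt * (p$phi_ca * i_ca - (traces$C - p$c0) / p$tau_c)
  Cbar <- traces$Cbar + dt * (C - traces$Cbar) / p$tau_cbar
  list(C = C, Cbar = Cbar, e = C - Cbar)
}

#' Step the per-synapse PSP traces
#'
#' `tau_p * dPSP/dt = I(i, t) - PSP` with `I(i, t)` a train of weighted delta
#' impulses at presynaptic spike times: a spike through synapse `i` makes
#' `PSP_i` jump by `w_i / tau_p` (the Euler-consistent delta normalization);
#' between spikes PSP decays exponentially (exact update). Inhibitory synapses
#' (negative weight) produce negative PSP excursions.
#'
#' @param psp Numeric vector of PSP states.
#' @param impulse Numeric vector: summed presynaptic weight impulses this step
#'   (i.e. `w_i` times the number of spikes arriving at synapse `i`).
#' @param dt Step, ms.
#' @param p Plasticity parameters.
#' @return Updated PSP vector.
#' @export
step_psp <- function(psp, impulse, dt, p) {
  psp * exp(-dt / p$tau_p) + impulse / p$tau_p
}

#' Alpha-function weight scaling
#'
#' `zeta(x) = ((x - phi_zeta)/tau_zeta) * exp(-(x - phi_zeta - tau_zeta)/tau_zeta)`
#' for `x >= phi_zeta`, clipped to 0 below `phi_zeta`. Root at `phi_zeta`, peak
#' value 1 at `phi_zeta + tau_zeta`, decaying towards 0 for large magnitudes so
#' that strong synapses saturate: small weights are the most plastic.
#'
#' @param w_abs Nonnegative weight magnitudes.
#' @param p Plasticity parameters (uses `phi_zeta`, `tau_zeta`).
#' @return Scaling values in `[0, 1]`.
#' @export
zeta <- function(w_abs, p = plasticity_params()) {
  x <- (w_abs - p$phi_zeta) / p$tau_zeta
  out <- x * exp(-(x - 1))
  out[w_abs < p$phi_zeta] <- 0
  out
}

#' Plasticity induction
#'
#' `PI_i = e * PSP_i * zeta(|w_i|)`: the product of the postsynaptic
#' excitability signal (spike-trace or calcium flavor), the per-synapse PSP
#' trace, and the weight scaling.
#'
#' @param e Scalar excitability signal.
#' @param psp PSP vector.
#' @param w Weight vector.
#' @param p Plasticity parameters.
#' @return PI vector.
#' @export
plasticity_induction <- function(e, psp, w, p = plasticity_params()) {
  e * psp * zeta(abs(w), p)
}

#' Eligibility and weight update with the Dale clamp
#'
#' `tau_delta * d(dw)/dt = PI - dw` (forward Euler), then any eligibility whose
#' application `w + eta * dw * dt` would flip the synapse against its Dale
#' identity is zeroed, and finally `w <- w + eta * dw * dt`. A weight may decay
#' arbitrarily close to zero but never changes sign.
#'
#' @param w Weight vector.
#' @param dw Eligibility vector.
#' @param pi_vec Plasticity-induction vector.
#' @param sign Dale identity per synapse (+1 excitatory, -1 inhibitory).
#' @param dt Step, ms.
#' @param p Plasticity parameters.
#' @return List with updated `w` and `dw`.
#' @export
step_weight_update <- function(w, dw, pi_vec, sign, dt, p) {
  dw <- dw + dt * (pi_vec - dw) / p$tau_delta
  prop <- w + p$eta * dw * dt
  flip <- prop * sign < 0
  dw[flip] <- 0
  w <- w + p$eta * dw * dt
  list(w = w, dw = dw)
}

#' Homeostatic rescaling of the synaptic gain
#'
#' Every `t_kappa` ms the scalar gain `kappa` (which multiplies all weights at
#' conductance-integration time only, never mutating the stored weights) is
#' renormalized to preserve the overall synaptic displacement:
#' `kappa_new * sum|w|_now = kappa_old * sum|w|_ref`, after which the reference
#' displacement is advanced to the current one.
#'
#' @param weights Current stored weight vector.
#' @param state List with `kappa` (current gain) and `theta` (reference
#'   displacement `sum(|w|)` at the previous update).
#' @return Updated state.
#' @export
homeostatic_rescale <- function(weights, state) {
  theta_star <- sum(abs(weights))
  if (theta_star == 0) {
    warning("sum|w| = 0: skipping homeostatic update")
    return(state)
  }
  kappa <- state$kappa * state$theta / theta_star
  list(kappa = kappa, theta = theta_star)
}
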