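# Shared miniature fixtures and helpers; everything is generated in code.

toy_stream <- function(seed = 1) make_fixture("toy_stream", seed)

toy_trial_config <- function(seed = 1, dur = 2) {
  trial_config(
    input = input_stream_spec(n_exc = 20, n_inh = 20, rate = 30, t_pat = 100,
                              n_patterns = 2, community_size = 10,
                              trial_duration = dur, p_fail = 0.1),
    neuron = neuron_params("spike_trace", gbar_e = 20, gbar_i = 20),
    seed = seed)
}

# engine call with explicit defaults, for low-level tests
run_engine <- function(stream, w0, np, pp, variant = 0L, plastic = TRUE,
                       kappa_on = TRUE, forced = integer(0),
                       nmda_mask = rep(FALSE, length(w0)),
                       snap_stride = 1000L, rec_stride = 10L,
                       n_steps = stream$n_steps) {
  bapboost:::sim_neuron_cpp(stream$step, stream$unit, n_steps, stream$spec$dt,
                            w0, stream$sign, nmda_mask, np, pp, variant,
                            forced, plastic, kappa_on, snap_stride, rec_stride)
}
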