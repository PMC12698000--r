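# Compiled trial engine: equivalence with the pure-R stepper, determinism,
# refractory gating, boost ordering, dt-convergence, Dale compliance.

test_that("the compiled engine reproduces the pure-R stepper", {
  s <- toy_stream(1)
  set.seed(2)
  w0 <- sample_initial_weights("gaussian", 20, 20)
  pp <- plasticity_params()
  for (variant in c("spike_trace", "calcium")) {
    np <- neuron_params(variant, gbar_e = 6, gbar_i = 7)
    vi <- if (variant == "spike_trace") 0L else 1L
    set.seed(3)
    ref <- simulate_neuron_r(s, w0, np, pp, record_stride = 10L)
    set.seed(3)
    cpp <- run_engine(s, w0, np, pp, variant = vi,
                      snap_stride = as.integer(100 / s$spec$dt))
    expect_identical(ref$spike_steps, as.integer(cpp$spike_steps))
    expect_equal(ref$w, cpp$w, tolerance = 1e-10)
    expect_equal(ref$e, cpp$e_rec, tolerance = 1e-10)
    expect_equal(ref$v_s, cpp$vs_rec, tolerance = 1e-10)
    expect_equal(ref$kappa_series, cpp$kappa_series, tolerance = 1e-10)
  }
})

test_that("identical configuration and seed give bit-identical trials", {
  t1 <- run_tuning_trial(toy_trial_config(seed = 7))
  t2 <- run_tuning_trial(toy_trial_config(seed = 7))
  expect_identical(t1$spike_times, t2$spike_times)
  expect_identical(t1$w_final, t2$w_final)
  t3 <- run_tuning_trial(toy_trial_config(seed = 8))
  expect_false(identical(t1$spike_times, t3$spike_times))
})

test_that("stored weights never flip sign during a plastic trial", {
  tr <- run_tuning_trial(toy_trial_config(seed = 4))
  sgn <- tr$sign
  expect_true(all(sweep(tr$W_snap, 1, sgn, `*`) >= 0))
  expect_true(all(tr$w_final * sgn >= 0))
})

test_that("dendrite-to-soma input is gated off for the whole refractory period", {
  # spike-trace variant: after each spike v_s stays exactly at v_re for t_ref
  s <- toy_stream(5)
  set.seed(2)
  w0 <- 3 * sample_initial_weights("gaussian", 20, 20)
  np <- neuron_params("spike_trace", gbar_e = 30, gbar_i = 10)
  res <- run_engine(s, w0, np, plasticity_params(), rec_stride = 1L)
  expect_gt(length(res$spike_steps), 3)
  tref_steps <- round(np$t_ref / s$spec$dt)
  for (k in res$spike_steps) {
    if (k + tref_steps > length(res$vs_rec)) next
    expect_true(all(abs(res$vs_rec[(k):(k + tref_steps - 1)] - np$v_re) < 1e-12))
  }
})

test_that("post-spike dendritic depolarization is non-decreasing in bAP strength", {
  spec <- input_stream_spec(n_exc = 2, n_inh = 2, rate = 0, community_size = 2,
                            n_patterns = 1, trial_duration = 0.2, p_fail = 0)
  set.seed(1)
  stream <- build_input_stream(spec)
  peaks <- vapply(c(0, 15, 60), function(m) {
    np <- neuron_params("calcium", m_csd = m)
    res <- run_engine(stream, c(1, 1, -1, -1), np, plasticity_params(),
                      variant = 1L, forced = 500L, rec_stride = 1L)
    max(res$vd_rec[500:700])
  }, numeric(1))
  expect_true(all(diff(peaks) >= -1e-9))
  expect_gt(peaks[3], peaks[1] + 5)  # 60 nS visibly boosts the dendrite
})

test_that("halving the integration step changes subthreshold trajectories by O(dt)", {
  mk <- function(dt) {
    spec <- input_stream_spec(n_exc = 10, n_inh = 10, rate = 20, t_pat = 50,
                              community_size = 4, n_patterns = 1,
                              trial_duration = 0.1, p_fail = 0, dt = dt)
    set.seed(9)
    build_input_stream(spec)
  }
  s1 <- mk(0.1)
  s2 <- mk(0.1)
  s2$step <- (s2$step - 1L) * 2L + 1L   # same spike times on the halved grid
  s2$spec$dt <- 0.05
  s2$n_steps <- s2$n_steps * 2L
  w0 <- c(rep(0.3, 10), rep(-0.3, 10))  # weak: no spikes
  np <- neuron_params("spike_trace")
  r1 <- run_engine(s1, w0, np, plasticity_params(), plastic = FALSE,
                   rec_stride = 10L)
  r2 <- run_engine(s2, w0, np, plasticity_params(), plastic = FALSE,
                   rec_stride = 20L)
  expect_length(r1$spike_steps, 0)
  err <- max(abs(r1$vd_rec - r2$vd_rec))
  expect_lt(err, 0.2)  # < O(dt) on the mV scale for a 100 ms segment
})

test_that("plasticity traces do not feed back into the membrane equations", {
  cfg_a <- toy_trial_config(seed = 11)
  cfg_b <- toy_trial_config(seed = 11)
  cfg_b$plasticity <- plasticity_params(tau_y = 50, tau_ybar = 500)
  a <- run_tuning_trial(cfg_a, plastic = FALSE)
  b <- run_tuning_trial(cfg_b, plastic = FALSE)
  expect_identical(a$spike_times, b$spike_times)
  expect_identical(a$vd_rec, b$vd_rec)
})

test_that("plasticity substep stride has negligible effect on the trajectory", {
  cfg1 <- toy_trial_config(seed = 12)
  cfg1$plasticity$plasticity_stride <- 1L
  cfg5 <- toy_trial_config(seed = 12)
  cfg5$plasticity$plasticity_stride <- 5L
  a <- run_tuning_trial(cfg1)
  b <- run_tuning_trial(cfg5)
  expect_gt(cor(a$w_final, b$w_final), 0.995)
  expect_lt(max(abs(a$w_final - b$w_final)) / max(abs(a$w_final)), 0.1)
})

test_that("the excitability signal integrates to ~zero over a response window", {
  # isolated forced spikes; integral of e over [onset, onset + 10 tau_ybar]
  spec <- input_stream_spec(n_exc = 2, n_inh = 2, rate = 0, community_size = 2,
                            n_patterns = 1, trial_duration = 3, p_fail = 0)
  set.seed(1)
  stream <- build_input_stream(spec)
  np <- neuron_params("spike_trace")
  res <- run_engine(stream, c(1, 1, -1, -1), np, plasticity_params(),
                    forced = c(1000L, 1100L, 1200L), rec_stride = 1L)
  e <- res$e_rec
  expect_lt(abs(sum(e)), 0.05 * sum(abs(e)))
})
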