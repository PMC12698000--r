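# The plasticity rule: traces, PSP, zeta scaling, induction, eligibility,
# Dale clamp, homeostasis.

pp <- plasticity_params()

test_that("spike traces follow their linear dynamics", {
  # single spike: Y decays exactly exponentially from 1
  tr <- list(Y = 0, Ybar = 0)
  tr <- step_spike_traces(tr, TRUE, 0.1, pp)
  expect_equal(tr$Y, 1)
  for (k in 1:100) tr <- step_spike_traces(tr, FALSE, 0.1, pp)
  expect_equal(tr$Y, exp(-10 / pp$tau_y), tolerance = 1e-12)
  # no spikes ever: all zero
  tr0 <- list(Y = 0, Ybar = 0)
  for (k in 1:50) tr0 <- step_spike_traces(tr0, FALSE, 0.1, pp)
  expect_identical(c(tr0$Y, tr0$Ybar, tr0$e), c(0, 0, 0))
  # steady spiking much faster than 1/tau_y: e fluctuates around 0 long-run
  tr <- list(Y = 0, Ybar = 0)
  es <- numeric(0)
  for (k in 1:200000) {
    tr <- step_spike_traces(tr, k %% 50 == 0, 0.1, pp)  # 200 Hz
    if (k > 100000) es <- c(es, tr$e)
  }
  expect_lt(abs(mean(es)), 0.05 * mean(abs(es)) + 0.02)
})

test_that("calcium trace has the stated fixed points", {
  tr <- list(C = pp$c0 + 1, Cbar = pp$c0)
  for (k in 1:50000) tr <- step_calcium_trace(tr, 0, 0.1, pp)
  expect_equal(tr$C, pp$c0, tolerance = 1e-6)
  expect_equal(tr$e, 0, tolerance = 1e-6)
  # constant current: C -> C0 + phi * I * tau_c
  istar <- 2
  tr <- list(C = pp$c0, Cbar = pp$c0)
  for (k in 1:50000) tr <- step_calcium_trace(tr, istar, 0.1, pp)
  expect_equal(tr$C, pp$c0 + pp$phi_ca * istar * pp$tau_c, tolerance = 1e-4)
})

test_that("PSP trace is the stated impulse response with signed excursions", {
  psp <- rep(0, 3)
  psp <- step_psp(psp, c(2, -1, 0), 0.1, pp)  # weighted impulses
  expect_equal(psp, c(2, -1, 0) / pp$tau_p)
  expect_lt(psp[2], 0)   # inhibitory synapse: negative excursion
  for (k in 1:1000) psp <- step_psp(psp, rep(0, 3), 0.1, pp)
  expect_equal(psp, c(2, -1, 0) / pp$tau_p * exp(-100 / pp$tau_p),
               tolerance = 1e-12)
})

test_that("zeta is an alpha function with root, unit peak, and bounded range", {
  expect_equal(zeta(pp$phi_zeta, pp), 0)
  expect_equal(zeta(pp$phi_zeta + pp$tau_zeta, pp), 1)
  g <- zeta(seq(0, 60, by = 0.01), pp)
  expect_true(all(g >= 0 & g <= 1))
  expect_lt(zeta(20 * (pp$phi_zeta + pp$tau_zeta), pp), 0.01) # saturation
  # clipped to zero below phi_zeta
  p2 <- plasticity_params(phi_zeta = 1)
  expect_identical(zeta(c(0, 0.5, 0.99), p2), c(0, 0, 0))
})

test_that("plasticity induction is the triple product with the right signs", {
  w <- c(1, -1); psp <- c(0.5, -0.5)
  expect_identical(plasticity_induction(0, psp, w, pp), c(0, 0))
  pi_pos <- plasticity_induction(1, psp, w, pp)
  expect_gt(pi_pos[1], 0)   # potentiation of an active excitatory synapse
  expect_lt(pi_pos[2], 0)   # inhibitory synapse strengthens (more negative)
  pi_neg <- plasticity_induction(-1, psp, w, pp)
  expect_lt(pi_neg[1], 0)   # depression after spiking ceases
  expect_equal(pi_pos, -pi_neg)
})

test_that("eligibility dynamics converge and the Dale clamp blocks sign flips", {
  # constant PI held forever: dw -> PI
  w <- 5; dwv <- 0
  for (k in 1:20000) {
    upd <- step_weight_update(w, dwv, 0.3, 1, 0.1,
                              plasticity_params(eta = 1e-9))
    dwv <- upd$dw
  }
  expect_equal(dwv, 0.3, tolerance = 1e-6)
  # sign flip blocked: w stays put for that step
  upd <- step_weight_update(0.01, -10, 0, 1, 0.1, pp)
  expect_identical(upd$dw, 0)
  expect_identical(upd$w, 0.01)
  # PI = 0 from t0: dw decays exponentially, w converges to a constant
  w <- 1; dwv <- 1
  ws <- numeric(0)
  for (k in 1:5000) {
    upd <- step_weight_update(w, dwv, 0, 1, 0.1, pp)
    w <- upd$w; dwv <- upd$dw
  }
  expect_equal(dwv, (1 - 0.1 / pp$tau_delta)^5000, tolerance = 1e-9)
  w_limit <- 1 + pp$eta * 0.1 * (1 - 0.1 / pp$tau_delta) / (0.1 / pp$tau_delta) * 1
  expect_lt(abs(w - w_limit) / w_limit, 0.05)
})

test_that("homeostatic rescaling preserves the displacement-weighted gain", {
  w <- c(1, -2, 3)
  st <- list(kappa = 1.5, theta = 4)
  st2 <- homeostatic_rescale(w, st)
  expect_equal(st2$kappa * sum(abs(w)), st$kappa * st$theta)  # conservation
  expect_equal(st2$theta, sum(abs(w)))
  # no displacement drift: kappa unchanged
  st3 <- homeostatic_rescale(w, st2)
  expect_equal(st3$kappa, st2$kappa)
  expect_warning(homeostatic_rescale(c(0, 0), st), "skipping")
})

test_that("the rule has no drift without activity", {
  # zero input, zero spiking: PSP, e, dw all decay to 0 and w is constant
  spec <- input_stream_spec(n_exc = 5, n_inh = 5, rate = 0, community_size = 2,
                            n_patterns = 1, trial_duration = 1, p_fail = 0)
  set.seed(1)
  stream <- build_input_stream(spec)
  expect_length(stream$step, 0)
  w0 <- c(1, 2, 3, 4, 5, -1, -2, -3, -4, -5)
  np <- neuron_params("spike_trace")
  res <- run_engine(stream, w0, np, pp)
  expect_identical(res$w, w0)
  expect_length(res$spike_steps, 0)
  expect_true(all(res$e_rec == 0))
})
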