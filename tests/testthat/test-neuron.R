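# Membrane machinery: compartments, conductance filters, HVA and NMDAR
# channels, coupling boost.

np <- neuron_params("spike_trace")
ppd <- plasticity_params()

test_that("double-exponential filters are unit-peak normalized and linear", {
  combos <- list(c(0.5, 3), c(0.5, 8), c(0.2, 1.2), c(3.3, 102.38))
  for (tc in combos) {
    tp <- double_exp_peak_time(tc[1], tc[2])
    # closed-form peak equals 1 exactly at t_peak
    f_analytic <- function(t) (exp(-t / tc[2]) - exp(-t / tc[1])) /
      (exp(-tp / tc[2]) - exp(-tp / tc[1]))
    expect_equal(f_analytic(tp), 1, tolerance = 1e-12)
    expect_lt(max(f_analytic(seq(0, 20 * tc[2], by = 0.01))), 1 + 1e-6)
    # the discrete state exactly samples the continuous impulse response
    st <- double_exp_state(tc[1], tc[2])
    st <- step_conductance(st, 1, 0)      # impulse at t = 0
    vals <- numeric(50)
    for (k in 1:50) { st <- step_conductance(st, 0, 0.1); vals[k] <- double_exp_value(st) }
    expect_equal(vals, f_analytic((1:50) * 0.1), tolerance = 1e-12)
  }
  # linearity: two simultaneous unit impulses peak at 2
  st <- double_exp_state(0.5, 3)
  st <- step_conductance(st, 2, 0)
  mx <- 0
  for (k in 1:200) { st <- step_conductance(st, 0, 0.1); mx <- max(mx, double_exp_value(st)) }
  expect_equal(mx, 2, tolerance = 1e-3)
  # decay to zero without input
  for (k in 1:5000) st <- step_conductance(st, 0, 0.1)
  expect_lt(abs(double_exp_value(st)), 1e-10)
  expect_error(double_exp_peak_time(3, 3), "differ")
})

test_that("HVA rate functions match direct evaluation and their identities", {
  r0 <- hva_rates(0)
  # frozen values from direct evaluation of the closed forms at V = 0 mV
  expect_equal(r0$m_alpha, 0.055 * (-27) / (exp(-27 / 3.8) - 1), tolerance = 1e-12)
  expect_equal(r0$m_beta, 0.94 * exp(-75 / 17), tolerance = 1e-12)
  expect_equal(r0$h_alpha, 0.000457 * exp(-13 / 50), tolerance = 1e-12)
  expect_equal(r0$h_beta, 0.0065 / (exp(-15 / 28) + 1), tolerance = 1e-12)
  # identities at arbitrary voltages
  for (v in c(-80, -50, -27, -10, 20)) {
    r <- hva_rates(v)
    expect_true(r$m_inf > 0 && r$m_inf < 1)
    expect_true(r$h_inf > 0 && r$h_inf < 1)
    expect_equal(r$m_inf * (r$m_alpha + r$m_beta), r$m_alpha, tolerance = 1e-12)
    expect_equal(r$tau_m * (r$m_alpha + r$m_beta), 1, tolerance = 1e-12)
  }
  # the removable singularity at V = -27 takes the analytic limit, never NaN
  expect_equal(hva_rates(-27)$m_alpha, 0.055 * 3.8, tolerance = 1e-9)
  expect_false(any(is.na(unlist(hva_rates(-27)))))
  # hyperpolarized dendrite: negligible activation
  expect_lt(hva_rates(-75)$m_inf, 1e-3)
})

test_that("HVA gates relax to their steady states under clamped voltage", {
  npc <- neuron_params("calcium")
  for (v in c(-60, -30, 0)) {
    r <- hva_rates(v)
    st <- list(m = 0.5, h = 0.5)
    n_steps <- ceiling(5 * max(r$tau_m, r$tau_h) / 0.1)
    for (k in seq_len(n_steps)) {
      s <- step_hva(st, v, 0.1, npc)
      st <- list(m = s$m, h = s$h)
    }
    expect_equal(st$m, r$m_inf, tolerance = 1e-2)
    expect_lt(abs(st$h - r$h_inf) / max(r$h_inf, 1e-3), 0.05)
  }
  # reversal: zero current at V = v_ca
  s <- step_hva(list(m = 0.5, h = 0.5), npc$v_ca, 0.1, npc)
  expect_equal(s$i_ca, 0)
})

test_that("the magnesium block has the stated limits and closed form", {
  expect_equal(nmda_mgb(0, 1), 1 / (1 + 1 / 3.57), tolerance = 1e-12)
  expect_equal(nmda_mgb(-65, 0), 1)         # Mg = 0: unblocked at any V
  expect_gt(nmda_mgb(200, 2), 0.999)        # strong depolarization: unblocked
  expect_lt(nmda_mgb(-90, 1), nmda_mgb(-40, 1))  # monotone in V
  npn <- neuron_params("calcium_nmdar")
  cur <- nmda_currents(-40, 2, npn)
  expect_equal(cur$i_ca_nmda / (cur$i_nmda + cur$i_ca_nmda), npn$f_ca,
               tolerance = 1e-12)
})

test_that("the coupling boost peaks at m_csd above rest and relaxes back", {
  npc <- neuron_params("calcium", m_csd = 60)
  st <- double_exp_state(npc$tau_csd_rise, npc$tau_csd_decay)
  out <- step_coupling(st, TRUE, 0, npc)   # spike: impulse, no decay yet
  st <- out$state
  g <- numeric(400)
  for (k in 1:400) {
    out <- step_coupling(st, FALSE, 0.1, npc)
    st <- out$state; g[k] <- out$g_csd
  }
  tp <- double_exp_peak_time(npc$tau_csd_rise, npc$tau_csd_decay)
  expect_equal(max(g) - npc$g_csdr, 60, tolerance = 5e-3)
  expect_equal(which.max(g) * 0.1, tp, tolerance = 0.1)
  expect_equal(g[400], npc$g_csdr, tolerance = 1e-6)
  # m_csd = 0: coupling stays at rest
  np0 <- neuron_params("calcium", m_csd = 0)
  st0 <- double_exp_state(np0$tau_csd_rise, np0$tau_csd_decay)
  out0 <- step_coupling(st0, TRUE, 0.1, np0)
  expect_equal(out0$g_csd, np0$g_csdr)
})

test_that("somatic compartment rests, spikes, resets, and gates correctly", {
  # rest fixed point
  s <- step_soma(list(v_s = np$v_ls, refrac = 0L), np$v_ls, 0.1, np)
  expect_equal(s$v_s, np$v_ls)
  # threshold crossing: spike-trace resets to v_re, calcium jumps to v_peak
  s <- step_soma(list(v_s = np$v_th + 0.5, refrac = 0L), 0, 0.1, np)
  expect_true(s$spiked)
  expect_equal(s$v_s, np$v_re)
  npc <- neuron_params("calcium")
  sc <- step_soma(list(v_s = npc$v_th + 0.5, refrac = 0L), 0, 0.1, npc)
  expect_true(sc$spiked)
  expect_equal(sc$v_s, npc$v_peak)
  # refractory: spike-trace soma frozen regardless of dendritic input
  s2 <- step_soma(list(v_s = np$v_re, refrac = 5L), 50, 0.1, np)
  expect_equal(s2$v_s, np$v_re)
  expect_equal(s2$refrac, 4L)
  # calcium variant hyperpolarizes under the strong refractory leak
  s3 <- step_soma(list(v_s = npc$v_peak, refrac = 5L), 50, 0.1, npc)
  expect_lt(s3$v_s, npc$v_peak)
  expect_error(step_soma(list(v_s = NaN, refrac = 0L), 0, 0.1, np), "divergence")
})

test_that("dendritic compartment rests and depolarizes toward reversals", {
  v <- step_dendrite(np$v_ld, np$v_ld, FALSE, 0, 0, np$g_csdr, 0, 0,
                     dt = 0.1, p = np)
  expect_equal(v, np$v_ld)
  v_up <- step_dendrite(np$v_ld, np$v_ld, FALSE, 10, 0, np$g_csdr, 0, 0,
                        dt = 0.1, p = np)
  expect_gt(v_up, np$v_ld)
  v_dn <- step_dendrite(np$v_ld, np$v_ld, FALSE, 0, 10, np$g_csdr, 0, 0,
                        dt = 0.1, p = np)
  expect_lt(v_dn, np$v_ld)
})

test_that("neuron and plasticity constructors reject invalid parameters", {
  expect_error(neuron_params("spike_trace", t_ref = 5))
  expect_error(neuron_params("spike_trace", nonsense = 1), "unknown")
  expect_error(plasticity_params(tau_p = -1))
  expect_error(plasticity_params(bogus = 2), "unknown")
})
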