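# Input generation: Poisson trains, templates, schedules, corruption, weights.

test_that("Poisson generator matches the Bernoulli-grid law", {
  expect_identical(generate_poisson_train(0, 100), numeric(0))
  set.seed(11)
  # mean count over many draws equals Binomial(n_steps, r*dt) mean
  counts <- replicate(1e4, length(generate_poisson_train(5, 100, 0.1)))
  expect_equal(mean(counts), 1000 * 5e-4, tolerance = 0.05)
  # count distribution consistent with the Binomial (chi-square on 0/1/2+)
  obs <- table(factor(pmin(counts, 2), levels = 0:2))
  p <- dbinom(0:1, 1000, 5e-4); p <- c(p, 1 - sum(p))
  expect_gt(chisq.test(obs, p = p)$p.value, 0.01)
  # determinism under a fixed seed
  set.seed(42); a <- generate_poisson_train(5, 1000, 0.1)
  set.seed(42); b <- generate_poisson_train(5, 1000, 0.1)
  expect_identical(a, b)
  expect_error(generate_poisson_train(-1, 100), "nonnegative")
  expect_error(generate_poisson_train(5, 100, 0), "positive")
})

test_that("pattern templates are frozen, Poisson-like, and flag bursting units", {
  spec <- input_stream_spec(n_exc = 50, n_inh = 50, rate = 30, t_pat = 500,
                            community_size = 100, trial_duration = 2,
                            disjoint_communities = FALSE)
  set.seed(5); t1 <- build_pattern_template(spec, 1:100)
  set.seed(5); t2 <- build_pattern_template(spec, 1:100)
  expect_identical(t1, t2)
  expect_true(all(unlist(t1$unit_spikes) >= 0 & unlist(t1$unit_spikes) < 500))
  expect_true(all(vapply(t1$unit_spikes, function(s) !is.unsorted(s, strictly = TRUE),
                         logical(1))))
  # ISIs pooled over units consistent with the exponential law
  isi <- unlist(lapply(t1$unit_spikes, diff))
  expect_gt(suppressWarnings(ks.test(isi, "pexp", rate = 30 / 1000))$p.value, 0.01)
  # burst_fraction = 0.2 on 100 units flags exactly 20
  spec$burst_fraction <- 0.2
  set.seed(6); tb <- build_pattern_template(spec, 1:100)
  expect_length(tb$burst_unit_ids, 20)
  expect_error(build_pattern_template(spec, integer(0)), "empty")
})

test_that("schedule covers the trial with exact pattern lengths and uniform gaps", {
  spec <- input_stream_spec(trial_duration = 300)
  set.seed(7)
  sch <- draw_schedule(spec)
  expect_equal(sch$start[1], 0)
  expect_equal(sch$end[nrow(sch)], 300e3)
  expect_true(all(abs(sch$start[-1] - sch$end[-nrow(sch)]) < 1e-9))
  pat <- sch[sch$label != "noise", ]
  expect_true(all(abs(pat$end - pat$start - 100) < 1e-9))
  # pattern identities equally likely (chi-square over >= 500 presentations)
  expect_gt(nrow(pat), 500)
  expect_gt(chisq.test(table(pat$label))$p.value, 0.01)
  # no two pattern epochs adjacent
  lab <- sch$label
  expect_false(any(lab[-1] != "noise" & lab[-length(lab)] != "noise"))
  # gaps uniform on [100, 300]: range and moments
  gaps <- sch$end[sch$label == "noise"] - sch$start[sch$label == "noise"]
  gaps <- gaps[-length(gaps)]
  expect_true(all(gaps >= 100 - 1e-9 & gaps <= 300 + 1e-9))
  expect_equal(mean(gaps), 200, tolerance = 0.05)
})

test_that("transmission failure thins spikes binomially and rejects p_fail = 1", {
  sp <- seq(0, 999.9, by = 0.1)
  expect_identical(apply_transmission_failure(sp, 0), sp)
  expect_error(apply_transmission_failure(sp, 1), "p_fail")
  set.seed(8)
  kept <- length(apply_transmission_failure(sp, 0.3)) / length(sp)
  expect_equal(kept, 0.7, tolerance = 3 * sqrt(0.3 * 0.7 / length(sp)) / 0.7 + 0.01)
})

test_that("jitter has the stated mean displacement and respects bounds", {
  sp <- runif(2000, 100, 900)
  expect_identical(apply_jitter(sp, 0, c(0, 1000)), sp)
  set.seed(9)
  j <- apply_jitter(sort(sp), 50, c(0, 1000))
  expect_true(all(j >= 0 & j < 1000))
  expect_false(is.unsorted(j))
  # mean |displacement| for interior spikes ~ mean_jitter (uniform(-2m, 2m))
  sp2 <- rep(500, 5000)
  set.seed(10)
  j2 <- apply_jitter(sp2, 50, c(0, 1000))
  expect_equal(mean(abs(j2 - 500)), 50, tolerance = 0.05)
})

test_that("initial weights obey the stated laws and the Dale sign convention", {
  set.seed(12)
  w <- sample_initial_weights("lognormal", 5e4, 5e4)
  expect_equal(stats::var(w[1:5e4]), 1, tolerance = 0.1)  # variance ~ 1
  expect_true(all(w[1:5e4] > 0))
  expect_true(all(w[5e4 + 1:5e4] < 0))
  wu <- sample_initial_weights("uniform", 1e4, 1e4)
  expect_true(all(wu >= -3 & wu <= 3))
  expect_true(all(wu[1e4 + 1:1e4] <= 0))
  expect_error(sample_initial_weights("cauchy", 10, 10))
})

test_that("input streams replay frozen templates and are seed-reproducible", {
  spec <- input_stream_spec(n_exc = 20, n_inh = 20, rate = 30, t_pat = 100,
                            n_patterns = 2, community_size = 10,
                            trial_duration = 4, p_fail = 0)
  set.seed(21); s1 <- build_input_stream(spec)
  set.seed(21); s2 <- build_input_stream(spec)
  expect_identical(s1$step, s2$step)
  expect_identical(s1$unit, s2$unit)
  # with p_fail = 0 and no jitter, two presentations of the same pattern give
  # identical community spike trains relative to epoch start
  sch <- s1$schedule
  p1 <- sch[sch$label == "P1", ]
  expect_gt(nrow(p1), 1)
  tmpl <- s1$templates[[1]]
  t_ms <- (s1$step - 1) * spec$dt
  reps <- lapply(seq_len(min(2, nrow(p1))), function(r) {
    sel <- s1$unit %in% tmpl$units & t_ms >= p1$start[r] & t_ms < p1$end[r]
    data.frame(u = s1$unit[sel], t = round(t_ms[sel] - p1$start[r], 6))
  })
  expect_identical(reps[[1]], reps[[2]])
  # schedule covers the trial: total epoch length equals the duration
  expect_equal(sum(sch$end - sch$start), 4000, tolerance = spec$dt)
})

test_that("raster writer round-trips through plain text", {
  s <- toy_stream(3)
  f <- tempfile(fileext = ".txt"); fs <- tempfile(fileext = ".csv")
  write_raster(s, f, fs)
  r <- read_raster(f)
  expect_equal(nrow(r), length(s$step))
  expect_equal(r$unit, s$unit)
  expect_equal(r$time_ms, (s$step - 1) * s$spec$dt)
  sch <- read.csv(fs)
  expect_equal(sch$label, s$schedule$label)
  unlink(c(f, fs))
})
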