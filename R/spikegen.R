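# Afferent input generation: Poisson units, frozen pattern templates, presentation
# schedules, transmission failure, jitter, and initial weight sampling.

#' Specification of the afferent input stream
#'
#' Bundles every parameter of the input layer: population sizes, Poisson rate,
#' pattern geometry, presentation statistics, and corruption processes.
#'
#' @param n_exc,n_inh Number of excitatory / inhibitory input units.
#' @param rate Firing rate of every unit, Hz. Units fire as homogeneous
#'   Bernoulli-grid Poisson processes: each step of length `dt` emits a spike
#'   independently with probability `rate * dt`.
#' @param t_pat Pattern duration, ms. Every pattern epoch has exactly this length.
#' @param n_patterns Number of distinct frozen pattern templates.
#' @param noise_gap_range Range (ms) from which the length of the noise segment
#'   separating consecutive pattern epochs is drawn uniformly. The lower bound
#'   must be at least `t_pat`.
#' @param p_fail Per-spike transmission failure probability in `[0, 1)`; applied
#'   independently at every presentation, so the received train differs from the
#'   sent train each time.
#' @param burst_fraction Fraction of community units designated bursting.
#' @param trial_duration Trial length, seconds.
#' @param dt Simulation step, ms. `rate * dt` must be small (warned above 0.05).
#' @param community_size Units per pattern community (split evenly across the
#'   excitatory and inhibitory classes).
#' @param disjoint_communities If `TRUE` (default) communities are disjoint unit
#'   subsets; pattern epochs never overlap in time regardless.
#' @param burst_len,burst_isi Burst shape: a bursting unit replaces each template
#'   spike by `burst_len` spikes at `burst_isi` ms intervals (truncated at the
#'   pattern end).
#' @return An object of class `input_stream_spec`.
#' @export
input_stream_spec <- function(n_exc = 1000L, n_inh = 1000L, rate = 5,
                              t_pat = 100, n_patterns = 3L,
                              noise_gap_range = c(t_pat, 3 * t_pat),
                              p_fail = 0.1, burst_fraction = 0,
                              trial_duration = 20, dt = 0.1,
                              community_size = 500L,
                              disjoint_communities = TRUE,
                              burst_len = 3L, burst_isi = 5) {
  spec <- list(n_exc = as.integer(n_exc), n_inh = as.integer(n_inh),
               rate = rate, t_pat = t_pat, n_patterns = as.integer(n_patterns),
               noise_gap_range = noise_gap_range, p_fail = p_fail,
               burst_fraction = burst_fraction,
               trial_duration = trial_duration, dt = dt,
               community_size = as.integer(community_size),
               disjoint_communities = isTRUE(disjoint_communities),
               burst_len = as.integer(burst_len), burst_isi = burst_isi)
  class(spec) <- "input_stream_spec"
  validate_input_spec(spec)
  spec
}

validate_input_spec <- function(spec) {
  stopifnot(spec$n_exc > 0L, spec$n_inh > 0L, spec$rate >= 0, spec$dt > 0,
            spec$t_pat > 0, spec$n_patterns >= 1L)
  if (spec$p_fail < 0 || spec$p_fail >= 1)
    stop("p_fail must lie in [0, 1): p_fail = 1 would empty every train")
  if (spec$burst_fraction < 0 || spec$burst_fraction > 1)
    stop("burst_fraction must lie in [0, 1]")
  if (spec$noise_gap_range[1] < spec$t_pat)
    stop("noise_gap_range lower bound must be >= t_pat")
  if (spec$trial_duration * 1000 <= spec$t_pat)
    stop("trial_duration must exceed t_pat")
  if (spec$rate * spec$dt / 1000 > 0.05)
    warning("rate * dt > 0.05: Bernoulli-grid approximation of the Poisson process is poor")
  if (spec$disjoint_communities &&
      spec$n_patterns * spec$community_size > spec$n_exc + spec$n_inh)
    stop("disjoint communities exceed the input population")
  invisible(spec)
}

#' Generate one homogeneous Poisson spike train on the simulation grid
#'
#' Each of the `duration / dt` steps fires independently with probability
#' `rate * dt` (rate in Hz, times in ms). Spike times are the left edges of the
#' firing steps, i.e. lie on the `dt` grid in `[0, duration)`.
#'
#' @param rate Firing rate, Hz (>= 0).
#' @param duration Train length, ms.
#' @param dt Grid step, ms (> 0).
#' @return Sorted numeric vector of spike times (ms).
#' @export
generate_poisson_train <- function(rate, duration, dt = 0.1) {
  if (rate < 0) stop("rate must be nonnegative")
  if (dt <= 0) stop("dt must be positive")
  p <- rate * dt / 1000
  if (p > 0.05) warning("rate * dt > 0.05: grid too coarse for the Poisson limit")
  n_steps <- floor(duration / dt + 1e-9)
  if (n_steps < 1 || p == 0) return(numeric(0))
  k <- stats::rbinom(1L, n_steps, p)
  if (k == 0L) return(numeric(0))
  (sort(sample.int(n_steps, k)) - 1) * dt
}

# Poisson trains for many units at once; returns list(step, unit) of 1-based grid
# steps. Distributionally identical to calling generate_poisson_train per unit.
poisson_population <- function(n_units, rate, n_steps, dt) {
  p <- rate * dt / 1000
  counts <- stats::rbinom(n_units, n_steps, p)
  tot <- sum(counts)
  if (tot == 0L) return(list(step = integer(0), unit = integer(0)))
  step <- integer(tot); unit <- rep.int(seq_len(n_units), counts)
  idx <- 1L
  for (u in which(counts > 0L)) {
    k <- counts[u]
    step[idx:(idx + k - 1L)] <- sort(sample.int(n_steps, k))
    idx <- idx + k
  }
  list(step = step, unit = unit)
}

#' Build a frozen pattern template
#'
#' Draws Poisson spikes at the stream rate over one pattern window for every
#' community unit and freezes them: the identical template is replayed at every
#' presentation (before failure or jitter corruption). A designated subset of
#' units bursts: each of their template spikes is replaced by a short
#' high-frequency run.
#'
#' @param spec An [input_stream_spec()].
#' @param community_units Integer ids of the units forming this community.
#' @param pattern_id Label for the pattern.
#' @return A `pattern_template`: list with `pattern_id`, `unit_spikes` (list of
#'   sorted times in `[0, t_pat)` indexed like `community_units`), `units`, and
#'   `burst_unit_ids`.
#' @export
build_pattern_template <- function(spec, community_units, pattern_id = "P1") {
  if (length(community_units) == 0L) stop("community must not be empty")
  n_steps <- as.integer(floor(spec$t_pat / spec$dt + 1e-9))
  n_burst <- round(spec$burst_fraction * length(community_units))
  burst_ids <- if (n_burst > 0L) sort(sample(community_units, n_burst)) else integer(0)
  spikes <- vector("list", length(community_units))
  for (j in seq_along(community_units)) {
    p <- spec$rate * spec$dt / 1000
    k <- stats::rbinom(1L, n_steps, p)
    st <- if (k > 0L) (sort(sample.int(n_steps, k)) - 1) * spec$dt else numeric(0)
    if (community_units[j] %in% burst_ids && length(st) > 0L) {
      st <- as.vector(outer(seq_len(spec$burst_len) - 1L, st,
                            function(a, b) b + a * spec$burst_isi))
      st <- sort(unique(round(st / spec$dt) * spec$dt))
      st <- st[st < spec$t_pat]
    }
    spikes[[j]] <- st
  }
  structure(list(pattern_id = pattern_id, unit_spikes = spikes,
                 units = as.integer(community_units),
                 burst_unit_ids = as.integer(burst_ids)),
            class = "pattern_template")
}

# Community membership: one stratified subset (half excitatory, half inhibitory)
# per pattern; disjoint across patterns when requested.
assign_communities <- function(spec) {
  n_half <- spec$community_size %/% 2L
  exc_pool <- seq_len(spec$n_exc)
  inh_pool <- spec$n_exc + seq_len(spec$n_inh)
  comms <- vector("list", spec$n_patterns)
  for (p in seq_len(spec$n_patterns)) {
    e <- sort(sample(exc_pool, n_half))
    i <- sort(sample(inh_pool, spec$community_size - n_half))
    if (spec$disjoint_communities) {
      exc_pool <- setdiff(exc_pool, e)
      inh_pool <- setdiff(inh_pool, i)
    }
    comms[[p]] <- c(e, i)
  }
  comms
}

#' Draw the presentation schedule
#'
#' Alternates noise epochs (lengths uniform over `noise_gap_range`) with pattern
#' epochs of exactly `t_pat` ms, pattern identities drawn with equal
#' probabilities, until the trial is covered. Epochs are contiguous,
#' non-overlapping and truncated so their union is exactly `[0, trial_duration]`.
#'
#' @param spec An [input_stream_spec()].
#' @return A data.frame with columns `start`, `end` (ms) and `label`
#'   (`"noise"` or `"P<k>"`).
#' @export
draw_schedule <- function(spec) {
  total <- spec$trial_duration * 1000
  start <- numeric(0); end <- numeric(0); label <- character(0)
  t <- 0
  repeat {
    gap <- stats::runif(1, spec$noise_gap_range[1], spec$noise_gap_range[2])
    gap <- round(gap / spec$dt) * spec$dt
    e1 <- min(t + gap, total)
    start <- c(start, t); end <- c(end, e1); label <- c(label, "noise")
    t <- e1
    if (t >= total) break
    if (t + spec$t_pat > total) { # not enough room for a full pattern: pad noise
      start <- c(start, t); end <- c(end, total); label <- c(label, "noise")
      break
    }
    pid <- sample.int(spec$n_patterns, 1L)
    start <- c(start, t); end <- c(end, t + spec$t_pat)
    label <- c(label, paste0("P", pid))
    t <- t + spec$t_pat
    if (t >= total) break
  }
  data.frame(start = start, end = end, label = label, stringsAsFactors = FALSE)
}

#' Delete spikes by independent transmission failure
#'
#' @param spikes Numeric vector of spike times.
#' @param p_fail Failure probability in `[0, 1)`.
#' @return The surviving spikes, order preserved.
#' @export
apply_transmission_failure <- function(spikes, p_fail) {
  if (p_fail < 0 || p_fail >= 1)
    stop("p_fail must lie in [0, 1): p_fail = 1 would empty the train")
  if (p_fail == 0 || length(spikes) == 0L) return(spikes)
  spikes[stats::runif(length(spikes)) >= p_fail]
}

#' Jitter spike times uniformly
#'
#' Each spike is displaced by an independent draw from
#' `Uniform(-2 * mean_jitter, +2 * mean_jitter)`, whose mean absolute
#' displacement equals `mean_jitter`. Displaced times are clipped to
#' `[bounds[1], bounds[2])`, snapped back to the `dt` grid, and re-sorted.
#'
#' @param spikes Numeric vector of spike times (ms).
#' @param mean_jitter Mean absolute displacement, ms (>= 0).
#' @param bounds Length-2 clipping window (ms).
#' @param dt Grid step (ms).
#' @return Sorted jittered spike times.
#' @export
apply_jitter <- function(spikes, mean_jitter, bounds, dt = 0.1) {
  if (mean_jitter < 0) stop("mean_jitter must be nonnegative")
  if (mean_jitter == 0 || length(spikes) == 0L) return(spikes)
  disp <- stats::runif(length(spikes), -2 * mean_jitter, 2 * mean_jitter)
  s <- pmin(pmax(spikes + disp, bounds[1]), bounds[2] - dt)
  sort(round(s / dt) * dt)
}

#' Sample an initial synaptic weight vector
#'
#' Weight magnitudes are drawn from the requested distribution and signed by the
#' Dale identity of the presynaptic unit: excitatory weights positive,
#' inhibitory weights negative. Supported laws: `"gaussian"` (|N(0, 1)|),
#' `"uniform"` (|U(-3, 3)|, matching the ~6-sigma support of the Gaussian), and
#' `"lognormal"` (LN(mu = -0.3466, sigma = 0.8326), variance approximately 1;
#' inhibitory draws multiplied by -1).
#'
#' @param distribution One of `"gaussian"`, `"uniform"`, `"lognormal"`.
#' @param n_exc,n_inh Unit counts per class (excitatory units come first).
#' @return Numeric weight vector of length `n_exc + n_inh`.
#' @export
sample_initial_weights <- function(distribution = c("gaussian", "uniform", "lognormal"),
                                   n_exc, n_inh) {
  distribution <- match.arg(distribution)
  n <- n_exc + n_inh
  mag <- switch(distribution,
                gaussian  = abs(stats::rnorm(n)),
                uniform   = abs(stats::runif(n, -3, 3)),
                lognormal = stats::rlnorm(n, meanlog = -0.3466, sdlog = 0.8326))
  sgn <- c(rep(1, n_exc), rep(-1, n_inh))
  mag * sgn
}

#' Build the full afferent input stream for one trial
#'
#' During a pattern epoch the corresponding community replays its frozen
#' template while every other unit keeps firing fresh Poisson noise; during
#' noise epochs all units fire fresh Poisson noise, so the stream is continuous
#' across the whole population. Transmission failure thins every received spike
#' independently per presentation.
#'
#' @param spec An [input_stream_spec()].
#' @param templates Optional list of `pattern_template`s (one per pattern); if
#'   `NULL`, communities are assigned and templates drawn here.
#' @param schedule Optional pre-drawn schedule (see [draw_schedule()]).
#' @param jitter Mean absolute jitter (ms) applied to template replays (0 = off).
#' @return An `input_stream`: list with `spec`, `schedule`, `templates`,
#'   `community` (per-unit pattern index, 0 = background), `sign` (+1/-1 per
#'   unit), and the event stream `step` / `unit` (1-based grid steps sorted by
#'   time then unit).
#' @export
build_input_stream <- function(spec, templates = NULL, schedule = NULL, jitter = 0) {
  if (is.null(templates)) {
    comms <- assign_communities(spec)
    templates <- lapply(seq_along(comms), function(p)
      build_pattern_template(spec, comms[[p]], paste0("P", p)))
  }
  if (length(templates) < 1L) stop("at least one template required")
  if (is.null(schedule)) schedule <- draw_schedule(spec)
  n_units <- spec$n_exc + spec$n_inh
  n_steps <- as.integer(round(spec$trial_duration * 1000 / spec$dt))
  community <- integer(n_units)
  for (p in seq_along(templates)) community[templates[[p]]$units] <- p

  # Fresh Poisson background for every unit over the whole trial
  bg <- poisson_population(n_units, spec$rate, n_steps, spec$dt)
  step <- bg$step; unit <- bg$unit

  # For community units, remove background spikes inside their own pattern's
  # epochs and substitute the (corrupted) template replay.
  pat_rows <- which(schedule$label != "noise")
  if (length(pat_rows) > 0L) {
    pat_idx <- as.integer(sub("^P", "", schedule$label[pat_rows]))
    # locate each background event's schedule row in one pass
    t_ms <- (step - 1) * spec$dt
    row_of <- findInterval(t_ms, schedule$start)
    ev_pat <- integer(length(step))
    ev_pat[schedule$label[row_of] != "noise"] <-
      as.integer(sub("^P", "", schedule$label[row_of[schedule$label[row_of] != "noise"]]))
    keep <- !(ev_pat > 0L & community[unit] == ev_pat)
    step <- step[keep]; unit <- unit[keep]
    # flatten each template once: (unit, time-within-pattern)
    flat <- lapply(templates, function(tmpl) {
      list(unit = rep.int(tmpl$units, lengths(tmpl$unit_spikes)),
           time = unlist(tmpl$unit_spikes, use.names = FALSE))
    })
    add <- vector("list", length(pat_rows))
    for (i in seq_along(pat_rows)) {
      r <- pat_rows[i]
      fl <- flat[[pat_idx[i]]]
      n_ev <- length(fl$time)
      if (n_ev == 0L) next
      ok <- if (spec$p_fail > 0) stats::runif(n_ev) >= spec$p_fail
            else rep(TRUE, n_ev)
      tt <- fl$time[ok]; uu <- fl$unit[ok]
      if (jitter > 0 && length(tt) > 0L) {
        disp <- stats::runif(length(tt), -2 * jitter, 2 * jitter)
        tt <- pmin(pmax(tt + disp, 0), spec$t_pat - spec$dt)
        tt <- round(tt / spec$dt) * spec$dt
      }
      gs <- as.integer(round((schedule$start[r] + tt) / spec$dt)) + 1L
      sel <- gs >= 1L & gs <= n_steps
      add[[i]] <- list(step = gs[sel], unit = uu[sel])
    }
    step <- c(step, unlist(lapply(add, `[[`, "step"), use.names = FALSE))
    unit <- c(unit, unlist(lapply(add, `[[`, "unit"), use.names = FALSE))
  }
  o <- order(step, unit)
  structure(list(spec = spec, schedule = schedule, templates = templates,
                 community = community,
                 sign = c(rep(1L, spec$n_exc), rep(-1L, spec$n_inh)),
                 step = step[o], unit = unit[o], n_steps = n_steps),
            class = "input_stream")
}

#' Write / read a raster as plain text
#'
#' Two-column whitespace format `(unit_id, time_ms)` ordered by time then unit,
#' with an optional CSV schedule sidecar `(start, end, label)`.
#'
#' @param stream An `input_stream` or a list with `step`, `unit`, and `spec$dt`.
#' @param path Output file path.
#' @param schedule_path Optional path for the schedule sidecar.
#' @return `path`, invisibly.
#' @export
write_raster <- function(stream, path, schedule_path = NULL) {
  t_ms <- (stream$step - 1) * stream$spec$dt
  utils::write.table(data.frame(unit = stream$unit, time_ms = t_ms),
                     path, row.names = FALSE, col.names = TRUE, quote = FALSE)
  if (!is.null(schedule_path))
    utils::write.csv(stream$schedule, schedule_path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  utils::read.table(path, header = TRUE)
}
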