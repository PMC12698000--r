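# Trial metrics: selectivity index, tuning time, SNR, spike-train correlation,
# and weight-distribution summaries.

#' Selectivity-index parameters
#'
#' `alpha` scales the standardized difference inside the tanh; `eps` guards the
#' denominator; `k` sets the dynamic threshold `T = mu_n + k * sigma_n`;
#' `lower` is the absolute lower bound on the index; `persist` (ms) is how long
#' the criterion must hold; `snap_stride` (ms) the weight-snapshot grid.
#'
#' `threshold_scale` selects the spread entering the dynamic threshold:
#' `"sem"` (default) uses the standard error of the non-pattern mean, reading
#' the k-sigma bound as a 5-standard-error confidence statement on the group
#' mean difference; `"sd"` uses the per-synapse standard deviation.
#'
#' @param ... Overrides.
#' @return Named list.
#' @export
selectivity_params <- function(...) {
  p <- list(alpha = 0.5, eps = 1e-6, k = 5, lower = 0.15,
            persist = 1000, snap_stride = 100, threshold_scale = "sem")
  ov <- list(...)
  unknown <- setdiff(names(ov), names(p))
  if (length(unknown) > 0) stop("unknown selectivity parameter(s): ",
                                paste(unknown, collapse = ", "))
  p[names(ov)] <- ov
  p
}

#' Pattern selectivity index over weight snapshots
#'
#' For each pattern the index standardizes the mean weight *change* of the
#' pattern's synapses against the non-pattern synapses and squashes it:
#' `s.i.(t) = tanh(alpha * (mu_pat(t) - mu_non(t)) / (sigma_non(t) + eps))`,
#' where the statistics are computed on `w(t) - w(0)` restricted to excitatory
#' afferents. Working on changes makes the index exactly zero at trial start
#' and insensitive to the initial-weight dispersion.
#'
#' @param W Weight snapshot matrix (synapses x snapshots), including inhibitory
#'   rows; only excitatory rows enter the statistics.
#' @param w0 Initial weight vector.
#' @param community Per-synapse pattern membership (0 = background).
#' @param sign Per-synapse Dale identity (+1/-1).
#' @param sp Selectivity parameters ([selectivity_params()]).
#' @return A `selectivity_series`: list with `si` (patterns x snapshots),
#'   `mu_pat`, `mu_non`, `sigma_non`, `threshold` (the dynamic `T`), and
#'   `patterns`.
#' @export
selectivity_index <- function(W, w0, community, sign, sp = selectivity_params()) {
  pats <- sort(unique(community[community > 0]))
  if (length(pats) == 0L) stop("no pattern synapses")
  exc <- which(sign > 0)
  D <- W[exc, , drop = FALSE] - w0[exc]
  commE <- community[exc]
  n_snap <- ncol(D)
  si <- mu_p <- mu_n <- sg_n <- thr <- matrix(0, length(pats), n_snap)
  for (ip in seq_along(pats)) {
    p <- pats[ip]
    inp <- commE == p
    if (!any(inp) || all(inp)) stop("pattern and non-pattern groups must both be non-empty")
    Dp <- D[inp, , drop = FALSE]; Dn <- D[!inp, , drop = FALSE]
    mu_p[ip, ] <- colMeans(Dp)
    mu_n[ip, ] <- colMeans(Dn)
    sg_n[ip, ] <- apply(Dn, 2, stats::sd)
    si[ip, ] <- tanh(sp$alpha * (mu_p[ip, ] - mu_n[ip, ]) / (sg_n[ip, ] + sp$eps))
    spread <- if (identical(sp$threshold_scale, "sem"))
      sg_n[ip, ] / sqrt(nrow(Dn)) else sg_n[ip, ]
    thr[ip, ] <- mu_n[ip, ] + sp$k * spread
  }
  structure(list(si = si, mu_pat = mu_p, mu_non = mu_n, sigma_non = sg_n,
                 threshold = thr, patterns = pats, params = sp),
            class = "selectivity_series")
}

#' Tuning time from a selectivity series
#'
#' A pattern counts as tuned from the first snapshot at which both
#' `mu_pat(t) > T(t) = mu_non(t) + k * sigma_non(t)` (the pattern-group mean
#' change exceeds the dynamic threshold) and `s.i.(t) > lower`, provided the
#' conditions persist for at least `persist` ms on the snapshot grid. Absence
#' of tuning is a valid result (`time = NA`). More than one qualifying pattern
#' is reported as-is (classified "others" upstream).
#'
#' @param series A `selectivity_series`.
#' @param snap_times Snapshot times, ms.
#' @return List with `time` (ms of earliest qualification, NA if none),
#'   `tuned_patterns` (integer vector), and `per_pattern` times.
#' @export
tuning_time <- function(series, snap_times) {
  sp <- series$params
  need <- max(1L, ceiling(sp$persist / diff(snap_times[1:2])))
  per <- rep(NA_real_, length(series$patterns))
  for (ip in seq_along(series$patterns)) {
    ok <- series$mu_pat[ip, ] > series$threshold[ip, ] &
      series$si[ip, ] > sp$lower
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    hit <- which(r$values & r$lengths >= need)
    # tuning dates from when the condition was first met; the persistence
    # requirement only validates the crossing
    if (length(hit) > 0) per[ip] <- snap_times[starts[hit[1]]]
  }
  tuned <- which(!is.na(per))
  list(time = if (length(tuned)) min(per, na.rm = TRUE) else NA_real_,
       tuned_patterns = series$patterns[tuned], per_pattern = per)
}

#' Signal-to-noise ratio of an output spike train
#'
#' `S` counts output spikes inside the tuned pattern's presentation epochs and
#' `N` all other spikes; the SNR is `S / N`. `N = 0` returns `Inf` (sentinel).
#'
#' @param spike_times Output spike times, ms.
#' @param schedule Presentation schedule (`start`, `end`, `label`).
#' @param pattern Tuned pattern index (or label like `"P2"`).
#' @param from Optional start time (ms): spikes before it are ignored.
#' @return The ratio S/N.
#' @export
snr <- function(spike_times, schedule, pattern, from = 0) {
  lab <- if (is.character(pattern)) pattern else paste0("P", pattern)
  ep <- schedule[schedule$label == lab, , drop = FALSE]
  st <- spike_times[spike_times >= from]
  if (length(st) == 0L) return(0)
  inside <- vapply(st, function(t) any(t >= ep$start & t < ep$end), logical(1))
  S <- sum(inside); N <- length(st) - S
  if (N == 0L) Inf else S / N
}

#' Pearson correlation of two binned spike trains
#'
#' Bins both trains on a common grid and correlates the counts.
#'
#' @param spikes_a,spikes_b Spike time vectors, ms.
#' @param bin_width Bin width, ms.
#' @param window Length-2 common time window, ms.
#' @return Correlation coefficient, or `NA` (with a warning) if either train
#'   has zero variance in the window.
#' @export
output_cross_correlation <- function(spikes_a, spikes_b, bin_width = 25,
                                     window) {
  if (bin_width <= 0) stop("bin_width must be positive")
  br <- seq(window[1], window[2] + bin_width, by = bin_width)
  ca <- tabulate(findInterval(spikes_a[spikes_a >= window[1] & spikes_a < window[2]], br),
                 nbins = length(br) - 1L)
  cb <- tabulate(findInterval(spikes_b[spikes_b >= window[1] & spikes_b < window[2]], br),
                 nbins = length(br) - 1L)
  if (stats::sd(ca) == 0 || stats::sd(cb) == 0) {
    warning("zero-variance binned train: correlation undefined")
    return(NA_real_)
  }
  stats::cor(ca, cb)
}

#' Weight-distribution summary with a bimodality report
#'
#' Kernel density estimates per group plus a two-component separation test:
#' a two-component Gaussian mixture (fitted by EM from a k-means start) is
#' preferred over a single Gaussian by BIC and the component means are
#' separated by more than twice the larger component spread.
#'
#' @param weights Numeric weight vector (one group).
#' @param n_kde Number of KDE evaluation points.
#' @return List with `kde` (data.frame x, y), `skewness`, and `bimodal`
#'   (logical).
#' @export
weight_distribution_summary <- function(weights, n_kde = 256) {
  if (length(weights) < 10) stop("group too small")
  d <- stats::density(weights, n = n_kde)
  m <- mean(weights); s <- stats::sd(weights)
  skew <- if (s > 0) mean(((weights - m) / s)^3) else 0
  bimodal <- if (s > 0) two_component_separation(weights) else FALSE
  list(kde = data.frame(x = d$x, y = d$y), skewness = skew, bimodal = bimodal)
}

# Two-component Gaussian separation test: EM from a k-means start, BIC
# comparison against a single Gaussian, plus a mean-separation requirement.
two_component_separation <- function(x, n_iter = 50) {
  n <- length(x)
  ll1 <- sum(stats::dnorm(x, mean(x), stats::sd(x) * sqrt((n - 1) / n),
                          log = TRUE))
  km <- stats::kmeans(x, centers = 2, nstart = 3)
  mu <- as.vector(km$centers)
  sdv <- vapply(1:2, function(k) {
    v <- stats::sd(x[km$cluster == k])
    if (is.na(v) || v < 1e-8) 1e-8 else v
  }, numeric(1))
  pi1 <- mean(km$cluster == 1)
  for (it in seq_len(n_iter)) {
    d1 <- pi1 * stats::dnorm(x, mu[1], sdv[1])
    d2 <- (1 - pi1) * stats::dnorm(x, mu[2], sdv[2])
    g <- d1 / pmax(d1 + d2, 1e-300)
    pi1 <- mean(g)
    if (pi1 < 1e-6 || pi1 > 1 - 1e-6) break
    mu[1] <- sum(g * x) / sum(g)
    mu[2] <- sum((1 - g) * x) / sum(1 - g)
    sdv[1] <- max(sqrt(sum(g * (x - mu[1])^2) / sum(g)), 1e-8)
    sdv[2] <- max(sqrt(sum((1 - g) * (x - mu[2])^2) / sum(1 - g)), 1e-8)
  }
  ll2 <- sum(log(pmax(pi1 * stats::dnorm(x, mu[1], sdv[1]) +
                        (1 - pi1) * stats::dnorm(x, mu[2], sdv[2]), 1e-300)))
  bic1 <- -2 * ll1 + 2 * log(n)
  bic2 <- -2 * ll2 + 5 * log(n)
  bic2 < bic1 && abs(diff(mu)) > 2 * max(sdv)
}
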