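# Recurrent network with pre-configured excitatory cell assemblies driven by
# the patterned afferent stream; all afferent and recurrent synapses plastic
# under the spike-trace rule.

#' Specification of the assembly network
#'
#' Cells 1..n_exc are excitatory, the rest inhibitory. Assemblies are disjoint
#' contiguous blocks of excitatory cells with sizes drawn from a Gaussian
#' (resampled to be at least 2). Recurrent connectivity is Bernoulli per class
#' pair with lognormal weight magnitudes; within-assembly excitatory pairs are
#' fully connected with Gaussian weights (positive-truncated): the "strong"
#' condition uses mean `w_assembly_mu`, the "weak" condition mean 0.
#' Excitatory-to-inhibitory connectivity is comparatively dense to recruit
#' inhibition reliably and prevent runaway excitation. Inhibitory cells have
#' smaller capacitances (faster, higher-rate units). Connection probabilities
#' and lognormal parameters are calibrated defaults.
#'
#' @param n_exc,n_inh Network population sizes.
#' @param n_assemblies Number of pre-configured assemblies.
#' @param assembly_mu,assembly_sd Gaussian assembly-size parameters.
#' @param p_conn Named connection probabilities `ee`, `ei`, `ie`, `ii`
#'   (pre -> post class).
#' @param w_meanlog,w_sdlog Lognormal recurrent weight-magnitude parameters,
#'   named per class pair (`ee`, `ei`, `ie`, `ii`); inhibition-recruiting and
#'   inhibitory couplings are stronger than baseline E-E.
#' @param w_assembly_mu,w_assembly_sd Within-assembly Gaussian weight law
#'   (positive-truncated); `w_assembly_mu = 3` is the strong condition, 0 the
#'   weak one.
#' @param p_assembly Connection probability among members of the same assembly
#'   (these connections override the baseline E-E law).
#' @param c_s_exc,c_d_exc,c_s_inh,c_d_inh Somatic/dendritic capacitances (pF)
#'   per cell class.
#' @param runaway_cap Population mean-rate cap (Hz over 500 ms) beyond which
#'   the simulation aborts.
#' @return A `network_spec`.
#' @export
network_spec <- function(n_exc = 400L, n_inh = 100L, n_assemblies = 20L,
                         assembly_mu = 18, assembly_sd = 3,
                         p_conn = c(ee = 0.1, ei = 0.4, ie = 0.3, ii = 0.3),
                         w_meanlog = c(ee = -0.5, ei = 0.7, ie = 0.7, ii = -0.2),
                         w_sdlog = c(ee = 0.5, ei = 0.5, ie = 0.5, ii = 0.5),
                         w_assembly_mu = 3, w_assembly_sd = 1, p_assembly = 0.5,
                         c_s_exc = 200, c_d_exc = 170,
                         c_s_inh = 100, c_d_inh = 85,
                         runaway_cap = 100) {
  stopifnot(all(p_conn >= 0 & p_conn <= 1), n_assemblies >= 1)
  structure(list(n_exc = as.integer(n_exc), n_inh = as.integer(n_inh),
                 n_assemblies = as.integer(n_assemblies),
                 assembly_mu = assembly_mu, assembly_sd = assembly_sd,
                 p_conn = p_conn, w_meanlog = w_meanlog, w_sdlog = w_sdlog,
                 w_assembly_mu = w_assembly_mu, w_assembly_sd = w_assembly_sd,
                 p_assembly = p_assembly,
                 c_s_exc = c_s_exc, c_d_exc = c_d_exc,
                 c_s_inh = c_s_inh, c_d_inh = c_d_inh,
                 runaway_cap = runaway_cap),
            class = "network_spec")
}

#' Build the recurrent network
#'
#' Samples assembly memberships, recurrent connectivity and weights from a
#' [network_spec()]. Dale's law holds by construction: excitatory rows of the
#' (post x pre) weight matrix are nonnegative, inhibitory rows nonpositive.
#'
#' @param spec A [network_spec()].
#' @return A `network`: list with `spec`, `assemblies` (list of cell-id
#'   vectors), `W_rec` (post x pre weights), `mask_rec` (existing connections),
#'   `cell_sign`, `c_s`, `c_d`.
#' @export
build_network <- function(spec) {
  n <- spec$n_exc + spec$n_inh
  cell_sign <- c(rep(1L, spec$n_exc), rep(-1L, spec$n_inh))
  sizes <- round(stats::rnorm(spec$n_assemblies, spec$assembly_mu, spec$assembly_sd))
  while (any(sizes < 2))
    sizes[sizes < 2] <- round(stats::rnorm(sum(sizes < 2), spec$assembly_mu,
                                           spec$assembly_sd))
  if (sum(sizes) > spec$n_exc)
    stop("total assembly membership exceeds the excitatory population")
  bounds <- cumsum(c(0, sizes))
  assemblies <- lapply(seq_len(spec$n_assemblies), function(a)
    seq.int(bounds[a] + 1L, bounds[a + 1L]))
  # class-pair Bernoulli connectivity, no self-connections
  pre_e <- matrix(rep(cell_sign > 0, each = n), n, n)   # [post, pre]
  post_e <- matrix(rep(cell_sign > 0, times = n), n, n)
  p_mat <- matrix(0, n, n)
  p_mat[post_e & pre_e] <- spec$p_conn["ee"]
  p_mat[!post_e & pre_e] <- spec$p_conn["ei"]
  p_mat[post_e & !pre_e] <- spec$p_conn["ie"]
  p_mat[!post_e & !pre_e] <- spec$p_conn["ii"]
  mask <- matrix(stats::runif(n * n) < p_mat, n, n)
  diag(mask) <- FALSE
  W <- matrix(0, n, n)
  for (pair in c("ee", "ei", "ie", "ii")) {
    sel <- mask & switch(pair, ee = post_e & pre_e, ei = !post_e & pre_e,
                         ie = post_e & !pre_e, ii = !post_e & !pre_e)
    W[sel] <- stats::rlnorm(sum(sel), spec$w_meanlog[[pair]], spec$w_sdlog[[pair]])
  }
  # within-assembly E-E connections are defined solely by the assembly law:
  # Bernoulli(p_assembly) with Gaussian positive-truncated weights, replacing
  # any baseline E-E draw between members
  for (a in assemblies) {
    for (i in a) {
      js <- setdiff(a, i)
      W[i, js] <- 0
      mask[i, js] <- FALSE
      js <- js[stats::runif(length(js)) < spec$p_assembly]
      if (length(js) == 0L) next
      W[i, js] <- abs(stats::rnorm(length(js), spec$w_assembly_mu,
                                   spec$w_assembly_sd))
      mask[i, js] <- TRUE
    }
  }
  # presynaptic Dale sign
  W <- sweep(W, 2, cell_sign, `*`)
  structure(list(spec = spec, assemblies = assemblies, W_rec = W,
                 mask_rec = mask, cell_sign = cell_sign,
                 c_s = ifelse(cell_sign > 0, spec$c_s_exc, spec$c_s_inh),
                 c_d = ifelse(cell_sign > 0, spec$c_d_exc, spec$c_d_inh)),
            class = "network")
}

#' Run a recurrent-network trial on a patterned afferent stream
#'
#' All-to-all Gaussian afferent weights; afferent and recurrent synapses are
#' plastic under the spike-trace rule with per-cell, per-class homeostatic
#' gains (initialized to a common population-mean reference drive). Aborts
#' with an error if the population mean rate exceeds the runaway cap.
#'
#' @param network A [build_network()] result.
#' @param stream An `input_stream` ([build_input_stream()]).
#' @param neuron Spike-trace neuron parameters shared by all cells
#'   (capacitances are taken per class from the network spec).
#' @param plasticity Plasticity parameters.
#' @param seed Integer seed (afferent weight draw and noise).
#' @param plastic Enable plasticity.
#' @param w_aff_scale Scale factor on the Gaussian afferent weight magnitudes
#'   (sets the afferent-vs-recurrent drive balance).
#' @return A `network_result`: `spike_times` (ms), `spike_cells`, `schedule`,
#'   `assemblies`, `W0`, `W_final` (post x [afferent, recurrent] weights),
#'   `n_aff`, `min_kappa`, `assembly_counts` (assembly x presentation spike
#'   counts), `presentation_labels`.
#' @export
run_network_trial <- function(network, stream, neuron = neuron_params("spike_trace"),
                              plasticity = plasticity_params(), seed = 1,
                              plastic = TRUE, w_aff_scale = 1) {
  spec <- stream$spec
  n_aff <- spec$n_exc + spec$n_inh
  n_cells <- length(network$cell_sign)
  set.seed(derive_seed(seed, "weights"))
  W_aff <- w_aff_scale * matrix(abs(stats::rnorm(n_cells * n_aff)), n_cells, n_aff)
  W_aff <- sweep(W_aff, 2, stream$sign, `*`)
  W0 <- cbind(W_aff, network$W_rec)
  mask <- cbind(matrix(TRUE, n_cells, n_aff), network$mask_rec)
  pre_sign <- c(stream$sign, network$cell_sign)
  # per-cell homeostatic gains normalized to the population-mean class drive
  the <- rowSums(abs(W0[, pre_sign > 0, drop = FALSE]))
  thi <- rowSums(abs(W0[, pre_sign < 0, drop = FALSE]))
  k0e <- mean(the) / the
  k0i <- mean(thi) / thi
  set.seed(derive_seed(seed, "noise"))
  res <- sim_network_cpp(stream$step, stream$unit, stream$sign, stream$n_steps,
                         spec$dt, W0, mask, sum(network$cell_sign > 0),
                         network$c_s, network$c_d, neuron, plasticity, plastic,
                         k0e, k0i, network$spec$runaway_cap)
  spike_times <- res$spike_step * spec$dt
  spike_cells <- res$spike_cell
  sch <- stream$schedule
  pres <- sch[sch$label != "noise", , drop = FALSE]
  counts <- matrix(0L, length(network$assemblies), nrow(pres))
  for (a in seq_along(network$assemblies)) {
    msel <- spike_cells %in% network$assemblies[[a]]
    ts <- spike_times[msel]
    counts[a, ] <- vapply(seq_len(nrow(pres)), function(r)
      sum(ts >= pres$start[r] & ts < pres$end[r]), integer(1))
  }
  structure(list(spike_times = spike_times, spike_cells = spike_cells,
                 schedule = sch, assemblies = network$assemblies,
                 W0 = W0, W_final = res$W_final, n_aff = n_aff,
                 min_kappa = res$min_kappa, assembly_counts = counts,
                 presentation_labels = pres$label,
                 cell_sign = network$cell_sign, seed = seed),
            class = "network_result")
}

#' Normalized spike counts of the strongest-activated assemblies
#'
#' Picks the `n_top` assemblies with the largest total spike count across
#' pattern presentations, keeps only those whose spike count relative to
#' assembly size exceeds 1 at the last presentation, and returns their
#' size-normalized counts per presentation.
#'
#' @param result A `network_result`.
#' @param n_top Number of strongest assemblies to consider.
#' @return Data frame with `assembly`, `presentation`, `normalized_count`.
#' @export
tuned_assembly_analysis <- function(result, n_top = 6) {
  if (ncol(result$assembly_counts) < 1) stop("no presentations in trial")
  sizes <- lengths(result$assemblies)
  norm <- sweep(result$assembly_counts, 1, sizes, `/`)
  top <- order(rowSums(result$assembly_counts), decreasing = TRUE)[
    seq_len(min(n_top, nrow(norm)))]
  keep <- top[norm[top, ncol(norm)] > 1]
  if (length(keep) == 0L)
    return(data.frame(assembly = integer(0), presentation = integer(0),
                      normalized_count = numeric(0)))
  do.call(rbind, lapply(keep, function(a)
    data.frame(assembly = a, presentation = seq_len(ncol(norm)),
               normalized_count = norm[a, ])))
}

#' Pairwise correlation matrix of binned network spike trains
#'
#' Pearson correlations of spike counts binned at `bin_width` over all cell
#' pairs. Silent (or constant-count) cells give undefined correlations,
#' returned as `NA` and flagged. The summary averages within-assembly and
#' between-assembly pairs over the excitatory cells that belong to assemblies.
#'
#' @param result A `network_result` (or list with `spike_times`,
#'   `spike_cells`, `assemblies` and a `window`).
#' @param bin_width Bin width, ms.
#' @param window Length-2 analysis window (ms); defaults to the full trial.
#' @return List with `matrix` (cells x cells), `silent` (cell ids),
#'   `within_mean`, `between_mean`.
#' @export
pairwise_correlation_matrix <- function(result, bin_width = 25, window = NULL) {
  if (bin_width <= 0) stop("bin width must be positive")
  if (is.null(window)) window <- c(0, max(result$schedule$end))
  n_cells <- length(result$cell_sign)
  br <- seq(window[1], window[2], by = bin_width)
  B <- matrix(0L, n_cells, length(br) - 1L)
  sel <- result$spike_times >= window[1] & result$spike_times < window[2]
  ts <- result$spike_times[sel]; cs <- result$spike_cells[sel]
  for (c in unique(cs)) {
    B[c, ] <- tabulate(findInterval(ts[cs == c], br), nbins = length(br) - 1L)
  }
  v <- apply(B, 1, stats::var)
  silent <- which(v == 0)
  M <- suppressWarnings(stats::cor(t(B)))
  M[silent, ] <- NA; M[, silent] <- NA
  asm_id <- rep(NA_integer_, n_cells)
  for (a in seq_along(result$assemblies)) asm_id[result$assemblies[[a]]] <- a
  in_asm <- which(!is.na(asm_id))
  wi <- c(); bt <- c()
  for (i in seq_along(in_asm)) {
    for (j in seq_len(i - 1L)) {
      ci <- in_asm[i]; cj <- in_asm[j]
      val <- M[ci, cj]
      if (is.na(val)) next
      if (asm_id[ci] == asm_id[cj]) wi <- c(wi, val) else bt <- c(bt, val)
    }
  }
  list(matrix = M, silent = silent,
       within_mean = if (length(wi)) mean(wi) else NA_real_,
       between_mean = if (length(bt)) mean(bt) else NA_real_)
}
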