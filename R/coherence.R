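#' Time-varying magnitude coherence between two channels
#'
#' Linear (magnitude) coherence from tapered sliding-window FFTs with the
#' trial index as the averaging dimension:
#' `C(f,t) = |<X(f,t) Y*(f,t)>| / sqrt(<|X|^2><|Y|^2>)`, bounded in [0, 1].
#' Trials of all conditions are pooled (coherence characterises the
#' predominant frequency range of communication, not condition effects).
#'
#' @param ep an [lfp_epochs()].
#' @param pair length-2 channel indices or labels (one per region).
#' @param window_s,time_step,freq_step,freq_range analysis grid; defaults
#'   match [compute_ersp()] so coherence maps can enter the same cluster
#'   statistics.
#' @return A [tf_map()] with `units = "coherence"`.
#' @export
time_varying_coherence <- function(ep, pair, window_s = 0.512,
                                   time_step = 0.002, freq_step = 0.2,
                                   freq_range = c(2, 140)) {
  stopifnot(inherits(ep, "lfp_epochs"), length(pair) == 2)
  ch <- vapply(pair, function(p) resolve_channel(ep, p), integer(1))
  trials <- which(ep$kept)
  if (length(trials) < 2)
    stop("coherence needs at least 2 trials (degenerate at 1)")
  ns <- dim(ep$data)[3]
  g <- stft_grid(ns, ep$fs, ep$t0, window_s, time_step, freq_step, freq_range)
  av <- stft_average(ep, ch, trials, g)
  coh <- abs(av$cross) / sqrt(av$pow[[1]] * av$pow[[2]])
  coh[!is.finite(coh)] <- 0
  tf_map(pmin(coh, 1), g$freqs, g$times, units = "coherence",
         channel = paste(ep$channel_labels[ch], collapse = "~"),
         condition = "all")
}

#' Contrast coherence maps between two dyads
#'
#' Unpaired cluster-based permutation comparison of per-pair coherence maps
#' from two dyads (e.g. OFC-mPFC vs amygdala-mPFC).  Pairs are the
#' observations; because the two dyads generally hold different numbers of
#' pairs, the permutation scheme shuffles dyad labels across pairs
#' (independent-sample t) rather than flipping paired signs.
#'
#' @param maps_dyad1,maps_dyad2 lists of [tf_map()] on identical axes.
#' @param n_perm,alpha_sample,min_size,connectivity as in
#'   [paired_cluster_permutation()].
#' @param seed permutation seed.
#' @return A `cluster_result` (see [paired_cluster_permutation()]).
#' @export
dyad_contrast <- function(maps_dyad1, maps_dyad2, n_perm = 1000,
                          alpha_sample = 0.01, min_size = 500,
                          connectivity = 4, seed = 1) {
  n1 <- length(maps_dyad1); n2 <- length(maps_dyad2)
  if (n1 < 5 || n2 < 5) stop("need at least 5 pairs per dyad")
  ref <- maps_dyad1[[1]]
  for (m in c(maps_dyad1, maps_dyad2))
    if (!same_axes(ref, m)) stop("maps must share axes")
  X <- t(vapply(c(maps_dyad1, maps_dyad2), function(m) as.vector(m$values),
                numeric(length(ref$values))))
  groups <- rep(1:2, c(n1, n2))
  cluster_permutation_core(X, groups = groups, shape = dim(ref$values),
                           freqs = ref$freqs, times = ref$times,
                           n_perm = n_perm, alpha_sample = alpha_sample,
                           min_size = min_size, connectivity = connectivity,
                           seed = seed, paired = FALSE)
}
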