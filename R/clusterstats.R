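#' Paired cluster-based permutation test on time-frequency maps
#'
#' Nonparametric control of multiple comparisons over a frequency x time
#' grid: per pixel, a paired t statistic across contacts; pixels with
#' two-tailed `p < alpha_sample` form candidate clusters by sign and
#' grid connectivity; clusters with `pixel_count <= min_size` are discarded;
#' the cluster statistic is the mass (sum of t).  The null distribution is
#' the maximal absolute surviving-cluster mass under random sign flips of
#' the paired differences (the same size gate is applied inside each
#' permutation, keeping the null exchangeable with the observed statistic);
#' `p_cluster = (1 + #(null >= |mass|)) / (1 + n_perm)`.
#'
#' @param maps_a,maps_b lists of [tf_map()] on identical axes, aligned by
#'   contact (paired).
#' @param n_perm number of permutations (warning below 100).
#' @param alpha_sample pixel-level two-tailed threshold.
#' @param min_size cluster-size gate in pixels (clusters must be strictly
#'   larger to survive).
#' @param connectivity 4 (edge-sharing neighbours) or 8 (plus diagonals).
#' @param seed permutation seed.
#' @param gate_in_permutation apply the size gate inside permutations too
#'   (default TRUE).
#' @return An object of class `cluster_result`: `clusters` (list with mask,
#'   pixel_count, mass, sign, p_cluster), the observed `t_map`, the `null`
#'   distribution of max |mass|, and the parameters.
#' @export
paired_cluster_permutation <- function(maps_a, maps_b, n_perm = 1000,
                                       alpha_sample = 0.01, min_size = 500,
                                       connectivity = 4, seed = 1,
                                       gate_in_permutation = TRUE) {
  if (length(maps_a) != length(maps_b))
    stop("unpaired inputs: map lists differ in length")
  n <- length(maps_a)
  if (n < 5) stop("need at least 5 contact pairs")
  ref <- maps_a[[1]]
  for (m in c(maps_a, maps_b))
    if (!same_axes(ref, m)) stop("maps must share axes")
  P <- length(ref$values)
  D <- matrix(0, n, P)
  for (i in seq_len(n))
    D[i, ] <- as.vector(maps_a[[i]]$values) - as.vector(maps_b[[i]]$values)
  cluster_permutation_core(D, groups = NULL, shape = dim(ref$values),
                           freqs = ref$freqs, times = ref$times,
                           n_perm = n_perm, alpha_sample = alpha_sample,
                           min_size = min_size, connectivity = connectivity,
                           seed = seed, paired = TRUE,
                           gate_in_permutation = gate_in_permutation)
}

# Shared engine.  For paired = TRUE, X holds paired differences (n x P) and
# the permutation scheme is random sign flips; for paired = FALSE, X holds
# both groups' maps and `groups` the dyad labels, permuted by shuffling.
cluster_permutation_core <- function(X, groups, shape, freqs, times,
                                     n_perm, alpha_sample, min_size,
                                     connectivity, seed, paired,
                                     gate_in_permutation = TRUE) {
  if (n_perm < 100)
    warning("n_perm < 100 gives a very coarse permutation p-value")
  n <- nrow(X); P <- ncol(X)
  if (paired) {
    df <- n - 1
    ss <- colSums(X^2)
    tfun <- function(s) {
      m <- as.vector(crossprod(s, X)) / n
      v <- (ss - n * m^2) / df
      m / sqrt(pmax(v, .Machine$double.eps) / n)
    }
    draw <- function() sample(c(-1, 1), n, replace = TRUE)
    t_obs <- tfun(rep(1, n))
  } else {
    df <- n - 2
    tfun <- function(g) {
      i1 <- g == 1; i2 <- !i1
      n1 <- sum(i1); n2 <- sum(i2)
      m1 <- colMeans(X[i1, , drop = FALSE]); m2 <- colMeans(X[i2, , drop = FALSE])
      v1 <- colMeans(X[i1, , drop = FALSE]^2) - m1^2
      v2 <- colMeans(X[i2, , drop = FALSE]^2) - m2^2
      sp <- (n1 * v1 + n2 * v2) / df
      (m1 - m2) / sqrt(pmax(sp, .Machine$double.eps) * (1 / n1 + 1 / n2))
    }
    draw <- function() sample(groups)
    t_obs <- tfun(groups)
  }
  t_crit <- qt(1 - alpha_sample / 2, df)
  obs <- label_clusters(t_obs, t_crit, shape, connectivity)
  obs <- obs[vapply(obs, function(cl) cl$pixel_count > min_size, logical(1))]
  null <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    tp <- tfun(draw())
    cls <- label_clusters(tp, t_crit, shape, connectivity)
    if (gate_in_permutation)
      cls <- cls[vapply(cls, function(cl) cl$pixel_count > min_size, logical(1))]
    if (length(cls) == 0) 0
    else max(vapply(cls, function(cl) abs(cl$mass), numeric(1)))
  }, numeric(1)))
  clusters <- lapply(obs, function(cl) {
    cl$p_cluster <- (1 + sum(null >= abs(cl$mass))) / (1 + n_perm)
    mask <- matrix(FALSE, shape[1], shape[2])
    mask[cl$idx] <- TRUE
    list(mask = mask, pixel_count = cl$pixel_count, mass = cl$mass,
         sign = cl$sign, p_cluster = cl$p_cluster)
  })
  ord <- order(vapply(clusters, function(cl) cl$p_cluster, numeric(1)))
  structure(list(clusters = clusters[ord],
                 t_map = matrix(t_obs, shape[1], shape[2]),
                 freqs = freqs, times = times, null = null,
                 params = list(n_perm = n_perm, alpha_sample = alpha_sample,
                               min_size = min_size,
                               connectivity = connectivity,
                               paired = paired,
                               p_floor = 1 / (n_perm + 1),
                               gate_hz_s_area = min_size *
                                 mean(diff(freqs)) * mean(diff(times)))),
            class = "cluster_result")
}

# connected components of suprathreshold pixels, split by sign.
# 4-connectivity uses EBImage's compiled flood fill on each sign's mask
# (signs cannot merge since they are labelled separately); 8-connectivity
# falls back to a sparse graph construction.
label_clusters <- function(tvals, t_crit, shape, connectivity) {
  if (connectivity == 4) {
    out <- list()
    tm <- matrix(tvals, shape[1], shape[2])
    for (sg in c(1, -1)) {
      mask <- if (sg > 0) tm > t_crit else tm < -t_crit
      if (!any(mask)) next
      L <- EBImage::bwlabel(mask)
      idx <- which(L > 0)
      lab <- L[idx]
      mass <- rowsum(tvals[idx], lab)
      cnt <- tabulate(lab)
      grp <- split(idx, lab)
      for (k in seq_along(grp))
        out[[length(out) + 1]] <- list(idx = grp[[k]],
                                       pixel_count = cnt[k],
                                       mass = mass[k], sign = sg)
    }
    return(out)
  }
  label_clusters_graph(tvals, t_crit, shape, connectivity)
}

label_clusters_graph <- function(tvals, t_crit, shape, connectivity) {
  idx <- which(abs(tvals) > t_crit)
  if (length(idx) == 0) return(list())
  nr <- shape[1]
  sgn <- sign(tvals[idx])
  pos <- integer(length(tvals))
  pos[idx] <- seq_along(idx)
  r <- (idx - 1) %% nr + 1
  offs <- if (connectivity == 4) list(c(1, 1), c(nr, 0)) else
    list(c(1, 1), c(nr, 0), c(nr + 1, 1), c(nr - 1, -1))
  from <- integer(0); to <- integer(0)
  for (o in offs) {
    nb <- idx + o[1]
    ok <- nb <= length(tvals) & pos[pmin(nb, length(tvals))] > 0
    if (o[2] == 1) ok <- ok & r < nr          # down: not from last row
    if (o[2] == -1) ok <- ok & r > 1          # up-diagonal: not from first row
    ok <- ok & abs(tvals[pmin(nb, length(tvals))] ) > t_crit
    nb_pos <- pos[pmin(nb, length(tvals))]
    same <- ok & sgn == sign(tvals[pmin(nb, length(tvals))])
    from <- c(from, which(same))
    to <- c(to, nb_pos[same])
  }
  comp <- if (length(from)) {
    g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
    if (igraph::vcount(g) < length(idx))
      g <- igraph::add_vertices(g, length(idx) - igraph::vcount(g))
    igraph::components(g)$membership
  } else seq_along(idx)
  out <- list()
  for (k in unique(comp)) {
    sel <- comp == k
    out[[length(out) + 1]] <- list(idx = idx[sel], pixel_count = sum(sel),
                                   mass = sum(tvals[idx[sel]]),
                                   sign = sgn[which(sel)[1]])
  }
  out
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("Cluster permutation result (%s, %d permutations, gate > %d px)\n",
              if (x$params$paired) "paired sign-flip" else "label shuffle",
              x$params$n_perm, x$params$min_size))
  if (length(x$clusters) == 0) {
    cat("  no clusters survive the size gate\n")
  } else {
    for (i in seq_along(x$clusters)) {
      cl <- x$clusters[[i]]
      fr <- range(x$freqs[rowSums(cl$mask) > 0])
      tr <- range(x$times[colSums(cl$mask) > 0])
      cat(sprintf("  %d: %s, %d px, %.1f-%.1f Hz, %.2f-%.2f s, mass %.1f, p = %.4g\n",
                  i, if (cl$sign > 0) "+" else "-", cl$pixel_count,
                  fr[1], fr[2], tr[1], tr[2], cl$mass, cl$p_cluster))
    }
  }
  invisible(x)
}

#' Post-hoc paired t-test on cluster means
#'
#' @param cluster_means_a,cluster_means_b per-contact mean dB inside a
#'   cluster, paired vectors.
#' @return list with `t`, `df`, `p` (two-tailed) and `degenerate` (TRUE when
#'   the differences have zero variance, in which case `p` is NA).
#' @export
posthoc_cluster_ttests <- function(cluster_means_a, cluster_means_b) {
  stopifnot(length(cluster_means_a) == length(cluster_means_b),
            length(cluster_means_a) >= 3)
  d <- cluster_means_a - cluster_means_b
  if (sd(d) < 1e-12 * (abs(mean(d)) + 1)) {
    warning("zero variance of paired differences; p undefined")
    return(list(t = NA_real_, df = length(d) - 1, p = NA_real_,
                degenerate = TRUE))
  }
  tt <- t.test(cluster_means_a, cluster_means_b, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, degenerate = FALSE)
}

#' Benjamini-Hochberg false discovery rate correction
#'
#' Step-up BH procedure; adjusted p-values are monotone in rank.
#'
#' @param pvals numeric vector of p-values in [0, 1].
#' @param q FDR level.
#' @return list with `adjusted` p-values and logical `rejected`.
#' @export
fdr_correct <- function(pvals, q = 0.05) {
  if (length(pvals) == 0) stop("empty p-value vector")
  stopifnot(all(pvals >= 0 & pvals <= 1, na.rm = TRUE))
  adj <- p.adjust(pvals, method = "BH")
  list(adjusted = adj, rejected = !is.na(adj) & adj <= q)
}
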