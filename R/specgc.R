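#' Fit a multi-trial VAR model to a channel pair
#'
#' Pooled least-squares estimation treating trials as independent
#' realisations: lagged design and response blocks are accumulated across
#' trials (no cross-trial products), each trial demeaned per channel, and
#' the coefficients solved from the pooled normal equations.  The residual
#' covariance is the pooled maximum-likelihood estimate.
#'
#' @param ep an [lfp_epochs()].
#' @param pair length-2 channel indices or labels.
#' @param order VAR model order (lags), >= 1.
#' @param trials optional trial subset (default: all kept trials).
#' @return An object of class `var_model`: `order`, `coeffs` (list of 2x2
#'   lag matrices), `sigma` (residual covariance), `fs`, `logdet_sigma`,
#'   `aic`, `n_obs`.
#' @export
fit_var <- function(ep, pair = c(1, 2), order, trials = NULL) {
  stopifnot(inherits(ep, "lfp_epochs"))
  if (order < 1) stop("VAR order must be >= 1")
  ch <- vapply(pair, function(p) resolve_channel(ep, p), integer(1))
  if (is.null(trials)) trials <- which(ep$kept)
  ns <- dim(ep$data)[3]
  if (length(trials) * (ns - order) < 8 * order)
    stop("too few samples for the requested order")
  acc <- var_normal_equations(ep, ch, order, trials)
  var_solve(acc, order, ep$fs)
}

# pooled X'X, X'Y, Y'Y over trials; X = [lag1 ch1, lag1 ch2, lag2 ch1, ...]
var_normal_equations <- function(ep, ch, m, trials) {
  k <- 2
  XtX <- matrix(0, k * m, k * m)
  XtY <- matrix(0, k * m, k)
  YtY <- matrix(0, k, k)
  n_obs <- 0L
  for (tr in trials) {
    x <- t(ep$data[tr, ch, , drop = TRUE])      # samples x 2
    x <- sweep(x, 2, colMeans(x))
    T <- nrow(x)
    Y <- x[(m + 1):T, , drop = FALSE]
    X <- lag_design(x, m)
    XtX <- XtX + crossprod(X)
    XtY <- XtY + crossprod(X, Y)
    YtY <- YtY + crossprod(Y)
    n_obs <- n_obs + (T - m)
  }
  list(XtX = XtX, XtY = XtY, YtY = YtY, n_obs = n_obs)
}

lag_design <- function(x, m) {
  T <- nrow(x)
  do.call(cbind, lapply(seq_len(m), function(l) x[(m + 1 - l):(T - l), ]))
}

var_solve <- function(acc, m, fs) {
  kap <- kappa(acc$XtX, exact = FALSE)
  if (!is.finite(kap) || kap > 1e12)
    stop("ill-conditioned lag covariance (condition number ",
         format(kap, digits = 3), ")")
  B <- solve(acc$XtX, acc$XtY)                  # (2m) x 2
  sigma <- (acc$YtY - crossprod(acc$XtY, solve(acc$XtX, acc$XtY))) / acc$n_obs
  sigma <- (sigma + t(sigma)) / 2
  coeffs <- lapply(seq_len(m), function(l) t(B[(2 * l - 1):(2 * l), , drop = FALSE]))
  ld <- determinant(sigma, logarithm = TRUE)
  if (ld$sign <= 0) stop("degenerate residual covariance")
  aic <- as.numeric(ld$modulus) + 2 * (4 * m) / acc$n_obs
  structure(list(order = m, coeffs = coeffs, sigma = sigma, fs = fs,
                 logdet_sigma = as.numeric(ld$modulus), aic = aic,
                 n_obs = acc$n_obs),
            class = "var_model")
}

#' @export
print.var_model <- function(x, ...) {
  rho <- companion_spectral_radius(x$coeffs)
  cat(sprintf("VAR(%d) on %d pooled observations @ %g Hz\n",
              x$order, x$n_obs, x$fs))
  cat(sprintf("  AIC %.4f | spectral radius %.3f%s\n", x$aic, rho,
              if (rho >= 1) " (UNSTABLE)" else ""))
  invisible(x)
}

#' Select the VAR order by AIC
#'
#' Fits orders `1..m_max` by pooled least squares and returns the AIC
#' minimiser, trading spectral resolution against complexity.
#'
#' @inheritParams fit_var
#' @param m_max largest order tried (default 20, covering the 7-12 range
#'   typical for 500 Hz LFP pairs).
#' @return list with `order` (the AIC argmin) and `aic` (the AIC curve).
#' @export
select_order_aic <- function(ep, pair = c(1, 2), m_max = 20, trials = NULL) {
  stopifnot(inherits(ep, "lfp_epochs"))
  ch <- vapply(pair, function(p) resolve_channel(ep, p), integer(1))
  if (is.null(trials)) trials <- which(ep$kept)
  ns <- dim(ep$data)[3]
  if (ns - m_max < 4 * m_max) stop("m_max infeasible for epoch length")
  # All orders are scored on the common sample conditioned at m_max (rows
  # m_max+1 .. T of every trial); the nested lag designs then make the
  # log-determinant term monotone and the AIC comparison clean.
  acc <- var_normal_equations(ep, ch, m_max, trials)
  aics <- vapply(seq_len(m_max), function(m) {
    idx <- seq_len(2 * m)
    XtX <- acc$XtX[idx, idx, drop = FALSE]
    XtY <- acc$XtY[idx, , drop = FALSE]
    sigma <- (acc$YtY - crossprod(XtY, solve(XtX, XtY))) / acc$n_obs
    ld <- determinant((sigma + t(sigma)) / 2, logarithm = TRUE)
    as.numeric(ld$modulus) + 2 * (4 * m) / acc$n_obs
  }, numeric(1))
  list(order = which.min(aics), aic = aics)
}

#' Geweke spectral Granger causality of a fitted VAR
#'
#' Computes the transfer function `H(f) = (I - sum_l A_l e^{-2 pi i f l/fs})^{-1}`,
#' the spectral matrix `S(f) = H Sigma H*`, and the Geweke directed-influence
#' measures with the standard noise-covariance rotation removing
#' instantaneous correlation: for direction 2 -> 1,
#' `f(f) = ln[S_11 / (S_11 - (Sigma_22 - Sigma_12^2/Sigma_11) |H_12|^2)]`
#' (and symmetrically for 1 -> 2).
#'
#' @param model a [fit_var()] result (must be stable).
#' @param freqs frequency grid in Hz (default 0 to Nyquist at 0.5 Hz).
#' @return An object of class `gc_spectrum`: `freqs`, `gc_xy` (1 -> 2),
#'   `gc_yx` (2 -> 1), in nats; permutation bounds NULL until
#'   [permutation_ci()] attaches them.
#' @export
spectral_gc <- function(model, freqs = NULL) {
  stopifnot(inherits(model, "var_model"))
  rho <- companion_spectral_radius(model$coeffs)
  if (rho >= 1) stop("unstable VAR (spectral radius ", format(rho), ")")
  if (is.null(freqs)) freqs <- seq(0, model$fs / 2, by = 0.5)
  gc <- geweke_pair(model$coeffs, model$sigma, freqs, model$fs)
  structure(list(freqs = freqs, gc_xy = gc$xy, gc_yx = gc$yx,
                 ci_xy = NULL, ci_yx = NULL, n_perm = 0, fs = model$fs,
                 order = model$order),
            class = "gc_spectrum")
}

# vectorised Geweke measures over a frequency grid for a 2x2 VAR
geweke_pair <- function(coeffs, sigma, freqs, fs) {
  m <- length(coeffs)
  E <- exp(-2i * pi * outer(freqs, seq_len(m)) / fs)   # nf x m
  a11 <- 1 - as.vector(E %*% vapply(coeffs, function(A) A[1, 1], numeric(1)))
  a12 <- -as.vector(E %*% vapply(coeffs, function(A) A[1, 2], numeric(1)))
  a21 <- -as.vector(E %*% vapply(coeffs, function(A) A[2, 1], numeric(1)))
  a22 <- 1 - as.vector(E %*% vapply(coeffs, function(A) A[2, 2], numeric(1)))
  det <- a11 * a22 - a12 * a21
  h11 <- a22 / det; h12 <- -a12 / det
  h21 <- -a21 / det; h22 <- a11 / det
  s11 <- Re(h11 * sigma[1, 1] * Conj(h11) + h12 * sigma[2, 2] * Conj(h12) +
              h11 * sigma[1, 2] * Conj(h12) + h12 * sigma[2, 1] * Conj(h11))
  s22 <- Re(h21 * sigma[1, 1] * Conj(h21) + h22 * sigma[2, 2] * Conj(h22) +
              h21 * sigma[1, 2] * Conj(h22) + h22 * sigma[2, 1] * Conj(h21))
  sig2_c <- sigma[2, 2] - sigma[1, 2]^2 / sigma[1, 1]  # Sigma_22 | 1
  sig1_c <- sigma[1, 1] - sigma[1, 2]^2 / sigma[2, 2]  # Sigma_11 | 2
  f_yx <- log(s11 / pmax(s11 - sig2_c * Mod(h12)^2, .Machine$double.xmin))
  f_xy <- log(s22 / pmax(s22 - sig1_c * Mod(h21)^2, .Machine$double.xmin))
  list(xy = pmax(f_xy, 0), yx = pmax(f_yx, 0), s11 = s11, s22 = s22)
}

#' Permutation confidence bounds for spectral Granger causality
#'
#' Builds a null distribution by destroying the cross-channel dependence
#' while preserving each channel's autocovariance.  The default scheme
#' re-pairs the second channel's trials by random permutation (trials are
#' the natural exchangeable blocks of epoched data); a within-trial
#' block-shuffling scheme (blocks of `4 * order` samples, tied to the
#' autocovariance horizon) is available via `scheme = "blocks"`.  The VAR is
#' refit and the Geweke spectrum recomputed per permutation; the bound is
#' the pointwise empirical quantile at `level` per frequency and direction.
#'
#' @inheritParams fit_var
#' @param order model order (e.g. from [select_order_aic()]).
#' @param freqs frequency grid (default 0 to Nyquist at 0.5 Hz).
#' @param n_perm number of permutations (warning below 100).
#' @param level quantile of the null curves (default 0.999).
#' @param scheme `"trials"` (default) or `"blocks"`.
#' @param seed permutation seed.
#' @return A `gc_spectrum` with observed curves and `ci_xy`, `ci_yx` bounds.
#' @export
permutation_ci <- function(ep, pair = c(1, 2), order, freqs = NULL,
                           n_perm = 1000, level = 0.999, scheme = "trials",
                           seed = 1, trials = NULL) {
  stopifnot(inherits(ep, "lfp_epochs"))
  if (n_perm < 100) warning("n_perm < 100 gives unstable extreme quantiles")
  ch <- vapply(pair, function(p) resolve_channel(ep, p), integer(1))
  if (is.null(trials)) trials <- which(ep$kept)
  if (is.null(freqs)) freqs <- seq(0, ep$fs / 2, by = 0.5)
  model <- fit_var(ep, ch, order, trials)
  obs <- spectral_gc(model, freqs)
  m <- order
  null_xy <- matrix(0, n_perm, length(freqs))
  null_yx <- matrix(0, n_perm, length(freqs))
  if (scheme == "trials") {
    pc <- gc_pair_blocks(ep, ch, m, trials)
    with_seed(seed, for (b in seq_len(n_perm)) {
      perm <- sample(length(trials))
      acc <- gc_assemble(pc, perm)
      g <- geweke_pair_from_acc(acc, m, freqs, ep$fs)
      null_xy[b, ] <- g$xy
      null_yx[b, ] <- g$yx
    })
  } else if (scheme == "blocks") {
    blk <- 4 * m
    with_seed(seed, for (b in seq_len(n_perm)) {
      eps <- shuffle_channel_blocks(ep, ch[2], blk, trials)
      mod <- fit_var(eps, ch, m, trials)
      g <- spectral_gc(mod, freqs)
      null_xy[b, ] <- g$gc_xy
      null_yx[b, ] <- g$gc_yx
    })
  } else stop("unknown scheme '", scheme, "'")
  obs$ci_xy <- apply(null_xy, 2, quantile, probs = level, names = FALSE)
  obs$ci_yx <- apply(null_yx, 2, quantile, probs = level, names = FALSE)
  obs$n_perm <- n_perm
  obs$level <- level
  obs$granularity <- 1 / n_perm
  obs
}

# Precompute per-ordered-trial-pair crossproducts so each trial-permutation
# VAR refit is an O(n_trials) sum instead of a full pass over the data.
gc_pair_blocks <- function(ep, ch, m, trials) {
  nt <- length(trials)
  ns <- dim(ep$data)[3]
  d <- m + 1
  Z1 <- vector("list", nt); Z2 <- vector("list", nt)
  for (i in seq_len(nt)) {
    x <- ep$data[trials[i], ch, , drop = TRUE]
    x1 <- x[1, ] - mean(x[1, ]); x2 <- x[2, ] - mean(x[2, ])
    L1 <- vapply(seq_len(m), function(l) x1[(m + 1 - l):(ns - l)],
                 numeric(ns - m))
    L2 <- vapply(seq_len(m), function(l) x2[(m + 1 - l):(ns - l)],
                 numeric(ns - m))
    Z1[[i]] <- cbind(L1, x1[(m + 1):ns])        # lags + response, channel 1
    Z2[[i]] <- cbind(L2, x2[(m + 1):ns])
  }
  # within-channel sums are permutation-invariant
  S11 <- Reduce(`+`, lapply(Z1, crossprod))
  S22 <- Reduce(`+`, lapply(Z2, crossprod))
  # cross blocks for every ordered pair (i pairs ch1 trial i with ch2 trial j)
  Z2big <- do.call(cbind, Z2)                   # (ns-m) x (nt*d)
  C <- vector("list", nt)
  for (i in seq_len(nt)) C[[i]] <- crossprod(Z1[[i]], Z2big)  # d x (nt*d)
  list(S11 = S11, S22 = S22, C = C, nt = nt, d = d,
       n_obs = nt * (ns - m))
}

# assemble pooled normal equations for pairing i -> perm[i]
gc_assemble <- function(pc, perm) {
  d <- pc$d; m <- d - 1; nt <- pc$nt
  S12 <- matrix(0, d, d)
  for (i in seq_len(nt)) {
    j <- perm[i]
    S12 <- S12 + pc$C[[i]][, ((j - 1) * d + 1):(j * d)]
  }
  list(S11 = pc$S11, S22 = pc$S22, S12 = S12, m = m, n_obs = pc$n_obs)
}

# Geweke spectrum from pooled pair blocks (channel-interleaved assembly)
geweke_pair_from_acc <- function(acc, m, freqs, fs) {
  d <- m + 1
  li <- seq_len(m)
  # X columns ordered [ch1 lag1..m | ch2 lag1..m] here; reorder to the
  # interleaved convention used by var_solve via explicit blocks instead
  XtX <- rbind(cbind(acc$S11[li, li], acc$S12[li, li]),
               cbind(t(acc$S12[li, li]), acc$S22[li, li]))
  XtY <- rbind(cbind(acc$S11[li, d], acc$S12[li, d]),
               cbind(acc$S12[d, li], acc$S22[li, d]))
  YtY <- matrix(c(acc$S11[d, d], acc$S12[d, d],
                  acc$S12[d, d], acc$S22[d, d]), 2, 2)
  B <- solve(XtX, XtY)                          # (2m) x 2, grouped layout
  sigma <- (YtY - crossprod(XtY, solve(XtX, XtY))) / acc$n_obs
  sigma <- (sigma + t(sigma)) / 2
  coeffs <- lapply(seq_len(m), function(l)
    rbind(c(B[l, 1], B[m + l, 1]), c(B[l, 2], B[m + l, 2])))
  geweke_pair(coeffs, sigma, freqs, fs)
}

# within-trial block shuffle of one channel (preserves autocovariance
# within blocks, destroys cross-channel alignment)
shuffle_channel_blocks <- function(ep, ch, blk, trials) {
  ns <- dim(ep$data)[3]
  nb <- floor(ns / blk)
  for (tr in trials) {
    ord <- sample(nb)
    idx <- as.vector(vapply(ord, function(b) ((b - 1) * blk + 1):(b * blk),
                            integer(blk)))
    keep <- if (nb * blk < ns) (nb * blk + 1):ns else integer(0)
    ep$data[tr, ch, ] <- c(ep$data[tr, ch, idx], ep$data[tr, ch, keep])
  }
  ep
}

#' Average spectral GC curves over the pairs of a dyad
#'
#' @param curves list of `gc_spectrum` objects on a common frequency axis.
#' @return list with `freqs`, `mean_xy`, `mean_yx`, `sem_xy`, `sem_yx`.
#' @export
average_dyad <- function(curves) {
  if (length(curves) == 0) stop("empty curve list")
  f <- curves[[1]]$freqs
  for (g in curves)
    if (length(g$freqs) != length(f) || max(abs(g$freqs - f)) > 1e-9)
      stop("curves must share a frequency axis")
  Mxy <- t(vapply(curves, function(g) g$gc_xy, numeric(length(f))))
  Myx <- t(vapply(curves, function(g) g$gc_yx, numeric(length(f))))
  n <- length(curves)
  sem <- function(M) if (n == 1) rep(0, ncol(M)) else apply(M, 2, sd) / sqrt(n)
  list(freqs = f, mean_xy = colMeans(Mxy), mean_yx = colMeans(Myx),
       sem_xy = sem(Mxy), sem_yx = sem(Myx), n_pairs = n)
}

#' @export
print.gc_spectrum <- function(x, ...) {
  cat(sprintf("Spectral GC, VAR(%d), %d freqs (%.1f-%.1f Hz)\n",
              x$order, length(x$freqs), min(x$freqs), max(x$freqs)))
  cat(sprintf("  peak 1->2: %.4f nats @ %.1f Hz | peak 2->1: %.4f nats @ %.1f Hz\n",
              max(x$gc_xy), x$freqs[which.max(x$gc_xy)],
              max(x$gc_yx), x$freqs[which.max(x$gc_yx)]))
  if (!is.null(x$ci_xy))
    cat(sprintf("  %g%% permutation bounds from %d permutations (granularity %.3g)\n",
                100 * x$level, x$n_perm, x$granularity))
  invisible(x)
}

#' @export
plot.gc_spectrum <- function(x, ...) {
  ylim <- range(0, x$gc_xy, x$gc_yx, x$ci_xy, x$ci_yx)
  plot(x$freqs, x$gc_xy, type = "l", col = "firebrick", ylim = ylim,
       xlab = "frequency (Hz)", ylab = "Granger causality (nats)", ...)
  lines(x$freqs, x$gc_yx, col = "navy")
  if (!is.null(x$ci_xy)) {
    lines(x$freqs, x$ci_xy, col = "firebrick", lty = 3)
    lines(x$freqs, x$ci_yx, col = "navy", lty = 3)
  }
  legend("topright", c("1 → 2", "2 → 1"),
         col = c("firebrick", "navy"), lty = 1, bty = "n")
  invisible(x)
}
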