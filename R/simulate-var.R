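#' Simulate epoched data from a stationary VAR process
#'
#' Draws independent trials from a vector-autoregressive process with known
#' coefficients, providing directed-coupling ground truth for coherence and
#' spectral Granger causality.  Each trial starts from a fresh burn-in so
#' trials are exchangeable; with a `modulation_gain` in the coupling spec the
#' off-diagonal coefficients are scaled per condition.
#'
#' @param spec a [coupling_spec()] (stationarity is enforced at construction).
#' @param paradigm a [paradigm_spec()].
#' @param seed integer master seed; per-trial streams are derived by counter,
#'   so identical seeds give identical output.
#' @param burn_in seconds of start-up transient discarded per trial.
#' @return An [lfp_epochs()] object with `t0 = -baseline`.
#' @export
simulate_var <- function(spec, paradigm = paradigm_spec(), seed = 1,
                         burn_in = 2) {
  stopifnot(inherits(spec, "coupling_spec"), inherits(paradigm, "paradigm_spec"))
  rho <- companion_spectral_radius(spec$var_coeffs)
  if (rho >= 1)
    stop("non-stationary VAR: companion spectral radius ",
         format(rho, digits = 4), " >= 1")
  k <- nrow(spec$var_coeffs[[1]])
  ns <- sum(epoch_samples(paradigm))
  nb <- round(burn_in * paradigm$fs)
  conds <- rep(paradigm$conditions, each = paradigm$n_trials_per_condition)
  nt <- length(conds)
  L <- t(chol(spec$noise_cov))
  out <- array(0, dim = c(nt, k, ns))
  for (i in seq_len(nt)) {
    coeffs <- spec$var_coeffs
    if (!is.null(spec$modulation_gain)) {
      g <- spec$modulation_gain[[conds[i]]]
      if (!is.null(g) && !is.na(g)) coeffs <- modulate_coeffs(coeffs, g)
    }
    out[i, , ] <- with_seed(derive_seed(seed, i),
                            var_trial(coeffs, L, ns, nb))
  }
  lfp_epochs(out, paradigm$fs, -paradigm$baseline, conds,
             region_labels = c("region1", "region2", rep(NA, max(0, k - 2)))[1:k])
}

# one trial: k x (n) after discarding nb burn-in samples
var_trial <- function(coeffs, L, n, nb) {
  k <- nrow(coeffs[[1]]); p <- length(coeffs)
  ntot <- n + nb
  eps <- L %*% matrix(rnorm(k * ntot), k, ntot)
  x <- matrix(0, k, ntot)
  all_zero <- all(vapply(coeffs, function(A) all(A == 0), logical(1)))
  if (all_zero) {
    x <- eps
  } else {
    for (t in seq_len(ntot)) {
      acc <- eps[, t]
      for (j in seq_len(min(p, t - 1)))
        acc <- acc + coeffs[[j]] %*% x[, t - j]
      x[, t] <- acc
    }
  }
  x[, (nb + 1):ntot, drop = FALSE]
}

#' Theoretical spectral matrix of a VAR process
#'
#' Evaluates `S(f) = H(f) Sigma H(f)^*` with
#' `H(f) = (I - sum_k A_k e^{-2 pi i f k / fs})^{-1}` on a frequency grid.
#'
#' @param coeffs list of lag coefficient matrices.
#' @param noise_cov innovation covariance.
#' @param freqs frequencies in Hz.
#' @param fs sampling rate in Hz.
#' @return list with `freqs`, `S` (k x k x nf complex array) and `H`
#'   (transfer functions, same layout).
#' @keywords internal
var_spectral_matrix <- function(coeffs, noise_cov, freqs, fs) {
  k <- nrow(coeffs[[1]]); p <- length(coeffs); nf <- length(freqs)
  S <- array(NA_complex_, c(k, k, nf))
  H <- array(NA_complex_, c(k, k, nf))
  for (j in seq_len(nf)) {
    A <- diag(k) + 0i
    for (l in seq_len(p))
      A <- A - coeffs[[l]] * exp(-2i * pi * freqs[j] * l / fs)
    Hj <- solve(A)
    H[, , j] <- Hj
    S[, , j] <- Hj %*% noise_cov %*% Conj(t(Hj))
  }
  list(freqs = freqs, S = S, H = H)
}
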