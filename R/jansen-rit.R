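#' Neural mass model parameters (Jansen-Rit type)
#'
#' Parameters of one cortical-column neural mass: pyramidal cells, excitatory
#' interneurons and inhibitory interneurons coupled through second-order
#' synaptic kernels `h(t) = H (t/tau) exp(1 - t/tau)` (equivalently
#' `H/tau * t * exp(-t/tau)` up to gain convention; here the rate form
#' `y'' = H k u - 2 k y' - k^2 y` with `k = 1/tau`).
#'
#' @param He excitatory synaptic gain, mV (default 3.25).
#' @param Hi inhibitory synaptic gain, mV (default 22).
#' @param tau_e,tau_i excitatory/inhibitory synaptic time constants, seconds
#'   (defaults 0.010 and 0.020, i.e. rate constants 100 and 50 per second).
#' @param C intrinsic connectivity scale; the four intrinsic gains are
#'   `C * c(1, 0.8, 0.25, 0.25)`.
#' @param e0,v0,r sigmoid parameters: maximal firing rate `2*e0` (per
#'   second), half-activation potential `v0` (mV) and slope `r` (1/mV).
#' @param p_mean,p_sd mean and SD of the stochastic pulse-density input to
#'   the excitatory PSP equation (per second).
#' @return An object of class `nmm_params`.
#' @export
nmm_params <- function(He = 3.25, Hi = 22, tau_e = 0.010, tau_i = 0.020,
                       C = 135, e0 = 2.5, v0 = 6, r = 0.56,
                       p_mean = 220, p_sd = 22) {
  stopifnot(tau_e > 0, tau_i > 0, He > 0, Hi > 0, C > 0)
  structure(list(He = He, Hi = Hi, tau_e = tau_e, tau_i = tau_i,
                 C1 = C, C2 = 0.8 * C, C3 = 0.25 * C, C4 = 0.25 * C,
                 e0 = e0, v0 = v0, r = r, p_mean = p_mean, p_sd = p_sd),
            class = "nmm_params")
}

nmm_sigmoid <- function(v, par) 2 * par$e0 / (1 + exp(par$r * (par$v0 - v)))
nmm_sigmoid_slope <- function(v, par) {
  s <- nmm_sigmoid(v, par)
  par$r * s * (1 - s / (2 * par$e0))
}

#' Simulate a coupled two-region Jansen-Rit dyad
#'
#' Numerically integrates two stochastic Jansen-Rit columns coupled by
#' forward (region 1 to region 2) and backward (region 2 to region 1)
#' connections -- extrinsic pyramidal firing from the source enters the
#' target's pyramidal excitatory drive -- with Euler-Maruyama at a fixed
#' step, then decimates to the paradigm sampling rate.  The observable is the net pyramidal membrane potential
#' `v = y1 - y2` per region.  Condition `u` in {+1, 0, -1} scales the
#' extrinsic gains by `exp(B * u)` where `B` is the per-direction modulation
#' gain.
#'
#' @param region_params list of two [nmm_params()] (recycled if one given).
#' @param coupling named numeric: `forward` = gain region1 -> region2,
#'   `backward` = gain region2 -> region1 (both >= 0).
#' @param modulation named numeric: log-scale modulation gains `forward`,
#'   `backward`, applied as `exp(B * u)` with u = +1 (positive), 0 (neutral),
#'   -1 (negative).
#' @param paradigm a [paradigm_spec()].
#' @param seed master seed; one derived stream per condition batch.
#' @param dt integration step in seconds (must be <= 0.001 and divide 1/fs).
#' @param burn_in discarded start-up transient per trial, seconds.
#' @return An [lfp_epochs()] object (trials x 2 regions x samples).
#' @export
simulate_jansen_rit_dyad <- function(region_params = list(nmm_params(), nmm_params()),
                                     coupling = c(forward = 0, backward = 0),
                                     modulation = c(forward = 0, backward = 0),
                                     paradigm = paradigm_spec(), seed = 1,
                                     dt = 0.001, burn_in = 2) {
  if (inherits(region_params, "nmm_params"))
    region_params <- list(region_params, region_params)
  stopifnot(length(region_params) == 2, dt <= 0.001 + 1e-12,
            all(coupling >= 0))
  dec <- (1 / paradigm$fs) / dt
  if (abs(dec - round(dec)) > 1e-9)
    stop("dt must divide the sampling interval 1/fs")
  dec <- round(dec)
  es <- epoch_samples(paradigm)
  ns <- sum(es)
  u_of <- c(positive = 1, neutral = 0, negative = -1)
  conds <- rep(paradigm$conditions, each = paradigm$n_trials_per_condition)
  nt_c <- paradigm$n_trials_per_condition
  out <- array(0, dim = c(length(conds), 2, ns))
  for (ci in seq_along(paradigm$conditions)) {
    cn <- paradigm$conditions[ci]
    u <- if (cn %in% names(u_of)) u_of[[cn]] else 0
    kf <- coupling[["forward"]] * exp(modulation[["forward"]] * u)
    kb <- coupling[["backward"]] * exp(modulation[["backward"]] * u)
    v <- with_seed(derive_seed(seed, ci),
                   jr_integrate_batch(region_params, kf, kb, nt_c,
                                      n_keep = ns, dec = dec, dt = dt,
                                      burn_in = burn_in))
    idx <- which(conds == cn)
    out[idx, 1, ] <- v[[1]]
    out[idx, 2, ] <- v[[2]]
  }
  lfp_epochs(out, paradigm$fs, -paradigm$baseline, conds,
             channel_labels = c("region1", "region2"),
             region_labels = c("region1", "region2"))
}

# Euler-Maruyama integration of n_trials independent dyads, vectorised
# across trials.  Returns list of two (n_trials x n_keep) matrices.
jr_integrate_batch <- function(rp, kf, kb, n_trials, n_keep, dec, dt, burn_in) {
  nb <- round(burn_in / dt)
  ntot <- nb + n_keep * dec
  p1 <- rp[[1]]; p2 <- rp[[2]]
  ke1 <- 1 / p1$tau_e; ki1 <- 1 / p1$tau_i
  ke2 <- 1 / p2$tau_e; ki2 <- 1 / p2$tau_i
  # states per region: y0, y1, y2 and their derivatives (matrices trials x 1)
  z <- function() numeric(n_trials)
  s1 <- list(y0 = z(), y1 = z(), y2 = z(), d0 = z(), d1 = z(), d2 = z())
  s2 <- list(y0 = z(), y1 = z(), y2 = z(), d0 = z(), d1 = z(), d2 = z())
  out1 <- matrix(0, n_trials, n_keep)
  out2 <- matrix(0, n_trials, n_keep)
  kcol <- 0
  bound <- 1e6
  for (t in seq_len(ntot)) {
    v1 <- s1$y1 - s1$y2
    v2 <- s2$y1 - s2$y2
    f21 <- nmm_sigmoid(v2, p2)   # firing of region 2 (source for backward)
    f12 <- nmm_sigmoid(v1, p1)   # firing of region 1 (source for forward)
    pin1 <- p1$p_mean + p1$p_sd * rnorm(n_trials)
    pin2 <- p2$p_mean + p2$p_sd * rnorm(n_trials)
    # Extrinsic afferents (source-region pyramidal firing) enter the
    # target's pyramidal excitatory drive: backward 2 -> 1, forward 1 -> 2.
    # (At the standard operating point the excitatory-interneuron sigmoid
    # is saturated, so extrinsic input routed inside it would not
    # transmit; the pyramidal excitatory target keeps both directions
    # effective and leaves direction as the discriminating feature.)
    a0_1 <- p1$He * ke1 * nmm_sigmoid(v1, p1)
    a1_1 <- p1$He * ke1 * (pin1 + p1$C2 * nmm_sigmoid(p1$C1 * s1$y0, p1) +
                             kb * f21)
    a2_1 <- p1$Hi * ki1 * p1$C4 * nmm_sigmoid(p1$C3 * s1$y0, p1)
    a0_2 <- p2$He * ke2 * nmm_sigmoid(v2, p2)
    a1_2 <- p2$He * ke2 * (pin2 + p2$C2 * nmm_sigmoid(p2$C1 * s2$y0, p2) +
                             kf * f12)
    a2_2 <- p2$Hi * ki2 * p2$C4 * nmm_sigmoid(p2$C3 * s2$y0, p2)
    s1$d0 <- s1$d0 + dt * (a0_1 - 2 * ke1 * s1$d0 - ke1^2 * s1$y0)
    s1$d1 <- s1$d1 + dt * (a1_1 - 2 * ke1 * s1$d1 - ke1^2 * s1$y1)
    s1$d2 <- s1$d2 + dt * (a2_1 - 2 * ki1 * s1$d2 - ki1^2 * s1$y2)
    s2$d0 <- s2$d0 + dt * (a0_2 - 2 * ke2 * s2$d0 - ke2^2 * s2$y0)
    s2$d1 <- s2$d1 + dt * (a1_2 - 2 * ke2 * s2$d1 - ke2^2 * s2$y1)
    s2$d2 <- s2$d2 + dt * (a2_2 - 2 * ki2 * s2$d2 - ki2^2 * s2$y2)
    s1$y0 <- s1$y0 + dt * s1$d0; s1$y1 <- s1$y1 + dt * s1$d1
    s1$y2 <- s1$y2 + dt * s1$d2
    s2$y0 <- s2$y0 + dt * s2$d0; s2$y1 <- s2$y1 + dt * s2$d1
    s2$y2 <- s2$y2 + dt * s2$d2
    if (t > nb && ((t - nb) %% dec == 0)) {
      kcol <- kcol + 1
      out1[, kcol] <- s1$y1 - s1$y2
      out2[, kcol] <- s2$y1 - s2$y2
    }
    if (t %% 1000 == 0 &&
        (max(abs(s1$y1)) > bound || max(abs(s2$y1)) > bound))
      stop("neural mass integration diverged (|state| > ", bound,
           "); check gains/time constants")
  }
  # remove per-trial mean (the DC operating point, not part of the LFP)
  list(out1 - rowMeans(out1), out2 - rowMeans(out2))
}

# --- linearised dyad (shared by the DCM forward model) ------------------

# Deterministic operating point (mean input, no noise), solved per region
# with the extrinsic inputs at zero: the linearisation expands around the
# uncoupled fixed point (standard small-signal assumption; coupling shifts
# of the operating point are second-order for weak extrinsic gains).
# Returns operating-point sigmoid slopes and state values per region.
jr_fixed_point <- function(rp, kf = 0, kb = 0) {
  one <- function(p) {
    ge <- p$He * p$tau_e; gi <- p$Hi * p$tau_i
    g <- function(v) {
      y0 <- ge * nmm_sigmoid(v, p)
      ge * (p$p_mean + p$C2 * nmm_sigmoid(p$C1 * y0, p)) -
        gi * p$C4 * nmm_sigmoid(p$C3 * y0, p) - v
    }
    grid <- seq(-30, 60, length.out = 61)
    gv <- g(grid)   # vectorised through the sigmoid
    sc <- which(diff(sign(gv)) != 0)
    if (length(sc) == 0) stop("no operating point found for parameter set")
    # self-consistency is monotone-bounded: take the largest root (the
    # branch the stochastic system relaxes to)
    j <- sc[length(sc)]
    v <- uniroot(g, c(grid[j], grid[j + 1]), tol = 1e-10)$root
    y0 <- ge * nmm_sigmoid(v, p)
    list(v = v, y0 = y0,
         rhoP = nmm_sigmoid_slope(v, p),
         rhoE = nmm_sigmoid_slope(p$C1 * y0, p),
         rhoI = nmm_sigmoid_slope(p$C3 * y0, p))
  }
  f1 <- one(rp[[1]])
  f2 <- if (identical(rp[[1]], rp[[2]])) f1 else one(rp[[2]])
  list(v = c(f1$v, f2$v), y0 = c(f1$y0, f2$y0),
       rhoP = c(f1$rhoP, f2$rhoP), rhoE = c(f1$rhoE, f2$rhoE),
       rhoI = c(f1$rhoI, f2$rhoI))
}

# Transfer matrix V(f) (2 x 2 x nf complex) of the linearised dyad from
# region innovations to observed pyramidal potentials, and the intrinsic
# loop gains.  Backward input kb enters region 1's pyramidal (he once);
# forward input kf enters region 2's excitatory interneurons (through
# C2 * rhoE).  `rho_scale` scales all sigmoid slopes (effective excitability).
jr_transfer <- function(rp, kf, kb, freqs, rho_scale = 1, fp = NULL) {
  p1 <- rp[[1]]; p2 <- rp[[2]]
  if (is.null(fp)) fp <- jr_fixed_point(rp, kf, kb)
  rhoP <- fp$rhoP * rho_scale; rhoE <- fp$rhoE * rho_scale
  rhoI <- fp$rhoI * rho_scale
  s <- 2i * pi * freqs
  he <- function(p) (p$He / p$tau_e) / (s + 1 / p$tau_e)^2
  hi <- function(p) (p$Hi / p$tau_i) / (s + 1 / p$tau_i)^2
  he1 <- he(p1); hi1 <- hi(p1); he2 <- he(p2); hi2 <- hi(p2)
  G1 <- rhoP[1] * (p1$C1 * p1$C2 * rhoE[1] * he1^2 -
                     p1$C3 * p1$C4 * rhoI[1] * he1 * hi1)
  G2 <- rhoP[2] * (p2$C1 * p2$C2 * rhoE[2] * he2^2 -
                     p2$C3 * p2$C4 * rhoI[2] * he2 * hi2)
  c12 <- he1 * kb * rhoP[2]   # region2 -> region1 (backward)
  c21 <- he2 * kf * rhoP[1]   # region1 -> region2 (forward)
  # M v = diag(he) p ; V = M^{-1} diag(he), closed-form 2x2 inverse
  m11 <- 1 - G1; m22 <- 1 - G2
  det <- m11 * m22 - c12 * c21
  nf <- length(freqs)
  V <- array(0i, c(2, 2, nf))
  V[1, 1, ] <- m22 * he1 / det
  V[1, 2, ] <- c12 * he2 / det
  V[2, 1, ] <- c21 * he1 / det
  V[2, 2, ] <- m11 * he2 / det
  V
}

# largest real part of the linearised system poles (stability check).
# Builds the 12-state linear ODE matrix and takes eigenvalues.
jr_linear_stability <- function(rp, kf, kb, rho_scale = 1, fp = NULL) {
  p1 <- rp[[1]]; p2 <- rp[[2]]
  if (is.null(fp)) fp <- jr_fixed_point(rp, kf, kb)
  rhoP <- fp$rhoP * rho_scale; rhoE <- fp$rhoE * rho_scale
  rhoI <- fp$rhoI * rho_scale
  # states: (y0, d0, y1, d1, y2, d2) x 2 regions
  A <- matrix(0, 12, 12)
  ke1 <- 1 / p1$tau_e; ki1 <- 1 / p1$tau_i
  ke2 <- 1 / p2$tau_e; ki2 <- 1 / p2$tau_i
  for (r in 1:2) {
    off <- (r - 1) * 6
    ke <- if (r == 1) ke1 else ke2; ki <- if (r == 1) ki1 else ki2
    A[off + 1, off + 2] <- 1
    A[off + 2, off + 1] <- -ke^2; A[off + 2, off + 2] <- -2 * ke
    A[off + 3, off + 4] <- 1
    A[off + 4, off + 3] <- -ke^2; A[off + 4, off + 4] <- -2 * ke
    A[off + 5, off + 6] <- 1
    A[off + 6, off + 5] <- -ki^2; A[off + 6, off + 6] <- -2 * ki
  }
  # region 1 drives: d0' += He ke rhoP1 (y1_1 - y2_1); etc.
  g1 <- p1$He * ke1; g2 <- p2$He * ke2
  A[2, 3] <- A[2, 3] + g1 * rhoP[1]; A[2, 5] <- A[2, 5] - g1 * rhoP[1]
  A[4, 1] <- A[4, 1] + g1 * p1$C2 * rhoE[1] * p1$C1
  A[6, 1] <- A[6, 1] + p1$Hi * ki1 * p1$C4 * rhoI[1] * p1$C3
  A[8, 9] <- A[8, 9] + g2 * rhoP[2]; A[8, 11] <- A[8, 11] - g2 * rhoP[2]
  A[10, 7] <- A[10, 7] + g2 * p2$C2 * rhoE[2] * p2$C1
  A[12, 7] <- A[12, 7] + p2$Hi * ki2 * p2$C4 * rhoI[2] * p2$C3
  # backward: region2 firing -> region1 y1 input
  A[4, 9] <- A[4, 9] + g1 * kb * rhoP[2]
  A[4, 11] <- A[4, 11] - g1 * kb * rhoP[2]
  # forward: region1 firing -> region2 y1 input
  A[10, 3] <- A[10, 3] + g2 * kf * rhoP[1]
  A[10, 5] <- A[10, 5] - g2 * kf * rhoP[1]
  max(Re(eigen(A, only.values = TRUE)$values))
}
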