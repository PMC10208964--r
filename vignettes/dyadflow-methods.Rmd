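---
title: "Methods: models, statistics and validation design in dyadflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, statistics and validation design in dyadflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

dyadflow analyses trial-structured intracranial LFP recordings from an
affective-picture paradigm and, because such clinical data cannot be
redistributed, validates every stage on synthetic data with known ground
truth. This vignette documents the models, the tunable parameters, the
numerical choices, and what the validation does and does not establish.

## The synthetic-data generator

The generator reproduces the acquisition and paradigm geometry used
throughout the package: 500 Hz sampling, epochs of 500 ms baseline plus
2000 ms post-stimulus (250 + 1000 samples), 30 trials in each of three
valence conditions (positive, neutral, negative), 2 s stimulus
presentation, and an inter-trial interval jittered uniformly on 1–1.5 s.

**Background.** Each channel's background is `1/f^χ` noise with `χ = 1`
plus a white floor at 1% of the 1 Hz level, synthesised exactly in the
frequency domain and normalised to unit variance. 1/f is the universal LFP
default; the floor keeps high-frequency bins non-degenerate.

**Condition effects.** A `burst_effect(condition, band, window, gain_dB)`
multiplies the expected band power inside its window by `10^(gain/10)`.
Positive gains add an independent band-limited noise burst (induced, not
phase-locked — ERSP measures induced power) with a 100 ms raised-cosine
on/off ramp; the burst variance is compensated for the ramp's mean square
so the window-average power hits the target exactly. Negative gains
attenuate the in-band component of the background inside the window
(event-related desynchronisation cannot be emulated by adding independent
noise). The default effect size (+3 dB) is chosen for testability; the
source recordings' per-contact effect sizes in physical units are unknown.

**Directed coupling.** `simulate_var()` draws independent trials from a
stationary VAR process (companion-matrix spectral radius < 1, enforced at
construction) with a 2 s burn-in per trial; trials are generated
independently because all analyses treat trials as exchangeable.

**Neural mass dyads.** `simulate_jansen_rit_dyad()` integrates two
stochastic Jansen–Rit columns (Euler–Maruyama, 1 ms step, decimated to
500 Hz, 2 s burn-in). Standard parameters: He = 3.25 mV, Hi = 22 mV,
τe = 10 ms, τi = 20 ms, C·(1, 0.8, 0.25, 0.25) with C = 135, sigmoid
2e₀/(1+exp(r(v₀−v))) with e₀ = 2.5 s⁻¹, v₀ = 6 mV, r = 0.56 mV⁻¹, and
stochastic drive p ~ N(220, 22) s⁻¹. At these values the column sits just
past a Hopf bifurcation and oscillates at ~11 Hz, giving the alpha-peaked
spectra expected of LFP. **Extrinsic routing:** source-region pyramidal
firing enters the *target's pyramidal excitatory drive* for both forward
(region 1 → 2) and backward (region 2 → 1) connections. The textbook
alternative of routing forward input into the excitatory-interneuron
sigmoid is not usable here: at the standard operating point that sigmoid
is saturated (slope ≈ 0.015), so input injected inside it does not
transmit. With pyramidal-drive routing, the direction of influence — which
is what the model space discriminates — remains fully identifiable.
Valence scales the extrinsic gains by `exp(B·u)`, `u ∈ {+1, 0, −1}`.

**Ratings.** `simulate_ratings()` maps per-condition band power (dB
relative to neutral) to a 0–100 rating through
`intercept + slope·power + N(0, noise_sd)`, clipped to the scale.
`simulate_association_study()` builds a cohort whose pooled power–rating
correlation is −0.6 by design: condition mean gains ±1 dB, between-patient
SD 1 dB, slope −6 ratings/dB and per-rating noise SD 8, giving
ρ = 6·σx/√((6·σx)² + 2·8²) ≈ 0.6 with the empirically measured pooled
power spread σx ≈ 1.4 dB (patient variation + condition shift + power
estimation noise at 10 trials/condition).

**Seeding.** Every generator is a pure function of its arguments and one
master seed; per-trial/subject/permutation streams are derived by a
counter through a multiplicative hash, so any unit can be regenerated in
isolation.

## Signal conditioning

Band-pass filtering uses a windowed-sinc (Hamming) linear-phase FIR
applied in a single pass with exact group-delay compensation, so the net
phase response is zero; the order follows the Hamming rule
≈ 3.3·fs/transition with the transition width defaulting to the low band
edge. Notches are 2 Hz-wide FIR band-stops at the line frequency and its
harmonics below the passband edge. Downsampling low-passes at 90% of the
new Nyquist before integer decimation; event onsets are remapped with
round-half-to-even. Bipolar re-referencing takes adjacent-contact
differences within a shaft; pairs straddling two regions are dropped
rather than assigned ambiguously. Epoching cuts −0.5..2 s windows; events
too close to the record edge are kept in the bookkeeping with reason
`"edge"` so that kept + rejected always equals the event count.

Spike-trial rejection automates a visual-inspection rule for inter-ictal
spikes (paroxysmal discharges shorter than 250 ms): a trial is rejected
when any channel shows a contiguous excursion of |z| > 6 (robust z from
the median and MAD over all trials) lasting at most 250 ms. Sub-threshold
dips shorter than 10 ms are bridged so one smooth transient counts once.
Longer paroxysms deliberately do not trigger this rule — it implements
the < 250 ms definition only.

## ERSP

FFT-based sliding-window analysis with a 256-sample (512 ms) Hann taper at
500 Hz, zero-padded to `round(fs/freq_step)` points (2500 for the 0.2 Hz
grid), trial-averaged power, and divisive dB baseline per frequency using
window centres at or before stimulus onset. Consequences worth knowing:
2 Hz is nominally inside the band but below the reliable resolution of a
512 ms window (maps are trustworthy from ~4 Hz); windows crossing epoch
edges are dropped, so the time axis covers ±256 ms less than the epoch;
and with a 500 ms baseline the baseline estimate rests on few effective
windows, so per-pixel ERSP noise scales roughly as √(2/n_trials) dB.
Trial averaging is of power, not complex spectra: the measure is induced
activity, blind to phase-locking.

## Cluster statistics

Per pixel, a paired t across contacts; pixels with two-tailed
`p < alpha_sample` (default 0.01) form clusters by sign and 4-connectivity
(the conservative reading of "connected sets"); clusters at or below
`min_size` pixels (default 500) are discarded; the cluster statistic is
the mass (sum of t). The null is the maximum |mass| of surviving clusters
under random sign flips of the paired differences, with the same size gate
applied inside each permutation — gating only the observed clusters would
break exchangeability between observed and null statistics. The
permutation p uses the add-one estimator, so the attainable floor is
`1/(n_perm+1)`. Because pixel area depends on the analysis grid, the
result object also reports the gate as an Hz·s area. The unpaired variant
(dyad contrasts) replaces sign flips by label shuffles, since dyads with
unequal pair counts cannot be sign-flipped.

## Association

Contact cluster means are averaged within patient; ratings are expressed
relative to neutral; positive and negative conditions each contribute one
row per patient (two points per patient), and Pearson correlation with a
two-tailed p is computed over the pooled rows, FDR-corrected across bands.
One pooled point per patient is a supported alternative.

## Coherence

Magnitude coherence (not imaginary coherence) from the same tapered
sliding-window engine as ERSP, with the trial index as the averaging
dimension and all conditions' kept trials pooled with equal weight. The
estimator is biased upward at small trial counts (null mean ≈ √(π/4n)),
which the tests check explicitly at 50 vs 200 trials.

## Spectral Granger causality

A VAR is fitted to each channel pair by pooled least squares across trials
(per-trial demeaning, no cross-trial products). Order selection minimises
AIC = ln|Σ| + 2·k²m/N over 1..20, with all orders scored on the common
sample conditioned at the largest order so that the log-determinant is
monotone and the comparison clean; the default cap comfortably admits the
7–12 range typical of 500 Hz LFP pairs. The Geweke measure uses the
standard noise-covariance rotation to remove instantaneous correlation and
is floored at zero against round-off. The permutation null re-pairs one
channel's trials at random (trials are the natural exchangeable blocks of
epoched data and preserve autocovariance exactly); a within-trial
block-shuffle with blocks of 4·order samples is available as an
alternative scheme. Bounds are pointwise 99.9% quantiles per frequency —
deliberately matching a per-frequency display convention, and liberal in
the family-wise sense. Permutation refits reuse per-trial-pair
cross-product blocks, making each refit an O(trials) sum.

## DCM on cross-spectral densities

Features are trial-averaged Hann-tapered cross-spectral matrices per
condition on 2–45 Hz. The generative model is the linearised two-region
Jansen–Rit dyad: second-order synaptic kernels `H·κ/(s+κ)²`, sigmoid
slopes evaluated at the *uncoupled* deterministic operating point
(coupling-induced shifts are second order), an effective-slope scale of
0.8 at the prior mean — full slope is marginally unstable, being exactly
the Hopf that makes the nonlinear column oscillate — innovations with a
1/f + white spectrum per region, and white observation noise. Effective
gains are `A·exp(B·u)` on modulated connections; all conditions are fitted
jointly, which is what makes the ±1/0 modulator identifiable.

Free parameters are log-scale deviations from the defaults (modulation
gains are linear, sign-carrying): τe, τi, slope scale (prior SD 0.25);
extrinsic gains, modulation gains, innovation amplitudes and observation
noise (prior SD 0.5). Inversion is Gauss–Newton ascent on the variational
free energy with EM updates of the residual precision, Levenberg damping
with step rejection (so the accepted free-energy trace is monotone
non-decreasing, an invariant the tests assert), convergence after three
successive improvements below 0.01 nats or 128 iterations, and a smooth
penalty on the largest real pole part when proposed parameters destabilise
the linearised system — the inversion degrades gracefully instead of
crashing. The innovation amplitude is calibrated once at the prior mean so
predicted and observed power share a scale; this constant is absorbed into
the parameterisation, not fitted.

The model space holds eight hypotheses: {F, B, FB} structures crossed with
modulation of F, of B, of both, or of neither, subject to modulation only
on existing connections. Random-effects BMS uses the Dirichlet-multinomial
variational scheme (α₀ = 1) with exceedance probabilities from 10⁵
Monte-Carlo Dirichlet draws.

## Validation design and problem sizes

The test suite checks each operation against an independent oracle
(closed forms, hand-computed examples, brute-force regressions, long
simulations) and then property-level behaviour end-to-end: cluster-test
family-wise error within Monte-Carlo bounds of nominal on 200 null
datasets (100×200 grids, 500 permutations, 20 contacts; calibration is
assessed on the ungated statistic, because a size gate truncates null
clusters and drives the family-wise error toward zero — the gate is a
deliberate conservatism, exercised separately); recovery of a
30 000-pixel +1 dB patch through the full >500-pixel gate with
Jaccard ≥ 0.3; spectral-GC directional nulls over 20 seeded
datasets at 1000 permutations; the Geweke band-integral identity within
5% on three stable VARs; the −0.6 designed power–rating correlation at
100 synthetic patients; and DCM model recovery — the backward-modulated
generator winning random-effects BMS over 10 subjects — across 20
replicates (32-iteration inversion cap, 1 Hz grid). These sizes are the
package's validation-study design: large enough for the stated tolerances,
small enough to run routinely.

What passing does **not** show: the generator has no volume conduction, no
shared reference, no epileptiform background beyond the injectable test
transient, no between-subject parameter heterogeneity in the DCM cohort,
and stationary 1/f noise rather than real LFP nonstationarity. Results on
real recordings inherit none of these guarantees.

## Known limitations

- ERSP values below ~4 Hz are under-resolved by the 512 ms window.
- The GC permutation bound is pointwise per frequency (no max-statistic
  correction across bins).
- The DCM is a reduced variational-Laplace implementation with a shared
  intrinsic parameter set across the two regions; it is not a port of the
  reference MATLAB machinery, and its absolute free energies are not
  comparable across different data normalisations.
- EDF export covers plain 16-bit EDF without annotations; BrainVision
  files are not read.
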