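---
title: "Models and methods behind counterphase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind counterphase}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(counterphase)
```

`counterphase` has two halves: a deterministic harmonic model of two
alternatively polyadenylated transcript isoforms, and a statistical pipeline
that mines expression time courses for probe pairs oscillating in opposite
phase. This vignette records the assumptions, parameter conventions,
numerical choices and open design decisions behind both, and what the
synthetic-data tests do and do not establish about real arrays.

## The two-isoform model

A gene's transcription rate oscillates sinusoidally; a fraction `p` of
transcripts becomes the long 3′-UTR isoform `n1`, the rest the short isoform
`n2`. Each isoform is removed at its own sinusoidally oscillating rate —
rhythmic miRNA action on the long isoform's extra UTR sequence is abstracted
into the decay amplitude `b`, with `c` the short isoform's counterpart:

$$\frac{dn_1}{dt} = p\,a\sin(\omega t+\alpha_1) - b\sin(\omega t+\alpha_2),
\qquad
\frac{dn_2}{dt} = (1-p)\,a\sin(\omega t+\alpha_1) - c\sin(\omega t+\alpha_3).$$

Three modelling conventions matter:

* **Decay is a rate, not a proportional loss.** The removal terms are pure
  sinusoids independent of current abundance. This keeps the system linear
  with a closed-form solution and is implemented literally; no
  proportional-decay correction is applied.
* **Signs are unconstrained.** Instantaneous rates and even abundances may
  go negative; the integration constants are exposed as explicit baseline
  offsets `m1`, `m2` (default 0) so users can shift trajectories into a
  non-negative range when emulating intensities.
* **`b > c` is biology, not algebra.** The "long isoform decays faster"
  regime motivates the model but the formulas hold without it, so
  `model_params()` documents rather than enforces it.

Integrating each equation gives one harmonic per isoform,
`n1 = A cos(wt + beta1)`, `n2 = B cos(wt + beta2)`. The amplitude follows
the cosine law applied to the two rotating vectors (production and decay);
the phase is the angle of their vector difference. The tangent form of that
angle loses the quadrant, which matters: with all phase angles zero and
`pa > b` the correct `beta1` is `pi`, not `0`. `isoform_waveform()`
therefore always applies the two-argument arctangent to the (numerator,
denominator) pair, and `phase_difference()` wraps `beta2 - beta1` to
`(-pi, pi]`. A wave whose numerator and denominator both vanish has zero
amplitude; it is flagged degenerate with phase defined as 0, and
`phase_difference()` refuses it.

The *rectifier* identity anchors the model tests: when the two waves have
equal amplitude and opposite phase (e.g. `a = 2, p = 0.5, b = 1.5, c = 0.5`,
all angles zero) the summed pool `n1 + n2` has amplitude exactly zero —
oscillating transcription, steady total transcript.

`integrate_ode()` is the model's independent numerical oracle: the classical
fixed-step fourth-order Runge–Kutta scheme with internal steps capped at
0.05 h. The right-hand side does not depend on the state, so the problem is
a quadrature and the scheme's error over two 24 h periods is far below the
1e-6 tolerance the tests assert against the analytic solution.

## What the synthetic generator emulates

`generate_panel()` reproduces the statistical structure the datamining
assumes, for the two study designs the pipeline targets:

* **mouse-like**: 0–24 h sampled every 4 h in duplicate (7 nominal time
  points including both endpoints, 14 arrays);
* **arabidopsis-like**: 0–44 h sampled every 4 h singly (12 arrays).

Rhythmic probes follow `baseline + amplitude * cos(2*pi*(t - phi)/24)` with
additive Gaussian noise; non-rhythmic probes are baseline plus noise.
Defaults are chosen once as plausible for normalized arrays: baselines
log-uniform on 50–500 (intensity spread), amplitudes 20–50 % of baseline
(robust oscillations), noise 10 % of amplitude, 30 % of genes rhythmic, and
15 % of multi-probe rhythmic genes planted as exact counter-phase pairs
(peaks 12 h apart) — the last matching the planted-fraction scenario the
end-to-end detection checks use. The rhythmic fraction and noise level of
the real arrays are unknown; these are calibration knobs, not claims.

Planted phases sit by default on the 4 h grid of phase-class *centres*
(0, 4, ..., 20 h). This is a deliberate choice: with six classes defined by
`round(phi/4) mod 6`, phases at odd multiples of 2 h lie exactly on class
boundaries, where the discrete label is ambiguous under any perturbation —
even floating-point jitter — and no estimator can recover it reliably. The
centre grid is the only planting scheme under which "exact class recovery at
zero noise" is a meaningful property. Boundary-including 2 h planting
(`phase_grid_h = 2`) and fully continuous phases (`phase_grid_h = NULL`)
remain available; continuous-phase recovery is exact at zero noise
regardless of the grid.

The generator does **not** emulate probe-level cross-hybridization,
chip geometry, intensity-dependent (multiplicative) noise,
normalization artefacts, or genes whose isoform phase lag is intermediate
rather than 0 or 12 h. Passing tests therefore demonstrate that the
pipeline recovers planted structure under idealized additive noise; they do
not certify performance on raw array data, where the confidence filter has
to do the heavy lifting the spec-level simulations make easy.

## Phase assignment

The published description of the assignment algorithm has three
ingredients: bootstrap replications of each probe's series, a bootstrapped
rhythmicity test, and a bootstrap percentile interval for the phase. The
concrete constructions here are the package's own choices:

* **Phase estimate**: least-squares first harmonic at the 24 h frequency
  (duplicate samples averaged first; duplicates are replication, not time
  structure). The peak time `phi` of the fitted cosine, in `[0, 24)` h, is
  the continuous phase; `round(phi/4) mod 6` the class; the harmonic's
  variance fraction the strength. Constant series have no phase and are
  flagged, never silently dropped.
* **Rhythmicity**: a permutation test. The statistic is the first-harmonic
  variance fraction; the null shuffles values across samples;
  `p = (1 + #[null >= obs]) / (n_perm + 1)`, so a noiseless cosine at 999
  permutations reaches the floor 1/1000 and a constant series returns 1 by
  convention. Under white noise the p-values are uniform (checked by a
  seeded Kolmogorov–Smirnov distance < 0.05).
* **Phase confidence**: the maximum-entropy bootstrap builds replicate
  series that keep the original rank ordering while resampling values from
  a piecewise-linear maximum-entropy density anchored on the order
  statistics (midpoint interval limits, ends extended by the 10 %-trimmed
  mean absolute difference, interval means adjusted to preserve the sample
  mean — the conventional defaults of the construction). The mean-preserving
  shifts can locally break the quantile map's monotonicity, so draws are
  sorted before rank placement, making rank preservation structural. Phase
  is re-estimated on every replicate; the confidence p-value is one minus
  the modal class fraction, and the central 90 % circular percentile
  interval of replicate phases is reported. Because replicates are genuine
  resamples, even a noiseless cosine yields a non-degenerate (if very
  narrow) interval; tests assert a small width rather than exactly zero.
* **Seeding**: one master seed; per-probe substreams derived
  deterministically from the probe index, so results do not depend on
  evaluation order and are bit-reproducible.

Whether the published filter p-value is the rhythmicity p or the
phase-confidence p is not recoverable; the pair filter defaults to the
phase-confidence p (`p_column = "p_phase"`), which is the quantity the
percentile interval is built for, with the rhythmicity p available as a
switch. Exact reproduction of the original study's per-probe p-values is
not promised — the original test statistic is not specified at this level
of detail.

## Pair analysis

Probes are grouped by exact gene-symbol match (mouse annotations) or as
connected components of the probe–identifier graph over RefSeq transcript,
AGI and Entrez fields (Arabidopsis annotations, `"///"`-delimited
multi-values split), so identifier chains merge transitively. Within each
group, all unordered pairs of probes passing the filter (`p <= 0.1`, ties
kept) contribute the absolute circular difference of their *continuous*
phases, folded to `[0, 12]` h and binned as `round(d/2)` into seven 2 h
classes. Two decisions deserve note:

* **Seven bins, df = 6.** A zero-difference bin plus one bin per
  pi/6 cyclic shift. The corroboration is arithmetic: the chi-square upper
  tail at df = 6 reproduces the published tissue-level p-values from their
  printed statistics (46.45 → 2.4e-08, 74.21 → 5.6e-14), and no other df
  does.
* **Continuous differences, not class differences.** Differences of the six
  coarse classes could only ever be even numbers of hours; the odd bins
  (2, 6, 10 h) are reachable only if differences are computed on continuous
  phases first. That is the reading implemented.

## Goodness of fit

Under stochastic decay, pair counts fall off with increasing difference;
the null models bin counts as Poisson over the bin index, `lambda` fitted
by maximum likelihood (the count-weighted mean index). Expected counts lump
the upper tail `P(K >= 6)` into the last bin so they sum exactly to the
total (renormalizing the truncated mass is available as a flag; at
`lambda ~ 1.5–2` the two differ by well under a percent). The chi-square
test keeps `df = 6 = bins − 1` with *no* subtraction for the estimated
rate — the convention of testing against supplied probabilities, and the
only df consistent with the published results.

Consequences, measured by the calibration tests: the Monte Carlo test at a
known rate is exactly calibrated (uniform p-values, 5 %-level rejection
within [0.03, 0.07] over 1000 simulated tables of 1000 pairs), while the
full fit-then-test procedure is mildly conservative (true 5 %-level rate
near 0.027) because the estimated `lambda` absorbs about one degree of
freedom. The procedure never becomes anti-conservative, which is the
property that matters for the counter-phase claim: rejections are not
manufactured by the convention. Monte Carlo p-values use the add-one rule
`(1 + #[X2* >= X2]) / (reps + 1)` and so never return zero; 1000-replicate
runs bottom out at 1/1001. A histogram with all mass in bin 0 fits the
`lambda = 0` Poisson exactly; it is reported as `X2 = 0, p = 1` rather than
run through the chi-square machinery, whose expected-count floor
(default 1e-8) otherwise refuses near-degenerate fits and points users to
the Monte Carlo mode.

## Problem sizes and runtime

The shipped tests and the acceptance script run at desk scale, chosen so
the full suite completes in about a minute: panels of 250–500 genes,
50–200 bootstrap replicates, 49–199 permutations per probe, 1000 simulated
tables for calibration, and 999–10,000 Monte Carlo replicates for the
goodness-of-fit checks. All are parameters; nothing in the implementation
depends on these sizes.

## Known limitations

* Arrays cannot tell which probe maps to the long versus short isoform, so
  the direction of the phase shift is unresolved and the planted-pair
  counting is symmetric.
* The period is fixed at 24 h; no period estimation is attempted, and no
  multiple-testing correction is applied across probes (the filter operates
  on raw p-values at 0.1, as in the analysis the pipeline reproduces).
* The decay model is abundance-independent by construction; regimes where
  proportional decay matters (strong turnover modulation) are outside the
  model family.
* The confidence filter preferentially retains probes whose phases sit away
  from class boundaries; pair retention is therefore not uniform over
  planted phase, which matters when interpreting retained-pair counts as
  population fractions.
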