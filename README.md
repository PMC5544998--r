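# counterphase

Mining circadian expression time courses for counter-phase alternatively
polyadenylated transcript isoforms.

## The problem

Many genes are transcribed into two 3′-UTR isoforms through alternative
polyadenylation (APA): a long isoform that carries extra regulatory sequence
(e.g. miRNA target sites) and a short one that lacks it. When transcription
oscillates with a circadian rhythm but the two isoforms decay at different
rhythmic rates, their abundance peaks drift apart — up to exact
counter-phase, where the summed transcript pool is *constant* even though
transcription oscillates. The mechanism acts like a molecular rectifier,
converting an oscillating input into a steady output.

On standard expression microarrays this leaves a detectable footprint:
redundant probe sets that interrogate the same gene sometimes report robust
oscillations in *opposite* phase. `counterphase` implements both sides of
the story for computational biologists working with circadian microarray or
expression time-course data:

* the **two-isoform harmonic model** that predicts when counter-phase
  arises, and
* the **datamining pipeline** that detects counter-phase probe pairs in a
  probes × samples time-course matrix and tests whether their excess can be
  explained by chance.

## The model

Let a fraction *p* of transcripts become the long isoform *n₁* and *1 − p*
the short isoform *n₂*, with sinusoidal production and decay rates sharing
one angular frequency ω:

    dn₁/dt = p·a·sin(ωt + α₁) − b·sin(ωt + α₂)
    dn₂/dt = (1−p)·a·sin(ωt + α₁) − c·sin(ωt + α₃)

Each isoform is then a single harmonic, n₁(t) = A·cos(ωt + β₁) and
n₂(t) = B·cos(ωt + β₂), with closed-form amplitudes and quadrant-correct
phases, e.g.

    A = √( (pa/ω)² + (b/ω)² − (2pab/ω²)·cos(α₁ − α₂) ),
    β₁ = atan2( b·sinα₂ − pa·sinα₁ , b·cosα₂ − pa·cosα₁ ).

The summed pool n₁ + n₂ has amplitude √(A² + B² + 2AB·cos(β₂ − β₁)); when
A = B and β₂ − β₁ = π it is exactly zero — the rectifier regime.

The pipeline side assigns each probe a peak time (first harmonic at the
24 h frequency), a permutation rhythmicity p-value, and a
maximum-entropy-bootstrap phase-confidence p-value; groups probes by gene;
computes all within-gene absolute circular phase differences; bins them
into seven 2 h classes (0–12 h); and tests the histogram against a Poisson
"stochastic decay" null with a chi-square (df = 6) and a Monte Carlo
p-value. Rejection driven by the 12 h bin is the counter-phase signal.

## Worked example

Simulate a mouse-style design (0–24 h every 4 h, duplicates) with 15 % of
multi-probe rhythmic genes planted in counter-phase, then run the full
pipeline:

```r
library(counterphase)

pr <- rectifier_params()
phase_difference(pr)   # 3.141593  (the isoforms are exactly counter-phase)
sum_amplitude(pr)      # 0         (their sum does not oscillate)

panel <- generate_panel(make_design("mouse"), n_genes = 400,
                        frac_rhythmic = 0.4, frac_counterphase = 0.15,
                        noise_frac = 0.1, seed = 405)
res <- run_pipeline(panel$expression, panel$annotation, seed = 405,
                    bootstrap_replicates = 100, n_perm = 99, mc_reps = 999)
res
#> Counter-phase mining pipeline result
#>   dataset: dataset (seed 405)
#>   probes_total     635
#>   phase_undefined  0
#>   filtered_by_p    279
#>   retained         356
#>   pairs            125
#>   histogram_total  125
#>   lambda = 1.088, X2 = 2629.85, p = 0
glance(res$gof)
#> # A tibble: 1 × 7
#>   lambda n_pairs statistic    df p.value p.value.mc mc_reps
#>    <dbl>   <int>     <dbl> <int>   <dbl>      <dbl>   <dbl>
#> 1   1.09     125     2630.     6       0      0.001     999
```

Of 635 probes, 356 pass the phase-confidence filter (p ≤ 0.1) and form 125
within-gene pairs. Most pairs agree in phase (bin 0 holds 96 of them), but
17 pairs sit a full 12 h apart — far above the ~0.1 pairs a Poisson decay
with λ ≈ 1.09 would put there — so the stochastic-decay null is rejected
(X² = 2630 at df = 6; Monte Carlo p = 0.001, the smallest value 999
replicates can report). `autoplot(res$histogram)` and `autoplot(res$gof)`
draw the histogram and the fit; `tidy(res$gof)` tabulates observed versus
expected counts per bin.

A thin command-line front end with `simulate`, `phase`, `pairs`, `gof` and
`run` subcommands lives at `inst/cli/counterphase.R`.

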