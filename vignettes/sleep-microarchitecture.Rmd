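---
title: "Sleep–wake microarchitecture: bouts, counts, durations, and transition heatmaps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sleep–wake microarchitecture: bouts, counts, durations, and transition heatmaps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hypnostats)
```

## The analysis problem

Rodent sleep studies score EEG/EMG recordings into discrete vigilance
states on a fixed epoch grid (4 s here): active wake (AW), passive wake
(PW), light and deep slow-wave sleep (S1, S2), the intermediate stage
(IS), and REM sleep (REMS). The conventional analysis — percent time per
state — discards most of the dynamics. This package implements a
bout-level analysis: a *bout* is a maximal run of identical-state epochs,
and the questions become how often bouts of each state occur, how long
they last, and *which state follows which* — the transition structure of
the sleep–wake cycle. The motivating application is a crossover
pharmacology design (6 subjects, vehicle and two dose levels, 3 h of
post-injection recording), where a drug may act on bout *frequencies*,
bout *durations*, or specific transition *pathways*, and these mechanisms
must be distinguished.

## Bout processing

`segment_bouts()` is run-length encoding of the epoch sequence; it is the
exact, forced construction, checked in the test suite against a naive
per-epoch scan. Bout-duration distributions are heavily right-skewed with
a "spike and slab" structure — many very short bouts plus rare long ones —
most pronounced for REMS. `reclassify_rems()` therefore splits REMS bouts
at a cutoff of 4 epochs (16 s) into short (`REMS_S`) and long (`REMS_L`)
bouts, which behave as distinct states downstream (for example, `REMS_L`
is typically followed by IS; `REMS_S` is not).

Time-resolved analyses cut the 3-h window into three 1-h bins (900
epochs). A bout belongs to the bin containing its **onset**; a bout
spanning a boundary is counted once, in its onset bin, with its full
duration. This keeps counts integral and avoids an arbitrary splitting
rule. The final truncated bout of a recording is kept as-is: no censoring
adjustment is applied, because the downstream models compare groups whose
truncation behaviour is identical by design.

### NREM sleep latency

`nrem_latency()` scores the time from drug administration to the first
qualifying NREM sleep episode. An episode is a stretch of NREM-superset
states (S1, S2, IS) that accumulates at least 3 min (45 epochs) of NREM
content, tolerating interruptions of at most 14 consecutive epochs and at
most 240 s (60 epochs) in total; exceeding either limit fails the episode
and the scan resumes after the offending run. Two readings of "lasting at
least 3 min" are possible — NREM content only, or wall time including
tolerated interruptions. The default counts NREM content only: the
interruption budget alone (240 s) exceeds 3 min, so the wall-time reading
could qualify an episode that is mostly not sleep. The wall-time reading
remains available via
`latency_params(episode_length_counts_interruptions = TRUE)`. Failure on
the cumulative budget is triggered at budget exhaustion (the 61st
interrupting epoch), not retroactively at the first interruption.

## Count and duration models

`count_bouts()` materializes a zero-filled subject × treatment × state ×
bin count table. `estimate_frequency_ratios()` fits a log-link negative
binomial regression (`MASS::glm.nb`) of counts on treatment, time bin,
and subject, and reports `exp` of the treatment coefficients — the
multiplicative bout-frequency ratio of each dose versus vehicle — with
95% Wald intervals. Two deliberate modelling choices:

* **Subject is a fixed blocking effect, not a random effect.** With six
  subjects a random-intercept negative binomial model is numerically
  fragile and its variance component is poorly identified; the fixed-
  effect formulation leaves the estimand (the within-subject dose ratio)
  unchanged. The test suite verifies ~95% interval coverage of both a
  null ratio and a planted 2× fold change under this formulation.
* **Boundary cases are flagged, not fitted.** A dose whose counts are all
  zero puts the coefficient on the boundary of the parameter space; the
  function reports it as not estimable rather than returning a diverging
  estimate. If the dispersion parameter itself is unidentifiable the fit
  falls back to Poisson with a warning.

`fit_duration_model()` log-transforms bout durations (they are strongly
right-skewed) and fits a linear model with treatment, bin, their
interaction, and subject blocking. The time × treatment interaction — the
question "does the drug change how durations evolve over the hours?" — is
tested by the F-ratio of residual mean squares of the nested fits with
and without the interaction. Cell-wise predicted mean log-durations with
confidence intervals, averaged over subjects (via `emmeans`), support the
graphical overlap assessment; back-transform with `exp()`. Constant
responses make both residual sums of squares numerically zero; the F
statistic is then defined as 0 (no interaction) rather than 0/0 noise.

No multiplicity adjustment is applied anywhere: nominal p-values are
reported, and the heatmap uses the conventional ±2 threshold as a visual
rule of thumb, not a formal test.

`pk_decline_percent()` is a small utility for the design context: under
one-compartment first-order elimination, a drug with a 22-h half-life
declines only `100 * (1 - 2^(-3/22))` ≈ 9.0% over a 3-h window, so
time-dependent effects within the window are not attributable to drug
elimination.

## The transition heatmap

`cross_tabulate()` counts successions of bouts (never across subjects):
`O[i, j]` is the number of times a state-`i` bout was immediately
followed by a state-`j` bout. The diagonal is structurally zero — a
maximal run cannot be followed by itself. A transition belongs to the bin
of the successor bout's onset, consistent with bout binning. Per
(treatment, hour) panel, transitions are pooled over subjects: per-rat
hourly tables at n = 6 would be almost entirely masked.

Under the "no preference" null the transition probability factorizes into
the row and column marginals, giving expected counts `E = R C / N`
computed over the full table *including* the structural-zero diagonal —
this is deliberately the naive construction, with no quasi-independence
correction. The standardized residual

* Pearson: `z = (O - E) / sqrt(E)` (default), or
* adjusted: `z = (O - E) / sqrt(E (1 - R/N) (1 - C/N))`,

measures preference (positive) or inhibition (negative) of each pathway;
`|z| > 2` is the conventional significance rule of thumb. Cells with
fewer than five **observed** transitions, and the diagonal, are masked
(gray): z cannot properly be estimated there. Masking on the expected
count, and a probability-scale residual (the count-scale z divided by
`sqrt(N)`), are available behind flags; the ±2 convention presumes the
count scale, which is why that is the default.

### Calibration of the ±2 rule, and a known limitation

Because expected counts are computed over a table whose diagonal can
never be observed, the naive independence null is misspecified: under a
true no-preference process the off-diagonal cells are inflated relative
to `E` by a term of order `sqrt(E) * sum_i p_i q_i`, which **grows with
the table total `N`**. Simulation (in the test suite) quantifies this:
with six states and realistic marginals, the proportion of unmasked
`|z| > 2` under a no-preference succession process is about 8% at
N = 300 transitions — the size of a pooled six-subject hourly panel, and
the regime in which the ±2 rule behaves as a usable screen — but rises to
roughly 30% at N = 2000. The practical reading: the heatmap is a
well-calibrated exploratory screen at the per-panel sizes this design
produces, and becomes anti-conservative if many hours or subjects are
pooled into one very large table. Users pooling at that scale should
interpret moderate |z| values cautiously; correcting the null for
structural zeros (quasi-independence fitting) is intentionally out of
scope, as the method's purpose is a faithful, simple screen.

## The hypnogram simulator

The original animal recordings are not publicly available, so every
pipeline stage is exercised against `simulate_study()`, a semi-Markov
generator whose defaults encode the study conditions: 6 subjects × 3
treatments × 2700 four-second epochs.

* **Dwell law**: per state, a two-component mixture of shifted geometric
  distributions (`1 + Geometric`), the discrete memoryless analogue of
  the spike-and-slab duration structure; mixture means are analytic
  (`dwell_mean()`), so observed mean dwells are testable. Mixtures are
  shared across treatments and hours, encoding the finding the pipeline
  must be able to recover: the drug alters transition frequencies, not
  state durations.
* **Embedded transition matrices** per (treatment, hour): zero diagonal,
  rows summing to 1. The vehicle matrices route AW ↔ PW ↔ S1 → S2 with
  S2 → IS/REMS → IS returns and relax wake–wake traffic over the hours;
  dosed matrices tilt all rows toward AW and starve IS (low dose) and
  additionally S2 (high dose), most strongly in hour 1. These values are
  qualitative mimics of rodent sleep architecture chosen once for
  realism; they are not estimates of any animal's physiology.
* **Regime switching**: parameters change at the 900- and 1800-epoch
  boundaries; the current state carries over and the next transition is
  drawn under the new regime — the simplest scheme consistent with
  hourly contingency tables.
* **Determinism**: each hypnogram's seed is a documented integer hash of
  (master seed, subject index, treatment index); the whole study is a
  pure function of its `sim_config`, and simulation never perturbs the
  caller's RNG stream.

What the simulator does *not* emulate: continuous circadian modulation
(hour effects are piecewise-constant), dependence of dwell time on the
*previous* state, scorer noise, and inter-subject heterogeneity in the
transition matrices. Passing tests therefore demonstrate correctness of
the statistical machinery under a controlled generative model, not
biological validity of any particular estimate.

## Problem sizes and numerical choices

The test suite uses study-scale simulations (6 × 3 × 2700 epochs) for
end-to-end checks, 200-replicate Monte-Carlo loops for coverage, power,
and calibration properties, and a one-million-epoch single-regime run for
convergence of empirical successor frequencies to the embedded matrix
(total-variation distance below 0.02 per row). Exported transition CSVs
print z with 17 significant digits so the files round-trip exactly.
Validation tolerances: simulator rows must sum to 1 within 1e-9;
vectorized z-statistics match a scalar oracle to 1e-12.

## A worked run

```{r example, fig.width = 7, fig.height = 6}
cfg <- default_sim_config(seed = 42L)
study <- simulate_study(cfg)
bouts <- study_bouts(study)

counts <- count_bouts(bouts)
estimate_frequency_ratios(counts, "AW")

grid <- heatmap_grid(bouts)
grid$plot
```
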