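---
title: "Rhythm analysis of oral poetry reading: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rhythm analysis of oral poetry reading: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(verserhythm)
```

## The scientific question

When a reader performs conventional metered poetry aloud, the metrical grid
— the alternation of strong and weak syllable positions that defines an iamb
(weak–strong) or a trochee (strong–weak) — leaves measurable traces in the
speech signal: stressed positions tend to be lengthened and produced with
more intensity, and the regular alternation produces a characteristic
contrast between adjacent syllables.  A useful experimental probe is to
replace single syllables of a poem at random grid positions with the
lexically meaningless syllable *tack*: the substitute keeps the metrical
slot but removes lexical support, so its realisation reveals how strongly
the reader's timing is driven by the grid itself.

`verserhythm` implements the complete desk-scale analysis for this paradigm:
stimulus representation, annotation ingestion, feature extraction, rhythm
statistics and hierarchical inference, together with a generative simulator
so every stage can be exercised and calibrated without audio recordings.

## Measures

**Syllable onset interval (SOI).**  For each syllable the SOI runs from its
onset to the onset of the following syllable.  Within a verse line this
integrates speaking pauses: a hesitation after a syllable lengthens that
syllable's SOI.  The pause at the end of a line is *not* part of any SOI —
the line-final syllable's SOI is its own duration.  SOIs above 2000 ms
(strictly) are flagged and excluded from modelling; the threshold is applied
after SOI computation, so it can only ever remove within-line hesitations.

**Mean intensity.**  A per-syllable mean level in dB, consumed as a table
keyed by interval (in a recording study it comes from an acoustic script;
here the generator supplies it).

**nPVI.**  The normalized pairwise variability index of an ordered sequence
$d_1,\dots,d_m$ ($m \ge 2$):

$$\mathrm{nPVI} \;=\; \frac{100}{m-1}\sum_{k=1}^{m-1}
  \frac{\lvert d_k - d_{k+1}\rvert}{(d_k + d_{k+1})/2}.$$

It is zero exactly for constant sequences, bounded by 200, scale-invariant
and reversal-invariant.  Some printed presentations of this index show the
pair *difference* instead of the pair *mean* in the denominator; that
variant degenerates (every term becomes $\pm 2$), so the package implements
only the standard mean-denominator form and does not offer the degenerate
one.  Per line we compute the nPVI over syllable SOIs (`npvi_soi`) and over
syllable intensities (`npvi_i_mean`), using the same SOI values as the
syllable-level analysis (line-final SOI = duration).

## The models

All models are Gaussian linear mixed models estimated by REML with `lme4`,
with Satterthwaite degrees of freedom via `lmerTest`.  Binary predictors are
sum-coded $\pm 1$ — strong stress, musically active, iambic meter, and the
line-*without*-tack level are $+1$ — so the intercept is the grand mean and
the model-implied difference between the two levels of a binary factor is
twice its coefficient.  The four canonical specifications are:

* **Regular syllables** (`spec_regular()`): response SOI (ms) or intensity
  (dB); fixed effects stress × musical × meter; random intercept and stress
  slope per participant, random intercept per syllable.
* **Tack syllables** (`spec_tack()`): the tack index — the 1-based ordinal
  of a tack among the tacks of its line, ranging 0–5 in practice — joins the
  factorial as a numeric predictor; the syllable random intercept is
  dropped (every tack is the same syllable).
* **Line level** (`spec_line()`): response `npvi_soi` or `npvi_i_mean`;
  the tack predictor is either the binary tack-line contrast or the
  grand-mean-centered tacks-per-line count; random intercept and predictor
  slope per participant, random intercept per poem.  An instruction variant
  lets the sum-coded 3-level instruction factor interact with the same
  predictors, to check whether musicality effects survive the (confounded)
  instruction assignment.

**Two-pass outlier filtering.**  Each model is fitted twice: residuals of
the first fit outside the Tukey boxplot fences (`boxplot()` hinges
± 1.5 × hinge-IQR; values exactly on a fence are kept) mark rows that are
dropped before the second, reported fit.  We use the `fivenum()` hinge
convention rather than `quantile()` quartiles because that is what
`boxplot(range = 1.5)` does; at study sizes the difference is negligible,
but the oracle tests pin the hinge convention exactly.

**Effect sizes.**  Cohen's $d = 2t/\sqrt{df}$ from the coefficient's $t$
and its Satterthwaite $df$; $|d| \le 0.1$ is suppressed in reports.  This
formula reproduces some published effect sizes exactly (e.g.
$d(3.09, 16.53) = 1.52$) and not others (a printed 4.77 where the formula
gives 4.90); the formula is fixed and such mismatches are documented, never
fitted.

**Variance reporting.**  ICC is the random-intercept share
$\sum\tau_{00} / (\sum\tau_{00} + \sigma^2)$; marginal and conditional $R^2$
follow the variance-partitioning convention (fixed-effect variance over
total, and fixed-plus-random over total, with random-slope contributions
averaged over the design).

## The synthetic oral reader

No public recordings exist for this paradigm, so the package includes a
first-class generative module that mirrors the fitted hierarchical models:

* **Stimuli** (`study_poems()`): six poems — three iambic, three trochaic —
  with syllable totals 273, 270, 76, 68, 154 and 150 (one partly
  catalectic), laid out over 120 verse lines.  Tacks are placed by
  independent per-slot Bernoulli draws at rate 0.18, never before line 3,
  capped at 5 per line.  The rate is not reported for the original stimuli;
  0.18 makes roughly one syllable in six a tack, which reproduces both the
  observed tack-row counts (about 2,000 tack tokens across 13 readers) and
  the observed 0–5 tacks-per-line range, and it is fixed once here, not
  adjusted per analysis.
* **Readers** (`study_participants()`): 13 profiles, 6 musically active and
  7 not (derived from the questionnaire coding rule implemented in
  `code_musical()`), with the study's instruction assignment (3 active + 1
  inactive with no instruction, 3 + 2 rhythmic, 0 + 4 on-beat).
* **Responses** (`simulate_syllables()`, `simulate_lines()`): each response
  is the sum-coded linear predictor plus participant intercept, participant
  stress (or tack-predictor) slope with the reported intercept–slope
  correlation, a syllable intercept for regular syllables only, a poem
  intercept at line level, and Gaussian residual noise.  The default
  parameter sets (`generative_params()`) are the published fixed effects
  and variance components of the corresponding fitted models, treated as
  generative truth — a standard identification that simulation can use but
  not verify.
* **Pauses** (`inject_pauses()`): line-final gaps are lognormal with mean
  300 ms and SD 150 ms — values chosen only to exercise the line-final
  exclusion rule, since the originals are unreported — and a small fraction
  (0.5 % by default) of within-line syllables receive a hesitation pushing
  their SOI past 2200 ms, which the 2000 ms filter then removes at the
  binomially expected rate.

**Time layout and numerical choices.**  Generated SOIs become contiguous
onset/offset times (duration = SOI).  Because the published variance
components imply a small probability (~0.4 %) of a non-positive SOI draw,
durations are floored at 1 ms so times stay strictly increasing; the floor
shifts the SOI mean by well under 0.2 ms and is applied identically in the
simulate and ingest paths.  All times are rounded to microseconds — the
grain at which TextGrids are serialized — so a reading written out as
TextGrid files and re-ingested reproduces the feature table exactly, and
model estimates agree across the two paths to better than $10^{-9}$.

**What the generator does not emulate.**  Real oral reading has serial
correlation within lines, tempo drift, phrase-final lengthening beyond the
line-final pause, non-Gaussian hesitation structure, and syllable identities
whose segmental content covaries with stress.  Passing recovery tests
therefore show that the pipeline estimates the assumed hierarchical
structure correctly at study scale — not that real data satisfy that
structure.

## Open design choices

* **Centering of line covariates.**  The original analysis centered numeric
  line covariates "using the scale function", whose default also divides by
  the SD; but the published per-tack interpretation of the tacks-per-line
  coefficient is only valid on the raw per-tack scale.
  `center_covariates()` supports both; model fits default to center-only so
  coefficients stay per tack, and the coding is recorded in run metadata.
* **Tack index reading.**  The tack index is implemented as the 1-based
  ordinal of a tack among the tacks of its line (recounted over realised
  tokens at ingestion), matching the 0–5 range of the tacks-per-line
  variable; a centered or 0-based variant would only shift the intercept.
* **Strict vs lenient alignment.**  Ingestion matches syllable-tier
  intervals to grid slots positionally and by label; by default any count
  or label mismatch is an error.  A lenient mode aligns greedily by label
  and drops unrealised slots (e.g. a tack omitted during reading) with a
  warning — opt-in, because silent guessing about omissions is unsafe.
* **Boundary conventions.**  The 2000 ms rule is strict (`> 2000` removed);
  Tukey fences are inclusive; intervals are half-open `[xmin, xmax)` in
  seconds; singular mixed-model fits (common with 13 participants and
  random slopes) are recorded on the fit object rather than raised.
* **Command-line interface.**  The package's interface is its functions —
  `run_study()` orchestrates the full pipeline deterministically from one
  seed — plus the acceptance script; no shell wrapper is shipped.

## Problem sizes

The test-suite and acceptance computations run the full synthetic study —
13 participants × 6 poems (991 syllable slots, 120 lines per participant,
≈ 12,900 syllable tokens) — for single-fit recovery checks, and 200
replicates of the 1,560-line line-level design for interval-coverage
calibration.  These sizes mirror the study design itself; property suites
(nPVI oracle, TextGrid round trips) use small randomized fixtures.

## A worked example

```{r example, eval = FALSE}
bundle <- run_study(run_config(mode = "simulate", seed = 1,
                               models = c("regular_soi",
                                          "line_tacks_per_line_soi")))
print(bundle$fits$regular_soi$final_fit)
```

The regular-syllable SOI fit reports a stress coefficient near the
generating 20.54 ms (so strong syllables are modelled as roughly 41 ms
longer than weak ones), and the line-level fit a tacks-per-line coefficient
near −1.49 nPVI units per tack: inserting tacks levels the durational
contrast of a line.

## Limitations

* The generator treats fitted variance components as generative truth; the
  reverse identification (that the original data arose from this process)
  is untestable from published summaries.
* With 13 participants, random-slope variances sit near the boundary in a
  non-trivial fraction of replicates; estimates remain usable but ICCs and
  slope correlations are then unstable.
* Satterthwaite intervals at these group counts are approximate; the
  calibration suite requires ≥ 93 % empirical coverage of nominal 95 %
  intervals rather than exact nominal coverage.
* The annotation reader handles Praat's two text dialects (UTF-8/UTF-16)
  but not the binary or collection formats, and ignores point tiers.
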