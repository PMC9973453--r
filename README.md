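# verserhythm

Rhythm analysis of oral readings of metered poetry.

When readers perform conventional iambic or trochaic verse aloud, the
metrical grid — the alternation of strong (s) and weak (w) syllable
positions — shapes syllable timing and loudness. A classic probe replaces
single syllables at random grid positions with the nonsense syllable
*"tack"*: the substitute keeps its metrical slot but has no lexical
content, so its realisation shows how much of the rhythm is carried by the
grid itself. `verserhythm` provides the complete analysis pipeline for this
paradigm, for phoneticians and psycholinguists working with Praat TextGrid
annotations — plus a hierarchical simulator of synthetic readings so the
whole pipeline runs and is testable without any recordings.

## What it computes

* **Syllable onset intervals (SOI)** — onset-to-onset durations in ms that
  integrate within-line pauses; the line-final pause is excluded (the
  line-final SOI is the syllable's own duration). SOIs > 2000 ms are
  flagged and excluded.
* **nPVI** — the normalized pairwise variability index of a sequence
  d₁,…,d_m:

  nPVI = 100/(m−1) · Σₖ |d_k − d_{k+1}| / ((d_k + d_{k+1})/2)

  computed per verse line over SOIs and over mean intensities (dB).
* **Sum-coded linear mixed models** (REML via `lme4`/`lmerTest`,
  Satterthwaite df) with a two-pass Tukey residual outlier filter:
  syllable-level models of SOI and intensity (stress × musicality × meter,
  with tack index for tack syllables; participant intercept + stress slope,
  syllable intercept), and line-level models of nPVI (tack-line or
  tacks-per-line × musicality × meter; participant and poem random
  effects). Because predictors are ±1 sum-coded, the intercept is the grand
  mean and a binary factor's two-level difference is 2β. Effect sizes use
  Cohen's d = 2t/√df.

## A worked example

```r
library(verserhythm)

npvi(c(250, 270, 280))
#> [1] 5.664336        # a nearly level line: tiny durational contrast

bundle <- run_study(run_config(mode = "simulate", seed = 1,
                               models = c("regular_soi",
                                          "line_tacks_per_line_soi")))
print(bundle$fits$regular_soi$final_fit)
#> Linear mixed model fit: regular_soi_ms
#>   response: soi_ms   observations: 10675
#>                  term   beta  ste      df     t        p     d
#>           (Intercept) 256.27 5.26   21.37 48.68 2.20e-23 21.06
#>                stress  26.43 3.17  194.94  8.35 1.28e-14  1.20
#>               musical  -0.51 4.46   11.02 -0.11 9.11e-01    NA
#>                 meter   1.05 2.84  825.23  0.37 7.12e-01    NA
#>        stress:musical   3.06 1.48   11.02  2.07 6.31e-02  1.25
#>          ...
#>   ICC = 0.73
```

The run simulates 13 readers × 6 poems (991 syllable slots, 120 lines per
reader) from the package's generative defaults, injects pauses, computes
SOIs, applies the 2000 ms filter, and fits the two-pass models. The stress
coefficient 26.43 ms means strong syllables are estimated ~53 ms (2β)
longer than weak ones — the generating value is 20.54 ms, and the estimate
lands within two standard errors of it. The line-level fit in the same
bundle estimates −1.32 nPVI units per additional tack in a line
(generating structure: −1.49): tacks level a line's durational contrast.

The ingestion path does the same starting from Praat TextGrids:

```r
tiers <- read_textgrid("P01_A1.TextGrid")
tokens <- build_syllable_table(tiers, poem, participant)
features <- filter_max_soi(compute_soi(tokens))
lines <- aggregate_lines(features)
```

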