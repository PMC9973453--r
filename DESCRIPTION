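Package: verserhythm
Title: Rhythm Analysis of Oral Poetry Reading
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the temporal and intensity rhythm of read
    metered poetry. Represents poems as iambic or trochaic metrical grids with
    optional nonsense "tack" syllable substitutions, ingests Praat TextGrid
    annotations into chronological syllable tables, computes syllable onset
    intervals (SOI) and the normalized pairwise variability index (nPVI) per
    verse line, and fits sum-coded linear mixed-effects models (participant and
    syllable random effects, Satterthwaite degrees of freedom, two-pass
    residual outlier filtering) relating rhythm measures to metrical stress,
    meter, musical activity and tack placement. Includes a hierarchical
    generative simulator of oral readings so the full pipeline can be exercised
    and calibrated without audio recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    lmerTest,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
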