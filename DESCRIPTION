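Package: callvar
Title: Spatial and Temporal Variability of Frog Advertisement Calls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Resampling-based analysis of intraspecific variability in anuran
    advertisement calls. Reads per-call or per-individual measurement tables,
    applies locality-based spatial thinning, measures call duration and peak
    frequency from audio, and quantifies how the spread of call traits in a
    sample depends on sample size, the convex-hull area spanned by recording
    locations, and the intra-annual time difference within a breeding season.
    Fits per-species linear models on intraspecific z-scores, a pooled linear
    mixed model with a species random intercept, and meta-regressions of
    species-level slopes on range size and body size. A synthetic-data module
    generates call records and audio with known spatial gradients, seasonal
    drift, and noise so every pipeline stage can be verified against ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    geosphere,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
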