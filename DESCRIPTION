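Package: needlebeat
Title: Contraction Analysis for Cardiac Constructs on Needle Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Video-based contraction analysis for scaffold-free engineered
    cardiac tissue cultured on a needle (Kenzan) array. Tracks needle-tip
    motion in grayscale microscopy recordings by normalized cross-correlation
    template matching with sub-pixel refinement, converts tracks to
    displacement traces, detects contraction events by prominence-based peak
    picking, and summarises beating rate (beats per 10 s), per-beat tip
    displacement amplitude ("top movement") and cross-needle beat
    synchronisation. Includes baseline-normalised drug-response and
    cardiotoxicity time-course analysis, an optional Euler-Bernoulli
    cantilever deflection-to-force converter, and a synthetic twitch/scene
    simulator that renders ground-truth needle-array videos so every pipeline
    stage can be validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    jsonlite,
    yaml,
    tiff,
    png,
    zoo,
    generics,
    EBImage,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
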