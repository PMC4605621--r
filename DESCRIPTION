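Package: koalacall
Title: Source-Filter Acoustic Analysis of Koala Vocalisations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising the acoustic structure and information
    content of koala (Phascolarctos cinereus) vocalisations with a
    source-filter approach. Includes a synthetic call generator for bellows,
    snarls and tonal rejection calls; extraction of fundamental-frequency,
    formant and nonlinear-phenomena features from audio; biomechanical
    calculators (vocal-fold string model, formant spacing, estimated vocal
    tract length); and the statistics stage: mixed-variable two-step
    clustering with silhouette model selection, discriminant function
    analysis with leave-one-out classification, binomial tests against
    chance, and MANOVA with univariate follow-ups.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
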