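Package: blinkrv
Title: Multifractal Scaling Analysis of Eye-Blink Rate Variability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for extracting eye-blink events from frontal EEG
    (Fp1/Fp2), building inter-blink-interval series (blink rate
    variability, BRV), and estimating their multifractal scale exponent
    alpha with a Gaussian sub-band variant of multifractal detrended
    fluctuation analysis (MFDFA).  Includes a classical
    polynomial-detrended MFDFA for cross-checking, colored-noise and
    synthetic-EEG generators for validation, and cohort statistics
    (median split, one-way ANOVA, Pearson correlation, Shapiro-Wilk)
    linking resting-state alpha to cognitive test scores.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
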