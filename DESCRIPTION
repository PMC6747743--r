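Package: somnoclock
Title: Sleep Diaries, Sleep Regularity, and Epigenetic-Clock Aging Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for a prospective analysis of sleep patterns and
    DNA-methylation (epigenetic) aging. Implements sleep-diary ingestion and
    total-sleep-time summaries; the Sleep Regularity Index, including a
    probabilistic variant for diaries that record nap and awakening totals but
    not their timing; a coefficient-driven epigenetic clock with BMIQ
    beta-mixture quantile normalization, reference-based blood cell
    deconvolution, cell-composition correction, and the piecewise log/linear
    age transformation; group construction (duration split crossed with a
    regularity median split) and the ANOVA/ANCOVA inference with adjusted
    means, contrasts, and confidence intervals; and synthetic-data generators
    for diaries and paired-timepoint methylation arrays with known ground
    truth so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    quadprog
Suggests:
    testthat (>= 3.0.0),
    emmeans,
    optparse,
    withr
Config/testthat/edition: 3
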