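Package: glycoprofiler
Title: N-Glycan Profiling from MALDI Peak Lists
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for MALDI mass-spectrometric N-glycomics at the
    composition level: monoisotopic mass calculus for glycan compositions
    and their MALDI ion species, GlycoMod-style enumeration of candidate
    compositions within a ppm tolerance with a biological plausibility
    filter, internal-standard (beta-cyclodextrin) normalization of peak
    intensities, replicate aggregation with detectability calls and
    Dixon's Q outlier screening, presence/absence and significance-based
    modulation classification across a three-group cohort design
    (control strain, disease-model strain, treated model), Pearson
    correlation screening of glycan abundance against behavioral memory
    measures, and a seeded synthetic cohort generator for end-to-end
    validation. Ships a machine-readable transcription of the published
    cortex and serum N-glycan tables together with a one-shot
    reproduction report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
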