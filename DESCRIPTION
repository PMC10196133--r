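Package: retinerg
Title: Retinal Structure-Function Analysis for the Mouse Eye
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Decomposition of full-field electroretinogram (ERG) waveform
    families into photoreceptoral (P3, delayed-Gaussian model),
    ON-bipolar-cell (P2, Naka-Rushton intensity-response) and ganglion-cell
    (positive scotopic threshold response) endpoints; retinal layer
    thickness summaries over an ETDRS-style annulus from optical coherence
    tomography segmentations; total-protein-normalized western-blot
    densitometry; and the accompanying statistical layer (ROUT outlier
    screening, two-way genotype-by-age ANOVA with Sidak post hoc
    comparisons, Deming errors-in-variables regression, Spearman rank
    correlation, percent-of-reference summaries). A seeded synthetic-cohort
    generator emulates a cross-sectional two-genotype, three-age mouse
    study with a latent severity factor coupling alpha-synuclein burden to
    outer-retinal structure and function, so the whole pipeline is
    verifiable end to end against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    minpack.lm,
    car
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
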