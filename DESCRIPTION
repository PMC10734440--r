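Package: mockamp
Title: Mock-Community Evaluation of 16S Amplicon Sequencing Artifacts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify artifacts and quantitation bias in 16S rRNA V4
    amplicon sequencing using defined mock communities. Provides a
    ground-truth-labeled simulator of PCR amplification (per-cycle polymerase
    errors, incomplete-extension chimera formation with GC-dependent
    re-annealing, primer-mismatch suppression, one-step and two-step phasing
    protocols) and paired-end sequencing (position-dependent quality decay,
    fluorophore cross-talk-biased miscalls), together with the evaluation
    pipeline: sliding-window quality trimming, overlap-based pair merging,
    reference-guided two-parent chimera detection against dual reference sets,
    per-position error-rate profiling, rarefaction and greedy 97% OTU
    clustering, spurious-OTU classification into chimeric, contaminant and
    erroneous sequences, and observed-versus-expected abundance statistics
    (one-sample t tests, ANOVA with Fisher's LSD letters, Pearson
    correlations).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    methods,
    stats,
    utils,
    tools,
    yaml
Suggests: testthat (>= 3.0.0), jsonlite, knitr, rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
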