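Package: rootindel
Title: Quantification of CRISPR/Cas9 Editing Outcomes in Hairy Roots
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for quantifying CRISPR/Cas9 editing outcomes in
    transgenic hairy roots from Sanger sequencing of amplicons. Provides
    sgRNA candidate enumeration and design filters (CDS targeting window,
    5' guanine, BbsI exclusion, mismatch/seed off-target dismissal),
    decomposition of mixed control/edited chromatogram signal into an indel
    spectrum by non-negative least squares with per-indel significance and
    fit quality, per-root INDEL and knockout (frameshift or >= 21 bp)
    scores with group aggregation and Welch contrasts, repair-outcome
    prediction from sequence context (microhomology-mediated deletions,
    out-of-frame score, microhomology strength, -4 templated single-base
    insertion), prediction-versus-observation concordance reporting, and a
    seeded synthetic-cohort generator emulating chimeric-root indel
    spectra for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    pracma,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
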