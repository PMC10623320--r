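# rootindel

Quantification of CRISPR/Cas9 editing outcomes in transgenic hairy roots
from Sanger sequencing of amplicons.

## The problem

Hairy-root transformation is a fast way to test genome-editing reagents in
plants, but each root is chimeric: its cells carry a mixture of wild-type
and differently edited alleles. A single Sanger chromatogram of a PCR
amplicon spanning the cut site is therefore a superposition of shifted
sequence signals. To evaluate a guide RNA / Cas9 construct you need to
answer, per root: *which indels are present, at what fraction, and do they
knock the gene out?* — and, across roots: *how efficient is the construct,
and do the observed outcomes match what repair-outcome models predict from
the sequence context?*

## The model

A trace is a matrix `T ∈ [0,1]^(L×4)` of per-position base fractions. For
indel sizes `s ∈ {−30, …, +30}` bp, templates `X_s` are built from the
control trace: identical up to the cut, then shifted by `s` (unknown
inserted bases become uniform rows). The edited trace is decomposed over
the window rows fully covered by all templates by non-negative least
squares,

```
min_{c ≥ 0} ‖ y − Σ_s c_s x_s ‖²,
```

coefficients are normalized to percentages, fit quality is `R²`, and
per-size p-values come from an OLS refit of the active set. Roots with
`R² ≤ 0.7` are rejected; events with `p ≥ 0.01` are dropped. Per root,
`INDEL = Σ pct(events)` and `KO = Σ pct(frameshift or ≥ 21 bp)`; groups are
compared with Welch's t-test. Repair outcomes are predicted from sequence
context: microhomology-mediated deletions scored by
`100·exp(−ΔL/20)·(2·GC + AT)` and the −4 templated +1 insertion. A seeded
synthetic-cohort generator reproduces the pooled indel-size spectrum of
hairy-root experiments (22.6% 1-bp deletions, 19.1% 1-bp insertions, ~3:1
deletions:insertions, 1–4 dominant indels per root) for end-to-end
validation. See `vignettes/rootindel-methods.Rmd` for the full method
description, thresholds and limitations.

## Worked example

Simulate one root, decompose its traces, score it, and compare with the
sequence-context prediction:

```r
library(rootindel)

amp  <- make_amplicon(300, gc_fraction = 0.5, seed = 42)
site <- pick_study_guide(amp)          # +-strand NGG site, cut_pos = 71

truth <- sample_root_spectrum(repair_spectrum_config(),
                              template_base = site_template_base(amp, site),
                              root_seed = 7)
truth
#> Indel spectrum: 3 event(s), wild-type 34.7%
#>    key percentage p_value
#> 1   -7   22.79582      NA
#> 2   -1   21.05861      NA
#> 3 +1:A   21.42283      NA

tr  <- synthesize_traces(amp, site, truth, noise_sd = 0.01, seed = 7)
fit <- decompose(tr$control, tr$edited, site$cut_pos)
q   <- filter_spectrum(fit)
round(fit$r_squared, 4)                # 0.9984; root passes QC
q$spectrum
#> Indel spectrum: 3 event(s), wild-type 34.7%
#>   key percentage p_value
#> 1  -7   22.75758       0
#> 2  -1   20.78412       0
#> 3  +1   21.35204       0

root_scores(q$spectrum)
#> $indel_score
#> [1] 64.89375
#> $ko_score
#> [1] 64.89375

top_k(predict_spectrum(amp$sequence, site$cut_pos), 5)
#>   size inserted_base     weight
#> 1    1             A 0.25000000
#> 2  -20          <NA> 0.18339089
#> 3  -10          <NA> 0.07956854
#> 4  -30          <NA> 0.06439759
#> 5  -15          <NA> 0.04957444

match_indels(q$spectrum$key, top_k(predict_spectrum(amp$sequence,
                                                    site$cut_pos), 5))
#> [1] "+1"
```

## Analysis workflow

Numbered drivers under `analysis/` run the full study over the package and
write tables under `results/`:

1. `analysis/01_simulate.R` — simulate the cohort (9 guides × 2 Cas9
   constructs × 15 roots); writes config, amplicons, ground-truth spectra.
2. `analysis/02_guides.R` — enumerate, filter (CDS window, 5′ G, BbsI,
   off-target dismissal) and rank guide candidates per amplicon.
3. `analysis/03_decompose_score.R` — decompose every root, apply QC, score,
   aggregate per group, test construct contrasts.
4. `analysis/04_predict_concordance.R` — benchmark concordance: shipped
   observed-vs-predicted tables from a published common-bean hairy-root
   editing study, plus the simulated cohort.

```sh
Rscript analysis/01_simulate.R && Rscript analysis/02_guides.R && \
Rscript analysis/03_decompose_score.R && Rscript analysis/04_predict_concordance.R
```

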