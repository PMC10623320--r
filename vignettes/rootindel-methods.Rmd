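---
title: "Methods: indel decomposition, scoring and repair-outcome prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: indel decomposition, scoring and repair-outcome prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rootindel)
```

# Scope

`rootindel` quantifies CRISPR/Cas9 editing outcomes in transgenic hairy
roots from Sanger sequencing of a PCR amplicon spanning the cut site. Each
root is a chimeric tissue: a mixture of wild-type and edited alleles, so a
single chromatogram is a superposition of shifted sequence signals. The
package covers the full desk-scale path: sgRNA design over an amplicon,
decomposition of the mixed signal into an indel spectrum, editing scores
and group statistics, sequence-context prediction of repair outcomes,
concordance of predictions with observations, and a seeded synthetic-cohort
generator used to validate all of it end to end.

# Coordinates

All coordinates are 1-based. For a guide on the `+` strand with protospacer
starting at position `p`, the PAM occupies `p+20 .. p+22` and `cut_pos =
p+16`: the index of the base immediately 5' of the blunt cut, i.e. the -4
position relative to the PAM. On the `-` strand the forward-strand CCN PAM
at `m .. m+2` gives `cut_pos = m+5`, and the templated base is the
complement of the forward base at `cut_pos + 1`.

# Trace decomposition

A trace is a matrix of per-position base fractions (columns `A`, `C`, `G`,
`T`, rows summing to 1). For each candidate indel size `s` in `-30 .. +30`
bp, a template trace is built from the control: identical up to `cut_pos`,
then shifted by `s`, with inserted positions (bases unknown at fit time)
and positions running off the sequence end set to the uninformative row
`(0.25, 0.25, 0.25, 0.25)`.

The edited trace is regressed on the 61 templates by non-negative least
squares (`pracma::lsqnonneg`) over the fit window
`(cut_pos + max_indel + 1) .. (L - max_indel)` so that every template is
fully defined on every fitted row. Coefficients are normalized to
percentages summing to 100; `R^2 = 1 - SS_res / SS_tot` measures fit
quality.

Per-size p-values use an ordinary least-squares refit restricted to the
active set (coefficients > 1e-10): the two-sided t-test on each
coefficient from `stats::lm(y ~ 0 + X_active)`. This is a standard
stated substitute for the significance recipe of trace-decomposition tools
in the TIDE family, whose exact test is not published in reproducible
detail; it behaves identically in practice (true mixture components get
vanishingly small p-values, spurious ones do not survive the 0.01 cut).
When the residual variance is numerically zero (noiseless synthetic input)
the p-value is set to 0.

Quality control (`filter_spectrum`): a root is rejected outright when
`R^2 <= 0.7`; in surviving roots, events with `p >= 0.01` are dropped.

# Thresholds

All defaults live in `default_thresholds()`:

| name | default | units | role |
|---|---|---|---|
| `max_indel` | 30 | bp | largest modelled indel (fit window half-width) |
| `p_cut` | 0.01 | — | per-event significance cut |
| `r2_cut` | 0.7 | — | minimum decomposition `R^2` (strictly above) |
| `ko_len` | 21 | bp | in-frame indels of at least this size count as knockouts |
| `dominance_pct` | 20 | % | an indel is "dominant" above this share in a root |
| `min_roots` | 15 | roots | group means reportable at this n |
| `mh_flank` | 100 | bp | microhomology-strength flank |
| `template_offset` | -4 | bp | templated-insertion source relative to the PAM |

# Scores and group statistics

Per root, `INDEL score` is the summed percentage of all indel events and
`KO score` the summed percentage of events that are frameshifts
(`size %% 3 != 0`) or at least `ko_len` bp. Group summaries report mean and
standard error (`sd/sqrt(n)`); between-construct contrasts use Welch's
unequal-variance t-test (`stats::t.test(var.equal = FALSE)`).
Transformation efficiency is a half-up rounded percentage to one decimal:
`(144, 300)` gives 48.0, `(53, 348)` gives 15.2.

# Repair-outcome prediction

**Microhomology-mediated deletions.** `enumerate_microhomologies` finds,
for every offset `d`, the maximal repeated block with one copy ending at or
5' of the cut and the other covering or 3' of it (both within `window` bp);
collapsing the copies deletes `d` bp. Patterns are scored with the widely
used microhomology weighting: `100 * exp(-d / 20) * (2*GC + AT)` — repeat
length counts, G/C doubly, and the score decays exponentially in the
implied deletion length. The `out_of_frame_score` is the score-weighted
percentage of patterns whose deletion is not a multiple of 3.

**Microhomology strength.** `mh_strength` sums pattern scores over a
100-bp flank, additionally decayed in the gap between the repeat copies and
the cut (`exp(-gap/25)`), and divides by a fixed normalization constant
(4400). That constant was calibrated once so random GC-balanced contexts
land mid-scale (median near 0.5) and is frozen; the class bands are
low < 0.3 <= average <= 0.8 < high. The value is unitless and only
meaningful relative to these bands.

**Templated insertion.** Staggered Cas9 cleavage leaves a 1-nt 5' overhang
whose fill-in duplicates the base at the -4 position; `templated_insertion`
returns that single +1 outcome with all mass. `predict_spectrum` mixes the
deletion predictions (75% of mass, proportional to summed pattern score per
size) with the templated +1 (25%, reflecting the roughly 3:1
deletion:insertion ratio of observed outcomes). `top_k` orders by weight,
breaking ties toward smaller absolute size, deletions first.

# Synthetic cohort generator

The generator emulates the observable structure of hairy-root editing
experiments:

* each chimeric root carries 1–4 dominant indels, each above 20% of the
  signal;
* pooled over roots, indel sizes follow the shipped weight fixture:
  22.6% 1-bp deletions, 19.1% 1-bp insertions, deletions up to 30 bp,
  insertions up to 4 bp, ~3:1 deletions:insertions;
* +1 insertions copy the -4 template base with probability 0.75;
* wild-type signal per root is drawn from a construct-specific range —
  the defaults (`pMR356` 10–35%, `pMR394` 15–45%) encode one construct
  editing more strongly than the other while both remain high-efficiency,
  which is the regime the scoring and contrast machinery is meant for;
* traces are the exact allele mixture plus truncated Gaussian noise,
  renormalized per row.

**Sampling design.** Drawing a root's `k` distinct dominant sizes by plain
weighted sampling without replacement would bias the pooled marginal
frequencies (large-weight sizes are under-represented when forced to be
distinct). The generator instead uses randomized systematic
probability-proportional-to-size sampling, whose inclusion probability for
size `s` is exactly `k * p_s`, so pooled frequencies match the fixture by
construction rather than by tuning.

**What it does not emulate:** chromatogram artefacts (dye blobs, mobility
shifts, degrading quality along the read), PCR/cloning biases, complex
alleles (combined insertion-deletion events), large structural variants,
or biological covariance between roots of one plant.

# Problem sizes and determinism

Amplicons are a few hundred bp (default 300); a decomposition is a
~61-template NNLS over ~180 rows x 4 channels and takes ~35 ms. The stock
cohort (9 guides x 2 constructs x 15 roots) simulates, decomposes and
scores in well under a minute. Every stochastic step takes an explicit
seed; independent streams are derived with `derive_seed`, so identical
configurations give byte-identical outputs.

# Limitations

* The decomposition assumes one cut site per amplicon and indels only at
  that site; off-window (> 30 bp) deletions are not representable and
  degrade `R^2` instead of being reported — by design they can never
  appear in output spectra.
* P-values come from an OLS refit of the NNLS active set; they are
  calibrated for screening (the 0.01 cut), not for fine-grained inference.
* The microhomology score and strength bands are heuristics; the strength
  normalization is frozen, so values are comparable across sites but have
  no physical unit.
* The predictor emits size-level (and +1 base-level) outcomes only; it
  does not predict full allele sequences.
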