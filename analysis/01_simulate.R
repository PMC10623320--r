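#!/usr/bin/env Rscript

# Step 1: simulate the synthetic hairy-root editing cohort.
#
# Nine guide targets, two Cas9 constructs (pMR356 stronger, pMR394 weaker),
# 15 roots per guide x construct group. The per-root repair spectra follow
# the shipped pooled size-weight fixture (22.6% 1-bp deletions, 19.1% 1-bp
# insertions, ~3:1 deletion:insertion); +1 insertions copy the -4 template
# base 75% of the time. Writes the study configuration, the amplicons and
# the ground-truth spectra for the later steps.

suppressPackageStartupMessages(library(rootindel))

outdir <- "results/01_simulate"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

cfg <- study_config(n_guides = 9, n_roots = 15, seed = 20230914,
                    noise_sd = 0.01, traces = FALSE)
write_study_config(cfg, file.path(outdir, "study_config.yaml"))

study <- simulate_study(cfg)
write_fasta(vapply(study$amplicons, `[[`, "", "sequence"),
            file.path(outdir, "amplicons.fasta"))
write_spectra(study$spectra, file.path(outdir, "true_spectra.tsv"))
write.table(study$records, file.path(outdir, "roots.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("simulated %d roots across %d guides x %d constructs -> %s\n",
            nrow(study$records), cfg$n_guides, length(cfg$constructs),
            outdir))
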