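#!/usr/bin/env Rscript

# Step 2: guide design over the simulated amplicons.
#
# For every amplicon from step 1: enumerate all NGG protospacers on both
# strands, apply the design filters (cut in the 5-65% CDS window, 5' G,
# no BbsI site in protospacer+PAM), scan the remaining candidates against
# the other amplicons as an off-target background (hits with > 4 mismatches
# including one in the 12-nt seed are dismissed), and rank by risk count,
# then microhomology out-of-frame score, then position.

suppressPackageStartupMessages(library(rootindel))

indir <- "results/01_simulate"
outdir <- "results/02_guides"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

cfg <- read_study_config(file.path(indir, "study_config.yaml"))
study <- simulate_study(cfg)

all_rows <- list()
for (g in names(study$amplicons)) {
  amp <- study$amplicons[[g]]
  cands <- filter_guides(enumerate_guides(amp))
  if (!nrow(cands)) next
  background <- vapply(study$amplicons[names(study$amplicons) != g],
                       `[[`, "", "sequence")
  scores <- numeric(nrow(cands))
  for (i in seq_len(nrow(cands))) {
    gs <- guide_site(cands$guide_id[i], cands$protospacer[i], cands$pam[i],
                     cands$strand[i], cands$cut_pos[i])
    hits <- off_target_scan(gs, background)
    cands$off_target_risk_count[i] <- off_target_risk_count(hits)
    oof <- out_of_frame_score(
      enumerate_microhomologies(amp$sequence, cands$cut_pos[i]))
    scores[i] <- if (is.na(oof)) 0 else oof
  }
  names(scores) <- cands$guide_id
  ranked <- rank_guides(cands, scores)
  ranked$amplicon <- g
  ranked$oof_score <- scores[ranked$guide_id]
  all_rows[[g]] <- ranked
}

tab <- do.call(rbind, all_rows)
rownames(tab) <- NULL
write.table(tab, file.path(outdir, "ranked_guides.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("ranked %d candidate guides across %d amplicons -> %s\n",
            nrow(tab), length(all_rows), outdir))
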