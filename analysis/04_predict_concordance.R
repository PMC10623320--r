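#!/usr/bin/env Rscript

# Step 4: repair-outcome prediction and benchmark concordance.
#
# Two comparisons:
#  (a) the shipped benchmark tables from the published common-bean
#      hairy-root study: how many observed dominant indels per guide fall
#      in each model's top-5 predicted list, plus whether observed 1-bp
#      insertion bases match the -4 templated base at each cut context;
#  (b) this package's own microhomology + templated-insertion predictor
#      applied to the simulated cohort from step 3 (already tabulated by
#      run_pipeline; summarized here).

suppressPackageStartupMessages(library(rootindel))

outdir <- "results/04_concordance"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

## (a) published benchmark ---------------------------------------------------
rep <- concordance_report(rfo_observed_dominant(), rfo_predicted_lists())
write.table(rep, file.path(outdir, "benchmark_concordance.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
per_model <- aggregate(cbind(n_matched, n_observed) ~ model, rep, sum)
per_model$fraction <- round(per_model$n_matched / per_model$n_observed, 3)
write.table(per_model, file.path(outdir, "benchmark_by_model.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("matched observed dominant indels per model:\n")
print(per_model, row.names = FALSE)

ctx <- rfo_cut_contexts()
ins <- do.call(rbind, lapply(seq_len(nrow(ctx)), function(i) {
  obs <- c(A = ctx$obs_A[i], C = ctx$obs_C[i],
           G = ctx$obs_G[i], T = ctx$obs_T[i])
  tb <- templated_insertion(paste0(ctx$left3[i], ctx$right3[i]),
                            nchar(ctx$left3[i]))$inserted_base
  r <- if (anyNA(obs)) list(no_insertions = TRUE, match = NA,
                            matching_fraction = NA_real_)
       else insertion_concordance(obs, tb)
  data.frame(target = ctx$target[i], guide = ctx$guide[i],
             template_base = tb, match = r$match,
             matching_fraction = r$matching_fraction,
             stringsAsFactors = FALSE)
}))
write.table(ins, file.path(outdir, "insertion_concordance.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("templated base is the modal observed insertion at %d/%d sites\n",
            sum(ins$match, na.rm = TRUE), sum(!is.na(ins$match))))

## (b) simulated cohort ------------------------------------------------------
sim <- read.delim("results/03_pipeline/concordance.tsv")
cat(sprintf("simulated cohort: %d/%d observed dominant indels in the top-5\n",
            sum(sim$n_matched), sum(sim$n_observed)))
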