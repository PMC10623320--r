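# File formats and the end-to-end pipeline driver. Amplicons travel as
# FASTA, trace matrices as TSV (pos, A, C, G, T), spectra as TSV
# (root_id, size, inserted_bases, percentage, p_value), study configuration
# as YAML. All round trips are lossless up to numeric formatting.

#' Read amplicon sequences from FASTA
#'
#' @param path FASTA file. Lower-case bases are upper-cased; characters
#'   outside A/C/G/T are an error.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  s <- toupper(as.character(x))
  bad <- grepl("[^ACGT]", s)
  if (any(bad))
    stop("non-ACGT characters in FASTA record(s): ",
         paste(names(s)[bad], collapse = ", "))
  s
}

#' @rdname read_fasta
#' @param sequences Named character vector.
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path)
  invisible(path)
}

#' Read or write a trace matrix
#'
#' @param path TSV with columns pos, A, C, G, T.
#' @return Matrix (rows = positions, columns A/C/G/T).
#' @export
read_trace <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("pos", BASES) %in% names(d)))
    stop("trace TSV must have columns pos, A, C, G, T: ", path)
  d <- d[order(d$pos), ]
  m <- as.matrix(d[, BASES])
  rownames(m) <- NULL
  validate_trace(m, basename(path))
  m
}

#' @rdname read_trace
#' @param m Trace matrix.
#' @export
write_trace <- function(m, path) {
  validate_trace(m)
  utils::write.table(data.frame(pos = seq_len(nrow(m)), m),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read or write per-root indel spectra
#'
#' The TSV carries one row per event (root_id, size, inserted_bases,
#' percentage, p_value) plus one `size = 0` row per root holding the
#' wild-type percentage.
#'
#' @param path TSV file.
#' @return Named list of [indel_spectrum()] objects.
#' @export
read_spectra <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c(inserted_bases = "character"))
  need <- c("root_id", "size", "inserted_bases", "percentage", "p_value")
  if (!all(need %in% names(d)))
    stop("spectra TSV must have columns ", paste(need, collapse = ", "))
  bad <- which(d$percentage < 0)
  if (length(bad))
    stop("negative percentage at data line ", bad[1], " of ", path)
  d$inserted_bases[d$inserted_bases == ""] <- NA_character_
  out <- lapply(split(d, d$root_id), function(r) {
    wt <- r$percentage[r$size == 0]
    r <- r[r$size != 0, , drop = FALSE]
    indel_spectrum(r$size, r$percentage, inserted_bases = r$inserted_bases,
                   p_values = r$p_value,
                   wt_percentage = if (length(wt)) wt[1] else 0)
  })
  out[unique(d$root_id)]
}

#' @rdname read_spectra
#' @param spectra Named list of spectra.
#' @export
write_spectra <- function(spectra, path) {
  rows <- lapply(names(spectra), function(id) {
    sp <- spectra[[id]]
    rbind(data.frame(root_id = id, size = 0L,
                     inserted_bases = NA_character_,
                     percentage = attr(sp, "wt_percentage"),
                     p_value = NA_real_, stringsAsFactors = FALSE),
          if (nrow(sp)) data.frame(root_id = id, size = sp$size,
                                   inserted_bases = sp$inserted_bases,
                                   percentage = sp$percentage,
                                   p_value = sp$p_value,
                                   stringsAsFactors = FALSE))
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read or write a study configuration as YAML
#'
#' @param path YAML file. Unknown keys are rejected.
#' @return A [study_config()].
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("n_guides", "n_roots", "constructs", "amplicon_length",
             "gc_fraction", "noise_sd", "seed", "traces", "spectrum")
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    stop("unknown study config key(s): ", paste(unknown, collapse = ", "))
  spec_args <- list()
  if (!is.null(y$spectrum)) {
    sknown <- c("dominant_count_range", "wt_fraction_range",
                "template_bias", "noise_sd", "size_weights_file")
    sunknown <- setdiff(names(y$spectrum), sknown)
    if (length(sunknown))
      stop("unknown spectrum config key(s): ",
           paste(sunknown, collapse = ", "))
    spec_args <- y$spectrum
    if (!is.null(spec_args$size_weights_file)) {
      spec_args$size_weights <- read_size_weights(spec_args$size_weights_file)
      spec_args$size_weights_file <- NULL
    }
  }
  y$spectrum <- do.call(repair_spectrum_config, spec_args)
  do.call(study_config, y)
}

#' @rdname read_study_config
#' @param config A [study_config()].
#' @export
write_study_config <- function(config, path) {
  y <- unclass(config)
  y$spectrum <- list(
    dominant_count_range = config$spectrum$dominant_count_range,
    wt_fraction_range = config$spectrum$wt_fraction_range,
    template_bias = config$spectrum$template_bias,
    noise_sd = config$spectrum$noise_sd)
  yaml::write_yaml(y, path)
  invisible(path)
}

log_line <- function(log, stage, msg) {
  line <- sprintf("[%s] %s", stage, msg)
  message(line)
  c(log, line)
}

#' Run the full pipeline on a synthetic study
#'
#' Simulates the cohort, decomposes every root's traces, applies QC
#' (R^2 and per-indel p-value), computes INDEL/KO scores, aggregates per
#' guide x construct group, tests every between-construct contrast per guide
#' (Welch), predicts repair outcomes per guide, and tabulates concordance of
#' predictions with the observed dominant indels. Outputs are
#' byte-identical for identical configuration and seed.
#'
#' @param config A [study_config()] (must have `traces = TRUE`).
#' @param outdir Optional directory; when given, per-root scores, group
#'   summaries, contrasts, concordance and the run log are written as TSV /
#'   text files.
#' @param thresholds A [default_thresholds()].
#' @return List: study, qc, spectra (filtered, QC-passing roots), scores,
#'   group_summaries, contrasts, predictions, concordance, log.
#' @export
run_pipeline <- function(config, outdir = NULL,
                         thresholds = default_thresholds()) {
  stopifnot(inherits(config, "rootindel_study_config"))
  if (!config$traces) stop("run_pipeline needs a config with traces = TRUE")
  log <- character()
  log <- log_line(log, "config",
                  sprintf("seed=%d guides=%d constructs=%d roots/group=%d",
                          config$seed, config$n_guides,
                          length(config$constructs), config$n_roots))
  log <- log_line(log, "config",
                  sprintf("max_indel=%d p_cut=%g r2_cut=%g ko_len=%d",
                          thresholds$max_indel, thresholds$p_cut,
                          thresholds$r2_cut, thresholds$ko_len))
  study <- simulate_study(config)
  log <- log_line(log, "simulate", sprintf("%d roots simulated",
                                           nrow(study$records)))
  qc <- list(); filtered <- list()
  for (i in seq_len(nrow(study$records))) {
    id <- study$records$root_id[i]
    tr <- study$traces[[id]]
    site <- study$sites[[study$records$guide_id[i]]]
    dec <- decompose(tr$control, tr$edited, site$cut_pos, thresholds)
    q <- filter_spectrum(dec, thresholds)
    qc[[id]] <- q
    if (q$rejected) {
      log <- log_line(log, "qc", sprintf("root %s rejected: %s", id,
                                         q$reason))
    } else {
      filtered[[id]] <- q$spectrum
    }
  }
  log <- log_line(log, "decompose",
                  sprintf("%d/%d roots passed QC", length(filtered),
                          nrow(study$records)))
  scores <- score_roots(filtered, thresholds)
  rec <- study$records[match(scores$root_id, study$records$root_id), ]
  scores$guide_id <- rec$guide_id
  scores$construct <- rec$construct
  groups <- split(scores, list(scores$guide_id, scores$construct),
                  drop = TRUE)
  summaries <- do.call(rbind, lapply(names(groups), function(g) {
    sc <- groups[[g]]
    ai <- aggregate_scores(sc$indel_score, thresholds$min_roots)
    ak <- aggregate_scores(sc$ko_score, thresholds$min_roots)
    data.frame(guide_id = sc$guide_id[1], construct = sc$construct[1],
               n = ai$n, mean_indel = ai$mean, se_indel = ai$se,
               mean_ko = ak$mean, se_ko = ak$se,
               reportable = ai$reportable, stringsAsFactors = FALSE)
  }))
  summaries <- summaries[order(summaries$guide_id, summaries$construct), ]
  rownames(summaries) <- NULL
  constructs <- names(config$constructs)
  contrasts <- list()
  if (length(constructs) >= 2) {
    pairs <- utils::combn(constructs, 2, simplify = FALSE)
    for (g in unique(scores$guide_id)) {
      for (pr in pairs) {
        a <- scores$indel_score[scores$guide_id == g &
                                  scores$construct == pr[1]]
        b <- scores$indel_score[scores$guide_id == g &
                                  scores$construct == pr[2]]
        if (length(a) >= 2 && length(b) >= 2) {
          wt <- welch_test(a, b)
          contrasts[[length(contrasts) + 1L]] <- data.frame(
            guide_id = g, construct_a = pr[1], construct_b = pr[2],
            measure = "indel_score", t = wt$t, df = wt$df, p = wt$p,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  contrasts <- if (length(contrasts)) do.call(rbind, contrasts) else NULL
  log <- log_line(log, "score", sprintf("%d groups, %d contrasts",
                                        nrow(summaries),
                                        if (is.null(contrasts)) 0L else
                                          nrow(contrasts)))
  observed <- list(); predictions <- list()
  for (g in names(study$sites)) {
    site <- study$sites[[g]]
    amp <- study$amplicons[[g]]
    ids <- scores$root_id[scores$guide_id == g]
    observed[[g]] <- dominant_indels(filtered[ids],
                                     thresholds$dominance_pct)
    ps <- predict_spectrum(amp$sequence, site$cut_pos)
    predictions[[g]] <- list(`mh+templated` = top_k(ps, 5L))
  }
  conc <- concordance_report(observed, predictions)
  log <- log_line(log, "concordance", sprintf("%d rows", nrow(conc)))
  out <- list(study = study, qc = qc, spectra = filtered, scores = scores,
              group_summaries = summaries, contrasts = contrasts,
              observed_dominant = observed, predictions = predictions,
              concordance = conc, log = log)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    wt <- function(d, f) utils::write.table(
      d, file.path(outdir, f), sep = "\t", quote = FALSE, row.names = FALSE)
    wt(scores, "root_scores.tsv")
    wt(summaries, "group_summaries.tsv")
    if (!is.null(contrasts)) wt(contrasts, "contrasts.tsv")
    wt(conc, "concordance.tsv")
    write_spectra(filtered, file.path(outdir, "filtered_spectra.tsv"))
    writeLines(out$log, file.path(outdir, "run_log.txt"))
  }
  out
}
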