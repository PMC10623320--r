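# Per-root INDEL and KO scores, group aggregation, the promoter-contrast
# Welch test, dominant-indel extraction, pooled spectrum summaries, and
# transformation-efficiency arithmetic.

#' Per-root INDEL and KO scores
#'
#' The INDEL score of a root is the summed percentage of all (significant)
#' indels; the KO score is the summed percentage of indels expected to knock
#' the gene out (frameshift, or in-frame but >= `ko_len` bp).
#'
#' @param spectrum A filtered [indel_spectrum()] (see [filter_spectrum()]).
#' @param thresholds A [default_thresholds()].
#' @return List with `indel_score` and `ko_score` (percent).
#' @export
root_scores <- function(spectrum, thresholds = default_thresholds()) {
  if (!nrow(spectrum)) return(list(indel_score = 0, ko_score = 0))
  ko <- is_knockout_indel(spectrum$size, thresholds$ko_len)
  list(indel_score = sum(spectrum$percentage),
       ko_score = sum(spectrum$percentage[ko]))
}

#' Score every root in a set of spectra
#'
#' @param spectra Named list of filtered spectra (names = root ids).
#' @param thresholds A [default_thresholds()].
#' @return data.frame with root_id, indel_score, ko_score.
#' @export
score_roots <- function(spectra, thresholds = default_thresholds()) {
  sc <- lapply(spectra, root_scores, thresholds = thresholds)
  data.frame(root_id = names(spectra),
             indel_score = vapply(sc, `[[`, numeric(1), "indel_score"),
             ko_score = vapply(sc, `[[`, numeric(1), "ko_score"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Summarize a group of root scores
#'
#' @param scores Numeric vector of per-root scores (one group, one measure).
#' @param min_roots Reportability floor on group size.
#' @return List: n, mean, se (sample SD / sqrt(n)), reportable.
#' @export
aggregate_scores <- function(scores, min_roots = 15L) {
  n <- length(scores)
  if (n == 0L) stop("empty group: no root scores to aggregate")
  list(n = n, mean = mean(scores),
       se = if (n > 1L) stats::sd(scores) / sqrt(n) else 0,
       reportable = n >= min_roots)
}

#' Welch two-sample t-test between two groups of scores
#'
#' Two-sample t-test assuming unequal variances (Welch-Satterthwaite
#' degrees of freedom), two-sided.
#'
#' @param group_a,group_b Numeric vectors of per-root scores.
#' @return List: t, df, p.
#' @export
welch_test <- function(group_a, group_b) {
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("each group needs at least 2 roots")
  if (stats::var(group_a) == 0 && stats::var(group_b) == 0) {
    if (mean(group_a) == mean(group_b)) return(list(t = 0, df = Inf, p = 1))
    stop("zero variance in both groups with unequal means")
  }
  ht <- stats::t.test(group_a, group_b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Extract dominant indels from a pool of roots
#'
#' An indel qualifies as dominant if its percentage exceeds the dominance
#' threshold within at least one root of the pool (`per_root = TRUE`,
#' default) or if its summed percentage across the pool, divided by the
#' number of roots, exceeds it (`per_root = FALSE`). The result is ordered
#' by the maximum observed percentage, descending.
#'
#' @param spectra List of filtered spectra (one pool, e.g. one sgRNA).
#' @param dominance_pct Threshold in percent (default 20).
#' @param per_root Judge dominance within single roots (default) or on the
#'   pooled mean.
#' @return Character vector of indel keys (see [indel_spectrum()]), ordered.
#' @export
dominant_indels <- function(spectra, dominance_pct = 20, per_root = TRUE) {
  ev <- do.call(rbind, lapply(spectra, as.data.frame))
  if (is.null(ev) || !nrow(ev)) return(character())
  stat <- if (per_root) tapply(ev$percentage, ev$key, max) else
    tapply(ev$percentage, ev$key, sum) / length(spectra)
  stat <- sort(stat[stat > dominance_pct], decreasing = TRUE)
  names(stat)
}

#' Pooled mutation-spectrum summary
#'
#' Counts each event occurrence across roots (an indel present in two roots
#' counts twice) and reports per-size occurrence frequencies plus the
#' deletion:insertion event ratio.
#'
#' @param spectra List of filtered spectra.
#' @return List: `table` (data.frame size, n, frequency summing to 100) and
#'   `del_ins_ratio` (`NA` with `ratio_defined = FALSE` when no insertions).
#' @export
spectrum_summary <- function(spectra) {
  ev <- do.call(rbind, lapply(spectra, as.data.frame))
  if (is.null(ev) || !nrow(ev)) stop("no events in any spectrum")
  n <- table(ev$size)
  tab <- data.frame(size = as.integer(names(n)), n = as.integer(n),
                    frequency = 100 * as.integer(n) / nrow(ev))
  tab <- tab[order(tab$size), ]
  rownames(tab) <- NULL
  n_del <- sum(ev$size < 0)
  n_ins <- sum(ev$size > 0)
  list(table = tab,
       del_ins_ratio = if (n_ins > 0) n_del / n_ins else NA_real_,
       ratio_defined = n_ins > 0, n_events = nrow(ev),
       n_roots = length(spectra))
}

#' Transformation efficiency
#'
#' Percentage of explants with reporter-positive hairy roots, half-up
#' rounded to one decimal.
#'
#' @param positives Number of explants with positive roots.
#' @param total Number of explants transformed.
#' @return Percent, one decimal.
#' @export
transformation_efficiency <- function(positives, total) {
  if (total <= 0) stop("total must be positive")
  if (positives < 0 || positives > total)
    stop("positives must lie in [0, total]")
  floor(1000 * positives / total + 0.5) / 10
}
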