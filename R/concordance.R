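# Prediction-versus-observation concordance: which observed dominant indels
# were among a model's top-k predicted outcomes (compared on signed size,
# since observed decomposition output carries sizes only), and whether
# observed 1-bp insertion bases match the -4 template base.

key_size <- function(keys) as.integer(sub(":.*$", "", keys))

#' Match observed dominant indels against a predicted list
#'
#' Predicted entries are deduplicated by signed size (a model may predict
#' the same size several times with different inserted bases); observed keys
#' match when their signed size occurs among the deduplicated predictions.
#' With `strict = TRUE` insertion entries are compared on size plus inserted
#' base (usable against synthetic ground truth).
#'
#' @param observed Character vector of indel keys (from [dominant_indels()])
#'   or signed sizes.
#' @param predicted A [prediction_set()], data.frame with a `size` column,
#'   or vector of signed sizes.
#' @param strict Compare insertion bases too (requires base-carrying keys on
#'   both sides).
#' @return Character vector: the matched subset of `observed` (order
#'   preserved).
#' @export
match_indels <- function(observed, predicted, strict = FALSE) {
  observed <- as.character(observed)
  if (is.data.frame(predicted)) {
    pred_size <- predicted$size
    pred_base <- if ("inserted_base" %in% names(predicted))
      predicted$inserted_base else rep(NA_character_, nrow(predicted))
  } else {
    pred_size <- as.integer(predicted)
    pred_base <- rep(NA_character_, length(pred_size))
  }
  if (strict) {
    pred_key <- spectrum_key(as.integer(pred_size), pred_base)
    obs_key <- spectrum_key(key_size(observed),
                            ifelse(grepl(":", observed),
                                   sub("^.*:", "", observed),
                                   NA_character_))
    observed[obs_key %in% pred_key]
  } else {
    observed[key_size(observed) %in% unique(as.integer(pred_size))]
  }
}

#' Concordance of observed 1-bp insertion bases with the template
#'
#' @param observed_bases Named numeric vector: base -> percentage of
#'   observed 1-bp insertions carrying that base (sums to <= 100).
#' @param template_base The -4 template base.
#' @return List: `match` (is the most frequent observed base the template
#'   base), `matching_fraction` (percentage mass on the template base), or
#'   `no_insertions = TRUE` when the mapping is empty.
#' @export
insertion_concordance <- function(observed_bases, template_base) {
  if (!length(observed_bases))
    return(list(no_insertions = TRUE, match = NA, matching_fraction = NA_real_))
  stopifnot(!is.null(names(observed_bases)),
            sum(observed_bases) <= 100 + 0.5)
  top <- names(observed_bases)[which.max(observed_bases)]
  frac <- if (template_base %in% names(observed_bases))
    unname(observed_bases[[template_base]]) else 0
  list(no_insertions = FALSE, match = top == template_base,
       matching_fraction = frac)
}

#' Tabulate prediction-vs-observation concordance across guides and models
#'
#' @param observed_by_guide Named list: guide id -> character vector of
#'   observed dominant indel keys (pooled across constructs).
#' @param predictions_by_guide Named list: guide id -> named list of
#'   predicted lists (model -> [prediction_set()] / sizes). A guide with no
#'   predictions yields warning rows with `NA` counts, not a failure.
#' @param strict Passed to [match_indels()].
#' @return data.frame: guide_id, model, n_observed, n_predicted, matched
#'   (comma-joined keys), n_matched; ordered by guide then model.
#' @export
concordance_report <- function(observed_by_guide, predictions_by_guide,
                               strict = FALSE) {
  rows <- list()
  models <- sort(unique(unlist(lapply(predictions_by_guide, names))))
  for (g in names(observed_by_guide)) {
    obs <- observed_by_guide[[g]]
    preds <- predictions_by_guide[[g]]
    if (is.null(preds)) {
      warning("no predictions for guide ", g)
      rows[[length(rows) + 1L]] <- data.frame(
        guide_id = g, model = NA_character_, n_observed = length(obs),
        n_predicted = NA_integer_, matched = NA_character_,
        n_matched = NA_integer_, stringsAsFactors = FALSE)
      next
    }
    for (m in intersect(models, names(preds))) {
      matched <- match_indels(obs, preds[[m]], strict = strict)
      np <- if (is.data.frame(preds[[m]])) nrow(preds[[m]]) else
        length(preds[[m]])
      rows[[length(rows) + 1L]] <- data.frame(
        guide_id = g, model = m, n_observed = length(obs),
        n_predicted = np, matched = paste(matched, collapse = ","),
        n_matched = length(matched), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$guide_id, out$model), ]
  rownames(out) <- NULL
  out
}
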