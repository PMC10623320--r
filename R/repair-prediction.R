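# Repair-outcome prediction from sequence context. Two mechanisms are
# modelled: microhomology-mediated end joining (deletions collapsing a short
# repeat flanking the cut, scored by repeat length, GC content and implied
# deletion size) and fill-in of the 1-nt 5' overhang left by staggered Cas9
# cleavage (a +1 insertion copying the base at the -4 position).

#' Enumerate microhomology patterns flanking a cut site
#'
#' Finds every repeated block of length >= `min_mh_len` with one copy ending
#' at or 5' of the cut (within `window` bp of it) and the other copy
#' covering or 3' of the cut (starting within `window` bp of it). Collapsing
#' the two copies by microhomology-mediated end joining deletes
#' `right_start - left_start` bp. Nested sub-patterns of a longer pattern at
#' the same locus (same implied deletion) are removed.
#'
#' @param sequence DNA string.
#' @param cut_pos 1-based index of the base 5' of the cut.
#' @param window Search window in bp on each side of the cut.
#' @param min_mh_len Minimum repeat length in nt.
#' @return data.frame: left_start, right_start, length, sequence,
#'   deletion_length, gc_count.
#' @export
enumerate_microhomologies <- function(sequence, cut_pos, window = 30L,
                                      min_mh_len = 2L) {
  sequence <- toupper(sequence)
  cut_pos <- as.integer(cut_pos)
  window <- as.integer(window)
  min_mh_len <- as.integer(min_mh_len)
  s <- strsplit(sequence, "")[[1]]
  L <- length(s)
  stopifnot(cut_pos >= 1L, cut_pos < L)
  out <- list()
  for (d in seq_len(min(cut_pos + window - 1L, L - 1L))) {
    eq <- s[seq_len(L - d)] == s[seq_len(L - d) + d]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (ri in which(r$values & r$lengths >= min_mh_len)) {
      a <- starts[ri]; b <- ends[ri]
      e <- min(b, cut_pos)                      # left copy end
      if (e < max(cut_pos - window + 1L, cut_pos + 1L - d)) next
      i <- max(a, e - d + 1L)                   # left copy start
      if (i + d > cut_pos + window) i <- cut_pos + window - d
      if (i < a || e - i + 1L < min_mh_len) next
      l <- e - i + 1L
      seq_mh <- substr(sequence, i, e)
      out[[length(out) + 1L]] <- data.frame(
        left_start = i, right_start = i + d, length = l,
        sequence = seq_mh, deletion_length = d,
        gc_count = sum(strsplit(seq_mh, "")[[1]] %in% c("G", "C")),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(left_start = integer(), right_start = integer(),
                      length = integer(), sequence = character(),
                      deletion_length = integer(), gc_count = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, out)
  out <- out[order(out$deletion_length, out$left_start), ]
  rownames(out) <- NULL
  out
}

#' Score microhomology patterns
#'
#' Pattern weight decays exponentially with the implied deletion length and
#' grows with pattern length, G/C bases counting double:
#' `100 * exp(-deletion_length / length_weight) * (2*GC + AT)`.
#'
#' @param patterns data.frame from [enumerate_microhomologies()].
#' @param length_weight Exponential decay constant in bp (default 20).
#' @return Numeric vector of non-negative scores.
#' @export
mh_pattern_score <- function(patterns, length_weight = 20) {
  at <- patterns$length - patterns$gc_count
  100 * exp(-patterns$deletion_length / length_weight) *
    (2 * patterns$gc_count + at)
}

#' Out-of-frame score of a cut site
#'
#' Score-weighted fraction (percent) of microhomology-mediated deletion
#' patterns whose implied deletion shifts the reading frame.
#'
#' @param patterns data.frame from [enumerate_microhomologies()].
#' @param length_weight Passed to [mh_pattern_score()].
#' @return Percent in `[0, 100]`, or `NA` when no patterns exist.
#' @export
out_of_frame_score <- function(patterns, length_weight = 20) {
  if (!nrow(patterns)) return(NA_real_)
  sc <- mh_pattern_score(patterns, length_weight)
  oof <- patterns$deletion_length %% 3L != 0L
  100 * sum(sc[oof]) / sum(sc)
}

# Normalization constant for mh_strength: fixed so that random
# GC-balanced 100-bp flanks give values centred near 0.5 (the middle of the
# "average" class); calibrated once on simulated sequence and frozen.
MH_STRENGTH_NORM <- 4400

#' Microhomology strength of the sequence flanking a cut
#'
#' Aggregates microhomology pattern scores over `flank` bp on each side of
#' the cut, additionally down-weighting patterns by their distance from the
#' cut (gap between the repeat copies and the cut site), and normalizes to a
#' unitless value classified as low (< 0.3), average (0.3-0.8) or
#' high (> 0.8). Sites with long, GC-rich repeats adjacent to the cut score
#' high; repair there is more likely to proceed by microhomology-mediated
#' deletions.
#'
#' @param sequence DNA string.
#' @param cut_pos 1-based index of the base 5' of the cut.
#' @param flank Flank length in bp on each side (default 100; clamped at the
#'   sequence ends).
#' @param min_mh_len Minimum repeat length.
#' @param length_weight Passed to [mh_pattern_score()].
#' @param distance_decay Exponential decay constant (bp) for the
#'   copy-to-cut gap.
#' @return List: `value` (>= 0) and `class` ("low", "average" or "high").
#' @export
mh_strength <- function(sequence, cut_pos, flank = 100L, min_mh_len = 2L,
                        length_weight = 20, distance_decay = 25) {
  pat <- enumerate_microhomologies(sequence, cut_pos, window = flank,
                                   min_mh_len = min_mh_len)
  value <- 0
  if (nrow(pat)) {
    sc <- mh_pattern_score(pat, length_weight)
    gap <- (cut_pos - (pat$left_start + pat$length - 1L)) +
      pmax(0L, pat$right_start - cut_pos - 1L)
    value <- sum(sc * exp(-gap / distance_decay)) / MH_STRENGTH_NORM
  }
  list(value = value, class = mh_strength_class(value))
}

#' @rdname mh_strength
#' @param value A strength value.
#' @export
mh_strength_class <- function(value) {
  ifelse(value < 0.3, "low", ifelse(value <= 0.8, "average", "high"))
}

#' Construct a prediction set
#'
#' @param model Model label.
#' @param size Signed indel sizes (bp).
#' @param weight Non-negative weights.
#' @param inserted_base Optional inserted base(s) for insertions.
#' @param normalize Rescale weights to sum to 1.
#' @return data.frame of class `"rootindel_prediction"` with attribute
#'   `model` and `normalized`.
#' @export
prediction_set <- function(model, size, weight, inserted_base = NULL,
                           normalize = TRUE) {
  size <- as.integer(size)
  stopifnot(length(size) == length(weight), all(weight >= 0),
            all(size != 0L))
  if (is.null(inserted_base)) inserted_base <- rep(NA_character_,
                                                   length(size))
  if (normalize) {
    if (sum(weight) <= 0) stop("cannot normalize zero-mass prediction")
    weight <- weight / sum(weight)
  }
  structure(data.frame(size = size, inserted_base = inserted_base,
                       weight = weight, stringsAsFactors = FALSE),
            model = model, normalized = normalize,
            class = c("rootindel_prediction", "data.frame"))
}

#' Predicted templated 1-bp insertion
#'
#' Staggered Cas9 cleavage leaves a 1-nt 5' overhang whose fill-in
#' duplicates the base at the -4 position relative to the PAM -- the base
#' immediately 5' of the cut. The predictor returns that single +1 insertion
#' with all the mass.
#'
#' @param sequence DNA string (protospacer-strand orientation).
#' @param cut_pos 1-based index of the base 5' of the cut.
#' @return A [prediction_set()] with one +1 entry, weight 1.
#' @export
templated_insertion <- function(sequence, cut_pos) {
  sequence <- toupper(sequence)
  if (cut_pos < 1L || cut_pos > nchar(sequence))
    stop("cut_pos outside sequence")
  base <- substr(sequence, cut_pos, cut_pos)
  prediction_set("templated_insertion", size = 1L, weight = 1,
                 inserted_base = base)
}

#' Combined predicted indel spectrum of a cut site
#'
#' Mixes microhomology-mediated deletion predictions (entries per implied
#' deletion size, weighted by summed pattern score) with the templated +1
#' insertion. The insertion receives `insertion_mass` of the total
#' (default 0.25, reflecting the roughly 3:1 deletion:insertion ratio of
#' observed repair outcomes).
#'
#' @param sequence DNA string.
#' @param cut_pos 1-based index of the base 5' of the cut.
#' @param insertion_mass Mass on the templated insertion, in `[0, 1]`.
#' @param window Microhomology search window (bp); implied deletions are
#'   also capped at `max_del`.
#' @param max_del Largest predicted deletion (bp).
#' @param min_mh_len,length_weight Passed to the microhomology stage.
#' @return A normalized [prediction_set()], or `NULL` (with a warning) when
#'   no mechanism yields an outcome.
#' @export
predict_spectrum <- function(sequence, cut_pos, insertion_mass = 0.25,
                             window = 30L, max_del = 30L, min_mh_len = 2L,
                             length_weight = 20) {
  stopifnot(insertion_mass >= 0, insertion_mass <= 1)
  pat <- enumerate_microhomologies(sequence, cut_pos, window = window,
                                   min_mh_len = min_mh_len)
  pat <- pat[pat$deletion_length <= max_del, , drop = FALSE]
  del_size <- integer(); del_w <- numeric()
  if (nrow(pat)) {
    sc <- tapply(mh_pattern_score(pat, length_weight),
                 pat$deletion_length, sum)
    del_size <- -as.integer(names(sc))
    del_w <- as.numeric(sc) / sum(sc) * (1 - insertion_mass)
  } else {
    insertion_mass <- if (insertion_mass > 0) 1 else 0
  }
  ins <- templated_insertion(sequence, cut_pos)
  size <- c(del_size, ins$size)
  weight <- c(del_w, insertion_mass)
  bases <- c(rep(NA_character_, length(del_size)), ins$inserted_base)
  keep <- weight > 0
  if (!any(keep)) {
    warning("no predicted outcome: no microhomology and zero insertion mass")
    return(NULL)
  }
  prediction_set("mh+templated", size[keep], weight[keep], bases[keep])
}

#' Top-k entries of a prediction set
#'
#' Orders entries by weight descending; ties broken by smaller absolute
#' size, then deletions before insertions.
#'
#' @param prediction A [prediction_set()].
#' @param k Number of entries (>= 1).
#' @return The top `min(k, nrow)` rows.
#' @export
top_k <- function(prediction, k = 5L) {
  if (k < 1L) stop("k must be at least 1")
  ord <- order(-prediction$weight, abs(prediction$size),
               prediction$size > 0)
  out <- prediction[ord, , drop = FALSE][seq_len(min(k, nrow(prediction))), ,
                                         drop = FALSE]
  rownames(out) <- NULL
  out
}
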