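#' rootindel: CRISPR editing-outcome quantification for hairy roots
#'
#' Tools to design sgRNAs on an amplicon, decompose mixed Sanger signal from
#' edited hairy roots into an indel spectrum, compute per-root INDEL and KO
#' scores, predict repair outcomes from sequence context, and compare
#' predictions with observations. A seeded synthetic-cohort generator makes
#' the whole pipeline testable without chromatogram data.
#'
#' @section Coordinate convention:
#' All positions are 1-based indices into the forward strand of the amplicon.
#' `cut_pos` is the index of the base immediately 5' of the blunt Cas9 cut,
#' i.e. the cut falls between `cut_pos` and `cut_pos + 1`. For a guide on the
#' plus strand this base is the -4 position relative to the PAM (SpCas9 cuts
#' between -4 and -3). Guides on the minus strand store their protospacer and
#' PAM in their own 5'->3' orientation but `cut_pos` in forward coordinates.
#'
#' @name rootindel-package
#' @keywords internal
"_PACKAGE"

BASES <- c("A", "C", "G", "T")

#' Default analysis thresholds
#'
#' Thresholds used throughout the pipeline. Defaults follow standard practice
#' for TIDE-style decomposition of Sanger-sequenced amplicons and knockout
#' calling in hairy-root screens.
#'
#' @param max_indel Largest indel size (bp) modelled by the decomposition.
#' @param p_cut Per-indel significance cutoff; indels with p-values at or
#'   above this are excluded from scores.
#' @param r2_cut Minimum decomposition R^2 for a root to be kept.
#' @param ko_len In-frame indels of at least this many bp still count as
#'   knockouts (likely null alleles).
#' @param dominance_pct Percentage above which an indel is called dominant
#'   within a root.
#' @param min_roots Minimum roots per group for a reportable summary.
#' @param mh_flank Flank length (bp) on each side of the cut used for
#'   microhomology-strength assessment.
#' @param template_offset Position relative to the PAM whose base templates
#'   1-bp insertions (the base immediately 5' of the cut).
#' @return A list of class `"rootindel_thresholds"`.
#' @export
default_thresholds <- function(max_indel = 30L, p_cut = 0.01, r2_cut = 0.7,
                               ko_len = 21L, dominance_pct = 20,
                               min_roots = 15L, mh_flank = 100L,
                               template_offset = -4L) {
  stopifnot(max_indel >= ko_len, max_indel > 0, ko_len > 0,
            p_cut > 0, p_cut < 1, r2_cut >= 0, r2_cut < 1,
            dominance_pct > 0, min_roots > 0, mh_flank > 0,
            template_offset == -4L)
  structure(list(max_indel = as.integer(max_indel), p_cut = p_cut,
                 r2_cut = r2_cut, ko_len = as.integer(ko_len),
                 dominance_pct = dominance_pct,
                 min_roots = as.integer(min_roots),
                 mh_flank = as.integer(mh_flank),
                 template_offset = as.integer(template_offset)),
            class = "rootindel_thresholds")
}

#' Construct an amplicon with annotated CDS bounds
#'
#' @param id Amplicon identifier.
#' @param sequence DNA string over A/C/G/T (lower case accepted, upper-cased).
#' @param cds_start,cds_end 1-based inclusive bounds of the coding sequence
#'   within `sequence`; the CDS length must be a multiple of 3.
#' @return An object of class `"rootindel_amplicon"`.
#' @export
amplicon <- function(id, sequence, cds_start, cds_end) {
  sequence <- toupper(sequence)
  if (grepl("[^ACGT]", sequence))
    stop("amplicon sequence must contain only A/C/G/T")
  cds_start <- as.integer(cds_start)
  cds_end <- as.integer(cds_end)
  if (!(cds_start >= 1 && cds_start < cds_end && cds_end <= nchar(sequence)))
    stop("CDS bounds must satisfy 1 <= cds_start < cds_end <= length(sequence)")
  if ((cds_end - cds_start + 1L) %% 3L != 0L)
    stop("CDS length must be divisible by 3")
  structure(list(id = id, sequence = sequence,
                 cds_start = cds_start, cds_end = cds_end),
            class = "rootindel_amplicon")
}

#' Construct a guide site on an amplicon
#'
#' @param guide_id Identifier.
#' @param protospacer 20-nt protospacer, 5'->3' on the protospacer strand.
#' @param pam 3-nt PAM (NGG), same orientation.
#' @param strand `"+"` or `"-"` relative to the amplicon.
#' @param cut_pos 1-based forward-strand index of the base 5' of the blunt cut.
#' @param cds_fraction Fraction of the CDS at which the cut falls, or `NA`.
#' @return An object of class `"rootindel_guide"`.
#' @export
guide_site <- function(guide_id, protospacer, pam, strand, cut_pos,
                       cds_fraction = NA_real_) {
  protospacer <- toupper(protospacer)
  pam <- toupper(pam)
  if (nchar(protospacer) != 20L) stop("protospacer must be 20 nt")
  if (!grepl("^[ACGT]GG$", pam)) stop("PAM must match NGG")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  cut_pos <- as.integer(cut_pos)
  if (cut_pos < 1L) stop("cut_pos must be positive")
  structure(list(guide_id = guide_id, protospacer = protospacer, pam = pam,
                 strand = strand, cut_pos = cut_pos,
                 cds_fraction = cds_fraction),
            class = "rootindel_guide")
}

#' Indel spectrum of a sequenced root
#'
#' An indel spectrum is the distribution of indel sizes in the sequence
#' population of one root (roots can be chimeric, so more than two alleles may
#' be present). Events are keyed by signed size plus, for insertions with
#' known bases, the inserted sequence; two insertions of equal size but
#' different bases are distinct events.
#'
#' @param sizes Signed integer indel sizes (negative = deletion, bp).
#' @param percentages Percentage of the sequence population per event.
#' @param inserted_bases Optional character vector; for insertions, the
#'   inserted sequence (or `NA` when unresolved, as from decomposition).
#' @param p_values Optional per-event p-values.
#' @param wt_percentage Percentage of unedited (wild-type) sequence.
#' @return An object of class `"rootindel_spectrum"`: a data.frame of events
#'   plus a `wt_percentage` attribute.
#' @export
indel_spectrum <- function(sizes = integer(), percentages = numeric(),
                           inserted_bases = NULL, p_values = NULL,
                           wt_percentage = 0) {
  sizes <- as.integer(sizes)
  n <- length(sizes)
  if (length(percentages) != n) stop("sizes and percentages lengths differ")
  if (is.null(inserted_bases)) inserted_bases <- rep(NA_character_, n)
  if (is.null(p_values)) p_values <- rep(NA_real_, n)
  if (any(sizes == 0L)) stop("indel size 0 is not an event")
  if (any(percentages < 0)) stop("percentages must be non-negative")
  ins_known <- !is.na(inserted_bases)
  if (any(ins_known & sizes < 0L))
    stop("deletions cannot carry inserted bases")
  if (any(nchar(inserted_bases[ins_known]) != sizes[ins_known]))
    stop("inserted_bases length must equal insertion size")
  key <- spectrum_key(sizes, inserted_bases)
  if (anyDuplicated(key)) stop("duplicate spectrum event keys")
  if (wt_percentage + sum(percentages) > 100 + 0.5)
    stop("percentages plus wild-type exceed 100")
  ev <- data.frame(size = sizes, inserted_bases = inserted_bases,
                   percentage = percentages, p_value = p_values,
                   key = key, stringsAsFactors = FALSE)
  ev <- ev[order(ev$size, ev$inserted_bases, method = "radix",
                 na.last = TRUE), , drop = FALSE]
  rownames(ev) <- NULL
  structure(ev, wt_percentage = wt_percentage,
            class = c("rootindel_spectrum", "data.frame"))
}

#' @rdname indel_spectrum
#' @param x A spectrum.
#' @export
wt_percentage <- function(x) attr(x, "wt_percentage")

spectrum_key <- function(sizes, inserted_bases) {
  ifelse(is.na(inserted_bases) | sizes < 0L,
         sprintf("%+d", sizes),
         sprintf("%+d:%s", sizes, inserted_bases))
}

#' Does an indel shift the reading frame?
#'
#' @param size Signed indel size in bp (non-zero).
#' @return `TRUE` iff `size` is not a multiple of 3.
#' @export
is_frameshift <- function(size) {
  size <- as.integer(size)
  if (any(size == 0L)) stop("indel size must be non-zero")
  size %% 3L != 0L
}

#' Is an indel expected to knock the gene out?
#'
#' An indel is counted as a knockout if it shifts the reading frame, or if it
#' is in-frame but at least `ko_len` bp long (either sign) -- large in-frame
#' indels are likely null alleles too.
#'
#' @param size Signed indel size in bp (non-zero).
#' @param ko_len Size threshold in bp (default 21).
#' @return Logical.
#' @export
is_knockout_indel <- function(size, ko_len = 21L) {
  is_frameshift(size) | abs(as.integer(size)) >= ko_len
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' @export
print.rootindel_spectrum <- function(x, ...) {
  cat(sprintf("Indel spectrum: %d event(s), wild-type %.1f%%\n",
              nrow(x), attr(x, "wt_percentage")))
  if (nrow(x)) print(as.data.frame(x)[, c("key", "percentage", "p_value")])
  invisible(x)
}
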