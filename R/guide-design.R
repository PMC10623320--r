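# sgRNA candidate enumeration and design filters: NGG-adjacent 20-mers on
# both strands, 5-65% CDS targeting window, 5' G (U6 transcription start),
# BbsI exclusion (cloning via a BbsI cut-ligation), and off-target dismissal
# by mismatch count and seed-region mismatches.

BBSI_PATTERN <- "GAAGAC|GTCTTC"

#' Enumerate all sgRNA candidates on an amplicon
#'
#' Every 20-nt window immediately 5' of an NGG PAM, on either strand, yields
#' one candidate. The cut position is projected onto CDS coordinates to give
#' `cds_fraction` (NA when the cut falls outside the CDS).
#'
#' @param amp An [amplicon()].
#' @return data.frame with columns guide_id, protospacer, pam, strand,
#'   cut_pos, cds_fraction, in_cds_window, starts_with_g, has_bbsi,
#'   off_target_risk_count (NA until [off_target_scan()] is run).
#' @export
enumerate_guides <- function(amp) {
  stopifnot(inherits(amp, "rootindel_amplicon"))
  s <- amp$sequence
  L <- nchar(s)
  rows <- list()
  # forward: protospacer p..p+19, PAM p+20..p+22 (positions p+21,p+22 = GG)
  gg <- gregexpr("(?=GG)", s, perl = TRUE)[[1]]
  if (gg[1] != -1) {
    for (q in gg) {                       # q = index of first G of the GG
      p <- q - 21L
      if (p >= 1L) {
        rows[[length(rows) + 1L]] <- list(
          protospacer = substr(s, p, p + 19L),
          pam = substr(s, p + 20L, p + 22L), strand = "+",
          cut_pos = p + 16L)
      }
    }
  }
  # reverse: forward m..m+2 = CCN is the PAM, protospacer m+3..m+22
  cc <- gregexpr("(?=CC)", s, perl = TRUE)[[1]]
  if (cc[1] != -1) {
    for (m in cc) {
      if (m + 22L <= L) {
        rows[[length(rows) + 1L]] <- list(
          protospacer = revcomp(substr(s, m + 3L, m + 22L)),
          pam = revcomp(substr(s, m, m + 2L)), strand = "-",
          cut_pos = m + 5L)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(guide_id = character(), protospacer = character(),
                      pam = character(), strand = character(),
                      cut_pos = integer(), cds_fraction = numeric(),
                      in_cds_window = logical(), starts_with_g = logical(),
                      has_bbsi = logical(),
                      off_target_risk_count = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, lapply(rows, as.data.frame,
                               stringsAsFactors = FALSE))
  cds_len <- amp$cds_end - amp$cds_start + 1L
  # cut falls between cut_pos and cut_pos+1; fraction measured at the cut
  out$cds_fraction <- ifelse(out$cut_pos >= amp$cds_start &
                               out$cut_pos < amp$cds_end,
                             (out$cut_pos - amp$cds_start + 1) / cds_len,
                             NA_real_)
  out$in_cds_window <- !is.na(out$cds_fraction) &
    out$cds_fraction >= 0.05 & out$cds_fraction <= 0.65
  out$starts_with_g <- startsWith(out$protospacer, "G")
  out$has_bbsi <- grepl(BBSI_PATTERN, paste0(out$protospacer, out$pam))
  out$off_target_risk_count <- NA_integer_
  out$guide_id <- sprintf("%s_%s%d", amp$id,
                          ifelse(out$strand == "+", "f", "r"), out$cut_pos)
  out <- out[order(out$cut_pos, out$strand), c(
    "guide_id", "protospacer", "pam", "strand", "cut_pos", "cds_fraction",
    "in_cds_window", "starts_with_g", "has_bbsi", "off_target_risk_count")]
  rownames(out) <- NULL
  out
}

#' Apply the sgRNA design filters
#'
#' Retains candidates cutting within the 5-65% CDS window, whose protospacer
#' starts with G (required by the U6 promoter), and whose protospacer + PAM
#' contain no BbsI recognition site (GAAGAC or GTCTTC, which would interfere
#' with BbsI-based cloning).
#'
#' @param candidates Output of [enumerate_guides()].
#' @return Subset of `candidates`; applying the filter twice is a no-op.
#' @export
filter_guides <- function(candidates) {
  candidates[candidates$in_cds_window & candidates$starts_with_g &
               !candidates$has_bbsi, , drop = FALSE]
}

#' Scan background sequences for off-target sites
#'
#' Finds every NGG-adjacent 20-mer in the background (both strands), counts
#' Hamming mismatches to the protospacer, and flags seed-region mismatches
#' (within `seed_len` PAM-proximal bases). Hits with more than 4 mismatches
#' including at least one in the seed are dismissed; exact matches are
#' treated as the on-target site. The off-target risk count is the number of
#' non-dismissed, non-exact hits.
#'
#' @param guide A [guide_site()] or one row of [enumerate_guides()] output.
#' @param background Named character vector of DNA sequences (or
#'   `Biostrings::DNAStringSet`).
#' @param seed_len Seed-region length in nt (default 12).
#' @return data.frame of hits (seq_id, position, strand, site, pam,
#'   mismatches, seed_mismatch, dismissed) with attribute `risk_count`.
#' @export
off_target_scan <- function(guide, background, seed_len = 12L) {
  proto <- strsplit(guide$protospacer, "")[[1]]
  seed_idx <- (20L - seed_len + 1L):20L
  if (inherits(background, "DNAStringSet"))
    background <- as.character(background)
  if (is.null(names(background)))
    names(background) <- sprintf("bg%d", seq_along(background))
  hits <- list()
  for (id in names(background)) {
    for (str in c("+", "-")) {
      s <- toupper(background[[id]])
      if (str == "-") s <- revcomp(s)
      gg <- gregexpr("(?=GG)", s, perl = TRUE)[[1]]
      if (gg[1] == -1) next
      for (q in gg) {
        p <- q - 21L
        if (p < 1L) next
        site <- substr(s, p, p + 19L)
        mm <- which(strsplit(site, "")[[1]] != proto)
        hits[[length(hits) + 1L]] <- data.frame(
          seq_id = id, position = p, strand = str, site = site,
          pam = substr(s, p + 20L, p + 22L), mismatches = length(mm),
          seed_mismatch = any(mm %in% seed_idx),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(hits)) do.call(rbind, hits) else
    data.frame(seq_id = character(), position = integer(),
               strand = character(), site = character(), pam = character(),
               mismatches = integer(), seed_mismatch = logical(),
               stringsAsFactors = FALSE)
  out$dismissed <- out$mismatches > 4L & out$seed_mismatch
  attr(out, "risk_count") <- sum(!out$dismissed & out$mismatches > 0L)
  out
}

#' @rdname off_target_scan
#' @param hits Output of `off_target_scan`.
#' @export
off_target_risk_count <- function(hits) attr(hits, "risk_count")

#' Rank guide candidates
#'
#' Orders by off-target risk (ascending), then predicted efficiency score
#' (descending), then cut position (ascending) as a tie-break.
#'
#' @param candidates data.frame of candidates with `off_target_risk_count`.
#' @param efficiency_scores Named numeric vector, guide_id -> score.
#' @return `candidates`, reordered.
#' @export
rank_guides <- function(candidates, efficiency_scores) {
  missing <- setdiff(candidates$guide_id, names(efficiency_scores))
  if (length(missing))
    stop("no efficiency score for guide(s): ",
         paste(missing, collapse = ", "))
  sc <- efficiency_scores[candidates$guide_id]
  out <- candidates[order(candidates$off_target_risk_count, -sc,
                          candidates$cut_pos), , drop = FALSE]
  out$efficiency_score <- efficiency_scores[out$guide_id]
  rownames(out) <- NULL
  out
}
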