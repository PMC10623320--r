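# Synthetic cohorts emulating the editing structure seen in hairy-root
# screens: chimeric roots carrying 1-4 dominant indels (>20% each), a pooled
# indel-size distribution with ~3:1 deletions:insertions, and 1-bp insertions
# templated from the base 5' of the cut.

#' Evaluate code under a temporary RNG seed
#'
#' Sets the seed, evaluates, and restores the caller's RNG state.
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @param code Expression to evaluate.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Derive a stream seed from a master seed
#'
#' Deterministically mixes a master seed with one or more stream indices via
#' an iterated Lehmer step; the result always stays below 2^31 so it is a
#' valid [set.seed()] input.
#'
#' @param seed Master integer seed.
#' @param ... Integer stream indices.
#' @return A single integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, ...) {
  x <- as.double(seed %% 2147483647L)
  for (i in c(...)) x <- (x * 48271 + as.double(i) + 1) %% 2147483647
  as.integer(x)
}

#' Load the pooled indel-size weight table
#'
#' @param path TSV with columns `size` (signed bp) and `weight`; defaults to
#'   the fixture shipped with the package (see its header comments for the
#'   provenance of each mass).
#' @return data.frame with columns `size`, `weight` (weights sum to 1).
#' @export
read_size_weights <- function(path = system.file("extdata",
                                                 "pooled_size_weights.tsv",
                                                 package = "rootindel")) {
  w <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("size", "weight") %in% names(w)))
  if (abs(sum(w$weight) - 1) > 1e-9) stop("size weights must sum to 1")
  if (any(w$size == 0)) stop("size 0 has no weight")
  w
}

#' Configuration of the synthetic repair-outcome generator
#'
#' @param size_weights data.frame (`size`, `weight`) giving the pooled indel
#'   size distribution; defaults to the shipped fixture.
#' @param dominant_count_range Integer range (inclusive) for the number of
#'   dominant indels per root.
#' @param wt_fraction_range Range for the unedited fraction of a root.
#' @param template_bias Probability that a +1 insertion copies the base 5' of
#'   the cut (the -4 position relative to the PAM).
#' @param noise_sd Gaussian noise SD added to each trace signal fraction.
#' @return A list of class `"rootindel_spectrum_config"`.
#' @export
repair_spectrum_config <- function(size_weights = read_size_weights(),
                                   dominant_count_range = c(1L, 4L),
                                   wt_fraction_range = c(0.10, 0.35),
                                   template_bias = 0.75,
                                   noise_sd = 0.01) {
  dominant_count_range <- as.integer(dominant_count_range)
  stopifnot(length(dominant_count_range) == 2,
            dominant_count_range[1] >= 1L,
            dominant_count_range[1] <= dominant_count_range[2],
            dominant_count_range[2] <= 4L,
            length(wt_fraction_range) == 2,
            wt_fraction_range[1] >= 0, wt_fraction_range[2] <= 1,
            wt_fraction_range[1] <= wt_fraction_range[2],
            template_bias >= 0, template_bias <= 1, noise_sd >= 0)
  structure(list(size_weights = size_weights,
                 dominant_count_range = dominant_count_range,
                 wt_fraction_range = wt_fraction_range,
                 template_bias = template_bias, noise_sd = noise_sd),
            class = "rootindel_spectrum_config")
}

# Randomized systematic probability-proportional-to-size draw of k distinct
# items. Inclusion probability of item i is exactly k * p_i (requires
# k * max(p) <= 1), so event frequencies pooled over many draws reproduce p.
sample_sizes_pps <- function(sizes, probs, k) {
  if (k * max(probs) > 1 + 1e-9)
    stop("cannot draw ", k, " distinct sizes with inclusion probability <= 1")
  ord <- sample.int(length(sizes))
  cum <- cumsum(probs[ord] * k)
  pts <- stats::runif(1) + seq_len(k) - 1
  idx <- vapply(pts, function(x) which(cum > x)[1], integer(1))
  sizes[ord[idx]]
}

#' Sample the indel spectrum of one synthetic root
#'
#' Draws a chimeric-root spectrum: an unedited fraction, then `k` dominant
#' indels (each above the dominance threshold) with sizes drawn from the
#' pooled size distribution by a randomized systematic
#' probability-proportional-to-size scheme, so that pooled over many roots
#' each size occurs at its configured frequency. Insertions of 1 bp copy the
#' template base with probability `template_bias`.
#'
#' @param config A [repair_spectrum_config()].
#' @param template_base Base 5' of the cut on the protospacer strand (the -4
#'   position relative to the PAM), templating +1 insertions.
#' @param root_seed Integer seed for this root, or `NULL`.
#' @param thresholds A [default_thresholds()].
#' @return A [indel_spectrum()].
#' @export
sample_root_spectrum <- function(config, template_base = "A",
                                 root_seed = NULL,
                                 thresholds = default_thresholds()) {
  stopifnot(inherits(config, "rootindel_spectrum_config"),
            template_base %in% BASES)
  dp <- thresholds$dominance_pct
  if (config$dominant_count_range[1] * dp >=
      100 * (1 - config$wt_fraction_range[1]))
    stop("dominance constraint unsatisfiable for this configuration")
  with_seed(root_seed, {
    wt_frac <- stats::runif(1, config$wt_fraction_range[1],
                            config$wt_fraction_range[2])
    edited_pct <- 100 * (1 - wt_frac)
    if (edited_pct < 1)
      return(indel_spectrum(wt_percentage = 100 - edited_pct))
    k <- sample(seq(config$dominant_count_range[1],
                    config$dominant_count_range[2]), 1)
    k <- max(1L, min(k, as.integer(floor(edited_pct / dp))))
    sizes <- sample_sizes_pps(config$size_weights$size,
                              config$size_weights$weight, k)
    spare <- max(0, edited_pct - k * dp)
    extra <- stats::rgamma(k, shape = 1)
    pct <- pmin(edited_pct, dp) + extra / sum(extra) * spare
    bases <- rep(NA_character_, k)
    for (i in which(sizes > 0)) {
      if (sizes[i] == 1L) {
        bases[i] <- if (stats::runif(1) < config$template_bias) template_base
                    else sample(setdiff(BASES, template_base), 1)
      } else {
        bases[i] <- paste(sample(BASES, sizes[i], replace = TRUE),
                          collapse = "")
      }
    }
    indel_spectrum(sizes, pct, inserted_bases = bases,
                   wt_percentage = 100 - edited_pct)
  })
}

one_hot <- function(sequence) {
  b <- strsplit(sequence, "")[[1]]
  m <- matrix(0, nrow = length(b), ncol = 4, dimnames = list(NULL, BASES))
  m[cbind(seq_along(b), match(b, BASES))] <- 1
  m
}

# Per-position base-signal matrix of one allele, aligned to the reference
# frame: identical to the reference up to cut_pos, then shifted by the indel.
# Rows running off the template end (deletions) and unknown inserted bases
# are uniform 0.25.
allele_matrix <- function(ref, cut_pos, size, inserted_bases = NA) {
  L <- nrow(ref)
  m <- matrix(0.25, nrow = L, ncol = 4, dimnames = list(NULL, BASES))
  m[seq_len(cut_pos), ] <- ref[seq_len(cut_pos), ]
  if (size == 0) return(ref)
  if (size < 0) {
    src <- (cut_pos + 1 - size):L          # shift left by |size|
    keep <- src <= L
    dst <- (cut_pos + 1):(cut_pos + sum(keep))
    m[dst, ] <- ref[src[keep], ]
  } else {
    if (!is.na(inserted_bases))
      m[cut_pos + seq_len(size), ] <- one_hot(inserted_bases)
    dst <- (cut_pos + size + 1):L
    m[dst, ] <- ref[(cut_pos + 1):(L - size), ]
  }
  m
}

add_trace_noise <- function(m, noise_sd) {
  if (noise_sd > 0) {
    m <- m + matrix(stats::rnorm(length(m), sd = noise_sd), nrow = nrow(m))
    m <- pmax(m, 0)
  }
  m / rowSums(m)
}

#' Synthesize paired control/edited trace matrices
#'
#' Builds the per-position base-signal matrices a Sanger chromatogram would
#' yield for an unedited control and for the mixed sequence population of an
#' edited root: upstream of the cut all alleles agree with the reference;
#' downstream, each allele contributes its shifted sequence weighted by its
#' percentage.
#'
#' @param amp An [amplicon()].
#' @param site A [guide_site()] on `amp`.
#' @param spectrum The root's [indel_spectrum()].
#' @param noise_sd Gaussian noise SD per signal fraction (rows renormalized).
#' @param seed Optional integer seed.
#' @param max_indel Largest indel size representable (error above this).
#' @return List with matrices `control` and `edited` (rows = positions,
#'   columns A/C/G/T, each row summing to 1).
#' @export
synthesize_traces <- function(amp, site, spectrum, noise_sd = 0, seed = NULL,
                              max_indel = 30L) {
  stopifnot(inherits(amp, "rootindel_amplicon"),
            inherits(site, "rootindel_guide"))
  if (nrow(spectrum) && any(abs(spectrum$size) > max_indel))
    stop("invalid spectrum: event exceeds max_indel of ", max_indel, " bp")
  ref <- one_hot(amp$sequence)
  cut <- site$cut_pos
  pct <- c(attr(spectrum, "wt_percentage"), spectrum$percentage)
  total <- sum(pct)
  if (total <= 0) stop("spectrum has no mass")
  frac <- pct / total
  edited <- frac[1] * ref
  if (nrow(spectrum)) {
    for (i in seq_len(nrow(spectrum))) {
      edited <- edited + frac[i + 1] *
        allele_matrix(ref, cut, spectrum$size[i], spectrum$inserted_bases[i])
    }
  }
  with_seed(seed, list(control = add_trace_noise(ref, noise_sd),
                       edited = add_trace_noise(edited, noise_sd)))
}

#' Generate a random amplicon with an internal CDS and a usable guide site
#'
#' The CDS starts with ATG, ends with a stop codon, is in frame, and the
#' amplicon is regenerated (bounded retries) until at least one NGG-adjacent
#' guide site cuts inside the 5-65% CDS targeting window.
#'
#' @param length Amplicon length in nt (>= 120).
#' @param gc_fraction Target GC content of the random background.
#' @param seed Integer seed; output is deterministic given the seed.
#' @return An [amplicon()].
#' @export
make_amplicon <- function(length, gc_fraction = 0.5, seed = 1L) {
  stopifnot(length >= 120)
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  for (try in 1:50) {
    amp <- with_seed(derive_seed(seed, try), {
      s <- sample(BASES, length, replace = TRUE, prob = p)
      cds_start <- sample(4:12, 1)
      cds_len <- ((length - cds_start - 3) %/% 3) * 3
      cds_end <- cds_start + cds_len - 1
      s[cds_start:(cds_start + 2)] <- c("A", "T", "G")
      s[(cds_end - 2):cds_end] <- strsplit(sample(c("TAA", "TAG", "TGA"), 1),
                                           "")[[1]]
      amplicon(sprintf("synthetic_len%d_seed%d", length, seed),
               paste(s, collapse = ""), cds_start, cds_end)
    })
    cands <- enumerate_guides(amp)
    if (nrow(cands) && any(cands$in_cds_window)) return(amp)
  }
  stop("could not place a guide site in the CDS window after 50 attempts")
}

#' Pick the study guide for an amplicon
#'
#' Prefers a fully filter-passing candidate (CDS window, 5' G, no BbsI),
#' falling back to any in-window candidate.
#' @param amp An [amplicon()].
#' @return A [guide_site()].
#' @export
pick_study_guide <- function(amp) {
  cands <- enumerate_guides(amp)
  if (!nrow(cands)) stop("no guide candidates on amplicon ", amp$id)
  keep <- filter_guides(cands)
  if (!nrow(keep)) keep <- cands[cands$in_cds_window, , drop = FALSE]
  if (!nrow(keep)) stop("no in-window guide candidate on amplicon ", amp$id)
  # prefer + strand so spectrum inserted bases are in forward orientation
  keep <- keep[order(keep$strand != "+", keep$cut_pos), , drop = FALSE]
  guide_site(keep$guide_id[1], keep$protospacer[1], keep$pam[1],
             keep$strand[1], keep$cut_pos[1], keep$cds_fraction[1])
}

#' Base templating 1-bp insertions at a guide site
#'
#' Returns the base at the -4 position relative to the PAM (immediately 5' of
#' the cut on the protospacer strand), in forward coordinates for + guides
#' and complemented for - guides.
#' @param amp An [amplicon()].
#' @param site A [guide_site()].
#' @return Single character base.
#' @export
site_template_base <- function(amp, site) {
  b <- substr(amp$sequence, site$cut_pos + (site$strand == "-"),
              site$cut_pos + (site$strand == "-"))
  if (site$strand == "-") revcomp(b) else b
}

#' Introduce a seed-region SNP next to the PAM
#'
#' Substitutes the protospacer base immediately adjacent to the PAM
#' (protospacer position 20) with a different base, reproducing the
#' seed-mismatch scenario that abolishes cleavage.
#'
#' @param amp An [amplicon()].
#' @param site A [guide_site()] on `amp`.
#' @param seed Optional integer seed for the substituted base.
#' @return A copy of `amp` with one substitution.
#' @export
inject_seed_snp <- function(amp, site, seed = NULL) {
  pos <- if (site$strand == "+") site$cut_pos + 3L else site$cut_pos - 2L
  stopifnot(pos >= 1, pos <= nchar(amp$sequence))
  old <- substr(amp$sequence, pos, pos)
  new <- with_seed(seed, sample(setdiff(BASES, old), 1))
  s <- amp$sequence
  substr(s, pos, pos) <- new
  amplicon(paste0(amp$id, "_seedSNP"), s, amp$cds_start, amp$cds_end)
}

#' Study design for a synthetic cohort
#'
#' Mirrors a hairy-root promoter-comparison screen: `n_guides` sgRNAs, each
#' paired with every construct (promoter driving Cas9), with `n_roots`
#' independent roots per guide x construct group. Each construct carries its
#' own unedited-fraction range, so configured mean editing levels are
#' recoverable downstream.
#'
#' @param n_guides Number of sgRNAs (each on its own amplicon).
#' @param n_roots Roots per guide x construct group.
#' @param constructs Named list: construct label -> length-2 unedited-fraction
#'   range for roots of that construct.
#' @param amplicon_length,gc_fraction Amplicon generation parameters.
#' @param spectrum A [repair_spectrum_config()].
#' @param noise_sd Trace noise SD.
#' @param seed Master seed.
#' @param traces Generate trace matrices (set `FALSE` for score-level work).
#' @return A list of class `"rootindel_study_config"`.
#' @export
study_config <- function(n_guides = 9L, n_roots = 15L,
                         constructs = list(pMR356 = c(0.10, 0.35),
                                           pMR394 = c(0.15, 0.45)),
                         amplicon_length = 300L, gc_fraction = 0.5,
                         spectrum = repair_spectrum_config(),
                         noise_sd = 0.01, seed = 1L, traces = TRUE) {
  stopifnot(n_guides >= 1, n_roots >= 1, length(constructs) >= 1,
            !is.null(names(constructs)), amplicon_length >= 120)
  structure(list(n_guides = as.integer(n_guides),
                 n_roots = as.integer(n_roots), constructs = constructs,
                 amplicon_length = as.integer(amplicon_length),
                 gc_fraction = gc_fraction, spectrum = spectrum,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 traces = isTRUE(traces)),
            class = "rootindel_study_config")
}

#' Simulate a full synthetic study
#'
#' @param config A [study_config()].
#' @return List with `amplicons`, `sites` (named by guide), `records`
#'   (data.frame: guide_id, construct, root_id, seed), `spectra` (ground-truth
#'   spectra named by root_id) and, when requested, `traces` (named list of
#'   control/edited pairs). Deterministic for a fixed master seed.
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "rootindel_study_config"))
  amplicons <- list(); sites <- list()
  for (g in seq_len(config$n_guides)) {
    amp <- make_amplicon(config$amplicon_length, config$gc_fraction,
                         seed = derive_seed(config$seed, g))
    site <- pick_study_guide(amp)
    gid <- sprintf("sgRNA%d", g)
    site$guide_id <- gid
    amplicons[[gid]] <- amp
    sites[[gid]] <- site
  }
  records <- expand.grid(root = seq_len(config$n_roots),
                         construct = names(config$constructs),
                         guide_id = names(sites),
                         stringsAsFactors = FALSE)[, 3:1]
  records$root_id <- sprintf("%s_%s_root%02d", records$guide_id,
                             records$construct, records$root)
  records$seed <- derive_seed(config$seed, 999) +
    seq_len(nrow(records))
  records$root <- NULL
  spectra <- list(); traces <- if (config$traces) list() else NULL
  for (i in seq_len(nrow(records))) {
    gid <- records$guide_id[i]
    amp <- amplicons[[gid]]; site <- sites[[gid]]
    cfg <- config$spectrum
    cfg$wt_fraction_range <- config$constructs[[records$construct[i]]]
    sp <- sample_root_spectrum(cfg, site_template_base(amp, site),
                               root_seed = records$seed[i])
    spectra[[records$root_id[i]]] <- sp
    if (config$traces)
      traces[[records$root_id[i]]] <-
        synthesize_traces(amp, site, sp, noise_sd = config$noise_sd,
                          seed = derive_seed(records$seed[i], 1))
  }
  list(amplicons = amplicons, sites = sites, records = records,
       spectra = spectra, traces = traces, config = config)
}
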