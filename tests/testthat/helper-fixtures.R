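# Shared fixture builders. Everything is generated in code; no binary data.

# Small amplicon with a known + strand guide site, built by hand so the
# guide geometry is fully known: protospacer at 61..80, PAM (TGG) at 81..83,
# cut between 76 and 77.
fixture_amplicon <- function() {
  set.seed(404)
  bg <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                                 prob = c(.3, .2, .2, .3)), collapse = "")
  proto <- "GTCAGATCCATTAGACCTAA"   # starts with G, no BbsI site
  seq <- paste0(bg(45), "ATG", bg(12), proto, "TGG", bg(151),
                "TAA", bg(45))
  # ATG at 46..48, protospacer 61..80, PAM 81..83, TAA at 235..237:
  # CDS 46..237 (192 nt, in frame), cut between 76 and 77
  amplicon("fx", seq, 46, 237)
}

fixture_site <- function(amp = fixture_amplicon()) {
  cands <- enumerate_guides(amp)
  row <- cands[cands$protospacer == "GTCAGATCCATTAGACCTAA", ]
  stopifnot(nrow(row) == 1)
  guide_site(row$guide_id, row$protospacer, row$pam, row$strand,
             row$cut_pos, row$cds_fraction)
}

# Spectrum with known composition for mixture tests.
two_allele_spectrum <- function(size, pct, bases = NA_character_) {
  indel_spectrum(size, pct, inserted_bases = bases,
                 wt_percentage = 100 - sum(pct))
}

# Independent brute-force microhomology enumeration: O(n^3) scan of all
# substring pairs, constraints applied literally, then per-offset/per-run
# maximality dedup.
brute_mh <- function(sequence, cut, window, min_len) {
  s <- strsplit(toupper(sequence), "")[[1]]
  L <- length(s)
  adm <- list()
  for (i in seq_len(L)) {
    for (l in min_len:(L - i + 1L)) {
      e <- i + l - 1L
      for (j in seq_len(L)) {
        d <- j - i
        if (d < l) next                         # non-overlapping copies
        if (j + l - 1L > L) next
        if (!identical(s[i:e], s[j:(j + l - 1L)])) next
        if (e > cut) next                       # left block 5' of cut
        if (e < cut - window + 1L) next         # left end near cut
        if (j + l - 1L < cut + 1L) next         # right block reaches cut
        if (j > cut + window) next              # right start near cut
        adm[[length(adm) + 1L]] <- c(i = i, e = e, d = d)
      }
    }
  }
  if (!length(adm)) return(data.frame(left_start = integer(),
                                      deletion_length = integer(),
                                      length = integer()))
  adm <- unique(do.call(rbind, adm))
  # run id: maximal stretch around [i, e] where s[x] == s[x + d]
  run_start <- function(i, d) {
    while (i > 1L && s[i - 1L] == s[i - 1L + d]) i <- i - 1L
    i
  }
  rid <- apply(adm, 1, function(r) paste(r["d"], run_start(r["i"], r["d"])))
  keep <- do.call(rbind, lapply(split(seq_len(nrow(adm)), rid), function(ix) {
    x <- adm[ix, , drop = FALSE]
    x <- x[order(-x[, "e"], x[, "i"]), , drop = FALSE]
    x[1, ]
  }))
  out <- data.frame(left_start = keep[, "i"],
                    deletion_length = keep[, "d"],
                    length = keep[, "e"] - keep[, "i"] + 1L)
  out[order(out$deletion_length, out$left_start), ]
}

mh_key <- function(df) {
  sprintf("%d:%d:%d", df$left_start, df$deletion_length, df$length)
}
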