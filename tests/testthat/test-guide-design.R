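# Regex-based oracle: protospacer+PAM sites on one strand of a sequence.
scan_strand <- function(s) {
  hits <- gregexpr("(?=([ACGT]{21}GG))", s, perl = TRUE)[[1]]
  if (hits[1] == -1) integer() else as.integer(hits)
}

test_that("guide enumeration matches a brute-force regex scan", {
  amp <- make_amplicon(300, 0.5, 11)
  cands <- enumerate_guides(amp)
  s <- amp$sequence
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  fwd <- scan_strand(s)
  rev <- scan_strand(rc)
  expect_identical(sum(cands$strand == "+"), length(fwd))
  expect_identical(sum(cands$strand == "-"), length(rev))
  expect_setequal(cands$protospacer[cands$strand == "+"],
                  unique(substring(s, fwd, fwd + 19)))
  # every forward candidate is followed by NGG on the amplicon
  for (i in which(cands$strand == "+")) {
    p <- cands$cut_pos[i] - 16L
    expect_identical(substr(s, p, p + 19), cands$protospacer[i])
    expect_match(substr(s, p + 20, p + 22), "^[ACGT]GG$")
  }
})

test_that("no PAM means no candidates; a single site is found", {
  a <- amplicon("noPAM", paste(rep("ACT", 20), collapse = ""), 1, 60)
  expect_identical(nrow(enumerate_guides(a)), 0L)
  one <- amplicon("one", paste0(strrep("A", 30), strrep("G", 20), "AGG",
                                strrep("A", 67)), 1, 120)
  cands <- enumerate_guides(one)
  fwd <- cands[cands$strand == "+", ]
  # the G-run protospacer with the AGG PAM is among the candidates
  hit <- fwd[fwd$protospacer == strrep("G", 20) & fwd$pam == "AGG", ]
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$cut_pos, 47L)  # 3 bp 5' of the AGG PAM at 51
})

test_that("enumeration is invariant under reverse complementation", {
  amp <- make_amplicon(300, 0.5, 13)
  L <- nchar(amp$sequence)
  rc_seq <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(amp$sequence)))
  rc <- amplicon("rc", rc_seq, L + 1 - amp$cds_end, L + 1 - amp$cds_start)
  a <- enumerate_guides(amp)
  b <- enumerate_guides(rc)
  expect_identical(nrow(a), nrow(b))
  # candidates map onto each other with strands swapped and cut mirrored
  key_a <- paste(a$protospacer, a$pam, a$strand, a$cut_pos)
  key_b <- paste(b$protospacer, b$pam,
                 ifelse(b$strand == "+", "-", "+"), L - b$cut_pos)
  expect_setequal(key_a, key_b)
})

test_that("design filters enforce window, 5' G and BbsI exclusion", {
  amp <- fixture_amplicon()
  cands <- enumerate_guides(amp)
  keep <- filter_guides(cands)
  expect_true(all(keep$cds_fraction >= 0.05 & keep$cds_fraction <= 0.65))
  expect_true(all(startsWith(keep$protospacer, "G")))
  expect_false(any(grepl("GAAGAC|GTCTTC",
                         paste0(keep$protospacer, keep$pam))))
  # idempotent and a subset of the input
  expect_identical(filter_guides(keep), keep)
  expect_true(all(keep$guide_id %in% cands$guide_id))
  # constructed pass/fail pairs on each single rule
  fake <- data.frame(
    guide_id = c("w", "g", "b", "ok"),
    protospacer = c("GTCAGATCCATTAGACCTAA", "ATCAGATCCATTAGACCTAA",
                    "GAAGACTCCATTAGACCTAA", "GTCAGATCCATTAGACCTAA"),
    pam = "TGG", strand = "+", cut_pos = 100L,
    cds_fraction = c(0.04, 0.30, 0.30, 0.30),
    stringsAsFactors = FALSE)
  fake$in_cds_window <- !is.na(fake$cds_fraction) &
    fake$cds_fraction >= 0.05 & fake$cds_fraction <= 0.65
  fake$starts_with_g <- startsWith(fake$protospacer, "G")
  fake$has_bbsi <- grepl("GAAGAC|GTCTTC", paste0(fake$protospacer, fake$pam))
  fake$off_target_risk_count <- NA_integer_
  expect_identical(filter_guides(fake)$guide_id, "ok")
})

test_that("off-target hits are dismissed by the mismatch/seed rule", {
  g <- guide_site("g", "GTCAGATCCATTAGACCTAA", "TGG", "+", 17)
  on_target <- paste0("AAAA", "GTCAGATCCATTAGACCTAA", "TGGAAAA")
  hits <- off_target_scan(g, c(bg = on_target))
  expect_identical(off_target_risk_count(hits), 0L)
  # 5 mismatches, one in the 12-nt seed: dismissed
  far <- "GACTGCTCCATTAGACCAAT"  # pos 2,4,6 (non-seed) + 18,20 (seed)
  h2 <- off_target_scan(g, c(bg = paste0("AA", far, "AGGAA")))
  expect_identical(h2$mismatches, 5L)
  expect_true(h2$seed_mismatch)
  expect_true(h2$dismissed)
  expect_identical(off_target_risk_count(h2), 0L)
  # 2 mismatches, none in seed: counted (brute-force check of the distance)
  near <- "GACTGATCCATTAGACCTAA"  # pos 2 and 4 differ
  expect_identical(sum(strsplit(near, "")[[1]] !=
                         strsplit(g$protospacer, "")[[1]]), 2L)
  h3 <- off_target_scan(g, c(bg = paste0("AA", near, "AGGAA")))
  expect_false(h3$dismissed)
  expect_identical(off_target_risk_count(h3), 1L)
})

test_that("ranking orders by risk, then score, then position", {
  cands <- data.frame(guide_id = c("a", "b", "c", "d"),
                      cut_pos = c(50L, 40L, 30L, 20L),
                      off_target_risk_count = c(0L, 0L, 3L, 0L),
                      stringsAsFactors = FALSE)
  sc <- c(a = 90, b = 70, c = 95, d = 90)
  r <- rank_guides(cands, sc)
  # equal risk: higher score first; equal risk+score: smaller cut_pos first
  expect_identical(r$guide_id, c("d", "a", "b", "c"))
  expect_error(rank_guides(cands, sc[-2]), "b")
})
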