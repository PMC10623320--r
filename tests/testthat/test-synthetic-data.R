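test_that("amplicon generation is seeded and respects GC content", {
  a1 <- make_amplicon(300, 0.5, 7)
  a2 <- make_amplicon(300, 0.5, 7)
  expect_identical(a1$sequence, a2$sequence)
  expect_identical(a1$cds_start, a2$cds_start)
  # gc = 1: only G/C outside the forced ATG and stop codon
  g <- make_amplicon(300, 1.0, 7)
  inner <- strsplit(g$sequence, "")[[1]]
  inner <- inner[-c(g$cds_start:(g$cds_start + 2),
                    (g$cds_end - 2):g$cds_end)]
  expect_true(all(inner %in% c("G", "C")))
  # a GG dinucleotide must exist so a PAM is available (independent scan)
  expect_true(grepl("GG", a1$sequence))
  cands <- enumerate_guides(a1)
  expect_true(any(cands$in_cds_window))
})

test_that("root spectra have 1-4 dominant indels above the threshold", {
  cfg <- repair_spectrum_config()
  for (i in 1:400) {
    sp <- sample_root_spectrum(cfg, "A", root_seed = i)
    expect_gte(nrow(sp), 1)
    expect_lte(nrow(sp), 4)
    expect_true(all(sp$percentage > 20))
    expect_lte(sum(sp$percentage) + wt_percentage(sp), 100 + 0.5)
  }
})

test_that("degenerate config yields a single event at 100%", {
  cfg <- repair_spectrum_config(dominant_count_range = c(1, 1),
                                wt_fraction_range = c(0, 0))
  sp <- sample_root_spectrum(cfg, "A", root_seed = 3)
  expect_identical(nrow(sp), 1L)
  expect_equal(sum(sp$percentage), 100)
  expect_equal(wt_percentage(sp), 0)
})

test_that("unsatisfiable dominance constraints are rejected", {
  cfg <- repair_spectrum_config(dominant_count_range = c(4, 4),
                                wt_fraction_range = c(0.9, 0.95))
  expect_error(sample_root_spectrum(cfg, "A", 1), "unsatisfiable")
})

test_that("+1 insertions copy the template base at the configured rate", {
  cfg <- repair_spectrum_config(template_bias = 0.75)
  bases <- character()
  for (i in 1:800) {
    sp <- sample_root_spectrum(cfg, "G", root_seed = 10000 + i)
    bases <- c(bases, sp$inserted_bases[sp$size == 1L])
  }
  n <- length(bases)
  expect_gt(n, 100)
  phat <- mean(bases == "G")
  se <- sqrt(0.75 * 0.25 / n)
  expect_lt(abs(phat - 0.75), 3 * se + 1e-12)
})

test_that("pooled sampled events reproduce the fixture size distribution", {
  cfg <- repair_spectrum_config()
  sizes <- integer()
  i <- 0
  while (length(sizes) < 10000) {
    i <- i + 1
    sizes <- c(sizes, sample_root_spectrum(cfg, "A",
                                           root_seed = 50000 + i)$size)
  }
  expect_true(all(sizes >= -30 & sizes <= 4 & sizes != 0))
  frac_del1 <- 100 * mean(sizes == -1)
  frac_ins1 <- 100 * mean(sizes == 1)
  expect_lt(abs(frac_del1 - 22.6), 1.5)
  expect_lt(abs(frac_ins1 - 19.1), 1.5)
  ratio <- sum(sizes < 0) / sum(sizes > 0)
  expect_lt(abs(ratio - 3), 0.3)
})

test_that("trace rows are normalized and the mixture is exact", {
  amp <- fixture_amplicon()
  site <- fixture_site(amp)
  # pure wild type, no noise: edited == control == one-hot reference
  sp0 <- indel_spectrum(wt_percentage = 100)
  tr0 <- synthesize_traces(amp, site, sp0)
  expect_equal(tr0$edited, tr0$control)
  expect_true(all(abs(rowSums(tr0$edited) - 1) < 1e-6))
  # pure -2 deletion: rows after the cut equal control shifted by 2
  spd <- two_allele_spectrum(-2L, 100)
  trd <- synthesize_traces(amp, site, spd)
  L <- nrow(trd$control)
  cut <- site$cut_pos
  expect_equal(trd$edited[(cut + 1):(L - 2), ],
               trd$control[(cut + 3):L, ])
  expect_equal(trd$edited[1:cut, ], trd$control[1:cut, ])
  # 60/40 WT/-1 mixture: each post-cut row is the analytic blend
  spm <- two_allele_spectrum(-1L, 40)
  trm <- synthesize_traces(amp, site, spm)
  expect_equal(trm$edited[(cut + 1):(L - 1), ],
               0.6 * trm$control[(cut + 1):(L - 1), ] +
                 0.4 * trm$control[(cut + 2):L, ])
  # noisy traces still have unit row sums
  trn <- synthesize_traces(amp, site, spm, noise_sd = 0.05, seed = 9)
  expect_true(all(abs(rowSums(trn$edited) - 1) < 1e-6))
  expect_true(all(trn$edited >= 0))
})

test_that("events beyond the representable size are rejected", {
  amp <- fixture_amplicon()
  site <- fixture_site(amp)
  sp <- two_allele_spectrum(-35L, 50)
  expect_error(synthesize_traces(amp, site, sp), "max_indel")
  expect_silent(synthesize_traces(amp, site, sp, max_indel = 40L))
})

test_that("seed SNP lands next to the PAM and changes one base", {
  amp <- fixture_amplicon()
  site <- fixture_site(amp)
  snp <- inject_seed_snp(amp, site, seed = 5)
  diffs <- which(strsplit(amp$sequence, "")[[1]] !=
                   strsplit(snp$sequence, "")[[1]])
  expect_identical(length(diffs), 1L)
  # + strand: protospacer position 20 is cut_pos + 3
  expect_identical(diffs, site$cut_pos + 3L)
})

test_that("simulated studies are deterministic and sized as configured", {
  cfg <- study_config(n_guides = 2, n_roots = 15, seed = 7, traces = FALSE)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(nrow(s1$records), 2L * 2L * 15L)
  expect_identical(s1$spectra, s2$spectra)
  expect_identical(lapply(s1$amplicons, `[[`, "sequence"),
                   lapply(s2$amplicons, `[[`, "sequence"))
})

test_that("configured group editing separation is recovered by Welch", {
  # groups at mean INDEL ~75 vs ~40: the contrast should essentially
  # always reject at alpha = 0.01 with 15 roots per group
  rejections <- 0L
  for (r in 1:100) {
    cfg <- study_config(n_guides = 1, n_roots = 15,
                        constructs = list(hi = c(0.15, 0.35),
                                          lo = c(0.50, 0.70)),
                        seed = 600 + r, traces = FALSE)
    st <- simulate_study(cfg)
    sc <- score_roots(st$spectra)
    grp <- st$records$construct[match(sc$root_id, st$records$root_id)]
    wt <- welch_test(sc$indel_score[grp == "hi"],
                     sc$indel_score[grp == "lo"])
    rejections <- rejections + (wt$p < 0.01)
  }
  expect_gte(rejections, 95L)
})
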