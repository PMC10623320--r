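test_that("templates reproduce the shift structure of each indel", {
  amp <- fixture_amplicon()
  site <- fixture_site(amp)
  ctrl <- synthesize_traces(amp, site,
                            indel_spectrum(wt_percentage = 100))$control
  tpl <- build_templates(ctrl, site$cut_pos, 30L)
  cut <- site$cut_pos
  expect_identical(length(tpl), 61L)
  expect_equal(tpl[["0"]], ctrl)
  # -1: row just after the cut equals the control one further along
  expect_equal(tpl[["-1"]][cut + 1, ], ctrl[cut + 2, ])
  # +2: inserted rows are uniform (bases unknown at fit time)
  expect_equal(unname(tpl[["2"]][cut + 1, ]), rep(0.25, 4))
  expect_equal(unname(tpl[["2"]][cut + 2, ]), rep(0.25, 4))
  expect_equal(tpl[["2"]][cut + 3, ], ctrl[cut + 1, ])
  expect_error(build_templates(ctrl[1:120, ], 100, 30), "short")
})

test_that("identity input decomposes to pure wild type with R^2 = 1", {
  amp <- fixture_amplicon()
  site <- fixture_site(amp)
  tr <- synthesize_traces(amp, site, indel_spectrum(wt_percentage = 100))
  d <- decompose(tr$control, tr$edited, site$cut_pos)
  expect_equal(d$wt_percentage, 100, tolerance = 1e-6)
  expect_identical(nrow(d$spectrum), 0L)
  expect_equal(d$r_squared, 1.0, tolerance = 1e-9)
})

test_that("noiseless two-allele mixtures are recovered exactly", {
  amp <- fixture_amplicon()
  site <- fixture_site(amp)
  # 60/40 WT/-1
  tr <- synthesize_traces(amp, site, two_allele_spectrum(-1L, 40))
  d <- decompose(tr$control, tr$edited, site$cut_pos)
  expect_lt(abs(d$percentages[["-1"]] - 40), 1)
  expect_lt(abs(d$wt_percentage - 60), 1)
  # 50/50 -1/+1 with no wild type
  sp <- indel_spectrum(c(-1L, 1L), c(50, 50),
                       inserted_bases = c(NA, "A"), wt_percentage = 0)
  tr2 <- synthesize_traces(amp, site, sp)
  d2 <- decompose(tr2$control, tr2$edited, site$cut_pos)
  expect_lt(abs(d2$percentages[["-1"]] - 50), 1)
  expect_lt(abs(d2$percentages[["1"]] - 50), 1)
  expect_lt(d2$wt_percentage, 1)
})

test_that("mixture recovery holds across seeded random cases", {
  amp <- fixture_amplicon()
  site <- fixture_site(amp)
  sizes <- c(-8:-1, 1:4)
  for (case in 1:100) {
    set.seed(7000 + case)
    s <- sample(sizes, 1)
    pct <- runif(1, 15, 85)
    base <- if (s > 0) paste(sample(c("A", "C", "G", "T"), s,
                                    replace = TRUE), collapse = "")
            else NA_character_
    tr <- synthesize_traces(amp, site,
                            two_allele_spectrum(s, pct, base))
    d <- decompose(tr$control, tr$edited, site$cut_pos)
    expect_lt(abs(d$percentages[[as.character(s)]] - pct), 2)
    expect_lt(abs(d$wt_percentage - (100 - pct)), 2)
  }
})

test_that("significant indels get small p-values, absent ones large", {
  amp <- fixture_amplicon()
  site <- fixture_site(amp)
  tr <- synthesize_traces(amp, site, two_allele_spectrum(-3L, 50),
                          noise_sd = 0.02, seed = 21)
  d <- decompose(tr$control, tr$edited, site$cut_pos)
  expect_lt(d$p_values[["-3"]], 0.01)
  q <- filter_spectrum(d)
  expect_false(q$rejected)
  expect_true(all(q$spectrum$p_value < 0.01))
  expect_true(-3L %in% q$spectrum$size)
})

test_that("QC rejects poor fits and drops non-significant events", {
  mk <- function(r2, sizes = integer(), pct = numeric(), p = numeric()) {
    structure(list(spectrum = indel_spectrum(sizes, pct, p_values = p,
                                             wt_percentage = 100 - sum(pct)),
                   wt_percentage = 100 - sum(pct), r_squared = r2,
                   window = c(start = 1, end = 2),
                   percentages = NULL, p_values = NULL),
              class = "rootindel_decomposition")
  }
  expect_true(filter_spectrum(mk(0.65))$rejected)
  expect_true(filter_spectrum(mk(0.70))$rejected)   # rule is strictly above
  q <- filter_spectrum(mk(0.95, c(-1L, -2L), c(30, 10), c(0.001, 0.02)))
  expect_false(q$rejected)
  expect_identical(q$spectrum$size, -1L)
  q2 <- filter_spectrum(mk(0.99, c(-1L, 2L), c(30, 10), c(1e-5, 1e-4)))
  expect_identical(nrow(q2$spectrum), 2L)
})

test_that("reported indel sizes never exceed the window cap", {
  amp <- fixture_amplicon()
  site <- fixture_site(amp)
  n_events <- 0L
  for (case in 1:10) {
    sp <- indel_spectrum(c(-40L, -1L), c(30, 40), wt_percentage = 30)
    tr <- synthesize_traces(amp, site, sp, noise_sd = 0.02,
                            seed = 8100 + case, max_indel = 40L)
    d <- decompose(tr$control, tr$edited, site$cut_pos)
    q <- filter_spectrum(d)
    if (!q$rejected && nrow(q$spectrum)) {
      n_events <- n_events + nrow(q$spectrum)
      expect_lte(max(abs(q$spectrum$size)), 30L)
    }
  }
  expect_gt(n_events, 0L)
})

test_that("more noise does not improve the fit", {
  amp <- fixture_amplicon()
  site <- fixture_site(amp)
  sp <- two_allele_spectrum(-2L, 50)
  mean_r2 <- sapply(c(0.01, 0.05, 0.15), function(nsd) {
    mean(sapply(1:8, function(i) {
      tr <- synthesize_traces(amp, site, sp, noise_sd = nsd,
                              seed = 9000 + i)
      decompose(tr$control, tr$edited, site$cut_pos)$r_squared
    }))
  })
  expect_true(all(diff(mean_r2) < 0))
})

test_that("degenerate and mismatched inputs raise errors", {
  amp <- fixture_amplicon()
  site <- fixture_site(amp)
  tr <- synthesize_traces(amp, site, indel_spectrum(wt_percentage = 100))
  expect_error(decompose(tr$control, tr$edited[1:100, ], site$cut_pos),
               "identical dimensions")
  flat <- matrix(0.25, nrow = nrow(tr$control), ncol = 4,
                 dimnames = list(NULL, c("A", "C", "G", "T")))
  expect_error(decompose(flat, flat, site$cut_pos), "degenerate")
})
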