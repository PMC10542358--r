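iv <- function(chrom, start, end, strand = ".") {
  tibble::tibble(chrom = chrom, start = start, end = end,
                 name = ".", score = 0, strand = strand)
}

test_that("RNaseH subtraction applies the covered-fraction rule", {
  # identical peak: fully covered -> removed
  expect_equal(nrow(subtract_rnaseh(iv("chr1", 100, 200),
                                    iv("chr1", 100, 200), 0.5)), 0L)
  # no overlap -> retained
  expect_equal(nrow(subtract_rnaseh(iv("chr1", 100, 200),
                                    iv("chr1", 300, 400), 0.5)), 1L)
  # 30/100 covered < 0.5 -> retained
  expect_equal(nrow(subtract_rnaseh(iv("chr1", 100, 200),
                                    iv("chr1", 170, 300), 0.5)), 1L)
  # but removed under a 0.25 threshold
  expect_equal(nrow(subtract_rnaseh(iv("chr1", 100, 200),
                                    iv("chr1", 170, 300), 0.25)), 0L)
  # split coverage sums across RNaseH peaks
  rn <- dplyr::bind_rows(iv("chr1", 100, 130), iv("chr1", 160, 200))
  expect_equal(nrow(subtract_rnaseh(iv("chr1", 100, 200), rn, 0.5)), 0L)
})

test_that("subtraction matches brute force, is a subset, and idempotent", {
  set.seed(71)
  for (rep in 1:20) {
    untreated <- random_intervals(sample(1:60, 1))
    rnaseh <- random_intervals(sample(1:60, 1))
    frac <- sample(c(0.25, 0.5, 0.9), 1)
    got <- subtract_rnaseh(untreated, rnaseh, frac)
    want <- oracle_subtract(untreated, rnaseh, frac)
    expect_equal(as.data.frame(got), as.data.frame(want))
    expect_true(all(got$name %in% untreated$name))
    again <- subtract_rnaseh(got, rnaseh, frac)
    expect_equal(as.data.frame(again), as.data.frame(got))
  }
})

test_that("site-in-peak containment is half-open and strand-blind", {
  peaks <- iv("chr1", 100, 200, strand = "+")
  sites <- tibble::tibble(chrom = "chr1", pos = c(99L, 100L, 150L, 199L,
                                                  200L),
                          strand = "-")
  ann <- annotate_sites_in_peaks(sites, peaks)
  expect_equal(ann$in_rloop, c(FALSE, TRUE, TRUE, TRUE, FALSE))
})

test_that("site annotation equals the all-pairs oracle on random instances", {
  set.seed(72)
  for (rep in 1:25) {
    peaks <- random_intervals(sample(1:50, 1))
    sites <- tibble::tibble(
      chrom = sample(c("chr1", "chr2"), 300, replace = TRUE),
      pos = sample.int(11000L, 300, replace = TRUE) - 1L)
    got <- annotate_sites_in_peaks(sites, peaks)$in_rloop
    expect_identical(got, oracle_in_peak(sites, peaks))
  }
})

test_that("enrichment builds the exact 2x2 table and odds ratio", {
  set.seed(73)
  peaks <- iv("chr1", 0, 1000)
  class_sites <- tibble::tibble(chrom = "chr1",
                                pos = c(sample(0:999, 40),
                                        sample(2000:9999, 60)))
  bg_sites <- tibble::tibble(chrom = "chr1",
                             pos = c(sample(0:999, 10),
                                     sample(2000:9999, 90)))
  e <- overlap_enrichment(class_sites, bg_sites, peaks)
  expect_equal(unname(e$table[1, ]), c(40, 60))
  expect_equal(unname(e$table[2, ]), c(10, 90))
  expect_equal(e$odds_ratio, (40 * 90) / (60 * 10))
  expect_equal(e$summary$fraction_in_rloop, c(0.4, 0.1))
  td <- tidy(e)
  expect_equal(td$n_in_rloop, c(40L, 10L))
  expect_equal(glance(e)$odds_ratio, 6)
})

test_that("Fisher p equals hypergeometric enumeration; null gives OR 1", {
  peaks <- iv("chr1", 0, 100)
  tables <- list(c(8, 2, 3, 7), c(1, 9, 5, 5), c(4, 4, 4, 4),
                 c(0, 10, 6, 4), c(12, 3, 2, 13))
  for (tb in tables) {
    class_sites <- tibble::tibble(
      chrom = "chr1", pos = c(seq_len(tb[1]) - 1L, 200L + seq_len(tb[2])))
    bg_sites <- tibble::tibble(
      chrom = "chr1", pos = c(seq_len(tb[3]) + 19L, 400L + seq_len(tb[4])))
    e <- overlap_enrichment(class_sites, bg_sites, peaks)
    expect_equal(e$p_value, oracle_fisher_p(tb[1], tb[2], tb[3], tb[4]),
                 tolerance = 1e-9)
  }
  # identical in-fractions: OR exactly 1, p 1 up to discreteness
  cls <- tibble::tibble(chrom = "chr1", pos = c(0:9, 200:289))
  bg <- tibble::tibble(chrom = "chr1", pos = c(10:19, 300:389))
  e0 <- overlap_enrichment(cls, bg, peaks)
  expect_equal(e0$odds_ratio, 1)
  expect_equal(e0$p_value, 1)
})

test_that("swapping class and background inverts the odds ratio", {
  set.seed(74)
  peaks <- random_intervals(10)
  a <- tibble::tibble(chrom = "chr1", pos = sample.int(10000L, 80) - 1L)
  b <- tibble::tibble(chrom = "chr1", pos = sample.int(10000L, 120) - 1L)
  e1 <- overlap_enrichment(a, b, peaks)
  e2 <- overlap_enrichment(b, a, peaks)
  expect_equal(e1$odds_ratio, 1 / e2$odds_ratio, tolerance = 1e-12)
  expect_equal(e1$p_value, e2$p_value, tolerance = 1e-12)
})

test_that("degenerate inputs are flagged, not silently computed", {
  peaks <- iv("chr1", 0, 100)
  sites <- tibble::tibble(chrom = "chr1", pos = 0:9)
  expect_error(overlap_enrichment(sites[0, ], sites, peaks), "non-empty")
  # empty peak set: all fractions zero, OR undefined
  res <- overlap_by_condition(list(a = sites),
                              tibble::tibble(chrom = "chr1", pos = 200:299),
                              peaks[0, ])
  expect_equal(res$fraction_in_rloop, 0)
  expect_equal(res$background_fraction, 0)
  expect_true(is.na(res$odds_ratio))
})

test_that("multi-set overlap summaries carry one row per site set", {
  set.seed(75)
  peaks <- iv("chr1", 0, 500)
  sets <- list(
    dependent = tibble::tibble(chrom = "chr1", pos = sample(0:499, 30)),
    independent = tibble::tibble(chrom = "chr1", pos = sample(1000:1999, 30))
  )
  bg <- tibble::tibble(chrom = "chr1", pos = sample(0:9999, 500))
  res <- overlap_by_condition(sets, bg, peaks)
  expect_equal(res$set, c("dependent", "independent"))
  expect_equal(res$fraction_in_rloop, c(1, 0))
  expect_gt(res$odds_ratio[1], 1)
})
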