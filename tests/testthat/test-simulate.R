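small_params <- function(...) {
  defaults <- list(genome_length = 30000L, n_chrom = 1L,
                   n_transcripts = 10L, transcript_length = 2000L,
                   n_rloops = 8L, rloop_length = 250L, n_dependent = 40L,
                   n_independent = 40L)
  do.call(sim_params, utils::modifyList(defaults, list(...)))
}

test_that("simulated genome hits the requested GC fraction and is seeded", {
  p <- sim_params(genome_length = 100000L, n_chrom = 1L, gc_background = 0.5,
                  n_transcripts = 0L, seed = 11L)
  g <- simulate_genome(p)
  expect_equal(nrow(g$transcripts), 0L)
  chars <- strsplit(g$genome[[1]], "")[[1]]
  gc <- mean(chars %in% c("G", "C"))
  expect_lt(abs(gc - 0.5), 3 * sqrt(0.25 / 100000))
  g2 <- simulate_genome(p)
  expect_identical(g$genome, g2$genome)
  expect_false(identical(simulate_genome(sim_params(seed = 12L,
                                                    n_chrom = 1L))$genome,
                         simulate_genome(sim_params(seed = 13L,
                                                    n_chrom = 1L))$genome))
})

test_that("transcripts are non-overlapping, stranded, and within bounds", {
  p <- small_params(seed = 2L)
  g <- simulate_genome(p)
  tx <- dplyr::arrange(g$transcripts, chrom, start)
  expect_true(all(tx$strand %in% c("+", "-")))
  expect_true(all(tx$end <= nchar(g$genome[tx$chrom])))
  same <- tx$chrom[-1] == tx$chrom[-nrow(tx)]
  expect_true(all(tx$start[-1][same] >= tx$end[-nrow(tx)][same]))
  expect_error(
    simulate_genome(sim_params(genome_length = 5000L, n_chrom = 1L,
                               n_transcripts = 10L,
                               transcript_length = 1000L)),
    "cannot be placed")
})

test_that("planted R-loop regions realise the target sense-strand skew", {
  p <- sim_params(genome_length = 20000L, n_chrom = 1L, n_transcripts = 4L,
                  transcript_length = 3000L, n_rloops = 4L,
                  rloop_length = 2000L, rloop_gc = 0.6, rloop_skew = 0.4,
                  seed = 5L)
  g <- simulate_genome(p)
  rl <- plant_rloop_regions(g$genome, g$transcripts, p)
  skews <- gcs <- numeric(nrow(rl$rloops))
  for (i in seq_len(nrow(rl$rloops))) {
    r <- rl$rloops[i, ]
    seq <- substr(rl$genome[[r$chrom]], r$start + 1, r$end)
    if (r$strand == "-") {
      seq <- chartr("ACGT", "TGCA", paste(rev(strsplit(seq, "")[[1]]),
                                          collapse = ""))
    }
    chars <- strsplit(seq, "")[[1]]
    ng <- sum(chars == "G"); nc <- sum(chars == "C")
    skews[i] <- (ng - nc) / (ng + nc)
    gcs[i] <- (ng + nc) / nchar(seq)
    # per-region sampling bound (~4 sigma at 2 kb)
    expect_lt(abs(skews[i] - 0.4), 0.11)
    expect_lt(abs(gcs[i] - 0.6), 0.05)
  }
  # averaged over regions the planted skew is recovered tightly
  expect_lt(abs(mean(skews) - 0.4), 0.05)
  expect_lt(abs(mean(gcs) - 0.6), 0.02)
})

test_that("zero regions leave the genome untouched; zero skew is symmetric", {
  p0 <- small_params(n_rloops = 0L, seed = 3L)
  g <- simulate_genome(p0)
  rl <- plant_rloop_regions(g$genome, g$transcripts, p0)
  expect_identical(rl$genome, g$genome)

  psym <- sim_params(genome_length = 20000L, n_chrom = 1L,
                     n_transcripts = 2L, transcript_length = 5000L,
                     n_rloops = 2L, rloop_length = 4000L, rloop_skew = 0,
                     rloop_gc = 0.6, seed = 8L)
  g2 <- simulate_genome(psym)
  rl2 <- plant_rloop_regions(g2$genome, g2$transcripts, psym)
  r <- rl2$rloops[1, ]
  chars <- strsplit(substr(rl2$genome[[r$chrom]], r$start + 1, r$end),
                    "")[[1]]
  ng <- sum(chars == "G"); nc <- sum(chars == "C")
  expect_lt(abs((ng - nc) / (ng + nc)), 4 * sqrt(1 / (0.6 * 4000)))
})

test_that("planted sites sit on sense-strand cytosines with stated levels", {
  p <- small_params(seed = 4L, coloc_prob = 1, level_induced = 0.30,
                    level_basal = 0.02)
  g <- simulate_genome(p)
  rl <- plant_rloop_regions(g$genome, g$transcripts, p)
  st <- plant_m5c_sites(rl$genome, g$transcripts, rl$rloops, p)
  truth <- st$truth
  expect_equal(nrow(truth), p$n_dependent + p$n_independent)
  base <- substr(st$genome[truth$chrom], truth$pos + 1, truth$pos + 1)
  expect_true(all(ifelse(truth$strand == "+", base == "C", base == "G")))
  dep <- truth[truth$dependent, ]
  expect_true(all(dep$level_wt_plus == 0.30))
  expect_true(all(dep$level_ko_plus == 0.02))
  expect_true(all(dep$level_wt_plus > dep$level_ko_plus))
  expect_true(all(dep$in_rloop))  # forced by coloc_prob = 1
  indep <- truth[!truth$dependent, ]
  expect_true(all(indep$level_wt_plus == indep$level_ko_plus))
})

test_that("with zero co-localization dependent sites fall per C coverage", {
  p <- small_params(seed = 6L, coloc_prob = 0, n_dependent = 120L,
                    n_independent = 0L, context_flank = 1L)
  g <- simulate_genome(p)
  rl <- plant_rloop_regions(g$genome, g$transcripts, p)
  st <- plant_m5c_sites(rl$genome, g$transcripts, rl$rloops, p)
  # expected in-R-loop share = share of transcript sense-C candidates inside
  # R-loop regions, computed independently from the rewritten genome
  cand <- do.call(rbind, lapply(seq_len(nrow(g$transcripts)), function(i) {
    tx <- g$transcripts[i, ]
    target <- if (tx$strand == "+") "C" else "G"
    chars <- strsplit(substr(st$genome[[tx$chrom]], tx$start + 1, tx$end),
                      "")[[1]]
    pos <- tx$start + which(chars == target) - 1
    data.frame(chrom = tx$chrom, pos = pos)
  }))
  p_in <- mean(oracle_in_peak(cand, rl$rloops))
  frac <- mean(st$truth$in_rloop)
  expect_lt(abs(frac - p_in),
            4 * sqrt(p_in * (1 - p_in) / nrow(st$truth)) + 0.02)
})

test_that("bisulfite counts follow the composed binomial error model", {
  p <- small_params(seed = 7L, nonconversion_rate = 0)
  g <- simulate_genome(p)
  rl <- plant_rloop_regions(g$genome, g$transcripts, p)
  st <- plant_m5c_sites(rl$genome, g$transcripts, rl$rloops, p)
  bs <- simulate_bisulfite_counts(st$genome, g$transcripts, st$truth, p)
  ko <- bs$counts$KO_plus
  planted <- dplyr::semi_join(ko, st$truth[!st$truth$dependent, ],
                              by = c("chrom", "pos"))
  unplanted <- dplyr::anti_join(ko, st$truth, by = c("chrom", "pos"))
  # eps = 0 and true level 0: unconverted counts must all be zero
  expect_true(all(unplanted$n_unconverted == 0))
  expect_gt(sum(planted$n_unconverted), 0)
  # every transcript sense-strand C receives a row
  n_c <- sum(vapply(seq_len(nrow(g$transcripts)), function(i) {
    tx <- g$transcripts[i, ]
    target <- if (tx$strand == "+") "C" else "G"
    sum(strsplit(substr(st$genome[[tx$chrom]], tx$start + 1, tx$end),
                 "")[[1]] == target)
  }, numeric(1)))
  expect_equal(nrow(ko), n_c)
})

test_that("high coverage recovers planted methylation levels", {
  p <- small_params(seed = 9L, coverage_mean = 10000, coverage_dispersion = 0,
                    nonconversion_rate = 0, level_independent = 0.2,
                    n_dependent = 0L, n_independent = 50L)
  g <- simulate_genome(p)
  rl <- plant_rloop_regions(g$genome, g$transcripts, p)
  st <- plant_m5c_sites(rl$genome, g$transcripts, rl$rloops, p)
  bs <- simulate_bisulfite_counts(st$genome, g$transcripts, st$truth, p)
  wt <- dplyr::semi_join(bs$counts$WT_plus, st$truth,
                         by = c("chrom", "pos"))
  frac <- wt$n_unconverted / (wt$n_unconverted + wt$n_converted)
  expect_true(all(abs(frac - 0.2) < 4 * sqrt(0.2 * 0.8 / 10000)))
})

test_that("spike-in counts cover the cytosines of the spike-in sequence", {
  expect_equal(nchar(spikein_sequence), 50L)
  cpos <- spikein_c_positions()
  expect_length(cpos, 5L)
  chars <- strsplit(spikein_sequence, "")[[1]]
  expect_true(all(chars[cpos + 1] == "C"))

  p <- small_params(seed = 10L)
  g <- simulate_genome(p)
  rl <- plant_rloop_regions(g$genome, g$transcripts, p)
  st <- plant_m5c_sites(rl$genome, g$transcripts, rl$rloops, p)
  bs <- simulate_bisulfite_counts(st$genome, g$transcripts, st$truth, p)
  expect_equal(bs$spikein$pos, cpos)
  frac <- sum(bs$spikein$n_unconverted) /
    sum(bs$spikein$n_unconverted + bs$spikein$n_converted)
  expect_lt(abs(frac - p$nonconversion_rate), 0.005)
})

test_that("DRIP peak sets decompose into R-loop peaks plus shared artifacts", {
  p <- small_params(seed = 12L, n_artifact_peaks = 10L, peak_jitter = 0L)
  g <- simulate_genome(p)
  rl <- plant_rloop_regions(g$genome, g$transcripts, p)
  dr <- simulate_drip_peaks(rl$genome, rl$rloops, p)
  expect_equal(nrow(dr$rnaseh), 10L)
  expect_equal(nrow(dr$untreated), nrow(rl$rloops) + 10L)
  # artifacts appear verbatim in both sets
  expect_equal(
    as.data.frame(dr$untreated[dr$untreated$name %in% dr$rnaseh$name,
                               c("chrom", "start", "end")]),
    as.data.frame(dr$rnaseh[, c("chrom", "start", "end")]))
  # jitter 0: R-loop-derived peaks coordinate-identical to truth regions
  rl_peaks <- dr$untreated[startsWith(dr$untreated$name, "peak_"), ]
  expect_equal(rl_peaks$start, rl$rloops$start)
  expect_equal(rl_peaks$end, rl$rloops$end)
  # artifacts never touch R-loop regions
  expect_false(any(oracle_in_peak(
    data.frame(chrom = dr$rnaseh$chrom, pos = dr$rnaseh$start),
    rl$rloops)))

  p0 <- small_params(seed = 13L, n_artifact_peaks = 0L)
  g0 <- simulate_genome(p0)
  rl0 <- plant_rloop_regions(g0$genome, g0$transcripts, p0)
  dr0 <- simulate_drip_peaks(rl0$genome, rl0$rloops, p0)
  expect_equal(nrow(dr0$rnaseh), 0L)
  expect_equal(nrow(dr0$untreated), nrow(rl0$rloops))
})

test_that("the full dataset is reproducible from its seed", {
  p <- small_params(seed = 21L)
  d1 <- simulate_dataset(p)
  d2 <- simulate_dataset(p)
  expect_identical(d1$genome, d2$genome)
  expect_equal(as.data.frame(d1$truth), as.data.frame(d2$truth))
  expect_equal(as.data.frame(d1$counts$WT_plus),
               as.data.frame(d2$counts$WT_plus))
  expect_equal(as.data.frame(d1$drip_untreated),
               as.data.frame(d2$drip_untreated))
})
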