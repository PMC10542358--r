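# Synthetic dataset generator: genome, transcripts, R-loop regions, planted
# m5C sites, bisulfite counts for four conditions + spike-in, and DRIP peaks
# with an RNaseH control — all with a truth table so downstream stages have
# known answers.

BASES <- c("A", "C", "G", "T")

# base sampling at a given GC fraction and (G-C)/(G+C) skew
sample_bases <- function(n, gc, skew = 0) {
  p <- c(A = (1 - gc) / 2, C = gc * (1 - skew) / 2,
         G = gc * (1 + skew) / 2, T = (1 - gc) / 2)
  sample(BASES, n, replace = TRUE, prob = p)
}

comp_base <- function(b) chartr("ACGTN", "TGCAN", b)

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
}

# coverage model: negative binomial with dispersion d (Var = mu + d*mu^2);
# d = 0 is the Poisson limit
draw_coverage <- function(n, mean, dispersion) {
  if (dispersion == 0) rpois(n, mean)
  else rnbinom(n, mu = mean, size = 1 / dispersion)
}

#' Simulate a random genome with non-overlapping stranded transcripts
#'
#' Bases are i.i.d. at the background GC fraction; transcripts are placed
#' without overlap, each on a random fixed strand.
#'
#' @param params Simulation parameters from [sim_params()]. The RNG is
#'   seeded from `params$seed`.
#' @return List with `genome` (named character vector) and `transcripts`
#'   (interval tibble, strand `+`/`-`).
#' @export
simulate_genome <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  chrom_len <- rep(params$genome_length %/% params$n_chrom, params$n_chrom)
  chrom_len[1] <- chrom_len[1] + params$genome_length %% params$n_chrom
  chrom_names <- paste0("chr", seq_len(params$n_chrom))
  genome <- setNames(vapply(chrom_len, function(L) {
    paste(sample_bases(L, params$gc_background), collapse = "")
  }, character(1)), chrom_names)

  ntx <- params$n_transcripts
  if (ntx == 0) {
    tx <- tibble(chrom = character(), start = integer(), end = integer(),
                 name = character(), score = numeric(), strand = character())
    return(list(genome = genome, transcripts = tx))
  }
  # spread transcripts over chromosomes proportionally to length
  n_per <- floor(ntx * chrom_len / sum(chrom_len))
  i <- 1L
  while (sum(n_per) < ntx) {
    n_per[i] <- n_per[i] + 1L
    i <- i %% length(n_per) + 1L
  }
  tl <- params$transcript_length
  if (any(n_per * tl > chrom_len)) {
    abort("transcripts cannot be placed without overlap at these lengths")
  }
  tx <- purrr::map2(chrom_names, seq_along(chrom_names), function(cn, ci) {
    k <- n_per[ci]
    if (k == 0) return(NULL)
    slack <- chrom_len[ci] - k * tl
    gaps <- sort(sample.int(slack + 1L, k, replace = TRUE) - 1L)
    starts <- gaps + (seq_len(k) - 1L) * tl
    tibble(chrom = cn, start = starts, end = starts + tl)
  })
  tx <- bind_rows(tx)
  tx$name <- paste0("tx", seq_len(nrow(tx)))
  tx$score <- 0
  tx$strand <- sample(c("+", "-"), nrow(tx), replace = TRUE)
  list(genome = genome, transcripts = validate_intervals(tx, genome))
}

#' Plant R-loop-prone regions inside transcripts
#'
#' Resamples the bases of each region so that, read on the transcribed
#' (sense) strand, the sequence has the target GC fraction and a positive GC
#' skew — the G-rich sense strand / C-rich template configuration that
#' favours DNA:RNA hybrid formation. Each region inherits its transcript's
#' strand.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param transcripts Transcript interval tibble.
#' @param params [sim_params()] object (uses `n_rloops`, `rloop_length`,
#'   `rloop_gc`, `rloop_skew`); draws from the current RNG state.
#' @return List with rewritten `genome` and `rloops` (interval tibble).
#' @export
plant_rloop_regions <- function(genome, transcripts, params) {
  if (params$n_rloops == 0) {
    rl <- tibble(chrom = character(), start = integer(), end = integer(),
                 name = character(), score = numeric(), strand = character())
    return(list(genome = genome, rloops = rl))
  }
  if (params$rloop_length > params$transcript_length) {
    abort("rloop_length exceeds transcript_length")
  }
  if (params$n_rloops > nrow(transcripts)) {
    abort("more R-loop regions requested than transcripts to host them")
  }
  host <- transcripts[sample.int(nrow(transcripts), params$n_rloops), ]
  offs <- sample.int(params$transcript_length - params$rloop_length + 1L,
                     params$n_rloops, replace = TRUE) - 1L
  rl <- tibble(
    chrom = host$chrom,
    start = host$start + offs,
    end = host$start + offs + params$rloop_length,
    name = paste0("rloop", seq_len(params$n_rloops)),
    score = 0,
    strand = host$strand
  )
  for (i in seq_len(nrow(rl))) {
    # sense-strand skew +s maps to reference-strand skew +s on '+' hosts
    # and -s on '-' hosts
    ref_skew <- if (rl$strand[i] == "+") params$rloop_skew else
      -params$rloop_skew
    piece <- paste(sample_bases(params$rloop_length, params$rloop_gc,
                                ref_skew), collapse = "")
    s <- genome[[rl$chrom[i]]]
    substr(s, rl$start[i] + 1L, rl$end[i]) <- piece
    genome[[rl$chrom[i]]] <- s
  }
  list(genome = genome, rloops = validate_intervals(rl, genome))
}

# 0-based reference positions within [start, end) whose sense-strand base is
# C for a transcript of the given strand (reference C on '+', G on '-')
sense_c_positions <- function(seq, start, end, strand) {
  target <- if (strand == "+") "C" else "G"
  sub <- substr(seq, start + 1L, end)
  start + which(strsplit(sub, "")[[1]] == target) - 1L
}

# sample n positions from pool, none within min_dist of each other or of
# already-taken positions (per chromosome)
pick_spaced <- function(pool, n, taken, min_dist) {
  chosen <- integer(0)
  chosen_chrom <- character(0)
  pool <- pool[sample.int(nrow(pool)), ]
  for (i in seq_len(nrow(pool))) {
    if (length(chosen) == n) break
    p <- pool$pos[i]; cn <- pool$chrom[i]
    prior <- c(chosen[chosen_chrom == cn],
               taken$pos[taken$chrom == cn])
    if (length(prior) == 0 || min(abs(prior - p)) >= min_dist) {
      chosen <- c(chosen, p)
      chosen_chrom <- c(chosen_chrom, cn)
    }
  }
  if (length(chosen) < n) {
    abort("requested site count exceeds available cytosine positions")
  }
  ord <- order(chosen_chrom, chosen)
  tibble(chrom = chosen_chrom[ord], pos = chosen[ord])
}

#' Plant TRDMT1-dependent and -independent m5C sites on transcripts
#'
#' Dependent sites fall inside R-loop regions with probability
#' `coloc_prob` and otherwise uniformly over transcript sense-strand
#' cytosines; their flanking bases (within `context_flank`) are resampled
#' with elevated G probability to emulate the G-rich context of
#' TRDMT1 targets. Independent sites are uniform with untouched context.
#' Per-condition true methylation levels come from `params`.
#'
#' @inheritParams plant_rloop_regions
#' @param rloops R-loop interval tibble from [plant_rloop_regions()].
#' @return List with rewritten `genome` and `truth`, a tibble with one row
#'   per planted site: `chrom`, `pos` (0-based), `strand`, the four true
#'   levels (`level_wt_minus`, `level_wt_plus`, `level_ko_minus`,
#'   `level_ko_plus`), `dependent`, `damage_induced`, `in_rloop`,
#'   `context_class`.
#' @export
plant_m5c_sites <- function(genome, transcripts, rloops, params) {
  flank <- params$context_flank
  min_dist <- 2L * flank + 1L
  cand <- purrr::pmap(
    list(transcripts$chrom, transcripts$start, transcripts$end,
         transcripts$strand),
    function(cn, s, e, st) {
      pos <- sense_c_positions(genome[[cn]], s, e, st)
      len <- nchar(genome[[cn]])
      pos <- pos[pos >= flank & pos < len - flank]
      if (length(pos) == 0) return(NULL)
      tibble(chrom = cn, pos = pos, strand = st)
    }
  )
  cand <- bind_rows(cand)
  if (nrow(cand) == 0) abort("no transcript sense-strand cytosines available")
  in_rl <- annotate_sites_in_peaks(cand, rloops)$in_rloop
  cand$in_rloop <- in_rl

  taken <- tibble(chrom = character(), pos = integer())
  n_forced <- rbinom(1, params$n_dependent, params$coloc_prob)
  dep_in <- pick_spaced(cand[cand$in_rloop, c("chrom", "pos")], n_forced,
                        taken, min_dist)
  taken <- bind_rows(taken, dep_in)
  dep_free <- pick_spaced(cand[, c("chrom", "pos")],
                          params$n_dependent - n_forced, taken, min_dist)
  taken <- bind_rows(taken, dep_free)
  indep <- pick_spaced(cand[, c("chrom", "pos")], params$n_independent,
                       taken, min_dist)

  dep <- bind_rows(dep_in, dep_free)
  dep$dependent <- TRUE
  indep$dependent <- FALSE
  truth <- bind_rows(dep, indep)
  truth <- left_join(truth, select(cand, "chrom", "pos", "strand",
                                   "in_rloop"),
                     by = c("chrom", "pos"))
  truth <- mutate(
    truth,
    level_wt_minus = if_else(.data$dependent, params$level_basal,
                             params$level_independent),
    level_wt_plus = if_else(.data$dependent, params$level_induced,
                            params$level_independent),
    level_ko_minus = if_else(.data$dependent, params$level_basal,
                             params$level_independent),
    level_ko_plus = if_else(.data$dependent, params$level_basal,
                            params$level_independent),
    damage_induced = .data$dependent,
    context_class = if_else(.data$dependent, "G-rich", "neutral")
  )

  # rewrite flanks of G-rich sites with elevated G on the sense strand
  gp <- params$context_g_prob
  rest <- (1 - gp) / 3
  grich <- truth[truth$context_class == "G-rich", ]
  for (i in seq_len(nrow(grich))) {
    cn <- grich$chrom[i]; p <- grich$pos[i]; st <- grich$strand[i]
    sense <- sample(BASES, 2L * flank,
                    replace = TRUE, prob = c(rest, rest, gp, rest))
    ref <- if (st == "+") sense else comp_base(sense)
    # sense offsets -flank..-1, 1..flank map to reference positions
    # pos+off on '+' hosts and pos-off on '-' hosts
    offs <- c(-(flank:1), 1:flank)
    ref_pos <- if (st == "+") p + offs else p - offs
    s <- genome[[cn]]
    for (j in seq_along(ref_pos)) {
      substr(s, ref_pos[j] + 1L, ref_pos[j] + 1L) <- ref[j]
    }
    genome[[cn]] <- s
  }
  truth <- arrange(truth, .data$chrom, .data$pos)
  truth <- select(truth, "chrom", "pos", "strand", "level_wt_minus",
                  "level_wt_plus", "level_ko_minus", "level_ko_plus",
                  "dependent", "damage_induced", "in_rloop", "context_class")
  list(genome = genome, truth = truth)
}

CONDITIONS <- c("WT_minus", "WT_plus", "KO_minus", "KO_plus")

#' Simulate per-cytosine bisulfite count tables
#'
#' Every transcript sense-strand cytosine receives a row in each of the four
#' condition tables (planted sites at their true level, all other cytosines
#' unmethylated). Coverage is negative-binomial; the unconverted read count
#' is Binomial(coverage, m + (1 - m) * eps), composing the true methylation
#' level m with the non-conversion rate eps (an unmethylated read fails to
#' convert with probability eps). Spike-in counts are generated fully
#' unmethylated over the cytosine positions of the spike-in sequence.
#'
#' @inheritParams plant_rloop_regions
#' @param truth Truth tibble from [plant_m5c_sites()].
#' @return List with `counts` (named list of four tibbles, columns `chrom`,
#'   `pos`, `strand`, `n_unconverted`, `n_converted`, `condition`) and
#'   `spikein` (same columns, `condition = "spikein"`).
#' @export
simulate_bisulfite_counts <- function(genome, transcripts, truth, params) {
  all_c <- purrr::pmap(
    list(transcripts$chrom, transcripts$start, transcripts$end,
         transcripts$strand),
    function(cn, s, e, st) {
      pos <- sense_c_positions(genome[[cn]], s, e, st)
      if (length(pos) == 0) return(NULL)
      tibble(chrom = cn, pos = pos, strand = st)
    }
  )
  all_c <- arrange(bind_rows(all_c), .data$chrom, .data$pos)
  eps <- params$nonconversion_rate
  level_col <- c(WT_minus = "level_wt_minus", WT_plus = "level_wt_plus",
                 KO_minus = "level_ko_minus", KO_plus = "level_ko_plus")
  counts <- lapply(CONDITIONS, function(cond) {
    tab <- left_join(all_c,
                     select(truth, "chrom", "pos",
                            m = dplyr::all_of(level_col[[cond]])),
                     by = c("chrom", "pos"))
    tab$m[is.na(tab$m)] <- 0
    nread <- draw_coverage(nrow(tab), params$coverage_mean,
                           params$coverage_dispersion)
    p_unconv <- tab$m + (1 - tab$m) * eps
    u <- rbinom(nrow(tab), nread, p_unconv)
    tibble(chrom = tab$chrom, pos = tab$pos, strand = tab$strand,
           n_unconverted = u, n_converted = nread - u, condition = cond)
  })
  names(counts) <- CONDITIONS

  cpos <- spikein_c_positions()
  n_sp <- draw_coverage(length(cpos), params$spikein_coverage,
                        params$coverage_dispersion)
  u_sp <- rbinom(length(cpos), n_sp, eps)
  spikein <- tibble(chrom = "spikein", pos = cpos, strand = "+",
                    n_unconverted = u_sp, n_converted = n_sp - u_sp,
                    condition = "spikein")
  list(counts = counts, spikein = spikein)
}

#' Simulate DRIP-seq peak sets with an RNaseH-treated control
#'
#' The untreated peak set is the R-loop regions (with optional boundary
#' jitter) plus RNaseH-insensitive artifact peaks placed uniformly outside
#' R-loops; the RNaseH-treated set contains only the artifact peaks, so
#' subtracting it recovers the genuine R-loop peaks.
#'
#' @inheritParams plant_m5c_sites
#' @return List with `untreated` and `rnaseh` interval tibbles (strand `.`,
#'   names flag `rloop`/`artifact` origin).
#' @export
simulate_drip_peaks <- function(genome, rloops, params) {
  chrom_len <- nchar(genome)
  jit <- params$peak_jitter
  if (nrow(rloops) > 0) {
    j1 <- sample.int(2L * jit + 1L, nrow(rloops), replace = TRUE) - jit - 1L
    j2 <- sample.int(2L * jit + 1L, nrow(rloops), replace = TRUE) - jit - 1L
    rl_peaks <- tibble(
      chrom = rloops$chrom,
      start = pmax(0L, rloops$start + j1),
      end = pmin(unname(chrom_len[rloops$chrom]), rloops$end + j2),
      name = paste0("peak_", rloops$name), score = 0, strand = "."
    )
    rl_peaks <- rl_peaks[rl_peaks$start < rl_peaks$end, ]
  } else {
    rl_peaks <- tibble(chrom = character(), start = integer(),
                       end = integer(), name = character(),
                       score = numeric(), strand = character())
  }

  art <- list()
  n_placed <- 0L
  tries <- 0L
  L <- params$artifact_peak_length
  while (n_placed < params$n_artifact_peaks) {
    tries <- tries + 1L
    if (tries > 1000L * max(1L, params$n_artifact_peaks)) {
      abort("artifact peaks cannot be placed without touching R-loop regions")
    }
    cn <- sample(names(genome), 1L, prob = chrom_len)
    if (chrom_len[[cn]] < L) next
    s <- sample.int(chrom_len[[cn]] - L + 1L, 1L) - 1L
    cand <- tibble(chrom = cn, start = s, end = s + L)
    placed <- bind_rows(c(list(rloops[, c("chrom", "start", "end")]),
                          lapply(art, `[`, c("chrom", "start", "end"))))
    if (nrow(placed) > 0) {
      clash <- placed$chrom == cn & placed$start < cand$end &
        cand$start < placed$end
      if (any(clash)) next
    }
    n_placed <- n_placed + 1L
    cand$name <- paste0("artifact", n_placed)
    cand$score <- 0
    cand$strand <- "."
    art[[n_placed]] <- cand
  }
  art <- bind_rows(art)
  if (nrow(art) == 0) {
    art <- tibble(chrom = character(), start = integer(), end = integer(),
                  name = character(), score = numeric(), strand = character())
  }
  list(untreated = bind_rows(rl_peaks, art), rnaseh = art)
}

#' Generate the full synthetic dataset
#'
#' Runs [simulate_genome()], [plant_rloop_regions()], [plant_m5c_sites()],
#' [simulate_bisulfite_counts()] and [simulate_drip_peaks()] in sequence,
#' seeded once from `params$seed`, so the whole dataset is reproducible from
#' the parameter set alone.
#'
#' @param params [sim_params()] object.
#' @return List with `genome`, `transcripts`, `rloops`, `truth`, `counts`
#'   (named list of four condition tibbles), `spikein`, `drip_untreated`,
#'   `drip_rnaseh`, and `params`.
#' @export
simulate_dataset <- function(params = sim_params()) {
  g <- simulate_genome(params)
  rl <- plant_rloop_regions(g$genome, g$transcripts, params)
  sites <- plant_m5c_sites(rl$genome, g$transcripts, rl$rloops, params)
  bs <- simulate_bisulfite_counts(sites$genome, g$transcripts, sites$truth,
                                  params)
  drip <- simulate_drip_peaks(sites$genome, rl$rloops, params)
  list(genome = sites$genome, transcripts = g$transcripts,
       rloops = rl$rloops, truth = sites$truth, counts = bs$counts,
       spikein = bs$spikein, drip_untreated = drip$untreated,
       drip_rnaseh = drip$rnaseh, params = params)
}

#' Write a simulated dataset to a directory
#'
#' Emits genome FASTA, transcripts/R-loop/DRIP BED6 files, the truth table,
#' and per-condition plus spike-in count TSVs (positions 0-based).
#'
#' @param dataset Result of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- Biostrings::DNAStringSet(dataset$genome)
  Biostrings::writeXStringSet(fa, file.path(dir, "genome.fa"), width = 70L)
  write_bed(dataset$transcripts, file.path(dir, "transcripts.bed"))
  write_bed(dataset$rloops, file.path(dir, "rloop_truth.bed"))
  write_bed(dataset$drip_untreated, file.path(dir, "drip_untreated.bed"))
  write_bed(dataset$drip_rnaseh, file.path(dir, "drip_rnaseh.bed"))
  hdr <- list(seed = dataset$params$seed, positions = "0-based")
  write_tsv_commented(dataset$truth, file.path(dir, "truth.tsv"), hdr)
  for (cond in names(dataset$counts)) {
    write_tsv_commented(dataset$counts[[cond]],
                        file.path(dir, paste0("counts_", cond, ".tsv")), hdr)
  }
  write_tsv_commented(dataset$spikein, file.path(dir, "counts_spikein.tsv"),
                      hdr)
  invisible(dir)
}
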