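#' Simulation parameters for the synthetic dataset
#'
#' Defines every tunable of the synthetic-data generator. The defaults are
#' the study conditions the rest of the package is exercised under: a small
#' multi-chromosome genome at background GC 0.45, transcripts covering about
#' half of it, R-loop-prone regions covering roughly 10% of transcript
#' territory with sense-strand GC skew +0.4 at GC fraction 0.6, 200 planted
#' TRDMT1-dependent and 200 -independent m5C sites with co-localization 0.8
#' of dependent sites with R-loops, negative-binomial coverage with mean 50,
#' and a bisulfite non-conversion rate of 0.005.
#'
#' @param genome_length Total genome length (bp), split over `n_chrom`.
#' @param n_chrom Number of chromosomes.
#' @param gc_background Background GC fraction outside planted regions.
#' @param n_transcripts,transcript_length Transcript count and fixed length.
#' @param n_rloops,rloop_length R-loop region count and fixed length.
#' @param rloop_gc,rloop_skew Target GC fraction and sense-strand GC skew
#'   inside R-loop regions.
#' @param n_dependent,n_independent Numbers of planted TRDMT1-dependent and
#'   -independent m5C sites.
#' @param coloc_prob Probability that a dependent site is placed inside an
#'   R-loop region (otherwise uniform over transcript cytosines).
#' @param level_basal Basal methylation level (undamaged WT; KO throughout).
#' @param level_induced Damage-induced methylation level at dependent sites.
#' @param level_independent Methylation level at independent sites (all four
#'   conditions).
#' @param context_g_prob Probability of G at flanking offsets
#'   `1..context_flank` around dependent (G-rich class) sites.
#' @param context_flank Extent of the planted G-rich flank (bp each side).
#' @param coverage_mean,coverage_dispersion Negative-binomial coverage model;
#'   dispersion 0 is the Poisson limit.
#' @param nonconversion_rate Per-read probability that an unmethylated C
#'   fails to convert.
#' @param spikein_coverage Mean coverage of spike-in cytosine positions.
#' @param n_artifact_peaks RNaseH-insensitive artifact peaks added to both
#'   DRIP peak sets.
#' @param artifact_peak_length Length of artifact peaks.
#' @param peak_jitter Maximum boundary jitter (bp) applied to R-loop-derived
#'   untreated peaks.
#' @param seed Integer seed; every generator draw descends from it.
#' @return A named list of class `sim_params`.
#' @export
sim_params <- function(genome_length = 100000L,
                       n_chrom = 2L,
                       gc_background = 0.45,
                       n_transcripts = 25L,
                       transcript_length = 2000L,
                       n_rloops = 20L,
                       rloop_length = 250L,
                       rloop_gc = 0.6,
                       rloop_skew = 0.4,
                       n_dependent = 200L,
                       n_independent = 200L,
                       coloc_prob = 0.8,
                       level_basal = 0.02,
                       level_induced = 0.30,
                       level_independent = 0.20,
                       context_g_prob = 0.6,
                       context_flank = 5L,
                       coverage_mean = 50,
                       coverage_dispersion = 0.1,
                       nonconversion_rate = 0.005,
                       spikein_coverage = 2000,
                       n_artifact_peaks = 10L,
                       artifact_peak_length = 200L,
                       peak_jitter = 10L,
                       seed = 1L) {
  p <- list(
    genome_length = as.integer(genome_length), n_chrom = as.integer(n_chrom),
    gc_background = gc_background, n_transcripts = as.integer(n_transcripts),
    transcript_length = as.integer(transcript_length),
    n_rloops = as.integer(n_rloops), rloop_length = as.integer(rloop_length),
    rloop_gc = rloop_gc, rloop_skew = rloop_skew,
    n_dependent = as.integer(n_dependent),
    n_independent = as.integer(n_independent),
    coloc_prob = coloc_prob, level_basal = level_basal,
    level_induced = level_induced, level_independent = level_independent,
    context_g_prob = context_g_prob, context_flank = as.integer(context_flank),
    coverage_mean = coverage_mean, coverage_dispersion = coverage_dispersion,
    nonconversion_rate = nonconversion_rate,
    spikein_coverage = spikein_coverage,
    n_artifact_peaks = as.integer(n_artifact_peaks),
    artifact_peak_length = as.integer(artifact_peak_length),
    peak_jitter = as.integer(peak_jitter), seed = as.integer(seed)
  )
  probs <- c("gc_background", "rloop_gc", "coloc_prob", "level_basal",
             "level_induced", "level_independent", "context_g_prob")
  for (k in probs) {
    if (p[[k]] < 0 || p[[k]] > 1) abort(paste0(k, " must lie in [0, 1]"))
  }
  if (abs(p$rloop_skew) > 1) abort("rloop_skew must lie in [-1, 1]")
  if (p$nonconversion_rate < 0 || p$nonconversion_rate > 0.05) {
    abort("nonconversion_rate must lie in [0, 0.05]")
  }
  if (p$coverage_mean <= 0) abort("coverage_mean must be > 0")
  if (p$coverage_dispersion < 0) abort("coverage_dispersion must be >= 0")
  # skew s at GC fraction g needs P(G), P(C) = g(1±s)/2 in [0, 1]
  if (p$rloop_gc * (1 + abs(p$rloop_skew)) / 2 > 1) {
    abort("rloop_skew and rloop_gc jointly infeasible")
  }
  structure(p, class = "sim_params")
}

#' Pipeline configuration
#'
#' All tunables of the analysis stages, with defaults matching the study's
#' stated cut-offs: best-site thresholds coverage > 25 reads and methylation
#' > 10%, a two-fold dependence rule, and 50-bp genome windows.
#'
#' @param alpha FDR level for m5C calling (Benjamini-Hochberg q cut-off).
#' @param min_call_coverage Minimum coverage for a site to be tested.
#' @param min_best_coverage,min_best_meth Strict lower bounds defining
#'   "best" sites (coverage > 25 reads, methylation fraction > 0.10).
#' @param top_fraction Fraction defining the best-ranked subset (0.10).
#' @param fold_threshold Minimum WT/KO (or +damage/-damage) methylation fold
#'   for dependence / damage-induction.
#' @param pseudocount_reads Pseudocount (reads) used in fold computation.
#' @param removal_overlap_frac Minimum fraction of an untreated DRIP peak
#'   covered by RNaseH-condition peaks for it to be removed as
#'   RNaseH-insensitive. Use a value near 0 for any-overlap removal.
#' @param window_size GC-skew/GC-fraction window (bp).
#' @param skew_bin_width,gc_bin_width Grid bin widths over skew in `[-1,1]`
#'   and GC fraction in `[0,1]`.
#' @param grid_pseudocount Pseudocount added to grid cell counts (0 keeps
#'   undefined cells flagged rather than smoothed).
#' @param context_flank Flank (bp) of sequence-context profiles.
#' @param context_quantile Quantile for top-vs-bottom context comparison.
#' @param background_meth_factor Background unmethylated-C sites must have
#'   methylation fraction at most this multiple of the non-conversion rate.
#' @param seed Integer seed for the simulation stage of [run_pipeline()].
#' @param sim Simulation parameters ([sim_params()]); used when the pipeline
#'   generates its own dataset.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(alpha = 0.05,
                            min_call_coverage = 10L,
                            min_best_coverage = 25L,
                            min_best_meth = 0.10,
                            top_fraction = 0.10,
                            fold_threshold = 2,
                            pseudocount_reads = 0.5,
                            removal_overlap_frac = 0.5,
                            window_size = 50L,
                            skew_bin_width = 0.1,
                            gc_bin_width = 0.05,
                            grid_pseudocount = 0,
                            context_flank = 10L,
                            context_quantile = 0.25,
                            background_meth_factor = 2,
                            seed = 1L,
                            sim = sim_params(seed = seed)) {
  cfg <- list(
    alpha = alpha, min_call_coverage = as.integer(min_call_coverage),
    min_best_coverage = as.integer(min_best_coverage),
    min_best_meth = min_best_meth, top_fraction = top_fraction,
    fold_threshold = fold_threshold, pseudocount_reads = pseudocount_reads,
    removal_overlap_frac = removal_overlap_frac,
    window_size = as.integer(window_size),
    skew_bin_width = skew_bin_width, gc_bin_width = gc_bin_width,
    grid_pseudocount = grid_pseudocount,
    context_flank = as.integer(context_flank),
    context_quantile = context_quantile,
    background_meth_factor = background_meth_factor,
    seed = as.integer(seed), sim = sim
  )
  if (cfg$window_size < 2) abort("window_size must be >= 2")
  if (cfg$fold_threshold <= 1) abort("fold_threshold must be > 1")
  for (k in c("alpha", "top_fraction", "context_quantile")) {
    if (cfg[[k]] <= 0 || cfg[[k]] > 1) abort(paste0(k, " must lie in (0, 1]"))
  }
  structure(cfg, class = "pipeline_config")
}

format_config_value <- function(v) {
  if (is.numeric(v)) paste(format(v, digits = 15, scientific = FALSE,
                                  trim = TRUE), collapse = ",")
  else paste(as.character(v), collapse = ",")
}

#' Write a configuration as a flat key=value file
#'
#' Nested simulation parameters are flattened with a `sim.` prefix. Every
#' pipeline run writes its fully resolved configuration beside its outputs
#' so the exact cut-offs used are always on record.
#'
#' @param config A `pipeline_config` or `sim_params` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  flat <- list()
  for (k in names(config)) {
    v <- config[[k]]
    if (inherits(v, "sim_params")) {
      for (k2 in names(v)) flat[[paste0("sim.", k2)]] <- v[[k2]]
    } else {
      flat[[k]] <- v
    }
  }
  writeLines(paste0(names(flat), "=",
                    vapply(flat, format_config_value, character(1))), path)
  invisible(path)
}

#' Read a flat key=value configuration file
#'
#' @param path Path written by [write_config()] (or hand-edited in the same
#'   format; `sim.`-prefixed keys populate the simulation parameters).
#' @return A `pipeline_config` object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- vapply(kv, `[`, character(1), 1L)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), character(1))
  num <- suppressWarnings(as.numeric(vals))
  parsed <- ifelse(is.na(num), vals, num)
  parsed <- as.list(setNames(parsed, keys))
  parsed <- lapply(parsed, function(v) {
    if (is.character(v)) v else if (v == trunc(v)) v else v
  })
  sim_keys <- grep("^sim\\.", names(parsed), value = TRUE)
  sim_args <- setNames(parsed[sim_keys], sub("^sim\\.", "", sim_keys))
  top_args <- parsed[setdiff(names(parsed), sim_keys)]
  cfg <- do.call(pipeline_config, top_args)
  if (length(sim_args) > 0) cfg$sim <- do.call(sim_params, sim_args)
  cfg
}
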