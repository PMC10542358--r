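# End-to-end pipeline: simulate (or load) -> call -> classify -> overlap ->
# GC skew/grids -> contexts, with a resolved config and an audit log.

log_line <- function(log_env, stage, msg) {
  line <- sprintf("[%s] %s", stage, msg)
  log_env$lines <- c(log_env$lines, line)
  invisible(line)
}

facet_file_tag <- function(facet) {
  c("+" = "plus", "-" = "minus", "." = "intergenic")[[facet]]
}

read_pipeline_inputs <- function(data_dir) {
  req <- c("genome.fa", "transcripts.bed", "drip_untreated.bed",
           "drip_rnaseh.bed", "counts_spikein.tsv",
           paste0("counts_", CONDITIONS, ".tsv"))
  missing_files <- req[!file.exists(file.path(data_dir, req))]
  if (length(missing_files) > 0) {
    abort(paste0("missing pipeline input(s) in ", data_dir, ": ",
                 paste(missing_files, collapse = ", ")))
  }
  counts <- lapply(CONDITIONS, function(cond) {
    read_tsv_commented(file.path(data_dir, paste0("counts_", cond, ".tsv")))
  })
  names(counts) <- CONDITIONS
  list(
    genome = read_genome_fasta(file.path(data_dir, "genome.fa")),
    transcripts = read_bed(file.path(data_dir, "transcripts.bed")),
    counts = counts,
    spikein = read_tsv_commented(file.path(data_dir, "counts_spikein.tsv")),
    drip_untreated = read_bed(file.path(data_dir, "drip_untreated.bed")),
    drip_rnaseh = read_bed(file.path(data_dir, "drip_rnaseh.bed"))
  )
}

#' Run the full m5C / R-loop analysis pipeline
#'
#' Chains every stage over one dataset: spike-in non-conversion
#' calibration, per-condition m5C calling with best-site flagging,
#' TRDMT1-dependence and damage-induction classification, RNaseH
#' subtraction of DRIP peaks, overlap enrichment of site classes (including
#' the best-10% subsets) against the unmethylated-C background, windowed
#' GC-skew statistics, strand-faceted observed-vs-expected grids, the
#' dependent-site grid distribution, and top-vs-bottom sequence contexts.
#' When `data_dir` is `NULL` the dataset is simulated from
#' `config$sim` first and written beside the results, so a single call is
#' a fully reproducible end-to-end run.
#'
#' Every stage appends its input/output counts and the rule applied to
#' `run.log`, and the fully resolved configuration is written to
#' `config.txt`; two runs with the same configuration and seed produce
#' byte-identical outputs.
#'
#' @param config [pipeline_config()] object.
#' @param out_dir Output directory (created if needed).
#' @param data_dir Optional directory of pre-existing inputs in the layout
#'   written by [write_dataset()]; when `NULL`, data are simulated.
#' @return Invisibly, a list with every intermediate object (`dataset`,
#'   `nonconversion`, `calls`, `dependence`, `rnaseh_sensitive`,
#'   `background`, `enrichment`, `windows`, `grid`, `site_grid`,
#'   `contexts`, `class_summary`) plus `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         data_dir = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_env <- new.env()
  log_env$lines <- character(0)
  set.seed(config$seed)

  if (is.null(data_dir)) {
    dataset <- simulate_dataset(config$sim)
    data_dir <- file.path(out_dir, "data")
    write_dataset(dataset, data_dir)
    log_line(log_env, "simulate",
             sprintf("seed=%d genome=%dbp transcripts=%d rloops=%d sites=%d",
                     config$sim$seed, sum(nchar(dataset$genome)),
                     nrow(dataset$transcripts), nrow(dataset$rloops),
                     nrow(dataset$truth)))
  } else {
    dataset <- read_pipeline_inputs(data_dir)
    log_line(log_env, "load", paste0("inputs read from ", data_dir))
  }
  hdr <- list(seed = config$seed, positions = "0-based")

  # spike-in calibration
  eps_tab <- estimate_nonconversion(dataset$spikein)
  eps <- eps_tab$rate
  log_line(log_env, "nonconversion",
           sprintf("rate=%.6f [%.6f, %.6f] from %d reads",
                   eps, eps_tab$conf_low, eps_tab$conf_high,
                   eps_tab$coverage))

  # per-condition calling
  calls <- lapply(CONDITIONS, function(cond) {
    cl <- call_sites(dataset$counts[[cond]], eps, alpha = config$alpha,
                     min_call_coverage = config$min_call_coverage)
    cl <- flag_best(cl, config$min_best_coverage, config$min_best_meth)
    log_line(log_env, "call",
             sprintf("%s: %d sites in, %d called, %d best (q<%g, cov>=%d)",
                     cond, nrow(cl), sum(cl$called), sum(cl$best),
                     config$alpha, config$min_call_coverage))
    write_tsv_commented(cl, file.path(out_dir,
                                      paste0("calls_", cond, ".tsv")), hdr)
    cl
  })
  names(calls) <- CONDITIONS

  # dependence (within matching damage condition) + damage induction in WT
  dep <- lapply(c(plus = "plus", minus = "minus"), function(dmg) {
    d <- classify_dependence(calls[[paste0("WT_", dmg)]],
                             calls[[paste0("KO_", dmg)]],
                             config$fold_threshold, config$pseudocount_reads)
    log_line(log_env, "classify",
             sprintf("%s damage: %d WT-called -> %d dependent, %d independent, %d unclassifiable (fold>=%g); %d KO-only sites set aside",
                     dmg, nrow(d), sum(d$label == "TRDMT1-dependent"),
                     sum(d$label == "TRDMT1-independent"),
                     sum(d$label == "unclassifiable"),
                     config$fold_threshold,
                     nrow(attr(d, "ko_only_sites"))))
    d
  })
  dmg_ind <- classify_damage_induction(calls$WT_minus, calls$WT_plus,
                                       config$fold_threshold,
                                       config$pseudocount_reads)
  dependence <- left_join(
    dep$plus,
    select(dmg_ind, "chrom", "pos", "fold_damage", "damage_induced"),
    by = c("chrom", "pos")
  )
  write_tsv_commented(dependence, file.path(out_dir, "dependence.tsv"), hdr)
  class_summary <- bind_rows(
    mutate(summarize_site_classes(dep$plus), condition = "damaged"),
    mutate(summarize_site_classes(dep$minus), condition = "undamaged")
  )
  write_tsv_commented(class_summary, file.path(out_dir,
                                               "class_summary.tsv"), hdr)

  # RNaseH-sensitive peaks
  rnaseh_sensitive <- subtract_rnaseh(dataset$drip_untreated,
                                      dataset$drip_rnaseh,
                                      config$removal_overlap_frac)
  log_line(log_env, "subtract_rnaseh",
           sprintf("%d untreated peaks -> %d RNaseH-sensitive (removed when covered >= %g of length)",
                   nrow(dataset$drip_untreated), nrow(rnaseh_sensitive),
                   config$removal_overlap_frac))
  write_bed(rnaseh_sensitive, file.path(out_dir, "rnaseh_sensitive.bed"))

  # overlap enrichment vs unmethylated-C background
  background <- background_c_sites(calls, eps,
                                   min_coverage = config$min_best_coverage,
                                   meth_factor = config$background_meth_factor)
  log_line(log_env, "background",
           sprintf("%d unmethylated background cytosines (cov>%d, meth<=%g*eps, called nowhere)",
                   nrow(background), config$min_best_coverage,
                   config$background_meth_factor))
  site_sets <- list()
  for (dmg in c("plus", "minus")) {
    d <- dep[[dmg]]
    cond_label <- if (dmg == "plus") "damaged" else "undamaged"
    dep_sites <- filter(d, .data$label == "TRDMT1-dependent")
    ind_sites <- filter(d, .data$label == "TRDMT1-independent")
    site_sets[[paste0("dependent_", cond_label)]] <- dep_sites
    site_sets[[paste0("independent_", cond_label)]] <- ind_sites
    wt_calls <- calls[[paste0("WT_", dmg)]]
    for (cls in c("dependent", "independent")) {
      cls_sites <- if (cls == "dependent") dep_sites else ind_sites
      sub <- inner_join(wt_calls, select(cls_sites, "chrom", "pos"),
                        by = c("chrom", "pos"))
      if (nrow(sub) > 0) {
        site_sets[[paste0("best10_", cls, "_", cond_label)]] <-
          rank_top_fraction(sub, config$top_fraction)
      }
    }
  }
  enrichment <- overlap_by_condition(site_sets, background,
                                     rnaseh_sensitive)
  write_tsv_commented(enrichment, file.path(out_dir, "enrichment.tsv"), hdr)
  log_line(log_env, "overlap",
           sprintf("%d site sets tested against %d background sites and %d peaks",
                   length(site_sets), nrow(background),
                   nrow(rnaseh_sensitive)))

  # windowed GC stats + grids
  windows <- windowed_gc_stats(dataset$genome, config$window_size,
                               dataset$transcripts, rnaseh_sensitive)
  log_line(log_env, "gcskew",
           sprintf("%d windows of %dbp (%d undefined skew, %d in R-loops)",
                   nrow(windows), config$window_size,
                   sum(!windows$skew_defined), sum(windows$in_rloop)))
  write_tsv_commented(windows, file.path(out_dir, "windows.tsv"),
                      c(hdr, window_size = config$window_size))
  grid <- build_obs_exp_grid(windows, config$skew_bin_width,
                             config$gc_bin_width, config$grid_pseudocount)
  for (fc in unique(grid$facet_strand)) {
    write_tsv_commented(
      filter(grid, .data$facet_strand == fc),
      file.path(out_dir, paste0("grid_", facet_file_tag(fc), ".tsv")), hdr)
  }

  dep_sites_plus <- filter(dep$plus, .data$label == "TRDMT1-dependent")
  site_grid <- site_grid_distribution(dep_sites_plus, windows,
                                      config$skew_bin_width,
                                      config$gc_bin_width)
  write_tsv_commented(site_grid$counts,
                      file.path(out_dir, "site_grid.tsv"), hdr)

  # sequence contexts
  contexts <- compare_top_bottom_contexts(calls$WT_plus, dataset$genome,
                                          config$context_flank,
                                          config$context_quantile)
  write_tsv_commented(as_tibble(contexts$top),
                      file.path(out_dir, "context_top.tsv"), hdr)
  write_tsv_commented(as_tibble(contexts$bottom),
                      file.path(out_dir, "context_bottom.tsv"), hdr)
  ctx_dep <- extract_contexts(dataset$genome, dep_sites_plus,
                              config$context_flank)
  write_tsv_commented(as_tibble(ctx_dep),
                      file.path(out_dir, "context_dependent.tsv"), hdr)
  log_line(log_env, "context",
           sprintf("top/bottom quantile %g over %d plus-strand called sites",
                   config$context_quantile,
                   sum(calls$WT_plus$called & calls$WT_plus$strand == "+")))

  write_config(config, file.path(out_dir, "config.txt"))
  writeLines(log_env$lines, file.path(out_dir, "run.log"))

  invisible(list(
    dataset = dataset, nonconversion = eps_tab, calls = calls,
    dependence = dependence, dependence_by_damage = dep,
    rnaseh_sensitive = rnaseh_sensitive, background = background,
    enrichment = enrichment, windows = windows, grid = grid,
    site_grid = site_grid, contexts = contexts,
    context_dependent = ctx_dep, class_summary = class_summary,
    out_dir = out_dir
  ))
}
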