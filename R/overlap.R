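# R-loop peak filtering and overlap enrichment of m5C site classes.

#' Remove RNaseH-insensitive peaks from an untreated DRIP peak set
#'
#' RNaseH destroys genuine DNA:RNA hybrids, so peaks that persist after
#' RNaseH treatment are artifacts. An untreated peak is removed when the
#' summed length of its intersections with RNaseH-condition peaks is at
#' least `removal_overlap_frac` of its own length; the survivors are the
#' RNaseH-sensitive (high-confidence R-loop) peaks. Output preserves input
#' order and is a subset of the input, so the filter is idempotent.
#'
#' @param peaks_untreated,peaks_rnaseh Interval tibbles of DRIP peaks from
#'   untreated and RNaseH-treated preparations.
#' @param removal_overlap_frac Removal threshold in `(0, 1]`; values near 0
#'   approximate any-overlap removal.
#' @return Tibble of retained (RNaseH-sensitive) peaks.
#' @export
subtract_rnaseh <- function(peaks_untreated, peaks_rnaseh,
                            removal_overlap_frac = 0.5) {
  peaks_untreated <- validate_intervals(peaks_untreated)
  peaks_rnaseh <- validate_intervals(peaks_rnaseh)
  if (removal_overlap_frac <= 0 || removal_overlap_frac > 1) {
    abort("removal_overlap_frac must lie in (0, 1]")
  }
  if (nrow(peaks_untreated) == 0 || nrow(peaks_rnaseh) == 0) {
    return(peaks_untreated)
  }
  q <- as_granges(peaks_untreated)
  s <- as_granges(peaks_rnaseh)
  hits <- GenomicRanges::findOverlaps(q, s, ignore.strand = TRUE)
  inter_w <- GenomicRanges::width(IRanges::pintersect(
    q[S4Vectors::queryHits(hits)], s[S4Vectors::subjectHits(hits)],
    ignore.strand = TRUE
  ))
  covered <- tapply(inter_w, S4Vectors::queryHits(hits), sum)
  frac <- numeric(nrow(peaks_untreated))
  frac[as.integer(names(covered))] <- as.numeric(covered)
  frac <- frac / (peaks_untreated$end - peaks_untreated$start)
  peaks_untreated[frac < removal_overlap_frac, ]
}

#' Annotate sites by R-loop peak containment
#'
#' A site is "in an R-loop" when its position lies inside a DRIP peak
#' (half-open containment, `start <= pos < end`), ignoring strand because
#' DRIP peaks are unstranded.
#'
#' @param sites Tibble with `chrom` and `pos` (0-based) columns.
#' @param peaks Interval tibble of peaks.
#' @return `sites` with a logical `in_rloop` column appended.
#' @export
annotate_sites_in_peaks <- function(sites, peaks) {
  sites <- as_tibble(sites)
  if (nrow(sites) == 0 || nrow(peaks) == 0) {
    sites$in_rloop <- rep(FALSE, nrow(sites))
    return(sites)
  }
  q <- GenomicRanges::GRanges(
    seqnames = sites$chrom,
    ranges = IRanges::IRanges(start = sites$pos + 1L, width = 1L)
  )
  hits <- GenomicRanges::findOverlaps(q, as_granges(peaks),
                                      ignore.strand = TRUE)
  sites$in_rloop <- seq_len(nrow(sites)) %in% S4Vectors::queryHits(hits)
  sites
}

# sample odds ratio of a 2x2 table with Haldane correction when any cell
# is zero
sample_odds_ratio <- function(a, b, c, d) {
  if (min(a, b, c, d) == 0) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  (a * d) / (b * c)
}

#' Overlap enrichment of a site class against a background
#'
#' Builds the 2x2 table (class/background x in/out of R-loop peaks),
#' reports per-set overlap fractions, the sample odds ratio (Haldane
#' 0.5-correction when a cell is zero), and a two-sided Fisher exact
#' p-value.
#'
#' @param class_sites,background_sites Tibbles with `chrom`, `pos`
#'   columns; the two sets should be disjoint.
#' @param peaks R-loop peak interval tibble (typically the output of
#'   [subtract_rnaseh()]).
#' @param class_label,background_label Labels used in the tidy output.
#' @return An object of class `rloop_enrichment`: list with `summary`
#'   (per-set tibble), `table` (2x2 matrix), `odds_ratio`, `p_value`.
#' @export
overlap_enrichment <- function(class_sites, background_sites, peaks,
                               class_label = "class",
                               background_label = "background") {
  if (nrow(class_sites) == 0 || nrow(background_sites) == 0) {
    abort("both site sets must be non-empty")
  }
  a_in <- sum(annotate_sites_in_peaks(class_sites, peaks)$in_rloop)
  b_in <- sum(annotate_sites_in_peaks(background_sites, peaks)$in_rloop)
  n_a <- nrow(class_sites)
  n_b <- nrow(background_sites)
  tab <- matrix(c(a_in, n_a - a_in, b_in, n_b - b_in), nrow = 2,
                byrow = TRUE,
                dimnames = list(set = c(class_label, background_label),
                                rloop = c("in", "out")))
  or <- sample_odds_ratio(a_in, n_a - a_in, b_in, n_b - b_in)
  p <- if (nrow(peaks) == 0) NA_real_ else fisher.test(tab)$p.value
  structure(list(
    summary = tibble(
      set = c(class_label, background_label),
      n_total = c(n_a, n_b),
      n_in_rloop = c(a_in, b_in),
      fraction_in_rloop = c(a_in / n_a, b_in / n_b)
    ),
    table = tab,
    odds_ratio = if (nrow(peaks) == 0) NA_real_ else or,
    p_value = p
  ), class = "rloop_enrichment")
}

#' @export
print.rloop_enrichment <- function(x, ...) {
  cat("R-loop overlap enrichment\n")
  print(x$summary)
  cat(sprintf("odds ratio = %.4g, Fisher two-sided p = %.3g\n",
              x$odds_ratio, x$p_value))
  invisible(x)
}

#' Tidy an `rloop_enrichment` object
#'
#' @param x An [overlap_enrichment()] result.
#' @param ... Unused.
#' @return One row per site set with totals and in-R-loop fractions.
#' @export
tidy.rloop_enrichment <- function(x, ...) x$summary

#' One-row summary of an `rloop_enrichment` object
#'
#' @param x An [overlap_enrichment()] result.
#' @param ... Unused.
#' @return Tibble with `odds_ratio` and `p_value`.
#' @export
glance.rloop_enrichment <- function(x, ...) {
  tibble(odds_ratio = x$odds_ratio, p_value = x$p_value)
}

#' Overlap enrichment for several site sets against one background
#'
#' Convenience wrapper running [overlap_enrichment()] for each named site
#' set (e.g. per condition and class, plus a best-10% subset) against a
#' shared unmethylated-C background.
#'
#' @param site_sets Named list of site tibbles (`chrom`, `pos`).
#' @param background_sites Background site tibble.
#' @param peaks R-loop peak interval tibble.
#' @return Tibble with one row per set: `set`, `n_total`, `n_in_rloop`,
#'   `fraction_in_rloop`, `background_fraction`, `odds_ratio`, `p_value`.
#' @export
overlap_by_condition <- function(site_sets, background_sites, peaks) {
  if (length(site_sets) == 0) abort("no site sets supplied")
  if (is.null(names(site_sets)) || any(!nzchar(names(site_sets)))) {
    abort("site_sets must be a named list")
  }
  rows <- purrr::imap(site_sets, function(sites, label) {
    if (nrow(sites) == 0) {
      return(tibble(set = label, n_total = 0L, n_in_rloop = 0L,
                    fraction_in_rloop = NA_real_,
                    background_fraction = NA_real_,
                    odds_ratio = NA_real_, p_value = NA_real_))
    }
    e <- overlap_enrichment(sites, background_sites, peaks,
                            class_label = label)
    tibble(set = label,
           n_total = e$summary$n_total[1],
           n_in_rloop = e$summary$n_in_rloop[1],
           fraction_in_rloop = e$summary$fraction_in_rloop[1],
           background_fraction = e$summary$fraction_in_rloop[2],
           odds_ratio = e$odds_ratio, p_value = e$p_value)
  })
  bind_rows(rows)
}
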