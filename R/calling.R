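# m5C calling from per-cytosine bisulfite counts, calibrated against the
# spike-in non-conversion rate.

#' Estimate the bisulfite non-conversion rate from spike-in counts
#'
#' The spike-in RNA is fully unmethylated, so every unconverted read at one
#' of its cytosines is a conversion failure. The estimate pools all
#' cytosine positions: eps = sum(n_unconverted) / sum(coverage), with an
#' exact (Clopper-Pearson) 95% binomial confidence interval.
#'
#' @param spikein_counts Tibble with `n_unconverted` and `n_converted`
#'   columns (one row per spike-in cytosine position).
#' @param conf_level Confidence level of the interval.
#' @return Tibble with one row: `rate`, `conf_low`, `conf_high`,
#'   `n_unconverted`, `coverage`, `n_positions`.
#' @export
estimate_nonconversion <- function(spikein_counts, conf_level = 0.95) {
  if (nrow(spikein_counts) == 0) {
    abort("spike-in count table is empty")
  }
  u <- sum(spikein_counts$n_unconverted)
  total <- u + sum(spikein_counts$n_converted)
  if (total == 0) abort("spike-in has zero total coverage")
  bt <- binom.test(u, total, conf.level = conf_level)
  tibble(rate = u / total,
         conf_low = bt$conf.int[1], conf_high = bt$conf.int[2],
         n_unconverted = u, coverage = total,
         n_positions = nrow(spikein_counts))
}

#' Call m5C sites from one condition's count table
#'
#' Tests each cytosine's unconverted count against the non-conversion rate
#' with a one-sided exact binomial test, P(X >= n_unconverted | coverage,
#' eps), and controls the FDR across all tested sites with
#' Benjamini-Hochberg. Sites below the coverage floor are reported as
#' `untested` rather than dropped, so they remain available for the
#' unmethylated-background definition.
#'
#' @param counts Tibble with `chrom`, `pos`, `strand`, `n_unconverted`,
#'   `n_converted` (one condition).
#' @param nonconversion_rate Non-conversion rate eps in `[0, 0.5)`, e.g.
#'   `estimate_nonconversion(spikein)$rate`.
#' @param alpha FDR level: called iff q < alpha (and tested).
#' @param min_call_coverage Minimum coverage for a site to be tested.
#' @return Tibble with `chrom`, `pos`, `strand`, `coverage`,
#'   `n_unconverted`, `meth_fraction`, `p_value`, `q_value`, `status`
#'   (`called` / `not_called` / `untested`), `called`, `best` (initialised
#'   `FALSE`; see [flag_best()]).
#' @export
call_sites <- function(counts, nonconversion_rate, alpha = 0.05,
                       min_call_coverage = 10L) {
  if (nonconversion_rate < 0 || nonconversion_rate >= 0.5) {
    abort("nonconversion_rate must lie in [0, 0.5)")
  }
  if (any(counts$n_unconverted < 0) || any(counts$n_converted < 0)) {
    abort("negative counts")
  }
  out <- tibble(
    chrom = counts$chrom, pos = counts$pos, strand = counts$strand,
    coverage = counts$n_unconverted + counts$n_converted,
    n_unconverted = counts$n_unconverted
  )
  out$meth_fraction <- ifelse(out$coverage > 0,
                              out$n_unconverted / out$coverage, NA_real_)
  tested <- out$coverage >= min_call_coverage
  # one-sided exact binomial upper tail P(X >= u)
  p <- rep(NA_real_, nrow(out))
  p[tested] <- pbinom(out$n_unconverted[tested] - 1, out$coverage[tested],
                      nonconversion_rate, lower.tail = FALSE)
  q <- rep(NA_real_, nrow(out))
  q[tested] <- p.adjust(p[tested], method = "BH")
  out$p_value <- p
  out$q_value <- q
  out$called <- tested & !is.na(q) & q < alpha
  out$status <- ifelse(!tested, "untested",
                       ifelse(out$called, "called", "not_called"))
  out$best <- FALSE
  out
}

#' Flag best sites by high coverage and high methylation
#'
#' A called site is `best` when its coverage strictly exceeds 25 reads and
#' its methylation fraction strictly exceeds 10% (both thresholds
#' configurable).
#'
#' @param calls Output of [call_sites()].
#' @param min_best_coverage Coverage must be strictly greater than this.
#' @param min_best_meth Methylation fraction must be strictly greater than
#'   this.
#' @return `calls` with the `best` column set.
#' @export
flag_best <- function(calls, min_best_coverage = 25L, min_best_meth = 0.10) {
  mutate(calls, best = .data$called &
           .data$coverage > min_best_coverage &
           .data$meth_fraction > min_best_meth)
}

#' Select the top fraction of called sites by methylation
#'
#' Returns the `ceiling(fraction * N)` called sites with the highest
#' methylation fraction; ties are broken by higher coverage, then by
#' `(chrom, pos)` lexicographic order.
#'
#' @param calls Output of [call_sites()] (only `status == "called"` rows
#'   are ranked).
#' @param fraction Fraction in `(0, 1]`.
#' @return Tibble of the selected calls, in rank order.
#' @export
rank_top_fraction <- function(calls, fraction = 0.10) {
  if (fraction <= 0 || fraction > 1) abort("fraction must lie in (0, 1]")
  called <- filter(calls, .data$status == "called")
  if (nrow(called) == 0) abort("no called sites to rank")
  called <- arrange(called, desc(.data$meth_fraction), desc(.data$coverage),
                    .data$chrom, .data$pos)
  head(called, ceiling(fraction * nrow(called)))
}

#' Define the unmethylated-cytosine background set
#'
#' The comparison background for overlap enrichment: well-covered cytosines
#' (coverage above the best-site floor) whose methylation fraction is
#' indistinguishable from the non-conversion rate (at most
#' `meth_factor * eps`) and that are called in none of the supplied
#' conditions.
#'
#' @param calls_list Named list of [call_sites()] outputs (one per
#'   condition). The first element supplies the coverage/fraction screen;
#'   all elements veto called sites.
#' @param nonconversion_rate Non-conversion rate eps.
#' @param min_coverage Coverage must strictly exceed this (default 25).
#' @param meth_factor Methylation ceiling as a multiple of eps.
#' @return Tibble of background sites (`chrom`, `pos`, `strand`,
#'   `coverage`, `meth_fraction`).
#' @export
background_c_sites <- function(calls_list, nonconversion_rate,
                               min_coverage = 25L, meth_factor = 2) {
  ref <- calls_list[[1]]
  keep <- ref$coverage > min_coverage &
    !is.na(ref$meth_fraction) &
    ref$meth_fraction <= meth_factor * nonconversion_rate
  bg <- ref[keep, c("chrom", "pos", "strand", "coverage", "meth_fraction")]
  for (calls in calls_list) {
    called <- calls[calls$called, c("chrom", "pos")]
    bg <- anti_join(bg, called, by = c("chrom", "pos"))
  }
  bg
}
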