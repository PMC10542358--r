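# Windowed GC skew / GC fraction, strand-faceted observed-vs-expected
# grids, and site grid distributions.

#' Windowed GC skew and GC fraction across a genome
#'
#' Tiles each chromosome with non-overlapping windows from position 0
#' (the terminal partial window is dropped) and computes, per window,
#' `gc_skew = (G - C) / (G + C)` and `gc_fraction = (G + C) /
#' window_size` on the reference (+) strand. Windows containing any `N`,
#' or with no G or C at all, carry an undefined skew flag and are excluded
#' from downstream skew statistics. When transcripts are supplied, each
#' window is assigned the strand of the transcript covering most of it
#' (`facet_strand`; `"."` for intergenic windows) and the reported
#' `gc_skew` is flipped on `-` facets so that a positive skew always means
#' G-rich on the transcribed (sense) strand.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param window_size Window length in bp (>= 2); default 50.
#' @param transcripts Optional transcript interval tibble for faceting.
#' @param rloops Optional R-loop interval tibble; windows overlapping any
#'   R-loop are flagged `in_rloop`.
#' @return Tibble with `chrom`, `start`, `gc_skew` (sense-strand,
#'   `NA` when undefined), `gc_fraction`, `skew_defined`, `facet_strand`,
#'   `in_rloop`, and `gc_skew_plus` (the unflipped reference-strand skew).
#'   The window size is recorded in the `window_size` attribute.
#' @export
windowed_gc_stats <- function(genome, window_size = 50L,
                              transcripts = NULL, rloops = NULL) {
  if (window_size < 2) abort("window_size must be >= 2")
  w <- as.integer(window_size)
  per_chrom <- purrr::imap(as.list(genome), function(seq, cn) {
    n_win <- nchar(seq) %/% w
    if (n_win == 0) return(NULL)
    x <- Biostrings::DNAString(seq)
    lf_all <- Biostrings::letterFrequencyInSlidingView(x, w,
                                                       c("G", "C", "N"))
    lf <- lf_all[(seq_len(n_win) - 1L) * w + 1L, , drop = FALSE]
    tibble(chrom = cn, start = (seq_len(n_win) - 1L) * w,
           n_g = lf[, "G"], n_c = lf[, "C"], n_n = lf[, "N"])
  })
  win <- bind_rows(per_chrom)
  gc <- win$n_g + win$n_c
  win$skew_defined <- gc > 0 & win$n_n == 0
  win$gc_skew_plus <- ifelse(win$skew_defined,
                             (win$n_g - win$n_c) / gc, NA_real_)
  win$gc_fraction <- gc / w

  win$facet_strand <- "."
  if (!is.null(transcripts) && nrow(transcripts) > 0) {
    q <- GenomicRanges::GRanges(
      seqnames = win$chrom,
      ranges = IRanges::IRanges(start = win$start + 1L, width = w)
    )
    s <- as_granges(transcripts)
    hits <- GenomicRanges::findOverlaps(q, s, ignore.strand = TRUE)
    if (length(hits) > 0) {
      ov_w <- GenomicRanges::width(IRanges::pintersect(
        q[S4Vectors::queryHits(hits)], s[S4Vectors::subjectHits(hits)],
        ignore.strand = TRUE
      ))
      hit_tab <- tibble(
        win_i = S4Vectors::queryHits(hits),
        strand = transcripts$strand[S4Vectors::subjectHits(hits)],
        ov = ov_w
      )
      best <- hit_tab |>
        arrange(.data$win_i, desc(.data$ov)) |>
        distinct(.data$win_i, .keep_all = TRUE)
      win$facet_strand[best$win_i] <- best$strand
    }
  }
  win$gc_skew <- ifelse(win$facet_strand == "-", -win$gc_skew_plus,
                        win$gc_skew_plus)

  win$in_rloop <- FALSE
  if (!is.null(rloops) && nrow(rloops) > 0) {
    q <- GenomicRanges::GRanges(
      seqnames = win$chrom,
      ranges = IRanges::IRanges(start = win$start + 1L, width = w)
    )
    hits <- GenomicRanges::findOverlaps(q, as_granges(rloops),
                                        ignore.strand = TRUE)
    win$in_rloop <- seq_len(nrow(win)) %in% S4Vectors::queryHits(hits)
  }
  out <- select(win, "chrom", "start", "gc_skew", "gc_fraction",
                "skew_defined", "facet_strand", "in_rloop", "gc_skew_plus")
  attr(out, "window_size") <- w
  out
}

# bin index over [lo, hi) with the final bin closed at hi
bin_index <- function(x, lo, hi, width) {
  k <- as.integer(round((hi - lo) / width))
  pmin(pmax(floor((x - lo) / width) + 1L, 1L), k)
}

check_bin_width <- function(width, span, what) {
  k <- span / width
  if (abs(k - round(k)) > 1e-9) {
    abort(paste0(what, " must divide its range evenly"))
  }
  as.integer(round(k))
}

#' Observed-vs-expected enrichment grid over (GC skew, GC fraction)
#'
#' For each transcribing-strand facet, bins the R-loop windows (observed)
#' and the remainder of the genome (expected: every defined-skew window
#' not in an R-loop, genome-wide, intergenic windows included) on a 2-D
#' grid of sense-strand GC skew versus GC fraction, and reports the ratio
#' of observed to expected cell proportions. Cells with no expected mass
#' are flagged (`NA` ratio) rather than divided; ratios above 1 indicate
#' enrichment of R-loops at that sequence composition.
#'
#' @param windows Output of [windowed_gc_stats()] with `in_rloop` set.
#' @param skew_bin_width Bin width over skew in `[-1, 1]` (default 0.1).
#' @param gc_bin_width Bin width over GC fraction in `[0, 1]`
#'   (default 0.05).
#' @param pseudocount Count added to every cell of both distributions
#'   before forming proportions (default 0: undefined cells stay flagged).
#' @return Tibble of class `rloop_grid`: `facet_strand`, bin indices and
#'   midpoints (`skew_mid`, `gc_mid`), `n_observed`, `n_expected`,
#'   `ratio`, plus per-facet totals `obs_total`, `exp_total`.
#' @export
build_obs_exp_grid <- function(windows, skew_bin_width = 0.1,
                               gc_bin_width = 0.05, pseudocount = 0) {
  k_skew <- check_bin_width(skew_bin_width, 2, "skew_bin_width")
  k_gc <- check_bin_width(gc_bin_width, 1, "gc_bin_width")
  defined <- filter(windows, .data$skew_defined)
  if (!any(defined$in_rloop)) {
    abort("no R-loop windows with defined skew in any facet")
  }
  expected <- filter(defined, !.data$in_rloop)
  facets <- sort(unique(defined$facet_strand[defined$in_rloop]))

  cell_counts <- function(df) {
    if (nrow(df) == 0) return(matrix(0, k_skew, k_gc))
    si <- bin_index(df$gc_skew, -1, 1, skew_bin_width)
    gi <- bin_index(df$gc_fraction, 0, 1, gc_bin_width)
    m <- matrix(0, k_skew, k_gc)
    for (i in seq_along(si)) m[si[i], gi[i]] <- m[si[i], gi[i]] + 1
    m
  }
  exp_m <- cell_counts(expected) + pseudocount
  exp_total <- sum(exp_m)

  grids <- lapply(facets, function(fc) {
    obs <- filter(defined, .data$in_rloop, .data$facet_strand == fc)
    if (nrow(obs) == 0) {
      abort(paste0("no R-loop windows in facet '", fc, "'"))
    }
    obs_m <- cell_counts(obs) + pseudocount
    obs_total <- sum(obs_m)
    ratio <- ifelse(exp_m > 0,
                    (obs_m / obs_total) / (exp_m / exp_total), NA_real_)
    tibble(
      facet_strand = fc,
      skew_bin = rep(seq_len(k_skew), times = k_gc),
      gc_bin = rep(seq_len(k_gc), each = k_skew),
      skew_mid = -1 + (rep(seq_len(k_skew), times = k_gc) - 0.5) *
        skew_bin_width,
      gc_mid = (rep(seq_len(k_gc), each = k_skew) - 0.5) * gc_bin_width,
      n_observed = as.vector(obs_m),
      n_expected = as.vector(exp_m),
      ratio = as.vector(ratio),
      obs_total = obs_total,
      exp_total = exp_total
    )
  })
  out <- bind_rows(grids)
  class(out) <- c("rloop_grid", class(out))
  attr(out, "skew_bin_width") <- skew_bin_width
  attr(out, "gc_bin_width") <- gc_bin_width
  out
}

#' Distribution of m5C sites over the (GC skew, GC fraction) grid
#'
#' Maps each site to the genome window containing it and counts sites per
#' grid cell, faceted by site strand; skew is expressed on the site's
#' strand (reference-strand skew, sign-flipped for `-` strand sites).
#' Sites falling in undefined-skew windows or outside any full window are
#' tallied separately rather than silently dropped.
#'
#' @param sites Tibble with `chrom`, `pos`, `strand`.
#' @param windows Output of [windowed_gc_stats()].
#' @param skew_bin_width,gc_bin_width Bin widths as in
#'   [build_obs_exp_grid()].
#' @return List with `counts` (tibble: `facet_strand`, bin indices and
#'   midpoints, `n_sites`) and `excluded` (tibble of reason/count:
#'   `no_window`, `undefined_skew`).
#' @export
site_grid_distribution <- function(sites, windows, skew_bin_width = 0.1,
                                   gc_bin_width = 0.05) {
  k_skew <- check_bin_width(skew_bin_width, 2, "skew_bin_width")
  k_gc <- check_bin_width(gc_bin_width, 1, "gc_bin_width")
  w <- attr(windows, "window_size")
  if (is.null(w)) abort("windows lack a window_size attribute")
  sites <- as_tibble(sites)
  sites$win_start <- (sites$pos %/% w) * w
  joined <- left_join(
    sites,
    select(windows, "chrom", win_start = "start", "gc_skew_plus",
           "gc_fraction", "skew_defined"),
    by = c("chrom", "win_start")
  )
  no_window <- is.na(joined$skew_defined)
  undef <- !no_window & !joined$skew_defined
  keep <- !no_window & joined$skew_defined
  kept <- joined[keep, ]
  counts <- tibble(facet_strand = character(), skew_bin = integer(),
                   gc_bin = integer(), skew_mid = numeric(),
                   gc_mid = numeric(), n_sites = integer())
  if (nrow(kept) > 0) {
    skew <- ifelse(kept$strand == "-", -kept$gc_skew_plus,
                   kept$gc_skew_plus)
    counts <- tibble(
      facet_strand = kept$strand,
      skew_bin = bin_index(skew, -1, 1, skew_bin_width),
      gc_bin = bin_index(kept$gc_fraction, 0, 1, gc_bin_width)
    ) |>
      count(.data$facet_strand, .data$skew_bin, .data$gc_bin,
            name = "n_sites") |>
      mutate(skew_mid = -1 + (.data$skew_bin - 0.5) * skew_bin_width,
             gc_mid = (.data$gc_bin - 0.5) * gc_bin_width)
  }
  list(
    counts = counts,
    excluded = tibble(reason = c("no_window", "undefined_skew"),
                      n = c(sum(no_window), sum(undef)))
  )
}
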