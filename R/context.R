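# Positional nucleotide context around m5C sites.

#' Positional nucleotide frequencies around sites
#'
#' Extracts the `2 * flank_k + 1` bases centred on each site, read 5'->3'
#' on the site's strand (reverse-complemented for `-` strand sites, so
#' offset 0 is the site's cytosine), and tallies per-offset base counts.
#' Sites too close to a chromosome end or whose window contains `N` are
#' excluded and counted.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param sites Tibble with `chrom`, `pos` (0-based), `strand`.
#' @param flank_k Flank extent in bp (>= 1); default 10.
#' @return Tibble of class `m5c_context` with `offset` (-k..k),
#'   `count_A`/`count_C`/`count_G`/`count_T`, the corresponding `freq_*`
#'   columns, and `n` (contributing sites). Attributes `n_sites`,
#'   `n_excluded_bounds`, `n_excluded_n` record input and exclusion
#'   counts.
#' @export
extract_contexts <- function(genome, sites, flank_k = 10L) {
  if (flank_k < 1) abort("flank_k must be >= 1")
  k <- as.integer(flank_k)
  sites <- as_tibble(sites)
  len <- nchar(genome)[sites$chrom]
  if (anyNA(len)) {
    abort(paste0("site chromosome absent from genome: ",
                 sites$chrom[which(is.na(len))[1]]))
  }
  in_bounds <- sites$pos >= k & sites$pos + k < len
  n_oob <- sum(!in_bounds)
  s <- sites[in_bounds, ]
  ctx <- if (nrow(s) == 0) character(0) else
    mapply(function(cn, p) substr(genome[[cn]], p - k + 1L, p + k + 1L),
           s$chrom, s$pos, USE.NAMES = FALSE)
  neg <- s$strand == "-"
  if (any(neg)) ctx[neg] <- revcomp(ctx[neg])
  has_n <- grepl("N", ctx, fixed = TRUE)
  n_with_n <- sum(has_n)
  ctx <- ctx[!has_n]

  offsets <- -k:k
  if (length(ctx) == 0) {
    counts <- matrix(0L, nrow = length(offsets), ncol = 4,
                     dimnames = list(NULL, BASES))
  } else {
    chars <- matrix(unlist(strsplit(ctx, ""), use.names = FALSE),
                    nrow = length(ctx), byrow = TRUE)
    counts <- t(apply(chars, 2, function(col) {
      tabulate(factor(col, levels = BASES), nbins = 4)
    }))
    colnames(counts) <- BASES
  }
  n_inc <- length(ctx)
  out <- tibble(
    offset = offsets,
    count_A = counts[, "A"], count_C = counts[, "C"],
    count_G = counts[, "G"], count_T = counts[, "T"],
    n = n_inc
  )
  for (b in BASES) {
    out[[paste0("freq_", b)]] <- if (n_inc > 0) out[[paste0("count_", b)]] /
      n_inc else NA_real_
  }
  class(out) <- c("m5c_context", class(out))
  attr(out, "n_sites") <- nrow(sites)
  attr(out, "n_excluded_bounds") <- n_oob
  attr(out, "n_excluded_n") <- n_with_n
  out
}

#' Compare sequence contexts of the most and least methylated sites
#'
#' Takes the plus-strand called sites, selects the top and bottom
#' `quantile` by methylation fraction (top ranked as in
#' [rank_top_fraction()]; bottom by the mirrored ordering so the two sets
#' are disjoint), and returns their positional context profiles.
#'
#' @param calls [call_sites()] output (a `status` column marks called
#'   sites).
#' @param genome Named character vector of chromosome sequences.
#' @param flank_k Flank extent in bp.
#' @param quantile Fraction in `(0, 0.5]` taken from each end.
#' @return List with `top` and `bottom` (`m5c_context` tibbles), `n_top`,
#'   `n_bottom`, and the selected `top_sites` / `bottom_sites`.
#' @export
compare_top_bottom_contexts <- function(calls, genome, flank_k = 10L,
                                        quantile = 0.25) {
  if (quantile <= 0 || quantile > 0.5) {
    abort("quantile must lie in (0, 0.5]")
  }
  plus <- filter(calls, .data$status == "called", .data$strand == "+")
  if (nrow(plus) < 2) {
    abort("fewer than 2 called plus-strand sites")
  }
  n_take <- ceiling(quantile * nrow(plus))
  top <- head(arrange(plus, desc(.data$meth_fraction),
                      desc(.data$coverage), .data$chrom, .data$pos), n_take)
  bottom <- head(arrange(plus, .data$meth_fraction, .data$coverage,
                         desc(.data$chrom), desc(.data$pos)), n_take)
  list(top = extract_contexts(genome, top, flank_k),
       bottom = extract_contexts(genome, bottom, flank_k),
       n_top = nrow(top), n_bottom = nrow(bottom),
       top_sites = select(top, "chrom", "pos", "strand", "meth_fraction"),
       bottom_sites = select(bottom, "chrom", "pos", "strand",
                             "meth_fraction"))
}
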