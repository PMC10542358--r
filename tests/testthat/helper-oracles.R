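# Independent brute-force oracles and random-instance generators used to
# cross-check the package's vectorised/library-backed implementations.

# O(n*m) all-pairs point-in-interval check
oracle_in_peak <- function(sites, peaks) {
  vapply(seq_len(nrow(sites)), function(i) {
    any(peaks$chrom == sites$chrom[i] &
          peaks$start <= sites$pos[i] &
          sites$pos[i] < peaks$end)
  }, logical(1))
}

# O(n*m) subtraction: drop untreated peaks whose summed intersection with
# rnaseh peaks covers >= frac of their length
oracle_subtract <- function(untreated, rnaseh, frac) {
  keep <- vapply(seq_len(nrow(untreated)), function(i) {
    s <- untreated$start[i]; e <- untreated$end[i]
    on_chrom <- rnaseh[rnaseh$chrom == untreated$chrom[i], , drop = FALSE]
    ov <- 0
    for (j in seq_len(nrow(on_chrom))) {
      ov <- ov + max(0, min(e, on_chrom$end[j]) - max(s, on_chrom$start[j]))
    }
    ov / (e - s) < frac
  }, logical(1))
  untreated[keep, ]
}

# per-window character counting by strsplit, no shared code with
# windowed_gc_stats
oracle_window_stats <- function(seq, w) {
  n_win <- nchar(seq) %/% w
  res <- lapply(seq_len(n_win), function(i) {
    chars <- strsplit(substr(seq, (i - 1) * w + 1, i * w), "")[[1]]
    g <- sum(chars == "G"); c_ <- sum(chars == "C"); n_n <- sum(chars == "N")
    defined <- (g + c_) > 0 && n_n == 0
    list(start = (i - 1) * w,
         skew = if (defined) (g - c_) / (g + c_) else NA_real_,
         gc = (g + c_) / w, defined = defined)
  })
  data.frame(start = vapply(res, `[[`, numeric(1), "start"),
             skew = vapply(res, `[[`, numeric(1), "skew"),
             gc = vapply(res, `[[`, numeric(1), "gc"),
             defined = vapply(res, `[[`, logical(1), "defined"))
}

# two-sided Fisher p by direct hypergeometric enumeration with choose()
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  ks <- max(0, c1 - r2):min(r1, c1)
  pk <- choose(r1, ks) * choose(r2, c1 - ks) / choose(n, c1)
  p_obs <- choose(r1, a) * choose(r2, c) / choose(n, c1)
  sum(pk[pk <= p_obs * (1 + 1e-7)])
}

# exact binomial upper tail by direct summation
oracle_binom_tail <- function(u, n, eps) {
  if (u <= 0) return(1)
  sum(dbinom(u:n, n, eps))
}

random_intervals <- function(n, chroms = c("chr1", "chr2"),
                             max_pos = 10000L, max_len = 500L) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  len <- sample.int(max_len, n, replace = TRUE)
  tibble::tibble(
    chrom = sample(chroms, n, replace = TRUE),
    start = start, end = start + len,
    name = paste0("iv", seq_len(n)),
    score = sample(0:1000, n, replace = TRUE),
    strand = sample(c("+", "-", "."), n, replace = TRUE)
  )
}

random_genome <- function(len, gc = 0.5, chrom = "chr1") {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  stats::setNames(
    paste(sample(names(p), len, replace = TRUE, prob = p), collapse = ""),
    chrom)
}
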