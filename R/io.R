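#' Read a genome FASTA into a named character vector
#'
#' Loads a (wrapped or unwrapped) FASTA file and returns one uppercase
#' sequence per chromosome, in file order. Only `A`, `C`, `G`, `T`, `N`
#' (either case) are accepted; ambiguity codes are rejected because every
#' downstream statistic (GC skew, GC fraction, sequence contexts) assumes an
#' unambiguous alphabet.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector; names are chromosome names (first word of
#'   each header), values are uppercase sequences.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "acgtACGT"), fa)
#' read_genome_fasta(fa)
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("FASTA file not found: ", path))
  }
  seqs <- Biostrings::readBStringSet(path)
  nm <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1L)
  if (anyNA(nm) || any(!nzchar(nm))) {
    abort("FASTA contains a record with an empty header")
  }
  if (anyDuplicated(nm)) {
    abort(paste0(
      "duplicate chromosome name in FASTA: ",
      paste(unique(nm[duplicated(nm)]), collapse = ", ")
    ))
  }
  out <- toupper(as.character(seqs))
  bad <- gsub("[ACGTN]", "", out)
  if (any(nzchar(bad))) {
    i <- which(nzchar(bad))[1]
    abort(paste0(
      "chromosome '", nm[i], "' contains characters outside {A,C,G,T,N}: ",
      paste(unique(strsplit(bad[i], "")[[1]]), collapse = "")
    ))
  }
  setNames(out, nm)
}

#' Validate an interval tibble
#'
#' Intervals are plain tibbles with columns `chrom`, `start`, `end`, `name`,
#' `score`, `strand` in 0-based half-open coordinates, the convention used
#' throughout the package (and by BED).
#'
#' @param x A data frame of intervals.
#' @param genome Optional genome (named character vector); when given, every
#'   interval must fit inside its chromosome.
#' @return `x` as a tibble, invisibly validated.
#' @export
validate_intervals <- function(x, genome = NULL) {
  x <- as_tibble(x)
  required <- c("chrom", "start", "end")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("interval table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"name" %in% names(x)) x$name <- "."
  if (!"score" %in% names(x)) x$score <- 0
  if (!"strand" %in% names(x)) x$strand <- "."
  if (any(!nzchar(x$chrom) | is.na(x$chrom))) {
    abort("interval with empty chromosome name")
  }
  if (any(x$start != trunc(x$start)) || any(x$end != trunc(x$end))) {
    abort("interval coordinates must be integers")
  }
  if (any(x$start < 0)) abort("interval with negative start")
  if (any(x$start >= x$end)) {
    i <- which(x$start >= x$end)[1]
    abort(paste0("empty or inverted interval: ", x$chrom[i], ":",
                 x$start[i], "-", x$end[i]))
  }
  if (any(!x$strand %in% c("+", "-", "."))) {
    abort("interval strand must be one of '+', '-', '.'")
  }
  if (!is.null(genome)) {
    len <- nchar(genome)[x$chrom]
    if (anyNA(len)) {
      abort(paste0("interval chromosome absent from genome: ",
                   x$chrom[which(is.na(len))[1]]))
    }
    if (any(x$end > len)) {
      i <- which(x$end > len)[1]
      abort(paste0("interval beyond chromosome end: ", x$chrom[i], ":",
                   x$start[i], "-", x$end[i]))
    }
  }
  select(x, "chrom", "start", "end", "name", "score", "strand")
}

#' Read a BED3/BED6 file into an interval tibble
#'
#' @param path Path to a tab-separated BED3 or BED6 file.
#' @return Tibble with columns `chrom`, `start` (0-based), `end` (exclusive),
#'   `name`, `score`, `strand` (`"."` when the file is BED3), rows in file
#'   order.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) abort(paste0("BED file not found: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  name = character(), score = numeric(), strand = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    abort(paste0("BED line ", which(nf < 3)[1], " has fewer than 3 columns"))
  }
  get_col <- function(i, default) {
    vapply(fields, function(f) if (length(f) >= i) f[i] else default,
           character(1))
  }
  start_chr <- get_col(2L, NA_character_)
  end_chr <- get_col(3L, NA_character_)
  if (any(!grepl("^[0-9]+$", start_chr)) || any(!grepl("^[0-9]+$", end_chr))) {
    abort("BED coordinates must be non-negative integers")
  }
  out <- tibble(
    chrom = get_col(1L, NA_character_),
    start = as.integer(start_chr),
    end = as.integer(end_chr),
    name = get_col(4L, "."),
    score = suppressWarnings(as.numeric(get_col(5L, "0"))),
    strand = get_col(6L, ".")
  )
  out$score[is.na(out$score)] <- 0
  validate_intervals(out)
}

#' Write an interval tibble as BED6
#'
#' Round-trips with [read_bed()] field-for-field.
#'
#' @param intervals Interval tibble (see [validate_intervals()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  intervals <- validate_intervals(intervals)
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s",
                   intervals$chrom, as.integer(intervals$start),
                   as.integer(intervals$end), intervals$name,
                   format(intervals$score, trim = TRUE, scientific = FALSE),
                   intervals$strand)
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(lines) > 0) writeLines(lines, con)
  invisible(path)
}

# interval tibble -> GRanges (shifts to 1-based closed for IRanges)
as_granges <- function(x) {
  x <- validate_intervals(x)
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = ifelse(x$strand == ".", "*", x$strand)
  )
}

#' Write a tibble as TSV with a commented key=value header
#'
#' All tabular pipeline outputs use this format: lines beginning `#` record
#' the parameters that produced the table, then a header row and the data.
#'
#' @param x Data frame to write.
#' @param path Output path.
#' @param header Named list/vector written as `#key=value` lines.
#' @return `path`, invisibly.
#' @export
write_tsv_commented <- function(x, path, header = list()) {
  con <- file(path, open = "wb")
  if (length(header) > 0) {
    writeLines(paste0("#", names(header), "=",
                      vapply(header, format_config_value, character(1))), con)
  }
  close(con)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a TSV written by [write_tsv_commented()]
#'
#' @param path Path to the TSV.
#' @return Tibble (comment lines skipped).
#' @export
read_tsv_commented <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}
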