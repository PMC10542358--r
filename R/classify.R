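# TRDMT1 dependence and damage-induction classification from WT vs KO
# (and +/- damage) methylation fold changes.

# pseudocount-adjusted fold between two (unconverted, coverage) pairs:
# ((u1 + c)/(n1 + 2c)) / ((u2 + c)/(n2 + 2c))
pseudo_fold <- function(u1, n1, u2, n2, pseudocount) {
  f1 <- (u1 + pseudocount) / (n1 + 2 * pseudocount)
  f2 <- (u2 + pseudocount) / (n2 + 2 * pseudocount)
  f1 / f2
}

#' Classify called sites as TRDMT1-dependent or -independent
#'
#' A site detected in wild-type cells is TRDMT1-dependent when its WT
#' methylation is at least `fold_threshold` times its knockout methylation
#' (pseudocount-adjusted to keep the fold finite at zero KO counts);
#' otherwise it is independent. Sites called in WT but with no KO coverage
#' are `unclassifiable`. Both inputs must come from the same damage
#' condition.
#'
#' @param wt_calls,ko_calls [call_sites()] outputs for wild-type and
#'   TRDMT1-knockout in the matching damage condition.
#' @param fold_threshold Minimum WT/KO fold for dependence (default 2).
#' @param pseudocount_reads Pseudocount in reads (default 0.5).
#' @return Tibble with one row per WT-called site: `chrom`, `pos`,
#'   `strand`, `wt_meth`, `ko_meth`, `fold`, `label`
#'   (`TRDMT1-dependent` / `TRDMT1-independent` / `unclassifiable`).
#'   Sites called in KO but not in WT fall outside these classes; they are
#'   kept visible for audit in the `ko_only_sites` attribute rather than
#'   mixed into the classification.
#' @export
classify_dependence <- function(wt_calls, ko_calls, fold_threshold = 2,
                                pseudocount_reads = 0.5) {
  wt <- filter(wt_calls, .data$status == "called")
  ko <- select(ko_calls, "chrom", "pos",
               ko_coverage = "coverage", ko_unconverted = "n_unconverted",
               ko_meth = "meth_fraction")
  joined <- left_join(wt, ko, by = c("chrom", "pos"))
  joined$ko_coverage[is.na(joined$ko_coverage)] <- 0L
  joined$ko_unconverted[is.na(joined$ko_unconverted)] <- 0L
  has_ko <- joined$ko_coverage > 0
  fold <- pseudo_fold(joined$n_unconverted, joined$coverage,
                      joined$ko_unconverted, joined$ko_coverage,
                      pseudocount_reads)
  label <- ifelse(!has_ko, "unclassifiable",
                  ifelse(fold >= fold_threshold, "TRDMT1-dependent",
                         "TRDMT1-independent"))
  out <- tibble(chrom = joined$chrom, pos = joined$pos,
                strand = joined$strand,
                wt_meth = joined$meth_fraction,
                ko_meth = ifelse(has_ko, joined$ko_meth, NA_real_),
                fold = ifelse(has_ko, fold, NA_real_),
                label = label)
  ko_only <- anti_join(filter(ko_calls, .data$status == "called"),
                       select(wt, "chrom", "pos"), by = c("chrom", "pos"))
  attr(out, "ko_only_sites") <- select(ko_only, "chrom", "pos", "strand",
                                       "coverage", "meth_fraction")
  out
}

#' Flag damage-induced sites from the +/- damage comparison
#'
#' Within one genotype, a site is damage-induced when its +damage
#' methylation is at least `fold_threshold` times its -damage methylation,
#' using the same pseudocount-adjusted fold as [classify_dependence()].
#' Sites with no -damage coverage are left unclassified (`NA` flag).
#'
#' @param calls_minus,calls_plus [call_sites()] outputs for the undamaged
#'   and damaged condition of the same genotype.
#' @param fold_threshold Minimum +damage/-damage fold (default 2).
#' @param pseudocount_reads Pseudocount in reads (default 0.5).
#' @return Tibble with one row per +damage-called site: site identity,
#'   `meth_plus`, `meth_minus`, `fold_damage`, `damage_induced` (logical,
#'   `NA` when unclassifiable).
#' @export
classify_damage_induction <- function(calls_minus, calls_plus,
                                      fold_threshold = 2,
                                      pseudocount_reads = 0.5) {
  plus <- filter(calls_plus, .data$status == "called")
  minus <- select(calls_minus, "chrom", "pos",
                  minus_coverage = "coverage",
                  minus_unconverted = "n_unconverted",
                  meth_minus = "meth_fraction")
  joined <- left_join(plus, minus, by = c("chrom", "pos"))
  joined$minus_coverage[is.na(joined$minus_coverage)] <- 0L
  joined$minus_unconverted[is.na(joined$minus_unconverted)] <- 0L
  has_minus <- joined$minus_coverage > 0
  fold <- pseudo_fold(joined$n_unconverted, joined$coverage,
                      joined$minus_unconverted, joined$minus_coverage,
                      pseudocount_reads)
  tibble(chrom = joined$chrom, pos = joined$pos, strand = joined$strand,
         meth_plus = joined$meth_fraction,
         meth_minus = ifelse(has_minus, joined$meth_minus, NA_real_),
         fold_damage = ifelse(has_minus, fold, NA_real_),
         damage_induced = ifelse(has_minus, fold >= fold_threshold, NA))
}

#' Count sites per dependence class
#'
#' @param dependence_calls Output of [classify_dependence()], optionally
#'   carrying a `condition` column.
#' @return Tibble of counts per `label` (and `condition` when present),
#'   including zero rows for absent labels; counts sum to the input rows.
#' @export
summarize_site_classes <- function(dependence_calls) {
  labels <- c("TRDMT1-dependent", "TRDMT1-independent", "unclassifiable")
  if ("condition" %in% names(dependence_calls)) {
    out <- count(dependence_calls, .data$condition, .data$label,
                 name = "n_sites")
    out <- tidyr::complete(out, condition = unique(dependence_calls$condition),
                           label = labels,
                           fill = list(n_sites = 0L))
  } else {
    out <- count(dependence_calls, .data$label, name = "n_sites")
    out <- tidyr::complete(out, label = labels, fill = list(n_sites = 0L))
  }
  arrange(out, dplyr::across(dplyr::any_of(c("condition", "label"))))
}
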