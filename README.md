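# rloopm5c

Where does TRDMT1 (DNMT2) put 5-methylcytosine on RNA, and do those sites
live in R-loops? `rloopm5c` is an R package for analysts working with RNA
bisulfite sequencing and DRIP-seq style data who want to answer that
question with a fully reproducible, testable pipeline — and for anyone who
needs its building blocks: spike-in-calibrated m5C calling,
wild-type-vs-knockout dependence classification, RNaseH-filtered R-loop
peak overlap enrichment, and strand-aware GC-skew analysis.

## The statistics at the core

* **Non-conversion calibration.** The spike-in RNA is unmethylated, so its
  unconverted reads measure the bisulfite error:
  ε̂ = Σuᵢ/Σnᵢ with an exact 95% CI.
* **m5C calling.** Per cytosine with coverage *n* and unconverted count
  *u*, a one-sided exact binomial test *p* = P(X ≥ u | n, ε̂), BH-corrected
  across sites; called iff *q* < α and *n* ≥ 10. "Best" sites have
  coverage > 25 reads and methylation > 10% (strict), and the best-10%
  subset ranks called sites by methylation fraction.
* **TRDMT1 dependence.** A WT-called site is dependent when
  ((u₍wt₎+c)/(n₍wt₎+2c)) / ((u₍ko₎+c)/(n₍ko₎+2c)) ≥ 2 with pseudocount
  c = 0.5 reads, within the matching damage condition; the same fold rule
  on the WT ±damage pair flags damage induction.
* **R-loop overlap.** Untreated DRIP peaks covered ≥ 50% of their length
  by RNaseH-condition peaks are removed as artifacts; a site is "in an
  R-loop" when it falls inside a surviving peak. Class-vs-background
  enrichment is the 2×2 sample odds ratio with a two-sided Fisher exact
  p-value, the background being well-covered never-called cytosines with
  methylation ≤ 2ε̂.
* **Sequence composition.** GC skew (G−C)/(G+C) and GC fraction on 50-bp
  windows, expressed on the transcribed strand; observed (R-loop) vs
  expected (remainder of the genome) ratio grids faceted by transcribing
  strand; positional base frequencies around sites.

A synthetic-data generator (`sim_params()` / `simulate_dataset()`) emits a
genome, stranded transcripts, G-skewed R-loop regions, planted
dependent/independent m5C sites, four-condition bisulfite count tables,
spike-in counts, and DRIP peak sets ± RNaseH — with a truth table, so every
claim the pipeline makes can be checked against a known answer.

## Worked example

```r
library(rloopm5c)
library(dplyr)

ds <- simulate_dataset(sim_params(seed = 1))

eps <- estimate_nonconversion(ds$spikein)
eps
#> # A tibble: 1 × 6
#>      rate conf_low conf_high n_unconverted coverage n_positions
#> 1 0.00500  0.00366   0.00666            46     9203           5

calls <- lapply(ds$counts, call_sites, nonconversion_rate = eps$rate)
dep <- classify_dependence(calls$WT_plus, calls$KO_plus)
summarize_site_classes(dep)
#>   label              n_sites
#> 1 TRDMT1-dependent       213
#> 2 TRDMT1-independent     191
#> 3 unclassifiable           0

peaks <- subtract_rnaseh(ds$drip_untreated, ds$drip_rnaseh, 0.5)
bg    <- background_c_sites(calls, eps$rate)
dep_sites <- filter(dep, label == "TRDMT1-dependent")
best10 <- rank_top_fraction(
  inner_join(calls$WT_plus, dep_sites[c("chrom", "pos")],
             by = c("chrom", "pos")), 0.10)
overlap_enrichment(best10, bg, peaks,
                   class_label = "best10_dependent",
                   background_label = "unmethylated_C")
#> R-loop overlap enrichment
#>   set              n_total n_in_rloop fraction_in_rloop
#> 1 best10_dependent      22         20            0.909
#> 2 unmethylated_C      7723        523            0.0677
#> odds ratio = 137.7, Fisher two-sided p = 1.2e-21
```

Reading the output: the estimated non-conversion rate (0.5%) matches the
simulated error; of the 404 WT-called sites, 213 classify as
TRDMT1-dependent (200 were planted, the remainder are borderline calls);
and the best-10% dependent sites sit in RNaseH-sensitive DRIP peaks far
more often (91%) than background unmethylated cytosines (6.8%), with a
Fisher p-value of ~10⁻²¹ — the planted co-localization recovered end to
end.

One call runs everything and writes all tabular outputs, a resolved
config, and an audit log:

```r
res <- run_pipeline(pipeline_config(seed = 1), out_dir = "results/run1")
autoplot(res$grid)                     # obs/exp grid, red = enriched
plot_context_comparison(res$contexts)  # G-frequency decay around sites
```

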