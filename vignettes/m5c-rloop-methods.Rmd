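---
title: "Methods: calling TRDMT1-dependent RNA m5C and measuring R-loop enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calling TRDMT1-dependent RNA m5C and measuring R-loop enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rloopm5c)
library(dplyr)
```

## The scientific question

TRDMT1 (DNMT2) writes 5-methylcytosine (m5C) on RNA, and this activity is
stimulated by DNA damage. Because G-rich nascent RNA hybridizes stably with
its C-rich template DNA strand, R-loops form preferentially where the sense
strand is G-rich, and m5C deposited on the RNA moiety of R-loops should
therefore live in a characteristic sequence environment: G-biased around the
site, high GC content, positive sense-strand GC skew. This package
implements the complete computational chain needed to test that picture on
bisulfite-sequencing and DRIP-seq style inputs:

1. estimate the bisulfite non-conversion error from an unmethylated
   spike-in;
2. call m5C sites per condition (wild-type and TRDMT1 knockout, each with
   and without oxidative damage) from per-cytosine count tables;
3. classify called sites as TRDMT1-dependent or -independent from the
   WT/KO methylation fold, and flag damage induction from the +/- damage
   fold;
4. derive the high-confidence (RNaseH-sensitive) R-loop peak set and
   measure overlap enrichment of site classes against an unmethylated-C
   background;
5. compute windowed GC skew / GC fraction, strand-faceted
   observed-vs-expected grids, and positional base-context profiles.

Because the real sequencing data are external, the package ships a
synthetic-data generator that emulates all of the above with a known truth
table; every stage is exercised and validated against that truth.

## Models and procedures

### Non-conversion and site calling

Bisulfite converts unmethylated C to U (read as T); m5C resists
conversion. An unmethylated cytosine therefore yields an unconverted read
with a small error probability $\varepsilon$ (the non-conversion rate),
estimated by pooling the cytosine positions of the spike-in RNA, which
carries no methylation by construction:
$\hat\varepsilon = \sum u_i / \sum n_i$ with an exact Clopper–Pearson 95%
interval. The spike-in is added at a 1:40000 mass ratio in the wet
protocol; computationally this only means spike-in coverage is a free
parameter, and per-base counts are consumed directly.

At a site with coverage $n$ and unconverted count $u$, methylation is
tested with the one-sided exact binomial tail
$p = P(X \ge u \mid n, \varepsilon)$, and Benjamini–Hochberg correction is
applied across all tested sites; a site is *called* when $q < \alpha$
(default 0.05) and $n \ge$ `min_call_coverage` (default 10). Low-coverage
sites are reported as `untested` rather than dropped, because the
unmethylated background set needs them visible. A methylated site at true
level $m$ produces unconverted reads with probability
$m + (1 - m)\varepsilon$; the same composition is used by the simulator,
so calling and simulation share the error model but not the code path.

Two derived selections follow the study's stated cut-offs exactly, as
strict inequalities: *best* sites have coverage $> 25$ reads and
methylation fraction $> 10\%$, and the *best 10%* subset takes the
$\lceil 0.1 N \rceil$ called sites with the highest methylation fraction,
ties broken by higher coverage, then by (chrom, pos). The $>10\%$ rule is
applied only to best-site selection, not at calling time; calling has its
own statistical filter and conflating the two would silently discard
genuine low-level sites from the class counts.

### Dependence and damage induction

A WT-called site is *TRDMT1-dependent* when its WT methylation is at least
two-fold its KO methylation, computed on pseudocount-adjusted fractions

$$\mathrm{fold} = \frac{(u_{wt} + c)/(n_{wt} + 2c)}{(u_{ko} + c)/(n_{ko} + 2c)},
\qquad c = 0.5 \text{ reads},$$

so that a KO count of zero still yields a finite fold. Sites with no KO
coverage at all are `unclassifiable`. The comparison is made within the
matching damage condition (+damage WT vs +damage KO), mirroring the
four-sample design; damage induction uses the identical fold rule on the
WT +/- damage pair. No significance test is attached to the fold — the
rule is deliberately the simple two-fold criterion, with the threshold and
pseudocount exposed as configuration.

### R-loop peaks and overlap enrichment

RNaseH destroys genuine DNA:RNA hybrids, so DRIP peaks that persist after
RNaseH treatment are artifacts. "Present in the RNaseH condition" is made
precise as: an untreated peak is removed when the summed length of its
intersections with RNaseH-condition peaks covers at least
`removal_overlap_frac` (default 0.5) of its own length. The default is a
deliberate middle ground — any-overlap removal is available by setting the
fraction near 0 — and the filter is idempotent and always returns a subset
of its input.

A site is *in an R-loop* when its position falls inside a retained peak
(0-based half-open containment, strand-ignored since DRIP peaks are
unstranded). Enrichment of a site class against the background uses the
2×2 table (class/background × in/out), the sample odds ratio with Haldane
0.5-correction when a cell is zero, and a two-sided Fisher exact p-value.
The *unmethylated-C background* is defined here — the source analyses use
the notion without a definition — as cytosines with coverage above the
best-site floor, methylation fraction at most $2\hat\varepsilon$, called
in no condition; both knobs are configuration keys.

### GC skew, grids, and contexts

GC skew $= (G - C)/(G + C)$ and GC fraction $= (G + C)/w$ are computed on
non-overlapping windows of $w = 50$ bp tiled from coordinate 0 (the
terminal partial window is dropped; the step is configurable). Windows
with no G/C, or containing `N`, carry an undefined-skew flag and are
excluded from skew statistics — exclusion avoids biasing skew with an
arbitrary convention for empty denominators. Skew is computed on the
reference strand and sign-flipped for windows assigned to minus-strand
transcripts (assignment by largest overlap), so a positive value always
means G-rich on the transcribed strand; intergenic windows form their own
facet.

The observed-vs-expected grid bins windows on (skew, GC fraction) with
default widths 0.1 and 0.05. Per transcribing-strand facet, *observed* is
the facet's R-loop windows and *expected* is "the remainder of the
genome" read literally: every defined-skew non-R-loop window genome-wide,
intergenic included, each in its own facet orientation. Cells with no
expected mass are flagged `NA` rather than smoothed (pseudocount 0 by
default). Ratios above 1 mean R-loops are over-represented at that
sequence composition; `autoplot()` renders log2 ratios red/blue.

Context profiles take the $2k + 1$ bases centred on each site
($k = 10$ by default, enough to see the planted decay), read 5'→3' on the
site's strand, with N-containing or boundary-clipped windows excluded and
counted. The top-vs-bottom comparison contrasts the most and least
methylated quartiles of plus-strand called sites; the bottom ranking
mirrors the top ranking (ascending methylation, ascending coverage,
descending position) so the two selections are disjoint even under
complete ties.

## What the synthetic data emulate

`sim_params()` defaults encode the study conditions the package is
validated under:

| parameter | default | meaning |
|---|---|---|
| `genome_length`, `n_chrom` | 100 kb, 2 | desk-scale genome |
| `gc_background` | 0.45 | mammalian-like background GC |
| `n_transcripts` × `transcript_length` | 25 × 2 kb | ~half the genome transcribed |
| `n_rloops` × `rloop_length` | 20 × 250 bp | ~10% of transcript territory |
| `rloop_gc`, `rloop_skew` | 0.6, +0.4 | GC-rich, strongly G-skewed sense strand |
| `n_dependent`, `n_independent` | 200, 200 | planted m5C sites |
| `coloc_prob` | 0.8 | dependent-site co-localization with R-loops |
| `level_basal` / `level_induced` / `level_independent` | 0.02 / 0.30 / 0.20 | true methylation levels |
| `coverage_mean`, `coverage_dispersion` | 50, 0.1 | negative-binomial coverage |
| `nonconversion_rate` | 0.005 | typical bisulfite error |

The sources report only qualitative "basal" versus induced methylation;
the numeric levels above are declared defaults chosen to be realistic for
bisulfite data (induced sites clearly detectable at coverage 50, basal
level near the detection floor), not inferred values. Dependent sites are
placed inside R-loop regions with probability `coloc_prob` and otherwise
uniformly over transcript sense-strand cytosines; their flanks within
±5 bp are resampled at G probability 0.6 to plant the G-rich context.
Coverage is negative-binomial with dispersion 0.1 (Var = μ + 0.1 μ²), a
mild overdispersion typical of count data; dispersion 0 gives the Poisson
limit. Unconverted counts compose the true level with the non-conversion
rate as $m + (1-m)\varepsilon$.

DRIP peaks are emulated as the R-loop regions with ±10 bp boundary jitter
plus RNaseH-insensitive artifact peaks placed away from R-loops; the
RNaseH-treated set contains exactly the artifacts, so subtraction has a
known answer.

What the generator deliberately does **not** model: read-level alignment
or its errors, RNA secondary-structure effects on conversion (heat
denaturation is assumed fully effective), sequence-context-dependent
non-conversion, transcript expression gradients, and overlapping genes.
Passing tests therefore demonstrate correctness of the analysis logic
under the declared error model, not robustness to alignment artifacts or
structure-driven conversion failures in real libraries.

Two generator interactions are worth knowing. Planted sites keep a
minimum spacing of $2 \cdot \texttt{context\_flank} + 1$ bp so one site's
flank resampling can never overwrite another site's cytosine; at high
site densities this spacing slightly depresses how often later-placed
sites land inside already crowded R-loop regions. And because G-rich
flanks are planted around dependent sites that co-localize with R-loops,
R-loop windows acquire extra G-bias beyond `rloop_skew` itself; a
composition null therefore sets `rloop_gc` to background, `rloop_skew` to
0 *and* `n_dependent` to 0, which is how the package's null checks
construct "observed windows drawn from the same distribution as the
rest".

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open everywhere, including count-table
  positions and all BED I/O; nothing reinterprets them.
* Exact binomial tails come from `pbinom`; at $\varepsilon = 0$ any
  unconverted read gives $p = 0$ exactly.
* Fisher p-values come from `fisher.test`; the reported odds ratio is the
  sample odds ratio (not the conditional MLE), Haldane-corrected only
  when a zero cell forces it.
* Grid bin widths must divide their ranges evenly; the boundary value
  (skew 1, GC 1) closes into the last bin.
* Empty peak sets, zero-coverage sites, windows of pure A/T, and sites at
  chromosome ends are all flagged or routed to explicit excluded buckets
  rather than producing NaN arithmetic.
* Null-grid calibration bands are simultaneous (Bonferroni-adjusted exact
  binomial) 99% bands across defined cells; per-cell unadjusted bands
  would be violated somewhere by chance in almost every realisation.

## Problem sizes

The shipped validation suite runs the full chain on 100-kb genomes
(2,000 windows of 50 bp, ~11,000 transcript cytosines per condition, 400
planted sites), oracle cross-checks on hundreds of random interval
instances of up to 500 intervals, and calibration/power/recovery
simulations of 1,000–5,000 sites per design point — sizes at which every
statistical bound in the tests is comfortably inside its sampling noise
while the whole suite stays fast on a single CPU.

## Known limitations

* The dependence rule is the study's two-fold criterion; it attaches no
  uncertainty to the fold, so sites near the threshold flip between
  labels under resampling. A shrinkage or test-based classifier would be
  a natural extension but would no longer be the published rule.
* The expected pool of the enrichment grid includes transcribed
  non-R-loop windows and intergenic windows alike ("remainder of the
  genome" read literally); restricting the expected set to transcribed
  windows is possible by filtering the windows table before
  `build_obs_exp_grid()` but is not the default.
* Site-level containment treats a peak hit as binary; distance-to-peak
  gradients are out of scope.
* The generator plants fixed per-class methylation levels rather than a
  continuous distribution, which makes class recovery sharper than real
  data would be; the calibration tests quantify error rates only under
  that model.
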