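# tidyatac

Differential chromatin-accessibility analysis for ATAC-seq, with a tidy
interface. The package targets the common immunology/epigenomics design in
which a reference cell state (e.g. naive CD8+ T cells) is compared against
two stimulated states (cytokine-primed, antigen-stimulated): which
regulatory regions open or close under each stimulus, how large each
response is, and how much the two responses overlap.

It implements the whole desk-side pipeline on fragment-level input:

* **QC** — fragment-length histograms with nucleosome-band mode detection
  (nucleosome-free / mono- / di-nucleosome), and TSS enrichment scores from
  cut-site profiles.
* **Peak atlas** — per-condition peak calls are concatenated and
  iteratively merged whenever two intervals overlap reciprocally by ≥ 75%
  of both lengths (union span, to a true fixpoint), giving one
  non-redundant coordinate system; fragments are then counted over atlas
  peaks.
* **Differential accessibility** — median-of-ratios size factors,
  method-of-moments negative-binomial dispersion with a 1/mean trend, and
  a regularized (shrunken) log2 transform:
  `rlog = mu + c * beta` with `c = sigma2 / (sigma2 + w)`, where `beta` is
  the deviation of `log2(n + 0.5)` from the peak mean, `w` its
  delta-method sampling variance `(1/ln2)^2 (1/(n+0.5) + alpha)`, and
  `sigma2` a quantile-matched prior `(q95(|beta|)/1.645)^2`. Peaks are
  classified **opening** / **closing** / **unchanged** at
  `|rlogFC| >= log2(1.5)`, and cross-condition overlap of the differential
  sets is summarized with integer percentages. Sample-level PCA and seeded
  random peak-set splitting round out the stage.
* **Annotation & enrichment** — nearest-TSS assignment with a signed
  (upstream-negative) distance; hypergeometric gene-set
  overrepresentation and ZOOPS motif enrichment (log2-odds PWM scanning on
  both strands) with Benjamini–Hochberg FDR.
* **Synthetic data** — a deterministic generator (`simulate_atac()`) that
  plants known differential regions, nucleosome-periodic fragment lengths,
  TSS-proximal genes and condition-specific motifs, emitting the same file
  formats as a real experiment plus a ground-truth table, so the pipeline
  is validated by parameter recovery.

Everything is a data-frame-in / tibble-out function that chains with the
pipe; fitted objects have broom-style `tidy()` / `glance()` methods and
ggplot2 `autoplot()` methods.

## Worked example

```r
library(tidyatac)

sim    <- simulate_atac(sim_config(seed = 1))          # 3 conditions, 500 regions
atlas  <- build_atlas(sim$peak_calls)                  # 500 atlas peaks
counts <- count_matrix(atlas, sim$fragments)
rl     <- rlog_transform(counts)

cytp <- classify_peaks(rl, c("N", "CytP"))
ags  <- classify_peaks(rl, c("N", "AgS"))
overlap_summary(cytp, ags)
#> # A tibble: 2 × 4
#>   class     n_a n_shared pct_shared
#>   <chr>   <int>    <int>      <dbl>
#> 1 opening    67       26         39
#> 2 closing    79       33         42

fragment_length_distribution(sim$fragments$N)
#> <length_histogram> 113041 fragments (0 outside [20, 800])
#> modes:
#>              band length    height
#> 1 nucleosome-free     77 1472.7273
#> 2 mono-nucleosome    198  532.6364
#> 3   di-nucleosome    392  171.4545

tss_enrichment(sim$fragments$N, sim$genes, chrom_sizes = nchar(sim$genome))
#> <tss_profile> 150 genes, enrichment score 12.1
```

Reading the output: the atlas collapses the three conditions' jittered
peak calls back to one peak per planted region; the cytokine-primed
contrast yields far fewer differential peaks than the antigen-stimulated
one (the generator plants a 10× asymmetry), and a third to a half of them
are shared with the stimulated response. The QC modes sit at the planted
nucleosome-periodic mixture means (75/200/400 bp), and the TSS score far
above 1 reflects the TSS-proximal placement of accessible regions.

`run_pipeline(sim_config(seed = 1), outdir = "run1")` executes every stage
in order and writes per-stage TSV/BED outputs plus a `manifest.json` with
the resolved seed, all thresholds and an md5 digest per file;
deterministic stages reproduce identical digests on rerun.

The methods vignette (`vignettes/differential-accessibility.Rmd`) documents
the models, every tunable parameter with its default and rationale, the
generator's scope, and an explicit power analysis of what the
fold-change-only classifier can and cannot recover from non-replicated
libraries.

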