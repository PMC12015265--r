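# xenopool

Deconvolution of inter-individual gene-expression variability from pooled
RNA-seq, with the downstream gene-list curation, gene-set comparison and
behavior-kinematics computations used to characterize Xenobots —
autonomously motile constructs self-assembled from *Xenopus laevis*
ectodermal explants — against age-matched embryos.

## The problem and who it is for

Tiny organisms are often sequenced as **pools** (here 50 Xenobots or 10
embryos per library) because one individual yields too little RNA. A
pool's per-gene count is then the *mean* over its individuals, which hides
the between-individual variability. But with `r` replicate pools per
group, the standard deviation of the pool values estimates the standard
error of that mean, so the individual-level SD is recoverable:

    SE = sigma / sqrt(n)   =>   sigma_hat = SD(pool values) * sqrt(n)
    CV_hat = sigma_hat / mean(pool values)

`xenopool` implements this deconvolution per gene and group, compares the
resulting CV distributions (Wilcoxon rank-sum), splits the
expression-ranked gene list into 100 percentile bins and tests each bin's
fraction of genes with `CV_X > CV_E` against a permutation null, and
provides:

- **counts**: TSV I/O, strict CPM filtering (`> 0.6` in `>= 3` samples),
  TMM normalization factors, the printed logCPM transform;
- **curation**: exact-ID gene-set subtraction, LOC annotation via supplied
  maps, `.L`/`.S` homeolog deduplication, human-ortholog mapping, with a
  per-stage count report;
- **genesets**: overlap percentages (thanatotranscriptome enrichment),
  germ-layer marker audits, phylostratum chi-square comparisons with
  standardized residuals;
- **kinematics**: tracking-export loading, velocity and per-interval peak
  velocity around a stimulus, and the ellipsoid total-cell estimate;
- **simdata**: a generator for every input with known ground truth, so the
  whole pipeline is testable offline.

Everything is tidyverse-native: data frames in, tibbles out, `tidy()` /
`glance()` on result objects, `autoplot()` for the figures.

## Worked example

Simulate the study design (three replicate pools per group, n = 50 vs
n = 10) with a 3x dispersion excess planted in the Xenobot group, then run
the variability pipeline:

```r
library(xenopool)

cfg <- sim_config(
  n_genes = 2000,
  dispersion = list(xenobot = 0.6, embryo = 0.2),
  seed = 42
)
sim <- simulate_pooled_counts(cfg)
cv  <- compute_cv_table(sim$counts)

compare_cv_distributions(cv, group_x = "xenobot", group_e = "embryo")
#> Wilcoxon rank-sum on 2000 genes: W = 2.83291e+06, p = 3.88183e-115
#>   xenobot: mean CV 0.7313, SD 0.3896
#>   embryo: mean CV 0.4750, SD 0.2822

res <- bin_fraction_analysis(cv, n_bins = 100,
                             group_x = "xenobot", group_e = "embryo") |>
  permutation_test(n_permutations = 1000, seed = 42)
res
#> <bin_fraction_result> 2000 genes in 100 bins; overall fraction xenobot > embryo: 0.7180
#>   permutation test: 1000 shuffles, 13/100 bins significant at alpha = 0.05

top_variable_genes(cv, sim$counts, k = 5, group = "xenobot")
#> # A tibble: 5 x 4
#>   gene_id      cv pool_mean sigma_hat
#>   <chr>     <dbl>     <dbl>     <dbl>
#> 1 gene00609  2.09    3856.     8058.
#> 2 gene01879  2.04    9185.    18766.
#> 3 gene00866  1.97    2376.     4675.
#> 4 gene00500  1.89      50.0      94.6
#> 5 gene00435  1.84      16.3      30.0
```

Reading the output: the planted dispersion excess makes the Xenobot-like
group's CV distribution stochastically larger (rank-sum p ~ 1e-115), and
71.8% of genes show `CV_X > CV_E`. With only three replicate pools the
per-gene CV estimate carries chi-square(2 df) noise, so even a 3x
variance excess cannot push that fraction much above 75% — see the
vignette for the exact ceiling; the very high fractions observed in real
data imply much larger per-gene effects. `autoplot(res)` draws the
bin-fraction bar chart with the overall-fraction line and significant bins
shaded.

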