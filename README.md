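# tilemeth

Comparative meDIP tiling-array methylation analysis between two inbred
genotypes, built as a tested, reusable R pipeline. The motivating design is
the maize inbred pair B73 x Mo17: methylated DNA is enriched by
immunoprecipitation (meDIP), hybridized against un-enriched input DNA on a
high-density tiling array, and per-probe log2(IP/input) is compared between
genotypes to find differentially methylated regions (DMRs), including
candidate *pure epialleles* — methylation differences in genomic regions
that are identical by descent — and to classify their inheritance as *cis*
(local haplotype) or *trans* (unlinked controller) using near-isogenic
lines (NILs).

The package is for epigenomics analysts who want the full statistical
machinery of this design without the wet-lab data: a synthetic-data
generator produces every input with known ground truth.

## What it computes

For probe *p* with channel-factor means fitted per probe by least squares:

- **B73 methylation** `m_B = B73_IP − B73_input`
- **CGH** `c = Mo17_input − B73_input` (copy number / hybridization
  efficiency)
- **Mo17 corrected methylation** `m_M = Mo17_IP − Mo17_input`
- **differential methylation** `d = m_B − m_M` (positive = B73
  hypermethylated)

with empirical-Bayes moderated t-statistics
(`s²_post = (d₀s₀² + df·s²)/(d₀ + df)`, prior by moment-matching the log
variances) and Benjamini–Hochberg q-values. Differential values are
segmented by circular binary segmentation (max two-sample |t| over arcs,
permutation-tested, recursive), segment means are fitted with a
three-component Gaussian mixture by EM, and segments with posterior > 0.95
in an outer component become CNV/PAV calls (on the CGH statistic) or DMR
calls (on the differential statistic, ≥ 3 probes). Downstream stages
profile methylation along chromosomes and metagenes, screen
identical-by-descent regions (≥ 2 Mb, SNP density ≥ 25-fold reduced, no
structural variation), and classify DMR inheritance from NIL panels via
the digest-qPCR statistic
`(B73 mock Ct − B73 digest Ct) − (Mo17 mock Ct − Mo17 digest Ct)`.

## Worked example

```r
library(tilemeth)

ref    <- sim_reference(chromosomes = c(chr1 = 2e5, chr2 = 2e5),
                        repeat_fraction = 0.1, seed = 1)
truth  <- sim_truth(ref, dmr_count = 6, cnv_count = 2, ibd_count = 1,
                    ibd_min_length = 3e4, seed = 2)
arrays <- sim_arrays(truth, ref, sigma = 0.3, seed = 3)

res <- run_pipeline(arrays, ref$probes, n_perm = 500, seed = 4)
tidy(res$mixture)
#> # A tibble: 3 × 4
#>   component     mean variance proportion
#>       <int>    <dbl>    <dbl>      <dbl>
#> 1         1 -2.02    0.00414       0.214
#> 2         2 -0.00640 0.000542      0.571
#> 3         3  1.91    0.0331        0.214
```

The three mixture components are Mo17-hypermethylated segments (left peak
near −2, the implanted effect size), unchanged segments (center), and
B73-hypermethylated segments (right peak). The called DMRs:

```r
dplyr::select(res$dmrs, chrom, start, end, n_probes, direction, posterior)
#> # A tibble: 6 × 6
#>   chrom  start    end n_probes direction  posterior
#> 1 chr1   97400  97850        3 Mo17_hyper         1
#> 2 chr1  129600 131050        8 B73_hyper          1
#> 3 chr1  170600 173450        7 Mo17_hyper         1
#> 4 chr2   48600  49850        7 Mo17_hyper         1
#> 5 chr2   93000  93450        3 B73_hyper          1
#> 6 chr2  165800 166450        4 B73_hyper          1

evaluate_dmr_recovery(res$dmrs, truth$dmrs)
#> # A tibble: 1 × 6
#>   n_true n_called recall precision exact_boundary_fraction direction_accuracy
#> 1      6        6      1         1                       1                  1
```

All six implanted DMRs are recovered with exact probe boundaries and
correct direction. The packaged validation tables tally the published
inheritance study:

```r
tally_validation_table(read_validation_assays(),
                       ibd_regions = read_ibd_regions())
#>   n_assays n_b73_direction n_mo17_direction n_confirmed n_ibd n_cis n_trans
#> 1       33              14               19          28     8    10       3
```

33 assayed DMR regions, 14 hypermethylated in B73 and 19 in Mo17, 28
confirmed by methylation-dependent digest qPCR, and 10 cis- versus 3
trans-controlled among the 13 mapped in NILs.

Plot helpers: `plot_window_profile()`, `plot_metagene()`, and
`autoplot()` on the fitted mixture (histogram of segment means with the
mixture density overlaid).

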