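---
title: "Methods behind tilemeth: models, parameters, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind tilemeth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tilemeth)
```

# The problem

`tilemeth` re-implements, as a tested and reusable pipeline, a comparative
meDIP (methylated-DNA immunoprecipitation) tiling-array analysis of two
inbred genotypes — the canonical design being the maize inbreds B73 and
Mo17. Fragmented genomic DNA is enriched for methylated fragments with a
5-methylcytosine antibody, labeled (IP in Cy5, input in Cy3), and hybridized
to a high-density tiling array; per-probe log2(IP/input) measures local
methylation density. The pipeline covers six analysis stages plus a
synthetic-data generator that stands in for the arrays with known ground
truth.

# The linear model and its contrasts

Each probe is modeled with one mean per channel factor —
`B73_IP`, `Mo17_IP`, `B73_input`, `Mo17_input` — fitted by least squares
across replicates. Four contrasts carry the biology:

* **B73 methylation**: `B73_IP - B73_input`;
* **CGH**: `Mo17_input - B73_input`, the copy-number / hybridization
  efficiency contrast;
* **Mo17 corrected methylation**: `Mo17_IP - Mo17_input`, i.e. Mo17 IP
  corrected by the input-vs-input contrast, so sequence divergence between
  the genotypes does not masquerade as methylation difference;
* **differential methylation**: the difference of the two methylation
  contrasts, positive when B73 is hypermethylated.

With one dye per channel type (IP always Cy5), the dye effect is confounded
with the IP/input distinction: it cannot be estimated separately and is
absorbed into the factor means. The two quantities used for inference are
dye-free by construction — CGH compares two Cy3 channels, and differential
methylation is an IP-vs-IP comparison after input correction. This is the
reason the Mo17 methylation estimate is corrected by the input contrast at
all.

**Normalization.** Channels are calibrated on the linear intensity scale by
the ratio of each array's median to the median of a per-probe-median
pseudo-array, followed by a generalized-log (`asinh`) transform scaled to
stay log2-like at high intensities, and a final additive per-array median
alignment. A zero-offset (purely multiplicative) calibration was a
deliberate numerical choice: additive log-scale array effects are exactly
multiplicative on the linear scale, and a scale-and-offset fit against a
pseudo-array that mixes IP and input channels was found to distort the
low-intensity tail (presence/absence probes) catastrophically. Full
maximum-likelihood variance-stabilizing normalization is intentionally out
of scope.

**Moderated statistics.** Per-probe residual variances are shrunk toward a
prior by empirical Bayes: the prior degrees of freedom `d0` and scale
`s0^2` are obtained by moment-matching the log sample variances (digamma /
trigamma matching under the scaled-F sampling model, with a Newton solve of
the trigamma inverse), the posterior variance is the df-weighted mix
`(d0*s0^2 + df*s2)/(d0 + df)`, and moderated t-statistics are referred to a
t distribution on `d0 + df` degrees of freedom. When the observed
log-variance spread is no larger than its sampling noise the prior df is
infinite and the pooled variance is used — the classical limit. q-values are
Benjamini-Hochberg; the procedure name is a package choice since only "FDR
controlled" is specified by the analysis this re-implements.

# Segmentation and mixture classification

**CBS.** Circular binary segmentation operates on the per-probe statistic in
genomic order, per chromosome. For the current segment every arc `(i, j]`
is scored by the two-sample |t| between the probes inside and outside the
arc; the maximal arc is tested against a permutation null (`n_perm = 1000`
shuffles, split accepted iff `p <= alpha = 0.01`), and accepted boundaries
recurse. Ties in the arc scan break toward the smallest left boundary, then
the shortest arc.

Numerical choices that matter:

* *Pooled-variance floor.* For noise-free data every arc with any mean
  contrast has zero within-arc variance; scoring such arcs as infinite
  would make the tie-break shred the series one probe at a time. The pooled
  variance is floored at `1e-10` times the segment's total variance, so
  noiseless arcs rank by effect size and the exact implanted boundary wins.
* *Scan resolution.* The observed arc scan is exact up to 5000 probes per
  segment (above that, a coarse grid with exact local refinement of the
  winning arc). The permutation replay caps its grid at ~1000 boundary
  positions per segment, and the observed maximum entering the test is
  computed at the same stride as the permuted maxima, so the test remains
  calibrated at any resolution; only the reported boundary location uses
  the finer scan. An exact permutation replay at 5000 probes would cost
  ~25 billion operations per accepted split, which no analysis needs.
* *No "undo splits" pruning.* The optional pruning pass of the reference
  segmentation tool is not implemented; a configuration hook is reserved.

**Mixture classification.** Segment means are fitted with a K = 3 Gaussian
mixture with unequal variances by EM: the left and right components capture
segments hypermethylated in one genotype (or, on the CGH statistic, copy
gain/loss in Mo17), the middle component the unchanged bulk. The fitting
population is the segment means, one point per segment and unweighted by
probe count — the histogram being modeled is a histogram of segments.
Initialization is quantile-based (means at the 10th/50th/90th percentiles),
making fits deterministic without a seed; collapsed components trigger up
to five jittered restarts before erroring. Component variances are floored
at `1e-8` so that exactly-clustered noise-free segment means remain
fittable. A segment is labeled only when one component's posterior
probability exceeds 0.95; otherwise it is unclassified, mirroring the
four-way segment table (hyper in either genotype / no change /
unclassified) of the analysis this package re-implements.

# Probe annotation

* **Copy number.** Perfect matches are exact substring occurrences of the
  probe on either strand. Close matches allow at least 90% identity over at
  least 90% of the probe, implemented as whole-probe alignments with at
  most `floor(0.1 * length)` edits (indels allowed) and overlapping hits
  merged into loci; loci containing a perfect hit are not double-counted.
* **Filter cascade**, applied in order with order-dependent semantics:
  (1) chromosome-9 thinning keeps every third probe of the densely tiled
  chromosome; (2) the unique filter keeps probes with exactly one perfect
  match — by default *and* no close match, since the copy-number analysis
  treats close matches as a separate methylation-inflating class; the
  perfect-only reading is available via `unique_definition`; (3) the CGH
  filter keeps probes with CGH strictly greater than -1. Removal provenance
  is recorded per probe.
* **Gene context.** The probe midpoint decides the feature class — midpoint
  rather than overlap fraction because it is unambiguous for 50-mers
  against kb-scale features. A probe is assigned to the nearest gene (by
  TSS distance) among genes containing it or whose TSS/TTS lies within
  1 kb; ties prefer high-confidence (FGS) models, then the smallest gene
  id. Distances are transcription-strand oriented with upstream negative.

# Profiles

Chromosome profiles use 5 Mb windows sliding 1 Mb (configurable), anchored
at the chromosome start with the last partial window retained; percent
methylation is a plain probe count ratio. Metagene profiles map probes onto
an axis of upstream flank (1 kb), gene body rescaled to 1000 units, and
downstream flank, each cut into 20 bins — the bin count is a smoothing
choice, exposed in the interface, as the source analysis does not state
its binning. Averaging is per probe-gene pair: a probe near two genes
contributes to both curves; this choice is flagged here because a
per-gene-then-bin average is equally defensible. CpG density uses the same
axis, counting CG dinucleotides per bin on the transcription strand.

# DMRs, the IBD screen, and inheritance

DMRs are decisively labeled segments of at least 3 probes. Two q-value
cutoffs coexist deliberately: probe-level differential calls use q < 0.001,
while the per-segment annotation column reports the fraction of member
probes significant at the stricter q < 0.0001 — both thresholds are
explicit parameters because the summaries they feed use different cutoffs.
Enrichment tests are Pearson chi-square without continuity correction (the
correction flag is exposed).

The IBD screen slides a window of the minimum region length, keeps windows
with no CNV/PAV segment and SNP density at least `fold_threshold` (25 by
default) below the genome-wide rate, merges passing windows, and reports
per-region SNP fold reduction (infinite, flagged, for zero-SNP regions).
The 2 Mb minimum length of the source analysis is rescaled through
configuration on synthetic genomes (100 kb at the default 1 Mb chromosome
scale).

For inheritance, the qPCR statistic is exactly
`(B73 mock Ct - B73 digest Ct) - (Mo17 mock Ct - Mo17 digest Ct)`. Its
printed sign convention (positive = Mo17 more methylated, for
methylation-dependent enzymes) is implemented as stated, with a
`sign_flip` flag because published validation tables are internally
consistent with the opposite reading; packaged fixture flags are consumed
verbatim rather than re-derived. Methylation states are called from the
digest-minus-mock differential with thresholds (1.0, 3.0) Ct — invented
defaults, exposed in the interface, since the source figures encode states
as colors without stating cutoffs. The cis/trans classifier requires a 0.75
majority of informative NILs (NILs with a donor introgression over the
DMR): cis when the donor-haplotype prediction wins at least 75% and beats
the recurrent match, trans when the recurrent state holds at least 75% —
the asymmetric tolerance exists because a trans-acting locus is itself
occasionally introgressed, which legitimately produces a minority of
donor-state NILs. The 0.75 value keeps two-NIL panels classifiable.
Control NILs feed a stability report (expected / partial / switched).

# What the synthetic generator emulates — and what it does not

The generator produces every input the pipeline consumes with known truth:
random-sequence chromosomes with masked repeat intervals excluded from
tiling; ~200 bp probe spacing (~56 bp on a chromosome named `chr9`, thinned
later by the filter cascade); duplicated blocks giving true multi-copy
probes; gene models with class, strand, synteny, subgenome, and expression
labels; per-probe bimodal methylation states (default half methylated);
DMRs implanted as runs of 3-8 consecutive probes flipped in one genotype —
matching the reported average DMR sizes of ~5-6 probes; CNV/PAV intervals
shifting the Mo17 channels; IBD blocks with SNP density reduced 36-fold
(the reported fold reductions span 25-49); NIL panels whose states follow
the local haplotype (cis, pure) or an unlinked controller locus (trans);
and digest qPCR with enzyme-appropriate Ct shifts. Implanted intervals keep
at least 10 untouched probes between them: closer intervals are not
resolvable as distinct regions at segment resolution and would make exact
recovery ill-posed. Trans controller loci are kept at least ~25 kb from
every DMR so introgressions covering one never accidentally cover the
other.

Noise is additive Gaussian on the log2 scale with independent dye and
per-array offsets — the source analysis does not state its noise model, so
magnitudes are configuration-exposed choices (channel SD 0.3 by default).
A single integer seed fans out to named substreams per stage
(`substream_seed`), so each stage is independently reproducible.

Deliberately not emulated: realistic transposon families, thermodynamic
probe design, sequence-level bisulfite chemistry, spatial array artifacts,
and probe-sequence-dependent hybridization efficiency. Passing tests on
synthetic data therefore demonstrate the statistical machinery — contrast
algebra, calibration, segmentation power, classification — not robustness
to the full mess of real two-color arrays.

# Problem sizes and power

The test and acceptance studies use synthetic genomes of one to two 0.3-1
Mb chromosomes (1500-10000 probes), 3 replicates, and 1000 CBS
permutations; these sizes were chosen as the package's desk-scale defaults.
Noise-free runs recover every implanted DMR and CNV with exact probe
boundaries, and at the default noise level (per-probe signal-to-noise ~6)
recovery is likewise complete.

One stress condition deserves honesty: with the per-probe effect at twice
the noise SD of the differential statistic and DMR sizes of 3-8 probes, a
3-probe DMR carries an arc t-statistic of `2 * sqrt(3) = 3.46`, while the
null distribution of the maximal arc |t| over a 1500-probe chromosome
concentrates near 4.5-5. Even an oracle t-test at the known locations,
corrected for the number of candidate windows, has roughly 50-65% power for
3-4-probe DMRs at this effect size, capping attainable recall near 0.8 for
the 3-8 size mix; the segmentation route lands near 0.5-0.7. This is an
information limit of the 2-sigma condition, not a property of this
implementation; recall targets above it require either larger DMRs or
stronger effects. The acceptance script reports the measured recall under
this condition (`dmr_recall_2sigma`) alongside the noise-free recovery
metrics so the trade-off is visible rather than hidden.

# Known limitations

* The design matrix (four channel-factor means) is a faithful but not
  provably identical reconstruction of the source analysis's limma design,
  which is not printed anywhere.
* The normalization is a calibrated generalized-log transform, not a full
  variance-stabilizing ML fit.
* Multi-sample joint segmentation, HMM alternatives, and the log-odds
  (B-statistic) are out of scope.
* Genome-scale (Gb) match counting is out of scope; the match counter is
  exact but quadratic-minded, intended for desk-scale genomes.
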