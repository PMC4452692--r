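---
title: "Methods: copy-number, expression, and mutation-spectrum analysis for cross-species driver discrimination"
author: "crossonc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: copy-number, expression, and mutation-spectrum analysis for cross-species driver discrimination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossonc)
```

## The scientific setting

Spontaneous canine head-and-neck squamous cell carcinoma (HNSCC) closely
mirrors the human disease, and the comparison between the two species can be
exploited statistically.  A region that is recurrently amplified in human
tumors typically carries a handful of driver genes among many passengers
that are amplified only because they are physically linked to the drivers.
Interspecies genomic rearrangement breaks that linkage: when a human
amplicon maps onto two (or more) separate regions of the dog genome, the
dog tumors are free to amplify only the region that carries the selective
advantage.  Genes whose dog-syntenic region is also recurrently amplified
become driver candidate genes (DCGs); genes whose region stays copy-neutral
become passenger candidate genes (PCGs).

`crossonc` implements the full analysis chain needed for that comparison:
aCGH copy-number segmentation and CNA calling, gene-level recurrence
scoring, copy-number/expression integration, substitution-spectrum analysis
from RNA-seq-derived variant calls, and the synteny projection with its
validation statistics.  Because the underlying tumor data cannot be bundled,
a synthetic-data generator with known ground truth stands in for every
input, which also makes each stage's error behaviour measurable.

## Copy-number segmentation

Probe-level log2 tumor/normal ratios are segmented per chromosome by exact
least-squares change-point detection.  For every number of change-points
$k = 0, \dots, k_{\max}$ the dynamic program finds the placement minimising
the Gaussian residual sum of squares (RSS) in $O(k_{\max} n^2)$ time; ties
are broken towards the leftmost breakpoint so results are deterministic.
The reported $k$ minimises a penalised cost
$\mathrm{RSS}(k) + \lambda k$ with the modified-BIC default
$\lambda = 2\hat\sigma^2 \log n$, where $\hat\sigma$ is estimated from the
median absolute first difference of the profile
($\hat\sigma = \mathrm{median}|x_{i+1}-x_i| / (0.6745\sqrt2)$) so that true
jumps barely inflate it.  When the profile is noise-free the penalty falls
back to a small numeric floor, which makes the smallest $k$ win among
equal-RSS solutions; implanted noise-free segments are therefore recovered
with exact breakpoints.

`max_k` defaults to 12 change-points per chromosome.  On the profiles this
package targets (a handful of focal and broad events per chromosome) that
is a generous budget, and the penalised selection uses far fewer; the bound
is configurable for denser landscapes.  At realistic noise
(amplitude 1.0, probe noise sd 0.2) breakpoints land within one probe of
the truth; the penalty occasionally admits one spurious change-point, whose
segments are then removed by the calling cutoffs below rather than by a
stricter penalty, keeping sensitivity high.

## CNA calling with FDR control

Each segment's probe ratios are tested against zero with a one-sample
t-test, p-values are Benjamini–Hochberg adjusted across all segments of the
sample's genome, and a segment is called amplified (deleted) only when all
three conditions hold: $q \le 0.01$, at least 3 probes, and
$|\bar{x}| \ge 0.4$ in log2 units.  These are the calling parameters of the
canine HNSCC study design this package reimplements, and they are the
package defaults.  Two boundary conventions required a decision:

* a segment with zero probe variance has an undefined t statistic; it is
  assigned $p = 0$ when its mean is nonzero and $p = 1$ otherwise — the
  noise-free limit, without which exactly-recovered noise-free segments
  could never be called;
* single-probe segments are untestable ($p = \mathrm{NA}$, never called).

Chromosome X is excluded from calling by default (`exclude_chroms`),
reflecting the common situation of a sex-mismatched tumor/reference pair;
excluded chromosomes are still segmented and reported, flagged, with no
calls and no part in the FDR adjustment.

On synthetic genomes (5 chromosomes × 10 Mb, one probe per 5–6 kb, 5% of
probes inside implanted segments at $|\log_2| \ge 0.6$, noise sd 0.2) the
realised false-discovery proportion among called segments, averaged over 20
seeded replicates, is well below the nominal 0.01 — the amplitude cutoff
makes calling conservative relative to the FDR bound — while every
implanted segment of at least 3 probes is recovered.  `scripts/acceptance.R`
recomputes this number from scratch.

## Gene-level recurrence

A gene takes the call of the segment containing its midpoint; midpoints in
probe gaps use the nearer flanking segment.  Recurrence across samples is
scored with a permutation analog of a G-score: per gene,
$S_g = \sum_s \max(0, a_{gs})$ where $a_{gs}$ is the mean log2 of the
assigning segment (deletions mirrored with $-a_{gs}$).  The null cyclically
shifts each sample's gene-amplitude vector along the genome gene order by
an independent random offset, which preserves the sample's total CNA burden
and its spatial autocorrelation exactly — the null asks whether the same
CNAs, placed blindly, would pile up this much.  Empirical p-values are
computed against the null scores pooled across genes and permutations
(per-gene nulls at 1000 permutations cannot resolve the small q-values the
recurrence threshold needs), then BH-adjusted; genes with $q \le 0.2$ are
recurrent.  This is a self-contained replacement for an external
recurrence tool used at the same threshold; equivalence of role, not of
output, is claimed.

## Expression classification against diploid references

For each gene, samples that are copy-neutral (status 0) form the reference.
On $y = \log_2(\mathrm{FPKM} + 1)$ the interval
$$\bar{y} \pm t_{1-\alpha/2,\,n-1}\; s \sqrt{1 + 1/n}$$
is a *prediction* interval for one new observation; values above it are
"high", below it "low".  The interval rule in the source method is stated
as a "95% confidence interval" of the diploid samples' expression; it is
implemented here as a prediction interval deliberately, because a
confidence interval for the mean shrinks like $1/\sqrt n$ and would flag
far more than 5% of perfectly diploid samples, contradicting the rule's
evident purpose of flagging expression outliers.  Diploid reference
samples are classified against the leave-one-out interval to avoid
self-inclusion bias; genes with fewer than 3 diploid references are
`unclassifiable`; a zero-variance reference produces a degenerate interval
and a warning.  Under a Gaussian null with 8 reference samples the rule
calls 95% of held-out diploid draws "normal" (recomputed by both the test
suite and the acceptance script).

The 3×3 concordance table (Del/unchanged/Amp × low/normal/high, columns
in percent) summarises copy-number/expression coupling; the t-test arm of
differential expression uses per-gene Welch tests on $\log_2(\mathrm{FPKM}+1)$
with BH adjustment at FDR 0.1.  A negative-binomial count-model arm is out
of scope; this package consumes an FPKM-scale matrix, not read counts.

## Hotelling's T² concordance comparison

To compare copy/expression concordance between two gene sets (DCGs vs
PCGs), each gene contributes a bivariate feature — its mean log2 copy ratio
and mean log2 expression — and the two sets are compared with the
two-sample Hotelling T² statistic,
$F = T^2 (n_1+n_2-p-1)/(p(n_1+n_2-2))$ with $p = 2$.  The per-gene
bivariate-mean reading is the most plausible construction of the published
comparison; an alternative (per-gene correlation coefficients as the
feature) would be a one-dimensional t-test and is left as a documented
extension.  With $p = 1$ the implementation reduces exactly to the squared
pooled-variance two-sample t, which the tests verify.

## Mutation spectra

Substitution records are depth-filtered to 30–300× (inclusive), the
accuracy filter appropriate for RNA-seq-derived variant calls.  Substitutions
are strand-collapsed onto the six pyrimidine-reference classes; CpG context
means the mutated base is the C of a CpG on either strand, and TpC means
the collapsed C has a 5′ T.  Records with an N in the deciding flank are
excluded from context-restricted analyses.

Virus-status groups are compared by pooling CpG-site transition/transversion
counts within each group and applying a two-sided Fisher's exact test.
Pooling is a deliberate choice: with only two virus-positive tumors in the
motivating cohort, per-sample tests are powerless; per-sample fractions are
still reported for transparency.  The test is two-sided and no direction is
hard-coded — the published account of the direction of the CpG-transversion
difference is internally inconsistent, so the package reports the
per-group fractions and lets the data speak.  The TpC fraction per group is
reported without an attached test for the same reason.  Coding consequences
(synonymous/missense/nonsense, with labels like `E233K`) use the standard
genetic code via `Biostrings`.

## Synteny projection and driver–passenger discrimination

A synteny map is a table of equal-length interval pairs with orientation;
projection is piecewise-linear coordinate transfer, reversing within-block
offsets for `-` blocks, reporting (never dropping) unmapped gaps, and
invertible on mapped bases.  Discrimination assigns each gene of the
projected human amplicon to its dog region, labels it amplified or
unchanged by the recurrence q-value at FDR ≤ 0.2 (recurrently *deleted*
genes are excluded from both candidate sets and reported separately), and
tests the amplified/unchanged split between the two regions with a
two-sided Fisher's exact test (one-vs-rest with BH when a map produces
more than two regions).  On the worked 8q-style table — 125 amplified / 85
unchanged genes in one dog region versus 2 amplified / 186 unchanged in the
other — the test gives $p \approx 5\times10^{-43}$, far beyond the
$2.2\times10^{-16}$ reporting floor.  Two validations are provided:
mutation enrichment of DCGs over PCGs (Fisher) and the Hotelling
concordance comparison above.

## The synthetic-data generator

The generator's defaults are the study conditions the pipeline is meant to
face, chosen once:

* **Genome**: 5 chromosomes × 10 Mb for generic tests; probes on a jittered
  grid (uniform ±40% around a 5.5 kb mean spacing, emulating a 385K oligo
  array at one probe per 5–6 kb, without grid artifacts); non-overlapping
  genes placed one per equal-width slot.
* **aCGH**: probe value = implanted segment amplitude + N(0, sd); the
  platform's true noise magnitude is not published, so sd 0.2 was chosen as
  a testability-driven default, not a platform calibration.
* **Expression**: log-normal around a baseline, with
  $\log_2 e = \mu + c \cdot \log_2(\mathrm{copy}) + \varepsilon$ for driver
  genes and no coupling term for passengers; Gaussian noise on the log2
  scale matches the log-scale treatment of FPKM throughout.
* **Variants**: classes drawn from a configurable six-class spectrum
  (transition-dominated by default), transversion odds multiplied at CpG
  sites per profile; depth uniform in 30–300× with a fixed 10% of records
  deliberately out of range so the coverage filter is always exercised.
* **Synteny scenario**: one 66 Mb "human" region split 210/188 genes across
  two "dog" chromosomes (the 8q geometry, with the second block inverted to
  exercise orientation handling); 125 contiguous driver genes implanted at
  +1.0 log2 in 80% of 10 samples, Poisson(1) random background segments per
  sample.  Gene counts follow the motivating 8q analysis; cohort size,
  recurrence rate and background rate are the package's own realistic
  choices.

What the generator does *not* emulate — tumor purity and subclonality, GC
waves and other array artifacts, germline contamination of RNA-seq variant
calls, sequence-context-dependent noise — bounds what passing tests prove:
they establish algorithmic correctness and calibration under the stated
model, not platform-level fidelity to real arrays or real transcriptomes.

## Numerical choices and degenerate inputs

* DP ties → leftmost breakpoint; penalty floor `1e-8 * (RSS(0)+1)` so
  noise-free profiles select the minimal sufficient $k$.
* Zero-variance segments and zero-variance expression references use the
  noise-free limiting p-value / degenerate interval, with flags.
* Empty margins in the CpG 2×2 give $p = 1$ with a warning; a singular
  pooled covariance in Hotelling's test is an error suggesting jitter or a
  dimension drop.
* All internal coordinates are 0-based half-open; BED (0-based), VCF and
  SEG (1-based) are converted only at the file boundary.  Chromosome names
  match exactly after stripping an optional `chr` prefix.
* Every stochastic function takes an explicit seed; the pipeline driver
  derives per-stage substreams from one root seed, so a rerun is
  byte-identical.

## Problem sizes used by the test suite

The shipped tests run the full stack at reduced but non-trivial scale,
chosen as the package's own balance of coverage against turnaround: DP
optimality is verified against exhaustive enumeration at $n \le 30$,
$k \le 3$; FDR calibration uses 20 genomes of 5 × 10 Mb chromosomes
(~9,000 probes each); classifier calibration uses 10,000 held-out draws;
the end-to-end driver recovery runs the full 66 Mb two-chromosome scenario
(~12,000 probes × 10 samples) once.  The headline cohort-level numbers of
the motivating study are not desk-reproducible — they require the original
tumor hybridizations, RNA-seq and external cohort data — so the suite
verifies the method's calibration and its worked statistical examples
instead.

## Known limitations

* Segmentation assumes homoskedastic Gaussian probe noise; no GC-wave or
  wave-bias correction, no allele-specific copy number, no purity/ploidy
  correction.
* Recurrence scoring does not decompose focal from broad events and does
  not deconvolve peak regions; a gene may be recurrent in both directions
  across different samples.
* Variant records are taken as given (no somatic/germline separation), as
  appropriate for reference-aligned RNA-seq calls without matched normals.
* Ortholog assignment is by coordinate projection of gene midpoints; a
  curated one-to-one ortholog table, where available, is the better input
  and can be expressed by editing the gene table before discrimination.
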