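---
title: "Methods: dosage analysis of a segmental duplication"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dosage analysis of a segmental duplication}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segdosage)
```

## The design this pipeline serves

The package analyzes a two-sample, no-replicate design: one
expression library (FPKM per gene) for a control line and one for a
variant carrying a segmental duplication — here, two extra copies of
a chromosome-11 short-arm segment, so four copies of each duplicated
gene against the diploid two. Without replicates, per-gene
differential-expression modeling is off the table; every conclusion
is distributional. The pipeline therefore revolves around the
per-gene ratio score

$$ r_g = \frac{\text{FPKM}_{\text{variant},g}}{\text{FPKM}_{\text{control},g}}, $$

defined for genes with positive expression in both samples, and asks
where along the genome, and in what proportions, $r_g$ concentrates
near 2 (dosage effect: transcription tracking copy number), near 1
(dosage compensation: buffering back to the diploid level), or below
0.5 (inverse effect).

## Classification and counting conventions

- A gene is **expressed** if FPKM > 0 in at least one sample. This is
  the denominator of the summary tables. Ratios and histograms are
  restricted to genes positive in *both* samples, so both statistics
  stay computable from one classification.
- Thresholds are **inclusive**: up means $r \ge 2.0$, down
  $r \le 0.5$. A gene detected only in the variant counts as up, only
  in the control as down; such genes carry no finite ratio and are
  excluded from histograms and window profiles (this also keeps
  infinities out of the binning).
- Genes absent from either expression file are dropped at the join,
  not zero-filled: absence from a quantification table is not
  evidence of zero expression.
- Summary percentages are rounded **half-up** to two decimals. Base
  R's `round()` is round-half-even, which renders borderline
  percentages differently from conventional table formatting; a
  small epsilon guards against `floor(x + 0.5)` dropping values that
  sit a float below the half.

## Spatial conventions

Coordinates are stored 1-based inclusive (the GFF3 convention); BED
input is converted on read and back on write, so a catalog round
trip is the identity. Genes are ordered by (chromosome, start,
gene id) — the id breaks coordinate ties so window profiles are
deterministic. A gene belongs to the region containing its **start**
coordinate; anchoring on one point makes the assignment unambiguous
for boundary-straddling genes. Genes on chromosomes without declared
regions fall back to a region named after the chromosome, keeping
the partition total.

The default partition splits the duplication chromosome at the
segment bounds (5.4 Mb and 12.1 Mb): `11S-1` (distal short arm,
non-duplicated), `11S-2` (duplicated segment), `11L` (long arm).

## Windows, bins, and peak calls

**Window profile.** The median of $r_g$ over windows of $W = 100$
consecutive usable genes, sliding by 1 gene, per chromosome. The
median (not mean) keeps the profile flat at 1.0 through scattered
up/down genes — a window needs more than $W/2$ altered genes to move
at all, so the 2.0 plateau over the duplicated segment is a
copy-number signal, not an expression-noise one. Step = 1 gives the
maximum-resolution profile; chromosomes with fewer than $W$ usable
genes yield no windows rather than shrunken ones.

**Ratio histogram.** Right-open bins $[kw, (k+1)w)$ with $w = 0.05$,
plus one overflow bin at the cap (default 5.0). Bin assignment is
`floor(r/w)` with a $10^{-9}$ guard so that ratios like 0.15 (not
exactly representable) land in their intended bin. Raw ratios, not
log ratios, are binned: the diagnostic contrast is between peaks at
1.0 and 2.0, which are equally visible on the raw scale, and the cap
absorbs the long right tail.

**Compensation call.** The modal (highest-count, non-overflow) bin
center, ties broken toward the smaller center; a region "peaks at 1"
when the modal center is within $\tau = 0.10$ of 1.0, analogously
for 2.0. $\tau$ spans two bins either side — "around 1.0" is a
qualitative notion and the call should not flip on a one-bin wobble.

## Statistics across regions

- **Kolmogorov–Smirnov.** The default mode compares variant against
  control expression values of the same region's genes, two-sided,
  with the direction (sign of the median difference) reported
  separately; an alternative mode compares a region's ratio
  distribution against the pooled background ratios. D is the exact
  ECDF supremum; the p-value uses the exact null distribution when
  the effective sample size $n_x n_y/(n_x+n_y)$ is below 35 and the
  asymptotic Kolmogorov distribution above (the two agree within
  0.01 by balanced $n = 100$, which the tests verify).
- **Fisher's exact test**, two-sided by the probability criterion
  (summing hypergeometric probabilities of tables no more probable
  than the observed one, with a $10^{-7}$ relative tie tolerance).
  The reported odds ratio is the sample odds ratio $(ad)/(bc)$, with
  Inf / NaN flags for degenerate margins, not the conditional MLE.
- **Wilson 95% intervals** for cell-count proportions: with $n \le
  30$ cells per cytological experiment, Wald intervals misbehave
  near the boundary; Wilson intervals stay inside $[0, 1]$ and are
  clamped to bracket the point estimate exactly at $k = 0$ and
  $k = n$.

No multiple-testing correction is applied: the pipeline runs a
handful of pre-specified regional tests, not a genome-wide scan of
per-gene hypotheses.

## qPCR breakpoint mapping

Relative copy number per marker comes from the 2^−ΔΔCT method:
$\Delta CT = Ct_{\text{target}} - Ct_{\text{reference}}$ within a
sample, $\Delta\Delta CT$ the difference of $\Delta CT$ between test
and origin samples, and $R = 2^{-\Delta\Delta CT}$. Technical
replicates are averaged **on the Ct scale** (cycle noise is additive
in cycles), ΔΔCT and $R$ are computed per experiment against that
experiment's reference wells, and the marker value is the mean of
$R$ over experiments with the between-experiment SD as dispersion.

The breakpoint fit works in $\log_2 R$, where Ct noise is additive
and the two copy states are symmetric levels 0 and 1. All $n-1$
split points are enumerated; each fits the left and right segments
by their means, and the split minimizing the residual sum of squares
wins, ties toward the smaller index. A step is only *called* when
the two-segment model beats the constant model by BIC (the step
model pays for an extra mean plus the changepoint location, k = 3 vs
k = 1); an SSE floor of $10^{-12}$ keeps the Gaussian BIC finite on
noiseless data, where the comparison then correctly prefers the
constant model for flat profiles. Fitted levels are reported raw and
snapped to the candidate set {1, 2} (copy ratios 2:2 and 2:4). A
single changepoint is assumed — the biology here is one breakpoint;
multi-step profiles are out of scope.

## The synthetic-data generator

Real libraries for this design are not publicly available, so the
generator stands in, with ground truth attached. Its defaults *are*
the study conditions and are not tuned per analysis:

| parameter | default | meaning |
|---|---|---|
| region sizes | published per-chromosome counts (23,604 genes, 12 chromosomes, 211-gene `11S-2`) | spatial backbone |
| `pi_dosage` | 0.346 | duplicated-region fraction at multiplier exactly 2 |
| `pi_compensated` | 0 | fraction at multiplier 1 (the studied segment showed no compensation peak) |
| partial effect | remainder, $d \sim U(1,2)$ | intermediate responses filling the 1–2 band |
| background up / down | 0.0555 / 0.0418 | genome-wide trans effects, $d = 2\,U(1,2)$ / $0.5\,U(0.5,1)$ |
| `baseline_log_mean`, `baseline_log_sd` | 1.0, 1.2 (natural log) | log-normal control FPKM, median ≈ 2.7 |
| `noise_log_sd` | 0.25 | multiplicative log-normal noise on the variant |
| qPCR | 21 markers, step after 10, levels (1, 2), Ct sd 0.1, 4 × 3 wells, bases 25 / 20 | plate layout |

The control value is $\text{lognormal}(\mu, \sigma)$; the variant is
control × d × ε with log-normal ε. No published noise model exists
for single-library FPKM ratios, so log-normal multiplicative noise
at `noise_log_sd = 0.25` is an **assumption**, chosen once as a
moderate technical-plus-biological spread, and documented rather
than inferred. RNG streams are split per component (control draws,
dosage assignment, noise, qPCR) from one master seed, so enlarging
the catalog does not perturb the plate draws and fixtures stay
stable.

What the generator does **not** emulate: count-level sequencing
noise (no negative-binomial read model — values are continuous
FPKM), mean–variance dependence (noise is homoscedastic on the log
scale), correlated expression along chromosomes, mappability or GC
artifacts, and replicate structure. Passing recovery tests on this
generator therefore demonstrates that the estimators are correct
under the stated model, not that the model captures every property
of real libraries.

## What recovery tests can and cannot show

Two consequences of the model are worth spelling out, because the
test suite asserts them deliberately:

1. **Noiseless recovery is exact.** With `noise_log_sd = 0`, ratios
   equal the true multipliers bit-for-bit, the up fraction in the
   duplicated region equals the realized fraction of multiplier-2
   genes, windows fully inside a pure-dosage segment have median
   exactly 2.0, and the modal histogram bin is $[2.00, 2.05)$.
2. **The noisy up-fraction estimator is biased low.** A gene at
   multiplier exactly 2 with symmetric log-scale noise lands at or
   above the inclusive threshold with probability exactly 1/2, and a
   partial-effect gene crosses it with probability
   $\Phi(\log(d/2)/\sigma)$. The naive up fraction therefore
   estimates
   $\pi_d/2 + (1-\pi_d)\,\mathbb{E}_d[\Phi(\log(d/2)/\sigma)]$
   (≈ 0.285 at $\pi_d = 0.346$, $\sigma = 0.25$), not $\pi_d$. The
   property tests assert convergence to this analytic expectation;
   treating the raw up percentage as an unbiased estimate of the
   dosage-responding fraction would be wrong under any symmetric
   noise model. The same applies to real data: the printed up
   percentage is a thresholded summary, not a mixture-model
   estimate.
3. **The modal-bin call is noise-sensitive for mixed regions.** With
   a third of genes at 2.0 and the rest spread over (1, 2), noiseless
   histograms peak cleanly at 2.0; at $\sigma = 0.25$ the 2.0 spike
   flattens faster than the broad partial-effect mass and the modal
   bin can land mid-range. The compensation call is exact on
   noiseless data and qualitative otherwise — which is how it should
   be read on real data too.

## Problem sizes

The test suite and acceptance script run the full 23,604-gene
catalog for deterministic checks, 200 seeded plates for the
breakpoint Monte-Carlo, 1,000 random cases each for the KS and
Fisher oracle comparisons (samples to n = 20, cells to 30, where
exhaustive enumeration is comfortable), and 30–60 seeds for the
noisy-recovery properties — sizes chosen so each property is tested
at meaningful power while the whole suite stays quick to run.

## Known limitations

- One library per condition: no per-gene inference, no shrinkage, no
  replicate-based dispersion estimates — by design.
- FPKM is consumed as given; no re-normalization, length or library
  size correction is applied.
- qPCR quantification assumes perfect doubling per cycle (the plain
  2^−ΔΔCT method); amplification-efficiency correction and melt-curve
  QC are out of scope.
- The changepoint model fits exactly one step; panels spanning
  nested or multiple rearrangements need a richer model.
- Region assignment by gene start means a gene physically straddling
  a breakpoint is attributed wholly to one side.
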