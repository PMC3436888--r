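---
title: "Genotype reproducibility with technical replicates: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotype reproducibility with technical replicates: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genorep)
```

## The problem

Genome-wide association studies lean on SNP-array genotypes whose markers
typically carry small effects; a per-call error rate of a few tenths of a
percent is invisible in routine QC yet can masquerade as association signal.
`genorep` packages the three analyses that quantify this:

1. **Concordance** between technical replicates — repeated assays of the
   same DNA — measured pairwise and aggregated within experiments, across
   laboratories on one platform, and across platforms.
2. **Replicate-based array QC** — call-rate and heterozygosity statistics
   per array, with outlier flagging inside replicate groups, catching
   failures that vendor quality metrics pass.
3. **An error-only odds-ratio simulation** — how large a spurious allelic
   odds ratio pure genotype discordance can produce in a case-control study,
   as a function of minor allele frequency (MAF) and concordance.

Because the raw array data behind such studies is rarely redistributable,
the package ships a synthetic replicate-study generator whose defaults
mirror the reference design: 6 subjects (coded A–F), 4 technical replicates,
5 genotyping experiments (E1–E3 on platform "Affy6", E4–E5 on "Illu1M"), 24
arrays per experiment on a shared synthetic plate layout.

## The concordance statistic

For two call vectors $G_i$ and $G_j$ over $N$ SNPs the concordance is

$$ C_{ij} = \frac{\sum_{k=1}^{N} \mathbf{1}\!\left[G_i^k = G_j^k\right]}{N'} $$

with two denominators exposed as modes:

* `co_called` (default): $N'$ counts only SNPs called in both samples.
  This is standard practice when no-calls are present and is what every
  summary in this package reports unless told otherwise.
* `strict`: $N'$ is all $N$ panel SNPs; only SNPs called **and** equal in
  both samples count as agreeing. A shared no-call therefore still reduces
  strict concordance. This convention keeps the invariant
  `strict <= co_called` exact (counting shared no-calls as agreements can
  invert it), at the cost of treating a doubly-missing SNP as evidence
  against reproducibility — a deliberate, conservative choice.

Both modes report their numerator and denominator, so nothing is hidden in
the fraction. Summaries use the sample ($n-1$) standard deviation.

## The synthetic truth and error model

Truth genotypes are drawn per subject per SNP from Hardy–Weinberg
proportions $((1-p)^2,\, 2p(1-p),\, p^2)$ with per-SNP MAF $p$ uniform on a
configurable interval (default $[0.05, 0.5]$). Replicates copy the truth and
then corrupt it independently per call:

* with probability `nocall_rate` the call becomes a no-call;
* otherwise with probability `call_error_rate` ($e$) it moves uniformly to
  one of the two **other** genotype classes (`uniform_other`).

Under this scheme two replicates of one subject agree at a called SNP unless
exactly one flipped, or both flipped to different classes:

$$ E[C] = (1-e)^2 + \tfrac{1}{2}e^2 = 1 - 2e + 1.5e^2 , $$

which is the calibration the tests assert at $10^5$ SNPs (e.g. $e = 0.003$
gives 99.40% to two decimals). The alternative `direct_pairwise` scheme
derives one call set from a designated reference by the same flip rule, so
its expected concordance against that reference is exactly $1-d$; it is the
natural way to emulate a stated cross-platform concordance (e.g.
$d = 0.012 \rightarrow 98.80\%$).

Real platforms do not err this way — allele dropout and cluster-boundary
errors are structured, and A/T vs C/G strand confusion is systematic — but
the published record does not characterize that structure, so the package
deliberately uses the simplest scheme whose observable consequence (the
pairwise concordance) is calibratable in closed form. What passing tests
show is therefore that the pipeline measures concordance correctly and
recovers planted anomalies, not that the generator reproduces platform
error physics. Likewise the generator draws SNPs independently (no linkage
disequilibrium), subjects independently (no trio structure), and replicates
independently (no plate or batch effects; the plate well is metadata only).

## Replicate-based QC

Per array: call rate = called/total, het rate = HET/called. Within each
(subject, experiment) replicate group, an array is flagged `het_outlier`
when

$$ |h_i - \mathrm{median}(h)| > \max(\texttt{abs\_floor},\;
   k \cdot \mathrm{MAD}(h)) $$

with defaults `abs_floor` = 0.02 (an absolute het-rate gap of two
percentage points), `k` = 5, and MAD the **raw** median absolute deviation
(constant 1, not 1.4826): in groups of four replicates of the same genome
the clean spread is binomial noise of order $10^{-3}$, and the raw MAD keeps
the rule's scale interpretable as "five typical within-group deviations".
The absolute floor dominates in clean groups and prevents flagging noise;
the MAD term adapts when a group is genuinely heterogeneous. Arrays with
call rate below `call_rate_min` (default 0.95) are flagged `low_call_rate`.
Groups of one cannot support the het rule (noted in the report); in groups
of two, a gap above the floor flags the member farther from the
experiment-wide median, since the within-pair median cannot identify the
outlier. Every flag records its rule, statistic, reference value and
threshold.

`exclusion_impact()` then recomputes the intra-level summaries with and
without the flagged arrays; on generated data with planted bad arrays the
with-flags means are strictly lower for affected groups, and untouched
groups are identical — the quantitative form of "replicates catch what
vendor QC misses".

## The error-only odds-ratio surface

Each grid cell $(p, c)$ does the following, `reps` times:

1. **Baseline**: deterministic genotype counts for 2,000 cases and 3,000
   controls with minor-allele count *exactly* $2np$ — het count
   $h = \mathrm{round}(2np(1-p))$, decremented by one if the remainder is
   odd so the leftover minor alleles pair into homozygotes. Identical
   construction in both populations makes the allelic odds ratio exactly 1;
   a stochastic baseline would contaminate the error-only OR distribution.
   MAFs for which $2np$ is not an integer are rejected (the default grids
   are aligned); $p = 0$ is rejected as degenerate.
2. **Noise**: each individual keeps its genotype with probability $c$, else
   moves uniformly to another class — applied independently to cases and
   controls, drawn at count level as one multinomial per source class
   (distributionally identical to a per-individual loop; tested, not
   assumed). Population sizes are conserved exactly.
3. **Odds ratio**: the allelic OR from the 2×2 allele table, with the
   Haldane–Anscombe correction (0.5 to all cells) when a cell is zero.
   The allelic OR is the GWAS-standard additive-model effect measure; the
   genotypic OR is out of scope.

The cell statistic is the nearest-rank 95th percentile (index
$\lceil 0.95 R \rceil$ of the ascending sample) — the "top 5%" spurious
odds ratio. Cells at $c = 1$ are exactly 1 in every repetition. Each cell
derives its RNG stream deterministically from (seed, row, column), so any
sub-grid reproduces the full grid's values.

Expected shape, asserted in the acceptance tests at `reps = 5000` on a
3×3 sub-grid: the percentile OR is non-increasing in $c$ and in $p$, and a
5,000/5,000 cohort gives strictly smaller percentile ORs than 2,000/3,000
at $(p, c) = (0.05, 0.94)$.

## Panel harmonization

Cross-platform comparison first reconciles the two SNP panels by id:
mappings `identical`, `swapped` (major/minor exchanged; homozygous dosages
remapped $0 \leftrightarrow 2$), `strand_flipped` (complementary alleles;
dosages unchanged), and `strand_flipped_swapped`. A/T and C/G SNPs are
dropped as `strand_ambiguous` — with only the allele pair in hand their
strand genuinely cannot be resolved — and irreconcilable allele pairs as
`allele_mismatch`. The shared-SNP count is reported alongside every
cross-platform concordance. Remapping is idempotent: a second harmonization
of an already-harmonized matrix changes no calls.

## Problem sizes and numerical choices

The package's own test battery uses $10^5$ SNPs for the closed-form
calibrations (Monte-Carlo SE of a pair concordance
$\approx \sqrt{c(1-c)/n} \approx 2.4\times10^{-4}$ at $e=0.003$, so a
5-SE band separates cleanly from miscalibration), 2,000–5,000 SNPs for QC
recovery (the outlier displacement, about $0.7\,\times$ `het_inflation`,
dwarfs binomial noise there), and 2,000–5,000 repetitions per simulation
cell. Monte-Carlo assertions use 5-standard-error bands; distributional
equivalence uses rank tests at $\alpha = 0.01$; exactness claims
(baseline OR, $c=1$ cells, oracle equality on small fixtures) are asserted
with no tolerance. The `analysis/` drivers run the same pipeline at 20,000
SNPs and a full 40×61 simulation grid at 2,000 repetitions — choices that
keep a complete run interactive on one core while every reported average
has SE well below its printed precision.

All randomness flows through explicit integer seeds (callers' RNG state is
saved and restored); identical seeds give bit-identical matrices, TSVs and
surfaces.

## Limitations

* The error model is exchangeable across SNPs and replicates; real arrays
  fail in structured ways (probe chemistry, DNA quality, batch effects).
  Concordance *measurement* is unaffected; simulation-based claims about
  real platforms are not supported.
* The QC thresholds operationalize a qualitative rule ("very disparate
  heterozygosity"); defaults are sensible for groups of ~4 replicates and
  are echoed into every report, but they are conventions, not estimates.
* Vendor quality metrics (per-array QC scores, GC scores) are intentionally
  absent: the analysis's point is what replicate comparison adds beyond
  them.
* No p-values or power are attached to the simulated odds ratios; the
  surface bounds error-attributable effect size, nothing more.
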