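# genorep

Genotype reproducibility analysis with technical replicates.

SNP-array genotypes drive case-control association studies in which most
markers carry small effects, so a per-call error rate of a few tenths of a
percent — invisible to vendor QC — can matter. `genorep` is for analysts who
want to quantify that: it measures pairwise genotype concordance between
technical replicates (within an experiment, across laboratories on one
platform, and across platforms), runs replicate-based array QC
(heterozygosity and call-rate outliers inside replicate groups), and
simulates how much spurious allelic odds ratio genotype discordance alone
can generate in a case-control cohort.

## The statistics

**Concordance** between two call vectors over N SNPs:

    C = ( Σ_k 1[G_i^k = G_j^k] ) / N'

where `N'` is the co-called SNP count (default) or all N SNPs (`strict`
mode). Under the package's uniform-reassignment error model with per-call
error rate e, two replicates of one subject have expected concordance
`1 − 2e + 1.5e²`, which is how the synthetic studies are calibrated to
published reproducibility figures.

**Replicate QC**: within each (subject, experiment) group an array is
flagged when its heterozygote rate deviates from the group median by more
than `max(0.02, 5 × MAD)`, or when its call rate falls below 0.95.

**Error-only odds ratio**: cases (n = 2,000) and controls (n = 3,000) are
built at an exact shared MAF (allelic OR exactly 1), each individual's
genotype is retained with probability c or reassigned, and the allelic odds
ratio of the perturbed table is recorded; the nearest-rank 95th percentile
over 50,000 repetitions per (MAF, concordance) cell is the "top 5%"
spurious OR surface.

## Worked example

```r
library(genorep)

# truth genomes for 6 subjects under HWE, then a 4-replicate study with
# per-call error 0.003 in one experiment
truth  <- generate_truth(6, 100000, maf_low = 0.05, maf_high = 0.5, seed = 1)
design <- reference_design()
e1     <- design[design$experiment_id == "E1", ]
gm     <- simulate_replicate_study(truth, e1, error_model(0.003), seed = 2)

pairs <- concordance_pairs(gm, e1)
tail(summarize_reproducibility(pairs, "intra"), 1)
#>    level subject group mean_concordance sd_concordance n_pairs
#> 7  intra     ALL   ALL        0.9939286   0.0002347662      36
```

The overall mean over the 36 intra-subject pairs sits at the closed form
`1 − 2(0.003) + 1.5(0.003)² = 0.99401` — 99.40% — with a between-pair SD a
few parts in 10⁴, i.e. the study reproduces its calibrated reproducibility.
(The mean varies by a few 10⁻⁵ with the seed.)

The full pipeline — simulated study with injected low-quality arrays,
QC, concordance summaries, odds-ratio surface — is driven by the numbered
scripts:

```sh
Rscript analysis/01_simulate_study.R    # calls.tsv, design.tsv
Rscript analysis/02_replicate_qc.R      # flags 6 arrays; retained 23 19 24 24 24
Rscript analysis/03_concordance.R       # summaries at the three levels
Rscript analysis/04_error_simulation.R  # 40 x 61 grid of top-5% odds ratios
```

Stage 4 prints, for concordance 0.94 (2,000 repetitions per cell):

    maf  percentile_or
    0.01      1.176882
    0.05      1.114654
    0.10      1.073594
    0.20      1.046140
    0.40      1.031427

read: at MAF 0.01, genotyping error alone (6% discordance) produces a top-5%
spurious odds ratio of ~1.18 — the scale of many reported GWAS effects. The
inflation shrinks as MAF or concordance grows.

See `vignettes/replicate-concordance.Rmd` for the models, parameter
rationale and limitations.

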