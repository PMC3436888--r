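Package: genorep
Title: Genotype Reproducibility Analysis with Technical Replicates
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing SNP-array genotyping reproducibility with
    technical replicates: a synthetic replicate-study generator (Hardy-Weinberg
    truth genotypes, per-replicate call error and no-call rates, injected
    low-quality arrays), a pairwise genotype-concordance engine with
    intra-laboratory, inter-laboratory and inter-platform summaries,
    replicate-based array quality control (call-rate and heterozygosity-outlier
    flagging), and a Monte-Carlo simulator quantifying the spurious
    case-control odds ratio attributable solely to genotype discordance as a
    top-percentile surface over the minor-allele-frequency by concordance grid.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
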