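test_that("truth generation respects degenerate and extreme allele frequencies", {
  tr0 <- generate_truth(3, 200, maf_low = 0, maf_high = 0, seed = 1)
  expect_true(all(tr0$truth$calls == 0L))
  expect_false(anyNA(tr0$truth$calls))

  n <- 100000
  tr5 <- generate_truth(6, n, maf_low = 0.5, maf_high = 0.5, seed = 2)
  het_frac <- mean(tr5$truth$calls == 1L)
  se <- sqrt(0.25 / (6 * n))
  expect_lt(abs(het_frac - 0.5), 5 * se)
})

test_that("truth generation is reproducible and seed-sensitive", {
  a <- generate_truth(4, 500, seed = 11)
  b <- generate_truth(4, 500, seed = 11)
  c <- generate_truth(4, 500, seed = 12)
  expect_identical(a$truth$calls, b$truth$calls)
  expect_identical(a$panel, b$panel)
  expect_false(identical(a$truth$calls, c$truth$calls))
  expect_error(generate_truth(2, 100, maf_low = -0.1, seed = 1), "maf")
  expect_error(generate_truth(2, 100, maf_low = 0.3, maf_high = 0.2,
                              seed = 1), "maf")
})

test_that("truth genotype frequencies fit HWE expectations (tally oracle)", {
  n_subj <- 50; n_snp <- 1000
  tr <- generate_truth(n_subj, n_snp, maf_low = 0.05, maf_high = 0.5,
                       seed = 3)
  tal <- oracle_genotype_tally(tr$truth$calls)
  # aggregate observed vs expected class totals, chi-square with 2 df
  p <- tr$panel$maf
  expected <- cbind((1 - p)^2, 2 * p * (1 - p), p^2) * n_subj
  obs <- colSums(tal)
  exp_tot <- colSums(expected)
  chisq <- sum((obs - exp_tot)^2 / exp_tot)
  expect_lt(chisq, qchisq(0.999, df = 2))
  # the oracle tally is itself consistent with a direct table()
  expect_identical(sum(tal), length(tr$truth$calls))
})

test_that("replicates are exact copies when noise is off", {
  tr <- generate_truth(6, 300, seed = 4)
  design <- reference_design()
  gm <- simulate_replicate_study(tr, design, error_model(0, 0), seed = 5)
  expect_identical(nrow(gm$calls), nrow(design))
  for (i in seq_len(nrow(design))) {
    expect_identical(unname(gm$calls[design$sample_id[i], ]),
                     unname(tr$truth$calls[design$subject_code[i], ]))
  }
  # 24 arrays per experiment in the reference design
  expect_identical(as.integer(table(design$experiment_id)), rep(24L, 5))
})

test_that("uniform_other error calibrates to the closed-form pair concordance", {
  n <- 100000
  e <- 0.003
  tr <- generate_truth(1, n, seed = 6)
  design <- make_toy_design(c("A-1", "A-2"), c("A", "A"))
  gm <- simulate_replicate_study(tr, design, error_model(e), seed = 7)
  conc <- pairwise_concordance(gm$calls["A-1", ], gm$calls["A-2", ])
  closed <- 1 - 2 * e + 1.5 * e^2
  se <- sqrt(closed * (1 - closed) / n)
  expect_lt(abs(conc$concordance - closed), 5 * se)

  # expected fraction of calls differing from truth is e * (1 - nocall_rate)
  nc <- 0.1
  gm2 <- simulate_replicate_study(tr, design, error_model(e, nc), seed = 8)
  called <- !is.na(gm2$calls["A-1", ])
  diff_frac <- mean(gm2$calls["A-1", called] != tr$truth$calls[1, called])
  se2 <- sqrt(e * (1 - e) / sum(called))
  expect_lt(abs(diff_frac - e), 5 * se2)
  # no-call rate itself
  expect_lt(abs(mean(!called) - nc), 5 * sqrt(nc * (1 - nc) / n))
})

test_that("direct_pairwise flips give expected concordance 1 - d vs the reference", {
  n <- 100000
  d <- 0.012
  tr <- generate_truth(2, n, seed = 9)
  design <- make_toy_design(c("A-1", "B-1"), c("A", "B"))
  ref <- simulate_replicate_study(tr, design, error_model(0), seed = 10)
  noisy <- simulate_replicate_study(
    tr, design, error_model(d, scheme = "direct_pairwise"),
    seed = 11, reference = ref)
  for (id in design$sample_id) {
    conc <- pairwise_concordance(ref$calls[id, ], noisy$calls[id, ])
    expect_lt(abs(conc$concordance - (1 - d)),
              5 * sqrt(d * (1 - d) / n))
  }
  expect_error(
    simulate_replicate_study(tr, design,
                             error_model(d, scheme = "direct_pairwise"),
                             seed = 11),
    "reference")
})

test_that("study simulation rejects unknown subjects and per-experiment rates work", {
  tr <- generate_truth(2, 100, seed = 12)  # subjects A, B
  bad <- make_toy_design("Z-1", "Z")
  expect_error(simulate_replicate_study(tr, bad, error_model(0), seed = 1),
               "subjects")
  # per-experiment no-call rates land on the right samples
  design <- rbind(make_toy_design("A-1-E1", "A", experiment = "E1"),
                  make_toy_design("A-1-E2", "A", experiment = "E2"))
  model <- error_model(0, nocall_rate = c(E1 = 0, E2 = 0.5))
  gm <- simulate_replicate_study(tr, study_design(design), model, seed = 13)
  expect_identical(sum(is.na(gm$calls["A-1-E1", ])), 0L)
  expect_gt(sum(is.na(gm$calls["A-1-E2", ])), 0L)
})

test_that("low-quality injection degrades exactly one sample, by the stated amounts", {
  n <- 100000
  tr <- generate_truth(1, n, seed = 14)
  design <- make_toy_design(c("A-1", "A-2"), c("A", "A"))
  gm <- simulate_replicate_study(tr, design, error_model(0), seed = 15)

  # identity when both knobs are zero
  same <- inject_low_quality(gm, "A-1", 0, 0, seed = 16)
  expect_identical(same$calls, gm$calls)

  before <- oracle_sample_stats(gm$calls)
  n_hom <- sum(!is.na(gm$calls["A-1", ]) & gm$calls["A-1", ] != 1L)
  bad <- inject_low_quality(gm, "A-1", het_inflation = 0.10, seed = 17)
  after <- oracle_sample_stats(bad$calls)
  gained <- after$n_het[after$sample_id == "A-1"] -
    before$n_het[before$sample_id == "A-1"]
  # exactly 10% of the homozygous calls (rounded) become HET
  expect_identical(as.integer(gained), as.integer(round(0.10 * n_hom)))

  worse <- inject_low_quality(bad, "A-1", callrate_drop = 0.02, seed = 18)
  after2 <- oracle_sample_stats(worse$calls)
  expect_identical(after2$n_called[after2$sample_id == "A-1"],
                   as.integer(n - round(0.02 * n)))
  # the untouched replicate is bit-identical
  expect_identical(worse$calls["A-2", ], gm$calls["A-2", ])
  expect_error(inject_low_quality(gm, "nope", 0.1, 0, seed = 1), "unknown")
})
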