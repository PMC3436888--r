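test_that("pairwise concordance handles the hand-enumerated 10-SNP case", {
  a <- c(0L, 1L, 2L, 0L, 1L, 2L, 0L, 1L, 2L, NA)
  b <- a
  b[3L] <- 0L          # one discordant call
  # SNP10 is a no-call in a only
  b[10L] <- 1L
  co <- pairwise_concordance(a, b, "co_called")
  expect_identical(co$n_compared, 9L)
  expect_identical(co$n_agree, 8L)
  expect_equal(co$concordance, 8 / 9)
  st <- pairwise_concordance(a, b, "strict")
  expect_identical(st$n_compared, 10L)
  expect_equal(st$concordance, 0.80)
})

test_that("pairwise concordance hits the exact boundary cases", {
  a <- c(0L, 1L, 2L, 1L)
  expect_equal(pairwise_concordance(a, a, "co_called")$concordance, 1)
  expect_equal(pairwise_concordance(a, a, "strict")$concordance, 1)
  b <- (a + 1L) %% 3L  # discordant everywhere
  expect_equal(pairwise_concordance(a, b)$concordance, 0)
  expect_equal(pairwise_concordance(a, b, "strict")$concordance, 0)
  expect_error(pairwise_concordance(a, a[1:3]), "length")
  expect_warning(
    r <- pairwise_concordance(c(NA, NA), c(0L, NA), "co_called"),
    "undefined")
  expect_true(is.na(r$concordance))
  # a shared no-call still counts in the strict denominator
  expect_equal(pairwise_concordance(c(NA, 0L), c(NA, 0L),
                                    "strict")$concordance, 0.5)
})

test_that("concordance is symmetric and strict never exceeds co-called", {
  set.seed(101)
  for (rep in 1:25) {
    n <- sample(5:60, 1)
    a <- sample(c(0:2, NA), n, replace = TRUE)
    b <- sample(c(0:2, NA), n, replace = TRUE)
    if (all(is.na(a) | is.na(b))) next
    for (mode in c("co_called", "strict")) {
      expect_identical(pairwise_concordance(a, b, mode)$concordance,
                       pairwise_concordance(b, a, mode)$concordance)
    }
    co <- pairwise_concordance(a, b, "co_called")$concordance
    st <- pairwise_concordance(a, b, "strict")$concordance
    if (anyNA(a) || anyNA(b)) expect_lte(st, co) else expect_equal(st, co)
  }
})

test_that("concordance matrices match a nested-loop oracle exactly", {
  set.seed(55)
  calls <- matrix(sample(c(0:2, NA), 8 * 50, replace = TRUE,
                         prob = c(0.3, 0.3, 0.3, 0.1)),
                  nrow = 8, dimnames = list(paste0("s", 1:8), NULL))
  gm <- make_toy_matrix(calls)
  for (mode in c("co_called", "strict")) {
    mat <- concordance_matrix(gm, mode = mode)
    expect_true(isSymmetric(unname(mat)))
    expect_equal(unname(diag(mat)), rep(1, 8))
    for (i in 1:7) {
      for (j in (i + 1):8) {
        expect_identical(mat[i, j],
                         oracle_concordance(calls[i, ], calls[j, ],
                                            mode)$concordance)
      }
    }
  }
  expect_error(concordance_matrix(gm, samples = character()), "empty")
  expect_error(concordance_matrix(gm, samples = "ghost"), "not in matrix")
})

test_that("error-free replicates give an all-ones concordance matrix", {
  tr <- generate_truth(1, 200, seed = 21)
  design <- make_toy_design(paste0("A-", 1:4), rep("A", 4))
  gm <- simulate_replicate_study(tr, design, error_model(0), seed = 22)
  mat <- concordance_matrix(gm)
  expect_true(all(mat == 1))
  expect_identical(dim(mat), c(4L, 4L))
})

test_that("the full design produces the documented comparison-level structure", {
  tr <- generate_truth(6, 120, seed = 23)
  design <- reference_design()
  gm <- simulate_replicate_study(tr, design, error_model(0.01), seed = 24)
  pairs <- concordance_pairs(gm, design)
  # per subject: C(20,2) = 190 same-subject pairs across the 5 experiments
  expect_identical(nrow(pairs), 6L * 190L)

  intra <- summarize_reproducibility(pairs, "intra")
  # 6 subjects x 5 experiments + overall; C(4,2) = 6 pairs each
  expect_identical(nrow(intra), 31L)
  expect_true(all(intra$n_pairs[intra$subject != "ALL"] == 6L))
  expect_identical(intra$n_pairs[intra$subject == "ALL"], 180L)

  lab <- summarize_reproducibility(pairs, "inter_lab")
  # experiment pairs: E1-E2, E1-E3, E2-E3 (Affy6) and E4-E5 (Illu1M)
  expect_identical(sort(unique(lab$group[lab$subject != "ALL"])),
                   c("E1-E2", "E1-E3", "E2-E3", "E4-E5"))
  # 4 x 4 = 16 cross-experiment pairs per subject per experiment pair
  expect_true(all(lab$n_pairs[lab$subject != "ALL"] == 16L))

  platf <- summarize_reproducibility(pairs, "inter_platform")
  expect_identical(sort(unique(platf$group[platf$subject != "ALL"])),
                   c("E1-E4", "E1-E5", "E2-E4", "E2-E5", "E3-E4", "E3-E5"))
  expect_identical(platf$n_pairs[platf$subject == "ALL"], 6L * 6L * 16L)
})

test_that("perfect replicates summarize to mean 1 and sd 0", {
  tr <- generate_truth(2, 80, seed = 25)
  design <- reference_design()
  design <- design[design$subject_code %in% c("A", "B"), ]
  gm <- simulate_replicate_study(tr, design, error_model(0), seed = 26)
  pairs <- concordance_pairs(gm, design)
  for (lv in c("intra", "inter_lab", "inter_platform")) {
    s <- summarize_reproducibility(pairs, lv)
    expect_true(all(s$mean_concordance == 1))
    expect_true(all(s$sd_concordance == 0))
  }
  # single-pair groups must report sd exactly 0
  one <- pairs[1, , drop = FALSE]
  s1 <- summarize_reproducibility(one, "intra")
  expect_true(all(s1$sd_concordance == 0))
})

test_that("panel harmonization classifies allele mappings and drops ambiguity", {
  pa <- snp_panel(paste0("rs", 1:6), rep("1", 6), 1:6,
                  allele_major = c("A", "A", "A", "C", "A", "G"),
                  allele_minor = c("G", "G", "G", "A", "T", "C"),
                  maf = rep(0.2, 6))
  pb <- snp_panel(c(paste0("rs", 1:5), "rsX"), rep("1", 6), 1:6,
                  allele_major = c("A", "G", "T", "T", "A", "A"),
                  allele_minor = c("G", "A", "C", "G", "T", "C"),
                  maf = rep(0.2, 6))
  h <- harmonize_panels(pa, pb)
  m <- setNames(h$shared$mapping, h$shared$snp_id)
  expect_identical(unname(m["rs1"]), "identical")
  expect_identical(unname(m["rs2"]), "swapped")
  expect_identical(unname(m["rs3"]), "strand_flipped")
  expect_identical(unname(m["rs4"]), "strand_flipped_swapped")
  d <- setNames(h$dropped$reason, h$dropped$snp_id)
  expect_identical(unname(d["rs5"]), "strand_ambiguous")  # A/T palindromic
  expect_false("rsX" %in% c(h$shared$snp_id, h$dropped$snp_id))

  # identical panels: everything shared, nothing dropped
  h2 <- harmonize_panels(pa, pa)
  # the A/T and G/C SNPs stay ambiguous even against an identical panel
  expect_identical(sort(h2$dropped$snp_id), c("rs5", "rs6"))
  expect_true(all(h2$shared$mapping == "identical"))

  expect_warning(
    h3 <- harmonize_panels(
      pa, snp_panel("zz", "1", 1, "A", "G", 0.1)), "no SNPs")
  expect_identical(nrow(h3$shared), 0L)
})

test_that("harmonized calls compare equal across a strand flip and remap is idempotent", {
  # same biological genotypes reported on opposite strands with swapped
  # major/minor: rs1 A/G vs T/C (flip), rs2 A/G vs C/T (flip + swap)
  pa <- snp_panel(c("rs1", "rs2"), c("1", "1"), 1:2, c("A", "A"),
                  c("G", "G"), c(0.2, 0.2))
  pb <- snp_panel(c("rs1", "rs2"), c("1", "1"), 1:2, c("T", "C"),
                  c("C", "T"), c(0.2, 0.2))
  calls_a <- matrix(c(0L, 1L, 2L, 0L), nrow = 2,
                    dimnames = list(c("x", "y"), NULL))
  # same genotypes in b's orientation: rs1 dosage identical, rs2 inverted
  calls_b <- calls_a
  calls_b[, 2L] <- 2L - calls_b[, 2L]
  ga <- genotype_matrix(pa, calls_a)
  gb <- genotype_matrix(pb, calls_b)
  h <- harmonize_panels(pa, pb)
  expect_identical(setNames(h$shared$mapping, h$shared$snp_id),
                   c(rs1 = "strand_flipped", rs2 = "strand_flipped_swapped"))
  gb_h <- apply_harmonization(gb, h)
  for (s in c("x", "y")) {
    expect_equal(pairwise_concordance(ga$calls[s, ],
                                      gb_h$calls[s, ])$concordance, 1)
  }
  # idempotence: after the remap the dosages sit on the a-orientation (the
  # letters stay on b's strand), so a second harmonization against panel a
  # involves no further swap and leaves the calls unchanged
  h2 <- harmonize_panels(pa, gb_h$panel)
  expect_true(all(h2$shared$mapping %in% c("identical", "strand_flipped")))
  expect_identical(apply_harmonization(gb_h, h2)$calls, gb_h$calls)
})
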