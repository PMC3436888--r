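#' Pairwise genotype concordance
#'
#' The core reproducibility statistic: the fraction of SNPs at which two call
#' sets of the same (harmonized) panel report the same genotype. Two
#' denominators are supported:
#' \describe{
#'   \item{`co_called`}{only SNPs called in both samples count (default;
#'     standard practice when no-calls are present).}
#'   \item{`strict`}{all `N` panel SNPs count in the denominator; only SNPs
#'     called and equal in both samples count as agreeing, so any no-call
#'     (one-sided or shared) reduces the concordance and strict concordance
#'     never exceeds co-called concordance.}
#' }
#'
#' @param a,b integer call vectors (dosage coding, `NA` = no-call) of equal
#'   length, bound to the same panel.
#' @param mode `"co_called"` or `"strict"`.
#' @param sample_i,sample_j optional sample labels carried into the result.
#' @return A `concordance_result` list with fields `sample_i`, `sample_j`,
#'   `n_total_snps`, `n_compared`, `n_agree`, `mode`, `concordance`.
#'   `concordance` is `NA` (with a warning) when the denominator is zero.
#' @export
pairwise_concordance <- function(a, b, mode = c("co_called", "strict"),
                                 sample_i = "a", sample_j = "b") {
  mode <- match.arg(mode)
  if (length(a) != length(b)) {
    stop("call vectors must have equal length (same panel)", call. = FALSE)
  }
  if (length(a) < 1L) stop("call vectors must be non-empty", call. = FALSE)
  n_total <- length(a)
  both <- !is.na(a) & !is.na(b)
  if (mode == "co_called") {
    n_compared <- sum(both)
    n_agree <- sum(a[both] == b[both])
    if (n_compared == 0L) {
      warning("no co-called SNPs; concordance undefined", call. = FALSE)
      conc <- NA_real_
    } else {
      conc <- n_agree / n_compared
    }
  } else {
    n_compared <- n_total
    n_agree <- sum(both & a == b)
    conc <- n_agree / n_total
  }
  structure(list(
    sample_i = sample_i, sample_j = sample_j,
    n_total_snps = n_total, n_compared = n_compared, n_agree = n_agree,
    mode = mode, concordance = conc
  ), class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("%s vs %s [%s]: %d/%d = %.4f\n", x$sample_i, x$sample_j,
              x$mode, x$n_agree, x$n_compared, x$concordance))
  invisible(x)
}

#' Pairwise concordance matrix
#'
#' Symmetric sample-by-sample concordance table (the numeric content of a
#' replicate heatmap); the diagonal is 1.
#'
#' @param matrix a `genotype_matrix`.
#' @param samples sample ids to include (default: all).
#' @param mode concordance mode, see [pairwise_concordance()].
#' @return A symmetric numeric matrix with dimnames = sample ids and
#'   attribute `mode`.
#' @export
concordance_matrix <- function(matrix, samples = NULL,
                               mode = c("co_called", "strict")) {
  mode <- match.arg(mode)
  stopifnot(inherits(matrix, "genotype_matrix"))
  if (is.null(samples)) samples <- rownames(matrix$calls)
  if (length(samples) == 0L) stop("empty sample selection", call. = FALSE)
  missing <- setdiff(samples, rownames(matrix$calls))
  if (length(missing)) {
    stop("samples not in matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  calls <- matrix$calls[samples, , drop = FALSE]
  n <- length(samples)
  out <- diag(nrow = n)
  dimnames(out) <- list(samples, samples)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        r <- pairwise_concordance(calls[i, ], calls[j, ], mode = mode,
                                  sample_i = samples[i],
                                  sample_j = samples[j])
        out[i, j] <- out[j, i] <- r$concordance
      }
    }
  }
  attr(out, "mode") <- mode
  out
}

#' All same-subject replicate pairs with their concordance
#'
#' Enumerates every unordered pair of samples sharing a subject and computes
#' the pairwise concordance, annotated with the experiments and platforms of
#' the two members. This long table is the input of
#' [summarize_reproducibility()].
#'
#' @param matrix a `genotype_matrix` (or a list of two matrices `a` and `b`
#'   for cross-set comparisons; pairs are then one sample from each set).
#' @param design a [study_design()] covering the samples (for a cross-set
#'   comparison, a list of two designs).
#' @param mode concordance mode.
#' @return data.frame with one row per pair: sample ids, subject, experiment
#'   and platform of each member, counts and concordance.
#' @export
concordance_pairs <- function(matrix, design, mode = c("co_called", "strict")) {
  mode <- match.arg(mode)
  stopifnot(inherits(matrix, "genotype_matrix"))
  design <- study_design(design)
  present <- design$sample_id %in% rownames(matrix$calls)
  if (!all(present)) {
    stop("design samples missing from matrix: ",
         paste(design$sample_id[!present], collapse = ", "), call. = FALSE)
  }
  rows <- list()
  k <- 0L
  for (subj in unique(design$subject_code)) {
    ids <- design$sample_id[design$subject_code == subj]
    if (length(ids) < 2L) next
    meta <- design[match(ids, design$sample_id), ]
    for (i in seq_len(length(ids) - 1L)) {
      for (j in (i + 1L):length(ids)) {
        r <- pairwise_concordance(matrix$calls[ids[i], ],
                                  matrix$calls[ids[j], ], mode = mode,
                                  sample_i = ids[i], sample_j = ids[j])
        k <- k + 1L
        rows[[k]] <- data.frame(
          sample_i = ids[i], sample_j = ids[j], subject = subj,
          experiment_i = meta$experiment_id[i],
          experiment_j = meta$experiment_id[j],
          platform_i = meta$platform[i], platform_j = meta$platform[j],
          n_total_snps = r$n_total_snps, n_compared = r$n_compared,
          n_agree = r$n_agree, concordance = r$concordance,
          mode = mode, stringsAsFactors = FALSE
        )
      }
    }
  }
  if (k == 0L) {
    warning("no same-subject pairs found", call. = FALSE)
    return(data.frame())
  }
  do.call(rbind, rows)
}

#' Reproducibility summaries at the three comparison levels
#'
#' Aggregates same-subject pairwise concordances into the three levels of a
#' replicate study:
#' \describe{
#'   \item{`intra`}{same experiment (same platform, same laboratory); grouped
#'     by experiment.}
#'   \item{`inter_lab`}{different experiments on the same platform; grouped by
#'     experiment pair.}
#'   \item{`inter_platform`}{different platforms; grouped by experiment pair.}
#' }
#' Means and sample (n-1) standard deviations are reported per subject per
#' group and overall (subject = group = `"ALL"`).
#'
#' @param pairs output of [concordance_pairs()].
#' @param level `"intra"`, `"inter_lab"` or `"inter_platform"`.
#' @return data.frame with columns `level`, `subject`, `group`,
#'   `mean_concordance`, `sd_concordance`, `n_pairs`.
#' @export
summarize_reproducibility <- function(pairs,
                                      level = c("intra", "inter_lab",
                                                "inter_platform")) {
  level <- match.arg(level)
  empty <- data.frame(level = character(), subject = character(),
                      group = character(), mean_concordance = numeric(),
                      sd_concordance = numeric(), n_pairs = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(pairs) == 0L) {
    warning("no pairs at level ", level, call. = FALSE)
    return(empty)
  }
  sel <- switch(level,
    intra = pairs$experiment_i == pairs$experiment_j,
    inter_lab = pairs$experiment_i != pairs$experiment_j &
      pairs$platform_i == pairs$platform_j,
    inter_platform = pairs$platform_i != pairs$platform_j
  )
  sub <- pairs[sel, , drop = FALSE]
  if (nrow(sub) == 0L) {
    warning("no pairs at level ", level, call. = FALSE)
    return(empty)
  }
  grp <- ifelse(sub$experiment_i == sub$experiment_j, sub$experiment_i,
                paste(pmin(sub$experiment_i, sub$experiment_j),
                      pmax(sub$experiment_i, sub$experiment_j), sep = "-"))
  summarise_block <- function(conc, subject, group) {
    data.frame(level = level, subject = subject, group = group,
               mean_concordance = mean(conc),
               sd_concordance = if (length(conc) > 1L) stats::sd(conc) else 0,
               n_pairs = length(conc), stringsAsFactors = FALSE)
  }
  keys <- split(seq_len(nrow(sub)), list(sub$subject, grp), drop = TRUE)
  per <- do.call(rbind, lapply(keys, function(idx) {
    summarise_block(sub$concordance[idx], sub$subject[idx[1L]], grp[idx[1L]])
  }))
  per <- per[order(per$group, per$subject), ]
  overall <- summarise_block(sub$concordance, "ALL", "ALL")
  rownames(per) <- NULL
  rbind(per, overall)
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Harmonize two SNP panels for cross-platform comparison
#'
#' Matches SNPs by id and reconciles the allele pairs of the two panels:
#' `identical` (same major/minor), `swapped` (major and minor exchanged, so
#' homozygous calls must be remapped), `strand_flipped` (reverse-strand
#' complement) or `strand_flipped_swapped`. A/T and C/G SNPs are dropped as
#' `strand_ambiguous` (their strand cannot be resolved from the allele pair),
#' and SNPs whose alleles cannot be reconciled are dropped as
#' `allele_mismatch`.
#'
#' @param panel_a,panel_b [snp_panel()] objects.
#' @return A `panel_harmonization` list: `shared` (data.frame `snp_id`,
#'   `mapping`), `dropped` (data.frame `snp_id`, `reason`).
#' @export
harmonize_panels <- function(panel_a, panel_b) {
  panel_a <- validate_snp_panel(as.data.frame(panel_a))
  panel_b <- validate_snp_panel(as.data.frame(panel_b))
  common <- intersect(panel_a$snp_id, panel_b$snp_id)
  if (length(common) == 0L) {
    warning("panels share no SNPs; downstream concordance is undefined",
            call. = FALSE)
    return(structure(list(
      shared = data.frame(snp_id = character(), mapping = character(),
                          stringsAsFactors = FALSE),
      dropped = data.frame(snp_id = character(), reason = character(),
                           stringsAsFactors = FALSE)
    ), class = "panel_harmonization"))
  }
  ia <- match(common, panel_a$snp_id)
  ib <- match(common, panel_b$snp_id)
  maj_a <- panel_a$allele_major[ia]; min_a <- panel_a$allele_minor[ia]
  maj_b <- panel_b$allele_major[ib]; min_b <- panel_b$allele_minor[ib]
  cmaj_a <- COMPLEMENT[maj_a]; cmin_a <- COMPLEMENT[min_a]

  palindromic_a <- maj_a == COMPLEMENT[min_a]
  palindromic_b <- maj_b == COMPLEMENT[min_b]
  mapping <- rep(NA_character_, length(common))
  mapping[maj_a == maj_b & min_a == min_b] <- "identical"
  mapping[is.na(mapping) & maj_a == min_b & min_a == maj_b] <- "swapped"
  mapping[is.na(mapping) & cmaj_a == maj_b & cmin_a == min_b] <-
    "strand_flipped"
  mapping[is.na(mapping) & cmaj_a == min_b & cmin_a == maj_b] <-
    "strand_flipped_swapped"

  reason <- rep(NA_character_, length(common))
  reason[palindromic_a | palindromic_b] <- "strand_ambiguous"
  reason[is.na(reason) & is.na(mapping)] <- "allele_mismatch"

  keep <- is.na(reason)
  structure(list(
    shared = data.frame(snp_id = common[keep], mapping = mapping[keep],
                        stringsAsFactors = FALSE),
    dropped = data.frame(snp_id = common[!keep], reason = reason[!keep],
                         stringsAsFactors = FALSE)
  ), class = "panel_harmonization")
}

#' Apply a panel harmonization to a call matrix
#'
#' Restricts a genotype matrix to the harmonized shared SNPs (in shared
#' order) and remaps calls of `swapped` / `strand_flipped_swapped` SNPs
#' (homozygous major and minor exchange; strand flips alone do not change the
#' genotype class). Applying the same harmonization twice is a no-op on the
#' already-harmonized side.
#'
#' @param matrix a `genotype_matrix` on the "b" panel of the harmonization.
#' @param harmonization result of [harmonize_panels()].
#' @param side `"b"` (default) remaps calls per the mapping; `"a"` only
#'   subsets to the shared SNPs.
#' @return A `genotype_matrix` on the shared SNPs.
#' @export
apply_harmonization <- function(matrix, harmonization, side = c("b", "a")) {
  side <- match.arg(side)
  stopifnot(inherits(matrix, "genotype_matrix"),
            inherits(harmonization, "panel_harmonization"))
  shared <- harmonization$shared
  missing <- setdiff(shared$snp_id, matrix$panel$snp_id)
  if (length(missing)) {
    stop("matrix panel lacks shared SNPs: ",
         paste(utils::head(missing), collapse = ", "), call. = FALSE)
  }
  idx <- match(shared$snp_id, matrix$panel$snp_id)
  calls <- matrix$calls[, idx, drop = FALSE]
  panel <- as.data.frame(matrix$panel)[idx, ]
  if (side == "b") {
    swap <- shared$mapping %in% c("swapped", "strand_flipped_swapped")
    if (any(swap)) {
      block <- calls[, swap, drop = FALSE]
      calls[, swap] <- 2L - block  # 0 <-> 2, het fixed
      ## panel bookkeeping: after remap the matrix is on the "a" orientation
      tmp <- panel$allele_major[swap]
      panel$allele_major[swap] <- panel$allele_minor[swap]
      panel$allele_minor[swap] <- tmp
      panel$maf[swap] <- pmin(1 - panel$maf[swap], 0.5)
    }
  }
  rownames(panel) <- NULL
  genotype_matrix(validate_snp_panel(panel), calls)
}

#' Plot a concordance matrix
#'
#' Minimal base-graphics heat image of a [concordance_matrix()]; the numeric
#' TSV written by [write_matrix_tsv()] is the analysis surface, this plot is
#' a convenience.
#'
#' @param mat symmetric concordance matrix.
#' @param ... passed to [graphics::image()].
#' @export
plot_concordance_matrix <- function(mat, ...) {
  n <- nrow(mat)
  graphics::image(seq_len(n), seq_len(n), t(mat[n:1, , drop = FALSE]),
                  axes = FALSE, xlab = "", ylab = "", ...)
  graphics::axis(1, at = seq_len(n), labels = colnames(mat), las = 2,
                 cex.axis = 0.6)
  graphics::axis(2, at = seq_len(n), labels = rev(rownames(mat)), las = 2,
                 cex.axis = 0.6)
  invisible(mat)
}
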