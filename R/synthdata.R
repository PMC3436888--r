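#' Generate truth genotypes under Hardy-Weinberg equilibrium
#'
#' Builds a SNP panel with per-SNP minor allele frequencies drawn uniformly
#' from `[maf_low, maf_high]` and, for each subject, a truth genotype at every
#' SNP drawn from the Hardy-Weinberg probabilities
#' \eqn{((1-p)^2, 2p(1-p), p^2)}. Truth genotypes contain no no-calls.
#'
#' @param n_subjects number of subjects; subject codes are `A`, `B`, ...
#' @param n_snps number of SNPs on the panel.
#' @param maf_low,maf_high bounds of the uniform MAF distribution, within
#'   `[0, 0.5]` with `maf_low <= maf_high`.
#' @param seed integer seed; all randomness in this package flows through
#'   explicit seeds (callers' RNG state is left untouched).
#'
#' @return A list with elements `panel` ([snp_panel()]) and `truth`
#'   ([genotype_matrix()] with one row per subject).
#' @export
generate_truth <- function(n_subjects, n_snps, maf_low = 0.05,
                           maf_high = 0.5, seed) {
  stopifnot(n_subjects >= 1, n_snps >= 1)
  if (!is.finite(maf_low) || !is.finite(maf_high) ||
      maf_low < 0 || maf_high > 0.5 || maf_low > maf_high) {
    stop("maf bounds must satisfy 0 <= maf_low <= maf_high <= 0.5",
         call. = FALSE)
  }
  withr::with_seed(as.integer(seed), {
    maf <- stats::runif(n_snps, maf_low, maf_high)
    nuc <- c("A", "C", "G", "T")
    maj_idx <- sample.int(4L, n_snps, replace = TRUE)
    min_idx <- ((maj_idx - 1L + sample.int(3L, n_snps, replace = TRUE)) %% 4L) + 1L
    panel <- snp_panel(
      snp_id = sprintf("snp%07d", seq_len(n_snps)),
      chromosome = as.character(rep_len(1:22, n_snps)),
      position = seq_len(n_snps) * 1000L,
      allele_major = nuc[maj_idx],
      allele_minor = nuc[min_idx],
      maf = maf
    )
    ## HWE draw: u < (1-p)^2 -> 0; u < (1-p)^2 + 2p(1-p) -> 1; else 2
    p0 <- (1 - maf)^2
    p01 <- p0 + 2 * maf * (1 - maf)
    u <- matrix(stats::runif(n_subjects * n_snps), nrow = n_subjects)
    calls <- matrix(2L, nrow = n_subjects, ncol = n_snps)
    calls[sweep(u, 2L, p01, "<")] <- 1L
    calls[sweep(u, 2L, p0, "<")] <- 0L
    rownames(calls) <- make_subject_codes(n_subjects)
    list(panel = panel, truth = genotype_matrix(panel, calls))
  })
}

make_subject_codes <- function(n) {
  if (n <= 26L) return(LETTERS[seq_len(n)])
  paste0("S", seq_len(n))
}

#' Per-experiment error model
#'
#' @param call_error_rate probability a (called) genotype is reassigned to a
#'   different class; a single value or a vector named by experiment id.
#' @param nocall_rate probability a call becomes a no-call; single value or
#'   vector named by experiment id.
#' @param scheme `"uniform_other"` reassigns an erroneous call uniformly to
#'   one of the two other genotype classes (applied against the subject's
#'   truth); `"direct_pairwise"` applies the same flip rule against a
#'   designated reference call set, so the expected pairwise concordance with
#'   that reference is exactly `1 - call_error_rate`.
#' @return An `error_model` list.
#' @export
error_model <- function(call_error_rate = 0, nocall_rate = 0,
                        scheme = c("uniform_other", "direct_pairwise")) {
  scheme <- match.arg(scheme)
  check_rate <- function(r, what) {
    if (any(!is.finite(r)) || any(r < 0) || any(r > 1)) {
      stop(what, " must be within [0, 1]", call. = FALSE)
    }
    r
  }
  structure(list(
    call_error_rate = check_rate(call_error_rate, "call_error_rate"),
    nocall_rate = check_rate(nocall_rate, "nocall_rate"),
    scheme = scheme
  ), class = "error_model")
}

rate_for <- function(rate, experiment_id) {
  if (is.null(names(rate))) return(rep_len(rate, length(experiment_id)))
  missing <- setdiff(unique(experiment_id), names(rate))
  if (length(missing)) {
    stop("no rate given for experiment(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  unname(rate[experiment_id])
}

#' Simulate a technical-replicate study
#'
#' Every designed sample copies its subject's truth genotypes, then noise is
#' applied independently per call: with probability `nocall_rate` the call
#' becomes a no-call, otherwise with probability `call_error_rate` it is
#' reassigned to another genotype class. Under the `uniform_other` scheme the
#' replacement class is drawn uniformly from the two other classes. Under
#' `direct_pairwise` the calls are derived from `reference` (a call set with
#' the same sample ids as the design) by the same flip rule, giving expected
#' concordance exactly `1 - call_error_rate` against the reference.
#'
#' Errors are independent across replicates and SNPs; plate layout is carried
#' as metadata only (no batch effects).
#'
#' @param truth result of [generate_truth()] or a `genotype_matrix` whose
#'   rownames are subject codes.
#' @param design a [study_design()].
#' @param model an [error_model()].
#' @param seed integer seed.
#' @param reference `genotype_matrix` required by the `direct_pairwise`
#'   scheme; row per design sample id.
#' @return A [genotype_matrix()] with one row per design row.
#' @export
simulate_replicate_study <- function(truth, design, model, seed,
                                     reference = NULL) {
  if (is.list(truth) && !inherits(truth, "genotype_matrix") &&
      !is.null(truth$truth)) {
    truth <- truth$truth
  }
  stopifnot(inherits(truth, "genotype_matrix"), inherits(model, "error_model"))
  design <- study_design(design)
  unknown <- setdiff(design$subject_code, rownames(truth$calls))
  if (length(unknown)) {
    stop("design subjects missing from truth: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (model$scheme == "direct_pairwise") {
    if (is.null(reference)) {
      stop("direct_pairwise scheme requires a reference call set",
           call. = FALSE)
    }
    missing <- setdiff(design$sample_id, rownames(reference$calls))
    if (length(missing)) {
      stop("reference is missing design samples: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    base <- reference$calls[design$sample_id, , drop = FALSE]
  } else {
    base <- truth$calls[design$subject_code, , drop = FALSE]
  }
  rownames(base) <- design$sample_id

  err <- rate_for(model$call_error_rate, design$experiment_id)
  nc <- rate_for(model$nocall_rate, design$experiment_id)
  n_samp <- nrow(base)
  n_snp <- ncol(base)
  n <- n_samp * n_snp

  withr::with_seed(as.integer(seed), {
    ## per-sample rates recycle down columns (matrices are column-major)
    drop_mask <- stats::runif(n) < rep(nc, n_snp)
    flip_mask <- !drop_mask & !is.na(base) & (stats::runif(n) < rep(err, n_snp))
    shift <- 1L + (stats::runif(n) < 0.5)  # uniformly one of the 2 other classes
    out <- base
    out[flip_mask] <- (base[flip_mask] + shift[flip_mask]) %% 3L
    out[drop_mask] <- NA_integer_
    genotype_matrix(truth$panel, out)
  })
}

#' Inject a low-quality array
#'
#' Degrades exactly one sample: a `het_inflation` fraction of its homozygous
#' calls (chosen uniformly) become heterozygous, and a `callrate_drop`
#' fraction of all its calls become no-calls. This emulates the failure mode
#' that replicate-based QC is designed to catch: an array whose heterozygote
#' rate is far out of line with the other replicates of the same subject.
#'
#' @param matrix a `genotype_matrix`.
#' @param sample_id the sample to degrade.
#' @param het_inflation,callrate_drop fractions in `[0, 1]`.
#' @param seed integer seed.
#' @return The modified `genotype_matrix`; all other rows are bit-identical.
#' @export
inject_low_quality <- function(matrix, sample_id, het_inflation = 0,
                               callrate_drop = 0, seed) {
  stopifnot(inherits(matrix, "genotype_matrix"))
  if (!sample_id %in% rownames(matrix$calls)) {
    stop("unknown sample: ", sample_id, call. = FALSE)
  }
  if (het_inflation < 0 || het_inflation > 1 ||
      callrate_drop < 0 || callrate_drop > 1) {
    stop("het_inflation and callrate_drop must be within [0, 1]",
         call. = FALSE)
  }
  row <- matrix$calls[sample_id, ]
  withr::with_seed(as.integer(seed), {
    hom <- which(!is.na(row) & row != 1L)
    n_het <- round(het_inflation * length(hom))
    if (n_het > 0L) row[sample(hom, n_het)] <- 1L
    n_drop <- round(callrate_drop * length(row))
    if (n_drop > 0L) row[sample(length(row), n_drop)] <- NA_integer_
  })
  matrix$calls[sample_id, ] <- row
  matrix
}
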