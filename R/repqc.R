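#' Per-sample call-rate and heterozygosity statistics
#'
#' Exact integer tallies per array: number of called SNPs, call rate
#' (called / total) and heterozygote rate (HET / called). The het rate is the
#' statistic replicate-based QC keys on: contaminated or failed arrays show a
#' het rate far from the other replicates of the same subject even when
#' vendor quality metrics look acceptable.
#'
#' @param matrix a `genotype_matrix`.
#' @return data.frame with columns `sample_id`, `n_snps`, `n_called`,
#'   `call_rate`, `n_het`, `het_rate` (`NA` when nothing was called).
#' @export
per_sample_stats <- function(matrix) {
  stopifnot(inherits(matrix, "genotype_matrix"))
  calls <- matrix$calls
  if (nrow(calls) == 0L) stop("empty genotype matrix", call. = FALSE)
  n_snps <- ncol(calls)
  n_called <- rowSums(!is.na(calls))
  n_het <- rowSums(calls == 1L, na.rm = TRUE)
  data.frame(
    sample_id = rownames(calls),
    n_snps = n_snps,
    n_called = as.integer(n_called),
    call_rate = n_called / n_snps,
    n_het = as.integer(n_het),
    het_rate = ifelse(n_called > 0, n_het / n_called, NA_real_),
    stringsAsFactors = FALSE
  )
}

#' Flag outlier replicates within replicate groups
#'
#' Replicate-based QC: within each (subject, experiment) group a sample is
#' flagged `het_outlier` when its heterozygote rate deviates from the group
#' median by more than `max(abs_floor, k_mad * MAD)` (MAD = raw median
#' absolute deviation of the group's het rates), and `low_call_rate` when its
#' call rate falls below `call_rate_min`. Groups of one cannot support the
#' het rule (the median is the sample itself) and are noted; in groups of two
#' a het gap above `abs_floor` flags the member farther from the
#' experiment-wide median het rate.
#'
#' @param stats output of [per_sample_stats()].
#' @param design a [study_design()] covering the samples.
#' @param abs_floor absolute het-rate deviation floor (default 0.02).
#' @param k_mad MAD multiplier (default 5).
#' @param call_rate_min minimum acceptable call rate (default 0.95).
#' @return A `qc_report` list: `stats` (input joined with design), `flags`
#'   (sample, rule, statistic, reference, threshold), `retained` (sample
#'   ids), `params`, `notes`.
#' @export
flag_outlier_replicates <- function(stats, design, abs_floor = 0.02,
                                    k_mad = 5, call_rate_min = 0.95) {
  design <- study_design(design)
  missing <- setdiff(stats$sample_id, design$sample_id)
  if (length(missing)) {
    stop("samples without design metadata: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  meta <- design[match(stats$sample_id, design$sample_id), ]
  stats <- cbind(stats, meta[c("subject_code", "experiment_id", "platform")])
  flags <- list(); notes <- character(); k <- 0L
  add_flag <- function(id, rule, value, ref, thr) {
    k <<- k + 1L
    flags[[k]] <<- data.frame(sample_id = id, rule = rule,
                              statistic = value, reference = ref,
                              threshold = thr, stringsAsFactors = FALSE)
  }
  ## low call rate: per sample, no group needed
  low <- stats$call_rate < call_rate_min
  for (i in which(low)) {
    add_flag(stats$sample_id[i], "low_call_rate", stats$call_rate[i],
             call_rate_min, call_rate_min)
  }
  ## het outlier: per (subject, experiment) group
  groups <- split(seq_len(nrow(stats)),
                  list(stats$subject_code, stats$experiment_id), drop = TRUE)
  for (idx in groups) {
    het <- stats$het_rate[idx]
    ids <- stats$sample_id[idx]
    if (length(idx) == 1L) {
      notes <- c(notes, paste0("group of size 1 (", ids,
                               "): het_outlier rule not applicable"))
      next
    }
    if (length(idx) == 2L) {
      gap <- abs(het[1L] - het[2L])
      if (is.finite(gap) && gap > abs_floor) {
        exp_med <- stats::median(
          stats$het_rate[stats$experiment_id == stats$experiment_id[idx[1L]]],
          na.rm = TRUE)
        far <- which.max(abs(het - exp_med))
        add_flag(ids[far], "het_outlier", het[far], exp_med, abs_floor)
      }
      next
    }
    med <- stats::median(het, na.rm = TRUE)
    mad_raw <- stats::median(abs(het - med), na.rm = TRUE)
    thr <- max(abs_floor, k_mad * mad_raw)
    out <- which(is.finite(het) & abs(het - med) > thr)
    for (i in out) add_flag(ids[i], "het_outlier", het[i], med, thr)
  }
  flags <- if (k > 0L) do.call(rbind, flags) else
    data.frame(sample_id = character(), rule = character(),
               statistic = numeric(), reference = numeric(),
               threshold = numeric(), stringsAsFactors = FALSE)
  flagged <- unique(flags$sample_id)
  structure(list(
    stats = stats,
    flags = flags,
    retained = setdiff(stats$sample_id, flagged),
    params = list(abs_floor = abs_floor, k_mad = k_mad,
                  call_rate_min = call_rate_min),
    notes = notes
  ), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report: %d samples, %d flagged, %d retained\n",
              nrow(x$stats), length(unique(x$flags$sample_id)),
              length(x$retained)))
  if (nrow(x$flags)) print(x$flags)
  invisible(x)
}

#' Concordance impact of retaining flagged arrays
#'
#' Computes the intra-level reproducibility summary twice -- over all samples
#' and over QC-retained samples only -- and aligns the per-(subject, group)
#' means, quantifying how much including flagged low-quality arrays drags
#' down replicate concordance.
#'
#' @param matrix a `genotype_matrix`.
#' @param design a [study_design()].
#' @param report a `qc_report` from [flag_outlier_replicates()] derived from
#'   the same matrix/design.
#' @param mode concordance mode.
#' @return A list: `with_flagged` and `without_flagged` (intra summaries),
#'   and `comparison` (per subject-group rows present in either summary with
#'   the mean difference `with - without`).
#' @export
exclusion_impact <- function(matrix, design, report,
                             mode = c("co_called", "strict")) {
  mode <- match.arg(mode)
  stopifnot(inherits(report, "qc_report"))
  design <- study_design(design)
  pairs_all <- concordance_pairs(matrix, design, mode = mode)
  sum_all <- summarize_reproducibility(pairs_all, "intra")
  keep <- design[design$sample_id %in% report$retained, , drop = FALSE]
  pairs_keep <- concordance_pairs(matrix, keep, mode = mode)
  sum_keep <- summarize_reproducibility(pairs_keep, "intra")
  key_all <- paste(sum_all$subject, sum_all$group)
  key_keep <- paste(sum_keep$subject, sum_keep$group)
  keys <- union(key_all, key_keep)
  comparison <- data.frame(
    subject = sub(" .*", "", keys),
    group = sub(".* ", "", keys),
    mean_with = sum_all$mean_concordance[match(keys, key_all)],
    mean_without = sum_keep$mean_concordance[match(keys, key_keep)],
    stringsAsFactors = FALSE
  )
  comparison$difference <- comparison$mean_with - comparison$mean_without
  list(with_flagged = sum_all, without_flagged = sum_keep,
       comparison = comparison)
}
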