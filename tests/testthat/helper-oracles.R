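# Independent brute-force implementations used as oracles. These stay
# deliberately naive (explicit loops, no shared code with the package).

oracle_concordance <- function(a, b, mode = "co_called") {
  n_total <- length(a)
  n_compared <- 0L
  n_agree <- 0L
  if (mode == "co_called") {
    for (k in seq_len(n_total)) {
      if (!is.na(a[k]) && !is.na(b[k])) {
        n_compared <- n_compared + 1L
        if (a[k] == b[k]) n_agree <- n_agree + 1L
      }
    }
    conc <- if (n_compared == 0L) NA_real_ else n_agree / n_compared
  } else {
    n_compared <- n_total
    for (k in seq_len(n_total)) {
      if (!is.na(a[k]) && !is.na(b[k]) && a[k] == b[k]) {
        n_agree <- n_agree + 1L
      }
    }
    conc <- n_agree / n_total
  }
  list(n_compared = n_compared, n_agree = n_agree, concordance = conc)
}

oracle_sample_stats <- function(calls) {
  out <- data.frame(sample_id = rownames(calls), n_called = NA_integer_,
                    n_het = NA_integer_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(calls))) {
    nc <- 0L; nh <- 0L
    for (j in seq_len(ncol(calls))) {
      g <- calls[i, j]
      if (!is.na(g)) {
        nc <- nc + 1L
        if (g == 1L) nh <- nh + 1L
      }
    }
    out$n_called[i] <- nc
    out$n_het[i] <- nh
  }
  out$call_rate <- out$n_called / ncol(calls)
  out$het_rate <- ifelse(out$n_called > 0, out$n_het / out$n_called, NA)
  out
}

# Per-SNP genotype tally by explicit loop (HWE goodness-of-fit oracle).
oracle_genotype_tally <- function(calls) {
  tal <- matrix(0L, nrow = ncol(calls), ncol = 3L)
  for (j in seq_len(ncol(calls))) {
    for (i in seq_len(nrow(calls))) {
      g <- calls[i, j]
      if (!is.na(g)) tal[j, g + 1L] <- tal[j, g + 1L] + 1L
    }
  }
  colnames(tal) <- c("hom_maj", "het", "hom_min")
  tal
}

# Per-individual Bernoulli noise: every individual keeps its genotype with
# probability `conc`, otherwise moves uniformly to one of the other two
# classes. Returns the resulting genotype counts.
oracle_noise_individual <- function(counts, conc) {
  g <- rep(0:2, times = c(counts$n_hom_major, counts$n_het,
                          counts$n_hom_minor))
  n <- length(g)
  move <- runif(n) >= conc
  shift <- 1L + (runif(n) < 0.5)
  g[move] <- (g[move] + shift[move]) %% 3L
  genotype_counts(sum(g == 0L), sum(g == 1L), sum(g == 2L))
}

# Small genotype matrix built directly from an explicit call table.
make_toy_matrix <- function(calls, mafs = NULL) {
  n_snp <- ncol(calls)
  panel <- snp_panel(
    snp_id = paste0("rs", seq_len(n_snp)),
    chromosome = rep("1", n_snp),
    position = seq_len(n_snp),
    allele_major = rep("A", n_snp),
    allele_minor = rep("G", n_snp),
    maf = if (is.null(mafs)) rep(0.3, n_snp) else mafs
  )
  genotype_matrix(panel, calls)
}

# One-experiment design for an arbitrary call-matrix rowset.
make_toy_design <- function(sample_ids, subjects,
                            experiment = "E1", platform = "Affy6") {
  reps <- stats::ave(seq_along(subjects), subjects, FUN = seq_along)
  study_design(data.frame(
    sample_id = sample_ids, subject_code = subjects,
    replicate_index = reps, experiment_id = experiment,
    platform = platform, well = paste0("W", seq_along(sample_ids)),
    stringsAsFactors = FALSE
  ))
}
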