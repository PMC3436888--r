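#' Deterministic baseline genotype counts at an exact allele frequency
#'
#' Builds the (hom-major, het, hom-minor) composition of a population of size
#' `n` whose minor-allele count is exactly `m = 2 n maf`, partitioned as close
#' to Hardy-Weinberg proportions as integer arithmetic allows: the het count
#' is `round(2 n maf (1 - maf))`, reduced by one if needed so that the
#' remaining minor alleles split evenly into homozygotes. Constructing cases
#' and controls identically therefore yields an allelic odds ratio of exactly
#' one before any noise -- the null the error simulation perturbs.
#'
#' @param maf minor allele frequency; `2 * n * maf` must be an integer.
#' @param n population size.
#' @return A `genotype_counts` list: `n_hom_major`, `n_het`, `n_hom_minor`.
#' @export
build_baseline <- function(maf, n) {
  stopifnot(n >= 1)
  if (maf <= 0 || maf > 0.5) {
    stop("maf must be in (0, 0.5]; maf = 0 has no minor allele", call. = FALSE)
  }
  m <- 2 * n * maf
  if (abs(m - round(m)) > 1e-8) {
    stop("2 * n * maf = ", m, " is not an integer; align the maf grid ",
         "with the population size", call. = FALSE)
  }
  m <- as.integer(round(m))
  h <- as.integer(round(2 * n * maf * (1 - maf)))
  if ((m - h) %% 2L != 0L) h <- h - 1L
  hom_min <- (m - h) %/% 2L
  genotype_counts(n - h - hom_min, h, hom_min)
}

#' Genotype counts of one population
#' @param n_hom_major,n_het,n_hom_minor nonnegative integer counts.
#' @return A `genotype_counts` list.
#' @export
genotype_counts <- function(n_hom_major, n_het, n_hom_minor) {
  counts <- c(n_hom_major, n_het, n_hom_minor)
  if (any(counts < 0)) stop("genotype counts must be nonnegative",
                            call. = FALSE)
  structure(list(n_hom_major = as.integer(n_hom_major),
                 n_het = as.integer(n_het),
                 n_hom_minor = as.integer(n_hom_minor)),
            class = "genotype_counts")
}

#' Minor/major allele counts of a population
#' @param counts a `genotype_counts`.
#' @return Named numeric vector `c(minor, major)`.
#' @export
allele_counts <- function(counts) {
  minor <- counts$n_het + 2 * counts$n_hom_minor
  total <- 2 * (counts$n_hom_major + counts$n_het + counts$n_hom_minor)
  c(minor = minor, major = total - minor)
}

#' Apply genotype noise to population counts
#'
#' Each individual's genotype is retained with probability `concordance` and
#' otherwise reassigned uniformly to one of the two other genotype classes
#' (`uniform_other`). The draw is made at the count level with one
#' multinomial per source class, which is distributionally identical to a
#' per-individual Bernoulli loop but orders of magnitude faster; the
#' equivalence is a tested property. Population size is conserved exactly.
#'
#' Uses the current RNG stream; seed control lives in the callers
#' ([percentile_surface()] derives one stream per grid cell).
#'
#' @param counts a `genotype_counts`.
#' @param concordance retention probability in `[0, 1]`.
#' @param scheme reassignment scheme; only `uniform_other` is defined.
#' @return A `genotype_counts` with the same total.
#' @export
apply_genotype_noise <- function(counts, concordance,
                                 scheme = "uniform_other") {
  stopifnot(inherits(counts, "genotype_counts"),
            concordance >= 0, concordance <= 1)
  scheme <- match.arg(scheme, "uniform_other")
  if (concordance == 1) return(counts)
  src <- c(counts$n_hom_major, counts$n_het, counts$n_hom_minor)
  out <- numeric(3)
  e <- (1 - concordance) / 2
  for (i in 1:3) {
    probs <- rep(e, 3); probs[i] <- concordance
    out <- out + stats::rmultinom(1L, src[i], probs)[, 1L]
  }
  genotype_counts(out[1L], out[2L], out[3L])
}

## Vectorised cell kernel: `reps` independent noisy copies of one population.
## Returns a 2 x reps matrix of (minor, major) allele counts.
noisy_allele_counts <- function(counts, concordance, reps) {
  src <- c(counts$n_hom_major, counts$n_het, counts$n_hom_minor)
  e <- (1 - concordance) / 2
  tot <- matrix(0, nrow = 3, ncol = reps)
  for (i in 1:3) {
    if (src[i] == 0L) next
    probs <- rep(e, 3); probs[i] <- concordance
    tot <- tot + stats::rmultinom(reps, src[i], probs)
  }
  minor <- tot[2L, ] + 2 * tot[3L, ]
  rbind(minor = minor, major = 2 * sum(src) - minor)
}

#' Allelic odds ratio from two genotype-count populations
#'
#' The 2x2 allele-table odds ratio `(a d) / (b c)` with `a` = case minor,
#' `b` = case major, `c` = control minor, `d` = control major allele counts
#' (minor alleles = het + 2 hom-minor). With `correction = TRUE` a zero cell
#' triggers the Haldane-Anscombe correction (0.5 added to all four cells);
#' with it off a zero cell yields `NA` with a warning.
#'
#' @param case,control `genotype_counts`.
#' @param correction apply the Haldane-Anscombe correction on zero cells.
#' @return Positive numeric odds ratio (or `NA` if undefined).
#' @export
allelic_odds_ratio <- function(case, control, correction = TRUE) {
  ca <- allele_counts(case); co <- allele_counts(control)
  cells <- c(ca["minor"], ca["major"], co["minor"], co["major"])
  if (any(cells == 0)) {
    if (!correction) {
      warning("zero cell in allele table; odds ratio undefined",
              call. = FALSE)
      return(NA_real_)
    }
    cells <- cells + 0.5
  }
  unname((cells[1L] * cells[4L]) / (cells[2L] * cells[3L]))
}

#' Simulation configuration
#'
#' Defaults mirror a realistic case-control GWAS: 2,000 cases, 3,000
#' controls, 50,000 repetitions per grid cell, MAF from 0.01 to 0.40 in steps
#' of 0.01 and genotype concordance from 0.940 to 1.000 in steps of 0.001,
#' reporting the 95th percentile (the "top 5%" spurious odds ratio).
#'
#' @param n_case,n_control population sizes.
#' @param reps Monte-Carlo repetitions per grid cell.
#' @param maf_grid sorted MAF values in `(0, 0.5]`.
#' @param concordance_grid sorted concordance values in `[0, 1]`.
#' @param percentile order of the reported top quantile, in `(0, 1)`.
#' @param seed root seed; per-cell streams are derived from it.
#' @param scheme reassignment scheme.
#' @param zero_cell_correction Haldane-Anscombe correction flag.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_case = 2000L, n_control = 3000L, reps = 50000L,
                       maf_grid = seq(0.01, 0.40, by = 0.01),
                       concordance_grid = seq(0.940, 1.000, by = 0.001),
                       percentile = 0.95, seed = 1L,
                       scheme = "uniform_other",
                       zero_cell_correction = TRUE) {
  stopifnot(n_case >= 1, n_control >= 1, reps >= 1,
            percentile > 0, percentile < 1)
  maf_grid <- round(sort(as.numeric(maf_grid)), 10)
  concordance_grid <- round(sort(as.numeric(concordance_grid)), 10)
  if (any(maf_grid <= 0) || any(maf_grid > 0.5)) {
    stop("maf_grid must lie in (0, 0.5]", call. = FALSE)
  }
  if (any(concordance_grid < 0) || any(concordance_grid > 1)) {
    stop("concordance_grid must lie in [0, 1]", call. = FALSE)
  }
  structure(list(n_case = as.integer(n_case),
                 n_control = as.integer(n_control),
                 reps = as.integer(reps), maf_grid = maf_grid,
                 concordance_grid = concordance_grid,
                 percentile = percentile, seed = as.integer(seed),
                 scheme = scheme,
                 zero_cell_correction = isTRUE(zero_cell_correction)),
            class = "sim_config")
}

## One deterministic sub-stream per grid cell so cells are reproducible
## independently of evaluation order. Kept below 2^31.
cell_seed <- function(seed, i, j) {
  (abs(seed) + 99991L * i + 7919L * j) %% 2147483629L
}

#' Nearest-rank percentile
#'
#' Order statistic at index `ceiling(q * n)` of the ascending sample.
#' @param x numeric sample.
#' @param q quantile order in `(0, 1)`.
#' @return The nearest-rank percentile value.
#' @export
nearest_rank_percentile <- function(x, q) {
  stopifnot(length(x) >= 1, q > 0, q < 1)
  sort(x, method = "quick")[ceiling(q * length(x))]
}

#' Top-percentile odds-ratio surface over the MAF x concordance grid
#'
#' For each grid cell, the baseline case and control populations are built at
#' the cell's exact MAF (odds ratio exactly one), genotype noise at the
#' cell's concordance is applied independently to both populations, and the
#' allelic odds ratio is recorded; after `reps` repetitions the nearest-rank
#' top percentile is stored. At concordance 1 no noise occurs and the cell is
#' exactly 1 in every repetition.
#'
#' @param config a [sim_config()].
#' @param keep_samples_cap retain the raw odds-ratio draws per cell when
#'   `reps` is at or below this cap (default 0 = never).
#' @return An `or_surface` list: `percentile_or` matrix (rows = maf, cols =
#'   concordance), the grids, `reps`, `percentile`, `seed`, and `samples`
#'   (list of raw draws or `NULL`).
#' @export
percentile_surface <- function(config, keep_samples_cap = 0L) {
  stopifnot(inherits(config, "sim_config"))
  nm <- length(config$maf_grid); nc <- length(config$concordance_grid)
  surf <- matrix(NA_real_, nrow = nm, ncol = nc,
                 dimnames = list(maf = format(config$maf_grid),
                                 concordance = format(config$concordance_grid)))
  keep <- config$reps <= keep_samples_cap
  samples <- if (keep) vector("list", nm * nc) else NULL
  for (i in seq_len(nm)) {
    maf <- config$maf_grid[i]
    case0 <- build_baseline(maf, config$n_case)
    ctrl0 <- build_baseline(maf, config$n_control)
    for (j in seq_len(nc)) {
      cc <- config$concordance_grid[j]
      if (cc == 1) {
        ors <- rep(1, config$reps)
      } else {
        ors <- withr::with_seed(cell_seed(config$seed, i, j), {
          ca <- noisy_allele_counts(case0, cc, config$reps)
          co <- noisy_allele_counts(ctrl0, cc, config$reps)
          num <- ca["minor", ] * co["major", ]
          den <- ca["major", ] * co["minor", ]
          zero <- ca["minor", ] == 0 | ca["major", ] == 0 |
            co["minor", ] == 0 | co["major", ] == 0
          if (any(zero)) {
            if (config$zero_cell_correction) {
              num[zero] <- (ca["minor", zero] + 0.5) * (co["major", zero] + 0.5)
              den[zero] <- (ca["major", zero] + 0.5) * (co["minor", zero] + 0.5)
            } else {
              num[zero] <- NA_real_
            }
          }
          num / den
        })
      }
      surf[i, j] <- nearest_rank_percentile(ors, config$percentile)
      if (keep) samples[[(i - 1L) * nc + j]] <- ors
    }
  }
  structure(list(percentile_or = surf, maf_grid = config$maf_grid,
                 concordance_grid = config$concordance_grid,
                 reps = config$reps, percentile = config$percentile,
                 seed = config$seed, samples = samples),
            class = "or_surface")
}

#' @export
print.or_surface <- function(x, ...) {
  cat(sprintf(
    "or_surface: %d maf x %d concordance cells, reps = %d, q = %.2f\n",
    length(x$maf_grid), length(x$concordance_grid), x$reps, x$percentile))
  invisible(x)
}

#' Long-format data.frame of an odds-ratio surface
#' @param x an `or_surface`.
#' @param ... unused.
#' @return data.frame with columns `maf`, `concordance`, `percentile_or`,
#'   `reps`, `seed`.
#' @export
as.data.frame.or_surface <- function(x, ...) {
  data.frame(
    maf = rep(x$maf_grid, times = length(x$concordance_grid)),
    concordance = rep(x$concordance_grid, each = length(x$maf_grid)),
    percentile_or = as.vector(x$percentile_or),
    reps = x$reps, seed = x$seed
  )
}
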