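#' @keywords internal
"_PACKAGE"

## Genotype calls are stored as minor-allele dosage:
##   0L = homozygous major, 1L = heterozygous, 2L = homozygous minor,
##   NA = no-call.
CALL_LEVELS <- c(HOM_MAJ = 0L, HET = 1L, HOM_MIN = 2L)

#' SNP panel
#'
#' A SNP panel describes the marker universe a genotype matrix is bound to:
#' one row per SNP with identifier, map position, the major/minor allele pair
#' and the population minor allele frequency used when simulating truth
#' genotypes.
#'
#' @param snp_id character vector of unique SNP identifiers.
#' @param chromosome character (or coercible) chromosome labels.
#' @param position 1-based integer positions (metadata only).
#' @param allele_major,allele_minor single nucleotides in `A`, `C`, `G`, `T`;
#'   the two alleles of a SNP must differ.
#' @param maf minor allele frequencies in `[0, 0.5]`.
#'
#' @return A `data.frame` of class `snp_panel`.
#' @export
snp_panel <- function(snp_id, chromosome, position, allele_major,
                      allele_minor, maf) {
  panel <- data.frame(
    snp_id = as.character(snp_id),
    chromosome = as.character(chromosome),
    position = as.integer(position),
    allele_major = as.character(allele_major),
    allele_minor = as.character(allele_minor),
    maf = as.numeric(maf),
    stringsAsFactors = FALSE
  )
  validate_snp_panel(panel)
}

validate_snp_panel <- function(panel) {
  if (anyDuplicated(panel$snp_id)) {
    stop("snp_panel: duplicate snp_id values", call. = FALSE)
  }
  nuc <- c("A", "C", "G", "T")
  if (!all(panel$allele_major %in% nuc) || !all(panel$allele_minor %in% nuc)) {
    stop("snp_panel: alleles must be one of A, C, G, T", call. = FALSE)
  }
  if (any(panel$allele_major == panel$allele_minor)) {
    stop("snp_panel: allele_major must differ from allele_minor", call. = FALSE)
  }
  if (any(!is.finite(panel$maf)) || any(panel$maf < 0) || any(panel$maf > 0.5)) {
    stop("snp_panel: maf must be finite and within [0, 0.5]", call. = FALSE)
  }
  if (any(panel$position < 1L)) {
    stop("snp_panel: positions must be positive", call. = FALSE)
  }
  class(panel) <- c("snp_panel", "data.frame")
  panel
}

#' Genotype matrix
#'
#' Binds a samples-by-SNPs call table to a [snp_panel()]. Calls are coded as
#' minor-allele dosage: `0` homozygous major, `1` heterozygous, `2` homozygous
#' minor, `NA` no-call.
#'
#' @param panel a [snp_panel()].
#' @param calls integer matrix, one row per sample, one column per panel SNP,
#'   values in `{0, 1, 2, NA}`; rownames are the sample ids.
#'
#' @return An object of class `genotype_matrix` with elements `panel` and
#'   `calls`.
#' @export
genotype_matrix <- function(panel, calls) {
  panel <- validate_snp_panel(as.data.frame(panel))
  if (!is.matrix(calls)) stop("calls must be a matrix", call. = FALSE)
  storage.mode(calls) <- "integer"
  if (ncol(calls) != nrow(panel)) {
    stop("calls must have one column per panel SNP", call. = FALSE)
  }
  if (is.null(rownames(calls)) || anyDuplicated(rownames(calls))) {
    stop("calls must have unique rownames (sample ids)", call. = FALSE)
  }
  bad <- calls[!is.na(calls)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L)) {
    stop("calls must be 0, 1, 2 or NA", call. = FALSE)
  }
  colnames(calls) <- panel$snp_id
  structure(list(panel = panel, calls = calls), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "genotype_matrix: %d samples x %d SNPs (%.2f%% no-call)\n",
    nrow(x$calls), ncol(x$calls), 100 * mean(is.na(x$calls))
  ))
  invisible(x)
}

#' Sample identifiers of a genotype matrix
#' @param x a `genotype_matrix`.
#' @return Character vector of sample ids (row order).
#' @export
sample_ids <- function(x) rownames(x$calls)

#' Study design table
#'
#' Per-sample metadata defining the replicate comparison groups: subject code,
#' replicate index, genotyping experiment, platform and plate well. Each
#' experiment must map to exactly one platform and the
#' (subject, replicate, experiment) triple must be unique.
#'
#' @param df data.frame with columns `sample_id`, `subject_code`,
#'   `replicate_index`, `experiment_id`, `platform`, `well`.
#' @return A validated `study_design` data.frame.
#' @export
study_design <- function(df) {
  needed <- c("sample_id", "subject_code", "replicate_index",
              "experiment_id", "platform", "well")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("study_design: missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df <- as.data.frame(df)[needed]
  df$sample_id <- as.character(df$sample_id)
  df$subject_code <- as.character(df$subject_code)
  df$replicate_index <- as.integer(df$replicate_index)
  df$experiment_id <- as.character(df$experiment_id)
  df$platform <- as.character(df$platform)
  df$well <- as.character(df$well)
  if (anyDuplicated(df$sample_id)) {
    stop("study_design: duplicate sample_id", call. = FALSE)
  }
  key <- paste(df$subject_code, df$replicate_index, df$experiment_id)
  if (anyDuplicated(key)) {
    stop("study_design: (subject, replicate, experiment) must be unique",
         call. = FALSE)
  }
  n_plat <- tapply(df$platform, df$experiment_id,
                   function(p) length(unique(p)))
  if (any(n_plat != 1L)) {
    stop("study_design: an experiment maps to more than one platform",
         call. = FALSE)
  }
  class(df) <- c("study_design", "data.frame")
  df
}

#' Reference replicate-study design
#'
#' The default study design: 6 subjects (A-F), 4 technical replicates each,
#' 5 genotyping experiments (E1-E3 on platform Affy6, E4-E5 on Illu1M), so 24
#' arrays per experiment and 120 in total. The 24 samples of each experiment
#' sit in a synthetic 96-well-plate layout (columns 1-3, rows A-H), identical
#' across experiments; the layout is deterministic and chosen so that well H3
#' holds a subject-B replicate.
#'
#' @param n_replicates replicates per subject per experiment (default 4).
#' @return A [study_design()] data.frame with 6 x `n_replicates` x 5 rows.
#' @export
reference_design <- function(n_replicates = 4L) {
  subjects <- LETTERS[1:6]
  experiments <- paste0("E", 1:5)
  platforms <- c(E1 = "Affy6", E2 = "Affy6", E3 = "Affy6",
                 E4 = "Illu1M", E5 = "Illu1M")
  ## fixed plate order (same for every experiment); H3 = slot 24 = B-4
  plate_subjects <- c(rep(c("A", "C", "D", "E", "F"), each = 4L),
                      rep("B", 4L))
  plate_reps <- c(rep(seq_len(4L), 5L), seq_len(4L))
  wells <- paste0(rep(LETTERS[1:8], 3L), rep(1:3, each = 8L))
  rows <- lapply(experiments, function(ex) {
    keep <- plate_reps <= n_replicates
    data.frame(
      sample_id = paste(plate_subjects[keep], plate_reps[keep], ex, sep = "-"),
      subject_code = plate_subjects[keep],
      replicate_index = plate_reps[keep],
      experiment_id = ex,
      platform = platforms[[ex]],
      well = wells[keep],
      stringsAsFactors = FALSE
    )
  })
  study_design(do.call(rbind, rows))
}
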