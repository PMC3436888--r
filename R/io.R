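#' Write a genotype matrix as TSV
#'
#' Canonical text format: one row per SNP with columns `snp_id`,
#' `chromosome`, `position`, `allele_major`, `allele_minor`, then one column
#' per sample holding the two-letter genotype (major allele first, e.g.
#' `"AG"`) or `"NN"` for a no-call.
#'
#' @param matrix a `genotype_matrix`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genotype_tsv <- function(matrix, path) {
  stopifnot(inherits(matrix, "genotype_matrix"))
  panel <- matrix$panel
  calls <- matrix$calls
  geno_strings <- function(g, maj, minr) {
    out <- character(length(g))
    out[is.na(g)] <- "NN"
    i0 <- which(!is.na(g) & g == 0L)
    i1 <- which(!is.na(g) & g == 1L)
    i2 <- which(!is.na(g) & g == 2L)
    out[i0] <- paste0(maj[i0], maj[i0])
    out[i1] <- paste0(maj[i1], minr[i1])
    out[i2] <- paste0(minr[i2], minr[i2])
    out
  }
  dt <- data.table::data.table(
    snp_id = panel$snp_id, chromosome = panel$chromosome,
    position = panel$position, allele_major = panel$allele_major,
    allele_minor = panel$allele_minor
  )
  for (s in rownames(calls)) {
    dt[[s]] <- geno_strings(calls[s, ], panel$allele_major,
                            panel$allele_minor)
  }
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a genotype matrix from TSV
#'
#' Inverse of [write_genotype_tsv()] with round-trip fidelity. Genotype
#' letters are validated against each SNP's allele pair; heterozygous calls
#' are accepted in either letter order and normalized. Formatting problems
#' (unknown allele letters, duplicate SNP ids) raise errors naming the
#' offending line (1-based, counting the header).
#'
#' @param path TSV file written by [write_genotype_tsv()].
#' @return A `genotype_matrix`.
#' @export
read_genotype_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t", colClasses = list(
    character = c("snp_id", "chromosome", "allele_major", "allele_minor")))
  fixed <- c("snp_id", "chromosome", "position", "allele_major",
             "allele_minor")
  missing <- setdiff(fixed, names(dt))
  if (length(missing)) {
    stop("malformed genotype TSV; missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(dt$snp_id)) {
    line <- which(duplicated(dt$snp_id))[1L] + 1L
    stop("duplicate snp_id at line ", line, call. = FALSE)
  }
  panel <- snp_panel(dt$snp_id, dt$chromosome, dt$position,
                     dt$allele_major, dt$allele_minor, maf = 0)
  sample_cols <- setdiff(names(dt), fixed)
  if (length(sample_cols) == 0L) stop("no sample columns found",
                                      call. = FALSE)
  n_snp <- nrow(dt)
  maj <- dt$allele_major; minr <- dt$allele_minor
  hom_maj <- paste0(maj, maj); hom_min <- paste0(minr, minr)
  het1 <- paste0(maj, minr); het2 <- paste0(minr, maj)
  calls <- matrix(NA_integer_, nrow = length(sample_cols), ncol = n_snp,
                  dimnames = list(sample_cols, dt$snp_id))
  for (k in seq_along(sample_cols)) {
    g <- dt[[sample_cols[k]]]
    v <- rep(NA_integer_, n_snp)
    v[g == hom_maj] <- 0L
    v[g == het1 | g == het2] <- 1L
    v[g == hom_min] <- 2L
    bad <- which(is.na(v) & g != "NN")
    if (length(bad)) {
      stop(sprintf(
        "sample %s: genotype '%s' incompatible with alleles %s/%s at line %d",
        sample_cols[k], g[bad[1L]], maj[bad[1L]], minr[bad[1L]],
        bad[1L] + 1L), call. = FALSE)
    }
    calls[k, ] <- v
  }
  genotype_matrix(panel, calls)
}

#' Write/read a study design as TSV
#'
#' @param design a [study_design()].
#' @param path TSV file.
#' @return `path` (writer) / a `study_design` (reader).
#' @export
write_design_tsv <- function(design, path) {
  data.table::fwrite(as.data.frame(study_design(design)), path, sep = "\t",
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_design_tsv
#' @export
read_design_tsv <- function(path) {
  study_design(data.table::fread(path, sep = "\t",
                                 colClasses = list(character = "well")))
}

#' Write a numeric matrix (concordance heatmap content) as TSV
#' @param mat numeric matrix with dimnames.
#' @param path TSV file.
#' @export
write_matrix_tsv <- function(mat, path) {
  dt <- data.table::data.table(sample_id = rownames(mat))
  for (cn in colnames(mat)) dt[[cn]] <- mat[, cn]
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Export a genotype matrix as PLINK-style text (.ped/.map)
#'
#' Writes `prefix.map` (chromosome, snp_id, 0, position) and `prefix.ped`
#' (six metadata columns -- family/individual id from the sample id, parents
#' and sex zeroed, phenotype -9 -- followed by one allele pair per SNP,
#' `0 0` for a no-call). Intended for interchange at fixture scale; the TSV
#' format is canonical.
#'
#' @param matrix a `genotype_matrix`.
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_ped_map <- function(matrix, prefix) {
  stopifnot(inherits(matrix, "genotype_matrix"))
  panel <- matrix$panel
  map <- data.frame(panel$chromosome, panel$snp_id, 0L, panel$position)
  utils::write.table(map, paste0(prefix, ".map"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  calls <- matrix$calls
  n_snp <- ncol(calls)
  a1 <- matrix(panel$allele_major, nrow = nrow(calls), ncol = n_snp,
               byrow = TRUE)
  a2 <- a1
  amin <- matrix(panel$allele_minor, nrow = nrow(calls), ncol = n_snp,
                 byrow = TRUE)
  i2 <- which(calls == 2L)
  i12 <- which(calls >= 1L)
  a1[i2] <- amin[i2]
  a2[i12] <- amin[i12]
  a1[is.na(calls)] <- "0"; a2[is.na(calls)] <- "0"
  geno <- matrix(paste(a1, a2), nrow = nrow(calls))
  ped <- cbind(rownames(calls), rownames(calls), "0", "0", "0", "-9", geno)
  utils::write.table(ped, paste0(prefix, ".ped"), sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Import PLINK-style text (.ped/.map)
#'
#' `0 0` becomes a no-call. Unless a `panel` is supplied, the major/minor
#' assignment is inferred from observed allele frequencies (ties broken
#' alphabetically); a monomorphic SNP keeps its observed allele as major and
#' records an `N` placeholder minor allele with a warning.
#'
#' @param ped_path,map_path input files.
#' @param panel optional [snp_panel()] fixing the allele orientation.
#' @return A `genotype_matrix`.
#' @export
read_ped_map <- function(ped_path, map_path, panel = NULL) {
  map <- utils::read.table(map_path, sep = "\t", stringsAsFactors = FALSE,
                           col.names = c("chromosome", "snp_id", "cm",
                                         "position"),
                           colClasses = c("character", "character",
                                          "integer", "integer"))
  ped <- utils::read.table(ped_path, sep = "", stringsAsFactors = FALSE,
                           colClasses = "character")
  n_snp <- nrow(map)
  if (ncol(ped) != 6L + 2L * n_snp) {
    stop(sprintf(".ped has %d genotype fields but .map lists %d SNPs",
                 ncol(ped) - 6L, n_snp), call. = FALSE)
  }
  ids <- ped[[2L]]
  al1 <- as.matrix(ped[, 6L + 2L * seq_len(n_snp) - 1L, drop = FALSE])
  al2 <- as.matrix(ped[, 6L + 2L * seq_len(n_snp), drop = FALSE])
  if (is.null(panel)) {
    maj <- character(n_snp); minr <- character(n_snp)
    mono <- logical(n_snp)
    for (k in seq_len(n_snp)) {
      obs <- c(al1[, k], al2[, k])
      obs <- obs[obs != "0"]
      tab <- sort(table(obs), decreasing = TRUE)
      if (length(tab) == 0L) {
        maj[k] <- "A"; minr[k] <- "C"; mono[k] <- TRUE
      } else if (length(tab) == 1L) {
        maj[k] <- names(tab)[1L]
        minr[k] <- "N"; mono[k] <- TRUE
      } else {
        nm <- names(tab)
        if (tab[1L] == tab[2L]) nm <- sort(nm[1:2]) else nm <- nm[1:2]
        maj[k] <- nm[1L]; minr[k] <- nm[2L]
      }
    }
    if (any(mono)) {
      warning(sum(mono), " monomorphic SNP(s): minor allele unknown",
              call. = FALSE)
      ## placeholder minor allele (never observed): any letter != major
      fix <- mono & minr == "N"
      minr[fix] <- ifelse(maj[fix] == "A", "C", "A")
    }
    panel <- snp_panel(map$snp_id, map$chromosome, map$position, maj, minr,
                       maf = 0)
  } else {
    panel <- validate_snp_panel(as.data.frame(panel))
    idx <- match(map$snp_id, panel$snp_id)
    if (anyNA(idx)) stop(".map SNPs missing from supplied panel",
                         call. = FALSE)
    panel <- validate_snp_panel(panel[idx, ])
  }
  maj <- panel$allele_major
  calls <- matrix(NA_integer_, nrow = nrow(ped), ncol = n_snp,
                  dimnames = list(ids, panel$snp_id))
  called <- al1 != "0" & al2 != "0"
  dose <- (al1 != matrix(maj, nrow(ped), n_snp, byrow = TRUE)) +
    (al2 != matrix(maj, nrow(ped), n_snp, byrow = TRUE))
  calls[called] <- as.integer(dose[called])
  genotype_matrix(panel, calls)
}
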