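#' Default pipeline configuration
#'
#' All stage parameters with their defaults: the reference 6-subject,
#' 4-replicate, 5-experiment study design, the error model, the QC
#' thresholds, and a reduced odds-ratio simulation grid suitable for an
#' end-to-end run in minutes. Any element can be overridden via `...` or by
#' loading a YAML file with [read_run_config()].
#'
#' @param ... named overrides of the defaults.
#' @return A `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(
    stages = c("simulate", "qc", "concordance", "summarize", "errorsim"),
    out_dir = "results",
    seed = 20120901L,
    n_snps = 20000L,
    n_subjects = 6L,
    maf_low = 0.05, maf_high = 0.5,
    call_error_rate = 0.003, nocall_rate = 0.005,
    scheme = "uniform_other",
    inject = list(),   # list of lists: sample_id, het_inflation, callrate_drop
    abs_floor = 0.02, k_mad = 5, call_rate_min = 0.95,
    mode = "co_called",
    sim = list(n_case = 2000L, n_control = 3000L, reps = 2000L,
               maf_grid = c(0.05, 0.10, 0.20),
               concordance_grid = c(0.94, 0.97, 1.00),
               percentile = 0.95)
  )
  dots <- list(...)
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path YAML file whose keys override the defaults.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' Run the replicate-study pipeline end to end
#'
#' Executes the selected stages in order -- simulate the replicate study,
#' replicate-based QC, pairwise concordance, reproducibility summaries at
#' the three comparison levels, and the odds-ratio error simulation -- and
#' writes every artifact plus a JSON manifest (parameters, seed, retained
#' samples, MD5 checksums of the outputs) under `config$out_dir`. Reruns
#' with the same configuration reproduce identical outputs.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character()
  res <- list()
  emit <- function(name) outputs <<- c(outputs, file.path(config$out_dir, name))

  design <- reference_design()
  truth <- generate_truth(config$n_subjects, config$n_snps,
                          config$maf_low, config$maf_high,
                          seed = config$seed)
  model <- error_model(config$call_error_rate, config$nocall_rate,
                       scheme = config$scheme)
  gm <- simulate_replicate_study(truth, design, model,
                                 seed = config$seed + 1L)
  for (k in seq_along(config$inject)) {
    inj <- config$inject[[k]]
    gm <- inject_low_quality(gm, inj$sample_id,
                             het_inflation = inj$het_inflation %||% 0,
                             callrate_drop = inj$callrate_drop %||% 0,
                             seed = config$seed + 100L + k)
  }
  res$matrix <- gm
  res$design <- design
  if ("simulate" %in% config$stages) {
    write_genotype_tsv(gm, file.path(config$out_dir, "calls.tsv"))
    write_design_tsv(design, file.path(config$out_dir, "design.tsv"))
    emit("calls.tsv"); emit("design.tsv")
  }

  report <- NULL
  if ("qc" %in% config$stages) {
    stats <- per_sample_stats(gm)
    report <- flag_outlier_replicates(stats, design,
                                      abs_floor = config$abs_floor,
                                      k_mad = config$k_mad,
                                      call_rate_min = config$call_rate_min)
    res$qc <- report
    qc_tab <- report$stats
    qc_tab$flagged <- qc_tab$sample_id %in% report$flags$sample_id
    data.table::fwrite(qc_tab, file.path(config$out_dir, "qc_report.tsv"),
                       sep = "\t")
    data.table::fwrite(report$flags, file.path(config$out_dir,
                                               "qc_flags.tsv"), sep = "\t")
    emit("qc_report.tsv"); emit("qc_flags.tsv")
  }

  if (any(c("concordance", "summarize") %in% config$stages)) {
    keep_design <- if (is.null(report)) design else
      design[design$sample_id %in% report$retained, , drop = FALSE]
    pairs <- concordance_pairs(gm, keep_design, mode = config$mode)
    res$pairs <- pairs
    if ("concordance" %in% config$stages) {
      data.table::fwrite(pairs, file.path(config$out_dir, "pairs.tsv"),
                         sep = "\t")
      emit("pairs.tsv")
    }
    if ("summarize" %in% config$stages) {
      summ <- do.call(rbind, lapply(
        c("intra", "inter_lab", "inter_platform"),
        function(lv) summarize_reproducibility(pairs, lv)))
      res$summaries <- summ
      data.table::fwrite(summ, file.path(config$out_dir, "summaries.tsv"),
                         sep = "\t")
      emit("summaries.tsv")
    }
  }

  if ("errorsim" %in% config$stages) {
    sim <- config$sim
    cfg <- sim_config(n_case = sim$n_case, n_control = sim$n_control,
                      reps = sim$reps, maf_grid = sim$maf_grid,
                      concordance_grid = sim$concordance_grid,
                      percentile = sim$percentile, seed = config$seed + 3L)
    surface <- percentile_surface(cfg)
    res$surface <- surface
    data.table::fwrite(as.data.frame(surface),
                       file.path(config$out_dir, "or_surface.tsv"),
                       sep = "\t")
    emit("or_surface.tsv")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("genorep")),
    seed = config$seed,
    parameters = unclass(config),
    n_samples = nrow(gm$calls),
    retained_samples = if (is.null(report)) rownames(gm$calls) else
      report$retained,
    outputs = as.list(stats::setNames(
      unname(tools::md5sum(outputs)), basename(outputs)))
  )
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  res$manifest <- manifest
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
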