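# Status codes returned by the run*() entry points:
# 0 success, 2 QC failure, 3 input/structure error, 4 statistical degeneracy.

writeJsonReport <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(path)
}

configForOutput <- function(config) {
  unclass(config)
}

#' Analyse one scan / lobe-mask pair
#'
#' Runs QC, the full per-region QCT metric set ([allRegionMetrics()]) and
#' the distribution phenotype ([phenotypePatient()]) on a NIfTI pair, and
#' writes `metrics.csv`, `metrics.json`, `phenotype.csv` and
#' `phenotype.json` (JSON outputs embed the effective configuration, the QC
#' report and the package version). Reruns on identical inputs are
#' byte-identical.
#'
#' @param ctPath Path to the CT NIfTI volume (HU).
#' @param lobesPath Path to the co-registered lobe-mask NIfTI.
#' @param outDir Output directory (created if needed).
#' @param config A [qctConfig()] list.
#' @param overrideQc Proceed despite QC failures (default FALSE).
#' @return Invisibly, a list with `status` (0 success, 2 QC failure,
#'   3 structural error), `qc`, `metrics`, `phenotype`, `files`.
#' @export
runScanAnalysis <- function(ctPath, lobesPath, outDir,
                            config = qctConfig(), overrideQc = FALSE) {
  res <- tryCatch({
    ct <- readCTScan(ctPath)
    lobes <- readLobeMask(lobesPath)
    qc <- qcReport(ct, lobes, config)
    if (!qcPassed(qc) && !overrideQc) {
      message("QC failed:\n", paste(sprintf("  [%s] %s: %s", qc$status,
                                            qc$check, qc$detail),
                                    collapse = "\n"))
      return(invisible(list(status = 2L, qc = qc, metrics = NULL,
                            phenotype = NULL, files = character())))
    }
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    metrics <- allRegionMetrics(ct, lobes, config)
    rounded <- metrics
    for (cn in c("mld", "ei", "pd15", "volume_cm3", "et1", "et2", "et3"))
      rounded[[cn]] <- roundHalfUp(metrics[[cn]], config$roundDigits)
    pheno <- phenotypePatient(ct, lobes, config)
    phenoRow <- data.frame(
      upper_ei = roundHalfUp(pheno$zones$upper, config$roundDigits),
      mid_ei = roundHalfUp(pheno$zones$mid, config$roundDigits),
      lower_ei = roundHalfUp(pheno$zones$lower, config$roundDigits),
      spread = roundHalfUp(pheno$zones$spread, config$roundDigits),
      heterogeneous = pheno$phenotype$heterogeneous,
      predominance = pheno$phenotype$predominance,
      tie = pheno$phenotype$tie)
    files <- file.path(outDir, c("metrics.csv", "metrics.json",
                                 "phenotype.csv", "phenotype.json"))
    utils::write.csv(rounded, files[1], row.names = FALSE)
    writeJsonReport(list(config = configForOutput(config),
                         package_version = as.character(
                           utils::packageVersion("qctemph")),
                         qc = qc, metrics = metrics), files[2])
    utils::write.csv(phenoRow, files[3], row.names = FALSE)
    writeJsonReport(list(config = configForOutput(config),
                         package_version = as.character(
                           utils::packageVersion("qctemph")),
                         ei_by_lobe = as.list(pheno$ei_by_lobe),
                         zones = pheno$zones,
                         phenotype = pheno$phenotype[c("heterogeneous",
                                                       "predominance",
                                                       "tie")]), files[4])
    invisible(list(status = 0L, qc = qc, metrics = metrics, phenotype = pheno,
                   files = files))
  }, qctemph_structural_error = function(e) {
    message("structural error: ", conditionMessage(e))
    invisible(list(status = 3L, qc = NULL, metrics = NULL, phenotype = NULL,
                   files = character()))
  })
  res
}

#' Analyse a cohort table
#'
#' Reads a cohort CSV, derives the serum groups, writes descriptive
#' summaries and between-group comparisons for the standard variable set,
#' and (when a phenotype column is present) fits the stepwise binary
#' logistic regression for the mid-predominant outcome with sex and BMI as
#' forced adjustment covariates. Outputs: `summary.csv`,
#' `comparisons.csv`, `model.json` (with selection trace and embedded
#' config).
#'
#' @param tablePath Path to the cohort CSV (see [readCohort()]).
#' @param outDir Output directory.
#' @param config A [qctConfig()] list.
#' @return Invisibly, a list with `status` (0 success, 3 structural error,
#'   4 statistical degeneracy), `summary`, `comparisons`, `model`, `files`.
#' @export
runCohortAnalysis <- function(tablePath, outDir, config = qctConfig()) {
  res <- tryCatch({
    co <- readCohort(tablePath)
    if (length(unique(co$group[!is.na(co$group)])) < 2L)
      stop(errorCondition("cohort has fewer than 2 non-empty serum groups",
                          class = c("qctemph_degenerate_error", "error")))
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    contVars <- intersect(c("age", "bmi", "serum_aat", "pack_years",
                            "fev1_pct", "rv_l"), names(co))
    catVars <- intersect(c("sex", "genotype", "phenotype"), names(co))
    smry <- summarizeGroups(co, c(contVars, catVars),
                            digits = config$roundDigits)
    comps <- do.call(rbind, lapply(c(contVars, catVars), function(v) {
      k <- if (v %in% contVars) "continuous" else "categorical"
      cr <- compareGroups(co, v, k, rankBased = config$rankBased)
      data.frame(variable = v, test = cr$test,
                 statistic = if (is.na(cr$statistic)) NA_real_ else cr$statistic,
                 p_value = cr$p_value,
                 flags = paste(cr$flags, collapse = ";"))
    }))
    model <- NULL
    if ("phenotype" %in% names(co) || "mid_predominant" %in% names(co)) {
      out <- if ("mid_predominant" %in% names(co)) co$mid_predominant
             else co$phenotype == "mid"
      cand <- intersect(c("age", "sex", "serum_aat", "bmi", "pack_years",
                          "fev1_pct", "rv_l"), names(co))
      model <- tryCatch(
        stepwiseLogistic(co, out, candidates = cand,
                         forced = intersect(c("sex", "bmi"), names(co)),
                         alphaEnter = config$alphaEnter,
                         alphaRemove = config$alphaRemove),
        qctemph_domain_error = function(e) {
          message("logistic model skipped: ", conditionMessage(e))
          NULL
        })
    }
    files <- file.path(outDir, c("summary.csv", "comparisons.csv",
                                 "model.json"))
    utils::write.csv(smry, files[1], row.names = FALSE)
    utils::write.csv(comps, files[2], row.names = FALSE)
    writeJsonReport(list(config = configForOutput(config),
                         package_version = as.character(
                           utils::packageVersion("qctemph")),
                         n_rows = nrow(co),
                         model = if (is.null(model)) NULL else
                           model[c("selected", "terms", "trace", "forced",
                                   "n_used", "n_dropped")]), files[3])
    invisible(list(status = 0L, summary = smry, comparisons = comps,
                   model = model, files = files))
  }, qctemph_structural_error = function(e) {
    message("structural error: ", conditionMessage(e))
    invisible(list(status = 3L, summary = NULL, comparisons = NULL,
                   model = NULL, files = character()))
  }, qctemph_degenerate_error = function(e) {
    message("degenerate cohort: ", conditionMessage(e))
    invisible(list(status = 4L, summary = NULL, comparisons = NULL,
                   model = NULL, files = character()))
  })
  res
}

#' Materialise synthetic data
#'
#' Generates a phantom ([generatePhantom()]) and/or a cohort
#' ([generateCohort()]) from a YAML/JSON spec file and writes the NIfTI
#' pair, cohort CSV and ground-truth JSON (which echoes the full spec).
#' The spec file may contain a `phantom:` block (fields of [phantomSpec()])
#' and/or a `cohort:` block (fields of [cohortSpec()]).
#'
#' @param specPath Path to the YAML/JSON spec file, or a list with
#'   `phantom` / `cohort` entries.
#' @param outDir Output directory.
#' @return Invisibly, a list with `status` (0 success, 3 invalid spec) and
#'   `files`.
#' @export
runSimulation <- function(specPath, outDir) {
  res <- tryCatch({
    spec <- if (is.character(specPath)) {
      if (!file.exists(specPath))
        stopStructural("spec file not found: %s", specPath)
      yaml::read_yaml(specPath)
    } else specPath
    if (is.null(spec$phantom) && is.null(spec$cohort))
      stopStructural("spec must contain a 'phantom' and/or 'cohort' block")
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    files <- character()
    if (!is.null(spec$phantom)) {
      pv <- spec$phantom
      if (!is.null(pv$eiTargets)) pv$eiTargets <- unlist(pv$eiTargets)
      ps <- do.call(phantomSpec, pv)
      ph <- generatePhantom(ps)
      f <- file.path(outDir, c("phantom_ct.nii.gz", "phantom_lobes.nii.gz",
                               "phantom_truth.json"))
      writeNiftiVolume(ph$ct, f[1])
      writeNiftiVolume(ph$lobes, f[2])
      writeJsonReport(ph$truth, f[3])
      files <- c(files, f)
    }
    if (!is.null(spec$cohort)) {
      cs <- do.call(cohortSpec, spec$cohort)
      co <- generateCohort(cs)
      f <- file.path(outDir, c("cohort.csv", "cohort_truth.json"))
      utils::write.csv(co$cohort, f[1], row.names = FALSE)
      writeJsonReport(co$truth, f[2])
      files <- c(files, f)
    }
    invisible(list(status = 0L, files = files))
  }, qctemph_structural_error = function(e) {
    message("invalid spec: ", conditionMessage(e))
    invisible(list(status = 3L, files = character()))
  }, qctemph_domain_error = function(e) {
    message("invalid spec: ", conditionMessage(e))
    invisible(list(status = 3L, files = character()))
  })
  res
}
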