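#' Quality-control checks for a scan / mask pair
#'
#' Automatable proxies for the usual technical exclusion rules: slice
#' thickness (z spacing) at most 1.25 mm, plausible HU range over the lung,
#' a valid lobe label set, and presence of all six lobes. Any `fail` blocks
#' analysis unless overridden.
#'
#' @param ct A [CTScan-class].
#' @param lobes A [LobeMask-class].
#' @param config A [qctConfig()] list.
#' @return A `data.frame` with columns `check`, `status`
#'   (`"pass"`/`"warn"`/`"fail"`) and `detail`.
#' @export
qcReport <- function(ct, lobes, config = qctConfig()) {
  rows <- list()
  add <- function(check, status, detail)
    rows[[length(rows) + 1L]] <<- data.frame(check = check, status = status,
                                             detail = detail)
  if (!identical(dim(ct@values), dim(lobes@labels))) {
    add("grid_alignment", "fail", "CT and lobe mask shapes differ")
  } else add("grid_alignment", "pass", "shapes match")

  st <- ct@spacing[3]
  add("slice_thickness",
      if (st > config$maxSliceThicknessMm) "fail" else "pass",
      sprintf("z spacing %.2f mm (limit %.2f mm)", st,
              config$maxSliceThicknessMm))

  lung <- lobes@labels > 0L
  if (any(lung) && identical(dim(ct@values), dim(lobes@labels))) {
    rng <- range(ct@values[lung])
    add("hu_range",
        if (rng[1] < -1100 || rng[2] > 100) "warn" else "pass",
        sprintf("lung HU in [%.0f, %.0f]", rng[1], rng[2]))
  } else add("hu_range", "fail", "no lung voxels in mask")

  lab <- unique(as.vector(lobes@labels))
  add("label_set", if (all(lab %in% 0:6)) "pass" else "fail",
      paste("labels:", paste(sort(lab), collapse = " ")))

  absent <- names(lobeLabels)[!lobeLabels %in% lab]
  add("lobe_presence", if (length(absent)) "warn" else "pass",
      if (length(absent)) paste("absent lobes:", paste(absent, collapse = ", "))
      else "all six lobes present")

  do.call(rbind, rows)
}

#' Did QC pass?
#'
#' @param report A [qcReport()] table.
#' @return TRUE iff no check failed.
#' @export
qcPassed <- function(report) !any(report$status == "fail")
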