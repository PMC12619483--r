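#' Analysis configuration
#'
#' All fixed constants of the pipeline in one place. Every analysis output
#' embeds the effective configuration, so a reported ET2/ET3 always carries
#' its rim and pseudo-lobule parameterisation.
#'
#' @param thresholdHU Emphysema threshold in HU; a voxel is emphysema iff its
#'   attenuation is strictly below this value (default -950).
#' @param pd15Fraction Quantile for the percentile density (default 0.15).
#' @param clusterConnectivity Voxel connectivity used for emphysema cluster
#'   labelling (26, fixed).
#' @param borderConnectivity Neighbourhood used for inner/border voxel
#'   classification (6, fixed).
#' @param rimMm Subpleural rim width in mm for ET2 (default 2.0): an
#'   emphysema voxel is peripheral if its distance to the nearest non-lung
#'   voxel is at most this.
#' @param lobuleMm Edge length (mm) of the axis-aligned cubic pseudo-lobules
#'   used by ET3 (default 15, the scale of a secondary pulmonary lobule).
#' @param destroyFrac Within-lobule emphysema fraction at or above which a
#'   pseudo-lobule counts as destroyed for ET3 (default 0.8).
#' @param heterogeneityPts Zone-EI spread (percentage points) strictly above
#'   which the distribution is heterogeneous (default 15).
#' @param serumCutSevere Serum AAT cut (mg/dl): severe iff <= this
#'   (default 40).
#' @param serumCutModerate Serum AAT cut (mg/dl): moderate iff above the
#'   severe cut and <= this; reduced-to-normal above (default 70).
#' @param alphaEnter,alphaRemove Stepwise logistic selection thresholds
#'   (defaults 0.05 / 0.10).
#' @param maxSliceThicknessMm QC limit on slice thickness (z spacing);
#'   thicker reconstructions fail QC (default 1.25).
#' @param roundDigits Decimals for reported summaries (default 1).
#' @param zoneWeighting `"unweighted"` (default) averages the two lobar EIs
#'   of a zone; `"volume"` weights them by lobe voxel counts.
#' @param rankBased Use Kruskal-Wallis instead of one-way ANOVA for k-group
#'   continuous comparisons (default FALSE).
#' @param seed Integer seed recorded with outputs (default 1).
#' @return A named list with class `"qctConfig"`.
#' @export
qctConfig <- function(thresholdHU = -950,
                      pd15Fraction = 0.15,
                      clusterConnectivity = 26,
                      borderConnectivity = 6,
                      rimMm = 2.0,
                      lobuleMm = 15,
                      destroyFrac = 0.8,
                      heterogeneityPts = 15,
                      serumCutSevere = 40,
                      serumCutModerate = 70,
                      alphaEnter = 0.05,
                      alphaRemove = 0.10,
                      maxSliceThicknessMm = 1.25,
                      roundDigits = 1,
                      zoneWeighting = c("unweighted", "volume"),
                      rankBased = FALSE,
                      seed = 1L) {
  zoneWeighting <- match.arg(zoneWeighting)
  stopifnot(clusterConnectivity == 26, borderConnectivity == 6,
            pd15Fraction > 0, pd15Fraction < 1,
            rimMm > 0, lobuleMm > 0, destroyFrac > 0, destroyFrac <= 1)
  structure(list(
    thresholdHU = thresholdHU, pd15Fraction = pd15Fraction,
    clusterConnectivity = clusterConnectivity,
    borderConnectivity = borderConnectivity,
    rimMm = rimMm, lobuleMm = lobuleMm, destroyFrac = destroyFrac,
    heterogeneityPts = heterogeneityPts,
    serumCutSevere = serumCutSevere, serumCutModerate = serumCutModerate,
    alphaEnter = alphaEnter, alphaRemove = alphaRemove,
    maxSliceThicknessMm = maxSliceThicknessMm,
    roundDigits = roundDigits, zoneWeighting = zoneWeighting,
    rankBased = rankBased, seed = as.integer(seed)
  ), class = "qctConfig")
}

#' Read a configuration file
#'
#' Reads a YAML (or JSON: YAML is a superset) configuration file and merges
#' it over the [qctConfig()] defaults. Unknown keys are an error. Values
#' passed in `...` override the file.
#'
#' @param path Path to a YAML/JSON config file, or `NULL` for defaults only.
#' @param ... Named overrides applied after the file.
#' @return A `qctConfig` list.
#' @export
readQctConfig <- function(path = NULL, ...) {
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stopStructural("config file not found: %s", path)
    vals <- yaml::read_yaml(path)
  }
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  known <- names(formals(qctConfig))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stopStructural("unknown config keys: %s", paste(bad, collapse = ", "))
  do.call(qctConfig, vals)
}
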