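#' Threshold emphysema voxels
#'
#' Flags every lung voxel whose attenuation lies strictly below the
#' threshold. A voxel at exactly the threshold is parenchyma, not emphysema.
#'
#' @param ct A [CTScan-class].
#' @param lobes A co-registered [LobeMask-class].
#' @param thresholdHU Threshold in HU (default -950).
#' @return An [EmphysemaMask-class].
#' @examples
#' ct <- CTScan(array(c(-980, -789, -950, -960), c(2, 2, 1)))
#' lm <- LobeMask(array(1L, c(2, 2, 1)))
#' sum(emphFlags(emphysemaMask(ct, lm)))  # 2: -950 itself is parenchyma
#' @export
emphysemaMask <- function(ct, lobes, thresholdHU = -950) {
  checkAligned(ct, lobes)
  if (!is.finite(thresholdHU)) stopStructural("thresholdHU must be finite")
  lung <- lobes@labels > 0L
  if (!any(lung)) stopDomain("lobe mask contains no lung voxels")
  flags <- lung & (ct@values < thresholdHU)
  dim(flags) <- dim(ct@values)
  new("EmphysemaMask", flags = flags, thresholdHU = thresholdHU,
      spacing = ct@spacing)
}

#' Mean lung density
#'
#' Arithmetic mean attenuation (HU) over the selected voxels.
#'
#' @param ct A [CTScan-class].
#' @param region Logical array (same shape) selecting the voxels.
#' @return Mean attenuation in HU.
#' @export
computeMLD <- function(ct, region) {
  if (!any(region)) stopDomain("empty region: MLD undefined")
  mean(ct@values[region])
}

#' Percentile density (PD15)
#'
#' The attenuation value below which the given fraction (default 15%) of the
#' region's voxels lie, computed by linear interpolation between order
#' statistics (the inclusive quantile, `stats::quantile` type 7). Falls as
#' emphysema adds mass to the left tail of the attenuation histogram.
#'
#' @param ct A [CTScan-class].
#' @param region Logical array selecting the voxels (>= 2 voxels).
#' @param fraction Quantile as a fraction (default 0.15).
#' @return Attenuation in HU.
#' @export
computePD15 <- function(ct, region, fraction = 0.15) {
  n <- sum(region)
  if (n < 2L) stopDomain("PD15 needs at least 2 voxels, got %d", n)
  unname(stats::quantile(ct@values[region], probs = fraction, type = 7))
}

#' Region volume
#'
#' Voxel count times physical voxel volume, in cm^3.
#'
#' @param lobes A [LobeMask-class].
#' @param region Integer vector of lobe labels, or a logical array.
#' @param spacing Voxel spacing in mm (defaults to the mask's).
#' @return Volume in cm^3.
#' @export
computeVolume <- function(lobes, region = 1:6, spacing = voxelSpacing(lobes)) {
  if (any(spacing <= 0)) stopStructural("spacing must be strictly positive")
  n <- if (is.logical(region)) sum(region) else sum(lobes@labels %in% region)
  n * prod(spacing) / 1000
}

#' Per-region QCT metrics
#'
#' Computes the full metric bundle for one region (a set of lobe labels):
#' mean lung density (MLD), emphysema index (EI), percentile density (PD15),
#' volume, and the three emphysema-type indices ET1 (cluster bulk,
#' inner/border ratio x 10), ET2 (% of emphysema voxels within the
#' subpleural rim) and ET3 (% of emphysema voxels in destroyed
#' pseudo-lobules). ET2/ET3 geometry (distance to pleura, pseudo-lobule
#' partition) is always defined on the whole lung; only the emphysema voxels
#' counted are restricted to the region.
#'
#' @param ct A [CTScan-class].
#' @param lobes A co-registered [LobeMask-class].
#' @param region Integer vector of lobe labels (subset of 1..6); default the
#'   whole lung.
#' @param config A [qctConfig()] list.
#' @param emph Optional precomputed [EmphysemaMask-class] (as returned by
#'   [emphysemaMask()]); pass it when computing several regions of one scan.
#' @param pleuralDistance Optional precomputed distance map
#'   ([pleuralDistanceMap()]).
#' @return A one-row `data.frame` with columns `mld`, `ei`, `pd15`,
#'   `volume_cm3`, `et1`, `et2`, `et3`, `n_lung_voxels`, `n_emph_voxels`,
#'   and a logical `degenerate` flag (TRUE when the region has no emphysema
#'   voxels, in which case ET1-ET3 are reported as 0). A region absent from
#'   the mask yields all-NA metrics with `missing_region = TRUE`.
#' @export
regionMetrics <- function(ct, lobes, region = 1:6, config = qctConfig(),
                          emph = NULL, pleuralDistance = NULL) {
  checkAligned(ct, lobes)
  if (is.null(emph)) emph <- emphysemaMask(ct, lobes, config$thresholdHU)
  sel <- lobes@labels %in% region
  dim(sel) <- dim(lobes@labels)
  base <- data.frame(mld = NA_real_, ei = NA_real_, pd15 = NA_real_,
                     volume_cm3 = NA_real_, et1 = NA_real_, et2 = NA_real_,
                     et3 = NA_real_, n_lung_voxels = NA_integer_,
                     n_emph_voxels = NA_integer_, degenerate = NA,
                     missing_region = FALSE)
  if (!any(sel)) {
    base$missing_region <- TRUE
    return(base)
  }
  nLung <- sum(sel)
  eSel <- emph@flags & sel
  nEmph <- sum(eSel)

  base$mld <- computeMLD(ct, sel)
  base$ei <- 100 * nEmph / nLung
  base$pd15 <- if (nLung >= 2L) computePD15(ct, sel, config$pd15Fraction)
               else NA_real_
  base$volume_cm3 <- computeVolume(lobes, region)
  base$n_lung_voxels <- nLung
  base$n_emph_voxels <- nEmph
  base$degenerate <- nEmph == 0L

  ib <- classifyInnerBorder(emph, within = sel)
  base$et1 <- if (ib$border_count > 0L) 10 * ib$inner_count / ib$border_count
              else 0
  base$et2 <- computeET2(emph, lobes, rimMm = config$rimMm, within = sel,
                         pleuralDistance = pleuralDistance)$et2
  base$et3 <- computeET3(emph, lobes, lobuleMm = config$lobuleMm,
                         destroyFrac = config$destroyFrac, within = sel)$et3
  base
}

#' QCT metrics for all reporting regions
#'
#' [regionMetrics()] for the six lobes, the right lung, the left lung and
#' the whole lung (the standard reporting granularity), sharing one
#' emphysema mask and one pleural distance map.
#'
#' @inheritParams regionMetrics
#' @return A `data.frame` with one row per region and a `region` column in
#'   the fixed order RUL, RML, RLL, LUL, LLi, LLL, RightLung, LeftLung,
#'   WholeLung.
#' @export
allRegionMetrics <- function(ct, lobes, config = qctConfig()) {
  checkAligned(ct, lobes)
  emph <- emphysemaMask(ct, lobes, config$thresholdHU)
  pd <- pleuralDistanceMap(lobes)
  rows <- lapply(names(reportRegions), function(rn) {
    m <- regionMetrics(ct, lobes, reportRegions[[rn]], config,
                       emph = emph, pleuralDistance = pd)
    cbind(region = rn, m)
  })
  do.call(rbind, rows)
}
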