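#' Aggregate lobar emphysema indices into three zones
#'
#' The lung is divided into three zones: the upper lobes (RUL, LUL), the
#' middle lobe together with the lingula (RML, LLi), and the lower lobes
#' (RLL, LLL). Each zone's EI is by default the unweighted mean of its two
#' lobes' EIs; with `weighting = "volume"` the lobar EIs are weighted by
#' lobe voxel counts (or volumes).
#'
#' @param eiByLobe Named numeric vector of lobar emphysema indices in
#'   percent; names must cover RUL, RML, RLL, LUL, LLi, LLL.
#' @param weighting `"unweighted"` (default) or `"volume"`.
#' @param volumes Named numeric vector of lobe volumes or voxel counts,
#'   required for `weighting = "volume"`.
#' @return A list with `upper`, `mid`, `lower` (percent) and `spread`
#'   (max - min, percentage points).
#' @examples
#' zoneAggregate(c(RUL = 55, RML = 37, RLL = 32, LUL = 55, LLi = 33, LLL = 28))
#' @export
zoneAggregate <- function(eiByLobe, weighting = c("unweighted", "volume"),
                          volumes = NULL) {
  weighting <- match.arg(weighting)
  need <- names(lobeLabels)
  miss <- need[!need %in% names(eiByLobe) | is.na(eiByLobe[need])]
  if (length(miss))
    stopDomain("missing lobar EI for: %s", paste(miss, collapse = ", "))
  ei <- eiByLobe[need]
  if (any(ei < 0 | ei > 100))
    stopDomain("lobar EIs must lie in [0, 100]")
  zones <- list(upper = c("RUL", "LUL"), mid = c("RML", "LLi"),
                lower = c("RLL", "LLL"))
  zoneMean <- function(lb) {
    if (weighting == "unweighted") return(mean(ei[lb]))
    if (is.null(volumes) || any(!lb %in% names(volumes)))
      stopDomain("volume weighting requires per-lobe volumes")
    sum(ei[lb] * volumes[lb]) / sum(volumes[lb])
  }
  z <- vapply(zones, zoneMean, numeric(1))
  list(upper = unname(z["upper"]), mid = unname(z["mid"]),
       lower = unname(z["lower"]), spread = unname(max(z) - min(z)))
}

#' Classify the emphysema distribution
#'
#' A distribution is heterogeneous when the spread between the highest and
#' lowest zone EI is strictly greater than `thresholdPts` percentage points
#' (a spread of exactly the threshold is homogeneous). For heterogeneous
#' cases the predominant type is the zone with the highest EI; exact argmax
#' ties are broken deterministically upper > mid > lower and flagged.
#'
#' @param zones A zone profile as returned by [zoneAggregate()].
#' @param thresholdPts Heterogeneity threshold in percentage points
#'   (default 15).
#' @return A list with `heterogeneous` (logical), `predominance` (one of
#'   `"none"`, `"upper"`, `"mid"`, `"lower"`; `"none"` iff homogeneous),
#'   `tie` (logical), and the input `zones`.
#' @examples
#' z <- zoneAggregate(c(RUL = 55, RML = 37, RLL = 32,
#'                      LUL = 55, LLi = 33, LLL = 28))
#' classifyDistribution(z)  # heterogeneous, upper-predominant
#' @export
classifyDistribution <- function(zones, thresholdPts = 15) {
  z <- c(upper = zones$upper, mid = zones$mid, lower = zones$lower)
  spread <- max(z) - min(z)
  het <- spread > thresholdPts
  if (!het)
    return(list(heterogeneous = FALSE, predominance = "none", tie = FALSE,
                zones = zones))
  top <- names(z)[z == max(z)]   # fixed order upper > mid > lower
  list(heterogeneous = TRUE, predominance = top[1], tie = length(top) > 1L,
       zones = zones)
}

#' Per-patient lobar profile and distribution phenotype
#'
#' End-to-end composition for one scan: lobar EIs from the CT volume and
#' lobe mask, zone aggregation, and the homogeneous/heterogeneous
#' predominance classification. Deterministic: identical inputs give
#' identical output.
#'
#' @param ct A [CTScan-class].
#' @param lobes A co-registered [LobeMask-class].
#' @param config A [qctConfig()] list.
#' @return A list with `ei_by_lobe` (named percent vector),
#'   `volumes` (named cm^3 vector), `zones`, and `phenotype`
#'   (see [classifyDistribution()]).
#' @export
phenotypePatient <- function(ct, lobes, config = qctConfig()) {
  checkAligned(ct, lobes)
  emph <- emphysemaMask(ct, lobes, config$thresholdHU)
  ei <- vapply(names(lobeLabels), function(lb) {
    sel <- lobes@labels == lobeLabels[[lb]]
    n <- sum(sel)
    if (n == 0L) return(NA_real_)
    100 * sum(emph@flags & sel) / n
  }, numeric(1))
  vols <- vapply(names(lobeLabels), function(lb)
    computeVolume(lobes, lobeLabels[[lb]]), numeric(1))
  zones <- zoneAggregate(ei, weighting = config$zoneWeighting,
                         volumes = vols)
  list(ei_by_lobe = ei, volumes = vols, zones = zones,
       phenotype = classifyDistribution(zones, config$heterogeneityPts))
}
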