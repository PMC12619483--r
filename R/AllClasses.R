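#' @useDynLib qctemph, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' Lobe label dictionary
#'
#' Integer labels used in lobe masks: 0 = non-lung, then the six lobes in the
#' fixed reporting order right upper lobe (RUL), middle lobe (RML), right
#' lower lobe (RLL), left upper lobe (LUL), lingula (LLi), left lower lobe
#' (LLL).
#'
#' @format Named integer vector of length 6.
#' @export
lobeLabels <- c(RUL = 1L, RML = 2L, RLL = 3L, LUL = 4L, LLi = 5L, LLL = 6L)

#' Composite reporting regions
#'
#' Label sets for the nine reporting regions: the six lobes, right lung,
#' left lung and whole lung.
#'
#' @format Named list of integer vectors.
#' @export
reportRegions <- c(
  lapply(lobeLabels, identity),
  list(RightLung = 1:3, LeftLung = 4:6, WholeLung = 1:6)
)

#' CTScan: a CT attenuation volume
#'
#' A 3D grid of CT attenuation values in Hounsfield units (HU) together with
#' the physical voxel spacing in mm. Grid axis 3 is the superior-inferior
#' (z) axis, increasing towards the apex; spacing along it is the
#' reconstructed slice thickness.
#'
#' @slot values 3D numeric array of attenuation values (HU).
#' @slot spacing Numeric vector of length 3, voxel edge lengths in mm (> 0),
#'   in grid-axis order (x, y, z).
#'
#' @seealso [CTScan()], [LobeMask-class], [emphysemaMask()]
#' @export
setClass("CTScan",
  representation(values = "array", spacing = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@values)) != 3L)
      msg <- c(msg, "'values' must be a 3D array")
    if (length(object@values) == 0L)
      msg <- c(msg, "'values' must be non-empty")
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
      msg <- c(msg, "'spacing' must be 3 strictly positive finite values (mm)")
    if (any(!is.finite(object@values)))
      msg <- c(msg, "all attenuation values must be finite")
    if (length(msg)) msg else TRUE
  }
)

#' LobeMask: a lobe-labelled lung segmentation
#'
#' Integer 3D grid co-registered with a [CTScan-class], assigning each voxel
#' to one of the six lobes (see [lobeLabels]) or to non-lung (0).
#'
#' @slot labels 3D integer array with values in 0..6.
#' @slot spacing Numeric vector of length 3, voxel spacing in mm.
#'
#' @export
setClass("LobeMask",
  representation(labels = "array", spacing = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@labels)) != 3L)
      msg <- c(msg, "'labels' must be a 3D array")
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
      msg <- c(msg, "'spacing' must be 3 strictly positive finite values (mm)")
    lab <- object@labels
    if (anyNA(lab) || !all(lab %in% 0:6))
      msg <- c(msg, "'labels' must only contain integers 0..6")
    if (length(msg)) msg else TRUE
  }
)

#' EmphysemaMask: thresholded emphysema voxels
#'
#' Logical 3D grid flagging the lung voxels whose attenuation lies strictly
#' below the emphysema threshold (default -950 HU). Constructed by
#' [emphysemaMask()]; flagged voxels are always a subset of lung voxels.
#'
#' @slot flags 3D logical array.
#' @slot thresholdHU The threshold used (HU).
#' @slot spacing Numeric vector of length 3, voxel spacing in mm.
#'
#' @export
setClass("EmphysemaMask",
  representation(flags = "array", thresholdHU = "numeric", spacing = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@flags)) != 3L || !is.logical(object@flags))
      msg <- c(msg, "'flags' must be a 3D logical array")
    if (length(object@thresholdHU) != 1L || !is.finite(object@thresholdHU))
      msg <- c(msg, "'thresholdHU' must be a single finite value")
    if (anyNA(object@flags))
      msg <- c(msg, "'flags' must not contain NA")
    if (length(msg)) msg else TRUE
  }
)

#' Construct a CTScan
#'
#' @param values 3D numeric array of attenuation values (HU).
#' @param spacing Voxel spacing in mm (length-3 positive numeric,
#'   x/y/z grid order; z is superior-inferior).
#' @return A [CTScan-class] object.
#' @examples
#' ct <- CTScan(array(-789, c(4, 4, 4)), spacing = c(1, 1, 1))
#' @export
CTScan <- function(values, spacing = c(1, 1, 1)) {
  new("CTScan", values = values, spacing = as.numeric(spacing))
}

#' Construct a LobeMask
#'
#' @param labels 3D integer array with values in 0..6 (see [lobeLabels]).
#' @param spacing Voxel spacing in mm (length-3 positive numeric).
#' @return A [LobeMask-class] object.
#' @export
LobeMask <- function(labels, spacing = c(1, 1, 1)) {
  storage.mode(labels) <- "integer"
  new("LobeMask", labels = labels, spacing = as.numeric(spacing))
}

setMethod("show", "CTScan", function(object) {
  d <- dim(object@values)
  cat(sprintf("CTScan: %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3],
              paste(format(object@spacing, digits = 3), collapse = " x ")))
  cat(sprintf("  HU range: [%.1f, %.1f]\n",
              min(object@values), max(object@values)))
})

setMethod("show", "LobeMask", function(object) {
  d <- dim(object@labels)
  present <- names(lobeLabels)[lobeLabels %in% unique(as.vector(object@labels))]
  cat(sprintf("LobeMask: %d x %d x %d voxels, %d lung voxels\n",
              d[1], d[2], d[3], sum(object@labels > 0L)))
  cat("  lobes present:", if (length(present)) paste(present, collapse = ", ")
      else "none", "\n")
})

setMethod("show", "EmphysemaMask", function(object) {
  d <- dim(object@flags)
  cat(sprintf("EmphysemaMask: %d x %d x %d voxels, %d flagged (< %g HU)\n",
              d[1], d[2], d[3], sum(object@flags), object@thresholdHU))
})
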