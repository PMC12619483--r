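#' @rdname accessors
#' @export
setGeneric("scanValues", function(x) standardGeneric("scanValues"))

#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' @rdname accessors
#' @export
setGeneric("maskLabels", function(x) standardGeneric("maskLabels"))

#' @rdname accessors
#' @export
setGeneric("emphFlags", function(x) standardGeneric("emphFlags"))

#' @rdname accessors
#' @export
setGeneric("thresholdHU", function(x) standardGeneric("thresholdHU"))

#' Accessors for imaging objects
#'
#' `scanValues()` returns the HU array of a [CTScan-class]; `maskLabels()`
#' the label array of a [LobeMask-class]; `emphFlags()` and `thresholdHU()`
#' the flag array and threshold of an [EmphysemaMask-class];
#' `voxelSpacing()` the physical voxel spacing (mm) of any of the three.
#'
#' @param x An imaging object.
#' @return The corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("scanValues", "CTScan", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("maskLabels", "LobeMask", function(x) x@labels)

#' @rdname accessors
#' @export
setMethod("emphFlags", "EmphysemaMask", function(x) x@flags)

#' @rdname accessors
#' @export
setMethod("thresholdHU", "EmphysemaMask", function(x) x@thresholdHU)

#' @rdname accessors
#' @export
setMethod("voxelSpacing", "CTScan", function(x) x@spacing)

#' @rdname accessors
#' @export
setMethod("voxelSpacing", "LobeMask", function(x) x@spacing)

#' @rdname accessors
#' @export
setMethod("voxelSpacing", "EmphysemaMask", function(x) x@spacing)
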