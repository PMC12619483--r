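#' Label emphysema clusters
#'
#' Connected-component labelling of the emphysema voxels under
#' 26-connectivity (voxels sharing a face, edge or corner are connected).
#' Labels are dense from 1 in grid scan order.
#'
#' @param emph An [EmphysemaMask-class].
#' @return A list with `labels` (integer array, 0 = background),
#'   `n_clusters`, and `cluster_sizes` (integer vector of voxel counts,
#'   indexed by label; sizes sum to the emphysema voxel count).
#' @export
clusterEmphysema <- function(emph) {
  labels <- .label_components_26(emph@flags, dim(emph@flags))
  n <- max(labels)
  sizes <- if (n > 0) tabulate(labels[labels > 0L], nbins = n) else integer()
  list(labels = labels, n_clusters = n, cluster_sizes = sizes)
}

# Logical array of same shape as x, shifted by one voxel along `axis` in
# direction `dir` (+1/-1), padding with FALSE: out-of-grid neighbours count
# as "not emphysema", so clusters touching the image boundary keep a border.
shiftLogical <- function(x, axis, dir) {
  d <- dim(x)
  out <- array(FALSE, d)
  idx <- lapply(d, seq_len)
  src <- idx
  if (dir > 0) {
    idx[[axis]] <- seq_len(d[axis] - 1L) + 1L
    src[[axis]] <- seq_len(d[axis] - 1L)
  } else {
    idx[[axis]] <- seq_len(d[axis] - 1L)
    src[[axis]] <- seq_len(d[axis] - 1L) + 1L
  }
  out[idx[[1]], idx[[2]], idx[[3]]] <- x[src[[1]], src[[2]], src[[3]]]
  out
}

#' Inner and border emphysema voxels
#'
#' A border voxel is an emphysema voxel with at least one face-adjacent
#' (6-neighbourhood) voxel that is not emphysema; non-lung voxels and
#' voxels outside the grid count as not-emphysema. Inner voxels are the
#' remaining emphysema voxels; the two counts partition the emphysema set.
#' ET1 = 10 * inner / border grows with cluster bulk: a single voxel has
#' ET1 = 0, large solid clusters have high ET1.
#'
#' @param emph An [EmphysemaMask-class].
#' @param within Optional logical array restricting which emphysema voxels
#'   are counted (adjacency is still evaluated on the full grid).
#' @return A list with `inner_count`, `border_count`, and logical arrays
#'   `inner`, `border`.
#' @export
classifyInnerBorder <- function(emph, within = NULL) {
  e <- emph@flags
  allEmphNb <- !logical(length(e))
  dim(allEmphNb) <- dim(e)
  for (axis in 1:3) for (dir in c(-1L, 1L))
    allEmphNb <- allEmphNb & shiftLogical(e, axis, dir)
  inner <- e & allEmphNb
  border <- e & !allEmphNb
  if (!is.null(within)) {
    inner <- inner & within
    border <- border & within
  }
  list(inner_count = sum(inner), border_count = sum(border),
       inner = inner, border = border)
}

#' Distance to the pleural surface
#'
#' Euclidean distance (mm) from every voxel to the nearest non-lung voxel,
#' computed with an exact separable distance transform honouring anisotropic
#' spacing. Distances are centre-to-centre: a lung voxel face-adjacent to
#' non-lung is one spacing away. Voxels outside the grid are not treated as
#' non-lung; a grid that is all lung yields infinite distances.
#'
#' @param lobes A [LobeMask-class].
#' @return Numeric array of distances in mm (0 at non-lung voxels).
#' @export
pleuralDistanceMap <- function(lobes) {
  .distance_to_background(lobes@labels > 0L, dim(lobes@labels),
                          as.numeric(lobes@spacing))
}

#' ET2: subpleural emphysema fraction
#'
#' Percentage of emphysema voxels lying within `rimMm` of the pleural
#' surface (distance to the nearest non-lung voxel at most `rimMm`). High
#' values indicate paraseptal/subpleural predominance.
#'
#' @param emph An [EmphysemaMask-class].
#' @param lobes The [LobeMask-class] defining the lung.
#' @param rimMm Rim width in mm (default 2.0).
#' @param within Optional logical array restricting the emphysema voxels
#'   counted (the rim is always measured against the whole-lung surface).
#' @param pleuralDistance Optional precomputed [pleuralDistanceMap()].
#' @return A list with `et2` (percent), `peripheral_count`, `total_count`,
#'   and `degenerate` (TRUE when there are no emphysema voxels; `et2` is
#'   then 0).
#' @export
computeET2 <- function(emph, lobes, rimMm = 2.0, within = NULL,
                       pleuralDistance = NULL) {
  e <- emph@flags
  if (!is.null(within)) e <- e & within
  total <- sum(e)
  if (total == 0L)
    return(list(et2 = 0, peripheral_count = 0L, total_count = 0L,
                degenerate = TRUE))
  if (is.null(pleuralDistance)) pleuralDistance <- pleuralDistanceMap(lobes)
  periph <- sum(pleuralDistance[e] <= rimMm)
  list(et2 = 100 * periph / total, peripheral_count = periph,
       total_count = total, degenerate = FALSE)
}

# Pseudo-lobule cell id for every voxel: the lung partitioned into
# axis-aligned cubes of edge ~lobuleMm (>= 1 voxel per axis), anchored at
# the grid origin.
lobuleCellIds <- function(dims, spacing, lobuleMm) {
  nCell <- pmax(1L, as.integer(round(lobuleMm / spacing)))
  ix <- (seq_len(dims[1]) - 1L) %/% nCell[1]
  iy <- (seq_len(dims[2]) - 1L) %/% nCell[2]
  iz <- (seq_len(dims[3]) - 1L) %/% nCell[3]
  nbx <- max(ix) + 1L
  nby <- max(iy) + 1L
  cell <- outer(outer(ix, iy * nbx, "+"), iz * nbx * nby, "+") + 1L
  storage.mode(cell) <- "integer"
  cell
}

#' ET3: panlobular emphysema fraction
#'
#' The lung is partitioned into axis-aligned cubic pseudo-lobules of edge
#' `lobuleMm` clipped to the lung. A pseudo-lobule is destroyed when its
#' within-lobule emphysema fraction reaches `destroyFrac`; ET3 is the
#' percentage of emphysema voxels lying in destroyed pseudo-lobules. The
#' index responds only once essentially whole lobules are destroyed, the
#' hallmark of panlobular emphysema.
#'
#' @param emph An [EmphysemaMask-class].
#' @param lobes The [LobeMask-class] defining the lung.
#' @param lobuleMm Pseudo-lobule edge length in mm (default 15).
#' @param destroyFrac Destruction threshold as a fraction (default 0.8).
#' @param within Optional logical array restricting the emphysema voxels
#'   counted (the partition and destruction calls use the whole lung).
#' @return A list with `et3` (percent), `panlobular_count`, `total_count`,
#'   `n_destroyed_lobules`, and `degenerate` (TRUE when there are no
#'   emphysema voxels; `et3` is then 0).
#' @export
computeET3 <- function(emph, lobes, lobuleMm = 15, destroyFrac = 0.8,
                       within = NULL) {
  e <- emph@flags
  if (!is.null(within)) e <- e & within
  total <- sum(e)
  if (total == 0L)
    return(list(et3 = 0, panlobular_count = 0L, total_count = 0L,
                n_destroyed_lobules = 0L, degenerate = TRUE))
  lung <- lobes@labels > 0L
  cell <- lobuleCellIds(dim(lung), lobes@spacing, lobuleMm)
  lungCells <- cell[lung]
  emphCells <- cell[lung & emph@flags]
  nLungPerCell <- tabulate(lungCells, nbins = max(cell))
  nEmphPerCell <- tabulate(emphCells, nbins = max(cell))
  destroyed <- which(nLungPerCell > 0L &
                     nEmphPerCell >= destroyFrac * nLungPerCell)
  pan <- sum(e & (cell %in% destroyed) & lung)
  list(et3 = 100 * pan / total, panlobular_count = pan, total_count = total,
       n_destroyed_lobules = length(destroyed), degenerate = FALSE)
}
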