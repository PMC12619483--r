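#' Specification for a synthetic lung phantom
#'
#' Describes a CT-like phantom: two plane-split ellipsoidal "lungs" on a
#' soft-tissue background, with an exact number of voxels per lobe set to
#' emphysematous attenuation to hit the requested lobar emphysema indices.
#' Attenuation noise is sampled from normals truncated at the -950 HU
#' threshold on each side, so the EI ground truth is exact regardless of
#' noise. Defaults: healthy parenchyma centred at -789 HU (the typical
#' healthy-lung mean; normal attenuation spans roughly -750 to -850 HU),
#' emphysema at -980 HU, 96^3 voxels at 1 mm isotropic spacing.
#'
#' @param dims Grid dimensions (default `c(96, 96, 96)`). Axis 3 is
#'   superior-inferior.
#' @param spacing Voxel spacing in mm (default 1 mm isotropic).
#' @param eiTargets Named numeric vector of lobar EI targets in percent
#'   (names RUL, RML, RLL, LUL, LLi, LLL; each in \[0, 95\]).
#' @param parenchymaHU,parenchymaSD Mean and SD of healthy-parenchyma
#'   attenuation (defaults -789 and 25; must stay above -900).
#' @param emphysemaHU,emphysemaSD Mean and SD of emphysema attenuation
#'   (defaults -980 and 15; mean must lie below -950).
#' @param backgroundHU Attenuation of non-lung voxels (default 40,
#'   soft tissue).
#' @param clusterVoxels Mean emphysema cluster size in voxels for the
#'   `"mixed"` placement (default 60).
#' @param placement One of `"mixed"` (random compact clusters, default),
#'   `"core"` (deepest voxels first), `"subpleural"` (closest to the pleura
#'   first), `"whole-lobule"` (entire pseudo-lobules destroyed).
#' @param lobuleMm Pseudo-lobule edge for `"whole-lobule"` placement
#'   (default 15 mm, matching [qctConfig()]).
#' @param seed Integer seed; identical spec + seed gives bit-identical
#'   output.
#' @return A list with class `"phantomSpec"`.
#' @export
phantomSpec <- function(dims = c(96, 96, 96), spacing = c(1, 1, 1),
                        eiTargets = c(RUL = 20, RML = 20, RLL = 20,
                                      LUL = 20, LLi = 20, LLL = 20),
                        parenchymaHU = -789, parenchymaSD = 25,
                        emphysemaHU = -980, emphysemaSD = 15,
                        backgroundHU = 40, clusterVoxels = 60,
                        placement = c("mixed", "core", "subpleural",
                                      "whole-lobule"),
                        lobuleMm = 15, seed = 1L) {
  placement <- match.arg(placement)
  need <- names(lobeLabels)
  if (!all(need %in% names(eiTargets)))
    stopStructural("eiTargets must name all six lobes")
  eiTargets <- eiTargets[need]
  if (any(eiTargets < 0 | eiTargets > 95))
    stopDomain("EI targets must lie in [0, 95] percent")
  if (emphysemaHU >= -950)
    stopDomain("emphysema mean attenuation must lie below -950 HU")
  if (parenchymaHU <= -900)
    stopDomain("parenchyma mean attenuation must lie above -900 HU")
  structure(list(dims = as.integer(dims), spacing = as.numeric(spacing),
                 eiTargets = eiTargets, parenchymaHU = parenchymaHU,
                 parenchymaSD = parenchymaSD, emphysemaHU = emphysemaHU,
                 emphysemaSD = emphysemaSD, backgroundHU = backgroundHU,
                 clusterVoxels = clusterVoxels, placement = placement,
                 lobuleMm = lobuleMm, seed = as.integer(seed)),
            class = "phantomSpec")
}

# Ellipsoidal lung labelled into three lobes by axial (z) planes at the
# 40% / 60% z-quantiles of the lung's voxels: lower lobe below, middle
# lobe / lingula between, upper lobe above (axis 3 increases superiorly).
buildLungLobes <- function(dims, centerFrac, semiFrac, labels) {
  cx <- centerFrac * dims
  ax <- semiFrac * dims
  x <- (seq_len(dims[1]) - cx[1]) / ax[1]
  y <- (seq_len(dims[2]) - cx[2]) / ax[2]
  z <- (seq_len(dims[3]) - cx[3]) / ax[3]
  r2 <- outer(outer(x^2, y^2, "+"), z^2, "+")
  inside <- r2 <= 1
  zIdx <- array(rep(seq_len(dims[3]), each = dims[1] * dims[2]), dims)
  zq <- stats::quantile(zIdx[inside], c(0.4, 0.6), type = 1)
  lab <- array(0L, dims)
  lab[inside & zIdx > zq[2]] <- labels["upper"]
  lab[inside & zIdx > zq[1] & zIdx <= zq[2]] <- labels["middle"]
  lab[inside & zIdx <= zq[1]] <- labels["lower"]
  lab
}

#' Generate a synthetic lung phantom
#'
#' Builds the CT volume, lobe mask and ground-truth record described by a
#' [phantomSpec()]. Each lobe is trimmed to a voxel count divisible by 100
#' so that any integer-percent EI target is met *exactly* by integer voxel
#' assignment; for fractional targets the achieved EI (recorded in the
#' truth) is the nearest integer count. In `"whole-lobule"` placement, only entire
#' pseudo-lobules are destroyed, so the achieved EI is the closest value not
#' exceeding the target attainable with whole lobules (and ET3 is 100 by
#' construction).
#'
#' @param spec A [phantomSpec()].
#' @return A list with `ct` ([CTScan-class]), `lobes` ([LobeMask-class]) and
#'   `truth`, a list with per-lobe voxel counts, emphysema counts, achieved
#'   EIs, the placement mode, cluster sizes (mixed placement), destroyed
#'   pseudo-lobule count (whole-lobule placement), and the spec itself.
#' @examples
#' ph <- generatePhantom(phantomSpec(dims = c(32, 32, 32), seed = 7))
#' ph$truth$ei_achieved
#' @export
generatePhantom <- function(spec) {
  stopifnot(inherits(spec, "phantomSpec"))
  withSeed(spec$seed, {
    dims <- spec$dims
    right <- buildLungLobes(dims, centerFrac = c(0.30, 0.50, 0.50),
                            semiFrac = c(0.17, 0.30, 0.42),
                            labels = c(upper = lobeLabels[["RUL"]],
                                       middle = lobeLabels[["RML"]],
                                       lower = lobeLabels[["RLL"]]))
    left <- buildLungLobes(dims, centerFrac = c(0.70, 0.50, 0.50),
                           semiFrac = c(0.17, 0.30, 0.42),
                           labels = c(upper = lobeLabels[["LUL"]],
                                      middle = lobeLabels[["LLi"]],
                                      lower = lobeLabels[["LLL"]]))
    lab <- right
    lab[left > 0L] <- left[left > 0L]

    # trim each lobe to a multiple of 100 voxels (drop trailing voxels in
    # scan order) so any integer-percent EI target is exactly attainable
    for (l in lobeLabels) {
      idx <- which(lab == l)
      drop <- length(idx) %% 100L
      if (drop > 0L) lab[idx[seq.int(length(idx) - drop + 1L, length(idx))]] <- 0L
    }
    lungIdx <- which(lab > 0L)
    if (length(lungIdx) == 0L) stopDomain("phantom grid too small: no lung")

    pd <- .distance_to_background(lab > 0L, dims, spec$spacing)
    cell <- lobuleCellIds(dims, spec$spacing, spec$lobuleMm)

    emph <- logical(length(lab))
    truthLobe <- list()
    clusterSizesAll <- list()
    nDestroyed <- 0L
    coordsOf <- function(idx) {
      arrayInd(idx, dims)
    }
    for (ln in names(lobeLabels)) {
      l <- lobeLabels[[ln]]
      idx <- which(lab == l)
      n <- length(idx)
      target <- spec$eiTargets[[ln]]
      k <- as.integer(round(target / 100 * n))
      if (k > n) stopDomain("EI target %.1f%% infeasible for lobe %s", target, ln)
      chosen <- integer()
      if (k > 0L) {
        if (spec$placement == "core") {
          o <- order(-pd[idx], idx)
          chosen <- idx[o[seq_len(k)]]
        } else if (spec$placement == "subpleural") {
          o <- order(pd[idx], idx)
          chosen <- idx[o[seq_len(k)]]
        } else if (spec$placement == "whole-lobule") {
          # only pseudo-lobules whose lung voxels lie entirely in this lobe
          # are candidates, so destroying them destroys the whole lobule
          cells <- cell[idx]
          nInLobe <- table(cells)
          nInLung <- tabulate(cell[lab > 0L], nbins = max(cell))
          contained <- nInLobe[nInLung[as.integer(names(nInLobe))] ==
                               as.integer(nInLobe)]
          sizes <- sort(contained, decreasing = TRUE)
          tot <- 0L
          for (cid in names(sizes)) {
            s <- sizes[[cid]]
            if (tot + s <= k) {
              chosen <- c(chosen, idx[cells == as.integer(cid)])
              tot <- tot + s
              nDestroyed <- nDestroyed + 1L
            }
          }
          k <- tot  # achieved count: whole lobules only
        } else {  # mixed: compact clusters grown around random seeds
          xyz <- coordsOf(idx)
          phys <- sweep(xyz, 2, spec$spacing, "*")
          assigned <- logical(n)
          sizes <- integer()
          remaining <- k
          while (remaining > 0L) {
            free <- which(!assigned)
            seedPos <- free[sample.int(length(free), 1L)]
            s <- min(remaining,
                     1L + stats::rgeom(1L, 1 / spec$clusterVoxels))
            d2 <- colSums((t(phys[free, , drop = FALSE]) -
                           phys[seedPos, ])^2)
            take <- free[order(d2, free)[seq_len(min(s, length(free)))]]
            assigned[take] <- TRUE
            sizes <- c(sizes, length(take))
            remaining <- remaining - length(take)
          }
          chosen <- idx[assigned]
          clusterSizesAll[[ln]] <- sizes
        }
        emph[chosen] <- TRUE
      }
      truthLobe[[ln]] <- list(n_voxels = n, n_emph = length(chosen),
                              ei_target = target,
                              ei_achieved = if (n > 0) 100 * length(chosen) / n
                                            else NA_real_)
    }

    # attenuation: truncated normals that never cross the -950 HU threshold
    vals <- array(spec$backgroundHU, dims)
    paren <- lungIdx[!emph[lungIdx]]
    vals[paren] <- rtruncnorm(length(paren), spec$parenchymaHU,
                              spec$parenchymaSD, lower = -950, upper = -600)
    eidx <- which(emph)
    vals[eidx] <- rtruncnorm(length(eidx), spec$emphysemaHU,
                             spec$emphysemaSD, lower = -1024,
                             upper = -950 - 1e-6)

    truth <- list(
      lobes = truthLobe,
      ei_achieved = vapply(truthLobe, function(x) x$ei_achieved, numeric(1)),
      n_emph_total = sum(emph),
      placement = spec$placement,
      cluster_sizes = clusterSizesAll,
      n_destroyed_lobules = nDestroyed,
      subpleural_count = sum(pd[emph] <= 2.0),
      spec = unclass(spec)
    )
    list(ct = CTScan(vals, spec$spacing),
         lobes = LobeMask(lab, spec$spacing),
         truth = truth)
  })
}
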