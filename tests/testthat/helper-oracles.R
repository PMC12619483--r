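# Independent brute-force oracles and tiny fixture builders used across the
# suite. Each oracle deliberately uses a different route than the package
# implementation it checks.

# A rectangular slab of lung (single lobe label) surrounded by one voxel of
# non-lung margin, uniform attenuation `hu`.
slabPair <- function(dims = c(6, 6, 6), hu = -789, label = 1L,
                     spacing = c(1, 1, 1)) {
  vals <- array(40, dims)
  lab <- array(0L, dims)
  core <- lapply(dims, function(d) 2:(d - 1))
  lab[core[[1]], core[[2]], core[[3]]] <- label
  vals[lab > 0L] <- hu
  list(ct = CTScan(vals, spacing), lobes = LobeMask(lab, spacing))
}

# Linear-interpolation quantile written out by hand (inclusive convention):
# h = (n-1)p; value = x_(floor(h)+1) + frac(h) * (x_(floor(h)+2) - x_(floor(h)+1))
quantileOracle <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p
  lo <- floor(h) + 1
  if (lo >= n) return(x[n])
  x[lo] + (h - floor(h)) * (x[lo + 1] - x[lo])
}

# Connected components of a logical 3D grid under 26-connectivity, via an
# igraph adjacency construction (independent of the package's flood fill).
componentsOracle <- function(flags) {
  d <- dim(flags)
  idx <- which(flags)
  if (length(idx) == 0) return(integer(0))
  co <- arrayInd(idx, d)
  id <- seq_along(idx)
  pos <- array(0L, d)
  pos[idx] <- id
  edges <- list()
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  for (r in seq_len(nrow(offs))) {
    nb <- sweep(co, 2, offs[r, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    if (!any(ok)) next
    nbId <- pos[nb[ok, , drop = FALSE]]
    src <- id[ok][nbId > 0]
    dst <- nbId[nbId > 0]
    if (length(src)) edges[[length(edges) + 1]] <- cbind(src, dst)
  }
  g <- igraph::graph_from_edgelist(do.call(rbind, c(list(cbind(id, id)), edges)),
                                   directed = FALSE)
  igraph::components(g)$membership[id]
}

# Per-voxel 6-neighbourhood scan classifying emphysema voxels as inner or
# border (out-of-grid counts as not-emphysema).
innerBorderOracle <- function(flags) {
  d <- dim(flags)
  idx <- which(flags)
  co <- arrayInd(idx, d)
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  isInner <- vapply(seq_along(idx), function(i) {
    for (r in 1:6) {
      nb <- co[i, ] + offs[r, ]
      if (any(nb < 1) || any(nb > d)) return(FALSE)
      if (!flags[nb[1], nb[2], nb[3]]) return(FALSE)
    }
    TRUE
  }, logical(1))
  list(inner = sum(isInner), border = sum(!isInner))
}

# Solid ball of emphysema of radius r voxels centred in a lung slab.
ballPair <- function(r, margin = 3) {
  n <- 2 * (r + margin) + 1
  ctr <- r + margin + 1
  vals <- array(-789, c(n, n, n))
  lab <- array(1L, c(n, n, n))
  g <- expand.grid(x = 1:n, y = 1:n, z = 1:n)
  inBall <- (g$x - ctr)^2 + (g$y - ctr)^2 + (g$z - ctr)^2 <= r^2
  vals[cbind(g$x, g$y, g$z)[inBall, ]] <- -980
  list(ct = CTScan(vals), lobes = LobeMask(lab))
}

# Independent re-statement of the three-zone classification rule, written
# as plain arithmetic on the six lobar EIs.
zoneRuleOracle <- function(ei, thresholdPts = 15) {
  up <- (ei[["RUL"]] + ei[["LUL"]]) / 2
  mid <- (ei[["RML"]] + ei[["LLi"]]) / 2
  lo <- (ei[["RLL"]] + ei[["LLL"]]) / 2
  z <- c(up, mid, lo)
  if (max(z) - min(z) <= thresholdPts) return("none")
  c("upper", "mid", "lower")[which.max(z)]
}
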