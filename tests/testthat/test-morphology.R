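emphOf <- function(flags, spacing = c(1, 1, 1)) {
  new("EmphysemaMask", flags = flags, thresholdHU = -950, spacing = spacing)
}

test_that("cluster labelling follows 26-connectivity conventions", {
  # two voxels touching only at a cube corner form one cluster
  f <- array(FALSE, c(3, 3, 3))
  f[1, 1, 1] <- TRUE; f[2, 2, 2] <- TRUE
  expect_equal(clusterEmphysema(emphOf(f))$n_clusters, 1)

  # two voxels separated by an empty voxel are two clusters
  g <- array(FALSE, c(3, 1, 1))
  g[1, 1, 1] <- TRUE; g[3, 1, 1] <- TRUE
  cl <- clusterEmphysema(emphOf(g))
  expect_equal(cl$n_clusters, 2)
  expect_equal(sum(cl$cluster_sizes), 2)
})

test_that("cluster partition agrees with an igraph components oracle", {
  skip_if_not_installed("igraph")
  set.seed(91)
  for (i in 1:40) {
    d <- sample(4:20, 3, replace = TRUE)
    f <- array(runif(prod(d)) < runif(1, 0.05, 0.4), d)
    got <- clusterEmphysema(emphOf(f))
    want <- componentsOracle(f)
    expect_equal(got$n_clusters, length(unique(want)))
    # identical partitions up to label permutation
    gl <- got$labels[f]
    expect_equal(length(unique(paste(gl, want))), got$n_clusters)
    expect_equal(sum(got$cluster_sizes), sum(f))
  }
})

test_that("inner/border classification partitions the emphysema set", {
  # single isolated voxel: all border, ET1 = 0
  f <- array(FALSE, c(3, 3, 3)); f[2, 2, 2] <- TRUE
  ib <- classifyInnerBorder(emphOf(f))
  expect_equal(ib$inner_count, 0)
  expect_equal(ib$border_count, 1)

  # solid 3x3x3 cube inside lung: 1 inner, 26 border
  f <- array(FALSE, c(5, 5, 5)); f[2:4, 2:4, 2:4] <- TRUE
  ib <- classifyInnerBorder(emphOf(f))
  expect_equal(ib$inner_count, 1)
  expect_equal(ib$border_count, 26)

  # a cube flush with the image boundary: out-of-grid counts as
  # not-emphysema, so the 26 outer voxels are border, the centre is inner
  f <- array(TRUE, c(3, 3, 3))
  ib <- classifyInnerBorder(emphOf(f))
  expect_equal(ib$inner_count, 1)
  expect_equal(ib$border_count, 26)

  set.seed(17)
  for (i in 1:25) {
    d <- sample(4:16, 3, replace = TRUE)
    f <- array(runif(prod(d)) < runif(1, 0.1, 0.6), d)
    ib <- classifyInnerBorder(emphOf(f))
    want <- innerBorderOracle(f)
    expect_equal(ib$inner_count, want$inner)
    expect_equal(ib$border_count, want$border)
    expect_equal(ib$inner_count + ib$border_count, sum(f))  # partition
  }
})

test_that("ET1 increases strictly with ball radius", {
  et1 <- vapply(c(3, 5, 8), function(r) {
    p <- ballPair(r)
    e <- emphysemaMask(p$ct, p$lobes)
    ib <- classifyInnerBorder(e)
    want <- innerBorderOracle(emphFlags(e))
    expect_equal(ib$inner_count, want$inner)
    10 * ib$inner_count / ib$border_count
  }, numeric(1))
  expect_true(all(diff(et1) > 0))
})

test_that("ET2 counts emphysema within the pleural rim", {
  p <- slabPair(dims = c(10, 10, 10), hu = -789)
  lab <- maskLabels(p$lobes)
  pd <- pleuralDistanceMap(p$lobes)

  # surface-layer emphysema only: ET2 = 100
  surf <- lab > 0 & pd <= 1
  ctS <- p$ct; ctS@values[surf] <- -980
  eS <- emphysemaMask(ctS, p$lobes)
  expect_equal(computeET2(eS, p$lobes, rimMm = 2)$et2, 100)

  # core-only emphysema deeper than the rim: ET2 = 0
  core <- lab > 0 & pd > 2
  ctC <- p$ct; ctC@values[core] <- -980
  eC <- emphysemaMask(ctC, p$lobes)
  expect_equal(computeET2(eC, p$lobes, rimMm = 2)$et2, 0)

  # equal rim/core counts: ET2 = 50 exactly; distances validated by an
  # exhaustive pairwise scan
  nonLung <- which(lab == 0)
  nlCo <- arrayInd(nonLung, dim(lab))
  bruteDist <- function(i) {
    co <- arrayInd(i, dim(lab))
    sqrt(min(colSums((t(nlCo) - as.vector(co))^2)))
  }
  surfIdx <- which(surf)[1:4]
  coreIdx <- which(core)[1:4]
  for (i in c(surfIdx, coreIdx)) expect_equal(pd[i], bruteDist(i))
  ctH <- p$ct; ctH@values[c(surfIdx, coreIdx)] <- -980
  eH <- emphysemaMask(ctH, p$lobes)
  expect_equal(computeET2(eH, p$lobes, rimMm = 2)$et2, 50)

  # shrinking the rim never increases ET2; a rim covering the lung gives 100
  rims <- c(0.5, 1, 2, 4, 8, 50)
  et2s <- vapply(rims, function(r) computeET2(eH, p$lobes, rimMm = r)$et2,
                 numeric(1))
  expect_true(all(diff(et2s) >= 0))
  expect_equal(et2s[length(rims)], 100)

  # no emphysema: defined as 0 with a degenerate flag
  eN <- emphysemaMask(p$ct, p$lobes)
  r <- computeET2(eN, p$lobes)
  expect_equal(r$et2, 0)
  expect_true(r$degenerate)
})

test_that("ET3 responds only to destroyed pseudo-lobules", {
  p <- slabPair(dims = c(14, 14, 14), hu = -789)
  lab <- maskLabels(p$lobes)

  # scattered sparse emphysema below the destruction threshold: ET3 = 0
  lung <- which(lab > 0)
  ctA <- p$ct; ctA@values[lung[seq(1, length(lung), by = 17)]] <- -980
  eA <- emphysemaMask(ctA, p$lobes)
  expect_equal(computeET3(eA, p$lobes, lobuleMm = 5, destroyFrac = 0.8)$et3, 0)

  # whole lung emphysematous: ET3 = 100
  ctB <- p$ct; ctB@values[lung] <- -980
  eB <- emphysemaMask(ctB, p$lobes)
  expect_equal(computeET3(eB, p$lobes, lobuleMm = 5, destroyFrac = 0.8)$et3, 100)

  # one fully destroyed 4-voxel-edge pseudo-lobule plus s scattered voxels:
  # ET3 = 100 v / (v + s); the 4^3 cell at voxels 5..8 lies inside the lung
  ctC <- p$ct
  cellVox <- as.matrix(expand.grid(5:8, 5:8, 5:8))
  ctC@values[cellVox] <- -980
  v <- nrow(cellVox)
  far <- rbind(c(2, 2, 2), c(2, 3, 2), c(12, 12, 12))  # outside that cell
  ctC@values[far] <- -980
  s <- nrow(far)
  eC <- emphysemaMask(ctC, p$lobes)
  got <- computeET3(eC, p$lobes, lobuleMm = 4, destroyFrac = 0.8)
  expect_equal(got$et3, 100 * v / (v + s))
  expect_equal(got$n_destroyed_lobules, 1)

  # no emphysema: 0 with degenerate flag
  r <- computeET3(emphysemaMask(p$ct, p$lobes), p$lobes)
  expect_true(r$degenerate)
  expect_equal(r$et3, 0)
})
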