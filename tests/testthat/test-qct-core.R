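test_that("emphysema thresholding is strict and masked to the lung", {
  p <- slabPair(hu = -980)
  expect_equal(sum(emphFlags(emphysemaMask(p$ct, p$lobes))),
               sum(maskLabels(p$lobes) > 0))           # all lung flagged
  p2 <- slabPair(hu = -789)
  expect_equal(sum(emphFlags(emphysemaMask(p2$ct, p2$lobes))), 0)

  # a voxel at exactly -950 HU is parenchyma, one epsilon below is emphysema
  p3 <- slabPair(hu = -950)
  expect_equal(sum(emphFlags(emphysemaMask(p3$ct, p3$lobes))), 0)
  p3$ct@values[2, 2, 2] <- -950.0001
  expect_equal(sum(emphFlags(emphysemaMask(p3$ct, p3$lobes))), 1)

  # constructed 30% mixture recovers EI = 30 exactly
  p4 <- slabPair(dims = c(12, 12, 12), hu = -789)
  lung <- which(maskLabels(p4$lobes) > 0)
  k <- round(0.3 * length(lung))
  p4$ct@values[lung[seq_len(k)]] <- -980
  m <- regionMetrics(p4$ct, p4$lobes)
  expect_equal(m$ei, 100 * k / length(lung))
  expect_equal(m$n_emph_voxels, k)

  # shape mismatch and empty lung are distinct errors
  expect_error(emphysemaMask(p4$ct, LobeMask(array(1L, c(3, 3, 3)))),
               class = "qctemph_structural_error")
  empty <- LobeMask(array(0L, c(12, 12, 12)))
  expect_error(emphysemaMask(p4$ct, empty), class = "qctemph_domain_error")
})

test_that("MLD is the arithmetic mean over the region", {
  p <- slabPair(hu = -789)
  sel <- maskLabels(p$lobes) > 0
  expect_equal(computeMLD(p$ct, sel), -789)
  p$ct@values[sel][1:2] <- c(-700, -800)  # no-op on copy; build explicitly
  ct <- CTScan(array(c(-700, -800), c(2, 1, 1)))
  expect_equal(computeMLD(ct, array(TRUE, c(2, 1, 1))), -750)
  expect_error(computeMLD(ct, array(FALSE, c(2, 1, 1))),
               class = "qctemph_domain_error")

  # analytic mixture mean: 30% at -980, 70% at -789
  vals <- array(rep(c(-980, -789), c(30, 70)), c(10, 10, 1))
  expect_equal(computeMLD(CTScan(vals), array(TRUE, c(10, 10, 1))), -846.3)
})

test_that("PD15 matches the sort-and-interpolate oracle and is monotone", {
  ramp <- array(seq(-1000, -901), c(10, 10, 1))
  ct <- CTScan(ramp)
  all <- array(TRUE, c(10, 10, 1))
  expect_equal(computePD15(ct, all), quantileOracle(as.vector(ramp), 0.15))

  set.seed(71)
  for (i in 1:25) {
    n <- sample(10:500, 1)
    vals <- runif(n, -1024, -700)
    ct <- CTScan(array(vals, c(n, 1, 1)))
    reg <- array(TRUE, c(n, 1, 1))
    frac <- runif(1, 0.05, 0.95)
    expect_equal(computePD15(ct, reg, frac), quantileOracle(vals, frac),
                 tolerance = 1e-9)
  }

  # adding -1000 HU voxels (left-tail mass) strictly decreases PD15
  base <- runif(200, -900, -760)
  pdBefore <- computePD15(CTScan(array(base, c(200, 1, 1))),
                          array(TRUE, c(200, 1, 1)))
  aug <- c(base, rep(-1000, 50))
  pdAfter <- computePD15(CTScan(array(aug, c(250, 1, 1))),
                         array(TRUE, c(250, 1, 1)))
  expect_lt(pdAfter, pdBefore)

  expect_error(computePD15(CTScan(array(-800, c(1, 1, 1))),
                           array(TRUE, c(1, 1, 1))),
               class = "qctemph_domain_error")
})

test_that("volume is voxel count times voxel volume", {
  lm <- LobeMask(array(1L, c(10, 10, 10)))
  expect_equal(computeVolume(lm, 1), 1.0)               # 1000 x 1 mm^3
  lm1 <- LobeMask(array(c(1L, rep(0L, 7)), c(2, 2, 2)),
                  spacing = c(0.7, 0.7, 1.0))
  expect_equal(computeVolume(lm1, 1), 0.00049)
  set.seed(5)
  lab <- array(sample(0:1, 1000, replace = TRUE), c(10, 10, 10))
  lm2 <- LobeMask(lab, spacing = c(0.6, 0.6, 1.0))
  expect_equal(computeVolume(lm2, 1), sum(lab == 1) * 0.36 / 1000)
})

test_that("EI is conserved across lobes and monotone in the threshold", {
  ph <- generatePhantom(phantomSpec(dims = c(48, 48, 48),
                                    eiTargets = c(RUL = 55, RML = 37, RLL = 32,
                                                  LUL = 55, LLi = 33, LLL = 28),
                                    seed = 21))
  m <- allRegionMetrics(ph$ct, ph$lobes)
  lobes <- m[m$region %in% names(lobeLabels), ]
  whole <- m[m$region == "WholeLung", ]
  expect_equal(whole$ei,
               sum(lobes$ei * lobes$n_lung_voxels) / sum(lobes$n_lung_voxels))
  expect_equal(whole$n_lung_voxels, sum(lobes$n_lung_voxels))

  eis <- vapply(c(-1000, -975, -950, -925, -900), function(th) {
    e <- emphysemaMask(ph$ct, ph$lobes, th)
    100 * sum(emphFlags(e)) / sum(maskLabels(ph$lobes) > 0)
  }, numeric(1))
  expect_true(all(diff(eis) >= 0))
})

test_that("metrics for a region absent from the mask are flagged missing", {
  p <- slabPair(hu = -789)                    # only label 1 present
  m <- regionMetrics(p$ct, p$lobes, region = lobeLabels[["RML"]])
  expect_true(m$missing_region)
  expect_true(is.na(m$mld) && is.na(m$ei))

  all9 <- allRegionMetrics(p$ct, p$lobes)
  expect_true(all9$missing_region[all9$region == "LLi"])
  expect_false(all9$missing_region[all9$region == "RUL"])
})
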