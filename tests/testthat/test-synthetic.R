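test_that("phantom generation is seed-deterministic and hits EI targets", {
  sp <- phantomSpec(dims = c(48, 48, 48),
                    eiTargets = c(RUL = 55, RML = 37, RLL = 32,
                                  LUL = 55, LLi = 33, LLL = 28), seed = 77)
  a <- generatePhantom(sp)
  b <- generatePhantom(sp)
  expect_identical(scanValues(a$ct), scanValues(b$ct))
  expect_identical(maskLabels(a$lobes), maskLabels(b$lobes))
  expect_identical(a$truth, b$truth)

  # integer-percent targets are achieved exactly, and measurement agrees
  expect_equal(unname(a$truth$ei_achieved), c(55, 37, 32, 55, 33, 28))
  m <- phenotypePatient(a$ct, a$lobes)
  expect_equal(m$ei_by_lobe, a$truth$ei_achieved)

  # a different seed changes the noise but not the EI ground truth
  c2 <- generatePhantom(phantomSpec(dims = c(48, 48, 48),
                                    eiTargets = sp$eiTargets, seed = 78))
  expect_false(identical(scanValues(a$ct), scanValues(c2$ct)))
  expect_equal(c2$truth$ei_achieved, a$truth$ei_achieved)
})

test_that("attenuation noise never crosses the -950 HU threshold", {
  ph <- generatePhantom(phantomSpec(dims = c(40, 40, 40),
                                    eiTargets = c(RUL = 30, RML = 30, RLL = 30,
                                                  LUL = 30, LLi = 30, LLL = 30),
                                    parenchymaSD = 80, emphysemaSD = 60,
                                    seed = 31))
  m <- allRegionMetrics(ph$ct, ph$lobes)
  lob <- m[m$region %in% names(lobeLabels), ]
  expect_equal(lob$ei, unname(ph$truth$ei_achieved))  # EI unaffected by noise

  # all-zero targets: empty emphysema mask, MLD near the parenchyma mean
  ph0 <- generatePhantom(phantomSpec(dims = c(40, 40, 40),
                                     eiTargets = c(RUL = 0, RML = 0, RLL = 0,
                                                   LUL = 0, LLi = 0, LLL = 0),
                                     seed = 31))
  e0 <- emphysemaMask(ph0$ct, ph0$lobes)
  expect_equal(sum(emphFlags(e0)), 0)
  expect_equal(computeMLD(ph0$ct, maskLabels(ph0$lobes) > 0), -789,
               tolerance = 1)
})

test_that("placement modes produce their advertised geometry", {
  ei <- c(RUL = 10, RML = 10, RLL = 10, LUL = 10, LLi = 10, LLL = 10)
  sub <- generatePhantom(phantomSpec(dims = c(48, 48, 48), eiTargets = ei,
                                     placement = "subpleural", seed = 41))
  eS <- emphysemaMask(sub$ct, sub$lobes)
  expect_equal(computeET2(eS, sub$lobes, rimMm = 2)$et2, 100)

  core <- generatePhantom(phantomSpec(dims = c(48, 48, 48), eiTargets = ei,
                                      placement = "core", seed = 41))
  eC <- emphysemaMask(core$ct, core$lobes)
  expect_equal(computeET2(eC, core$lobes, rimMm = 2)$et2, 0)

  wl <- generatePhantom(phantomSpec(dims = c(64, 64, 64),
                                    eiTargets = ei * 3,
                                    placement = "whole-lobule", seed = 41))
  eW <- emphysemaMask(wl$ct, wl$lobes)
  expect_equal(computeET3(eW, wl$lobes)$et3, 100)
  expect_gt(wl$truth$n_destroyed_lobules, 0)
})

test_that("infeasible phantom specs are rejected", {
  expect_error(phantomSpec(eiTargets = c(RUL = 99, RML = 0, RLL = 0,
                                         LUL = 0, LLi = 0, LLL = 0)),
               class = "qctemph_domain_error")
  expect_error(phantomSpec(emphysemaHU = -900),
               class = "qctemph_domain_error")
  expect_error(phantomSpec(parenchymaHU = -940),
               class = "qctemph_domain_error")
})

test_that("cohort generation respects group sizes and serum bands", {
  co <- generateCohort(cohortSpec(seed = 55))
  tab <- table(co$cohort$group)
  expect_equal(unname(tab[c("reduced-to-normal", "moderate", "severe")]),
               c(13L, 16L, 46L), ignore_attr = TRUE)
  s <- co$cohort$serum_aat
  g <- as.character(co$cohort$group)
  expect_true(all(s[g == "severe"] <= 40))
  expect_true(all(s[g == "moderate"] > 40 & s[g == "moderate"] <= 70))
  expect_true(all(s[g == "reduced-to-normal"] > 70))

  expect_identical(generateCohort(cohortSpec(seed = 55))$cohort, co$cohort)

  # group serum means stay within 3 SE of the spec means
  spec <- cohortSpec(seed = 55)
  for (gi in 1:3) {
    gname <- c("reduced-to-normal", "moderate", "severe")[gi]
    x <- s[g == gname]
    se <- spec$serumSD[gi] / sqrt(length(x))
    expect_lt(abs(mean(x) - spec$serumMean[gi]), 3 * se + 3)  # +3: truncation shift
  }
})

test_that("planted logistic coefficients are recovered at large n", {
  big <- cohortSpec(nPerGroup = c("reduced-to-normal" = 520, moderate = 640,
                                  severe = 1840), seed = 99)
  co <- generateCohort(big)$cohort
  fit <- glm(mid_predominant ~ age + serum_aat, binomial(), co)
  sm <- summary(fit)$coefficients
  expect_lt(abs(sm["age", "Estimate"] - 0.06), 2 * sm["age", "Std. Error"])
  expect_lt(abs(sm["serum_aat", "Estimate"] + 0.05),
            2 * sm["serum_aat", "Std. Error"])

  # bias shrinks with n (checked against a small-n fit)
  small <- generateCohort(cohortSpec(nPerGroup = c("reduced-to-normal" = 52,
                                                   moderate = 64, severe = 184),
                                     seed = 99))$cohort
  fitS <- glm(mid_predominant ~ age + serum_aat, binomial(), small)
  seS <- summary(fitS)$coefficients[, "Std. Error"]
  seB <- sm[, "Std. Error"]
  expect_true(all(seB < seS))             # information grows with n

  # null coefficients give a flat mid-predominance rate near plogis(beta0)
  nul <- generateCohort(cohortSpec(nPerGroup = c("reduced-to-normal" = 500,
                                                 moderate = 500, severe = 1000),
                                   betaAge = 0, betaSerum = 0, beta0 = -1,
                                   seed = 7))$cohort
  rate <- mean(nul$mid_predominant)
  expect_lt(abs(rate - plogis(-1)), 3 * sqrt(plogis(-1) * (1 - plogis(-1)) / 2000))
})
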