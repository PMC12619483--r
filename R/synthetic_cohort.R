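#' Specification for a synthetic AATD cohort
#'
#' Describes a cohort with the three serum-level groups of an AATD referral
#' population and a planted logistic dependence of middle-lobe/lingula-
#' predominant emphysema on age and serum level. Group sizes, serum
#' distributions and covariate distributions default to values typical of a
#' monocentric AATD referral cohort (13 reduced-to-normal, 16 moderate and
#' 46 severe patients; serum means 88.5, 57.9 and 16.7 mg/dl). Serum draws
#' are truncated normals confined to their group band, so every draw
#' respects the group definition.
#'
#' @param nPerGroup Named integer vector of group sizes in the order
#'   reduced-to-normal, moderate, severe (default `c(13, 16, 46)`).
#' @param serumMean,serumSD Per-group serum mean and SD in mg/dl (same
#'   order; defaults 88.5/57.9/16.7 and 11.4/9.1/9.9).
#' @param ageMean,ageSD Per-group age distributions in years.
#' @param femaleProb Per-group probability of female sex.
#' @param bmiMean,bmiSD Per-group BMI (kg/m^2).
#' @param packYearsMean,packYearsSD Per-group pack-years.
#' @param fev1Mean,fev1SD Per-group FEV1 in % predicted.
#' @param rvMean,rvSD Per-group residual volume in litres.
#' @param beta0,betaAge,betaSerum Planted logistic coefficients for the
#'   mid-predominant outcome: log-odds = beta0 + betaAge * age +
#'   betaSerum * serum (defaults -2.2, 0.06 per year, -0.05 per mg/dl).
#' @param seed Integer seed; identical spec + seed gives identical tables.
#' @return A list with class `"cohortSpec"`.
#' @export
cohortSpec <- function(nPerGroup = c("reduced-to-normal" = 13,
                                     moderate = 16, severe = 46),
                       serumMean = c(88.5, 57.9, 16.7),
                       serumSD = c(11.4, 9.1, 9.9),
                       ageMean = c(58.0, 54.7, 53.2),
                       ageSD = c(16.2, 17.4, 13.3),
                       femaleProb = c(3 / 13, 9 / 16, 26 / 46),
                       bmiMean = c(27.4, 24.0, 24.9),
                       bmiSD = c(6.0, 5.8, 5.8),
                       packYearsMean = c(14.9, 39.4, 15.1),
                       packYearsSD = c(17.2, 31.9, 14.6),
                       fev1Mean = c(65.5, 42.0, 55.0),
                       fev1SD = c(30.4, 23.6, 29.1),
                       rvMean = c(3.5, 4.1, 4.0),
                       rvSD = c(1.1, 1.8, 1.9),
                       beta0 = -2.2, betaAge = 0.06, betaSerum = -0.05,
                       seed = 1L) {
  if (any(nPerGroup < 0)) stopDomain("group sizes must be >= 0")
  structure(list(nPerGroup = nPerGroup, serumMean = serumMean,
                 serumSD = serumSD, ageMean = ageMean, ageSD = ageSD,
                 femaleProb = femaleProb, bmiMean = bmiMean, bmiSD = bmiSD,
                 packYearsMean = packYearsMean, packYearsSD = packYearsSD,
                 fev1Mean = fev1Mean, fev1SD = fev1SD,
                 rvMean = rvMean, rvSD = rvSD,
                 beta0 = beta0, betaAge = betaAge, betaSerum = betaSerum,
                 seed = as.integer(seed)), class = "cohortSpec")
}

# genotype frequencies per group, typical of an AATD referral population
.genotypeFreq <- list(
  "reduced-to-normal" = c(MZ = 8, MS = 3, SZ = 1, rare = 1),
  "moderate"          = c(SZ = 8, rare = 4, MZ = 3, unknown = 1),
  "severe"            = c(ZZ = 36, rare = 7, SZ = 1, unknown = 2)
)

#' Generate a synthetic AATD cohort table
#'
#' Draws one patient table from a [cohortSpec()]: per group, serum levels
#' from a truncated normal confined to the group band (severe \[0, 40\],
#' moderate (40, 70\], reduced-to-normal (70, Inf)), covariates from
#' truncated normals, genotype labels from typical group-specific
#' frequencies, and the mid-predominant outcome from the planted logistic
#' model. The generator truth (the planted coefficients and band limits) is
#' returned alongside the table.
#'
#' @param spec A [cohortSpec()].
#' @return A list with `cohort` (a `data.frame` with columns `patient_id`,
#'   `serum_aat`, `genotype`, `has_deficiency_allele`, `age`, `sex`, `bmi`,
#'   `pack_years`, `fev1_pct`, `rv_l`, `phenotype`, `mid_predominant`,
#'   `group`) and `truth` (planted coefficients and the spec).
#' @examples
#' co <- generateCohort(cohortSpec(seed = 42))
#' table(co$cohort$group)
#' @export
generateCohort <- function(spec) {
  stopifnot(inherits(spec, "cohortSpec"))
  groups <- c("reduced-to-normal", "moderate", "severe")
  bands <- list("reduced-to-normal" = c(70 + 1e-9, Inf),
                "moderate" = c(40 + 1e-9, 70),
                "severe" = c(0, 40))
  withSeed(spec$seed, {
    rows <- list()
    for (gi in seq_along(groups)) {
      g <- groups[gi]
      n <- spec$nPerGroup[[gi]]
      if (n == 0L) next
      serum <- rtruncnorm(n, spec$serumMean[gi], spec$serumSD[gi],
                          lower = bands[[g]][1], upper = bands[[g]][2])
      age <- rtruncnorm(n, spec$ageMean[gi], spec$ageSD[gi], 18, 95)
      sex <- ifelse(stats::runif(n) < spec$femaleProb[gi], "female", "male")
      bmi <- rtruncnorm(n, spec$bmiMean[gi], spec$bmiSD[gi], 14, 60)
      py <- rtruncnorm(n, spec$packYearsMean[gi], spec$packYearsSD[gi], 0, 150)
      fev1 <- rtruncnorm(n, spec$fev1Mean[gi], spec$fev1SD[gi], 10, 160)
      rv <- rtruncnorm(n, spec$rvMean[gi], spec$rvSD[gi], 0.5, 12)
      gfreq <- .genotypeFreq[[g]]
      genotype <- sample(names(gfreq), n, replace = TRUE,
                         prob = gfreq / sum(gfreq))
      rows[[g]] <- data.frame(
        patient_id = sprintf("%s-%03d", toupper(substr(g, 1, 3)), seq_len(n)),
        serum_aat = serum, genotype = genotype,
        has_deficiency_allele = TRUE, age = age, sex = sex, bmi = bmi,
        pack_years = py, fev1_pct = fev1, rv_l = rv
      )
    }
    cohort <- do.call(rbind, rows)
    rownames(cohort) <- NULL
    eta <- spec$beta0 + spec$betaAge * cohort$age +
      spec$betaSerum * cohort$serum_aat
    cohort$mid_predominant <- stats::runif(nrow(cohort)) < stats::plogis(eta)
    other <- sample(c("none", "upper", "lower"), nrow(cohort),
                    replace = TRUE, prob = c(38, 8, 7) / 53)
    cohort$phenotype <- ifelse(cohort$mid_predominant, "mid", other)
    cohort$group <- assignSerumGroup(cohort$serum_aat,
                                     cohort$has_deficiency_allele)$group
    list(cohort = cohort,
         truth = list(beta0 = spec$beta0, betaAge = spec$betaAge,
                      betaSerum = spec$betaSerum, bands = bands,
                      spec = unclass(spec)))
  })
}
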