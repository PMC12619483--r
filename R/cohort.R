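#' Serum AAT group labels, in severity order
#' @format Character vector of length 3.
#' @export
serumGroups <- c("severe", "moderate", "reduced-to-normal")

#' Assign serum AAT severity groups
#'
#' Severity is defined on the serum alpha-1-antitrypsin level: severe when
#' at most 40 mg/dl, moderate when above 40 and at most 70 mg/dl, and
#' reduced-to-normal above 70 mg/dl. Study eligibility for the
#' reduced-to-normal band additionally requires at least one deficiency
#' allele; this is reported as an `eligible` flag, not a different group.
#' Every non-negative serum level maps to exactly one group.
#'
#' @param serum Numeric vector of serum AAT levels (mg/dl, >= 0).
#' @param hasDeficiencyAllele Logical vector (recycled) indicating carriage
#'   of at least one deficiency allele.
#' @param cutSevere,cutModerate Band cuts in mg/dl (defaults 40 and 70).
#' @return A `data.frame` with columns `group` (factor with levels
#'   severe < moderate < reduced-to-normal) and `eligible`.
#' @examples
#' assignSerumGroup(c(16.7, 40, 40.5, 70, 70.1, 88.5))$group
#' @export
assignSerumGroup <- function(serum, hasDeficiencyAllele = TRUE,
                             cutSevere = 40, cutModerate = 70) {
  if (any(!is.finite(serum)) || any(serum < 0))
    stopDomain("serum AAT levels must be finite and non-negative")
  grp <- ifelse(serum <= cutSevere, "severe",
         ifelse(serum <= cutModerate, "moderate", "reduced-to-normal"))
  grp <- factor(grp, levels = serumGroups, ordered = TRUE)
  eligible <- grp != "reduced-to-normal" | rep_len(as.logical(hasDeficiencyAllele),
                                                  length(serum))
  data.frame(group = grp, eligible = eligible)
}

#' Size-weighted pooled mean
#'
#' Recovers the all-patients column of a summary table from per-group means
#' and group sizes.
#'
#' @param means Numeric vector of group means.
#' @param ns Integer vector of group sizes.
#' @return The pooled mean.
#' @examples
#' pooledMean(c(-774.0, -807.1, -819.8), c(13, 16, 46))  # -809.2 (1 d.p.)
#' @export
pooledMean <- function(means, ns) {
  stopifnot(length(means) == length(ns), all(ns >= 0))
  if (sum(ns) == 0) stopDomain("pooled mean over zero observations")
  sum(means * ns) / sum(ns)
}

#' Descriptive group summaries
#'
#' Per-group descriptive statistics in table style: mean +/- SD for
#' continuous variables, n (%) for categorical ones, percentages relative to
#' the group size, all rounded (half away from zero) to `digits` decimals.
#'
#' @param cohort A `data.frame` with a `group` column.
#' @param variables Character vector of column names to summarise.
#' @param kinds Character vector (recycled) of `"continuous"` or
#'   `"categorical"` per variable; default guesses from the column type.
#' @param digits Decimals for the rounded display values (default 1).
#' @return A `data.frame` with one row per variable (continuous) or per
#'   variable level (categorical) and per group, with columns `variable`,
#'   `level`, `group`, `n`, `mean`, `sd`, `count`, `percent`, `display`.
#' @export
summarizeGroups <- function(cohort, variables, kinds = NULL, digits = 1) {
  if (nrow(cohort) == 0L) stopDomain("empty cohort")
  if (!"group" %in% names(cohort)) stopStructural("cohort lacks 'group' column")
  if (is.null(kinds))
    kinds <- ifelse(vapply(cohort[variables], is.numeric, logical(1)),
                    "continuous", "categorical")
  kinds <- rep_len(kinds, length(variables))
  groups <- if (is.factor(cohort$group)) levels(cohort$group)
            else unique(cohort$group)
  out <- list()
  for (i in seq_along(variables)) {
    v <- variables[i]
    if (!v %in% names(cohort)) stopStructural("unknown cohort column '%s'", v)
    for (g in groups) {
      x <- cohort[[v]][cohort$group == g]
      n <- length(x)
      if (kinds[i] == "continuous") {
        m <- mean(x, na.rm = TRUE)
        s <- if (sum(!is.na(x)) > 1L) stats::sd(x, na.rm = TRUE) else 0
        out[[length(out) + 1L]] <- data.frame(
          variable = v, level = NA_character_, group = g, n = n,
          mean = m, sd = s, count = NA_integer_, percent = NA_real_,
          display = sprintf("%s ± %s", roundHalfUp(m, digits),
                            roundHalfUp(s, digits)))
      } else {
        for (lv in sort(unique(stats::na.omit(as.character(cohort[[v]]))))) {
          cnt <- sum(x == lv, na.rm = TRUE)
          pct <- 100 * cnt / n
          out[[length(out) + 1L]] <- data.frame(
            variable = v, level = lv, group = g, n = n,
            mean = NA_real_, sd = NA_real_, count = cnt, percent = pct,
            display = sprintf("%d (%s%%)", cnt, roundHalfUp(pct, digits)))
        }
      }
    }
  }
  do.call(rbind, out)
}

#' Between-group comparison for one variable
#'
#' Categorical variables are compared with Pearson's chi-square test on the
#' group-by-level contingency table (no continuity correction). Continuous
#' variables with two groups use Student's t-test (Mann-Whitney U behind
#' `rankBased`); with three or more groups, one-way ANOVA as the k-group
#' extension (Kruskal-Wallis behind `rankBased`). The test used is always
#' reported with the p-value.
#'
#' @param cohort A `data.frame` with a `group` column.
#' @param variable Column name to compare.
#' @param kind `"continuous"` or `"categorical"`.
#' @param rankBased Use the rank-based alternative for continuous variables.
#' @return A list with `variable`, `test`, `statistic`, `p_value`, and
#'   `flags` (character vector; `"constant"` when the variable has a single
#'   value, in which case p is 1; `"small-expected"` when a chi-square
#'   expected cell is below 1).
#' @examples
#' sex <- data.frame(
#'   group = rep(c("reduced-to-normal", "moderate", "severe"), c(13, 16, 46)),
#'   female = c(rep(c(TRUE, FALSE), c(3, 10)), rep(c(TRUE, FALSE), c(9, 7)),
#'              rep(c(TRUE, FALSE), c(26, 20))))
#' compareGroups(sex, "female", "categorical")$p_value  # ~0.091
#' @export
compareGroups <- function(cohort, variable, kind = c("continuous", "categorical"),
                          rankBased = FALSE) {
  kind <- match.arg(kind)
  if (!variable %in% names(cohort)) stopStructural("unknown column '%s'", variable)
  g <- factor(cohort$group)
  x <- cohort[[variable]]
  ok <- !is.na(x) & !is.na(g)
  x <- x[ok]; g <- droplevels(g[ok])
  if (nlevels(g) < 2L) stopDomain("need at least 2 non-empty groups")
  flags <- character()
  if (length(unique(x)) < 2L) {
    return(list(variable = variable, test = "none (constant variable)",
                statistic = NA_real_, p_value = 1, flags = "constant"))
  }
  if (kind == "categorical") {
    tab <- table(g, x)
    exp <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(exp < 1)) flags <- c(flags, "small-expected")
    ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    res <- list(variable = variable, test = "Pearson chi-square",
                statistic = unname(ht$statistic), p_value = unname(ht$p.value),
                flags = flags)
  } else if (nlevels(g) == 2L) {
    if (rankBased) {
      ht <- stats::wilcox.test(x ~ g)
      res <- list(variable = variable, test = "Mann-Whitney U",
                  statistic = unname(ht$statistic),
                  p_value = unname(ht$p.value), flags = flags)
    } else {
      ht <- stats::t.test(x ~ g, var.equal = TRUE)
      res <- list(variable = variable, test = "Student t-test",
                  statistic = unname(ht$statistic),
                  p_value = unname(ht$p.value), flags = flags)
    }
  } else {
    if (rankBased) {
      ht <- stats::kruskal.test(x ~ g)
      res <- list(variable = variable, test = "Kruskal-Wallis",
                  statistic = unname(ht$statistic),
                  p_value = unname(ht$p.value), flags = flags)
    } else {
      fit <- stats::aov(x ~ g)
      s <- summary(fit)[[1]]
      res <- list(variable = variable, test = "one-way ANOVA",
                  statistic = s[["F value"]][1], p_value = s[["Pr(>F)"]][1],
                  flags = flags)
    }
  }
  res
}
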