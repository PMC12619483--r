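#' Wald confidence interval for an odds ratio
#'
#' @param b Log-odds coefficient.
#' @param se Standard error of `b` (> 0).
#' @param level Confidence level (default 0.95).
#' @return A named list with `or` (= exp(b)), `lo` and `hi`
#'   (= exp(b -/+ z se)).
#' @examples
#' oddsRatioCI(log(2), 0.1)
#' @export
oddsRatioCI <- function(b, se, level = 0.95) {
  if (!is.finite(se) || se <= 0) stopDomain("standard error must be > 0")
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(or = exp(b), lo = exp(b - z * se), hi = exp(b + z * se))
}

#' Stepwise binary logistic regression
#'
#' Forward selection with backward pruning on likelihood-ratio p-values:
#' at each step the candidate with the smallest add-one LRT p-value enters
#' if it is below `alphaEnter`; after each entry, selected terms (never the
#' forced ones) with drop-one LRT p-values above `alphaRemove` are removed,
#' worst first. The final model is refit with the selected terms plus any
#' forced adjustment covariates. Coefficients are reported with Wald
#' standard errors, odds ratios (exp(B)) with Wald 95% CIs, and Wald
#' p-values. Rows with missing model inputs are dropped and counted.
#'
#' @param cohort A `data.frame`.
#' @param outcome Name of a logical/0-1 outcome column (e.g. mid-predominant
#'   emphysema), or a logical vector of length `nrow(cohort)`.
#' @param candidates Character vector of candidate predictor columns.
#' @param forced Character vector of adjustment covariates always included
#'   in the final refit (default none).
#' @param alphaEnter Entry threshold on the LRT p-value (default 0.05).
#' @param alphaRemove Removal threshold (default 0.10).
#' @param level Confidence level for the Wald CIs (default 0.95).
#' @return A list with `selected` (character), `terms` (a `data.frame` with
#'   one row per final model coefficient: `term`, `b`, `se`, `or`,
#'   `ci_lo`, `ci_hi`, `p_value`), `trace` (a `data.frame` of entry/removal
#'   steps with p-values), `forced`, `n_used`, `n_dropped`, and `fit`
#'   (the final `glm`).
#' @export
stepwiseLogistic <- function(cohort, outcome, candidates, forced = character(),
                             alphaEnter = 0.05, alphaRemove = 0.10,
                             level = 0.95) {
  y <- if (is.character(outcome) && length(outcome) == 1L) {
    if (!outcome %in% names(cohort)) stopStructural("unknown outcome '%s'", outcome)
    cohort[[outcome]]
  } else outcome
  y <- as.logical(y)
  vars <- unique(c(candidates, forced))
  bad <- setdiff(vars, names(cohort))
  if (length(bad))
    stopStructural("unknown predictor columns: %s", paste(bad, collapse = ", "))
  dat <- cohort[vars]
  dat$.y <- y
  cc <- stats::complete.cases(dat)
  nDropped <- sum(!cc)
  dat <- dat[cc, , drop = FALSE]
  if (length(unique(dat$.y)) < 2L)
    stopDomain("outcome is degenerate: only one class present")

  fitModel <- function(terms) {
    fml <- stats::reformulate(if (length(terms)) terms else "1",
                              response = ".y")
    suppressWarnings(stats::glm(fml, family = stats::binomial(), data = dat))
  }
  checkSeparation <- function(fit) {
    co <- stats::coef(fit)[-1]
    if (length(co) && any(abs(co) > 15 & !is.na(co))) {
      term <- names(co)[which.max(abs(co))]
      stopDomain("complete (or quasi-complete) separation on term '%s'", term)
    }
  }

  selected <- character()
  trace <- data.frame(step = integer(), action = character(),
                      term = character(), p_value = numeric())
  repeat {
    changed <- FALSE
    pool <- setdiff(candidates, selected)
    if (length(pool)) {
      cur <- fitModel(selected)
      addP <- vapply(pool, function(tm) {
        aug <- fitModel(c(selected, tm))
        p <- stats::anova(cur, aug, test = "LRT")[2, "Pr(>Chi)"]
        if (is.na(p)) 1 else p   # zero deviance change: nothing to add
      }, numeric(1))
      if (min(addP) < alphaEnter) {
        tm <- pool[which.min(addP)]
        selected <- c(selected, tm)
        trace <- rbind(trace, data.frame(step = nrow(trace) + 1L,
                                         action = "enter", term = tm,
                                         p_value = min(addP)))
        changed <- TRUE
      }
    }
    # backward pruning among the selected terms
    repeat {
      if (length(selected) == 0L) break
      cur <- fitModel(selected)
      dropP <- vapply(selected, function(tm) {
        red <- fitModel(setdiff(selected, tm))
        p <- stats::anova(red, cur, test = "LRT")[2, "Pr(>Chi)"]
        if (is.na(p)) 1 else p   # contributes nothing: removable
      }, numeric(1))
      if (max(dropP) > alphaRemove) {
        tm <- selected[which.max(dropP)]
        selected <- setdiff(selected, tm)
        trace <- rbind(trace, data.frame(step = nrow(trace) + 1L,
                                         action = "remove", term = tm,
                                         p_value = max(dropP)))
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }

  finalTerms <- unique(c(selected, forced))
  fit <- fitModel(finalTerms)
  checkSeparation(fit)
  sm <- summary(fit)$coefficients
  z <- stats::qnorm(1 - (1 - level) / 2)
  terms <- data.frame(
    term = rownames(sm),
    b = sm[, "Estimate"],
    se = sm[, "Std. Error"],
    or = exp(sm[, "Estimate"]),
    ci_lo = exp(sm[, "Estimate"] - z * sm[, "Std. Error"]),
    ci_hi = exp(sm[, "Estimate"] + z * sm[, "Std. Error"]),
    p_value = sm[, "Pr(>|z|)"],
    row.names = NULL
  )
  list(selected = selected, terms = terms, trace = trace, forced = forced,
       n_used = nrow(dat), n_dropped = nDropped, fit = fit)
}
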