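#' Round half away from zero
#'
#' Commercial statistics packages (and the tables this pipeline reproduces)
#' round halves away from zero rather than to even, so 0.05 -> 0.1 and
#' -0.05 -> -0.1 at one decimal.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 1, the table precision).
#' @return Rounded numeric vector.
#' @export
roundHalfUp <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Truncated normal draws via inverse-CDF sampling; exact on the open
# interval (lower, upper) up to floating point.
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) {
    if (mean < lower || mean > upper)
      stop("degenerate truncated normal: mean outside [lower, upper]")
    return(rep(mean, n))
  }
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  if (phi - plo < 1e-12)
    stop("truncated normal band has ~zero probability mass")
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

# stop() with a condition class so callers can distinguish contract
# violations (structural) from domain errors (valid structure, invalid data).
stopDomain <- function(...) {
  stop(errorCondition(sprintf(...), class = c("qctemph_domain_error", "error")))
}

stopStructural <- function(...) {
  stop(errorCondition(sprintf(...), class = c("qctemph_structural_error", "error")))
}

checkAligned <- function(ct, lobes) {
  if (!identical(dim(ct@values), dim(lobes@labels)))
    stopStructural("CT grid %s and lobe mask grid %s have different shapes",
                   paste(dim(ct@values), collapse = "x"),
                   paste(dim(lobes@labels), collapse = "x"))
  invisible(TRUE)
}
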