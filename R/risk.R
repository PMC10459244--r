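#' Acceptable daily intake from a NOAEL and safety factor
#'
#' @param noael point of departure, mg/kg/day.
#' @param safety_factor generic safety factor (default 100, covering inter-
#'   and intraspecies variability).
#' @return the ADI in mg/kg/day.
#' @export
derive_adi <- function(noael, safety_factor = 100) {
  if (noael <= 0 || safety_factor <= 0)
    stop("noael and safety_factor must be positive")
  noael / safety_factor
}

#' Hazard quotient
#'
#' Exposure divided by a reference dose (ADI or pRfD); values above 1 flag a
#' potential concern.
#'
#' @param exposure exposure estimate(s), mg/kg/day.
#' @param reference reference dose, mg/kg/day (> 0).
#' @return unitless hazard quotient(s).
#' @export
hazard_quotient <- function(exposure, reference) {
  if (reference <= 0) stop("reference dose must be positive")
  if (any(exposure < 0)) stop("exposures must be nonnegative")
  exposure / reference
}

#' Exceedance summary of a simulated population
#'
#' Counts individuals whose hazard quotient exceeds 1 (strictly; HQ exactly 1
#' is not an exceedance), overall and within groups.
#'
#' @param exposures nonnegative exposures, mg/kg/day.
#' @param reference reference dose, mg/kg/day.
#' @param groups optional factor/character vector (same length as `exposures`)
#'   of group labels, or a data.frame of several grouping columns.
#' @return an object of class `risk_summary`: overall `count` and `fraction`
#'   plus a `by_group` data.frame when groups are supplied.
#' @export
exceedance_summary <- function(exposures, reference, groups = NULL) {
  hq <- hazard_quotient(exposures, reference)
  exceed <- hq > 1
  by_group <- NULL
  if (!is.null(groups)) {
    if (is.data.frame(groups)) {
      if (nrow(groups) != length(exposures))
        stop("groups must match exposures in length")
      by_group <- do.call(rbind, lapply(names(groups), function(col) {
        agg <- tapply(exceed, groups[[col]], function(e)
          c(n = length(e), count = sum(e), fraction = mean(e)))
        data.frame(variable = col, group = names(agg),
                   do.call(rbind, agg), row.names = NULL)
      }))
    } else {
      if (length(groups) != length(exposures))
        stop("groups must match exposures in length")
      agg <- tapply(exceed, groups, function(e)
        c(n = length(e), count = sum(e), fraction = mean(e)))
      by_group <- data.frame(group = names(agg), do.call(rbind, agg),
                             row.names = NULL)
    }
  }
  structure(list(reference = reference, n = length(exposures),
                 count = sum(exceed), fraction = mean(exceed),
                 by_group = by_group, hq_summary = summary(hq)),
            class = "risk_summary")
}

#' @export
print.risk_summary <- function(x, ...) {
  cat(sprintf("Exceedance vs reference %.4g mg/kg/day: %d of %d individuals (%.4f%%)\n",
              x$reference, x$count, x$n, 100 * x$fraction))
  if (!is.null(x$by_group)) print(x$by_group)
  invisible(x)
}
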