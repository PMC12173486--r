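#' Fit the tensioned-beam stress / squared-wave-speed relationship
#'
#' Ordinary least squares of axial stress (dependent, Pa) on squared
#' wave speed (independent, m^2 s^-2), exactly in the direction of the
#' tensioned-beam relationship `sigma = rho_eff c^2 - k' mu`.  The slope
#' is the effective-density estimate (kg m^-3) and the intercept an
#' estimate of `-k' mu` (Pa).
#'
#' @param speeds wave speeds, m s^-1 (> 0).
#' @param stresses paired axial stresses, Pa.
#' @param reference expected slope for the deviation flag (default the
#'   tissue density, 1500 kg m^-3).
#' @param subtendon,cohort,twist_deg optional identifiers carried on the
#'   result.
#' @return a `regression_result`: list with `slope`, `intercept`,
#'   `r_squared`, `n`, `deviation_flag` and identifiers.
#' @examples
#' c2 <- seq(10, 100, length.out = 8)^2
#' r <- fit_wave_speed_stress(sqrt(c2), 1500 * c2 - 8.2e6)
#' r$slope       # 1500
#' r$r_squared   # 1
#' @export
fit_wave_speed_stress <- function(speeds, stresses, reference = 1500,
                                  subtendon = NA_character_,
                                  cohort = NA_character_,
                                  twist_deg = NA_real_) {
  if (length(speeds) != length(stresses))
    stop("'speeds' and 'stresses' must have equal length")
  if (length(speeds) < 3) stop("need at least 3 points")
  if (any(!is.finite(speeds)) || any(!is.finite(stresses)))
    stop("non-finite inputs")
  if (any(speeds <= 0)) stop("speeds must be > 0")
  c2 <- speeds^2
  if (stats::sd(c2) < .Machine$double.eps^0.5 * mean(c2))
    stop("degenerate input: squared speeds are constant")
  fit <- stats::lm(stresses ~ c2)
  slope <- unname(stats::coef(fit)[2])
  r2 <- summary(fit)$r.squared
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2, n = length(speeds),
                 deviation_flag = flag_slope_deviation(slope, reference),
                 reference = reference, subtendon = subtendon,
                 cohort = cohort, twist_deg = twist_deg),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf(
    "sigma ~ c^2: slope %.1f kg m^-3%s, intercept %.3g Pa, R^2 %.5f (n = %d)\n",
    x$slope, if (x$deviation_flag) " [>10% deviation]" else "",
    x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' Flag slopes deviating more than 10 percent from the expected density
#'
#' `TRUE` iff `|slope - reference| / reference > 0.10` (strictly greater:
#' exactly 10 percent is not flagged).
#'
#' @param slope fitted slope, kg m^-3 (vectorised).
#' @param reference expected slope (> 0), kg m^-3.
#' @return logical.
#' @examples
#' flag_slope_deviation(c(1465, 2145, 1650), 1500)  # FALSE TRUE FALSE
#' @export
flag_slope_deviation <- function(slope, reference = 1500) {
  if (any(reference <= 0)) stop("'reference' must be > 0")
  abs(slope - reference) / reference > 0.10
}

#' Tabulate regression results
#'
#' Binds `regression_result` objects into a tidy data frame (one row
#' per cohort x twist x subtendon), the machine-readable analogue of a
#' slope/deviation summary table, and optionally writes it as CSV.
#'
#' @param results list of `regression_result` objects.
#' @param path optional CSV output path.
#' @return a data.frame with columns `cohort`, `twist_deg`, `subtendon`,
#'   `slope`, `intercept`, `r_squared`, `n`, `deviation_flag`.
#' @export
regression_table <- function(results, path = NULL) {
  stopifnot(all(vapply(results, inherits, TRUE, "regression_result")))
  out <- do.call(rbind, lapply(results, function(r)
    data.frame(cohort = r$cohort, twist_deg = r$twist_deg,
               subtendon = r$subtendon, slope = r$slope,
               intercept = r$intercept, r_squared = r$r_squared,
               n = r$n, deviation_flag = r$deviation_flag)))
  rownames(out) <- NULL
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
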