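#' Plan a standard dilution series from ICG stock
#'
#' Computes, for each target concentration, the volume of stock solution and
#' of diluent (MilliQ water) needed to prepare `total_volume_uL` of standard.
#' Volumes are reported to the nearest microlitre (matching bench pipetting
#' precision); the mass-balance identity
#' `stock_volume * stock_conc == target * total_volume` holds exactly for the
#' unrounded volumes, which are kept in the `stock_uL_exact` column.
#'
#' @param targets_mg_L numeric vector of target concentrations (mg/L).
#' @param stock_conc_mg_L stock concentration in mg/L (2.5 mg/mL = 2500).
#' @param total_volume_uL total volume prepared per standard (µL).
#' @return A data.frame with one row per target: `target_mg_L`, `stock_uL`,
#'   `water_uL`, `total_uL`, `stock_uL_exact`.
#' @examples
#' # the bench series: 2.5 mg/mL stock diluted into 25 mL flasks
#' plan_standard_dilutions(c(5, 7.5, 10, 15, 20, 30), 2500, 25000)
#' @export
plan_standard_dilutions <- function(targets_mg_L, stock_conc_mg_L,
                                    total_volume_uL) {
  stopifnot(is.numeric(targets_mg_L), length(targets_mg_L) >= 1,
            is.finite(stock_conc_mg_L), stock_conc_mg_L > 0,
            is.finite(total_volume_uL), total_volume_uL > 0)
  if (any(targets_mg_L < 0)) {
    stop("target concentrations must be >= 0", call. = FALSE)
  }
  if (any(targets_mg_L >= stock_conc_mg_L)) {
    stop("infeasible dilution: target concentration at or above stock (",
         stock_conc_mg_L, " mg/L)", call. = FALSE)
  }
  stock_exact <- targets_mg_L * total_volume_uL / stock_conc_mg_L
  stock <- round(stock_exact)
  data.frame(
    target_mg_L = targets_mg_L,
    stock_uL = stock,
    water_uL = total_volume_uL - stock,
    total_uL = rep(total_volume_uL, length(targets_mg_L)),
    stock_uL_exact = stock_exact
  )
}

#' Mix a water-based ICG standard with blank plasma
#'
#' Standards are prepared in the participant's own pre-injection plasma so
#' that the calibration matrix matches the timed samples.  Plasma contributes
#' no ICG, so the final concentration is the volume-weighted dilution of the
#' premix.
#'
#' @param premix_conc_mg_L concentration of the water-based standard (mg/L).
#' @param standard_uL volume of standard added (µL).
#' @param plasma_uL volume of blank plasma added (µL).
#' @return A data.frame: `premix_mg_L`, `standard_uL`, `plasma_uL`,
#'   `final_mg_L`.
#' @examples
#' mix_with_plasma(c(5, 30), 200, 200)  # 1:1 mixing halves each premix
#' @export
mix_with_plasma <- function(premix_conc_mg_L, standard_uL, plasma_uL) {
  n <- max(length(premix_conc_mg_L), length(standard_uL), length(plasma_uL))
  premix <- rep_len(premix_conc_mg_L, n)
  sv <- rep_len(standard_uL, n)
  pv <- rep_len(plasma_uL, n)
  if (any(sv < 0) || any(pv < 0)) {
    stop("volumes must be >= 0", call. = FALSE)
  }
  if (any(sv + pv <= 0)) {
    stop("standard and plasma volumes cannot both be zero", call. = FALSE)
  }
  data.frame(
    premix_mg_L = premix,
    standard_uL = sv,
    plasma_uL = pv,
    final_mg_L = premix * sv / (sv + pv)
  )
}

#' Average replicate well readings
#'
#' The protocol reads each well group (blank, standard, or timed sample) in
#' triplicate and uses the arithmetic mean.  The coefficient of variation
#' (sample SD / mean, as a percent) is reported for QC; readings are never
#' rejected automatically.
#'
#' @param absorbances numeric vector of >= 1 absorbance readings (AU).
#' @return A list: `mean`, `cv_pct` (`NA` for a single reading or zero mean),
#'   `n`.
#' @examples
#' average_wells(c(0.09, 0.10, 0.11))
#' @export
average_wells <- function(absorbances) {
  if (length(absorbances) == 0) {
    stop("empty well group: no absorbance readings", call. = FALSE)
  }
  if (any(!is.finite(absorbances)) || any(absorbances < 0)) {
    stop("absorbances must be finite and >= 0", call. = FALSE)
  }
  m <- mean(absorbances)
  cv <- if (length(absorbances) < 2 || m == 0) NA_real_ else
    100 * stats::sd(absorbances) / m
  list(mean = m, cv_pct = cv, n = length(absorbances))
}

#' Fit the plasma-matrix calibration curve
#'
#' Ordinary least-squares line of absorbance (805 nm) on ICG concentration
#' across the plasma-matched standards.  The plasma background is absorbed
#' into the intercept, so no separate blank subtraction is performed; the
#' linear (Beer-Lambert) range is recorded as `valid_range`.
#'
#' @param conc_mg_L standard concentrations (mg/L), within the linear range.
#' @param absorbance mean absorbance per standard (AU).
#' @param linear_cap_mg_L upper limit of the linear range (mg/L).
#' @return An object of class `"icg_calibration"`: `slope` (AU per mg/L),
#'   `intercept` (AU), `r` (Pearson correlation of the points), `n_points`,
#'   `valid_range`, and the underlying `lm` fit.
#' @seealso [invert_absorbance()], [predict.icg_calibration()]
#' @examples
#' cal <- fit_calibration(c(2.5, 3.75, 5, 7.5, 10),
#'                        0.04 * c(2.5, 3.75, 5, 7.5, 10) + 0.05)
#' coef(cal)
#' @export
fit_calibration <- function(conc_mg_L, absorbance, linear_cap_mg_L = 15) {
  stopifnot(length(conc_mg_L) == length(absorbance))
  if (length(conc_mg_L) < 3) {
    stop("calibration needs at least 3 standards", call. = FALSE)
  }
  if (any(conc_mg_L < 0) || any(conc_mg_L > linear_cap_mg_L)) {
    stop("standard concentrations must lie in [0, ", linear_cap_mg_L,
         "] mg/L", call. = FALSE)
  }
  if (stats::sd(conc_mg_L) == 0) {
    stop("singular fit: all standard concentrations identical",
         call. = FALSE)
  }
  d <- data.frame(conc = conc_mg_L, abs = absorbance)
  fit <- stats::lm(abs ~ conc, data = d)
  structure(
    list(
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      r = stats::cor(conc_mg_L, absorbance),
      n_points = length(conc_mg_L),
      valid_range = c(0, linear_cap_mg_L),
      lm = fit
    ),
    class = "icg_calibration"
  )
}

#' @export
print.icg_calibration <- function(x, ...) {
  cat("ICG calibration curve (805 nm, plasma matrix)\n")
  cat(sprintf("  absorbance = %.6g * conc + %.6g   (AU, conc in mg/L)\n",
              x$slope, x$intercept))
  cat(sprintf("  Pearson r = %.4f over %d standards; linear range %g-%g mg/L\n",
              x$r, x$n_points, x$valid_range[1], x$valid_range[2]))
  invisible(x)
}

#' @export
coef.icg_calibration <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
summary.icg_calibration <- function(object, ...) {
  out <- list(curve = object, lm_summary = summary(object$lm))
  class(out) <- "summary.icg_calibration"
  out
}

#' @export
print.summary.icg_calibration <- function(x, ...) {
  print(x$curve)
  cat("\nUnderlying OLS fit:\n")
  print(stats::coef(x$lm_summary))
  invisible(x)
}

#' Predicted absorbance for given concentrations
#'
#' @param object an `"icg_calibration"` curve.
#' @param newdata numeric vector of concentrations (mg/L); if missing, the
#'   fitted values are returned.
#' @param ... unused.
#' @return numeric vector of absorbances (AU).
#' @export
predict.icg_calibration <- function(object, newdata, ...) {
  if (missing(newdata)) return(unname(stats::fitted(object$lm)))
  object$intercept + object$slope * newdata
}

#' @export
plot.icg_calibration <- function(x, ...) {
  d <- x$lm$model
  graphics::plot(d$conc, d$abs, xlab = "ICG concentration (mg/L)",
                 ylab = "Absorbance at 805 nm (AU)",
                 main = "ICG standard curve", ...)
  graphics::abline(x$intercept, x$slope)
  invisible(x)
}

#' Invert the calibration curve: absorbance to concentration
#'
#' Applies `conc = (absorbance - intercept) / slope`.  Concentrations above
#' the linear cap are flagged `above_range` (they should be excluded from
#' kinetic fits); negative results are clamped to zero and flagged `clamped`.
#' Flags are attached as a two-column logical attribute `"flags"` and also
#' raised as warnings.
#'
#' @param curve an `"icg_calibration"` object.
#' @param absorbance numeric vector of absorbances (AU).
#' @return numeric vector of concentrations (mg/L) with attribute `"flags"`.
#' @examples
#' cal <- fit_calibration(c(2.5, 5, 10), 0.04 * c(2.5, 5, 10) + 0.05)
#' invert_absorbance(cal, 0.25)  # 5 mg/L
#' @export
invert_absorbance <- function(curve, absorbance) {
  stopifnot(inherits(curve, "icg_calibration"))
  if (!is.finite(curve$slope) || curve$slope <= 0) {
    stop("invalid calibration curve: slope must be > 0", call. = FALSE)
  }
  conc <- (absorbance - curve$intercept) / curve$slope
  above <- conc > curve$valid_range[2]
  clamped <- conc < 0
  if (any(above)) {
    warning(sum(above), " reading(s) above the linear range (",
            curve$valid_range[2], " mg/L)", call. = FALSE)
  }
  if (any(clamped)) {
    warning(sum(clamped), " reading(s) below blank; clamped to 0 mg/L",
            call. = FALSE)
    conc[clamped] <- 0
  }
  attr(conc, "flags") <- data.frame(above_range = above, clamped = clamped)
  conc
}
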