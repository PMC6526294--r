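#' Fit the mono-exponential ICG elimination curve
#'
#' Plasma ICG concentrations from timed post-injection draws are transformed
#' to natural logs and regressed on draw time in seconds (ordinary least
#' squares).  The fitted line is back-extrapolated to t = 0 and t = 1 min to
#' give the two concentration conventions used for plasma-volume estimation,
#' and the elimination rate constant k, circulatory half-life, and plasma
#' disappearance rate are derived from the slope.
#'
#' The model is \eqn{\ln C(t) = \ln C_0 - k t}, with t in seconds internally
#' and k reported per minute (\eqn{k = -60 \times slope}).  Natural logs are
#' used throughout; a base-10 fit would silently rescale k.
#'
#' @param draw_time_s draw times, seconds since the start of injection.
#' @param conc_mg_L plasma ICG concentrations (mg/L), all > 0.
#' @param window two-element numeric: only samples with
#'   `window[1] <= t <= window[2]` enter the fit (default the 120--300 s
#'   elimination-phase window of the draw schedule).  `NULL` uses all
#'   samples.
#' @return An object of class `"icg_decay"` with components
#'   `slope_per_s` (1/s, negative for a physiologic fit), `ln_intercept`
#'   (\eqn{\ln} mg/L at t = 0), `r` (Pearson correlation of ln-conc vs
#'   time), `n_points`, `k_per_min`, `c0_t0` (mg/L, back-extrapolated to
#'   t = 0), `c_t60` (mg/L, t = 1 min), `half_life_min`, `pdr_pct_per_min`
#'   (plasma disappearance rate, `100 * k`), `window`, and the underlying
#'   `lm` fit.
#' @examples
#' t <- c(120, 165, 210, 255, 300)
#' fit <- fit_decay(t, 8 * exp(-(0.25 / 60) * t))
#' fit$k_per_min   # 0.25
#' fit$c0_t0       # 8
#' @export
fit_decay <- function(draw_time_s, conc_mg_L, window = c(120, 300)) {
  stopifnot(length(draw_time_s) == length(conc_mg_L))
  keep <- rep(TRUE, length(draw_time_s))
  if (!is.null(window)) {
    stopifnot(length(window) == 2)
    keep <- draw_time_s >= window[1] & draw_time_s <= window[2]
    if (any(!keep)) {
      message(sum(!keep), " sample(s) outside the ", window[1], "-",
              window[2], " s fit window excluded")
    }
  }
  t_s <- draw_time_s[keep]
  conc <- conc_mg_L[keep]
  if (length(t_s) < 3) {
    stop("insufficient data: at least 3 timed samples required",
         call. = FALSE)
  }
  if (any(duplicated(t_s))) {
    stop("draw times must be distinct", call. = FALSE)
  }
  if (any(!is.finite(conc)) || any(conc <= 0)) {
    stop("nonpositive concentration: all samples must have conc > 0 ",
         "for the log transform", call. = FALSE)
  }
  if (any(t_s <= 0)) {
    stop("draw times must be > 0 s", call. = FALSE)
  }
  d <- data.frame(t_s = t_s, ln_conc = log(conc))
  fit <- stats::lm(ln_conc ~ t_s, data = d)
  slope <- unname(stats::coef(fit)[2])
  ln_int <- unname(stats::coef(fit)[1])
  if (slope >= 0) {
    warning("nonphysiologic fit: ln-concentration does not decay with time",
            call. = FALSE)
  }
  k <- -slope * 60
  structure(
    list(
      slope_per_s = slope,
      ln_intercept = ln_int,
      r = stats::cor(d$t_s, d$ln_conc),
      n_points = length(t_s),
      k_per_min = k,
      c0_t0 = exp(ln_int),
      c_t60 = exp(ln_int + slope * 60),
      half_life_min = log(2) / k,
      pdr_pct_per_min = 100 * k,
      window = if (is.null(window)) c(min(t_s), max(t_s)) else
        as.numeric(window),
      lm = fit
    ),
    class = "icg_decay"
  )
}

#' @export
print.icg_decay <- function(x, ...) {
  cat("ICG elimination fit (ln concentration vs time)\n")
  cat(sprintf("  k = %.4f /min   half-life = %.3f min   PDR = %.2f %%/min\n",
              x$k_per_min, x$half_life_min, x$pdr_pct_per_min))
  cat(sprintf("  back-extrapolated: C(t=0) = %.4f mg/L, C(t=1 min) = %.4f mg/L\n",
              x$c0_t0, x$c_t60))
  cat(sprintf("  r = %.4f over %d samples (window %g-%g s)\n",
              x$r, x$n_points, x$window[1], x$window[2]))
  invisible(x)
}

#' @export
coef.icg_decay <- function(object, ...) {
  c(ln_intercept = object$ln_intercept, slope_per_s = object$slope_per_s)
}

#' @export
summary.icg_decay <- function(object, ...) {
  out <- list(fit = object, lm_summary = summary(object$lm))
  class(out) <- "summary.icg_decay"
  out
}

#' @export
print.summary.icg_decay <- function(x, ...) {
  print(x$fit)
  cat("\nUnderlying OLS fit on ln(conc):\n")
  print(stats::coef(x$lm_summary))
  invisible(x)
}

#' @export
residuals.icg_decay <- function(object, ...) {
  unname(stats::residuals(object$lm))
}

#' Back-extrapolated or interpolated concentration from a decay fit
#'
#' `predict()` evaluates the fitted exponential at arbitrary times;
#' `extrapolate_concentration()` is the explicit-name alias used by the
#' pipeline for the t = 0 and t = 1 min conventions.
#'
#' @param object,fit an `"icg_decay"` fit.
#' @param t_s times in seconds (0 gives `c0_t0`, 60 gives `c_t60`).
#' @param ... unused.
#' @return concentrations in mg/L.
#' @examples
#' t <- c(120, 165, 210, 255, 300)
#' fit <- fit_decay(t, 8 * exp(-(0.25 / 60) * t))
#' extrapolate_concentration(fit, c(0, 60))
#' @export
extrapolate_concentration <- function(fit, t_s) {
  stopifnot(inherits(fit, "icg_decay"))
  exp(fit$ln_intercept + fit$slope_per_s * t_s)
}

#' @rdname extrapolate_concentration
#' @export
predict.icg_decay <- function(object, t_s, ...) {
  if (missing(t_s)) t_s <- object$lm$model$t_s
  extrapolate_concentration(object, t_s)
}

#' @export
plot.icg_decay <- function(x, ...) {
  d <- x$lm$model
  tt <- seq(0, max(d$t_s), length.out = 200)
  graphics::plot(d$t_s, d$ln_conc, xlim = c(0, max(d$t_s)),
                 ylim = range(c(d$ln_conc, x$ln_intercept)),
                 xlab = "Time post-injection (s)",
                 ylab = "ln ICG concentration (ln mg/L)",
                 main = "ICG decay curve with back-extrapolation", ...)
  graphics::lines(tt, x$ln_intercept + x$slope_per_s * tt)
  graphics::points(c(0, 60), log(c(x$c0_t0, x$c_t60)), pch = 4)
  invisible(x)
}

#' Hepatic clearance of ICG
#'
#' Clearance is the plasma volume cleared of dye per unit time,
#' \eqn{k \times PV}.
#'
#' @param k_per_min elimination rate constant (1/min).
#' @param pv_mL plasma volume (mL).
#' @return clearance in mL/min.
#' @examples
#' clearance(0.25, 1608)  # 402 mL/min
#' @export
clearance <- function(k_per_min, pv_mL) {
  if (any(!is.finite(k_per_min)) || any(k_per_min <= 0)) {
    stop("k must be positive", call. = FALSE)
  }
  if (any(!is.finite(pv_mL)) || any(pv_mL < 0)) {
    stop("plasma volume must be >= 0", call. = FALSE)
  }
  k_per_min * pv_mL
}
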