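#' Injected ICG dose from syringe weights
#'
#' The syringe is weighed before and after the bolus injection; the weight
#' loss divided by the solution density gives the injected volume, and the
#' volume times the stock concentration gives the dose in mg.
#'
#' @param syringe_pre_g syringe weight before injection (g).
#' @param syringe_post_g syringe weight after injection (g).
#' @param stock_conc_mg_mL ICG concentration of the injectate (mg/mL).
#' @param density_g_mL solution density (g/mL); the reconstituted aqueous
#'   solution is close to 1.
#' @return dose in mg.
#' @examples
#' compute_dose(10.5, 4.1)  # 16 mg
#' @export
compute_dose <- function(syringe_pre_g, syringe_post_g,
                         stock_conc_mg_mL = 2.5, density_g_mL = 1.0) {
  stopifnot(stock_conc_mg_mL > 0, density_g_mL > 0)
  if (any(syringe_post_g >= syringe_pre_g)) {
    stop("post-injection syringe weight must be below pre-injection weight",
         call. = FALSE)
  }
  (syringe_pre_g - syringe_post_g) / density_g_mL * stock_conc_mg_mL
}

#' Planned injection volume for a participant
#'
#' The protocol targets 0.25 mg ICG per kg body weight drawn from a
#' 2.5 mg/mL stock: volume (mL) = dose_per_kg * weight / stock_conc.
#'
#' @param weight_kg body weight (kg).
#' @param target_dose_per_kg planned dose (mg/kg).
#' @param stock_conc_mg_mL stock concentration (mg/mL).
#' @return planned volume to draw, in mL.
#' @examples
#' planned_dose_volume(63.8)  # 6.38 mL
#' @export
planned_dose_volume <- function(weight_kg, target_dose_per_kg = 0.25,
                                stock_conc_mg_mL = 2.5) {
  stopifnot(all(weight_kg > 0), target_dose_per_kg > 0, stock_conc_mg_mL > 0)
  target_dose_per_kg * weight_kg / stock_conc_mg_mL
}

#' Plasma volume by the indicator-dilution principle
#'
#' `PV = D / C0`: the injected dose (mg) divided by the back-extrapolated
#' plasma concentration (mg/L) gives the dilution volume in litres.  The
#' caller chooses the concentration convention (`c0_t0` for t = 0,
#' `c_t60` for t = 1 min).
#'
#' @param dose_mg injected ICG dose (mg).
#' @param c0_mg_L back-extrapolated concentration (mg/L).
#' @return plasma volume in litres.
#' @examples
#' compute_pv(16, 8)  # 2 L
#' @export
compute_pv <- function(dose_mg, c0_mg_L) {
  if (any(!is.finite(dose_mg)) || any(dose_mg <= 0)) {
    stop("dose must be positive", call. = FALSE)
  }
  if (any(!is.finite(c0_mg_L)) || any(c0_mg_L <= 0)) {
    stop("extrapolated concentration must be positive", call. = FALSE)
  }
  dose_mg / c0_mg_L
}

#' Body surface area
#'
#' Du Bois-Du Bois (default): `0.007184 * weight^0.425 * height^0.725`;
#' Mosteller: `sqrt(weight * height / 3600)`.  Weight in kg, height in cm,
#' BSA in m².
#'
#' @param weight_kg body weight (kg).
#' @param height_cm height (cm).
#' @param formula `"dubois"` or `"mosteller"`.
#' @return BSA in m².
#' @examples
#' bsa(70, 170)
#' bsa(70, 170, formula = "mosteller")
#' @export
bsa <- function(weight_kg, height_cm, formula = c("dubois", "mosteller")) {
  formula <- match.arg(formula)
  if (any(weight_kg <= 0) || any(height_cm <= 0)) {
    stop("weight and height must be positive", call. = FALSE)
  }
  switch(formula,
    dubois = 0.007184 * weight_kg^0.425 * height_cm^0.725,
    mosteller = sqrt(weight_kg * height_cm / 3600)
  )
}

#' Per-participant plasma-volume result
#'
#' Combines an injected dose and a fitted decay curve into the full result
#' set: PV at both back-extrapolation conventions, body-size normalizations,
#' hepatic clearance, half-life and plasma disappearance rate.  Both PV
#' conventions are always reported side by side; normalized quantities use
#' the t = 0 convention, matching how cohort summaries are usually printed.
#'
#' @param dose_mg injected ICG dose (mg).
#' @param decay an `"icg_decay"` fit.
#' @param weight_kg body weight (kg).
#' @param height_cm height (cm).
#' @param bsa_formula `"dubois"` or `"mosteller"`.
#' @return An object of class `"icg_pv"`: `pv_t0_L`, `pv_t1_L`, `pv_t0_mL`,
#'   `pv_t1_mL`, `pv_per_kg_mL`, `bsa_m2`, `pv_per_bsa_mL`,
#'   `clearance_t0_mL_min`, `k_per_min`, `half_life_min`,
#'   `pdr_pct_per_min`, `dose_mg`, `decay_r`.
#' @examples
#' t <- c(120, 165, 210, 255, 300)
#' fit <- fit_decay(t, 8 * exp(-(0.25 / 60) * t))
#' pv_result(16, fit, weight_kg = 63.8, height_cm = 165)
#' @export
pv_result <- function(dose_mg, decay, weight_kg, height_cm,
                      bsa_formula = c("dubois", "mosteller")) {
  stopifnot(inherits(decay, "icg_decay"))
  bsa_formula <- match.arg(bsa_formula)
  pv_t0 <- compute_pv(dose_mg, decay$c0_t0)
  pv_t1 <- compute_pv(dose_mg, decay$c_t60)
  b <- bsa(weight_kg, height_cm, formula = bsa_formula)
  structure(
    list(
      dose_mg = dose_mg,
      pv_t0_L = pv_t0,
      pv_t1_L = pv_t1,
      pv_t0_mL = 1000 * pv_t0,
      pv_t1_mL = 1000 * pv_t1,
      pv_per_kg_mL = 1000 * pv_t0 / weight_kg,
      bsa_m2 = b,
      pv_per_bsa_mL = 1000 * pv_t0 / b,
      clearance_t0_mL_min = clearance(decay$k_per_min, 1000 * pv_t0),
      k_per_min = decay$k_per_min,
      half_life_min = decay$half_life_min,
      pdr_pct_per_min = decay$pdr_pct_per_min,
      decay_r = decay$r,
      weight_kg = weight_kg,
      height_cm = height_cm
    ),
    class = "icg_pv"
  )
}

#' @export
print.icg_pv <- function(x, ...) {
  cat("ICG plasma-volume result\n")
  cat(sprintf("  dose: %.2f mg\n", x$dose_mg))
  cat(sprintf("  PV(t=0): %.0f mL   PV(t=1 min): %.0f mL\n",
              x$pv_t0_mL, x$pv_t1_mL))
  cat(sprintf("  %.1f mL/kg   %.0f mL/m2 (BSA %.2f m2)\n",
              x$pv_per_kg_mL, x$pv_per_bsa_mL, x$bsa_m2))
  cat(sprintf("  k = %.3f /min   half-life = %.2f min   PDR = %.1f %%/min   clearance = %.0f mL/min\n",
              x$k_per_min, x$half_life_min, x$pdr_pct_per_min,
              x$clearance_t0_mL_min))
  invisible(x)
}

#' @export
as.data.frame.icg_pv <- function(x, ...) {
  data.frame(
    dose_mg = x$dose_mg, pv_t0_mL = x$pv_t0_mL, pv_t1_mL = x$pv_t1_mL,
    pv_per_kg_mL = x$pv_per_kg_mL, bsa_m2 = x$bsa_m2,
    pv_per_bsa_mL = x$pv_per_bsa_mL,
    clearance_t0_mL_min = x$clearance_t0_mL_min,
    k_per_min = x$k_per_min, half_life_min = x$half_life_min,
    pdr_pct_per_min = x$pdr_pct_per_min, decay_r = x$decay_r
  )
}
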