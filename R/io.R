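#' Read a long-format plate table
#'
#' One row per reading; columns `well`, `label`, `role` (blank / standard /
#' sample), `nominal_conc_mg_L` (standards only), `draw_time_s` (samples
#' only), `absorbance`.  Triplicate reads share a `label`.  Units are fixed
#' by the column names and never inferred.
#'
#' @param path CSV file path.
#' @return validated data.frame.
#' @export
read_plate_csv <- function(path) {
  if (!file.exists(path)) stop("plate file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("well", "label", "role", "nominal_conc_mg_L", "draw_time_s",
           "absorbance")
  missing_cols <- setdiff(req, names(d))
  if (length(missing_cols)) {
    stop("malformed plate CSV, missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!all(d$role %in% c("blank", "standard", "sample"))) {
    stop("plate roles must be blank/standard/sample", call. = FALSE)
  }
  if (any(!is.finite(d$absorbance)) || any(d$absorbance < 0)) {
    stop("absorbances must be finite and >= 0", call. = FALSE)
  }
  d
}

#' Read participant metadata
#'
#' Columns: `id`, `weight_kg`, `height_cm`, and optionally `age_y`,
#' `syringe_pre_g`, `syringe_post_g` (required to compute the actual
#' injected dose) and other anthropometrics.
#'
#' @param path CSV file path.
#' @return validated data.frame.
#' @export
read_participants_csv <- function(path) {
  if (!file.exists(path)) {
    stop("participant file not found: ", path, call. = FALSE)
  }
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("id", "weight_kg", "height_cm")
  missing_cols <- setdiff(req, names(d))
  if (length(missing_cols)) {
    stop("malformed participant CSV, missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(d$weight_kg <= 0) || any(d$height_cm <= 0)) {
    stop("weights and heights must be positive", call. = FALSE)
  }
  d
}

# collapse replicate reads to one mean per group, with QC CV
collapse_wells <- function(plate, cv_warn_pct = 15) {
  labs <- unique(plate$label)
  out <- do.call(rbind, lapply(labs, function(l) {
    g <- plate[plate$label == l, ]
    a <- average_wells(g$absorbance)
    data.frame(label = l, role = g$role[1],
               nominal_conc_mg_L = g$nominal_conc_mg_L[1],
               draw_time_s = g$draw_time_s[1],
               mean_absorbance = a$mean, cv_pct = a$cv_pct, n_reads = a$n)
  }))
  # blanks sit near zero absorbance, where CV is not a meaningful QC metric
  high <- !is.na(out$cv_pct) & out$cv_pct > cv_warn_pct &
    out$role != "blank"
  if (any(high)) {
    warning("triplicate CV above ", cv_warn_pct, "% for group(s): ",
            paste(out$label[high], collapse = ", "), call. = FALSE)
  }
  out
}

#' Calibrate from a plate table
#'
#' Averages replicate reads per group, fits the calibration curve on the
#' standard groups, and returns the curve together with per-group QC.
#'
#' @param plate data.frame from [read_plate_csv()] (or [simulate_plate()]).
#' @param config an [icg_config()].
#' @return A list: `curve` (an `"icg_calibration"`), `groups` (collapsed
#'   per-group means with CVs), `blank_absorbance` (mean of the blank group,
#'   QC only; `NA` if no blank present).
#' @export
calibrate_plate <- function(plate, config = icg_config()) {
  groups <- collapse_wells(plate, cv_warn_pct = config$cv_warn_pct)
  std <- groups[groups$role == "standard", ]
  if (nrow(std) < 3) {
    stop("plate has fewer than 3 standard groups", call. = FALSE)
  }
  curve <- fit_calibration(std$nominal_conc_mg_L, std$mean_absorbance,
                           linear_cap_mg_L = config$linear_cap_mg_L)
  blank <- groups$mean_absorbance[groups$role == "blank"]
  list(curve = curve, groups = groups,
       blank_absorbance = if (length(blank)) blank[1] else NA_real_)
}

#' Full per-participant pipeline: plate to plasma volume
#'
#' Runs calibrate -> invert -> decay fit -> PV for one participant:
#' the calibration curve is fitted from the plate's own standards, timed
#' sample absorbances are inverted to concentrations, samples flagged above
#' the linear range are excluded (with a warning), and the elimination curve
#' is fitted on the samples inside the configured time window.
#'
#' @param plate plate data.frame (see [read_plate_csv()]).
#' @param dose_mg injected ICG dose (mg).
#' @param weight_kg,height_cm participant anthropometrics.
#' @param config an [icg_config()].
#' @return A list of class `"icg_participant_fit"`: `calibration`,
#'   `decay` (an `"icg_decay"`), `pv` (an `"icg_pv"`), `samples`
#'   (data.frame of time, concentration and exclusion flags), `exclusions`
#'   (character log).
#' @examples
#' p <- simulate_participant(seed = 7, mixing_tau_s = 0,
#'                           absorbance_noise_sd = 0, timing_jitter_sd = 0)
#' plate <- simulate_plate(p$truth, seed = 8)
#' fit <- pv_from_plate(plate, p$truth$dose_mg, p$record$weight_kg,
#'                      p$record$height_cm)
#' fit$pv$pv_t0_L            # recovers p$truth$true_pv_L
#' @export
pv_from_plate <- function(plate, dose_mg, weight_kg, height_cm,
                          config = icg_config()) {
  cal <- calibrate_plate(plate, config)
  smp <- cal$groups[cal$groups$role == "sample", ]
  if (nrow(smp) == 0) stop("plate has no timed samples", call. = FALSE)
  conc <- invert_absorbance(cal$curve, smp$mean_absorbance)
  flags <- attr(conc, "flags")
  exclusions <- character(0)
  usable <- !flags$above_range
  if (any(!usable)) {
    exclusions <- paste0(smp$label[!usable],
                         ": above linear range, excluded from decay fit")
    warning(length(exclusions),
            " sample(s) above the linear range excluded from the decay fit",
            call. = FALSE)
  }
  samples <- data.frame(
    label = smp$label, draw_time_s = smp$draw_time_s,
    conc_mg_L = as.numeric(conc),
    above_range = flags$above_range, clamped = flags$clamped
  )
  if (sum(usable) < 3) {
    stop("fewer than 3 usable timed samples after exclusions",
         call. = FALSE)
  }
  decay <- fit_decay(samples$draw_time_s[usable], samples$conc_mg_L[usable],
                     window = config$fit_window_s)
  pv <- pv_result(dose_mg, decay, weight_kg, height_cm,
                  bsa_formula = config$bsa_formula)
  structure(
    list(calibration = cal, decay = decay, pv = pv, samples = samples,
         exclusions = exclusions),
    class = "icg_participant_fit"
  )
}

#' @export
print.icg_participant_fit <- function(x, ...) {
  print(x$calibration$curve)
  cat("\n")
  print(x$decay)
  cat("\n")
  print(x$pv)
  if (length(x$exclusions)) {
    cat("\nExclusions:\n")
    cat(paste0("  ", x$exclusions, collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Run the full workflow over a study directory
#'
#' Consumes the layout written by [simulate_study()] (or assembled by hand):
#' `participants.csv` plus one `plate_<id>.csv` per participant.  The dose
#' is taken from syringe weights when present, otherwise from the planned
#' 0.25 mg/kg.  Returns the per-participant results and the cohort summary.
#'
#' @param dir study directory.
#' @param config an [icg_config()].
#' @return A list: `results` (data.frame, one row per participant with PV at
#'   both conventions and all kinetic quantities), `fits` (list of
#'   `"icg_participant_fit"`), `cohort` (an `"icg_cohort"`).
#' @export
run_study <- function(dir, config = icg_config()) {
  meta <- read_participants_csv(file.path(dir, "participants.csv"))
  fits <- vector("list", nrow(meta))
  rows <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    id <- meta$id[i]
    plate_path <- file.path(dir, paste0("plate_", id, ".csv"))
    if (!file.exists(plate_path)) {
      stop("no plate file for participant ", id, call. = FALSE)
    }
    plate <- read_plate_csv(plate_path)
    dose <- if (!is.null(meta$syringe_pre_g) &&
                !is.null(meta$syringe_post_g) &&
                is.finite(meta$syringe_pre_g[i]) &&
                is.finite(meta$syringe_post_g[i])) {
      compute_dose(meta$syringe_pre_g[i], meta$syringe_post_g[i],
                   stock_conc_mg_mL = config$stock_conc_mg_mL,
                   density_g_mL = config$density_g_mL)
    } else {
      config$target_dose_per_kg * meta$weight_kg[i]
    }
    fit <- pv_from_plate(plate, dose, meta$weight_kg[i], meta$height_cm[i],
                         config = config)
    fits[[i]] <- fit
    rows[[i]] <- cbind(
      data.frame(id = id, weight_kg = meta$weight_kg[i],
                 height_cm = meta$height_cm[i],
                 calibration_r = fit$calibration$curve$r),
      as.data.frame(fit$pv)
    )
  }
  results <- do.call(rbind, rows)
  cohort <- summarize_cohort(results, bsa_formula = config$bsa_formula)
  list(results = results, fits = fits, cohort = cohort)
}

#' Write a calibration report as JSON
#'
#' @param cal result of [calibrate_plate()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_calibration_report <- function(cal, path) {
  report <- list(
    slope = cal$curve$slope, intercept = cal$curve$intercept,
    r = cal$curve$r, n_points = cal$curve$n_points,
    valid_range = cal$curve$valid_range,
    blank_absorbance = cal$blank_absorbance,
    groups = cal$groups
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null", dataframe = "rows")
  invisible(path)
}

#' Write per-participant PV results as CSV
#'
#' @param results the `results` data.frame from [run_study()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_pv_report <- function(results, path) {
  utils::write.csv(results, path, row.names = FALSE)
  invisible(path)
}

#' Write a cohort summary (means/SDs and correlations) as JSON
#'
#' @param cohort an `"icg_cohort"`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_cohort_report <- function(cohort, path) {
  report <- list(n = cohort$n, summary = cohort$summary,
                 correlations = cohort$correlations)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null", dataframe = "rows")
  invisible(path)
}
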