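# truncated-normal draw by rejection; bounds are a few SD from the mean in
# every use here, so rejection is cheap
rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

#' Simulate one study participant with ground-truth kinetics
#'
#' Draws anthropometrics matching the cohort the generator emulates
#' (women of reproductive age: weight ~ N(63.8, 7.4) kg truncated to
#' [45, 100], height ~ N(165, 7) cm truncated to [145, 185]) and a
#' ground-truth parameter set: elimination rate constant
#' k ~ N(0.25, 0.06)/min truncated to [0.10, 0.45], and true plasma volume
#' linearly tied to body surface area
#' (`PV = 1.175 * BSA + N(0, 0.10)` L, truncated to [1.0, 3.5] L).  The
#' coefficient makes PV average about 2 L at the cohort-mean BSA of about
#' 1.70 m2, and the scatter SD is set so the population PV-BSA correlation
#' is about 0.75 (the anthropometric distributions imply a BSA SD near
#' 0.10 m2, hence a PV signal SD near 0.12 L).  The planned dose is
#' 0.25 mg/kg.
#'
#' @param id participant identifier.
#' @param seed optional integer seed (sets the RNG before drawing).
#' @param mixing_tau_s time constant of the post-injection mixing phase (s);
#'   0 gives instantaneous mixing (pure mono-exponential).
#' @param absorbance_noise_sd SD of additive plate-reader noise per reading
#'   (AU).
#' @param timing_jitter_sd SD of draw-time jitter (s); the jittered time is
#'   what gets recorded, emulating "record the exact time of each draw".
#' @param cal_slope_true,cal_intercept_true true absorbance response
#'   (AU per mg/L, AU); the intercept is the plasma background at 805 nm.
#' @param pv_coef_L_per_m2,pv_noise_sd_L slope and scatter of the PV-BSA
#'   relation in the generator.
#' @return A list with `record` (one-row data.frame: `id`, `weight_kg`,
#'   `height_cm`, `age_y`, `bmi`, `body_fat_pct`, `syringe_pre_g`,
#'   `syringe_post_g`) and `truth` (list of class `"icg_truth"`: `true_pv_L`,
#'   `true_k_per_min`, `mixing_tau_s`, `dose_mg`, `cal_slope_true`,
#'   `cal_intercept_true`, `absorbance_noise_sd`, `timing_jitter_sd`).
#' @examples
#' p <- simulate_participant(seed = 7)
#' p$truth$true_pv_L
#' @export
simulate_participant <- function(id = "P1", seed = NULL,
                                 mixing_tau_s = 30,
                                 absorbance_noise_sd = 0.0075,
                                 timing_jitter_sd = 2,
                                 cal_slope_true = 0.04,
                                 cal_intercept_true = 0.05,
                                 pv_coef_L_per_m2 = 1.175,
                                 pv_noise_sd_L = 0.10) {
  if (!is.null(seed)) set.seed(seed)
  weight <- rtruncnorm1(1, 63.8, 7.4, 45, 100)
  height <- rtruncnorm1(1, 165, 7, 145, 185)
  age <- rtruncnorm1(1, 25, 4.5, 18, 45)
  body_fat <- rtruncnorm1(1, 28.6, 5, 15, 45)
  true_k <- rtruncnorm1(1, 0.25, 0.06, 0.10, 0.45)
  b <- bsa(weight, height)
  true_pv <- max(1.0, min(3.5,
    pv_coef_L_per_m2 * b + stats::rnorm(1, 0, pv_noise_sd_L)))
  dose <- 0.25 * weight
  # syringe weights consistent with the injected dose at density 1 g/mL
  pre <- 10 + dose / 2.5
  record <- data.frame(
    id = id, weight_kg = weight, height_cm = height, age_y = age,
    bmi = weight / (height / 100)^2, body_fat_pct = body_fat,
    syringe_pre_g = pre, syringe_post_g = 10
  )
  truth <- structure(
    list(
      id = id, true_pv_L = true_pv, true_k_per_min = true_k,
      mixing_tau_s = mixing_tau_s, dose_mg = dose,
      cal_slope_true = cal_slope_true,
      cal_intercept_true = cal_intercept_true,
      absorbance_noise_sd = absorbance_noise_sd,
      timing_jitter_sd = timing_jitter_sd
    ),
    class = "icg_truth"
  )
  list(record = record, truth = truth)
}

#' Ground-truth plasma ICG concentration
#'
#' The generative kinetic model is a single well-mixed plasma pool with a
#' saturating mixing factor:
#' \deqn{C(t) = \frac{D}{PV} (1 - e^{-t/\tau}) e^{-k t / 60}}
#' with t in seconds, k per minute, and mixing time constant \eqn{\tau}
#' (default 30 s).  With \eqn{\tau = 0} this reduces to the pure
#' mono-exponential, and C(0) = D/PV.
#'
#' @param truth an `"icg_truth"` parameter set.
#' @param t_s time(s) since start of injection (s), >= 0.
#' @return concentration(s) in mg/L.
#' @examples
#' p <- simulate_participant(seed = 7, mixing_tau_s = 0)
#' simulate_concentration(p$truth, 0)  # dose / PV exactly
#' @export
simulate_concentration <- function(truth, t_s) {
  stopifnot(inherits(truth, "icg_truth"), all(t_s >= 0))
  mix <- if (truth$mixing_tau_s <= 0) 1 else
    1 - exp(-t_s / truth$mixing_tau_s)
  (truth$dose_mg / truth$true_pv_L) * mix * exp(-truth$true_k_per_min *
                                                  t_s / 60)
}

#' Simulate a 96-well plate readout for one participant
#'
#' Generates the long-format plate table the reader consumes: a blank group
#' (plasma background only), one group per calibration standard, and one
#' group per timed draw, each read in triplicate.  Absorbance =
#' `cal_slope_true * conc + cal_intercept_true + N(0, absorbance_noise_sd)`
#' per reading.  Draw times are jittered by `N(0, timing_jitter_sd)` and the
#' jittered time is recorded, mirroring a bench protocol where the actual
#' draw time is written down.
#'
#' @param truth an `"icg_truth"` parameter set.
#' @param draw_times_s nominal draw times (s), within (0, 600].
#' @param standards_mg_L final standard concentrations (mg/L).
#' @param n_reps replicate reads per group.
#' @param seed optional integer seed.
#' @return A data.frame with columns `well`, `label`, `role`
#'   (blank/standard/sample), `nominal_conc_mg_L`, `draw_time_s`,
#'   `absorbance` - one row per read.
#' @examples
#' p <- simulate_participant(seed = 7)
#' plate <- simulate_plate(p$truth, seed = 8)
#' head(plate)
#' @export
simulate_plate <- function(truth,
                           draw_times_s = c(120, 165, 210, 255, 300),
                           standards_mg_L = c(2.5, 3.75, 5, 7.5, 10),
                           n_reps = 3, seed = NULL) {
  stopifnot(inherits(truth, "icg_truth"),
            all(draw_times_s > 0), all(draw_times_s <= 600))
  if (!is.null(seed)) set.seed(seed)
  jit <- stats::rnorm(length(draw_times_s), 0, truth$timing_jitter_sd)
  rec_times <- pmax(1, draw_times_s + jit)
  sample_conc <- simulate_concentration(truth, rec_times)

  groups <- data.frame(
    label = c("blank",
              paste0("std_", standards_mg_L),
              paste0("t_", seq_along(rec_times))),
    role = c("blank", rep("standard", length(standards_mg_L)),
             rep("sample", length(rec_times))),
    nominal_conc_mg_L = c(0, standards_mg_L, rep(NA, length(rec_times))),
    draw_time_s = c(rep(NA, 1 + length(standards_mg_L)), rec_times),
    conc = c(0, standards_mg_L, sample_conc)
  )
  idx <- rep(seq_len(nrow(groups)), each = n_reps)
  out <- groups[idx, c("label", "role", "nominal_conc_mg_L", "draw_time_s")]
  out$absorbance <- truth$cal_slope_true * groups$conc[idx] +
    truth$cal_intercept_true +
    stats::rnorm(length(idx), 0, truth$absorbance_noise_sd)
  out$absorbance <- pmax(out$absorbance, 0)
  out <- cbind(well = paste0("W", seq_len(nrow(out))), out)
  rownames(out) <- NULL
  out
}

#' Simulate a complete study and write it to disk
#'
#' Generates `n` participants with ground truth, one plate table per
#' participant, a participant metadata table, and a run manifest; the file
#' layout round-trips through [read_plate_csv()] and
#' [read_participants_csv()].
#'
#' @param out_dir directory to write into (created if needed).
#' @param n cohort size (default 9).
#' @param seed integer seed governing every random draw.
#' @param config an [icg_config()]; its standard series and seed are
#'   recorded in the manifest.
#' @param ... passed to [simulate_participant()] (noise and mixing
#'   parameters).
#' @return Invisibly, a list with `participants` (data.frame), `truths`
#'   (list), `files` (character vector of paths written).
#' @examples
#' \donttest{
#' study <- simulate_study(tempfile("study"), n = 3, seed = 42)
#' }
#' @export
simulate_study <- function(out_dir, n = 9, seed = 1, config = icg_config(),
                           ...) {
  stopifnot(n >= 1)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create ", out_dir, call. = FALSE)
  set.seed(seed)
  ids <- sprintf("P%02d", seq_len(n))
  sims <- lapply(ids, function(id) simulate_participant(id = id, ...))
  participants <- do.call(rbind, lapply(sims, `[[`, "record"))
  truths <- lapply(sims, `[[`, "truth")

  files <- character(0)
  meta_path <- file.path(out_dir, "participants.csv")
  utils::write.csv(participants, meta_path, row.names = FALSE)
  files <- c(files, meta_path)

  for (i in seq_len(n)) {
    plate <- simulate_plate(truths[[i]],
                            standards_mg_L = config$standards_mg_L)
    p <- file.path(out_dir, paste0("plate_", ids[i], ".csv"))
    utils::write.csv(plate, p, row.names = FALSE, na = "")
    files <- c(files, p)
  }

  truth_path <- file.path(out_dir, "truth.json")
  jsonlite::write_json(
    lapply(truths, unclass), truth_path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  files <- c(files, truth_path)

  manifest <- list(seed = seed, n = n, config_hash = config_hash(config),
                   standards_mg_L = config$standards_mg_L,
                   files = basename(files))
  man_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(files, man_path)

  invisible(list(participants = participants, truths = truths,
                 files = files))
}
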