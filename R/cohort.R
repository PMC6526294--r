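# all permutations of 1:n as an (n!) x n integer matrix, built iteratively
# by insertion; n <= 9 keeps this under ~13 MB
all_permutations <- function(n) {
  stopifnot(n >= 1, n <= 9)
  p <- matrix(1L, nrow = 1, ncol = 1)
  for (k in 2:max(2, n)) {
    if (k > n) break
    m <- nrow(p)
    out <- matrix(0L, nrow = m * k, ncol = k)
    for (pos in seq_len(k)) {
      rows <- (pos - 1) * m + seq_len(m)
      if (pos > 1) out[rows, seq_len(pos - 1)] <- p[, seq_len(pos - 1),
                                                    drop = FALSE]
      out[rows, pos] <- k
      if (pos < k) out[rows, (pos + 1):k] <- p[, pos:(k - 1), drop = FALSE]
    }
    p <- out
  }
  if (n == 1) matrix(1L, 1, 1) else p
}

#' Spearman rank correlation with exact permutation p-value
#'
#' Ranks are mid-ranks for ties.  For `n <= 9` the two-sided p-value is
#' computed by complete enumeration of all `n!` permutations of one
#' variable's ranks (valid with ties, unlike the classical null
#' distribution); for larger n the t-approximation is used.
#'
#' @param x,y numeric vectors of equal length, n >= 3.
#' @param exact_max largest n for which the permutation null is enumerated.
#' @return A list: `r` (Spearman rho), `p` (two-sided), `method`
#'   (`"exact permutation"` or `"t approximation"`), `n`.
#' @examples
#' spearman_test(1:6, c(2, 1, 4, 3, 6, 5))
#' @export
spearman_test <- function(x, y, exact_max = 9) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("need at least 3 pairs", call. = FALSE)
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    return(list(r = NA_real_, p = NA_real_, method = "degenerate", n = n))
  }
  r <- stats::cor(rx, ry)
  if (n <= exact_max) {
    perms <- all_permutations(n)
    rxc <- rx - mean(rx)
    ryp <- matrix(ry[perms], nrow = nrow(perms))
    # correlation of each permuted ry with rx; denominators are permutation-
    # invariant so only the cross-product varies
    num <- as.numeric(ryp %*% rxc)
    denom <- sqrt(sum(rxc^2) * sum((ry - mean(ry))^2))
    r_perm <- num / denom
    p <- mean(abs(r_perm) >= abs(r) - 1e-12)
    list(r = r, p = p, method = "exact permutation", n = n)
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    list(r = r, p = p, method = "t approximation", n = n)
  }
}

#' Cohort-level summary of plasma-volume results
#'
#' Means and SDs of the anthropometric and PV variables, plus, for each
#' anthropometric predictor (height, weight, BMI, BSA), the Spearman rank
#' correlation with PV (t = 0 convention, litres) with an exact permutation
#' p-value for small cohorts, and the OLS slope with its normal-theory 95%
#' confidence interval.
#'
#' @param cohort a data.frame with one row per participant, containing at
#'   least `weight_kg`, `height_cm`, `pv_t0_mL`; optional `bmi`, `bsa_m2`,
#'   `pv_t1_mL`, `k_per_min`, `half_life_min`, `pdr_pct_per_min`,
#'   `clearance_t0_mL_min`, `pv_per_kg_mL`, `pv_per_bsa_mL`, `age_y`.
#' @param bsa_formula used to derive `bsa_m2` when absent.
#' @return An object of class `"icg_cohort"`: `n`, `summary` (data.frame of
#'   variable, mean, sd), `correlations` (data.frame of predictor, spearman
#'   r and p, OLS slope, CI bounds), and the input `cohort`.
#' @examples
#' co <- data.frame(weight_kg = c(54, 64, 66, 80), height_cm = c(158, 163,
#'   167, 175), pv_t0_mL = c(1250, 1510, 1640, 2000))
#' summarize_cohort(co)
#' @export
summarize_cohort <- function(cohort, bsa_formula = c("dubois", "mosteller")) {
  bsa_formula <- match.arg(bsa_formula)
  stopifnot(is.data.frame(cohort))
  n <- nrow(cohort)
  if (n < 3) stop("cohort summary needs at least 3 participants",
                  call. = FALSE)
  req <- c("weight_kg", "height_cm", "pv_t0_mL")
  missing_cols <- setdiff(req, names(cohort))
  if (length(missing_cols)) {
    stop("cohort is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(cohort$bmi)) {
    cohort$bmi <- cohort$weight_kg / (cohort$height_cm / 100)^2
  }
  if (is.null(cohort$bsa_m2)) {
    cohort$bsa_m2 <- bsa(cohort$weight_kg, cohort$height_cm,
                         formula = bsa_formula)
  }

  num_vars <- names(cohort)[vapply(cohort, is.numeric, logical(1))]
  summ <- data.frame(
    variable = num_vars,
    mean = vapply(num_vars, function(v) mean(cohort[[v]]), numeric(1)),
    sd = vapply(num_vars, function(v) stats::sd(cohort[[v]]), numeric(1)),
    row.names = NULL
  )

  pv_L <- cohort$pv_t0_mL / 1000
  constant_pv <- stats::sd(pv_L) == 0
  predictors <- c(height_cm = "height_cm", weight_kg = "weight_kg",
                  bmi = "bmi", bsa_m2 = "bsa_m2")
  cors <- do.call(rbind, lapply(names(predictors), function(p) {
    xx <- cohort[[predictors[[p]]]]
    if (constant_pv || stats::sd(xx) == 0) {
      return(data.frame(predictor = p, spearman_r = NA_real_,
                        spearman_p = NA_real_, ols_slope = NA_real_,
                        ci_lo = NA_real_, ci_hi = NA_real_))
    }
    st <- spearman_test(xx, pv_L)
    fit <- stats::lm(pv_L ~ xx)
    ci <- stats::confint(fit, "xx", level = 0.95)
    data.frame(predictor = p, spearman_r = st$r, spearman_p = st$p,
               ols_slope = unname(stats::coef(fit)["xx"]),
               ci_lo = ci[1], ci_hi = ci[2])
  }))
  if (constant_pv) {
    warning("plasma volume is constant across the cohort; ",
            "correlations are undefined", call. = FALSE)
  }
  structure(
    list(n = n, summary = summ, correlations = cors, cohort = cohort),
    class = "icg_cohort"
  )
}

#' @export
print.icg_cohort <- function(x, digits = 3, ...) {
  cat(sprintf("ICG plasma-volume cohort (n = %d)\n\n", x$n))
  s <- x$summary
  s$mean <- signif(s$mean, digits + 1)
  s$sd <- signif(s$sd, digits)
  print(s, row.names = FALSE)
  cat("\nPV (t = 0, L) vs anthropometrics:\n")
  co <- x$correlations
  co[-1] <- lapply(co[-1], signif, digits)
  print(co, row.names = FALSE)
  invisible(x)
}

#' @export
summary.icg_cohort <- function(object, ...) object

#' @export
plot.icg_cohort <- function(x, predictor = "bsa_m2", ...) {
  xx <- x$cohort[[predictor]]
  pv <- x$cohort$pv_t0_mL / 1000
  graphics::plot(xx, pv, xlab = predictor, ylab = "Plasma volume, t = 0 (L)",
                 main = "Plasma volume vs body size", ...)
  graphics::abline(stats::lm(pv ~ xx))
  invisible(x)
}
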