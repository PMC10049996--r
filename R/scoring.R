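#' Construct a patient exposure profile
#'
#' A profile assigns one level to every factor of the active coefficient
#' set. Binary factors take `"present"`/`"absent"`; lipid-lowering drug
#' duration takes `"none"`, `"lt3y"` or `"gt3y"`. Demographics such as
#' age, height and weight may be supplied and are carried through but
#' never enter the score (the model has no coefficients for them).
#'
#' @param ... Named factor levels, e.g. `male = "present"`,
#'   `lipid_lowering = "none"`.
#' @param demographics Optional named list passed through unchanged.
#' @return A named character vector of class `patient_profile`.
#' @export
#' @examples
#' patient_profile(male = "present", bariatric = "absent", myopia = "absent",
#'   lipid_lowering = "none", fpg = "present", duration = "present",
#'   hba1c = "present", intensive_control = "present",
#'   hypertension = "present", insulin = "present", rural = "present",
#'   smoking = "present")
patient_profile <- function(..., demographics = NULL) {
  x <- c(...)
  if (is.null(names(x)) || any(names(x) == "")) {
    stop("all factor levels must be named by factor_id")
  }
  structure(x, demographics = demographics, class = "patient_profile")
}

#' The published worked-example patient
#'
#' A 60-year-old male, 170 cm / 60 kg, no bariatric surgery, no myopia, no
#' lipid-lowering drugs, fasting plasma glucose 6.5 mmol/L (elevated),
#' 10 years of diabetes, HbA1c 7% (elevated), intensive glycemic control,
#' hypertensive, on insulin, rural resident, smoker. Scored against the
#' printed coefficient set this profile yields logit 1.177 and a
#' relative-risk score of 2.75 at local prevalence 27.8%.
#'
#' @return A `patient_profile`.
#' @export
example_patient <- function() {
  patient_profile(
    male = "present", bariatric = "absent", myopia = "absent",
    lipid_lowering = "none",
    fpg = binarize_fpg(6.5), duration = "present",
    hba1c = binarize_hba1c(7),
    intensive_control = "present", hypertension = "present",
    insulin = "present", rural = "present", smoking = "present",
    demographics = list(age = 60, height_cm = 170, weight_kg = 60)
  )
}

#' Binarize continuous glycemic measurements
#'
#' The model codes fasting plasma glucose and HbA1c as binary
#' elevated/normal states. Defaults: FPG is elevated above 6.1 mmol/L
#' (impaired fasting glucose threshold) and HbA1c at or above 6.5%
#' (diagnostic threshold). Both are configurable.
#'
#' @param fpg_mmol_l Fasting plasma glucose in mmol/L.
#' @param hba1c_pct Glycated hemoglobin in percent.
#' @param threshold Cut point for elevation.
#' @return `"present"` or `"absent"` (vectorised).
#' @export
#' @examples
#' binarize_fpg(6.5)   # "present"
#' binarize_hba1c(6.0) # "absent"
binarize_fpg <- function(fpg_mmol_l, threshold = 6.1) {
  stopifnot(is.numeric(fpg_mmol_l), all(is.finite(fpg_mmol_l)))
  ifelse(fpg_mmol_l > threshold, "present", "absent")
}

#' @rdname binarize_fpg
#' @export
binarize_hba1c <- function(hba1c_pct, threshold = 6.5) {
  stopifnot(is.numeric(hba1c_pct), all(is.finite(hba1c_pct)))
  ifelse(hba1c_pct >= threshold, "present", "absent")
}

# Validate a profile against a coefficient set; returns the profile
# restricted and ordered to the set's factors.
validate_profile <- function(profile, coeffs) {
  levels <- coef_levels(coeffs)
  factors <- names(levels)
  missing <- setdiff(factors, names(profile))
  if (length(missing) > 0L) {
    stop("profile is missing factor(s): ", paste(missing, collapse = ", "))
  }
  unknown_f <- setdiff(names(profile), factors)
  if (length(unknown_f) > 0L) {
    stop("profile has unknown factor(s): ", paste(unknown_f, collapse = ", "))
  }
  p <- unclass(profile)[factors]
  bad <- vapply(factors, function(f) !(p[[f]] %in% levels[[f]]), logical(1L))
  if (any(bad)) {
    offenders <- paste0(factors[bad], "='", p[factors[bad]], "'")
    stop("unknown level(s): ", paste(offenders, collapse = ", "))
  }
  p
}

#' Compute the linear predictor (logit) for one patient
#'
#' The model's linear predictor is the prevalence-anchored intercept plus
#' the sum of the coefficients of the patient's active factor levels:
#' logit(P) = alpha + sum_i beta_i X_i. Per-factor additive contributions
#' are returned as an attribute for reporting.
#'
#' @param profile A `patient_profile` (or named character vector).
#' @param coeffs A `coefficient_set`.
#' @return The logit (log-odds) as a numeric scalar, with attribute
#'   `"contributions"`: a named numeric vector of each factor's additive
#'   term (baseline levels contribute 0).
#' @export
#' @examples
#' cs <- build_coefficient_set()
#' compute_logit(example_patient(), cs)  # 1.177
compute_logit <- function(profile, coeffs) {
  stopifnot(inherits(coeffs, "coefficient_set"))
  p <- validate_profile(profile, coeffs)
  key <- paste(coeffs$betas$factor_id, coeffs$betas$level, sep = ":")
  beta <- stats::setNames(coeffs$betas$beta, key)
  contributions <- beta[paste(names(p), p, sep = ":")]
  names(contributions) <- names(p)
  structure(coeffs$alpha + sum(contributions),
            contributions = contributions)
}

#' Inverse logit, numerically stable
#'
#' Maps a log-odds value to a probability; saturates smoothly at the
#' floating-point limits for very large magnitudes.
#'
#' @param logit Finite log-odds value(s).
#' @return Probability in (0, 1).
#' @export
probability_from_logit <- function(logit) {
  stopifnot(is.numeric(logit), !anyNA(logit))
  stats::plogis(as.numeric(logit))
}

#' Relative-risk (LP) score
#'
#' The model reports risk as a multiple of the local prevalence:
#' LP = P / p, where P is the patient's predicted DR probability and p the
#' local DR prevalence among type 2 diabetics. LP = 2.75 reads "2.75 times
#' the risk of the local diabetic population". Summaries print it at two
#' decimals.
#'
#' @param probability Predicted probability in (0, 1).
#' @param prevalence Local prevalence in (0, 1).
#' @return LP, a non-negative dimensionless score.
#' @export
relative_risk <- function(probability, prevalence) {
  stopifnot(is.numeric(probability), is.numeric(prevalence))
  if (any(prevalence <= 0 | prevalence >= 1)) {
    stop("prevalence must lie strictly inside (0, 1)")
  }
  if (any(probability <= 0 | probability >= 1)) {
    stop("probability must lie strictly inside (0, 1)")
  }
  probability / prevalence
}

#' Classify a scored patient as high or low risk
#'
#' Two rules are supported: `"p_half"` labels a patient high-risk when the
#' predicted probability is at least 0.5 (equivalently logit >= 0), the
#' dividing node chosen on the simulated sorted probability curve;
#' `"lp_cutoff"` labels high-risk when the LP score strictly exceeds the
#' cut-off (published value 2.24). Boundary conventions: a probability of
#' exactly 0.5 is high under `p_half`; an LP exactly at the cut-off is low
#' under `lp_cutoff`, following the published "greater than" wording.
#'
#' @param result A `risk_result` from [score_patient()], or a list with
#'   elements `probability` and `lp`.
#' @param rule `"p_half"` or `"lp_cutoff"`.
#' @param lp_cutoff Positive LP threshold used by the `"lp_cutoff"` rule.
#' @return `"high"` or `"low"`.
#' @export
classify <- function(result, rule = c("p_half", "lp_cutoff"),
                     lp_cutoff = 2.24) {
  rule <- match.arg(rule)
  if (rule == "p_half") {
    ifelse(result$probability >= 0.5, "high", "low")
  } else {
    if (!is.numeric(lp_cutoff) || lp_cutoff <= 0) {
      stop("lp_cutoff must be positive")
    }
    ifelse(result$lp > lp_cutoff, "high", "low")
  }
}

#' Score one patient
#'
#' Runs the full chain logit -> probability -> LP -> risk class for a
#' single profile.
#'
#' @inheritParams compute_logit
#' @inheritParams classify
#' @return A `risk_result`: list with `logit`, `probability`, `lp`,
#'   `risk_class`, and `contributions` (named per-factor logit terms).
#' @export
#' @examples
#' cs <- build_coefficient_set()
#' score_patient(example_patient(), cs, rule = "lp_cutoff")
score_patient <- function(profile, coeffs,
                          rule = c("p_half", "lp_cutoff"),
                          lp_cutoff = 2.24) {
  rule <- match.arg(rule)
  logit <- compute_logit(profile, coeffs)
  probability <- probability_from_logit(logit)
  lp <- relative_risk(probability, coeffs$prevalence)
  res <- list(logit = as.numeric(logit), probability = probability, lp = lp,
              contributions = attr(logit, "contributions"))
  res$risk_class <- classify(res, rule, lp_cutoff)
  structure(res, class = "risk_result")
}

#' @export
print.risk_result <- function(x, ...) {
  cat(sprintf("logit %.3f  P %.4f  LP %.2f  risk: %s\n",
              x$logit, x$probability, x$lp, x$risk_class))
  invisible(x)
}

#' Score a table of patients
#'
#' Each row is one patient; columns named after factor ids hold level
#' strings. Continuous columns `fpg_mmol_l` and `hba1c_pct`, if present,
#' are binarized into the `fpg` / `hba1c` factors via [binarize_fpg()] and
#' [binarize_hba1c()]. Other columns (age, height, weight, ...) are
#' ignored by the score.
#'
#' @param patients data.frame of patient rows.
#' @param coeffs A `coefficient_set`.
#' @inheritParams classify
#' @param fpg_threshold,hba1c_threshold Binarization cut points.
#' @return data.frame with one row per patient: `logit`, `probability`,
#'   `lp`, `risk_class`, plus one `contrib_<factor>` column per factor.
#' @export
score_patients <- function(patients, coeffs,
                           rule = c("p_half", "lp_cutoff"), lp_cutoff = 2.24,
                           fpg_threshold = 6.1, hba1c_threshold = 6.5) {
  rule <- match.arg(rule)
  stopifnot(is.data.frame(patients), nrow(patients) > 0L)
  if ("fpg_mmol_l" %in% names(patients) && !("fpg" %in% names(patients))) {
    patients$fpg <- binarize_fpg(patients$fpg_mmol_l, fpg_threshold)
  }
  if ("hba1c_pct" %in% names(patients) && !("hba1c" %in% names(patients))) {
    patients$hba1c <- binarize_hba1c(patients$hba1c_pct, hba1c_threshold)
  }
  factors <- unique(coeffs$betas$factor_id)
  missing <- setdiff(factors, names(patients))
  if (length(missing) > 0L) {
    stop("patient table is missing factor column(s): ",
         paste(missing, collapse = ", "))
  }
  beta <- stats::setNames(
    coeffs$betas$beta,
    paste(coeffs$betas$factor_id, coeffs$betas$level, sep = ":")
  )
  n <- nrow(patients)
  contrib <- vapply(factors, function(f) {
    v <- beta[paste(f, as.character(patients[[f]]), sep = ":")]
    if (anyNA(v)) {
      stop("unknown level(s) for factor '", f, "': ",
           paste(unique(patients[[f]][is.na(v)]), collapse = ", "))
    }
    unname(v)
  }, numeric(n))
  contrib <- matrix(contrib, nrow = n,
                    dimnames = list(NULL, paste0("contrib_", factors)))
  logit <- coeffs$alpha + rowSums(contrib)
  probability <- probability_from_logit(logit)
  lp <- probability / coeffs$prevalence
  risk_class <- if (rule == "p_half") {
    ifelse(probability >= 0.5, "high", "low")
  } else {
    ifelse(lp > lp_cutoff, "high", "low")
  }
  cbind(
    data.frame(logit = logit, probability = probability, lp = lp,
               risk_class = risk_class, stringsAsFactors = FALSE),
    as.data.frame(contrib)
  )
}

#' Write a per-patient scoring report as JSON
#'
#' @param scored data.frame from [score_patients()].
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_score_report <- function(scored, path) {
  jsonlite::write_json(scored, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
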