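# Elastography-based grading/staging and study-eligibility screening.

#' Device and threshold constants
#'
#' Published thresholds used throughout the package. CAP steatosis grade
#' cut-offs (dB/m) and TE fibrosis stage cut-offs (kPa) are lower-bound
#' inclusive; the device ranges are those of vibration-controlled transient
#' elastography systems (liver stiffness 2.5--75 kPa, CAP 100--400 dB/m).
#'
#' @format `cap_thresholds`: named numeric (S1, S2, S3). `te_thresholds`:
#'   named numeric (F2, F3, F4). `device_range`: list with `cap` and `te`
#'   two-element numeric ranges.
#' @name staging-constants
NULL

#' @rdname staging-constants
#' @export
cap_thresholds <- c(S1 = 294, S2 = 310, S3 = 331)

#' @rdname staging-constants
#' @export
te_thresholds <- c(F2 = 8.2, F3 = 9.7, F4 = 13.6)

#' @rdname staging-constants
#' @export
device_range <- list(cap = c(100, 400), te = c(2.5, 75))

# CAP screen for steatosis presence (eligibility, not severity grading)
.CAP_STEATOSIS_SCREEN <- 248

#' Grade steatosis from CAP
#'
#' Maps CAP (dB/m) to the ordinal steatosis grade S0--S3 using lower-bound
#' inclusive cut-offs: S1 >= 294, S2 >= 310, S3 >= 331 dB/m. Grades S2--S3
#' constitute significant steatosis.
#'
#' @param cap CAP readings, dB/m, within the device range 100--400.
#' @param thresholds Named numeric of lower bounds for S1, S2, S3.
#' @return Ordered factor with levels `S0 < S1 < S2 < S3`.
#' @export
grade_steatosis <- function(cap, thresholds = cap_thresholds) {
  out_of_range <- !is.na(cap) & (cap < device_range$cap[1] | cap > device_range$cap[2])
  if (any(out_of_range))
    stop("cap outside device range [100, 400] dB/m", call. = FALSE)
  cut(cap, breaks = c(-Inf, thresholds, Inf), labels = c("S0", "S1", "S2", "S3"),
      right = FALSE, ordered_result = TRUE)
}

#' Stage fibrosis from liver stiffness
#'
#' Maps TE liver stiffness (kPa) to the ordinal fibrosis stage using
#' lower-bound inclusive cut-offs F2 >= 8.2, F3 >= 9.7, F4 >= 13.6 kPa.
#' Stages F3--F4 constitute severe fibrosis.
#'
#' @param te Liver stiffness, kPa, within the device range 2.5--75.
#' @param thresholds Named numeric of lower bounds for F2, F3, F4.
#' @return Ordered factor with levels `F0F1 < F2 < F3 < F4`.
#' @export
stage_fibrosis <- function(te, thresholds = te_thresholds) {
  out_of_range <- !is.na(te) & (te < device_range$te[1] | te > device_range$te[2])
  if (any(out_of_range))
    stop("te outside device range [2.5, 75] kPa", call. = FALSE)
  cut(te, breaks = c(-Inf, thresholds, Inf), labels = c("F0F1", "F2", "F3", "F4"),
      right = FALSE, ordered_result = TRUE)
}

#' Significant steatosis / severe fibrosis predicates
#'
#' `is_significant_steatosis` is TRUE for grades S2--S3;
#' `is_severe_fibrosis` is TRUE for stages F3--F4.
#'
#' @param grade Ordered factor from [grade_steatosis()].
#' @param stage Ordered factor from [stage_fibrosis()].
#' @return Logical vector.
#' @export
is_significant_steatosis <- function(grade) grade >= "S2"

#' @rdname is_significant_steatosis
#' @export
is_severe_fibrosis <- function(stage) stage >= "F3"

#' VCTE measurement reliability
#'
#' A liver stiffness / CAP examination is reliable when the interquartile
#' range to median ratio is below 30% and the median was computed from at
#' least 10 valid readings.
#'
#' @param iqr_over_median IQR/median ratio of the readings (>= 0).
#' @param valid_count Number of valid readings.
#' @return Logical vector.
#' @export
is_reliable_vcte <- function(iqr_over_median, valid_count) {
  .check_nonneg(iqr_over_median, "iqr_over_median")
  if (any(!is.na(valid_count) & valid_count < 0))
    stop("'valid_count' must be non-negative", call. = FALSE)
  iqr_over_median < 0.30 & valid_count >= 10
}

.opt_col <- function(cohort, name, default = NA) {
  if (is.null(cohort[[name]])) rep(default, nrow(cohort)) else cohort[[name]]
}

#' Count cardiometabolic risk factors
#'
#' Counts how many of the five consensus cardiometabolic criteria a subject
#' satisfies: (1) waist circumference >= 102 cm (men) / >= 88 cm (women);
#' (2) blood pressure >= 130/85 mmHg or antihypertensive treatment;
#' (3) triglycerides >= 150 mg/dL or lipid-lowering treatment for
#' hypertriglyceridemia; (4) HDL < 40 mg/dL (men) / < 50 mg/dL (women);
#' (5) fasting glucose 100--125 mg/dL or HbA1c >= 5.7%. Missing optional
#' fields count as criterion-not-met.
#'
#' @param cohort Data frame of subject records (see [read_cohort()]).
#' @return Integer vector in 0--5.
#' @export
count_metabolic_risk_factors <- function(cohort) {
  stopifnot(is.data.frame(cohort), !is.null(cohort$sex))
  sex <- .check_sex(cohort$sex)
  male <- sex == "male"
  met <- function(x) !is.na(x) & x   # missing -> not met

  wc  <- .opt_col(cohort, "waist_circumference", NA_real_)
  sbp <- .opt_col(cohort, "systolic_bp", NA_real_)
  dbp <- .opt_col(cohort, "diastolic_bp", NA_real_)
  tg  <- .opt_col(cohort, "tg", NA_real_)
  hdl <- .opt_col(cohort, "hdl", NA_real_)
  fbg <- .opt_col(cohort, "fbg", NA_real_)
  hba1c <- .opt_col(cohort, "hba1c", NA_real_)
  on_aht <- .opt_col(cohort, "on_antihypertensives", NA)
  on_tgt <- .opt_col(cohort, "on_tg_treatment", NA)

  c1 <- met(ifelse(male, wc >= 102, wc >= 88))
  c2 <- met(sbp >= 130) | met(dbp >= 85) | met(on_aht)
  c3 <- met(tg >= 150) | met(on_tgt)
  c4 <- met(ifelse(male, hdl < 40, hdl < 50))
  c5 <- met(fbg >= 100 & fbg <= 125) | met(hba1c >= 5.7)
  as.integer(c1) + as.integer(c2) + as.integer(c3) + as.integer(c4) + as.integer(c5)
}

#' Screen subjects into MASLD, control, or ineligible
#'
#' Applies the study-style eligibility rules. Exclusions are evaluated first:
#' alcohol intake above the toxic threshold (> 210 g/week men, > 140 g/week
#' women) and aminotransferases above five times the upper limit of normal.
#' MASLD then requires steatosis evidence (ultrasound positive and/or CAP
#' > 248 dB/m) plus at least one metabolic-dysfunction criterion (BMI >= 25,
#' type 2 diabetes, or >= 2 risk factors per
#' [count_metabolic_risk_factors()]). Controls require absence of steatosis
#' (CAP < 248 dB/m, and a negative ultrasound when available), BMI < 25, no
#' diabetes, and at most one risk factor. Subjects matching neither
#' definition -- including CAP exactly 248 dB/m, which satisfies neither the
#' strict `>` inclusion nor the strict `<` control rule -- are ineligible.
#'
#' Type 2 diabetes is inferred as fasting glucose >= 126 mg/dL or HbA1c >=
#' 6.5% (or an explicit logical `type2_diabetes` column when present);
#' isolated impaired fasting glucose (100--125 mg/dL) counts only as a risk
#' factor, not as diabetes.
#'
#' @param cohort Data frame of subject records.
#' @param uln_ast,uln_alt Upper limits of normal for AST and ALT, U/L, used
#'   by the five-fold aminotransferase exclusion.
#' @return Data frame with `subject_id`, `label` (factor: masld, control,
#'   ineligible), `reasons` (semicolon-separated rule identifiers, non-empty
#'   whenever `label == "ineligible"`), and `risk_factors`.
#' @export
classify_eligibility <- function(cohort, uln_ast = 40, uln_alt = 40) {
  stopifnot(is.data.frame(cohort))
  cohort <- .ensure_bmi(cohort)
  n <- nrow(cohort)
  sex <- .check_sex(cohort$sex)
  male <- sex == "male"

  cap <- .opt_col(cohort, "cap", NA_real_)
  us  <- .opt_col(cohort, "ultrasound_steatosis", NA)
  alcohol <- .opt_col(cohort, "alcohol_g_week", NA_real_)
  ast <- .opt_col(cohort, "ast", NA_real_)
  alt <- .opt_col(cohort, "alt", NA_real_)
  fbg <- .opt_col(cohort, "fbg", NA_real_)
  hba1c <- .opt_col(cohort, "hba1c", NA_real_)
  bmi <- cohort$bmi

  met <- function(x) !is.na(x) & x
  t2dm <- if (!is.null(cohort$type2_diabetes)) met(cohort$type2_diabetes)
          else met(fbg >= 126) | met(hba1c >= 6.5)
  rf <- count_metabolic_risk_factors(cohort)

  reasons <- vector("list", n)
  add_reason <- function(idx, tag) {
    for (i in which(idx)) reasons[[i]] <<- c(reasons[[i]], tag)
  }

  excl_alcohol <- met(ifelse(male, alcohol > 210, alcohol > 140))
  excl_amino <- met(ast > 5 * uln_ast) | met(alt > 5 * uln_alt)
  add_reason(excl_alcohol, "alcohol_toxic_dose")
  add_reason(excl_amino, "aminotransferases_gt_5x_uln")
  excluded <- excl_alcohol | excl_amino

  no_assessment <- is.na(cap) & is.na(us)
  add_reason(no_assessment & !excluded, "no_steatosis_assessment")

  steatosis_pos <- met(cap > .CAP_STEATOSIS_SCREEN) | met(us)
  steatosis_neg <- met(cap < .CAP_STEATOSIS_SCREEN) & !met(us)
  metabolic <- met(bmi >= 25) | t2dm | rf >= 2

  is_masld <- !excluded & !no_assessment & steatosis_pos & metabolic
  is_control <- !excluded & !no_assessment & !is_masld &
    steatosis_neg & met(bmi < 25) & !t2dm & rf <= 1

  label <- rep("ineligible", n)
  label[is_masld] <- "masld"
  label[is_control] <- "control"

  inel <- label == "ineligible" & !excluded & !no_assessment
  add_reason(inel & steatosis_pos & !metabolic, "steatosis_without_metabolic_dysfunction")
  add_reason(inel & !steatosis_pos & !steatosis_neg, "indeterminate_steatosis_evidence")
  add_reason(inel & steatosis_neg & !met(bmi < 25), "control_bmi_not_below_25")
  add_reason(inel & steatosis_neg & t2dm, "control_has_diabetes")
  add_reason(inel & steatosis_neg & rf > 1, "control_gt_1_risk_factor")
  still_empty <- label == "ineligible" & vapply(reasons, length, 1L) == 0
  add_reason(still_empty, "matches_no_group_definition")

  data.frame(
    subject_id = if (is.null(cohort$subject_id)) seq_len(n) else cohort$subject_id,
    label = factor(label, levels = c("masld", "control", "ineligible")),
    reasons = vapply(reasons, function(r) paste(r, collapse = ";"), ""),
    risk_factors = rf,
    stringsAsFactors = FALSE
  )
}

#' Stage a cohort: steatosis grade, fibrosis stage, reliability, eligibility
#'
#' Convenience wrapper adding `steatosis_grade`, `significant_steatosis`,
#' `fibrosis_stage`, `severe_fibrosis`, `vcte_reliable` (when IQR/median and
#' valid-count columns are present), `eligibility` and `risk_factors`
#' columns to a cohort table.
#'
#' @inheritParams classify_eligibility
#' @return The cohort with staging columns appended.
#' @export
stage_cohort <- function(cohort, uln_ast = 40, uln_alt = 40) {
  stopifnot(is.data.frame(cohort))
  out <- .ensure_bmi(cohort)
  out$steatosis_grade <- grade_steatosis(.opt_col(out, "cap", NA_real_))
  out$significant_steatosis <- is_significant_steatosis(out$steatosis_grade)
  out$fibrosis_stage <- stage_fibrosis(.opt_col(out, "te", NA_real_))
  out$severe_fibrosis <- is_severe_fibrosis(out$fibrosis_stage)
  if (!is.null(cohort$te_iqr_over_median) && !is.null(cohort$te_valid_count))
    out$vcte_reliable <- is_reliable_vcte(cohort$te_iqr_over_median,
                                          cohort$te_valid_count)
  elig <- classify_eligibility(cohort, uln_ast = uln_ast, uln_alt = uln_alt)
  out$eligibility <- elig$label
  out$risk_factors <- elig$risk_factors
  out
}
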