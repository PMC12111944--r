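# Index calculators. All functions are vectorised; NA inputs propagate to NA
# outputs, but values that are present and outside the mathematical domain
# raise an error (silent zeros are never returned).

# molar-mass based conversion factors, mg/dL per mmol/L
.TG_MGDL_PER_MMOL <- 88.57
.HDL_MGDL_PER_MMOL <- 38.67

.check_nonneg <- function(x, name) {
  if (any(!is.na(x) & x < 0))
    stop(sprintf("'%s' must be non-negative", name), call. = FALSE)
}

.check_pos <- function(x, name) {
  if (any(!is.na(x) & x <= 0))
    stop(sprintf("'%s' must be strictly positive", name), call. = FALSE)
}

.check_sex <- function(sex) {
  sex <- tolower(as.character(sex))
  bad <- !is.na(sex) & !sex %in% c("male", "female")
  if (any(bad))
    stop("'sex' must be \"male\" or \"female\"", call. = FALSE)
  sex
}

#' Convert triglycerides from mg/dL to mmol/L
#'
#' @param tg Triglycerides in mg/dL.
#' @return Triglycerides in mmol/L (divides by 88.57).
#' @export
tg_mgdl_to_mmol <- function(tg) {
  .check_nonneg(tg, "tg")
  tg / .TG_MGDL_PER_MMOL
}

#' Convert HDL cholesterol from mg/dL to mmol/L
#'
#' @param hdl HDL cholesterol in mg/dL.
#' @return HDL in mmol/L (divides by 38.67).
#' @export
hdl_mgdl_to_mmol <- function(hdl) {
  .check_nonneg(hdl, "hdl")
  hdl / .HDL_MGDL_PER_MMOL
}

#' Triglyceride-glucose (TyG) index
#'
#' TyG = log(fasting glucose \[mg/dL\] x triglycerides \[mg/dL\] / 2).
#' Published cut-offs for TyG vary widely because sources differ in the
#' logarithm base; the base is therefore an explicit argument. The natural
#' logarithm is the default, matching the usual printed formula; rank-based
#' statistics (Spearman correlations, ROC curves, AUROC) are identical under
#' either base because the two scales differ by the positive factor ln(10).
#'
#' @param fbg Fasting blood glucose, mg/dL.
#' @param tg Triglycerides, mg/dL.
#' @param log_base `"natural"` (default) or `"decimal"`.
#' @return The TyG index (dimensionless).
#' @export
compute_tyg <- function(fbg, tg, log_base = c("natural", "decimal")) {
  log_base <- match.arg(log_base)
  .check_pos(fbg, "fbg")
  .check_pos(tg, "tg")
  x <- fbg * tg / 2
  if (log_base == "natural") log(x) else log10(x)
}

#' Visceral adiposity index (VAI)
#'
#' Sex-specific composite of waist circumference, BMI, triglycerides and HDL:
#' \deqn{VAI_{male} = \frac{WC}{39.68 + 1.88\,BMI} \cdot \frac{TG}{1.03}
#'       \cdot \frac{1.31}{HDL}}
#' \deqn{VAI_{female} = \frac{WC}{36.58 + 1.89\,BMI} \cdot \frac{TG}{0.81}
#'       \cdot \frac{1.52}{HDL}}
#' TG and HDL must be supplied in mmol/L (see [tg_mgdl_to_mmol()],
#' [hdl_mgdl_to_mmol()]). At the sex-specific anchor values every factor is 1
#' and the index equals 1 exactly.
#'
#' @param sex `"male"` or `"female"` (vectorised).
#' @param wc Waist circumference, cm.
#' @param bmi Body mass index, kg/m^2.
#' @param tg Triglycerides, mmol/L.
#' @param hdl HDL cholesterol, mmol/L.
#' @return VAI (dimensionless, > 0).
#' @export
compute_vai <- function(sex, wc, bmi, tg, hdl) {
  sex <- .check_sex(sex)
  .check_pos(wc, "wc"); .check_pos(bmi, "bmi")
  .check_pos(tg, "tg"); .check_pos(hdl, "hdl")
  male <- sex == "male"
  denom <- ifelse(male, 39.68 + 1.88 * bmi, 36.58 + 1.89 * bmi)
  tg_ref <- ifelse(male, 1.03, 0.81)
  hdl_ref <- ifelse(male, 1.31, 1.52)
  (wc / denom) * (tg / tg_ref) * (hdl_ref / hdl)
}

#' Lipid accumulation product (LAP)
#'
#' LAP = (WC - 65) x TG for men and (WC - 58) x TG for women, with WC in cm
#' and TG in mmol/L. A waist circumference below the sex anchor gives a
#' non-positive value; this is mathematically valid and returned as-is with
#' a warning, since it signals an input outside the index's intended range.
#'
#' @inheritParams compute_vai
#' @return LAP in cm x mmol/L.
#' @export
compute_lap <- function(sex, wc, tg) {
  sex <- .check_sex(sex)
  .check_pos(wc, "wc"); .check_pos(tg, "tg")
  anchor <- ifelse(sex == "male", 65, 58)
  out <- (wc - anchor) * tg
  if (any(!is.na(out) & out <= 0))
    warning("LAP <= 0 for some subjects (waist circumference at or below the sex anchor)",
            call. = FALSE)
  out
}

#' NAFLD fibrosis score (NFS)
#'
#' Linear score: -1.675 + 0.037 age + 0.094 BMI + 1.13 (IFG or diabetes)
#' + 0.99 AST/ALT - 0.013 platelets - 0.66 albumin. Albumin is in g/dL,
#' platelets in 10^9/L.
#'
#' @param age Age, years.
#' @param bmi Body mass index, kg/m^2.
#' @param diabetes_or_ifg Logical: impaired fasting glucose or diabetes.
#' @param ast,alt Aminotransferases, U/L.
#' @param platelets Platelet count, 10^9/L.
#' @param albumin Serum albumin, g/dL.
#' @return NFS (dimensionless).
#' @export
compute_nfs <- function(age, bmi, diabetes_or_ifg, ast, alt, platelets, albumin) {
  .check_pos(age, "age"); .check_pos(bmi, "bmi")
  .check_pos(ast, "ast"); .check_pos(alt, "alt")
  .check_pos(platelets, "platelets"); .check_pos(albumin, "albumin")
  -1.675 + 0.037 * age + 0.094 * bmi + 1.13 * as.numeric(diabetes_or_ifg) +
    0.99 * ast / alt - 0.013 * platelets - 0.66 * albumin
}

#' FIB-4 index
#'
#' FIB-4 = age x AST / (platelets x sqrt(ALT)).
#'
#' @inheritParams compute_nfs
#' @return FIB-4 (dimensionless, > 0).
#' @export
compute_fib4 <- function(age, ast, alt, platelets) {
  .check_pos(age, "age"); .check_pos(ast, "ast")
  .check_pos(alt, "alt"); .check_pos(platelets, "platelets")
  age * ast / (platelets * sqrt(alt))
}

# Fill bmi from height/weight when absent; checks consistency when all three
# are present.
.ensure_bmi <- function(cohort) {
  if (is.null(cohort$bmi)) cohort$bmi <- NA_real_
  if (!is.null(cohort$height) && !is.null(cohort$weight)) {
    derived <- cohort$weight / (cohort$height / 100)^2
    fill <- is.na(cohort$bmi) & !is.na(derived)
    cohort$bmi[fill] <- derived[fill]
    both <- !is.na(cohort$bmi) & !is.na(derived)
    if (any(abs(cohort$bmi[both] - derived[both]) > 0.1))
      warning("supplied bmi disagrees with weight/(height/100)^2 by more than 0.1 kg/m^2",
              call. = FALSE)
  }
  cohort
}

.panel_inputs <- list(
  tyg  = c("fbg", "tg"),
  vai  = c("sex", "waist_circumference", "bmi", "tg", "hdl"),
  lap  = c("sex", "waist_circumference", "tg"),
  nfs  = c("age", "bmi", "diabetes_or_ifg", "ast", "alt", "platelets", "albumin"),
  fib4 = c("age", "ast", "alt", "platelets")
)

#' Compute the five-index panel for a cohort
#'
#' Applies [compute_tyg()], [compute_vai()], [compute_lap()],
#' [compute_nfs()] and [compute_fib4()] row-wise, converting TG and HDL from
#' mg/dL to mmol/L where the formula requires molar units. An index is `NA`
#' for a subject whenever any of its inputs is missing; no imputation is
#' performed. BMI is derived from height and weight when absent.
#'
#' @param cohort Data frame of subject records; see [read_cohort()] for the
#'   column dictionary (labs in mg/dL, waist circumference in cm).
#' @param tyg_base Log base for TyG, `"natural"` or `"decimal"`.
#' @return Data frame with columns `subject_id`, `tyg`, `vai`, `lap`, `nfs`,
#'   `fib4`; the TyG base used is recorded in attribute `tyg_log_base`.
#' @export
compute_panel <- function(cohort, tyg_base = c("natural", "decimal")) {
  tyg_base <- match.arg(tyg_base)
  stopifnot(is.data.frame(cohort))
  cohort <- .ensure_bmi(cohort)
  n <- nrow(cohort)
  col <- function(name) if (is.null(cohort[[name]])) rep(NA, n) else cohort[[name]]

  ok_rows <- function(fields) {
    ok <- rep(TRUE, n)
    for (f in fields) ok <- ok & !is.na(col(f))
    ok
  }
  panel <- data.frame(
    subject_id = if (is.null(cohort$subject_id)) seq_len(n) else cohort$subject_id,
    tyg = NA_real_, vai = NA_real_, lap = NA_real_,
    nfs = NA_real_, fib4 = NA_real_
  )

  ok <- ok_rows(.panel_inputs$tyg)
  panel$tyg[ok] <- compute_tyg(col("fbg")[ok], col("tg")[ok], tyg_base)

  ok <- ok_rows(.panel_inputs$vai)
  panel$vai[ok] <- compute_vai(col("sex")[ok], col("waist_circumference")[ok],
                               col("bmi")[ok], tg_mgdl_to_mmol(col("tg")[ok]),
                               hdl_mgdl_to_mmol(col("hdl")[ok]))

  ok <- ok_rows(.panel_inputs$lap)
  panel$lap[ok] <- suppressWarnings(
    compute_lap(col("sex")[ok], col("waist_circumference")[ok],
                tg_mgdl_to_mmol(col("tg")[ok])))

  ok <- ok_rows(.panel_inputs$nfs)
  panel$nfs[ok] <- compute_nfs(col("age")[ok], col("bmi")[ok],
                               col("diabetes_or_ifg")[ok], col("ast")[ok],
                               col("alt")[ok], col("platelets")[ok],
                               col("albumin")[ok])

  ok <- ok_rows(.panel_inputs$fib4)
  panel$fib4[ok] <- compute_fib4(col("age")[ok], col("ast")[ok],
                                 col("alt")[ok], col("platelets")[ok])

  attr(panel, "tyg_log_base") <- tyg_base
  panel
}
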