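# Cohort table I/O and report rendering.

# column dictionary: name -> list(type, required, min, max)
.cohort_schema <- list(
  subject_id = list(type = "character", required = TRUE),
  sex = list(type = "character", required = TRUE,
             values = c("male", "female")),
  age = list(type = "numeric", required = TRUE, min = 18, max = 110),
  height = list(type = "numeric", required = FALSE, min = 100, max = 230),
  weight = list(type = "numeric", required = FALSE, min = 25, max = 350),
  bmi = list(type = "numeric", required = FALSE, min = 10, max = 80),
  waist_circumference = list(type = "numeric", required = FALSE, min = 40, max = 220),
  fbg = list(type = "numeric", required = FALSE, min = 0),
  tg = list(type = "numeric", required = FALSE, min = 0),
  hdl = list(type = "numeric", required = FALSE, min = 0),
  ldl = list(type = "numeric", required = FALSE, min = 0),
  total_cholesterol = list(type = "numeric", required = FALSE, min = 0),
  ast = list(type = "numeric", required = FALSE, min = 0),
  alt = list(type = "numeric", required = FALSE, min = 0),
  ggt = list(type = "numeric", required = FALSE, min = 0),
  albumin = list(type = "numeric", required = FALSE, min = 0),
  platelets = list(type = "numeric", required = FALSE, min = 0),
  diabetes_or_ifg = list(type = "logical", required = FALSE),
  on_antihypertensives = list(type = "logical", required = FALSE),
  systolic_bp = list(type = "numeric", required = FALSE, min = 0),
  diastolic_bp = list(type = "numeric", required = FALSE, min = 0),
  on_tg_treatment = list(type = "logical", required = FALSE),
  type2_diabetes = list(type = "logical", required = FALSE),
  hba1c = list(type = "numeric", required = FALSE, min = 0),
  alcohol_g_week = list(type = "numeric", required = FALSE, min = 0),
  cap = list(type = "numeric", required = FALSE, min = 100, max = 400),
  te = list(type = "numeric", required = FALSE, min = 2.5, max = 75),
  te_iqr_over_median = list(type = "numeric", required = FALSE, min = 0),
  te_valid_count = list(type = "numeric", required = FALSE, min = 0),
  ultrasound_steatosis = list(type = "logical", required = FALSE)
)

#' Read a cohort table from delimited text
#'
#' Reads a comma-separated cohort file with a header row and validates it
#' against the package's column dictionary (`subject_id`, `sex`, `age` are
#' mandatory; labs in mg/dL, waist circumference in cm, CAP in dB/m, liver
#' stiffness in kPa). Rows violating a range constraint (e.g. negative
#' platelets, CAP outside 100--400 dB/m) are dropped with a warning naming
#' the offending lines; valid rows pass through. Unknown columns are kept
#' untouched.
#'
#' @param path Path to a CSV file.
#' @return Validated data frame; dropped row numbers (if any) are in
#'   attribute `rejected_rows`.
#' @export
read_cohort <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- names(.cohort_schema)[vapply(.cohort_schema, `[[`, TRUE, "required")]
  missing <- setdiff(required, names(raw))
  if (length(missing))
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  bad <- rep(FALSE, nrow(raw))
  msgs <- character(0)
  for (col in intersect(names(raw), names(.cohort_schema))) {
    sch <- .cohort_schema[[col]]
    x <- raw[[col]]
    if (sch$type == "numeric") {
      x <- suppressWarnings(as.numeric(x))
      lo <- if (is.null(sch$min)) -Inf else sch$min
      hi <- if (is.null(sch$max)) Inf else sch$max
      viol <- (!is.na(raw[[col]]) & is.na(x)) |
        (!is.na(x) & (x < lo | x > hi))
    } else if (sch$type == "logical") {
      x <- as.logical(x)
      viol <- !is.na(raw[[col]]) & is.na(x)
    } else {
      x <- as.character(x)
      viol <- if (!is.null(sch$values)) !is.na(x) & !tolower(x) %in% sch$values
              else rep(FALSE, length(x))
    }
    raw[[col]] <- x
    if (any(viol)) {
      msgs <- c(msgs, sprintf("%s: line(s) %s", col,
                              paste(which(viol) + 1L, collapse = ",")))
      bad <- bad | viol
    }
  }
  if (any(bad))
    warning(sprintf("dropped %d row(s) failing validation (%s)", sum(bad),
                    paste(msgs, collapse = "; ")), call. = FALSE)
  out <- raw[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected_rows") <- which(bad)
  out
}

#' Write a cohort table as delimited text
#'
#' Inverse of [read_cohort()]: writes the cohort as a comma-separated file
#' with a header row, so that `read_cohort(write_cohort(x, f))` returns
#' the same table.
#'
#' @param cohort Data frame of subject records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(is.data.frame(cohort))
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}

#' One-decimal percentage (round half up)
#'
#' Formats a 0--100 percentage to one decimal, rounding halves upward
#' (so 86.25 -> "86.3"); trailing ".0" is kept to make the precision
#' explicit. Used for all rendered report percentages.
#'
#' @param x Percentages on the 0--100 scale.
#' @return Character vector.
#' @export
format_pct <- function(x) {
  ifelse(is.na(x), "NA",
         sprintf("%.1f%%", floor(x * 10 + 0.5) / 10))
}

#' Render a cascade classification report
#'
#' Produces a human-readable (markdown) rendering of a
#' [evaluate_cascade()] report: the stage-1 rule-out / grey / rule-in
#' partition, per-cell correctness against the elastography reference,
#' stage-2 reclassification, and the headline reduction in unclassified
#' subjects. Percentages are printed to one decimal (half-up). With
#' `format = "json"` the raw (unrounded) numbers are serialised instead.
#'
#' @param report A `cascade_report` from [evaluate_cascade()].
#' @param format `"markdown"` (default) or `"json"`.
#' @return Character vector of lines (markdown) or a JSON string.
#' @export
render_report <- function(report, format = c("markdown", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(report, "cascade_report"))
  if (format == "json")
    return(jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA))
  r <- report
  frac <- function(k, d) sprintf("%d/%d (%s)", k, d, format_pct(100 * k / max(d, 1)))
  lines <- c(
    "# Severe-fibrosis cascade classification",
    "",
    sprintf("Subjects analysed: n = %d%s", r$n_total,
            if (r$n_total == 0) "  [EMPTY COHORT]" else ""),
    "",
    "| | Absence of F3-F4 | Unclassified subjects | Presence of F3-F4 |",
    "|---|---|---|---|",
    sprintf("| Stage 1 (NFS + FIB-4) | %s | %s | %s |",
            frac(r$n_stage1_ruled_out, r$n_total),
            frac(r$n_grey, r$n_total),
            frac(r$n_stage1_ruled_in, r$n_total)),
    sprintf("| Correct vs TE reference | %s | | %s |",
            frac(r$n_stage1_ruled_out_correct, r$n_stage1_ruled_out),
            frac(r$n_stage1_ruled_in_correct, r$n_stage1_ruled_in)),
    sprintf("| Stage 2 (TyG + VAI) | | %s additionally classified, %s correct | |",
            frac(r$n_stage2_classified, r$n_grey),
            frac(r$n_stage2_correct, r$n_stage2_classified)),
    "",
    sprintf("Unclassified subjects: %s before stage 2, %s after.",
            format_pct(r$pct_unclassified_before),
            format_pct(r$pct_unclassified_after))
  )
  lines
}
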