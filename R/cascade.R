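# Two-stage sequential classifier for severe fibrosis (F3-F4):
# stage 1 = NFS + FIB-4 published rule-in/rule-out cut-offs;
# stage 2 = TyG + VAI cut-offs, applied only to stage-1 grey-zone subjects.

#' Default cut-off sets for the fibrosis cascade
#'
#' Published rule-in/rule-out cut-offs for NFS (> 0.676 / <= -1.455) and
#' FIB-4 (> 2.67 / <= 1.3), and the severe-fibrosis TyG and VAI cut-offs
#' used at stage 2 (optimal 4.80 / 4.76; rule-in 5.61 / 6.21; rule-out
#' 2.65 / 1.67). Every threshold can be overridden by supplying a modified
#' copy of this list.
#'
#' @return Named list with one entry per score (`nfs`, `fib4`, `tyg`,
#'   `vai`), each a list with `rule_in`, `rule_out` and optionally
#'   `optimal` thresholds.
#' @export
default_cutoffs <- function() {
  list(
    nfs  = list(rule_in = 0.676, rule_out = -1.455),
    fib4 = list(rule_in = 2.67,  rule_out = 1.3),
    tyg  = list(optimal = 4.80, rule_in = 5.61, rule_out = 2.65),
    vai  = list(optimal = 4.76, rule_in = 6.21, rule_out = 1.67)
  )
}

#' Stage-1 classification by NFS and FIB-4
#'
#' A subject is ruled out for severe fibrosis when NFS <= rule-out AND
#' FIB-4 <= rule-out, ruled in when NFS > rule-in AND FIB-4 > rule-in,
#' and grey otherwise. Rule-out comparisons are inclusive (`<=`), rule-in
#' strict (`>`). A missing score yields `grey` with a warning.
#'
#' @param nfs,fib4 Score vectors.
#' @param cutoffs Cut-off list as from [default_cutoffs()].
#' @return Factor with levels `ruled_out`, `grey`, `ruled_in`.
#' @export
stage1_classify <- function(nfs, fib4, cutoffs = default_cutoffs()) {
  if (any(is.na(nfs) | is.na(fib4)))
    warning("missing NFS or FIB-4; affected subjects classified as grey",
            call. = FALSE)
  out_ <- !is.na(nfs) & !is.na(fib4) &
    nfs <= cutoffs$nfs$rule_out & fib4 <= cutoffs$fib4$rule_out
  in_ <- !is.na(nfs) & !is.na(fib4) &
    nfs > cutoffs$nfs$rule_in & fib4 > cutoffs$fib4$rule_in
  factor(ifelse(out_, "ruled_out", ifelse(in_, "ruled_in", "grey")),
         levels = c("ruled_out", "grey", "ruled_in"))
}

#' Stage-2 classification by TyG and VAI
#'
#' Applied to stage-1 grey-zone subjects. Under the default `combination =
#' "both"` rule (mirroring the AND logic of stage 1), a subject is ruled in
#' when both TyG and VAI exceed their rule-in cut-offs, and ruled out when
#' both are at or below their rule-out cut-offs. Under `"either"`, one score
#' suffices, but conflicting signals (one score ruling in while the other
#' rules out) always yield `unclassified`.
#'
#' @param tyg,vai Score vectors.
#' @param cutoffs Cut-off list as from [default_cutoffs()].
#' @param combination `"both"` (default) or `"either"`.
#' @return Factor with levels `ruled_out`, `unclassified`, `ruled_in`.
#' @export
stage2_classify <- function(tyg, vai, cutoffs = default_cutoffs(),
                            combination = c("both", "either")) {
  combination <- match.arg(combination)
  tyg_in <- !is.na(tyg) & tyg > cutoffs$tyg$rule_in
  vai_in <- !is.na(vai) & vai > cutoffs$vai$rule_in
  tyg_out <- !is.na(tyg) & tyg <= cutoffs$tyg$rule_out
  vai_out <- !is.na(vai) & vai <= cutoffs$vai$rule_out
  if (combination == "both") {
    in_ <- tyg_in & vai_in
    out_ <- tyg_out & vai_out
  } else {
    in_ <- tyg_in | vai_in
    out_ <- tyg_out | vai_out
  }
  conflict <- (tyg_in & vai_out) | (tyg_out & vai_in)
  in_[conflict] <- FALSE
  out_[conflict] <- FALSE
  factor(ifelse(out_, "ruled_out", ifelse(in_, "ruled_in", "unclassified")),
         levels = c("ruled_out", "unclassified", "ruled_in"))
}

#' Run the two-stage fibrosis cascade on an index panel
#'
#' Stage 1 labels every subject by NFS and FIB-4; stage 2 re-examines only
#' the stage-1 grey zone using TyG and VAI. Stage 2 never relabels a subject
#' already classified at stage 1 (monotone refinement).
#'
#' @param panel Data frame from [compute_panel()] (needs `subject_id`,
#'   `nfs`, `fib4`, `tyg`, `vai`).
#' @param cutoffs Cut-off list as from [default_cutoffs()].
#' @param combination Stage-2 combination rule, see [stage2_classify()].
#' @return Data frame with `subject_id`, `label` (`ruled_out`,
#'   `unclassified`, `ruled_in`), `stage` (1, 2 or NA for never-classified),
#'   and `inputs_used`.
#' @export
run_cascade <- function(panel, cutoffs = default_cutoffs(),
                        combination = c("both", "either")) {
  combination <- match.arg(combination)
  stopifnot(is.data.frame(panel))
  n <- nrow(panel)
  if (n == 0)
    return(data.frame(subject_id = character(0),
                      label = factor(character(0),
                                     levels = c("ruled_out", "unclassified", "ruled_in")),
                      stage = integer(0), inputs_used = character(0),
                      stringsAsFactors = FALSE))
  s1 <- stage1_classify(panel$nfs, panel$fib4, cutoffs)
  label <- as.character(s1)
  label[label == "grey"] <- "unclassified"
  stage <- ifelse(s1 == "grey", NA_integer_, 1L)
  inputs <- ifelse(s1 == "grey", "", "nfs+fib4")

  grey <- which(s1 == "grey")
  if (length(grey)) {
    s2 <- stage2_classify(panel$tyg[grey], panel$vai[grey], cutoffs, combination)
    classified2 <- s2 != "unclassified"
    label[grey] <- as.character(s2)
    stage[grey][classified2] <- 2L
    inputs[grey] <- "tyg+vai"
  }
  data.frame(subject_id = panel$subject_id,
             label = factor(label, levels = c("ruled_out", "unclassified", "ruled_in")),
             stage = stage, inputs_used = inputs, stringsAsFactors = FALSE)
}

#' Evaluate cascade labels against an elastography reference
#'
#' Correctness is judged against TE-based staging: a rule-out is correct
#' when the reference stage is not severe (below F3), a rule-in is correct
#' when the reference is severe (F3--F4). Stage-2 correct counts pool
#' rule-ins and rule-outs.
#'
#' @param results Data frame from [run_cascade()].
#' @param reference Data frame with `subject_id` and `fibrosis_stage`
#'   (ordered factor from [stage_fibrosis()]) or logical `severe_fibrosis`.
#' @return Object of class `cascade_report`: a list of counts and
#'   percentages (percentages on the 0--100 scale, unrounded; see
#'   [render_report()] for one-decimal formatting).
#' @export
evaluate_cascade <- function(results, reference) {
  stopifnot(is.data.frame(results), is.data.frame(reference))
  m <- match(results$subject_id, reference$subject_id)
  if (any(is.na(m)))
    stop("no reference stage for subject(s): ",
         paste(utils::head(results$subject_id[is.na(m)], 5), collapse = ", "),
         call. = FALSE)
  severe <- if (!is.null(reference$severe_fibrosis)) reference$severe_fibrosis[m]
            else is_severe_fibrosis(reference$fibrosis_stage[m])
  if (any(is.na(severe) & results$label != "unclassified"))
    stop("classified subject(s) lack a reference fibrosis stage", call. = FALSE)

  n <- nrow(results)
  s1_out <- results$label == "ruled_out" & results$stage %in% 1L
  s1_in  <- results$label == "ruled_in" & results$stage %in% 1L
  grey   <- is.na(results$stage) | results$stage == 2L
  s2_out <- results$label == "ruled_out" & results$stage %in% 2L
  s2_in  <- results$label == "ruled_in" & results$stage %in% 2L
  uncl_after <- results$label == "unclassified"

  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  report <- list(
    n_total = n,
    n_stage1_ruled_out = sum(s1_out),
    n_stage1_ruled_in = sum(s1_in),
    n_grey = sum(grey),
    n_stage2_classified = sum(s2_out | s2_in),
    n_stage1_ruled_out_correct = sum(s1_out & !severe),
    n_stage1_ruled_in_correct = sum(s1_in & severe),
    n_stage2_correct = sum((s2_out & !severe) | (s2_in & severe)),
    n_unclassified_after = sum(uncl_after),
    pct_stage1_ruled_out = pct(sum(s1_out), n),
    pct_stage1_ruled_in = pct(sum(s1_in), n),
    pct_grey = pct(sum(grey), n),
    pct_stage1_ruled_out_correct = pct(sum(s1_out & !severe), sum(s1_out)),
    pct_stage1_ruled_in_correct = pct(sum(s1_in & severe), sum(s1_in)),
    pct_stage2_classified = pct(sum(s2_out | s2_in), sum(grey)),
    pct_stage2_correct = pct(sum((s2_out & !severe) | (s2_in & severe)),
                             sum(s2_out | s2_in)),
    pct_unclassified_before = pct(sum(grey), n),
    pct_unclassified_after = pct(sum(uncl_after), n)
  )
  class(report) <- "cascade_report"
  report
}

#' @export
print.cascade_report <- function(x, ...) {
  cat(render_report(x), sep = "\n")
  invisible(x)
}

#' Deterministic example cohort for the fibrosis cascade
#'
#' Constructs, by design, a 114-subject panel-plus-reference table on which
#' the two-stage cascade gives 51 stage-1 rule-outs (44 of them with a
#' non-severe TE reference), 21 stage-1 rule-ins (17 severe), and a
#' 42-subject grey zone of which stage 2 classifies 12 (9 correctly: 4 of 5
#' rule-outs, 5 of 7 rule-ins). Useful for demonstrating
#' [run_cascade()] / [evaluate_cascade()] and as a fixed regression anchor.
#'
#' @return List with `panel` (scores) and `reference` (`subject_id`,
#'   `severe_fibrosis`).
#' @export
example_cascade_cohort <- function() {
  block <- function(n, nfs, fib4, tyg, vai, severe) {
    if (n == 0) return(NULL)
    data.frame(nfs = rep(nfs, n), fib4 = rep(fib4, n),
               tyg = rep(tyg, n), vai = rep(vai, n),
               severe = rep(severe, n))
  }
  rows <- rbind(
    # stage-1 rule-outs: 44 truly non-severe, 7 severe (misclassified)
    block(44, -2.0, 1.0, 4.0, 3.0, FALSE),
    block(7,  -2.0, 1.0, 4.0, 3.0, TRUE),
    # stage-1 rule-ins: 17 severe, 4 non-severe
    block(17, 1.0, 3.0, 5.0, 5.0, TRUE),
    block(4,  1.0, 3.0, 5.0, 5.0, FALSE),
    # grey zone, stage-2 rule-outs: 4 correct, 1 not
    block(4, 0.0, 2.0, 2.0, 1.0, FALSE),
    block(1, 0.0, 2.0, 2.0, 1.0, TRUE),
    # grey zone, stage-2 rule-ins: 5 correct, 2 not
    block(5, 0.0, 2.0, 6.0, 7.0, TRUE),
    block(2, 0.0, 2.0, 6.0, 7.0, FALSE),
    # grey zone, unresolved by stage 2
    block(18, 0.0, 2.0, 4.0, 3.0, FALSE),
    block(12, 0.0, 2.0, 4.0, 3.0, TRUE)
  )
  ids <- sprintf("EX%03d", seq_len(nrow(rows)))
  list(
    panel = data.frame(subject_id = ids, tyg = rows$tyg, vai = rows$vai,
                       nfs = rows$nfs, fib4 = rows$fib4,
                       stringsAsFactors = FALSE),
    reference = data.frame(subject_id = ids, severe_fibrosis = rows$severe,
                           stringsAsFactors = FALSE)
  )
}
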