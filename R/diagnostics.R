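# ROC construction, AUC comparison, cut-off selection, diagnostic
# performance with confidence intervals, correlation/group statistics, and
# backward-stepwise logistic modelling.
#
# Convention used throughout: a positive call is score >= threshold (higher
# scores indicate disease).

.check_labels <- function(labels) {
  labels <- as.logical(labels)
  if (any(is.na(labels))) stop("labels must not contain NA", call. = FALSE)
  if (!any(labels) || all(labels))
    stop("need at least one positive and one negative label", call. = FALSE)
  labels
}

#' Empirical ROC curve
#'
#' Builds the empirical ROC curve of a score against a binary reference.
#' Candidate thresholds are the unique observed score values plus an
#' always-negative sentinel above the maximum; at threshold t, sensitivity
#' is the fraction of positives with score >= t and specificity the
#' fraction of negatives with score < t. The AUC is the Mann-Whitney
#' concordance probability with ties counted 1/2 (midrank estimator).
#'
#' @param scores Numeric score vector (higher = more likely positive).
#' @param labels Logical (or 0/1) reference labels.
#' @return Object of class `hep_roc`: list with `thresholds`, `se`, `sp`,
#'   `auc`, `n_pos`, `n_neg`, and the original `scores`/`labels`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- .check_labels(labels)
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  if (any(is.na(scores))) stop("scores must not contain NA", call. = FALSE)
  thr <- c(sort(unique(scores)), Inf)
  pos <- scores[labels]; neg <- scores[!labels]
  se <- vapply(thr, function(t) mean(pos >= t), 0)
  sp <- vapply(thr, function(t) mean(neg < t), 0)
  r <- rank(scores)   # midranks handle ties as 1/2
  auc <- (sum(r[labels]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
  structure(list(thresholds = thr, se = se, sp = sp, auc = auc,
                 n_pos = length(pos), n_neg = length(neg),
                 scores = scores, labels = labels),
            class = "hep_roc")
}

#' @export
print.hep_roc <- function(x, ...) {
  cat(sprintf("Empirical ROC curve: %d positives, %d negatives, AUC = %.4f\n",
              x$n_pos, x$n_neg, x$auc))
  invisible(x)
}

# DeLong structural components: V10 (per positive) and V01 (per negative)
.delong_components <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  psi <- outer(pos, neg, function(x, y) (x > y) + 0.5 * (x == y))
  list(v10 = rowMeans(psi), v01 = colMeans(psi), auc = mean(psi))
}

#' Paired comparison of two AUCs (DeLong)
#'
#' Two-sided test of equality of the AUCs of two scores measured on the
#' same subjects, using the DeLong covariance construction for paired
#' empirical AUCs.
#'
#' @param scores_a,scores_b Paired score vectors.
#' @param labels Logical reference labels shared by both scores.
#' @return List with `auc_a`, `auc_b`, `delta`, `z` and `p_value`.
#' @export
compare_auc <- function(scores_a, scores_b, labels) {
  labels <- .check_labels(labels)
  if (length(scores_a) != length(labels) || length(scores_b) != length(labels))
    stop("scores_a, scores_b and labels must have equal length", call. = FALSE)
  ca <- .delong_components(scores_a, labels)
  cb <- .delong_components(scores_b, labels)
  m <- sum(labels); n <- sum(!labels)
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  var_delta <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  delta <- ca$auc - cb$auc
  if (var_delta <= .Machine$double.eps) {
    z <- 0; p <- 1
  } else {
    z <- delta / sqrt(var_delta)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(auc_a = ca$auc, auc_b = cb$auc, delta = delta, z = z, p_value = p)
}

#' Optimal (Youden) cut-off
#'
#' Threshold maximising sensitivity + specificity; ties are broken toward
#' the lower threshold.
#'
#' @param roc Object from [roc_curve()].
#' @return List with `threshold` and the [performance_at()] assessment at
#'   that threshold.
#' @export
optimal_cutoff <- function(roc) {
  stopifnot(inherits(roc, "hep_roc"))
  j <- roc$se + roc$sp
  best <- which(j == max(j))[1]   # thresholds sorted ascending -> lowest wins
  thr <- roc$thresholds[best]
  list(threshold = thr,
       performance = performance_at(roc$scores, roc$labels, thr))
}

#' Rule-in and rule-out cut-offs under performance floors
#'
#' The rule-out cut-off maximises specificity among thresholds whose
#' sensitivity is at least `se_floor` (so a negative call confidently
#' excludes disease); the rule-in cut-off maximises sensitivity among
#' thresholds whose specificity is at least `sp_floor`. Ties are broken
#' toward the lower threshold. Degenerate thresholds whose optimised
#' quantity is zero (a rule-out that excludes nobody, a rule-in that calls
#' nobody) are never returned: when no informative threshold satisfies a
#' floor the corresponding cut-off is `NA`.
#'
#' @param roc Object from [roc_curve()].
#' @param se_floor Minimum sensitivity for the rule-out scan (default 0.80).
#' @param sp_floor Minimum specificity for the rule-in scan (default 0.74).
#' @return List with `rule_out` and `rule_in`, each a threshold +
#'   performance pair (threshold `NA` when infeasible).
#' @export
rule_cutoffs <- function(roc, se_floor = 0.80, sp_floor = 0.74) {
  stopifnot(inherits(roc, "hep_roc"), se_floor > 0, se_floor < 1,
            sp_floor > 0, sp_floor < 1)
  pick <- function(feasible, objective) {
    feasible <- feasible & objective > 0
    if (!any(feasible)) return(NA_real_)
    obj <- ifelse(feasible, objective, -Inf)
    roc$thresholds[which(obj == max(obj))[1]]
  }
  t_out <- pick(roc$se >= se_floor, roc$sp)
  t_in <- pick(roc$sp >= sp_floor, roc$se)
  wrap <- function(t) {
    if (is.na(t)) list(threshold = NA_real_, performance = NULL)
    else list(threshold = t, performance = performance_at(roc$scores, roc$labels, t))
  }
  list(rule_out = wrap(t_out), rule_in = wrap(t_in))
}

# Wilson score interval for a binomial proportion
.wilson <- function(k, n, conf = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  c(max(0, centre - half), min(1, centre + half))
}

#' Diagnostic performance at a fixed threshold
#'
#' Confusion-matrix summary with a positive call defined as score >=
#' threshold: sensitivity, specificity, PPV, NPV and accuracy, each with a
#' 95% Wilson confidence interval. A ratio with zero denominator (e.g. PPV
#' when nothing is called positive) is `NA`, never 0.
#'
#' @param scores Numeric scores.
#' @param labels Logical reference labels.
#' @param threshold Decision threshold.
#' @return Data frame with one row per measure (`se`, `sp`, `ppv`, `npv`,
#'   `accuracy`): `estimate`, `ci_low`, `ci_high`, `numerator`,
#'   `denominator`; the threshold is attached as attribute `threshold`.
#' @export
performance_at <- function(scores, labels, threshold) {
  labels <- .check_labels(labels)
  call_pos <- scores >= threshold
  tp <- sum(call_pos & labels); fn <- sum(!call_pos & labels)
  tn <- sum(!call_pos & !labels); fp <- sum(call_pos & !labels)
  row <- function(k, n) {
    if (n == 0) return(c(NA_real_, NA_real_, NA_real_, k, n))
    ci <- .wilson(k, n)
    c(k / n, ci[1], ci[2], k, n)
  }
  out <- rbind(se = row(tp, tp + fn), sp = row(tn, tn + fp),
               ppv = row(tp, tp + fp), npv = row(tn, tn + fn),
               accuracy = row(tp + tn, tp + fn + tn + fp))
  out <- data.frame(measure = rownames(out), estimate = out[, 1],
                    ci_low = out[, 2], ci_high = out[, 3],
                    numerator = out[, 4], denominator = out[, 5],
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "threshold") <- threshold
  out
}

#' Spearman correlation with Fisher-transform confidence interval
#'
#' Rank correlation using average ranks for ties; the confidence interval
#' is tanh(atanh(rho) +/- z / sqrt(n - 3)) and the p-value is the usual
#' large-sample test from [stats::cor.test()].
#'
#' @param x,y Paired numeric vectors, n >= 4.
#' @param conf Confidence level (default 0.95).
#' @return List with `rho`, `ci_low`, `ci_high`, `p_value`, `n`.
#' @export
spearman_ci <- function(x, y, conf = 0.95) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete pairs", call. = FALSE)
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    stop("constant vector: Spearman correlation undefined", call. = FALSE)
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman", exact = FALSE))
  rho <- unname(ct$estimate)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  fz <- atanh(min(max(rho, -1 + 1e-15), 1 - 1e-15))
  half <- z / sqrt(n - 3)
  list(rho = rho, ci_low = tanh(fz - half), ci_high = tanh(fz + half),
       p_value = ct$p.value, n = n)
}

#' Two-group comparison with distribution-based test routing
#'
#' Categorical variables (factor or logical) are compared with Pearson's
#' chi-squared test. Numeric variables are first checked for normality in
#' each group with a Kolmogorov-Smirnov test against a normal distribution
#' with the group's moments; if both groups are compatible with normality
#' (p > 0.05) Student's t-test is used, otherwise the Mann-Whitney U-test.
#'
#' @param values Numeric vector, or factor/logical for categorical data.
#' @param groups Two-level grouping vector.
#' @param normality_alpha Significance level of the KS normality gate.
#' @return List with `statistic`, `p_value`, `test_used`.
#' @export
group_compare <- function(values, groups, normality_alpha = 0.05) {
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop("exactly two groups required", call. = FALSE)
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- droplevels(groups[keep])
  if (nlevels(groups) != 2 || any(table(groups) < 3))
    stop("each group needs at least 3 observations", call. = FALSE)

  if (is.factor(values) || is.logical(values) || is.character(values)) {
    tab <- table(values, groups)
    ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    return(list(statistic = unname(ht$statistic), p_value = ht$p.value,
                test_used = "chi_squared"))
  }
  normal_in <- function(v) {
    if (stats::sd(v) == 0) return(FALSE)
    p <- suppressWarnings(stats::ks.test(v, "pnorm", mean(v), stats::sd(v)))$p.value
    p > normality_alpha
  }
  both_normal <- all(vapply(split(values, groups), normal_in, TRUE))
  if (both_normal) {
    ht <- stats::t.test(values ~ groups, var.equal = TRUE)
    list(statistic = unname(ht$statistic), p_value = ht$p.value,
         test_used = "t_test")
  } else {
    ht <- suppressWarnings(stats::wilcox.test(values ~ groups))
    list(statistic = unname(ht$statistic), p_value = ht$p.value,
         test_used = "mann_whitney")
  }
}

#' Backward-stepwise logistic regression
#'
#' Starts from the full logistic model and iteratively removes the
#' predictor with the largest Wald p-value above `p_remove` (default 0.10),
#' accepting each removal only while the model AIC does not worsen beyond
#' the usual two-unit indistinguishability band (a removal sanctioned by
#' the p-rule raises AIC by at most 2 - qchisq(1 - p_remove, 1) < 2, so
#' the band makes the p-rule decisive while still stopping on gross
#' deterioration, e.g. under collinearity).
#' Reported effect sizes are odds ratios exp(beta) with Wald confidence
#' intervals. Suspected perfect separation (diverging coefficients) is
#' flagged with a warning and the current model returned.
#'
#' @param outcome Logical (or 0/1) outcome vector.
#' @param predictors Data frame of candidate predictor columns.
#' @param p_remove Wald p-value above which a predictor is eligible for
#'   removal (default 0.10).
#' @param conf Confidence level for the odds-ratio intervals.
#' @return List with the final `model` (a `glm`), `selected` predictor
#'   names, `dropped` names in removal order, and a `coefficients` data
#'   frame (`term`, `beta`, `se`, `p_value`, `or`, `or_low`, `or_high`).
#' @export
stepwise_logistic <- function(outcome, predictors, p_remove = 0.10, conf = 0.95) {
  stopifnot(is.data.frame(predictors), ncol(predictors) >= 1)
  outcome <- as.logical(outcome)
  if (any(is.na(outcome)) || any(!stats::complete.cases(predictors)))
    stop("missing values in outcome or predictors", call. = FALSE)
  if (nrow(predictors) <= 10 * ncol(predictors))
    warning("fewer than 10 observations per candidate predictor", call. = FALSE)
  constant <- vapply(predictors, function(v) length(unique(v)) < 2, TRUE)
  if (any(constant))
    stop("constant predictor(s): ", paste(names(predictors)[constant], collapse = ", "),
         call. = FALSE)

  dat <- cbind(.outcome = outcome, predictors)
  fit_with <- function(vars) {
    fml <- if (length(vars)) stats::reformulate(vars, response = ".outcome")
           else .outcome ~ 1
    suppressWarnings(stats::glm(fml, family = stats::binomial(), data = dat))
  }
  vars <- names(predictors)
  fit <- fit_with(vars)
  dropped <- character(0)
  repeat {
    if (!length(vars)) break
    sm <- summary(fit)$coefficients
    pv <- sm[rownames(sm) != "(Intercept)", 4]
    names(pv) <- rownames(sm)[rownames(sm) != "(Intercept)"]
    worst <- names(pv)[which.max(pv)]
    worst_var <- vars[vapply(vars, function(v) any(startsWith(worst, v)), TRUE)][1]
    if (max(pv) <= p_remove) break
    cand_vars <- setdiff(vars, worst_var)
    cand <- fit_with(cand_vars)
    if (stats::AIC(cand) > stats::AIC(fit) + 2) break
    vars <- cand_vars
    fit <- cand
    dropped <- c(dropped, worst_var)
  }
  if (any(abs(stats::coef(fit)) > 15) || !fit$converged)
    warning("possible (quasi-)separation: coefficient estimates unstable",
            call. = FALSE)
  sm <- summary(fit)$coefficients
  z <- stats::qnorm(1 - (1 - conf) / 2)
  coefs <- data.frame(term = rownames(sm), beta = sm[, 1], se = sm[, 2],
                      p_value = sm[, 4], or = exp(sm[, 1]),
                      or_low = exp(sm[, 1] - z * sm[, 2]),
                      or_high = exp(sm[, 1] + z * sm[, 2]),
                      row.names = NULL, stringsAsFactors = FALSE)
  list(model = fit, selected = vars, dropped = dropped, coefficients = coefs)
}
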