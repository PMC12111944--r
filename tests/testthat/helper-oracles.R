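# Brute-force oracles, independent of the implementation paths they check.

# AUC as the exhaustive pairwise concordance probability, ties = 1/2
bf_auc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (x in pos) for (y in neg) tot <- tot + (x > y) + 0.5 * (x == y)
  tot / (length(pos) * length(neg))
}

# exhaustive Se/Sp scan over candidate thresholds (positive call: >= t)
bf_scan <- function(scores, labels) {
  thr <- c(sort(unique(scores)), Inf)
  pos <- scores[labels]; neg <- scores[!labels]
  data.frame(
    threshold = thr,
    se = vapply(thr, function(t) mean(pos >= t), 0),
    sp = vapply(thr, function(t) mean(neg < t), 0)
  )
}

bf_best_youden <- function(scores, labels) {
  s <- bf_scan(scores, labels)
  max(s$se + s$sp)
}

bf_rule_out <- function(scores, labels, se_floor) {
  s <- bf_scan(scores, labels)
  s <- s[s$se >= se_floor & s$sp > 0, ]
  if (!nrow(s)) return(NA_real_)
  s$threshold[which(s$sp == max(s$sp))[1]]
}

bf_rule_in <- function(scores, labels, sp_floor) {
  s <- bf_scan(scores, labels)
  s <- s[s$sp >= sp_floor & s$se > 0, ]
  if (!nrow(s)) return(NA_real_)
  s$threshold[which(s$se == max(s$se))[1]]
}

# random small score/label fixture, with optional ties
random_fixture <- function(n, tie_prob = 0.3) {
  scores <- if (runif(1) < tie_prob) sample(1:5, n, replace = TRUE)
            else round(rnorm(n), 2)
  labels <- runif(n) < 0.5
  if (all(labels)) labels[1] <- FALSE
  if (!any(labels)) labels[1] <- TRUE
  list(scores = scores, labels = labels)
}

# a fully populated subject record row
full_record <- function(n = 1) {
  data.frame(
    subject_id = sprintf("R%03d", seq_len(n)),
    sex = rep_len(c("male", "female"), n),
    age = rep(52.79, n), bmi = rep(31.4, n),
    waist_circumference = rep(109.1, n),
    fbg = rep(114.5, n), tg = rep(198.2, n), hdl = rep(44.3, n),
    ast = rep(42.3, n), alt = rep(53.1, n),
    platelets = rep(225, n), albumin = rep(3.3, n),
    diabetes_or_ifg = rep(TRUE, n),
    cap = rep(322.5, n), te = rep(8.5, n),
    stringsAsFactors = FALSE
  )
}
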