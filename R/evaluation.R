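#' Harrell's concordance index
#'
#' Over admissible pairs (i, j) with `time_i < time_j` and `event_i = 1`, a
#' pair is concordant when the shorter-lived sample has the higher predicted
#' risk; prediction ties count 0.5. Higher prediction = higher risk = shorter
#' expected survival.
#'
#' @param prediction length-n risk predictions (e.g. prognostic index).
#' @param time,event survival outcome.
#' @return concordance in `[0, 1]`.
#' @export
concordance_index <- function(prediction, time, event) {
  n <- length(prediction)
  stopifnot(length(time) == n, length(event) == n)
  # vectorized over the pair matrix: admissible (i, j): t_i < t_j, event_i = 1
  dt <- outer(time, time, `<`)
  adm <- dt & matrix(event == 1, n, n)
  total <- sum(adm)
  if (total == 0) stopf("no comparable pairs")
  dp <- outer(prediction, prediction, `-`)
  conc <- sum(adm & dp > 0) + 0.5 * sum(adm & dp == 0)
  conc / total
}

#' Area under the ROC curve
#'
#' The Mann-Whitney U normalization with midrank handling of score ties.
#'
#' @param score length-n predicted scores.
#' @param label length-n 0/1 labels; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(score, label) {
  stopifnot(length(score) == length(label))
  n1 <- sum(label == 1); n0 <- sum(label == 0)
  if (n1 == 0 || n0 == 0) stopf("both classes must be present")
  r <- rank(score)
  (sum(r[label == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Sort samples by risk and divide into five groups
#'
#' Samples are sorted by score descending (ties broken by stable original
#' order); with `n = 5k + m` the first `m` groups receive `k + 1` samples,
#' so group 1 is the highest-risk group.
#'
#' @param score length-n predicted risk scores, `n >= 5`.
#' @return integer vector of group labels 1..5 in original sample order,
#'   with attribute `sizes`.
#' @export
stratify_five_groups <- function(score) {
  n <- length(score)
  if (n < 5) stopf("need at least 5 samples to form five groups")
  k <- n %/% 5; m <- n %% 5
  sizes <- rep(k, 5) + c(rep(1, m), rep(0, 5 - m))
  ord <- order(-score, seq_along(score))
  groups <- integer(n)
  groups[ord] <- rep(seq_len(5), times = sizes)
  structure(groups, sizes = sizes)
}

#' Observed per-group disease ratios
#'
#' @param groups group assignment from [stratify_five_groups()].
#' @param label 0/1 disease labels.
#' @return fraction of cases per group, in predicted-risk order.
#' @export
disease_ratios <- function(groups, label) {
  stopifnot(length(groups) == length(label))
  vapply(seq_len(max(groups)), function(g) {
    in_g <- groups == g
    if (!any(in_g)) stopf("empty group %d", g)
    mean(label[in_g])
  }, numeric(1))
}

#' Ideal (best-achievable) per-group disease ratios
#'
#' Fills the risk-ordered groups with all cases first, then controls, and
#' returns the resulting per-group case fractions: the disease ratios a
#' perfect risk ranking would achieve.
#'
#' @param label 0/1 disease labels (only the case count is used).
#' @param sizes per-group sizes (e.g. `attr(groups, "sizes")`).
#' @return per-group ideal ratios.
#' @export
ideal_disease_ratios <- function(label, sizes) {
  cases <- sum(label == 1)
  if (sum(sizes) != length(label))
    stopf("group sizes must sum to the number of samples")
  ends <- cumsum(sizes)
  starts <- ends - sizes
  pmin(pmax(cases - starts, 0), sizes) / sizes
}

#' Mean squared prediction error between ratio vectors
#'
#' @param observed,ideal equal-length ratio vectors.
#' @return mean of squared differences.
#' @export
mspe <- function(observed, ideal) {
  if (length(observed) != length(ideal))
    stopf("ratio vectors must have equal length")
  mean((observed - ideal)^2)
}

#' Compare repeat-level metrics of two models
#'
#' Two-sided Wilcoxon rank-sum test on the two samples of repeat-level
#' metric values (e.g. C-index over 10 repeats).
#'
#' @param a,b numeric vectors of metric values, `>= 3` each.
#' @return two-sided p-value.
#' @export
compare_repeats <- function(a, b) {
  if (length(a) < 3 || length(b) < 3)
    stopf("need at least 3 repeats per model")
  if (length(unique(c(a, b))) == 1) {
    warning("all metric values identical across both models", call. = FALSE)
    return(1)
  }
  suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided", exact = NULL)$p.value)
}

#' Evaluate a trained model on a test dataset
#'
#' @param model a trained `spin_model`.
#' @param test an aligned, normalized `spin_dataset`.
#' @return named list of metrics: C-index for survival; AUC, observed and
#'   ideal five-group disease ratios and their MSPE for the risk task.
#' @export
evaluate_model <- function(model, test) {
  pred <- predict(model, test)
  if (test$task == "survival") {
    list(c_index = concordance_index(pred, test$time, test$event))
  } else {
    groups <- stratify_five_groups(pred)
    obs <- disease_ratios(groups, test$label)
    ideal <- ideal_disease_ratios(test$label, attr(groups, "sizes"))
    list(auc = roc_auc(pred, test$label),
         disease_ratios = obs, ideal_ratios = ideal,
         mspe = mspe(obs, ideal))
  }
}
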