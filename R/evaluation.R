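#' @title Classifier evaluation: MCC, balanced accuracy, predictive values,
#'   bootstrap uncertainty and clinical-applicability grading
#' @name evaluation
#' @description
#' Metrics follow the conventions of diagnostic-classification reporting:
#' MCC (binary and multiclass covariance form), balanced accuracy as the
#' mean per-class recall (in percent), sensitivity/specificity,
#' prevalence-adjusted and standardized (50% prevalence) predictive values,
#' rank-based ROC AUC, percentile bootstrap confidence intervals (2000
#' resamples), paired bootstrap classifier comparison, and the AUC to
#' odds-ratio conversion feeding a two-axis clinical-applicability score.
NULL

#' Binary confusion matrix
#'
#' @param tn,fp,fn,tp Non-negative integer cell counts (tn = true negative,
#'   fp = false positive, fn = false negative, tp = true positive).
#' @return A list of class `confusion2`.
#' @export
confusion2 <- function(tn, fp, fn, tp) {
  cells <- c(tn = as.numeric(tn), fp = as.numeric(fp),
             fn = as.numeric(fn), tp = as.numeric(tp))
  stopifnot(all(cells >= 0), all(cells == round(cells)), sum(cells) >= 1)
  structure(as.list(cells), class = "confusion2")
}

#' Build a k-class confusion matrix from labels
#'
#' Rows are truth, columns prediction, in the factor level order.
#'
#' @param truth,pred Factors over the same levels.
#' @return Integer matrix, rows = truth, columns = prediction.
#' @export
confusion_k <- function(truth, pred) {
  stopifnot(identical(levels(truth), levels(pred)))
  as.matrix(table(truth = truth, pred = pred))
}

as_confusion2 <- function(m) {
  if (inherits(m, "confusion2")) return(m)
  m <- as.matrix(m)
  stopifnot(nrow(m) == 2, ncol(m) == 2)
  confusion2(tn = m[1, 1], fp = m[1, 2], fn = m[2, 1], tp = m[2, 2])
}

#' Matthews correlation coefficient (binary)
#'
#' `(tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`, defined as 0 when
#' any marginal is zero.
#'
#' @param m A [confusion2()] or 2x2 matrix (rows truth, columns prediction,
#'   negative class first).
#' @return MCC in [-1, 1].
#' @export
mcc2 <- function(m) {
  m <- as_confusion2(m)
  tp <- m$tp; tn <- m$tn; fp <- m$fp; fn <- m$fn
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom == 0) return(0)
  ((tp * tn) - (fp * fn)) / sqrt(denom)
}

#' Matthews correlation coefficient (multiclass, covariance form)
#'
#' `(c*s - sum(p_k t_k)) / sqrt((s^2 - sum(p_k^2)) (s^2 - sum(t_k^2)))`
#' where `c` is the trace, `s` the total, `t_k` the true and `p_k` the
#' predicted class counts; 0 when either variance term vanishes. Reduces to
#' [mcc2()] for two classes.
#'
#' @param m Square count matrix, rows = truth, columns = prediction.
#' @return Generalized MCC.
#' @export
mcck <- function(m) {
  m <- as.matrix(m)
  storage.mode(m) <- "double" # count products overflow integers at large n
  stopifnot(nrow(m) == ncol(m))
  s <- sum(m); cc <- sum(diag(m))
  tk <- rowSums(m); pk <- colSums(m)
  denom <- (s^2 - sum(pk^2)) * (s^2 - sum(tk^2))
  if (denom <= 0) return(0)
  (cc * s - sum(pk * tk)) / sqrt(denom)
}

#' Balanced accuracy (mean per-class recall), in percent
#'
#' @param m A [confusion2()] or k x k count matrix (rows = truth).
#' @return Percentage in [0, 100].
#' @export
bac <- function(m) {
  if (inherits(m, "confusion2")) m <- matrix(c(m$tn, m$fp, m$fn, m$tp), 2, 2,
                                             byrow = TRUE)
  m <- as.matrix(m)
  rs <- rowSums(m)
  if (any(rs == 0)) stop("empty true class: balanced accuracy undefined",
                         call. = FALSE)
  100 * mean(diag(m) / rs)
}

#' Sensitivity and specificity, in percent
#'
#' @param m A [confusion2()] or 2x2 matrix.
#' @return Named numeric `c(sensitivity, specificity)` in percent.
#' @export
sens_spec <- function(m) {
  m <- as_confusion2(m)
  if (m$tp + m$fn < 1 || m$tn + m$fp < 1)
    stop("sensitivity/specificity need at least one subject per true class",
         call. = FALSE)
  c(sensitivity = 100 * m$tp / (m$tp + m$fn),
    specificity = 100 * m$tn / (m$tn + m$fp))
}

#' Prevalence-adjusted predictive values, in percent
#'
#' Bayes' rule: `PPV = sens p / (sens p + (1 - spec)(1 - p))` and
#' `NPV = spec (1 - p) / ((1 - sens) p + spec (1 - p))`. At `prevalence =
#' 0.5` these are the "standardized" predictive values.
#'
#' @param sens,spec Sensitivity and specificity as proportions in [0, 1].
#' @param prevalence Positive-class prevalence in (0, 1).
#' @return Named numeric `c(ppv, npv)` in percent; `NA` where the
#'   denominator vanishes.
#' @export
predictive_values <- function(sens, spec, prevalence) {
  sens <- unname(sens); spec <- unname(spec)
  stopifnot(sens >= 0, sens <= 1, spec >= 0, spec <= 1,
            prevalence > 0, prevalence < 1)
  dp <- sens * prevalence + (1 - spec) * (1 - prevalence)
  dn <- (1 - sens) * prevalence + spec * (1 - prevalence)
  c(ppv = if (dp > 0) 100 * sens * prevalence / dp else NA_real_,
    npv = if (dn > 0) 100 * spec * (1 - prevalence) / dn else NA_real_)
}

#' Clinical first-visit prevalences per binary diagnostic task
#'
#' Relative prevalence of the positive (more severe) class given first-visit
#' clinical prevalence estimates of HC 42.0%, MCI 18.6%, AD 26.3%:
#' MCI vs HC 0.307, AD vs HC 0.385, AD vs MCI 0.586.
#'
#' @return Named numeric vector for tasks `"HC.vs.MCI"`, `"HC.vs.AD"`,
#'   `"MCI.vs.AD"`.
#' @export
clinical_prevalences <- function() {
  base <- c(HC = 0.420, MCI = 0.186, AD = 0.263)
  c(HC.vs.MCI = unname(base["MCI"] / (base["HC"] + base["MCI"])),
    HC.vs.AD = unname(base["AD"] / (base["HC"] + base["AD"])),
    MCI.vs.AD = unname(base["AD"] / (base["MCI"] + base["AD"])))
}

#' Rank-based ROC AUC
#'
#' Mann-Whitney formulation with ties counted half. The multiclass variant
#' macro-averages one-vs-rest AUCs over a score matrix with one column per
#' class.
#'
#' @param scores Numeric vector of positive-class scores (binary), or a
#'   matrix with one column per class (multiclass).
#' @param labels Factor or logical/0-1 vector of true labels; for the matrix
#'   form, a factor whose levels match the score columns.
#' @return AUC as a proportion in [0, 1].
#' @export
roc_auc <- function(scores, labels) {
  if (is.matrix(scores)) {
    labels <- as.factor(labels)
    stopifnot(!is.null(colnames(scores)),
              all(levels(labels) %in% colnames(scores)))
    aucs <- vapply(levels(labels), function(cl)
      roc_auc(scores[, cl], labels == cl), numeric(1))
    return(mean(aucs))
  }
  pos <- if (is.factor(labels)) labels == levels(labels)[nlevels(labels)]
         else as.logical(labels) # logical or 0/1; TRUE/1 is the positive class
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0)
    stop("roc_auc needs both classes present", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Percentile bootstrap confidence interval for a test-set metric
#'
#' Resamples subjects with replacement `B` times and takes the 2.5th and
#' 97.5th percentiles of the metric. Resamples missing a true class present
#' in the original test set are skipped (and counted); if all resamples are
#' degenerate this is an error.
#'
#' @param metric Function of `(truth, pred)` returning a scalar.
#' @param truth,pred Vectors/factors of equal length.
#' @param B Number of bootstrap resamples (default 2000).
#' @param seed Integer seed.
#' @param conf Confidence level (default 0.95).
#' @return List with `point`, `lower`, `upper`, `n_skipped`.
#' @export
bootstrap_ci <- function(metric, truth, pred, B = 2000L, seed = 1L,
                         conf = 0.95) {
  stopifnot(length(truth) == length(pred), length(truth) >= 1, B >= 1)
  set.seed(seed)
  point <- metric(truth, pred)
  n <- length(truth)
  present <- unique(as.character(truth))
  vals <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    if (!all(present %in% as.character(truth[idx]))) next
    vals[b] <- metric(truth[idx], pred[idx])
  }
  ok <- !is.na(vals)
  if (!any(ok)) stop("all bootstrap resamples were degenerate", call. = FALSE)
  q <- stats::quantile(vals[ok], c((1 - conf) / 2, 1 - (1 - conf) / 2),
                       names = FALSE, type = 7)
  list(point = point, lower = min(q[1], point), upper = max(q[2], point),
       n_skipped = sum(!ok))
}

#' Two-tailed bootstrap comparison of two classifiers
#'
#' Resamples both test sets `B` times and computes the metric difference
#' `metric(A) - metric(B)` per resample; the two-tailed p-value is
#' `2 * min(Pr(diff <= 0), Pr(diff >= 0))`, clipped to `[2/B, 1]`. When both
#' classifiers share a test set of the same size (`paired = TRUE`), the same
#' resample indices are used on both sides.
#'
#' @param metric Function of `(truth, pred)` returning a scalar.
#' @param truth_a,pred_a,truth_b,pred_b Labeled predictions of the two
#'   classifiers.
#' @param B Number of resamples (default 2000).
#' @param seed Integer seed.
#' @param paired Resample with shared indices (default: automatically when
#'   the two test sets have equal length).
#' @return List with `p_value`, `diff` (point difference), `n_used`.
#' @export
bootstrap_compare <- function(metric, truth_a, pred_a, truth_b, pred_b,
                              B = 2000L, seed = 1L,
                              paired = length(truth_a) == length(truth_b)) {
  set.seed(seed)
  na <- length(truth_a); nb <- length(truth_b)
  pa <- unique(as.character(truth_a)); pb <- unique(as.character(truth_b))
  diffs <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    ia <- sample.int(na, na, replace = TRUE)
    ib <- if (paired) ia else sample.int(nb, nb, replace = TRUE)
    if (!all(pa %in% as.character(truth_a[ia])) ||
        !all(pb %in% as.character(truth_b[ib]))) next
    diffs[b] <- metric(truth_a[ia], pred_a[ia]) -
      metric(truth_b[ib], pred_b[ib])
  }
  ok <- !is.na(diffs)
  if (!any(ok)) stop("all bootstrap resamples were degenerate", call. = FALSE)
  d <- diffs[ok]
  p <- 2 * min(mean(d <= 0), mean(d >= 0))
  list(p_value = min(max(p, 2 / B), 1),
       diff = metric(truth_a, pred_a) - metric(truth_b, pred_b),
       n_used = sum(ok))
}

#' Convert ROC AUC to an odds ratio
#'
#' Chains the standard effect-size conversions: AUC to Cohen's d via
#' `d = sqrt(2) * qnorm(auc)`, then d to the log odds ratio via
#' `log(OR) = d * pi / sqrt(3)`.
#'
#' @param auc AUC as a proportion in (0, 1).
#' @return Odds ratio (`Inf`-bounded endpoints are rejected).
#' @export
auc_to_or <- function(auc) {
  stopifnot(auc > 0, auc < 1)
  d <- sqrt(2) * stats::qnorm(auc)
  exp(d * pi / sqrt(3))
}

#' Two-axis clinical-applicability score
#'
#' Combines a user-supplied "quality of evidence" grade (1-4, a study-design
#' judgment, not computed) with an "effect size" grade derived from the odds
#' ratio through a cutoff table (defaults: OR < 1.5 grade 1, < 2.5 grade 2,
#' < 5 grade 3, >= 5 grade 4). The sum (2-8) indicates potential clinical
#' applicability.
#'
#' @param quality_grade Integer 1-4.
#' @param or_value Odds ratio from [auc_to_or()].
#' @param cutoffs Increasing numeric vector of 3 OR cutoffs separating
#'   grades 1|2, 2|3, 3|4.
#' @return List with `effect_grade` and `sum` (quality + effect).
#' @export
applicability_score <- function(quality_grade, or_value,
                                cutoffs = c(1.5, 2.5, 5)) {
  stopifnot(quality_grade %in% 1:4, or_value > 0, length(cutoffs) == 3,
            !is.unsorted(cutoffs))
  effect <- 1L + sum(or_value >= cutoffs)
  list(effect_grade = effect, sum = as.integer(quality_grade) + effect)
}

#' Full evaluation report for a labeled test set
#'
#' Computes the confusion matrix and, for binary tasks, MCC, balanced
#' accuracy, AUC (when scores are given), sensitivity, specificity, and
#' prevalence-adjusted plus standardized predictive values, each with a
#' percentile bootstrap confidence interval; multiclass tasks report MCC,
#' balanced accuracy and macro one-vs-rest AUC.
#'
#' @param truth Factor of true labels.
#' @param pred Factor of predicted labels over the same levels.
#' @param scores Optional numeric vector (binary: positive-class
#'   probability) or matrix (multiclass: one column per class) for AUC.
#' @param prevalence Positive-class prevalence for the prevalence-adjusted
#'   predictive values (binary only); default 0.5 reports standardized
#'   values twice.
#' @param B Bootstrap resamples (default 2000).
#' @param seed Integer seed for the bootstrap.
#' @return A list of class `evaluation_report`.
#' @export
evaluate_predictions <- function(truth, pred, scores = NULL,
                                 prevalence = 0.5, B = 2000L, seed = 1L) {
  truth <- as.factor(truth)
  pred <- factor(pred, levels = levels(truth))
  cm <- confusion_k(truth, pred)
  k <- nlevels(truth)
  metrics <- list()
  ci <- list()
  if (k == 2) {
    metrics$mcc <- mcc2(cm)
    metrics$bac <- bac(cm)
    ss <- sens_spec(cm)
    metrics$sensitivity <- ss[["sensitivity"]]
    metrics$specificity <- ss[["specificity"]]
    pv_prev <- predictive_values(ss[["sensitivity"]] / 100,
                                 ss[["specificity"]] / 100, prevalence)
    pv_std <- predictive_values(ss[["sensitivity"]] / 100,
                                ss[["specificity"]] / 100, 0.5)
    metrics$ppv_prevalence <- pv_prev[["ppv"]]
    metrics$npv_prevalence <- pv_prev[["npv"]]
    metrics$ppv_standard <- pv_std[["ppv"]]
    metrics$npv_standard <- pv_std[["npv"]]
    ci$mcc <- bootstrap_ci(function(t, p) mcc2(confusion_k(t, p)),
                           truth, pred, B = B, seed = seed)
    ci$bac <- bootstrap_ci(function(t, p) bac(confusion_k(t, p)),
                           truth, pred, B = B, seed = seed)
  } else {
    metrics$mcc <- mcck(cm)
    metrics$bac <- bac(cm)
    ci$mcc <- bootstrap_ci(function(t, p) mcck(confusion_k(t, p)),
                           truth, pred, B = B, seed = seed)
    ci$bac <- bootstrap_ci(function(t, p) bac(confusion_k(t, p)),
                           truth, pred, B = B, seed = seed)
  }
  if (!is.null(scores)) metrics$auc <- roc_auc(scores, truth)
  structure(list(confusion = cm, metrics = metrics, ci = ci,
                 n = length(truth), prevalence = prevalence, seed = seed),
            class = "evaluation_report")
}

#' @method print evaluation_report
#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation_report (n = %d)\n", x$n))
  print(x$confusion)
  for (nm in names(x$metrics)) {
    v <- x$metrics[[nm]]
    if (nm %in% names(x$ci))
      cat(sprintf("  %-16s %.3f  [%.3f; %.3f]\n", nm, v,
                  x$ci[[nm]]$lower, x$ci[[nm]]$upper))
    else cat(sprintf("  %-16s %.3f\n", nm, v))
  }
  invisible(x)
}
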