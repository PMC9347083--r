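# Printed confusion matrices from published multi-site dementia
# classification experiments, used as exact arithmetic oracles
published_rows <- list(
  list(cm = c(61, 7, 5, 54), mcc = 0.811, bac = 90.6),
  list(cm = c(39, 6, 2, 37), mcc = 0.814, bac = 90.8,
       sens = 94.9, spec = 86.7),
  list(cm = c(127, 5, 9, 11), mcc = 0.564, bac = 75.6,
       sens = 55.0, spec = 96.2),
  list(cm = c(146, 3, 38, 91), mcc = 0.722),
  list(cm = c(409, 41, 11, 56), mcc = 0.641, bac = 87.2),
  list(cm = c(30, 4, 4, 26), mcc = 0.749),  # female stratum
  list(cm = c(31, 3, 1, 28), mcc = 0.875))  # male stratum

test_that("metric arithmetic reproduces every published confusion-matrix row", {
  for (row in published_rows) {
    m <- confusion2(row$cm[1], row$cm[2], row$cm[3], row$cm[4])
    expect_equal(round(mcc2(m), 3), row$mcc)
    if (!is.null(row$bac)) expect_equal(round(bac(m), 1), row$bac)
    if (!is.null(row$sens)) {
      ss <- sens_spec(m)
      expect_equal(round(ss[["sensitivity"]], 1), row$sens)
      expect_equal(round(ss[["specificity"]], 1), row$spec)
    }
  }
})

test_that("predictive values reproduce the published prevalence-adjusted row", {
  ss <- sens_spec(confusion2(39, 6, 2, 37)) / 100
  pv_prev <- predictive_values(ss[["sensitivity"]], ss[["specificity"]], 0.385)
  expect_equal(round(pv_prev[["ppv"]], 1), 81.7)
  expect_equal(round(pv_prev[["npv"]], 1), 96.4)
  pv_std <- predictive_values(ss[["sensitivity"]], ss[["specificity"]], 0.5)
  expect_equal(round(pv_std[["ppv"]], 1), 87.7)
  expect_equal(round(pv_std[["npv"]], 1), 94.4)
})

test_that("binary MCC equals the Pearson correlation of label indicators", {
  set.seed(21)
  for (i in 1:50) {
    t <- stats::rbinom(60, 1, 0.5); p <- stats::rbinom(60, 1, 0.5)
    if (length(unique(t)) < 2 || length(unique(p)) < 2) next
    m <- base::table(factor(t, 0:1), factor(p, 0:1))
    expect_equal(mcc2(m), as.numeric(stats::cor(t, p)), tolerance = 1e-12)
  }
})

test_that("MCC degenerate conventions: perfect, all-positive, zero marginals", {
  expect_equal(mcc2(confusion2(10, 0, 0, 10)), 1)
  expect_equal(mcc2(confusion2(0, 10, 0, 10)), 0)
  expect_equal(mcc2(confusion2(5, 0, 5, 0)), 0)
})

test_that("multiclass MCC: diagonal, uniform, and 2x2 reduction", {
  expect_equal(mcck(diag(c(4, 9, 7))), 1)
  expect_equal(mcck(matrix(3, 3, 3)), 0)
  expect_equal(round(mcck(matrix(c(61, 7, 5, 54), 2, 2, byrow = TRUE)), 3),
               0.811)
  set.seed(8)
  for (i in 1:100) {
    m <- matrix(stats::rpois(4, 20), 2, 2)
    expect_equal(mcck(m), mcc2(m), tolerance = 1e-12)
  }
})

test_that("balanced accuracy averages per-class recall and rejects empty rows", {
  expect_equal(bac(diag(c(5, 8, 2))), 100)
  expect_error(bac(matrix(c(0, 0, 3, 4), 2, 2, byrow = TRUE)), "empty")
  expect_error(sens_spec(confusion2(0, 0, 2, 8)), "at least one")
})

test_that("predictive values obey the standardized-form identities at p = 0.5", {
  for (sens in c(0.3, 0.7, 0.949)) for (spec in c(0.5, 0.867)) {
    pv <- predictive_values(sens, spec, 0.5)
    expect_equal(pv[["ppv"]], 100 * sens / (sens + 1 - spec))
    expect_equal(pv[["npv"]], 100 * spec / (spec + 1 - sens))
  }
  expect_equal(predictive_values(1, 1, 0.2), c(ppv = 100, npv = 100))
  # degenerate denominator -> NA, not an error
  expect_true(is.na(predictive_values(0, 1, 0.5)[["ppv"]]))
})

test_that("rank AUC matches pROC and satisfies antisymmetry", {
  set.seed(13)
  scores <- stats::rnorm(80)
  labels <- factor(ifelse(stats::rnorm(80) + scores > 0, "pos", "neg"),
                   levels = c("neg", "pos"))
  a <- roc_auc(scores, labels)
  ref <- as.numeric(suppressMessages(pROC::auc(labels, scores,
                                               direction = "<")))
  expect_equal(a, ref, tolerance = 1e-12)
  expect_equal(roc_auc(-scores, labels), 1 - a, tolerance = 1e-12)
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12),
                       factor(rep(c("a", "b"), each = 3))), 1)
  expect_error(roc_auc(scores, factor(rep("pos", 80), levels = c("neg", "pos"))),
               "both classes")
})

test_that("permuted scores give chance-level AUC", {
  set.seed(31)
  labels <- factor(rep(c("neg", "pos"), each = 3000))
  scores <- sample(stats::rnorm(6000))
  expect_equal(roc_auc(scores, labels), 0.5, tolerance = 0.03)
})

test_that("macro multiclass AUC averages one-vs-rest columns", {
  set.seed(14)
  y <- factor(sample(c("HC", "MCI", "AD"), 90, replace = TRUE),
              levels = c("HC", "MCI", "AD"))
  s <- matrix(stats::runif(270), 90, 3, dimnames = list(NULL, levels(y)))
  s[cbind(seq_len(90), as.integer(y))] <- s[cbind(seq_len(90), as.integer(y))] + 2
  expect_equal(roc_auc(s, y), 1)
  by_hand <- mean(vapply(levels(y), function(cl) roc_auc(s[, cl], y == cl),
                         numeric(1)))
  expect_equal(roc_auc(s, y), by_hand)
})

test_that("bootstrap CI brackets the point and collapses for constant metrics", {
  df <- simulate_labels_only(60, 0.8, classes = c("neg", "pos"), seed = 9)
  ci <- bootstrap_ci(function(t, p) mcc2(confusion_k(t, p)),
                     df$truth, df$pred, B = 300, seed = 2)
  expect_lte(ci$lower, ci$point)
  expect_gte(ci$upper, ci$point)
  const <- bootstrap_ci(function(t, p) 0.42, df$truth, df$pred, B = 50,
                        seed = 3)
  expect_equal(const$lower, 0.42)
  expect_equal(const$upper, 0.42)
})

test_that("bootstrap comparison: identity gives p = 1, symmetry holds", {
  df <- simulate_labels_only(80, 0.7, classes = c("neg", "pos"), seed = 4)
  same <- bootstrap_compare(function(t, p) mcc2(confusion_k(t, p)),
                            df$truth, df$pred, df$truth, df$pred,
                            B = 200, seed = 5)
  expect_equal(same$p_value, 1)
  dfb <- simulate_labels_only(80, 0.55, classes = c("neg", "pos"), seed = 6)
  ab <- bootstrap_compare(function(t, p) mcc2(confusion_k(t, p)),
                          df$truth, df$pred, dfb$truth, dfb$pred,
                          B = 400, seed = 7)
  ba <- bootstrap_compare(function(t, p) mcc2(confusion_k(t, p)),
                          dfb$truth, dfb$pred, df$truth, df$pred,
                          B = 400, seed = 7)
  expect_equal(ab$p_value, ba$p_value)
  expect_equal(ab$diff, -ba$diff)
})

test_that("a perfect classifier beats a chance classifier at n = 100", {
  perfect <- simulate_labels_only(100, 1, classes = c("neg", "pos"), seed = 8)
  chance <- simulate_labels_only(100, 0.5, classes = c("neg", "pos"), seed = 9)
  cmp <- bootstrap_compare(function(t, p) mcc2(confusion_k(t, p)),
                           perfect$truth, perfect$pred,
                           chance$truth, chance$pred, B = 1000, seed = 10)
  expect_lte(cmp$p_value, 0.05)
})

test_that("AUC to odds ratio: null point, monotonicity, reciprocal symmetry", {
  expect_equal(auc_to_or(0.5), 1)
  aucs <- seq(0.55, 0.95, by = 0.05)
  ors <- vapply(aucs, auc_to_or, numeric(1))
  expect_true(all(diff(ors) > 0))
  for (a in c(0.6, 0.777, 0.9))
    expect_equal(auc_to_or(1 - a), 1 / auc_to_or(a), tolerance = 1e-12)
  expect_error(auc_to_or(1), "auc < 1")
})

test_that("applicability grading maps odds ratios through the cutoff table", {
  expect_equal(applicability_score(2, 7.06)$effect_grade, 4)
  expect_equal(applicability_score(2, 7.06)$sum, 6)
  expect_equal(applicability_score(2, 146)$sum, 6)
  expect_equal(applicability_score(3, 1.0)$effect_grade, 1)
  expect_equal(applicability_score(1, 2.6)$effect_grade, 3)
})

test_that("evaluate_predictions assembles a coherent binary report", {
  df <- simulate_labels_only(120, 0.85, classes = c("HC", "AD"), seed = 12)
  rep <- evaluate_predictions(df$truth, df$pred, prevalence = 0.385,
                              B = 200, seed = 1)
  expect_s3_class(rep, "evaluation_report")
  expect_equal(sum(rep$confusion), 120)
  expect_equal(rep$metrics$mcc, mcc2(rep$confusion))
  expect_equal(rep$metrics$bac, bac(rep$confusion))
  expect_true(rep$ci$mcc$lower <= rep$metrics$mcc &
                rep$metrics$mcc <= rep$ci$mcc$upper)
  ss <- sens_spec(rep$confusion)
  pv <- predictive_values(ss[[1]] / 100, ss[[2]] / 100, 0.385)
  expect_equal(rep$metrics$ppv_prevalence, pv[["ppv"]])
})
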