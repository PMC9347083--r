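mk_cand <- function(algorithm, score, source = "morphometric") {
  # candidate with a prescribed ranking score (constant folds, sd = 0)
  candidate(algorithm, list(metric = "ANOVA F", percentile = 50),
            rep(score, 5), feature_source = source)
}

test_that("ranking score uses the sample-sd convention", {
  cand <- candidate("l-SVM", list(), c(0.6, 0.4, 0.5, 0.5, 0.5))
  expect_equal(cand$mean_mcc, 0.5)
  expect_equal(cand$ranking_score, 0.5 - stats::sd(c(0.6, 0.4, 0.5, 0.5, 0.5)))
  expect_equal(round(cand$ranking_score, 4), 0.4293)
})

test_that("above-mean selection keeps the top scorers, with a fallback", {
  scores <- c(0.5, 0.4, 0.3, 0.2, 0.1, 0.0, -0.1)
  cands <- Map(mk_cand, base_algorithms(), scores)
  sel <- rank_and_select(unname(cands))
  expect_equal(vapply(sel, `[[`, numeric(1), "ranking_score"),
               c(0.5, 0.4, 0.3)) # mean is 0.2; strictly above
  # all-equal scores: single best selected by algorithm order
  equal <- Map(mk_cand, base_algorithms(), rep(0.3, 7))
  sel_eq <- rank_and_select(unname(equal))
  expect_length(sel_eq, 1)
  expect_equal(sel_eq[[1]]$algorithm, "l-SVM")
})

test_that("GT replacement substitutes the worst voters in descending order", {
  sel <- list(mk_cand("l-SVM", 0.6), mk_cand("RF", 0.5), mk_cand("LR", 0.4))
  # no GT candidate above the worst -> unchanged
  out <- apply_gt_replacement(sel, list(mk_cand("DT", 0.35, "GT@0.3")))
  expect_equal(vapply(out, `[[`, character(1), "feature_source"),
               rep("morphometric", 3))
  # one GT above the worst -> exactly that one replaced, size constant
  out1 <- apply_gt_replacement(sel, list(mk_cand("DT", 0.45, "GT@0.3")))
  expect_length(out1, 3)
  expect_setequal(vapply(out1, `[[`, numeric(1), "ranking_score"),
                  c(0.6, 0.5, 0.45))
  # two GT above the two worst -> both replaced
  out2 <- apply_gt_replacement(sel, list(mk_cand("DT", 0.55, "GT@0.3"),
                                         mk_cand("ET", 0.52, "GT@0.5")))
  expect_setequal(vapply(out2, `[[`, numeric(1), "ranking_score"),
                  c(0.6, 0.55, 0.52))
  expect_setequal(vapply(out2, `[[`, character(1), "feature_source"),
                  c("morphometric", "GT@0.3", "GT@0.5"))
})

test_that("fold pipeline scales, selects and scores without leakage", {
  d <- separable_xy(n = 25, shift = 4)
  idx_te <- c(1:5, 26:30)
  fit <- fold_pipeline_fit(d$x[-idx_te, ], d$y[-idx_te],
                           d$x[idx_te, ], d$y[idx_te], "LDA",
                           list(metric = "ANOVA F", percentile = 100,
                                estimator = "moment"))
  expect_equal(fit$mcc, 1) # cleanly separable
  expect_equal(sum(fit$mask), ncol(d$x)) # percentile 100 keeps everything
  # scaler fitted on the training part only
  expect_equal(unname(fit$scaler$min), unname(apply(d$x[-idx_te, ], 2, min)))
  # chi-square never sees negatives even when raw data has them
  fit_chi <- fold_pipeline_fit(d$x[-idx_te, ] - 50, d$y[-idx_te],
                               d$x[idx_te, ] - 50, d$y[idx_te], "DT",
                               list(metric = "chi-square", percentile = 50,
                                    max_depth = 5, min_leaf = 1))
  expect_true(is.finite(fit_chi$mcc))
  expect_error(fold_pipeline_fit(d$x[-idx_te, ],
                                 factor(rep("pos", 40),
                                        levels = c("neg", "pos")),
                                 d$x[idx_te, ], d$y[idx_te], "LDA",
                                 list(metric = "ANOVA F", percentile = 100,
                                      estimator = "moment")),
               "single-class")
})

test_that("the cached per-fold search path equals the reference pipeline", {
  d <- separable_xy(n = 20, shift = 2, seed = 13)
  fold <- morphdx:::stratified_folds(d$y, 5, seed = 1)
  ctx <- morphdx:::fold_context(d$x, d$y, fold)
  for (genome in list(list(metric = "ANOVA F", percentile = 40, C = 1),
                      list(metric = "chi-square", percentile = 100, C = 0.1),
                      list(metric = "mutual information", percentile = 20,
                           C = 10))) {
    ref <- morphdx:::evaluate_genome(d$x, d$y, fold, "l-SVM", genome, 5)
    fast <- morphdx:::evaluate_genome_ctx(ctx, "l-SVM", genome, 5)
    expect_equal(fast, ref)
  }
})

test_that("a single-point search space is returned immediately", {
  d <- separable_xy(n = 15, shift = 4, seed = 5)
  grids <- list("l-SVM" = list(C = 1))
  cfg <- evolution_config(generations = 1, population = 2)
  cand <- evolve(d$x, d$y, "l-SVM",
                 grids = grids, cfg = cfg, seed = 2)
  # metric/percentile still searched, but C is pinned
  expect_equal(cand$genome$C, 1)
  expect_length(cand$fold_mccs, 5)
  expect_equal(cand$ranking_score,
               mean(cand$fold_mccs) - stats::sd(cand$fold_mccs))
})

test_that("evolution finds a strong candidate on a strong-signal task and is reproducible", {
  d <- separable_xy(n = 30, shift = 3, seed = 6)
  cfg <- evolution_config(generations = 4, population = 6)
  c1 <- evolve(d$x, d$y, "LR", cfg = cfg, seed = 3)
  expect_gte(c1$mean_mcc, 0.9)
  c2 <- evolve(d$x, d$y, "LR", cfg = cfg, seed = 3)
  expect_identical(c1$genome, c2$genome)
  expect_identical(c1$fold_mccs, c2$fold_mccs)
})

test_that("voting: single member is the identity, importances average and sum to 1", {
  d <- separable_xy(n = 20, shift = 4, seed = 8)
  blocks <- list(morphometric = d$x)
  v1 <- candidate("LR", list(metric = "ANOVA F", percentile = 100, C = 1),
                  rep(0.9, 5))
  ens1 <- fit_voting_ensemble(list(v1), blocks, d$y, seed = 1)
  member_prob <- {
    m <- ens1$members[[1]]
    s <- minmax_apply(m$scaler, d$x[, m$columns])
    predict_prob(m$learner, s[, m$mask, drop = FALSE])
  }
  expect_equal(predict(ens1, d$x), member_prob)
  expect_equal(sum(ens1$importance), 1)

  v2 <- candidate("DT", list(metric = "ANOVA F", percentile = 50,
                             max_depth = 5, min_leaf = 1), rep(0.8, 5))
  ens2 <- fit_voting_ensemble(list(v1, v2), blocks, d$y, seed = 1)
  expect_equal(sum(ens2$importance), 1)
  p_members <- vapply(ens2$members, function(m) {
    s <- minmax_apply(m$scaler, d$x[, m$columns])
    predict_prob(m$learner, s[, m$mask, drop = FALSE])
  }, numeric(nrow(d$x)))
  expect_equal(predict(ens2, d$x), rowMeans(p_members))
  # class ties at exactly 0.5 go to the negative class
  lab <- predict(ens2, d$x, type = "class")
  expect_true(all(lab == ifelse(predict(ens2, d$x) > 0.5, "pos", "neg")))
})

test_that("end-to-end binary training on a well-separated synthetic cohort", {
  cfg <- sim_config(n_per_class = c(HC = 30, MCI = 0, AD = 30),
                    n_features = 30, n_graph_nodes = 8, seed = 21)
  tab <- simulate_cohort(cfg)
  sp <- stratified_split(tab, seed = 21)
  ens <- train_binary_ensemble(sp$train, task = c("HC", "AD"),
                               cfg = evolution_config(generations = 2,
                                                      population = 4),
                               seed = 21)
  expect_gte(length(ens$members), 1)
  prob <- predict_table(ens, sp$test)
  expect_true(all(prob >= 0 & prob <= 1))
  truth <- factor(as.character(sp$test$metadata$final_dx),
                  levels = c("HC", "AD"))
  pred <- factor(ifelse(prob > 0.5, "AD", "HC"), levels = c("HC", "AD"))
  expect_gte(mcc2(confusion_k(truth, pred)), 0.5)
  expect_equal(sum(ens$importance), 1)
  # candidates bookkeeping: one per algorithm, consistent scores
  expect_equal(vapply(ens$candidates, `[[`, character(1), "algorithm"),
               base_algorithms())
  for (cand in ens$candidates)
    expect_equal(cand$ranking_score,
                 mean(cand$fold_mccs) - stats::sd(cand$fold_mccs))
})

test_that("GT candidates train per threshold and can join the vote", {
  cfg <- sim_config(n_per_class = c(HC = 24, MCI = 0, AD = 24),
                    n_features = 12, n_graph_nodes = 6, seed = 31)
  tab <- simulate_cohort(cfg)
  ens <- train_binary_ensemble(tab, task = c("HC", "AD"), use_gt = TRUE,
                               thresholds = c(0.7, 0.9),
                               cfg = evolution_config(generations = 1,
                                                      population = 3),
                               seed = 31)
  expect_equal(length(ens$candidates), 7 + 7 * 2)
  gt_sources <- vapply(ens$candidates[8:21], `[[`, character(1),
                       "feature_source")
  expect_setequal(unique(gt_sources), c("GT@0.7", "GT@0.9"))
  # prediction works regardless of which sources won the vote
  prob <- predict_table(ens, tab)
  expect_true(all(prob >= 0 & prob <= 1))
})
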