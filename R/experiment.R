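#' @title Experiment orchestration
#' @name cli_app
#' @description
#' Ties the pipeline into the train-on-X / test-on-Y experiment patterns of
#' multi-site morphometry studies: same-source experiments use the
#' constrained 70/30 split; cross-source experiments train on the entire
#' one source and test on the entire other (no internal split);
#' combined-source training balances source proportions across diagnoses
#' so a classifier cannot extrapolate diagnosis from source-specific
#' feature offsets. A source-discrimination experiment reuses the binary
#' machinery with the protocol or dataset tag as the label.
NULL

#' Experiment specification
#'
#' @param id Free-form experiment identifier.
#' @param train_filter,test_filter Named lists of metadata filters, e.g.
#'   `list(protocol = "MPRAGE")` or `list(dataset = c("SIM-A", "SIM-B"))`;
#'   `NULL` selects everything.
#' @param tasks Character subset of `"HC.vs.MCI"`, `"HC.vs.AD"`,
#'   `"MCI.vs.AD"`, `"multiclass"`.
#' @param use_gt Train graph-theory candidates too.
#' @param balance_by When combining several values of this metadata column
#'   in training (e.g. `"protocol"`), balance their proportions across
#'   diagnoses (default: automatic when a filter names > 1 value).
#' @param seed Integer seed.
#' @return List of class `experiment_spec`.
#' @export
experiment_spec <- function(id, train_filter = NULL, test_filter = NULL,
                            tasks = c("HC.vs.AD"), use_gt = FALSE,
                            balance_by = NULL, seed = 1L) {
  stopifnot(all(tasks %in% c(binary_task_names(), "multiclass")))
  structure(as.list(environment()), class = "experiment_spec")
}

apply_filter <- function(table, filt) {
  if (is.null(filt)) return(table)
  keep <- rep(TRUE, n_subjects(table))
  for (nm in names(filt))
    keep <- keep & table$metadata[[nm]] %in% filt[[nm]]
  if (!any(keep)) stop("selector matches no subjects", call. = FALSE)
  subset_subjects(table, keep)
}

same_selection <- function(a, b) {
  identical(a, b) || (is.null(a) && is.null(b))
}

#' Balance source proportions across diagnoses by down-sampling
#'
#' Within each final diagnosis, subjects are down-sampled so every source
#' holds the same proportion across diagnoses (within one subject),
#' preventing the classifier from reading a diagnosis off source-specific
#' offsets.
#'
#' @param table A [feature_table()].
#' @param by Metadata column with the source tag (`"protocol"` or
#'   `"dataset"`).
#' @param seed Integer seed.
#' @return A down-sampled `feature_table`.
#' @export
balance_sources <- function(table, by, seed = 1L) {
  set.seed(seed)
  dx <- as.character(table$metadata$final_dx)
  src <- table$metadata[[by]]
  counts <- base::table(dx, src)
  if (ncol(counts) < 2) return(table)
  # target: per diagnosis, source proportions equal to the global minimum
  # feasible proportion profile; achieved by scaling each diagnosis row to
  # the most restrictive source share
  share <- sweep(counts, 1, rowSums(counts), "/")
  target_share <- apply(share, 2, min)
  target_share <- target_share / sum(target_share)
  keep <- logical(n_subjects(table))
  for (d in rownames(counts)) {
    nd_max <- min(counts[d, ] / target_share)
    for (s in colnames(counts)) {
      idx <- which(dx == d & src == s)
      take <- min(length(idx), round_half_up(nd_max * target_share[[s]]))
      keep[sample(idx, take)] <- TRUE
    }
  }
  subset_subjects(table, keep)
}

#' Run one diagnostic classification experiment
#'
#' Executes the full pattern: subject selection, split (same-source) or
#' whole-source train/test (cross-source), optional source balancing,
#' binary ensemble training per task, stacking for the multiclass task,
#' and evaluation with bootstrap confidence intervals.
#'
#' @param spec An [experiment_spec()].
#' @param table The full cohort [feature_table()].
#' @param cfg An [evolution_config()].
#' @param constraints A [split_constraints()] for same-source splits.
#' @param B Bootstrap resamples for the evaluation reports.
#' @return List with `reports` (one `evaluation_report` per task),
#'   `ensembles`, `stacked` (when multiclass), `importance`, and `spec`.
#' @export
run_experiment <- function(spec, table, cfg = evolution_config(),
                           constraints = NULL, B = 2000L) {
  stopifnot(inherits(spec, "experiment_spec"))
  cross_source <- !same_selection(spec$train_filter, spec$test_filter)
  if (cross_source) {
    train <- apply_filter(table, spec$train_filter)
    test <- apply_filter(table, spec$test_filter)
  } else {
    pool <- apply_filter(table, spec$train_filter)
    if (!is.null(spec$balance_by))
      pool <- balance_sources(pool, spec$balance_by, seed = spec$seed)
    if (is.null(constraints))
      constraints <- split_constraints(seed = spec$seed)
    sp <- build_split(pool, constraints)
    train <- sp$train; test <- sp$test
  }
  binary_tasks <- setdiff(spec$tasks, "multiclass")
  if ("multiclass" %in% spec$tasks)
    binary_tasks <- union(binary_task_names(), binary_tasks)
  for (tk in binary_tasks) {
    cls <- task_classes(tk)
    for (side in list(train, test))
      if (!all(cls %in% as.character(side$metadata$final_dx)))
        stop("class absent for task ", tk,
             " in train or test selection", call. = FALSE)
  }
  ensembles <- list()
  reports <- list()
  for (tk in binary_tasks) {
    cls <- task_classes(tk)
    ensembles[[tk]] <- train_binary_ensemble(
      train, task = cls, use_gt = spec$use_gt, cfg = cfg,
      seed = spec$seed + match(tk, binary_task_names()) * 1000L)
    keep <- as.character(test$metadata$final_dx) %in% cls
    sub <- subset_subjects(test, keep)
    truth <- factor(as.character(sub$metadata$final_dx), levels = cls)
    prob <- predict_table(ensembles[[tk]], sub, type = "prob")
    pred <- factor(ifelse(prob > 0.5, cls[2], cls[1]), levels = cls)
    prev <- clinical_prevalences()[[tk]]
    if (tk %in% spec$tasks)
      reports[[tk]] <- evaluate_predictions(truth, pred, scores = prob,
                                            prevalence = prev, B = B,
                                            seed = spec$seed)
  }
  stacked <- NULL
  if ("multiclass" %in% spec$tasks) {
    stacked <- stack_fit(ensembles, train, seed = spec$seed)
    out <- stack_predict(stacked, test)
    truth <- factor(as.character(test$metadata$final_dx),
                    levels = stacked$classes)
    reports$multiclass <- evaluate_predictions(
      truth, out$label, scores = NULL, B = B, seed = spec$seed)
    reports$multiclass$metrics$auc <- roc_auc(
      norm_rep_scores(out$representation, stacked$classes), truth)
  }
  importance <- if (!is.null(stacked)) stacked$importance
                else if (length(ensembles)) ensembles[[1]]$importance
  list(reports = reports, ensembles = ensembles, stacked = stacked,
       importance = importance, train = train, test = test, spec = spec)
}

# per-class scores for the multiclass AUC from the one-vs-one probability
# representation: HC gets (1-P(MCI|HCvsMCI)) + (1-P(AD|HCvsAD)), etc.
norm_rep_scores <- function(rep_mat, classes) {
  s <- cbind(HC = (1 - rep_mat[, "HC.vs.MCI"]) + (1 - rep_mat[, "HC.vs.AD"]),
             MCI = rep_mat[, "HC.vs.MCI"] + (1 - rep_mat[, "MCI.vs.AD"]),
             AD = rep_mat[, "HC.vs.AD"] + rep_mat[, "MCI.vs.AD"])
  s[, classes, drop = FALSE] / 2
}

#' Source-discrimination experiment
#'
#' Trains the binary voting machinery to distinguish two source tags
#' (protocols or datasets) instead of diagnoses, after balancing diagnosis
#' proportions across the sources in training.
#'
#' @param table A [feature_table()].
#' @param by Metadata column holding the source tag (`"protocol"` or
#'   `"dataset"`).
#' @param cfg An [evolution_config()].
#' @param test_fraction Held-out fraction (default 0.30).
#' @param B Bootstrap resamples.
#' @param seed Integer seed.
#' @return List with `report` (an `evaluation_report`), `ensemble`.
#' @export
run_source_discrimination <- function(table, by = "protocol",
                                      cfg = evolution_config(),
                                      test_fraction = 0.30, B = 2000L,
                                      seed = 1L) {
  src <- table$metadata[[by]]
  lv <- sort(unique(src))
  if (length(lv) != 2)
    stop("source discrimination needs exactly 2 source labels, found ",
         length(lv), call. = FALSE)
  # balance diagnosis proportions across sources: within each diagnosis,
  # down-sample to the per-source minimum
  set.seed(seed)
  dx <- as.character(table$metadata$final_dx)
  keep <- logical(n_subjects(table))
  for (d in unique(dx)) {
    nmin <- min(base::table(src[dx == d]))
    for (s in lv) {
      idx <- which(dx == d & src == s)
      keep[sample(idx, min(nmin, length(idx)))] <- TRUE
    }
  }
  tab <- subset_subjects(table, keep)
  y <- factor(tab$metadata[[by]], levels = lv)
  # stratified holdout on the source label
  set.seed(seed + 1L)
  test_idx <- unlist(lapply(lv, function(s) {
    idx <- which(y == s)
    sample(idx, round_half_up(test_fraction * length(idx)))
  }))
  is_test <- seq_along(y) %in% test_idx
  ens <- train_binary_ensemble(subset_subjects(tab, !is_test),
                               y = droplevels(y[!is_test]),
                               cfg = cfg, seed = seed)
  sub <- subset_subjects(tab, is_test)
  prob <- predict_table(ens, sub, type = "prob")
  truth <- factor(as.character(y[is_test]), levels = lv)
  pred <- factor(ifelse(prob > 0.5, lv[2], lv[1]), levels = lv)
  list(report = evaluate_predictions(truth, pred, scores = prob,
                                     B = B, seed = seed),
       ensemble = ens)
}
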