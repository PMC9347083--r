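#' @title Multi-diagnostic stacking of the binary ensembles
#' @name stacker
#' @description
#' The three binary voting ensembles (HC vs MCI, HC vs AD, MCI vs AD) are
#' combined into one multi-diagnostic classifier: each subject is mapped to
#' the 3-dimensional vector of higher-class (more severe) probabilities
#' output by the binaries, and a linear maximum-margin one-vs-one
#' classifier over that representation picks one of HC, MCI, AD. The margin
#' parameter C is tuned by 5-fold stratified cross-validation on multiclass
#' MCC. Feature importances of the binaries are merged by weighting each
#' binary's importance vector with the mean absolute combiner coefficient
#' on its probability across the three one-vs-one decision functions.
NULL

binary_task_names <- function() c("HC.vs.MCI", "HC.vs.AD", "MCI.vs.AD")

task_classes <- function(task) {
  switch(task,
         HC.vs.MCI = c("HC", "MCI"),
         HC.vs.AD = c("HC", "AD"),
         MCI.vs.AD = c("MCI", "AD"),
         stop("unknown task: ", task, call. = FALSE))
}

#' Higher-class probability representation of subjects
#'
#' @param binaries Named list of the three `voting_ensemble`s, names
#'   `"HC.vs.MCI"`, `"HC.vs.AD"`, `"MCI.vs.AD"`.
#' @param table A [feature_table()].
#' @return Matrix with one column per binary task: the probability of the
#'   more severe class of that task.
#' @export
stack_representation <- function(binaries, table) {
  stopifnot(all(binary_task_names() %in% names(binaries)))
  rep_mat <- vapply(binary_task_names(), function(tk)
    predict_table(binaries[[tk]], table, type = "prob"),
    numeric(n_subjects(table)))
  if (is.null(dim(rep_mat))) rep_mat <- matrix(rep_mat, nrow = 1,
                                               dimnames = list(NULL, binary_task_names()))
  rep_mat
}

# one linear SVM per unordered class pair over the representation
fit_ovo <- function(rep_mat, y, C) {
  pairs <- utils::combn(levels(y), 2, simplify = FALSE)
  fits <- lapply(pairs, function(pr) {
    idx <- y %in% pr
    yy <- factor(as.character(y[idx]), levels = pr)
    model <- e1071::svm(rep_mat[idx, , drop = FALSE], yy, kernel = "linear",
                        cost = C, scale = FALSE)
    w <- as.numeric(t(model$coefs) %*% model$SV)
    list(pair = pr, model = model, w = w)
  })
  names(fits) <- vapply(pairs, paste, character(1), collapse = ".vs.")
  fits
}

predict_ovo <- function(fits, rep_mat, classes) {
  votes <- matrix(0, nrow(rep_mat), length(classes),
                  dimnames = list(NULL, classes))
  margin <- matrix(0, nrow(rep_mat), length(classes),
                   dimnames = list(NULL, classes))
  for (f in fits) {
    pred <- predict(f$model, rep_mat, decision.values = TRUE)
    dv <- as.numeric(attr(pred, "decision.values"))
    # decision value is positive toward the first named class of the pair
    first <- strsplit(colnames(attr(pred, "decision.values")), "/")[[1]][1]
    second <- setdiff(f$pair, first)
    ij <- cbind(seq_len(nrow(rep_mat)), match(as.character(pred), classes))
    votes[ij] <- votes[ij] + 1
    margin[, first] <- margin[, first] + dv
    margin[, second] <- margin[, second] - dv
  }
  # majority vote; ties broken by accumulated signed margins
  lab <- apply(votes + 1e-9 * margin, 1, function(r) classes[which.max(r)])
  factor(lab, levels = classes)
}

#' Fit the stacked multi-diagnostic model
#'
#' @param binaries Named list of the three binary `voting_ensemble`s.
#' @param train A [feature_table()] of the training subjects the binaries
#'   were trained on.
#' @param c_grid Candidate margin parameters C (default
#'   `c(0.01, 0.1, 1, 10, 100)`).
#' @param seed Integer seed (CV fold assignment).
#' @return Object of class `stacked_model` with the fitted one-vs-one
#'   combiner, the chosen C, and the aggregated importance vector.
#' @export
stack_fit <- function(binaries, train, c_grid = c(0.01, 0.1, 1, 10, 100),
                      seed = 1L) {
  stopifnot(all(binary_task_names() %in% names(binaries)),
            length(c_grid) >= 1)
  y <- factor(as.character(train$metadata$final_dx), levels = dx_levels())
  y <- droplevels(y)
  if (nlevels(y) < 3)
    warning("fewer than 3 diagnosis classes in the training set")
  rep_mat <- stack_representation(binaries, train)
  colnames(rep_mat) <- binary_task_names()
  fold <- stratified_folds(y, 5L, seed)
  cv_mcc <- vapply(c_grid, function(C) {
    mean(vapply(seq_len(max(fold)), function(f) {
      tr <- fold != f
      fits <- fit_ovo(rep_mat[tr, , drop = FALSE], droplevels(y[tr]), C)
      pred <- predict_ovo(fits, rep_mat[!tr, , drop = FALSE], levels(y))
      mcck(confusion_k(y[!tr], pred))
    }, numeric(1)))
  }, numeric(1))
  C <- c_grid[which.max(cv_mcc)]
  fits <- fit_ovo(rep_mat, y, C)
  model <- structure(list(binaries = binaries, combiner = fits, C = C,
                          cv_mcc = stats::setNames(cv_mcc, c_grid),
                          classes = levels(y)),
                     class = "stacked_model")
  model$importance <- aggregate_importance(model)
  model
}

#' Predict diagnoses with a stacked model
#'
#' @param model A `stacked_model`.
#' @param table A [feature_table()].
#' @return List with `label` (factor over HC/MCI/AD) and `representation`
#'   (the 3-column probability matrix, returned for audit).
#' @export
stack_predict <- function(model, table) {
  rep_mat <- stack_representation(model$binaries, table)
  colnames(rep_mat) <- binary_task_names()
  list(label = predict_ovo(model$combiner, rep_mat, model$classes),
       representation = rep_mat)
}

#' Aggregate feature importance across the stacked binaries
#'
#' Each binary ensemble's importance vector (summing to 1) is weighted by
#' the mean absolute coefficient its probability column receives across the
#' three one-vs-one decision functions, then the weighted sum is
#' renormalized to 1.
#'
#' @param model A `stacked_model`.
#' @return Named numeric importance vector over the union of features.
#' @export
aggregate_importance <- function(model) {
  w_b <- vapply(seq_along(binary_task_names()), function(b)
    mean(vapply(model$combiner, function(f) abs(f$w[b]), numeric(1))),
    numeric(1))
  names(w_b) <- binary_task_names()
  all_feats <- unique(unlist(lapply(binary_task_names(), function(tk)
    names(model$binaries[[tk]]$importance))))
  agg <- numeric(length(all_feats)); names(agg) <- all_feats
  for (b in binary_task_names()) {
    imp <- model$binaries[[b]]$importance
    imp <- imp / sum(imp)
    agg[names(imp)] <- agg[names(imp)] + w_b[[b]] * imp
  }
  agg / sum(agg)
}

#' Group an importance vector by feature metadata
#'
#' @param importance Named importance vector (features must appear in
#'   `meta$name`).
#' @param meta Feature metadata data.frame (columns `name`,
#'   `anatomical_group`, `measure_type`).
#' @param by `"anatomical_group"` or `"measure_type"`.
#' @return data.frame with columns `group` and `share_pct`, sorted
#'   decreasing; shares sum to 100.
#' @export
grouped_importance <- function(importance, meta, by = c("anatomical_group",
                                                        "measure_type")) {
  by <- match.arg(by)
  idx <- match(names(importance), meta$name)
  if (anyNA(idx))
    stop("importance names missing from feature metadata", call. = FALSE)
  shares <- tapply(importance, meta[[by]][idx], sum)
  out <- data.frame(group = names(shares),
                    share_pct = 100 * as.numeric(shares) / sum(importance),
                    stringsAsFactors = FALSE)
  out[order(-out$share_pct), , drop = FALSE]
}
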