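#' @title Base learners, scaling and univariate feature selection
#' @name base_learners
#' @description
#' The seven base algorithms of the voting ensembles — linear SVM (l-SVM),
#' decision tree (DT), random forest (RF), extremely randomized trees (ET),
#' linear discriminant analysis (LDA), logistic regression (LR), and
#' logistic regression trained by stochastic gradient descent (LR-SGD) —
#' behind a uniform fit / predict-probability / importance interface. All
#' expose per-feature importances (absolute weights for linear models,
#' impurity importance for tree models) and positive-class probabilities.
#' Preprocessing is min-max scaling to [0, 1] followed by percentile
#' selection of the best features under one of three univariate scores
#' (mutual information, ANOVA F, chi-square).
NULL

#' The seven base algorithm identifiers, in canonical order
#' @return Character vector; the order is also the tie-break order used in
#'   candidate ranking.
#' @export
base_algorithms <- function() {
  c("l-SVM", "DT", "RF", "ET", "LDA", "LR", "LR-SGD")
}

#' Default hyperparameter grids per algorithm
#'
#' Standard desk-scale ranges: l-SVM and LR cost C over {0.01, 0.1, 1, 10,
#' 100}; trees over depth {3, 5, 10, unlimited}, forests over {100, 300}
#' trees, minimum leaf size {1, 5, 10}; LDA covariance estimator
#' {moment, mle}; LR-SGD learning-rate schedule {optimal, adaptive} and L2
#' strength alpha {1e-4, 1e-3, 1e-2}.
#'
#' @return Named list: per algorithm, a named list of gene -> value vector.
#' @export
default_grids <- function() {
  list(
    "l-SVM" = list(C = c(0.01, 0.1, 1, 10, 100)),
    "DT" = list(max_depth = c(3, 5, 10, 0), min_leaf = c(1, 5, 10)),
    "RF" = list(n_trees = c(100, 300), max_depth = c(3, 5, 10, 0),
                min_leaf = c(1, 5, 10)),
    "ET" = list(n_trees = c(100, 300), max_depth = c(3, 5, 10, 0),
                min_leaf = c(1, 5, 10)),
    "LDA" = list(estimator = c("moment", "mle")),
    "LR" = list(C = c(0.01, 0.1, 1, 10, 100)),
    "LR-SGD" = list(schedule = c("optimal", "adaptive"),
                    alpha = c(1e-4, 1e-3, 1e-2)))
}

#' Fit a min-max scaler on training data
#' @param x Numeric matrix.
#' @return List with `min` and `range` per column; constant columns map
#'   to 0.
#' @export
minmax_fit <- function(x) {
  mn <- apply(x, 2, min)
  rg <- apply(x, 2, max) - mn
  list(min = mn, range = rg)
}

#' Apply a fitted min-max scaler
#' @param scaler From [minmax_fit()].
#' @param x Numeric matrix with the same columns.
#' @return Scaled matrix; training-range columns land in [0, 1], constant
#'   columns at 0. Out-of-range values (new data) are not clipped.
#' @export
minmax_apply <- function(scaler, x) {
  rg <- ifelse(scaler$range == 0, 1, scaler$range)
  out <- sweep(sweep(x, 2, scaler$min, "-"), 2, rg, "/")
  out[, scaler$range == 0] <- 0
  out
}

#' Univariate feature scores for selection
#'
#' Scores each column of a scaled (non-negative) feature matrix against a
#' class factor. `"ANOVA F"` is the one-way F statistic; `"chi-square"` is
#' the chi-square statistic between class-wise feature totals and the
#' class-prior expectation (valid for non-negative features, as after
#' min-max scaling); `"mutual information"` is estimated by equal-width
#' binning of each feature (10 bins) against the class variable.
#'
#' @param x Numeric matrix (non-negative for chi-square).
#' @param y Factor of class labels.
#' @param metric One of `"mutual information"`, `"ANOVA F"`, `"chi-square"`.
#' @return Numeric vector of per-column scores (higher = more informative).
#' @export
score_features <- function(x, y,
                           metric = c("mutual information", "ANOVA F",
                                      "chi-square")) {
  metric <- match.arg(metric)
  y <- droplevels(as.factor(y))
  n <- nrow(x); k <- nlevels(y)
  switch(metric,
    "ANOVA F" = {
      grand <- colMeans(x)
      ssb <- 0; ssw <- 0
      for (lv in levels(y)) {
        xi <- x[y == lv, , drop = FALSE]
        m <- colMeans(xi)
        ssb <- ssb + nrow(xi) * (m - grand)^2
        ssw <- ssw + colSums(sweep(xi, 2, m)^2)
      }
      f <- (ssb / (k - 1)) / (ssw / (n - k))
      f[!is.finite(f)] <- 0
      f
    },
    "chi-square" = {
      if (any(x < 0)) stop("chi-square selection requires non-negative values",
                           call. = FALSE)
      observed <- rowsum(x, y)             # k x p class-wise feature sums
      priors <- as.numeric(base::table(y)) / n
      total <- colSums(observed)
      expected <- outer(priors, total)
      chi <- colSums((observed - expected)^2 /
                       ifelse(expected == 0, 1, expected))
      chi[total == 0] <- 0
      chi
    },
    "mutual information" = {
      n_bins <- 10L
      py <- as.numeric(base::table(y)) / n
      class_rows <- lapply(levels(y), function(lv) which(y == lv))
      vapply(seq_len(ncol(x)), function(j) {
        col <- x[, j]
        rngv <- range(col)
        if (rngv[2] - rngv[1] < .Machine$double.eps) return(0)
        bin <- pmin(floor((col - rngv[1]) / (rngv[2] - rngv[1]) * n_bins) + 1L,
                    n_bins)
        joint <- vapply(class_rows, function(rows)
          tabulate(bin[rows], n_bins), integer(n_bins)) / n
        px <- rowSums(joint)
        pij <- joint[joint > 0]
        ex <- outer(px, py)[joint > 0]
        max(sum(pij * log(pij / ex)), 0)
      }, numeric(1))
    })
}

#' Select the top percentile of features by score
#'
#' @param scores Numeric per-feature scores.
#' @param percentile Integer in {10, 20, ..., 100}: keep the top
#'   `percentile`% of features (at least one).
#' @return Logical mask over features.
#' @export
select_percentile <- function(scores, percentile) {
  stopifnot(percentile >= 1, percentile <= 100)
  p <- length(scores)
  keep_n <- max(1L, ceiling(p * percentile / 100))
  mask <- logical(p)
  mask[order(scores, decreasing = TRUE)[seq_len(keep_n)]] <- TRUE
  mask
}

# ---- the seven learners ----------------------------------------------------

#' Fit one of the seven base algorithms
#'
#' @param algorithm One of [base_algorithms()].
#' @param x Numeric matrix (already scaled and feature-selected).
#' @param y Two-level factor; the second level is the positive (more
#'   severe) class.
#' @param hyper Named list of hyperparameters for this algorithm (see
#'   [default_grids()]).
#' @param seed Integer seed for stochastic learners (RF, ET, LR-SGD).
#' @return Object of class `base_learner`.
#' @export
fit_base_learner <- function(algorithm, x, y, hyper, seed = 1L) {
  stopifnot(algorithm %in% base_algorithms(), nlevels(y) == 2)
  if (length(unique(as.character(y))) < 2)
    stop("single-class training data for base learner", call. = FALSE)
  fit <- switch(algorithm,
    "l-SVM" = fit_lsvm(x, y, hyper, seed),
    "DT" = fit_dt(x, y, hyper),
    "RF" = fit_rf(x, y, hyper, seed, extratrees = FALSE),
    "ET" = fit_rf(x, y, hyper, seed, extratrees = TRUE),
    "LDA" = fit_lda(x, y, hyper),
    "LR" = fit_lr(x, y, hyper),
    "LR-SGD" = fit_lrsgd(x, y, hyper, seed))
  structure(c(list(algorithm = algorithm, levels = levels(y),
                   p = ncol(x), colnames = colnames(x)), fit),
            class = "base_learner")
}

#' Positive-class probability of a fitted base learner
#' @param learner A `base_learner`.
#' @param x Matrix over the same (scaled, selected) columns used in fitting.
#' @return Numeric vector of probabilities of the positive (second) level.
#' @export
predict_prob <- function(learner, x) {
  stopifnot(inherits(learner, "base_learner"))
  p <- learner$predict(x)
  pmin(pmax(as.numeric(p), 0), 1)
}

#' Per-feature importance of a fitted base learner
#'
#' Absolute weights for the linear models (l-SVM, LDA, LR, LR-SGD),
#' impurity importance for the tree models (DT, RF, ET). Non-negative, over
#' the columns the learner was fitted on; not normalized.
#'
#' @param learner A `base_learner`.
#' @return Numeric vector of length `learner$p`.
#' @export
learner_importance <- function(learner) {
  stopifnot(inherits(learner, "base_learner"))
  imp <- learner$importance()
  imp[!is.finite(imp) | imp < 0] <- 0
  imp
}

fit_lsvm <- function(x, y, hyper, seed) {
  set.seed(seed)
  model <- tryCatch(
    e1071::svm(x, y, kernel = "linear", cost = hyper$C, probability = TRUE,
               scale = FALSE),
    error = function(e) e1071::svm(x, y, kernel = "linear", cost = hyper$C,
                                   probability = FALSE, scale = FALSE))
  pos <- levels(y)[2]
  prob_of <- function(pr) {
    probs <- attr(pr, "probabilities")
    dv <- as.numeric(attr(pr, "decision.values"))
    dv_pos <- if (grepl(paste0("^", pos, "/"),
                        colnames(attr(pr, "decision.values"))[1])) dv else -dv
    if (is.null(probs) || !pos %in% colnames(probs))
      return(stats::plogis(dv_pos)) # Platt unavailable: logistic link
    list(p = probs[, pos], dv = dv_pos)
  }
  # libsvm's Platt sigmoid can come out inverted relative to the decision
  # function (degenerate internal CV at small cost); detect once on the
  # training data and flip if so
  tr_out <- prob_of(predict(model, x, probability = TRUE,
                            decision.values = TRUE))
  flip <- is.list(tr_out) && stats::var(tr_out$p) > 0 &&
    stats::var(tr_out$dv) > 0 && stats::cor(tr_out$p, tr_out$dv) < 0
  list(
    predict = function(newx) {
      out <- prob_of(predict(model, newx, probability = TRUE,
                             decision.values = TRUE))
      if (!is.list(out)) return(out)
      if (flip) 1 - out$p else out$p
    },
    importance = function() {
      w <- as.numeric(t(model$coefs) %*% model$SV)
      abs(w)
    })
}

fit_dt <- function(x, y, hyper) {
  df <- as.data.frame(x)
  names(df) <- paste0("V", seq_len(ncol(x)))
  df$.y <- y
  depth <- if (hyper$max_depth == 0) 30 else hyper$max_depth
  model <- rpart::rpart(.y ~ ., data = df, method = "class",
                        control = rpart::rpart.control(
                          maxdepth = depth, minbucket = hyper$min_leaf,
                          cp = 0, xval = 0))
  pos <- levels(y)[2]
  list(
    predict = function(newx) {
      nd <- as.data.frame(newx)
      names(nd) <- paste0("V", seq_len(ncol(newx)))
      predict(model, nd, type = "prob")[, pos]
    },
    importance = function() {
      imp <- rep(0, ncol(x))
      vi <- model$variable.importance
      if (!is.null(vi)) {
        idx <- match(names(vi), paste0("V", seq_len(ncol(x))))
        imp[idx[!is.na(idx)]] <- vi[!is.na(idx)]
      }
      imp
    })
}

fit_rf <- function(x, y, hyper, seed, extratrees) {
  colnames(x) <- paste0("V", seq_len(ncol(x)))
  model <- ranger::ranger(
    x = x, y = y, probability = TRUE,
    num.trees = hyper$n_trees,
    max.depth = hyper$max_depth,           # 0 = unlimited
    min.node.size = hyper$min_leaf,
    splitrule = if (extratrees) "extratrees" else "gini",
    replace = !extratrees, sample.fraction = 1,
    importance = "impurity", seed = seed, num.threads = 1)
  pos <- levels(y)[2]
  list(
    predict = function(newx) {
      colnames(newx) <- paste0("V", seq_len(ncol(newx)))
      predict(model, data = newx, num.threads = 1)$predictions[, pos]
    },
    importance = function() as.numeric(model$variable.importance))
}

fit_lda <- function(x, y, hyper) {
  # LDA cannot handle within-group constant variables; drop them
  within_var <- vapply(seq_len(ncol(x)), function(j) {
    v <- tapply(x[, j], y, stats::var)
    sum(v, na.rm = TRUE)
  }, numeric(1))
  keep <- which(within_var > 1e-12)
  if (!length(keep)) {
    prior_pos <- mean(y == levels(y)[2])
    return(list(predict = function(newx) rep(prior_pos, nrow(newx)),
                importance = function() rep(0, ncol(x))))
  }
  # collinearity among morphometric features is routine; lda warns but the
  # pseudo-inverse discriminant it returns is what we want
  model <- withCallingHandlers(
    MASS::lda(x[, keep, drop = FALSE], grouping = y,
              method = hyper$estimator),
    warning = function(w) {
      if (grepl("collinear", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  pos <- levels(y)[2]
  list(
    predict = function(newx)
      predict(model, newx[, keep, drop = FALSE])$posterior[, pos],
    importance = function() {
      imp <- rep(0, ncol(x))
      imp[keep] <- abs(model$scaling[, 1])
      imp
    })
}

fit_lr <- function(x, y, hyper) {
  n <- nrow(x)
  lambda <- 1 / (hyper$C * n)   # ridge penalty equivalent to cost C
  padded <- ncol(x) < 2
  xx <- if (padded) cbind(x, `..pad..` = 0) else x
  model <- glmnet::glmnet(xx, y, family = "binomial", alpha = 0,
                          lambda = lambda, standardize = FALSE)
  list(
    predict = function(newx) {
      nx <- if (padded) cbind(newx, `..pad..` = 0) else newx
      as.numeric(predict(model, nx, s = lambda, type = "response"))
    },
    importance = function() {
      co <- as.numeric(stats::coef(model, s = lambda))[-1] # drop intercept
      abs(co[seq_len(ncol(x))])
    })
}

# Logistic regression by stochastic gradient descent: log loss with L2
# penalty `alpha`, one sample per update, data reshuffled every epoch.
# Schedules: "optimal" eta_t = 1 / (alpha * (t0 + t)) with t0 = 1/alpha;
# "adaptive" starts at eta0 = 0.1 and divides eta by 5 whenever an epoch
# fails to improve the penalized loss.
fit_lrsgd <- function(x, y, hyper, seed, epochs = 100L) {
  set.seed(seed)
  n <- nrow(x); p <- ncol(x)
  yy <- as.numeric(y == levels(y)[2])
  w <- rep(0, p); b <- 0
  alpha <- hyper$alpha
  eta0 <- 0.1; eta <- eta0; t0 <- 1 / alpha; t <- 0
  best_loss <- Inf
  pen_loss <- function(w, b) {
    z <- as.numeric(x %*% w) + b
    mean(log1p(exp(-ifelse(yy == 1, z, -z)))) + alpha * sum(w^2) / 2
  }
  for (ep in seq_len(epochs)) {
    for (i in sample.int(n)) {
      t <- t + 1
      if (hyper$schedule == "optimal") eta <- 1 / (alpha * (t0 + t))
      z <- sum(x[i, ] * w) + b
      g <- stats::plogis(z) - yy[i]
      w <- w - eta * (g * x[i, ] + alpha * w)
      b <- b - eta * g
    }
    if (hyper$schedule == "adaptive") {
      l <- pen_loss(w, b)
      if (l > best_loss - 1e-8) eta <- eta / 5 else best_loss <- min(best_loss, l)
      if (eta < 1e-6) break
    }
  }
  list(
    predict = function(newx) stats::plogis(as.numeric(newx %*% w) + b),
    importance = function() abs(w))
}
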