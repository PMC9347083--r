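#' @title Voting-ensemble training with evolutionary hyperparameter search
#' @name ensemble_trainer
#' @description
#' One voting ensemble is trained per binary diagnostic task. For each of
#' the seven base algorithms, a simple evolutionary algorithm searches over
#' the feature-selection metric, the feature percentile, and the
#' algorithm's hyperparameters, with the mean Matthews correlation
#' coefficient across 5 stratified cross-validation folds as fitness (all
#' preprocessing fitted within each fold's training part only). Candidates
#' are ranked by mean fold MCC minus its standard deviation; candidates
#' above the mean ranking score are refit on the full training set and
#' combined by soft voting. Graph-theory candidates (seven algorithms times
#' four binarization thresholds) can replace the worst selected
#' morphometric voters when they rank higher.
NULL

#' Evolutionary search configuration
#'
#' Defaults: 10 generations of 10 individuals, 30% per-gene mutation, 50%
#' crossover, tournament size 3, elitism of one, 5 CV folds.
#'
#' @param generations,population,tournament_size Positive integers.
#' @param gene_mutation_prob,crossover_prob Probabilities in [0, 1].
#' @param n_folds Stratified CV folds used for fitness (default 5).
#' @return List of class `evolution_config`.
#' @export
evolution_config <- function(generations = 10L, population = 10L,
                             gene_mutation_prob = 0.30,
                             crossover_prob = 0.50,
                             tournament_size = 3L, n_folds = 5L) {
  stopifnot(generations >= 1, population >= 1, tournament_size >= 1,
            gene_mutation_prob >= 0, gene_mutation_prob <= 1,
            crossover_prob >= 0, crossover_prob <= 1, n_folds >= 2)
  structure(as.list(environment()), class = "evolution_config")
}

selector_metrics <- function() c("mutual information", "ANOVA F", "chi-square")
percentile_space <- function() seq(10L, 100L, by = 10L)

# stratified k-fold assignment; returns integer fold id per row
stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (lv in unique(as.character(y))) {
    idx <- sample(which(as.character(y) == lv))
    fold[idx] <- rep(seq_len(k), length.out = length(idx))
  }
  if (any(vapply(split(as.character(y), fold), function(s)
    length(unique(s)), integer(1)) < 2))
    stop("stratification produced a single-class fold; more subjects per ",
         "class are needed for ", k, "-fold CV", call. = FALSE)
  fold
}

# full gene space for one algorithm: selector metric, percentile, hypers
genome_space <- function(algorithm, grids) {
  c(list(metric = selector_metrics(), percentile = percentile_space()),
    grids[[algorithm]])
}

# safe uniform draw from a grid (sample() would misread a length-1 numeric)
draw_gene <- function(v) v[sample.int(length(v), 1)]

random_genome <- function(space) lapply(space, draw_gene)

genome_key <- function(genome) paste(unlist(genome), collapse = "|")

#' Fit the fold pipeline for one candidate and score the held-out fold
#'
#' Scales the fold's training part to [0, 1], fits the percentile selector
#' on the scaled training part, fits the classifier, and returns the MCC on
#' the held-out fold. Nothing is fitted on held-out rows.
#'
#' @param x_tr,y_tr Training-part features and labels.
#' @param x_te,y_te Held-out fold features and labels.
#' @param algorithm One of [base_algorithms()].
#' @param genome Named list with `metric`, `percentile` and the algorithm's
#'   hyperparameters.
#' @param seed Integer seed for stochastic learners.
#' @return List with `mcc` and the fitted pieces (`scaler`, `mask`,
#'   `learner`).
#' @export
fold_pipeline_fit <- function(x_tr, y_tr, x_te, y_te, algorithm, genome,
                              seed = 1L) {
  if (length(unique(as.character(y_tr))) < 2)
    stop("single-class fold: stratification bug upstream", call. = FALSE)
  scaler <- minmax_fit(x_tr)
  s_tr <- minmax_apply(scaler, x_tr)
  scores <- score_features(s_tr, y_tr, genome$metric)
  mask <- select_percentile(scores, genome$percentile)
  hyper <- genome[setdiff(names(genome), c("metric", "percentile"))]
  learner <- fit_base_learner(algorithm, s_tr[, mask, drop = FALSE], y_tr,
                              hyper, seed = seed)
  s_te <- minmax_apply(scaler, x_te)
  prob <- predict_prob(learner, s_te[, mask, drop = FALSE])
  pred <- factor(ifelse(prob > 0.5, levels(y_tr)[2], levels(y_tr)[1]),
                 levels = levels(y_tr))
  list(mcc = mcc2(confusion_k(factor(y_te, levels = levels(y_tr)), pred)),
       scaler = scaler, mask = mask, learner = learner)
}

evaluate_genome <- function(x, y, fold, algorithm, genome, seed) {
  k <- max(fold)
  mccs <- vapply(seq_len(k), function(f) {
    tr <- fold != f
    fold_pipeline_fit(x[tr, , drop = FALSE], y[tr],
                      x[!tr, , drop = FALSE], y[!tr],
                      algorithm, genome, seed = seed + f)$mcc
  }, numeric(1))
  mccs
}

# per-fold context reused across every genome of an evolve() run: the fold
# scaler and the per-metric selector scores do not depend on the genome, so
# computing them once removes most of the search's preprocessing cost.
# Produces results identical to evaluate_genome()/fold_pipeline_fit().
fold_context <- function(x, y, fold) {
  lapply(seq_len(max(fold)), function(f) {
    tr <- fold != f
    scaler <- minmax_fit(x[tr, , drop = FALSE])
    list(s_tr = minmax_apply(scaler, x[tr, , drop = FALSE]),
         y_tr = y[tr],
         s_te = minmax_apply(scaler, x[!tr, , drop = FALSE]),
         y_te = y[!tr],
         scores = new.env(parent = emptyenv()))
  })
}

evaluate_genome_ctx <- function(ctx, algorithm, genome, seed) {
  hyper <- genome[setdiff(names(genome), c("metric", "percentile"))]
  vapply(seq_along(ctx), function(f) {
    cx <- ctx[[f]]
    sc <- cx$scores[[genome$metric]]
    if (is.null(sc)) {
      sc <- score_features(cx$s_tr, cx$y_tr, genome$metric)
      cx$scores[[genome$metric]] <- sc
    }
    mask <- select_percentile(sc, genome$percentile)
    learner <- fit_base_learner(algorithm, cx$s_tr[, mask, drop = FALSE],
                                cx$y_tr, hyper, seed = seed + f)
    prob <- predict_prob(learner, cx$s_te[, mask, drop = FALSE])
    pred <- factor(ifelse(prob > 0.5, levels(cx$y_tr)[2], levels(cx$y_tr)[1]),
                   levels = levels(cx$y_tr))
    mcc2(confusion_k(factor(cx$y_te, levels = levels(cx$y_tr)), pred))
  }, numeric(1))
}

#' Evolve the best candidate for one algorithm
#'
#' Tournament selection (size 3), uniform crossover (50% pair probability,
#' 50% per-gene swap), per-gene mutation (30%, resampling uniformly from
#' the gene's grid), elitism of one. Fitness is the mean MCC over the
#' stratified CV folds; the candidate with the highest mean fold MCC ever
#' encountered is returned, with its fold MCCs and ranking score
#' (mean minus sample standard deviation) recorded. Fully reproducible
#' given the seed.
#'
#' @param x,y Training features (matrix) and two-level factor labels.
#' @param algorithm One of [base_algorithms()].
#' @param grids Hyperparameter grids (default [default_grids()]).
#' @param cfg An [evolution_config()].
#' @param fold Integer fold assignment (shared across algorithms so fold
#'   MCCs are comparable); built with [stratified_folds()] when `NULL`.
#' @param seed Integer seed.
#' @return A `classifier_candidate`: list with `algorithm`, `genome`,
#'   `fold_mccs`, `mean_mcc`, `ranking_score`, `feature_source`.
#' @export
evolve <- function(x, y, algorithm, grids = default_grids(),
                   cfg = evolution_config(), fold = NULL, seed = 1L) {
  space <- genome_space(algorithm, grids)
  if (any(vapply(space, length, integer(1)) == 0))
    stop("empty search space", call. = FALSE)
  if (is.null(fold)) fold <- stratified_folds(y, cfg$n_folds, seed)
  ctx <- fold_context(x, y, fold)
  set.seed(seed)
  cache <- new.env(parent = emptyenv())
  eval_cached <- function(genome) {
    key <- genome_key(genome)
    if (!is.null(cache[[key]])) return(cache[[key]])
    mccs <- evaluate_genome_ctx(ctx, algorithm, genome, seed)
    cache[[key]] <- mccs
    mccs
  }
  pop <- replicate(cfg$population, random_genome(space), simplify = FALSE)
  fits <- lapply(pop, eval_cached)
  best_i <- which.max(vapply(fits, mean, numeric(1)))
  best <- list(genome = pop[[best_i]], mccs = fits[[best_i]])
  for (gen in seq_len(max(0, cfg$generations - 1))) {
    # tournament selection
    parents <- lapply(seq_len(cfg$population), function(i) {
      contenders <- sample.int(cfg$population, cfg$tournament_size,
                               replace = TRUE)
      pop[[contenders[which.max(vapply(fits[contenders], mean, numeric(1)))]]]
    })
    # uniform crossover on consecutive pairs
    for (i in seq(1, cfg$population - 1, by = 2)) {
      if (stats::runif(1) < cfg$crossover_prob) {
        for (g in names(space)) {
          if (stats::runif(1) < 0.5) {
            tmp <- parents[[i]][[g]]
            parents[[i]][[g]] <- parents[[i + 1]][[g]]
            parents[[i + 1]][[g]] <- tmp
          }
        }
      }
    }
    # per-gene mutation
    pop <- lapply(parents, function(ind) {
      for (g in names(space))
        if (stats::runif(1) < cfg$gene_mutation_prob)
          ind[[g]] <- draw_gene(space[[g]])
      ind
    })
    # elitism: best-ever replaces the first slot
    pop[[1]] <- best$genome
    fits <- lapply(pop, eval_cached)
    gen_best <- which.max(vapply(fits, mean, numeric(1)))
    if (mean(fits[[gen_best]]) > mean(best$mccs))
      best <- list(genome = pop[[gen_best]], mccs = fits[[gen_best]])
  }
  candidate(algorithm, best$genome, best$mccs, feature_source = "morphometric")
}

#' Construct a classifier candidate record
#'
#' @param algorithm One of [base_algorithms()].
#' @param genome Named list (selector metric, percentile, hypers).
#' @param fold_mccs Numeric vector of fold MCCs.
#' @param feature_source `"morphometric"` or `"GT@<threshold>"`.
#' @return List of class `classifier_candidate` with the ranking score
#'   `mean(fold_mccs) - sd(fold_mccs)` (sample SD, divisor n-1).
#' @export
candidate <- function(algorithm, genome, fold_mccs,
                      feature_source = "morphometric") {
  structure(list(algorithm = algorithm, genome = genome,
                 fold_mccs = fold_mccs,
                 mean_mcc = mean(fold_mccs),
                 ranking_score = mean(fold_mccs) -
                   (if (length(fold_mccs) > 1) stats::sd(fold_mccs) else 0),
                 feature_source = feature_source),
            class = "classifier_candidate")
}

#' Select candidates scoring above the mean ranking score
#'
#' Strictly above the mean of all ranking scores; if no candidate clears
#' the mean (all equal), the single best is selected, ties broken by the
#' fixed algorithm order of [base_algorithms()].
#'
#' @param candidates List of `classifier_candidate`s (one per algorithm).
#' @return Sub-list of selected candidates.
#' @export
rank_and_select <- function(candidates) {
  scores <- vapply(candidates, `[[`, numeric(1), "ranking_score")
  sel <- which(scores > mean(scores))
  if (!length(sel)) {
    ord <- order(-scores, match(vapply(candidates, `[[`, character(1),
                                       "algorithm"), base_algorithms()))
    sel <- ord[1]
  }
  candidates[sel]
}

#' Replace the worst selected voters with better-ranked GT candidates
#'
#' Graph-theory candidates are considered in descending ranking score; each
#' one that scores strictly above the current worst selected voter replaces
#' that voter. The voter count never changes.
#'
#' @param selected List of selected (morphometric) candidates.
#' @param gt_candidates List of GT candidates (any length).
#' @return The final voter list.
#' @export
apply_gt_replacement <- function(selected, gt_candidates) {
  if (!length(gt_candidates)) return(selected)
  gt_scores <- vapply(gt_candidates, `[[`, numeric(1), "ranking_score")
  for (g in order(gt_scores, decreasing = TRUE)) {
    scores <- vapply(selected, `[[`, numeric(1), "ranking_score")
    worst <- which.min(scores)
    if (gt_scores[g] > scores[worst]) {
      selected[[worst]] <- gt_candidates[[g]]
    } else break
  }
  selected
}

# refit one candidate on the full training block
refit_candidate <- function(cand, x, y, seed) {
  scaler <- minmax_fit(x)
  s <- minmax_apply(scaler, x)
  scores <- score_features(s, y, cand$genome$metric)
  mask <- select_percentile(scores, cand$genome$percentile)
  hyper <- cand$genome[setdiff(names(cand$genome), c("metric", "percentile"))]
  learner <- fit_base_learner(cand$algorithm, s[, mask, drop = FALSE], y,
                              hyper, seed = seed)
  list(candidate = cand, scaler = scaler, mask = mask, learner = learner,
       columns = colnames(x), feature_source = cand$feature_source)
}

member_importance <- function(member) {
  imp_sel <- learner_importance(member$learner)
  full <- numeric(length(member$columns))
  names(full) <- member$columns
  if (sum(imp_sel) <= 0) imp_sel <- rep(1, length(imp_sel)) # uninformative
  full[member$mask] <- imp_sel / sum(imp_sel)
  full
}

#' Refit selected voters on the full training data and combine by voting
#'
#' Each voter's scaler and selector are refit on its full training block
#' with the tuned genome frozen. The ensemble's probability is the mean of
#' the members' positive-class probabilities (soft voting); its per-feature
#' importance is the mean of the members' normalized importance vectors
#' (zeros outside each member's selected features), renormalized to sum 1.
#'
#' @param voters List of `classifier_candidate`s.
#' @param blocks Named list of feature matrices per feature source
#'   (`"morphometric"`, `"GT@0.3"`, ...); each voter is refit on its own
#'   source block.
#' @param y Two-level factor of training labels.
#' @param seed Integer seed.
#' @return Object of class `voting_ensemble` with members, task levels and
#'   the importance vector over the union of block columns.
#' @export
fit_voting_ensemble <- function(voters, blocks, y, seed = 1L) {
  stopifnot(length(voters) >= 1)
  members <- lapply(seq_along(voters), function(i) {
    src <- voters[[i]]$feature_source
    if (!src %in% names(blocks))
      stop("no feature block for source '", src, "'", call. = FALSE)
    refit_candidate(voters[[i]], blocks[[src]], y, seed = seed + i)
  })
  all_cols <- unique(unlist(lapply(blocks, colnames)))
  imp <- numeric(length(all_cols)); names(imp) <- all_cols
  for (m in members) {
    mi <- member_importance(m)
    imp[names(mi)] <- imp[names(mi)] + mi / length(members)
  }
  imp <- imp / sum(imp)
  structure(list(members = members, levels = levels(y), importance = imp),
            class = "voting_ensemble")
}

#' Predict with a voting ensemble
#'
#' @param object A `voting_ensemble`.
#' @param newdata Matrix (or named list of matrices per feature source)
#'   with the training columns.
#' @param type `"prob"` for the positive-class probability (mean of member
#'   probabilities) or `"class"` for labels (positive when probability is
#'   strictly above 0.5; exact ties go to the negative, less severe class).
#' @param ... Unused.
#' @return Numeric vector or factor.
#' @export
predict.voting_ensemble <- function(object, newdata, type = c("prob", "class"),
                                    ...) {
  type <- match.arg(type)
  get_block <- function(member) {
    if (is.list(newdata) && !is.data.frame(newdata)) {
      blk <- newdata[[member$feature_source]]
      if (is.null(blk)) stop("newdata lacks feature block '",
                             member$feature_source, "'", call. = FALSE)
      blk
    } else newdata
  }
  probs <- vapply(object$members, function(m) {
    blk <- get_block(m)
    missing_cols <- setdiff(m$columns, colnames(blk))
    if (length(missing_cols))
      stop("newdata is missing column(s): ",
           paste(utils::head(missing_cols, 5), collapse = ", "), call. = FALSE)
    s <- minmax_apply(m$scaler, blk[, m$columns, drop = FALSE])
    predict_prob(m$learner, s[, m$mask, drop = FALSE])
  }, numeric(if (is.list(newdata) && !is.data.frame(newdata))
    nrow(newdata[[1]]) else nrow(newdata)))
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1)
  p <- rowMeans(probs)
  if (type == "prob") return(p)
  factor(ifelse(p > 0.5, object$levels[2], object$levels[1]),
         levels = object$levels)
}

#' Train one voting ensemble for a binary task
#'
#' Runs the full per-task procedure: per-algorithm evolutionary search on
#' the morphometric block (and, when `use_gt`, on each graph-theory
#' threshold block), above-mean selection, the GT replacement rule, and the
#' final refit into a soft-voting ensemble.
#'
#' @param table A [feature_table()] containing only the task's subjects (or
#'   all subjects plus an explicit `y`).
#' @param y Two-level factor of labels, second level positive. When `NULL`,
#'   built from `task` over `final_dx`.
#' @param task Length-2 character vector `c(negative, positive)` of
#'   diagnosis labels (used when `y` is `NULL`).
#' @param use_gt Also train graph-theory candidates and apply the
#'   replacement rule (default `FALSE`).
#' @param thresholds Graph binarization thresholds for the GT stage.
#' @param grids Hyperparameter grids.
#' @param cfg An [evolution_config()].
#' @param seed Integer seed; the entire run is reproducible given it.
#' @return A `voting_ensemble` with extra fields `candidates` (all
#'   evolved candidates) and `thresholds`.
#' @export
train_binary_ensemble <- function(table, y = NULL, task = NULL,
                                  use_gt = FALSE,
                                  thresholds = c(0.3, 0.5, 0.7, 0.9),
                                  grids = default_grids(),
                                  cfg = evolution_config(), seed = 1L) {
  if (is.null(y)) {
    stopifnot(length(task) == 2)
    keep <- as.character(table$metadata$final_dx) %in% task
    table <- subset_subjects(table, keep)
    y <- factor(as.character(table$metadata$final_dx), levels = task)
  }
  stopifnot(nlevels(y) == 2, length(y) == n_subjects(table))
  morph_cols <- table$meta$measure_type != "graph"
  blocks <- list(morphometric = table$features[, morph_cols, drop = FALSE])
  if (use_gt) {
    gt_tab <- gt_features(table, thresholds)
    for (th in format(thresholds, trim = TRUE)) {
      cols <- grepl(paste0("@", th, ":"), gt_tab$meta$name, fixed = TRUE)
      blocks[[paste0("GT@", th)]] <-
        gt_tab$features[, cols, drop = FALSE]
    }
  }
  fold <- stratified_folds(y, cfg$n_folds, seed)
  algos <- base_algorithms()
  morph_cands <- lapply(seq_along(algos), function(i)
    evolve(blocks$morphometric, y, algos[i], grids, cfg, fold = fold,
           seed = seed + 100L * i))
  selected <- rank_and_select(morph_cands)
  gt_cands <- list()
  if (use_gt) {
    k <- 0
    for (th in format(thresholds, trim = TRUE)) {
      for (i in seq_along(algos)) {
        k <- k + 1
        cand <- evolve(blocks[[paste0("GT@", th)]], y, algos[i], grids, cfg,
                       fold = fold, seed = seed + 10000L + 100L * k)
        cand$feature_source <- paste0("GT@", th)
        gt_cands[[k]] <- cand
      }
    }
    selected <- apply_gt_replacement(selected, gt_cands)
  }
  ens <- fit_voting_ensemble(selected, blocks, y, seed = seed + 77L)
  ens$candidates <- c(morph_cands, gt_cands)
  ens$thresholds <- if (use_gt) thresholds else numeric(0)
  ens$use_gt <- use_gt
  ens
}

#' Predict with a trained binary ensemble on a feature table
#'
#' Computes graph-theory blocks on the fly when any member uses a GT
#' feature source.
#'
#' @param ensemble A `voting_ensemble` from [train_binary_ensemble()].
#' @param table A [feature_table()] with the training feature columns.
#' @param type `"prob"` or `"class"`.
#' @return Numeric probabilities or factor labels.
#' @export
predict_table <- function(ensemble, table, type = "prob") {
  sources <- unique(vapply(ensemble$members, `[[`, character(1),
                           "feature_source"))
  morph_cols <- table$meta$measure_type != "graph"
  blocks <- list(morphometric = table$features[, morph_cols, drop = FALSE])
  gt_sources <- setdiff(sources, "morphometric")
  if (length(gt_sources)) {
    gt_tab <- gt_features(table, ensemble$thresholds)
    for (src in gt_sources) {
      th <- sub("^GT@", "", src)
      cols <- grepl(paste0("@", th, ":"), gt_tab$meta$name, fixed = TRUE)
      blocks[[src]] <- gt_tab$features[, cols, drop = FALSE]
    }
  }
  predict(ensemble, blocks, type = type)
}
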