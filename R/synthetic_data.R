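#' @title Synthetic cohort generator
#' @name synthetic_data
#' @description
#' Generates cohorts with the statistical structure the pipeline assumes:
#' positive morphometric features with diagnosis-graded atrophy concentrated
#' in hippocampal, then temporal/cingulate/frontal groups; multiplicative
#' protocol- and dataset-specific offsets; diagnostic transitions with
#' intermediate severity; and realistic age/sex structure. Every draw is
#' seed-deterministic.
NULL

#' Simulation configuration
#'
#' Defaults encode the study conditions the generator emulates: per-class
#' age means/SDs and sex ratios from a typical multi-site dementia cohort
#' (HC 72.4 +- 6.6 y, MCI 73.1 +- 7.5, AD 74.6 +- 7.9), transition rates per
#' final-diagnosis class (HC: 26/211 reverted from MCI; MCI: 16/188
#' progressed from HC; AD: 83/171 progressed from MCI and 1/171 from HC),
#' fractional atrophy at full AD severity of 10% in hippocampus, 5% in
#' temporal, 3% in cingulate and frontal, 1% elsewhere, multiplicative
#' lognormal noise with 5% coefficient of variation, and protocol/dataset
#' multiplicative offsets of scale 3% and 2%.
#'
#' @param n_per_class Named integer vector of subject counts, e.g.
#'   `c(HC = 100, MCI = 100, AD = 100)`. Classes with 0 subjects may be
#'   omitted.
#' @param n_features Total feature count (default 694).
#' @param n_graph_nodes Number of volume features used as graph nodes
#'   (default 209).
#' @param group_effects Named vector, fractional reduction at AD severity
#'   per anatomical group.
#' @param severity Named vector mapping diagnosis to severity in [0, 1].
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   noise (default 0.05).
#' @param protocol_offset_scale,dataset_offset_scale SDs of the per-protocol
#'   / per-dataset per-feature multiplicative factors around 1 (defaults
#'   0.03 and 0.02).
#' @param protocols,datasets Character vectors of source tags; subjects are
#'   assigned uniformly.
#' @param transition_rates Named list per final class: named numeric vector
#'   of P(baseline = b | final = class) for baseline classes other than the
#'   final one.
#' @param age_model Named list per class: `c(mean, sd)` of age in years.
#' @param age_slope Fractional feature change per year of age relative to
#'   age 70 (default -0.002, i.e. 0.2% loss per year).
#' @param sex_ratio Named vector, probability of male per class.
#' @param seed Integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_per_class = c(HC = 100, MCI = 100, AD = 100),
                       n_features = 694,
                       n_graph_nodes = 209,
                       group_effects = c(hippocampus = 0.10, temporal = 0.05,
                                         cingulate = 0.03, frontal = 0.03,
                                         other = 0.01),
                       severity = c(HC = 0, MCI = 0.5, AD = 1),
                       noise_cv = 0.05,
                       protocol_offset_scale = 0.03,
                       dataset_offset_scale = 0.02,
                       protocols = c("MPRAGE", "IR-SPGR"),
                       datasets = c("SIM-A", "SIM-B"),
                       transition_rates = list(
                         HC = c(MCI = 26 / 211),
                         MCI = c(HC = 16 / 188),
                         AD = c(MCI = 83 / 171, HC = 1 / 171)),
                       age_model = list(HC = c(72.4, 6.6),
                                        MCI = c(73.1, 7.5),
                                        AD = c(74.6, 7.9)),
                       age_slope = -0.002,
                       sex_ratio = c(HC = 98 / 211, MCI = 113 / 188,
                                     AD = 97 / 171),
                       seed = 1L) {
  stopifnot(all(names(n_per_class) %in% dx_levels()),
            n_graph_nodes >= 2, n_features >= n_graph_nodes,
            noise_cv >= 0, protocol_offset_scale >= 0,
            dataset_offset_scale >= 0,
            all(unlist(transition_rates) >= 0),
            all(unlist(transition_rates) <= 1),
            all(diff(severity[intersect(dx_levels(), names(severity))]) >= 0))
  structure(as.list(environment()), class = "sim_config")
}

# deterministic feature metadata layout for a simulated cohort: the first
# n_graph_nodes features are volumes (graph nodes) spread across groups with
# hippocampus/temporal/cingulate/frontal first; remaining features cycle
# through the other measure types and groups.
sim_feature_meta <- function(cfg) {
  groups <- c("hippocampus", "temporal", "cingulate", "frontal", "parietal",
              "occipital", "insula", "subcortical", "white-matter",
              "ventricles/CSF", "other")
  # group proportions loosely follow a FreeSurfer-style inventory: the
  # hippocampus block is small, association cortices larger
  props <- c(hippocampus = 0.06, temporal = 0.14, cingulate = 0.08,
             frontal = 0.18, parietal = 0.12, occipital = 0.08,
             insula = 0.04, subcortical = 0.12, `white-matter` = 0.10,
             `ventricles/CSF` = 0.04, other = 0.04)
  assign_groups <- function(n) {
    counts <- floor(props * n)
    rem <- n - sum(counts)
    if (rem > 0) {
      extra <- rep(names(props), length.out = rem)
      for (g in extra) counts[g] <- counts[g] + 1
    }
    rep(names(counts), times = counts)
  }
  node_groups <- assign_groups(cfg$n_graph_nodes)
  n_rest <- cfg$n_features - cfg$n_graph_nodes
  rest_groups <- if (n_rest > 0) assign_groups(n_rest) else character(0)
  rest_types <- rep(setdiff(measure_types(), c("volume", "graph")),
                    length.out = n_rest)
  data.frame(
    name = c(sprintf("vol_%s_%03d", gsub("[^a-zA-Z]", "", node_groups),
                     seq_len(cfg$n_graph_nodes)),
             if (n_rest > 0)
               sprintf("f_%s_%03d", gsub("[^a-zA-Z]", "", rest_types),
                       seq_len(n_rest))),
    anatomical_group = c(node_groups, rest_groups),
    measure_type = c(rep("volume", cfg$n_graph_nodes), rest_types),
    is_graph_node = c(rep(TRUE, cfg$n_graph_nodes), rep(FALSE, n_rest)),
    stringsAsFactors = FALSE)
}

# baseline positive scale per feature, by measure type
sim_baseline_scale <- function(meta) {
  base <- c("volume" = 3000, "surface area" = 2000, "mean thickness" = 2.5,
            "thickness SD" = 0.5, "mean curvature" = 0.13,
            "Gaussian curvature" = 0.15, "folding index" = 15,
            "curvature index" = 2)
  mu <- base[meta$measure_type]
  mu * exp(stats::rnorm(nrow(meta), 0, 0.4))
}

#' Simulate a morphometric cohort
#'
#' Feature values follow
#' `x = mu_f * (1 - effect[group(f)] * severity) * protocol_factor *
#' dataset_factor * (1 + age_slope * (age - 70)) * lognormal_noise`,
#' where a transition subject's severity is the mean of its baseline and
#' final severities (so such subjects are genuinely ambiguous), and the
#' lognormal noise has the configured coefficient of variation. Baseline
#' scales `mu_f` are drawn once per feature; protocol and dataset factors
#' are drawn once per (tag, feature) pair.
#'
#' @param cfg A [sim_config()].
#' @return A validated [feature_table()].
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  meta <- sim_feature_meta(cfg)
  mu <- sim_baseline_scale(meta)
  effects <- vapply(meta$anatomical_group, function(g) {
    if (g %in% names(cfg$group_effects)) cfg$group_effects[[g]]
    else cfg$group_effects[["other"]]
  }, numeric(1))

  proto_fac <- sapply(cfg$protocols, function(p)
    stats::rnorm(cfg$n_features, 1, cfg$protocol_offset_scale))
  ds_fac <- sapply(cfg$datasets, function(d)
    stats::rnorm(cfg$n_features, 1, cfg$dataset_offset_scale))
  proto_fac <- pmax(proto_fac, 0.5) # keep factors positive
  ds_fac <- pmax(ds_fac, 0.5)
  dim(proto_fac) <- c(cfg$n_features, length(cfg$protocols))
  dim(ds_fac) <- c(cfg$n_features, length(cfg$datasets))
  colnames(proto_fac) <- cfg$protocols
  colnames(ds_fac) <- cfg$datasets

  classes <- names(cfg$n_per_class)[cfg$n_per_class > 0]
  rows <- list(); feats <- list(); k <- 0
  sdlog <- sqrt(log(1 + cfg$noise_cv^2))
  for (cl in classes) {
    n <- cfg$n_per_class[[cl]]
    am <- cfg$age_model[[cl]]
    age <- stats::rnorm(n, am[1], am[2])
    age <- pmin(pmax(age, 45), 95)
    sex <- ifelse(stats::runif(n) < cfg$sex_ratio[[cl]], "M", "F")
    protocol <- sample(cfg$protocols, n, replace = TRUE)
    dataset <- sample(cfg$datasets, n, replace = TRUE)
    tr <- cfg$transition_rates[[cl]]
    baseline <- rep(cl, n)
    if (length(tr)) {
      u <- stats::runif(n)
      cum <- cumsum(tr)
      for (j in seq_along(tr)) {
        lo <- if (j == 1) 0 else cum[j - 1]
        baseline[u >= lo & u < cum[j]] <- names(tr)[j]
      }
    }
    sev_final <- cfg$severity[[cl]]
    sev_base <- cfg$severity[match(baseline, names(cfg$severity))]
    sev <- (sev_base + sev_final) / 2
    followup <- stats::runif(n, 12, 36)
    for (i in seq_len(n)) {
      k <- k + 1
      noise <- stats::rlnorm(cfg$n_features, -sdlog^2 / 2, sdlog)
      x <- mu * (1 - effects * sev[i]) *
        proto_fac[, protocol[i]] * ds_fac[, dataset[i]] *
        (1 + cfg$age_slope * (age[i] - 70)) * noise
      feats[[k]] <- x
      rows[[k]] <- data.frame(
        subject_id = sprintf("S%05d", k), age_at_scan = age[i],
        sex = sex[i], dataset = dataset[i], protocol = protocol[i],
        baseline_dx = baseline[i], final_dx = cl,
        followup_months = followup[i], stringsAsFactors = FALSE)
    }
  }
  metadata <- do.call(rbind, rows)
  fm <- do.call(rbind, feats)
  colnames(fm) <- meta$name
  feature_table(metadata, fm, meta)
}

#' Simulate a labeled prediction set with known accuracy
#'
#' Truth is uniform over classes; each prediction is correct with
#' probability `accuracy` and otherwise uniform over the wrong classes.
#' Supports coverage and calibration tests of the evaluation module.
#'
#' @param n Number of subjects.
#' @param accuracy Probability of a correct prediction, in [0, 1].
#' @param classes Character vector of class labels (default the three
#'   diagnosis levels).
#' @param seed Integer seed.
#' @return data.frame with factor columns `truth` and `pred` sharing levels.
#' @export
simulate_labels_only <- function(n, accuracy, classes = dx_levels(),
                                 seed = 1L) {
  stopifnot(accuracy >= 0, accuracy <= 1, length(classes) >= 2)
  set.seed(seed)
  truth <- sample(classes, n, replace = TRUE)
  correct <- stats::runif(n) < accuracy
  pred <- truth
  if (any(!correct)) {
    pred[!correct] <- vapply(truth[!correct], function(tr)
      sample(setdiff(classes, tr), 1), character(1))
  }
  data.frame(truth = factor(truth, levels = classes),
             pred = factor(pred, levels = classes))
}
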