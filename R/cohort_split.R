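#' @title Constrained train/test cohort splitting
#' @name cohort_split
#' @description
#' Test sets are built to be age-matched across diagnosis groups (pairwise
#' mean-age differences within a tolerance), split evenly between sexes
#' within each diagnosis, and to contain a fixed proportion of every
#' diagnosis-transition type, so that age, sex or transition imbalances in
#' the training data cannot inflate test metrics.
NULL

round_half_up <- function(x) floor(x + 0.5)

#' Split constraints
#'
#' @param test_fraction Fraction of stable subjects per stratum assigned to
#'   the test set (default 0.30).
#' @param age_match_tolerance Maximum allowed pairwise difference of
#'   test-set mean ages between diagnosis groups, in years (default 1.0);
#'   `Inf` disables age matching.
#' @param sex_balanced Balance M/F within each diagnosis in the test set to
#'   within one subject (default `TRUE`).
#' @param transition_fraction Fraction of each transition type assigned to
#'   the test set (default 0.30).
#' @param seed Integer seed for the stratified draw.
#' @param max_passes Bound on greedy age-matching swap passes (default 1000).
#' @return A list of class `split_constraints`.
#' @export
split_constraints <- function(test_fraction = 0.30,
                              age_match_tolerance = 1.0,
                              sex_balanced = TRUE,
                              transition_fraction = 0.30,
                              seed = 1L,
                              max_passes = 1000L) {
  stopifnot(test_fraction > 0, test_fraction < 1,
            transition_fraction > 0, transition_fraction < 1,
            age_match_tolerance >= 0)
  structure(as.list(environment()), class = "split_constraints")
}

# allocate a stratum's test target across sexes, nudging the per-diagnosis
# running M/F totals toward balance
allocate_sexes <- function(target, n_m, n_f, run_m, run_f, balanced) {
  lo <- max(0, target - n_f); hi <- min(target, n_m)
  if (lo > hi) stop("stratum too small for its test target", call. = FALSE)
  if (!balanced) {
    # proportional allocation
    tm <- round_half_up(target * n_m / max(1, n_m + n_f))
    return(c(m = min(max(tm, lo), hi), f = target - min(max(tm, lo), hi)))
  }
  cand <- lo:hi
  imbalance <- abs((run_m + cand) - (run_f + (target - cand)))
  tm <- cand[which.min(imbalance)]
  c(m = tm, f = target - tm)
}

#' Build a constrained train/test split
#'
#' Subjects are drawn per (final diagnosis x sex x transition type) cell so
#' that each transition type contributes `round(fraction * n)` (half-up)
#' subjects to the test set, M/F counts per diagnosis differ by at most one,
#' and greedy same-sex, same-transition-type swaps between train and test
#' bring all pairwise test mean-age differences between diagnosis groups
#' within the tolerance. Deterministic given the seed.
#'
#' @param table A [feature_table()].
#' @param constraints A [split_constraints()].
#' @return List with `train` and `test` (feature tables) and `report`
#'   (per-group counts, mean ages, transition counts, swap log, satisfied
#'   flags).
#' @export
build_split <- function(table, constraints = split_constraints()) {
  stopifnot(inherits(constraints, "split_constraints"))
  set.seed(constraints$seed)
  md <- table$metadata
  n <- nrow(md)
  dx <- as.character(md$final_dx)
  sex <- md$sex
  ttype <- transition_type(table)
  stable <- !is_transition(table)

  in_test <- logical(n)
  for (d in unique(dx)) {
    run_m <- 0; run_f <- 0
    for (tt in unique(ttype[dx == d])) {
      idx <- which(dx == d & ttype == tt)
      frac <- if (startsWith(tt, "stable")) constraints$test_fraction
              else constraints$transition_fraction
      target <- round_half_up(frac * length(idx))
      if (target == 0) next
      im <- idx[sex[idx] == "M"]; jf <- idx[sex[idx] == "F"]
      al <- allocate_sexes(target, length(im), length(jf), run_m, run_f,
                           constraints$sex_balanced)
      pick_m <- if (al[["m"]] > 0) sample(im, al[["m"]]) else integer(0)
      pick_f <- if (al[["f"]] > 0) sample(jf, al[["f"]]) else integer(0)
      in_test[c(pick_m, pick_f)] <- TRUE
      run_m <- run_m + al[["m"]]; run_f <- run_f + al[["f"]]
    }
  }

  # greedy age matching by train/test swaps within (dx, sex, ttype) cells
  age <- md$age_at_scan
  swaps <- 0L
  max_gap <- function() {
    means <- tapply(age[in_test], dx[in_test], mean)
    if (length(means) < 2) return(0)
    max(stats::dist(means))
  }
  tol <- constraints$age_match_tolerance
  if (is.finite(tol)) {
    for (pass in seq_len(constraints$max_passes)) {
      gap <- max_gap()
      if (gap <= tol) break
      means <- tapply(age[in_test], dx[in_test], mean)
      grand <- mean(means)
      # the group whose mean deviates most, moved toward the grand mean
      g <- names(means)[which.max(abs(means - grand))]
      dir_down <- means[[g]] > grand
      test_idx <- which(in_test & dx == g)
      # extreme test subject in the deviating direction
      ord <- order(age[test_idx], decreasing = dir_down)
      improved <- FALSE
      for (s in test_idx[ord[seq_len(min(5, length(ord)))]]) {
        cand <- which(!in_test & dx == g & sex == sex[s] & ttype == ttype[s])
        if (!length(cand)) next
        # train candidate that best moves the mean toward the grand mean
        want <- if (dir_down) cand[which.min(age[cand])]
                else cand[which.max(age[cand])]
        in_test[s] <- FALSE; in_test[want] <- TRUE
        if (max_gap() < gap - 1e-12) { swaps <- swaps + 1L; improved <- TRUE; break }
        in_test[s] <- TRUE; in_test[want] <- FALSE # revert
      }
      if (!improved) break
    }
    final_gap <- max_gap()
    if (final_gap > tol)
      stop(sprintf(paste0("age matching infeasible: closest achieved pairwise",
                          " mean-age gap %.2f y exceeds tolerance %.2f y"),
                   final_gap, tol), call. = FALSE)
  }

  test <- subset_subjects(table, in_test)
  train <- subset_subjects(table, !in_test)
  report <- list(
    n_train = sum(!in_test), n_test = sum(in_test),
    test_age_means = tapply(age[in_test], dx[in_test], mean),
    test_sex_counts = base::table(dx = dx[in_test], sex = sex[in_test]),
    test_transition_counts = base::table(ttype[in_test]),
    transition_targets = vapply(unique(ttype), function(tt) {
      frac <- if (startsWith(tt, "stable")) constraints$test_fraction
              else constraints$transition_fraction
      round_half_up(frac * sum(ttype == tt))
    }, numeric(1)),
    n_swaps = swaps,
    age_gap = if (sum(in_test) && length(unique(dx[in_test])) > 1)
      max(stats::dist(tapply(age[in_test], dx[in_test], mean))) else 0)
  report$age_matched <- report$age_gap <= constraints$age_match_tolerance
  list(train = train, test = test, report = report)
}

#' Stratified 70/30 split (convenience wrapper)
#'
#' Plain stratified split by final diagnosis and transition type; age
#' matching and sex balancing are applied when a full
#' [split_constraints()] is supplied.
#'
#' @param table A [feature_table()].
#' @param test_fraction Test fraction (default 0.30).
#' @param constraints Optional [split_constraints()]; when `NULL`, sex
#'   balancing and age matching are disabled.
#' @param seed Integer seed.
#' @return List with `train`, `test`, `report` as in [build_split()].
#' @export
stratified_split <- function(table, test_fraction = 0.30,
                             constraints = NULL, seed = 1L) {
  if (is.null(constraints))
    constraints <- split_constraints(test_fraction = test_fraction,
                                     age_match_tolerance = Inf,
                                     sex_balanced = FALSE,
                                     transition_fraction = test_fraction,
                                     seed = seed)
  build_split(table, constraints)
}
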