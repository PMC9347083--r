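#' @title Canonical data model: subjects, diagnoses and morphometric features
#' @name feature_table
#' @description
#' The whole pipeline operates on a `feature_table`: per-subject metadata
#' (age, sex, dataset and acquisition-protocol tags, baseline and follow-up
#' diagnosis), a numeric subjects-by-features matrix, and per-feature
#' metadata (anatomical group, measure type, and whether the feature is a
#' regional volume used as a graph node).
NULL

#' Diagnosis severity levels, in increasing order
#'
#' The three diagnostic classes form a fixed severity ordering:
#' healthy control (HC) < mild cognitive impairment (MCI) < Alzheimer's
#' disease (AD).
#'
#' @return Character vector `c("HC", "MCI", "AD")`.
#' @export
dx_levels <- function() c("HC", "MCI", "AD")

#' Normalize diagnosis tokens to the canonical HC/MCI/AD labels
#'
#' Tokens are matched case-insensitively: `HC`, `CN` and `CONTROL` map to
#' `HC`; `MCI` maps to `MCI`; `AD` and `DEMENTIA-AD` map to `AD`. Anything
#' else is an error (no silent coercion).
#'
#' @param x Character vector of diagnosis tokens.
#' @return Ordered factor with levels `HC < MCI < AD`.
#' @export
normalize_dx <- function(x) {
  tok <- toupper(trimws(as.character(x)))
  map <- c(HC = "HC", CN = "HC", CONTROL = "HC",
           MCI = "MCI",
           AD = "AD", "DEMENTIA-AD" = "AD")
  out <- unname(map[tok])
  if (anyNA(out)) {
    bad <- unique(tok[is.na(out)])
    stop("unrecognized diagnosis token(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  factor(out, levels = dx_levels(), ordered = TRUE)
}

#' Measure types recognized in feature metadata
#' @return Character vector of the eight morphometric measure types plus
#'   `"graph"`, used for derived graph-theory columns.
#' @export
measure_types <- function() {
  c("surface area", "volume", "mean thickness", "thickness SD",
    "mean curvature", "Gaussian curvature", "folding index",
    "curvature index", "graph")
}

#' Anatomical groups recognized in feature metadata
#' @return Character vector of group labels.
#' @export
anatomical_groups <- function() {
  c("hippocampus", "temporal", "cingulate", "frontal", "parietal",
    "occipital", "insula", "subcortical", "white-matter",
    "ventricles/CSF", "other")
}

#' Construct a validated feature table
#'
#' @param metadata data.frame with columns `subject_id`, `age_at_scan`,
#'   `sex` (`"M"`/`"F"`), `dataset`, `protocol`, `baseline_dx`, `final_dx`,
#'   `followup_months`. Diagnosis columns accept any token understood by
#'   [normalize_dx()].
#' @param features Numeric matrix, one row per subject in metadata order;
#'   column names are feature names.
#' @param meta data.frame with columns `name`, `anatomical_group`,
#'   `measure_type`, `is_graph_node`, one row per feature column.
#' @return An object of class `feature_table` with elements `metadata`,
#'   `features`, `meta`.
#' @export
feature_table <- function(metadata, features, meta) {
  required <- c("subject_id", "age_at_scan", "sex", "dataset", "protocol",
                "baseline_dx", "final_dx", "followup_months")
  missing_cols <- setdiff(required, names(metadata))
  if (length(missing_cols))
    stop("metadata is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  metadata <- as.data.frame(metadata, stringsAsFactors = FALSE)
  metadata$subject_id <- as.character(metadata$subject_id)
  if (anyDuplicated(metadata$subject_id))
    stop("duplicated subject_id in metadata", call. = FALSE)
  metadata$baseline_dx <- normalize_dx(metadata$baseline_dx)
  metadata$final_dx <- normalize_dx(metadata$final_dx)
  metadata$sex <- as.character(metadata$sex)
  if (!all(metadata$sex %in% c("M", "F")))
    stop("sex must be 'M' or 'F'", call. = FALSE)
  metadata$age_at_scan <- as.numeric(metadata$age_at_scan)
  if (any(!is.finite(metadata$age_at_scan)) || any(metadata$age_at_scan <= 0))
    stop("age_at_scan must be finite and > 0", call. = FALSE)
  metadata$followup_months <- as.numeric(metadata$followup_months)
  metadata$dataset <- as.character(metadata$dataset)
  metadata$protocol <- as.character(metadata$protocol)

  features <- as.matrix(features)
  storage.mode(features) <- "double"
  if (nrow(features) != nrow(metadata))
    stop("features has ", nrow(features), " rows but metadata has ",
         nrow(metadata), " subjects", call. = FALSE)
  if (is.null(colnames(features)))
    stop("features must have column names", call. = FALSE)
  if (anyNA(features)) {
    idx <- which(is.na(features), arr.ind = TRUE)[1, ]
    stop("missing feature value at subject '", metadata$subject_id[idx[1]],
         "', feature '", colnames(features)[idx[2]], "'", call. = FALSE)
  }
  rownames(features) <- metadata$subject_id

  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  needed <- c("name", "anatomical_group", "measure_type", "is_graph_node")
  if (!all(needed %in% names(meta)))
    stop("feature meta must have columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  if (!identical(as.character(meta$name), colnames(features)))
    stop("feature meta names do not match feature columns (order-sensitive)",
         call. = FALSE)
  bad_mt <- setdiff(unique(meta$measure_type), measure_types())
  if (length(bad_mt))
    stop("unknown measure_type token(s): ", paste(bad_mt, collapse = ", "),
         call. = FALSE)
  bad_gr <- setdiff(unique(meta$anatomical_group), anatomical_groups())
  if (length(bad_gr))
    stop("unknown anatomical_group token(s): ", paste(bad_gr, collapse = ", "),
         call. = FALSE)
  meta$is_graph_node <- as.logical(meta$is_graph_node)
  if (any(meta$is_graph_node & meta$measure_type != "volume"))
    stop("is_graph_node requires measure_type 'volume'", call. = FALSE)

  structure(list(metadata = metadata, features = features, meta = meta),
            class = "feature_table")
}

#' @method print feature_table
#' @export
print.feature_table <- function(x, ...) {
  cat("feature_table:", nrow(x$features), "subjects x",
      ncol(x$features), "features (",
      sum(x$meta$is_graph_node), "graph nodes )\n")
  print(table(final_dx = x$metadata$final_dx))
  invisible(x)
}

#' Number of subjects in a feature table
#' @param table A `feature_table`.
#' @return Integer subject count.
#' @export
n_subjects <- function(table) nrow(table$features)

#' Subset a feature table by subject index
#'
#' @param table A `feature_table`.
#' @param i Integer or logical index over subjects.
#' @return A `feature_table` with the selected subjects, feature columns
#'   untouched.
#' @export
subset_subjects <- function(table, i) {
  feature_table(table$metadata[i, , drop = FALSE],
                table$features[i, , drop = FALSE],
                table$meta)
}

#' Flag subjects whose diagnosis changed between scan and follow-up
#' @param table A `feature_table`.
#' @return Logical vector, `TRUE` where baseline and final diagnosis differ.
#' @export
is_transition <- function(table) {
  as.character(table$metadata$baseline_dx) != as.character(table$metadata$final_dx)
}

#' Transition type label per subject ("HC>MCI", "stable-AD", ...)
#' @param table A `feature_table`.
#' @return Character vector of transition-type labels; stable subjects are
#'   labelled `stable-<dx>`.
#' @export
transition_type <- function(table) {
  b <- as.character(table$metadata$baseline_dx)
  f <- as.character(table$metadata$final_dx)
  ifelse(b == f, paste0("stable-", f), paste0(b, ">", f))
}

#' Enforce the follow-up inclusion window
#'
#' Subjects whose follow-up diagnosis was made less than `min_months` or more
#' than `max_months` after the scan are excluded, with a message giving the
#' exclusion count. This mirrors the study-inclusion rule that the
#' ground-truth diagnosis be at least one year and at most three years after
#' the selected scan.
#'
#' @param table A `feature_table`.
#' @param min_months,max_months Window bounds in months (defaults 12 and 36).
#' @return The filtered `feature_table`.
#' @export
filter_followup_window <- function(table, min_months = 12, max_months = 36) {
  keep <- table$metadata$followup_months >= min_months &
    table$metadata$followup_months <= max_months
  if (!all(keep))
    message("filter_followup_window: excluded ", sum(!keep), " of ",
            length(keep), " subjects outside [", min_months, ", ",
            max_months, "] months")
  subset_subjects(table, keep)
}

#' Read a feature table from its three delimited text files
#'
#' The canonical on-disk layout is three UTF-8 comma-separated files:
#' `<prefix>_metadata.csv`, `<prefix>_features.csv` (with a `subject_id` key
#' column), and `<prefix>_meta.csv` (per-feature metadata). Subject
#' identifier sets must agree between metadata and features; features are
#' reordered to metadata order.
#'
#' @param metadata_path,features_path,meta_path Paths to the three files.
#' @return A validated [feature_table()].
#' @export
read_feature_table <- function(metadata_path, features_path, meta_path) {
  for (p in c(metadata_path, features_path, meta_path))
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  metadata <- utils::read.csv(metadata_path, stringsAsFactors = FALSE,
                              colClasses = c(subject_id = "character"))
  feats <- utils::read.csv(features_path, stringsAsFactors = FALSE,
                           check.names = FALSE,
                           colClasses = c(subject_id = "character"))
  meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (!"subject_id" %in% names(feats))
    stop("features file must have a subject_id column", call. = FALSE)
  only_meta <- setdiff(metadata$subject_id, feats$subject_id)
  only_feat <- setdiff(feats$subject_id, metadata$subject_id)
  if (length(only_meta) || length(only_feat))
    stop("subject sets disagree between metadata and features; only in ",
         "metadata: [", paste(only_meta, collapse = ", "), "]; only in ",
         "features: [", paste(only_feat, collapse = ", "), "]", call. = FALSE)
  feats <- feats[match(metadata$subject_id, feats$subject_id), , drop = FALSE]
  fm <- as.matrix(feats[, setdiff(names(feats), "subject_id"), drop = FALSE])
  if (nrow(fm) > 0 && anyNA(suppressWarnings({storage.mode(fm) <- "double"; fm}))) {
    idx <- which(is.na(fm), arr.ind = TRUE)[1, ]
    stop("missing/non-numeric feature value at subject '",
         metadata$subject_id[idx[1]], "', feature '",
         colnames(fm)[idx[2]], "'", call. = FALSE)
  }
  storage.mode(fm) <- "double"
  feature_table(metadata, fm, meta)
}

#' Read a FreeSurfer-style stats-table export
#'
#' Optional convenience reader for tab-separated tables as produced by
#' FreeSurfer's table exporters (one row per subject, first column the
#' subject identifier, one column per regional measure). The caller
#' supplies the per-column feature metadata (`meta_map`) and the subject
#' metadata file; columns of the stats table not named in `meta_map` are
#' ignored. This is a thin front end: the canonical on-disk layout is the
#' three-file form of [read_feature_table()].
#'
#' @param stats_path Path to the tab-separated stats table.
#' @param metadata_path Path to the subject metadata CSV (same schema as
#'   [read_feature_table()]).
#' @param meta_map data.frame with columns `name`, `anatomical_group`,
#'   `measure_type`, `is_graph_node`; `name` must match stats-table column
#'   headers.
#' @return A validated [feature_table()].
#' @export
read_freesurfer_stats <- function(stats_path, metadata_path, meta_map) {
  if (!file.exists(stats_path)) stop("file not found: ", stats_path,
                                     call. = FALSE)
  stats <- utils::read.delim(stats_path, stringsAsFactors = FALSE,
                             check.names = FALSE)
  if (ncol(stats) < 2) stop("stats table needs an id column plus features",
                            call. = FALSE)
  names(stats)[1] <- "subject_id"
  stats$subject_id <- as.character(stats$subject_id)
  missing_cols <- setdiff(meta_map$name, names(stats))
  if (length(missing_cols))
    stop("stats table lacks mapped column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  metadata <- utils::read.csv(metadata_path, stringsAsFactors = FALSE,
                              colClasses = c(subject_id = "character"))
  only_meta <- setdiff(metadata$subject_id, stats$subject_id)
  if (length(only_meta))
    stop("subjects missing from stats table: ",
         paste(only_meta, collapse = ", "), call. = FALSE)
  stats <- stats[match(metadata$subject_id, stats$subject_id), , drop = FALSE]
  fm <- as.matrix(stats[, meta_map$name, drop = FALSE])
  storage.mode(fm) <- "double"
  feature_table(metadata, fm, meta_map)
}

#' Write a feature table to three delimited text files
#'
#' Values are serialized at full precision (17 significant digits) so that
#' `read_feature_table()` reproduces the table value-identically.
#'
#' @param table A `feature_table`.
#' @param out_prefix Path prefix; `<prefix>_metadata.csv`,
#'   `<prefix>_features.csv` and `<prefix>_meta.csv` are written.
#' @return Invisibly, the three file paths.
#' @export
write_feature_table <- function(table, out_prefix) {
  dir <- dirname(out_prefix)
  if (!dir.exists(dir)) stop("directory does not exist: ", dir, call. = FALSE)
  paths <- paste0(out_prefix, c("_metadata.csv", "_features.csv", "_meta.csv"))
  md <- table$metadata
  md$baseline_dx <- as.character(md$baseline_dx)
  md$final_dx <- as.character(md$final_dx)
  utils::write.csv(md, paths[1], row.names = FALSE, quote = TRUE)
  fm <- table$features
  df <- data.frame(subject_id = table$metadata$subject_id,
                   stringsAsFactors = FALSE, check.names = FALSE)
  for (j in seq_len(ncol(fm)))
    df[[colnames(fm)[j]]] <- sprintf("%.17g", fm[, j])
  utils::write.csv(df, paths[2], row.names = FALSE, quote = TRUE)
  utils::write.csv(table$meta, paths[3], row.names = FALSE, quote = TRUE)
  invisible(paths)
}
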