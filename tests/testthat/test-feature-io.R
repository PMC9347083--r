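test_that("diagnosis tokens normalize case-insensitively and errors are loud", {
  expect_equal(as.character(normalize_dx(c("hc", "CN", "Control", "mci",
                                           "AD", "dementia-ad"))),
               c("HC", "HC", "HC", "MCI", "AD", "AD"))
  expect_true(is.ordered(normalize_dx("HC")))
  expect_true(normalize_dx("HC") < normalize_dx("AD"))
  expect_error(normalize_dx("SCD"), "unrecognized diagnosis")
})

test_that("fixture table validates: counts, node flags, transitions", {
  tab <- tiny_table()
  expect_equal(n_subjects(tab), 3)
  expect_equal(ncol(tab$features), 5)
  expect_equal(sum(tab$meta$is_graph_node), 2)
  expect_equal(tab$meta$measure_type[tab$meta$is_graph_node],
               rep("volume", 2))
  expect_false(any(is_transition(tab)))
  tab$metadata$baseline_dx[2] <- "MCI"
  tab$metadata$final_dx[2] <- "AD"
  t2 <- feature_table(tab$metadata, tab$features, tab$meta)
  expect_equal(is_transition(t2), c(FALSE, TRUE, FALSE))
  expect_equal(transition_type(t2)[2], "MCI>AD")
})

test_that("validation rejects missing values, bad tokens and node flags", {
  tab <- tiny_table()
  f2 <- tab$features; f2[2, 3] <- NA
  expect_error(feature_table(tab$metadata, f2, tab$meta), "s2.*thick")
  m2 <- tab$meta; m2$measure_type[1] <- "voxels"
  expect_error(feature_table(tab$metadata, tab$features, m2),
               "unknown measure_type")
  m3 <- tab$meta; m3$is_graph_node[3] <- TRUE # a thickness column
  expect_error(feature_table(tab$metadata, tab$features, m3),
               "requires measure_type 'volume'")
  md <- tab$metadata; md$sex[1] <- "X"
  expect_error(feature_table(md, tab$features, tab$meta), "sex")
})

test_that("read-write-read round trip is value-identical", {
  dir <- withr::local_tempdir()
  tab <- tiny_table()
  write_feature_table(tab, file.path(dir, "tiny"))
  back <- read_feature_table(file.path(dir, "tiny_metadata.csv"),
                             file.path(dir, "tiny_features.csv"),
                             file.path(dir, "tiny_meta.csv"))
  expect_identical(back$features, tab$features)
  expect_equal(back$metadata, tab$metadata)
  expect_equal(back$meta, tab$meta)
  # idempotence on re-write
  write_feature_table(back, file.path(dir, "tiny2"))
  again <- read_feature_table(file.path(dir, "tiny2_metadata.csv"),
                              file.path(dir, "tiny2_features.csv"),
                              file.path(dir, "tiny2_meta.csv"))
  expect_identical(again$features, tab$features)
})

test_that("synthetic cohort round trip preserves every value and mean", {
  dir <- withr::local_tempdir()
  tab <- simulate_cohort(sim_config(n_per_class = c(HC = 40, MCI = 30,
                                                    AD = 30),
                                    n_features = 25, n_graph_nodes = 6,
                                    seed = 5))
  write_feature_table(tab, file.path(dir, "cohort"))
  back <- read_feature_table(file.path(dir, "cohort_metadata.csv"),
                             file.path(dir, "cohort_features.csv"),
                             file.path(dir, "cohort_meta.csv"))
  expect_identical(back$features, tab$features)
  expect_equal(colMeans(back$features), colMeans(tab$features))
})

test_that("subject-set disagreement between files is a located error", {
  dir <- withr::local_tempdir()
  tab <- tiny_table()
  write_feature_table(tab, file.path(dir, "t"))
  md <- utils::read.csv(file.path(dir, "t_metadata.csv"))
  md$subject_id[3] <- "s99"
  utils::write.csv(md, file.path(dir, "t_metadata.csv"), row.names = FALSE)
  expect_error(read_feature_table(file.path(dir, "t_metadata.csv"),
                                  file.path(dir, "t_features.csv"),
                                  file.path(dir, "t_meta.csv")),
               "s99")
})

test_that("empty (0-subject) table writes and reads as headers only", {
  dir <- withr::local_tempdir()
  tab <- tiny_table()
  empty <- subset_subjects(tab, integer(0))
  write_feature_table(empty, file.path(dir, "e"))
  back <- read_feature_table(file.path(dir, "e_metadata.csv"),
                             file.path(dir, "e_features.csv"),
                             file.path(dir, "e_meta.csv"))
  expect_equal(n_subjects(back), 0)
  expect_equal(colnames(back$features), colnames(tab$features))
})

test_that("the FreeSurfer stats-table reader maps columns through meta", {
  dir <- withr::local_tempdir()
  tab <- tiny_table()
  md <- tab$metadata
  md$baseline_dx <- as.character(md$baseline_dx)
  md$final_dx <- as.character(md$final_dx)
  utils::write.csv(md, file.path(dir, "meta.csv"), row.names = FALSE)
  stats <- data.frame(Measure = tab$metadata$subject_id,
                      extra_col = 1:3, check.names = FALSE)
  for (j in seq_len(ncol(tab$features)))
    stats[[colnames(tab$features)[j]]] <- tab$features[, j]
  utils::write.table(stats, file.path(dir, "aparc.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  got <- read_freesurfer_stats(file.path(dir, "aparc.tsv"),
                               file.path(dir, "meta.csv"), tab$meta)
  expect_equal(got$features, tab$features)
  expect_equal(got$meta, tab$meta)
  bad_map <- tab$meta; bad_map$name[1] <- "nonexistent"
  expect_error(read_freesurfer_stats(file.path(dir, "aparc.tsv"),
                                     file.path(dir, "meta.csv"), bad_map),
               "nonexistent")
})

test_that("follow-up window filter logs and drops out-of-window subjects", {
  tab <- tiny_table()
  tab$metadata$followup_months[1] <- 6
  t2 <- feature_table(tab$metadata, tab$features, tab$meta)
  expect_message(out <- filter_followup_window(t2), "excluded 1 of 3")
  expect_equal(n_subjects(out), 2)
  expect_false("s1" %in% out$metadata$subject_id)
})
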