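make_demo_cohort <- function(n_pat, n_ctl, sex_pat, sex_ctl,
                             age_pat = NULL, age_ctl = NULL, seed = 1) {
  cohort <- generate_cohort(synth_config(n_patients = n_pat,
                                         n_controls = n_ctl,
                                         n_timepoints = 20, seed = seed),
                            default_atlas())
  k <- 0
  for (i in seq_along(cohort$subjects)) {
    s <- cohort$subjects[[i]]
    if (s$group == "patient") {
      j <- sum(vapply(cohort$subjects[seq_len(i)], `[[`, "", "group")
               == "patient")
      cohort$subjects[[i]]$sex <- sex_pat[j]
      if (!is.null(age_pat)) cohort$subjects[[i]]$age_years <- age_pat[j]
    } else {
      j <- sum(vapply(cohort$subjects[seq_len(i)], `[[`, "", "group")
               == "control")
      cohort$subjects[[i]]$sex <- sex_ctl[j]
      if (!is.null(age_ctl)) cohort$subjects[[i]]$age_years <- age_ctl[j]
    }
  }
  cohort
}

test_that("the sex Chi-squared statistic matches an expected-counts hand computation", {
  # the study's sex split: patients 26F/5M, controls 8F/9M
  cohort <- make_demo_cohort(31, 17,
                             c(rep("F", 26), rep("M", 5)),
                             c(rep("F", 8), rep("M", 9)))
  tab <- demographics_table(cohort)
  obs <- matrix(c(26, 5, 8, 9), 2, byrow = TRUE)
  expected <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  x2_hand <- sum((obs - expected)^2 / expected)
  uncorrected <- tab[tab$test == "Chi-squared (uncorrected)", ]
  expect_equal(uncorrected$statistic, x2_hand, tolerance = 1e-10)
  expect_equal(uncorrected$df, 1)
  # Yates correction shrinks the statistic on a 2x2 table
  corrected <- tab[tab$test == "Chi-squared (Yates-corrected)", ]
  x2_yates <- sum((abs(obs - expected) - 0.5)^2 / expected)
  expect_equal(corrected$statistic, x2_yates, tolerance = 1e-10)
  expect_lt(corrected$statistic, uncorrected$statistic)
})

test_that("identical age distributions give a Mann-Whitney p near 1", {
  ages <- rep(c(21L, 24L, 27L, 30L, 33L), 4)
  cohort <- make_demo_cohort(20, 20, rep(c("F", "M"), 10),
                             rep(c("F", "M"), 10),
                             age_pat = ages, age_ctl = ages)
  tab <- demographics_table(cohort)
  mw <- tab[tab$test == "Mann-Whitney U", ]
  expect_gt(mw$p_value, 0.95)
})

test_that("degenerate demographics are handled explicitly", {
  one_sex <- make_demo_cohort(4, 4, rep("F", 4), rep("F", 4))
  tab <- demographics_table(one_sex)
  expect_true("skipped (constant)" %in% tab$test[tab$variable == "sex"])

  only_pat <- generate_cohort(synth_config(n_patients = 3, n_controls = 2,
                                           n_timepoints = 20, seed = 2),
                              default_atlas())
  only_pat$subjects <- Filter(function(s) s$group == "patient",
                              only_pat$subjects)
  expect_error(demographics_table(only_pat), "non-empty")
})

test_that("run_config demands exactly one input source", {
  expect_error(run_config(out_dir = tempdir()), "exactly one")
  expect_error(run_config(out_dir = tempdir(), cohort_dir = "x",
                          synth = synth_config()), "exactly one")
})

test_that("the pipeline runs end to end and writes a checksummed manifest", {
  out <- withr::local_tempdir()
  cfg <- run_config(
    out_dir = out, seed = 5,
    synth = synth_config(n_patients = 8, n_controls = 6, n_timepoints = 60,
                         fc_effects = list(list(region_a = "L_45",
                                                region_b = "L_44",
                                                delta = -0.8))),
    grid = list(model_spec(0.3, 2, 15, 0), model_spec(0.1, 3, 15, 0)),
    default_spec = model_spec(0.3, 3, 15, 0))
  res <- suppressMessages(run_pipeline(cfg))
  expected_files <- c("demographics.csv", "classification.json",
                      "feature_importance.csv", "network_importance.csv",
                      "mad_counts.csv", "mad_summary.csv",
                      "pagerank_heatmap.csv", "pagerank_table.csv",
                      "pagerank_flags.csv", "manifest.json")
  expect_true(all(file.exists(file.path(out, expected_files))))
  checksummed <- sort(setdiff(expected_files, "manifest.json"))
  expect_setequal(names(res$manifest$checksums), checksummed)
  # manifest checksums describe the written files
  sums <- tools::md5sum(file.path(out, checksummed))
  expect_identical(unname(sums),
                   unlist(res$manifest$checksums, use.names = FALSE))
})

test_that("requesting centrality without structural matrices is a clear error", {
  dir <- withr::local_tempdir()
  cohort <- generate_cohort(synth_config(n_patients = 3, n_controls = 3,
                                         n_timepoints = 30, seed = 4),
                            default_atlas())
  write_cohort(cohort, dir)
  cfg <- run_config(out_dir = withr::local_tempdir(), cohort_dir = dir,
                    structural = TRUE)
  expect_error(suppressMessages(run_pipeline(cfg)), "structural")
})
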