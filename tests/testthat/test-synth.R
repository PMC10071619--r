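# Analytic correlation of the generative model for a planted pair in
# different networks: cov = delta, var = coupling^2/(1 - phi^2) +
# noise^2 + |delta| per region.
planted_pair_correlation <- function(delta, coupling = 1, noise_sd = 1,
                                     phi = 0.3, same_network = FALSE) {
  v_lat <- coupling^2 / (1 - phi^2)
  v <- v_lat + noise_sd^2 + abs(delta)
  base_cov <- if (same_network) v_lat else 0
  (base_cov + delta) / v
}

test_that("default configuration reproduces the study group sizes", {
  cohort <- memo("default_cohort", generate_cohort(synth_config(seed = 7),
                                                   default_atlas()))
  groups <- vapply(cohort$subjects, `[[`, "", "group")
  expect_identical(sum(groups == "patient"), 31L)
  expect_identical(sum(groups == "control"), 17L)
  sex <- vapply(cohort$subjects, `[[`, "", "sex")
  expect_identical(sum(sex == "F" & groups == "patient"), 26L)
  expect_identical(sum(sex == "F" & groups == "control"), 8L)
  expect_true(all(vapply(cohort$subjects,
                         function(s) ncol(s$timeseries) == 379L &&
                           !anyNA(s$timeseries), logical(1))))
})

test_that("generation is bit-reproducible from the seed", {
  cfg <- synth_config(n_patients = 3, n_controls = 3, n_timepoints = 50,
                      seed = 42)
  a <- generate_cohort(cfg, default_atlas(), structural = TRUE)
  b <- generate_cohort(cfg, default_atlas(), structural = TRUE)
  expect_identical(a$subjects, b$subjects)
})

test_that("adding patients does not perturb control data", {
  atlas <- default_atlas()
  small <- generate_cohort(synth_config(n_patients = 2, n_controls = 3,
                                        n_timepoints = 40, seed = 9), atlas)
  large <- generate_cohort(synth_config(n_patients = 5, n_controls = 3,
                                        n_timepoints = 40, seed = 9), atlas)
  ctl <- function(ch) Filter(function(s) s$group == "control", ch$subjects)
  expect_identical(ctl(small), ctl(large))
})

test_that("planted pair effect shifts group mean FC as the analytic model predicts", {
  atlas <- default_atlas()
  delta <- -0.4
  cfg <- synth_config(n_patients = 200, n_controls = 200,
                      fc_effects = list(list(region_a = "L_45",
                                             region_b = "L_23c",
                                             delta = delta)),
                      seed = 13)
  cohort <- generate_cohort(cfg, atlas)
  ia <- match("L_45", atlas$name); ib <- match("L_23c", atlas$name)
  r <- vapply(cohort$subjects, function(s)
    stats::cor(s$timeseries[, ia], s$timeseries[, ib]), numeric(1))
  groups <- vapply(cohort$subjects, `[[`, "", "group")
  r_pat <- mean(r[groups == "patient"])
  r_ctl <- mean(r[groups == "control"])
  expect_lt(r_pat, r_ctl)
  expect_lt(abs(r_ctl - 0), 0.02)
  expect_lt(abs(r_pat - planted_pair_correlation(delta)), 0.02)
})

test_that("larger planted effects produce larger group FC differences", {
  atlas <- default_atlas()
  gap <- vapply(c(-0.2, -0.5, -0.9), function(delta) {
    cfg <- synth_config(n_patients = 60, n_controls = 60, n_timepoints = 150,
                        fc_effects = list(list(region_a = "L_45",
                                               region_b = "L_23c",
                                               delta = delta)),
                        seed = 77)
    cohort <- generate_cohort(cfg, atlas)
    ia <- match("L_45", atlas$name); ib <- match("L_23c", atlas$name)
    r <- vapply(cohort$subjects, function(s)
      stats::cor(s$timeseries[, ia], s$timeseries[, ib]), numeric(1))
    groups <- vapply(cohort$subjects, `[[`, "", "group")
    abs(mean(r[groups == "patient"]) - mean(r[groups == "control"]))
  }, numeric(1))
  expect_true(all(diff(gap) > 0))
})

test_that("effects naming unknown regions are rejected", {
  cfg <- synth_config(n_patients = 2, n_controls = 2, n_timepoints = 20,
                      fc_effects = list(list(region_a = "L_Nowhere",
                                             region_b = "L_45",
                                             delta = 0.3)))
  expect_error(generate_cohort(cfg, default_atlas()), "unknown region")
  expect_error(synth_config(hub_effects = list(list(region = "L_45",
                                                    factor = -1))),
               "positive")
})

test_that("structural connectomes are symmetric integer matrices near the streamline budget", {
  cfg <- synth_config(seed = 21)
  sc <- generate_structural_connectome(cfg, "control", default_atlas())
  expect_identical(sc, t(sc))
  expect_true(all(sc >= 0))
  expect_true(all(diag(sc) == 0))
  expect_true(all(sc == round(sc)))
  expect_lt(abs(sum(sc) / 2 - 300000), 379)
})

test_that("hub boosts raise the boosted region's expected node strength", {
  atlas <- default_atlas()
  cfg <- synth_config(hub_effects = list(list(region = "R_Amygdala",
                                              factor = 1.5)), seed = 33)
  i <- match("R_Amygdala", atlas$name)
  rel_strength <- function(group, draw) {
    sc <- generate_structural_connectome(cfg, group, atlas, draw = draw)
    sum(sc[i, ]) / sum(sc)
  }
  pat <- vapply(1:30, function(d) rel_strength("patient", d), numeric(1))
  ctl <- vapply(1:30, function(d) rel_strength("control", d), numeric(1))
  expect_gt(mean(pat), mean(ctl))
  expect_gt(min(pat), max(ctl) * 0.9)
})

test_that("cohorts round-trip through the on-disk format", {
  cohort <- generate_cohort(synth_config(n_patients = 2, n_controls = 3,
                                         n_timepoints = 30, seed = 3),
                            default_atlas(), structural = TRUE)
  dir <- withr::local_tempdir()
  write_cohort(cohort, dir)
  back <- read_cohort(dir)
  expect_identical(vapply(back$subjects, `[[`, "", "subject_id"),
                   vapply(cohort$subjects, `[[`, "", "subject_id"))
  expect_equal(back$subjects[[1]]$timeseries,
               cohort$subjects[[1]]$timeseries, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(unname(back$subjects[[5]]$structural),
               unname(cohort$subjects[[5]]$structural))
  expect_identical(as.data.frame(back$atlas), as.data.frame(cohort$atlas))
})
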