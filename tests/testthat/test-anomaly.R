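test_that("control reference reproduces hand-computed medians and MADs", {
  controls <- rbind(c(1, 1, 1), c(2, 7, 2), c(3, 7, 3), c(4, 7, 4),
                    c(5, 7, 100))
  colnames(controls) <- c("p1", "p2", "p3")
  ref <- control_reference(controls)
  expect_equal(unname(ref$median), c(3, 7, 3))
  # {1,2,3,4,5}: MAD 1; {1,7,7,7,7}: MAD 0; {1,2,3,4,100}: MAD 1 (robust)
  expect_equal(unname(ref$mad), c(1, 0, 1))
  expect_identical(unname(ref$evaluable), c(TRUE, FALSE, TRUE))
  expect_error(control_reference(controls[1:2, ]), "at least 3")
})

test_that("the scaled variant applies the normal-consistency constant", {
  controls <- matrix(c(1:5), 5, 1, dimnames = list(NULL, "f"))
  expect_equal(unname(control_reference(controls, scaled = TRUE)$mad),
               1.4826)
})

test_that("a patient at the control medians has zero anomalies everywhere", {
  feats <- planted_feats_small()
  ctl <- feats$X[feats$group == "control", ]
  ref <- control_reference(ctl)
  counts <- count_anomalies(ref$median, ref, default_atlas())
  expect_true(all(counts == 0))
})

test_that("the 3-MAD threshold is inclusive and non-evaluable features never count", {
  atlas <- default_atlas()
  # two features: L_45-L_44 within Language; L_45-L_23c Language x Salience
  f <- c("L_44|L_45" = 0.2, "L_23c|L_45" = 0.1)
  controls <- rbind(c(0.20, 0.10), c(0.25, 0.10), c(0.15, 0.10),
                    c(0.30, 0.10), c(0.10, 0.10))
  colnames(controls) <- names(f)
  ref <- control_reference(controls)
  # feature 1: median 0.2, MAD 0.05; feature 2: constant, MAD 0
  patient <- c(0.35, 99)  # deviation exactly 3 MADs; huge but non-evaluable
  counts <- count_anomalies(patient, ref, atlas)
  expect_equal(unname(counts["Language"]), 1)
  expect_equal(sum(counts), 1)

  just_below <- count_anomalies(c(0.3499, 99), ref, atlas)
  expect_equal(sum(just_below), 0)
})

test_that("cross-network anomalies credit both endpoint networks", {
  atlas <- default_atlas()
  f <- c("L_23c|L_45" = 0)  # Language x Salience
  controls <- matrix(c(0, 0.05, -0.05, 0.02, -0.02), 5, 1,
                     dimnames = list(NULL, names(f)))
  ref <- control_reference(controls)
  counts <- count_anomalies(c(1), ref, atlas)
  expect_equal(unname(counts["Language"]), 1)
  expect_equal(unname(counts["Salience"]), 1)
  half <- count_anomalies(c(1), ref, atlas, cross_credit = "half")
  expect_equal(unname(half["Language"]), 0.5)
  expect_equal(unname(half["Salience"]), 0.5)
})

test_that("counts match a brute-force per-feature recount", {
  atlas <- default_atlas()
  feats <- planted_feats_small()
  set.seed(123)
  keep <- sample(seq_len(ncol(feats$X)), 1000)
  X <- feats$X[, sort(keep)]
  ref <- control_reference(X[feats$group == "control", ])
  patient <- X[1, ]
  counts <- count_anomalies(patient, ref, atlas)

  nets <- sort(unique(atlas$network))
  brute <- stats::setNames(numeric(length(nets)), nets)
  n_within <- 0; n_cross <- 0
  for (j in seq_along(patient)) {
    if (!ref$evaluable[j]) next
    if (abs(patient[j] - ref$median[j]) / ref$mad[j] >= 3) {
      regs <- strsplit(names(patient)[j], "|", fixed = TRUE)[[1]]
      na <- network_of(atlas, regs[1]); nb <- network_of(atlas, regs[2])
      if (na == nb) {
        brute[na] <- brute[na] + 1; n_within <- n_within + 1
      } else {
        brute[na] <- brute[na] + 1; brute[nb] <- brute[nb] + 1
        n_cross <- n_cross + 1
      }
    }
  }
  expect_equal(as.numeric(counts), as.numeric(brute))
  expect_equal(sum(counts), n_within + 2 * n_cross)
})

test_that("feature misalignment is rejected", {
  controls <- matrix(rnorm(15), 5, 3,
                     dimnames = list(NULL, c("L_44|L_45", "L_23c|L_45",
                                             "L_44|L_55b")))
  ref <- control_reference(controls)
  expect_error(count_anomalies(rnorm(2), ref, default_atlas()),
               "mismatch")
  bad_names <- stats::setNames(rnorm(3), c("L_44|L_45", "L_44|L_55b",
                                           "L_23c|L_45"))
  expect_error(count_anomalies(bad_names, ref, default_atlas()),
               "mismatch")
})

test_that("perturbing many pairs within one network maximizes its mean count", {
  # Null anomaly counts scale with a network's pair degree, so recovery
  # is demonstrated on a large network that is NOT the null-maximal one
  # (Visual; the larger DMN dominates under the null), with the
  # perturbed pairs spread across its regions so within-network FC
  # attenuates broadly.
  atlas <- default_atlas()
  effects <- spread_pair_effects(atlas, "Visual", n_pairs = 50,
                                 delta = -0.4)
  cohort <- generate_cohort(
    synth_config(n_patients = 12, n_controls = 10, fc_effects = effects,
                 seed = 55), atlas)
  rep <- anomaly_report(cohort)
  expect_identical(names(which.max(rep$mean_counts)), "Visual")
})
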