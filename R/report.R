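#' @title Demographics testing and the end-to-end pipeline driver
#' @description
#' Cohort demographics are compared with the field-standard tests:
#' Chi-squared on the 2x2 group-by-sex table (reported both with and
#' without Yates continuity correction, since small-cohort conventions
#' differ) and Mann-Whitney U (Wilcoxon rank-sum) for continuous
#' variables, with medians and IQRs per group. [run_pipeline()] chains
#' every stage — synthesis, FC, classification (untuned and tuned), MAD
#' anomaly counting, PageRank rank shifts, demographics — writes all
#' tabular outputs as CSV and structured outputs as JSON, and records a
#' manifest with seeds and file checksums for reproducibility.
#' @name report_cli
NULL

#' Demographics comparison table
#'
#' @param cohort A `cohort_dataset`.
#' @return A `demographics_table` data.frame with one row per
#'   variable/test: group summaries, test name, statistic, df, p-value.
#' @export
demographics_table <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_dataset"))
  group <- vapply(cohort$subjects, `[[`, "", "group")
  sex <- vapply(cohort$subjects, `[[`, "", "sex")
  age <- vapply(cohort$subjects, function(s) as.numeric(s$age_years),
                numeric(1))
  if (!all(c("patient", "control") %in% group))
    stop("both groups must be non-empty for demographics comparison")

  fmt_sex <- function(g) {
    f <- sum(group == g & sex == "F"); m <- sum(group == g & sex == "M")
    sprintf("%d/%d (%.1f/%.1f%%)", f, m, 100 * f / (f + m),
            100 * m / (f + m))
  }
  fmt_age <- function(g) {
    a <- age[group == g]
    sprintf("%g (%g)", stats::median(a), stats::IQR(a))
  }

  rows <- list()
  sex_tab <- table(factor(group, levels = c("patient", "control")),
                   factor(sex, levels = c("F", "M")))
  if (length(unique(sex)) < 2) {
    rows[[length(rows) + 1]] <- data.frame(
      variable = "sex", patient = fmt_sex("patient"),
      control = fmt_sex("control"), test = "skipped (constant)",
      statistic = NA_real_, df = NA_real_, p_value = NA_real_)
  } else {
    for (correct in c(FALSE, TRUE)) {
      ct <- suppressWarnings(stats::chisq.test(sex_tab, correct = correct))
      rows[[length(rows) + 1]] <- data.frame(
        variable = "sex", patient = fmt_sex("patient"),
        control = fmt_sex("control"),
        test = paste0("Chi-squared",
                      if (correct) " (Yates-corrected)" else " (uncorrected)"),
        statistic = unname(ct$statistic), df = unname(ct$parameter),
        p_value = ct$p.value)
    }
  }
  if (stats::var(age) == 0) {
    rows[[length(rows) + 1]] <- data.frame(
      variable = "age_years", patient = fmt_age("patient"),
      control = fmt_age("control"), test = "skipped (constant)",
      statistic = NA_real_, df = NA_real_, p_value = NA_real_)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(age[group == "patient"],
                                              age[group == "control"]))
    rows[[length(rows) + 1]] <- data.frame(
      variable = "age_years", patient = fmt_age("patient"),
      control = fmt_age("control"), test = "Mann-Whitney U",
      statistic = unname(wt$statistic), df = NA_real_,
      p_value = wt$p.value)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("demographics_table", "data.frame")
  out
}

#' Pipeline run configuration
#'
#' Exactly one of `cohort_dir` (a directory written by [write_cohort()])
#' or `synth` (an inline [synth_config()]) must be supplied.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Global seed driving every stage's substream.
#' @param cohort_dir Optional path to an on-disk cohort.
#' @param synth Optional inline [synth_config()].
#' @param atlas_path Optional affiliation-table CSV overriding the
#'   packaged default atlas.
#' @param grid Hyperparameter grid for tuning.
#' @param default_spec Untuned [model_spec()] reported alongside the
#'   tuned result.
#' @param mad_threshold,mad_cross_credit,mad_scaled MAD stage options.
#' @param damping,rank_shift_threshold PageRank stage options.
#' @param structural Whether to run the structural centrality stage.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir, seed = 1L, cohort_dir = NULL, synth = NULL,
                       atlas_path = NULL, grid = default_model_grid(),
                       default_spec = model_spec(),
                       mad_threshold = 3, mad_cross_credit = "both",
                       mad_scaled = FALSE, damping = 0.85,
                       rank_shift_threshold = 20, structural = TRUE) {
  if (is.null(cohort_dir) == is.null(synth))
    stop("exactly one of cohort_dir or synth must be supplied")
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 cohort_dir = cohort_dir, synth = synth,
                 atlas_path = atlas_path, grid = grid,
                 default_spec = default_spec,
                 mad_threshold = mad_threshold,
                 mad_cross_credit = mad_cross_credit,
                 mad_scaled = mad_scaled, damping = damping,
                 rank_shift_threshold = rank_shift_threshold,
                 structural = structural),
            class = "run_config")
}

.stage_log <- function(stage, detail, t0) {
  message(sprintf("[%s] %s (%.1fs)", stage, detail,
                  as.numeric(Sys.time() - t0, units = "secs")))
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  path
}

#' Run the full analysis pipeline
#'
#' Stages: cohort synthesis or loading; demographics; FC feature
#' extraction; untuned CV classification, grid tuning and directional
#' importance with network aggregation; MAD anomaly report; PageRank
#' rank-shift report (when structural matrices are present). All
#' randomness derives from `config$seed`; two runs with the same config
#' produce byte-identical outputs.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list of all stage results plus the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  if (!dir.exists(out)) {
    dir.create(out, recursive = TRUE)
    message("[setup] created output directory ", out)
  }
  t0 <- Sys.time()

  atlas <- if (!is.null(config$atlas_path))
    load_affiliation_table(config$atlas_path) else build_default_atlas()

  if (!is.null(config$synth)) {
    synth <- config$synth
    synth$seed <- substream_seed(config$seed, "synth")
    cohort <- generate_cohort(synth, atlas, structural = config$structural)
    .stage_log("synth", sprintf("%d subjects, T = %d",
                                length(cohort$subjects),
                                synth$n_timepoints), t0)
  } else {
    cohort <- read_cohort(config$cohort_dir)
    cohort$atlas <- atlas
    .stage_log("load", sprintf("%d subjects from %s",
                               length(cohort$subjects),
                               config$cohort_dir), t0)
  }
  has_sc <- all(vapply(cohort$subjects,
                       function(s) !is.null(s$structural), logical(1)))
  if (config$structural && !has_sc)
    stop("configuration error: structural centrality requested but ",
         "cohort has no structural matrices")

  demo <- demographics_table(cohort)
  utils::write.csv(demo, file.path(out, "demographics.csv"),
                   row.names = FALSE)
  .stage_log("demographics", "2 variables tested", t0)

  feats <- cohort_feature_matrix(cohort)
  .stage_log("fc", sprintf("%d x %d feature matrix", nrow(feats$X),
                           ncol(feats$X)), t0)

  cv_default <- crossval_classify(feats, config$default_spec)
  tuned <- tune_hyperparameters(feats, config$grid)
  imp <- directional_importance(feats, tuned$best_spec)
  net_imp <- aggregate_by_network(imp, atlas)
  .write_json(list(
    default_spec = unclass(config$default_spec),
    default = list(fold_aucs = cv_default$fold_aucs,
                   mean_auc = cv_default$mean_auc,
                   sd_auc = cv_default$sd_auc),
    tuned_spec = unclass(tuned$best_spec),
    tuned = list(fold_aucs = tuned$best_result$fold_aucs,
                 mean_auc = tuned$best_result$mean_auc,
                 sd_auc = tuned$best_result$sd_auc)),
    file.path(out, "classification.json"))
  utils::write.csv(
    data.frame(region_a = imp$region_a, region_b = imp$region_b,
               magnitude = imp$magnitude, direction = imp$direction)[
                 !is.na(imp$region_a), ],
    file.path(out, "feature_importance.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(net_imp),
                   file.path(out, "network_importance.csv"),
                   row.names = FALSE)
  .stage_log("classify", sprintf("default AUC %.3f, tuned AUC %.3f",
                                 cv_default$mean_auc,
                                 tuned$best_result$mean_auc), t0)

  mad <- anomaly_report(feats, threshold = config$mad_threshold,
                        cross_credit = config$mad_cross_credit,
                        scaled = config$mad_scaled)
  utils::write.csv(data.frame(subject_id = rownames(mad$counts),
                              mad$counts, check.names = FALSE),
                   file.path(out, "mad_counts.csv"), row.names = FALSE)
  utils::write.csv(data.frame(network = names(mad$mean_counts),
                              mean_count = as.numeric(mad$mean_counts)),
                   file.path(out, "mad_summary.csv"), row.names = FALSE)
  .stage_log("mad", sprintf("top network: %s",
                            names(which.max(mad$mean_counts))), t0)

  deviation <- NULL
  if (config$structural && has_sc) {
    rk <- cohort_rank_matrices(cohort, damping = config$damping)
    deviation <- rank_deviation(rk$patient, rk$control,
                                threshold = config$rank_shift_threshold)
    utils::write.csv(data.frame(subject_id = rownames(deviation$heatmap),
                                deviation$heatmap, check.names = FALSE),
                     file.path(out, "pagerank_heatmap.csv"),
                     row.names = FALSE)
    utils::write.csv(deviation$table, file.path(out, "pagerank_table.csv"),
                     row.names = FALSE)
    utils::write.csv(deviation$flags, file.path(out, "pagerank_flags.csv"),
                     row.names = FALSE)
    .stage_log("pagerank", sprintf("%d region(s) flagged",
                                   nrow(deviation$flags)), t0)
  }

  files <- sort(setdiff(list.files(out), "manifest.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("connectopy")),
    seed = config$seed,
    n_subjects = length(cohort$subjects),
    stages = c("demographics", "fc", "classify", "mad",
               if (!is.null(deviation)) "pagerank"),
    checksums = as.list(tools::md5sum(file.path(out, files)) |>
                          stats::setNames(files)))
  .write_json(manifest, file.path(out, "manifest.json"))
  .stage_log("manifest", sprintf("%d files checksummed", length(files)), t0)

  invisible(list(cohort = cohort, demographics = demo,
                 cv_default = cv_default, tuned = tuned,
                 importance = imp, network_importance = net_imp,
                 anomaly = mad, deviation = deviation,
                 manifest = manifest))
}
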