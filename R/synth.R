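#' @title Synthetic two-group cohorts with planted connectivity effects
#' @description
#' The study design this package targets — a small clinical case-control
#' cohort with regional BOLD time series and streamline-count structural
#' connectomes — has no public data. The generator here emulates it:
#' per-network latent AR(1) signals shared by member regions produce
#' realistic within-network functional-connectivity blocks; group effects
#' are planted as pair-specific shared latent components so they flow
#' through the genuine Pearson pipeline; structural connectomes are
#' heavy-tailed (log-normal) streamline-count matrices with optional
#' patient-side hub perturbations.
#' @name synthetic_cohort
NULL

#' Configuration for the synthetic cohort generator
#'
#' Defaults reproduce the reference study conditions: 31 patients and 17
#' controls, 240 timepoints at TR = 2 s (an 8-minute resting-state run),
#' a strongly female-skewed patient group (26/31) versus a balanced
#' control group (8/17), and structural connectomes totalling ~300,000
#' streamlines.
#'
#' @param n_patients,n_controls Group sizes.
#' @param n_timepoints Number of BOLD samples per subject.
#' @param tr_seconds Repetition time in seconds (metadata only).
#' @param latent_coupling Loading of each region on its network's latent
#'   AR(1) factor (unitless; noise innovations have unit SD).
#' @param noise_sd SD of region-specific white noise.
#' @param fc_effects List of pairwise coupling perturbations applied to
#'   patients only; each element is `list(region_a=, region_b=, delta=)`
#'   with `delta` the signed coupling change (a shared pair component of
#'   variance `|delta|` added with equal signs for `delta > 0`, opposite
#'   signs for `delta < 0`).
#' @param hub_effects List of structural hub perturbations applied to
#'   patients only; each element is `list(region=, factor=)` with
#'   `factor > 0` multiplying the region's streamline weights before
#'   rescaling.
#' @param female_fraction_patients,female_fraction_controls Proportion of
#'   female subjects per group.
#' @param age_range Integer age bounds (years), sampled uniformly.
#' @param total_streamlines Target sum of streamline counts over unique
#'   region pairs.
#' @param ar_coef Lag-1 coefficient of the network latent AR(1) factors.
#' @param seed Master seed; all randomness derives from it through named
#'   substreams, so e.g. adding patients does not change control data.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_patients = 31L,
                         n_controls = 17L,
                         n_timepoints = 240L,
                         tr_seconds = 2.0,
                         latent_coupling = 1.0,
                         noise_sd = 1.0,
                         fc_effects = list(),
                         hub_effects = list(),
                         female_fraction_patients = 26 / 31,
                         female_fraction_controls = 8 / 17,
                         age_range = c(20L, 35L),
                         total_streamlines = 300000L,
                         ar_coef = 0.3,
                         seed = 1L) {
  stop_if_not_count(n_patients, "n_patients")
  stop_if_not_count(n_controls, "n_controls")
  stop_if_not_count(n_timepoints, "n_timepoints")
  stop_if_not_count(total_streamlines, "total_streamlines")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  if (latent_coupling < 0) stop("latent_coupling must be nonnegative")
  for (fr in c(female_fraction_patients, female_fraction_controls))
    if (fr < 0 || fr > 1) stop("female fractions must lie in [0, 1]")
  if (abs(ar_coef) >= 1) stop("ar_coef must lie in (-1, 1)")
  fc_effects <- lapply(fc_effects, function(e) {
    e <- as.list(e)
    if (!all(c("region_a", "region_b", "delta") %in% names(e)))
      stop("each fc_effect needs region_a, region_b, delta")
    e
  })
  hub_effects <- lapply(hub_effects, function(e) {
    e <- as.list(e)
    if (!all(c("region", "factor") %in% names(e)))
      stop("each hub_effect needs region, factor")
    if (e$factor <= 0) stop("hub_effect factor must be positive")
    e
  })
  structure(list(
    n_patients = as.integer(n_patients),
    n_controls = as.integer(n_controls),
    n_timepoints = as.integer(n_timepoints),
    tr_seconds = tr_seconds,
    latent_coupling = latent_coupling,
    noise_sd = noise_sd,
    fc_effects = fc_effects,
    hub_effects = hub_effects,
    female_fraction_patients = female_fraction_patients,
    female_fraction_controls = female_fraction_controls,
    age_range = as.integer(age_range),
    total_streamlines = as.integer(total_streamlines),
    ar_coef = ar_coef,
    seed = as.integer(seed)
  ), class = "synth_config")
}

# Stationary AR(1) series of length n with lag-1 coefficient phi and unit
# innovation SD; initial value drawn from the stationary distribution.
.ar1_series <- function(n, phi) {
  x0 <- stats::rnorm(1, sd = 1 / sqrt(1 - phi^2))
  innov <- stats::rnorm(n)
  stats::filter(innov, phi, method = "recursive", init = x0)
}

# One subject's T x 379 regional time-series matrix.
.simulate_timeseries <- function(config, atlas, apply_effects) {
  Tn <- config$n_timepoints
  nets <- unique(atlas$network)
  latents <- vapply(nets, function(nw) as.numeric(.ar1_series(Tn, config$ar_coef)),
                    numeric(Tn))
  colnames(latents) <- nets
  ts <- config$latent_coupling * latents[, atlas$network, drop = FALSE] +
    matrix(stats::rnorm(Tn * nrow(atlas), sd = config$noise_sd),
           Tn, nrow(atlas))
  colnames(ts) <- atlas$name
  if (apply_effects && length(config$fc_effects) > 0) {
    for (eff in config$fc_effects) {
      ia <- resolve_region(atlas, eff$region_a)
      ib <- resolve_region(atlas, eff$region_b)
      g <- stats::rnorm(Tn)
      cc <- sqrt(abs(eff$delta))
      ts[, ia] <- ts[, ia] + cc * g
      ts[, ib] <- ts[, ib] + sign(eff$delta) * cc * g
    }
  }
  ts
}

#' Generate a synthetic two-group cohort
#'
#' Simulates regional BOLD-like time series for every subject: each
#' region's series is `latent_coupling` times its network's latent AR(1)
#' factor plus independent Gaussian noise, with patient-only pairwise
#' coupling perturbations from `config$fc_effects`, plus per-subject
#' structural connectomes (see [generate_structural_connectome()]) when
#' `structural = TRUE`. Sex is assigned deterministically by the
#' configured fractions (the first `round(fraction * n)` subjects of each
#' group are female); ages are uniform integers over `config$age_range`.
#'
#' @param config A [synth_config()].
#' @param atlas An `atlas_registry`; defaults to [build_default_atlas()].
#' @param structural Also simulate per-subject structural connectomes.
#' @return A `cohort_dataset` list with elements `subjects` (list of
#'   subject records with `subject_id`, `group`, `sex`, `age_years`,
#'   `timeseries`, optionally `structural`), `atlas`, and `config`.
#' @examples
#' cohort <- generate_cohort(synth_config(seed = 7))
#' length(cohort$subjects)  # 48
#' @export
generate_cohort <- function(config, atlas = build_default_atlas(),
                            structural = FALSE) {
  stopifnot(inherits(config, "synth_config"),
            inherits(atlas, "atlas_registry"))
  for (eff in config$fc_effects) {
    resolve_region(atlas, eff$region_a)
    resolve_region(atlas, eff$region_b)
  }
  for (eff in config$hub_effects) resolve_region(atlas, eff$region)

  make_group <- function(group, n, female_fraction) {
    n_f <- round(female_fraction * n)
    lapply(seq_len(n), function(i) {
      id <- sprintf("%s%02d", if (group == "patient") "P" else "C", i)
      ts <- with_substream(config$seed, paste0("ts:", id),
                           .simulate_timeseries(config, atlas,
                                                apply_effects = group == "patient"))
      age <- with_substream(config$seed, paste0("age:", id),
                            sample(seq(config$age_range[1], config$age_range[2]), 1))
      rec <- list(subject_id = id, group = group,
                  sex = if (i <= n_f) "F" else "M",
                  age_years = as.integer(age), timeseries = ts)
      if (structural) {
        rec$structural <- with_substream(
          config$seed, paste0("sc:", id),
          .draw_structural(config, atlas, apply_effects = group == "patient"))
      }
      rec
    })
  }
  subjects <- c(
    make_group("patient", config$n_patients, config$female_fraction_patients),
    make_group("control", config$n_controls, config$female_fraction_controls)
  )
  structure(list(subjects = subjects, atlas = atlas, config = config),
            class = "cohort_dataset")
}

# Fixed per-region log-propensities: the cohort's shared "anatomy",
# giving every subject the same expected hub ordering. Drawn once per
# config seed so all subjects (and draws) of a cohort share it.
.anatomy_propensity <- function(config, n) {
  with_substream(config$seed, "anatomy",
                 stats::rnorm(n, mean = 0, sd = 0.45))
}

# Raw structural draw (RNG state managed by caller). Hierarchical
# log-normal edge weights: log w_ij = 2 + a_i + a_j + e_ij with
# a ~ N(0, 0.45^2) shared across subjects and e ~ N(0, 0.771^2)
# subject-specific, so the marginal edge weight is log-normal with
# sdlog 1 while region hubness persists across subjects.
.draw_structural <- function(config, atlas, apply_effects) {
  n <- nrow(atlas)
  a <- .anatomy_propensity(config, n)
  w <- matrix(0, n, n)
  ut <- upper.tri(w)
  edge_sd <- sqrt(1 - 2 * 0.45^2)
  lw <- 2 + outer(a, a, `+`) + matrix(0, n, n)
  noise <- matrix(0, n, n)
  noise[ut] <- stats::rnorm(sum(ut), sd = edge_sd)
  lw <- lw + noise
  w[ut] <- exp(lw[ut])
  w <- w + t(w)
  if (apply_effects && length(config$hub_effects) > 0) {
    for (eff in config$hub_effects) {
      i <- resolve_region(atlas, eff$region)
      w[i, ] <- w[i, ] * eff$factor
      w[, i] <- w[, i] * eff$factor
      diag(w) <- 0
    }
  }
  w <- w * (config$total_streamlines / (sum(w) / 2))
  w <- round(w)
  w <- pmax(w, t(w))  # keep symmetry after rounding
  dimnames(w) <- list(atlas$name, atlas$name)
  w
}

#' Draw one synthetic structural connectome
#'
#' Streamline-count adjacency: symmetric nonnegative integer 379x379
#' matrix, zero diagonal, drawn from a distance-free hierarchical
#' log-normal edge-weight model (marginal meanlog 2, sdlog 1, with
#' per-region propensities shared across a cohort's subjects so hub
#' ordering persists), rescaled so the sum over unique pairs is
#' `config$total_streamlines` up to integer rounding.
#' For `group = "patient"`, each `config$hub_effects` entry multiplies
#' the named region's row and column by its factor before rescaling.
#'
#' @param config A [synth_config()].
#' @param group `"patient"` or `"control"` (hub effects apply to patients).
#' @param atlas An `atlas_registry`.
#' @param draw Integer draw index (names the random substream).
#' @return Symmetric integer matrix with region dimnames.
#' @export
generate_structural_connectome <- function(config, group = c("control", "patient"),
                                           atlas = build_default_atlas(),
                                           draw = 1L) {
  group <- match.arg(group)
  stopifnot(inherits(config, "synth_config"))
  for (eff in config$hub_effects) resolve_region(atlas, eff$region)
  with_substream(config$seed, sprintf("sc:%s:%d", group, draw),
                 .draw_structural(config, atlas,
                                  apply_effects = group == "patient"))
}

#' @export
print.cohort_dataset <- function(x, ...) {
  groups <- vapply(x$subjects, `[[`, "", "group")
  cat(sprintf("<cohort_dataset> %d patients, %d controls, T = %d, %d regions\n",
              sum(groups == "patient"), sum(groups == "control"),
              x$config$n_timepoints, nrow(x$atlas)))
  invisible(x)
}

#' Write a cohort to disk as plain-text files
#'
#' Writes `manifest.csv` (`subject_id,group,sex,age_years`), the atlas as
#' `atlas.csv`, a YAML `config.yaml`, and per-subject tab-separated
#' matrices `<id>_timeseries.tsv` (T x 379) and, when present,
#' `<id>_structural.tsv` (379 x 379).
#'
#' @param cohort A `cohort_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- data.frame(
    subject_id = vapply(cohort$subjects, `[[`, "", "subject_id"),
    group = vapply(cohort$subjects, `[[`, "", "group"),
    sex = vapply(cohort$subjects, `[[`, "", "sex"),
    age_years = vapply(cohort$subjects, function(s) s$age_years, integer(1))
  )
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  write_affiliation_table(cohort$atlas, file.path(dir, "atlas.csv"))
  cfg <- cohort$config
  class(cfg) <- NULL
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  for (s in cohort$subjects) {
    utils::write.table(s$timeseries,
                       file.path(dir, paste0(s$subject_id, "_timeseries.tsv")),
                       sep = "\t", row.names = FALSE, col.names = TRUE,
                       quote = FALSE)
    if (!is.null(s$structural))
      utils::write.table(s$structural,
                         file.path(dir, paste0(s$subject_id, "_structural.tsv")),
                         sep = "\t", row.names = FALSE, col.names = TRUE,
                         quote = FALSE)
  }
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `manifest.csv`, `atlas.csv` and the
#'   per-subject matrices.
#' @return A `cohort_dataset`.
#' @export
read_cohort <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  atlas <- load_affiliation_table(file.path(dir, "atlas.csv"))
  cfg_path <- file.path(dir, "config.yaml")
  config <- if (file.exists(cfg_path)) {
    raw <- yaml::read_yaml(cfg_path)
    do.call(synth_config, raw[intersect(names(raw),
                                        names(formals(synth_config)))])
  } else NULL
  subjects <- lapply(seq_len(nrow(manifest)), function(i) {
    id <- manifest$subject_id[i]
    ts <- as.matrix(utils::read.table(
      file.path(dir, paste0(id, "_timeseries.tsv")),
      sep = "\t", header = TRUE, check.names = FALSE))
    rec <- list(subject_id = id, group = manifest$group[i],
                sex = manifest$sex[i],
                age_years = as.integer(manifest$age_years[i]),
                timeseries = ts)
    sc_path <- file.path(dir, paste0(id, "_structural.tsv"))
    if (file.exists(sc_path))
      rec$structural <- as.matrix(utils::read.table(
        sc_path, sep = "\t", header = TRUE, check.names = FALSE))
    rec
  })
  structure(list(subjects = subjects, atlas = atlas, config = config),
            class = "cohort_dataset")
}
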