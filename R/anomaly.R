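#' @title Control-referenced MAD anomaly detection on FC features
#' @description
#' For every unique-pair FC feature, the control group defines a robust
#' reference: its median and median absolute deviation (MAD, raw — no
#' normal-consistency constant). A patient's feature is an anomaly when
#' it lies at least 3 MADs from the control median (threshold
#' inclusive). Anomalies are counted per large-scale network: a
#' within-network anomaly increments its network once, a cross-network
#' anomaly increments both endpoint networks once each (half-credit
#' attribution available). Features whose control MAD is zero are not
#' evaluable and never counted.
#' @name anomaly_mad
NULL

#' Build the control MAD reference
#'
#' @param controls Numeric matrix, controls x features (e.g. rows of
#'   [cohort_feature_matrix()]`$X`), or a list of equal-length feature
#'   vectors. At least 3 controls.
#' @param scaled If `TRUE`, multiply the MAD by the 1.4826
#'   normal-consistency constant (default off: the threshold is in raw
#'   MAD units).
#' @return A `mad_reference` list: `median`, `mad`, `evaluable` (logical,
#'   `FALSE` where MAD = 0), `scaled`, `feature` names.
#' @export
control_reference <- function(controls, scaled = FALSE) {
  if (is.list(controls) && !is.matrix(controls))
    controls <- do.call(rbind, lapply(controls, as.numeric))
  controls <- as.matrix(controls)
  if (nrow(controls) < 3)
    stop("need at least 3 controls to build a MAD reference, got ",
         nrow(controls))
  med <- apply(controls, 2, stats::median)
  mad_raw <- apply(abs(sweep(controls, 2, med)), 2, stats::median)
  if (scaled) mad_raw <- mad_raw * 1.4826
  structure(list(median = med, mad = mad_raw,
                 evaluable = mad_raw > 0, scaled = scaled,
                 feature = colnames(controls)),
            class = "mad_reference")
}

#' Count per-network anomalies for one patient
#'
#' @param patient Named numeric feature vector (same feature order as
#'   the reference; names checked when present).
#' @param ref A [control_reference()].
#' @param atlas An `atlas_registry`.
#' @param threshold Number of MADs at or beyond which a deviation is an
#'   anomaly (default 3, inclusive).
#' @param cross_credit `"both"` (default): a cross-network anomaly adds
#'   1 to each endpoint network; `"half"`: 0.5 to each.
#' @return Named numeric vector of anomaly counts, one per network in
#'   the atlas; attribute `"anomalous"` is the logical per-feature flag.
#' @export
count_anomalies <- function(patient, ref, atlas, threshold = 3,
                            cross_credit = c("both", "half")) {
  cross_credit <- match.arg(cross_credit)
  stopifnot(inherits(ref, "mad_reference"))
  if (length(patient) != length(ref$median))
    stop("feature count mismatch: patient has ", length(patient),
         ", reference has ", length(ref$median))
  if (!is.null(names(patient)) && !is.null(ref$feature) &&
      !identical(names(patient), ref$feature))
    stop("feature index mismatch between patient vector and MAD reference")

  dev <- abs(as.numeric(patient) - ref$median)
  # inclusive threshold, with a relative epsilon so a deviation of
  # exactly `threshold` MADs is counted despite floating-point rounding
  anom <- ref$evaluable &
    (dev >= threshold * ref$mad * (1 - 1e-9) - 1e-12)

  nets_memo <- attr(ref, "feature_networks")
  if (is.null(nets_memo)) {
    feat_names <- ref$feature %||% names(patient)
    if (is.null(feat_names)) stop("feature names required to map networks")
    parts <- strsplit(feat_names, "|", fixed = TRUE)
    nets_memo <- list(a = network_of(atlas, vapply(parts, `[[`, "", 1)),
                      b = network_of(atlas, vapply(parts, `[[`, "", 2)))
  }
  net_a <- nets_memo$a
  net_b <- nets_memo$b

  nets <- sort(unique(atlas$network))
  counts <- stats::setNames(numeric(length(nets)), nets)
  if (any(anom)) {
    a <- net_a[anom]; b <- net_b[anom]
    same <- a == b
    w_cross <- if (cross_credit == "both") 1 else 0.5
    inc <- c(a[same], a[!same], b[!same])
    wts <- c(rep(1, sum(same)), rep(w_cross, 2 * sum(!same)))
    add <- tapply(wts, inc, sum)
    counts[names(add)] <- counts[names(add)] + add
  }
  attr(counts, "anomalous") <- anom
  counts
}

#' Cohort-level anomaly report
#'
#' Builds the control reference from the cohort's controls and counts
#' per-network anomalies for every patient.
#'
#' @param cohort A `cohort_dataset` or [cohort_feature_matrix()] output.
#' @inheritParams count_anomalies
#' @param scaled Passed to [control_reference()].
#' @return An `anomaly_report` list: `counts` (patients x networks
#'   matrix), `mean_counts` (named vector, mean over patients),
#'   `reference`.
#' @export
anomaly_report <- function(cohort, threshold = 3,
                           cross_credit = c("both", "half"),
                           scaled = FALSE) {
  cross_credit <- match.arg(cross_credit)
  feats <- if (inherits(cohort, "cohort_dataset"))
    cohort_feature_matrix(cohort) else cohort
  is_pat <- feats$group == "patient"
  ref <- control_reference(feats$X[!is_pat, , drop = FALSE],
                           scaled = scaled)
  atlas <- if (inherits(cohort, "cohort_dataset")) cohort$atlas
           else build_default_atlas()
  parts <- strsplit(ref$feature, "|", fixed = TRUE)
  attr(ref, "feature_networks") <-
    list(a = network_of(atlas, vapply(parts, `[[`, "", 1)),
         b = network_of(atlas, vapply(parts, `[[`, "", 2)))
  rows <- lapply(which(is_pat), function(i)
    count_anomalies(feats$X[i, ], ref, atlas, threshold = threshold,
                    cross_credit = cross_credit))
  counts <- do.call(rbind, rows)
  rownames(counts) <- rownames(feats$X)[is_pat]
  structure(list(counts = counts,
                 mean_counts = colMeans(counts),
                 reference = ref),
            class = "anomaly_report")
}

#' @export
print.anomaly_report <- function(x, ...) {
  cat("<anomaly_report>", nrow(x$counts), "patients; mean counts:\n")
  print(round(sort(x$mean_counts, decreasing = TRUE), 2))
  invisible(x)
}
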