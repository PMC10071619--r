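#' @title Cross-validated boosted-tree classification of diagnostic group
#' @description
#' Diagnostic group is modelled from the unique-pair FC feature vector
#' plus a binary sex covariate with gradient-boosted trees (XGBoost),
#' evaluated by stratified 5-fold cross-validation with the mean AUC-ROC
#' over folds. Feature influence is summarised by signed SHAP-style tree
#' attributions: magnitude is the mean absolute per-subject attribution,
#' direction the sign of the association between feature value and
#' attribution. Region-level influence is the full-credit sum over
#' incident pair features, and network-level influence the mean over
#' member regions.
#' @name classify
NULL

#' Boosted-tree model specification
#'
#' @param learning_rate Shrinkage per boosting round (> 0).
#' @param max_tree_depth Maximum depth of each tree (>= 1).
#' @param n_estimators Number of boosting rounds.
#' @param seed Seed for tree construction and fold assignment.
#' @param colsample_bytree Fraction of features sampled per tree, in
#'   (0, 1]; sampling is deterministic given `seed`.
#' @return A `model_spec` list.
#' @export
model_spec <- function(learning_rate = 0.3, max_tree_depth = 3L,
                       n_estimators = 100L, seed = 0L,
                       colsample_bytree = 1) {
  if (learning_rate <= 0) stop("learning_rate must be positive")
  if (max_tree_depth < 1) stop("max_tree_depth must be >= 1")
  stop_if_not_count(n_estimators, "n_estimators")
  if (colsample_bytree <= 0 || colsample_bytree > 1)
    stop("colsample_bytree must lie in (0, 1]")
  structure(list(learning_rate = learning_rate,
                 max_tree_depth = as.integer(max_tree_depth),
                 n_estimators = as.integer(n_estimators),
                 seed = as.integer(seed),
                 colsample_bytree = colsample_bytree),
            class = "model_spec")
}

#' Default hyperparameter grid
#'
#' Three learning rates x three depths x three seeds, mirroring tuning
#' over the learning rate, tree depth and seed with the round count held
#' fixed.
#'
#' @param learning_rates,max_tree_depths,seeds Grid axes.
#' @param n_estimators Fixed boosting rounds for every grid point.
#' @return List of [model_spec()] objects.
#' @export
default_model_grid <- function(learning_rates = c(0.05, 0.1, 0.3),
                               max_tree_depths = 2:4,
                               seeds = 0:2,
                               n_estimators = 100L) {
  g <- expand.grid(lr = learning_rates, depth = max_tree_depths,
                   seed = seeds)
  lapply(seq_len(nrow(g)), function(i)
    model_spec(g$lr[i], g$depth[i], n_estimators, g$seed[i]))
}

# Exact (presorted) tree growth: for few-subject, many-feature FC
# designs it is both deterministic and faster than histogram methods.
.xgb_params <- function(spec) {
  list(objective = "binary:logistic", eval_metric = "logloss",
       eta = spec$learning_rate, max_depth = spec$max_tree_depth,
       tree_method = "exact",
       colsample_bytree = spec$colsample_bytree %||% 1,
       nthread = 1, seed = spec$seed)
}

# AUC with the probability direction pinned (higher score = patient), so
# null-label permutations are not biased upward by direction auto-choice.
.auc <- function(y01, score) {
  r <- pROC::roc(response = factor(y01, levels = c(0, 1)),
                 predictor = score, direction = "<", quiet = TRUE)
  as.numeric(pROC::auc(r))
}

# Stratified fold assignment: within each class, a seeded random
# permutation of fold labels 1..k.
stratified_folds <- function(y01, k, seed) {
  folds <- integer(length(y01))
  with_substream(seed, "folds", {
    for (cls in unique(y01)) {
      idx <- which(y01 == cls)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  for (f in seq_len(k)) {
    tr <- y01[folds != f]
    if (length(unique(tr)) < 2 || length(unique(y01[folds == f])) < 2)
      stop("stratification failed: fold ", f,
           " leaves a single class in train or test")
  }
  folds
}

# Design matrix: unique-pair FC features plus binary sex covariate.
.design_matrix <- function(feats) {
  cbind(feats$X, sex = as.numeric(feats$sex == "F"))
}

# Core CV engine on a prebuilt design matrix.
.cv_auc <- function(Xd, y01, folds, spec) {
  k <- max(folds)
  fold_aucs <- numeric(k)
  for (f in seq_len(k)) {
    tr <- folds != f
    dtr <- xgboost::xgb.DMatrix(Xd[tr, , drop = FALSE],
                                label = y01[tr], nthread = 1)
    dte <- xgboost::xgb.DMatrix(Xd[!tr, , drop = FALSE],
                                label = y01[!tr], nthread = 1)
    bst <- xgboost::xgb.train(params = .xgb_params(spec), data = dtr,
                              nrounds = spec$n_estimators, verbose = 0)
    fold_aucs[f] <- .auc(y01[!tr], predict(bst, dte))
  }
  fold_aucs
}

#' Cross-validated classification of diagnostic group
#'
#' Fits gradient-boosted trees on unique-pair FC features plus the sex
#' covariate under stratified k-fold cross-validation; each fold's AUC
#' is computed on its held-out subjects only. Deterministic given
#' `spec$seed`.
#'
#' @param cohort A `cohort_dataset`, or a precomputed feature set from
#'   [cohort_feature_matrix()] (avoids recomputing FC).
#' @param spec A [model_spec()].
#' @param n_folds Number of CV folds (default 5).
#' @return A `cv_result` list: `fold_aucs`, `mean_auc`, `sd_auc`,
#'   `folds` (per-subject fold assignment), `spec`.
#' @export
crossval_classify <- function(cohort, spec = model_spec(), n_folds = 5L) {
  feats <- if (inherits(cohort, "cohort_dataset"))
    cohort_feature_matrix(cohort) else cohort
  y01 <- as.numeric(feats$group == "patient")
  if (length(unique(y01)) < 2) stop("need both groups present")
  Xd <- .design_matrix(feats)
  folds <- stratified_folds(y01, n_folds, spec$seed)
  fold_aucs <- .cv_auc(Xd, y01, folds, spec)
  structure(list(fold_aucs = fold_aucs,
                 mean_auc = mean(fold_aucs),
                 sd_auc = stats::sd(fold_aucs),
                 folds = stats::setNames(folds, rownames(feats$X)),
                 spec = spec),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> mean AUC %.3f +/- %.3f over %d folds\n",
              x$mean_auc, x$sd_auc, length(x$fold_aucs)))
  invisible(x)
}

#' Hyperparameter tuning over a grid of model specs
#'
#' Evaluates every grid point with [crossval_classify()] and returns the
#' spec maximizing mean AUC; ties broken by smaller depth, then smaller
#' learning rate, then smaller seed. Tuning selects on the same CV folds
#' it reports, the optimistic protocol; pair with
#' [nested_crossval_classify()] for a selection-protected estimate.
#'
#' @param cohort A `cohort_dataset` or [cohort_feature_matrix()] output.
#' @param grid Non-empty list of [model_spec()] objects.
#' @param n_folds CV folds per evaluation.
#' @return List with `best_spec`, `best_result` (its `cv_result`) and
#'   `results`, a data.frame of mean/sd AUC per grid point.
#' @export
tune_hyperparameters <- function(cohort, grid = default_model_grid(),
                                 n_folds = 5L) {
  if (length(grid) == 0) stop("hyperparameter grid must be non-empty")
  feats <- if (inherits(cohort, "cohort_dataset"))
    cohort_feature_matrix(cohort) else cohort
  evals <- lapply(grid, function(sp)
    crossval_classify(feats, sp, n_folds = n_folds))
  tab <- data.frame(
    learning_rate = vapply(grid, `[[`, 0, "learning_rate"),
    max_tree_depth = vapply(grid, function(s) s$max_tree_depth, integer(1)),
    n_estimators = vapply(grid, function(s) s$n_estimators, integer(1)),
    seed = vapply(grid, function(s) s$seed, integer(1)),
    mean_auc = vapply(evals, `[[`, 0, "mean_auc"),
    sd_auc = vapply(evals, `[[`, 0, "sd_auc"))
  best <- order(-tab$mean_auc, tab$max_tree_depth, tab$learning_rate,
                tab$seed)[1]
  list(best_spec = grid[[best]], best_result = evals[[best]],
       results = tab)
}

#' Nested cross-validation around grid tuning
#'
#' Outer stratified k-fold loop; within each outer training set the grid
#' is tuned by inner CV, and the selected spec is refit on the outer
#' training set and scored on the untouched outer test fold. The mean
#' outer AUC is the selection-protected performance estimate.
#'
#' @inheritParams tune_hyperparameters
#' @param outer_folds,inner_folds Fold counts for the two loops.
#' @param seed Seed for the outer fold assignment.
#' @return A `cv_result` over outer folds, with the per-fold chosen specs
#'   in `$chosen_specs`.
#' @export
nested_crossval_classify <- function(cohort, grid = default_model_grid(),
                                     outer_folds = 5L, inner_folds = 5L,
                                     seed = 0L) {
  feats <- if (inherits(cohort, "cohort_dataset"))
    cohort_feature_matrix(cohort) else cohort
  y01 <- as.numeric(feats$group == "patient")
  Xd <- .design_matrix(feats)
  folds <- stratified_folds(y01, outer_folds, seed)
  fold_aucs <- numeric(outer_folds)
  chosen <- vector("list", outer_folds)
  for (f in seq_len(outer_folds)) {
    tr <- folds != f
    inner <- list(X = feats$X[tr, , drop = FALSE],
                  group = feats$group[tr], sex = feats$sex[tr],
                  pair_index = feats$pair_index)
    tuned <- tune_hyperparameters(inner, grid, n_folds = inner_folds)
    chosen[[f]] <- tuned$best_spec
    dtr <- xgboost::xgb.DMatrix(Xd[tr, , drop = FALSE], label = y01[tr],
                                nthread = 1)
    dte <- xgboost::xgb.DMatrix(Xd[!tr, , drop = FALSE],
                                label = y01[!tr], nthread = 1)
    bst <- xgboost::xgb.train(params = .xgb_params(tuned$best_spec),
                              data = dtr,
                              nrounds = tuned$best_spec$n_estimators,
                              verbose = 0)
    fold_aucs[f] <- .auc(y01[!tr], predict(bst, dte))
  }
  structure(list(fold_aucs = fold_aucs, mean_auc = mean(fold_aucs),
                 sd_auc = stats::sd(fold_aucs),
                 folds = stats::setNames(folds, rownames(feats$X)),
                 chosen_specs = chosen),
            class = "cv_result")
}

#' Label-permutation null distribution of the CV AUC
#'
#' Repeatedly permutes diagnostic labels and recomputes the full
#' stratified CV on each permuted labelling (folds are re-stratified per
#' permutation, so every held-out fold contains both classes). Under
#' exchangeable labels the mean AUC should centre on 0.5.
#'
#' @param cohort A `cohort_dataset` or [cohort_feature_matrix()] output.
#' @param spec A [model_spec()].
#' @param n_permutations Number of label permutations.
#' @param n_folds CV folds.
#' @param seed Seed for the permutation stream.
#' @return Numeric vector of mean CV AUCs, one per permutation.
#' @export
permutation_null_auc <- function(cohort, spec = model_spec(),
                                 n_permutations = 100L, n_folds = 5L,
                                 seed = 0L) {
  feats <- if (inherits(cohort, "cohort_dataset"))
    cohort_feature_matrix(cohort) else cohort
  y01 <- as.numeric(feats$group == "patient")
  Xd <- .design_matrix(feats)
  perms <- with_substream(seed, "permutation_null",
                          replicate(n_permutations, sample(y01),
                                    simplify = FALSE))
  vapply(seq_along(perms), function(i) {
    yp <- perms[[i]]
    folds <- stratified_folds(yp, n_folds,
                              substream_seed(seed, paste0("perm_folds", i)))
    mean(.cv_auc(Xd, yp, folds, spec))
  }, numeric(1))
}

#' Signed SHAP-style directional feature importance
#'
#' Fits the model on all subjects, computes per-subject additive tree
#' attributions (SHAP values from the fitted booster), and summarises
#' each feature by magnitude = mean |attribution| over subjects and
#' direction = sign of the Pearson correlation between feature value and
#' attribution. This is a signed-SHAP summary, not the HoTS
#' tree-linearization it stands in for.
#'
#' @param cohort A `cohort_dataset` or [cohort_feature_matrix()] output.
#' @param spec A [model_spec()].
#' @return A `feature_importance` data.frame sorted by descending
#'   magnitude: `feature`, `region_a`, `region_b`, `magnitude`,
#'   `direction`. The sex covariate appears with `NA` regions. Attribute
#'   `"additivity_error"` carries the max |sum(attributions) - margin|.
#' @export
directional_importance <- function(cohort, spec = model_spec()) {
  feats <- if (inherits(cohort, "cohort_dataset"))
    cohort_feature_matrix(cohort) else cohort
  y01 <- as.numeric(feats$group == "patient")
  Xd <- .design_matrix(feats)
  dall <- xgboost::xgb.DMatrix(Xd, label = y01, nthread = 1)
  bst <- xgboost::xgb.train(params = .xgb_params(spec), data = dall,
                            nrounds = spec$n_estimators, verbose = 0)
  contrib <- predict(bst, dall, predcontrib = TRUE)
  margin <- predict(bst, dall, outputmargin = TRUE)
  add_err <- max(abs(rowSums(contrib) - margin))
  contrib <- contrib[, seq_len(ncol(Xd)), drop = FALSE]  # drop BIAS column

  magnitude <- colMeans(abs(contrib))
  # Vectorized per-feature correlation sign between value and attribution.
  n <- nrow(Xd)
  xc <- sweep(Xd, 2, colMeans(Xd))
  cc <- sweep(contrib, 2, colMeans(contrib))
  cov_xc <- colSums(xc * cc) / (n - 1)
  denom <- sqrt(colSums(xc^2) * colSums(cc^2))
  direction <- ifelse(denom > 0, sign(cov_xc), 0)

  pi <- feats$pair_index
  out <- data.frame(
    feature = colnames(Xd),
    region_a = c(pi$region_a, NA),
    region_b = c(pi$region_b, NA),
    magnitude = as.numeric(magnitude),
    direction = as.numeric(direction),
    stringsAsFactors = FALSE)
  out <- out[order(-out$magnitude, out$feature), ]
  rownames(out) <- NULL
  class(out) <- c("feature_importance", "data.frame")
  attr(out, "additivity_error") <- add_err
  out
}

#' Top-k view of a feature-importance table
#'
#' @param importance A `feature_importance` table.
#' @param k Number of top-magnitude features (default 20).
#' @return The first `k` rows.
#' @export
top_features <- function(importance, k = 20L) {
  if (k > nrow(importance))
    stop("k = ", k, " exceeds the ", nrow(importance), " available features")
  utils::head(importance, k)
}

#' Aggregate feature importance over large-scale networks
#'
#' Each pair feature credits its full magnitude to both endpoint
#' regions; a network's value is the mean of its member regions' summed
#' scores. Non-pair covariates (sex) are excluded.
#'
#' @param importance A `feature_importance` table.
#' @param atlas An `atlas_registry`.
#' @return A `network_importance` data.frame (`network`,
#'   `mean_importance`) sorted descending, one row per network present
#'   in the atlas; attribute `"region_scores"` carries the per-region
#'   sums.
#' @export
aggregate_by_network <- function(importance, atlas) {
  pairs <- importance[!is.na(importance$region_a), ]
  resolve_region(atlas, unique(c(pairs$region_a, pairs$region_b)))
  score <- stats::setNames(numeric(nrow(atlas)), atlas$name)
  add_a <- tapply(pairs$magnitude, pairs$region_a, sum)
  add_b <- tapply(pairs$magnitude, pairs$region_b, sum)
  score[names(add_a)] <- score[names(add_a)] + add_a
  score[names(add_b)] <- score[names(add_b)] + add_b
  mean_imp <- tapply(score, atlas$network, mean)
  out <- data.frame(network = names(mean_imp),
                    mean_importance = as.numeric(mean_imp),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$mean_importance, out$network), ]
  rownames(out) <- NULL
  class(out) <- c("network_importance", "data.frame")
  attr(out, "region_scores") <- score
  out
}
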