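#' @title Functional connectivity matrices and feature vectors
#' @description
#' Subject-level functional connectivity is the Pearson correlation of
#' regional BOLD time series between every pair of regions, self-pairs
#' included: on the 379-region parcellation the full self-inclusive set
#' has 379^2 = 143,641 entries. For classification the matrix is
#' flattened to one value per unordered off-diagonal pair
#' (379 * 378 / 2 = 71,631 features); the redundant full-matrix feature
#' set is available via `include_diagonal`/full flattening for fidelity
#' experiments.
#' @name connectivity
NULL

#' Pearson functional-connectivity matrix
#'
#' @param ts Numeric matrix, timepoints x regions (columns named by
#'   region). At least 3 rows.
#' @return An `fc_matrix`: symmetric correlation matrix with unit
#'   diagonal, same column order as `ts`.
#' @examples
#' ts <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
#' fc <- fc_matrix(ts)
#' @export
fc_matrix <- function(ts) {
  ts <- as.matrix(ts)
  if (nrow(ts) < 3)
    stop("need at least 3 timepoints to estimate correlations, got ",
         nrow(ts))
  if (anyNA(ts)) stop("time series contains missing values")
  sds <- apply(ts, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(ts)[sds == 0] %||% which(sds == 0)
    stop("zero-variance time series, correlation undefined for region(s): ",
         paste(bad, collapse = ", "))
  }
  fc <- stats::cor(ts)
  diag(fc) <- 1
  class(fc) <- c("fc_matrix", class(fc))
  fc
}

# Unique-pair index table for n regions: row-major upper triangle, a < b.
pair_index <- function(region_names) {
  n <- length(region_names)
  ij <- which(upper.tri(diag(n)), arr.ind = TRUE)
  ij <- ij[order(ij[, "row"], ij[, "col"]), , drop = FALSE]
  data.frame(a = ij[, "row"], b = ij[, "col"],
             region_a = region_names[ij[, "row"]],
             region_b = region_names[ij[, "col"]],
             stringsAsFactors = FALSE)
}

#' Flatten an FC matrix to a unique-pair feature vector
#'
#' Deterministic row-major upper-triangle order (a < b), diagonal
#' excluded; names are `"<region_a>|<region_b>"`.
#'
#' @param fc An `fc_matrix` (or any symmetric matrix with dimnames).
#' @param full If `TRUE`, return the full self-inclusive flattening
#'   (row-major, n^2 values) instead of unique pairs.
#' @return Named numeric vector; attribute `"pair_index"` carries the
#'   position-to-pair table (unique-pair mode only).
#' @export
vectorize_features <- function(fc, full = FALSE) {
  fc <- unclass(fc)
  n <- nrow(fc)
  stopifnot(n == ncol(fc))
  nm <- colnames(fc) %||% as.character(seq_len(n))
  if (full) {
    v <- as.vector(t(fc))
    names(v) <- paste0(rep(nm, each = n), "|", rep(nm, times = n))
    return(v)
  }
  pi <- pair_index(nm)
  v <- fc[cbind(pi$a, pi$b)]
  names(v) <- paste0(pi$region_a, "|", pi$region_b)
  attr(v, "pair_index") <- pi
  v
}

#' Rebuild an FC matrix from a unique-pair feature vector
#'
#' Inverse of [vectorize_features()] (unique-pair mode); the diagonal is
#' restored as 1.
#'
#' @param v Named vector from [vectorize_features()].
#' @param region_names Region order; inferred from `v`'s pair index if
#'   absent.
#' @return An `fc_matrix`.
#' @export
unvectorize_features <- function(v, region_names = NULL) {
  pi <- attr(v, "pair_index")
  if (is.null(region_names)) {
    if (is.null(pi)) stop("region_names required when v has no pair_index")
    region_names <- unique(c(pi$region_a[1],
                             pi$region_b[pi$a == 1]))
  }
  n <- length(region_names)
  if (is.null(pi)) pi <- pair_index(region_names)
  if (length(v) != nrow(pi))
    stop("feature vector length ", length(v), " does not match ",
         nrow(pi), " unique pairs for ", n, " regions")
  fc <- diag(n)
  fc[cbind(pi$a, pi$b)] <- v
  fc[cbind(pi$b, pi$a)] <- v
  dimnames(fc) <- list(region_names, region_names)
  class(fc) <- c("fc_matrix", class(fc))
  fc
}

# Subject x feature matrix of unique-pair FC values for a whole cohort,
# with group labels and sex; the shared workhorse for the classifier and
# the anomaly modules.
cohort_feature_matrix <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_dataset"))
  feats <- lapply(cohort$subjects, function(s)
    vectorize_features(fc_matrix(s$timeseries)))
  X <- do.call(rbind, lapply(feats, as.numeric))
  colnames(X) <- names(feats[[1]])
  rownames(X) <- vapply(cohort$subjects, `[[`, "", "subject_id")
  list(X = X,
       group = vapply(cohort$subjects, `[[`, "", "group"),
       sex = vapply(cohort$subjects, `[[`, "", "sex"),
       pair_index = attr(feats[[1]], "pair_index"))
}

#' Write / read an FC matrix as tab-separated text
#'
#' 379x379 (or n x n) matrix with a one-line region-order header.
#'
#' @param fc An `fc_matrix`.
#' @param path Output path.
#' @return `path` (writer) or an `fc_matrix` (reader).
#' @export
write_fc_matrix <- function(fc, path) {
  utils::write.table(unclass(fc), path, sep = "\t", row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' @rdname write_fc_matrix
#' @export
read_fc_matrix <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   check.names = FALSE))
  rownames(m) <- colnames(m)
  class(m) <- c("fc_matrix", class(m))
  m
}
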