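#' @title Weighted PageRank centrality and control-referenced rank shifts
#' @description
#' Hubness of each region in the structural connectome is measured by
#' weighted PageRank on the streamline-count adjacency matrix: the
#' stationary distribution of a damped random walk whose transition
#' probabilities are proportional to edge weight. Scores are converted
#' to ranks (1 = highest centrality, 379 = lowest); the control-cohort
#' median rank per region defines the listing order, and regions whose
#' patient median rank shifts by at least a threshold number of
#' positions are flagged, with the shift direction.
#' @name structural_centrality
NULL

#' Weighted PageRank of a structural connectome
#'
#' Power iteration on the column-stochastic weighted transition matrix
#' with uniform teleportation; rows with zero total weight (dangling
#' regions) teleport uniformly. Iterates to L1 tolerance `tol` and
#' errors if not converged within `max_iter`.
#'
#' @param connectome Nonnegative square weight matrix (streamline
#'   counts); symmetric matrices are treated as bidirectional directed
#'   graphs.
#' @param damping Damping factor in (0, 1); default 0.85.
#' @param tol L1 convergence tolerance (default 1e-10).
#' @param max_iter Maximum power iterations (default 1000).
#' @return Named numeric vector of PageRank scores summing to 1.
#' @examples
#' w <- matrix(1, 4, 4); diag(w) <- 0
#' weighted_pagerank(w)  # uniform 0.25 by symmetry
#' @export
weighted_pagerank <- function(connectome, damping = 0.85, tol = 1e-10,
                              max_iter = 1000L) {
  w <- as.matrix(connectome)
  n <- nrow(w)
  stopifnot(n == ncol(w))
  if (any(!is.finite(w))) stop("connectome weights must be finite")
  if (any(w < 0)) stop("connectome weights must be nonnegative")
  if (damping <= 0 || damping >= 1)
    stop("damping must lie strictly between 0 and 1")
  out_strength <- rowSums(w)
  dangling <- out_strength == 0
  # Column-stochastic transition matrix P[j, i] = w[i, j] / strength(i).
  P <- t(w / ifelse(out_strength == 0, 1, out_strength))
  x <- rep(1 / n, n)
  teleport <- (1 - damping) / n
  for (it in seq_len(max_iter)) {
    dangling_mass <- sum(x[dangling])
    x_new <- damping * (P %*% x + dangling_mass / n) + teleport
    x_new <- as.numeric(x_new)
    if (sum(abs(x_new - x)) < tol) {
      x <- x_new / sum(x_new)
      names(x) <- rownames(w) %||% colnames(w)
      return(x)
    }
    x <- x_new
  }
  stop("PageRank power iteration did not converge within ", max_iter,
       " iterations")
}

#' Convert centrality scores to ranks
#'
#' Descending-score ranking: rank 1 is the highest centrality, rank n
#' the lowest. Exact ties are broken deterministically by ascending
#' region position (region id), so the result is always a permutation
#' of 1..n.
#'
#' @param scores Named numeric centrality vector.
#' @return Named integer rank vector.
#' @export
rank_centralities <- function(scores) {
  n <- length(scores)
  ord <- order(-as.numeric(scores), seq_len(n))
  ranks <- integer(n)
  ranks[ord] <- seq_len(n)
  names(ranks) <- names(scores)
  ranks
}

#' Control-referenced rank-shift detection
#'
#' Computes per-region median ranks in each group, orders regions by
#' ascending control median rank (the listing order), and flags regions
#' whose patient median rank deviates from the control median by at
#' least `threshold` positions. Direction is `"higher"` centrality when
#' the patient median rank is numerically smaller. Whole subjects whose
#' rank vector is unusually discordant with the control median order
#' (Spearman correlation more than 3 raw MADs below the all-subject
#' median) are listed as rank outliers, descriptively.
#'
#' @param patient_ranks,control_ranks Matrices subjects x regions (or
#'   lists of rank vectors) from [rank_centralities()]; at least 3
#'   subjects per group, identical region sets.
#' @param threshold Minimum absolute median-rank shift to flag
#'   (default 20 positions).
#' @return A `deviation_report` list: `table` (data.frame `region`,
#'   `control_median_rank`, `patient_median_rank`, `shift`, `flagged`,
#'   `direction`, in listing order), `flags` (flagged subset),
#'   `heatmap` (all subjects x regions rank matrix in listing order,
#'   patients first), `outlier_subjects`.
#' @export
rank_deviation <- function(patient_ranks, control_ranks, threshold = 20) {
  as_mat <- function(x) {
    if (is.list(x) && !is.matrix(x)) x <- do.call(rbind, x)
    as.matrix(x)
  }
  pr <- as_mat(patient_ranks)
  cr <- as_mat(control_ranks)
  if (nrow(pr) < 3 || nrow(cr) < 3)
    stop("need at least 3 subjects per group for rank deviation")
  if (ncol(pr) != ncol(cr) ||
      (!is.null(colnames(pr)) && !is.null(colnames(cr)) &&
       !identical(colnames(pr), colnames(cr))))
    stop("patient and control rank matrices cover different region sets")
  regions <- colnames(pr) %||% as.character(seq_len(ncol(pr)))

  cmed <- apply(cr, 2, stats::median)
  pmed <- apply(pr, 2, stats::median)
  shift <- pmed - cmed
  listing <- order(cmed, seq_along(cmed))
  tab <- data.frame(region = regions,
                    control_median_rank = cmed,
                    patient_median_rank = pmed,
                    shift = shift,
                    flagged = abs(shift) >= threshold,
                    direction = ifelse(shift < 0, "higher",
                                       ifelse(shift > 0, "lower", "none")),
                    stringsAsFactors = FALSE)[listing, ]
  rownames(tab) <- NULL

  heat <- rbind(pr, cr)[, listing, drop = FALSE]
  rownames(heat) <- c(rownames(pr) %||% paste0("patient_", seq_len(nrow(pr))),
                      rownames(cr) %||% paste0("control_", seq_len(nrow(cr))))

  ref_order <- cmed
  sp <- apply(rbind(pr, cr), 1, function(r)
    stats::cor(r, ref_order, method = "spearman"))
  # High Spearman = concordant with the control listing order (ranks and
  # median ranks rise together); flag subjects far below the typical value.
  med_sp <- stats::median(sp)
  mad_sp <- stats::median(abs(sp - med_sp))
  outliers <- if (mad_sp > 0) names(sp)[sp < med_sp - 3 * mad_sp]
              else character(0)

  structure(list(table = tab, flags = tab[tab$flagged, ],
                 heatmap = heat, outlier_subjects = outliers,
                 threshold = threshold),
            class = "deviation_report")
}

#' @export
print.deviation_report <- function(x, ...) {
  cat(sprintf("<deviation_report> %d/%d regions shifted >= %g positions\n",
              nrow(x$flags), nrow(x$table), x$threshold))
  if (nrow(x$flags) > 0) print(utils::head(x$flags, 10))
  invisible(x)
}

#' PageRank ranks for every subject with a structural connectome
#'
#' @param cohort A `cohort_dataset` whose subjects carry `structural`
#'   matrices.
#' @param damping Damping factor for [weighted_pagerank()].
#' @return List of `patient` and `control` rank matrices
#'   (subjects x regions).
#' @export
cohort_rank_matrices <- function(cohort, damping = 0.85) {
  stopifnot(inherits(cohort, "cohort_dataset"))
  has_sc <- vapply(cohort$subjects, function(s) !is.null(s$structural),
                   logical(1))
  if (!all(has_sc))
    stop("structural connectomes missing for subject(s): ",
         paste(vapply(cohort$subjects[!has_sc], `[[`, "", "subject_id"),
               collapse = ", "))
  ranks <- t(vapply(cohort$subjects, function(s)
    rank_centralities(weighted_pagerank(s$structural, damping = damping)),
    integer(nrow(cohort$atlas))))
  rownames(ranks) <- vapply(cohort$subjects, `[[`, "", "subject_id")
  groups <- vapply(cohort$subjects, `[[`, "", "group")
  list(patient = ranks[groups == "patient", , drop = FALSE],
       control = ranks[groups == "control", , drop = FALSE])
}
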