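# Shared fixtures, built in code and memoized per test run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

default_atlas <- function() memo("atlas", build_default_atlas())

# Small cohort with a strong planted within-Language pair effect, used by
# several classifier tests.
planted_cohort_small <- function() memo("planted_small", {
  generate_cohort(
    synth_config(n_patients = 16, n_controls = 10, n_timepoints = 120,
                 fc_effects = list(list(region_a = "L_45",
                                        region_b = "L_44",
                                        delta = -0.8)),
                 seed = 101),
    default_atlas())
})

planted_feats_small <- function() memo("planted_small_feats",
  connectopy:::cohort_feature_matrix(planted_cohort_small()))

# n_pairs within-network coupling perturbations, spread evenly across
# the network's region pairs so every member region is touched.
spread_pair_effects <- function(atlas, network, n_pairs, delta) {
  regions <- atlas$name[atlas$network == network]
  pairs <- utils::combn(regions, 2)
  idx <- round(seq(1, ncol(pairs), length.out = n_pairs))
  lapply(idx, function(k) list(region_a = pairs[1, k],
                               region_b = pairs[2, k], delta = delta))
}

# Random symmetric nonnegative weight matrix on n nodes (connected w.h.p.).
random_connectome <- function(n, density = 0.5) {
  w <- matrix(0, n, n)
  ut <- upper.tri(w)
  vals <- stats::runif(sum(ut))
  vals[stats::runif(sum(ut)) > density] <- 0
  w[ut] <- vals * 10
  w <- w + t(w)
  diag(w) <- 0
  w
}

# Dense linear-algebra PageRank oracle: solves the stationarity system
# directly, with dangling nodes teleporting uniformly.
pagerank_dense_oracle <- function(w, damping = 0.85) {
  n <- nrow(w)
  strength <- rowSums(w)
  P <- t(w / ifelse(strength == 0, 1, strength))
  dangle <- as.numeric(strength == 0)
  M <- damping * (P + matrix(1 / n, n, n) %*% diag(dangle))
  x <- solve(diag(n) - M, rep((1 - damping) / n, n))
  x / sum(x)
}
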