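---
title: "Methods: connectome-based classification, anomaly counting and hub-shift analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: connectome-based classification, anomaly counting and hub-shift analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and coordinate system

`connectopy` implements a case-control connectome analysis pipeline on the
379-region HCP-MMP1 parcellation (180 cortical parcels per hemisphere, 9
subcortical structures per hemisphere, the brainstem as one midline parcel).
The pipeline starts at parcel level: regional BOLD time series and
streamline-count adjacency matrices are its inputs. Voxel-level processing —
motion correction, confound regression, tractography — is out of scope.

Every region carries one large-scale network affiliation. The packaged
default (`build_default_atlas()`) uses a Yeo-style scheme extended with the
left-lateralized Language (15 parcels: L_55b, L_8C, L_44, L_45, L_8BM,
L_IFJa, L_AIP, L_PFm, L_SFL, L_SCEF, L_PBelt, L_STSdp, L_STSvp, L_TE1p,
L_PHT) and AccessoryLanguage (L_STSda, L_TE1a, L_TGv, L_STSva) systems,
Auditory, MultipleDemand, VAN and a distinct MedialTemporal system; regions
without a confident affiliation are `"Unassigned"`. Network membership of
individual parcels is genuinely contested in the literature — left area 45
in particular is described both as a language region and as part of the
extended default mode network; the default table places it in Language.
Every analysis accepts a user-supplied affiliation CSV
(`load_affiliation_table()`) to override the default.

# The synthetic cohort generator

The generator stands in for non-public clinical data and defines the
conditions under which the package validates itself. Defaults emulate a
small clinical study: 31 patients and 17 controls, 240 timepoints at
TR = 2 s, a female-skewed patient group (26/31) against a balanced control
group (8/17), ages uniform on 20–35 years (both groups share the same age
distribution; sex is the only covariate carried into models), and
structural connectomes totalling 300,000 streamlines.

**Functional model.** Each of the 14 networks has a latent stationary AR(1)
factor (lag-1 coefficient 0.3, unit innovation SD). A region's series is
`latent_coupling` (default 1) times its network factor plus white noise
(`noise_sd`, default 1), giving within-network correlations near 0.52 and
cross-network correlations near 0 — block structure with two interpretable
knobs. Group effects are planted as *pair-specific shared latent
components*: for a pair effect of size `delta`, both regions receive a
shared standard-normal series scaled by `sqrt(|delta|)`, with opposite
signs when `delta < 0`. The planted covariance is therefore exactly
`delta`, each region's variance grows by `|delta|`, and the induced
correlation is available in closed form — the oracle used in tests. Effects
pass through the genuine Pearson pipeline rather than editing correlation
matrices.

**Structural model.** Edge weights are hierarchical log-normal:
`log w_ij = 2 + a_i + a_j + e_ij` with per-region propensities
`a ~ N(0, 0.45^2)` drawn once per cohort seed and shared by all subjects,
and subject noise `e ~ N(0, 0.771^2)`, so the marginal edge weight is
log-normal with sdlog 1 (heavy-tailed, like empirical streamline counts)
while the expected hub ordering persists across subjects. The persistence
term is essential: with independent edges, node strengths are exchangeable
and per-subject centrality ranks are pure noise, making hub analysis
meaningless. Matrices are symmetrized, patient-side hub effects multiply
the named region's row and column, and weights are rescaled and rounded so
streamlines over unique pairs total `total_streamlines`.

**Reproducibility.** One master seed drives named substreams (one per
subject per quantity), so adding subjects to one group leaves the other
group's data bit-identical.

**What the generator does not emulate:** spatial autocorrelation and
distance-dependent connectivity, head-motion and physiological artefacts,
global signal, non-Gaussian BOLD marginals, and any coupling between the
functional and structural channels. Passing recovery tests therefore show
that the estimators work when their generative assumptions hold at the
study's sample sizes — not that real migraine effects are detectable.

# Functional connectivity features

Connectivity is the plain Pearson correlation over the full provided
series; no Fisher z-transform, scrubbing or windowing. The self-inclusive
correlation set on 379 regions has 379² = 143,641 entries. Classification
uses each unordered off-diagonal pair once — 71,631 features in a fixed
row-major upper-triangle order — because the diagonal is constant 1 and the
lower triangle duplicates the upper; `vectorize_features(fc, full = TRUE)`
restores the redundant full-matrix set for fidelity experiments. A
zero-variance series is an error naming the region, not a silent `NA`.

# Classification and directional importance

Diagnostic group is modelled by gradient-boosted trees (XGBoost,
`binary:logistic`) on the FC features plus a binary sex covariate.
Evaluation is stratified 5-fold cross-validation scored by mean held-out
AUC-ROC, with the probability direction pinned (higher score = patient) so
that null-data AUC centres on 0.5 rather than being inflated by direction
auto-selection. Trees are grown with the exact (presorted) algorithm:
deterministic, and for designs of ~50 subjects by ~72k features it is also
the fastest option available.

Tunable knobs follow the three the study varied — learning rate
(default grid 0.05/0.1/0.3), maximum tree depth (2/3/4; the study's
"minimum tree depth" wording is interpreted as the standard max-depth
control), and seed (0/1/2) — with 100 boosting rounds fixed.
`tune_hyperparameters()` selects on the same CV it reports, the optimistic
protocol; `nested_crossval_classify()` wraps selection in an outer fold
loop and is the honest generalization estimate. Both are reported by the
pipeline. Published headline AUCs from any particular clinical cohort are
not reproduction targets here: synthetic cohorts answer calibration and
recovery questions instead.

Feature influence is a signed SHAP-style summary, deliberately named
`directional_importance` rather than after any published linearization
method: magnitude is the mean absolute per-subject additive attribution
(xgboost's `predcontrib`), direction the sign of the Pearson correlation
between feature value and attribution across subjects. Attributions sum to
the prediction margin per subject to single-precision accuracy (~1e-5 with
70k features; xgboost emits float32 contributions). Region scores credit
each pair feature's full magnitude to both endpoints; a network's value is
the mean over its member regions' scores, so `sum(region scores) = 2 ×
sum(feature magnitudes)` exactly.

The label-permutation null (`permutation_null_auc()`) re-runs the full CV
per permuted labelling, re-stratifying folds each time (a fixed fold
partition can leave a held-out fold single-class, where AUC is undefined).
The calibration experiment in the test suite uses 100 permutations of the
default 31/17 null cohort with a light spec (depth 2, 30 rounds, 5% column
subsampling per tree) — under exchangeable labels calibration does not
depend on model capacity, and this spec completes 500 fits in a few
minutes on one core.

# MAD anomaly counting

For each FC feature the controls define a robust reference: median and raw
MAD (no 1.4826 normal-consistency constant — a `scaled` flag enables it).
A patient's feature is anomalous when it deviates from the control median
by at least 3 MADs (inclusive; implemented with a 1e-9 relative epsilon so
an exactly-3-MAD deviation counts despite floating point). Features with
zero control MAD are excluded rather than auto-flagged: with 17 controls,
ties can zero the MAD and would otherwise flag trivially. A within-network
anomaly increments its network once; a cross-network anomaly increments
both endpoint networks once each (half-credit by flag), so a patient's
total equals within-anomalies + 2 × cross-anomalies.

Two structural facts of this procedure matter for interpretation. First,
the raw-MAD threshold of 3 corresponds to roughly ±2 SD under normality,
so a null anomaly rate of several percent per feature is expected — counts
are descriptive, not inferential. Second, a network's null count is
proportional to its pair degree (number of incident unique pairs), so
large networks dominate the raw table. The recovery experiment in the test
suite therefore perturbs 50 pairs spread across the Visual network — large
enough that broad within-network attenuation outweighs the size advantage
of the still-larger DMN, making "Visual tops the table" a genuine recovery
signal rather than a degree artefact. A small network (e.g.
AccessoryLanguage, 4 regions) cannot top this counting scheme regardless
of effect size; comparisons across networks of very different sizes should
be read accordingly.

# Weighted PageRank and rank shifts

Hubness is the stationary distribution of a damped random walk on the
streamline graph: transition probabilities proportional to edge weight,
uniform teleportation, damping 0.85 (not dictated by the application;
exposed). Symmetric matrices are treated as bidirectional directed graphs.
Power iteration runs to L1 tolerance 1e-10 (max 1000 iterations, error on
non-convergence); rows with zero strength teleport uniformly. The
implementation is checked in tests against a dense stationary solve and an
independent graph-library implementation.

Scores become ranks 1 (highest centrality) to 379, ties broken by
ascending region id so the result is always a permutation. Regions are
listed by ascending control median rank; a region is flagged when the
patient median rank shifts by at least 20 positions (a package decision
replacing visual heatmap inspection; configurable), with direction
"higher" centrality when the patient median rank is smaller. Subjects
whose rank vector's Spearman correlation with the control listing order
falls more than 3 raw MADs below the cohort median are listed as
whole-subject outliers, purely descriptively.

# Demographics and the pipeline driver

Sex is compared by Chi-squared on the 2×2 group-by-sex table — reported
both with and without Yates continuity correction, since small-cohort
conventions differ and the choice moves the statistic substantially at
these sizes — and age by Mann-Whitney U, with medians and IQRs per group.
Constant variables are skipped with a notice rather than tested.

`run_pipeline()` chains synthesis (or loading a cohort directory),
demographics, FC extraction, untuned and tuned classification with
importance aggregation, MAD counting, and rank-shift analysis; all tabular
outputs are CSV, structured outputs JSON, and a manifest records the seed,
package version and an MD5 checksum per output file. All randomness flows
from the single config seed through named substreams; two runs with the
same config are byte-identical.

# Numerical and design choices

- Pearson via the standard `cor()`; equality with a two-pass computation
  is asserted to 1e-12 in tests.
- PageRank convergence: L1 tolerance 1e-10, max 1000 iterations; the
  oracle equivalence suite demands 1e-8 agreement with a dense solve.
- Rank ties: ascending region id — deterministic, hemisphere-stable.
- Tuning ties: smaller depth, then smaller learning rate, then smaller
  seed — prefer the simpler model.
- Degenerate inputs error early and name the offending region, fold or
  file (zero-variance series, single-class folds, missing structural
  matrices, malformed affiliation tables).

# Problem sizes used in the validation suite

Recovery experiments run at the emulated study scale — 31/17 subjects, 240
timepoints, 379 regions — over 10 generator seeds each; the permutation
null uses 100 permutations; oracle equivalence uses 50 random graphs of up
to 20 nodes; end-to-end determinism is exercised on an 8/6-subject,
60-timepoint configuration with a 2-point grid, sizes chosen so the full
suite stays comfortably desktop-scale.

# Known limitations

- The generator's independence assumptions (no spatial autocorrelation, no
  global signal, functional and structural channels decoupled) make the
  planted-effect recovery results upper bounds on real-data behaviour.
- Anomaly counts and network importance both aggregate over networks of
  very different sizes; neither is size-normalized, by design fidelity to
  the procedure they implement.
- Tuned-on-reporting-CV AUC is optimistically biased; use the nested
  estimate for generalization claims.
- No multimodal fusion of functional and structural channels.
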