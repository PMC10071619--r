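# connectopy

Case-control analysis of brain connectomes on the 379-region HCP-MMP1
parcellation, for researchers studying disorders — chronic pain and
migraine among them — through resting-state functional connectivity and
diffusion tractography. The package takes parcel-level data (regional BOLD
time series and streamline-count adjacency matrices) and answers four
questions about a patient group against a control group:

1. **Can diagnostic group be classified from functional connectivity?**
   Subject-level FC is the Pearson correlation matrix over all region
   pairs (self-inclusive: 379² = 143,641 correlations); its 71,631 unique
   off-diagonal pairs, plus a sex covariate, feed a gradient-boosted-tree
   classifier (XGBoost) evaluated by stratified 5-fold cross-validation
   with mean held-out AUC-ROC, with grid tuning over learning rate, tree
   depth and seed (and a nested-CV variant protecting the estimate from
   selection bias).
2. **Which connections and networks drive the classification?** Signed
   SHAP-style attributions: per-feature magnitude = mean |per-subject
   additive attribution|, direction = sign of the value–attribution
   correlation; region scores credit each pair to both endpoints, and
   network importance is the mean over member-region scores.
3. **Where is a patient's FC anomalous?** Control-group median and raw
   median absolute deviation per feature; a patient feature deviating by
   ≥ 3 MADs is an anomaly, counted per large-scale network.
4. **Which structural hubs shift?** Weighted PageRank on the streamline
   graph (power iteration, damping 0.85), ranks 1–379 per subject, and
   flags for regions whose patient median rank shifts ≥ 20 positions from
   the control median ordering.

Because clinical cohorts of this kind are rarely public, the package
includes a first-class synthetic-cohort generator (network latent-factor
BOLD model, hierarchical log-normal streamline model, ~300,000 streamlines
per brain) with plantable pair-coupling and hub effects, emulating a
31-patient / 17-control study design (240 timepoints, TR = 2 s, sex split
26F/5M vs 8F/9M). All validation runs against it; see
`vignettes/methods.Rmd` for the models, assumptions and limitations.

## Worked example

Generate a cohort with a planted functional effect (lowered L_45–L_23c
coupling in patients) and a planted structural effect (1.5× boosted right
amygdala connectivity), then run each analysis:

```r
library(connectopy)
atlas  <- build_default_atlas()
cfg    <- synth_config(
  fc_effects  = list(list(region_a = "L_45", region_b = "L_23c", delta = -0.4)),
  hub_effects = list(list(region = "R_Amygdala", factor = 1.5)),
  seed = 1)
cohort <- generate_cohort(cfg, atlas, structural = TRUE)
#> <cohort_dataset> 31 patients, 17 controls, T = 240, 379 regions

crossval_classify(cohort, model_spec(seed = 1))
#> <cv_result> mean AUC 0.950 +/- 0.068 over 5 folds

imp <- directional_importance(cohort, model_spec(seed = 1))
head(imp[, c("feature", "magnitude", "direction")], 3)
#>        feature magnitude direction
#> 1   L_23c|L_45 2.6474596        -1
#> 2 L_5mv|R_PoI2 0.1499844        -1
#> 3   L_SFL|L_45 0.1375178        -1

head(as.data.frame(aggregate_by_network(imp, atlas)), 3)
#>    network mean_importance
#> 1 Language     0.194833020
#> 2 Salience     0.098278275
#> 3   Visual     0.007870279

ranks <- cohort_rank_matrices(cohort)
rank_deviation(ranks$patient, ranks$control)$flags[
  , c("region", "control_median_rank", "patient_median_rank", "direction")]
#>         region control_median_rank patient_median_rank direction
#> 349 R_Amygdala                 349                 255    higher
```

Reading the output: the held-out AUC of 0.95 says the planted effect makes
patients separable at this sample size; the planted pair `L_23c|L_45` is
the top feature by an order of magnitude, its negative direction meaning
*lower* FC there pushes predictions toward the patient class; the Language
network (home of L_45) tops the network table; and the only flagged hub
shift is the boosted right amygdala, at *higher* centrality in patients
(median rank 255 vs 349). `anomaly_report(cohort)` adds per-network MAD
anomaly counts, `demographics_table(cohort)` the group comparison
(Chi-squared for sex, Mann-Whitney U for age), and `run_pipeline()` chains
everything and writes CSV/JSON outputs with a checksummed manifest.

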