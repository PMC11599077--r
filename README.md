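# sigroi

Subgroup discovery in vaccination-attitude surveys via spatial
information gain.

## What it does, and for whom

Public-health teams running Likert-battery surveys (vaccine hesitancy,
trust in doctors, pharmacists, and public health authorities) usually ask
*which perceptions predict vaccine uptake on average*. `sigroi` asks a
sharper question: **where in the population does a specific perception
cleanly separate vaccinated from unvaccinated respondents?** Respondents
who share a perception profile with highly vaccinated peers but report few
or no doses are promising targets for outreach — and the factor that
splits them from those peers names the concern to address.

The pipeline:

1. **Ingestion** — validate responses against a scale schema, reflect
   reverse-phrased items (`v -> min + max - v`), encode the dose outcome
   (0–5, "5 or more" capped), summarize the cohort.
2. **Factor extraction** — per scale: Pearson correlation matrix, Ward
   agglomeration on `d = 1 - pcc`, cluster count chosen by a centroid
   silhouette (threshold 0.25) and per-cluster correlation floors; factor
   scores aggregate each cluster's items.
3. **Latent projection** — UMAP (or deterministic PCA) of the z-scored
   factor scores into 2D; a square grid with step 0.5 over the extrema.
4. **Spatial information gain** — per cell and factor, binarize the factor
   at the cell median and compute the expected KL divergence of the
   conditional dose distribution from the cell's marginal:

   `SIG = sum_a P(a) KL( P(dose|a) || P(dose) ) = I(dose; split)` (nats),

   the plug-in mutual information. Sum over factors, interpolate with a
   Gaussian kernel `h(p) = sum_v h_v exp(-||p-v||^2 / (2 sigma^2)) / (sqrt(2 pi) sigma)`,
   threshold at 34% of the surface maximum, and extract 8-connected
   regions of interest (ROIs) with their dose mean ± SD.
5. **Profiling** — per ROI: factors with `|pcc| >= 0.2` against dose;
   chi-square goodness-of-fit disparity of each demographic variable
   against whole-cohort expectations (expected counts < 5 pooled), with
   significance stars and pie-chart data.
6. **Regression benchmark** — a configurable model suite (linear and
   penalized linear, Huber, tree, kNN, random forest, extra trees,
   gradient boosting, plus a dummy baseline) on a 70/30 split with 10-fold
   CV for tunable settings, reporting R², MAE, MSE, RMSE, RMSLE, MAPE;
   predictor ranking by feature importance and Monte-Carlo Shapley values
   with multi-seed stability.

A fully seeded synthetic-survey generator (`synthetic_config()`,
`generate_dataset()`) plants item clusters with calibrated
post-discretization correlations, factor-driven doses, demographic shifts,
and compact high-dose-variance subgroups — so the whole pipeline is
testable with known ground truth.

## Worked example

Run the full pipeline on a synthetic benchmark cohort (3000 respondents,
85 items in four scales, 16 planted item clusters, and one planted
subgroup whose first hesitancy factor splits its doses):

```r
library(sigroi)

cfg    <- roi_benchmark_config(seed = 42)
result <- run_pipeline(cfg, pipeline_config(embedding_method = "pca",
                                            min_cell_members = 75))

result$solutions[["CoVaH"]]   # per-k quality table for one scale
#> factor_solution [CoVaH] chosen k = 4
#>  k    sc pcc_mean_min pcc_pair_min pcc_var_sum admissible
#>  2 0.637        0.423        0.248    0.053138      FALSE
#>  3 0.699        0.509        0.264    0.061750      FALSE
#>  4 0.890        0.722        0.709    0.000152       TRUE
#>  5 0.729        0.723        0.720    0.000133       TRUE
#>  6 0.748        0.723        0.723    0.000122       TRUE
#>  7 0.716        0.723        0.723    0.000122       TRUE
#>  8 0.693        0.733        0.728    0.000122       TRUE

result$sig                    # the spatial stage
#> sig_surface: 19 x 18 grid, 16 factors, max smoothed 0.483, cutoff 0.164
#>   1 ROI subgroup(s)
#>   ROI-1: n = 362, dose 2.5 +/- 2.5, 23 cells, peak signal 0.483

result$profiles[["ROI-1"]]
#> ROI-1 (n = 362): dose 2.5 +/- 2.5
#>   correlated factors:
#>     C-c1     pcc = +0.89
#>   no significant demographic disparity
```

Reading the output: the silhouette peaks at k = 4 for the first scale and
only k >= 4 clears the within-cluster correlation floor of 0.7, so four
factors are extracted (16 across the four scales). The spatial stage finds
one region whose members average 2.5 doses *with a standard deviation of
2.5* — a subgroup of similar perceptions and sharply divided uptake — and
the screen identifies factor `C-c1` as the axis of that divide
(pcc = +0.89 with dose inside the region). That factor, for this planted
cohort, is exactly the generator's dose-driving factor.

`render_report(result, "figures/")` writes the functional figure set (PCC
heatmaps with cluster frames, embedding scatters, the SIG contour map with
dashed levels at 0/17/34/51% of the maximum, per-ROI pies). A thin
command-line front-end lives at `inst/cli/sigroi-pipeline.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/sigroi-pipeline.R", package="sigroi"))')" \
    --synthetic --seed 42 --embedding pca --out runs/demo --report
```

## Documentation

The methods vignette (`vignettes/sigroi-methods.Rmd`) covers the model and
its assumptions, every tunable parameter with its default and rationale,
the synthetic generator's scope and blind spots, numerical conventions,
and known limitations.
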