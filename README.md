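# contextpriors

Humans form systematic expectations about objects that are *absent* from a
scene: how likely a car or a person is to appear, and where and at what
size it would. `contextpriors` is an R package for researchers in visual
psychophysics and computational cognitive science who want to measure such
contextual expectations behaviourally, model them from scene features, and
use the modelled priors to improve object detectors.

The pipeline has four scientific stages:

1. **Expectation models.** Per-scene mean ratings (likelihood in [0, 1];
   box x, y, area, aspect from the raters who gave a non-zero likelihood)
   are regressed on three feature channels — target-detector summaries
   (**T**, 62 dims), binary nontarget-object labels (**N**) and coarse
   scene features (**C**) — each reduced to its first 20 principal
   components so channels compete at equal complexity. Models are ordinary
   least squares, `y = Xb`, evaluated by the Pearson correlation between
   concatenated out-of-fold predictions and observed ratings (5-fold CV).
2. **Model comparison and noise ceiling.** All seven channel subsets
   (T, N, C, TN, TC, NC, TNC) are compared over 1000 random 80–20
   resamplings; significance is the *exceedance fraction* — the fraction
   of resamplings in which a competitor beats the best subset. The ceiling
   on attainable performance is the Spearman–Brown-corrected split-half
   correlation of the subject means, `rc = 2r/(r + 1)`.
3. **Late fusion.** Priors predicted for novel scenes (from the
   coarse-feature-only models, which need no manual annotation) are
   concatenated with a detector's confidence score and classified by
   5-fold cross-validated linear discriminant analysis; gains are reported
   as top-1 accuracy deltas in percentage points and as ROC/AUC
   improvements.
4. **Transfer.** The association index
   `|p(object | anchor present) − p(object)|` quantifies co-occurrence
   coupling, and the package tests whether strongly coupled categories
   gain more from the anchor's priors.

A synthetic-data module (`generator_config()`, `generate_scene_set()`,
`generate_subject_ratings()`, `generate_eval_set()`) generates behavioural
and evaluation datasets with this exact statistical structure and known
ground truth — 650 scenes, 11 subjects, a long-tailed 36-label nontarget
vocabulary, rating noise calibrated to a ~0.9 likelihood ceiling — so the
whole pipeline is testable without any data downloads. See the methods
vignette (`vignettes/contextual-priors.Rmd`) for the model, the generator
design, and every numerical convention.

## Worked example

```r
library(contextpriors)

cfg     <- generator_config(seed = 42)       # the default study conditions
ss      <- generate_scene_set(cfg)
ratings <- generate_subject_ratings(ss)
agg     <- aggregate_ratings(ratings)

car <- agg[agg$category == "car", ]
y   <- car$likelihood[match(rownames(ss$channels$T), car$scene_id)]

noise_ceiling(ratings, "likelihood", "car", seed = 1)$mean  # 0.90
compare_models(ss$channels, y, n_splits = 200, seed = 2)
#> Model comparison over 200 random 80-20 splits (reference: NC)
#>   T    -0.04 +/- 0.03  exceedance 0.000
#>   N     0.35 +/- 0.01  exceedance 0.000
#>   C     0.72 +/- 0.00  exceedance 0.000
#>   TN    0.31 +/- 0.01  exceedance 0.000
#>   TC    0.71 +/- 0.01  exceedance 0.000
#>   NC    0.80 +/- 0.00  (reference)
#>   TNC   0.79 +/- 0.01  exceedance 0.000
```

The nontarget + coarse (NC) model predicts held-out likelihood ratings at
r = 0.80 against a noise ceiling of 0.90; single channels are decisively
worse (exceedance 0), and the target-only model is at chance — the
expectations live in the nontargets and the coarse scene structure, as the
generator prescribes.

Fusing the predicted likelihood prior with a synthetic detector
(AUC 0.85, 3000 scenes per class):

```r
m  <- fit_expectation_model(ss$channels, y, "C",
                            response = "likelihood", category = "car")
es <- generate_eval_set(eval_config(seed = 3), truth = ss$truth,
                        category = "car")
ev <- cbind(es$eval[c("label", "score")],
            predict_priors(list(likelihood = m), es$eval))
augmentation_table(ev, list(lklhd = "prior_likelihood"), seed = 4)
#>     config accuracy_mean       auc delta_points
#> 1 baseline     0.7636667 0.8502419         0.00
#> 2    lklhd     0.7911667 0.8731812         2.75
```

The prior lifts cross-validated top-1 accuracy by 2.75 percentage points
and AUC by 0.023 — scenes whose context says "car plausible" rescue weak
detections, and implausible contexts suppress false alarms.

The end-to-end pipeline (simulate → aggregate → fit → compare → ceiling →
fuse → transfer → report) runs with one master seed and writes CSVs plus a
checksummed manifest:

```r
res <- run_pipeline(default_run_config(seed = 1), out_dir = "runs/demo")
cat(report(res$dir), sep = "\n")
```

or from the shell via
`Rscript inst/scripts/contextpriors-pipeline.R --out runs/demo --seed 1`.

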