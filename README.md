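# ttrec — two-tower content-based drug response recommendation

Cytotoxic chemotherapy works for some tumors and fails for others, and the
difference is written in the tumor itself. `ttrec` is an R package for
oncology-minded computational scientists that predicts per-pair drug
sensitivity with a content-based filtering recommender: tumor samples are
"users", drugs are "items", and a learned scorer rates every (sample, drug)
pair from features of each side alone — so new samples can be scored against
the whole drug panel.

**Sample features** are the tumor-microenvironment triple: phenotype dummies
(sex, decade-binned age, cancer type), binary non-silent mutation status over
a driver-gene panel, and the panel's expression in TPM. **Drug features**
are hashed Morgan/ECFP fingerprints (512 bits, radius 2, via RDKit).
**Responses** are harmonized per endpoint: ln IC50, MFI log-fold-change
as-is, or best overall response collapsed to PD vs non-PD.

Two fusion architectures share this input; both are MLP towers with ReLU
hidden layers and linear tower outputs, trained with Adam on

&nbsp;&nbsp;&nbsp;&nbsp;MSE + α · Σ‖W‖²&nbsp;&nbsp;&nbsp;&nbsp;(uniform L2 on all weight matrices),

* **dot** — score = ⟨V_sample, V_drug⟩, an explicitly bilinear fusion;
* **concat** — tower outputs concatenated and passed through one more dense
  block ending in a linear scalar.

α is tuned by sample-level k-fold cross-validation over the grid
{1, 1e-1, …, 1e-5}. Downstream, the package evaluates predictions with
grouped Pearson correlations (overall / per cancer type / per drug / per
cell) and turns per-patient scores into the standard clinical read-out:
median-split Kaplan–Meier curves with Greenwood variance, log-rank,
univariate Cox HR (Breslow ties), fixed-horizon survival-rate z-tests, and
cumulative/dynamic time-dependent ROC with KM censoring weights. A seeded
synthetic-cohort generator with a recoverable bilinear latent signal makes
the whole pipeline testable without any external download.

## Worked example

```r
library(ttrec)

cohort   <- simulate_cohort(sim_config(n_samples = 120, n_drugs = 8,
                                       n_genes = 100, seed = 1))
features <- featurize_cohort(cohort$phenotype, cohort$mutations,
                             cohort$expression, cohort$drugs)
pairs    <- build_pairs(features$sample_features, features$drug_features,
                        cohort$response, phenotypes = cohort$phenotype,
                        schema = features$schema)
#> <pair_dataset> 960 pairs (120 samples x 8 drugs measured), endpoint IC50
#>   sample features: 224, drug features: 512

split <- stratified_split(pairs, train_frac = 0.75, seed = 2)
fit   <- train_recommender(split$train,
                           model_config(architecture = "concat",
                                        l2_alpha = 1e-3, epochs = 60, seed = 3))
#> <ttrec_model> concat fusion, trained, 154,241 parameters
#>   sample tower: 224 -> [256, 64] -> 32
#>   drug tower:   512 -> [128, 64] -> 32
#>   final training MSE: 0.06495

report <- evaluate_scores(score_pairs(fit, split$test))
#> <ttrec_eval> overall r = 0.869 (p = 1.52e-74, n = 240)
#>   12 cancer types, 8 drugs, 96 cells (min n = 3)
```

The held-out correlation of 0.87 says the model recovered most of the
planted bilinear signal from the encoded features (the generator's 4:1
signal-to-noise ratio caps the attainable r near 0.97). Per-group numbers
live in `tidy(report)`, and `autoplot(report)` draws the per-drug /
per-cancer bars.

Clinical stratification of the same cohort's survival arm:

```r
surv     <- cohort$survival
surv$bor <- cohort$bor$value
clinical_report(surv, horizons = c(6, 12))
#> <ttrec_clinical> 120 patients (low 60 / high 60), 86 events
#>   log-rank chi2 = 11.120 (p = 0.000854); HR(low vs high) = 0.477 [0.31, 0.74]
#>   6-month rate: low 0.7922 vs high 0.5600 (p = 0.00564)
#>   12-month rate: low 0.6071 vs high 0.3415 (p = 0.0042)
#>   AUC at 6 months: 0.716
#>   AUC at 12 months: 0.725
```

Low predicted scores (predicted-sensitive tumors) progress later: the hazard
ratio below 1, the higher 6-month progression-free rate, and the
time-dependent AUC all measure the same planted association between the
response surface and the hazard.

`run_pipeline()` chains all stages (simulate → fingerprint → featurize →
split → tune → train → predict → evaluate → clinical) from a JSON/YAML
config with artifacts and a provenance manifest on disk; `inst/cli/ttrec`
is a thin command-line wrapper over it. The methods vignette
(`vignettes/drug-response-recommendation.Rmd`) documents the model,
the statistics, every tunable default, and the synthetic world's scope.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

re-runs the package's main computation from scratch at the reference scale —
generates the 542 × 18 × 776 synthetic cohort under `--seed`, featurizes,
splits 75:25 by cancer type, trains the concat model (α = 1e-3, 100 epochs),
evaluates held-out correlation, and computes the clinical survival
statistics — then writes its JSON result object to `--out`.
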