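# anfisdd — explainable neuro-fuzzy screening for early developmental disability

`anfisdd` is an R package for building and evaluating an interpretable
screening classifier for developmental disability in children aged 1–6
years. It targets the common situation in pediatric decision support where
tabular multi-domain assessment data (cognitive, behavioral, motor, social
interaction scores on a 0–100 scale, plus age, sex, and family history) must
be turned into a diagnostic probability **and** an explanation a clinician
can interrogate: which domains drove the call, how strongly, and with what
confidence.

The package is aimed at methodologists and applied biostatisticians who want
a complete, reproducible workbench for this class of model: a seeded
synthetic cohort generator (so every stage is testable without access to
clinical records), deterministic preprocessing, engineered cross-domain
features, the classifier itself, and the full evaluation and reporting
stack.

## The model

The classifier is an Adaptive Neuro-Fuzzy Inference System (ANFIS) of the
first-order Sugeno type with five layers:

1. **Fuzzification.** Each of the 11 normalized input features *x*ᵢ is mapped
   through three Gaussian membership functions (Low, Medium, High),
   μ(x) = exp(−(x − c)² / 2σ²), with centers *c* and widths *σ* learned
   during training.
2. **Rule firing.** Each of 8 fuzzy rules selects one membership function
   per feature; its firing strength is the product T-norm
   wₖ = ∏ᵢ μₖᵢ(xᵢ), computed in log-space with memberships floored at
   ε = 10⁻¹² so the 11-way product cannot underflow.
3. **Normalization.** w̄ₖ = wₖ / Σⱼ wⱼ.
4. **Consequents.** Each rule carries a linear function
   fₖ(x) = pₖᵀx + rₖ of the inputs.
5. **Output.** y = sigmoid(Σₖ w̄ₖ fₖ(x)), a probability of developmental
   disability, thresholded at 0.5.

All parameters (centers, widths, slopes, intercepts) are trained jointly by
Adam on binary cross-entropy (learning rate 0.01, batch size 32, up to 100
epochs) with a 20% stratified validation hold-out, early stopping at
patience 10, and best-epoch weight restoration. Rule antecedents are
initialized by k-means clustering of the training features.

The 11 model inputs are the four raw domain scores, four age-adjusted ratios
(score / age), two cross-domain ratios — cognitive/(social+1) and
motor/(behavioral+1) — and a weighted composite risk score
0.3·(100−cog) + 0.2·(100−beh) + 0.2·(100−mot) + 0.3·(100−soc), multiplied
by a family-history factor (default 1.25) when history is positive.

Evaluation covers confusion-matrix metrics, ROC AUC (Mann–Whitney
concordance with ties counted ½), stratified 5-fold cross-validation, and
perturbation feature importance (each feature zeroed in turn; importance =
accuracy drop). Reports stratify confidence |p − 0.5| / 0.5 into Low (≤ 0.5),
Medium (0.5–0.8], High (> 0.8).

## Worked example

```r
library(anfisdd)

# 1. a seeded cohort with the study's group structure (4,311 + 689 children)
cohort <- generate_cohort(cohort_config(seed = 1))
summarize_cohort(cohort)
#> Cohort summary (n = 5000)
#>   prevalence 0.138, female 0.511, family history 0.515 (group0 0.456 / group1 0.887)
#>      domain mean_group0 sd_group0 mean_group1 sd_group1 mean_overall sd_overall r_point_biserial
#>   cognitive       60.66    14.289       52.40    16.673        59.52     14.913          -0.1908
#>  behavioral       55.78     9.375       50.23    11.263        55.02      9.844          -0.1946
#>       motor       51.02     7.755       45.17     8.068        50.21      8.054          -0.2505
#>      social       51.17    11.526       41.55    10.907        49.84     11.913          -0.2784
#>   phi(family history, diagnosis) = 0.297

# 2. preprocess, engineer the 11 features, split 80/20
cohort <- encode_sex(cohort)
parts  <- stratified_split(cohort, 0.20, seed = 1)
scaler <- fit_scaler(as.data.frame(build_feature_matrix(parts$train)))
X_train <- build_feature_matrix(parts$train, scaler = scaler)
X_test  <- build_feature_matrix(parts$test,  scaler = scaler)

# 3. train the ANFIS (Adam, early stopping on a 20% validation hold-out)
fit <- anfis_train(X_train, parts$train$diagnosis, training_config(seed = 1))
#> ANFIS fit: 100 epochs (best epoch 98)
#>   final train loss 0.2646 acc 0.894; val loss 0.2688 acc 0.897

# 4. held-out evaluation
p <- predict(fit$model, X_test)
m <- metrics_from_confusion(confusion(parts$test$diagnosis, p))
m$auc <- roc_auc(parts$test$diagnosis, p)
m
#>   accuracy             0.8940
#>   sensitivity          0.3986
#>   specificity          0.9733
#>   auc                  0.8646
```

Test accuracy 0.894 beats the majority-class rate (0.862) and AUC 0.865
shows solid ranking; sensitivity is low at the fixed 0.5 threshold because
the synthetic group distributions overlap heavily — exactly the behavior the
density analysis of the assessment domains predicts for a 13.8%-prevalence
cohort with no reweighting.

A clinical report for a child with scores 64.45 / 74.14 / 68.35 / 61.20 and
no family history:

```r
case <- data.frame(child_id = "CASE1", age = 4L, sex = "female",
  cognitive_score = 64.45, behavioral_score = 74.14, motor_skills = 68.35,
  social_interaction = 61.20, family_history = 0L, diagnosis = 0L)
generate_report(case, fit$model, scaler)
#> Clinical screening report
#>   Prediction:  No diagnosis (p = 0.001)
#>   Confidence:  99.9% (High)
#>   Cognitive-social ratio: 1.04; composite risk: 33.81
#>   Recommendation: Continue routine monitoring
```

The cognitive–social ratio of 1.04 (≈ 1 means balanced cognitive–social
development) and the low composite risk of 33.81 are computed on the raw
score scale before normalization.

A command-line front end wrapping the same functions lives at
`inst/cli/anfisdd.R` (subcommands `simulate`, `train`, `evaluate`,
`crossval`, `importance`, `report`; common flags `--config`, `--seed`,
`--out`).

## Documentation

The methods vignette (`vignettes/anfis-screening.Rmd`) describes the
generative model behind the synthetic cohorts, what it does and does not
emulate about real assessment data, the ANFIS architecture and training
choices, numerical safeguards, and known limitations.
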