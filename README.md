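# gspsvm

Hybrid metaheuristic tuning of RBF support vector machines for
computer-aided diagnosis.

## The problem

An RBF-kernel SVM classifies well only when its two hyperparameters are
right: the soft-margin penalty `c` (trade-off between margin width and
training error) and the kernel coefficient `g` in
`K(x, x') = exp(-g * ||x - x'||^2)`. On small clinical tables — a few
hundred patients, ordinal or categorical attributes — grid search is
coarse and single metaheuristics stall in local optima. `gspsvm`
implements a fused search (the *GSP* engine) that runs a real-coded
genetic algorithm and a particle swarm side by side:

- the swarm's inertia weight follows the harmonic schedule
  `omega_m = omega1 - (omega1 - omega2) * (m - 1)^2 / t^2`, shifting from
  exploration to exploitation;
- every particle move passes a Metropolis gate: worsening moves are
  accepted with probability `exp(delta_f / t_temp)` under geometric
  cooling, so the swarm can escape local optima early;
- each generation, the better of the two populations' incumbents
  overwrites the other population's worst member (migration).

Fitness is the training-partition classification accuracy of the SVM at
the candidate `(c, g)` (5-fold cross-validated by default); `c` is
searched in [0.1, 100] and `g` in [0.01, 1000], the latter on a log
scale. Baselines with the same result contract: exhaustive log-spaced
grid search, GA-only, PSO-only, a fixed-parameter SVM (`c = 100`,
`g = 4`) and a PCA + fixed-parameter SVM.

Around the optimizer sit the pieces needed to run a full comparison:
preprocessing for ordinal clinical tables (ID-column drop, deletion of
records with missing-value tokens, min-max scaling to [0,1] fitted on
the training partition only), seed-reproducible stratified splits,
synthetic generators for both binary ordinal and multiclass categorical
diagnostic data, and a metric suite covering precision, recall,
specificity, G-mean, F-beta, Matthews correlation, AUC, micro-averaged
multiclass scores, Hamming loss, Cohen's kappa and micro Jaccard.

## Worked example

```r
library(gspsvm)

# a 300-patient synthetic ordinal table, two well-separated classes
d <- synth_binary(300, separation = 12, noise_sd = 1.5, seed = 5)

sp <- random_split(d, 0.7, seed = 42)          # stratified 70/30 split
scaler <- fit_minmax(sp$train$features)        # fitted on train only
train <- sp$train; train$features <- apply_minmax(scaler, train$features)
test  <- sp$test;  test$features  <- apply_minmax(scaler, test$features)

res <- run_gsp(make_svm_fitness(train), generations = 30, seed = 7)
res
#> <optimizer_result:gsp> best c = 98.892, g = 0.97438, fitness = 1 (430 evaluations, 11 generations)

model <- train_rbf_svm(res$best_params, train)
pr <- predict_svm(model, test$features, scores = TRUE)
binary_report(test$labels, pr$labels, pr$scores, positive = 1L)
#>   precision      recall specificity      g_mean   f_measure         mcc
#>           1           1           1           1           1           1
#>    accuracy         auc
#>           1           1
```

`res$best_params` is the tuned `(c, g)` pair, `res$best_fitness` the
cross-validated training accuracy it achieved, and `res$history` the
per-generation convergence trace (exportable with
`write_history_csv()`). The report metrics are computed on the held-out
30%: on this cleanly separated toy every one of them is 1.

The full protocol — algorithms x training fractions (50–90%) x 10
repeated random splits, metric means per cell — is one call:

```r
spec <- experiment_spec(algorithms = c("svm_fixed", "gs_svm", "gsp_svm"),
                        fractions = c(0.5, 0.7), repeats = 10)
tab <- run_experiment(d, spec)   # tidy (metric, fraction, algorithm) table
```

A thin command-line wrapper with `optimize`, `evaluate`, `compare` and
`synth` subcommands ships at
`system.file("cli", "gspsvm.R", package = "gspsvm")`.

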