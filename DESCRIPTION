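Package: gspsvm
Title: Hybrid Genetic Algorithm, Particle Swarm and Simulated Annealing
    Tuning of RBF Support Vector Machines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tunes the cost (c) and radial-basis-function kernel coefficient
    (g) of a support vector machine with a fused metaheuristic that couples a
    real-coded genetic algorithm with particle swarm optimisation under a
    harmonic inertia-weight schedule and a Metropolis (simulated annealing)
    acceptance gate, with per-generation migration between the two
    populations.  Includes the single-engine baselines (grid search, GA-only,
    PSO-only), preprocessing for ordinal clinical tables with missing-value
    tokens (ID-column removal, record deletion, min-max scaling to [0,1]),
    synthetic data generators emulating ordinal binary and categorical
    multiclass diagnostic data, a diagnostic metric suite (precision, recall,
    specificity, G-mean, F-beta, Matthews correlation, AUC, micro-averaged
    multiclass scores, Hamming loss, Cohen's kappa, micro Jaccard), and a
    repeated random-split comparison harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    e1071,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    kernlab
Config/testthat/edition: 3
RoxygenNote: 7.3.3
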