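# fast experiment settings used throughout: a tuned engine on a small
# separable problem converges in a handful of generations
fast_spec <- function(...) {
  experiment_spec(generations = 8L, grid_resolution = 8L,
                  ga = ga_config(pop_size = 8L), pso = pso_config(swarm_size = 8L),
                  fitness = fitness_spec("cv_k", k = 3L), ...)
}

test_that("a fixed-parameter cell on separable data is perfect and reproducible", {
  d <- synth_binary(120, separation = 12, noise_sd = 1, seed = 41)
  spec <- fast_spec(algorithms = "svm_fixed", fractions = 0.7, repeats = 1,
                    base_seed = 5)
  cell <- run_cell("svm_fixed", d, 0.7, 1, spec)
  expect_equal(unname(cell$metrics["accuracy"]), 1)
  expect_equal(unname(cell$params), c(100, 4))
  cell2 <- run_cell("svm_fixed", d, 0.7, 1, spec)
  expect_identical(cell$metrics, cell2$metrics)
})

test_that("different repeats and fractions get independent seeds", {
  d <- synth_binary(100, separation = 4, seed = 2)
  spec <- fast_spec(fractions = c(0.5, 0.7), repeats = 2, base_seed = 9)
  c11 <- run_cell("svm_fixed", d, 0.5, 1, spec)
  c12 <- run_cell("svm_fixed", d, 0.5, 2, spec)
  c21 <- run_cell("svm_fixed", d, 0.7, 1, spec)
  expect_false(identical(c11$seed, c12$seed))
  expect_false(identical(c11$seed, c21$seed))
})

test_that("tuned cells pick parameters inside the bounds", {
  d <- synth_binary(90, separation = 6, seed = 31)
  spec <- fast_spec(fractions = 0.7, repeats = 1, base_seed = 3)
  for (alg in c("gs_svm", "ga_svm", "pso_svm", "gsp_svm")) {
    cell <- run_cell(alg, d, 0.7, 1, spec)
    expect_gte(cell$params[["bestc"]], 0.1)
    expect_lte(cell$params[["bestc"]], 100)
    expect_gte(cell$params[["bestg"]], 0.01)
    expect_lte(cell$params[["bestg"]], 1000)
    expect_gt(cell$fit_evals, 0)
  }
})

test_that("the PCA baseline projects both partitions into the same subspace", {
  d <- synth_binary(120, separation = 10, noise_sd = 1, seed = 8)
  spec <- fast_spec(fractions = 0.7, repeats = 1, base_seed = 2)
  cell <- run_cell("pca_svm", d, 0.7, 1, spec)
  expect_gte(unname(cell$metrics["accuracy"]), 0.9)
})

test_that("a minimal experiment emits one row per metric", {
  d <- synth_binary(100, separation = 8, seed = 14)
  spec <- fast_spec(algorithms = "svm_fixed", fractions = 0.6, repeats = 1,
                    base_seed = 1)
  tab <- run_experiment(d, spec)
  expect_setequal(unique(tab$metric),
                  c("precision", "recall", "specificity", "g_mean",
                    "f_measure", "mcc", "accuracy", "auc"))
  expect_true(all(tab$n == 1))
})

test_that("reported means equal the hand-average of the per-repeat log", {
  d <- synth_binary(100, separation = 4, seed = 23)
  spec <- fast_spec(algorithms = c("svm_fixed", "gs_svm"), fractions = 0.7,
                    repeats = 3, base_seed = 7)
  tab <- run_experiment(d, spec)
  log_df <- attr(tab, "per_repeat")
  for (i in seq_len(nrow(tab))) {
    sub <- log_df[log_df$metric == tab$metric[i] &
                  log_df$fraction == tab$fraction[i] &
                  log_df$algorithm == tab$algorithm[i], ]
    expect_equal(tab$mean[i], mean(sub$value, na.rm = TRUE))
    expect_equal(nrow(sub), 3)
  }
})

test_that("multiclass experiments satisfy the micro identity row-for-row", {
  d <- synth_multiclass(160, n_classes = 3, concentration = 0.85, seed = 6)
  spec <- fast_spec(algorithms = "svm_fixed", fractions = 0.7, repeats = 2,
                    base_seed = 4)
  tab <- run_experiment(d, spec)
  acc <- tab$mean[tab$metric == "accuracy"]
  for (m in c("precision_micro", "recall_micro", "f1_micro")) {
    expect_equal(tab$mean[tab$metric == m], acc)
  }
  expect_equal(tab$mean[tab$metric == "hamming_loss"], 1 - acc)
})

test_that("experiment outputs round-trip to disk with a manifest", {
  d <- synth_binary(90, separation = 8, seed = 3)
  spec <- fast_spec(algorithms = "svm_fixed", fractions = 0.5, repeats = 2,
                    base_seed = 11)
  tab <- run_experiment(d, spec)
  dir <- tempfile()
  write_experiment(tab, dir)
  expect_true(file.exists(file.path(dir, "results.csv")))
  expect_true(file.exists(file.path(dir, "per_repeat.csv")))
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(manifest$base_seed, 11)
  expect_equal(manifest$repeats, 2)
})

test_that("experiment configs read from YAML and reject unknown keys", {
  cfg <- tempfile(fileext = ".yaml")
  writeLines(c("algorithms: [svm_fixed, gsp_svm]",
               "fractions: [0.6, 0.8]",
               "repeats: 2",
               "base_seed: 13",
               "fixed_c: 50",
               "ga:",
               "  pop_size: 6"), cfg)
  spec <- read_experiment_config(cfg)
  expect_equal(spec$algorithms, c("svm_fixed", "gsp_svm"))
  expect_equal(spec$repeats, 2L)
  expect_equal(spec$fixed_c, 50)
  expect_equal(spec$ga$pop_size, 6L)
  writeLines("reppeats: 3", cfg)
  expect_error(read_experiment_config(cfg), "unknown config key")
})

test_that("the command-line wrapper is deterministic and matches the API", {
  cli <- system.file("cli", "gspsvm.R", package = "gspsvm")
  expect_true(nzchar(cli))
  dir <- tempfile(); dir.create(dir)
  data_csv <- file.path(dir, "toy.csv")
  d <- synth_binary(80, separation = 10, noise_sd = 1, seed = 12)
  write_dataset_csv(d, data_csv)
  run_cli <- function(args) {
    system2("Rscript", c(cli, args), stdout = TRUE, stderr = FALSE)
  }
  out1 <- run_cli(c("evaluate", "--data", data_csv, "--c", "100", "--g", "4",
                    "--fraction", "0.7", "--seed", "5", "--out-dir", dir))
  out2 <- run_cli(c("evaluate", "--data", data_csv, "--c", "100", "--g", "4",
                    "--fraction", "0.7", "--seed", "5", "--out-dir", dir))
  expect_identical(out1, out2)
  # CLI result equals the library-call result
  sp <- random_split(d, 0.7, seed = 5)
  sc <- fit_minmax(sp$train$features)
  tr <- sp$train; tr$features <- apply_minmax(sc, tr$features)
  te <- sp$test; te$features <- apply_minmax(sc, te$features)
  model <- train_rbf_svm(svm_params(100, 4), tr)
  pr <- predict_svm(model, te$features, scores = TRUE)
  rep_api <- binary_report(te$labels, pr$labels, pr$scores, positive = 1L)
  acc_cli <- as.numeric(sub("accuracy=", "",
                            grep("^accuracy=", out1, value = TRUE)))
  expect_equal(acc_cli, unname(rep_api["accuracy"]), tolerance = 1e-6)
  # synth smoke: file written with expected header
  out_csv <- file.path(dir, "synth.csv")
  run_cli(c("synth", "binary", "--out", out_csv, "--n", "50", "--seed", "3"))
  expect_true(file.exists(out_csv))
  expect_named(read.csv(out_csv)[0, ], c(paste0("x", 1:9), "label"))
})
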