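ALGORITHMS <- c("svm_fixed", "pca_svm", "ga_svm", "gs_svm", "pso_svm", "gsp_svm")

# independent, reproducible per-cell seed from (base seed, fraction, repeat)
.cell_seed <- function(base_seed, frac_idx, rep_idx) {
  s <- (as.double(base_seed) * 1000003 + frac_idx * 10007 + rep_idx * 101) %%
    2147483629
  as.integer(s) + 1L
}

#' Describe a comparison experiment
#'
#' The protocol: for every training fraction and repeat, draw a fresh
#' stratified random split, tune (or fix) the SVM parameters on the
#' training partition only, train on the full training partition, and score
#' the held-out test partition; report per-metric means over the repeats.
#'
#' @param algorithms Subset of `svm_fixed`, `pca_svm`, `ga_svm`, `gs_svm`,
#'   `pso_svm`, `gsp_svm`.
#' @param fractions Training fractions (default 0.5-0.9).
#' @param repeats Independent repeats per cell (default 10).
#' @param base_seed Base seed; per-cell seeds are derived from it.
#' @param bounds Search bounds for the tuned algorithms.
#' @param fitness Fitness scheme used during tuning (see [fitness_spec()]).
#' @param ga,pso,sa Engine configurations.
#' @param generations Tuning budget per engine run.
#' @param grid_resolution Lattice size per dimension for `gs_svm`.
#' @param fixed_c,fixed_g Parameters for `svm_fixed` and `pca_svm`
#'   (defaults 100 and 4).
#' @param pca_var Variance fraction retained by the PCA baseline.
#' @return An `experiment_spec` list.
#' @export
experiment_spec <- function(algorithms = ALGORITHMS,
                            fractions = c(0.5, 0.6, 0.7, 0.8, 0.9),
                            repeats = 10L, base_seed = 1L,
                            bounds = bounds_spec(),
                            fitness = fitness_spec(),
                            ga = ga_config(), pso = pso_config(),
                            sa = sa_config(), generations = 50L,
                            grid_resolution = 20L,
                            fixed_c = 100, fixed_g = 4, pca_var = 0.95) {
  algorithms <- match.arg(algorithms, ALGORITHMS, several.ok = TRUE)
  if (repeats < 1L) stop("`repeats` must be >= 1", call. = FALSE)
  if (any(fractions <= 0 | fractions >= 1)) {
    stop("`fractions` must lie in (0, 1)", call. = FALSE)
  }
  structure(list(algorithms = algorithms, fractions = fractions,
                 repeats = as.integer(repeats),
                 base_seed = as.integer(base_seed), bounds = bounds,
                 fitness = fitness, ga = ga, pso = pso, sa = sa,
                 generations = as.integer(generations),
                 grid_resolution = as.integer(grid_resolution),
                 fixed_c = fixed_c, fixed_g = fixed_g, pca_var = pca_var),
            class = "experiment_spec")
}

.pca_project <- function(train_x, test_x, var_frac) {
  pc <- stats::prcomp(train_x, center = TRUE, scale. = FALSE)
  v <- pc$sdev^2
  ncomp <- max(1L, which(cumsum(v) / sum(v) >= var_frac)[1])
  list(train = pc$x[, seq_len(ncomp), drop = FALSE],
       test = stats::predict(pc, test_x)[, seq_len(ncomp), drop = FALSE],
       ncomp = ncomp)
}

#' Run one experiment cell
#'
#' One (algorithm, fraction, repeat) combination: split, scale (scaler
#' fitted on the training partition only), tune on the training partition,
#' train the final model on it, and score the held-out test partition.
#'
#' @param algorithm One of the supported algorithm names.
#' @param data A `gspsvm_dataset`.
#' @param fraction Training fraction in (0, 1).
#' @param rep_idx Repeat index (>= 1).
#' @param spec An [experiment_spec()] carrying seeds, bounds and configs.
#' @return List with `metrics` (named vector), `params` (chosen c and g),
#'   `fit_evals`, `algorithm`, `fraction`, `rep`, `seed`.
#' @export
run_cell <- function(algorithm, data, fraction, rep_idx, spec = experiment_spec()) {
  algorithm <- match.arg(algorithm, ALGORITHMS)
  frac_idx <- match(fraction, spec$fractions)
  if (is.na(frac_idx)) frac_idx <- as.integer(round(fraction * 100))
  seed <- .cell_seed(spec$base_seed, frac_idx, rep_idx)

  sp <- random_split(data, fraction, stratified = TRUE, seed = seed)
  scaler <- fit_minmax(sp$train$features)
  tr <- sp$train; te <- sp$test
  tr$features <- apply_minmax(scaler, tr$features)
  te$features <- apply_minmax(scaler, te$features)

  if (algorithm == "pca_svm") {
    pj <- .pca_project(tr$features, te$features, spec$pca_var)
    tr$features <- pj$train
    te$features <- pj$test
    tr$feature_names <- colnames(pj$train)
    te$feature_names <- colnames(pj$test)
  }

  fit_spec <- spec$fitness
  fit_spec$seed <- seed
  evals <- 0L
  params <- switch(algorithm,
    svm_fixed = , pca_svm = svm_params(spec$fixed_c, spec$fixed_g),
    gs_svm = {
      r <- grid_search(make_svm_fitness(tr, fit_spec), spec$bounds,
                       spec$grid_resolution)
      evals <- r$evaluations
      r$best_params
    },
    ga_svm = {
      r <- run_ga(make_svm_fitness(tr, fit_spec), spec$bounds, spec$ga,
                  generations = spec$generations, seed = seed)
      evals <- r$evaluations
      r$best_params
    },
    pso_svm = {
      r <- run_pso(make_svm_fitness(tr, fit_spec), spec$bounds, spec$pso,
                   generations = spec$generations, seed = seed)
      evals <- r$evaluations
      r$best_params
    },
    gsp_svm = {
      r <- run_gsp(make_svm_fitness(tr, fit_spec), spec$bounds, spec$ga,
                   spec$pso, spec$sa, generations = spec$generations,
                   seed = seed)
      evals <- r$evaluations
      r$best_params
    })

  model <- train_rbf_svm(params, tr)
  if (data$n_classes == 2L) {
    pr <- predict_svm(model, te$features, scores = TRUE)
    metrics <- binary_report(te$labels, pr$labels, scores = pr$scores,
                             positive = 1L)
  } else {
    pred <- predict_svm(model, te$features)
    metrics <- multiclass_report(te$labels, pred)
  }
  list(metrics = metrics, params = c(bestc = params$c, bestg = params$g),
       fit_evals = evals, algorithm = algorithm, fraction = fraction,
       rep = rep_idx, seed = seed)
}

#' Run the full comparison experiment
#'
#' Iterates algorithms x fractions x repeats via [run_cell()], averages
#' each metric over the repeats, and returns a tidy result table. A failed
#' cell is recorded (with its error message) and the table is still built
#' from the completed cells.
#'
#' @param data A `gspsvm_dataset`.
#' @param spec An [experiment_spec()].
#' @param verbose Print one line per completed cell to stderr.
#' @return A data frame with columns `metric`, `fraction`, `algorithm`,
#'   `mean`, `sd`, `n`; attributes `per_repeat` (the full per-cell log),
#'   `params` (chosen c and g per cell), `failures`, and `manifest`.
#' @export
run_experiment <- function(data, spec = experiment_spec(), verbose = FALSE) {
  stopifnot(inherits(data, "gspsvm_dataset"))
  rows <- list(); prows <- list(); failures <- list()
  for (alg in spec$algorithms) {
    for (frac in spec$fractions) {
      for (r in seq_len(spec$repeats)) {
        cell <- tryCatch(run_cell(alg, data, frac, r, spec),
                         error = function(e) e)
        if (inherits(cell, "error")) {
          failures[[length(failures) + 1L]] <- data.frame(
            algorithm = alg, fraction = frac, rep = r,
            error = conditionMessage(cell))
          next
        }
        rows[[length(rows) + 1L]] <- data.frame(
          algorithm = alg, fraction = frac, rep = r, seed = cell$seed,
          metric = names(cell$metrics), value = unname(cell$metrics))
        prows[[length(prows) + 1L]] <- data.frame(
          algorithm = alg, fraction = frac, rep = r,
          bestc = cell$params[["bestc"]], bestg = cell$params[["bestg"]])
        if (verbose) {
          message(sprintf("cell %s f=%.2f rep=%d done", alg, frac, r))
        }
      }
    }
  }
  log_df <- do.call(rbind, rows)
  if (is.null(log_df)) stop("every cell failed", call. = FALSE)
  agg_mean <- stats::aggregate(value ~ metric + fraction + algorithm, log_df,
                               mean, na.rm = TRUE)
  agg_sd <- stats::aggregate(value ~ metric + fraction + algorithm, log_df,
                             stats::sd, na.rm = TRUE)
  agg_n <- stats::aggregate(value ~ metric + fraction + algorithm, log_df,
                            length)
  out <- agg_mean
  names(out)[names(out) == "value"] <- "mean"
  out$sd <- agg_sd$value
  out$n <- agg_n$value
  attr(out, "per_repeat") <- log_df
  attr(out, "params") <- do.call(rbind, prows)
  attr(out, "failures") <- if (length(failures)) do.call(rbind, failures) else NULL
  attr(out, "manifest") <- list(
    base_seed = spec$base_seed, algorithms = spec$algorithms,
    fractions = spec$fractions, repeats = spec$repeats,
    bounds = spec$bounds[c("c_min", "c_max", "g_min", "g_max")],
    fitness_scheme = spec$fitness$scheme, generations = spec$generations,
    fixed_c = spec$fixed_c, fixed_g = spec$fixed_g)
  out
}

#' Write experiment outputs
#'
#' Emits the tidy result table, the per-repeat log and a JSON run manifest.
#' @param result Table from [run_experiment()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(result, file.path(dir, "results.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(attr(result, "per_repeat"),
                   file.path(dir, "per_repeat.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(attr(result, "manifest"),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read an experiment configuration file
#'
#' YAML mirror of [experiment_spec()]; unknown keys are rejected so typos
#' surface instead of silently using a default.
#' @param path YAML file.
#' @return An `experiment_spec`.
#' @export
read_experiment_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("algorithms", "fractions", "repeats", "base_seed", "generations",
             "grid_resolution", "fixed_c", "fixed_g", "pca_var",
             "bounds", "fitness", "ga", "pso", "sa")
  bad <- setdiff(names(cfg), known)
  if (length(bad)) {
    stop(sprintf("unknown config key: %s", bad[1]), call. = FALSE)
  }
  args <- cfg[intersect(names(cfg), c("algorithms", "fractions", "repeats",
                                      "base_seed", "generations",
                                      "grid_resolution", "fixed_c", "fixed_g",
                                      "pca_var"))]
  if (!is.null(cfg$bounds)) args$bounds <- do.call(bounds_spec, cfg$bounds)
  if (!is.null(cfg$fitness)) args$fitness <- do.call(fitness_spec, cfg$fitness)
  if (!is.null(cfg$ga)) args$ga <- do.call(ga_config, cfg$ga)
  if (!is.null(cfg$pso)) args$pso <- do.call(pso_config, cfg$pso)
  if (!is.null(cfg$sa)) args$sa <- do.call(sa_config, cfg$sa)
  do.call(experiment_spec, args)
}
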