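#' Train an RBF-kernel support vector machine
#'
#' Thin wrapper around the libsvm C-SVC solver (via \pkg{e1071}) in the
#' parameterisation used throughout this package: `cost = c` and the kernel
#' `K(x, x') = exp(-g * ||x - x'||^2)`, i.e. `g` is the multiplicative
#' coefficient (`g = 1 / sigma^2` relative to the bandwidth form).
#' Multiclass problems use the solver's one-vs-one decomposition.
#'
#' @param params List or numeric vector with elements `c` and `g`, both
#'   positive (see [svm_params()]).
#' @param train A `gspsvm_dataset` with at least two classes present.
#' @return A fitted model usable with [predict_svm()].
#' @export
train_rbf_svm <- function(params, train) {
  stopifnot(inherits(train, "gspsvm_dataset"))
  if (length(unique(train$labels)) < 2L) {
    stop("training data contains a single class", call. = FALSE)
  }
  if (params[["c"]] <= 0 || params[["g"]] <= 0) {
    stop("`c` and `g` must be positive", call. = FALSE)
  }
  e1071::svm(x = train$features,
             y = factor(train$labels, levels = sort(unique(train$labels))),
             type = "C-classification", kernel = "radial",
             cost = params[["c"]], gamma = params[["g"]], scale = FALSE)
}

#' Predict class labels (and optionally decision scores)
#'
#' @param model Fitted model from [train_rbf_svm()].
#' @param features Numeric feature matrix.
#' @param scores Also return decision values (binary models only; the score
#'   is oriented so larger means more likely the higher class code).
#' @return Integer labels, or a list with `labels` and `scores`.
#' @export
predict_svm <- function(model, features, scores = FALSE) {
  pr <- stats::predict(model, as.matrix(features), decision.values = scores)
  labels <- as.integer(as.character(pr))
  if (!scores) return(labels)
  dv <- attr(pr, "decision.values")
  s <- dv[, 1]
  # libsvm orients the decision value toward the first factor level; flip so
  # larger score always favours the larger class code
  lev <- colnames(dv)[1]
  first <- as.integer(strsplit(lev, "/")[[1]][1])
  if (!is.na(first) && first == min(labels, na.rm = TRUE)) s <- -s
  list(labels = labels, scores = unname(s))
}

#' Bundle SVM hyperparameters
#' @param c Penalty (cost) parameter, positive.
#' @param g RBF kernel coefficient, positive.
#' @return Named list of class `svm_params`.
#' @export
svm_params <- function(c, g) {
  if (c <= 0 || g <= 0) stop("`c` and `g` must be positive", call. = FALSE)
  structure(list(c = c, g = g), class = "svm_params")
}

#' Describe how classifier fitness is measured
#'
#' The optimizers maximise a scalar fitness of `(c, g)`. `"cv_k"` (the
#' default, k = 5) is mean accuracy over k stratified folds of the training
#' partition built from a seeded permutation; `"train_accuracy"` is
#' resubstitution accuracy; `"holdout"` carves an inner validation fraction
#' out of the training partition.
#'
#' @param scheme One of `"cv_k"`, `"train_accuracy"`, `"holdout"`.
#' @param k Folds for `"cv_k"` (>= 2).
#' @param holdout_fraction Inner validation fraction for `"holdout"`.
#' @param seed Integer seed fixing folds / the inner split.
#' @return A `fitness_spec` list.
#' @export
fitness_spec <- function(scheme = c("cv_k", "train_accuracy", "holdout"),
                         k = 5L, holdout_fraction = 0.25, seed = 1L) {
  scheme <- match.arg(scheme)
  if (scheme == "cv_k" && k < 2L) stop("`k` must be >= 2", call. = FALSE)
  structure(list(scheme = scheme, k = as.integer(k),
                 holdout_fraction = holdout_fraction, seed = as.integer(seed)),
            class = "fitness_spec")
}

# stratified fold ids from a seeded permutation; invariant to input order
.make_folds <- function(labels, k, seed) {
  n <- length(labels)
  folds <- integer(n)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  for (cls in sort(unique(labels))) {
    idx <- which(labels == cls)
    if (length(idx) < k) {
      stop(sprintf("class %s has %d samples, fewer than k = %d folds",
                   cls, length(idx), k), call. = FALSE)
    }
    # order within class by feature-independent permutation
    folds[sample(idx)] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Classifier fitness at a candidate parameter pair
#'
#' The objective every optimizer engine maximises: training-partition
#' classification accuracy of the RBF SVM at `(c, g)`, measured per the
#' [fitness_spec()]. Deterministic at a fixed spec seed, and invariant to
#' the order of the training rows.
#'
#' @param params `svm_params` (or list with `c`, `g`).
#' @param train A `gspsvm_dataset` (the training partition only).
#' @param spec A [fitness_spec()].
#' @return Accuracy in [0, 1].
#' @export
svm_fitness <- function(params, train, spec = fitness_spec()) {
  stopifnot(inherits(train, "gspsvm_dataset"))
  # canonical row order so fitness is invariant to input permutation
  ord <- do.call(order, c(as.data.frame(train$features), list(train$labels)))
  train <- dataset_subset(train, ord)
  switch(spec$scheme,
    train_accuracy = {
      model <- train_rbf_svm(params, train)
      mean(predict_svm(model, train$features) == train$labels)
    },
    cv_k = {
      folds <- .make_folds(train$labels, spec$k, spec$seed)
      accs <- vapply(seq_len(spec$k), function(f) {
        tr <- dataset_subset(train, which(folds != f))
        te <- dataset_subset(train, which(folds == f))
        model <- train_rbf_svm(params, tr)
        mean(predict_svm(model, te$features) == te$labels)
      }, 0)
      mean(accs)
    },
    holdout = {
      sp <- random_split(train, 1 - spec$holdout_fraction,
                         stratified = TRUE, seed = spec$seed)
      model <- train_rbf_svm(params, sp$train)
      mean(predict_svm(model, sp$test$features) == sp$test$labels)
    })
}

#' Build a fitness closure over (c, g) for the optimizers
#'
#' @inheritParams svm_fitness
#' @return A function `f(c, g)` returning accuracy in [0, 1].
#' @export
make_svm_fitness <- function(train, spec = fitness_spec()) {
  force(train); force(spec)
  function(c, g) svm_fitness(list(c = c, g = g), train, spec)
}
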