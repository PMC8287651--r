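#' Generate a synthetic ordinal binary diagnostic dataset
#'
#' Emulates the structure of ordinal clinical tables: integer attributes on a
#' bounded scale (default 1-10), two classes whose feature means are
#' separated by a controllable distance, optional missing-value injection for
#' exercising the preprocessing path. Features are Gaussian around each class
#' mean, then rounded and clipped to `value_range`.
#'
#' @param n_samples Number of records.
#' @param n_features Number of ordinal attributes (default 9).
#' @param class_balance Probability of class 1, in (0,1) (default 0.35,
#'   roughly the malignant share of the emulated clinical table).
#' @param separation Distance between class mean vectors, in feature units
#'   (applied along every feature axis divided by sqrt(n_features)).
#' @param noise_sd Within-class standard deviation per feature.
#' @param missing_rate Fraction of records to flag with a missing token when
#'   written to file (in [0,1)); the returned dataset never contains them.
#' @param value_range Integer bounds of the attribute scale.
#' @param seed Integer seed; identical spec + seed gives identical output.
#' @param file Optional path: also emit a raw comma-delimited file in the
#'   clinical dialect (ID column, attributes, 2/4 class coding) with
#'   `missing_rate` of rows carrying "?" in one attribute field.
#' @return A `gspsvm_dataset` of the complete (non-missing) records. When
#'   `file` is given, the emitted file contains all records including the
#'   missing-flagged ones, and the attribute `n_missing_rows` reports how
#'   many rows carry the token.
#' @export
synth_binary <- function(n_samples, n_features = 9L, class_balance = 0.35,
                         separation = 4, noise_sd = 1.5, missing_rate = 0,
                         value_range = c(1L, 10L), seed = 1L, file = NULL) {
  if (separation < 0) stop("`separation` must be nonnegative", call. = FALSE)
  if (!(class_balance > 0 && class_balance < 1)) {
    stop("`class_balance` must be in (0, 1)", call. = FALSE)
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("`missing_rate` must be in [0, 1)", call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  mid <- mean(value_range)
  # class mean vectors straddling the scale midpoint at the stated distance
  offset <- separation / (2 * sqrt(n_features))
  mu0 <- rep(mid - offset, n_features)
  mu1 <- rep(mid + offset, n_features)
  labels <- stats::rbinom(n_samples, 1L, class_balance)
  mu <- ifelse(matrix(labels, n_samples, n_features) == 1L,
               matrix(mu1, n_samples, n_features, byrow = TRUE),
               matrix(mu0, n_samples, n_features, byrow = TRUE))
  feats <- mu + matrix(stats::rnorm(n_samples * n_features, sd = noise_sd),
                       n_samples, n_features)
  feats <- round(feats)
  feats[feats < value_range[1]] <- value_range[1]
  feats[feats > value_range[2]] <- value_range[2]
  # guarantee both classes present (tiny-n edge)
  if (length(unique(labels)) < 2L) {
    labels[1] <- 1L - labels[1]
  }
  n_missing_rows <- 0L
  if (!is.null(file)) {
    miss <- stats::runif(n_samples) < missing_rate
    n_missing_rows <- sum(miss)
    field <- matrix(as.character(feats), n_samples, n_features)
    # missing token lands in one attribute column, as in the source dialect
    # where one lab value is the usual culprit
    miss_col <- min(6L, n_features)
    field[miss, miss_col] <- "?"
    ids <- sprintf("%07d", 1000000L + seq_len(n_samples))
    cls <- ifelse(labels == 1L, "4", "2")
    writeLines(apply(cbind(ids, field, cls), 1L, paste, collapse = ","), file)
    keep <- !miss
  } else {
    keep <- rep(TRUE, n_samples)
  }
  out <- dataset(feats[keep, , drop = FALSE], labels[keep],
                 feature_names = paste0("x", seq_len(n_features)),
                 class_names = c("2", "4"))
  attr(out, "n_missing_rows") <- n_missing_rows
  out
}

#' Generate a synthetic categorical multiclass dataset
#'
#' Emulates enumerated-attribute clinical tables with a multiclass outcome:
#' class labels are drawn from stated priors and each feature from a
#' class-conditional categorical distribution over its levels. Encoding is
#' ordinal (level index) by default or one-hot.
#'
#' @param n_samples Number of records.
#' @param n_classes Number of outcome classes (>= 3 for a genuinely
#'   multiclass task; 2 is allowed).
#' @param n_features Number of enumerated attributes (default 10).
#' @param levels_per_feature Integer vector of level counts (recycled).
#' @param class_priors Class prior probabilities (default uniform).
#' @param prob_tables Optional list (one per feature) of `n_classes` x
#'   `levels` probability matrices, rows summing to 1. By default each class
#'   concentrates mass (weight `concentration`) on a class-specific level.
#' @param concentration Probability mass on each class's preferred level in
#'   the default tables (the rest spread uniformly); 1 makes classes
#'   perfectly separable, `1/levels` removes all signal.
#' @param encoding `"ordinal"` (level index as a number) or `"onehot"`.
#' @param seed Integer seed.
#' @return A `gspsvm_dataset`.
#' @export
synth_multiclass <- function(n_samples, n_classes = 4L, n_features = 10L,
                             levels_per_feature = 3L, class_priors = NULL,
                             prob_tables = NULL, concentration = 0.7,
                             encoding = c("ordinal", "onehot"), seed = 1L) {
  encoding <- match.arg(encoding)
  if (n_classes < 2L) stop("`n_classes` must be at least 2", call. = FALSE)
  if (is.null(class_priors)) class_priors <- rep(1 / n_classes, n_classes)
  if (length(class_priors) != n_classes ||
      abs(sum(class_priors) - 1) > 1e-8) {
    stop("`class_priors` must have length n_classes and sum to 1", call. = FALSE)
  }
  levels_per_feature <- rep_len(as.integer(levels_per_feature), n_features)
  if (is.null(prob_tables)) {
    prob_tables <- lapply(seq_len(n_features), function(j) {
      L <- levels_per_feature[j]
      tab <- matrix((1 - concentration) / max(L - 1L, 1L), n_classes, L)
      for (k in seq_len(n_classes)) {
        pref <- ((k - 1L) %% L) + 1L
        tab[k, pref] <- if (L == 1L) 1 else concentration
      }
      tab / rowSums(tab)
    })
  }
  for (j in seq_len(n_features)) {
    tab <- prob_tables[[j]]
    if (nrow(tab) != n_classes || ncol(tab) != levels_per_feature[j]) {
      stop(sprintf("probability table %d has wrong dimensions", j), call. = FALSE)
    }
    if (any(abs(rowSums(tab) - 1) > 1e-6)) {
      stop(sprintf("probability table %d has a row not summing to 1", j),
           call. = FALSE)
    }
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  labels <- sample.int(n_classes, n_samples, replace = TRUE,
                       prob = class_priors) - 1L
  # ensure every class appears at least once
  missing_cls <- setdiff(seq_len(n_classes) - 1L, unique(labels))
  if (length(missing_cls) > 0L) {
    labels[seq_along(missing_cls)] <- missing_cls
  }
  feats <- matrix(0L, n_samples, n_features)
  for (j in seq_len(n_features)) {
    tab <- prob_tables[[j]]
    for (k in seq_len(n_classes)) {
      rows <- which(labels == k - 1L)
      if (length(rows) > 0L) {
        feats[rows, j] <- sample.int(ncol(tab), length(rows),
                                     replace = TRUE, prob = tab[k, ])
      }
    }
  }
  if (encoding == "onehot") {
    blocks <- lapply(seq_len(n_features), function(j) {
      L <- levels_per_feature[j]
      m <- matrix(0, n_samples, L)
      m[cbind(seq_len(n_samples), feats[, j])] <- 1
      colnames(m) <- paste0("x", j, "_l", seq_len(L))
      m
    })
    mat <- do.call(cbind, blocks)
  } else {
    mat <- feats
    colnames(mat) <- paste0("x", seq_len(n_features))
  }
  dataset(mat, labels, class_names = paste0("class", seq_len(n_classes) - 1L))
}

#' Build a deterministic injected fitness surface
#'
#' Returns a unimodal function over `(c, g)` with its global maximum exactly
#' at `(c_star, g_star)`, used as an oracle landscape for optimizer tests:
#' the true optimum is known by construction, so any search engine can be
#' scored against an exhaustive grid scan. Distance in `g` is measured on
#' the log10 scale, matching how the kernel coefficient spans decades.
#'
#' @param c_star,g_star Peak location (must lie inside the search bounds
#'   when used with an optimizer).
#' @param curvature Positive scalar (or length-2 vector for the c and log-g
#'   axes) controlling how fast fitness falls off the peak.
#' @return A function `f(c, g)` returning values in (0, 1] with
#'   `f(c_star, g_star) == 1`.
#' @export
injected_fitness <- function(c_star, g_star, curvature = 1) {
  if (c_star <= 0 || g_star <= 0) stop("peak must be positive", call. = FALSE)
  if (any(curvature <= 0)) stop("`curvature` must be positive", call. = FALSE)
  curv <- rep_len(curvature, 2L)
  force(c_star); force(g_star)
  function(c, g) {
    dc <- (c - c_star) / 10
    dg <- log10(g) - log10(g_star)
    exp(-(curv[1] * dc^2 + curv[2] * dg^2))
  }
}
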