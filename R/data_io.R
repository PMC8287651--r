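#' Read a raw comma-delimited clinical table
#'
#' Reads files in the Wisconsin breast-cancer dialect: comma-separated, no
#' header, an ID column, ordinal attribute columns and a class column, with
#' missing values encoded by a token (usually `"?"`). Fields are returned as
#' text, verbatim; no coercion happens here. Blank lines are skipped.
#'
#' @param path File path.
#' @param missing_token Token that marks a missing field (kept verbatim).
#' @return A character matrix, one row per non-blank line.
#' @export
load_wbc_dialect <- function(path, missing_token = "?") {
  if (!file.exists(path)) stop(sprintf("cannot read '%s'", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop("file contains no data rows", call. = FALSE)
  fields <- strsplit(lines, ",", fixed = TRUE)
  widths <- lengths(fields)
  if (widths[1] < 3L) stop("expected at least 3 comma-separated columns",
                           call. = FALSE)
  bad <- which(widths != widths[1])
  if (length(bad) > 0L) {
    stop(sprintf("ragged row at line %d: %d fields, expected %d",
                 line_no[bad[1]], widths[bad[1]], widths[1]), call. = FALSE)
  }
  mat <- do.call(rbind, fields)
  mat
}

#' Preprocess a raw clinical table into a dataset
#'
#' Applies the standard cleaning sequence for ordinal clinical tables:
#' drop the sample-ID column, delete every record containing the missing
#' token, parse the remaining attribute fields as numbers, and encode class
#' labels to 0-based codes (in sorted order of the distinct source labels,
#' so e.g. the 2/4 benign/malignant coding maps to 0/1).
#'
#' @param raw Character matrix from [load_wbc_dialect()].
#' @param id_column Index of the sample-ID column to drop (NULL for none).
#' @param label_column Index of the class column (in the original table).
#' @param missing_token Token marking a missing field.
#' @return A `gspsvm_dataset` with attributes `n_removed` (records deleted
#'   for missingness) and `label_mapping` (named integer vector, source
#'   label -> code).
#' @export
preprocess_wbc <- function(raw, id_column = 1L, label_column = ncol(raw),
                           missing_token = "?") {
  if (!is.matrix(raw) || nrow(raw) == 0L) stop("empty raw table", call. = FALSE)
  has_missing <- apply(raw, 1L, function(r) any(r == missing_token))
  n_removed <- sum(has_missing)
  raw <- raw[!has_missing, , drop = FALSE]
  if (nrow(raw) == 0L) stop("all records removed for missingness", call. = FALSE)
  lab_raw <- raw[, label_column]
  drop_cols <- c(id_column, label_column)
  feat_raw <- raw[, -drop_cols, drop = FALSE]
  feats <- suppressWarnings(matrix(as.numeric(feat_raw), nrow = nrow(feat_raw)))
  if (anyNA(feats)) {
    bad <- which(apply(is.na(feats), 1L, any))[1]
    stop(sprintf("non-numeric attribute in record %d after missing-value removal",
                 bad), call. = FALSE)
  }
  lev <- sort(unique(lab_raw))
  if (length(lev) < 2L) stop("only one class present after filtering",
                             call. = FALSE)
  labels <- match(lab_raw, lev) - 1L
  mapping <- stats::setNames(seq_along(lev) - 1L, lev)
  out <- dataset(feats, labels,
                 feature_names = paste0("x", seq_len(ncol(feats))),
                 class_names = as.character(lev))
  attr(out, "n_removed") <- n_removed
  attr(out, "label_mapping") <- mapping
  out
}

#' Fit a min-max scaler on training features
#'
#' Per-feature minimum and maximum are learned from the training partition
#' only; see [apply_minmax()] for the transform. Constant features map to 0.
#'
#' @param features Numeric training feature matrix.
#' @return A `minmax_scaler` with per-feature `min` and `max`.
#' @export
fit_minmax <- function(features) {
  features <- as.matrix(features)
  if (nrow(features) == 0L || ncol(features) == 0L) {
    stop("cannot fit scaler on an empty matrix", call. = FALSE)
  }
  structure(
    list(min = apply(features, 2L, min), max = apply(features, 2L, max)),
    class = "minmax_scaler"
  )
}

#' Apply a fitted min-max scaler
#'
#' Maps each feature through `(x - min) / (max - min)`. Values outside the
#' training range (possible on a test partition) are clipped to `[0, 1]`;
#' features constant in training map to 0.
#'
#' @param scaler A `minmax_scaler` from [fit_minmax()].
#' @param features Feature matrix with the same columns as at fit time.
#' @return Scaled matrix, all values in `[0, 1]`.
#' @export
apply_minmax <- function(scaler, features) {
  stopifnot(inherits(scaler, "minmax_scaler"))
  features <- as.matrix(features)
  if (ncol(features) != length(scaler$min)) {
    stop("feature count differs from the fitted scaler", call. = FALSE)
  }
  span <- scaler$max - scaler$min
  out <- sweep(features, 2L, scaler$min, "-")
  safe <- ifelse(span > 0, span, 1)
  out <- sweep(out, 2L, safe, "/")
  out[, span == 0] <- 0
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

#' Split a dataset into train and test partitions
#'
#' Random, seed-reproducible split; stratified by class by default so that
#' class proportions are preserved to within one sample per class.
#'
#' @param data A `gspsvm_dataset`.
#' @param train_fraction Fraction of samples assigned to training, in (0,1).
#' @param stratified Preserve per-class proportions (default TRUE).
#' @param seed Integer seed; the same seed always yields the same split.
#' @return List with `train` and `test` (`gspsvm_dataset`s) and the
#'   `train_idx` row indices.
#' @export
random_split <- function(data, train_fraction, stratified = TRUE, seed = 1L) {
  stopifnot(inherits(data, "gspsvm_dataset"))
  if (!(train_fraction > 0 && train_fraction < 1)) {
    stop("`train_fraction` must be in (0, 1)", call. = FALSE)
  }
  n <- n_samples(data)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  if (stratified) {
    train_idx <- integer(0)
    # largest-remainder allocation so the overall train size is round(n * f)
    target_total <- round(n * train_fraction)
    cls_idx <- split(seq_len(n), data$labels)
    raw_sizes <- vapply(cls_idx, function(ix) length(ix) * train_fraction, 0)
    sizes <- floor(raw_sizes)
    rem <- target_total - sum(sizes)
    if (rem > 0) {
      order_frac <- order(raw_sizes - sizes, decreasing = TRUE)
      # prefer classes whose test side survives the bump
      lens <- lengths(cls_idx)
      for (k in order_frac) {
        if (rem == 0) break
        if (sizes[k] + 1 < lens[k]) {
          sizes[k] <- sizes[k] + 1
          rem <- rem - 1
        }
      }
      for (k in order_frac) {
        if (rem == 0) break
        sizes[k] <- sizes[k] + 1
        rem <- rem - 1
      }
    }
    for (k in seq_along(cls_idx)) {
      ix <- cls_idx[[k]]
      sz <- sizes[k]
      if (sz == 0L || sz == length(ix)) {
        if (sz == 0L && length(ix) > 0L) {
          stop("stratified split leaves a class empty in training", call. = FALSE)
        }
        if (sz == length(ix)) {
          stop("stratified split leaves a class empty in test", call. = FALSE)
        }
      }
      train_idx <- c(train_idx, sample(ix, sz))
    }
    train_idx <- sort(train_idx)
  } else {
    sz <- round(n * train_fraction)
    if (sz == 0L || sz == n) stop("split produces an empty partition", call. = FALSE)
    train_idx <- sort(sample.int(n, sz))
  }
  list(train = dataset_subset(data, train_idx),
       test = dataset_subset(data, setdiff(seq_len(n), train_idx)),
       train_idx = train_idx)
}

# save/restore the global RNG state so seeded helpers do not perturb the
# caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
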