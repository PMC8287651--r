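#' Construct a labelled dataset
#'
#' The common currency between preprocessing, generators, fitness evaluation
#' and the experiment harness: a numeric feature matrix plus 0-based integer
#' class codes.
#'
#' @param features Numeric matrix, samples in rows.
#' @param labels Integer vector of class codes in `0:(n_classes-1)`, one per
#'   row of `features`.
#' @param feature_names Optional character vector, one per column.
#' @param class_names Optional character vector naming each class code.
#' @return An object of class `gspsvm_dataset` with elements `features`,
#'   `labels`, `feature_names`, `class_names`, `n_classes`.
#' @examples
#' d <- dataset(matrix(rnorm(20), 10, 2), rep(0:1, 5))
#' d$n_classes
#' @export
dataset <- function(features, labels, feature_names = NULL, class_names = NULL) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  labels <- as.integer(labels)
  if (nrow(features) != length(labels)) {
    stop("`features` rows and `labels` length differ", call. = FALSE)
  }
  if (nrow(features) < 2L) stop("need at least 2 samples", call. = FALSE)
  if (ncol(features) < 1L) stop("need at least 1 feature", call. = FALSE)
  if (anyNA(features)) stop("`features` contains missing values", call. = FALSE)
  if (anyNA(labels)) stop("`labels` contains missing values", call. = FALSE)
  n_classes <- length(unique(labels))
  if (!setequal(unique(labels), seq_len(n_classes) - 1L)) {
    stop("labels must be consecutive 0-based codes with every class present",
         call. = FALSE)
  }
  if (is.null(feature_names)) {
    feature_names <- colnames(features)
    if (is.null(feature_names)) {
      feature_names <- paste0("x", seq_len(ncol(features)))
    }
  }
  if (is.null(class_names)) class_names <- as.character(seq_len(n_classes) - 1L)
  colnames(features) <- feature_names
  structure(
    list(features = features, labels = labels,
         feature_names = feature_names, class_names = class_names,
         n_classes = n_classes),
    class = "gspsvm_dataset"
  )
}

#' @export
print.gspsvm_dataset <- function(x, ...) {
  cat(sprintf("<gspsvm_dataset> %d samples x %d features, %d classes\n",
              nrow(x$features), ncol(x$features), x$n_classes))
  tab <- table(factor(x$labels, levels = seq_len(x$n_classes) - 1L,
                      labels = x$class_names))
  print(tab)
  invisible(x)
}

#' Number of samples in a dataset
#' @param x A `gspsvm_dataset`.
#' @return Integer sample count.
#' @export
n_samples <- function(x) {
  stopifnot(inherits(x, "gspsvm_dataset"))
  nrow(x$features)
}

# subset by row index, preserving class coding (classes may drop out in a
# subset; callers that require all classes must check)
dataset_subset <- function(x, idx) {
  structure(
    list(features = x$features[idx, , drop = FALSE],
         labels = x$labels[idx],
         feature_names = x$feature_names, class_names = x$class_names,
         n_classes = x$n_classes),
    class = "gspsvm_dataset"
  )
}

#' Write a dataset to CSV
#'
#' Features and a final `label` column (0-based codes), round-trippable with
#' [read_labeled_csv()].
#' @param x A `gspsvm_dataset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dataset_csv <- function(x, path) {
  stopifnot(inherits(x, "gspsvm_dataset"))
  df <- as.data.frame(x$features)
  df$label <- x$labels
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a generic labelled CSV
#'
#' Expects a header, numeric feature columns and a label column (default the
#' last). Labels are re-encoded to 0-based codes in sorted order of the
#' distinct source values.
#' @param path CSV file path.
#' @param label_column Column name or index holding the class label.
#' @return A `gspsvm_dataset`.
#' @export
read_labeled_csv <- function(path, label_column = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(label_column)) label_column <- ncol(df)
  if (is.character(label_column)) {
    label_column <- match(label_column, names(df))
    if (is.na(label_column)) stop("label column not found", call. = FALSE)
  }
  lab_raw <- df[[label_column]]
  feats <- as.matrix(df[, -label_column, drop = FALSE])
  storage.mode(feats) <- "double"
  lev <- sort(unique(lab_raw))
  labels <- match(lab_raw, lev) - 1L
  dataset(feats, labels, feature_names = colnames(feats),
          class_names = as.character(lev))
}
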