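# shared toy fixtures, all built in code

# 4-point linearly separable 2-D toy
toy_separable <- function() {
  dataset(matrix(c(0, 0, 0.1, 0.2, 1, 0.9, 1.1, 1, 0, 0.1, 0, 0.2, 1, 1.1,
                   0.9, 1), ncol = 2),
          labels = c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L))
}

# write a tiny WBC-dialect file; returns path
write_toy_wbc <- function(rows, path = tempfile(fileext = ".data")) {
  writeLines(rows, path)
  path
}

# random binary confusion counts with all cells positive
random_counts <- function() {
  confusion_counts(TP = sample(1:50, 1), FP = sample(1:50, 1),
                   FN = sample(1:50, 1), TN = sample(1:50, 1))
}

expect_undefined_metric <- function(expr) {
  testthat::expect_error(expr, class = "gspsvm_undefined_metric")
}
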