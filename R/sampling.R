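# SPXY train/test partitioning: Kennard-Stone greedy max-min selection on a
# joint, normalized descriptor + response distance.

#' Joint descriptor-response distance matrix
#'
#' Computes the SPXY distance
#' `d_xy(p, q) = d_x(p, q) / max d_x + d_y(p, q) / max d_y`,
#' where `d_x` is the Euclidean distance between descriptor rows and `d_y`
#' the absolute difference of responses, each normalized by its maximum over
#' all sample pairs. If one block is degenerate (all rows identical, or all
#' responses equal) its term is defined as 0; if both are degenerate the data
#' carry no distance information and an error is raised.
#'
#' @param X Numeric matrix of (normalized) descriptors, one row per sample.
#' @param y Numeric (normalized) response vector, one value per row of `X`.
#' @return Symmetric matrix with zero diagonal and values in `[0, 2]`.
#' @export
joint_distance_matrix <- function(X, y) {
  X <- as.matrix(X)
  if (nrow(X) < 2) {
    abort("joint_distance_matrix needs at least 2 samples",
          "grnncorr_argument_error")
  }
  if (length(y) != nrow(X)) {
    abort("length(y) must equal nrow(X)", "grnncorr_argument_error")
  }
  dx <- as.matrix(stats::dist(X))
  dy <- abs(outer(y, y, "-"))
  mx <- max(dx)
  my <- max(dy)
  if (mx == 0 && my == 0) {
    abort("all samples identical in both X and y: no distances to partition on",
          "grnncorr_degenerate_error")
  }
  d <- matrix(0, nrow(X), nrow(X))
  if (mx > 0) d <- d + dx / mx
  if (my > 0) d <- d + dy / my
  dimnames(d) <- NULL
  d
}

#' SPXY sample set partitioning
#'
#' Splits a dataset into training and test sets by greedy max-min selection
#' on the joint descriptor-response distance (see
#' [joint_distance_matrix()]): the pair of samples at maximal joint distance
#' seeds the training set, then the sample whose minimum distance to the
#' selected set is largest is added until `n_train` samples are selected.
#' The remaining samples form the test set. With a constant response the
#' procedure reduces to classic Kennard-Stone selection on the descriptors
#' alone. Descriptors and response are normalized to \[-1, 1\] internally
#' over the full dataset before distances are computed. Ties are broken by
#' the lowest row index, so the split is deterministic.
#'
#' @param data An [nci_dataset] with reference values on every record.
#' @param n_train Number of training samples, `2 <= n_train <= n`.
#' @return List of class `spxy_split` with `train_ids`, `test_ids` (both in
#'   dataset row order) and `selection_order` (the order in which training
#'   samples were picked).
#' @export
spxy_split <- function(data, n_train) {
  require_references(data, "spxy_split")
  n <- n_records(data)
  if (!is_scalar_number(n_train) || n_train != round(n_train) ||
      n_train < 2 || n_train > n) {
    abort(sprintf("n_train must be an integer in [2, %d]", n),
          "grnncorr_argument_error")
  }
  n_train <- as.integer(n_train)
  map <- fit_normalization(data, include_target = TRUE)
  X <- norm_apply_matrix(map, descriptor_matrix(data))
  y <- norm_target(map, reference_nci(data))
  d <- joint_distance_matrix(X, y)
  ids <- data$records$id

  # Seed: the (i, j) pair at maximal joint distance, ties to lowest indices.
  best <- which(d == max(d), arr.ind = TRUE)
  best <- best[best[, 1] < best[, 2], , drop = FALSE]
  best <- best[order(best[, 1], best[, 2]), , drop = FALSE]
  selected <- as.integer(best[1, ])

  while (length(selected) < n_train) {
    remaining <- setdiff(seq_len(n), selected)
    min_d <- vapply(remaining,
                    function(i) min(d[i, selected]), numeric(1))
    selected <- c(selected, remaining[which.max(min_d)])
  }

  structure(
    list(
      train_ids = ids[sort(selected)],
      test_ids = ids[setdiff(seq_len(n), selected)],
      selection_order = ids[selected]
    ),
    class = "spxy_split"
  )
}

#' @export
print.spxy_split <- function(x, ...) {
  cat(sprintf("<spxy_split> %d train / %d test\n",
              length(x$train_ids), length(x$test_ids)))
  cat("  first picks:",
      paste(utils::head(x$selection_order, 5), collapse = ", "), "...\n")
  invisible(x)
}

#' Training-set size from a train fraction
#'
#' Rounds `fraction * n` to the nearest integer; the default fraction
#' 91/121 reproduces the 91/30 division of the 121-complex benchmark
#' database.
#'
#' @param n Total sample count.
#' @param fraction Train fraction in (0, 1\].
#' @return Integer training-set size.
#' @export
train_size <- function(n, fraction = 91 / 121) {
  if (!is_scalar_number(fraction) || fraction <= 0 || fraction > 1) {
    abort("fraction must be in (0, 1]", "grnncorr_argument_error")
  }
  as.integer(round(fraction * n))
}
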