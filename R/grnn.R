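# General regression neural network: Gaussian-kernel (Nadaraya-Watson)
# regression with a single smoothing factor sigma. The "network" is lazy:
# one pattern neuron per training sample, no iterative optimization; fitting
# stores the normalized patterns and targets verbatim and training amounts to
# choosing sigma by cross-validation.

#' Fit a GRNN correction model
#'
#' Stores the \[-1, 1\]-normalized training patterns and targets; the number
#' of pattern neurons equals the number of training samples. The response is
#' the reference interaction energy (kcal/mol), normalized through `map`;
#' predictions are denormalized back to kcal/mol on request.
#'
#' @param train An [nci_dataset] with references on every record.
#' @param subset Character vector of descriptor names to use as network
#'   inputs; must contain `"dft_nci"`.
#' @param sigma Smoothing factor, > 0. Controls the Gaussian kernel width
#'   and hence the bias-variance trade-off.
#' @param map Optional `nci_normmap` fitted with the target; defaults to a
#'   map fitted on `train` restricted to `subset`.
#' @param training_meta Optional list of provenance (sigma grid, K, seed,
#'   subset search details) stored with the model.
#' @return Object of class `grnn_model`.
#' @export
grnn_fit <- function(train, subset = train$descriptor_names, sigma = 0.2,
                     map = NULL, training_meta = list()) {
  require_references(train, "grnn_fit")
  if (!is_scalar_number(sigma) || sigma <= 0) {
    abort("sigma must be a positive number", "grnncorr_argument_error")
  }
  if (!"dft_nci" %in% subset) {
    abort("subset must contain the primary descriptor 'dft_nci'",
          "grnncorr_argument_error")
  }
  sub <- select_descriptors(train, subset)
  map <- map %||% fit_normalization(sub, include_target = TRUE)
  new_grnn_model(
    patterns = norm_apply_matrix(map, descriptor_matrix(sub)),
    targets = norm_target(map, reference_nci(sub)),
    sigma = sigma,
    descriptor_names = subset,
    normalization = map,
    training_meta = training_meta
  )
}

# Low-level constructor; `normalization = NULL` means patterns/targets are
# taken as-is and predictions stay on the input scale.
new_grnn_model <- function(patterns, targets, sigma,
                           descriptor_names = colnames(patterns),
                           normalization = NULL, training_meta = list()) {
  patterns <- as.matrix(patterns)
  if (nrow(patterns) < 1) {
    abort("a GRNN needs at least one pattern neuron", "grnncorr_empty_error")
  }
  if (length(targets) != nrow(patterns)) {
    abort("length(targets) must equal nrow(patterns)",
          "grnncorr_argument_error")
  }
  if (!is_scalar_number(sigma) || sigma <= 0) {
    abort("sigma must be a positive number", "grnncorr_argument_error")
  }
  colnames(patterns) <- descriptor_names
  structure(
    list(
      descriptor_names = descriptor_names,
      patterns = patterns,
      targets = as.numeric(targets),
      sigma = sigma,
      normalization = normalization,
      training_meta = training_meta
    ),
    class = "grnn_model"
  )
}

#' @export
print.grnn_model <- function(x, ...) {
  cat(sprintf(
    "<grnn_model> %d pattern neuron(s), %d input(s), sigma = %g\n",
    nrow(x$patterns), length(x$descriptor_names), x$sigma))
  cat("  inputs:", paste(x$descriptor_names, collapse = ", "), "\n")
  invisible(x)
}

# Kernel-weighted average of targets from a matrix of squared distances
# (queries x patterns). The max exponent is shifted out before
# exponentiation so distant queries never underflow to 0/0: after the shift
# the nearest pattern always has weight exactly 1.
grnn_eval <- function(D2, targets, sigma) {
  E <- -D2 / (2 * sigma^2)
  shift <- apply(E, 1, max)
  W <- exp(E - shift)
  drop(W %*% targets) / rowSums(W)
}

#' Predict with a GRNN model
#'
#' Evaluates `y(X) = sum_i y_i exp(-||X - X_i||^2 / (2 sigma^2)) /
#' sum_i exp(-||X - X_i||^2 / (2 sigma^2))` over the stored pattern neurons.
#' The prediction is a convex combination of the training targets, so it
#' always lies within their range. Exponents are shifted by their maximum
#' before normalization, so queries arbitrarily far from all patterns return
#' the nearest pattern's target rather than 0/0.
#'
#' @param model A `grnn_model`.
#' @param query A named numeric vector, a data.frame/matrix with the model's
#'   descriptor columns, or an [nci_dataset].
#' @param denormalize If `TRUE`, return kcal/mol via the model's stored
#'   normalization map; otherwise the normalized scale (models built without
#'   a map always return the raw scale).
#' @return Numeric predictions, one per query row.
#' @export
grnn_predict <- function(model, query, denormalize = FALSE) {
  Q <- query_matrix(model, query)
  if (!is.null(model$normalization)) {
    Q <- norm_apply_matrix(model$normalization, Q)
  }
  pred <- grnn_eval(cross_sqdist(Q, model$patterns), model$targets,
                    model$sigma)
  if (denormalize) {
    if (is.null(model$normalization)) {
      abort("model has no normalization map to denormalize with",
            "grnncorr_argument_error")
    }
    pred <- invert_target(model$normalization, pred)
  }
  pred
}

query_matrix <- function(model, query) {
  if (inherits(query, "nci_dataset")) {
    missing_cols <- setdiff(model$descriptor_names, query$descriptor_names)
    if (length(missing_cols)) {
      abort(sprintf("query is missing model descriptor(s): %s",
                    paste(missing_cols, collapse = ", ")),
            "grnncorr_schema_error")
    }
    return(descriptor_matrix(query, model$descriptor_names))
  }
  if (is.numeric(query) && is.null(dim(query))) {
    query <- matrix(query, nrow = 1, dimnames = list(NULL, names(query)))
  }
  query <- as.matrix(query)
  if (is.null(colnames(query))) {
    if (ncol(query) != length(model$descriptor_names)) {
      abort("unnamed query must have one column per model descriptor",
            "grnncorr_schema_error")
    }
    colnames(query) <- model$descriptor_names
  }
  missing_cols <- setdiff(model$descriptor_names, colnames(query))
  if (length(missing_cols)) {
    abort(sprintf("query is missing model descriptor(s): %s",
                  paste(missing_cols, collapse = ", ")),
          "grnncorr_schema_error")
  }
  query[, model$descriptor_names, drop = FALSE]
}

#' Cross-validation configuration
#'
#' @param K Number of folds, >= 2 (use `K = n` for leave-one-out).
#' @param seed Integer seed for the fold-assignment shuffle.
#' @return Object of class `cv_config`.
#' @export
cv_config <- function(K = 10, seed = 1) {
  if (!is_scalar_number(K) || K < 2 || K != round(K)) {
    abort("K must be an integer >= 2", "grnncorr_argument_error")
  }
  structure(list(K = as.integer(K), seed = as.integer(seed)),
            class = "cv_config")
}

#' Partition ids into K cross-validation folds
#'
#' Seeded shuffle followed by round-robin assignment, so fold sizes differ
#' by at most one (e.g. 91 samples in 10 folds give one fold of 10 and nine
#' of 9) and the partition is deterministic given the seed.
#'
#' @param ids Vector of sample ids.
#' @param cv A [cv_config()].
#' @return List of `K` id vectors.
#' @export
kfold_partition <- function(ids, cv) {
  n <- length(ids)
  if (cv$K > n) {
    abort(sprintf("K = %d exceeds the %d available samples", cv$K, n),
          "grnncorr_argument_error")
  }
  perm <- with_local_seed(cv$seed, sample.int(n))
  split(ids[perm], rep_len(seq_len(cv$K), n))
}

# Shared CV engine: out-of-fold GRNN predictions for each sigma in `sigmas`.
# Normalization is refitted on each fold's training part only (no leakage);
# per-fold squared distances are computed once and reused across the sigma
# sweep. Returns a list with `oof` (n x length(sigmas) matrix of
# denormalized predictions, rows named by id) and `rmse` (per-sigma, kcal/mol).
cv_oof_predictions <- function(train, subset, sigmas, cv) {
  require_references(train, "cross-validation")
  sub <- select_descriptors(train, subset)
  ids <- sub$records$id
  folds <- kfold_partition(ids, cv)
  obs <- reference_nci(sub)
  oof <- matrix(NA_real_, length(ids), length(sigmas),
                dimnames = list(ids, NULL))
  for (fold in folds) {
    fit_ids <- setdiff(ids, fold)
    fit_set <- subset_records(sub, fit_ids)
    map <- fit_normalization(fit_set, include_target = TRUE)
    P <- norm_apply_matrix(map, descriptor_matrix(fit_set))
    t_norm <- norm_target(map, reference_nci(fit_set))
    Q <- norm_apply_matrix(
      map, descriptor_matrix(subset_records(sub, fold)))
    D2 <- cross_sqdist(Q, P)
    for (s in seq_along(sigmas)) {
      oof[fold, s] <- invert_target(map, grnn_eval(D2, t_norm, sigmas[s]))
    }
  }
  rmse_per_sigma <- apply(oof, 2, function(p) sqrt(mean((p - obs)^2)))
  list(oof = oof, obs = obs, rmse = rmse_per_sigma)
}

#' Cross-validated RMSE of a GRNN
#'
#' K-fold cross-validation: for each fold the network is fitted on the other
#' `K - 1` folds (with the normalization refitted on those folds only), the
#' held-out fold is predicted and denormalized, and the RMSE over all
#' out-of-fold predictions is returned in kcal/mol. The per-sample
#' out-of-fold predictions (used for the cross-validated q2) are attached as
#' attributes `oof_pred` and `obs`.
#'
#' @param train An [nci_dataset] with references.
#' @param subset Descriptor names used as network inputs.
#' @param sigma Smoothing factor, > 0.
#' @param cv A [cv_config()]; `K = n` gives leave-one-out.
#' @return RMSE (kcal/mol) with attributes `oof_pred` and `obs`.
#' @export
cv_rmse <- function(train, subset, sigma, cv) {
  if (!is_scalar_number(sigma) || sigma <= 0) {
    abort("sigma must be a positive number", "grnncorr_argument_error")
  }
  res <- cv_oof_predictions(train, subset, sigma, cv)
  structure(res$rmse[1], oof_pred = res$oof[, 1], obs = res$obs)
}

#' Grid search for the GRNN smoothing factor
#'
#' Evaluates the cross-validated RMSE at every sigma on the grid and returns
#' the minimizer; ties go to the larger sigma (the smoother network). The
#' default grid is `[0.1, 2]` in steps of 0.1 (20 candidates).
#'
#' @param train An [nci_dataset] with references.
#' @param subset Descriptor names used as network inputs.
#' @param grid Numeric `c(lo, hi, step)` with `lo > 0`, or an explicit
#'   vector of candidate sigmas (length != 3, or pass a grid made with
#'   [sigma_grid_points()]).
#' @param cv A [cv_config()].
#' @return List with `sigma` (the winner), `table` (data.frame of sigma and
#'   cv_rmse), and `oof_pred` (out-of-fold predictions at the winning sigma).
#' @export
optimize_sigma <- function(train, subset, grid = c(0.1, 2, 0.1), cv) {
  sigmas <- sigma_grid_points(grid)
  res <- cv_oof_predictions(train, subset, sigmas, cv)
  # which.max on the reversed order implements "ties -> larger sigma"
  best <- length(sigmas) + 1L - which.min(rev(res$rmse))
  list(
    sigma = sigmas[best],
    table = data.frame(sigma = sigmas, cv_rmse = unname(res$rmse)),
    oof_pred = res$oof[, best],
    obs = res$obs
  )
}

#' Expand a sigma grid specification
#'
#' @param grid Either `c(lo, hi, step)` (inclusive arithmetic grid, `lo > 0`)
#'   or an explicit vector of positive candidate values of length != 3.
#' @return Increasing numeric vector of candidate sigmas.
#' @export
sigma_grid_points <- function(grid) {
  grid <- as.numeric(grid)
  if (length(grid) == 3 && grid[3] > 0 && grid[1] <= grid[2]) {
    pts <- seq(grid[1], grid[2] + grid[3] / 2, by = grid[3])
    pts <- pts[pts <= grid[2] + 1e-9]
  } else {
    pts <- sort(unique(grid))
  }
  if (!length(pts) || any(!is.finite(pts)) || any(pts <= 0)) {
    abort("sigma grid must contain positive finite values",
          "grnncorr_argument_error")
  }
  pts
}
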