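# End-to-end training pipeline: SPXY split -> normalization -> PLS ranking
# -> CV subset search -> sigma grid search -> final GRNN fit -> validation.

#' Pipeline configuration
#'
#' @param train_fraction Fraction of samples selected into the training set
#'   by SPXY (default 91/121, reproducing the 91/30 benchmark division).
#' @param K Cross-validation folds (default 10).
#' @param seed Global seed; stage seeds are derived from it (CV fold
#'   shuffling uses `seed + 1000`).
#' @param sigma_grid Smoothing-factor grid `c(lo, hi, step)`; default
#'   `[0.1, 2]` in steps of 0.1.
#' @param top_k PLS shortlist length (default 10).
#' @param max_subset Largest GRNN input subset searched (default 6).
#' @param pls_components PLS components used for the coefficient ranking
#'   (default 2).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(train_fraction = 91 / 121, K = 10, seed = 7,
                            sigma_grid = c(0.1, 2, 0.1), top_k = 10,
                            max_subset = 6, pls_components = 2) {
  structure(
    list(train_fraction = train_fraction, K = as.integer(K),
         seed = as.integer(seed), sigma_grid = sigma_grid,
         top_k = as.integer(top_k), max_subset = as.integer(max_subset),
         pls_components = as.integer(pls_components)),
    class = "pipeline_config"
  )
}

#' Train a correction model end to end
#'
#' Runs the full step-wise procedure on a labelled descriptor table:
#' \enumerate{
#'   \item SPXY partition into training and test sets (joint
#'     descriptor-response distance, greedy max-min selection);
#'   \item \[-1, 1\] normalization fitted on the training set;
#'   \item PLS coefficient ranking of all descriptors and top-`k`
#'     shortlisting;
#'   \item exhaustive cross-validated subset search over the shortlist
#'     (primary descriptor always included), each candidate scored at its
#'     best smoothing factor on the grid;
#'   \item final GRNN fit on the full training set with the winning subset
#'     and sigma;
#'   \item validation: R-squared on the training fit, cross-validated q2
#'     from the out-of-fold predictions, and RMSE / MAE / q2 on the SPXY
#'     test set (all energies in kcal/mol).
#' }
#'
#' @param data An [nci_dataset] with a reference energy on every record.
#' @param config A [pipeline_config()].
#' @return Object of class `correction_pipeline`: a list with `model`
#'   (the fitted `grnn_model`), `split` (`spxy_split`), `screening`
#'   (`screening_result`), `report` (`validation_report`), and `config`.
#' @export
train_pipeline <- function(data, config = pipeline_config()) {
  require_references(data, "train_pipeline")
  n <- n_records(data)
  n_train <- min(max(train_size(n, config$train_fraction), 2L), n)
  K <- config$K
  if (K > n_train) {
    warning(sprintf(
      "K = %d exceeds the %d training samples; using leave-one-out",
      K, n_train))
    K <- n_train
  }
  cv <- cv_config(K = K, seed = config$seed + 1000L)

  split <- spxy_split(data, n_train)
  train <- subset_records(data, split$train_ids)
  test <- if (length(split$test_ids)) {
    subset_records(data, split$test_ids)
  } else {
    NULL
  }

  # PLS ranking on [-1, 1]-normalized training data
  map_full <- fit_normalization(train, include_target = TRUE)
  Xn <- norm_apply_matrix(map_full, descriptor_matrix(train))
  yn <- norm_target(map_full, reference_nci(train))
  n_comp <- min(config$pls_components, n_train - 1,
                length(train$descriptor_names))
  if (n_train >= 3 && stats::sd(yn) > 0) {
    pls <- fit_pls(Xn, yn, n_components = n_comp)
    screening <- rank_descriptors(pls, k = min(config$top_k,
                                               ncol(Xn)))
  } else {
    warning("training set too small for PLS screening; ",
            "shortlisting descriptors in input order")
    shortlist <- utils::head(
      union("dft_nci", train$descriptor_names), config$top_k)
    screening <- structure(
      list(ranking = NULL, shortlist = shortlist,
           final_subset = NULL, subset_scores = NULL),
      class = "screening_result")
  }
  if (!"dft_nci" %in% screening$shortlist) {
    # the primary descriptor is forced into every candidate subset, so it
    # joins the shortlist even when its PLS rank falls outside the top k
    screening$shortlist <- c("dft_nci",
                             utils::head(screening$shortlist,
                                         config$top_k - 1))
  }
  screening <- select_final_subset(
    screening$shortlist, train, cv,
    grid = config$sigma_grid, max_size = config$max_subset,
    screening = screening
  )

  model <- grnn_fit(
    train, subset = screening$final_subset, sigma = screening$best_sigma,
    training_meta = list(
      sigma_grid = config$sigma_grid, K = K, seed = config$seed,
      train_fraction = config$train_fraction,
      shortlist = screening$shortlist,
      subset = screening$final_subset
    )
  )

  train_obs <- reference_nci(train)
  train_pred <- grnn_predict(model, train, denormalize = TRUE)
  oof <- screening$best_oof[names(train_obs)]
  test_pred <- test_obs <- NULL
  if (!is.null(test)) {
    test_obs <- reference_nci(test)
    test_pred <- grnn_predict(model, test, denormalize = TRUE)
  }
  report <- build_report(train_pred, train_obs, oof, test_pred, test_obs)

  structure(
    list(model = model, split = split, screening = screening,
         report = report, config = config),
    class = "correction_pipeline"
  )
}

#' @export
print.correction_pipeline <- function(x, ...) {
  cat("<correction_pipeline>\n")
  cat(sprintf("  split: %d train / %d test\n",
              length(x$split$train_ids), length(x$split$test_ids)))
  cat("  inputs:", paste(x$model$descriptor_names, collapse = ", "),
      sprintf(" (sigma = %g)\n", x$model$sigma))
  print(x$report)
  invisible(x)
}

#' Apply a trained correction model to new complexes
#'
#' For every record, the corrected interaction energy is the denormalized
#' GRNN prediction and the correction is defined as
#' `correction = corrected_nci - dft_nci`, so the decomposition
#' `corrected_nci = dft_nci + correction` holds exactly by construction.
#'
#' @param model A `grnn_model`.
#' @param data An [nci_dataset] carrying every model descriptor (reference
#'   values not required).
#' @return data.frame of class `correction_result` with columns `id`,
#'   `dft_nci`, `corrected_nci`, `correction` (kcal/mol).
#' @export
apply_correction <- function(model, data) {
  corrected <- grnn_predict(model, data, denormalize = TRUE)
  dft <- descriptor_matrix(data, "dft_nci")[, 1]
  out <- data.frame(
    id = data$records$id,
    dft_nci = unname(dft),
    corrected_nci = unname(corrected),
    correction = unname(corrected - dft),
    stringsAsFactors = FALSE
  )
  class(out) <- c("correction_result", "data.frame")
  out
}
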