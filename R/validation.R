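# OECD-style model quality metrics and the over-fit diagnostic.
#
# q2 and the cross-validated q2 use the external-validation convention
# 1 - PRESS / sum((obs - mean(y_train))^2), with the training-set mean as
# the null model; both may be negative. Values above 0.5 are conventionally
# deemed valid, and R^2 - q2cv > 0.3 flags a likely over-fit model.

check_lengths <- function(pred, obs) {
  if (length(pred) != length(obs) || length(pred) == 0) {
    abort("pred and obs must have equal, nonzero length",
          "grnncorr_argument_error")
  }
}

#' Root mean square error
#' @param pred,obs Numeric vectors of equal nonzero length (kcal/mol).
#' @return `sqrt(mean((pred - obs)^2))`.
#' @export
rmse <- function(pred, obs) {
  check_lengths(pred, obs)
  sqrt(mean((pred - obs)^2))
}

#' Mean absolute error
#' @param pred,obs Numeric vectors of equal nonzero length (kcal/mol).
#' @return `mean(abs(pred - obs))`. Always `<= rmse(pred, obs)`.
#' @export
mae <- function(pred, obs) {
  check_lengths(pred, obs)
  mean(abs(pred - obs))
}

#' Goodness-of-fit R-squared
#'
#' Squared Pearson correlation between predictions and observations,
#' reported on the training set as the model's goodness-of-fit. The
#' coefficient-of-determination variant `1 - SSE/SST` is available via
#' `variant = "determination"`.
#'
#' @param pred,obs Numeric vectors; `obs` must not be constant; `n >= 2`.
#' @param variant `"pearson"` (default) or `"determination"`.
#' @return A value `<= 1` (the determination variant may be negative).
#' @export
r2_fit <- function(pred, obs, variant = c("pearson", "determination")) {
  check_lengths(pred, obs)
  variant <- match.arg(variant)
  if (length(obs) < 2 || stats::sd(obs) == 0) {
    abort("R^2 undefined: obs constant or fewer than 2 values",
          "grnncorr_degenerate_error")
  }
  if (variant == "pearson") {
    if (stats::sd(pred) == 0) return(0)
    stats::cor(pred, obs)^2
  } else {
    1 - sum((pred - obs)^2) / sum((obs - mean(obs))^2)
  }
}

#' Predictive squared correlation coefficient (external test set)
#'
#' `q2 = 1 - sum((pred - obs)^2) / sum((obs - train_mean)^2)`, with the
#' training-set mean as the null model. May be negative when the model
#' predicts worse than that null model.
#'
#' @param pred,obs Test-set predictions and observations (kcal/mol).
#' @param train_mean Mean reference energy of the training set.
#' @return q2 value `<= 1`.
#' @export
q2 <- function(pred, obs, train_mean) {
  check_lengths(pred, obs)
  denom <- sum((obs - train_mean)^2)
  if (denom == 0) {
    abort("q2 undefined: zero deviance about the training mean",
          "grnncorr_degenerate_error")
  }
  1 - sum((pred - obs)^2) / denom
}

#' Cross-validated q2 from out-of-fold predictions
#'
#' Same form as [q2()] but evaluated on the training set's out-of-fold
#' predictions, with the training-set mean as the null model.
#'
#' @param oof_pred Out-of-fold predictions for every training sample.
#' @param obs_train Training-set reference energies (kcal/mol).
#' @return q2cv value `<= 1`.
#' @export
q2cv <- function(oof_pred, obs_train) {
  q2(oof_pred, obs_train, mean(obs_train))
}

#' Assemble a validation report
#'
#' Collects training, cross-validation and test performance into one report
#' and applies the over-fit rule: `overfit_flag` is `TRUE` exactly when
#' `R^2 - q2cv > 0.3`.
#'
#' @param train_pred,train_obs Training-set predictions/observations.
#' @param oof_pred Out-of-fold (cross-validation) predictions on the
#'   training set.
#' @param test_pred,test_obs Test-set predictions/observations; `NULL` when
#'   no test set exists (test metrics then reported as `NA`).
#' @return Object of class `validation_report` with `rmse_train`,
#'   `rmse_test`, `mae_train`, `mae_test`, `r2`, `q2`, `q2cv`,
#'   `overfit_flag`, `n_train`, `n_test` (energies in kcal/mol).
#' @export
build_report <- function(train_pred, train_obs, oof_pred,
                         test_pred = NULL, test_obs = NULL) {
  r2_val <- r2_fit(train_pred, train_obs)
  q2cv_val <- q2cv(oof_pred, train_obs)
  has_test <- !is.null(test_pred) && length(test_pred) > 0
  structure(
    list(
      rmse_train = rmse(train_pred, train_obs),
      mae_train = mae(train_pred, train_obs),
      rmse_test = if (has_test) rmse(test_pred, test_obs) else NA_real_,
      mae_test = if (has_test) mae(test_pred, test_obs) else NA_real_,
      r2 = r2_val,
      q2 = if (has_test) q2(test_pred, test_obs, mean(train_obs))
           else NA_real_,
      q2cv = q2cv_val,
      overfit_flag = (r2_val - q2cv_val) > 0.3,
      n_train = length(train_obs),
      n_test = if (has_test) length(test_obs) else 0L
    ),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report> (energies in kcal/mol)\n")
  cat(sprintf("  train (n=%d): RMSE %.4f  MAE %.4f  R2 %.4f  q2cv %.4f\n",
              x$n_train, x$rmse_train, x$mae_train, x$r2, x$q2cv))
  if (x$n_test > 0) {
    cat(sprintf("  test  (n=%d): RMSE %.4f  MAE %.4f  q2 %.4f\n",
                x$n_test, x$rmse_test, x$mae_test, x$q2))
  }
  cat(sprintf("  over-fit flag (R2 - q2cv > 0.3): %s\n",
              if (x$overfit_flag) "TRUE" else "FALSE"))
  invisible(x)
}
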