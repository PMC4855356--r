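# Partial least squares (PLS1, NIPALS) used to rank descriptors by the
# magnitude of their regression coefficients. PLS serves only as a filter
# here: coefficients computed on centered, [-1, 1]-scaled variables are
# comparable across descriptors, and the top-k shortlist feeds the
# cross-validated subset search.

#' Fit a univariate-response PLS regression (NIPALS)
#'
#' Deterministic NIPALS PLS1: no random initialization; for a single
#' response each component's weight vector has the closed form
#' `w = X' y / ||X' y||` on the deflated matrices. With `n_components`
#' equal to the rank of the centered `X`, the fitted values coincide with
#' the least-squares solution.
#'
#' @param X Numeric matrix (samples x descriptors), already scaled so that
#'   coefficient magnitudes are comparable (the pipeline passes \[-1, 1\]
#'   normalized descriptors). Centered internally.
#' @param y Numeric response vector, centered internally.
#' @param n_components Number of latent components,
#'   `1 <= n_components <= min(n - 1, ncol(X))`.
#' @return Object of class `pls_model` with centers, per-component weights
#'   (`x_weights`), loadings (`x_loadings`, `y_loadings`) and the regression
#'   `coefficients` on the centered scale (plus `intercept` on the input
#'   scale).
#' @export
fit_pls <- function(X, y, n_components = 2) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (n < 3) abort("PLS needs at least 3 samples", "grnncorr_argument_error")
  if (length(y) != n) {
    abort("length(y) must equal nrow(X)", "grnncorr_argument_error")
  }
  if (stats::sd(y) == 0) {
    abort("response has zero variance: PLS undefined",
          "grnncorr_degenerate_error")
  }
  if (!is_scalar_number(n_components) || n_components < 1 ||
      n_components > min(n - 1, p)) {
    abort(sprintf("n_components must be in [1, %d]", min(n - 1, p)),
          "grnncorr_argument_error")
  }
  A <- as.integer(n_components)
  var_names <- colnames(X) %||% paste0("x", seq_len(p))

  x_center <- colMeans(X)
  y_center <- mean(y)
  E <- sweep(X, 2, x_center)
  f <- y - y_center

  W <- P <- matrix(0, p, A)
  q <- numeric(A)
  for (a in seq_len(A)) {
    w <- drop(crossprod(E, f))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-14) {  # residual X carries no covariance with y; stop early
      W <- W[, seq_len(a - 1), drop = FALSE]
      P <- P[, seq_len(a - 1), drop = FALSE]
      q <- q[seq_len(a - 1)]
      A <- a - 1L
      break
    }
    w <- w / nw
    t_score <- drop(E %*% w)
    tt <- sum(t_score^2)
    p_load <- drop(crossprod(E, t_score)) / tt
    q_load <- sum(f * t_score) / tt
    E <- E - tcrossprod(t_score, p_load)
    f <- f - t_score * q_load
    W[, a] <- w
    P[, a] <- p_load
    q[a] <- q_load
  }
  if (A == 0) {
    abort("X carries no covariance with y: no PLS component extractable",
          "grnncorr_degenerate_error")
  }
  # Regression vector B with y_hat = y_center + (x - x_center)' B
  B <- drop(W %*% solve(crossprod(P, W), q))

  structure(
    list(
      n_components = A,
      variable_names = var_names,
      x_center = stats::setNames(x_center, var_names),
      y_center = y_center,
      x_weights = W,
      x_loadings = P,
      y_loadings = q,
      coefficients = stats::setNames(B, var_names)
    ),
    class = "pls_model"
  )
}

#' Predict from a fitted PLS model
#' @param object A `pls_model`.
#' @param newdata Matrix with the model's descriptor columns.
#' @param ... Unused.
#' @return Numeric predictions.
#' @export
predict.pls_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  drop(sweep(newdata, 2, object$x_center) %*% object$coefficients) +
    object$y_center
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> %d component(s), %d descriptor(s)\n",
              x$n_components, length(x$coefficients)))
  top <- sort(abs(x$coefficients), decreasing = TRUE)
  cat("  largest |coefficients|:",
      paste(sprintf("%s=%.3g", names(utils::head(top, 4)),
                    utils::head(top, 4)), collapse = " "), "\n")
  invisible(x)
}

#' Rank descriptors by PLS coefficient magnitude
#'
#' Orders the descriptors by decreasing `|coefficient|` (ties broken by
#' input column order) and shortlists the top `k` for the subsequent
#' cross-validated subset search.
#'
#' @param model A `pls_model` from [fit_pls()].
#' @param k Shortlist length (default 10). Clamped, with a warning, when it
#'   exceeds the number of descriptors.
#' @return Object of class `screening_result` with `ranking` (data.frame of
#'   name and coefficient in rank order) and `shortlist`; `final_subset` and
#'   `subset_scores` are filled later by [select_final_subset()].
#' @export
rank_descriptors <- function(model, k = 10) {
  coefs <- model$coefficients
  if (!is_scalar_number(k) || k < 1) {
    abort("k must be a positive integer", "grnncorr_argument_error")
  }
  if (k > length(coefs)) {
    warning(sprintf("k = %d exceeds the %d available descriptors; clamped",
                    k, length(coefs)))
    k <- length(coefs)
  }
  ord <- order(-abs(coefs), seq_along(coefs))
  ranking <- data.frame(
    name = names(coefs)[ord],
    coefficient = unname(coefs[ord]),
    stringsAsFactors = FALSE
  )
  structure(
    list(
      ranking = ranking,
      shortlist = ranking$name[seq_len(k)],
      final_subset = NULL,
      subset_scores = NULL
    ),
    class = "screening_result"
  )
}

#' @export
print.screening_result <- function(x, ...) {
  cat(sprintf("<screening_result> shortlist of %d from %d descriptor(s)\n",
              length(x$shortlist), nrow(x$ranking)))
  cat("  shortlist:", paste(x$shortlist, collapse = ", "), "\n")
  if (!is.null(x$final_subset)) {
    cat("  final subset:", paste(x$final_subset, collapse = ", "), "\n")
    best <- x$subset_scores[1, ]
    cat(sprintf("  CV RMSE %.4f kcal/mol at sigma = %.2f (%d subsets scored)\n",
                best$cv_rmse, best$sigma, nrow(x$subset_scores)))
  }
  invisible(x)
}
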