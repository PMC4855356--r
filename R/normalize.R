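# [-1, 1] min-max normalization of descriptors and target.
#
# All model fitting happens on the normalized scale; energies are always
# reported denormalized, in kcal/mol. Constant variables are flagged and
# mapped to 0 rather than dropped so column indices stay stable. Query values
# outside the fitted range map outside [-1, 1]; no clipping, since Gaussian
# kernel distances remain meaningful there.

#' Fit a [-1, 1] normalization map
#'
#' Records per-variable minima and maxima over the dataset for the affine map
#' `x -> 2 (x - min) / (max - min) - 1`. Variables with `max == min` are
#' listed in `constant_variables` and mapped to 0.
#'
#' @param data An [nci_dataset].
#' @param include_target Also fit the map for the reference energy
#'   (`ref_nci`), required when the map will feed model training.
#' @return An object of class `nci_normmap`.
#' @export
fit_normalization <- function(data, include_target = TRUE) {
  if (n_records(data) == 0) {
    abort("cannot fit normalization on an empty dataset",
          "grnncorr_argument_error")
  }
  vars <- data$descriptor_names
  m <- descriptor_matrix(data)
  lo <- apply(m, 2, min)
  hi <- apply(m, 2, max)
  if (include_target) {
    require_references(data, "fit_normalization(include_target = TRUE)")
    y <- reference_nci(data)
    lo <- c(lo, ref_nci = min(y))
    hi <- c(hi, ref_nci = max(y))
    vars <- c(vars, "ref_nci")
  }
  structure(
    list(
      variables = vars,
      min = stats::setNames(as.numeric(lo), vars),
      max = stats::setNames(as.numeric(hi), vars),
      constant_variables = vars[hi == lo],
      include_target = include_target
    ),
    class = "nci_normmap"
  )
}

#' @export
print.nci_normmap <- function(x, ...) {
  cat(sprintf("<nci_normmap> %d variable(s)%s\n", length(x$variables),
              if (x$include_target) " incl. target ref_nci" else ""))
  if (length(x$constant_variables)) {
    cat("  constant (mapped to 0):",
        paste(x$constant_variables, collapse = ", "), "\n")
  }
  invisible(x)
}

# Scale a matrix whose colnames are map variables. Constant vars -> 0.
norm_apply_matrix <- function(map, m) {
  missing_vars <- setdiff(colnames(m), map$variables)
  if (length(missing_vars)) {
    abort(sprintf("variable(s) not covered by normalization map: %s",
                  paste(missing_vars, collapse = ", ")),
          "grnncorr_schema_error")
  }
  lo <- map$min[colnames(m)]
  hi <- map$max[colnames(m)]
  rng <- hi - lo
  out <- sweep(sweep(m, 2, lo, "-"), 2, ifelse(rng > 0, rng / 2, 1), "/") - 1
  out[, rng == 0] <- 0
  out
}

norm_invert_matrix <- function(map, m) {
  lo <- map$min[colnames(m)]
  hi <- map$max[colnames(m)]
  rng <- hi - lo
  out <- sweep(sweep(m + 1, 2, rng / 2, "*"), 2, lo, "+")
  if (any(rng == 0)) {
    out[, rng == 0] <- rep(lo[rng == 0], each = nrow(m))
  }
  out
}

#' Apply a normalization map to a dataset
#'
#' Transforms every descriptor column (and `ref_nci`, when the map includes
#' the target and the data carry references) with the map's affine transform.
#' Values outside the fitted range map outside \[-1, 1\]; they are not
#' clipped.
#'
#' @param map An `nci_normmap` from [fit_normalization()].
#' @param data An [nci_dataset] whose variables all appear in `map`.
#' @return The transformed [nci_dataset].
#' @export
apply_normalization <- function(map, data) {
  m <- norm_apply_matrix(map, descriptor_matrix(data))
  rec <- data$records
  rec[, data$descriptor_names] <- m
  if (map$include_target && any(is.finite(rec$ref_nci))) {
    rec$ref_nci <- norm_target(map, rec$ref_nci)
  }
  nci_dataset(rec, data$descriptor_names,
              paste0(data$provenance, " [normalized]"))
}

# Forward map for the target variable.
norm_target <- function(map, y) {
  if (!map$include_target) {
    abort("normalization map was fitted without the target",
          "grnncorr_argument_error")
  }
  lo <- map$min[["ref_nci"]]
  hi <- map$max[["ref_nci"]]
  if (hi > lo) 2 * (y - lo) / (hi - lo) - 1 else rep(0, length(y))
}

#' Invert the target normalization
#'
#' Maps a normalized response value back to kcal/mol with the exact inverse
#' affine transform. For a degenerate (constant) target the fitted value is
#' returned.
#'
#' @param map An `nci_normmap` fitted with `include_target = TRUE`.
#' @param value Numeric vector on the normalized scale.
#' @return Numeric vector in kcal/mol.
#' @export
invert_target <- function(map, value) {
  if (!map$include_target) {
    abort("normalization map was fitted without the target",
          "grnncorr_argument_error")
  }
  lo <- map$min[["ref_nci"]]
  hi <- map$max[["ref_nci"]]
  if (hi > lo) (value + 1) / 2 * (hi - lo) + lo else rep(lo, length(value))
}
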