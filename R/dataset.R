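# Core domain containers: descriptor datasets of molecular complexes.

INTERACTION_CLASSES <- c("h_bonded", "dispersion", "mixed", "halogen", "unknown")
DATABASE_TAGS <- c("S22", "S66", "X40", "synthetic", "other")

#' Construct a descriptor dataset of molecular complexes
#'
#' A dataset holds one row per molecular complex: a unique identifier, an
#' interaction class (`h_bonded`, `dispersion`, `mixed`, `halogen`, or
#' `unknown`), a block of numeric molecular descriptors that must contain the
#' primary descriptor `dft_nci` (the DFT-calculated non-covalent interaction
#' energy, kcal/mol), and optionally the reference interaction energy
#' `ref_nci` (kcal/mol, e.g. CCSD(T)/CBS-quality values). Reference values may
#' be absent only for prediction-time data.
#'
#' @param records data.frame with columns `id`, `class`, every descriptor in
#'   `descriptor_names`, and (optionally) `ref_nci` and `database_tag`.
#' @param descriptor_names character vector of descriptor column names, in
#'   order; must contain `"dft_nci"`.
#' @param provenance free-text metadata describing the origin of the table.
#' @return An object of class `nci_dataset`.
#' @examples
#' df <- data.frame(
#'   id = c("a", "b"), class = c("h_bonded", "mixed"),
#'   dft_nci = c(-12.1, -4.0), nve = c(20, 30), ref_nci = c(-10.3, -3.7)
#' )
#' ds <- nci_dataset(df, c("dft_nci", "nve"))
#' n_records(ds)
#' @export
nci_dataset <- function(records, descriptor_names,
                        provenance = "user-supplied") {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (!"id" %in% names(records)) {
    abort("records must have an 'id' column", "grnncorr_schema_error")
  }
  records$id <- as.character(records$id)
  if (anyDuplicated(records$id)) {
    dup <- records$id[duplicated(records$id)][1]
    abort(sprintf("duplicate id '%s' in dataset", dup),
          "grnncorr_integrity_error")
  }
  if (!"class" %in% names(records)) records$class <- "unknown"
  records$class <- tolower(as.character(records$class))
  bad <- setdiff(unique(records$class), INTERACTION_CLASSES)
  if (length(bad)) {
    abort(sprintf("unknown interaction class token(s): %s",
                  paste(bad, collapse = ", ")),
          "grnncorr_schema_error")
  }
  if (!"database_tag" %in% names(records)) records$database_tag <- "other"
  if (!"ref_nci" %in% names(records)) records$ref_nci <- NA_real_
  records$ref_nci <- as.numeric(records$ref_nci)

  descriptor_names <- as.character(descriptor_names)
  if (!"dft_nci" %in% descriptor_names) {
    abort("descriptor set must contain the primary descriptor 'dft_nci'",
          "grnncorr_schema_error")
  }
  missing_cols <- setdiff(descriptor_names, names(records))
  if (length(missing_cols)) {
    abort(sprintf("descriptor column(s) missing from records: %s",
                  paste(missing_cols, collapse = ", ")),
          "grnncorr_schema_error")
  }
  for (d in descriptor_names) {
    v <- records[[d]]
    if (!is.numeric(v)) {
      abort(sprintf("descriptor '%s' is not numeric", d),
            "grnncorr_parse_error")
    }
    if (nrow(records) && any(!is.finite(v))) {
      row <- which(!is.finite(v))[1]
      abort(sprintf("non-finite value in descriptor '%s' at row %d", d, row),
            "grnncorr_integrity_error")
    }
  }

  ord <- c("id", "database_tag", "class", descriptor_names, "ref_nci")
  structure(
    list(
      records = records[, ord, drop = FALSE],
      descriptor_names = descriptor_names,
      provenance = provenance
    ),
    class = "nci_dataset"
  )
}

#' @export
print.nci_dataset <- function(x, ...) {
  cat(sprintf("<nci_dataset> %d complexes, %d descriptors\n",
              n_records(x), length(x$descriptor_names)))
  cls <- table(x$records$class)
  cat("  classes:", paste(sprintf("%s=%d", names(cls), cls), collapse = " "),
      "\n")
  cat("  descriptors:",
      paste(utils::head(x$descriptor_names, 6), collapse = ", "),
      if (length(x$descriptor_names) > 6) "...", "\n")
  if (all(is.na(x$records$ref_nci))) {
    cat("  reference NCI: absent (prediction-time data)\n")
  } else {
    cat(sprintf("  reference NCI: mean %.2f kcal/mol\n",
                mean(x$records$ref_nci, na.rm = TRUE)))
  }
  cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' Number of complexes in a dataset
#' @param data An `nci_dataset`.
#' @return Integer row count.
#' @export
n_records <- function(data) nrow(data$records)

#' Extract the descriptor matrix of a dataset
#'
#' @param data An `nci_dataset`.
#' @param descriptors Optional character subset of descriptor names (default:
#'   all, in dataset order).
#' @return Numeric matrix, one row per complex, rownames = ids.
#' @export
descriptor_matrix <- function(data, descriptors = NULL) {
  descriptors <- descriptors %||% data$descriptor_names
  missing_cols <- setdiff(descriptors, data$descriptor_names)
  if (length(missing_cols)) {
    abort(sprintf("descriptor(s) not in dataset: %s",
                  paste(missing_cols, collapse = ", ")),
          "grnncorr_schema_error")
  }
  m <- as.matrix(data$records[, descriptors, drop = FALSE])
  rownames(m) <- data$records$id
  m
}

#' Reference interaction energies of a dataset
#' @param data An `nci_dataset`.
#' @return Named numeric vector (kcal/mol); `NA` where absent.
#' @export
reference_nci <- function(data) {
  stats::setNames(data$records$ref_nci, data$records$id)
}

#' Subset a dataset by complex ids
#' @param data An `nci_dataset`.
#' @param ids Character ids to keep, in the order given.
#' @return An `nci_dataset` with the selected records.
#' @export
subset_records <- function(data, ids) {
  idx <- match(ids, data$records$id)
  if (anyNA(idx)) {
    abort(sprintf("id(s) not in dataset: %s",
                  paste(ids[is.na(idx)], collapse = ", ")),
          "grnncorr_schema_error")
  }
  nci_dataset(data$records[idx, , drop = FALSE], data$descriptor_names,
              data$provenance)
}

#' Restrict a dataset to a subset of its descriptors
#' @param data An `nci_dataset`.
#' @param descriptors Names to keep; must include `"dft_nci"`.
#' @return An `nci_dataset` with only those descriptor columns.
#' @export
select_descriptors <- function(data, descriptors) {
  nci_dataset(data$records, descriptors, data$provenance)
}

# TRUE when every record carries a finite reference value (training use).
has_references <- function(data) {
  n_records(data) > 0 && all(is.finite(data$records$ref_nci))
}

require_references <- function(data, what = "this operation") {
  if (!has_references(data)) {
    abort(sprintf("%s requires a reference_nci for every record", what),
          "grnncorr_integrity_error")
  }
  invisible(data)
}
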