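# Versioned structured-text (JSON) serialization of GRNN models.

MODEL_FORMAT <- "grnncorr-model"
MODEL_VERSION <- 1L

#' Save a GRNN model to a JSON file
#'
#' Writes a versioned structured-text representation holding the descriptor
#' names, normalization map, smoothing factor, training patterns and
#' targets, and training provenance. Numeric values are written at full
#' precision, so a reloaded model reproduces predictions bit-identically.
#'
#' @param model A `grnn_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  if (!inherits(model, "grnn_model")) {
    abort("model must be a grnn_model", "grnncorr_argument_error")
  }
  norm <- if (is.null(model$normalization)) NULL else list(
    variables = model$normalization$variables,
    min = unname(model$normalization$min),
    max = unname(model$normalization$max),
    constant_variables = model$normalization$constant_variables,
    include_target = model$normalization$include_target
  )
  obj <- list(
    format = MODEL_FORMAT,
    version = MODEL_VERSION,
    descriptor_names = model$descriptor_names,
    sigma = model$sigma,
    normalization = norm,
    patterns = unname(model$patterns),
    targets = model$targets,
    training_meta = model$training_meta
  )
  # 17 significant digits: doubles survive the text round-trip exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Load a GRNN model from a JSON file
#'
#' @param path File written by [save_model()].
#' @return A `grnn_model`.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), "grnncorr_io_error")
  }
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, MODEL_FORMAT)) {
    abort("not a grnncorr model file (format tag mismatch)",
          "grnncorr_compat_error")
  }
  if (!identical(as.integer(obj$version), MODEL_VERSION)) {
    abort(sprintf("unsupported model file version '%s'", obj$version),
          "grnncorr_compat_error")
  }
  for (field in c("descriptor_names", "sigma", "patterns", "targets")) {
    if (is.null(obj[[field]])) {
      abort(sprintf("model file is missing field '%s'", field),
            "grnncorr_compat_error")
    }
  }
  patterns <- obj$patterns
  if (is.list(patterns)) patterns <- do.call(rbind, patterns)
  patterns <- matrix(as.numeric(patterns), ncol = length(obj$descriptor_names))
  norm <- NULL
  if (!is.null(obj$normalization)) {
    vars <- obj$normalization$variables
    norm <- structure(
      list(
        variables = vars,
        min = stats::setNames(as.numeric(obj$normalization$min), vars),
        max = stats::setNames(as.numeric(obj$normalization$max), vars),
        constant_variables =
          as.character(obj$normalization$constant_variables %||% character()),
        include_target = isTRUE(obj$normalization$include_target)
      ),
      class = "nci_normmap"
    )
  }
  new_grnn_model(
    patterns = patterns,
    targets = as.numeric(obj$targets),
    sigma = as.numeric(obj$sigma),
    descriptor_names = as.character(obj$descriptor_names),
    normalization = norm,
    training_meta = obj$training_meta %||% list()
  )
}
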