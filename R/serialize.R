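MODEL_SCHEMA_VERSION <- 1L

#' Save a fitted model to JSON
#'
#' Writes every field of a fitted `"nblda"` model to a documented JSON
#' schema (with a `schema_version` field) at full floating-point precision,
#' so that [read_nblda_model()] reproduces the model exactly.
#'
#' @param model A fitted `"nblda"` model.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_nblda_model <- function(model, path) {
  if (!inherits(model, "nblda")) stop("model must be an 'nblda' fit", call. = FALSE)
  payload <- list(
    schema_version = MODEL_SCHEMA_VERSION,
    class_names = model$class_names,
    gene_ids = model$gene_ids,
    lambda = as.numeric(model$lambda),
    d = unname(model$d),          # K x G, row-major list of rows in JSON
    pi = model$pi,
    phi = as.numeric(model$phi),
    sf = model$sf,
    sf_method = model$sf_method,
    sf_stats = model$sf_stats[setdiff(names(model$sf_stats), "method")],
    dispersion = list(
      phi_initial = as.numeric(model$dispersion$phi_initial),
      xi = model$dispersion$xi,
      delta = model$dispersion$delta,
      phi_hat = as.numeric(model$dispersion$phi_hat),
      xi_strategy = model$dispersion$xi_strategy
    )
  )
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Load a fitted model from JSON
#'
#' Reads a model written by [write_nblda_model()], checking the schema
#' version and the presence and consistency of every field.
#'
#' @param path Path to a model JSON file.
#' @return An object of class `"nblda"`.
#' @export
read_nblda_model <- function(path) {
  payload <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                      error = function(e) {
                        stop(sprintf("cannot parse model file '%s': %s",
                                     path, conditionMessage(e)), call. = FALSE)
                      })
  required <- c("schema_version", "class_names", "gene_ids", "lambda", "d",
                "pi", "phi", "sf", "sf_method", "sf_stats", "dispersion")
  missing <- setdiff(required, names(payload))
  if (length(missing) > 0L) {
    stop(sprintf("model file is missing field(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (!identical(as.integer(payload$schema_version), MODEL_SCHEMA_VERSION)) {
    stop(sprintf("model schema version %s not supported (expected %d)",
                 payload$schema_version, MODEL_SCHEMA_VERSION), call. = FALSE)
  }
  K <- length(payload$class_names)
  G <- length(payload$gene_ids)
  d <- matrix(as.numeric(payload$d), K, G,
              dimnames = list(payload$class_names, payload$gene_ids))
  disp_fields <- c("phi_initial", "xi", "delta", "phi_hat", "xi_strategy")
  if (!all(disp_fields %in% names(payload$dispersion))) {
    stop("model file has an incomplete dispersion block", call. = FALSE)
  }
  model <- structure(list(
    lambda = stats::setNames(as.numeric(payload$lambda), payload$gene_ids),
    d = d,
    pi = as.numeric(payload$pi),
    phi = stats::setNames(as.numeric(payload$phi), payload$gene_ids),
    sf = as.numeric(payload$sf),
    sf_method = payload$sf_method,
    sf_stats = c(list(method = payload$sf_method), as.list(payload$sf_stats)),
    dispersion = structure(payload$dispersion[disp_fields],
                           class = "dispersion_fit"),
    class_names = payload$class_names,
    gene_ids = payload$gene_ids
  ), class = "nblda")
  if (length(model$lambda) != G || length(model$phi) != G ||
      length(model$pi) != K || length(model$sf_stats) < 2L) {
    stop("model file fields have inconsistent dimensions", call. = FALSE)
  }
  check_model_params(model)
  model
}
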