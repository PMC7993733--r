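# JSON serialisation of trained age models.

#' Write / read an age model as JSON
#'
#' The file records the tissue, ordered predictors with their transforms,
#' coefficients and standardized coefficients, the intercept, adjusted
#' R-squared, training n, and the panel checksum, so prediction-time
#' mismatches are detectable.
#'
#' @param model An `age_model`.
#' @param path Output JSON path.
#' @return `write_age_model()`: `path`, invisibly. `read_age_model()`: an
#'   `age_model`.
#' @export
write_age_model <- function(model, path) {
  stopifnot(inherits(model, "age_model"))
  obj <- list(
    tissue = model$tissue,
    predictors = lapply(model$predictors, function(cp) list(
      cpg = cp,
      transform = list(form = model$transforms[[cp]]$form,
                       exponent = model$transforms[[cp]]$exponent),
      coefficient = model$coefficients[[cp]],
      std_beta = model$std_beta[[cp]])),
    intercept = model$intercept,
    adjusted_r2 = model$adjusted_r2,
    training_n = model$training_n,
    panel_checksum = model$panel_checksum)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_age_model
#' @export
read_age_model <- function(path) {
  if (!file.exists(path)) stopf("model file not found: %s", path)
  obj <- jsonlite::read_json(path)
  preds <- vapply(obj$predictors, function(p) p$cpg, character(1))
  transforms <- lapply(obj$predictors, function(p)
    transform_spec(p$transform$form, p$transform$exponent %||% 1))
  names(transforms) <- preds
  structure(list(
    tissue = obj$tissue,
    predictors = preds,
    transforms = transforms,
    intercept = obj$intercept,
    coefficients = stats::setNames(
      vapply(obj$predictors, function(p) p$coefficient, numeric(1)), preds),
    std_beta = stats::setNames(
      vapply(obj$predictors, function(p) p$std_beta, numeric(1)), preds),
    adjusted_r2 = obj$adjusted_r2,
    training_n = obj$training_n,
    panel_checksum = obj$panel_checksum %||% NA_character_),
    class = "age_model")
}
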