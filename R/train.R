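#' Train a tissue-specific age model end to end
#'
#' The full modelling procedure on a training table: per-CpG curve
#' estimation selects identity vs power transform ([fit_power_transform()]),
#' univariate screening records each CpG's standardized coefficient, and
#' stepwise probability-of-F selection builds the multivariable model, which
#' is refit by OLS. Samples missing any candidate value are dropped per
#' fit (mechanical per-sample rejection, as when a donor lacks data at one
#' CpG).
#'
#' @param meth Matrix (samples x CpGs, percent betas).
#' @param age Ages in years.
#' @param tissue Tissue label.
#' @param candidates CpG ids eligible (default: all columns).
#' @param config A [stepwise_config()].
#' @param exponent_grid Grid for curve estimation.
#' @param min_n Minimum training samples; fewer is an error.
#' @param panel_checksum Recorded on the model.
#' @return An `age_model` with attributes `screen` (the univariate screen)
#'   and `trace` (the stepwise log), or an `empty_model`.
#' @export
train_age_model <- function(meth, age, tissue = "blood",
                            candidates = colnames(meth),
                            config = stepwise_config(),
                            exponent_grid = seq(0.5, 3, by = 0.1),
                            min_n = 10, panel_checksum = NA_character_) {
  if (length(age) < min_n)
    stopf("refusing to train on %d samples (minimum %d)", length(age), min_n)
  transforms <- lapply(candidates, function(cp) {
    x <- meth[, cp]
    ok <- stats::complete.cases(x, age)
    if (sum(ok) >= 10 && all(x[ok] > 0) && stats::sd(x[ok]) > 0) {
      fit_power_transform(x[ok], age[ok], exponent_grid)
    } else transform_spec("identity")
  })
  names(transforms) <- candidates
  screen <- univariate_screen(meth[, candidates, drop = FALSE], age, transforms)
  model <- stepwise_select(meth, age, candidates = candidates,
                           config = config, transforms = transforms,
                           tissue = tissue, panel_checksum = panel_checksum)
  attr(model, "screen") <- screen
  model
}
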