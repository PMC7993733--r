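# Tissue-specific age-prediction models: OLS of age on (possibly power
# transformed) percent methylation predictors.

#' Transform specifications
#'
#' A transform spec describes how one CpG's methylation enters the model:
#' identity, or a power transform `x^exponent` (strictly monotone on
#' (0, 100]), used for markers whose methylation-age trajectory is
#' non-linear.
#'
#' @param form `"identity"` or `"power"`.
#' @param exponent Positive exponent (ignored for identity).
#' @return A `transform_spec` list.
#' @export
transform_spec <- function(form = c("identity", "power"), exponent = 1) {
  form <- match.arg(form)
  stopifnot(is.numeric(exponent), exponent > 0)
  structure(list(form = form, exponent = if (form == "power") exponent else 1),
            class = "transform_spec")
}

apply_transform <- function(x, spec) {
  if (is.null(spec) || spec$form == "identity") return(x)
  if (any(x < 0, na.rm = TRUE)) stopf("power transform of negative methylation")
  x^spec$exponent
}

#' Select a power transform by curve estimation
#'
#' Compares the linear-fit R-squared of age against raw methylation with age
#' against `meth^k` over an exponent grid, returning the transform that
#' maximizes R-squared; ties (no strict improvement over identity) return
#' identity. This is the curve-estimation step that motivates power
#' transforming non-linear markers before multivariable modelling.
#'
#' @param meth Percent methylation (all > 0 for power fitting).
#' @param age Ages in years.
#' @param exponent_grid Candidate exponents (default 0.5 to 3.0 by 0.1).
#' @return A `transform_spec`, with attributes `r2_identity` and `r2_best`.
#' @export
fit_power_transform <- function(meth, age, exponent_grid = seq(0.5, 3, by = 0.1)) {
  stopifnot(length(meth) == length(age))
  if (length(meth) < 10) stopf("need at least 10 observations")
  if (any(meth <= 0)) stopf("nonpositive methylation: power fitting requires all values > 0")
  r2 <- function(x) {
    f <- stats::lm.fit(cbind(1, x), age)
    1 - sum(f$residuals^2) / sum((age - mean(age))^2)
  }
  r2_id <- r2(meth)
  r2_grid <- vapply(exponent_grid, function(k) r2(meth^k), numeric(1))
  best <- which.max(r2_grid)
  out <- if (r2_grid[best] > r2_id + 1e-12) {
    transform_spec("power", exponent_grid[best])
  } else transform_spec("identity")
  attr(out, "r2_identity") <- r2_id
  attr(out, "r2_best") <- max(r2_grid[best], r2_id)
  out
}

#' Univariate screening of CpG predictors
#'
#' Per CpG, simple linear regression of age on (transformed) methylation.
#' The standardized coefficient equals the Pearson correlation in simple
#' regression and is reported with its t statistic, two-sided p-value and
#' R-squared. Zero-variance predictors are flagged and excluded.
#'
#' @param meth Matrix (samples x CpGs, percent), colnames = CpG ids.
#' @param age Ages in years.
#' @param transforms Optional named list of `transform_spec` per CpG.
#' @return Data frame `cpg_id, std_beta, t_stat, p_value, r_squared,
#'   excluded`.
#' @export
univariate_screen <- function(meth, age, transforms = NULL) {
  stopifnot(nrow(meth) == length(age))
  if (length(age) < 3) stopf("need at least 3 records")
  rows <- lapply(colnames(meth), function(cp) {
    x <- apply_transform(meth[, cp], transforms[[cp]])
    ok <- stats::complete.cases(x, age)
    x <- x[ok]; y <- age[ok]
    if (length(x) < 3 || stats::sd(x) == 0) {
      return(data.frame(cpg_id = cp, std_beta = NA_real_, t_stat = NA_real_,
                        p_value = NA_real_, r_squared = NA_real_,
                        excluded = TRUE, stringsAsFactors = FALSE))
    }
    r <- stats::cor(x, y)
    n <- length(x)
    tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    data.frame(cpg_id = cp, std_beta = r, t_stat = tt, p_value = p,
               r_squared = r^2, excluded = FALSE, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Fit an age-prediction model
#'
#' Ordinary least squares of age on transformed methylation predictors.
#' Reports the intercept and coefficients (years per transformed percent),
#' standardized coefficients (coefficient times SD of the transformed
#' predictor over SD of age), per-coefficient t and p, R-squared and
#' adjusted R-squared `1 - (1 - R2)(n - 1)/(n - p - 1)`.
#'
#' @param meth Matrix (samples x CpGs, percent), colnames = CpG ids.
#' @param age Ages in years.
#' @param predictors Character vector of CpG ids to use (columns of `meth`).
#' @param transforms Optional named list of `transform_spec` per predictor.
#' @param tissue Tissue label stored on the model.
#' @param panel_checksum Optional checksum recorded for predict-time
#'   mismatch detection (see [panel_checksum()]).
#' @param condition_limit Reciprocal-condition threshold below which
#'   predictors are declared collinear.
#' @return An `age_model` object.
#' @export
fit_model <- function(meth, age, predictors, transforms = NULL,
                      tissue = "unspecified", panel_checksum = NA_character_,
                      condition_limit = 1e-10) {
  stopifnot(nrow(meth) == length(age), length(predictors) >= 1)
  miss <- setdiff(predictors, colnames(meth))
  if (length(miss)) stopf("predictor(s) absent from data: %s",
                          paste(miss, collapse = ", "))
  X <- sapply(predictors, function(cp)
    apply_transform(meth[, cp], transforms[[cp]]))
  X <- matrix(X, ncol = length(predictors),
              dimnames = list(NULL, predictors))
  ok <- stats::complete.cases(X, age)
  X <- X[ok, , drop = FALSE]; y <- age[ok]
  n <- length(y); p <- ncol(X)
  if (n <= p + 1) stopf("need n > p + 1 (n = %d, p = %d)", n, p)
  cx <- stats::cor(X)
  rc <- rcond(cx)
  if (rc < condition_limit) {
    off <- abs(cx - diag(p))
    worst <- which(off == max(off), arr.ind = TRUE)[1, ]
    stopf("collinear predictors: %s and %s",
          predictors[worst[1]], predictors[worst[2]])
  }
  df <- data.frame(age = y, X, check.names = FALSE)
  fml <- stats::as.formula(paste("age ~", paste(sprintf("`%s`", predictors),
                                                collapse = " + ")))
  fit <- stats::lm(fml, data = df)
  sm <- summary(fit)
  coefs <- stats::coef(fit)
  std_beta <- coefs[-1] * apply(X, 2, stats::sd) / stats::sd(y)
  structure(list(
    tissue = tissue,
    predictors = predictors,
    transforms = lapply(predictors, function(cp)
      transforms[[cp]] %||% transform_spec("identity")) |>
      stats::setNames(predictors),
    intercept = unname(coefs[1]),
    coefficients = stats::setNames(unname(coefs[-1]), predictors),
    std_beta = stats::setNames(unname(std_beta), predictors),
    t_stat = stats::setNames(unname(sm$coefficients[-1, "t value"]), predictors),
    p_value = stats::setNames(unname(sm$coefficients[-1, "Pr(>|t|)"]), predictors),
    r2 = sm$r.squared,
    adjusted_r2 = sm$adj.r.squared,
    sigma = sm$sigma,
    training_n = n,
    panel_checksum = panel_checksum,
    fitted = unname(stats::fitted(fit)),
    residuals = unname(stats::residuals(fit)),
    training_age = y),
    class = "age_model")
}

#' @export
print.age_model <- function(x, ...) {
  cat(sprintf("Age-prediction model (%s): %d predictors, n = %d, adj. R2 = %.3f\n",
              x$tissue, length(x$predictors), x$training_n, x$adjusted_r2))
  tf <- vapply(x$transforms, function(t)
    if (t$form == "power") sprintf("^%.1f", t$exponent) else "", character(1))
  df <- data.frame(predictor = x$predictors, transform = tf,
                   coefficient = round(x$coefficients, 4),
                   std_beta = round(x$std_beta, 3))
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
summary.age_model <- function(object, ...) {
  tf <- vapply(object$transforms, function(t)
    if (t$form == "power") sprintf("power(%.1f)", t$exponent) else "identity",
    character(1))
  tab <- data.frame(predictor = object$predictors, transform = tf,
                    coefficient = object$coefficients,
                    std_beta = object$std_beta,
                    t_stat = object$t_stat, p_value = object$p_value)
  rownames(tab) <- NULL
  out <- list(tissue = object$tissue, table = tab,
              intercept = object$intercept, r2 = object$r2,
              adjusted_r2 = object$adjusted_r2,
              training_n = object$training_n,
              training_mae = mean(abs(object$residuals)))
  class(out) <- "summary.age_model"
  out
}

#' @export
print.summary.age_model <- function(x, ...) {
  cat(sprintf("Age-prediction model for %s\n", x$tissue))
  cat(sprintf("Training n = %d; R2 = %.3f; adjusted R2 = %.3f; training MAE = %.2f years\n",
              x$training_n, x$r2, x$adjusted_r2, x$training_mae))
  cat(sprintf("Intercept: %.3f years\n", x$intercept))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.age_model <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coefficients)
}

#' @export
residuals.age_model <- function(object, ...) object$residuals

#' @export
plot.age_model <- function(x, ...) {
  plot(x$training_age, x$fitted, xlab = "chronological age [years]",
       ylab = "predicted age [years]",
       main = sprintf("%s model (training)", x$tissue), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Predict age from methylation data
#'
#' Affine prediction on transformed predictors; raw values are returned
#' without clamping to a plausible age range. `newdata` may be a matrix or
#' data frame of percent betas (columns = CpG ids) or a
#' `methylation_calls` table (long format): samples with a missing or
#' depth-failing predictor get `NA` with the reason recorded in the
#' `reasons` attribute.
#'
#' @param object An `age_model`.
#' @param newdata Beta matrix/data frame or `methylation_calls`.
#' @param panel_checksum Optional checksum of the panel the calls came from;
#'   a mismatch with the model's stored checksum is an error.
#' @param ... Unused.
#' @return Named numeric vector of predicted ages in years.
#' @export
predict.age_model <- function(object, newdata, panel_checksum = NULL, ...) {
  if (!is.null(panel_checksum) && !is.na(object$panel_checksum) &&
      !identical(panel_checksum, object$panel_checksum)) {
    stopf("panel checksum mismatch: model trained on a different panel")
  }
  if (inherits(newdata, "methylation_calls")) {
    return(predict_age(object, newdata, panel_checksum = panel_checksum))
  }
  newdata <- as.matrix(newdata)
  miss <- setdiff(object$predictors, colnames(newdata))
  if (length(miss)) stopf("predictor(s) missing from newdata: %s",
                          paste(miss, collapse = ", "))
  pred <- rep(object$intercept, nrow(newdata))
  for (cp in object$predictors) {
    pred <- pred + object$coefficients[[cp]] *
      apply_transform(newdata[, cp], object$transforms[[cp]])
  }
  names(pred) <- rownames(newdata)
  pred
}

#' @rdname predict.age_model
#' @param model An `age_model`.
#' @param calls A `methylation_calls` data frame with a `sample` column.
#' @export
predict_age <- function(model, calls, panel_checksum = NULL) {
  if (!is.null(panel_checksum) && !is.na(model$panel_checksum) &&
      !identical(panel_checksum, model$panel_checksum)) {
    stopf("panel checksum mismatch: model trained on a different panel")
  }
  miss <- setdiff(model$predictors, calls$cpg_id)
  if (length(miss)) stopf("calls lack model predictor(s): %s",
                          paste(miss, collapse = ", "))
  samples <- unique(calls$sample)
  pred <- stats::setNames(rep(NA_real_, length(samples)), samples)
  reasons <- stats::setNames(rep(NA_character_, length(samples)), samples)
  for (s in samples) {
    d <- calls[calls$sample == s & calls$cpg_id %in% model$predictors, ]
    bad <- d$cpg_id[is.na(d$beta) | !d$pass_depth]
    absent <- setdiff(model$predictors, d$cpg_id)
    if (length(bad) || length(absent)) {
      reasons[s] <- sprintf("predictor(s) missing or failing depth QC: %s",
                            paste(c(absent, bad), collapse = ", "))
      next
    }
    b <- stats::setNames(d$beta, d$cpg_id)[model$predictors]
    pred[s] <- model$intercept +
      sum(vapply(model$predictors, function(cp)
        model$coefficients[[cp]] * apply_transform(b[[cp]], model$transforms[[cp]]),
        numeric(1)))
  }
  attr(pred, "reasons") <- reasons[!is.na(reasons)]
  pred
}

#' Stratified train/test split
#'
#' Assigns `train`/`test` labels preserving the joint age-quartile by sex
#' composition: within every stratum the training fraction matches the
#' overall `train_n / n` up to rounding (largest-remainder allocation), as
#' when a donor cohort is divided while retaining comparable age and sex
#' distributions.
#'
#' @param cohort Data frame with `age` and `sex` columns.
#' @param train_n Training-set size (< cohort size).
#' @param seed RNG seed.
#' @param stratify_on Columns used for stratification (subset of
#'   `c("age", "sex")`; age is cut at its quartiles).
#' @return The cohort with its `split` column set.
#' @export
split_train_test <- function(cohort, train_n, seed = NULL,
                             stratify_on = c("age", "sex")) {
  n <- nrow(cohort)
  if (!is_count(train_n) || train_n >= n)
    stopf("train_n must be a count below the cohort size (%d)", n)
  strata <- rep("all", n)
  if ("age" %in% stratify_on) {
    q <- stats::quantile(cohort$age, c(0.25, 0.5, 0.75))
    strata <- paste(strata, cut(cohort$age, c(-Inf, q, Inf), labels = 1:4))
  }
  if ("sex" %in% stratify_on) strata <- paste(strata, cohort$sex)
  f <- train_n / n
  tab <- table(strata)
  quota <- floor(tab * f)
  rem <- tab * f - quota
  short <- train_n - sum(quota)
  if (short > 0) {
    add <- names(sort(rem, decreasing = TRUE))[seq_len(short)]
    quota[add] <- quota[add] + 1
  }
  with_seed(seed, {
    cohort$split <- "test"
    for (s in names(tab)) {
      idx <- which(strata == s)
      take <- sample(idx, min(quota[[s]], length(idx)))
      cohort$split[take] <- "train"
    }
    # largest-remainder rounding is exact unless a stratum ran dry
    deficit <- train_n - sum(cohort$split == "train")
    if (deficit > 0) {
      pool <- which(cohort$split == "test")
      cohort$split[sample(pool, deficit)] <- "train"
    }
    cohort
  })
}

#' Checksum of a panel definition
#'
#' MD5 over the marker and CpG tables, recorded in trained models so a
#' model/panel mismatch is detectable at prediction time.
#' @param panel A `panel_definition`.
#' @return Character checksum.
#' @export
panel_checksum <- function(panel) {
  con <- textConnection("dump", "w", local = TRUE)
  utils::write.table(panel$markers, con, row.names = FALSE)
  utils::write.table(panel$cpgs, con, row.names = FALSE)
  close(con)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(dump, tmp)
  unname(tools::md5sum(tmp))
}
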