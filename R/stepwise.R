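# Stepwise predictor selection by probability of F.

#' Stepwise selection configuration
#'
#' Entry/removal thresholds on the partial-F p-value. The defaults (0.05 to
#' enter, 0.10 to remove) are the conventional stepwise defaults of the
#' major statistics packages; `p_enter <= p_remove` guarantees termination.
#'
#' @param p_enter Maximum partial-F p-value for a candidate to enter.
#' @param p_remove Minimum partial-F p-value for an included predictor to
#'   be removed.
#' @param max_steps Step budget.
#' @return A `stepwise_config` list.
#' @export
stepwise_config <- function(p_enter = 0.05, p_remove = 0.10, max_steps = 100) {
  stopifnot(p_enter > 0, p_remove < 1, p_enter <= p_remove, max_steps >= 1)
  structure(list(p_enter = p_enter, p_remove = p_remove,
                 max_steps = max_steps), class = "stepwise_config")
}

# partial-F p-values of each coefficient in an OLS fit of y on X (with
# intercept); for a single coefficient the partial F equals t^2.
coef_pvalues <- function(X, y) {
  n <- length(y); p <- ncol(X)
  fit <- stats::lm.fit(cbind(1, X), y)
  rss <- sum(fit$residuals^2)
  df <- n - p - 1
  XtX_inv <- chol2inv(chol(crossprod(cbind(1, X))))
  se <- sqrt(diag(XtX_inv)[-1] * rss / df)
  tt <- fit$coefficients[-1] / se
  2 * stats::pt(-abs(tt), df = df)
}

#' Stepwise multivariable selection of CpG predictors
#'
#' Iterative entry/removal driven by partial-F p-values: at each step the
#' excluded candidate with the smallest p-value enters if it passes
#' `p_enter`; then any included predictor whose p-value exceeds `p_remove`
#' leaves (worst first). Iteration stops when nothing changes or the step
#' budget is exhausted; the final model is refit with [fit_model()].
#' Deterministic: the same data always yield the same model.
#'
#' @param meth Matrix (samples x CpGs, percent), colnames = CpG ids.
#' @param age Ages in years.
#' @param candidates CpG ids eligible for selection.
#' @param config A [stepwise_config()].
#' @param transforms Optional named list of `transform_spec` per candidate.
#' @param tissue,panel_checksum Passed to [fit_model()].
#' @return An `age_model` (with attribute `trace`, the entry/removal log),
#'   or an `empty_model` object when no candidate passes `p_enter`.
#' @export
stepwise_select <- function(meth, age, candidates = colnames(meth),
                            config = stepwise_config(), transforms = NULL,
                            tissue = "unspecified",
                            panel_checksum = NA_character_) {
  stopifnot(inherits(config, "stepwise_config"), length(candidates) >= 1)
  X_all <- sapply(candidates, function(cp)
    apply_transform(meth[, cp], transforms[[cp]]))
  X_all <- matrix(X_all, ncol = length(candidates),
                  dimnames = list(NULL, candidates))
  ok <- stats::complete.cases(X_all, age)
  X_all <- X_all[ok, , drop = FALSE]; y <- age[ok]
  n <- length(y)
  usable <- candidates[apply(X_all, 2, stats::sd) > 0]
  selected <- character(0)
  trace <- list()
  for (step in seq_len(config$max_steps)) {
    changed <- FALSE
    pool <- setdiff(usable, selected)
    if (n <= length(selected) + 3) pool <- character(0)  # room for one more + intercept
    if (length(pool)) {
      entry_p <- vapply(pool, function(cp) {
        Xc <- X_all[, c(selected, cp), drop = FALSE]
        if (rcond(crossprod(cbind(1, Xc))) < 1e-12) return(NA_real_)
        tail(coef_pvalues(Xc, y), 1)
      }, numeric(1))
      if (any(!is.na(entry_p)) && min(entry_p, na.rm = TRUE) < config$p_enter) {
        enter <- pool[which.min(entry_p)]
        selected <- c(selected, enter)
        trace[[length(trace) + 1]] <- list(step = step, action = "enter",
                                           cpg = enter,
                                           p = min(entry_p, na.rm = TRUE))
        changed <- TRUE
      }
    }
    while (length(selected) > 1) {
      pv <- coef_pvalues(X_all[, selected, drop = FALSE], y)
      if (max(pv) <= config$p_remove) break
      drop_cp <- selected[which.max(pv)]
      selected <- setdiff(selected, drop_cp)
      trace[[length(trace) + 1]] <- list(step = step, action = "remove",
                                         cpg = drop_cp, p = max(pv))
      changed <- TRUE
    }
    if (!changed) break
  }
  if (!length(selected)) {
    return(structure(list(tissue = tissue, predictors = character(0),
                          trace = trace), class = "empty_model"))
  }
  model <- fit_model(meth, age, predictors = selected,
                     transforms = transforms, tissue = tissue,
                     panel_checksum = panel_checksum)
  attr(model, "trace") <- trace
  model
}

#' @rdname stepwise_select
#' @param x Object to test.
#' @export
is_empty_model <- function(x) inherits(x, "empty_model")
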