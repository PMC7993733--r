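# Prediction evaluation and assay-equivalence testing.

#' Evaluate age predictions
#'
#' Mean absolute error overall and per age category (default bounds: 1-20,
#' 21-40, 41-60, >60 years), plus the Pearson correlation of the absolute
#' error with age and its p-value (prediction error grows with age for the
#' soft-tissue models). Samples with `NA` predictions are excluded and
#' counted.
#'
#' @param pred Predicted ages (years), may contain NA.
#' @param truth Chronological ages (years), same length.
#' @param category_bounds Upper bounds of the first categories; the last
#'   category is open-ended. Default `c(20, 40, 60)` gives four categories.
#' @return An `evaluation_report` list: `mae_overall`, `by_category` (data
#'   frame `category, bounds, n, mae` with NA MAE for empty categories),
#'   `pearson_r`, `pearson_p`, `n_used`, `n_missing`.
#' @export
evaluate_predictions <- function(pred, truth, category_bounds = c(20, 40, 60)) {
  stopifnot(length(pred) == length(truth))
  ok <- !is.na(pred) & !is.na(truth)
  if (sum(ok) < 2) stopf("need at least 2 usable prediction/truth pairs")
  p <- pred[ok]; a <- truth[ok]
  err <- abs(p - a)
  brk <- c(-Inf, category_bounds, Inf)
  cat_idx <- cut(a, brk, labels = FALSE)
  k <- length(category_bounds) + 1
  lab <- vapply(seq_len(k), function(i) {
    lo <- if (i == 1) 1 else category_bounds[i - 1] + 1
    if (i == k) sprintf(">%g", category_bounds[k - 1])
    else sprintf("%g-%g", lo, category_bounds[i])
  }, character(1))
  by_cat <- data.frame(
    category = seq_len(k), bounds = lab,
    n = vapply(seq_len(k), function(i) sum(cat_idx == i), integer(1)),
    mae = vapply(seq_len(k), function(i)
      if (any(cat_idx == i)) mean(err[cat_idx == i]) else NA_real_, numeric(1)))
  ct <- if (stats::sd(err) > 0 && stats::sd(a) > 0) {
    stats::cor.test(err, a)
  } else list(estimate = NA_real_, p.value = NA_real_)
  structure(list(mae_overall = mean(err), by_category = by_cat,
                 pearson_r = unname(ct$estimate), pearson_p = ct$p.value,
                 n_used = sum(ok), n_missing = sum(!ok)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("MAE = %.2f years (n = %d%s)\n", x$mae_overall, x$n_used,
              if (x$n_missing) sprintf(", %d without prediction", x$n_missing)
              else ""))
  print(x$by_category, row.names = FALSE, digits = 3)
  if (!is.na(x$pearson_r))
    cat(sprintf("Pearson r(|error|, age) = %.3f, p = %.3g\n",
                x$pearson_r, x$pearson_p))
  invisible(x)
}

#' Joint slope/intercept equivalence test between two assays
#'
#' Per marker, regresses assay-b methylation on assay-a methylation and
#' jointly tests (intercept, slope) = (0, 1) with an F test: the restricted
#' model is the identity line, so `F = ((RSS0 - RSS1)/2) / (RSS1/(n - 2))`
#' with `RSS0 = sum((b - a)^2)`. P-values are Bonferroni-adjusted over
#' `n_tests` markers (capped at 1). Non-rejection means no detectable
#' performance difference between the assays at that marker.
#'
#' @param measurements_a,measurements_b Data frames with columns `marker`
#'   and `beta` (paired rows in matching order within marker), or named
#'   lists of paired numeric vectors.
#' @param n_tests Number of tests for the Bonferroni correction (default:
#'   number of markers compared).
#' @param alpha Significance level used for the `reject` flag.
#' @return Data frame `marker, n, slope, intercept, F_stat, p_value,
#'   p_adjusted, reject`.
#' @export
test_assay_equivalence <- function(measurements_a, measurements_b,
                                   n_tests = NULL, alpha = 0.05) {
  if (is.data.frame(measurements_a)) {
    measurements_a <- split(measurements_a$beta, measurements_a$marker)
  }
  if (is.data.frame(measurements_b)) {
    measurements_b <- split(measurements_b$beta, measurements_b$marker)
  }
  markers <- intersect(names(measurements_a), names(measurements_b))
  if (!length(markers)) stopf("no common markers to compare")
  if (is.null(n_tests)) n_tests <- length(markers)
  rows <- lapply(markers, function(mk) {
    a <- measurements_a[[mk]]; b <- measurements_b[[mk]]
    stopifnot(length(a) == length(b))
    ok <- stats::complete.cases(a, b)
    a <- a[ok]; b <- b[ok]
    n <- length(a)
    if (n < 3) stopf("marker %s: need at least 3 paired observations", mk)
    if (stats::sd(a) == 0) stopf("marker %s: degenerate variance in assay a", mk)
    fit <- stats::lm(b ~ a)
    rss1 <- sum(stats::residuals(fit)^2)
    rss0 <- sum((b - a)^2)
    if (rss1 < 1e-12) {            # perfect fit: identity line or exact offset
      Fst <- if (rss0 - rss1 < 1e-12) 0 else Inf
    } else {
      Fst <- ((rss0 - rss1) / 2) / (rss1 / (n - 2))
    }
    p <- stats::pf(Fst, 2, n - 2, lower.tail = FALSE)
    padj <- min(1, n_tests * p)
    data.frame(marker = mk, n = n,
               slope = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]),
               F_stat = Fst, p_value = p, p_adjusted = padj,
               reject = padj < alpha, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
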