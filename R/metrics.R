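#' Pearson correlation between observations and predictions
#'
#' Product-moment correlation with the standard t-transform p-value
#' (n - 2 degrees of freedom) and an approximate 95% confidence interval
#' by the Fisher z transform, as returned by [stats::cor.test()]. The
#' interval is reported for description only; model selection uses the
#' Index, never the interval.
#'
#' @param observed,predicted Numeric vectors of equal length >= 3, each
#'   with non-zero variance.
#'
#' @return A list with `r`, `p_value` and `ci` (length-2 vector).
#' @export
pearson_r <- function(observed, predicted) {
  observed <- as.numeric(observed); predicted <- as.numeric(predicted)
  if (length(observed) != length(predicted))
    stop("observed and predicted must have equal length", call. = FALSE)
  if (length(observed) < 3L)
    stop("need at least 3 paired values", call. = FALSE)
  if (sd(observed) == 0 || sd(predicted) == 0)
    stop("undefined-correlation: zero variance input", call. = FALSE)
  ct <- cor.test(observed, predicted, conf.level = 0.95)
  ci <- if (!is.null(ct$conf.int)) as.numeric(ct$conf.int)
        else c(NA_real_, NA_real_)
  list(r = unname(ct$estimate), p_value = unname(ct$p.value), ci = ci)
}

#' Mean squared error
#'
#' @param observed,predicted Numeric vectors of equal, non-zero length.
#' @return Mean of the squared residuals (rating units squared when
#'   applied to SAM-scale ratings).
#' @export
mse <- function(observed, predicted) {
  observed <- as.numeric(observed); predicted <- as.numeric(predicted)
  if (length(observed) == 0L) stop("empty input", call. = FALSE)
  if (length(observed) != length(predicted))
    stop("observed and predicted must have equal length", call. = FALSE)
  mean((observed - predicted)^2)
}

#' Index model-selection score
#'
#' Combines the two evaluation metrics into one score,
#' `Index = r / MSE`: a better model has a larger correlation and a
#' smaller mean squared error, hence a larger Index. A perfect fit
#' (`mse = 0`) yields `Inf` as a documented sentinel rather than an
#' error.
#'
#' @param r Pearson correlation coefficient.
#' @param mse Mean squared error (>= 0).
#' @return The Index (dimensionless).
#' @export
#' @examples
#' index_score(0.9600, 0.3894)
index_score <- function(r, mse) {
  if (!is.numeric(r) || !is.numeric(mse) || !is.finite(r) || !is.finite(mse))
    stop("r and mse must be finite numerics", call. = FALSE)
  if (mse < 0) stop("mse must be >= 0", call. = FALSE)
  if (mse == 0) return(Inf)
  r / mse
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA (between/within decomposition,
#' `F = MSB / MSW`), used to screen SCR feature columns for differences
#' across affect classes. Computed via [stats::aov()].
#'
#' @param values Numeric response vector.
#' @param group_labels Group labels (coerced to factor), same length.
#'
#' @return A list of class `"anova_result"` with `F`, `df_between`
#'   (k - 1), `df_within` (N - k) and `p_value`.
#' @export
#' @examples
#' one_way_anova(c(1, 2, 3, 2, 3, 4, 6, 7, 8), rep(c("a", "b", "c"), each = 3))
one_way_anova <- function(values, group_labels) {
  values <- as.numeric(values)
  g <- factor(group_labels)
  if (length(values) != length(g))
    stop("values and group_labels must have equal length", call. = FALSE)
  if (nlevels(droplevels(g)) < 2L)
    stop("need at least 2 groups", call. = FALSE)
  if (length(values) <= nlevels(droplevels(g)))
    stop("need more observations than groups", call. = FALSE)
  g <- droplevels(g)
  s <- summary(aov(values ~ g))[[1L]]
  structure(list(F = s[["F value"]][1L],
                 df_between = s[["Df"]][1L],
                 df_within = s[["Df"]][2L],
                 p_value = s[["Pr(>F)"]][1L]),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df_between, x$df_within, x$F, x$p_value))
  invisible(x)
}

#' Evaluate a polynomial model on a feature table
#'
#' Predicts the target for every row of the table and assembles the
#' evaluation report: Pearson r with its p-value and 95% CI, MSE, and
#' the Index.
#'
#' @param model An `"hmpm"` model.
#' @param table Data frame containing the model's input columns and the
#'   target column.
#' @param target_label Name of the target column; defaults to the
#'   model's own.
#'
#' @return A list of class `"eval_report"` with `target_label`, `n`,
#'   `r`, `r_ci`, `p_value`, `mse` and `index`.
#' @export
evaluate <- function(model, table, target_label = model$target_label) {
  stopifnot(inherits(model, "hmpm"), is.data.frame(table))
  if (is.na(target_label) || !target_label %in% names(table))
    stop(sprintf("schema error: target column '%s' not in table",
                 target_label), call. = FALSE)
  observed <- as.numeric(table[[target_label]])
  predicted <- predict(model, table)
  err <- mse(observed, predicted)
  pr <- pearson_r(observed, predicted)
  structure(list(target_label = target_label, n = length(observed),
                 r = pr$r, r_ci = pr$ci, p_value = pr$p_value,
                 mse = err, index = index_score(pr$r, err)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "%s estimation on n = %d: r = %.4f (%.4f, %.4f), p = %.4g, MSE = %.4f, Index = %.4f\n",
    x$target_label, x$n, x$r, x$r_ci[1], x$r_ci[2], x$p_value, x$mse,
    x$index))
  invisible(x)
}

#' @export
as.data.frame.eval_report <- function(x, ...) {
  data.frame(target = x$target_label, n = x$n, r = x$r,
             ci_low = x$r_ci[1], ci_high = x$r_ci[2],
             p_value = x$p_value, mse = x$mse, index = x$index)
}
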