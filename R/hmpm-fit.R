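#' Fitting configuration for higher-order polynomial models
#'
#' @param singular_criterion Relative singular-value cutoff for the
#'   truncated least-squares solve: singular values below
#'   `singular_criterion` times the largest are zeroed (default `1e-8`).
#' @param significance_level Retention threshold for coefficient pruning:
#'   terms with two-sided p-value above this are eliminated backwards,
#'   one per refit (default `1e-4`).
#' @param max_order Largest polynomial order considered by order sweeps
#'   (default 10).
#' @param scale_inputs Centre and scale input variables before basis
#'   expansion (conditioning aid; default `FALSE`, i.e. raw units).
#'
#' @return A list of class `"fit_config"`.
#' @export
fit_config <- function(singular_criterion = 1e-8, significance_level = 1e-4,
                       max_order = 10L, scale_inputs = FALSE) {
  if (!is.numeric(singular_criterion) || singular_criterion <= 0)
    stop("singular_criterion must be > 0", call. = FALSE)
  if (!is.numeric(significance_level) || significance_level <= 0 ||
      significance_level >= 1)
    stop("significance_level must be in (0, 1)", call. = FALSE)
  structure(list(singular_criterion = singular_criterion,
                 significance_level = significance_level,
                 max_order = as.integer(max_order),
                 scale_inputs = isTRUE(scale_inputs)),
            class = "fit_config")
}

#' Truncated-SVD least squares with coefficient inference
#'
#' Solves `A b = y` in the least-squares sense through the singular value
#' decomposition, zeroing singular values smaller than
#' `singular_criterion` times the largest (the minimum-norm solution on
#' the retained subspace). High-order monomial columns are nearly
#' collinear, so the plain normal equations can be numerically singular;
#' truncation regularises the solve. Standard errors come from the
#' truncated pseudoinverse and the residual variance with
#' `df = nrow(A) - retained rank`; p-values are two-sided from the t
#' distribution. When `df <= 0` the p-values are returned as `NA`
#' (undefined) rather than failing.
#'
#' @param A Numeric design matrix.
#' @param y Numeric response vector, `length(y) == nrow(A)`.
#' @param singular_criterion Relative cutoff (default `1e-8`).
#'
#' @return A list with `coefficients`, `se`, `p_values`, `rank`, `df`,
#'   `sigma2` (residual variance estimate), `fitted` and `sse`.
#' @export
truncated_ls <- function(A, y, singular_criterion = 1e-8) {
  A <- as.matrix(A); y <- as.numeric(y)
  if (nrow(A) == 0L) stop("empty-data: design has zero rows", call. = FALSE)
  if (length(y) != nrow(A))
    stop("length(y) must equal nrow(A)", call. = FALSE)
  sv <- svd(A)
  dmax <- if (length(sv$d)) sv$d[1] else 0
  keep <- sv$d > singular_criterion * dmax & sv$d > 0
  dinv <- ifelse(keep, 1 / sv$d, 0)
  coefs <- drop(sv$v %*% (dinv * drop(crossprod(sv$u, y))))
  fitted_vals <- drop(A %*% coefs)
  sse <- sum((y - fitted_vals)^2)
  rank <- sum(keep)
  df <- nrow(A) - rank
  sigma2 <- if (df > 0) sse / df else NA_real_
  # diag of the truncated (A^T A)^+ = V D^-2 V^T
  unscaled <- rowSums(sweep(sv$v^2, 2L, dinv^2, `*`))
  if (df > 0) {
    se <- sqrt(sigma2 * unscaled)
    tstat <- coefs / se
    p <- ifelse(is.finite(tstat), 2 * pt(-abs(tstat), df),
                ifelse(se == 0 & coefs == 0, 1, NA_real_))
  } else {
    se <- rep(NA_real_, length(coefs))
    p <- rep(NA_real_, length(coefs))
  }
  list(coefficients = coefs, se = se, p_values = p, rank = rank, df = df,
       sigma2 = sigma2, fitted = fitted_vals, sse = sse)
}

# assemble an hmpm object from a tLS solve on a given basis
new_hmpm <- function(ls_fit, exponents, var_names, X, y, order, config,
                     target_label = NA_character_, centers = NULL,
                     scales = NULL, call = NULL) {
  labels <- monomial_labels(exponents, var_names)
  coefs <- ls_fit$coefficients
  names(coefs) <- labels
  structure(list(
    coefficients = coefs,
    exponents = exponents,
    se = stats::setNames(ls_fit$se, labels),
    p_values = stats::setNames(ls_fit$p_values, labels),
    order = as.integer(order),
    m = length(var_names),
    var_names = var_names,
    rank = ls_fit$rank,
    df = ls_fit$df,
    sigma2 = ls_fit$sigma2,
    sse = ls_fit$sse,
    fitted.values = ls_fit$fitted,
    residuals = y - ls_fit$fitted,
    y = y, X = X,
    config = config,
    target_label = target_label,
    centers = centers, scales = scales,
    call = call), class = "hmpm")
}

apply_scaling <- function(X, centers, scales) {
  if (is.null(centers)) return(X)
  sweep(sweep(X, 2L, centers, `-`), 2L, scales, `/`)
}

#' Fit a higher-order multivariable polynomial model (matrix interface)
#'
#' Expands `X` into the full monomial basis of total degree `order`,
#' solves by [truncated_ls()], then (by default) prunes statistically
#' insignificant terms by [prune_insignificant()]. For `order = 1` this
#' coincides with ordinary multivariate linear regression.
#'
#' @param X Numeric observation matrix (or data frame), one column per
#'   input variable.
#' @param y Numeric response vector.
#' @param order Polynomial order `p` (non-negative integer).
#' @param config A [fit_config()].
#' @param prune Prune insignificant terms after the initial fit
#'   (default `TRUE`).
#' @param target_label Optional response name stored on the model.
#'
#' @return An object of class `"hmpm"`; see [hmpm()] for the available
#'   methods.
#' @seealso [hmpm()] for the formula interface.
#' @export
fit_hmpm <- function(X, y, order, config = fit_config(), prune = TRUE,
                     target_label = NA_character_) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  y <- as.numeric(y)
  var_names <- colnames(X)
  centers <- scales <- NULL
  Xs <- X
  if (isTRUE(config$scale_inputs)) {
    centers <- colMeans(X)
    scales <- apply(X, 2L, sd)
    scales[scales == 0] <- 1
    Xs <- apply_scaling(X, centers, scales)
  }
  exponents <- monomial_exponents(ncol(X), order)
  colnames(exponents) <- var_names
  fit <- truncated_ls(build_design(Xs, exponents), y,
                      config$singular_criterion)
  model <- new_hmpm(fit, exponents, var_names, X, y, order, config,
                    target_label, centers, scales, call = sys.call())
  if (prune) model <- prune_insignificant(model, config = config)
  model
}

#' Backward elimination of insignificant polynomial terms
#'
#' Repeatedly removes the single least-significant non-intercept term
#' whose p-value exceeds `config$significance_level` and refits, until
#' every retained term is significant or only the intercept remains. The
#' intercept is exempt from removal. Terms whose p-value is undefined
#' (`NA`, e.g. a saturated fit) are never removed on that evidence.
#'
#' @param model A fitted `"hmpm"` carrying its training data.
#' @param X,y Optional training data overriding those stored on the model.
#' @param config A [fit_config()]; defaults to the model's own.
#'
#' @return The pruned `"hmpm"` model (refitted on the retained basis).
#' @export
prune_insignificant <- function(model, X = model$X, y = model$y,
                                config = model$config) {
  stopifnot(inherits(model, "hmpm"))
  alpha <- config$significance_level
  X <- as.matrix(X); y <- as.numeric(y)
  Xs <- apply_scaling(X, model$centers, model$scales)
  exponents <- model$exponents
  fit <- NULL
  repeat {
    fit <- truncated_ls(build_design(Xs, exponents), y,
                        config$singular_criterion)
    intercept <- rowSums(exponents) == 0L
    p <- fit$p_values
    removable <- which(!intercept & !is.na(p) & p > alpha)
    if (!length(removable) || sum(!intercept) == 0L) break
    worst <- removable[which.max(p[removable])]
    exponents <- exponents[-worst, , drop = FALSE]
  }
  new_hmpm(fit, exponents, model$var_names, X, y, model$order, config,
           model$target_label, model$centers, model$scales,
           call = model$call)
}

#' Higher-order multivariable polynomial regression
#'
#' Formula interface to [fit_hmpm()]. Fits the response as a polynomial
#' of total degree `order` in the right-hand-side variables by
#' truncated-SVD least squares, with backward elimination of terms whose
#' coefficients are not significant at `config$significance_level`. The
#' polynomial basis approximates any smooth response surface (Taylor
#' expansion rationale) while remaining linear in its coefficients, so
#' estimation stays an ordinary linear least-squares problem.
#'
#' @param formula Model formula, e.g.
#'   `valence ~ gain + decay_time_constant`; right-hand-side variables
#'   enter the polynomial basis jointly (all cross terms up to total
#'   degree `order`).
#' @param data Data frame containing the variables.
#' @param order Polynomial order `p`.
#' @param config A [fit_config()].
#' @param prune Prune insignificant terms (default `TRUE`).
#'
#' @return An object of class `"hmpm"` with methods [print()],
#'   [summary()], [coef()], [predict.hmpm()], [fitted()], [residuals()],
#'   [simulate()], [plot.hmpm()], [gradient()] and [gradient_field()].
#' @export
#' @examples
#' tab <- generate_feature_table(default_affective_config(seed = 1))
#' fit <- hmpm(valence ~ gain + decay_time_constant, tab, order = 2)
#' summary(fit)
hmpm <- function(formula, data, order, config = fit_config(),
                 prune = TRUE) {
  mf <- model.frame(formula, data)
  y <- model.response(mf)
  X <- as.matrix(mf[, -1L, drop = FALSE])
  target <- deparse(formula[[2L]])
  model <- fit_hmpm(X, y, order, config, prune = prune,
                    target_label = target)
  model$call <- match.call()
  model$formula <- formula
  model
}

#' @export
print.hmpm <- function(x, digits = 6, ...) {
  cat(sprintf("Higher-order multivariable polynomial model (order %d, %d variable%s)\n",
              x$order, x$m, if (x$m == 1) "" else "s"))
  if (!is.na(x$target_label)) cat("Target:", x$target_label, "\n")
  cat(sprintf("Retained %d of %d order-%d monomials\n",
              length(x$coefficients), nrow(monomial_exponents(x$m, x$order)),
              x$order))
  print(round(x$coefficients, digits))
  invisible(x)
}

#' @export
coef.hmpm <- function(object, ...) object$coefficients

#' @export
fitted.hmpm <- function(object, ...) object$fitted.values

#' @export
residuals.hmpm <- function(object, ...) object$residuals

#' @export
summary.hmpm <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients,
               `Std. Error` = object$se,
               `t value` = object$coefficients / object$se,
               `Pr(>|t|)` = object$p_values)
  structure(list(model = object, coefficients = tab,
                 sigma = sqrt(object$sigma2), df = object$df,
                 rank = object$rank, sse = object$sse),
            class = "summary.hmpm")
}

#' @export
print.summary.hmpm <- function(x, ...) {
  m <- x$model
  cat(sprintf("Polynomial order: %d | variables: %s | target: %s\n",
              m$order, paste(m$var_names, collapse = ", "),
              if (is.na(m$target_label)) "-" else m$target_label))
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  cat(sprintf("Residual sd %.6g on %d df (retained rank %d), SSE %.6g\n",
              x$sigma, x$df, x$rank, x$sse))
  invisible(x)
}

#' Predict from a fitted polynomial model
#'
#' @param object An `"hmpm"` model.
#' @param newdata Data frame containing the model's input variables, or a
#'   numeric matrix with `m` columns. Omitted: returns fitted values.
#' @param ... Unused.
#'
#' @return Numeric vector of predictions.
#' @export
predict.hmpm <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  X <- resolve_inputs(object, newdata)
  Xs <- apply_scaling(X, object$centers, object$scales)
  drop(build_design(Xs, object$exponents) %*% object$coefficients)
}

resolve_inputs <- function(object, newdata) {
  if (is.data.frame(newdata)) {
    missing_cols <- setdiff(object$var_names, names(newdata))
    if (length(missing_cols))
      stop(sprintf("schema error: missing input columns: %s",
                   paste(missing_cols, collapse = ", ")), call. = FALSE)
    X <- as.matrix(newdata[, object$var_names, drop = FALSE])
  } else {
    X <- as.matrix(newdata)
    if (ncol(X) == 1L && object$m > 1L && nrow(X) == object$m) X <- t(X)
    if (ncol(X) != object$m)
      stop("schema error: newdata must have one column per model variable",
           call. = FALSE)
    colnames(X) <- object$var_names
  }
  storage.mode(X) <- "double"
  X
}

#' @export
simulate.hmpm <- function(object, nsim = 1, seed = NULL, newdata = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- if (is.null(newdata)) object$fitted.values else
    predict(object, newdata)
  sd_hat <- if (is.finite(object$sigma2)) sqrt(object$sigma2) else 0
  out <- as.data.frame(replicate(nsim, mu + rnorm(length(mu), 0, sd_hat)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Plot a fitted polynomial surface or its gradient field
#'
#' For two-variable models, draws either the fitted response surface as a
#' filled contour map or the gradient field as arrows on a regular grid,
#' over the bounding box of the training inputs (or explicit bounds).
#'
#' @param x An `"hmpm"` model with `m = 2`.
#' @param what `"surface"` or `"gradient"`.
#' @param lower,upper Numeric length-2 grid bounds; default the training
#'   input ranges.
#' @param n Grid resolution per axis (default 40 for the surface, 15 for
#'   the gradient field).
#' @param ... Passed on to the underlying plotting primitive.
#' @return Invisibly, the grid data frame used.
#' @export
plot.hmpm <- function(x, what = c("surface", "gradient"),
                      lower = NULL, upper = NULL, n = NULL, ...) {
  what <- match.arg(what)
  if (x$m != 2L)
    stop("plot.hmpm supports two-variable models only", call. = FALSE)
  if (is.null(lower)) lower <- apply(x$X, 2L, min)
  if (is.null(upper)) upper <- apply(x$X, 2L, max)
  if (is.null(n)) n <- if (what == "surface") 40L else 15L
  g1 <- seq(lower[1], upper[1], length.out = n)
  g2 <- seq(lower[2], upper[2], length.out = n)
  grid <- as.matrix(expand.grid(g1, g2))
  colnames(grid) <- x$var_names
  z <- predict(x, grid)
  if (what == "surface") {
    filled.contour(g1, g2, matrix(z, n, n),
                   color.palette = function(k) hcl.colors(k, "viridis"),
                   xlab = x$var_names[1], ylab = x$var_names[2],
                   main = paste("Fitted", x$target_label, "surface"), ...)
  } else {
    G <- gradient(x, grid)
    span <- c(diff(range(g1)), diff(range(g2))) / n
    len <- sqrt(G[, 1]^2 + G[, 2]^2)
    scl <- 0.8 * min(span) / max(len, na.rm = TRUE)
    plot(grid[, 1], grid[, 2], type = "n",
         xlab = x$var_names[1], ylab = x$var_names[2],
         main = paste("Gradient field of", x$target_label))
    arrows(grid[, 1], grid[, 2],
           grid[, 1] + scl * G[, 1], grid[, 2] + scl * G[, 2],
           length = 0.04, ...)
  }
  invisible(as.data.frame(cbind(grid, value = z)))
}
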