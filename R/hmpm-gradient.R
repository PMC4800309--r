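#' Gradient of a fitted polynomial surface
#'
#' Analytic partial derivatives of the fitted polynomial with respect to
#' each input variable: every monomial contributes its exponent-weighted,
#' degree-lowered term. The gradient field of the valence and arousal
#' surfaces shows which input direction (gain vs decay time constant)
#' dominates the response locally.
#'
#' @param model An `"hmpm"` model.
#' @param points A single point (numeric vector of length `m`), a numeric
#'   matrix with `m` columns, or a data frame containing the model
#'   variables.
#' @param ... Unused.
#'
#' @return For a single point, a named numeric gradient vector; otherwise
#'   a matrix with one row per point and one column per variable.
#' @export
#' @examples
#' tab <- generate_feature_table(default_affective_config(seed = 1))
#' fit <- hmpm(arousal ~ gain + decay_time_constant, tab, order = 2)
#' gradient(fit, c(gain = 0.5, decay_time_constant = 3))
gradient <- function(model, points, ...) UseMethod("gradient")

#' @rdname gradient
#' @export
gradient.hmpm <- function(model, points, ...) {
  single <- is.null(dim(points)) && !is.data.frame(points)
  X <- resolve_inputs(model, if (single) matrix(as.numeric(points), 1L)
                      else points)
  Xs <- apply_scaling(X, model$centers, model$scales)
  E <- model$exponents
  out <- matrix(0, nrow(Xs), model$m,
                dimnames = list(NULL, model$var_names))
  for (v in seq_len(model$m)) {
    active <- E[, v] > 0L
    if (!any(active)) next
    Ed <- E[active, , drop = FALSE]
    Ed[, v] <- Ed[, v] - 1L
    w <- model$coefficients[active] * E[active, v]
    out[, v] <- drop(build_design(Xs, Ed) %*% w)
    # chain rule for the optional input scaling x' = (x - mu)/s
    if (!is.null(model$scales)) out[, v] <- out[, v] / model$scales[v]
  }
  if (single) out[1L, ] else out
}

#' Gradient field on a rectangular grid
#'
#' Evaluates [gradient()] at every node of a regular rectangular grid,
#' suitable for quiver-style plots and CSV export.
#'
#' @param model An `"hmpm"` model.
#' @param lower,upper Numeric vectors of length `m`: grid bounds per
#'   variable.
#' @param n Integer grid resolution per axis (scalar or length `m`).
#'
#' @return A data frame with one row per grid node: the input
#'   coordinates, the predicted `value`, and one `d_<var>` column per
#'   partial derivative.
#' @export
gradient_field <- function(model, lower, upper, n = 15L) {
  stopifnot(inherits(model, "hmpm"))
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  if (length(lower) != model$m || length(upper) != model$m)
    stop("schema error: bounds must have one entry per model variable",
         call. = FALSE)
  n <- rep_len(as.integer(n), model$m)
  if (any(n < 1L)) stop("empty grid", call. = FALSE)
  if (any(upper < lower)) stop("upper bounds below lower bounds", call. = FALSE)
  axes <- lapply(seq_len(model$m), function(v)
    if (n[v] == 1L) (lower[v] + upper[v]) / 2
    else seq(lower[v], upper[v], length.out = n[v]))
  names(axes) <- model$var_names
  grid <- as.matrix(expand.grid(axes))
  G <- gradient(model, grid)
  colnames(G) <- paste0("d_", model$var_names)
  out <- data.frame(grid, value = predict(model, grid), G,
                    check.names = FALSE)
  rownames(out) <- NULL
  out
}
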