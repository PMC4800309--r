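#' Extend a sample by the variance-preserving pairwise formula
#'
#' From a sample \eqn{\xi_1, \ldots, \xi_n} constructs one pseudo-observation
#' per unordered pair \eqn{i < j}:
#' \deqn{\eta_{ij} = \bar{x} + \frac{\xi_i + \xi_j - 2\bar{x}}{\sqrt{2}}}
#' with the population mean \eqn{\mu} if known (`mu`), otherwise the
#' sample mean \eqn{\bar{x}} plugged in for it.
#' With the true \eqn{\mu}, each \eqn{\eta_{ij}} retains the mean
#' \eqn{\mu} and variance \eqn{\sigma^2}; pairs sharing an index
#' correlate at 0.5, disjoint pairs at 0, and \eqn{\eta_{ij}} correlates
#' with its source \eqn{\xi_i} at \eqn{1/\sqrt{2}}. With the plug-in
#' sample mean (the applied default, since \eqn{\mu} is unknown for real
#' feature columns) these moments hold approximately, with finite-sample
#' attenuation of order \eqn{1/n}. The construction is deterministic:
#' all \eqn{n(n-1)/2} pairs are enumerated in lexicographic order.
#'
#' @param values Numeric vector, length >= 2, all finite.
#' @param mu Optional known population mean; default `NULL` uses
#'   `mean(values)`.
#'
#' @return A list of class `"extended_column"` with `values` (length
#'   `n(n-1)/2`) and `pair_index` (two-column integer matrix of source
#'   indices, `i < j`, lexicographic).
#' @seealso [extend_table()]
#' @export
#' @examples
#' extend_column(c(1, 2, 3))$values
extend_column <- function(values, mu = NULL) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2L) stop("too-few-values: need n >= 2 to extend", call. = FALSE)
  if (!all(is.finite(values)))
    stop("values must be finite", call. = FALSE)
  idx <- pair_indices(n)
  xbar <- if (is.null(mu)) mean(values) else as.numeric(mu)
  eta <- xbar + (values[idx[, 1L]] + values[idx[, 2L]] - 2 * xbar) / sqrt(2)
  structure(list(values = eta, pair_index = idx), class = "extended_column")
}

# all unordered pairs i < j of 1..n, lexicographic order
pair_indices <- function(n) {
  idx <- t(combn(n, 2L))
  colnames(idx) <- c("i", "j")
  idx
}

#' @export
print.extended_column <- function(x, ...) {
  cat(sprintf("Extended column: %d values from %d pairs\n",
              length(x$values), nrow(x$pair_index)))
  invisible(x)
}

#' Extend a feature table class-by-class
#'
#' Applies [extend_column()] within each affect class to every requested
#' numeric column, using the \emph{same} pair enumeration for all columns
#' of a class so that each simulated row combines the same two source
#' stimuli in every column. This preserves the joint pattern of the
#' source rows (e.g. the clustering of gain and decay time constant per
#' class), which independent per-column pairing would destroy.
#'
#' @param table A feature table data frame (see [read_feature_table()] for
#'   the schema).
#' @param group_column Name of the class column (default
#'   `"affect_class"`).
#' @param columns Character vector of columns to extend; defaults to the
#'   numeric feature and rating columns present in the table.
#'
#' @return A data frame of simulated rows: one per class per unordered
#'   source pair, with `provenance = "simulated"`, a `source_pair` column
#'   (`"i-j"` within-class row indices) and constructed `stimulus_id`s.
#' @export
#' @examples
#' tab <- generate_feature_table(default_affective_config(seed = 1))
#' sim <- extend_table(tab)
#' nrow(sim)  # 3 classes x choose(8, 2) = 84
extend_table <- function(table, group_column = "affect_class",
                         columns = NULL) {
  stopifnot(is.data.frame(table))
  if (!group_column %in% names(table))
    stop(sprintf("schema error: missing group column '%s'", group_column),
         call. = FALSE)
  if (is.null(columns)) {
    candidates <- c("onset_time", "gain", "rise_time",
                    "decay_time_constant", "valence", "arousal")
    columns <- intersect(candidates, names(table))
    columns <- columns[vapply(table[columns], is.numeric, logical(1))]
  }
  if (length(columns) == 0L)
    stop("schema error: no numeric columns to extend", call. = FALSE)
  missing_cols <- setdiff(columns, names(table))
  if (length(missing_cols))
    stop(sprintf("schema error: missing columns: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  groups <- split(seq_len(nrow(table)), table[[group_column]])
  out <- lapply(names(groups), function(cls) {
    rows <- groups[[cls]]
    if (length(rows) < 2L)
      stop(sprintf("too-few-values: class '%s' has fewer than 2 rows", cls),
           call. = FALSE)
    idx <- pair_indices(length(rows))
    ext <- lapply(columns, function(col) {
      v <- table[[col]][rows]
      xbar <- mean(v)
      xbar + (v[idx[, 1L]] + v[idx[, 2L]] - 2 * xbar) / sqrt(2)
    })
    names(ext) <- columns
    df <- as.data.frame(ext)
    df[[group_column]] <- cls
    df$stimulus_id <- sprintf("sim_%s_%d_%d", cls, idx[, 1L], idx[, 2L])
    df$provenance <- "simulated"
    df$source_pair <- sprintf("%d-%d", idx[, 1L], idx[, 2L])
    df
  })
  out <- do.call(rbind, out)
  lead <- intersect(c("stimulus_id", group_column, columns,
                      "provenance", "source_pair"), names(out))
  rownames(out) <- NULL
  out[, lead]
}
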