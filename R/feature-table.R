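#' @name feature_table
#' @title The per-stimulus feature table schema
#' @description
#' The tabular currency of the package: one row per stimulus, with the
#' SCR parameters extracted from the averaged skin conductance segment
#' and the affective ratings. Columns: `stimulus_id`, `affect_class`
#' (pleasant / neutral / unpleasant, extensible), `onset_time` (s),
#' `gain` (\eqn{\mu}S), `rise_time` (s), `decay_time_constant` (s),
#' `valence` and `arousal` (SAM 1-9), `provenance` (`experimental`,
#' `simulated` or `synthetic`). Statistically extended rows carry an
#' additional `source_pair` column. Ratings must lie in 1 to 9 except on
#' `simulated` rows, where the variance-preserving extension may
#' legitimately step slightly outside the scale; SCR parameter columns
#' must be positive; stimulus ids must be unique within a provenance.
NULL

ft_numeric_cols <- c("onset_time", "gain", "rise_time",
                     "decay_time_constant", "valence", "arousal")
ft_required_cols <- c("stimulus_id", "affect_class", ft_numeric_cols)

#' Validate a feature table against the schema
#'
#' @param table A data frame.
#' @param require_all Require every schema column (default TRUE; the
#'   rating columns may be absent on tables mid-pipeline when FALSE).
#' @return Invisibly, the table; stops with a message listing every
#'   violation otherwise.
#' @seealso [feature_table]
#' @export
validate_feature_table <- function(table, require_all = TRUE) {
  stopifnot(is.data.frame(table))
  problems <- character(0)
  need <- if (require_all) ft_required_cols
          else c("stimulus_id", "affect_class")
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols))
    problems <- c(problems, sprintf("missing columns: %s",
                                    paste(missing_cols, collapse = ", ")))
  prov <- if ("provenance" %in% names(table)) as.character(table$provenance)
          else rep("experimental", nrow(table))
  for (col in intersect(c("valence", "arousal"), names(table))) {
    v <- table[[col]]
    bad <- which(is.finite(v) & (v < 1 | v > 9) & prov != "simulated")
    if (length(bad))
      problems <- c(problems, sprintf(
        "%s outside [1, 9] at row%s %s", col,
        if (length(bad) > 1) "s" else "",
        paste(head(bad, 5L), collapse = ", ")))
  }
  for (col in intersect(c("gain", "rise_time", "decay_time_constant"),
                        names(table))) {
    v <- table[[col]]
    bad <- which(is.finite(v) & v < 0)
    if (length(bad))
      problems <- c(problems, sprintf("%s negative at rows %s", col,
                                      paste(head(bad, 5L), collapse = ", ")))
  }
  if ("stimulus_id" %in% names(table) && nrow(table)) {
    dup <- duplicated(paste(prov, table$stimulus_id))
    if (any(dup))
      problems <- c(problems, sprintf(
        "duplicate stimulus_id within provenance at rows %s",
        paste(head(which(dup), 5L), collapse = ", ")))
  }
  if (length(problems))
    stop("validation error:\n  - ", paste(problems, collapse = "\n  - "),
         call. = FALSE)
  invisible(table)
}

#' Read a feature table from CSV
#'
#' Parses a CSV in the [feature_table] schema, reporting the offending
#' row and column on malformed numeric entries, and validating the
#' schema invariants. Unknown extra columns are preserved.
#'
#' @param path Path to a CSV file.
#' @param validate Run [validate_feature_table()] (default TRUE).
#' @return A data frame in the feature-table schema; a missing
#'   `provenance` column is filled with `"experimental"`.
#' @export
read_feature_table <- function(path, validate = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  table <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  for (col in intersect(ft_numeric_cols, names(table))) {
    v <- table[[col]]
    if (is.numeric(v)) next
    parsed <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(parsed) & !is.na(v) & nzchar(trimws(v)))
    if (length(bad))
      stop(sprintf("parse error in %s: column '%s', row %d: '%s' is not numeric",
                   basename(path), col, bad[1], v[bad[1]]), call. = FALSE)
    table[[col]] <- parsed
  }
  if (!"provenance" %in% names(table))
    table$provenance <- rep("experimental", nrow(table))
  if (validate) validate_feature_table(table)
  table
}

#' Write a feature table to CSV
#'
#' Writes at full double precision so that a read/write cycle is
#' lossless for the printed representation.
#'
#' @param table The feature table data frame.
#' @param path Output path.
#' @param validate Run [validate_feature_table()] first (default TRUE).
#' @return Invisibly, `path`.
#' @export
write_feature_table <- function(table, path, validate = TRUE) {
  if (validate) validate_feature_table(table, require_all = FALSE)
  out <- table
  for (col in names(out))
    if (is.numeric(out[[col]]))
      out[[col]] <- sprintf("%.15g", out[[col]])
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a skin conductance trace file
#'
#' Traces are two-column delimited text: time in seconds and conductance
#' in \eqn{\mu}S, comma or whitespace separated, header line optional.
#'
#' @param path File path.
#' @return For `read_sc_trace`, an [sc_trace()].
#' @export
read_sc_trace <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  fields <- strsplit(trimws(first), if (sep == ",") "," else "[[:space:]]+")[[1]]
  has_header <- anyNA(suppressWarnings(as.numeric(fields)))
  tab <- read.table(path, sep = sep, header = has_header,
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 2L)
    stop("parse error: trace file needs two columns (time_s, conductance_uS)",
         call. = FALSE)
  sc_trace(as.numeric(tab[[1]]), as.numeric(tab[[2]]))
}

#' @rdname read_sc_trace
#' @param trace An [sc_trace()] to write.
#' @export
write_sc_trace <- function(trace, path) {
  stopifnot(inherits(trace, "sc_trace"))
  df <- data.frame(time_s = sprintf("%.15g", trace$times),
                   conductance_uS = sprintf("%.15g", trace$values))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
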