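#' Serialize a polynomial model to delimited text
#'
#' Writes a fitted (or published) model as a self-describing tab-delimited
#' file: comment headers carrying the variable names, order and target,
#' then one row per retained monomial with its exponent tuple,
#' coefficient, standard error and p-value at full double precision
#' (17 significant digits), so that reading the file back reproduces the
#' written decimal representation bit-exactly.
#'
#' @param model An `"hmpm"` model.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @seealso [read_hmpm()], [load_published_model()]
#' @export
write_hmpm <- function(model, path) {
  stopifnot(inherits(model, "hmpm"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    sprintf("# hmpm model serialization v1"),
    sprintf("# variables: %s", paste(model$var_names, collapse = ",")),
    sprintf("# order: %d", model$order),
    sprintf("# target: %s", model$target_label)), con)
  header <- paste(c(paste0("e_", model$var_names),
                    "coefficient", "se", "p_value"), collapse = "\t")
  writeLines(header, con)
  fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))
  for (k in seq_along(model$coefficients)) {
    writeLines(paste(c(model$exponents[k, ],
                       fmt(model$coefficients[k]),
                       fmt(model$se[k]),
                       fmt(model$p_values[k])), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a serialized polynomial model
#'
#' Parses the text format written by [write_hmpm()] and validates it:
#' exponent tuples must be unique non-negative integers with tuple sum at
#' most the declared order.
#'
#' @param path Path to a model file.
#' @return An `"hmpm"` model (without training data; prediction,
#'   gradients and serialization all work).
#' @export
read_hmpm <- function(path) {
  if (!file.exists(path)) stop("no such model file: ", path, call. = FALSE)
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  get_field <- function(key) {
    ln <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (!length(ln)) stop("validation error: missing header '", key, "'",
                          call. = FALSE)
    trimws(sub(paste0("^# ", key, ":"), "", ln[1]))
  }
  var_names <- strsplit(get_field("variables"), ",")[[1]]
  order <- as.integer(get_field("order"))
  target <- get_field("target")
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(body)]
  tab <- read.delim(text = paste(body, collapse = "\n"), sep = "\t",
                    check.names = FALSE)
  m <- length(var_names)
  e_cols <- paste0("e_", var_names)
  if (!all(e_cols %in% names(tab)) ||
      !all(c("coefficient", "se", "p_value") %in% names(tab)))
    stop("validation error: malformed model file columns", call. = FALSE)
  E <- as.matrix(tab[, e_cols, drop = FALSE])
  storage.mode(E) <- "integer"
  colnames(E) <- var_names
  if (anyNA(E) || any(E < 0L))
    stop("validation error: exponents must be non-negative integers",
         call. = FALSE)
  if (anyDuplicated(as.data.frame(E)))
    stop("validation error: duplicate exponent tuple", call. = FALSE)
  if (any(rowSums(E) > order))
    stop("validation error: exponent tuple exceeds declared order",
         call. = FALSE)
  ls_like <- list(coefficients = as.numeric(tab$coefficient),
                  se = as.numeric(tab$se),
                  p_values = as.numeric(tab$p_value),
                  rank = NA_integer_, df = NA_integer_,
                  sigma2 = NA_real_, fitted = numeric(0), sse = NA_real_)
  model <- new_hmpm(ls_like, E, var_names, X = NULL, y = NULL,
                    order = order, config = fit_config(),
                    target_label = if (identical(target, "NA")) NA_character_
                    else target)
  model$fitted.values <- NULL
  model$residuals <- NULL
  model
}

#' Load published model coefficients
#'
#' Reads an externally supplied coefficient file (e.g. coefficients
#' transcribed from a publication's supplementary table) in the
#' [write_hmpm()] serialization and checks it against the expected
#' target. In the affective application the valence and arousal models
#' are polynomials in gain and decay time constant.
#'
#' @param path Path to the coefficient file.
#' @param target_label Expected target (`"valence"`, `"arousal"`, or any
#'   other response name); mismatch with the file header is an error.
#' @return An `"hmpm"` model ready for [predict.hmpm()].
#' @export
load_published_model <- function(path, target_label) {
  model <- read_hmpm(path)
  if (!is.na(model$target_label) && !is.na(target_label) &&
      !identical(model$target_label, target_label))
    stop(sprintf(
      "validation error: file targets '%s' but '%s' was requested",
      model$target_label, target_label), call. = FALSE)
  model$target_label <- target_label
  model
}
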