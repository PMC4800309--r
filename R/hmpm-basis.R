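#' Monomial exponent basis of a multivariable polynomial
#'
#' Enumerates every monomial of an `m`-variable polynomial of total degree
#' at most `p`: all m-tuples of non-negative integer exponents with tuple
#' sum <= p, in graded order (degree 0, 1, ..., p) with the first variable
#' dominant within each degree. The count is `choose(m + p, m)`.
#'
#' @param m Number of input variables (>= 1).
#' @param p Polynomial order (>= 0).
#'
#' @return Integer matrix with `choose(m + p, m)` rows and `m` columns;
#'   each row is one exponent tuple.
#' @export
#' @examples
#' monomial_exponents(2, 1)  # intercept, x1, x2
#' nrow(monomial_exponents(2, 8))  # choose(10, 2) = 45
monomial_exponents <- function(m, p) {
  m <- as.integer(m); p <- as.integer(p)
  if (m < 1L) stop("m must be >= 1", call. = FALSE)
  if (p < 0L) stop("p must be >= 0", call. = FALSE)
  out <- do.call(rbind, lapply(0:p, function(d) degree_compositions(d, m)))
  storage.mode(out) <- "integer"
  out
}

# all m-part compositions of d, first part descending (x1-dominant order)
degree_compositions <- function(d, m) {
  if (m == 1L) return(matrix(d, nrow = 1L))
  do.call(rbind, lapply(seq(d, 0L), function(k) {
    rest <- degree_compositions(d - k, m - 1L)
    cbind(k, rest, deparse.level = 0)
  }))
}

#' Polynomial design matrix
#'
#' Expands an observation matrix into the monomial design matrix: entry
#' (i, k) is the product over variables v of `X[i, v] ^ exponents[k, v]`
#' (with the convention `0^0 = 1` for the intercept and lower-order
#' terms).
#'
#' @param X Numeric matrix (observations x variables) or data frame.
#' @param exponents Integer matrix of exponent tuples, one row per
#'   monomial, `ncol(exponents) == ncol(X)`.
#'
#' @return Numeric matrix, `nrow(X)` rows and `nrow(exponents)` columns.
#' @export
build_design <- function(X, exponents) {
  X <- as.matrix(X)
  if (!is.numeric(X)) stop("invalid-data: X must be numeric", call. = FALSE)
  if (!all(is.finite(X)))
    stop("invalid-data: X contains non-finite entries", call. = FALSE)
  exponents <- as.matrix(exponents)
  if (ncol(X) != ncol(exponents))
    stop("schema error: ncol(X) must equal ncol(exponents)", call. = FALSE)
  n <- nrow(X); K <- nrow(exponents)
  D <- matrix(1, n, K)
  for (k in seq_len(K)) {
    for (v in seq_len(ncol(X))) {
      e <- exponents[k, v]
      if (e != 0L) D[, k] <- D[, k] * X[, v]^e
    }
  }
  D
}

# human-readable monomial labels, e.g. "1", "g", "g^2*t_d"
monomial_labels <- function(exponents, var_names) {
  apply(exponents, 1L, function(e) {
    nz <- which(e > 0L)
    if (!length(nz)) return("1")
    paste(ifelse(e[nz] == 1L, var_names[nz],
                 paste0(var_names[nz], "^", e[nz])), collapse = "*")
  })
}
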