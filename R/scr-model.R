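#' Pure SCR parameter vector
#'
#' Constructs the four-parameter description of a pure skin conductance
#' response (SCR): an amplitude (gain), an onset latency, a sigmoid rise
#' governed by a rise time, and an exponential recovery governed by a decay
#' time constant.
#'
#' @param g Gain (amplitude scale, \eqn{\mu}S); interpreted as neural
#'   activation intensity. Must be >= 0.
#' @param T_os Response onset time (s), the latency after the stimulus.
#'   Must be >= 0.
#' @param t_r Rise time (s), controlling the rising slope pattern. Must be > 0.
#' @param t_d Decay time constant (s), controlling the falling limb. Must be > 0.
#'
#' @return A named numeric vector of class `"scr_params"` with elements
#'   `g`, `T_os`, `t_r`, `t_d`.
#' @seealso [scr_waveform()], [sc_params()]
#' @export
#' @examples
#' scr_params(g = 0.8, T_os = 1.2, t_r = 0.7, t_d = 3.5)
scr_params <- function(g, T_os, t_r, t_d) {
  p <- c(g = as.numeric(g), T_os = as.numeric(T_os),
         t_r = as.numeric(t_r), t_d = as.numeric(t_d))
  validate_scr_params(p)
  structure(p, class = "scr_params")
}

validate_scr_params <- function(p) {
  if (!all(is.finite(p)))
    stop("invalid-parameter: SCR parameters must be finite", call. = FALSE)
  if (p[["g"]] < 0) stop("invalid-parameter: g must be >= 0", call. = FALSE)
  if (p[["T_os"]] < 0) stop("invalid-parameter: T_os must be >= 0", call. = FALSE)
  if (p[["t_r"]] <= 0) stop("invalid-parameter: t_r must be > 0", call. = FALSE)
  if (p[["t_d"]] <= 0) stop("invalid-parameter: t_d must be > 0", call. = FALSE)
  invisible(p)
}

#' Six-parameter event-related skin conductance parameter vector
#'
#' Extends [scr_params()] with the two terms needed to describe a typical
#' event-related skin conductance segment: the decaying tail of a previous
#' response (amplitude `a0` at stimulus onset) and the tonic skin
#' conductance level `c` (SCL). The tail reuses the SCR decay constant
#' `t_d`, keeping the total parameter count at six.
#'
#' @param scr An `"scr_params"` object (or a named numeric vector with
#'   elements `g`, `T_os`, `t_r`, `t_d`).
#' @param a0 Amplitude of the previous-response tail at stimulus onset
#'   (\eqn{\mu}S). Must be >= 0.
#' @param c Tonic skin conductance level, SCL (\eqn{\mu}S). Must be >= 0.
#'
#' @return A named numeric vector of class `"sc_params"` with elements
#'   `g`, `T_os`, `t_r`, `t_d`, `a0`, `c`.
#' @seealso [sc_waveform()], [fit_sc_segment()]
#' @export
sc_params <- function(scr, a0 = 0, c = 0) {
  scr <- scr[c("g", "T_os", "t_r", "t_d")]
  p <- c(unclass(scr), a0 = as.numeric(a0), c = as.numeric(c))
  validate_sc_params(p)
  structure(p, class = "sc_params")
}

validate_sc_params <- function(p) {
  validate_scr_params(p)
  if (!all(is.finite(p)))
    stop("invalid-parameter: SC parameters must be finite", call. = FALSE)
  if (p[["a0"]] < 0) stop("invalid-parameter: a0 must be >= 0", call. = FALSE)
  if (p[["c"]] < 0) stop("invalid-parameter: c must be >= 0", call. = FALSE)
  invisible(p)
}

#' @export
print.scr_params <- function(x, ...) {
  cat("Pure SCR parameters:\n")
  print(round(unclass(x), 6)); invisible(x)
}

#' @export
print.sc_params <- function(x, ...) {
  cat("Event-related SC parameters (6):\n")
  print(round(unclass(x), 6)); invisible(x)
}

#' Uniformly sampled skin conductance segment
#'
#' Carrier for a post-stimulus skin conductance segment: a strictly
#' increasing, uniformly spaced time axis (seconds from stimulus onset) and
#' conductance values in \eqn{\mu}S.
#'
#' @param times Numeric vector of sample times (s), uniformly spaced,
#'   strictly increasing.
#' @param values Numeric vector of conductance values (\eqn{\mu}S), same
#'   length as `times`.
#'
#' @return An object of class `"sc_trace"`: a list with elements `times`,
#'   `values` and `sampling_rate` (Hz; `NA` for a single sample).
#' @export
#' @examples
#' tr <- sc_trace(seq(0, 10, by = 0.1), rep(2, 101))
sc_trace <- function(times, values) {
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) != length(values))
    stop("times and values must have the same length", call. = FALSE)
  if (length(times) == 0L) stop("empty trace", call. = FALSE)
  if (!all(is.finite(times)) || !all(is.finite(values)))
    stop("non-finite entries in trace", call. = FALSE)
  rate <- NA_real_
  if (length(times) > 1L) {
    dt <- diff(times)
    if (any(dt <= 0)) stop("times must be strictly increasing", call. = FALSE)
    if (max(abs(dt - dt[1])) > 1e-9 * abs(dt[1]))
      stop("times must be uniformly spaced", call. = FALSE)
    rate <- 1 / dt[1]
  }
  structure(list(times = times, values = values, sampling_rate = rate),
            class = "sc_trace")
}

#' @export
print.sc_trace <- function(x, ...) {
  cat(sprintf("SC trace: %d samples, %.6g s to %.6g s (%.6g Hz)\n",
              length(x$times), x$times[1], x$times[length(x$times)],
              x$sampling_rate))
  invisible(x)
}

#' @export
length.sc_trace <- function(x) length(x$times)

#' Pure SCR waveform
#'
#' Evaluates the four-parameter sigmoid-exponential model of a single pure
#' skin conductance response:
#' \deqn{f(t) = g \, \frac{\exp\{-(t - T_{os})/t_d\}}{1 + \exp\{-(t - T_{os})/t_r\}}}
#' The sigmoid factor produces the rising limb around the onset latency
#' \eqn{T_{os}} with slope pattern set by \eqn{t_r}; the exponential factor
#' produces the falling limb with decay constant \eqn{t_d}. The waveform is
#' non-negative and decays to zero as \eqn{t \to \infty}.
#'
#' @param params An `"scr_params"` object (or named vector with `g`,
#'   `T_os`, `t_r`, `t_d`).
#' @param times Numeric vector of evaluation times (s).
#'
#' @return Numeric vector of conductance values (\eqn{\mu}S), one per time.
#' @seealso [sc_waveform()]
#' @export
#' @examples
#' t <- seq(0, 10, by = 0.05)
#' f <- scr_waveform(scr_params(0.8, 1.2, 0.7, 3.5), t)
scr_waveform <- function(params, times) {
  p <- as.numeric(params[c("g", "T_os", "t_r", "t_d")])
  names(p) <- c("g", "T_os", "t_r", "t_d")
  validate_scr_params(p)
  times <- as.numeric(times)
  if (!all(is.finite(times))) stop("times must be finite", call. = FALSE)
  u <- times - p[["T_os"]]
  p[["g"]] * exp(-u / p[["t_d"]]) / (1 + exp(-u / p[["t_r"]]))
}

#' Six-parameter event-related skin conductance waveform
#'
#' Evaluates the full event-related model: the pure SCR of
#' [scr_waveform()], plus the exponentially decaying tail of the previous
#' response \eqn{a_0 e^{-t/t_d}} (the segment starts at stimulus onset,
#' \eqn{t = 0}), plus the constant tonic level \eqn{c}:
#' \deqn{s(t) = a_0 e^{-t/t_d} + c + f(t)}
#'
#' @param params An `"sc_params"` object (or named vector with `g`,
#'   `T_os`, `t_r`, `t_d`, `a0`, `c`).
#' @param times Numeric vector of evaluation times (s), measured from
#'   stimulus onset.
#'
#' @return Numeric vector of conductance values (\eqn{\mu}S).
#' @export
sc_waveform <- function(params, times) {
  p <- as.numeric(params[c("g", "T_os", "t_r", "t_d", "a0", "c")])
  names(p) <- c("g", "T_os", "t_r", "t_d", "a0", "c")
  validate_sc_params(p)
  times <- as.numeric(times)
  if (!all(is.finite(times))) stop("times must be finite", call. = FALSE)
  p[["a0"]] * exp(-times / p[["t_d"]]) + p[["c"]] +
    scr_waveform(p[c("g", "T_os", "t_r", "t_d")], times)
}

#' Average skin conductance segments across subjects
#'
#' Pointwise mean of a list of segments sharing the same time axis, the
#' standard across-subject averaging applied to post-stimulus segments
#' before curve fitting.
#'
#' @param traces A non-empty list of [sc_trace()] objects with identical
#'   lengths and sampling rates.
#'
#' @return An `"sc_trace"` whose values are the pointwise means; the time
#'   axis of the first trace is retained.
#' @export
average_segments <- function(traces) {
  if (!is.list(traces) || length(traces) == 0L)
    stop("empty-input: need at least one trace", call. = FALSE)
  if (!all(vapply(traces, inherits, logical(1), "sc_trace")))
    stop("all elements must be sc_trace objects", call. = FALSE)
  n <- vapply(traces, function(x) length(x$times), integer(1))
  if (length(unique(n)) != 1L)
    stop("incompatible-traces: lengths differ", call. = FALSE)
  rates <- vapply(traces, function(x) x$sampling_rate, numeric(1))
  if (length(n) > 0 && n[1] > 1L &&
      max(abs(rates - rates[1])) > 1e-9 * abs(rates[1]))
    stop("incompatible-traces: sampling rates differ", call. = FALSE)
  vals <- rowMeans(vapply(traces, function(x) x$values, numeric(n[1])))
  sc_trace(traces[[1]]$times, vals)
}

#' Heuristic starting point for the six-parameter fit
#'
#' Derives a rough parameter vector from the segment itself. The tonic
#' level comes from the trace minimum and the previous-response tail from
#' the value at onset. Because a strong decaying tail can make the whole
#' segment monotone (hiding the SCR rise from a raw slope search), the
#' implied tail `a0 * exp(-t / 3) + c` is subtracted first; the gain is
#' the maximum of that detrended residual and the onset latency the time
#' of its steepest rise. Rise and decay constants start at field-typical
#' 0.5 s and 3 s. Never fails; degenerate (flat or single-sample) traces
#' fall back to small positive floors where positivity is required.
#'
#' @param trace An [sc_trace()].
#' @return An `"sc_params"` starting vector inside the feasible region.
#' @seealso [fit_sc_segment()]
#' @export
initial_guess <- function(trace) {
  stopifnot(inherits(trace, "sc_trace"))
  v <- trace$values; tt <- trace$times
  cc <- min(v)
  a0 <- max(v[1] - cc, 0)
  if (length(v) > 1L) {
    resid_detrended <- v - (cc + a0 * exp(-tt / 3))
    g <- max(max(resid_detrended), 0)
    slope <- diff(resid_detrended) / diff(tt)
    T_os <- max(tt[which.max(slope)] - tt[1], 0)
  } else {
    g <- 0; T_os <- 0
  }
  sc_params(scr_params(g = g, T_os = T_os, t_r = 0.5, t_d = 3),
            a0 = a0, c = cc)
}

#' Fit the six-parameter model to a skin conductance segment
#'
#' Separates an event-related segment into a pure SCR, the decaying tail
#' of the previous response and the tonic level by bound-constrained
#' Marquardt-Levenberg nonlinear least squares (via
#' [minpack.lm::nls.lm()]). Convergence is declared when the relative
#' change in the residual sum of squares falls below `tol`. Parameters
#' are box-constrained to their physiologically meaningful ranges
#' (non-negative amplitudes and latency; onset within the segment; rise
#' time at most 10 s and decay constant at most 20 s).
#'
#' The SSE surface has local minima in which the SCR escapes past the end
#' of the segment and the tail absorbs the signal; with `restarts = TRUE`
#' (the default) the optimizer is additionally started from a small fixed
#' grid of alternative onset latencies and decay constants and the
#' lowest-SSE solution is kept, so the returned SSE is never above that
#' of a fit started at `init` alone.
#'
#' @param trace An [sc_trace()] with at least 7 samples (more points than
#'   parameters).
#' @param init Starting `"sc_params"`; defaults to [initial_guess()].
#' @param max_iterations Maximum number of Marquardt-Levenberg iterations
#'   per start (default 20).
#' @param tol Relative SSE convergence tolerance (default `1e-8`).
#' @param restarts Also try the deterministic alternative starts
#'   (default `TRUE`).
#'
#' @return An object of class `"sc_fit"`: a list with `params`
#'   (`"sc_params"`), `sse` (residual sum of squares, \eqn{\mu S^2}),
#'   `iterations` (of the winning start), `converged`, `fitted`,
#'   `trace`, and the optimizer `message`.
#' @export
#' @examples
#' truth <- sc_params(scr_params(0.8, 1.2, 0.7, 3.5), a0 = 0.3, c = 2)
#' tr <- sc_trace(seq(0, 10, by = 0.1), sc_waveform(truth, seq(0, 10, by = 0.1)))
#' fit <- fit_sc_segment(tr, max_iterations = 100)
fit_sc_segment <- function(trace, init = initial_guess(trace),
                           max_iterations = 20, tol = 1e-8,
                           restarts = TRUE) {
  stopifnot(inherits(trace, "sc_trace"))
  if (length(trace$values) < 7L)
    stop("underdetermined-fit: need at least 7 samples for 6 parameters",
         call. = FALSE)
  if (max_iterations < 1) stop("max_iterations must be >= 1", call. = FALSE)
  p0 <- as.numeric(init[c("g", "T_os", "t_r", "t_d", "a0", "c")])
  names(p0) <- c("g", "T_os", "t_r", "t_d", "a0", "c")
  floor_pos <- 1e-3  # keeps t_r, t_d strictly positive during the search
  lower <- c(g = 0, T_os = 0, t_r = floor_pos, t_d = floor_pos, a0 = 0, c = 0)
  upper <- c(g = Inf, T_os = max(trace$times), t_r = 10, t_d = 20,
             a0 = Inf, c = Inf)
  one_fit <- function(start) {
    start <- pmin(pmax(start, lower), upper)
    resid_fun <- function(par) {
      par <- pmax(par, lower)
      trace$values - sc_waveform(par, trace$times)
    }
    res <- suppressWarnings(minpack.lm::nls.lm(
      par = start, lower = lower, upper = upper, fn = resid_fun,
      control = minpack.lm::nls.lm.control(
        maxiter = as.integer(max_iterations), ftol = tol, maxfev = 10000L)))
    list(par = pmax(res$par, lower), sse = res$deviance,
         niter = res$niter, info = res$info, message = res$message)
  }
  best <- one_fit(p0)
  if (isTRUE(restarts)) {
    span <- diff(range(trace$times))
    for (T_alt in trace$times[1] + span * c(0.1, 0.2, 0.3)) {
      for (td_alt in c(1.5, 6)) {
        start <- p0
        start[["T_os"]] <- T_alt
        start[["t_d"]] <- td_alt
        cand <- one_fit(start)
        if (cand$sse < best$sse) best <- cand
      }
    }
  }
  par <- best$par
  fitted_vals <- sc_waveform(par, trace$times)
  structure(list(
    params = sc_params(scr_params(par[["g"]], par[["T_os"]], par[["t_r"]],
                                  par[["t_d"]]),
                       a0 = par[["a0"]], c = par[["c"]]),
    sse = sum((trace$values - fitted_vals)^2),
    iterations = best$niter,
    converged = best$info %in% 1:4,
    fitted = fitted_vals,
    trace = trace,
    message = best$message), class = "sc_fit")
}

#' @export
print.sc_fit <- function(x, ...) {
  cat(sprintf("Six-parameter SC fit: SSE = %.6g, %d iterations, %s\n",
              x$sse, x$iterations,
              if (x$converged) "converged" else "not converged"))
  print(x$params)
  invisible(x)
}

#' @export
coef.sc_fit <- function(object, ...) unclass(object$params)

#' @export
fitted.sc_fit <- function(object, ...) object$fitted

#' @export
residuals.sc_fit <- function(object, ...) object$trace$values - object$fitted
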