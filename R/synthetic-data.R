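#' Synthetic affective experiment configuration
#'
#' Describes the synthetic three-class picture-viewing experiment the
#' generator emulates: per-class SCR parameter distributions, a known
#' polynomial ground-truth mapping from (gain, decay time constant) to
#' valence and arousal on the 1-9 SAM scale, and trace-level settings
#' (previous-response tail, tonic level, sampling, noise).
#'
#' The default class centres place pleasant stimuli at high gain with a
#' slow decay, neutral at low gain, and unpleasant at the highest gain
#' with a fast decay, so that pure SCR waveforms cluster by class. The
#' ground-truth coefficients are solved from the class-centre rating
#' targets (valence about 7 / 5 / 2.5 and arousal about 5.5 / 3 / 6 for
#' pleasant / neutral / unpleasant): arousal is affine and gain-dominated;
#' valence depends on both inputs and, when `valence_interaction` is
#' non-zero, carries a gain-by-decay interaction making the surface
#' genuinely nonlinear. These are synthetic study conditions, not
#' published coefficients.
#'
#' @param seed Integer seed controlling every draw.
#' @param n_per_class Stimuli per affect class (default 8).
#' @param classes Class labels (default pleasant, neutral, unpleasant).
#' @param rating_noise_sd SD of rating noise on the 1-9 scale
#'   (default 0.3).
#' @param trace_noise_sd SD of additive Gaussian trace noise in
#'   \eqn{\mu}S (default 0.01).
#' @param sampling_rate Trace sampling rate in Hz (default 32, a typical
#'   electrodermal analysis rate).
#' @param segment_length Post-stimulus segment length in s (default 10).
#' @param valence_interaction Coefficient of the `gain *
#'   decay_time_constant` term in the valence ground truth (default 0.5;
#'   set 0 for an affine ground truth).
#'
#' @return A list of class `"affect_generator_config"` with the fields
#'   above plus `param_means`, `param_sds` (per-class rows, columns
#'   `onset_time`, `gain`, `rise_time`, `decay_time_constant`), `truth`
#'   (exponent/coefficient lists for valence and arousal over
#'   `(gain, decay_time_constant)`), `a0_range` and `scl_range`.
#' @export
default_affective_config <- function(seed = 1L, n_per_class = 8L,
                                     classes = c("pleasant", "neutral",
                                                 "unpleasant"),
                                     rating_noise_sd = 0.3,
                                     trace_noise_sd = 0.01,
                                     sampling_rate = 32,
                                     segment_length = 10,
                                     valence_interaction = 0.5) {
  if (length(classes) != 3L)
    stop("the default config defines exactly three classes", call. = FALSE)
  if (rating_noise_sd < 0 || trace_noise_sd < 0)
    stop("noise SDs must be >= 0", call. = FALSE)
  param_means <- data.frame(
    onset_time = c(1.5, 1.8, 1.2),
    gain = c(0.70, 0.25, 0.95),
    rise_time = c(0.8, 1.0, 0.7),
    decay_time_constant = c(5.5, 3.0, 2.0),
    row.names = c("pleasant", "neutral", "unpleasant"))
  param_sds <- data.frame(
    onset_time = c(0.15, 0.15, 0.15),
    gain = c(0.06, 0.05, 0.07),
    rise_time = c(0.10, 0.10, 0.10),
    decay_time_constant = c(0.50, 0.40, 0.30),
    row.names = rownames(param_means))
  if (!all(classes %in% rownames(param_means)))
    stop("default parameter centres exist only for pleasant/neutral/unpleasant;",
         " supply a full custom config for other classes", call. = FALSE)
  param_means <- param_means[classes, , drop = FALSE]
  param_sds <- param_sds[classes, , drop = FALSE]

  # ground truth solved so class-centre (g, t_d) map to the rating targets
  centres <- as.matrix(param_means[, c("gain", "decay_time_constant")])
  v_target <- c(pleasant = 7.0, neutral = 5.0, unpleasant = 2.5)[classes]
  a_target <- c(pleasant = 5.5, neutral = 3.0, unpleasant = 6.0)[classes]
  A3 <- cbind(1, centres[seq_len(3), 1L], centres[seq_len(3), 2L])
  a_coef <- solve(A3, a_target[seq_len(3)])
  v_rhs <- v_target[seq_len(3)] -
    valence_interaction * centres[seq_len(3), 1L] * centres[seq_len(3), 2L]
  v_coef <- solve(A3, v_rhs)
  v_expo <- rbind(c(0L, 0L), c(1L, 0L), c(0L, 1L))
  v_beta <- v_coef
  if (valence_interaction != 0) {
    v_expo <- rbind(v_expo, c(1L, 1L))
    v_beta <- c(v_coef, valence_interaction)
  }
  colnames(v_expo) <- c("gain", "decay_time_constant")
  a_expo <- rbind(c(0L, 0L), c(1L, 0L), c(0L, 1L))
  colnames(a_expo) <- colnames(v_expo)
  truth <- list(
    valence = list(exponents = v_expo, coefficients = unname(v_beta)),
    arousal = list(exponents = a_expo, coefficients = unname(a_coef)))

  structure(list(seed = as.integer(seed), n_per_class = as.integer(n_per_class),
                 classes = classes, param_means = param_means,
                 param_sds = param_sds, truth = truth,
                 rating_noise_sd = rating_noise_sd,
                 trace_noise_sd = trace_noise_sd,
                 sampling_rate = sampling_rate,
                 segment_length = segment_length,
                 a0_range = c(0.1, 0.6), scl_range = c(2, 4)),
            class = "affect_generator_config")
}

#' @export
print.affect_generator_config <- function(x, ...) {
  cat(sprintf(
    "Affective generator: %d classes x %d stimuli, seed %d\n",
    length(x$classes), x$n_per_class, x$seed))
  cat("Class centres (gain, decay_time_constant):\n")
  print(x$param_means[, c("gain", "decay_time_constant")])
  invisible(x)
}

# truncated-normal draw by reject-and-redraw below `lower`
rtruncnorm_pos <- function(n, mean, sd, lower = 1e-6) {
  out <- rnorm(n, mean, sd)
  while (any(bad <- out <= lower)) out[bad] <- rnorm(sum(bad), mean, sd)
  out
}

eval_truth <- function(truth_component, g, t_d) {
  X <- cbind(gain = g, decay_time_constant = t_d)
  drop(build_design(X, truth_component$exponents) %*%
         truth_component$coefficients)
}

#' Generate a synthetic per-stimulus feature table
#'
#' Draws per-class SCR parameters from truncated normal distributions
#' (reject-and-redraw at zero, preserving positivity) and produces
#' valence and arousal ratings from the configured ground-truth
#' polynomial of (gain, decay time constant) plus Gaussian noise, clipped
#' to the 1-9 SAM scale. Deterministic under the config seed.
#'
#' @param config An [default_affective_config()] (or compatible) object.
#'
#' @return A feature table data frame with columns `stimulus_id`,
#'   `affect_class`, `onset_time`, `gain`, `rise_time`,
#'   `decay_time_constant`, `valence`, `arousal`, `provenance`
#'   (= `"synthetic"`).
#' @export
#' @examples
#' tab <- generate_feature_table(default_affective_config(seed = 1))
generate_feature_table <- function(config) {
  stopifnot(inherits(config, "affect_generator_config"))
  set.seed(config$seed)
  n <- config$n_per_class
  rows <- lapply(config$classes, function(cls) {
    mu <- config$param_means[cls, ]; sdv <- config$param_sds[cls, ]
    if (n == 0L) return(NULL)
    g <- rtruncnorm_pos(n, mu$gain, sdv$gain)
    t_d <- rtruncnorm_pos(n, mu$decay_time_constant, sdv$decay_time_constant)
    data.frame(
      stimulus_id = sprintf("%s_%02d", cls, seq_len(n)),
      affect_class = cls,
      onset_time = rtruncnorm_pos(n, mu$onset_time, sdv$onset_time, 0),
      gain = g,
      rise_time = rtruncnorm_pos(n, mu$rise_time, sdv$rise_time),
      decay_time_constant = t_d,
      valence = clip19(eval_truth(config$truth$valence, g, t_d) +
                         rnorm(n, 0, config$rating_noise_sd)),
      arousal = clip19(eval_truth(config$truth$arousal, g, t_d) +
                         rnorm(n, 0, config$rating_noise_sd)),
      provenance = "synthetic")
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(stimulus_id = character(0), affect_class = character(0),
                      onset_time = numeric(0), gain = numeric(0),
                      rise_time = numeric(0),
                      decay_time_constant = numeric(0),
                      valence = numeric(0), arousal = numeric(0),
                      provenance = character(0))
  rownames(out) <- NULL
  out
}

clip19 <- function(x) pmin(pmax(x, 1), 9)

#' Generate synthetic event-related skin conductance traces
#'
#' Produces post-stimulus segments from the six-parameter model — a pure
#' SCR superposed on the decaying tail of a previous response and a tonic
#' level — with additive Gaussian noise, returning the generating truth
#' alongside each trace for parameter-recovery studies.
#'
#' @param config An [default_affective_config()] (or compatible) object.
#' @param n Number of traces; default one per stimulus
#'   (`n_per_class * number of classes`), cycling through the classes.
#'
#' @return A list of length `n`; each element is a list with `trace`
#'   (an [sc_trace()]) and `truth` (the generating `"sc_params"`).
#' @export
generate_sc_traces <- function(config, n = NULL) {
  stopifnot(inherits(config, "affect_generator_config"))
  set.seed(config$seed + 1L)  # independent stream from the feature table
  if (is.null(n)) n <- config$n_per_class * length(config$classes)
  n <- as.integer(n)
  times <- seq(0, by = 1 / config$sampling_rate,
               length.out = round(config$segment_length * config$sampling_rate))
  cls_cycle <- rep_len(config$classes, n)
  lapply(seq_len(n), function(i) {
    cls <- cls_cycle[i]
    mu <- config$param_means[cls, ]; sdv <- config$param_sds[cls, ]
    truth <- sc_params(
      scr_params(g = rtruncnorm_pos(1, mu$gain, sdv$gain),
                 T_os = rtruncnorm_pos(1, mu$onset_time, sdv$onset_time, 0),
                 t_r = rtruncnorm_pos(1, mu$rise_time, sdv$rise_time),
                 t_d = rtruncnorm_pos(1, mu$decay_time_constant,
                                      sdv$decay_time_constant)),
      a0 = runif(1, config$a0_range[1], config$a0_range[2]),
      c = runif(1, config$scl_range[1], config$scl_range[2]))
    values <- sc_waveform(truth, times) +
      rnorm(length(times), 0, config$trace_noise_sd)
    list(trace = sc_trace(times, values), truth = truth,
         affect_class = cls)
  })
}
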