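#' Pipeline configuration
#'
#' Bundles everything a full estimation run needs: the input table (a
#' path or a data frame; absent, the synthetic generator supplies one),
#' the candidate polynomial orders, the input-variable subset, the
#' fitting configuration and the seed. Two variable presets mirror the
#' two-stage narrowing of the workflow: the three-input stage
#' (`onset_time`, `gain`, `decay_time_constant`) and the final two-input
#' stage (`gain`, `decay_time_constant`); the choice between them is
#' deliberately the user's, not automated.
#'
#' @param input Path to a feature-table CSV, or a feature table data
#'   frame, or `NULL` to generate one from `generator`.
#' @param output_dir Directory for run artifacts.
#' @param orders Integer vector of candidate polynomial orders.
#' @param variables Input-variable subset; one of the two presets above
#'   or any non-empty subset of the numeric feature columns.
#' @param fit A [fit_config()].
#' @param generator An [default_affective_config()] used when `input` is
#'   `NULL`.
#' @param seed Integer seed for any randomness in the run.
#'
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(input = NULL, output_dir = tempfile("hmpr_run_"),
                            orders = 1:9,
                            variables = c("gain", "decay_time_constant"),
                            fit = fit_config(), generator = NULL,
                            seed = 1L) {
  if (length(variables) == 0L)
    stop("variables must be non-empty", call. = FALSE)
  if (!all(variables %in% ft_numeric_cols))
    stop("variables must be feature columns: ",
         paste(setdiff(variables, ft_numeric_cols), collapse = ", "),
         call. = FALSE)
  if (is.null(generator)) generator <- default_affective_config(seed = seed)
  structure(list(input = input, output_dir = output_dir,
                 orders = as.integer(orders), variables = variables,
                 fit = fit, generator = generator, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognised keys mirror the [pipeline_config()] arguments
#' (`input`, `output_dir`, `orders`, `variables`, `seed`) plus the flat
#' [fit_config()] keys (`singular_criterion`, `significance_level`,
#' `scale_inputs`) and generator keys (`n_per_class`, `rating_noise_sd`,
#' `trace_noise_sd`, `valence_interaction`).
#'
#' @param path Path to a YAML file.
#' @return A `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  seed <- if (!is.null(raw$seed)) as.integer(raw$seed) else 1L
  fit <- fit_config(
    singular_criterion = raw$singular_criterion %||% 1e-8,
    significance_level = raw$significance_level %||% 1e-4,
    scale_inputs = isTRUE(raw$scale_inputs))
  gen <- default_affective_config(
    seed = seed,
    n_per_class = raw$n_per_class %||% 8L,
    rating_noise_sd = raw$rating_noise_sd %||% 0.3,
    trace_noise_sd = raw$trace_noise_sd %||% 0.01,
    valence_interaction = raw$valence_interaction %||% 0.5)
  pipeline_config(
    input = raw$input,
    output_dir = raw$output_dir %||% tempfile("hmpr_run_"),
    orders = if (!is.null(raw$orders)) as.integer(unlist(raw$orders)) else 1:9,
    variables = raw$variables %||% c("gain", "decay_time_constant"),
    fit = fit, generator = gen, seed = seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full estimation pipeline
#'
#' Orchestrates the end-to-end workflow: load (or synthesise) the
#' per-stimulus feature table; screen the SCR feature columns by one-way
#' ANOVA across affect classes (reported, never used to drop variables
#' automatically); statistically extend the table within each class;
#' sweep polynomial orders for valence and for arousal, training each
#' model on the extended rows and scoring its Index on the experimental
#' rows; evaluate the selected models on the full experimental table;
#' and export gradient fields of both fitted surfaces over the observed
#' bounding box of the first two input variables.
#'
#' Artifacts written to `config$output_dir`: `screening.csv`,
#' `extended_table.csv`, `order_reports_<target>.csv`,
#' `model_<target>.tsv`, `evaluation.csv`,
#' `gradient_field_<target>.csv`, `manifest.json` and `run.log`. Reruns
#' with an identical manifest produce identical numeric outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the table, the extended table, the
#'   screening data frame, the per-target selection results, the
#'   evaluation reports and the output directory.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$output_dir, "run.log")
  logf <- function(fmt, ...) {
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%H:%M:%S"),
                sprintf(fmt, ...)), file = log_path, append = TRUE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      logf("stage %s FAILED: %s", name, conditionMessage(e))
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  set.seed(config$seed)

  table <- stage("input", {
    if (is.null(config$input)) {
      logf("generating synthetic table (seed %d)", config$generator$seed)
      generate_feature_table(config$generator)
    } else if (is.character(config$input)) {
      logf("reading %s", config$input)
      read_feature_table(config$input)
    } else {
      validate_feature_table(config$input)
    }
  })
  experimental <- table[table$provenance != "simulated", , drop = FALSE]
  logf("input: %d rows (%d experimental)", nrow(table), nrow(experimental))

  screening <- stage("screening", {
    cols <- intersect(c("onset_time", "gain", "rise_time",
                        "decay_time_constant"), names(experimental))
    res <- lapply(cols, function(col) {
      a <- one_way_anova(experimental[[col]], experimental$affect_class)
      data.frame(column = col, F = a$F, df_between = a$df_between,
                 df_within = a$df_within, p_value = a$p_value)
    })
    do.call(rbind, res)
  })
  write.csv(screening, file.path(config$output_dir, "screening.csv"),
            row.names = FALSE)

  extended <- stage("extend", extend_table(experimental))
  write_feature_table(extended,
                      file.path(config$output_dir, "extended_table.csv"))
  logf("extended: %d simulated rows", nrow(extended))

  X_train <- as.matrix(extended[, config$variables, drop = FALSE])
  X_eval <- as.matrix(experimental[, config$variables, drop = FALSE])
  selections <- list()
  evaluations <- list()
  for (target in c("valence", "arousal")) {
    sel <- stage(paste0("sweep_", target),
                 select_order(X_train, extended[[target]], config$orders,
                              config$fit, X_eval, experimental[[target]],
                              target_label = target))
    selections[[target]] <- sel
    write.csv(sel$reports,
              file.path(config$output_dir,
                        sprintf("order_reports_%s.csv", target)),
              row.names = FALSE)
    write_hmpm(sel$best,
               file.path(config$output_dir, sprintf("model_%s.tsv", target)))
    evaluations[[target]] <- stage(paste0("evaluate_", target),
                                   evaluate(sel$best, experimental))
    logf("%s: selected order %d, r = %.4f, MSE = %.4f, Index = %.4f",
         target, sel$best_order, evaluations[[target]]$r,
         evaluations[[target]]$mse, evaluations[[target]]$index)
  }
  eval_df <- do.call(rbind, lapply(evaluations, as.data.frame))
  rownames(eval_df) <- NULL
  write.csv(eval_df, file.path(config$output_dir, "evaluation.csv"),
            row.names = FALSE)

  if (length(config$variables) >= 2L) {
    stage("gradient_fields", {
      v2 <- config$variables[1:2]
      lower <- apply(experimental[, v2, drop = FALSE], 2, min)
      upper <- apply(experimental[, v2, drop = FALSE], 2, max)
      for (target in c("valence", "arousal")) {
        model <- selections[[target]]$best
        gf_model <- if (length(config$variables) == 2L) model else NULL
        if (is.null(gf_model)) next  # fields only defined for 2-input models
        gf <- gradient_field(gf_model, lower, upper, n = 15L)
        write.csv(gf, file.path(config$output_dir,
                                sprintf("gradient_field_%s.csv", target)),
                  row.names = FALSE)
      }
    })
  }

  manifest <- list(
    package = "hmpr",
    version = as.character(packageVersion("hmpr")),
    seed = config$seed,
    variables = config$variables,
    orders = config$orders,
    fit = config$fit[c("singular_criterion", "significance_level",
                       "scale_inputs")],
    rows = list(input = nrow(table), experimental = nrow(experimental),
                simulated = nrow(extended)),
    selected_orders = lapply(selections, `[[`, "best_order"))
  jsonlite::write_json(manifest,
                       file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  logf("done")
  invisible(list(table = table, experimental = experimental,
                 extended = extended, screening = screening,
                 selections = selections, evaluations = evaluations,
                 output_dir = config$output_dir))
}
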