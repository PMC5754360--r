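# Configuration-driven pipeline tying the stages together: deterministic
# tradeoff sweeps, stochastic simulation, synthetic observation tables,
# quantification, and the end-to-end quantity-vs-quality experiment
# emulating a KinA/RapA-style induction series. All stage seeds derive from
# one master seed; every output directory receives the resolved
# configuration so a run can be reproduced bit-identically.

#' Pipeline configuration
#'
#' @param model A [model_params()] object (the wild-type / base strain).
#' @param generator A [generator_config()] object.
#' @param sweep_param Parameter swept to emulate induction levels
#'   (`"delta"`, `"eta"`, `"lambda"` or `"mu"`).
#' @param sweep_values Numeric vector of swept values ("induction levels").
#'   Values are abstract rates; experimental inducer concentrations have no
#'   stated quantitative map to them.
#' @param wt_value Sweep value used as the wild-type reference for
#'   normalization; defaults to the base model's value of `sweep_param` if
#'   present among `sweep_values`, else the first value.
#' @param founders_per_level Founder cells simulated per induction level in
#'   the in-silico experiment.
#' @param seed Master seed; all stage seeds derive from it.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(model = model_params(0.5, 1, 1, 0.5),
                            generator = generator_config(),
                            sweep_param = "delta",
                            sweep_values = c(0.5, 1, 1.5, 2, 3),
                            wt_value = NULL,
                            founders_per_level = 5000,
                            seed = 1) {
  stopifnot(inherits(model, "model_params"),
            inherits(generator, "generator_config"))
  sweep_param <- match.arg(sweep_param, c("delta", "eta", "lambda", "mu"))
  if (is.null(wt_value)) {
    base <- model[[sweep_param]]
    wt_value <- if (any(sweep_values == base)) base else sweep_values[1]
  }
  if (!any(sweep_values == wt_value)) {
    stop("wt_value must be one of sweep_values", call. = FALSE)
  }
  structure(list(model = model, generator = generator,
                 sweep_param = sweep_param, sweep_values = sweep_values,
                 wt_value = wt_value,
                 founders_per_level = as.integer(founders_per_level),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Expects top-level keys `model` (with `lambda`, `eta`, `mu`, `delta`,
#' optional `k`, `variant`), optional `generator` (arguments of
#' [generator_config()]), and optional `sweep_param`, `sweep_values`,
#' `wt_value`, `founders_per_level`, `seed`.
#'
#' @param path Path to the config file.
#' @return A [pipeline_config()] object.
#' @export
read_pipeline_config <- function(path) {
  cfg <- read_config_file(path)
  if (is.null(cfg$model)) stop("config needs a 'model' block", call. = FALSE)
  m <- cfg$model
  model <- model_params(m$lambda, m$eta, m$mu, m$delta,
                        k = m$k %||% 2, variant = m$variant %||% "depleting")
  gen <- do.call(generator_config, cfg$generator %||% list())
  args <- list(model = model, generator = gen)
  for (key in c("sweep_param", "sweep_values", "wt_value",
                "founders_per_level", "seed")) {
    if (!is.null(cfg[[key]])) args[[key]] <- cfg[[key]]
  }
  do.call(pipeline_config, args)
}

resolved_config <- function(config) {
  list(model = unclass(config$model),
       generator = unclass(config$generator),
       sweep_param = config$sweep_param,
       sweep_values = config$sweep_values,
       wt_value = config$wt_value,
       founders_per_level = config$founders_per_level,
       seed = config$seed)
}

write_provenance <- function(config, output_dir, stage) {
  prov <- list(stage = stage,
               package = "sporememory",
               version = as.character(utils::packageVersion("sporememory")),
               seed = config$seed,
               config = resolved_config(config))
  jsonlite::write_json(prov, file.path(output_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Run the deterministic model sweep and write its outputs
#'
#' Delegates to [sweep_tradeoff()] over `sweep_param`/`sweep_values` and
#' writes `sweep.csv` (columns `param_name`, `param_value`, `yield_s`,
#' `quality_ebar`, `variant`) plus `provenance.json` with the resolved
#' configuration.
#'
#' @param config A [pipeline_config()].
#' @param output_dir Output directory (created if needed); `NULL` skips
#'   writing.
#' @return The `sweep_result` tibble, invisibly when writing.
#' @export
run_model_sweep <- function(config, output_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  res <- sweep_tradeoff(config$model, config$sweep_param,
                        config$sweep_values)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(res, file.path(output_dir, "sweep.csv"))
    write_provenance(config, output_dir, "model_sweep")
    return(invisible(res))
  }
  res
}

#' Run the end-to-end in-silico quantity-vs-quality experiment
#'
#' For each sweep value ("induction level"): simulate lineages with the
#' stochastic simulator, generate per-spore observations mechanistically,
#' quantify yield `Y` (spores per founder cell), quality `Q` (mean Ald
#' reporter fluorescence) and revival frequency `f_r`, then normalize all
#' three to the wild-type level. The analogue of an induction-series
#' experiment: under the depleting variant, relative yield and relative
#' quality are strongly anti-correlated.
#'
#' @inheritParams run_model_sweep
#' @return A tibble with one row per level: `level`, `param_value`,
#'   `n_founders`, `N_s`, `Y`, `Q`, `f_r`, `Y_rel`, `Q_rel`, `f_r_rel`,
#'   `is_wt`; written to `experiment.csv` when `output_dir` is given.
#' @export
run_insilico_experiment <- function(config, output_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  rows <- purrr::imap(config$sweep_values, function(v, i) {
    p <- config$model
    p[[config$sweep_param]] <- v
    p <- model_params(p$lambda, p$eta, p$mu, p$delta, p$k, p$variant)
    if (!params_converge(p)) {
      stop("in-silico experiment stage 'simulate' failed at ",
           config$sweep_param, " = ", v, ": divergent parameters",
           call. = FALSE)
    }
    gen <- config$generator
    gen$mode <- "mechanistic"
    gen$n_colonies <- 1L
    gen$founders_per_colony <- config$founders_per_level
    gen$seed <- derive_seed(config$seed, 100 + i)
    records <- generate_spore_table(gen, model_params = p)
    summ <- revival_frequencies(records)
    yq <- yield_and_quality(records, colony_area = config$founders_per_level)
    tibble::tibble(level = paste0("L", i), param_value = v,
                   n_founders = config$founders_per_level,
                   N_s = yq$N_s, Y = yq$Y, Q = yq$Q, f_r = summ$f_r)
  })
  out <- dplyr::bind_rows(rows)
  wt <- out[out$param_value == config$wt_value, ][1, ]
  out$Y_rel <- normalize_to_wt(out$Y, wt$Y)
  out$Q_rel <- normalize_to_wt(out$Q, wt$Q)
  out$f_r_rel <- if (wt$f_r > 0) normalize_to_wt(out$f_r, wt$f_r)
                 else NA_real_
  out$is_wt <- out$param_value == config$wt_value
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(out, file.path(output_dir, "experiment.csv"))
    write_provenance(config, output_dir, "insilico_experiment")
    return(invisible(out))
  }
  out
}

#' Quantify and compare spore revival from an observation table
#'
#' Reads (or takes) a spore table, classifies spores early/late, computes
#' per-group and per-colony revival frequencies, the cumulative germination
#' curves and half-times, and the Welch t test comparing per-colony revival
#' frequencies between groups. Deterministic given its inputs.
#'
#' @param records A spore-record tibble or a path to a spore-table CSV.
#' @param classify `"time"` (threshold on `t_spor_h`) or `"fluorescence"`
#'   (median split on `fluor_rapa`).
#' @param threshold Early/late time threshold, hours.
#' @param frame_interval,window Acquisition parameters for the germination
#'   curve grid.
#' @param output_dir Optional directory: writes `group_summary.csv`,
#'   `colony_summary.csv`, `germination_curve.csv` and `comparison.json`.
#' @return A list with `group_summary`, `colony_summary`, `curve`,
#'   `half_times`, `f_r_test` (class `revival_report`).
#' @export
run_revival_report <- function(records, classify = c("time", "fluorescence"),
                               threshold = 20, frame_interval = 1 / 3,
                               window = 12, output_dir = NULL) {
  classify <- match.arg(classify)
  if (is.character(records) && length(records) == 1) {
    records <- read_spore_table(records)
  }
  validate_spore_table(records)
  records <- if (classify == "time") {
    classify_by_time(records, threshold)
  } else {
    classify_by_fluorescence(records, method = "median")
  }
  n_by_group <- table(records$group)
  if (any(n_by_group == 0)) {
    stop("empty group after classification: ",
         paste(names(n_by_group)[n_by_group == 0], collapse = ", "),
         call. = FALSE)
  }
  group_summary <- revival_frequencies(records)
  colony_summary <- revival_frequencies(records, per_colony = TRUE)
  curve <- germination_curve(records, frame_interval = frame_interval,
                             window = window)
  half_times <- germination_half_time(curve)
  fr_early <- colony_summary$f_r[colony_summary$group == "early"]
  fr_late <- colony_summary$f_r[colony_summary$group == "late"]
  f_r_test <- unpaired_t_test(fr_early, fr_late)
  out <- structure(
    list(group_summary = group_summary, colony_summary = colony_summary,
         curve = curve, half_times = half_times, f_r_test = f_r_test),
    class = "revival_report")
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(group_summary,
                     file.path(output_dir, "group_summary.csv"))
    readr::write_csv(colony_summary,
                     file.path(output_dir, "colony_summary.csv"))
    readr::write_csv(curve, file.path(output_dir, "germination_curve.csv"))
    jsonlite::write_json(
      list(test = f_r_test$method, t = f_r_test$statistic, df = f_r_test$df,
           p = f_r_test$p_value, stars = f_r_test$stars),
      file.path(output_dir, "comparison.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  out
}

#' @export
print.revival_report <- function(x, ...) {
  cat("<revival_report>\n")
  print(x$group_summary)
  cat("Per-colony f_r comparison: ")
  print(x$f_r_test)
  invisible(x)
}
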