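# Synthetic time-lapse "microscopy" data: per-spore observation tables with
# the statistical structure of single-cell sporulation/revival experiments.
# Two sporulation-time modes: "parametric" draws heterochronic sporulation
# times from a two-component lognormal mixture (early wave around 15 h, late
# wave around 30 h, roughly 50/50); "mechanistic" takes spore births from
# the stochastic lineage simulator. Reporters, stimulus response, outgrowth
# and frame-rate censoring are layered on top.

#' Configuration of the synthetic spore-table generator
#'
#' Defaults emulate the study conditions: a ~50/50 split between an early
#' sporulation wave (lognormal, median 15 h) and a late wave (median 30 h,
#' i.e. 20 h or more after the downshift); acquisition every 20 min with a
#' 12-h revival scoring window; a saturating l-alanine-like stimulus under
#' which >90% of spores germinate, early spores germinate twice as fast as
#' late ones, and outgrowth depends on the carried-over enzyme level through
#' a logistic law on log enzyme. Absolute fluorescence scales and noise
#' magnitudes are not experimentally constrained; the defaults here are
#' plausible placeholders in arbitrary units.
#'
#' @param mode `"parametric"` (mixture model) or `"mechanistic"` (spore
#'   births from [simulate_population()]; requires model parameters).
#' @param n_colonies Number of microcolonies.
#' @param spores_per_colony Mean spores per colony (Poisson), parametric
#'   mode.
#' @param founders_per_colony Founder cells per colony, mechanistic mode.
#' @param weight_early Mixture weight of the early wave, in `[0, 1]`.
#' @param early_median,early_sigma Lognormal median (h) and log-sd of the
#'   early sporulation-time component (truncated below `early_threshold`:
#'   the first wave ends at the threshold).
#' @param late_median,late_sigma Same for the late component (truncated
#'   above `early_threshold`: late spores form at the threshold or later).
#' @param early_threshold Sporulation time (h) separating the waves; spores
#'   formed before it are truly "early" (`group_true`).
#' @param lambda_eff Effective dilution rate (1/h) mapping sporulation time
#'   to enzyme level in parametric mode, `enzyme = exp(-lambda_eff * t)`.
#' @param E0 Ald-mCherry fluorescence scale (a.u.) at enzyme level 1.
#' @param sigma_ald Log-sd of the unit-mean multiplicative lognormal reporter
#'   noise on Ald-mCherry.
#' @param rapa_base,rapa_slope,sigma_rapa P_rapA reporter: fluorescence
#'   `rapa_base * exp(rapa_slope * t_spor)` times unit-mean lognormal noise;
#'   monotone in sporulation time and bimodal under the default mixture.
#' @param stimulus Germinant stimulus level in `[0, 1]`.
#' @param p_g_base Germination probability at `stimulus = 1` (identical for
#'   early and late spores).
#' @param germ_rate_early Germination rate constant of early spores (1/h).
#' @param germ_rate_ratio Early:late germination rate ratio (default 2,
#'   "twice as fast").
#' @param outgrowth_slope,outgrowth_midpoint Logistic law for outgrowth
#'   among germinated spores: `P = outgrowth_scale *
#'   plogis(outgrowth_slope * (log(enzyme) - log(outgrowth_midpoint)))`.
#' @param outgrowth_scale Multiplier of the outgrowth probability; defaults
#'   to `stimulus`.
#' @param enzyme_coupled If `FALSE`, outgrowth ignores the enzyme level and
#'   uses the constant `outgrowth_p_const` (AGFK-like germinants whose
#'   outgrowth response is decoupled from the enzyme).
#' @param outgrowth_p_const Constant outgrowth probability when decoupled.
#' @param frame_interval Acquisition interval, hours (default 1/3 h
#'   = 20 min).
#' @param window Revival scoring window, hours (default 12).
#' @param colony_area Area per colony (a.u.) for yield computation; in
#'   mechanistic mode defaults to the number of founders per colony.
#' @param seed Master seed; the same seed gives an identical table.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(mode = c("parametric", "mechanistic"),
                             n_colonies = 8,
                             spores_per_colony = 125,
                             founders_per_colony = 500,
                             weight_early = 0.5,
                             early_median = 15, early_sigma = 0.2,
                             late_median = 30, late_sigma = 0.3,
                             early_threshold = 20,
                             lambda_eff = 0.1,
                             E0 = 1000, sigma_ald = 0.2,
                             rapa_base = 10, rapa_slope = 0.2,
                             sigma_rapa = 0.3,
                             stimulus = 1, p_g_base = 0.93,
                             germ_rate_early = 1.0, germ_rate_ratio = 2,
                             outgrowth_slope = 3,
                             outgrowth_midpoint = exp(-2.2),
                             outgrowth_scale = NULL,
                             enzyme_coupled = TRUE,
                             outgrowth_p_const = 0.3,
                             frame_interval = 1 / 3, window = 12,
                             colony_area = NULL,
                             seed = 1) {
  mode <- match.arg(mode)
  if (weight_early < 0 || weight_early > 1) {
    stop("weight_early must lie in [0, 1]", call. = FALSE)
  }
  if (stimulus < 0 || stimulus > 1) {
    stop("stimulus must lie in [0, 1]", call. = FALSE)
  }
  if (frame_interval <= 0) stop("frame_interval must be > 0", call. = FALSE)
  if (window < 0) stop("window must be >= 0", call. = FALSE)
  if (sigma_ald < 0 || sigma_rapa < 0) {
    stop("reporter noise sigma must be >= 0", call. = FALSE)
  }
  if (n_colonies < 1) stop("need at least one colony", call. = FALSE)
  structure(as.list(environment()), class = "generator_config")
}

#' Named germinant stimulus presets
#'
#' Returns a [generator_config()] updated for a named germinant condition:
#' `"l_ala_strong"` (saturating l-alanine: >90% germination,
#' enzyme-dependent outgrowth), `"l_ala_weak"` (20-fold weaker stimulus:
#' partial germination, spores stall without outgrowth), `"agfk"` (AGFK
#' mixture: efficient germination, outgrowth decoupled from the enzyme
#' level).
#'
#' @param config A [generator_config()].
#' @param preset One of `"l_ala_strong"`, `"l_ala_weak"`, `"agfk"`.
#' @return The updated config.
#' @export
apply_stimulus_preset <- function(config,
                                  preset = c("l_ala_strong", "l_ala_weak",
                                             "agfk")) {
  stopifnot(inherits(config, "generator_config"))
  preset <- match.arg(preset)
  if (preset == "l_ala_strong") {
    config$stimulus <- 1; config$p_g_base <- 0.93
    config$outgrowth_scale <- 1; config$enzyme_coupled <- TRUE
  } else if (preset == "l_ala_weak") {
    config$stimulus <- 0.43; config$p_g_base <- 0.93
    config$outgrowth_scale <- 0; config$enzyme_coupled <- TRUE
  } else {
    config$stimulus <- 1; config$p_g_base <- 0.9
    config$enzyme_coupled <- FALSE
  }
  config
}

derive_seed <- function(master, stage) {
  s <- (as.numeric(master) + 9973 * stage) %% 2147483647
  as.integer(max(s, 1))
}

#' Generate a synthetic per-spore observation table
#'
#' Runs the full generator chain: sporulation times and enzyme levels (per
#' `config$mode`), fluorescent reporters ([assign_reporters()]), stimulus
#' response ([simulate_revival()]) and acquisition censoring
#' ([discretize_observations()]). All randomness is derived from
#' `config$seed`.
#'
#' @param config A [generator_config()].
#' @param model_params A [model_params()] object; required in mechanistic
#'   mode.
#' @return A tibble with columns `colony_id`, `spore_id`, `t_spor_h`,
#'   `enzyme`, `fluor_ald`, `fluor_rapa`, `group_true`, `germinated`,
#'   `t_germ_h`, `outgrown`. Attribute `n_founders` is set in mechanistic
#'   mode.
#' @examples
#' tab <- generate_spore_table(generator_config(seed = 7))
#' dplyr::count(tab, group_true)
#' @export
generate_spore_table <- function(config, model_params = NULL) {
  stopifnot(inherits(config, "generator_config"))
  records <- draw_sporulation(config, model_params)
  records <- assign_reporters(records, config)
  records <- simulate_revival(records, config)
  discretize_observations(records, config)
}

# Sporulation times, enzyme levels and true group labels.
draw_sporulation <- function(config, model_params = NULL) {
  if (config$mode == "mechanistic") {
    if (is.null(model_params)) {
      stop("mechanistic mode requires model_params", call. = FALSE)
    }
    n_found <- config$n_colonies * config$founders_per_colony
    sim <- simulate_population(
      model_params,
      sim_config(n_initial = n_found, seed = derive_seed(config$seed, 10)))
    sp <- sim$spores
    if (nrow(sp) == 0) stop("simulation produced no spores", call. = FALSE)
    colony <- ceiling(sp$founder_id / config$founders_per_colony)
    records <- tibble::tibble(
      colony_id = sprintf("c%02d", colony),
      t_spor_h = sp$time_h,
      enzyme = sp$enzyme
    )
    records <- dplyr::arrange(records, .data$colony_id, .data$t_spor_h)
    n_founders <- n_found
  } else {
    records <- withr::with_seed(derive_seed(config$seed, 11), {
      n_per <- stats::rpois(config$n_colonies, config$spores_per_colony)
      if (sum(n_per) == 0) stop("all colonies are empty", call. = FALSE)
      colony <- sprintf("c%02d", rep(seq_len(config$n_colonies), n_per))
      n <- sum(n_per)
      is_early <- stats::runif(n) < config$weight_early
      # components truncated at the wave boundary: the early wave ends, and
      # the late wave begins, at early_threshold hours (inverse-CDF draw)
      u <- stats::runif(n)
      thr <- config$early_threshold
      Fe <- stats::plnorm(thr, log(config$early_median), config$early_sigma)
      Fl <- stats::plnorm(thr, log(config$late_median), config$late_sigma)
      t_spor <- ifelse(
        is_early,
        stats::qlnorm(u * Fe, log(config$early_median), config$early_sigma),
        stats::qlnorm(Fl + u * (1 - Fl), log(config$late_median),
                      config$late_sigma))
      tibble::tibble(colony_id = colony, t_spor_h = t_spor,
                     enzyme = exp(-config$lambda_eff * t_spor))
    })
    n_founders <- NA_integer_
  }
  records <- dplyr::mutate(
    dplyr::group_by(records, .data$colony_id),
    spore_id = dplyr::row_number(), .after = "colony_id")
  records <- dplyr::ungroup(records)
  records$group_true <- factor(
    ifelse(records$t_spor_h < config$early_threshold, "early", "late"),
    levels = c("early", "late"))
  if (config$mode == "mechanistic") attr(records, "n_founders") <- n_founders
  records
}

#' Attach fluorescent-reporter readouts to spore records
#'
#' `fluor_ald` is the carried-over enzyme reporter: `E0 * enzyme` times
#' unit-mean multiplicative lognormal noise, so the population mean of
#' `fluor_ald / E0` is an unbiased readout of the mean enzyme level.
#' `fluor_rapa` reports sporulation timing through a monotone increasing
#' (exponential) map of `t_spor_h` times unit-mean lognormal noise; under
#' the default bimodal timing mixture its marginal is bimodal.
#'
#' @param records Spore records carrying `enzyme` and `t_spor_h`.
#' @param config A [generator_config()].
#' @return `records` with `fluor_ald`, `fluor_rapa` columns.
#' @export
assign_reporters <- function(records, config) {
  stopifnot(all(c("enzyme", "t_spor_h") %in% names(records)))
  if (config$sigma_ald < 0 || config$sigma_rapa < 0) {
    stop("reporter noise sigma must be >= 0", call. = FALSE)
  }
  n <- nrow(records)
  withr::with_seed(derive_seed(config$seed, 12), {
    noise_ald <- stats::rlnorm(n, -config$sigma_ald^2 / 2, config$sigma_ald)
    noise_rapa <- stats::rlnorm(n, -config$sigma_rapa^2 / 2,
                                config$sigma_rapa)
    records$fluor_ald <- config$E0 * records$enzyme * noise_ald
    records$fluor_rapa <- config$rapa_base *
      exp(config$rapa_slope * records$t_spor_h) * noise_rapa
  })
  records
}

#' Simulate the revival response to a germinant stimulus
#'
#' Germination is Bernoulli with probability `p_g_base * stimulus`,
#' identical for early and late spores. Germinating spores draw an
#' exponential germination time with a group-specific rate (late =
#' early / `germ_rate_ratio`). Outgrowth is Bernoulli among germinated
#' spores with probability `outgrowth_scale` times a logistic function of
#' log enzyme level (or a constant when `enzyme_coupled = FALSE`).
#' Continuous `t_germ_h` values are produced here; apply
#' [discretize_observations()] for frame quantization and window censoring.
#'
#' @inheritParams assign_reporters
#' @return `records` with `germinated`, `t_germ_h`, `outgrown` columns.
#' @export
simulate_revival <- function(records, config) {
  if (!"enzyme" %in% names(records)) {
    stop("records lack an 'enzyme' column", call. = FALSE)
  }
  stopifnot(config$stimulus >= 0, config$stimulus <= 1)
  n <- nrow(records)
  grp <- if ("group_true" %in% names(records)) {
    records$group_true
  } else {
    factor(ifelse(records$t_spor_h < config$early_threshold,
                  "early", "late"), levels = c("early", "late"))
  }
  p_g <- min(max(config$p_g_base * config$stimulus, 0), 1)
  rate <- ifelse(grp == "early", config$germ_rate_early,
                 config$germ_rate_early / config$germ_rate_ratio)
  scale <- config$outgrowth_scale %||% config$stimulus
  withr::with_seed(derive_seed(config$seed, 13), {
    germ <- stats::runif(n) < p_g
    t_germ <- ifelse(germ, stats::rexp(n, rate), NA_real_)
    p_out <- if (config$enzyme_coupled) {
      scale * stats::plogis(config$outgrowth_slope *
                              (log(records$enzyme) -
                                 log(config$outgrowth_midpoint)))
    } else {
      rep(min(max(config$outgrowth_p_const, 0), 1), n)
    }
    outg <- germ & stats::runif(n) < p_out
  })
  records$germinated <- germ
  records$t_germ_h <- t_germ
  records$outgrown <- outg
  records
}

#' Quantize germination times to the acquisition frame grid
#'
#' An event is first seen at the next acquisition frame, so `t_germ_h` is
#' rounded up to the frame grid (values already on the grid are unchanged).
#' Events past the scoring window become unobserved: `t_germ_h` missing,
#' `germinated` and `outgrown` set to `FALSE`.
#'
#' @inheritParams assign_reporters
#' @return `records` with frame-quantized, window-censored observations.
#' @export
discretize_observations <- function(records, config) {
  stopifnot(all(c("germinated", "t_germ_h", "outgrown") %in% names(records)))
  fr <- config$frame_interval
  t_q <- fr * ceiling(records$t_germ_h / fr - 1e-9)
  seen <- records$germinated & !is.na(t_q) & t_q <= config$window + 1e-9
  records$t_germ_h <- ifelse(seen, t_q, NA_real_)
  records$germinated <- seen
  records$outgrown <- records$outgrown & seen
  records
}

spore_table_cols <- c("colony_id", "spore_id", "t_spor_h", "enzyme",
                      "fluor_ald", "fluor_rapa", "group_true", "germinated",
                      "t_germ_h", "outgrown")

#' Validate a per-spore observation table
#'
#' Enforces the documented schema and record invariants (required columns;
#' positive fluorescence; enzyme in `(0, 1]`; non-negative times;
#' `outgrown` implies `germinated`; `germinated` if and only if an observed
#' `t_germ_h`). Violations raise errors naming the offending column.
#'
#' @param records A spore-record tibble.
#' @return `records`, invisibly, if valid.
#' @export
validate_spore_table <- function(records) {
  miss <- setdiff(spore_table_cols, names(records))
  if (length(miss)) {
    stop("spore table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  chk <- function(bad, col, what) {
    if (any(bad, na.rm = TRUE)) {
      stop("column '", col, "': ", sum(bad, na.rm = TRUE), " record(s) ",
           what, call. = FALSE)
    }
  }
  chk(records$t_spor_h < 0, "t_spor_h", "with negative sporulation time")
  chk(records$enzyme <= 0 | records$enzyme > 1, "enzyme",
      "outside (0, 1]")
  chk(records$fluor_ald <= 0, "fluor_ald", "with non-positive fluorescence")
  chk(records$fluor_rapa <= 0, "fluor_rapa",
      "with non-positive fluorescence")
  chk(records$t_germ_h < 0, "t_germ_h", "with negative germination time")
  chk(records$outgrown & !records$germinated, "outgrown",
      "outgrown without germination")
  chk(records$germinated & is.na(records$t_germ_h), "t_germ_h",
      "germinated but missing germination time")
  chk(!records$germinated & !is.na(records$t_germ_h), "t_germ_h",
      "germination time recorded for non-germinated spore")
  invisible(records)
}

#' Write / read the spore-table CSV
#'
#' Lossless round-trip of the documented schema (one row per spore, columns
#' `colony_id, spore_id, t_spor_h, enzyme, fluor_ald, fluor_rapa,
#' group_true, germinated, t_germ_h, outgrown`); a missing `t_germ_h` is an
#' empty field. Tables are validated on both ends.
#'
#' @param records A valid spore-record tibble.
#' @param path File path.
#' @return `write_spore_table()` returns `path` invisibly;
#'   `read_spore_table()` returns the validated tibble.
#' @export
write_spore_table <- function(records, path) {
  validate_spore_table(records)
  readr::write_csv(records[spore_table_cols], path, na = "")
  invisible(path)
}

#' @rdname write_spore_table
#' @export
read_spore_table <- function(path) {
  records <- readr::read_csv(
    path,
    col_types = readr::cols(
      colony_id = readr::col_character(),
      spore_id = readr::col_integer(),
      t_spor_h = readr::col_double(),
      enzyme = readr::col_double(),
      fluor_ald = readr::col_double(),
      fluor_rapa = readr::col_double(),
      group_true = readr::col_character(),
      germinated = readr::col_logical(),
      t_germ_h = readr::col_double(),
      outgrown = readr::col_logical()
    ),
    na = ""
  )
  records$group_true <- factor(records$group_true,
                               levels = c("early", "late"))
  validate_spore_table(records)
  records
}
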