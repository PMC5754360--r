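# Quantification layer for per-spore observation tables: early/late
# classification, revival/germination/outgrowth frequencies, germination
# kinetics, yield and quality with wild-type normalization, and group
# comparisons.

#' Classify spores as early or late by sporulation time
#'
#' Early spores are those formed strictly before `threshold` hours after the
#' nutrient downshift (the first sporulation wave); spores at or past the
#' threshold are late.
#'
#' @param records Spore records with `t_spor_h`.
#' @param threshold Classification boundary in hours (default 20).
#' @return `records` with an added `group` factor column (`early`/`late`).
#' @examples
#' tab <- generate_spore_table(generator_config(seed = 1))
#' tab <- classify_by_time(tab)
#' table(tab$group, tab$group_true)
#' @export
classify_by_time <- function(records, threshold = 20) {
  if (!"t_spor_h" %in% names(records) || anyNA(records$t_spor_h)) {
    stop("records must carry a complete t_spor_h column", call. = FALSE)
  }
  records$group <- factor(
    ifelse(records$t_spor_h < threshold, "early", "late"),
    levels = c("early", "late"))
  records
}

#' Classify spores as early or late by reporter fluorescence
#'
#' The sporulation-timing reporter (`fluor_rapa`) increases with sporulation
#' time, so dim spores are early. `method = "median"` labels spores at or
#' below the sample median as early (so a constant column classifies every
#' spore as early). `method = "valley"` fits a two-component Gaussian
#' mixture to log fluorescence and splits at equal posterior probability;
#' the dimmer component is early. Both methods are deterministic given the
#' data.
#'
#' @param records Spore records with `fluor_rapa` (`n >= 10`).
#' @param method `"median"` or `"valley"`.
#' @return `records` with an added `group` factor column.
#' @export
classify_by_fluorescence <- function(records,
                                     method = c("median", "valley")) {
  method <- match.arg(method)
  if (!"fluor_rapa" %in% names(records) || anyNA(records$fluor_rapa)) {
    stop("records must carry a complete fluor_rapa column", call. = FALSE)
  }
  if (nrow(records) < 10) {
    stop("need at least 10 records to classify by fluorescence",
         call. = FALSE)
  }
  x <- log(records$fluor_rapa)
  if (method == "median") {
    early <- x <= stats::median(x)
  } else {
    if (stats::sd(x) == 0) {
      stop("constant fluorescence column: valley method undefined",
           call. = FALSE)
    }
    fit <- Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
    dim_comp <- which.min(fit$parameters$mean)
    early <- fit$z[, dim_comp] >= 0.5
  }
  records$group <- factor(ifelse(early, "early", "late"),
                          levels = c("early", "late"))
  records
}

#' Revival, germination and outgrowth frequencies
#'
#' From counts of dormant (`N_s`), germinated (`N_g`) and outgrown (`N_o`)
#' spores: revival frequency `f_r = N_o / N_s`, germination frequency
#' `f_g = N_g / N_s`, outgrowth frequency `f_o = N_o / N_g` (`NA` when
#' `N_g = 0`; so `f_r = f_g * f_o` whenever all three are defined). With a
#' `group` column the summary is per group; `per_colony = TRUE` further
#' splits by `colony_id` (useful for colony-level means and SEMs).
#'
#' @param records Spore records with `germinated` and `outgrown` flags
#'   (add a `group` column with [classify_by_time()] or
#'   [classify_by_fluorescence()] first for per-group summaries).
#' @param per_colony Split by colony as well as group.
#' @return A tibble of class `revival_summary` with columns `group`
#'   (and `colony_id`), `N_s`, `N_g`, `N_o`, `f_r`, `f_g`, `f_o`.
#' @examples
#' revival_counts(N_s = 20, N_g = 18, N_o = 9)
#' @export
revival_frequencies <- function(records, per_colony = FALSE) {
  stopifnot(all(c("germinated", "outgrown") %in% names(records)))
  grp_vars <- intersect(
    c("group", if (per_colony) "colony_id"), names(records))
  if (per_colony && !"colony_id" %in% names(records)) {
    stop("per_colony = TRUE requires a colony_id column", call. = FALSE)
  }
  out <- dplyr::summarise(
    dplyr::group_by(records, dplyr::across(dplyr::all_of(grp_vars))),
    N_s = dplyr::n(),
    N_g = sum(.data$germinated),
    N_o = sum(.data$outgrown),
    .groups = "drop")
  if (!"group" %in% names(out)) {
    out <- tibble::add_column(out, group = "all", .before = 1)
  }
  finish_frequencies(out)
}

#' @rdname revival_frequencies
#' @param N_s,N_g,N_o Spore counts (vectors allowed) with
#'   `N_o <= N_g <= N_s`.
#' @param group Optional group labels for count vectors.
#' @export
revival_counts <- function(N_s, N_g, N_o, group = "all") {
  out <- tibble::tibble(group = group, N_s = N_s, N_g = N_g, N_o = N_o)
  finish_frequencies(out)
}

finish_frequencies <- function(out) {
  if (any(out$N_o > out$N_g | out$N_g > out$N_s | out$N_o < 0)) {
    stop("invalid counts: need 0 <= N_o <= N_g <= N_s", call. = FALSE)
  }
  out$f_r <- out$N_o / out$N_s
  out$f_g <- out$N_g / out$N_s
  out$f_o <- ifelse(out$N_g > 0, out$N_o / out$N_g, NA_real_)
  class(out) <- c("revival_summary", class(out))
  out
}

#' Cumulative germination curve
#'
#' Fraction of all dormant spores in each group that have germinated by each
#' grid time (frame-quantized observations; spores whose germination is
#' censored past the window never count). The curve is non-decreasing and
#' terminates at the group's germination frequency `f_g`.
#'
#' @param records Spore records with `germinated` and frame-quantized
#'   `t_germ_h` (and optionally `group`).
#' @param grid Time grid in hours; must contain every observed `t_germ_h`.
#'   Defaults to the frame grid `seq(0, window, by = frame_interval)`.
#' @param frame_interval,window Acquisition parameters used for the default
#'   grid.
#' @return A tibble of class `germination_curve` with columns `group`,
#'   `time`, `fraction`.
#' @export
germination_curve <- function(records, grid = NULL, frame_interval = 1 / 3,
                              window = 12) {
  stopifnot(all(c("germinated", "t_germ_h") %in% names(records)))
  if (is.null(grid)) {
    grid <- seq(0, window, by = frame_interval)
  }
  obs <- records$t_germ_h[records$germinated]
  if (length(obs) &&
      any(vapply(obs, function(t) min(abs(grid - t)) > 1e-6, logical(1)))) {
    stop("grid is not a superset of the observed germination frame times",
         call. = FALSE)
  }
  if (!"group" %in% names(records)) records$group <- factor("all")
  out <- purrr::map_dfr(split(records, records$group), function(df) {
    tibble::tibble(
      group = df$group[1],
      time = grid,
      fraction = vapply(grid, function(g) {
        mean(df$germinated & !is.na(df$t_germ_h) & df$t_germ_h <= g + 1e-9)
      }, numeric(1)))
  })
  class(out) <- c("germination_curve", class(out))
  out
}

#' Germination half-time per group
#'
#' Time at which a group's cumulative germination curve reaches half of its
#' final level, linearly interpolated between frames.
#'
#' @param curve A [germination_curve()] result.
#' @return Tibble with `group`, `half_time` (hours).
#' @export
germination_half_time <- function(curve) {
  stopifnot(inherits(curve, "germination_curve"))
  purrr::map_dfr(split(curve, curve$group), function(df) {
    final <- df$fraction[nrow(df)]
    if (final == 0) {
      return(tibble::tibble(group = df$group[1], half_time = NA_real_))
    }
    target <- final / 2
    i <- which(df$fraction >= target)[1]
    ht <- if (i == 1) df$time[1] else {
      t0 <- df$time[i - 1]; t1 <- df$time[i]
      f0 <- df$fraction[i - 1]; f1 <- df$fraction[i]
      t0 + (target - f0) / (f1 - f0) * (t1 - t0)
    }
    tibble::tibble(group = df$group[1], half_time = ht)
  })
}

#' Spore yield and quality of a colony or condition
#'
#' Yield `Y = N_s / colony_area` (dormant spores per unit initial colony
#' area) and quality `Q` = mean Ald-reporter fluorescence over the dormant
#' spores.
#'
#' @param records Spore records with `fluor_ald`.
#' @param colony_area Initial colony area (a.u.), `> 0`.
#' @return One-row tibble with `N_s`, `Y`, `Q`.
#' @export
yield_and_quality <- function(records, colony_area) {
  stopifnot("fluor_ald" %in% names(records))
  if (!is.numeric(colony_area) || colony_area <= 0) {
    stop("colony_area must be > 0", call. = FALSE)
  }
  tibble::tibble(N_s = nrow(records),
                 Y = nrow(records) / colony_area,
                 Q = mean(records$fluor_ald))
}

#' Normalize values to a wild-type reference
#'
#' Elementwise ratio to the co-cultured wild-type value, so the reference
#' maps to 1 and ratios are invariant to a common rescaling of raw units.
#'
#' @param values Numeric vector.
#' @param wt_value Positive wild-type reference (scalar or vector).
#' @return `values / wt_value`.
#' @export
normalize_to_wt <- function(values, wt_value) {
  if (any(!is.finite(wt_value)) || any(wt_value <= 0)) {
    stop("wild-type reference must be positive and finite", call. = FALSE)
  }
  values / wt_value
}

#' Unpaired two-sample t test with significance stars
#'
#' Welch's unequal-variance t test by default (`welch = FALSE` gives the
#' pooled Student test), two-sided, with the star convention
#' `* p <= 0.05`, `** p <= 0.01`, `*** p <= 0.001`, `**** p <= 0.0001`.
#'
#' @param x,y Numeric vectors, each with at least 2 finite values.
#' @param welch Use the Welch-Satterthwaite statistic (default `TRUE`).
#' @return An object of class `revival_test` with elements `statistic`,
#'   `df`, `p_value`, `stars`, `estimate` (mean difference), `method`.
#' @examples
#' unpaired_t_test(c(1, 2, 3), c(2, 3, 4))
#' @export
unpaired_t_test <- function(x, y, welch = TRUE) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2 || length(y) < 2) {
    stop("each group needs at least 2 finite values", call. = FALSE)
  }
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    stop("zero variance in both groups: t statistic undefined",
         call. = FALSE)
  }
  ht <- stats::t.test(x, y, var.equal = !welch)
  structure(
    list(statistic = unname(ht$statistic),
         df = unname(ht$parameter),
         p_value = ht$p.value,
         stars = significance_stars(ht$p.value),
         estimate = mean(x) - mean(y),
         n_x = length(x), n_y = length(y),
         method = if (welch) "Welch unpaired t test"
                  else "Student unpaired t test"),
    class = "revival_test")
}

#' Map a p value to significance stars
#'
#' @param p P value(s) in `[0, 1]`.
#' @return `"****"`, `"***"`, `"**"`, `"*"` or `"ns"`.
#' @export
significance_stars <- function(p) {
  vapply(p, function(pi) {
    if (pi <= 1e-4) "****"
    else if (pi <= 1e-3) "***"
    else if (pi <= 0.01) "**"
    else if (pi <= 0.05) "*"
    else "ns"
  }, character(1))
}

#' @export
print.revival_test <- function(x, ...) {
  cat(sprintf("%s: t = %.4f, df = %.2f, p = %.4g %s\n",
              x$method, x$statistic, x$df, x$p_value, x$stars))
  invisible(x)
}

#' Rank correlation of a quantity-quality sweep
#'
#' Spearman rank correlation between paired sweep observations (e.g.
#' relative yield vs relative quality, or yield vs revival frequency), with
#' an exact permutation p value for small sweeps (`n <= 8`, no ties) and
#' the asymptotic approximation otherwise.
#'
#' @param x A two-column data frame of paired observations, or a numeric
#'   vector (then supply `y`). At least 4 pairs.
#' @param y Numeric vector when `x` is a vector.
#' @return An object of class `tradeoff_cor` with `rho`, `p_value`, `n`.
#' @export
tradeoff_correlation <- function(x, y = NULL) {
  if (is.data.frame(x)) {
    num <- x[vapply(x, is.numeric, logical(1))]
    if (ncol(num) < 2) stop("need two numeric columns", call. = FALSE)
    y <- num[[2]]; x <- num[[1]]
  }
  stopifnot(length(x) == length(y))
  if (length(x) < 4) {
    stop("need at least 4 sweep points for a rank correlation",
         call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("rank correlation undefined: constant input", call. = FALSE)
  }
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman",
                    exact = length(x) <= 8 && !ties))
  structure(list(rho = unname(ct$estimate), p_value = ct$p.value,
                 n = length(x)),
            class = "tradeoff_cor")
}

#' @export
print.tradeoff_cor <- function(x, ...) {
  cat(sprintf("Spearman rank correlation: rho = %.3f, p = %.4g (n = %d)\n",
              x$rho, x$p_value, x$n))
  invisible(x)
}
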