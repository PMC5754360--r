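# ggplot2 autoplot() methods for the package's result types.

#' Plot cascade state occupancies over time
#'
#' @param object A `spore_trajectory` from [solve_trajectories()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.spore_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    cols = -c("time", "spor_rate"),
    names_to = "state", values_to = "occupancy")
  long$state <- factor(long$state, levels = setdiff(names(object),
                                                    c("time", "spor_rate")))
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$occupancy,
                                     colour = .data$state)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time after downshift (h)",
                  y = "occupancy (per initial cell)",
                  colour = "state") +
    ggplot2::theme_minimal()
}

#' Plot the spore quantity-quality tradeoff of a sweep
#'
#' @param object A `sweep_result` from [sweep_tradeoff()].
#' @param ... Unused.
#' @return A ggplot of quality `ebar` against yield `s`, path ordered by the
#'   swept parameter.
#' @export
autoplot.sweep_result <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$yield_s, .data$quality_ebar)) +
    ggplot2::geom_path(colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$param_value), size = 2) +
    ggplot2::labs(x = "spore yield s (spores per initial cell)",
                  y = "mean enzyme level per spore",
                  colour = unique(object$param_name)) +
    ggplot2::theme_minimal()
}

#' Plot the enzyme-level density of the spore population
#'
#' @param object An `enzyme_density` from [enzyme_density()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.enzyme_density <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$e, .data$density)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "carried-over enzyme level e",
                  y = expression(rho(e))) +
    ggplot2::theme_minimal()
}

#' Plot cumulative germination curves by group
#'
#' @param object A `germination_curve` from [germination_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.germination_curve <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$time, .data$fraction,
                               colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "time after stimulus (h)",
                  y = "fraction of spores germinated",
                  colour = NULL) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal()
}

#' Plot revival, germination and outgrowth frequencies by group
#'
#' @param object A `revival_summary` from [revival_frequencies()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.revival_summary <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    cols = c("f_r", "f_g", "f_o"),
    names_to = "frequency", values_to = "value")
  long$frequency <- factor(long$frequency, levels = c("f_g", "f_o", "f_r"))
  ggplot2::ggplot(long, ggplot2::aes(.data$frequency, .data$value,
                                     fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "frequency", fill = NULL) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal()
}
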