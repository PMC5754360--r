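# broom-style tidy()/glance() methods.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an unpaired t test
#'
#' @param x A `revival_test` from [unpaired_t_test()].
#' @param ... Unused.
#' @return One-row tibble: `estimate`, `statistic`, `df`, `p.value`,
#'   `stars`, `method`.
#' @export
tidy.revival_test <- function(x, ...) {
  tibble::tibble(estimate = x$estimate, statistic = x$statistic,
                 df = x$df, p.value = x$p_value, stars = x$stars,
                 method = x$method)
}

#' @rdname tidy.revival_test
#' @export
glance.revival_test <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p.value = x$p_value,
                 n_x = x$n_x, n_y = x$n_y)
}

#' Tidy a sweep rank correlation
#'
#' @param x A `tradeoff_cor` from [tradeoff_correlation()].
#' @param ... Unused.
#' @return One-row tibble: `estimate` (Spearman rho), `p.value`, `n`.
#' @export
tidy.tradeoff_cor <- function(x, ...) {
  tibble::tibble(estimate = x$rho, p.value = x$p_value, n = x$n,
                 method = "Spearman rank correlation")
}

#' Tidy / summarise a stochastic lineage simulation
#'
#' `tidy()` returns the spore-birth table; `glance()` the one-row summary
#' (yield and quality estimates with standard errors, truncation flag).
#'
#' @param x A `spore_sim` from [simulate_population()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.spore_sim <- function(x, ...) {
  x$spores
}

#' @rdname tidy.spore_sim
#' @export
glance.spore_sim <- function(x, ...) {
  x$summary
}
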