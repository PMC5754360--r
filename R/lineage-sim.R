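# Continuous-time branching-process realization of the spore-memory model.
# Each cell carries independent exponential clocks for division (rate
# lambda), cascade progression (eta), sporulation (delta; removing under the
# depleting variant, marking under as_written) and death (mu, starved state
# only). Enzyme concentration is the deterministic global dilution curve
# exp(-lambda * t), so divisions do not change it. Expected state occupancies
# reproduce the deterministic cascade by linearity of expectation, which
# makes the simulator an independent Monte-Carlo oracle for the closed-form
# model.

#' Simulation configuration
#'
#' @param n_initial Number of founder cells (`>= 1`).
#' @param t_max Simulation horizon in hours. Default `20 / min(eta, mu +
#'   delta)` at simulation time, long enough that the residual vegetative
#'   mass is negligible for convergent parameter sets.
#' @param seed Integer seed; the same seed yields a bit-identical event
#'   stream.
#' @param record_events If `TRUE`, keep a per-event log and per-cell state
#'   intervals (needed for occupancy reconstruction).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_initial = 1000, t_max = NULL, seed = 1,
                       record_events = FALSE) {
  stopifnot(n_initial >= 1, is.null(t_max) || t_max > 0)
  structure(list(n_initial = as.integer(n_initial), t_max = t_max,
                 seed = as.integer(seed), record_events = record_events),
            class = "sim_config")
}

default_t_max <- function(params) {
  20 / min(params$eta, params$mu + params$delta)
}

#' Simulate a founder population of sporulating lineages
#'
#' Exact first-reaction stochastic simulation of independent cell lineages.
#' Division duplicates a cell in its current state; progression moves
#' `c_i -> c_(i+1)` and `c_k -> c_s`; sporulation (from `c_1..c_k`, `c_s`)
#' records a spore carrying enzyme level `exp(-lambda * t)` and, under the
#' `depleting` variant, removes the cell; death removes starved cells.
#'
#' @param params A [model_params()] object.
#' @param config A [sim_config()] object.
#' @return An object of class `spore_sim`: a list with
#'   \describe{
#'     \item{spores}{tibble of spore births: `lineage_id`, `founder_id`,
#'       `time_h`, `enzyme`, `origin_state`.}
#'     \item{summary}{one-row tibble: `yield_hat`, `se_yield`, `quality_hat`,
#'       `se_quality`, `n_spores`, `n_founders`, `n_alive_at_tmax`,
#'       `truncated`.}
#'     \item{events}{event log tibble (`record_events = TRUE` only).}
#'     \item{intervals}{per-cell state intervals (`record_events = TRUE`).}
#'   }
#' @examples
#' p <- model_params(0.5, 1, 1, 0.5)
#' sim <- simulate_population(p, sim_config(n_initial = 200, seed = 42))
#' sim$summary
#' @export
simulate_population <- function(params, config) {
  stopifnot(inherits(params, "model_params"), inherits(config, "sim_config"))
  t_max <- config$t_max %||% default_t_max(params)
  if (!is.finite(t_max)) {
    stop("t_max is not finite (mu + delta = 0 gives no default horizon); ",
         "supply t_max in sim_config()", call. = FALSE)
  }
  withr::with_seed(config$seed, {
    run_branching(params, config$n_initial, t_max, config$record_events)
  })
}

# states coded 0..k vegetative cascade, k+1 = starved (c_s)
run_branching <- function(params, n0, t_max, record_events) {
  k <- params$k
  s_state <- k + 1L
  lambda <- params$lambda; eta <- params$eta
  mu <- params$mu; delta <- params$delta
  dep <- params$variant == "depleting"

  state <- rep(0L, n0)
  now <- rep(0, n0)
  founder <- seq_len(n0)
  lineage <- seq_len(n0)
  enter <- rep(0, n0)           # time current state was entered
  next_lineage <- n0 + 1L

  sp_list <- list(); ev_list <- list(); iv_list <- list()
  alive_at_tmax <- 0L

  while (length(state) > 0L) {
    n <- length(state)
    has_prog <- state <= k
    has_spor <- state >= 1L
    has_death <- state == s_state
    r_prog <- ifelse(has_prog, eta, 0)
    r_spor <- ifelse(has_spor, delta, 0)
    r_death <- ifelse(has_death, mu, 0)
    R <- lambda + r_prog + r_spor + r_death

    dt <- ifelse(R > 0, stats::rexp(n, pmax(R, 1e-300)), Inf)
    t_new <- now + dt
    past <- t_new > t_max
    if (any(past)) {
      alive_at_tmax <- alive_at_tmax + sum(past)
      if (record_events) {
        iv_list[[length(iv_list) + 1L]] <- data.frame(
          lineage_id = lineage[past], founder_id = founder[past],
          state = state[past], t_start = enter[past], t_end = t_max)
      }
    }
    keep <- !past
    if (!any(keep)) break
    state <- state[keep]; now <- t_new[keep]; founder <- founder[keep]
    lineage <- lineage[keep]; enter <- enter[keep]
    R <- R[keep]; r_prog <- r_prog[keep]; r_spor <- r_spor[keep]
    r_death <- r_death[keep]

    u <- stats::runif(length(state)) * R
    is_div <- u < lambda
    is_prog <- !is_div & u < lambda + r_prog
    is_spor <- !is_div & !is_prog & u < lambda + r_prog + r_spor
    is_death <- !(is_div | is_prog | is_spor)

    if (record_events) {
      etype <- character(length(state))
      etype[is_div] <- "division"; etype[is_prog] <- "progression"
      etype[is_spor] <- "sporulation"; etype[is_death] <- "death"
      ev_list[[length(ev_list) + 1L]] <- data.frame(
        time_h = now, lineage_id = lineage, event_type = etype,
        state_from = state,
        state_to = ifelse(is_prog, state + 1L, state))
    }

    # spore births
    if (any(is_spor)) {
      sp_list[[length(sp_list) + 1L]] <- data.frame(
        lineage_id = lineage[is_spor], founder_id = founder[is_spor],
        time_h = now[is_spor], enzyme = exp(-lambda * now[is_spor]),
        origin_state = state[is_spor])
    }

    # removals: death always; sporulation removes only under depleting
    gone <- is_death | (dep & is_spor)
    if (record_events && any(gone | is_prog)) {
      closed <- gone | is_prog
      iv_list[[length(iv_list) + 1L]] <- data.frame(
        lineage_id = lineage[closed], founder_id = founder[closed],
        state = state[closed], t_start = enter[closed], t_end = now[closed])
    }

    # divisions: append a daughter with the same state and clock
    if (any(is_div)) {
      nd <- sum(is_div)
      d_state <- state[is_div]; d_now <- now[is_div]
      d_founder <- founder[is_div]
      state <- c(state, d_state)
      now <- c(now, d_now)
      founder <- c(founder, d_founder)
      lineage <- c(lineage, seq.int(next_lineage, length.out = nd))
      enter <- c(enter, d_now)
      next_lineage <- next_lineage + nd
      is_prog <- c(is_prog, rep(FALSE, nd)); gone <- c(gone, rep(FALSE, nd))
    }
    # progressions
    if (any(is_prog)) {
      state[is_prog] <- state[is_prog] + 1L
      enter[is_prog] <- now[is_prog]
    }
    if (any(gone)) {
      keep2 <- !gone
      state <- state[keep2]; now <- now[keep2]; founder <- founder[keep2]
      lineage <- lineage[keep2]; enter <- enter[keep2]
    }
  }

  spores <- if (length(sp_list)) {
    tibble::as_tibble(do.call(rbind, sp_list))
  } else {
    tibble::tibble(lineage_id = integer(), founder_id = integer(),
                   time_h = numeric(), enzyme = numeric(),
                   origin_state = integer())
  }
  spores$origin_state <- state_label(spores$origin_state, k)

  per_founder <- tabulate(
    if (nrow(spores)) spores$founder_id else integer(), nbins = n0)
  n_sp <- nrow(spores)
  summary <- tibble::tibble(
    yield_hat = n_sp / n0,
    se_yield = stats::sd(per_founder) / sqrt(n0),
    quality_hat = if (n_sp > 0) mean(spores$enzyme) else NA_real_,
    se_quality = if (n_sp > 1) stats::sd(spores$enzyme) / sqrt(n_sp)
                 else NA_real_,
    n_spores = n_sp,
    n_founders = n0,
    n_alive_at_tmax = alive_at_tmax,
    truncated = alive_at_tmax > 0L
  )
  if (summary$truncated) {
    warning("t_max = ", signif(t_max, 4), " h reached with ", alive_at_tmax,
            " cell(s) still alive; yield/quality estimates exclude their ",
            "future spores (truncated_mass)", call. = FALSE)
  }
  out <- list(spores = spores, summary = summary, params = params,
              t_max = t_max)
  if (record_events) {
    out$events <- tibble::as_tibble(do.call(rbind, ev_list))
    out$events <- out$events[order(out$events$time_h), ]
    out$intervals <- tibble::as_tibble(do.call(rbind, iv_list))
  }
  class(out) <- "spore_sim"
  out
}

state_label <- function(code, k) {
  factor(ifelse(code == k + 1L, "c_s", paste0("c_", code)),
         levels = c(paste0("c_", 0:k), "c_s"))
}

#' @export
print.spore_sim <- function(x, ...) {
  cat("<spore_sim>", x$summary$n_founders, "founders,",
      x$summary$n_spores, "spores\n")
  print(x$summary)
  invisible(x)
}

#' Empirical state occupancies from a recorded simulation
#'
#' Reconstructs mean per-founder occupancy of each cascade state at the
#' requested times from the state-interval log (requires
#' `record_events = TRUE`), with standard errors across founders.
#'
#' @param sim A `spore_sim` with intervals recorded.
#' @param times Numeric times within `[0, t_max]`.
#' @return Tibble with columns `time`, `state`, `occupancy`, `se`.
#' @export
sim_occupancy <- function(sim, times) {
  stopifnot(inherits(sim, "spore_sim"))
  if (is.null(sim$intervals)) {
    stop("simulation was run without record_events = TRUE", call. = FALSE)
  }
  iv <- sim$intervals
  n0 <- sim$summary$n_founders
  k <- sim$params$k
  purrr::map_dfr(times, function(tt) {
    live <- iv[iv$t_start <= tt & tt < iv$t_end, ]
    purrr::map_dfr(0:(k + 1L), function(st) {
      cnt <- tabulate(live$founder_id[live$state == st], nbins = n0)
      tibble::tibble(time = tt,
                     state = as.character(state_label(st, k)),
                     occupancy = mean(cnt),
                     se = stats::sd(cnt) / sqrt(n0))
    })
  })
}

#' Empirical enzyme-level histogram of simulated spores
#'
#' Normalized (density-scaled) histogram of carried-over enzyme levels over
#' `(0, 1]`; converges to the model density [enzyme_density()] as the number
#' of founders grows.
#'
#' @param spores Spore-birth tibble (e.g. `sim$spores`) with column `enzyme`,
#'   or a `spore_sim` object.
#' @param bins Number of equal-width bins on `(0, 1]`.
#' @return Tibble with `bin_lo`, `bin_hi`, `mid`, `count`, `density`
#'   (`sum(density * width) == 1`).
#' @export
empirical_enzyme_hist <- function(spores, bins = 50) {
  if (inherits(spores, "spore_sim")) spores <- spores$spores
  stopifnot("enzyme" %in% names(spores))
  if (nrow(spores) == 0) {
    stop("no spores: empirical enzyme histogram undefined", call. = FALSE)
  }
  breaks <- seq(0, 1, length.out = bins + 1)
  idx <- pmin(pmax(ceiling(spores$enzyme * bins), 1L), bins)
  count <- tabulate(idx, nbins = bins)
  width <- 1 / bins
  tibble::tibble(
    bin_lo = breaks[-(bins + 1)], bin_hi = breaks[-1],
    mid = (breaks[-1] + breaks[-(bins + 1)]) / 2,
    count = count,
    density = count / (sum(count) * width)
  )
}
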