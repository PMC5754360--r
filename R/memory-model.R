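# Deterministic kinetic model of the sporulation cascade with enzyme dilution.
#
# Cells start in a naive state c_0, progress at rate eta through k intermediate
# states c_1..c_k into a starved state c_s, grow (divide) at rate lambda,
# die at rate mu (starved state only), and sporulate at rate delta from
# c_1..c_k and c_s. Enzyme production stops at the nutrient downshift (t = 0),
# so the per-cell enzyme concentration is diluted by growth as
# e(t) = exp(-lambda * t) and is fixed into a spore at the moment of
# sporulation. The model yields the spore quantity s (spores per initial
# cell), the spore quality ebar (mean enzyme level per spore), and the full
# enzyme-level density rho(e) of the spore population.

#' Model parameters for the spore-memory cascade
#'
#' Constructs and validates the parameter set of the kinetic spore-memory
#' model: a linear cascade `c_0 -> c_1 -> ... -> c_k -> c_s` with growth,
#' death and sporulation.
#'
#' Two model variants are supported. Under `"as_written"` sporulation is a
#' pure marking process: spores are produced at rate `delta` from the
#' sporulation-competent states without removing cells from the vegetative
#' pool, which makes the spore yield linear in `delta` and the mean enzyme
#' level independent of it. Under `"depleting"` (the default) sporulation
#' additionally removes the sporulating cell, the physically consistent
#' branching interpretation under which faster sporulation trades spore
#' quantity against spore quality.
#'
#' @param lambda Growth (dilution) rate, 1/h; `>= 0`.
#' @param eta Progression rate through the cascade, 1/h; `> 0`.
#' @param mu Death rate, 1/h, acting in the starved state `c_s` only; `>= 0`.
#' @param delta Sporulation rate, 1/h, acting in `c_1..c_k` and `c_s`; `>= 0`.
#' @param k Number of intermediate states, integer `>= 1`. Default 2.
#' @param variant `"depleting"` or `"as_written"`.
#'
#' @return An object of class `model_params` (a named list).
#' @examples
#' p <- model_params(lambda = 0.5, eta = 1, mu = 1, delta = 0.5)
#' spore_yield(p)
#' mean_enzyme(p)
#' @export
model_params <- function(lambda, eta, mu, delta, k = 2,
                         variant = c("depleting", "as_written")) {
  variant <- match.arg(variant)
  stopifnot(is.numeric(lambda), is.numeric(eta), is.numeric(mu),
            is.numeric(delta), length(lambda) == 1, length(eta) == 1,
            length(mu) == 1, length(delta) == 1)
  if (!all(is.finite(c(lambda, eta, mu, delta)))) {
    stop("all rates must be finite", call. = FALSE)
  }
  if (lambda < 0 || mu < 0 || delta < 0) {
    stop("rates lambda, mu, delta must be non-negative", call. = FALSE)
  }
  if (eta <= 0) stop("progression rate eta must be > 0", call. = FALSE)
  k <- as.integer(k)
  if (is.na(k) || k < 1) stop("k must be an integer >= 1", call. = FALSE)
  structure(
    list(lambda = lambda, eta = eta, mu = mu, delta = delta, k = k,
         variant = variant),
    class = "model_params"
  )
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf(
    "<model_params> variant=%s  lambda=%g  eta=%g  mu=%g  delta=%g  k=%d\n",
    x$variant, x$lambda, x$eta, x$mu, x$delta, x$k))
  conv <- params_converge(x)
  cat(sprintf("  yield convergence (t -> Inf): %s\n",
              if (conv) "satisfied" else "violated"))
  invisible(x)
}

# Effective exponential loss rates of each state's occupancy. c_0 cannot
# sporulate; delta is a loss only in the depleting variant.
state_loss_rates <- function(params) {
  dep <- params$variant == "depleting"
  d0 <- params$eta - params$lambda
  di <- params$eta + (if (dep) params$delta else 0) - params$lambda
  ds <- params$mu + (if (dep) params$delta else 0) - params$lambda
  list(d0 = d0, di = di, ds = ds)
}

#' Check the yield-convergence condition
#'
#' The improper integrals defining spore yield and quality converge only if
#' every state's occupancy decays: `lambda < eta` always, plus
#' `lambda < mu` (`as_written`) or `lambda < mu + delta` (`depleting`).
#'
#' @param params A [model_params()] object.
#' @return `TRUE`/`FALSE`.
#' @export
params_converge <- function(params) {
  r <- state_loss_rates(params)
  r$d0 > 0 && r$di > 0 && r$ds > 0
}

assert_convergence <- function(params) {
  if (params$lambda >= params$eta) {
    stop("divergent parameters: requires lambda < eta (growth must be slower ",
         "than cascade progression)", call. = FALSE)
  }
  r <- state_loss_rates(params)
  if (r$ds <= 0) {
    ineq <- if (params$variant == "as_written") "lambda < mu"
            else "lambda < mu + delta"
    stop("divergent parameters: requires ", ineq,
         " (starved-state population must decay)", call. = FALSE)
  }
  invisible(TRUE)
}

#' Carried-over enzyme level at a given sporulation time
#'
#' Enzyme production ceases at the nutrient downshift (`t = 0`); continued
#' growth dilutes the concentration exponentially, `e(t) = exp(-lambda * t)`.
#' A spore formed at time `t` fixes this level.
#'
#' @param t Time since downshift, hours; `>= 0` (vectorised).
#' @param lambda Growth rate, 1/h; `>= 0`.
#' @return Enzyme level(s) in `(0, 1]`.
#' @examples
#' enzyme_level(c(0, 2, 10), lambda = 0.5)
#' @export
enzyme_level <- function(t, lambda) {
  stopifnot(is.numeric(t), is.numeric(lambda), length(lambda) == 1,
            lambda >= 0)
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  exp(-lambda * t)
}

## ---- closed-form cascade solution --------------------------------------
## Each state occupancy is a sum of terms coef * t^pow * exp(-rate * t),
## obtained by iterated convolution of exponentials down the chain.
## Terms are stored as a data.frame(coef, pow, rate).

.term_tol <- 1e-12

# Convolve source terms through a state with loss rate `decay` and inflow
# rate `inflow`: solves x' = inflow * src(t) - decay * x, x(0) = 0.
convolve_terms <- function(src, inflow, decay) {
  out <- list()
  for (i in seq_len(nrow(src))) {
    cf <- inflow * src$coef[i]
    m <- src$pow[i]
    d <- src$rate[i]
    if (abs(decay - d) < .term_tol) {
      out[[length(out) + 1L]] <-
        data.frame(coef = cf / (m + 1), pow = m + 1, rate = d)
    } else {
      Delta <- decay - d
      j <- 0:m
      coefs <- cf * (-1)^(m - j) * exp(lfactorial(m) - lfactorial(j)) /
        Delta^(m - j + 1)
      out[[length(out) + 1L]] <- data.frame(coef = coefs, pow = j, rate = d)
      out[[length(out) + 1L]] <-
        data.frame(coef = -cf * (-1)^m * factorial(m) / Delta^(m + 1),
                   pow = 0, rate = decay)
    }
  }
  merge_terms(do.call(rbind, out))
}

merge_terms <- function(tm) {
  key <- paste(tm$pow, signif(tm$rate, 15))
  agg <- stats::aggregate(tm$coef, by = list(key = key), FUN = sum)
  first <- !duplicated(key)
  ref <- tm[first, c("pow", "rate")]
  ref$key <- key[first]
  m <- merge(ref, agg, by = "key")
  data.frame(coef = m$x, pow = m$pow, rate = m$rate)
}

# List of term tables for c_0, c_1, ..., c_k, c_s.
cascade_terms <- function(params) {
  r <- state_loss_rates(params)
  terms <- vector("list", params$k + 2L)
  terms[[1]] <- data.frame(coef = 1, pow = 0, rate = r$d0)
  for (i in seq_len(params$k)) {
    terms[[i + 1]] <- convolve_terms(terms[[i]], params$eta, r$di)
  }
  terms[[params$k + 2L]] <-
    convolve_terms(terms[[params$k + 1L]], params$eta, r$ds)
  names(terms) <- c(paste0("c_", 0:params$k), "c_s")
  terms
}

eval_terms <- function(tm, t) {
  v <- numeric(length(t))
  for (i in seq_len(nrow(tm))) {
    v <- v + tm$coef[i] * t^tm$pow[i] * exp(-tm$rate[i] * t)
  }
  v
}

# Integral of terms over [0, T] (T = Inf allowed); requires all rates > 0.
integrate_terms <- function(tm, upper = Inf) {
  full <- tm$coef * exp(lfactorial(tm$pow)) / tm$rate^(tm$pow + 1)
  if (is.infinite(upper)) return(sum(full))
  sum(full * stats::pgamma(tm$rate * upper, tm$pow + 1))
}

# Spore-formation rate r(t) = delta * (sum_i c_i + c_s) as a term table.
spor_rate_terms <- function(params) {
  tms <- cascade_terms(params)
  src <- do.call(rbind, tms[-1])
  src$coef <- src$coef * params$delta
  merge_terms(src)
}

#' Solve the cascade state occupancies over time
#'
#' Returns the occupancies `c_0(t), ..., c_k(t), c_s(t)` (per initial cell,
#' with `c_0(0) = 1`) and the spore-formation rate
#' `r(t) = delta * (c_1 + ... + c_k + c_s)` on a time grid. The default
#' method evaluates the exact closed-form solution of the linear cascade
#' (iterated convolution of exponentials); `method = "ode"` integrates the
#' same equations numerically with [deSolve::ode()] as an independent route.
#'
#' @param params A [model_params()] object.
#' @param times Numeric grid, starting at 0, strictly increasing.
#' @param method `"closed_form"` (default) or `"ode"`.
#' @return A tibble of class `spore_trajectory` with columns `time`,
#'   `c_0..c_k`, `c_s`, `spor_rate`.
#' @examples
#' p <- model_params(0.5, 1, 1, 0.5)
#' tr <- solve_trajectories(p, seq(0, 20, by = 0.5))
#' head(tr)
#' @export
solve_trajectories <- function(params, times,
                               method = c("closed_form", "ode")) {
  method <- match.arg(method)
  stopifnot(inherits(params, "model_params"), is.numeric(times),
            length(times) >= 1)
  if (times[1] != 0) stop("time grid must start at 0", call. = FALSE)
  if (length(times) > 1 && any(diff(times) <= 0)) {
    stop("time grid must be strictly increasing", call. = FALSE)
  }
  nm <- c(paste0("c_", 0:params$k), "c_s")
  if (method == "closed_form") {
    tms <- cascade_terms(params)
    occ <- vapply(tms, eval_terms, numeric(length(times)), t = times)
    occ <- matrix(occ, nrow = length(times), dimnames = list(NULL, nm))
  } else {
    dep <- params$variant == "depleting"
    rhs <- function(t, y, p) {
      k <- params$k
      dy <- numeric(k + 2)
      dy[1] <- (params$lambda - params$eta) * y[1]
      loss_i <- params$lambda - params$eta - (if (dep) params$delta else 0)
      for (i in seq_len(k)) dy[i + 1] <- params$eta * y[i] + loss_i * y[i + 1]
      loss_s <- params$lambda - params$mu - (if (dep) params$delta else 0)
      dy[k + 2] <- params$eta * y[k + 1] + loss_s * y[k + 2]
      list(dy)
    }
    y0 <- c(1, rep(0, params$k + 1))
    sol <- deSolve::ode(y0, times, rhs, parms = NULL, method = "lsoda",
                        rtol = 1e-11, atol = 1e-13)
    occ <- unname(sol[, -1, drop = FALSE])
    colnames(occ) <- nm
  }
  spor_rate <- params$delta * rowSums(occ[, -1, drop = FALSE])
  out <- tibble::as_tibble(as.data.frame(occ))
  out <- tibble::add_column(out, time = times, .before = 1)
  out$spor_rate <- spor_rate
  class(out) <- c("spore_trajectory", class(out))
  attr(out, "params") <- params
  out
}

#' Spore yield (quantity): expected spores per initial cell
#'
#' Integrates the spore-formation rate to `t -> Inf`:
#' `s = integral_0^Inf r(t) dt`. The closed form uses the chain-integral
#' identity of linear cascades (each state's time integral is the inflow
#' integral times inflow rate over its own loss rate); `"quadrature"`
#' cross-checks by adaptive quadrature of the exact `r(t)`.
#'
#' @inheritParams solve_trajectories
#' @param method `"closed_form"` (default) or `"quadrature"`.
#' @return Spore yield `s` (scalar).
#' @examples
#' spore_yield(model_params(0.5, 1, 1, 1, variant = "as_written")) # 28
#' @export
spore_yield <- function(params, method = c("closed_form", "quadrature")) {
  method <- match.arg(method)
  stopifnot(inherits(params, "model_params"))
  assert_convergence(params)
  if (params$delta == 0) {
    warning("delta = 0: no sporulation channel, yield is 0", call. = FALSE)
    return(0)
  }
  if (method == "closed_form") {
    ints <- chain_integrals(params, weight_lambda = 0)
    params$delta * sum(ints[-1])
  } else {
    rfun <- make_spor_rate_fun(params)
    stats::integrate(rfun, 0, Inf, rel.tol = 1e-10,
                     abs.tol = 1e-12)$value
  }
}

# Time integrals of c_0..c_k, c_s, optionally weighted by exp(-w * t).
# With weight w the loss rate of each state is shifted by +w.
chain_integrals <- function(params, weight_lambda = 0) {
  r <- state_loss_rates(params)
  w <- weight_lambda
  I <- numeric(params$k + 2L)
  I[1] <- 1 / (r$d0 + w)
  for (i in seq_len(params$k)) I[i + 1] <- params$eta * I[i] / (r$di + w)
  I[params$k + 2L] <- params$eta * I[params$k + 1L] / (r$ds + w)
  I
}

make_spor_rate_fun <- function(params) {
  tm <- spor_rate_terms(params)
  function(t) eval_terms(tm, t)
}

#' Mean enzyme level per spore (quality)
#'
#' The average carried-over enzyme level over the whole spore population:
#' `ebar = (1/s) * integral_0^Inf e(t) r(t) dt`, equivalently
#' `integral e * rho(e) de`. The closed form uses the weighted
#' chain-integral identity; `"quadrature"` cross-checks numerically.
#'
#' @inheritParams spore_yield
#' @return Mean enzyme level `ebar` in `[0, 1]`.
#' @examples
#' mean_enzyme(model_params(0.5, 1, 1, 0.5)) # ~0.23457
#' @export
mean_enzyme <- function(params, method = c("closed_form", "quadrature")) {
  method <- match.arg(method)
  stopifnot(inherits(params, "model_params"))
  assert_convergence(params)
  if (params$delta == 0) {
    stop("mean enzyme level is undefined when the spore yield is 0 (delta = 0)",
         call. = FALSE)
  }
  s <- spore_yield(params)
  if (method == "closed_form") {
    J <- chain_integrals(params, weight_lambda = params$lambda)
    params$delta * sum(J[-1]) / s
  } else {
    rfun <- make_spor_rate_fun(params)
    num <- stats::integrate(function(t) exp(-params$lambda * t) * rfun(t),
                            0, Inf, rel.tol = 1e-10, abs.tol = 1e-12)$value
    num / s
  }
}

#' Enzyme-level density of the spore population
#'
#' Change of variable `e = exp(-lambda * t)` applied to the normalized
#' spore-formation rate gives the density of carried-over enzyme levels,
#' `rho(e) = r(-log(e)/lambda) / (lambda * e * s)` on `(0, 1]`. `rho(1) = 0`
#' because `r(0) = 0`.
#'
#' @inheritParams spore_yield
#' @param e_grid Strictly increasing grid of enzyme levels in `(0, 1]`.
#' @return A tibble of class `enzyme_density` with columns `e`, `density`,
#'   and attribute `norm_check` (numerical integral of the density over the
#'   grid; close to 1 for a grid covering `(0, 1]`).
#' @examples
#' p <- model_params(0.5, 1, 1, 0.5)
#' rho <- enzyme_density(p, seq(1e-4, 1, length.out = 200))
#' @export
enzyme_density <- function(params, e_grid = seq(1e-4, 1, length.out = 512)) {
  stopifnot(inherits(params, "model_params"))
  if (params$lambda == 0) {
    stop("lambda = 0: enzyme level is degenerate at e = 1 (no dilution); ",
         "use mean_enzyme(), which is exactly 1", call. = FALSE)
  }
  assert_convergence(params)
  if (any(e_grid <= 0) || any(e_grid > 1)) {
    stop("e_grid values must lie in (0, 1]", call. = FALSE)
  }
  s <- spore_yield(params)
  rfun <- make_spor_rate_fun(params)
  t_of_e <- -log(e_grid) / params$lambda
  dens <- rfun(t_of_e) / (params$lambda * e_grid * s)
  # quadrature of the exact density over (0, 1] for the normalization check
  norm <- stats::integrate(function(e) rfun(-log(e) / params$lambda) /
                             (params$lambda * e * s),
                           0, 1, rel.tol = 1e-9)$value
  out <- tibble::tibble(e = e_grid, density = dens)
  class(out) <- c("enzyme_density", class(out))
  attr(out, "params") <- params
  attr(out, "norm_check") <- norm
  out
}

#' Cumulative distribution function of spore enzyme levels
#'
#' Returns a vectorised CDF `F(e)` of the enzyme level among spores:
#' `F(e) = 1 - (spores formed before t(e)) / s` with `t(e) = -log(e)/lambda`.
#' Useful as the reference distribution in goodness-of-fit tests against
#' simulated spore populations.
#'
#' @inheritParams enzyme_density
#' @return A function of `e` in `[0, 1]`.
#' @export
enzyme_cdf <- function(params) {
  stopifnot(inherits(params, "model_params"))
  if (params$lambda == 0) {
    stop("lambda = 0: enzyme level is degenerate at e = 1", call. = FALSE)
  }
  assert_convergence(params)
  s <- spore_yield(params)
  tm <- spor_rate_terms(params)
  function(e) {
    e <- pmin(pmax(e, 0), 1)
    vapply(e, function(ei) {
      if (ei == 0) return(0)
      Tup <- -log(ei) / params$lambda
      1 - integrate_terms(tm, upper = Tup) / s
    }, numeric(1))
  }
}

#' Sweep a model parameter and record the quantity-quality tradeoff
#'
#' Recomputes spore yield `s` and spore quality `ebar` for each value of one
#' swept rate parameter, emulating experimental tuning of sporulation timing
#' (e.g. KinA/RapA induction). Values are reported in input order. Any
#' parameter set violating the convergence condition aborts the sweep with
#' the offending values named.
#'
#' @param params Base [model_params()].
#' @param param_name One of `"delta"`, `"eta"`, `"lambda"`, `"mu"`.
#' @param values Numeric vector of parameter values.
#' @return A tibble of class `sweep_result` with columns `param_name`,
#'   `param_value`, `yield_s`, `quality_ebar`, `variant`.
#' @examples
#' p <- model_params(0.5, 1, 1, 0.5)
#' sweep_tradeoff(p, "delta", c(0.5, 1, 2))
#' @export
sweep_tradeoff <- function(params, param_name, values) {
  stopifnot(inherits(params, "model_params"))
  param_name <- match.arg(param_name, c("delta", "eta", "lambda", "mu"))
  stopifnot(is.numeric(values), length(values) >= 1)
  plist <- purrr::map(values, function(v) {
    p <- params
    p[[param_name]] <- v
    model_params(p$lambda, p$eta, p$mu, p$delta, p$k, p$variant)
  })
  bad <- !purrr::map_lgl(plist, params_converge)
  if (any(bad)) {
    stop("divergent sweep points at ", param_name, " = ",
         paste(values[bad], collapse = ", "),
         " (yield integral does not converge)", call. = FALSE)
  }
  out <- tibble::tibble(
    param_name = param_name,
    param_value = values,
    yield_s = purrr::map_dbl(plist, spore_yield),
    quality_ebar = purrr::map_dbl(plist, mean_enzyme),
    variant = params$variant
  )
  class(out) <- c("sweep_result", class(out))
  out
}

#' Read model parameters from a YAML or JSON config file
#'
#' Expects keys `lambda`, `eta`, `mu`, `delta` and optionally `k`, `variant`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [model_params()] object.
#' @export
read_model_params <- function(path) {
  cfg <- read_config_file(path)
  need <- c("lambda", "eta", "mu", "delta")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) {
    stop("config is missing keys: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  model_params(cfg$lambda, cfg$eta, cfg$mu, cfg$delta,
               k = cfg$k %||% 2,
               variant = cfg$variant %||% "depleting")
}

read_config_file <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}
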