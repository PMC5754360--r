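test_that("enzyme level is the exponential dilution curve", {
  expect_equal(enzyme_level(0, 0.5), 1)
  expect_equal(enzyme_level(7.3, 0), 1)
  expect_equal(enzyme_level(2, 0.5), exp(-1))
  t <- seq(0, 30, by = 0.5)
  expect_true(all(diff(enzyme_level(t, 0.3)) <= 0))
  expect_error(enzyme_level(-1, 0.5), "non-negative")
})

test_that("parameter validation and convergence predicate work", {
  expect_error(model_params(-0.1, 1, 1, 1), "non-negative")
  expect_error(model_params(0.5, 0, 1, 1), "eta")
  expect_error(model_params(0.5, 1, 1, 1, k = 0), "k must be")
  # as_written needs lambda < mu; depleting only lambda < mu + delta
  expect_false(params_converge(model_params(0.5, 1, 0.2, 1,
                                            variant = "as_written")))
  expect_true(params_converge(model_params(0.5, 1, 0.2, 1)))
  expect_error(spore_yield(model_params(0.5, 1, 0.2, 1,
                                        variant = "as_written")),
               "lambda < mu")
  expect_error(spore_yield(model_params(1.2, 2, 0.5, 0.5)),
               "lambda < mu \\+ delta")
  expect_error(spore_yield(model_params(1.5, 1.2, 9, 9)), "lambda < eta")
})

test_that("closed-form trajectories match hand solutions of the cascade", {
  times <- seq(0, 12, by = 0.25)
  # as_written, lambda=0.5, eta=1, k=2: repeated-rate chain
  tr <- solve_trajectories(model_params(0.5, 1, 1, 1,
                                        variant = "as_written"), times)
  expect_equal(tr$c_0, exp(-0.5 * times), tolerance = 1e-12)
  expect_equal(tr$c_1, times * exp(-0.5 * times), tolerance = 1e-12)
  expect_equal(tr$c_2, times^2 / 2 * exp(-0.5 * times), tolerance = 1e-12)
  # depleting, delta=0.5: distinct-rate integrating-factor solution
  trd <- solve_trajectories(p_dep(0.5), times)
  expect_equal(trd$c_1, 2 * exp(-0.5 * times) * (1 - exp(-0.5 * times)),
               tolerance = 1e-12)
  # initial condition and r(0) = 0
  expect_equal(unlist(trd[1, c("c_0", "c_1", "c_2", "c_s", "spor_rate")],
                      use.names = FALSE), c(1, 0, 0, 0, 0))
  expect_true(all(as.matrix(trd[-1]) >= 0))
  expect_error(solve_trajectories(p_dep(), c(0, 2, 1)), "increasing")
  expect_error(solve_trajectories(p_dep(), c(1, 2)), "start at 0")
})

test_that("closed-form and ODE trajectories agree to 1e-8 relative", {
  times <- seq(0, 15, by = 0.5)
  for (p in param_grid()) {
    a <- as.matrix(solve_trajectories(p, times)[-1])
    b <- as.matrix(solve_trajectories(p, times, method = "ode")[-1])
    expect_lt(max(abs(a - b) / pmax(abs(a), 1)), 1e-8)
  }
})

test_that("spore yield matches hand-derived closed forms", {
  expect_equal(spore_yield(p_aw()), 28, tolerance = 1e-12)
  expect_equal(spore_yield(p_dep(0.5)), 3, tolerance = 1e-12)
  expect_equal(spore_yield(p_dep(2)), 2.496, tolerance = 1e-10)
  # first-step analysis oracle for lambda = 0 (embedded jump chain):
  # P(spore) from c_1, c_2 is delta/(delta+eta), from c_s delta/(delta+mu)
  expect_equal(spore_yield(model_params(0, 1, 1, 1)), 0.875,
               tolerance = 1e-12)
  # no growth, no death: every founder sporulates exactly once
  for (eta in c(0.5, 1, 3)) {
    for (delta in c(0.2, 1)) {
      expect_equal(spore_yield(model_params(0, eta, 0, delta, k = 3)), 1,
                   tolerance = 1e-12)
    }
  }
  expect_warning(s0 <- spore_yield(model_params(0.5, 1, 1, 0)), "delta = 0")
  expect_equal(s0, 0)
})

test_that("mean enzyme level matches hand-derived closed forms", {
  expect_equal(mean_enzyme(p_aw()), 3 / 28, tolerance = 1e-12)
  expect_equal(mean_enzyme(p_dep(0.5)), 19 / 81, tolerance = 1e-12)
  expect_equal(mean_enzyme(p_dep(2)), (26 / 27) / 2.496, tolerance = 1e-10)
  # lambda = 0: no dilution, quality exactly 1 in both variants
  expect_equal(mean_enzyme(model_params(0, 1, 1, 1)), 1, tolerance = 1e-14)
  expect_equal(mean_enzyme(model_params(0, 1, 2, 1, variant = "as_written")),
               1, tolerance = 1e-14)
  expect_error(mean_enzyme(model_params(0.5, 1, 1, 0)), "undefined")
})

test_that("closed-form and quadrature routes agree to 1e-8 relative", {
  for (p in param_grid()) {
    expect_lt(rel_diff(spore_yield(p), spore_yield(p, "quadrature")), 1e-8)
    expect_lt(rel_diff(mean_enzyme(p), mean_enzyme(p, "quadrature")), 1e-8)
  }
})

test_that("as_written yield is linear in delta and quality independent of it", {
  base <- model_params(0.5, 1, 1, 1, variant = "as_written")
  sw <- sweep_tradeoff(base, "delta", c(0.1, 1, 10))
  expect_lt(max(abs(sw$quality_ebar - sw$quality_ebar[1])), 1e-10)
  s_over_delta <- sw$yield_s / sw$param_value
  expect_lt(max(abs(s_over_delta - s_over_delta[1])), 1e-10)
})

test_that("depleting variant shows the quantity-quality tradeoff in delta", {
  base <- p_dep()
  grid <- seq(0.5, 4, by = 0.25)
  sw <- sweep_tradeoff(base, "delta", grid)
  expect_true(all(diff(sw$quality_ebar) >= 0))
  # region where yield strictly falls while quality strictly rises
  trade <- diff(sw$yield_s) < 0 & diff(sw$quality_ebar) > 0
  expect_true(any(trade))
  # spec'd endpoint pair
  sw2 <- sweep_tradeoff(base, "delta", c(0.5, 2))
  expect_equal(sw2$yield_s, c(3, 2.496), tolerance = 1e-10)
  expect_equal(sw2$quality_ebar, c(19 / 81, (26 / 27) / 2.496),
               tolerance = 1e-10)
})

test_that("sweep preserves input order and reports divergent points by value", {
  vals <- c(2, 0.5, 1)
  sw <- sweep_tradeoff(p_dep(), "delta", vals)
  expect_equal(sw$param_value, vals)
  expect_error(
    sweep_tradeoff(model_params(0.5, 1, 0.2, 0.5), "delta", c(0.5, 0.1, 1)),
    "0.1")
})

test_that("enzyme density normalizes, reproduces the mean, vanishes at e = 1", {
  for (p in list(p_dep(0.5), p_dep(2), p_aw(),
                 model_params(0.3, 1.5, 0.1, 0.8, k = 4))) {
    d <- enzyme_density(p)
    expect_lt(abs(attr(d, "norm_check") - 1), 1e-6)
    expect_equal(d$density[d$e == 1], 0)
    ebar_rho <- stats::integrate(
      function(e) e * approx_density(p, e), 0, 1, rel.tol = 1e-9)$value
    expect_lt(abs(ebar_rho - mean_enzyme(p)), 1e-6)
  }
  expect_error(enzyme_density(model_params(0, 1, 1, 1)), "degenerate")
  expect_error(enzyme_density(p_dep(), e_grid = c(0, 0.5)), "\\(0, 1\\]")
})

test_that("enzyme CDF is a proper CDF consistent with the density", {
  p <- p_dep()
  FF <- enzyme_cdf(p)
  e <- seq(0.01, 1, by = 0.01)
  Fe <- FF(e)
  expect_true(all(diff(Fe) >= -1e-12))
  expect_equal(FF(1), 1, tolerance = 1e-10)
  expect_equal(FF(0), 0)
  # numerical derivative of the CDF matches rho(e)
  d <- enzyme_density(p, e_grid = seq(0.1, 0.9, by = 0.1))
  dF <- (FF(d$e + 1e-5) - FF(d$e - 1e-5)) / 2e-5
  expect_equal(dF, d$density, tolerance = 1e-5)
})

test_that("model parameters round-trip through config files", {
  p <- model_params(0.4, 1.2, 0.9, 0.7, k = 3, variant = "as_written")
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(lambda = 0.4, eta = 1.2, mu = 0.9, delta = 0.7,
                        k = 3, variant = "as_written"), path)
  expect_equal(read_model_params(path), p)
  jpath <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(lambda = 0.4, eta = 1.2, mu = 0.9, delta = 0.7),
                       jpath, auto_unbox = TRUE)
  p2 <- read_model_params(jpath)
  expect_equal(p2$k, 2L)
  expect_equal(p2$variant, "depleting")
  expect_error(read_model_params(path = withr::local_tempfile()), "no such")
})
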