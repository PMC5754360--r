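# Shared parameter sets and small builders used across the suite.

# reference parameter sets with hand-derived closed-form solutions
p_aw <- function() model_params(0.5, 1, 1, 1, variant = "as_written")
p_dep <- function(delta = 0.5) model_params(0.5, 1, 1, delta)

# a small grid of convergent parameter sets spanning both variants
param_grid <- function() {
  list(
    model_params(0.5, 1, 1, 1, variant = "as_written"),
    model_params(0.2, 1, 0.5, 0.3, k = 1, variant = "as_written"),
    model_params(0.4, 2, 0.8, 1.5, k = 3, variant = "as_written"),
    model_params(0.5, 1, 1, 0.5),
    model_params(0.5, 1, 1, 2),
    model_params(0.2, 1, 1, 0.5),
    model_params(0.3, 1.5, 0.1, 0.8, k = 4),
    model_params(0, 1, 1, 1),
    model_params(0.9, 1, 0.2, 1.2)
  )
}

rel_diff <- function(a, b) abs(a - b) / pmax(abs(a), abs(b), 1e-300)

# vectorized evaluation of the enzyme-level density at arbitrary e
approx_density <- function(p, e) enzyme_density(p, e_grid = e)$density

# a simulation that produces no spores (no sporulation channel)
s0_empty_spores <- function() {
  suppressWarnings(
    simulate_population(model_params(0.3, 1, 1, 0), sim_config(50, seed = 1)))
}

# small, fast generator config for statistical tests
quick_config <- function(seed = 1, n_colonies = 8, spores_per_colony = 125,
                         ...) {
  generator_config(seed = seed, n_colonies = n_colonies,
                   spores_per_colony = spores_per_colony, ...)
}
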