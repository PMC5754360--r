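test_that("time classification applies the strict 20-h threshold", {
  rec <- tibble::tibble(t_spor_h = c(15, 20, 19.999, 25))
  out <- classify_by_time(rec)
  expect_equal(as.character(out$group), c("early", "late", "early", "late"))
  # configurable threshold
  out2 <- classify_by_time(rec, threshold = 16)
  expect_equal(as.character(out2$group), c("early", "late", "late", "late"))
  expect_error(classify_by_time(tibble::tibble(x = 1)), "t_spor_h")
  # under generator defaults the true labels are recovered
  tab <- classify_by_time(generate_spore_table(quick_config(seed = 2)))
  expect_gte(mean(tab$group == tab$group_true), 0.99)
})

test_that("fluorescence classification: median and valley methods agree", {
  # symmetric synthetic bimodal sample
  x <- withr::with_seed(1, {
    exp(c(stats::rnorm(500, 2, 0.4), stats::rnorm(500, 5, 0.4)))
  })
  rec <- tibble::tibble(fluor_rapa = x)
  med <- classify_by_fluorescence(rec, "median")
  val <- classify_by_fluorescence(rec, "valley")
  expect_gte(mean(med$group == val$group), 0.95)
  # degenerate constant column: all at the median, tie rule gives all early
  const <- tibble::tibble(fluor_rapa = rep(3, 20))
  expect_true(all(classify_by_fluorescence(const, "median")$group ==
                    "early"))
  expect_error(classify_by_fluorescence(const, "valley"), "constant")
  expect_error(classify_by_fluorescence(rec[1:5, ]), "at least 10")
  # recovers true groups on generated data
  tab <- generate_spore_table(quick_config(seed = 3, n_colonies = 8,
                                           spores_per_colony = 125))
  cl <- classify_by_fluorescence(tab, "median")
  expect_gte(mean(cl$group == cl$group_true), 0.90)
})

test_that("revival frequencies are exact ratios with guarded edge cases", {
  rc <- revival_counts(N_s = 20, N_g = 18, N_o = 9)
  expect_equal(rc$f_r, 0.45)
  expect_equal(rc$f_g, 0.9)
  expect_equal(rc$f_o, 0.5)
  # N_g = 0: outgrowth frequency undefined, not 0
  rc0 <- revival_counts(N_s = 10, N_g = 0, N_o = 0)
  expect_true(is.na(rc0$f_o))
  expect_equal(rc0$f_r, 0)
  expect_equal(rc0$f_g, 0)
  expect_error(revival_counts(N_s = 5, N_g = 6, N_o = 1), "N_o <= N_g <= N_s")
  expect_error(revival_counts(N_s = 5, N_g = 3, N_o = 4), "N_o <= N_g <= N_s")
})

test_that("f_r = f_g * f_o on random valid count triples", {
  withr::with_seed(10, {
    for (i in 1:200) {
      N_s <- sample(1:500, 1)
      N_g <- sample(1:N_s, 1)
      N_o <- sample(0:N_g, 1)
      rc <- revival_counts(N_s, N_g, N_o)
      expect_equal(rc$f_r, rc$f_g * rc$f_o, tolerance = 1e-12)
    }
  })
})

test_that("germination curves are monotone and terminate at f_g", {
  tab <- classify_by_time(generate_spore_table(quick_config(seed = 4)))
  cur <- germination_curve(tab)
  for (g in c("early", "late")) {
    fr <- cur$fraction[cur$group == g]
    expect_true(all(diff(fr) >= 0))
    expect_true(all(fr >= 0 & fr <= 1))
    summ <- revival_frequencies(tab)
    expect_equal(fr[length(fr)], summ$f_g[summ$group == g],
                 tolerance = 1e-12)
  }
  # no germination: flat zero curve
  none <- tab
  none$germinated <- FALSE; none$t_germ_h <- NA_real_
  none$outgrown <- FALSE
  expect_true(all(germination_curve(none)$fraction == 0))
  expect_error(germination_curve(tab, grid = c(0, 1, 2)), "superset")
})

test_that("early spores germinate about twice as fast as late spores", {
  cfg <- quick_config(seed = 5, n_colonies = 8, spores_per_colony = 125)
  tab <- classify_by_time(generate_spore_table(cfg))
  ht <- germination_half_time(germination_curve(tab))
  ratio <- ht$half_time[ht$group == "late"] /
    ht$half_time[ht$group == "early"]
  expect_gte(ratio, 1.7)
  expect_lte(ratio, 2.3)
})

test_that("yield and quality recover the model's quantity and quality", {
  rec <- tibble::tibble(fluor_ald = rep(2, 50))
  yq <- yield_and_quality(rec, colony_area = 10)
  expect_equal(yq$Y, 5)
  expect_equal(yq$Q, 2)
  expect_error(yield_and_quality(rec, 0), "colony_area")
  # noise-free reporter: Q = E0 * mean enzyme
  cfg <- quick_config(seed = 6, sigma_ald = 0)
  tab <- generate_spore_table(cfg)
  yq2 <- yield_and_quality(tab, colony_area = 1)
  expect_equal(yq2$Q, cfg$E0 * mean(tab$enzyme), tolerance = 1e-12)
  # mechanistic generator: Q/E0 estimates the model's mean enzyme level
  p <- model_params(0.5, 1, 1, 0.5)
  mcfg <- quick_config(seed = 7, mode = "mechanistic", n_colonies = 4,
                       founders_per_colony = 2500)
  mtab <- suppressWarnings(generate_spore_table(mcfg, model_params = p))
  se <- stats::sd(mtab$fluor_ald / mcfg$E0) / sqrt(nrow(mtab))
  expect_lt(abs(mean(mtab$fluor_ald) / mcfg$E0 - mean_enzyme(p)), 3 * se)
})

test_that("wild-type normalization is a guarded elementwise ratio", {
  expect_equal(normalize_to_wt(6, 3), 2)
  expect_equal(normalize_to_wt(3, 3), 1)
  # invariance under common rescaling of raw units
  v <- c(2, 4, 8)
  expect_equal(normalize_to_wt(v * 17.3, 4 * 17.3), normalize_to_wt(v, 4))
  expect_error(normalize_to_wt(1, 0), "positive")
  expect_error(normalize_to_wt(1, -2), "positive")
})

test_that("the unpaired t test matches the hand-computed Welch oracle", {
  # A=(1,2,3), B=(2,3,4): means 2,3; var 1,1
  # t = -1 / sqrt(1/3 + 1/3) = -1.224745; df = (2/3)^2 / (2 * (1/9)) = 4
  tt <- unpaired_t_test(c(1, 2, 3), c(2, 3, 4))
  expect_equal(tt$statistic, -1.224745, tolerance = 1e-6)
  expect_equal(tt$df, 4, tolerance = 1e-12)
  expect_equal(tt$p_value, 2 * stats::pt(-1.224745, 4), tolerance = 1e-6)
  expect_equal(tt$p_value, 0.2878, tolerance = 1e-3)
  expect_equal(tt$stars, "ns")
  # identical groups: t = 0, p = 1
  t0 <- unpaired_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p_value, 1)
  # pooled variant agrees with base R
  tp <- unpaired_t_test(c(1, 2, 3, 7), c(2, 3, 4), welch = FALSE)
  ref <- stats::t.test(c(1, 2, 3, 7), c(2, 3, 4), var.equal = TRUE)
  expect_equal(tp$statistic, unname(ref$statistic))
  expect_equal(tp$df, 5)
  expect_error(unpaired_t_test(1, c(1, 2)), "at least 2")
  expect_error(unpaired_t_test(c(2, 2, 2), c(3, 3, 3)), "zero variance")
  td <- tidy(tt)
  expect_equal(td$p.value, tt$p_value)
  expect_equal(glance(tt)$df, tt$df)
})

test_that("significance stars map p values at the exact boundaries", {
  expect_equal(significance_stars(c(0.05, 0.01, 0.001, 0.0001, 0.051, 1)),
               c("*", "**", "***", "****", "ns", "ns"))
})

test_that("tradeoff rank correlation handles monotone and degenerate input", {
  expect_equal(tradeoff_correlation(c(1, 2, 3, 4), c(8, 6, 4, 2))$rho, -1)
  expect_equal(tradeoff_correlation(c(1, 2, 3, 4, 5), c(1, 3, 4, 7, 9))$rho,
               1)
  expect_error(tradeoff_correlation(c(1, 2, 3, 4), c(2, 2, 2, 2)),
               "constant")
  expect_error(tradeoff_correlation(c(1, 2, 3), c(3, 2, 1)), "at least 4")
  td <- tidy(tradeoff_correlation(c(1, 2, 3, 4), c(8, 6, 4, 2)))
  expect_equal(td$estimate, -1)
})

test_that("statistics are invariant to row order and colony partitioning", {
  tab <- classify_by_time(generate_spore_table(quick_config(seed = 8)))
  shuffled <- withr::with_seed(1, tab[sample(nrow(tab)), ])
  a <- revival_frequencies(tab)
  b <- revival_frequencies(shuffled)
  expect_equal(as.data.frame(a), as.data.frame(b))
  # repartitioning colonies leaves pooled group frequencies unchanged
  repart <- tab
  repart$colony_id <- rep_len(c("x1", "x2", "x3"), nrow(tab))
  expect_equal(as.data.frame(revival_frequencies(repart)),
               as.data.frame(a))
  expect_equal(germination_curve(shuffled), germination_curve(tab))
})
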