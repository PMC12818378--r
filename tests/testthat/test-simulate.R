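test_that("default configuration reproduces the designed study structure", {
  cfg <- sim_config(seed = 3)
  ctl <- simulate_condition(cfg, "CTL")
  expect_equal(nrow(ctl), 5000L)
  expect_equal(as.vector(table(ctl$subgroup)), rep(1000L, 5))
  fib <- compute_fiber_and_g(ctl)
  expect_true(all(fib$fiber_diameter <= cfg$fiber_cap))
  expect_true(all(ctl$true_g >= 0.65 & ctl$true_g <= 0.95))
  withext <- append_extremes(ctl, cfg)
  expect_equal(nrow(withext), 5500L)
  expect_equal(sum(withext$is_extreme), 500L)
})

test_that("the pipeline g equals the drawn ground-truth g exactly", {
  cfg <- small_config(seed = 13)
  rec <- simulate_condition(cfg, "EXP")
  fib <- compute_fiber_and_g(rec)
  expect_lt(max(abs(fib$g_ratio - rec$true_g)), 1e-12)
})

test_that("generation is bit-reproducible and seed-sensitive", {
  cfg <- small_config(seed = 21)
  a <- simulate_condition(cfg, "CTL")
  b <- simulate_condition(cfg, "CTL")
  expect_identical(a, b)
  expect_identical(append_extremes(a, cfg), append_extremes(b, cfg))
  c2 <- simulate_condition(small_config(seed = 22), "CTL")
  expect_false(identical(a, c2))
  # CTL and EXP streams differ
  expect_false(identical(a$axon_diameter,
                         simulate_condition(cfg, "EXP")$axon_diameter))
})

test_that("extreme rows sit below both cleaning thresholds by construction", {
  cfg <- small_config(seed = 31)
  rec <- append_extremes(simulate_condition(cfg, "CTL"), cfg)
  ext <- rec[rec$is_extreme, ]
  expect_true(all(ext$axon_diameter < 0.15))
  expect_true(all(ext$myelin_total / 2 < 0.03))       # one-sided m
  expect_equal(ext$true_g,
               ext$axon_diameter / (ext$axon_diameter + ext$myelin_total))
  # every appended row fails the axon filter
  out <- clean_measurements(rec)
  expect_true(all(ext$source_row %in%
                    out$log$source_row[out$log$reason == "axon_below_min"]))
})

test_that("sensitivity delta is zero without extremes and small with them", {
  cfg <- small_config(seed = 43)
  base <- simulate_condition(cfg, "CTL")
  expect_equal(sensitivity_delta(base)$delta, 0)
  withext <- append_extremes(base, cfg)
  d <- sensitivity_delta(withext)
  expect_equal(d$delta, abs(d$mean_with - d$mean_without))
  expect_lt(d$delta, 0.05)
})

test_that("subgroup means recover their imposed offsets", {
  cfg <- sim_config(seed = 101)
  rec <- simulate_condition(cfg, "CTL")
  for (s in 1:5) {
    g <- rec$true_g[rec$subgroup == s]
    mu <- implied_subgroup_mean_g(0.70 + cfg$subgroup_offsets[s], cfg)
    se <- sd(g) / sqrt(length(g))
    expect_lt(abs(mean(g) - mu), 3 * se)
  }
})

test_that("invalid configurations are rejected up front", {
  expect_error(sim_config(subgroup_offsets = c(0, 0, 0, 0, 0.01)),
               "zero mean")
  expect_error(sim_config(g_bounds = c(0.9, 0.6)))
  expect_error(sim_config(n_baseline = 0))
})

test_that("an infeasible fiber cap aborts with a diagnostic", {
  cfg <- sim_config(n_subgroups = 1, n_baseline = 50, subgroup_offsets = 0,
                    fiber_cap = 0.05, seed = 5, max_redraw_factor = 20)
  expect_error(simulate_condition(cfg, "CTL"), "budget")
})

test_that("the calibrated preset reproduces the 0.3-1.2 um interquartile range", {
  cfg <- sim_config(seed = 9, preset = "calibrated_iqr")
  expect_equal(exp(cfg$axon_log_mu + stats::qnorm(c(0.25, 0.75)) *
                     cfg$axon_log_sigma), c(0.3, 1.2), tolerance = 1e-9)
})
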