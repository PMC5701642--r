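# Experiment driver: tiny configurations so the full stack runs in seconds.

small_config <- function(...) {
  experiment_config(
    modality = "eeg", n_reference_sources = 2, n_nodes = 50,
    perturbation_levels = c(0, 0.1),
    constraints = "unit_array_gain", criteria = c("variance", "kurtosis"),
    orientation_classes = "quasi_tangential",
    noise_levels = c(low = 1e-3), n_replicates = 1,
    master_seed = 77, geometry_seed = 78, ...
  )
}

test_that("the results table has one row per condition and is reproducible", {
  cfg <- small_config()
  geo <- experiment_geometry(cfg)
  tab <- run_experiment(cfg, geo)
  # 2 sources x 2 models x 2 criteria x 1 constraint x 1 noise x 1 orientation
  expect_equal(nrow(tab), 8)
  expect_true(all(!is.na(tab$error)))
  tab2 <- run_experiment(cfg, geo)
  expect_identical(tab, tab2)
  # matched model at low noise localizes at the grid floor
  matched <- subset(tab, model == "perturb_0")
  expect_true(all(matched$error > 0.5 & matched$error < 0.6))
})

test_that("row seeds follow the stated counter scheme", {
  cfg <- small_config()
  geo <- experiment_geometry(cfg)
  tab <- run_experiment(cfg, geo)
  expect_equal(unique(tab$noise_seed[tab$source == 1]), 77 + 1000 * 1 + 1)
  expect_equal(unique(tab$noise_seed[tab$source == 2]), 77 + 1000 * 1 + 2)
})

test_that("summaries cover exactly the non-empty condition groups", {
  cfg <- small_config()
  geo <- experiment_geometry(cfg)
  tab <- run_experiment(cfg, geo)
  s <- summarize_experiment(tab)
  expect_equal(nrow(s), 4) # 2 models x 2 criteria
  expect_true(all(s$n == 2))
  expect_equal(s$median_mm, round(s$median))
  # group inputs are exactly the group's rows
  g <- subset(tab, model == "perturb_0" & criterion == "variance")
  srow <- subset(s, model == "perturb_0" & criterion == "variance")
  expect_equal(srow$median, median(g$error))
})

test_that("the config validates its levels and seeds are explicit", {
  expect_error(experiment_config(modality = "meg", shell_levels = "3C"), "EEG")
  expect_error(experiment_config(shell_levels = "nope"), "unknown cascade level")
  expect_error(experiment_config(noise_levels = c(1, 2)), "named")
})
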