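test_that("grid-to-county aggregation is the renormalized overlap-weighted mean", {
  cells <- data.frame(cell_id = c("g1", "g2"), delta_t = c(1.0, 3.0))
  ov1 <- data.frame(county_id = "A", cell_id = "g1", weight = 1)
  expect_equal(grid_to_county(cells, ov1)$delta_t, 1.0)
  ov2 <- data.frame(county_id = "A", cell_id = c("g1", "g2"),
                    weight = c(0.25, 0.75))
  expect_equal(grid_to_county(cells, ov2)$delta_t, 2.5)
  set.seed(41)
  cells5 <- data.frame(cell_id = paste0("g", 1:5), delta_t = rnorm(5))
  ov5 <- data.frame(county_id = "A", cell_id = paste0("g", 1:5),
                    weight = runif(5))
  expect_equal(grid_to_county(cells5, ov5)$delta_t,
               sum(ov5$weight * cells5$delta_t) / sum(ov5$weight),
               tolerance = 1e-12)
  ov0 <- data.frame(county_id = "B", cell_id = "g1", weight = 0)
  expect_error(grid_to_county(cells, ov0), "zero grid overlap.*B")
})

test_that("warming paths ramp as configured and start at zero", {
  d <- data.frame(model = "m1", county_id = "A", delta_t = 3.0)
  lin <- build_delta_paths(d, 2020, 2050, ramp = "linear")
  expect_equal(lin$delta_t[lin$year == 2020], 0)
  expect_equal(lin$delta_t[lin$year == 2030], 1.0)
  expect_equal(lin$delta_t[lin$year == 2050], 3.0)
  stp <- build_delta_paths(d, 2020, 2050, ramp = "step")
  expect_equal(stp$delta_t[stp$year == 2020], 0)
  expect_equal(unique(stp$delta_t[stp$year > 2020]), 3.0)
  expect_error(build_delta_paths(d, 2050, 2020), "exceed")
})

test_that("excess deaths follow the closed-form arithmetic and are linear", {
  pp <- data.frame(county_id = "X", year = 2021:2030, population = 1e6)
  dp <- data.frame(county_id = "X", year = 2021:2030, delta_t = 1.0)
  ed <- excess_deaths(pp, dp, beta = 2, beta_scale = 1e7)
  expect_equal(ed$cumulative_excess[10], 24.0, tolerance = 1e-12)
  expect_equal(excess_deaths(pp, dp, beta = 0)$cumulative_excess, rep(0, 10))
  # linearity in beta, population, and warming under random scalings
  set.seed(42)
  for (s in runif(3, 0.2, 5)) {
    expect_equal(excess_deaths(pp, dp, beta = 2 * s, beta_scale = 1e7)$cumulative_excess,
                 s * ed$cumulative_excess, tolerance = 1e-12)
    pp2 <- transform(pp, population = population * s)
    expect_equal(excess_deaths(pp2, dp, beta = 2, beta_scale = 1e7)$cumulative_excess,
                 s * ed$cumulative_excess, tolerance = 1e-12)
    dp2 <- transform(dp, delta_t = delta_t * s)
    expect_equal(excess_deaths(pp, dp2, beta = 2, beta_scale = 1e7)$cumulative_excess,
                 s * ed$cumulative_excess, tolerance = 1e-12)
  }
  expect_error(excess_deaths(pp, dp, beta = 1, beta_scale = -1), "beta_scale")
  expect_error(excess_deaths(pp, dp[dp$year > 2025, ] , beta = 1), NA)
  expect_error(excess_deaths(pp[pp$year > 2025, ], dp, beta = 1), "missing")
})

test_that("a degenerate ensemble reproduces the deterministic projection", {
  sim <- generate_panel(panel_dgp_config(n_counties = 20, n_states = 4,
                                         years = 2013:2017, beta_temp = 1.0,
                                         lag_effects = c("1" = -0.3), seed = 43))
  p <- sim$panel
  counties <- unique(p$county_id)
  deltas <- generate_climate_models(1, counties, delta_mean = 2, delta_sd = 0,
                                    seed = 44)
  pop0 <- stats::setNames(p$population[!duplicated(p$county_id)], counties)
  pops <- generate_population_paths(pop0, 2020, 2030, growth_rate = 0)
  ens <- suppressMessages(project_excess_deaths(
    p, deltas, pops, B = 1, base_year = 2020, end_year = 2030, seed = 45))
  expect_equal(dim(ens$trajectories), c(1L, 11L))
  paths <- build_delta_paths(deltas, 2020, 2030)
  direct <- excess_deaths(pops, paths, beta = ens$beta_hat, beta_scale = 1e7)
  expect_equal(unname(ens$trajectories[1, ]), direct$cumulative_excess,
               tolerance = 1e-10)
})

test_that("a noiseless panel collapses bootstrap spread to the climate models", {
  sim <- generate_panel(panel_dgp_config(n_counties = 15, n_states = 3,
                                         years = 2013:2016, beta_temp = 1.0,
                                         lag_effects = c("1" = -0.3),
                                         noise_sd = 0, seed = 46))
  p <- sim$panel
  counties <- unique(p$county_id)
  deltas <- generate_climate_models(4, counties, seed = 47)
  pop0 <- stats::setNames(p$population[!duplicated(p$county_id)], counties)
  pops <- generate_population_paths(pop0, 2020, 2025)
  ens <- suppressMessages(project_excess_deaths(
    p, deltas, pops, B = 8, base_year = 2020, end_year = 2025, seed = 48))
  expect_equal(max(ens$betas) - min(ens$betas), 0, tolerance = 1e-8)
  expect_equal(unname(ens$betas[1]), 0.7, tolerance = 1e-8)
})

test_that("ensembles are seed-reproducible with B x M trajectories and monotone quantiles", {
  sim <- generate_panel(panel_dgp_config(n_counties = 15, n_states = 3,
                                         years = 2013:2016, seed = 49,
                                         lag_effects = c("1" = -0.3)))
  p <- sim$panel
  counties <- unique(p$county_id)
  deltas <- generate_climate_models(3, counties, seed = 50)
  pop0 <- stats::setNames(p$population[!duplicated(p$county_id)], counties)
  pops <- generate_population_paths(pop0, 2020, 2026)
  run <- function() suppressMessages(project_excess_deaths(
    p, deltas, pops, B = 5, base_year = 2020, end_year = 2026, seed = 51))
  e1 <- run(); e2 <- run()
  expect_identical(e1$trajectories, e2$trajectories)
  expect_equal(nrow(e1$trajectories), 5L * 3L)
  s <- e1$summary
  expect_true(all(s$q2.5 <= s$q25 & s$q25 <= s$median &
                  s$median <= s$q75 & s$q75 <= s$q97.5))
})
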