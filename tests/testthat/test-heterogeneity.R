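test_that("interaction coefficient is null when both groups share a slope", {
  p <- generate_panel(panel_dgp_config(n_counties = 50, n_states = 5,
                                       years = 2013:2019, seed = 31))$panel
  d <- as.numeric(p$precip > stats::weighted.mean(p$precip, p$population))
  ia <- interaction_fit(p, d)
  expect_lt(abs(ia$gamma2$estimate), 3 * ia$gamma2$se)
  expect_false(ia$indicator_absorbed)  # row-level indicator survives demeaning
})

test_that("interaction model recovers a constructed slope difference", {
  sim <- generate_panel(panel_dgp_config(n_counties = 60, n_states = 6,
                                         years = 2013:2020, beta_temp = 1.0,
                                         seed = 32))
  p <- sim$panel
  hot_half <- p$county_id %in% unique(p$county_id)[1:30]
  p$death_rate <- p$death_rate + 1.0 * p$temp * hot_half  # true gamma2 = 1
  ia <- interaction_fit(p, as.numeric(hot_half))
  expect_true(ia$indicator_absorbed)  # county-level indicator is in the FE span
  expect_gt(1.0, ia$gamma2$ci_lower)
  expect_lt(1.0, ia$gamma2$ci_upper)
  expect_equal(ia$slopes$estimate,
               c(ia$fit$coefficients["temp"],
                 ia$fit$coefficients["temp"] + ia$fit$coefficients["temp_x_d"]),
               ignore_attr = TRUE)
})

test_that("interaction slopes equal separate per-group fits when FE never cross groups", {
  p <- generate_panel(panel_dgp_config(n_counties = 40, n_states = 4,
                                       years = 2013:2017, seed = 33))$panel
  # split along state lines: FE cells are nested inside the indicator
  d <- as.numeric(p$state_id %in% c("S01", "S02"))
  ia <- interaction_fit(p, d)
  sep0 <- fe_fit(p[d == 0, ], fe_spec("death_rate", c("temp", "precip")))
  sep1 <- fe_fit(p[d == 1, ], fe_spec("death_rate", c("temp", "precip")))
  expect_equal(ia$slopes$estimate[1], unname(coef(sep0)["temp"]),
               tolerance = 1e-7)
  expect_equal(ia$slopes$estimate[2], unname(coef(sep1)["temp"]),
               tolerance = 1e-7)
})

test_that("a constant indicator is rejected", {
  p <- generate_panel(panel_dgp_config(n_counties = 10, n_states = 2,
                                       years = 2013:2014, seed = 34))$panel
  expect_error(interaction_fit(p, rep(1, nrow(p))), "constant")
})

test_that("binned fits report empty and thin bins without estimates", {
  p <- generate_panel(panel_dgp_config(n_counties = 20, n_states = 4,
                                       years = 2013:2016,
                                       temp_base_range = c(14, 16),
                                       temp_seasonal_amplitude = 1,
                                       temp_noise_sd = 0.5, seed = 35))$panel
  sg <- binned_fit(p, "temp", c(10, 20))
  expect_equal(nrow(sg), 3L)
  expect_equal(sg$n[c(1, 3)], c(0L, 0L))
  expect_true(all(is.na(sg$estimate[c(1, 3)])))
  expect_false(is.na(sg$estimate[2]))
  expect_equal(sg$note[c(1, 3)], c("empty bin", "empty bin"))
})

test_that("population bins are assigned per county, temperature bins per row", {
  p <- generate_panel(panel_dgp_config(n_counties = 30, n_states = 5,
                                       years = 2013:2016, seed = 36))$panel
  med <- stats::median(unique(p$population))
  sg <- binned_fit(p, "population", med)
  # every county's rows are wholly inside one bin: 48 rows each
  expect_equal(sum(sg$n), nrow(p))
  expect_true(all(sg$n %% 48 == 0))
  expect_true(all(!is.na(sg$estimate)))
})

test_that("per-category slopes are homogeneous under a common-slope DGP", {
  p <- generate_panel(panel_dgp_config(n_counties = 50, n_states = 5,
                                       years = 2013:2019, beta_temp = 1.0,
                                       seed = 37))$panel
  ce <- categorical_effects(p, "year")
  expect_equal(nrow(ce), 7L)
  z <- (ce$estimate - 1.0) / ce$se
  expect_true(all(abs(z) < 4))
  expect_true(all(ce$n_clusters == 50))
})

test_that("a year with a doubled slope separates from the rest", {
  sim <- generate_panel(panel_dgp_config(n_counties = 50, n_states = 5,
                                         years = 2013:2019, beta_temp = 1.0,
                                         seed = 38))
  p <- sim$panel
  p$death_rate <- p$death_rate + 1.0 * p$temp * (p$year == 2016)
  ce <- categorical_effects(p, "year")
  est <- ce$estimate[ce$group == "2016"]
  se <- ce$se[ce$group == "2016"]
  others <- ce$estimate[ce$group != "2016"]
  expect_gt(est - 3 * se, max(others))
})

test_that("per-category slopes aggregate to the pooled fit (matrix-weighted identity)", {
  # categories = states; both FE dimensions are nested inside states, so the
  # pooled coefficient is the A_k-weighted combination of per-state slopes
  p <- generate_panel(panel_dgp_config(n_counties = 20, n_states = 4,
                                       years = 2013:2016, seed = 39))$panel
  pooled <- fe_fit(p, fe_spec("death_rate", c("temp", "precip")))
  ce <- categorical_effects(p, "state_id")
  fit_full <- attr(ce, "fit")
  Xd <- pooled$demeaned_design
  w <- pooled$weights
  states <- sort(unique(p$state_id))
  A_sum <- matrix(0, 2, 2)
  b_sum <- c(0, 0)
  for (s in states) {
    rows <- p$state_id == s
    A_k <- crossprod(Xd[rows, , drop = FALSE], Xd[rows, , drop = FALSE] * w[rows])
    th_k <- c(fit_full$coefficients[paste0("temp_", s)],
              fit_full$coefficients[paste0("precip_", s)])
    A_sum <- A_sum + A_k
    b_sum <- b_sum + A_k %*% th_k
  }
  expect_equal(unname(solve(A_sum, b_sum)[, 1]), unname(coef(pooled)),
               tolerance = 1e-6)
})

test_that("climate-region lookup covers the contiguous US with nine regions", {
  cz <- noaa_climate_regions()
  expect_equal(length(unique(cz$climate_region)), 9L)
  expect_equal(nrow(cz), 49L)
  expect_false(any(duplicated(cz$state)))
})
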