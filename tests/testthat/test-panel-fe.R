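test_that("one fixed-effect dimension equals direct weighted group-mean subtraction", {
  set.seed(1)
  x <- matrix(rnorm(40), 20, 2)
  g <- rep(letters[1:4], each = 5)
  w <- runif(20, 0.5, 2)
  d <- within_demean(x, list(g), weights = w)
  means <- apply(x, 2, function(col) tapply(col * w, g, sum) / tapply(w, g, sum))
  expect_equal(unname(d), unname(x - means[g, ]), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(attr(d, "iterations"), 2L)  # second sweep only verifies
})

test_that("values constant within every group demean to zero", {
  g1 <- rep(1:3, each = 4)
  g2 <- rep(1:2, times = 6)
  x <- cbind(g1 * 2.5, as.numeric(g1 == 2))
  d <- within_demean(x, list(g1), weights = NULL)
  expect_equal(max(abs(d)), 0)
})

test_that("crossed demeaning matches explicit dummy-variable least squares on a toy panel", {
  toy <- data.frame(y = c(1, 4, 2, 8, 5, 7),
                    f1 = c("a", "a", "b", "b", "c", "c"),
                    f2 = c("u", "v", "u", "v", "u", "v"))
  d <- within_demean(matrix(toy$y), list(toy$f1, toy$f2))
  res <- stats::resid(stats::lm(y ~ f1 + f2, data = toy))
  expect_equal(as.vector(d), unname(res), tolerance = 1e-8)
})

test_that("no fixed effects and unit weights reduce to textbook OLS", {
  p <- data.frame(y = 2 * (1:5) + 3, x = 1:5, id = 1:5)
  fit <- fe_fit(p, fe_spec("y", "x", fe = list(), weights = NULL, cluster = NULL))
  expect_equal(unname(coef(fit)), 2.0, tolerance = 1e-12)
})

test_that("FE estimator equals dense dummy-variable WLS on random panels", {
  for (seed in 1:8) {
    p <- random_small_panel(seed)
    fit <- fe_fit(p, fe_spec("death_rate", c("temp", "precip")))
    oracle <- dummy_wls_coef(p, "death_rate", c("temp", "precip"),
                             fe_two_way, "population")
    expect_equal(coef(fit), oracle, tolerance = 1e-8)
  }
})

test_that("FE estimate covers a confounded truth that pooled OLS misses", {
  beta <- 1.5
  cfg <- panel_dgp_config(n_counties = 60, n_states = 8, years = 2013:2020,
                          beta_temp = beta, confounded = TRUE, seed = 42)
  p <- generate_panel(cfg)$panel
  fit <- fe_fit(p, fe_spec("death_rate", c("temp", "precip")))
  tab <- coef_table(fit)
  expect_gt(beta, tab$ci_lower[tab$term == "temp"])
  expect_lt(beta, tab$ci_upper[tab$term == "temp"])
  pooled <- stats::coef(stats::lm(death_rate ~ temp + precip, data = p,
                                  weights = population))["temp"]
  expect_gt(abs(pooled - beta), 3 * tab$se[tab$term == "temp"])
})

test_that("coefficients and vcov are invariant to rescaling all weights", {
  p <- random_small_panel(30)
  p$w2 <- p$population * 2
  f1 <- fe_fit(p, fe_spec("death_rate", c("temp", "precip")))
  f2 <- fe_fit(p, fe_spec("death_rate", c("temp", "precip"), weights = "w2"))
  expect_equal(coef(f1), coef(f2), tolerance = 1e-12)
  expect_equal(vcov(f1), vcov(f2), tolerance = 1e-12)
})

test_that("coefficients are invariant to shifts inside the absorbed span", {
  p <- random_small_panel(31)
  f1 <- fe_fit(p, fe_spec("death_rate", c("temp", "precip")))
  # add an arbitrary constant to every row of a few county-month cells
  cell <- interaction(p$county_id, p$month)
  shift <- c(5, -3, 11)[match(cell, levels(cell)[1:3])]
  p$death_rate <- p$death_rate + ifelse(is.na(shift), 0, shift)
  f2 <- fe_fit(p, fe_spec("death_rate", c("temp", "precip")))
  expect_equal(coef(f1), coef(f2), tolerance = 1e-8)
})

test_that("rank-deficient designs error naming the absorbed column", {
  p <- random_small_panel(32)
  p$cm_const <- as.numeric(factor(p$month))  # constant within county-month cells
  expect_error(fe_fit(p, fe_spec("death_rate", c("temp", "cm_const"))),
               "cm_const")
})

test_that("cluster covariance matches a brute-force sum over clusters", {
  for (seed in c(3, 9)) {
    p <- random_small_panel(seed)
    fit <- fe_fit(p, fe_spec("death_rate", c("temp", "precip")))
    V <- brute_cluster_vcov(fit$demeaned_design, fit$residuals, fit$weights,
                            p$county_id, fit$k_model)
    expect_equal(unname(vcov(fit)), unname(V), tolerance = 1e-10)
  }
})

test_that("row-level clusters with unit weights reduce to HC1", {
  skip_if_not_installed("sandwich")
  set.seed(5)
  p <- data.frame(y = rnorm(40), x1 = rnorm(40), x2 = rnorm(40), id = 1:40)
  fit <- fe_fit(p, fe_spec("y", c("x1", "x2"), fe = list(), weights = NULL,
                           cluster = "id"))
  lmf <- stats::lm(y ~ x1 + x2, data = p)
  Vhc1 <- sandwich::vcovHC(lmf, type = "HC1")[c("x1", "x2"), c("x1", "x2")]
  expect_equal(unname(vcov(fit)), unname(Vhc1), tolerance = 1e-10)
})

test_that("fit-level clustered SEs match the lm + vcovCL route", {
  skip_if_not_installed("sandwich")
  p <- random_small_panel(12)
  fit <- fe_fit(p, fe_spec("death_rate", c("temp", "precip")))
  lmf <- dummy_wls_fit(p, "death_rate", c("temp", "precip"), fe_two_way,
                       "population")
  Vcl <- sandwich::vcovCL(lmf, cluster = p$county_id, type = "HC1")
  expect_equal(unname(vcov(fit)),
               unname(Vcl[c("temp", "precip"), c("temp", "precip")]),
               tolerance = 1e-6)
})

test_that("duplicating every row into fresh clusters leaves estimates unchanged", {
  p <- random_small_panel(13)
  p2 <- rbind(p, transform(p, county_id = paste0(county_id, "_dup")))
  f1 <- fe_fit(p, fe_spec("death_rate", c("temp", "precip")))
  f2 <- fe_fit(p2, fe_spec("death_rate", c("temp", "precip")))
  expect_equal(coef(f1), coef(f2), tolerance = 1e-8)
})

test_that("a single cluster is rejected", {
  p <- random_small_panel(14)
  p$one <- "all"
  expect_error(fe_fit(p, fe_spec("death_rate", c("temp", "precip"),
                                 cluster = "one")), "2 clusters")
})

test_that("AIC penalty arithmetic and degeneracy behave as documented", {
  set.seed(21)
  n <- 60
  p <- data.frame(y = rnorm(n), x1 = rnorm(n), id = 1:n)
  f1 <- fe_fit(p, fe_spec("y", "x1", fe = list(), weights = NULL, cluster = NULL))
  # regressor orthogonal to x1 and to the residuals: zero explanatory power
  e <- f1$residuals
  v <- rnorm(n)
  x1d <- f1$demeaned_design[, 1]
  z <- v - sum(v * e) / sum(e * e) * e
  z <- z - sum(z * x1d) / sum(x1d^2) * x1d
  p$z <- z
  f2 <- fe_fit(p, fe_spec("y", c("x1", "z"), fe = list(), weights = NULL,
                          cluster = NULL))
  expect_equal(AIC(f2), AIC(f1) + 2, tolerance = 1e-6)
  expect_equal(AIC(f1), AIC(fe_fit(p, fe_spec("y", "x1", fe = list(),
                                              weights = NULL, cluster = NULL))))
  exact <- data.frame(y = 2 * (1:5), x = 1:5, id = 1:5)
  f0 <- fe_fit(exact, fe_spec("y", "x", fe = list(), weights = NULL,
                              cluster = NULL))
  expect_error(AIC(f0), "degenerate")
})

test_that("absorbed degrees of freedom count connected FE components", {
  # 30 counties x 12 months and 5 states x 6 years, counties nested in states:
  # components = number of states
  p <- generate_panel(panel_dgp_config(n_counties = 30, n_states = 5,
                                       years = 2013:2018, seed = 2))$panel
  fit <- fe_fit(p, fe_spec("death_rate", c("temp", "precip")))
  expect_equal(fit$fe_dof, 30 * 12 + 5 * 6 - 5)
})
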