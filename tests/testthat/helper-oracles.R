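# Independent oracles used across the suite. These deliberately take the
# slow, literal route (dense dummy regressions, explicit loops) so they
# share no code with the estimators they check.

# dense dummy-variable WLS: fixed effects as explicit factor dummies
dummy_wls_fit <- function(panel, response, regressors, fe,
                          weights = NULL) {
  df <- panel
  df$.y <- df[[response]]
  for (i in seq_along(fe)) {
    df[[paste0(".fe", i)]] <- interaction(df[fe[[i]]], drop = TRUE)
  }
  rhs <- paste(c(regressors, if (length(fe)) paste0(".fe", seq_along(fe))),
               collapse = " + ")
  df$.w <- if (is.null(weights)) rep(1, nrow(df)) else df[[weights]]
  stats::lm(stats::as.formula(paste(".y ~", rhs)), data = df, weights = .w)
}

dummy_wls_coef <- function(panel, response, regressors, fe, weights = NULL) {
  stats::coef(dummy_wls_fit(panel, response, regressors, fe, weights))[regressors]
}

# literal sum-over-clusters CR1 sandwich, elementwise loops throughout
brute_cluster_vcov <- function(X, e, w, cl, k_model) {
  p <- ncol(X)
  A <- matrix(0, p, p)
  for (i in seq_len(nrow(X))) A <- A + w[i] * (X[i, ] %o% X[i, ])
  meat <- matrix(0, p, p)
  for (g in unique(cl)) {
    s <- rep(0, p)
    for (i in which(cl == g)) s <- s + w[i] * e[i] * X[i, ]
    meat <- meat + s %o% s
  }
  n <- nrow(X)
  G <- length(unique(cl))
  Ainv <- solve(A)
  (G / (G - 1)) * ((n - 1) / (n - k_model)) * (Ainv %*% meat %*% Ainv)
}

# a small panel with randomized dimensions and DGP settings
random_small_panel <- function(seed) {
  set.seed(seed)
  cfg <- panel_dgp_config(
    n_counties = sample(5:20, 1),
    n_states = sample(2:5, 1),
    years = 2013:(2013 + sample(1:3, 1)),
    beta_temp = stats::runif(1, -2, 2),
    beta_precip = stats::runif(1, -0.1, 0.1),
    fe_sd_county_month = stats::runif(1, 0, 3),
    fe_sd_state_year = stats::runif(1, 0, 2),
    noise_sd = stats::runif(1, 0.5, 3),
    confounded = sample(c(TRUE, FALSE), 1),
    seed = seed + 1000L)
  generate_panel(cfg)$panel
}

fe_two_way <- list(c("county_id", "month"), c("state_id", "year"))
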