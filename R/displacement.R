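#' Add lagged and lead exposure columns to a panel
#'
#' For each requested lag L, the value of `var` at calendar month `m - L`
#' within the same county (L = 1 is the previous month, L = -1 the next
#' month). Shifts never cross county boundaries; a gap in a county's month
#' sequence is an error, never a silent shift across the gap. Rows whose
#' required lags or leads fall outside the observed series are dropped from
#' the returned panel (the count is available as attribute `n_dropped` and
#' is reported via `message()`).
#'
#' Column naming: lag 1 of `temp` is `temp_lag1`, lag 0 is `temp_lag0`,
#' lag -1 (lead) is `temp_lead1`.
#'
#' @param panel county-month panel data frame.
#' @param lags integer vector of lags; must contain 0 and is applied to
#'   every variable in `vars`.
#' @param vars columns to shift (temperature and precipitation by default).
#' @param drop_incomplete drop rows missing any requested lag (default);
#'   otherwise keep them with NA.
#' @return the panel with the shifted columns appended; attributes
#'   `n_dropped` and `lag_cols` (named list var -> column names).
#' @export
add_lags <- function(panel, lags = c(-1L, 0L, 1L), vars = c("temp", "precip"),
                     drop_incomplete = TRUE) {
  lags <- sort(unique(as.integer(lags)))
  if (!0L %in% lags) stop("lags must include 0 (the current month)")
  stopifnot(all(vars %in% names(panel)))
  tix <- panel$year * 12L + panel$month
  ord <- order(panel$county_id, tix)
  if (!identical(ord, seq_len(nrow(panel)))) panel <- panel[ord, , drop = FALSE]
  tix <- panel$year * 12L + panel$month
  cty <- panel$county_id
  gaps <- which(cty[-1] == cty[-length(cty)] & diff(tix) != 1L)
  if (length(gaps)) {
    stop("gaps in the month sequence within county(ies): ",
         paste(unique(utils::head(cty[gaps], 10)), collapse = ", "))
  }
  lag_cols <- list()
  for (v in vars) {
    for (L in lags) {
      nm <- if (L >= 0) paste0(v, "_lag", L) else paste0(v, "_lead", -L)
      shifted <- rep(NA_real_, nrow(panel))
      # within-county match of calendar index m - L
      key_have <- paste(cty, tix)
      key_want <- paste(cty, tix - L)
      idx <- match(key_want, key_have)
      shifted[!is.na(idx)] <- panel[[v]][idx[!is.na(idx)]]
      panel[[nm]] <- shifted
      lag_cols[[v]] <- c(lag_cols[[v]], nm)
    }
  }
  all_cols <- unlist(lag_cols)
  complete <- stats::complete.cases(panel[all_cols])
  n_dropped <- sum(!complete)
  if (drop_incomplete && n_dropped > 0) {
    panel <- panel[complete, , drop = FALSE]
    message("add_lags: dropped ", n_dropped,
            " row(s) lacking a requested lag/lead")
  }
  rownames(panel) <- NULL
  attr(panel, "n_dropped") <- n_dropped
  attr(panel, "lag_cols") <- lag_cols
  panel
}

#' Fit the displacement (distributed-lag) model
#'
#' Adds lagged/lead temperature and precipitation columns and fits the
#' standard weighted two-way fixed-effects regression on all of them
#' jointly, i.e. the linear model with exposure terms at every requested
#' lag.
#'
#' @param panel county-month panel data frame.
#' @param lags integer lags (must include 0).
#' @param fe,weights,cluster,response regression setup as in
#'   [fit_basis_model()].
#' @param vars exposure variables to lag.
#' @param ... passed to [fe_spec()].
#' @return an `fe_fit`; the lag column names are stored as `lag_cols`.
#' @export
fit_lag_model <- function(panel, lags = c(-1L, 0L, 1L),
                          fe = list(c("county_id", "month"), c("state_id", "year")),
                          weights = "population", cluster = "county_id",
                          response = "death_rate",
                          vars = c("temp", "precip"), ...) {
  lp <- add_lags(panel, lags = lags, vars = vars)
  regs <- unlist(attr(lp, "lag_cols"))
  fit <- fe_fit(lp, fe_spec(response, regs, fe = fe,
                            weights = weights, cluster = cluster, ...))
  fit$lag_cols <- attr(lp, "lag_cols")
  fit$n_dropped <- attr(lp, "n_dropped")
  fit
}

#' Net (overall) temperature effect across lags
#'
#' The sum of the current-month and previous-month temperature
#' coefficients, with its standard error from the full cluster-robust
#' covariance: `SE^2 = sum_ij V[i, j]` over the included lag terms.
#'
#' @param fit an `fe_fit` containing the lag coefficients (e.g. from
#'   [fit_lag_model()]).
#' @param lags lags to sum (default current + previous month).
#' @param var exposure variable name.
#' @param level confidence level.
#' @return list with `estimate`, `se`, `ci_lower`, `ci_upper`, `terms`.
#' @export
net_effect <- function(fit, lags = c(0L, 1L), var = "temp", level = 0.95) {
  nms <- ifelse(lags >= 0, paste0(var, "_lag", lags), paste0(var, "_lead", -lags))
  miss <- setdiff(nms, names(fit$coefficients))
  if (length(miss)) stop("fit lacks lag coefficient(s): ", paste(miss, collapse = ", "))
  est <- sum(fit$coefficients[nms])
  V <- fit$vcov[nms, nms, drop = FALSE]
  se <- sqrt(sum(V))
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(estimate = est, se = se,
       ci_lower = est - z * se, ci_upper = est + z * se, terms = nms)
}
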