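#' Aggregate gridded warming to counties by overlap weights
#'
#' County warming is the overlap-weighted mean of the climate-model grid
#' cells intersecting it, with weights renormalized within each county.
#'
#' @param cells data frame with columns `cell_id`, `delta_t`, and
#'   optionally `model` (processed per model when present).
#' @param overlaps data frame with columns `county_id`, `cell_id`, `weight`
#'   (nonnegative; must sum to a positive total per county).
#' @return data frame with columns (`model`,) `county_id`, `delta_t`.
#' @export
grid_to_county <- function(cells, overlaps) {
  stopifnot(all(c("cell_id", "delta_t") %in% names(cells)),
            all(c("county_id", "cell_id", "weight") %in% names(overlaps)))
  if (any(overlaps$weight < 0)) stop("overlap weights must be nonnegative")
  tot <- tapply(overlaps$weight, overlaps$county_id, sum)
  bad <- names(tot)[!(tot > 0)]
  if (length(bad)) stop("county(ies) with zero grid overlap: ",
                        paste(bad, collapse = ", "))
  one <- function(cc) {
    m <- merge(overlaps, cc, by = "cell_id")
    missing_cells <- setdiff(overlaps$cell_id, cc$cell_id)
    if (length(missing_cells))
      stop("overlap references cell(s) absent from the model field: ",
           paste(missing_cells, collapse = ", "))
    agg <- by(m, m$county_id, function(d)
      sum(d$weight * d$delta_t) / sum(d$weight))
    data.frame(county_id = names(agg), delta_t = as.vector(agg),
               row.names = NULL, stringsAsFactors = FALSE)
  }
  if ("model" %in% names(cells)) {
    parts <- lapply(split(cells, cells$model), one)
    out <- do.call(rbind, Map(function(mod, d) cbind(model = mod, d),
                              names(parts), parts))
    rownames(out) <- NULL
    out
  } else one(cells)
}

#' Expand end-of-horizon warming into per-year warming paths
#'
#' The climate input gives each county one warming value per model: the
#' future-period minus baseline-period mean. The within-horizon path is not
#' observed; by default it is a linear ramp from 0 at `base_year` to the
#' model's county value at `end_year` (a `"step"` alternative holds the
#' end value over the whole horizon). The base-year value is 0 under either
#' ramp.
#'
#' @param deltas data frame with columns `model`, `county_id`, `delta_t`
#'   (end-of-horizon warming, degC).
#' @param base_year,end_year projection horizon (`end_year > base_year`).
#' @param ramp `"linear"` or `"step"`.
#' @return data frame with columns model, county_id, year, delta_t.
#' @export
build_delta_paths <- function(deltas, base_year, end_year,
                              ramp = c("linear", "step")) {
  ramp <- match.arg(ramp)
  if (end_year <= base_year) stop("end_year must exceed base_year")
  stopifnot(all(c("model", "county_id", "delta_t") %in% names(deltas)))
  years <- base_year:end_year
  frac <- switch(ramp,
                 linear = (years - base_year) / (end_year - base_year),
                 step = as.numeric(years != base_year))
  out <- deltas[rep(seq_len(nrow(deltas)), each = length(years)),
                c("model", "county_id", "delta_t")]
  out$year <- rep(years, times = nrow(deltas))
  out$delta_t <- out$delta_t * rep(frac, times = nrow(deltas))
  rownames(out) <- NULL
  out[c("model", "county_id", "year", "delta_t")]
}

#' Cumulative excess deaths from a warming path
#'
#' Per county and year, excess deaths are
#' `population * delta_t * beta / beta_scale * months_per_year`;
#' the national cumulative series is the running sum over years of the
#' county totals. `beta` is the net per-degC change in the monthly death
#' rate, expressed per `beta_scale` person-months (so a fit on rates per
#' 1e7 person-months uses `beta_scale = 1e7`); the default
#' `months_per_year = 12` converts the monthly rate sensitivity to
#' annual deaths, applying the annual-mean warming to every month.
#'
#' @param pop_paths data frame with columns county_id, year, population.
#' @param delta_paths data frame with columns (`model`,) county_id, year,
#'   delta_t, e.g. from [build_delta_paths()].
#' @param beta net temperature effect (rate units per degC).
#' @param beta_scale person-months per rate unit (> 0).
#' @param months_per_year annualization factor for the monthly coefficient.
#' @return data frame with columns (`model`,) year, annual_excess,
#'   cumulative_excess.
#' @export
excess_deaths <- function(pop_paths, delta_paths, beta, beta_scale = 1,
                          months_per_year = 12) {
  if (!is.finite(beta_scale) || beta_scale <= 0)
    stop("beta_scale must be a positive number (rate-unit/person-month mismatch?)")
  stopifnot(all(c("county_id", "year", "population") %in% names(pop_paths)),
            all(c("county_id", "year", "delta_t") %in% names(delta_paths)))
  m <- merge(delta_paths, pop_paths, by = c("county_id", "year"))
  if (nrow(m) < nrow(delta_paths))
    stop("population path missing for some (county, year) cells")
  m$excess <- m$population * m$delta_t * beta / beta_scale * months_per_year
  grp <- if ("model" %in% names(m)) list(model = m$model, year = m$year)
         else list(year = m$year)
  agg <- stats::aggregate(m$excess, grp, sum)
  names(agg)[ncol(agg)] <- "annual_excess"
  agg <- agg[do.call(order, agg[setdiff(names(agg), "annual_excess")]), ,
             drop = FALSE]
  if ("model" %in% names(agg)) {
    agg$cumulative_excess <- as.vector(
      unlist(tapply(agg$annual_excess, agg$model, cumsum)))
  } else {
    agg$cumulative_excess <- cumsum(agg$annual_excess)
  }
  rownames(agg) <- NULL
  agg
}

#' Monte Carlo projection of cumulative excess deaths
#'
#' Propagates both statistical and climate-model uncertainty: a county-level
#' cluster bootstrap of the historical panel (counties resampled with
#' replacement, the distributed-lag model refit, and the net current-plus-
#' previous-month temperature effect taken as that draw's beta) is crossed
#' with each climate model's county warming path, giving `B x M` cumulative
#' trajectories. With B = 1000 draws and 30 models this is the conventional
#' 30,000-member ensemble; tests and examples run smaller.
#'
#' @param panel historical county-month panel.
#' @param deltas end-of-horizon warming per model and county (`model`,
#'   `county_id`, `delta_t`), e.g. from [generate_climate_models()] or
#'   [grid_to_county()].
#' @param pop_paths county population projections over the horizon.
#' @param B number of bootstrap draws (>= 1).
#' @param base_year,end_year,ramp warming-path settings
#'   (see [build_delta_paths()]).
#' @param lags lags of the historical displacement model.
#' @param net_lags lags summed into the net beta (current + previous month).
#' @param beta_scale,months_per_year unit conversion (see [excess_deaths()]).
#' @param fe,weights,cluster,response,vars historical regression setup.
#' @param seed integer seed for the bootstrap.
#' @param max_retries redraws allowed per failed bootstrap refit.
#' @param ... passed to [fe_spec()].
#' @return object of class `projection_ensemble`: `trajectories`
#'   (`B*M x years` matrix), `summary` (year, median, q2.5, q25, q75,
#'   q97.5), `betas`, `beta_hat` (full-sample net effect), `B`, `M`,
#'   `years`, `n_retries`.
#' @export
project_excess_deaths <- function(panel, deltas, pop_paths,
                                  B = 1000L, base_year, end_year,
                                  ramp = c("linear", "step"),
                                  lags = c(-1L, 0L, 1L), net_lags = c(0L, 1L),
                                  beta_scale = 1e7, months_per_year = 12,
                                  fe = list(c("county_id", "month"), c("state_id", "year")),
                                  weights = "population", cluster = "county_id",
                                  response = "death_rate",
                                  vars = c("temp", "precip"),
                                  seed = 1L, max_retries = 10L, ...) {
  ramp <- match.arg(ramp)
  stopifnot(B >= 1L)
  models <- sort(unique(deltas$model))
  M <- length(models)
  paths <- build_delta_paths(deltas, base_year, end_year, ramp)
  years <- base_year:end_year

  # pop * delta_t summed over counties, per (model, year); a trajectory is
  # then beta * months_per_year / beta_scale * cumsum of this series
  pd <- merge(paths, pop_paths, by = c("county_id", "year"))
  if (nrow(pd) < nrow(paths))
    stop("population path missing for some (county, year) cells")
  S <- tapply(pd$population * pd$delta_t, list(pd$model, pd$year), sum)
  S <- S[models, as.character(years), drop = FALSE]
  cumS <- t(apply(S, 1L, cumsum))
  if (length(years) == 1L) cumS <- matrix(S, nrow = M)

  lp <- add_lags(panel, lags = lags, vars = vars)
  regs <- unlist(attr(lp, "lag_cols"))
  spec <- fe_spec(response, regs, fe = fe, weights = weights,
                  cluster = cluster, ...)
  full_fit <- fe_fit(lp, spec)
  beta_hat <- net_effect(full_fit, lags = net_lags)$estimate

  counties <- unique(lp$county_id)
  by_county <- split(seq_len(nrow(lp)), lp$county_id)
  set.seed(seed)
  betas <- numeric(B)
  n_retries <- 0L
  if (B == 1L) {
    betas[1L] <- beta_hat  # degenerate ensemble: the point estimate
  } else {
    for (b in seq_len(B)) {
      for (tries in 0:max_retries) {
        draw <- sample(counties, length(counties), replace = TRUE)
        idx <- unlist(by_county[draw], use.names = FALSE)
        bp <- lp[idx, , drop = FALSE]
        # each resampled copy becomes its own county (FE unit and cluster)
        bp$county_id <- rep(paste0(draw, "#", seq_along(draw)),
                            lengths(by_county[draw]))
        fit_b <- tryCatch(fe_fit(bp, spec), error = function(e) e)
        if (!inherits(fit_b, "error")) {
          betas[b] <- net_effect(fit_b, lags = net_lags)$estimate
          break
        }
        n_retries <- n_retries + 1L
        if (tries == max_retries)
          stop("bootstrap refit failed ", max_retries + 1L,
               " times in a row: ", conditionMessage(fit_b))
      }
    }
  }

  fac <- months_per_year / beta_scale
  traj <- kronecker(matrix(betas, ncol = 1), cumS) * fac
  rownames(traj) <- paste(rep(seq_len(B), each = M),
                          rep(models, times = B), sep = ":")
  colnames(traj) <- as.character(years)
  qs <- apply(traj, 2L, stats::quantile, probs = c(0.025, 0.25, 0.5, 0.75, 0.975))
  summ <- data.frame(year = years, median = qs["50%", ],
                     q2.5 = qs["2.5%", ], q25 = qs["25%", ],
                     q75 = qs["75%", ], q97.5 = qs["97.5%", ],
                     row.names = NULL)
  structure(list(trajectories = traj, summary = summ, betas = betas,
                 beta_hat = beta_hat, B = B, M = M, years = years,
                 n_retries = n_retries,
                 months_per_year = months_per_year, beta_scale = beta_scale),
            class = "projection_ensemble")
}

#' @export
print.projection_ensemble <- function(x, ...) {
  cat("Projection ensemble:", x$B, "bootstrap draws x", x$M, "climate models =",
      x$B * x$M, "trajectories over", length(x$years), "years\n")
  cat("  full-sample net beta:", format(x$beta_hat), "\n")
  print(utils::tail(x$summary, 3))
  invisible(x)
}
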