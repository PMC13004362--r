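#' Configuration of the county-month panel data-generating process
#'
#' Defines a balanced county-by-month panel in which a monthly outcome rate
#' responds to temperature (linearly, through a known spline, or through an
#' arbitrary function), to precipitation, and to lagged temperature, on top
#' of additive county-month and state-year fixed effects and Gaussian noise.
#' Rates are expressed per `rate_scale` person-months (default 1e7), which
#' puts realistic US-scale police-violence death rates and their temperature
#' coefficients on an O(1) scale.
#'
#' County mean temperatures are drawn uniformly over `temp_base_range`, a
#' sinusoidal seasonal cycle of amplitude `temp_seasonal_amplitude` peaking
#' in July is added, plus month-level noise. When `confounded = TRUE` the
#' county-month intercepts are drawn with correlation `confound_rho` to the
#' cell's mean temperature, so that pooled OLS is biased while the
#' fixed-effects estimator remains consistent.
#'
#' @param n_counties,n_states positive integers; counties are assigned to
#'   states round-robin (`n_states <= n_counties`).
#' @param years inclusive vector of calendar years (>= 2 years whenever
#'   state-year effects are requested).
#' @param beta_temp contemporaneous linear temperature effect, rate units
#'   per degree C (ignored when `response_shape` overrides it).
#' @param beta_precip precipitation effect, rate units per mm.
#' @param response_shape `"linear"`, or a list describing a nonlinear truth:
#'   `list(kind = "spline", knots =, coefficients =)` for a natural cubic
#'   spline (coefficients on the [build_basis()] columns for those knots),
#'   or `list(kind = "custom", fn = function(temp) ...)`.
#' @param lag_effects named numeric vector of additional linear temperature
#'   effects at integer lags, e.g. `c("1" = -0.3)` for the previous month;
#'   negative names are leads. Contemporaneous effects belong in
#'   `beta_temp`/`response_shape`, not here.
#' @param fe_sd_county_month,fe_sd_state_year,noise_sd nonnegative spreads
#'   of the county-month intercepts, state-year intercepts, and residual.
#' @param confounded draw county-month intercepts correlated with cell mean
#'   temperature (`confound_rho`)?
#' @param confound_rho correlation between county-month intercept and the
#'   cell's deterministic mean temperature when `confounded`.
#' @param baseline_rate intercept of the rate, per `rate_scale`
#'   person-months.
#' @param population_range min/max county population (uniform draw, constant
#'   over time).
#' @param temp_base_range min/max of county mean annual temperature, deg C.
#' @param temp_seasonal_amplitude seasonal half-range, deg C.
#' @param temp_noise_sd month-level temperature noise, deg C.
#' @param precip_mean,precip_sd monthly precipitation distribution, mm
#'   (draws truncated at 0).
#' @param deaths_mode `"rate"` generates the continuous rate directly (the
#'   estimator is linear in the rate); `"poisson"` additionally draws
#'   integer deaths ~ Poisson(rate * population / rate_scale) and recomputes
#'   the rate from them.
#' @param rate_scale person-months per rate unit.
#' @param seed integer RNG seed; a fixed seed reproduces the panel exactly.
#' @return an object of class `panel_dgp_config` (a validated list).
#' @export
panel_dgp_config <- function(n_counties = 100L, n_states = 10L,
                             years = 2013:2022,
                             beta_temp = 1.0, beta_precip = -0.02,
                             response_shape = "linear",
                             lag_effects = NULL,
                             fe_sd_county_month = 2.0, fe_sd_state_year = 1.0,
                             noise_sd = 2.0,
                             confounded = FALSE, confound_rho = 0.5,
                             baseline_rate = 3.0,
                             population_range = c(5e4, 2e6),
                             temp_base_range = c(2, 22),
                             temp_seasonal_amplitude = 12,
                             temp_noise_sd = 2,
                             precip_mean = 80, precip_sd = 40,
                             deaths_mode = c("rate", "poisson"),
                             rate_scale = 1e7,
                             seed = 1L) {
  deaths_mode <- match.arg(deaths_mode)
  if (n_counties < 1) stop("n_counties must be positive")
  if (n_states < 1 || n_states > n_counties)
    stop("need 1 <= n_states <= n_counties")
  years <- sort(unique(as.integer(years)))
  if (fe_sd_state_year > 0 && length(years) < 2)
    stop("state-year effects need at least 2 years")
  sds <- c(fe_sd_county_month, fe_sd_state_year, noise_sd,
           temp_noise_sd, precip_sd)
  if (any(sds < 0)) stop("all sd parameters must be nonnegative")
  if (!is.null(lag_effects)) {
    lg <- as.integer(names(lag_effects))
    if (anyNA(lg)) stop("lag_effects must be named by integer lag")
    if (any(lg == 0L)) stop("contemporaneous effect belongs in beta_temp, not lag_effects")
    max_l <- max(abs(lg))
    if (length(years) * 12L < max_l + 1L)
      stop("years span shorter than the lag window + 1 month")
  }
  if (!identical(response_shape, "linear")) {
    stopifnot(is.list(response_shape),
              response_shape$kind %in% c("spline", "custom"))
    if (response_shape$kind == "spline")
      stopifnot(length(response_shape$coefficients) ==
                length(response_shape$knots) - 1L)
    if (response_shape$kind == "custom")
      stopifnot(is.function(response_shape$fn))
  }
  cfg <- mget(names(formals()), envir = environment())
  structure(cfg, class = "panel_dgp_config")
}

# evaluate the generating temperature response at given temperatures
.dgp_response <- function(cfg, temp) {
  if (identical(cfg$response_shape, "linear")) return(cfg$beta_temp * temp)
  rs <- cfg$response_shape
  if (rs$kind == "custom") return(rs$fn(temp))
  B <- build_basis(temp, basis_spec("ncs", knots = rs$knots))
  drop(B %*% rs$coefficients)
}

#' Generate a synthetic county-month panel with known truth
#'
#' Simulates the panel described by [panel_dgp_config()]. The generating
#' model is
#' `rate = baseline + f(temp) + sum_L gamma_L temp[m - L] + beta_precip * precip
#'  + delta[county, month] + alpha[state, year] + eps`,
#' with `eps ~ Normal(0, noise_sd)`. Temperatures follow the county's
#' seasonal cycle plus noise; the series is extended beyond the panel years
#' by the lag window so every panel row has its lagged and lead exposures
#' defined.
#'
#' @param config a [panel_dgp_config()].
#' @return a list of class `panel_sim` with elements `panel` (the
#'   county-month data frame: county_id, state_id, year, month, population,
#'   death_rate, temp, precip, and deaths in `"poisson"` mode) and `truth`
#'   (all generating coefficients and per-cell fixed effects).
#' @export
generate_panel <- function(config) {
  stopifnot(inherits(config, "panel_dgp_config"))
  cfg <- config
  set.seed(cfg$seed)

  counties <- sprintf("C%03d", seq_len(cfg$n_counties))
  states <- sprintf("S%02d", ((seq_len(cfg$n_counties) - 1L) %% cfg$n_states) + 1L)
  pop <- stats::runif(cfg$n_counties, cfg$population_range[1], cfg$population_range[2])
  base_temp <- stats::runif(cfg$n_counties, cfg$temp_base_range[1], cfg$temp_base_range[2])

  max_lag <- if (is.null(cfg$lag_effects)) 0L else max(abs(as.integer(names(cfg$lag_effects))))
  # calendar index over an extended window so lags/leads never run off the end
  t0 <- min(cfg$years) * 12L + 1L - max_lag
  t1 <- max(cfg$years) * 12L + 12L + max_lag
  cal <- t0:t1
  n_cal <- length(cal)
  month_of <- ((cal - 1L) %% 12L) + 1L
  year_of <- (cal - 1L) %/% 12L

  seasonal <- cfg$temp_seasonal_amplitude * cos(2 * pi * (month_of - 7L) / 12)

  # full temperature matrix: counties x extended months
  temp <- outer(base_temp, seasonal, "+") +
    matrix(stats::rnorm(cfg$n_counties * n_cal, 0, cfg$temp_noise_sd),
           cfg$n_counties, n_cal)

  # county-month fixed effects, optionally confounded with cell mean temp
  cell_mean <- outer(base_temp, cfg$temp_seasonal_amplitude *
                       cos(2 * pi * (1:12 - 7L) / 12), "+")
  if (cfg$fe_sd_county_month > 0) {
    z <- matrix(stats::rnorm(cfg$n_counties * 12L), cfg$n_counties, 12L)
    if (cfg$confounded) {
      zt <- (cell_mean - mean(cell_mean)) / stats::sd(cell_mean)
      delta_im <- cfg$fe_sd_county_month *
        (cfg$confound_rho * zt + sqrt(1 - cfg$confound_rho^2) * z)
    } else {
      delta_im <- cfg$fe_sd_county_month * z
    }
  } else {
    delta_im <- matrix(0, cfg$n_counties, 12L)
  }

  state_ids <- sort(unique(states))
  alpha_st <- matrix(stats::rnorm(length(state_ids) * length(cfg$years),
                                  0, cfg$fe_sd_state_year),
                     length(state_ids), length(cfg$years),
                     dimnames = list(state_ids, as.character(cfg$years)))

  in_panel <- year_of %in% cfg$years
  keep <- which(in_panel)
  n_months <- length(keep)

  rate <- matrix(cfg$baseline_rate, cfg$n_counties, n_months)
  rate <- rate + .dgp_response(cfg, temp[, keep, drop = FALSE])
  if (!is.null(cfg$lag_effects)) {
    for (j in seq_along(cfg$lag_effects)) {
      L <- as.integer(names(cfg$lag_effects))[j]
      rate <- rate + cfg$lag_effects[[j]] * temp[, keep - L, drop = FALSE]
    }
  }
  precip <- pmax(matrix(stats::rnorm(cfg$n_counties * n_months,
                                     cfg$precip_mean, cfg$precip_sd),
                        cfg$n_counties, n_months), 0)
  rate <- rate + cfg$beta_precip * precip
  rate <- rate + delta_im[, month_of[keep], drop = FALSE]
  st_idx <- match(states, state_ids)
  yr_idx <- match(year_of[keep], cfg$years)
  rate <- rate + alpha_st[st_idx, yr_idx, drop = FALSE]
  if (cfg$noise_sd > 0)
    rate <- rate + matrix(stats::rnorm(cfg$n_counties * n_months, 0, cfg$noise_sd),
                          cfg$n_counties, n_months)

  panel <- data.frame(
    county_id = rep(counties, times = n_months),
    state_id = rep(states, times = n_months),
    year = rep(year_of[keep], each = cfg$n_counties),
    month = rep(month_of[keep], each = cfg$n_counties),
    population = rep(pop, times = n_months),
    death_rate = as.vector(rate),
    temp = as.vector(temp[, keep]),
    precip = as.vector(precip),
    stringsAsFactors = FALSE
  )
  if (cfg$deaths_mode == "poisson") {
    lam <- pmax(panel$death_rate, 0) * panel$population / cfg$rate_scale
    panel$deaths <- stats::rpois(nrow(panel), lam)
    panel$death_rate <- panel$deaths / panel$population * cfg$rate_scale
  }
  ord <- order(panel$county_id, panel$year, panel$month)
  panel <- panel[ord, , drop = FALSE]
  rownames(panel) <- NULL

  truth <- list(beta_temp = cfg$beta_temp, beta_precip = cfg$beta_precip,
                response_shape = cfg$response_shape,
                lag_effects = cfg$lag_effects,
                baseline_rate = cfg$baseline_rate,
                delta_county_month = delta_im, alpha_state_year = alpha_st,
                county_population = stats::setNames(pop, counties),
                county_base_temp = stats::setNames(base_temp, counties),
                rate_scale = cfg$rate_scale, config = cfg)
  structure(list(panel = panel, truth = truth), class = "panel_sim")
}

#' Generate a synthetic meteorological station network
#'
#' Places stations uniformly at random inside a lat/lon bounding box and
#' evaluates known smooth fields at their coordinates for each date, so that
#' interpolation error can be asserted against the true field.
#'
#' @param n_stations number of stations (>= 1).
#' @param bbox numeric `c(lat_min, lat_max, lon_min, lon_max)` with positive
#'   extent in each direction.
#' @param temp_field function of `(lat, lon)` returning temperature.
#' @param precip_field function of `(lat, lon)` returning precipitation.
#' @param dates vector of `Date`s at which each station reports.
#' @param seed integer RNG seed.
#' @return data frame with columns station_id, lat, lon, date, temp, precip.
#' @export
generate_station_network <- function(n_stations, bbox,
                                     temp_field,
                                     precip_field = function(lat, lon) 0,
                                     dates = as.Date("2020-06-01") + 0:29,
                                     seed = 1L) {
  stopifnot(n_stations >= 1, length(bbox) == 4)
  if (bbox[2] <= bbox[1] || bbox[4] <= bbox[3]) stop("empty bounding box")
  set.seed(seed)
  lat <- stats::runif(n_stations, bbox[1], bbox[2])
  lon <- stats::runif(n_stations, bbox[3], bbox[4])
  grid <- expand.grid(station = seq_len(n_stations), date = dates)
  data.frame(
    station_id = sprintf("ST%03d", grid$station),
    lat = lat[grid$station], lon = lon[grid$station],
    date = grid$date,
    temp = temp_field(lat[grid$station], lon[grid$station]),
    precip = precip_field(lat[grid$station], lon[grid$station]),
    stringsAsFactors = FALSE
  )
}

#' Generate synthetic climate-model warming fields
#'
#' Draws, for each of `n_models` climate models and each county, an
#' end-of-horizon warming `Delta T` (future-period mean minus baseline mean)
#' from Normal(delta_mean, delta_sd) — a stand-in for a multi-model
#' projection ensemble.
#'
#' @param n_models number of models (>= 1).
#' @param counties vector of county ids.
#' @param delta_mean,delta_sd distribution of county warming, deg C.
#' @param seed integer RNG seed.
#' @return data frame with columns model, county_id, delta_t.
#' @export
generate_climate_models <- function(n_models, counties, delta_mean = 2.0,
                                    delta_sd = 0.5, seed = 1L) {
  stopifnot(n_models >= 1, length(counties) >= 1)
  if (delta_sd < 0) stop("delta_sd must be nonnegative")
  set.seed(seed)
  grid <- expand.grid(model = sprintf("GCM%02d", seq_len(n_models)),
                      county_id = as.character(counties),
                      stringsAsFactors = FALSE)
  grid$delta_t <- stats::rnorm(nrow(grid), delta_mean, delta_sd)
  grid[order(grid$model, grid$county_id), , drop = FALSE]
}

#' Generate geometric county population paths
#'
#' `pop[c, t] = pop0[c] * (1 + growth_rate)^(t - start_year)` — a simple
#' stand-in for external population projections.
#'
#' @param pop0 named vector of base-year county populations.
#' @param start_year,end_year inclusive projection horizon.
#' @param growth_rate annual growth rate (> -1).
#' @return data frame with columns county_id, year, population.
#' @export
generate_population_paths <- function(pop0, start_year, end_year,
                                      growth_rate = 0.005) {
  if (end_year < start_year) stop("end_year must be >= start_year")
  if (growth_rate <= -1) stop("growth_rate must exceed -1")
  years <- start_year:end_year
  grid <- expand.grid(county_id = names(pop0), year = years,
                      stringsAsFactors = FALSE)
  grid$population <- pop0[grid$county_id] * (1 + growth_rate)^(grid$year - start_year)
  rownames(grid) <- NULL
  grid
}
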