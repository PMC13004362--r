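#' Interaction (moderator) heterogeneity model
#'
#' Fits the main-plus-interaction design: temperature, precipitation, and
#' both of their products with a binary indicator D, under the standard
#' fixed effects, weights and clustering. The indicator's own main effect
#' is included when it survives demeaning and silently absorbed (recorded,
#' not estimated) when it is constant within fixed-effect cells, as with
#' any time-invariant county attribute.
#'
#' @param panel county-month panel data frame.
#' @param indicator a logical/0-1 vector, or the name of such a column;
#'   both levels must be present.
#' @param fe,weights,cluster,response,temp_col,precip_col as in
#'   [fit_basis_model()].
#' @param ... passed to [fe_spec()].
#' @return list with `fit`, `gamma2`/`beta2` (interaction rows of the
#'   coefficient table), `slopes` (per-group temperature slopes with
#'   delta-method SEs), and `indicator_absorbed`.
#' @export
interaction_fit <- function(panel, indicator,
                            fe = list(c("county_id", "month"), c("state_id", "year")),
                            weights = "population", cluster = "county_id",
                            response = "death_rate",
                            temp_col = "temp", precip_col = "precip", ...) {
  d <- if (is.character(indicator) && length(indicator) == 1L)
    panel[[indicator]] else indicator
  d <- as.numeric(d)
  stopifnot(length(d) == nrow(panel), all(d %in% c(0, 1)))
  if (length(unique(d)) < 2L) stop("indicator is constant; interaction is collinear")
  aug <- panel
  aug$.d <- d
  aug$temp_x_d <- aug[[temp_col]] * d
  aug$precip_x_d <- aug[[precip_col]] * d
  regs <- c(temp_col, "temp_x_d", precip_col, "precip_x_d", ".d")
  fit <- tryCatch(
    fe_fit(aug, fe_spec(response, regs, fe = fe, weights = weights,
                        cluster = cluster, ...)),
    error = function(e) e)
  absorbed <- FALSE
  if (inherits(fit, "error")) {
    if (!grepl("\\.d", conditionMessage(fit))) stop(fit)
    absorbed <- TRUE  # indicator constant within FE cells: drop its main effect
    regs <- setdiff(regs, ".d")
    fit <- fe_fit(aug, fe_spec(response, regs, fe = fe, weights = weights,
                               cluster = cluster, ...))
  }
  tab <- coef_table(fit)
  b <- fit$coefficients
  V <- fit$vcov
  s0 <- b[temp_col]
  s1 <- b[temp_col] + b["temp_x_d"]
  se0 <- sqrt(V[temp_col, temp_col])
  se1 <- sqrt(V[temp_col, temp_col] + V["temp_x_d", "temp_x_d"] +
                2 * V[temp_col, "temp_x_d"])
  slopes <- data.frame(group = c("D=0", "D=1"),
                       estimate = c(s0, s1), se = c(se0, se1),
                       ci_lower = c(s0 - 1.96 * se0, s1 - 1.96 * se1),
                       ci_upper = c(s0 + 1.96 * se0, s1 + 1.96 * se1),
                       row.names = NULL)
  list(fit = fit,
       gamma2 = tab[tab$term == "temp_x_d", ],
       beta2 = tab[tab$term == "precip_x_d", ],
       slopes = slopes, indicator_absorbed = absorbed)
}

.subgroup_row <- function(label, fit, term, n, n_clusters, note = "",
                          mean_rate = NA_real_) {
  if (is.null(fit)) {
    return(data.frame(group = label, n = n, n_clusters = n_clusters,
                      estimate = NA_real_, se = NA_real_, p_value = NA_real_,
                      ci_lower = NA_real_, ci_upper = NA_real_,
                      estimate_pct = NA_real_, significant = NA, note = note,
                      row.names = NULL))
  }
  tab <- coef_table(fit)
  row <- tab[tab$term == term, ]
  data.frame(group = label, n = n, n_clusters = n_clusters,
             estimate = row$estimate, se = row$se, p_value = row$p_value,
             ci_lower = row$ci_lower, ci_upper = row$ci_upper,
             estimate_pct = 100 * row$estimate / mean_rate,
             significant = row$p_value < 0.05, note = note, row.names = NULL)
}

#' Binned subgroup fits
#'
#' Splits the panel by bins of one moderating variable and fits the linear
#' temperature model independently in each bin under the same fixed-effect,
#' weight and cluster settings. Temperature and precipitation bins are
#' assigned per row; population bins per county (a county's population is
#' time-invariant here). Bins with no rows are reported with `n = 0`; bins
#' with fewer than two county clusters are reported without an estimate.
#'
#' `estimate_pct` rescales the per-degC effect to percent of the bin's
#' population-weighted mean rate, for comparison across rate scales.
#'
#' @param panel county-month panel data frame.
#' @param variable column to bin on (`"temp"`, `"precip"`, `"population"`,
#'   ...).
#' @param breaks interior cut points; bins are `(-Inf, b1], (b1, b2], ...,
#'   (bk, Inf)`.
#' @param per_county assign bins by the county's (first) value rather than
#'   per row; default for population.
#' @param fe,weights,cluster,response,temp_col,precip_col as in
#'   [fit_basis_model()].
#' @param ... passed to [fe_spec()].
#' @return data frame of per-bin effects (class `subgroup_effects`).
#' @export
binned_fit <- function(panel, variable, breaks,
                       per_county = identical(variable, "population"),
                       fe = list(c("county_id", "month"), c("state_id", "year")),
                       weights = "population", cluster = "county_id",
                       response = "death_rate",
                       temp_col = "temp", precip_col = "precip", ...) {
  x <- panel[[variable]]
  if (is.null(x)) stop("no such column: ", variable)
  edges <- c(-Inf, sort(breaks), Inf)
  if (per_county) {
    first <- !duplicated(panel$county_id)
    cbin <- cut(x[first], edges)
    bin <- cbin[match(panel$county_id, panel$county_id[first])]
  } else {
    bin <- cut(x, edges)
  }
  out <- lapply(levels(bin), function(lv) {
    sub <- panel[which(bin == lv), , drop = FALSE]
    ncl <- length(unique(sub$county_id))
    if (nrow(sub) == 0L)
      return(.subgroup_row(lv, NULL, temp_col, 0L, 0L, "empty bin"))
    if (ncl < 2L)
      return(.subgroup_row(lv, NULL, temp_col, nrow(sub), ncl,
                           "fewer than 2 clusters"))
    fit <- tryCatch(
      fe_fit(sub, fe_spec(response, c(temp_col, precip_col), fe = fe,
                          weights = weights, cluster = cluster, ...)),
      error = function(e) e)
    if (inherits(fit, "error"))
      return(.subgroup_row(lv, NULL, temp_col, nrow(sub), ncl,
                           conditionMessage(fit)))
    mr <- stats::weighted.mean(sub[[response]], sub[[weights]])
    .subgroup_row(lv, fit, temp_col, nrow(sub), ncl, "", mean_rate = mr)
  })
  out <- do.call(rbind, out)
  class(out) <- c("subgroup_effects", "data.frame")
  out
}

#' Per-category temperature effects (year / state / month / climate region)
#'
#' Interacts temperature and precipitation fully with a categorical
#' dimension using cell-means coding: one temperature-slope and one
#' precipitation-slope column per category, no common base slope. Each
#' reported estimate is therefore that category's own slope (no reference
#' category; the coding convention is recorded in the output attribute
#' `coding`). Categories observed in a single county cluster are flagged.
#'
#' @param panel county-month panel data frame.
#' @param dimension column name of the categorical dimension (`"year"`,
#'   `"state_id"`, `"month"`, or e.g. a climate-region column).
#' @param fe,weights,cluster,response,temp_col,precip_col as in
#'   [fit_basis_model()].
#' @param ... passed to [fe_spec()].
#' @return data frame of per-category effects (class `subgroup_effects`),
#'   with the underlying `fe_fit` as attribute `fit`.
#' @export
categorical_effects <- function(panel, dimension,
                                fe = list(c("county_id", "month"), c("state_id", "year")),
                                weights = "population", cluster = "county_id",
                                response = "death_rate",
                                temp_col = "temp", precip_col = "precip", ...) {
  cat_raw <- panel[[dimension]]
  if (is.null(cat_raw)) stop("no such column: ", dimension)
  f <- factor(cat_raw)
  if (nlevels(f) < 2L) stop("need at least 2 categories in ", dimension)
  aug <- panel
  tcols <- paste0("temp_", levels(f))
  pcols <- paste0("precip_", levels(f))
  for (i in seq_along(levels(f))) {
    ind <- as.numeric(f == levels(f)[i])
    aug[[tcols[i]]] <- aug[[temp_col]] * ind
    aug[[pcols[i]]] <- aug[[precip_col]] * ind
  }
  fit <- fe_fit(aug, fe_spec(response, c(tcols, pcols), fe = fe,
                             weights = weights, cluster = cluster, ...))
  tab <- coef_table(fit)
  mr_all <- stats::weighted.mean(panel[[response]], panel[[weights]])
  rows <- lapply(seq_along(levels(f)), function(i) {
    lv <- levels(f)[i]
    sub <- f == lv
    ncl <- length(unique(panel$county_id[sub]))
    row <- tab[tab$term == tcols[i], ]
    data.frame(group = lv, n = sum(sub), n_clusters = ncl,
               estimate = row$estimate, se = row$se, p_value = row$p_value,
               ci_lower = row$ci_lower, ci_upper = row$ci_upper,
               estimate_pct = 100 * row$estimate / mr_all,
               significant = row$p_value < 0.05,
               note = if (ncl < 2L) "single cluster" else "",
               row.names = NULL)
  })
  out <- do.call(rbind, rows)
  attr(out, "fit") <- fit
  attr(out, "coding") <- "cell-means (per-category slope, no reference category)"
  class(out) <- c("subgroup_effects", "data.frame")
  out
}

#' NOAA nine-region climate-zone lookup for the contiguous US
#'
#' Returns the conventional mapping from the 48 contiguous states (plus DC)
#' to the nine NOAA climate regions, for attaching a `climate_region`
#' column to real state-level data. Synthetic panels may assign regions
#' arbitrarily.
#'
#' @return data frame with columns `state` (postal code) and
#'   `climate_region`.
#' @export
noaa_climate_regions <- function() {
  path <- system.file("extdata", "noaa_climate_regions.csv", package = "heatfe")
  utils::read.csv(path, stringsAsFactors = FALSE)
}
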