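#' Inverse-distance-weighted interpolation at one target point
#'
#' `sum(w_i v_i) / sum(w_i)` with `w_i = d_i^(-power)` over the `k` nearest
#' stations, using great-circle (haversine) distances. A station coincident
#' with the target returns that station's value exactly; several coincident
#' stations with conflicting values are an error naming the stations.
#'
#' @param points data frame with columns `lat`, `lon`, `value` and
#'   optionally `station_id`; rows with missing value are ignored.
#' @param target numeric `c(lat, lon)` of the interpolation point.
#' @param power positive distance-decay exponent (2 by default).
#' @param k number of nearest stations to use; `NULL` (default) uses all.
#' @param distances optional precomputed distances to the target, overriding
#'   the haversine computation (any consistent length unit; IDW is invariant
#'   to a uniform rescaling of all distances).
#' @return interpolated value (a convex combination of the station values).
#' @export
idw <- function(points, target, power = 2, k = NULL, distances = NULL) {
  stopifnot(power > 0)
  keep <- is.finite(points$value)
  if (!any(keep)) stop("no finite station values to interpolate from")
  points <- points[keep, , drop = FALSE]
  d <- if (!is.null(distances)) {
    as.numeric(distances)[keep]
  } else {
    geosphere::distHaversine(cbind(points$lon, points$lat),
                             c(target[2], target[1]))
  }
  if (!is.null(k) && k < length(d)) {
    nn <- order(d)[seq_len(k)]
    d <- d[nn]
    points <- points[nn, , drop = FALSE]
  }
  hit <- d == 0
  if (any(hit)) {
    v <- unique(points$value[hit])
    if (length(v) > 1) {
      ids <- if (!is.null(points$station_id)) points$station_id[hit]
             else which(hit)
      stop("coincident stations with conflicting values at target: ",
           paste(ids, collapse = ", "))
    }
    return(v)
  }
  w <- d^(-power)
  sum(w * points$value) / sum(w)
}

#' Interpolate station meteorology to county-month covariates
#'
#' For each day with any station report, interpolates temperature and
#' precipitation to every county centroid by IDW, then aggregates the daily
#' centroid values within calendar months (mean for temperature; mean for
#' precipitation by default, with a `sum` option for monthly totals).
#' Months with no daily records are absent from the output, never
#' zero-filled. Counties for which no station is ever reachable are listed
#' in an exclusion report rather than dropped silently.
#'
#' @param stations data frame: station_id, lat, lon, date, temp, precip.
#' @param centroids data frame: county_id, lat, lon.
#' @param power,k IDW parameters (see [idw()]).
#' @param precip_agg `"mean"` of daily values (default) or `"sum"`.
#' @return list with `panel` (county_id, year, month, temp, precip) and
#'   `excluded` (county ids with no reachable station).
#' @export
build_weather_panel <- function(stations, centroids, power = 2, k = NULL,
                                precip_agg = c("mean", "sum")) {
  precip_agg <- match.arg(precip_agg)
  stopifnot(all(c("lat", "lon", "date", "temp", "precip") %in% names(stations)),
            all(c("county_id", "lat", "lon") %in% names(centroids)))
  if (any(abs(stations$lat) > 90) || any(abs(stations$lon) > 180))
    stop("station coordinates out of range")
  days <- split(stations, stations$date)
  rows <- vector("list", length(days) * nrow(centroids))
  r <- 0L
  excluded <- character(0)
  for (ci in seq_len(nrow(centroids))) {
    tgt <- c(centroids$lat[ci], centroids$lon[ci])
    any_ok <- FALSE
    for (dd in days) {
      ok_t <- is.finite(dd$temp); ok_p <- is.finite(dd$precip)
      if (!any(ok_t) && !any(ok_p)) next
      tv <- if (any(ok_t)) idw(data.frame(lat = dd$lat, lon = dd$lon,
                                          value = dd$temp,
                                          station_id = dd$station_id),
                               tgt, power = power, k = k) else NA_real_
      pv <- if (any(ok_p)) idw(data.frame(lat = dd$lat, lon = dd$lon,
                                          value = dd$precip,
                                          station_id = dd$station_id),
                               tgt, power = power, k = k) else NA_real_
      any_ok <- TRUE
      r <- r + 1L
      rows[[r]] <- data.frame(county_id = centroids$county_id[ci],
                              date = dd$date[1], temp = tv, precip = pv,
                              stringsAsFactors = FALSE)
    }
    if (!any_ok) excluded <- c(excluded, as.character(centroids$county_id[ci]))
  }
  daily <- do.call(rbind, rows[seq_len(r)])
  if (is.null(daily)) return(list(panel = NULL, excluded = excluded))
  daily$date <- as.Date(daily$date)
  key <- list(county_id = daily$county_id,
              year = as.integer(format(daily$date, "%Y")),
              month = as.integer(format(daily$date, "%m")))
  agg_t <- stats::aggregate(daily$temp, key, mean, na.rm = TRUE)
  agg_p <- stats::aggregate(daily$precip, key,
                            if (precip_agg == "mean") function(z) mean(z, na.rm = TRUE)
                            else function(z) sum(z, na.rm = TRUE))
  out <- agg_t
  names(out)[4] <- "temp"
  out$precip <- agg_p$x[match(paste(out$county_id, out$year, out$month),
                              paste(agg_p$county_id, agg_p$year, agg_p$month))]
  out <- out[order(out$county_id, out$year, out$month), , drop = FALSE]
  rownames(out) <- NULL
  list(panel = out, excluded = excluded)
}
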