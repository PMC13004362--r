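#' Specify a temperature basis
#'
#' Candidate parameterizations of the nonlinear temperature response:
#' natural cubic splines (linear beyond their boundary knots), raw
#' polynomials, and cubic B-splines. The conventional candidates are
#' `"ncs3"` (natural cubic spline, knots at 0, 10, 20 degC), `"ncs7"`
#' (7 knots evenly spaced from -17 to 33 degC), `"linear"`,
#' `"polynomial"` (degree 3) and `"bspline"` (cubic, interior knots at
#' 0/10/20, boundary at the sample range).
#'
#' @param kind one of `"linear"`, `"ncs3"`, `"ncs7"`, `"ncs"`,
#'   `"polynomial"`, `"bspline"`.
#' @param knots spline knots (degC), strictly increasing. For `"ncs"` the
#'   first and last knot are the boundary knots (so the basis has
#'   `length(knots) - 1` columns); for `"bspline"` these are interior knots.
#' @param degree polynomial or B-spline degree (>= 1).
#' @param reference_temperature anchor of the response curve, degC.
#' @return an object of class `basis_spec`.
#' @export
basis_spec <- function(kind = c("linear", "ncs3", "ncs7", "ncs",
                                "polynomial", "bspline"),
                       knots = NULL, degree = NULL,
                       reference_temperature = 10) {
  kind <- match.arg(kind)
  if (kind == "ncs3") { kind <- "ncs"; knots <- knots %||% c(0, 10, 20) }
  if (kind == "ncs7") { kind <- "ncs"; knots <- knots %||% seq(-17, 33, length.out = 7) }
  if (kind == "linear") { kind <- "polynomial"; degree <- 1L }
  if (kind == "polynomial") degree <- as.integer(degree %||% 3L)
  if (kind == "bspline") {
    degree <- as.integer(degree %||% 3L)
    knots <- knots %||% c(0, 10, 20)
  }
  if (kind == "ncs") {
    if (is.null(knots) || length(knots) < 2) stop("ncs basis needs >= 2 knots")
  }
  if (!is.null(knots) && any(diff(knots) <= 0)) stop("knots must be strictly increasing")
  if (!is.null(degree) && degree < 1) stop("degree must be >= 1")
  structure(list(kind = kind, knots = knots, degree = degree,
                 boundary = NULL,
                 reference_temperature = reference_temperature),
            class = "basis_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate the temperature basis
#'
#' Returns the design columns representing `f(temp)`. Natural cubic spline
#' columns have zero second derivative beyond the outermost knots (linear
#' extrapolation). Data-dependent choices (the B-spline boundary knots) are
#' resolved on first use and frozen into the `resolved_spec` attribute so
#' the identical basis can be re-evaluated on a prediction grid.
#'
#' @param temps numeric vector of temperatures, degC.
#' @param spec a [basis_spec()], possibly already resolved.
#' @param check error when all temperatures are identical (a degenerate
#'   fitting basis); disable for prediction-grid evaluation.
#' @return numeric matrix with one row per temperature; attribute
#'   `resolved_spec` carries the frozen spec.
#' @export
build_basis <- function(temps, spec, check = TRUE) {
  stopifnot(inherits(spec, "basis_spec"))
  temps <- as.numeric(temps)
  if (any(!is.finite(temps))) stop("temperatures must be finite")
  if (check && length(unique(temps)) == 1L && length(temps) > 1L)
    stop("all temperatures identical; basis is degenerate")
  B <- switch(spec$kind,
    polynomial = {
      m <- outer(temps, seq_len(spec$degree), `^`)
      colnames(m) <- paste0("poly", seq_len(spec$degree))
      m
    },
    ncs = {
      k <- spec$knots
      m <- splines::ns(temps, knots = k[-c(1L, length(k))],
                       Boundary.knots = k[c(1L, length(k))])
      m <- unclass(m)
      colnames(m) <- paste0("ncs", seq_len(ncol(m)))
      m
    },
    bspline = {
      if (is.null(spec$boundary)) spec$boundary <- range(temps)
      m <- splines::bs(temps, degree = spec$degree, knots = spec$knots,
                       Boundary.knots = spec$boundary)
      m <- unclass(m)
      colnames(m) <- paste0("bs", seq_len(ncol(m)))
      m
    },
    stop("unknown basis kind: ", spec$kind))
  m <- matrix(as.numeric(B), nrow = length(temps),
              dimnames = list(NULL, colnames(B)))
  attr(m, "resolved_spec") <- spec
  m
}

#' Number of slope parameters a basis contributes
#' @param spec a [basis_spec()].
#' @return integer column count.
#' @export
basis_dim <- function(spec) {
  switch(spec$kind,
         polynomial = spec$degree,
         ncs = length(spec$knots) - 1L,
         bspline = spec$degree + length(spec$knots))
}

#' Fit an exposure-response model with a given temperature basis
#'
#' Adds the basis columns for `temp_col` to the panel and fits the standard
#' weighted two-way fixed-effects regression with precipitation as a linear
#' control. The returned fit carries the resolved basis and the sample
#' temperatures, so [response_curve()] can be applied directly.
#'
#' @param panel county-month panel data frame.
#' @param bspec a [basis_spec()].
#' @param fe,weights,cluster,response,temp_col,precip_col regression setup,
#'   defaulting to the standard design (county-month x state-year fixed
#'   effects, population weights, county clusters).
#' @param ... passed to [fe_spec()].
#' @return an `fe_fit` with extra fields `basis_spec`, `basis_cols`, and
#'   `sample_temps`.
#' @export
fit_basis_model <- function(panel, bspec,
                            fe = list(c("county_id", "month"), c("state_id", "year")),
                            weights = "population", cluster = "county_id",
                            response = "death_rate",
                            temp_col = "temp", precip_col = "precip", ...) {
  B <- build_basis(panel[[temp_col]], bspec)
  rs <- attr(B, "resolved_spec")
  cols <- colnames(B)
  aug <- cbind(panel, as.data.frame(B))
  regs <- c(cols, if (!is.null(precip_col)) precip_col)
  fit <- fe_fit(aug, fe_spec(response, regs, fe = fe,
                             weights = weights, cluster = cluster, ...))
  fit$basis_spec <- rs
  fit$basis_cols <- cols
  fit$sample_temps <- panel[[temp_col]]
  fit
}

#' Select the temperature basis by AIC
#'
#' Fits every candidate basis under identical fixed effects, weights,
#' clustering and rows, and returns the AIC-minimizing candidate together
#' with the full comparison table. Candidates that fail to fit are recorded
#' and excluded from the argmin with a warning; exact AIC ties break toward
#' fewer parameters, then listing order.
#'
#' @param panel county-month panel data frame.
#' @param candidates named list of [basis_spec()]s (>= 2).
#' @param ... passed to [fit_basis_model()].
#' @return list with `best` (name), `best_spec`, `table` (model, n_params,
#'   aic, ok, error), and `fits`.
#' @export
select_model <- function(panel, candidates = list(linear = basis_spec("linear"),
                                                  ncs3 = basis_spec("ncs3")),
                         ...) {
  stopifnot(length(candidates) >= 2, !is.null(names(candidates)))
  fits <- lapply(candidates, function(sp) tryCatch(
    fit_basis_model(panel, sp, ...), error = function(e) e))
  ok <- !vapply(fits, inherits, logical(1), "error")
  aic <- vapply(seq_along(fits), function(i)
    if (ok[i]) fits[[i]]$aic else NA_real_, numeric(1))
  np <- vapply(candidates, basis_dim, integer(1))
  tab <- data.frame(model = names(candidates), n_params = np, aic = aic,
                    ok = ok,
                    error = vapply(fits, function(f)
                      if (inherits(f, "error")) conditionMessage(f) else "",
                      character(1)),
                    row.names = NULL)
  if (!any(ok)) stop("every candidate basis failed to fit")
  if (!all(ok)) warning("candidate(s) failed to fit: ",
                        paste(tab$model[!ok], collapse = ", "))
  cand <- which(ok)
  cand <- cand[order(aic[cand], np[cand], cand)]
  best <- cand[1L]
  list(best = names(candidates)[best], best_spec = candidates[[best]],
       table = tab, fits = fits)
}

#' Exposure-response curve anchored at a reference temperature
#'
#' Effect at temperature T is `b(T)'g - b(ref)'g` with `g` the fitted basis
#' coefficients, so the curve is exactly 0 at the reference. Pointwise
#' variance comes from the delta method on the cluster-robust covariance:
#' `(b(T) - b(ref))' V (b(T) - b(ref))`; 95% bounds are +/- 1.96 SE. A
#' histogram of sample temperatures over the grid bins is attached, and
#' grid points outside the observed range are flagged as extrapolation.
#'
#' @param fit a fit from [fit_basis_model()].
#' @param grid temperature grid, degC; defaults to 60 points over the
#'   sample range.
#' @param reference anchor temperature; defaults to the basis spec's
#'   reference (10 degC).
#' @param level confidence level.
#' @return data frame of class `response_curve`: temp, effect, se, lower,
#'   upper, freq, extrapolated.
#' @export
response_curve <- function(fit, grid = NULL, reference = NULL, level = 0.95) {
  stopifnot(inherits(fit, "fe_fit"), !is.null(fit$basis_spec))
  rs <- fit$basis_spec
  reference <- reference %||% rs$reference_temperature
  rng <- range(fit$sample_temps)
  grid <- grid %||% seq(rng[1], rng[2], length.out = 60)
  Bg <- build_basis(c(reference, grid), rs, check = FALSE)
  Bref <- Bg[1L, , drop = FALSE]
  Bg <- Bg[-1L, , drop = FALSE]
  D <- sweep(Bg, 2L, Bref)
  g <- fit$coefficients[fit$basis_cols]
  V <- fit$vcov[fit$basis_cols, fit$basis_cols, drop = FALSE]
  eff <- drop(D %*% g)
  se <- sqrt(pmax(rowSums((D %*% V) * D), 0))
  z <- stats::qnorm(1 - (1 - level) / 2)
  edges <- if (length(grid) >= 2) {
    c(grid[1] - diff(grid[1:2]) / 2,
      grid[-length(grid)] + diff(grid) / 2,
      grid[length(grid)] + diff(grid)[length(grid) - 1] / 2)
  } else grid + c(-0.5, 0.5)
  freq <- as.vector(table(cut(fit$sample_temps, edges, include.lowest = TRUE)))
  out <- data.frame(temp = grid, effect = eff, se = se,
                    lower = eff - z * se, upper = eff + z * se,
                    freq = freq,
                    extrapolated = grid < rng[1] | grid > rng[2])
  attr(out, "reference") <- reference
  class(out) <- c("response_curve", "data.frame")
  out
}
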