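#' Specify a fixed-effects regression
#'
#' Describes a weighted panel regression whose fixed effects are absorbed by
#' iterated within-group demeaning rather than estimated as dummy
#' coefficients. The default grouping reproduces the two-way design used
#' throughout this package: county-by-calendar-month cells (absorbing local
#' seasonality) crossed with state-by-year cells (absorbing state-level
#' annual trends).
#'
#' @param response name of the response column (an outcome rate).
#' @param regressors character vector of regressor column names (exposure
#'   basis columns, precipitation terms, interactions, ...).
#' @param fe list of character vectors; each vector names the columns whose
#'   interaction defines one fixed-effect dimension. An empty list fits with
#'   a global intercept only.
#' @param weights name of the weight column (typically population), or
#'   `NULL` for unit weights. Weights are rescaled to mean 1 internally so
#'   that results are invariant to the weight scale.
#' @param cluster name of the cluster column for the robust covariance
#'   (typically the county id), or `NULL` to cluster on rows
#'   (heteroskedasticity-robust).
#' @param demean_tol convergence tolerance of the alternating-projection
#'   demeaning, relative to each column's scale.
#' @param max_iter maximum demeaning sweeps before aborting.
#' @return an object of class `fe_spec`.
#' @seealso [fe_fit()]
#' @export
fe_spec <- function(response, regressors,
                    fe = list(c("county_id", "month"), c("state_id", "year")),
                    weights = "population", cluster = "county_id",
                    demean_tol = 1e-10, max_iter = 2000L) {
  stopifnot(is.character(response), length(response) == 1L,
            is.character(regressors), length(regressors) >= 1L,
            is.list(fe), demean_tol > 0, max_iter >= 1L)
  structure(list(response = response, regressors = regressors, fe = fe,
                 weights = weights, cluster = cluster,
                 demean_tol = demean_tol, max_iter = as.integer(max_iter)),
            class = "fe_spec")
}

#' Iterated within-group demeaning (alternating projections)
#'
#' Removes weighted group means over each fixed-effect dimension in turn
#' until no cell changes by more than `tol` times its column scale. For a
#' single dimension one sweep is exact; for crossed dimensions the sweeps
#' converge to the projection onto the orthogonal complement of the span of
#' all group indicators under the weighted inner product.
#'
#' @param values numeric matrix (or vector) of columns to demean.
#' @param groups list of grouping vectors (coerced to factor), one per
#'   fixed-effect dimension; each must have `nrow(values)` entries.
#' @param weights positive observation weights, or `NULL` for unit weights.
#' @param tol convergence tolerance relative to column scale.
#' @param max_iter maximum number of full sweeps.
#' @return the demeaned matrix, with attribute `iterations`.
#' @export
within_demean <- function(values, groups, weights = NULL,
                          tol = 1e-10, max_iter = 2000L) {
  x <- as.matrix(values)
  storage.mode(x) <- "double"
  n <- nrow(x)
  stopifnot(tol > 0, length(groups) >= 1L)
  idx <- lapply(groups, function(g) {
    stopifnot(length(g) == n)
    as.integer(factor(g))
  })
  w <- if (is.null(weights)) rep.int(1, n) else as.numeric(weights)
  stopifnot(length(w) == n, all(w > 0))
  # column scale for the relative convergence test (guards near-constant cols)
  scl <- pmax(apply(abs(x), 2L, max), 1)
  wsum <- lapply(idx, function(g) as.vector(rowsum(w, g)))
  iter <- 0L
  repeat {
    iter <- iter + 1L
    delta <- 0
    for (d in seq_along(idx)) {
      g <- idx[[d]]
      m <- rowsum(x * w, g) / wsum[[d]]
      adj <- m[g, , drop = FALSE]
      x <- x - adj
      delta <- max(delta, max(apply(abs(adj), 2L, max) / scl))
    }
    if (delta < tol) break
    if (iter >= max_iter) {
      stop("within_demean did not converge in ", max_iter,
           " sweeps (last relative change ", format(delta), ")")
    }
  }
  attr(x, "iterations") <- iter
  x
}

#' Fit a weighted fixed-effects panel regression
#'
#' Demeans the response and regressors jointly over the fixed-effect
#' dimensions, solves weighted least squares on the demeaned data, and
#' attaches a cluster-robust (CR1) covariance. Coefficients are identical to
#' the full dummy-variable weighted regression; the absorbed fixed-effect
#' degrees of freedom enter the small-sample correction.
#'
#' @param panel data frame holding all columns named by `spec`.
#' @param spec an [fe_spec()].
#' @return an object of class `fe_fit` with components `coefficients`,
#'   `vcov`, `se`, `residuals` (on demeaned data), `wSSR`, `n_obs`,
#'   `n_clusters`, `fe_dof`, `k_model`, `df_residual`, `aic`,
#'   `demean_iterations`, plus the spec.
#' @examples
#' sim <- generate_panel(panel_dgp_config(n_counties = 20, n_states = 4,
#'                                        years = 2013:2016, seed = 1))
#' fit <- fe_fit(sim$panel, fe_spec("death_rate", c("temp", "precip")))
#' coef(fit)
#' @export
fe_fit <- function(panel, spec) {
  stopifnot(inherits(spec, "fe_spec"))
  need <- c(spec$response, spec$regressors, unlist(spec$fe),
            spec$weights, spec$cluster)
  miss <- setdiff(need, names(panel))
  if (length(miss)) stop("panel is missing columns: ", paste(miss, collapse = ", "))

  y <- as.numeric(panel[[spec$response]])
  X <- as.matrix(panel[spec$regressors])
  storage.mode(X) <- "double"
  n <- length(y)
  if (any(!is.finite(y)) || any(!is.finite(X)))
    stop("non-finite values in response or regressors; validate the panel first")

  w <- if (is.null(spec$weights)) rep.int(1, n) else as.numeric(panel[[spec$weights]])
  if (any(w <= 0) || anyNA(w)) stop("weights must be strictly positive")
  w <- w / mean(w)

  groups <- if (length(spec$fe)) {
    lapply(spec$fe, function(cols) interaction(panel[cols], drop = TRUE, lex.order = TRUE))
  } else {
    list(rep.int(1L, n))  # grand mean only: plain intercept model
  }

  zd <- within_demean(cbind(y, X), groups, weights = w,
                      tol = spec$demean_tol, max_iter = spec$max_iter)
  iters <- attr(zd, "iterations")
  yd <- zd[, 1L]
  Xd <- zd[, -1L, drop = FALSE]
  colnames(Xd) <- spec$regressors

  # a regressor constant within FE cells demeans to (numerical) zero; qr's
  # rank test is relative to each column's own scale and would miss it
  norm0 <- sqrt(colSums(w * X^2))
  normd <- sqrt(colSums(w * Xd^2))
  absorbed <- normd <= 1e-8 * pmax(norm0, 1)
  if (any(absorbed)) {
    stop("rank-deficient design after demeaning; collinear/absorbed column(s): ",
         paste(spec$regressors[absorbed], collapse = ", "))
  }
  sw <- sqrt(w)
  qrX <- qr(Xd * sw)
  p <- ncol(Xd)
  if (qrX$rank < p) {
    bad <- colnames(Xd)[qrX$pivot[(qrX$rank + 1L):p]]
    stop("rank-deficient design after demeaning; collinear/absorbed column(s): ",
         paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qrX, yd * sw)
  names(beta) <- spec$regressors
  e <- yd - drop(Xd %*% beta)
  wssr <- sum(w * e^2)

  fe_dof <- .fe_dof(groups)
  k_model <- p + fe_dof
  df_resid <- n - k_model
  if (df_resid <= 0) stop("no residual degrees of freedom (n = ", n,
                          ", absorbed + slope parameters = ", k_model, ")")

  cl <- if (is.null(spec$cluster)) seq_len(n) else panel[[spec$cluster]]
  if (anyNA(cl)) stop("cluster column contains missing values")
  V <- cluster_vcov(Xd, e, w, cl, k_model = k_model)

  # a residual sum at floating-point roundoff of the response scale counts
  # as an exact (degenerate) fit: AIC is then undefined
  degenerate <- wssr <= .Machine$double.eps^2 * max(sum(w * yd^2), .Machine$double.xmin)
  aic <- if (!degenerate) n * log(wssr / n) + 2 * p else NA_real_

  structure(list(coefficients = beta, vcov = V, se = sqrt(diag(V)),
                 residuals = e, weights = w, wSSR = wssr, n_obs = n,
                 n_clusters = length(unique(cl)), fe_dof = fe_dof,
                 k_model = k_model, df_residual = df_resid, aic = aic,
                 demean_iterations = iters, demeaned_design = Xd,
                 spec = spec),
            class = "fe_fit")
}

# Rank of the absorbed fixed-effect space: for one dimension, the number of
# cells; for two crossed dimensions, n1 + n2 minus the number of connected
# components of the bipartite cell graph (union-find). Additional dimensions
# (not used by the standard two-way design) are counted conservatively as
# nlevels - 1 each.
.fe_dof <- function(groups) {
  ks <- vapply(groups, function(g) nlevels(factor(g)), integer(1))
  if (length(groups) == 1L) return(ks[1L])
  g1 <- as.integer(factor(groups[[1L]]))
  g2 <- as.integer(factor(groups[[2L]])) + ks[1L]
  parent <- seq_len(ks[1L] + ks[2L])
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (r in seq_along(g1)) {
    a <- find(g1[r]); b <- find(g2[r])
    if (a != b) parent[b] <- a
  }
  ncomp <- length(unique(vapply(seq_len(ks[1L] + ks[2L]), find, integer(1))))
  extra <- if (length(groups) > 2L) sum(ks[-(1:2)] - 1L) else 0L
  ks[1L] + ks[2L] - ncomp + extra
}

#' Cluster-robust (CR1) covariance for a demeaned weighted regression
#'
#' Sandwich estimator summing weighted score vectors within clusters, with
#' the small-sample factor G/(G-1) * (N-1)/(N-K), where K counts slope
#' parameters plus absorbed fixed-effect degrees of freedom. With every
#' observation its own cluster this reduces to the HC1 estimator.
#'
#' @param X demeaned design matrix.
#' @param residuals residual vector from the demeaned regression.
#' @param weights observation weights (same scale as used in the fit).
#' @param clusters cluster membership vector.
#' @param k_model total parameters K for the degrees-of-freedom correction.
#' @return a symmetric covariance matrix for the slope coefficients.
#' @export
cluster_vcov <- function(X, residuals, weights, clusters, k_model = ncol(X)) {
  X <- as.matrix(X)
  n <- nrow(X)
  g <- factor(clusters)
  G <- nlevels(g)
  if (G < 2L) stop("need at least 2 clusters; variance is unidentified with ", G)
  A <- crossprod(X, X * weights)
  Ainv <- chol2inv(chol(A))
  scores <- X * (weights * residuals)
  S <- rowsum(scores, g)
  meat <- crossprod(S)
  adj <- (G / (G - 1)) * ((n - 1) / (n - k_model))
  V <- adj * (Ainv %*% meat %*% Ainv)
  V <- (V + t(V)) / 2
  dimnames(V) <- list(colnames(X), colnames(X))
  V
}

#' @export
coef.fe_fit <- function(object, ...) object$coefficients

#' @export
vcov.fe_fit <- function(object, ...) object$vcov

#' Gaussian AIC of a fixed-effects fit
#'
#' `n * log(weighted SSR / n) + 2k` with `k` the number of slope parameters.
#' The absorbed fixed-effect dimension is identical across the candidate
#' models this package compares, so its parameter count is a common additive
#' constant and is omitted; the value is meaningful only for comparing fits
#' of the same response on the same rows and weights.
#'
#' @param object an `fe_fit`.
#' @param ... ignored.
#' @param k ignored (the penalty per parameter is fixed at 2).
#' @return the AIC value.
#' @export
AIC.fe_fit <- function(object, ..., k = 2) {
  if (is.na(object$aic))
    stop("AIC undefined: weighted SSR is zero (degenerate, noiseless fit)")
  object$aic
}

#' @export
print.fe_fit <- function(x, ...) {
  cat("Fixed-effects panel fit\n")
  cat("  n =", x$n_obs, " clusters =", x$n_clusters,
      " absorbed dof =", x$fe_dof,
      " demeaning sweeps =", x$demean_iterations, "\n")
  print(coef_table(x))
  invisible(x)
}

#' Coefficient table with cluster-robust inference
#'
#' @param fit an `fe_fit`.
#' @param level confidence level (normal quantiles).
#' @return data frame with estimate, SE, z, p, and confidence bounds.
#' @export
coef_table <- function(fit, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  est <- fit$coefficients
  se <- fit$se
  zval <- est / se
  data.frame(term = names(est), estimate = unname(est), se = unname(se),
             z = unname(zval),
             p_value = unname(2 * stats::pnorm(-abs(zval))),
             ci_lower = unname(est - z * se), ci_upper = unname(est + z * se),
             row.names = NULL)
}
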