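#' Validate a county-month panel
#'
#' Enforces the panel contract: required columns present; one row per
#' (county, year, month); month in 1..12; population strictly positive;
#' finite temperature and precipitation; nonnegative deaths; and, when both
#' deaths and a rate are present, consistency of
#' `death_rate = deaths / population * rate_scale`. Failing rows are
#' excluded and counted per rule — never imputed. When only deaths are
#' present the rate is computed.
#'
#' @param table data frame to validate.
#' @param rate_scale person-months per rate unit (used to derive or check
#'   the rate when deaths are present).
#' @param rate_tol relative tolerance of the deaths/rate consistency check.
#' @return list with `panel` (the clean rows) and `report` (data frame of
#'   rule, n_excluded).
#' @export
validate_panel <- function(table, rate_scale = 1e7, rate_tol = 1e-8) {
  required <- c("county_id", "state_id", "year", "month", "population",
                "temp", "precip")
  miss <- setdiff(required, names(table))
  if (length(miss)) stop("required column(s) missing: ", paste(miss, collapse = ", "))
  if (!("death_rate" %in% names(table)) && !("deaths" %in% names(table)))
    stop("required column(s) missing: death_rate (or deaths)")

  rules <- c(duplicate_key = 0L, bad_month = 0L, nonpositive_population = 0L,
             missing_meteorology = 0L, negative_deaths = 0L,
             missing_outcome = 0L, rate_inconsistent = 0L)
  drop <- rep(FALSE, nrow(table))
  mark <- function(bad, rule) {
    new <- bad & !drop
    rules[rule] <<- rules[rule] + sum(new)
    drop <<- drop | bad
  }

  key <- paste(table$county_id, table$year, table$month)
  mark(duplicated(key), "duplicate_key")
  mark(!(table$month %in% 1:12), "bad_month")
  mark(!is.finite(table$population) | table$population <= 0,
       "nonpositive_population")
  mark(!is.finite(table$temp) | !is.finite(table$precip), "missing_meteorology")
  if ("deaths" %in% names(table))
    mark(is.finite(table$deaths) & table$deaths < 0, "negative_deaths")
  has_rate <- "death_rate" %in% names(table) && any(is.finite(table$death_rate))
  if (has_rate) {
    mark(!is.finite(table$death_rate), "missing_outcome")
  } else {
    mark(!is.finite(table$deaths), "missing_outcome")
  }
  if (has_rate && "deaths" %in% names(table)) {
    implied <- table$deaths / table$population * rate_scale
    bad <- is.finite(table$deaths) & is.finite(table$death_rate) &
      abs(implied - table$death_rate) >
        rate_tol * pmax(abs(implied), abs(table$death_rate), 1)
    mark(bad, "rate_inconsistent")
  }

  clean <- table[!drop, , drop = FALSE]
  if (!has_rate)
    clean$death_rate <- clean$deaths / clean$population * rate_scale
  rownames(clean) <- NULL
  list(panel = clean,
       report = data.frame(rule = names(rules), n_excluded = as.integer(rules),
                           row.names = NULL))
}

# full-precision decimal serialization so write -> read round-trips exactly
.fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (!is.finite(v)) return(as.character(v))
    s <- sprintf("%.17g", v)
    if (as.numeric(sprintf("%.15g", v)) == v) s <- sprintf("%.15g", v)
    s
  }, character(1))
  out
}

#' Write a table as CSV with round-trip-exact numerics
#'
#' One UTF-8 header row; doubles serialized with enough digits that
#' [read_panel_csv()] reproduces them bit-for-bit.
#'
#' @param table data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_panel_csv <- function(table, path) {
  out <- table
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- .fmt_num(out[[j]])
  }
  utf8 <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(utf8))
  utils::write.csv(out, utf8, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a CSV written by [write_panel_csv()] (or any plain CSV)
#' @param path input file.
#' @return data frame.
#' @export
read_panel_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
}

# small stable rolling hash of the serialized configuration, for the manifest
.config_hash <- function(x) {
  bytes <- utf8ToInt(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                      force = TRUE))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full analysis pipeline on one configuration
#'
#' Synthesizes (or loads) a county-month panel, validates it, selects the
#' temperature basis by AIC, fits the displacement model and reports the
#' net effect, tabulates the anchored response curve, runs the default
#' heterogeneity analyses, and projects cumulative excess deaths under a
#' synthetic (or supplied) multi-model warming ensemble. All tables are
#' written as CSV to `out_dir` together with a machine-readable manifest
#' (seed, package version, configuration hash) and a line-oriented log.
#'
#' @param config a named list (or path to a JSON/YAML file) with optional
#'   entries: `seed`; `panel_csv` (skip simulation); `dgp` (arguments to
#'   [panel_dgp_config()]); `candidates` (basis names among linear, ncs3,
#'   ncs7, polynomial, bspline); `lags`; `hetero_by`/`hetero_breaks`;
#'   `projection` (list: enabled, n_models, delta_mean, delta_sd, B,
#'   base_year, end_year, growth_rate, ramp, months_per_year) and
#'   `out_dir`.
#' @param out_dir output directory (created if absent); overrides the
#'   config entry.
#' @return invisibly, a list of the in-memory stage results.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("reading YAML configs requires the yaml package")
      yaml::read_yaml(config)
    } else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  out_dir <- out_dir %||% config$out_dir %||% stop("out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L
  log_path <- file.path(out_dir, "log.txt")
  cat("", file = log_path)
  logline <- function(stage, ...) {
    cat(sprintf("[%s] %s\n", stage, paste0(...)), file = log_path, append = TRUE)
  }
  stage <- function(name, expr) {
    logline(name, "start")
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           " (partial outputs kept in ", out_dir, ")", call. = FALSE))
    logline(name, "done")
    res
  }
  results <- list()

  results$panel_raw <- stage("simulate", {
    if (!is.null(config$panel_csv)) {
      read_panel_csv(config$panel_csv)
    } else {
      dgp <- do.call(panel_dgp_config,
                     utils::modifyList(config$dgp %||% list(), list(seed = seed)))
      sim <- generate_panel(dgp)
      jsonlite::write_json(sim$truth[c("beta_temp", "beta_precip",
                                       "lag_effects", "baseline_rate",
                                       "rate_scale")],
                           file.path(out_dir, "truth.json"),
                           auto_unbox = TRUE, digits = NA)
      sim$panel
    }
  })
  val <- stage("validate", validate_panel(results$panel_raw))
  results$validation <- val$report
  panel <- val$panel
  write_panel_csv(panel, file.path(out_dir, "panel.csv"))
  write_panel_csv(val$report, file.path(out_dir, "validation.csv"))
  logline("validate", sum(val$report$n_excluded), " row(s) excluded")

  cand_names <- config$candidates %||% c("linear", "ncs3")
  results$selection <- stage("select", {
    cands <- stats::setNames(lapply(cand_names, basis_spec), cand_names)
    sel <- select_model(panel, cands)
    write_panel_csv(sel$table[c("model", "n_params", "aic", "ok")],
                    file.path(out_dir, "aic_table.csv"))
    sel
  })

  lags <- as.integer(config$lags %||% c(-1L, 0L, 1L))
  results$lag_fit <- stage("fit", {
    fit <- fit_lag_model(panel, lags = lags)
    net <- net_effect(fit)
    jsonlite::write_json(
      list(coefficients = coef_table(fit), n_obs = fit$n_obs,
           n_clusters = fit$n_clusters, aic = fit$aic,
           net_effect = net[c("estimate", "se", "ci_lower", "ci_upper")]),
      file.path(out_dir, "fit.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
    list(fit = fit, net = net)
  })

  results$curve <- stage("curve", {
    bfit <- results$selection$fits[[results$selection$best]]
    crv <- response_curve(bfit)
    write_panel_csv(as.data.frame(crv), file.path(out_dir, "curve.csv"))
    crv
  })

  results$subgroups <- stage("hetero", {
    by <- config$hetero_by %||% "temp"
    breaks <- config$hetero_breaks %||% c(10, 20)
    sg <- binned_fit(panel, by, breaks)
    write_panel_csv(as.data.frame(sg), file.path(out_dir, "subgroups.csv"))
    sg
  })

  pj <- config$projection %||% list()
  if (isTRUE(pj$enabled %||% TRUE)) {
    results$projection <- stage("project", {
      counties <- unique(panel$county_id)
      deltas <- generate_climate_models(pj$n_models %||% 10L, counties,
                                        delta_mean = pj$delta_mean %||% 2.0,
                                        delta_sd = pj$delta_sd %||% 0.5,
                                        seed = seed + 1L)
      pop0 <- panel$population[match(counties, panel$county_id)]
      names(pop0) <- counties
      base_year <- pj$base_year %||% 2020L
      end_year <- pj$end_year %||% 2050L
      pops <- generate_population_paths(pop0, base_year, end_year,
                                        growth_rate = pj$growth_rate %||% 0.005)
      ens <- project_excess_deaths(
        panel, deltas, pops, B = pj$B %||% 200L,
        base_year = base_year, end_year = end_year,
        ramp = pj$ramp %||% "linear", lags = lags,
        months_per_year = pj$months_per_year %||% 12,
        beta_scale = pj$beta_scale %||% 1e7, seed = seed + 2L)
      write_panel_csv(ens$summary, file.path(out_dir, "projection.csv"))
      ens
    })
  }

  manifest <- list(seed = seed,
                   package = "heatfe",
                   version = as.character(utils::packageVersion("heatfe")),
                   config = config,
                   config_hash = .config_hash(config),
                   outputs = list.files(out_dir))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  logline("manifest", "written")
  invisible(results)
}
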