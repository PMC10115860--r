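# Readers and writers for the delimited interchange formats. Dates are
# ISO-8601; windspeeds are m/s throughout (unit conversion belongs at the
# boundary of the pipeline, not inside it).

#' Read storm events from CSV
#'
#' Expects columns `storm_id`, `closest_date` (ISO-8601), `windspeed` (m/s)
#' and one of `zcta_id` or `county_id`.
#'
#' @param path CSV file path.
#' @return data frame of storm events with `closest_date` parsed as `Date`.
#' @export
read_storm_events <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("storm_id", "closest_date", "windspeed")
  missing <- setdiff(need, names(d))
  if (length(missing) > 0L) {
    stop("storm event file lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (!any(c("zcta_id", "county_id") %in% names(d))) {
    stop("storm event file needs a `zcta_id` or `county_id` column")
  }
  d$closest_date <- as.Date(d$closest_date)
  if (anyNA(d$closest_date)) stop("unparseable closest_date values (expect ISO-8601)")
  d
}

#' Read daily counts from CSV
#'
#' Expects `zcta_id`, `date` (ISO-8601), `count`, and optionally the
#' subgroup columns `age`, `sex`, `dual`.
#'
#' @param path CSV file path.
#' @return data frame with `date` parsed as `Date`.
#' @export
read_counts <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("zcta_id", "date", "count"), names(d))
  if (length(missing) > 0L) {
    stop("counts file lacks column(s): ", paste(missing, collapse = ", "))
  }
  d$date <- as.Date(d$date)
  if (any(d$count < 0) || any(d$count != round(d$count))) {
    stop("counts must be nonnegative integers")
  }
  d
}

#' Read beneficiary denominators from CSV
#'
#' Expects `zcta_id`, `year`, `n`, and optionally subgroup columns.
#'
#' @param path CSV file path.
#' @return data frame.
#' @export
read_denominators <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("zcta_id", "year", "n"), names(d))
  if (length(missing) > 0L) {
    stop("denominator file lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (any(d$n <= 0)) stop("denominators must be positive")
  d
}

#' Read community covariates from CSV
#'
#' Expects `zcta_id` plus numeric covariate columns.
#'
#' @param path CSV file path.
#' @return data frame.
#' @export
read_community <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"zcta_id" %in% names(d)) stop("community file needs a `zcta_id` column")
  d
}

#' Read ZCTA-county overlap weights from CSV
#'
#' Expects `zcta_id`, `county_id`, `land_area_fraction`.
#'
#' @param path CSV file path.
#' @return data frame.
#' @export
read_overlaps <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("zcta_id", "county_id", "land_area_fraction"), names(d))
  if (length(missing) > 0L) {
    stop("overlap file lacks column(s): ", paste(missing, collapse = ", "))
  }
  d
}

#' Read a scenario configuration from YAML
#'
#' @param path YAML file (keys are [tc_scenario()] arguments).
#' @return a `tc_scenario` object.
#' @export
read_scenario <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(tc_scenario))
  extra <- setdiff(names(cfg), c(known, "annual_denominators"))
  if (length(extra) > 0L) {
    stop("unknown scenario field(s): ", paste(extra, collapse = ", "))
  }
  if (!is.null(cfg$years)) {
    cfg$years <- seq(min(unlist(cfg$years)), max(unlist(cfg$years)))
  }
  do.call(tc_scenario, cfg)
}

#' Serialize a fitted model as JSON
#'
#' Writes coefficients, the lag covariance matrix, nuisance terms, the
#' random-intercept variance and convergence diagnostics.
#'
#' @param fit a [stormlag()] fit.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_stormlag_json <- function(fit, path) {
  stopifnot(inherits(fit, "stormlag"))
  payload <- list(
    beta = as.list(fit$beta),
    se_beta = as.list(fit$se_beta),
    vcov_beta = fit$vcov_beta,
    nuisance = as.list(fit$nuisance),
    ranef_variance = fit$ranef_variance,
    separated = as.list(fit$separated),
    method = fit$method, fallback = fit$fallback,
    converged = fit$converged, iterations = fit$iterations,
    nobs = fit$nobs, n_sets = fit$n_sets, n_zctas = fit$n_zctas
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor", na = "null")
  invisible(path)
}

#' Write a relative-risk table as CSV
#'
#' @param rr data frame of RR estimates (per lag and/or cumulative).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_rr_table <- function(rr, path) {
  utils::write.csv(rr, path, row.names = FALSE)
  invisible(path)
}
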