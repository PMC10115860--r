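#' Simulation scenario configuration
#'
#' Defines the data-generating process for the synthetic study: the storm
#' calendar, community covariates, Medicare-style beneficiary denominators,
#' and daily cause-specific hospitalization counts drawn from the same
#' distributed-lag mixed Poisson model that [stormlag()] fits. Every downstream
#' stage of the pipeline (exposure classification, matching, model fitting,
#' stratified analyses) can therefore be validated against known truth.
#'
#' The linear predictor of the generative model for ZCTA \eqn{z} on day
#' \eqn{t} is
#' \deqn{\log \mu_{zt} = \alpha + \alpha_z + \sum_{l=-2}^{7} \beta_l x_{t+l,z}
#'   + \log n_{zy} + \delta'\mathrm{DOW}_t + \gamma'\mathrm{Year}_t,}
#' with \eqn{\alpha_z \sim N(0, \sigma^2)} a ZCTA random intercept,
#' \eqn{x_{t+l,z}} the indicator that day \eqn{t} sits at lag \eqn{l} of a
#' storm's closest-approach day in \eqn{z}, and \eqn{n_{zy}} the beneficiary
#' denominator for the ZCTA-year. Counts are Poisson given \eqn{\mu_{zt}}.
#'
#' @param n_zctas number of ZCTAs (spatial units).
#' @param years inclusive year range of the study period, e.g. `1999:2016`.
#' @param storms_per_year expected qualifying storms per ZCTA per year. The
#'   default 0.2261 reproduces a mean burden of about 4.07 storms per ZCTA
#'   over an 18-year period, the burden observed for Florida ZCTAs.
#' @param windspeed_location,windspeed_scale location and scale (m/s) of the
#'   normal distribution of peak sustained windspeed, truncated below at
#'   `windspeed_min`; the generator emits only qualifying storms.
#' @param windspeed_min lower truncation for generated windspeeds (m/s);
#'   defaults to the 21 m/s gale-force exposure threshold.
#' @param true_lag_betas numeric vector of 10 log rate ratios, one per lag in
#'   -2..7. The default is a respiratory-disease-like profile whose sum is
#'   1.47 (cumulative RR about 4.35).
#' @param baseline_log_rate log hospitalizations per beneficiary-day on
#'   reference days (Monday of the first year, no storm).
#' @param dow_effects 7 log-rate effects for Monday..Sunday; Monday must be 0.
#' @param year_effects one log-rate effect per study year; the first must be
#'   0. `NULL` gives a mild 1 percent-per-year drift.
#' @param random_intercept_sd standard deviation of the ZCTA random intercept.
#' @param denominator_range length-2 integer bounds for beneficiaries per
#'   ZCTA-year (drawn uniformly per ZCTA, then perturbed mildly by year).
#' @param annual_denominators if `FALSE`, each ZCTA keeps its first-year
#'   denominator for the whole period.
#' @param season integer months in which storms can occur (default
#'   June-November, the Atlantic hurricane season).
#' @param modifier_effect optional multiplier applied to `true_lag_betas` in
#'   ZCTAs above the median of `modifier_covariate` (scalar, recycled, or one
#'   value per lag). Used for effect-modification scenarios.
#' @param modifier_covariate community covariate whose median split defines
#'   the modified stratum.
#' @param community_correlation optional 10x10 positive-definite correlation
#'   matrix for the community covariates; `NULL` uses a one-factor
#'   socioeconomic structure.
#' @param subgroups if `TRUE`, counts and denominators are generated at
#'   age x sex x dual-eligibility resolution (fixed enrollment proportions)
#'   and sum exactly to the ZCTA totals.
#' @param rate_ceiling guard: the generator aborts if any Poisson mean
#'   exceeds this value (catches runaway configurations).
#' @param seed integer seed controlling all randomness in the generator.
#'
#' @return an object of class `tc_scenario`: a validated list of the above.
#' @seealso [simulate_tc_data()], [simulate_storm_calendar()],
#'   [simulate_counts()], [simulate_community()]
#' @examples
#' cfg <- tc_scenario(n_zctas = 20, years = 2004:2009, seed = 1)
#' cfg$true_lag_betas
#' @export
tc_scenario <- function(n_zctas = 100L,
                        years = 1999:2016,
                        storms_per_year = 0.2261,
                        windspeed_location = 27.65,
                        windspeed_scale = 5,
                        windspeed_min = 21,
                        true_lag_betas = c(0, 0.18, 0.10, 0.20, 0.25,
                                           0.25, 0.20, 0.15, 0.10, 0.04),
                        baseline_log_rate = log(8.3e-5),
                        dow_effects = c(0, 0.01, 0, -0.01, 0.02, -0.05, -0.07),
                        year_effects = NULL,
                        random_intercept_sd = 0.25,
                        denominator_range = c(500L, 3000L),
                        annual_denominators = TRUE,
                        season = 6:11,
                        modifier_effect = NULL,
                        modifier_covariate = "poverty",
                        community_correlation = NULL,
                        subgroups = FALSE,
                        rate_ceiling = 1e6,
                        seed = 1L) {
  n_zctas <- as.integer(n_zctas)
  if (is.na(n_zctas) || n_zctas < 1L) stop("`n_zctas` must be a positive integer")
  years <- as.integer(years)
  if (length(years) < 1L || any(diff(years) != 1L)) {
    stop("`years` must be a consecutive, increasing year range")
  }
  stop_if_not_scalar_number(storms_per_year, "storms_per_year")
  if (storms_per_year < 0) stop("`storms_per_year` must be nonnegative")
  if (windspeed_min < 0) stop("`windspeed_min` must be nonnegative")
  if (length(true_lag_betas) != length(.LAGS)) {
    stop(sprintf("`true_lag_betas` must have %d entries (lags %d..%d)",
                 length(.LAGS), min(.LAGS), max(.LAGS)))
  }
  if (length(dow_effects) != 7L) stop("`dow_effects` must have 7 entries")
  if (dow_effects[1L] != 0) stop("`dow_effects[1]` (Monday, the reference) must be 0")
  if (is.null(year_effects)) {
    year_effects <- 0.01 * (seq_along(years) - 1L)
  }
  if (length(year_effects) != length(years)) {
    stop("`year_effects` must have one entry per study year")
  }
  if (year_effects[1L] != 0) stop("`year_effects[1]` (first year, the reference) must be 0")
  stop_if_not_scalar_number(random_intercept_sd, "random_intercept_sd")
  if (random_intercept_sd < 0) stop("`random_intercept_sd` must be nonnegative")
  denominator_range <- as.integer(denominator_range)
  if (length(denominator_range) != 2L || any(denominator_range < 1L) ||
      denominator_range[1L] > denominator_range[2L]) {
    stop("`denominator_range` must be increasing positive integer bounds")
  }
  if (!all(season %in% 1:12)) stop("`season` must be months in 1..12")
  if (!is.null(modifier_effect)) {
    if (!length(modifier_effect) %in% c(1L, length(.LAGS))) {
      stop("`modifier_effect` must be a scalar or one multiplier per lag")
    }
    modifier_effect <- rep_len(as.numeric(modifier_effect), length(.LAGS))
    if (!modifier_covariate %in% community_covariate_names()) {
      stop("`modifier_covariate` must be one of: ",
           paste(community_covariate_names(), collapse = ", "))
    }
  }
  if (!is.null(community_correlation)) {
    community_correlation <- validate_correlation(community_correlation)
  }
  structure(list(
    n_zctas = n_zctas, years = years, storms_per_year = storms_per_year,
    windspeed_location = windspeed_location, windspeed_scale = windspeed_scale,
    windspeed_min = windspeed_min,
    true_lag_betas = as.numeric(true_lag_betas),
    baseline_log_rate = baseline_log_rate,
    dow_effects = as.numeric(dow_effects),
    year_effects = as.numeric(year_effects),
    random_intercept_sd = random_intercept_sd,
    denominator_range = denominator_range,
    annual_denominators = isTRUE(annual_denominators),
    season = as.integer(season),
    modifier_effect = modifier_effect,
    modifier_covariate = modifier_covariate,
    community_correlation = community_correlation,
    subgroups = isTRUE(subgroups),
    rate_ceiling = rate_ceiling,
    seed = as.integer(seed)
  ), class = "tc_scenario")
}

#' @export
print.tc_scenario <- function(x, ...) {
  cat("Tropical cyclone simulation scenario\n")
  cat(sprintf("  ZCTAs: %d   years: %d-%d   storms/ZCTA-year: %.4g\n",
              x$n_zctas, min(x$years), max(x$years), x$storms_per_year))
  cat(sprintf("  true lag betas (%s): %s\n",
              paste(range(.LAGS), collapse = ".."),
              paste(format(x$true_lag_betas, digits = 3), collapse = " ")))
  cat(sprintf("  baseline log rate: %.3f   random intercept sd: %.3g   seed: %d\n",
              x$baseline_log_rate, x$random_intercept_sd, x$seed))
  if (!is.null(x$modifier_effect)) {
    cat(sprintf("  effect modifier: x%s on betas in above-median %s ZCTAs\n",
                paste(format(unique(x$modifier_effect)), collapse = "/"),
                x$modifier_covariate))
  }
  invisible(x)
}

#' Packaged study scenarios
#'
#' Three ready-made scenarios used throughout the package's validation:
#' \describe{
#'   \item{"recovery"}{the package default: 100 ZCTAs, study years
#'     1999-2016, ~4 storms per ZCTA, a respiratory-disease-like lag profile
#'     summing to 1.47 (cumulative RR about 4.35), and ZCTA random
#'     intercepts. Used for parameter recovery.}
#'   \item{"null"}{all lag effects zero over the same 18-year calendar, 12
#'     ZCTAs, no random intercept; cheap enough for hundreds of replicates.
#'     Used for confidence-interval calibration and null contrasts.}
#'   \item{"modifier"}{40 ZCTAs over 6 years with a lag-0 log RR of ln 2,
#'     doubled (on the log scale) in ZCTAs above the poverty median, so the
#'     between-strata RR ratio at lag 0 is exactly 2. Used for
#'     effect-modification recovery.}
#' }
#'
#' @param name one of "recovery", "null", "modifier".
#' @param seed scenario seed (default: a fixed per-scenario seed).
#' @return a [tc_scenario()] object.
#' @export
tc_example_scenario <- function(name = c("recovery", "null", "modifier"),
                                seed = NULL) {
  name <- match.arg(name)
  switch(name,
    recovery = tc_scenario(seed = seed %||% 10L),
    null = tc_scenario(n_zctas = 12L, years = 1999:2016,
                       storms_per_year = 0.2261,
                       true_lag_betas = rep(0, 10),
                       baseline_log_rate = log(3e-4),
                       random_intercept_sd = 0,
                       modifier_covariate = "income",
                       seed = seed %||% 20L),
    modifier = tc_scenario(n_zctas = 40L, years = 2004:2009,
                           storms_per_year = 0.5,
                           true_lag_betas = c(0, 0, log(2), 0, 0, 0, 0, 0, 0, 0),
                           baseline_log_rate = log(5e-4),
                           random_intercept_sd = 0,
                           modifier_effect = c(1, 1, 2, 1, 1, 1, 1, 1, 1, 1),
                           modifier_covariate = "poverty",
                           seed = seed %||% 30L))
}

#' Names of the ten community covariates
#'
#' The covariates mirror the census variables used for neighborhood
#' stratification: education, poverty, income, non-English speakers, household
#' density, housing value, population density, percent urban, percent Black
#' residents, and percent owner-occupied units.
#'
#' @return character vector of length 10.
#' @export
community_covariate_names <- function() {
  c("education", "poverty", "income", "non_english", "household_density",
    "housing_value", "population_density", "pct_urban", "pct_black",
    "pct_owner_occupied")
}

# One-factor SES correlation structure used as the default for community
# covariates: R = L L' + diag(1 - L^2), positive definite by construction.
default_community_correlation <- function() {
  loadings <- c(education = 0.6, poverty = -0.5, income = 0.7,
                non_english = 0.3, household_density = 0.2,
                housing_value = 0.7, population_density = 0.4,
                pct_urban = 0.4, pct_black = -0.1, pct_owner_occupied = -0.3)
  r <- tcrossprod(loadings) + diag(1 - loadings^2)
  dimnames(r) <- list(names(loadings), names(loadings))
  r
}

validate_correlation <- function(r) {
  r <- as.matrix(r)
  p <- length(community_covariate_names())
  if (!all(dim(r) == p)) stop(sprintf("correlation matrix must be %dx%d", p, p))
  if (max(abs(r - t(r))) > 1e-10) stop("correlation matrix must be symmetric")
  if (any(abs(diag(r) - 1) > 1e-10)) stop("correlation matrix must have unit diagonal")
  ok <- tryCatch({ chol(r); TRUE }, error = function(e) FALSE)
  if (!ok) stop("correlation matrix must be positive definite")
  dimnames(r) <- list(community_covariate_names(), community_covariate_names())
  r
}
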