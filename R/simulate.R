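#' Simulate a storm calendar
#'
#' Draws, for each ZCTA, a Poisson number of qualifying storms over the study
#' period, with closest-approach dates uniform over the storm season and peak
#' sustained windspeeds from a truncated normal distribution (all emitted
#' storms meet the exposure threshold). Two storms in the same ZCTA may fall
#' arbitrarily close in time, which exercises the matching module's 3-day
#' exclusion rule.
#'
#' @param config a [tc_scenario()] object.
#' @return a data frame of storm events with columns `storm_id`, `zcta_id`,
#'   `closest_date` (`Date`) and `windspeed` (m/s).
#' @examples
#' ev <- simulate_storm_calendar(tc_scenario(n_zctas = 5, years = 2004:2006, seed = 2))
#' @export
simulate_storm_calendar <- function(config) {
  stopifnot(inherits(config, "tc_scenario"))
  set.seed(config$seed + 101L)
  zctas <- zcta_ids(config$n_zctas)
  n_years <- length(config$years)
  n_storms <- stats::rpois(config$n_zctas, config$storms_per_year * n_years)

  all_days <- seq(as.Date(sprintf("%04d-01-01", min(config$years))),
                  as.Date(sprintf("%04d-12-31", max(config$years))), by = "day")
  season_days <- all_days[(as.POSIXlt(all_days)$mon + 1L) %in% config$season]
  if (length(season_days) == 0L) stop("season window contains no days")

  total <- sum(n_storms)
  if (total == 0L) {
    return(data.frame(storm_id = character(), zcta_id = character(),
                      closest_date = as.Date(character()), windspeed = numeric(),
                      stringsAsFactors = FALSE))
  }
  zcta_rep <- rep(zctas, n_storms)
  # dates without replacement within a ZCTA so no two storms share a day there
  dates <- as.Date(unlist(lapply(n_storms[n_storms > 0L], function(k) {
    sample(season_days, k, replace = FALSE)
  })), origin = "1970-01-01")
  # truncated normal via inverse CDF
  p_lo <- stats::pnorm(config$windspeed_min, config$windspeed_location,
                       config$windspeed_scale)
  u <- stats::runif(total, p_lo, 1)
  winds <- stats::qnorm(u, config$windspeed_location, config$windspeed_scale)
  winds <- pmax(winds, config$windspeed_min)  # guard against rounding at the bound

  ev <- data.frame(storm_id = sprintf("S%05d", seq_len(total)),
                   zcta_id = zcta_rep,
                   closest_date = dates,
                   windspeed = winds,
                   stringsAsFactors = FALSE)
  ev[order(ev$zcta_id, ev$closest_date), , drop = FALSE]
}

zcta_ids <- function(n) sprintf("Z%04d", seq_len(n))

#' Simulate community covariate profiles
#'
#' Draws the ten community covariates for each ZCTA from a multivariate normal
#' with a configurable correlation structure (default: a one-factor
#' socioeconomic structure), then rescales each covariate to a realistic
#' census-like location and spread. Percentages are clamped to \[0, 100\] and
#' densities/values to nonnegative; clamping is rare under the default scales.
#'
#' @param config a [tc_scenario()] object with `n_zctas >= 2`.
#' @return data frame with `zcta_id` and one column per covariate (see
#'   [community_covariate_names()]).
#' @export
simulate_community <- function(config) {
  stopifnot(inherits(config, "tc_scenario"))
  if (config$n_zctas < 2L) stop("community simulation needs at least 2 ZCTAs")
  set.seed(config$seed + 202L)
  r <- config$community_correlation %||% default_community_correlation()
  r <- validate_correlation(r)
  p <- ncol(r)
  z <- matrix(stats::rnorm(config$n_zctas * p), config$n_zctas, p) %*% chol(r)
  scales <- community_scales()
  x <- sweep(sweep(z, 2L, scales$sd, "*"), 2L, scales$mean, "+")
  colnames(x) <- community_covariate_names()
  pct <- c("education", "poverty", "non_english", "pct_urban", "pct_black",
           "pct_owner_occupied")
  x[, pct] <- pmin(pmax(x[, pct], 0), 100)
  pos <- c("income", "household_density", "housing_value", "population_density")
  x[, pos] <- pmax(x[, pos], 0)
  data.frame(zcta_id = zcta_ids(config$n_zctas), x, stringsAsFactors = FALSE)
}

community_scales <- function() {
  list(mean = c(education = 25, poverty = 12, income = 55000, non_english = 8,
                household_density = 2.5, housing_value = 180000,
                population_density = 1500, pct_urban = 65, pct_black = 14,
                pct_owner_occupied = 68),
       sd = c(education = 8, poverty = 5, income = 12000, non_english = 4,
              household_density = 0.3, housing_value = 60000,
              population_density = 900, pct_urban = 18, pct_black = 8,
              pct_owner_occupied = 12))
}

# Fixed enrollment proportions used when subgroup resolution is requested.
subgroup_grid <- function() {
  g <- expand.grid(age = c("65-74", "75-84", "85+"),
                   sex = c("male", "female"),
                   dual = c("no", "yes"),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  p_age <- c(`65-74` = 0.45, `75-84` = 0.37, `85+` = 0.18)
  p_sex <- c(male = 0.45, female = 0.55)
  p_dual <- c(no = 0.80, yes = 0.20)
  g$prop <- p_age[g$age] * p_sex[g$sex] * p_dual[g$dual]
  g
}

#' Simulate daily hospitalization counts
#'
#' The forward model of the fitted equation: for each ZCTA-day the Poisson
#' mean is `exp(baseline + random intercept + sum of lag effects + DOW effect
#' + year effect) * denominator`, where the lag effect at lag `l` is active on
#' any day sitting `l` days after a storm's closest approach in that ZCTA.
#' Every ZCTA-day in the study period receives a count row; zeros are genuine
#' Poisson zeros, not missingness.
#'
#' @param config a [tc_scenario()] object.
#' @param events storm events as returned by [simulate_storm_calendar()];
#'   their dates must fall inside the scenario years.
#' @param modifier_above optional character vector of ZCTA ids forming the
#'   "above-median" stratum whose lag effects are multiplied by
#'   `config$modifier_effect`.
#' @return a list with elements `counts` (zcta_id, date, count, plus
#'   age/sex/dual columns when `config$subgroups`), `denominators` (zcta_id,
#'   year, n, plus subgroup columns when applicable) and `random_intercepts`
#'   (named numeric, the realized ZCTA intercepts).
#' @export
simulate_counts <- function(config, events, modifier_above = NULL) {
  stopifnot(inherits(config, "tc_scenario"))
  if (nrow(events) > 0L) {
    ev_years <- date_year(events$closest_date)
    if (any(!ev_years %in% config$years)) {
      stop("storm event dates fall outside the scenario years")
    }
  }
  set.seed(config$seed + 303L)
  zctas <- zcta_ids(config$n_zctas)
  days <- seq(as.Date(sprintf("%04d-01-01", min(config$years))),
              as.Date(sprintf("%04d-12-31", max(config$years))), by = "day")
  n_days <- length(days)
  day_year <- date_year(days)
  dow_idx <- as.integer(day_of_week(days))
  year_idx <- match(day_year, config$years)
  fixed_part <- config$baseline_log_rate + config$dow_effects[dow_idx] +
    config$year_effects[year_idx]

  alpha_z <- stats::rnorm(config$n_zctas, 0, config$random_intercept_sd)
  names(alpha_z) <- zctas

  base_denom <- round(stats::runif(config$n_zctas,
                                   config$denominator_range[1L],
                                   config$denominator_range[2L]))
  n_years <- length(config$years)
  if (config$annual_denominators) {
    denom_mat <- round(outer(base_denom, rep(1, n_years)) *
                         matrix(stats::runif(config$n_zctas * n_years, 0.97, 1.03),
                                config$n_zctas, n_years))
  } else {
    denom_mat <- matrix(base_denom, config$n_zctas, n_years)
  }
  storage.mode(denom_mat) <- "integer"
  dimnames(denom_mat) <- list(zctas, config$years)

  grid <- if (config$subgroups) subgroup_grid() else NULL
  storm_idx_by_zcta <- split(match(events$closest_date, days), events$zcta_id)

  counts_list <- vector("list", config$n_zctas)
  denom_list <- vector("list", config$n_zctas)
  for (i in seq_along(zctas)) {
    z <- zctas[i]
    betas <- config$true_lag_betas
    if (!is.null(modifier_above) && z %in% modifier_above) {
      betas <- betas * (config$modifier_effect %||% rep(1, length(.LAGS)))
    }
    lag_part <- numeric(n_days)
    s_idx <- storm_idx_by_zcta[[z]]
    if (!is.null(s_idx)) {
      for (k in seq_along(.LAGS)) {
        x <- logical(n_days)
        at <- s_idx + .LAGS[k]
        at <- at[at >= 1L & at <= n_days]
        x[at] <- TRUE
        lag_part <- lag_part + betas[k] * x
      }
    }
    log_rate <- fixed_part + alpha_z[i] + lag_part
    denom_day <- denom_mat[i, year_idx]
    if (is.null(grid)) {
      mu <- exp(log_rate) * denom_day
      if (any(mu > config$rate_ceiling)) {
        stop("Poisson mean exceeds the configured rate ceiling; check the scenario")
      }
      counts_list[[i]] <- data.frame(zcta_id = z, date = days,
                                     count = stats::rpois(n_days, mu),
                                     stringsAsFactors = FALSE)
      denom_list[[i]] <- data.frame(zcta_id = z, year = config$years,
                                    n = denom_mat[i, ], stringsAsFactors = FALSE)
    } else {
      # subgroup denominators: proportional split, last cell absorbs rounding
      n_sub <- t(vapply(denom_mat[i, ], function(tot) {
        n_g <- floor(grid$prop * tot)
        n_g[nrow(grid)] <- tot - sum(n_g[-nrow(grid)])
        n_g
      }, numeric(nrow(grid))))  # n_years x n_groups
      storage.mode(n_sub) <- "integer"
      sub_counts <- vector("list", nrow(grid))
      for (gidx in seq_len(nrow(grid))) {
        denom_g <- n_sub[year_idx, gidx]
        mu <- exp(log_rate) * denom_g
        if (any(mu > config$rate_ceiling)) {
          stop("Poisson mean exceeds the configured rate ceiling; check the scenario")
        }
        sub_counts[[gidx]] <- data.frame(zcta_id = z, date = days,
                                         age = grid$age[gidx], sex = grid$sex[gidx],
                                         dual = grid$dual[gidx],
                                         count = stats::rpois(n_days, mu),
                                         stringsAsFactors = FALSE)
      }
      counts_list[[i]] <- do.call(rbind, sub_counts)
      denom_list[[i]] <- data.frame(zcta_id = z,
                                    year = rep(config$years, each = nrow(grid)),
                                    age = rep(grid$age, n_years),
                                    sex = rep(grid$sex, n_years),
                                    dual = rep(grid$dual, n_years),
                                    n = as.vector(t(n_sub)),
                                    stringsAsFactors = FALSE)
    }
  }
  list(counts = do.call(rbind, counts_list),
       denominators = do.call(rbind, denom_list),
       random_intercepts = alpha_z)
}

#' Simulate a complete synthetic study dataset
#'
#' Orchestrates the generator: storm calendar, community covariates, the
#' effect-modification stratum (ZCTAs above the median of the modifier
#' covariate, when a modifier is configured), beneficiary denominators, and
#' daily counts from the distributed-lag Poisson process. Identical
#' configurations (including seed) give identical datasets.
#'
#' @param config a [tc_scenario()] object.
#' @return an object of class `tc_simulation`: a list with `storm_events`,
#'   `counts`, `denominators`, `community`, `stratum` (named character vector,
#'   "above"/"below" the modifier covariate's median), `random_intercepts`,
#'   and `truth` (the scenario).
#' @examples
#' sim <- simulate_tc_data(tc_scenario(n_zctas = 4, years = 2004:2006,
#'                                     storms_per_year = 0.5, seed = 7))
#' sim
#' @export
simulate_tc_data <- function(config) {
  stopifnot(inherits(config, "tc_scenario"))
  events <- simulate_storm_calendar(config)
  community <- if (config$n_zctas >= 2L) simulate_community(config) else NULL
  stratum <- NULL
  modifier_above <- NULL
  if (!is.null(community)) {
    vals <- stats::setNames(community[[config$modifier_covariate]],
                            community$zcta_id)
    split <- median_split(vals)
    stratum <- stats::setNames(as.character(split$labels), names(vals))
    if (!is.null(config$modifier_effect)) {
      modifier_above <- names(stratum)[stratum == "above"]
    }
  }
  gen <- simulate_counts(config, events, modifier_above = modifier_above)
  structure(list(storm_events = events,
                 counts = gen$counts,
                 denominators = gen$denominators,
                 community = community,
                 stratum = stratum,
                 random_intercepts = gen$random_intercepts,
                 truth = config),
            class = "tc_simulation")
}

#' @export
print.tc_simulation <- function(x, ...) {
  cat("Synthetic tropical cyclone study dataset\n")
  cat(sprintf("  %d ZCTAs, years %d-%d, %d storm events\n",
              x$truth$n_zctas, min(x$truth$years), max(x$truth$years),
              nrow(x$storm_events)))
  cat(sprintf("  %d count rows (%s resolution), %d denominator rows\n",
              nrow(x$counts),
              if (x$truth$subgroups) "subgroup" else "ZCTA",
              nrow(x$denominators)))
  invisible(x)
}

#' Aggregate subgroup counts to ZCTA-day totals
#'
#' @param counts a counts data frame, possibly with subgroup columns.
#' @return data frame with columns `zcta_id`, `date`, `count`.
#' @export
aggregate_counts <- function(counts) {
  if (!all(c("age", "sex", "dual") %in% names(counts))) return(counts)
  agg <- stats::aggregate(count ~ zcta_id + date, data = counts, FUN = sum)
  agg[order(agg$zcta_id, agg$date), c("zcta_id", "date", "count")]
}

#' Write a synthetic dataset as delimited text
#'
#' Writes storm events, counts, denominators and community covariates as CSV
#' and the scenario configuration as YAML into `dir`.
#'
#' @param sim a `tc_simulation` object.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_tc_data <- function(sim, dir) {
  stopifnot(inherits(sim, "tc_simulation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(storm_events = file.path(dir, "storm_events.csv"),
             counts = file.path(dir, "counts.csv"),
             denominators = file.path(dir, "denominators.csv"),
             community = file.path(dir, "community.csv"),
             scenario = file.path(dir, "scenario.yaml"))
  utils::write.csv(sim$storm_events, paths["storm_events"], row.names = FALSE)
  utils::write.csv(sim$counts, paths["counts"], row.names = FALSE)
  utils::write.csv(sim$denominators, paths["denominators"], row.names = FALSE)
  if (!is.null(sim$community)) {
    utils::write.csv(sim$community, paths["community"], row.names = FALSE)
  }
  cfg <- sim$truth
  cfg$community_correlation <- NULL  # matrices round-trip poorly in flat YAML
  yaml::write_yaml(unclass(cfg), paths["scenario"])
  invisible(paths)
}
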