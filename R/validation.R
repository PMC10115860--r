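# Simulation-study drivers: the package's own tools for checking that the
# matched design plus the distributed-lag model recover what the generator
# put in. Used by the test suite and by scripts/acceptance.R.

#' Simulate one scenario replicate and fit the model
#'
#' Runs generator -> exposure filter -> matching -> model table -> fit on one
#' seeded scenario replicate.
#'
#' @param config a [tc_scenario()] object.
#' @param random_intercept passed to [stormlag()]; the default fits the
#'   mixed model only when the scenario's random-intercept SD is positive
#'   (the fixed-effect route is exact, and much faster, when it is zero).
#' @param match_seed seed for control sampling (default derived from the
#'   scenario seed).
#' @return list with the `fit`, the `table`, the `matched` design, the
#'   simulated dataset `sim`, and `truth` (the scenario).
#' @export
simulate_and_fit <- function(config,
                             random_intercept = if (config$random_intercept_sd > 0)
                               "auto" else "never",
                             match_seed = config$seed + 404L) {
  sim <- simulate_tc_data(config)
  events <- filter_exposed(sim$storm_events)
  matched <- suppressWarnings(
    match_storm_days(events, config$years, seed = match_seed))
  tab <- build_model_table(matched, aggregate_counts(sim$counts),
                           sim$denominators)
  fit <- stormlag(tab, random_intercept = random_intercept)
  list(fit = fit, table = tab, matched = matched, sim = sim, truth = config)
}

#' Confidence-interval calibration study
#'
#' Repeatedly simulates a scenario, fits the model, and records whether the
#' Wald confidence interval for the cumulative log relative risk covers the
#' scenario's true cumulative effect. Optionally also records, per
#' replicate, the p value of a between-strata contrast on a community
#' covariate that is unlinked to risk (a true null), to check that the
#' contrast's p values are uniform.
#'
#' @param config a [tc_scenario()] object (the per-replicate scenario).
#' @param n_reps number of replicates.
#' @param seed base seed; replicate `r` uses scenario seed `seed + r`.
#' @param level confidence level (default 0.95).
#' @param null_contrast if `TRUE`, fit the two strata of
#'   `config$modifier_covariate`'s median split per replicate and record the
#'   cumulative-RR contrast p value.
#' @return list with `coverage` (empirical coverage), `covered` (logical per
#'   replicate), `estimates` (cumulative log RR per replicate), `true`
#'   (true cumulative log RR), and `p_values` (contrast p values, when
#'   requested).
#' @export
coverage_study <- function(config, n_reps = 500L, seed = 2000L, level = 0.95,
                           null_contrast = FALSE) {
  true_cum <- sum(config$true_lag_betas)
  covered <- logical(n_reps)
  estimates <- numeric(n_reps)
  p_values <- if (null_contrast) rep(NA_real_, n_reps) else NULL
  for (r in seq_len(n_reps)) {
    cfg <- config
    cfg$seed <- as.integer(seed + r)
    run <- simulate_and_fit(cfg)
    cum <- cumulative_rr(run$fit, level = level)
    estimates[r] <- cum$log_rr
    covered[r] <- !cum$flagged &&
      cum$ci_low <= exp(true_cum) && exp(true_cum) <= cum$ci_high
    if (null_contrast) {
      labels <- community_labels(run$sim$community)$labels
      contrast <- tryCatch({
        s <- suppressWarnings(
          stratify_community(run$table, labels,
                             covariate = config$modifier_covariate,
                             random_intercept = "never"))
        s$comparison$p_value
      }, error = function(e) NA_real_)
      p_values[r] <- contrast %||% NA_real_
    }
  }
  list(coverage = mean(covered), covered = covered, estimates = estimates,
       true = true_cum, p_values = p_values)
}

#' Effect-modification recovery study
#'
#' Repeatedly simulates an effect-modification scenario (lag effects
#' multiplied by `modifier_effect` in above-median ZCTAs of the modifier
#' covariate), fits the two community strata, and records the estimated
#' between-strata RR ratio at the target lag and the contrast p value.
#'
#' @param config a [tc_scenario()] with a non-null `modifier_effect`.
#' @param n_reps number of replicates.
#' @param seed base seed; replicate `r` uses scenario seed `seed + r`.
#' @param target lag passed to [compare_strata_rr()] (default `0`).
#' @return list with per-replicate `rr_ratio`, `se_diff`, `p_values`, the
#'   `true_ratio` implied by the scenario, and `power` at alpha = 0.05.
#' @export
modification_study <- function(config, n_reps = 200L, seed = 3000L, target = 0) {
  if (is.null(config$modifier_effect)) {
    stop("`config` must define a modifier_effect")
  }
  k <- match(target, .LAGS)
  if (is.na(k)) stop("`target` must be one of the model lags")
  true_ratio <- exp(config$true_lag_betas[k] * (config$modifier_effect[k] - 1))
  rr_ratio <- numeric(n_reps)
  se_diff <- numeric(n_reps)
  p_values <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    cfg <- config
    cfg$seed <- as.integer(seed + r)
    run <- simulate_and_fit(cfg)
    labels <- run$sim$stratum
    s <- suppressWarnings(
      stratify_community(run$table, labels,
                         covariate = config$modifier_covariate,
                         random_intercept = "never"))
    cmp <- compare_strata_rr(s$fits$above, s$fits$below, target = target,
                             labels = c("above", "below"))
    rr_ratio[r] <- cmp$rr_ratio
    se_diff[r] <- cmp$se_diff
    p_values[r] <- cmp$p_value
  }
  list(rr_ratio = rr_ratio, se_diff = se_diff, p_values = p_values,
       true_ratio = true_ratio,
       power = mean(p_values < 0.05, na.rm = TRUE))
}
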