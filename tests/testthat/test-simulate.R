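test_that("storm calendar respects rate, season, threshold and determinism", {
  cfg0 <- tc_scenario(n_zctas = 5, years = 2004:2006, storms_per_year = 0,
                      seed = 1)
  expect_identical(nrow(simulate_storm_calendar(cfg0)), 0L)

  cfg <- tc_scenario(n_zctas = 200, years = 1999:2016, storms_per_year = 0.23,
                     seed = 42)
  ev <- simulate_storm_calendar(cfg)
  per_zcta <- table(factor(ev$zcta_id, levels = unique(ev$zcta_id)))
  mean_burden <- nrow(ev) / cfg$n_zctas
  # Poisson mean 4.14; allow 3 MC standard errors of the mean
  expect_lt(abs(mean_burden - 0.23 * 18), 3 * sqrt(0.23 * 18 / 200))
  expect_true(all(ev$windspeed >= 21))
  expect_true(all((as.POSIXlt(ev$closest_date)$mon + 1L) %in% 6:11))
  expect_false(any(duplicated(paste(ev$storm_id, ev$zcta_id))))

  ev2 <- simulate_storm_calendar(cfg)
  expect_identical(ev, ev2)
})

test_that("null generator reproduces the baseline rate", {
  cfg <- tc_scenario(n_zctas = 30, years = 2004:2008, storms_per_year = 0.3,
                     true_lag_betas = rep(0, 10),
                     dow_effects = rep(0, 7),
                     year_effects = rep(0, 5),
                     random_intercept_sd = 0,
                     baseline_log_rate = log(2e-4), seed = 5)
  sim <- simulate_tc_data(cfg)
  denom <- sim$denominators
  d <- merge(sim$counts, denom,
             by.x = c("zcta_id"), by.y = c("zcta_id"))
  d <- d[d$year == as.integer(format(d$date, "%Y")), ]
  emp <- sum(d$count) / sum(d$n)
  rel_err <- abs(emp - 2e-4) / 2e-4
  # ~55k person-day cells; MC error on the ratio is well under 5%
  expect_lt(rel_err, 0.05)
})

test_that("a lag-0 effect of ln 2 doubles the storm-day rate", {
  cfg <- tc_scenario(n_zctas = 100, years = 2004:2009, storms_per_year = 1,
                     true_lag_betas = c(0, 0, log(2), rep(0, 7)),
                     dow_effects = rep(0, 7), year_effects = rep(0, 6),
                     random_intercept_sd = 0,
                     baseline_log_rate = log(5e-4), seed = 6)
  ev <- simulate_storm_calendar(cfg)
  gen <- simulate_counts(cfg, ev)
  counts <- gen$counts
  denom_by_zy <- gen$denominators
  counts$year <- as.integer(format(counts$date, "%Y"))
  counts <- merge(counts, denom_by_zy, by = c("zcta_id", "year"))
  storm_key <- paste(ev$zcta_id, ev$closest_date)
  on_storm <- paste(counts$zcta_id, counts$date) %in% storm_key
  expect_gt(sum(!on_storm), 1e5)
  rate_storm <- sum(counts$count[on_storm]) / sum(counts$n[on_storm])
  rate_other <- sum(counts$count[!on_storm]) / sum(counts$n[!on_storm])
  ratio <- rate_storm / rate_other
  # closed-form rate ratio is exactly 2; storm days carry ~150 events here,
  # so 3 MC standard errors is about 0.5
  se_log <- sqrt(1 / sum(counts$count[on_storm]) + 1 / sum(counts$count[!on_storm]))
  expect_lt(abs(log(ratio) - log(2)), 3 * se_log)
})

test_that("identical config and seed give identical datasets", {
  cfg <- tc_scenario(n_zctas = 6, years = 2004:2006, storms_per_year = 0.8,
                     seed = 9)
  s1 <- simulate_tc_data(cfg)
  s2 <- simulate_tc_data(cfg)
  expect_identical(s1$storm_events, s2$storm_events)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$denominators, s2$denominators)
  expect_identical(s1$community, s2$community)
})

test_that("every zcta-day has a nonnegative integer count row", {
  sim <- small_sim(seed = 11, n_zctas = 4, years = 2004:2005)
  expect_identical(nrow(sim$counts), 4L * as.integer(
    length(seq(as.Date("2004-01-01"), as.Date("2005-12-31"), by = "day"))))
  expect_true(all(sim$counts$count >= 0))
  expect_true(all(sim$counts$count == round(sim$counts$count)))
})

test_that("community covariates follow the requested correlation", {
  r <- diag(10)
  dimnames(r) <- list(community_covariate_names(), community_covariate_names())
  cfg_id <- tc_scenario(n_zctas = 1000, years = 2004:2005,
                        community_correlation = r, seed = 12)
  comm <- simulate_community(cfg_id)
  cors <- covariate_correlation(comm[setdiff(names(comm), "zcta_id")])
  offdiag <- cors[upper.tri(cors)]
  expect_lt(max(abs(offdiag)), 0.12)

  r2 <- r
  r2["income", "housing_value"] <- r2["housing_value", "income"] <- 0.9
  cfg_r <- tc_scenario(n_zctas = 1000, years = 2004:2005,
                       community_correlation = r2, seed = 13)
  comm2 <- simulate_community(cfg_r)
  expect_lt(abs(cor(comm2$income, comm2$housing_value) - 0.9), 0.05)
})

test_that("degenerate community inputs are handled", {
  bad <- matrix(1, 10, 10)  # rank 1, not positive definite
  expect_error(tc_scenario(community_correlation = bad), "positive definite")

  cfg2 <- tc_scenario(n_zctas = 2, years = 2004:2005, seed = 14)
  comm <- simulate_community(cfg2)
  split <- median_split(setNames(comm$income, comm$zcta_id))
  expect_identical(split$n_above, 1L)
  expect_identical(split$n_below, 1L)
})

test_that("subgroup counts and denominators aggregate to ZCTA totals", {
  sim <- small_sim(seed = 15, n_zctas = 3, years = 2004:2005, subgroups = TRUE)
  expect_true(all(c("age", "sex", "dual") %in% names(sim$counts)))
  denom_tot <- aggregate(n ~ zcta_id + year, data = sim$denominators, FUN = sum)
  cfg_range <- sim$truth$denominator_range
  expect_true(all(denom_tot$n >= cfg_range[1] * 0.9))
  # 12 subgroup rows per zcta-day, and totals are exact sums
  agg <- aggregate_counts(sim$counts)
  expect_identical(nrow(sim$counts), 12L * nrow(agg))
  expect_identical(sum(agg$count), sum(sim$counts$count))
})

test_that("scenario validation rejects malformed configurations", {
  expect_error(tc_scenario(years = c(2004, 2006)), "consecutive")
  expect_error(tc_scenario(true_lag_betas = rep(0, 9)), "10 entries")
  expect_error(tc_scenario(dow_effects = c(0.1, rep(0, 6))), "reference")
  expect_error(tc_scenario(year_effects = c(0.1, rep(0, 17))), "reference")
  expect_error(tc_scenario(storms_per_year = -1), "nonnegative")
  expect_error(simulate_counts(tc_scenario(years = 2005:2006, n_zctas = 2),
                               data.frame(storm_id = "S1", zcta_id = "Z0001",
                                          closest_date = as.Date("2003-07-01"),
                                          windspeed = 25)),
               "outside")
})

test_that("the generator guards against runaway rates", {
  cfg <- tc_scenario(n_zctas = 2, years = 2004:2004, storms_per_year = 0,
                     baseline_log_rate = 5, rate_ceiling = 1e4, seed = 16)
  ev <- simulate_storm_calendar(cfg)
  expect_error(simulate_counts(cfg, ev), "ceiling")
})

test_that("written synthetic datasets round-trip through the CSV readers", {
  sim <- small_sim(seed = 17, n_zctas = 3, years = 2004:2005)
  dir <- withr::local_tempdir()
  paths <- write_tc_data(sim, dir)
  ev <- read_storm_events(paths[["storm_events"]])
  expect_identical(ev$storm_id, sim$storm_events$storm_id)
  expect_identical(ev$closest_date, sim$storm_events$closest_date)
  counts <- read_counts(paths[["counts"]])
  expect_identical(sum(counts$count), sum(sim$counts$count))
  denom <- read_denominators(paths[["denominators"]])
  expect_identical(denom$n, sim$denominators$n)
  cfg2 <- read_scenario(paths[["scenario"]])
  expect_identical(cfg2$true_lag_betas, sim$truth$true_lag_betas)
  expect_identical(cfg2$years, sim$truth$years)
})
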