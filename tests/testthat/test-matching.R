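test_that("an unobstructed mid-period exposed day has 17 x 15 candidates", {
  years <- 1999:2016
  d0 <- as.Date("2008-08-15")
  cand <- find_control_candidates(d0, d0, years)
  expect_length(cand, 255L)
  expect_false(any(format(cand, "%Y") == "2008"))
  expect_true(all(stormlag:::doy_distance(cand, d0) <= 7))
})

test_that("single-year studies and nearby storms shrink the candidate set", {
  d0 <- as.Date("2005-08-15")
  expect_length(find_control_candidates(d0, d0, 2005L), 0L)

  # a second storm 2 days after an otherwise-eligible candidate excludes it
  other <- as.Date("2006-08-18")
  cand <- find_control_candidates(d0, c(d0, other), 1999:2016)
  expect_false(as.Date("2006-08-16") %in% cand)   # 2 days before the storm
  expect_false(as.Date("2006-08-21") %in% cand)   # 3 days after (inclusive)
  expect_true(as.Date("2006-08-22") %in% cand)    # 4 days after is eligible
})

test_that("candidate enumeration equals the brute-force calendar oracle", {
  set.seed(202)
  year_starts <- 1999:2012
  for (i in 1:12) {
    y0 <- sample(year_starts, 1)
    years <- y0:(y0 + sample(3:8, 1))
    n_storms <- sample(1:5, 1)
    storm_days <- sort(sample(seq(as.Date(sprintf("%d-01-01", min(years))),
                                  as.Date(sprintf("%d-12-31", max(years))),
                                  by = "day"), n_storms))
    d0 <- storm_days[sample(n_storms, 1)]
    got <- find_control_candidates(d0, storm_days, years)
    want <- oracle_candidates(d0, storm_days, years)
    expect_identical(got, want)
  }
  # leap-day exposed day
  d_leap <- as.Date("2004-02-29")
  expect_identical(find_control_candidates(d_leap, d_leap, 2000:2008),
                   oracle_candidates(d_leap, d_leap, 2000:2008))
  # storm at the period boundary: window containment trims candidates
  d_edge <- as.Date("2004-01-02")
  got <- find_control_candidates(d_edge, d_edge, 2004:2008)
  expect_identical(got, oracle_candidates(d_edge, d_edge, 2004:2008))
  expect_true(all(got - 2 >= as.Date("2004-01-01")))
})

test_that("control sampling is uniform without replacement with deficit rule", {
  cand <- as.Date("2005-01-01") + 0:254
  set.seed(1)
  s <- sample_controls(cand, 10)
  expect_length(s, 10L)
  expect_true(all(s %in% cand))
  expect_false(any(duplicated(s)))

  few <- cand[1:7]
  expect_warning(s2 <- sample_controls(few, 10), "7")
  expect_identical(sort(s2), sort(few))

  expect_identical(sample_controls(cand, 10, seed = 99),
                   sample_controls(cand, 10, seed = 99))
  expect_length(sample_controls(cand[0], 10), 0L)
})

test_that("a fully matched storm-ZCTA yields 110 model rows", {
  ev <- data.frame(storm_id = "S1", zcta_id = "Z0001",
                   closest_date = as.Date("2008-08-15"), windspeed = 30)
  m <- match_storm_days(ev, 1999:2016, seed = 4)
  expect_length(m$sets, 1L)
  set <- m$sets[[1]]
  expect_length(set$control_days, 10L)
  expect_true(all(format(set$control_days, "%Y") != "2008"))

  days <- seq(as.Date("1999-01-01"), as.Date("2016-12-31"), by = "day")
  counts <- data.frame(zcta_id = "Z0001", date = days,
                       count = rpois(length(days), 1))
  denom <- data.frame(zcta_id = "Z0001", year = 1999:2016, n = 1000)
  tab <- build_model_table(m, counts, denom)
  expect_identical(nrow(tab), 110L)

  # exposed-window rows form a permutation over the 10 lag positions
  lag_cols <- stormlag:::lag_col_names()
  exp_rows <- tab[tab$exposed == 1L, lag_cols]
  expect_identical(dim(exp_rows), c(10L, 10L))
  expect_true(all(colSums(exp_rows) == 1L))
  expect_true(all(rowSums(exp_rows) == 1L))
  ctl_rows <- tab[tab$exposed == 0L, lag_cols]
  expect_true(all(as.matrix(ctl_rows) == 0L))
  expect_true(all(rowSums(tab[, lag_cols]) <= 1L))

  # each window is 10 consecutive dates centered on its index day
  for (sid in unique(paste(tab$index_day))) {
    w <- tab[paste(tab$index_day) == sid, ]
    expect_identical(sort(w$date), sort(w$index_day[1] + (-2:7)))
  }
})

test_that("sets without candidates are dropped and row counts add up", {
  # only one study year: no different-year controls exist
  ev <- data.frame(storm_id = "S1", zcta_id = "Z0001",
                   closest_date = as.Date("2005-08-15"), windspeed = 30)
  expect_warning(m <- match_storm_days(ev, 2005L, seed = 5), "dropped")
  expect_length(m$sets, 0L)
  days <- seq(as.Date("2005-01-01"), as.Date("2005-12-31"), by = "day")
  counts <- data.frame(zcta_id = "Z0001", date = days, count = 0L)
  denom <- data.frame(zcta_id = "Z0001", year = 2005, n = 100)
  tab <- build_model_table(m, counts, denom)
  expect_identical(nrow(tab), 0L)

  # exposed day whose window exits the period is ineligible
  ev_edge <- data.frame(storm_id = "S2", zcta_id = "Z0001",
                        closest_date = as.Date("2016-12-30"), windspeed = 30)
  m2 <- match_storm_days(ev_edge, 1999:2016, seed = 6)
  expect_length(m2$sets, 0L)
  expect_identical(m2$report$dropped_window, "S2:Z0001")

  # row count = sum over retained sets of (1 + controls) * 10
  sim <- small_sim(seed = 23)
  m3 <- match_storm_days(filter_exposed(sim$storm_events), sim$truth$years,
                         seed = 7)
  tab3 <- build_model_table(m3, aggregate_counts(sim$counts),
                            sim$denominators)
  expected_rows <- sum(vapply(m3$sets, function(s)
    (1L + length(s$control_days)) * 10L, integer(1)))
  expect_identical(nrow(tab3), expected_rows)
})

test_that("no exposed day ever serves as a control in its ZCTA", {
  for (seed in c(31, 32, 33)) {
    sim <- small_sim(seed = seed, n_zctas = 6, storms_per_year = 1.2)
    ev <- filter_exposed(sim$storm_events)
    m <- suppressWarnings(match_storm_days(ev, sim$truth$years, seed = seed))
    storm_days_by_z <- split(ev$closest_date, ev$zcta_id)
    for (s in m$sets) {
      expect_false(any(s$control_days %in% storm_days_by_z[[s$zcta_id]]))
      # the 3-day exclusion holds for every control index day
      gaps <- outer(as.numeric(s$control_days),
                    as.numeric(storm_days_by_z[[s$zcta_id]]), `-`)
      expect_true(all(abs(gaps) > 3))
      # controls come from different years, within the day-of-year window
      expect_false(any(format(s$control_days, "%Y") ==
                         format(s$exposed_day, "%Y")))
      expect_true(all(stormlag:::doy_distance(s$control_days,
                                              s$exposed_day) <= 7))
    }
  }
})

test_that("missing counts trigger the configured policy", {
  ev <- data.frame(storm_id = "S1", zcta_id = "Z0001",
                   closest_date = as.Date("2008-08-15"), windspeed = 30)
  m <- match_storm_days(ev, 2006:2010, seed = 8)
  days <- seq(as.Date("2006-01-01"), as.Date("2010-12-31"), by = "day")
  counts <- data.frame(zcta_id = "Z0001", date = days,
                       count = rpois(length(days), 1))
  denom <- data.frame(zcta_id = "Z0001", year = 2006:2010, n = 500)
  counts_gap <- counts[counts$date != as.Date("2008-08-16"), ]
  expect_error(build_model_table(m, counts_gap, denom), "2008-08-16")
  expect_warning(tab <- build_model_table(m, counts_gap, denom,
                                          on_missing = "drop"), "dropping")
  expect_identical(nrow(tab), 0L)
  expect_error(build_model_table(m, counts, denom[denom$year != 2007, ]),
               "2007")
})

test_that("disallowing shared controls removes reused days within a ZCTA", {
  ev <- data.frame(storm_id = c("S1", "S2"), zcta_id = "Z0001",
                   closest_date = as.Date(c("2006-08-15", "2010-08-16")),
                   windspeed = 30)
  m <- match_storm_days(ev, 1999:2016, k = 10, seed = 13,
                        allow_shared_controls = FALSE)
  days <- unlist(lapply(m$sets, function(s) as.character(s$control_days)))
  expect_false(any(duplicated(days)))
})

test_that("matching is deterministic under a fixed seed", {
  sim <- small_sim(seed = 24)
  ev <- filter_exposed(sim$storm_events)
  m1 <- match_storm_days(ev, sim$truth$years, seed = 12)
  m2 <- match_storm_days(ev, sim$truth$years, seed = 12)
  expect_identical(lapply(m1$sets, `[[`, "control_days"),
                   lapply(m2$sets, `[[`, "control_days"))
})
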