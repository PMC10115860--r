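test_that("the single-indicator Poisson MLE has its closed form", {
  # 20 rows, one ZCTA, constant day-of-week and year: the rate-ratio MLE for
  # a single binary indicator is (sum y1/sum n1)/(sum y0/sum n0)
  counts <- c(5, 3, 4, 6, 2, 7, 4, 5,    # 8 exposed rows
              1, 2, 1, 0, 3, 1, 2, 1, 0, 2, 1, 1)  # 12 control rows
  tab <- make_fixture_table(exposed_idx = 1:8, counts = counts, denom = 1000)
  fit <- stormlag(tab, random_intercept = "never")
  expect_identical(fit$method, "glm")
  hand <- log((sum(counts[1:8]) / (8 * 1000)) /
                (sum(counts[9:20]) / (12 * 1000)))
  expect_equal(unname(fit$beta[["lag_0"]]), hand, tolerance = 1e-8)
  # the other nine lags never occur and are flagged inestimable
  expect_true(all(is.na(fit$beta[names(fit$beta) != "lag_0"])))
  expect_true(all(is.infinite(fit$se_beta[names(fit$beta) != "lag_0"])))
})

test_that("fixed-effect fits match a hand-coded IRLS Poisson GLM", {
  sim <- small_sim(seed = 41, n_zctas = 5, years = 2004:2009,
                   storms_per_year = 0.8, baseline_log_rate = log(1e-3),
                   random_intercept_sd = 0)
  m <- match_storm_days(filter_exposed(sim$storm_events), sim$truth$years,
                        seed = 42)
  tab <- build_model_table(m, aggregate_counts(sim$counts), sim$denominators)
  fit <- stormlag(tab, random_intercept = "never")
  expect_identical(fit$method, "glm_fixed")
  expect_true(fit$converged)

  dat <- tab
  dat$dowf <- droplevels(factor(dat$dow, levels = c("Mon", "Tue", "Wed", "Thu",
                                                    "Fri", "Sat", "Sun")))
  dat$yearf <- factor(dat$year)
  dat$zcta <- factor(dat$zcta_id)
  lag_cols <- stormlag:::lag_col_names()
  X <- model.matrix(reformulate(c(lag_cols, "dowf", "yearf", "zcta")), dat)
  beta_oracle <- oracle_irls_poisson(X, dat$count, offset = dat$log_denom)
  names(beta_oracle) <- colnames(X)
  got <- coef(fit, "all")[names(beta_oracle)]
  expect_equal(unname(got), unname(beta_oracle), tolerance = 1e-6)
})

test_that("shifting all log-offsets moves only the intercept", {
  sim <- small_sim(seed = 43, n_zctas = 4, storms_per_year = 0.8,
                   baseline_log_rate = log(1e-3), random_intercept_sd = 0)
  m <- match_storm_days(filter_exposed(sim$storm_events), sim$truth$years,
                        seed = 44)
  tab <- build_model_table(m, aggregate_counts(sim$counts), sim$denominators)
  fit1 <- stormlag(tab, random_intercept = "never")
  tab2 <- tab
  tab2$log_denom <- tab2$log_denom + 1.7
  attr(tab2, "lags") <- attr(tab, "lags")
  fit2 <- stormlag(tab2, random_intercept = "never")
  expect_equal(fit1$beta, fit2$beta, tolerance = 1e-8)
  expect_equal(unname(fit2$nuisance[["(Intercept)"]]),
               unname(fit1$nuisance[["(Intercept)"]]) - 1.7, tolerance = 1e-7)
})

test_that("the mixed model agrees with the GLM when the intercept variance is nil", {
  sim <- small_sim(seed = 45, n_zctas = 8, storms_per_year = 0.8,
                   baseline_log_rate = log(1e-3), random_intercept_sd = 0)
  m <- match_storm_days(filter_exposed(sim$storm_events), sim$truth$years,
                        seed = 46)
  tab <- build_model_table(m, aggregate_counts(sim$counts), sim$denominators)
  glmm <- stormlag(tab, random_intercept = "auto")
  glm_fit <- stormlag(tab, random_intercept = "never")
  expect_identical(glmm$method, "glmm")
  expect_lt(glmm$ranef_variance, 0.02)
  expect_equal(glmm$beta, glm_fit$beta, tolerance = 5e-3)
})

test_that("the mixed model recovers a lag-0 effect from its own DGP", {
  cfg <- tc_scenario(n_zctas = 30, years = 2004:2009, storms_per_year = 0.8,
                     true_lag_betas = c(0, 0, log(2), rep(0, 7)),
                     baseline_log_rate = log(1e-3),
                     random_intercept_sd = 0.3, seed = 47)
  run <- simulate_and_fit(cfg)
  expect_identical(run$fit$method, "glmm")
  expect_gt(run$fit$ranef_variance, 0.01)
  b0 <- run$fit$beta[["lag_0"]]
  se0 <- run$fit$se_beta[["lag_0"]]
  expect_lt(abs(b0 - log(2)), 3 * se0)
  # vcov is symmetric PSD
  v <- vcov(run$fit)
  expect_equal(v, t(v), tolerance = 1e-10)
  expect_gt(min(eigen(v, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
})

test_that("Wald RR intervals follow the stated formulas", {
  fake <- make_fake_fit(beta = rep(0, 10), se = rep(0.1, 10))
  tab <- lag_rr(fake)
  z <- qnorm(0.975)
  expect_equal(tab$rr, rep(1, 10))
  expect_equal(tab$ci_low, rep(exp(-z * 0.1), 10))
  expect_equal(tab$ci_high, rep(exp(z * 0.1), 10))

  # degenerate-variance limit: CI collapses onto the point estimate
  fake2 <- make_fake_fit(beta = c(0, 0, log(2), rep(0, 7)),
                         se = rep(1e-12, 10))
  tab2 <- lag_rr(fake2)
  expect_equal(tab2$rr[3], 2)
  expect_equal(tab2$ci_low[3], 2, tolerance = 1e-9)
  expect_equal(tab2$ci_high[3], 2, tolerance = 1e-9)
})

test_that("cumulative RR is the delta-method sum of the lags", {
  fake0 <- make_fake_fit(beta = rep(0, 10))
  expect_equal(cumulative_rr(fake0)$rr, 1)

  se <- c(0.3, rep(0.05, 9))
  fake1 <- make_fake_fit(beta = c(log(2), rep(0, 9)), se = se)
  cum <- cumulative_rr(fake1)
  expect_equal(cum$rr, 2)
  expect_equal(cum$se_log_rr, sqrt(sum(se^2)))

  # dense covariance fixture: se matches the brute-force 1'V1 double sum
  set.seed(48)
  A <- matrix(rnorm(100), 10)
  V <- crossprod(A) / 50
  beta <- rnorm(10, 0, 0.1)
  fake2 <- make_fake_fit(beta = beta, se = sqrt(diag(V)), vcov = V)
  cum2 <- cumulative_rr(fake2)
  brute <- 0
  for (i in 1:10) for (j in 1:10) brute <- brute + V[i, j]
  expect_equal(cum2$se_log_rr, sqrt(brute), tolerance = 1e-12)
  expect_equal(cum2$log_rr, sum(beta))
  # cumulative RR equals the product of the lag RRs exactly
  expect_equal(cum2$rr, prod(exp(beta)), tolerance = 1e-12)
})

test_that("separated lags are flagged and poison the cumulative estimate", {
  set.seed(49)
  counts <- rpois(110, 2)
  tab <- make_fixture_table(exposed_idx = 1:10, counts = counts)
  # make lag 0 separated: zero counts on its only active row
  lag_cols <- stormlag:::lag_col_names()
  for (cl in lag_cols) tab[[cl]] <- 0L
  tab[1:10, lag_cols] <- diag(10)
  tab$count[tab$lag_0 == 1L] <- 0L
  fit <- stormlag(tab, random_intercept = "never")
  expect_true(fit$separated[["lag_0"]])
  expect_identical(fit$se_beta[["lag_0"]], Inf)
  tabr <- lag_rr(fit)
  expect_true(tabr$separated[tabr$lag == 0])
  expect_warning(cum <- cumulative_rr(fit), "unavailable")
  expect_true(cum$flagged)
  expect_true(is.na(cum$rr))
})

test_that("empty and malformed tables are rejected", {
  expect_error(stormlag(data.frame()), "nonempty")
  tab <- make_fixture_table(1:5, rpois(20, 1))
  tab$log_denom[1] <- Inf
  expect_error(stormlag(tab), "finite")
  tab2 <- make_fixture_table(1:5, rpois(20, 1))
  tab2$count <- NULL
  expect_error(stormlag(tab2), "count")
})

test_that("model methods expose the usual generics", {
  sim <- small_sim(seed = 50, n_zctas = 4, storms_per_year = 0.8,
                   baseline_log_rate = log(1e-3))
  run <- simulate_and_fit(sim$truth)
  fit <- run$fit
  expect_length(coef(fit), 10L)
  expect_identical(dim(vcov(fit)), c(10L, 10L))
  ci <- confint(fit)
  expect_true(all(ci[, 1] <= coef(fit) & coef(fit) <= ci[, 2]))
  expect_identical(length(fitted(fit)), nrow(run$table))
  expect_identical(length(residuals(fit)), nrow(run$table))
  expect_identical(nobs(fit), nrow(run$table))
  expect_s3_class(summary(fit), "summary.stormlag")
  expect_output(print(summary(fit)), "Cumulative")
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_identical(dim(sims), c(nrow(run$table), 2L))
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit))
})
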