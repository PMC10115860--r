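# Independent oracles used to cross-check the implementation. These are
# deliberately naive re-derivations (brute-force scans, textbook formulas)
# kept separate from the package code paths they verify.

# Hand-coded iteratively-reweighted-least-squares Poisson regression with an
# offset; returns the coefficient vector for a dense design matrix X.
oracle_irls_poisson <- function(X, y, offset = rep(0, length(y)),
                                tol = 1e-12, maxit = 100L) {
  beta <- rep(0, ncol(X))
  beta[1L] <- log(mean(y)) - mean(offset)  # crude start at the mean rate
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta) + offset
    mu <- exp(eta)
    w <- mu
    zz <- eta - offset + (y - mu) / mu
    WX <- X * w
    beta_new <- solve(crossprod(X, WX), crossprod(WX, zz))
    if (max(abs(beta_new - beta)) < tol) {
      return(drop(beta_new))
    }
    beta <- drop(beta_new)
  }
  drop(beta)
}

# Brute-force control-candidate enumeration: scan every day of the study
# calendar and apply the four eligibility predicates independently.
oracle_candidates <- function(exposed_day, storm_days, study_years,
                              doy_window = 7L, exclusion_days = 3L,
                              lags = -2:7) {
  start <- as.Date(sprintf("%04d-01-01", min(study_years)))
  end <- as.Date(sprintf("%04d-12-31", max(study_years)))
  all_days <- seq(start, end, by = "day")
  # independent pseudo day-of-year: rebuild the month-day in the non-leap
  # reference year 2001 (Feb 29 collapsed onto Feb 28)
  ref_doy <- function(d) {
    lt <- as.POSIXlt(d)
    mday <- lt$mday
    mday[lt$mon == 1L & mday == 29L] <- 28L
    as.integer(format(as.Date(sprintf("2001-%02d-%02d", lt$mon + 1L, mday)), "%j"))
  }
  d0 <- ref_doy(exposed_day)
  keep <- vapply(seq_along(all_days), function(i) {
    d <- all_days[i]
    yr <- as.integer(format(d, "%Y"))
    if (!(yr %in% study_years)) return(FALSE)
    if (yr == as.integer(format(exposed_day, "%Y"))) return(FALSE)
    dd <- abs(ref_doy(d) - d0)
    if (min(dd, 365L - dd) > doy_window) return(FALSE)
    if (length(storm_days) > 0L &&
        any(abs(as.numeric(d - storm_days)) <= exclusion_days)) return(FALSE)
    if (d + min(lags) < start || d + max(lags) > end) return(FALSE)
    TRUE
  }, logical(1))
  all_days[keep]
}

# Welch two-sample t statistic and two-sided p value from the textbook
# formulas.
oracle_welch <- function(x, y) {
  vx <- var(x) / length(x)
  vy <- var(y) / length(y)
  t_stat <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t_stat, df = df, p = 2 * pt(-abs(t_stat), df))
}

# Pearson correlation from raw sums.
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- sum(x * y) - n * mean(x) * mean(y)
  den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  num / den
}

# Minimal stormlag object for exercising the RR formulas directly.
make_fake_fit <- function(beta, se = rep(0.1, length(beta)), vcov = NULL) {
  lag_cols <- stormlag:::lag_col_names()
  names(beta) <- lag_cols
  names(se) <- lag_cols
  if (is.null(vcov)) vcov <- diag(se^2)
  dimnames(vcov) <- list(lag_cols, lag_cols)
  structure(list(beta = beta, se_beta = se, vcov_beta = vcov,
                 separated = setNames(rep(FALSE, 10), lag_cols),
                 converged = TRUE, lags = -2:7, method = "glm",
                 fallback = FALSE, nobs = 0L, n_sets = 0L, n_zctas = 1L),
            class = "stormlag")
}

# Build a small hand-rolled model table (bypassing build_model_table) for
# direct fits: one ZCTA unless zcta given, constant day-of-week and year.
make_fixture_table <- function(exposed_idx, counts, denom = 1000,
                               zcta = "Z0001", lags = -2:7) {
  n <- length(counts)
  lag_cols <- stormlag:::lag_col_names(lags)
  tab <- data.frame(set_id = "S:F", zcta_id = zcta, storm_id = "S",
                    index_day = as.Date("2005-08-01"),
                    exposed = as.integer(seq_len(n) %in% exposed_idx),
                    date = as.Date("2005-08-01") + seq_len(n),
                    stringsAsFactors = FALSE)
  for (cl in lag_cols) tab[[cl]] <- 0L
  tab$lag_0 <- as.integer(seq_len(n) %in% exposed_idx)
  tab$count <- counts
  tab$year <- 2005L
  tab$log_denom <- log(denom)
  tab$dow <- "Mon"
  attr(tab, "lags") <- lags
  tab
}
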