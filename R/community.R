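#' Area-weighted interpolation between boundary vintages
#'
#' Interpolates a covariate observed on an old set of spatial units (e.g.
#' 2000 ZCTA boundaries) onto a new set (e.g. 2010 boundaries) as the
#' area-weighted average of the overlapping old-unit values:
#' `new = sum(w * old) / sum(w)`.
#'
#' @param values named numeric vector of covariate values on the old units.
#' @param overlap data frame with columns `old_id`, `new_id`, `weight`
#'   (nonnegative areal weights).
#' @return named numeric vector on the new units; a new unit with zero total
#'   weight (or only missing contributing values) is `NA` with a warning.
#' @examples
#' ov <- data.frame(old_id = c("a", "b"), new_id = "n1", weight = c(0.5, 0.5))
#' interpolate_boundaries(c(a = 10, b = 20), ov)  # 15
#' @export
interpolate_boundaries <- function(values, overlap) {
  stopifnot(is.numeric(values), !is.null(names(values)),
            is.data.frame(overlap),
            all(c("old_id", "new_id", "weight") %in% names(overlap)))
  if (any(overlap$weight < 0)) stop("overlap weights must be nonnegative")
  unknown <- setdiff(overlap$old_id, names(values))
  if (length(unknown) > 0L) {
    stop("overlap references old units without values: ",
         paste(unknown, collapse = ", "))
  }
  v <- values[overlap$old_id]
  w <- overlap$weight
  ok <- !is.na(v)
  num <- tapply(ifelse(ok, w * v, 0), overlap$new_id, sum)
  den <- tapply(ifelse(ok, w, 0), overlap$new_id, sum)
  out <- ifelse(den > 0, num / den, NA_real_)
  if (any(is.na(out))) {
    warning("new unit(s) with zero usable weight flagged missing: ",
            paste(names(out)[is.na(out)], collapse = ", "), call. = FALSE)
  }
  stats::setNames(as.numeric(out), names(num))
}

#' Time-weighted average of covariate observations
#'
#' Collapses several census observations (e.g. decennial and ACS releases)
#' into one fixed value per ZCTA, weighting each observation by the number of
#' study years it represents.
#'
#' @param observations data frame with columns `zcta_id`, `value`, `weight`
#'   (positive, in years).
#' @param zctas optional ZCTAs to report; those with no observations are `NA`
#'   with a warning.
#' @return named numeric vector of fixed per-ZCTA values.
#' @export
time_weighted_average <- function(observations, zctas = NULL) {
  stopifnot(is.data.frame(observations),
            all(c("zcta_id", "value", "weight") %in% names(observations)))
  if (any(observations$weight <= 0)) stop("weights must be positive")
  num <- tapply(observations$value * observations$weight, observations$zcta_id, sum)
  den <- tapply(observations$weight, observations$zcta_id, sum)
  out <- stats::setNames(as.numeric(num / den), names(num))
  if (!is.null(zctas)) {
    missing <- setdiff(zctas, names(out))
    if (length(missing) > 0L) {
      warning("ZCTA(s) with no observations flagged missing: ",
              paste(missing, collapse = ", "), call. = FALSE)
      out <- c(out, stats::setNames(rep(NA_real_, length(missing)), missing))
    }
    out <- out[zctas]
  }
  out
}

#' Median split of a community covariate
#'
#' Labels each ZCTA "above" or "below" the across-ZCTA median. Ties at the
#' median are labeled "below" (a deterministic convention; the label is
#' "above" only for values strictly greater than the median).
#'
#' @param values named numeric vector, one value per ZCTA; at least two must
#'   be non-missing.
#' @return a list with `labels` (factor "below"/"above", `NA` where the value
#'   is missing), `median`, `n_above`, `n_below`.
#' @examples
#' median_split(c(a = 1, b = 2, c = 3))$labels
#' @export
median_split <- function(values) {
  stopifnot(is.numeric(values))
  ok <- !is.na(values)
  if (sum(ok) < 2L) stop("median split needs at least 2 non-missing values")
  med <- stats::median(values[ok])
  lab <- ifelse(values > med, "above", "below")
  labels <- factor(lab, levels = c("below", "above"))
  names(labels) <- names(values)
  list(labels = labels, median = med,
       n_above = sum(labels == "above", na.rm = TRUE),
       n_below = sum(labels == "below", na.rm = TRUE))
}

#' Stability of a covariate over the study period
#'
#' Checks the assumption behind fixed median-split labels: computes Pearson's
#' correlation between beginning-of-period and end-of-period values, and the
#' fraction of ZCTAs whose above/below-median side (relative to the median of
#' the period-average values) differs between the two time points.
#'
#' @param begin_values,end_values paired named numeric vectors (n >= 3
#'   non-missing pairs).
#' @param r_threshold minimum correlation regarded as stable (default 0.85).
#' @param consistency_threshold minimum fraction of ZCTAs that must stay on
#'   one side of the median (default 0.92).
#' @return list with `r`, `crossing_fraction`, `consistent_fraction`,
#'   `pass_r`, `pass_consistency`. `r` is `NA` (flagged) when either vector
#'   has zero variance.
#' @export
stability_check <- function(begin_values, end_values,
                            r_threshold = 0.85, consistency_threshold = 0.92) {
  stopifnot(is.numeric(begin_values), is.numeric(end_values),
            length(begin_values) == length(end_values))
  ok <- !is.na(begin_values) & !is.na(end_values)
  if (sum(ok) < 3L) stop("stability check needs at least 3 complete pairs")
  b <- begin_values[ok]; e <- end_values[ok]
  r <- if (stats::sd(b) == 0 || stats::sd(e) == 0) {
    warning("zero variance: correlation undefined", call. = FALSE)
    NA_real_
  } else {
    stats::cor(b, e)
  }
  period_med <- stats::median((b + e) / 2)
  crossed <- (b > period_med) != (e > period_med)
  crossing_fraction <- mean(crossed)
  list(r = r,
       crossing_fraction = crossing_fraction,
       consistent_fraction = 1 - crossing_fraction,
       pass_r = !is.na(r) && r >= r_threshold,
       pass_consistency = (1 - crossing_fraction) >= consistency_threshold)
}

#' Compare a storm metric across median-split strata
#'
#' Two-sided two-sample t test (Welch by default) of a per-ZCTA storm metric
#' between the above-median and below-median strata of a community covariate.
#'
#' @param metric_values named numeric vector of the metric (e.g. number of
#'   storms) per ZCTA.
#' @param labels factor/character of "above"/"below" labels aligned with
#'   `metric_values`.
#' @param covariate,metric optional names recorded in the output.
#' @param var_equal use the pooled-variance t test instead of Welch.
#' @param alpha significance level for the flag (default 0.05).
#' @return one-row data frame: covariate, metric, group means and SDs, the t
#'   statistic, degrees of freedom, p value and significance flag.
#' @export
compare_strata <- function(metric_values, labels, covariate = NA_character_,
                           metric = NA_character_, var_equal = FALSE,
                           alpha = 0.05) {
  labels <- as.character(labels)
  ok <- !is.na(metric_values) & !is.na(labels)
  above <- metric_values[ok & labels == "above"]
  below <- metric_values[ok & labels == "below"]
  if (length(above) < 2L || length(below) < 2L) {
    stop("each stratum needs at least 2 non-missing values")
  }
  tt <- stats::t.test(above, below, var.equal = var_equal,
                      alternative = "two.sided")
  data.frame(covariate = covariate, metric = metric,
             mean_above = mean(above), sd_above = stats::sd(above),
             mean_below = mean(below), sd_below = stats::sd(below),
             t_statistic = unname(tt$statistic), df = unname(tt$parameter),
             p_value = tt$p.value, significant = tt$p.value < alpha,
             stringsAsFactors = FALSE)
}

#' Pearson correlation matrix of community covariates
#'
#' @param profiles data frame of community profiles (as from
#'   [simulate_community()]); all numeric columns are used.
#' @return symmetric correlation matrix with unit diagonal; a constant
#'   covariate gives an `NA` row/column with a warning.
#' @export
covariate_correlation <- function(profiles) {
  stopifnot(is.data.frame(profiles))
  num <- profiles[vapply(profiles, is.numeric, logical(1))]
  if (nrow(num) < 3L) stop("need at least 3 profiles")
  if (ncol(num) < 2L) stop("need at least 2 numeric covariates")
  sds <- vapply(num, function(x) stats::sd(x, na.rm = TRUE), numeric(1))
  r <- suppressWarnings(stats::cor(num, use = "pairwise.complete.obs"))
  if (any(sds == 0)) {
    warning("constant covariate(s) flagged undefined: ",
            paste(names(sds)[sds == 0], collapse = ", "), call. = FALSE)
    r[sds == 0, ] <- NA_real_
    r[, sds == 0] <- NA_real_
  }
  diag(r) <- ifelse(sds == 0, NA_real_, 1)
  r
}

#' Community profiles with median-split labels
#'
#' Convenience wrapper: computes the median split of every covariate across
#' ZCTAs and returns the labels alongside the medians.
#'
#' @param profiles community covariate data frame with a `zcta_id` column.
#' @return list with `labels` (data frame of "above"/"below" factors, one
#'   column per covariate, rownames = ZCTA ids) and `medians` (named numeric).
#' @export
community_labels <- function(profiles) {
  stopifnot(is.data.frame(profiles), "zcta_id" %in% names(profiles))
  covs <- setdiff(names(profiles), "zcta_id")
  splits <- lapply(covs, function(cv) {
    median_split(stats::setNames(profiles[[cv]], profiles$zcta_id))
  })
  labels <- as.data.frame(lapply(splits, `[[`, "labels"),
                          col.names = covs, row.names = profiles$zcta_id)
  medians <- stats::setNames(vapply(splits, `[[`, numeric(1), "median"), covs)
  list(labels = labels, medians = medians)
}
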