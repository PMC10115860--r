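#' Stratify the model by a community median split
#'
#' Partitions the model table by each ZCTA's above/below-median label for one
#' community covariate and fits the distributed-lag model independently in
#' the two strata. Partitioning conserves rows and matched sets exactly.
#'
#' @param table a model table from [build_model_table()].
#' @param labels either the `labels` data frame from [community_labels()] (one
#'   column per covariate, rownames = ZCTA ids) or a named vector of
#'   "above"/"below" labels per ZCTA.
#' @param covariate covariate name (required when `labels` is a data frame).
#' @param ... passed to [stormlag()].
#' @return an object of class `stormlag_strata`: list with `stratifier`,
#'   `fits` (named list; an empty stratum is `NULL`), `results` (tidy data
#'   frame of per-lag and cumulative RRs per stratum with `n_sets`,
#'   `n_rows`), and `comparison` (cumulative-RR contrast from
#'   [compare_strata_rr()], when both strata were fitted).
#' @export
stratify_community <- function(table, labels, covariate = NULL, ...) {
  if (is.data.frame(labels)) {
    if (is.null(covariate)) stop("`covariate` is required with a label data frame")
    if (!covariate %in% names(labels)) {
      stop(sprintf("no labels for covariate '%s'", covariate))
    }
    labels <- stats::setNames(as.character(labels[[covariate]]), rownames(labels))
  } else {
    labels <- stats::setNames(as.character(labels), names(labels))
    covariate <- covariate %||% "covariate"
  }
  zctas <- unique(table$zcta_id)
  unlabeled <- zctas[is.na(labels[zctas])]
  if (length(unlabeled) > 0L) {
    stop("ZCTA(s) without a label for '", covariate, "': ",
         paste(unlabeled, collapse = ", "))
  }
  fits <- lapply(c(below = "below", above = "above"), function(side) {
    sub <- table[labels[table$zcta_id] == side, , drop = FALSE]
    if (nrow(sub) == 0L) return(NULL)
    attr(sub, "lags") <- attr(table, "lags")
    stormlag(sub, ...)
  })
  comparison <- if (!is.null(fits$below) && !is.null(fits$above)) {
    compare_strata_rr(fits$above, fits$below, target = "cumulative",
                      labels = c("above", "below"))
  } else NULL
  structure(list(stratifier = covariate, fits = fits,
                 results = strata_results(fits, covariate),
                 comparison = comparison),
            class = "stormlag_strata")
}

#' Stratify the model by an individual-level characteristic
#'
#' Refits the distributed-lag model per subgroup of an individual-level
#' stratifier (age group, sex, or dual Medicaid eligibility). The same
#' matched windows are reused for every subgroup; only the counts and
#' beneficiary offsets are subgroup-specific.
#'
#' @param matched a `tc_matched` object.
#' @param counts subgroup-resolution counts (`zcta_id`, `date`, `age`, `sex`,
#'   `dual`, `count`).
#' @param denominators subgroup-resolution denominators (`zcta_id`, `year`,
#'   `age`, `sex`, `dual`, `n`).
#' @param stratifier one of "age", "sex", "dual".
#' @param ... passed to [stormlag()].
#' @return a `stormlag_strata` object with one fit per subgroup level.
#' @export
stratify_individual <- function(matched, counts, denominators,
                                stratifier = c("age", "sex", "dual"), ...) {
  stratifier <- match.arg(stratifier)
  for (d in list(counts, denominators)) {
    if (!stratifier %in% names(d)) {
      stop(sprintf("'%s' column missing from subgroup data", stratifier))
    }
  }
  levels_present <- sort(unique(counts[[stratifier]]))
  missing_denom <- setdiff(levels_present, unique(denominators[[stratifier]]))
  if (length(missing_denom) > 0L) {
    stop("subgroup(s) absent from denominators: ",
         paste(missing_denom, collapse = ", "))
  }
  fits <- lapply(stats::setNames(levels_present, levels_present), function(lv) {
    csub <- counts[counts[[stratifier]] == lv, , drop = FALSE]
    csub <- stats::aggregate(count ~ zcta_id + date, data = csub, FUN = sum)
    dsub <- denominators[denominators[[stratifier]] == lv, , drop = FALSE]
    dsub <- stats::aggregate(n ~ zcta_id + year, data = dsub, FUN = sum)
    tab <- build_model_table(matched, csub, dsub)
    stormlag(tab, ...)
  })
  structure(list(stratifier = stratifier, fits = fits,
                 results = strata_results(fits, stratifier),
                 comparison = NULL),
            class = "stormlag_strata")
}

strata_results <- function(fits, stratifier) {
  rows <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    if (is.null(f)) return(NULL)
    lag_tab <- lag_rr(f)
    lag_tab$separated <- NULL
    cum <- cumulative_rr(f)
    cum$flagged <- NULL
    cum$lag <- NA_integer_
    out <- rbind(lag_tab[, c("label", "lag", "log_rr", "se_log_rr", "rr",
                             "ci_low", "ci_high")],
                 cum[, c("label", "lag", "log_rr", "se_log_rr", "rr",
                         "ci_low", "ci_high")])
    out <- cbind(stratifier = stratifier, stratum = nm, out,
                 n_sets = f$n_sets, n_rows = f$nobs)
    out
  })
  res <- do.call(rbind, rows)
  if (!is.null(res)) rownames(res) <- NULL
  res
}

#' @export
print.stormlag_strata <- function(x, ...) {
  cat(sprintf("Stratified distributed-lag fits by %s\n", x$stratifier))
  for (nm in names(x$fits)) {
    f <- x$fits[[nm]]
    if (is.null(f)) {
      cat(sprintf("  %s: empty stratum\n", nm))
    } else {
      cum <- cumulative_rr(f)
      cat(sprintf("  %s: %d rows, cumulative RR %.3f (%.3f, %.3f)\n",
                  nm, f$nobs, cum$rr, cum$ci_low, cum$ci_high))
    }
  }
  if (!is.null(x$comparison)) {
    cat(sprintf("  contrast (cumulative): RR ratio %.3f, z = %.2f, p = %.3g\n",
                x$comparison$rr_ratio, x$comparison$z, x$comparison$p_value))
  }
  invisible(x)
}

#' Contrast a relative risk between two independently fitted strata
#'
#' Two-sample z test on the log relative risks of two strata fitted on
#' disjoint data: `z = (logRR_a - logRR_b) / sqrt(se_a^2 + se_b^2)`, with a
#' two-sided p value. The strata are assumed independent (they are fitted on
#' disjoint matched sets or disjoint beneficiaries).
#'
#' @param fit_a,fit_b `stormlag` fits.
#' @param target `"cumulative"` or a single lag value (e.g. `0`).
#' @param labels length-2 character naming the strata in the output.
#' @return one-row data frame: target, labels, the two log RRs and standard
#'   errors, `diff_log_rr`, `se_diff`, `rr_ratio`, `z`, `p_value`.
#' @examples
#' # z for log RRs 0.37 vs -0.39 with SEs 0.12 each: (0.76)/0.1697 = 4.48
#' @export
compare_strata_rr <- function(fit_a, fit_b, target = "cumulative",
                              labels = c("a", "b")) {
  get_est <- function(fit) {
    if (identical(target, "cumulative")) {
      est <- cumulative_rr(fit)
      c(log_rr = est$log_rr, se = est$se_log_rr)
    } else {
      tab <- lag_rr(fit)
      row <- tab[tab$lag == target, , drop = FALSE]
      if (nrow(row) != 1L) stop("unknown lag target: ", target)
      c(log_rr = row$log_rr, se = row$se_log_rr)
    }
  }
  a <- suppressWarnings(get_est(fit_a))
  b <- suppressWarnings(get_est(fit_b))
  if (anyNA(c(a, b)) || !all(is.finite(c(a, b)))) {
    warning("comparison unavailable: flagged estimate in a stratum", call. = FALSE)
    return(data.frame(target = format(target), label_a = labels[1L],
                      label_b = labels[2L], log_rr_a = a[["log_rr"]],
                      log_rr_b = b[["log_rr"]], se_a = a[["se"]], se_b = b[["se"]],
                      diff_log_rr = NA_real_, se_diff = NA_real_,
                      rr_ratio = NA_real_, z = NA_real_, p_value = NA_real_,
                      stringsAsFactors = FALSE))
  }
  diff <- a[["log_rr"]] - b[["log_rr"]]
  se <- sqrt(a[["se"]]^2 + b[["se"]]^2)
  z <- diff / se
  data.frame(target = format(target), label_a = labels[1L], label_b = labels[2L],
             log_rr_a = a[["log_rr"]], log_rr_b = b[["log_rr"]],
             se_a = a[["se"]], se_b = b[["se"]],
             diff_log_rr = diff, se_diff = se, rr_ratio = exp(diff), z = z,
             p_value = 2 * stats::pnorm(-abs(z)),
             stringsAsFactors = FALSE)
}
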