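#' Enumerate eligible control days for an exposed day
#'
#' A candidate control index day must (i) fall in a study year different from
#' the exposed day's year, (ii) lie within a seven-day window of the exposed
#' day's day-of-year (month-day distance on a 365-day circle, February 29
#' treated as February 28), (iii) not fall within the exclusion window (3
#' days, inclusive) of any storm's closest-approach day in the same ZCTA, and
#' (iv) carry a complete lag window (-2..+7 by default) inside the study
#' period.
#'
#' @param exposed_day the storm's closest-approach date (`Date`).
#' @param zcta_storm_days `Date` vector of all storm days in the ZCTA.
#' @param study_years integer vector of study years (consecutive).
#' @param doy_window day-of-year half-width (default 7).
#' @param exclusion_days half-width of the storm exclusion window (default 3,
#'   inclusive: days with `|d - storm| <= 3` are excluded).
#' @param lags lag grid whose window must fit in the study period.
#' @return sorted `Date` vector of candidates (possibly empty).
#' @examples
#' find_control_candidates(as.Date("2005-08-20"), as.Date("2005-08-20"),
#'                         1999:2016)
#' @export
find_control_candidates <- function(exposed_day, zcta_storm_days, study_years,
                                    doy_window = 7L, exclusion_days = 3L,
                                    lags = .LAGS) {
  stopifnot(inherits(exposed_day, "Date"), length(exposed_day) == 1L)
  study_years <- as.integer(study_years)
  exposed_year <- date_year(exposed_day)
  if (!exposed_year %in% study_years) {
    stop("`exposed_day` must fall within `study_years`")
  }
  start <- as.Date(sprintf("%04d-01-01", min(study_years)))
  end <- as.Date(sprintf("%04d-12-31", max(study_years)))

  # superset: the exposed month-day placed in every year around the period,
  # padded beyond the day-of-year window to cover year-boundary wrap
  pool <- unlist(lapply((min(study_years) - 1L):(max(study_years) + 1L),
                        function(y) shift_year(exposed_day, y) + (-(doy_window + 2L)):(doy_window + 2L)))
  pool <- sort(unique(as.Date(pool, origin = "1970-01-01")))

  keep <- date_year(pool) %in% study_years &
    date_year(pool) != exposed_year &
    doy_distance(pool, exposed_day) <= doy_window &
    pool + min(lags) >= start & pool + max(lags) <= end
  if (length(zcta_storm_days) > 0L) {
    near_storm <- vapply(pool, function(d) {
      any(abs(as.numeric(d - zcta_storm_days)) <= exclusion_days)
    }, logical(1))
    keep <- keep & !near_storm
  }
  pool[keep]
}

#' Sample control index days
#'
#' Draws `k` control days uniformly without replacement from the candidate
#' set. When fewer than `k` candidates exist, all candidates are returned and
#' the deficit is reported with a warning; an empty candidate set returns an
#' empty vector (the caller drops the matched set).
#'
#' @param candidates `Date` vector of eligible control days.
#' @param k number of controls to draw (default 10).
#' @param seed optional integer seed; when `NULL` the current RNG stream is
#'   used (the matching driver seeds it once).
#' @return `Date` vector of sampled controls (length `min(k, |candidates|)`).
#' @export
sample_controls <- function(candidates, k = 10L, seed = NULL) {
  if (k < 1L) stop("`k` must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  n <- length(candidates)
  if (n == 0L) return(candidates)
  if (n < k) {
    warning(sprintf("only %d control candidates available (requested %d)", n, k),
            call. = FALSE)
    return(sort(candidates))
  }
  sort(candidates[sample.int(n, k)])
}

#' Build matched exposed/unexposed-day sets
#'
#' For every storm-ZCTA pair, matches the closest-approach ("exposed") day to
#' `k` unexposed control days from other years via
#' [find_control_candidates()] and [sample_controls()]. Exposed days whose
#' own lag window leaves the study period are ineligible and dropped with a
#' log entry, keeping every retained set balanced.
#'
#' @param events ZCTA-keyed storm events (`storm_id`, `zcta_id`,
#'   `closest_date`), already threshold-filtered.
#' @param study_years integer vector of study years.
#' @param k controls per exposed day (default 10).
#' @param seed integer seed for the matching RNG (one seeded stream for the
#'   whole run, recorded in the result).
#' @param doy_window,exclusion_days,lags matching-rule parameters, see
#'   [find_control_candidates()].
#' @param require_full if `TRUE`, sets with fewer than `k` available controls
#'   are dropped instead of retained with a deficit.
#' @param allow_shared_controls if `FALSE`, a day already sampled as a
#'   control for an earlier storm in the same ZCTA is removed from later
#'   candidate sets.
#' @return an object of class `tc_matched`: list of matched sets (each with
#'   `zcta_id`, `storm_id`, `exposed_day`, `control_days`) plus a matching
#'   report.
#' @export
match_storm_days <- function(events, study_years, k = 10L, seed = 1L,
                             doy_window = 7L, exclusion_days = 3L, lags = .LAGS,
                             require_full = FALSE,
                             allow_shared_controls = TRUE) {
  stopifnot(is.data.frame(events),
            all(c("storm_id", "zcta_id", "closest_date") %in% names(events)))
  study_years <- as.integer(study_years)
  set.seed(seed)
  start <- as.Date(sprintf("%04d-01-01", min(study_years)))
  end <- as.Date(sprintf("%04d-12-31", max(study_years)))

  sets <- list()
  dropped_window <- character()
  dropped_empty <- character()
  dropped_deficit <- character()
  deficits <- list()
  ev_split <- split(events, events$zcta_id)
  for (z in names(ev_split)) {
    ev <- ev_split[[z]]
    ev <- ev[order(ev$closest_date), , drop = FALSE]
    storm_days <- ev$closest_date
    used_controls <- as.Date(character())
    for (i in seq_len(nrow(ev))) {
      set_key <- paste(ev$storm_id[i], z, sep = ":")
      d0 <- ev$closest_date[i]
      if (d0 + min(lags) < start || d0 + max(lags) > end) {
        dropped_window <- c(dropped_window, set_key)
        next
      }
      cand <- find_control_candidates(d0, storm_days, study_years,
                                      doy_window = doy_window,
                                      exclusion_days = exclusion_days,
                                      lags = lags)
      if (!allow_shared_controls) cand <- cand[!cand %in% used_controls]
      if (length(cand) == 0L) {
        dropped_empty <- c(dropped_empty, set_key)
        warning(sprintf("no control candidates for %s; set dropped", set_key),
                call. = FALSE)
        next
      }
      if (length(cand) < k && require_full) {
        dropped_deficit <- c(dropped_deficit, set_key)
        next
      }
      controls <- suppressWarnings(sample_controls(cand, k))
      if (length(controls) < k) {
        deficits[[set_key]] <- data.frame(set_id = set_key,
                                          n_controls = length(controls),
                                          requested = k,
                                          stringsAsFactors = FALSE)
        warning(sprintf("%s: only %d of %d controls available", set_key,
                        length(controls), k), call. = FALSE)
      }
      used_controls <- c(used_controls, controls)
      sets[[set_key]] <- list(set_id = set_key, zcta_id = z,
                              storm_id = ev$storm_id[i], exposed_day = d0,
                              control_days = controls)
    }
  }
  structure(list(
    sets = sets,
    report = list(n_storm_zcta = nrow(events),
                  n_sets = length(sets),
                  dropped_window = dropped_window,
                  dropped_no_candidates = dropped_empty,
                  dropped_deficit = dropped_deficit,
                  deficits = if (length(deficits)) do.call(rbind, deficits) else NULL),
    k = k, lags = lags, study_years = study_years, seed = seed,
    doy_window = doy_window, exclusion_days = exclusion_days
  ), class = "tc_matched")
}

#' @export
print.tc_matched <- function(x, ...) {
  cat("Matched exposed/unexposed-day design\n")
  cat(sprintf("  %d storm-ZCTA pairs -> %d matched sets (k = %d controls)\n",
              x$report$n_storm_zcta, x$report$n_sets, x$k))
  nd <- length(x$report$dropped_window) + length(x$report$dropped_no_candidates) +
    length(x$report$dropped_deficit)
  if (nd > 0L) cat(sprintf("  %d sets dropped (window/no-candidate/deficit)\n", nd))
  if (!is.null(x$report$deficits)) {
    cat(sprintf("  %d sets retained with a control deficit\n",
                nrow(x$report$deficits)))
  }
  invisible(x)
}

#' Assemble the long model table with distributed-lag indicators
#'
#' Expands each matched set into day-level rows: the 10-day lag window around
#' the exposed index day and around each control index day. With a full set
#' of 10 controls this yields (1 + 10) x 10 = 110 rows per storm-ZCTA. Rows
#' from the exposed window carry exactly one nonzero lag indicator (the row's
#' position in the window); control-window rows carry all-zero indicators.
#' Counts and log beneficiary denominators are joined by ZCTA-date and
#' ZCTA-year; day of week and calendar year are derived from the date.
#'
#' @param matched a `tc_matched` object.
#' @param counts data frame (`zcta_id`, `date`, `count`) covering all window
#'   dates (aggregate subgroup counts first, see [aggregate_counts()]).
#' @param denominators data frame (`zcta_id`, `year`, `n`).
#' @param on_missing what to do when a window date has no count row: "error"
#'   (default) lists the offending (zcta, date) pairs; "drop" removes the
#'   whole matched set with a warning.
#' @return data frame with columns `set_id`, `zcta_id`, `storm_id`, `date`,
#'   `index_day`, `exposed`, ten lag-indicator columns (`lag_m2`..`lag_7`),
#'   `count`, `log_denom`, `dow`, `year`; attribute `"lags"` records the lag
#'   grid.
#' @export
build_model_table <- function(matched, counts, denominators,
                              on_missing = c("error", "drop")) {
  stopifnot(inherits(matched, "tc_matched"),
            is.data.frame(counts),
            all(c("zcta_id", "date", "count") %in% names(counts)),
            is.data.frame(denominators),
            all(c("zcta_id", "year", "n") %in% names(denominators)))
  on_missing <- match.arg(on_missing)
  if (any(c("age", "sex", "dual") %in% names(counts))) {
    stop("`counts` has subgroup columns; filter to one subgroup or aggregate first")
  }
  lags <- matched$lags
  nl <- length(lags)
  if (length(matched$sets) == 0L) {
    out <- empty_model_table(lags)
    attr(out, "lags") <- lags
    return(out)
  }
  blocks <- lapply(matched$sets, function(s) {
    idx_days <- c(s$exposed_day, s$control_days)
    n_idx <- length(idx_days)
    data.frame(set_id = s$set_id, zcta_id = s$zcta_id, storm_id = s$storm_id,
               index_day = rep(idx_days, each = nl),
               exposed = rep(c(1L, integer(n_idx - 1L)), each = nl),
               lag = rep(lags, n_idx),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, blocks)
  rownames(tab) <- NULL
  tab$date <- tab$index_day + tab$lag

  ind <- matrix(0L, nrow(tab), nl, dimnames = list(NULL, lag_col_names(lags)))
  on_rows <- tab$exposed == 1L
  ind[cbind(which(on_rows), match(tab$lag[on_rows], lags))] <- 1L
  tab <- cbind(tab, as.data.frame(ind))

  ckey <- paste(counts$zcta_id, counts$date, sep = "\r")
  m <- match(paste(tab$zcta_id, tab$date, sep = "\r"), ckey)
  if (anyNA(m)) {
    bad <- unique(tab[is.na(m), c("zcta_id", "date", "set_id")])
    if (on_missing == "error") {
      stop("missing count rows for window dates: ",
           paste(utils::head(paste(bad$zcta_id, bad$date), 10L), collapse = "; "),
           if (nrow(bad) > 10L) sprintf(" ... (%d total)", nrow(bad)) else "")
    }
    drop_sets <- unique(bad$set_id)
    warning(sprintf("dropping %d matched set(s) with missing count rows",
                    length(drop_sets)), call. = FALSE)
    keep <- !tab$set_id %in% drop_sets
    tab <- tab[keep, , drop = FALSE]
    m <- m[keep]
  }
  tab$count <- counts$count[m]

  tab$year <- date_year(tab$date)
  dkey <- paste(denominators$zcta_id, denominators$year, sep = "\r")
  md <- match(paste(tab$zcta_id, tab$year, sep = "\r"), dkey)
  if (anyNA(md)) {
    bad <- unique(tab[is.na(md), c("zcta_id", "year")])
    stop("missing denominators for ZCTA-year(s): ",
         paste(paste(bad$zcta_id, bad$year), collapse = "; "))
  }
  tab$log_denom <- log(denominators$n[md])
  tab$dow <- as.character(day_of_week(tab$date))
  tab$lag <- NULL
  attr(tab, "lags") <- lags
  tab
}

empty_model_table <- function(lags = .LAGS) {
  cols <- c("set_id", "zcta_id", "storm_id", "index_day", "exposed", "date",
            lag_col_names(lags), "count", "year", "log_denom", "dow")
  out <- as.data.frame(stats::setNames(rep(list(character(0)), length(cols)), cols))
  out
}
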