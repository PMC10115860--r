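#' Classify windspeeds as tropical-cyclone exposure
#'
#' A spatial unit is exposed to a storm when its modeled peak sustained
#' windspeed reaches gale force, 21 m/s or more (closed lower bound).
#'
#' @param windspeed numeric vector of peak sustained windspeeds in m/s; must
#'   be finite and nonnegative.
#' @param threshold exposure threshold in m/s (default 21).
#' @return logical vector, `TRUE` where the unit qualifies as exposed.
#' @examples
#' classify_exposed(c(20.999, 21, 33.55))
#' @export
classify_exposed <- function(windspeed, threshold = 21) {
  if (!is.numeric(windspeed)) stop("`windspeed` must be numeric")
  if (any(!is.finite(windspeed))) stop("`windspeed` must be finite")
  if (any(windspeed < 0)) stop("`windspeed` must be nonnegative")
  windspeed >= threshold
}

#' Restrict storm events to qualifying exposures
#'
#' @param events storm event data frame with a `windspeed` column (m/s).
#' @param threshold exposure threshold in m/s.
#' @return the subset of `events` with `windspeed >= threshold`. Filtering is
#'   idempotent.
#' @export
filter_exposed <- function(events, threshold = 21) {
  stopifnot(is.data.frame(events), "windspeed" %in% names(events))
  events[classify_exposed(events$windspeed, threshold), , drop = FALSE]
}

#' Assign county storm exposures to ZCTAs
#'
#' Each ZCTA inherits the complete storm-event list of the single county
#' holding the largest share of its land area. Windspeeds and
#' closest-approach dates are copied unchanged. Ties on the land-area
#' fraction are broken deterministically toward the lexicographically
#' smallest county identifier, with a warning.
#'
#' @param county_events data frame of storm events keyed by county, with
#'   columns `storm_id`, `county_id`, `closest_date`, `windspeed`.
#' @param overlaps data frame with columns `zcta_id`, `county_id`,
#'   `land_area_fraction` (fractions in \[0,1\], summing to at most 1 per
#'   ZCTA; a water/unassigned remainder is allowed).
#' @param zctas optional character vector of ZCTAs that must be assigned; an
#'   entry absent from `overlaps` raises an error naming it.
#' @return data frame of storm events keyed by ZCTA: `storm_id`, `zcta_id`,
#'   `county_id` (the assigned county), `closest_date`, `windspeed`.
#' @export
assign_zcta_exposure <- function(county_events, overlaps, zctas = NULL) {
  stopifnot(is.data.frame(county_events),
            all(c("storm_id", "county_id", "closest_date", "windspeed") %in%
                  names(county_events)),
            is.data.frame(overlaps),
            all(c("zcta_id", "county_id", "land_area_fraction") %in% names(overlaps)))
  f <- overlaps$land_area_fraction
  if (any(!is.finite(f)) || any(f < 0) || any(f > 1)) {
    stop("land_area_fraction values must lie in [0, 1]")
  }
  tot <- tapply(f, overlaps$zcta_id, sum)
  if (any(tot > 1 + 1e-8)) {
    stop("land_area_fractions exceed 1 for ZCTA(s): ",
         paste(names(tot)[tot > 1 + 1e-8], collapse = ", "))
  }
  if (!is.null(zctas)) {
    missing <- setdiff(zctas, overlaps$zcta_id)
    if (length(missing) > 0L) {
      stop("no county overlap recorded for ZCTA(s): ",
           paste(missing, collapse = ", "))
    }
  }
  pick <- lapply(split(overlaps, overlaps$zcta_id), function(d) {
    best <- d[d$land_area_fraction == max(d$land_area_fraction), , drop = FALSE]
    if (nrow(best) > 1L) {
      best <- best[order(best$county_id), , drop = FALSE]
      warning(sprintf("ZCTA %s: land-area tie between counties %s; using %s",
                      best$zcta_id[1L],
                      paste(sort(best$county_id), collapse = ", "),
                      best$county_id[1L]), call. = FALSE)
    }
    best[1L, c("zcta_id", "county_id")]
  })
  assignment <- do.call(rbind, pick)
  out <- merge(assignment, county_events, by = "county_id")
  out <- out[, c("storm_id", "zcta_id", "county_id", "closest_date", "windspeed")]
  out[order(out$zcta_id, out$closest_date), , drop = FALSE]
}

#' Per-ZCTA storm summary metrics
#'
#' Computes, for each ZCTA, the number of qualifying storms, the average
#' storm intensity, and the intensity of the most extreme storm (peak
#' sustained windspeed, m/s). Events are expected to be threshold-filtered
#' already (see [filter_exposed()]). ZCTAs supplied via `zctas` but absent
#' from `events` are reported with zero storms and missing intensities.
#'
#' @param events data frame with columns `storm_id`, `zcta_id`, `windspeed`.
#' @param zctas optional character vector of ZCTAs to report (default: those
#'   present in `events`).
#' @return data frame with columns `zcta_id`, `n_storms`, `mean_windspeed`,
#'   `max_windspeed`.
#' @export
summarize_exposure <- function(events, zctas = NULL) {
  stopifnot(is.data.frame(events),
            all(c("storm_id", "zcta_id", "windspeed") %in% names(events)))
  key <- paste(events$storm_id, events$zcta_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (storm_id, zcta_id) rows in `events`")
  }
  zctas <- zctas %||% sort(unique(events$zcta_id))
  by_z <- split(events, factor(events$zcta_id, levels = zctas))
  out <- data.frame(zcta_id = zctas,
                    n_storms = vapply(by_z, nrow, integer(1)),
                    mean_windspeed = vapply(by_z, function(d) {
                      if (nrow(d) == 0L) NA_real_ else mean(d$windspeed)
                    }, numeric(1)),
                    max_windspeed = vapply(by_z, function(d) {
                      if (nrow(d) == 0L) NA_real_ else max(d$windspeed)
                    }, numeric(1)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
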