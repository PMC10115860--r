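# Internal date and validation helpers shared across modules.

# Cumulative days at the start of each month in a 365-day (non-leap) year.
.MONTH_OFFSET <- c(0L, 31L, 59L, 90L, 120L, 151L, 181L, 212L, 243L, 273L, 304L, 334L)

#' Day-of-year position on a fixed 365-day circle
#'
#' Maps each date to its month-day position in a non-leap reference year, with
#' February 29 mapped to February 28. This avoids integer day-of-year drift
#' across leap years when matching control days by season.
#'
#' @param dates a `Date` vector.
#' @return integer vector in 1..365.
#' @keywords internal
#' @noRd
pseudo_doy <- function(dates) {
  lt <- as.POSIXlt(dates)
  m <- lt$mon + 1L
  d <- lt$mday
  d[m == 2L & d == 29L] <- 28L
  .MONTH_OFFSET[m] + d
}

# Circular distance between two dates on the 365-day month-day circle.
doy_distance <- function(a, b) {
  diff <- abs(pseudo_doy(a) - pseudo_doy(b))
  pmin(diff, 365L - diff)
}

# The same calendar month-day placed in another year (Feb 29 -> Feb 28).
shift_year <- function(date, year) {
  lt <- as.POSIXlt(date)
  m <- lt$mon + 1L
  d <- lt$mday
  d[m == 2L & d == 29L] <- 28L
  as.Date(sprintf("%04d-%02d-%02d", year, m, d))
}

date_year <- function(dates) as.POSIXlt(dates)$year + 1900L

# Day-of-week labels with Monday first (the model's reference level).
.DOW_LEVELS <- c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun")

day_of_week <- function(dates) {
  wday <- as.POSIXlt(dates)$wday        # 0 = Sunday
  idx <- ifelse(wday == 0L, 7L, wday)   # 1 = Monday ... 7 = Sunday
  factor(.DOW_LEVELS[idx], levels = .DOW_LEVELS)
}

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# The distributed-lag grid: 2 days before to 7 days after an index day.
.LAGS <- -2:7

lag_col_names <- function(lags = .LAGS) {
  paste0("lag_", ifelse(lags < 0L, paste0("m", -lags), as.character(lags)))
}

lag_labels <- function(lags = .LAGS) paste0("lag ", lags)
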