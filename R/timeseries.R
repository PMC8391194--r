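# Date-indexed series containers and rate construction.
#
# Two raw containers: a weekly employment series (percent-employed outcome,
# regime dummy, weekly infection rate) and a daily epidemic count series
# (cumulative positives / tests / deaths). Rates derived from counts are
# carried as `rate_series` objects holding fractions in [0, 1].

#' Weekly employment series
#'
#' Container for the weekly modelling frame: percent employed \eqn{E_t} on
#' the 0--100 scale, a binary regime-shift dummy \eqn{d_t} (1 during
#' recession/pandemic windows, 0 elsewhere), and the weekly infection rate
#' \eqn{c_t} as a fraction (zero before pandemic onset).
#'
#' @param dates Week-start dates (\code{Date}), strictly increasing with
#'   7-day spacing.
#' @param values Percent employed per week, in \eqn{[0, 100]}.
#' @param dummy Regime-shift indicator per week, each 0 or 1.
#' @param infection_rate Weekly infection rate per week, in \eqn{[0, 1]}.
#' @return A \code{data.frame} of class \code{weekly_series} with columns
#'   \code{date}, \code{employment_pct}, \code{infection_rate}, \code{dummy}.
#' @export
weekly_series <- function(dates, values, dummy = NULL, infection_rate = NULL) {
  dates <- as.Date(dates)
  n <- length(dates)
  if (is.null(dummy)) dummy <- rep(0, n)
  if (is.null(infection_rate)) infection_rate <- rep(0, n)
  if (length(values) != n || length(dummy) != n || length(infection_rate) != n)
    stop_input("all weekly columns must have the same length as `dates`")
  if (n > 1L && !all(diff(as.integer(dates)) == 7L))
    stop_input("weekly dates must be strictly increasing with 7-day spacing")
  if (any(!is.finite(values)) || any(values < 0 | values > 100))
    stop_input("employment values must be finite and within [0, 100]")
  if (!all(dummy %in% c(0, 1)))
    stop_input("dummy must be binary (0/1)")
  if (any(!is.finite(infection_rate)) ||
      any(infection_rate < 0 | infection_rate > 1))
    stop_input("infection_rate must be within [0, 1]")
  out <- data.frame(date = dates, employment_pct = as.numeric(values),
                    infection_rate = as.numeric(infection_rate),
                    dummy = as.numeric(dummy))
  class(out) <- c("weekly_series", "data.frame")
  out
}

#' Daily epidemic count series
#'
#' Cumulative confirmed positives, cumulative tests, and cumulative deaths
#' per calendar day. All three series must be non-negative, non-decreasing,
#' with positives never exceeding tests.
#'
#' @param dates Calendar days (\code{Date}), strictly ascending.
#' @param cum_positives,cum_tests,cum_deaths Cumulative counts.
#' @return A \code{data.frame} of class \code{daily_epidemic_series}.
#' @export
daily_epidemic_series <- function(dates, cum_positives, cum_tests, cum_deaths) {
  dates <- as.Date(dates)
  n <- length(dates)
  cols <- list(cum_positives = cum_positives, cum_tests = cum_tests,
               cum_deaths = cum_deaths)
  for (nm in names(cols)) {
    x <- cols[[nm]]
    if (length(x) != n)
      stop_input(nm, " must have the same length as `dates`")
    if (any(!is.finite(x)) || any(x < 0))
      stop_input(nm, " must be non-negative and finite")
    if (any(abs(x - round(x)) > 1e-8))
      stop_input(nm, " must be integer-valued counts")
    bad <- which(diff(x) < 0)
    if (length(bad))
      stop_input(nm, " must be non-decreasing (violated at row ", bad[1L] + 1L, ")")
  }
  if (n > 1L && any(diff(as.integer(dates)) <= 0))
    stop_input("daily dates must be strictly ascending")
  if (any(cum_positives > cum_tests))
    stop_input("cum_positives must not exceed cum_tests")
  out <- data.frame(date = dates,
                    cum_positives = round(as.numeric(cum_positives)),
                    cum_tests = round(as.numeric(cum_tests)),
                    cum_deaths = round(as.numeric(cum_deaths)))
  class(out) <- c("daily_epidemic_series", "data.frame")
  out
}

#' Rate series (fractions in [0, 1])
#'
#' @param dates Ascending dates.
#' @param values Fractions in \eqn{[0, 1]}.
#' @param kind One of \code{"infection"} or \code{"death_rate"}.
#' @return A \code{data.frame} of class \code{rate_series} with columns
#'   \code{date} and \code{value}; the kind is stored as an attribute.
#' @export
rate_series <- function(dates, values, kind = c("infection", "death_rate")) {
  kind <- match.arg(kind)
  dates <- as.Date(dates)
  if (length(values) != length(dates))
    stop_input("`values` must match `dates` in length")
  if (length(dates) > 1L && any(diff(as.integer(dates)) <= 0))
    stop_input("rate dates must be strictly ascending")
  if (any(!is.finite(values)) || any(values < 0 | values > 1))
    stop_input("rate values must be within [0, 1]")
  out <- data.frame(date = dates, value = as.numeric(values))
  attr(out, "kind") <- kind
  class(out) <- c("rate_series", "data.frame")
  out
}

#' Infection rate from cumulative counts
#'
#' Test positivity on day \eqn{t}: cumulative confirmed positives divided by
#' cumulative tests. Days with zero tests (and zero positives) are dropped;
#' a day with positives but no tests is an error.
#'
#' @param series A \code{\link{daily_epidemic_series}}.
#' @return A \code{\link{rate_series}} of kind \code{"infection"}.
#' @export
compute_infection_rate <- function(series) {
  stopifnot(inherits(series, "daily_epidemic_series"))
  bad <- series$cum_tests == 0 & series$cum_positives > 0
  if (any(bad))
    stop_input("cum_tests is zero on a day with positive cases (",
               format(series$date[which(bad)[1L]]), ")")
  keep <- series$cum_tests > 0
  rate_series(series$date[keep],
              series$cum_positives[keep] / series$cum_tests[keep],
              kind = "infection")
}

#' Lagged case-fatality rate from cumulative counts
#'
#' Death rate on day \eqn{t}: cumulative deaths on day \eqn{t} divided by the
#' cumulative number of confirmed cases on day \eqn{t - \mathrm{lag}}, emitted
#' for \eqn{t = \mathrm{lag} + 1, \ldots, T}. The lag reflects the delay
#' between infection and death. Days whose lagged case count is zero are
#' dropped with a warning. The numerator defaults to cumulative deaths, which
#' keeps the rate on the case-fatality scale reported by health agencies;
#' \code{numerator = "incident"} divides daily new deaths instead.
#'
#' @param series A \code{\link{daily_epidemic_series}}.
#' @param lag_days Lag in days between case denominator and death numerator.
#' @param numerator \code{"cumulative"} (default) or \code{"incident"}.
#' @return A \code{\link{rate_series}} of kind \code{"death_rate"}.
#' @export
compute_death_rate <- function(series, lag_days = 7L,
                               numerator = c("cumulative", "incident")) {
  stopifnot(inherits(series, "daily_epidemic_series"))
  numerator <- match.arg(numerator)
  lag_days <- as.integer(lag_days)
  if (lag_days < 0L) stop_input("`lag_days` must be non-negative")
  n <- nrow(series)
  idx <- seq.int(lag_days + 1L, length.out = max(0L, n - lag_days))
  if (!length(idx)) {
    return(rate_series(as.Date(character()), numeric(), kind = "death_rate"))
  }
  deaths <- if (numerator == "cumulative") {
    series$cum_deaths[idx]
  } else {
    series$cum_deaths[idx] - c(0, series$cum_deaths)[idx]
  }
  denom <- series$cum_positives[idx - lag_days]
  drop <- denom == 0
  if (any(drop)) {
    warning(sum(drop), " day(s) dropped: lagged cumulative cases are zero",
            call. = FALSE)
    idx <- idx[!drop]
    deaths <- deaths[!drop]
    denom <- denom[!drop]
  }
  rate_series(series$date[idx], deaths / denom, kind = "death_rate")
}

#' Weekly aggregation of a daily rate
#'
#' Collapses a daily rate series onto week starts using the last observed day
#' of each week (the most recent information available within the week).
#' Weeks ending before the first daily observation are treated as pre-onset
#' and filled with zero; a week after onset with no daily observations is an
#' error.
#'
#' @param daily A \code{\link{rate_series}}.
#' @param week_starts Week-start dates; each week spans
#'   \code{[start, start + 6]}.
#' @return Numeric vector of per-week fractions aligned to \code{week_starts}.
#' @export
aggregate_weekly_rate <- function(daily, week_starts) {
  stopifnot(inherits(daily, "rate_series"))
  week_starts <- as.Date(week_starts)
  if (!nrow(daily)) return(rep(0, length(week_starts)))
  onset <- min(daily$date)
  vapply(week_starts, function(ws) {
    in_week <- daily$date >= ws & daily$date <= ws + 6L
    if (!any(in_week)) {
      if (ws + 6L < onset) return(0)
      stop_input("week starting ", format(ws),
                 " has no daily observations after onset")
    }
    daily$value[max(which(in_week))]
  }, numeric(1L))
}

#' Read / write date-indexed series as CSV
#'
#' Schemas: weekly files have header
#' \code{date,employment_pct,infection_rate,dummy}; daily files have
#' \code{date,cum_positives,cum_tests,cum_deaths}. Dates are ISO-8601,
#' UTF-8, comma-separated. All container invariants are re-validated on
#' read, so a file with (say) a decreasing cumulative column is rejected.
#'
#' @param path File path.
#' @param schema \code{"weekly"} or \code{"daily"}.
#' @return \code{read_series_csv}: a \code{\link{weekly_series}} or
#'   \code{\link{daily_epidemic_series}}. \code{write_series_csv}: the path,
#'   invisibly.
#' @export
read_series_csv <- function(path, schema = c("weekly", "daily")) {
  schema <- match.arg(schema)
  df <- read.csv(path, stringsAsFactors = FALSE)
  want <- if (schema == "weekly") {
    c("date", "employment_pct", "infection_rate", "dummy")
  } else {
    c("date", "cum_positives", "cum_tests", "cum_deaths")
  }
  missing_cols <- setdiff(want, names(df))
  if (length(missing_cols))
    stop_input("missing column(s) in ", path, ": ",
               paste(missing_cols, collapse = ", "))
  dates <- as.Date(df$date, format = "%Y-%m-%d")
  if (anyNA(dates))
    stop_input("unparsable date at row ", which(is.na(dates))[1L], " of ", path)
  if (schema == "weekly") {
    weekly_series(dates, df$employment_pct, df$dummy, df$infection_rate)
  } else {
    daily_epidemic_series(dates, df$cum_positives, df$cum_tests, df$cum_deaths)
  }
}

#' @rdname read_series_csv
#' @param series A \code{weekly_series} or \code{daily_epidemic_series}.
#' @export
write_series_csv <- function(series, path) {
  if (!inherits(series, c("weekly_series", "daily_epidemic_series")))
    stop_input("`series` must be a weekly_series or daily_epidemic_series")
  df <- as.data.frame(series)
  df$date <- format(df$date, "%Y-%m-%d")
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], function(x) formatC(x, digits = 10, format = "g"))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
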