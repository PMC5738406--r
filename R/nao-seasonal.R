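#' Dialect for year-by-month teleconnection index tables
#'
#' Monthly teleconnection indices are distributed as plain-text tables with
#' one row per year: the year followed by twelve monthly values. Public NAO
#' tables differ in delimiter and in the sentinel used for missing months;
#' the dialect captures both.
#'
#' @param sep Field delimiter: `"whitespace"` (default) or `","`.
#' @param missing_sentinel Numeric value encoding a missing month (e.g.
#'   `-99.99` or `-99.9` in the public NAO tables); `NA` to disable.
#' @param header Logical: does the file carry a header row?
#' @return A list of dialect settings.
#' @export
monthly_table_dialect <- function(sep = "whitespace", missing_sentinel = -99.99,
                                  header = FALSE) {
  list(sep = sep, missing_sentinel = missing_sentinel, header = header)
}

#' Read a monthly teleconnection index table
#'
#' @param path Path to a year-by-12-months table.
#' @param dialect See [monthly_table_dialect()].
#' @return A tibble with columns `year`, `month` (1--12) and `value`
#'   (`NA` where the sentinel appeared), ordered by year and month.
#' @export
read_monthly_index <- function(path, dialect = monthly_table_dialect()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (identical(dialect$sep, "whitespace")) {
    raw <- readr::read_table(path, col_names = isTRUE(dialect$header),
                             show_col_types = FALSE, progress = FALSE)
  } else {
    raw <- readr::read_delim(path, delim = dialect$sep,
                             col_names = isTRUE(dialect$header),
                             show_col_types = FALSE, progress = FALSE)
  }
  if (ncol(raw) < 13) {
    stop("monthly index table must have a year column plus 12 monthly columns",
         call. = FALSE)
  }
  raw <- raw[, 1:13]
  names(raw) <- c("year", sprintf("m%02d", 1:12))
  if (anyDuplicated(raw$year)) stop("duplicate year rows in ", path, call. = FALSE)
  out <- raw %>%
    tidyr::pivot_longer(-"year", names_to = "month", values_to = "value") %>%
    mutate(year = as.integer(.data$year),
           month = as.integer(sub("^m", "", .data$month)))
  sent <- dialect$missing_sentinel
  if (!is.null(sent) && !is.na(sent)) {
    out$value[abs(out$value - sent) < 1e-8] <- NA_real_
  }
  arrange(out, .data$year, .data$month)
}

#' Write a monthly index series as a year-by-12-months table
#'
#' @param monthly Tibble with `year`, `month`, `value`.
#' @param path Output path.
#' @param dialect See [monthly_table_dialect()]; missing values are written
#'   as the dialect's sentinel.
#' @return `path`, invisibly.
#' @export
write_monthly_index <- function(monthly, path,
                                dialect = monthly_table_dialect()) {
  wide <- monthly %>%
    arrange(.data$year, .data$month) %>%
    tidyr::pivot_wider(names_from = "month", values_from = "value",
                       names_prefix = "m")
  sent <- dialect$missing_sentinel
  if (!is.null(sent) && !is.na(sent)) {
    wide[is.na(wide)] <- sent
  }
  if (identical(dialect$sep, "whitespace")) {
    utils::write.table(wide, path, row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  } else {
    utils::write.table(wide, path, row.names = FALSE, col.names = FALSE,
                       quote = FALSE, sep = dialect$sep)
  }
  invisible(path)
}

# Season definitions. Winter (DJFM) for year T uses December of T-1 and
# January-March of T, so the label year is the one containing Jan-Mar.
season_months <- function(season) {
  switch(season,
    DJFM = list(months = c(12L, 1L, 2L, 3L), year_offset = c(-1L, 0L, 0L, 0L)),
    AM   = list(months = c(4L, 5L), year_offset = c(0L, 0L)),
    JJAS = list(months = 6:9, year_offset = rep(0L, 4)),
    stop("unknown season '", season, "'; use DJFM, AM or JJAS", call. = FALSE)
  )
}

#' Aggregate a monthly series to a seasonal mean series
#'
#' Seasons follow the standard teleconnection windows: winter `DJFM`
#' (December of the previous year through March), spring `AM` (April-May)
#' and summer `JJAS` (June-September). A seasonal value is emitted only when
#' every month of the season is present; otherwise that year is missing.
#'
#' @param monthly Tibble with `year`, `month`, `value`.
#' @param season One of `"DJFM"`, `"AM"`, `"JJAS"`.
#' @return A tibble with columns `year`, `value` and attribute `"season"`.
#' @export
#' @examples
#' monthly <- tidyr::expand_grid(year = 1950:1960, month = 1:12)
#' monthly$value <- 1
#' seasonal_aggregate(monthly, "DJFM")
seasonal_aggregate <- function(monthly, season) {
  def <- season_months(season)
  key <- paste(monthly$year, monthly$month)
  vals <- setNames(monthly$value, key)
  years <- sort(unique(monthly$year))
  value <- vapply(years, function(y) {
    k <- paste(y + def$year_offset, def$months)
    v <- vals[k]
    if (length(v) < length(k) || anyNA(v)) NA_real_ else mean(v)
  }, numeric(1))
  out <- tibble(year = as.integer(years), value = value)
  attr(out, "season") <- season
  out
}

#' Attach a seasonal series to masting years at a fixed lag
#'
#' Mast-year predictors use seasonal values from the mast year itself
#' (`lag = 0`), the year before fruit ripening (`lag = -1`) or two years
#' before (`lag = -2`). The returned series is indexed by the masting year:
#' the predictor for masting year `Y` is the seasonal value of year
#' `Y + lag`.
#'
#' @param seasonal Tibble with `year`, `value` from [seasonal_aggregate()].
#' @param lag Integer lag offset: 0, -1 or -2.
#' @param target_years Masting years to cover.
#' @return A tibble with columns `year` (masting year) and `value`, plus
#'   attributes `"season"` and `"lag"`.
#' @export
lag_align <- function(seasonal, lag, target_years) {
  stopifnot(lag %in% c(0L, -1L, -2L))
  source_years <- as.integer(target_years) + as.integer(lag)
  missing_years <- setdiff(source_years, seasonal$year)
  if (length(missing_years) > 0) {
    stop("seasonal series does not cover source year(s) ",
         paste(range(missing_years), collapse = "-"),
         " required for lag ", lag, call. = FALSE)
  }
  out <- tibble(
    year = as.integer(target_years),
    value = seasonal$value[match(source_years, seasonal$year)]
  )
  attr(out, "season") <- attr(seasonal, "season")
  attr(out, "lag") <- as.integer(lag)
  out
}
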