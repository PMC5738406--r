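#' Fixed-span running-line smoother
#'
#' At each observation the smoother fits an ordinary least-squares line to
#' the points inside a centred window of `span_years` observations and takes
#' the fitted value at the centre. Near the series ends the window is
#' truncated symmetrically (equal reach on both sides) down to a minimum of
#' 3 points, which avoids end-of-series extrapolation artifacts in the
#' decadal component. The smoother is linear in its input and reproduces an
#' exactly linear series unchanged.
#'
#' Annual series are assumed, so a span of 11 years means an 11-observation
#' window. Even spans are shrunk to the next lower odd count so the window
#' stays centred.
#'
#' @param x Numeric vector of values, no internal gaps.
#' @param span_years Window length in observations (>= 3).
#' @param years Optional abscissa (defaults to the observation index).
#' @return Numeric vector of smoothed values, same length as `x`.
#' @export
#' @examples
#' running_line_smooth(3 + 0.5 * (1:30), span_years = 11)  # returned unchanged
running_line_smooth <- function(x, span_years, years = seq_along(x)) {
  n <- length(x)
  span <- as.integer(span_years)
  if (span < 3L) stop("span_years must be at least 3", call. = FALSE)
  if (n <= span) stop("series length (", n, ") must exceed span (", span, ")",
                      call. = FALSE)
  if (anyNA(x)) stop("running_line_smooth requires a gap-free series", call. = FALSE)
  h <- (span - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    hi <- min(h, i - 1L, n - i)
    idx <- (i - hi):(i + hi)
    if (length(idx) < 3L) {
      # series endpoints: fall back to the 3 nearest points (one-sided)
      idx <- if (i <= 2L) 1:3 else (n - 2L):n
    }
    tt <- years[idx] - years[i]
    yy <- x[idx]
    # local OLS of value on time, evaluated at the window centre
    b <- sum((tt - mean(tt)) * yy) / sum((tt - mean(tt))^2)
    mean(yy) + b * (0 - mean(tt))
  }, numeric(1))
}

#' Split a seasonal series into low- and high-frequency components
#'
#' The low-frequency (decadal) component is the running-line smooth of the
#' raw series at the given span; the high-frequency (inter-annual) component
#' is the raw series minus the smooth, so `raw = low + high` holds exactly
#' at every year.
#'
#' @param data Tibble with a `year` column and a value column.
#' @param span_years Smoother span in years, typically the midpoint of the
#'   period band where wavelet coherence with masting is significant
#'   (about 11 years).
#' @param value_col Name of the value column (default `"value"`).
#' @return A tibble of class `freq_components` with columns `year`, `raw`,
#'   `low`, `high` and attribute `"span_years"`.
#' @export
split_frequencies <- function(data, span_years, value_col = "value") {
  check_year_column(data)
  x <- data[[value_col]]
  low <- running_line_smooth(x, span_years, years = data$year)
  out <- tibble(year = as.integer(data$year), raw = as.numeric(x),
                low = low, high = as.numeric(x) - low)
  attr(out, "span_years") <- span_years
  class(out) <- c("freq_components", class(out))
  out
}
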