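# Internal helpers shared across modules.

# Statistical mode of an integer vector with deterministic tie handling:
# the lowest tied class wins (conservative: biases against declaring mast years).
modal_class <- function(x) {
  tab <- table(x)
  cls <- as.integer(names(tab))
  cls[tab == max(tab)][1L]
}

# Lag-1 sample autocorrelation about the sample mean.
acf_lag1 <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3L) stop("need at least 3 finite values to estimate lag-1 autocorrelation")
  xc <- x - mean(x)
  sum(xc[-1L] * xc[-n]) / sum(xc^2)
}

check_year_column <- function(data, year_col = "year") {
  if (!year_col %in% names(data)) {
    stop("column '", year_col, "' not found in input data", call. = FALSE)
  }
  invisible(data)
}
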