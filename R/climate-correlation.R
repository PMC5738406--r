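#' Aggregate a gridded monthly field to seasonal means
#'
#' Applies the same season windows as [seasonal_aggregate()] (DJFM, AM,
#' JJAS) independently at every grid cell. A cell-year is emitted only when
#' every month of the season is present for that cell.
#'
#' @param grid Long-format tibble with columns `lat`, `lon`, `year`,
#'   `month`, `value`.
#' @param season One of `"DJFM"`, `"AM"`, `"JJAS"`.
#' @return Tibble with columns `lat`, `lon`, `year`, `value`.
#' @export
seasonal_grid_aggregate <- function(grid, season) {
  stopifnot(all(c("lat", "lon", "year", "month", "value") %in% names(grid)))
  grid %>%
    group_by(.data$lat, .data$lon) %>%
    dplyr::group_modify(~ seasonal_aggregate(.x, season)) %>%
    ungroup()
}

#' Remove a linear time trend by ordinary least squares
#'
#' @param x Numeric series (length >= 3).
#' @param years Abscissa (default: observation index).
#' @return Detrended series: `x` minus the fitted line; mean 0 and zero
#'   correlation with time.
#' @export
detrend_linear <- function(x, years = seq_along(x)) {
  ok <- is.finite(x)
  if (sum(ok) < 3) stop("need at least 3 finite values to detrend", call. = FALSE)
  out <- rep(NA_real_, length(x))
  fit <- lm.fit(cbind(1, years[ok]), x[ok])
  out[ok] <- fit$residuals
  out
}

# Spearman rho with a two-sided p-value. Large-sample t approximation on the
# ranks; exact permutation (full enumeration up to n = 8, otherwise sampled)
# for n below 15, where the t approximation is unreliable.
spearman_test <- function(x, y, n_perm = 2000) {
  ok <- is.finite(x) & is.finite(y)
  n <- sum(ok)
  if (n < 4) return(c(rho = NA_real_, p = NA_real_, n = n))
  rx <- rank(x[ok]); ry <- rank(y[ok])
  rho <- cor(rx, ry)
  if (n >= 15) {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, 1e-12))
    p <- 2 * pt(-abs(tt), df = n - 2)
  } else if (n <= 8) {
    perms <- asplit(permutations_of(n), 1)
    null_rho <- vapply(perms, function(pp) cor(rx, ry[pp]), numeric(1))
    p <- mean(abs(null_rho) >= abs(rho) - 1e-12)
  } else {
    null_rho <- vapply(seq_len(n_perm),
                       function(i) cor(rx, sample(ry)), numeric(1))
    p <- (sum(abs(null_rho) >= abs(rho) - 1e-12) + 1) / (n_perm + 1)
  }
  c(rho = rho, p = min(p, 1), n = n)
}

# All permutations of 1:n as an n! x n matrix (used only for tiny n).
permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' Spearman correlation map between a seasonal index and a seasonal grid
#'
#' At every grid cell, the (linearly detrended) cell series and the
#' (linearly detrended) index series are correlated by Spearman's rank
#' correlation over their common years, with a two-sided p-value and a
#' significance flag at `alpha`. Cells with fewer than `min_years`
#' overlapping years are reported as missing.
#'
#' @param index Tibble with `year`, `value` (a seasonal index series).
#' @param grid Seasonal grid from [seasonal_grid_aggregate()].
#' @param alpha Significance level for the `significant` flag (default
#'   0.05; the choice of level for map dots is a convention, not a given).
#' @param min_years Minimum overlapping years per cell (default 10).
#' @param detrend Linearly detrend both series first (default TRUE).
#' @return Tibble with columns `lat`, `lon`, `rho`, `p`, `n`, `significant`.
#' @export
spearman_map <- function(index, grid, alpha = 0.05, min_years = 10,
                         detrend = TRUE) {
  idx <- index
  if (detrend) idx$value <- detrend_linear(idx$value, idx$year)
  grid %>%
    group_by(.data$lat, .data$lon) %>%
    dplyr::group_modify(function(cell, key) {
      common <- intersect(cell$year[is.finite(cell$value)],
                          idx$year[is.finite(idx$value)])
      if (length(common) < min_years) {
        return(tibble(rho = NA_real_, p = NA_real_, n = length(common)))
      }
      gv <- cell$value[match(common, cell$year)]
      iv <- idx$value[match(common, idx$year)]
      if (detrend) gv <- detrend_linear(gv, common)
      st <- spearman_test(gv, iv)
      tibble(rho = st[["rho"]], p = st[["p"]], n = as.integer(st[["n"]]))
    }) %>%
    ungroup() %>%
    mutate(significant = !is.na(.data$p) & .data$p < alpha)
}
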