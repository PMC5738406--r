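#' Variance-stabilizing arcsine transform for unit-interval series
#'
#' Applies `asin(sqrt(y))`, the classical variance-stabilizing transform for
#' proportions, used here to reduce non-normality of the rescaled masting
#' index before wavelet analysis. Monotone on \[0, 1\], mapping 0 to 0 and
#' 1 to pi/2.
#'
#' @param y Numeric vector in \[0, 1\].
#' @return Transformed numeric vector.
#' @export
#' @examples
#' arcsine_transform(c(0, 0.5, 1))
arcsine_transform <- function(y) {
  if (any(y < 0 | y > 1, na.rm = TRUE)) {
    stop("arcsine_transform requires values in [0, 1]", call. = FALSE)
  }
  asin(sqrt(y))
}

# Fourier factor of the Morlet wavelet: period = fourier_factor * scale.
morlet_fourier_factor <- function(omega0 = 6) {
  (4 * pi) / (omega0 + sqrt(2 + omega0^2))
}

# Precomputed machinery for repeated transforms/coherences on series of a
# fixed length: wavelet daughters, time-smoothing Fourier multipliers and the
# scale-smoothing boxcar. Building this once and reusing it is what makes
# 500-surrogate Monte Carlo significance affordable.
cwt_engine <- function(n, dt = 1, dj = 1 / 12, s0 = 2 * dt, max_period = 32,
                       omega0 = 6) {
  if (n < 16) stop("series too short for wavelet analysis (need >= 16)", call. = FALSE)
  ff <- morlet_fourier_factor(omega0)
  npad <- 2^ceiling(log2(n))          # zero padding to the next power of two
  J <- ceiling(log2(max_period / (ff * s0)) / dj)
  scales <- s0 * 2^(dj * (0:J))
  periods <- ff * scales
  k <- c(0:(npad / 2), -((npad / 2 - 1):1))
  omega <- 2 * pi * k / (npad * dt)
  # Morlet daughters in Fourier space, one column per scale
  arg <- outer(omega, scales)
  daughters <- sqrt(2 * pi * rep(scales, each = npad) / dt) * pi^(-0.25) *
    exp(-0.5 * (arg - omega0)^2)
  dim(daughters) <- c(npad, J + 1L)
  daughters[omega <= 0, ] <- 0
  # time smoothing: Gaussian with sd = scale / sqrt(2) (the Morlet |psi|^2
  # footprint), as a Fourier multiplier per scale
  tsmooth <- exp(-0.25 * outer(omega^2, scales^2))
  # scale smoothing: boxcar of 0.6 octaves (0.6 / dj scale steps), edge
  # truncated and row-normalized; positive weights keep coherence in [0, 1]
  hw <- 0.6 / (2 * dj)
  off <- outer(0:J, 0:J, function(i, j) j - i)
  w <- pmax(pmin(off + 0.5, hw) - pmax(off - 0.5, -hw), 0)
  ksc <- w / rowSums(w)
  # cone of influence: maximum trustworthy period at each time point
  d_edge <- pmin(seq_len(n) - 1, n - seq_len(n))
  coi <- ff / sqrt(2) * dt * pmax(d_edge, 1e-8)
  list(n = n, dt = dt, dj = dj, npad = npad, omega0 = omega0,
       scales = scales, periods = periods, coi = coi,
       daughters = daughters, tsmooth = tsmooth, ksc = ksc)
}

# Continuous wavelet transform of a standardized series: n x nscale complex.
engine_cwt <- function(eng, x) {
  xs <- (x - mean(x)) / sd(x)
  xhat <- fft(c(xs, rep(0, eng$npad - eng$n)))
  W <- mvfft(eng$daughters * xhat, inverse = TRUE) / eng$npad
  W[seq_len(eng$n), , drop = FALSE]
}

# Scale-dependent smoothing used by wavelet coherence: Gaussian in time
# (via the padded Fourier domain) then boxcar across scales. The identical
# positive weights are applied to cross- and auto-spectra, so the smoothed
# coherence obeys the Cauchy-Schwarz bound by construction.
engine_smooth <- function(eng, field) {
  pad <- matrix(0 + 0i, eng$npad, ncol(field))
  pad[seq_len(eng$n), ] <- field
  sm <- mvfft(mvfft(pad) * eng$tsmooth, inverse = TRUE) / eng$npad
  sm <- sm[seq_len(eng$n), , drop = FALSE]
  sm %*% t(eng$ksc)
}

engine_coherence <- function(eng, x, y) {
  wx <- engine_cwt(eng, x)
  wy <- engine_cwt(eng, y)
  inv_s <- matrix(1 / eng$scales, eng$n, length(eng$scales), byrow = TRUE)
  sxx <- Re(engine_smooth(eng, Mod(wx)^2 * inv_s))
  syy <- Re(engine_smooth(eng, Mod(wy)^2 * inv_s))
  sxy <- engine_smooth(eng, wx * Conj(wy) * inv_s)
  r2 <- Mod(sxy)^2 / (sxx * syy)
  list(r2 = r2, phase = Arg(sxy))
}

# Mean coherence per scale over cells inside the cone of influence.
coi_scale_average <- function(eng, r2) {
  inside <- outer(eng$coi, eng$periods, `>=`)
  colSums(r2 * inside) / pmax(colSums(inside), 1e-300)
}

#' Morlet continuous wavelet transform
#'
#' FFT-based continuous wavelet transform with the Morlet mother wavelet
#' (omega0 = 6), dyadic scales `s0 * 2^(dj * j)` reaching at least
#' `max_period` years, and zero padding to the next power of two to limit
#' wraparound. The series is standardized (zero mean, unit variance)
#' internally. The Fourier period of each scale is about 1.033 times the
#' scale; the cone of influence uses the sqrt(2)-scale e-folding rule.
#'
#' @param data Tibble with `year` and a value column, annual steps.
#' @param value_col Value column name (default `"value"`).
#' @param dj Scale resolution in octaves (default 1/12).
#' @param s0 Smallest scale (default 2 years).
#' @param max_period Largest Fourier period to resolve (default 32 years).
#' @return An object of class `mast_cwt`: list with `years`, `periods`,
#'   `scales`, complex `coefficients` (time x scale), `power`, and `coi`
#'   (maximum trustworthy period per time point).
#' @export
cwt_morlet <- function(data, value_col = "value", dj = 1 / 12, s0 = 2,
                       max_period = 32) {
  check_year_column(data)
  x <- data[[value_col]]
  if (anyNA(x)) stop("wavelet analysis requires a gap-free series", call. = FALSE)
  if (sd(x) == 0) stop("cannot standardize a constant series", call. = FALSE)
  eng <- cwt_engine(length(x), dt = 1, dj = dj, s0 = s0, max_period = max_period)
  W <- engine_cwt(eng, x)
  structure(list(years = as.integer(data$year), periods = eng$periods,
                 scales = eng$scales, coefficients = W, power = Mod(W)^2,
                 coi = eng$coi, dj = dj, s0 = s0),
            class = "mast_cwt")
}

#' Wavelet coherence between two annual series
#'
#' Squared wavelet coherence in the Torrence-Webster / Grinsted convention:
#' the cross-wavelet spectrum and both auto-spectra are divided by scale,
#' smoothed in time by a scale-proportional Gaussian and across scales by a
#' 0.6-octave boxcar, and combined as
#' `r2 = |S(Wxy/s)|^2 / (S(|Wx|^2/s) * S(|Wy|^2/s))`. The identical
#' positive smoothing weights guarantee `0 <= r2 <= 1`. Phases come from the
#' argument of the smoothed cross-spectrum.
#'
#' Call [coherence_significance()] afterwards to attach Monte Carlo
#' p-values from AR(1) surrogates.
#'
#' @param x,y Tibbles with `year` and a value column, sharing the same years.
#' @param value_col Value column name in both inputs.
#' @inheritParams cwt_morlet
#' @return Object of class `mast_coherence`: list with `years`, `periods`,
#'   `r2` and `phase` matrices (time x scale), `coi`, and the inputs needed
#'   for surrogate significance.
#' @export
wavelet_coherence <- function(x, y, value_col = "value", dj = 1 / 12, s0 = 2,
                              max_period = 32) {
  check_year_column(x); check_year_column(y)
  if (nrow(x) != nrow(y) || !all(x$year == y$year)) {
    stop("x and y must share the same years", call. = FALSE)
  }
  xv <- x[[value_col]]; yv <- y[[value_col]]
  if (anyNA(xv) || anyNA(yv)) stop("coherence requires gap-free series", call. = FALSE)
  eng <- cwt_engine(length(xv), dt = 1, dj = dj, s0 = s0, max_period = max_period)
  coh <- engine_coherence(eng, xv, yv)
  r2 <- coh$r2
  if (any(r2 < -1e-8 | r2 > 1 + 1e-8)) {
    stop("coherence left [0, 1]; smoothing configuration is inconsistent")
  }
  r2 <- pmin(pmax(r2, 0), 1)
  structure(list(years = as.integer(x$year), periods = eng$periods, r2 = r2,
                 phase = coh$phase, coi = eng$coi, x = xv, y = yv,
                 engine = eng, pointwise_p = NULL, scale_avg = NULL,
                 n_surrogates = 0L, seed = NULL),
            class = "mast_coherence")
}

#' Generate AR(1) surrogate series matching a series' red-noise signature
#'
#' Estimates the lag-1 autocorrelation and variance of the input and draws
#' stationary Gaussian AR(1) series with the same length, lag-1
#' autocorrelation and marginal variance. These serve as the red-noise null
#' for coherence significance testing.
#'
#' @param x Numeric series (length >= 3).
#' @param n_surrogates Number of surrogate series (columns).
#' @param seed Integer seed; same seed gives identical surrogates.
#' @return Numeric matrix, `length(x)` rows by `n_surrogates` columns, with
#'   attribute `"rho"` (the estimated lag-1 autocorrelation).
#' @export
ar1_surrogates <- function(x, n_surrogates = 500, seed = NULL) {
  n <- length(x)
  rho <- acf_lag1(x)
  if (abs(rho) >= 1) stop("degenerate series: |lag-1 autocorrelation| >= 1",
                          call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  s2 <- var(x)
  out <- matrix(0, n, n_surrogates)
  out[1, ] <- rnorm(n_surrogates, 0, sqrt(s2))
  innov_sd <- sqrt(s2 * (1 - rho^2))
  for (t in 2:n) {
    out[t, ] <- rho * out[t - 1, ] + rnorm(n_surrogates, 0, innov_sd)
  }
  attr(out, "rho") <- rho
  out
}

#' Monte Carlo significance of wavelet coherence against AR(1) surrogates
#'
#' Draws independent AR(1) surrogate pairs matching the lag-1
#' autocorrelation and variance of each input series, recomputes coherence
#' for every pair, and attaches two p-value fields: a pointwise field
#' (fraction of surrogate pairs whose coherence at that cell is at least the
#' observed one, with the +1 rank correction) and a scale-averaged test in
#' which coherence is first averaged over time inside the cone of influence
#' at each scale. The scale-averaged test is reported only for periods above
#' `min_period` (default 5 years, the low-frequency domain). Coherence is
#' bounded in \[0, 1\] so exceedance p-values are the natural one-sided
#' summary; the conventional significance contour is drawn at alpha = 0.1.
#'
#' @param coh A `mast_coherence` object.
#' @param n_surrogates Number of surrogate pairs (default 500; minimum 20).
#' @param seed Integer seed for reproducibility.
#' @param min_period Smallest period (years) reported by the scale-averaged
#'   test.
#' @return The input object with `pointwise_p` (time x scale matrix) and
#'   `scale_avg` (tibble: `period`, `mean_r2`, `p`, `in_test_band`) filled.
#' @export
coherence_significance <- function(coh, n_surrogates = 500, seed = NULL,
                                   min_period = 5) {
  stopifnot(inherits(coh, "mast_coherence"))
  if (n_surrogates < 20) stop("need at least 20 surrogates", call. = FALSE)
  eng <- coh$engine
  if (!is.null(seed)) set.seed(seed)
  sx <- ar1_surrogates(coh$x, n_surrogates)
  sy <- ar1_surrogates(coh$y, n_surrogates)
  obs_avg <- coi_scale_average(eng, coh$r2)
  exceed_point <- matrix(0, nrow(coh$r2), ncol(coh$r2))
  exceed_avg <- numeric(length(eng$periods))
  for (i in seq_len(n_surrogates)) {
    r2s <- engine_coherence(eng, sx[, i], sy[, i])$r2
    exceed_point <- exceed_point + (r2s >= coh$r2)
    exceed_avg <- exceed_avg + (coi_scale_average(eng, r2s) >= obs_avg)
  }
  coh$pointwise_p <- (exceed_point + 1) / (n_surrogates + 1)
  scale_p <- (exceed_avg + 1) / (n_surrogates + 1)
  in_band <- eng$periods > min_period & eng$periods <= max(eng$coi)
  coh$scale_avg <- tibble(period = eng$periods, mean_r2 = obs_avg,
                          p = scale_p, in_test_band = in_band)
  coh$n_surrogates <- as.integer(n_surrogates)
  coh$seed <- seed
  coh
}

#' Midpoint of the significant low-frequency coherence band
#'
#' Summarizes one or several significance-tested coherence analyses into a
#' single smoother span: within each analysis, the scales whose
#' scale-averaged p-value falls below `alpha` (inside the tested band) form
#' a period band whose midpoint `(min + max) / 2` is taken; midpoints are
#' averaged across analyses, and the result is rounded to the nearest odd
#' integer (`2 * floor(x / 2) + 1`) so it can serve directly as a centred
#' running-line span. A band spanning periods 7-16 years yields 11.
#'
#' @param coh A `mast_coherence` object with significance attached, or a
#'   list of them.
#' @param alpha Significance level (default 0.1).
#' @param default_span Span returned (with a warning) when no scale is
#'   significant in any analysis.
#' @param round_to_odd Round the result to the nearest odd integer
#'   (default TRUE).
#' @return Span in years (numeric scalar).
#' @export
mean_significant_period <- function(coh, alpha = 0.1, default_span = 11,
                                    round_to_odd = TRUE) {
  cohs <- if (inherits(coh, "mast_coherence")) list(coh) else coh
  mids <- purrr::map_dbl(cohs, function(cc) {
    sa <- cc$scale_avg
    if (is.null(sa)) stop("run coherence_significance() first", call. = FALSE)
    sig <- sa$period[sa$in_test_band & sa$p < alpha]
    if (length(sig) == 0) return(NA_real_)
    (min(sig) + max(sig)) / 2
  })
  if (all(is.na(mids))) {
    warning("no significant coherence band; using default span of ",
            default_span, " years")
    return(default_span)
  }
  span <- mean(mids, na.rm = TRUE)
  if (round_to_odd) span <- 2 * floor(span / 2) + 1
  span
}

#' Export a coherence field as a tidy long table
#'
#' @param x A `mast_coherence` object.
#' @param ... Unused.
#' @return Tibble with columns `year`, `period`, `r2`, `phase`,
#'   `pointwise_p` (NA when significance has not been run) and `in_coi`.
#' @method tidy mast_coherence
#' @export
tidy.mast_coherence <- function(x, ...) {
  grid <- tidyr::expand_grid(period = x$periods, year = x$years) %>%
    arrange(.data$year, .data$period)
  np <- length(x$periods)
  grid %>%
    mutate(
      r2 = as.vector(t(x$r2)),
      phase = as.vector(t(x$phase)),
      pointwise_p = if (is.null(x$pointwise_p)) NA_real_ else
        as.vector(t(x$pointwise_p)),
      in_coi = .data$period <= rep(x$coi, each = np)
    )
}
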