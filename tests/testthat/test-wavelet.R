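test_that("arcsine transform matches its closed form and rejects bad input", {
  expect_equal(arcsine_transform(c(0, 0.5, 1)), c(0, pi / 4, pi / 2))
  expect_error(arcsine_transform(c(0.2, 1.2)), "requires values")
  y <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(arcsine_transform(y)) > 0))  # monotone
})

test_that("CWT locates a pure sinusoid at its analytic period", {
  t <- 1:128
  dat <- tibble::tibble(year = t, value = sin(2 * pi * t / 8))
  w <- cwt_morlet(dat)
  inside <- outer(w$coi, w$periods, `>=`)
  avg_power <- colSums(w$power * inside) / pmax(colSums(inside), 1)
  peak_period <- w$periods[which.max(avg_power)]
  dj_step <- 2^(1 / 12)
  expect_lt(abs(log(peak_period / 8)), log(dj_step) * 1.5)
  expect_error(cwt_morlet(tibble::tibble(year = t, value = 1)), "constant")
})

test_that("white-noise wavelet power is flat across well-sampled scales", {
  set.seed(21)
  n <- 128
  reps <- 200
  acc <- NULL
  for (i in seq_len(reps)) {
    w <- cwt_morlet(tibble::tibble(year = 1:n, value = rnorm(n)))
    inside <- outer(w$coi, w$periods, `>=`)
    avg <- colSums(w$power * inside) / pmax(colSums(inside), 1)
    acc <- if (is.null(acc)) avg else acc + avg
  }
  avg_power <- acc / reps
  # periods at the Nyquist limit are biased low by discretization; flatness
  # holds on the resolved, well-sampled scales
  well_sampled <- w$periods >= 3 & w$periods <= n / 4
  rel <- avg_power[well_sampled] / mean(avg_power[well_sampled])
  expect_lt(max(abs(rel - 1)), 0.15)
})

test_that("self-coherence is 1 inside the cone of influence", {
  set.seed(31)
  x <- tibble::tibble(year = 1:66, value = rnorm(66))
  coh <- wavelet_coherence(x, x)
  expect_gte(min(coh$r2[coi_mask(coh)]), 0.99)
})

test_that("coherence is symmetric and bounded", {
  set.seed(32)
  x <- tibble::tibble(year = 1:66, value = rnorm(66))
  y <- tibble::tibble(year = 1:66, value = rnorm(66))
  cxy <- wavelet_coherence(x, y)
  cyx <- wavelet_coherence(y, x)
  expect_lt(max(abs(cxy$r2 - cyx$r2)), 1e-10)
  expect_true(all(cxy$r2 >= 0 & cxy$r2 <= 1))
})

test_that("coherence away from edges is insensitive to a common time shift", {
  set.seed(33)
  n_full <- 90
  base <- sin(2 * pi * (1:n_full) / 6) + rnorm(n_full, 0, 0.5)
  other <- sin(2 * pi * (1:n_full) / 6 + 1) + rnorm(n_full, 0, 0.5)
  win1 <- 1:66; win2 <- 13:78
  c1 <- wavelet_coherence(tibble::tibble(year = win1, value = base[win1]),
                          tibble::tibble(year = win1, value = other[win1]))
  c2 <- wavelet_coherence(tibble::tibble(year = win2, value = base[win2]),
                          tibble::tibble(year = win2, value = other[win2]))
  # common interior time points, short periods, deep inside both cones
  small <- which(c1$periods <= 8)
  overlap1 <- 25:54        # positions in window 1
  overlap2 <- overlap1 - 12
  d <- abs(c1$r2[overlap1, small] - c2$r2[overlap2, small])
  expect_lt(stats::median(d), 0.05)
  expect_lt(max(d), 0.25)
})

test_that("AR(1) surrogates reproduce the target autocorrelation", {
  set.seed(41)
  white <- rnorm(300)
  s <- ar1_surrogates(white, 200, seed = 1)
  rhos <- apply(s, 2, mastnao:::acf_lag1)
  expect_lt(abs(mean(rhos)), 0.05)

  red <- as.numeric(stats::arima.sim(list(ar = 0.6), 500))
  rho_hat <- mastnao:::acf_lag1(red)
  expect_lt(abs(rho_hat - 0.6), 0.1)
  s2 <- ar1_surrogates(red, 200, seed = 2)
  # surrogates are built to match the estimated, not the generating, rho
  expect_lt(abs(mean(apply(s2, 2, mastnao:::acf_lag1)) - rho_hat), 0.05)

  expect_identical(ar1_surrogates(red, 10, seed = 5),
                   ar1_surrogates(red, 10, seed = 5))
})

test_that("pointwise p-values follow the +1 rank convention", {
  set.seed(51)
  x <- tibble::tibble(year = 1:66, value = rnorm(66))
  y <- tibble::tibble(year = 1:66, value = rnorm(66))
  coh <- coherence_significance(wavelet_coherence(x, y), n_surrogates = 25,
                                seed = 3)
  p <- coh$pointwise_p
  expect_true(all(p >= 1 / 26 & p <= 1))
  # every p is a multiple of 1/(n_surrogates + 1)
  expect_true(all(abs(p * 26 - round(p * 26)) < 1e-9))
  expect_error(coherence_significance(wavelet_coherence(x, y), 10), "at least 20")
})

test_that("the significant-band midpoint produces the smoother span", {
  fake_coh <- function(periods, p) {
    structure(list(scale_avg = tibble::tibble(
      period = periods, mean_r2 = 0.5, p = p,
      in_test_band = periods > 5
    )), class = "mast_coherence")
  }
  periods <- seq(2, 32, by = 0.5)
  p <- rep(0.5, length(periods))
  p[periods >= 7 & periods <= 16] <- 0.01
  expect_equal(mean_significant_period(fake_coh(periods, p)), 11)  # 11.5 -> 11
  p2 <- rep(0.5, length(periods)); p2[periods == 9] <- 0.01
  expect_equal(mean_significant_period(fake_coh(periods, p2)), 9)
  expect_warning(sp <- mean_significant_period(fake_coh(periods, rep(0.5, length(periods)))),
                 "default span")
  expect_equal(sp, 11)
})

test_that("tidy export carries the field cell-for-cell", {
  set.seed(61)
  x <- tibble::tibble(year = 1:66, value = rnorm(66))
  y <- tibble::tibble(year = 1:66, value = rnorm(66))
  coh <- wavelet_coherence(x, y)
  td <- tidy(coh)
  expect_equal(nrow(td), length(coh$years) * length(coh$periods))
  i <- 40; j <- 17
  row <- td[td$year == coh$years[i] & abs(td$period - coh$periods[j]) < 1e-12, ]
  expect_equal(row$r2, coh$r2[i, j])
  expect_equal(row$in_coi, coh$periods[j] <= coh$coi[i])
})
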