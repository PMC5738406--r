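#' Configuration for the synthetic masting study generator
#'
#' Bundles every generating parameter of the synthetic study: a monthly
#' teleconnection-like index (AR(1) noise plus a decadal sinusoid injected
#' into one target season) and region-level ordinal masting records whose
#' continental aggregate is driven by lagged high/low-frequency index
#' components through a beta-distributed latent process with a negative
#' lag-1 autoregression.
#'
#' The defaults mirror the structure of the continental beech analysis:
#' a 64-year study window, 40 regions with 8 series each, near-white
#' monthly noise, an 11-year decadal cycle in the winter months, and
#' generating coefficients with the magnitudes and signs of the published
#' final beech model (negative effect of the high-frequency summer index
#' two years back, positive effects of high-frequency winter/summer one
#' year back and same-year spring, positive low-frequency winter effect,
#' negative lag-1 autoregression).
#'
#' @param n_years Number of masting years (>= 20).
#' @param n_regions Number of regions.
#' @param series_per_region Observation series per region.
#' @param start_year First masting year (calendar label only).
#' @param ar1_noise AR(1) coefficient of the monthly noise, in (-1, 1).
#' @param noise_sd Innovation standard deviation of the monthly noise
#'   (index units); 0 switches the noise off.
#' @param decadal_period Period of the decadal sinusoid in years (> 2).
#' @param decadal_amplitude Amplitude of the decadal sinusoid (index units).
#' @param decadal_target_season Season whose months receive the sinusoid:
#'   `"DJFM"` (default), `"AM"`, `"JJAS"` or `"all"`.
#' @param beta_coefficients Named list of generating coefficients on the
#'   logit scale: `intercept`, any of `high_summer_Ym2`, `high_winter_Ym1`,
#'   `high_summer_Ym1`, `high_spring_Ym`, `low_winter`, `low_summer`,
#'   `low_spring`, `ar1_term`, and optionally the interaction
#'   `"low_winter:high_summer_Ym1"`.
#' @param precision_phi Beta-distribution precision (> 0).
#' @param class_noise_sd SD of the Gaussian perturbation applied before
#'   rounding the latent index to ordinal classes (class units).
#' @param species Species label written into the records.
#' @param seed Integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_years = 64, n_regions = 40, series_per_region = 8,
                       start_year = 1952, ar1_noise = 0.15, noise_sd = 1,
                       decadal_period = 11, decadal_amplitude = 1,
                       decadal_target_season = "DJFM",
                       beta_coefficients = list(
                         intercept = 0,
                         high_summer_Ym2 = -0.500,
                         high_winter_Ym1 = 0.174,
                         high_summer_Ym1 = 0.373,
                         high_spring_Ym = 0.514,
                         low_winter = 0.402,
                         ar1_term = -0.633
                       ),
                       precision_phi = 50, class_noise_sd = 0.5,
                       species = "synthetic_beech", seed = 1L) {
  cfg <- list(n_years = as.integer(n_years), n_regions = as.integer(n_regions),
              series_per_region = as.integer(series_per_region),
              start_year = as.integer(start_year), ar1_noise = ar1_noise,
              noise_sd = noise_sd, decadal_period = decadal_period,
              decadal_amplitude = decadal_amplitude,
              decadal_target_season = decadal_target_season,
              beta_coefficients = beta_coefficients,
              precision_phi = precision_phi, class_noise_sd = class_noise_sd,
              species = species, seed = as.integer(seed))
  num <- unlist(cfg[c("n_years", "n_regions", "series_per_region", "ar1_noise",
                      "noise_sd", "decadal_period", "decadal_amplitude",
                      "precision_phi", "class_noise_sd", "seed")])
  if (any(!is.finite(num))) stop("non-finite configuration value", call. = FALSE)
  if (any(!is.finite(unlist(beta_coefficients)))) {
    stop("non-finite generating coefficient", call. = FALSE)
  }
  if (cfg$n_years < 20) stop("n_years must be at least 20", call. = FALSE)
  if (cfg$precision_phi <= 0) stop("precision_phi must be positive", call. = FALSE)
  if (cfg$decadal_period <= 2) stop("decadal_period must exceed 2", call. = FALSE)
  if (abs(cfg$ar1_noise) >= 1) stop("ar1_noise must lie in (-1, 1)", call. = FALSE)
  structure(cfg, class = "sim_config")
}

#' Simulate a monthly teleconnection-like index series
#'
#' Each monthly value is the sum of a decadal sinusoid (amplitude applied
#' only in the months of the target season, or everywhere for `"all"`) and
#' stationary AR(1) Gaussian noise. The series covers the masting window
#' plus a three-year lead so that all lagged seasonal predictors (back to
#' the summer two years before the first masting year, including the
#' December needed by the preceding winter) can be built from it.
#'
#' @param config A [sim_config()].
#' @return Tibble with columns `year`, `month`, `value`; identical output
#'   for identical seeds.
#' @export
simulate_monthly_index <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  years <- (config$start_year - 3L):(config$start_year + config$n_years - 1L)
  grid <- tidyr::expand_grid(year = years, month = 1:12)
  tcont <- grid$year + (grid$month - 0.5) / 12
  target_months <- if (identical(config$decadal_target_season, "all")) 1:12 else
    season_months(config$decadal_target_season)$months
  decadal <- config$decadal_amplitude *
    sin(2 * pi * tcont / config$decadal_period) *
    (grid$month %in% target_months)
  set.seed(config$seed)
  n <- nrow(grid)
  rho <- config$ar1_noise
  noise <- numeric(n)
  if (config$noise_sd > 0) {
    noise[1] <- rnorm(1, 0, config$noise_sd / sqrt(1 - rho^2))
    eps <- rnorm(n - 1, 0, config$noise_sd)
    for (t in 2:n) noise[t] <- rho * noise[t - 1] + eps[t - 1]
  }
  tibble(year = grid$year, month = grid$month, value = decadal + noise)
}

#' Build the lag-aligned high/low-frequency NAO predictor table
#'
#' The shared predictor construction used by both the generator and the
#' analysis pipeline: each seasonal series (winter DJFM, spring AM, summer
#' JJAS) is decomposed once into low- and high-frequency parts at the given
#' span, then lag-aligned to the masting years at the season's model lag
#' (winter and summer at the year before fruit ripening, spring at the mast
#' year, plus the summer high-frequency component two years back).
#'
#' @param monthly Tibble with `year`, `month`, `value`.
#' @param years Masting years to cover.
#' @param span_years Running-line span for the decomposition (years).
#' @return Tibble with columns `year`, `high_summer_Ym2`, `high_winter_Ym1`,
#'   `high_summer_Ym1`, `high_spring_Ym`, `low_winter`, `low_summer`,
#'   `low_spring`.
#' @export
nao_component_table <- function(monthly, years, span_years = 11) {
  comp_of <- function(season) {
    sa <- seasonal_aggregate(monthly, season)
    sa <- sa[!is.na(sa$value), , drop = FALSE]
    split_frequencies(sa, span_years)
  }
  winter <- comp_of("DJFM")
  spring <- comp_of("AM")
  summer <- comp_of("JJAS")
  pick <- function(fc, col, lag) {
    ser <- tibble(year = fc$year, value = fc[[col]])
    lag_align(ser, lag, years)$value
  }
  tibble(
    year = as.integer(years),
    high_summer_Ym2 = pick(summer, "high", -2L),
    high_winter_Ym1 = pick(winter, "high", -1L),
    high_summer_Ym1 = pick(summer, "high", -1L),
    high_spring_Ym  = pick(spring, "high", 0L),
    low_winter      = pick(winter, "low", -1L),
    low_summer      = pick(summer, "low", -1L),
    low_spring      = pick(spring, "low", 0L)
  )
}

#' Simulate region-level ordinal masting records from a monthly index
#'
#' Builds the lag-aligned high/low-frequency components of the supplied
#' monthly index ([nao_component_table()], span = the configured decadal
#' period), standardizes them over the masting years, and drives a latent
#' beta process: `eta_t` is the linear combination of the components under
#' the generating coefficients plus the autoregressive term applied to the
#' previous year's latent index expressed on the \[-1, 1\] masting-index
#' scale (`4 * (M_{t-1} - 0.5)`, so the AR coefficient is comparable in
#' magnitude to the standardized component coefficients);
#' `mu_t = logistic(eta_t)`; `M_t ~ Beta(mu_t * phi, (1 - mu_t) * phi)`.
#' Every region series then observes the same continental latent state
#' through an ordinal filter:
#' `class = clamp(round(1 + 4 * M_t + N(0, class_noise_sd)), 1, 5)`.
#'
#' @param nao Monthly index tibble covering the masting years plus the
#'   lags (from [simulate_monthly_index()], or any compatible table).
#' @param config A [sim_config()].
#' @return A list with `records` (tibble: `series_id`, `region`, `species`,
#'   `year`, `ord_class`, `proxy`) and `truth` (list: `years`, `mu`,
#'   `m_latent`, `ar_series`, `components` with standardized predictor
#'   columns, `config`).
#' @export
simulate_masting_records <- function(nao, config) {
  stopifnot(inherits(config, "sim_config"))
  years <- config$start_year:(config$start_year + config$n_years - 1L)
  span <- 2 * floor(config$decadal_period / 2) + 1
  comps <- tryCatch(
    nao_component_table(nao, years, span_years = span),
    error = function(e) stop("monthly index does not cover the lag window: ",
                             conditionMessage(e), call. = FALSE))
  comp_names <- setdiff(names(comps), "year")
  zcomp <- comps
  for (cl in comp_names) {
    zcomp[[cl]] <- (comps[[cl]] - mean(comps[[cl]])) / sd(comps[[cl]])
  }
  bc <- config$beta_coefficients
  unknown <- setdiff(names(bc),
                     c("intercept", "ar1_term", comp_names,
                       "low_winter:high_summer_Ym1"))
  if (length(unknown) > 0) {
    stop("unknown generating coefficient(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  coef_of <- function(nm) if (is.null(bc[[nm]])) 0 else bc[[nm]]
  base_eta <- rep(coef_of("intercept"), config$n_years)
  for (cl in comp_names) base_eta <- base_eta + coef_of(cl) * zcomp[[cl]]
  if (!is.null(bc[["low_winter:high_summer_Ym1"]])) {
    base_eta <- base_eta + bc[["low_winter:high_summer_Ym1"]] *
      zcomp$low_winter * zcomp$high_summer_Ym1
  }
  set.seed(config$seed + 1L)
  phi <- config$precision_phi
  m_latent <- mu <- ar_series <- numeric(config$n_years)
  m_prev <- 0.5
  for (t in seq_len(config$n_years)) {
    ar_series[t] <- 4 * (m_prev - 0.5)
    eta <- base_eta[t] + coef_of("ar1_term") * ar_series[t]
    mu[t] <- plogis(eta)
    m_latent[t] <- min(max(rbeta(1, mu[t] * phi, (1 - mu[t]) * phi),
                           1e-12), 1 - 1e-12)
    m_prev <- m_latent[t]
  }
  n_series <- config$n_regions * config$series_per_region
  obs_noise <- matrix(rnorm(n_series * config$n_years, 0,
                            config$class_noise_sd),
                      nrow = config$n_years)
  classes <- round(1 + 4 * m_latent + obs_noise)
  classes <- pmin(pmax(classes, 1), 5)
  ids <- tidyr::expand_grid(region = seq_len(config$n_regions),
                            series = seq_len(config$series_per_region))
  records <- tidyr::expand_grid(
    idx = seq_len(n_series), year_i = seq_len(config$n_years)
  ) %>%
    mutate(
      series_id = sprintf("R%02d_S%02d", ids$region[.data$idx],
                          ids$series[.data$idx]),
      region = sprintf("R%02d", ids$region[.data$idx]),
      species = config$species,
      year = years[.data$year_i],
      ord_class = as.integer(classes[cbind(.data$year_i, .data$idx)]),
      proxy = "seed"
    ) %>%
    select("series_id", "region", "species", "year", "ord_class", "proxy") %>%
    arrange(.data$series_id, .data$year)
  truth <- list(years = years, mu = mu, m_latent = m_latent,
                ar_series = ar_series, components = zcomp, config = config)
  list(records = records, truth = truth)
}

#' Simulate a complete synthetic masting study
#'
#' Convenience wrapper: generates the monthly index and the masting records
#' in one call.
#'
#' @param config A [sim_config()].
#' @return List with `nao` (monthly tibble), `records` and `truth`.
#' @export
simulate_mast_study <- function(config = sim_config()) {
  nao <- simulate_monthly_index(config)
  rec <- simulate_masting_records(nao, config)
  list(nao = nao, records = rec$records, truth = rec$truth)
}

#' Write a synthetic study to fixture files
#'
#' Writes the record table as a MASTREE-dialect CSV and the monthly index
#' as a year-by-12-months whitespace table, such that both round-trip
#' losslessly through [read_mast_records()] and [read_monthly_index()].
#'
#' @param records Record tibble.
#' @param nao Monthly index tibble.
#' @param dir Output directory (created if needed).
#' @return Named list of file paths (`records`, `monthly`), invisibly.
#' @export
write_fixture_bundle <- function(records, nao, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rec_path <- file.path(dir, "mast_records.csv")
  mon_path <- file.path(dir, "monthly_index.txt")
  dialect <- mastree_dialect()
  out <- records
  names(out) <- unname(dialect[names(records)])
  readr::write_csv(out, rec_path, progress = FALSE)
  write_monthly_index(nao, mon_path)
  invisible(list(records = rec_path, monthly = mon_path))
}
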