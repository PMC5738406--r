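# Shared fixture builders and independent oracles.

# Random ordinal record tables spread over regions/series/years.
random_records <- function(n_regions, n_series, years, p_obs = 0.8) {
  grid <- tidyr::expand_grid(
    region = sprintf("R%02d", seq_len(n_regions)),
    series = seq_len(n_series),
    year = years
  )
  grid <- grid[stats::runif(nrow(grid)) < p_obs, , drop = FALSE]
  tibble::tibble(
    series_id = paste0(grid$region, "_S", grid$series),
    region = grid$region,
    species = "sp",
    year = grid$year,
    ord_class = sample(1:5, nrow(grid), replace = TRUE),
    proxy = "seed"
  )
}

# Brute-force masting-index oracle: explicit counting loops, no shared code
# with compute_m_index()/aggregate_modal().
oracle_m_index <- function(records, years) {
  sapply(years, function(y) {
    sub <- records[records$year == y, ]
    if (nrow(sub) == 0) return(NA_real_)
    regions <- unique(sub$region)
    n45 <- n12 <- 0
    for (r in regions) {
      cls <- sub$ord_class[sub$region == r]
      counts <- sapply(1:5, function(k) sum(cls == k))
      mode_cls <- which(counts == max(counts))[1]
      if (mode_cls >= 4) n45 <- n45 + 1
      if (mode_cls <= 2) n12 <- n12 + 1
    }
    n45 / length(regions) - n12 / length(regions)
  })
}

# Direct beta-response simulator on the latent scale (no ordinal layer).
simulate_beta_response <- function(n, beta, phi, intercept = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  k <- length(beta)
  nm <- if (is.null(names(beta))) paste0("x", seq_len(k)) else names(beta)
  X <- matrix(rnorm(n * k), n, k, dimnames = list(NULL, nm))
  X <- scale(X)[, , drop = FALSE]
  eta <- intercept + drop(X %*% beta)
  mu <- stats::plogis(eta)
  y <- stats::rbeta(n, mu * phi, (1 - mu) * phi)
  y <- pmin(pmax(y, 1e-10), 1 - 1e-10)
  out <- tibble::as_tibble(as.data.frame(X))
  out$y <- y
  out
}

# Fraction of coherence cells inside the cone of influence, per scale.
coi_mask <- function(coh) outer(coh$coi, coh$periods, `>=`)
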