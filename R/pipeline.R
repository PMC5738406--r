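#' Run the full masting-NAO analysis pipeline
#'
#' Orchestrates the complete analysis from a single configuration:
#' record ingestion (or simulation) -> masting index -> unit-interval
#' rescaling -> wavelet coherence of the arcsine-transformed index against
#' each raw seasonal NAO series (with AR(1) Monte Carlo significance) ->
#' smoother span from the mean significant low-frequency band -> frequency
#' decomposition -> standardized predictors -> maximum-likelihood beta
#' regression (optionally with residual-screened interactions) ->
#' leave-one-out cross-validation. Every stochastic stage is seeded, so a
#' fixed seed reproduces the run exactly; any stage failure aborts with a
#' stage-tagged message.
#'
#' @param config Either a list or the path to a YAML file. Recognized
#'   entries:
#'   \describe{
#'     \item{simulate}{List of [sim_config()] arguments; mutually exclusive
#'       with `records_path`/`monthly_path`.}
#'     \item{records_path, monthly_path}{Input files read with
#'       [read_mast_records()] / [read_monthly_index()].}
#'     \item{max_year, excluded_proxies, region_whitelist}{Record filters,
#'       see [filter_mast_records()].}
#'     \item{fit_window}{Length-2 vector of first and last masting year;
#'       default: all years with an index value.}
#'     \item{min_regions}{Minimum regions per year for the index.}
#'     \item{predictors}{Predictor columns for the model; default the five
#'       components with generating support plus the AR1 term.}
#'     \item{span}{Smoother span override in years; if absent the span
#'       comes from the coherence stage.}
#'     \item{surrogates}{Monte Carlo surrogate count (default 500).}
#'     \item{alpha}{Significance level of the coherence band (default 0.1).}
#'     \item{screen_interactions}{Screen and add two-way interactions
#'       (default FALSE).}
#'     \item{allow_collinear}{Override the collinearity gate (default
#'       FALSE).}
#'     \item{seed}{Integer seed, required when any stochastic stage runs.}
#'     \item{out_dir}{If set, stage outputs and a run manifest are written
#'       there as plain files.}
#'   }
#' @return A list of class `mast_pipeline` with elements `m_index`,
#'   `model_table`, `coherence` (list per season), `span`, `components`,
#'   `fit`, `interactions`, `loocv`, `config` and `manifest`.
#' @export
run_masting_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("[stage ", name, "] ", conditionMessage(e), call. = FALSE)
    })
  }
  seed <- config$seed
  if (is.null(seed)) stop("config$seed is required", call. = FALSE)

  # --- ingest -------------------------------------------------------------
  dat <- stage("ingest", {
    if (!is.null(config$simulate)) {
      sim_args <- config$simulate
      sim_args$seed <- sim_args$seed %||% seed
      study <- simulate_mast_study(do.call(sim_config, sim_args))
      list(records = study$records, monthly = study$nao, truth = study$truth)
    } else {
      if (is.null(config$records_path) || is.null(config$monthly_path)) {
        stop("provide either a simulate block or records_path + monthly_path")
      }
      list(records = read_mast_records(config$records_path),
           monthly = read_monthly_index(config$monthly_path), truth = NULL)
    }
  })

  # --- masting index ------------------------------------------------------
  m_index <- stage("masting_index", {
    recs <- filter_mast_records(
      dat$records,
      max_year = config$max_year %||% Inf,
      excluded_proxies = config$excluded_proxies %||% character(),
      region_whitelist = config$region_whitelist
    )
    if (nrow(recs) == 0) stop("no records survive filtering")
    compute_m_index(aggregate_modal(recs),
                    min_regions = config$min_regions %||% 1L)
  })
  window <- stage("masting_index", {
    w <- config$fit_window %||% range(m_index$year[!is.na(m_index$m)])
    yrs <- w[1]:w[2]
    if (!all(yrs %in% m_index$year[!is.na(m_index$m)])) {
      stop("masting index has missing years inside the fit window ",
           w[1], ":", w[2])
    }
    yrs
  })
  response <- stage("masting_index", {
    mw <- m_index[match(window, m_index$year), ]
    y <- rescale_unit(mw$m)
    tibble(year = window, m = mw$m, y = as.numeric(y)) %>%
      mutate(index_n = attr(y, "n"))
  })

  # --- wavelet coherence --------------------------------------------------
  seasons <- c(winter = "DJFM", spring = "AM", summer = "JJAS")
  season_lag <- c(winter = -1L, spring = 0L, summer = -1L)
  surrogates <- config$surrogates %||% 500L
  alpha <- config$alpha %||% 0.1
  coherence <- stage("coherence", {
    mast_series <- tibble(year = response$year,
                          value = arcsine_transform(response$y))
    purrr::imap(seasons, function(season, nm) {
      sa <- seasonal_aggregate(dat$monthly, season)
      sa <- sa[!is.na(sa$value), , drop = FALSE]
      nao_series <- lag_align(sa, season_lag[[nm]], response$year)
      coh <- wavelet_coherence(mast_series, nao_series)
      coherence_significance(coh, n_surrogates = surrogates,
                             seed = seed + match(nm, names(seasons)))
    })
  })
  span <- stage("span", {
    if (!is.null(config$span)) config$span else
      mean_significant_period(coherence, alpha = alpha)
  })

  # --- decomposition and model table --------------------------------------
  components <- stage("decompose", {
    nao_component_table(dat$monthly, response$year, span_years = span)
  })
  default_predictors <- c("high_summer_Ym2", "high_winter_Ym1",
                          "high_summer_Ym1", "high_spring_Ym", "low_winter",
                          "ar1_term")
  predictors <- config$predictors %||% default_predictors
  model_table <- stage("model_table", {
    tab <- dplyr::left_join(response, components, by = "year") %>%
      mutate(ar1_term = dplyr::lag(.data$y))
    tab <- tab[-1, , drop = FALSE]  # first year has no AR1 predecessor
    standardize_predictors(tab, cols = setdiff(names(tab),
                                               c("year", "m", "y", "index_n")))
  })

  # --- fit ----------------------------------------------------------------
  allow_collinear <- isTRUE(config$allow_collinear)
  fit0 <- stage("fit", {
    fit_beta_regression(model_table, "y", predictors,
                        allow_collinear = allow_collinear)
  })
  interactions <- NULL
  fit <- fit0
  if (isTRUE(config$screen_interactions)) {
    interactions <- stage("interactions", {
      screen_interactions(fit0,
                          candidates = utils::combn(
                            setdiff(predictors, "ar1_term"), 2,
                            simplify = FALSE))
    })
    selected <- dplyr::filter(interactions, .data$selected)
    if (nrow(selected) > 0) {
      fit <- stage("fit", {
        tab <- model_table
        for (i in seq_len(nrow(selected))) {
          tab <- add_interaction(tab, selected$term1[i], selected$term2[i])
        }
        fit_beta_regression(tab, "y", c(predictors, selected$interaction),
                            allow_collinear = TRUE)
      })
    }
  }

  # --- LOOCV --------------------------------------------------------------
  loocv <- stage("loocv", {
    loocv_beta(fit$data, "y", fit$predictors, allow_collinear = TRUE)
  })

  manifest <- list(
    package = as.character(utils::packageVersion("mastnao")),
    seed = seed, span = span, surrogates = surrogates,
    n_years_fit = fit$n, predictors = fit$predictors,
    config_hash = rlang::hash(config)
  )
  result <- structure(
    list(m_index = m_index, response = response, coherence = coherence,
         span = span, components = components, model_table = model_table,
         fit = fit, interactions = interactions, loocv = loocv,
         truth = dat$truth, config = config, manifest = manifest),
    class = "mast_pipeline")
  if (!is.null(config$out_dir)) write_pipeline_outputs(result, config$out_dir)
  result
}

# Persist every stage output as a plain file so stages can be inspected and
# re-run individually.
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_m_index(result$m_index, file.path(out_dir, "m_index.csv"))
  readr::write_csv(result$components, file.path(out_dir, "components.csv"),
                   progress = FALSE)
  purrr::iwalk(result$coherence, function(coh, nm) {
    readr::write_csv(tidy(coh), file.path(out_dir, paste0("coherence_", nm, ".csv")),
                     progress = FALSE)
    readr::write_csv(coh$scale_avg,
                     file.path(out_dir, paste0("coherence_", nm, "_scales.csv")),
                     progress = FALSE)
  })
  readr::write_csv(tidy(result$fit), file.path(out_dir, "coefficients.csv"),
                   progress = FALSE)
  readr::write_csv(result$loocv$predictions,
                   file.path(out_dir, "loocv_predictions.csv"), progress = FALSE)
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.mast_pipeline <- function(x, ...) {
  cat("Masting-NAO pipeline run\n")
  cat(sprintf("  fit window: %d-%d (%d years), span = %s yr, surrogates = %d\n",
              min(x$response$year), max(x$response$year), x$fit$n,
              format(x$span), x$manifest$surrogates))
  cat(sprintf("  pseudo-R2 = %.3f, AIC = %.2f, LOOCV r = %.3f\n",
              x$fit$pseudo_r2, x$fit$aic, x$loocv$pearson_r))
  invisible(x)
}
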