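#' Standardize predictor columns over a fit window
#'
#' Centres and scales each chosen column to mean 0, sd 1 over the rows
#' supplied, recording the transforms so they can be re-applied to new data
#' at prediction time.
#'
#' @param data Tibble of predictors (one row per year).
#' @param cols Character vector of columns to standardize (default: all
#'   numeric columns except `year`).
#' @return `data` with the chosen columns standardized and a
#'   `"standardization"` attribute (tibble: `term`, `center`, `scale`).
#' @export
standardize_predictors <- function(data, cols = NULL) {
  if (is.null(cols)) {
    cols <- setdiff(names(data)[vapply(data, is.numeric, logical(1))], "year")
  }
  transforms <- purrr::map_dfr(cols, function(cl) {
    x <- data[[cl]]
    mu <- mean(x, na.rm = TRUE)
    sg <- sd(x, na.rm = TRUE)
    if (!is.finite(sg) || sg == 0) {
      stop("cannot standardize constant column '", cl, "'", call. = FALSE)
    }
    tibble(term = cl, center = mu, scale = sg)
  })
  for (i in seq_len(nrow(transforms))) {
    cl <- transforms$term[i]
    data[[cl]] <- (data[[cl]] - transforms$center[i]) / transforms$scale[i]
  }
  attr(data, "standardization") <- transforms
  data
}

# Re-apply stored standardization transforms to new data.
apply_standardization <- function(data, transforms) {
  for (i in seq_len(nrow(transforms))) {
    cl <- transforms$term[i]
    if (cl %in% names(data)) {
      data[[cl]] <- (data[[cl]] - transforms$center[i]) / transforms$scale[i]
    }
  }
  data
}

#' Pairwise collinearity report for a predictor set
#'
#' Computes all pairwise Pearson correlations among predictors and flags
#' pairs at or above the threshold (|r| >= 0.4 by default, the conventional
#' gate for this analysis). [fit_beta_regression()] refuses to fit while
#' flagged pairs remain, unless overridden.
#'
#' @param data Tibble holding the predictor columns.
#' @param cols Predictor columns to check (default: all numeric except
#'   `year`).
#' @param threshold Absolute correlation at or above which a pair is flagged.
#' @return Tibble with columns `term1`, `term2`, `r`, `flagged`.
#' @export
collinearity_check <- function(data, cols = NULL, threshold = 0.4) {
  if (is.null(cols)) {
    cols <- setdiff(names(data)[vapply(data, is.numeric, logical(1))], "year")
  }
  if (length(cols) < 2) {
    return(tibble(term1 = character(), term2 = character(),
                  r = numeric(), flagged = logical()))
  }
  cm <- cor(as.matrix(data[cols]), use = "pairwise.complete.obs")
  pairs <- which(upper.tri(cm), arr.ind = TRUE)
  tibble(term1 = cols[pairs[, 1]], term2 = cols[pairs[, 2]],
         r = cm[pairs]) %>%
    mutate(flagged = abs(.data$r) >= threshold) %>%
    arrange(dplyr::desc(abs(.data$r)))
}

# Beta log-likelihood with logit mean link and constant precision phi.
# par = c(beta, log(phi)); X includes the intercept column.
beta_negll <- function(par, X, y) {
  k <- ncol(X)
  mu <- plogis(drop(X %*% par[seq_len(k)]))
  phi <- exp(par[k + 1L])
  -sum(lgamma(phi) - lgamma(mu * phi) - lgamma((1 - mu) * phi) +
         (mu * phi - 1) * log(y) + ((1 - mu) * phi - 1) * log1p(-y))
}

# Analytic score of the negative log-likelihood in (beta, log phi).
beta_negll_grad <- function(par, X, y) {
  k <- ncol(X)
  eta <- drop(X %*% par[seq_len(k)])
  mu <- plogis(eta)
  phi <- exp(par[k + 1L])
  ystar <- log(y) - log1p(-y)
  mustar <- digamma(mu * phi) - digamma((1 - mu) * phi)
  gbeta <- -phi * drop(crossprod(X, (ystar - mustar) * mu * (1 - mu)))
  gphi <- -sum(mu * (ystar - mustar) + log1p(-y) -
                 digamma((1 - mu) * phi) + digamma(phi)) * phi
  c(gbeta, gphi)
}

# Numerical Hessian of the negative log-likelihood in the natural
# parametrization (beta, phi), from central differences of the analytic
# score in (beta, log phi) mapped back.
beta_obs_info <- function(par, X, y) {
  k <- ncol(X) + 1L
  h <- pmax(abs(par), 1) * 1e-5
  H <- matrix(0, k, k)
  for (j in seq_len(k)) {
    up <- dn <- par
    up[j] <- up[j] + h[j]; dn[j] <- dn[j] - h[j]
    H[, j] <- (beta_negll_grad(up, X, y) - beta_negll_grad(dn, X, y)) / (2 * h[j])
  }
  (H + t(H)) / 2
}

#' Maximum-likelihood beta regression with logit mean link
#'
#' Fits the beta regression model `y_t ~ Beta(mu_t * phi, (1 - mu_t) * phi)`
#' with `mu_t = logistic(x_t' beta)` and constant precision `phi`, by
#' maximizing the exact beta log-likelihood (BFGS with analytic score,
#' followed by Newton polishing until the score is below 1e-8 in every
#' component). Standard errors come from the observed information;
#' `AIC = 2k - 2 logLik` with `k` counting the regression coefficients plus
#' the precision parameter. Before fitting, pairwise predictor collinearity
#' is checked ([collinearity_check()]); flagged pairs abort the fit unless
#' `allow_collinear = TRUE`. On convergence failure the optimizer is
#' restarted from up to 3 jittered starting points.
#'
#' @param data Tibble with the response and predictor columns (one row per
#'   year; a `year` column is carried through if present). Rows with any
#'   missing value are dropped with a message.
#' @param response Name of the response column; values must lie strictly
#'   inside (0, 1) (see [rescale_unit()]).
#' @param predictors Character vector of predictor column names; the
#'   intercept is always included.
#' @param allow_collinear Set TRUE to fit despite flagged predictor pairs.
#' @param collinearity_threshold Passed to [collinearity_check()].
#' @return An object of class `beta_fit`.
#' @export
fit_beta_regression <- function(data, response, predictors,
                                allow_collinear = FALSE,
                                collinearity_threshold = 0.4) {
  stopifnot(response %in% names(data), all(predictors %in% names(data)))
  std_transforms <- attr(data, "standardization")
  keep <- complete.cases(data[c(response, predictors)])
  if (any(!keep)) message(sum(!keep), " row(s) with missing values dropped")
  data <- data[keep, , drop = FALSE]
  y <- data[[response]]
  if (any(y <= 0 | y >= 1)) {
    stop("response must lie strictly inside (0, 1); use rescale_unit()",
         call. = FALSE)
  }
  if (length(predictors) >= 2) {
    coll <- collinearity_check(data, predictors,
                               threshold = collinearity_threshold)
    if (any(coll$flagged) && !allow_collinear) {
      bad <- dplyr::filter(coll, .data$flagged)
      stop("collinear predictor pair(s): ",
           paste0(bad$term1, "~", bad$term2, " (r=", round(bad$r, 2), ")",
                  collapse = ", "),
           "; resolve them or set allow_collinear = TRUE", call. = FALSE)
    }
  } else {
    coll <- collinearity_check(data, predictors)
  }
  X <- cbind(`(Intercept)` = 1, as.matrix(data[predictors]))
  k <- ncol(X)
  # starting values: OLS on the logit scale, moment estimate of phi
  z <- qlogis(y)
  beta0 <- tryCatch(coef(lm.fit(X, z)), error = function(e) rep(0, k))
  beta0[!is.finite(beta0)] <- 0
  mu0 <- plogis(drop(X %*% beta0))
  r0 <- var(y - mu0)
  phi0 <- max(mean(mu0 * (1 - mu0)) / max(r0, 1e-6) - 1, 2)
  start <- c(beta0, log(phi0))
  fit <- NULL
  for (attempt in 0:3) {
    st <- if (attempt == 0) start else
      start + rnorm(length(start), 0, 0.25 * attempt)
    opt <- tryCatch(
      optim(st, beta_negll, beta_negll_grad, X = X, y = y, method = "BFGS",
            control = list(maxit = 500, reltol = 1e-14)),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$value)) next
    # Newton polish: push the score to numerical stationarity
    par <- opt$par
    for (it in 1:50) {
      g <- beta_negll_grad(par, X, y)
      if (max(abs(g)) < 1e-8) break
      H <- beta_obs_info(par, X, y)
      step <- tryCatch(solve(H, g), error = function(e) NULL)
      if (is.null(step)) break
      cand <- par - step
      if (!is.finite(beta_negll(cand, X, y))) break
      par <- cand
    }
    if (max(abs(beta_negll_grad(par, X, y))) < 1e-6) {
      fit <- list(par = par, value = beta_negll(par, X, y))
      break
    }
  }
  if (is.null(fit)) {
    stop("beta regression did not converge after multiple starts", call. = FALSE)
  }
  par <- fit$par
  beta <- setNames(par[seq_len(k)], colnames(X))
  phi <- exp(par[k + 1L])
  loglik <- -fit$value
  H <- beta_obs_info(par, X, y)
  # delta method from log(phi) to phi for the last row/column
  Jac <- diag(k + 1L); Jac[k + 1L, k + 1L] <- 1 / phi
  vc <- tryCatch(Jac %*% solve(H) %*% t(Jac), error = function(e) {
    warning("observed information is singular; SEs unavailable")
    matrix(NA_real_, k + 1L, k + 1L)
  })
  se <- sqrt(pmax(diag(vc), 0))[seq_len(k)]
  eta <- drop(X %*% beta)
  mu <- plogis(eta)
  obj <- structure(list(
    beta = beta, se = setNames(se, colnames(X)), phi = phi,
    phi_se = sqrt(pmax(diag(vc), 0))[k + 1L],
    loglik = loglik, aic = 2 * (k + 1) - 2 * loglik,
    n = length(y), fitted_mean = mu, linear_predictor = eta,
    residuals = y - mu, response = y, X = X,
    response_name = response, predictors = predictors,
    years = if ("year" %in% names(data)) data$year else NULL,
    data = data, collinearity = coll,
    standardization = std_transforms
  ), class = "beta_fit")
  # quiet here: an intercept-only fit legitimately has pseudo-R2 = 0, and
  # reduced-model refits (delta_aic, LOOCV) should not chatter
  obj$pseudo_r2 <- suppressWarnings(pseudo_r2(obj))
  obj
}

#' Pseudo-R-squared of a beta regression fit
#'
#' The squared Pearson correlation between the fitted linear predictor and
#' the link-transformed (logit) response. For an intercept-only model the
#' linear predictor has zero variance and the value is 0, with a warning.
#'
#' @param fit A `beta_fit` object.
#' @return A value in \[0, 1\].
#' @export
pseudo_r2 <- function(fit) {
  stopifnot(inherits(fit, "beta_fit"))
  eta <- fit$linear_predictor
  if (sd(eta) == 0) {
    warning("zero-variance linear predictor; pseudo-R2 set to 0")
    return(0)
  }
  cor(eta, qlogis(fit$response))^2
}

#' AIC-based importance of one predictor
#'
#' `delta_aic = AIC(full) - AIC(model without the predictor)`: negative
#' values mean the predictor improves the model (its removal raises the
#' AIC).
#'
#' @param fit A `beta_fit` object (the full model).
#' @param term Name of a predictor present in the fit.
#' @return Numeric scalar.
#' @seealso [importance_aic()] for all predictors at once.
#' @export
delta_aic <- function(fit, term) {
  stopifnot(inherits(fit, "beta_fit"))
  if (!term %in% fit$predictors) {
    stop("predictor '", term, "' is not in the model", call. = FALSE)
  }
  reduced <- fit_beta_regression(fit$data, fit$response_name,
                                 setdiff(fit$predictors, term),
                                 allow_collinear = TRUE)
  fit$aic - reduced$aic
}

#' AIC importance table for every predictor in a fit
#'
#' @param fit A `beta_fit` object.
#' @return Tibble with columns `term` and `delta_aic`.
#' @export
importance_aic <- function(fit) {
  tibble(term = fit$predictors,
         delta_aic = purrr::map_dbl(fit$predictors, ~ delta_aic(fit, .x)))
}

#' Screen two-way interactions against null-model residuals
#'
#' Overfitting control for interaction terms: the residuals of the additive
#' ("null") model on the unit scale are regressed, one candidate at a time,
#' on the product of two standardized predictors by ordinary least squares.
#' Only candidates whose slope is significant at `alpha` (two-sided, default
#' 0.05) are retained for the final model.
#'
#' @param fit The additive `beta_fit` (no interactions).
#' @param candidates List of length-2 character vectors naming predictor
#'   pairs; default: all pairs of the fit's predictors.
#' @param alpha Retention threshold on the slope p-value.
#' @param residual_scale `"response"` (unit-scale residuals, default) or
#'   `"link"` (logit response minus linear predictor).
#' @return Tibble with columns `term1`, `term2`, `interaction`, `slope`,
#'   `p_value`, `selected`.
#' @export
screen_interactions <- function(fit, candidates = NULL, alpha = 0.05,
                                residual_scale = c("response", "link")) {
  stopifnot(inherits(fit, "beta_fit"))
  residual_scale <- match.arg(residual_scale)
  if (is.null(candidates)) {
    candidates <- utils::combn(fit$predictors, 2, simplify = FALSE)
  }
  if (length(candidates) == 0) {
    return(tibble(term1 = character(), term2 = character(),
                  interaction = character(), slope = numeric(),
                  p_value = numeric(), selected = logical()))
  }
  resid <- if (residual_scale == "response") fit$residuals else
    qlogis(fit$response) - fit$linear_predictor
  purrr::map_dfr(candidates, function(pair) {
    prod_term <- fit$data[[pair[1]]] * fit$data[[pair[2]]]
    sm <- summary(lm(resid ~ prod_term))
    tibble(term1 = pair[1], term2 = pair[2],
           interaction = paste(pair, collapse = ":"),
           slope = sm$coefficients["prod_term", "Estimate"],
           p_value = sm$coefficients["prod_term", "Pr(>|t|)"])
  }) %>%
    mutate(selected = .data$p_value < alpha)
}

#' Add an interaction column to a model table
#'
#' @param data Model tibble with both predictor columns.
#' @param term1,term2 Predictor names; the new column is their product,
#'   named `term1:term2`.
#' @return `data` with the product column appended.
#' @export
add_interaction <- function(data, term1, term2) {
  data[[paste(term1, term2, sep = ":")]] <- data[[term1]] * data[[term2]]
  data
}

#' Predictions from a beta regression fit
#'
#' @param object A `beta_fit` object.
#' @param newdata Optional tibble of predictors on the same scale as used in
#'   fitting; if the fit carries standardization transforms (from
#'   [standardize_predictors()]) and `standardized = FALSE`, they are
#'   applied first. Defaults to the training data.
#' @param scale `"mu"` for unit-interval means (default) or `"m"` for the
#'   \[-1, 1\] masting-index scale (requires `index_n`).
#' @param standardized Are `newdata` columns already standardized?
#' @param index_n Compression size used by [rescale_unit()] when inverting
#'   to the masting-index scale.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.beta_fit <- function(object, newdata = NULL, scale = c("mu", "m"),
                             standardized = TRUE, index_n = NULL, ...) {
  scale <- match.arg(scale)
  if (is.null(newdata)) {
    mu <- object$fitted_mean
  } else {
    missing_terms <- setdiff(object$predictors, names(newdata))
    if (length(missing_terms) > 0) {
      stop("newdata lacks predictor(s): ",
           paste(missing_terms, collapse = ", "), call. = FALSE)
    }
    if (!standardized) {
      if (is.null(object$standardization)) {
        stop("fit carries no standardization transforms", call. = FALSE)
      }
      newdata <- apply_standardization(newdata, object$standardization)
    }
    X <- cbind(1, as.matrix(newdata[object$predictors]))
    mu <- plogis(drop(X %*% object$beta))
  }
  if (scale == "mu") return(mu)
  if (is.null(index_n)) stop("index_n required for the masting-index scale",
                             call. = FALSE)
  unscale_unit(mu, n = index_n)
}

#' Leave-one-out cross-validation of a beta regression
#'
#' Refits the model `n` times, omitting one year at a time, and predicts the
#' omitted year's response from each refit. Validation statistic: the
#' Pearson correlation between observed and out-of-sample predicted values.
#' Any refit that fails to converge flags its year and the correlation is
#' computed on the converged subset with a warning.
#'
#' @param data,response,predictors As in [fit_beta_regression()]; `data`
#'   must yield at least 10 complete rows.
#' @param allow_collinear Passed through to the refits.
#' @return A list of class `beta_loocv`: `predictions` tibble (`year` if
#'   available, `observed`, `predicted`, `converged`) and `pearson_r`.
#' @export
loocv_beta <- function(data, response, predictors, allow_collinear = FALSE) {
  keep <- complete.cases(data[c(response, predictors)])
  data <- data[keep, , drop = FALSE]
  n <- nrow(data)
  if (n < 10) stop("need at least 10 complete rows for LOOCV", call. = FALSE)
  preds <- rep(NA_real_, n)
  ok <- rep(TRUE, n)
  for (i in seq_len(n)) {
    f <- tryCatch(
      fit_beta_regression(data[-i, , drop = FALSE], response, predictors,
                          allow_collinear = allow_collinear),
      error = function(e) NULL)
    if (is.null(f)) { ok[i] <- FALSE; next }
    preds[i] <- predict(f, newdata = data[i, , drop = FALSE])
  }
  if (any(!ok)) {
    warning(sum(!ok), " LOOCV refit(s) failed; r computed on the converged subset")
  }
  out <- tibble(
    observed = data[[response]], predicted = preds, converged = ok
  )
  if ("year" %in% names(data)) out <- dplyr::bind_cols(tibble(year = data$year), out)
  structure(list(predictions = out,
                 pearson_r = cor(out$observed[ok], out$predicted[ok])),
            class = "beta_loocv")
}

#' @export
print.beta_fit <- function(x, ...) {
  cat("Beta regression (logit link, constant precision)\n")
  cat(sprintf("  n = %d, logLik = %.3f, AIC = %.2f, pseudo-R2 = %.3f, phi = %.2f\n",
              x$n, x$loglik, x$aic, x$pseudo_r2, x$phi))
  tab <- tidy(x)
  print(as.data.frame(tab), digits = 3, row.names = FALSE)
  invisible(x)
}

#' Coefficient table of a beta regression fit
#'
#' @param x A `beta_fit` object.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std_error`, `statistic`
#'   (Wald z) and `p_value` (two-sided normal).
#' @method tidy beta_fit
#' @export
tidy.beta_fit <- function(x, ...) {
  z <- x$beta / x$se
  tibble(term = names(x$beta), estimate = unname(x$beta),
         std_error = unname(x$se), statistic = unname(z),
         p_value = unname(2 * pnorm(-abs(z))))
}

#' One-row model summary of a beta regression fit
#'
#' @param x A `beta_fit` object.
#' @param ... Unused.
#' @return Tibble with `n`, `phi`, `log_lik`, `aic`, `pseudo_r2`.
#' @method glance beta_fit
#' @export
glance.beta_fit <- function(x, ...) {
  tibble(n = x$n, phi = x$phi, log_lik = x$loglik, aic = x$aic,
         pseudo_r2 = x$pseudo_r2)
}
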