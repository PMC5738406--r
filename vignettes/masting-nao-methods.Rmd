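---
title: "Methods: masting synchrony, NAO frequency components, and beta regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: masting synchrony, NAO frequency components, and beta regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(mastnao)
```

This vignette documents the statistical machinery of `mastnao`: the models
and procedures, the parameters that matter, the numerical choices made where
the design was genuinely open, and what the synthetic-data tests do and do
not demonstrate about real archives.

## The masting synchrony index

Ordinal seed-crop records (classes 1–5) arrive as one observation per
series, year and region. Two regions holding very different numbers of
series would otherwise contribute unequally, so records are first collapsed
to one value per region-year: the **modal class** across that region's
series. The annual continental index is then

$$M_t \;=\; \mathrm{NC45}_t - \mathrm{NC12}_t,$$

the proportion of regions whose modal class is 4–5 minus the proportion in
classes 1–2, over the regions reporting in year $t$. $M \in [-1, 1]$; zero
means either a prevalence of class 3 or a balanced split of good and poor
regions — which is why a year with *no* reporting regions is missing, never
zero.

Two conventions required a decision:

* **Mode ties.** The tie-breaking rule is not dictated by the index
  definition. We take the *lowest tied class*: deterministic, and
  conservative in that it biases against declaring mast years. A
  permutation-invariance and monotone-influence property (adding a
  duplicate series can move the mode only toward that series' classes) is
  enforced by test against a brute-force counting oracle.
* **Unit-interval rescaling.** The beta likelihood needs the response
  strictly inside $(0,1)$. After the affine map $y = (m+1)/2$ we apply the
  Smithson–Verkuilen compression $y' = (y(n-1) + 0.5)/n$ with $n$ the
  series length. The compression parameters are stored so predictions can
  be mapped back to the $[-1,1]$ scale exactly (`unscale_unit()`).

## Seasonal aggregation and lags

Monthly teleconnection values are averaged over DJFM (winter; December of
the previous calendar year through March, labelled to the year containing
January–March), AM (spring) and JJAS (summer). A seasonal mean is emitted
only when **every** month of the season is present — partial-season means
would silently bias the winter series, whose four months straddle a year
boundary. Predictors attach to the mast year $Y_M$ at fixed lags: summer
two years back ($Y_{M-2}$), winter and summer of the previous year
($Y_{M-1}$), spring of the mast year ($Y_M$). The low-frequency components
inherit the lag of their season's aligned series; since they vary on a
decadal scale, a one-year lag shift is immaterial to them.

## Wavelet coherence and its Monte Carlo test

The index (rescaled, then arcsine-transformed as $\arcsin\sqrt{y}$, the
variance-stabilizing transform for proportions) is compared to each raw
seasonal series by squared wavelet coherence:

* Morlet mother wavelet with $\omega_0 = 6$, dyadic scales
  $s_j = s_0 2^{j\,dj}$ with $dj = 1/12$, $s_0 = 2\,\mathrm{yr}$, reaching
  periods of at least 32 years; Fourier period $\approx 1.033\,s$.
* FFT-based transform with zero padding to the next power of two;
  the cone of influence follows the $\sqrt{2}s$ e-folding rule.
* Coherence in the Torrence–Webster/Grinsted convention:
  cross- and auto-spectra are divided by scale, smoothed in time by a
  Gaussian whose width is proportional to scale (sd $= s/\sqrt2$, the
  Morlet $|\psi|^2$ footprint) and across scales by a 0.6-octave boxcar,
  then combined as $R^2 = |S(W_{xy}/s)|^2 / (S(|W_x|^2/s)\,S(|W_y|^2/s))$.
  Because the identical positive smoothing weights act on numerator and
  denominators, $0 \le R^2 \le 1$ holds by the Cauchy–Schwarz inequality —
  it is asserted, not clamped into existence.

Significance is Monte Carlo: surrogate pairs are stationary Gaussian AR(1)
series matching each input's estimated lag-1 autocorrelation and variance.
Both a pointwise exceedance field and a **time-averaged test** (coherence
averaged over the cells inside the cone of influence at each scale) are
computed with the $+1$ rank correction, $p = (\#\{R^2_{\mathrm{surr}} \ge
R^2_{\mathrm{obs}}\} + 1)/(n_{\mathrm{surr}} + 1)$. The scale-averaged test
is reported for periods above 5 years — the low-frequency domain of
interest — and the conventional contour is drawn at $\alpha = 0.1$.
Coherence is bounded and one-sided by construction, so exceedance
p-values are the natural summary even where a two-sided label is used for
the contour.

The span fed to the smoother is the midpoint of the significant
scale-averaged band (several analyses are combined by averaging their band
midpoints), rounded to the nearest odd integer
($x \mapsto 2\lfloor x/2\rfloor + 1$) so it can serve directly as a
centred running-line window; a band covering periods 7–16 years yields 11.
When nothing is significant the configured default (11 years) is used with
a warning. On short series this estimate is noticeably variable — the
worked example in the README lands on 5 where the generating decadal scale
is 11 — which is why the pipeline accepts a `span` override.

## Frequency decomposition

The low-frequency component is a **fixed-span running-line smoother**: at
each year, an ordinary least-squares line is fitted to the observations in
a centred window of `span_years` points and evaluated at the centre. At the
series ends the window is truncated symmetrically (minimum three points,
one-sided at the extreme ends) rather than extrapolated, avoiding
end-of-series artifacts in the decadal component. The high-frequency
component is the raw series minus the smooth, so `raw = low + high` is an
identity (checked to 1e-10). The smoother is linear in its input and
reproduces exactly linear series unchanged.

A variable-span smoother would be the generic tool here, but the span is
deliberately *fixed* to the wavelet-derived value, so the span-selection
machinery is unnecessary; a fixed-span local line is reproducible and makes
the low/high split depend only on the data and one interpretable parameter.
Spans are counted in annual observations (11 years = 11 points).

## Beta regression by maximum likelihood

The rescaled index is modelled as $y_t \sim \mathrm{Beta}(\mu_t\phi,
(1-\mu_t)\phi)$ with $\operatorname{logit}(\mu_t) = x_t^\top\beta$ and
constant precision $\phi$ — the logit link is the standard choice for this
model family and the only one consistent with reporting standardized
coefficients on a common scale. Fitting is by direct maximization of the
exact log-likelihood: BFGS with the analytic score, followed by Newton
polishing until every score component is below $10^{-8}$ (the test suite
requires $10^{-6}$ at the reported optimum); up to three jittered restarts
guard against bad starting points (starting values come from an OLS fit on
the logit scale and a moment estimate of $\phi$). Standard errors come
from the observed information (delta method for $\phi$ from the
$\log\phi$ parametrization); $\mathrm{AIC} = 2k - 2\ell$ with $k$ counting
the regression coefficients plus $\phi$.

Model-building conventions:

* **Standardization.** All predictors are centred and scaled over the fit
  window; the transforms are stored in the fit and re-applied to new data
  at prediction time.
* **Autoregression.** The AR1 predictor is the previous year's rescaled
  response, standardized like any other predictor; the first window year
  is dropped. An AR2 column can be added the same way.
* **Collinearity gate.** Pairwise Pearson $|r| \ge 0.4$ among predictors
  aborts the fit unless explicitly overridden. The gate exists for
  unvetted observational predictor sets; analyses of synthetic data with a
  known generating model override it deliberately.
* **Interaction screening.** To limit overfitting, the residuals of the
  additive model (unit scale by default; link scale available) are
  regressed by OLS on one candidate product of standardized predictors at
  a time; only candidates with slope $p < 0.05$ enter the final model.
* **Pseudo-R².** $\operatorname{cor}(x^\top\hat\beta,
  \operatorname{logit} y)^2$; an intercept-only model returns 0 with a
  warning.
* **ΔAIC.** $\mathrm{AIC}_{\mathrm{full}} -
  \mathrm{AIC}_{\mathrm{without\ predictor}}$, negative when the predictor
  improves the model.
* **LOOCV.** $n$ refits, each omitting one year, predicting the omitted
  year; the summary is the Pearson correlation between observed and
  out-of-sample predicted values. Non-converging refits flag their year
  and the correlation is computed on the converged subset with a warning.

One statistical caveat is worth recording: under a pure-noise response the
LOOCV correlation is **not** centred at zero. Each refit's prediction
anti-tracks the omitted observation, so the null distribution of $r$ is
centred clearly below zero (an OLS-based LOOCV oracle on Gaussian noise at
$n = 30$ gives mean $r \approx -0.33$, sd $0.33$). The acceptance tests
therefore check for *absence of positive skill* and agreement with that
oracle-derived null, not for a zero-centred $r$.

## The synthetic-data generator

`sim_config()` fixes the world the tests live in:

| parameter | default | rationale |
|---|---|---|
| `n_years` | 64 | length of a 1952–2015-style fit window |
| `n_regions`, `series_per_region` | 40, 8 | a ~40-region continental archive with a few hundred series |
| `ar1_noise`, `noise_sd` | 0.15, 1 | near-white monthly index noise |
| `decadal_period`, `decadal_amplitude` | 11 yr, 1 | one decadal cycle injected into the winter months |
| `beta_coefficients` | −0.500, +0.174, +0.373, +0.514, +0.402; AR1 −0.633 | magnitudes and signs of a published beech-type effect structure |
| `precision_phi` | 50 | latent beta noise; with the ordinal layer this yields fitted standardized SEs near 0.11 |
| `class_noise_sd` | 0.5 | half a class of observer noise, enough to spread regions across classes |

The monthly simulator adds a decadal sinusoid (winter months only, by
default) to stationary AR(1) noise. The record simulator builds the
*same* lag-aligned high/low components the analysis pipeline builds
(`nao_component_table()`, shared code path), standardizes them, and drives
a latent beta process $\mu_t = \operatorname{logit}^{-1}(\eta_t)$,
$M_t \sim \mathrm{Beta}(\mu_t\phi, (1-\mu_t)\phi)$. The autoregressive
term enters the linear predictor as the previous *latent* index expressed
on the $[-1,1]$ scale, $4(M_{t-1}-\tfrac12)$ — using the latent rather
than the reconstructed index keeps the generative model well defined, and
the $[-1,1]$ scaling puts the AR coefficient on roughly the same
standardized footing as the component coefficients. Every region series
observes the shared latent state through an ordinal filter
$\mathrm{class} = \mathrm{clamp}(\mathrm{round}(1 + 4M_t +
\mathcal N(0, \sigma_c)), 1, 5)$ — the simplest monotone map whose
aggregate recovers the latent index.

What the generator **does not** emulate: spatial autocorrelation between
regions beyond the shared driver, species mixtures, observation gaps and
proxy heterogeneity, non-stationary teleconnection behaviour, and real
masting's skewed inter-mast interval distribution. Passing tests therefore
demonstrate that the *machinery* is correct and calibrated under a known
truth — not that real archives satisfy the model's assumptions.

## Problem sizes and test design

The statistical acceptance checks run at sizes chosen to balance power
against runtime on a single CPU: 66-year series with 500 surrogates and
100 repetitions for coherence size and power; 500 simulations at
$n = 200$ for Wald coverage; 200 end-to-end runs at the generator defaults
for simultaneous six-sign recovery; 100 simulations at $n = 64$ for
interaction-screening size and power (generating interaction +0.24, a
published effect size). Monte Carlo assertions use fixed seeds and
pre-committed binomial error bands around the nominal rates.

## Known limitations

* The coherence smoothing convention (Gaussian-in-time bandwidth, boxcar
  octaves) varies slightly between published implementations; absolute
  $R^2$ values and hence band edges can differ at the margin between
  conventions, which propagates into the estimated span on short series.
* Wald intervals and p-values are asymptotic; at $n \approx 60$ they are
  adequate (coverage verified 90–98% at nominal 95%) but not exact.
* The running-line smoother is not a spectral filter: its band separation
  at span 11 is strong (tested correlations > 0.9) but not sharp.
* Grid correlation p-values use the large-sample t approximation on ranks
  (permutation for very short overlaps) and are reported per cell without
  multiplicity adjustment; the significance level for map dots is a
  convention (default α = 0.05).
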