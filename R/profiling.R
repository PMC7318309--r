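# Provider profiling Z-scores and flagging rules.
#
# FE:   Z = Ybar / (sigma_w / sqrt(n))          -- sharp null, within noise only
# RE:   Z = sqrt(IUR_i) * Z_FE                  -- shrinkage (BLUP) scale
# FERE: Z = Ybar / sqrt(sigma_b^2 + sigma_w^2/n) -- marginal (total) scale
# EN:   Z_FE judged against a normal fitted robustly to the central Z mass.

#' Fixed-effects Z-score
#'
#' @param y_bar provider mean of the risk-adjusted outcome.
#' @param sigma_w2 within-provider variance (> 0).
#' @param n provider size (>= 1).
#' @return `y_bar * sqrt(n) / sqrt(sigma_w2)`; vectorized.
#' @export
z_fe <- function(y_bar, sigma_w2, n) {
  if (any(sigma_w2 <= 0)) stop("sigma_w2 must be > 0")
  if (any(n < 1)) stop("n must be >= 1")
  y_bar * sqrt(n) / sqrt(sigma_w2)
}

#' Random-effects (shrinkage) Z-score
#'
#' The BLUP of the provider effect is `IUR_i * Ybar` with posterior standard
#' deviation `sqrt(IUR_i) * sigma_w / sqrt(n)`, so the RE Z-score is
#' `sqrt(IUR_i)` times the FE Z-score. Its null variance is
#' `rho / (1 - rho)`, not 1; flagging still compares it to `z_p`.
#'
#' @param z_fe_value FE Z-score(s).
#' @param iur_i provider-specific IUR in `[0, 1)`.
#' @return the RE Z-score(s); vectorized.
#' @export
z_re <- function(z_fe_value, iur_i) {
  if (any(iur_i < 0 | iur_i >= 1)) stop("iur_i must be in [0, 1)")
  sqrt(iur_i) * z_fe_value
}

#' FERE Z-score
#'
#' Judges the provider mean against the marginal (between + within) scale:
#' `Ybar / sqrt(sigma_b2 + sigma_w2 / n)`, equal to
#' `sqrt(1 - IUR_i) * Z_FE`. Marginally standard normal under the null model
#' for every provider size.
#'
#' @param y_bar provider mean of the risk-adjusted outcome.
#' @param sigma_b2 between-provider variance (>= 0).
#' @param sigma_w2 within-provider variance (> 0).
#' @param n provider size (>= 1).
#' @return the FERE Z-score(s); vectorized.
#' @export
z_fere <- function(y_bar, sigma_b2, sigma_w2, n) {
  if (any(sigma_b2 < 0)) stop("sigma_b2 must be >= 0")
  if (any(sigma_w2 <= 0)) stop("sigma_w2 must be > 0")
  if (any(n < 1)) stop("n must be >= 1")
  y_bar / sqrt(sigma_b2 + sigma_w2 / n)
}

#' Flagging configuration
#'
#' @param method one of `"FE"`, `"RE"`, `"FERE"`, `"EN"`.
#' @param p one-sided level in `(0, 0.5)`.
#' @param direction `"worse"` (upper tail, default) or `"better"` (lower).
#' @return an object of class `flag_config`.
#' @export
flag_config <- function(method = c("FERE", "FE", "RE", "EN"), p = 0.025,
                        direction = c("worse", "better")) {
  method <- toupper(match.arg(toupper(method[1L]),
                              c("FERE", "FE", "RE", "EN")))
  direction <- match.arg(direction)
  structure(list(method = method, p = p, z_p = zp_of(p),
                 direction = direction),
            class = "flag_config")
}

#' Robust empirical-null fit to a Z-score collection
#'
#' Fits a normal distribution to the central part of the Z-score
#' distribution, so that tail providers (true outliers) do not inflate the
#' null scale. `truncated_mle` maximizes the truncated-normal likelihood of
#' the observations inside a sample-quantile window, with truncation limits
#' fixed at those quantiles; `huber` uses joint Huber location/scale
#' M-estimates (tuning constant 1.345).
#'
#' @param z_scores numeric vector of at least 30 Z-scores.
#' @param quantile_window lower/upper quantile probabilities of the fitting
#'   window (default `c(0.10, 0.90)`).
#' @param fit_method `"truncated_mle"` (default) or `"huber"`.
#' @return an object of class `empirical_null` with elements `mu_M`,
#'   `sigma_M`, `fit_window`, `n_used`, `fit_method`.
#' @export
fit_empirical_null <- function(z_scores, quantile_window = c(0.10, 0.90),
                               fit_method = c("truncated_mle", "huber")) {
  fit_method <- match.arg(fit_method)
  z_scores <- as.numeric(z_scores)
  if (length(z_scores) < 30L)
    stop("need at least 30 Z-scores to fit an empirical null")
  if (fit_method == "huber") {
    fit <- MASS::hubers(z_scores, k = 1.345)
    window <- range(z_scores)
    return(structure(list(mu_M = fit$mu, sigma_M = fit$s,
                          fit_window = window, n_used = length(z_scores),
                          fit_method = "huber"),
                     class = "empirical_null"))
  }
  qs <- stats::quantile(z_scores, quantile_window, names = FALSE)
  a <- qs[1L]; b <- qs[2L]
  inside <- z_scores[z_scores >= a & z_scores <= b]
  if (length(inside) < 10L)
    stop("fewer than 10 Z-scores inside the quantile window")
  # negative truncated-normal log likelihood over (mu, log sigma)
  nll <- function(par) {
    mu <- par[1L]; sigma <- exp(par[2L])
    pin <- stats::pnorm(b, mu, sigma) - stats::pnorm(a, mu, sigma)
    if (pin <= 1e-300) return(1e10)
    val <- -sum(stats::dnorm(inside, mu, sigma, log = TRUE)) +
      length(inside) * log(pin)
    if (!is.finite(val)) 1e10 else val
  }
  s0 <- max(stats::sd(inside), 1e-6)
  w <- b - a
  # The truncated-normal likelihood degenerates (sigma -> Inf, density ->
  # uniform on the window) when the windowed sample is at least as flat as a
  # uniform; bound the search and fall back to the Huber fit in that case.
  opt <- stats::optim(c(mean(inside), log(s0)), nll, method = "L-BFGS-B",
                      lower = c(a - w, log(s0 / 50)),
                      upper = c(b + w, log(5 * s0)),
                      control = list(maxit = 200L, factr = 1e4))
  if (opt$convergence != 0 && opt$convergence != 52L)
    stop("truncated-normal fit did not converge after 200 iterations ",
         "(last iterate mu = ", signif(opt$par[1L], 6),
         ", sigma = ", signif(exp(opt$par[2L]), 6), ")")
  sigma_hat <- exp(opt$par[2L])
  if (opt$convergence == 52L || sigma_hat > 4 * s0) {
    message("central window carries no scale information ",
            "(truncated-normal fit degenerate); falling back to Huber")
    fit <- MASS::hubers(z_scores, k = 1.345)
    return(structure(list(mu_M = fit$mu, sigma_M = fit$s,
                          fit_window = c(a, b), n_used = length(inside),
                          fit_method = "huber_fallback"),
                     class = "empirical_null"))
  }
  structure(list(mu_M = opt$par[1L], sigma_M = sigma_hat,
                 fit_window = c(a, b), n_used = length(inside),
                 fit_method = "truncated_mle"),
            class = "empirical_null")
}

#' @export
print.empirical_null <- function(x, ...) {
  cat(sprintf("empirical null: N(%.4f, %.4f^2)  [%s, %d points in (%.3g, %.3g)]\n",
              x$mu_M, x$sigma_M, x$fit_method, x$n_used,
              x$fit_window[1L], x$fit_window[2L]))
  invisible(x)
}

#' Outlier-robust IUR from the empirical null
#'
#' On the FE Z-score scale the null variance is `1 / (1 - IUR)`, so the
#' robust scale estimate converts to `IUR = 1 - 1 / sigma_M^2`, clamped at 0
#' when `sigma_M < 1`. Because the fit ignores the tails, contamination by
#' outlier providers barely moves this estimate, unlike the ANOVA IUR.
#'
#' @param null an [fit_empirical_null()] result.
#' @return the robust IUR estimate in `[0, 1)`.
#' @export
en_iur <- function(null) {
  stopifnot(inherits(null, "empirical_null"))
  if (null$sigma_M < 1)
    message("sigma_M = ", signif(null$sigma_M, 4),
            " < 1; EN IUR clamped to 0")
  max(0, 1 - 1 / null$sigma_M^2)
}

#' Flag providers at one-sided level p
#'
#' FE/RE/FERE compare the Z-score to the standard-normal quantile `z_p`;
#' EN compares the FE Z-score to `mu_M + z_p * sigma_M` from a fitted
#' empirical null. `direction = "better"` mirrors to the lower tail.
#'
#' @param z named numeric vector of per-provider Z-scores (FE scores for the
#'   EN method).
#' @param config a [flag_config()].
#' @param null an `empirical_null` (required when `config$method == "EN"`).
#' @return a data.frame with columns `provider_id`, `z`, `flagged`,
#'   `method`, `threshold`.
#' @export
flag_providers <- function(z, config, null = NULL) {
  stopifnot(inherits(config, "flag_config"))
  if (config$method == "EN") {
    if (is.null(null)) stop("EN flagging requires a fitted empirical null")
    thr <- null$mu_M + config$z_p * null$sigma_M
    lo <- null$mu_M - config$z_p * null$sigma_M
  } else {
    thr <- config$z_p
    lo <- -config$z_p
  }
  flagged <- if (config$direction == "worse") z > thr else z < lo
  data.frame(provider_id = if (is.null(names(z))) seq_along(z) else names(z),
             z = as.numeric(z), flagged = as.logical(flagged),
             method = config$method,
             threshold = if (config$direction == "worse") thr else lo,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Profile a panel: Z-scores and flags for every provider
#'
#' Convenience driver: risk-adjusts if needed, estimates variance components
#' by ANOVA, computes the configured Z-scores (with provider-specific sizes)
#' and flags. For EN the null is fitted to the FE Z-scores; with
#' `en_strata > 1` providers are split into size-quantile strata and one
#' null is fitted per stratum (the FE Z variance grows with provider size
#' when `sigma_b2 > 0`).
#'
#' @param panel a [provider_panel()].
#' @param config a [flag_config()].
#' @param components optional [variance_components()] with known
#'   `sigma_b2`/`sigma_w2`; estimated by ANOVA when `NULL`.
#' @param en_window,en_fit empirical-null window and fit method, passed to
#'   [fit_empirical_null()].
#' @param en_strata number of provider-size strata for the EN fit.
#' @return the [flag_providers()] data.frame, with attribute `"iur"`
#'   carrying the `iur_estimate` (when components were estimated) and
#'   `"null"` the empirical null fit(s).
#' @export
profile_panel <- function(panel, config = flag_config(),
                          components = NULL,
                          en_window = c(0.10, 0.90),
                          en_fit = "truncated_mle", en_strata = 1L) {
  panel <- ensure_adjusted(panel)
  est <- NULL
  if (is.null(components)) {
    est <- estimate_variance_components(panel)
    sb2 <- est$sigma_b2; sw2 <- est$sigma_w2
  } else {
    sb2 <- components$sigma_b2; sw2 <- components$sigma_w2
  }
  means <- provider_means(panel)
  sz <- provider_sizes(panel)[names(means)]
  zfe <- z_fe(means, sw2, sz)
  z <- switch(config$method,
              FE = zfe,
              RE = z_re(zfe, sb2 / (sb2 + sw2 / sz)),
              FERE = z_fere(means, sb2, sw2, sz),
              EN = zfe)
  nulls <- NULL
  if (config$method == "EN") {
    if (en_strata > 1L) {
      br <- stats::quantile(sz, probs = seq(0, 1, length.out = en_strata + 1L))
      strat <- cut(sz, unique(br), include.lowest = TRUE)
      nulls <- lapply(split(z, strat), fit_empirical_null,
                      quantile_window = en_window, fit_method = en_fit)
      res <- do.call(rbind, lapply(levels(strat), function(lv) {
        flag_providers(z[strat == lv], config, nulls[[lv]])
      }))
      res <- res[match(names(z), res$provider_id), ]
      rownames(res) <- NULL
    } else {
      nulls <- fit_empirical_null(z, quantile_window = en_window,
                                  fit_method = en_fit)
      res <- flag_providers(z, config, nulls)
    }
  } else {
    res <- flag_providers(z, config)
  }
  attr(res, "iur") <- est
  attr(res, "null") <- nulls
  res
}
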