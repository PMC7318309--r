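# One-way linear model with provider random effects:
#   Y*_ij = mu + alpha_i + X_ij' beta + eps_ij,
#   alpha_i ~ N(0, sigma_b^2), eps_ij ~ N(0, sigma_w^2).
# The IUR of a provider mean is sigma_b^2 / (sigma_b^2 + sigma_w^2 / n_i);
# the overall IUR replaces n_i by the effective size n' of the unbalanced
# one-way ANOVA decomposition.

#' Variance components of the provider linear model
#'
#' Container for the grand mean, within-provider covariate coefficients and
#' the between-/within-provider variances that drive all Z-scores and IURs.
#'
#' @param mu grand mean.
#' @param beta numeric vector of within-provider covariate coefficients
#'   (length 0 when there are no covariates).
#' @param sigma_b2 between-provider variance (>= 0).
#' @param sigma_w2 within-provider variance (> 0); may be `NA` when only
#'   risk adjustment is needed.
#' @return an object of class `variance_components`.
#' @export
variance_components <- function(mu = 0, beta = numeric(), sigma_b2 = NA_real_,
                                sigma_w2 = NA_real_) {
  stopifnot(is.numeric(mu), length(mu) == 1L, is.numeric(beta))
  if (!is.na(sigma_b2) && sigma_b2 < 0) stop("sigma_b2 must be >= 0")
  if (!is.na(sigma_w2) && sigma_w2 <= 0) stop("sigma_w2 must be > 0")
  structure(list(mu = mu, beta = beta, sigma_b2 = sigma_b2,
                 sigma_w2 = sigma_w2),
            class = "variance_components")
}

#' Within-provider (fixed-effects) covariate coefficients
#'
#' Estimates beta by least squares after demeaning outcome and covariates
#' within each provider — equivalent to a fit with one indicator per provider.
#' This guards against bias when patient characteristics are correlated with
#' provider effects, which a pooled or random-effects fit would absorb into
#' beta.
#'
#' @param panel a [provider_panel()].
#' @return named numeric vector of coefficients; `numeric(0)` if the panel
#'   has no covariates.
#' @export
estimate_beta_fixed_effects <- function(panel) {
  cv <- attr(panel, "covariates")
  if (!length(cv)) return(numeric())
  X <- covariate_matrix(panel)
  id <- panel$provider_id
  yc <- panel$y - stats::ave(panel$y, id)
  Xc <- X - apply(X, 2L, function(col) stats::ave(col, id))
  sz <- provider_sizes(panel)
  df_within <- sum(sz) - length(sz)
  if (df_within < ncol(Xc))
    stop("not enough within-provider degrees of freedom to estimate beta")
  qrX <- qr(Xc)
  if (qrX$rank < ncol(Xc)) {
    dropped <- colnames(Xc)[qrX$pivot[(qrX$rank + 1L):ncol(Xc)]]
    stop("collinear covariates after within-provider demeaning: ",
         paste(dropped, collapse = ", "))
  }
  stats::setNames(as.numeric(qr.coef(qrX, yc)), colnames(X))
}

#' Grand mean of covariate-adjusted outcomes
#'
#' Observation-weighted mean of `y - X beta`, so that risk-adjusted outcomes
#' have overall mean zero.
#'
#' @param panel a [provider_panel()].
#' @param beta coefficient vector (length must match the covariate count).
#' @return the estimated grand mean mu.
#' @export
center_mu <- function(panel, beta = numeric()) {
  X <- covariate_matrix(panel)
  if (length(beta) != ncol(X))
    stop("beta has length ", length(beta), " but panel has ", ncol(X),
         " covariates")
  offset <- if (length(beta)) as.numeric(X %*% beta) else 0
  mean(panel$y - offset)
}

#' Risk-adjust a provider panel
#'
#' Sets `y_adj = y - mu - X beta`. With `components = NULL` the coefficients
#' are estimated by [estimate_beta_fixed_effects()] and the mean by
#' [center_mu()].
#'
#' @param panel a [provider_panel()].
#' @param components a [variance_components()] carrying `mu` and `beta`, or
#'   `NULL` to estimate both from the panel.
#' @return the panel with a `y_adj` column.
#' @export
risk_adjust <- function(panel, components = NULL) {
  if (is.null(components)) {
    beta <- estimate_beta_fixed_effects(panel)
    components <- variance_components(mu = center_mu(panel, beta), beta = beta)
  }
  X <- covariate_matrix(panel)
  if (length(components$beta) != ncol(X))
    stop("beta dimension (", length(components$beta),
         ") does not match covariate count (", ncol(X), ")")
  offset <- if (length(components$beta)) as.numeric(X %*% components$beta) else 0
  out <- data.table::copy(panel)
  data.table::set(out, j = "y_adj", value = out$y - components$mu - offset)
  out
}

#' Per-provider means of the risk-adjusted outcome
#'
#' @param panel a risk-adjusted [provider_panel()].
#' @return named numeric vector, one mean per provider.
#' @export
provider_means <- function(panel) {
  y <- adjusted_y(panel)
  means <- tapply(y, panel$provider_id, mean)
  stats::setNames(as.numeric(means), names(means))
}

#' Effective provider size n'
#'
#' The size appearing in the expectation of the between sums of squares of an
#' unbalanced one-way ANOVA, `E(SSB) = (m - 1)(sigma_w^2 + n' sigma_b^2)`:
#' \deqn{n' = \frac{\sum n_i - \sum n_i^2 / \sum n_i}{m - 1}.}
#' Equals the common size when all providers are the same size, and is never
#' larger than the arithmetic mean size.
#'
#' @param sizes vector of positive integer provider sizes (length >= 2).
#' @return n' as a double.
#' @export
n_prime <- function(sizes) {
  sizes <- as.numeric(sizes)
  if (length(sizes) < 2L) stop("n_prime needs at least 2 providers")
  if (any(sizes < 1)) stop("provider sizes must be >= 1")
  N <- sum(sizes)
  (N - sum(sizes^2) / N) / (length(sizes) - 1)
}

#' ANOVA variance components and the inter-unit reliability
#'
#' Method-of-moments estimation from the one-way decomposition of the
#' risk-adjusted outcomes: the within mean square estimates sigma_w^2, and
#' `(SSB/(m-1) - sigma_w^2) / n'` estimates sigma_b^2 (clamped at zero). The
#' overall IUR is `sigma_b^2 / (sigma_b^2 + sigma_w^2 / n')`; per-provider
#' IURs substitute n_i for n'.
#'
#' @param panel a risk-adjusted [provider_panel()] with at least one provider
#'   of size >= 2.
#' @return an object of class `iur_estimate` with elements `sigma_b2`,
#'   `sigma_w2`, `n_prime`, `iur_overall`, `iur_by_provider`, `ssb`,
#'   `grand_mean`, `m`, `sizes`, `clamped`.
#' @export
estimate_variance_components <- function(panel) {
  y <- adjusted_y(panel)
  id <- panel$provider_id
  sz <- provider_sizes(panel)
  m <- length(sz)
  if (m < 2L) stop("need at least 2 providers")
  if (all(sz == 1L))
    stop("all providers have a single patient; sigma_w2 is not estimable")
  gmean <- mean(y)
  means <- provider_means(panel)
  ssb <- sum(sz * (means - gmean)^2)
  ssw <- sum((y - stats::ave(y, id))^2)
  sigma_w2 <- ssw / (sum(sz) - m)
  if (sigma_w2 <= 0)
    stop("degenerate panel: zero within-provider variance (sigma_w2 = 0)")
  np <- n_prime(sz)
  raw_b2 <- (ssb / (m - 1) - sigma_w2) / np
  clamped <- raw_b2 < 0
  if (clamped)
    message("negative between-provider variance estimate (",
            signif(raw_b2, 3), ") clamped to 0")
  sigma_b2 <- max(0, raw_b2)
  iur <- sigma_b2 / (sigma_b2 + sigma_w2 / np)
  iur_i <- sigma_b2 / (sigma_b2 + sigma_w2 / sz)
  structure(list(sigma_b2 = sigma_b2, sigma_w2 = sigma_w2, n_prime = np,
                 iur_overall = iur,
                 iur_by_provider = stats::setNames(iur_i, names(sz)),
                 ssb = ssb, grand_mean = gmean, m = m, sizes = sz,
                 clamped = clamped),
            class = "iur_estimate")
}

#' @export
print.iur_estimate <- function(x, ...) {
  cat("IUR estimate (one-way ANOVA):\n")
  cat(sprintf("  sigma_b2 = %.6g  sigma_w2 = %.6g  n' = %.2f\n",
              x$sigma_b2, x$sigma_w2, x$n_prime))
  cat(sprintf("  overall IUR = %.4f  (m = %d providers)\n", x$iur_overall, x$m))
  if (x$clamped) cat("  note: between-provider variance clamped at 0\n")
  invisible(x)
}

#' Serialize an IUR estimate as JSON
#'
#' @param x an `iur_estimate`.
#' @param path output file path, or `NULL` to return the JSON string.
#' @return invisibly the JSON string.
#' @export
write_iur_json <- function(x, path = NULL) {
  obj <- list(sigma_b2 = x$sigma_b2, sigma_w2 = x$sigma_w2,
              n_prime = x$n_prime, iur_overall = x$iur_overall,
              iur_by_provider = as.list(x$iur_by_provider))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) jsonlite::write_json(obj, path, auto_unbox = TRUE,
                                           digits = NA)
  invisible(js)
}
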