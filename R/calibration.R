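# Closed-form split-half reflagging calibration.
#
# Under the null one-way model the two half-sample Z-scores of a provider with
# IUR = R are bivariate normal with correlation rho = R / (2 - R); each
# profiling method's conditional reflagging probability
#   G(R) = Pr(flagged in half B | flagged in half A, IUR = R)
# is a ratio of a bivariate to a univariate normal tail. The PIUR is the R
# solving G(R) = observed reflagging rate.

#' Bivariate standard normal CDF
#'
#' Joint lower-orthant probability `Pr(U <= h, V <= k)` for standard normal
#' margins with correlation `rho`, computed by the double-precision TVPACK
#' algorithm (absolute accuracy well below 1e-8).
#'
#' @param h,k upper integration limits.
#' @param rho correlation, `|rho| < 1`.
#' @return the probability.
#' @examples
#' pbvnorm(0, 0, 0.5)  # 1/4 + asin(0.5) / (2 * pi)
#' @export
pbvnorm <- function(h, k, rho) {
  stopifnot(length(rho) == 1L, is.finite(rho))
  if (abs(rho) >= 1)
    stop("|rho| must be < 1 (the R -> 1 limit is handled by the caller)")
  if (rho == 0) return(stats::pnorm(h) * stats::pnorm(k))
  as.numeric(mvtnorm::pmvnorm(
    lower = c(-Inf, -Inf), upper = c(h, k),
    corr = matrix(c(1, rho, rho, 1), 2L),
    algorithm = mvtnorm::TVPACK(abseps = 1e-12)))
}

#' Half-sample Z-score correlation implied by the IUR
#'
#' @param R IUR in `[0, 1)`.
#' @return `rho = R / (2 - R)`.
#' @export
rho_of_R <- function(R) {
  if (any(R < 0 | R >= 1)) stop("R must be in [0, 1)")
  R / (2 - R)
}

# One-sided flagging level -> upper quantile, with validation.
zp_of <- function(p) {
  stopifnot(is.numeric(p), length(p) == 1L)
  if (p <= 0 || p >= 0.5) stop("p must be in (0, 0.5)")
  stats::qnorm(1 - p)
}

#' Reflagging calibration curve, fixed-effects method
#'
#' `G_FE(R) = Phi2_rho(s1, s1) / Phi(s1)` with `s1 = -z_p sqrt(1 - rho)`:
#' the FE half-sample Z-scores have variance `1 / (1 - rho)`, so the
#' threshold `z_p` sits at `z_p sqrt(1 - rho)` on the unit scale.
#'
#' @param R IUR value(s) in `[0, 1)`.
#' @param p one-sided flagging level in `(0, 0.5)`.
#' @return reflagging probability, same length as `R`.
#' @export
G_fe <- function(R, p = 0.025) {
  zp <- zp_of(p)
  vapply(R, function(r) {
    rho <- rho_of_R(r)
    s1 <- -zp * sqrt(1 - rho)
    pbvnorm(s1, s1, rho) / stats::pnorm(s1)
  }, numeric(1))
}

#' Reflagging calibration curve, random-effects (shrinkage) method
#'
#' `G_RE(R) = Phi2_rho(s2, s2) / Phi(s2)` with `s2 = s1 / sqrt(rho)`: the RE
#' Z-scores have null variance `rho / (1 - rho)`. Undefined at `R = 0`, where
#' the shrinkage estimator collapses to zero and nothing is ever flagged.
#'
#' @inheritParams G_fe
#' @export
G_re <- function(R, p = 0.025) {
  zp <- zp_of(p)
  vapply(R, function(r) {
    if (r <= 0)
      stop("G_re is undefined at R = 0: the RE method flags with probability",
           " 0 at the null")
    rho <- rho_of_R(r)
    s2 <- -zp * sqrt(1 - rho) / sqrt(rho)
    pbvnorm(s2, s2, rho) / stats::pnorm(s2)
  }, numeric(1))
}

#' Reflagging calibration curve, FERE method
#'
#' `G_FERE(R) = Phi2_rho(-z_p, -z_p) / p`: the FERE Z-scores are marginally
#' standard normal for every R, so only the correlation changes with R. The
#' empirical-null method shares this curve (the two are asymptotically
#' equivalent under the null model).
#'
#' @inheritParams G_fe
#' @export
G_fere <- function(R, p = 0.025) {
  zp <- zp_of(p)
  vapply(R, function(r) pbvnorm(-zp, -zp, rho_of_R(r)) / p, numeric(1))
}

G_curve <- function(method) {
  switch(toupper(method),
         FE = G_fe,
         RE = G_re,
         FERE = G_fere,
         EN = G_fere,  # EN calibrates against the FERE curve
         stop("unknown method: ", method))
}

#' Contamination mixture specification
#'
#' Provider effects come from `N(0, sigma_b^2)` with probability `1 - pi1`
#' and from an outlier distribution with probability `pi1`. Outliers are
#' one-sided (worse). `point_mass` places them at `gamma * sigma_T`, where
#' `sigma_T = sqrt(sigma_b^2 + sigma_w^2 / n')` is the total standard
#' deviation of a provider mean; `truncated_density` draws them from a
#' half-normal shifted to start at `C` (default `2 sigma_b`).
#'
#' @param pi1 outlier proportion in `[0, 1)`.
#' @param gamma outlier magnitude as a multiple of `sigma_T` (> 0).
#' @param sigma_T total standard deviation of a provider mean (default 1, the
#'   analytic normalization).
#' @param outlier_kind `"point_mass"` (default) or `"truncated_density"`.
#' @param C lower support bound for `truncated_density` outliers; `NULL`
#'   means `2 sigma_b`, resolved by the simulator.
#' @return an object of class `mixture_spec`.
#' @export
mixture_spec <- function(pi1, gamma = 2, sigma_T = 1,
                         outlier_kind = c("point_mass", "truncated_density"),
                         C = NULL) {
  outlier_kind <- match.arg(outlier_kind)
  if (pi1 < 0 || pi1 >= 1) stop("pi1 must be in [0, 1)")
  if (gamma <= 0) stop("gamma must be > 0")
  if (sigma_T <= 0) stop("sigma_T must be > 0")
  structure(list(pi1 = pi1, gamma = gamma, sigma_T = sigma_T,
                 outlier_kind = outlier_kind, C = C),
            class = "mixture_spec")
}

#' Mixture reflagging probability under contamination
#'
#' The FERE reflagging probability when a fraction `pi1` of providers carry a
#' fixed effect `gamma * sigma_T`:
#' \deqn{\theta(R) = \frac{\pi_0 \Phi_{2,\rho}(-z_p, -z_p) + \pi_1 \Phi(s)^2}
#'                        {\pi_0 \Phi(-z_p) + \pi_1 \Phi(s)},}
#' with `s = -z_p / sqrt(1 - rho) + gamma / sqrt(2 - 2R)`. Given the fixed
#' outlier effect the two half-sample Z-scores are independent, hence the
#' squared univariate tail in the numerator.
#'
#' @param R IUR in `[0, 1)`.
#' @param mix a [mixture_spec()] with `outlier_kind = "point_mass"`.
#' @param p one-sided flagging level.
#' @return the reflagging probability.
#' @export
mixture_theta <- function(R, mix, p = 0.025) {
  stopifnot(inherits(mix, "mixture_spec"))
  if (mix$outlier_kind != "point_mass")
    stop("no closed form for truncated_density outliers; ",
         "use the split-reflag simulation route")
  zp <- zp_of(p)
  vapply(R, function(r) {
    rho <- rho_of_R(r)
    s <- -zp / sqrt(1 - rho) + mix$gamma / sqrt(2 - 2 * r)
    pi1 <- mix$pi1
    num <- (1 - pi1) * pbvnorm(-zp, -zp, rho) + pi1 * stats::pnorm(s)^2
    den <- (1 - pi1) * p + pi1 * stats::pnorm(s)
    num / den
  }, numeric(1))
}

#' Invert a calibration curve: the PIUR for a given reflagging rate
#'
#' Solves `G_method(R) = theta` for R on `[0, 1)` by bracketed root finding
#' to `|G(R) - theta| <= 1e-8`. Rates at or below the curve's value at 0
#' clamp to 0; rates at or above 1 clamp to `1 - 1e-9`.
#'
#' @param theta reflagging rate in `[0, 1]`.
#' @param p one-sided flagging level.
#' @param method one of `"FE"`, `"RE"`, `"FERE"`, `"EN"` (EN uses the FERE
#'   curve).
#' @return an object of class `piur_result` with elements `piur`,
#'   `theta_hat`, `method`, `p`, `clamped`, `n_flagged_A`.
#' @export
piur_from_theta <- function(theta, p = 0.025, method = "FERE") {
  stopifnot(is.numeric(theta), length(theta) == 1L)
  if (is.na(theta) || theta < 0 || theta > 1)
    stop("theta must be a probability in [0, 1]")
  G <- G_curve(method)
  # G_re underflows to 0/0 below R ~ 0.006 (the RE flag rate vanishes);
  # rates at or below the curve there clamp to 0 like the other methods.
  lower <- if (toupper(method) == "RE") 0.006 else 0
  upper <- 1 - 1e-9
  g0 <- G(lower, p)
  res <- if (theta <= g0) {
    list(piur = 0, clamped = TRUE)
  } else if (theta >= G(upper, p)) {
    list(piur = upper, clamped = TRUE)
  } else {
    root <- stats::uniroot(function(r) G(r, p) - theta, c(lower, upper),
                           tol = .Machine$double.eps^0.75)$root
    if (abs(G(root, p) - theta) > 1e-8)
      stop("root polish failed: |G(R) - theta| > 1e-8")
    list(piur = root, clamped = FALSE)
  }
  structure(list(piur = res$piur, theta_hat = theta, method = toupper(method),
                 p = p, clamped = res$clamped, n_flagged_A = NA_integer_),
            class = "piur_result")
}

#' @export
print.piur_result <- function(x, ...) {
  cat(sprintf("PIUR (%s, one-sided p = %g): %.4f\n", x$method, x$p, x$piur))
  cat(sprintf("  reflagging rate theta = %.4f%s\n", x$theta_hat,
              if (x$clamped) "  [clamped]" else ""))
  if (!is.na(x$n_flagged_A))
    cat(sprintf("  flag events conditioned on: %d\n", x$n_flagged_A))
  invisible(x)
}

#' Theoretical PIUR under the contamination model
#'
#' Composes [mixture_theta()] with the FERE inversion: the PIUR an infinitely
#' large study with outlier contamination `(pi1, gamma)` and true IUR `R`
#' would produce. With `pi1 = 0` the mixture collapses to the null curve and
#' the composition recovers `R` (no-outlier identity).
#'
#' @inheritParams mixture_theta
#' @return numeric PIUR value(s), same length as `R`.
#' @export
theoretical_piur <- function(R, mix, p = 0.025) {
  vapply(R, function(r) {
    piur_from_theta(mixture_theta(r, mix, p), p, "FERE")$piur
  }, numeric(1))
}

#' Analytic PIUR grid under contamination
#'
#' Evaluates [theoretical_piur()] over a grid of IUR values, outlier
#' proportions and magnitudes (default: the canonical 3 x 4 x 3 grid at
#' one-sided p = 0.025, with `sigma_T = 1`).
#'
#' @param p one-sided flagging level.
#' @param iur IUR grid.
#' @param pi1 outlier-proportion grid.
#' @param gamma outlier-magnitude grid (multiples of `sigma_T`).
#' @return a data.frame with columns `iur`, `pi1`, `gamma`, `theta`, `piur`.
#' @export
piur_table1 <- function(p = 0.025, iur = c(0, 0.25, 0.5),
                        pi1 = c(0, 0.01, 0.02, 0.05), gamma = c(2, 3, 4)) {
  grid <- expand.grid(iur = iur, gamma = gamma, pi1 = pi1,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$pi1, grid$iur, grid$gamma), ]
  grid$theta <- NA_real_
  grid$piur <- NA_real_
  for (i in seq_len(nrow(grid))) {
    mix <- mixture_spec(pi1 = grid$pi1[i], gamma = grid$gamma[i])
    grid$theta[i] <- mixture_theta(grid$iur[i], mix, p)
    grid$piur[i] <- piur_from_theta(grid$theta[i], p, "FERE")$piur
  }
  rownames(grid) <- NULL
  grid
}
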