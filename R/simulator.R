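# Synthetic panels from the contamination model: provider effects drawn from
# N(0, sigma_b^2) with probability 1 - pi1 and from a one-sided outlier
# distribution with probability pi1; patient noise N(0, sigma_w^2).

#' Provider-size model
#'
#' `fixed` gives every provider the same size; `normal_rounded` rounds
#' normal draws to integers and floors small values, emulating the skewed
#' size distribution of real facility panels (default mean 100, sd 50,
#' floor 10).
#'
#' @param kind `"fixed"` or `"normal_rounded"`.
#' @param n_fixed common size for `kind = "fixed"`.
#' @param mean,sd normal parameters for `kind = "normal_rounded"`.
#' @param floor minimum size after rounding.
#' @return an object of class `size_model`.
#' @export
size_model <- function(kind = c("fixed", "normal_rounded"), n_fixed = 100L,
                       mean = 100, sd = 50, floor = 10L) {
  kind <- match.arg(kind)
  stopifnot(n_fixed >= 1L, floor >= 1L, sd >= 0)
  structure(list(kind = kind, n_fixed = as.integer(n_fixed), mean = mean,
                 sd = sd, floor = as.integer(floor)),
            class = "size_model")
}

#' Draw provider sizes
#'
#' @param sm a [size_model()].
#' @param m number of providers (>= 2).
#' @return integer vector of sizes, all >= the model floor.
#' @export
sample_sizes <- function(sm, m) {
  stopifnot(inherits(sm, "size_model"), m >= 2L)
  if (sm$kind == "fixed") return(rep.int(sm$n_fixed, m))
  sz <- as.integer(round(stats::rnorm(m, sm$mean, sm$sd)))
  sz[sz < sm$floor] <- sm$floor
  sz
}

#' Between-provider variance for a target overall IUR
#'
#' Inverts the overall-IUR definition on the realized size vector:
#' `sigma_b^2 = (sigma_w^2 / n') * R / (1 - R)`.
#'
#' @param target_iur desired overall IUR in `[0, 1)`.
#' @param sigma_w2 within-provider variance.
#' @param sizes realized provider sizes.
#' @return `sigma_b^2`.
#' @export
resolve_sigma_b2 <- function(target_iur, sigma_w2, sizes) {
  if (target_iur < 0 || target_iur >= 1) stop("target_iur must be in [0, 1)")
  (sigma_w2 / n_prime(sizes)) * target_iur / (1 - target_iur)
}

#' Draw provider effects from the contamination mixture
#'
#' Each provider is independently an outlier with probability `pi1`.
#' Non-outliers draw `alpha ~ N(0, sigma_b2)`. Point-mass outliers sit at
#' `gamma * sigma_T`; truncated-density outliers draw from a half-normal
#' shifted to start at `C` (default `2 sigma_b`), scaled so the mean outlier
#' effect is `gamma * sigma_T`.
#'
#' @param m number of providers.
#' @param sigma_b2 null between-provider variance.
#' @param mix a [mixture_spec()]; its `sigma_T` must be resolved to the
#'   panel's total standard deviation.
#' @return a list (class `sim_truth`) with `alphas`, `outlier_flags`,
#'   `sigma_b2`, `sigma_T`, `mix`.
#' @export
sample_provider_effects <- function(m, sigma_b2, mix) {
  stopifnot(inherits(mix, "mixture_spec"), m >= 1L, sigma_b2 >= 0)
  out <- stats::runif(m) < mix$pi1
  alphas <- stats::rnorm(m, 0, sqrt(sigma_b2))
  n_out <- sum(out)
  if (n_out > 0L) {
    target <- mix$gamma * mix$sigma_T
    if (mix$outlier_kind == "point_mass") {
      alphas[out] <- target
    } else {
      C <- if (is.null(mix$C)) 2 * sqrt(sigma_b2) else mix$C
      if (C <= 0)
        stop("truncated_density outliers need a positive support bound C")
      if (target <= C)
        stop("gamma * sigma_T must exceed the support bound C = ", signif(C, 4))
      scale <- (target - C) * sqrt(pi / 2)  # half-normal mean matches target
      alphas[out] <- C + abs(stats::rnorm(n_out, 0, scale))
    }
  }
  structure(list(alphas = alphas, outlier_flags = out, sigma_b2 = sigma_b2,
                 sigma_T = mix$sigma_T, mix = mix),
            class = "sim_truth")
}

#' Simulate a provider panel from the contamination model
#'
#' Generates `y = mu + alpha_i + X beta + eps` with `eps ~ N(0, sigma_w2)`.
#' Either `target_iur` (converted through the realized `n'`) or `sigma_b2`
#' fixes the between-provider variance. Outlier magnitudes are multiples of
#' the realized `sigma_T = sqrt(sigma_b2 + sigma_w2 / n')`. When `beta` is
#' supplied, covariates are drawn as `confounding * alpha_i + N(0, 1)`, so
#' provider-level covariate means correlate with the provider effect
#' (exercising the fixed-effects beta estimator).
#'
#' @param m number of providers.
#' @param sm a [size_model()].
#' @param sigma_w2 within-provider variance (default 1).
#' @param target_iur overall IUR to aim for (exactly one of `target_iur`,
#'   `sigma_b2`).
#' @param sigma_b2 between-provider variance, alternatively.
#' @param pi1 outlier proportion.
#' @param gamma outlier magnitude in `sigma_T` units.
#' @param outlier_kind passed to [mixture_spec()].
#' @param mu grand mean (default 0).
#' @param beta optional covariate coefficient vector.
#' @param confounding provider-effect loading on covariate means.
#' @param seed optional integer seed (local to this call).
#' @return a list with `panel` (a [provider_panel()]) and `truth`
#'   (a `sim_truth` whose `components` element holds the generating
#'   [variance_components()]).
#' @export
simulate_panel <- function(m = 1000L, sm = size_model("fixed", 100L),
                           sigma_w2 = 1, target_iur = NULL, sigma_b2 = NULL,
                           pi1 = 0, gamma = 4,
                           outlier_kind = "point_mass",
                           mu = 0, beta = NULL, confounding = 0,
                           seed = NULL) {
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_rng(old), add = TRUE)
    set.seed(seed)
  }
  if (is.null(target_iur) == is.null(sigma_b2))
    stop("supply exactly one of target_iur or sigma_b2")
  sizes <- sample_sizes(sm, m)
  np <- n_prime(sizes)
  if (is.null(sigma_b2))
    sigma_b2 <- resolve_sigma_b2(target_iur, sigma_w2, sizes)
  sigma_T <- sqrt(sigma_b2 + sigma_w2 / np)
  mix <- if (pi1 > 0) {
    mixture_spec(pi1 = pi1, gamma = gamma, sigma_T = sigma_T,
                 outlier_kind = outlier_kind)
  } else {
    mixture_spec(pi1 = 0, gamma = max(gamma, 1e-6), sigma_T = sigma_T)
  }
  truth <- sample_provider_effects(m, sigma_b2, mix)
  ids <- sprintf("P%05d", seq_len(m))
  id <- rep(ids, sizes)
  alpha_long <- rep(truth$alphas, sizes)
  N <- length(id)
  eps <- stats::rnorm(N, 0, sqrt(sigma_w2))
  y <- mu + alpha_long + eps
  df <- data.frame(provider_id = id, y = y, stringsAsFactors = FALSE)
  covs <- character()
  if (!is.null(beta) && length(beta)) {
    covs <- paste0("x", seq_along(beta))
    X <- matrix(stats::rnorm(N * length(beta)), N, length(beta))
    X <- X + confounding * alpha_long
    df$y <- df$y + as.numeric(X %*% beta)
    for (k in seq_along(beta)) df[[covs[k]]] <- X[, k]
  }
  panel <- provider_panel(df, covariates = covs)
  truth$components <- variance_components(
    mu = mu, beta = if (is.null(beta)) numeric() else beta,
    sigma_b2 = sigma_b2, sigma_w2 = sigma_w2)
  truth$sizes <- sizes
  truth$n_prime <- np
  list(panel = panel, truth = truth)
}

# Restore (or remove) the global RNG state after a locally seeded section.
restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

#' Write a simulated panel to CSV
#'
#' Columns `provider_id`, `y` and any covariates, in the schema expected by
#' [read_panel()].
#'
#' @param panel a [provider_panel()].
#' @param path output path.
#' @export
write_panel <- function(panel, path) {
  cols <- c("provider_id", "y", attr(panel, "covariates"))
  utils::write.csv(as.data.frame(panel)[, cols, drop = FALSE], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
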