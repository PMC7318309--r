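# Standardized-ratio quality measures (SMR/SRR style): per provider an
# observed event count O_i and a model-based expected count E_i; under the
# null that the provider's rate equals the population rate, O_i is
# approximately Poisson with mean E_i. The PIUR machinery applies through
# FE-type Z-scores (O - E)/sqrt(E) and the empirical null.

#' Standardized ratio O/E
#'
#' @param O observed event count(s) (non-negative).
#' @param E expected count(s) (> 0).
#' @return `O / E`; vectorized.
#' @export
standardized_ratio <- function(O, E) {
  if (any(E <= 0)) stop("expected counts must be > 0")
  if (any(O < 0)) stop("observed counts must be >= 0")
  O / E
}

#' Upper-tail Poisson P-value for an observed count
#'
#' `Pr(Poisson(E) >= O)` under the null that the provider's event rate is the
#' population rate; `mid_p = TRUE` gives `Pr(> O) + Pr(= O) / 2`, which is
#' less conservative for discrete counts.
#'
#' @param O observed count(s).
#' @param E expected count(s) (> 0).
#' @param mid_p use the mid-P variant.
#' @return upper-tail probability; vectorized.
#' @export
poisson_pvalue <- function(O, E, mid_p = FALSE) {
  if (any(E <= 0)) stop("expected counts must be > 0")
  if (mid_p) {
    stats::ppois(O, E, lower.tail = FALSE) + 0.5 * stats::dpois(O, E)
  } else {
    stats::ppois(O - 1, E, lower.tail = FALSE)
  }
}

#' FE-type Z-score for a count measure
#'
#' Default is the Poisson-approximation score `(O - E) / sqrt(E)`;
#' `type = "exact"` converts the exact upper-tail mid-P Poisson probability
#' to a normal quantile, which behaves better for small expecteds.
#'
#' @param O observed count(s).
#' @param E expected count(s) (> 0).
#' @param type `"approx"` (default) or `"exact"`.
#' @return the Z-score(s); vectorized.
#' @export
count_z <- function(O, E, type = c("approx", "exact")) {
  type <- match.arg(type)
  if (any(E <= 0)) stop("expected counts must be > 0")
  if (type == "approx") return((O - E) / sqrt(E))
  p <- pmin(pmax(poisson_pvalue(O, E, mid_p = TRUE), 1e-15), 1 - 1e-15)
  stats::qnorm(p, lower.tail = FALSE)
}

#' Construct a count-measure panel
#'
#' Patient-level (or discharge-level) event/expected pairs nested within
#' providers. Ratio-only data (per-provider O and E without patient rows)
#' cannot be split and so cannot produce a PIUR.
#'
#' @param data a data.frame with columns `provider_id`, `y` (0/1 or small
#'   count) and `e` (patient-level expected, > 0).
#' @return an object of class `count_panel` (a `data.table`).
#' @export
count_panel <- function(data) {
  need <- c("provider_id", "y", "e")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    if (all(c("O", "E") %in% names(data)))
      stop("ratio-only data (O, E columns): patient-level rows are needed ",
           "to split; PIUR is unavailable")
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  dt <- data.table::data.table(provider_id = as.character(data$provider_id),
                               y = as.numeric(data$y),
                               e = as.numeric(data$e))
  if (any(!is.finite(dt$y)) || any(dt$y < 0))
    stop("event counts must be finite and >= 0")
  if (any(!is.finite(dt$e)) || any(dt$e <= 0))
    stop("patient-level expecteds must be finite and > 0")
  data.table::setkey(dt, provider_id)
  data.table::setattr(dt, "class", c("count_panel", class(dt)))
  dt
}

#' Per-provider totals of a count panel
#'
#' @param counts a [count_panel()].
#' @return data.frame with `provider_id`, `O`, `E`, `n`, `ratio`.
#' @export
count_totals <- function(counts) {
  O <- tapply(counts$y, counts$provider_id, sum)
  E <- tapply(counts$e, counts$provider_id, sum)
  n <- tapply(counts$y, counts$provider_id, length)
  data.frame(provider_id = names(O), O = as.numeric(O), E = as.numeric(E),
             n = as.integer(n), ratio = as.numeric(O) / as.numeric(E),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Simulate a count-measure panel under the contamination model
#'
#' Patient-level expecteds are Gamma-distributed with mean `mean_e`; events
#' are Poisson with mean `e * exp(alpha_i)`, where the log-rate provider
#' effects follow the contamination mixture: null effects
#' `N(0, sigma_b2_log)`, outliers at `gamma * sigma_T` with `sigma_T` the
#' null standard deviation of the FE count Z-score's log-rate analog,
#' `sqrt(sigma_b2_log + 1 / Ebar)` with `Ebar` the mean provider total
#' expected.
#'
#' @param m number of providers.
#' @param sm a [size_model()] for patients per provider.
#' @param mean_e mean patient-level expected (default 0.1).
#' @param sigma_b2_log between-provider variance of the log rate.
#' @param pi1 outlier proportion.
#' @param gamma outlier magnitude in `sigma_T` units.
#' @param seed optional integer seed, local to this call.
#' @return a list with `counts` (a [count_panel()]) and `truth`
#'   (a `sim_truth`).
#' @export
simulate_count_panel <- function(m = 1000L, sm = size_model("fixed", 100L),
                                 mean_e = 0.1, sigma_b2_log = 0, pi1 = 0,
                                 gamma = 2, seed = NULL) {
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_rng(old), add = TRUE)
    set.seed(seed)
  }
  sizes <- sample_sizes(sm, m)
  Ebar <- mean(sizes) * mean_e
  sigma_T <- sqrt(sigma_b2_log + 1 / Ebar)
  mix <- mixture_spec(pi1 = pi1, gamma = gamma, sigma_T = sigma_T)
  truth <- sample_provider_effects(m, sigma_b2_log, mix)
  ids <- sprintf("F%05d", seq_len(m))
  id <- rep(ids, sizes)
  # shape 2 gives mild right skew, as in real case-mix expecteds
  e <- stats::rgamma(length(id), shape = 2, rate = 2 / mean_e)
  e <- pmax(e, mean_e / 100)
  lam <- e * exp(rep(truth$alphas, sizes))
  y <- stats::rpois(length(id), lam)
  counts <- count_panel(data.frame(provider_id = id, y = y, e = e,
                                   stringsAsFactors = FALSE))
  truth$sizes <- sizes
  list(counts = counts, truth = truth)
}

# Internal: split layout for count panels (same machinery as the linear
# route but tracking (y, e) sums per half).
count_layout <- function(counts, min_expected = 3) {
  tot <- count_totals(counts)
  eligible <- tot$provider_id[tot$E >= min_expected & tot$n >= 2L]
  dropped <- setdiff(tot$provider_id, eligible)
  if (length(dropped))
    message(length(dropped), " provider(s) excluded (total expected < ",
            min_expected, " or fewer than 2 patients)")
  if (length(eligible) < 2L)
    stop("fewer than 2 providers eligible for splitting")
  keep <- counts$provider_id %in% eligible
  pid <- factor(counts$provider_id[keep], levels = eligible)
  ord0 <- order(as.integer(pid))
  y <- counts$y[keep][ord0]
  e <- counts$e[keep][ord0]
  pid_sorted <- as.integer(pid)[ord0]
  n_i <- as.integer(table(pid))
  m <- length(n_i)
  ends <- cumsum(n_i)
  list(y = y, e = e, pid = pid_sorted, ids = eligible, n_i = n_i, m = m,
       starts = ends - n_i + 1L, ends = ends, excluded = dropped)
}

# Internal: one random half-split of a count layout; per-provider (O, E)
# for each half. Patients (with their expecteds) are partitioned; events
# follow their patients, so O_A + O_B = O and E_A + E_B = E exactly.
draw_count_split <- function(lay) {
  u <- stats::runif(length(lay$y))
  ord <- order(lay$pid, u, method = "radix")
  y_perm <- lay$y[ord]
  e_perm <- lay$e[ord]
  k <- lay$n_i %/% 2L +
    ifelse(lay$n_i %% 2L == 1L, stats::rbinom(lay$m, 1L, 0.5), 0L)
  csy <- cumsum(y_perm); cse <- cumsum(e_perm)
  prevy <- c(0, csy[lay$ends[-lay$m]]); preve <- c(0, cse[lay$ends[-lay$m]])
  OA <- csy[lay$starts - 1L + k] - prevy
  EA <- cse[lay$starts - 1L + k] - preve
  Otot <- csy[lay$ends] - prevy
  Etot <- cse[lay$ends] - preve
  list(OA = OA, EA = EA, OB = Otot - OA, EB = Etot - EA)
}

#' PIUR for a count measure via the empirical null
#'
#' The split-half algorithm on patient-level (O, E) data: each split
#' partitions every provider's patients (with their expecteds) into halves,
#' computes per-half FE count Z-scores, fits the empirical null within each
#' half, flags, pools the reflagging rate over providers and splits (both
#' conditional directions), and inverts the FERE calibration curve.
#' Providers with total expected below `min_expected` (judged on the full
#' panel) are excluded.
#'
#' @param counts a [count_panel()].
#' @param p one-sided flagging level.
#' @param n_splits number of random splits.
#' @param min_expected exclusion threshold on full-panel expected events.
#' @param z_type `"approx"` or `"exact"` (see [count_z()]).
#' @param en_window,en_fit empirical-null controls.
#' @param seed optional integer seed, local to this call.
#' @return a `piur_result` (method `"EN"`) with the `split_reflag_estimate`
#'   in `$reflag` and the full-panel empirical null in `$null`.
#' @export
piur_counts <- function(counts, p = 0.025, n_splits = 200L, min_expected = 3,
                        z_type = "approx", en_window = c(0.10, 0.90),
                        en_fit = "truncated_mle", seed = NULL) {
  stopifnot(inherits(counts, "count_panel"), n_splits >= 1L)
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_rng(old), add = TRUE)
    set.seed(seed)
  }
  config <- flag_config("EN", p = p)
  lay <- count_layout(counts, min_expected)
  times_flagged <- integer(lay$m)
  times_reflag <- integer(lay$m)
  for (s in seq_len(n_splits)) {
    sp <- draw_count_split(lay)
    zA <- count_z(sp$OA, sp$EA, z_type)
    zB <- count_z(sp$OB, sp$EB, z_type)
    fA <- half_flags(zA, config, en_window, en_fit)
    fB <- half_flags(zB, config, en_window, en_fit)
    times_flagged <- times_flagged + fA + fB
    times_reflag <- times_reflag + 2L * (fA & fB)
  }
  flagged_total <- sum(times_flagged)
  if (flagged_total == 0L)
    stop("reflagging rate undefined: no provider was ever flagged")
  theta <- sum(times_reflag) / flagged_total
  res <- piur_from_theta(theta, p, "EN")
  res$n_flagged_A <- flagged_total
  res$reflag <- structure(
    list(theta_hat = theta, n_splits = as.integer(n_splits),
         flagged_A_total = flagged_total,
         reflagged_total = sum(times_reflag),
         per_provider = data.frame(provider_id = lay$ids,
                                   times_flagged_A = times_flagged,
                                   times_reflagged = times_reflag,
                                   stringsAsFactors = FALSE),
         rng_seed = if (is.null(seed)) NA_integer_ else seed,
         method = "EN", p = p, excluded = lay$excluded),
    class = "split_reflag_estimate")
  tot <- count_totals(counts)
  tot <- tot[tot$provider_id %in% lay$ids, ]
  res$null <- fit_empirical_null(count_z(tot$O, tot$E, z_type),
                                 quantile_window = en_window,
                                 fit_method = en_fit)
  res
}
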