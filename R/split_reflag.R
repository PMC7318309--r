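# Split-half reflagging: repeatedly partition each provider's patients into
# two near-equal halves, flag each half, and estimate the probability of
# being flagged in one half given a flag in the other. Calibrating that rate
# onto the IUR scale yields the empirical PIUR.

# Internal: precompute sorted-order bookkeeping for fast repeated splits.
# Returns NULL-free list: y sorted by provider, block starts/ends, sizes.
split_layout <- function(panel, min_split_size = 2L) {
  panel <- ensure_adjusted(panel)
  sz_all <- provider_sizes(panel)
  eligible <- names(sz_all)[sz_all >= min_split_size]
  excluded <- setdiff(names(sz_all), eligible)
  if (length(excluded))
    message(length(excluded), " provider(s) below min_split_size excluded ",
            "from splitting")
  if (length(eligible) < 2L)
    stop("fewer than 2 providers eligible for splitting")
  keep <- panel$provider_id %in% eligible
  pid <- factor(panel$provider_id[keep], levels = eligible)
  y <- adjusted_y(panel)[keep]
  ord0 <- order(as.integer(pid))
  y <- y[ord0]
  pid_sorted <- as.integer(pid)[ord0]
  n_i <- as.integer(table(pid))
  m <- length(n_i)
  ends <- cumsum(n_i)
  starts <- ends - n_i + 1L
  list(y = y, pid = pid_sorted, ids = eligible, n_i = n_i, m = m,
       starts = starts, ends = ends, excluded = excluded,
       block = rep.int(seq_len(m), n_i), rank = sequence(n_i))
}

# Internal: one random half-split on a layout. Returns per-provider half
# means and sizes. The larger half of an odd-sized provider goes to A or B
# by a fair coin.
draw_split <- function(lay) {
  u <- stats::runif(length(lay$y))
  ord <- order(lay$pid, u, method = "radix")
  y_perm <- lay$y[ord]
  k <- lay$n_i %/% 2L +
    ifelse(lay$n_i %% 2L == 1L, stats::rbinom(lay$m, 1L, 0.5), 0L)
  cs <- cumsum(y_perm)
  tot <- cs[lay$ends] - c(0, cs[lay$ends[-lay$m]])
  csA <- cs[lay$starts - 1L + k] - c(0, cs[lay$ends[-lay$m]])
  nA <- k
  nB <- lay$n_i - k
  list(meanA = csA / nA, meanB = (tot - csA) / nB, nA = nA, nB = nB,
       ord = ord, k = k)
}

# Internal: Z-scores for one half given components and the method.
half_z <- function(means, n, method, sb2, sw2) {
  switch(method,
         FE = z_fe(means, sw2, n),
         RE = z_re(z_fe(means, sw2, n), sb2 / (sb2 + sw2 / n)),
         FERE = z_fere(means, sb2, sw2, n),
         EN = z_fe(means, sw2, n))
}

# Internal: flags for one half's Z-scores.
half_flags <- function(z, config, en_window, en_fit) {
  if (config$method == "EN") {
    null <- fit_empirical_null(z, quantile_window = en_window,
                               fit_method = en_fit)
    thr <- null$mu_M + config$z_p * null$sigma_M
    lo <- null$mu_M - config$z_p * null$sigma_M
  } else {
    thr <- config$z_p
    lo <- -config$z_p
  }
  if (config$direction == "worse") z > thr else z < lo
}

#' Randomly split a panel into two half-panels
#'
#' Each eligible provider's patients are partitioned uniformly at random
#' into halves of sizes `ceiling(n_i/2)` and `floor(n_i/2)`; for odd sizes a
#' fair coin decides which half is larger. Providers below `min_split_size`
#' are excluded (with a message), not an error.
#'
#' @param panel a [provider_panel()].
#' @param min_split_size smallest provider size eligible for splitting.
#' @return a list with `A` and `B` (two [provider_panel()]s, disjoint and
#'   exhaustive for the eligible providers) and `excluded` (provider ids).
#' @export
split_panel <- function(panel, min_split_size = 2L) {
  panel <- ensure_adjusted(panel)
  lay <- split_layout(panel, min_split_size)
  sp <- draw_split(lay)
  inA_sorted <- lay$rank <= sp$k[lay$block]
  idxA <- sp$ord[inA_sorted]
  take <- function(idx) {
    df <- data.frame(provider_id = lay$ids[lay$pid[idx]], y = lay$y[idx],
                     stringsAsFactors = FALSE)
    pp <- provider_panel(df)
    data.table::set(pp, j = "y_adj", value = pp$y)  # layout y is adjusted
    pp
  }
  list(A = take(idxA), B = take(sp$ord[!inA_sorted]), excluded = lay$excluded)
}

#' One split-and-flag replicate
#'
#' Performs a single random half-split and flags each provider in both
#' halves using the configured method, half-sample sizes, and the supplied
#' (or ANOVA-estimated) variance components. For EN the null is refitted
#' within each half's Z-score collection.
#'
#' @param panel a [provider_panel()].
#' @param config a [flag_config()].
#' @param components [variance_components()]; estimated from the full panel
#'   when `NULL`.
#' @param min_split_size,en_window,en_fit see [estimate_theta()].
#' @return a data.frame with `provider_id`, `z_A`, `z_B`, `flagged_A`,
#'   `flagged_B`.
#' @export
reflag_once <- function(panel, config = flag_config(), components = NULL,
                        min_split_size = 2L, en_window = c(0.10, 0.90),
                        en_fit = "truncated_mle") {
  panel <- ensure_adjusted(panel)
  comp <- resolve_components(panel, components)
  lay <- split_layout(panel, min_split_size)
  sp <- draw_split(lay)
  zA <- half_z(sp$meanA, sp$nA, config$method, comp$sigma_b2, comp$sigma_w2)
  zB <- half_z(sp$meanB, sp$nB, config$method, comp$sigma_b2, comp$sigma_w2)
  data.frame(provider_id = lay$ids,
             z_A = zA, z_B = zB,
             flagged_A = half_flags(zA, config, en_window, en_fit),
             flagged_B = half_flags(zB, config, en_window, en_fit),
             row.names = NULL, stringsAsFactors = FALSE)
}

# Internal: variance components for split flagging, ANOVA-estimated from the
# full panel unless supplied.
resolve_components <- function(panel, components) {
  if (!is.null(components)) {
    if (is.na(components$sigma_b2) || is.na(components$sigma_w2))
      stop("components must carry sigma_b2 and sigma_w2")
    return(components)
  }
  est <- estimate_variance_components(panel)
  variance_components(mu = 0, beta = numeric(), sigma_b2 = est$sigma_b2,
                      sigma_w2 = est$sigma_w2)
}

#' Empirical split-half reflagging rate
#'
#' Algorithm: repeat `n_splits` random half-splits; in each, flag every
#' provider in both halves; pool flag events over providers and splits and
#' estimate `theta_hat = #(flagged in both) / #(flagged in one)`. Both
#' conditional directions (B given A and A given B) contribute — they are
#' exchangeable by construction, and pooling them halves the Monte-Carlo
#' variance. Variance components are estimated once from the full panel
#' (or supplied); the empirical null, whose scale differs between half and
#' full samples, is refitted within each half.
#'
#' @param panel a [provider_panel()].
#' @param config a [flag_config()].
#' @param n_splits number of random splits (default 200).
#' @param components optional known [variance_components()].
#' @param min_split_size smallest provider size eligible for splitting.
#' @param en_window,en_fit empirical-null controls (EN method only).
#' @param seed optional integer seed, local to this call.
#' @return an object of class `split_reflag_estimate`: `theta_hat` (`NA`
#'   when no provider was ever flagged), `n_splits`, `flagged_A_total`,
#'   `reflagged_total`, `per_provider` (counts data.frame), `rng_seed`,
#'   `method`, `p`, `excluded`.
#' @export
estimate_theta <- function(panel, config = flag_config(), n_splits = 200L,
                           components = NULL, min_split_size = 2L,
                           en_window = c(0.10, 0.90),
                           en_fit = "truncated_mle", seed = NULL) {
  stopifnot(n_splits >= 1L)
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_rng(old), add = TRUE)
    set.seed(seed)
  }
  panel <- ensure_adjusted(panel)
  comp <- resolve_components(panel, components)
  lay <- split_layout(panel, min_split_size)
  times_flagged <- integer(lay$m)
  times_reflag <- integer(lay$m)
  for (s in seq_len(n_splits)) {
    sp <- draw_split(lay)
    zA <- half_z(sp$meanA, sp$nA, config$method, comp$sigma_b2, comp$sigma_w2)
    zB <- half_z(sp$meanB, sp$nB, config$method, comp$sigma_b2, comp$sigma_w2)
    fA <- half_flags(zA, config, en_window, en_fit)
    fB <- half_flags(zB, config, en_window, en_fit)
    times_flagged <- times_flagged + fA + fB
    times_reflag <- times_reflag + 2L * (fA & fB)
  }
  flagged_total <- sum(times_flagged)
  reflag_total <- sum(times_reflag)
  theta <- if (flagged_total > 0L) reflag_total / flagged_total else NA_real_
  structure(list(theta_hat = theta, n_splits = as.integer(n_splits),
                 flagged_A_total = flagged_total,
                 reflagged_total = reflag_total,
                 per_provider = data.frame(provider_id = lay$ids,
                                           times_flagged_A = times_flagged,
                                           times_reflagged = times_reflag,
                                           stringsAsFactors = FALSE),
                 rng_seed = if (is.null(seed)) NA_integer_ else seed,
                 method = config$method, p = config$p,
                 components = comp, excluded = lay$excluded),
            class = "split_reflag_estimate")
}

#' @export
print.split_reflag_estimate <- function(x, ...) {
  cat(sprintf("split-half reflagging (%s, p = %g, %d splits):\n",
              x$method, x$p, x$n_splits))
  if (is.na(x$theta_hat)) {
    cat("  theta_hat undefined: no provider was ever flagged\n")
  } else {
    cat(sprintf("  theta_hat = %.4f  (%d reflag / %d flag events)\n",
                x$theta_hat, x$reflagged_total, x$flagged_A_total))
  }
  invisible(x)
}

#' Empirical profile inter-unit reliability (PIUR)
#'
#' Runs [estimate_theta()] and inverts the configured method's calibration
#' curve at the pooled reflagging rate (the EN method calibrates against the
#' FERE curve). The result carries the reflagging bookkeeping.
#'
#' @inheritParams estimate_theta
#' @return a `piur_result` with extra elements `reflag` (the
#'   `split_reflag_estimate`) and `n_flagged_A` filled in.
#' @export
empirical_piur <- function(panel, config = flag_config(), n_splits = 200L,
                           components = NULL, min_split_size = 2L,
                           en_window = c(0.10, 0.90),
                           en_fit = "truncated_mle", seed = NULL) {
  est <- estimate_theta(panel, config, n_splits = n_splits,
                        components = components,
                        min_split_size = min_split_size,
                        en_window = en_window, en_fit = en_fit, seed = seed)
  if (is.na(est$theta_hat))
    stop("reflagging rate undefined: no provider was ever flagged; ",
         "use a larger panel or a higher p")
  res <- piur_from_theta(est$theta_hat, config$p, config$method)
  res$n_flagged_A <- est$flagged_A_total
  res$reflag <- est
  res
}
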