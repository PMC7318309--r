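# Simulation-study driver: for each contamination configuration, simulate
# panels, and report the ANOVA IUR, the robust empirical-null IUR, the
# theoretical PIUR, and the empirical FERE- and EN-based PIURs.

#' Simulation summary of IUR and PIUR estimators under contamination
#'
#' For every combination of `true_iur` and `pi1`, simulates `reps` panels
#' (outlier magnitude `gamma * sigma_T`) and reports five quantities:
#' `total_iur` (ANOVA estimate), `en_iur` (robust empirical-null estimate),
#' `piur_true` (analytic, from the contamination closed form), and
#' `fere_piur` / `en_piur` (empirical, via split-half reflagging). IUR
#' estimates are averaged over replicates. For the empirical PIURs the
#' reflagging counts are pooled over replicates before the calibration
#' curve is inverted: the per-panel reflagging rate is noisy and its
#' inversion clamp-biased at small m, while the pooled rate is a consistent
#' estimate of the population reflagging probability.
#'
#' @param true_iur vector of target overall IURs.
#' @param pi1 vector of outlier proportions.
#' @param gamma outlier magnitude in `sigma_T` units.
#' @param m providers per panel.
#' @param sm a [size_model()].
#' @param sigma_w2 within-provider variance.
#' @param reps simulated panels per configuration.
#' @param n_splits random splits per panel for the empirical PIURs.
#' @param p one-sided flagging level.
#' @param en_window,en_fit empirical-null controls.
#' @param seed integer seed for the whole table (local to this call).
#' @return a data.frame with one row per configuration: `total_iur`,
#'   `en_iur` (replicate means, with `*_se` when `reps > 1`), `piur_true`,
#'   `fere_piur`, `en_piur` (pooled-count estimates), and the pooled flag
#'   counts `fere_flags`, `en_flags`.
#' @export
piur_sim_table <- function(true_iur = c(0.25, 0.5),
                           pi1 = c(0, 0.01, 0.02, 0.05), gamma = 4,
                           m = 1000L, sm = size_model("fixed", 100L),
                           sigma_w2 = 1, reps = 1L, n_splits = 200L,
                           p = 0.025, en_window = c(0.10, 0.90),
                           en_fit = "truncated_mle", seed = NULL) {
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_rng(old), add = TRUE)
    set.seed(seed)
  }
  grid <- expand.grid(true_iur = true_iur, pi1 = pi1,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$true_iur, grid$pi1), ]
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    R <- grid$true_iur[i]; q1 <- grid$pi1[i]
    piur_true <- if (q1 > 0) {
      theoretical_piur(R, mixture_spec(pi1 = q1, gamma = gamma), p)
    } else R
    iur_mat <- matrix(NA_real_, 2L, reps,
                      dimnames = list(c("total_iur", "en_iur"), NULL))
    fere_counts <- c(flagged = 0, reflagged = 0)
    en_counts <- c(flagged = 0, reflagged = 0)
    for (r in seq_len(reps)) {
      sim <- simulate_panel(m = m, sm = sm, sigma_w2 = sigma_w2,
                            target_iur = R, pi1 = q1, gamma = gamma)
      panel <- risk_adjust(sim$panel,
                           variance_components(mu = 0, beta = numeric()))
      est <- estimate_variance_components(panel)
      zfe <- z_fe(provider_means(panel), est$sigma_w2,
                  provider_sizes(panel))
      en <- fit_empirical_null(zfe, quantile_window = en_window,
                               fit_method = en_fit)
      iur_mat[, r] <- c(est$iur_overall, en_iur(en))
      thf <- estimate_theta(panel, flag_config("FERE", p = p),
                            n_splits = n_splits)
      the <- estimate_theta(panel, flag_config("EN", p = p),
                            n_splits = n_splits, en_window = en_window,
                            en_fit = en_fit)
      fere_counts <- fere_counts + c(thf$flagged_A_total,
                                     thf$reflagged_total)
      en_counts <- en_counts + c(the$flagged_A_total, the$reflagged_total)
    }
    invert <- function(cnt) {
      if (cnt[["flagged"]] == 0) return(NA_real_)
      piur_from_theta(cnt[["reflagged"]] / cnt[["flagged"]], p, "FERE")$piur
    }
    out <- data.frame(true_iur = R, pi1 = q1, gamma = gamma,
                      total_iur = mean(iur_mat["total_iur", ]),
                      en_iur = mean(iur_mat["en_iur", ]),
                      piur_true = piur_true,
                      fere_piur = invert(fere_counts),
                      en_piur = invert(en_counts),
                      fere_flags = fere_counts[["flagged"]],
                      en_flags = en_counts[["flagged"]])
    if (reps > 1L) {
      out$total_iur_se <- stats::sd(iur_mat["total_iur", ]) / sqrt(reps)
      out$en_iur_se <- stats::sd(iur_mat["en_iur", ]) / sqrt(reps)
    }
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
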