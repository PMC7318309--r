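# Shared fixtures, built in code.

# A tiny hand-made panel with known group means.
tiny_panel <- function() {
  provider_panel(data.frame(
    provider_id = c("a", "a", "b", "b", "b", "c", "c"),
    y = c(1, 3, 2, 2, 2, 0, 4)))
}

# A null-model panel with known components, pre-adjusted.
null_panel <- function(m = 100L, n = 50L, iur = 0.25, sigma_w2 = 1,
                       seed = NULL) {
  sim <- simulate_panel(m = m, sm = size_model("fixed", n),
                        sigma_w2 = sigma_w2, target_iur = iur, pi1 = 0,
                        seed = seed)
  list(panel = risk_adjust(sim$panel, variance_components()),
       truth = sim$truth)
}

# Pool reflagging counts over independently simulated panels (one split
# each), so flag events are independent and binomial standard errors apply.
pooled_theta <- function(n_panels, m, n, iur, method, p,
                         sm = size_model("fixed", n)) {
  tot_f <- 0L; tot_r <- 0L
  for (i in seq_len(n_panels)) {
    sim <- simulate_panel(m = m, sm = sm, target_iur = iur, pi1 = 0)
    panel <- risk_adjust(sim$panel, variance_components())
    th <- estimate_theta(panel, flag_config(method, p = p), n_splits = 1L,
                         components = sim$truth$components)
    tot_f <- tot_f + th$flagged_A_total
    tot_r <- tot_r + th$reflagged_total
  }
  list(theta = tot_r / tot_f, flagged = tot_f)
}
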