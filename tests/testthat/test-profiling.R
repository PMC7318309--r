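test_that("Z-score arithmetic and algebraic identities hold", {
  expect_equal(z_fe(0, 1, 100), 0)
  expect_equal(z_fe(0.2, 1, 100), 2)
  expect_equal(z_re(2, 0.25), 1)
  expect_equal(z_re(5, 0), 0)
  expect_equal(z_fere(0.3, 0.05, 1, 25), 1)
  expect_equal(z_fere(0.4, 0, 2, 50), z_fe(0.4, 2, 50))
  expect_error(z_fe(1, 0, 10), "sigma_w2")
  expect_error(z_re(1, 1), "iur_i")
  # z_fere = sqrt(1 - IUR_i) z_fe and z_re = sqrt(IUR_i) z_fe identically
  set.seed(31)
  for (i in 1:25) {
    ybar <- rnorm(1); sb2 <- runif(1, 0, 2); sw2 <- runif(1, 0.1, 3)
    n <- sample(1:500, 1)
    iur_i <- sb2 / (sb2 + sw2 / n)
    zf <- z_fe(ybar, sw2, n)
    expect_equal(z_fere(ybar, sb2, sw2, n), sqrt(1 - iur_i) * zf,
                 tolerance = 1e-12)
    expect_equal(z_re(zf, iur_i), sqrt(iur_i) * zf, tolerance = 1e-12)
  }
})

test_that("FERE Z-scores are marginally standard normal under the null model", {
  set.seed(37)
  sim <- simulate_panel(m = 3000L, sm = size_model("fixed", 40L),
                        target_iur = 0.4, pi1 = 0)
  panel <- risk_adjust(sim$panel, variance_components())
  comp <- sim$truth$components
  z <- z_fere(provider_means(panel), comp$sigma_b2, comp$sigma_w2,
              provider_sizes(panel))
  expect_lt(abs(mean(z)), 0.06)
  expect_lt(abs(stats::var(z) - 1), 0.12)
  # FE scores with sigma_b = 0 are standard normal too
  sim0 <- simulate_panel(m = 3000L, sm = size_model("fixed", 40L),
                         sigma_b2 = 0, pi1 = 0)
  p0 <- risk_adjust(sim0$panel, variance_components())
  z0 <- z_fe(provider_means(p0), 1, provider_sizes(p0))
  expect_equal(stats::var(z0), 1, tolerance = 0.08)
  expect_gt(stats::shapiro.test(sample(z0, 1000))$p.value, 1e-4)
})

test_that("empirical null recovers N(0,1) and is affinely equivariant", {
  set.seed(41)
  z <- rnorm(5000)
  for (fm in c("truncated_mle", "huber")) {
    fit <- fit_empirical_null(z, fit_method = fm)
    expect_equal(fit$mu_M, 0, tolerance = 0.05)
    expect_equal(fit$sigma_M, 1, tolerance = 0.05)
  }
  # affine equivariance
  fit1 <- fit_empirical_null(z)
  fit2 <- fit_empirical_null(1.7 + 2.5 * z)
  expect_equal(fit2$mu_M, 1.7 + 2.5 * fit1$mu_M, tolerance = 0.01)
  expect_equal(fit2$sigma_M, 2.5 * fit1$sigma_M, tolerance = 0.01)
})

test_that("empirical null resists tail contamination where plain moments fail", {
  set.seed(43)
  z <- c(rnorm(4750), rep(6, 250))  # 5% point contamination at +6
  fit <- fit_empirical_null(z)
  expect_equal(fit$sigma_M, 1, tolerance = 0.05)
  expect_gt(stats::sd(z), 1.3)
  # breakdown property: up to 10% contamination moves sigma_M by < 0.1
  for (frac in c(0.02, 0.10)) {
    zc <- c(rnorm(5000 * (1 - frac)), rep(6, 5000 * frac))
    expect_lt(abs(fit_empirical_null(zc)$sigma_M - 1), 0.1)
  }
})

test_that("empirical null fit validates its inputs", {
  expect_error(fit_empirical_null(rnorm(20)), "at least 30")
  expect_error(fit_empirical_null(rnorm(40), quantile_window = c(0.48, 0.52)),
               "fewer than 10")
})

test_that("en_iur converts the robust scale to the IUR scale with clamping", {
  mk <- function(s) structure(list(mu_M = 0, sigma_M = s,
                                   fit_window = c(-1, 1), n_used = 100,
                                   fit_method = "huber"),
                              class = "empirical_null")
  expect_equal(en_iur(mk(1)), 0)
  expect_equal(en_iur(mk(sqrt(2))), 0.5)
  expect_message(val <- en_iur(mk(0.9)), "clamped")
  expect_equal(val, 0)
})

test_that("EN IUR stays near truth under contamination while ANOVA inflates", {
  set.seed(47)
  vals <- replicate(6, {
    sim <- simulate_panel(m = 1000L, sm = size_model("fixed", 100L),
                          target_iur = 0.25, pi1 = 0.05, gamma = 4)
    panel <- risk_adjust(sim$panel, variance_components())
    est <- estimate_variance_components(panel)
    z <- z_fe(provider_means(panel), est$sigma_w2, provider_sizes(panel))
    c(robust = en_iur(fit_empirical_null(z)), anova = est$iur_overall)
  })
  expect_lt(abs(mean(vals["robust", ]) - 0.25), 0.06)
  expect_gt(mean(vals["anova", ]), 0.45)  # ANOVA absorbs the outliers
})

test_that("flagging thresholds follow the method and direction", {
  cfg <- flag_config("FERE", p = 0.025)
  res <- flag_providers(c(a = 1.97, b = 1.9), cfg)
  expect_true(res$flagged[res$provider_id == "a"])
  expect_false(res$flagged[res$provider_id == "b"])
  null <- structure(list(mu_M = 0.1, sigma_M = 1.2, fit_window = c(-2, 2),
                         n_used = 100, fit_method = "huber"),
                    class = "empirical_null")
  resEN <- flag_providers(c(a = 2.0, b = 2.5), flag_config("EN"), null)
  expect_false(resEN$flagged[resEN$provider_id == "a"])  # threshold 2.452
  expect_true(resEN$flagged[resEN$provider_id == "b"])
  expect_error(flag_providers(1:3, flag_config("EN")), "empirical null")
  # direction = better mirrors to the lower tail
  resB <- flag_providers(c(a = -2.2, b = 0), flag_config("FERE",
                                                         direction = "better"))
  expect_true(resB$flagged[resB$provider_id == "a"])
  expect_false(resB$flagged[resB$provider_id == "b"])
  # monotonicity: raising z can only turn a flag on
  zgrid <- seq(-3, 3, by = 0.1)
  fl <- flag_providers(zgrid, cfg)$flagged
  expect_true(all(diff(fl) >= 0))
})

test_that("FERE holds its level and EN agrees with FERE under the null model", {
  set.seed(53)
  sim <- simulate_panel(m = 2000L, sm = size_model("fixed", 100L),
                        target_iur = 0.4, pi1 = 0)
  panel <- risk_adjust(sim$panel, variance_components())
  fere <- profile_panel(panel, flag_config("FERE", p = 0.025))
  expect_lt(abs(mean(fere$flagged) - 0.025), 0.012)
  en <- profile_panel(panel, flag_config("EN", p = 0.025))
  agree <- mean(fere$flagged == en$flagged[match(fere$provider_id,
                                                 en$provider_id)])
  expect_gte(agree, 0.95)
})

test_that("stratified empirical nulls handle strong size heterogeneity", {
  set.seed(59)
  sim <- simulate_panel(m = 1500L, sm = size_model("normal_rounded"),
                        target_iur = 0.5, pi1 = 0)
  panel <- risk_adjust(sim$panel, variance_components())
  res <- profile_panel(panel, flag_config("EN"), en_strata = 4L)
  expect_equal(nrow(res), 1500L)
  expect_length(attr(res, "null"), 4L)
  expect_lt(abs(mean(res$flagged) - 0.025), 0.02)
})
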