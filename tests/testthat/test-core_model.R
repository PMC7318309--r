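test_that("n_prime matches direct arithmetic and reduces to n for equal sizes", {
  expect_equal(n_prime(rep(100, 1000)), 100)
  expect_equal(n_prime(c(2, 2)), 2)
  sizes <- c(10, 50, 200)
  expect_equal(n_prime(sizes),
               (260 - (100 + 2500 + 40000) / 260) / 2,
               tolerance = 1e-12)
  expect_error(n_prime(5), "at least 2")
})

test_that("n_prime is bounded by the mean size, with equality iff balanced", {
  set.seed(101)
  for (i in 1:20) {
    sizes <- sample(1:300, sample(2:50, 1), replace = TRUE)
    np <- n_prime(sizes)
    if (length(unique(sizes)) == 1L) {
      expect_equal(np, mean(sizes))
    } else {
      expect_lt(np, mean(sizes))
    }
  }
})

test_that("within-provider beta is exact for an exact linear relation and
           immune to provider-level offsets", {
  df <- data.frame(provider_id = rep(c("u", "v"), each = 4),
                   x = c(1, 2, 3, 4, 2, 4, 6, 8))
  df$y <- 2 * df$x + ifelse(df$provider_id == "u", 10, -7)
  panel <- provider_panel(df, covariates = "x")
  expect_equal(unname(estimate_beta_fixed_effects(panel)), 2, tolerance = 1e-10)
  # no covariates -> empty vector
  expect_identical(estimate_beta_fixed_effects(tiny_panel()), numeric())
})

test_that("within-provider beta equals the provider-indicator least-squares fit
           and beats the pooled fit under confounding", {
  set.seed(7)
  sim <- simulate_panel(m = 15L, sm = size_model("fixed", 30L),
                        target_iur = 0.3, beta = c(1.5, -0.5),
                        confounding = 8)
  panel <- sim$panel
  beta_hat <- estimate_beta_fixed_effects(panel)
  # small-instance oracle: one indicator per provider
  df <- as.data.frame(panel)
  oracle <- stats::lm(y ~ 0 + factor(provider_id) + x1 + x2, data = df)
  expect_equal(unname(beta_hat),
               unname(stats::coef(oracle)[c("x1", "x2")]),
               tolerance = 1e-8)
  # the pooled (non-demeaned) regression absorbs the provider effects
  pooled <- stats::coef(stats::lm(y ~ x1 + x2, data = df))[c("x1", "x2")]
  expect_gt(abs(pooled[["x1"]] - 1.5), abs(beta_hat[["x1"]] - 1.5))
})

test_that("beta recovery at scale under provider-covariate confounding", {
  set.seed(11)
  sim <- simulate_panel(m = 200L, sm = size_model("fixed", 50L),
                        target_iur = 0.3, beta = c(1.5, -0.5),
                        confounding = 3)
  beta_hat <- estimate_beta_fixed_effects(sim$panel)
  expect_equal(unname(beta_hat), c(1.5, -0.5), tolerance = 0.02)
})

test_that("collinear demeaned covariates are reported by name", {
  df <- data.frame(provider_id = rep(c("a", "b"), each = 3),
                   x1 = c(1, 2, 3, 4, 5, 6))
  df$x2 <- 2 * df$x1  # collinear after demeaning too
  df$y <- rnorm(6)
  panel <- provider_panel(df, covariates = c("x1", "x2"))
  expect_error(estimate_beta_fixed_effects(panel), "x2")
})

test_that("risk adjustment is the exact inverse of the model offset", {
  p <- tiny_panel()
  # mu = 0, empty beta: identity
  adj <- risk_adjust(p, variance_components(mu = 0))
  expect_equal(adj$y_adj, adj$y)
  # single-record arithmetic: 5 - 1 - 2 * 1.5 = 1
  df <- data.frame(provider_id = c("a", "b"), y = c(5, 0), x = c(2, 0))
  pp <- provider_panel(df, covariates = "x")
  adj <- risk_adjust(pp, variance_components(mu = 1, beta = 1.5))
  expect_equal(adj$y_adj[adj$provider_id == "a"], 1.0)
  # round trip on a random panel
  set.seed(3)
  sim <- simulate_panel(m = 20L, sm = size_model("fixed", 10L),
                        target_iur = 0.2, beta = 0.7, mu = 2)
  comp <- sim$truth$components
  adj <- risk_adjust(sim$panel, comp)
  X <- as.matrix(as.data.frame(adj)[, "x1", drop = FALSE])
  expect_equal(adj$y_adj + comp$mu + as.numeric(X %*% comp$beta), adj$y,
               tolerance = 1e-12)
  # dimension mismatch
  expect_error(risk_adjust(pp, variance_components(mu = 0, beta = c(1, 2))),
               "dimension")
})

test_that("center_mu is the weighted grand mean of covariate-adjusted outcomes", {
  df <- data.frame(provider_id = c("a", "a", "b"), y = c(1, 2, 3))
  expect_equal(center_mu(provider_panel(df)), 2)
  set.seed(5)
  sim <- simulate_panel(m = 30L, sm = size_model("fixed", 8L),
                        target_iur = 0.2, beta = 1.2, mu = 5)
  panel <- sim$panel
  X <- as.matrix(as.data.frame(panel)[, "x1", drop = FALSE])
  expect_equal(center_mu(panel, 1.2), mean(panel$y - 1.2 * X[, 1]),
               tolerance = 1e-12)
})

test_that("provider means agree with brute-force groupwise means", {
  p <- risk_adjust(tiny_panel(), variance_components())
  means <- provider_means(p)
  expect_equal(means[["a"]], 2)
  expect_equal(means[["b"]], 2)
  expect_equal(means[["c"]], 2)
  set.seed(13)
  np <- null_panel(m = 40L, n = 12L, iur = 0.3)
  brute <- sapply(split(np$panel$y_adj, np$panel$provider_id), mean)
  expect_equal(provider_means(np$panel), brute[names(provider_means(np$panel))])
})

test_that("ANOVA components recover the truth and are permutation invariant", {
  set.seed(17)
  np <- null_panel(m = 400L, n = 100L, iur = 0.25)
  est <- estimate_variance_components(np$panel)
  # single-panel sampling sd of the IUR estimate is ~0.05 here
  expect_lt(abs(est$iur_overall - 0.25), 0.15)
  expect_equal(est$sigma_w2, 1, tolerance = 0.02)
  # permuting records and relabeling providers changes nothing material
  perm <- sample(nrow(np$panel))
  df <- as.data.frame(np$panel)[perm, ]
  df$provider_id <- paste0("relabeled_", df$provider_id)
  p2 <- risk_adjust(provider_panel(df), variance_components())
  est2 <- estimate_variance_components(p2)
  expect_equal(est2$iur_overall, est$iur_overall, tolerance = 1e-12)
  expect_equal(est2$sigma_b2, est$sigma_b2, tolerance = 1e-12)
})

test_that("mean estimated IUR concentrates on the target over replications", {
  set.seed(19)
  for (target in c(0.25, 0.5)) {
    ests <- replicate(50, {
      np <- null_panel(m = 500L, n = 100L, iur = target)
      estimate_variance_components(np$panel)$iur_overall
    })
    expect_lt(abs(mean(ests) - target), 0.02)
  }
})

test_that("degenerate panels error informatively", {
  # zero within-provider variance
  df <- data.frame(provider_id = rep(c("a", "b"), each = 3),
                   y = rep(c(1, 5), each = 3))
  p <- risk_adjust(provider_panel(df), variance_components())
  expect_error(estimate_variance_components(p), "within-provider variance")
  # all singletons
  df1 <- data.frame(provider_id = c("a", "b", "c"), y = c(1, 2, 3))
  p1 <- risk_adjust(provider_panel(df1), variance_components())
  expect_error(estimate_variance_components(p1), "single patient")
  # all equal with tiny noise: sigma_b2 clamped, IUR ~ 0
  set.seed(23)
  df2 <- data.frame(provider_id = rep(letters[1:20], each = 10),
                    y = 3 + rnorm(200, 0, 1e-6))
  p2 <- risk_adjust(provider_panel(df2), variance_components())
  est <- suppressMessages(estimate_variance_components(p2))
  expect_lt(est$iur_overall, 0.3)
  expect_gte(est$sigma_b2, 0)
})

test_that("panel IO round-trips through CSV with validation", {
  set.seed(29)
  sim <- simulate_panel(m = 10L, sm = size_model("fixed", 5L),
                        target_iur = 0.2, beta = 0.5)
  path <- tempfile(fileext = ".csv")
  write_panel(sim$panel, path)
  back <- read_panel(path, covariates = "x1")
  expect_equal(nrow(back), nrow(sim$panel))
  expect_equal(sort(back$y), sort(sim$panel$y), tolerance = 1e-12)
  # missing values rejected with row numbers
  df <- utils::read.csv(path)
  df$y[3] <- NA
  path2 <- tempfile(fileext = ".csv")
  utils::write.csv(df, path2, row.names = FALSE)
  expect_error(read_panel(path2), "rows: 3")
})
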