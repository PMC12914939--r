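test_that("REML tau2 matches an independent grid-search maximiser", {
  set.seed(14)
  for (i in 1:8) {
    k <- sample(4:12, 1)
    yi <- rnorm(k, 0, 0.5)
    vi <- runif(k, 0.01, 0.2)
    expect_equal(reml_tau2(yi, vi), grid_reml_tau2(yi, vi), tolerance = 1e-6)
  }
  expect_equal(reml_tau2(rep(0.3, 5), runif(5, 0.05, 0.1)), 0,
               tolerance = 1e-10)
})

test_that("pooling reduces to closed forms in degenerate settings", {
  # two studies, equal variances, no heterogeneity
  p <- pool(c(0.2, 0.4), c(0.05, 0.05), tau2 = 0)
  expect_equal(p$mu, 0.3, tolerance = 1e-12)
  expect_equal(p$se, sqrt(0.05 / 2), tolerance = 1e-12)
  # one dominant weight: pooled estimate approaches that trial
  d <- suppressWarnings(pool(c(1, -1, 0.5), c(1e-8, 1, 1), tau2 = 0))
  expect_equal(d$mu, 1, tolerance = 1e-3)
  expect_error(pool(1, 1), "k >= 2")
  expect_error(pool(c(1, 2), c(1, 0)), "positive")
})

test_that("I2 is invariant to common rescaling of all variances", {
  set.seed(3)
  yi <- rnorm(8); vi <- runif(8, 0.02, 0.3)
  p1 <- pool(yi, vi)
  p2 <- pool(yi * 2, vi * 4)  # rescale effects and variances together
  expect_equal(p1$i2, p2$i2, tolerance = 1e-6)
  expect_equal(p2$tau2, 4 * p1$tau2, tolerance = 1e-6)
})

test_that("standard errors back out of reported confidence intervals", {
  expect_equal(se_from_ci(2.12, 5.13, log_scale = TRUE),
               (log(5.13) - log(2.12)) / (2 * qnorm(0.975)), tolerance = 1e-12)
  expect_equal(se_from_ci(2.12, 5.13, log_scale = TRUE), 0.2254,
               tolerance = 1e-3)
  expect_equal(se_from_ci(-1, 1), 0.5102, tolerance = 1e-4)
  expect_equal(se_from_ci(-2.90, 0.52), 0.8724, tolerance = 1e-4)
  expect_error(se_from_ci(1, 1), "high > low")
  expect_error(se_from_ci(-1, 1, log_scale = TRUE), "positive")
})

test_that("correlated differences behave algebraically", {
  a <- meta_input(paste0("t", 1:5), c(-0.4, -0.1, -0.2, -0.3, -0.15),
                  c(0.01, 0.02, 0.015, 0.03, 0.02))
  b <- meta_input(paste0("t", 1:5), c(-0.5, -0.15, -0.25, -0.32, -0.2),
                  c(0.012, 0.022, 0.018, 0.028, 0.021))
  # identical record sets pool to zero difference
  d0 <- difference_meta(a, a, r = 1)
  expect_equal(d0$pooled$mu, 0, tolerance = 1e-10)
  # per-trial difference variance is non-increasing in r
  grid <- sensitivity_r_grid(a, b, r_values = seq(0, 1, 0.25))
  d_lo <- difference_meta(a, b, r = 0)
  d_hi <- difference_meta(a, b, r = 1)
  expect_true(all(d_hi$per_trial$v_delta <= d_lo$per_trial$v_delta + 1e-12))
  # r = 0 equals pooling of independent differences
  ind <- pool(abs(b$yi) - abs(a$yi), a$vi + b$vi)
  expect_equal(d_lo$pooled$mu, ind$mu, tolerance = 1e-10)
  expect_error(difference_meta(a, b, r = 1.5), "r must lie")
  b_bad <- b; b_bad$trial_id[1] <- "other"
  expect_error(difference_meta(a, b_bad), "trial sets differ")
})

test_that("degenerate difference variances are floored and flagged", {
  a <- meta_input(c("x", "y"), c(-0.3, -0.1), c(0.02, 0.02))
  b <- meta_input(c("x", "y"), c(-0.4, -0.2), c(0.02, 0.02))
  d <- difference_meta(a, b, r = 1)  # va = vb, r = 1 -> var collapses
  expect_identical(d$floored, 2L)
  expect_true(all(d$per_trial$v_delta >= 1e-8))
})

test_that("subgroup pooling detects separated groups and collapses cleanly", {
  mi <- table1_meta_input("ITT", "continuous")
  cbt <- ifelse(mi$intervention_type == "CBT", "CBT", "other")
  sg <- subgroup_analysis(mi, cbt)
  mu <- setNames(sg$groups$mu, sg$groups$group)
  expect_gt(abs(mu[["CBT"]]), abs(mu[["other"]]))
  expect_lt(sg$p, 0.001)
  # identical groups: between-group Q vanishes
  dup <- meta_input(paste0("t", 1:4), rep(c(-0.2, -0.3), 2),
                    rep(c(0.01, 0.02), 2))
  sg0 <- subgroup_analysis(dup, c("g1", "g1", "g2", "g2"))
  expect_lt(sg0$q_between, 1e-20)
  # two singleton groups reduce to a z-test of the difference
  two <- meta_input(c("a", "b"), c(0.5, 0.1), c(0.02, 0.03))
  sg2 <- subgroup_analysis(two, c("A", "B"))
  z2 <- (0.5 - 0.1)^2 / (0.02 + 0.03)
  expect_equal(sg2$q_between, z2, tolerance = 1e-10)
  expect_error(subgroup_analysis(two, c("A", "A")), ">= 2 groups")
})

test_that("meta-regression recovers a linear moderator and rejects rank loss", {
  set.seed(9)
  mod <- seq(0, 1, length.out = 8)
  yi <- 0.1 + 0.6 * mod + rnorm(8, 0, 1e-4)
  mi <- meta_input(paste0("t", 1:8), yi, rep(1e-4, 8),
                   moderators = tibble::tibble(x = mod))
  fit <- meta_regression(mi, "x")
  expect_equal(fit$coefficients$estimate[2], 0.6, tolerance = 1e-3)
  const <- meta_input(paste0("t", 1:8), yi, rep(1e-4, 8),
                      moderators = tibble::tibble(x = rep(1, 8)))
  expect_error(meta_regression(const, "x"), "rank")
})

test_that("Egger's regression matches a hand-rolled least-squares oracle", {
  set.seed(5)
  yi <- rnorm(9, 0.2, 0.3); vi <- runif(9, 0.01, 0.2)
  eg <- eggers_test(yi, vi)
  X <- cbind(1, 1 / sqrt(vi))
  beta <- solve(crossprod(X), crossprod(X, yi / sqrt(vi)))
  expect_equal(eg$intercept, beta[1, 1], tolerance = 1e-10)
  expect_equal(eg$slope, beta[2, 1], tolerance = 1e-10)
  # perfectly symmetric funnel: zero intercept
  sym <- eggers_test(c(-0.3, 0.3, -0.1, 0.1), c(0.04, 0.04, 0.09, 0.09))
  expect_equal(sym$intercept, 0, tolerance = 1e-10)
  expect_error(eggers_test(c(1, 2), c(1, 1)), "k >= 3")
  expect_error(eggers_test(c(1, 2, 3), c(1, 1, 1)), "constant precision")
})

test_that("the variance-ratio F test matches the reference distribution", {
  eq <- variance_ratio_test(2, 30, 2, 30)
  expect_equal(eq$f, 1)
  expect_equal(eq$p, 1, tolerance = 1e-12)
  vr <- variance_ratio_test(sqrt(2), 50, 1, 50)
  expect_equal(vr$f, 2, tolerance = 1e-12)
  expect_equal(vr$p, 2 * (1 - pf(2, 49, 49)), tolerance = 1e-12)
  expect_error(variance_ratio_test(0, 10, 1, 10), "zero variance")
})

test_that("ITT and PP outcome spreads from a shared outcome model look alike", {
  set.seed(77)
  hits <- 0
  for (i in 1:30) {
    sim <- simulate_trial(trial_config("v", n_per_arm = 200,
                                       compliance_prob = 0.7,
                                       cace_effect = -4, seed = 1000 + i))
    pp <- make_pp_table(sim$ipd)
    vr <- variance_ratio_test(sd(sim$ipd$followup, na.rm = TRUE),
                              sum(!is.na(sim$ipd$followup)),
                              sd(pp$followup, na.rm = TRUE),
                              sum(!is.na(pp$followup)))
    if (vr$p > 0.05) hits <- hits + 1
  }
  expect_gte(hits / 30, 0.9)
})
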