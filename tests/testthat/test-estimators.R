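test_that("Wald ratios match direct arithmetic for both SE orders", {
  inst <- data.frame(rsid = "rs1", beta_exposure = 0.02, se_exposure = 0.003,
                     beta_outcome = 0.01, se_outcome = 0.004,
                     proxy_of = NA, palindromic = FALSE, flipped = FALSE)
  r1 <- wald_ratios(inst, "first")
  expect_equal(r1$theta, 0.5)
  expect_equal(r1$se, 0.2)
  expect_equal(r1$weight, 25)
  # second order evaluated independently at high precision:
  # sqrt(0.004^2/0.02^2 + 0.01^2*0.003^2/0.02^4) = 0.2136000936...
  r2 <- wald_ratios(inst, "second")
  expect_equal(r2$se, 0.2136000936, tolerance = 1e-9)

  inst$beta_outcome <- 0
  expect_equal(wald_ratios(inst)$theta, 0)
  expect_equal(wald_ratios(inst)$se, 0.2)

  inst$beta_exposure <- 0
  expect_error(wald_ratios(inst), "null instrument")
})

test_that("IVW matches hand arithmetic on the toy set and handles homogeneity", {
  inst <- make_instruments(c(0.1, 0.2, 0.3), rep(0.1, 3))
  est <- mr_ivw(inst, model = "fixed")
  expect_equal(est$beta, 0.2)
  expect_equal(est$se, 0.1 / sqrt(3), tolerance = 1e-9)
  expect_equal(est$q_stat, 2.0, tolerance = 1e-9)
  r <- mr_ivw(inst, model = "random")
  expect_equal(r$se, est$se)          # max(1, sqrt(2/2)) = 1
  expect_equal(r$or, exp(0.2))

  homog <- make_instruments(rep(0.25, 5), rep(0.1, 5))
  h <- mr_ivw(homog, "random")
  expect_equal(h$beta, 0.25)
  expect_equal(h$q_stat, 0)
  expect_equal(h$se, mr_ivw(homog, "fixed")$se)

  expect_error(mr_ivw(make_instruments(0.1, 0.1), "random"), "k >= 2")
})

test_that("IVW fixed equals the weighted regression-through-origin oracle to 1e-10", {
  for (seed in 1:10) {
    set.seed(seed)
    k <- sample(3:20, 1)
    inst <- random_instruments(k, seed = seed + 100)
    est <- mr_ivw(inst, model = "fixed")
    # independent oracle: closed-form WLS through the origin with weights se_Y^-2
    w <- inst$se_outcome^-2
    b_oracle <- sum(w * inst$beta_exposure * inst$beta_outcome) /
      sum(w * inst$beta_exposure^2)
    expect_equal(est$beta, b_oracle, tolerance = 1e-10)
  }
})

test_that("random-effects SE never falls below the fixed-effects SE", {
  for (seed in 1:20) {
    inst <- random_instruments(sample(4:30, 1), seed = seed, se_y = runif(1, 0.01, 0.2))
    expect_gte(mr_ivw(inst, "random")$se, mr_ivw(inst, "fixed")$se)
  }
})

test_that("weighted median interpolates the standardized cumulative weights", {
  # equal weights, theta = {1,2,3}: s = (1/6, 3/6, 5/6) hits 0.5 at the middle
  inst <- make_instruments(c(1, 2, 3), rep(0.1, 3))
  est <- mr_weighted_median(inst, n_boot = 50, seed = 1)
  expect_equal(est$beta, 2)

  # hand enumeration, unequal weights: se = {0.1, 0.1, 0.1/sqrt(2)} gives
  # w = {100, 100, 200}; sorted theta {0.1, 0.2, 0.4};
  # s = {0.125, 0.375, 0.75}; interpolate 0.2 + 0.2*(0.5-0.375)/0.375
  inst2 <- make_instruments(c(0.1, 0.2, 0.4), c(0.1, 0.1, 0.1 / sqrt(2)))
  est2 <- mr_weighted_median(inst2, n_boot = 50, seed = 1)
  expect_equal(est2$beta, 0.2 + 0.2 * (0.5 - 0.375) / 0.375, tolerance = 1e-12)

  # all equal: estimate c, point deterministic across seeds, small bootstrap SE
  instc <- make_instruments(rep(0.7, 5), rep(0.05, 5))
  e1 <- mr_weighted_median(instc, n_boot = 200, seed = 1)
  e2 <- mr_weighted_median(instc, n_boot = 200, seed = 99)
  expect_equal(e1$beta, 0.7)
  expect_equal(e1$beta, e2$beta)
  expect_lt(e1$se, 0.1)

  expect_error(mr_weighted_median(make_instruments(c(1, 2), c(1, 1)), seed = 1), "k >= 3")
  expect_error(mr_weighted_median(inst, n_boot = 10), "seed")
})

test_that("weighted median with equal weights equals the sample median (odd k) and stays in range", {
  for (seed in 1:10) {
    set.seed(seed)
    k <- sample(c(5, 7, 9), 1)
    th <- rnorm(k)
    inst <- make_instruments(th, rep(0.1, k))
    est <- mr_weighted_median(inst, n_boot = 20, seed = seed)
    expect_equal(est$beta, median(th), tolerance = 1e-12)
    # unequal weights: estimate bracketed by the extremes
    inst2 <- make_instruments(th, runif(k, 0.05, 0.3))
    est2 <- mr_weighted_median(inst2, n_boot = 20, seed = seed)
    expect_gte(est2$beta, min(th))
    expect_lte(est2$beta, max(th))
  }
})

test_that("Egger recovers an exact affine relation and matches a WLS oracle", {
  set.seed(3)
  bx <- runif(6, 0.05, 0.2)
  inst <- data.frame(rsid = sprintf("rs%d", 1:6), beta_exposure = bx, se_exposure = 0.01,
                     beta_outcome = 0.02 + 0.5 * bx, se_outcome = runif(6, 0.01, 0.05),
                     proxy_of = NA, palindromic = FALSE, flipped = FALSE)
  eg <- mr_egger(inst)
  expect_equal(eg$slope$beta, 0.5, tolerance = 1e-10)
  expect_equal(eg$intercept, 0.02, tolerance = 1e-10)
  expect_equal(eg$slope$q_stat, 0, tolerance = 1e-12)   # RSS 0 exact fit

  # matrix-algebra oracle on a noisy instance
  inst$beta_outcome <- inst$beta_outcome + rnorm(6, 0, 0.03)
  eg2 <- mr_egger(inst)
  W <- diag(inst$se_outcome^-2)
  X <- cbind(1, inst$beta_exposure)
  co <- solve(t(X) %*% W %*% X, t(X) %*% W %*% inst$beta_outcome)
  expect_equal(eg2$intercept, co[1], tolerance = 1e-10)
  expect_equal(eg2$slope$beta, co[2], tolerance = 1e-10)
  resid <- inst$beta_outcome - X %*% co
  rss_w <- sum(inst$se_outcome^-2 * resid^2)
  V <- solve(t(X) %*% W %*% X)
  scale <- max(1, sqrt(rss_w / (6 - 2)))
  expect_equal(eg2$slope$se, sqrt(V[2, 2]) * scale, tolerance = 1e-10)
  expect_equal(eg2$intercept_se, sqrt(V[1, 1]) * scale, tolerance = 1e-10)
})

test_that("Egger is invariant to flipping any single instrument's allele coding", {
  inst <- random_instruments(8, seed = 5)
  eg0 <- mr_egger(inst)
  for (i in c(1, 4, 8)) {
    inst2 <- inst
    inst2$beta_exposure[i] <- -inst2$beta_exposure[i]
    inst2$beta_outcome[i] <- -inst2$beta_outcome[i]
    eg1 <- mr_egger(inst2)
    expect_equal(eg1$slope$beta, eg0$slope$beta, tolerance = 1e-12)
    expect_equal(eg1$intercept, eg0$intercept, tolerance = 1e-12)
  }
  degen <- make_instruments(c(1, 2, 3), rep(0.1, 3))  # beta_exposure all equal
  expect_error(mr_egger(degen), "degenerate regressor")
})

test_that("Egger slope recovers the causal effect and intercept is null under balanced pleiotropy", {
  # 500 replicates with known truth; instruments need spread in strength for
  # the Egger regressor to be identified
  reps <- 500
  theta <- 0.3
  slope_est <- numeric(reps); int_est <- numeric(reps)
  for (r in seq_len(reps)) {
    set.seed(1000 + r)
    k <- 40
    alpha <- rnorm(k, 0, 0.02) # balanced: mean zero, InSIDE holds
    inst <- random_instruments(k, seed = 2000 + r, theta = theta, alpha = alpha)
    eg <- mr_egger(inst)
    slope_est[r] <- eg$slope$beta
    int_est[r] <- eg$intercept
  }
  mcse_s <- sd(slope_est) / sqrt(reps)
  mcse_i <- sd(int_est) / sqrt(reps)
  expect_lt(abs(mean(slope_est) - theta), 3 * mcse_s)
  expect_lt(abs(mean(int_est)), 3 * mcse_i)
})

test_that("under directional pleiotropy with InSIDE, Egger is less biased than IVW", {
  reps <- 500
  theta <- 0.3; mu_alpha <- 0.015
  bias_ivw <- numeric(reps); bias_egger <- numeric(reps)
  for (r in seq_len(reps)) {
    set.seed(3000 + r)
    alpha <- rnorm(40, mu_alpha, 0.005)   # directional, independent of strength
    inst <- random_instruments(40, seed = 4000 + r, theta = theta, alpha = alpha)
    bias_ivw[r] <- mr_ivw(inst)$beta - theta
    bias_egger[r] <- mr_egger(inst)$slope$beta - theta
  }
  expect_lt(abs(mean(bias_egger)), abs(mean(bias_ivw)))
})

test_that("Cochran's Q matches the chi-square closed form", {
  homog <- make_instruments(rep(0.3, 4), rep(0.1, 4))
  q0 <- cochran_q(homog, 0.3)
  expect_equal(q0$q, 0)
  expect_equal(q0$pval, 1)

  inst <- make_instruments(c(0.1, 0.2, 0.3), rep(0.1, 3))  # w = 100 each
  q <- cochran_q(inst, 0.2)
  expect_equal(q$q, 2.0, tolerance = 1e-9)
  expect_equal(q$df, 2L)
  expect_equal(q$pval, exp(-1), tolerance = 1e-9)
})

test_that("Q/(k-1) is approximately 1 on heterogeneity-free data", {
  reps <- 1000
  qn <- numeric(reps)
  for (r in seq_len(reps)) {
    set.seed(r)
    inst <- make_instruments(rnorm(10, 0.2, 0.05), rep(0.05, 10))
    est <- mr_ivw(inst, "fixed")
    qn[r] <- est$q_stat / 9
  }
  mcse <- sd(qn) / sqrt(reps)
  expect_lt(abs(mean(qn) - 1), 3 * mcse)
})

test_that("forest rows format ORs to two decimals with scientific p-values", {
  null_est <- mrpipe:::new_mr_estimate("ivw_random", 0, 0.1, 10)
  row <- to_forest_row(null_est)
  expect_equal(row$label, "OR 1.00 (0.82–1.22)")

  # SE back-calculated from the printed CI width of the headline estimate
  est <- mrpipe:::new_mr_estimate("ivw_random", log(1.32), 0.0718, 367)
  expect_equal(to_forest_row(est)$label, "OR 1.32 (1.15–1.52)")

  # monotonicity of the printed OR in beta
  ors <- sapply(c(0, 0.1, 0.3, 0.6), function(b)
    as.numeric(to_forest_row(mrpipe:::new_mr_estimate("x", b, 0.1, 5))$or))
  expect_true(all(diff(ors) > 0))
})
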