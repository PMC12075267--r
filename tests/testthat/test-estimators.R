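test_that("Wald ratio arithmetic, sign symmetry and zero handling", {
  e <- wald_ratio(0.5, 0.05, 0.1, 0.02)
  expect_equal(e$beta, 0.2)
  expect_equal(e$se, 0.04)
  expect_equal(e$or_, exp(0.2))
  null <- wald_ratio(0.5, 0.05, 0, 0.02)
  expect_equal(null$beta, 0)
  expect_equal(null$or_, 1)
  neg <- wald_ratio(-0.5, 0.05, 0.1, 0.02)
  expect_equal(neg$beta, -0.2)
  expect_equal(neg$se, 0.04)
  expect_error(wald_ratio(0, 0.05, 0.1, 0.02), "beta_x = 0")
})

test_that("odds-ratio conversion is exp on the log scale", {
  o <- to_odds_ratio(0, 0.1)
  expect_equal(o$or_, 1)
  expect_equal(o$ci_low * o$ci_high, 1)  # symmetric in log scale around 1
  z <- qnorm(0.975)
  o2 <- to_odds_ratio(-0.2, 0.1)
  expect_equal(o2$ci_low, exp(-0.2 - z * 0.1))
  expect_equal(o2$ci_high, exp(-0.2 + z * 0.1))
  o3 <- to_odds_ratio(log(2), 1e-12)
  expect_equal(o3$ci_low, 2, tolerance = 1e-9)
  expect_equal(o3$ci_high, 2, tolerance = 1e-9)
})

test_that("IVW reduces to the Wald ratio at J=1 and is exact on perfect fits", {
  s1 <- make_set(0.5, 0.1, se_x = 0.05, se_y = 0.02)
  expect_message(e1 <- mr_ivw(s1, model = "fixed"), "Wald")
  expect_equal(e1$beta, 0.2)
  expect_equal(e1$se, 0.04)
  # exact proportionality: beta = theta, fixed and random se equal
  bx <- c(0.1, 0.2, 0.3)
  s <- make_set(bx, 0.4 * bx, se_y = c(0.01, 0.02, 0.03))
  expect_equal(mr_ivw(s, model = "fixed")$beta, 0.4)
  expect_equal(mr_ivw(s)$se, mr_ivw(s, model = "fixed")$se)
})

test_that("IVW matches the weighted-least-squares normal equations", {
  s <- random_set(J = 7, seed = 3)
  fit <- lm(s$beta_y ~ 0 + s$beta_x, weights = 1 / s$se_y^2)
  est <- mr_ivw(s, model = "fixed")
  expect_equal(est$beta, unname(coef(fit)), tolerance = 1e-12)
  # fixed-effect se is the known-variance one, not lm's residual-scaled se
  expect_equal(est$se, sqrt(1 / sum(s$beta_x^2 / s$se_y^2)), tolerance = 1e-12)
  # multiplicative random effects only ever inflates
  expect_gte(mr_ivw(s)$se, est$se)
})

test_that("IVW fixed equals the inverse-variance meta-analysis of Wald ratios", {
  skip_if_not_installed("metafor")
  for (seed in 1:5) {
    s <- random_set(J = 9, seed = seed)
    ratios <- s$beta_y / s$beta_x
    ratio_se <- s$se_y / abs(s$beta_x)
    meta <- metafor::rma(yi = ratios, sei = ratio_se, method = "FE")
    est <- mr_ivw(s, model = "fixed")
    expect_equal(est$beta, as.numeric(meta$beta), tolerance = 1e-10)
    expect_equal(est$se, as.numeric(meta$se), tolerance = 1e-10)
  }
})

test_that("Egger recovers an exact affine relation and ignores orientation", {
  bx <- c(0.1, 0.15, 0.25, 0.4)
  s <- make_set(bx, 0.02 + 0.3 * bx, se_y = c(0.01, 0.03, 0.02, 0.04))
  fit <- mr_egger(s)
  expect_equal(fit$slope$beta, 0.3, tolerance = 1e-12)
  expect_equal(fit$intercept, 0.02, tolerance = 1e-12)
  expect_equal(fit$q_prime, 0, tolerance = 1e-20)
  # flipping one SNP's (beta_x, beta_y) jointly changes nothing
  s2 <- make_set(c(-bx[1], bx[-1]), c(-(0.02 + 0.3 * bx[1]), 0.02 + 0.3 * bx[-1]),
                 se_y = c(0.01, 0.03, 0.02, 0.04))
  fit2 <- mr_egger(s2)
  expect_equal(fit2$slope$beta, fit$slope$beta)
  expect_equal(fit2$intercept, fit$intercept)
  expect_error(mr_egger(make_set(c(0.1, 0.2), c(0.1, 0.2))), "at least 3")
})

test_that("Egger matches a weighted lm oracle and approaches IVW when a=0", {
  s <- random_set(J = 10, seed = 5)
  flip <- s$beta_x < 0
  x <- abs(s$beta_x); y <- ifelse(flip, -s$beta_y, s$beta_y)
  ref <- lm(y ~ x, weights = 1 / s$se_y^2)
  fit <- mr_egger(s)
  expect_equal(fit$slope$beta, unname(coef(ref)[2]), tolerance = 1e-12)
  expect_equal(fit$intercept, unname(coef(ref)[1]), tolerance = 1e-12)
  # intercept-free data with wide beta_x spread: slope close to IVW's
  set.seed(8)
  bx <- seq(0.05, 0.6, length.out = 12)
  s0 <- make_set(bx, 0.25 * bx + rnorm(12, 0, 1e-4), se_y = rep(0.01, 12))
  expect_equal(mr_egger(s0)$slope$beta, mr_ivw(s0, model = "fixed")$beta,
               tolerance = 5e-3)
  expect_lt(abs(mr_egger(s0)$intercept), 1e-4)
})

test_that("weighted median interpolates the weight-0.5 quantile of ratios", {
  # equal weights, middle value
  s <- make_set(c(1, 1, 1), c(0.1, 0.2, 0.9), se_y = rep(0.1, 3))
  expect_equal(mr_weighted_median(s, n_boot = 50, seed = 1)$beta, 0.2)
  # all ratios equal: estimate is that constant regardless of weights
  s2 <- make_set(c(0.1, 0.4, 0.8), 0.3 * c(0.1, 0.4, 0.8),
                 se_y = c(0.01, 0.05, 0.02))
  expect_equal(mr_weighted_median(s2, n_boot = 50, seed = 1)$beta, 0.3)
  # estimate always lies within the ratio range
  for (seed in 1:10) {
    s3 <- random_set(J = sample(3:12, 1), seed = seed)
    est <- mr_weighted_median(s3, n_boot = 30, seed = seed)$beta
    th <- s3$beta_y / s3$beta_x
    expect_gte(est, min(th))
    expect_lte(est, max(th))
  }
})

test_that("weighted-median bootstrap is seed-deterministic and leaves the RNG alone", {
  s <- random_set(J = 8, seed = 2)
  e1 <- mr_weighted_median(s, n_boot = 200, seed = 42)
  set.seed(1); before <- rnorm(1)
  set.seed(1)
  e2 <- mr_weighted_median(s, n_boot = 200, seed = 42)
  after <- rnorm(1)
  expect_identical(e1$se, e2$se)
  expect_identical(before, after)  # caller's stream restored
  e3 <- mr_weighted_median(s, n_boot = 4000, seed = 43)
  e4 <- mr_weighted_median(s, n_boot = 4000, seed = 44)
  expect_lt(abs(e3$se - e4$se) / e3$se, 0.25)  # agree within Monte-Carlo error
})

test_that("estimators are equivariant under exposure rescaling", {
  s <- random_set(J = 9, seed = 13)
  c_scale <- 2.5
  s_scaled <- harmonized_set(s$snp_id, c_scale * s$beta_x, c_scale * s$se_x,
                             s$beta_y, s$se_y)
  expect_equal(mr_ivw(s_scaled)$beta, mr_ivw(s)$beta / c_scale, tolerance = 1e-12)
  expect_equal(mr_egger(s_scaled)$slope$beta, mr_egger(s)$slope$beta / c_scale,
               tolerance = 1e-12)
  expect_equal(mr_weighted_median(s_scaled, n_boot = 10, seed = 1)$beta,
               mr_weighted_median(s, n_boot = 10, seed = 1)$beta / c_scale,
               tolerance = 1e-12)
  # negating the outcome effects negates every point estimate
  s_neg <- harmonized_set(s$snp_id, s$beta_x, s$se_x, -s$beta_y, s$se_y)
  expect_equal(mr_ivw(s_neg)$beta, -mr_ivw(s)$beta, tolerance = 1e-12)
  expect_equal(mr_weighted_median(s_neg, n_boot = 10, seed = 1)$beta,
               -mr_weighted_median(s, n_boot = 10, seed = 1)$beta,
               tolerance = 1e-12)
})
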