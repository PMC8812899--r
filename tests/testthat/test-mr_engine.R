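test_that("Wald ratio follows the closed form and its degenerate cases", {
  p <- pairs_from(1, 0.1, 0.25, 0.05)
  e <- wald_ratio(p)
  expect_equal(e$theta, 0.25)
  expect_equal(e$se_theta, 0.05)
  e2 <- wald_ratio(pairs_from(-0.5, 0.1, 0.2, 0.05))
  expect_equal(e2$theta, -0.4)
  expect_equal(e2$se_theta, 0.1)
  e3 <- wald_ratio(pairs_from(0.4, 0.1, 0, 0.05))
  expect_equal(e3$theta, 0)
  expect_equal(e3$odds_ratio, 1)
  expect_error(wald_ratio(pairs_from(0, 0.1, 0.2, 0.05)), "undefined ratio")
})

test_that("single-variant IVW reduces to the Wald ratio", {
  p <- pairs_from(-0.63, 0.02, 0.08, 0.03)
  w <- wald_ratio(p)
  i <- ivw_correlated(p)
  expect_equal(i$theta, w$theta)
  expect_equal(i$se_theta, w$se_theta)
  expect_equal(i$method, "wald")
})

test_that("identity-LD IVW equals the textbook independent estimator exactly", {
  set.seed(21)
  for (rep in 1:20) {
    j <- sample(3:8, 1)
    bx <- rnorm(j, 0.3, 0.1)
    by <- 0.5 * bx + rnorm(j, 0, 0.02)
    se <- runif(j, 0.01, 0.08)
    est <- ivw_correlated(pairs_from(bx, 0.01, by, se))
    oracle <- independent_ivw_oracle(bx, by, se)
    expect_equal(est$theta, oracle$theta, tolerance = 1e-12)
    # fixed-effect SE recovered after undoing the dispersion scale
    expect_equal(est$se_theta / est$phi, oracle$se_fixed, tolerance = 1e-12)
  }
})

test_that("correlated IVW matches the explicit-inversion GLS oracle", {
  set.seed(22)
  for (rep in 1:50) {
    j <- sample(3:10, 1)
    rho <- random_corr(j)
    bx <- rnorm(j, 0.3, 0.1)
    by <- 0.4 * bx + rnorm(j, 0, 0.05)
    se <- runif(j, 0.01, 0.1)
    est <- ivw_correlated(pairs_from(bx, 0.01, by, se,
                                     ids = rownames(rho)), rho)
    oracle <- gls_oracle(bx, by, se, rho)
    expect_equal(est$theta, oracle$theta, tolerance = 1e-10)
    expect_equal(est$se_theta, oracle$se, tolerance = 1e-10)
    expect_equal(est$phi, oracle$phi, tolerance = 1e-10)
  }
})

test_that("exact-fit outcomes trigger the underdispersion floor", {
  bx <- c(0.2, 0.3, 0.5)
  p <- pairs_from(bx, 0.01, 0.7 * bx, c(0.02, 0.03, 0.04))
  est <- ivw_correlated(p)
  expect_equal(est$phi, 1)
  expect_equal(est$theta, 0.7, tolerance = 1e-12)
  oracle <- independent_ivw_oracle(bx, 0.7 * bx, c(0.02, 0.03, 0.04))
  expect_equal(est$se_theta, oracle$se_fixed, tolerance = 1e-12)
})

test_that("overdispersed outcomes inflate the SE multiplicatively", {
  set.seed(30)
  bx <- rnorm(8, 0.4, 0.05)
  by <- 0.5 * bx + rnorm(8, 0, 0.3)  # noise far beyond the nominal SEs
  p <- pairs_from(bx, 0.01, by, rep(0.02, 8))
  est <- ivw_correlated(p)
  expect_gt(est$phi, 1)
  oracle <- independent_ivw_oracle(bx, by, rep(0.02, 8))
  expect_equal(est$se_theta, oracle$se_fixed * est$phi, tolerance = 1e-12)
})

test_that("odds-ratio rescaling is equivariant and preserves the null", {
  p <- pairs_from(c(0.3, 0.4, 0.5), 0.01, c(0.04, 0.05, 0.06),
                  c(0.02, 0.02, 0.02))
  est <- ivw_correlated(p)
  expect_equal(scale_odds_ratio(est, 1)$theta, est$theta)
  ab <- scale_odds_ratio(est, 6)
  stepwise <- scale_odds_ratio(scale_odds_ratio(est, 2), 3)
  expect_equal(ab$theta, stepwise$theta)
  expect_equal(ab$se_theta, stepwise$se_theta)
  expect_equal(ab$ci_low, stepwise$ci_low)
  # null effect is invariant under any scale
  null_est <- wald_ratio(pairs_from(0.5, 0.1, 0, 0.05))
  expect_equal(scale_odds_ratio(null_est, 8)$odds_ratio, 1)
  # the 8-fold trial-dose scaling rule on a rounded published-scale estimate
  est_print <- scale_odds_ratio(
    mr_estimate_for_test(log(1.13), 0.036), 8)
  expect_equal(est_print$odds_ratio, exp(8 * log(1.13)), tolerance = 1e-12)
  expect_equal(round(est_print$odds_ratio, 2), 2.66)
})

test_that("negating exposure betas flips the estimate (orientation)", {
  set.seed(31)
  rho <- random_corr(5)
  bx <- rnorm(5, 0.3, 0.05)
  by <- 0.3 * bx + rnorm(5, 0, 0.03)
  se <- runif(5, 0.02, 0.05)
  a <- ivw_correlated(pairs_from(bx, 0.01, by, se, rownames(rho)), rho)
  b <- ivw_correlated(pairs_from(-bx, 0.01, by, se, rownames(rho)), rho)
  expect_equal(b$theta, -a$theta, tolerance = 1e-12)
  expect_equal(b$odds_ratio, 1 / a$odds_ratio, tolerance = 1e-12)
  # the reporting orientation flag performs the same flip
  c_ <- ivw_correlated(pairs_from(bx, 0.01, by, se, rownames(rho)), rho,
                       orientation = "per_unit_lower_exposure")
  expect_equal(c_$theta, -a$theta, tolerance = 1e-12)
  expect_equal(c_$se_theta, a$se_theta, tolerance = 1e-12)
})

test_that("leave-one-out reproduces direct subset calls and bookkeeping", {
  set.seed(32)
  j <- 5
  rho <- random_corr(j)
  bx <- rnorm(j, 0.35, 0.05)
  by <- 0.4 * bx + rnorm(j, 0, 0.03)
  se <- runif(j, 0.02, 0.05)
  p <- pairs_from(bx, 0.01, by, se, rownames(rho))
  loo <- leave_one_out(p, rho)
  expect_equal(nrow(loo), j)
  expect_setequal(loo$excluded_snp, p$snp_id)
  for (i in seq_len(j)) {
    direct <- ivw_correlated(p[-i, ], rho[-i, -i])
    expect_equal(loo$theta[i], direct$theta, tolerance = 1e-12)
    expect_equal(loo$se_theta[i], direct$se_theta, tolerance = 1e-12)
  }
  # j = 2 reduces to Wald ratios on the remaining variant
  p2 <- p[1:2, ]
  loo2 <- leave_one_out(p2, rho[1:2, 1:2])
  expect_equal(loo2$theta[1], wald_ratio(p2[2, ])$theta)
  expect_equal(loo2$theta[2], wald_ratio(p2[1, ])$theta)
  expect_error(leave_one_out(p[1, , drop = FALSE]), "leave out")
})

test_that("multivariable MR matches explicit weighted normal equations", {
  set.seed(33)
  j <- 5
  rho <- random_corr(j)
  b_mat <- cbind(exp1 = rnorm(j, 0.3, 0.1), exp2 = rnorm(j, -0.2, 0.1))
  theta_true <- c(0.5, -0.3)
  by <- drop(b_mat %*% theta_true) + rnorm(j, 0, 0.02)
  se <- runif(j, 0.02, 0.06)
  fit <- mvmr_correlated(b_mat, by, se, rho)
  omega <- diag(se) %*% rho %*% diag(se)
  oi <- solve(omega)
  xtx_inv <- solve(t(b_mat) %*% oi %*% b_mat)
  theta_o <- drop(xtx_inv %*% t(b_mat) %*% oi %*% by)
  resid <- by - drop(b_mat %*% theta_o)
  phi <- max(1, sqrt(drop(t(resid) %*% oi %*% resid) / (j - 2)))
  expect_equal(fit$theta, unname(theta_o), tolerance = 1e-10)
  expect_equal(fit$se_theta, unname(sqrt(diag(xtx_inv))) * phi,
               tolerance = 1e-10)
  expect_equal(attr(fit, "phi"), phi, tolerance = 1e-10)
})

test_that("a nuisance exposure without signal leaves the primary estimate", {
  set.seed(34)
  j <- 6
  bx <- rnorm(j, 0.4, 0.05)
  by <- 0.3 * bx + rnorm(j, 0, 0.01)
  se <- rep(0.03, j)
  # second column carries negligible independent signal (full rank padding)
  b_mat <- cbind(main = bx, nuisance = rnorm(j, 0, 1e-6))
  fit <- mvmr_correlated(b_mat, by, se)
  uni <- ivw_correlated(pairs_from(bx, 0.01, by, se))
  expect_equal(fit$theta[1], uni$theta, tolerance = 0.02)
  # duplicated exposure columns are singular
  expect_error(mvmr_correlated(cbind(bx, bx), by, se), "collinear")
  expect_error(mvmr_correlated(cbind(bx, bx + rnorm(j)), by[1:3], se),
               "length")
})

test_that("multiplicity tiers reproduce the Bonferroni thresholds", {
  p36 <- rep(0.5, 36)
  tiers <- apply_multiplicity(p36)
  expect_equal(signif(attr(tiers, "threshold"), 2), 0.0014)
  tiers2 <- apply_multiplicity(rep(0.5, 21482))
  expect_equal(signif(attr(tiers2, "threshold"), 3), 2.33e-6)
  # tier assignment around the printed threshold
  mix <- apply_multiplicity(c(a = 3.6e-4, b = 0.08, c = 0.5, d = 0.0014),
                            alpha = 0.05)
  # threshold = 0.05/4 = 0.0125 here; use a 36-test family for the heuristic
  fam <- setNames(rep(0.5, 36), paste0("t", 1:36))
  fam[1:3] <- c(3.6e-4, 0.08, 0.0014)
  tiers3 <- apply_multiplicity(fam)
  expect_equal(unname(tiers3$tier[1:3]), c("strong", "weak", "weak"))
  expect_equal(unname(tiers3$tier[4]), "little")
})

test_that("confidence bounds straddle the odds ratio consistently", {
  set.seed(35)
  for (rep in 1:10) {
    est <- wald_ratio(pairs_from(rnorm(1, 0.5, 0.1), 0.05,
                                 rnorm(1, 0.1, 0.2), runif(1, 0.02, 0.2)))
    expect_lt(est$ci_low, est$odds_ratio)
    expect_gt(est$ci_high, est$odds_ratio)
    expect_equal(est$ci_low, exp(est$theta - qnorm(0.975) * est$se_theta))
  }
})
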