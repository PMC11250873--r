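manual_fixed_fit <- function(beta, psi1, cov_scale = 1e-4) {
  theta <- c(beta, delta = log(psi1))
  structure(list(beta = beta, psi1 = psi1, theta = theta,
                 cov = diag(cov_scale, length(theta))),
            class = "fixed_fit")
}

test_that("effects match analytic logistic probability differences", {
  beta <- c(constant = -0.5, x1 = 0.8, x2 = -0.6)
  psi1 <- 1.2
  fit <- manual_fixed_fit(beta, psi1)
  set.seed(51)
  X <- cbind(constant = 1, x1 = as.numeric(runif(120) < 0.5),
             x2 = as.numeric(runif(120) < 0.3))
  d <- make_design(X, sample(0:2, 120, TRUE))
  xbar <- colMeans(X)
  for (v in c("x1", "x2")) for (k in 0:2) {
    x1v <- xbar; x1v[v] <- 1
    x0v <- xbar; x0v[v] <- 0
    analytic <- function(x) {
      eta <- sum(x * beta)
      c(plogis(-eta), plogis(psi1 - eta) - plogis(-eta),
        1 - plogis(psi1 - eta))[k + 1]
    }
    expect_equal(marginal_effect_indicator(fit, d, v, k),
                 analytic(x1v) - analytic(x0v), tolerance = 1e-10)
  }
  expect_error(marginal_effect_indicator(fit, d, "nope", 0), "unknown")
})

test_that("effects of every variable sum to zero over the categories", {
  d <- compact_design(n = 1500, seed = 21)
  ff <- fit_fixed(d)
  eff_f <- marginal_effects(ff, d, pvalues = FALSE)
  sums_f <- rowSums(eff_f[, c("effect_y0", "effect_y1", "effect_y2")])
  expect_true(all(abs(sums_f) < 1e-12))
  fc <- fit_crp(d, crp_spec(D = 60), fixed = ff)
  eff_c <- marginal_effects(fc, d, pvalues = FALSE)
  sums_c <- rowSums(eff_c[, c("effect_y0", "effect_y1", "effect_y2")])
  expect_true(all(abs(sums_c) < 1e-3))
  # observation-averaged variant conserves probability too
  eff_o <- marginal_effects(ff, d, variables = c("urban", "year_index"),
                            average_over = "observations")
  expect_true(all(abs(rowSums(
    eff_o[, c("effect_y0", "effect_y1", "effect_y2")])) < 1e-12))
})

test_that("a zero coefficient yields zero effect with p near 1", {
  beta <- c(constant = -0.4, x1 = 0.9, x2 = 0)
  fit <- manual_fixed_fit(beta, 1.1)
  set.seed(52)
  X <- cbind(constant = 1, x1 = as.numeric(runif(60) < 0.5),
             x2 = as.numeric(runif(60) < 0.5))
  d <- make_design(X, sample(0:2, 60, TRUE))
  eff <- marginal_effects(fit, d, variables = "x2")
  expect_equal(unlist(eff[1, c("effect_y0", "effect_y1", "effect_y2")]),
               c(effect_y0 = 0, effect_y1 = 0, effect_y2 = 0),
               tolerance = 1e-10)
  expect_true(all(eff[1, c("p_y0", "p_y1", "p_y2")] > 0.95))
})

test_that("a strong true effect is detected at n = 10000", {
  set.seed(53)
  n <- 10000
  X <- cbind(constant = 1, x1 = as.numeric(runif(n) < 0.5))
  eta <- drop(X %*% c(-0.5, 1.0))
  ystar <- eta + rlogis(n)
  y <- ifelse(ystar <= 0, 0L, ifelse(ystar <= 1.3, 1L, 2L))
  d <- make_design(X, y)
  fit <- fit_fixed(d)
  eff <- marginal_effects(fit, d, variables = "x1")
  expect_true(all(eff[1, c("p_y0", "p_y2")] < 0.01))
  expect_lt(eff$effect_y0[1], 0)  # positive coefficient lowers category 0
})

test_that("delta-method variances are nonnegative and refreshable", {
  d <- compact_design(n = 1500, seed = 21)
  ff <- fit_fixed(d)
  eff <- marginal_effects(ff, d, variables = c("urban", "female"),
                          pvalues = FALSE)
  filled <- effect_pvalues(ff, d, eff)
  expect_true(all(filled$p_y0 >= 0 & filled$p_y0 <= 1))
  expect_true(all(filled$p_y2 >= 0 & filled$p_y2 <= 1))
})

test_that("McFadden pseudo R-squared follows its definition", {
  expect_equal(mcfadden_r2(-100, -100), 0)
  expect_equal(mcfadden_r2(-50, -100), 0.5)
  set.seed(54)
  ll <- -runif(1, 400, 600)
  ll0 <- ll - runif(1, 10, 50)
  expect_equal(mcfadden_r2(ll, ll0), 1 - ll / ll0)
  expect_error(mcfadden_r2(-120, -100), "below null")
  expect_error(mcfadden_r2(-50, 10), "negative")
  # monotone in loglik for fixed null
  r <- vapply(c(-90, -80, -70), mcfadden_r2, numeric(1), null_loglik = -100)
  expect_false(is.unsorted(r))
})

test_that("the likelihood-ratio comparison reproduces printed-style arithmetic", {
  fixed <- list(loglik = -6138.570)
  crp <- list(loglik = -6124.668, random_columns = letters[1:5])
  cmp <- likelihood_ratio_test(fixed, crp, null_loglik = -6640)
  expect_equal(cmp$lr_statistic, 27.804)
  expect_equal(cmp$lr_df, 15)
  expect_equal(cmp$pseudo_r2_crp, 1 - (-6124.668) / (-6640))
  expect_lt(cmp$lr_p, 0.05)
  # degenerate and error cases
  same <- likelihood_ratio_test(list(loglik = -10), list(loglik = -10), df = 3)
  expect_equal(same$lr_statistic, 0)
  expect_error(likelihood_ratio_test(list(loglik = -10),
                                     list(loglik = -11), df = 3), "negative")
})

test_that("model comparison on fitted models is internally consistent", {
  d <- compact_design(n = 1500, seed = 21)
  ff <- fit_fixed(d)
  fc <- fit_crp(d, crp_spec(D = 60), fixed = ff)
  cmp <- likelihood_ratio_test(ff, fc)
  expect_equal(cmp$lr_df, 15)
  expect_gte(cmp$lr_statistic, 0)
  expect_equal(cmp$null_loglik, ff$null_loglik)
  expect_gte(cmp$pseudo_r2_crp, cmp$pseudo_r2_fixed)
  expect_true(cmp$pseudo_r2_fixed >= 0 && cmp$pseudo_r2_fixed < 1)
})
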