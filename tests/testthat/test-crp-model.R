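fixed_params_from <- function(fit, random_columns, L = NULL) {
  pr <- length(random_columns)
  if (is.null(L)) L <- matrix(0, pr, pr)
  list(fixed_beta = fit$beta[setdiff(names(fit$beta), random_columns)],
       random_means = fit$beta[random_columns],
       cholesky = L, psi1 = fit$psi1)
}

test_that("drawn coefficients propagate the Cholesky structure", {
  dr <- halton_normal_draws(4, 2, 6)
  means <- c(a = 0.5, b = -1)
  zero <- draw_coefficients(means, matrix(0, 2, 2), dr)
  expect_equal(unique(as.vector(zero[, , 1])), 0.5)
  expect_equal(unique(as.vector(zero[, , 2])), -1)
  # identity factor, single known draw
  dr1 <- structure(list(values = array(c(1, 0), dim = c(1, 1, 2)),
                        primes = c(2, 3), discard = 0, D = 1),
                   class = "draw_matrix")
  b <- draw_coefficients(c(a = 1, b = 2), diag(2), dr1)
  expect_equal(as.vector(b), c(2, 2))
  expect_error(draw_coefficients(means, diag(3), dr), "mismatch")
})

test_that("drawn-coefficient sample covariance approaches the implied one", {
  set.seed(41)
  L <- matrix(c(0.8, 0, -0.5, 0.6), 2, 2, byrow = FALSE)
  L[upper.tri(L)] <- 0
  phi <- array(rnorm(2e5), dim = c(1, 1e5, 2))
  dr <- structure(list(values = phi, primes = c(2, 3), discard = 0, D = 1e5),
                  class = "draw_matrix")
  b <- draw_coefficients(c(x = 0, y = 0), L, dr)
  emp <- cov(cbind(as.vector(b[, , 1]), as.vector(b[, , 2])))
  expect_equal(emp, L %*% t(L), tolerance = 0.05)
})

test_that("the simulated likelihood nests the fixed model exactly", {
  d <- compact_design(n = 800, seed = 22)
  ff <- fit_fixed(d)
  params <- fixed_params_from(ff, default_random_columns())
  for (D in c(1, 10)) {
    dr <- halton_normal_draws(d$n_rows, 5, D)
    expect_equal(as.numeric(simulated_loglik(params, d, dr)),
                 fixed_loglik(ff$beta, ff$psi1, d))
  }
})

test_that("the simulated likelihood is invariant to permuting observations", {
  d <- compact_design(n = 800, seed = 22)
  ff <- fit_fixed(d)
  L <- diag(0.4, 5)
  L[3, 1] <- -0.3
  params <- fixed_params_from(ff, default_random_columns(), L)
  dr <- halton_normal_draws(d$n_rows, 5, 25)
  ll <- as.numeric(simulated_loglik(params, d, dr))
  set.seed(42)
  perm <- sample(d$n_rows)
  dperm <- make_design(d$X[perm, ], d$y[perm], default_random_columns())
  drp <- dr
  drp$values <- dr$values[perm, , , drop = FALSE]
  expect_equal(as.numeric(simulated_loglik(params, dperm, drp)), ll)
})

test_that("the simulated likelihood stabilizes as draws increase", {
  d <- compact_design(n = 800, seed = 22)
  ff <- fit_fixed(d)
  L <- diag(0.5, 5)
  params <- fixed_params_from(ff, default_random_columns(), L)
  lls <- vapply(c(50, 100, 200, 400), function(D) {
    dr <- halton_normal_draws(d$n_rows, 5, D)
    as.numeric(simulated_loglik(params, d, dr))
  }, numeric(1))
  gaps <- abs(diff(lls))
  expect_lt(gaps[3], gaps[1])
})

test_that("fitting recovers structure and dominates the nested fixed model", {
  d <- compact_design(n = 1500, seed = 21)
  ff <- fit_fixed(d)
  fc <- fit_crp(d, crp_spec(D = 60), fixed = ff)
  expect_gte(fc$loglik, ff$loglik)
  expect_true(all(diag(fc$cholesky) >= 0))
  # sign normalization preserves the implied covariance and the reported
  # log-likelihood is the one at the estimated parameters
  expect_equal(unname(fc$cholesky %*% t(fc$cholesky)),
               fc$cholesky_raw %*% t(fc$cholesky_raw))
  expect_equal(unname(fc$estimate["psi1"]), fc$psi1)
  # threshold must be positive, probabilities proper
  expect_gt(fc$psi1, 0)
})

test_that("the random-parameter covariance summary is exact arithmetic", {
  fc <- list(cholesky = matrix(c(1, 1, 0, 1), 2, 2,
                               dimnames = list(c("a", "b"), c("a", "b"))),
             cholesky_raw = matrix(c(1, 1, 0, 1), 2, 2),
             fixed_columns = character(0),
             cov = diag(0.01, 4 + 1),
             estimate = c(mean_a = 0, mean_b = 0, chol_a = 1,
                          `chol_b.a` = 1, chol_b = 1),
             z = c(0, 0, 10, 10, 10), p = c(1, 1, 0, 0, 0))
  names(fc$z) <- names(fc$p) <- names(fc$estimate)
  dimnames(fc$cov) <- list(names(fc$estimate), names(fc$estimate))
  class(fc) <- "crp_fit"
  rpc <- random_param_covariance(fc)
  expect_equal(unname(rpc$covariance), matrix(c(1, 1, 1, 2), 2, 2))
  expect_equal(rpc$correlation["a", "b"], 1 / sqrt(2))
  expect_true(all(abs(rpc$correlation) <= 1 + 1e-12))
  # diagonal factor implies independence
  fc$cholesky <- diag(c(2, 3))
  dimnames(fc$cholesky) <- list(c("a", "b"), c("a", "b"))
  fc$cholesky_raw <- fc$cholesky
  rpc2 <- random_param_covariance(fc)
  expect_equal(unname(rpc2$covariance), diag(c(4, 9)))
  expect_equal(rpc2$correlation["a", "b"], 0)
})
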