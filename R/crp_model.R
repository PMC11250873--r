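# Correlated random parameters ordered logit, estimated by simulated
# maximum likelihood.  Coefficients on the designated driver-behaviour
# columns vary across observations as beta_i = b + L phi_i with phi_i
# standard normal, so the coefficient covariance is L L' with L an
# unrestricted lower-triangular Cholesky factor; off-diagonal elements carry
# the correlation between random parameters.  The integral over phi is
# approximated by averaging over Halton draws.

#' Specification of the correlated random parameters model
#'
#' @param random_columns Design columns given random coefficients.
#' @param D Halton draws per observation (default 900, the stable-estimate
#'   draw count used in this literature).
#' @param discard,primes Passed to [halton_normal_draws()].
#' @return A `crp_spec` list.
#' @export
crp_spec <- function(random_columns = default_random_columns(), D = 900,
                     discard = 10, primes = NULL) {
  if (length(random_columns) == 0) stop("random_columns must be non-empty")
  if (D < 1) stop("D must be >= 1")
  structure(list(random_columns = random_columns, D = D, discard = discard,
                 primes = primes), class = "crp_spec")
}

# split a design into fixed and random blocks, preserving column order
crp_blocks <- function(design, random_columns) {
  miss <- setdiff(random_columns, colnames(design$X))
  if (length(miss)) stop("random column(s) not in design: ",
                         paste(miss, collapse = ", "))
  fixed_columns <- setdiff(colnames(design$X), random_columns)
  list(Xf = design$X[, fixed_columns, drop = FALSE],
       Xr = design$X[, random_columns, drop = FALSE],
       fixed_columns = fixed_columns, random_columns = random_columns)
}

# row-major lower-triangle <-> matrix
vech_to_L <- function(v, pr) {
  L <- matrix(0, pr, pr)
  L[upper.tri(L, diag = TRUE)] <- 0
  pos <- 1L
  for (j in seq_len(pr)) for (k in seq_len(j)) {
    L[j, k] <- v[pos]; pos <- pos + 1L
  }
  L
}
L_to_vech <- function(L) {
  pr <- nrow(L)
  v <- numeric(pr * (pr + 1) / 2)
  pos <- 1L
  for (j in seq_len(pr)) for (k in seq_len(j)) {
    v[pos] <- L[j, k]; pos <- pos + 1L
  }
  v
}

crp_param_names <- function(fixed_columns, random_columns) {
  pr <- length(random_columns)
  chol_names <- character(0)
  for (j in seq_len(pr)) for (k in seq_len(j))
    chol_names <- c(chol_names,
                    if (j == k) paste0("chol_", random_columns[j])
                    else paste0("chol_", random_columns[j], ".", random_columns[k]))
  c(fixed_columns, paste0("mean_", random_columns), chol_names, "psi1")
}

#' Per-observation, per-draw random coefficient vectors
#'
#' Materializes `beta_i^(d) = b + L phi_i^(d)` for every observation and
#' draw.
#'
#' @param random_means Mean vector `b` (length `pr`).
#' @param cholesky Lower-triangular `pr x pr` factor `L`.
#' @param draws A `draw_matrix` with `pr` dimensions.
#' @return Array `n_obs x D x pr` of coefficient values.
#' @export
draw_coefficients <- function(random_means, cholesky, draws) {
  pr <- length(random_means)
  dm <- dim(draws$values)
  if (!is.matrix(cholesky) || any(dim(cholesky) != pr) || dm[3] != pr)
    stop("dimension mismatch between means, Cholesky factor and draws")
  out <- array(0, dim = dm)
  for (k in seq_len(pr)) {
    acc <- matrix(random_means[k], dm[1], dm[2])
    for (m in seq_len(k)) acc <- acc + cholesky[k, m] * draws$values[, , m]
    out[, , k] <- acc
  }
  out
}

#' Simulated log-likelihood of the correlated model
#'
#' Averages, per observation, the ordered-logit probability of the observed
#' outcome over the Halton draws of the random coefficients, then sums the
#' logs.  With a zero Cholesky factor every draw yields the same
#' probability, so the value collapses exactly to [fixed_loglik()].
#' Simulated probabilities are floored at `floor_eps` (flagged via the
#' `n_floored` attribute) to keep the log finite.
#'
#' @param params List with `fixed_beta` (named, aligned to the fixed-role
#'   columns), `random_means`, `cholesky` (lower-triangular matrix), `psi1`.
#' @param design A `design_matrix`.
#' @param draws A `draw_matrix` built for `nrow(design$X)` observations and
#'   the random dimensions.
#' @param floor_eps Probability floor (default 1e-300).
#' @return Scalar log-likelihood with attribute `n_floored`.
#' @export
simulated_loglik <- function(params, design, draws, floor_eps = 1e-300) {
  if (params$psi1 <= 0) stop("psi1 must be > 0")
  rc <- colnames_or(names(params$random_means), length(params$random_means))
  blocks <- crp_blocks(design, rc)
  theta <- c(params$fixed_beta[blocks$fixed_columns], params$random_means,
             L_to_vech(params$cholesky), log(params$psi1))
  res <- crp_sll_cpp(theta, blocks$Xf, blocks$Xr, design$y, draws$values,
                     want_grad = FALSE, floor_eps = floor_eps)
  structure(res$ll, n_floored = res$n_floored)
}

colnames_or <- function(nm, k) {
  if (is.null(nm)) stop("random_means must be named with design column names")
  nm
}

#' Fit the correlated random parameters ordered logit
#'
#' Simulated maximum likelihood over Halton draws.  Initialization takes the
#' fixed-model coefficients for all means and `0.1 * I` for the Cholesky
#' factor; maximization is quasi-Newton (BFGS) with the analytic simulated
#' gradient, followed by Newton polishing.  Standard errors come from the
#' inverse numerical Hessian of the simulated log-likelihood.  The reported
#' Cholesky factor is column-sign normalized (diagonal made nonnegative),
#' which leaves the implied covariance `L L'` unchanged.
#'
#' @param design A `design_matrix`.
#' @param spec A [crp_spec()].
#' @param fixed Optional pre-computed [fit_fixed()] result used as start.
#' @param gtol Gradient infinity-norm target (default 1e-4; the simulated
#'   surface is flatter than the fixed one, scale with n).
#' @param draws Optional pre-built `draw_matrix` (otherwise built from
#'   `spec`).
#' @return A `crp_fit` list with `fixed_beta`, `random_means`, `cholesky`
#'   (sign-normalized), `psi1`, `loglik`, full parameter covariance `cov`,
#'   `estimate`/`se`/`z`/`p` per reported parameter, provenance (`D`,
#'   `primes`, `discard`), convergence diagnostics, and the nested
#'   `fixed_fit`.
#' @export
fit_crp <- function(design, spec = crp_spec(), fixed = NULL, gtol = 1e-4,
                    draws = NULL) {
  blocks <- crp_blocks(design, spec$random_columns)
  pf <- length(blocks$fixed_columns)
  pr <- length(blocks$random_columns)
  if (is.null(fixed)) fixed <- fit_fixed(design)
  if (is.null(draws))
    draws <- halton_normal_draws(design$n_rows, pr, spec$D,
                                 discard = spec$discard, primes = spec$primes)
  L0 <- diag(0.1, pr)
  theta <- c(fixed$beta[blocks$fixed_columns],
             fixed$beta[blocks$random_columns],
             L_to_vech(L0), log(fixed$psi1))
  par_names <- crp_param_names(blocks$fixed_columns, blocks$random_columns)
  names(theta) <- par_names

  # one C++ pass computes the value and gradient together; cache them per
  # parameter point since BFGS asks for both at every accepted point
  cache <- new.env(parent = emptyenv())
  eval_point <- function(th) {
    if (!is.null(cache$theta) && identical(cache$theta, th)) return(cache$res)
    res <- crp_sll_cpp(th, blocks$Xf, blocks$Xr, design$y, draws$values, TRUE)
    cache$theta <- th
    cache$res <- res
    res
  }
  negll <- function(th) -eval_point(th)$ll
  neggrad <- function(th) -eval_point(th)$grad
  opt <- stats::optim(theta, negll, neggrad, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-8))
  theta <- opt$par
  g <- neggrad(theta)
  # Newton polish: a few rounds of numerical-Hessian Newton steps
  for (round in 1:3) {
    if (max(abs(g)) < gtol) break
    Hp <- stats::optimHess(theta, negll, neggrad)
    f_cur <- negll(theta)
    improved <- FALSE
    for (it in 1:5) {
      step <- tryCatch(solve(Hp, g), error = function(e) NULL)
      if (is.null(step)) break
      cand <- theta - step
      f_cand <- negll(cand)
      if (f_cand > f_cur) break
      improved <- improved || f_cand < f_cur
      theta <- cand
      f_cur <- f_cand
      g <- neggrad(theta)
      if (max(abs(g)) < gtol) break
    }
    if (!improved) break
  }
  grad_norm <- max(abs(g))
  H <- stats::optimHess(theta, negll, neggrad)
  cov <- tryCatch(solve(H), error = function(e) {
    warning("near-singular Hessian; standard errors flagged NA")
    matrix(NA_real_, length(theta), length(theta))
  })
  dimnames(cov) <- list(par_names, par_names)

  final <- crp_sll_cpp(theta, blocks$Xf, blocks$Xr, design$y, draws$values, TRUE)
  nL <- pr * (pr + 1) / 2
  idx_L <- pf + pr + seq_len(nL)
  L_hat <- vech_to_L(theta[idx_L], pr)
  # column-sign normalization: L and L with a negated column imply the same
  # L L', so report with a nonnegative diagonal
  flip <- diag(L_hat) < 0
  L_rep <- L_hat
  L_rep[, flip] <- -L_rep[, flip]
  theta_rep <- theta
  theta_rep[idx_L] <- L_to_vech(L_rep)
  psi1 <- exp(theta[pf + pr + nL + 1])

  se <- sqrt(pmax(diag(cov), 0))
  estimate <- theta_rep
  estimate[length(theta)] <- psi1
  se[length(theta)] <- psi1 * se[length(theta)]
  names(estimate) <- names(se) <- par_names
  z <- estimate / se
  rownames(L_rep) <- colnames(L_rep) <- blocks$random_columns

  structure(list(
    fixed_beta = theta[seq_len(pf)],
    random_means = stats::setNames(theta[pf + seq_len(pr)], blocks$random_columns),
    cholesky = L_rep, cholesky_raw = L_hat, psi1 = unname(psi1),
    loglik = final$ll, n_floored = final$n_floored,
    theta = theta, cov = cov,
    estimate = estimate, se = se, z = z, p = 2 * stats::pnorm(-abs(z)),
    converged = opt$convergence == 0, grad_norm = grad_norm,
    D = spec$D, primes = draws$primes, discard = draws$discard,
    random_columns = blocks$random_columns,
    fixed_columns = blocks$fixed_columns,
    n = design$n_rows, fixed_fit = fixed),
    class = "crp_fit")
}

#' @export
print.crp_fit <- function(x, ...) {
  cat(sprintf(
    "Correlated random parameters ordered logit: n = %d, D = %d draws\n",
    x$n, x$D))
  cat(sprintf("  simulated logLik = %.3f (fixed-parameter nested model: %.3f)\n",
              x$loglik, x$fixed_fit$loglik))
  cat(sprintf("  threshold psi1 = %.3f, gradient norm %.2e\n",
              x$psi1, x$grad_norm))
  print(round(coef_table(x), 4))
  invisible(x)
}

#' Random-coefficient covariance and correlation
#'
#' Reconstructs the coefficient covariance `L L'` and its correlation
#' matrix from the fitted Cholesky factor, with delta-method standard
#' errors for the covariance diagonal and the per-element z/p of the
#' Cholesky terms carried from the fit.
#'
#' @param fit A `crp_fit`.
#' @return List with `covariance`, `correlation`, `diag_se` (delta-method
#'   SEs of the covariance diagonal) and `cholesky_tests` (z and p per
#'   Cholesky element).
#' @export
random_param_covariance <- function(fit) {
  L <- fit$cholesky
  pr <- nrow(L)
  Sigma <- L %*% t(L)
  sd_ <- sqrt(diag(Sigma))
  corr <- Sigma / tcrossprod(sd_)
  corr[!is.finite(corr)] <- 0
  # delta method: Sigma_jj = sum_k L_jk^2, d/dL_jk = 2 L_jk
  nL <- pr * (pr + 1) / 2
  idx_L <- length(fit$fixed_columns) + pr + seq_len(nL)
  covL <- fit$cov[idx_L, idx_L, drop = FALSE]
  diag_se <- numeric(pr)
  vech_index <- function(j, k) (j - 1) * j / 2 + k
  for (j in seq_len(pr)) {
    grad <- numeric(nL)
    for (k in seq_len(j)) grad[vech_index(j, k)] <- 2 * fit$cholesky_raw[j, k]
    diag_se[j] <- sqrt(max(0, drop(t(grad) %*% covL %*% grad)))
  }
  chol_names <- grep("^chol_", names(fit$estimate), value = TRUE)
  list(covariance = Sigma, correlation = corr,
       diag_se = stats::setNames(diag_se, rownames(L)),
       cholesky_tests = data.frame(
         element = chol_names,
         estimate = unname(fit$estimate[chol_names]),
         z = unname(fit$z[chol_names]),
         p = unname(fit$p[chol_names]), row.names = NULL))
}

# Draw-averaged category probabilities at a single covariate row, used for
# marginal effects under the mixed model.  Deterministic: fresh Halton draws
# of size D for one observation.
crp_row_probs <- function(theta, fixed_columns, random_columns, x_row, draws1) {
  pf <- length(fixed_columns)
  pr <- length(random_columns)
  nL <- pr * (pr + 1) / 2
  bf <- theta[seq_len(pf)]
  br <- theta[pf + seq_len(pr)]
  L <- vech_to_L(theta[pf + pr + seq_len(nL)], pr)
  psi <- exp(theta[pf + pr + nL + 1])
  xf <- x_row[fixed_columns]
  xr <- x_row[random_columns]
  phi <- matrix(draws1$values[1, , ], ncol = pr)   # D x pr
  eta <- sum(xf * bf) + drop(phi %*% (t(L) %*% xr)) + sum(xr * br)
  p0 <- stats::plogis(-eta)
  p01 <- stats::plogis(psi - eta)
  c(mean(p0), mean(p01 - p0), mean(1 - p01))
}
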