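# Fixed-parameter ordered logit for the warning-system count (0/1/2).
#
# Latent propensity y* = X b + e with logistic error; categories cut at
# thresholds (-Inf, 0, psi1, +Inf).  The intercept is estimated and the
# first threshold fixed at zero for identification, so psi1 > 0 is the only
# free threshold.  psi1 is optimized as exp(delta) to enforce positivity and
# reported on the natural scale with a delta-method standard error.

ol_category_probs <- function(eta, psi1, y = NULL) {
  p0 <- stats::plogis(-eta)
  p01 <- stats::plogis(psi1 - eta)
  if (is.null(y)) return(cbind(p0, p01 - p0, 1 - p01))
  ifelse(y == 0L, p0, ifelse(y == 1L, p01 - p0, 1 - p01))
}

#' Fixed-parameter ordered logit log-likelihood
#'
#' @param beta Coefficient vector aligned with `design$X` columns.
#' @param psi1 Upper threshold, strictly positive.
#' @param design A `design_matrix` from [encode_design()].
#' @return The log-likelihood.  Rows with zero probability contribute
#'   `-Inf`; the result is then `-Inf` with attribute `zero_rows`.
#' @export
fixed_loglik <- function(beta, psi1, design) {
  if (psi1 <= 0) stop("psi1 must be > 0")
  eta <- drop(design$X %*% beta)
  p <- ol_category_probs(eta, psi1, design$y)
  if (any(p <= 0)) {
    ll <- -Inf
    attr(ll, "zero_rows") <- which(p <= 0)
    return(ll)
  }
  sum(log(p))
}

# negative log-likelihood and gradient in theta = c(beta, delta), psi1=exp(delta)
ol_negll <- function(theta, design) {
  p <- length(theta)
  beta <- theta[-p]
  psi1 <- exp(theta[p])
  eta <- drop(design$X %*% beta)
  pr <- ol_category_probs(eta, psi1, design$y)
  if (any(pr <= 0)) return(.Machine$double.xmax)
  -sum(log(pr))
}

ol_negll_grad <- function(theta, design) {
  p <- length(theta)
  beta <- theta[-p]
  psi1 <- exp(theta[p])
  eta <- drop(design$X %*% beta)
  y <- design$y
  f0 <- stats::dlogis(-eta)           # density at lower cut 0
  f1 <- stats::dlogis(psi1 - eta)     # density at upper cut psi1
  pr <- ol_category_probs(eta, psi1, y)
  pr <- pmax(pr, 1e-300)
  # dP/deta by outcome
  dP_deta <- ifelse(y == 0L, -f0, ifelse(y == 1L, -f1 + f0, f1))
  # dP/dpsi1: only categories 1 (+f1) and 2 (-f1) touch psi1
  dP_dpsi <- ifelse(y == 0L, 0, ifelse(y == 1L, f1, -f1))
  w <- dP_deta / pr
  g_beta <- -drop(crossprod(design$X, w))
  g_delta <- -sum(dP_dpsi / pr) * psi1
  c(g_beta, g_delta)
}

#' Fit the fixed-parameter ordered logit by maximum likelihood
#'
#' Quasi-Newton (BFGS) maximization with the analytic gradient, followed by
#' Newton polishing until the gradient infinity-norm falls below `gtol`.
#' Standard errors come from the inverse numerical Hessian at the optimum.
#'
#' @param design A `design_matrix`; every outcome category must be present.
#' @param gtol Gradient infinity-norm convergence tolerance (default 1e-6).
#' @param start Optional named start vector `c(beta, delta = log psi1)`.
#' @return A `fixed_fit` list: `beta`, `psi1`, `loglik`, `theta`, `cov`
#'   (covariance of `c(beta, delta)`), `se`, `z`, `p` (with psi1's entries
#'   delta-method transformed to the natural scale), `converged`,
#'   `grad_norm`, `n`, plus the condition number of the design
#'   (`design_condition`) as a multicollinearity diagnostic.
#' @export
fit_fixed <- function(design, gtol = 1e-6, start = NULL) {
  X <- design$X
  y <- design$y
  shares <- tabulate(y + 1L, 3) / length(y)
  if (any(shares == 0)) stop("every outcome category must appear in the data")
  if (is.null(start)) {
    alpha0 <- -stats::qlogis(shares[1])
    psi0 <- stats::qlogis(shares[1] + shares[2]) + alpha0
    start <- c(stats::setNames(rep(0, ncol(X)), colnames(X)), delta = log(psi0))
    start["constant"] <- alpha0
  }
  opt <- stats::optim(start, ol_negll, ol_negll_grad, design = design,
                      method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  theta <- opt$par
  # Newton polish on the analytic gradient; damped steps for flat or
  # ill-conditioned directions (near-empty categories)
  for (it in 1:50) {
    g <- ol_negll_grad(theta, design)
    if (max(abs(g)) < gtol) break
    H <- stats::optimHess(theta, ol_negll, ol_negll_grad, design = design)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    f_cur <- ol_negll(theta, design)
    lambda <- 1
    repeat {
      cand <- theta - lambda * step
      if (ol_negll(cand, design) <= f_cur) break
      lambda <- lambda / 2
      if (lambda < 1e-4) break
    }
    if (lambda < 1e-4) break
    theta <- cand
  }
  g <- ol_negll_grad(theta, design)
  grad_norm <- max(abs(g))
  H <- stats::optimHess(theta, ol_negll, ol_negll_grad, design = design)
  cov <- tryCatch(solve(H), error = function(e) matrix(NA_real_, length(theta), length(theta)))
  p <- length(theta)
  beta <- theta[-p]
  psi1 <- exp(theta[p])
  se <- sqrt(pmax(diag(cov), 0))
  est_nat <- c(beta, psi1 = unname(psi1))
  se_nat <- se
  se_nat[p] <- psi1 * se[p]             # delta method for exp()
  names(se_nat) <- names(est_nat)
  z <- est_nat / se_nat
  sv <- svd(X, nu = 0, nv = 0)$d
  structure(list(
    beta = beta, psi1 = unname(psi1), loglik = -opt$value,
    theta = theta, cov = cov,
    estimate = est_nat, se = se_nat, z = z,
    p = 2 * stats::pnorm(-abs(z)),
    converged = grad_norm < gtol, grad_norm = grad_norm,
    iterations = opt$counts[["function"]],
    n = length(y), shares = shares,
    null_loglik = sum(length(y) * shares * log(shares)),
    design_condition = max(sv) / min(sv)),
    class = "fixed_fit")
}

#' @export
print.fixed_fit <- function(x, ...) {
  cat(sprintf("Fixed-parameter ordered logit: n = %d, logLik = %.3f%s\n",
              x$n, x$loglik, if (x$converged) "" else "  [NOT CONVERGED]"))
  print(round(coef_table(x), 4))
  invisible(x)
}

#' Coefficient table of a fitted model
#'
#' @param fit A `fixed_fit` or `crp_fit`.
#' @return Data.frame with columns `variable`, `coefficient`,
#'   `std_error`, `z_value`, `p_value`.
#' @export
coef_table <- function(fit) {
  data.frame(variable = names(fit$estimate),
             coefficient = unname(fit$estimate),
             std_error = unname(fit$se),
             z_value = unname(fit$z),
             p_value = unname(fit$p),
             row.names = NULL)
}

#' Predicted category probabilities
#'
#' @param fit A `fixed_fit`.
#' @param X Design matrix with the same columns the model was fitted on.
#' @return Matrix `n x 3` of probabilities for outcomes 0, 1, 2; rows sum
#'   to 1.
#' @export
predict_probs <- function(fit, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1, dimnames = list(NULL, names(X)))
  if (!identical(colnames(X), names(fit$beta)))
    stop("design columns do not match the fitted coefficients")
  eta <- drop(X %*% fit$beta)
  pr <- ol_category_probs(eta, fit$psi1)
  colnames(pr) <- c("p0", "p1", "p2")
  pr
}
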