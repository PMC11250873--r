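# Marginal (partial) effects on the outcome-category probabilities, model
# fit indices and nested-model comparison.
#
# For an indicator covariate the effect on category k is
#   P(Y = k | Xbar, X_j = 1) - P(Y = k | Xbar, X_j = 0)
# with all other covariates at their sample means; the numeric year-index
# column uses a +1 increment from its mean instead.  Because probabilities
# are conserved, the three effects of any variable sum to zero.

# parameter-vector probability function for either model class, evaluated
# at a single covariate row
fit_prob_fun <- function(fit) {
  if (inherits(fit, "fixed_fit")) {
    nm <- names(fit$beta)
    function(theta, x_row) {
      p <- length(theta)
      eta <- sum(x_row[nm] * theta[-p])
      unname(drop(ol_category_probs(eta, exp(theta[p]))))
    }
  } else if (inherits(fit, "crp_fit")) {
    draws1 <- halton_normal_draws(1, length(fit$random_columns), fit$D,
                                  discard = fit$discard, primes = fit$primes)
    function(theta, x_row)
      crp_row_probs(theta, fit$fixed_columns, fit$random_columns, x_row, draws1)
  } else stop("unsupported fit class")
}

effect_variables <- function(design) {
  setdiff(colnames(design$X), "constant")
}

# the two evaluation rows for one variable: indicator 0 -> 1, or mean -> mean+1
effect_rows <- function(xbar, variable) {
  if (variable == "year_index") {
    x0 <- xbar
    x1 <- xbar; x1[variable] <- xbar[variable] + 1
  } else {
    vals <- NULL
    x0 <- xbar; x0[variable] <- 0
    x1 <- xbar; x1[variable] <- 1
  }
  list(x0 = x0, x1 = x1)
}

#' Marginal effect of one variable on one outcome category
#'
#' @param fit A `fixed_fit` or `crp_fit`.
#' @param design The `design_matrix` the model was fitted on.
#' @param variable Design column name (an indicator, or `year_index` which
#'   uses a +1 increment from its mean).
#' @param k Outcome category, 0, 1 or 2.
#' @return The probability difference.
#' @export
marginal_effect_indicator <- function(fit, design, variable, k) {
  if (!variable %in% colnames(design$X)) stop("unknown design column: ", variable)
  if (variable != "year_index" &&
      !all(design$X[, variable] %in% c(0, 1)))
    stop("'", variable, "' is not an indicator column and has no increment rule")
  xbar <- colMeans(design$X)
  rows <- effect_rows(xbar, variable)
  pf <- fit_prob_fun(fit)
  (pf(fit$theta, rows$x1) - pf(fit$theta, rows$x0))[k + 1L]
}

#' Marginal effects table
#'
#' Computes, for every non-constant design column, the effect on each of
#' the three outcome-category probabilities, with delta-method p-values
#' obtained from the numerical gradient of each effect with respect to the
#' full parameter vector.
#'
#' @param fit A `fixed_fit` or `crp_fit`.
#' @param design The fitted `design_matrix`.
#' @param variables Columns to evaluate (default all non-constant columns).
#' @param average_over `"means"` (the default: other covariates held at
#'   sample means) or `"observations"` (effects averaged over the sample
#'   rows; a sensitivity variant, reported without p-values).
#' @param pvalues Compute delta-method p-values (default TRUE under
#'   `"means"`).
#' @return An `effects_table` data.frame: `variable`, then
#'   `effect_y0/p_y0/effect_y1/p_y1/effect_y2/p_y2`.  Effects per variable
#'   sum to zero across categories.
#' @export
marginal_effects <- function(fit, design, variables = effect_variables(design),
                             average_over = c("means", "observations"),
                             pvalues = NULL) {
  average_over <- match.arg(average_over)
  if (is.null(pvalues)) pvalues <- average_over == "means"
  if (pvalues && average_over == "observations")
    stop("p-values are only computed for the at-means variant")
  pfun <- fit_prob_fun(fit)
  theta <- fit$theta
  xbar <- colMeans(design$X)

  one_variable <- function(v) {
    if (average_over == "means") {
      rows <- effect_rows(xbar, v)
      eff <- pfun(theta, rows$x1) - pfun(theta, rows$x0)
    } else {
      eff <- obs_averaged_effect(fit, design, v)
    }
    pv <- rep(NA_real_, 3)
    if (pvalues) {
      se <- effect_se(fit, pfun, xbar, v)
      z <- eff / se
      pv <- 2 * stats::pnorm(-abs(z))
      pv[se == 0] <- 1
    }
    c(eff, pv)
  }
  res <- t(vapply(variables, one_variable, numeric(6)))
  out <- data.frame(variable = variables,
                    effect_y0 = res[, 1], effect_y1 = res[, 2],
                    effect_y2 = res[, 3],
                    p_y0 = res[, 4], p_y1 = res[, 5], p_y2 = res[, 6],
                    row.names = NULL)
  out <- out[, c("variable", "effect_y0", "p_y0", "effect_y1", "p_y1",
                 "effect_y2", "p_y2")]
  class(out) <- c("effects_table", "data.frame")
  attr(out, "average_over") <- average_over
  out
}

# delta-method SEs of the three effects of one variable
effect_se <- function(fit, pfun, xbar, variable) {
  theta <- fit$theta
  rows <- effect_rows(xbar, variable)
  eff_fun <- function(th) pfun(th, rows$x1) - pfun(th, rows$x0)
  np <- length(theta)
  G <- matrix(0, 3, np)
  h <- 1e-5 * pmax(1, abs(theta))
  for (j in seq_len(np)) {
    tp <- theta; tp[j] <- tp[j] + h[j]
    tm <- theta; tm[j] <- tm[j] - h[j]
    G[, j] <- (eff_fun(tp) - eff_fun(tm)) / (2 * h[j])
  }
  V <- G %*% fit$cov %*% t(G)
  sqrt(pmax(diag(V), 0))
}

# observation-averaged variant (no p-values): average the probability
# difference over the sample rows
obs_averaged_effect <- function(fit, design, variable) {
  pfun <- fit_prob_fun(fit)
  X1 <- X0 <- design$X
  if (variable == "year_index") {
    X1[, variable] <- X1[, variable] + 1
  } else {
    X0[, variable] <- 0
    X1[, variable] <- 1
  }
  n <- nrow(X1)
  acc <- numeric(3)
  for (i in seq_len(n))
    acc <- acc + pfun(fit$theta, X1[i, ]) - pfun(fit$theta, X0[i, ])
  acc / n
}

#' Delta-method p-values for an effects table
#'
#' @param fit The fitted model used for `effects`.
#' @param design The fitted `design_matrix`.
#' @param effects An `effects_table` (at-means) whose p-value columns should
#'   be (re)computed.
#' @return The table with `p_y0`, `p_y1`, `p_y2` filled.
#' @export
effect_pvalues <- function(fit, design, effects) {
  pfun <- fit_prob_fun(fit)
  xbar <- colMeans(design$X)
  for (i in seq_len(nrow(effects))) {
    v <- effects$variable[i]
    se <- effect_se(fit, pfun, xbar, v)
    eff <- unlist(effects[i, c("effect_y0", "effect_y1", "effect_y2")])
    z <- eff / se
    pv <- 2 * stats::pnorm(-abs(z))
    pv[se == 0] <- 1
    effects[i, c("p_y0", "p_y1", "p_y2")] <- pv
  }
  effects
}

# closed-form log-likelihood of the intercept+threshold-only null model:
# the MLE fits the empirical category shares exactly
null_loglik_design <- function(design) {
  counts <- tabulate(design$y + 1L, 3)
  sum(counts[counts > 0] * log(counts[counts > 0] / sum(counts)))
}

#' McFadden pseudo R-squared
#'
#' `1 - loglik / null_loglik`, with the null model containing only the
#' intercept and threshold (i.e. fitting the empirical category shares).
#'
#' @param loglik Fitted-model log-likelihood.
#' @param null_loglik Null-model log-likelihood (negative).
#' @return Value in `[0, 1)`.
#' @export
mcfadden_r2 <- function(loglik, null_loglik) {
  if (null_loglik >= 0) stop("null_loglik must be negative")
  if (loglik < null_loglik)
    stop("loglik below null log-likelihood; check model convergence")
  1 - loglik / null_loglik
}

#' Likelihood-ratio comparison of the fixed and correlated models
#'
#' The correlated model nests the fixed one at a zero Cholesky factor, so
#' twice the log-likelihood gap is referred to a chi-square with one degree
#' of freedom per free Cholesky element.  Because the null pins variance
#' parameters to the boundary of the parameter space, the chi-square
#' reference is conservative in direction (true p-values are smaller).
#'
#' @param fixed A `fixed_fit` (or any list with `loglik`).
#' @param crp A `crp_fit` (or any list with `loglik`).
#' @param df Degrees of freedom; defaults to the number of free Cholesky
#'   elements `n_r (n_r + 1) / 2` taken from `crp`.
#' @param null_loglik Optional null-model log-likelihood for the pseudo
#'   R-squared entries; taken from the nested fit's design shares when a
#'   full `crp_fit` is supplied.
#' @return A `fit_comparison` list: `loglik_fixed`, `loglik_crp`,
#'   `null_loglik`, `pseudo_r2_fixed`, `pseudo_r2_crp`, `lr_statistic`,
#'   `lr_df`, `lr_p`.
#' @export
likelihood_ratio_test <- function(fixed, crp, df = NULL, null_loglik = NULL) {
  if (is.null(df)) {
    if (is.null(crp$random_columns))
      stop("supply df when crp is not a crp_fit")
    nr <- length(crp$random_columns)
    df <- nr * (nr + 1) / 2
  }
  stat <- 2 * (crp$loglik - fixed$loglik)
  if (stat < 0)
    stop("negative LR statistic: correlated model log-likelihood below the ",
         "nested fixed model; check convergence")
  if (is.null(null_loglik) && !is.null(fixed$null_loglik))
    null_loglik <- fixed$null_loglik
  r2f <- r2c <- NA_real_
  if (!is.null(null_loglik)) {
    r2f <- mcfadden_r2(fixed$loglik, null_loglik)
    r2c <- mcfadden_r2(crp$loglik, null_loglik)
  }
  structure(list(loglik_fixed = fixed$loglik, loglik_crp = crp$loglik,
                 null_loglik = null_loglik,
                 pseudo_r2_fixed = r2f, pseudo_r2_crp = r2c,
                 lr_statistic = stat, lr_df = df,
                 lr_p = stats::pchisq(stat, df, lower.tail = FALSE)),
            class = "fit_comparison")
}

#' @export
print.fit_comparison <- function(x, ...) {
  cat("Model comparison (fixed vs correlated random parameters)\n")
  cat(sprintf("  logLik fixed: %.3f   logLik correlated: %.3f\n",
              x$loglik_fixed, x$loglik_crp))
  if (!is.null(x$null_loglik))
    cat(sprintf("  McFadden pseudo-R2: %.3f vs %.3f (null logLik %.3f)\n",
                x$pseudo_r2_fixed, x$pseudo_r2_crp, x$null_loglik))
  cat(sprintf("  LR statistic %.3f on %d df, p = %.4g\n",
              x$lr_statistic, x$lr_df, x$lr_p))
  invisible(x)
}
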