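# Satterthwaite degrees of freedom for lmer fixed effects.
#
# For each coefficient, df = 2 * Var(beta_i)^2 / Var(Var(beta_i)), where
# the outer variance is obtained by the delta method: the gradient of
# Var(beta_i) with respect to the variance parameters (theta, sigma) times
# the asymptotic covariance of those parameters, taken as 2 * H^{-1} with H
# the Hessian of the (RE)ML criterion. Everything is computed from lme4's
# deviance function by finite differences; no external df package is
# required.

num_grad <- function(f, x, rel_h = 1e-4) {
  h <- rel_h * pmax(abs(x), 1)
  vapply(seq_along(x), function(i) {
    xp <- x; xm <- x
    xp[i] <- x[i] + h[i]; xm[i] <- x[i] - h[i]
    (f(xp) - f(xm)) / (2 * h[i])
  }, numeric(1))
}

num_hess <- function(f, x, rel_h = 1e-4) {
  k <- length(x)
  h <- rel_h * pmax(abs(x), 1)
  H <- matrix(NA_real_, k, k)
  f0 <- f(x)
  for (i in seq_len(k)) {
    xp <- x; xm <- x
    xp[i] <- x[i] + h[i]; xm[i] <- x[i] - h[i]
    H[i, i] <- (f(xp) - 2 * f0 + f(xm)) / h[i]^2
    for (j in seq_len(i - 1L)) {
      xpp <- x; xpm <- x; xmp <- x; xmm <- x
      xpp[c(i, j)] <- x[c(i, j)] + h[c(i, j)]
      xpm[i] <- x[i] + h[i]; xpm[j] <- x[j] - h[j]
      xmp[i] <- x[i] - h[i]; xmp[j] <- x[j] + h[j]
      xmm[c(i, j)] <- x[c(i, j)] - h[c(i, j)]
      H[i, j] <- H[j, i] <-
        (f(xpp) - f(xpm) - f(xmp) + f(xmm)) / (4 * h[i] * h[j])
    }
  }
  H
}

# Rebuild lme4's profiled deviance function for a fitted model.
# (as.function.merMod needs lme4 on the search path, so it is avoided.)
lmer_devfun <- function(fit) {
  fr <- stats::model.frame(fit)
  reTrms <- lme4::mkReTrms(lme4::findbars(stats::formula(fit)), fr)
  lme4::mkLmerDevfun(fr = fr, X = lme4::getME(fit, "X"), reTrms = reTrms,
                     REML = lme4::isREML(fit))
}

# -2 log-likelihood (REML or ML criterion) as a function of the full
# variance-parameter vector c(theta, sigma), via lme4's profiled devfun.
make_full_deviance <- function(fit) {
  devfun <- lmer_devfun(fit)
  rho <- environment(devfun)
  reml <- lme4::isREML(fit)
  n <- nrow(stats::model.frame(fit))
  p <- length(lme4::fixef(fit))
  nmp <- n - if (reml) p else 0L
  function(par) {
    nth <- length(par) - 1L
    theta <- par[seq_len(nth)]
    sigma <- par[nth + 1L]
    devfun(theta)
    pwrss <- rho$resp$wrss() + rho$pp$sqrL(1)
    ld <- rho$pp$ldL2() + if (reml) rho$pp$ldRX2() else 0
    ld + nmp * log(2 * pi * sigma^2) + pwrss / sigma^2
  }
}

# Covariance of the fixed effects at arbitrary variance parameters.
make_vcov_beta <- function(fit) {
  devfun <- lmer_devfun(fit)
  rho <- environment(devfun)
  function(par) {
    nth <- length(par) - 1L
    devfun(par[seq_len(nth)])
    par[nth + 1L]^2 * as.matrix(rho$pp$unsc())
  }
}

#' Coefficient table with Satterthwaite degrees of freedom
#'
#' Estimates, standard errors, Satterthwaite-approximated degrees of
#' freedom, t statistics, and two-sided p values for every fixed effect of
#' a fitted `lmer` model. When the variance-parameter Hessian is not
#' positive definite (e.g. a singular fit), df fall back to the residual
#' count `n - p` and the table is flagged via the `df_method` attribute.
#'
#' @param fit a fitted `lmerMod`.
#' @return data.frame with columns `term`, `estimate`, `se`, `df`, `t`, `p`.
#' @export
satterthwaite_coefs <- function(fit) {
  beta <- lme4::fixef(fit)
  V0 <- as.matrix(stats::vcov(fit))
  se <- sqrt(diag(V0))
  tval <- beta / se
  n <- nrow(stats::model.frame(fit))
  p <- length(beta)
  par_hat <- c(lme4::getME(fit, "theta"), stats::sigma(fit))
  df <- rep(NA_real_, p)
  method <- "satterthwaite"
  res <- tryCatch({
    dev_full <- make_full_deviance(fit)
    vcov_fun <- make_vcov_beta(fit)
    H <- num_hess(dev_full, par_hat)
    A <- 2 * solve(H)
    for (i in seq_len(p)) {
      g <- num_grad(function(par) vcov_fun(par)[i, i], par_hat)
      denom <- as.numeric(t(g) %*% A %*% g)
      df[i] <- if (denom > 0) 2 * V0[i, i]^2 / denom else NA_real_
    }
    df
  }, error = function(e) rep(NA_real_, p))
  df <- res
  bad <- !is.finite(df) | df < 1
  if (any(bad)) {
    df[bad] <- n - p
    if (all(bad)) method <- "residual"
  }
  out <- data.frame(term = names(beta), estimate = unname(beta),
                    se = unname(se), df = df, t = unname(tval),
                    p = 2 * stats::pt(-abs(tval), df),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "df_method") <- method
  out
}
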