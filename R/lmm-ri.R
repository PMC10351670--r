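# Gaussian linear mixed model with a single random intercept grouping
# factor, y = X beta + b_g + e, b_g ~ N(0, tau2), e ~ N(0, sigma2).
#
# Fitting profiles beta and sigma2 out of the (restricted) likelihood and
# optimises the single variance ratio gamma = tau2/sigma2 in closed form
# from per-group sufficient statistics, so a fit costs a handful of p x p
# solves. This is the workhorse behind the spline trajectory models, where
# BIC selection requires fitting large candidate families.

ri_suffstats <- function(X, y, group) {
  group <- factor(group)
  S <- rowsum(X, group)          # per-group column sums of X
  q <- as.numeric(rowsum(y, group))
  m <- as.numeric(table(group))
  list(XtX = crossprod(X), Xty = crossprod(X, y), yty = sum(y^2),
       S = S, q = q, m = m, n = length(y), p = ncol(X),
       group = group, levels = levels(group))
}

ri_profile <- function(ss, gamma, reml) {
  w <- gamma / (1 + ss$m * gamma)
  A <- ss$XtX - crossprod(ss$S, ss$S * w)
  b <- ss$Xty - crossprod(ss$S, ss$q * w)
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch)) return(list(ok = FALSE))
  beta <- backsolve(ch, backsolve(ch, b, transpose = TRUE))
  u <- ss$q - as.numeric(ss$S %*% beta)   # per-group residual sums
  Q <- ss$yty - 2 * sum(beta * ss$Xty) + sum(beta * (ss$XtX %*% beta)) -
    sum(w * u^2)
  Q <- max(Q, 1e-300)
  ldV <- sum(log1p(ss$m * gamma))
  if (reml) {
    df <- ss$n - ss$p
    s2 <- Q / df
    ll <- -0.5 * (df * log(2 * pi * s2) + df + ldV + 2 * sum(log(diag(ch))))
  } else {
    s2 <- Q / ss$n
    ll <- -0.5 * (ss$n * log(2 * pi * s2) + ss$n + ldV)
  }
  list(ok = TRUE, beta = beta, sigma2 = s2, loglik = ll, w = w, u = u,
       chol = ch)
}

#' Fit a random-intercept linear mixed model
#'
#' Maximum-likelihood or REML fit of `y = X beta + b[group] + e` with
#' independent Gaussian errors and a Gaussian random intercept per group
#' level, via profiling of the variance ratio. Agrees with
#' \pkg{lme4}\code{::lmer} on the same model to numerical tolerance while
#' being much cheaper for repeated fits.
#'
#' @param X Fixed-effects design matrix (including intercept column).
#' @param y Response vector.
#' @param group Grouping factor for the random intercept.
#' @param reml Use REML (default FALSE = ML).
#' @return List with `beta`, `tau2`, `sigma2`, `loglik` (of the criterion
#'   fitted), `npar` (fixed effects + 2 variances), `ranef` (named BLUPs),
#'   `fitted`, `n`, `gamma`.
#' @export
fit_ri_lmm <- function(X, y, group, reml = FALSE) {
  X <- as.matrix(X)
  if (qr(X)$rank < ncol(X)) stop("singular fixed-effects design", call. = FALSE)
  ss <- ri_suffstats(X, y, group)
  obj <- function(lg) {
    pr <- ri_profile(ss, exp(lg), reml)
    if (!pr$ok) return(1e12)
    -pr$loglik
  }
  opt <- stats::optimize(obj, interval = c(-14, 14), tol = 1e-8)
  cand <- list(c(-Inf, -ri_profile(ss, 0, reml)$loglik),
               c(opt$minimum, opt$objective))
  best <- cand[[which.min(vapply(cand, `[`, numeric(1), 2))]]
  gamma <- if (is.finite(best[1])) exp(best[1]) else 0
  pr <- ri_profile(ss, gamma, reml)
  if (!pr$ok) stop("random-intercept fit failed", call. = FALSE)
  bl <- gamma / (1 + ss$m * gamma) * pr$u
  list(beta = as.numeric(pr$beta), tau2 = gamma * pr$sigma2,
       sigma2 = pr$sigma2, loglik = pr$loglik, npar = ss$p + 2L,
       ranef = stats::setNames(as.numeric(bl), ss$levels),
       fitted = as.numeric(X %*% pr$beta), n = ss$n, gamma = gamma)
}

#' BIC of a fitted random-intercept model
#'
#' Uses effective sample size = number of observations (the usual
#' mixed-model convention for BIC-based selection).
#'
#' @param fit A [fit_ri_lmm()] fit.
#' @return BIC value.
#' @export
bic_ri_lmm <- function(fit) {
  -2 * fit$loglik + fit$npar * log(fit$n)
}
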