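# Block updates for the least-squares majorizer ||Z - 1m' - Phi B V'||^2 and
# the two likelihood blocks outside it (sigma^2 and the thresholds).

#' Update the regression weights B
#'
#' Minimizes `||Ztilde - Phi B V'||^2` over B for fixed orthonormal V.  The
#' vec-form normal equations collapse to `B = (Phi'Phi)^{-1} Phi' Ztilde V`
#' because the cross-product of the design is `I_S (x) Phi'Phi`.
#'
#' @param Phi N x P transformed predictors.
#' @param Ztilde N x R working responses minus intercepts (`Z - 1 m'`).
#' @param V R x S orthonormal loadings.
#' @return the P x S weight matrix.
#' @export
update_B <- function(Phi, Ztilde, V) {
  XtX <- crossprod(Phi)
  ch <- tryCatch(chol(XtX), error = function(e) NULL)
  if (is.null(ch))
    stop("Phi'Phi is singular; remove collinear predictors")
  chol2inv(ch) %*% crossprod(Phi, Ztilde %*% V)
}

#' Update the loadings V (orthogonal Procrustes)
#'
#' Minimizes `||Ztilde - Phi B V'||^2` over V with `V'V = I_S`.  With the
#' singular value decomposition `B' Phi' Ztilde = P Delta Q'`, the minimizer
#' is `V = Q_S P_S'`.  Ties or trailing zero singular values are resolved by
#' taking the first S singular vector pairs with a deterministic sign
#' convention (largest-magnitude element of each right singular vector
#' positive), which fixes an otherwise arbitrary choice.
#'
#' @inheritParams update_B
#' @param B P x S weight matrix.
#' @return the R x S orthonormal loading matrix.
#' @export
update_V <- function(Phi, B, Ztilde) {
  M <- crossprod(B, crossprod(Phi, Ztilde))      # S x R
  sv <- svd(M)
  S <- ncol(B)
  P_S <- sv$u[, seq_len(S), drop = FALSE]
  Q_S <- sv$v[, seq_len(S), drop = FALSE]
  for (s in seq_len(S)) {
    j <- which.max(abs(Q_S[, s]))
    if (Q_S[j, s] < 0) { Q_S[, s] <- -Q_S[, s]; P_S[, s] <- -P_S[, s] }
  }
  Q_S %*% t(P_S)
}

#' Update the intercepts
#'
#' Column means of `Z - Phi B V'` for numeric and binary responses; ordinal
#' intercepts stay at zero (the latent variable is centred).
#'
#' @param Zres N x R matrix `Z - Phi B V'`.
#' @param resp_specs list of response [variable_spec()]s.
#' @return the length-R intercept vector.
#' @export
update_intercepts <- function(Zres, resp_specs) {
  m <- colMeans(Zres)
  ord <- vapply(resp_specs, function(s) s$level == "ordinal", logical(1))
  m[ord] <- 0
  m
}

#' Update the shared residual variance of the numeric responses
#'
#' `sigma^2 = sum(e^2) / (N * R_num - 1)` with residuals taken against the
#' observed numeric responses.  When `kappa* = 1/sigma^2` the working
#' responses of numeric columns equal the observations exactly (`z = theta -
#' sigma^2 (theta - y)/sigma^2 = y`), so residuals against Y and against Z
#' coincide on that branch; against Y they remain the likelihood residuals
#' also when `sigma^2 > 4`.
#'
#' @param Y_num N x R_num observed numeric responses.
#' @param fitted corresponding columns of `1 m' + Phi B V'`.
#' @return the variance estimate (warns below 0.05).
#' @export
update_sigma2 <- function(Y_num, fitted) {
  e <- Y_num - fitted
  s2 <- sum(e^2) / (length(e) - 1)
  if (s2 < 0.05)
    warning("estimated residual variance sigma^2 = ", signif(s2, 3),
            " < 0.05: the algorithm may stall", call. = FALSE)
  s2
}

# negative log-likelihood of one cumulative-logit response in the
# (t1, log-gaps) parameterization, plus its analytic gradient
threshold_objective <- function(par, y, theta, C) {
  t <- cumsum(c(par[1], exp(par[-1])))
  t_ext <- c(-Inf, t, Inf)
  lo <- stats::plogis(t_ext[y] - theta)
  hi <- stats::plogis(t_ext[y + 1L] - theta)
  -sum(log(pmax(hi - lo, 1e-300)))
}

threshold_gradient <- function(par, y, theta, C) {
  t <- cumsum(c(par[1], exp(par[-1])))
  t_ext <- c(-Inf, t, Inf)
  pr <- pmax(stats::plogis(t_ext[y + 1L] - theta) - stats::plogis(t_ext[y] - theta),
             1e-300)
  # d(-log pr)/d t_k: f(t_k - theta) enters with +1 when k = y, -1 when k = y-1
  dens_hi <- stats::dlogis(t_ext[y + 1L] - theta)
  dens_lo <- stats::dlogis(t_ext[y] - theta)
  g_t <- numeric(C - 1L)
  for (k in seq_len(C - 1L)) {
    g_t[k] <- -sum(dens_hi[y == k] / pr[y == k]) +
      sum(dens_lo[y == k + 1L] / pr[y == k + 1L])
  }
  # chain rule through t = cumsum(c(par1, exp(par[-1]))):
  # dt_j/dpar_1 = 1; dt_j/dpar_k = exp(par_k) for j >= k
  g <- numeric(C - 1L)
  g[1] <- sum(g_t)
  if (C > 2L)
    for (k in 2:(C - 1L))
      g[k] <- exp(par[k]) * sum(g_t[k:(C - 1L)])
  g
}

#' Maximum-likelihood thresholds of one ordinal response
#'
#' Maximizes the cumulative-logit likelihood over strictly increasing
#' thresholds with the canonical parameters held fixed, using quasi-Newton
#' optimization of the `(t_1, log-gap)` reparameterization (strict ordering
#' holds by construction).  Initialized from the supplied thresholds, or from
#' logits of the empirical cumulative proportions.
#'
#' @param y length-N ordinal codes in `1..C`.
#' @param theta length-N canonical parameters (held fixed).
#' @param C number of categories.
#' @param init optional starting thresholds.
#' @return the length-(C-1) strictly increasing threshold vector.
#' @export
update_thresholds <- function(y, theta, C, init = NULL) {
  y <- as.integer(y)
  if (is.null(init)) init <- empirical_thresholds(y, C)
  par0 <- c(init[1], if (C > 2L) log(diff(init)))
  opt <- stats::optim(par0, threshold_objective, gr = threshold_gradient,
                      y = y, theta = theta, C = C, method = "BFGS",
                      control = list(reltol = 1e-12, maxit = 500))
  if (opt$convergence != 0 && opt$convergence != 1)
    stop("threshold optimization failed (code ", opt$convergence, "): ",
         opt$message)
  t_new <- cumsum(c(opt$par[1], exp(opt$par[-1])))
  # strict descent: keep whichever of start/optimized has the lower NLL
  if (threshold_objective(par0, y, theta, C) <
      threshold_objective(opt$par, y, theta, C))
    return(init)
  t_new
}

# logits of the empirical cumulative proportions (the ML thresholds when all
# canonical parameters are zero)
empirical_thresholds <- function(y, C) {
  pr <- tabulate(as.integer(y), nbins = C) / length(y)
  cum <- cumsum(pr)[seq_len(C - 1L)]
  cum <- pmin(pmax(cum, 1e-10), 1 - 1e-10)
  stats::qlogis(cum)
}
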