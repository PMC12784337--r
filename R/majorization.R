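# Mixed negative log-likelihood and the quadratic-majorization working set.
#
# Every response family contributes a per-element loss L_ir(theta_ir):
#   numeric:  (y - theta)^2 / (2 sigma^2) + log(2 pi sigma^2) / 2
#   binary:   -log F(q theta),  q = 2y - 1,  F the logistic cdf
#   ordinal:  -log pi_c,  pi_c = F(t_c - theta) - F(t_{c-1} - theta)
# Each loss admits a quadratic upper bound with curvature kappa* and slope
# xi_ir at the support point, which turns one outer iteration into a least
# squares problem on the working responses z = theta - xi / kappa*.

PROB_FLOOR <- 1e-300

#' Logistic cumulative distribution function
#'
#' `F(eta) = 1 / (1 + exp(-eta))`, computed in a numerically safe form.
#'
#' @param eta numeric vector.
#' @return probabilities in (0, 1).
#' @export
logistic_cdf <- function(eta) stats::plogis(eta)

#' Canonical parameter matrix
#'
#' Computes `Theta = 1 m' + Phi B V'`, the N x R matrix of canonical
#' parameters: the conditional mean for numeric responses, the log-odds for
#' binary responses, and the latent-variable location for ordinal responses.
#' Intercepts of ordinal responses are identically zero (the latent variable
#' is centred by convention).
#'
#' @param Phi N x P matrix of transformed predictors.
#' @param m length-R intercept vector (must be 0 for ordinal responses).
#' @param B P x S weight matrix.
#' @param V R x S loading matrix.
#' @return the N x R matrix Theta.
#' @export
canonical_params <- function(Phi, m, B, V) {
  if (ncol(Phi) != nrow(B) || ncol(B) != ncol(V) || length(m) != nrow(V))
    stop("dimension mismatch between Phi, m, B and V")
  sweep(Phi %*% B %*% t(V), 2, m, `+`)
}

#' Category probabilities of a cumulative-logit (proportional-odds) response
#'
#' @param theta canonical parameter (scalar or vector).
#' @param thresholds strictly increasing cutpoints `t_1 < ... < t_{C-1}`.
#' @return a length-C probability vector (or a matrix with one row per
#'   element of `theta`).
#' @export
ordinal_category_probs <- function(theta, thresholds) {
  C <- length(thresholds) + 1L
  cum <- vapply(thresholds, function(t) stats::plogis(t - theta),
                numeric(length(theta)))
  cum <- matrix(cum, nrow = length(theta))
  pr <- cbind(cum, 1) - cbind(0, cum)
  colnames(pr) <- NULL
  if (length(theta) == 1L) drop(pr) else pr
}

#' Conditional expectation of the latent logistic probability integral
#'
#' For an ordinal response modelled through a latent logistic variable
#' `y* = theta + eps`, the quantity `p = F(y* - theta)` is uniform on (0,1)
#' before truncation; conditioning on the observed category `y` truncates it
#' to the interval `(F(t_{y-1} - theta), F(t_y - theta))`, so its expectation
#' is the interval midpoint.  This closed form drives the EM-style gradient
#' `xi = 1 - 2 E(p)` of the ordinal loss.
#'
#' @param y observed category code(s) in `1..C`.
#' @param theta canonical parameter(s).
#' @param thresholds strictly increasing cutpoints (length C-1).
#' @return expectation(s) in (0, 1).
#' @export
expected_p <- function(y, theta, thresholds) {
  C <- length(thresholds) + 1L
  t_ext <- c(-Inf, thresholds, Inf)
  lo <- stats::plogis(t_ext[y] - theta)       # F(t_{y-1} - theta), 0 for y = 1
  hi <- stats::plogis(t_ext[y + 1L] - theta)  # F(t_y - theta), 1 for y = C
  (lo + hi) / 2
}

#' Curvature bound for the majorization working responses
#'
#' `kappa* = max(1/4, 1/sigma^2)` when numeric responses are present, and
#' `1/4` otherwise: 1/4 bounds the logistic curvatures, `1/sigma^2` is the
#' exact Gaussian curvature.  Warns when `sigma^2 < 0.05`, where the working
#' responses barely move and the algorithm is prone to stalling.
#'
#' @param sigma2 residual variance of the numeric responses (ignored when
#'   `has_numeric` is `FALSE`).
#' @param has_numeric are any responses numeric?
#' @return the scalar bound.
#' @export
kappa_star <- function(sigma2 = NULL, has_numeric = !is.null(sigma2)) {
  if (!has_numeric) return(0.25)
  if (is.null(sigma2) || sigma2 <= 0) stop("sigma2 must be positive")
  if (sigma2 < 0.05)
    warning("estimated residual variance sigma^2 = ", signif(sigma2, 3),
            " < 0.05: the algorithm may stall", call. = FALSE)
  max(0.25, 1 / sigma2)
}

# per-family first derivatives xi_ir of the loss at Theta, as an N x R matrix
derivative_matrix <- function(Y, Theta, resp_specs, thresholds, sigma2) {
  Xi <- matrix(0, nrow(Theta), ncol(Theta))
  for (r in seq_along(resp_specs)) {
    s <- resp_specs[[r]]
    if (s$level == "numeric") {
      Xi[, r] <- (Theta[, r] - Y[, r]) / sigma2
    } else if (s$level == "binary") {
      Xi[, r] <- -(Y[, r] - stats::plogis(Theta[, r]))
    } else {
      Xi[, r] <- 1 - 2 * expected_p(as.integer(Y[, r]), Theta[, r],
                                    thresholds[[s$name]])
    }
  }
  Xi
}

#' Working responses for one majorization step
#'
#' Builds the working-response matrix `Z = Theta - Xi / kappa*`, where `Xi`
#' holds the per-element first derivatives of the loss at the current
#' canonical parameters: `(theta - y)/sigma^2` for numeric, `-(y - pi)` for
#' binary and `1 - 2 E(p | y, theta, t)` for ordinal responses.  For a numeric
#' response with `kappa* = 1/sigma^2` the working response collapses to the
#' observation itself.
#'
#' @param Y raw response matrix (numeric values, 0/1, or codes 1..C).
#' @param Theta current canonical parameters.
#' @param resp_specs list of response [variable_spec()]s.
#' @param thresholds named list of threshold vectors for ordinal responses.
#' @param sigma2 current residual variance (if numeric responses exist).
#' @param kappa curvature bound from [kappa_star()].
#' @return a list with `Z`, `Xi` and `kappa`.
#' @export
working_matrix <- function(Y, Theta, resp_specs, thresholds = list(),
                           sigma2 = NULL, kappa = kappa_star(sigma2)) {
  Xi <- derivative_matrix(Y, Theta, resp_specs, thresholds, sigma2)
  list(Z = Theta - Xi / kappa, Xi = Xi, kappa = kappa)
}

#' Mixed negative log-likelihood
#'
#' Sums the per-element losses of all response families at the given
#' canonical parameters.  Probabilities are floored at a tiny positive
#' constant before taking logs; hitting the floor signals a degenerate fit
#' and raises a warning.
#'
#' @inheritParams working_matrix
#' @param per_element return the N x R matrix of per-element losses as
#'   attribute `"losses"`?
#' @return the scalar negative log-likelihood (optionally with attribute
#'   `"losses"`).
#' @export
negative_loglik <- function(Y, Theta, resp_specs, thresholds = list(),
                            sigma2 = NULL, per_element = FALSE) {
  L <- matrix(0, nrow(Theta), ncol(Theta))
  floored <- FALSE
  for (r in seq_along(resp_specs)) {
    s <- resp_specs[[r]]
    if (s$level == "numeric") {
      if (is.null(sigma2) || sigma2 <= 0)
        stop("sigma2 must be positive when numeric responses are present")
      L[, r] <- (Y[, r] - Theta[, r])^2 / (2 * sigma2) +
        0.5 * log(2 * pi * sigma2)
    } else if (s$level == "binary") {
      q <- 2 * Y[, r] - 1
      pr <- stats::plogis(q * Theta[, r])
      if (any(pr < PROB_FLOOR)) { floored <- TRUE; pr <- pmax(pr, PROB_FLOOR) }
      L[, r] <- -log(pr)
    } else {
      th <- thresholds[[s$name]]
      pr_all <- matrix(ordinal_category_probs(Theta[, r], th),
                       nrow = nrow(Theta))
      pr <- pr_all[cbind(seq_len(nrow(Theta)), as.integer(Y[, r]))]
      if (any(pr < PROB_FLOOR)) { floored <- TRUE; pr <- pmax(pr, PROB_FLOOR) }
      L[, r] <- -log(pr)
    }
  }
  if (floored)
    warning("some category probabilities underflowed and were floored; ",
            "the fit is degenerate", call. = FALSE)
  out <- sum(L)
  if (per_element) attr(out, "losses") <- L
  out
}
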