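#' Fit a mixed-response reduced-rank regression
#'
#' Maximum-likelihood reduced-rank regression for a multivariate outcome
#' mixing numeric, binary and ordinal responses, with optimal scaling of
#' discrete predictors.  Each response r is driven by a canonical parameter
#' `theta_ir = m_r + phi_i' B v_r` with `B` (P x S) and orthonormal `V`
#' (R x S), so the implied coefficient matrix `A = B V'` has rank S.  The
#' model is estimated by a majorization-minimization algorithm: every outer
#' iteration builds quadratic upper bounds of the per-element losses (exact
#' Gaussian curvature for numeric, 1/4 for the logistic losses, an EM-style
#' expectation for the ordinal latent variable), turning the step into a
#' least-squares problem solved in closed form, followed by maximum-likelihood
#' threshold updates.  The negative log-likelihood decreases monotonically.
#'
#' @param data a [mixed_data()] object.
#' @param rank the required rank S, `1 <= S <= min(P, R)`.
#' @param tol convergence criterion on the absolute decrease of the negative
#'   log-likelihood (default `1e-6`).
#' @param max_iter maximum number of outer iterations.
#' @param init optional warm start: a previous `mixed_rrr` fit on data with
#'   the same variable structure (used by cross-validation and the bootstrap).
#' @param verbose print the negative log-likelihood each iteration?
#' @return an object of class `mixed_rrr` with components `m` (intercepts,
#'   0 for ordinal responses), `B`, `V`, `A = B V'`, `thresholds`, `sigma2`,
#'   `quantifications`, `Phi`, `nll` and `nll_trace`, `K` (parameter count),
#'   `converged`, `n_iter`, plus the training metadata needed by
#'   [predict.mixed_rrr()].
#' @export
#' @examples
#' sim <- sim_scenario("cond1", N = 200, seed = 7)
#' fit <- mixed_rrr(sim$data, rank = 2)
#' fit
mixed_rrr <- function(data, rank, tol = 1e-6, max_iter = 1000L,
                      init = NULL, verbose = FALSE) {
  stopifnot(inherits(data, "mixed_data"), tol > 0)
  pred_specs <- data$specs$predictors
  resp_specs <- data$specs$responses
  P <- ncol(data$X); R <- ncol(data$Y); N <- data$N
  S <- as.integer(rank)
  if (S < 1 || S > min(P, R))
    stop("rank must be between 1 and min(P, R) = ", min(P, R))
  if (N <= P) stop("need more observations than predictors (N > P)")

  levels_r <- vapply(resp_specs, `[[`, "", "level")
  num_r <- which(levels_r == "numeric")
  ord_r <- which(levels_r == "ordinal")
  has_numeric <- length(num_r) > 0
  discrete_p <- which(vapply(pred_specs, is_discrete, logical(1)))

  st <- if (is.null(init)) initialize_fit(data, S) else warm_start(init, data, S)
  B <- st$B; V <- st$V; m <- st$m
  thresholds <- st$thresholds; sigma2 <- st$sigma2
  sc <- scale_predictors(data$X, pred_specs, st$quantifications)
  Phi <- sc$Phi; indicators <- sc$indicators; quants <- sc$quantifications

  Theta <- canonical_params(Phi, m, B, V)
  nll <- negative_loglik(data$Y, Theta, resp_specs, thresholds, sigma2)
  nll_trace <- nll
  converged <- FALSE
  iter <- 0L

  while (iter < max_iter) {
    iter <- iter + 1L
    kappa <- kappa_star(sigma2, has_numeric)
    ws <- working_matrix(data$Y, Theta, resp_specs, thresholds, sigma2, kappa)
    Z <- ws$Z

    # (1) quantifications, cyclically over discrete predictors, each seeing
    # the freshest Phi columns; the working matrix Z is held fixed
    if (length(discrete_p)) {
      A <- B %*% t(V)
      Zc <- sweep(Z, 2, m)               # Z - 1 m'
      Res <- Zc - Phi %*% A              # full residual, updated in place
      for (p in discrete_p) {
        a_p <- A[p, ]
        Z_target <- Res + outer(Phi[, p], a_p)
        upd <- update_quantification(Z_target, a_p, indicators[[p]],
                                     pred_specs[[p]]$level,
                                     previous = quants[[p]]$w)
        if (upd$flipped) {
          B[p, ] <- -B[p, ]
          A[p, ] <- -A[p, ]
          a_p <- -a_p
        }
        quants[[p]] <- upd[c("w", "level", "direction")]
        Phi[, p] <- indicators[[p]]$G %*% upd$w
        Res <- Z_target - outer(Phi[, p], a_p)
      }
    }

    # (2)-(4) weights, loadings, intercepts on the least-squares majorizer
    Ztilde <- sweep(Z, 2, m)
    B <- update_B(Phi, Ztilde, V)
    V <- update_V(Phi, B, Ztilde)
    m <- update_intercepts(Z - Phi %*% B %*% t(V), resp_specs)
    Theta <- canonical_params(Phi, m, B, V)

    # (5) residual variance of the numeric responses.  The (N R_num - 1)
    # divisor is not the exact minimizer of the Gaussian NLL (that uses
    # N R_num), so in the convergence tail the update could raise the NLL by
    # O(1/(N R_num)); accept it only when it does not.
    if (has_numeric) {
      E <- data$Y[, num_r, drop = FALSE] - Theta[, num_r, drop = FALSE]
      rss <- sum(E^2)
      s2_new <- update_sigma2(data$Y[, num_r, drop = FALSE],
                              Theta[, num_r, drop = FALSE])
      gauss_nll <- function(s2) rss / (2 * s2) + length(E) * 0.5 * log(2 * pi * s2)
      if (s2_new > 0 && gauss_nll(s2_new) <= gauss_nll(sigma2))
        sigma2 <- s2_new
    }

    # (6) maximum-likelihood thresholds, response by response
    for (r in ord_r) {
      nmr <- resp_specs[[r]]$name
      thresholds[[nmr]] <- update_thresholds(data$Y[, r], Theta[, r],
                                             resp_specs[[r]]$n_categories,
                                             init = thresholds[[nmr]])
    }

    nll_new <- negative_loglik(data$Y, Theta, resp_specs, thresholds, sigma2)
    if (nll_new > nll + 1e-8)
      stop("internal error: negative log-likelihood increased by ",
           signif(nll_new - nll, 4), " at iteration ", iter)
    dec <- nll - nll_new
    nll <- nll_new
    nll_trace <- c(nll_trace, nll)
    if (verbose)
      message(sprintf("iter %4d  nll %.8f  decrease %.2e", iter, nll, dec))
    if (dec < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("not converged after ", max_iter, " iterations", call. = FALSE)

  fit <- structure(list(
    m = stats::setNames(m, vapply(resp_specs, `[[`, "", "name")),
    B = B, V = V, A = B %*% t(V),
    thresholds = thresholds,
    sigma2 = if (has_numeric) sigma2 else NULL,
    quantifications = stats::setNames(quants, colnames(data$X))[
      vapply(pred_specs, is_discrete, logical(1))],
    Phi = Phi,
    nll = nll, nll_trace = nll_trace,
    K = count_parameters(data$specs, S),
    rank = S, N = N,
    converged = converged, n_iter = iter,
    specs = data$specs,
    numeric_scaling = numeric_scaling(data$X, pred_specs)
  ), class = "mixed_rrr")
  identify_fit(fit)
}

# training means/sds (population convention) of numeric predictors, for
# transforming prediction data
numeric_scaling <- function(X, pred_specs) {
  out <- list()
  for (p in seq_along(pred_specs)) {
    s <- pred_specs[[p]]
    if (s$level == "numeric") {
      mu <- mean(X[, p])
      out[[s$name]] <- c(mean = mu, sd = sqrt(mean((X[, p] - mu)^2)))
    }
  }
  out
}

#' Starting values from a classical reduced-rank regression
#'
#' Codes every variable numerically (discrete predictors as standardized
#' integer codes; responses as category indices or 0/1, column-standardized),
#' fits the multivariate least-squares regression and truncates its fitted
#' values to rank S: V from the top eigenvectors of `Yhat' Yhat`, `B = C V`
#' with C the least-squares coefficients.  Intercepts start at the response
#' mean (numeric), the logit of the observed proportion (binary) or zero
#' (ordinal); thresholds at logits of empirical cumulative proportions;
#' `sigma^2` at the residual variance of the numeric columns (floored at 0.1).
#'
#' @param data a [mixed_data()] object.
#' @param S the required rank.
#' @return a list of starting values as used by [mixed_rrr()].
#' @export
initialize_fit <- function(data, S) {
  pred_specs <- data$specs$predictors
  resp_specs <- data$specs$responses
  Xc <- apply(data$X, 2, standardize)
  Yc <- apply(data$Y, 2, standardize)
  C_ols <- tryCatch(solve(crossprod(Xc), crossprod(Xc, Yc)),
                    error = function(e)
                      stop("starting-value regression failed: ",
                           conditionMessage(e), call. = FALSE))
  Yhat <- Xc %*% C_ols
  eg <- eigen(crossprod(Yhat), symmetric = TRUE)
  V <- eg$vectors[, seq_len(S), drop = FALSE]
  B <- C_ols %*% V

  m <- numeric(length(resp_specs))
  thresholds <- list()
  for (r in seq_along(resp_specs)) {
    s <- resp_specs[[r]]
    if (s$level == "numeric") {
      m[r] <- mean(data$Y[, r])
    } else if (s$level == "binary") {
      pr <- min(max(mean(data$Y[, r]), 1e-6), 1 - 1e-6)
      m[r] <- stats::qlogis(pr)
    } else {
      thresholds[[s$name]] <- empirical_thresholds(data$Y[, r], s$n_categories)
    }
  }
  num_r <- which(vapply(resp_specs, `[[`, "", "level") == "numeric")
  sigma2 <- if (length(num_r)) {
    res <- data$Y[, num_r, drop = FALSE] -
      sweep(Yhat[, num_r, drop = FALSE] * 0, 2, colMeans(data$Y[, num_r, drop = FALSE]), `+`)
    max(0.1, sum(res^2) / (length(res) - 1))
  }
  list(B = B, V = V, m = m, thresholds = thresholds, sigma2 = sigma2,
       quantifications = NULL, A_start = C_ols %*% V %*% t(V))
}

warm_start <- function(init, data, S) {
  stopifnot(inherits(init, "mixed_rrr"))
  if (init$rank != S)
    stop("warm start has rank ", init$rank, ", requested ", S)
  quants <- stats::setNames(vector("list", ncol(data$X)), colnames(data$X))
  for (nm in names(init$quantifications)) quants[[nm]] <- init$quantifications[[nm]]
  list(B = init$B, V = init$V, m = unname(init$m),
       thresholds = init$thresholds, sigma2 = init$sigma2,
       quantifications = quants)
}

#' Identify a fitted solution
#'
#' The likelihood only determines `A = B V'`; the factors are fixed by the
#' identification constraints: `V'V = I_S` and `(Phi B)'(Phi B)` diagonal with
#' non-increasing diagonal.  Rotates `B` and `V` by the eigenvectors of
#' `(Phi B)'(Phi B)` (leaving `A` unchanged to machine precision), orders
#' dimensions by decreasing explained canonical variance, and fixes column
#' signs so the largest-magnitude entry of each loading column is positive.
#'
#' @param fit a `mixed_rrr` object.
#' @return the fit with rotated `B`, `V` (and recomputed `A`).
#' @export
identify_fit <- function(fit) {
  U <- fit$Phi %*% fit$B
  eg <- eigen(crossprod(U), symmetric = TRUE)   # eigenvalues decreasing
  T_rot <- eg$vectors
  B <- fit$B %*% T_rot
  V <- fit$V %*% T_rot
  for (s in seq_len(ncol(V))) {
    j <- which.max(abs(V[, s]))
    if (V[j, s] < 0) { V[, s] <- -V[, s]; B[, s] <- -B[, s] }
  }
  fit$B <- B
  fit$V <- V
  fit$A <- B %*% t(V)
  dimnames(fit$A) <- list(vapply(fit$specs$predictors, `[[`, "", "name"),
                          vapply(fit$specs$responses, `[[`, "", "name"))
  rownames(fit$B) <- rownames(fit$A)
  rownames(fit$V) <- colnames(fit$A)
  fit
}

#' @export
print.mixed_rrr <- function(x, ...) {
  cat(sprintf(paste0("Mixed-response reduced-rank regression (rank S = %d)\n",
                     "  N = %d, P = %d predictors, R = %d responses\n",
                     "  negative log-likelihood %.4f after %d iterations (%s)\n",
                     "  K = %d parameters\n"),
              x$rank, x$N, nrow(x$B), nrow(x$V), x$nll, x$n_iter,
              if (x$converged) "converged" else "NOT converged", x$K))
  if (!is.null(x$sigma2))
    cat(sprintf("  residual variance of numeric responses: %.4f\n", x$sigma2))
  invisible(x)
}

#' @export
coef.mixed_rrr <- function(object, ...) object$A

#' Predict from a fitted mixed-response reduced-rank regression
#'
#' Transforms new predictor rows with the training quantifications (numeric
#' predictors with the training mean/sd) and returns, per response, the
#' canonical parameter plus the family-appropriate prediction: the expected
#' value for numeric responses, the success probability `F(theta)` for binary
#' responses, and for ordinal responses the full category-probability vector
#' together with the modal latent class `c` with `t_{c-1} <= theta < t_c`.
#' Categories unseen in training have no quantification and raise an error.
#'
#' @param object a `mixed_rrr` fit.
#' @param newdata a data frame with the training predictor columns (raw
#'   values / category codes).
#' @param ... unused.
#' @return a list with `theta` (N x R matrix), `expected` (N x R matrix of
#'   expected values / probabilities / modal classes per family), and
#'   `probabilities` (named list of N x C matrices, ordinal responses only).
#' @export
predict.mixed_rrr <- function(object, newdata, ...) {
  pred_specs <- object$specs$predictors
  resp_specs <- object$specs$responses
  newdata <- as.data.frame(newdata)
  Phi_new <- matrix(0, nrow(newdata), length(pred_specs))
  for (p in seq_along(pred_specs)) {
    s <- pred_specs[[p]]
    v <- newdata[[s$name]]
    if (is.null(v)) stop("newdata lacks predictor column '", s$name, "'")
    if (s$level == "numeric") {
      sc <- object$numeric_scaling[[s$name]]
      Phi_new[, p] <- (v - sc["mean"]) / sc["sd"]
    } else {
      codes <- normalize_codes(v, s)
      w <- object$quantifications[[s$name]]$w
      if (any(codes < 1 | codes > length(w) | codes != round(codes)))
        stop("unseen or invalid category for predictor '", s$name, "': ",
             v[which(codes < 1 | codes > length(w) | codes != round(codes))[1]])
      Phi_new[, p] <- w[codes]
    }
  }
  Theta <- canonical_params(Phi_new, unname(object$m), object$B, object$V)
  R <- length(resp_specs)
  expected <- matrix(NA_real_, nrow(Theta), R,
                     dimnames = list(NULL, vapply(resp_specs, `[[`, "", "name")))
  probabilities <- list()
  for (r in seq_len(R)) {
    s <- resp_specs[[r]]
    if (s$level == "numeric") {
      expected[, r] <- Theta[, r]
    } else if (s$level == "binary") {
      expected[, r] <- stats::plogis(Theta[, r])
    } else {
      t_r <- object$thresholds[[s$name]]
      pr <- ordinal_category_probs(Theta[, r], t_r)
      probabilities[[s$name]] <- matrix(pr, nrow = nrow(Theta))
      # half-open classification: class c with t_{c-1} <= theta < t_c
      expected[, r] <- findInterval(Theta[, r], t_r, left.open = FALSE) + 1
    }
  }
  list(theta = Theta, expected = expected, probabilities = probabilities)
}
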