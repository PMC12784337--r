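# Parameter counting, information criteria, repeated V-fold cross-validation
# and the balanced pairs bootstrap.

#' Number of free parameters of a rank-S model
#'
#' `K = (P + R - S) S + sum_{p discrete} (C_p - 2) + #[numeric or binary
#' responses] + sum_{r ordinal} (C_r - 1)`.  The bilinear part contributes
#' `(P + R - S) S` (a P x S weight matrix and an R x S orthonormal loading
#' matrix, minus the `S^2` rotational indeterminacy); each discrete predictor
#' contributes its `C_p` quantifications minus the two standardization
#' constraints; numeric and binary responses contribute one intercept each
#' and ordinal responses their `C_r - 1` thresholds.
#'
#' @param specs the `$specs` element of a [mixed_data()] object (a list with
#'   `predictors` and `responses`), or a [mixed_data()] object.
#' @param S the rank (`S = 0` gives the intercept/threshold-only null model).
#' @return the integer parameter count.
#' @export
count_parameters <- function(specs, S) {
  if (inherits(specs, "mixed_data")) specs <- specs$specs
  P <- length(specs$predictors); R <- length(specs$responses)
  if (S > min(P, R)) stop("S must be at most min(P, R)")
  k_bilinear <- (P + R - S) * S
  # the null model (S = 0) has no predictor contribution, hence no
  # quantification parameters either
  k_quant <- if (S == 0) 0L else sum(vapply(specs$predictors, function(s)
    if (is_discrete(s)) s$n_categories - 2L else 0L, integer(1)))
  k_resp <- sum(vapply(specs$responses, function(s)
    if (s$level == "ordinal") s$n_categories - 1L else 1L, integer(1)))
  as.integer(k_bilinear + k_quant + k_resp)
}

#' Information criteria and adjusted McFadden R-squared
#'
#' `AIC = 2 nll + 2 K`, `BIC = 2 nll + log(N) K`, and the adjusted McFadden
#' measure `Ra2 = 1 - (nll + K) / nll_null`, where `nll` is the minimized
#' negative log-likelihood, `nll_null` that of the intercept/threshold-only
#' null model, and K the total parameter count of the fitted model.  (An
#' alternative reading of the adjustment penalizes only the parameters added
#' over the null model; set `ra2_added_only = TRUE` for that variant.)
#'
#' @param nll minimized negative log-likelihood of the model.
#' @param nll_null negative log-likelihood of the null model.
#' @param K parameter count of the model (see [count_parameters()]).
#' @param N sample size.
#' @param K_null parameter count of the null model (used only by the
#'   `ra2_added_only` variant).
#' @param ra2_added_only penalize `Ra2` by `K - K_null` instead of `K`?
#' @return a list with `aic`, `bic` and `ra2`.
#' @export
information_criteria <- function(nll, nll_null, K, N, K_null = 0L,
                                 ra2_added_only = FALSE) {
  pen <- if (ra2_added_only) K - K_null else K
  list(aic = 2 * nll + 2 * K,
       bic = 2 * nll + log(N) * K,
       ra2 = 1 - (nll + pen) / nll_null)
}

#' Negative log-likelihood of the null model
#'
#' The null model has no predictor contribution: numeric responses keep their
#' mean and a shared residual variance, binary responses the logit of their
#' observed proportion, ordinal responses zero canonical parameter with
#' thresholds at logits of the empirical cumulative proportions.
#'
#' @param data a [mixed_data()] object.
#' @return the scalar negative log-likelihood.
#' @export
null_nll <- function(data) {
  resp_specs <- data$specs$responses
  N <- data$N
  m <- numeric(length(resp_specs))
  thresholds <- list()
  num_r <- integer(0)
  for (r in seq_along(resp_specs)) {
    s <- resp_specs[[r]]
    if (s$level == "numeric") {
      m[r] <- mean(data$Y[, r]); num_r <- c(num_r, r)
    } else if (s$level == "binary") {
      m[r] <- stats::qlogis(min(max(mean(data$Y[, r]), 1e-10), 1 - 1e-10))
    } else {
      thresholds[[s$name]] <- empirical_thresholds(data$Y[, r], s$n_categories)
    }
  }
  sigma2 <- if (length(num_r)) {
    res <- sweep(data$Y[, num_r, drop = FALSE], 2, m[num_r])
    sum(res^2) / (length(res) - 1)
  }
  Theta <- matrix(rep(m, each = N), N)
  negative_loglik(data$Y, Theta, resp_specs, thresholds, sigma2)
}

#' Fit a grid of ranks and tabulate model-selection criteria
#'
#' @param data a [mixed_data()] object.
#' @param ranks integer vector of candidate ranks.
#' @param ... passed to [mixed_rrr()] (e.g. `tol`, `max_iter`).
#' @return a data frame with one row per rank: `S`, `nll`, `K`, `aic`, `bic`,
#'   `ra2`, plus the fits as attribute `"fits"`.
#' @export
select_rank <- function(data, ranks, ...) {
  nll0 <- null_nll(data)
  fits <- lapply(ranks, function(S) mixed_rrr(data, rank = S, ...))
  rows <- lapply(seq_along(ranks), function(i) {
    f <- fits[[i]]
    ic <- information_criteria(f$nll, nll0, f$K, data$N)
    data.frame(S = ranks[i], nll = f$nll, K = f$K,
               aic = ic$aic, bic = ic$bic, ra2 = ic$ra2)
  })
  out <- do.call(rbind, rows)
  attr(out, "fits") <- fits
  attr(out, "nll_null") <- nll0
  out
}

# fold assignment: rows shuffled, sizes as equal as possible; resampled (up
# to `retries` times) until every training fold retains all categories of
# every discrete variable
make_folds <- function(data, V, retries = 50L) {
  disc <- c(Filter(is_discrete, data$specs$predictors),
            Filter(is_discrete, data$specs$responses))
  get_col <- function(s) {
    col <- if (s$role == "predictor") data$X[, s$name] else data$Y[, s$name]
    normalize_codes(col, s)
  }
  for (try in seq_len(retries)) {
    folds <- sample(rep(seq_len(V), length.out = data$N))
    ok <- all(vapply(seq_len(V), function(v) {
      train <- folds != v
      all(vapply(disc, function(s)
        length(unique(get_col(s)[train])) == s$n_categories, logical(1)))
    }, logical(1)))
    if (ok) return(folds)
  }
  stop("could not build ", V, " folds retaining every category; use fewer folds")
}

subset_mixed_data <- function(data, idx) {
  structure(list(X = data$X[idx, , drop = FALSE],
                 Y = data$Y[idx, , drop = FALSE],
                 specs = data$specs, N = length(idx)),
            class = "mixed_data")
}

# held-out negative log-likelihood of a fitted model on new rows, summed over
# responses per participant
holdout_losses <- function(fit, data_test) {
  pred_df <- as.data.frame(data_test$X)
  Theta <- predict(fit, pred_df)$theta
  nll <- negative_loglik(data_test$Y, Theta, data_test$specs$responses,
                         fit$thresholds, fit$sigma2, per_element = TRUE)
  rowSums(attr(nll, "losses"))
}

#' Repeated V-fold cross-validation over a rank grid
#'
#' Estimates the expected prediction error of each candidate rank by L-times
#' repeated V-fold cross-validation: for each fold, the model is fitted on
#' the remaining folds (warm-started from the full-data fit) and the
#' per-participant held-out negative log-likelihood (summed over responses)
#' is averaged; fold means are then averaged over the `L * V` evaluations.
#' The standard error of each rank's estimate is computed over the `L * V`
#' fold means.  Reports both the rank minimizing the estimate and the most
#' parsimonious rank within one standard error of the minimum.
#'
#' @param data a [mixed_data()] object.
#' @param ranks integer vector of candidate ranks.
#' @param V number of folds (>= 2).
#' @param L number of repeats.
#' @param seed integer seed controlling fold assignment.
#' @param ... passed to [mixed_rrr()].
#' @return a list with `table` (data frame: `S`, `cv`, `se`), `fold_means`
#'   (ranks x (L*V) matrix), `best` and `one_se` (chosen ranks).
#' @export
cv_mixed_rrr <- function(data, ranks, V = 10L, L = 10L, seed = 1L, ...) {
  stopifnot(V >= 2)
  set.seed(seed)
  parents <- lapply(ranks, function(S) mixed_rrr(data, rank = S, ...))
  fold_means <- matrix(NA_real_, length(ranks), L * V,
                       dimnames = list(paste0("S", ranks), NULL))
  col <- 0L
  for (l in seq_len(L)) {
    folds <- make_folds(data, V)
    for (v in seq_len(V)) {
      col <- col + 1L
      train <- subset_mixed_data(data, which(folds != v))
      test <- subset_mixed_data(data, which(folds == v))
      for (k in seq_along(ranks)) {
        fit_v <- mixed_rrr(train, rank = ranks[k], init = parents[[k]], ...)
        fold_means[k, col] <- mean(holdout_losses(fit_v, test))
      }
    }
  }
  cv <- rowMeans(fold_means)
  se <- apply(fold_means, 1, function(x) stats::sd(x) / sqrt(length(x)))
  best <- ranks[which.min(cv)]
  one_se <- min(ranks[cv <= min(cv) + se[which.min(cv)]])
  list(table = data.frame(S = ranks, cv = unname(cv), se = unname(se)),
       fold_means = fold_means, best = best, one_se = one_se)
}

#' Balanced pairs bootstrap with confidence-ellipse origin tests
#'
#' Draws `B_boot` balanced bootstrap resamples of participants (each
#' participant appears exactly `B_boot` times across all resamples, obtained
#' by permuting `B_boot` concatenated copies of the index vector), refits the
#' model on each (warm-started from the parent fit), and aligns each
#' replicate's loadings to the parent solution by orthogonal Procrustes
#' rotation (the same rotation is applied to the weights; without alignment
#' the replicate clouds are smeared by rotational indeterminacy).  For every
#' predictor row of B and response row of V it returns the replicate cloud's
#' mean and covariance and whether the `(1 - alpha)` chi-square confidence
#' ellipse excludes the origin (a significance flag).
#'
#' @param data a [mixed_data()] object.
#' @param S the rank.
#' @param B_boot number of bootstrap resamples (>= 100 recommended).
#' @param alpha significance level of the ellipses.
#' @param seed integer seed for the balanced permutation.
#' @param parent optional parent fit (computed if omitted).
#' @param ... passed to [mixed_rrr()].
#' @return a list with `B_rep` and `V_rep` (arrays replicate x row x
#'   dimension), `ellipses` (data frame: variable, side, center and whether
#'   the origin is excluded), `dropped` (non-converged replicate count) and
#'   `parent`.
#' @export
balanced_bootstrap <- function(data, S, B_boot = 1000L, alpha = 0.05,
                               seed = 1L, parent = NULL, ...) {
  if (B_boot < 100)
    warning("fewer than 100 bootstrap resamples; ellipses will be unstable")
  if (is.null(parent)) parent <- mixed_rrr(data, rank = S, ...)
  set.seed(seed)
  idx_pool <- sample(rep(seq_len(data$N), B_boot))
  P <- nrow(parent$B); R <- nrow(parent$V)
  B_rep <- array(NA_real_, c(B_boot, P, S))
  V_rep <- array(NA_real_, c(B_boot, R, S))
  dropped <- 0L
  for (b in seq_len(B_boot)) {
    idx <- idx_pool[((b - 1L) * data$N + 1L):(b * data$N)]
    boot_data <- subset_mixed_data(data, idx)
    fit_b <- tryCatch(
      suppressWarnings(mixed_rrr(boot_data, rank = S, init = parent, ...)),
      error = function(e) NULL)
    if (is.null(fit_b)) {
      dropped <- dropped + 1L
      warning("bootstrap replicate ", b, " failed; dropped", call. = FALSE)
      next
    }
    # Procrustes-align replicate loadings to the parent
    sv <- svd(crossprod(fit_b$V, parent$V))
    O <- sv$u %*% t(sv$v)
    B_rep[b, , ] <- fit_b$B %*% O
    V_rep[b, , ] <- fit_b$V %*% O
  }
  if (dropped > 0.05 * B_boot)
    stop("more than 5% of bootstrap replicates failed (", dropped, "/",
         B_boot, ")")
  keep <- which(!is.na(B_rep[, 1, 1]))
  crit <- stats::qchisq(1 - alpha, df = S)
  ellipse_row <- function(cloud, name, side) {
    ctr <- colMeans(cloud)
    cv <- stats::cov(cloud)
    d2 <- tryCatch(drop(t(-ctr) %*% solve(cv, -ctr)), error = function(e) Inf)
    data.frame(variable = name, side = side,
               t(stats::setNames(ctr, paste0("dim", seq_len(S)))),
               mahalanobis2 = d2, origin_excluded = d2 > crit)
  }
  pn <- vapply(data$specs$predictors, `[[`, "", "name")
  rn <- vapply(data$specs$responses, `[[`, "", "name")
  ell <- rbind(
    do.call(rbind, lapply(seq_len(P), function(p)
      ellipse_row(matrix(B_rep[keep, p, ], ncol = S), pn[p], "predictor"))),
    do.call(rbind, lapply(seq_len(R), function(r)
      ellipse_row(matrix(V_rep[keep, r, ], ncol = S), rn[r], "response"))))
  rownames(ell) <- NULL
  list(B_rep = B_rep, V_rep = V_rep, ellipses = ell,
       dropped = dropped, alpha = alpha, parent = parent)
}

#' Long-format table of bootstrap replicate coordinates
#'
#' @param boot result of [balanced_bootstrap()].
#' @return a data frame with columns `replicate`, `side`, `variable`,
#'   `dimension`, `value`, suitable for external plotting.
#' @export
bootstrap_cloud <- function(boot) {
  pn <- rownames(boot$parent$B); rn <- rownames(boot$parent$V)
  melt <- function(arr, names, side) {
    d <- dim(arr)
    data.frame(replicate = rep(seq_len(d[1]), times = d[2] * d[3]),
               side = side,
               variable = rep(rep(names, each = d[1]), times = d[3]),
               dimension = rep(seq_len(d[3]), each = d[1] * d[2]),
               value = as.vector(arr))
  }
  out <- rbind(melt(boot$B_rep, pn, "predictor"),
               melt(boot$V_rep, rn, "response"))
  out[!is.na(out$value), ]
}
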