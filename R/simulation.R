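# Synthetic-data generators for the two built-in simulation designs, the RMSE
# recovery metric and an experiment runner.
#
# All scenarios share the same backbone: latent standard-normal predictors, a
# true weight matrix B from the QR decomposition of a Gaussian matrix, true
# loadings V with uniform(-1, 1) entries, zero intercepts, unit-variance
# Gaussian noise for numeric responses, Bernoulli(F(theta)) for binary
# responses and cumulative-logit draws with thresholds (-1, 0, 1) for ordinal
# responses (four categories).  Discretized predictors enter the generating
# linear predictor through their per-category means while the analysis sees
# integer codes.

SCENARIOS <- c("cond1", "gmr3-p1", "gmr3-p2", "gmr3-r1", "gmr3-r2", "gmr3-pr")

#' Discretize a numeric variable at fixed quantiles
#'
#' Cuts `values` at the stated quantiles and returns both the integer codes
#' `1..n_levels` used for analysis and the per-category mean of the
#' underlying numeric values, which is what enters the generating linear
#' predictor.  The balanced set uses the .2/.4/.6/.8 quantiles, the
#' unbalanced set the .1/.5/.7/.8 quantiles.
#'
#' @param values numeric vector.
#' @param quantile_set `"balanced"` or `"unbalanced"`, or a numeric vector of
#'   probabilities.
#' @return a list with `codes`, `generating` (category means substituted per
#'   observation) and `category_means`.
#' @export
discretize_quantiles <- function(values, quantile_set = c("balanced", "unbalanced")) {
  probs <- if (is.numeric(quantile_set)) quantile_set
  else switch(match.arg(quantile_set),
              balanced = c(.2, .4, .6, .8),
              unbalanced = c(.1, .5, .7, .8))
  br <- stats::quantile(values, probs, names = FALSE, type = 7)
  if (anyDuplicated(br)) stop("duplicate quantile boundaries; input degenerate")
  codes <- findInterval(values, br, left.open = TRUE) + 1L
  means <- vapply(seq_len(length(br) + 1L),
                  function(c) mean(values[codes == c]), numeric(1))
  list(codes = codes, generating = means[codes], category_means = means)
}

# dichotomize at the median (balanced) or the .8 quantile (unbalanced); the
# two-category analogue of the quantile discretization above
dichotomize <- function(values, balanced = TRUE) {
  discretize_quantiles(values, if (balanced) 0.5 else 0.8)
}

#' Weaken the trailing structure of a true coefficient product
#'
#' Takes the singular value decomposition of `B V'` and replaces singular
#' values `3..S_true` with `lambda_weak`, returning factors that reproduce
#' the modified product.  The true rank is preserved but only the first two
#' dimensions carry strong signal.
#'
#' @param B_true,V_true true factors (P x S and R x S, `S >= 3`).
#' @param lambda_weak replacement singular value (default 0.20).
#' @return a list with `B`, `V` (modified factors) and `A = B V'`.
#' @export
weaken_structure <- function(B_true, V_true, lambda_weak = 0.20) {
  S_true <- ncol(B_true)
  if (S_true < 3) stop("nothing to weaken: true rank must be at least 3")
  sv <- svd(B_true %*% t(V_true))
  lam <- sv$d
  lam[3:S_true] <- lambda_weak
  B <- sv$u[, seq_len(S_true), drop = FALSE] %*% diag(lam[seq_len(S_true)])
  V <- sv$v[, seq_len(S_true), drop = FALSE]
  list(B = B, V = V, A = B %*% t(V))
}

scenario_levels <- function(scenario) {
  switch(scenario,
    "cond1" = list(pred = rep("numeric", 8),
                   resp = c(rep("numeric", 4), rep("binary", 4))),
    "gmr3-p1" = ,
    "gmr3-p2" = list(pred = rep("ordinal", 8),
                     resp = c(rep("numeric", 4), rep("binary", 4))),
    "gmr3-r1" = list(pred = rep("numeric", 8),
                     resp = c(rep("binary", 4), rep("ordinal", 4))),
    "gmr3-r2" = list(pred = rep("numeric", 8),
                     resp = c(rep("numeric", 4), rep("ordinal", 4))),
    "gmr3-pr" = list(pred = c("binary", "binary", "ordinal", "ordinal",
                              "ordinal", "numeric", "numeric", "numeric")[1:8],
                     resp = c("binary", "binary", "ordinal", "ordinal",
                              "ordinal", "numeric", "numeric", "numeric")[1:8]),
    stop("unknown scenario '", scenario, "'; use one of ",
         paste(SCENARIOS, collapse = ", ")))
}

# balance pattern of the discretized predictors per scenario; for gmr3-pr the
# design has 2 balanced + 1 unbalanced ordinal and 1 balanced + 1 unbalanced
# binary predictor
scenario_balance <- function(scenario, pred_levels) {
  bal <- rep(TRUE, length(pred_levels))
  if (scenario == "gmr3-p2") bal[] <- FALSE
  if (scenario == "gmr3-pr") {
    bal[which(pred_levels == "binary")[2]] <- FALSE
    bal[which(pred_levels == "ordinal")[3]] <- FALSE
  }
  bal
}

#' Generate one synthetic dataset from the simulation designs
#'
#' The six scenarios vary the measurement levels: `cond1` (numeric
#' predictors; 4 numeric + 4 binary responses), `gmr3-p1`/`gmr3-p2`
#' (all-ordinal predictors, balanced/unbalanced discretization), `gmr3-r1`
#' (4 binary + 4 ordinal responses), `gmr3-r2` (4 numeric + 4 ordinal
#' responses) and `gmr3-pr` (2 binary + 3 ordinal + 3 numeric on both sides,
#' the design also used for the rank-recovery study with `rank_true` 2, 4 or
#' 7 and a `"strong"` or `"weak"` trailing structure).
#'
#' @param scenario one of `"cond1"`, `"gmr3-p1"`, `"gmr3-p2"`, `"gmr3-r1"`,
#'   `"gmr3-r2"`, `"gmr3-pr"`.
#' @param N sample size.
#' @param seed integer seed (identical seeds give identical datasets).
#' @param rank_true true rank S of the generating structure (default 2).
#' @param strength `"strong"`, or `"weak"` to replace singular values
#'   `3..rank_true` of `B V'` with 0.20 (requires `rank_true >= 3`).
#' @return a list with `data` (a [mixed_data()] object), `A_true`
#'   (`B_true V_true'`), `B_true`, `V_true`, `thresholds` and the scenario
#'   settings.
#' @export
sim_scenario <- function(scenario = SCENARIOS, N, seed,
                         rank_true = 2L, strength = c("strong", "weak")) {
  scenario <- match.arg(scenario)
  strength <- match.arg(strength)
  set.seed(as.integer(seed))
  lv <- scenario_levels(scenario)
  P <- length(lv$pred); R <- length(lv$resp)
  S <- as.integer(rank_true)
  stopifnot(S >= 1, S <= min(P, R))

  B_true <- qr.Q(qr(matrix(stats::rnorm(P * S), P, S)))
  V_true <- matrix(stats::runif(R * S, -1, 1), R, S)
  if (strength == "weak") {
    wk <- weaken_structure(B_true, V_true)
    B_true <- wk$B; V_true <- wk$V
  }
  A_true <- B_true %*% t(V_true)
  thresholds_gen <- c(-1, 0, 1)

  X_lat <- matrix(stats::rnorm(N * P), N, P)
  bal <- scenario_balance(scenario, lv$pred)
  X_gen <- X_lat           # values entering the generating linear predictor
  X_obs <- X_lat           # values the analyst sees
  for (p in seq_len(P)) {
    if (lv$pred[p] == "ordinal") {
      d <- discretize_quantiles(X_lat[, p], if (bal[p]) "balanced" else "unbalanced")
      X_gen[, p] <- d$generating
      X_obs[, p] <- d$codes
    } else if (lv$pred[p] == "binary") {
      d <- dichotomize(X_lat[, p], balanced = bal[p])
      X_gen[, p] <- d$generating
      X_obs[, p] <- d$codes
    }
  }

  Theta <- X_gen %*% A_true     # zero intercepts
  Y <- matrix(0, N, R)
  for (r in seq_len(R)) {
    Y[, r] <- switch(lv$resp[r],
      numeric = Theta[, r] + stats::rnorm(N),
      binary = stats::rbinom(N, 1, stats::plogis(Theta[, r])),
      ordinal = draw_cumlogit(Theta[, r], thresholds_gen))
  }

  colnames(X_obs) <- paste0("x", seq_len(P))
  colnames(Y) <- paste0("y", seq_len(R))
  specs <- c(
    lapply(seq_len(P), function(p)
      variable_spec(paste0("x", p), "predictor", lv$pred[p],
                    n_categories = switch(lv$pred[p], numeric = 0,
                                          binary = 2, ordinal = 5))),
    lapply(seq_len(R), function(r)
      variable_spec(paste0("y", r), "response", lv$resp[r],
                    n_categories = switch(lv$resp[r], numeric = 0,
                                          binary = 2, ordinal = 4))))
  data <- mixed_data(as.data.frame(cbind(X_obs, Y)), specs)
  list(data = data, A_true = A_true, B_true = B_true, V_true = V_true,
       thresholds = thresholds_gen, scenario = scenario, N = N,
       rank_true = S, strength = strength, seed = seed)
}

# multinomial draws from the cumulative-logit probabilities implied by theta
draw_cumlogit <- function(theta, thresholds) {
  cum <- vapply(thresholds, function(t) stats::plogis(t - theta),
                numeric(length(theta)))
  u <- stats::runif(length(theta))
  rowSums(u > matrix(cum, nrow = length(theta))) + 1L
}

#' Root-mean-squared error between coefficient matrices
#'
#' `sqrt(mean((A_true - A_hat)^2))` over all P x R entries; the recovery
#' metric comparing the true product `B V'` with the estimated one.
#'
#' @param A_true,A_hat equal-shape matrices.
#' @return the scalar RMSE.
#' @export
rmse <- function(A_true, A_hat) {
  if (!all(dim(A_true) == dim(A_hat))) stop("shape mismatch")
  sqrt(mean((A_true - A_hat)^2))
}

#' Run a simulation experiment over a grid of conditions
#'
#' For each replication of each (scenario, N, true-rank/strength) cell,
#' generates a dataset, fits every requested rank and records the recovery
#' RMSE together with the model-selection quantities (NLL, K, AIC, BIC).
#' Per-replication seeds derive from the master seed by a counter so the grid
#' is reproducible cell by cell.
#'
#' @param scenarios character vector of scenario names.
#' @param Ns integer vector of sample sizes.
#' @param fit_ranks integer vector of ranks to fit to every dataset.
#' @param replications replications per cell.
#' @param seed master seed.
#' @param rank_true,strength generating structure (see [sim_scenario()]).
#' @param ... passed to [mixed_rrr()].
#' @return a data frame with one row per (cell, replication, fitted rank):
#'   `scenario`, `N`, `rank_true`, `strength`, `replication`, `fitted_rank`,
#'   `rmse`, `nll`, `K`, `aic`, `bic`, `converged`, `failed`.
#' @export
run_experiment <- function(scenarios, Ns, fit_ranks, replications,
                           seed = 1L, rank_true = 2L, strength = "strong",
                           ...) {
  rows <- list()
  counter <- 0L
  for (sc in scenarios) for (N in Ns) for (rep_i in seq_len(replications)) {
    counter <- counter + 1L
    sim <- sim_scenario(sc, N = N,
                        seed = (as.numeric(seed) * 10000 + counter) %% 2147483647,
                        rank_true = rank_true, strength = strength)
    nll0 <- null_nll(sim$data)
    for (S in fit_ranks) {
      fit <- tryCatch(
        suppressWarnings(mixed_rrr(sim$data, rank = S, ...)),
        error = function(e) NULL)
      failed <- is.null(fit)
      ic <- if (!failed)
        information_criteria(fit$nll, nll0, fit$K, N) else list(aic = NA, bic = NA)
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = sc, N = N, rank_true = rank_true, strength = strength,
        replication = rep_i, fitted_rank = S,
        rmse = if (failed) NA_real_ else rmse(sim$A_true, fit$A),
        nll = if (failed) NA_real_ else fit$nll,
        K = if (failed) NA_integer_ else fit$K,
        aic = ic$aic, bic = ic$bic,
        converged = if (failed) NA else fit$converged,
        failed = failed)
    }
  }
  out <- do.call(rbind, rows)
  n_failed <- sum(out$failed)
  if (n_failed) message(n_failed, " fit(s) failed and were recorded as NA")
  out
}

#' Tabulate rank-selection counts from an experiment table
#'
#' Counts, per (scenario, N, criterion), how often each fitted rank attains
#' the minimal AIC and BIC across the ranks fitted to the same replication.
#'
#' @param results a table from [run_experiment()].
#' @return a data frame with columns `scenario`, `N`, `criterion`,
#'   `selected_rank`, `count`.
#' @export
selection_counts <- function(results) {
  rows <- list()
  for (cell in split(results,
                     list(results$scenario, results$N), drop = TRUE)) {
    for (crit in c("aic", "bic")) {
      sel <- vapply(split(cell, cell$replication), function(d) {
        d <- d[!d$failed, ]
        if (!nrow(d)) return(NA_integer_)
        as.integer(d$fitted_rank[which.min(d[[crit]])])
      }, integer(1))
      tab <- table(sel)
      for (k in names(tab))
        rows[[length(rows) + 1L]] <- data.frame(
          scenario = cell$scenario[1], N = cell$N[1], criterion = crit,
          selected_rank = as.integer(k), count = as.integer(tab[[k]]))
    }
  }
  do.call(rbind, rows)
}
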