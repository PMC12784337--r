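#' Weighted monotone (isotonic) regression
#'
#' Projects a vector onto the cone of monotone vectors in the weighted
#' least-squares sense: minimizes `sum(weights * (values - out)^2)` subject to
#' `out` being non-decreasing (`direction = "increasing"`) or non-increasing.
#' Solved by the pool-adjacent-violators algorithm; pooled blocks carry the
#' weighted mean of their members.
#'
#' @param values numeric vector.
#' @param weights positive weights, same length.
#' @param direction `"increasing"` or `"decreasing"`.
#' @return the projected vector.
#' @export
#' @examples
#' weighted_monotone_regression(c(3, 1, 2), c(1, 1, 1), "increasing")
weighted_monotone_regression <- function(values, weights,
                                         direction = c("increasing", "decreasing")) {
  direction <- match.arg(direction)
  stopifnot(length(values) == length(weights), all(weights > 0))
  y <- if (direction == "decreasing") -values else values
  n <- length(y)
  # PAVA over blocks: (value, weight, size) stacks
  val <- numeric(n); wt <- numeric(n); sz <- integer(n)
  k <- 0L
  for (i in seq_len(n)) {
    k <- k + 1L
    val[k] <- y[i]; wt[k] <- weights[i]; sz[k] <- 1L
    while (k > 1L && val[k - 1L] > val[k]) {
      w <- wt[k - 1L] + wt[k]
      val[k - 1L] <- (wt[k - 1L] * val[k - 1L] + wt[k] * val[k]) / w
      wt[k - 1L] <- w
      sz[k - 1L] <- sz[k - 1L] + sz[k]
      k <- k - 1L
    }
  }
  out <- rep.int(val[seq_len(k)], sz[seq_len(k)])
  if (direction == "decreasing") -out else out
}

#' Rescale quantifications to a standardized quantified variable
#'
#' Applies the affine map with positive scale that gives the category
#' quantifications `w` a frequency-weighted mean of 0 and a frequency-weighted
#' (population-convention) variance of 1, so that the quantified variable
#' `G %*% w` is standardized.
#'
#' @param w length-C quantifications.
#' @param frequencies length-C observed category counts.
#' @return the rescaled quantifications.
#' @export
rescale_quantification <- function(w, frequencies) {
  stopifnot(length(w) == length(frequencies), all(frequencies > 0))
  N <- sum(frequencies)
  mu <- sum(frequencies * w) / N
  s <- sqrt(sum(frequencies * (w - mu)^2) / N)
  if (s < 1e-12) stop("degenerate quantification: all categories equal")
  (w - mu) / s
}

#' Update the quantifications of one discrete predictor
#'
#' Given the working-residual matrix with every other predictor's contribution
#' removed, solves the least-squares problem for the category quantifications
#' of predictor p.  The cross-product matrix of the vec-form regression is
#' diagonal (`||a_p||^2 * frequencies`), giving a closed-form unconstrained
#' update.  Ordinal quantifications are then projected onto the monotone cone
#' by running [weighted_monotone_regression()] in both directions and keeping
#' the direction with the smaller weighted residual sum of squares.  Finally
#' the result is rescaled to a standardized quantified variable.
#'
#' @param Z_target N x R working-residual matrix (all other predictors'
#'   contributions removed).
#' @param a_p length-R coefficient row for predictor p (p-th row of `B %*% t(V)`).
#' @param indicator result of [build_indicator()] for predictor p.
#' @param level `"binary"`, `"nominal"` or `"ordinal"`.
#' @param previous previous quantifications, returned unchanged when
#'   `||a_p|| = 0` (the least-squares problem is then degenerate).
#' @return a list with elements `w` (rescaled quantifications), `level`,
#'   `direction` (`"increasing"`, `"decreasing"` or `NA` for non-ordinal) and
#'   `flipped` (`TRUE` when the binary/nominal sign convention negated `w`).
#' @export
update_quantification <- function(Z_target, a_p, indicator, level,
                                  previous = NULL) {
  freq <- indicator$frequencies
  a2 <- sum(a_p^2)
  if (a2 < 1e-14) {
    if (is.null(previous))
      stop("predictor currently has zero coefficients and no previous quantification")
    message("predictor has zero coefficient norm; keeping previous quantification")
    return(list(w = previous, level = level, direction = NA_character_,
                flipped = FALSE))
  }
  # unconstrained LS: w = (G'Z a_p) / (||a_p||^2 freq)
  w_unc <- drop(crossprod(indicator$G, Z_target %*% a_p)) / (a2 * freq)
  direction <- NA_character_
  if (level == "ordinal") {
    up <- weighted_monotone_regression(w_unc, freq, "increasing")
    dn <- weighted_monotone_regression(w_unc, freq, "decreasing")
    sse_up <- sum(freq * (w_unc - up)^2)
    sse_dn <- sum(freq * (w_unc - dn)^2)
    if (sse_up <= sse_dn) {
      w_unc <- up; direction <- "increasing"
    } else {
      w_unc <- dn; direction <- "decreasing"
    }
  }
  w <- rescale_quantification(w_unc, freq)
  flipped <- FALSE
  if (level != "ordinal" && w[1] > 0) {
    # reproducibility convention: first category negative; the compensating
    # sign lives in the coefficient row, handled by the caller via `flipped`
    w <- -w
    flipped <- TRUE
  }
  list(w = w, level = level, direction = direction, flipped = flipped)
}

# Build the N x P matrix Phi of transformed predictors from raw X.
# Numeric columns are standardized once and never change; discrete columns are
# G_p %*% w_p for the current quantifications.  Returns Phi plus per-variable
# indicator matrices and quantifications.
scale_predictors <- function(X, pred_specs, quantifications = NULL) {
  P <- ncol(X)
  Phi <- matrix(0, nrow(X), P, dimnames = list(NULL, colnames(X)))
  indicators <- vector("list", P)
  quants <- vector("list", P)
  names(indicators) <- names(quants) <- colnames(X)
  for (p in seq_len(P)) {
    s <- pred_specs[[p]]
    if (s$level == "numeric") {
      Phi[, p] <- standardize(X[, p])
    } else {
      codes <- normalize_codes(X[, p], s)
      ind <- build_indicator(codes, s$n_categories)
      indicators[[p]] <- ind
      w <- if (!is.null(quantifications) && !is.null(quantifications[[p]]))
        quantifications[[p]]$w
      else
        start_quantification(ind, s)
      quants[[p]] <- list(w = w, level = s$level, direction = NA_character_)
      Phi[, p] <- ind$G %*% w
    }
  }
  list(Phi = Phi, indicators = indicators, quantifications = quants)
}

# starting quantifications: standardized integer codes (monotone by
# construction, hence admissible for every scaling level)
start_quantification <- function(indicator, spec) {
  rescale_quantification(seq_len(spec$n_categories), indicator$frequencies)
}

#' Tidy table of estimated category quantifications
#'
#' @param fit a fitted [mixed_rrr()] model.
#' @return a data frame with columns `variable`, `category`, `label` and
#'   `quantification`, one row per category of each discrete predictor.
#' @export
quantification_table <- function(fit) {
  stopifnot(inherits(fit, "mixed_rrr"))
  rows <- list()
  for (p in seq_along(fit$specs$predictors)) {
    s <- fit$specs$predictors[[p]]
    if (!is_discrete(s)) next
    w <- fit$quantifications[[s$name]]$w
    rows[[length(rows) + 1L]] <- data.frame(
      variable = s$name,
      category = seq_along(w),
      label = s$order,
      quantification = w)
  }
  if (!length(rows))
    return(data.frame(variable = character(), category = integer(),
                      label = character(), quantification = numeric()))
  do.call(rbind, rows)
}
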