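# Shared fixtures and independent oracles used across the test files.

# small all-numeric dataset builder
toy_numeric_data <- function(N = 60, P = 3, R = 2, seed = 1, A = NULL,
                             sigma = 1) {
  set.seed(seed)
  X <- matrix(rnorm(N * P), N, P)
  if (is.null(A)) A <- matrix(rnorm(P * R), P, R)
  Y <- X %*% A + sigma * matrix(rnorm(N * R), N, R)
  df <- data.frame(X, Y)
  names(df) <- c(paste0("x", seq_len(P)), paste0("y", seq_len(R)))
  specs <- c(
    lapply(seq_len(P), function(p) variable_spec(paste0("x", p), "predictor", "numeric")),
    lapply(seq_len(R), function(r) variable_spec(paste0("y", r), "response", "numeric")))
  mixed_data(df, specs)
}

# dataset with one response of the requested family on numeric predictors
toy_single_response <- function(level, N = 300, P = 4, seed = 1, C = 4) {
  set.seed(seed)
  X <- matrix(rnorm(N * P), N, P)
  Phi <- apply(X, 2, standardize)
  beta <- seq(0.8, -0.4, length.out = P)
  eta <- drop(Phi %*% beta)
  y <- switch(level,
    binary = rbinom(N, 1, plogis(0.3 + eta)),
    ordinal = vapply(eta, function(th) {
      u <- runif(1); sum(u > plogis(seq(-1, 1, length.out = C - 1) - th)) + 1L
    }, integer(1)),
    numeric = 0.3 + eta + rnorm(N))
  df <- data.frame(X, y = y)
  names(df) <- c(paste0("x", seq_len(P)), "y")
  specs <- c(
    lapply(seq_len(P), function(p) variable_spec(paste0("x", p), "predictor", "numeric")),
    list(variable_spec("y", "response", level,
                       n_categories = if (level == "ordinal") C)))
  mixed_data(df, specs)
}

# brute-force weighted projection onto the monotone-increasing cone:
# enumerate all partitions of 1..C into consecutive blocks, pool each block
# at its weighted mean, keep feasible (non-decreasing block means) candidates
brute_force_isotonic <- function(values, weights) {
  C <- length(values)
  best <- NULL; best_sse <- Inf
  # each of the 2^(C-1) cut patterns defines a partition into blocks
  for (mask in 0:(2^(C - 1) - 1)) {
    cuts <- which(bitwAnd(mask, 2^(0:(C - 2))) > 0)
    starts <- c(1, cuts + 1); ends <- c(cuts, C)
    fit <- numeric(C)
    means <- numeric(length(starts))
    for (b in seq_along(starts)) {
      idx <- starts[b]:ends[b]
      means[b] <- sum(weights[idx] * values[idx]) / sum(weights[idx])
      fit[idx] <- means[b]
    }
    if (is.unsorted(means)) next
    sse <- sum(weights * (values - fit)^2)
    if (sse < best_sse) { best_sse <- sse; best <- fit }
  }
  best
}

# quadrature oracle for the truncated-logistic probability-integral mean:
# E[F(e) | t_{y-1} - theta < e < t_y - theta] under the logistic density
quadrature_expected_p <- function(y, theta, thresholds) {
  t_ext <- c(-Inf, thresholds, Inf)
  lo <- t_ext[y] - theta; hi <- t_ext[y + 1] - theta
  num <- integrate(function(e) plogis(e) * dlogis(e), lo, hi,
                   rel.tol = 1e-12)$value
  den <- plogis(hi) - plogis(lo)
  num / den
}

# structure of the worked survey application: 5 predictors (numeric age,
# binary gender, ordinal alignment/urbanization C=3, ordinal education C=9)
# and 7 responses (2 binary, 5 ordinal C=4)
survey_structure <- function() {
  list(predictors = list(
         variable_spec("A", "predictor", "numeric"),
         variable_spec("G", "predictor", "binary"),
         variable_spec("PA", "predictor", "ordinal", n_categories = 3),
         variable_spec("U", "predictor", "ordinal", n_categories = 3),
         variable_spec("E", "predictor", "ordinal", n_categories = 9)),
       responses = list(
         variable_spec("T", "response", "binary"),
         variable_spec("FE", "response", "binary"),
         variable_spec("CI", "response", "ordinal", n_categories = 4),
         variable_spec("MW", "response", "ordinal", n_categories = 4),
         variable_spec("FS", "response", "ordinal", n_categories = 4),
         variable_spec("DI", "response", "ordinal", n_categories = 4),
         variable_spec("RE", "response", "ordinal", n_categories = 4)))
}
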