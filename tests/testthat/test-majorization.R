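test_that("canonical parameters reproduce the worked survey profile", {
  expect_equal(logistic_cdf(0), 0.5)
  expect_equal(logistic_cdf(1e4), 1)
  expect_equal(logistic_cdf(0.85), 0.70, tolerance = 0.005)

  # 70-year-old woman, left-aligned, rural, bachelor: published quantified
  # profile and implied coefficient columns
  phi <- c(A = 1.25, PA = -1.13, G = 1.39, U = -0.64, E = 0.32)
  a_T <- c(-0.16, -0.63, -0.06, 0.21, 0.34)
  a_CI <- c(-0.05, -0.60, -0.10, 0.21, 0.31)
  # inputs are printed to two decimals, so agreement is to ~0.01 absolute
  theta_T <- 0.45 + sum(phi * a_T)
  expect_lt(abs(theta_T - 0.85), 0.01)
  theta_CI <- sum(phi * a_CI)
  expect_lt(abs(theta_CI - 0.45), 0.01)

  # same numbers through canonical_params with a rank-1 factorization
  Theta <- canonical_params(matrix(phi, 1), m = 0.45,
                            B = matrix(a_T, ncol = 1), V = matrix(1))
  expect_equal(drop(Theta), theta_T, tolerance = 1e-12)
  expect_equal(canonical_params(matrix(1, 2, 3), m = c(1, 2),
                                B = matrix(0, 3, 2), V = matrix(0, 2, 2)),
               rbind(c(1, 2), c(1, 2)))  # B = 0 gives the null model
  expect_error(canonical_params(matrix(1, 2, 3), 1:2, matrix(0, 2, 2),
                                matrix(0, 2, 2)), "dimension")
})

test_that("ordinal category probabilities match the published profile", {
  pr <- ordinal_category_probs(0.4413, c(-2.57, -0.91, 1.80))
  expect_equal(sum(pr), 1, tolerance = 1e-12)
  expect_lt(max(abs(pr - c(0.05, 0.16, 0.59, 0.21))), 0.01)
  expect_equal(ordinal_category_probs(0, 0), c(0.5, 0.5))
  expect_equal(ordinal_category_probs(50, c(-1, 0, 1)), c(0, 0, 0, 1),
               tolerance = 1e-12)
  # rows of the vectorized form are simplex points
  pm <- ordinal_category_probs(seq(-3, 3, length.out = 7), c(-1, 0.5))
  expect_equal(rowSums(pm), rep(1, 7))
  expect_true(all(pm >= 0))
})

test_that("negative log-likelihood matches closed forms per family", {
  sp_b <- list(variable_spec("y", "response", "binary"))
  expect_equal(negative_loglik(matrix(1), matrix(0), sp_b), log(2))
  sp_n <- list(variable_spec("y", "response", "numeric"))
  expect_equal(negative_loglik(matrix(2), matrix(2), sp_n, sigma2 = 1),
               0.5 * log(2 * pi))
  sp_o <- list(variable_spec("y", "response", "ordinal", n_categories = 4))
  thr <- list(y = c(-1, 0, 1))
  expect_equal(negative_loglik(matrix(2), matrix(0), sp_o, thr),
               -log(plogis(0) - plogis(-1)), tolerance = 1e-12)
  expect_equal(-log(plogis(0) - plogis(-1)), 1.46508, tolerance = 1e-5)
})

test_that("expected_p equals the midpoint identity and the quadrature oracle", {
  expect_equal(expected_p(1, 0, 0), 0.25)
  expect_equal(expected_p(2, 0, c(-1, 1)), 0.5)
  expect_equal(expected_p(3, 0, c(-2, 0)), 0.75)
  set.seed(13)
  for (i in 1:20) {
    C <- sample(2:5, 1)
    thr <- sort(rnorm(C - 1, sd = 1.5))
    theta <- rnorm(1)
    y <- sample(seq_len(C), 1)
    t_ext <- c(-Inf, thr, Inf)
    midpoint <- (plogis(t_ext[y] - theta) + plogis(t_ext[y + 1] - theta)) / 2
    ep <- expected_p(y, theta, thr)
    expect_equal(ep, midpoint, tolerance = 1e-12)
    expect_equal(ep, quadrature_expected_p(y, theta, thr), tolerance = 1e-8)
  }
})

test_that("kappa_star applies the curvature bound and small-variance warning", {
  expect_equal(kappa_star(has_numeric = FALSE), 0.25)
  expect_equal(kappa_star(1), 1)
  expect_equal(kappa_star(9), 0.25)   # sigma^2 > 4: logistic bound dominates
  expect_warning(k <- kappa_star(0.04), "0.05")
  expect_equal(k, 25)
  expect_error(kappa_star(-1), "positive")
})

test_that("working responses follow the per-family derivative formulas", {
  # numeric with kappa* = 1/sigma^2 collapses to the observation
  sp <- list(variable_spec("y", "response", "numeric"))
  ws <- working_matrix(matrix(3.7), matrix(1.2), sp, sigma2 = 0.5,
                       kappa = kappa_star(0.5))
  expect_equal(drop(ws$Z), 3.7)
  # binary y=1 at theta=0: xi = -0.5, z = 2
  sp_b <- list(variable_spec("y", "response", "binary"))
  wb <- working_matrix(matrix(1), matrix(0), sp_b, kappa = 0.25)
  expect_equal(drop(wb$Xi), -0.5)
  expect_equal(drop(wb$Z), 2)
  # ordinal y=1, t=(0), theta=0: E(p)=1/4, xi=1/2, z=-2
  sp_o <- list(variable_spec("y", "response", "ordinal", n_categories = 2))
  wo <- working_matrix(matrix(1), matrix(0), sp_o, thresholds = list(y = 0),
                       kappa = 0.25)
  expect_equal(drop(wo$Xi), 0.5)
  expect_equal(drop(wo$Z), -2)
})

test_that("the quadratic bound majorizes the numeric and binary losses", {
  grid <- seq(-4, 4, length.out = 17)
  for (support in grid) for (theta in grid) {
    # binary, y = 1, kappa = 1/4
    loss <- function(t) -log(plogis(t))
    xi <- -(1 - plogis(support))
    M <- loss(support) + xi * (theta - support) + 0.125 * (theta - support)^2
    expect_gte(M + 1e-12, loss(theta))
    # numeric, y = 1, sigma2 = 2, kappa = 1/2 (exact curvature: equality)
    lnum <- function(t) (1 - t)^2 / 4 + 0.5 * log(4 * pi)
    xin <- (support - 1) / 2
    Mn <- lnum(support) + xin * (theta - support) + 0.25 * (theta - support)^2
    expect_equal(Mn, lnum(theta), tolerance = 1e-9)
  }
})
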