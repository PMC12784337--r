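test_that("weighted monotone regression matches brute-force cone projection", {
  expect_equal(weighted_monotone_regression(c(3, 1, 2), c(1, 1, 1), "increasing"),
               c(2, 2, 2))
  expect_equal(weighted_monotone_regression(c(1, 2, 3), c(1, 1, 1), "increasing"),
               c(1, 2, 3))
  expect_equal(weighted_monotone_regression(c(3, 2, 1), c(1, 1, 1), "decreasing"),
               c(3, 2, 1))
  set.seed(11)
  for (i in 1:25) {
    C <- sample(2:6, 1)
    v <- rnorm(C) * sample(1:3, 1)
    w <- runif(C, 0.2, 4)
    pava <- weighted_monotone_regression(v, w, "increasing")
    expect_equal(pava, brute_force_isotonic(v, w), tolerance = 1e-8)
    # decreasing direction via reflection
    pava_dn <- weighted_monotone_regression(v, w, "decreasing")
    expect_equal(pava_dn, -brute_force_isotonic(-v, w), tolerance = 1e-8)
  }
})

test_that("rescale_quantification standardizes with frequency weights", {
  expect_equal(rescale_quantification(c(0, 1), c(2, 2)), c(-1, 1))
  expect_equal(rescale_quantification(c(1, 2, 3), c(1, 1, 1)),
               c(-1.224744871, 0, 1.224744871), tolerance = 1e-8)
  expect_error(rescale_quantification(c(5, 5), c(3, 1)), "degenerate")
  # order preserved, weighted moments exact
  set.seed(3)
  w <- sort(rnorm(5)); f <- sample(1:10, 5, replace = TRUE)
  r <- rescale_quantification(w, f)
  expect_equal(order(r), order(w))
  expect_equal(sum(f * r) / sum(f), 0, tolerance = 1e-12)
  expect_equal(sum(f * r^2) / sum(f), 1, tolerance = 1e-12)
})

test_that("quantification update solves the closed-form least-squares problem", {
  # binary, unbalanced: z-scores of the dummy (-sqrt(p/q), sqrt(q/p))
  set.seed(21)
  codes <- rep(c(1, 2), times = c(30, 10))     # prop of category 2 = 0.25
  ind <- build_indicator(codes, 2)
  Zt <- cbind(rnorm(40), ind$G %*% c(0, 1) + rnorm(40, sd = 0.1))
  upd <- update_quantification(Zt, c(0.2, 0.9), ind, "binary")
  expect_equal(sort(abs(upd$w)), sort(c(sqrt(1 / 3), sqrt(3))), tolerance = 1e-8)
  expect_lt(upd$w[1], 0)    # sign convention: first category negative

  # nominal C=3 with equal frequencies: per-category targets (2, -1, -1)
  codes3 <- rep(1:3, each = 5)
  ind3 <- build_indicator(codes3, 3)
  Zt3 <- matrix(ind3$G %*% c(2, -1, -1), ncol = 1)
  upd3 <- update_quantification(Zt3, 1, ind3, "nominal")
  expect_equal(abs(upd3$w), c(sqrt(2), sqrt(0.5), sqrt(0.5)), tolerance = 1e-8)
  # cross-check against a generic least-squares solve of the vec form
  a_p <- c(0.7, -0.4)
  ZtA <- cbind(rnorm(15), rnorm(15))
  Q <- kronecker(matrix(a_p, ncol = 1), ind3$G)
  w_ls <- qr.solve(Q, as.vector(ZtA))
  upd_ls <- update_quantification(ZtA, a_p, ind3, "nominal")
  expect_equal(abs(upd_ls$w),
               abs(rescale_quantification(w_ls, ind3$frequencies)),
               tolerance = 1e-8)

  # zero coefficient row: previous quantification kept
  expect_message(
    kept <- update_quantification(ZtA, c(0, 0), ind3, "nominal",
                                  previous = c(-1, 0, 1)),
    "zero coefficient")
  expect_equal(kept$w, c(-1, 0, 1))
})

test_that("ordinal projection picks the better-fitting direction", {
  set.seed(31)
  for (i in 1:10) {
    C <- sample(3:6, 1)
    codes <- c(seq_len(C), sample(seq_len(C), 60, replace = TRUE))
    ind <- build_indicator(codes, C)
    mono <- sort(rnorm(C)) * sample(c(1, -1), 1)
    Zt <- matrix(ind$G %*% mono + rnorm(length(codes), sd = 0.5), ncol = 1)
    upd <- update_quantification(Zt, 1, ind, "ordinal")
    # quantified column standardized and monotone in the chosen direction
    phi <- ind$G %*% upd$w
    expect_equal(mean(phi), 0, tolerance = 1e-10)
    expect_equal(mean(phi^2), 1, tolerance = 1e-10)
    d <- diff(upd$w)
    expect_true(all(d >= -1e-12) || all(d <= 1e-12))
    # chosen direction fits at least as well as the other
    w_unc <- drop(crossprod(ind$G, Zt)) / ind$frequencies
    sse <- function(dir) {
      pr <- weighted_monotone_regression(w_unc, ind$frequencies, dir)
      sum(ind$frequencies * (w_unc - pr)^2)
    }
    chosen <- if (upd$direction == "increasing") sse("increasing") else sse("decreasing")
    expect_lte(chosen, min(sse("increasing"), sse("decreasing")) + 1e-12)
  }
})

test_that("a full quantification sweep never increases the least-squares majorizer", {
  sim <- sim_scenario("gmr3-p1", N = 150, seed = 7)
  d <- sim$data
  sc <- scale_predictors(d$X, d$specs$predictors)
  Phi <- sc$Phi
  set.seed(8)
  S <- 2
  B <- matrix(rnorm(8 * S), 8, S)
  V <- qr.Q(qr(matrix(rnorm(8 * S), 8, S)))
  A <- B %*% t(V)
  Z <- matrix(rnorm(150 * 8), 150, 8) + Phi %*% A
  loss_before <- sum((Z - Phi %*% A)^2)
  quants <- sc$quantifications
  for (p in 1:8) {
    Res <- Z - Phi %*% A
    Z_target <- Res + outer(Phi[, p], A[p, ])
    upd <- update_quantification(Z_target, A[p, ], sc$indicators[[p]],
                                 "ordinal", previous = quants[[p]]$w)
    Phi[, p] <- sc$indicators[[p]]$G %*% upd$w
  }
  loss_after <- sum((Z - Phi %*% A)^2)
  expect_lte(loss_after, loss_before + 1e-8)
})
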