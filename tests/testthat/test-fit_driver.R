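test_that("starting values reduce to classical reduced-rank regression", {
  d <- toy_numeric_data(N = 120, P = 5, R = 4, seed = 51)
  st <- initialize_fit(d, 2)
  Xc <- apply(d$X, 2, standardize)
  Yc <- apply(d$Y, 2, standardize)
  C_ols <- solve(crossprod(Xc), crossprod(Xc, Yc))
  eg <- eigen(crossprod(Xc %*% C_ols), symmetric = TRUE)
  Vo <- eg$vectors[, 1:2]
  expect_equal(st$A_start, C_ols %*% Vo %*% t(Vo), tolerance = 1e-8)
  expect_equal(abs(st$B), abs(C_ols %*% Vo), tolerance = 1e-8)

  # pure-noise data: trailing structure is near zero
  set.seed(52)
  d0 <- toy_numeric_data(N = 2000, P = 4, R = 3, seed = 52,
                         A = matrix(0, 4, 3))
  st0 <- initialize_fit(d0, 2)
  expect_lt(max(svd(st0$A_start)$d), 0.12)

  # ordinal thresholds start at logits of cumulative proportions
  df <- data.frame(x = rnorm(100), y = rep(1:4, each = 25))
  d_o <- mixed_data(df, list(variable_spec("x", "predictor", "numeric"),
                             variable_spec("y", "response", "ordinal",
                                           n_categories = 4)))
  expect_equal(initialize_fit(d_o, 1)$thresholds$y,
               qlogis(c(0.25, 0.5, 0.75)), tolerance = 1e-10)
})

test_that("the fit descends monotonically on every scenario", {
  for (sc in c("cond1", "gmr3-p2", "gmr3-r1", "gmr3-pr")) {
    sim <- sim_scenario(sc, N = 120, seed = 53)
    fit <- mixed_rrr(sim$data, rank = 2)
    expect_true(all(diff(fit$nll_trace) <= 1e-8), info = sc)
    expect_true(fit$converged, info = sc)
  }
})

test_that("single-response fits match the standard GLM oracles", {
  # binary, S = 1: logistic regression on the standardized predictors
  d_b <- toy_single_response("binary", N = 300, seed = 54)
  fit_b <- mixed_rrr(d_b, rank = 1, tol = 1e-11, max_iter = 20000)
  Phi <- apply(d_b$X, 2, standardize)
  g <- glm(d_b$Y[, 1] ~ Phi, family = binomial)
  expect_equal(fit_b$nll, -as.numeric(logLik(g)), tolerance = 1e-6)

  # ordinal, S = 1: proportional-odds regression
  d_o <- toy_single_response("ordinal", N = 300, seed = 55)
  fit_o <- mixed_rrr(d_o, rank = 1, tol = 1e-11, max_iter = 20000)
  Phi_o <- apply(d_o$X, 2, standardize)
  po <- MASS::polr(factor(d_o$Y[, 1]) ~ Phi_o, method = "logistic")
  expect_equal(fit_o$nll, -as.numeric(logLik(po)), tolerance = 1e-5)
})

test_that("all-numeric fits equal closed-form reduced-rank regression", {
  d <- toy_numeric_data(N = 150, P = 5, R = 4, seed = 56)
  Phi <- apply(d$X, 2, standardize)
  Yc <- sweep(d$Y, 2, colMeans(d$Y))
  C_ols <- solve(crossprod(Phi), crossprod(Phi, Yc))
  for (S in c(2, 4)) {
    fit <- mixed_rrr(d, rank = S, tol = 1e-12)
    eg <- eigen(crossprod(Phi %*% C_ols), symmetric = TRUE)
    Vo <- eg$vectors[, 1:S, drop = FALSE]
    expect_equal(fit$A, C_ols %*% Vo %*% t(Vo), tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
  # full rank: unconstrained multivariate regression
  fit_full <- mixed_rrr(d, rank = 4, tol = 1e-12)
  expect_equal(fit_full$A, C_ols, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("identification yields orthonormal V, diagonal U'U, invariant A", {
  sim <- sim_scenario("gmr3-pr", N = 150, seed = 57)
  fit <- mixed_rrr(sim$data, rank = 3)
  S <- 3
  expect_lt(max(abs(crossprod(fit$V) - diag(S))), 1e-10)
  UtU <- crossprod(fit$Phi %*% fit$B)
  expect_lt(max(abs(UtU - diag(diag(UtU)))), 1e-8)
  expect_true(all(diff(diag(UtU)) <= 1e-8))      # non-increasing order
  # re-identifying is idempotent up to machine precision
  fit2 <- identify_fit(fit)
  expect_equal(fit2$A, fit$A, tolerance = 1e-12)
  expect_equal(fit2$B, fit$B, tolerance = 1e-8)
  # rotation invariance of A under an arbitrary rotation before identify
  ang <- 0.7; Rot <- matrix(c(cos(ang), sin(ang), 0,
                              -sin(ang), cos(ang), 0, 0, 0, 1), 3, 3)
  fit_rot <- fit; fit_rot$B <- fit$B %*% Rot; fit_rot$V <- fit$V %*% Rot
  fit_rot <- identify_fit(fit_rot)
  expect_lt(max(abs(fit_rot$B %*% t(fit_rot$V) - fit$A)), 1e-12)
  expect_equal(fit_rot$B, fit$B, tolerance = 1e-6)
  expect_equal(fit_rot$V, fit$V, tolerance = 1e-6)
})

test_that("independent starts agree after identification", {
  sim <- sim_scenario("gmr3-pr", N = 200, seed = 58)
  fit1 <- mixed_rrr(sim$data, rank = 2, tol = 1e-11, max_iter = 20000)
  # perturbed start: random rotation and noise on the default start
  st <- initialize_fit(sim$data, 2)
  set.seed(59)
  st$B <- st$B + matrix(rnorm(length(st$B), sd = 0.3), nrow(st$B))
  st$V <- qr.Q(qr(st$V + matrix(rnorm(length(st$V), sd = 0.3), nrow(st$V))))
  init <- structure(c(st, list(rank = 2, quantifications = list(),
                               A = st$B %*% t(st$V))), class = "mixed_rrr")
  fit2 <- mixed_rrr(sim$data, rank = 2, tol = 1e-11, max_iter = 20000, init = init)
  expect_lt(max(abs(fit1$A - fit2$A)), 2e-4)
  expect_lt(max(abs(fit1$B - fit2$B)), 5e-4)
  expect_lt(max(abs(fit1$V - fit2$V)), 5e-4)
})

test_that("prediction applies training scaling, thresholds and the class rule", {
  sim <- sim_scenario("gmr3-pr", N = 200, seed = 60)
  fit <- mixed_rrr(sim$data, rank = 2)
  nd <- as.data.frame(sim$data$X[1:5, , drop = FALSE])
  pr <- predict(fit, nd)
  # theta of training rows equals the training canonical parameters
  Theta_train <- canonical_params(fit$Phi, unname(fit$m), fit$B, fit$V)
  expect_equal(pr$theta, Theta_train[1:5, ], tolerance = 1e-10,
               ignore_attr = TRUE)
  # binary predictions are F(theta)
  bin <- which(vapply(fit$specs$responses, function(s) s$level == "binary",
                      logical(1)))
  expect_equal(pr$expected[, bin[1]], plogis(pr$theta[, bin[1]]),
               ignore_attr = TRUE)
  # ordinal class is the half-open interval containing theta
  ordr <- which(vapply(fit$specs$responses, function(s) s$level == "ordinal",
                       logical(1)))[1]
  nm <- fit$specs$responses[[ordr]]$name
  t_r <- fit$thresholds[[nm]]
  cls <- pr$expected[, ordr]
  for (i in 1:5) {
    lo <- c(-Inf, t_r)[cls[i]]; hi <- c(t_r, Inf)[cls[i]]
    expect_true(pr$theta[i, ordr] >= lo && pr$theta[i, ordr] < hi)
  }
  expect_equal(rowSums(pr$probabilities[[nm]]), rep(1, 5), tolerance = 1e-12)
  # boundary: theta exactly at t_1 belongs to class 2
  fake <- fit
  expect_equal(findInterval(t_r[1], t_r) + 1, 2)
  # unseen categories are refused
  nd_bad <- nd; nd_bad[[1, "x3"]] <- 7
  expect_error(predict(fit, nd_bad), "unseen")
})

test_that("parameter recovery improves with sample size", {
  med_rmse <- vapply(c(250, 1000), function(N) {
    r <- vapply(1:20, function(i) {
      sim <- sim_scenario("cond1", N = N, seed = 6000 + i)
      fit <- suppressWarnings(mixed_rrr(sim$data, rank = 2))
      rmse(sim$A_true, fit$A)
    }, numeric(1))
    median(r)
  }, numeric(1))
  expect_lt(med_rmse[2], med_rmse[1])
})
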