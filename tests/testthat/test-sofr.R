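test_that("least squares at lambda = 0 matches the normal-equations oracle", {
  # noise-free recovery of known coefficients
  set.seed(7)
  Z <- matrix(rnorm(60), 20, 3)
  y <- 1 + Z %*% c(2, -1, 0.5)
  f <- sofr(as.numeric(y), Z, lambda = 0)
  expect_equal(f$alpha, 1, tolerance = 1e-8)
  expect_equal(unname(f$gamma), c(2, -1, 0.5), tolerance = 1e-8)
  expect_equal(f$r2, 1, tolerance = 1e-10)

  # seeded random designs vs an explicit solve of the normal equations
  for (r in 1:25) {
    set.seed(r)
    n <- sample(8:30, 1); p <- sample(1:5, 1)
    Z <- matrix(rnorm(n * p), n, p)
    y <- rnorm(n)
    f <- sofr(y, Z, lambda = 0)
    X <- cbind(1, Z)
    beta <- solve(crossprod(X), crossprod(X, y))
    expect_equal(unname(c(f$alpha, f$gamma)), as.numeric(beta),
                 tolerance = 1e-8)
    # residuals orthogonal to the design columns
    expect_lt(max(abs(crossprod(X, f$residuals))), 1e-8)
    expect_equal(f$fitted + f$residuals, y)
    expect_true(f$r2 >= 0 && f$r2 <= 1)
  }
})

test_that("ridge limits and degenerate inputs behave as contracted", {
  set.seed(8)
  Z <- matrix(rnorm(45), 15, 3)
  y <- rnorm(15, 5)
  f <- sofr(y, Z, lambda = 1e12)
  expect_lt(max(abs(f$gamma)), 1e-6)
  expect_equal(f$fitted, rep(mean(y), 15), tolerance = 1e-6)
  expect_lt(f$r2, 1e-10)

  expect_error(sofr(rep(2, 10), matrix(rnorm(10)), 0), "degenerate")
  expect_error(sofr(y[1:2], Z[1:2, ], 0), "insufficient")
  expect_error(sofr(y, Z, lambda = -1), "non-negative")
})

test_that("fit statistics respect nesting, permutation and scaling", {
  set.seed(9)
  g <- season_grid(2000)
  n <- 17
  X <- matrix(rnorm(n * 62, -2, 1), n, 62)
  y <- rnorm(n, 3)
  # in-sample R^2 is non-decreasing in K at lambda = 0 (nested Fourier)
  r2s <- vapply(1:6, function(K) {
    sofr(y, quadrature_scores(X, make_basis("fourier", K, g)), 0)$r2
  }, numeric(1))
  expect_true(all(diff(r2s) >= -1e-10))

  # joint permutation of rows leaves the fit invariant
  b <- make_basis("fourier", 4, g)
  Z <- quadrature_scores(X, b)
  f <- sofr(y, Z, lambda = 0)
  pi <- sample(n)
  fp <- sofr(y[pi], Z[pi, ], lambda = 0)
  expect_equal(fp$alpha, f$alpha, tolerance = 1e-9)
  expect_equal(fp$gamma, f$gamma, tolerance = 1e-9)
  expect_equal(fp$r2, f$r2, tolerance = 1e-9)

  # scale equivariance: X -> cX divides gamma by c, fitted unchanged
  f2 <- sofr(y, 4 * Z, lambda = 0)
  expect_equal(unname(f2$gamma), unname(f$gamma) / 4, tolerance = 1e-9)
  expect_equal(f2$fitted, f$fitted, tolerance = 1e-9)
})

test_that("LOOCV lambda selection penalizes overfitting", {
  expect_equal(as.numeric(select_lambda(rnorm(10), matrix(rnorm(20), 10),
                                        lambdas = 7)), 7)

  # exact linear signal, no noise -> no shrinkage wanted
  set.seed(10)
  Z <- matrix(rnorm(30), 10, 3)
  y <- as.numeric(2 + Z %*% c(1, -2, 0.5))
  expect_equal(as.numeric(select_lambda(y, Z, lambdas = c(0, 1, 100))), 0)

  # pure noise with many columns -> the larger penalty usually wins
  wins <- logical(50)
  for (r in 1:50) {
    set.seed(400 + r)
    Zr <- matrix(rnorm(17 * 8), 17, 8)
    yr <- rnorm(17)
    wins[r] <- as.numeric(select_lambda(yr, Zr, lambdas = c(0, 10))) == 10
  }
  expect_gte(mean(wins), 0.8)
})

test_that("coefficient curves reconstruct and integrate consistently", {
  g <- season_grid(2000)
  b <- make_basis("fourier", 4, g)
  set.seed(11)
  Z <- matrix(rnorm(17 * 4), 17, 4)
  f <- sofr(rnorm(17), Z, lambda = 0.5, basis = b, streams = "s")

  # single-coefficient and zero cases
  f1 <- f; f1$gamma <- c(1, 0, 0, 0)
  expect_equal(as.numeric(reconstruct_beta(f1, b)),
               rep(1 / sqrt(g$T), 62))
  f0 <- f; f0$gamma <- rep(0, 4)
  expect_equal(as.numeric(reconstruct_beta(f0, b)), rep(0, 62))

  # quadrature of beta against any curve reproduces Z gamma
  X <- matrix(rnorm(5 * 62, -2), 5, 62)
  ZX <- quadrature_scores(X, b)
  beta <- reconstruct_beta(f, b)
  lhs <- as.numeric(quadrature_scores(X, b) %*% f$gamma)
  rhs <- as.numeric(X[, 1:61] %*% beta[1:61, 1]) * g$dt
  expect_equal(lhs, rhs, tolerance = 1e-10)

  b5 <- make_basis("fourier", 5, g)
  expect_error(reconstruct_beta(f, b5), "K mismatch")
})

test_that("per-stream fitting splits the design and ranks signal carriers", {
  set.seed(12)
  g <- season_grid(2000)
  b <- make_basis("fourier", 3, g)
  n <- 12
  Xs <- list(a = matrix(rnorm(n * 62, -2), n, 62),
             b = matrix(rnorm(n * 62, -2), n, 62),
             c = matrix(rnorm(n * 62, -2), n, 62))
  d <- toy_design(rnorm(n, 5), Xs, g)
  fits <- fit_per_stream_models(d, b, lambda = 0)
  expect_named(fits, c("a", "b", "c"))
  expect_length(fits, 3L)

  # identical covariates give identical fits
  d2 <- toy_design(rnorm(n, 5), list(a = Xs$a, b = Xs$a), g)
  fits2 <- fit_per_stream_models(d2, b, lambda = 0)
  expect_equal(fits2$a$r2, fits2$b$r2, tolerance = 1e-12)

  # only stream a carries signal -> its model explains more, most runs
  better <- logical(20)
  for (r in 1:20) {
    sc <- synthetic_scenario(seed = 600 + r, n_seasons = 12,
                             gamma_stream_scale = c(1, 0, 0))
    ds <- gen_dataset(sc)
    X1 <- t(vapply(ds$truths, function(p) p$canada, numeric(62)))
    X2 <- t(vapply(ds$truths, function(p) p$lost_seal, numeric(62)))
    dd <- toy_design(ds$responses$ppr$y,
                     list(canada = X1, lost_seal = X2), g)
    fr <- fit_per_stream_models(dd, b, lambda = 0)
    better[r] <- fr$canada$r2 > fr$lost_seal$r2
  }
  expect_gte(mean(better), 0.9)
})

test_that("ensemble averaging combines predictions, bands and R-squared", {
  set.seed(13)
  g <- season_grid(2000)
  b <- make_basis("fourier", 3, g)
  n <- 10
  X <- matrix(rnorm(n * 62, -2), n, 62)
  d <- toy_design(rnorm(n, 4), list(a = X, b = X, c = X), g)
  fits <- fit_per_stream_models(d, b, lambda = 0)
  ens <- ensemble_predict(fits)
  expect_equal(ens$predictions$pred, fits$a$fitted)
  expect_equal(ens$predictions$se, fits$a$se_fit)
  expect_equal(ens$r2_avg, fits$a$r2)
  expect_equal(ens$predictions$upper - ens$predictions$pred,
               2 * ens$predictions$se)

  # averaged R^2 is the arithmetic mean of the per-model values
  f1 <- fits$a; f1$r2 <- 0.10
  f2 <- fits$b; f2$r2 <- 0.20
  f3 <- fits$c; f3$r2 <- 0.30
  mock <- structure(list(a = f1, b = f2, c = f3), class = "sofr_list")
  expect_equal(ensemble_predict(mock)$r2_avg, 0.2)

  # fits on different responses are refused
  f2$y <- f2$y + 1
  bad <- structure(list(a = f1, b = f2), class = "sofr_list")
  expect_error(ensemble_predict(bad), "alignment")
})

test_that("model methods expose the usual fitted-model interface", {
  set.seed(14)
  g <- season_grid(2000)
  b <- make_basis("fourier", 3, g)
  Z <- matrix(rnorm(30), 10, 3,
              dimnames = list(NULL, paste0("s:phi", 1:3)))
  y <- as.numeric(1 + Z %*% c(1, 0.5, -1) + rnorm(10, 0, 0.1))
  f <- sofr(y, Z, lambda = 0, basis = b, streams = "s",
            seasons = 2001:2010)
  expect_equal(unname(coef(f)[1]), f$alpha)
  expect_equal(fitted(f) + residuals(f), y)
  expect_equal(predict(f), fitted(f))
  expect_equal(predict(f, newdata = Z), fitted(f))
  pr <- predict(f, newdata = Z[1:2, ], se.fit = TRUE)
  expect_length(pr$se.fit, 2L)
  expect_true(all(pr$se.fit > 0))
  expect_output(print(f), "R-squared")
  expect_output(print(summary(f)), "gamma")
  sim <- simulate(f, nsim = 3, seed = 1)
  expect_equal(dim(sim), c(10L, 3L))
})
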