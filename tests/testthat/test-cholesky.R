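test_that("build_sigma reproduces the closed-form examples", {
  # identity case: phi = 0, lam = 0
  f <- chol_factors(matrix(0, 4, 4), rep(0, 4))
  expect_equal(unname(build_sigma(f)), diag(4))

  # independent 2-d case: D carries the scales
  f2 <- chol_factors(matrix(0, 2, 2), c(0, log(2)))
  expect_equal(unname(build_sigma(f2)), diag(c(1, 4)))

  # correlated 2-d case, checked against dense inversion T^{-1} D^2 T^{-t}
  phi <- matrix(0, 2, 2); phi[2, 1] <- 0.5
  f3 <- chol_factors(phi, c(0, 0))
  Tm <- diag(2) - phi
  oracle <- solve(Tm) %*% diag(c(1, 1)) %*% t(solve(Tm))
  s3 <- build_sigma(f3)
  expect_equal(unname(s3), oracle)
  expect_equal(unname(s3), matrix(c(1, 0.5, 0.5, 1.25), 2))
  expect_equal(s3[1, 2] / sqrt(s3[1, 1] * s3[2, 2]), 0.4472136, tolerance = 1e-6)
})

test_that("build_sigma output is symmetric positive definite for random factors", {
  set.seed(42)
  for (i in 1:200) {
    phi <- matrix(0, 4, 4)
    phi[lower.tri(phi)] <- rnorm(6, sd = 1.5)
    f <- chol_factors(phi, rnorm(4, sd = 1))
    s <- build_sigma(f)
    expect_equal(s, t(s))
    expect_gt(min(eigen(s, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
})

test_that("factor construction rejects invalid input", {
  expect_error(chol_factors(matrix(1, 4, 4), rep(0, 4)), "lower triangular")
  expect_error(chol_factors(matrix(0, 4, 4), c(0, 0, NA, 0)), "finite")
  expect_error(sigma_to_factors(matrix(c(1, 2, 2, 1), 2)), "positive definite")
})

test_that("sigma_to_factors inverts build_sigma", {
  # frozen 2-d example: inverse of the build_sigma example
  f <- sigma_to_factors(matrix(c(1, 0.5, 0.5, 1.25), 2))
  expect_equal(f$phi[2, 1], 0.5, tolerance = 1e-12)
  expect_equal(f$lam, c(0, 0), tolerance = 1e-12)

  # identity
  f4 <- sigma_to_factors(diag(4))
  expect_equal(f4$phi, matrix(0, 4, 4))
  expect_equal(f4$lam, rep(0, 4))

  # round trip on random SPD matrices
  set.seed(7)
  for (i in 1:1000) {
    s <- rand_spd(4)
    s2 <- build_sigma(sigma_to_factors(s))
    expect_lt(max(abs(s2 - s)), 1e-10)
  }
})

test_that("log-density from factors matches the dense-matrix oracle", {
  # standard normal at the origin, M = 4
  f0 <- chol_factors(matrix(0, 4, 4), rep(0, 4))
  expect_equal(dmvn_chol(rep(0, 4), rep(0, 4), f0), -2 * log(2 * pi), tolerance = 1e-12)

  # mode property: density maximal at y = mu
  set.seed(11)
  phi <- matrix(0, 4, 4); phi[lower.tri(phi)] <- rnorm(6)
  f <- chol_factors(phi, rnorm(4))
  mu <- rnorm(4)
  at_mode <- dmvn_chol(mu, mu, f)
  for (i in 1:20) expect_lt(dmvn_chol(mu + rnorm(4), mu, f), at_mode)

  # 100 random tuples vs dense oracle
  set.seed(23)
  for (i in 1:100) {
    phi <- matrix(0, 4, 4); phi[lower.tri(phi)] <- rnorm(6)
    f <- chol_factors(phi, rnorm(4, sd = 0.7))
    mu <- rnorm(4, sd = 2)
    y <- rnorm(4, sd = 3)
    expect_equal(dmvn_chol(y, mu, f),
                 dense_mvn_logdens(y, mu, build_sigma(f)),
                 tolerance = 1e-8)
  }
})

test_that("vectorised row kernels agree with the scalar interface", {
  set.seed(5)
  n <- 50
  eta <- cbind(matrix(rnorm(n * 4, sd = 2), n), matrix(rnorm(n * 4, sd = .5), n),
               matrix(rnorm(n * 6, sd = .8), n))
  colnames(eta) <- par_labels()
  par <- mvdreg:::.eta_to_par(eta)
  y <- mvdreg:::.sample_rows(par)
  ll <- mvdreg:::.ll_rows(y, par)
  mom <- mvdreg:::.par_moments(par)
  for (i in seq_len(n)) {
    phi <- matrix(0, 4, 4)
    phi[2, 1] <- par$phi[i, 1]; phi[3, 1] <- par$phi[i, 2]; phi[3, 2] <- par$phi[i, 3]
    phi[4, 1] <- par$phi[i, 4]; phi[4, 2] <- par$phi[i, 5]; phi[4, 3] <- par$phi[i, 6]
    f <- chol_factors(phi, par$lam[i, ])
    expect_equal(ll[i], unname(dmvn_chol(y[i, ], par$mu[i, ], f)), tolerance = 1e-10)
    s <- build_sigma(f)
    expect_equal(unname(mom$sd[i, ]), unname(sqrt(diag(s))), tolerance = 1e-10)
    rho <- s / tcrossprod(sqrt(diag(s)))
    expect_equal(unname(mom$rho[i, ]),
                 unname(c(rho[2, 1], rho[3, 1], rho[3, 2], rho[4, 1], rho[4, 2], rho[4, 3])),
                 tolerance = 1e-10)
  }
})

test_that("row score matches a numerical gradient of the row log-likelihood", {
  set.seed(9)
  n <- 5
  eta <- cbind(matrix(rnorm(n * 4), n), matrix(rnorm(n * 4, sd = .4), n),
               matrix(rnorm(n * 6, sd = .6), n))
  par <- mvdreg:::.eta_to_par(eta)
  y <- mvdreg:::.sample_rows(par)
  g <- mvdreg:::.grad_rows(y, par)
  h <- 1e-6
  for (k in 1:14) {
    eta_p <- eta; eta_p[, k] <- eta_p[, k] + h
    eta_m <- eta; eta_m[, k] <- eta_m[, k] - h
    num <- (mvdreg:::.ll_rows(y, mvdreg:::.eta_to_par(eta_p)) -
            mvdreg:::.ll_rows(y, mvdreg:::.eta_to_par(eta_m))) / (2 * h)
    expect_equal(unname(g[, k]), num, tolerance = 1e-5)
  }
})

test_that("sampling reproduces the target covariance", {
  # empty draw keeps the contract
  f0 <- chol_factors(matrix(0, 4, 4), rep(0, 4))
  expect_equal(nrow(rmvn_chol(0, rep(0, 4), f0)), 0)
  expect_error(rmvn_chol(-1, rep(0, 4), f0), "non-negative")

  # identity covariance: all pairwise correlations near zero
  y <- rmvn_chol(1e5, rep(0, 4), f0, seed = 31)
  emp <- cor(y)
  expect_lt(max(abs(emp[lower.tri(emp)])), 0.02)

  # correlated case: empirical covariance close to the reconstruction
  phi <- matrix(0, 2, 2); phi[2, 1] <- 0.5
  f <- chol_factors(phi, c(0, 0))
  y2 <- rmvn_chol(1e5, c(1, -1), f, seed = 32)
  expect_lt(max(abs(cov(y2) - build_sigma(f))), 0.02)
  expect_equal(unname(colMeans(y2)), c(1, -1), tolerance = 0.02)

  # determinism under a fixed seed
  expect_identical(rmvn_chol(10, rep(0, 4), f0, seed = 5),
                   rmvn_chol(10, rep(0, 4), f0, seed = 5))
})

test_that("threshold probabilities follow the Gaussian CDF and its symmetries", {
  expect_equal(threshold_probability(110, 15, 110, "below"), 0.5)
  expect_equal(threshold_probability(-1, 1, -2, "below"), pnorm(-1))
  expect_equal(threshold_probability(0, 1, 2, "above"), 1 - pnorm(2))
  expect_error(threshold_probability(0, 0, 1), "positive")

  # complementarity and monotonicity in the mean
  set.seed(3)
  mu <- rnorm(50); sd <- rexp(50) + 0.1; cut <- rnorm(50)
  expect_equal(threshold_probability(mu, sd, cut, "below") +
               threshold_probability(mu, sd, cut, "above"), rep(1, 50))
  p1 <- threshold_probability(mu, sd, cut, "below")
  p2 <- threshold_probability(mu + 0.5, sd, cut, "below")
  expect_true(all(p2 < p1))

  # Monte-Carlo prevalence converges to the analytic tail probability
  f <- sigma_to_factors(diag(c(225, 1.3, 1.2, 1.1)))
  y <- rmvn_chol(4e4, c(112, -1.2, -1, -0.4), f, seed = 77)
  expect_equal(mean(y[, "hb"] < 110),
               threshold_probability(112, 15, 110, "below"),
               tolerance = 3 / sqrt(4e4) + 1e-9)
})
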