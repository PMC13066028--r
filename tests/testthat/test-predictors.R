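test_that("P-spline basis is a partition of unity with a PSD difference penalty", {
  set.seed(1)
  x <- runif(200, 6, 59)
  b <- pspline_basis(x, k = 20)
  expect_equal(rowSums(b$X), rep(1, 200))
  expect_equal(dim(b$X), c(200L, 20L))
  # clamped evaluation outside the boundary still sums to one
  st <- mvdreg:::.build_term(term_pspline("age"), data.frame(age = x))
  Xout <- mvdreg:::.eval_term_raw(st, data.frame(age = c(-5, 100)))
  expect_equal(rowSums(Xout), c(1, 1))
  # penalties are symmetric PSD
  for (bb in list(b, spatial2d_basis(runif(50), runif(50), k = 6))) {
    expect_equal(bb$K, t(bb$K))
    expect_gt(min(eigen(bb$K, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
  }
})

test_that("second-order difference penalty annihilates linear coefficient sequences", {
  b <- pspline_basis(runif(50), k = 12, penalty_order = 2)
  j <- seq_len(12)
  for (ab in list(c(1, 0), c(0, 1), c(2, -3))) {
    cvec <- ab[1] + ab[2] * j
    expect_equal(drop(cvec %*% b$K %*% cvec), 0, tolerance = 1e-10)
  }
  # but a quadratic sequence is penalised
  q <- j^2
  expect_gt(drop(q %*% b$K %*% q), 1)
})

test_that("degenerate covariates are handled as specified", {
  expect_warning(pspline_basis(rep(2, 10), k = 8), "rank deficient")
  expect_error(spatial2d_basis(rep(1, 5), rep(2, 5)), "degenerate")
})

test_that("spatial tensor smooth represents constants and smooth surfaces", {
  set.seed(4)
  n <- 2000
  lon <- runif(n, 0, 6); lat <- runif(n, 0, 3)
  b <- spatial2d_basis(lon, lat, k = 10)
  # constant surface lies in the span (partition of unity in the tensor basis)
  expect_equal(rowSums(b$X), rep(1, n))
  # noiseless smooth surface: penalised fit with grid-searched smoothing
  f <- sin(lon) * cos(lat)
  XtX <- crossprod(b$X); Xtf <- crossprod(b$X, f)
  rmse <- sapply(10^seq(-4, 2), function(l) {
    beta <- solve(XtX + l * b$K + 1e-8 * diag(ncol(b$X)), Xtf)
    sqrt(mean((drop(b$X %*% beta) - f)^2))
  })
  expect_lt(min(rmse), 0.05)
})

test_that("term evaluation is identical row-wise and batched", {
  set.seed(8)
  d <- data.frame(age = runif(30, 6, 59), lon = runif(30), lat = runif(30))
  for (tm in list(term_pspline("age", k = 8), term_spatial(k = 5))) {
    st <- mvdreg:::.build_term(tm, d)
    Xb <- mvdreg:::.eval_term(st, d)
    Xr <- do.call(rbind, lapply(seq_len(30), function(i)
      mvdreg:::.eval_term(st, d[i, , drop = FALSE])))
    expect_equal(Xb, Xr)
  }
})

test_that("model specification enforces the 14-parameter contract", {
  spec <- mvdr_spec()
  expect_s3_class(spec, "mvdr_spec")
  expect_length(spec$parameter_terms, 14L)
  expect_identical(names(spec$parameter_terms), par_labels())
  # every parameter has at least an intercept
  expect_true(all(vapply(spec$parameter_terms,
                         function(tl) "intercept" %in% names(tl), TRUE)))
  expect_error(mvdr_spec(mu_height = term_linear("age")), "unknown parameter")
})

test_that("model specification round-trips through YAML", {
  spec <- mvdr_spec(mu_haz = list(term_pspline("age", k = 12), term_spatial()),
                    mu_hb = term_factor("sex"),
                    phi_43 = term_linear("temperature"))
  path <- tempfile(fileext = ".yaml")
  spec_to_yaml(spec, path)
  spec2 <- spec_from_yaml(path)
  expect_equal(spec, spec2)
})

test_that("predictor evaluation matches its contracts", {
  set.seed(12)
  n <- 60
  d <- data.frame(age = runif(n, 6, 59), lon = runif(n, 0, 5), lat = runif(n, 0, 5),
                  sex = factor(sample(c("female", "male"), n, TRUE)))

  # intercept-only with zero coefficients: mu = 0, Sigma = I
  spec0 <- mvdr_spec()
  designs0 <- mvdreg:::.build_designs(spec0, d)
  ev0 <- evaluate_predictor(spec0, d, mvdreg:::.zero_coefs(designs0))
  expect_equal(unname(ev0$mu), matrix(0, n, 4))
  expect_equal(unname(ev0$sd), matrix(1, n, 4))
  expect_equal(unname(ev0$rho), matrix(0, n, 6))

  # linearity in the covariate for a linear term
  spec1 <- mvdr_spec(mu_haz = term_linear("age"))
  designs1 <- mvdreg:::.build_designs(spec1, d)
  cf <- mvdreg:::.zero_coefs(designs1)
  cf$mu_haz$age <- 0.8
  d2 <- d; d2$age <- d$age + 10
  e1 <- mvdreg:::.eval_eta(designs1, d, cf)
  e2 <- mvdreg:::.eval_eta(designs1, d2, cf)
  sc <- designs1$params$mu_haz$age$scale
  expect_equal(e2[, "mu_haz"] - e1[, "mu_haz"], rep(0.8 * 10 / sc, n))
  expect_equal(e1[, colnames(e1) != "mu_haz"], e2[, colnames(e2) != "mu_haz"])
})

test_that("predictor evaluation is linear in coefficients and ignores zero terms", {
  set.seed(19)
  n <- 40
  d <- data.frame(age = runif(n, 6, 59), lon = runif(n, 0, 5), lat = runif(n, 0, 5),
                  sex = factor(sample(c("f", "m"), n, TRUE)))
  spec <- mvdr_spec(mu_haz = list(term_pspline("age", k = 8), term_factor("sex")),
                    lam_whz = term_pspline("age", k = 8),
                    phi_43 = term_linear("age"),
                    mu_hb = term_spatial(k = 4))
  designs <- mvdreg:::.build_designs(spec, d)
  rand_cf <- function() {
    cf <- mvdreg:::.zero_coefs(designs)
    for (lab in names(cf)) for (tn in names(cf[[lab]]))
      cf[[lab]][[tn]] <- rnorm(length(cf[[lab]][[tn]]), sd = 0.3)
    cf
  }
  c1 <- rand_cf(); c2 <- rand_cf()
  lincomb <- function(a, b, x, y) {
    out <- x
    for (lab in names(out)) for (tn in names(out[[lab]]))
      out[[lab]][[tn]] <- a * x[[lab]][[tn]] + b * y[[lab]][[tn]]
    out
  }
  e1 <- mvdreg:::.eval_eta(designs, d, c1)
  e2 <- mvdreg:::.eval_eta(designs, d, c2)
  e12 <- mvdreg:::.eval_eta(designs, d, lincomb(2, -0.5, c1, c2))
  expect_equal(e12, 2 * e1 - 0.5 * e2, tolerance = 1e-12)

  # brute-force term-by-term accumulation oracle
  oracle <- matrix(0, n, 14, dimnames = list(NULL, par_labels()))
  for (lab in par_labels()) for (tn in names(designs$params[[lab]])) {
    X <- mvdreg:::.eval_term(designs$params[[lab]][[tn]], d)
    oracle[, lab] <- oracle[, lab] + drop(X %*% c1[[lab]][[tn]])
  }
  expect_equal(e1, oracle)

  # a freshly added zero-coefficient term changes nothing
  spec2 <- mvdr_spec(mu_haz = list(term_pspline("age", k = 8), term_factor("sex")),
                     lam_whz = term_pspline("age", k = 8),
                     phi_43 = term_linear("age"),
                     mu_hb = term_spatial(k = 4),
                     mu_waz = term_pspline("age", k = 6))
  designs2 <- mvdreg:::.build_designs(spec2, d)
  c1b <- c1; c1b$mu_waz$`s(age)` <- numeric(designs2$params$mu_waz$`s(age)`$p)
  expect_equal(mvdreg:::.eval_eta(designs2, d, c1b), e1)
})

test_that("missing covariate columns raise a schema error naming the column", {
  d <- data.frame(age = runif(10, 6, 59))
  spec <- mvdr_spec(mu_haz = term_pspline("wealth"))
  expect_error(mvdreg:::.build_designs(spec, d), "wealth")
})
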