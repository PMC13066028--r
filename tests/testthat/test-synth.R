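test_that("default configuration encodes the intended joint structure", {
  cfg <- synth_config()
  # base covariance is SPD with the configured correlations
  ev <- eigen(cfg$base_sigma, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  rho <- cov2cor(cfg$base_sigma)
  expect_equal(rho["waz", "whz"], 0.70, tolerance = 1e-12)
  expect_equal(rho["haz", "waz"], 0.68, tolerance = 1e-12)
  expect_lt(rho["haz", "whz"], 0)              # chronic vs acute: negative
  expect_lt(max(abs(rho["hb", c("haz", "waz", "whz")])), 0.2)

  # stunting prevalence rises with age up to month 36 under the default truth
  ages <- 6:59
  tp <- true_parameters(cfg, data.frame(lon = 0, lat = 0, age = ages))
  stunt <- threshold_probability(tp$mu[, 2], tp$sd[, 2], -2, "below")
  expect_true(all(diff(stunt[ages <= 36]) >= -1e-12))
  # anemia and wasting decline with age
  anemia <- threshold_probability(tp$mu[, 1], tp$sd[, 1], 110, "below")
  wasting <- threshold_probability(tp$mu[, 4], tp$sd[, 4], -2, "below")
  expect_true(all(diff(anemia) <= 1e-12))
  expect_true(all(diff(wasting) <= 1e-12))
})

test_that("covariate fields are smooth functions of location", {
  cfg <- synth_config(n_clusters = 100)
  cl <- simulate_covariate_fields(cfg, seed = 4)
  expect_equal(nrow(cl), 100)
  fields <- attr(cl, "fields")
  # pure function of location: same site -> identical covariates
  e1 <- eval_fields(fields, c(1.3, 1.3), c(-2.1, -2.1))
  expect_equal(e1[1, ], e1[2, ], ignore_attr = TRUE)
  # a fresh evaluation at cluster sites reproduces the cluster table
  e2 <- eval_fields(fields, cl$lon, cl$lat)
  expect_equal(e2$temperature, cl$temperature)
  expect_equal(e2$wealth_index, cl$wealth_index)

  # amplitude 0 -> spatially constant covariates
  cfg0 <- synth_config(n_clusters = 50, field_amp = 0)
  cl0 <- simulate_covariate_fields(cfg0, seed = 5)
  expect_equal(diff(range(cl0$temperature)), 0)
  expect_equal(diff(range(cl0$elevation)), 0)
  expect_length(unique(cl0$landcover), 1L)

  # empty bounding box errors
  cfgbad <- synth_config(bbox = list(lon = c(1, 1), lat = c(0, 2)))
  expect_error(simulate_covariate_fields(cfgbad), "bounding box")
})

test_that("fields show positive spatial autocorrelation against a permutation null", {
  cfg <- synth_config(n_clusters = 500)
  cl <- simulate_covariate_fields(cfg, seed = 9)
  # nearest-neighbour Moran-style statistic
  nn <- sapply(seq_len(500), function(i) {
    d <- (cl$lon - cl$lon[i])^2 + (cl$lat - cl$lat[i])^2
    d[i] <- Inf
    which.min(d)
  })
  moran <- function(v) cor(v, v[nn])
  set.seed(1)
  for (v in list(cl$temperature, cl$malaria, cl$elevation)) {
    obs <- moran(v)
    null <- replicate(200, moran(sample(v)))
    expect_gt(obs, stats::quantile(null, 0.99))
  }
})

test_that("simulated surveys are reproducible and schema-complete", {
  cfg <- synth_config(n_clusters = 10, children_per_cluster = c(4, 6))
  s1 <- simulate_survey(cfg, seed = 2)
  s2 <- simulate_survey(cfg, seed = 2)
  expect_identical(s1, s2)
  s3 <- simulate_survey(cfg, seed = 3)
  expect_false(identical(s1$hb, s3$hb))

  cols <- c("child", "cluster", "lon", "lat", "age", "sex", "wealth_index",
            "year", "temperature", "malaria", "elevation", "landcover",
            "hb", "haz", "waz", "whz")
  expect_true(all(cols %in% names(s1)))
  expect_true(all(s1$age >= 6 & s1$age <= 59))
  expect_true(all(s1$lon >= -10 & s1$lon <= 10))

  # empty survey keeps the full schema
  s0 <- simulate_survey(synth_config(n_clusters = 0), seed = 1)
  expect_equal(nrow(s0), 0L)
  expect_true(all(cols %in% names(s0)))
})

test_that("generated responses recover the configured correlation structure", {
  # constant-parameter configuration: correlations straight from base_rho
  cfg <- synth_config(n_clusters = 2000, children_per_cluster = c(25, 25),
                      age_amp = c(mu_hb = 0, mu_haz = 0, mu_waz = 0, mu_whz = 0),
                      spatial_amp = c(mu_hb = 0, mu_haz = 0))
  sv <- simulate_survey(cfg, seed = 21)
  expect_gte(nrow(sv), 50000)
  emp <- cor(.y <- as.matrix(sv[, c("hb", "haz", "waz", "whz")]))
  expect_equal(emp["waz", "whz"], 0.70, tolerance = 0.02)
  expect_equal(emp["haz", "waz"], 0.68, tolerance = 0.02)
  expect_equal(cov(.y), unname(cfg$base_sigma), tolerance = 0.05, ignore_attr = TRUE)

  # WHO-plausibility guard at default scales
  sv2 <- simulate_survey(synth_config(n_clusters = 300), seed = 22)
  expect_true(all(sv2$hb > 0))
  expect_true(all(abs(sv2[, c("haz", "waz", "whz")]) < 6))

  # per-child truth is attached and matches a direct truth evaluation
  tr <- attr(sv2, "truth")
  tp <- true_parameters(synth_config(n_clusters = 300), sv2)
  expect_equal(tr$mu, tp$mu)
  expect_equal(tr$rho, tp$rho)
})
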