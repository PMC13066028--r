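# one small fitted pipeline model shared by the surface tests: constant
# parameters (intercept-only truth and spec), short chain
local_flat_model <- local({
  model <- NULL
  function() {
    if (is.null(model)) {
      cfg <- synth_config(n_clusters = 40, children_per_cluster = c(10, 12),
                          age_amp = c(mu_hb = 0, mu_haz = 0, mu_waz = 0, mu_whz = 0),
                          spatial_amp = c(mu_hb = 0, mu_haz = 0))
      sv <- simulate_survey(cfg, seed = 31)
      model <<- mvdr(sv, mvdr_spec(), mcmc_iter = 300, burn_in = 100, thin = 4,
                     seed = 7)
      attr(model, "survey") <<- sv
    }
    model
  }
})

test_that("indicator definitions encode the clinical thresholds", {
  ind <- indicator_definitions()
  expect_equal(ind$name, c("anemia", "stunting", "underweight", "wasting",
                           "overweight"))
  expect_equal(ind$response, c("hb", "haz", "waz", "whz", "waz"))
  expect_equal(ind$cut, c(110, -2, -2, -2, 2))
  expect_equal(ind$tail, c(rep("below", 4), "above"))
  # the overweight indicator is configurable to weight-for-height
  ind2 <- indicator_definitions(overweight_on = "whz")
  expect_equal(ind2$response[5], "whz")
})

test_that("pixel masking applies exactly the three exclusion rules", {
  grid <- data.frame(
    pixel = 1:6,
    lon = 0, lat = 0,
    landcover = c("Cropland", "Barren", "Permanent Snow and Ice", "Forest",
                  "Savanna", "Cropland"),
    elevation = c(500, 100, 2800, 3200, 3000, NA))
  g <- mask_pixels(grid)
  expect_equal(as.character(g$mask),
               c("ok", "barren", "snow_ice", "elevation_gt_3000", "ok",
                 "missing"))
  # exactly 3000 m is not excluded (strictly above)
  expect_equal(as.character(g$mask[5]), "ok")
})

test_that("a covariate-free fit yields spatially constant, bounded surfaces", {
  m <- local_flat_model()
  grid <- prediction_grid(attr(attr(m, "survey"), "fields"), step = 1.5)
  grid <- mask_pixels(grid)
  surf <- predict_grid(m, grid, at = list(age = 24))
  expect_setequal(unique(surf$quantity),
                  c("anemia", "stunting", "underweight", "wasting",
                    "overweight", cor_labels()))
  ok <- surf$mask == "ok"
  expect_true(all(is.na(surf$mean[!ok])))
  # constant across pixels for every quantity
  sp <- split(surf$mean[ok], surf$quantity[ok])
  for (v in sp) expect_lt(diff(range(v)), 1e-10)
  # prevalences in [0,1]; intervals ordered
  prev <- surf[ok & surf$quantity %in% indicator_definitions()$name, ]
  expect_true(all(prev$mean >= 0 & prev$mean <= 1))
  expect_true(all(prev$lower95 <= prev$mean + 1e-12 &
                  prev$mean <= prev$upper95 + 1e-12))
  # correlations bounded in [-1, 1]
  corr <- surf[ok & surf$quantity %in% cor_labels(), ]
  expect_true(all(corr$mean >= -1 & corr$mean <= 1))
  expect_true(all(corr$lower95 >= -1 & corr$upper95 <= 1))
  # P(waz < -2) + P(waz > 2) <= 1 pixelwise
  uw <- prev$mean[prev$quantity == "underweight"]
  ow <- prev$mean[prev$quantity == "overweight"]
  expect_true(all(uw + ow <= 1))
})

test_that("correlation surfaces stay bounded for every posterior draw", {
  m <- local_flat_model()
  fit <- m$fit
  grid <- data.frame(age = 24, lon = c(-5, 0, 5), lat = c(0, 2, -3))
  for (d in seq_len(nrow(fit$samples))) {
    eta <- mvdreg:::.eval_eta(fit$designs, grid, mvdreg:::.coefs_from_draw(fit, d))
    rho <- mvdreg:::.par_moments(mvdreg:::.eta_to_par(eta))$rho
    expect_true(all(rho >= -1 & rho <= 1))
  }
})

test_that("prevalence is monotone in the threshold", {
  m <- local_flat_model()
  nd <- data.frame(age = c(12, 24, 48), lon = 0, lat = 0)
  cuts <- c(100, 110, 120)
  prev <- sapply(cuts, function(cc)
    predict(m, nd, type = "prevalence",
            indicators = indicator_definitions(anemia_cut = cc))[, "anemia"])
  expect_true(all(diff(t(prev)) >= 0))
})

test_that("age profiles fix covariates at within-buffer medians and modes", {
  m <- local_flat_model()
  sv <- attr(m, "survey")
  loc <- c(sv$lon[1], sv$lat[1])
  prof <- age_profile(m, loc[1], loc[2], buffer_km = 50, ages = c(12, 36))
  at <- attr(prof, "at")
  # brute-force recomputation on the buffered subset
  d_km <- geosphere::distHaversine(cbind(sv$lon, sv$lat), loc) / 1000
  sub <- sv[d_km <= 50, ]
  expect_gt(nrow(sub), 0)
  expect_equal(at$temperature, median(sub$temperature))
  expect_equal(at$elevation, median(sub$elevation))
  tab <- table(as.character(sub$wealth_index))
  expect_equal(as.character(at$wealth_index),
               sort(names(tab)[tab == max(tab)])[1])
  expect_equal(attr(prof, "n_buffer"), nrow(sub))
  expect_setequal(unique(prof$quantity),
                  c(indicator_definitions()$name, cor_labels()))

  # empty buffer errors with advice
  expect_error(age_profile(m, 9.95, 9.95, buffer_km = 1), "buffer")
})

test_that("a declining anemia-age truth yields a declining fitted age curve", {
  cfg <- synth_config(n_clusters = 60, children_per_cluster = c(18, 22),
                      age_amp = c(mu_hb = 12, mu_haz = 0, mu_waz = 0, mu_whz = 0),
                      spatial_amp = c(mu_hb = 0, mu_haz = 0))
  sv <- simulate_survey(cfg, seed = 33)
  m <- mvdr(sv, mvdr_spec(mu_hb = term_pspline("age", k = 10)),
            boost_iter = 80, mcmc_iter = 500, burn_in = 200, thin = 5, seed = 8)
  prof <- age_profile(m, 0, 0, buffer_km = 2000, ages = seq(8, 57, by = 7),
                      summaries = FALSE)
  an <- prof$mean[prof$quantity == "anemia"]
  # monotone decline of the truth; allow small wiggle in the estimate
  expect_lt(an[length(an)], an[1] - 0.05)
  expect_true(all(diff(an) < 0.03))
})
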