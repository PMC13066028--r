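# Synthetic DHS-like survey generator.  Emulates the statistical structure the
# joint model assumes -- clustered spatial sampling, covariate-dependent means
# and covariances of the (Hb, HAZ, WAZ, WHZ) vector, nonlinear age effects and
# smooth environmental fields -- so every pipeline stage can be exercised and
# scored against known truth without restricted survey data.

#' Configuration of the synthetic survey generator
#'
#' Defaults encode the study conditions the package is exercised under: a
#' sub-Saharan-like survey of children aged 6-59 months with base pairwise
#' correlations rho(HAZ,WAZ) = 0.68, rho(WAZ,WHZ) = 0.70, a weakly negative
#' rho(HAZ,WHZ) and small Hb-anthropometry correlations; age effects under
#' which anemia and wasting decline with age while stunting rises and
#' plateaus around month 36; and smooth spatial effects on Hb and HAZ.
#'
#' @param n_clusters Number of survey clusters (PSUs).
#' @param children_per_cluster Length-2 integer range of children per cluster
#'   (drawn uniformly), approximating DHS PSU sizes.
#' @param bbox List with \code{lon} and \code{lat} ranges (decimal degrees).
#' @param years Interview-year range.
#' @param age_range Child age range in months (fixed at 6-59 by the design).
#' @param base_mu Baseline means of (hb, haz, waz, whz); hb in g/L.
#' @param base_sd Baseline marginal standard deviations.
#' @param base_rho Baseline pairwise correlations in the order of
#'   \code{\link{cor_labels}}.
#' @param age_amp Named amplitudes of the default age effects on the means
#'   (units of the response).
#' @param spatial_amp Named amplitudes of the default sinusoidal spatial
#'   effects on distributional parameters.
#' @param effects Optional list overriding the constructed effect list: per
#'   parameter label, a list of \code{list(covariate =, fun =)} entries where
#'   \code{covariate} is a column name or \code{"spatial"} (then \code{fun}
#'   takes \code{lon, lat}).
#' @param field_amp Amplitude of the random-cosine environmental fields
#'   (0 makes all environmental covariates spatially constant).
#' @param field_range Correlation range of the fields as a fraction of the
#'   bounding-box span.
#' @param landcover_props Named proportions of land-cover classes; must
#'   include \code{"Barren"} and \code{"Permanent Snow and Ice"}.
#' @param elev_mean Mean elevation (m).
#' @param elev_exceed Target fraction of locations above 3000 m.
#' @param thresholds Clinical thresholds: anemia cut (g/L) and z-score cut.
#' @return An object of class \code{"synth_config"}.
#' @export
synth_config <- function(n_clusters = 250,
                         children_per_cluster = c(15, 30),
                         bbox = list(lon = c(-10, 10), lat = c(-10, 10)),
                         years = c(2015, 2020),
                         age_range = c(6, 59),
                         base_mu = c(hb = 105, haz = -1.4, waz = -0.9, whz = -0.3),
                         base_sd = c(hb = 15, haz = 1.3, waz = 1.2, whz = 1.1),
                         base_rho = c(cor_hb_haz = 0.10, cor_hb_waz = 0.15,
                                      cor_haz_waz = 0.68, cor_hb_whz = 0.08,
                                      cor_haz_whz = -0.03, cor_waz_whz = 0.70),
                         age_amp = c(mu_hb = 8, mu_haz = -0.9, mu_waz = 0.3,
                                     mu_whz = 0.5),
                         spatial_amp = c(mu_hb = 4, mu_haz = 0.4),
                         effects = NULL,
                         field_amp = 1,
                         field_range = 0.3,
                         landcover_props = c(Cropland = 0.40, Savanna = 0.36,
                                             Forest = 0.20, Barren = 0.03,
                                             "Permanent Snow and Ice" = 0.01),
                         elev_mean = 800,
                         elev_exceed = 0.02,
                         thresholds = list(anemia = 110, z = 2)) {
  stopifnot(length(children_per_cluster) == 2L,
            age_range[1] >= 6, age_range[2] <= 59,
            abs(sum(landcover_props) - 1) < 1e-8,
            all(c("Barren", "Permanent Snow and Ice") %in% names(landcover_props)))
  rho <- diag(4)
  idx <- .phi_index()
  rho[idx] <- base_rho[cor_labels()]
  rho[idx[, c(2, 1)]] <- base_rho[cor_labels()]
  base_sigma <- diag(base_sd) %*% rho %*% diag(base_sd)
  dimnames(base_sigma) <- list(response_names(), response_names())
  ev <- eigen(base_sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("'base_rho'/'base_sd' do not define a positive definite covariance")
  cfg <- structure(list(
    n_clusters = n_clusters, children_per_cluster = children_per_cluster,
    bbox = bbox, years = years, age_range = age_range,
    base_mu = base_mu, base_sd = base_sd, base_rho = base_rho,
    base_sigma = base_sigma, field_amp = field_amp, field_range = field_range,
    landcover_props = landcover_props, elev_mean = elev_mean,
    elev_exceed = elev_exceed, thresholds = thresholds),
    class = "synth_config")
  cfg$effects <- if (is.null(effects))
    .default_effects(age_amp, spatial_amp, age_range, bbox) else effects
  cfg
}

# default effect list: centered age curves (so base_mu stays the population
# mean) plus centered sinusoidal spatial surfaces
.default_effects <- function(age_amp, spatial_amp, age_range, bbox) {
  centered_age <- function(f) {
    grid <- seq(age_range[1], age_range[2], length.out = 400)
    m <- mean(f(grid))
    function(a) f(a) - m
  }
  shapes <- list(
    # Hb rises with age (anemia declines, steepest early in life)
    mu_hb  = function(a) sqrt((a - 6) / 53),
    # HAZ declines up to month 36, then plateaus (stunting rises then levels)
    mu_haz = function(a) pmin((a - 6) / 30, 1),
    # WAZ and WHZ improve roughly linearly with age (wasting declines)
    mu_waz = function(a) (a - 6) / 53,
    mu_whz = function(a) (a - 6) / 53)
  eff <- list()
  for (p in names(age_amp)) {
    if (is.null(shapes[[p]]) || age_amp[[p]] == 0) next
    amp <- age_amp[[p]]; f <- shapes[[p]]
    eff[[p]] <- c(eff[[p]], list(list(
      covariate = "age",
      fun = centered_age(local({a1 <- amp; f1 <- f; function(a) a1 * f1(a)})))))
  }
  Lx <- diff(bbox$lon); Ly <- diff(bbox$lat)
  x0 <- mean(bbox$lon); y0 <- mean(bbox$lat)
  for (p in names(spatial_amp)) {
    if (spatial_amp[[p]] == 0) next
    amp <- spatial_amp[[p]]
    eff[[p]] <- c(eff[[p]], list(list(
      covariate = "spatial",
      fun = local({a1 <- amp
        function(lon, lat) a1 * sin(2 * pi * (lon - x0) / Lx) *
                                cos(2 * pi * (lat - y0) / Ly)}))))
  }
  eff
}

#' @export
print.synth_config <- function(x, ...) {
  cat("Synthetic survey configuration\n")
  cat(sprintf("  %d clusters of %d-%d children, ages %d-%d months\n",
              x$n_clusters, x$children_per_cluster[1], x$children_per_cluster[2],
              x$age_range[1], x$age_range[2]))
  cat("  base correlations:",
      paste(sprintf("%s=%.2f", sub("cor_", "", cor_labels()),
                    x$base_rho[cor_labels()]), collapse = ", "), "\n")
  cat("  effects on:", paste(names(x$effects), collapse = ", "), "\n")
  invisible(x)
}

## ---------------------------------------------------------------------------
## Environmental covariate fields (low-rank random-cosine expansions)
## ---------------------------------------------------------------------------

# one smooth mean-zero, roughly unit-variance Gaussian-process-like field
.draw_field <- function(range_x, range_y, n_waves = 60) {
  list(omega = cbind(stats::rnorm(n_waves, sd = 1 / range_x),
                     stats::rnorm(n_waves, sd = 1 / range_y)),
       phase = stats::runif(n_waves, 0, 2 * pi),
       n_waves = n_waves)
}

.eval_field <- function(fld, lon, lat) {
  arg <- outer(lon, fld$omega[, 1]) + outer(lat, fld$omega[, 2])
  arg <- sweep(arg, 2L, fld$phase, "+")
  sqrt(2 / fld$n_waves) * rowSums(cos(arg))
}

#' Draw a realisation of the environmental covariate fields
#'
#' Environmental covariates are smooth spatial fields built from a fixed
#' low-rank random-cosine expansion (a fast stand-in for Gaussian-process
#' simulation): surface temperature, malaria incidence, elevation, a spatially
#' correlated land-cover class (including \code{"Barren"} and
#' \code{"Permanent Snow and Ice"}) and a wealth quintile with a west-east
#' gradient.  The realisation can be evaluated at any coordinates via
#' \code{eval_fields}, so cluster sites and prediction-grid pixels see the
#' same surfaces.
#'
#' @param config A \code{\link{synth_config}}.
#' @param seed Optional integer seed.
#' @return An object of class \code{"synth_fields"}.
#' @export
covariate_fields <- function(config, seed = NULL) {
  stopifnot(inherits(config, "synth_config"))
  if (!is.null(seed)) set.seed(seed)
  rx <- config$field_range * diff(config$bbox$lon)
  ry <- config$field_range * diff(config$bbox$lat)
  fl <- structure(list(
    temperature = .draw_field(rx, ry),
    malaria = .draw_field(rx, ry),
    elevation = .draw_field(rx, ry),
    landcover = .draw_field(rx, ry),
    wealth = .draw_field(rx, ry),
    config = config), class = "synth_fields")
  # freeze wealth-quintile cutpoints on a dense reference sample so the
  # realised fields are pure functions of location
  lon0 <- stats::runif(2000, config$bbox$lon[1], config$bbox$lon[2])
  lat0 <- stats::runif(2000, config$bbox$lat[1], config$bbox$lat[2])
  wl <- .wealth_latent(fl, lon0, lat0)
  fl$wealth_cuts <- if (stats::sd(wl) < 1e-12) c(-Inf, -Inf, Inf, Inf) else
    stats::quantile(wl, probs = seq(0.2, 0.8, 0.2), names = FALSE)
  fl
}

.wealth_latent <- function(fields, lon, lat) {
  cfg <- fields$config
  2 * (lon - mean(cfg$bbox$lon)) / max(diff(cfg$bbox$lon), 1e-9) +
    0.8 * cfg$field_amp * .eval_field(fields$wealth, lon, lat)
}

#' @rdname covariate_fields
#' @param fields A \code{"synth_fields"} realisation.
#' @param lon,lat Coordinates at which to evaluate the fields.
#' @return \code{eval_fields}: data frame with columns \code{temperature}
#'   (deg C), \code{malaria} (incidence, 0-1), \code{elevation} (m),
#'   \code{landcover} (factor) and \code{wealth_index} (factor, 5 quintiles).
#' @export
eval_fields <- function(fields, lon, lat) {
  stopifnot(inherits(fields, "synth_fields"))
  cfg <- fields$config
  amp <- cfg$field_amp
  n <- length(lon)
  g <- function(name) amp * .eval_field(fields[[name]], lon, lat)
  temperature <- 25 + 4 * g("temperature")
  malaria <- stats::plogis(-1 + 1.5 * g("malaria"))
  elev_sd <- if (cfg$elev_exceed > 0 && amp > 0)
    (3000 - cfg$elev_mean) / stats::qnorm(1 - cfg$elev_exceed) else 700
  elevation <- pmax(0, cfg$elev_mean + elev_sd * g("elevation"))
  # spatially correlated categorical field: latent Gaussian cut at the
  # configured class proportions (constant latent -> single class)
  props <- cfg$landcover_props
  cuts <- stats::qnorm(cumsum(props))
  lc_latent <- g("landcover")
  landcover <- factor(names(props)[1 + rowSums(outer(lc_latent, cuts[-length(cuts)], ">"))],
                      levels = names(props))
  # wealth: ordered quintiles with a deterministic west-east gradient,
  # cutpoints frozen in the field realisation
  wl <- .wealth_latent(fields, lon, lat)
  qs <- fields$wealth_cuts
  wealth_index <- factor(paste0("q", 1:5)[1 + rowSums(outer(wl, qs, ">"))],
                         levels = paste0("q", 1:5))
  data.frame(temperature = temperature, malaria = malaria,
             elevation = elevation, landcover = landcover,
             wealth_index = wealth_index)
}

#' Simulate cluster-level environmental covariates
#'
#' Draws cluster sites uniformly inside the bounding box and evaluates a fresh
#' realisation of the covariate fields at those sites.
#'
#' @inheritParams covariate_fields
#' @return Data frame with one row per cluster: \code{cluster}, \code{lon},
#'   \code{lat} and the environmental covariates, with the field realisation
#'   attached as attribute \code{"fields"}.
#' @export
simulate_covariate_fields <- function(config, seed = NULL) {
  stopifnot(inherits(config, "synth_config"))
  if (diff(config$bbox$lon) <= 0 || diff(config$bbox$lat) <= 0)
    stop("empty bounding box")
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_clusters
  lon <- stats::runif(n, config$bbox$lon[1], config$bbox$lon[2])
  lat <- stats::runif(n, config$bbox$lat[1], config$bbox$lat[2])
  fields <- covariate_fields(config)
  out <- cbind(data.frame(cluster = seq_len(n), lon = lon, lat = lat),
               eval_fields(fields, lon, lat))
  attr(out, "fields") <- fields
  out
}

## ---------------------------------------------------------------------------
## Truth evaluation and survey simulation
## ---------------------------------------------------------------------------

#' True distributional parameters of the generator at given covariates
#'
#' Evaluates the configured truth -- baseline intercepts (from the base mean
#' vector and the modified Cholesky factors of the base covariance) plus all
#' configured covariate effects -- for each row of \code{data}, and returns
#' the implied per-row means, standard deviations, correlations and
#' prevalence-relevant parameters.
#'
#' @param config A \code{\link{synth_config}}.
#' @param data Data frame with the covariate columns referenced by the
#'   configured effects (always \code{lon}, \code{lat}; \code{age} for the
#'   default age effects).
#' @return List with \code{eta} (n x 14), \code{mu}, \code{sd} (n x 4) and
#'   \code{rho} (n x 6).
#' @export
true_parameters <- function(config, data) {
  stopifnot(inherits(config, "synth_config"))
  n <- nrow(data)
  f0 <- sigma_to_factors(config$base_sigma)
  theta <- c(config$base_mu, f0$lam, f0$phi[.phi_index()])
  eta <- matrix(theta, n, 14L, byrow = TRUE, dimnames = list(NULL, par_labels()))
  for (p in names(config$effects)) {
    for (ef in config$effects[[p]]) {
      add <- if (identical(ef$covariate, "spatial")) {
        ef$fun(data$lon, data$lat)
      } else {
        x <- data[[ef$covariate]]
        if (is.null(x)) stop("effect covariate missing from data: ", ef$covariate)
        ef$fun(x)
      }
      eta[, p] <- eta[, p] + add
    }
  }
  par <- .eta_to_par(eta)
  mom <- .par_moments(par)
  list(eta = eta, mu = par$mu, sd = mom$sd, rho = mom$rho, par = par)
}

#' Simulate a child-level survey
#'
#' Places children in clusters, draws ages, sex, interview year and
#' environmental covariates, evaluates the configured truth for all 14
#' distributional parameters, and draws the (Hb, HAZ, WAZ, WHZ) response
#' vector from the implied multivariate Gaussian.  The per-child truth
#' (means, standard deviations, correlations) is attached for recovery
#' testing.
#'
#' @inheritParams covariate_fields
#' @return Data frame with one row per child: \code{child}, \code{cluster},
#'   \code{lon}, \code{lat}, \code{age} (months), \code{sex},
#'   \code{wealth_index}, \code{year}, environmental covariates, and
#'   responses \code{hb} (g/L), \code{haz}, \code{waz}, \code{whz}.
#'   Attributes: \code{"truth"} (list from \code{\link{true_parameters}}),
#'   \code{"fields"} (the covariate-field realisation) and \code{"config"}.
#' @examples
#' cfg <- synth_config(n_clusters = 20, children_per_cluster = c(5, 8))
#' sv <- simulate_survey(cfg, seed = 1)
#' head(sv)
#' @export
simulate_survey <- function(config, seed = NULL) {
  stopifnot(inherits(config, "synth_config"))
  if (!is.null(seed)) set.seed(seed)
  clusters <- simulate_covariate_fields(config)
  fields <- attr(clusters, "fields")
  if (config$n_clusters == 0L) {
    empty <- data.frame(child = integer(), cluster = integer(), lon = numeric(),
                        lat = numeric(), age = integer(),
                        sex = factor(character(), levels = c("female", "male")),
                        wealth_index = factor(character(), levels = paste0("q", 1:5)),
                        year = integer(), temperature = numeric(),
                        malaria = numeric(), elevation = numeric(),
                        landcover = factor(character(),
                                           levels = names(config$landcover_props)),
                        hb = numeric(), haz = numeric(), waz = numeric(),
                        whz = numeric())
    attr(empty, "config") <- config
    return(empty)
  }
  runifint <- function(n, lo, hi) lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
  sizes <- runifint(config$n_clusters, config$children_per_cluster[1],
                    config$children_per_cluster[2])
  ci <- rep.int(seq_len(config$n_clusters), sizes)
  n <- length(ci)
  d <- data.frame(child = seq_len(n), cluster = ci,
                  lon = clusters$lon[ci], lat = clusters$lat[ci],
                  age = runifint(n, config$age_range[1], config$age_range[2]),
                  sex = factor(sample(c("female", "male"), n, replace = TRUE)),
                  wealth_index = clusters$wealth_index[ci],
                  year = runifint(n, config$years[1], config$years[2]),
                  temperature = clusters$temperature[ci],
                  malaria = clusters$malaria[ci],
                  elevation = clusters$elevation[ci],
                  landcover = clusters$landcover[ci])
  truth <- true_parameters(config, d)
  y <- .sample_rows(truth$par)
  # WHO-plausibility guard: redraw the rare rows (Gaussian tail mass ~1e-3 at
  # default scales) with non-positive Hb or |z| >= 6, i.e. mild truncation
  for (it in 1:25) {
    bad <- which(y[, 1L] <= 0 | rowSums(abs(y[, 2:4, drop = FALSE]) >= 6) > 0)
    if (!length(bad)) break
    sub <- list(mu = truth$par$mu[bad, , drop = FALSE],
                lam = truth$par$lam[bad, , drop = FALSE],
                phi = truth$par$phi[bad, , drop = FALSE])
    y[bad, ] <- .sample_rows(sub)
  }
  d$hb <- y[, "hb"]; d$haz <- y[, "haz"]; d$waz <- y[, "waz"]; d$whz <- y[, "whz"]
  attr(d, "truth") <- truth
  attr(d, "fields") <- fields
  attr(d, "config") <- config
  d
}

# response matrix from an observation table
.response_matrix <- function(data) {
  y <- as.matrix(data[, response_names()])
  if (!all(is.finite(y))) stop("non-finite responses")
  y
}
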