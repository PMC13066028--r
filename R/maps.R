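# Deliverables of a fitted model: gridded prevalence and pairwise-correlation
# surfaces with the standard pixel masking, and age profiles at buffered
# locations with covariates fixed at local medians/modes.

#' Clinical indicator definitions
#'
#' The five prevalence indicators derived from the fitted Gaussian marginals:
#' anemia P(Hb < 110 g/L), stunting P(HAZ < -2), underweight P(WAZ < -2),
#' wasting P(WHZ < -2) and overweight.  Overweight defaults to P(WAZ > 2);
#' the WHO weight-for-height convention P(WHZ > 2) is available via
#' \code{overweight_on = "whz"}.
#'
#' @param overweight_on Response carrying the overweight indicator
#'   (\code{"waz"} default or \code{"whz"}).
#' @param anemia_cut Anemia threshold in g/L (110 for children 6-59 months;
#'   altitude/age/sex adjustments are assumed applied upstream to Hb).
#' @param z_cut Absolute z-score threshold (2).
#' @return Data frame with columns \code{name}, \code{response}, \code{cut},
#'   \code{tail}.
#' @export
indicator_definitions <- function(overweight_on = c("waz", "whz"),
                                  anemia_cut = 110, z_cut = 2) {
  overweight_on <- match.arg(overweight_on)
  data.frame(
    name = c("anemia", "stunting", "underweight", "wasting", "overweight"),
    response = c("hb", "haz", "waz", "whz", overweight_on),
    cut = c(anemia_cut, -z_cut, -z_cut, -z_cut, z_cut),
    tail = c("below", "below", "below", "below", "above"))
}

#' Build a regular prediction grid over the survey region
#'
#' Pixel centers on a regular step of 0.18 degrees (about 20 km at the
#' equator) spanning the bounding box, with environmental covariates
#' evaluated from a covariate-field realisation (see
#' \code{\link{covariate_fields}}).  An equal-area grid is deliberately not
#' attempted; the regular-degree step is an approximation.
#'
#' @param fields A \code{"synth_fields"} realisation (e.g. the
#'   \code{"fields"} attribute of a simulated survey).
#' @param step Pixel step in degrees (default 0.18).
#' @return Data frame of class \code{"mvdr_grid"}: \code{pixel}, \code{lon},
#'   \code{lat} and the environmental covariates per pixel.
#' @export
prediction_grid <- function(fields, step = 0.18) {
  stopifnot(inherits(fields, "synth_fields"))
  bbox <- fields$config$bbox
  lon <- seq(bbox$lon[1] + step / 2, bbox$lon[2], by = step)
  lat <- seq(bbox$lat[1] + step / 2, bbox$lat[2], by = step)
  g <- expand.grid(lon = lon, lat = lat)
  out <- cbind(data.frame(pixel = seq_len(nrow(g))), g,
               eval_fields(fields, g$lon, g$lat))
  class(out) <- c("mvdr_grid", "data.frame")
  out
}

#' Flag pixels excluded from prediction surfaces
#'
#' Applies the standard masking rules: land cover \code{"Barren"} or
#' \code{"Permanent Snow and Ice"}, and elevation above 3000 m, are flagged
#' as not included; pixels with missing elevation get a distinct
#' missing-data flag.
#'
#' @param grid A prediction grid with \code{landcover} and \code{elevation}
#'   columns.
#' @param barren_classes Land-cover classes to mask.
#' @param elevation_limit Mask elevations strictly above this value (m).
#' @return The grid with a \code{mask} factor column: \code{"ok"},
#'   \code{"barren"}, \code{"snow_ice"}, \code{"elevation_gt_3000"} or
#'   \code{"missing"}.
#' @export
mask_pixels <- function(grid, barren_classes = c("Barren",
                                                 "Permanent Snow and Ice"),
                        elevation_limit = 3000) {
  stopifnot(all(c("landcover", "elevation") %in% names(grid)))
  lc <- as.character(grid$landcover)
  mask <- rep("ok", nrow(grid))
  mask[grid$elevation > elevation_limit] <- "elevation_gt_3000"
  mask[lc == "Permanent Snow and Ice"] <- "snow_ice"
  mask[lc == "Barren"] <- "barren"
  mask[is.na(grid$elevation) | is.na(lc)] <- "missing"
  grid$mask <- factor(mask, levels = c("ok", "barren", "snow_ice",
                                       "elevation_gt_3000", "missing"))
  grid
}

#' Prevalence and correlation surfaces on a prediction grid
#'
#' Evaluates all 14 additive predictors at every unmasked pixel (age, year
#' and any further non-grid covariates held fixed), reconstructs the joint
#' distribution, and derives the five indicator prevalences and six pairwise
#' correlations with posterior means and equal-tailed 95% credible intervals
#' over the stored MCMC draws.
#'
#' @param fit A fitted \code{\link{mvdr}} model.
#' @param grid A (masked) prediction grid; \code{\link{mask_pixels}} is
#'   applied if no \code{mask} column is present.
#' @param at Named list of covariate values held fixed across pixels
#'   (e.g. \code{list(age = 24, year = 2020, sex = "female")}); must cover
#'   every model covariate not on the grid.
#' @param indicators See \code{\link{indicator_definitions}}.
#' @param summaries Posterior summaries over draws (default TRUE); otherwise
#'   point surfaces from posterior-mean coefficients.
#' @return Long data frame: \code{pixel}, \code{lon}, \code{lat},
#'   \code{quantity} (indicator or correlation name), \code{mean},
#'   \code{lower95}, \code{upper95} (NA unless \code{summaries}) and
#'   \code{mask}; masked pixels carry NA values.
#' @export
predict_grid <- function(fit, grid, at = list(),
                         indicators = indicator_definitions(),
                         summaries = TRUE) {
  stopifnot(inherits(fit, "mvdr"))
  if (!"mask" %in% names(grid)) grid <- mask_pixels(grid)
  ok <- grid$mask == "ok"
  nd <- grid[ok, , drop = FALSE]
  for (nm in names(at)) nd[[nm]] <- at[[nm]]
  quantities <- c(indicators$name, cor_labels())
  prev <- predict(fit, nd, type = "prevalence", indicators = indicators,
                  summaries = summaries)
  corr <- predict(fit, nd, type = "correlation", summaries = summaries)
  n_ok <- sum(ok)
  if (summaries) {
    comb <- rbind(prev, corr)
    m <- matrix(NA_real_, nrow(grid), length(quantities))
    lo <- hi <- m
    qi <- match(comb$quantity, quantities)
    m[cbind(which(ok)[comb$row], qi)] <- comb$mean
    lo[cbind(which(ok)[comb$row], qi)] <- comb$lower95
    hi[cbind(which(ok)[comb$row], qi)] <- comb$upper95
  } else {
    m <- matrix(NA_real_, nrow(grid), length(quantities))
    m[ok, ] <- cbind(prev, corr)
    lo <- hi <- matrix(NA_real_, nrow(grid), length(quantities))
  }
  data.frame(
    pixel = rep(grid$pixel, times = length(quantities)),
    lon = rep(grid$lon, times = length(quantities)),
    lat = rep(grid$lat, times = length(quantities)),
    quantity = rep(quantities, each = nrow(grid)),
    mean = as.vector(m), lower95 = as.vector(lo), upper95 = as.vector(hi),
    mask = rep(grid$mask, times = length(quantities)))
}

#' Age profiles of prevalence and correlation at a location
#'
#' Varies child age over a grid while fixing every other numeric covariate at
#' the median -- and every categorical covariate at the mode (ties broken by
#' the first sorted level) -- observed among survey children within a
#' great-circle buffer around the location, then evaluates the five indicator
#' prevalences and six pairwise correlations.
#'
#' @param fit A fitted \code{\link{mvdr}}.
#' @param lon,lat Location (decimal degrees).
#' @param survey Observation table supplying the within-buffer covariates;
#'   defaults to the model's training data.
#' @param buffer_km Buffer radius in kilometers (default 20, haversine).
#' @param ages Age grid in months.
#' @param indicators See \code{\link{indicator_definitions}}.
#' @param summaries Posterior summaries over draws (default TRUE).
#' @return Long data frame: \code{age}, \code{quantity}, \code{mean},
#'   \code{lower95}, \code{upper95}; the fixed covariate row is attached as
#'   attribute \code{"at"}, the buffer size as \code{"n_buffer"}.
#' @export
age_profile <- function(fit, lon, lat, survey = NULL, buffer_km = 20,
                        ages = 6:59, indicators = indicator_definitions(),
                        summaries = TRUE) {
  stopifnot(inherits(fit, "mvdr"))
  if (is.null(survey)) survey <- fit$data[fit$train_idx, , drop = FALSE]
  dist_km <- geosphere::distHaversine(cbind(survey$lon, survey$lat),
                                      c(lon, lat)) / 1000
  inside <- which(dist_km <= buffer_km)
  if (!length(inside))
    stop("no survey observations within ", buffer_km,
         " km of the location; increase the buffer")
  sub <- survey[inside, , drop = FALSE]
  fixed <- lapply(names(sub), function(nm) {
    x <- sub[[nm]]
    if (is.numeric(x)) stats::median(x)
    else {
      tab <- table(x)
      nm_lev <- sort(names(tab)[tab == max(tab)])[1]  # tie -> first sorted level
      factor(nm_lev, levels = levels(factor(x)))
    }
  })
  names(fixed) <- names(sub)
  nd <- data.frame(fixed, check.names = FALSE)[rep(1, length(ages)), , drop = FALSE]
  nd$age <- ages
  nd$lon <- lon; nd$lat <- lat
  prev <- predict(fit, nd, type = "prevalence", indicators = indicators,
                  summaries = summaries)
  corr <- predict(fit, nd, type = "correlation", summaries = summaries)
  if (summaries) {
    comb <- rbind(prev, corr)
    out <- data.frame(age = ages[comb$row], quantity = comb$quantity,
                      mean = comb$mean, lower95 = comb$lower95,
                      upper95 = comb$upper95)
  } else {
    q <- cbind(prev, corr)
    out <- data.frame(age = rep(ages, times = ncol(q)),
                      quantity = rep(colnames(q), each = length(ages)),
                      mean = as.vector(q), lower95 = NA_real_,
                      upper95 = NA_real_)
  }
  attr(out, "at") <- nd[1, setdiff(names(nd), "age"), drop = FALSE]
  attr(out, "n_buffer") <- length(inside)
  out
}
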