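# The user-facing model fit: one function running the staged modelling
# approach -- spatial 80/20 split, intercept-only baseline, boosting-based
# term selection, pruning, MCMC estimation, held-out validation -- and
# returning a classed object with the usual methods.

#' Fit a multivariate Gaussian distributional regression for malnutrition
#' indicators
#'
#' Runs the full staged analysis on a child-level survey: (i) a spatially
#' representative cluster-level train/test split via Delaunay triangulation;
#' (ii) an intercept-only baseline fit; (iii) componentwise gradient boosting
#' over the candidate terms of all 14 distributional parameters; (iv) pruning
#' of uninformative terms and Bayesian MCMC estimation of the final model;
#' (v) held-out validation of the joint log-score against the baseline.
#'
#' @param data Child-level observation table: responses \code{hb}, \code{haz},
#'   \code{waz}, \code{whz}, a \code{cluster} column, coordinates \code{lon},
#'   \code{lat}, and all covariates used by \code{spec}.
#' @param spec Candidate \code{\link{mvdr_spec}}; defaults to intercept-only
#'   (no selection stage needed).
#' @param frac_train Training fraction of the cluster-level split.
#' @param boost_iter Boosting iteration budget for term selection.
#' @param prune_threshold Minimum selection frequency for a term to enter the
#'   final model.
#' @param mcmc_iter,burn_in,thin MCMC settings of the final fit.
#' @param seed Integer seed controlling every stochastic stage.
#' @param verbose Report stage progress.
#' @return An object of class \code{"mvdr"}; see
#'   \code{\link{predict.mvdr}}, \code{\link{residuals.mvdr}},
#'   \code{\link{simulate.mvdr}}, \code{summary}, \code{coef}, \code{plot}.
#' @examples
#' \donttest{
#' cfg <- synth_config(n_clusters = 40, children_per_cluster = c(10, 15))
#' sv <- simulate_survey(cfg, seed = 1)
#' m <- mvdr(sv, mvdr_spec(mu_haz = term_pspline("age", k = 8)),
#'           boost_iter = 50, mcmc_iter = 300, burn_in = 100, thin = 4, seed = 1)
#' print(m)
#' }
#' @export
mvdr <- function(data, spec = mvdr_spec(), frac_train = 0.8,
                 boost_iter = 300, prune_threshold = 0.05,
                 mcmc_iter = 1500, burn_in = 500, thin = 5,
                 seed = NULL, verbose = FALSE) {
  cl <- match.call()
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(spec, "mvdr_spec"))
  need <- c("cluster", "lon", "lat", response_names())
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))

  if (verbose) message("(i) spatial train/test split")
  clusters <- unique(data[, c("cluster", "lon", "lat")])
  clusters <- clusters[!duplicated(clusters$cluster), ]
  split <- delaunay_split(clusters, frac_train = frac_train)
  idx <- split_observations(split, data)
  train <- data[idx$train, , drop = FALSE]
  test <- data[idx$test, , drop = FALSE]

  if (verbose) message("(ii) intercept-only baseline")
  baseline <- fit_baseline(train)

  selection <- NULL
  final_spec <- spec
  if (any(n_terms(spec) > 0) && boost_iter > 0) {
    if (verbose) message("(iii) boosting-based term selection")
    selection <- boost_select(train, spec, n_iter = boost_iter)
    if (verbose) message("(iv) pruning and MCMC estimation")
    final_spec <- prune_spec(spec, selection, prune_threshold)
  } else if (verbose) message("(iv) MCMC estimation")
  fit <- fit_mcmc(train, final_spec, n_iter = mcmc_iter, burn_in = burn_in,
                  thin = thin, verbose = verbose)

  if (verbose) message("(v) held-out validation")
  baseline_logscore <- heldout_logscore(baseline, test)
  final_logscore <- heldout_logscore(fit, test)
  if (final_logscore < baseline_logscore)
    warning("final model scores below the intercept-only baseline on the ",
            "held-out clusters", call. = FALSE)

  structure(list(
    call = cl, candidate_spec = spec, spec = final_spec,
    selection = selection, baseline = baseline, fit = fit,
    split = split, train_idx = idx$train, test_idx = idx$test,
    data = data,
    scores = c(baseline = baseline_logscore, final = final_logscore),
    seed = seed), class = "mvdr")
}

#' @export
print.mvdr <- function(x, ...) {
  cat("Joint distributional regression of (Hb, HAZ, WAZ, WHZ)\n\n")
  print(x$split)
  nt <- n_terms(x$spec)
  cat("final model terms beyond intercepts:",
      if (any(nt > 0)) "" else "none", "\n")
  if (any(nt > 0)) {
    for (lab in names(nt)[nt > 0])
      cat(sprintf("  %-8s ~ %s\n", lab,
                  paste(setdiff(names(x$spec$parameter_terms[[lab]]),
                                "intercept"), collapse = " + ")))
  }
  cat(sprintf("held-out mean log-score: %.4f (intercept-only baseline %.4f)\n",
              x$scores["final"], x$scores["baseline"]))
  invisible(x)
}

#' @export
summary.mvdr <- function(object, ...) {
  f <- object$fit
  theta_cols <- paste0(par_labels(), ":intercept")
  have <- theta_cols %in% colnames(f$samples)
  # posterior summaries of the intercept-implied distribution parameters
  mom <- t(apply(f$samples[, theta_cols[have], drop = FALSE], 1, function(v) {
    par <- .theta_to_par(setNames(v, par_labels()[have])[par_labels()], 1)
    m <- .par_moments(par)
    c(par$mu[1, ], sd = m$sd[1, ], m$rho[1, ])
  }))
  colnames(mom) <- c(paste0("mu_", response_names()),
                     paste0("sd_", response_names()), cor_labels())
  qs <- apply(mom, 2, stats::quantile, c(0.025, 0.5, 0.975))
  tab <- data.frame(mean = colMeans(mom), lower95 = qs[1, ],
                    median = qs[2, ], upper95 = qs[3, ])
  sel <- if (!is.null(object$selection)) {
    fr <- object$selection$frequencies
    fr[order(-fr$frequency), ][fr$frequency[order(-fr$frequency)] > 0, ]
  } else NULL
  out <- list(call = object$call, moments = tab, selection = sel,
              scores = object$scores, accept = mean(f$accept_rates),
              ess = stats::median(f$ess), n_train = length(object$train_idx),
              n_test = length(object$test_idx))
  class(out) <- "summary.mvdr"
  out
}

#' @export
print.summary.mvdr <- function(x, ...) {
  cat("Call:", deparse(x$call), "\n\n")
  cat(sprintf("n = %d training / %d test children\n\n", x$n_train, x$n_test))
  cat("Posterior summaries of the reference (intercept-level) distribution:\n")
  print(round(x$moments, 4))
  if (!is.null(x$selection) && nrow(x$selection)) {
    cat("\nSelected terms (boosting selection frequencies):\n")
    print(utils::head(x$selection, 12), row.names = FALSE)
  }
  cat(sprintf("\nHeld-out mean log-score: %.4f (baseline %.4f)\n",
              x$scores["final"], x$scores["baseline"]))
  cat(sprintf("Sampler: mean acceptance %.2f, median ESS %.0f\n",
              x$accept, x$ess))
  invisible(x)
}

#' @export
coef.mvdr <- function(object, type = c("list", "vector"), ...) {
  type <- match.arg(type)
  if (type == "list") return(object$fit$coefficients)
  unlist(object$fit$coefficients)
}

#' @export
logLik.mvdr <- function(object, ...) {
  val <- mean(object$fit$ll_samples)
  structure(val, df = ncol(object$fit$samples), nobs = object$fit$n,
            class = "logLik")
}

#' @export
.fit_par.mvdr <- function(fit, data) {
  .fit_par(fit$fit, data)
}

#' Predict distribution parameters, prevalences and correlations
#'
#' Evaluates the fitted joint distribution at new covariate rows.  With
#' \code{summaries = FALSE} (default) point predictions use the posterior-mean
#' coefficients; with \code{summaries = TRUE} every stored posterior draw is
#' propagated and the posterior mean and equal-tailed 95% interval are
#' returned for each quantity.
#'
#' @param object A fitted \code{\link{mvdr}} model.
#' @param newdata Data frame of covariate rows (all covariates of the final
#'   model must be present).
#' @param type \code{"parameters"} (eta for all 14 predictors),
#'   \code{"moments"} (mu, sd, rho per row), \code{"prevalence"} (the five
#'   indicator probabilities), or \code{"correlation"} (six pairwise
#'   correlations).
#' @param indicators Indicator definitions for \code{type = "prevalence"}
#'   (see \code{\link{indicator_definitions}}).
#' @param summaries Return posterior mean/lower95/upper95 over MCMC draws
#'   instead of point predictions.
#' @param ... Unused.
#' @return A matrix (point predictions) or a long data frame with columns
#'   \code{row}, \code{quantity}, \code{mean}, \code{lower95}, \code{upper95}
#'   (posterior summaries).
#' @export
predict.mvdr <- function(object, newdata,
                         type = c("moments", "parameters", "prevalence",
                                  "correlation"),
                         indicators = indicator_definitions(),
                         summaries = FALSE, ...) {
  type <- match.arg(type)
  fit <- object$fit
  if (!summaries) {
    eta <- .eval_eta(fit$designs, newdata, fit$coefficients)
    return(.quantities_from_eta(eta, type, indicators))
  }
  draws <- nrow(fit$samples)
  acc <- NULL
  for (d in seq_len(draws)) {
    eta <- .eval_eta(fit$designs, newdata, .coefs_from_draw(fit, d))
    q <- .quantities_from_eta(eta, type, indicators)
    if (is.null(acc)) acc <- array(NA_real_, c(draws, nrow(q), ncol(q)),
                                   dimnames = list(NULL, NULL, colnames(q)))
    acc[d, , ] <- q
  }
  out <- data.frame(
    row = rep(seq_len(dim(acc)[2]), times = dim(acc)[3]),
    quantity = rep(dimnames(acc)[[3]], each = dim(acc)[2]),
    mean = as.vector(apply(acc, c(2, 3), mean)),
    lower95 = as.vector(apply(acc, c(2, 3), stats::quantile, 0.025)),
    upper95 = as.vector(apply(acc, c(2, 3), stats::quantile, 0.975)))
  out
}

# map an eta matrix to the requested quantity matrix
.quantities_from_eta <- function(eta, type, indicators) {
  if (type == "parameters") return(eta)
  par <- .eta_to_par(eta)
  mom <- .par_moments(par)
  if (type == "moments")
    return(cbind(structure(par$mu, dimnames = list(NULL, paste0("mu_", response_names()))),
                 structure(mom$sd, dimnames = list(NULL, paste0("sd_", response_names()))),
                 mom$rho))
  if (type == "correlation") return(mom$rho)
  ri <- match(indicators$response, response_names())
  out <- sapply(seq_len(nrow(indicators)), function(j)
    threshold_probability(par$mu[, ri[j]], mom$sd[, ri[j]],
                          indicators$cut[j], indicators$tail[j]))
  if (!is.matrix(out)) out <- matrix(out, nrow = nrow(eta))
  colnames(out) <- indicators$name
  out
}

#' Simulate response vectors from the fitted model
#'
#' Draws (Hb, HAZ, WAZ, WHZ) vectors at the covariate rows of \code{newdata}
#' from the fitted conditional distribution (posterior-mean parameters).
#'
#' @param object A fitted \code{\link{mvdr}}.
#' @param nsim Number of replicate data sets.
#' @param seed Optional seed.
#' @param newdata Covariate rows; defaults to the training data.
#' @param ... Unused.
#' @return A list of \code{nsim} matrices (n x 4).
#' @export
simulate.mvdr <- function(object, nsim = 1, seed = NULL, newdata = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(newdata)) newdata <- object$data[object$train_idx, , drop = FALSE]
  par <- .fit_par(object, newdata)
  lapply(seq_len(nsim), function(i) .sample_rows(par))
}

#' Quantile residuals of a fitted model
#'
#' @param object A fitted \code{\link{mvdr}}.
#' @param newdata Observation rows to evaluate; defaults to the held-out test
#'   children of the fitting split.
#' @param ... Unused.
#' @return See \code{\link{quantile_residuals}}.
#' @export
residuals.mvdr <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$data[object$test_idx, , drop = FALSE]
  quantile_residuals(object, newdata)
}

#' Plot method: selection frequencies and residual calibration
#'
#' \code{which = 1} draws the barplot of boosting selection frequencies per
#' distributional parameter (the term-informativeness display); \code{which =
#' 2} draws normal Q-Q plots of the held-out quantile residuals per response.
#'
#' @param x A fitted \code{\link{mvdr}}.
#' @param which Plot selection (1, 2 or both).
#' @param ... Passed to the underlying graphics calls.
#' @export
plot.mvdr <- function(x, which = 1, ...) {
  if (1 %in% which && !is.null(x$selection)) {
    fr <- x$selection$frequencies
    fr <- fr[fr$frequency > 0, ]
    if (nrow(fr)) {
      fr <- fr[order(fr$frequency), ]
      lab <- paste(fr$parameter, fr$term, sep = " : ")
      op <- graphics::par(mar = c(4, 10, 2, 1)); on.exit(graphics::par(op))
      graphics::barplot(fr$frequency, names.arg = lab, horiz = TRUE, las = 1,
                        xlab = "selection frequency",
                        main = "Boosting term selection", ...)
    }
  }
  if (2 %in% which) {
    r <- residuals(x)
    op <- graphics::par(mfrow = c(2, 2)); on.exit(graphics::par(op), add = TRUE)
    for (m in response_names()) {
      stats::qqnorm(r[[m]], main = paste("quantile residuals:", m), ...)
      stats::qqline(r[[m]])
    }
  }
  invisible(x)
}
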