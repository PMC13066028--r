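# Step (v): calibration and predictive-performance checks, and the spatial
# cross-validation harness probing data sparsity.

#' Per-response quantile residuals
#'
#' Transforms each observed response through its fitted conditional Gaussian
#' marginal, \eqn{r = \Phi^{-1}(F_m(y_m))}; under a correctly specified model
#' the residuals are standard normal.  Rows with non-finite fitted standard
#' deviations are excluded and counted.
#'
#' @param fit A fitted model: \code{\link{mvdr}}, \code{\link{fit_mcmc}}
#'   result or \code{\link{fit_baseline}} result.
#' @param data Observation rows (responses + covariates).
#' @return Data frame with one residual column per response; attribute
#'   \code{"excluded"} counts dropped rows.
#' @export
quantile_residuals <- function(fit, data) {
  y <- .response_matrix(data)
  par <- .fit_par(fit, data)
  mom <- .par_moments(par)
  ok <- rowSums(!is.finite(mom$sd) | mom$sd <= 0) == 0
  r <- stats::qnorm(stats::pnorm(y[ok, , drop = FALSE],
                                 mean = par$mu[ok, , drop = FALSE],
                                 sd = mom$sd[ok, , drop = FALSE]))
  out <- as.data.frame(r)
  names(out) <- response_names()
  attr(out, "excluded") <- sum(!ok)
  out
}

#' Held-out mean joint log-score
#'
#' Mean joint Gaussian log-density of the observed response vectors under the
#' fitted conditional distribution; higher is better.  Invariant to row
#' order.
#'
#' @inheritParams quantile_residuals
#' @return A single number (mean log-density per child).
#' @export
heldout_logscore <- function(fit, data) {
  y <- .response_matrix(data)
  par <- .fit_par(fit, data)
  mean(.ll_rows(y, par))
}

#' Calibration and predictive-performance report
#'
#' Summarises per-response quantile residuals (mean, sd, skewness, excess
#' kurtosis), the coverage of central 90% predictive intervals per response,
#' and the held-out joint log-score, optionally against a baseline model.
#'
#' @inheritParams quantile_residuals
#' @param baseline Optional reference fit scored on the same rows.
#' @return An object of class \code{"mvdr_validation"}.
#' @export
validation_report <- function(fit, data, baseline = NULL) {
  r <- quantile_residuals(fit, data)
  stats_tab <- t(vapply(r, function(x) {
    m <- mean(x); s <- stats::sd(x)
    z <- (x - m) / s
    c(mean = m, sd = s, skew = mean(z^3), ex_kurt = mean(z^4) - 3)
  }, numeric(4)))
  y <- .response_matrix(data)
  par <- .fit_par(fit, data)
  mom <- .par_moments(par)
  zc <- stats::qnorm(0.95)
  coverage <- vapply(seq_len(4), function(m)
    mean(abs(y[, m] - par$mu[, m]) <= zc * mom$sd[, m]), 0)
  names(coverage) <- response_names()
  out <- list(residual_summary = stats_tab, coverage90 = coverage,
              logscore = heldout_logscore(fit, data),
              baseline_logscore = if (!is.null(baseline))
                heldout_logscore(baseline, data) else NA_real_,
              n = nrow(data), excluded = attr(r, "excluded"))
  class(out) <- "mvdr_validation"
  out
}

#' @export
print.mvdr_validation <- function(x, ...) {
  cat("Validation report (n =", x$n,
      if (x$excluded) paste0(", ", x$excluded, " rows excluded") else "", ")\n")
  cat("quantile-residual summaries (target: mean 0, sd 1, skew 0, ex. kurtosis 0):\n")
  print(round(x$residual_summary, 3))
  cat("coverage of central 90% predictive intervals:\n")
  print(round(x$coverage90, 3))
  cat(sprintf("held-out mean log-score: %.4f", x$logscore))
  if (is.finite(x$baseline_logscore))
    cat(sprintf(" (baseline %.4f)", x$baseline_logscore))
  cat("\n")
  invisible(x)
}

#' Spatial cross-validation
#'
#' Splits the survey clusters into spatially spread folds (see
#' \code{\link{spatial_folds}}) and runs a reduced fit/validate cycle per
#' fold: baseline, optional boosting selection, MCMC on the pruned model,
#' and a \code{\link{validation_report}} on the held-out fold.
#'
#' @param data Observation table with \code{cluster}, \code{lon}, \code{lat},
#'   responses and covariates.
#' @param spec Candidate \code{\link{mvdr_spec}}.
#' @param k_folds Number of folds (default 5).
#' @param seed Integer seed for fold assignment and fits.
#' @param boost_iter,mcmc_iter,burn_in,thin Reduced per-fold settings.
#' @param prune_threshold Selection threshold per fold.
#' @return An object of class \code{"mvdr_cv"}: per-fold reports,
#'   per-fold held-out log-scores, their mean and standard deviation, and the
#'   fold assignment.
#' @export
spatial_cv <- function(data, spec = mvdr_spec(), k_folds = 5, seed = NULL,
                       boost_iter = 100, mcmc_iter = 500, burn_in = 200,
                       thin = 5, prune_threshold = 0.05) {
  if (k_folds < 2) stop("'k_folds' must be at least 2")
  if (!is.null(seed)) set.seed(seed)
  clusters <- unique(data[, c("cluster", "lon", "lat")])
  clusters <- clusters[!duplicated(clusters$cluster), ]
  if (nrow(clusters) < k_folds) stop("too few clusters for ", k_folds, " folds")
  fold <- spatial_folds(clusters, k = k_folds)
  cluster_fold <- setNames(fold, clusters$cluster)
  obs_fold <- cluster_fold[as.character(data$cluster)]
  reports <- vector("list", k_folds)
  scores <- numeric(k_folds)
  for (f in seq_len(k_folds)) {
    train <- data[obs_fold != f, , drop = FALSE]
    test <- data[obs_fold == f, , drop = FALSE]
    final_spec <- spec
    if (any(n_terms(spec) > 0) && boost_iter > 0) {
      sel <- boost_select(train, spec, n_iter = boost_iter)
      final_spec <- prune_spec(spec, sel, prune_threshold)
    }
    fit <- fit_mcmc(train, final_spec, n_iter = mcmc_iter, burn_in = burn_in,
                    thin = thin)
    reports[[f]] <- validation_report(fit, test, baseline = fit_baseline(train))
    scores[f] <- reports[[f]]$logscore
  }
  structure(list(reports = reports, scores = scores,
                 mean_score = mean(scores), sd_score = stats::sd(scores),
                 fold = obs_fold, k_folds = k_folds), class = "mvdr_cv")
}

#' @export
print.mvdr_cv <- function(x, ...) {
  cat("Spatial", x$k_folds, "fold cross-validation\n")
  cat("per-fold held-out mean log-scores:\n")
  print(round(x$scores, 4))
  cat(sprintf("mean %.4f, sd %.4f\n", x$mean_score, x$sd_score))
  invisible(x)
}
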