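# Steps (ii)-(iii) of the modelling approach: the intercept-only baseline and
# componentwise gradient boosting across all 14 distributional parameters.
# At every boosting iteration each candidate term of each parameter is fitted
# to the score of that parameter's predictor; the single best (parameter,
# term) update -- judged by the actual log-likelihood improvement, which is
# comparable across parameters -- is applied with a small step length, and
# selection frequencies over iterations measure term informativeness.

#' Intercept-only baseline fit
#'
#' Maximum-likelihood fit of the multivariate Gaussian with constant mean
#' vector and covariance: the mean equals the sample mean and the covariance
#' the n-denominator sample covariance, re-expressed as the 14 intercepts of
#' the modified Cholesky parameterisation.  Serves as the reference model and
#' as the offset for boosting.
#'
#' @param data Observation table with response columns \code{hb}, \code{haz},
#'   \code{waz}, \code{whz} (at least 20 rows).
#' @return An object of class \code{"mvdr_baseline"} with elements
#'   \code{theta} (named vector of 14 intercepts), \code{mu}, \code{sigma},
#'   \code{loglik} and \code{n}.
#' @export
fit_baseline <- function(data) {
  y <- .response_matrix(data)
  n <- nrow(y)
  if (n < 20) stop("baseline fit needs at least 20 observations")
  mu <- colMeans(y)
  S <- crossprod(sweep(y, 2L, mu)) / n
  if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) < 1e-10)
    stop("singular response covariance (degenerate responses)")
  f <- sigma_to_factors(S)
  theta <- c(mu, f$lam, f$phi[.phi_index()])
  names(theta) <- par_labels()
  par <- .theta_to_par(theta, n)
  structure(list(theta = theta, mu = mu, sigma = S,
                 loglik = sum(.ll_rows(y, par)), n = n),
            class = "mvdr_baseline")
}

#' @export
print.mvdr_baseline <- function(x, ...) {
  cat("Intercept-only baseline (n =", x$n, ")\n")
  cat("mean vector:", format(x$mu, digits = 4), "\n")
  cat("log-likelihood:", format(x$loglik), "\n")
  invisible(x)
}

# smoothing parameter giving a penalised term ~df effective degrees of
# freedom: solves trace((X'X + l K)^{-1} X'X) = df on a log grid + uniroot
.lambda_for_df <- function(XtX, K, df) {
  p <- ncol(XtX)
  if (df >= p) return(0)
  edf <- function(loglam) {
    A <- XtX + 10^loglam * K + 1e-10 * diag(p)
    sum(diag(solve(A, XtX))) - df
  }
  lo <- -8; hi <- 12
  if (edf(lo) < 0) return(0)          # even unpenalised fit has < df
  if (edf(hi) > 0) return(10^hi)
  10^stats::uniroot(edf, c(lo, hi), tol = 1e-3)$root
}

# candidate list for boosting: every non-intercept (parameter, term) pair,
# with design, equal-df ridge solve operator and labels
.boost_candidates <- function(designs, data, df = 4) {
  cand <- list()
  for (lab in par_labels()) {
    tl <- designs$params[[lab]]
    for (tn in names(tl)) {
      if (tn == "intercept") next
      st <- tl[[tn]]
      X <- .eval_term(st, data)
      XtX <- crossprod(X)
      K <- st$K
      lam <- if (!is.null(K)) .lambda_for_df(XtX, K, df) else 0
      pen <- if (!is.null(K)) lam * K else matrix(0, ncol(X), ncol(X))
      M <- solve(XtX + pen + 1e-8 * diag(ncol(X)))
      cand[[length(cand) + 1L]] <- list(parameter = lab, term = tn, X = X, M = M)
    }
  }
  cand
}

#' Componentwise gradient boosting over the 14 distributional parameters
#'
#' Starting from the intercept-only baseline, each iteration fits every
#' candidate term (equal-degrees-of-freedom ridge fit to the score of its
#' parameter's predictor), applies the single best update -- the one whose
#' damped step most increases the training log-likelihood -- and records the
#' selection.  Selection frequencies are per-iteration selection shares over
#' the iterations actually executed (early stopping included).
#' Boosting stops early when no candidate improves the log-likelihood even
#' after step halving, so the training log-likelihood is non-decreasing.
#'
#' @param data Training observation table.
#' @param spec An \code{\link{mvdr_spec}} listing the candidate terms.
#' @param n_iter Number of boosting iterations (>= 0).
#' @param step_length Step length nu applied to each fitted update
#'   (default 0.1).
#' @param df Effective degrees of freedom given to every penalised candidate,
#'   so smooth and parametric terms compete on an equal footing.
#' @param holdout_frac Fraction of observations held out internally to choose
#'   the effective number of iterations: boosting stops once the held-out
#'   log-score has not improved for \code{patience} iterations, and selections
#'   after the best-scoring iteration are discarded.  Set to 0 to run all
#'   \code{n_iter} iterations on the full data.
#' @param patience Early-stopping patience (iterations without held-out
#'   improvement; default 30).
#' @param seed Optional seed fixing the internal holdout draw.
#' @return An object of class \code{"mvdr_selection"}: \code{frequencies}
#'   (data frame parameter/term/frequency), \code{counts}, \code{loglik_path},
#'   \code{coefficients} (accumulated nested list), the baseline \code{theta},
#'   \code{n_iter} requested and \code{n_used} actually performed.
#' @export
boost_select <- function(data, spec, n_iter = 500, step_length = 0.1,
                         df = 4, holdout_frac = 0.1, patience = 30,
                         seed = NULL) {
  stopifnot(inherits(spec, "mvdr_spec"), n_iter >= 0,
            holdout_frac >= 0, holdout_frac < 0.5)
  if (!is.null(seed)) set.seed(seed)
  n_all <- nrow(data)
  hold <- if (holdout_frac > 0 && n_all >= 50)
    sort(sample.int(n_all, ceiling(holdout_frac * n_all))) else integer()
  inner <- if (length(hold)) setdiff(seq_len(n_all), hold) else seq_len(n_all)
  din <- data[inner, , drop = FALSE]
  y <- .response_matrix(din)
  n <- nrow(y)
  base <- fit_baseline(din)
  designs <- .build_designs(spec, din)
  cand <- .boost_candidates(designs, din)
  labs <- vapply(cand, function(cc) paste(cc$parameter, cc$term, sep = " : "), "")
  counts <- setNames(integer(length(cand)), labs)
  coefs <- .zero_coefs(designs)
  for (lab in par_labels()) coefs[[lab]][["intercept"]] <- unname(base$theta[lab])
  eta <- matrix(base$theta, n, 14L, byrow = TRUE,
                dimnames = list(NULL, par_labels()))
  ll <- sum(.ll_rows(y, .eta_to_par(eta)))
  kidx <- match(vapply(cand, `[[`, "", "parameter"), par_labels())
  # held-out state for early stopping
  if (length(hold)) {
    dho <- data[hold, , drop = FALSE]
    yho <- .response_matrix(dho)
    Xho <- lapply(cand, function(cc)
      .eval_term(designs$params[[cc$parameter]][[cc$term]], dho))
    eta_ho <- matrix(base$theta, nrow(yho), 14L, byrow = TRUE,
                     dimnames = list(NULL, par_labels()))
    ho_score <- mean(.ll_rows(yho, .eta_to_par(eta_ho)))
  } else ho_score <- NA_real_
  ll_path <- numeric(0)
  ho_path <- numeric(0)
  history <- integer(0)                  # selected candidate per iteration
  best_it <- 0L; best_ho <- ho_score
  used <- 0L
  if (length(cand) && n_iter > 0) {
    for (it in seq_len(n_iter)) {
      g <- .grad_rows(y, .eta_to_par(eta))
      best <- NULL
      for (j in seq_along(cand)) {
        cc <- cand[[j]]
        b <- cc$M %*% crossprod(cc$X, g[, kidx[j]])
        eta_try <- eta
        eta_try[, kidx[j]] <- eta_try[, kidx[j]] + step_length * drop(cc$X %*% b)
        ll_try <- sum(.ll_rows(y, .eta_to_par(eta_try)))
        if (is.finite(ll_try) && (is.null(best) || ll_try > best$ll)) {
          best <- list(j = j, b = b, ll = ll_try, step = step_length)
        }
      }
      if (is.null(best)) break
      # step-halving safeguard: training log-likelihood must not decrease
      while (best$ll < ll && best$step > step_length / 32) {
        best$step <- best$step / 2
        eta_try <- eta
        eta_try[, kidx[best$j]] <- eta_try[, kidx[best$j]] +
          best$step * drop(cand[[best$j]]$X %*% best$b)
        best$ll <- sum(.ll_rows(y, .eta_to_par(eta_try)))
      }
      if (best$ll < ll) break
      cc <- cand[[best$j]]
      eta[, kidx[best$j]] <- eta[, kidx[best$j]] +
        best$step * drop(cc$X %*% best$b)
      coefs[[cc$parameter]][[cc$term]] <- coefs[[cc$parameter]][[cc$term]] +
        best$step * drop(best$b)
      history <- c(history, best$j)
      ll <- best$ll
      ll_path <- c(ll_path, ll)
      used <- used + 1L
      if (length(hold)) {
        eta_ho[, kidx[best$j]] <- eta_ho[, kidx[best$j]] +
          best$step * drop(Xho[[best$j]] %*% best$b)
        ho_score <- mean(.ll_rows(yho, .eta_to_par(eta_ho)))
        ho_path <- c(ho_path, ho_score)
        if (ho_score > best_ho + 1e-10) { best_ho <- ho_score; best_it <- it }
        if (it - best_it >= patience) break
      } else best_it <- it
    }
  }
  # selections after the best held-out iteration do not count
  if (best_it < length(history)) history <- history[seq_len(best_it)]
  counts[] <- tabulate(history, nbins = length(cand))
  # per-iteration selection shares over the executed iterations (the patience
  # window counts: iterations spent finding nothing are evidence of nothing)
  freq <- data.frame(parameter = vapply(cand, `[[`, "", "parameter"),
                     term = vapply(cand, `[[`, "", "term"),
                     frequency = if (used > 0) unname(counts) / used
                                 else rep(0, length(cand)))
  structure(list(frequencies = freq, counts = counts, loglik_path = ll_path,
                 holdout_path = ho_path, best_iteration = best_it,
                 coefficients = coefs, baseline = base, spec = spec,
                 n_iter = n_iter, n_used = used, step_length = step_length),
            class = "mvdr_selection")
}

#' @export
print.mvdr_selection <- function(x, ...) {
  cat("Componentwise boosting selection (", x$n_used, "of", x$n_iter,
      "iterations used )\n")
  f <- x$frequencies[order(-x$frequencies$frequency), ]
  print(utils::head(f[f$frequency > 0, ], 15), row.names = FALSE)
  invisible(x)
}

#' Drop uninformative terms from a model specification
#'
#' Keeps every intercept and every term whose boosting selection frequency
#' reaches the threshold; everything else is omitted from the final model.
#'
#' @param spec The candidate \code{\link{mvdr_spec}}.
#' @param freqs An \code{"mvdr_selection"} object or its \code{frequencies}
#'   data frame.
#' @param threshold Relative selection frequency required to keep a term
#'   (default 0.05).
#' @return The pruned \code{\link{mvdr_spec}}.
#' @export
prune_spec <- function(spec, freqs, threshold = 0.05) {
  stopifnot(inherits(spec, "mvdr_spec"), threshold >= 0)
  if (inherits(freqs, "mvdr_selection")) freqs <- freqs$frequencies
  keep_args <- list()
  for (lab in par_labels()) {
    tl <- spec$parameter_terms[[lab]]
    kept <- list()
    for (tn in names(tl)) {
      if (tn == "intercept") next
      fr <- freqs$frequency[freqs$parameter == lab & freqs$term == tn]
      if (length(fr) && fr[1] >= threshold) kept[[tn]] <- tl[[tn]]
    }
    if (length(kept)) keep_args[[lab]] <- unname(kept)
  }
  do.call(mvdr_spec, keep_args)
}
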