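# Step (iv): Bayesian estimation of the (pruned) model by single-chain MCMC.
# One coefficient block per (parameter, term).  Each block is updated by a
# Metropolis-Hastings step whose Gaussian proposal is an iteratively-weighted
# least-squares (expected-Fisher) approximation of the full conditional;
# smoothing variances of penalised blocks get conjugate inverse-gamma Gibbs
# updates.  Gaussian likelihood throughout, multivariate-normal priors with
# penalty-matrix precision on penalised coefficients.

# add delta to the predictor column k of a parameter list (copy-on-write
# touches only the affected n x 4 / n x 6 component)
.par_bump <- function(par, k, delta) {
  if (k <= 4L) par$mu[, k] <- par$mu[, k] + delta
  else if (k <= 8L) par$lam[, k - 4L] <- par$lam[, k - 4L] + delta
  else par$phi[, k - 8L] <- par$phi[, k - 8L] + delta
  par
}

# shared innovation quantities of one parameter state (the expensive part of
# every block update; cached across blocks while the state is unchanged)
.state_core <- function(y, par) {
  r <- y - par$mu
  p <- par$phi
  u <- cbind(r[, 1L],
             r[, 2L] - p[, 1L] * r[, 1L],
             r[, 3L] - p[, 2L] * r[, 1L] - p[, 3L] * r[, 2L],
             r[, 4L] - p[, 4L] * r[, 1L] - p[, 5L] * r[, 2L] - p[, 6L] * r[, 3L])
  e2 <- exp(-2 * par$lam)
  w <- u * e2
  ll <- sum(-0.5 * rowSums(u * w) - rowSums(par$lam)) - 2 * nrow(y) * log(2 * pi)
  list(r = r, u = u, e2 = e2, w = w, ll = ll)
}

# log-likelihood, score column and IWLS weight column for predictor k
.block_quantities <- function(y, par, k, core = NULL) {
  if (is.null(core)) core <- .state_core(y, par)
  r <- core$r; u <- core$u; e2 <- core$e2; w <- core$w
  ll <- core$ll
  p <- par$phi
  if (k <= 4L) {
    g <- switch(k,
      w[, 1L] - p[, 1L] * w[, 2L] - p[, 2L] * w[, 3L] - p[, 4L] * w[, 4L],
      w[, 2L] - p[, 3L] * w[, 3L] - p[, 5L] * w[, 4L],
      w[, 3L] - p[, 6L] * w[, 4L],
      w[, 4L])
    wt <- switch(k,
      e2[, 1L] + p[, 1L]^2 * e2[, 2L] + p[, 2L]^2 * e2[, 3L] + p[, 4L]^2 * e2[, 4L],
      e2[, 2L] + p[, 3L]^2 * e2[, 3L] + p[, 5L]^2 * e2[, 4L],
      e2[, 3L] + p[, 6L]^2 * e2[, 4L],
      e2[, 4L])
  } else if (k <= 8L) {
    m <- k - 4L
    g <- u[, m] * w[, m] - 1          # = v^2 - 1
    wt <- rep.int(2, nrow(u))
  } else {
    j <- k - 8L                        # phi columns (21,31,32,41,42,43)
    row_m <- c(2L, 3L, 3L, 4L, 4L, 4L)[j]
    col_j <- c(1L, 1L, 2L, 1L, 2L, 3L)[j]
    g <- w[, row_m] * r[, col_j]
    wt <- e2[, row_m] * r[, col_j]^2
  }
  list(ll = ll, g = g, w = wt)
}

# Gaussian log-density with precision matrix A (up to a constant)
.ldens_prec <- function(x, m, cholA) {
  d <- drop(cholA %*% (x - m))
  sum(log(diag(cholA))) - 0.5 * sum(d * d)
}

#' Bayesian estimation by MCMC with IWLS proposals
#'
#' Fits the multivariate Gaussian distributional regression defined by
#' \code{spec} to \code{data} with a single-chain block Metropolis-Hastings
#' sampler.  Each (parameter, term) coefficient block is proposed from its
#' iteratively-weighted-least-squares Gaussian approximation (expected Fisher
#' information plus prior precision) and accepted with the exact
#' Metropolis-Hastings ratio; penalised blocks carry multivariate normal
#' priors with precision \eqn{K/\tau^2} and weakly informative inverse-gamma
#' IG(0.001, 0.001) hyperpriors on the smoothing variances \eqn{\tau^2},
#' updated by conjugate Gibbs steps.  Chains are initialised at the
#' intercept-only baseline.
#'
#' @param data Training observation table (responses + covariates).
#' @param spec The (typically pruned) \code{\link{mvdr_spec}}.
#' @param n_iter Total MCMC iterations (default 2000).
#' @param burn_in Burn-in iterations discarded (default 1000).
#' @param thin Thinning interval for stored draws (default 10).
#' @param seed Optional integer seed; identical seeds give identical chains.
#' @param verbose Print progress every 500 iterations.
#' @return An object of class \code{"mvdr_fit"} with posterior draws
#'   (\code{samples}, one column per coefficient), posterior-mean
#'   \code{coefficients} (nested per parameter and term), the frozen
#'   \code{designs}, per-block acceptance rates and effective sample sizes,
#'   smoothing-variance draws, and the stored log-likelihood trace.
#' @export
fit_mcmc <- function(data, spec, n_iter = 2000, burn_in = 1000, thin = 10,
                     seed = NULL, verbose = FALSE) {
  stopifnot(inherits(spec, "mvdr_spec"), n_iter > burn_in, thin >= 1)
  if (!is.null(seed)) set.seed(seed)
  y <- .response_matrix(data)
  n <- nrow(y)
  base <- fit_baseline(data)
  designs <- .build_designs(spec, data)

  # block bookkeeping: designs, penalties, prior ranks, coefficient slots
  blocks <- list()
  for (lab in par_labels()) {
    tl <- designs$params[[lab]]
    for (tn in names(tl)) {
      st <- tl[[tn]]
      X <- .eval_term(st, data)
      p <- ncol(X)
      penalised <- !is.null(st$K) && any(st$K != 0)
      K <- if (penalised) st$K else diag(p) * 0
      beta0 <- if (tn == "intercept") unname(base$theta[lab]) else numeric(p)
      blocks[[length(blocks) + 1L]] <- list(
        parameter = lab, term = tn, k = match(lab, par_labels()),
        X = X, K = K, rankK = if (penalised) qr(st$K)$rank else 0L,
        penalised = penalised, beta = beta0, tau2 = 10)
    }
  }
  nb <- length(blocks)
  pvec <- vapply(blocks, function(b) length(b$beta), 0L)
  col_names <- unlist(lapply(blocks, function(b)
    paste0(b$parameter, ":", b$term, if (length(b$beta) > 1)
      paste0("[", seq_along(b$beta), "]") else "")))
  eta <- matrix(0, n, 14L, dimnames = list(NULL, par_labels()))
  for (b in blocks) if (any(b$beta != 0))
    eta[, b$k] <- eta[, b$k] + drop(b$X %*% b$beta)
  par <- .eta_to_par(eta)

  n_keep <- floor((n_iter - burn_in) / thin)
  samples <- matrix(NA_real_, n_keep, sum(pvec), dimnames = list(NULL, col_names))
  tau2_samples <- matrix(NA_real_, n_keep, nb)
  ll_samples <- numeric(n_keep)
  accept <- numeric(nb)
  a_ig <- 0.001; b_ig <- 0.001
  keep <- 0L

  core <- .state_core(y, par)
  for (it in seq_len(n_iter)) {
    for (ib in seq_len(nb)) {
      bl <- blocks[[ib]]
      X <- bl$X
      P0 <- if (bl$penalised) bl$K / bl$tau2 else diag(length(bl$beta)) * 0
      diag(P0) <- diag(P0) + 1e-6
      q1 <- .block_quantities(y, par, bl$k, core)
      A1 <- crossprod(X * q1$w, X) + P0
      R1 <- chol(A1)
      m1 <- bl$beta + backsolve(R1, forwardsolve(t(R1),
              drop(crossprod(X, q1$g)) - drop(P0 %*% bl$beta)))
      prop <- m1 + backsolve(R1, stats::rnorm(length(bl$beta)))
      par_prop <- .par_bump(par, bl$k, drop(X %*% (prop - bl$beta)))
      core_prop <- .state_core(y, par_prop)
      q2 <- .block_quantities(y, par_prop, bl$k, core_prop)
      if (is.finite(q2$ll)) {
        A2 <- crossprod(X * q2$w, X) + P0
        ok <- TRUE
        R2 <- tryCatch(chol(A2), error = function(e) {ok <<- FALSE; NULL})
        if (ok) {
          m2 <- prop + backsolve(R2, forwardsolve(t(R2),
                  drop(crossprod(X, q2$g)) - drop(P0 %*% prop)))
          lp1 <- q1$ll - 0.5 * drop(crossprod(bl$beta, P0 %*% bl$beta))
          lp2 <- q2$ll - 0.5 * drop(crossprod(prop, P0 %*% prop))
          la <- lp2 - lp1 + .ldens_prec(bl$beta, m2, R2) - .ldens_prec(prop, m1, R1)
          if (is.finite(la) && log(stats::runif(1)) < la) {
            blocks[[ib]]$beta <- drop(prop)
            par <- par_prop
            core <- core_prop
            if (it > burn_in) accept[ib] <- accept[ib] + 1
          }
        }
      }
      # conjugate smoothing-variance update
      if (bl$penalised) {
        bKb <- drop(crossprod(blocks[[ib]]$beta, bl$K %*% blocks[[ib]]$beta))
        blocks[[ib]]$tau2 <- 1 / stats::rgamma(1, a_ig + bl$rankK / 2,
                                               rate = b_ig + bKb / 2)
      }
    }
    if (it > burn_in && (it - burn_in) %% thin == 0L) {
      keep <- keep + 1L
      samples[keep, ] <- unlist(lapply(blocks, `[[`, "beta"))
      tau2_samples[keep, ] <- vapply(blocks, `[[`, 0, "tau2")
      ll_samples[keep] <- core$ll
    }
    if (verbose && it %% 500 == 0) message("iteration ", it, " / ", n_iter)
  }

  coefs <- .zero_coefs(designs)
  pm <- colMeans(samples)
  off <- 0L
  for (ib in seq_len(nb)) {
    b <- blocks[[ib]]
    coefs[[b$parameter]][[b$term]] <- unname(pm[off + seq_len(pvec[ib])])
    off <- off + pvec[ib]
  }
  structure(list(
    spec = spec, designs = designs, coefficients = coefs, samples = samples,
    tau2_samples = tau2_samples, ll_samples = ll_samples,
    accept_rates = setNames(accept / (n_iter - burn_in),
                            vapply(blocks, function(b)
                              paste(b$parameter, b$term, sep = " : "), "")),
    ess = apply(samples, 2L, .ess),
    blocks = lapply(blocks, function(b) b[c("parameter", "term", "k")]),
    block_cols = rep(seq_len(nb), pvec),
    baseline = base, n = n, n_iter = n_iter, burn_in = burn_in, thin = thin),
    class = "mvdr_fit")
}

# initial-sequence effective sample size from the autocorrelation function
.ess <- function(x) {
  n <- length(x)
  if (n < 10 || stats::sd(x) == 0) return(n)
  acf <- stats::acf(x, lag.max = min(n - 1, 100), plot = FALSE)$acf[-1]
  pos <- which(acf < 0.05)
  L <- if (length(pos)) pos[1] - 1 else length(acf)
  n / (1 + 2 * sum(acf[seq_len(L)]))
}

#' @export
print.mvdr_fit <- function(x, ...) {
  cat("Multivariate Gaussian distributional regression (MCMC fit)\n")
  cat(sprintf("  n = %d, %d iterations (burn-in %d, thin %d), %d stored draws\n",
              x$n, x$n_iter, x$burn_in, x$thin, nrow(x$samples)))
  cat(sprintf("  %d coefficient blocks, mean acceptance rate %.2f\n",
              length(x$accept_rates), mean(x$accept_rates)))
  nt <- n_terms(x$spec)
  cat("  terms beyond intercepts on:",
      if (any(nt > 0)) paste(names(nt)[nt > 0], collapse = ", ") else "none", "\n")
  invisible(x)
}

# posterior-mean distribution parameters at new data rows
.fit_par <- function(fit, data) {
  UseMethod(".fit_par")
}

#' @export
.fit_par.mvdr_fit <- function(fit, data) {
  eta <- .eval_eta(fit$designs, data, fit$coefficients)
  .eta_to_par(eta)
}

#' @export
.fit_par.mvdr_baseline <- function(fit, data) {
  .theta_to_par(fit$theta, nrow(data))
}

# nested coefficient list from one stored draw
.coefs_from_draw <- function(fit, draw) {
  coefs <- .zero_coefs(fit$designs)
  vec <- fit$samples[draw, ]
  for (ib in seq_along(fit$blocks)) {
    b <- fit$blocks[[ib]]
    coefs[[b$parameter]][[b$term]] <- unname(vec[fit$block_cols == ib])
  }
  coefs
}
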