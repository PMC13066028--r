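# Modified Cholesky parameterisation of the multivariate Gaussian:
#   T Sigma T' = D^2,  T = I - Phi unit lower triangular, D = diag(exp(lam)).
# Phi and lam are unconstrained, so every distributional parameter can carry an
# additive predictor while Sigma stays positive definite by construction.

#' Response ordering of the joint malnutrition model
#'
#' The four responses are always ordered (Hb, HAZ, WAZ, WHZ); the Cholesky
#' parameterisation is order dependent, so this ordering is fixed throughout.
#'
#' @return Character vector of the four response names.
#' @export
response_names <- function() c("hb", "haz", "waz", "whz")

#' Labels of the 14 distributional parameters
#'
#' Four means (identity link), four log innovation scales (log link for the
#' diagonal of D), and six unconstrained entries of the Cholesky factor
#' (identity link), in the flat serialisation order
#' (mu_1..4, lam_1..4, phi_21, phi_31, phi_32, phi_41, phi_42, phi_43).
#'
#' @return Character vector of length 14.
#' @export
par_labels <- function() {
  c(paste0("mu_", response_names()),
    paste0("lam_", response_names()),
    "phi_21", "phi_31", "phi_32", "phi_41", "phi_42", "phi_43")
}

.phi_labels <- function() c("phi_21", "phi_31", "phi_32", "phi_41", "phi_42", "phi_43")

# (row, col) index pairs of the strictly lower triangle in serialisation order
.phi_index <- function(M = 4L) {
  idx <- which(lower.tri(matrix(0, M, M)), arr.ind = TRUE)
  idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
}

#' Cholesky factors of a covariance matrix
#'
#' Bundles the strictly-lower-triangular coefficient matrix \code{phi} and the
#' log innovation scales \code{lam} that parameterise a covariance matrix via
#' the modified Cholesky decomposition \eqn{T \Sigma T' = D^2} with
#' \eqn{T = I - \phi} and \eqn{D = diag(exp(\lambda))}.
#'
#' @param phi Numeric M x M matrix; entries on and above the diagonal must be
#'   zero (they are checked, not silently dropped).
#' @param lam Numeric vector of length M of log innovation scales.
#' @return An object of class \code{"chol_factors"}.
#' @examples
#' f <- chol_factors(matrix(0, 4, 4), rep(0, 4))
#' build_sigma(f)  # identity
#' @export
chol_factors <- function(phi, lam) {
  phi <- as.matrix(phi)
  lam <- as.numeric(lam)
  M <- length(lam)
  if (!all(dim(phi) == c(M, M)))
    stop("'phi' must be a ", M, " x ", M, " matrix matching length(lam)")
  if (!all(is.finite(phi)) || !all(is.finite(lam)))
    stop("non-finite entries in Cholesky factors")
  if (any(phi[upper.tri(phi, diag = TRUE)] != 0))
    stop("'phi' must be strictly lower triangular (zeros on and above diagonal)")
  structure(list(phi = phi, lam = lam, M = M), class = "chol_factors")
}

#' @export
print.chol_factors <- function(x, ...) {
  cat("Modified Cholesky factors (M =", x$M, ")\n")
  cat("log innovation scales:", format(x$lam, digits = 4), "\n")
  cat("phi (strictly lower triangular):\n")
  print(x$phi)
  invisible(x)
}

#' Reconstruct a covariance matrix from its modified Cholesky factors
#'
#' Computes \eqn{\Sigma = T^{-1} D^2 T^{-T}} with \eqn{T = I - \phi} and
#' \eqn{D = diag(exp(\lambda))}.  The result is symmetric positive definite for
#' every finite input, which is what makes the parameterisation attractive for
#' covariance regression.
#'
#' @param factors A \code{\link{chol_factors}} object (or a list with elements
#'   \code{phi} and \code{lam}).
#' @return The M x M covariance matrix.
#' @export
build_sigma <- function(factors) {
  if (!inherits(factors, "chol_factors"))
    factors <- chol_factors(factors$phi, factors$lam)
  M <- factors$M
  Tm <- diag(M) - factors$phi
  A <- backsolve(Tm, diag(M), upper.tri = FALSE)   # T^{-1}, unit lower triangular
  B <- A %*% diag(exp(factors$lam), M)             # T^{-1} D
  sigma <- tcrossprod(B)
  dimnames(sigma) <- if (M == 4L) list(response_names(), response_names()) else NULL
  (sigma + t(sigma)) / 2
}

#' Decompose a covariance matrix into modified Cholesky factors
#'
#' Inverse of \code{\link{build_sigma}}: given a symmetric positive definite
#' \eqn{\Sigma}, returns \code{phi} and \code{lam} such that
#' \code{build_sigma(sigma_to_factors(sigma))} reconstructs \eqn{\Sigma}.
#'
#' @param sigma Symmetric positive definite matrix.
#' @return A \code{\link{chol_factors}} object.
#' @export
sigma_to_factors <- function(sigma) {
  sigma <- as.matrix(sigma)
  if (!isTRUE(all.equal(sigma, t(sigma), tolerance = 1e-8)))
    stop("'sigma' must be symmetric")
  L <- tryCatch(t(chol(sigma)), error = function(e)
    stop("'sigma' is not positive definite: ", conditionMessage(e)))
  d <- diag(L)
  Tm <- diag(d) %*% backsolve(L, diag(nrow(L)), upper.tri = FALSE)  # unit lower tri
  phi <- diag(nrow(L)) - Tm
  phi[abs(phi) < .Machine$double.eps * 100] <- phi[abs(phi) < .Machine$double.eps * 100]
  phi[upper.tri(phi, diag = TRUE)] <- 0
  chol_factors(phi, log(d))
}

#' Moments implied by mean and Cholesky factors
#'
#' @param mu Mean vector.
#' @param factors A \code{\link{chol_factors}} object.
#' @return List of class \code{"mvn_params"} with elements \code{mu},
#'   \code{sigma}, \code{sd} (marginal standard deviations) and \code{rho}
#'   (correlation matrix).
#' @export
mvn_params <- function(mu, factors) {
  sigma <- build_sigma(factors)
  sd <- sqrt(diag(sigma))
  rho <- sigma / tcrossprod(sd)
  structure(list(mu = mu, sigma = sigma, sd = sd, rho = rho), class = "mvn_params")
}

#' Log-density of the MVN distribution from its Cholesky factors
#'
#' Evaluates the multivariate Gaussian log-density directly from the modified
#' Cholesky factors, without forming \eqn{\Sigma}:
#' \deqn{\log f(y) = -\tfrac12 \|D^{-1} T (y - \mu)\|^2 - \sum_m \lambda_m -
#'   \tfrac{M}{2}\log 2\pi.}
#'
#' @param y Numeric vector of length M, or an n x M matrix of observations.
#' @param mu Mean vector (length M) or n x M matrix.
#' @param factors A \code{\link{chol_factors}} object.
#' @param log Return the log-density (default) or the density.
#' @return Numeric vector of (log-)density values, one per row of \code{y}.
#' @export
dmvn_chol <- function(y, mu, factors, log = TRUE) {
  if (!inherits(factors, "chol_factors"))
    factors <- chol_factors(factors$phi, factors$lam)
  M <- factors$M
  y <- if (is.matrix(y)) y else matrix(y, ncol = M)
  mu <- if (is.matrix(mu)) mu else matrix(mu, nrow(y), M, byrow = TRUE)
  if (!all(is.finite(y)) || !all(is.finite(mu))) stop("non-finite 'y' or 'mu'")
  Tm <- diag(M) - factors$phi
  u <- tcrossprod(y - mu, Tm)                      # rows are T (y - mu)
  v <- sweep(u, 2L, exp(factors$lam), "/")
  ll <- -0.5 * rowSums(v^2) - sum(factors$lam) - (M / 2) * log(2 * pi)
  if (log) ll else exp(ll)
}

#' Draw samples from the MVN distribution given its Cholesky factors
#'
#' Samples via \eqn{y = \mu + T^{-1} D z} with standard normal \eqn{z}.
#'
#' @param n Number of draws (n >= 0).
#' @param mu Mean vector of length M.
#' @param factors A \code{\link{chol_factors}} object.
#' @param seed Optional integer seed for reproducibility.
#' @return An n x M matrix (with response names as columns when M = 4).
#' @export
rmvn_chol <- function(n, mu, factors, seed = NULL) {
  if (length(n) != 1L || is.na(n) || n < 0) stop("'n' must be a non-negative count")
  if (!is.null(seed)) set.seed(seed)
  if (!inherits(factors, "chol_factors"))
    factors <- chol_factors(factors$phi, factors$lam)
  M <- factors$M
  Tm <- diag(M) - factors$phi
  A <- backsolve(Tm, diag(M), upper.tri = FALSE)
  B <- A %*% diag(exp(factors$lam), M)            # T^{-1} D
  z <- matrix(stats::rnorm(n * M), ncol = M)
  y <- sweep(z %*% t(B), 2L, mu, "+")
  colnames(y) <- if (M == 4L) response_names() else NULL
  y
}

#' Tail probability of a Gaussian marginal at a clinical threshold
#'
#' Computes \eqn{P(Y < c)} (tail \code{"below"}) or \eqn{P(Y > c)} (tail
#' \code{"above"}) for a Gaussian marginal with mean \code{mu} and standard
#' deviation \code{sd}.  This is the prevalence operator behind anemia
#' (Hb < 110 g/L), stunting (HAZ < -2), underweight (WAZ < -2), wasting
#' (WHZ < -2) and overweight (z > 2).
#'
#' @param mu Marginal mean(s).
#' @param sd Marginal standard deviation(s); must be positive.
#' @param cut Threshold on the response scale.
#' @param tail \code{"below"} or \code{"above"}.
#' @return Probabilities, recycled over the longest argument.
#' @examples
#' threshold_probability(110, 15, 110, "below")  # 0.5 at the threshold
#' threshold_probability(-1, 1, -2, "below")     # pnorm(-1)
#' @export
threshold_probability <- function(mu, sd, cut, tail = c("below", "above")) {
  tail <- match.arg(tail)
  if (any(!is.finite(sd)) || any(sd <= 0)) stop("'sd' must be positive and finite")
  p <- stats::pnorm(cut, mean = mu, sd = sd)
  if (tail == "below") p else 1 - p
}

## ---------------------------------------------------------------------------
## Vectorised per-observation kernels (M = 4).  A parameter set for n rows is
## a list par = list(mu = n x 4, lam = n x 4, phi = n x 6), phi columns in the
## serialisation order (21, 31, 32, 41, 42, 43).  These are the hot loops of
## boosting and MCMC, so they stay allocation-light and purely vectorised.
## ---------------------------------------------------------------------------

# eta (n x 14, columns par_labels()) -> par list
.eta_to_par <- function(eta) {
  list(mu = eta[, 1:4, drop = FALSE],
       lam = eta[, 5:8, drop = FALSE],
       phi = eta[, 9:14, drop = FALSE])
}

# innovations u = T (y - mu), one row per observation
.residual_innovations <- function(y, par) {
  r <- y - par$mu
  p <- par$phi
  cbind(r[, 1L],
        r[, 2L] - p[, 1L] * r[, 1L],
        r[, 3L] - p[, 2L] * r[, 1L] - p[, 3L] * r[, 2L],
        r[, 4L] - p[, 4L] * r[, 1L] - p[, 5L] * r[, 2L] - p[, 6L] * r[, 3L])
}

# joint Gaussian log-density per row
.ll_rows <- function(y, par) {
  u <- .residual_innovations(y, par)
  v <- u * exp(-par$lam)
  -0.5 * rowSums(v * v) - rowSums(par$lam) - 2 * log(2 * pi)
}

# score d loglik / d eta_k per row, for all 14 predictors
.grad_rows <- function(y, par) {
  r <- y - par$mu
  p <- par$phi
  u <- .residual_innovations(y, par)
  e2 <- exp(-2 * par$lam)
  w <- u * e2                                    # D^{-2} T r
  g_mu <- cbind(w[, 1L] - p[, 1L] * w[, 2L] - p[, 2L] * w[, 3L] - p[, 4L] * w[, 4L],
                w[, 2L] - p[, 3L] * w[, 3L] - p[, 5L] * w[, 4L],
                w[, 3L] - p[, 6L] * w[, 4L],
                w[, 4L])
  g_lam <- u * u * e2 - 1
  g_phi <- cbind(w[, 2L] * r[, 1L],
                 w[, 3L] * r[, 1L], w[, 3L] * r[, 2L],
                 w[, 4L] * r[, 1L], w[, 4L] * r[, 2L], w[, 4L] * r[, 3L])
  g <- cbind(g_mu, g_lam, g_phi)
  colnames(g) <- par_labels()
  g
}

# positive IWLS working weights per row (expected information for mu and lam,
# observed for phi, which is exact conditional on the other responses)
.weights_rows <- function(y, par) {
  r <- y - par$mu
  p <- par$phi
  e2 <- exp(-2 * par$lam)
  w_mu <- cbind(e2[, 1L] + p[, 1L]^2 * e2[, 2L] + p[, 2L]^2 * e2[, 3L] + p[, 4L]^2 * e2[, 4L],
                e2[, 2L] + p[, 3L]^2 * e2[, 3L] + p[, 5L]^2 * e2[, 4L],
                e2[, 3L] + p[, 6L]^2 * e2[, 4L],
                e2[, 4L])
  w_lam <- matrix(2, nrow(r), 4L)
  w_phi <- cbind(e2[, 2L] * r[, 1L]^2,
                 e2[, 3L] * r[, 1L]^2, e2[, 3L] * r[, 2L]^2,
                 e2[, 4L] * r[, 1L]^2, e2[, 4L] * r[, 2L]^2, e2[, 4L] * r[, 3L]^2)
  w <- cbind(w_mu, w_lam, w_phi)
  colnames(w) <- par_labels()
  w
}

# per-row marginal sd (n x 4) and pairwise correlations (n x 6) from par.
# Column order of rho matches the phi serialisation: pairs
# (2,1) (3,1) (3,2) (4,1) (4,2) (4,3) in response order (hb, haz, waz, whz).
.par_moments <- function(par) {
  p <- par$phi
  d2 <- exp(2 * pmax(par$lam, log(1e-8)))        # floor exp(lam) at 1e-8
  a21 <- p[, 1L]
  a31 <- p[, 2L] + p[, 3L] * p[, 1L]
  a32 <- p[, 3L]
  a41 <- p[, 4L] + p[, 5L] * a21 + p[, 6L] * a31
  a42 <- p[, 5L] + p[, 6L] * a32
  a43 <- p[, 6L]
  s11 <- d2[, 1L]
  s21 <- a21 * d2[, 1L]
  s22 <- a21^2 * d2[, 1L] + d2[, 2L]
  s31 <- a31 * d2[, 1L]
  s32 <- a31 * a21 * d2[, 1L] + a32 * d2[, 2L]
  s33 <- a31^2 * d2[, 1L] + a32^2 * d2[, 2L] + d2[, 3L]
  s41 <- a41 * d2[, 1L]
  s42 <- a41 * a21 * d2[, 1L] + a42 * d2[, 2L]
  s43 <- a41 * a31 * d2[, 1L] + a42 * a32 * d2[, 2L] + a43 * d2[, 3L]
  s44 <- a41^2 * d2[, 1L] + a42^2 * d2[, 2L] + a43^2 * d2[, 3L] + d2[, 4L]
  sd <- sqrt(cbind(s11, s22, s33, s44))
  colnames(sd) <- response_names()
  rho <- cbind(s21 / (sd[, 2L] * sd[, 1L]),
               s31 / (sd[, 3L] * sd[, 1L]),
               s32 / (sd[, 3L] * sd[, 2L]),
               s41 / (sd[, 4L] * sd[, 1L]),
               s42 / (sd[, 4L] * sd[, 2L]),
               s43 / (sd[, 4L] * sd[, 3L]))
  colnames(rho) <- cor_labels()
  list(sd = sd, rho = rho)
}

#' Labels of the six pairwise correlations
#'
#' Pair order follows the Cholesky serialisation (2,1), (3,1), (3,2), (4,1),
#' (4,2), (4,3) over the fixed response ordering (hb, haz, waz, whz).
#'
#' @return Character vector of length 6, e.g. \code{"cor_hb_haz"}.
#' @export
cor_labels <- function() {
  rn <- response_names()
  idx <- .phi_index()
  paste0("cor_", rn[idx[, 2L]], "_", rn[idx[, 1L]])
}

# draw one response row per observation given par (used by the generator and
# by posterior-predictive simulation); z optionally supplied for reuse
.sample_rows <- function(par, z = NULL) {
  n <- nrow(par$mu)
  if (is.null(z)) z <- matrix(stats::rnorm(n * 4L), n, 4L)
  u <- z * exp(par$lam)
  p <- par$phi
  y1 <- u[, 1L]
  y2 <- u[, 2L] + p[, 1L] * y1
  y3 <- u[, 3L] + p[, 2L] * y1 + p[, 3L] * y2
  y4 <- u[, 4L] + p[, 4L] * y1 + p[, 5L] * y2 + p[, 6L] * y3
  y <- cbind(y1, y2, y3, y4) + par$mu
  colnames(y) <- response_names()
  y
}

# flatten per-row factors for a single shared parameter vector (theta: 14)
.theta_to_par <- function(theta, n) {
  .eta_to_par(matrix(theta, n, 14L, byrow = TRUE))
}
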