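# Shared helpers for the test suite.  Fixtures are built in code; anything
# stochastic takes an explicit seed.

# random symmetric positive definite matrix via A'A + eps I
rand_spd <- function(M = 4L, jitter = 0.1) {
  A <- matrix(rnorm(M * M), M, M)
  crossprod(A) + diag(jitter, M)
}

# dense-matrix MVN log-density oracle: explicit covariance, determinant and
# quadratic form -- independent of the factor-based implementation path
dense_mvn_logdens <- function(y, mu, sigma) {
  M <- length(mu)
  quad <- stats::mahalanobis(matrix(y, ncol = M), center = mu, cov = sigma)
  -0.5 * (quad + determinant(sigma, logarithm = TRUE)$modulus[1] + M * log(2 * pi))
}

# small synthetic survey for smoke tests of the full pipeline
quick_survey <- function(n_clusters = 40, seed = 1, ...) {
  cfg <- synth_config(n_clusters = n_clusters, children_per_cluster = c(8, 12), ...)
  simulate_survey(cfg, seed = seed)
}
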