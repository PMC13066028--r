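# Additive predictor machinery.  Each of the 14 distributional parameters has
# a term list; terms are built once on training data (freezing knots, factor
# levels and centering constraints) and can then be evaluated on new data.

#' Term constructors for additive predictors
#'
#' Build term specifications for the additive predictor of a distributional
#' parameter: an intercept, a linear effect, a penalised B-spline (P-spline)
#' smooth, a tensor-product spatial smooth over (lon, lat), or a dummy-coded
#' factor effect.
#'
#' @param covariate Name of the covariate column (one numeric column for
#'   \code{term_linear}/\code{term_pspline}, a factor column for
#'   \code{term_factor}).
#' @param k Number of marginal basis functions (P-spline default 20; spatial
#'   default 10 per margin, i.e. up to 100 tensor coefficients).
#' @param degree B-spline degree (default cubic).
#' @param penalty_order Order of the difference penalty (default 2).
#' @param lon,lat Names of the coordinate columns for the spatial term.
#' @return A list of class \code{"term_spec"}.
#' @export
term_pspline <- function(covariate, k = 20, degree = 3, penalty_order = 2) {
  stopifnot(is.character(covariate), length(covariate) == 1L)
  if (k < penalty_order + 1) stop("'k' must be at least penalty_order + 1")
  if (k < degree + 1) stop("'k' must be at least degree + 1")
  structure(list(kind = "pspline", covariate = covariate, k = k, degree = degree,
                 penalty_order = penalty_order, label = paste0("s(", covariate, ")")),
            class = "term_spec")
}

#' @rdname term_pspline
#' @export
term_intercept <- function() {
  structure(list(kind = "intercept", label = "intercept"), class = "term_spec")
}

#' @rdname term_pspline
#' @export
term_linear <- function(covariate) {
  stopifnot(is.character(covariate), length(covariate) == 1L)
  structure(list(kind = "linear", covariate = covariate, label = covariate),
            class = "term_spec")
}

#' @rdname term_pspline
#' @export
term_spatial <- function(lon = "lon", lat = "lat", k = 10, degree = 3,
                         penalty_order = 2) {
  structure(list(kind = "spatial2d", covariate = c(lon, lat), k = k,
                 degree = degree, penalty_order = penalty_order,
                 label = paste0("s(", lon, ",", lat, ")")),
            class = "term_spec")
}

#' @rdname term_pspline
#' @export
term_factor <- function(covariate) {
  stopifnot(is.character(covariate), length(covariate) == 1L)
  structure(list(kind = "factor", covariate = covariate, label = covariate),
            class = "term_spec")
}

#' @export
print.term_spec <- function(x, ...) {
  cat("term:", x$label, "(", x$kind, ")\n")
  invisible(x)
}

#' P-spline basis and difference penalty
#'
#' Evaluates \code{k} B-spline basis functions of the given degree on
#' equidistant knots spanning \code{range(x)} (expanded by \code{degree} outer
#' knots on each side) and the corresponding difference-penalty matrix
#' \eqn{K = \Delta' \Delta}.  Rows of the basis matrix sum to one (partition of
#' unity); evaluation outside the knot range is clamped to the boundary.
#'
#' @inheritParams term_pspline
#' @param x Numeric vector of covariate values.
#' @param boundary Optional length-2 numeric giving the knot range to freeze
#'   (defaults to \code{range(x)}).
#' @return A list of class \code{"design_block"} with the n x k basis
#'   \code{X}, the k x k penalty \code{K}, and the knot vector.
#' @examples
#' b <- pspline_basis(runif(50, 6, 59), k = 10)
#' range(rowSums(b$X))  # partition of unity
#' @export
pspline_basis <- function(x, k = 20, degree = 3, penalty_order = 2,
                          boundary = NULL) {
  if (!all(is.finite(x))) stop("'x' must be finite")
  if (is.null(boundary)) boundary <- range(x)
  if (diff(boundary) <= 0) boundary <- boundary + c(-0.5, 0.5)
  if (length(unique(x)) < k)
    warning("fewer distinct covariate values than basis functions; ",
            "the basis is rank deficient", call. = FALSE)
  h <- diff(boundary) / (k - degree)
  knots <- boundary[1] + h * ((-degree):k)
  # clamp to the spline's exact support (guards floating-point at the ends)
  xc <- pmin(pmax(x, knots[degree + 1L]), knots[k + 1L])
  X <- splines::splineDesign(knots, xc, ord = degree + 1)
  D <- diff(diag(k), differences = penalty_order)
  structure(list(X = X, K = crossprod(D), knots = knots, degree = degree,
                 boundary = boundary, penalty_order = penalty_order),
            class = "design_block")
}

#' Tensor-product spatial P-spline basis
#'
#' Row-wise tensor product of marginal P-spline bases over longitude and
#' latitude with a Kronecker-sum difference penalty
#' \eqn{K = K_{lon} \otimes I + I \otimes K_{lat}}.  Evaluation outside the
#' training bounding box is clamped to the boundary.
#'
#' @inheritParams pspline_basis
#' @param lon,lat Numeric coordinate vectors (decimal degrees).
#' @param bbox Optional list with elements \code{lon} and \code{lat} (each a
#'   length-2 range) freezing the bounding box.
#' @return A \code{"design_block"} with the n x k^2 tensor basis and penalty.
#' @export
spatial2d_basis <- function(lon, lat, k = 10, degree = 3, penalty_order = 2,
                            bbox = NULL) {
  if (!all(is.finite(lon)) || !all(is.finite(lat))) stop("coordinates must be finite")
  if (length(unique(lon)) == 1L && length(unique(lat)) == 1L && is.null(bbox))
    stop("degenerate spatial term: all locations identical")
  if (is.null(bbox)) bbox <- list(lon = range(lon), lat = range(lat))
  bl <- pspline_basis(lon, k, degree, penalty_order, boundary = bbox$lon)
  bt <- pspline_basis(lat, k, degree, penalty_order, boundary = bbox$lat)
  X <- bl$X[, rep(seq_len(k), each = k), drop = FALSE] *
       bt$X[, rep(seq_len(k), times = k), drop = FALSE]
  K <- kronecker(bl$K, diag(k)) + kronecker(diag(k), bt$K)
  structure(list(X = X, K = K, knots = list(lon = bl$knots, lat = bt$knots),
                 degree = degree, bbox = bbox, k = k,
                 penalty_order = penalty_order),
            class = "design_block")
}

## ---------------------------------------------------------------------------
## Model specification
## ---------------------------------------------------------------------------

#' Specify the additive model for all 14 distributional parameters
#'
#' Maps each distributional parameter (see \code{\link{par_labels}}) to a list
#' of terms.  An intercept is always included for every parameter; additional
#' terms are supplied per parameter.  Means and Cholesky coefficients use the
#' identity link; innovation scales are modelled on the log scale.
#'
#' @param ... Named arguments, one per parameter label, each a list of
#'   \code{\link{term_pspline}}-style term specifications (a single term may be
#'   given without wrapping in a list).
#' @param .all A list of terms appended to every one of the 14 parameters
#'   (convenient for candidate sets in boosting).
#' @return An object of class \code{"mvdr_spec"}.
#' @examples
#' spec <- mvdr_spec(mu_haz = list(term_pspline("age"), term_spatial()),
#'                   mu_hb  = term_pspline("age"))
#' @export
mvdr_spec <- function(..., .all = NULL) {
  extra <- list(...)
  labs <- par_labels()
  bad <- setdiff(names(extra), labs)
  if (length(bad)) stop("unknown parameter label(s): ", paste(bad, collapse = ", "))
  norm_terms <- function(x) {
    if (is.null(x)) return(list())
    if (inherits(x, "term_spec")) return(list(x))
    stopifnot(all(vapply(x, inherits, TRUE, "term_spec")))
    x
  }
  if (!is.null(.all)) .all <- norm_terms(.all)
  pt <- lapply(labs, function(lab) {
    tl <- c(list(term_intercept()), norm_terms(extra[[lab]]), .all)
    names(tl) <- vapply(tl, `[[`, "", "label")
    if (anyDuplicated(names(tl))) stop("duplicate term labels for ", lab)
    tl
  })
  names(pt) <- labs
  structure(list(parameter_terms = pt), class = "mvdr_spec")
}

#' @export
print.mvdr_spec <- function(x, ...) {
  cat("Multivariate distributional regression specification (14 parameters)\n")
  for (lab in names(x$parameter_terms)) {
    tl <- x$parameter_terms[[lab]]
    cat(sprintf("  %-8s ~ %s\n", lab, paste(names(tl), collapse = " + ")))
  }
  invisible(x)
}

#' Number of non-intercept terms per parameter
#' @param spec An \code{\link{mvdr_spec}}.
#' @return Named integer vector over the 14 parameters.
#' @export
n_terms <- function(spec) {
  vapply(spec$parameter_terms, function(tl) sum(names(tl) != "intercept"), 0L)
}

#' Write or read a model specification as YAML
#'
#' Round-trips an \code{\link{mvdr_spec}} through a YAML file of the form
#' \code{parameters: {mu_haz: [{kind: pspline, covariate: age, k: 20}, ...]}}.
#'
#' @param spec An \code{\link{mvdr_spec}}.
#' @param path File path.
#' @return \code{spec_to_yaml} returns \code{path} invisibly;
#'   \code{spec_from_yaml} returns the reconstructed \code{mvdr_spec}.
#' @export
spec_to_yaml <- function(spec, path) {
  stopifnot(inherits(spec, "mvdr_spec"))
  out <- lapply(spec$parameter_terms, function(tl) {
    tl <- tl[names(tl) != "intercept"]
    unname(lapply(tl, function(tm) tm[setdiff(names(tm), "label")]))
  })
  yaml::write_yaml(list(parameters = out), path)
  invisible(path)
}

#' @rdname spec_to_yaml
#' @export
spec_from_yaml <- function(path) {
  raw <- yaml::read_yaml(path)$parameters
  args <- lapply(raw, function(terms) {
    lapply(terms, function(tm) {
      switch(tm$kind,
        intercept = term_intercept(),
        linear    = term_linear(tm$covariate),
        factor    = term_factor(tm$covariate),
        pspline   = term_pspline(tm$covariate, k = tm$k %||% 20,
                                 degree = tm$degree %||% 3,
                                 penalty_order = tm$penalty_order %||% 2),
        spatial2d = term_spatial(tm$covariate[1], tm$covariate[2],
                                 k = tm$k %||% 10, degree = tm$degree %||% 3,
                                 penalty_order = tm$penalty_order %||% 2),
        stop("unknown term kind: ", tm$kind))
    })
  })
  do.call(mvdr_spec, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---------------------------------------------------------------------------
## Building frozen designs and evaluating predictors
## ---------------------------------------------------------------------------

# build one term on training data -> frozen state (knots, levels, centering)
.build_term <- function(term, data) {
  need <- term$covariate
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("covariate column(s) missing from data: ", paste(miss, collapse = ", "))
  st <- switch(term$kind,
    intercept = list(p = 1L),
    linear = {
      x <- data[[term$covariate]]
      s <- stats::sd(x)
      list(center = mean(x), scale = if (is.finite(s) && s > 0) s else 1, p = 1L)
    },
    factor = {
      lev <- levels(factor(data[[term$covariate]]))
      list(levels = lev, p = length(lev) - 1L)
    },
    pspline = {
      b <- pspline_basis(data[[term$covariate]], term$k, term$degree,
                         term$penalty_order)
      list(knots = b$knots, boundary = b$boundary, K = b$K, p = term$k)
    },
    spatial2d = {
      b <- spatial2d_basis(data[[term$covariate[1]]], data[[term$covariate[2]]],
                           term$k, term$degree, term$penalty_order)
      list(knots = b$knots, bbox = b$bbox, K = b$K, p = term$k^2)
    },
    stop("unknown term kind: ", term$kind))
  st$term <- term
  # sum-to-zero centering for penalised smooths (identifiability next to the
  # intercept): X -> X Z with Z the orthogonal complement of colSums(X)
  if (term$kind %in% c("pspline", "spatial2d")) {
    X <- .eval_term_raw(st, data)
    C <- matrix(colSums(X), nrow = 1L)
    Z <- qr.Q(qr(t(C)), complete = TRUE)[, -1L, drop = FALSE]
    st$Z <- Z
    st$K <- crossprod(Z, st$K %*% Z)
    st$p <- ncol(Z)
  }
  class(st) <- "mvdr_term_state"
  st
}

# raw (uncentered) design of a frozen term on arbitrary data
.eval_term_raw <- function(st, data) {
  tm <- st$term
  n <- nrow(data)
  switch(tm$kind,
    intercept = matrix(1, n, 1L),
    linear = {
      x <- data[[tm$covariate]]
      if (is.null(x)) stop("covariate column missing from data: ", tm$covariate)
      matrix((x - st$center) / st$scale, ncol = 1L)
    },
    factor = {
      x <- factor(data[[tm$covariate]], levels = st$levels)
      if (anyNA(x)) stop("unseen level in factor covariate ", tm$covariate)
      stats::model.matrix(~x)[, -1L, drop = FALSE]
    },
    pspline = {
      x <- data[[tm$covariate]]
      if (is.null(x)) stop("covariate column missing from data: ", tm$covariate)
      deg <- tm$degree
      k <- length(st$knots) - deg - 1L
      xc <- pmin(pmax(x, st$knots[deg + 1L]), st$knots[k + 1L])
      splines::splineDesign(st$knots, xc, ord = deg + 1)
    },
    spatial2d = {
      lon <- data[[tm$covariate[1]]]; lat <- data[[tm$covariate[2]]]
      if (is.null(lon) || is.null(lat))
        stop("coordinate column missing from data")
      k <- tm$k; deg <- tm$degree
      bl <- splines::splineDesign(st$knots$lon,
              pmin(pmax(lon, st$knots$lon[deg + 1L]), st$knots$lon[k + 1L]),
              ord = deg + 1)
      bt <- splines::splineDesign(st$knots$lat,
              pmin(pmax(lat, st$knots$lat[deg + 1L]), st$knots$lat[k + 1L]),
              ord = deg + 1)
      bl[, rep(seq_len(k), each = k), drop = FALSE] *
        bt[, rep(seq_len(k), times = k), drop = FALSE]
    })
}

# centered design used in fitting/prediction
.eval_term <- function(st, data) {
  X <- .eval_term_raw(st, data)
  if (!is.null(st$Z)) X <- X %*% st$Z
  X
}

# build all terms for all 14 parameters; returns class "mvdr_designs"
.build_designs <- function(spec, data) {
  stopifnot(inherits(spec, "mvdr_spec"))
  params <- lapply(spec$parameter_terms, function(tl)
    lapply(tl, .build_term, data = data))
  structure(list(params = params, spec = spec), class = "mvdr_designs")
}

# zero coefficient template matching a design set
.zero_coefs <- function(designs) {
  lapply(designs$params, function(tl) lapply(tl, function(st) numeric(st$p)))
}

#' Evaluate the additive predictors and implied distribution parameters
#'
#' Computes \eqn{\eta_k = \sum_t X_t \beta_t} for each of the 14
#' distributional parameters and maps them to per-observation distribution
#' parameters: means, marginal standard deviations and pairwise correlations
#' (via the modified Cholesky reconstruction).
#'
#' @param spec An \code{\link{mvdr_spec}}.
#' @param data Data frame holding all covariates named in the spec.
#' @param coefs Nested list of coefficients, \code{coefs[[parameter]][[term]]}
#'   (as produced by the fitting functions; missing entries count as zero).
#' @param designs Optional pre-built designs (internal use); when supplied,
#'   knots and levels frozen at build time are reused.
#' @return A list with \code{eta} (n x 14 matrix), \code{mu} (n x 4),
#'   \code{sd} (n x 4), \code{rho} (n x 6) and the internal parameter list
#'   \code{par}.
#' @export
evaluate_predictor <- function(spec, data, coefs, designs = NULL) {
  if (is.null(designs)) designs <- .build_designs(spec, data)
  eta <- .eval_eta(designs, data, coefs)
  par <- .eta_to_par(eta)
  mom <- .par_moments(par)
  list(eta = eta, mu = structure(par$mu, dimnames = list(NULL, response_names())),
       sd = mom$sd, rho = mom$rho, par = par)
}

# eta matrix (n x 14) from designs + nested coefficient list
.eval_eta <- function(designs, data, coefs) {
  labs <- par_labels()
  n <- nrow(data)
  eta <- matrix(0, n, 14L, dimnames = list(NULL, labs))
  for (j in seq_along(labs)) {
    lab <- labs[j]
    tl <- designs$params[[lab]]
    for (tn in names(tl)) {
      b <- coefs[[lab]][[tn]]
      if (is.null(b) || all(b == 0)) next
      eta[, j] <- eta[, j] + drop(.eval_term(tl[[tn]], data) %*% b)
    }
  }
  eta
}
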