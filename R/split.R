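# Spatially representative train/test splitting.  Survey clusters (PSUs) are
# triangulated (Delaunay); test clusters are chosen whole-cluster by
# farthest-point sampling over the triangulation adjacency so that the test
# set spreads across the sampled region instead of clumping, and children of
# one cluster never straddle the two partitions.

# adjacency list + hull from a Delaunay triangulation of cluster sites;
# returns NULL on degenerate geometry
.triangulate <- function(lon, lat) {
  # collinear sites admit no proper triangulation
  sv <- svd(cbind(lon - mean(lon), lat - mean(lat)), nu = 0, nv = 0)$d
  if (sv[2] < 1e-10 * max(sv[1], 1)) return(NULL)
  tri <- tryCatch(
    suppressMessages(deldir::deldir(lon, lat, suppressMsge = TRUE)),
    error = function(e) NULL)
  if (is.null(tri) || nrow(tri$delsgs) == 0L) return(NULL)
  edges <- as.matrix(tri$delsgs[, c("ind1", "ind2")])
  adj <- vector("list", length(lon))
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1L]; b <- edges[i, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  hull <- grDevices::chull(lon, lat)
  list(edges = edges, adj = adj, hull = hull)
}

# multi-source BFS hop distances over an adjacency list
.hop_distance <- function(adj, sources) {
  d <- rep.int(NA_integer_, length(adj))
  d[sources] <- 0L
  frontier <- sources
  step <- 0L
  while (length(frontier)) {
    step <- step + 1L
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- nxt[is.na(d[nxt])]
    d[nxt] <- step
    frontier <- nxt
  }
  d[is.na(d)] <- length(adj)  # disconnected components count as far
  d
}

# farthest-point sampling of n_pick vertices over triangulation adjacency;
# interior vertices (not on the convex hull) are preferred so selected test
# sites sit inside the train hull (interpolation rather than extrapolation)
.select_spread <- function(adj, hull, n_pick) {
  n <- length(adj)
  interior <- setdiff(seq_len(n), hull)
  if (!length(interior)) interior <- seq_len(n)
  picked <- interior[sample.int(length(interior), 1L)]
  while (length(picked) < n_pick) {
    d <- .hop_distance(adj, picked)
    d[picked] <- -1L
    pool <- if (any(d[interior] > 0)) interior else seq_len(n)
    dmax <- max(d[pool])
    cand <- pool[d[pool] == dmax]
    picked <- c(picked, cand[sample.int(length(cand), 1L)])
  }
  picked
}

#' Spatially representative train/test split via Delaunay triangulation
#'
#' Splits survey clusters into a training and a test partition at the cluster
#' (PSU) level.  The cluster sites are Delaunay-triangulated and test clusters
#' are picked by farthest-point sampling over the triangulation adjacency,
#' preferring interior vertices, which spreads the held-out clusters across
#' the convex hull of the survey region.  Degenerate geometry (fewer than four
#' sites, collinear sites) falls back to a seeded random split with a warning.
#'
#' @param clusters Data frame with one row per cluster and columns
#'   \code{cluster} (id), \code{lon}, \code{lat}.
#' @param frac_train Target training fraction in (0, 1); default 0.8.
#' @param seed Optional integer seed; fixed seeds give identical splits.
#' @return An object of class \code{"mvdr_split"}: list with
#'   \code{train_clusters}, \code{test_clusters} (cluster ids), \code{edges}
#'   (triangulation edges as index pairs), \code{hull} (indices of hull
#'   vertices) and \code{method} (\code{"delaunay"} or \code{"random"}).
#' @examples
#' cl <- data.frame(cluster = 1:30, lon = runif(30), lat = runif(30))
#' sp <- delaunay_split(cl, 0.8, seed = 1)
#' length(sp$test_clusters) / 30
#' @export
delaunay_split <- function(clusters, frac_train = 0.8, seed = NULL) {
  stopifnot(all(c("cluster", "lon", "lat") %in% names(clusters)))
  if (anyDuplicated(clusters$cluster)) stop("duplicated cluster ids")
  if (frac_train <= 0 || frac_train >= 1) stop("'frac_train' must be in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(clusters)
  n_test <- max(1L, round((1 - frac_train) * n))
  if (n_test >= n) stop("too few clusters for the requested split")
  tri <- if (n >= 4L) .triangulate(clusters$lon, clusters$lat) else NULL
  if (is.null(tri)) {
    warning("degenerate cluster geometry; falling back to a random split",
            call. = FALSE)
    test_idx <- sample.int(n, n_test)
    method <- "random"
    edges <- matrix(integer(), 0L, 2L)
    hull <- integer()
  } else {
    test_idx <- .select_spread(tri$adj, tri$hull, n_test)
    method <- "delaunay"
    edges <- tri$edges
    hull <- tri$hull
  }
  structure(list(
    train_clusters = clusters$cluster[-test_idx],
    test_clusters = clusters$cluster[test_idx],
    edges = edges, hull = hull, coords = clusters[, c("cluster", "lon", "lat")],
    frac_train = frac_train, method = method), class = "mvdr_split")
}

#' @export
print.mvdr_split <- function(x, ...) {
  n <- length(x$train_clusters) + length(x$test_clusters)
  cat(sprintf("Cluster-level %s split: %d train / %d test clusters (test fraction %.2f)\n",
              x$method, length(x$train_clusters), length(x$test_clusters),
              length(x$test_clusters) / n))
  invisible(x)
}

#' Apply a cluster-level split to child observations
#'
#' @param split An \code{\link{delaunay_split}} result.
#' @param data Observation table with a \code{cluster} column.
#' @return List with integer row indices \code{train} and \code{test};
#'   together they partition \code{seq_len(nrow(data))}.
#' @export
split_observations <- function(split, data) {
  stopifnot(inherits(split, "mvdr_split"), "cluster" %in% names(data))
  test <- which(data$cluster %in% split$test_clusters)
  train <- which(data$cluster %in% split$train_clusters)
  if (length(train) + length(test) != nrow(data))
    stop("observations reference clusters absent from the split")
  list(train = train, test = test)
}

#' Spatially spread cross-validation folds at cluster level
#'
#' Forms \code{k} folds by repeatedly applying the farthest-point selection of
#' \code{\link{delaunay_split}} to the not-yet-assigned clusters, so each fold
#' is spread over the survey region rather than forming one contiguous block.
#'
#' @inheritParams delaunay_split
#' @param k Number of folds (>= 2).
#' @return Integer vector of fold labels (1..k), one per row of
#'   \code{clusters}.
#' @export
spatial_folds <- function(clusters, k = 5, seed = NULL) {
  stopifnot(all(c("cluster", "lon", "lat") %in% names(clusters)))
  if (k < 2) stop("'k' must be at least 2")
  n <- nrow(clusters)
  if (n < k) stop("too few clusters for ", k, " folds")
  if (!is.null(seed)) set.seed(seed)
  fold <- rep.int(NA_integer_, n)
  for (f in seq_len(k - 1L)) {
    remaining <- which(is.na(fold))
    n_pick <- round(length(which(is.na(fold))) / (k - f + 1L))
    n_pick <- max(1L, n_pick)
    tri <- if (length(remaining) >= 4L)
      .triangulate(clusters$lon[remaining], clusters$lat[remaining]) else NULL
    picked_local <- if (is.null(tri)) sample.int(length(remaining), n_pick)
                    else .select_spread(tri$adj, tri$hull, n_pick)
    fold[remaining[picked_local]] <- f
  }
  fold[is.na(fold)] <- k
  fold
}
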