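#' DBSCAN configuration for protomer merging
#'
#' DNA-PAINT produces repeated binding traces on the same protomer; their
#' centers are merged with DBSCAN. The defaults (epsilon 8 nm, minPoints 2)
#' reflect MINFLUX localization precision plus tag flexibility.
#'
#' @param epsilon Neighborhood radius in nm.
#' @param min_points Minimum neighborhood size for a core point. The count
#'   includes the point itself, so `min_points = 2` means "self plus at
#'   least one neighbor" — with that convention the clustering equals the
#'   connected components of the epsilon proximity graph. Implementations
#'   differ on this convention, hence it is spelled out here.
#' @return An object of class `cluster_config`.
#' @export
cluster_config <- function(epsilon = 8, min_points = 2) {
  stopifnot(is.numeric(epsilon), length(epsilon) == 1, epsilon > 0,
            is.numeric(min_points), length(min_points) == 1, min_points >= 1)
  structure(list(epsilon = epsilon, min_points = as.integer(min_points)),
            class = "cluster_config")
}

#' Geometric rules for triple-labelled trimer identification
#'
#' @param pair_max All three pairwise distances must be strictly below this
#'   (nm); 40 nm is the maximum physically possible distance between two
#'   blade-tip tags in the fully flattened conformation.
#' @param isolation_radius No non-member site may lie within this distance
#'   (nm) of any member site.
#' @param angle_max The maximum internal angle of the site triangle must be
#'   strictly below this (degrees); rejects near-collinear artefacts.
#' @return An object of class `trimer_rules`.
#' @export
trimer_rules <- function(pair_max = 40, isolation_radius = 60,
                         angle_max = 120) {
  stopifnot(pair_max > 0, isolation_radius > 0, pair_max < isolation_radius,
            angle_max >= 60, angle_max < 180)
  structure(list(pair_max = pair_max, isolation_radius = isolation_radius,
                 angle_max = angle_max),
            class = "trimer_rules")
}

# DBSCAN on a 3-column coordinate matrix. Returns an integer cluster label
# per point; noise points get their own singleton labels (callers keep
# singleton sites). Distance-matrix implementation: the site sets here are
# at most a few thousand points.
.dbscan3 <- function(xyz, epsilon, min_points) {
  n <- nrow(xyz)
  if (n == 0) return(integer(0))
  if (n == 1) return(1L)
  d <- as.matrix(stats::dist(xyz))
  adj <- d <= epsilon
  deg <- rowSums(adj)             # includes self (diagonal is 0 <= eps)
  core <- deg >= min_points
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue) > 0) {
      p <- queue[[1]]
      queue <- queue[-1]
      nb <- which(adj[p, ])
      for (q in nb) {
        if (labels[q] == 0L) {
          labels[q] <- cl
          if (core[q]) queue <- c(queue, q)
        }
      }
    }
  }
  # remaining unlabelled points are DBSCAN noise: keep as singletons
  for (i in which(labels == 0L)) {
    cl <- cl + 1L
    labels[i] <- cl
  }
  labels
}

#' Merge trace centers into protomer sites
#'
#' Clusters trace centers with DBSCAN in 3D Euclidean metric; every cluster
#' becomes one protomer site at the mean coordinate of its member trace
#' centers. Unclustered singleton centers (protomers detected only once)
#' are retained as single-trace sites.
#'
#' @param centers Trace-center table from [trace_centers()], with z already
#'   corrected.
#' @param config A [cluster_config()].
#' @return Data frame `site_id, x_nm, y_nm, z_nm, n_traces` with a
#'   list-column `tids` of the member trace ids.
#' @export
cluster_protomers <- function(centers, config = cluster_config()) {
  stopifnot(inherits(config, "cluster_config"))
  xyz <- as.matrix(centers[, c("x_nm", "y_nm", "z_nm")])
  labels <- .dbscan3(xyz, config$epsilon, config$min_points)
  if (length(labels) == 0) {
    return(data.frame(site_id = integer(), x_nm = numeric(), y_nm = numeric(),
                      z_nm = numeric(), n_traces = integer()))
  }
  f <- factor(labels, levels = sort(unique(labels)))
  n <- as.vector(table(f))
  pos <- rowsum(xyz, f, reorder = TRUE) / n
  out <- data.frame(site_id = seq_along(n), x_nm = pos[, 1], y_nm = pos[, 2],
                    z_nm = pos[, 3], n_traces = n, row.names = NULL)
  out$tids <- I(split(centers$tid, f))
  out
}

#' Maximum internal angle of a triangle through three 3D points
#'
#' Computed via the law of cosines on the three pairwise distances. For a
#' non-degenerate triangle the result lies in `[60, 180)` degrees.
#'
#' @param p A 3x3 matrix, one point per row.
#' @return Maximum internal angle in degrees.
#' @export
max_internal_angle <- function(p) {
  stopifnot(is.matrix(p), nrow(p) == 3, ncol(p) == 3)
  d <- stats::dist(p)
  if (any(d < .Machine$double.eps^0.5)) {
    stop("degenerate geometry: duplicate points", call. = FALSE)
  }
  a <- d[1]; b <- d[2]; c <- d[3]   # d12, d13, d23
  cosines <- c(
    (a^2 + b^2 - c^2) / (2 * a * b),  # angle at point 1
    (a^2 + c^2 - b^2) / (2 * a * c),  # angle at point 2
    (b^2 + c^2 - a^2) / (2 * b * c)   # angle at point 3
  )
  cosines <- pmin(1, pmax(-1, cosines))
  max(acos(cosines)) * 180 / pi
}

#' Interblade distance of a site triple
#'
#' The interblade distance of a trimer is the arithmetic mean of the three
#' pairwise 3D distances between its protomer sites.
#'
#' @param p A 3x3 matrix of site positions (nm), one per row.
#' @return Mean pairwise distance in nm.
#' @export
interblade_distance <- function(p) {
  stopifnot(is.matrix(p), nrow(p) == 3, ncol(p) == 3)
  mean(stats::dist(p))
}

#' Identify triple-labelled trimers among protomer sites
#'
#' Returns every unordered site triple satisfying all three rules:
#' (i) all three pairwise 3D distances strictly below `pair_max`;
#' (ii) no non-member site within `isolation_radius` of any member;
#' (iii) maximum internal angle of the triangle strictly below `angle_max`.
#'
#' @param sites Protomer-site table from [cluster_protomers()].
#' @param rules A [trimer_rules()].
#' @return Data frame with one row per accepted trimer: member site ids and
#'   coordinates, the three pairwise distances `d12, d13, d23`, the
#'   `interblade_nm` mean distance, `max_angle_deg`, and the per-site trace
#'   counts `n_traces_1..3`.
#' @export
find_trimers <- function(sites, rules = trimer_rules()) {
  stopifnot(inherits(rules, "trimer_rules"))
  empty <- data.frame(
    trimer_id = integer(), site1 = integer(), site2 = integer(),
    site3 = integer(), x1 = numeric(), y1 = numeric(), z1 = numeric(),
    x2 = numeric(), y2 = numeric(), z2 = numeric(), x3 = numeric(),
    y3 = numeric(), z3 = numeric(), d12 = numeric(), d13 = numeric(),
    d23 = numeric(), interblade_nm = numeric(), max_angle_deg = numeric(),
    n_traces_1 = integer(), n_traces_2 = integer(), n_traces_3 = integer())
  n <- nrow(sites)
  if (n < 3) return(empty)
  xyz <- as.matrix(sites[, c("x_nm", "y_nm", "z_nm")])
  d <- as.matrix(stats::dist(xyz))
  close <- d < rules$pair_max
  diag(close) <- FALSE
  # candidate triples: triangles of the pair_max proximity graph
  idx <- seq_len(n)
  triples <- matrix(integer(0), ncol = 3)
  for (i in seq_len(n - 2)) {
    nb_i <- which(close[i, ] & idx > i)
    for (j in nb_i) {
      ks <- which(close[i, ] & close[j, ] & idx > j)
      for (k in ks) triples <- rbind(triples, c(i, j, k))
    }
  }
  if (nrow(triples) == 0) return(empty)
  keep <- logical(nrow(triples))
  angs <- numeric(nrow(triples))
  for (r in seq_len(nrow(triples))) {
    trip <- triples[r, ]
    others <- idx[-trip]
    if (length(others) > 0 &&
        min(d[trip, others]) < rules$isolation_radius) next
    ang <- max_internal_angle(xyz[trip, , drop = FALSE])
    if (ang >= rules$angle_max) next
    keep[r] <- TRUE
    angs[r] <- ang
  }
  triples <- triples[keep, , drop = FALSE]
  if (nrow(triples) == 0) return(empty)
  i <- triples[, 1]; j <- triples[, 2]; k <- triples[, 3]
  dij <- d[cbind(i, j)]; dik <- d[cbind(i, k)]; djk <- d[cbind(j, k)]
  data.frame(
    trimer_id = seq_len(nrow(triples)),
    site1 = sites$site_id[i], site2 = sites$site_id[j],
    site3 = sites$site_id[k],
    x1 = xyz[i, 1], y1 = xyz[i, 2], z1 = xyz[i, 3],
    x2 = xyz[j, 1], y2 = xyz[j, 2], z2 = xyz[j, 3],
    x3 = xyz[k, 1], y3 = xyz[k, 2], z3 = xyz[k, 3],
    d12 = dij, d13 = dik, d23 = djk,
    interblade_nm = (dij + dik + djk) / 3,
    max_angle_deg = angs[keep],
    n_traces_1 = sites$n_traces[i], n_traces_2 = sites$n_traces[j],
    n_traces_3 = sites$n_traces[k], row.names = NULL)
}

#' Maximum-likelihood bivariate Gaussian fit of in-plane localizations
#'
#' Fits mean and covariance of the 2D in-plane (x, y) projection of a
#' protomer's raw localizations. Used for visualization and as an
#' alternative blade-position estimate. The ML mean equals the arithmetic
#' mean of the points; the ML covariance divides by n.
#'
#' @param xy An n x 2 matrix (or data frame) of projected points, n >= 3.
#' @param ridge Ridge added to the covariance diagonal if it is singular.
#' @return An object of class `bivariate_gaussian_fit` with elements
#'   `mean` (length-2), `sigma` (2x2 SPD), `n` and `regularized` flag.
#' @export
fit_bivariate_gaussian <- function(xy, ridge = 1e-9) {
  xy <- as.matrix(xy)
  if (nrow(xy) < 3) {
    stop("insufficient data: bivariate Gaussian fit needs >= 3 points",
         call. = FALSE)
  }
  stopifnot(ncol(xy) == 2)
  mu <- colMeans(xy)
  centered <- sweep(xy, 2, mu)
  sigma <- crossprod(centered) / nrow(xy)
  regularized <- FALSE
  if (det(sigma) <= .Machine$double.eps) {
    sigma <- sigma + diag(ridge, 2)
    regularized <- TRUE
    message("singular covariance regularized with ridge ", ridge)
  }
  structure(list(mean = mu, sigma = sigma, n = nrow(xy),
                 regularized = regularized),
            class = "bivariate_gaussian_fit")
}

#' @export
print.bivariate_gaussian_fit <- function(x, ...) {
  cat("Bivariate Gaussian fit (n =", x$n, ")\n")
  cat("  mean:", format(x$mean, digits = 4), "\n")
  cat("  sds :", format(sqrt(diag(x$sigma)), digits = 4), "\n")
  invisible(x)
}

#' Run filtering, merging and trimer identification in one call
#'
#' Convenience wrapper chaining [filter_pipeline()], [cluster_protomers()]
#' and [find_trimers()].
#'
#' @param locs Raw localization data frame.
#' @param filter A [filter_config()].
#' @param cluster A [cluster_config()].
#' @param rules A [trimer_rules()].
#' @return List with `centers`, `sites`, `trimers` and the filter `report`.
#' @export
trimer_pipeline <- function(locs, filter = filter_config(),
                            cluster = cluster_config(),
                            rules = trimer_rules()) {
  filtered <- filter_pipeline(locs, filter)
  sites <- cluster_protomers(filtered$centers, cluster)
  trimers <- find_trimers(sites, rules)
  list(centers = filtered$centers, sites = sites, trimers = trimers,
       report = filtered$report)
}
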