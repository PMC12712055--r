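# Independent oracles used across tests. These deliberately re-derive
# results by brute force rather than calling the implementation paths they
# check.

# connected components of the eps proximity graph (single linkage), the
# reference partition for DBSCAN with min_points = 2
proximity_components <- function(xyz, eps) {
  n <- nrow(xyz)
  if (n == 0) return(integer(0))
  d <- as.matrix(dist(xyz))
  adj <- d <= eps
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  igraph::components(g)$membership
}

# exhaustive enumeration of accepted site triples under the trimer rules
brute_force_trimers <- function(xyz, pair_max = 40, isolation_radius = 60,
                                angle_max = 120) {
  n <- nrow(xyz)
  if (n < 3) return(matrix(integer(0), ncol = 3))
  d <- as.matrix(dist(xyz))
  trips <- t(combn(n, 3))
  keep <- apply(trips, 1, function(trip) {
    i <- trip[1]; j <- trip[2]; k <- trip[3]
    if (!(d[i, j] < pair_max && d[i, k] < pair_max && d[j, k] < pair_max)) {
      return(FALSE)
    }
    others <- setdiff(seq_len(n), trip)
    if (length(others) > 0 && min(d[trip, others]) < isolation_radius) {
      return(FALSE)
    }
    # internal angles via law of cosines
    a <- d[i, j]; b <- d[i, k]; cc <- d[j, k]
    cosines <- c((a^2 + b^2 - cc^2) / (2 * a * b),
                 (a^2 + cc^2 - b^2) / (2 * a * cc),
                 (b^2 + cc^2 - a^2) / (2 * b * cc))
    max(acos(pmin(1, pmax(-1, cosines)))) * 180 / pi < angle_max
  })
  trips[keep, , drop = FALSE]
}

# canonical form of a set of index triples, for set comparison
triple_set <- function(m) {
  if (nrow(m) == 0) return(character(0))
  sort(apply(t(apply(m, 1, sort)), 1, paste, collapse = "-"))
}

# random rigid motion (proper rotation + translation)
random_rigid_motion <- function(seed) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  list(rotation = q, translation = rnorm(3, 0, 100))
}

apply_rigid <- function(xyz, motion) {
  sweep(as.matrix(xyz) %*% t(motion$rotation), 2, -motion$translation)
}

# build a localization data frame from explicit per-trace coordinates
make_locs <- function(tid, x, y, z, cfr = 0.1, efo = 50) {
  n <- length(x)
  data.frame(tid = rep_len(tid, n), x_nm = x, y_nm = y, z_nm = z,
             cfr = rep_len(cfr, n), efo = rep_len(efo, n),
             t_s = seq_len(n))
}

# construct a triangle with prescribed side lengths d12, d13, d23 in 3D
triangle_with_sides <- function(d12, d13, d23) {
  x3 <- (d12^2 + d13^2 - d23^2) / (2 * d12)
  y3 <- sqrt(max(d13^2 - x3^2, 0))
  rbind(c(0, 0, 0), c(d12, 0, 0), c(x3, y3, 0))
}
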