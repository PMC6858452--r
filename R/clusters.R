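# Cluster-scale point-pattern statistics: grouping, convex-hull area and
# nearest-neighbor distances.

# Single-linkage component labels: two points share a label iff they are
# connected by a chain of steps <= linkage um. Labels are 1..k in order of
# the minimum member index, so the partition is deterministic and
# permutation-stable up to relabeling.
single_linkage_labels <- function(pts, linkage) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  if (n == 0) return(integer(0))
  if (n == 1) return(1L)
  tree <- hclust(dist(pts), method = "single")
  raw <- cutree(tree, h = linkage)
  first <- vapply(split(seq_len(n), raw), min, integer(1))
  relabel <- rank(first)
  unname(relabel[as.character(raw)])
}

#' Group podosome centers into clusters
#'
#' Single-linkage grouping: two centers belong to the same cluster iff they
#' are connected by a chain of steps no longer than `linkage_distance`.
#'
#' @param centers a `podosome_centers` object or a 2-column matrix /
#'   data.frame of (x, y) positions in um.
#' @param linkage_distance chain step length, um (default 2).
#' @return A list of `cluster_stats` objects, each with `cluster_id`,
#'   `member_indices`, `n_members` and the member `coordinates`.
#' @export
group_clusters <- function(centers, linkage_distance = 2) {
  pts <- center_coords(centers)
  if (nrow(pts) < 1) stop("need at least one center")
  labels <- single_linkage_labels(pts, linkage_distance)
  lapply(sort(unique(labels)), function(id) {
    idx <- which(labels == id)
    structure(list(
      cluster_id = id,
      member_indices = idx,
      n_members = length(idx),
      coordinates = pts[idx, , drop = FALSE]
    ), class = "cluster_stats")
  })
}

# Accepts podosome_centers, matrix or data.frame; returns an n x 2 matrix (um).
center_coords <- function(centers) {
  if (inherits(centers, "podosome_centers")) {
    return(cbind(x = centers$coordinates$x_um, y = centers$coordinates$y_um))
  }
  m <- as.matrix(as.data.frame(centers)[, 1:2])
  colnames(m) <- c("x", "y")
  m
}

shoelace_area <- function(xy) {
  n <- nrow(xy)
  j <- c(2:n, 1)
  abs(sum(xy[, 1] * xy[j, 2] - xy[j, 1] * xy[, 2])) / 2
}

#' Convex-hull area of a podosome cluster
#'
#' @param cluster a `cluster_stats` object from [group_clusters()], or a
#'   matrix of member coordinates (um).
#' @return Area in um^2. Degenerate clusters (fewer than 3 members, or all
#'   members collinear) return 0 with attribute `degenerate = TRUE`.
#' @export
cluster_area <- function(cluster) {
  xy <- if (inherits(cluster, "cluster_stats")) cluster$coordinates
        else center_coords(cluster)
  if (nrow(xy) < 3) return(structure(0, degenerate = TRUE))
  hull <- chull(xy)
  if (length(hull) < 3) return(structure(0, degenerate = TRUE))
  a <- shoelace_area(xy[hull, , drop = FALSE])
  if (a < .Machine$double.eps^0.5) return(structure(0, degenerate = TRUE))
  a
}

#' Nearest-neighbor distances within a cluster
#'
#' Per-member Euclidean distance to the nearest other member, emitted only
#' for clusters of at least `min_cluster_size` podosomes (the reporting rule
#' used for local-density analysis; small clusters are excluded).
#'
#' @param cluster a `cluster_stats` object or coordinate matrix (um).
#' @param min_cluster_size minimum cluster size for which NNDs are reported.
#' @return Numeric vector of NNDs in um, or `NULL` (invisibly, with a
#'   message) when the cluster is below the size threshold.
#' @export
nearest_neighbor_distances <- function(cluster, min_cluster_size = 15) {
  xy <- if (inherits(cluster, "cluster_stats")) cluster$coordinates
        else center_coords(cluster)
  n <- nrow(xy)
  if (n < min_cluster_size) {
    message(sprintf("cluster with %d members < %d: NND not reported",
                    n, min_cluster_size))
    return(invisible(NULL))
  }
  dm <- as.matrix(dist(xy))
  diag(dm) <- Inf
  unname(apply(dm, 1, min))
}
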