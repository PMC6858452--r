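# Cluster grouping, hull areas, NND and intensity metrics.

test_that("single-linkage grouping follows the chain rule", {
  two_near <- rbind(c(0, 0), c(1, 0))
  expect_length(group_clusters(two_near, 2), 1)
  two_far <- rbind(c(0, 0), c(5, 0))
  expect_length(group_clusters(two_far, 2), 2)
  # chains connect transitively even when endpoints are far apart
  chain <- cbind(seq(0, 8, by = 1.5), 0)
  expect_length(group_clusters(chain, 2), 1)
})

test_that("grouping matches brute-force transitive closure on random sets", {
  withr::with_seed(5, {
    pts <- cbind(runif(100, 0, 12), runif(100, 0, 12))
    link <- 1.5
    cl <- group_clusters(pts, link)
    labels <- integer(100)
    for (k in seq_along(cl)) labels[cl[[k]]$member_indices] <- k
    # oracle: repeated boolean closure over the adjacency matrix
    adj <- as.matrix(dist(pts)) <= link
    reach <- adj
    repeat {
      nxt <- (reach %*% reach) > 0
      if (identical(nxt, reach)) break
      reach <- nxt
    }
    oracle <- unname(apply(reach, 1, function(r) min(which(r))))
    # identical partition: same co-membership for every pair
    expect_identical(outer(labels, labels, "=="), outer(oracle, oracle, "=="))
  })
})

test_that("grouping is invariant to input permutation", {
  withr::with_seed(8, {
    pts <- cbind(runif(40, 0, 8), runif(40, 0, 8))
    perm <- sample(40)
    l1 <- integer(40); l2 <- integer(40)
    for (k in seq_along(cl1 <- group_clusters(pts, 2))) {
      l1[cl1[[k]]$member_indices] <- k
    }
    for (k in seq_along(cl2 <- group_clusters(pts[perm, ], 2))) {
      l2[cl2[[k]]$member_indices] <- k
    }
    expect_identical(outer(l1, l1, "=="),
                     outer(l2[order(perm)], l2[order(perm)], "=="))
  })
})

test_that("hull area handles squares, collinear sets and random points", {
  expect_equal(as.numeric(cluster_area(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))), 1)
  col3 <- cluster_area(rbind(c(0, 0), c(1, 1), c(2, 2)))
  expect_equal(as.numeric(col3), 0)
  expect_true(attr(col3, "degenerate"))
  expect_true(attr(cluster_area(rbind(c(0, 0), c(1, 1))), "degenerate"))

  withr::with_seed(11, {
    pts <- cbind(runif(12, 0, 4), runif(12, 0, 4))
    a <- as.numeric(cluster_area(pts))
    # oracle: the hull is the union of all triangles over point triples;
    # rasterize membership on a fine grid
    gx <- seq(0, 4, length.out = 161)
    g <- as.matrix(expand.grid(x = gx, y = gx))
    inside <- rep(FALSE, nrow(g))
    tri <- t(combn(12, 3))
    sign_area <- function(p1, p2, p3) {
      (p2[1] - p1[1]) * (p3[2] - p1[2]) - (p3[1] - p1[1]) * (p2[2] - p1[2])
    }
    for (k in seq_len(nrow(tri))) {
      p1 <- pts[tri[k, 1], ]; p2 <- pts[tri[k, 2], ]; p3 <- pts[tri[k, 3], ]
      b1 <-(p2[1] - p1[1]) * (g[, 2] - p1[2]) - (p2[2] - p1[2]) * (g[, 1] - p1[1])
      b2 <- (p3[1] - p2[1]) * (g[, 2] - p2[2]) - (p3[2] - p2[2]) * (g[, 1] - p2[1])
      b3 <- (p1[1] - p3[1]) * (g[, 2] - p3[2]) - (p1[2] - p3[2]) * (g[, 1] - p3[1])
      s <- sign(sign_area(p1, p2, p3))
      if (s == 0) next
      inside <- inside | (s * b1 >= 0 & s * b2 >= 0 & s * b3 >= 0)
    }
    cell <- diff(gx)[1]^2
    expect_equal(a, sum(inside) * cell, tolerance = 0.03)
  })
})

test_that("area and NND are rigid-motion invariant", {
  withr::with_seed(3, {
    pts <- cbind(runif(20, 0, 5), runif(20, 0, 5))
    th <- 0.7
    rot <- pts %*% matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2) +
      matrix(c(10, -3), 20, 2, byrow = TRUE)
    expect_equal(as.numeric(cluster_area(pts)), as.numeric(cluster_area(rot)),
                 tolerance = 1e-9)
    expect_equal(nearest_neighbor_distances(pts, min_cluster_size = 1),
                 nearest_neighbor_distances(rot, min_cluster_size = 1),
                 tolerance = 1e-9)
  })
})

test_that("NND values match the quadratic oracle and the size threshold", {
  # 4x4 unit grid: every point's nearest neighbor is 1 um away
  grid <- as.matrix(expand.grid(x = 0:3, y = 0:3))
  expect_equal(nearest_neighbor_distances(grid, min_cluster_size = 15),
               rep(1, 16))
  withr::with_seed(21, {
    pts <- cbind(runif(16, 0, 3), runif(16, 0, 3))
    got <- nearest_neighbor_distances(pts, min_cluster_size = 15)
    oracle <- vapply(1:16, function(i) {
      min(sqrt((pts[i, 1] - pts[-i, 1])^2 + (pts[i, 2] - pts[-i, 2])^2))
    }, numeric(1))
    expect_equal(unname(got), oracle, tolerance = 1e-12)
  })
  # 14-member cluster is excluded by the >= 15 rule
  small <- cbind(runif(14), runif(14))
  expect_message(res <- nearest_neighbor_distances(small), "not reported")
  expect_null(res)
})

test_that("degradation metrics are exact on constructed masks", {
  m <- matrix(100, 60, 60)
  cell <- matrix(FALSE, 60, 60); cell[16:45, 16:45] <- TRUE
  ref <- matrix(FALSE, 60, 60); ref[1:10, ] <- TRUE
  # zero out 20% of the footprint
  idx <- which(cell)
  m[idx[seq_len(0.2 * length(idx))]] <- 0
  dm <- degradation_metrics(m, cell, ref)
  expect_equal(dm$degraded_area_fraction, 0.2)
  expect_equal(dm$mean_ratio, 0.8)
  # scale invariance
  dm2 <- degradation_metrics(m * 7.3, cell, ref)
  expect_equal(dm2$mean_ratio, dm$mean_ratio, tolerance = 1e-12)
  expect_equal(dm2$degraded_area_fraction, dm$degraded_area_fraction)
  # full degradation
  m[cell] <- 0
  dm3 <- degradation_metrics(m, cell, ref)
  expect_equal(dm3$mean_ratio, 0)
  expect_equal(dm3$degraded_area_fraction, 1)
  expect_error(degradation_metrics(m, cell, matrix(FALSE, 60, 60)), "empty")
  expect_error(degradation_metrics(m, cell, cell), "disjoint")
})

test_that("intensity ratios are background-robust", {
  mk <- function(a, b) {
    arr <- array(0, dim = c(1, 1, 2, 40, 40))
    arr[1, 1, 1, , ] <- a; arr[1, 1, 2, , ] <- b
    image_series(arr, 0.04, channels = c("pMyo", "Myo"))
  }
  mask <- matrix(FALSE, 40, 40); mask[11:30, 11:30] <- TRUE
  base <- matrix(0, 40, 40); base[mask] <- 50
  expect_equal(intensity_ratio(mk(base, base), "pMyo", "Myo", mask), 1)
  expect_equal(intensity_ratio(mk(2 * base, base), "pMyo", "Myo", mask), 2)
  # constant offset on both channels cancels after background subtraction
  expect_equal(intensity_ratio(mk(2 * base + 13, base + 13), "pMyo", "Myo", mask),
               2, tolerance = 1e-12)
  expect_error(intensity_ratio(mk(base, matrix(1, 40, 40)), "pMyo", "Myo", mask),
               "non-positive")
})
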