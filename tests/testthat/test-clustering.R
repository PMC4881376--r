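# From-scratch clustering algorithms against hand computations,
# exhaustive enumeration, and independent implementations.

set.seed(1)

test_that("standardize z-scores columns and records the inverse transform", {
  X <- cbind(a = c(1, 2, 3, 4, 6), b = c(10, 0, 5, 2, 8), const = rep(3, 5))
  expect_warning(Z <- standardize(X), "constant")
  expect_equal(unname(colMeans(Z)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(Z, 2, sd)), c(1, 1), tolerance = 1e-12)
  expect_equal(attr(Z, "dropped_columns"), "const")
  # back-transform of standardized coordinates equals raw coordinates
  expect_equal(unname(unstandardize(Z, Z)), unname(X[, 1:2]),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(standardize(matrix(1, 4, 2)), "constant")
})

test_that("kmeans finds the optimal partition on enumerable instances", {
  # 1-D {0,1,9,10,11}: exhaustive minimum-WSS 2-partition is {0,1}|{9,10,11}
  X <- matrix(c(0, 1, 9, 10, 11), ncol = 1)
  oracle <- bf_kmeans(X, 2)
  fit <- cluster_kmeans(X, 2, seed = 7, restarts = 10)
  expect_equal(partition_signature(fit$hard_labels),
               partition_signature({l <- integer(5); for (b in seq_along(oracle$blocks)) l[oracle$blocks[[b]]] <- b; l}))
  expect_equal(fit$objective, oracle$wss, tolerance = 1e-9)
  # two well-separated pairs
  Y <- rbind(c(0, 0), c(0, 1), c(10, 0), c(10, 1))
  f2 <- cluster_kmeans(Y, 2, seed = 1)
  expect_equal(f2$hard_labels[1], f2$hard_labels[2])
  expect_equal(f2$hard_labels[3], f2$hard_labels[4])
  expect_equal(f2$objective, 0.5 + 0.5, tolerance = 1e-9)
  # k = n: every point its own cluster, WSS 0
  f3 <- cluster_kmeans(Y, 4, seed = 1)
  expect_equal(sort(f3$hard_labels), 1:4)
  expect_equal(f3$objective, 0)
  expect_error(cluster_kmeans(Y, 5), "exceeds")
  # WSS trace is non-increasing
  Z <- matrix(rnorm(60), ncol = 2)
  f4 <- cluster_kmeans(Z, 3, seed = 2, restarts = 5)
  expect_true(all(diff(f4$trace) <= 1e-9))
})

test_that("kmeans matches exhaustive search on random small instances", {
  for (s in 1:3) {
    set.seed(s)
    X <- matrix(rnorm(14), ncol = 2)
    oracle <- bf_kmeans(X, 3)
    fit <- cluster_kmeans(X, 3, seed = s, restarts = 50)
    expect_equal(fit$objective, oracle$wss, tolerance = 1e-9)
  }
})

test_that("fuzzy c-means converges to symmetric memberships and known centers", {
  # point equidistant from two symmetric clusters gets membership 1/2
  X <- matrix(c(-10, -10, 0, 10, 10, 1, -1, 0, 1, -1), ncol = 2)
  fit <- cluster_fcm(X, 2, seed = 3, restarts = 5)
  expect_equal(unname(fit$membership[3, ]), c(0.5, 0.5), tolerance = 1e-4)
  expect_equal(unname(rowSums(fit$membership)), rep(1, 5), tolerance = 1e-9)
  expect_true(all(fit$membership >= 0 & fit$membership <= 1))
  # 1-D toy: centers at the two pair midpoints
  Y <- matrix(c(0, 0.1, 10, 10.1), ncol = 1)
  f2 <- cluster_fcm(Y, 2, seed = 1, restarts = 5)
  expect_equal(sort(as.numeric(f2$centers)), c(0.05, 10.05),
               tolerance = 1e-3)
  # k = 1: center is the mean, memberships all 1
  f3 <- cluster_fcm(Y, 1, seed = 1, restarts = 1)
  expect_equal(as.numeric(f3$centers), mean(Y), tolerance = 1e-6)
  expect_equal(as.numeric(f3$membership), rep(1, 4))
  # objective trace is non-increasing at every iteration
  set.seed(4)
  Z <- matrix(rnorm(80), ncol = 2)
  f4 <- cluster_fcm(Z, 3, seed = 4, restarts = 3)
  expect_true(all(diff(f4$trace) <= 1e-8))
  expect_error(cluster_fcm(Z, 3, m = 1), "m must be > 1")
  # a point coincident with a center gets membership 1 there
  W <- matrix(c(0, 0, 0, 5, 6, 7), ncol = 1)
  f5 <- cluster_fcm(W, 2, seed = 2, restarts = 5)
  hit <- which.min(abs(f5$centers))
  expect_equal(max(f5$membership[1, ]), f5$membership[1, hit])
})

test_that("fuzzy c-means reaches the same objective as an independent implementation", {
  skip_if_not_installed("e1071")
  set.seed(9)
  X <- rbind(matrix(rnorm(40, 0), ncol = 2),
             matrix(rnorm(40, 4), ncol = 2))
  fit <- cluster_fcm(X, 2, seed = 9, restarts = 10)
  ref <- e1071::cmeans(X, 2, m = 2, iter.max = 500)
  # evaluate the standard objective for the reference solution
  U <- ref$membership
  C <- ref$centers
  D2 <- outer(rowSums(X^2), rep(1, 2)) - 2 * X %*% t(C) +
    outer(rep(1, nrow(X)), rowSums(C^2))
  J_ref <- sum(U^2 * pmax(D2, 0))
  expect_equal(fit$objective, J_ref, tolerance = 1e-4)
})

test_that("pam build+swap reaches the exhaustive optimum", {
  X <- matrix(c(0, 1, 2, 10, 11, 12), ncol = 1)
  fit <- cluster_pam(X, 2)
  expect_equal(sort(X[fit$medoid_ids, ]), c(1, 11))
  expect_equal(fit$objective, bf_pam(X, 2)$cost, tolerance = 1e-9)
  # k = n: zero cost
  expect_equal(cluster_pam(X, 6)$objective, 0)
  # duplicated data: same medoid values
  Xd <- rbind(X, X)
  fd <- cluster_pam(Xd, 2)
  expect_equal(sort(unique(Xd[fd$medoid_ids, ])), c(1, 11))
  # random small instances vs enumeration
  for (s in 1:3) {
    set.seed(s)
    Y <- matrix(rnorm(16), ncol = 2)
    expect_equal(cluster_pam(Y, 3)$objective, bf_pam(Y, 3)$cost,
                 tolerance = 1e-9)
  }
  expect_error(cluster_pam(X, 7), "exceeds")
})

test_that("pam agrees with the cluster package on a larger instance", {
  skip_if_not_installed("cluster")
  set.seed(11)
  X <- rbind(matrix(rnorm(60, 0), ncol = 2), matrix(rnorm(60, 3), ncol = 2),
             matrix(rnorm(60, c(0, 6)), ncol = 2))
  fit <- cluster_pam(X, 3)
  ref <- cluster::pam(X, 3)
  # both are local optima of the same objective; costs should agree closely
  ref_cost <- ref$objective[["swap"]] * nrow(X)
  expect_equal(fit$objective, ref_cost, tolerance = 0.02)
})

test_that("lance-williams linkages match hand computation and naive recomputation", {
  # n = 2: a single merge at the pair distance, for every linkage
  X2 <- matrix(c(0, 3), ncol = 1)
  for (lk in c("single", "median", "average", "complete", "centroid",
               "ward", "mcquitty")) {
    d2 <- hclust_lw(X2, lk)
    expect_equal(nrow(d2$merge), 1)
    expect_equal(d2$height, 3, tolerance = 1e-9, label = lk)
  }
  # 1-D {0, 1, 5}: single linkage merges (0,1) at 1 then at 4
  d3 <- hclust_lw(matrix(c(0, 1, 5), ncol = 1), "single")
  expect_equal(d3$height, c(1, 4))
  expect_equal(d3$merge[1, ], c(-1L, -2L))
  # naive recomputation oracles on random points
  set.seed(5)
  X <- matrix(rnorm(20), ncol = 2)
  for (lk in c("single", "complete", "average", "centroid", "ward")) {
    for (k in c(2, 4)) {
      mine <- cut_dendrogram(hclust_lw(X, lk), k)
      ref <- bf_hclust_labels(X, lk, k)
      expect_equal(partition_signature(mine), partition_signature(ref),
                   label = paste(lk, k))
    }
  }
})

test_that("lance-williams linkages agree with stats::hclust partitions", {
  set.seed(6)
  X <- matrix(rnorm(30), ncol = 2)
  map <- c(single = "single", complete = "complete", average = "average",
           mcquitty = "mcquitty", ward = "ward.D2", centroid = "centroid",
           median = "median")
  for (lk in names(map)) {
    d <- dist(X)
    h <- stats::hclust(if (lk %in% c("centroid", "median", "ward")) d^2
                       else d, method = map[[lk]])
    if (map[[lk]] == "ward.D2") h <- stats::hclust(d, method = "ward.D2")
    mine <- hclust_lw(X, lk)
    for (k in c(2, 3, 5)) {
      expect_equal(partition_signature(cut_dendrogram(mine, k)),
                   partition_signature(stats::cutree(h, k)),
                   label = paste(lk, k))
    }
  }
  expect_error(hclust_lw(X, "density"), "arg")
})

test_that("CH index matches hand arithmetic and the direct definition", {
  # 1-D {0,1,10,11}, labels {1,1,2,2}: B = 100, W = 1, CH = 200
  X <- matrix(c(0, 1, 10, 11), ncol = 1)
  expect_equal(ch_index(X, c(1, 1, 2, 2)), 200)
  # label renaming leaves CH unchanged
  expect_equal(ch_index(X, c(2, 2, 1, 1)), 200)
  # moving the blobs closer strictly decreases CH
  X2 <- matrix(c(0, 1, 5, 6), ncol = 1)
  expect_lt(ch_index(X2, c(1, 1, 2, 2)), 200)
  # brute-force agreement on random instances
  for (s in 1:3) {
    set.seed(s)
    Y <- matrix(rnorm(24), ncol = 2)
    lab <- sample(1:3, 12, replace = TRUE)
    if (length(unique(lab)) < 2) next
    expect_equal(ch_index(Y, lab), bf_ch(Y, lab), tolerance = 1e-9)
  }
  expect_error(ch_index(X, rep(1, 4)), "requires")
  expect_error(ch_index(X, 1:4), "requires")
})

test_that("silhouette widths match the direct definition and conventions", {
  # two singleton clusters: both widths 0 by convention
  X <- matrix(c(0, 5), ncol = 1)
  s <- silhouette_widths(X, c(1, 2))
  expect_equal(s$widths, c(0, 0))
  # perfectly separated duplicate pairs: widths 1 (a = 0)
  Y <- matrix(c(0, 0, 10, 10, 20, 20), ncol = 1)
  s2 <- silhouette_widths(Y, c(1, 1, 2, 2, 3, 3))
  expect_equal(s2$widths, rep(1, 6))
  expect_equal(s2$overall, 1)
  # brute-force agreement on random labelings
  for (s in 1:3) {
    set.seed(s + 10)
    Z <- matrix(rnorm(12), ncol = 2)
    lab <- sample(1:3, 6, replace = TRUE)
    if (length(unique(lab)) < 2) next
    mine <- silhouette_widths(Z, lab)
    expect_equal(mine$widths, bf_silhouette(Z, lab), tolerance = 1e-9)
    expect_equal(mine$overall, mean(mine$widths), tolerance = 1e-12)
  }
})

test_that("silhouette agrees with the cluster package", {
  skip_if_not_installed("cluster")
  set.seed(12)
  X <- matrix(rnorm(40), ncol = 2)
  lab <- sample(1:3, 20, replace = TRUE)
  ref <- cluster::silhouette(lab, dist(X))
  mine <- silhouette_widths(X, lab)
  expect_equal(mine$widths, as.numeric(ref[, "sil_width"]), tolerance = 1e-9)
})

test_that("the method scan picks forced structure and fills the grid", {
  set.seed(21)
  X <- rbind(matrix(rnorm(40, 0, 0.3), ncol = 2),
             matrix(rnorm(40, 5, 0.3), ncol = 2))
  sc <- scan_methods(X, methods = c("kmeans", "ward"), k_range = 2:6,
                     seed = 21, restarts = 5)
  expect_equal(nrow(sc$grid), 2 * 5)
  expect_equal(sc$best$k, 2)
  # full grid has |methods| x 9 cells
  sc2 <- scan_methods(X, methods = "all", k_range = 2:4, seed = 21,
                      restarts = 3)
  expect_equal(nrow(sc2$grid), 10 * 3)
  expect_true(all(sc2$grid$ch[sc2$grid$valid] > 0))
  expect_error(scan_methods(X, methods = "gmm"), "unknown method")
})
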