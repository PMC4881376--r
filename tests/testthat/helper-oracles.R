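# Independent brute-force reference implementations used as oracles.
# These deliberately share no code with the package.

# all set partitions of 1..n into exactly k nonempty blocks
bf_partitions <- function(n, k) {
  res <- list()
  rec <- function(i, blocks) {
    if (i > n) {
      if (length(blocks) == k) res[[length(res) + 1]] <<- blocks
      return(invisible())
    }
    for (b in seq_along(blocks)) {
      nb <- blocks; nb[[b]] <- c(nb[[b]], i)
      rec(i + 1, nb)
    }
    if (length(blocks) < k) rec(i + 1, c(blocks, list(i)))
  }
  rec(2, list(1L))
  res
}

bf_wss <- function(X, blocks) {
  sum(vapply(blocks, function(ix) {
    Xi <- X[ix, , drop = FALSE]
    sum(sweep(Xi, 2, colMeans(Xi))^2)
  }, numeric(1)))
}

# exhaustive minimum-WSS partition
bf_kmeans <- function(X, k) {
  X <- as.matrix(X)
  parts <- bf_partitions(nrow(X), k)
  wss <- vapply(parts, function(p) bf_wss(X, p), numeric(1))
  list(blocks = parts[[which.min(wss)]], wss = min(wss))
}

# exhaustive PAM: best medoid subset by total distance to nearest medoid
bf_pam <- function(X, k) {
  X <- as.matrix(X)
  D <- as.matrix(dist(X))
  cmb <- utils::combn(nrow(X), k)
  costs <- apply(cmb, 2, function(ms)
    sum(apply(D[, ms, drop = FALSE], 1, min)))
  list(medoids = sort(cmb[, which.min(costs)]), cost = min(costs))
}

# direct-definition CH index
bf_ch <- function(X, labels) {
  X <- as.matrix(X)
  labs <- unique(labels)
  n <- nrow(X); k <- length(labs)
  grand <- apply(X, 2, mean)
  B <- 0; W <- 0
  for (l in labs) {
    Xi <- X[labels == l, , drop = FALSE]
    ci <- apply(Xi, 2, mean)
    B <- B + nrow(Xi) * sum((ci - grand)^2)
    for (i in seq_len(nrow(Xi))) W <- W + sum((Xi[i, ] - ci)^2)
  }
  (B / (k - 1)) / (W / (n - k))
}

# direct O(n^2) silhouette
bf_silhouette <- function(X, labels) {
  X <- as.matrix(X)
  n <- nrow(X)
  d <- function(i, j) sqrt(sum((X[i, ] - X[j, ])^2))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels[i]
    mates <- setdiff(which(labels == own), i)
    if (length(mates) == 0) { s[i] <- 0; next }
    a <- mean(vapply(mates, function(j) d(i, j), numeric(1)))
    b <- min(vapply(setdiff(unique(labels), own), function(l) {
      mean(vapply(which(labels == l), function(j) d(i, j), numeric(1)))
    }, numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  s
}

# naive agglomerative clustering recomputing inter-cluster distances from
# raw points each step (linkages with a raw-point definition)
bf_hclust_labels <- function(X, linkage, k) {
  X <- as.matrix(X)
  clusters <- lapply(seq_len(nrow(X)), identity)
  cdist <- function(a, b) {
    pts <- expand.grid(i = a, j = b)
    pw <- vapply(seq_len(nrow(pts)),
                 function(r) sqrt(sum((X[pts$i[r], ] - X[pts$j[r], ])^2)),
                 numeric(1))
    ca <- colMeans(X[a, , drop = FALSE]); cb <- colMeans(X[b, , drop = FALSE])
    switch(linkage,
      single = min(pw), complete = max(pw), average = mean(pw),
      centroid = sqrt(sum((ca - cb)^2)),
      ward = sqrt(length(a) * length(b) / (length(a) + length(b)) *
                    sum((ca - cb)^2)))
  }
  while (length(clusters) > k) {
    best <- c(Inf, 0, 0)
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      dd <- cdist(clusters[[i]], clusters[[j]])
      if (dd < best[1] - 1e-12) best <- c(dd, i, j)
    }
    i <- best[2]; j <- best[3]
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    clusters[[j]] <- NULL
  }
  # label clusters 1..k by lowest member index
  lab <- integer(nrow(X))
  firsts <- vapply(clusters, function(cl) min(cl), numeric(1))
  ord <- order(firsts)
  for (rank in seq_along(ord)) lab[clusters[[ord[rank]]]] <- rank
  lab
}

# canonical partition signature: sorted list of sorted member vectors
partition_signature <- function(labels) {
  blocks <- split(seq_along(labels), labels)
  blocks <- lapply(blocks, sort)
  blocks <- blocks[order(vapply(blocks, min, integer(1)))]
  unname(blocks)
}

# minimum-cost assignment by permutation enumeration
bf_assignment <- function(cost) {
  k <- nrow(cost)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))))
  }
  ps <- perms(seq_len(k))
  costs <- vapply(ps, function(p) sum(cost[cbind(seq_len(k), p)]),
                  numeric(1))
  list(p = ps[[which.min(costs)]], cost = min(costs))
}

# brute-force 8-connected components by flood fill
bf_components <- function(fg) {
  lab <- matrix(0L, nrow(fg), ncol(fg))
  cur <- 0L
  for (cc in seq_len(ncol(fg))) for (r in seq_len(nrow(fg))) {
    if (!fg[r, cc] || lab[r, cc] > 0) next
    cur <- cur + 1L
    queue <- list(c(r, cc))
    lab[r, cc] <- cur
    while (length(queue) > 0) {
      p <- queue[[1]]; queue <- queue[-1]
      for (dr in -1:1) for (dc in -1:1) {
        rr <- p[1] + dr; ccc <- p[2] + dc
        if (rr < 1 || rr > nrow(fg) || ccc < 1 || ccc > ncol(fg)) next
        if (fg[rr, ccc] && lab[rr, ccc] == 0) {
          lab[rr, ccc] <- cur
          queue[[length(queue) + 1]] <- c(rr, ccc)
        }
      }
    }
  }
  lab
}
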