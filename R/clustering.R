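# From-scratch clustering: k-means, fuzzy c-means, PAM, the seven
# Lance-Williams hierarchical linkages, the Calinski-Harabasz index,
# silhouette widths, and the method x k validation scan.

.linkages <- c("single", "median", "average", "complete", "centroid",
               "ward", "mcquitty")
.scan_method_order <- c(.linkages, "pam", "kmeans", "fuzzy_cmeans")

#' Standardize a feature matrix for clustering
#'
#' Per-column z-scoring ((x - mean)/sd). Constant columns (sd = 0) are
#' dropped with a warning; if all columns are constant an error is raised.
#' The centering and scaling vectors are attached as attributes so cluster
#' centers can be back-transformed to raw ratio space.
#'
#' @param x Numeric matrix or data frame of features (rows = ROIs); no
#'   missing values; at least 2 rows.
#' @param scaling \code{"zscore"} (default) or \code{"none"}.
#' @return Numeric matrix with attributes \code{scaled_center},
#'   \code{scaled_scale} and \code{dropped_columns}.
#' @export
standardize <- function(x, scaling = c("zscore", "none")) {
  scaling <- match.arg(scaling)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (nrow(x) < 2) stop("need at least 2 rows")
  if (anyNA(x)) stop("feature matrix contains missing values")
  dropped <- character(0)
  if (scaling == "zscore") {
    sds <- apply(x, 2, stats::sd)
    if (all(sds == 0)) stop("all feature columns are constant")
    if (any(sds == 0)) {
      dropped <- colnames(x)[sds == 0]
      warning("dropping constant column(s): ", paste(dropped, collapse = ", "))
      x <- x[, sds > 0, drop = FALSE]
      sds <- sds[sds > 0]
    }
    ctr <- colMeans(x)
    x <- sweep(sweep(x, 2, ctr), 2, sds, "/")
    attr(x, "scaled_center") <- ctr
    attr(x, "scaled_scale") <- sds
  } else {
    attr(x, "scaled_center") <- rep(0, ncol(x))
    attr(x, "scaled_scale") <- rep(1, ncol(x))
    names(attr(x, "scaled_center")) <- names(attr(x, "scaled_scale")) <-
      colnames(x)
  }
  attr(x, "dropped_columns") <- dropped
  attr(x, "scaling") <- scaling
  x
}

#' Back-transform standardized coordinates to raw feature space
#'
#' @param centers Matrix of coordinates in the standardized space.
#' @param x A matrix produced by [standardize()] (source of the recorded
#'   centering/scaling), or \code{NULL} if \code{center}/\code{scale} given.
#' @param center,scale Optional explicit per-column center and scale.
#' @return Matrix in raw feature space.
#' @export
unstandardize <- function(centers, x = NULL, center = NULL, scale = NULL) {
  if (!is.null(x)) {
    center <- attr(x, "scaled_center")
    scale <- attr(x, "scaled_scale")
  }
  sweep(sweep(as.matrix(centers), 2, scale, "*"), 2, center, "+")
}

.new_solution <- function(method, k, hard_labels, centers = NULL,
                          membership = NULL, medoid_ids = NULL,
                          objective = NA_real_, trace = NULL,
                          seed = NULL, restarts = NA_integer_,
                          converged = NA) {
  structure(list(method = method, k = as.integer(k),
                 hard_labels = as.integer(hard_labels), centers = centers,
                 membership = membership, medoid_ids = medoid_ids,
                 objective = objective, trace = trace, seed = seed,
                 restarts = restarts, converged = converged),
            class = "cluster_solution")
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat("Cluster solution:", x$method, " k =", x$k, "\n")
  cat("sizes:", paste(tabulate(x$hard_labels, x$k), collapse = " "), "\n")
  if (!is.na(x$objective))
    cat("objective:", format(x$objective, digits = 6), "\n")
  invisible(x)
}

.pairwise_sqdist <- function(X, C) {
  # n x k matrix of squared Euclidean distances, clipped at 0
  D2 <- outer(rowSums(X^2), rep(1, nrow(C))) - 2 * X %*% t(C) +
    outer(rep(1, nrow(X)), rowSums(C^2))
  D2[D2 < 0] <- 0
  D2
}

.kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1)
  d2 <- rowSums(sweep(X, 2, X[idx[1], ])^2)
  for (j in seq_len(k - 1)) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    idx[j + 1] <- sample.int(n, 1, prob = p)
    d2 <- pmin(d2, rowSums(sweep(X, 2, X[idx[j + 1], ])^2))
  }
  X[idx, , drop = FALSE]
}

#' k-means clustering (Lloyd iterations, k-means++ seeding)
#'
#' Minimizes the within-cluster sum of squares (WSS) by Lloyd
#' iterations from k-means++ style seeding, keeping the best of
#' \code{restarts} runs by WSS. An empty cluster is repaired by
#' re-seeding it with the point farthest from its assigned center.
#' Assignment ties go to the lowest cluster index. Deterministic
#' given \code{seed}.
#'
#' @param X Numeric matrix (rows = objects).
#' @param k Number of clusters, \code{2 <= k <= nrow(X)} (k = n allowed).
#' @param seed Optional integer seed.
#' @param restarts Number of random restarts (default 20).
#' @param max_iter Maximum Lloyd iterations per restart.
#' @return A \code{cluster_solution} with WSS \code{objective} and the
#'   per-iteration WSS \code{trace} of the winning restart.
#' @export
cluster_kmeans <- function(X, k, seed = NULL, restarts = 20, max_iter = 100) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (k > n) stop("k exceeds the number of objects")
  if (!is.null(seed)) set.seed(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    C <- .kmeanspp_centers(X, k)
    lab <- rep(0L, n)
    trace <- numeric(0)
    for (it in seq_len(max_iter)) {
      D2 <- .pairwise_sqdist(X, C)
      new_lab <- max.col(-D2, ties.method = "first")
      # repair empty clusters with the farthest point from its center
      for (j in which(tabulate(new_lab, k) == 0)) {
        far <- which.max(D2[cbind(seq_len(n), new_lab)])
        new_lab[far] <- j
        D2[far, ] <- Inf; D2[far, j] <- 0
      }
      trace <- c(trace, sum(D2[cbind(seq_len(n), new_lab)]))
      if (identical(new_lab, lab)) break
      lab <- new_lab
      C <- do.call(rbind, lapply(seq_len(k), function(j)
        colMeans(X[lab == j, , drop = FALSE])))
    }
    wss <- sum(.pairwise_sqdist(X, C)[cbind(seq_len(n), lab)])
    if (is.null(best) || wss < best$objective - 1e-12)
      best <- .new_solution("kmeans", k, lab, centers = C,
                            objective = wss, trace = trace, seed = seed,
                            restarts = restarts, converged = TRUE)
  }
  colnames(best$centers) <- colnames(X)
  best
}

#' Fuzzy c-means clustering
#'
#' Minimizes \eqn{J = \sum_i \sum_j u_{ij}^m \|x_i - c_j\|^2} by
#' alternating center updates \eqn{c_j = \sum u^m x / \sum u^m} and
#' membership updates \eqn{u_{ij} = 1/\sum_l (d_{ij}/d_{il})^{2/(m-1)}}
#' until \eqn{\max |\Delta u| <} \code{tol}. A point coincident with a
#' center receives membership 1 there. Hard labels are the arg-max
#' membership (ties to the lowest cluster index). The best of
#' \code{restarts} random-membership starts by final \eqn{J} is kept.
#'
#' @param X Numeric matrix (rows = objects).
#' @param k Number of clusters.
#' @param m Fuzzifier, > 1 (default 2, the standard choice).
#' @param tol Convergence tolerance on memberships (default 1e-6).
#' @param max_iter Maximum iterations per restart (default 500).
#' @param seed Optional integer seed.
#' @param restarts Number of random restarts (default 20).
#' @return A \code{cluster_solution} with \code{membership} (rows sum to
#'   1), fuzzy \code{centers}, objective \eqn{J} and its per-iteration
#'   \code{trace} for the winning restart.
#' @export
cluster_fcm <- function(X, k, m = 2, tol = 1e-6, max_iter = 500,
                        seed = NULL, restarts = 20) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X)
  if (k > n) stop("k exceeds the number of objects")
  if (m <= 1) stop("fuzzifier m must be > 1")
  if (!is.null(seed)) set.seed(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    U0 <- matrix(stats::runif(n * k), n, k)
    U0 <- U0 / rowSums(U0)
    fit <- .fcm_core(X, U0, m, tol, as.integer(max_iter))
    if (is.null(best) || fit$objective < best$objective - 1e-12) best <- fit
  }
  lab <- max.col(best$membership, ties.method = "first")
  colnames(best$centers) <- colnames(X)
  .new_solution("fuzzy_cmeans", k, lab, centers = best$centers,
                membership = best$membership, objective = best$objective,
                trace = best$trace, seed = seed, restarts = restarts,
                converged = best$converged)
}

#' Partitioning around medoids (PAM)
#'
#' BUILD phase (greedy medoid selection) followed by SWAP (the best
#' cost-lowering medoid/non-medoid exchange is applied repeatedly until
#' no swap lowers the total dissimilarity). Cost is the sum of Euclidean
#' distances of each object to its nearest medoid. Deterministic given
#' the data order.
#'
#' @param X Numeric matrix (rows = objects).
#' @param k Number of medoids.
#' @return A \code{cluster_solution} with \code{medoid_ids}, medoid
#'   coordinates as \code{centers}, and the total dissimilarity as
#'   \code{objective}.
#' @export
cluster_pam <- function(X, k) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (k > n) stop("k exceeds the number of objects")
  D <- as.matrix(stats::dist(X))
  # BUILD
  med <- which.min(rowSums(D))
  dn <- D[, med]
  while (length(med) < k) {
    gain <- vapply(seq_len(n), function(h) {
      if (h %in% med) return(-Inf)
      sum(pmax(dn - D[, h], 0))
    }, numeric(1))
    med <- c(med, which.max(gain))
    dn <- pmin(dn, D[, med[length(med)]])
  }
  # SWAP (best improvement)
  cost <- function(ms) sum(apply(D[, ms, drop = FALSE], 1, min))
  cur <- cost(med)
  repeat {
    Dm <- D[, med, drop = FALSE]
    ord <- apply(Dm, 1, order)          # k x n
    d1 <- Dm[cbind(seq_len(n), ord[1, ])]
    d2 <- if (k > 1) Dm[cbind(seq_len(n), ord[2, ])] else rep(Inf, n)
    near <- ord[1, ]
    best_delta <- 0; best_swap <- NULL
    for (mi in seq_len(k)) {
      base <- ifelse(near == mi, d2, d1)
      for (h in setdiff(seq_len(n), med)) {
        newcost <- sum(pmin(base, D[, h]))
        delta <- newcost - cur
        if (delta < best_delta - 1e-12) {
          best_delta <- delta; best_swap <- c(mi, h)
        }
      }
    }
    if (is.null(best_swap)) break
    med[best_swap[1]] <- best_swap[2]
    cur <- cur + best_delta
  }
  lab <- max.col(-D[, med, drop = FALSE], ties.method = "first")
  .new_solution("pam", k, lab, centers = X[med, , drop = FALSE],
                medoid_ids = med, objective = cur, converged = TRUE)
}

.lw_coef <- function(linkage, ni, nj, nk) {
  switch(linkage,
    single   = c(0.5, 0.5, 0, -0.5),
    complete = c(0.5, 0.5, 0, 0.5),
    average  = c(ni / (ni + nj), nj / (ni + nj), 0, 0),
    mcquitty = c(0.5, 0.5, 0, 0),
    centroid = c(ni / (ni + nj), nj / (ni + nj),
                 -ni * nj / (ni + nj)^2, 0),
    median   = c(0.5, 0.5, -0.25, 0),
    ward     = c((ni + nk) / (ni + nj + nk), (nj + nk) / (ni + nj + nk),
                 -nk / (ni + nj + nk), 0),
    stop("unknown linkage: ", linkage)
  )
}

#' Agglomerative hierarchical clustering via the Lance-Williams recurrence
#'
#' Implements the seven classical linkages (single, complete, average/
#' UPGMA, McQuitty/WPGMA, centroid/UPGMC, median/WPGMC, Ward) through the
#' Lance-Williams update
#' \deqn{d(ij,k) = \alpha_i d(i,k) + \alpha_j d(j,k) + \beta d(i,j)
#'   + \gamma |d(i,k) - d(j,k)|.}
#' Centroid, median and Ward operate on squared Euclidean distances
#' (Ward.D2-equivalent merge ordering); their reported heights are square
#' roots, i.e. on the distance scale. Merge ties are broken by the lowest
#' pair index.
#'
#' @param X Numeric matrix (rows = objects), n >= 2.
#' @param linkage One of \code{"single"}, \code{"median"},
#'   \code{"average"}, \code{"complete"}, \code{"centroid"},
#'   \code{"ward"}, \code{"mcquitty"}.
#' @return Object of class \code{lw_dendrogram} with \code{merge} and
#'   \code{height} in \code{\link[stats]{hclust}} convention.
#' @seealso [cut_dendrogram()]
#' @export
hclust_lw <- function(X, linkage = .linkages) {
  linkage <- match.arg(linkage)
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2) stop("need at least 2 objects")
  squared <- linkage %in% c("centroid", "median", "ward")
  D <- as.matrix(stats::dist(X))
  if (squared) D <- D^2
  diag(D) <- Inf
  active <- rep(TRUE, n)
  id <- -(seq_len(n))               # hclust convention
  size <- rep(1, n)
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  for (s in seq_len(n - 1)) {
    idx <- which(active)
    sub <- D[idx, idx, drop = FALSE]
    # lowest (i, j) pair among the minima, i < j in current index order
    mn <- min(sub)
    hit <- which(sub == mn, arr.ind = TRUE)
    hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
    i <- idx[hit[1, 1]]; j <- idx[hit[1, 2]]
    # hclust row convention: singletons (negative) first, by original
    # index; merged clusters after, by step number
    pair <- c(id[i], id[j])
    merge[s, ] <- pair[order(pair >= 0, abs(pair))]
    height[s] <- if (squared) sqrt(mn) else mn
    others <- setdiff(idx, c(i, j))
    if (length(others) > 0) {
      co <- vapply(others, function(o) {
        a <- .lw_coef(linkage, size[i], size[j], size[o])
        a[1] * D[i, o] + a[2] * D[j, o] + a[3] * D[i, j] +
          a[4] * abs(D[i, o] - D[j, o])
      }, numeric(1))
      D[i, others] <- co
      D[others, i] <- co
    }
    size[i] <- size[i] + size[j]
    id[i] <- s
    active[j] <- FALSE
    D[j, ] <- Inf; D[, j] <- Inf
  }
  structure(list(merge = merge, height = height, linkage = linkage,
                 n = n), class = "lw_dendrogram")
}

#' Cut a dendrogram into k clusters
#'
#' Applies the first \code{n - k} merges and labels the resulting
#' clusters 1..k in order of their lowest member index.
#'
#' @param dend An \code{lw_dendrogram} from [hclust_lw()].
#' @param k Number of clusters, 1..n.
#' @return Integer vector of hard labels in 1..k.
#' @export
cut_dendrogram <- function(dend, k) {
  stopifnot(inherits(dend, "lw_dendrogram"))
  n <- dend$n
  if (k < 1 || k > n) stop("k must be in 1..n")
  grp <- seq_len(n)
  merged <- vector("list", n - 1)   # members of each positive merge id
  for (s in seq_len(n - k)) {
    m1 <- dend$merge[s, 1]; m2 <- dend$merge[s, 2]
    mem1 <- if (m1 < 0) -m1 else merged[[m1]]
    mem2 <- if (m2 < 0) -m2 else merged[[m2]]
    merged[[s]] <- c(mem1, mem2)
    grp[merged[[s]]] <- min(grp[merged[[s]]])
  }
  # label clusters 1..k by lowest member index
  match(grp, sort(unique(grp)))
}

#' Calinski-Harabasz index of a hard partition
#'
#' \deqn{CH = \frac{B/(k-1)}{W/(n-k)}} with between-cluster dispersion
#' \eqn{B = \sum_j n_j \|\bar c_j - \bar c\|^2} and within-cluster
#' dispersion \eqn{W = \sum_j \sum_{i \in j} \|x_i - \bar c_j\|^2},
#' computed in the (possibly standardized) feature space. Higher values
#' indicate better cohesion and separation.
#'
#' @param X Numeric matrix (rows = objects).
#' @param labels Hard cluster labels; every cluster nonempty;
#'   \code{2 <= k <= n - 1}.
#' @return The CH value (finite, positive for any non-degenerate input).
#' @export
ch_index <- function(X, labels) {
  X <- as.matrix(X)
  n <- nrow(X)
  labels <- as.integer(factor(labels))
  k <- max(labels)
  if (k < 2 || k > n - 1) stop("CH index requires 2 <= k <= n - 1")
  g <- colMeans(X)
  B <- 0; W <- 0
  for (j in seq_len(k)) {
    Xi <- X[labels == j, , drop = FALSE]
    ci <- colMeans(Xi)
    B <- B + nrow(Xi) * sum((ci - g)^2)
    W <- W + sum(sweep(Xi, 2, ci)^2)
  }
  (B / (k - 1)) / (W / (n - k))
}

#' Silhouette widths of a hard partition
#'
#' For each object, \eqn{s(i) = (b - a)/\max(a, b)} where \eqn{a} is the
#' mean distance to the other members of its own cluster and \eqn{b} the
#' smallest mean distance to another cluster. Objects in singleton
#' clusters get \eqn{s(i) = 0} by convention.
#'
#' @param X Numeric matrix (rows = objects).
#' @param labels Hard cluster labels, k >= 2.
#' @return List with \code{widths} (per object), \code{cluster_avg}
#'   (named per-cluster means) and \code{overall} (mean of all widths).
#' @export
silhouette_widths <- function(X, labels) {
  X <- as.matrix(X)
  n <- nrow(X)
  f <- factor(labels)
  k <- nlevels(f)
  if (k < 2) stop("silhouette requires k >= 2")
  D <- as.matrix(stats::dist(X))
  sizes <- tabulate(as.integer(f), k)
  # column j: mean distance of each point to cluster j's members
  sums <- t(rowsum(D, group = f))       # n x k sums
  s <- numeric(n)
  li <- as.integer(f)
  for (i in seq_len(n)) {
    own <- li[i]
    if (sizes[own] == 1) { s[i] <- 0; next }
    a <- sums[i, own] / (sizes[own] - 1)
    b <- min(sums[i, -own] / sizes[-own])
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  avg <- tapply(s, f, mean)
  list(widths = s, cluster_avg = avg, overall = mean(s))
}

#' Scan clustering methods and cluster numbers by CH index
#'
#' Produces a hard partition for every (method, k) cell of the grid
#' (fuzzy solutions hardened by arg-max membership) and scores it with
#' the Calinski-Harabasz index. The best cell is the arg-max CH; ties go
#' to the smaller k, then to method order (single, median, average,
#' complete, centroid, ward, mcquitty, pam, kmeans, fuzzy_cmeans).
#' Degenerate cells (an empty cluster after hardening) are recorded as
#' invalid and excluded from the arg-max.
#'
#' @param X Numeric matrix (rows = objects), typically [standardize()]d.
#' @param methods Character vector of method names, or \code{"all"}.
#' @param k_range Cluster numbers to scan (default 2:10).
#' @param seed Optional integer seed; each stochastic cell derives its
#'   own sub-seed from it.
#' @param restarts Restarts for kmeans and fuzzy c-means (default 20).
#' @param m Fuzzifier for fuzzy c-means (default 2).
#' @return Object of class \code{isophene_scan}: \code{grid} (data frame
#'   of method, k, CH, validity), \code{solutions} (named list), and
#'   \code{best}.
#' @export
scan_methods <- function(X, methods = "all", k_range = 2:10, seed = NULL,
                         restarts = 20, m = 2) {
  X <- as.matrix(X)
  if (identical(methods, "all")) methods <- .scan_method_order
  bad <- setdiff(methods, .scan_method_order)
  if (length(bad) > 0) stop("unknown method(s): ", paste(bad, collapse = ", "))
  methods <- .scan_method_order[.scan_method_order %in% methods]
  grid <- expand.grid(k = k_range, method = methods,
                      stringsAsFactors = FALSE)[, c("method", "k")]
  grid$ch <- NA_real_
  grid$valid <- FALSE
  solutions <- vector("list", nrow(grid))
  names(solutions) <- paste(grid$method, grid$k, sep = "_")
  dendros <- list()
  for (r in seq_len(nrow(grid))) {
    meth <- grid$method[r]; k <- grid$k[r]
    cell_seed <- if (is.null(seed)) NULL else
      (seed + 7919L * match(meth, .scan_method_order) + k) %% 2147483647L
    sol <- if (meth %in% .linkages) {
      if (is.null(dendros[[meth]])) dendros[[meth]] <- hclust_lw(X, meth)
      lab <- cut_dendrogram(dendros[[meth]], k)
      centers <- do.call(rbind, lapply(seq_len(k), function(j)
        colMeans(X[lab == j, , drop = FALSE])))
      .new_solution(meth, k, lab, centers = centers)
    } else if (meth == "pam") {
      cluster_pam(X, k)
    } else if (meth == "kmeans") {
      cluster_kmeans(X, k, seed = cell_seed, restarts = restarts)
    } else {
      cluster_fcm(X, k, m = m, seed = cell_seed, restarts = restarts)
    }
    solutions[[r]] <- sol
    sizes <- tabulate(sol$hard_labels, k)
    if (any(sizes == 0)) {
      message("degenerate partition for ", meth, " k=", k,
              " (empty cluster); cell excluded")
      next
    }
    grid$ch[r] <- ch_index(X, sol$hard_labels)
    grid$valid[r] <- TRUE
  }
  ok <- which(grid$valid)
  ord <- ok[order(-grid$ch[ok], grid$k[ok],
                  match(grid$method[ok], .scan_method_order))]
  best <- if (length(ord) > 0)
    list(method = grid$method[ord[1]], k = grid$k[ord[1]],
         ch = grid$ch[ord[1]]) else NULL
  structure(list(grid = grid, solutions = solutions, best = best,
                 k_range = k_range, methods = methods),
            class = "isophene_scan")
}

#' @export
print.isophene_scan <- function(x, ...) {
  cat("CH validity scan:", length(x$methods), "method(s), k in",
      min(x$k_range), "..", max(x$k_range), "\n")
  if (!is.null(x$best))
    cat("best: ", x$best$method, " k = ", x$best$k,
        " (CH = ", format(x$best$ch, digits = 5), ")\n", sep = "")
  tab <- stats::reshape(x$grid[, c("method", "k", "ch")],
                        direction = "wide", idvar = "method",
                        timevar = "k")
  names(tab) <- sub("^ch\\.", "k=", names(tab))
  print(tab, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Plot a CH validity scan
#'
#' CH index against cluster number, one line per method.
#'
#' @param x An \code{isophene_scan}.
#' @param ... Passed to \code{\link[graphics]{matplot}}.
#' @export
plot.isophene_scan <- function(x, ...) {
  wide <- sapply(x$methods, function(mth)
    x$grid$ch[x$grid$method == mth][order(x$grid$k[x$grid$method == mth])])
  graphics::matplot(x$k_range, wide, type = "b", pch = seq_along(x$methods),
                    lty = 1, xlab = "number of clusters k",
                    ylab = "Calinski-Harabasz index", ...)
  graphics::legend("topright", legend = x$methods, cex = 0.7,
                   pch = seq_along(x$methods),
                   col = seq_along(x$methods))
  invisible(x)
}
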