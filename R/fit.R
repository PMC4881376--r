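# The core estimator: partition single-cell ratio profiles into isotope
# phenotypes, with canonical labeling against reference archetypes.

#' Fit isotope phenotypes to single-cell ratio profiles
#'
#' Clusters ROIs in ratio space into isotope phenotypes. Features are
#' z-scored by default (the ratio columns span an order of magnitude),
#' clustered with the requested method, and — when archetypes are
#' supplied and their number equals k — assigned canonical phenotype
#' names by optimal matching of cluster centers to the archetype centers.
#'
#' @param ratios Ratio table: key columns (session, region, roi_id) plus
#'   ratio columns, e.g. from [compute_ratios()] or
#'   [generate_ratio_table()].
#' @param columns Ratio columns to cluster on (default: the five
#'   labeling-sensitive ratios \code{r13C, r15N, r33S, rC_CN, rS_CN}).
#' @param method One of \code{"fuzzy_cmeans"} (default), \code{"kmeans"},
#'   \code{"pam"}, or a hierarchical linkage (\code{"single"},
#'   \code{"median"}, \code{"average"}, \code{"complete"},
#'   \code{"centroid"}, \code{"ward"}, \code{"mcquitty"}).
#' @param k Number of phenotype clusters (default 5).
#' @param scaling \code{"zscore"} (default) or \code{"none"}.
#' @param seed Integer seed for stochastic methods.
#' @param restarts Restarts for kmeans / fuzzy c-means (default 20).
#' @param m Fuzzifier for fuzzy c-means (default 2).
#' @param archetypes Archetype matrix from [archetypes()], or NULL to
#'   keep integer labels. Defaults to the day-7 archetypes when k = 5 and
#'   the columns allow it.
#' @return Object of class \code{isophene}: the solution, canonical
#'   labels per ROI, raw-space cluster centers and member means, CH index
#'   and silhouette summary.
#' @examples
#' sim <- generate_ratio_table("day7", seed = 42)
#' fit <- isophene(sim$ratios, seed = 42)
#' print(fit)
#' head(coef(fit))
#' @export
isophene <- function(ratios, columns = .cluster_cols,
                     method = "fuzzy_cmeans", k = 5,
                     scaling = c("zscore", "none"), seed = NULL,
                     restarts = 20, m = 2, archetypes = NULL) {
  scaling <- match.arg(scaling)
  stopifnot(is.data.frame(ratios), all(columns %in% names(ratios)))
  X <- standardize(as.matrix(ratios[columns]), scaling)
  sol <- if (method == "fuzzy_cmeans") {
    cluster_fcm(X, k, m = m, seed = seed, restarts = restarts)
  } else if (method == "kmeans") {
    cluster_kmeans(X, k, seed = seed, restarts = restarts)
  } else if (method == "pam") {
    cluster_pam(X, k)
  } else if (method %in% .linkages) {
    lab <- cut_dendrogram(hclust_lw(X, method), k)
    centers <- do.call(rbind, lapply(seq_len(k), function(j)
      colMeans(X[lab == j, , drop = FALSE])))
    colnames(centers) <- colnames(X)
    .new_solution(method, k, lab, centers = centers)
  } else stop("unknown method: ", method)

  if (is.null(archetypes) && k == 5 &&
      all(colnames(X) %in% .cluster_cols))
    archetypes <- isophene::archetypes("day7", colnames(X))
  mapping <- NULL
  labels <- as.character(sol$hard_labels)
  if (!is.null(archetypes) && nrow(archetypes) == k) {
    mapping <- canonicalize_labels(sol, archetypes, X = X)
    labels <- mapping[sol$hard_labels]
  }
  sizes <- tabulate(sol$hard_labels, k)
  ch <- if (all(sizes > 0) && k >= 2 && k <= nrow(X) - 1)
    ch_index(X, sol$hard_labels) else NA_real_
  sil <- if (all(sizes > 0) && k >= 2)
    silhouette_widths(X, sol$hard_labels) else NULL
  centers_raw <- unstandardize(sol$centers, X)
  raw <- as.matrix(ratios[columns])
  member_means <- do.call(rbind, lapply(seq_len(k), function(j)
    colMeans(raw[sol$hard_labels == j, , drop = FALSE])))
  dimnames(member_means) <- list(NULL, columns)
  if (!is.null(mapping)) {
    rownames(centers_raw) <- rownames(member_means) <- mapping
  }
  structure(list(
    method = method, k = as.integer(k), columns = columns,
    scaling = scaling, solution = sol, mapping = mapping,
    labels = labels, keys = ratios[intersect(.key_cols, names(ratios))],
    ratios = ratios, features = X,
    centers_raw = centers_raw, member_means = member_means,
    ch = ch, silhouette = sil, seed = seed
  ), class = "isophene")
}

#' @export
print.isophene <- function(x, ...) {
  cat("Isotope phenotype fit:", x$method, " k =", x$k,
      " on", paste(x$columns, collapse = ", "), "\n")
  cat("n =", nrow(x$features), " scaling =", x$scaling, "\n")
  tab <- table(factor(x$labels, levels = sort(unique(x$labels))))
  cat("phenotype sizes:\n")
  print(tab)
  if (!is.na(x$ch)) cat("CH index:", format(x$ch, digits = 5), "\n")
  if (!is.null(x$silhouette))
    cat("average silhouette width:",
        format(x$silhouette$overall, digits = 3), "\n")
  invisible(x)
}

#' @export
summary.isophene <- function(object, ...) {
  out <- summarize_clusters(object$ratios, object$labels)
  class(out) <- c("summary.isophene", class(out))
  out
}

#' Raw-space phenotype centers
#'
#' Cluster centers back-transformed to raw ratio space (fuzzy centroids,
#' k-means centers, medoids, or per-cluster means for hierarchical
#' methods). Rows are named by canonical label when available.
#'
#' @param object An \code{isophene} fit.
#' @param type \code{"centers"} (the method's own centers) or
#'   \code{"member_means"} (raw per-cluster means of member ROIs, the
#'   construction used in phenotype summary tables).
#' @param ... Unused.
#' @export
coef.isophene <- function(object, type = c("centers", "member_means"),
                          ...) {
  type <- match.arg(type)
  if (type == "centers") object$centers_raw else object$member_means
}

#' Assign new ROIs to fitted phenotypes
#'
#' Nearest-center assignment in the fit's (standardized) feature space;
#' for fuzzy fits the graded memberships of the new rows are also
#' returned.
#'
#' @param object An \code{isophene} fit.
#' @param newdata Ratio table containing the fit's ratio columns.
#' @param ... Unused.
#' @return Data frame with \code{cluster} (canonical label) and, for
#'   fuzzy fits, membership columns.
#' @export
predict.isophene <- function(object, newdata, ...) {
  X <- as.matrix(newdata[object$columns])
  ctr <- attr(object$features, "scaled_center")
  scl <- attr(object$features, "scaled_scale")
  Z <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  D2 <- .pairwise_sqdist(Z, object$solution$centers)
  j <- max.col(-D2, ties.method = "first")
  lab <- if (!is.null(object$mapping)) object$mapping[j] else
    as.character(j)
  out <- data.frame(cluster = lab, stringsAsFactors = FALSE)
  if (object$method == "fuzzy_cmeans") {
    U <- 1 / (D2 * rowSums(1 / pmax(D2, 1e-300)))
    U[!is.finite(U)] <- 0
    hit <- D2 <= 0
    if (any(hit)) { U[rowSums(hit) > 0, ] <- 0; U[hit] <- 1 }
    colnames(U) <- if (!is.null(object$mapping)) object$mapping else
      paste0("u", seq_len(object$k))
    out <- cbind(out, U)
  }
  out
}

#' Residual enrichment relative to the assigned phenotype center
#'
#' Per-ROI differences between observed ratios and the member mean of
#' the assigned phenotype, in raw ratio units.
#'
#' @param object An \code{isophene} fit.
#' @param ... Unused.
#' @export
residuals.isophene <- function(object, ...) {
  mm <- object$member_means
  idx <- object$solution$hard_labels
  as.matrix(object$ratios[object$columns]) - mm[idx, , drop = FALSE]
}

#' Plot an isotope phenotype fit
#'
#' Pairwise scatter of two ratio columns colored by phenotype, or a
#' silhouette bar plot.
#'
#' @param x An \code{isophene} fit.
#' @param which \code{"scatter"} or \code{"silhouette"}.
#' @param dims Two ratio columns for the scatter (default first two).
#' @param ... Passed to the underlying plot call.
#' @export
plot.isophene <- function(x, which = c("scatter", "silhouette"),
                          dims = x$columns[1:2], ...) {
  which <- match.arg(which)
  if (which == "scatter") {
    pal <- .phenotype_palette
    labs <- x$labels
    extra <- setdiff(unique(labs), names(pal))
    if (length(extra) > 0)
      pal <- c(pal, stats::setNames(grDevices::rainbow(length(extra)),
                                    extra))
    graphics::plot(x$ratios[[dims[1]]], x$ratios[[dims[2]]],
                   col = pal[labs], pch = 19, cex = 0.6,
                   xlab = dims[1], ylab = dims[2], ...)
    graphics::legend("topright", legend = names(pal[unique(labs)]),
                     col = pal[unique(labs)], pch = 19, cex = 0.8)
  } else {
    if (is.null(x$silhouette)) stop("no silhouette available")
    ord <- order(x$labels, -x$silhouette$widths)
    graphics::barplot(x$silhouette$widths[ord], border = NA, space = 0,
                      col = .phenotype_palette[x$labels[ord]],
                      ylab = "silhouette width", ...)
  }
  invisible(x)
}

#' Simulate from the fitted phenotype model
#'
#' Draws synthetic ROIs from a Gaussian mixture whose component means,
#' sds and sizes are the fitted per-phenotype member statistics — the
#' same construction the synthetic presets use for the published
#' summary parameters.
#'
#' @param object An \code{isophene} fit.
#' @param nsim Number of datasets.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return A list of \code{nsim} ratio tables (with truth attributes).
#' @export
simulate.isophene <- function(object, nsim = 1, seed = 1, ...) {
  s <- summary(object)
  s <- s[s$cluster != "All", , drop = FALSE]
  comp <- data.frame(name = s$cluster, n = s$n)
  for (rc in .ratio_cols) {
    mc <- paste0("mean_", rc); sc <- paste0("sd_", rc)
    comp[[mc]] <- if (mc %in% names(s)) s[[mc]] else 0.0442
    comp[[sc]] <- if (sc %in% names(s)) s[[sc]] else 0.002
  }
  spec <- mixture_spec("custom", components = comp)
  lapply(seq_len(nsim), function(i)
    generate_ratio_table(spec, seed = seed + i - 1))
}
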