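# Phenotype deliverables: canonical a-e labels, per-cluster summary
# tables, FISH cross-tabulations, ratio-subset comparisons, spatial maps.

.phenotype_palette <- c(a = "#E41A1C", b = "#377EB8", c = "#4DAF4A",
                        d = "#984EA3", e = "#FF7F00")

#' Reference phenotype archetype centers
#'
#' Named reference centers in ratio space used to assign reproducible
#' canonical labels (a-e) to cluster solutions. Defaults to the published
#' per-cluster mean ratios of the chosen study condition (the 7-day
#' incubation by default).
#'
#' @param preset One of \code{"day2"}, \code{"day7"}, \code{"day10"},
#'   \code{"NL"} (unlabeled control), \code{"K"} (killed control).
#' @param columns Ratio columns to include (default: the five clustering
#'   ratios).
#' @return Matrix with rows a-e and the requested ratio columns.
#' @export
archetypes <- function(preset = "day7", columns = .cluster_cols) {
  blk <- .presets[[match.arg(preset, names(.presets))]]
  A <- t(blk$mean[columns, , drop = FALSE])
  A[stats::complete.cases(A), , drop = FALSE]
}

#' Solve a minimum-cost bijective assignment
#'
#' Exact assignment solver (dynamic programming over column subsets;
#' optimal like the Hungarian algorithm) for square cost matrices up to
#' 20 x 20.
#'
#' @param cost Square numeric cost matrix; \code{cost[i, j]} is the cost
#'   of assigning row i to column j.
#' @return Integer vector \code{p} with \code{p[i]} the column assigned
#'   to row i; attribute \code{cost} holds the total.
#' @export
solve_assignment <- function(cost) {
  cost <- as.matrix(cost)
  k <- nrow(cost)
  stopifnot(k == ncol(cost), k >= 1)
  if (k > 20) stop("assignment solver limited to k <= 20")
  nset <- bitwShiftL(1L, k)
  best <- rep(Inf, nset)
  choice <- matrix(NA_integer_, k, nset)
  best[1] <- 0
  for (s in 0:(nset - 1)) {
    if (!is.finite(best[s + 1])) next
    i <- sum(bitwAnd(s, bitwShiftL(1L, 0:(k - 1))) > 0) + 1L  # next row
    if (i > k) next
    for (j in seq_len(k)) {
      bit <- bitwShiftL(1L, j - 1L)
      if (bitwAnd(s, bit) > 0) next
      s2 <- bitwOr(s, bit)
      v <- best[s + 1] + cost[i, j]
      if (v < best[s2 + 1]) { best[s2 + 1] <- v; choice[i, s2 + 1] <- j }
    }
  }
  p <- integer(k)
  s <- nset - 1L
  for (i in rev(seq_len(k))) {
    j <- choice[i, s + 1]
    p[i] <- j
    s <- bitwAnd(s, bitwNot(bitwShiftL(1L, j - 1L)))
  }
  structure(p, cost = best[nset])
}

#' Assign canonical phenotype labels to a cluster solution
#'
#' Matches the solution's cluster centers one-to-one to a set of named
#' archetype centers by minimizing the total squared Euclidean distance
#' (exact optimal assignment). For methods without explicit centers, the
#' per-cluster means are used. When the solution was fitted in a
#' standardized space, pass the standardized feature matrix so the
#' archetypes are z-scored consistently.
#'
#' @param solution A \code{cluster_solution}, or a k x d matrix of
#'   cluster centers.
#' @param archetypes Named center matrix from [archetypes()]; must have
#'   as many rows as the solution has clusters and the same columns.
#' @param X Optional matrix from [standardize()]; its recorded
#'   center/scale is applied to the archetypes before matching.
#' @return Character vector of length k: \code{mapping[j]} is the
#'   canonical name of cluster j. Attribute \code{cost} holds the total
#'   matching cost.
#' @export
canonicalize_labels <- function(solution, archetypes, X = NULL) {
  centers <- if (inherits(solution, "cluster_solution"))
    solution$centers else as.matrix(solution)
  if (nrow(archetypes) != nrow(centers))
    stop("number of clusters (", nrow(centers),
         ") does not match number of archetypes (", nrow(archetypes), ")")
  cols <- colnames(centers)
  if (!is.null(cols) && !all(cols %in% colnames(archetypes)))
    stop("archetypes lack columns: ",
         paste(setdiff(cols, colnames(archetypes)), collapse = ", "))
  A <- if (is.null(cols)) as.matrix(archetypes)
       else as.matrix(archetypes[, cols, drop = FALSE])
  if (!is.null(X))
    A <- sweep(sweep(A, 2, attr(X, "scaled_center")), 2,
               attr(X, "scaled_scale"), "/")
  k <- nrow(centers)
  cost <- outer(seq_len(k), seq_len(k),
                Vectorize(function(i, j) sum((centers[i, ] - A[j, ])^2)))
  p <- solve_assignment(cost)
  structure(rownames(archetypes)[p], cost = attr(p, "cost"))
}

#' Per-phenotype summary table
#'
#' For each canonical cluster: number of ROIs, mean and sample sd
#' (n - 1 denominator) of every ratio column, plus an "All" column over
#' the full set — the layout of a per-condition phenotype summary.
#'
#' @param ratios Ratio table (keys + ratio columns).
#' @param labels Canonical (or integer) cluster label per row of
#'   \code{ratios}.
#' @return Data frame with columns \code{cluster}, \code{n}, then
#'   \code{mean_*} and \code{sd_*} per ratio; first row is "All".
#'   Single-member clusters report sd 0 with a warning.
#' @export
summarize_clusters <- function(ratios, labels) {
  stopifnot(nrow(ratios) == length(labels))
  cols <- intersect(.ratio_cols, names(ratios))
  lev <- sort(unique(as.character(labels)))
  one <- function(idx, name) {
    x <- ratios[idx, cols, drop = FALSE]
    sds <- vapply(x, stats::sd, numeric(1))
    if (nrow(x) == 1) {
      warning("cluster ", name, " has a single ROI; sd reported as 0")
      sds[] <- 0
    }
    out <- data.frame(cluster = name, n = nrow(x))
    for (cc in cols) {
      out[[paste0("mean_", cc)]] <- mean(x[[cc]])
      out[[paste0("sd_", cc)]] <- sds[[cc]]
    }
    out
  }
  res <- do.call(rbind, c(list(one(seq_len(nrow(ratios)), "All")),
                          lapply(lev, function(l)
                            one(which(labels == l), l))))
  rownames(res) <- NULL
  res
}

#' Cross-tabulate phenotype clusters against FISH taxon labels
#'
#' Joins canonical cluster labels with a FISH label table on
#' (session, region, roi_id); ROIs without a FISH row are counted under
#' taxon "unknown".
#'
#' @param labels_df Data frame with the key columns and a \code{cluster}
#'   column of canonical labels.
#' @param fish FISH label table (see [read_fish_table()]), or NULL.
#' @return List of class \code{phenotype_crosstab}: \code{counts}
#'   (taxon x cluster matrix), \code{cluster_pct} (per-cluster taxon
#'   percentages) and \code{taxon_pct} (per-taxon cluster percentages).
#' @export
crosstab_fish <- function(labels_df, fish = NULL) {
  stopifnot(all(c(.key_cols, "cluster") %in% names(labels_df)))
  key <- function(d) do.call(paste, c(d[.key_cols], sep = "\r"))
  taxon <- rep("unknown", nrow(labels_df))
  if (!is.null(fish)) {
    i <- match(key(labels_df), key(fish))
    taxon[!is.na(i)] <- fish$taxon[i[!is.na(i)]]
  }
  counts <- table(taxon = factor(taxon, levels = .taxa),
                  cluster = factor(labels_df$cluster))
  counts <- unclass(counts)
  cl_tot <- colSums(counts)
  tx_tot <- rowSums(counts)
  structure(list(
    counts = counts,
    cluster_pct = sweep(counts, 2, pmax(cl_tot, 1), "/") * 100,
    taxon_pct = sweep(counts, 1, pmax(tx_tot, 1), "/") * 100
  ), class = "phenotype_crosstab")
}

#' @export
print.phenotype_crosstab <- function(x, ...) {
  cat("ROI counts (taxon x cluster):\n")
  print(x$counts)
  cat("\nper-cluster taxon percentages:\n")
  print(round(x$cluster_pct, 1))
  invisible(x)
}

#' Default ratio subset menu
#'
#' The standard comparison menu: single-isotope subsets (one labeled
#' substrate), two-substrate subsets with the matching elemental ratio,
#' and the full five-ratio set. The carbon+sulfur block is represented
#' by both elemental ratios (C/CN and S/CN).
#'
#' @return Named list of ratio column vectors.
#' @export
default_ratio_subsets <- function() {
  list(
    "15N"            = "r15N",
    "13C"            = "r13C",
    "33S"            = "r33S",
    "13C+15N+C/CN"   = c("r13C", "r15N", "rC_CN"),
    "13C+33S+C,S/CN" = c("r13C", "r33S", "rC_CN", "rS_CN"),
    "15N+33S+S/CN"   = c("r15N", "r33S", "rS_CN"),
    "all5"           = .cluster_cols
  )
}

#' Compare phenotype assignments across ratio subsets
#'
#' Clusters the same ROIs independently on each ratio subset (identical
#' method, k and seed), canonicalizes every solution against the
#' archetypes restricted to the subset's columns, and counts the ROIs
#' whose canonical label is identical across all subsets.
#'
#' @param ratios Ratio table.
#' @param subsets Named list of ratio column vectors
#'   (default [default_ratio_subsets()]).
#' @param method Clustering method (default fuzzy c-means).
#' @param k Number of clusters (default 5).
#' @param seed Integer seed shared by all subsets.
#' @param archetypes Archetype matrix covering all used columns.
#' @param scaling Feature scaling (default z-score).
#' @param restarts Restarts for stochastic methods.
#' @return List of class \code{subset_comparison}: \code{labels} (ROI x
#'   subset canonical label matrix), \code{consistent_n},
#'   \code{consistent_pct}, and the per-subset solutions.
#' @export
compare_ratio_subsets <- function(ratios, subsets = default_ratio_subsets(),
                                  method = "fuzzy_cmeans", k = 5,
                                  seed = NULL,
                                  archetypes = isophene::archetypes("day7"),
                                  scaling = "zscore", restarts = 20) {
  stopifnot(length(subsets) >= 1)
  lab <- matrix(NA_character_, nrow(ratios), length(subsets),
                dimnames = list(NULL, names(subsets)))
  fits <- vector("list", length(subsets))
  names(fits) <- names(subsets)
  for (s in seq_along(subsets)) {
    cols <- subsets[[s]]
    if (length(cols) == 0 || !all(cols %in% names(ratios)))
      stop("subset ", names(subsets)[s], " uses unknown ratio columns")
    feat <- as.matrix(ratios[cols])
    if (nrow(unique(feat)) < k)
      stop("subset ", names(subsets)[s], " has fewer than k distinct rows")
    fit <- isophene(ratios, columns = cols, method = method, k = k,
                    seed = seed, scaling = scaling, restarts = restarts,
                    archetypes = archetypes[, cols, drop = FALSE])
    lab[, s] <- fit$labels
    fits[[s]] <- fit
  }
  same <- apply(lab, 1, function(r) length(unique(r)) == 1)
  structure(list(labels = lab, consistent_n = sum(same),
                 consistent_pct = 100 * mean(same), fits = fits),
            class = "subset_comparison")
}

#' @export
print.subset_comparison <- function(x, ...) {
  cat("Ratio-subset comparison over", ncol(x$labels), "subsets:",
      paste(colnames(x$labels), collapse = ", "), "\n")
  cat(sprintf("consistent ROIs: n = %d (%.1f%%)\n",
              x$consistent_n, x$consistent_pct))
  invisible(x)
}

#' Export a spatial phenotype map
#'
#' Writes, per region, a PNG of ROI centroids (or mask pixels) colored by
#' canonical cluster with a fixed a-e palette, an optional side-by-side
#' FISH taxon panel, and a TSV of (roi_id, x, y, cluster, taxon).
#'
#' @param labels_df Data frame with key columns, \code{cluster},
#'   \code{centroid_x}, \code{centroid_y} (0-based pixel coordinates,
#'   origin top-left).
#' @param path Output directory (created if needed).
#' @param fish Optional FISH label table for the taxon panel.
#' @param mask Optional label matrix; when given, ROI pixel sets are
#'   painted instead of centroids (single-region input only).
#' @param pixels Image extent in pixels (for axis limits).
#' @return Invisible character vector of files written. ROIs without
#'   coordinates are omitted with a warning.
#' @export
export_spatial_map <- function(labels_df, path, fish = NULL, mask = NULL,
                               pixels = 512) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  miss <- is.na(labels_df$centroid_x) | is.na(labels_df$centroid_y)
  if (any(miss)) {
    warning(sum(miss), " ROI(s) without coordinates omitted")
    labels_df <- labels_df[!miss, , drop = FALSE]
  }
  key <- function(d) do.call(paste, c(d[.key_cols], sep = "\r"))
  taxon <- rep("unknown", nrow(labels_df))
  if (!is.null(fish)) {
    i <- match(key(labels_df), key(fish))
    taxon[!is.na(i)] <- fish$taxon[i[!is.na(i)]]
  }
  labels_df$taxon <- taxon
  pal <- .phenotype_palette
  extra <- setdiff(unique(labels_df$cluster), names(pal))
  if (length(extra) > 0)
    pal <- c(pal, stats::setNames(grDevices::rainbow(length(extra)), extra))
  files <- character(0)
  tsv <- file.path(path, "spatial_map.tsv")
  utils::write.table(
    labels_df[c(.key_cols, "centroid_x", "centroid_y", "cluster", "taxon")],
    tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, tsv)
  tpal <- c(gamma = "#1B9E77", delta = "#7570B3", unknown = "#BDBDBD")
  for (reg in unique(paste(labels_df$session, labels_df$region, sep = "_"))) {
    d <- labels_df[paste(labels_df$session, labels_df$region,
                         sep = "_") == reg, ]
    png_file <- file.path(path, paste0("map_", gsub("[^A-Za-z0-9_.-]", "_",
                                                    reg), ".png"))
    grDevices::png(png_file, width = 900, height = 480)
    op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
    on.exit({ graphics::par(op); grDevices::dev.off() }, add = FALSE)
    for (panel in c("cluster", "taxon")) {
      cols <- if (panel == "cluster") pal[d$cluster] else tpal[d$taxon]
      if (!is.null(mask)) {
        img <- matrix("#FFFFFF", nrow(mask), ncol(mask))
        by_cl <- if (panel == "cluster") d$cluster else d$taxon
        lut <- stats::setNames(cols, d$roi_id)
        sel <- mask > 0 & matrix(as.character(mask) %in% names(lut),
                                 nrow(mask))
        img[sel] <- lut[as.character(mask[sel])]
        graphics::plot(NA, xlim = c(0, ncol(mask)), ylim = c(nrow(mask), 0),
                       xlab = "x (px)", ylab = "y (px)", main = panel,
                       asp = 1)
        graphics::rasterImage(img, 0, nrow(mask), ncol(mask), 0,
                              interpolate = FALSE)
      } else {
        graphics::plot(d$centroid_x, pixels - d$centroid_y, col = cols,
                       pch = 19, xlim = c(0, pixels), ylim = c(0, pixels),
                       xlab = "x (px)", ylab = "y (px, flipped)",
                       main = panel, asp = 1)
      }
    }
    graphics::par(op)
    grDevices::dev.off()
    on.exit()
    files <- c(files, png_file)
  }
  invisible(files)
}
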