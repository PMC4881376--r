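# Raw ion images -> per-ROI accumulated counts: dead-time correction,
# integer-pixel plane alignment, accumulation, ROI extraction, tabulation.

#' Dead-time correction of ion counts
#'
#' Pulse-counting detectors are blind for a dead time tau after each ion;
#' measured counts underestimate true arrivals. Per pixel, plane and
#' channel, with rate r = counts/dwell:
#' \deqn{corrected = counts / (1 - r \tau)}
#' The correction is strictly increasing in measured counts, is the
#' identity at tau = 0, and is applied per plane (before accumulation)
#' because it is rate-based.
#'
#' @param stack An [ion_stack()] of raw (integral) counts.
#' @param tau Detector dead time in seconds (default 44 ns, a typical
#'   electron-multiplier dead time; configurable).
#' @return The stack with real-valued corrected counts and attribute
#'   \code{dead_time_corrected = TRUE}. Pixels at or beyond saturation
#'   (r tau >= 1) raise an error identifying pixel and channel.
#' @export
dead_time_correct <- function(stack, tau = 44e-9) {
  stopifnot(inherits(stack, "ion_stack"), tau >= 0)
  rate <- stack$counts / stack$dwell_time
  sat <- rate * tau >= 1
  if (any(sat)) {
    i <- which(sat, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "saturated pixel: channel %s plane %d (row %d, col %d); r*tau >= 1",
      stack$channels[i[1]], i[2], i[3], i[4]))
  }
  stack$counts <- stack$counts / (1 - rate * tau)
  attr(stack, "dead_time_corrected") <- TRUE
  stack
}

# normalized cross-correlation of two matrices over their full extent
.ncc <- function(a, b) {
  va <- stats::sd(a); vb <- stats::sd(b)
  if (va == 0 || vb == 0) return(NA_real_)
  mean((a - mean(a)) * (b - mean(b))) / (va * vb)
}

#' Estimate per-plane drift by cross-correlation
#'
#' For every plane of the reference channel (the CN biomass channel by
#' default, which carries the most structure), finds the integer (dy, dx)
#' displacement relative to plane 1 that maximizes the normalized
#' cross-correlation over the overlap region, searched over
#' \code{-max_shift..max_shift}. The reported shift is the detected
#' displacement of the plane's content; [accumulate_planes()] applies the
#' inverse translation. Ties are broken toward the smallest |shift|.
#'
#' @param stack An [ion_stack()].
#' @param reference_channel Channel label used for alignment
#'   (default \code{"14N12C"}).
#' @param max_shift Maximum displacement searched, in pixels.
#' @return Integer matrix (n_planes x 2, columns dy, dx); the reference
#'   plane has shift (0, 0). A flat (zero-variance) reference plane is an
#'   error.
#' @export
align_planes <- function(stack, reference_channel = "14N12C",
                         max_shift = 10) {
  stopifnot(inherits(stack, "ion_stack"))
  ci <- match(reference_channel, stack$channels)
  if (is.na(ci)) stop("reference channel ", reference_channel, " not in stack")
  d <- dim(stack$counts)
  n_planes <- d[2]; nr <- d[3]; nc <- d[4]
  ref <- stack$counts[ci, 1, , ]
  if (stats::sd(ref) == 0) stop("flat reference plane; cannot align")
  shifts <- matrix(0L, n_planes, 2, dimnames = list(NULL, c("dy", "dx")))
  if (n_planes == 1) return(shifts)
  cand <- expand.grid(dy = -max_shift:max_shift, dx = -max_shift:max_shift)
  cand <- cand[order(abs(cand$dy) + abs(cand$dx), cand$dy, cand$dx), ]
  for (p in 2:n_planes) {
    pl <- stack$counts[ci, p, , ]
    if (stats::sd(pl) == 0) stop("flat reference-channel plane ", p)
    best <- -Inf; best_s <- c(0L, 0L)
    for (ri in seq_len(nrow(cand))) {
      dy <- cand$dy[ri]; dx <- cand$dx[ri]
      # plane content displaced by (dy, dx): plane[r, c] ~ ref[r - dy, c - dx]
      r1 <- max(1, 1 + dy); r2 <- min(nr, nr + dy)
      c1 <- max(1, 1 + dx); c2 <- min(nc, nc + dx)
      if (r1 > r2 || c1 > c2) next
      cc <- .ncc(pl[r1:r2, c1:c2, drop = FALSE],
                 ref[(r1 - dy):(r2 - dy), (c1 - dx):(c2 - dx), drop = FALSE])
      if (!is.na(cc) && cc > best + 1e-12) { best <- cc; best_s <- c(dy, dx) }
    }
    shifts[p, ] <- as.integer(best_s)
  }
  shifts
}

#' Accumulate aligned planes
#'
#' Per channel, sums the planes after undoing the estimated per-plane
#' displacements. Pixels outside the common overlap of all planes are set
#' to NA (excluded downstream). With zero shifts the accumulation
#' conserves total counts exactly.
#'
#' @param stack An [ion_stack()] (raw or dead-time corrected).
#' @param shifts Integer matrix from [align_planes()] (default: zero
#'   shifts).
#' @return Named list of per-channel accumulated matrices with attributes
#'   \code{overlap_rows}/\code{overlap_cols} (the valid range).
#' @export
accumulate_planes <- function(stack, shifts = NULL) {
  stopifnot(inherits(stack, "ion_stack"))
  d <- dim(stack$counts)
  n_planes <- d[2]; nr <- d[3]; nc <- d[4]
  if (is.null(shifts))
    shifts <- matrix(0L, n_planes, 2)
  if (nrow(shifts) != n_planes)
    stop("shifts must cover every plane")
  # reference-frame pixel (r, c) reads plane p at (r + dy_p, c + dx_p)
  r_lo <- max(1, 1 - min(shifts[, 1])); r_hi <- min(nr, nr - max(shifts[, 1]))
  c_lo <- max(1, 1 - min(shifts[, 2])); c_hi <- min(nc, nc - max(shifts[, 2]))
  if (r_lo > r_hi || c_lo > c_hi) stop("no common overlap across planes")
  out <- vector("list", d[1])
  names(out) <- stack$channels
  for (ch in seq_len(d[1])) {
    acc <- matrix(NA_real_, nr, nc)
    acc[r_lo:r_hi, c_lo:c_hi] <- 0
    for (p in seq_len(n_planes)) {
      dy <- shifts[p, 1]; dx <- shifts[p, 2]
      acc[r_lo:r_hi, c_lo:c_hi] <- acc[r_lo:r_hi, c_lo:c_hi] +
        stack$counts[ch, p, (r_lo + dy):(r_hi + dy),
                     (c_lo + dx):(c_hi + dx)]
    }
    attr(acc, "overlap_rows") <- c(r_lo, r_hi)
    attr(acc, "overlap_cols") <- c(c_lo, c_hi)
    out[[ch]] <- acc
  }
  out
}

#' Otsu threshold of a non-negative image
#'
#' Classic between-class-variance maximization on a 256-bin histogram.
#'
#' @param img Numeric matrix; NAs ignored.
#' @return Threshold value; pixels strictly above it are foreground.
#' @export
otsu_threshold <- function(img) {
  v <- img[!is.na(img)]
  if (length(v) == 0 || min(v) == max(v)) return(max(v, 0))
  brk <- seq(min(v), max(v), length.out = 257)
  h <- tabulate(findInterval(v, brk, rightmost.closed = TRUE), 256)
  mids <- (brk[-1] + brk[-257]) / 2
  w <- cumsum(h); tot <- w[256]
  mu <- cumsum(h * mids); mu_t <- mu[256]
  w1 <- w[-256]; mu1 <- mu[-256]
  w2 <- tot - w1
  valid <- w1 > 0 & w2 > 0
  bcv <- rep(-Inf, 255)
  bcv[valid] <- (mu_t * w1[valid] - tot * mu1[valid])^2 /
    (w1[valid] * w2[valid])
  brk[which.max(bcv) + 1]
}

# 8-connected components of a logical matrix, labeled in raster-scan
# (row-major) order of each component's first pixel
.label_components <- function(fg) {
  nr <- nrow(fg); nc <- ncol(fg)
  lab <- matrix(0L, nr, nc)
  parent <- integer(0)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  nxt <- 0L
  # two-pass with union-find; neighbors W, NW, N, NE in row-major scan
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    if (!fg[r, cc]) next
    nb <- integer(0)
    if (cc > 1 && fg[r, cc - 1]) nb <- c(nb, lab[r, cc - 1])
    if (r > 1) {
      if (cc > 1 && fg[r - 1, cc - 1]) nb <- c(nb, lab[r - 1, cc - 1])
      if (fg[r - 1, cc]) nb <- c(nb, lab[r - 1, cc])
      if (cc < nc && fg[r - 1, cc + 1]) nb <- c(nb, lab[r - 1, cc + 1])
    }
    if (length(nb) == 0) {
      nxt <- nxt + 1L
      parent[nxt] <- nxt
      lab[r, cc] <- nxt
    } else {
      roots <- unique(vapply(nb, find, integer(1)))
      m <- min(roots)
      lab[r, cc] <- m
      for (x in roots) parent[x] <- m
    }
  }
  if (nxt == 0L) return(lab)
  # resolve and relabel by raster order of first pixel (column of t())
  roots <- vapply(seq_len(nxt), find, integer(1))
  lab2 <- t(lab)
  pos <- which(lab2 > 0)
  root_of_px <- roots[lab2[pos]]
  first <- tapply(pos, root_of_px, min)
  order_ids <- as.integer(names(sort(first)))
  remap <- integer(nxt)
  remap[order_ids] <- seq_along(order_ids)
  lab2[pos] <- remap[root_of_px]
  t(lab2)
}

#' Automatic ROI extraction from a biomass image
#'
#' Thresholds the accumulated CN (biomass) image (Otsu by default),
#' groups foreground pixels by 8-connectivity, discards components
#' smaller than \code{min_area_px}, and labels the rest 1..n in
#' raster-scan order of their first pixel. An automated stand-in for
#' hand-drawn ROIs.
#'
#' @param img Accumulated biomass image (matrix, NAs = outside overlap).
#' @param threshold \code{"otsu"} or an explicit numeric threshold.
#' @param min_area_px Minimum component area in pixels (default 20).
#' @return Integer ROI label matrix; all-background with a warning when
#'   no foreground survives.
#' @export
extract_rois_auto <- function(img, threshold = "otsu", min_area_px = 20) {
  stopifnot(is.matrix(img))
  if (any(img < 0, na.rm = TRUE)) stop("image must be non-negative")
  thr <- if (identical(threshold, "otsu")) otsu_threshold(img)
         else as.numeric(threshold)
  fg <- !is.na(img) & img > thr
  lab <- .label_components(fg)
  if (max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0], max(lab))
    small <- which(sizes < min_area_px)
    if (length(small) > 0) {
      lab[lab %in% small] <- 0L
      keep <- which(sizes >= min_area_px)
      remap <- integer(max(lab))
      remap[keep] <- seq_along(keep)
      lab[lab > 0] <- remap[lab[lab > 0]]
    }
  }
  if (max(lab) == 0)
    warning("no foreground components above min_area_px; empty mask")
  lab
}

#' Tabulate per-ROI accumulated counts
#'
#' Sums accumulated counts over each ROI's member pixels for every
#' channel; adds the 0-based pixel centroid (x = column, y = row, origin
#' top-left; unweighted mean of member pixels), area and plane count.
#' Per-ROI Poisson counting uncertainties (sqrt of total counts) are
#' attached as attribute \code{sigma}.
#'
#' @param images Named list of per-channel accumulated matrices from
#'   [accumulate_planes()] (names = channel labels).
#' @param mask Integer ROI label matrix with the same dimensions.
#' @param session,region Key values for the output rows.
#' @param n_planes Number of accumulated planes (metadata column).
#' @return ROI count table (one row per ROI id present in the mask).
#' @export
tabulate_roi_counts <- function(images, mask, session = "s1", region = 1L,
                                n_planes = 1L) {
  stopifnot(is.list(images), length(images) >= 1)
  if (!all(.mass_channels$label %in% names(images)))
    stop("images must include all seven mass channels")
  if (!all(dim(images[[1]]) == dim(mask)))
    stop("mask and images have different dimensions")
  ids <- sort(unique(mask[mask > 0]))
  if (length(ids) == 0)
    return(cbind(data.frame(session = character(0), region = integer(0),
                            roi_id = integer(0)),
                 stats::setNames(rep(list(numeric(0)), 7), .count_cols),
                 data.frame(centroid_x = numeric(0), centroid_y = numeric(0),
                            area_px = integer(0), n_planes = integer(0))))
  sel <- mask > 0
  g <- factor(mask[sel], levels = ids)
  counts <- sapply(.mass_channels$label, function(lb) {
    x <- images[[lb]][sel]
    if (anyNA(x)) stop("ROI extends outside the plane-overlap region")
    as.numeric(tapply(x, g, sum))
  })
  counts <- matrix(counts, nrow = length(ids),
                   dimnames = list(NULL, .count_cols))
  rows <- row(mask)[sel]; cols <- col(mask)[sel]
  out <- data.frame(session = session, region = region, roi_id = ids,
                    counts,
                    centroid_x = as.numeric(tapply(cols - 1, g, mean)),
                    centroid_y = as.numeric(tapply(rows - 1, g, mean)),
                    area_px = as.integer(table(g)),
                    n_planes = as.integer(n_planes),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "sigma") <- sqrt(out[.count_cols])
  out
}

#' Run the full preprocessing chain on a stack
#'
#' Dead-time correction, plane alignment on the biomass channel,
#' accumulation, ROI extraction (supplied mask or automatic), and
#' tabulation.
#'
#' @param stack An [ion_stack()].
#' @param mask Optional ROI label matrix; when NULL, ROIs are extracted
#'   automatically from the accumulated biomass image.
#' @param tau Dead time in seconds (NULL skips the correction).
#' @param align Logical; estimate and undo per-plane drift.
#' @param ... Passed to [extract_rois_auto()].
#' @return List with \code{table} (ROI count table), \code{mask},
#'   \code{images} (accumulated channels) and \code{shifts}.
#' @export
preprocess_stack <- function(stack, mask = NULL, tau = 44e-9,
                             align = TRUE, ...) {
  if (!is.null(tau)) stack <- dead_time_correct(stack, tau)
  shifts <- if (align) align_planes(stack) else NULL
  images <- accumulate_planes(stack, shifts)
  if (is.null(mask)) mask <- extract_rois_auto(images[["14N12C"]], ...)
  meta <- stack$session_meta
  tab <- tabulate_roi_counts(
    images, mask,
    session = if (!is.null(meta$session)) meta$session else "s1",
    region = if (!is.null(meta$region)) meta$region else 1L,
    n_planes = dim(stack$counts)[2])
  list(table = tab, mask = mask, images = images, shifts = shifts)
}
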