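# Synthetic data with the statistical structure of a multi-isotope SIP
# NanoSIMS experiment: ratio-space Gaussian mixtures parameterized by the
# published per-cluster summaries, Poisson count realizations, and full
# ion-image scenes with simple cell morphologies.

#' Mixture specification for the synthetic generator
#'
#' A preset names one of the five study conditions and populates the
#' component means/sds/sizes verbatim from the published per-cluster
#' summary table (components a-e). The 34S/32S ratio is not part of that
#' table; all presets assume natural-abundance 34S (mean 0.0442,
#' sd 0.002). Custom mixtures supply a component data frame instead.
#'
#' @param preset \code{"day2"}, \code{"day7"}, \code{"day10"},
#'   \code{"NL"}, \code{"K"}, or \code{"custom"}.
#' @param components For \code{preset = "custom"}: data frame with
#'   columns \code{name}, \code{n}, \code{mean_<ratio>} and
#'   \code{sd_<ratio>} for the six ratio columns, optionally
#'   \code{morphology} and taxon mix columns \code{p_gamma, p_delta,
#'   p_unknown} (rows must sum to 1).
#' @param ratio_floor Lower truncation bound for generated ratios;
#'   values below it are resampled (not clipped), avoiding a point mass
#'   at the floor.
#' @return Object of class \code{mixture_spec}.
#' @export
mixture_spec <- function(preset = c("day7", "day2", "day10", "NL", "K",
                                    "custom"),
                         components = NULL, ratio_floor = 1e-6) {
  preset <- match.arg(preset)
  if (preset == "custom") {
    stopifnot(is.data.frame(components))
  } else {
    blk <- .presets[[preset]]
    keep <- blk$n > 0
    components <- data.frame(name = names(blk$n)[keep],
                             n = unname(blk$n[keep]))
    for (rc in .ratio_cols) {
      components[[paste0("mean_", rc)]] <- blk$mean[rc, keep]
      components[[paste0("sd_", rc)]] <- blk$sd[rc, keep]
    }
    tm <- .component_taxon_mix[keep, , drop = FALSE]
    components$p_gamma <- tm[, "gamma"]
    components$p_delta <- tm[, "delta"]
    components$p_unknown <- tm[, "unknown"]
    components$morphology <- unname(.component_morphology[keep])
  }
  need <- c("name", "n", paste0("mean_", .ratio_cols),
            paste0("sd_", .ratio_cols))
  miss <- setdiff(need, names(components))
  if (length(miss) > 0)
    stop("custom components missing columns: ", paste(miss, collapse = ", "))
  if (!all(c("p_gamma", "p_delta", "p_unknown") %in% names(components))) {
    components$p_gamma <- 0; components$p_delta <- 0
    components$p_unknown <- 1
  }
  if (!"morphology" %in% names(components))
    components$morphology <- "coccus"
  if (sum(components$n) <= 0) stop("mixture has no ROIs (all n = 0)")
  if (any(components$n < 0) ||
      any(components[paste0("sd_", .ratio_cols)] < 0))
    stop("component sizes and sds must be non-negative")
  pm <- as.matrix(components[c("p_gamma", "p_delta", "p_unknown")])
  if (any(abs(rowSums(pm) - 1) > 1e-8))
    stop("taxon mix probabilities must sum to 1")
  stopifnot(ratio_floor > 0)
  structure(list(preset = preset, components = components,
                 ratio_floor = ratio_floor), class = "mixture_spec")
}

#' Generate a synthetic ratio table from a Gaussian mixture
#'
#' Draws, per component, \code{n} independent 6-dimensional Gaussian
#' ratio vectors (diagonal covariance), truncating below at the ratio
#' floor by resampling. Taxa are drawn from each component's taxon mix.
#' Fully reproducible from the seed.
#'
#' @param spec A [mixture_spec()] (or preset name).
#' @param seed Integer seed.
#' @param session,region Key values for the generated rows.
#' @return List with \code{ratios} (key columns + six ratio columns) and
#'   \code{truth} (component name, taxon and morphology per ROI).
#' @export
generate_ratio_table <- function(spec = "day7", seed = 1,
                                 session = "sim", region = 1L) {
  if (is.character(spec)) spec <- mixture_spec(spec)
  stopifnot(inherits(spec, "mixture_spec"))
  set.seed(seed)
  comp <- spec$components
  rows <- vector("list", nrow(comp))
  for (ci in seq_len(nrow(comp))) {
    n <- comp$n[ci]
    if (n == 0) next
    vals <- sapply(.ratio_cols, function(rc) {
      mu <- comp[[paste0("mean_", rc)]][ci]
      sd <- comp[[paste0("sd_", rc)]][ci]
      x <- stats::rnorm(n, mu, sd)
      while (any(x < spec$ratio_floor))
        x[x < spec$ratio_floor] <-
          stats::rnorm(sum(x < spec$ratio_floor), mu, sd)
      x
    })
    vals <- matrix(vals, nrow = n,
                   dimnames = list(NULL, .ratio_cols))
    taxon <- sample(.taxa[1:3], n, replace = TRUE,
                    prob = c(comp$p_gamma[ci], comp$p_delta[ci],
                             comp$p_unknown[ci]))
    rows[[ci]] <- data.frame(component = comp$name[ci], taxon = taxon,
                             morphology = comp$morphology[ci], vals,
                             stringsAsFactors = FALSE)
  }
  all <- do.call(rbind, rows)
  n_tot <- nrow(all)
  ratios <- data.frame(session = session, region = region,
                       roi_id = seq_len(n_tot),
                       all[.ratio_cols], stringsAsFactors = FALSE)
  attr(ratios, "corrected") <- FALSE
  truth <- data.frame(session = session, region = region,
                      roi_id = seq_len(n_tot),
                      all[c("component", "taxon", "morphology")],
                      stringsAsFactors = FALSE)
  list(ratios = ratios, truth = truth)
}

# Expected per-channel counts consistent with a row of target ratios,
# given the total CN count. Inverts the ratio definitions exactly.
.expected_counts <- function(ratios, total_cn) {
  r <- ratios
  if (any(!is.finite(as.matrix(r[.ratio_cols]))) ||
      any(as.matrix(r[.ratio_cols]) < 0))
    stop("ratios must be finite and non-negative")
  nc14 <- total_cn / (1 + r$r15N)
  nc15 <- total_cn * r$r15N / (1 + r$r15N)
  c_tot <- r$rC_CN * total_cn
  c12 <- c_tot / (1 + r$r13C)
  c13 <- c_tot * r$r13C / (1 + r$r13C)
  s_tot <- r$rS_CN * total_cn
  s32 <- s_tot / (1 + r$r33S + r$r34S)
  if (any(s32 < 0)) stop("inconsistent sulfur ratios (negative 32S share)")
  data.frame(c12 = c12, c13 = c13, nc14 = nc14, nc15 = nc15,
             s32 = s32, s33 = s32 * r$r33S, s34 = s32 * r$r34S)
}

#' Generate a synthetic ROI count table from target ratios
#'
#' Solves for the per-channel expected counts that reproduce each row's
#' six ratios exactly at the given total CN count (14N12C + 15N12C), then
#' draws every channel count as an independent Poisson realization of its
#' expectation.
#'
#' @param ratios Ratio table (keys + six ratio columns), e.g. from
#'   [generate_ratio_table()].
#' @param total_cn Expected total CN counts per ROI (scalar or vector).
#' @param seed Integer seed.
#' @param poisson If \code{FALSE}, return the exact expectations instead
#'   of Poisson draws.
#' @return ROI count table (keys, seven channel counts, centroid/area
#'   placeholders, n_planes = 1).
#' @export
generate_count_table <- function(ratios, total_cn = 1e6, seed = 1,
                                 poisson = TRUE) {
  stopifnot(all(total_cn > 0))
  ex <- .expected_counts(ratios, total_cn)
  if (poisson) {
    set.seed(seed)
    ex[] <- lapply(ex, function(mu) stats::rpois(length(mu), mu))
  }
  out <- data.frame(ratios[.key_cols], ex,
                    centroid_x = 0, centroid_y = 0,
                    area_px = 1L, n_planes = 1L,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Scene specification for synthetic ion-image stacks
#'
#' Geometry and counting parameters of a simulated raster area:
#' filaments are thick line segments, cocci disks, rods short thick
#' segments; each cell's expected channel counts are spread uniformly
#' over its pixel area and split over planes.
#'
#' @param pixels Image side in pixels.
#' @param raster_size Raster side in micrometers.
#' @param n_cells Number of cells to place.
#' @param n_planes Number of acquisition planes.
#' @param cn_per_cell Expected total CN counts per cell (over all planes).
#' @param background_cn Expected background CN counts per pixel per plane
#'   (background pixels carry natural-abundance ratios).
#' @param filament_length,filament_width,coccus_radius,rod_length,rod_width
#'   Cell shape parameters in pixels (lengths may be length-2 ranges).
#' @param drift Per-plane (dy, dx) drift in pixels; plane p is displaced
#'   by (p-1) * drift.
#' @param dwell_time Dwell time per pixel in seconds.
#' @param max_retries Placement retries before giving up.
#' @return Object of class \code{scene_spec}.
#' @export
scene_spec <- function(pixels = 128, raster_size = 7.5, n_cells = 30,
                       n_planes = 4, cn_per_cell = 2e5,
                       background_cn = 0.2,
                       filament_length = c(20, 40), filament_width = 3,
                       coccus_radius = c(2, 4), rod_length = c(5, 9),
                       rod_width = 3, drift = c(0, 0),
                       dwell_time = 0.015, max_retries = 200) {
  stopifnot(pixels >= 16, raster_size > 0, n_cells >= 1, n_planes >= 1,
            cn_per_cell > 0, background_cn >= 0, max_retries >= 1)
  structure(list(pixels = pixels, raster_size = raster_size,
                 n_cells = n_cells, n_planes = n_planes,
                 cn_per_cell = cn_per_cell, background_cn = background_cn,
                 filament_length = filament_length,
                 filament_width = filament_width,
                 coccus_radius = coccus_radius, rod_length = rod_length,
                 rod_width = rod_width, drift = drift,
                 dwell_time = dwell_time, max_retries = max_retries),
            class = "scene_spec")
}

# pixel set (row, col) within dist w/2 of segment (r0,c0)-(r1,c1)
.segment_pixels <- function(r0, c0, r1, c1, width, pixels) {
  rad <- width / 2
  rmin <- max(1, floor(min(r0, r1) - rad)); rmax <- min(pixels, ceiling(max(r0, r1) + rad))
  cmin <- max(1, floor(min(c0, c1) - rad)); cmax <- min(pixels, ceiling(max(c0, c1) + rad))
  if (rmin > rmax || cmin > cmax) return(NULL)
  g <- expand.grid(row = rmin:rmax, col = cmin:cmax)
  vx <- r1 - r0; vy <- c1 - c0
  L2 <- vx^2 + vy^2
  t <- if (L2 > 0)
    pmin(1, pmax(0, ((g$row - r0) * vx + (g$col - c0) * vy) / L2)) else 0
  d2 <- (g$row - (r0 + t * vx))^2 + (g$col - (c0 + t * vy))^2
  g[d2 <= rad^2, , drop = FALSE]
}

.draw_cell_pixels <- function(morphology, spec) {
  px <- spec$pixels
  rng <- function(r) if (length(r) == 2) stats::runif(1, r[1], r[2]) else r
  if (morphology == "filament") {
    len <- rng(spec$filament_length)
    ang <- stats::runif(1, 0, pi)
    r0 <- stats::runif(1, 2, px - 1); c0 <- stats::runif(1, 2, px - 1)
    .segment_pixels(r0, c0, r0 + len * sin(ang), c0 + len * cos(ang),
                    spec$filament_width, px)
  } else if (morphology == "coccus") {
    rad <- rng(spec$coccus_radius)
    r0 <- stats::runif(1, rad + 1, px - rad)
    c0 <- stats::runif(1, rad + 1, px - rad)
    .segment_pixels(r0, c0, r0, c0, 2 * rad, px)
  } else {
    len <- rng(spec$rod_length)
    ang <- stats::runif(1, 0, pi)
    r0 <- stats::runif(1, 2, px - 1); c0 <- stats::runif(1, 2, px - 1)
    .segment_pixels(r0, c0, r0 + len * sin(ang), c0 + len * cos(ang),
                    spec$rod_width, px)
  }
}

#' Generate a synthetic ion-image scene
#'
#' Places cells without overlap (filaments, cocci, rods per component
#' morphology), assigns each cell a mixture component and a taxon, paints
#' per-pixel expected channel rates (cell expectation spread uniformly
#' over its area, plus a natural-abundance background), and emits
#' independent Poisson planes with optional integer per-plane drift.
#'
#' @param scene A [scene_spec()].
#' @param mixture A [mixture_spec()] or preset name (cell components are
#'   sampled proportionally to the mixture's component sizes).
#' @param seed Integer seed.
#' @param session,region Metadata for the generated stack.
#' @return List: \code{stack} (an \code{ion_stack}), \code{mask} (ground
#'   truth ROI label matrix, plane-0 frame), \code{fish} (ground-truth
#'   taxon table) and \code{truth} (per-cell component/ratios).
#' @export
generate_ion_scene <- function(scene = scene_spec(), mixture = "day7",
                               seed = 1, session = "sim", region = 1L) {
  stopifnot(inherits(scene, "scene_spec"))
  if (is.character(mixture)) mixture <- mixture_spec(mixture)
  set.seed(seed)
  comp <- mixture$components
  px <- scene$pixels
  prob <- comp$n / sum(comp$n)
  cells <- sample(seq_len(nrow(comp)), scene$n_cells, replace = TRUE,
                  prob = prob)
  occupied <- matrix(FALSE, px, px)
  mask <- matrix(0L, px, px)
  placed <- list()
  for (ci in seq_along(cells)) {
    comp_i <- cells[ci]
    ok <- FALSE
    for (try in seq_len(scene$max_retries)) {
      pxs <- .draw_cell_pixels(comp$morphology[comp_i], scene)
      if (is.null(pxs) || nrow(pxs) == 0) next
      # 1-px dilation margin against the occupancy grid
      rr <- pmax(1, pmin(px, rep(pxs$row, 9) + rep(-1:1, each = 3 * nrow(pxs))))
      cc <- pmax(1, pmin(px, rep(rep(pxs$col, each = 1), 9) +
                           rep(rep(-1:1, each = nrow(pxs)), 3)))
      if (any(occupied[cbind(rr, cc)])) next
      occupied[cbind(rr, cc)] <- TRUE
      mask[cbind(pxs$row, pxs$col)] <- ci
      placed[[ci]] <- pxs
      ok <- TRUE
      break
    }
    if (!ok) stop("cell placement failed after ", scene$max_retries,
                  " retries; lower n_cells or cell sizes")
  }
  # per-cell target ratios drawn from the component Gaussians
  draw_row <- function(comp_i) {
    v <- vapply(.ratio_cols, function(rc) {
      mu <- comp[[paste0("mean_", rc)]][comp_i]
      sd <- comp[[paste0("sd_", rc)]][comp_i]
      x <- stats::rnorm(1, mu, sd)
      while (x < mixture$ratio_floor) x <- stats::rnorm(1, mu, sd)
      x
    }, numeric(1))
    as.data.frame(as.list(v))
  }
  cell_ratios <- do.call(rbind, lapply(cells, draw_row))
  cell_expect <- .expected_counts(cell_ratios, scene$cn_per_cell)
  # background: natural-abundance ratios at background_cn CN/px/plane
  rr <- reference_ratios()
  bg_ratio <- data.frame(r13C = rr$R13C_VPDB, r15N = rr$R15N_AIR,
                         r33S = rr$R33S_VCDT, r34S = rr$R34S_VCDT,
                         rC_CN = 0.4, rS_CN = 0.1)
  bg <- .expected_counts(bg_ratio, scene$background_cn * scene$n_planes)
  # paint per-pixel per-plane expected rates
  labels <- .mass_channels$label
  rates <- array(0, dim = c(length(labels), px, px))
  for (ch in seq_along(labels)) rates[ch, , ] <- bg[[ch]] / scene$n_planes
  for (ci in seq_along(cells)) {
    pxs <- placed[[ci]]
    a <- nrow(pxs)
    for (ch in seq_along(labels)) {
      plane <- rates[ch, , ]
      plane[cbind(pxs$row, pxs$col)] <- plane[cbind(pxs$row, pxs$col)] +
        cell_expect[ci, ch] / (a * scene$n_planes)
      rates[ch, , ] <- plane
    }
  }
  # emit Poisson planes with cumulative integer drift
  counts <- array(0L, dim = c(length(labels), scene$n_planes, px, px))
  for (p in seq_len(scene$n_planes)) {
    dy <- round(scene$drift[1] * (p - 1))
    dx <- round(scene$drift[2] * (p - 1))
    for (ch in seq_along(labels)) {
      lam <- matrix(0, px, px)
      src_r <- seq_len(px) - dy
      src_c <- seq_len(px) - dx
      vr <- src_r >= 1 & src_r <= px
      vc <- src_c >= 1 & src_c <= px
      lam[vr, vc] <- rates[ch, src_r[vr], src_c[vc]]
      counts[ch, p, , ] <- stats::rpois(px * px, lam)
    }
  }
  stack <- ion_stack(counts, channels = labels,
                     dwell_time = scene$dwell_time,
                     raster_size = scene$raster_size,
                     session_meta = list(session = session, region = region,
                                         generator = "isophene-synthetic"))
  truth <- data.frame(session = session, region = region,
                      roi_id = seq_along(cells),
                      component = comp$name[cells],
                      morphology = comp$morphology[cells],
                      cell_ratios, stringsAsFactors = FALSE)
  taxon <- vapply(cells, function(comp_i)
    sample(.taxa, 1, prob = c(comp$p_gamma[comp_i], comp$p_delta[comp_i],
                              comp$p_unknown[comp_i])), character(1))
  fish <- data.frame(session = session, region = region,
                     roi_id = seq_along(cells), taxon = taxon,
                     morphology = comp$morphology[cells],
                     stringsAsFactors = FALSE)
  list(stack = stack, mask = mask, fish = fish, truth = truth)
}
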