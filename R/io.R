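# On-disk artifacts: ion-image stacks (one multi-page 32-bit TIFF per mass
# channel + a YAML sidecar), 16-bit label-TIFF ROI masks, TSV count tables,
# CSV FISH label tables, and TSV/PNG reports.
#
# R's tiff writer treats sample values outside [0, 1] as undefined, so
# count images are stored as counts/(2^32 - 1) at 32 bits/sample: integer
# counts below 2^31 round-trip bit-equal through readTIFF(as.is = TRUE).

.MAX32 <- 2^32 - 1
.MAX16 <- 2^16 - 1

#' Construct an ion-image stack
#'
#' In-memory container for a multi-mass, multi-plane NanoSIMS
#' acquisition: a numeric array indexed (channel, plane, row, col) plus
#' acquisition metadata.
#'
#' @param counts Array (channel, plane, row, col); non-negative. Raw
#'   acquisitions are integral; dead-time-corrected stacks are real.
#' @param channels Character vector of channel labels (one per array
#'   slice), e.g. \code{c("12C", "13C", ...)}; must be unique.
#' @param dwell_time Dwell time per pixel in seconds (> 0).
#' @param raster_size Raster side length in micrometers (> 0).
#' @param session_meta Free-form named list (wafer id, time point, ...).
#' @return Object of class \code{ion_stack}.
#' @export
ion_stack <- function(counts, channels, dwell_time, raster_size,
                      session_meta = list()) {
  if (length(dim(counts)) == 3)  # single channel convenience
    dim(counts) <- c(1, dim(counts))
  stopifnot(length(dim(counts)) == 4)
  if (length(channels) != dim(counts)[1])
    stop("number of channel labels does not match the counts array")
  if (anyDuplicated(channels)) stop("channel labels must be unique")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (dwell_time <= 0) stop("dwell_time must be positive")
  if (raster_size <= 0) stop("raster_size must be positive")
  dimnames(counts) <- list(channels, NULL, NULL, NULL)
  structure(list(counts = counts, channels = channels,
                 dwell_time = dwell_time, raster_size = raster_size,
                 session_meta = session_meta),
            class = "ion_stack")
}

#' @export
print.ion_stack <- function(x, ...) {
  d <- dim(x$counts)
  cat("Ion image stack:", d[1], "channels x", d[2], "plane(s),",
      d[3], "x", d[4], "px,", x$raster_size, "um raster,",
      x$dwell_time * 1000, "ms dwell\n")
  cat("channels:", paste(x$channels, collapse = " "), "\n")
  invisible(x)
}

#' Write / read an ion-image stack directory
#'
#' Layout: one multi-page 32-bit TIFF per mass channel
#' (\code{<label>.tif}) plus a \code{stack.yaml} sidecar carrying channel
#' names, dwell time, raster size and session metadata.
#'
#' @param stack An [ion_stack()].
#' @param path Directory (created if needed).
#' @return \code{write_ion_stack} invisibly returns the files written;
#'   \code{read_ion_stack} returns the \code{ion_stack}. Missing channel
#'   files and plane-count mismatches across channels raise errors naming
#'   the offending channel.
#' @export
write_ion_stack <- function(stack, path) {
  stopifnot(inherits(stack, "ion_stack"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  d <- dim(stack$counts)
  if (any(stack$counts > 2^31 - 1))
    stop("counts exceed the 32-bit storage range")
  files <- character(0)
  for (ch in seq_len(d[1])) {
    pages <- lapply(seq_len(d[2]),
                    function(p) stack$counts[ch, p, , ] / .MAX32)
    f <- file.path(path, paste0(stack$channels[ch], ".tif"))
    tiff::writeTIFF(pages, f, bits.per.sample = 32L, reduce = FALSE)
    files <- c(files, f)
  }
  side <- file.path(path, "stack.yaml")
  yaml::write_yaml(list(channels = as.list(stack$channels),
                        dwell_time = stack$dwell_time,
                        raster_size = stack$raster_size,
                        pixels = c(d[3], d[4]), n_planes = d[2],
                        session_meta = stack$session_meta), side)
  invisible(c(files, side))
}

#' @rdname write_ion_stack
#' @export
read_ion_stack <- function(path) {
  side <- file.path(path, "stack.yaml")
  if (!file.exists(side)) stop("no stack.yaml sidecar in ", path)
  meta <- yaml::read_yaml(side)
  channels <- unlist(meta$channels)
  pages <- vector("list", length(channels))
  for (ch in seq_along(channels)) {
    f <- file.path(path, paste0(channels[ch], ".tif"))
    if (!file.exists(f))
      stop("missing image file for channel ", channels[ch])
    pg <- tiff::readTIFF(f, all = TRUE, as.is = TRUE)
    if (!is.list(pg)) pg <- list(pg)
    pages[[ch]] <- pg
  }
  n_planes <- vapply(pages, length, integer(1))
  if (length(unique(n_planes)) != 1)
    stop("plane-count mismatch across channels: ",
         paste(channels, n_planes, sep = "=", collapse = ", "))
  dims <- dim(pages[[1]][[1]])
  counts <- array(0, dim = c(length(channels), n_planes[1], dims[1], dims[2]))
  for (ch in seq_along(channels))
    for (p in seq_len(n_planes[1]))
      counts[ch, p, , ] <- pages[[ch]][[p]]
  if (any(counts < 0))
    stop("negative stored counts; file exceeds the 32-bit storage range")
  ion_stack(counts, channels, meta$dwell_time, meta$raster_size,
            if (is.null(meta$session_meta)) list() else meta$session_meta)
}

#' Write / read an ROI label mask
#'
#' Single-page 16-bit unsigned label TIFF: 0 = background, i >= 1 = ROI id.
#'
#' @param mask Integer matrix of labels (0 .. 65535).
#' @param path File path.
#' @return \code{read_roi_mask} returns the integer label matrix.
#' @export
write_roi_mask <- function(mask, path) {
  mask <- as.matrix(mask)
  if (any(mask < 0) || any(mask != round(mask)))
    stop("mask labels must be non-negative integers")
  if (any(mask > .MAX16)) stop("mask labels exceed 16-bit range")
  tiff::writeTIFF(mask / .MAX16, path, bits.per.sample = 16L,
                  reduce = FALSE)
  invisible(path)
}

#' @rdname write_roi_mask
#' @export
read_roi_mask <- function(path) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  storage.mode(m) <- "integer"
  m
}

.validate_roi_table <- function(tab) {
  miss <- setdiff(.roi_table_cols, names(tab))
  if (length(miss) > 0)
    stop("ROI table missing columns: ", paste(miss, collapse = ", "))
  for (cc in .count_cols) {
    bad <- which(tab[[cc]] < 0)
    if (length(bad) > 0)
      stop("negative count in column ", cc, " at row ", bad[1])
  }
  if (any(tab$area_px < 1)) stop("area_px must be >= 1")
  key <- do.call(paste, c(tab[.key_cols], sep = "\r"))
  if (anyDuplicated(key))
    stop("duplicate (session, region, roi_id) key at row ",
         which(duplicated(key))[1])
  tab
}

#' Write / read an ROI count table (TSV)
#'
#' Tab-separated with header
#' \code{session region roi_id c12 c13 nc14 nc15 s32 s33 s34 centroid_x
#' centroid_y area_px n_planes}; unknown extra columns are preserved.
#' Negative counts and duplicate keys are validation errors citing the
#' offending row.
#'
#' @param tab ROI count table data frame.
#' @param path File path.
#' @return \code{read_roi_table} returns the validated data frame.
#' @export
write_roi_table <- function(tab, path) {
  tab <- .validate_roi_table(tab)
  extra <- setdiff(names(tab), .roi_table_cols)
  utils::write.table(tab[c(.roi_table_cols, extra)], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_roi_table
#' @export
read_roi_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  .validate_roi_table(tab)
}

#' Write / read a FISH taxon label table (CSV)
#'
#' Header \code{session,region,roi_id,taxon,morphology}; \code{taxon}
#' drawn from \{gamma, delta, unknown\}, \code{morphology} (optional)
#' from \{filament, coccus, rod, unknown\}.
#'
#' @param tab FISH label data frame.
#' @param path File path.
#' @return \code{read_fish_table} returns the validated data frame.
#' @export
write_fish_table <- function(tab, path) {
  stopifnot(all(c(.key_cols, "taxon") %in% names(tab)))
  if (!"morphology" %in% names(tab)) tab$morphology <- "unknown"
  utils::write.csv(tab[c(.key_cols, "taxon", "morphology")], path,
                   quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fish_table
#' @export
read_fish_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c(.key_cols, "taxon"), names(tab))
  if (length(miss) > 0)
    stop("FISH table missing columns: ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(tab$taxon), .taxa)
  if (length(bad) > 0)
    stop("unknown taxon value(s): ", paste(bad, collapse = ", "))
  if ("morphology" %in% names(tab)) {
    badm <- setdiff(unique(tab$morphology), .morphologies)
    if (length(badm) > 0)
      stop("unknown morphology value(s): ", paste(badm, collapse = ", "))
  }
  tab
}

#' Write an analysis report directory
#'
#' Writes each table of a named list as a TSV with deterministic column
#' order (as supplied), plus optional spatial phenotype maps.
#'
#' @param tables Named list of data frames (e.g. phenotype summary,
#'   crosstab counts).
#' @param path Output directory (created if needed).
#' @param spatial Optional list passed to [export_spatial_map()]:
#'   \code{labels_df}, and optionally \code{fish}, \code{mask},
#'   \code{pixels}.
#' @return Invisible character vector of files written.
#' @export
write_report <- function(tables, path, spatial = NULL) {
  stopifnot(is.list(tables), !is.null(names(tables)))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (nm in names(tables)) {
    x <- tables[[nm]]
    if (is.matrix(x)) x <- data.frame(rownames = rownames(x), x,
                                      check.names = FALSE)
    f <- file.path(path, paste0(nm, ".tsv"))
    utils::write.table(x, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)
  }
  if (!is.null(spatial))
    files <- c(files, do.call(export_spatial_map,
                              c(spatial, list(path = path))))
  invisible(files)
}
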