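# Isotope arithmetic: ratio computation from accumulated counts,
# instrumental fractionation correction, delta/ratio/atom-fraction
# conversions, and the labeling mass-balance mixing formula.

#' Compute isotope and elemental ratios from an ROI count table
#'
#' Ratios are computed from ROI-summed accumulated counts (not from
#' per-pixel ratio averages): \code{r13C} = 13C/12C, \code{r15N} =
#' 15N12C/14N12C, \code{r33S} = 33S/32S, \code{r34S} = 34S/32S,
#' \code{rC_CN} = (12C+13C)/(14N12C+15N12C) and \code{rS_CN} =
#' (32S+33S+34S)/(14N12C+15N12C). Rows with a zero denominator for any
#' ratio (no 12C, no CN or no 32S signal) are dropped with a message;
#' a cell with no biomass signal is not a cell measurement.
#'
#' @param table ROI count table as returned by [tabulate_roi_counts()] or
#'   [read_roi_table()]: one row per ROI with columns
#'   \code{c12, c13, nc14, nc15, s32, s33, s34} plus key columns
#'   \code{session, region, roi_id}.
#' @return Data frame with the key columns and the six ratio columns,
#'   attribute \code{corrected = FALSE}, and attribute \code{dropped}
#'   holding the keys of any removed rows.
#' @seealso [fractionation_correct()]
#' @export
compute_ratios <- function(table) {
  stopifnot(is.data.frame(table))
  miss <- setdiff(c(.key_cols, .count_cols), names(table))
  if (length(miss) > 0)
    stop("count table is missing columns: ", paste(miss, collapse = ", "))
  cnt <- table[.count_cols]
  if (any(vapply(cnt, function(x) any(x < 0), logical(1))))
    stop("negative counts in count table")
  cn <- table$nc14 + table$nc15
  bad <- table$c12 == 0 | table$nc14 == 0 | table$s32 == 0 | cn == 0
  dropped <- table[bad, .key_cols, drop = FALSE]
  if (any(bad))
    message(sum(bad), " ROI(s) dropped: zero denominator counts")
  t2 <- table[!bad, , drop = FALSE]
  cn <- cn[!bad]
  out <- data.frame(
    t2[.key_cols],
    r13C  = t2$c13 / t2$c12,
    r15N  = t2$nc15 / t2$nc14,
    r33S  = t2$s33 / t2$s32,
    r34S  = t2$s34 / t2$s32,
    rC_CN = (t2$c12 + t2$c13) / cn,
    rS_CN = (t2$s32 + t2$s33 + t2$s34) / cn,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "corrected") <- FALSE
  attr(out, "dropped") <- dropped
  out
}

#' Correct ratios for instrumental isotope fractionation
#'
#' Multiplies each ratio column by \code{true/measured} of a calibration
#' standard measured in the same session (e.g. spores of known isotopic
#' composition measured independently by EA-IRMS). By default only the
#' carbon and nitrogen isotope ratios are corrected; a sulfur correction
#' is typically not possible when the standard contains too little sulfur,
#' and uncorrected columns pass through unchanged.
#'
#' @param ratios Ratio table from [compute_ratios()].
#' @param standard Named list; each element, named after a ratio column,
#'   is a numeric vector with elements \code{measured} (the session mean
#'   ratio of the standard on the instrument) and \code{true} (its
#'   independently measured value). See [calibration_standard()].
#' @return The ratio table with corrected columns and attribute
#'   \code{corrected = TRUE}.
#' @export
fractionation_correct <- function(ratios, standard) {
  stopifnot(is.data.frame(ratios), is.list(standard))
  for (col in names(standard)) {
    if (!col %in% .ratio_cols)
      stop("unknown ratio column in standard: ", col)
    st <- standard[[col]]
    if (!all(c("measured", "true") %in% names(st)))
      stop("standard for ", col, " must have 'measured' and 'true'")
    if (st[["measured"]] <= 0 || st[["true"]] <= 0)
      stop("standard ratios for ", col, " must be positive")
    ratios[[col]] <- ratios[[col]] * (st[["true"]] / st[["measured"]])
  }
  attr(ratios, "corrected") <- TRUE
  ratios
}

#' Build a calibration standard from session measurements
#'
#' Convenience constructor for the \code{standard} argument of
#' [fractionation_correct()].
#'
#' @param r13C,r15N,r33S,r34S Each \code{NULL} (no correction for that
#'   ratio) or a numeric vector \code{c(measured = , true = )}.
#' @return Named list of measured/true pairs.
#' @export
calibration_standard <- function(r13C = NULL, r15N = NULL,
                                 r33S = NULL, r34S = NULL) {
  std <- list(r13C = r13C, r15N = r15N, r33S = r33S, r34S = r34S)
  std[!vapply(std, is.null, logical(1))]
}

#' Delta notation conversions
#'
#' \code{ratio_from_delta} computes \eqn{R = R_{ref} (1 + \delta/1000)};
#' \code{delta_from_ratio} is its exact inverse. Deltas are in permil.
#'
#' @param delta Delta value(s) in permil; must exceed -1000.
#' @param ratio Isotope ratio(s), non-negative.
#' @param R_ref Reference ratio of the standard (e.g. VPDB for carbon),
#'   strictly positive. See [reference_ratios()].
#' @return Numeric vector of ratios (or deltas).
#' @export
ratio_from_delta <- function(delta, R_ref) {
  stopifnot(is.numeric(delta), is.numeric(R_ref), all(R_ref > 0))
  if (any(delta <= -1000))
    stop("delta <= -1000 permil implies a nonpositive ratio")
  R_ref * (1 + delta / 1000)
}

#' @rdname ratio_from_delta
#' @export
delta_from_ratio <- function(ratio, R_ref) {
  stopifnot(is.numeric(ratio), is.numeric(R_ref), all(R_ref > 0))
  if (any(ratio < 0)) stop("ratio must be non-negative")
  1000 * (ratio / R_ref - 1)
}

#' Atom fraction conversions (two-isotope system)
#'
#' \code{atom_fraction_from_ratio} computes \eqn{F = R/(1+R)};
#' \code{ratio_from_atom_fraction} computes \eqn{R = F/(1-F)}. These are
#' mutually inverse. at.\% = 100 F. The two-isotope approximation is used
#' for all elements, including sulfur (34S/36S neglected in the 33S atom
#' fraction), matching single-ratio usage in labeling experiments.
#'
#' @param R Isotope ratio(s), non-negative.
#' @param F Atom fraction(s) in [0, 1).
#' @return Numeric vector.
#' @export
atom_fraction_from_ratio <- function(R) {
  stopifnot(is.numeric(R))
  if (any(R < 0)) stop("ratio must be non-negative")
  R / (1 + R)
}

#' @rdname atom_fraction_from_ratio
#' @export
ratio_from_atom_fraction <- function(F) {
  stopifnot(is.numeric(F))
  if (any(F < 0) || any(F >= 1)) stop("atom fraction must be in [0, 1)")
  F / (1 - F)
}

#' Isotope mass balance of a labeled/unlabeled mixture
#'
#' Amount-weighted mean atom fraction of a mixture of an unlabeled and an
#' isotopically labeled pool:
#' \deqn{F_{final} = (F_{unl} m_{unl} + F_{lab} m_{lab}) / (m_{unl} + m_{lab})}
#' Used to compute the at.\% enrichment of a substrate amendment prepared
#' from a labeled stock.
#'
#' @param F_unlabeled,F_labeled Atom fractions in [0, 1].
#' @param m_unlabeled,m_labeled Amounts (mol or g; any consistent unit),
#'   non-negative with a positive sum.
#' @return List with \code{F_final} and \code{at_percent} (= 100 F).
#' @export
mass_balance_mix <- function(F_unlabeled, m_unlabeled, F_labeled, m_labeled) {
  stopifnot(F_unlabeled >= 0, F_unlabeled <= 1,
            F_labeled >= 0, F_labeled <= 1,
            m_unlabeled >= 0, m_labeled >= 0)
  m_final <- m_unlabeled + m_labeled
  if (m_final <= 0) stop("total amount must be positive")
  Ff <- (F_unlabeled * m_unlabeled + F_labeled * m_labeled) / m_final
  list(F_final = Ff, at_percent = 100 * Ff)
}
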