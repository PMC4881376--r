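#' @useDynLib isophene, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Canonical seven-mass channel set of a NanoSIMS 50L CN/S session and the
# ratio columns derived from it. Column order is fixed package-wide.
.mass_channels <- data.frame(
  label        = c("12C", "13C", "14N12C", "15N12C", "32S", "33S", "34S"),
  species      = c("C", "C", "CN", "CN", "S", "S", "S"),
  nominal_mass = c(12L, 13L, 26L, 27L, 32L, 33L, 34L),
  stringsAsFactors = FALSE
)

# ROI count table columns holding the seven accumulated mass counts,
# in channel order.
.count_cols <- c("c12", "c13", "nc14", "nc15", "s32", "s33", "s34")

.roi_table_cols <- c("session", "region", "roi_id", .count_cols,
                     "centroid_x", "centroid_y", "area_px", "n_planes")

.ratio_cols <- c("r13C", "r15N", "r33S", "r34S", "rC_CN", "rS_CN")

# The five ratios used for phenotype clustering (r34S carries no label
# signal in a 13C/15N/33S experiment and is excluded by default).
.cluster_cols <- c("r13C", "r15N", "r33S", "rC_CN", "rS_CN")

.key_cols <- c("session", "region", "roi_id")

.taxa <- c("gamma", "delta", "unknown")
.morphologies <- c("filament", "coccus", "rod", "unknown")

#' Mass channels measured in parallel
#'
#' The canonical seven-mass set collected in a single-session CN/S
#' NanoSIMS run: \code{12C}, \code{13C}, \code{14N12C}, \code{15N12C},
#' \code{32S}, \code{33S}, \code{34S}.
#'
#' @return A data frame with columns \code{label}, \code{species}
#'   (element-composition tag) and \code{nominal_mass} (amu).
#' @export
mass_channels <- function() .mass_channels

#' Reference isotope ratios
#'
#' Standard reference ratios used in delta-notation conversions:
#' VPDB for carbon, atmospheric N2 (AIR) for nitrogen, VCDT for sulfur.
#' All values are dimensionless isotope ratios and can be overridden by
#' passing explicit \code{R_ref} arguments to the conversion functions.
#'
#' @return Named list with elements \code{R13C_VPDB}, \code{R15N_AIR},
#'   \code{R33S_VCDT}, \code{R34S_VCDT}.
#' @export
reference_ratios <- function() {
  list(R13C_VPDB = 0.0112372, R15N_AIR = 0.0036765,
       R33S_VCDT = 0.0078772, R34S_VCDT = 0.0441626)
}

# Per-cluster mixture parameters for the five study conditions: incubation
# time points 2, 7 and 10 days, an unlabeled control (NL, 7 days) and a
# formaldehyde-killed control (K, 10 days). Each block gives, per phenotype
# component a-e: number of ROIs, mean and sd of the five measured ratios.
#
# The 34S/32S ratio is not part of the published per-cluster summaries; the
# generator assumes natural-abundance 34S (mean 0.0442, sd 0.002) for every
# component, documented in the methods vignette.
.preset_block <- function(n, m, s) {
  m <- rbind(m[1:3, , drop = FALSE],
             r34S = rep(0.0442, 5),
             m[4:5, , drop = FALSE])
  s <- rbind(s[1:3, , drop = FALSE],
             r34S = rep(0.002, 5),
             s[4:5, , drop = FALSE])
  dimnames(m) <- dimnames(s) <- list(.ratio_cols, letters[1:5])
  names(n) <- letters[1:5]
  list(n = n, mean = m, sd = s)
}

.presets <- list(
  day2 = .preset_block(
    n = c(253, 107, 257, 30, 18),
    m = rbind(c(0.0625, 0.2284, 0.1889, 0.1086, 0.1757),
              c(0.0187, 0.0569, 0.0508, 0.0370, 0.0704),
              c(0.0094, 0.0164, 0.0141, 0.0122, 0.0622),
              c(0.4239, 0.5943, 0.3383, 0.2667, 0.3066),
              c(0.1084, 0.1415, 0.1028, 0.2554, 0.1281)),
    s = rbind(c(0.0363, 0.1024, 0.0580, 0.0486, 0.0974),
              c(0.0112, 0.0158, 0.0123, 0.0167, 0.0259),
              c(0.0028, 0.0070, 0.0056, 0.0051, 0.0245),
              c(0.1159, 0.1267, 0.0830, 0.0842, 0.1191),
              c(0.0219, 0.0213, 0.0206, 0.1106, 0.0268))),
  day7 = .preset_block(
    n = c(443, 136, 106, 32, 60),
    m = rbind(c(0.0304, 0.0499, 0.2687, 0.0694, 0.1323),
              c(0.0105, 0.0157, 0.0532, 0.0217, 0.1001),
              c(0.0151, 0.0150, 0.0306, 0.0078, 0.2229),
              c(0.3736, 0.7612, 0.5187, 0.4769, 0.2759),
              c(0.0886, 0.1509, 0.1188, 0.3125, 0.0690)),
    s = rbind(c(0.0298, 0.0385, 0.1112, 0.0397, 0.0850),
              c(0.0105, 0.0100, 0.0125, 0.0103, 0.0162),
              c(0.0109, 0.0102, 0.0249, 0.0016, 0.0899),
              c(0.1042, 0.1953, 0.1529, 0.2435, 0.1203),
              c(0.0193, 0.0326, 0.0275, 0.0815, 0.0193))),
  day10 = .preset_block(
    n = c(306, 0, 158, 66, 230),
    m = rbind(c(0.0655, NA, 0.1943, 0.0910, 0.0968),
              c(0.0379, NA, 0.0561, 0.0448, 0.0739),
              c(0.0146, NA, 0.0285, 0.0446, 0.0887),
              c(0.3113, NA, 0.5350, 0.8700, 0.3907),
              c(0.0648, NA, 0.0650, 0.1660, 0.0833)),
    s = rbind(c(0.0385, NA, 0.0638, 0.0452, 0.0307),
              c(0.0207, NA, 0.0104, 0.0196, 0.0106),
              c(0.0169, NA, 0.0233, 0.0283, 0.0199),
              c(0.1853, NA, 0.1987, 0.3895, 0.1100),
              c(0.0243, NA, 0.0134, 0.0905, 0.0213))),
  NL = .preset_block(
    n = c(155, 133, 39, 193, 125),
    m = rbind(c(0.0109, 0.0105, 0.0106, 0.0109, 0.0112),
              c(0.0036, 0.0034, 0.0034, 0.0034, 0.0034),
              c(0.0074, 0.0074, 0.0092, 0.0068, 0.0067),
              c(0.3687, 0.4739, 0.4149, 0.1868, 0.3557),
              c(0.0656, 0.0697, 0.0652, 0.1103, 0.2220)),
    s = rbind(c(0.0003, 0.0003, 0.0004, 0.0003, 0.0003),
              c(0.0001, 0.0001, 0.0001, 0.0001, 0.0001),
              c(0.0004, 0.0004, 0.0009, 0.0003, 0.0002),
              c(0.0891, 0.1442, 0.1209, 0.0701, 0.1202),
              c(0.0168, 0.0274, 0.0213, 0.0387, 0.0607))),
  K = .preset_block(
    n = c(110, 79, 55, 13, 11),
    m = rbind(c(0.0115, 0.0123, 0.0116, 0.0120, 0.0241),
              c(0.0046, 0.0041, 0.0044, 0.0064, 0.0048),
              c(0.0049, 0.0063, 0.0061, 0.0066, 0.0061),
              c(0.3165, 0.1999, 0.4473, 0.2845, 0.4123),
              c(0.0738, 0.0855, 0.1433, 0.0684, 0.0841)),
    s = rbind(c(0.0015, 0.0015, 0.0010, 0.0009, 0.0060),
              c(0.0004, 0.0003, 0.0003, 0.0008, 0.0005),
              c(0.0009, 0.0007, 0.0008, 0.0015, 0.0003),
              c(0.0729, 0.0935, 0.1433, 0.0504, 0.0903),
              c(0.0137, 0.0255, 0.0618, 0.0287, 0.0225)))
)

# Default taxon composition and morphology per phenotype component,
# following the FISH correspondence of the phenotype clusters: a-c are
# predominantly filamentous Gammaproteobacteria (86/98/92%), d coccoidal
# Gammaproteobacteria (85%, rest DAPI-only), e Deltaproteobacteria
# (68%, rest unhybridized).
.component_taxon_mix <- rbind(
  a = c(gamma = 0.86, delta = 0.02, unknown = 0.12),
  b = c(gamma = 0.98, delta = 0.01, unknown = 0.01),
  c = c(gamma = 0.92, delta = 0.03, unknown = 0.05),
  d = c(gamma = 0.85, delta = 0.00, unknown = 0.15),
  e = c(gamma = 0.00, delta = 0.68, unknown = 0.32)
)

.component_morphology <- c(a = "filament", b = "filament", c = "filament",
                           d = "coccus", e = "rod")
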