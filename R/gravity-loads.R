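# Distributed body-weight loading of the L3-S1 model.
#
# A body-segment table (head, cervical, thoracic and lumbar levels)
# provides per-level body-mass percentages, sagittal moments of inertia
# and anteroposterior eccentricities of the segmental centers of mass.
# The standing scenario lumps everything cranial to L3 into one eccentric
# vertical load at L3/L4 and applies the L4 and L5 segment weights
# locally.  Units: kg, cm (inertia input), mm (eccentricities), N.

#' Body segment table
#'
#' Reads the packaged body-segment fixture: per-level body-mass
#' percentage (`bm_percent`), local sagittal moment of inertia `iz`
#' (kg cm^2), the parallel-axis-transferred inertia about the L3/L4
#' center-of-mass axis `iz_L3` (kg cm^2, thoracic and upper lumbar rows
#' only), and the anteroposterior eccentricity `r_mm` of the segmental
#' center of mass relative to the vertebral center.  The `r_mm` column is
#' a calibrated default (see the fixture header and the vignette): the
#' profile shape is anthropometrically plausible and its overall scale is
#' set so that the default effective eccentricity at L3/L4 is 41.4 mm.
#'
#' @return Data frame with one row per level, `HD`, `C1`..`C7`,
#'   `T1`..`T12`, `L1`..`L5`.
#' @export
body_segment_table <- function() {
  path <- system.file("extdata", "body_segments.csv", package = "spinewell",
                      mustWork = TRUE)
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Scale segment masses to a total body mass
#'
#' `mass_i = bm_percent_i / 100 * total_body_mass`.  The percentages are
#' authoritative; the historically published per-segment masses of the
#' lower lumbar rows are internally inconsistent with them and are kept
#' in the fixture only for provenance.
#'
#' @param total_body_mass Total body mass (kg, >= 0).
#' @param table A [body_segment_table()] (or subset of rows).
#' @return Named numeric vector of masses (kg).
#' @export
scale_masses <- function(total_body_mass, table = body_segment_table()) {
  if (!is.numeric(total_body_mass) || total_body_mass < 0) {
    stop("total_body_mass must be >= 0")
  }
  m <- table$bm_percent / 100 * total_body_mass
  names(m) <- table$label
  m
}

#' Parallel-axis (Huygens-Steiner) inertia transfer
#'
#' @param mass Segment mass (kg, >= 0).
#' @param d Perpendicular distance between the segment's own vertical
#'   center-of-mass axis and the reference axis (cm).
#' @return Transferred moment of inertia `mass * d^2` (kg cm^2).
#' @export
steiner_inertia <- function(mass, d) {
  if (any(mass < 0)) stop("mass must be >= 0")
  mass * d^2
}

#' Effective sagittal moment of inertia at L3/L4
#'
#' Sum of the 14 parallel-axis-transferred contributions of T1..L2 about
#' the vertical axis through the L3/L4 center of mass, plus the local
#' L3/L4 term.  Head and cervical rows are excluded: their axis distances
#' are of order 1e-2 cm^2 squared, so their transfer terms are
#' negligible.
#'
#' @param table A [body_segment_table()].
#' @param iz_local_L3 Local moment of inertia at L3/L4 (kg cm^2).  The
#'   fixture's published L3 `iz` entry refers to a larger model and is not
#'   this local term, so it must be given explicitly (default 0).
#' @return Effective inertia (kg cm^2).
#' @export
effective_inertia_L3 <- function(table = body_segment_table(),
                                 iz_local_L3 = 0) {
  lev <- c(paste0("T", 1:12), "L1", "L2")
  rows <- table[match(lev, table$label), ]
  bad <- lev[is.na(rows$iz_L3)]
  if (length(bad)) {
    stop("config error: missing iz_L3 entries for rows ",
         paste(bad, collapse = ", "))
  }
  sum(rows$iz_L3) + iz_local_L3
}

#' Effective eccentricity of the lumped gravity load at L3/L4
#'
#' Mass-weighted mean anteroposterior eccentricity of the segmental
#' centers of mass of all levels lumped at L3/L4 (head through L3):
#' `R_eff = sum(m_i r_i) / sum(m_i)`.  Independent of the total body mass
#' because the weights are proportional to the body-mass percentages.
#'
#' @param table A [body_segment_table()].
#' @param total_body_mass Total body mass (kg).
#' @return Effective eccentricity (mm).
#' @export
effective_eccentricity <- function(table = body_segment_table(),
                                   total_body_mass = 70.8) {
  lev <- c("HD", paste0("C", 1:7), paste0("T", 1:12), "L1", "L2", "L3")
  rows <- table[table$label %in% lev & !is.na(table$r_mm), ]
  if (nrow(rows) == 0L) stop("no rows with eccentricity data")
  m <- scale_masses(total_body_mass, rows)
  sum(m * rows$r_mm) / sum(m)
}

#' Distribute the standing gravity load over the modeled levels
#'
#' Three eccentric vertical loads: the lumped weight of everything
#' cranial to the L3/L4 disk (head through L3) applied at the effective
#' eccentricity, and the local L4 and L5 segment weights at their own
#' eccentricities.
#'
#' @param total_body_mass Total body mass (kg, > 0).
#' @param table A [body_segment_table()].
#' @param g Gravitational acceleration (m/s^2).
#' @param ecc_l45,ecc_l5s1 Anterior eccentricities of the local L4/L5
#'   and L5/S1 loads (mm).
#' @return Object of class `load_set`: data frame with columns `level`,
#'   `magnitude` (N) and `eccentricity` (mm anterior to the segmental
#'   vertebral center).
#' @export
distribute_gravity_loads <- function(total_body_mass = 70.8,
                                     table = body_segment_table(),
                                     g = 9.81,
                                     ecc_l45 = 11,
                                     ecc_l5s1 = 4) {
  if (total_body_mass <= 0) stop("total_body_mass must be > 0")
  m <- scale_masses(total_body_mass, table)
  upper <- c("HD", paste0("C", 1:7), paste0("T", 1:12), "L1", "L2", "L3")
  w_upper <- g * sum(m[upper])
  out <- data.frame(
    level = c("L3/L4", "L4/L5", "L5/S1"),
    magnitude = c(w_upper, g * m[["L4"]], g * m[["L5"]]),
    eccentricity = c(effective_eccentricity(table, total_body_mass),
                     ecc_l45, ecc_l5s1),
    stringsAsFactors = FALSE
  )
  structure(out, class = c("load_set", "data.frame"))
}
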