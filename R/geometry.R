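# Area-to-volume geometry for xenografted tumor masses.
#
# The stained tumor cross-section is treated as the equatorial disc of a
# sphere, so a 2-D area A maps to an equivalent radius r = sqrt(A/pi) and an
# equivalent volume V = (4/3) pi r^3.  Because V is proportional to A^{3/2},
# the percent volume change between the two imaging timepoints can be
# computed directly from the area ratio without materializing volumes.

#' Canonical treatment arm labels
#'
#' The five arms of the screening design: an untreated control plus the four
#' fluoropyrimidine-based regimens tested on the avatars. `CONTROL` is always
#' the model baseline.
#'
#' @format Character vector of length 5.
#' @export
TREATMENT_LEVELS <- c("CONTROL", "5FU", "FOLFOX", "FOLFIRI", "FOLFOXIRI")

# Offset added to percent volume change before the log10 transform; chosen so
# the transformed outcome is defined down to complete regression (-100%).
PDV_OFFSET <- 110

#' Equivalent radius of a stained tumor area
#'
#' Radius of the circle with the same area as the segmented tumor
#' cross-section, i.e. `r = sqrt(area / pi)`.
#'
#' @param area Numeric vector of areas (any consistent unit, `>= 0`).
#' @return Numeric vector of radii in the corresponding length unit.
#' @examples
#' equivalent_radius(pi)  # 1
#' @export
equivalent_radius <- function(area) {
  if (!is.numeric(area)) stop("'area' must be numeric", call. = FALSE)
  if (any(is.finite(area) & area < 0))
    stop("invalid measurement: negative area", call. = FALSE)
  sqrt(area / pi)
}

#' Volume of a sphere of given radius
#'
#' @param r Numeric vector of radii (`>= 0`).
#' @return `(4/3) * pi * r^3`.
#' @export
sphere_volume <- function(r) {
  if (!is.numeric(r)) stop("'r' must be numeric", call. = FALSE)
  if (any(is.finite(r) & r < 0)) stop("invalid input: negative radius", call. = FALSE)
  (4 / 3) * pi * r^3
}

#' Percent change in equivalent tumor volume
#'
#' Percent change of the equivalent spherical volume between the start
#' (2 hpi) and end (48 hpi) images. Since volume scales as area^{3/2},
#' `%dV = 100 * ((area_end / area_start)^{3/2} - 1)`; the value is bounded
#' below by -100 (complete regression).
#'
#' @param area_start Positive start areas (2 hpi).
#' @param area_end Non-negative end areas (48 hpi), same units.
#' @return Numeric vector of percent volume changes.
#' @examples
#' percent_delta_v(10, 40)  # ratio 4 -> 4^1.5 = 8 -> +700%
#' @export
percent_delta_v <- function(area_start, area_end) {
  if (any(is.finite(area_start) & area_start <= 0))
    stop("invalid measurement: 'area_start' must be > 0", call. = FALSE)
  if (any(is.finite(area_end) & area_end < 0))
    stop("invalid measurement: 'area_end' must be >= 0", call. = FALSE)
  100 * ((area_end / area_start)^(3 / 2) - 1)
}

#' Log-shifted transform of percent volume change
#'
#' The outcome modelled by [zpdx_lmm()]: `y = log10(pdv + 110)`. The offset
#' keeps the argument positive for any attainable percent change
#' (`pdv >= -100` gives `y >= 1`) and symmetrizes the strong positive skew of
#' raw percent changes.
#'
#' @param pdv Percent volume change, `>= -100`.
#' @return `log10(pdv + 110)`.
#' @seealso [inv_transform_pdv()] for the inverse.
#' @export
transform_pdv <- function(pdv) {
  if (any(is.finite(pdv) & pdv < -100))
    stop("domain error: percent volume change below -100", call. = FALSE)
  log10(pdv + PDV_OFFSET)
}

#' Inverse of the log-shifted transform
#'
#' @param y Transformed outcome.
#' @return `10^y - 110`, the percent volume change.
#' @export
inv_transform_pdv <- function(y) 10^y - PDV_OFFSET

#' Circularity shape factor
#'
#' Standard isoperimetric shape factor `4 * pi * A / P^2`, equal to 1 for a
#' perfect circle and below 1 for any other simple closed shape. Used to
#' screen grafts for which the spherical-volume assumption is doubtful;
#' screening warns, it never excludes.
#'
#' @param area Cross-section area.
#' @param perimeter Cross-section perimeter, `> 0`.
#' @return Shape factor in `(0, 1]` for simple closed contours.
#' @export
circularity <- function(area, perimeter) {
  if (any(is.finite(perimeter) & perimeter <= 0))
    stop("invalid input: perimeter must be > 0", call. = FALSE)
  4 * pi * area / perimeter^2
}

#' Derive per-embryo volume-change outcomes from raw measurements
#'
#' Computes, for every embryo, the equivalent start radius, its cube (the
#' initial-volume proxy used as model covariate), the percent equivalent
#' volume change and its log-shifted transform. If start perimeters are
#' available, grafts whose circularity falls below `circularity_threshold`
#' are flagged (with a single summary warning); they are never dropped.
#'
#' @param measurements Data frame with columns `zpdx_id`, `patient_id`,
#'   `treatment`, `embryo_id`, `area_start`, `area_end` and optionally
#'   `perimeter_start`, as returned by [read_measurements()] or
#'   [simulate_cohort()].
#' @param circularity_threshold Shape-factor value below which a graft is
#'   flagged as poorly spherical (default 0.6).
#' @return The input with added columns `r_start`, `r_cubed_start`, `pdv`,
#'   `y`, and (when perimeters exist) `circ` and `low_circularity`.
#' @export
derive_volume_changes <- function(measurements, circularity_threshold = 0.6) {
  required <- c("zpdx_id", "patient_id", "treatment", "embryo_id",
                "area_start", "area_end")
  missing_cols <- setdiff(required, names(measurements))
  if (length(missing_cols) > 0)
    stop("missing columns: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(as.character(measurements$treatment)), TREATMENT_LEVELS)
  if (length(bad) > 0)
    stop("unknown treatment labels: ", paste(bad, collapse = ", "), call. = FALSE)
  out <- measurements
  out$treatment <- factor(as.character(out$treatment), levels = TREATMENT_LEVELS)
  out$r_start <- equivalent_radius(out$area_start)
  out$r_cubed_start <- out$r_start^3
  out$pdv <- percent_delta_v(out$area_start, out$area_end)
  out$y <- transform_pdv(out$pdv)
  if ("perimeter_start" %in% names(out) && any(!is.na(out$perimeter_start))) {
    out$circ <- ifelse(is.na(out$perimeter_start), NA_real_,
                       circularity(out$area_start, out$perimeter_start))
    out$low_circularity <- !is.na(out$circ) & out$circ < circularity_threshold
    n_low <- sum(out$low_circularity)
    if (n_low > 0)
      warning(sprintf(
        "%d graft(s) with circularity below %.2f; spherical-volume assumption doubtful for these",
        n_low, circularity_threshold), call. = FALSE)
  }
  out
}
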