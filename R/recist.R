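# Adapted RECIST classification of avatar-arm responses.
#
# The readout is the relative stained area (end / start) of a treated arm,
# referenced to the control arm of the same avatar.  The classification uses
# the standard RECIST percentages on this control-normalized change of the
# 2-D area — never the equivalent-volume scale of the mixed model.

#' RECIST class levels, ordered
#'
#' `PD < SD < PR < CR` (increasing clinical benefit). This total order is
#' the ordinal coding used by the rank correlation in the concordance test.
#'
#' @format Character vector of length 4.
#' @export
RECIST_LEVELS <- c("PD", "SD", "PR", "CR")

#' Classify a control-referenced area change into RECIST classes
#'
#' Thresholds on the percent change of the relative stained area versus the
#' control reference: progressive disease (PD) for an increase of 20% or
#' more; stable disease (SD) between -30% and +20% (both exclusive); partial
#' response (PR) for a decrease of at least 30% but less than 90%; complete
#' response (CR) for a decrease of 90% or more. Boundaries follow the
#' inclusive readings `+20 -> PD`, `-30 -> PR`, `-90 -> CR`, which make the
#' four intervals partition `[-100, Inf)`.
#'
#' @param change Numeric vector of percent changes, `>= -100`.
#' @return Ordered factor with levels `PD < SD < PR < CR`.
#' @examples
#' classify_recist(c(25, 0, -50, -95))
#' @export
classify_recist <- function(change) {
  if (any(is.finite(change) & change < -100))
    stop("domain error: change below -100%", call. = FALSE)
  cls <- ifelse(change >= 20, "PD",
         ifelse(change > -30, "SD",
         ifelse(change > -90, "PR", "CR")))
  factor(cls, levels = RECIST_LEVELS, ordered = TRUE)
}

.mean_ratio <- function(df, reference) {
  ratios <- df$area_end / df$area_start
  if (reference == "mean-of-ratios") mean(ratios)
  else mean(df$area_end) / mean(df$area_start)
}

#' Response of one treated arm relative to its control arm
#'
#' Computes the percent change of the treated arm's mean relative stained
#' area (end/start) versus the control arm of the same avatar, and its
#' RECIST class.
#'
#' @param treated,control Data frames of embryo measurements (columns
#'   `zpdx_id`, `treatment`, `area_start`, `area_end`) for a treated arm and
#'   the control arm of the same avatar.
#' @param reference `"mean-of-ratios"` (default: mean over embryos of
#'   per-embryo end/start ratios, per arm) or `"ratio-of-means"`.
#' @param min_embryos Minimum embryos per arm for a valid call (default 5);
#'   smaller arms raise an insufficient-data error.
#' @return One-row data frame: `zpdx_id`, `treatment`,
#'   `mean_relative_area`, `normalized_change` (percent), `recist`,
#'   `n_embryos`, `n_control`.
#' @export
arm_response <- function(treated, control,
                         reference = c("mean-of-ratios", "ratio-of-means"),
                         min_embryos = 5) {
  reference <- match.arg(reference)
  if (nrow(treated) == 0 || nrow(control) == 0)
    stop("insufficient data: empty arm", call. = FALSE)
  if (nrow(treated) < min_embryos || nrow(control) < min_embryos)
    stop(sprintf("insufficient data: fewer than %d embryos in an arm (low engraftment)",
                 min_embryos), call. = FALSE)
  ids <- unique(c(as.character(treated$zpdx_id), as.character(control$zpdx_id)))
  if (length(ids) != 1)
    stop("treated and control arms must belong to the same zPDX", call. = FALSE)
  mt <- .mean_ratio(treated, reference)
  mc <- .mean_ratio(control, reference)
  if (mc == 0) stop("degenerate reference: control mean relative area is 0",
                    call. = FALSE)
  change <- 100 * (mt / mc - 1)
  data.frame(zpdx_id = ids,
             treatment = as.character(treated$treatment[1]),
             mean_relative_area = mt,
             normalized_change = change,
             recist = classify_recist(change),
             n_embryos = nrow(treated),
             n_control = nrow(control))
}

#' RECIST calls for every avatar-arm of a cohort
#'
#' Applies [arm_response()] to each treated arm of each avatar. Arms below
#' the engraftment cutoff are skipped with a message rather than an error.
#'
#' @param measurements Measurement table (as read by [read_measurements()] or
#'   simulated by [simulate_cohort()]).
#' @inheritParams arm_response
#' @return Data frame of arm responses, one row per avatar x treated arm
#'   that passed the cutoff; skipped arms are listed in
#'   `attr(, "skipped")`.
#' @export
arm_response_table <- function(measurements,
                               reference = c("mean-of-ratios", "ratio-of-means"),
                               min_embryos = 5) {
  reference <- match.arg(reference)
  rows <- list(); skipped <- character(0)
  for (id in unique(as.character(measurements$zpdx_id))) {
    sub <- measurements[measurements$zpdx_id == id, ]
    control <- sub[sub$treatment == "CONTROL", ]
    for (trt in TREATMENT_LEVELS[-1]) {
      treated <- sub[sub$treatment == trt, ]
      if (nrow(treated) == 0) next
      res <- tryCatch(
        arm_response(treated, control, reference, min_embryos),
        error = function(e) {
          skipped <<- c(skipped, sprintf("%s/%s: %s", id, trt,
                                         conditionMessage(e)))
          NULL
        })
      if (!is.null(res)) rows[[length(rows) + 1]] <- res
    }
  }
  if (length(skipped) > 0)
    message(length(skipped), " avatar-arm(s) skipped:\n  ",
            paste(skipped, collapse = "\n  "))
  out <- do.call(rbind, rows)
  attr(out, "skipped") <- skipped
  out
}

#' Cohort-level RECIST response percentages per treatment
#'
#' For every treated arm, the percentage of avatars in each RECIST class.
#'
#' @param responses Arm-response table from [arm_response_table()].
#' @return Data frame with one row per treatment and columns `PD`, `SD`,
#'   `PR`, `CR` (percent; rows sum to 100 up to rounding) plus `n`.
#' @export
cohort_response_table <- function(responses) {
  if (is.null(responses) || nrow(responses) == 0)
    stop("no responses to tabulate", call. = FALSE)
  trts <- intersect(TREATMENT_LEVELS, unique(responses$treatment))
  out <- do.call(rbind, lapply(trts, function(trt) {
    cls <- responses$recist[responses$treatment == trt]
    counts <- table(factor(cls, levels = RECIST_LEVELS))
    pct <- 100 * as.numeric(counts) / length(cls)
    df <- as.data.frame(as.list(stats::setNames(pct, RECIST_LEVELS)))
    df$n <- length(cls)
    cbind(data.frame(treatment = trt), df)
  }))
  rownames(out) <- NULL
  out
}
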