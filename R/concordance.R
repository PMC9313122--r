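# Patient-avatar concordance: match each recurrent patient's clinical
# first-line RECIST outcome with the avatar's class under the same regimen,
# then summarize agreement as a percentage and a tie-corrected Kendall rank
# correlation (tau-b) with a continuity-corrected normal p-value.

#' Pair clinical outcomes with avatar RECIST calls
#'
#' Inner-joins clinical records to the avatar class matrix on patient id and
#' first-line regimen. Patients without a first-line regimen, on a regimen
#' not tested in the screen, or whose avatar lacks a valid call for that
#' regimen (e.g. low engraftment) are excluded; each exclusion is recorded
#' with its reason in `attr(, "excluded")`.
#'
#' @param clinical Data frame with columns `patient_id`, `regimen` (already
#'   mapped to the canonical treatment labels, see [read_clinical()]; `NA`
#'   or `""` means no first-line chemotherapy) and `clinical_response`
#'   (`"PD"`, `"SD"` or `"PR"`).
#' @param avatar_classes Data frame with columns `zpdx_id` (the patient's
#'   avatar, keyed by patient id), `treatment` and `recist`, as produced by
#'   [arm_response_table()].
#' @return Data frame of pairs: `patient_id`, `regimen`, `clinical`,
#'   `avatar`, `concordant`.
#' @export
build_pairs <- function(clinical, avatar_classes) {
  if (anyDuplicated(clinical$patient_id))
    stop("duplicate patient ids in clinical records", call. = FALSE)
  excluded <- character(0)
  rows <- list()
  for (i in seq_len(nrow(clinical))) {
    pid <- as.character(clinical$patient_id[i])
    reg <- as.character(clinical$regimen[i])
    if (is.na(reg) || reg == "") {
      excluded <- c(excluded, paste0(pid, ": no first-line chemotherapy"))
      next
    }
    if (!reg %in% TREATMENT_LEVELS[-1]) {
      excluded <- c(excluded, paste0(pid, ": regimen not tested (", reg, ")"))
      next
    }
    hit <- avatar_classes$zpdx_id == pid & avatar_classes$treatment == reg
    if (!any(hit)) {
      excluded <- c(excluded, paste0(pid, ": no avatar call for ", reg,
                                     " (low engraftment or missing arm)"))
      next
    }
    av <- as.character(avatar_classes$recist[which(hit)[1]])
    cl <- as.character(clinical$clinical_response[i])
    rows[[length(rows) + 1]] <- data.frame(
      patient_id = pid, regimen = reg, clinical = cl, avatar = av,
      concordant = cl == av)
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(patient_id = character(0), regimen = character(0),
               clinical = character(0), avatar = character(0),
               concordant = logical(0))
  attr(out, "excluded") <- excluded
  out
}

#' Percent concordance of paired responses
#'
#' @param pairs Data frame from [build_pairs()].
#' @return `100 * #concordant / #pairs`.
#' @export
percent_concordance <- function(pairs) {
  if (nrow(pairs) == 0) stop("no pairs: concordance undefined", call. = FALSE)
  100 * mean(pairs$concordant)
}

.ordinal_rank <- function(v) {
  if (is.ordered(v)) return(as.integer(v))
  if (is.character(v) || is.factor(v)) {
    v <- as.character(v)
    if (all(v %in% RECIST_LEVELS))
      return(match(v, RECIST_LEVELS))
    stop("cannot order values: supply numeric codes or RECIST classes",
         call. = FALSE)
  }
  as.numeric(v)
}

#' Kendall rank correlation with tie correction (tau-b)
#'
#' From-scratch tau-b: with `S = nc - nd` over all pairs,
#' `tau_b = S / sqrt((n0 - n1)(n0 - n2))` where `n0 = n(n-1)/2` and `n1`,
#' `n2` are the within-tie pair counts of each margin. The two-sided p-value
#' uses the normal approximation with the full tie-corrected variance
#' (including both higher-order joint-tie terms) and a continuity
#' correction, `z = (|S| - 1) / sqrt(Var S)`.
#'
#' RECIST classes are coded `PD < SD < PR < CR` automatically; any ordered
#' factor or numeric coding is accepted.
#'
#' @param x,y Equal-length ordinal vectors, length `>= 2`.
#' @return List of class `"zpdx_kendall"`: `tau`, `p_value`, `S`, `var_S`,
#'   `n`, `nc`, `nd`, `n1`, `n2`.
#' @examples
#' kendall_tau_b(c(1, 2, 3, 4), c(1, 2, 3, 4))$tau  # 1
#' @export
kendall_tau_b <- function(x, y) {
  if (length(x) != length(y)) stop("unequal lengths", call. = FALSE)
  n <- length(x)
  if (n < 2) stop("need at least 2 observations", call. = FALSE)
  xs <- .ordinal_rank(x)
  ys <- .ordinal_rank(y)
  nc <- 0L; nd <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- sign(xs[i] - xs[j]) * sign(ys[i] - ys[j])
      if (s > 0) nc <- nc + 1L else if (s < 0) nd <- nd + 1L
    }
  }
  S <- nc - nd
  n0 <- n * (n - 1) / 2
  tx <- as.numeric(table(xs)); ty <- as.numeric(table(ys))
  n1 <- sum(tx * (tx - 1) / 2)
  n2 <- sum(ty * (ty - 1) / 2)
  denom <- sqrt((n0 - n1) * (n0 - n2))
  if (denom == 0)
    stop("undefined tau: a margin is completely tied", call. = FALSE)
  tau <- S / denom
  v0 <- n * (n - 1) * (2 * n + 5)
  vt <- sum(tx * (tx - 1) * (2 * tx + 5))
  vu <- sum(ty * (ty - 1) * (2 * ty + 5))
  v1 <- sum(tx * (tx - 1)) * sum(ty * (ty - 1)) / (2 * n * (n - 1))
  v2 <- sum(tx * (tx - 1) * (tx - 2)) * sum(ty * (ty - 1) * (ty - 2)) /
    (9 * n * (n - 1) * (n - 2))
  var_S <- (v0 - vt - vu) / 18 + v1 + v2
  p <- if (S == 0) 1 else {
    z <- (abs(S) - 1) / sqrt(var_S)
    2 * stats::pnorm(z, lower.tail = FALSE)
  }
  structure(list(tau = tau, p_value = min(1, p), S = S, var_S = var_S,
                 n = n, nc = nc, nd = nd, n1 = n1, n2 = n2),
            class = "zpdx_kendall")
}

#' @export
print.zpdx_kendall <- function(x, ...) {
  cat(sprintf("Kendall tau-b = %.3f (S = %d, n = %d), two-sided p = %.3f\n",
              x$tau, x$S, x$n, x$p_value))
  invisible(x)
}

#' Summarize a co-clinical comparison
#'
#' Percent concordance plus the Kendall tau-b test between clinical and
#' avatar RECIST classes.
#'
#' @param pairs Data frame from [build_pairs()].
#' @return List: `n_pairs`, `n_concordant`, `concordance_percent`, `tau`,
#'   `p_value`, `excluded` (carried over from the pairing step).
#' @export
coclinical_summary <- function(pairs) {
  kt <- kendall_tau_b(pairs$clinical, pairs$avatar)
  list(n_pairs = nrow(pairs),
       n_concordant = sum(pairs$concordant),
       concordance_percent = percent_concordance(pairs),
       tau = kt$tau,
       p_value = kt$p_value,
       excluded = attr(pairs, "excluded"))
}
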