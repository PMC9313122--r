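# Synthetic zPDX cohorts with known ground truth.
#
# Noise is placed on the transformed outcome scale y = log10(%dV + 110),
# where the mixed model operates, and then inverted back to end-point areas;
# running the geometry stage on a simulated cohort therefore reproduces the
# simulated y exactly, and parameter-recovery tests exercise the full
# pipeline transform.

#' Simulation parameters for a synthetic zPDX cohort
#'
#' Defaults mirror the screening design: 36 avatars, five arms (control plus
#' four regimens), 10 embryos per arm. The control mean outcome
#' `beta0 = 2.18` corresponds to roughly +41% tumor growth without
#' treatment, so untreated grafts grow; the default treatment effects pull
#' the mean response into the stable-disease / partial-response range with
#' rare complete responses. Avatar heterogeneity enters through a random
#' intercept (SD 0.08) and per-arm random slopes (SD 0.12) on the
#' transformed scale; residual embryo-to-embryo noise has SD 0.15. Start
#' areas are lognormal; a small engraftment failure rate drops embryos at
#' random.
#'
#' @param n_zpdx Number of avatars (default 36).
#' @param embryos_per_arm Embryos per avatar-arm (default 10).
#' @param beta0 Control mean of the transformed outcome (default 2.18).
#' @param beta_treatment Named length-4 numeric: arm effects on the
#'   transformed scale, relative to control.
#' @param covariate_effect Slope of the standardized initial-volume proxy.
#' @param sd_intercept,sd_slopes Random-effect SDs (slopes: length 4).
#' @param random_correlation Common correlation between random terms
#'   (default 0).
#' @param sigma_resid Residual SD.
#' @param area_log_mean,area_log_sd Natural-log mean/SD of start areas.
#' @param engraftment_failure_rate Probability an embryo is dropped.
#' @param perimeter_circularity Mean circularity used to synthesize start
#'   perimeters (default 0.9).
#' @return Object of class `"zpdx_sim_params"`.
#' @export
sim_params <- function(n_zpdx = 36,
                       embryos_per_arm = 10,
                       beta0 = 2.18,
                       beta_treatment = c(`5FU` = -0.22, FOLFOX = -0.25,
                                          FOLFIRI = -0.28, FOLFOXIRI = -0.30),
                       covariate_effect = -0.02,
                       sd_intercept = 0.08,
                       sd_slopes = rep(0.12, 4),
                       random_correlation = 0,
                       sigma_resid = 0.15,
                       area_log_mean = log(3e4),
                       area_log_sd = 0.35,
                       engraftment_failure_rate = 0.05,
                       perimeter_circularity = 0.9) {
  stopifnot(n_zpdx >= 1, embryos_per_arm >= 1,
            sd_intercept >= 0, all(sd_slopes >= 0), sigma_resid >= 0,
            random_correlation >= -1, random_correlation <= 1,
            engraftment_failure_rate >= 0, engraftment_failure_rate < 1,
            length(beta_treatment) == 4, length(sd_slopes) == 4)
  names(beta_treatment) <- TREATMENT_LEVELS[-1]
  names(sd_slopes) <- TREATMENT_LEVELS[-1]
  structure(as.list(environment()), class = "zpdx_sim_params")
}

#' @export
print.zpdx_sim_params <- function(x, ...) {
  cat(sprintf("zPDX cohort simulation: %d avatars x 5 arms x %d embryos\n",
              x$n_zpdx, x$embryos_per_arm))
  cat(sprintf("  beta0 = %.3f; effects: %s\n", x$beta0,
              paste(sprintf("%s %.2f", names(x$beta_treatment),
                            x$beta_treatment), collapse = ", ")))
  cat(sprintf("  SD intercept %.3f, slopes %s, residual %.3f\n",
              x$sd_intercept, paste(format(x$sd_slopes), collapse = "/"),
              x$sigma_resid))
  invisible(x)
}

#' Simulate a zPDX screening cohort with known truth
#'
#' For each avatar, random effects (intercept plus four arm slopes) are
#' drawn once from the specified covariance; for each embryo a lognormal
#' start area is drawn and the transformed outcome is
#' `y = beta0 + beta_t + gamma * z + b0 + bt + e`, with `z` the
#' cohort-standardized cube of the equivalent start radius. `y` is inverted
#' to a percent volume change (clamped at -100, the clamp rate is recorded
#' and warned about above 5%) and then to an end-point area, so the
#' geometry stage recovers the simulated outcome exactly. Engraftment
#' failures drop embryos at random.
#'
#' @param params A [sim_params()] object.
#' @param seed Integer seed; the same seed reproduces the cohort exactly.
#' @return List of class `"zpdx_cohort"`: `measurements` (per-embryo table
#'   with areas and perimeters) and `truth` (the parameters, the realized
#'   per-avatar random effects, per-avatar expected percent volume change
#'   per arm at the mean initial volume, the clamp rate and the seed).
#' @examples
#' cohort <- simulate_cohort(sim_params(n_zpdx = 4, embryos_per_arm = 5), seed = 42)
#' head(cohort$measurements)
#' @export
simulate_cohort <- function(params = sim_params(), seed) {
  stopifnot(inherits(params, "zpdx_sim_params"))
  if (missing(seed)) stop("'seed' is required for reproducibility", call. = FALSE)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)

  ids <- sprintf("Z%03d", seq_len(params$n_zpdx))
  k <- 5  # intercept + 4 slopes
  sds <- c(params$sd_intercept, params$sd_slopes)
  R <- matrix(params$random_correlation, k, k); diag(R) <- 1
  Sigma <- diag(sds, k) %*% R %*% diag(sds, k)
  Z <- matrix(stats::rnorm(params$n_zpdx * k), params$n_zpdx, k)
  raneff <- Z %*% chol_psd(Sigma)  # eigen-based factor tolerates zero SDs
  colnames(raneff) <- c("intercept", names(params$beta_treatment))
  rownames(raneff) <- ids

  grid <- expand.grid(embryo = seq_len(params$embryos_per_arm),
                      treatment = TREATMENT_LEVELS,
                      zpdx = seq_len(params$n_zpdx),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n <- nrow(grid)
  area_start <- stats::rlnorm(n, params$area_log_mean, params$area_log_sd)
  r3 <- (area_start / pi)^(3 / 2)
  z <- (r3 - mean(r3)) / stats::sd(r3)
  ti <- match(grid$treatment, TREATMENT_LEVELS) - 1L  # 0 = control
  beta_t <- c(0, params$beta_treatment)[ti + 1L]
  b0 <- raneff[grid$zpdx, 1]
  bt <- ifelse(ti == 0, 0, raneff[cbind(grid$zpdx, ti + 1L)])
  y <- params$beta0 + beta_t + params$covariate_effect * z + b0 + bt +
    stats::rnorm(n, 0, params$sigma_resid)
  pdv <- inv_transform_pdv(y)
  clamped <- pdv < -100
  pdv[clamped] <- -100
  clamp_rate <- mean(clamped)
  if (clamp_rate > 0.05)
    warning(sprintf("%.1f%% of simulated outcomes clamped at -100%%; ",
                    100 * clamp_rate),
            "parameters push volume change below total regression",
            call. = FALSE)
  area_end <- area_start * (pdv / 100 + 1)^(2 / 3)
  perimeter_start <- sqrt(4 * pi * area_start / params$perimeter_circularity)

  measurements <- data.frame(
    zpdx_id = ids[grid$zpdx],
    patient_id = ids[grid$zpdx],
    treatment = grid$treatment,
    embryo_id = sprintf("E%02d", grid$embryo),
    area_start = area_start,
    area_end = area_end,
    perimeter_start = perimeter_start
  )
  if (params$engraftment_failure_rate > 0) {
    keep <- stats::runif(n) >= params$engraftment_failure_rate
    measurements <- measurements[keep, ]
    rownames(measurements) <- NULL
  }

  expected <- outer(raneff[, 1], rep(1, 4)) +
    sweep(raneff[, -1, drop = FALSE], 2,
          params$beta_treatment, `+`) + params$beta0
  expected_pdv <- inv_transform_pdv(cbind(CONTROL = params$beta0 + raneff[, 1],
                                          expected))
  colnames(expected_pdv) <- TREATMENT_LEVELS

  structure(list(
    measurements = measurements,
    truth = list(params = params, random_effects = raneff,
                 expected_pdv = expected_pdv, clamp_rate = clamp_rate,
                 seed = seed)
  ), class = "zpdx_cohort")
}

# Cholesky-like factor of a positive semi-definite matrix via eigen
# decomposition; tolerates zero-variance terms.
chol_psd <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  t(e$vectors %*% diag(sqrt(vals), length(vals)) %*% t(e$vectors))
}

#' @export
print.zpdx_cohort <- function(x, ...) {
  cat(sprintf("Simulated zPDX cohort: %d measurements, %d avatars (seed %s)\n",
              nrow(x$measurements),
              length(unique(x$measurements$zpdx_id)),
              format(x$truth$seed)))
  if (x$truth$clamp_rate > 0)
    cat(sprintf("  clamp rate at -100%%: %.2f%%\n", 100 * x$truth$clamp_rate))
  invisible(x)
}

#' Reconstructed co-clinical comparison fixture
#'
#' The eight-pair patient-avatar comparison table of the colorectal screen,
#' reconstructed from the published summary: five patients with clinical
#' partial response (avatar classes: four PR, one CR) and three with
#' clinical stable disease (avatar classes: two SD, one PR), giving 6/8
#' concordant pairs. Patient `C038` received capecitabine clinically while
#' its avatar was tested with 5-FU; the other patient identities are
#' synthetic labels. The discordance pattern is the one consistent with the
#' reported concordance, rank correlation and p-value jointly.
#'
#' @return List with `clinical` (patient records; `C038` carries regimen
#'   `"Capecitabine"`, mapped to `"5FU"` by [read_clinical()]'s alias table)
#'   and `avatar_classes` (avatar-arm RECIST calls for the matching
#'   regimens).
#' @examples
#' fx <- coclinical_fixture()
#' pairs <- build_pairs(map_regimens(fx$clinical), fx$avatar_classes)
#' percent_concordance(pairs)  # 75
#' @export
coclinical_fixture <- function() {
  clinical <- data.frame(
    patient_id = c("P01", "P02", "P03", "P04", "C038", "P06", "P07", "P08"),
    regimen = c("FOLFOX", "FOLFIRI", "FOLFOXIRI", "FOLFOX", "Capecitabine",
                "FOLFIRI", "FOLFOXIRI", "FOLFOX"),
    clinical_response = c("PR", "PR", "PR", "PR", "PR", "SD", "SD", "SD")
  )
  avatar_classes <- data.frame(
    zpdx_id = clinical$patient_id,
    treatment = c("FOLFOX", "FOLFIRI", "FOLFOXIRI", "FOLFOX", "5FU",
                  "FOLFIRI", "FOLFOXIRI", "FOLFOX"),
    recist = c("PR", "PR", "PR", "PR", "CR", "SD", "SD", "PR")
  )
  list(clinical = clinical, avatar_classes = avatar_classes)
}
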