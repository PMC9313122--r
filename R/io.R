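# CSV schemas, label canonicalization, and the end-to-end pipeline driver.
#
# Measurement CSV: zpdx_id,patient_id,treatment,embryo_id,area_2hpi,
#   area_48hpi[,perimeter_2hpi]   (areas in any consistent unit).
# Clinical CSV:   patient_id,regimen,clinical_response.
# All tables are plain RFC-4180 CSV, UTF-8, "." decimal; nested summaries
# are JSON.

.default_treatment_aliases <- function() {
  data.frame(
    alias = c("CONTROL", "CTRL", "VEHICLE", "5FU", "5-FU", "FU5",
              "FOLFOX", "FOLFIRI", "FOLFOXIRI"),
    canonical = c("CONTROL", "CONTROL", "CONTROL", "5FU", "5FU", "5FU",
                  "FOLFOX", "FOLFIRI", "FOLFOXIRI")
  )
}

.canonical_treatment <- function(labels, aliases = .default_treatment_aliases()) {
  idx <- match(toupper(trimws(labels)), toupper(aliases$alias))
  out <- aliases$canonical[idx]
  ifelse(is.na(out), as.character(labels), out)
}

#' Read a per-embryo measurement CSV
#'
#' Validates the measurement schema: required columns, positive start areas,
#' non-negative end areas, treatment labels from the five-arm set (after
#' alias mapping), and unique (zpdx, treatment, embryo) keys. Violations
#' raise errors naming the offending rows.
#'
#' @param path CSV path with header
#'   `zpdx_id,patient_id,treatment,embryo_id,area_2hpi,area_48hpi` and
#'   optionally `perimeter_2hpi`.
#' @param aliases Treatment alias table (columns `alias`, `canonical`);
#'   defaults to the built-in map (e.g. `5-FU -> 5FU`, `CTRL -> CONTROL`).
#' @return Data frame with canonical columns `zpdx_id`, `patient_id`,
#'   `treatment`, `embryo_id`, `area_start`, `area_end` and, when present,
#'   `perimeter_start`.
#' @export
read_measurements <- function(path, aliases = .default_treatment_aliases()) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("zpdx_id", "patient_id", "treatment", "embryo_id",
                "area_2hpi", "area_48hpi")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0)
    stop("parse error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  raw$treatment <- .canonical_treatment(raw$treatment, aliases)
  bad_trt <- which(!raw$treatment %in% TREATMENT_LEVELS)
  if (length(bad_trt) > 0)
    stop("parse error: unknown treatment in row(s) ",
         paste(utils::head(bad_trt, 10), collapse = ", "),
         " (column 'treatment')", call. = FALSE)
  bad_start <- which(!is.finite(raw$area_2hpi) | raw$area_2hpi <= 0)
  if (length(bad_start) > 0)
    stop("parse error: non-positive area_2hpi in row(s) ",
         paste(utils::head(bad_start, 10), collapse = ", "), call. = FALSE)
  bad_end <- which(!is.finite(raw$area_48hpi) | raw$area_48hpi < 0)
  if (length(bad_end) > 0)
    stop("parse error: negative or missing area_48hpi in row(s) ",
         paste(utils::head(bad_end, 10), collapse = ", "), call. = FALSE)
  key <- paste(raw$zpdx_id, raw$treatment, raw$embryo_id)
  if (anyDuplicated(key))
    stop("parse error: duplicate (zpdx, treatment, embryo) key in row(s) ",
         paste(utils::head(which(duplicated(key)), 10), collapse = ", "),
         call. = FALSE)
  out <- data.frame(zpdx_id = as.character(raw$zpdx_id),
                    patient_id = as.character(raw$patient_id),
                    treatment = raw$treatment,
                    embryo_id = as.character(raw$embryo_id),
                    area_start = raw$area_2hpi,
                    area_end = raw$area_48hpi)
  if ("perimeter_2hpi" %in% names(raw)) out$perimeter_start <- raw$perimeter_2hpi
  out
}

#' Write a measurement table in the CSV schema read by [read_measurements()]
#'
#' @param measurements Canonical measurement data frame.
#' @param path Output CSV path.
#' @export
write_measurements <- function(measurements, path) {
  out <- data.frame(zpdx_id = measurements$zpdx_id,
                    patient_id = measurements$patient_id,
                    treatment = measurements$treatment,
                    embryo_id = measurements$embryo_id,
                    area_2hpi = measurements$area_start,
                    area_48hpi = measurements$area_end)
  if ("perimeter_start" %in% names(measurements))
    out$perimeter_2hpi <- measurements$perimeter_start
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Default clinical regimen alias table
#'
#' Maps clinically administered regimens to the arm actually tested on the
#' avatar; notably capecitabine, an oral fluoropyrimidine metabolized to
#' 5-FU, maps to the `5FU` arm. The packaged copy lives at
#' `system.file("extdata", "regimen_aliases.csv", package = "zpdxscreen")`
#' and can be replaced by any CSV with columns `alias`, `canonical`.
#'
#' @return Data frame with columns `alias` and `canonical`.
#' @export
regimen_aliases <- function() {
  path <- system.file("extdata", "regimen_aliases.csv", package = "zpdxscreen")
  if (nzchar(path)) utils::read.csv(path, stringsAsFactors = FALSE)
  else data.frame(alias = c("CAPECITABINE", "5-FU", "XELOX"),
                  canonical = c("5FU", "5FU", "FOLFOX"))
}

#' Map clinical regimen labels to tested treatment arms
#'
#' @param clinical Clinical data frame with a `regimen` column.
#' @param aliases Alias table (see [regimen_aliases()]).
#' @return The input with `regimen` rewritten to canonical arm labels where
#'   an alias matches; unmatched labels are left as-is (and will be excluded
#'   with a reason by [build_pairs()]).
#' @export
map_regimens <- function(clinical, aliases = regimen_aliases()) {
  clinical$regimen <- .canonical_treatment(clinical$regimen, aliases)
  clinical
}

#' Read a clinical records CSV
#'
#' @param path CSV with header `patient_id,regimen,clinical_response`.
#' @param aliases Regimen alias table (see [regimen_aliases()]).
#' @return Data frame with regimens mapped to canonical arm labels.
#' @export
read_clinical <- function(path, aliases = regimen_aliases()) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("patient_id", "regimen", "clinical_response")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0)
    stop("parse error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  bad <- which(!is.na(raw$clinical_response) & raw$clinical_response != "" &
                 !raw$clinical_response %in% RECIST_LEVELS)
  if (length(bad) > 0)
    stop("parse error: unknown clinical_response in row(s) ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  map_regimens(raw, aliases)
}

.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full chemosensitivity analysis pipeline
#'
#' Executes the stages in order — geometry derivation, mixed-model fit,
#' Tukey post-hoc contrasts, per-avatar response calls, response-profile
#' clustering, adapted RECIST classification, and (when clinical records
#' are supplied) patient-avatar concordance — and writes one artifact per
#' stage into `out_dir`. Every JSON artifact embeds the seed and a hash of
#' the configuration, so identical inputs yield byte-identical outputs.
#'
#' @param measurements Measurement data frame or path to a measurement CSV.
#' @param out_dir Output directory (created if needed).
#' @param clinical Optional clinical data frame or CSV path; when absent the
#'   concordance stage is skipped with a notice.
#' @param seed Integer seed (drives k-means restarts).
#' @param random,covariance,conf_level Passed to [zpdx_lmm()] (default:
#'   random slopes, as required by the clustering stage).
#' @param k_candidates Cluster counts for [cluster_avatars()].
#' @param n_restarts k-means restarts.
#' @param recist_reference,min_embryos Passed to [arm_response_table()].
#' @return Invisibly, a list with all stage results and the paths written.
#' @export
run_pipeline <- function(measurements, out_dir, clinical = NULL, seed = 1,
                         random = "slopes", covariance = "general",
                         conf_level = 0.95, k_candidates = c(4, 5),
                         n_restarts = 50,
                         recist_reference = "mean-of-ratios",
                         min_embryos = 5) {
  if (is.character(measurements)) measurements <- read_measurements(measurements)
  if (is.character(clinical)) clinical <- read_clinical(clinical)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  config <- list(seed = seed, random = random, covariance = covariance,
                 conf_level = conf_level, k_candidates = k_candidates,
                 n_restarts = n_restarts, recist_reference = recist_reference,
                 min_embryos = min_embryos)
  hash <- .config_hash(config)
  paths <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] stage failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  derived <- stage("geometry", derive_volume_changes(measurements))
  paths$derived <- file.path(out_dir, "derived_volume_changes.csv")
  utils::write.csv(
    derived[c("zpdx_id", "patient_id", "treatment", "embryo_id",
              "r_start", "r_cubed_start", "pdv", "y")],
    paths$derived, row.names = FALSE)

  fit <- stage("lmm", zpdx_lmm(derived, random = random,
                               covariance = covariance,
                               conf_level = conf_level))
  sm <- summary(fit)
  paths$fit <- file.path(out_dir, "fit_summary.json")
  jsonlite::write_json(list(
    config_hash = hash, seed = seed,
    fixed = cbind(term = rownames(sm$fixed), sm$fixed),
    random_sd = as.list(sm$random_sd),
    sigma = fit$sigma, loglik = fit$loglik,
    n_obs = fit$n_obs, n_groups = fit$n_groups,
    random_structure = fit$spec$random, covariance = fit$spec$covariance,
    singular = fit$singular, converged = fit$converged,
    notes = fit$notes,
    prediction_interval = "fixed Wald variance + conditional random variance; fixed-random covariance ignored (conservative)"
  ), paths$fit, auto_unbox = TRUE, digits = 10)

  contrasts <- stage("contrasts", posthoc_contrasts(fit))
  paths$contrasts <- file.path(out_dir, "treatment_contrasts.csv")
  utils::write.csv(as.data.frame(contrasts), paths$contrasts, row.names = FALSE)

  calls <- stage("avatar_calls", avatar_calls(fit))
  paths$calls <- file.path(out_dir, "avatar_calls.csv")
  utils::write.csv(calls, paths$calls, row.names = FALSE)

  clusters_written <- FALSE
  if (fit$spec$random == "slopes") {
    X <- response_matrix(fit)
    clus <- stage("clustering",
                  cluster_avatars(X, k_candidates = k_candidates,
                                  n_restarts = n_restarts, seed = seed))
    assign_df <- data.frame(zpdx_id = rownames(X))
    for (nm in names(clus)) assign_df[[nm]] <- clus[[nm]]$assignments
    paths$clusters <- file.path(out_dir, "cluster_assignments.csv")
    utils::write.csv(assign_df, paths$clusters, row.names = FALSE)
    pca <- pca_project(X)
    paths$pca <- file.path(out_dir, "pca_scores.csv")
    utils::write.csv(data.frame(zpdx_id = rownames(X), pca$scores),
                     paths$pca, row.names = FALSE)
  } else {
    clus <- NULL
    message("clustering skipped: intercept-only random structure has no ",
            "response profiles")
  }

  responses <- stage("recist",
                     arm_response_table(measurements,
                                        reference = recist_reference,
                                        min_embryos = min_embryos))
  paths$recist <- file.path(out_dir, "recist_arm_responses.csv")
  utils::write.csv(responses, paths$recist, row.names = FALSE)
  cohort_tab <- stage("recist", cohort_response_table(responses))
  paths$cohort <- file.path(out_dir, "recist_cohort_table.csv")
  utils::write.csv(cohort_tab, paths$cohort, row.names = FALSE)

  concord <- NULL
  if (!is.null(clinical)) {
    pairs <- stage("concordance", build_pairs(clinical, responses))
    concord <- stage("concordance", c(coclinical_summary(pairs),
                                      list(config_hash = hash, seed = seed)))
    paths$pairs <- file.path(out_dir, "concordance_pairs.csv")
    utils::write.csv(pairs, paths$pairs, row.names = FALSE)
    paths$concordance <- file.path(out_dir, "concordance_summary.json")
    jsonlite::write_json(concord, paths$concordance, auto_unbox = TRUE,
                         digits = 10)
  } else {
    message("concordance skipped: no clinical records supplied")
  }

  invisible(list(derived = derived, fit = fit, contrasts = contrasts,
                 calls = calls, clusters = clus, responses = responses,
                 cohort_table = cohort_tab, concordance = concord,
                 config = config, config_hash = hash, paths = paths))
}
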