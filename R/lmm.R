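# Mixed-model stage: treatment effects on the log-shifted percent volume
# change, with per-avatar random effects.
#
# The model is
#   y_ij = beta0 + beta_t[trt_ij] + gamma * z_ij + b0_i + bt_i[trt_ij] + e_ij
# where y is log10(%dV + 110), z the standardized cube of the equivalent
# start radius (initial-volume proxy), i indexes avatars (zPDXs) and t the
# five treatment arms with CONTROL as baseline.  Random intercepts b0_i and,
# when selected, per-arm random slopes bt_i carry the avatar-specific
# response; their conditional modes (BLUPs) feed the downstream clustering
# and the per-avatar significance calls.

.trt_dummy_names <- function() paste0("trt_", TREATMENT_LEVELS[-1])

.add_dummies <- function(data) {
  for (lev in TREATMENT_LEVELS[-1])
    data[[paste0("trt_", lev)]] <- as.numeric(data$treatment == lev)
  data
}

.fit_one <- function(data, random, covariance, reml) {
  dn <- .trt_dummy_names()
  rhs <- switch(random,
    intercept = "(1 | zpdx_id)",
    slopes = if (covariance == "general")
      sprintf("(1 + %s | zpdx_id)", paste(dn, collapse = " + "))
    else
      sprintf("(1 + %s || zpdx_id)", paste(dn, collapse = " + "))
  )
  form <- stats::as.formula(paste("y ~ treatment + r3_std +", rhs))
  notes <- character(0)
  fit <- withCallingHandlers(
    lme4::lmer(form, data = data, REML = reml,
               control = lme4::lmerControl(check.conv.singular = "ignore")),
    warning = function(w) {
      notes <<- c(notes, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  list(fit = fit, notes = notes)
}

#' Fit the avatar drug-response mixed model
#'
#' Fits a linear mixed-effects model (via \pkg{lme4}) of the log-shifted
#' percent volume change on treatment arm (5 levels, `CONTROL` baseline) and
#' the standardized initial-volume proxy, with per-avatar random effects.
#' `random = "auto"` performs forward stepwise selection of the random
#' structure (intercept first, then treatment slopes; see
#' [stepwise_select()]). A general random-effect covariance that estimates as
#' singular triggers an automatic fallback to a diagonal covariance, with a
#' warning; the fallback is recorded in the fitted object.
#'
#' @param data Derived per-embryo table from [derive_volume_changes()]
#'   (columns `zpdx_id`, `treatment`, `y`, `r_cubed_start`).
#' @param random Random-effect structure: `"auto"` (stepwise selection),
#'   `"intercept"`, or `"slopes"` (intercept plus one slope per treated arm).
#' @param covariance Random-effect covariance for slope models: `"general"`
#'   (unstructured, the default, with singular-fit fallback) or `"diagonal"`.
#' @param conf_level Confidence level for all downstream intervals
#'   (default 0.95).
#' @param reml Use REML for the reported fit (default `TRUE`); stepwise
#'   comparison of random structures always uses ML.
#' @param standardize_covariate Standardize the `r_cubed_start` covariate to
#'   zero mean and unit variance before fitting (default `TRUE`).
#' @return An object of class `"zpdx_lmm"`: fixed estimates with their
#'   covariance, per-avatar conditional modes with conditional variances, the
#'   random-effect covariance estimate, residual SD, log-likelihood,
#'   convergence/singularity diagnostics, and (for `"auto"`) the selection
#'   trace. Methods: [print.zpdx_lmm()], [summary.zpdx_lmm()],
#'   [coef.zpdx_lmm()], [predict.zpdx_lmm()], [residuals.zpdx_lmm()].
#' @seealso [posthoc_contrasts()], [random_effect_cis()], [avatar_calls()],
#'   [response_matrix()]
#' @examples
#' cohort <- simulate_cohort(sim_params(n_zpdx = 8, embryos_per_arm = 6), seed = 1)
#' d <- derive_volume_changes(cohort$measurements)
#' fit <- zpdx_lmm(d, random = "intercept")
#' coef(fit)
#' @export
zpdx_lmm <- function(data,
                     random = c("auto", "intercept", "slopes"),
                     covariance = c("general", "diagonal"),
                     conf_level = 0.95,
                     reml = TRUE,
                     standardize_covariate = TRUE) {
  random <- match.arg(random)
  covariance <- match.arg(covariance)
  stopifnot(conf_level > 0, conf_level < 1)
  required <- c("zpdx_id", "treatment", "y", "r_cubed_start")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0)
    stop("missing columns: ", paste(missing_cols, collapse = ", "), call. = FALSE)

  data <- as.data.frame(data)
  data$zpdx_id <- factor(as.character(data$zpdx_id))
  data$treatment <- factor(as.character(data$treatment), levels = TREATMENT_LEVELS)
  n_groups <- nlevels(data$zpdx_id)
  if (n_groups < 2)
    stop("at least 2 zPDX groups are required; random effects are ",
         "inestimable from a single group", call. = FALSE)

  cov_mean <- mean(data$r_cubed_start)
  cov_sd <- stats::sd(data$r_cubed_start)
  if (standardize_covariate && cov_sd > 0) {
    data$r3_std <- (data$r_cubed_start - cov_mean) / cov_sd
  } else {
    data$r3_std <- data$r_cubed_start - cov_mean
    cov_sd <- 1
  }
  data <- .add_dummies(data)

  selection <- NULL
  if (random == "auto") {
    selection <- stepwise_select(data, covariance = covariance,
                                 .prepared = TRUE)
    random <- selection$random
  }

  notes <- character(0)
  used_covariance <- if (random == "slopes") covariance else NA_character_
  res <- .fit_one(data, random, if (random == "slopes") covariance else "general",
                  reml)
  if (random == "slopes" && covariance == "general" &&
      lme4::isSingular(res$fit, tol = 1e-4)) {
    warning("general random-effect covariance is singular; ",
            "falling back to a diagonal covariance", call. = FALSE)
    notes <- c(notes, "singular general covariance: diagonal fallback applied")
    used_covariance <- "diagonal"
    res <- .fit_one(data, "slopes", "diagonal", reml)
  }
  fit <- res$fit
  notes <- c(notes, res$notes)
  converged <- !any(grepl("failed to converge", notes, fixed = TRUE))

  re <- lme4::ranef(fit, condVar = TRUE)$zpdx_id
  modes <- as.matrix(re)
  pv <- attr(re, "postVar")
  if (is.list(pv)) {
    # a diagonal (||) structure reports one variance block per term; stack
    # them into a single block-diagonal k x k x n array in column order
    k <- ncol(modes); n <- nrow(modes)
    cond_var <- array(0, dim = c(k, k, n))
    off <- 0
    for (blk in pv) {
      kb <- dim(blk)[1]
      idx <- off + seq_len(kb)
      cond_var[idx, idx, ] <- blk
      off <- off + kb
    }
  } else {
    cond_var <- pv  # k x k x n_groups
  }
  vc <- lme4::VarCorr(fit)
  vcov_random <- as.matrix(Matrix::bdiag(lapply(vc, function(m) m)))
  # lme4 splits a diagonal (||) structure into independent terms; assemble
  # one block-diagonal matrix with rows in model term order
  term_names <- unlist(lapply(vc, rownames), use.names = FALSE)
  dimnames(vcov_random) <- list(term_names, term_names)
  if (!identical(colnames(modes), term_names) && ncol(modes) == length(term_names))
    vcov_random <- vcov_random[colnames(modes), colnames(modes), drop = FALSE]

  structure(list(
    fit = fit,
    call = match.call(),
    spec = list(random = random, covariance = used_covariance,
                conf_level = conf_level, reml = reml,
                standardize_covariate = standardize_covariate),
    beta = lme4::fixef(fit),
    vcov_beta = as.matrix(stats::vcov(fit)),
    random_modes = modes,
    cond_var = cond_var,
    vcov_random = vcov_random,
    sigma = stats::sigma(fit),
    loglik = as.numeric(stats::logLik(fit)),
    n_obs = nrow(data),
    n_groups = n_groups,
    group_levels = levels(data$zpdx_id),
    converged = converged,
    singular = lme4::isSingular(fit, tol = 1e-4),
    notes = notes,
    covariate = list(mean = cov_mean, sd = cov_sd),
    selection = selection,
    data = data
  ), class = "zpdx_lmm")
}

#' Forward stepwise selection of the random-effect structure
#'
#' Fits the random-intercept model first, then adds per-arm random treatment
#' slopes, both by maximum likelihood, and keeps the slopes when the
#' likelihood-ratio test rejects (or, with `criterion = "aic"`, when AIC
#' improves). Ties favor the simpler model.
#'
#' @param data Derived per-embryo table (as for [zpdx_lmm()]).
#' @param covariance Slope covariance structure used for the comparison.
#' @param criterion `"lrt"` (default) or `"aic"`.
#' @param alpha LRT significance level (default 0.05). The reference
#'   distribution is a naive chi-squared on the parameter-count difference;
#'   boundary issues make this conservative toward the simpler model.
#' @param .prepared Internal: data already carries `r3_std` and dummies.
#' @return List with elements `random` (the selected structure), `lrt_stat`,
#'   `df`, `p_value`, `aic_intercept`, `aic_slopes`, `criterion`.
#' @export
stepwise_select <- function(data, covariance = c("general", "diagonal"),
                            criterion = c("lrt", "aic"), alpha = 0.05,
                            .prepared = FALSE) {
  covariance <- match.arg(covariance)
  criterion <- match.arg(criterion)
  if (!.prepared) {
    data <- as.data.frame(data)
    data$zpdx_id <- factor(as.character(data$zpdx_id))
    data$treatment <- factor(as.character(data$treatment),
                             levels = TREATMENT_LEVELS)
    mu <- mean(data$r_cubed_start); sdv <- stats::sd(data$r_cubed_start)
    data$r3_std <- if (sdv > 0) (data$r_cubed_start - mu) / sdv else
      data$r_cubed_start - mu
    data <- .add_dummies(data)
  }
  f0 <- .fit_one(data, "intercept", covariance, reml = FALSE)$fit
  f1 <- .fit_one(data, "slopes", covariance, reml = FALSE)$fit
  ll0 <- as.numeric(stats::logLik(f0)); ll1 <- as.numeric(stats::logLik(f1))
  df_extra <- attr(stats::logLik(f1), "df") - attr(stats::logLik(f0), "df")
  lrt <- max(0, 2 * (ll1 - ll0))
  p <- stats::pchisq(lrt, df = df_extra, lower.tail = FALSE)
  aic0 <- stats::AIC(f0); aic1 <- stats::AIC(f1)
  keep_slopes <- if (criterion == "lrt") p < alpha else aic1 < aic0
  list(random = if (keep_slopes) "slopes" else "intercept",
       lrt_stat = lrt, df = df_extra, p_value = p,
       aic_intercept = aic0, aic_slopes = aic1, criterion = criterion)
}

#' @export
print.zpdx_lmm <- function(x, ...) {
  cat("zPDX drug-response mixed model\n")
  cat(sprintf("  outcome: log10(%%dV + 110); %d embryos, %d avatars\n",
              x$n_obs, x$n_groups))
  cat(sprintf("  random structure: %s%s\n", x$spec$random,
              if (!is.na(x$spec$covariance))
                paste0(" (", x$spec$covariance, " covariance)") else ""))
  if (x$singular) cat("  note: random-effect covariance on boundary (singular)\n")
  if (!x$converged) cat("  WARNING: optimizer did not converge cleanly\n")
  cat("Fixed effects:\n")
  print(round(x$beta, 4))
  invisible(x)
}

#' @export
coef.zpdx_lmm <- function(object, ...) object$beta

#' @export
vcov.zpdx_lmm <- function(object, ...) object$vcov_beta

#' @export
logLik.zpdx_lmm <- function(object, ...) stats::logLik(object$fit)

#' @export
fitted.zpdx_lmm <- function(object, ...) stats::fitted(object$fit)

#' @export
residuals.zpdx_lmm <- function(object, ...) stats::residuals(object$fit)

#' Summarize a fitted avatar response model
#'
#' @param object A `zpdx_lmm` fit.
#' @param ... Unused.
#' @return A `summary.zpdx_lmm` list: fixed-effect table with Wald
#'   confidence limits, random-effect standard deviations, residual SD,
#'   selection trace and diagnostics.
#' @export
summary.zpdx_lmm <- function(object, ...) {
  se <- sqrt(diag(object$vcov_beta))
  z <- stats::qnorm(1 - (1 - object$spec$conf_level) / 2)
  fixed <- data.frame(
    estimate = object$beta, se = se,
    lower = object$beta - z * se, upper = object$beta + z * se,
    row.names = names(object$beta)
  )
  out <- list(fixed = fixed,
              random_sd = sqrt(diag(object$vcov_random)),
              sigma = object$sigma,
              loglik = object$loglik,
              n_obs = object$n_obs, n_groups = object$n_groups,
              spec = object$spec, selection = object$selection,
              singular = object$singular, converged = object$converged,
              notes = object$notes)
  class(out) <- "summary.zpdx_lmm"
  out
}

#' @export
print.summary.zpdx_lmm <- function(x, ...) {
  cat("zPDX drug-response mixed model —", x$n_obs, "embryos,",
      x$n_groups, "avatars\n")
  cat(sprintf("random structure: %s; residual SD %.4f; logLik %.2f\n",
              x$spec$random, x$sigma, x$loglik))
  cat("\nFixed effects (", x$spec$conf_level * 100, "% Wald CI):\n", sep = "")
  print(round(x$fixed, 4))
  cat("\nRandom-effect SDs:\n")
  print(round(x$random_sd, 4))
  if (!is.null(x$selection))
    cat(sprintf("\nStepwise selection: kept '%s' (LRT %.2f on %d df, p = %.3g)\n",
                x$spec$random, x$selection$lrt_stat, x$selection$df,
                x$selection$p_value))
  if (x$singular) cat("note: singular random-effect covariance\n")
  invisible(x)
}

# Index of a treatment's slope column in the random-mode matrix (NA for
# CONTROL or intercept-only fits).
.slope_col <- function(object, treatment) {
  if (object$spec$random != "slopes" || treatment == "CONTROL") return(NA_integer_)
  match(paste0("trt_", treatment), colnames(object$random_modes))
}

#' Predict avatar-level response with confidence intervals
#'
#' Predicted log-shifted percent volume change for given avatar/treatment
#' combinations, evaluated at the cohort-mean initial volume: the fixed-part
#' fit plus that avatar's conditional modes. The interval variance adds the
#' fixed-effect Wald variance and the conditional variance of the random
#' part (including the intercept-slope conditional covariance); the
#' covariance between fixed estimates and conditional modes is ignored,
#' which is conservative. Intervals are mapped back to the percent scale by
#' the monotone inverse transform.
#'
#' @param object A `zpdx_lmm` fit.
#' @param zpdx_id Avatar ids (default: all in the fit).
#' @param treatment Treatment arms (default: all five).
#' @param level Confidence level (default: the fit's `conf_level`).
#' @param ... Unused.
#' @return Data frame with one row per avatar-arm: `pred_y`, `se_y`,
#'   `lower_y`, `upper_y`, and the back-transformed `pred_pdv`, `lower_pdv`,
#'   `upper_pdv`.
#' @export
predict.zpdx_lmm <- function(object, zpdx_id = NULL, treatment = NULL,
                             level = NULL, ...) {
  if (is.null(zpdx_id)) zpdx_id <- object$group_levels
  if (is.null(treatment)) treatment <- TREATMENT_LEVELS
  if (is.null(level)) level <- object$spec$conf_level
  zpdx_id <- as.character(zpdx_id)
  treatment <- as.character(treatment)
  unknown <- setdiff(zpdx_id, object$group_levels)
  if (length(unknown) > 0)
    stop("unknown zPDX id(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  bad <- setdiff(treatment, TREATMENT_LEVELS)
  if (length(bad) > 0)
    stop("unknown treatment(s): ", paste(bad, collapse = ", "), call. = FALSE)

  grid <- expand.grid(zpdx_id = zpdx_id, treatment = treatment,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- length(object$beta)
  res <- lapply(seq_len(nrow(grid)), function(r) {
    id <- grid$zpdx_id[r]; trt <- grid$treatment[r]
    gi <- match(id, object$group_levels)
    L <- numeric(p); names(L) <- names(object$beta)
    L["(Intercept)"] <- 1
    if (trt != "CONTROL") L[paste0("treatment", trt)] <- 1
    mu_fixed <- sum(L * object$beta)
    var_fixed <- drop(t(L) %*% object$vcov_beta %*% L)
    sc <- .slope_col(object, trt)
    b <- object$random_modes[gi, 1]
    v <- object$cond_var[1, 1, gi]
    if (!is.na(sc)) {
      b <- b + object$random_modes[gi, sc]
      v <- v + object$cond_var[sc, sc, gi] + 2 * object$cond_var[1, sc, gi]
    }
    c(pred_y = mu_fixed + b, se_y = sqrt(var_fixed + v))
  })
  res <- do.call(rbind, res)
  out <- cbind(grid, as.data.frame(res))
  out$lower_y <- out$pred_y - z * out$se_y
  out$upper_y <- out$pred_y + z * out$se_y
  out$pred_pdv <- inv_transform_pdv(out$pred_y)
  out$lower_pdv <- inv_transform_pdv(out$lower_y)
  out$upper_pdv <- inv_transform_pdv(out$upper_y)
  out
}

#' Confidence intervals for per-avatar random effects
#'
#' For every avatar and every random term, the conditional mode (BLUP) with
#' a normal interval `mode +/- z * conditional SD`, and a flag for intervals
#' excluding zero — i.e. avatars whose response to that term differs
#' detectably from the population mean.
#'
#' @param object A `zpdx_lmm` fit.
#' @param level Confidence level (default: the fit's `conf_level`).
#' @return Data frame with columns `zpdx_id`, `term`, `mode`, `cond_sd`,
#'   `lower`, `upper`, `differs`.
#' @export
random_effect_cis <- function(object, level = NULL) {
  stopifnot(inherits(object, "zpdx_lmm"))
  if (is.null(level)) level <- object$spec$conf_level
  z <- stats::qnorm(1 - (1 - level) / 2)
  terms <- colnames(object$random_modes)
  n <- nrow(object$random_modes)
  out <- do.call(rbind, lapply(seq_along(terms), function(j) {
    sd_j <- sqrt(object$cond_var[j, j, seq_len(n)])
    data.frame(zpdx_id = object$group_levels,
               term = terms[j],
               mode = object$random_modes[, j],
               cond_sd = sd_j,
               lower = object$random_modes[, j] - z * sd_j,
               upper = object$random_modes[, j] + z * sd_j,
               row.names = NULL)
  }))
  out$differs <- out$lower > 0 | out$upper < 0
  out
}

#' Per-avatar drug-response calls
#'
#' Combines [predict.zpdx_lmm()] intervals with the decision rules of the
#' screening analysis. For each avatar and treated arm:
#' \describe{
#'   \item{significant_reduction}{the upper confidence limit of the
#'     predicted response lies below the no-change point (transformed scale
#'     `log10(110)`, i.e. back-transformed percent volume change below 0).}
#'   \item{beats_control}{the arm's interval and the same avatar's control
#'     interval are disjoint, with the treated interval entirely lower.}
#'   \item{differs_from_population}{that avatar's random effect for the arm
#'     (slope; intercept for `CONTROL`) has an interval excluding zero.}
#' }
#'
#' @param object A `zpdx_lmm` fit.
#' @param level Confidence level (default: the fit's `conf_level`).
#' @return Data frame with one row per avatar-arm (all five arms; the
#'   decision flags are `NA` for `CONTROL` rows except
#'   `differs_from_population`).
#' @export
avatar_calls <- function(object, level = NULL) {
  stopifnot(inherits(object, "zpdx_lmm"))
  if (is.null(level)) level <- object$spec$conf_level
  pred <- predict(object, level = level)
  recis <- random_effect_cis(object, level = level)
  y0 <- log10(PDV_OFFSET)  # no volume change on the transformed scale

  ctrl <- pred[pred$treatment == "CONTROL",
               c("zpdx_id", "lower_y", "upper_y")]
  names(ctrl) <- c("zpdx_id", "ctrl_lower_y", "ctrl_upper_y")
  out <- merge(pred, ctrl, by = "zpdx_id", sort = FALSE)

  out$significant_reduction <- ifelse(out$treatment == "CONTROL", NA,
                                      out$upper_y < y0)
  out$beats_control <- ifelse(out$treatment == "CONTROL", NA,
                              out$upper_y < out$ctrl_lower_y)
  re_term <- ifelse(out$treatment == "CONTROL", "(Intercept)",
                    paste0("trt_", out$treatment))
  key <- paste(out$zpdx_id, re_term)
  re_key <- paste(recis$zpdx_id, recis$term)
  out$differs_from_population <- recis$differs[match(key, re_key)]
  out$ctrl_lower_y <- out$ctrl_upper_y <- NULL
  out[order(match(out$treatment, TREATMENT_LEVELS), out$zpdx_id), ]
}

#' Tukey-adjusted pairwise treatment contrasts
#'
#' Least-square means of the five arms evaluated at the cohort-mean initial
#' volume, and all ten pairwise differences with standard errors,
#' studentized-range (Tukey HSD) adjusted p-values and adjusted confidence
#' intervals. Degrees of freedom use the residual approximation
#' `n_obs - n_fixed` by default, or the normal reference with
#' `df = "normal"`.
#'
#' @param object A converged `zpdx_lmm` fit.
#' @param level Confidence level for the adjusted intervals.
#' @param df `"residual"` (default) or `"normal"`.
#' @return A `zpdx_contrasts` data frame with columns `level_a`, `level_b`,
#'   `estimate`, `se`, `t`, `df`, `p_tukey`, `lower`, `upper`, plus the
#'   least-square means in `attr(, "lsmeans")`.
#' @export
posthoc_contrasts <- function(object, level = NULL,
                              df = c("residual", "normal")) {
  stopifnot(inherits(object, "zpdx_lmm"))
  df <- match.arg(df)
  if (!object$converged)
    stop("refusing to compute contrasts from a non-converged fit", call. = FALSE)
  if (is.null(level)) level <- object$spec$conf_level
  p <- length(object$beta)
  k <- length(TREATMENT_LEVELS)
  # lsmean contrast vectors: intercept + own dummy, covariate at its mean (0)
  Lmat <- matrix(0, k, p, dimnames = list(TREATMENT_LEVELS, names(object$beta)))
  Lmat[, "(Intercept)"] <- 1
  for (lev in TREATMENT_LEVELS[-1]) Lmat[lev, paste0("treatment", lev)] <- 1
  lsm <- drop(Lmat %*% object$beta)
  lsm_se <- sqrt(diag(Lmat %*% object$vcov_beta %*% t(Lmat)))
  dfree <- if (df == "residual") object$n_obs - p else Inf

  pairs <- utils::combn(TREATMENT_LEVELS, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    Ld <- Lmat[a, ] - Lmat[b, ]
    est <- sum(Ld * object$beta)
    se <- sqrt(drop(t(Ld) %*% object$vcov_beta %*% Ld))
    tval <- est / se
    pt <- stats::ptukey(sqrt(2) * abs(tval), nmeans = k, df = dfree,
                        lower.tail = FALSE)
    crit <- stats::qtukey(level, nmeans = k, df = dfree) / sqrt(2)
    data.frame(level_a = a, level_b = b, estimate = est, se = se,
               t = tval, df = dfree, p_tukey = pt,
               lower = est - crit * se, upper = est + crit * se)
  })
  out <- do.call(rbind, rows)
  attr(out, "lsmeans") <- data.frame(treatment = TREATMENT_LEVELS,
                                     lsmean = lsm, se = lsm_se)
  class(out) <- c("zpdx_contrasts", "data.frame")
  out
}

#' @export
print.zpdx_contrasts <- function(x, ...) {
  cat("Pairwise treatment contrasts (Tukey HSD adjusted)\n")
  print.data.frame(cbind(x[c("level_a", "level_b")],
                         round(x[c("estimate", "se", "p_tukey",
                                   "lower", "upper")], 4)),
                   row.names = FALSE)
  invisible(x)
}

#' Avatar response-profile matrix for clustering
#'
#' Extracts the per-avatar random-effect conditional modes as a numeric
#' matrix (rows = avatars), by default the four treatment-slope terms only —
#' the avatar-specific deviations from the population mean response under
#' each regimen, on the transformed outcome scale.
#'
#' @param object A `zpdx_lmm` fit with random slopes.
#' @param include_intercept Also include the random intercept column
#'   (default `FALSE`).
#' @return Numeric matrix, one row per avatar, labelled by zPDX id.
#' @export
response_matrix <- function(object, include_intercept = FALSE) {
  stopifnot(inherits(object, "zpdx_lmm"))
  if (object$spec$random != "slopes")
    stop("response profiles require a random-slopes fit ",
         "(refit with random = \"slopes\")", call. = FALSE)
  cols <- paste0("trt_", TREATMENT_LEVELS[-1])
  if (include_intercept) cols <- c("(Intercept)", cols)
  m <- object$random_modes[, cols, drop = FALSE]
  rownames(m) <- object$group_levels
  m
}
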