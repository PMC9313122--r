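test_that("fixed effects are recovered from a seeded cohort", {
  co <- simulate_cohort(sim_params(), seed = 11)
  d <- derive_volume_changes(co$measurements)
  fit <- zpdx_lmm(d, random = "slopes", covariance = "diagonal")
  truth <- co$truth$params$beta_treatment
  est <- coef(fit)[paste0("treatment", names(truth))]
  se <- sqrt(diag(vcov(fit)))[paste0("treatment", names(truth))]
  expect_true(all(abs(est - truth) < 3.5 * se))
  expect_equal(fit$n_groups, 36)
  expect_true(fit$converged)
})

test_that("shifting the outcome moves only the intercept", {
  d <- small_derived(seed = 2, n_zpdx = 12, embryos_per_arm = 8)
  f1 <- zpdx_lmm(d, random = "slopes", covariance = "diagonal")
  d2 <- d; d2$y <- d2$y + 0.5
  f2 <- zpdx_lmm(d2, random = "slopes", covariance = "diagonal")
  expect_equal(unname(coef(f2)["(Intercept)"] - coef(f1)["(Intercept)"]),
               0.5, tolerance = 1e-5)
  expect_equal(coef(f1)[-1], coef(f2)[-1], tolerance = 1e-4)
  expect_equal(f1$random_modes, f2$random_modes, tolerance = 1e-4)
  c1 <- posthoc_contrasts(f1); c2 <- posthoc_contrasts(f2)
  expect_equal(c1$estimate, c2$estimate, tolerance = 1e-5)
  expect_equal(c1$p_tukey, c2$p_tukey, tolerance = 1e-5)
  a1 <- avatar_calls(f1); a2 <- avatar_calls(f2)
  expect_identical(a1$beats_control, a2$beats_control)
  expect_identical(a1$differs_from_population, a2$differs_from_population)
})

test_that("conditional modes average to zero across avatars (shrinkage)", {
  fit <- zpdx_lmm(small_derived(seed = 3, n_zpdx = 15, embryos_per_arm = 8),
                  random = "slopes", covariance = "diagonal")
  means <- colMeans(fit$random_modes)
  spread <- apply(fit$random_modes, 2, sd)
  expect_true(all(abs(means) < pmax(0.05 * spread, 1e-6)))
})

test_that("degenerate designs and lookups error out cleanly", {
  d <- small_derived(seed = 4, n_zpdx = 2)
  d1 <- d[d$zpdx_id == d$zpdx_id[1], ]
  expect_error(zpdx_lmm(d1, random = "slopes"), "single group")
  fit <- zpdx_lmm(small_derived(seed = 4), random = "intercept")
  expect_error(predict(fit, zpdx_id = "NOPE"), "unknown zPDX")
  expect_error(predict(fit, treatment = "FOLFIRINOX"), "unknown treatment")
})

test_that("a singular general covariance falls back to diagonal", {
  d <- small_derived(seed = 6, n_zpdx = 10, embryos_per_arm = 6,
                     sd_slopes = rep(0, 4))
  expect_warning(fit <- zpdx_lmm(d, random = "slopes", covariance = "general"),
                 "falling back")
  expect_equal(fit$spec$covariance, "diagonal")
  expect_true(any(grepl("fallback", fit$notes)))
})

test_that("stepwise selection keeps slopes only when the data support them", {
  d0 <- small_derived(seed = 7, n_zpdx = 14, embryos_per_arm = 8,
                      sd_slopes = rep(0, 4))
  s0 <- stepwise_select(d0, covariance = "diagonal")
  expect_equal(s0$random, "intercept")

  d1 <- small_derived(seed = 8, n_zpdx = 14, embryos_per_arm = 8,
                      sd_slopes = rep(0.3, 4))
  s1 <- stepwise_select(d1, covariance = "diagonal")
  expect_equal(s1$random, "slopes")

  fit_auto <- zpdx_lmm(d1, random = "auto", covariance = "diagonal")
  expect_equal(fit_auto$spec$random, "slopes")
  expect_false(is.null(fit_auto$selection))
})

test_that("avatar predictions decompose into fixed part plus conditional modes", {
  fit <- zpdx_lmm(small_derived(seed = 9, n_zpdx = 8, embryos_per_arm = 8),
                  random = "slopes", covariance = "diagonal")
  pred <- predict(fit)
  for (r in sample(nrow(pred), 10)) {
    trt <- pred$treatment[r]
    gi <- match(pred$zpdx_id[r], fit$group_levels)
    fixed <- coef(fit)["(Intercept)"] +
      if (trt == "CONTROL") 0 else coef(fit)[paste0("treatment", trt)]
    b <- fit$random_modes[gi, "(Intercept)"] +
      if (trt == "CONTROL") 0 else fit$random_modes[gi, paste0("trt_", trt)]
    expect_equal(pred$pred_y[r], unname(fixed + b), tolerance = 1e-10)
  }
  # percent-scale interval limits are the monotone transform of the y limits
  expect_equal(pred$lower_pdv, inv_transform_pdv(pred$lower_y))
  expect_equal(pred$upper_pdv, inv_transform_pdv(pred$upper_y))
  expect_true(all(pred$lower_y < pred$upper_y))
  expect_true(all(pred$lower_pdv < pred$upper_pdv))
})

test_that("random-effect intervals flag an avatar far from the population", {
  # inject one avatar with a FOLFIRI slope 4 population-SDs from the mean
  co <- small_cohort(seed = 10, n_zpdx = 12, embryos_per_arm = 10,
                     sd_slopes = rep(0.1, 4), sigma_resid = 0.1)
  m <- co$measurements
  sel <- m$zpdx_id == "Z001" & m$treatment == "FOLFIRI"
  d <- derive_volume_changes(m)
  d$y[sel] <- d$y[sel] - 0.4
  fit <- zpdx_lmm(d, random = "slopes", covariance = "diagonal")
  cis <- random_effect_cis(fit)
  hit <- cis[cis$zpdx_id == "Z001" & cis$term == "trt_FOLFIRI", ]
  expect_true(hit$differs)
  expect_lt(hit$upper, 0)
  # flag count invariant under relabeling of avatar ids
  d_rl <- d
  d_rl$zpdx_id <- chartr("Z", "Q", d_rl$zpdx_id)
  fit_rl <- zpdx_lmm(d_rl, random = "slopes", covariance = "diagonal")
  expect_equal(sum(random_effect_cis(fit_rl)$differs), sum(cis$differs))
})

test_that("avatar calls implement the reduction and control-comparison rules", {
  fit <- zpdx_lmm(small_derived(seed = 12, n_zpdx = 10, embryos_per_arm = 10),
                  random = "slopes", covariance = "diagonal")
  calls <- avatar_calls(fit)
  treated <- calls[calls$treatment != "CONTROL", ]
  expect_identical(treated$significant_reduction,
                   treated$upper_y < log10(110))
  expect_identical(treated$significant_reduction,
                   treated$upper_pdv < 0)
  expect_true(all(is.na(calls$beats_control[calls$treatment == "CONTROL"])))
  # beats_control implies the treated interval sits entirely below control
  ctrl <- calls[calls$treatment == "CONTROL", c("zpdx_id", "lower_y")]
  merged <- merge(treated, ctrl, by = "zpdx_id", suffixes = c("", "_ctrl"))
  expect_identical(merged$beats_control,
                   merged$upper_y < merged$lower_y_ctrl)
})

test_that("posthoc contrasts match emmeans and behave like a contrast table", {
  skip_if_not_installed("emmeans")
  fit <- zpdx_lmm(small_derived(seed = 13, n_zpdx = 12, embryos_per_arm = 8),
                  random = "intercept")
  ours <- posthoc_contrasts(fit, df = "normal")
  em <- emmeans::emmeans(fit$fit, ~ treatment, lmer.df = "asymptotic")
  emc <- summary(pairs(em, adjust = "tukey"))
  expect_equal(ours$estimate, emc$estimate, tolerance = 1e-8)
  expect_equal(ours$se, emc$SE, tolerance = 1e-8)
  expect_equal(ours$p_tukey, emc$p.value, tolerance = 1e-6)
  # estimates are the least-square-mean differences (antisymmetric by
  # construction: reversing a pair flips the sign, keeps the p-value)
  lsm <- attr(ours, "lsmeans")
  diffs <- lsm$lsmean[match(ours$level_a, lsm$treatment)] -
    lsm$lsmean[match(ours$level_b, lsm$treatment)]
  expect_equal(ours$estimate, diffs)
  expect_true(all(ours$p_tukey >= 0 & ours$p_tukey <= 1))
  expect_equal(nrow(ours), 10)
})
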