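test_that("thresholds classify the documented boundary values", {
  expect_equal(as.character(classify_recist(c(-100, -90, -30, 0, 20))),
               c("CR", "CR", "PR", "SD", "PD"))
  expect_equal(as.character(classify_recist(c(25, -50, -89.9, -29.9, 19.9))),
               c("PD", "PR", "PR", "SD", "SD"))
  expect_error(classify_recist(-100.1), "domain")
  expect_true(is.ordered(classify_recist(0)))
  expect_true(classify_recist(-95) > classify_recist(-50))  # CR > PR
})

test_that("the four classes partition [-100, Inf) and are monotone", {
  grid <- c(seq(-100, 400, by = 0.5), runif(500, -100, 500))
  cls <- classify_recist(grid)
  expect_false(any(is.na(cls)))
  # larger decreases never yield a worse (lower-benefit) class
  ord <- order(grid)
  ranks <- as.integer(cls)[ord]
  expect_true(all(diff(ranks) <= 0))
})

test_that("arm response normalizes against the same avatar's control", {
  mk <- function(trt, ratios, id = "Z1") data.frame(
    zpdx_id = id, treatment = trt,
    area_start = rep(100, length(ratios)), area_end = 100 * ratios)
  ctrl <- mk("CONTROL", rep(1.2, 6))
  same <- mk("FOLFOX", rep(1.2, 6))
  r0 <- arm_response(same, ctrl)
  expect_equal(r0$normalized_change, 0)
  expect_equal(as.character(r0$recist), "SD")

  half <- mk("FOLFOX", rep(0.6, 6))
  r1 <- arm_response(half, ctrl)
  expect_equal(r1$normalized_change, -50)
  expect_equal(as.character(r1$recist), "PR")

  up <- mk("FOLFOX", rep(1.5, 6))
  r2 <- arm_response(up, ctrl)
  expect_equal(r2$normalized_change, 25)
  expect_equal(as.character(r2$recist), "PD")

  # embryo order and common rescaling of one avatar's areas do not matter
  shuf <- mk("FOLFOX", sample(c(0.4, 0.5, 0.6, 0.7, 0.8, 0.6)))
  scaled <- shuf; scaled$area_start <- shuf$area_start * 3
  scaled$area_end <- shuf$area_end * 3
  ctrl_scaled <- ctrl; ctrl_scaled$area_start <- ctrl$area_start * 3
  ctrl_scaled$area_end <- ctrl$area_end * 3
  expect_equal(arm_response(shuf, ctrl)$normalized_change,
               arm_response(scaled, ctrl_scaled)$normalized_change)

  expect_error(arm_response(mk("FOLFOX", 0.6), ctrl), "insufficient")
  expect_error(arm_response(half, mk("CONTROL", rep(0, 6))), "degenerate")
  expect_error(arm_response(half, mk("CONTROL", rep(1, 6), id = "Z2")),
               "same zPDX")
})

test_that("the two control-reference conventions differ as expected", {
  treated <- data.frame(zpdx_id = "Z1", treatment = "5FU",
                        area_start = c(10, 100, 10, 100, 10),
                        area_end = c(20, 50, 20, 50, 20))
  ctrl <- data.frame(zpdx_id = "Z1", treatment = "CONTROL",
                     area_start = rep(10, 5), area_end = rep(10, 5))
  mor <- arm_response(treated, ctrl, reference = "mean-of-ratios")
  rom <- arm_response(treated, ctrl, reference = "ratio-of-means")
  expect_equal(mor$mean_relative_area, mean(c(2, 0.5, 2, 0.5, 2)))
  expect_equal(rom$mean_relative_area, sum(treated$area_end) / sum(treated$area_start))
  expect_false(isTRUE(all.equal(mor$normalized_change, rom$normalized_change)))
})

test_that("cohort table reproduces an injected class mix and sums to 100", {
  changes <- c(rep(30, 8), rep(0, 8), rep(-50, 18), rep(-95, 2))
  responses <- data.frame(zpdx_id = sprintf("Z%02d", 1:36),
                          treatment = "FOLFIRI",
                          normalized_change = changes,
                          recist = classify_recist(changes))
  tab <- cohort_response_table(responses)
  expect_equal(tab$PD, 100 * 8 / 36, tolerance = 1e-10)
  expect_equal(tab$SD, 100 * 8 / 36, tolerance = 1e-10)
  expect_equal(tab$PR, 50)
  expect_equal(tab$CR, 100 * 2 / 36, tolerance = 1e-10)
  expect_equal(round(c(tab$PD, tab$SD, tab$PR, tab$CR), 1),
               c(22.2, 22.2, 50.0, 5.6))
  expect_equal(tab$PD + tab$SD + tab$PR + tab$CR, 100)

  one <- data.frame(zpdx_id = "Z1", treatment = "5FU",
                    recist = classify_recist(0))
  t1 <- cohort_response_table(one)
  expect_equal(t1$SD, 100)
})

test_that("arm_response_table skips low-engraftment arms with a reason", {
  co <- small_cohort(seed = 20, n_zpdx = 4, embryos_per_arm = 6)
  m <- co$measurements
  # knock one arm below the default cutoff of 5
  drop <- which(m$zpdx_id == "Z002" & m$treatment == "FOLFOX")[1:3]
  m <- m[-drop, ]
  expect_message(tab <- arm_response_table(m), "skipped")
  expect_false(any(tab$zpdx_id == "Z002" & tab$treatment == "FOLFOX"))
  expect_match(attr(tab, "skipped"), "Z002/FOLFOX", all = FALSE)
  expect_equal(sum(tab$zpdx_id == "Z001"), 4)
})
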