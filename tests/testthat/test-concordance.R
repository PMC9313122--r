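test_that("pair building joins on patient and regimen with logged exclusions", {
  fx <- coclinical_fixture()
  clinical <- map_regimens(fx$clinical)
  pairs <- build_pairs(clinical, fx$avatar_classes)
  expect_equal(nrow(pairs), 8)
  expect_equal(sum(pairs$concordant), 6)

  # capecitabine maps onto the 5-FU arm
  expect_equal(pairs$regimen[pairs$patient_id == "C038"], "5FU")

  extra <- rbind(clinical,
                 data.frame(patient_id = c("X1", "X2", "X3"),
                            regimen = c(NA, "GEMCITABINE", "FOLFOX"),
                            clinical_response = c("PR", "SD", "PR")))
  pairs2 <- build_pairs(extra, fx$avatar_classes)
  expect_equal(nrow(pairs2), 8)
  ex <- attr(pairs2, "excluded")
  expect_match(ex, "X1: no first-line", all = FALSE)
  expect_match(ex, "X2: regimen not tested", all = FALSE)
  expect_match(ex, "X3: no avatar call", all = FALSE)

  dup <- rbind(clinical, clinical[1, ])
  expect_error(build_pairs(dup, fx$avatar_classes), "duplicate")

  empty <- clinical[0, ]
  expect_equal(nrow(build_pairs(empty, fx$avatar_classes)), 0)
})

test_that("percent concordance counts agreements", {
  p <- data.frame(concordant = c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(percent_concordance(p), 75)
  expect_equal(percent_concordance(data.frame(concordant = rep(TRUE, 3))), 100)
  expect_equal(percent_concordance(data.frame(concordant = rep(FALSE, 3))), 0)
  expect_error(percent_concordance(data.frame(concordant = logical(0))), "no pairs")
})

test_that("tau-b agrees with base R on tied and untied data", {
  x <- c(3, 1, 4, 2, 5)
  expect_equal(kendall_tau_b(x, x)$tau, 1)
  expect_equal(kendall_tau_b(x, -x)$tau, -1)
  expect_error(kendall_tau_b(rep(2, 4), c(1, 2, 3, 4)), "tied")
  expect_error(kendall_tau_b(1:3, 1:4), "unequal")

  set.seed(31)
  for (rep in 1:40) {
    n <- sample(5:8, 1)
    a <- sample(1:3, n, replace = TRUE)
    b <- sample(1:4, n, replace = TRUE)
    if (sd(a) == 0 || sd(b) == 0) next
    kt <- kendall_tau_b(a, b)
    expect_equal(kt$tau, cor(a, b, method = "kendall"), tolerance = 1e-12)
    bf <- brute_force_S(a, b)
    expect_identical(kt$S, bf$S)
    expect_identical(kt$nc, bf$nc)
    expect_identical(kt$nd, bf$nd)
    if (bf$S != 0) {
      # tie-corrected Var(S) cross-checked via the z statistic of cor.test
      ct <- suppressWarnings(cor.test(a, b, method = "kendall"))
      if (ct$statistic != 0 && names(ct$statistic) == "z") {
        var_from_ct <- (bf$S / unname(ct$statistic))^2
        expect_equal(kt$var_S, var_from_ct, tolerance = 1e-8)
      }
    }
  }
})

test_that("tau-b is invariant under monotone recoding and antisymmetric", {
  a <- c(1, 2, 2, 3, 1, 3, 2)
  b <- c(2, 2, 3, 3, 1, 2, 1)
  base <- kendall_tau_b(a, b)
  recoded <- kendall_tau_b(c(10, 100, 100, 1000, 10, 1000, 100), b)
  expect_equal(base$tau, recoded$tau)
  expect_equal(base$p_value, recoded$p_value)
  expect_equal(kendall_tau_b(a, -b)$tau, -base$tau)

  # p shrinks as |S| grows with the same margins: perfect vs shuffled order
  strong <- kendall_tau_b(1:8, 1:8)
  weak <- kendall_tau_b(1:8, c(2, 1, 4, 3, 6, 5, 8, 7))
  expect_gt(strong$S, weak$S)
  expect_lt(strong$p_value, weak$p_value)
})

test_that("RECIST classes are coded in the clinical benefit order", {
  kt <- kendall_tau_b(c("PD", "SD", "PR", "CR"), c("PD", "SD", "PR", "CR"))
  expect_equal(kt$tau, 1)
  kt2 <- kendall_tau_b(factor(c("PD", "PR"), levels = RECIST_LEVELS,
                              ordered = TRUE), c(1, 2))
  expect_equal(kt2$tau, 1)
  expect_error(kendall_tau_b(c("PD", "WAT"), c(1, 2)), "cannot order")
})

test_that("coclinical summary ties pairing and the rank test together", {
  fx <- coclinical_fixture()
  pairs <- build_pairs(map_regimens(fx$clinical), fx$avatar_classes)
  s <- coclinical_summary(pairs)
  expect_equal(s$n_pairs, 8)
  expect_equal(s$concordance_percent, 75)
  expect_equal(s$tau, 11 / sqrt(255))
})
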