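test_that("Egger regression matches a closed-form least-squares oracle", {
  eff <- make_effects(c(-0.6, 0.1, 0.45), c(0.12, 0.22, 0.35))
  # independent oracle: normal equations for y = b0 + b1 x
  y <- eff$log_or / eff$se
  x <- 1 / eff$se
  n <- 3
  sxx <- sum((x - mean(x))^2)
  b1 <- sum((x - mean(x)) * (y - mean(y))) / sxx
  b0 <- mean(y) - b1 * mean(x)
  rss <- sum((y - b0 - b1 * x)^2)
  se_b0 <- sqrt(rss / (n - 2)) * sqrt(1 / n + mean(x)^2 / sxx)

  res <- egger_test(eff)
  expect_equal(res$intercept, b0)
  expect_equal(res$se, se_b0)
  expect_equal(res$statistic, b0 / se_b0)
  expect_equal(res$df, 1L)
  expect_equal(res$p_value, 2 * pt(-abs(b0 / se_b0), df = 1))
})

test_that("Egger test errors on too few studies or equal precisions", {
  eff <- make_effects(c(-0.2, 0.2), c(0.1, 0.2))
  expect_error(egger_test(eff), "at least 3")
  flat <- make_effects(c(-0.2, 0.0, 0.2), c(0.25, 0.25, 0.25))
  expect_error(egger_test(flat), "degenerate")
})

test_that("Egger agrees with metafor's classical regression test on real data", {
  eff <- study_effects(build_contrasts(cfi_studies("rs10033900_total"), "allele"))
  res <- egger_test(eff)
  ref <- metafor::regtest(x = eff$log_or, sei = eff$se, model = "lm")
  # regtest parameterizes as a weighted regression of effect on SE, whose
  # SE coefficient equals the classical Egger intercept
  expect_equal(res$intercept, as.numeric(coef(ref$fit)[2]), tolerance = 1e-10)
  expect_equal(res$statistic, ref$zval, tolerance = 1e-10)
  expect_equal(res$p_value, ref$pval, tolerance = 1e-10)
})

test_that("Egger reproduces the published values on the reproducible study sets", {
  # recessive contrast, 12-study rs10033900 set
  rec <- study_effects(build_contrasts(cfi_studies("rs10033900_total"), "recessive"))
  res <- egger_test(rec)
  expect_equal(res$intercept, -0.577, tolerance = 0.002)
  expect_equal(res$se, 1.243, tolerance = 0.002)
  expect_equal(round(res$statistic, 2), -0.46)
  expect_equal(res$p_value, 0.653, tolerance = 0.002)
  expect_equal(res$ci_low, -3.347, tolerance = 0.005)
  expect_equal(res$ci_high, 2.194, tolerance = 0.005)

  # allele contrast, 3-study rs2285714 set
  al <- study_effects(build_contrasts(cfi_studies("rs2285714"), "allele"))
  res2 <- egger_test(al)
  expect_equal(res2$intercept, 1.247, tolerance = 0.002)
  expect_equal(res2$se, 1.837, tolerance = 0.002)
  expect_equal(round(res2$statistic, 2), 0.68)
  expect_equal(res2$p_value, 0.62, tolerance = 0.005)
})

test_that("Begg's Kendall score matches an independent pair count", {
  eff <- make_effects(c(-0.9, -0.1, 0.3, 0.6), c(0.1, 0.18, 0.26, 0.4))
  res <- begg_test(eff)
  # independent route: Kendall correlation of the standardized deviates
  v <- eff$se^2
  w <- 1 / v
  t_std <- (eff$log_or - sum(w * eff$log_or) / sum(w)) / sqrt(v - 1 / sum(w))
  tau <- cor(t_std, v, method = "kendall")
  expect_equal(res$s, as.integer(tau * choose(4, 2)))
  expect_equal(res$statistic, abs(res$s) / sqrt(4 * 3 * 13 / 18))

  with_cc <- begg_test(eff, continuity = TRUE)
  expect_equal(with_cc$statistic, (abs(res$s) - 1) / sqrt(4 * 3 * 13 / 18))
})

test_that("Begg's score is antisymmetric under effect reflection", {
  eff <- make_effects(c(-0.7, -0.2, 0.15, 0.4, 0.9), c(0.11, 0.17, 0.23, 0.31, 0.45))
  plus <- begg_test(eff)
  minus <- begg_test(dplyr::mutate(eff, log_or = -log_or))
  expect_equal(minus$s, -plus$s)
  expect_equal(minus$statistic, plus$statistic)
  expect_error(begg_test(eff[1, ]), "at least 2")
})

test_that("Begg agrees with metafor's rank test and the published rs2285714 value", {
  eff <- study_effects(build_contrasts(cfi_studies("rs10033900_total"), "allele"))
  res <- begg_test(eff)
  ref <- metafor::ranktest(x = eff$log_or, sei = eff$se)
  expect_equal(res$s / choose(12, 2), as.numeric(ref$tau), tolerance = 1e-10)

  rs2 <- study_effects(build_contrasts(cfi_studies("rs2285714"), "allele"))
  res2 <- begg_test(rs2)
  expect_equal(round(res2$statistic, 2), 0.52)
  expect_equal(res2$p_value, 0.602, tolerance = 0.001)
})

test_that("leave-one-out reports k sub-pools and flags a constructed outlier", {
  ct <- build_contrasts(cfi_studies("rs10033900_total"), "allele")
  loo <- leave_one_out(ct)
  expect_equal(nrow(loo), 12)
  expect_true(all(loo$k == 11))
  expect_false(any(loo$influential))

  # five null studies plus one precise shifted study that dominates the pool
  stress <- tibble::tibble(
    study_id = c(sprintf("null_%d", 1:5), "outlier"),
    a = c(rep(50, 5), 4500), b = c(rep(50, 5), 4024),
    c = c(rep(50, 5), 4024), d = c(rep(50, 5), 4500)
  )
  loo_stress <- leave_one_out(stress)
  expect_true(loo_stress$influential[loo_stress$omitted_study == "outlier"])
  expect_false(any(loo_stress$influential[loo_stress$omitted_study != "outlier"]))

  three <- leave_one_out(ct[1:3, ])
  expect_equal(nrow(three), 3)
  expect_true(all(three$k == 2))
  expect_error(leave_one_out(ct[1:2, ]), "at least 3")
})

test_that("funnel coordinates centre on the fixed pooled mean", {
  eff <- study_effects(build_contrasts(cfi_studies("rs10033900_total"), "allele"))
  fd <- funnel_data(eff)
  expect_equal(nrow(fd$points), 12)
  w <- 1 / eff$se^2
  expect_equal(fd$guides$center[1], sum(w * eff$log_or) / sum(w))
  expect_equal(fd$guides$lower + 2 * qnorm(0.975) * fd$guides$se, fd$guides$upper)

  one <- funnel_data(eff[3, ])
  expect_equal(nrow(one$points), 1)
  expect_equal(one$guides$center[1], eff$log_or[3])
  expect_false(one$points$outside)

  empty <- funnel_data(eff[0, ])
  expect_equal(nrow(empty$points), 0)
  expect_equal(nrow(empty$guides), 0)

  expect_s3_class(plot_funnel(eff), "ggplot")
})
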