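test_that("per-study effects follow the odds-ratio formulas", {
  null_table <- tibble::tibble(study_id = "n", a = 10, b = 10, c = 10, d = 10)
  eff <- study_effects(null_table)
  expect_equal(eff$or, 1)
  expect_equal(eff$se, sqrt(0.4))
  expect_equal(eff$ci_low, exp(-qnorm(0.975) * sqrt(0.4)))

  kondo <- build_contrasts(
    dplyr::filter(cfi_studies("rs10033900_total"), study_id == "Kondo_2010"),
    "homozygote"
  )
  expect_equal(study_effects(kondo)$or, 438 / 1581)

  zero <- tibble::tibble(study_id = "z", a = 0, b = 10, c = 10, d = 10)
  eff0 <- study_effects(zero)
  expect_equal(eff0$or, (0.5 * 10.5) / (10.5 * 10.5))
  expect_equal(eff0$se, sqrt(1 / 0.5 + 3 / 10.5))

  empty_row <- tibble::tibble(study_id = "e", a = 0, b = 0, c = 10, d = 10)
  expect_error(study_effects(empty_row), "empty table margin")
})

test_that("Cochran's Q and tau2 match a direct evaluation of their definitions", {
  same <- make_effects(c(-0.2, -0.2), c(0.1, 0.1))
  het0 <- cochran_q(same)
  expect_equal(het0$q, 0)
  expect_equal(het0$p_value, 1)
  expect_equal(het0$tau2, 0)
  expect_equal(het0$i2, 0)

  eff <- make_effects(c(-0.5, 0.1, 0.4), c(0.15, 0.25, 0.4))
  # independent oracle: spell the definitions out term by term
  w <- c(1 / 0.15^2, 1 / 0.25^2, 1 / 0.4^2)
  theta <- sum(w * c(-0.5, 0.1, 0.4)) / sum(w)
  q_manual <- w[1] * (-0.5 - theta)^2 + w[2] * (0.1 - theta)^2 + w[3] * (0.4 - theta)^2
  tau2_manual <- max(0, (q_manual - 2) / (sum(w) - (w[1]^2 + w[2]^2 + w[3]^2) / sum(w)))
  res <- cochran_q(eff)
  expect_equal(res$q, q_manual)
  expect_equal(res$df, 2L)
  expect_equal(res$p_value, pchisq(q_manual, 2, lower.tail = FALSE))
  expect_equal(res$tau2, tau2_manual)

  expect_error(cochran_q(eff[1, ]), "at least 2")
})

test_that("Mantel-Haenszel pooling is exact on one study and replication-invariant", {
  ct <- tibble::tibble(study_id = "s1", a = 12, b = 30, c = 9, d = 41)
  single <- pool_mh(ct)
  expect_equal(single$or, (12 * 41) / (30 * 9))
  expect_equal(single$se, sqrt(1 / 12 + 1 / 30 + 1 / 9 + 1 / 41))

  twice <- pool_mh(dplyr::bind_rows(ct, dplyr::mutate(ct, study_id = "s2")))
  expect_equal(twice$or, single$or)
})

test_that("MH estimate and RBG variance agree with metafor's rma.mh", {
  studies <- cfi_studies("rs10033900_total")
  for (m in c("allele", "homozygote")) {
    ct <- build_contrasts(studies, m)
    ours <- pool_mh(ct)
    ref <- metafor::rma.mh(measure = "OR", ai = ct$a, bi = ct$b,
                           ci = ct$c, di = ct$d, correct = FALSE)
    expect_equal(ours$log_or, as.numeric(ref$beta), tolerance = 1e-12)
    expect_equal(ours$se, ref$se, tolerance = 1e-12)
  }
})

test_that("DL pooling reduces to inverse-variance at tau2 = 0 and matches its formulas", {
  # effects homogeneous enough that Q < df forces tau2 to 0
  eff <- make_effects(c(-0.20, -0.21, -0.19), c(0.2, 0.3, 0.25))
  dl <- pool_dl(eff)
  expect_equal(dl$heterogeneity$tau2, 0)
  w <- 1 / eff$se^2
  expect_equal(dl$log_or, sum(w * eff$log_or) / sum(w))
  expect_equal(dl$se, 1 / sqrt(sum(w)))

  # heterogeneous case against a hand-summed DL oracle
  eff <- make_effects(c(-0.8, 0.0, 0.5), c(0.15, 0.2, 0.3))
  w <- 1 / eff$se^2
  theta_iv <- sum(w * eff$log_or) / sum(w)
  q <- sum(w * (eff$log_or - theta_iv)^2)
  tau2 <- max(0, (q - 2) / (sum(w) - sum(w^2) / sum(w)))
  wr <- 1 / (eff$se^2 + tau2)
  dl <- pool_dl(eff)
  expect_equal(dl$log_or, sum(wr * eff$log_or) / sum(wr))
  expect_equal(dl$se, 1 / sqrt(sum(wr)))
  expect_error(pool_dl(eff[2, ]), "at least 2")
})

test_that("DL pooling agrees with metafor on the full allele-model data", {
  ct <- build_contrasts(cfi_studies("rs10033900_total"), "allele")
  ours <- pool_dl(study_effects(ct))
  ref <- metafor::rma(measure = "OR", ai = ct$a, bi = ct$b, ci = ct$c, di = ct$d,
                      method = "DL")
  expect_equal(ours$log_or, as.numeric(ref$beta), tolerance = 1e-10)
  expect_equal(ours$se, ref$se, tolerance = 1e-10)
  expect_equal(ours$heterogeneity$tau2, ref$tau2, tolerance = 1e-10)
  expect_equal(ours$heterogeneity$q, ref$QE, tolerance = 1e-10)
})

test_that("heterogeneity-driven selection picks the documented effect model", {
  studies <- cfi_studies("rs10033900_total")
  total <- select_and_pool(build_contrasts(studies, "allele"))
  expect_equal(total$effect_model, "random_DL")
  expect_lt(total$heterogeneity$p_value, 0.10)

  cauc <- dplyr::filter(studies, ethnicity == "Caucasian")
  fixed <- select_and_pool(build_contrasts(cauc, "allele"))
  expect_equal(fixed$effect_model, "fixed_MH")
  expect_gt(fixed$heterogeneity$p_value, 0.10)

  ct <- tibble::tibble(study_id = c("s1", "s2"), a = c(12, 12), b = c(30, 30),
                       c = c(9, 9), d = c(41, 41))
  expect_equal(select_and_pool(ct)$effect_model, "fixed_MH")
})

test_that("pooled estimates are convex and random CIs are no narrower than fixed", {
  studies <- cfi_studies("rs10033900_total")
  for (m in genetic_models()) {
    ct <- build_contrasts(studies, m)
    eff <- study_effects(ct)
    mh <- pool_mh(ct)
    expect_gte(mh$or, min(eff$or))
    expect_lte(mh$or, max(eff$or))
    dl <- pool_dl(eff)
    iv_se <- 1 / sqrt(sum(1 / eff$se^2))
    expect_gte(dl$se, iv_se)
  }
})

test_that("tidy and glance expose broom-style summaries", {
  pool <- select_and_pool(build_contrasts(cfi_studies("rs10033900_total"), "allele"))
  td <- tidy(pool)
  expect_equal(nrow(td), 12)
  expect_equal(sum(td$weight), 100)
  expect_named(td, c("study_id", "estimate", "conf.low", "conf.high",
                     "log_or", "std.error", "weight"))
  gl <- glance(pool)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$estimate, pool$or)
  expect_equal(gl$effect_model, "random_DL")

  plt <- autoplot(pool)
  expect_s3_class(plt, "ggplot")
})
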