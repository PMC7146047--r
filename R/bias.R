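#' Egger's regression test for funnel-plot asymmetry
#'
#' Ordinary least squares of each study's standard normal deviate
#' `log_or / se` on its precision `1 / se`. Under a symmetric funnel the
#' intercept is zero; it is tested with a t statistic (`intercept / SE`) on
#' `k - 2` degrees of freedom. This is the classical Egger formulation, and
#' is algebraically identical to the weighted regression of `log_or` on `se`
#' with weights `1/se^2`.
#'
#' @inheritParams cochran_q
#' @param conf_level Confidence level for the intercept interval.
#' @return A one-row tibble: `k`, `intercept`, `se`, `statistic` (t), `df`,
#'   `p_value`, `ci_low`, `ci_high`.
#' @examples
#' eff <- study_effects(build_contrasts(cfi_studies("rs10033900_total"), "allele"))
#' egger_test(eff)
#' @export
egger_test <- function(effects, conf_level = 0.95) {
  effects <- check_effects(effects)
  k <- nrow(effects)
  if (k < 3) {
    abort("Egger's test needs at least 3 studies")
  }
  precision <- 1 / effects$se
  if (diff(range(precision)) < sqrt(.Machine$double.eps)) {
    abort("degenerate regression: all study precisions are equal")
  }
  snd <- effects$log_or / effects$se
  fit <- lm(snd ~ precision)
  est <- summary(fit)$coefficients
  tcrit <- qt(1 - (1 - conf_level) / 2, df = k - 2)
  tibble(
    k = k,
    intercept = est[1, 1],
    se = est[1, 2],
    statistic = est[1, 3],
    df = k - 2L,
    p_value = est[1, 4],
    ci_low = est[1, 1] - tcrit * est[1, 2],
    ci_high = est[1, 1] + tcrit * est[1, 2]
  )
}

#' Begg-Mazumdar rank-correlation test for publication bias
#'
#' Standardizes each study's deviation from the fixed inverse-variance pooled
#' mean using the conditional variance `v_i* = se_i^2 - 1/sum(1/se_j^2)`,
#' then computes the Kendall score S (concordant minus discordant pairs)
#' between the standardized effects and the sampling variances. The normal
#' deviate is `z = (|S| - c) / sqrt(k (k-1) (2k+5) / 18)` with `c = 1` when
#' `continuity` is `TRUE` (default `FALSE`, the plain Begg-Mazumdar
#' statistic), and the p-value is two-sided.
#'
#' @inheritParams cochran_q
#' @param continuity Apply the continuity correction of 1 to `|S|`.
#' @return A one-row tibble: `k`, `s` (Kendall score), `statistic` (z),
#'   `p_value`, `continuity`.
#' @examples
#' eff <- study_effects(build_contrasts(cfi_studies("rs2285714"), "allele"))
#' begg_test(eff)
#' @export
begg_test <- function(effects, continuity = FALSE) {
  effects <- check_effects(effects)
  k <- nrow(effects)
  if (k < 2) {
    abort("Begg's test needs at least 2 studies")
  }
  v <- effects$se^2
  w <- 1 / v
  theta_iv <- sum(w * effects$log_or) / sum(w)
  vstar <- v - 1 / sum(w)
  t_std <- (effects$log_or - theta_iv) / sqrt(vstar)
  s <- 0L
  for (i in seq_len(k - 1)) {
    for (j in seq.int(i + 1, k)) {
      s <- s + sign(t_std[j] - t_std[i]) * sign(v[j] - v[i])
    }
  }
  sd_s <- sqrt(k * (k - 1) * (2 * k + 5) / 18)
  z <- max(0, abs(s) - if (continuity) 1 else 0) / sd_s
  tibble(
    k = k,
    s = as.integer(s),
    statistic = z,
    p_value = 2 * pnorm(-abs(z)),
    continuity = continuity
  )
}

#' Leave-one-out sensitivity analysis
#'
#' Re-runs [select_and_pool()] `k` times, omitting each study in turn. A
#' study is flagged influential when its omission moves the pooled odds
#' ratio outside the all-study 95% CI — the usual graphical criterion of
#' influence plots, where every leave-one-out estimate is drawn against the
#' overall confidence limits. Whether the omission also flips the
#' significance of the pooled Z test at `alpha` is reported separately in
#' `sign_flip`; a flip can reflect a merely borderline overall p-value
#' rather than a genuinely influential study, so it does not enter the flag.
#'
#' @inheritParams select_and_pool
#' @param alpha Significance level used for the `sign_flip` column.
#' @return A tibble with one row per omitted study: `omitted_study`,
#'   `effect_model`, `k`, `or`, `ci_low`, `ci_high`, `p_value`,
#'   `influential`, `sign_flip`.
#' @examples
#' leave_one_out(build_contrasts(cfi_studies("rs10033900_total"), "allele"))
#' @export
leave_one_out <- function(contrasts, q_threshold = 0.10, continuity = 0.5,
                          alpha = 0.05) {
  ct <- check_contrasts(contrasts)
  if (nrow(ct) < 3) {
    abort("leave-one-out needs at least 3 studies")
  }
  full <- select_and_pool(ct, q_threshold = q_threshold, continuity = continuity)
  rows <- lapply(seq_len(nrow(ct)), function(i) {
    sub <- select_and_pool(ct[-i, ], q_threshold = q_threshold,
                           continuity = continuity)
    tibble(
      omitted_study = ct$study_id[i],
      effect_model = sub$effect_model,
      k = sub$k,
      or = sub$or,
      ci_low = sub$ci_low,
      ci_high = sub$ci_high,
      p_value = sub$p_value,
      influential = sub$or < full$ci_low | sub$or > full$ci_high,
      sign_flip = (sub$p_value < alpha) != (full$p_value < alpha)
    )
  })
  bind_rows(rows)
}

#' Funnel-plot coordinates with pseudo-confidence guides
#'
#' Per-study `(log_or, se)` coordinates together with the usual pseudo 95%
#' confidence funnel `theta +/- 1.96 * se` around the fixed inverse-variance
#' pooled mean, for plotting or export.
#'
#' @inheritParams cochran_q
#' @return A list with two tibbles: `points` (`study_id`, `log_or`, `se`,
#'   `or`, `outside` — whether the study falls outside the funnel) and
#'   `guides` (`se`, `center`, `lower`, `upper` along a grid from 0 to the
#'   largest study SE).
#' @export
funnel_data <- function(effects) {
  if (is.data.frame(effects) && nrow(effects) == 0) {
    return(list(
      points = tibble(study_id = character(), log_or = double(),
                      se = double(), or = double(), outside = logical()),
      guides = tibble(se = double(), center = double(),
                      lower = double(), upper = double())
    ))
  }
  effects <- check_effects(effects)
  w <- 1 / effects$se^2
  center <- sum(w * effects$log_or) / sum(w)
  zc <- qnorm(0.975)
  se_grid <- seq(0, max(effects$se) * 1.05, length.out = 50)
  list(
    points = tibble(
      study_id = effects$study_id,
      log_or = effects$log_or,
      se = effects$se,
      or = exp(effects$log_or),
      outside = abs(effects$log_or - center) > zc * effects$se
    ),
    guides = tibble(
      se = se_grid,
      center = center,
      lower = center - zc * se_grid,
      upper = center + zc * se_grid
    )
  )
}

#' Begg-style funnel plot
#'
#' @inheritParams cochran_q
#' @return A ggplot of per-study log odds ratios against their standard
#'   errors (inverted axis), with the pooled mean and pseudo 95% confidence
#'   funnel.
#' @export
plot_funnel <- function(effects) {
  fd <- funnel_data(effects)
  ggplot2::ggplot(fd$points, ggplot2::aes(x = .data$log_or, y = .data$se)) +
    ggplot2::geom_line(data = fd$guides, ggplot2::aes(x = .data$lower),
                       linetype = "dotted", colour = "grey40") +
    ggplot2::geom_line(data = fd$guides, ggplot2::aes(x = .data$upper),
                       linetype = "dotted", colour = "grey40") +
    ggplot2::geom_vline(xintercept = fd$guides$center[1], colour = "grey40") +
    ggplot2::geom_point(shape = 21, fill = "white", size = 2) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "log OR", y = "Standard error of log OR") +
    ggplot2::theme_minimal()
}
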