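#' Per-study odds ratios with Wald confidence intervals
#'
#' Computes each study's log odds ratio `log(ad/bc)` and its large-sample
#' standard error `sqrt(1/a + 1/b + 1/c + 1/d)` from a contrast table. When a
#' study has any zero cell, the Haldane-Anscombe correction adds `continuity`
#' (default 0.5) to all four of that study's cells first; studies with an
#' entirely empty margin carry no information about the odds ratio and raise
#' an error.
#'
#' @param contrasts A contrast tibble from [build_contrasts()] (columns
#'   `study_id`, `a`, `b`, `c`, `d`, optionally `model`).
#' @param continuity Value added to all four cells of a study containing a
#'   zero cell.
#' @return A tibble with `study_id` (and `model` if present), the corrected
#'   cells, `log_or`, `se`, `or`, `ci_low`, `ci_high` (95% Wald interval).
#' @examples
#' studies <- cfi_studies("rs10033900_total")
#' study_effects(build_contrasts(studies, "allele"))
#' @export
study_effects <- function(contrasts, continuity = 0.5) {
  ct <- check_contrasts(contrasts)
  bad <- with(ct, (a + b) == 0 | (c + d) == 0 | (a + c) == 0 | (b + d) == 0)
  if (any(bad)) {
    abort(sprintf("effect undefined for study %s: empty table margin",
                  ct$study_id[which(bad)[1]]))
  }
  zero <- with(ct, a == 0 | b == 0 | c == 0 | d == 0)
  for (col in c("a", "b", "c", "d")) {
    ct[[col]] <- ct[[col]] + ifelse(zero, continuity, 0)
  }
  ct$log_or <- log(ct$a * ct$d / (ct$b * ct$c))
  ct$se <- sqrt(1 / ct$a + 1 / ct$b + 1 / ct$c + 1 / ct$d)
  ct$or <- exp(ct$log_or)
  ct$ci_low <- exp(ct$log_or - qnorm(0.975) * ct$se)
  ct$ci_high <- exp(ct$log_or + qnorm(0.975) * ct$se)
  ct
}

check_contrasts <- function(contrasts, single_model = TRUE) {
  if (!is.data.frame(contrasts)) {
    abort("`contrasts` must be a data frame")
  }
  need <- c("study_id", "a", "b", "c", "d")
  missing_cols <- setdiff(need, names(contrasts))
  if (length(missing_cols) > 0) {
    abort(paste0("missing contrast columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (single_model && "model" %in% names(contrasts) &&
      length(unique(contrasts$model)) > 1) {
    abort("expected contrasts for a single genetic model; got several")
  }
  if (any(contrasts$a < 0 | contrasts$b < 0 | contrasts$c < 0 | contrasts$d < 0)) {
    abort("contrast cells must be non-negative")
  }
  as_tibble(contrasts)
}

check_effects <- function(effects) {
  if (!is.data.frame(effects) ||
      !all(c("study_id", "log_or", "se") %in% names(effects))) {
    abort("`effects` must be a data frame with study_id, log_or and se columns")
  }
  if (any(effects$se <= 0)) {
    abort("standard errors must be positive")
  }
  as_tibble(effects)
}

#' Cochran's Q heterogeneity test and the DerSimonian-Laird tau-squared
#'
#' Q is the inverse-variance weighted sum of squared deviations of the
#' per-study log odds ratios around the fixed-effect mean, referred to a
#' chi-square distribution with `k - 1` degrees of freedom. `i2` is
#' `max(0, (Q - df)/Q)` and `tau2` the DerSimonian-Laird moment estimate
#' `max(0, (Q - df) / (sum(w) - sum(w^2)/sum(w)))`, truncated at zero.
#'
#' @param effects A tibble of per-study effects from [study_effects()]
#'   (columns `study_id`, `log_or`, `se`).
#' @return A one-row tibble: `q`, `df`, `p_value`, `i2`, `tau2`.
#' @export
cochran_q <- function(effects) {
  effects <- check_effects(effects)
  k <- nrow(effects)
  if (k < 2) {
    abort("heterogeneity test needs at least 2 studies")
  }
  w <- 1 / effects$se^2
  theta_iv <- sum(w * effects$log_or) / sum(w)
  q <- sum(w * (effects$log_or - theta_iv)^2)
  df <- k - 1L
  tibble(
    q = q,
    df = df,
    p_value = pchisq(q, df = df, lower.tail = FALSE),
    i2 = if (q > 0) max(0, (q - df) / q) else 0,
    tau2 = max(0, (q - df) / (sum(w) - sum(w^2) / sum(w)))
  )
}

new_meta_pool <- function(theta, se, effect_model, het, per_study, model) {
  z <- theta / se
  structure(
    list(
      model = model,
      effect_model = effect_model,
      k = nrow(per_study),
      log_or = theta,
      se = se,
      or = exp(theta),
      ci_low = exp(theta - qnorm(0.975) * se),
      ci_high = exp(theta + qnorm(0.975) * se),
      z = z,
      p_value = 2 * pnorm(-abs(z)),
      heterogeneity = het,
      per_study = per_study
    ),
    class = "meta_pool"
  )
}

het_or_na <- function(effects) {
  if (nrow(effects) >= 2) {
    cochran_q(effects)
  } else {
    tibble(q = NA_real_, df = 0L, p_value = NA_real_, i2 = NA_real_, tau2 = 0)
  }
}

#' Mantel-Haenszel fixed-effect pooled odds ratio
#'
#' Pools 2x2 tables directly with the Mantel-Haenszel estimator
#' `OR = sum(a*d/n) / sum(b*c/n)`; the variance of its logarithm uses the
#' Robins-Breslow-Greenland formula. No continuity correction enters the MH
#' sums (zero cells are handled naturally); the per-study effects attached to
#' the result use [study_effects()] with its usual correction.
#'
#' @inheritParams study_effects
#' @return A `meta_pool` object; see [tidy.meta_pool()] and
#'   [glance.meta_pool()].
#' @examples
#' cauc <- dplyr::filter(cfi_studies("rs10033900_total"), ethnicity == "Caucasian")
#' pool_mh(build_contrasts(cauc, "allele"))
#' @export
pool_mh <- function(contrasts, continuity = 0.5) {
  ct <- check_contrasts(contrasts)
  if (nrow(ct) < 1) {
    abort("no studies to pool")
  }
  n <- ct$a + ct$b + ct$c + ct$d
  R <- sum(ct$a * ct$d / n)
  S <- sum(ct$b * ct$c / n)
  if (R == 0 || S == 0) {
    abort("Mantel-Haenszel odds ratio undefined: all tables degenerate")
  }
  # Robins-Breslow-Greenland variance of log(OR_MH)
  P <- (ct$a + ct$d) / n
  Q <- (ct$b + ct$c) / n
  v <- sum(P * ct$a * ct$d / n) / (2 * R^2) +
    sum(P * ct$b * ct$c / n + Q * ct$a * ct$d / n) / (2 * R * S) +
    sum(Q * ct$b * ct$c / n) / (2 * S^2)
  per_study <- study_effects(ct, continuity = continuity)
  new_meta_pool(
    theta = log(R / S), se = sqrt(v), effect_model = "fixed_MH",
    het = het_or_na(per_study), per_study = per_study,
    model = if ("model" %in% names(ct)) ct$model[1] else NA_character_
  )
}

#' DerSimonian-Laird random-effects pooled odds ratio
#'
#' Inverse-variance pooling of per-study log odds ratios with weights
#' `1 / (se^2 + tau2)`, where `tau2` is the DerSimonian-Laird moment
#' estimate from [cochran_q()]. With `tau2 = 0` this reduces to fixed
#' inverse-variance pooling.
#'
#' @inheritParams cochran_q
#' @return A `meta_pool` object.
#' @examples
#' eff <- study_effects(build_contrasts(cfi_studies("rs10033900_total"), "allele"))
#' pool_dl(eff)
#' @export
pool_dl <- function(effects) {
  effects <- check_effects(effects)
  if (nrow(effects) < 2) {
    abort("random-effects pooling needs at least 2 studies")
  }
  het <- cochran_q(effects)
  w <- 1 / (effects$se^2 + het$tau2)
  theta <- sum(w * effects$log_or) / sum(w)
  new_meta_pool(
    theta = theta, se = 1 / sqrt(sum(w)), effect_model = "random_DL",
    het = het, per_study = effects,
    model = if ("model" %in% names(effects)) effects$model[1] else NA_character_
  )
}

#' Heterogeneity-driven model selection and pooling
#'
#' Runs Cochran's Q on the per-study effects; when the Q-test p-value exceeds
#' `q_threshold` (default 0.10, i.e. no detectable heterogeneity) the tables
#' are pooled with the Mantel-Haenszel fixed-effect estimator, otherwise with
#' DerSimonian-Laird random effects. The returned object records which model
#' was used in `$effect_model`.
#'
#' @inheritParams study_effects
#' @param q_threshold Q-test p-value above which fixed effects are used.
#' @return A `meta_pool` object.
#' @examples
#' select_and_pool(build_contrasts(cfi_studies("rs10033900_total"), "allele"))
#' @export
select_and_pool <- function(contrasts, q_threshold = 0.10, continuity = 0.5) {
  ct <- check_contrasts(contrasts)
  if (nrow(ct) < 2) {
    abort("model selection needs at least 2 studies")
  }
  effects <- study_effects(ct, continuity = continuity)
  het <- cochran_q(effects)
  if (het$p_value > q_threshold) {
    pool_mh(ct, continuity = continuity)
  } else {
    pool_dl(effects)
  }
}

#' @export
print.meta_pool <- function(x, ...) {
  label <- if (!is.na(x$model) && x$model %in% names(model_labels)) {
    model_labels[[x$model]]
  } else {
    x$model
  }
  cat(sprintf(
    "Pooled odds ratio (%s), %d studies%s\n",
    if (x$effect_model == "fixed_MH") "Mantel-Haenszel fixed effect"
    else "DerSimonian-Laird random effects",
    x$k,
    if (is.na(label)) "" else paste0(", ", label)
  ))
  cat(sprintf("  OR %.2f (95%% CI %.2f-%.2f), Z = %.2f, p = %.3g\n",
              x$or, x$ci_low, x$ci_high, x$z, x$p_value))
  if (!is.na(x$heterogeneity$q)) {
    cat(sprintf("  Heterogeneity: Q = %.2f (df %d, p = %.3f), I2 = %.0f%%, tau2 = %.4f\n",
                x$heterogeneity$q, x$heterogeneity$df, x$heterogeneity$p_value,
                100 * x$heterogeneity$i2, x$heterogeneity$tau2))
  }
  invisible(x)
}

#' Tidy the per-study estimates of a pooled result
#'
#' @param x A `meta_pool` object.
#' @param ... Unused.
#' @return A tibble with one row per study: `study_id`, `estimate` (odds
#'   ratio), `conf.low`, `conf.high`, `log_or`, `std.error` and `weight`
#'   (normalized pooling weight, in percent, under the effect model used).
#' @method tidy meta_pool
#' @export
tidy.meta_pool <- function(x, ...) {
  eff <- x$per_study
  w <- if (x$effect_model == "random_DL") {
    1 / (eff$se^2 + x$heterogeneity$tau2)
  } else {
    1 / eff$se^2
  }
  tibble(
    study_id = eff$study_id,
    estimate = eff$or,
    conf.low = eff$ci_low,
    conf.high = eff$ci_high,
    log_or = eff$log_or,
    std.error = eff$se,
    weight = 100 * w / sum(w)
  )
}

#' One-row summary of a pooled result
#'
#' @param x A `meta_pool` object.
#' @param ... Unused.
#' @return A one-row tibble: `model`, `effect_model`, `k`, `estimate` (pooled
#'   OR), `conf.low`, `conf.high`, `statistic` (Z), `p.value`, and the
#'   heterogeneity summaries `q`, `q.p.value`, `i2`, `tau2`.
#' @method glance meta_pool
#' @export
glance.meta_pool <- function(x, ...) {
  tibble(
    model = x$model,
    effect_model = x$effect_model,
    k = x$k,
    estimate = x$or,
    conf.low = x$ci_low,
    conf.high = x$ci_high,
    statistic = x$z,
    p.value = x$p_value,
    q = x$heterogeneity$q,
    q.p.value = x$heterogeneity$p_value,
    i2 = x$heterogeneity$i2,
    tau2 = x$heterogeneity$tau2
  )
}

#' Forest plot of a pooled result
#'
#' @param object A `meta_pool` object.
#' @param ... Unused.
#' @return A ggplot: per-study odds ratios with 95% CIs (point size
#'   proportional to pooling weight) and the pooled estimate underneath.
#' @method autoplot meta_pool
#' @export
autoplot.meta_pool <- function(object, ...) {
  per <- tidy(object)
  pooled <- tibble(
    study_id = sprintf("Pooled (%s)",
                       if (object$effect_model == "fixed_MH") "MH fixed" else "DL random"),
    estimate = object$or, conf.low = object$ci_low, conf.high = object$ci_high,
    weight = NA_real_, pooled = TRUE
  )
  per$pooled <- FALSE
  dat <- bind_rows(per[names(pooled)], pooled)
  dat$study_id <- factor(dat$study_id, levels = rev(dat$study_id))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$estimate, y = .data$study_id)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$conf.low, xmax = .data$conf.high), height = 0.2
    ) +
    ggplot2::geom_point(ggplot2::aes(size = .data$weight, shape = .data$pooled),
                        show.legend = FALSE) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 15, `TRUE` = 18)) +
    ggplot2::labs(x = "Odds ratio (log scale)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.meta_pool
#' @param pool A `meta_pool` object.
#' @export
plot_forest <- function(pool, ...) {
  autoplot.meta_pool(pool, ...)
}
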