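stratum_factors <- c("total", "ethnicity", "source_of_control", "amd_type", "genotyping")

display_levels <- list(
  ethnicity = c("Asian", "Caucasian"),
  source_of_control = c("HB", "PB"),
  amd_type = c("neovascular", "geographic_atrophy"),
  genotyping = c("Sequencing", "TaqMan", "MALDI-TOF MS", "Mixed methods", "PCR-RFLP")
)

#' Define an analysis plan
#'
#' Bundles the knobs of a full meta-analysis run: which SNP to analyze,
#' which strata to pool, which genetic models to test, the Q-test threshold
#' that switches between fixed and random effects, and the significance
#' level.
#'
#' @param snp Optional SNP id; when set, [run_analysis()] keeps only matching
#'   rows of its input.
#' @param strata Either `"all"` (the default: total plus every observed level
#'   of ethnicity, source of control, AMD type and genotyping method),
#'   `"total"` (no subgroups), or a data frame with columns `factor` and
#'   `level`.
#' @param models Genetic models to test, a subset of [genetic_models()].
#' @param q_threshold Q-test p-value above which Mantel-Haenszel fixed
#'   effects are used (otherwise DerSimonian-Laird random effects).
#' @param alpha Two-sided significance level for Z tests, bias tests and the
#'   leave-one-out influence flag.
#' @return An `analysis_plan` list.
#' @export
analysis_plan <- function(snp = NULL, strata = "all", models = genetic_models(),
                          q_threshold = 0.10, alpha = 0.05) {
  if (!(q_threshold > 0 && q_threshold < 1)) {
    abort("`q_threshold` must be in (0, 1)")
  }
  models <- match.arg(models, genetic_models(), several.ok = TRUE)
  if (is.data.frame(strata)) {
    if (!all(c("factor", "level") %in% names(strata))) {
      abort("`strata` data frame needs `factor` and `level` columns")
    }
    bad <- setdiff(unique(strata$factor), stratum_factors)
    if (length(bad) > 0) {
      abort(sprintf("unknown stratum factor: %s", bad[1]))
    }
  } else {
    strata <- match.arg(strata, c("all", "total"))
  }
  structure(
    list(snp = snp, strata = strata, models = models,
         q_threshold = q_threshold, alpha = alpha),
    class = "analysis_plan"
  )
}

resolve_strata <- function(plan, studies, amd_type_studies) {
  if (is.data.frame(plan$strata)) {
    return(as_tibble(plan$strata[c("factor", "level")]))
  }
  out <- tibble(factor = "total", level = "total")
  if (identical(plan$strata, "total")) {
    return(out)
  }
  for (fct in c("ethnicity", "source_of_control")) {
    lev <- intersect(display_levels[[fct]], unique(studies[[fct]]))
    out <- bind_rows(out, tibble(factor = fct, level = lev))
  }
  type_src <- if (is.null(amd_type_studies)) studies else amd_type_studies
  lev <- intersect(display_levels$amd_type, unique(type_src$amd_type))
  out <- bind_rows(out, tibble(factor = "amd_type", level = lev))
  lev <- intersect(display_levels$genotyping, unique(studies$genotyping))
  bind_rows(out, tibble(factor = "genotyping", level = lev))
}

#' Run the full meta-analysis pipeline
#'
#' For every stratum and genetic model in the plan, pools the studies with
#' [select_and_pool()] (strata with a single study are reported unpooled,
#' carrying that study's own effect); screens control groups for HWE; runs
#' Egger and Begg publication-bias tests for each model on the full study
#' set; and performs leave-one-out sensitivity analysis on the primary
#' (allele) model.
#'
#' AMD-type strata are drawn from `amd_type_studies` when supplied: disease
#' subtypes are typically reported as separate case subsets of the same
#' cohorts (so they may not be pooled together with the total-AMD rows), and
#' keeping them in a separate table preserves that structure.
#'
#' @inheritParams write_studies
#' @param plan An [analysis_plan()].
#' @param amd_type_studies Optional second study table holding the
#'   disease-subtype case subsets used for AMD-type strata.
#' @return A `meta_results` object: a list with tibbles `results` (one row
#'   per stratum x model), `bias` (one row per model), `sensitivity`
#'   (leave-one-out, allele model), `hwe` (control-group screen), the
#'   resolved `plan`, and `pools` (the underlying `meta_pool` objects, named
#'   `"<factor>:<level>:<model>"`).
#' @examples
#' res <- run_analysis(
#'   cfi_studies("rs10033900_total"),
#'   analysis_plan(snp = "rs10033900"),
#'   amd_type_studies = cfi_studies("rs10033900_by_type")
#' )
#' res$results
#' @export
run_analysis <- function(studies, plan = analysis_plan(), amd_type_studies = NULL) {
  studies <- validate_studies(studies)
  if (!is.null(amd_type_studies)) {
    amd_type_studies <- validate_studies(amd_type_studies)
  }
  if (!is.null(plan$snp)) {
    studies <- filter(studies, .data$snp == !!plan$snp)
    if (!is.null(amd_type_studies)) {
      amd_type_studies <- filter(amd_type_studies, .data$snp == !!plan$snp)
    }
  }
  if (nrow(studies) == 0) {
    abort("no studies to analyze")
  }
  strata <- resolve_strata(plan, studies, amd_type_studies)

  pick <- function(fct, lev) {
    if (fct == "total") {
      return(studies)
    }
    src <- if (fct == "amd_type" && !is.null(amd_type_studies)) {
      amd_type_studies
    } else {
      studies
    }
    filter(src, .data[[fct]] == lev)
  }

  pools <- list()
  rows <- list()
  for (i in seq_len(nrow(strata))) {
    fct <- strata$factor[i]
    lev <- strata$level[i]
    sub <- pick(fct, lev)
    if (nrow(sub) == 0) {
      abort(sprintf("stratum %s = %s selects no studies", fct, lev))
    }
    sizes <- total_sample_sizes(sub)
    for (m in plan$models) {
      ct <- build_contrasts(sub, m)
      if (nrow(sub) >= 2) {
        pool <- select_and_pool(ct, q_threshold = plan$q_threshold)
        pools[[paste(fct, lev, m, sep = ":")]] <- pool
        row <- glance(pool)
      } else {
        eff <- study_effects(ct)
        row <- tibble(
          model = m, effect_model = "not_pooled", k = 1L,
          estimate = eff$or, conf.low = eff$ci_low, conf.high = eff$ci_high,
          statistic = eff$log_or / eff$se,
          p.value = 2 * pnorm(-abs(eff$log_or / eff$se)),
          q = NA_real_, q.p.value = NA_real_, i2 = NA_real_, tau2 = NA_real_
        )
      }
      rows[[length(rows) + 1L]] <- tibble(
        stratum_factor = fct, stratum_level = lev,
        k = row$k, n_cases = sizes$n_cases, n_controls = sizes$n_controls,
        model = m, effect_model = row$effect_model,
        or = row$estimate, ci_low = row$conf.low, ci_high = row$conf.high,
        z = row$statistic, p_value = row$p.value,
        q_p = row$q.p.value, i2 = row$i2, tau2 = row$tau2
      )
    }
  }

  full_effects <- lapply(
    setNames(plan$models, plan$models),
    function(m) study_effects(build_contrasts(studies, m))
  )
  bias <- bind_rows(lapply(plan$models, function(m) {
    eff <- full_effects[[m]]
    if (nrow(eff) >= 3) {
      eg <- egger_test(eff)
      bg <- begg_test(eff)
      tibble(
        model = m, k = eg$k,
        egger_intercept = eg$intercept, egger_se = eg$se,
        egger_t = eg$statistic, egger_p = eg$p_value,
        egger_ci_low = eg$ci_low, egger_ci_high = eg$ci_high,
        begg_s = bg$s, begg_z = bg$statistic, begg_p = bg$p_value
      )
    } else {
      tibble(model = m, k = nrow(eff))
    }
  }))
  sensitivity <- if ("allele" %in% plan$models && nrow(studies) >= 3) {
    leave_one_out(build_contrasts(studies, "allele"),
                  q_threshold = plan$q_threshold, alpha = plan$alpha)
  } else {
    tibble()
  }

  structure(
    list(
      results = bind_rows(rows),
      bias = bias,
      sensitivity = sensitivity,
      hwe = hwe_screen(studies, alpha = plan$alpha),
      plan = plan,
      pools = pools
    ),
    class = "meta_results"
  )
}

#' @export
print.meta_results <- function(x, ...) {
  cat(sprintf("Meta-analysis of %d strata x %d genetic models\n",
              length(unique(paste(x$results$stratum_factor, x$results$stratum_level))),
              length(unique(x$results$model))))
  print(x$results, n = Inf)
  invisible(x)
}

fmt_or_ci <- function(or, lo, hi) {
  ifelse(is.na(or), "—",
         sprintf("%.2f (%.2f-%.2f)", or, lo, hi))
}

fmt_p <- function(p) {
  ifelse(is.na(p), "—", sprintf("%.3f", p))
}

rounded_results <- function(results) {
  dplyr::mutate(
    results,
    dplyr::across(c("or", "ci_low", "ci_high"), ~ round(.x, 2)),
    dplyr::across(c("p_value", "q_p"), ~ round(.x, 3)),
    dplyr::across(c("z", "i2", "tau2"), ~ round(.x, 4))
  )
}

#' Render a results table as CSV, JSON or markdown
#'
#' Deterministic, presentation-ready serialization of a [run_analysis()]
#' result. Odds ratios and CI bounds are rounded to 2 decimals and p-values
#' to 3 (values below 0.0005 therefore print as `0.000`); unpooled cells
#' render as an em dash in markdown.
#'
#' @param results A `meta_results` object.
#' @param format One of `"markdown"`, `"csv"`, `"json"`.
#' @return A single character string holding the document.
#' @export
render_report <- function(results, format = c("markdown", "csv", "json")) {
  if (!inherits(results, "meta_results")) {
    abort("`results` must come from run_analysis()")
  }
  format <- match.arg(format)
  res <- rounded_results(results$results)
  if (format == "csv") {
    return(readr::format_csv(res))
  }
  if (format == "json") {
    payload <- list(
      results = res,
      bias = dplyr::mutate(results$bias,
                           dplyr::across(dplyr::where(is.numeric), ~ round(.x, 4))),
      sensitivity = if (nrow(results$sensitivity) > 0) {
        dplyr::mutate(results$sensitivity,
                      dplyr::across(dplyr::where(is.double), ~ round(.x, 4)))
      } else {
        results$sensitivity
      },
      hwe = dplyr::mutate(results$hwe,
                          dplyr::across(dplyr::where(is.double), ~ round(.x, 4))),
      config = list(
        snp = results$plan$snp,
        models = results$plan$models,
        q_threshold = results$plan$q_threshold,
        alpha = results$plan$alpha
      )
    )
    return(as.character(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                                         null = "null")))
  }
  wide <- res %>%
    mutate(
      cell = paste0(fmt_or_ci(.data$or, .data$ci_low, .data$ci_high),
                    " Ph=", fmt_p(.data$q_p), " P=", fmt_p(.data$p_value)),
      stratum = paste0(.data$stratum_factor, ": ", .data$stratum_level)
    ) %>%
    select("stratum", "k", "n_cases", "n_controls", "model", "cell") %>%
    tidyr::pivot_wider(names_from = "model", values_from = "cell")
  header <- paste0("| ", paste(names(wide), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(wide)), collapse = "|"), "|")
  body <- apply(wide, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  paste(c(header, sep, body), collapse = "\n")
}

#' Reproduce the bundled CFI/AMD analysis end to end
#'
#' Runs the full pipeline on the bundled study tables: all strata and all
#' five genetic models for rs10033900 (with AMD-type strata from the
#' disease-subtype table), and the total-only analysis for rs2285714 (its
#' three studies are too few to split into subgroups).
#'
#' @return A named list of two `meta_results` objects, `rs10033900` and
#'   `rs2285714`.
#' @examples
#' rep <- reproduce_cfi()
#' dplyr::filter(rep$rs10033900$results, stratum_factor == "total")
#' @export
reproduce_cfi <- function() {
  list(
    rs10033900 = run_analysis(
      cfi_studies("rs10033900_total"),
      analysis_plan(snp = "rs10033900"),
      amd_type_studies = cfi_studies("rs10033900_by_type")
    ),
    rs2285714 = run_analysis(
      cfi_studies("rs2285714"),
      analysis_plan(snp = "rs2285714", strata = "total")
    )
  )
}
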