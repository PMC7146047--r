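#' Pearson chi-square test of Hardy-Weinberg equilibrium
#'
#' Compares observed genotype counts with the proportions `p^2 : 2pq : q^2`
#' expected under Hardy-Weinberg equilibrium (HWE) at the observed allele
#' frequency. The statistic is referred to a chi-square distribution with one
#' degree of freedom (one allele frequency is estimated from the data); no
#' continuity correction is applied. Vectorized over its arguments.
#'
#' @inheritParams allele_frequency
#' @return A tibble with one row per input group: `chi2`, `df` (always 1),
#'   `p_value` and `maf` (observed mutant-allele frequency).
#' @examples
#' hwe_test(25, 50, 25)       # exact HWE proportions: chi2 = 0, p = 1
#' hwe_test(35, 138, 126)     # p ~ 0.764
#' @export
hwe_test <- function(hom_mut, het, hom_wt) {
  n <- hom_mut + het + hom_wt
  if (any(n < 1)) {
    abort("HWE test undefined for an empty genotype group")
  }
  p <- (2 * hom_mut + het) / (2 * n)
  if (any(p == 0 | p == 1)) {
    abort("HWE undefined: genotype group is monomorphic")
  }
  q <- 1 - p
  exp_mut <- n * p^2
  exp_het <- n * 2 * p * q
  exp_wt <- n * q^2
  chi2 <- (hom_mut - exp_mut)^2 / exp_mut +
    (het - exp_het)^2 / exp_het +
    (hom_wt - exp_wt)^2 / exp_wt
  tibble(
    chi2 = chi2,
    df = 1L,
    p_value = pchisq(chi2, df = 1, lower.tail = FALSE),
    maf = pmin(p, q)
  )
}

#' Screen control groups of a study table for HWE
#'
#' Runs [hwe_test()] on every study's control (by default) genotype counts
#' and flags departures at level `alpha`. Studies whose controls violate HWE
#' can optionally be dropped before pooling via `exclude_violations`.
#'
#' @inheritParams write_studies
#' @param group `"control"` (conventional) or `"case"`.
#' @param alpha Significance level for flagging a departure.
#' @return A tibble with `study_id`, `chi2`, `p_value`, `maf` and the logical
#'   `hwe_violation`.
#' @examples
#' hwe_screen(cfi_studies("rs10033900_total"))
#' @export
hwe_screen <- function(studies, group = c("control", "case"), alpha = 0.05) {
  studies <- validate_studies(studies)
  group <- match.arg(group)
  counts <- if (group == "control") {
    list(studies$ctrl_cc, studies$ctrl_ct, studies$ctrl_tt)
  } else {
    list(studies$case_cc, studies$case_ct, studies$case_tt)
  }
  res <- hwe_test(counts[[1]], counts[[2]], counts[[3]])
  tibble(
    study_id = studies$study_id,
    chi2 = res$chi2,
    p_value = res$p_value,
    maf = res$maf,
    hwe_violation = res$p_value < alpha
  )
}

#' Drop studies whose controls violate HWE
#'
#' @inheritParams hwe_screen
#' @return The study table restricted to studies whose control groups are
#'   consistent with HWE at level `alpha`.
#' @export
filter_hwe <- function(studies, alpha = 0.05) {
  screen <- hwe_screen(studies, alpha = alpha)
  keep <- screen$study_id[!screen$hwe_violation]
  filter(validate_studies(studies), .data$study_id %in% keep)
}
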