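#' The five classical genetic-model contrasts
#'
#' Returns the names of the five 2x2 contrasts derivable from case-control
#' genotype counts when C is the mutant and T the wild-type allele:
#'
#' * `allele`: C vs T allele counts (each subject contributes two alleles),
#' * `heterozygote`: CT vs TT (CC carriers excluded),
#' * `dominant`: CC+CT vs TT,
#' * `homozygote`: CC vs TT (CT carriers excluded),
#' * `recessive`: CC vs CT+TT.
#'
#' In every model the exposure is the mutant-bearing category, so a pooled
#' odds ratio below 1 reads as a protective C allele (or CC genotype).
#'
#' @return A character vector of length five.
#' @export
genetic_models <- function() {
  c("allele", "heterozygote", "dominant", "homozygote", "recessive")
}

model_labels <- c(
  allele = "C-allele vs. T-allele",
  heterozygote = "CT vs. TT",
  dominant = "CC+CT vs. TT",
  homozygote = "CC vs. TT",
  recessive = "CC vs. CT+TT"
)

#' Build 2x2 contrast tables under a genetic model
#'
#' Collapses each study's genotype counts into the exposure-by-status 2x2
#' table of the requested genetic model(s). Cells follow the epidemiological
#' convention `a` = exposed cases, `b` = unexposed cases, `c` = exposed
#' controls, `d` = unexposed controls. The heterozygote and homozygote models
#' are conditional contrasts: the excluded genotype is dropped from the table
#' entirely. Zero cells are retained; downstream effect estimation applies
#' the continuity correction.
#'
#' @inheritParams write_studies
#' @param model One or more of [genetic_models()].
#' @return A tibble with columns `study_id`, `model`, `a`, `b`, `c`, `d`,
#'   one row per study per model.
#' @examples
#' build_contrasts(cfi_studies("rs10033900_total"), "allele")
#' @export
build_contrasts <- function(studies, model = genetic_models()) {
  studies <- validate_studies(studies)
  model <- match.arg(model, genetic_models(), several.ok = TRUE)
  one <- function(m) {
    cells <- switch(m,
      allele = list(
        a = 2L * studies$case_cc + studies$case_ct,
        b = 2L * studies$case_tt + studies$case_ct,
        c = 2L * studies$ctrl_cc + studies$ctrl_ct,
        d = 2L * studies$ctrl_tt + studies$ctrl_ct
      ),
      heterozygote = list(
        a = studies$case_ct, b = studies$case_tt,
        c = studies$ctrl_ct, d = studies$ctrl_tt
      ),
      dominant = list(
        a = studies$case_cc + studies$case_ct, b = studies$case_tt,
        c = studies$ctrl_cc + studies$ctrl_ct, d = studies$ctrl_tt
      ),
      homozygote = list(
        a = studies$case_cc, b = studies$case_tt,
        c = studies$ctrl_cc, d = studies$ctrl_tt
      ),
      recessive = list(
        a = studies$case_cc, b = studies$case_ct + studies$case_tt,
        c = studies$ctrl_cc, d = studies$ctrl_ct + studies$ctrl_tt
      )
    )
    tibble(study_id = studies$study_id, model = m, !!!cells)
  }
  bind_rows(lapply(model, one))
}
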