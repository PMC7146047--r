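#' Simulate one case-control study's genotype counts
#'
#' Control genotypes are drawn multinomially from Hardy-Weinberg proportions
#' at the control mutant-allele frequency `maf` (optionally distorted by an
#' inbreeding coefficient `f`, which shifts probability from heterozygotes
#' to both homozygotes: `p^2 + f p q`, `2 p q (1 - f)`, `q^2 + f p q`). The
#' case allele frequency is implied by the allelic odds ratio,
#' `odds_case = odds_control * or_study`, and case genotypes are drawn under
#' HWE at that frequency (a multiplicative allelic risk model, under which
#' all five genetic-model contrasts follow deterministically).
#'
#' @param maf Control mutant-allele frequency, in (0, 1).
#' @param or_study The study's allelic odds ratio.
#' @param n_case,n_control Subjects per group.
#' @param f Inbreeding-style HWE distortion of the controls (0 = HWE).
#' @param study_id Identifier for the generated row.
#' @return A one-row study tibble in the [read_studies()] layout.
#' @export
simulate_study <- function(maf, or_study, n_case, n_control, f = 0,
                           study_id = "sim_001") {
  if (maf <= 0 || maf >= 1) {
    abort("`maf` must be in (0, 1)")
  }
  if (or_study <= 0) {
    abort("`or_study` must be positive")
  }
  p <- maf
  q <- 1 - p
  ctrl_probs <- c(p^2 + f * p * q, 2 * p * q * (1 - f), q^2 + f * p * q)
  if (any(ctrl_probs < 0)) {
    abort("invalid control genotype probabilities (check `f`)")
  }
  odds_case <- p / q * or_study
  p_case <- odds_case / (1 + odds_case)
  case_probs <- c(p_case^2, 2 * p_case * (1 - p_case), (1 - p_case)^2)
  cases <- as.integer(rmultinom(1, n_case, case_probs))
  ctrls <- as.integer(rmultinom(1, n_control, ctrl_probs))
  tibble(
    study_id = study_id, snp = "simulated", year = 2020L,
    country = "Simulated", ethnicity = "Caucasian", amd_type = "AMD",
    source_of_control = "PB", genotyping = "TaqMan",
    case_cc = cases[1], case_ct = cases[2], case_tt = cases[3],
    ctrl_cc = ctrls[1], ctrl_ct = ctrls[2], ctrl_tt = ctrls[3]
  )
}

#' Simulate a set of case-control studies for meta-analysis
#'
#' Generates `k` studies whose log odds ratios are drawn from
#' `Normal(log(true_or), tau2)` and whose genotype counts follow
#' [simulate_study()]. A fraction `hwe_violation_rate` of studies has its
#' control group perturbed away from HWE (inbreeding coefficient 0.5).
#'
#' The defaults mirror the bundled 12-study rs10033900 data set: its pooled
#' control C-allele frequency (0.43), its headline allele-model random-effects
#' estimates (OR 0.87, tau2 0.032) and its observed study-size ranges.
#'
#' @param k Number of studies.
#' @param maf Control mutant-allele frequency.
#' @param true_or True allelic odds ratio (the mean of the random-effects
#'   distribution on the log scale).
#' @param tau2 Between-study variance of the log odds ratio.
#' @param n_case_range,n_control_range Integer ranges (length 2) from which
#'   group sizes are drawn uniformly.
#' @param hwe_violation_rate Fraction of studies whose controls violate HWE.
#' @param seed Optional integer seed; with a fixed seed the output is fully
#'   reproducible.
#' @return A validated study tibble with `k` rows, compatible with every
#'   other function in the package (and with [write_studies()]).
#' @examples
#' sim <- simulate_meta(k = 5, seed = 1)
#' glance(select_and_pool(build_contrasts(sim, "allele")))
#' @export
simulate_meta <- function(k = 12, maf = 0.43, true_or = 0.87, tau2 = 0.032,
                          n_case_range = c(100, 1100),
                          n_control_range = c(55, 1260),
                          hwe_violation_rate = 0, seed = NULL) {
  if (k < 1) {
    abort("`k` must be at least 1")
  }
  if (tau2 < 0) {
    abort("`tau2` must be non-negative")
  }
  if (hwe_violation_rate < 0 || hwe_violation_rate > 1) {
    abort("`hwe_violation_rate` must be in [0, 1]")
  }
  check_range <- function(r, nm) {
    if (length(r) != 2 || r[1] > r[2] || r[1] < 1) {
      abort(sprintf("`%s` must be a non-empty positive integer range", nm))
    }
  }
  check_range(n_case_range, "n_case_range")
  check_range(n_control_range, "n_control_range")
  if (!is.null(seed)) {
    set.seed(seed)
  }
  log_ors <- rnorm(k, mean = log(true_or), sd = sqrt(tau2))
  # guard against sample()'s 1:n behaviour when a range collapses to one value
  draw_n <- function(r) {
    grid <- seq.int(r[1], r[2])
    grid[sample.int(length(grid), k, replace = TRUE)]
  }
  n_cases <- draw_n(n_case_range)
  n_ctrls <- draw_n(n_control_range)
  violate <- runif(k) < hwe_violation_rate
  rows <- lapply(seq_len(k), function(i) {
    simulate_study(
      maf = maf, or_study = exp(log_ors[i]),
      n_case = n_cases[i], n_control = n_ctrls[i],
      f = if (violate[i]) 0.5 else 0,
      study_id = sprintf("sim_%03d", i)
    )
  })
  validate_studies(bind_rows(rows))
}
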