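#' @keywords internal
study_columns <- c(
  "study_id", "snp", "year", "country", "ethnicity", "amd_type",
  "source_of_control", "genotyping",
  "case_cc", "case_ct", "case_tt", "ctrl_cc", "ctrl_ct", "ctrl_tt"
)

count_columns <- c("case_cc", "case_ct", "case_tt", "ctrl_cc", "ctrl_ct", "ctrl_tt")

ethnicity_levels <- c("Asian", "Caucasian")
amd_type_levels <- c("AMD", "advanced_AMD", "neovascular", "geographic_atrophy")
soc_levels <- c("PB", "HB")
genotyping_levels <- c("MALDI-TOF MS", "Mixed methods", "PCR-RFLP", "Sequencing", "TaqMan")

#' Read a study-level genotype-count table
#'
#' Reads a CSV of case-control genotype counts, one study per row, and
#' validates it. The expected columns are `study_id`, `snp`, `year`,
#' `country`, `ethnicity` (`Asian`/`Caucasian`), `amd_type`,
#' `source_of_control` (`PB`/`HB`), `genotyping`, and the six genotype counts
#' `case_cc`, `case_ct`, `case_tt`, `ctrl_cc`, `ctrl_ct`, `ctrl_tt`. The
#' `cc` column counts mutant homozygotes (the C allele is the mutant allele
#' for both CFI SNPs shipped with the package), `tt` counts wild-type
#' homozygotes.
#'
#' @param path Path to a CSV file.
#' @param snp Optional SNP identifier (e.g. `"rs10033900"`); when given, only
#'   rows for that SNP are returned.
#' @return A tibble with one validated row per study, in file order.
#' @examples
#' studies <- cfi_studies("rs10033900_total")
#' tmp <- tempfile(fileext = ".csv")
#' write_studies(studies, tmp)
#' identical(read_studies(tmp), studies)
#' @seealso [cfi_studies()] for the bundled data, [write_studies()] for the
#'   inverse operation.
#' @export
read_studies <- function(path, snp = NULL) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path))
  }
  studies <- readr::read_csv(
    path,
    col_types = readr::cols(
      year = readr::col_integer(),
      case_cc = readr::col_integer(), case_ct = readr::col_integer(),
      case_tt = readr::col_integer(), ctrl_cc = readr::col_integer(),
      ctrl_ct = readr::col_integer(), ctrl_tt = readr::col_integer(),
      .default = readr::col_character()
    ),
    progress = FALSE, show_col_types = FALSE
  )
  prob <- readr::problems(studies)
  if (nrow(prob) > 0) {
    abort(sprintf(
      "malformed value in row %d, column %d of %s (expected %s, got %s)",
      prob$row[1], prob$col[1], basename(path), prob$expected[1], prob$actual[1]
    ))
  }
  studies <- validate_studies(studies)
  if (!is.null(snp)) {
    studies <- filter(studies, .data$snp == !!snp)
  }
  studies
}

#' Write a study table to CSV
#'
#' Serializes a validated study table in the same dialect [read_studies()]
#' consumes, so that a write/read round trip is the identity.
#'
#' @param studies A study table, as from [read_studies()] or [simulate_meta()].
#' @param path Output file path.
#' @return `studies`, invisibly.
#' @export
write_studies <- function(studies, path) {
  studies <- validate_studies(studies)
  readr::write_csv(studies, path, progress = FALSE)
  invisible(studies)
}

#' Validate a study table
#'
#' Checks the column set, genotype-count integrity (non-negative integers,
#' at least one subject per group) and the categorical metadata levels.
#' Called internally by every consumer; exported because simulated or
#' hand-built tables can be checked directly.
#'
#' @inheritParams write_studies
#' @return The validated table as a tibble, with counts stored as integers.
#' @export
validate_studies <- function(studies) {
  if (!is.data.frame(studies)) {
    abort("`studies` must be a data frame")
  }
  missing_cols <- setdiff(study_columns, names(studies))
  if (length(missing_cols) > 0) {
    abort(paste0("missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  studies <- as_tibble(studies)[study_columns]
  for (col in count_columns) {
    x <- studies[[col]]
    if (!is.numeric(x) || anyNA(x) || any(x != floor(x))) {
      bad <- which(!is.finite(studies[[col]]) | studies[[col]] != floor(studies[[col]]))[1]
      abort(sprintf("column %s, row %s: genotype counts must be integers", col, bad))
    }
    if (any(x < 0)) {
      abort(sprintf("column %s, row %d: negative genotype count", col, which(x < 0)[1]))
    }
    studies[[col]] <- as.integer(x)
  }
  if (nrow(studies) > 0) {
    n_case <- studies$case_cc + studies$case_ct + studies$case_tt
    n_ctrl <- studies$ctrl_cc + studies$ctrl_ct + studies$ctrl_tt
    if (any(n_case < 1) || any(n_ctrl < 1)) {
      abort("every study needs at least one case and one control")
    }
    if (anyDuplicated(studies$study_id)) {
      dup <- studies$study_id[duplicated(studies$study_id)][1]
      abort(sprintf("duplicated study_id: %s", dup))
    }
    check_levels <- function(col, levels) {
      bad <- setdiff(unique(studies[[col]]), levels)
      if (length(bad) > 0) {
        abort(sprintf("unknown %s value: %s", col, bad[1]))
      }
    }
    check_levels("ethnicity", ethnicity_levels)
    check_levels("amd_type", amd_type_levels)
    check_levels("source_of_control", soc_levels)
    check_levels("genotyping", genotyping_levels)
  }
  studies
}

#' Bundled CFI polymorphism case-control data
#'
#' Study-level genotype counts for the two complement factor I (CFI) SNPs
#' rs10033900 and rs2285714 and age-related macular degeneration (AMD),
#' assembled from the primary case-control literature. Three sets are
#' available:
#'
#' * `"rs10033900_total"`: 12 case-control studies of total AMD
#'   (4131 cases / 3798 controls),
#' * `"rs10033900_by_type"`: the same cohorts split into 7 neovascular and 4
#'   geographic-atrophy case subsets against the shared controls (11 rows),
#' * `"rs2285714"`: 3 case-control studies (650 cases / 535 controls).
#'
#' For both SNPs the wild-type allele is T and the mutant allele is C, so the
#' `cc` count columns hold mutant homozygotes and odds ratios below 1 indicate
#' a protective C allele.
#'
#' @param set Which study set to load.
#' @return A validated study tibble (see [read_studies()] for the columns).
#' @examples
#' cfi_studies("rs2285714")
#' @export
cfi_studies <- function(set = c("rs10033900_total", "rs10033900_by_type", "rs2285714")) {
  set <- match.arg(set)
  path <- system.file("extdata", paste0(set, ".csv"), package = "snpmeta", mustWork = TRUE)
  read_studies(path)
}

#' Total case and control sample sizes
#'
#' @inheritParams write_studies
#' @return A one-row tibble with `k` (number of studies), `n_cases` and
#'   `n_controls`.
#' @examples
#' total_sample_sizes(cfi_studies("rs10033900_total"))
#' @export
total_sample_sizes <- function(studies) {
  studies <- validate_studies(studies)
  if (nrow(studies) == 0) {
    abort("`studies` is empty")
  }
  tibble(
    k = nrow(studies),
    n_cases = sum(studies$case_cc + studies$case_ct + studies$case_tt),
    n_controls = sum(studies$ctrl_cc + studies$ctrl_ct + studies$ctrl_tt)
  )
}

#' Mutant-allele frequency from genotype counts
#'
#' Frequency of the mutant (C) allele, `(2 * hom_mut + het) / (2 * n)`.
#' Vectorized over its arguments.
#'
#' @param hom_mut,het,hom_wt Counts of mutant homozygotes, heterozygotes and
#'   wild-type homozygotes.
#' @return A numeric vector of frequencies in `[0, 1]`.
#' @examples
#' allele_frequency(25, 50, 25)   # 0.5
#' @export
allele_frequency <- function(hom_mut, het, hom_wt) {
  n <- hom_mut + het + hom_wt
  if (any(n < 1)) {
    abort("allele frequency undefined for an empty genotype group")
  }
  (2 * hom_mut + het) / (2 * n)
}

#' Per-study case and control allele frequencies
#'
#' @inheritParams write_studies
#' @return A tibble with `study_id`, `ethnicity`, `case_freq` and
#'   `control_freq` (mutant-allele frequencies).
#' @export
allele_frequencies <- function(studies) {
  studies <- validate_studies(studies)
  tibble(
    study_id = studies$study_id,
    ethnicity = studies$ethnicity,
    case_freq = allele_frequency(studies$case_cc, studies$case_ct, studies$case_tt),
    control_freq = allele_frequency(studies$ctrl_cc, studies$ctrl_ct, studies$ctrl_tt)
  )
}
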