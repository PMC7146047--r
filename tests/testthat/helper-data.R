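# Small builders used across test files.

make_effects <- function(log_or, se, ids = sprintf("s%02d", seq_along(log_or))) {
  tibble::tibble(study_id = ids, log_or = log_or, se = se)
}

# A hand-written two-study table with easy round numbers.
tiny_studies <- function() {
  tibble::tibble(
    study_id = c("toy_A", "toy_B"),
    snp = "rs0",
    year = c(2001L, 2002L),
    country = "Nowhere",
    ethnicity = c("Asian", "Caucasian"),
    amd_type = "AMD",
    source_of_control = c("HB", "PB"),
    genotyping = "TaqMan",
    case_cc = c(25L, 10L), case_ct = c(50L, 20L), case_tt = c(25L, 30L),
    ctrl_cc = c(25L, 15L), ctrl_ct = c(50L, 30L), ctrl_tt = c(25L, 15L)
  )
}

# The control-group HWE p-values as published alongside the study table,
# keyed by study_id (rs10033900 total-AMD set).
published_hwe <- c(
  Yang_2014 = 0.764, Seddon_2010 = 0.852, Reynolds_2009 = 0.561,
  Cipriani_2012a = 0.843, Cipriani_2012b = 0.273, Wu_2013 = 0.997,
  Smailhodzic_2012 = 0.175, Aygun_2019 = 0.151, Qian_2014 = 0.063,
  Kondo_2010 = 0.459, Peter_2011 = 0.751, Yu_2011 = 0.998
)
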