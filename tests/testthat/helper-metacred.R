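# Small catalogue builders used across the test files.

make_record <- function(variant = "rs0001", comparison = "A vs. G",
                        odds_ratio = 1.25, ci_lower = 1.10, ci_upper = 1.42,
                        p_value = 0.001, study_type = "observational",
                        ethnicity = "Overall", subtype = "overall",
                        year = 2019, n_cases = 1000, n_controls = 1000, ...) {
  tibble::tibble(author = "Doe J", year = year, gene = "GENE",
                 variant = variant, comparison = comparison,
                 odds_ratio = odds_ratio, ci_lower = ci_lower,
                 ci_upper = ci_upper, p_value = p_value,
                 study_type = study_type, ethnicity = ethnicity,
                 subtype = subtype, n_cases = n_cases,
                 n_controls = n_controls, ...)
}

# Migraine-without-aura block of the observational subtype table
# (MTHFR/rs1801131, 5-HTT/VNTR, ACE/rs1799752) with the printed
# FPRP(OR 1.2) values at prior 0.05 — all above the 0.2 cut-off.
mo_subgroup_block <- function() {
  dplyr::bind_rows(
    make_record("rs1801131", "C vs. A", 1.43, 1.06, 1.92, 0.018,
                subtype = "MO", year = 2019,
                n_cases = 159, n_controls = 1477,
                `fprp_or1.2_0.05` = 0.730),
    make_record("rs1801131", "CC vs. AC + AA", 2.74, 1.46, 5.14, 0.002,
                subtype = "MO", year = 2019,
                n_cases = 159, n_controls = 1477,
                `fprp_or1.2_0.05` = 0.864),
    make_record("rs1801131", "CC vs. AA", 2.83, 1.30, 6.16, 0.009,
                subtype = "MO", year = 2019,
                n_cases = 159, n_controls = 1477,
                `fprp_or1.2_0.05` = 0.916),
    make_record("VNTR", "12/other", 1.30, 1.02, 1.67, 0.037,
                subtype = "MO", year = 2011,
                n_cases = 319, n_controls = 697,
                `fprp_or1.2_0.05` = 0.741),
    make_record("VNTR", "12/12 vs. 12/other +other", 1.55, 1.11, 2.16,
                0.010, subtype = "MO", year = 2011,
                n_cases = 319, n_controls = 697,
                `fprp_or1.2_0.05` = 0.737),
    make_record("rs1799752", "II vs. ID + DD", 0.84, 0.70, 0.99, 0.049,
                subtype = "MO", year = 2010,
                n_cases = 2853, n_controls = 22310,
                `fprp_or1.2_0.05` = 0.570))
}

# Direct-formula (non-log-space) references used as oracles for the
# numerically stable implementations.
naive_fprp <- function(p, power, prior) {
  p * (1 - prior) / (p * (1 - prior) + power * prior)
}

naive_bfdp <- function(log_or, se, prior, bound = 1.5) {
  V <- se^2
  W <- (log(bound) / qnorm(0.975))^2
  z <- log_or / se
  bf <- sqrt((V + W) / V) * exp(-z^2 * W / (2 * (V + W)))
  po <- (1 - prior) / prior
  bf * po / (bf * po + 1)
}
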