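#' Specification for a synthetic meta-analysis catalogue
#'
#' Describes the generative model behind [simulate_catalog()]: a set of
#' variants, a fraction of which carry a true allelic effect, each observed
#' through several case-control studies whose allele counts are binomial.
#' Scalar count arguments may instead be length-2 ranges `c(min, max)`
#' sampled uniformly per variant/study.
#'
#' @param n_variants Number of variants to simulate.
#' @param fraction_true Fraction of variants with a true effect, in
#'   `[0, 1]`.
#' @param true_or Either a single odds ratio (> 0) applied to every
#'   non-null variant, or a list `list(meanlog = , sdlog = )` giving a
#'   log-normal distribution on the odds ratio.
#' @param maf_range Interval in (0, 1) from which each variant's control
#'   minor allele frequency is drawn uniformly.
#' @param studies_per_variant Number of studies pooled per variant (scalar
#'   or range).
#' @param cases_per_study,controls_per_study Subjects per study (scalar or
#'   range).
#' @param study_type_label `"observational"` or `"gwas"`, stamped on the
#'   generated records.
#' @param seed Integer seed; the whole catalogue is reproducible from it.
#' @return A list of class `"simulation_spec"`.
#' @examples
#' simulation_spec(n_variants = 10, seed = 42)
#' @export
simulation_spec <- function(n_variants = 100,
                            fraction_true = 0.1,
                            true_or = 1.2,
                            maf_range = c(0.05, 0.5),
                            studies_per_variant = 5,
                            cases_per_study = 1000,
                            controls_per_study = 1000,
                            study_type_label = c("observational", "gwas"),
                            seed = 1L) {
  stopifnot(n_variants >= 1, studies_per_variant >= 1,
            all(cases_per_study >= 1), all(controls_per_study >= 1))
  check_range(fraction_true, "fraction_true", 0, 1,
              open_lower = FALSE, open_upper = FALSE)
  check_range(maf_range, "maf_range", 0, 1)
  if (is.numeric(true_or)) check_range(true_or, "true_or", 0)
  structure(
    list(n_variants = as.integer(n_variants),
         fraction_true = fraction_true,
         true_or = true_or,
         maf_range = maf_range,
         studies_per_variant = studies_per_variant,
         cases_per_study = cases_per_study,
         controls_per_study = controls_per_study,
         study_type_label = match.arg(study_type_label),
         seed = as.integer(seed)),
    class = "simulation_spec")
}

#' Simulate allele counts of one case-control study
#'
#' Control minor-allele count is Binomial(2 n_controls, maf); the case
#' minor-allele frequency follows from the odds transform
#' \deqn{f_{case} = \frac{OR\, f/(1-f)}{1 + OR\, f/(1-f)}}
#' and the case count is Binomial(2 n_cases, f_case). Allele-level (2n)
#' counting matches allelic odds-ratio comparisons. Uses the current R
#' random number generator state; seed outside (or via
#' [simulate_catalog()]) for reproducibility.
#'
#' @param maf Control minor allele frequency in (0, 1).
#' @param true_or True allelic odds ratio (> 0).
#' @param n_cases,n_controls Subjects per arm.
#' @return A one-row tibble with `case_minor`, `case_major`,
#'   `control_minor`, `control_major`.
#' @examples
#' withr::with_seed(1, simulate_study(0.3, 1.5, 500, 500))
#' @export
simulate_study <- function(maf, true_or, n_cases, n_controls) {
  check_range(maf, "maf", 0, 1)
  check_range(true_or, "true_or", 0)
  odds_case <- true_or * maf / (1 - maf)
  f_case <- odds_case / (1 + odds_case)
  case_minor <- rbinom(1L, 2L * n_cases, f_case)
  control_minor <- rbinom(1L, 2L * n_controls, maf)
  tibble::tibble(case_minor = case_minor,
                 case_major = 2L * n_cases - case_minor,
                 control_minor = control_minor,
                 control_major = 2L * n_controls - control_minor)
}

#' Fixed-effect inverse-variance pooling of 2x2 allele tables
#'
#' Per-study log odds ratio and Woolf standard error from each 2x2 table
#' (0.5 added to every cell of a table containing a zero, keeping the SE
#' finite), pooled with inverse-variance weights:
#' \eqn{\hat\theta = \sum w_i \theta_i / \sum w_i}, \eqn{w_i = 1/SE_i^2},
#' pooled \eqn{SE = (\sum w_i)^{-1/2}}; 95% CI and two-sided p follow via
#' [z_and_p()].
#'
#' @param studies A data frame of 2x2 tables (columns `case_minor`,
#'   `case_major`, `control_minor`, `control_major`), one row per study.
#' @return A one-row tibble shaped like a catalogue record: `odds_ratio`,
#'   `ci_lower`, `ci_upper`, `p_value`, `n_cases`, `n_controls`,
#'   `n_studies`.
#' @export
pool_fixed_effect <- function(studies) {
  studies <- tibble::as_tibble(studies)
  if (nrow(studies) == 0) stop("`studies` must be non-empty", call. = FALSE)
  m <- as.matrix(studies[, c("case_minor", "case_major",
                             "control_minor", "control_major")])
  zero <- rowSums(m == 0) > 0
  m[zero, ] <- m[zero, , drop = FALSE] + 0.5
  theta <- log(m[, "case_minor"]) - log(m[, "case_major"]) -
    log(m[, "control_minor"]) + log(m[, "control_major"])
  v <- rowSums(1 / m)
  w <- 1 / v
  pooled_theta <- sum(w * theta) / sum(w)
  pooled_se <- 1 / sqrt(sum(w))
  eff <- z_and_p(exp(pooled_theta), pooled_se)
  half <- qnorm(0.975) * pooled_se
  tibble::tibble(odds_ratio = exp(pooled_theta),
                 ci_lower = exp(pooled_theta - half),
                 ci_upper = exp(pooled_theta + half),
                 p_value = eff$p_two_sided,
                 n_cases = as.integer(round(sum(studies$case_minor +
                                                  studies$case_major) / 2)),
                 n_controls = as.integer(round(sum(studies$control_minor +
                                                     studies$control_major) / 2)),
                 n_studies = nrow(studies))
}

draw_count <- function(x, n) {
  if (length(x) == 2) sample(seq(x[1], x[2]), n, replace = TRUE)
  else rep(as.integer(x), n)
}

#' Simulate a pooled meta-analysis catalogue with known truth
#'
#' Draws `n_variants` variants per the spec — the first
#' `round(fraction_true * n_variants)` carry the spec's true odds ratio,
#' the rest are null (OR = 1) — simulates each variant's studies with
#' [simulate_study()] and pools them with [pool_fixed_effect()]. The truth
#' labels (`true_or`, `is_true`) and the generating `maf` are kept on the
#' records for operating-characteristic evaluation. Fully reproducible from
#' `spec$seed`; the caller's random number generator state is untouched.
#'
#' @param spec A [simulation_spec()].
#' @return A catalogue tibble (validating under the same rules as
#'   [read_catalog()]) with extra columns `maf`, `true_or`, `is_true`.
#' @examples
#' simulate_catalog(simulation_spec(n_variants = 5, seed = 7))
#' @export
simulate_catalog <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  withr::with_seed(spec$seed, {
    n <- spec$n_variants
    n_true <- round(spec$fraction_true * n)
    is_true <- seq_len(n) <= n_true
    true_or <- rep(1, n)
    if (n_true > 0) {
      true_or[is_true] <- if (is.list(spec$true_or)) {
        exp(stats::rnorm(n_true, spec$true_or$meanlog, spec$true_or$sdlog))
      } else {
        rep(spec$true_or, n_true)
      }
    }
    maf <- stats::runif(n, spec$maf_range[1], spec$maf_range[2])
    n_studies <- draw_count(spec$studies_per_variant, n)
    records <- purrr::map(seq_len(n), function(i) {
      studies <- purrr::map(seq_len(n_studies[i]), function(j) {
        simulate_study(maf[i], true_or[i],
                       draw_count(spec$cases_per_study, 1L),
                       draw_count(spec$controls_per_study, 1L))
      }) %>% dplyr::bind_rows()
      pool_fixed_effect(studies)
    }) %>% dplyr::bind_rows()
    out <- dplyr::bind_cols(
      tibble::tibble(variant = sprintf("sim%04d", seq_len(n)),
                     comparison = "minor vs. major",
                     study_type = spec$study_type_label,
                     subtype = "overall",
                     ethnicity = "simulated",
                     maf = maf, true_or = true_or, is_true = is_true),
      records)
    out <- as_catalog(out)
    validate_catalog(out)
    attr(out, "provenance") <- "simulation"
    out
  })
}

#' Write a simulated catalogue and its truth labels
#'
#' Writes the catalogue TSV (truth columns removed, so it round-trips
#' through [read_catalog()] like any external catalogue) next to a
#' `*_truth.tsv` with `variant`, `true_or`, `is_true`.
#'
#' @param catalog Output of [simulate_catalog()].
#' @param path Path of the catalogue TSV; the truth file replaces the
#'   extension with `_truth.tsv`.
#' @return Character vector of the two paths, invisibly.
#' @export
write_simulation <- function(catalog, path) {
  truth_path <- sub("\\.tsv$", "_truth.tsv", path)
  if (identical(truth_path, path)) truth_path <- paste0(path, "_truth.tsv")
  write_catalog(dplyr::select(catalog, -"true_or", -"is_true"), path)
  readr::write_tsv(dplyr::select(as_catalog(catalog), "variant", "true_or",
                                 "is_true"), truth_path)
  invisible(c(path, truth_path))
}
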