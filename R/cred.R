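#' Standard error of a log odds ratio from a published confidence interval
#'
#' Reconstructs the standard error of \eqn{\ln OR} from the bounds of a
#' symmetric-on-the-log-scale confidence interval:
#' \deqn{SE = \frac{\ln(\mathrm{upper}) - \ln(\mathrm{lower})}{2\, z_{(1+level)/2}}}
#' The normal quantile is computed, not hard-coded, so any interval level
#' works.
#'
#' @param or Positive odds ratio point estimate(s). Only used for validation
#'   (the SE depends on the bounds alone).
#' @param lower,upper Positive confidence-interval bounds, `lower < upper`.
#' @param level Interval coverage in (0, 1); default `0.95`.
#' @return Numeric vector of standard errors on the log odds-ratio scale.
#' @examples
#' se_from_ci(1.19, 1.06, 1.33)
#' @export
se_from_ci <- function(or, lower, upper, level = 0.95) {
  check_range(or, "or", 0)
  check_range(lower, "lower", 0)
  check_range(upper, "upper", 0)
  check_range(level, "level", 0, 1)
  if (any(lower >= upper)) {
    stop("`lower` must be strictly below `upper`", call. = FALSE)
  }
  (log(upper) - log(lower)) / (2 * qnorm((1 + level) / 2))
}

#' Z statistic and two-sided p-value for a log odds ratio
#'
#' Computes \eqn{z = \ln(OR)/SE} and the two-sided normal tail probability
#' \eqn{p = 2\bar\Phi(|z|)}. The tail is evaluated in log space
#' (`pnorm(..., log.p = TRUE)`) so `log_p` stays finite for |z| far beyond
#' the double-precision underflow point of `p` itself (|z| of 50 gives
#' log10(p) near -545).
#'
#' @param or Positive odds ratio(s).
#' @param se Positive standard error(s) of the log odds ratio.
#' @return A tibble with columns `log_or`, `se`, `z`, `p_two_sided` and
#'   `log_p` (natural log of the two-sided p-value).
#' @examples
#' z_and_p(1.19, 0.0579)
#' @export
z_and_p <- function(or, se) {
  check_range(or, "or", 0)
  check_range(se, "se", 0)
  log_or <- log(or)
  z <- log_or / se
  log_p <- log(2) + pnorm(abs(z), lower.tail = FALSE, log.p = TRUE)
  log_p <- pmin(log_p, 0)
  tibble::tibble(log_or = log_or, se = se, z = z,
                 p_two_sided = exp(log_p), log_p = log_p)
}

#' Power to detect a target odds ratio
#'
#' Probability that an estimator with standard error `se` yields a
#' significant two-sided result when the true effect is `detection_or`:
#' \deqn{\Phi(\theta_1/SE - c) + \Phi(-\theta_1/SE - c)}
#' with \eqn{\theta_1 = \ln(\mathrm{detection\_or})}. The critical value `c`
#' is either `qnorm(1 - alpha/2)` (`alpha_mode = "fixed"`) or the observed
#' |z| (`alpha_mode = "observed_p"`, the convention of Wacholder's FPRP
#' spreadsheet, where the significance level is set to the observed
#' p-value).
#'
#' @param detection_or Target odds ratio(s) > 1 at which power is evaluated.
#' @param se Positive standard error(s) of the log odds ratio.
#' @param alpha_mode `"observed_p"` (default) or `"fixed"`.
#' @param alpha Two-sided significance level for `alpha_mode = "fixed"`.
#' @param observed_z Observed z statistic(s), required for
#'   `alpha_mode = "observed_p"`.
#' @param log If `TRUE` return the natural log of the power.
#' @return Numeric vector of powers in `[0, 1]` (or their logs).
#' @examples
#' power_to_detect(1.2, 0.0579, alpha_mode = "fixed")
#' @export
power_to_detect <- function(detection_or, se,
                            alpha_mode = c("observed_p", "fixed"),
                            alpha = 0.05, observed_z = NULL, log = FALSE) {
  alpha_mode <- match.arg(alpha_mode)
  check_range(detection_or, "detection_or", 1)
  check_range(se, "se", 0)
  crit <- if (alpha_mode == "fixed") {
    check_range(alpha, "alpha", 0, 1)
    qnorm(1 - alpha / 2)
  } else {
    if (is.null(observed_z)) {
      stop("`observed_z` is required when alpha_mode = \"observed_p\"",
           call. = FALSE)
    }
    abs(observed_z)
  }
  t1 <- log(detection_or) / se
  log_power <- logspace_add(pnorm(t1 - crit, log.p = TRUE),
                            pnorm(-t1 - crit, log.p = TRUE))
  log_power <- pmin(log_power, 0)
  if (log) log_power else exp(log_power)
}

#' False-positive report probability
#'
#' FPRP is the probability that a statistically significant association is a
#' false positive, given a prior probability `prior` that the association is
#' real, the observed p-value and the power to detect a target effect:
#' \deqn{FPRP = \frac{p\,(1-\pi)}{p\,(1-\pi) + (1-\beta)\,\pi}}
#' The ratio is evaluated in log space so it remains defined for p-values
#' far below double-precision underflow when `log_p`/`log_power` are
#' supplied. If both the p-value and the power underflow to exactly zero the
#' ratio is undefined and `NA` is returned (mirroring the "not computable"
#' cells that appear in published synopses); `NA` is never flagged
#' noteworthy downstream.
#'
#' @param p_value Observed two-sided p-value(s) in (0, 1].
#' @param power Power(s) to detect the target odds ratio, in `[0, 1]`.
#' @param prior Prior probability(ies) of a true association, in (0, 1).
#' @param log_p,log_power Optional natural logs of `p_value` and `power` for
#'   underflow-safe evaluation; default to `log(p_value)` / `log(power)`.
#' @return Numeric vector of FPRP values in `[0, 1]`, `NA` where undefined.
#' @examples
#' fprp(0.004, 0.88, 0.05)
#' @export
fprp <- function(p_value, power, prior,
                 log_p = log(p_value), log_power = log(power)) {
  # p_value = 0 is tolerated: it means underflow, with log_p carrying the
  # information (or jointly undefined with power, yielding NA)
  check_range(p_value, "p_value", 0, 1, open_lower = FALSE,
              open_upper = FALSE)
  check_range(power, "power", 0, 1, open_lower = FALSE, open_upper = FALSE)
  check_range(prior, "prior", 0, 1)
  log_num <- log_p + log1p(-prior)
  log_den <- logspace_add(log_num, log_power + log(prior))
  out <- exp(log_num - log_den)
  out[is.infinite(log_p) & is.infinite(log_power)] <- NA_real_
  out
}

#' Bayesian false discovery probability
#'
#' BFDP is the posterior probability that a reported association is a false
#' discovery, based on Wakefield's approximate Bayes factor. With
#' \eqn{V = SE^2}, prior variance \eqn{W = (\ln\kappa / z_{0.975})^2} where
#' \eqn{\kappa} is the 97.5th percentile of the prior on the odds ratio
#' under the alternative, and \eqn{z = \hat\theta/SE}:
#' \deqn{\log BF = \tfrac12 \ln\frac{V+W}{V} - \frac{z^2 W}{2(V+W)}, \qquad
#'       BFDP = \mathrm{logit}^{-1}\left(\log BF + \ln\frac{1-\pi}{\pi}\right)}
#' The logistic transform is applied to the summed logs, so extreme values
#' never underflow to an uninformative 0: with `log = TRUE` the natural log
#' of the BFDP is returned and stays finite for |z| well beyond 50.
#'
#' @param log_or Estimated log odds ratio(s).
#' @param se Positive standard error(s).
#' @param prior Prior probability(ies) of association, in (0, 1).
#' @param prior_or_bound 97.5th percentile \eqn{\kappa > 1} of the prior on
#'   the odds ratio under the alternative; default `1.5`.
#' @param log If `TRUE` return the natural log of the BFDP.
#' @return Numeric vector of BFDP values in `[0, 1]` (or their logs).
#' @examples
#' bfdp(log(1.19), 0.0579, prior = 0.05)
#' @export
bfdp <- function(log_or, se, prior, prior_or_bound = 1.5, log = FALSE) {
  check_range(se, "se", 0)
  check_range(prior, "prior", 0, 1)
  check_range(prior_or_bound, "prior_or_bound", 1)
  V <- se^2
  W <- (base::log(prior_or_bound) / qnorm(0.975))^2
  z <- log_or / se
  log_bf <- 0.5 * base::log((V + W) / V) - z^2 * W / (2 * (V + W))
  log_odds <- log_bf + log1p(-prior) - base::log(prior)
  if (log) plogis(log_odds, log.p = TRUE) else plogis(log_odds)
}

#' Configuration for credibility profiling
#'
#' Collects the tunable conventions of the FPRP/BFDP re-analysis. When
#' `priors` is `NULL`, [credibility_profile()] picks the conventional
#' medium/low levels per record: 0.05 and 0.001 for observational
#' (candidate-gene) records, 0.001 and 1e-6 for GWAS records.
#'
#' @param priors Optional numeric vector of prior probabilities in (0, 1)
#'   applied to every record regardless of study type.
#' @param detection_ors Odds ratios > 1 at which FPRP power is evaluated;
#'   default `c(1.2, 1.5)`.
#' @param fprp_threshold FPRP noteworthiness cut-off; default `0.2`.
#' @param bfdp_threshold BFDP noteworthiness cut-off; default `0.8`.
#' @param bfdp_prior_or_bound 97.5th percentile of the prior odds ratio used
#'   by [bfdp()]; default `1.5`.
#' @param fprp_alpha_mode Power convention for FPRP, `"observed_p"`
#'   (default, per Wacholder's spreadsheet) or `"fixed"`.
#' @param fixed_alpha Significance level used when
#'   `fprp_alpha_mode = "fixed"`; default `0.05`.
#' @param p_source `"reconstructed"` (default) recomputes the p-value from
#'   the confidence interval; `"printed"` uses the catalogue's `p_value`
#'   column where present.
#' @return A list of class `"cred_config"`.
#' @examples
#' cred_config(priors = c(0.001, 1e-6))
#' @export
cred_config <- function(priors = NULL,
                        detection_ors = c(1.2, 1.5),
                        fprp_threshold = 0.2,
                        bfdp_threshold = 0.8,
                        bfdp_prior_or_bound = 1.5,
                        fprp_alpha_mode = c("observed_p", "fixed"),
                        fixed_alpha = 0.05,
                        p_source = c("reconstructed", "printed")) {
  if (!is.null(priors)) check_range(priors, "priors", 0, 1)
  check_range(detection_ors, "detection_ors", 1)
  check_range(fprp_threshold, "fprp_threshold", 0, 1)
  check_range(bfdp_threshold, "bfdp_threshold", 0, 1)
  check_range(bfdp_prior_or_bound, "bfdp_prior_or_bound", 1)
  check_range(fixed_alpha, "fixed_alpha", 0, 1)
  structure(
    list(priors = priors,
         detection_ors = sort(detection_ors),
         fprp_threshold = fprp_threshold,
         bfdp_threshold = bfdp_threshold,
         bfdp_prior_or_bound = bfdp_prior_or_bound,
         fprp_alpha_mode = match.arg(fprp_alpha_mode),
         fixed_alpha = fixed_alpha,
         p_source = match.arg(p_source)),
    class = "cred_config")
}

#' @export
print.cred_config <- function(x, ...) {
  cat("<cred_config>\n")
  cat("  priors:             ",
      if (is.null(x$priors)) "per study type (obs 0.05/0.001, gwas 0.001/1e-6)"
      else paste(format(x$priors), collapse = ", "), "\n")
  cat("  detection ORs:      ", paste(x$detection_ors, collapse = ", "), "\n")
  cat("  thresholds:          FPRP <", x$fprp_threshold,
      ", BFDP <", x$bfdp_threshold, "\n")
  cat("  BFDP prior OR bound:", x$bfdp_prior_or_bound, "\n")
  cat("  FPRP alpha mode:    ", x$fprp_alpha_mode,
      if (x$fprp_alpha_mode == "fixed") paste0("(alpha = ", x$fixed_alpha, ")")
      else "", "\n")
  cat("  p source:           ", x$p_source, "\n")
  invisible(x)
}

default_priors <- function(study_type) {
  if (identical(study_type, "gwas")) c(0.001, 1e-6) else c(0.05, 0.001)
}

#' Credibility profile of a catalogue of association records
#'
#' Evaluates, for every record, the full grid of FPRP values over
#' (prior x detection OR), the BFDP per prior, the power per detection OR,
#' and the noteworthiness flags. Protective effects (OR < 1) are handled
#' through |z| and the same positive detection odds ratio, which is
#' equivalent to inverting the odds ratio and mirroring the interval bounds;
#' profiles are therefore invariant under OR -> 1/OR.
#'
#' @param catalog A catalogue data frame (see [read_catalog()]) with at
#'   least `odds_ratio`, `ci_lower`, `ci_upper` and `study_type` columns.
#' @param config A [cred_config()] object.
#' @return A tibble in long format, one row per
#'   (record x prior x detection OR): identifying columns, the effect
#'   summary (`log_or`, `se`, `z`, `p_two_sided`, `log_p`), `prior`,
#'   `detection_or`, `power`, `fprp`, `bfdp`, `log_bfdp` and the logical
#'   flags `noteworthy_fprp`, `noteworthy_bfdp`, `noteworthy_any`. The
#'   `bfdp` value is repeated across detection ORs within a record-prior
#'   pair, since it does not involve power. `NA` FPRP (undefined) is never
#'   noteworthy.
#' @examples
#' credibility_profile(load_fixture("table1"))
#' @export
credibility_profile <- function(catalog, config = cred_config()) {
  stopifnot(inherits(config, "cred_config"))
  catalog <- as_catalog(catalog)
  eff <- z_and_p(catalog$odds_ratio,
                 se_from_ci(catalog$odds_ratio, catalog$ci_lower,
                            catalog$ci_upper,
                            if ("ci_level" %in% names(catalog)) {
                              catalog$ci_level
                            } else 0.95))
  base <- dplyr::bind_cols(
    catalog[intersect(c("row_id", "author", "year", "gene", "variant",
                        "comparison", "study_type", "subtype", "ethnicity"),
                      names(catalog))],
    eff)
  if (config$p_source == "printed" && "p_value" %in% names(catalog)) {
    printed_ok <- !is.na(catalog$p_value)
    base$p_two_sided[printed_ok] <- catalog$p_value[printed_ok]
    base$log_p[printed_ok] <- log(catalog$p_value[printed_ok])
  }

  grid <- base %>%
    dplyr::mutate(prior = purrr::map(.data$study_type, function(st) {
      config$priors %||% default_priors(st)
    })) %>%
    tidyr::unnest("prior") %>%
    tidyr::crossing(detection_or = config$detection_ors)

  grid <- grid %>%
    dplyr::mutate(
      log_power = power_to_detect(
        .data$detection_or, .data$se,
        alpha_mode = config$fprp_alpha_mode,
        alpha = config$fixed_alpha,
        observed_z = .data$z, log = TRUE),
      power = exp(.data$log_power),
      fprp = fprp(.data$p_two_sided, .data$power, .data$prior,
                  log_p = .data$log_p, log_power = .data$log_power),
      log_bfdp = bfdp(.data$log_or, .data$se, .data$prior,
                      config$bfdp_prior_or_bound, log = TRUE),
      bfdp = exp(.data$log_bfdp),
      noteworthy_fprp = !is.na(.data$fprp) & .data$fprp < config$fprp_threshold,
      noteworthy_bfdp = .data$bfdp < config$bfdp_threshold,
      noteworthy_any = .data$noteworthy_fprp | .data$noteworthy_bfdp
    ) %>%
    dplyr::select(-"log_power")
  grid
}
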