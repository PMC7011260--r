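#' Population attributable risk of one variant
#'
#' Levin's allele-frequency form of the population attributable risk,
#' \deqn{PAR = \frac{f\,(OR - 1)}{f\,(OR - 1) + 1}}
#' with `f` the minor allele frequency. For protective effects (OR < 1) the
#' signed value is negative; by default the magnitude is returned, the
#' convention used when protective variants are folded into a joint risk
#' summary.
#'
#' @param maf Minor allele frequency(ies) in (0, 1).
#' @param or Positive allelic odds ratio(s).
#' @param signed If `TRUE` return the signed value (negative for OR < 1)
#'   instead of the magnitude.
#' @return Numeric vector of attributable risks as fractions in `[0, 1)`
#'   (magnitude convention) or `(-1, 1)` (signed).
#' @examples
#' single_par(0.3510, 1.18)   # risk allele
#' single_par(0.3894, 0.90)   # protective allele, magnitude
#' @export
single_par <- function(maf, or, signed = FALSE) {
  check_range(maf, "maf", 0, 1)
  check_range(or, "or", 0)
  den <- maf * (or - 1) + 1
  if (any(den <= 0)) stop("f(OR - 1) + 1 must be positive", call. = FALSE)
  out <- maf * (or - 1) / den
  if (signed) out else abs(out)
}

#' Joint attributable risk of a set of variants
#'
#' Combines per-variant attributable risks multiplicatively through their
#' complements. Both conventions are reported: `complement_product`
#' \eqn{\prod_i (1 - PAR_i)} — the quantity some published synopses label
#' "joint PAR" — and `one_minus_product` \eqn{1 - \prod_i (1 - PAR_i)},
#' the conventional joint attributable risk under independence. The two
#' always sum to 1; neither is silently preferred.
#'
#' @param pars Numeric vector of per-variant attributable risks in `[0, 1)`
#'   (fractions, not percent).
#' @return A one-row tibble with `n_snps`, `complement_product` and
#'   `one_minus_product`.
#' @examples
#' joint_par(c(0.1, 0.2))
#' @export
joint_par <- function(pars) {
  if (length(pars) == 0) stop("`pars` must be non-empty", call. = FALSE)
  check_range(pars, "pars", 0, 1, open_lower = FALSE)
  cp <- prod(1 - pars)
  tibble::tibble(n_snps = length(pars),
                 complement_product = cp,
                 one_minus_product = 1 - cp)
}

#' Attributable-risk table for a catalogue with allele frequencies
#'
#' Computes the per-variant attributable risk (magnitude and signed, in
#' percent) for every record with a `maf`, plus the joint summary over the
#' set. Records without `maf` are dropped with a message.
#'
#' @param catalog A catalogue tibble with `maf` and `odds_ratio` columns.
#' @return A list of class `"par_table"` with elements `per_snp` (tibble:
#'   identifying columns, `maf`, `odds_ratio`, `par_percent`,
#'   `par_signed_percent`) and `joint` (see [joint_par()], with percent
#'   columns added).
#' @examples
#' par_table(load_fixture("table6"))
#' @export
par_table <- function(catalog) {
  catalog <- as_catalog(catalog)
  if (!"maf" %in% names(catalog)) {
    stop("catalogue has no `maf` column", call. = FALSE)
  }
  no_maf <- is.na(catalog$maf)
  if (any(no_maf)) {
    message(sum(no_maf), " record(s) without MAF excluded from PAR table")
    catalog <- catalog[!no_maf, , drop = FALSE]
  }
  if (nrow(catalog) == 0) stop("no records with MAF", call. = FALSE)
  id_cols <- intersect(c("row_id", "author", "year", "gene", "variant",
                         "comparison"), names(catalog))
  per_snp <- dplyr::bind_cols(
    catalog[id_cols],
    tibble::tibble(
      maf = catalog$maf,
      odds_ratio = catalog$odds_ratio,
      par_percent = 100 * single_par(catalog$maf, catalog$odds_ratio),
      par_signed_percent = 100 * single_par(catalog$maf, catalog$odds_ratio,
                                            signed = TRUE)))
  joint <- joint_par(per_snp$par_percent / 100)
  joint$complement_product_percent <- 100 * joint$complement_product
  joint$one_minus_product_percent <- 100 * joint$one_minus_product
  structure(list(per_snp = per_snp, joint = joint), class = "par_table")
}

#' @export
print.par_table <- function(x, ...) {
  cat("<par_table> ", x$joint$n_snps, " variants\n", sep = "")
  print(x$per_snp, n = 5)
  cat(sprintf("joint: prod(1 - PAR) = %.4f%% (as published in some synopses);\n",
              x$joint$complement_product_percent))
  cat(sprintf("       1 - prod(1 - PAR) = %.4f%% (conventional joint PAR)\n",
              x$joint$one_minus_product_percent))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.par_table <- function(x, ...) x$per_snp

#' @exportS3Method generics::glance
glance.par_table <- function(x, ...) x$joint

#' Select the noteworthy variant set for attributable-risk combination
#'
#' Filters a credibility profile (recomputed, from
#' [credibility_profile()], or printed, from [printed_stats()]) to the
#' variants that are noteworthy at the requested prior — FPRP below
#' `fprp_threshold` at the requested detection odds ratio, or BFDP below
#' `bfdp_threshold` — and returns the corresponding catalogue rows, one per
#' variant (a variant qualifies if any of its genetic-model rows does).
#'
#' @param catalog The catalogue the profile was computed from; must carry
#'   `maf` if the result feeds [par_table()].
#' @param profile A long profile tibble with `row_id`, `prior`,
#'   `detection_or` and either `fprp`/`bfdp` columns (recomputed) or
#'   `statistic`/`value` columns (printed).
#' @param prior Prior probability of the grid slice to use.
#' @param detection_or Detection odds ratio for the FPRP side; default
#'   `1.5`.
#' @param fprp_threshold,bfdp_threshold Noteworthiness cut-offs; defaults
#'   `0.2` and `0.8`. Missing (undefined) FPRP never qualifies.
#' @return The subset of `catalog`, one row per noteworthy variant (the
#'   first qualifying row of each variant).
#' @export
select_par_set <- function(catalog, profile, prior, detection_or = 1.5,
                           fprp_threshold = 0.2, bfdp_threshold = 0.8) {
  catalog <- as_catalog(catalog)
  pr <- prior
  if ("statistic" %in% names(profile)) {
    slice <- profile %>%
      dplyr::filter(.data$prior == pr,
                    .data$statistic == "bfdp" |
                      .data$detection_or == !!detection_or) %>%
      dplyr::group_by(.data$row_id) %>%
      dplyr::summarise(noteworthy = any(
        (.data$statistic == "fprp" & !is.na(.data$value) &
           .data$value < fprp_threshold) |
          (.data$statistic == "bfdp" & !is.na(.data$value) &
             .data$value < bfdp_threshold)), .groups = "drop")
  } else {
    slice <- profile %>%
      dplyr::filter(.data$prior == pr, .data$detection_or == !!detection_or) %>%
      dplyr::group_by(.data$row_id) %>%
      dplyr::summarise(noteworthy = any(
        (!is.na(.data$fprp) & .data$fprp < fprp_threshold) |
          (.data$bfdp < bfdp_threshold)), .groups = "drop")
  }
  keep_ids <- slice$row_id[slice$noteworthy]
  out <- catalog %>%
    dplyr::filter(.data$row_id %in% keep_ids) %>%
    dplyr::distinct(.data$variant, .keep_all = TRUE)
  attr(out, "provenance") <- attr(catalog, "provenance")
  out
}
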