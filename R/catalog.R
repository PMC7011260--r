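#' @title Association catalogues
#' @description A catalogue is a plain tibble with one row per pooled
#'   meta-analysis result. Mandatory columns: `variant`, `comparison`,
#'   `odds_ratio`, `ci_lower`, `ci_upper`, `study_type` (`"observational"`
#'   or `"gwas"`). Recognised optional columns: `author`, `year`, `gene`,
#'   `p_value`, `ethnicity`, `subtype` (`"overall"`, `"MA"`, `"MO"`),
#'   `n_cases`, `n_controls`, `n_studies`, `maf`, `ci_level`,
#'   `venice_grades`, plus any number of printed-statistic columns named
#'   `fprp_or<OR>_<prior>` / `bfdp_<prior>`. Empty, `"NA"` and dash cells
#'   are read as missing.
#' @name catalog
NULL

catalog_required <- c("variant", "comparison", "odds_ratio",
                      "ci_lower", "ci_upper", "study_type")

catalog_na <- c("", "NA", "–", "—", "-")

# Ensure row_id exists and column types are sane; used at module entry
# points so piped tibbles from any source are accepted.
as_catalog <- function(x) {
  stopifnot(is.data.frame(x))
  x <- tibble::as_tibble(x)
  if (!"row_id" %in% names(x)) x <- dplyr::mutate(x, row_id = dplyr::row_number())
  x
}

validate_catalog <- function(catalog) {
  missing_cols <- setdiff(catalog_required, names(catalog))
  if (length(missing_cols) > 0) {
    stop("catalogue is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad_or <- which(!is.finite(catalog$odds_ratio) | catalog$odds_ratio <= 0 |
                    !is.finite(catalog$ci_lower) | catalog$ci_lower <= 0 |
                    !is.finite(catalog$ci_upper) | catalog$ci_upper <= 0)
  if (length(bad_or) > 0) {
    stop("unparseable or non-positive OR/CI in row(s): ",
         paste(head(bad_or, 5L), collapse = ", "), call. = FALSE)
  }
  bad_ci <- which(catalog$ci_lower >= catalog$odds_ratio |
                    catalog$odds_ratio >= catalog$ci_upper)
  if (length(bad_ci) > 0) {
    stop("point estimate outside its confidence interval in row(s): ",
         paste(head(bad_ci, 5L), collapse = ", "), call. = FALSE)
  }
  if ("maf" %in% names(catalog)) {
    check_range(catalog$maf, "maf", 0, 1, allow_na = TRUE)
  }
  if ("p_value" %in% names(catalog)) {
    check_range(catalog$p_value, "p_value", 0, 1, open_upper = FALSE,
                allow_na = TRUE)
  }
  bad_type <- which(!catalog$study_type %in% c("observational", "gwas"))
  if (length(bad_type) > 0) {
    stop("`study_type` must be \"observational\" or \"gwas\"; bad row(s): ",
         paste(head(bad_type, 5L), collapse = ", "), call. = FALSE)
  }
  invisible(catalog)
}

#' Read an association catalogue from a delimited file
#'
#' Reads a TSV (default) or CSV of pooled meta-analysis records, applies
#' optional column aliases, validates the rows and returns a tibble with a
#' stable `row_id` column. Dash-like cells (`–`, `-`, `—`), empty cells and
#' `"NA"` become missing values, so printed "not computable" statistics are
#' carried as absent rather than as numbers.
#'
#' @param path Path to the delimited file; a header row is mandatory.
#' @param delim Field delimiter, `"\t"` by default.
#' @param col_aliases Optional named character vector mapping file column
#'   names to canonical names, e.g. `c(OR = "odds_ratio")`. Matching is
#'   case-insensitive.
#' @return A validated catalogue tibble; the input path is recorded in the
#'   `"provenance"` attribute.
#' @seealso [load_fixture()], [write_catalog()]
#' @export
read_catalog <- function(path, delim = "\t", col_aliases = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_delim(path, delim = delim, na = catalog_na,
                           show_col_types = FALSE, progress = FALSE,
                           trim_ws = TRUE)
  if (!is.null(col_aliases)) {
    idx <- match(tolower(names(raw)), tolower(names(col_aliases)))
    names(raw)[!is.na(idx)] <- unname(col_aliases[idx[!is.na(idx)]])
  }
  canon <- c(catalog_required, "author", "year", "gene", "p_value",
             "ethnicity", "subtype", "n_cases", "n_controls", "n_studies",
             "maf", "ci_level", "venice_grades", "venice_credibility",
             "par_printed")
  idx <- match(tolower(names(raw)), tolower(canon))
  names(raw)[!is.na(idx)] <- canon[idx[!is.na(idx)]]
  out <- as_catalog(raw)
  validate_catalog(out)
  attr(out, "provenance") <- path
  out
}

#' Write a catalogue back to a delimited file
#'
#' Inverse of [read_catalog()]: numeric columns are written at full
#' precision so that read/write round-trips reproduce every field.
#'
#' @param catalog A catalogue tibble.
#' @param path Output path.
#' @param delim Field delimiter, `"\t"` by default.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path, delim = "\t") {
  out <- dplyr::select(as_catalog(catalog), -"row_id")
  readr::write_delim(out, path, delim = delim, na = "NA")
  invisible(path)
}

#' Load a bundled synopsis table
#'
#' The package ships transcriptions of three published migraine-synopsis
#' tables as plain TSV fixtures:
#' * `"table1"` — 19 significant records (8 variants) from meta-analyses of
#'   observational studies, with the printed FPRP/BFDP grid at priors
#'   0.05/0.001 and the Venice grades;
#' * `"table2"` — 47 significant GWAS records with the printed FPRP/BFDP
#'   grid at priors 0.001/1e-6 ("not computable" cells are missing values);
#' * `"table6"` — the 36 noteworthy GWAS variants with minor allele
#'   frequency and the printed per-SNP attributable risk (percent), plus
#'   the printed FPRP (OR 1.5) and BFDP cells at prior 1e-6 that define
#'   the set's membership.
#'
#' @param name One of `"table1"`, `"table2"`, `"table6"`.
#' @return A catalogue tibble (see [read_catalog()]).
#' @examples
#' load_fixture("table6")
#' @export
load_fixture <- function(name = c("table1", "table2", "table6")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".tsv"), package = "metacred",
                      mustWork = TRUE)
  out <- read_catalog(path)
  attr(out, "provenance") <- name
  out
}

#' Drop superseded records of the same association
#'
#' When several meta-analyses cover the same association — identical
#' (`variant`, `comparison`, `study_type`, `subtype`, `ethnicity`) — only
#' the most recent one is kept; ties on `year` are broken by the larger
#' total sample size (`n_cases + n_controls`), and residual ties keep the
#' first-seen record with a warning. Subgroup rows (`subtype`, `ethnicity`)
#' are part of the key, so stratified results coexist with overall ones.
#' The operation is idempotent.
#'
#' @param catalog A catalogue tibble.
#' @return The catalogue restricted to the retained records, original order
#'   preserved.
#' @export
deduplicate <- function(catalog) {
  catalog <- as_catalog(catalog)
  key_cols <- intersect(c("variant", "comparison", "study_type",
                          "subtype", "ethnicity"), names(catalog))
  yr <- col_or(catalog, "year", 0)
  n_tot <- col_or(catalog, "n_cases", 0) + col_or(catalog, "n_controls", 0)
  ranked <- catalog %>%
    dplyr::mutate(.yr = dplyr::coalesce(yr, 0),
                  .n = dplyr::coalesce(n_tot, 0)) %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(key_cols)))
  ties <- ranked %>%
    dplyr::summarise(
      tie = dplyr::n() > 1 &&
        sum(.data$.yr == max(.data$.yr) &
              .data$.n == max(.data$.n[.data$.yr == max(.data$.yr)])) > 1,
      .groups = "drop")
  if (any(ties$tie)) {
    warning("tie on year and sample size for ", sum(ties$tie),
            " association key(s); keeping first-seen record", call. = FALSE)
  }
  out <- ranked %>%
    dplyr::arrange(dplyr::desc(.data$.yr), dplyr::desc(.data$.n),
                   .data$row_id, .by_group = TRUE) %>%
    dplyr::slice(1L) %>%
    dplyr::ungroup() %>%
    dplyr::arrange(.data$row_id) %>%
    dplyr::select(-".yr", -".n")
  attr(out, "provenance") <- attr(catalog, "provenance")
  out
}

#' Keep statistically significant records
#'
#' Retains records whose two-sided p-value is strictly below the threshold
#' for their study type (`obs_alpha` for observational meta-analyses,
#' `gwas_alpha` for GWAS) *and* whose confidence interval excludes 1
#' (`ci_lower > 1` or `ci_upper < 1`). Records without a p-value have one
#' reconstructed from the confidence interval via [z_and_p()] before the
#' test. Records exactly at a threshold are dropped. Idempotent; the output
#' is always a subset of the input.
#'
#' @param catalog A catalogue tibble.
#' @param obs_alpha Significance level for observational records; default
#'   `0.05`.
#' @param gwas_alpha Genome-wide significance level for GWAS records;
#'   default `5e-8`.
#' @return The significant subset of `catalog`.
#' @export
filter_significant <- function(catalog, obs_alpha = 0.05, gwas_alpha = 5e-8) {
  check_range(obs_alpha, "obs_alpha", 0, 1)
  check_range(gwas_alpha, "gwas_alpha", 0, 1)
  catalog <- as_catalog(catalog)
  if (nrow(catalog) == 0) return(catalog)
  p <- col_or(catalog, "p_value", NA_real_)
  need <- is.na(p)
  if (any(need)) {
    p[need] <- z_and_p(
      catalog$odds_ratio[need],
      se_from_ci(catalog$odds_ratio[need], catalog$ci_lower[need],
                 catalog$ci_upper[need]))$p_two_sided
  }
  alpha <- ifelse(catalog$study_type == "gwas", gwas_alpha, obs_alpha)
  keep <- p < alpha & (catalog$ci_lower > 1 | catalog$ci_upper < 1)
  out <- catalog[keep, , drop = FALSE]
  attr(out, "provenance") <- attr(catalog, "provenance")
  out
}

#' Printed credibility statistics in long format
#'
#' Gathers the `fprp_or<OR>_<prior>` and `bfdp_<prior>` columns of a
#' fixture catalogue into one row per (record, statistic, detection OR,
#' prior). Missing cells — the synopsis' "not computable" dashes — are kept
#' as `NA` rows so downstream counting can treat them explicitly.
#'
#' @param catalog A catalogue with printed-statistic columns, e.g. from
#'   [load_fixture()].
#' @return A tibble with columns `row_id`, `gene`, `variant`, `comparison`,
#'   `statistic` (`"fprp"`/`"bfdp"`), `detection_or` (`NA` for BFDP),
#'   `prior` and `value`.
#' @export
printed_stats <- function(catalog) {
  catalog <- as_catalog(catalog)
  stat_cols <- grep("^(fprp_or[0-9.]+|bfdp)_[0-9.e+-]+$", names(catalog),
                    value = TRUE)
  if (length(stat_cols) == 0) {
    stop("catalogue has no printed fprp_*/bfdp_* columns", call. = FALSE)
  }
  id_cols <- intersect(c("row_id", "gene", "variant", "comparison",
                         "study_type", "subtype"), names(catalog))
  catalog %>%
    dplyr::select(dplyr::all_of(c(id_cols, stat_cols))) %>%
    tidyr::pivot_longer(dplyr::all_of(stat_cols), names_to = "label",
                        values_to = "value") %>%
    dplyr::mutate(
      statistic = ifelse(startsWith(.data$label, "fprp"), "fprp", "bfdp"),
      detection_or = ifelse(
        .data$statistic == "fprp",
        as.numeric(stringr::str_match(.data$label, "^fprp_or([0-9.]+)_")[, 2]),
        NA_real_),
      prior = as.numeric(stringr::str_match(.data$label,
                                            "_([0-9.e+-]+)$")[, 2])
    ) %>%
    dplyr::select(-"label")
}
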