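#' Count noteworthy associations in a credibility profile
#'
#' Tallies, for every (criterion, prior, detection OR) cell of the grid,
#' how many rows and how many distinct variants are noteworthy. A variant
#' counts as noteworthy if any of its genetic-model rows is. The `"any"`
#' criterion combines FPRP at every detection OR with BFDP at the same
#' prior. Works on recomputed profiles ([credibility_profile()]) and on
#' printed fixtures ([printed_stats()]); for printed profiles the
#' thresholds are applied to the printed cells, missing cells never
#' qualifying.
#'
#' @param profile A long profile tibble.
#' @param fprp_threshold,bfdp_threshold Cut-offs used when the profile does
#'   not carry precomputed noteworthiness flags (printed mode); defaults
#'   `0.2` and `0.8`.
#' @return A tibble with `criterion` (`"fprp"`, `"bfdp"`, `"any"`),
#'   `prior`, `detection_or` (`NA` for `"bfdp"` and `"any"`), `n_rows`,
#'   `n_variants`.
#' @export
count_noteworthy <- function(profile, fprp_threshold = 0.2,
                             bfdp_threshold = 0.8) {
  flags <- noteworthy_flags(profile, fprp_threshold, bfdp_threshold)
  fprp_counts <- flags %>%
    dplyr::group_by(.data$prior, .data$detection_or) %>%
    dplyr::summarise(criterion = "fprp",
                     n_rows = sum(.data$nw_fprp),
                     n_variants = dplyr::n_distinct(.data$variant[.data$nw_fprp]),
                     .groups = "drop")
  bfdp_counts <- flags %>%
    dplyr::distinct(.data$prior, .data$row_id, .data$variant, .data$nw_bfdp) %>%
    dplyr::group_by(.data$prior) %>%
    dplyr::summarise(criterion = "bfdp", detection_or = NA_real_,
                     n_rows = sum(.data$nw_bfdp),
                     n_variants = dplyr::n_distinct(.data$variant[.data$nw_bfdp]),
                     .groups = "drop")
  any_counts <- flags %>%
    dplyr::group_by(.data$prior, .data$row_id, .data$variant) %>%
    dplyr::summarise(nw = any(.data$nw_fprp | .data$nw_bfdp),
                     .groups = "drop") %>%
    dplyr::group_by(.data$prior) %>%
    dplyr::summarise(criterion = "any", detection_or = NA_real_,
                     n_rows = sum(.data$nw),
                     n_variants = dplyr::n_distinct(.data$variant[.data$nw]),
                     .groups = "drop")
  dplyr::bind_rows(fprp_counts, bfdp_counts, any_counts) %>%
    dplyr::select("criterion", "prior", "detection_or",
                  "n_rows", "n_variants") %>%
    dplyr::arrange(.data$criterion, dplyr::desc(.data$prior),
                   .data$detection_or)
}

# Normalise recomputed and printed profiles to per-(row, prior,
# detection_or) noteworthiness flags.
noteworthy_flags <- function(profile, fprp_threshold, bfdp_threshold) {
  if (!"variant" %in% names(profile)) profile$variant <- as.character(profile$row_id)
  if ("statistic" %in% names(profile)) {
    fprp_part <- profile %>%
      dplyr::filter(.data$statistic == "fprp") %>%
      dplyr::mutate(nw_fprp = !is.na(.data$value) &
                      .data$value < fprp_threshold)
    bfdp_part <- profile %>%
      dplyr::filter(.data$statistic == "bfdp") %>%
      dplyr::mutate(nw_bfdp = !is.na(.data$value) &
                      .data$value < bfdp_threshold) %>%
      dplyr::select("row_id", "prior", "nw_bfdp")
    dplyr::left_join(fprp_part, bfdp_part, by = c("row_id", "prior")) %>%
      dplyr::mutate(nw_bfdp = dplyr::coalesce(.data$nw_bfdp, FALSE)) %>%
      dplyr::select("row_id", "variant", "prior", "detection_or",
                    "nw_fprp", "nw_bfdp")
  } else {
    profile %>%
      dplyr::mutate(nw_fprp = !is.na(.data$fprp) &
                      .data$fprp < fprp_threshold,
                    nw_bfdp = .data$bfdp < bfdp_threshold) %>%
      dplyr::select("row_id", "variant", "prior", "detection_or",
                    "nw_fprp", "nw_bfdp")
  }
}

#' Run the full credibility re-analysis of a catalogue
#'
#' The pipeline of the field synopsis: deduplicate overlapping
#' meta-analyses, keep statistically significant records, evaluate the
#' FPRP/BFDP credibility grid, grade Venice credibility where grade strings
#' are available, count noteworthy associations, and (when allele
#' frequencies are present) build the attributable-risk table over the
#' noteworthy set at the lowest prior and largest detection odds ratio.
#' When the catalogue carries printed statistic columns the same counting
#' is also run on the printed cells (`counts_printed`), which is how the
#' published headline counts are reproduced exactly despite the rounding of
#' the printed ORs and intervals. Deterministic: identical catalogue and
#' configuration give identical reports.
#'
#' @param catalog A catalogue tibble.
#' @param config A [cred_config()].
#' @param obs_alpha,gwas_alpha Significance thresholds passed to
#'   [filter_significant()].
#' @return An object of class `"reanalysis"`: a list with `records` (the
#'   post-filter catalogue), `profile` (recomputed long grid), `printed`
#'   (printed long stats or `NULL`), `counts` / `counts_printed`
#'   (noteworthiness tallies), `venice`, `par` (a [par_table()] or `NULL`),
#'   `config`, and `provenance`.
#' @examples
#' run_reanalysis(load_fixture("table1"))
#' @export
run_reanalysis <- function(catalog, config = cred_config(),
                           obs_alpha = 0.05, gwas_alpha = 5e-8) {
  catalog <- as_catalog(catalog)
  if (nrow(catalog) == 0) stop("catalogue is empty", call. = FALSE)
  deduped <- deduplicate(catalog)
  records <- filter_significant(deduped, obs_alpha, gwas_alpha)
  message("reanalysis: ", nrow(catalog), " records in, ",
          nrow(deduped), " after deduplication, ",
          nrow(records), " significant")
  if (nrow(records) == 0) {
    warning("no significant records; returning an empty report",
            call. = FALSE)
    empty <- structure(list(records = records, profile = NULL,
                            printed = NULL, counts = NULL,
                            counts_printed = NULL, venice = NULL,
                            par = NULL, config = config,
                            provenance = attr(catalog, "provenance")),
                       class = "reanalysis")
    return(empty)
  }
  profile <- credibility_profile(records, config)
  counts <- count_noteworthy(profile, config$fprp_threshold,
                             config$bfdp_threshold)
  has_printed <- any(grepl("^(fprp_or|bfdp_)", names(records)))
  printed <- if (has_printed) printed_stats(records) else NULL
  counts_printed <- if (has_printed) {
    count_noteworthy(printed, config$fprp_threshold, config$bfdp_threshold)
  } else NULL
  venice <- if ("venice_grades" %in% names(records) &&
                any(!is.na(records$venice_grades))) {
    venice_assess(records)
  } else NULL
  par <- if ("maf" %in% names(records) && any(!is.na(records$maf))) {
    low_prior <- min(config$priors %||%
                       default_priors(records$study_type[1]))
    base_profile <- if (has_printed) printed else profile
    chosen <- select_par_set(records, base_profile, prior = low_prior,
                             detection_or = max(config$detection_ors),
                             fprp_threshold = config$fprp_threshold,
                             bfdp_threshold = config$bfdp_threshold)
    if (nrow(chosen) > 0) par_table(chosen) else NULL
  } else NULL
  structure(list(records = records, profile = profile, printed = printed,
                 counts = counts, counts_printed = counts_printed,
                 venice = venice, par = par, config = config,
                 provenance = attr(catalog, "provenance")),
            class = "reanalysis")
}

#' @export
print.reanalysis <- function(x, ...) {
  cat("<reanalysis> ", nrow(x$records), " significant record(s)",
      if (!is.null(x$provenance)) paste0(" [", x$provenance, "]"), "\n",
      sep = "")
  if (!is.null(x$counts)) {
    cat("recomputed noteworthy counts:\n")
    print(x$counts)
  }
  if (!is.null(x$counts_printed)) {
    cat("printed-statistics noteworthy counts:\n")
    print(x$counts_printed)
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.reanalysis <- function(x, ...) {
  if (is.null(x$profile)) return(tibble::tibble())
  x$profile
}

#' @exportS3Method generics::glance
glance.reanalysis <- function(x, ...) {
  counts <- x$counts_printed %||% x$counts
  low <- if (!is.null(counts)) min(counts$prior) else NA_real_
  any_low <- if (!is.null(counts)) {
    counts$n_variants[counts$criterion == "any" & counts$prior == low]
  } else NA_integer_
  tibble::tibble(
    n_records = nrow(x$records),
    n_variants = dplyr::n_distinct(x$records$variant),
    lowest_prior = low,
    n_noteworthy_lowest_prior = any_low,
    counting_mode = if (!is.null(x$counts_printed)) "printed" else "recomputed")
}

#' Stratified re-analysis
#'
#' Partitions the catalogue by `subtype` (e.g. migraine with/without aura)
#' or `ethnicity` and runs [run_reanalysis()] on every non-empty level.
#'
#' @param catalog A catalogue tibble.
#' @param axis `"subtype"` or `"ethnicity"`.
#' @param config A [cred_config()].
#' @param ... Passed on to [run_reanalysis()].
#' @return A named list of `"reanalysis"` objects, one per level.
#' @export
subgroup_analysis <- function(catalog, axis = c("subtype", "ethnicity"),
                              config = cred_config(), ...) {
  axis <- match.arg(axis)
  catalog <- as_catalog(catalog)
  if (!axis %in% names(catalog)) {
    stop("catalogue has no `", axis, "` column", call. = FALSE)
  }
  levels <- unique(catalog[[axis]][!is.na(catalog[[axis]])])
  out <- lapply(levels, function(lv) {
    message("subgroup ", axis, " = ", lv)
    run_reanalysis(catalog[!is.na(catalog[[axis]]) &
                             catalog[[axis]] == lv, , drop = FALSE],
                   config = config, ...)
  })
  setNames(out, levels)
}

#' Reconcile recomputed statistics with printed cells
#'
#' Joins the recomputed FPRP/BFDP grid of a report with the printed cells
#' of its fixture catalogue and reports the absolute deviation per cell.
#' Cells printed as dashes ("not computable") are kept with status
#' `"printed_missing"` and excluded from the deviation summary; the printed
#' values come from spreadsheet runs on the rounded published ORs and
#' intervals, so small deviations are expected and quantified rather than
#' scored.
#'
#' @param report A `"reanalysis"` object whose catalogue carried printed
#'   statistic columns (or a recomputed long profile tibble).
#' @param printed Long printed statistics ([printed_stats()]); taken from
#'   the report when omitted.
#' @return A list with `cells` (per-cell tibble: identifiers, `statistic`,
#'   `prior`, `detection_or`, `printed`, `recomputed`, `deviation`,
#'   `status`) and `summary` (per statistic-prior-OR column: number of
#'   comparable cells, median and max absolute deviation).
#' @export
compare_to_printed <- function(report, printed = NULL) {
  if (inherits(report, "reanalysis")) {
    profile <- report$profile
    printed <- printed %||% report$printed
  } else {
    profile <- report
  }
  if (is.null(printed)) stop("no printed statistics to compare against",
                             call. = FALSE)
  recomputed <- profile %>%
    dplyr::select("row_id", "variant", "prior", "detection_or",
                  "fprp", "bfdp") %>%
    tidyr::pivot_longer(c("fprp", "bfdp"), names_to = "statistic",
                        values_to = "recomputed") %>%
    dplyr::mutate(detection_or = ifelse(.data$statistic == "bfdp",
                                        NA_real_, .data$detection_or)) %>%
    dplyr::distinct()
  cells <- printed %>%
    dplyr::rename(printed = "value") %>%
    dplyr::left_join(recomputed,
                     by = c("row_id", "statistic", "prior", "detection_or")) %>%
    dplyr::mutate(
      deviation = abs(.data$recomputed - .data$printed),
      status = dplyr::case_when(
        is.na(.data$printed) & !is.na(.data$recomputed) ~ "printed_missing",
        is.na(.data$recomputed) ~ "recomputed_undefined",
        TRUE ~ "compared"))
  summary <- cells %>%
    dplyr::filter(.data$status == "compared") %>%
    dplyr::group_by(.data$statistic, .data$prior, .data$detection_or) %>%
    dplyr::summarise(n = dplyr::n(),
                     median_abs_dev = median(.data$deviation),
                     max_abs_dev = max(.data$deviation),
                     .groups = "drop")
  list(cells = cells, summary = summary)
}

#' Write a re-analysis report to disk
#'
#' Emits the table-shaped outputs of a report: the per-record catalogue and
#' long credibility grid as TSV, the noteworthiness counts as JSON, the
#' attributable-risk table (with both joint conventions) as TSV, and the
#' resolved configuration as JSON. Numeric columns keep full double
#' precision.
#'
#' @param report A `"reanalysis"` object.
#' @param out_dir Output directory, created if needed.
#' @param formats Subset of `c("tsv", "json")`.
#' @return Character vector of the files written, invisibly.
#' @export
write_report <- function(report, out_dir, formats = c("tsv", "json")) {
  stopifnot(inherits(report, "reanalysis"))
  formats <- match.arg(formats, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  emit_tsv <- function(df, name) {
    f <- file.path(out_dir, paste0(name, ".tsv"))
    readr::write_tsv(df, f, na = "NA")
    files <<- c(files, f)
  }
  emit_json <- function(x, name) {
    f <- file.path(out_dir, paste0(name, ".json"))
    jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA, null = "null")
    files <<- c(files, f)
  }
  if ("tsv" %in% formats) {
    emit_tsv(report$records, "records")
    if (!is.null(report$profile)) emit_tsv(report$profile, "profile")
    if (!is.null(report$venice)) emit_tsv(report$venice, "venice")
    if (!is.null(report$par)) {
      emit_tsv(report$par$per_snp, "par")
      emit_tsv(report$par$joint, "par_joint")
    }
  }
  if ("json" %in% formats) {
    if (!is.null(report$counts)) emit_json(report$counts, "counts")
    if (!is.null(report$counts_printed)) {
      emit_json(report$counts_printed, "counts_printed")
    }
    emit_json(unclass(report$config), "config")
  }
  invisible(files)
}
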