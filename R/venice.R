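#' Parse a Venice grade string
#'
#' Splits strings of the form `"A + C + C"` (flexible whitespace) into the
#' three Venice criteria grades: amount of evidence, replication of the
#' association, and protection from bias. Each grade must be `A`, `B`, `C`
#' or `NA`.
#'
#' @param text Character vector of grade strings; `NA` elements yield `NA`
#'   grades.
#' @return A tibble with character columns `amount`, `replication`, `bias`.
#' @examples
#' parse_grade_string("A + C + C")
#' @export
parse_grade_string <- function(text) {
  parts <- stringr::str_split(text, stringr::fixed("+"))
  parsed <- purrr::map(seq_along(parts), function(i) {
    if (is.na(text[[i]])) return(rep(NA_character_, 3))
    g <- stringr::str_trim(parts[[i]])
    if (length(g) != 3 || !all(g %in% c("A", "B", "C", "NA"))) {
      bad <- if (length(g) != 3) text[[i]] else g[!g %in% c("A", "B", "C", "NA")][1]
      stop("malformed Venice grade string: \"", bad, "\"", call. = FALSE)
    }
    g
  })
  tibble::tibble(amount = purrr::map_chr(parsed, 1),
                 replication = purrr::map_chr(parsed, 2),
                 bias = purrr::map_chr(parsed, 3))
}

#' Grade the amount of evidence
#'
#' Venice criterion A/B/C from the number of subjects in the minor group
#' (by default the minor-allele count): `A` above the upper threshold, `B`
#' between the thresholds, `C` below the lower one.
#'
#' @param n Non-negative integer count(s).
#' @param thresholds Pair `c(upper, lower)`; defaults `c(1000, 100)`, the
#'   conventional Venice cut-offs.
#' @return Character vector of grades.
#' @examples
#' grade_amount(c(5000, 500, 50))
#' @export
grade_amount <- function(n, thresholds = c(1000, 100)) {
  stopifnot(length(thresholds) == 2, thresholds[1] > thresholds[2])
  dplyr::case_when(is.na(n) ~ NA_character_,
                   n > thresholds[1] ~ "A",
                   n >= thresholds[2] ~ "B",
                   TRUE ~ "C")
}

#' Grade replication of the association from heterogeneity
#'
#' Venice criterion A/B/C from the meta-analytic I-squared statistic: `A`
#' for low heterogeneity, `B` for moderate, `C` for high. `NA` input gives
#' an `NA` grade.
#'
#' @param i_squared I-squared value(s) in `[0, 100]`, or `NA`.
#' @param thresholds Pair `c(low, high)`; defaults `c(25, 50)`.
#' @return Character vector of grades.
#' @examples
#' grade_replication(c(10, 40, 80, NA))
#' @export
grade_replication <- function(i_squared, thresholds = c(25, 50)) {
  stopifnot(length(thresholds) == 2, thresholds[1] < thresholds[2])
  check_range(i_squared, "i_squared", 0, 100, open_lower = FALSE,
              open_upper = FALSE, allow_na = TRUE)
  dplyr::case_when(is.na(i_squared) ~ NA_character_,
                   i_squared < thresholds[1] ~ "A",
                   i_squared <= thresholds[2] ~ "B",
                   TRUE ~ "C")
}

#' Combine Venice grades into a credibility level
#'
#' Maps the three grades to the summary credibility of the cumulative
#' evidence: all `A` gives `"high"`, any `C` gives `"low"` (a `C` is
#' decisive even when other grades are missing), a mix of `A`/`B` with no
#' `C` gives `"intermediate"`, and any missing grade without a `C` gives
#' `NA`. The mapping is symmetric in its three arguments.
#'
#' @param amount,replication,bias Character grade vectors (`"A"`, `"B"`,
#'   `"C"` or `NA`; the literal string `"NA"` is also accepted).
#' @return Character vector with values `"high"`, `"intermediate"`,
#'   `"low"` or `NA`.
#' @examples
#' combine_grades("A", "C", "C")
#' combine_grades("A", "B", "A")
#' @export
combine_grades <- function(amount, replication, bias) {
  g <- cbind(amount, replication, bias)
  g[g == "NA"] <- NA_character_
  apply(g, 1L, function(r) {
    if (any(r == "C", na.rm = TRUE)) return("low")
    if (anyNA(r)) return(NA_character_)
    if (all(r == "A")) return("high")
    "intermediate"
  })
}

#' Venice assessment of a catalogue
#'
#' Convenience wrapper: parses the `venice_grades` column of a catalogue
#' and appends the three grades and the combined credibility level.
#'
#' @param catalog A catalogue tibble with a `venice_grades` column; rows
#'   with no grade string get `NA` throughout.
#' @return The catalogue's identifying columns plus `amount`,
#'   `replication`, `bias` and `credibility`.
#' @export
venice_assess <- function(catalog) {
  catalog <- as_catalog(catalog)
  grades_text <- col_or(catalog, "venice_grades", NA_character_)
  grades <- parse_grade_string(grades_text)
  id_cols <- intersect(c("row_id", "gene", "variant", "comparison"),
                       names(catalog))
  dplyr::bind_cols(
    catalog[id_cols], grades,
    tibble::tibble(credibility = combine_grades(grades$amount,
                                                grades$replication,
                                                grades$bias)))
}
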