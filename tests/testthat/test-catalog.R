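test_that("read/write round-trips a well-formed catalogue", {
  cat0 <- dplyr::bind_rows(
    make_record("rs1", odds_ratio = 1.19, ci_lower = 1.06, ci_upper = 1.33),
    make_record("rs2", odds_ratio = 0.88, ci_lower = 0.79, ci_upper = 0.98),
    make_record("rs3", study_type = "gwas", p_value = 3.81e-10,
                odds_ratio = 2.44, ci_lower = 1.85, ci_upper = 3.23))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_catalog(cat0, path)
  back <- read_catalog(path)
  expect_equal(nrow(back), 3L)
  common <- setdiff(names(cat0), "row_id")
  expect_equal(as.data.frame(back[common]), as.data.frame(cat0[common]),
               ignore_attr = TRUE)
  # and once more: the round-trip is a fixed point
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_catalog(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("schema and row-level validation fail informatively", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(variant = "rs1", odds_ratio = 1.2), path)
  expect_error(read_catalog(path), "mandatory column")

  bad <- make_record("rs1", odds_ratio = 1.05, ci_lower = 1.10,
                     ci_upper = 1.42)
  path_bad <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(bad, path_bad)
  expect_error(read_catalog(path_bad), "confidence interval in row\\(s\\): 1")

  expect_error(read_catalog(withr::local_tempfile(fileext = ".tsv")),
               "not found")
})

test_that("dash and NA cells become missing values", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("variant\tcomparison\todds_ratio\tci_lower\tci_upper\tstudy_type\tp_value\tmaf",
               "rs1\tA vs. G\t1.2\t1.1\t1.3\tgwas\t–\tNA"), path)
  cat1 <- read_catalog(path)
  expect_true(is.na(cat1$p_value))
  expect_true(is.na(cat1$maf))
})

test_that("bundled fixtures have the published shape", {
  t1 <- load_fixture("table1")
  expect_equal(nrow(t1), 19L)
  expect_equal(dplyr::n_distinct(t1$variant), 8L)
  expect_true(all(t1$study_type == "observational"))

  t2 <- load_fixture("table2")
  expect_equal(nrow(t2), 47L)
  expect_true(all(t2$study_type == "gwas"))

  t6 <- load_fixture("table6")
  expect_equal(nrow(t6), 36L)
  expect_true(all(!is.na(t6$maf)))

  expect_error(load_fixture("table9"), "arg")
})

test_that("fixture printed statistics match frozen checksums", {
  # guards the transcriptions against accidental edits
  t2 <- load_fixture("table2")
  m2 <- as.matrix(t2[grep("^(fprp|bfdp)", names(t2), value = TRUE)])
  expect_equal(length(m2), 282L)
  expect_equal(sum(is.na(m2)), 36L)      # 9 rows x 4 not-computable FPRP cells
  expect_equal(sum(m2, na.rm = TRUE), 52.617544059, tolerance = 1e-9)

  t1 <- load_fixture("table1")
  m1 <- as.matrix(t1[grep("^(fprp|bfdp)", names(t1), value = TRUE)])
  expect_equal(sum(is.na(m1)), 0L)
  expect_equal(sum(m1), 83.927, tolerance = 1e-9)

  t6 <- load_fixture("table6")
  expect_equal(sum(t6$par_printed), 79.6612410313, tolerance = 1e-9)
})

test_that("printed_stats pivots the grid correctly", {
  ps <- printed_stats(load_fixture("table1"))
  expect_equal(nrow(ps), 19L * 6L)
  expect_setequal(unique(ps$prior), c(0.05, 0.001))
  expect_setequal(unique(ps$detection_or), c(1.2, 1.5, NA))
  expect_true(all(is.na(ps$detection_or[ps$statistic == "bfdp"])))
  one <- ps[ps$variant == "rs1801133" & ps$statistic == "fprp" &
              ps$prior == 0.05 & ps$detection_or == 1.2 &
              ps$comparison == "T vs. C", ]
  expect_equal(one$value, 0.069)
})

test_that("deduplication keeps the newer, larger meta-analysis", {
  dup <- dplyr::bind_rows(
    make_record("rs1801133", "T vs. C", year = 2015, n_cases = 500),
    make_record("rs1801133", "T vs. C", year = 2019, n_cases = 900))
  kept <- deduplicate(dup)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$year, 2019)

  tie_year <- dplyr::bind_rows(
    make_record("rs2", year = 2018, n_cases = 500, n_controls = 500),
    make_record("rs2", year = 2018, n_cases = 1000, n_controls = 1000))
  expect_equal(deduplicate(tie_year)$n_cases, 1000)

  full_tie <- dplyr::bind_rows(
    make_record("rs3", p_value = 0.01),
    make_record("rs3", p_value = 0.02))
  expect_warning(kept3 <- deduplicate(full_tie), "tie")
  expect_equal(kept3$p_value, 0.01)  # first seen

  single <- make_record("rs4")
  expect_equal(nrow(deduplicate(single)), 1L)
})

test_that("deduplication is idempotent and keys include subgroup fields", {
  mixed <- dplyr::bind_rows(
    make_record("rs1", subtype = "overall"),
    make_record("rs1", subtype = "MA"),
    make_record("rs1", subtype = "MO"),
    make_record("rs1", ethnicity = "Caucasian"))
  once <- deduplicate(mixed)
  expect_equal(nrow(once), 4L)  # distinct keys all coexist
  expect_equal(deduplicate(once), once)
  t1 <- load_fixture("table1")
  expect_equal(nrow(deduplicate(t1)), nrow(t1))
})

test_that("significance filtering applies type-specific thresholds and the CI rule", {
  cat0 <- dplyr::bind_rows(
    make_record("gw_in", study_type = "gwas", p_value = 3e-8,
                odds_ratio = 1.10, ci_lower = 1.06, ci_upper = 1.14),
    make_record("gw_out", study_type = "gwas", p_value = 1e-7,
                odds_ratio = 1.10, ci_lower = 1.06, ci_upper = 1.14),
    make_record("obs_ci_out", p_value = 0.04, odds_ratio = 1.10,
                ci_lower = 0.98, ci_upper = 1.23),
    make_record("obs_in", p_value = 0.04, odds_ratio = 1.10,
                ci_lower = 1.01, ci_upper = 1.20),
    make_record("obs_at_threshold", p_value = 0.05, odds_ratio = 1.10,
                ci_lower = 1.01, ci_upper = 1.20))
  kept <- filter_significant(cat0)
  expect_setequal(kept$variant, c("gw_in", "obs_in"))
})

test_that("missing p-values are reconstructed from the interval before filtering", {
  cat0 <- make_record("rs_na_p", p_value = NA_real_, odds_ratio = 1.50,
                      ci_lower = 1.30, ci_upper = 1.73)
  expect_equal(nrow(filter_significant(cat0)), 1L)
  weak <- make_record("rs_weak", p_value = NA_real_, odds_ratio = 1.05,
                      ci_lower = 1.001, ci_upper = 1.101)
  # reconstructed p ~ 0.045: kept at 0.05, dropped at 0.01
  expect_equal(nrow(filter_significant(weak, obs_alpha = 0.01)), 0L)
  expect_equal(nrow(filter_significant(weak, obs_alpha = 0.05)), 1L)
})

test_that("significance filtering is a subset operation and idempotent", {
  t2 <- load_fixture("table2")
  once <- filter_significant(t2)
  expect_true(all(once$row_id %in% t2$row_id))
  expect_equal(filter_significant(once), once)
})
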