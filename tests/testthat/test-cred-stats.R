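test_that("se_from_ci inverts published intervals", {
  # frozen from independent evaluation of (ln U - ln L) / (2 z_{0.975})
  expect_equal(se_from_ci(1.19, 1.06, 1.33), 0.057886276, tolerance = 1e-7)
  expect_equal(se_from_ci(0.90, 0.89, 0.91), 0.0056692717, tolerance = 1e-8)
  # symmetric construction inverts exactly
  k <- exp(qnorm(0.975))
  expect_equal(se_from_ci(2.0, 2.0 / k, 2.0 * k), 1.0, tolerance = 1e-12)
  # 90% interval uses the matching quantile
  expect_equal(se_from_ci(1.5, 1.2, 1.875, level = 0.90),
               log(1.875 / 1.2) / (2 * qnorm(0.95)), tolerance = 1e-12)

  expect_error(se_from_ci(1.2, 1.3, 1.1), "strictly below")
  expect_error(se_from_ci(1.2, -1, 1.5), "out of range")
})

test_that("z_and_p reproduces the normal tail and survives extreme z", {
  eff <- z_and_p(1.19, 0.057886)
  expect_equal(eff$z, 3.0051015, tolerance = 1e-6)
  expect_equal(eff$p_two_sided, 0.00265492, tolerance = 1e-5)
  expect_equal(eff$log_or / eff$se, eff$z, tolerance = 1e-12)

  null <- z_and_p(1.0, 0.3)
  expect_equal(null$z, 0)
  expect_equal(null$p_two_sided, 1)

  # strongly protective variant with a tight interval: p underflows but
  # log_p must not; oracle is the Mills-ratio asymptotic tail series
  extreme <- z_and_p(0.90, 0.0056692)
  z <- abs(extreme$z)
  oracle_log10p <- (log(2) - z^2 / 2 - log(z * sqrt(2 * pi)) +
                      log1p(-1 / z^2 + 3 / z^4)) / log(10)
  expect_equal(extreme$log_p / log(10), oracle_log10p, tolerance = 1e-4)
  expect_equal(extreme$log_p / log(10), -76.369, tolerance = 0.2)
  expect_true(is.finite(z_and_p(exp(50 * 0.01), 0.01)$log_p))  # |z| = 50
})

test_that("p decreases strictly as |z| grows", {
  zs <- seq(0.5, 40, by = 0.5)
  logp <- z_and_p(exp(zs * 0.1), 0.1)$log_p
  expect_true(all(diff(logp) < 0))
})

test_that("power_to_detect matches hand-evaluated cases and limits", {
  expect_equal(power_to_detect(1.2, 0.057886, alpha_mode = "fixed"),
               0.8829184, tolerance = 1e-5)
  expect_equal(power_to_detect(1.2, 0.057886, alpha_mode = "observed_p",
                               observed_z = 3.0051),
               0.5575, tolerance = 1e-3)
  # se -> 0: any fixed-level test detects the effect with certainty
  expect_equal(power_to_detect(1.2, 1e-8, alpha_mode = "fixed"), 1)
  expect_error(power_to_detect(1.2, 0.1), "observed_z")
})

test_that("power is increasing in detection OR and decreasing in se", {
  ors <- c(1.05, 1.1, 1.2, 1.5, 2, 3)
  pw <- power_to_detect(ors, 0.1, alpha_mode = "fixed")
  expect_true(all(diff(pw) > 0))
  ses <- c(0.02, 0.05, 0.1, 0.2, 0.5)
  pw2 <- power_to_detect(1.5, ses, alpha_mode = "fixed")
  expect_true(all(diff(pw2) < 0))
})

test_that("fprp matches closed-form cases", {
  expect_equal(fprp(0.05, 1, 0.5), 0.05 / 1.05, tolerance = 1e-12)
  expect_equal(fprp(0.004, 0.88293, 0.05), 0.0792550, tolerance = 1e-5)
  # p -> 0 with positive power drives FPRP to 0
  expect_lt(fprp(1e-300, 0.5, 0.05), 1e-290)
  # joint underflow of p and power is undefined, not an error or a 0/0
  expect_true(is.na(fprp(1e-300, 0, 0.5, log_p = -Inf, log_power = -Inf)))
})

test_that("bfdp matches algebraic reductions and stays finite at extreme z", {
  # z = 0 and V = W reduce BFDP at pi = 0.5 to sqrt(2)/(sqrt(2)+1)
  W <- (log(1.5) / qnorm(0.975))^2
  expect_equal(bfdp(0, sqrt(W), 0.5), sqrt(2) / (sqrt(2) + 1),
               tolerance = 1e-12)
  expect_equal(bfdp(log(1.19), 0.057886, 0.05), 0.517069, tolerance = 1e-4)
  # protective extreme: log-space value survives far below underflow
  expect_equal(bfdp(log(0.90), 0.0056692, 0.001, log = TRUE) / log(10),
               -70.3827, tolerance = 0.5)
})

test_that("log-space FPRP and BFDP agree with naive evaluation for |z| <= 8", {
  withr::local_seed(421)
  for (i in 1:200) {
    se <- runif(1, 0.01, 0.5)
    z <- runif(1, -8, 8)
    prior <- 10^runif(1, -6, -0.5)
    or1 <- runif(1, 1.05, 2)
    eff <- z_and_p(exp(z * se), se)
    pw <- power_to_detect(or1, se, alpha_mode = "observed_p",
                          observed_z = z)
    expect_equal(fprp(eff$p_two_sided, pw, prior,
                      log_p = eff$log_p,
                      log_power = power_to_detect(
                        or1, se, alpha_mode = "observed_p",
                        observed_z = z, log = TRUE)),
                 naive_fprp(eff$p_two_sided, pw, prior),
                 tolerance = 1e-10)
    expect_equal(bfdp(z * se, se, prior),
                 naive_bfdp(z * se, se, prior),
                 tolerance = 1e-10)
  }
})

test_that("FPRP and BFDP are strictly decreasing in the prior", {
  priors <- 10^seq(-8, -0.5, length.out = 12)
  f <- fprp(0.003, 0.85, priors)
  b <- bfdp(log(1.2), 0.05, priors)
  expect_true(all(diff(f) < 0))
  expect_true(all(diff(b) < 0))
  # BFDP -> 1 as the prior vanishes
  expect_equal(bfdp(log(1.2), 0.05, 1e-15), 1, tolerance = 1e-4)
  # FPRP strictly decreasing in power
  powers <- seq(0.05, 1, by = 0.05)
  expect_true(all(diff(fprp(0.003, powers, 0.01)) < 0))
})

test_that("all credibility outputs are probabilities", {
  withr::local_seed(77)
  for (i in 1:300) {
    se <- 10^runif(1, -3, 0.5)
    or <- exp(rnorm(1, 0, 1.5))
    prior <- 10^runif(1, -9, -0.1)
    or1 <- 1 + 10^runif(1, -2, 0.7)
    eff <- z_and_p(or, se)
    pw <- power_to_detect(or1, se, alpha_mode = "observed_p",
                          observed_z = eff$z)
    f <- fprp(eff$p_two_sided, pw, prior, log_p = eff$log_p)
    b <- bfdp(eff$log_or, se, prior)
    expect_true(pw >= 0 && pw <= 1)
    expect_true(is.na(f) || (f >= 0 && f <= 1))
    expect_true(b >= 0 && b <= 1)
  }
})

test_that("profiles are invariant under OR <-> 1/OR", {
  risk <- make_record("rs_sym", odds_ratio = 1.25, ci_lower = 1.10,
                      ci_upper = 1.42, p_value = NA_real_)
  prot <- make_record("rs_sym", odds_ratio = 1 / 1.25,
                      ci_lower = 1 / 1.42, ci_upper = 1 / 1.10,
                      p_value = NA_real_)
  p1 <- credibility_profile(risk)
  p2 <- credibility_profile(prot)
  for (col in c("p_two_sided", "power", "fprp", "bfdp")) {
    expect_equal(p1[[col]], p2[[col]], tolerance = 1e-10)
  }
})

test_that("the profile grid has one row per record-prior-OR combination", {
  cfg <- cred_config(priors = c(0.01, 0.001), detection_ors = c(1.2, 1.5))
  prof <- credibility_profile(make_record("rs1"), cfg)
  expect_equal(nrow(prof), 4L)
  expect_equal(nrow(dplyr::distinct(prof, prior, detection_or)), 4L)
  # BFDP is constant across detection ORs within a prior
  expect_equal(dplyr::n_distinct(prof$bfdp[prof$prior == 0.01]), 1L)
})

test_that("study-type defaults pick the conventional prior ladders", {
  both <- dplyr::bind_rows(
    make_record("rs_obs", study_type = "observational"),
    make_record("rs_gwas", study_type = "gwas", p_value = 1e-9))
  prof <- credibility_profile(both)
  expect_setequal(unique(prof$prior[prof$variant == "rs_obs"]),
                  c(0.05, 0.001))
  expect_setequal(unique(prof$prior[prof$variant == "rs_gwas"]),
                  c(0.001, 1e-6))
})

test_that("recomputed values track the printed cells of a published row", {
  t1 <- load_fixture("table1")
  row <- t1[t1$variant == "rs1801133" & t1$comparison == "T vs. C", ]
  prof <- credibility_profile(row)
  for (or1 in c(1.2, 1.5)) for (pi in c(0.05, 0.001)) {
    got <- prof$fprp[prof$detection_or == or1 & prof$prior == pi]
    expect_lt(abs(got - row[[sprintf("fprp_or%s_%s", or1, pi)]]), 0.06)
  }
  for (pi in c(0.05, 0.001)) {
    got <- unique(prof$bfdp[prof$prior == pi])
    expect_lt(abs(got - row[[sprintf("bfdp_%s", pi)]]), 0.06)
  }
})
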