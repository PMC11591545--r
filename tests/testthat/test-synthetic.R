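# Synthetic cohort generator: covariate calibration, observation model,
# determinism, and study-replica structure.

test_that("covariate draws match the cohort's demographic summaries", {
  cfg <- cohort_config(n_subjects = 10000, force_low_crcl = FALSE)
  cov <- sample_covariates(cfg, seed = 41)
  expect_equal(mean(cov$AGE), 57, tolerance = 0.02)
  expect_equal(sd(cov$AGE), 9, tolerance = 0.1)
  expect_equal(mean(cov$BSA), 1.95, tolerance = 0.02)
  expect_equal(mean(cov$CRCL), 90.8, tolerance = 0.05)
  expect_equal(mean(cov$ALB), 42.5, tolerance = 0.02)
  expect_equal(median(cov$WT), 76, tolerance = 0.02)
  expect_equal(unname(diff(quantile(cov$WT, c(0.25, 0.75)))), 20,
               tolerance = 0.1)
  expect_true(all(cov$PB >= 96 & cov$PB <= 98))
  expect_true(all(cov$CRCL >= 30)) # truncation, no engineered subject

  cfg1 <- cohort_config(n_subjects = 13)
  cov1 <- sample_covariates(cfg1, seed = 4)
  expect_lt(cov1$CRCL[1], 30)    # the engineered renal-impairment subject
  expect_gte(min(cov1$CRCL), 15)
  expect_true(all(cov1$CRCL[-1] >= 30))
})

test_that("noise-free cohorts reproduce the analytic typical curve", {
  m0 <- pop_model(dalbavancin_params(), omega = c(CL = 0, V1 = 0, V2 = 0),
                  error_b = 0)
  cfg <- cohort_config(n_subjects = 3, truth = m0, force_low_crcl = FALSE)
  d <- generate_cohort(cfg, seed = 6)
  obs <- dplyr::filter(tibble::as_tibble(d), EVID == 0, ANALYTE == "total")
  expected <- conc_profile(dalbavancin_params(),
                           regimen_preset("1500_d1_d8_q6w"),
                           c(1, 168, 1008))$conc
  for (id in unique(obs$ID)) {
    expect_equal(obs$DV[obs$ID == id], expected, tolerance = 1e-12)
  }
})

test_that("cohort structure mirrors the study design", {
  d <- generate_cohort(cohort_config(), seed = 51)
  dt <- tibble::as_tibble(d)
  expect_equal(length(unique(dt$ID)), 13)
  expect_equal(sum(dt$EVID == 0 & dt$ANALYTE == "total"), 39) # 13 x 3
  # dose reduction for the low-CrCl subject
  tr <- cohort_truth(d)
  low <- tr$id[tr$CRCL < 30]
  expect_length(low, 1)
  expect_true(all(dt$AMT[dt$ID == low & dt$EVID == 1] == 1000))
  expect_true(all(dt$AMT[dt$ID != low & dt$EVID == 1] == 1500))
  # per-subject binding within the observed range
  expect_true(all(tr$PB >= 96 & tr$PB <= 98))
  # unbound observations scale with (1 - PB)
  expect_true(all(c("total", "unbound") %in% dt$ANALYTE[dt$EVID == 0]))

  # strict replica mode drops records
  d38 <- generate_cohort(cohort_config(n_missing = 1), seed = 51)
  expect_equal(sum(tibble::as_tibble(d38)$EVID == 0 &
                     tibble::as_tibble(d38)$ANALYTE == "total"), 38)
})

test_that("generation is seed-deterministic and eta moments match omega", {
  c1 <- generate_cohort(cohort_config(), seed = 77)
  c2 <- generate_cohort(cohort_config(), seed = 77)
  expect_identical(tibble::as_tibble(c1), tibble::as_tibble(c2))
  expect_identical(cohort_truth(c1), cohort_truth(c2))

  big <- generate_cohort(cohort_config(n_subjects = 4000,
                                       force_low_crcl = FALSE), seed = 3)
  tr <- cohort_truth(big)
  expect_equal(sd(tr$eta_CL), 0.230, tolerance = 0.05)
  expect_equal(sd(tr$eta_V2), 0.410, tolerance = 0.05)
  expect_equal(mean(tr$eta_V1), 0, tolerance = 0.02)
})

test_that("cohort summaries track the observed concentration scale", {
  d <- generate_cohort(cohort_config(), seed = 19)
  s <- summarize_cohort(d)
  expect_equal(s$time, c(1, 168, 1008))
  expect_equal(s$n, rep(13L, 3))
  # single-cohort scatter is wide; the scale must still be right
  expect_equal(s$mean[s$time == 1], 218.4, tolerance = 0.35)
  expect_equal(s$mean[s$time == 168], 41.1, tolerance = 0.35)
  expect_error(summarize_cohort(tibble::as_tibble(d)[0, ]), "Empty")
  expect_identical(summarize_cohort(d), summarize_cohort(d))
})
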