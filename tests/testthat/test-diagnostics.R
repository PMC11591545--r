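# Goodness of fit, VPC calibration and misfit detection, bootstrap,
# shrinkage, conditioning.

test_that("individual predictions outperform population predictions", {
  d <- replica_cohort(25, seed = 45)
  ft <- suppressWarnings(fit_popmodel(d, control = fast_ctrl(), seed = 5))
  g <- gof(ft)
  expect_gt(g$r2_individual, g$r2_population)
  expect_gt(g$r2_population, 0.5)
  expect_lte(g$r2_individual, 1)
  expect_equal(nrow(g$table), ft$n_obs)

  # near-perfect data give R^2 ~ 1 for both
  m0 <- pop_model(dalbavancin_params(), omega = c(CL = 0, V1 = 0, V2 = 0),
                  error_b = 1e-3)
  d0 <- impute_bql(generate_cohort(
    cohort_config(n_subjects = 6, truth = m0, force_low_crcl = FALSE,
                  sample_times = c(1, 24, 168, 504, 1008), ql_total = 1e-9),
    seed = 6), ql_total = 1e-9)
  f0 <- suppressWarnings(fit_popmodel(d0, control = fast_ctrl(), seed = 2))
  g0 <- gof(f0)
  expect_gt(g0$r2_population, 0.999)
  expect_gt(g0$r2_individual, 0.999)
})

test_that("VPC bands cover self-simulated data and collapse at n_sim = 1", {
  d <- replica_cohort(40, seed = 71)
  ft <- suppressWarnings(fit_popmodel(d,
    control = saem_control(250, 120, n_mc_ll = 200), seed = 5))
  v <- vpc(ft, n_sim = 500, seed = 9)
  expect_equal(nrow(v), 9L) # 3 nominal times x 3 percentiles
  expect_true(all(v$band_lower <= v$band_upper))
  inside <- v$observed >= v$band_lower & v$observed <= v$band_upper
  expect_gte(mean(inside), 7 / 9) # nominal ~95% bands, binomial slack

  v1 <- vpc(ft, n_sim = 1, seed = 9)
  expect_true(all(v1$band_lower == v1$band_upper))
  expect_true(all(v1$band_lower == v1$sim_median))
})

test_that("VPC flags data simulated with doubled clearance", {
  cfg_ok <- cohort_config(n_subjects = 40)
  d_ok <- impute_bql(generate_cohort(cfg_ok, seed = 81))
  ft <- suppressWarnings(fit_popmodel(d_ok,
    control = saem_control(250, 120, n_mc_ll = 200), seed = 5))

  # same design, but the data come from a model with twice the clearance
  fast <- dalbavancin_popmodel()
  fast_truth <- pop_model(pk_params(0.100, 6.5, 0.476, 15.4),
                          omega = fast$omega, error_b = fast$error_b)
  d_fast <- impute_bql(generate_cohort(
    cohort_config(n_subjects = 40, truth = fast_truth), seed = 81))
  obs_fast <- dplyr::filter(tibble::as_tibble(d_fast), EVID == 0,
                            ANALYTE == "total")
  obs_fast <- dplyr::arrange(obs_fast, ID, TIME)
  ft_mis <- ft
  ft_mis$sdata$obs$y <- obs_fast$DV # swap in the misfit observations

  v <- vpc(ft_mis, n_sim = 400, seed = 13)
  # at the day-8 trough the doubled clearance has already drained the
  # profile well below the band (the week-6 bin is floored at QL/2 for
  # both observed and simulated values, so it cannot discriminate)
  mis_med <- dplyr::filter(v, bin_time == 168, percentile == 50)
  expect_lt(mis_med$observed, mis_med$band_lower)
})

test_that("bootstrap collapses on a noise-free cohort and is reproducible", {
  m0 <- pop_model(dalbavancin_params(), omega = c(CL = 0, V1 = 0, V2 = 0),
                  error_b = 1e-3)
  cfg <- cohort_config(n_subjects = 5, truth = m0, force_low_crcl = FALSE,
                       sample_times = c(1, 24, 168, 504, 1008), ql_total = 1e-9)
  d <- impute_bql(generate_cohort(cfg, seed = 7), ql_total = 1e-9)
  ctrl <- saem_control(150, 80, n_mc_ll = 100)
  b1 <- bootstrap_fit(d, n_boot = 8, seed = 11, control = ctrl)
  expect_equal(b1$n_failed, 0L)
  expect_false(b1$quality_warning)
  s <- b1$summary
  cl <- s[s$term == "CL", ]
  expect_lt((cl$ci_upper - cl$ci_lower) / cl$mean, 5e-3)
  expect_true(cl$ci_lower <= cl$mean && cl$mean <= cl$ci_upper)

  b2 <- bootstrap_fit(d, n_boot = 8, seed = 11, control = ctrl)
  expect_identical(b1$summary, b2$summary)
  expect_identical(b1$replicates, b2$replicates)
})

test_that("bootstrap re-estimates straddle the full-data estimates", {
  d <- replica_cohort(13, seed = 23)
  ctrl <- saem_control(150, 80, n_mc_ll = 100)
  ft <- suppressWarnings(fit_popmodel(d, control = ctrl, seed = 3))
  bt <- bootstrap_fit(d, n_boot = 20, seed = 4, control = ctrl)
  expect_lte(bt$n_failed, 4L)
  for (tm in c("CL", "V1", "V2")) {
    row <- bt$summary[bt$summary$term == tm, ]
    est <- ft$typical[[tm]]
    expect_lt(row$ci_lower, est * 1.1)
    expect_gt(row$ci_upper, est * 0.9)
    expect_equal(row$mean, est, tolerance = 0.25)
  }
})

test_that("shrinkage spans its extremes with the information content", {
  # rich design: shrinkage near zero
  rich <- cohort_config(n_subjects = 20, force_low_crcl = FALSE,
                        sample_times = c(1, 6, 24, 72, 168, 336, 672, 1008))
  d_rich <- impute_bql(generate_cohort(rich, seed = 9))
  f_rich <- suppressWarnings(fit_popmodel(d_rich, control = fast_ctrl(), seed = 2))
  s_rich <- shrinkage(f_rich)
  expect_true(all(abs(s_rich$shrinkage) < 35))

  # a single trough sample per subject cannot resolve three random effects:
  # the EBEs collapse toward the population mean
  sparse1 <- cohort_config(n_subjects = 25, force_low_crcl = FALSE,
                           sample_times = c(168))
  d_sp <- impute_bql(generate_cohort(sparse1, seed = 10))
  f_sp <- suppressWarnings(fit_popmodel(d_sp, control = fast_ctrl(), seed = 3))
  s_sp <- shrinkage(f_sp)
  expect_gt(mean(s_sp$shrinkage), 50)
  expect_gt(max(s_sp$shrinkage), 70)
})

test_that("condition ratio is 1 for independent estimates and flags collinearity", {
  d <- replica_cohort(8, seed = 5)
  ft <- suppressWarnings(fit_popmodel(d, control = fast_ctrl(), seed = 1))
  expect_equal(as.numeric(condition_ratio(ft, cov = diag(4))), 1)
  near_sing <- matrix(c(1, 0.999999999999, 0.999999999999, 1), 2)
  cr <- condition_ratio(ft, cov = near_sing)
  expect_true(attr(cr, "capped") || cr > 1e6)
})
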