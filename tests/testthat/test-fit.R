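# SAEM estimation: degenerate noise-free limit, determinism and
# exchangeability, likelihood consistency, model comparison, standard errors.

test_that("noise-free dense data reduce the fit to nonlinear least squares", {
  m0 <- pop_model(dalbavancin_params(), omega = c(CL = 0, V1 = 0, V2 = 0),
                  error_b = 1e-3)
  cfg <- cohort_config(n_subjects = 12, truth = m0, force_low_crcl = FALSE,
                       sample_times = c(0.75, 1, 2, 6, 24, 72, 168, 336, 672, 1008),
                       ql_total = 1e-9, ql_unbound = 1e-12)
  d <- impute_bql(generate_cohort(cfg, seed = 3), ql_total = 1e-9,
                  ql_unbound = 1e-12)
  ft <- suppressWarnings(
    fit_popmodel(d, control = saem_control(300, 200, n_mc_ll = 200), seed = 5))
  expect_equal(ft$typical[["CL"]], 0.050, tolerance = 1e-3)
  expect_equal(ft$typical[["V1"]], 6.5, tolerance = 1e-3)
  expect_equal(ft$typical[["V2"]], 15.4, tolerance = 1e-3)
  expect_lt(ft$error[["b"]], 0.005) # residual error collapses with the noise
})

test_that("fits are seed-deterministic and invariant to subject order", {
  d <- replica_cohort(20, seed = 15)
  ctrl <- fast_ctrl()
  f1 <- suppressWarnings(fit_popmodel(d, control = ctrl, seed = 2))
  f2 <- suppressWarnings(fit_popmodel(d, control = ctrl, seed = 2))
  expect_identical(f1$typical, f2$typical)
  expect_identical(f1$ofv, f2$ofv)

  ids <- withr::with_seed(99, sample(unique(d$ID)))
  d_perm <- dplyr::bind_rows(lapply(ids, function(i) d[d$ID == i, ]))
  f3 <- suppressWarnings(fit_popmodel(d_perm, control = ctrl, seed = 2))
  expect_identical(f1$typical, f3$typical)
  expect_identical(f1$omega, f3$omega)
})

test_that("importance-sampling OFV matches Gauss-Hermite quadrature on a toy", {
  skip_if_not_installed("pracma")
  times <- c(2, 24, 100)
  y <- c(8.5, 7.0, 4.4)
  d1 <- tibble::tibble(
    ID = 1L, TIME = c(0, times), EVID = c(1L, 0L, 0L, 0L),
    AMT = c(1000, NA, NA, NA), DUR = c(0.5, NA, NA, NA),
    DV = c(NA, y), BQL = c(NA, 0L, 0L, 0L),
    ANALYTE = c(NA, rep("total", 3)),
    WT = 76, BSA = 1.95, AGE = 57, CRCL = 90, ALB = 42, PB = 97)
  sp <- model_spec(n_compartments = 1, fixed = c(V1 = 10))
  ft <- suppressWarnings(fit_popmodel(
    d1, sp, init = list(typical = c(CL = 0.5), omega = c(CL = 0.4),
                        error_b = 0.15),
    control = saem_control(200, 100, n_mc_ll = 1000), seed = 3))
  ofv_is <- log_likelihood(ft, n_mc = 50000, seed = 7)$ofv

  # independent oracle: 80-node Gauss-Hermite integral over the single
  # log-normal random effect, with its own one-compartment infusion formula
  gh <- pracma::gaussHermite(80)
  f1cmt <- function(CL, t) {
    k <- CL / 10; R0 <- 1000 / 0.5
    ifelse(t <= 0.5, R0 / CL * (1 - exp(-k * t)),
           R0 / CL * (1 - exp(-k * 0.5)) * exp(-k * (t - 0.5)))
  }
  mu <- log(ft$typical[["CL"]]); om <- ft$omega[["CL"]]; b <- ft$error[["b"]]
  L <- sum(gh$w * vapply(gh$x, function(x) {
    f <- f1cmt(exp(mu + sqrt(2) * om * x), times)
    prod(dnorm(y, f, b * abs(f)))
  }, numeric(1))) / sqrt(pi)
  expect_lt(abs(ofv_is - (-2 * log(L))), 0.1)

  # doubling the Monte Carlo size roughly halves the OFV variance
  se_small <- log_likelihood(ft, n_mc = 2000, seed = 11)$mc_se
  se_large <- log_likelihood(ft, n_mc = 8000, seed = 11)$mc_se
  expect_lt(se_large, se_small)
})

test_that("AIC prefers the two-compartment model on two-compartment data", {
  cfg <- cohort_config(n_subjects = 30, sample_times = c(1, 6, 24, 168, 1008))
  d <- impute_bql(generate_cohort(cfg, seed = 15))
  ctrl <- saem_control(200, 100, n_mc_ll = 1000)
  f2 <- suppressWarnings(fit_popmodel(d, model_spec(2), control = ctrl, seed = 2))
  f1 <- suppressWarnings(fit_popmodel(d, model_spec(1, fixed = c()),
                                      control = ctrl, seed = 2))
  expect_lt(f2$aic, f1$aic)
  # fixing Q removes it from the free-parameter count: 3 mu + 3 omega + b
  expect_equal(f2$n_param, 7L)
  expect_equal(f1$n_param, 5L)
  expect_equal(f2$aic, f2$ofv + 2 * 7)
  expect_equal(f2$bic, f2$ofv + log(30) * 7)
})

test_that("information-matrix RSEs mirror the sparse-design pattern", {
  d13 <- replica_cohort(13, seed = 23)
  f13 <- suppressWarnings(
    fit_popmodel(d13, control = saem_control(300, 150, n_mc_ll = 500), seed = 3))
  se <- standard_errors(f13, seed = 1)
  struct <- se$rse[se$term %in% c("CL", "V1", "V2")]
  expect_true(all(struct < 30)) # structural parameters well determined
  expect_gt(se$rse[se$term == "b"], max(struct)) # error SD is the weak spot
  expect_true(all(se$se > 0))
  cr <- condition_ratio(f13, cov = attr(se, "cov"))
  expect_gte(cr, 1)
  expect_lt(cr, 50) # no overparameterization flag on the final model
})

test_that("observations before any dose are rejected", {
  d <- tibble::as_tibble(replica_cohort(3, seed = 2))
  d$TIME[which(d$EVID == 1)[1]] <- 2 # subject 1's day-1 sample now precedes its dose
  d <- dplyr::arrange(d, ID, TIME, dplyr::desc(EVID))
  expect_error(suppressWarnings(fit_popmodel(d, control = fast_ctrl(), seed = 1)),
               "precedes every dose")
})
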