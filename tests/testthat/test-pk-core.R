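# Deterministic two-compartment kinetics: rate constants, analytic
# concentration and AUC against independent numerical oracles.

ref <- dalbavancin_params()

test_that("micro rate constants follow the clearance/volume ratios", {
  k <- micro_rates(ref)
  expect_equal(k$k10, 0.050 / 6.5, tolerance = 1e-12)
  expect_equal(k$k12, 0.476 / 6.5, tolerance = 1e-12)
  expect_equal(k$k21, 0.476 / 15.4, tolerance = 1e-12)

  unit <- pk_params(1, 1, 1, 1)
  expect_equal(unlist(micro_rates(unit)), c(k10 = 1, k12 = 1, k21 = 1))

  one_cmt <- pk_params(1, 1, 0, 1)
  expect_equal(unlist(micro_rates(one_cmt))[c("k12", "k21")],
               c(k12 = 0, k21 = 0))
  expect_error(pk_params(-1, 1, 1, 1), "positive")
})

test_that("hybrid constants match the eigenvalues of the rate matrix", {
  k <- micro_rates(ref)
  A <- matrix(c(-(k$k10 + k$k12), k$k21, k$k12, -k$k21), 2, 2, byrow = TRUE)
  ev <- sort(-eigen(A, only.values = TRUE)$values) # both positive
  m <- macro_constants(ref)
  expect_equal(m$beta, ev[1], tolerance = 1e-10)
  expect_equal(m$alpha, ev[2], tolerance = 1e-10)
  # magnitudes of the dalbavancin disposition phases
  expect_equal(m$beta, 2.17e-3, tolerance = 0.01)
  expect_equal(m$alpha, 1.10e-1, tolerance = 0.01)

  # Vieta identities on random valid parameter draws
  withr::with_seed(11, {
    for (i in 1:20) {
      p <- pk_params(CL = runif(1, 0.01, 5), V1 = runif(1, 1, 50),
                     Q = runif(1, 0.05, 5), V2 = runif(1, 1, 50))
      kk <- micro_rates(p)
      mm <- macro_constants(p)
      expect_equal(mm$alpha + mm$beta, kk$k10 + kk$k12 + kk$k21,
                   tolerance = 1e-12)
      expect_equal(mm$alpha * mm$beta, kk$k10 * kk$k21, tolerance = 1e-12)
      expect_gt(mm$alpha, mm$beta)
    }
  })

  # one-compartment limit
  m1 <- macro_constants(pk_params(1, 1, 0, 1))
  expect_equal(m1$alpha, 1)
  expect_equal(m1$coefB, 0)
})

test_that("terminal half-life is ln2 over the slow phase and scale-invariant", {
  m <- macro_constants(ref)
  expect_equal(terminal_half_life(ref), log(2) / m$beta)
  expect_equal(terminal_half_life(ref), 3.2e2, tolerance = 0.01)
  expect_equal(terminal_half_life(pk_params(1, 1, 0, 1)), log(2))
  # scaling CL, Q by c and V1, V2 by c leaves every rate unchanged
  c_ <- 3.7
  scaled <- pk_params(ref$CL * c_, ref$V1 * c_, ref$Q * c_, ref$V2 * c_)
  expect_equal(terminal_half_life(scaled), terminal_half_life(ref),
               tolerance = 1e-12)
})

test_that("analytic concentrations agree with a high-accuracy ODE oracle", {
  skip_if_not_installed("deSolve")
  ev <- data.frame(start_time = 0, amount = 1500, duration = 0.5)
  times <- seq(0.05, 1000, length.out = 200)
  ana <- conc_profile(ref, ev, times)$conc
  ode <- ode_conc_oracle(ref, ev, times)
  expect_lt(max(abs(ana - ode) / pmax(ode, 1e-9)), 1e-6)

  # random parameter draws, multi-dose schedule
  withr::with_seed(7, {
    for (i in 1:5) {
      p <- pk_params(CL = runif(1, 0.02, 2), V1 = runif(1, 3, 30),
                     Q = runif(1, 0.1, 3), V2 = runif(1, 5, 40))
      ev2 <- data.frame(start_time = c(0, 168), amount = c(1500, 1000),
                        duration = c(0.5, 1))
      tg <- seq(0.1, 600, length.out = 200)
      ana <- conc_profile(p, ev2, tg)$conc
      ode <- ode_conc_oracle(p, ev2, tg)
      expect_lt(max(abs(ana - ode) / pmax(ode, 1e-9)), 1e-6)
    }
  })
})

test_that("concentration limits: zero before dosing, bolus limit dose/V1", {
  r_none <- data.frame(start_time = numeric(), amount = numeric(),
                       duration = numeric())
  expect_equal(conc_profile(ref, r_none, 100)$conc, 0)
  expect_error(conc_profile(ref, regimen_preset("1500_q3w"), numeric()),
               "empty")
  # near-instantaneous infusion approaches the bolus value 1500 / V1
  ev <- data.frame(start_time = 0, amount = 1500, duration = 1e-6)
  c0 <- conc_profile(ref, ev, 1e-6)$conc
  expect_equal(c0, 1500 / 6.5, tolerance = 1e-4)
  # zero before the first event, continuous and nonnegative after
  r <- regimen_preset("1500_d1_d8_q6w")
  cc <- conc_profile(ref, r, c(0, 1e-9, 167.9999, 168.0001, 5000))
  expect_true(all(cc$conc >= 0))
  expect_equal(cc$conc[1], 0)
})

test_that("superposition and dose linearity hold exactly", {
  ev2 <- data.frame(start_time = c(0, 336), amount = c(1500, 1500),
                    duration = 0.5)
  tg <- c(1, 100, 336.6, 400, 900)
  both <- conc_profile(ref, ev2, tg)$conc
  single1 <- conc_profile(ref, ev2[1, ], tg)$conc
  single2 <- conc_profile(ref, ev2[2, ], tg)$conc
  expect_equal(both, single1 + single2, tolerance = 1e-10)

  scaled <- ev2
  scaled$amount <- scaled$amount * 2.5
  expect_equal(conc_profile(ref, scaled, tg)$conc, 2.5 * both,
               tolerance = 1e-12)
  expect_equal(auc_window(ref, scaled, 0, 1000),
               2.5 * auc_window(ref, ev2, 0, 1000), tolerance = 1e-12)
})

test_that("AUC is exact: additive, mass-balance limit, quadrature oracle", {
  r1 <- regimen(1, 1500, cycle_weeks = NULL)
  expect_equal(auc_window(ref, data.frame(start_time = numeric(),
                                          amount = numeric(),
                                          duration = numeric()), 0, 100), 0)
  expect_error(auc_window(ref, r1, 10, 10), "t0 < t1")

  # AUC to ~20 terminal half-lives approaches Dose / CL
  t_inf <- 20 * terminal_half_life(ref)
  expect_equal(auc_window(ref, r1, 0, t_inf), 1500 / 0.050, tolerance = 1e-3)

  # additivity over adjacent windows
  a <- auc_window(ref, r1, 0, 137)
  b <- auc_window(ref, r1, 137, 503)
  expect_equal(a + b, auc_window(ref, r1, 0, 503), tolerance = 1e-9)

  # steady-state q3w tail window against composite-trapezoid quadrature
  r <- regimen_preset("1500_q3w")
  t_end <- 6 * 504
  ana <- auc_window(ref, r, t_end - 24, t_end)
  quad <- trapz_auc_oracle(function(tt) conc_profile(ref, r, tt)$conc,
                           t_end - 24, t_end, step = 1 / 3600)
  expect_equal(ana, quad, tolerance = 1e-3)
})
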