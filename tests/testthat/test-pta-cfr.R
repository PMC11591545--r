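# Free tail exposure, PTA, CFR, desirability.

ref <- dalbavancin_params()
r_q3w <- regimen_preset("1500_q3w")

test_that("free tail AUC responds to protein binding as a pure scalar", {
  expect_equal(fauc_tail(ref, r_q3w, pb = 100), 0)
  total <- auc_window(ref, r_q3w, 6 * 504 - 24, 6 * 504)
  expect_equal(fauc_tail(ref, r_q3w, pb = 0), total, tolerance = 1e-12)
  expect_equal(fauc_tail(ref, r_q3w, pb = 99), 0.01 * total, tolerance = 1e-12)

  # numerical quadrature oracle on the free-concentration curve
  quad <- 0.01 * trapz_auc_oracle(function(tt) conc_profile(ref, r_q3w, tt)$conc,
                                  6 * 504 - 24, 6 * 504, step = 1 / 600)
  expect_equal(fauc_tail(ref, r_q3w, pb = 99), quad, tolerance = 1e-3)

  # worst-interval rule: for d1+d8 q6w the cycle-end interval is the worst
  r18 <- regimen_preset("1500_d1_d8_q6w")
  ends <- redose_times(r18)
  per_end <- vapply(ends, function(te) {
    auc_window(ref, r18, te - 24, te)
  }, numeric(1))
  expect_equal(fauc_tail(ref, r18, pb = 0), min(per_end), tolerance = 1e-12)
  expect_equal(which.min(per_end), length(ends))
})

test_that("zero-variability PTA is the deterministic step function", {
  m0 <- pop_model(ref, omega = c(CL = 0, V1 = 0, V2 = 0))
  pop0 <- sample_population(m0, 200, seed = 1)
  fa <- fauc_tail(ref, r_q3w, pb = 99)
  mic_star <- fa / 27.1 # PTA flips from 100 to 0 at this MIC
  expect_equal(pta(pop0, r_q3w, mic = 0.9 * mic_star, pb = 99), 100)
  expect_equal(pta(pop0, r_q3w, mic = 1.1 * mic_star, pb = 99), 0)
  # strict inequality at the boundary: fauc/mic == threshold does not attain
  expect_equal(pta(pop0, r_q3w, mic = mic_star, pb = 99), 0)
})

test_that("PTA is monotone in MIC, binding, threshold, and dose", {
  pop <- sample_population(dalbavancin_popmodel(), 3000, seed = 17)
  cur <- pta_curve(pop, r_q3w, pb = 98)
  expect_true(all(diff(cur$pta) <= 0))
  expect_true(all(cur$pta >= 0 & cur$pta <= 100))
  expect_error(pta_curve(pop, r_q3w, mic_grid = c(0.5, 0.25), pb = 98),
               "increasing")

  # binding dominance: lower binding -> pointwise higher PTA
  cur93 <- pta_curve(pop, r_q3w, pb = 93)
  cur99 <- pta_curve(pop, r_q3w, pb = 99)
  expect_true(all(cur93$pta >= cur99$pta))

  # threshold monotonicity
  for (m in c(0.06, 0.125, 0.25)) {
    p_st <- pta(pop, r_q3w, m, 98, 27.1)
    p_l1 <- pta(pop, r_q3w, m, 98, 53.3)
    p_l2 <- pta(pop, r_q3w, m, 98, 111.1)
    expect_true(p_st >= p_l1 && p_l1 >= p_l2)
  }

  # dose monotonicity at fixed interval
  r_double <- regimen(1, 3000, cycle_weeks = 3, label = "3000 q3w")
  expect_gte(pta(pop, r_double, 0.25, 99), pta(pop, r_q3w, 0.25, 99))

  # tiny MIC attains for any nonzero dose
  expect_equal(pta(pop, r_q3w, 1e-6, 99), 100)
  expect_error(pta(pop[0, ], r_q3w, 0.125, 99), "empty")
})

test_that("CFR is the frequency-weighted PTA and respects its bounds", {
  pop <- sample_population(dalbavancin_popmodel(), 3000, seed = 23)
  cur <- pta_curve(pop, r_q3w, pb = 98)

  point <- mic_distribution(0.125, 1)
  expect_equal(cfr(cur, point)$cfr, cur$pta[cur$mic == 0.125])

  two <- mic_distribution(c(0.06, 0.25), c(0.5, 0.5))
  expect_equal(cfr(cur, two)$cfr,
               mean(cur$pta[cur$mic %in% c(0.06, 0.25)]))

  dist <- mic_saureus_synthetic()
  v <- cfr(cur, dist)
  # hand-computed weighted sum from the packaged table
  expect_equal(v$cfr, sum(cur$pta[match(dist$mic, cur$mic)] * dist$frequency),
               tolerance = 1e-12)
  expect_gte(v$cfr, min(cur$pta[match(dist$mic, cur$mic)]))
  expect_lte(v$cfr, max(cur$pta[match(dist$mic, cur$mic)]))
  expect_gte(v$cfr, 90) # 1500 mg q3w at 98% binding is comfortably desirable

  # mismatched grids error and name the missing MICs
  cur_small <- pta_curve(pop, r_q3w, mic_grid = c(0.06, 0.125), pb = 98)
  expect_error(cfr(cur_small, dist), "0.016")
})

test_that("desirability uses the 90% bound inclusively", {
  expect_true(desirable(90))
  expect_false(desirable(89.999))
  expect_true(desirable(100))
  pop <- sample_population(pop_model(ref, omega = c(CL = 0, V1 = 0, V2 = 0)),
                           10, seed = 1)
  cur <- pta_curve(pop, r_q3w, pb = 99)
  expect_true(desirable(cur, mic = 0.016))
  expect_error(desirable(cur), "mic")
})

test_that("MIC distribution validation and CSV reading are strict", {
  expect_error(mic_distribution(c(0.125, 0.06), c(0.5, 0.5)), "increasing")
  expect_error(mic_distribution(c(0.06, 0.125), c(0.6, 0.6)), "sum to 1")
  expect_error(mic_distribution(c(0.06, 4), c(0.5, 0.5)), "within")
  dist <- mic_saureus_synthetic()
  expect_equal(sum(dist$frequency), 1, tolerance = 1e-9)
  expect_true(all(dist$mic %in% mic_grid_default()))
})
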