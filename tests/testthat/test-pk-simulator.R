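test_that("bolus and steady-state limits match closed forms", {
  sys <- ref_system()
  tc <- simulate_pkpd(sys, dose_schedule(dose_bolus(0, 10)), c(0, 1, 5))
  expect_equal(tc$cp_art[1], 10 / 4.31)

  # constant infusion: Cp -> R/CL, Ce -> Cp, Ca -> R/CLm (mass conversion 1)
  tc2 <- simulate_pkpd(sys, dose_schedule(dose_infusion(0, duration = 2e4,
                                                        rate = 1)),
                       c(0, 1.5e4))
  expect_equal(tc2$cp_art[2], 1 / 1.12, tolerance = 1e-6)
  expect_equal(tc2$ce_moaas[2], tc2$cp_art[2], tolerance = 1e-6)
  expect_equal(tc2$ca_metab[2], 1 / 0.0665, tolerance = 1e-4)

  # zero dosing: identically zero
  tc0 <- simulate_pkpd(sys, dose_schedule(), c(0, 10, 60))
  expect_true(all(as.matrix(tc0[, -1]) == 0))
})

test_that("mass balance holds to 1e-8 and metabolism is complete", {
  withr::with_seed(21, {
    for (i in 1:5) {
      sys <- ref_system(random_cov())
      sched <- random_schedule()
      tc <- simulate_pkpd(sys, sched, seq(0, 90, 5))
      dosed <- tc$cum_dose
      # administered = in body + eliminated
      expect_lt(max(abs(dosed - (tc$A1 + tc$A2 + tc$A3 + tc$ElimR)) /
                      max(dosed[-1])), 1e-8)
      # everything eliminated becomes metabolite (conversion factor 1)
      expect_lt(max(abs(tc$ElimR - (tc$Adepot + tc$Am1 + tc$Am2 + tc$ElimM)) /
                      max(dosed[-1])), 1e-8)
    }
  })
  # long after a bolus, the full dose has passed through the metabolite
  sys <- ref_system()
  tcl <- simulate_pkpd(sys, dose_schedule(dose_bolus(0, 10)), c(0, 5e4))
  expect_equal(tcl$ElimM[2], 10, tolerance = 1e-6)
})

test_that("system is linear and obeys superposition", {
  sys <- ref_system()
  times <- seq(0, 60, 2.5)
  sched1 <- dose_schedule(dose_bolus(0, 5),
                          dose_infusion(10, duration = 20, rate = 1))
  tc1 <- simulate_pkpd(sys, sched1, times)
  sched2 <- dose_schedule(dose_bolus(0, 10),
                          dose_infusion(10, duration = 20, rate = 2))
  tc2 <- simulate_pkpd(sys, sched2, times)
  expect_equal(2 * tc1$cp_art, tc2$cp_art, tolerance = 1e-10)
  expect_equal(2 * tc1$ca_metab, tc2$ca_metab, tolerance = 1e-10)

  # two boluses = sum of shifted single-bolus responses
  tcb <- simulate_pkpd(sys, dose_schedule(dose_bolus(c(0, 10), 5)), times)
  single <- simulate_pkpd(sys, dose_schedule(dose_bolus(0, 5)),
                          seq(0, 60, 2.5))
  shifted <- approx(single$time + 10, single$cp_art, xout = times,
                    yleft = 0)$y
  expect_equal(tcb$cp_art, single$cp_art[match(times, single$time)] + shifted,
               tolerance = 1e-8)
})

test_that("matrix-exponential propagation matches the adaptive ODE oracle", {
  withr::with_seed(31, {
    for (i in 1:5) {
      sys <- ref_system(random_cov())
      sched <- random_schedule()
      times <- sort(unique(c(0, seq(0.5, 75, 2.5), runif(8, 0, 75))))
      tc <- simulate_pkpd(sys, sched, times)
      orc <- ode_oracle(sys, sched, times)
      expect_lt(max_rel_err(tc, orc), 1e-6)
    }
  })
})

test_that("venous concentration lags and never exceeds arterial after a bolus", {
  sys <- ref_system()
  tc <- simulate_pkpd(sys, dose_schedule(dose_bolus(0, 10)), seq(0, 120, 0.25))
  expect_gte(tc$time[which.max(tc$c_ven)], tc$time[which.max(tc$cp_art)])
  expect_lte(max(tc$c_ven), max(tc$cp_art))
  expect_true(all(tc$c_ven >= 0))
})

test_that("time to peak effect agrees with a dense-grid search", {
  remi <- remi_pk_params(ref_cov())
  tp <- time_to_peak_effect(remi, ke0 = 0.298)
  sys <- ref_system()
  grid <- seq(0.001, 10, by = 0.001)
  tc <- simulate_pkpd(sys, dose_schedule(dose_bolus(0, 1)), grid)
  expect_lt(abs(tp - grid[which.max(tc$ce_moaas)]), 0.01)
  # a huge ke0 makes the effect site track plasma: peak right after bolus
  expect_lt(time_to_peak_effect(remi, ke0 = 1e6), 0.01)
})

test_that("near-contiguous infusion records merge dose-preservingly", {
  # two 30-s records, rates 1.00 and 1.02 mg/min, 0.5-s gap -> one record
  sch <- dose_schedule(
    dose_infusion(0, duration = 0.5, rate = 1.00),
    dose_infusion(0.5 + 0.5 / 60, duration = 0.5, rate = 1.02))
  m <- merge_dose_records(sch)
  expect_equal(nrow(m), 1)
  expect_equal(m$amount, 0.5 + 0.51)
  expect_equal(m$duration, 0.5 + 0.5 / 60 + 0.5)

  # a 10-min gap defeats the gap criterion
  far <- dose_schedule(dose_infusion(0, duration = 0.5, rate = 1),
                       dose_infusion(10, duration = 0.5, rate = 1))
  expect_equal(nrow(merge_dose_records(far)), 2)

  # rate difference of 60 ug/min defeats the rate criterion
  fast <- dose_schedule(dose_infusion(0, duration = 0.5, rate = 1),
                        dose_infusion(0.5, duration = 0.5, rate = 1.06))
  expect_equal(nrow(merge_dose_records(fast)), 2)

  # long records are not merged; boluses never merge
  long <- dose_schedule(dose_infusion(0, duration = 3, rate = 1),
                        dose_infusion(3, duration = 3, rate = 1))
  expect_equal(nrow(merge_dose_records(long)), 2)

  # chains collapse iteratively and total dose is invariant
  withr::with_seed(41, {
    n <- 20
    starts <- cumsum(c(0, rep(0.25 + 0.1 / 3600, n - 1)))
    chain <- dose_schedule(dose_bolus(0, 2),
                           dose_infusion(starts, duration = 0.25,
                                         rate = 1 + cumsum(runif(n, 0, 0.002))))
    m2 <- merge_dose_records(chain)
    expect_lt(nrow(m2), nrow(chain))
    expect_equal(sum(m2$amount), sum(chain$amount))
  })
})

test_that("simulation inputs are validated", {
  sys <- ref_system()
  expect_error(simulate_pkpd(sys, dose_schedule(), c(5, 1)), "sorted")
  expect_error(simulate_pkpd(sys, dose_schedule(), c(-1, 1)), "non-negative")
  bad <- remi_pk_params(ref_cov())
  bad$V1 <- -1
  expect_error(build_system(bad, NULL), "positive")
  expect_error(dose_schedule(dose_bolus(0, -5)), "non-negative")
})
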