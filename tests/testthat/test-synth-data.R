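zero_omega <- function() {
  stats::setNames(as.list(rep(0, length(eta_names()))), eta_names())
}

test_that("cohorts are reproducible and seeds separate subjects", {
  spec <- population_spec(n = 6, bis_duration = 2)
  a <- sample_population(spec, 42)
  b <- sample_population(spec, 42)
  expect_identical(a, b)
  c <- sample_population(spec, 43)
  expect_false(identical(a$age, c$age))
  da <- generate_observations(a, spec, 42)
  db <- generate_observations(b, spec, 42)
  expect_identical(tibble::as_tibble(da), tibble::as_tibble(db))
})

test_that("zero variability collapses to the population prediction", {
  spec <- population_spec(n = 4, omega2 = zero_omega(), sigma_pk = 0,
                          moaas_times = numeric())
  subj <- sample_population(spec, 1)
  expect_true(all(as.matrix(subj[grep("^eta_", names(subj))]) == 0))
  ds <- generate_observations(subj, spec, 1)
  obs <- ds[ds$EVID == 0 & ds$TYPE == "remi_art" & ds$ID == 1, ]
  cov <- subj[1, ]
  sys <- build_system(remi_pk_params(cov), metab_pk_params(cov))
  tc <- simulate_pkpd(sys, dose_schedule(
    dose_bolus(0, 0.1 * cov$weight),
    dose_infusion(0, duration = 60, rate = cov$weight / 60)), obs$TIME)
  expect_equal(obs$DV, tc$cp_art, tolerance = 1e-12)
})

test_that("sampled variability reproduces the reported CL dispersion", {
  spec <- population_spec(n = 10000)
  subj <- sample_population(spec, 99)
  # CV of individual CL multipliers ~ 17.4% (Monte Carlo)
  clmult <- exp(subj$eta_CL)
  expect_equal(100 * stats::sd(clmult) / mean(clmult), 17.4, tolerance = 0.08)
  expect_equal(stats::var(subj$eta_V2), 0.203, tolerance = 0.05)
})

test_that("venous-only sampling inflates the CL eta variance by 1.86", {
  spec <- population_spec(n = 20000, prob_venous_only = 0.5)
  subj <- sample_population(spec, 7)
  v_ven <- stats::var(subj$eta_CL[subj$venous_only])
  v_art <- stats::var(subj$eta_CL[!subj$venous_only])
  expect_equal(v_ven / v_art, 1.86, tolerance = 0.1)
})

test_that("PK exclusion windows are enforced", {
  spec <- population_spec(n = 3, pk_times = c(0.5, 1, 1.9, 2, 2.5, 3, 5, 10))
  ds <- generate_observations(sample_population(spec, 3), spec, 3)
  remi <- ds[ds$TYPE %in% c("remi_art", "remi_ven"), ]
  metab <- ds[ds$TYPE %in% c("metab_art", "metab_ven"), ]
  expect_true(all(remi$TIME >= 2))
  expect_true(all(metab$TIME >= 3))
  expect_true(any(remi$TIME == 2))   # boundary samples retained
})

test_that("MOAA/S draws follow the model distribution", {
  # long steady infusion, scores drawn on a near-constant plateau
  spec <- population_spec(n = 1, omega2 = zero_omega(), sigma_pk = 0,
                          prob_female = 0, prob_opioids = 0,
                          age_range = c(35, 35), weight_range = c(70, 70),
                          dose_per_kg = 0.05, infusion_rate_per_kg = 0.6,
                          infusion_duration = 180,
                          pk_times = numeric(),
                          moaas_times = seq(150, 180, length.out = 1500))
  subj <- sample_population(spec, 11)
  ds <- generate_observations(subj, spec, 11)
  sc <- ds[ds$TYPE == "MOAAS", ]
  expect_true(all(sc$DV %in% 0:5))
  cov <- subj[1, ]
  sys <- build_system(remi_pk_params(cov), metab_pk_params(cov))
  tc <- simulate_pkpd(sys, dose_schedule(
    dose_bolus(0, 0.05 * 70),
    dose_infusion(0, duration = 180, rate = 0.6 * 70 / 60)), 165)
  pr <- moaas_probabilities(tc$ce_moaas, tc$ca_metab, moaas_params(cov))
  emp <- tabulate(sc$DV + 1, 6) / nrow(sc)
  the <- as.numeric(pr[1, paste0("p", 0:5)])
  # binomial Monte Carlo error + small plateau drift
  expect_lt(max(abs(emp - the)), 4 * sqrt(0.25 / nrow(sc)) + 0.02)
})

test_that("BIS stream is delayed, noisy at 1 Hz and median-filtered", {
  spec <- population_spec(n = 1, omega2 = zero_omega(), sigma_bis = 0,
                          sigma_pk = 0, age_range = c(35, 35),
                          weight_range = c(70, 70), prob_female = 0,
                          prob_opioids = 0, pk_times = numeric(),
                          moaas_times = numeric(), bis_duration = 5)
  subj <- sample_population(spec, 13)
  ds <- generate_observations(subj, spec, 13)
  bis <- ds[ds$TYPE == "BIS", ]
  expect_equal(nrow(bis), 5 * 60 / 10)   # one record per 10-s epoch
  # noise-free stream: each DV is the median of the delayed prediction
  cov <- subj[1, ]
  sys <- build_system(remi_pk_params(cov), metab_pk_params(cov),
                      ke0_bis = bis_params(cov)$ke0[1])
  sched <- dose_schedule(dose_bolus(0, 7), dose_infusion(0, duration = 60,
                                                         rate = 70 / 60))
  stream_t <- seq_len(5 * 60) / 60
  src_t <- pmax(stream_t - 15 / 60, 0)
  tc <- simulate_pkpd(sys, sched, sort(unique(src_t)))
  pred <- bis_predict(tc$ce_bis[match(src_t, tc$time)],
                      tc$ca_metab[match(src_t, tc$time)], bis_params(cov))
  manual <- tapply(pred, ceiling(stream_t / (10 / 60)), stats::median)
  expect_equal(bis$DV, as.numeric(manual), tolerance = 1e-10)
  # the first epochs reflect the awake baseline through the 15-s delay
  expect_equal(bis$DV[1], 93.7, tolerance = 0.5)
})

test_that("median filter of a constant stream is the constant", {
  f <- remipkpd:::median_filter(rep(42, 120), seq(0, 119) / 60, 10 / 60)
  expect_true(all(f$value == 42))
})

test_that("log-parameter variances converge to their targets", {
  spec <- population_spec(n = 5000)
  subj <- sample_population(spec, 17)
  om <- pkpd_omega2()$omega2
  for (nm in c("V1", "CL", "Q2m", "Ce50_bis")) {
    expect_equal(stats::var(subj[[paste0("eta_", nm)]]), unname(om[[nm]]),
                 tolerance = 0.1)
  }
  # normality of the log effects (they are exactly Gaussian by construction)
  expect_gt(stats::shapiro.test(subj$eta_V1[1:3000])$p.value, 1e-4)
})
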