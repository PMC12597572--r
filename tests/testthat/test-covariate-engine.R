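test_that("reference individual reproduces the published structural estimates", {
  remi <- remi_pk_params(ref_cov())
  expect_equal(remi$V1, 4.31)
  expect_equal(remi$V2, 12.3)
  expect_equal(remi$V3, 18.6)
  expect_equal(remi$CL, 1.12)
  expect_equal(remi$Q2, 1.45)
  expect_equal(remi$Q3, 0.298)
  expect_equal(remi$Fven, 0.132)
  expect_equal(remi$Kdelay, 0.0144)

  metab <- metab_pk_params(ref_cov())
  expect_equal(metab$CLm, 0.0665)
  expect_equal(metab$V1m, 6.85)
  expect_equal(metab$Kdepot, 0.215)

  mo <- moaas_params(ref_cov())
  expect_equal(mo$Ce50, 0.182)
  expect_equal(mo$ke0, 0.298)
  bi <- bis_params(ref_cov())
  expect_equal(bi$Ce50, 0.982)
  expect_equal(bi$ke0, 0.145)
  expect_equal(bi$baseline, 93.7)
})

test_that("covariate factors act as estimated", {
  # female with opioids: the published simplified code is the oracle for CL
  cl_oracle <- 1.11977 * exp(0.162802 - 0.139340)
  cl <- remi_pk_params(subject_covariates(35, 70, sex = "female",
                                          opioids = TRUE))$CL
  expect_equal(cl, cl_oracle, tolerance = 2e-3)

  # linear volume allometry
  expect_equal(remi_pk_params(subject_covariates(35, 35))$V1, 4.31 * 0.5)
  # metabolite volumes use the estimated exponent, identity at 70 kg
  expect_equal(metab_pk_params(subject_covariates(35, 70))$V1m, 6.85)
  m35 <- metab_pk_params(subject_covariates(35, 35))
  expect_equal(m35$V1m, 6.85 * 0.5^0.518)
  expect_equal(m35$CLm, 0.0665 * 0.5^0.75)

  # end-stage renal disease multiplies metabolite clearance by exp(-2.18)
  esrd <- metab_pk_params(subject_covariates(35, 70, esrd = TRUE))
  expect_equal(esrd$CLm, 0.0665 * exp(-2.18))

  # sex effect on clearance is exp(0.163) regardless of other covariates
  for (cv in list(c(25, 50), c(70, 100))) {
    f <- remi_pk_params(subject_covariates(cv[1], cv[2], sex = "female"))$CL
    m <- remi_pk_params(subject_covariates(cv[1], cv[2], sex = "male"))$CL
    expect_equal(f / m, exp(0.163))
  }

  # V3 increases with age; both Ce50 values decrease with age
  v3 <- function(a) remi_pk_params(subject_covariates(a, 70))$V3
  expect_true(all(diff(vapply(c(20, 40, 60, 80), v3, 1)) > 0))
  expect_lt(moaas_params(subject_covariates(85, 70))$Ce50,
            moaas_params(subject_covariates(35, 70))$Ce50)
  expect_lt(bis_params(subject_covariates(85, 70))$Ce50,
            bis_params(subject_covariates(35, 70))$Ce50)

  # compartmental allometry: Q3 follows V3^0.75, so age raises Q3 too
  r80 <- remi_pk_params(subject_covariates(80, 70))
  expect_equal(r80$Q3, 0.298 * (r80$V3 / 18.6)^0.75)
})

test_that("eta handling follows the canonical order and log-normal form", {
  eta <- tibble::tibble(V1 = 0.2, CL = -0.1)
  r <- remi_pk_params(ref_cov(), eta = eta)
  expect_equal(r$V1, 4.31 * exp(0.2))
  expect_equal(r$CL, 1.12 * exp(-0.1))
  expect_equal(r$V2, 12.3)  # unlisted etas default to zero
  expect_error(remi_pk_params(ref_cov(), eta = tibble::tibble(bogus = 1)),
               "unknown eta")
  # parameters without reported variability accept no eta: Fven unchanged
  expect_equal(r$Fven, 0.132)
})

test_that("opioid cut-point derivation preserves the S<=1 logit", {
  op <- derive_opioid_cutpoints(-16.6, 2.65, 1.67)
  expect_equal(op$d01_op, 2.65 * exp(-1.67))
  expect_equal(op$b0_op + op$d01_op, -16.6 + 2.65)  # exact invariance
  # identity at K = 0
  id <- derive_opioid_cutpoints(-16.6, 2.65, 0)
  expect_equal(id$b0_op, -16.6)
  expect_equal(id$d01_op, 2.65)
  expect_error(derive_opioid_cutpoints(-16.6, -1, 1.67), "non-negative")
})

test_that("ECMO and ICU adjustments multiply as reported", {
  th <- pkpd_theta()
  base_cov <- subject_covariates(35, 70)
  remi <- remi_pk_params(base_cov)
  metab <- metab_pk_params(base_cov)

  # all flags off: identity
  off <- apply_ecmo_icu(remi, metab, base_cov)
  expect_equal(off$remi, remi)
  expect_equal(off$metab, metab)

  ecmo <- subject_covariates(35, 70, ecmo_subject = TRUE, ecmo_active = TRUE)
  on <- apply_ecmo_icu(remi, metab, ecmo)
  expect_equal(on$remi$V1, remi$V1 * 46.1 * 0.189)
  expect_equal(on$remi$V2, remi$V2 * 0.189)
  expect_equal(on$remi$V3, remi$V3 * 0.722)
  expect_equal(on$remi$CL, remi$CL * 0.815)
  expect_equal(on$metab$V2m, metab$V2m * 2.03)
  expect_equal(on$metab$CLm, metab$CLm * 0.815)

  icu <- subject_covariates(35, 70, icu_subject = TRUE, icu_gt24h = TRUE)
  on2 <- apply_ecmo_icu(remi, metab, icu)
  expect_equal(on2$remi$CL, remi$CL * 0.264)
  expect_equal(on2$remi$V3, remi$V3 * 1.59)
  expect_equal(on2$metab$CLm, metab$CLm * 0.426)
})

test_that("CV conversion is exact, monotone and invertible", {
  expect_equal(cv_from_omega2(0), 0)
  expect_equal(round(cv_from_omega2(0.0631), 1), 25.5)
  expect_equal(round(cv_from_omega2(0.145), 1), 39.5)
  x <- seq(0, 1, by = 0.05)
  expect_true(all(diff(cv_from_omega2(x)) > 0))
  expect_equal(omega2_from_cv(cv_from_omega2(x)), x)
  expect_error(cv_from_omega2(-0.1), "non-negative")
})

test_that("covariate validation rejects impossible records", {
  expect_error(subject_covariates(-1, 70), "age")
  expect_error(subject_covariates(35, 0), "weight")
  expect_error(subject_covariates(35, 70, sex = "other"), "sex")
  expect_error(subject_covariates(35, 70, icu_gt24h = TRUE), "icu_subject")
  expect_error(subject_covariates(35, 70, ecmo_active = TRUE), "ecmo_subject")
})

test_that("all parameters stay positive across the demographic envelope", {
  withr::with_seed(11, {
    for (i in 1:50) {
      cov <- random_cov(pugh = TRUE, esrd = TRUE)
      vals <- c(unlist(remi_pk_params(cov)),
                unlist(metab_pk_params(cov)),
                unlist(bis_params(cov)[c("ke0", "Ce50", "Ca50", "baseline")]))
      expect_true(all(vals > 0))
    }
  })
})

test_that("theta overrides are applied and typos rejected", {
  th <- pkpd_theta(list(remi = list(CL = 0.9), gamma_bis = 2))
  expect_equal(th$remi$CL, 0.9)
  expect_equal(th$gamma_bis, 2)
  expect_equal(th$remi$V1, 4.31)
  expect_error(pkpd_theta(list(remi = list(CLX = 1))), "unknown parameter")
  om <- pkpd_omega2(list(omega2 = list(CL = 0)))
  expect_equal(unname(om$omega2[["CL"]]), 0)
  expect_equal(unname(om$omega2[["V1"]]), 0.0631)
})
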