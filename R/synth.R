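#' Define a virtual population
#'
#' Describes the statistical structure of a simulated cohort: covariate
#' distributions over the demographic envelope of the modelled population
#' (ages 6-93 yr, weights 21-171 kg), prevalences of the binary covariates,
#' interindividual variances, residual-error magnitudes, the sampling
#' design and the dosing template.
#'
#' Defaults: uniform age and weight over the envelope; probability of
#' female 365/933 (the sex split of the PK cohort); opioid prevalence 0.5;
#' hepatic/renal/ECMO/ICU/venous-only prevalence 0. The residual-error
#' magnitudes are not reported with the model estimates, so the defaults
#' (`sigma_pk` = 0.20 on the log scale, `sigma_bis` = 4 BIS units) are
#' package choices, recorded in the dataset attributes.
#'
#' @param n number of subjects, >= 1.
#' @param age_range,weight_range covariate envelopes.
#' @param prob_female,prob_opioids,prob_pugh,prob_esrd,prob_ecmo,prob_icu,prob_venous_only
#'   prevalences in `[0, 1]`. Sampled ECMO subjects are treated as having
#'   ECMO running during the simulated administration; half of sampled ICU
#'   subjects are treated beyond 24 h.
#' @param omega2 overrides for [pkpd_omega2()].
#' @param sigma_pk proportional (log-scale) PK residual SD.
#' @param sigma_bis additive BIS residual SD (BIS units).
#' @param pk_times PK sampling times (min).
#' @param pk_sites `"arterial"`, `"venous"` or `"both"`.
#' @param sample_metabolite logical; emit CNS7054 concentration records in
#'   addition to remimazolam ones.
#' @param moaas_times MOAA/S scoring times (min).
#' @param bis_duration duration of the 1-Hz BIS stream (min); 0 disables.
#' @param bis_delay BIS signal-processing delay (s).
#' @param bis_epoch BIS median-filter epoch (s).
#' @param dose_per_kg bolus dose at time 0 (mg/kg).
#' @param infusion_rate_per_kg maintenance infusion from time 0 (mg/kg/h).
#' @param infusion_duration maintenance infusion duration (min).
#' @return A list of class `population_spec`.
#' @export
population_spec <- function(n = 20,
                            age_range = c(6, 93), weight_range = c(21, 171),
                            prob_female = 365 / 933, prob_opioids = 0.5,
                            prob_pugh = 0, prob_esrd = 0,
                            prob_ecmo = 0, prob_icu = 0,
                            prob_venous_only = 0,
                            omega2 = NULL,
                            sigma_pk = 0.20, sigma_bis = 4,
                            pk_times = c(2, 3, 5, 7.5, 10, 15, 20, 30, 45, 60),
                            pk_sites = c("both", "arterial", "venous"),
                            sample_metabolite = TRUE,
                            moaas_times = seq(1, 60, by = 2),
                            bis_duration = 0, bis_delay = 15, bis_epoch = 10,
                            dose_per_kg = 0.1, infusion_rate_per_kg = 1,
                            infusion_duration = 60) {
  stopifnot(n >= 1, sigma_pk >= 0, sigma_bis >= 0)
  iiv <- pkpd_omega2(if (is.null(omega2)) NULL else list(omega2 = omega2))
  structure(list(
    n = n, age_range = age_range, weight_range = weight_range,
    prob_female = prob_female, prob_opioids = prob_opioids,
    prob_pugh = prob_pugh, prob_esrd = prob_esrd,
    prob_ecmo = prob_ecmo, prob_icu = prob_icu,
    prob_venous_only = prob_venous_only,
    omega2 = iiv$omega2, venous_cl_multiplier = iiv$venous_cl_multiplier,
    sigma_pk = sigma_pk, sigma_bis = sigma_bis,
    pk_times = pk_times, pk_sites = match.arg(pk_sites),
    sample_metabolite = sample_metabolite,
    moaas_times = moaas_times,
    bis_duration = bis_duration, bis_delay = bis_delay, bis_epoch = bis_epoch,
    dose_per_kg = dose_per_kg, infusion_rate_per_kg = infusion_rate_per_kg,
    infusion_duration = infusion_duration
  ), class = "population_spec")
}

#' Sample a virtual cohort
#'
#' Draws covariates from the population spec and interindividual random
#' effects `eta ~ Normal(0, omega2)` independently per parameter. For
#' subjects with venous-only sampling, the variance of the remimazolam CL
#' eta is multiplied by the venous inflation factor (1.86 by default).
#' Reproducible: the RNG state is fully determined by `seed`.
#'
#' @param spec a [population_spec()].
#' @param seed integer seed.
#' @return Tibble, one row per subject: `ID`, covariate columns and one
#'   `eta_*` column per parameter with interindividual variability.
#' @export
sample_population <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "population_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  n <- spec$n
  cov <- subject_covariates(
    age = stats::runif(n, spec$age_range[1], spec$age_range[2]),
    weight = stats::runif(n, spec$weight_range[1], spec$weight_range[2]),
    sex = ifelse(stats::runif(n) < spec$prob_female, "female", "male"),
    opioids = stats::runif(n) < spec$prob_opioids,
    pugh_gt8 = stats::runif(n) < spec$prob_pugh,
    esrd = stats::runif(n) < spec$prob_esrd,
    ecmo_subject = ecmo <- stats::runif(n) < spec$prob_ecmo,
    ecmo_active = ecmo,
    icu_subject = icu <- stats::runif(n) < spec$prob_icu,
    icu_gt24h = icu & stats::runif(n) < 0.5,
    venous_only = stats::runif(n) < spec$prob_venous_only
  )
  om <- spec$omega2
  eta <- purrr::map_dfc(names(om), function(nm) {
    sd <- sqrt(om[[nm]])
    tibble::tibble(!!paste0("eta_", nm) := stats::rnorm(n, 0, sd))
  })
  if (any(cov$venous_only) && om[["CL"]] > 0) {
    idx <- which(cov$venous_only)
    eta$eta_CL[idx] <- stats::rnorm(
      length(idx), 0, sqrt(om[["CL"]] * spec$venous_cl_multiplier))
  }
  dplyr::bind_cols(tibble::tibble(ID = seq_len(n)), cov, eta)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

subject_etas <- function(subjects, i) {
  nm <- grep("^eta_", names(subjects), value = TRUE)
  e <- as.list(subjects[i, nm])
  names(e) <- sub("^eta_", "", nm)
  tibble::as_tibble(e)
}

# epoch median filter of a 1-Hz stream: one value per complete epoch
# (0, e], (e, 2e], ..., stamped at the epoch end
median_filter <- function(x, times, epoch) {
  ep <- ceiling(times / epoch)
  agg <- tapply(x, ep, stats::median)
  tibble::tibble(time = as.numeric(names(agg)) * epoch,
                 value = as.numeric(agg))
}

#' Generate a synthetic NONMEM-style dataset
#'
#' Simulates every subject of a sampled cohort under the spec's dosing
#' template and emits long-format observation records:
#'
#' * PK observations (`remi_art`, `remi_ven`, `metab_art`, `metab_ven`):
#'   true concentration times `exp(Normal(0, sigma_pk^2))`
#'   (transform-both-sides proportional error); samples within the first
#'   2 min (remimazolam) / 3 min (metabolite) of the start of
#'   administration are excluded.
#' * MOAA/S scores: drawn categorically from the model probabilities at the
#'   scheduled times.
#' * BIS: the noise-free prediction delayed by 15 s, per-subject baseline
#'   shift `Normal(0, sigma_bis^2)` (baseline variability equal to the
#'   residual variability), 1-Hz additive residual noise, then median
#'   filtering in 10-s epochs.
#'
#' @param subjects tibble from [sample_population()].
#' @param spec the matching [population_spec()].
#' @param seed integer seed; each subject consumes an independent stream
#'   derived from it, so datasets are bit-identical under identical seeds.
#' @param theta fixed effects.
#' @return Tibble of class `pkpd_dataset` with NONMEM-style columns `ID,
#'   TIME, EVID, AMT, RATE, CMT, DV, MDV, TYPE` plus covariate columns.
#'   The true subject parameters are attached as attribute `"true_params"`,
#'   the spec as `"spec"`.
#' @export
generate_observations <- function(subjects, spec, seed = 1,
                                  theta = pkpd_theta()) {
  stopifnot(inherits(spec, "population_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)

  rows <- vector("list", nrow(subjects))
  truth <- vector("list", nrow(subjects))
  for (i in seq_len(nrow(subjects))) {
    set.seed((seed * 1000L + subjects$ID[i]) %% .Machine$integer.max)
    cov <- subjects[i, ]
    eta <- subject_etas(subjects, i)
    remi <- remi_pk_params(cov, theta, eta)
    metab <- metab_pk_params(cov, theta, eta)
    adj <- apply_ecmo_icu(remi, metab, cov, theta)
    mo <- moaas_params(cov, theta, eta)
    bi <- bis_params(cov, theta, eta)
    sys <- build_system(adj$remi, adj$metab, mo$ke0[1], bi$ke0[1])
    truth[[i]] <- dplyr::bind_cols(
      tibble::tibble(ID = subjects$ID[i]), adj$remi,
      dplyr::rename_with(adj$metab, ~paste0(.x, "_metab")),
      tibble::tibble(ke0_moaas = mo$ke0[1], Ce50_moaas = mo$Ce50[1],
                     ke0_bis = bi$ke0[1], Ce50_bis = bi$Ce50[1]),
      subjects[i, grep("^eta_", names(subjects), value = TRUE)])

    w <- cov$weight
    sched <- dose_schedule(
      if (spec$dose_per_kg > 0) dose_bolus(0, spec$dose_per_kg * w),
      if (spec$infusion_rate_per_kg > 0 && spec$infusion_duration > 0)
        dose_infusion(0, duration = spec$infusion_duration,
                      rate = spec$infusion_rate_per_kg * w / 60))
    bis_times <- if (spec$bis_duration > 0)
      seq_len(spec$bis_duration * 60) / 60 else numeric()
    all_t <- sort(unique(c(spec$pk_times, spec$moaas_times,
                           pmax(bis_times - spec$bis_delay / 60, 0))))
    tc <- simulate_pkpd(sys, sched, all_t)
    at <- function(tt, col) tc[[col]][match(tt, tc$time)]

    recs <- list(dose_rows(sched, cov))
    # PK observations, exclusion windows relative to start of administration
    t_start <- min(sched$time)
    pk_t_remi <- spec$pk_times[spec$pk_times - t_start >= 2]
    pk_t_met <- spec$pk_times[spec$pk_times - t_start >= 3]
    noisy <- function(x) x * exp(stats::rnorm(length(x), 0, spec$sigma_pk))
    art <- spec$pk_sites %in% c("arterial", "both") && !cov$venous_only
    ven <- spec$pk_sites %in% c("venous", "both") || cov$venous_only
    if (art) {
      recs <- c(recs, list(
        obs_rows(cov, pk_t_remi, noisy(at(pk_t_remi, "cp_art")), 1,
                 "remi_art")))
      if (spec$sample_metabolite) {
        recs <- c(recs, list(
          obs_rows(cov, pk_t_met, noisy(at(pk_t_met, "ca_metab")), 8,
                   "metab_art")))
      }
    }
    if (ven) {
      recs <- c(recs, list(
        obs_rows(cov, pk_t_remi, noisy(at(pk_t_remi, "c_ven")), 4,
                 "remi_ven")))
      if (spec$sample_metabolite) {
        recs <- c(recs, list(
          obs_rows(cov, pk_t_met, noisy(at(pk_t_met, "cven_metab")), 10,
                   "metab_ven")))
      }
    }
    # MOAA/S: categorical draw from the model probabilities
    if (length(spec$moaas_times) > 0) {
      pr <- moaas_probabilities(at(spec$moaas_times, "ce_moaas"),
                                at(spec$moaas_times, "ca_metab"), mo,
                                opioids = cov$opioids)
      pm <- as.matrix(pr[paste0("p", 0:5)])
      score <- apply(pm, 1, function(p) sample(0:5, 1, prob = p))
      recs <- c(recs, list(obs_rows(cov, spec$moaas_times, score, 5, "MOAAS")))
    }
    # BIS: delayed noise-free signal + baseline shift + 1-Hz noise,
    # median-filtered per epoch
    if (spec$bis_duration > 0) {
      src_t <- pmax(bis_times - spec$bis_delay / 60, 0)
      base_shift <- stats::rnorm(1, 0, spec$sigma_bis)
      stream <- bis_predict(at(src_t, "ce_bis"), at(src_t, "ca_metab"), bi) +
        base_shift + stats::rnorm(length(src_t), 0, spec$sigma_bis)
      filt <- median_filter(stream, bis_times, spec$bis_epoch / 60)
      recs <- c(recs, list(obs_rows(cov, filt$time, filt$value, 6, "BIS")))
    }
    rows[[i]] <- dplyr::bind_rows(recs)
  }
  out <- dplyr::arrange(dplyr::bind_rows(rows), .data$ID, .data$TIME,
                        dplyr::desc(.data$EVID))
  attr(out, "true_params") <- dplyr::bind_rows(truth)
  attr(out, "spec") <- spec
  class(out) <- c("pkpd_dataset", class(out))
  out
}

cov_cols <- function(cov) {
  tibble::tibble(
    AGE = cov$age, WGT = cov$weight,
    SEX = ifelse(cov$sex == "female", 2L, 1L),
    OPI = as.integer(cov$opioids), PUGH = as.integer(cov$pugh_gt8),
    ESRD = as.integer(cov$esrd), ECMO_S = as.integer(cov$ecmo_subject),
    ECMO_A = as.integer(cov$ecmo_active), ICU = as.integer(cov$icu_subject),
    ICU24 = as.integer(cov$icu_gt24h), VEN = as.integer(cov$venous_only)
  )
}

dose_rows <- function(sched, cov) {
  if (nrow(sched) == 0) return(NULL)
  dplyr::bind_cols(
    tibble::tibble(
      ID = rep(if (is.null(cov$ID)) NA_integer_ else cov$ID, nrow(sched)),
      TIME = sched$time, EVID = 1L, AMT = sched$amount,
      RATE = ifelse(sched$duration > 0, sched$amount / sched$duration, 0),
      CMT = 1L, DV = NA_real_, MDV = 1L, TYPE = "dose"),
    cov_cols(cov)[rep(1, nrow(sched)), ])
}

obs_rows <- function(cov, times, dv, cmt, type) {
  if (length(times) == 0) return(NULL)
  dplyr::bind_cols(
    tibble::tibble(
      ID = rep(if (is.null(cov$ID)) NA_integer_ else cov$ID, length(times)),
      TIME = times, EVID = 0L, AMT = 0, RATE = 0, CMT = as.integer(cmt),
      DV = as.numeric(dv), MDV = 0L, TYPE = type),
    cov_cols(cov)[rep(1, length(times)), ])
}
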