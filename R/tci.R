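# discrete-time controller precomputation: propagator over one control tick
# and the peak-prediction map used by the effect-site law
tci_precompute <- function(system, dt, horizon) {
  n <- length(system$states)
  Eaug <- as.matrix(Matrix::expm(rbind(cbind(system$A, system$b), 0) * dt))
  Phi <- Eaug[seq_len(n), seq_len(n)]
  Gam <- Eaug[seq_len(n), n + 1]
  ce_row <- as.numeric(system$states == "Ce_moaas")
  cp_row <- as.numeric(system$states == "A1") / system$remi$V1
  m <- ceiling(horizon / dt)
  P <- matrix(0, m + 1, n)
  v <- ce_row
  P[1, ] <- v
  for (j in seq_len(m)) {
    v <- as.numeric(v %*% Phi)
    P[j + 1, ] <- v
  }
  list(Phi = Phi, Gam = Gam, P = P, v1 = as.numeric(P %*% Gam),
       ce_row = ce_row, cp_row = cp_row, n = n, dt = dt)
}

# run the control loop; returns states at tick boundaries and rates per tick
tci_run <- function(system, pre, target, n_ticks, mode, rate_cap) {
  n <- pre$n
  X <- matrix(0, n_ticks + 1, n, dimnames = list(NULL, system$states))
  rates <- numeric(n_ticks)
  x <- numeric(n)
  bolus <- 0
  if (mode == "plasma") {
    bolus <- target * system$remi$V1
    x[1] <- bolus
    # analytic required-rate profile holding Cp at target, averaged per tick
    r <- system$remi
    k2 <- r$Q2 / r$V2; k3 <- r$Q3 / r$V3
    t0 <- (seq_len(n_ticks) - 1) * pre$dt; t1 <- t0 + pre$dt
    rates <- target * (r$CL +
      r$Q2 * (exp(-k2 * t0) - exp(-k2 * t1)) / (k2 * pre$dt) +
      r$Q3 * (exp(-k3 * t0) - exp(-k3 * t1)) / (k3 * pre$dt))
    rates <- pmin(rates, rate_cap)
  }
  X[1, ] <- x
  ok <- pre$v1 > 1e-300
  for (i in seq_len(n_ticks)) {
    x_free <- as.numeric(pre$Phi %*% x)
    if (mode == "effect_site") {
      v0 <- as.numeric(pre$P %*% x_free)
      r_i <- min((target - v0[ok]) / pre$v1[ok])
      rates[i] <- min(max(r_i, 0), rate_cap)
    }
    x <- x_free + pre$Gam * rates[i]
    X[i + 1, ] <- x
  }
  list(X = X, rates = rates, bolus = bolus)
}

#' Plan a target-controlled infusion
#'
#' Computes the pump-rate profile attaining and holding a plasma or
#' effect-site remimazolam target for a given individual system, together
#' with the predicted timecourse and dosing summaries.
#'
#' Plasma mode gives a `target * V1` loading bolus and then the exact
#' required-rate profile from the linear-system inverse,
#' `r(t) = target * (CL + Q2 e^(-Q2/V2 t) + Q3 e^(-Q3/V3 t))`, averaged
#' over each control tick. Effect-site mode recomputes, at every control
#' tick, the largest admissible rate such that the predicted future peak of
#' the effect-site concentration does not exceed the target; the
#' effect-site concentration therefore rises monotonically to the target
#' with no overshoot, as fast as the pump cap allows. The MOAA/S `ke0`
#' drives the controller's effect site.
#'
#' @param system a [build_system()] object.
#' @param target target concentration (ug/mL), > 0.
#' @param duration simulated duration (min).
#' @param mode `"effect_site"` (default) or `"plasma"`.
#' @param control_interval control tick (s).
#' @param rate_cap maximum pump rate (mg/h).
#' @param horizon look-ahead horizon of the effect-site peak predictor
#'   (min); must comfortably exceed the time to peak effect.
#' @param weight optional body weight (kg) for per-kg dose summaries.
#' @param maintenance_window window (min) over which the maintenance
#'   infusion rate is averaged.
#' @param induction_fraction fraction of target defining attainment; the
#'   induction dose is the cumulative dose at first attainment.
#' @return An object of class `tci_plan`: list with `schedule`
#'   (a [dose_schedule()]), `timecourse` (a `pkpd_timecourse`), `target`,
#'   `mode`, `induction_time` (min), `induction_dose` (mg; per-kg in
#'   `induction_dose_mg_kg` when `weight` given), `maintenance_rate_mg_min`
#'   (and `_mg_kg_h`), `achieved` and `overshoot`.
#' @export
#' @examples
#' cov <- subject_covariates(35, 70, opioids = TRUE)
#' sys <- build_system(remi_pk_params(cov), metab_pk_params(cov))
#' plan <- plan_tci(sys, target = 0.9, duration = 20, weight = 70)
plan_tci <- function(system, target, duration = 60,
                     mode = c("effect_site", "plasma"),
                     control_interval = 1, rate_cap = 600, horizon = 15,
                     weight = NULL, maintenance_window = c(30, 60),
                     induction_fraction = 0.99) {
  mode <- match.arg(mode)
  stopifnot(target > 0, duration > 0)
  dt <- control_interval / 60
  cap <- rate_cap / 60  # mg/min
  pre <- tci_precompute(system, dt, horizon)
  n_ticks <- ceiling(duration / dt)
  run <- tci_run(system, pre, target, n_ticks, mode, cap)
  tgrid <- seq(0, n_ticks) * dt

  sig <- if (mode == "plasma") run$X[, "A1"] / system$remi$V1 else
    run$X[, "Ce_moaas"]
  hit <- which(sig >= induction_fraction * target)
  achieved <- length(hit) > 0
  cum <- c(0, cumsum(run$rates * dt)) + run$bolus
  ind_time <- if (achieved) tgrid[hit[1]] else NA_real_
  ind_dose <- if (achieved) cum[hit[1]] else NA_real_
  mw <- maintenance_window
  in_w <- tgrid[-1] > mw[1] & tgrid[-1] <= mw[2]
  maint <- if (any(in_w)) sum(run$rates[in_w] * dt) / (diff(mw)) else NA_real_

  tc <- dplyr::bind_cols(tibble::tibble(time = tgrid),
                         observe_states(system, run$X),
                         tibble::as_tibble(run$X)[c("A1", "A2", "A3",
                                                    "Adepot", "Am1", "Am2",
                                                    "ElimR", "ElimM")])
  tc$cum_dose <- cum
  attr(tc, "system") <- system
  class(tc) <- c("pkpd_timecourse", class(tc))

  # compress the per-tick rates into dosing records
  rl <- rle(round(run$rates, 9))
  ends <- cumsum(rl$lengths)
  starts <- c(0, ends[-length(ends)]) * dt
  recs <- tibble::tibble(time = starts, amount = rl$values * rl$lengths * dt,
                         duration = rl$lengths * dt)
  recs <- recs[recs$amount > 0, ]
  sched <- dose_schedule(
    if (run$bolus > 0) dose_bolus(0, run$bolus) else NULL, recs)

  structure(list(
    schedule = sched, timecourse = tc, target = target, mode = mode,
    control_interval = control_interval, rate_cap = rate_cap,
    induction_time = ind_time, induction_dose = ind_dose,
    induction_dose_mg_kg = if (is.null(weight)) NA_real_ else ind_dose / weight,
    maintenance_rate_mg_min = maint,
    maintenance_rate_mg_kg_h = if (is.null(weight)) NA_real_ else
      maint * 60 / weight,
    weight = weight, achieved = achieved,
    overshoot = max(sig) / target - 1
  ), class = "tci_plan")
}

#' @export
print.tci_plan <- function(x, ...) {
  cat(sprintf("<tci_plan> %s TCI, target %.3g ug/mL\n", x$mode, x$target))
  cat(sprintf("  attained: %s at %.2f min; induction dose %.2f mg%s\n",
              x$achieved, x$induction_time, x$induction_dose,
              if (!is.na(x$induction_dose_mg_kg))
                sprintf(" (%.3f mg/kg)", x$induction_dose_mg_kg) else ""))
  cat(sprintf("  maintenance rate %.3f mg/min%s; overshoot %.2f%%\n",
              x$maintenance_rate_mg_min,
              if (!is.na(x$maintenance_rate_mg_kg_h))
                sprintf(" (%.2f mg/kg/h)", x$maintenance_rate_mg_kg_h) else "",
              100 * x$overshoot))
  invisible(x)
}

# build the individual's full system from covariates (population prediction
# unless etas are supplied)
subject_system <- function(cov, theta = pkpd_theta(), eta = NULL) {
  remi <- remi_pk_params(cov, theta, eta)
  metab <- metab_pk_params(cov, theta, eta)
  adj <- apply_ecmo_icu(remi, metab, cov, theta)
  build_system(adj$remi, adj$metab,
               ke0_moaas = moaas_params(cov, theta, eta)$ke0[1],
               ke0_bis = bis_params(cov, theta, eta)$ke0[1])
}

#' Find the effect-site target for a sedation or anaesthesia criterion
#'
#' Searches for the constant effect-site target concentration satisfying
#' the scenario criterion under effect-site TCI, by simulation of the full
#' system (so the accumulating metabolite and the opioid cut-point shift
#' are accounted for):
#' * `"sedation"`: the target maximising the probability of MOAA/S 2 or 3
#'   at 10 min.
#' * `"anaesthesia"`: the minimal target achieving a 90% probability of
#'   MOAA/S 0 at first target attainment (induction).
#'
#' @param cov one-row covariate table.
#' @param theta fixed effects.
#' @param scenario `"sedation"` or `"anaesthesia"`.
#' @param eta optional random effects (population prediction by default).
#' @param p_induction induction probability criterion for anaesthesia.
#' @param tol search tolerance (ug/mL).
#' @param interval search interval for the target (ug/mL).
#' @param ... passed to [plan_tci()].
#' @return One-row tibble: `scenario`, `target` (ug/mL), `ce50`,
#'   `target_over_ce50`, `criterion` (the achieved criterion value).
#' @export
find_sedation_target <- function(cov, theta = pkpd_theta(),
                                 scenario = c("sedation", "anaesthesia"),
                                 eta = NULL, p_induction = 0.9, tol = 1e-3,
                                 interval = c(0.02, 2), ...) {
  scenario <- match.arg(scenario)
  stopifnot(nrow(cov) == 1)
  sys <- subject_system(cov, theta, eta)
  mo <- moaas_params(cov, theta, eta)
  opi <- cov$opioids[1]

  if (scenario == "anaesthesia") {
    crit <- function(target) {
      plan <- plan_tci(sys, target, duration = 15, ...)
      if (!plan$achieved) return(NA_real_)
      i <- which.min(abs(plan$timecourse$time - plan$induction_time))
      moaas_probabilities(plan$timecourse$ce_moaas[i],
                          plan$timecourse$ca_metab[i], mo,
                          opioids = opi)$p0
    }
    hi <- crit(interval[2])
    if (is.na(hi) || hi < p_induction) {
      stop("anaesthesia criterion unattainable within the search interval",
           call. = FALSE)
    }
    root <- stats::uniroot(function(x) crit(x) - p_induction, interval,
                           tol = tol)
    target <- root$root
    value <- root$f.root + p_induction
  } else {
    crit <- function(target) {
      plan <- plan_tci(sys, target, duration = 10, ...)
      i <- nrow(plan$timecourse)
      pr <- moaas_probabilities(plan$timecourse$ce_moaas[i],
                                plan$timecourse$ca_metab[i], mo,
                                opioids = opi)
      pr$p2 + pr$p3
    }
    opt <- stats::optimize(crit, interval, maximum = TRUE, tol = tol)
    target <- opt$maximum
    value <- opt$objective
  }
  tibble::tibble(scenario = scenario, target = target, ce50 = mo$Ce50[1],
                 target_over_ce50 = target / mo$Ce50[1], criterion = value)
}

#' Dosing requirements across age
#'
#' For each age, finds the scenario target with [find_sedation_target()],
#' plans a 60-min effect-site TCI and summarises the induction dose and the
#' maintenance infusion rate (averaged over minutes 30-60), together with
#' the predicted MOAA/S and BIS at selected times. Defaults follow the
#' simulation conditions: opioids present, normal hepatic and renal
#' function.
#'
#' @param ages vector of ages (years).
#' @param scenario `"sedation"` or `"anaesthesia"`.
#' @param weight kg; @param sex `"male"`/`"female"`; @param opioids logical.
#' @param theta fixed effects.
#' @param ... passed to [plan_tci()] / [find_sedation_target()].
#' @return Tibble with one row per age: `age`, `target`,
#'   `target_over_ce50`, `induction_dose_mg_kg`,
#'   `maintenance_rate_mg_kg_h`, `ews_10min`, `ews_60min`, `bis_10min`,
#'   `bis_60min`.
#' @export
dosing_vs_age <- function(ages, scenario = c("sedation", "anaesthesia"),
                          weight = 70, sex = "male", opioids = TRUE,
                          theta = pkpd_theta(), ...) {
  scenario <- match.arg(scenario)
  purrr::map_dfr(ages, function(a) {
    cov <- subject_covariates(a, weight, sex = sex, opioids = opioids)
    tg <- find_sedation_target(cov, theta, scenario, ...)
    sys <- subject_system(cov, theta)
    plan <- plan_tci(sys, tg$target, duration = 60, weight = weight, ...)
    tc <- pd_timecourse(plan$timecourse, moaas_params(cov, theta),
                        bis_params(cov, theta), opioids = opioids)
    at <- function(t, col) tc[[col]][which.min(abs(tc$time - t))]
    tibble::tibble(
      age = a, target = tg$target, target_over_ce50 = tg$target_over_ce50,
      induction_dose_mg_kg = plan$induction_dose_mg_kg,
      maintenance_rate_mg_kg_h = plan$maintenance_rate_mg_kg_h,
      ews_10min = at(10, "ews"), ews_60min = at(60, "ews"),
      bis_10min = at(10, "bis"), bis_60min = at(60, "bis")
    )
  })
}
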