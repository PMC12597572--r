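#' Assemble the full remimazolam / CNS7054 compartmental system
#'
#' Builds the constant-coefficient linear ODE system coupling the
#' remimazolam three-compartment mammillary model, the arteriovenous delay
#' compartment, the two mass-less effect sites (MOAA/S and BIS), and the
#' CNS7054 depot / two-compartment chain with its own venous delay. All
#' eliminated remimazolam mass enters the metabolite depot (fraction
#' metabolised 100%), scaled by `mass_conversion`. Two bookkeeping states
#' accumulate eliminated remimazolam and metabolite mass so that mass
#' balance can be checked exactly.
#'
#' State vector (amounts in mg, delay/effect states in ug/mL):
#' `A1, A2, A3, Cdel, Ce_moaas, Ce_bis, Adepot, Am1, Am2, CdelM, ElimR,
#' ElimM`. Venous concentrations are the convex combination
#' `Cven = Fven * Cart + (1 - Fven) * Cdel` with a mass-less first-order
#' delay tracer `dCdel/dt = Kdelay * (Cart - Cdel)`; the remimazolam
#' arteriovenous model is reused for CNS7054.
#'
#' @param remi one-row tibble from [remi_pk_params()].
#' @param metab one-row tibble from [metab_pk_params()], or `NULL` to omit
#'   the metabolite chain (its states remain zero).
#' @param ke0_moaas,ke0_bis effect-site equilibration rate constants
#'   (1/min).
#' @return An object of class `pkpd_system`: list with the rate matrix `A`,
#'   input vector `b` (unit infusion into the remimazolam central
#'   compartment), state names and the parameter set.
#' @export
#' @examples
#' cov <- subject_covariates(35, 70)
#' sys <- build_system(remi_pk_params(cov), metab_pk_params(cov))
build_system <- function(remi, metab = NULL,
                         ke0_moaas = pkpd_theta()$moaas$ke0,
                         ke0_bis = pkpd_theta()$bis$ke0) {
  remi <- as.list(tibble::as_tibble(remi)[1, ])
  with_m <- !is.null(metab)
  if (with_m) metab <- as.list(tibble::as_tibble(metab)[1, ])
  pos <- c(remi$V1, remi$V2, remi$V3, remi$CL, remi$Q2, remi$Q3, remi$Kdelay,
           ke0_moaas, ke0_bis,
           if (with_m) c(metab$V1m, metab$V2m, metab$CLm, metab$Q2m,
                         metab$Kdepot))
  if (any(!is.finite(pos)) || any(pos <= 0)) {
    stop("all volumes, clearances and rate constants must be positive",
         call. = FALSE)
  }
  states <- c("A1", "A2", "A3", "Cdel", "Ce_moaas", "Ce_bis",
              "Adepot", "Am1", "Am2", "CdelM", "ElimR", "ElimM")
  n <- length(states)
  A <- matrix(0, n, n, dimnames = list(states, states))
  V1 <- remi$V1; V2 <- remi$V2; V3 <- remi$V3
  CL <- remi$CL; Q2 <- remi$Q2; Q3 <- remi$Q3
  A["A1", "A1"] <- -(CL + Q2 + Q3) / V1
  A["A1", "A2"] <- Q2 / V2
  A["A1", "A3"] <- Q3 / V3
  A["A2", "A1"] <- Q2 / V1; A["A2", "A2"] <- -Q2 / V2
  A["A3", "A1"] <- Q3 / V1; A["A3", "A3"] <- -Q3 / V3
  A["Cdel", "A1"] <- remi$Kdelay / V1; A["Cdel", "Cdel"] <- -remi$Kdelay
  A["Ce_moaas", "A1"] <- ke0_moaas / V1; A["Ce_moaas", "Ce_moaas"] <- -ke0_moaas
  A["Ce_bis", "A1"] <- ke0_bis / V1; A["Ce_bis", "Ce_bis"] <- -ke0_bis
  A["ElimR", "A1"] <- CL / V1
  if (with_m) {
    mc <- if (is.null(metab$mass_conversion)) 1 else metab$mass_conversion
    V1m <- metab$V1m; V2m <- metab$V2m
    CLm <- metab$CLm; Q2m <- metab$Q2m; Kdep <- metab$Kdepot
    A["Adepot", "A1"] <- mc * CL / V1
    A["Adepot", "Adepot"] <- -Kdep
    A["Am1", "Adepot"] <- Kdep
    A["Am1", "Am1"] <- -(CLm + Q2m) / V1m
    A["Am1", "Am2"] <- Q2m / V2m
    A["Am2", "Am1"] <- Q2m / V1m; A["Am2", "Am2"] <- -Q2m / V2m
    A["CdelM", "Am1"] <- remi$Kdelay / V1m; A["CdelM", "CdelM"] <- -remi$Kdelay
    A["ElimM", "Am1"] <- CLm / V1m
  }
  b <- numeric(n); b[1] <- 1
  structure(list(A = A, b = b, states = states,
                 remi = remi, metab = if (with_m) metab else NULL,
                 ke0_moaas = ke0_moaas, ke0_bis = ke0_bis),
            class = "pkpd_system")
}

#' @export
print.pkpd_system <- function(x, ...) {
  cat("<pkpd_system> ", length(x$states), " states",
      if (is.null(x$metab)) " (remimazolam only)" else
        " (remimazolam + CNS7054)", "\n", sep = "")
  cat(sprintf("  remi: V1=%.3g V2=%.3g V3=%.3g L, CL=%.3g Q2=%.3g Q3=%.3g L/min\n",
              x$remi$V1, x$remi$V2, x$remi$V3, x$remi$CL, x$remi$Q2, x$remi$Q3))
  invisible(x)
}

# cached matrix exponential of the augmented [A b; 0 0] system, keyed by dt
make_propagator <- function(A, b) {
  n <- nrow(A)
  M <- rbind(cbind(A, b), 0)
  cache <- new.env(parent = emptyenv())
  function(dt) {
    key <- sprintf("%.15g", dt)
    e <- cache[[key]]
    if (is.null(e)) {
      e <- as.matrix(Matrix::expm(M * dt))
      cache[[key]] <- e
    }
    e
  }
}

# state -> observed signals
observe_states <- function(system, X) {
  r <- system$remi
  sig <- tibble::tibble(
    cp_art = X[, "A1"] / r$V1,
    c_ven = r$Fven * X[, "A1"] / r$V1 + (1 - r$Fven) * X[, "Cdel"],
    ce_moaas = X[, "Ce_moaas"],
    ce_bis = X[, "Ce_bis"]
  )
  if (!is.null(system$metab)) {
    m <- system$metab
    sig$ca_metab <- X[, "Am1"] / m$V1m
    sig$cven_metab <- r$Fven * X[, "Am1"] / m$V1m +
      (1 - r$Fven) * X[, "CdelM"]
  } else {
    sig$ca_metab <- 0
    sig$cven_metab <- 0
  }
  sig
}

#' Simulate a dosing schedule
#'
#' Exact piecewise solution of the linear system: within every interval of
#' constant infusion rate the state is propagated with the matrix
#' exponential of the augmented (state, input) system; boluses are
#' instantaneous increments of the remimazolam central compartment, applied
#' before sampling at the same time point.
#'
#' @param system a [build_system()] object.
#' @param schedule a [dose_schedule()].
#' @param times sorted non-negative output times (min).
#' @param x0 optional initial state (default zero).
#' @return A tibble of class `pkpd_timecourse`: `time`, arterial and venous
#'   remimazolam (`cp_art`, `c_ven`), effect-site concentrations
#'   (`ce_moaas`, `ce_bis`), arterial and venous CNS7054 (`ca_metab`,
#'   `cven_metab`) in ug/mL, compartment amounts, cumulative eliminated
#'   masses and `cum_dose` (mg). The system is attached as attribute
#'   `system`.
#' @export
#' @examples
#' cov <- subject_covariates(35, 70)
#' sys <- build_system(remi_pk_params(cov), metab_pk_params(cov))
#' tc <- simulate_pkpd(sys, dose_schedule(dose_bolus(0, 10)), seq(0, 60, 1))
simulate_pkpd <- function(system, schedule, times, x0 = NULL) {
  stopifnot(inherits(system, "pkpd_system"))
  times <- as.numeric(times)
  if (is.unsorted(times)) stop("times must be sorted", call. = FALSE)
  if (any(times < 0)) stop("times must be non-negative", call. = FALSE)
  sch <- dose_schedule(schedule)
  prof <- schedule_profile(sch)
  prop <- make_propagator(system$A, system$b)
  n <- length(system$states)
  x <- if (is.null(x0)) numeric(n) else as.numeric(x0)
  stopifnot(length(x) == n)

  # walk the union of breakpoints and output times
  ev <- sort(unique(c(prof$breaks, times)))
  ev <- ev[ev <= max(times, 0)]
  out <- matrix(NA_real_, nrow = length(times), ncol = n,
                dimnames = list(NULL, system$states))
  t_cur <- 0
  ti <- 1
  record <- function(tt, x) {
    while (ti <= length(times) && times[ti] == tt) {
      out[ti, ] <<- x
      ti <<- ti + 1
    }
  }
  apply_bolus <- function(tt, x) {
    amt <- sum(prof$boluses$amount[prof$boluses$time == tt])
    if (amt > 0) x[1] <- x[1] + amt
    x
  }
  x <- apply_bolus(0, x)
  record(0, x)
  for (tt in ev[ev > 0]) {
    dt <- tt - t_cur
    r <- prof$rate_at(t_cur + dt / 2)
    E <- prop(dt)
    x <- as.numeric(E[seq_len(n), ] %*% c(x, r))
    t_cur <- tt
    x <- apply_bolus(tt, x)
    record(tt, x)
  }
  tc <- dplyr::bind_cols(
    tibble::tibble(time = times),
    observe_states(system, out),
    tibble::as_tibble(out)[c("A1", "A2", "A3", "Adepot", "Am1", "Am2",
                             "ElimR", "ElimM")]
  )
  tc$cum_dose <- cumulative_dose(sch, times)
  attr(tc, "system") <- system
  attr(tc, "schedule") <- sch
  class(tc) <- c("pkpd_timecourse", class(tc))
  tc
}

#' Time to peak effect-site concentration after a bolus
#'
#' For a linear system the post-bolus effect-site trajectory is
#' dose-independent up to scale, so the time of peak effect is a property
#' of the PK parameter set and `ke0`. Located by bracketing on a coarse
#' grid followed by golden-section refinement of the continuous
#' matrix-exponential solution.
#'
#' @param remi one-row tibble from [remi_pk_params()].
#' @param ke0 effect-site rate constant (1/min); the MOAA/S value by
#'   default, as used by the TCI algorithm.
#' @param t_max search horizon (min).
#' @param tol time tolerance (min).
#' @return Peak time in min, with the peak effect-site concentration per mg
#'   of bolus attached as attribute `peak_ce`.
#' @export
#' @examples
#' time_to_peak_effect(remi_pk_params(subject_covariates(35, 70)))
time_to_peak_effect <- function(remi, ke0 = pkpd_theta()$moaas$ke0,
                                t_max = 60, tol = 1e-4) {
  sys <- build_system(remi, metab = NULL, ke0_moaas = ke0)
  A <- sys$A[1:6, 1:6]  # metabolite/bookkeeping states not needed
  x0 <- c(1, numeric(5))
  i_ce <- match("Ce_moaas", sys$states[1:6])
  ce <- function(t) {
    vapply(t, function(tt) (as.matrix(Matrix::expm(A * tt)) %*% x0)[i_ce],
           numeric(1))
  }
  grid <- seq(tol, t_max, length.out = 200)
  vals <- ce(grid)
  i <- which.max(vals)
  lo <- grid[max(i - 1, 1)]; hi <- grid[min(i + 1, length(grid))]
  opt <- stats::optimize(ce, c(lo, hi), maximum = TRUE, tol = tol)
  structure(opt$maximum, peak_ce = opt$objective)
}
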