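# reference individual: 70 kg, 35 yr, male, no opioids, normal organ function
ref_cov <- function(...) subject_covariates(35, 70, ...)

ref_system <- function(cov = ref_cov(), theta = pkpd_theta()) {
  build_system(remi_pk_params(cov, theta), metab_pk_params(cov, theta),
               ke0_moaas = moaas_params(cov, theta)$ke0[1],
               ke0_bis = bis_params(cov, theta)$ke0[1])
}

# random covariate draw over the modelled demographic envelope
random_cov <- function(pugh = FALSE, esrd = FALSE) {
  subject_covariates(
    age = runif(1, 6, 93), weight = runif(1, 21, 171),
    sex = sample(c("male", "female"), 1),
    opioids = runif(1) < 0.5,
    pugh_gt8 = pugh && runif(1) < 0.5, esrd = esrd && runif(1) < 0.5)
}

# random bolus/infusion schedule over a 60-min window
random_schedule <- function() {
  n_bol <- sample(0:2, 1)
  n_inf <- sample(1:2, 1)
  dose_schedule(
    if (n_bol > 0) dose_bolus(sort(runif(n_bol, 0, 20)),
                              runif(n_bol, 1, 10)),
    dose_infusion(runif(n_inf, 0, 30), duration = runif(n_inf, 5, 25),
                  rate = runif(n_inf, 0.2, 2)))
}

# independent adaptive ODE solution of the same linear system (piecewise
# per constant-rate segment so solver restarts line up with discontinuities)
ode_oracle <- function(system, schedule, times, rtol = 1e-10, atol = 1e-12) {
  skip_if_not_installed("deSolve")
  prof <- remipkpd:::schedule_profile(schedule)
  n <- length(system$states)
  deriv <- function(t, y, parms) {
    list(as.numeric(system$A %*% y) + system$b * parms)
  }
  brk <- sort(unique(c(prof$breaks, max(times))))
  brk <- brk[brk <= max(times)]
  if (brk[1] != 0) brk <- c(0, brk)
  x <- numeric(n)
  bump <- function(tt, x) {
    amt <- sum(prof$boluses$amount[prof$boluses$time == tt])
    x[1] <- x[1] + amt
    x
  }
  x <- bump(0, x)
  out <- matrix(NA_real_, length(times), n, dimnames = list(NULL, system$states))
  record <- function(tt, x) {
    hit <- which(times == tt)
    for (j in hit) out[j, ] <<- x
  }
  record(0, x)
  for (k in seq_len(length(brk) - 1)) {
    t0 <- brk[k]; t1 <- brk[k + 1]
    inner <- times[times > t0 & times < t1]
    tt <- sort(unique(c(t0, inner, t1)))
    r <- prof$rate_at((t0 + t1) / 2)
    sol <- deSolve::lsoda(x, tt, deriv, parms = r, rtol = rtol, atol = atol)
    for (ti in inner) record(ti, as.numeric(sol[match(ti, tt), -1]))
    x <- as.numeric(sol[nrow(sol), -1])
    x <- bump(t1, x)
    record(t1, x)
  }
  dplyr::bind_cols(tibble::tibble(time = times),
                   remipkpd:::observe_states(system, out))
}

# largest discrepancy between two timecourses, relative to signal scale
max_rel_err <- function(a, b, cols = c("cp_art", "c_ven", "ce_moaas",
                                       "ce_bis", "ca_metab", "cven_metab")) {
  max(vapply(cols, function(cl) {
    ref <- b[[cl]]
    scale <- max(abs(ref), 1e-12)
    max(abs(a[[cl]] - ref) / pmax(abs(ref), 1e-3 * scale))
  }, numeric(1)))
}
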