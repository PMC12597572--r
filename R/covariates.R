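#' Build a subject covariate table
#'
#' Constructs and validates the covariate record(s) driving all parameter
#' individualisation. All arguments are vectorised and recycled to a common
#' length.
#'
#' @param age age in years, > 0.
#' @param weight total body weight in kg, > 0.
#' @param sex `"male"` or `"female"`.
#' @param opioids logical, concomitant opioids present.
#' @param pugh_gt8 logical, Pugh-Child score > 8 (severe hepatic dysfunction).
#' @param esrd logical, end-stage renal disease.
#' @param ecmo_subject logical, individual receiving ECMO at any time.
#' @param ecmo_active logical, ECMO currently running (implies
#'   `ecmo_subject`).
#' @param icu_subject logical, treated in the ICU.
#' @param icu_gt24h logical, ICU treatment longer than 24 h (implies
#'   `icu_subject`).
#' @param venous_only logical, only venous PK samples available (inflates
#'   the variance of the remimazolam CL random effect).
#' @return A tibble with one row per subject, class `pkpd_covariates`.
#' @export
#' @examples
#' subject_covariates(35, 70)                     # the reference individual
#' subject_covariates(c(25, 80), 70, sex = "female", opioids = TRUE)
subject_covariates <- function(age, weight, sex = "male", opioids = FALSE,
                               pugh_gt8 = FALSE, esrd = FALSE,
                               ecmo_subject = FALSE, ecmo_active = FALSE,
                               icu_subject = FALSE, icu_gt24h = FALSE,
                               venous_only = FALSE) {
  cov <- tibble::tibble(
    age = as.numeric(age), weight = as.numeric(weight),
    sex = as.character(sex), opioids = as.logical(opioids),
    pugh_gt8 = as.logical(pugh_gt8), esrd = as.logical(esrd),
    ecmo_subject = as.logical(ecmo_subject),
    ecmo_active = as.logical(ecmo_active),
    icu_subject = as.logical(icu_subject),
    icu_gt24h = as.logical(icu_gt24h),
    venous_only = as.logical(venous_only)
  )
  validate_covariates(cov)
  class(cov) <- c("pkpd_covariates", class(cov))
  cov
}

validate_covariates <- function(cov) {
  stopifnot(is.data.frame(cov))
  if (any(!is.finite(cov$age)) || any(cov$age <= 0)) {
    stop("age must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(cov$weight)) || any(cov$weight <= 0)) {
    stop("weight must be positive and finite", call. = FALSE)
  }
  if (!all(cov$sex %in% c("male", "female"))) {
    stop("sex must be \"male\" or \"female\"", call. = FALSE)
  }
  if (any(cov$icu_gt24h & !cov$icu_subject)) {
    stop("icu_gt24h implies icu_subject", call. = FALSE)
  }
  if (any(cov$ecmo_active & !cov$ecmo_subject)) {
    stop("ecmo_active implies ecmo_subject", call. = FALSE)
  }
  invisible(cov)
}

# covariate factor helpers; K scales exactly as estimated:
# continuous (age): exp(K/1000 * (age - 35)); binary: exp(K/100)
f_age <- function(K, age) exp(K / 1000 * (age - 35))
f_bin <- function(K, flag) ifelse(flag, exp(K / 100), 1)

# expand an eta data frame / named vector to one column per requested name,
# zero-filled; rows recycled against n
eta_matrix <- function(eta, names, n) {
  m <- matrix(0, nrow = n, ncol = length(names), dimnames = list(NULL, names))
  if (is.null(eta)) return(m)
  if (is.numeric(eta) && !is.null(names(eta))) eta <- as.list(eta)
  eta <- tibble::as_tibble(eta)
  bad <- setdiff(names(eta), eta_names())
  if (length(bad) > 0) {
    stop("unknown eta name(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  keep <- intersect(names(eta), names)
  if (nrow(eta) == 1 && n > 1) eta <- eta[rep(1, n), , drop = FALSE]
  if (nrow(eta) != n) stop("eta rows must match covariate rows", call. = FALSE)
  for (nm in keep) m[, nm] <- eta[[nm]]
  m
}

#' Individualised remimazolam pharmacokinetic parameters
#'
#' Applies the final-model covariate equations to a covariate table:
#' `V1` and `V2` scale linearly with `weight/70`; `CL` scales with
#' `(weight/70)^0.75` and carries sex and opioid factors; `V3` scales with
#' weight and carries age, sex and Pugh-Child factors; `Q2` and `Q3` use
#' compartmental allometry, `Qx = Qx_ref * (Vx/Vx_ref)^0.75`, so covariate
#' effects on the volumes propagate into the intercompartmental clearances.
#' `Fven` and `Kdelay` (arteriovenous model) are returned unchanged.
#'
#' @param cov covariate table from [subject_covariates()] (or any data frame
#'   with the same columns).
#' @param theta fixed effects, see [pkpd_theta()].
#' @param eta optional data frame / named vector of log-scale random effects
#'   (columns among `V1, V2, V3, CL, Q2, Q3`); `NULL` gives the population
#'   prediction.
#' @return Tibble, one row per subject: `V1, V2, V3` (L), `CL, Q2, Q3`
#'   (L/min), `Fven` (fraction), `Kdelay` (1/min).
#' @export
#' @examples
#' remi_pk_params(subject_covariates(35, 70))   # Table-of-estimates values
remi_pk_params <- function(cov, theta = pkpd_theta(), eta = NULL) {
  validate_covariates(cov)
  th <- theta$remi
  n <- nrow(cov)
  e <- eta_matrix(eta, c("V1", "V2", "V3", "CL", "Q2", "Q3"), n)
  fsize <- cov$weight / 70
  female <- cov$sex == "female"
  V1 <- th$V1 * fsize * exp(as.vector(e[, "V1"]))
  V2 <- th$V2 * fsize * exp(as.vector(e[, "V2"]))
  V3 <- th$V3 * fsize * f_age(th$K_V3_age, cov$age) *
    f_bin(th$K_V3_sex, female) * f_bin(th$K_V3_pugh, cov$pugh_gt8) *
    exp(as.vector(e[, "V3"]))
  CL <- th$CL * fsize^0.75 * f_bin(th$K_CL_sex, female) *
    f_bin(th$K_CL_opiates, cov$opioids) * exp(as.vector(e[, "CL"]))
  Q2 <- th$Q2 * (V2 / th$V2)^0.75 * exp(as.vector(e[, "Q2"]))
  Q3 <- th$Q3 * (V3 / th$V3)^0.75 * exp(as.vector(e[, "Q3"]))
  tibble::tibble(V1 = V1, V2 = V2, V3 = V3, CL = CL, Q2 = Q2, Q3 = Q3,
                 Fven = th$Fven, Kdelay = th$Kdelay)
}

#' Individualised CNS7054 (metabolite) pharmacokinetic parameters
#'
#' Metabolite volumes scale with an estimated allometric exponent,
#' `(weight/70)^Kscale`; metabolite clearance scales with
#' `(weight/70)^0.75` and carries end-stage-renal-disease and opioid
#' factors; `Q2m` uses compartmental allometry and carries age and
#' Pugh-Child factors. `Kdepot` is the first-order transfer from the
#' metabolite formation depot into the CNS7054 central compartment.
#'
#' @inheritParams remi_pk_params
#' @param eta optional random effects (columns among
#'   `Kdepot, V1m, V2m, CLm, Q2m`).
#' @return Tibble: `Kdepot` (1/min), `V1m, V2m` (L), `CLm, Q2m` (L/min),
#'   `mass_conversion`.
#' @export
metab_pk_params <- function(cov, theta = pkpd_theta(), eta = NULL) {
  validate_covariates(cov)
  th <- theta$metab
  n <- nrow(cov)
  e <- eta_matrix(eta, c("Kdepot", "V1m", "V2m", "CLm", "Q2m"), n)
  fsize <- (cov$weight / 70)^th$Kscale
  Kdepot <- th$Kdepot * exp(as.vector(e[, "Kdepot"]))
  V1m <- th$V1 * fsize * exp(as.vector(e[, "V1m"]))
  V2m <- th$V2 * fsize * exp(as.vector(e[, "V2m"]))
  CLm <- th$CL * (cov$weight / 70)^0.75 * f_bin(th$K_CL_renal, cov$esrd) *
    f_bin(th$K_CL_opiates, cov$opioids) * exp(as.vector(e[, "CLm"]))
  Q2m <- th$Q2 * (V2m / th$V2)^0.75 * f_age(th$K_Q2_age, cov$age) *
    f_bin(th$K_Q2_pugh, cov$pugh_gt8) * exp(as.vector(e[, "Q2m"]))
  tibble::tibble(Kdepot = Kdepot, V1m = V1m, V2m = V2m, CLm = CLm, Q2m = Q2m,
                 mass_conversion = theta$mass_conversion)
}

#' Opioid-adjusted MOAA/S cut-points
#'
#' When opioids are present the proportional-odds model shifts probability
#' density from MOAA/S score 1 toward 0 while leaving the cumulative
#' probability of scores <= 1 unchanged:
#' `d01_op = d01 * exp(-K)` and `b0_op = b0 + d01 - d01_op`, so
#' `b0_op + d01_op = b0 + d01` exactly.
#'
#' @param b0 logit of P(S = 0) at zero drug effect, opioid-free.
#' @param d01 difference between the S<=1 and S=0 cumulative logits, >= 0.
#' @param K_d01_opiates opioid shift coefficient (log scale on `d01`).
#' @return Named list with `b0_op` and `d01_op`.
#' @export
#' @examples
#' derive_opioid_cutpoints(-16.6, 2.65, 1.67)
derive_opioid_cutpoints <- function(b0, d01, K_d01_opiates) {
  if (any(d01 < 0)) stop("d01 must be non-negative", call. = FALSE)
  d01_op <- d01 * exp(-K_d01_opiates)
  list(b0_op = b0 + d01 - d01_op, d01_op = d01_op)
}

#' Individualised MOAA/S pharmacodynamic parameters
#'
#' `Ce50` decreases with age (`exp(K/1000*(age-35))`, K negative); `ke0` has
#' no covariates and no interindividual variability. The opioid-adjusted
#' cut-points `(b0_op, d01_op)` are derived via
#' [derive_opioid_cutpoints()] and carried alongside the opioid-free ones.
#'
#' @inheritParams remi_pk_params
#' @param eta optional random effects (column `Ce50_moaas`).
#' @return Tibble: `ke0` (1/min), `b0, d01, d12, d23, d34, b0_op, d01_op,
#'   DEFF` (logit units), `Ce50, Ca50` (ug/mL), `gamma`.
#' @export
moaas_params <- function(cov, theta = pkpd_theta(), eta = NULL) {
  validate_covariates(cov)
  th <- theta$moaas
  n <- nrow(cov)
  e <- eta_matrix(eta, "Ce50_moaas", n)
  op <- derive_opioid_cutpoints(th$b0, th$d01, th$K_d01_opiates)
  tibble::tibble(
    ke0 = th$ke0,
    b0 = th$b0, d01 = th$d01, d12 = th$d12, d23 = th$d23, d34 = th$d34,
    b0_op = op$b0_op, d01_op = op$d01_op,
    DEFF = th$DEFF,
    Ce50 = th$Ce50 * f_age(th$K_Ce50_age, cov$age) * exp(as.vector(e[, "Ce50_moaas"])),
    Ca50 = th$Ca50,
    gamma = theta$gamma_moaas
  )
}

#' Individualised BIS pharmacodynamic parameters
#'
#' Both `Ce50` and `ke0` decrease with age.
#'
#' @inheritParams remi_pk_params
#' @param eta optional random effects (columns among `ke0_bis, Ce50_bis`).
#' @return Tibble: `ke0` (1/min), `Ce50, Ca50` (ug/mL), `baseline` (BIS
#'   units), `gamma`.
#' @export
bis_params <- function(cov, theta = pkpd_theta(), eta = NULL) {
  validate_covariates(cov)
  th <- theta$bis
  n <- nrow(cov)
  e <- eta_matrix(eta, c("ke0_bis", "Ce50_bis"), n)
  tibble::tibble(
    ke0 = th$ke0 * f_age(th$K_ke0_age, cov$age) * exp(as.vector(e[, "ke0_bis"])),
    Ce50 = th$Ce50 * f_age(th$K_Ce50_age, cov$age) * exp(as.vector(e[, "Ce50_bis"])),
    Ca50 = th$Ca50,
    baseline = th$baseline,
    gamma = theta$gamma_bis
  )
}

#' Post hoc ECMO / ICU adjustments to the PK parameters
#'
#' Applies the post hoc multiplicative adjustments for individuals
#' receiving ECMO or treated in the ICU, as direct factors:
#' remimazolam `V1` is multiplied by `K_V1_ecmo` while ECMO is running and
#' by `K_V_iecmo` for ECMO subjects; `V2` by `K_V_iecmo`; `V3` by
#' `K_V3_iecmo` (ECMO subjects) and `K_V3_icu` (ICU subjects); remimazolam
#' `CL` by `K_CL_iecmo` (ECMO subjects) and `K_CL_24h` (ICU > 24 h).
#' CNS7054 `V2` is multiplied by `K_V2_iecmo` and CNS7054 `CL` by
#' `K_CL_iecmo` (ECMO subjects) and `K_CL_icu` (ICU subjects). All factors
#' are 1 when the corresponding flag is off.
#'
#' Intercompartmental clearances are left as computed by the base model
#' (the adjustments are direct parameter multipliers, not covariates that
#' re-enter the compartmental-allometry chain).
#'
#' @param remi tibble from [remi_pk_params()].
#' @param metab tibble from [metab_pk_params()], or `NULL`.
#' @param cov matching covariate table.
#' @param theta fixed effects.
#' @return List with adjusted `remi` and `metab` tibbles.
#' @export
apply_ecmo_icu <- function(remi, metab = NULL, cov, theta = pkpd_theta()) {
  validate_covariates(cov)
  k <- theta$ecmo_icu
  fac <- function(K, flag) ifelse(flag, K, 1)
  remi <- dplyr::mutate(
    remi,
    V1 = .data$V1 * fac(k$K_V1_ecmo, cov$ecmo_active) *
      fac(k$K_V_iecmo, cov$ecmo_subject),
    V2 = .data$V2 * fac(k$K_V_iecmo, cov$ecmo_subject),
    V3 = .data$V3 * fac(k$K_V3_iecmo, cov$ecmo_subject) *
      fac(k$K_V3_icu, cov$icu_subject),
    CL = .data$CL * fac(k$K_CL_iecmo, cov$ecmo_subject) *
      fac(k$K_CL_24h, cov$icu_gt24h)
  )
  if (!is.null(metab)) {
    metab <- dplyr::mutate(
      metab,
      V2m = .data$V2m * fac(k$K_V2_iecmo, cov$ecmo_subject),
      CLm = .data$CLm * fac(k$K_CL_iecmo, cov$ecmo_subject) *
        fac(k$K_CL_icu, cov$icu_subject)
    )
  }
  list(remi = remi, metab = metab)
}

#' Simplified remimazolam population predictions
#'
#' Literal transcription of the simplified population-prediction equations
#' published for TCI use (normal hepatic and renal function, no
#' interindividual variability). Serves as an internal cross-check of
#' [remi_pk_params()]; the two agree to within the rounding of the
#' published estimates (< 0.2% relative).
#'
#' @param age years; @param weight kg; @param sex `"male"`/`"female"`;
#' @param opioids logical.
#' @return Tibble with `V1, V2, V3, CL, Q2, Q3, ke0`.
#' @export
simplified_remi_params <- function(age, weight, sex = "male", opioids = FALSE) {
  m1f2 <- ifelse(sex == "female", 2, 1)
  oa1p2 <- ifelse(opioids, 2, 1)
  KOCL <- -0.139340 * (oa1p2 - 1)
  KSV3 <- 0.287037 * (m1f2 - 1)
  KSCL <- 0.162802 * (m1f2 - 1)
  KAV3 <- 0.00730817 * (age - 35)
  VSIZ <- weight / 70
  CSIZ <- (weight / 70)^0.75
  V3 <- VSIZ * 18.6411 * exp(KAV3 + KSV3)
  tibble::tibble(
    V1 = VSIZ * 4.30730,
    V2 = VSIZ * 12.2994,
    V3 = V3,
    CL = CSIZ * 1.11977 * exp(KSCL + KOCL),
    Q2 = (VSIZ^0.75) * 1.45260,
    Q3 = ((V3 / 18.6411)^0.75) * 0.297838,
    ke0 = 0.298269
  )
}
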