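#' Default fixed-effect estimates for the remimazolam / CNS7054 PK-PD model
#'
#' Returns the full set of population fixed effects ("theta") of the final
#' model: structural parameters for the remimazolam three-compartment model
#' with arteriovenous delay, the sequential CNS7054 depot/two-compartment
#' model, the proportional-odds MOAA/S model and the sigmoidal BIS model,
#' together with the covariate coefficients, the post hoc ECMO/ICU
#' multipliers, the (unreported, hence configurable) Hill exponents and the
#' remimazolam-to-CNS7054 mass conversion factor.
#'
#' All estimates refer to a reference individual: a 70-kg, 35-yr-old male
#' without concomitant opioids and with normal hepatic and renal function.
#' Units: volumes L, clearances L/min, first-order rate constants 1/min,
#' concentrations ug/mL, time min.
#'
#' Covariate coefficient conventions (as estimated): age effects enter as
#' `exp(K/1000 * (age - 35))`, binary effects as `exp(K/100)`, and the
#' ECMO/ICU coefficients are direct multiplicative factors.
#'
#' @param overrides optional named list of replacement values, possibly
#'   nested (e.g. `list(remi = list(CL = 1.0))`), as produced by
#'   [read_pkpd_config()]. Unknown names are an error.
#' @return A nested list with components `remi`, `metab`, `moaas`, `bis`,
#'   `ecmo_icu` and scalars `gamma_moaas`, `gamma_bis`, `mass_conversion`.
#' @seealso [pkpd_omega2()] for the interindividual variances,
#'   [remi_pk_params()] and friends for individualisation.
#' @export
#' @examples
#' theta <- pkpd_theta()
#' theta$remi$CL   # 1.12 L/min for the reference individual
pkpd_theta <- function(overrides = NULL) {
  theta <- list(
    remi = list(
      V1 = 4.31, V2 = 12.3, V3 = 18.6,
      CL = 1.12, Q2 = 1.45, Q3 = 0.298,
      Fven = 0.132, Kdelay = 0.0144,
      K_V3_age = 7.31, K_CL_sex = 16.3, K_V3_sex = 28.7,
      K_CL_opiates = -13.9, K_V3_pugh = 82.4,
      K_omega2_CL_ven = 1.86
    ),
    metab = list(
      Kdepot = 0.215, V1 = 6.85, V2 = 5.12,
      CL = 0.0665, Q2 = 0.141,
      K_CL_renal = -218, Kscale = 0.518, K_CL_opiates = -32.8,
      K_Q2_pugh = 188, K_Q2_age = 15.7
    ),
    moaas = list(
      DEFF = 19.9, ke0 = 0.298,
      b0 = -16.6, d01 = 2.65, d12 = 0.942, d23 = 1.47, d34 = 2.54,
      Ce50 = 0.182, Ca50 = 11.9,
      K_Ce50_age = -7.63, K_d01_opiates = 1.67
    ),
    bis = list(
      ke0 = 0.145, Ce50 = 0.982, baseline = 93.7, Ca50 = 8.41,
      K_Ce50_age = -16.4, K_ke0_age = -10.6
    ),
    ecmo_icu = list(
      K_V1_ecmo = 46.1,   # remi V1, while ECMO is running
      K_V_iecmo = 0.189,  # remi V1 and V2, individuals receiving ECMO
      K_V2_iecmo = 2.03,  # CNS7054 V2, individuals receiving ECMO
      K_V3_iecmo = 0.722, # remi V3, individuals receiving ECMO
      K_V3_icu = 1.59,    # remi V3, individuals treated in ICU
      K_CL_iecmo = 0.815, # remi and CNS7054 CL, individuals receiving ECMO
      K_CL_24h = 0.264,   # remi CL, ICU treatment > 24 h
      K_CL_icu = 0.426    # CNS7054 CL, individuals treated in ICU
    ),
    gamma_moaas = 1,
    gamma_bis = 1,
    mass_conversion = 1
  )
  modifyList_strict(theta, overrides)
}

#' Default interindividual variances (omega-squared)
#'
#' Log-domain variances of the log-normally distributed interindividual
#' random effects, in the canonical eta order used throughout the package:
#' remimazolam `V1, V2, V3, CL, Q2, Q3`, CNS7054 `Kdepot, V1m, V2m, CLm,
#' Q2m`, MOAA/S `Ce50_moaas`, BIS `ke0_bis, Ce50_bis`. Parameters without an
#' estimated variance accept no eta. The variance of the remimazolam CL eta
#' is inflated by the multiplier `venous_cl_multiplier` for individuals with
#' venous-only sampling.
#'
#' @param overrides optional named list of replacement values.
#' @return Named list: `omega2` (named numeric vector) and
#'   `venous_cl_multiplier`.
#' @export
#' @examples
#' cv_from_omega2(pkpd_omega2()$omega2[["CL"]])  # ~17.4% CV
pkpd_omega2 <- function(overrides = NULL) {
  out <- list(
    omega2 = c(
      V1 = 0.0631, V2 = 0.203, V3 = 0.138, CL = 0.0297, Q2 = 0.105, Q3 = 0.118,
      Kdepot = 0.257, V1m = 0.0888, V2m = 0.443, CLm = 0.145, Q2m = 0.989,
      Ce50_moaas = 0.195,
      ke0_bis = 0.549, Ce50_bis = 0.228
    ),
    venous_cl_multiplier = 1.86
  )
  modifyList_strict(out, overrides)
}

#' Canonical eta names
#'
#' Order of the interindividual random effects as used by
#' [sample_population()], [map_etas()] and the `eta` arguments of the
#' parameter-individualisation functions.
#' @return Character vector of eta names.
#' @export
eta_names <- function() names(pkpd_omega2()$omega2)

# recursive modifyList that refuses unknown names (typo protection for configs)
modifyList_strict <- function(base, overrides) {
  if (is.null(overrides)) return(base)
  stopifnot(is.list(overrides))
  bad <- setdiff(names(overrides), names(base))
  if (length(bad) > 0) {
    stop("unknown parameter name(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  for (nm in names(overrides)) {
    if (is.list(base[[nm]]) && is.list(overrides[[nm]])) {
      base[[nm]] <- modifyList_strict(base[[nm]], overrides[[nm]])
    } else if (is.vector(base[[nm]]) && length(base[[nm]]) > 1 &&
               !is.null(names(base[[nm]]))) {
      ov <- unlist(overrides[[nm]])
      bad2 <- setdiff(names(ov), names(base[[nm]]))
      if (length(bad2) > 0) {
        stop("unknown parameter name(s): ", paste(bad2, collapse = ", "),
             call. = FALSE)
      }
      base[[nm]][names(ov)] <- ov
    } else {
      base[[nm]] <- overrides[[nm]]
    }
  }
  base
}

#' Convert a log-domain variance to a coefficient of variation
#'
#' For a log-normal random effect with log-domain variance `omega2`, the
#' implied coefficient of variation is `100 * sqrt(exp(omega2) - 1)` percent.
#'
#' @param omega2 non-negative numeric vector of log-domain variances.
#' @return CV in percent, same length as `omega2`.
#' @export
#' @examples
#' cv_from_omega2(0.0631)  # 25.5
cv_from_omega2 <- function(omega2) {
  if (any(omega2 < 0)) stop("omega2 must be non-negative", call. = FALSE)
  100 * sqrt(exp(omega2) - 1)
}

#' Inverse of [cv_from_omega2()]
#' @param cv coefficient of variation in percent, non-negative.
#' @return Log-domain variance.
#' @export
omega2_from_cv <- function(cv) {
  if (any(cv < 0)) stop("cv must be non-negative", call. = FALSE)
  log1p((cv / 100)^2)
}
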