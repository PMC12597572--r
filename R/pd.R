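#' Competitive-interaction drug-effect fraction
#'
#' Shared Hill kernel of both pharmacodynamic models:
#' `(Ce/Ce50)^gamma / (1 + (Ce/Ce50)^gamma + (Ca/Ca50)^gamma)`.
#' The metabolite concentration `Ca` enters only the denominator
#' (competitive antagonism): it attenuates the remimazolam effect at fixed
#' `Ce` but produces no effect of its own when `Ce = 0`. This term is the
#' model's representation of tolerance: accumulating CNS7054 shifts
#' apparent sensitivity over time.
#'
#' @param ce remimazolam effect-site concentration (ug/mL), >= 0.
#' @param ca CNS7054 arterial concentration (ug/mL), >= 0.
#' @param ce50 remimazolam concentration for half-maximal effect.
#' @param ca50 CNS7054 concentration for half-maximal competitive
#'   interaction.
#' @param gamma Hill exponent, > 0.
#' @return Effect fraction in `[0, 1)`, vectorised.
#' @export
#' @examples
#' drug_effect_fraction(0.182, 0, 0.182, 11.9)     # 0.5
#' drug_effect_fraction(0.182, 11.9, 0.182, 11.9)  # 1/3
drug_effect_fraction <- function(ce, ca, ce50, ca50, gamma = 1) {
  if (any(ce < 0) || any(ca < 0)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  if (any(ce50 <= 0) || any(ca50 <= 0) || any(gamma <= 0)) {
    stop("ce50, ca50 and gamma must be positive", call. = FALSE)
  }
  u <- (ce / ce50)^gamma
  v <- (ca / ca50)^gamma
  u / (1 + u + v)
}

#' MOAA/S category probabilities
#'
#' Proportional-odds model for the ordinal MOAA/S score (0 = unresponsive
#' to noxious stimulus ... 5 = responds readily to name). The drug effect
#' enters the logit of the deepest category,
#' `l(S=0) = b0 + DEFF * f(Ce, Ca)`, and the cumulative logits follow by
#' adding the positive cut-point differences `d01, d12, d23, d34`. When
#' opioids are present the opioid-adjusted cut-points `(b0_op, d01_op)`
#' replace `(b0, d01)`: probability mass shifts from score 1 toward 0 while
#' `P(S <= 1)` is unchanged.
#'
#' @param ce,ca concentrations (ug/mL), vectorised.
#' @param params one-row tibble from [moaas_params()].
#' @param opioids logical, opioid co-administration.
#' @return Tibble with columns `ce`, `ca`, `p0`..`p5` (category
#'   probabilities), `ews` (probability-weighted mean score) and
#'   `cum0`..`cum4` (cumulative probabilities `P(S <= k)`).
#' @export
moaas_probabilities <- function(ce, ca, params, opioids = FALSE) {
  p <- as.list(tibble::as_tibble(params)[1, ])
  k <- max(length(ce), length(ca))
  ce <- rep_len(ce, k); ca <- rep_len(ca, k)
  f <- drug_effect_fraction(ce, ca, p$Ce50, p$Ca50, p$gamma)
  b0 <- if (opioids) p$b0_op else p$b0
  d01 <- if (opioids) p$d01_op else p$d01
  l0 <- b0 + p$DEFF * f
  lc <- cbind(l0, l0 + d01, l0 + d01 + p$d12, l0 + d01 + p$d12 + p$d23,
              l0 + d01 + p$d12 + p$d23 + p$d34)
  cum <- stats::plogis(lc)
  prob <- cbind(cum[, 1, drop = FALSE],
                cum[, -1, drop = FALSE] - cum[, -5, drop = FALSE],
                1 - cum[, 5, drop = FALSE])
  colnames(prob) <- paste0("p", 0:5)
  colnames(cum) <- paste0("cum", 0:4)
  out <- dplyr::bind_cols(tibble::tibble(ce = ce, ca = ca),
                          tibble::as_tibble(prob))
  out$ews <- as.numeric(prob %*% (0:5))
  dplyr::bind_cols(out, tibble::as_tibble(cum))
}

#' Predicted bispectral index
#'
#' Sigmoidal Emax model with competitive metabolite interaction:
#' `BIS = baseline * (1 - f(Ce, Ca))`. The prediction is noise-free; the
#' 15-s signal-processing delay, the additive residual and the 10-s median
#' filtering of the monitor stream belong to observation generation
#' ([generate_observations()]), not to the structural model.
#'
#' @param ce,ca concentrations (ug/mL), vectorised.
#' @param params one-row tibble from [bis_params()].
#' @return Numeric vector of predicted BIS in `(0, baseline]`.
#' @export
#' @examples
#' bis_predict(0, 0, bis_params(subject_covariates(35, 70)))  # 93.7
bis_predict <- function(ce, ca, params) {
  p <- as.list(tibble::as_tibble(params)[1, ])
  p$baseline * (1 - drug_effect_fraction(ce, ca, p$Ce50, p$Ca50, p$gamma))
}

#' Evaluate both pharmacodynamic models along a simulated timecourse
#'
#' Joins MOAA/S category probabilities (driven by the MOAA/S effect-site
#' concentration) and predicted BIS (driven by the BIS effect-site
#' concentration) to a [simulate_pkpd()] timecourse, using the arterial
#' CNS7054 concentration as the competing species. Because the metabolite
#' accumulates (its clearance is roughly 20-fold lower than the parent's),
#' predicted BIS and the probability-weighted MOAA/S score drift upward
#' over time at constant remimazolam effect-site concentration - the
#' model's tolerance behaviour.
#'
#' @param timecourse a `pkpd_timecourse`.
#' @param moaas one-row tibble from [moaas_params()].
#' @param bis one-row tibble from [bis_params()].
#' @param opioids logical.
#' @return The timecourse with added columns `p0`..`p5`, `ews`, `bis`.
#' @export
pd_timecourse <- function(timecourse, moaas, bis, opioids = FALSE) {
  mo <- moaas_probabilities(timecourse$ce_moaas, timecourse$ca_metab,
                            moaas, opioids = opioids)
  out <- dplyr::bind_cols(
    timecourse,
    mo[c(paste0("p", 0:5), "ews")],
    tibble::tibble(bis = bis_predict(timecourse$ce_bis,
                                     timecourse$ca_metab, bis))
  )
  class(out) <- class(timecourse)
  for (a in c("system", "schedule")) attr(out, a) <- attr(timecourse, a)
  out
}
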