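#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a simulated timecourse
#'
#' Faceted concentration panels (arterial/venous remimazolam, effect
#' sites, CNS7054), plus MOAA/S probability-weighted score and BIS panels
#' when present (see [pd_timecourse()]).
#'
#' @param object a `pkpd_timecourse`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot pkpd_timecourse
#' @export
autoplot.pkpd_timecourse <- function(object, ...) {
  conc_cols <- intersect(c("cp_art", "c_ven", "ce_moaas", "ce_bis",
                           "ca_metab", "cven_metab"), names(object))
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[c("time", conc_cols)],
    -"time", names_to = "signal", values_to = "conc")
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$conc,
                                          colour = .data$signal)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (min)", y = "concentration (µg/mL)",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (all(c("ews", "bis") %in% names(object))) {
    pd <- tidyr::pivot_longer(
      tibble::as_tibble(object)[c("time", "ews", "bis")],
      -"time", names_to = "measure", values_to = "value")
    p2 <- ggplot2::ggplot(pd, ggplot2::aes(.data$time, .data$value)) +
      ggplot2::geom_line() +
      ggplot2::facet_wrap(~measure, scales = "free_y") +
      ggplot2::labs(x = "time (min)", y = NULL) +
      ggplot2::theme_minimal()
    if (requireNamespace("patchwork", quietly = TRUE)) {
      return(patchwork::wrap_plots(p, p2, ncol = 1))
    }
    return(p2)
  }
  p
}

#' Plot a TCI plan
#'
#' Pump rate, targeted concentration with the target line, and cumulative
#' dose over time.
#'
#' @param object a `tci_plan`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot tci_plan
#' @export
autoplot.tci_plan <- function(object, ...) {
  tc <- object$timecourse
  sig <- if (object$mode == "plasma") "cp_art" else "ce_moaas"
  d <- tibble::tibble(time = tc$time, conc = tc[[sig]],
                      cum_dose = tc$cum_dose)
  ggplot2::ggplot(d, ggplot2::aes(.data$time, .data$conc)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$target, linetype = 2) +
    ggplot2::labs(
      x = "time (min)",
      y = sprintf("%s concentration (µg/mL)",
                  if (object$mode == "plasma") "plasma" else "effect-site"),
      title = sprintf("%s TCI, target %.3g µg/mL", object$mode,
                      object$target),
      subtitle = sprintf("induction %.2f mg at %.1f min; maintenance %.2f mg/min",
                         object$induction_dose, object$induction_time,
                         object$maintenance_rate_mg_min)) +
    ggplot2::theme_minimal()
}

#' Plot dosing requirements against age
#'
#' Induction dose and maintenance rate panels from a [dosing_vs_age()]
#' table, showing the age-dependence of remimazolam dosing.
#'
#' @param table tibble from [dosing_vs_age()].
#' @return A ggplot object.
#' @export
plot_dosing_vs_age <- function(table) {
  long <- tidyr::pivot_longer(
    table[c("age", "induction_dose_mg_kg", "maintenance_rate_mg_kg_h")],
    -"age", names_to = "quantity", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$age, .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "age (yr)", y = NULL) +
    ggplot2::theme_minimal()
}
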