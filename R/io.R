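dataset_required_cols <- c("ID", "TIME", "EVID", "AMT", "RATE", "CMT",
                           "DV", "MDV", "TYPE")

#' Read / write NONMEM-style long-format datasets
#'
#' Comma-separated, `.` decimal, UTF-8; columns `ID, TIME, EVID, AMT, RATE,
#' CMT, DV, MDV, TYPE` plus any covariate columns. `write_pkpd_dataset()`
#' followed by `read_pkpd_dataset()` is the identity on the numeric
#' content.
#'
#' Validation errors name the offending column or row: missing required
#' columns, non-numeric fields, dose rows with `AMT <= 0`, observation
#' rows with `MDV != 0` or without a `TYPE`, and MOAA/S observations with
#' `DV` outside `{0..5}`.
#'
#' @param path file path.
#' @param data a dataset tibble.
#' @return `read_pkpd_dataset()` returns a validated tibble of class
#'   `pkpd_dataset`; `write_pkpd_dataset()` returns `data` invisibly.
#' @export
read_pkpd_dataset <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_dataset(d)
}

#' @rdname read_pkpd_dataset
#' @export
write_pkpd_dataset <- function(data, path) {
  readr::write_csv(tibble::as_tibble(data), path, progress = FALSE)
  invisible(data)
}

#' @rdname read_pkpd_dataset
#' @export
validate_dataset <- function(data) {
  missing <- setdiff(dataset_required_cols, names(data))
  if (length(missing) > 0) {
    stop("dataset is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in c("TIME", "EVID", "AMT", "RATE", "CMT", "MDV")) {
    if (!is.numeric(data[[col]])) {
      stop("column ", col, " must be numeric", call. = FALSE)
    }
  }
  bad <- which(data$EVID == 1 & !(data$AMT > 0))
  if (length(bad) > 0) {
    stop("dose rows (EVID=1) must have AMT > 0; first offending row: ",
         bad[1], call. = FALSE)
  }
  bad <- which(data$EVID == 0 & data$MDV != 0)
  if (length(bad) > 0) {
    stop("observation rows (EVID=0) must have MDV = 0; first offending row: ",
         bad[1], call. = FALSE)
  }
  moaas <- which(data$EVID == 0 & data$TYPE == "MOAAS")
  bad <- moaas[!(data$DV[moaas] %in% 0:5)]
  if (length(bad) > 0) {
    stop("MOAA/S DV must be an integer in 0..5; first offending row: ",
         bad[1], call. = FALSE)
  }
  d <- tibble::as_tibble(data)
  if (!inherits(d, "pkpd_dataset")) class(d) <- c("pkpd_dataset", class(d))
  d
}

#' Read a model configuration file
#'
#' YAML or JSON (by extension) configuration overriding any fixed effect,
#' interindividual variance, Hill exponent, mass-conversion factor or
#' residual SD. Recognised top-level keys: `theta` (nested, as in
#' [pkpd_theta()]), `omega2`, `venous_cl_multiplier`, `gamma_moaas`,
#' `gamma_bis`, `mass_conversion`, `sigma_pk`, `sigma_bis`. Unknown
#' parameter names are an error (typo protection).
#'
#' @param path file path (`.yaml`, `.yml` or `.json`).
#' @return List with elements `theta` (complete fixed-effect list),
#'   `omega2` (complete variance list) and `sigma` (named residual SDs).
#' @export
read_pkpd_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    "yaml" = , "yml" = yaml::read_yaml(path),
    "json" = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported config format: .", ext, call. = FALSE))
  known <- c("theta", "omega2", "venous_cl_multiplier", "gamma_moaas",
             "gamma_bis", "mass_conversion", "sigma_pk", "sigma_bis")
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  th_over <- raw$theta
  for (k in c("gamma_moaas", "gamma_bis", "mass_conversion")) {
    if (!is.null(raw[[k]])) th_over[[k]] <- raw[[k]]
  }
  om_over <- list()
  if (!is.null(raw$omega2)) om_over$omega2 <- raw$omega2
  if (!is.null(raw$venous_cl_multiplier)) {
    om_over$venous_cl_multiplier <- raw$venous_cl_multiplier
  }
  list(
    theta = pkpd_theta(th_over),
    omega2 = pkpd_omega2(if (length(om_over)) om_over else NULL),
    sigma = c(sigma_pk = raw$sigma_pk %||% 0.20,
              sigma_bis = raw$sigma_bis %||% 4)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
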