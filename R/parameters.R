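#' Kinetic parameters of the saturable antibody-uptake model
#'
#' Container for the rate constants and antigen pool of the three-compartment
#' tumor uptake model.  In the `"nonlinear"` variant the plasma-to-surface
#' transfer is the saturable bimolecular term
#' `k_a * ([Ag_total] - [Ag-Ab]) * [Ab]_plasma`; in the `"linear"` comparator
#' the transfer is first-order in plasma concentration with rate `k21_lin`,
#' independent of antigen occupancy.
#'
#' @param k_a association rate constant, M^-1 h^-1 (nonlinear variant only).
#' @param ag_total total antigen concentration in tumor, uM.  Equals B_max
#'   expressed per unit tumor volume (nonlinear variant only).
#' @param k_int internalization rate of the surface antigen-antibody complex,
#'   h^-1 (first-order).
#' @param k_efflux efflux rate of label from the internalized compartment,
#'   h^-1 (first-order).
#' @param blood_fraction fraction of the plasma activity concentration
#'   contributing to the measured tumor signal (tumor vascular content).
#'   Default 0.08.
#' @param model_variant `"nonlinear"` (default) or `"linear"`.
#' @param k21_lin plasma-to-surface first-order rate, h^-1 (linear variant
#'   only).
#' @return An object of class `kinetic_parameters`.
#' @examples
#' kinetic_parameters(k_a = 2e5, ag_total = 1.3, k_int = 0.2, k_efflux = 0.09)
#' kinetic_parameters(k21_lin = 0.005, k_int = 0.2, k_efflux = 0.09,
#'                    model_variant = "linear")
#' @export
kinetic_parameters <- function(k_a = NULL, ag_total = NULL,
                               k_int, k_efflux,
                               blood_fraction = 0.08,
                               model_variant = c("nonlinear", "linear"),
                               k21_lin = NULL) {
  model_variant <- match.arg(model_variant)
  chk_rate <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0)
      stop(sprintf("'%s' must be a single finite non-negative number", nm),
           call. = FALSE)
    x
  }
  k_int <- chk_rate(k_int, "k_int")
  k_efflux <- chk_rate(k_efflux, "k_efflux")
  if (!is.numeric(blood_fraction) || blood_fraction < 0 || blood_fraction >= 1)
    stop("'blood_fraction' must be in [0, 1)", call. = FALSE)
  if (model_variant == "nonlinear") {
    if (is.null(k_a) || is.null(ag_total))
      stop("nonlinear variant requires 'k_a' and 'ag_total'", call. = FALSE)
    if (!is.null(k21_lin))
      stop("'k21_lin' applies to the linear variant only", call. = FALSE)
    k_a <- chk_rate(k_a, "k_a")
    ag_total <- chk_rate(ag_total, "ag_total")
  } else {
    if (is.null(k21_lin))
      stop("linear variant requires 'k21_lin'", call. = FALSE)
    if (!is.null(k_a) || !is.null(ag_total))
      stop("'k_a'/'ag_total' apply to the nonlinear variant only", call. = FALSE)
    k21_lin <- chk_rate(k21_lin, "k21_lin")
  }
  structure(
    list(k_a = k_a, ag_total = ag_total, k_int = k_int, k_efflux = k_efflux,
         blood_fraction = blood_fraction, model_variant = model_variant,
         k21_lin = k21_lin),
    class = "kinetic_parameters"
  )
}

#' @export
print.kinetic_parameters <- function(x, ...) {
  cat("Kinetic parameters (", x$model_variant, " variant)\n", sep = "")
  if (x$model_variant == "nonlinear") {
    cat(sprintf("  k_a       : %.4g M^-1 h^-1\n", x$k_a))
    cat(sprintf("  ag_total  : %.4g uM\n", x$ag_total))
  } else {
    cat(sprintf("  k21_lin   : %.4g h^-1\n", x$k21_lin))
  }
  cat(sprintf("  k_int     : %.4g h^-1\n", x$k_int))
  cat(sprintf("  k_efflux  : %.4g h^-1\n", x$k_efflux))
  cat(sprintf("  blood frac: %.3g\n", x$blood_fraction))
  invisible(x)
}

#' Read or write kinetic parameters as a configuration file
#'
#' Serializes a [kinetic_parameters()] object to a YAML (or JSON) key-value
#' file, keys named exactly as the constructor arguments, and reads it back.
#'
#' @param params a `kinetic_parameters` object.
#' @param path file path; extension `.json` selects JSON, anything else YAML.
#' @return `write_params` returns `path` invisibly; `read_params` returns a
#'   `kinetic_parameters` object.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "kinetic_parameters"))
  lst <- Filter(Negate(is.null), unclass(params))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(lst, path)
  }
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  lst <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(kinetic_parameters, lst)
}
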