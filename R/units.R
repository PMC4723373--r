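#' Antibody mass to amount conversion
#'
#' @param mass_ug antibody mass, micrograms.
#' @param mw molecular weight, g/mol (default 150,000, intact IgG).
#' @return amount, nmol.
#' @examples
#' mass_to_moles(60)    # 0.4 nmol
#' mass_to_moles(2000)  # 13.3 nmol
#' @export
mass_to_moles <- function(mass_ug, mw = .MW_IGG) {
  if (any(mass_ug <= 0) || mw <= 0)
    stop("mass and molecular weight must be > 0", call. = FALSE)
  mass_ug * 1e-6 / mw * 1e9
}

#' Convert between %ID/g and molar concentration
#'
#' `%ID/g` is a dose-normalized concentration; converting it to molarity
#' requires the administered antibody amount (from the injection record) and
#' the tissue density (g/mL, default 1):
#' `uM = (value / 100) * (mass_ug * 1e-6 / mw) * density * 1e9`.
#'
#' @param value_pidg activity concentration, %ID/g.
#' @param value_uM concentration, uM.
#' @param injection an [injection_record()] (mass and molecular weight).
#' @return `pidg_to_molar`: uM; `molar_to_pidg`: %ID/g.
#' @examples
#' inj <- injection_record(mass_ug = 150)
#' pidg_to_molar(100, inj)  # 1.0 uM
#' @export
pidg_to_molar <- function(value_pidg, injection) {
  .chk_inj(injection)
  dose_mol <- injection$mass_ug * 1e-6 / injection$mw
  value_pidg / 100 * dose_mol * injection$density * 1e9
}

#' @rdname pidg_to_molar
#' @export
molar_to_pidg <- function(value_uM, injection) {
  .chk_inj(injection)
  dose_mol <- injection$mass_ug * 1e-6 / injection$mw
  value_uM / (dose_mol * injection$density * 1e9) * 100
}

.chk_inj <- function(injection) {
  if (!inherits(injection, "injection_record"))
    stop("molar-mode modeling needs an injection_record (administered mass ",
         "and molecular weight) to convert %ID/g to molarity", call. = FALSE)
  invisible(TRUE)
}
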