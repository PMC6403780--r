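#' Inverse Debye screening length
#'
#' At 298 K in water the Debye length is `0.304 / sqrt(I)` nm for an ionic
#' strength `I` in mol/L; this returns its inverse, `kappa` in 1/nm.
#'
#' @param ionic_strength ionic strength in mol/L (> 0).
#' @return kappa in 1/nm.
#' @examples
#' 1 / debye_kappa(1)     # 0.304 nm
#' 1 / debye_kappa(0.01)  # 3.04 nm
#' @export
debye_kappa <- function(ionic_strength) {
  if (!is.numeric(ionic_strength) || any(ionic_strength <= 0))
    stop("`ionic_strength` must be > 0", call. = FALSE)
  sqrt(ionic_strength) / 0.304
}

#' Debye screening length
#'
#' @inheritParams debye_kappa
#' @return The Debye length `0.304 / sqrt(I)` in nm.
#' @export
debye_length <- function(ionic_strength) 1 / debye_kappa(ionic_strength)

#' Screened Coulomb pair potential
#'
#' Bundles the Bjerrum length and the inverse Debye length for use by
#' [dh_pair()].
#'
#' @inheritParams debye_kappa
#' @param bjerrum_length Bjerrum length in nm (0.7 nm: water, 298 K).
#' @return An object of class `screened_potential` with fields
#'   `bjerrum_length` and `kappa`.
#' @export
screened_potential <- function(ionic_strength, bjerrum_length = 0.7) {
  if (!is.numeric(bjerrum_length) || bjerrum_length <= 0)
    stop("`bjerrum_length` must be > 0", call. = FALSE)
  structure(list(bjerrum_length = bjerrum_length,
                 kappa = debye_kappa(ionic_strength)),
            class = "screened_potential")
}

#' Debye-Hueckel pair energy between two unit charges
#'
#' Returns the screened Coulomb interaction in decimal-log units (already
#' divided by ln 10, so it adds directly to reduced free energies):
#' `(1/ln 10) * (lB / d) * exp(-kappa * d)`.
#'
#' @param d separation in nm (> 0); vectorized.
#' @param pot a [screened_potential()].
#' @return The pair energy (decimal-log units), strictly positive and
#'   strictly decreasing in both `d` and the ionic strength.
#' @export
dh_pair <- function(d, pot) {
  if (any(!is.finite(d)) || any(d <= 0))
    stop("`d` must be finite and > 0 (a non-positive distance signals a ",
         "geometry bug upstream)", call. = FALSE)
  (pot$bjerrum_length / d) * exp(-pot$kappa * d) / log(10)
}
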