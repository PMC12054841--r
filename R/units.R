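#' @title Unit handling at the configuration boundary
#' @description Internally everything is strict SI (m, s, Pa, mol). Presets
#'   and configuration files may state quantities in the mixed units common in
#'   plant physiology (cm, mm, MPa, mmol m^-2 s^-1, ...); they are converted
#'   once, at parse time.
#' @name units
NULL

# multiplicative factor to SI for every accepted unit string
.unit_factors <- c(
  "m" = 1, "cm" = 1e-2, "mm" = 1e-3, "um" = 1e-6, "µm" = 1e-6,
  "s" = 1, "min" = 60,
  "Pa" = 1, "MPa" = 1e6,
  "mol/m^2/s" = 1, "mmol/m^2/s" = 1e-3,
  "m^2/s" = 1,
  "mol/m^3/Pa" = 1,
  "mol/m^2/Pa/s" = 1,
  "m^2" = 1, "mm^2" = 1e-6,
  "mol" = 1, "mmol" = 1e-3
)

#' Convert a possibly unit-tagged value to SI
#'
#' Accepts either a bare numeric (assumed SI already) or a list/record of the
#' form `list(value = 0.4, unit = "mm")`.
#'
#' @param x numeric, or a list with elements `value` and `unit`.
#' @param field name used in error messages.
#' @return numeric scalar (or vector) in SI units.
#' @export
#' @examples
#' si_value(list(value = 0.4, unit = "mm"))  # 4e-4
#' si_value(-0.2e6)                          # already SI
si_value <- function(x, field = "value") {
  if (is.numeric(x)) return(as.numeric(x))
  if (is.list(x) && !is.null(x$value)) {
    if (is.null(x$unit)) return(as.numeric(x$value))
    u <- as.character(x$unit)
    if (!u %in% names(.unit_factors)) {
      stop(sprintf("unknown unit '%s' for field '%s'", u, field), call. = FALSE)
    }
    return(as.numeric(x$value) * .unit_factors[[u]])
  }
  stop(sprintf("field '%s' must be numeric or {value, unit}", field),
       call. = FALSE)
}

#' Molar volume of liquid water, in m^3 per mol
#'
#' Standard physical constant used to convert molar water fluxes to volumetric
#' strain and tracer velocities.
#' @export
VW_WATER <- 1.8e-5
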