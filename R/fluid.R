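#' Blood rheology for the network model
#'
#' Container for the two material constants the loss laws need. Blood is
#' treated as an incompressible Newtonian fluid, which is the standard
#' assumption for vessels of portal-vein calibre where shear rates are well
#' above the shear-thinning range.
#'
#' @param density Mass density in kg m^-3. Default 1060.
#' @param dynamic_viscosity Dynamic viscosity in Pa s. Default 0.0035.
#'
#' @return An object of class `fluid_properties`.
#' @examples
#' fluid_properties()
#' @export
fluid_properties <- function(density = 1060, dynamic_viscosity = 0.0035) {
  stopifnot(is.numeric(density), length(density) == 1L, is.finite(density),
            is.numeric(dynamic_viscosity), length(dynamic_viscosity) == 1L,
            is.finite(dynamic_viscosity))
  if (density <= 0) stop("`density` must be strictly positive", call. = FALSE)
  if (dynamic_viscosity <= 0) {
    stop("`dynamic_viscosity` must be strictly positive", call. = FALSE)
  }
  structure(list(density = density, dynamic_viscosity = dynamic_viscosity),
            class = "fluid_properties")
}

#' @export
print.fluid_properties <- function(x, ...) {
  cat("<fluid_properties> rho =", x$density, "kg/m^3, mu =",
      x$dynamic_viscosity, "Pa s\n")
  invisible(x)
}

#' Pressure unit conversion
#'
#' The portal pressure gradient is quoted clinically in mmHg while the solver
#' works in Pa. The conversion constant is declared once: 133.322 Pa per mmHg.
#'
#' @param x Numeric vector of pressures.
#' @return Numeric vector in the other unit.
#' @examples
#' mmhg_to_pa(25)     # 3333.05 Pa
#' pa_to_mmhg(1500)   # ~11.25 mmHg
#' @export
mmhg_to_pa <- function(x) x * 133.322

#' @rdname mmhg_to_pa
#' @export
pa_to_mmhg <- function(x) x / 133.322
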