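#' Edge loss model parameters
#'
#' Tunable constants of the per-edge momentum-loss laws. `regime_threshold`
#' is the Reynolds number above which the Blasius turbulent correlation
#' replaces the laminar 64/Re friction factor (the shunt operates in the
#' laminar-turbulent transition range, which the surrogate treats with the
#' turbulent correlation and no blending). `k_contraction` and `k_bend` are
#' the handbook minor-loss coefficients applied at the shunt entrance: a
#' sudden contraction from the host portal vein into the 8 mm stent, and the
#' curvature of the intrahepatic tract. No exit-recovery term is used: the
#' shunt jet discharges into the IVC where its kinetic energy is dissipated.
#'
#' @param regime_threshold Reynolds number separating the two friction
#'   branches. Default 2300.
#' @param k_contraction Entrance contraction coefficient. Default 0.45.
#' @param k_bend Bend coefficient. Default 0.25.
#' @return An object of class `edge_loss_model`.
#' @export
edge_loss_model <- function(regime_threshold = 2300, k_contraction = 0.45,
                            k_bend = 0.25) {
  stopifnot(is.finite(regime_threshold), is.finite(k_contraction),
            is.finite(k_bend))
  if (regime_threshold <= 0) {
    stop("`regime_threshold` must be strictly positive", call. = FALSE)
  }
  if (k_contraction < 0 || k_bend < 0) {
    stop("minor-loss coefficients must be nonnegative", call. = FALSE)
  }
  structure(list(regime_threshold = regime_threshold,
                 k_contraction = k_contraction, k_bend = k_bend),
            class = "edge_loss_model")
}

#' Circular cross-sectional area
#'
#' @param d Diameter in m.
#' @return Area in m^2 (`pi * d^2 / 4`).
#' @examples
#' cross_section_area(0.008)
#' @export
cross_section_area <- function(d) {
  if (any(!is.finite(d)) || any(d <= 0)) {
    stop("`d` must be strictly positive", call. = FALSE)
  }
  pi * d^2 / 4
}

#' Reynolds number of pipe flow
#'
#' `rho * V * d / mu` with the mean velocity `V = q / (pi d^2 / 4)`.
#' Returns 0 for zero flow.
#'
#' @param q Volumetric flow in m^3 s^-1 (sign ignored).
#' @param d Diameter in m.
#' @param fluid A [fluid_properties()].
#' @return Dimensionless Reynolds number (nonnegative).
#' @examples
#' reynolds(1.2 * cross_section_area(0.008), 0.008, fluid_properties())
#' @export
reynolds <- function(q, d, fluid = fluid_properties()) {
  v <- abs(q) / cross_section_area(d)
  fluid$density * v * d / fluid$dynamic_viscosity
}

#' Darcy friction factor
#'
#' `64/Re` on the laminar branch (`0 < Re <= regime_threshold`), Blasius
#' `0.316 * Re^-0.25` above it. `Re = 0` returns `Inf` by the laminar
#' formula; [frictional_drop()] handles that limit by computing the linear
#' Poiseuille drop directly, which vanishes at zero flow.
#'
#' @param re Reynolds number (>= 0).
#' @param model An [edge_loss_model()].
#' @return Dimensionless Darcy friction factor.
#' @examples
#' friction_factor(64)    # 1
#' friction_factor(2907)  # Blasius branch
#' @export
friction_factor <- function(re, model = edge_loss_model()) {
  if (any(!is.finite(re)) || any(re < 0)) {
    stop("`re` must be nonnegative", call. = FALSE)
  }
  ifelse(re <= model$regime_threshold, 64 / re, 0.316 * re^(-0.25))
}

#' Frictional pressure drop along a segment
#'
#' Darcy-Weisbach drop `f * (L/d) * rho V^2 / 2`, with the friction factor
#' from [friction_factor()]. On the laminar branch this reduces exactly to
#' the Poiseuille closed form `128 mu L q / (pi d^4)`. The sign follows the
#' flow direction; zero flow gives zero drop.
#'
#' @param q Signed volumetric flow in m^3 s^-1.
#' @param d Diameter in m.
#' @param length Segment length in m.
#' @param fluid A [fluid_properties()].
#' @param model An [edge_loss_model()].
#' @return Pressure drop in Pa (same sign as `q`).
#' @examples
#' frictional_drop(1e-6, 0.01, 0.1)  # Poiseuille: ~1.426 Pa
#' @export
frictional_drop <- function(q, d, length, fluid = fluid_properties(),
                            model = edge_loss_model()) {
  if (!is.finite(d) || !is.finite(length) || d <= 0 || length <= 0) {
    stop("`d` and `length` must be strictly positive", call. = FALSE)
  }
  aq <- abs(q)
  re <- reynolds(aq, d, fluid)
  if (re == 0) return(0)
  mag <- if (re <= model$regime_threshold) {
    128 * fluid$dynamic_viscosity * length * aq / (pi * d^4)
  } else {
    v <- aq / cross_section_area(d)
    friction_factor(re, model) * (length / d) * fluid$density * v^2 / 2
  }
  sign(q) * mag
}

#' Minor (local) pressure loss
#'
#' `K * rho V^2 / 2` for a dimensionless loss coefficient `K`, signed by the
#' flow direction.
#'
#' @param q Signed volumetric flow in m^3 s^-1.
#' @param d Diameter in m at which the reference velocity is taken.
#' @param k Loss coefficient(s); summed if a vector.
#' @param fluid A [fluid_properties()].
#' @return Pressure loss in Pa (same sign as `q`).
#' @export
minor_loss <- function(q, d, k, fluid = fluid_properties()) {
  if (any(!is.finite(k)) || any(k < 0)) {
    stop("`k` must be nonnegative", call. = FALSE)
  }
  v <- abs(q) / cross_section_area(d)
  sign(q) * sum(k) * fluid$density * v^2 / 2
}

#' Static pressure change across an area transition
#'
#' Bernoulli bookkeeping at constant flow: the static pressure decreases by
#' `rho/2 * (V_down^2 - V_up^2)` when the flow accelerates into a narrower
#' vessel (and increases on an expansion). Velocities are the given flow
#' through the upstream and downstream cross-sections. Signed odd in `q`.
#'
#' @param q Signed volumetric flow in m^3 s^-1.
#' @param d_upstream,d_downstream Diameters in m.
#' @param fluid A [fluid_properties()].
#' @return Static pressure decrease in Pa (positive for a contraction at
#'   `q > 0`).
#' @examples
#' static_pressure_correction(6.087e-5, 0.01645, 0.008)
#' @export
static_pressure_correction <- function(q, d_upstream, d_downstream,
                                       fluid = fluid_properties()) {
  v_up <- abs(q) / cross_section_area(d_upstream)
  v_dn <- abs(q) / cross_section_area(d_downstream)
  sign(q) * fluid$density / 2 * (v_dn^2 - v_up^2)
}

#' Segment-mean wall shear stress
#'
#' `(f/8) * rho V^2` with the Darcy friction factor; on the laminar branch
#' this reduces to the Poiseuille wall shear `8 mu V / d`. A 0D surrogate
#' for the area-mean of the 3D wall shear stress field over a segment.
#'
#' @param q Volumetric flow in m^3 s^-1 (sign ignored).
#' @param d Diameter in m.
#' @param fluid A [fluid_properties()].
#' @param model An [edge_loss_model()].
#' @return Wall shear stress in Pa (nonnegative).
#' @examples
#' wall_shear(0.37 * cross_section_area(0.01645), 0.01645)  # ~0.63 Pa
#' @export
wall_shear <- function(q, d, fluid = fluid_properties(),
                       model = edge_loss_model()) {
  aq <- abs(q)
  re <- reynolds(aq, d, fluid)
  if (re == 0) return(0)
  v <- aq / cross_section_area(d)
  if (re <= model$regime_threshold) {
    8 * fluid$dynamic_viscosity * v / d
  } else {
    friction_factor(re, model) / 8 * fluid$density * v^2
  }
}
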