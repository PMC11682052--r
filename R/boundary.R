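#' Preoperative MPV volumetric flow from velocity and diameter
#'
#' The velocity-area product: the area-averaged ultrasound velocity in the
#' main portal vein times its cross-sectional area.
#'
#' @param v_mpv_pre Preoperative area-averaged MPV velocity in m s^-1.
#' @param d_mpv MPV diameter in m.
#' @return Volumetric flow in m^3 s^-1.
#' @examples
#' preop_mpv_flow(0.18492, 0.01645)  # ~3.93e-5 m^3/s
#' @export
preop_mpv_flow <- function(v_mpv_pre, d_mpv) {
  if (!is.finite(v_mpv_pre) || v_mpv_pre <= 0) {
    stop("`v_mpv_pre` must be strictly positive", call. = FALSE)
  }
  v_mpv_pre * cross_section_area(d_mpv)
}

#' Postoperative MPV volumetric flow
#'
#' After shunt placement the portal flow roughly doubles (the low-resistance
#' shunt recruits splanchnic flow); the postoperative MPV flow is estimated
#' as twice the preoperative one.
#'
#' @param q_pre Preoperative MPV flow in m^3 s^-1.
#' @return Postoperative flow in m^3 s^-1.
#' @examples
#' postop_mpv_flow(3.93e-5)  # 7.86e-5
#' @export
postop_mpv_flow <- function(q_pre) {
  if (!is.finite(q_pre) || q_pre <= 0) {
    stop("`q_pre` must be strictly positive", call. = FALSE)
  }
  2 * q_pre
}

#' Murray's-law flow partition between two branches
#'
#' Apportions a total flow between two vessels in proportion to the cubes of
#' their nominal diameters. The fractions are scale-free, so any consistent
#' diameter unit may be used. The two outputs sum to `q_total` exactly:
#' `q_b` is computed as the complement `q_total - q_a`.
#'
#' @param q_total Total volumetric flow (any unit; >= 0).
#' @param d_a,d_b Nominal diameters of the two branches (consistent units).
#' @return Named numeric vector `c(q_a, q_b)`.
#' @examples
#' murray_split(7.86e-5, 8.98, 10.38)  # Q_SV, Q_SMV of the first patient
#' @export
murray_split <- function(q_total, d_a, d_b) {
  if (!is.finite(q_total) || q_total < 0) {
    stop("`q_total` must be nonnegative", call. = FALSE)
  }
  if (!is.finite(d_a) || !is.finite(d_b) || d_a <= 0 || d_b <= 0) {
    stop("diameters must be strictly positive", call. = FALSE)
  }
  f_a <- d_a^3 / (d_a^3 + d_b^3)
  q_a <- q_total * f_a
  # complement with a compensation step so the pair sums to q_total exactly
  q_b <- q_total - q_a
  q_b <- q_b - ((q_a + q_b) - q_total)
  c(q_a = q_a, q_b = q_b)
}

#' Outlet resistance closure from a portal pressure estimate
#'
#' Closes the left and right portal-vein outlet resistances so that, under
#' the preoperative MPV flow split by Murray's law, each branch sustains the
#' preoperative portal pressure against the zero-pressure IVC:
#' `R_i = P_pv / (Q_pre * d_i^3 / (d_lpv^3 + d_rpv^3))`.
#'
#' @param p_pv Preoperative portal pressure in mmHg.
#' @param q_mpv_pre Preoperative MPV volumetric flow in m^3 s^-1.
#' @param d_lpv,d_rpv Branch nominal diameters (consistent units).
#' @return Named vector `c(r_lpv, r_rpv)` in Pa s m^-3.
#' @examples
#' outlet_resistances(25, 3.93e-5, 9.60, 8.96)
#' @export
outlet_resistances <- function(p_pv, q_mpv_pre, d_lpv, d_rpv) {
  if (!is.finite(p_pv) || p_pv <= 0 || !is.finite(q_mpv_pre) ||
      q_mpv_pre <= 0) {
    stop("`p_pv` and `q_mpv_pre` must be strictly positive", call. = FALSE)
  }
  q <- murray_split(q_mpv_pre, d_lpv, d_rpv)
  p_pa <- mmhg_to_pa(p_pv)
  c(r_lpv = p_pa / q[["q_a"]], r_rpv = p_pa / q[["q_b"]])
}

#' Assemble the boundary set for one patient and simplification type
#'
#' Composes the flow doubling, the Murray's-law inflow split, and the
#' resistance closure into the full boundary condition set. The set is
#' identical for all nine cases of a patient, except that Type C replaces
#' the separate SV/SMV inflows with a single combined inflow at the MPV
#' inlet.
#'
#' @param patient A `patient_record`.
#' @param simplification A `simplification_type` (or a label `"A"`, `"B"`,
#'   `"C"`).
#' @return An object of class `boundary_set` with fields `q_sv`, `q_smv`
#'   (NULL for Type C), `q_total`, `r_lpv`, `r_rpv`, `p_ivc` (0 Pa).
#' @examples
#' assemble_boundary_set(patient_fixtures()$patient1, "A")
#' @export
assemble_boundary_set <- function(patient, simplification = "A") {
  stopifnot(inherits(patient, "patient_record"))
  if (is.character(simplification)) {
    simplification <- simplification_type(simplification)
  }
  stopifnot(inherits(simplification, "simplification_type"))
  q_pre <- patient_preop_flow(patient)
  q_total <- postop_mpv_flow(q_pre)
  r <- outlet_resistances(patient$p_pv, q_pre, patient$d_lpv, patient$d_rpv)
  if (simplification$label == "C") {
    q_sv <- NULL
    q_smv <- NULL
  } else {
    qs <- murray_split(q_total, patient$d_sv, patient$d_smv)
    q_sv <- qs[["q_a"]]
    q_smv <- qs[["q_b"]]
  }
  structure(list(q_sv = q_sv, q_smv = q_smv, q_total = q_total,
                 r_lpv = r[["r_lpv"]], r_rpv = r[["r_rpv"]],
                 p_ivc = 0, patient_id = patient$id,
                 simplification = simplification$label),
            class = "boundary_set")
}

#' @export
print.boundary_set <- function(x, ...) {
  cat("<boundary_set>", x$patient_id, "/ Type", x$simplification, "\n")
  if (!is.null(x$q_sv)) {
    cat(sprintf("  Q_SV %.3e  Q_SMV %.3e m^3/s\n", x$q_sv, x$q_smv))
  }
  cat(sprintf("  Q_total %.3e m^3/s\n", x$q_total))
  cat(sprintf("  R_LPV %.3e  R_RPV %.3e Pa s/m^3, P_IVC = %g Pa\n",
              x$r_lpv, x$r_rpv, x$p_ivc))
  invisible(x)
}

#' Serialize a boundary set to JSON
#'
#' Writes the boundary set with explicit SI unit tags; readable back with
#' [jsonlite::fromJSON()].
#'
#' @param boundary A `boundary_set`.
#' @param path Optional file path; if NULL, the JSON string is returned.
#' @return The JSON string, invisibly when written to file.
#' @export
boundary_to_json <- function(boundary, path = NULL) {
  stopifnot(inherits(boundary, "boundary_set"))
  x <- list(
    patient_id = boundary$patient_id,
    simplification = boundary$simplification,
    inflows = list(
      q_sv = if (is.null(boundary$q_sv)) NULL else
        list(value = boundary$q_sv, units = "m^3 s^-1"),
      q_smv = if (is.null(boundary$q_smv)) NULL else
        list(value = boundary$q_smv, units = "m^3 s^-1"),
      q_total = list(value = boundary$q_total, units = "m^3 s^-1")),
    outlets = list(
      r_lpv = list(value = boundary$r_lpv, units = "Pa s m^-3"),
      r_rpv = list(value = boundary$r_rpv, units = "Pa s m^-3")),
    p_ivc = list(value = boundary$p_ivc, units = "Pa"))
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
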