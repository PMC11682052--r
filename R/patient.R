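#' Patient anatomy and physiology record
#'
#' A patient is summarised by the five nominal vessel diameters that survive
#' geometric simplification of the portal venous system (main, splenic,
#' superior mesenteric, left and right portal veins), the preoperative
#' ultrasound velocity in the main portal vein (MPV) or, equivalently, the
#' postoperative MPV volumetric flow, and an estimate of the preoperative
#' portal pressure. Diameters are carried in millimetres, exactly as clinical
#' reports print them; conversion to SI happens when a network is built.
#'
#' At least one of `v_mpv_pre` (m s^-1) and `q_mpv_post` (m^3 s^-1) must be
#' given: the preoperative MPV flow is `v_mpv_pre * pi * d_mpv^2 / 4` and the
#' postoperative flow is taken as twice the preoperative one, so each field
#' is derivable from the other.
#'
#' @param id Character label.
#' @param d_mpv,d_sv,d_smv,d_lpv,d_rpv Nominal diameters in mm.
#' @param v_mpv_pre Preoperative area-averaged MPV velocity in m s^-1, or NULL.
#' @param q_mpv_post Postoperative MPV volumetric flow in m^3 s^-1, or NULL.
#' @param p_pv Preoperative portal pressure estimate in mmHg.
#'
#' @return An object of class `patient_record`.
#' @seealso [patient_fixtures()], [preop_mpv_flow()], [postop_mpv_flow()]
#' @examples
#' patient_record("demo", 16.4, 9.0, 10.4, 9.6, 9.0, v_mpv_pre = 0.18)
#' @export
patient_record <- function(id, d_mpv, d_sv, d_smv, d_lpv, d_rpv,
                           v_mpv_pre = NULL, q_mpv_post = NULL, p_pv = 25) {
  d <- c(d_mpv = d_mpv, d_sv = d_sv, d_smv = d_smv,
         d_lpv = d_lpv, d_rpv = d_rpv)
  if (!all(is.finite(d)) || any(d <= 0)) {
    stop("all diameters must be finite and strictly positive", call. = FALSE)
  }
  if (is.null(v_mpv_pre) && is.null(q_mpv_post)) {
    stop("at least one of `v_mpv_pre` and `q_mpv_post` must be supplied",
         call. = FALSE)
  }
  if (!is.null(v_mpv_pre) && (!is.finite(v_mpv_pre) || v_mpv_pre <= 0)) {
    stop("`v_mpv_pre` must be strictly positive", call. = FALSE)
  }
  if (!is.null(q_mpv_post) && (!is.finite(q_mpv_post) || q_mpv_post <= 0)) {
    stop("`q_mpv_post` must be strictly positive", call. = FALSE)
  }
  if (!is.finite(p_pv) || p_pv <= 0) {
    stop("`p_pv` must be strictly positive (mmHg)", call. = FALSE)
  }
  structure(list(id = as.character(id),
                 d_mpv = d_mpv, d_sv = d_sv, d_smv = d_smv,
                 d_lpv = d_lpv, d_rpv = d_rpv,
                 v_mpv_pre = v_mpv_pre, q_mpv_post = q_mpv_post,
                 p_pv = p_pv),
            class = "patient_record")
}

#' @export
print.patient_record <- function(x, ...) {
  cat("<patient_record>", x$id, "\n")
  cat(sprintf("  D (mm): MPV %.2f  SV %.2f  SMV %.2f  LPV %.2f  RPV %.2f\n",
              x$d_mpv, x$d_sv, x$d_smv, x$d_lpv, x$d_rpv))
  if (!is.null(x$v_mpv_pre)) {
    cat(sprintf("  preop MPV velocity: %.3f m/s\n", x$v_mpv_pre))
  }
  if (!is.null(x$q_mpv_post)) {
    cat(sprintf("  postop MPV flow: %.3e m^3/s\n", x$q_mpv_post))
  }
  cat(sprintf("  portal pressure estimate: %.1f mmHg\n", x$p_pv))
  invisible(x)
}

#' Preoperative MPV volumetric flow for a patient record
#'
#' Uses `q_mpv_post / 2` when the postoperative flow is recorded, otherwise
#' the velocity-area product (see [preop_mpv_flow()]).
#'
#' @param patient A `patient_record`.
#' @return Preoperative MPV flow in m^3 s^-1.
#' @export
patient_preop_flow <- function(patient) {
  stopifnot(inherits(patient, "patient_record"))
  if (!is.null(patient$q_mpv_post)) {
    patient$q_mpv_post / 2
  } else {
    preop_mpv_flow(patient$v_mpv_pre, patient$d_mpv / 1000)
  }
}

#' The two reference patients of the comparison study
#'
#' Returns the printed anatomy and boundary data of the two portal
#' hypertensive patients on which the 18-case study design is anchored:
#' nominal diameters of the five retained vessels, the postoperative MPV
#' volumetric flow, and the population-averaged preoperative portal pressure
#' of 25 mmHg.
#'
#' @return A named list of two `patient_record` objects, `patient1` and
#'   `patient2`.
#' @examples
#' patient_fixtures()$patient1
#' @export
patient_fixtures <- function() {
  list(
    patient1 = patient_record(
      id = "patient1",
      d_mpv = 16.45, d_sv = 8.98, d_smv = 10.38, d_lpv = 9.60, d_rpv = 8.96,
      q_mpv_post = 7.86e-5, p_pv = 25),
    patient2 = patient_record(
      id = "patient2",
      d_mpv = 16.27, d_sv = 14.18, d_smv = 16.08, d_lpv = 12.92, d_rpv = 9.75,
      q_mpv_post = 8.73e-5, p_pv = 25)
  )
}
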