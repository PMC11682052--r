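#' Wall-shear-stress classification thresholds
#'
#' Thresholds (Pa) separating low, normal and high segment-mean wall shear
#' stress: low below 6 Pa on venous walls and below 10 Pa on the shunt wall;
#' high above 15 Pa on either.
#'
#' @param venous_low,shunt_low,high Thresholds in Pa.
#' @return A named list.
#' @export
wss_thresholds <- function(venous_low = 6, shunt_low = 10, high = 15) {
  stopifnot(venous_low > 0, shunt_low > 0, high > 0)
  list(venous_low = venous_low, shunt_low = shunt_low, high = high)
}

#' Classify a wall shear stress value
#'
#' Pure threshold function: `"low"` below the wall-appropriate low
#' threshold, `"high"` above the high threshold, `"normal"` between.
#'
#' @param tau Wall shear stress in Pa (vectorized).
#' @param wall `"venous"` or `"shunt"`.
#' @param thresholds A [wss_thresholds()] list.
#' @return Character vector of classes.
#' @export
classify_wss <- function(tau, wall = c("venous", "shunt"),
                         thresholds = wss_thresholds()) {
  wall <- match.arg(wall)
  low <- if (wall == "venous") thresholds$venous_low else thresholds$shunt_low
  ifelse(tau < low, "low", ifelse(tau > thresholds$high, "high", "normal"))
}

#' Clinical metrics for one solved case
#'
#' Extracts the quantities the study design compares: the portal pressure
#' gradient (MPV-midsection static pressure minus the zero IVC pressure, in
#' mmHg), the area-averaged shunt velocity, the shunt flow fraction and
#' Reynolds number, the probe-plane pressures, and the segment-mean wall
#' shear stress of every vessel segment and the shunt, with its
#' low/normal/high classification.
#'
#' @param case The `case_spec` of the solution (consistency-checked).
#' @param solution A converged [solve_network()] `network_solution`.
#' @param thresholds A [wss_thresholds()] list.
#' @return An object of class `case_result`.
#' @export
case_metrics <- function(case, solution, thresholds = wss_thresholds()) {
  stopifnot(inherits(case, "case_spec"),
            inherits(solution, "network_solution"))
  if (!isTRUE(solution$converged)) {
    stop("`solution` is not converged", call. = FALSE)
  }
  net <- solution$network
  if (!identical(net$case$patient$id, case$patient$id) ||
      !identical(net$case$shunt$position, case$shunt$position) ||
      !identical(net$case$simplification$label, case$simplification$label)) {
    stop("`case` does not match the case the solution was computed for",
         call. = FALSE)
  }
  fluid <- solution$fluid
  model <- solution$model
  e <- net$edges
  q <- solution$edge_flows
  qs <- q[["shunt"]]
  sh <- e[e$type == "shunt", ]
  area <- cross_section_area(sh$diameter)
  q_total <- solution$boundary$q_total

  seg <- e[e$type != "resistance", ]
  tau <- vapply(seq_len(nrow(seg)), function(i) {
    wall_shear(q[[seg$name[i]]], seg$diameter[i], fluid, model)
  }, numeric(1))
  names(tau) <- seg$name
  cls <- vapply(seq_along(tau), function(i) {
    wall <- if (seg$type[i] == "shunt") "shunt" else "venous"
    classify_wss(tau[i], wall, thresholds)
  }, character(1))
  names(cls) <- seg$name

  structure(list(
    patient = case$patient$id,
    position = case$shunt$position,
    simplification = case$simplification$label,
    ppg = pa_to_mmhg(pressure_at(solution, "mpv_mid")),
    shunt_velocity = abs(qs) / area,
    shunt_flow_fraction = abs(qs) / q_total,
    p_shunt_inlet = pressure_at(solution, "shunt_inlet"),
    p_shunt_outlet = pressure_at(solution, "shunt_outlet"),
    shunt_re = reynolds(qs, sh$diameter, fluid),
    segment_wss = tau,
    wss_class = cls),
    class = "case_result")
}

#' @export
print.case_result <- function(x, ...) {
  cat(sprintf("<case_result> %s / shunt at %s / Type %s\n",
              x$patient, x$position, x$simplification))
  cat(sprintf("  PPG %.2f mmHg | shunt velocity %.3f m/s (Re %.0f) | ",
              x$ppg, x$shunt_velocity, x$shunt_re))
  cat(sprintf("shunt fraction %.3f\n", x$shunt_flow_fraction))
  invisible(x)
}

#' Relative error against a reference value, in percent
#'
#' `(x - x_ref) / x_ref * 100`. The comparator used throughout the study:
#' simplified-model metrics (Types B and C) against the relatively intact
#' Type A reference, and equally applicable to published low-WSS areas.
#'
#' @param x Metric value(s).
#' @param x_ref Reference value(s); must be nonzero.
#' @return Relative error(s) in percent.
#' @examples
#' relative_error(22.85, 24.38)  # -6.28
#' @export
relative_error <- function(x, x_ref) {
  if (any(!is.finite(x_ref)) || any(x_ref == 0)) {
    stop("`x_ref` must be finite and nonzero", call. = FALSE)
  }
  (x - x_ref) / x_ref * 100
}

#' Assemble the study comparison table
#'
#' Collects the per-case metrics into one table over the complete study
#' grid (every patient with all three shunt positions and all three
#' simplification types), and computes the relative errors of the Type B
#' and Type C metrics against Type A for each patient and position, for the
#' MPV-midsection pressure (PPG) and the shunt velocity. The per-patient
#' maximum absolute relative error is flagged.
#'
#' @param results A list of [case_metrics()] `case_result` objects covering
#'   the full grid (18 for two patients).
#' @return An object of class `study_table`: a list with `rows` (data.frame,
#'   one row per case), `relative_errors` (data.frame with columns patient,
#'   position, metric, type, e_r) and `max_abs_error` (named by patient).
#' @export
study_table <- function(results) {
  stopifnot(length(results) > 0,
            all(vapply(results, inherits, logical(1), "case_result")))
  rows <- do.call(rbind, lapply(results, function(r) {
    data.frame(patient = r$patient, position = r$position,
               simplification = r$simplification,
               ppg_mmhg = r$ppg, shunt_velocity_ms = r$shunt_velocity,
               shunt_flow_fraction = r$shunt_flow_fraction,
               p_shunt_inlet_pa = r$p_shunt_inlet,
               p_shunt_outlet_pa = r$p_shunt_outlet,
               shunt_re = r$shunt_re,
               stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  patients <- unique(rows$patient)
  grid <- expand.grid(patient = patients, position = c("LPV", "MPV", "RPV"),
                      simplification = c("A", "B", "C"),
                      stringsAsFactors = FALSE)
  have <- paste(rows$patient, rows$position, rows$simplification)
  want <- paste(grid$patient, grid$position, grid$simplification)
  if (!setequal(have, want) || anyDuplicated(have)) {
    stop(sprintf(paste0("incomplete study: expected the full %d-case grid ",
                        "(every patient x 3 positions x 3 types)"),
                 nrow(grid)), call. = FALSE)
  }
  rows <- rows[order(rows$patient, rows$position, rows$simplification), ]
  rownames(rows) <- NULL

  errs <- list()
  for (p in patients) {
    for (pos in c("LPV", "MPV", "RPV")) {
      ref <- rows[rows$patient == p & rows$position == pos &
                    rows$simplification == "A", ]
      for (ty in c("B", "C")) {
        alt <- rows[rows$patient == p & rows$position == pos &
                      rows$simplification == ty, ]
        for (m in c("ppg_mmhg", "shunt_velocity_ms")) {
          errs[[length(errs) + 1L]] <- data.frame(
            patient = p, position = pos,
            metric = sub("_mmhg$|_ms$", "", m), type = ty,
            e_r = relative_error(alt[[m]], ref[[m]]),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  errs <- do.call(rbind, errs)
  max_abs <- c(tapply(abs(errs$e_r), errs$patient, max))
  structure(list(rows = rows, relative_errors = errs,
                 max_abs_error = max_abs),
            class = "study_table")
}

#' @export
print.study_table <- function(x, ...) {
  cat(sprintf("<study_table> %d cases, %d patients\n", nrow(x$rows),
              length(unique(x$rows$patient))))
  print(x$rows[, c("patient", "position", "simplification", "ppg_mmhg",
                   "shunt_velocity_ms", "shunt_flow_fraction")],
        digits = 4)
  cat("max |E_r| (%) per patient:",
      paste(sprintf("%s %.3g", names(x$max_abs_error), x$max_abs_error),
            collapse = ", "), "\n")
  invisible(x)
}

#' Run the full comparison study
#'
#' Convenience pipeline: enumerate the case grid for the given patients,
#' build each network, assemble its boundary set, solve, extract metrics,
#' and assemble the [study_table()].
#'
#' @param patients List of `patient_record`s. Defaults to the two reference
#'   patients.
#' @param lengths Segment-length table ([default_segment_lengths()]).
#' @param fluid A [fluid_properties()].
#' @param model An [edge_loss_model()].
#' @param thresholds A [wss_thresholds()] list.
#' @return A `study_table`.
#' @examples
#' \donttest{
#' run_study(patient_fixtures())
#' }
#' @export
run_study <- function(patients = patient_fixtures(),
                      lengths = default_segment_lengths(),
                      fluid = fluid_properties(),
                      model = edge_loss_model(),
                      thresholds = wss_thresholds()) {
  cases <- enumerate_cases(patients)
  results <- lapply(cases, function(cs) {
    net <- build_network(cs, lengths, model)
    bnd <- assemble_boundary_set(cs$patient, cs$simplification)
    sol <- solve_network(net, bnd, fluid, model)
    case_metrics(cs, sol, thresholds)
  })
  study_table(results)
}

#' Write the study report to CSV and JSON
#'
#' CSV: one row per case plus the relative-error table appended as a second
#' file section is avoided — the errors go to the JSON. Output is
#' deterministic: identical input produces byte-identical files.
#'
#' @param table A `study_table`.
#' @param csv_path Path for the per-case CSV (units in the column names).
#' @param json_path Path for the nested JSON
#'   (patient -> position -> type -> metrics, plus relative errors).
#' @return Invisibly, the two paths.
#' @export
write_report <- function(table, csv_path, json_path) {
  stopifnot(inherits(table, "study_table"))
  utils::write.csv(table$rows, csv_path, row.names = FALSE, quote = FALSE)
  nested <- list()
  for (i in seq_len(nrow(table$rows))) {
    r <- table$rows[i, ]
    nested[[r$patient]][[r$position]][[r$simplification]] <-
      as.list(r[, setdiff(names(r), c("patient", "position",
                                      "simplification"))])
  }
  out <- list(cases = nested, relative_errors = table$relative_errors,
              max_abs_error = as.list(table$max_abs_error))
  writeLines(jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA,
                              dataframe = "rows", pretty = TRUE),
             json_path)
  invisible(c(csv = csv_path, json = json_path))
}

#' Read a study report back from JSON
#'
#' Inverse of the JSON half of [write_report()]: reconstructs a
#' `study_table` equal (up to numeric round-trip) to the one written.
#'
#' @param json_path Path written by [write_report()].
#' @return A `study_table`.
#' @export
read_report_json <- function(json_path) {
  x <- jsonlite::fromJSON(json_path, simplifyVector = TRUE)
  rows <- list()
  for (p in names(x$cases)) {
    for (pos in names(x$cases[[p]])) {
      for (ty in names(x$cases[[p]][[pos]])) {
        m <- x$cases[[p]][[pos]][[ty]]
        rows[[length(rows) + 1L]] <- data.frame(
          patient = p, position = pos, simplification = ty,
          as.data.frame(m), stringsAsFactors = FALSE)
      }
    }
  }
  rows <- do.call(rbind, rows)
  rows <- rows[order(rows$patient, rows$position, rows$simplification), ]
  rownames(rows) <- NULL
  errs <- x$relative_errors
  structure(list(rows = rows, relative_errors = errs,
                 max_abs_error = unlist(x$max_abs_error)),
            class = "study_table")
}
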