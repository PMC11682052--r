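#' Read a study configuration file
#'
#' Reads patients, segment lengths, loss-model parameters, wall-shear
#' thresholds and an optional cohort specification from one YAML (or JSON)
#' file. Patient keys mirror the clinical parameter names: diameters in mm
#' (`d_mpv`, `d_sv`, `d_smv`, `d_lpv`, `d_rpv`), `v_mpv_pre` in m/s or
#' `q_mpv_post` in m^3/s, `p_pv` in mmHg. A template ships with the package:
#' `system.file("extdata", "study-config.yaml", package = "portalflow")`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A list with elements `patients` (list of [patient_record()]),
#'   `lengths`, `loss_model` ([edge_loss_model()]), `thresholds`
#'   ([wss_thresholds()]) and `cohort` ([cohort_spec()] or NULL).
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  patients <- lapply(names(raw$patients), function(nm) {
    p <- raw$patients[[nm]]
    patient_record(id = nm, d_mpv = p$d_mpv, d_sv = p$d_sv, d_smv = p$d_smv,
                   d_lpv = p$d_lpv, d_rpv = p$d_rpv,
                   v_mpv_pre = p$v_mpv_pre, q_mpv_post = p$q_mpv_post,
                   p_pv = if (is.null(p$p_pv)) 25 else p$p_pv)
  })
  names(patients) <- names(raw$patients)

  lengths <- default_segment_lengths()
  for (nm in names(raw$segment_lengths)) {
    lengths[[nm]] <- raw$segment_lengths[[nm]]
  }
  lm <- raw$loss_model
  loss_model <- edge_loss_model(
    regime_threshold = if (is.null(lm$regime_threshold)) 2300 else
      lm$regime_threshold,
    k_contraction = if (is.null(lm$k_contraction)) 0.45 else lm$k_contraction,
    k_bend = if (is.null(lm$k_bend)) 0.25 else lm$k_bend)
  th <- raw$wss_thresholds
  thresholds <- wss_thresholds(
    venous_low = if (is.null(th$venous_low)) 6 else th$venous_low,
    shunt_low = if (is.null(th$shunt_low)) 10 else th$shunt_low,
    high = if (is.null(th$high)) 15 else th$high)
  cohort <- NULL
  if (!is.null(raw$cohort)) {
    ranges <- default_cohort_ranges()
    for (nm in names(raw$cohort$ranges)) {
      ranges[[nm]] <- as.numeric(raw$cohort$ranges[[nm]])
    }
    cohort <- cohort_spec(n = raw$cohort$n,
                          seed = if (is.null(raw$cohort$seed)) 1L else
                            raw$cohort$seed,
                          ranges = ranges)
  }
  list(patients = patients, lengths = lengths, loss_model = loss_model,
       thresholds = thresholds, cohort = cohort)
}
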