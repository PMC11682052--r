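# Printed clinical study values used as test fixtures.

# Per-patient boundary table: diameters (mm), flows (m^3/s), outlet
# resistances (Pa s/m^3) as printed to 3 significant figures.
table1 <- list(
  patient1 = list(
    d_mpv = 16.45, d_sv = 8.98, d_smv = 10.38, d_lpv = 9.60, d_rpv = 8.96,
    q_mpv_post = 7.86e-5, q_sv = 3.09e-5, q_smv = 4.77e-5,
    r_lpv = 1.53e8, r_rpv = 1.89e8),
  patient2 = list(
    d_mpv = 16.27, d_sv = 14.18, d_smv = 16.08, d_lpv = 12.92, d_rpv = 9.75,
    q_mpv_post = 8.73e-5, q_sv = 3.55e-5, q_smv = 5.18e-5,
    r_lpv = 1.09e8, r_rpv = 2.54e8)
)

# Published low-WSS-area (ALWSS, cm^2) comparison of the simplified models
# (Types B and C) against the relatively intact Type A model, with the
# printed relative errors (%): the reference data for the relative-error
# comparator. Columns: patient, position, wall, type, alwss, alwss_a,
# er_printed.
alwss_reference <- local({
  rows <- rbind(
    c(1, "LPV", "bifurcation", "B", 22.85, 24.38, -6.28),
    c(1, "LPV", "bifurcation", "C", 24.38, 24.38, 0.00),
    c(1, "LPV", "shunt", "B", 2.72, 3.58, -24.02),
    c(1, "LPV", "shunt", "C", 3.25, 3.58, -9.22),
    c(1, "MPV", "bifurcation", "B", 26.00, 27.28, -4.69),
    c(1, "MPV", "bifurcation", "C", 26.78, 27.28, -1.83),
    c(1, "MPV", "shunt", "B", 3.86, 3.53, 9.35),
    c(1, "MPV", "shunt", "C", 2.45, 3.53, -30.59),
    c(1, "RPV", "bifurcation", "B", 22.80, 25.35, -10.06),
    c(1, "RPV", "bifurcation", "C", 25.16, 25.35, -0.74),
    c(1, "RPV", "shunt", "B", 3.36, 2.86, 17.48),
    c(1, "RPV", "shunt", "C", 2.24, 2.86, -21.68),
    c(2, "LPV", "bifurcation", "B", 24.82, 24.76, 0.24),
    c(2, "LPV", "bifurcation", "C", 25.26, 24.76, 2.02),
    c(2, "LPV", "shunt", "B", 1.92, 1.70, 12.94),
    c(2, "LPV", "shunt", "C", 1.98, 1.70, 16.47),
    c(2, "MPV", "bifurcation", "B", 26.77, 26.17, 2.29),
    c(2, "MPV", "bifurcation", "C", 25.69, 26.17, -1.83),
    c(2, "MPV", "shunt", "B", 3.08, 3.13, -1.60),
    c(2, "MPV", "shunt", "C", 2.08, 3.13, -33.55),
    c(2, "RPV", "bifurcation", "B", 25.80, 25.93, -0.50),
    c(2, "RPV", "bifurcation", "C", 26.23, 25.93, 1.16),
    c(2, "RPV", "shunt", "B", 2.02, 2.02, 0.00),
    c(2, "RPV", "shunt", "C", 1.43, 2.02, -29.21))
  df <- data.frame(patient = as.integer(rows[, 1]), position = rows[, 2],
                   wall = rows[, 3], type = rows[, 4],
                   alwss = as.numeric(rows[, 5]),
                   alwss_a = as.numeric(rows[, 6]),
                   er_printed = as.numeric(rows[, 7]),
                   stringsAsFactors = FALSE)
  df
})
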