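solved_case <- function(patient = "patient1", pos = "MPV", ty = "A") {
  p <- patient_fixtures()[[patient]]
  cs <- case_spec(p, shunt_config(pos), simplification_type(ty))
  sol <- solve_network(build_network(cs), assemble_boundary_set(p, ty))
  list(case = cs, sol = sol)
}

test_that("case metrics summarise the reference operating point", {
  x <- solved_case()
  cm <- case_metrics(x$case, x$sol)
  expect_equal(cm$ppg, 11.44, tolerance = 1e-3)
  expect_equal(cm$shunt_velocity, 1.209, tolerance = 1e-3)
  expect_equal(cm$shunt_re, 2.93e3, tolerance = 1e-2)
  expect_gt(cm$shunt_flow_fraction, 0.5)
  expect_lt(cm$shunt_flow_fraction, 0.95)
  expect_equal(cm$p_shunt_outlet, 0)
  # velocity is flow over area by definition
  expect_equal(cm$shunt_velocity,
               abs(x$sol$edge_flows[["shunt"]]) / cross_section_area(0.008))
  # the slow venous trunk is a low-shear wall, whatever the threshold set
  expect_identical(unname(cm$wss_class[["mpv_a"]]), "low")
})

test_that("case metrics refuse mismatched or unconverged input", {
  x <- solved_case()
  other <- solved_case("patient2", "LPV", "B")
  expect_error(case_metrics(other$case, x$sol), "does not match")
  x$sol$converged <- FALSE
  expect_error(case_metrics(x$case, x$sol), "not converged")
})

test_that("zero inflow yields zero stress everywhere, classified low", {
  x <- solved_case()
  bnd <- x$sol$boundary
  bnd$q_sv <- 0
  bnd$q_smv <- 0
  bnd$q_total <- 0
  sol0 <- solve_network(x$sol$network, bnd)
  cm <- case_metrics(x$case, sol0)
  expect_true(all(cm$segment_wss == 0))
  expect_true(all(cm$wss_class == "low"))
  expect_equal(cm$ppg, 0)
})

test_that("wall shear classification is a pure threshold function", {
  th <- wss_thresholds()
  expect_identical(classify_wss(5.99, "venous", th), "low")
  expect_identical(classify_wss(6.01, "venous", th), "normal")
  expect_identical(classify_wss(9.99, "shunt", th), "low")
  expect_identical(classify_wss(10.01, "shunt", th), "normal")
  expect_identical(classify_wss(15.01, "venous", th), "high")
  expect_identical(classify_wss(15.01, "shunt", th), "high")
  # perturbing a value across a threshold flips exactly that class
  tau <- c(3, 7, 12)
  before <- classify_wss(tau, "venous", th)
  after <- classify_wss(tau + c(0, 0, 3.5), "venous", th)
  expect_identical(before, c("low", "normal", "normal"))
  expect_identical(after, c("low", "normal", "high"))
})

test_that("the relative-error comparator reproduces the reference table", {
  expect_equal(relative_error(22.85, 24.38), -6.28, tolerance = 1e-3)
  expect_equal(relative_error(2.08, 3.13), -33.55, tolerance = 1e-3)
  expect_equal(relative_error(7, 7), 0)
  expect_error(relative_error(1, 0), "nonzero")
  # every published low-WSS-area cell, at the printed precision (one unit
  # in the second decimal place, since the inputs are themselves rounded)
  er <- relative_error(alwss_reference$alwss, alwss_reference$alwss_a)
  expect_true(all(abs(er - alwss_reference$er_printed) <= 0.01 + 1e-9))
})

test_that("study table assembles the full design with its error summary", {
  tb <- run_study()
  expect_s3_class(tb, "study_table")
  expect_equal(nrow(tb$rows), 18)
  expect_equal(nrow(tb$relative_errors), 2 * 3 * 2 * 2)
  expect_true(all(tb$relative_errors$type %in% c("B", "C")))
  # prescribed inflows make the downstream solution independent of the
  # simplification type, so every relative error collapses to zero
  expect_lt(max(abs(tb$relative_errors$e_r)), 1e-8)
  expect_equal(sort(names(tb$max_abs_error)), c("patient1", "patient2"))
})

test_that("an incomplete study is rejected", {
  cases <- enumerate_cases(patient_fixtures())
  results <- lapply(cases[-1], function(cs) {
    sol <- solve_network(build_network(cs),
                         assemble_boundary_set(cs$patient,
                                               cs$simplification))
    case_metrics(cs, sol)
  })
  expect_error(study_table(results), "incomplete study")
})

test_that("reports are deterministic and round-trip through JSON", {
  tb <- run_study(patient_fixtures()["patient1"])
  csv1 <- tempfile(fileext = ".csv")
  csv2 <- tempfile(fileext = ".csv")
  js1 <- tempfile(fileext = ".json")
  js2 <- tempfile(fileext = ".json")
  write_report(tb, csv1, js1)
  write_report(tb, csv2, js2)
  expect_identical(readLines(csv1), readLines(csv2))
  expect_identical(readLines(js1), readLines(js2))
  df <- utils::read.csv(csv1)
  expect_equal(nrow(df), 9)
  back <- read_report_json(js1)
  expect_equal(back$rows, tb$rows, tolerance = 1e-12)
  expect_equal(back$max_abs_error, tb$max_abs_error, tolerance = 1e-12)
  unlink(c(csv1, csv2, js1, js2))
})
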