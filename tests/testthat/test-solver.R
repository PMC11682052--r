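fixture_case <- function(patient = "patient1", pos = "MPV", ty = "A") {
  p <- patient_fixtures()[[patient]]
  cs <- case_spec(p, shunt_config(pos), simplification_type(ty))
  list(case = cs, net = build_network(cs),
       bnd = assemble_boundary_set(p, ty))
}

test_that("solver matches the independent bisection oracle", {
  for (pn in c("patient1", "patient2")) {
    p <- patient_fixtures()[[pn]]
    for (pos in c("LPV", "MPV", "RPV")) {
      fx <- fixture_case(pn, pos)
      sol <- solve_network(fx$net, fx$bnd)
      o <- oracle_solve(p, pos)
      expect_equal(abs(sol$edge_flows[["shunt"]]), o$q_shunt,
                   tolerance = 1e-8)
      expect_equal(pressure_at(sol, "mpv_mid"), o$p_mpv_mid,
                   tolerance = 1e-8)
    }
  }
})

test_that("reference case lands at the expected operating point", {
  fx <- fixture_case()
  sol <- solve_network(fx$net, fx$bnd)
  expect_true(sol$converged)
  # frozen from the independent oracle
  expect_equal(abs(sol$edge_flows[["shunt"]]), 6.0790e-5, tolerance = 1e-4)
  expect_equal(pressure_at(sol, "mpv_mid"), 1525.7, tolerance = 1e-3)
  expect_equal(pa_to_mmhg(pressure_at(sol, "mpv_mid")), 11.44,
               tolerance = 1e-3)
})

test_that("mass is conserved at every node", {
  for (pn in c("patient1", "patient2")) {
    for (pos in c("LPV", "MPV", "RPV")) {
      for (ty in c("A", "B", "C")) {
        fx <- fixture_case(pn, pos, ty)
        sol <- solve_network(fx$net, fx$bnd)
        r <- residual_report(fx$net, fx$bnd, sol)
        expect_lte(max(abs(r)), sol$tolerance)
        expect_lte(abs(max(abs(r)) - sol$residual_norm), 1e-12)
        # global balance: inflow equals outflow
        out <- sum(sol$edge_flows[c("shunt", "r_lpv", "r_rpv")])
        expect_equal(out, fx$bnd$q_total, tolerance = 1e-7)
      }
    }
  }
})

test_that("residual report flags a perturbed edge flow at its two nodes", {
  fx <- fixture_case()
  sol <- solve_network(fx$net, fx$bnd)
  delta <- 1e-6
  sol$edge_flows[["mpv_a"]] <- sol$edge_flows[["mpv_a"]] + delta
  r <- residual_report(fx$net, fx$bnd, sol)
  bad <- r[abs(r) > 1e-9]
  expect_setequal(names(bad), c("confluence", "mpv_mid"))
  expect_equal(unname(bad[["confluence"]]), -delta)
  expect_equal(unname(bad[["mpv_mid"]]), delta)
})

test_that("an all-zero flow pattern shows the imbalance at the inlets", {
  fx <- fixture_case()
  sol <- solve_network(fx$net, fx$bnd)
  sol$edge_flows[] <- 0
  r <- residual_report(fx$net, fx$bnd, sol)
  expect_equal(unname(r[["sv_inlet"]]), fx$bnd$q_sv)
  expect_equal(unname(r[["smv_inlet"]]), fx$bnd$q_smv)
})

test_that("probe pressures honour the boundary conditions", {
  fx <- fixture_case("patient2", "RPV", "B")
  sol <- solve_network(fx$net, fx$bnd)
  expect_equal(pressure_at(sol, "sink"), 0)
  expect_equal(pressure_at(sol, "shunt_outlet"), 0)
  # outlet pressures equal R * Q
  expect_equal(pressure_at(sol, "lpv_outlet"),
               fx$bnd$r_lpv * sol$edge_flows[["r_lpv"]])
  expect_error(pressure_at(sol, "nowhere"), "unknown probe")
})

test_that("pressure drops along the shunt match the clinical picture", {
  # ~10 mmHg lost between the MPV midsection and the shunt inlet plane,
  # ~2 mmHg along the shunt itself
  fx <- fixture_case()
  sol <- solve_network(fx$net, fx$bnd)
  d_entry <- pa_to_mmhg(pressure_at(sol, "mpv_mid") -
                          pressure_at(sol, "shunt_inlet"))
  d_shunt <- pa_to_mmhg(pressure_at(sol, "shunt_inlet") -
                          pressure_at(sol, "shunt_outlet"))
  expect_gt(d_entry, 8)
  expect_lt(d_entry, 11)
  expect_gt(d_shunt, 1)
  expect_lt(d_shunt, 2.5)
})

test_that("solutions are deterministic and serializable", {
  fx <- fixture_case("patient1", "LPV", "A")
  s1 <- solve_network(fx$net, fx$bnd)
  s2 <- solve_network(fx$net, fx$bnd)
  expect_identical(s1$node_pressures, s2$node_pressures)
  expect_identical(s1$edge_flows, s2$edge_flows)
  tmp <- tempfile(fileext = ".json")
  solution_to_json(s1, tmp)
  x <- jsonlite::fromJSON(tmp)
  expect_equal(x$node_pressures_pa$mpv_mid,
               unname(s1$node_pressures[["mpv_mid"]]))
  expect_true(x$diagnostics$converged)
  unlink(tmp)
})

test_that("creeping flow reduces the network to linear resistances", {
  # at a tiny inflow every loss law linearizes (laminar friction only, the
  # quadratic terms vanish to second order), so the network must reproduce
  # the analytic series/parallel resistor solution: an Ohm's-law element
  # per edge and the two-parallel-resistor current divider at the
  # bifurcation
  p <- patient_fixtures()$patient1
  fx <- fixture_case()
  q_tiny <- 1e-11
  bnd <- fx$bnd
  bnd$q_total <- q_tiny
  qs <- murray_split(q_tiny, p$d_sv, p$d_smv)
  bnd$q_sv <- qs[["q_a"]]
  bnd$q_smv <- qs[["q_b"]]
  sol <- solve_network(fx$net, bnd, tolerance = 1e-18)
  mu <- fluid_properties()$dynamic_viscosity
  r_lam <- function(d, l) 128 * mu * l / (pi * d^4)
  r1 <- bnd$r_lpv + r_lam(p$d_lpv / 1000, 0.030)
  r2 <- bnd$r_rpv + r_lam(p$d_rpv / 1000, 0.030)
  r_hep <- r_lam(p$d_mpv / 1000, 0.010) + r1 * r2 / (r1 + r2)
  r_shunt <- r_lam(0.008, 0.060)
  # current divider at the tee: shunt vs hepatic path
  frac <- r_hep / (r_hep + r_shunt)
  expect_equal(abs(sol$edge_flows[["shunt"]]) / q_tiny, frac,
               tolerance = 1e-4)
  # current divider at the bifurcation
  q_h <- q_tiny - abs(sol$edge_flows[["shunt"]])
  expect_equal(sol$edge_flows[["r_lpv"]], q_h * r2 / (r1 + r2),
               tolerance = 1e-4)
  expect_equal(sol$edge_flows[["r_rpv"]], q_h * r1 / (r1 + r2),
               tolerance = 1e-4)
  # Ohm's law across each outlet
  expect_equal(pressure_at(sol, "lpv_outlet"),
               bnd$r_lpv * sol$edge_flows[["r_lpv"]], tolerance = 1e-6)
})

test_that("zero inflow returns the zero solution without iteration", {
  fx <- fixture_case()
  bnd <- fx$bnd
  bnd$q_sv <- 0
  bnd$q_smv <- 0
  bnd$q_total <- 0
  sol <- solve_network(fx$net, bnd)
  expect_true(sol$converged)
  expect_equal(sol$iterations, 0L)
  expect_true(all(sol$node_pressures == 0))
  expect_true(all(sol$edge_flows == 0))
})

test_that("mismatched boundary and network are rejected", {
  p <- patient_fixtures()$patient1
  net_a <- build_network(case_spec(p, shunt_config("MPV"),
                                   simplification_type("A")))
  bnd_c <- assemble_boundary_set(p, "C")
  expect_error(solve_network(net_a, bnd_c), "inconsistent boundary")
})

test_that("MPV pressure falls and shunt fraction rises with shunt size", {
  p <- patient_fixtures()$patient1
  res <- vapply(c(0.006, 0.008, 0.010), function(d) {
    cs <- case_spec(p, shunt_config("MPV", diameter = d),
                    simplification_type("A"))
    sol <- solve_network(build_network(cs), assemble_boundary_set(p, "A"))
    c(pressure_at(sol, "mpv_mid"),
      abs(sol$edge_flows[["shunt"]]) / sol$boundary$q_total)
  }, numeric(2))
  expect_true(all(diff(res[1, ]) < 0))
  expect_true(all(diff(res[2, ]) > 0))
})
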