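# Nonlinear hydraulic network solver.
#
# Formulation: nodal static pressures are the unknowns. Every non-resistance
# edge carries a strictly increasing odd pressure-loss law dp(q) (Darcy
# friction + minor losses + Bernoulli static correction); resistance edges
# are linear. Mass balance at every interior node closes the system, which
# is solved by damped Newton initialized from the all-laminar linear
# solution. The loss law has a jump at the laminar/turbulent threshold; its
# generalized inverse (flat over the jump) keeps the nodal flows continuous
# in the pressures, so Newton remains well behaved near the transition.


# plain-list views of the edge table rows: much faster than data.frame row
# indexing in the solver's inner loops
edge_rows <- function(e) {
  lapply(seq_len(nrow(e)), function(i) {
    list(name = e$name[i], from = e$from[i], to = e$to[i], type = e$type[i],
         diameter = e$diameter[i], length = e$length[i],
         d_upstream = e$d_upstream[i], resistance = e$resistance[i],
         loss_k = e$loss_k[i])
  })
}

# total pressure drop along a pipe/shunt edge at signed flow q
edge_drop <- function(e, q, fluid, model) {
  if (e$type == "resistance") return(e$resistance * q)
  dp <- frictional_drop(q, e$diameter, e$length, fluid, model) +
    minor_loss(q, e$diameter, e$loss_k[[1]], fluid)
  if (!is.na(e$d_upstream)) {
    dp <- dp + static_pressure_correction(q, e$d_upstream, e$diameter, fluid)
  }
  dp
}

# d(edge_drop)/dq at signed flow q (one-sided, by attained branch)
edge_drop_deriv <- function(e, q, fluid, model) {
  if (e$type == "resistance") return(e$resistance)
  aq <- abs(q)
  d <- e$diameter
  a <- cross_section_area(d)
  lam_slope <- 128 * fluid$dynamic_viscosity * e$length / (pi * d^4)
  re <- reynolds(aq, d, fluid)
  fr <- if (re == 0 || re <= model$regime_threshold) {
    lam_slope
  } else {
    v <- aq / a
    1.75 * friction_factor(re, model) * (e$length / d) *
      fluid$density * v^2 / 2 / aq
  }
  quad <- sum(e$loss_k[[1]]) * fluid$density / a^2
  if (!is.na(e$d_upstream)) {
    a_up <- cross_section_area(e$d_upstream)
    quad <- quad + fluid$density * (1 / a^2 - 1 / a_up^2)
  }
  fr + quad * aq
}

# generalized inverse of the loss law: signed flow carrying drop dp
edge_flow_from_drop <- function(e, dp, fluid, model) {
  if (e$type == "resistance") return(dp / e$resistance)
  if (dp == 0) return(0)
  s <- sign(dp)
  target <- abs(dp)
  # bracket [0, hi]
  hi <- target / edge_drop_deriv(e, 0, fluid, model)  # laminar guess
  if (!is.finite(hi) || hi <= 0) hi <- 1e-6
  it <- 0
  while (edge_drop(e, hi, fluid, model) < target && it < 200) {
    hi <- hi * 2
    it <- it + 1
  }
  lo <- 0
  for (i in seq_len(100)) {
    mid <- (lo + hi) / 2
    if (mid == lo || mid == hi) break
    if (edge_drop(e, mid, fluid, model) < target) lo <- mid else hi <- mid
  }
  s * (lo + hi) / 2
}

# map boundary inflows onto the network's inflow nodes
inflow_map <- function(network, boundary) {
  inn <- network$inflow_nodes
  if (setequal(inn, c("sv_inlet", "smv_inlet"))) {
    if (is.null(boundary$q_sv) || is.null(boundary$q_smv)) {
      stop("inconsistent boundary: network expects separate SV/SMV inflows",
           call. = FALSE)
    }
    c(sv_inlet = boundary$q_sv, smv_inlet = boundary$q_smv)
  } else if (identical(inn, "confluence")) {
    c(confluence = boundary$q_total)
  } else {
    stop("inconsistent boundary: unrecognised inflow node set", call. = FALSE)
  }
}

#' Solve the flow network for nodal pressures and edge flows
#'
#' Computes the steady state of the reduced-order network: static pressures
#' at every node and signed flows on every edge, such that mass is conserved
#' at each interior node, each edge's pressure difference equals its loss
#' law at its flow, the outlet edges satisfy `P = R * Q`, and the sink (IVC)
#' pressure is zero. Inflow edges carry exactly their prescribed flow.
#'
#' A damped Newton iteration on the interior nodal pressures is used,
#' initialized from the all-laminar linear solution. The loss laws are
#' strictly monotone in flow, so the tree-plus-shunt topologies built by
#' [build_network()] have a unique solution. Zero total inflow returns the
#' identically-zero solution without iteration.
#'
#' @param network A [build_network()] `flow_network`.
#' @param boundary An [assemble_boundary_set()] `boundary_set` whose inflow
#'   structure matches the network (separate SV/SMV inflows, or one combined
#'   inflow for Type C).
#' @param fluid A [fluid_properties()].
#' @param model An [edge_loss_model()].
#' @param tolerance Convergence criterion: maximum absolute nodal mass
#'   imbalance in m^3 s^-1. Default 1e-12 (about 1e-8 of the total inflow).
#' @param max_iter Maximum Newton iterations. Default 200.
#' @return An object of class `network_solution` with `node_pressures` (Pa,
#'   including the shunt inlet/outlet probe planes), `edge_flows`
#'   (m^3 s^-1, signed by edge orientation), `residual_norm`, `iterations`
#'   and `converged`.
#' @examples
#' p <- patient_fixtures()$patient1
#' cs <- case_spec(p, shunt_config("MPV"), simplification_type("A"))
#' sol <- solve_network(build_network(cs), assemble_boundary_set(p, "A"))
#' pa_to_mmhg(pressure_at(sol, "mpv_mid"))
#' @export
solve_network <- function(network, boundary,
                          fluid = fluid_properties(),
                          model = edge_loss_model(),
                          tolerance = 1e-12, max_iter = 200) {
  stopifnot(inherits(network, "flow_network"),
            inherits(boundary, "boundary_set"))
  validate_flow_network(network)
  inflows <- inflow_map(network, boundary)
  e <- network$edges
  ne <- nrow(e)
  er <- edge_rows(e)
  # inflow edges: the single edge incident to each inflow node
  prescribed <- setNames(rep(NA_real_, ne), e$name)
  for (nd in names(inflows)) {
    idx <- which(e$from == nd | e$to == nd)
    # orientation: flow enters the network, so edge must leave the inflow
    # node (for a Type C network the inflow node has only outgoing edges)
    idx <- idx[e$from[idx] == nd | e$to[idx] == nd][1]
    prescribed[idx] <- if (e$from[idx] == nd) inflows[[nd]] else -inflows[[nd]]
  }
  # interior unknowns: not sink, not inflow nodes
  interior <- setdiff(network$nodes, c(network$sink, network$inflow_nodes))
  n <- length(interior)

  total_in <- sum(abs(inflows))
  if (total_in == 0) {
    return(finish_solution(network, boundary, fluid, model,
                           p_int = setNames(rep(0, n), interior),
                           prescribed = prescribed,
                           residual_norm = 0, iterations = 0L,
                           converged = TRUE, tolerance = tolerance))
  }

  # edge flows and residual at interior pressures p (sink & inflow handled)
  edge_flows_at <- function(p) {
    q <- numeric(ne)
    for (i in seq_len(ne)) {
      if (!is.na(prescribed[i])) {
        q[i] <- prescribed[i]
        next
      }
      pf <- if (e$from[i] == network$sink) 0 else p[[e$from[i]]]
      pt <- if (e$to[i] == network$sink) 0 else p[[e$to[i]]]
      q[i] <- edge_flow_from_drop(er[[i]], pf - pt, fluid, model)
    }
    q
  }
  residual_at <- function(q) {
    r <- setNames(rep(0, n), interior)
    for (i in seq_len(ne)) {
      if (e$from[i] %in% interior) {
        r[[e$from[i]]] <- r[[e$from[i]]] - q[i]
      }
      if (e$to[i] %in% interior) {
        r[[e$to[i]]] <- r[[e$to[i]]] + q[i]
      }
    }
    r
  }

  # all-laminar linear initialization
  A <- matrix(0, n, n, dimnames = list(interior, interior))
  b <- setNames(rep(0, n), interior)
  for (i in seq_len(ne)) {
    if (!is.na(prescribed[i])) {
      if (e$to[i] %in% interior) {
        b[[e$to[i]]] <- b[[e$to[i]]] + prescribed[i]
      }
      if (e$from[i] %in% interior) {
        b[[e$from[i]]] <- b[[e$from[i]]] - prescribed[i]
      }
      next
    }
    g <- if (e$type[i] == "resistance") {
      1 / e$resistance[i]
    } else {
      pi * e$diameter[i]^4 /
        (128 * fluid$dynamic_viscosity * e$length[i])
    }
    u <- e$from[i]
    v <- e$to[i]
    if (u %in% interior) A[u, u] <- A[u, u] + g
    if (v %in% interior) A[v, v] <- A[v, v] + g
    if (u %in% interior && v %in% interior) {
      A[u, v] <- A[u, v] - g
      A[v, u] <- A[v, u] - g
    }
  }
  p <- setNames(drop(solve(A, b)), interior)

  q <- edge_flows_at(p)
  r <- residual_at(q)
  rnorm <- max(abs(r))
  iter <- 0L
  while (rnorm > tolerance && iter < max_iter) {
    # Jacobian of residual wrt interior pressures
    J <- matrix(0, n, n, dimnames = list(interior, interior))
    for (i in seq_len(ne)) {
      if (!is.na(prescribed[i])) next
      dd <- edge_drop_deriv(er[[i]], q[i], fluid, model)
      h <- 1 / max(dd, .Machine$double.eps)
      u <- e$from[i]
      v <- e$to[i]
      if (u %in% interior) J[u, u] <- J[u, u] - h
      if (v %in% interior) J[v, v] <- J[v, v] - h
      if (u %in% interior && v %in% interior) {
        J[u, v] <- J[u, v] + h
        J[v, u] <- J[v, u] + h
      }
    }
    step <- tryCatch(drop(solve(J, -r)), error = function(err) NULL)
    if (is.null(step)) break
    # damped update: halve until the residual norm decreases; if no damped
    # step helps, expand instead — the loss law jumps at the laminar/
    # turbulent threshold, and a Newton step sized on the attained branch's
    # slope can be too short to carry an edge across the jump
    alphas <- c(2^-(0:40), 2^(1:24))
    improved <- FALSE
    for (alpha in alphas) {
      p_try <- p + alpha * step
      q_try <- edge_flows_at(p_try)
      r_try <- residual_at(q_try)
      if (max(abs(r_try)) < rnorm) {
        p <- p_try
        q <- q_try
        r <- r_try
        rnorm <- max(abs(r))
        improved <- TRUE
        break
      }
    }
    if (!improved) break
    iter <- iter + 1L
  }

  if (rnorm > tolerance) {
    # Newton can stall when an edge's working point must cross the
    # laminar/turbulent jump of the friction law; fall back to nested
    # bisection on the shunt flow, which parameterizes by flows (mass
    # conserved by construction) and tolerates the discontinuity
    sol <- tryCatch(
      solve_tree_shunt(network, boundary, fluid, model, tolerance,
                       newton_iterations = iter),
      error = function(err) NULL)
    if (!is.null(sol)) return(sol)
    stop(sprintf(paste0("network solver did not converge: residual %.3e ",
                        "m^3/s after %d iterations (tolerance %.1e)"),
                 rnorm, iter, tolerance), call. = FALSE)
  }
  finish_solution(network, boundary, fluid, model, p_int = p,
                  prescribed = prescribed, residual_norm = rnorm,
                  iterations = iter, converged = TRUE, tolerance = tolerance)
}

# Nested-bisection fallback for the tree-plus-shunt topologies produced by
# build_network(). Outer bisection on the shunt flow; given the shunt flow,
# every remaining flow follows from mass conservation and one inner
# monotone scalar solve (the bifurcation split, or the leak past the tee on
# a branch host). The outer residual is the pressure mismatch at the
# bifurcation, strictly increasing in the shunt flow.
solve_tree_shunt <- function(network, boundary, fluid, model, tolerance,
                             newton_iterations = 0L) {
  e <- network$edges
  er <- edge_rows(e)
  en <- function(nm) er[[which(e$name == nm)]]
  drop_of <- function(nm, q) edge_drop(en(nm), q, fluid, model)
  pos <- network$case$shunt$position
  inflows <- inflow_map(network, boundary)
  q_total <- sum(inflows)
  r_l <- network$outlet_resistances[["lpv"]]
  r_r <- network$outlet_resistances[["rpv"]]

  bisect <- function(f, lo, hi, n = 200) {
    flo <- f(lo)
    if (flo > 0) return(lo)
    if (f(hi) < 0) return(hi)
    for (i in seq_len(n)) {
      mid <- (lo + hi) / 2
      if (mid == lo || mid == hi) break
      if (f(mid) < 0) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }

  if (pos == "MPV") {
    split_l <- function(q_h) {
      bisect(function(ql) {
        (drop_of("lpv", ql) + r_l * ql) -
          (drop_of("rpv", q_h - ql) + r_r * (q_h - ql))
      }, 0, q_h)
    }
    resid <- function(qs) {
      q_h <- q_total - qs
      ql <- split_l(q_h)
      p_bif <- drop_of("rpv", q_h - ql) + r_r * (q_h - ql)
      drop_of("shunt", qs) - (p_bif + drop_of("mpv_c", q_h))
    }
    qs <- bisect(resid, 0, q_total)
    q_h <- q_total - qs
    ql <- split_l(q_h)
    qr <- q_h - ql
    p_bif <- drop_of("rpv", qr) + r_r * qr
    p_tee <- p_bif + drop_of("mpv_c", q_h)
    p_mid <- p_tee + drop_of("mpv_b", q_total)
    flows <- c(mpv_b = q_total, mpv_c = q_h, lpv = ql, rpv = qr,
               r_lpv = ql, r_rpv = qr, shunt = qs)
    pall <- c(shunt_tee = p_tee, bifurcation = p_bif, mpv_mid = p_mid,
              lpv_outlet = r_l * ql, rpv_outlet = r_r * qr)
  } else {
    # shunt on a branch: `host` edges carry the tee
    host <- tolower(pos)              # "lpv" or "rpv"
    other <- if (host == "lpv") "rpv" else "lpv"
    r_host <- if (host == "lpv") r_l else r_r
    r_other <- if (host == "lpv") r_r else r_l
    leak_of <- function(p_tee) {
      bisect(function(qk) {
        (drop_of(paste0(host, "_b"), qk) + r_host * qk) - p_tee
      }, 0, max(q_total, 1e-12))
    }
    resid <- function(qs) {
      p_tee <- drop_of("shunt", qs)
      qk <- leak_of(p_tee)
      q_host <- qs + qk
      q_other <- q_total - q_host
      (p_tee + drop_of(paste0(host, "_a"), q_host)) -
        (drop_of(other, q_other) + r_other * q_other)
    }
    qs <- bisect(resid, 0, q_total)
    p_tee <- drop_of("shunt", qs)
    qk <- leak_of(p_tee)
    q_host <- qs + qk
    q_other <- q_total - q_host
    p_bif <- drop_of(other, q_other) + r_other * q_other
    p_mid <- p_bif + drop_of("mpv_b", q_total)
    flows <- c(mpv_b = q_total, shunt = qs, r_lpv = NA, r_rpv = NA)
    flows[[paste0(host, "_a")]] <- q_host
    flows[[paste0(host, "_b")]] <- qk
    flows[[other]] <- q_other
    flows[[paste0("r_", host)]] <- qk
    flows[[paste0("r_", other)]] <- q_other
    pall <- c(shunt_tee = p_tee, bifurcation = p_bif, mpv_mid = p_mid)
    pall[[paste0(host, "_outlet")]] <- r_host * qk
    pall[[paste0(other, "_outlet")]] <- r_other * q_other
  }
  flows[["mpv_a"]] <- q_total
  pall[["confluence"]] <- pall[["mpv_mid"]] + drop_of("mpv_a", q_total)
  if (length(inflows) == 2L) {
    flows[["sv"]] <- inflows[["sv_inlet"]]
    flows[["smv"]] <- inflows[["smv_inlet"]]
  }
  # Type C has no sv/smv edges and the confluence is the inflow node
  keep <- intersect(names(flows), e$name)
  q <- setNames(flows[keep], keep)[e$name]
  p_int <- pall[setdiff(names(pall),
                        c(network$sink, network$inflow_nodes))]

  prescribed <- setNames(rep(NA_real_, nrow(e)), e$name)
  for (nd in names(inflows)) {
    i <- which(e$from == nd)[1]
    prescribed[i] <- inflows[[nd]]
  }
  sol <- finish_solution(network, boundary, fluid, model,
                         p_int = p_int, prescribed = prescribed,
                         residual_norm = NA_real_,
                         iterations = newton_iterations,
                         converged = TRUE, tolerance = tolerance,
                         q = q)
  r <- residual_report(network, boundary, sol)
  sol$residual_norm <- max(abs(r))
  if (sol$residual_norm > tolerance) {
    stop("bisection fallback did not reach the mass tolerance",
         call. = FALSE)
  }
  sol
}

# assemble the full solution object: inflow-node and probe pressures,
# named edge flows, diagnostics; `q` may be supplied precomputed (flow-
# parameterized fallback path), otherwise flows are inverted from pressures
finish_solution <- function(network, boundary, fluid, model, p_int,
                            prescribed, residual_norm, iterations,
                            converged, tolerance, q = NULL) {
  e <- network$edges
  ne <- nrow(e)
  er <- edge_rows(e)
  pall <- c(p_int, setNames(0, network$sink))
  if (is.null(q)) {
    q <- setNames(numeric(ne), e$name)
    for (i in seq_len(ne)) {
      if (!is.na(prescribed[i])) {
        q[i] <- prescribed[i]
      } else {
        q[i] <- edge_flow_from_drop(
          er[[i]], pall[[e$from[i]]] - pall[[e$to[i]]], fluid, model)
      }
    }
  }
  # inflow node pressures follow from their single edge's loss law
  for (nd in network$inflow_nodes) {
    i <- which(e$from == nd)[1]
    pall[nd] <- pall[[e$to[i]]] + edge_drop(er[[i]], q[i], fluid, model)
  }
  # shunt probe planes: inlet sits `inlet_offset` into the shunt, past the
  # entrance minor losses and the acceleration into the stent; the outlet
  # discharges directly into the sink
  si <- which(e$type == "shunt")
  qs <- q[si]
  se <- e[si, ]
  cs <- network$case$shunt
  entry <- minor_loss(qs, se$diameter, se$loss_k[[1]], fluid) +
    static_pressure_correction(qs, se$d_upstream, se$diameter, fluid)
  fr_in <- if (cs$inlet_offset > 0) {
    frictional_drop(qs, se$diameter, cs$inlet_offset, fluid, model)
  } else 0
  pall["shunt_inlet"] <- pall[[se$from]] - entry - fr_in
  pall["shunt_outlet"] <- pall[[network$sink]]

  structure(list(node_pressures = pall, edge_flows = q,
                 residual_norm = residual_norm, iterations = iterations,
                 converged = converged, tolerance = tolerance,
                 network = network, boundary = boundary,
                 fluid = fluid, model = model),
            class = "network_solution")
}

#' @export
print.network_solution <- function(x, ...) {
  cs <- x$network$case
  cat(sprintf("<network_solution> %s / shunt at %s / Type %s\n",
              cs$patient$id, cs$shunt$position, cs$simplification$label))
  cat(sprintf("  converged: %s in %d iterations, residual %.2e m^3/s\n",
              x$converged, x$iterations, x$residual_norm))
  cat(sprintf("  MPV midsection: %.1f Pa (%.2f mmHg); shunt flow %.3e m^3/s\n",
              x$node_pressures[["mpv_mid"]],
              pa_to_mmhg(x$node_pressures[["mpv_mid"]]),
              x$edge_flows[["shunt"]]))
  invisible(x)
}

#' Static pressure at a probe
#'
#' Looks up the nodal static pressure at a node or probe plane
#' (`"shunt_inlet"`, `"shunt_outlet"` included). Pressures are in Pa;
#' convert with [pa_to_mmhg()].
#'
#' @param solution A `network_solution`.
#' @param probe Node or probe label.
#' @return Pressure in Pa.
#' @export
pressure_at <- function(solution, probe) {
  stopifnot(inherits(solution, "network_solution"))
  if (!probe %in% names(solution$node_pressures)) {
    stop(sprintf("unknown probe '%s'", probe), call. = FALSE)
  }
  solution$node_pressures[[probe]]
}

#' Per-node mass imbalance of a solution
#'
#' Recomputes the mass balance at every non-sink node from the solution's
#' edge flows (and, at inflow nodes, the prescribed inflow), independently
#' of the solver's own bookkeeping. For a converged solution the maximum
#' absolute imbalance equals the solution's `residual_norm` up to the solver
#' tolerance.
#'
#' @param network The `flow_network` the solution was computed on.
#' @param boundary The `boundary_set` used.
#' @param solution A `network_solution` (its edge flows may have been
#'   perturbed for diagnostic purposes).
#' @return Named numeric vector of imbalances in m^3 s^-1.
#' @export
residual_report <- function(network, boundary, solution) {
  stopifnot(inherits(network, "flow_network"),
            inherits(solution, "network_solution"))
  e <- network$edges
  if (!setequal(names(solution$edge_flows), e$name)) {
    stop("solution edge set does not match the network", call. = FALSE)
  }
  q <- solution$edge_flows
  inflows <- inflow_map(network, boundary)
  nodes <- setdiff(network$nodes, network$sink)
  r <- setNames(rep(0, length(nodes)), nodes)
  for (i in seq_len(nrow(e))) {
    if (e$from[i] %in% nodes) r[[e$from[i]]] <- r[[e$from[i]]] - q[[e$name[i]]]
    if (e$to[i] %in% nodes) r[[e$to[i]]] <- r[[e$to[i]]] + q[[e$name[i]]]
  }
  for (nd in names(inflows)) r[[nd]] <- r[[nd]] + inflows[[nd]]
  r
}

#' Serialize a network solution to JSON
#'
#' Node pressures in Pa and mmHg, edge flows in m^3 s^-1, and convergence
#' diagnostics.
#'
#' @param solution A `network_solution`.
#' @param path Optional file path; if NULL the JSON string is returned.
#' @return The JSON string, invisibly when written to file.
#' @export
solution_to_json <- function(solution, path = NULL) {
  stopifnot(inherits(solution, "network_solution"))
  x <- list(
    node_pressures_pa = as.list(solution$node_pressures),
    node_pressures_mmhg = as.list(pa_to_mmhg(solution$node_pressures)),
    edge_flows_m3s = as.list(solution$edge_flows),
    diagnostics = list(residual_norm = solution$residual_norm,
                       iterations = solution$iterations,
                       converged = solution$converged,
                       tolerance = solution$tolerance))
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
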