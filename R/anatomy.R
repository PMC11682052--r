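#' Shunt configuration
#'
#' Geometry of the TIPS stent channel. Clinical practice places an 8 mm
#' covered stent of roughly 60 mm working length into the left, main or
#' right portal vein; the inlet probe plane sits `inlet_offset` metres
#' downstream of the shunt entrance (10 mm by default, i.e. 50 mm from the
#' outlet).
#'
#' @param position One of `"LPV"`, `"MPV"`, `"RPV"`.
#' @param diameter Shunt diameter in m. Default 0.008.
#' @param length Shunt length in m. Default 0.060.
#' @param inlet_offset Distance from the shunt entrance to the inlet probe
#'   plane, in m. Must satisfy `0 <= inlet_offset < length`. Default 0.010.
#'
#' @return An object of class `shunt_config`.
#' @examples
#' shunt_config("MPV")
#' @export
shunt_config <- function(position = c("LPV", "MPV", "RPV"),
                         diameter = 0.008, length = 0.060,
                         inlet_offset = 0.010) {
  position <- match.arg(position)
  stopifnot(is.finite(diameter), is.finite(length), is.finite(inlet_offset))
  if (diameter <= 0 || length <= 0) {
    stop("shunt `diameter` and `length` must be strictly positive",
         call. = FALSE)
  }
  if (inlet_offset < 0 || inlet_offset >= length) {
    stop("`inlet_offset` must lie in [0, length)", call. = FALSE)
  }
  structure(list(position = position, diameter = diameter, length = length,
                 inlet_offset = inlet_offset),
            class = "shunt_config")
}

#' Geometric simplification strategy
#'
#' Three strategies for truncating the portal venous model upstream of the
#' splenic/superior-mesenteric confluence: Type A keeps relatively intact
#' (long) SV and SMV tributaries, Type B keeps short stubs, and Type C drops
#' them entirely, applying the combined inflow at the MPV inlet.
#'
#' Default tributary lengths (Type A: SV 80 mm, SMV 100 mm; Type B: SV 30 mm,
#' SMV 40 mm) are plausible adult dimensions; because the tributary inflows
#' are prescribed, everything downstream of the confluence is insensitive to
#' them.
#'
#' @param label One of `"A"`, `"B"`, `"C"`.
#' @param l_sv,l_smv Tributary centreline lengths in m; ignored (forced to 0)
#'   for Type C.
#'
#' @return An object of class `simplification_type`.
#' @examples
#' simplification_type("C")
#' @export
simplification_type <- function(label = c("A", "B", "C"),
                                l_sv = NULL, l_smv = NULL) {
  label <- match.arg(label)
  defaults <- switch(label,
                     A = c(sv = 0.080, smv = 0.100),
                     B = c(sv = 0.030, smv = 0.040),
                     C = c(sv = 0.000, smv = 0.000))
  if (is.null(l_sv)) l_sv <- defaults[["sv"]]
  if (is.null(l_smv)) l_smv <- defaults[["smv"]]
  if (label == "C") {
    l_sv <- 0
    l_smv <- 0
  } else if (l_sv <= 0 || l_smv <= 0) {
    stop("tributary lengths must be strictly positive for Types A and B",
         call. = FALSE)
  }
  structure(list(label = label, l_sv = l_sv, l_smv = l_smv),
            class = "simplification_type")
}

#' Case specification
#'
#' One cell of the study design: a patient, a shunt position, and a
#' simplification strategy.
#'
#' @param patient A `patient_record`.
#' @param shunt A `shunt_config`.
#' @param simplification A `simplification_type`.
#' @return An object of class `case_spec`.
#' @export
case_spec <- function(patient, shunt, simplification) {
  stopifnot(inherits(patient, "patient_record"),
            inherits(shunt, "shunt_config"),
            inherits(simplification, "simplification_type"))
  structure(list(patient = patient, shunt = shunt,
                 simplification = simplification),
            class = "case_spec")
}

#' @export
print.case_spec <- function(x, ...) {
  cat(sprintf("<case_spec> %s / shunt at %s / Type %s\n",
              x$patient$id, x$shunt$position, x$simplification$label))
  invisible(x)
}

#' Enumerate the full study design
#'
#' Cartesian product of patients x shunt positions (LPV, MPV, RPV) x
#' simplification types (A, B, C), in that nesting order (types vary
#' fastest, patients slowest). Two patients give the 18-case study; one
#' patient gives 9 cases.
#'
#' @param patients A list of `patient_record` objects.
#' @param shunt_diameter,shunt_length Shunt geometry passed to
#'   [shunt_config()].
#' @return A list of `case_spec` objects with names
#'   `<patient>_<position>_<type>`.
#' @examples
#' length(enumerate_cases(patient_fixtures()))  # 18
#' @export
enumerate_cases <- function(patients, shunt_diameter = 0.008,
                            shunt_length = 0.060) {
  if (inherits(patients, "patient_record")) patients <- list(patients)
  if (length(patients) == 0L) {
    stop("`patients` must contain at least one patient_record", call. = FALSE)
  }
  stopifnot(all(vapply(patients, inherits, logical(1), "patient_record")))
  cases <- list()
  for (p in patients) {
    for (pos in c("LPV", "MPV", "RPV")) {
      for (ty in c("A", "B", "C")) {
        cs <- case_spec(p,
                        shunt_config(pos, diameter = shunt_diameter,
                                     length = shunt_length),
                        simplification_type(ty))
        cases[[paste(p$id, pos, ty, sep = "_")]] <- cs
      }
    }
  }
  cases
}

#' Default vessel segment lengths
#'
#' Centreline lengths (m) of the reduced-order segments: the MPV trunk and
#' the intrahepatic left/right portal branches. Tributary lengths come from
#' the [simplification_type()]. The shunt tee sits `tee_offset` from the
#' portal bifurcation on the host vessel.
#'
#' @return A named list of lengths in metres.
#' @export
default_segment_lengths <- function() {
  list(mpv = 0.040, lpv = 0.030, rpv = 0.030, tee_offset = 0.010)
}

#' Build the reduced-order flow network for one case
#'
#' Translates a [case_spec()] into a directed network of vessel segments,
#' the shunt, and the two resistance outlets, all discharging into a single
#' zero-pressure sink representing the inferior vena cava (IVC).
#'
#' Topology: SV and SMV inflow stubs (omitted for Type C, where the combined
#' inflow enters at the confluence node directly) feed the MPV trunk, which
#' is split at its midpoint by the pressure probe node `mpv_mid` and ends at
#' the portal bifurcation. The left and right branches terminate in their
#' outlet resistances. The shunt tee is placed 10 mm upstream of the
#' bifurcation on the MPV (position `"MPV"`) or 10 mm downstream of the
#' bifurcation on the named branch (positions `"LPV"`/`"RPV"`); the shunt
#' discharges directly into the sink. Edges that start at a vessel of
#' different calibre carry a `d_upstream` attribute so the solver can apply
#' Bernoulli static-pressure corrections consistently along the flow path.
#'
#' Outlet resistances are closed from the patient record via
#' [outlet_resistances()]; diameters are converted from mm to m here.
#'
#' @param case A `case_spec`.
#' @param lengths Segment-length table, see [default_segment_lengths()].
#' @param loss_model An [edge_loss_model()] supplying the shunt minor-loss
#'   coefficients.
#' @return An object of class `flow_network`.
#' @examples
#' p <- patient_fixtures()$patient1
#' net <- build_network(case_spec(p, shunt_config("MPV"),
#'                                simplification_type("A")))
#' net
#' @export
build_network <- function(case, lengths = default_segment_lengths(),
                          loss_model = edge_loss_model()) {
  stopifnot(inherits(case, "case_spec"))
  if (any(unlist(lengths) <= 0)) {
    stop("all default segment lengths must be strictly positive",
         call. = FALSE)
  }
  pt <- case$patient
  pos <- case$shunt$position
  ty <- case$simplification
  mm <- function(x) x / 1000
  tee <- lengths$tee_offset
  if (tee >= lengths$mpv / 2 || tee >= lengths$lpv || tee >= lengths$rpv) {
    stop("`tee_offset` must be shorter than the host half-segment",
         call. = FALSE)
  }

  edge <- function(name, from, to, diameter, length,
                   loss_k = numeric(0), d_upstream = NA_real_,
                   type = "vessel", resistance = NA_real_) {
    data.frame(name = name, from = from, to = to, type = type,
               diameter = diameter, length = length,
               d_upstream = d_upstream, resistance = resistance,
               loss_k = I(list(loss_k)), stringsAsFactors = FALSE)
  }

  edges <- list()
  if (ty$label == "C") {
    inflow_nodes <- "confluence"
  } else {
    inflow_nodes <- c("sv_inlet", "smv_inlet")
    edges$sv <- edge("sv", "sv_inlet", "confluence", mm(pt$d_sv), ty$l_sv)
    edges$smv <- edge("smv", "smv_inlet", "confluence",
                      mm(pt$d_smv), ty$l_smv)
  }

  half <- lengths$mpv / 2
  edges$mpv_a <- edge("mpv_a", "confluence", "mpv_mid", mm(pt$d_mpv), half)
  if (pos == "MPV") {
    edges$mpv_b <- edge("mpv_b", "mpv_mid", "shunt_tee", mm(pt$d_mpv),
                        half - tee)
    edges$mpv_c <- edge("mpv_c", "shunt_tee", "bifurcation", mm(pt$d_mpv),
                        tee)
    host_d <- mm(pt$d_mpv)
  } else {
    edges$mpv_b <- edge("mpv_b", "mpv_mid", "bifurcation", mm(pt$d_mpv), half)
  }

  if (pos == "LPV") {
    edges$lpv_a <- edge("lpv_a", "bifurcation", "shunt_tee", mm(pt$d_lpv),
                        tee, d_upstream = mm(pt$d_mpv))
    edges$lpv_b <- edge("lpv_b", "shunt_tee", "lpv_outlet", mm(pt$d_lpv),
                        lengths$lpv - tee)
    host_d <- mm(pt$d_lpv)
  } else {
    edges$lpv <- edge("lpv", "bifurcation", "lpv_outlet", mm(pt$d_lpv),
                      lengths$lpv, d_upstream = mm(pt$d_mpv))
  }
  if (pos == "RPV") {
    edges$rpv_a <- edge("rpv_a", "bifurcation", "shunt_tee", mm(pt$d_rpv),
                        tee, d_upstream = mm(pt$d_mpv))
    edges$rpv_b <- edge("rpv_b", "shunt_tee", "rpv_outlet", mm(pt$d_rpv),
                        lengths$rpv - tee)
    host_d <- mm(pt$d_rpv)
  } else {
    edges$rpv <- edge("rpv", "bifurcation", "rpv_outlet", mm(pt$d_rpv),
                      lengths$rpv, d_upstream = mm(pt$d_mpv))
  }

  edges$shunt <- edge("shunt", "shunt_tee", "sink",
                      case$shunt$diameter, case$shunt$length,
                      loss_k = c(contraction = loss_model$k_contraction,
                                 bend = loss_model$k_bend),
                      d_upstream = host_d, type = "shunt")

  q_pre <- patient_preop_flow(pt)
  r <- outlet_resistances(pt$p_pv, q_pre, pt$d_lpv, pt$d_rpv)
  edges$r_lpv <- edge("r_lpv", "lpv_outlet", "sink", NA_real_, NA_real_,
                      type = "resistance", resistance = r[["r_lpv"]])
  edges$r_rpv <- edge("r_rpv", "rpv_outlet", "sink", NA_real_, NA_real_,
                      type = "resistance", resistance = r[["r_rpv"]])

  edges <- do.call(rbind, unname(edges))
  net <- structure(
    list(nodes = unique(c(edges$from, edges$to)),
         inflow_nodes = inflow_nodes,
         sink = "sink",
         edges = edges,
         outlet_resistances = c(lpv = r[["r_lpv"]], rpv = r[["r_rpv"]]),
         probes = c("shunt_inlet", "shunt_outlet"),
         case = case),
    class = "flow_network")
  validate_flow_network(net)
  net
}

#' Validate a flow network
#'
#' Checks the structural invariants: the undirected graph is connected, the
#' sink is reachable from every inflow node following edge directions, each
#' inflow node has exactly one incident edge, and there is exactly one shunt
#' edge and exactly two resistance outlets.
#'
#' @param net A `flow_network`.
#' @return `net`, invisibly; errors on violation.
#' @export
validate_flow_network <- function(net) {
  stopifnot(inherits(net, "flow_network"))
  e <- net$edges
  g <- igraph::graph_from_data_frame(e[, c("from", "to")], directed = TRUE,
                                     vertices = net$nodes)
  if (!igraph::is_connected(g, mode = "weak")) {
    stop("flow network is not connected", call. = FALSE)
  }
  reach <- igraph::subcomponent(g, net$sink, mode = "in")
  reach <- igraph::V(g)$name[as.integer(reach)]
  if (!all(net$inflow_nodes %in% reach)) {
    stop("sink is not reachable from every inflow node", call. = FALSE)
  }
  deg <- igraph::degree(g, v = net$inflow_nodes, mode = "all")
  if (any(deg != 1)) {
    stop("every inflow node must have exactly one incident edge",
         call. = FALSE)
  }
  if (sum(e$type == "shunt") != 1L) {
    stop("network must contain exactly one shunt edge", call. = FALSE)
  }
  if (sum(e$type == "resistance") != 2L) {
    stop("network must contain exactly two resistance outlets", call. = FALSE)
  }
  invisible(net)
}

#' @export
print.flow_network <- function(x, ...) {
  cs <- x$case
  cat(sprintf("<flow_network> %s / shunt at %s / Type %s\n",
              cs$patient$id, cs$shunt$position, cs$simplification$label))
  cat(sprintf("  %d nodes, %d edges, inflow at: %s\n",
              length(x$nodes), nrow(x$edges),
              paste(x$inflow_nodes, collapse = ", ")))
  cat(sprintf("  outlet resistances (Pa s/m^3): LPV %.3e, RPV %.3e\n",
              x$outlet_resistances[["lpv"]], x$outlet_resistances[["rpv"]]))
  invisible(x)
}
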