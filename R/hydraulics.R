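# Lumped hydraulic-resistance model of the trap-array device.
#
# In the Stokes regime a microchannel network is the exact analogue of a
# resistor network: pressure <-> voltage, volumetric flow <-> current. The
# device is modelled as a comb/ladder: the cell inlet (CI) feeds an entrance
# junction with a release-outlet (RO) branch; the main channel passes 20
# capture-port stations (10 per side, staggered at half-pitch); each open port
# bridges to a bypass channel; both bypasses and the main channel terminate at
# a downstream junction carrying short channels to the waste outlet (WO) and
# buffer inlet (BI).

#' Rectangular channel segment
#'
#' @param width_um,height_um,length_um dimensions in um, all > 0.
#' @param label optional label.
#' @return an object of class `channel_segment`.
#' @export
channel_segment <- function(width_um, height_um, length_um, label = "") {
  dims <- c(width_um, height_um, length_um)
  if (!is.numeric(dims) || any(!is.finite(dims)) || any(dims <= 0)) {
    stop("channel dimensions must be positive and finite (um)", call. = FALSE)
  }
  structure(list(width_um = width_um, height_um = height_um,
                 length_um = length_um, label = label),
            class = "channel_segment")
}

#' Hydraulic resistance of a rectangular duct
#'
#' Exact series solution for pressure-driven Stokes flow in a rectangular
#' cross-section (with `h <= w` after swapping, which makes the formula
#' manifestly symmetric in the two transverse dimensions):
#' `R = 12 mu L / (w h^3 [1 - sum_{k odd} (192 h)/(k^5 pi^5 w)
#' tanh(k pi w / (2 h))])`.
#'
#' @param seg a [channel_segment()].
#' @param viscosity dynamic viscosity, Pa s (default water at room
#'   temperature).
#' @param kmax series truncation (odd terms up to `kmax`; default 99).
#' @return resistance in Pa s / m^3.
#' @examples
#' rect_duct_resistance(channel_segment(100, 25, 100))
#' @export
rect_duct_resistance <- function(seg, viscosity = 1e-3, kmax = 99L) {
  if (!inherits(seg, "channel_segment")) {
    stop("`seg` must be a channel_segment", call. = FALSE)
  }
  w <- seg$width_um * 1e-6
  h <- seg$height_um * 1e-6
  L <- seg$length_um * 1e-6
  if (h > w) { tmp <- w; w <- h; h <- tmp }
  k <- seq(1L, kmax, by = 2L)
  series <- sum((192 * h) / (k^5 * pi^5 * w) * tanh(k * pi * w / (2 * h)))
  12 * viscosity * L / (w * h^3 * (1 - series))
}

new_hydraulic_network <- function() {
  structure(list(
    nodes = character(0),
    edges = data.frame(from = character(0), to = character(0), R = numeric(0),
                       label = character(0), is_port = logical(0),
                       port_index = integer(0), blocked = logical(0),
                       leak_multiplier = numeric(0),
                       stringsAsFactors = FALSE),
    meta = list()
  ), class = "hydraulic_network")
}

#' Add a resistive edge to a hydraulic network
#'
#' @param net a `hydraulic_network`.
#' @param from,to node names (created if new).
#' @param R resistance, Pa s / m^3 (> 0).
#' @param label edge label.
#' @param is_port whether the edge is a capture port.
#' @param port_index ordinal of the port from the inlet (1 = nearest CI).
#' @return the updated network.
#' @export
add_edge <- function(net, from, to, R, label = "", is_port = FALSE,
                     port_index = NA_integer_) {
  stopifnot(inherits(net, "hydraulic_network"))
  if (!is.numeric(R) || length(R) != 1L || !is.finite(R) || R <= 0) {
    stop("edge resistance must be positive and finite", call. = FALSE)
  }
  net$nodes <- union(net$nodes, c(from, to))
  net$edges <- rbind(net$edges, data.frame(
    from = from, to = to, R = R, label = label, is_port = is_port,
    port_index = as.integer(port_index), blocked = FALSE,
    leak_multiplier = Inf, stringsAsFactors = FALSE))
  net
}

#' @export
print.hydraulic_network <- function(x, ...) {
  np <- sum(x$edges$is_port)
  cat(sprintf("<hydraulic_network> %d nodes, %d edges (%d ports, %d blocked)\n",
              length(x$nodes), nrow(x$edges), np,
              sum(x$edges$is_port & x$edges$blocked)))
  invisible(x)
}

#' Default trap-array device geometry
#'
#' Channel dimensions stated for the device: 100 um main and bypass widths,
#' 25 um uniform height, 10 capture ports per side at 100 um pitch, port
#' narrow mouth 6 um and wide mouth 18 um. Segment lengths outside the trap
#' region are not printed for the device and are package defaults (see the
#' methods vignette): they are chosen so that roughly half of the inlet flow
#' diverts to the release outlet and the waste-outlet short-circuit dominates
#' in release mode.
#'
#' @return named list of geometry defaults (um unless noted).
#' @export
device_geometry_defaults <- function() {
  list(
    n_ports_per_side = 10L,
    pitch_um = 100,
    main_width_um = 100,
    bypass_width_um = 100,
    height_um = 25,
    port_narrow_width_um = 6,
    port_narrow_length_um = 40,
    port_wide_width_um = 18,
    port_wide_length_um = 18,
    inlet_length_um = 300,
    ro_length_um = 1300,
    outlet_length_um = 300,
    bypass_end_length_um = 100,
    wo_length_um = 150,
    bi_length_um = 150,
    viscosity_pa_s = 1e-3
  )
}

#' Build the lumped network of the trap-array device
#'
#' Constructs the comb/ladder network described in the package overview: main
#' channel subdivided at every port station (ports on the two sides staggered
#' at half-pitch so each port occupies a distinct axial station), port edges
#' bridging to the side bypass channels (wide + narrow mouth segments in
#' series, lumped into one edge), and boundary nodes `CI`, `RO`, `BI`, `WO`.
#'
#' @param config named list overriding entries of
#'   [device_geometry_defaults()].
#' @return a `hydraulic_network` with `2 * n_ports_per_side` open port edges.
#' @export
build_device_network <- function(config = list()) {
  g <- device_geometry_defaults()
  unknown <- setdiff(names(config), names(g))
  if (length(unknown)) {
    stop("unknown device geometry keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  g <- modifyList(g, config)
  n_side <- as.integer(g$n_ports_per_side)
  if (is.na(n_side) || n_side < 1L) {
    stop("`n_ports_per_side` must be a positive integer", call. = FALSE)
  }
  for (key in setdiff(names(g), "n_ports_per_side")) {
    if (!is.numeric(g[[key]]) || !is.finite(g[[key]]) || g[[key]] <= 0) {
      stop("device geometry entry `", key, "` must be positive", call. = FALSE)
    }
  }
  mu <- g$viscosity_pa_s
  res <- function(w, h, L) {
    rect_duct_resistance(channel_segment(w, h, L), viscosity = mu)
  }

  n_ports <- 2L * n_side
  half <- g$pitch_um / 2
  R_main_seg <- res(g$main_width_um, g$height_um, half)
  R_byp_seg <- res(g$bypass_width_um, g$height_um, g$pitch_um)
  R_port <- res(g$port_wide_width_um, g$height_um, g$port_wide_length_um) +
    res(g$port_narrow_width_um, g$height_um, g$port_narrow_length_um)

  net <- new_hydraulic_network()
  net <- add_edge(net, "CI", "M0",
                  res(g$main_width_um, g$height_um, g$inlet_length_um),
                  "inlet")
  net <- add_edge(net, "M0", "RO",
                  res(g$main_width_um, g$height_um, g$ro_length_um),
                  "ro_channel")
  for (k in seq_len(n_ports)) {
    net <- add_edge(net, paste0("M", k - 1L), paste0("M", k), R_main_seg,
                    paste0("main_", k))
  }
  net <- add_edge(net, paste0("M", n_ports), "D",
                  res(g$main_width_um, g$height_um, g$outlet_length_um),
                  "main_outlet")
  # staggered ports: odd stations on the top bypass, even on the bottom
  for (side in c("T", "B")) {
    stations <- if (side == "T") seq(1L, n_ports, by = 2L)
                else seq(2L, n_ports, by = 2L)
    for (j in seq_along(stations)) {
      k <- stations[j]
      bnode <- paste0(side, j)
      net <- add_edge(net, paste0("M", k), bnode, R_port,
                      paste0("port_", k), is_port = TRUE, port_index = k)
      if (j > 1L) {
        net <- add_edge(net, paste0(side, j - 1L), bnode, R_byp_seg,
                        paste0("bypass_", side, j))
      }
    }
    net <- add_edge(net, paste0(side, n_side), "D",
                    res(g$bypass_width_um, g$height_um, g$bypass_end_length_um),
                    paste0("bypass_end_", side))
  }
  net <- add_edge(net, "D", "WO",
                  res(g$main_width_um, g$height_um, g$wo_length_um),
                  "wo_channel")
  net <- add_edge(net, "D", "BI",
                  res(g$main_width_um, g$height_um, g$bi_length_um),
                  "bi_channel")
  net$meta$geometry <- g
  net$meta$n_ports <- n_ports
  net
}

# internal: edges participating in conduction, with effective resistances
active_edges <- function(net) {
  e <- net$edges
  eff <- e$R
  leaky <- e$blocked & is.finite(e$leak_multiplier)
  eff[leaky] <- e$R[leaky] * e$leak_multiplier[leaky]
  keep <- !(e$blocked & !is.finite(e$leak_multiplier))
  list(edges = e[keep, , drop = FALSE], R = eff[keep])
}

# internal: connected component containing `start` over active edges
reachable_nodes <- function(net, start) {
  ae <- active_edges(net)$edges
  adj <- split(c(ae$to, ae$from), c(ae$from, ae$to))
  seen <- character(0)
  queue <- start
  while (length(queue)) {
    nd <- queue[1]; queue <- queue[-1]
    if (nd %in% seen) next
    seen <- c(seen, nd)
    queue <- c(queue, setdiff(adj[[nd]], seen))
  }
  seen
}

#' Solve flows and pressures in a hydraulic network
#'
#' Nodal-pressure (Kirchhoff) linear solve: a fixed volumetric inflow is
#' injected at one node and one or more nodes are held at the reference
#' pressure 0 Pa (multiple reference nodes model several outlets at
#' atmospheric pressure).
#'
#' @param net a `hydraulic_network`.
#' @param inflow_node node receiving the fixed inflow.
#' @param Q inflow, m^3/s.
#' @param ground_nodes nodes held at 0 Pa.
#' @return object of class `flow_solution`: named node pressures (Pa), the
#'   edge table with signed flows `q` (m^3/s, positive from `from` to `to`),
#'   and the worst interior Kirchhoff residual relative to `Q`.
#' @export
solve_flows <- function(net, inflow_node, Q, ground_nodes) {
  stopifnot(inherits(net, "hydraulic_network"))
  missing_nodes <- setdiff(c(inflow_node, ground_nodes), net$nodes)
  if (length(missing_nodes)) {
    stop("unknown boundary nodes: ", paste(missing_nodes, collapse = ", "),
         call. = FALSE)
  }
  if (!is.numeric(Q) || length(Q) != 1L || !is.finite(Q)) {
    stop("`Q` must be a single finite flow (m^3/s)", call. = FALSE)
  }
  comp <- reachable_nodes(net, ground_nodes[1])
  if (!inflow_node %in% comp) {
    stop("network is disconnected: inflow node `", inflow_node,
         "` cannot reach the reference node; its component is {",
         paste(reachable_nodes(net, inflow_node), collapse = ", "), "}",
         call. = FALSE)
  }
  ae <- active_edges(net)
  e <- ae$edges
  keep <- e$from %in% comp & e$to %in% comp
  e <- e[keep, , drop = FALSE]
  Reff <- ae$R[keep]

  nodes <- comp
  idx <- setNames(seq_along(nodes), nodes)
  n <- length(nodes)
  G <- matrix(0, n, n)
  gi <- idx[e$from]; gj <- idx[e$to]; gval <- 1 / Reff
  for (k in seq_along(gval)) {
    G[gi[k], gi[k]] <- G[gi[k], gi[k]] + gval[k]
    G[gj[k], gj[k]] <- G[gj[k], gj[k]] + gval[k]
    G[gi[k], gj[k]] <- G[gi[k], gj[k]] - gval[k]
    G[gj[k], gi[k]] <- G[gj[k], gi[k]] - gval[k]
  }
  rhs <- numeric(n)
  rhs[idx[inflow_node]] <- Q
  fixed <- idx[intersect(ground_nodes, nodes)]
  freei <- setdiff(seq_len(n), fixed)
  p <- numeric(n)
  if (length(freei)) {
    p[freei] <- solve(G[freei, freei, drop = FALSE], rhs[freei])
  }
  pressures <- setNames(p, nodes)

  q <- (p[idx[e$from]] - p[idx[e$to]]) / Reff
  edges <- e
  edges$q <- q
  edges$R_effective <- Reff

  # Kirchhoff residual at interior (non-boundary) nodes
  netflow <- setNames(numeric(n), nodes)
  for (k in seq_len(nrow(edges))) {
    netflow[edges$from[k]] <- netflow[edges$from[k]] - q[k]
    netflow[edges$to[k]] <- netflow[edges$to[k]] + q[k]
  }
  interior <- setdiff(nodes, c(inflow_node, ground_nodes))
  resid <- if (length(interior) && Q != 0) {
    max(abs(netflow[interior])) / abs(Q)
  } else 0
  structure(list(pressures = pressures, edges = edges,
                 inflow_node = inflow_node, Q = Q,
                 ground_nodes = ground_nodes, residual = resid),
            class = "flow_solution")
}

#' @export
print.flow_solution <- function(x, ...) {
  cat(sprintf(
    "<flow_solution> %d nodes, inflow %g m^3/s at %s, residual %.2g\n",
    length(x$pressures), x$Q, x$inflow_node, x$residual))
  invisible(x)
}

#' Pressure difference across each open capture port
#'
#' Returns the per-port pressure drops ordered from the first port (nearest
#' the cell inlet) to the last; with all ports open and forward capture flow
#' the sequence decreases monotonically along the array.
#'
#' @param solution a [solve_flows()] result.
#' @param net the solved `hydraulic_network`.
#' @return `data.frame` with `port_index`, `label`, and `dp_pa` (main-side
#'   minus bypass-side pressure, Pa).
#' @export
port_pressure_differences <- function(solution, net) {
  e <- solution$edges
  ports <- e[e$is_port, , drop = FALSE]
  ports <- ports[order(ports$port_index), , drop = FALSE]
  p <- solution$pressures
  data.frame(port_index = ports$port_index, label = ports$label,
             dp_pa = unname(p[ports$from] - p[ports$to]),
             q_m3s = ports$q, stringsAsFactors = FALSE)
}

#' Fraction of release flow entering the capture area
#'
#' In release mode flow is injected at the buffer inlet (BI) with the release
#' outlet (RO) and waste outlet (WO) at atmospheric pressure. The short
#' BI-to-WO path short-circuits most of the flow; the remainder traverses the
#' capture area (ports and trap channels) to the RO.
#'
#' @param net a device network from [build_device_network()].
#' @param Q release inflow, m^3/s (default 150 uL/min).
#' @return list with `capture_fraction` (flow traversing the capture area over
#'   BI inflow), `outlet_fractions` (named, sums to 1), and the underlying
#'   `flow_solution`.
#' @export
release_flow_fraction <- function(net, Q = ul_per_min_to_m3s(150)) {
  sol <- solve_flows(net, inflow_node = "BI", Q = Q,
                     ground_nodes = c("RO", "WO"))
  e <- sol$edges
  q_ro <- e$q[e$label == "ro_channel"]  # oriented M0 -> RO
  q_wo <- e$q[e$label == "wo_channel"]  # oriented D -> WO
  out <- c(RO = q_ro / Q, WO = q_wo / Q)
  list(capture_fraction = unname(out["RO"]), outlet_fractions = out,
       solution = sol)
}

#' Block a capture port (captured cell)
#'
#' A captured cell blocks its port; by default the port becomes an open
#' circuit (removed from conduction). Real cells seal imperfectly, so a finite
#' leak-resistance multiplier can be supplied instead.
#'
#' @param net a `hydraulic_network`.
#' @param port_index index of the port (1 = nearest CI).
#' @param leak_multiplier resistance multiplier for the blocked port; `Inf`
#'   (default) removes the edge from conduction.
#' @return the updated network. Blocking an already-blocked port is a no-op
#'   with a warning.
#' @export
occupy_port <- function(net, port_index, leak_multiplier = Inf) {
  k <- which(net$edges$is_port & net$edges$port_index == port_index)
  if (!length(k)) stop("no port with index ", port_index, call. = FALSE)
  if (net$edges$blocked[k]) {
    warning("port ", port_index, " is already blocked; no-op")
    return(net)
  }
  net$edges$blocked[k] <- TRUE
  net$edges$leak_multiplier[k] <- leak_multiplier
  net
}

#' @rdname occupy_port
#' @export
free_port <- function(net, port_index) {
  k <- which(net$edges$is_port & net$edges$port_index == port_index)
  if (!length(k)) stop("no port with index ", port_index, call. = FALSE)
  net$edges$blocked[k] <- FALSE
  net$edges$leak_multiplier[k] <- Inf
  net
}
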