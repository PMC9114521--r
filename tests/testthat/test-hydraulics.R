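test_that("rectangular duct resistance: limits, symmetry, truncation", {
  mu <- 1e-3
  # thin-slot limit within 1%
  thin <- channel_segment(1000, 10, 100)
  R_slot <- 12 * mu * 100e-6 / (1000e-6 * (10e-6)^3)
  expect_equal(rect_duct_resistance(thin, mu), R_slot, tolerance = 0.01)
  # symmetric in (w, h)
  expect_equal(rect_duct_resistance(channel_segment(100, 25, 50)),
               rect_duct_resistance(channel_segment(25, 100, 50)))
  # square duct vs high-order series oracle
  sq <- channel_segment(30, 30, 100)
  expect_equal(rect_duct_resistance(sq, mu, kmax = 99L),
               rect_duct_resistance(sq, mu, kmax = 9999L),
               tolerance = 1e-6)
  # monotone in length and viscosity
  expect_gt(rect_duct_resistance(channel_segment(100, 25, 200)),
            rect_duct_resistance(channel_segment(100, 25, 100)))
  expect_gt(rect_duct_resistance(sq, 2e-3), rect_duct_resistance(sq, 1e-3))
  expect_error(channel_segment(-1, 25, 100), "positive")
})

test_that("single edge and symmetric parallel edges solve exactly", {
  R <- 3.7e12; Q <- 1e-12
  net <- add_edge(depmech:::new_hydraulic_network(), "in", "out", R, "only")
  sol <- solve_flows(net, "in", Q, "out")
  expect_equal(unname(sol$pressures["in"]), Q * R)
  two <- add_edge(net, "in", "out", R, "second")
  sol2 <- solve_flows(two, "in", Q, "out")
  expect_equal(sol2$edges$q, c(Q / 2, Q / 2))
})

test_that("bridge network matches hand mesh-current algebra", {
  R1 <- 1e12; R2 <- 2e12; R3 <- 3e12; R4 <- 4e12; R5 <- 5e12
  Q <- 2e-12
  # mesh currents i1 (A-B-D loop) and i2 (B-C-D loop) with source current Q
  # entering A and leaving C; loop equations derived by hand:
  #   (R1+R5+R3) i1 - R5 i2 = R3 Q
  #   -R5 i1 + (R2+R4+R5) i2 = R4 Q
  A <- matrix(c(R1 + R5 + R3, -R5, -R5, R2 + R4 + R5), 2, 2)
  i <- solve(A, c(R3 * Q, R4 * Q))
  sol <- solve_flows(toy_bridge(R1, R2, R3, R4, R5), "A", Q, "C")
  q <- setNames(sol$edges$q, sol$edges$label)
  expect_equal(unname(q["e1"]), i[1], tolerance = 1e-9)
  expect_equal(unname(q["e2"]), i[2], tolerance = 1e-9)
  expect_equal(unname(q["e3"]), Q - i[1], tolerance = 1e-9)
  expect_equal(unname(q["e5"]), i[1] - i[2], tolerance = 1e-9)
  expect_lt(sol$residual, 1e-10)
})

test_that("device network has the designed topology", {
  net <- build_device_network()
  expect_s3_class(net, "hydraulic_network")
  expect_equal(sum(net$edges$is_port), 20)
  expect_true(all(!net$edges$blocked))
  expect_setequal(intersect(c("CI", "RO", "BI", "WO"), net$nodes),
                  c("CI", "RO", "BI", "WO"))
  # network stays connected for random subsets of blocked ports
  set.seed(11)
  for (i in 1:5) {
    blocked <- sample(1:20, sample(0:20, 1))
    nb <- net
    for (p in blocked) nb <- occupy_port(nb, p)
    reach <- depmech:::reachable_nodes(nb, "CI")
    expect_true(all(c("RO", "WO", "BI", "D") %in% reach))
  }
  expect_error(build_device_network(list(bogus_key = 1)), "unknown")
  expect_error(build_device_network(list(pitch_um = -5)), "positive")
})

test_that("capture mode: Kirchhoff conservation, decreasing port dp, linearity", {
  net <- build_device_network()
  Q <- ul_per_h_to_m3s(3)
  sol <- solve_flows(net, "CI", Q, c("RO", "WO"))
  expect_lt(sol$residual, 1e-10)
  dp <- port_pressure_differences(sol, net)
  expect_equal(nrow(dp), 20)
  expect_equal(dp$port_index, 1:20)
  expect_true(all(diff(dp$dp_pa) < 0))
  expect_gt(dp$dp_pa[1], 0.1)
  expect_lt(dp$dp_pa[1], 10)
  # doubling the inlet flow doubles every port dp
  dp2 <- port_pressure_differences(solve_flows(net, "CI", 2 * Q,
                                               c("RO", "WO")), net)
  expect_equal(dp2$dp_pa, 2 * dp$dp_pa, tolerance = 1e-9)
})

test_that("release mode: conservation of outlet fractions, short-circuit to WO", {
  net <- build_device_network()
  rel <- release_flow_fraction(net)
  expect_equal(sum(rel$outlet_fractions), 1, tolerance = 1e-9)
  expect_gt(rel$capture_fraction, 0)
  expect_lt(rel$capture_fraction, 0.5)  # the WO short-circuit dominates
  # reverse flow passes through every capture port
  e <- rel$solution$edges
  expect_true(all(abs(e$q[e$is_port]) > 0))
})

test_that("blocking the WO path forces all release flow through the capture area", {
  net <- build_device_network()
  k <- which(net$edges$label == "wo_channel")
  net$edges$R[k] <- net$edges$R[k] * 1e9   # effectively infinite
  rel <- release_flow_fraction(net)
  expect_equal(rel$capture_fraction, 1, tolerance = 1e-6)
})

test_that("occupying ports raises dp at the remaining open ports", {
  net <- build_device_network()
  Q <- ul_per_h_to_m3s(3)
  dp0 <- port_pressure_differences(solve_flows(net, "CI", Q, c("RO", "WO")),
                                   net)
  nb <- occupy_port(net, 1)
  dp1 <- port_pressure_differences(solve_flows(nb, "CI", Q, c("RO", "WO")),
                                   nb)
  open0 <- dp0[dp0$port_index != 1, "dp_pa"]
  expect_true(all(dp1$dp_pa > open0))
  # round trip restores the solution
  nb2 <- free_port(nb, 1)
  dp_rt <- port_pressure_differences(solve_flows(nb2, "CI", Q, c("RO", "WO")),
                                     nb2)
  expect_equal(dp_rt$dp_pa, dp0$dp_pa)
  expect_warning(occupy_port(nb, 1), "already blocked")
})

test_that("blocking all ports sends all inlet flow out through RO and the main outlet", {
  net <- build_device_network()
  for (p in 1:20) net <- occupy_port(net, p)
  Q <- ul_per_h_to_m3s(3)
  sol <- solve_flows(net, "CI", Q, c("RO", "WO"))
  e <- sol$edges
  expect_false(any(e$is_port))  # open-circuit ports drop out of conduction
  q_ro <- e$q[e$label == "ro_channel"]
  q_main_out <- e$q[e$label == "main_outlet"]
  expect_equal(q_ro + q_main_out, Q, tolerance = 1e-9)
})

test_that("disconnected boundary raises a named error", {
  net <- add_edge(depmech:::new_hydraulic_network(), "a", "b", 1e12)
  net <- add_edge(net, "c", "d", 1e12)
  expect_error(solve_flows(net, "a", 1e-12, "c"), "disconnected")
  expect_error(solve_flows(net, "zz", 1e-12, "a"), "unknown boundary")
})
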