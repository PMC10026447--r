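test_that("synthetic networks are deterministic and realistically shaped", {
  net1 <- generate_synthetic_network(seed = 4)
  net2 <- generate_synthetic_network(seed = 4)
  expect_identical(net1$segments, net2$segments)
  expect_identical(net1$nodes, net2$nodes)
  expect_false(identical(net1$segments,
                         generate_synthetic_network(seed = 5)$segments))

  expect_true(all(net1$segments$r_v > 0))
  expect_true(all(net1$segments$length > 0))
  expect_gte(max(net1$nodes$z) - min(net1$nodes$z), 1000)

  flow <- solve_pressures(net1)
  labels <- classify_segments(net1, flow)
  coeffs <- network_coefficients(net1, labels)
  ns <- network_summary(net1, coeffs)
  # surface-to-volume ratio of order 1e4 m^2/m^3
  expect_gt(ns$S_over_V, 0.5e4); expect_lt(ns$S_over_V, 3e4)
  # capillary surface dominates the larger vessels
  expect_gte(ns$S_C / (ns$S_A + ns$S_V), 5)
  # outer vessel volume fraction exceeds the lumen fraction (r_o > r_v)
  expect_gt(ns$zeta, ns$zeta_L)
})

test_that("Poiseuille solve matches closed forms and conserves mass", {
  # single segment: Q = pi r^4 dp / (8 mu l)
  net <- chain_network(n = 1, r_v = 3, seg_len = 100, p_in = 100, p_out = 0)
  flow <- solve_pressures(net, viscosity_law = "constant",
                          constant_viscosity_pa_s = 1e-3)
  expect_equal(flow$segments$flow,
               pi * (3e-6)^4 * 100 / (8 * 1e-3 * 100e-6),
               tolerance = 1e-12)

  # symmetric Y-junction splits the inflow 50/50
  yf <- solve_pressures(y_network(), viscosity_law = "constant")
  expect_equal(yf$segments$flow[2], yf$segments$flow[3])
  expect_equal(yf$segments$flow[1], yf$segments$flow[2] + yf$segments$flow[3])

  # equal boundary pressures: uniform field, no flow
  net_eq <- chain_network(n = 5, p_in = 50, p_out = 50)
  f_eq <- solve_pressures(net_eq, viscosity_law = "constant")
  expect_equal(f_eq$node_pressures$pressure, rep(50, 6))
  expect_equal(max(abs(f_eq$segments$flow)), 0)

  # conservation and boundary bracketing on the synthetic fixture
  net_s <- generate_synthetic_network(seed = 1)
  fs <- solve_pressures(net_s)
  expect_lt(fs$max_imbalance, 1e-8)
  expect_true(all(fs$node_pressures$pressure <= 8000 + 1e-9))
  expect_true(all(fs$node_pressures$pressure >= 2000 - 1e-9))
  # global balance: boundary inflow equals boundary outflow
  bn <- fs$boundary$node
  imb <- vapply(bn, function(nd) {
    s <- net_s$segments
    sum(fs$segments$flow[s$from == nd]) - sum(fs$segments$flow[s$to == nd])
  }, numeric(1))
  expect_lt(abs(sum(imb)) / (sum(abs(imb)) / 2), 1e-8)
})

test_that("apparent viscosity laws behave at their known limits", {
  expect_equal(apparent_viscosity(6, hematocrit = 0, law = "invitro",
                                  relative = TRUE), 1)
  # in-vivo law keeps the wall-layer correction at zero hematocrit
  D <- 6 * (92 / 55)^(1 / 3)
  expect_equal(apparent_viscosity(6, hematocrit = 0, law = "invivo",
                                  relative = TRUE), (D / (D - 1.1))^2)
  expect_equal(apparent_viscosity(123, law = "constant",
                                  constant_viscosity_pa_s = 2e-3), 2e-3)
  # mouse rescaling factor for a 92 fL reference cell
  expect_equal((92 / 55)^(1 / 3), 1.187, tolerance = 1e-3)
  # capillary-scale apparent viscosity exceeds plasma viscosity
  expect_gt(apparent_viscosity(8, hematocrit = 0.45, relative = TRUE), 1)
  expect_error(apparent_viscosity(6, hematocrit = 1.2), "0, 1")
  expect_error(apparent_viscosity(-1), "positive")
})

test_that("pressure classification splits a chain at mid pressure", {
  net <- chain_network(n = 10, r_v = 2, p_in = 100, p_out = 0)
  flow <- solve_pressures(net, viscosity_law = "constant")
  lab <- classify_segments(net, flow)
  expect_equal(lab$label, c(rep("arterial", 5), rep("venous", 5)))
  expect_equal(lab$category, rep("C", 10)) # r_v < 3

  # identical pressures everywhere: strict "exceeds" makes all venous
  net_eq <- chain_network(n = 4, p_in = 10, p_out = 10)
  lab_eq <- classify_segments(net_eq, solve_pressures(net_eq,
                                                      viscosity_law = "constant"))
  expect_true(all(lab_eq$label == "venous"))

  # synthetic fixture: penetrating inlet trees arterial, outlet trees venous
  net_s <- generate_synthetic_network(seed = 3)
  lab_s <- classify_segments(net_s, solve_pressures(net_s))
  cls <- net_s$segments$vessel_class
  expect_true(all(lab_s$label[cls == "penetrating_arteriole"] == "arterial"))
  expect_true(all(lab_s$label[cls == "penetrating_venule"] == "venous"))
  expect_error(
    classify_segments(net_s, solve_pressures(net_s), small_radius_um = 0.1),
    "threshold"
  )
})

test_that("layer summaries add up and average consistently", {
  net <- generate_synthetic_network(seed = 6)
  flow <- solve_pressures(net)
  coeffs <- network_coefficients(net, classify_segments(net, flow))
  ls <- summarize_layers(net, coeffs)

  expect_equal(nrow(ls$layers), 18) # 6 layers x 3 categories, gaps kept
  expect_equal(ls$layers$depth_to_um[ls$layers$layer == 5][1] -
                 ls$layers$depth_from_um[ls$layers$layer == 5][1], 100)

  tot <- ls$network[ls$network$category == "all", ]
  expect_equal(sum(ls$layers$surface_m2), tot$surface_m2)
  expect_equal(sum(ls$layers$filtration_capacity), tot$filtration_capacity)
  expect_equal(sum(ls$layers$diffusion_capacity), tot$diffusion_capacity)

  # surface-weighted averages lie between per-segment extremes
  expect_gte(tot$mean_L_p, min(coeffs$L_p))
  expect_lte(tot$mean_L_p, max(coeffs$L_p))

  # capillaries dominate the network averages
  cap <- ls$network[ls$network$category == "C", ]
  expect_lt(abs(log(tot$mean_L_p / cap$mean_L_p)), log(2))

  # one-segment network: layer average equals that segment's value
  one <- chain_network(n = 1, r_v = 2, seg_len = 50)
  f1 <- solve_pressures(one, viscosity_law = "constant")
  c1 <- network_coefficients(one, classify_segments(one, f1))
  l1 <- summarize_layers(one, c1, layer_breaks_um = c(0, 100))
  expect_equal(l1$network$mean_L_p[1], c1$L_p[1])
})

test_that("endfoot counts divide surface by local mean area", {
  one <- chain_network(n = 1, r_v = 2, seg_len = 50)
  f1 <- solve_pressures(one, viscosity_law = "constant")
  c1 <- network_coefficients(one, classify_segments(one, f1))
  ec <- endfoot_counts(one, c1)
  r_o <- c1$r_o[1]
  A <- mean_endfoot_area(r_o, area_relation("venous"), extrapolate = TRUE)
  expect_equal(ec$total_endfeet, c1$S[1] / (A * 1e-12))
  expect_error(endfoot_counts(one, c1, astrocyte_density_mm3 = 0), "positive")

  net <- generate_synthetic_network(seed = 2)
  co <- network_coefficients(net, classify_segments(net, solve_pressures(net)))
  ec2 <- endfoot_counts(net, co, astrocyte_density_mm3 = 20000)
  dens_c <- ec2$by_category$density_per_mm2[ec2$by_category$category == "C"]
  expect_gt(dens_c, 1e4); expect_lt(dens_c, 3e4)
  expect_gt(ec2$endfeet_per_astrocyte, 1)
})

test_that("Douglas-Peucker simplification uses the radius tolerance", {
  straight <- cbind(x = seq(0, 100, by = 10), y = 0, z = 0)
  straight[2:10, "y"] <- runif(9, -0.5, 0.5) # jitter below r_v
  net <- chain_network(n = 1, r_v = 2)
  net$segments$polyline <- list(straight)
  simp <- simplify_network(net)
  expect_equal(nrow(simp$segments$polyline[[1]]), 2)

  zig <- cbind(x = c(0, 25, 50, 75, 100), y = c(0, 5, 0, -5, 0), z = 0)
  net$segments$polyline <- list(zig)
  simp2 <- simplify_network(net)
  expect_gt(nrow(simp2$segments$polyline[[1]]), 2)
  expect_equal(simp2$segments$length[1],
               endfeet:::polyline_length(simp2$segments$polyline[[1]]))
  # idempotence
  simp3 <- simplify_network(simp2)
  expect_identical(simp2$segments$polyline, simp3$segments$polyline)
})

test_that("network CSV dialect round-trips", {
  net <- generate_synthetic_network(seed = 8, lateral_um = 220,
                                    capillary_spacing_um = 110)
  stem <- file.path(withr::local_tempdir(), "net")
  write_network(net, stem)
  back <- read_network(stem)
  expect_equal(back$nodes$z, net$nodes$z)
  expect_equal(back$segments$r_v, net$segments$r_v)
  expect_equal(back$metadata$provenance, "synthetic")
  flow_a <- solve_pressures(net); flow_b <- solve_pressures(back)
  expect_equal(flow_b$node_pressures$pressure, flow_a$node_pressures$pressure)
})
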