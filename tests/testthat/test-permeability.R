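test_that("filtration coefficient follows the parallel-plate formula", {
  gap <- gap_geometry(d_g_nm = 20, h_es_um = 1, l_g_um = 1.5)
  fl <- fluid_properties(mu = 0.7e-3)
  expect_equal(filtration_coefficient(0.0056, gap, fl),
               0.0056 * (20e-9)^2 / (12 * 0.7e-3 * 1.5e-6))
  expect_equal(filtration_coefficient(0.0056, gap, fl), 1.78e-10,
               tolerance = 0.005)
  expect_equal(filtration_coefficient(0, gap, fl), 0)
  # L_p scales with d_g^3 at fixed tessellation geometry: phi carries one
  # power of d_g, the transmissibility two
  lp1 <- filtration_coefficient(0.0056, gap, fl)
  gap2 <- gap_geometry(d_g_nm = 40, h_es_um = 1, l_g_um = 1.5)
  lp2 <- filtration_coefficient(0.0056 * 2, gap2, fl)
  expect_equal(lp2 / lp1, 8)
  expect_error(filtration_coefficient(-0.1, gap, fl), "0, 1")
})

test_that("membrane diffusion coefficient and fluxes follow their formulas", {
  gap <- gap_geometry(d_g_nm = 20, h_es_um = 1, l_g_um = 1, alpha = 1)
  expect_equal(membrane_diffusion_coefficient(0.00588, gap), 5880)
  expect_equal(membrane_diffusion_coefficient(0.00588,
    gap_geometry(h_es_um = 1, l_g_um = 1, alpha = 0)), 0)

  fx <- transmembrane_fluxes(C_M = 4400, L_p = 2e-10, S = 1.885e-9,
                             D = 3.5e-10, delta_c = 1, delta_p = 0)
  expect_equal(fx$F_D, 4400 * 3.5e-10 * 1) # 1.54e-6 mol m^-2 s^-1
  expect_equal(fx$F_D, 1.54e-6, tolerance = 0.001)
  expect_equal(fx$Q, 0)
  expect_equal(transmembrane_fluxes(4400, 2e-10, 1e-9, delta_c = 0,
                                    delta_p = 100)$F_D, 0)
  # tubular surface area: r_v = 3 um, l_v = 100 um
  expect_equal(2 * pi * 3e-6 * 100e-6, 1.885e-9, tolerance = 1e-3)

  # linear coupling between the two coefficients: C_M / L_p = 12 mu a / d^2
  phi <- c(0.002, 0.0056, 0.01)
  g <- gap_geometry(d_g_nm = 20, h_es_um = 1.2, alpha = 0.8)
  fl <- fluid_properties(mu = 0.7e-3)
  ratio <- membrane_diffusion_coefficient(phi, g) /
    filtration_coefficient(phi, g, fl)
  expect_equal(ratio, rep(12 * 0.7e-3 * 0.8 / (20e-9)^2, 3))
})

test_that("Renkin hindrance has the free and blocked limits", {
  expect_equal(renkin_hindrance(0), 1)
  expect_equal(renkin_hindrance(1), 0)
  expect_equal(renkin_hindrance(0.1), 0.6413, tolerance = 1e-3)
  l <- seq(0, 1, by = 0.05)
  a <- renkin_hindrance(l)
  expect_true(all(a >= 0 & a <= 1))
  expect_true(all(diff(a) <= 0))
  expect_error(renkin_hindrance(1.2), "0, 1")
})

test_that("Peclet numbers stay diffusion-dominated at sheath pressures", {
  expect_equal(peclet_number(0), 0)
  pe <- peclet_number(100, gap_geometry(d_g_nm = 20),
                      fluid_properties(mu = 0.7e-3, D = 1e-9))
  expect_equal(pe, 100 * (20e-9)^2 / (12 * 0.7e-3 * 1e-9))
  expect_lt(pe, 1)
  expect_equal(peclet_number(100, gap_geometry(d_g_nm = 40)) / pe, 4)
  expect_error(peclet_number(100, gap_geometry(alpha = 0)), "alpha")
})

test_that("sheath geometry from lumen radius matches the structural model", {
  g <- sheath_geometry_from_lumen(c(2, 3, 10))
  expect_equal(g$h_es_um, c(1, 1, 2.05)) # clamped at 1 um below r_v = 3
  expect_equal(g$l_g_um, 1.5 * g$h_es_um)
  expect_equal(g$r_o, c(1.15 * 2 + 0.95, 1.3 * 3 + 1.5, 1.3 * 10 + 1.5))
  expect_error(sheath_geometry_from_lumen(-1), "positive")
  # the smooth-muscle layer creates a genuine jump at r_v = 3
  expect_gt(sheath_geometry_from_lumen(3)$r_o - sheath_geometry_from_lumen(2.999)$r_o, 0.9)
})

test_that("coefficient sweep spans the expected physiological ranges", {
  tab <- vessel_coefficient_table(seq(1.5, 10, length.out = 20), "arterial",
                                  extrapolate = TRUE)
  expect_true(all(tab$L_p > 1e-11 & tab$L_p < 5e-10))
  expect_true(all(tab$C_M > 4e2 & tab$C_M < 7e3))
  expect_true(all(diff(tab$L_p) < 0)) # larger vessels are tighter
})
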