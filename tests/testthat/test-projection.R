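test_that("flat-surface limit measures cells at the 2/pi foreshortening ratio", {
  dom <- surface_domain(50, mean_area = 20, n_cells_target = 2000)
  tess <- build_periodic_voronoi(sample_hardcore_points(dom, 1 / 20, seed = 3))
  pm <- simulate_projected_measurement(tess)
  expect_equal(pm$mean_measured / 20, 2 / pi, tolerance = 0.05)
  # roughly half the cells lie on the visible arc
  expect_equal(pm$n_included / nrow(tess$cells), 0.5, tolerance = 0.1)
})

test_that("a cell wrapping the full cylinder measures its silhouette", {
  dom <- surface_domain(3, L = 10)
  t1 <- build_periodic_voronoi(tibble::tibble(u = 1, z = 5), domain = dom)
  expect_equal(simulate_projected_measurement(t1)$mean_measured, 2 * 3 * 10,
               tolerance = 1e-4)
})

test_that("capillary-scale projection roughly halves the measured area", {
  ms <- vapply(1:10, function(i) {
    tess <- build_periodic_voronoi(
      sample_hardcore_points(surface_domain(2.9, mean_area = 50), 1 / 50,
                             seed = 300 + i)
    )
    simulate_projected_measurement(tess)$mean_measured
  }, numeric(1))
  expect_equal(mean(ms), 25, tolerance = 0.25)
})

test_that("correction tables are monotone, conservative and invertible", {
  tab <- build_area_correction(
    r_o_grid = c(2.4, 2.9, 3.5), a_true_grid = seq(20, 90, 10),
    n_realizations = 12, seed = 5
  )
  # projection only shrinks areas
  expect_true(all(tab$A_meas_um2 <= tab$A_true_um2))
  # strictly increasing measured area in true area at fixed radius
  by_r <- split(tab, tab$r_o_um)
  for (s in by_r) expect_true(all(diff(s$A_meas_um2) > 0))
  # wrapping is worse for smaller vessels: correction ratio decreases in r_o
  ratio <- vapply(by_r, function(s) mean(s$A_true_um2 / s$A_meas_um2),
                  numeric(1))
  expect_true(all(diff(ratio) < 0))

  # round trip: correct(simulate(A_true)) recovers A_true within 10%
  node <- tab[tab$r_o_um == 2.9 & tab$A_true_um2 == 50, ]
  expect_equal(correct_measured_area(node$A_meas_um2, 2.9, tab), 50,
               tolerance = 0.1)

  expect_error(correct_measured_area(1, 2.9, tab), "outside the table")
  expect_error(correct_measured_area(30, 10, tab), "radius range")

  path <- withr::local_tempfile(fileext = ".csv")
  write_area_correction(tab, path)
  back <- read_area_correction(path)
  expect_equal(correct_measured_area(25, 2.9, back),
               correct_measured_area(25, 2.9, tab))
})

test_that("Monte-Carlo standard errors shrink with realization count", {
  t1 <- build_area_correction(c(2.5, 2.9, 3.5), c(40, 50, 60),
                              n_realizations = 8, seed = 11)
  t2 <- build_area_correction(c(2.5, 2.9, 3.5), c(40, 50, 60),
                              n_realizations = 32, seed = 11)
  # quadrupling realizations should halve the standard error (within noise)
  expect_equal(mean(t2$se_um2) / mean(t1$se_um2), 0.5, tolerance = 0.2)
})

test_that("inclusion rule is a documented switch", {
  dom <- surface_domain(4, mean_area = 40, n_cells_target = 300)
  tess <- build_periodic_voronoi(sample_hardcore_points(dom, 1 / 40, seed = 8))
  m_gen <- simulate_projected_measurement(
    tess, projection_convention(inclusion_rule = "generator"))
  m_full <- simulate_projected_measurement(
    tess, projection_convention(inclusion_rule = "complete"))
  expect_lt(m_full$n_included, m_gen$n_included)
  expect_error(projection_convention(visible_halfwidth = 4), "0, pi")
})
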