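test_that("hexagonal lattice reproduces the closed-form gap fraction", {
  for (A in c(50, 110)) {
    hl <- hex_lattice_points(A = A, nx = 8, ny = 8)
    tess <- build_periodic_voronoi(hl$points, domain = hl$domain,
                                   keep_polygons = FALSE)
    phi <- sheath_metrics(tess, d_g = 0.02)$phi_g
    expect_equal(phi, hexagonal_gap_fraction(A, 0.02), tolerance = 1e-4)
    expect_equal(tess$cells$area, rep(A, nrow(tess$cells)), tolerance = 1e-9)
  }
})

test_that("gap metrics follow their definitions and refuse wide gaps", {
  dom <- surface_domain(2.9, L = 200)
  tess <- build_periodic_voronoi(sample_hardcore_points(dom, 1 / 50, seed = 3),
                                 keep_polygons = FALSE)
  m <- sheath_metrics(tess, d_g = 0.02)
  expect_equal(m$phi_g, 0.02 * tess$l_sigma / dom$area)
  expect_equal(m$phi_perp, 0.02 * tess$l_perp / dom$area)
  expect_equal(m$gaps_per_ring, tess$l_perp / dom$L)
  expect_lte(m$phi_perp, m$phi_g)
  expect_gt(m$phi_g, 0); expect_lt(m$phi_g, 1)
  expect_error(sheath_metrics(tess, d_g = 3), "thin-gap")
  expect_error(sheath_metrics(tess, d_g = -1), "positive")
})

test_that("isotropic patterns project edges at the 2/pi ratio", {
  dom <- surface_domain(5, L = 5 * 2 * pi)
  ratios <- vapply(1:5, function(i) {
    tess <- build_periodic_voronoi(
      sample_hardcore_points(dom, 1 / 25, seed = 20 + i),
      keep_polygons = FALSE
    )
    tess$l_perp / tess$l_sigma
  }, numeric(1))
  expect_equal(mean(ratios), 2 / pi, tolerance = 0.02)
})

test_that("ensembles are deterministic per seed and summarised correctly", {
  s1 <- simulate_sheath(2.9, 50, n_realizations = 4, seed = 9)
  s2 <- simulate_sheath(2.9, 50, n_realizations = 4, seed = 9)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
  expect_identical(attr(s1, "area_samples"), attr(s2, "area_samples"))
  g <- glance(s1)
  expect_equal(g$phi_g, mean(s1$phi_g))
  expect_equal(g$n_realizations, 4)
  # per-realization seeds are derived, so realizations differ
  expect_gt(stats::sd(s1$phi_g), 0)
})

test_that("distribution fits recover the sample means", {
  sim <- simulate_sheath(2.9, 50, n_realizations = 25, seed = 13)
  fits <- fit_sheath_distributions(sim)
  expect_equal(fits$area_fit$mean, 50, tolerance = 0.03)
  expect_equal(fits$phi_fit$mean, mean(sim$phi_g))
  # fitted gamma mean within 2% of the pooled sample mean (>= 1e4 samples)
  expect_gte(fits$area_fit$n, 1e4)
  expect_equal(fits$area_fit$mean, fits$sample_means$area, tolerance = 0.02)
  td <- tidy(fits)
  expect_equal(td$distribution, c("gamma", "normal"))

  sim_small <- simulate_sheath(2.9, 50, n_realizations = 2, seed = 1)
  expect_error(fit_sheath_distributions(sim_small), ">= 20 realizations")
  sim_const <- sim
  attr(sim_const, "area_samples") <- rep(50, 200)
  expect_error(fit_sheath_distributions(sim_const), "zero-variance")
})

test_that("ensemble CSV export is tidy", {
  sim <- simulate_sheath(2.9, 50, n_realizations = 3, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_sheath_metrics(sim, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_named(back, c("realization", "r_o_um", "mean_area_um2", "phi_g",
                       "phi_perp", "gaps_per_ring", "n_cells", "seed"))
  expect_equal(back$phi_g, sim$phi_g)
})
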