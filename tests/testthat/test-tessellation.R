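test_that("hard-core sampling honours count, spacing and determinism", {
  dom <- surface_domain(2.9, L = 100)
  pts <- sample_hardcore_points(dom, rho = 1 / 50, seed = 42)
  expect_equal(nrow(pts), round(dom$area / 50))
  expect_equal(attr(pts, "hardcore_distance"), 0.3 * sqrt(50))

  # minimum toroidal pairwise distance respects the hard core
  n <- nrow(pts)
  du <- abs(outer(pts$u, pts$u, "-")); du <- pmin(du, dom$width - du)
  dz <- abs(outer(pts$z, pts$z, "-")); dz <- pmin(dz, dom$L - dz)
  d <- sqrt(du^2 + dz^2); diag(d) <- Inf
  expect_gte(min(d), 0.3 * sqrt(50) - 1e-12)

  pts2 <- sample_hardcore_points(dom, rho = 1 / 50, seed = 42)
  expect_identical(pts$u, pts2$u)
  expect_identical(pts$z, pts2$z)
  pts3 <- sample_hardcore_points(dom, rho = 1 / 50, seed = 43)
  expect_false(identical(pts$u, pts3$u))

  expect_error(sample_hardcore_points(dom, rho = 0, seed = 1), "positive")
  expect_error(sample_hardcore_points(dom, rho = -1, seed = 1), "positive")
})

test_that("infeasible hard-core density aborts with the attempt budget", {
  dom <- surface_domain(2, L = 20)
  # force an impossible packing via a tiny attempt budget and a dense target
  expect_error(
    sample_hardcore_points(dom, rho = 1 / 2, seed = 1, attempt_factor = 1.01),
    "attempt budget"
  )
})

test_that("degenerate tessellations on the torus are exact", {
  dom <- surface_domain(2, L = 10)
  t1 <- build_periodic_voronoi(tibble::tibble(u = 3, z = 4), domain = dom)
  expect_equal(t1$cells$area, dom$area)
  expect_equal(t1$l_sigma, dom$width + dom$L)

  t2 <- build_periodic_voronoi(
    tibble::tibble(u = c(1, 1 + dom$width / 2), z = c(2, 7)),
    domain = dom
  )
  expect_equal(t2$cells$area, rep(dom$area / 2, 2))

  expect_error(
    build_periodic_voronoi(tibble::tibble(u = c(1, 1), z = c(2, 2)),
                           domain = dom),
    "coincident"
  )
})

test_that("cells tile the domain and every bisector is shared by two cells", {
  dom <- surface_domain(4, L = 120)
  tess <- build_periodic_voronoi(sample_hardcore_points(dom, 1 / 30, seed = 7))
  expect_lt(abs(sum(tess$cells$area) - dom$area) / dom$area, 1e-9)
  expect_equal(nrow(tess$cells), round(dom$area / 30))
  # each physical edge appears exactly twice among per-cell boundary edges
  expect_equal(tess$n_dup_edges, 2 * nrow(tess$edges))
  expect_lte(tess$l_perp, tess$l_sigma)
  # deduplicated edge lengths add back to the totals
  expect_equal(sum(tess$edges$length), tess$l_sigma, tolerance = 1e-9)
  expect_equal(sum(tess$edges$dz), tess$l_perp, tolerance = 1e-9)
})

test_that("periodic tessellation agrees with a planar Voronoi oracle", {
  skip_if_not_installed("deldir")
  dom <- surface_domain(3, L = 3 * pi * 2) # square-ish torus
  pts <- sample_hardcore_points(dom, 1 / 18, seed = 11)
  tess <- build_periodic_voronoi(pts)

  # oracle: planar Voronoi of the 3x3 replicated pattern; interior copy
  # cells must match the periodic cells' areas
  W <- dom$width; H <- dom$L
  rep_pts <- do.call(rbind, lapply(-1:1, function(sx) {
    do.call(rbind, lapply(-1:1, function(sy) {
      cbind(pts$u + sx * W, pts$z + sy * H, seq_len(nrow(pts)))
    }))
  }))
  dd <- deldir::deldir(rep_pts[, 1], rep_pts[, 2],
                       rw = c(-W, 2 * W, -H, 2 * H))
  central <- which(rep_pts[, 1] >= 0 & rep_pts[, 1] < W &
                     rep_pts[, 2] >= 0 & rep_pts[, 2] < H)
  oracle_areas <- dd$summary$dir.area[central]
  ord <- rep_pts[central, 3]
  expect_equal(tess$cells$area[ord], oracle_areas, tolerance = 1e-6)
})

test_that("tessellation metrics are scale invariant", {
  dom <- surface_domain(3, L = 90)
  pts <- sample_hardcore_points(dom, 1 / 40, seed = 5)
  t1 <- build_periodic_voronoi(pts, keep_polygons = FALSE)
  k <- 2.5
  dom_k <- surface_domain(3 * k, L = 90 * k)
  pts_k <- tibble::tibble(u = pts$u * k, z = pts$z * k)
  t2 <- build_periodic_voronoi(pts_k, domain = dom_k, keep_polygons = FALSE)
  expect_equal(t2$l_sigma, k * t1$l_sigma, tolerance = 1e-9)
  m1 <- sheath_metrics(t1, d_g = 0.02)
  m2 <- sheath_metrics(t2, d_g = 0.02 * k)
  expect_equal(m2$phi_g, m1$phi_g, tolerance = 1e-9)
})

test_that("cylinder mapping preserves axial coordinate and radius", {
  dom <- surface_domain(3, L = 30)
  tess <- build_periodic_voronoi(sample_hardcore_points(dom, 1 / 30, seed = 2))
  xyz <- tessellation_cylinder_coords(tess)
  expect_equal(xyz$z3, xyz$z)
  expect_equal(sqrt(xyz$x3^2 + xyz$y3^2), rep(3, nrow(xyz)), tolerance = 1e-12)
})
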