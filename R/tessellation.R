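#' Sample a hard-core point pattern on the vessel surface
#'
#' Endfoot positions are drawn as sequentially proposed uniform points on
#' the periodic surface, rejecting proposals closer than the hard-core
#' distance `0.3 * sqrt(1 / rho)` (toroidal metric) to any accepted point.
#' The hard core suppresses unrealistically small endfoot cells. Exactly
#' `round(rho * area)` points are returned.
#'
#' @param domain A [surface_domain()].
#' @param rho Target point density in points per square micrometre
#'   (`1 / mean_area`).
#' @param seed Integer RNG seed; identical `(domain, rho, seed)` give
#'   identical patterns.
#' @param attempt_factor The rejection loop aborts after
#'   `attempt_factor * n` proposals (signals an infeasible density).
#'
#' @return A tibble with columns `u` (circumferential, um) and `z` (axial,
#'   um), with attributes `domain`, `rho`, `hardcore_distance` and `seed`.
#' @examples
#' dom <- surface_domain(r_o = 2.9, L = 100)
#' pts <- sample_hardcore_points(dom, rho = 1 / 50, seed = 1)
#' nrow(pts) # round(dom$area / 50)
#' @export
sample_hardcore_points <- function(domain, rho, seed,
                                   attempt_factor = 1e4) {
  stopifnot(is_surface_domain(domain))
  if (!is.numeric(rho) || length(rho) != 1 || !is.finite(rho) || rho <= 0) {
    abort("`rho` must be a single positive density (points per um^2).")
  }
  n <- round(rho * domain$area)
  if (n < 1) abort("`rho * area` rounds to zero points; increase the density or the domain.")
  hc <- 0.3 * sqrt(1 / rho)
  set.seed(seed)
  m <- cpp_sample_hardcore(n, domain$width, domain$L, hc,
                           max_attempts = attempt_factor * n)
  out <- tibble(u = m[, 1], z = m[, 2])
  attr(out, "domain") <- domain
  attr(out, "rho") <- rho
  attr(out, "hardcore_distance") <- hc
  attr(out, "seed") <- seed
  out
}

#' Sample a Poisson point pattern on the vessel surface
#'
#' Binomial point process (hard core disabled): `round(rho * area)` i.i.d.
#' uniform points. Used for the analytic Poisson-Voronoi edge-intensity
#' oracle, for which the expected total edge length per unit area is
#' `2 * sqrt(rho)`.
#'
#' @inheritParams sample_hardcore_points
#' @return A tibble as in [sample_hardcore_points()], with hard-core
#'   distance 0.
#' @export
sample_poisson_points <- function(domain, rho, seed) {
  stopifnot(is_surface_domain(domain))
  if (rho <= 0) abort("`rho` must be positive.")
  n <- round(rho * domain$area)
  if (n < 1) abort("`rho * area` rounds to zero points.")
  set.seed(seed)
  out <- tibble(u = stats::runif(n, 0, domain$width),
                z = stats::runif(n, 0, domain$L))
  attr(out, "domain") <- domain
  attr(out, "rho") <- rho
  attr(out, "hardcore_distance") <- 0
  attr(out, "seed") <- seed
  out
}

#' Periodic Voronoi tessellation of the endfoot sheath
#'
#' Computes the Voronoi tessellation of a point pattern on the periodic
#' (toroidal) vessel surface. Each polygonal cell is the set of surface
#' points nearest (periodic metric) to its generator; polygon edges are the
#' bisectors marking inter-endfoot gaps. Construction replicates the
#' generators on a 3x3 ghost grid and clips each cell by half-planes, so
#' cells spanning more than the fundamental domain (possible only for
#' fewer than 3 generators) are still handled, but patterns are expected
#' to contain at least a handful of points in practice.
#'
#' @param points A tibble of generator coordinates from
#'   [sample_hardcore_points()] or [sample_poisson_points()], or any tibble
#'   with columns `u`, `z` (then `domain` must be supplied).
#' @param domain A [surface_domain()]; defaults to the pattern's own.
#' @param keep_polygons Keep full cell polygons (needed for projection and
#'   plotting); disable for very large oracle runs to save memory.
#'
#' @return An object of class `endfoot_tessellation`: list with
#'   * `cells`: tibble (`cell`, `u`, `z`, `area`) — generator and cell area
#'     in um^2;
#'   * `edges`: tibble of unique bisector edges (`cell_a`, `cell_b`, `x1`,
#'     `y1`, `x2`, `y2`, `length`, `dz`), each physical edge once;
#'   * `l_sigma`: total edge length (um); `l_perp`: total axially projected
#'     edge length `sum(|dz|)` (um);
#'   * `domain`, `polygons` (list of vertex matrices or `NULL`).
#' @examples
#' dom <- surface_domain(r_o = 2.9, L = 100)
#' tess <- build_periodic_voronoi(sample_hardcore_points(dom, 1 / 50, seed = 1))
#' glance(tess)
#' @export
build_periodic_voronoi <- function(points, domain = attr(points, "domain"),
                                   keep_polygons = TRUE) {
  if (!is_surface_domain(domain)) {
    abort("`domain` must be a surface_domain (supply it explicitly if `points` has no domain attribute).")
  }
  if (!all(c("u", "z") %in% names(points))) abort("`points` needs columns `u` and `z`.")
  n <- nrow(points)
  if (n < 1) abort("need at least one generator point.")
  if (anyDuplicated(points[, c("u", "z")])) {
    abort("coincident generator points; use a hard-core pattern upstream.")
  }

  res <- cpp_periodic_voronoi(points$u, points$z, domain$width, domain$L,
                              keep_polygons)

  cell_edges <- tibble(
    cell_a = res$edge_cell, cell_b = res$edge_nbr,
    x1 = res$edge_x1, y1 = res$edge_y1, x2 = res$edge_x2, y2 = res$edge_y2
  ) %>%
    mutate(
      length = sqrt((.data$x2 - .data$x1)^2 + (.data$y2 - .data$y1)^2),
      dz = abs(.data$y2 - .data$y1)
    )

  # Each bisector is traversed once by each of its two cells; totals are
  # halved and the exported edge list is deduplicated by the canonical
  # (sorted cell pair, midpoint modulo domain) key.
  l_sigma <- sum(cell_edges$length) / 2
  l_perp <- sum(cell_edges$dz) / 2

  mxy <- cbind((cell_edges$x1 + cell_edges$x2) / 2,
               (cell_edges$y1 + cell_edges$y2) / 2)
  mxy[, 1] <- mxy[, 1] %% domain$width
  mxy[, 2] <- mxy[, 2] %% domain$L
  scale <- max(domain$width, domain$L)
  key <- paste(
    pmin(cell_edges$cell_a, cell_edges$cell_b),
    pmax(cell_edges$cell_a, cell_edges$cell_b),
    round(mxy[, 1] / scale, 7), round(mxy[, 2] / scale, 7),
    round(cell_edges$length / scale, 7),
    sep = "|"
  )
  edges <- cell_edges[!duplicated(key), ]

  polygons <- NULL
  if (keep_polygons) {
    off <- res$poly_offsets
    polygons <- lapply(seq_len(n), function(i) {
      idx <- (off[i] + 1):off[i + 1]
      cbind(u = res$poly_x[idx], z = res$poly_y[idx])
    })
  }

  structure(
    list(
      cells = tibble(cell = seq_len(n), u = points$u, z = points$z,
                     area = res$areas),
      edges = edges,
      l_sigma = l_sigma,
      l_perp = l_perp,
      n_dup_edges = nrow(cell_edges),
      domain = domain,
      polygons = polygons
    ),
    class = "endfoot_tessellation"
  )
}

#' @export
print.endfoot_tessellation <- function(x, ...) {
  cat(sprintf(
    "<endfoot_tessellation> %d cells on r_o = %.4g um, L = %.4g um; l_sigma = %.5g um, l_perp = %.5g um\n",
    nrow(x$cells), x$domain$r_o, x$domain$L, x$l_sigma, x$l_perp
  ))
  invisible(x)
}

#' @describeIn build_periodic_voronoi One-row summary (cell count, total
#'   edge lengths, mean cell area).
#' @param x An `endfoot_tessellation`.
#' @param ... Unused.
#' @export
glance.endfoot_tessellation <- function(x, ...) {
  tibble(
    n_cells = nrow(x$cells),
    area = x$domain$area,
    l_sigma = x$l_sigma,
    l_perp = x$l_perp,
    mean_area = mean(x$cells$area)
  )
}

#' @describeIn build_periodic_voronoi Per-cell tibble (generator position
#'   and cell area).
#' @export
tidy.endfoot_tessellation <- function(x, ...) x$cells

#' Map tessellation geometry onto the 3D cylinder
#'
#' Converts cell polygon vertices from unrolled coordinates `(u, z)` to 3D
#' cylinder coordinates `x = r_o cos(theta)`, `y = r_o sin(theta)`,
#' `z` with `theta = u / r_o`, for visualization export.
#'
#' @param tess An `endfoot_tessellation` built with `keep_polygons = TRUE`.
#' @return A tibble with columns `cell`, `vertex`, `u`, `z`, `x3`, `y3`,
#'   `z3`.
#' @export
tessellation_cylinder_coords <- function(tess) {
  stopifnot(inherits(tess, "endfoot_tessellation"))
  if (is.null(tess$polygons)) abort("tessellation was built with `keep_polygons = FALSE`.")
  r_o <- tess$domain$r_o
  purrr::imap_dfr(tess$polygons, function(m, i) {
    theta <- m[, "u"] / r_o
    tibble(cell = i, vertex = seq_len(nrow(m)), u = m[, "u"], z = m[, "z"],
           x3 = r_o * cos(theta), y3 = r_o * sin(theta), z3 = m[, "z"])
  })
}
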