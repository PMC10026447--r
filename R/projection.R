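#' Convention for simulated 2D endfoot-area measurement
#'
#' Endfoot areas measured on 2D micrographs underestimate true (3D
#' surface) areas for two reasons: orthographic projection foreshortens
#' the curved vessel surface, and the far half of the vessel is hidden.
#' Both effects strengthen as cells wrap around small vessels. This
#' convention object fixes how the virtual measurement emulates that
#' process:
#' * `visible_halfwidth`: angular half-width of the visible arc (default
#'   `pi / 2`, i.e. exactly the near half of the cylinder);
#' * `inclusion_rule`: which cells enter the measured-area average —
#'   `"generator"` (default; cells whose generator lies on the visible
#'   arc) or `"complete"` (cells entirely inside the visible arc);
#' * measured area is always the image-plane (x = r_o sin(theta), y = z)
#'   area of the cell's part clipped to the visible arc.
#'
#' @param visible_halfwidth Half-width of the visible angular window, rad.
#' @param inclusion_rule `"generator"` or `"complete"`.
#' @param max_dtheta Angular resolution for subdividing projected edges.
#' @return A `projection_convention` object.
#' @export
projection_convention <- function(visible_halfwidth = pi / 2,
                                  inclusion_rule = c("generator", "complete"),
                                  max_dtheta = 0.02) {
  inclusion_rule <- match.arg(inclusion_rule)
  if (visible_halfwidth <= 0 || visible_halfwidth > pi) {
    abort("`visible_halfwidth` must be in (0, pi].")
  }
  structure(
    list(visible_halfwidth = visible_halfwidth,
         inclusion_rule = inclusion_rule, max_dtheta = max_dtheta),
    class = "projection_convention"
  )
}

#' Simulate the 2D-projected measurement of endfoot areas
#'
#' Maps a tessellation onto its cylinder, projects it orthographically
#' into the image plane, hides the far half, and measures each included
#' cell's visible projected area.
#'
#' @param tess An [build_periodic_voronoi()] tessellation (with polygons).
#' @param convention A [projection_convention()].
#' @return A list: `mean_measured` (um^2), `cell_areas` tibble (`cell`,
#'   `true_area`, `measured_area`, `included`), `n_included`.
#' @examples
#' dom <- surface_domain(r_o = 10, L = 80)
#' tess <- build_periodic_voronoi(sample_hardcore_points(dom, 1 / 25, seed = 2))
#' simulate_projected_measurement(tess)$mean_measured
#' @export
simulate_projected_measurement <- function(tess,
                                           convention = projection_convention()) {
  stopifnot(inherits(tess, "endfoot_tessellation"),
            inherits(convention, "projection_convention"))
  if (is.null(tess$polygons)) abort("tessellation must be built with `keep_polygons = TRUE`.")
  dom <- tess$domain
  n <- nrow(tess$cells)
  off <- c(0L, cumsum(vapply(tess$polygons, nrow, integer(1))))
  px <- unlist(lapply(tess$polygons, function(m) m[, "u"]))
  pz <- unlist(lapply(tess$polygons, function(m) m[, "z"]))

  measured <- cpp_projected_areas(px, pz, as.integer(off), tess$cells$u,
                                  dom$r_o, dom$width,
                                  convention$visible_halfwidth,
                                  convention$max_dtheta)

  included <- !is.na(measured)
  if (convention$inclusion_rule == "complete") {
    # keep only cells whose full angular extent is visible
    u_vis <- dom$r_o * convention$visible_halfwidth
    full <- vapply(seq_len(n), function(i) {
      m <- tess$polygons[[i]]
      shift <- -round(tess$cells$u[i] / dom$width) * dom$width
      all(abs(m[, "u"] + shift) < u_vis)
    }, logical(1))
    included <- included & full
  }
  if (!any(included)) abort("no cells fall on the visible arc; empty inclusion set.")

  cell_areas <- tibble(
    cell = tess$cells$cell,
    true_area = tess$cells$area,
    measured_area = measured,
    included = included
  )
  list(
    mean_measured = mean(measured[included]),
    cell_areas = cell_areas,
    n_included = sum(included)
  )
}

#' Build the measured-to-true area correction table
#'
#' For each grid node `(r_o, A_true)` the virtual measurement is run on
#' `n_realizations` independent sheath realizations, giving the mean
#' measured area and its Monte-Carlo standard error. Monotonicity of
#' `A_measured` in `A_true` at fixed radius is enforced by isotonic
#' post-processing (violations beyond Monte-Carlo noise raise an error).
#' The resulting table defines, by inversion, the unique mapping from a
#' measured 2D area back to the true surface area.
#'
#' @param r_o_grid Radii (um), ordered, >= 3 values.
#' @param a_true_grid True mean areas (um^2), ordered, >= 3 values.
#' @param n_realizations Realizations per node.
#' @param seed Base seed.
#' @param convention A [projection_convention()].
#' @param n_cells_target Cells per realization.
#' @return An `area_correction_table`: tibble (`r_o_um`, `A_true_um2`,
#'   `A_meas_um2`, `se_um2`, `n_realizations`) with the convention
#'   attached.
#' @export
build_area_correction <- function(r_o_grid = c(2, 2.9, 4, 6, 8, 10, 12, 15, 20),
                                  a_true_grid = NULL,
                                  n_realizations = 50, seed = 1,
                                  convention = projection_convention(),
                                  n_cells_target = 500) {
  if (length(r_o_grid) < 3 || length(a_true_grid %||% 1:12) < 3) {
    abort("need >= 3 grid points per axis.")
  }
  if (is.unsorted(r_o_grid) || (!is.null(a_true_grid) && is.unsorted(a_true_grid))) {
    abort("grids must be ordered increasingly.")
  }
  a_true_grid <- a_true_grid %||% seq(20, 600, length.out = 12)

  grid <- tidyr::expand_grid(r_o_um = r_o_grid, A_true_um2 = a_true_grid)
  rows <- purrr::pmap_dfr(
    list(grid$r_o_um, grid$A_true_um2, seq_len(nrow(grid))),
    function(r, A, k) {
      means <- vapply(seq_len(n_realizations), function(i) {
        pts <- sample_hardcore_points(
          surface_domain(r, mean_area = A, n_cells_target = n_cells_target),
          rho = 1 / A, seed = seed + (k - 1) * n_realizations + i - 1
        )
        tess <- build_periodic_voronoi(pts)
        simulate_projected_measurement(tess, convention)$mean_measured
      }, numeric(1))
      tibble(r_o_um = r, A_true_um2 = A, A_meas_um2 = mean(means),
             se_um2 = sd(means) / sqrt(n_realizations),
             n_realizations = n_realizations)
    }
  )

  # isotonic post-processing per radius; reject violations beyond noise
  rows <- rows %>%
    group_by(.data$r_o_um) %>%
    group_modify(function(df, key) {
      iso <- isoreg(df$A_true_um2, df$A_meas_um2)
      viol <- abs(iso$yf - df$A_meas_um2)
      if (any(viol > pmax(6 * df$se_um2, 0.05 * df$A_meas_um2))) {
        abort("measured areas are non-monotone in true area beyond Monte-Carlo noise; check the projection convention.")
      }
      df$A_meas_um2 <- make_strictly_increasing(iso$yf)
      df
    }) %>%
    ungroup()

  if (any(rows$A_meas_um2 > rows$A_true_um2 + 6 * rows$se_um2)) {
    abort("measured areas exceed true areas; projection must only shrink areas.")
  }

  out <- rows
  attr(out, "convention") <- convention
  class(out) <- c("area_correction_table", class(out))
  out
}

make_strictly_increasing <- function(y, eps = NULL) {
  eps <- eps %||% (1e-9 * max(abs(y)))
  for (i in seq_along(y)[-1]) if (y[i] <= y[i - 1]) y[i] <- y[i - 1] + eps
  y
}

#' Correct a measured 2D endfoot area
#'
#' Inverts the correction table: per radius, the measured area is mapped
#' back to the true area by monotone linear interpolation, then linearly
#' interpolated between the two bracketing table radii. Arguments outside
#' the table hull raise an error.
#'
#' @param A_meas Measured 2D area (um^2), vectorized.
#' @param r_o Outer sheath radius (um), scalar or vectorized with
#'   `A_meas`.
#' @param table An [build_area_correction()] table.
#' @return Corrected true area(s) in um^2.
#' @examples
#' \dontrun{
#' tab <- build_area_correction(c(2.5, 2.9, 3.5), seq(20, 90, 10),
#'                              n_realizations = 20, seed = 1)
#' correct_measured_area(25, 2.9, tab)  # ~50
#' }
#' @export
correct_measured_area <- function(A_meas, r_o, table) {
  stopifnot(inherits(table, "area_correction_table"))
  nmax <- max(length(A_meas), length(r_o))
  A_meas <- rep_len(A_meas, nmax)
  r_o <- rep_len(r_o, nmax)
  radii <- sort(unique(table$r_o_um))
  if (any(r_o < radii[1] | r_o > radii[length(radii)])) {
    abort("`r_o` outside the correction table's radius range.")
  }
  invert_at <- function(r, a) {
    sub <- table[table$r_o_um == r, ]
    if (a < min(sub$A_meas_um2) || a > max(sub$A_meas_um2)) {
      abort(sprintf(
        "measured area %.3g um^2 outside the table range [%.3g, %.3g] at r_o = %.3g um.",
        a, min(sub$A_meas_um2), max(sub$A_meas_um2), r
      ))
    }
    approx(sub$A_meas_um2, sub$A_true_um2, xout = a)$y
  }
  vapply(seq_len(nmax), function(i) {
    below <- max(radii[radii <= r_o[i]])
    above <- min(radii[radii >= r_o[i]])
    if (below == above) return(invert_at(below, A_meas[i]))
    w <- (r_o[i] - below) / (above - below)
    (1 - w) * invert_at(below, A_meas[i]) + w * invert_at(above, A_meas[i])
  }, numeric(1))
}

#' Write / read an area-correction table as CSV
#'
#' @param table An `area_correction_table`.
#' @param path CSV path.
#' @return `path` (write) or the re-loaded table (read).
#' @export
write_area_correction <- function(table, path) {
  stopifnot(inherits(table, "area_correction_table"))
  readr::write_csv(as_tibble(table), path)
  invisible(path)
}

#' @rdname write_area_correction
#' @export
read_area_correction <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  attr(out, "convention") <- projection_convention()
  class(out) <- c("area_correction_table", class(out))
  out
}
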