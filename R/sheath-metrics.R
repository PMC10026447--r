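#' Gap metrics of one tessellation
#'
#' Given the inter-endfoot gap width `d_g`, computes from a tessellation:
#' * `phi_g = d_g * l_sigma / (2 * pi * r_o * L)` — gap area fraction, the
#'   fraction of the sheath surface occupied by inter-endfoot gaps;
#' * `gaps_per_ring = l_perp / L` — expected number of gaps crossed by a
#'   circular cross-sectional cut of the vessel, where `l_perp` is the
#'   total edge length after projecting each edge onto the vessel axis;
#' * `phi_perp = d_g * l_perp / (2 * pi * r_o * L)` — the reduced gap area
#'   fraction that a cross-section-based estimate would give.
#'
#' The finite gap width is not subtracted from cell areas: gap fractions
#' stay below about 1% in the regimes modelled, so `d_g` enters only
#' through these definitions. The computation refuses gap widths that are
#' no longer small against the cell scale (estimated `phi_g` above 5%),
#' where that thin-gap assumption breaks down.
#'
#' @param tess An [build_periodic_voronoi()] tessellation.
#' @param d_g Gap width in micrometres (default 0.02, i.e. 20 nm).
#' @return A one-row tibble: `phi_g`, `phi_perp`, `gaps_per_ring`,
#'   `n_cells`, `mean_area`, `l_sigma`, `l_perp`.
#' @export
sheath_metrics <- function(tess, d_g = 0.02) {
  stopifnot(inherits(tess, "endfoot_tessellation"))
  if (!is.numeric(d_g) || length(d_g) != 1 || d_g <= 0) {
    abort("`d_g` must be a single positive gap width in micrometres.")
  }
  phi_g <- d_g * tess$l_sigma / tess$domain$area
  if (phi_g > 0.05) {
    abort(sprintf(
      "gap width d_g = %.3g um gives gap area fraction %.3g; the thin-gap model assumes fractions well below 1%%.",
      d_g, phi_g
    ))
  }
  tibble(
    phi_g = phi_g,
    phi_perp = d_g * tess$l_perp / tess$domain$area,
    gaps_per_ring = tess$l_perp / tess$domain$L,
    n_cells = nrow(tess$cells),
    mean_area = mean(tess$cells$area),
    l_sigma = tess$l_sigma,
    l_perp = tess$l_perp
  )
}

#' Simulate an ensemble of endfoot sheath realizations
#'
#' Runs `n_realizations` independent hard-core Voronoi tessellations for a
#' vessel of sheath radius `r_o` and target mean endfoot area `mean_area`,
#' and collects the gap metrics of each realization. Per-realization seeds
#' are derived as `seed + realization - 1`.
#'
#' @param r_o Outer sheath radius (um).
#' @param mean_area Target mean endfoot cell area (um^2); the point density
#'   is `1 / mean_area`.
#' @param d_g Gap width (um); default 0.02 (20 nm).
#' @param n_realizations Number of independent realizations (>= 1).
#' @param seed Base RNG seed.
#' @param L Axial domain length (um); default derived so each realization
#'   holds about 500 cells (see [surface_domain()]).
#' @param hardcore If `FALSE`, sample Poisson (no hard core) patterns.
#' @param keep_areas Pool per-cell areas across realizations into the
#'   `area_samples` attribute (needed for distribution fitting).
#'
#' @return A tibble with one row per realization (`realization`, `r_o_um`,
#'   `mean_area_um2`, `phi_g`, `phi_perp`, `gaps_per_ring`, `n_cells`,
#'   `seed`), class `sheath_ensemble`, with attributes `area_samples`
#'   (numeric vector) and `d_g`.
#' @examples
#' sim <- simulate_sheath(r_o = 2.9, mean_area = 50, n_realizations = 3, seed = 1)
#' mean(sim$phi_g)
#' @export
simulate_sheath <- function(r_o, mean_area, d_g = 0.02, n_realizations = 200,
                            seed = 1, L = NULL, hardcore = TRUE,
                            keep_areas = TRUE) {
  if (n_realizations < 1) abort("`n_realizations` must be >= 1.")
  dom <- surface_domain(r_o, L = L, mean_area = mean_area)
  sampler <- if (hardcore) sample_hardcore_points else sample_poisson_points
  rho <- 1 / mean_area

  rows <- vector("list", n_realizations)
  areas <- if (keep_areas) vector("list", n_realizations) else NULL
  for (i in seq_len(n_realizations)) {
    pts <- sampler(dom, rho, seed = seed + i - 1)
    tess <- build_periodic_voronoi(pts, keep_polygons = FALSE)
    m <- sheath_metrics(tess, d_g = d_g)
    rows[[i]] <- tibble(
      realization = i, r_o_um = r_o, mean_area_um2 = m$mean_area,
      phi_g = m$phi_g, phi_perp = m$phi_perp,
      gaps_per_ring = m$gaps_per_ring, n_cells = m$n_cells,
      seed = seed + i - 1
    )
    if (keep_areas) areas[[i]] <- tess$cells$area
  }
  out <- bind_rows(rows)
  if (keep_areas) attr(out, "area_samples") <- unlist(areas)
  attr(out, "d_g") <- d_g
  attr(out, "target_mean_area") <- mean_area
  class(out) <- c("sheath_ensemble", class(out))
  out
}

#' @describeIn simulate_sheath Ensemble means of the gap metrics.
#' @param x A `sheath_ensemble`.
#' @param ... Unused.
#' @export
glance.sheath_ensemble <- function(x, ...) {
  tibble(
    n_realizations = nrow(x),
    r_o_um = x$r_o_um[1],
    mean_area_um2 = mean(x$mean_area_um2),
    phi_g = mean(x$phi_g),
    phi_perp = mean(x$phi_perp),
    gaps_per_ring = mean(x$gaps_per_ring),
    d_g_um = attr(x, "d_g")
  )
}

#' Write ensemble metrics as tidy CSV
#'
#' @param x A `sheath_ensemble` from [simulate_sheath()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sheath_metrics <- function(x, path) {
  readr::write_csv(
    as_tibble(x)[, c("realization", "r_o_um", "mean_area_um2", "phi_g",
                     "phi_perp", "gaps_per_ring", "n_cells", "seed")],
    path
  )
  invisible(path)
}

#' Fit parametric distributions to ensemble samples
#'
#' The per-cell area samples of an ensemble are well described by a Gamma
#' distribution and the per-realization gap area fractions by a normal
#' distribution; this fits both by maximum likelihood.
#'
#' @param ensemble A `sheath_ensemble` from [simulate_sheath()] run with
#'   `keep_areas = TRUE`, holding at least 100 pooled cell areas and 20
#'   realizations.
#' @return Object of class `sheath_distribution_fits` with elements
#'   `area_fit` (shape, rate/scale) and `phi_fit` (mean, sd); use
#'   [tidy.sheath_distribution_fits()] for a tabular view.
#' @export
fit_sheath_distributions <- function(ensemble) {
  areas <- attr(ensemble, "area_samples")
  if (is.null(areas) || length(areas) < 100) {
    abort("need >= 100 pooled cell-area samples (run simulate_sheath with keep_areas = TRUE).")
  }
  phi <- ensemble$phi_g
  if (length(phi) < 20) abort("need >= 20 realizations to fit the phi_g distribution.")
  if (sd(areas) == 0 || sd(phi) == 0) abort("zero-variance samples; cannot fit distributions.")

  area_fit <- fitdistrplus::fitdist(areas, "gamma",
                                    start = list(shape = (mean(areas) / sd(areas))^2,
                                                 rate = mean(areas) / sd(areas)^2))
  phi_fit <- list(mean = mean(phi), sd = sd(phi))

  structure(
    list(
      area_fit = list(
        shape = unname(coef(area_fit)["shape"]),
        rate = unname(coef(area_fit)["rate"]),
        scale = 1 / unname(coef(area_fit)["rate"]),
        mean = unname(coef(area_fit)["shape"] / coef(area_fit)["rate"]),
        n = length(areas)
      ),
      phi_fit = c(phi_fit, list(n = length(phi))),
      sample_means = list(area = mean(areas), phi = mean(phi))
    ),
    class = "sheath_distribution_fits"
  )
}

#' @describeIn fit_sheath_distributions Tabular view of the fitted
#'   parameters.
#' @param x A `sheath_distribution_fits` object.
#' @param ... Unused.
#' @export
tidy.sheath_distribution_fits <- function(x, ...) {
  tibble(
    quantity = c("cell_area", "phi_g"),
    distribution = c("gamma", "normal"),
    parameter1 = c(x$area_fit$shape, x$phi_fit$mean),
    parameter2 = c(x$area_fit$scale, x$phi_fit$sd),
    fitted_mean = c(x$area_fit$mean, x$phi_fit$mean),
    n = c(x$area_fit$n, x$phi_fit$n)
  )
}

#' @export
print.sheath_distribution_fits <- function(x, ...) {
  cat(sprintf(
    "<sheath_distribution_fits>\n  cell area ~ Gamma(shape = %.4g, scale = %.4g), mean %.4g um^2 (n = %d)\n  phi_g ~ Normal(mean = %.4g, sd = %.3g) (n = %d)\n",
    x$area_fit$shape, x$area_fit$scale, x$area_fit$mean, x$area_fit$n,
    x$phi_fit$mean, x$phi_fit$sd, x$phi_fit$n
  ))
  invisible(x)
}

#' Gap area fraction of a regular hexagonal tiling
#'
#' Closed-form benchmark: for a regular hexagonal tiling with cell area `A`
#' the edge length per unit area is `3 s / A` with side
#' `s = sqrt(2 A / (3 sqrt(3)))`, giving
#' `phi_g = d_g * sqrt(2 sqrt(3) / A)`. Regular tiling is the minimal-edge
#' (most ordered) limit and slightly undercuts random tessellations.
#'
#' @param mean_area Cell area `A` (um^2).
#' @param d_g Gap width (um), default 0.02.
#' @return Gap area fraction (dimensionless).
#' @examples
#' hexagonal_gap_fraction(50)  # ~0.0053
#' @export
hexagonal_gap_fraction <- function(mean_area, d_g = 0.02) {
  stopifnot(all(mean_area > 0), d_g > 0)
  d_g * sqrt(2 * sqrt(3) / mean_area)
}
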