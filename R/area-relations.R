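#' Vessel radius to mean endfoot area relations
#'
#' Mean endfoot coverage area grows with vessel caliber: quadratically for
#' arterial vessels and linearly for venous vessels. The default,
#' projection-corrected coefficients are anchored to the corrected mean
#' areas of the reference vessels — capillary (r_o = 2.9 um, 50 um^2),
#' arteriole (15 um, 490 um^2) and venule (15 um, 110 um^2) — giving
#' `A_arterial(r) = 2.032 r^2 + 32.91` and
#' `A_venous(r) = 4.959 r + 35.62` (um^2, r in um). The two relations share
#' the capillary anchor, where arterial and venous vessels are
#' indistinguishable. Coefficients may be overridden by users who have
#' their own calibration of the diameter-area data.
#'
#' The uncorrected (`corrected = FALSE`) relations are rescaled to the
#' measured capillary anchor of 25 um^2, the value obtained from 2D image
#' analysis before projection-error correction.
#'
#' @param vessel_kind `"arterial"` or `"venous"`.
#' @param corrected Use projection-corrected (`TRUE`, default) or measured
#'   2D-scale coefficients.
#' @param coefficients Optional numeric override: `c(intercept, r^2)` for
#'   arterial, `c(intercept, r)` for venous.
#' @param valid_radius_range Radius validity range in um.
#'
#' @return An `area_relation` object (fields `vessel_kind`, `form`,
#'   `coefficients`, `valid_radius_range`, `corrected`).
#' @examples
#' mean_endfoot_area(15, area_relation("arterial"))  # ~490
#' @export
area_relation <- function(vessel_kind = c("arterial", "venous"),
                          corrected = TRUE, coefficients = NULL,
                          valid_radius_range = c(2.5, 20)) {
  vessel_kind <- match.arg(vessel_kind)
  form <- if (vessel_kind == "arterial") "quadratic" else "linear"
  if (is.null(coefficients)) {
    coefficients <- if (vessel_kind == "arterial") {
      # a + b r^2 through the corrected anchors (2.9, 50) and (15, 490)
      solve_anchor(c(2.9, 15), c(50, 490), power = 2)
    } else {
      solve_anchor(c(2.9, 15), c(50, 110), power = 1)
    }
    if (!corrected) {
      # measured 2D scale: capillary anchor 25 um^2 instead of 50
      coefficients <- coefficients * 25 / 50
    }
  }
  structure(
    list(vessel_kind = vessel_kind, form = form,
         coefficients = coefficients,
         valid_radius_range = valid_radius_range, corrected = corrected),
    class = "area_relation"
  )
}

solve_anchor <- function(r, A, power) {
  m <- cbind(1, r^power)
  as.numeric(solve(m, A))
}

#' Evaluate a radius to endfoot-area relation
#'
#' @param r_o Outer sheath radius (um), vectorized.
#' @param relation An [area_relation()].
#' @param extrapolate Allow evaluation outside the validity range.
#' @return Mean endfoot area(s) in um^2.
#' @export
mean_endfoot_area <- function(r_o, relation = area_relation("arterial"),
                              extrapolate = FALSE) {
  stopifnot(inherits(relation, "area_relation"))
  rng <- relation$valid_radius_range
  if (!extrapolate && any(r_o < rng[1] | r_o > rng[2])) {
    abort(sprintf(
      "r_o outside the validity range [%.3g, %.3g] um; set `extrapolate = TRUE` to force.",
      rng[1], rng[2]
    ))
  }
  p <- if (relation$form == "quadratic") 2 else 1
  relation$coefficients[1] + relation$coefficients[2] * r_o^p
}

#' @export
print.area_relation <- function(x, ...) {
  p <- if (x$form == "quadratic") "r^2" else "r"
  cat(sprintf(
    "<area_relation> %s (%s scale): A(r) = %.4g + %.4g %s um^2, r in [%.3g, %.3g] um\n",
    x$vessel_kind, if (x$corrected) "corrected" else "measured",
    x$coefficients[1], x$coefficients[2], p,
    x$valid_radius_range[1], x$valid_radius_range[2]
  ))
  invisible(x)
}

#' Empirical gap-fraction versus radius fits
#'
#' Three-parameter exponential decay `phi_g(r_o) = c1 exp(-c2 r_o) + c3`
#' summarizing how the simulated gap area fraction falls with vessel
#' caliber at fixed 20 nm gap width. The packaged default coefficients are
#' the model calibration for arterial
#' (`0.00704 exp(-0.1668 r) + 0.00124`, r in 2.5-15 um) and venous
#' vessels (`0.00468 exp(-0.0716 r) + 0.00226`, r in 2.5-20 um).
#'
#' @param vessel_kind `"arterial"` or `"venous"`.
#' @param c1,c2,c3 Optional coefficient overrides (all > 0).
#' @param valid_radius_range Radius range (um) over which the fit holds.
#' @return A `gap_fraction_fit` object.
#' @examples
#' eval_gap_fraction(2.9, gap_fraction_fit("arterial"))  # ~0.0056
#' @export
gap_fraction_fit <- function(vessel_kind = c("arterial", "venous"),
                             c1 = NULL, c2 = NULL, c3 = NULL,
                             valid_radius_range = NULL) {
  vessel_kind <- match.arg(vessel_kind)
  defaults <- if (vessel_kind == "arterial") {
    list(c1 = 0.00704, c2 = 0.1668, c3 = 0.00124, range = c(2.5, 15))
  } else {
    list(c1 = 0.00468, c2 = 0.0716, c3 = 0.00226, range = c(2.5, 20))
  }
  c1 <- c1 %||% defaults$c1
  c2 <- c2 %||% defaults$c2
  c3 <- c3 %||% defaults$c3
  if (any(c(c1, c2, c3) <= 0)) abort("coefficients c1, c2, c3 must all be positive.")
  structure(
    list(vessel_kind = vessel_kind, c1 = c1, c2 = c2, c3 = c3,
         valid_radius_range = valid_radius_range %||% defaults$range),
    class = "gap_fraction_fit"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate a gap-fraction fit
#'
#' @param r_o Outer sheath radius (um), vectorized.
#' @param fit A [gap_fraction_fit()].
#' @param extrapolate Allow radii outside the fit range (the exponential is
#'   well behaved, tending to `c3` for large radii).
#' @return Gap area fraction(s), dimensionless.
#' @export
eval_gap_fraction <- function(r_o, fit, extrapolate = FALSE) {
  stopifnot(inherits(fit, "gap_fraction_fit"))
  rng <- fit$valid_radius_range
  if (!extrapolate && any(r_o < rng[1] | r_o > rng[2])) {
    abort(sprintf(
      "r_o outside the fit range [%.3g, %.3g] um; set `extrapolate = TRUE` to force.",
      rng[1], rng[2]
    ))
  }
  fit$c1 * exp(-fit$c2 * r_o) + fit$c3
}

#' @export
print.gap_fraction_fit <- function(x, ...) {
  cat(sprintf(
    "<gap_fraction_fit> %s: phi(r) = %.4g exp(-%.4g r) + %.4g, r in [%.3g, %.3g] um\n",
    x$vessel_kind, x$c1, x$c2, x$c3,
    x$valid_radius_range[1], x$valid_radius_range[2]
  ))
  invisible(x)
}

#' @describeIn gap_fraction_fit Coefficients as a one-row tibble.
#' @param x A `gap_fraction_fit`.
#' @param ... Unused.
#' @export
tidy.gap_fraction_fit <- function(x, ...) {
  tibble(vessel_kind = x$vessel_kind, c1 = x$c1, c2 = x$c2, c3 = x$c3,
         r_min = x$valid_radius_range[1], r_max = x$valid_radius_range[2])
}

#' Fit the exponential gap-fraction model to samples
#'
#' Least-squares fit of `phi = c1 exp(-c2 r) + c3` to `(r_o, phi_g)`
#' samples, e.g. per-realization simulation output across radii.
#'
#' @param data Tibble/data frame with columns `r_o` (um) and `phi_g`.
#' @param vessel_kind Label stored on the resulting fit.
#' @return A `gap_fraction_fit` with an added `residual_norm` field (RMS
#'   residual of the fit).
#' @export
fit_gap_fraction_model <- function(data, vessel_kind = c("arterial", "venous")) {
  vessel_kind <- match.arg(vessel_kind)
  if (!all(c("r_o", "phi_g") %in% names(data))) {
    abort("`data` needs columns `r_o` and `phi_g`.")
  }
  if (length(unique(data$r_o)) < 4) abort("need samples at >= 4 distinct radii.")
  c3_0 <- max(min(data$phi_g), 1e-6)
  c1_0 <- max(max(data$phi_g) - c3_0, 1e-6)
  fit <- minpack.lm::nlsLM(
    phi_g ~ c1 * exp(-c2 * r_o) + c3,
    data = data,
    start = list(c1 = c1_0, c2 = 0.1, c3 = c3_0),
    lower = c(1e-8, 1e-4, 1e-8),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  cf <- coef(fit)
  out <- gap_fraction_fit(vessel_kind, c1 = cf[["c1"]], c2 = cf[["c2"]],
                          c3 = cf[["c3"]],
                          valid_radius_range = range(data$r_o))
  out$residual_norm <- sqrt(mean(stats::residuals(fit)^2))
  out
}

#' Simulate gap fractions across the vascular tree
#'
#' Sweeps vessel radii, derives the mean endfoot area at each radius from
#' an [area_relation()], simulates hard-core Voronoi sheath realizations
#' and records the per-realization gap area fraction. The output feeds
#' [fit_gap_fraction_model()] to re-derive the exponential radius
#' relations from scratch.
#'
#' @param vessel_kind `"arterial"` or `"venous"` (selects the default area
#'   relation and fit range).
#' @param radii Radii to sweep (um); default 10 radii across the fit range.
#' @param n_per_radius Realizations per radius.
#' @param d_g Gap width (um).
#' @param seed Base seed; realization seeds are derived per radius.
#' @param relation Override the [area_relation()].
#' @param n_cells_target Cells per realization (domain length rule).
#' @return A tibble (`vessel_kind`, `r_o`, `mean_area`, `realization`,
#'   `phi_g`, `phi_perp`, `gaps_per_ring`).
#' @export
simulate_gap_fraction_profile <- function(vessel_kind = c("arterial", "venous"),
                                          radii = NULL, n_per_radius = 20,
                                          d_g = 0.02, seed = 1,
                                          relation = NULL,
                                          n_cells_target = 500) {
  vessel_kind <- match.arg(vessel_kind)
  fit0 <- gap_fraction_fit(vessel_kind)
  radii <- radii %||% seq(fit0$valid_radius_range[1],
                          fit0$valid_radius_range[2], length.out = 10)
  relation <- relation %||% area_relation(vessel_kind)

  purrr::imap_dfr(radii, function(r, j) {
    A <- mean_endfoot_area(r, relation, extrapolate = TRUE)
    sim <- simulate_sheath(
      r_o = r, mean_area = A, d_g = d_g, n_realizations = n_per_radius,
      seed = seed + (j - 1) * n_per_radius,
      L = n_cells_target * A / (2 * pi * r), keep_areas = FALSE
    )
    tibble(vessel_kind = vessel_kind, r_o = r, mean_area = A,
           realization = sim$realization, phi_g = sim$phi_g,
           phi_perp = sim$phi_perp, gaps_per_ring = sim$gaps_per_ring)
  })
}

#' Serialize relations and fits to a config list
#'
#' Round-trippable plain-list (YAML/JSON ready) representation of an
#' [area_relation()] or [gap_fraction_fit()].
#'
#' @param x The object to serialize.
#' @return A named list.
#' @export
relation_config <- function(x) {
  if (inherits(x, "area_relation")) {
    list(type = "area_relation", vessel_kind = x$vessel_kind, form = x$form,
         coefficients = as.numeric(x$coefficients),
         valid_radius_range = as.numeric(x$valid_radius_range),
         corrected = x$corrected)
  } else if (inherits(x, "gap_fraction_fit")) {
    list(type = "gap_fraction_fit", vessel_kind = x$vessel_kind,
         coefficients = c(c1 = x$c1, c2 = x$c2, c3 = x$c3),
         valid_radius_range = as.numeric(x$valid_radius_range))
  } else {
    abort("`x` must be an area_relation or gap_fraction_fit.")
  }
}
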