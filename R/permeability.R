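#' Inter-endfoot gap geometry
#'
#' Geometry of the extra-cellular pathway through the endfoot sheath:
#' * `d_g_nm` — inter-endfoot gap width (default 20 nm, electron
#'   microscopy value for cortical capillaries);
#' * `h_es_um` — endfoot sheath thickness;
#' * `l_g_um` — tortuous gap path length; endfoot overlap makes the path
#'   longer than the sheath is thick, `l_g >= h_ES`, and the default
#'   coupling is `l_g = 1.5 * h_ES` (the capillary ratio 0.45/0.3 um,
#'   extrapolated linearly);
#' * `alpha` — obstruction/hindrance factor in `[0, 1]` (1 = free
#'   diffusion of small solutes; see [renkin_hindrance()]).
#'
#' @param d_g_nm Gap width in nanometres.
#' @param h_es_um Sheath thickness in micrometres.
#' @param l_g_um Gap path length in micrometres; default `1.5 * h_es_um`.
#' @param alpha Hindrance factor in `[0, 1]`.
#' @return A `gap_geometry` object (also carries SI fields `d_g_m`,
#'   `l_g_m`).
#' @export
gap_geometry <- function(d_g_nm = 20, h_es_um = 1, l_g_um = 1.5 * h_es_um,
                         alpha = 1) {
  if (d_g_nm <= 0) abort("`d_g_nm` must be positive.")
  if (h_es_um <= 0 || l_g_um <= 0) abort("thickness and gap length must be positive.")
  if (l_g_um < h_es_um - 1e-12) {
    abort("`l_g_um` must be >= `h_es_um` (overlap can only lengthen the path).")
  }
  if (alpha < 0 || alpha > 1) abort("`alpha` must lie in [0, 1].")
  structure(
    list(d_g_nm = d_g_nm, h_es_um = h_es_um, l_g_um = l_g_um, alpha = alpha,
         d_g_m = d_g_nm * 1e-9, l_g_m = l_g_um * 1e-6),
    class = "gap_geometry"
  )
}

#' Fluid properties
#'
#' @param mu Dynamic viscosity in Pa s (default `0.7e-3`, water at 37 C).
#' @param D Free binary diffusion coefficient in m^2/s (default `1e-9`,
#'   typical small solute in aqueous solution).
#' @return A `fluid_properties` object.
#' @export
fluid_properties <- function(mu = 0.7e-3, D = 1e-9) {
  if (mu <= 0 || D <= 0) abort("`mu` and `D` must be positive.")
  structure(list(mu = mu, D = D), class = "fluid_properties")
}

#' Hydraulic gap transmissibility (parallel-plate model)
#'
#' `t_g = d_g^3 / (12 mu l_g)`: laminar no-slip flow between parallel
#' plates a gap width apart, over the tortuous path length.
#'
#' @param gap A [gap_geometry()].
#' @param fluid A [fluid_properties()].
#' @return Transmissibility in m^3 Pa^-1 s^-1 per unit gap length.
#' @export
gap_transmissibility <- function(gap = gap_geometry(), fluid = fluid_properties()) {
  stopifnot(inherits(gap, "gap_geometry"), inherits(fluid, "fluid_properties"))
  gap$d_g_m^3 / (12 * fluid$mu * gap$l_g_m)
}

#' Filtration coefficient of the endfoot sheath
#'
#' `L_p = phi_g * t_g / d_g = phi_g * d_g^2 / (12 mu l_g)`: the volumetric
#' water flux across the sheath per unit area and unit pressure drop
#' (m Pa^-1 s^-1). Scales with the cube of the gap width at fixed
#' tessellation geometry (one power through `phi_g`, two through `t_g`).
#'
#' @param phi_g Gap area fraction in `[0, 1)`, vectorized.
#' @param gap A [gap_geometry()].
#' @param fluid A [fluid_properties()].
#' @return Filtration coefficient(s) in m Pa^-1 s^-1.
#' @examples
#' filtration_coefficient(0.0056, gap_geometry(h_es_um = 1))  # ~1.8e-10
#' @export
filtration_coefficient <- function(phi_g, gap = gap_geometry(),
                                   fluid = fluid_properties()) {
  check_phi(phi_g)
  phi_g * gap$d_g_m^2 / (12 * fluid$mu * gap$l_g_m)
}

#' Diffusion membrane coefficient of the endfoot sheath
#'
#' `C_M = alpha * phi_g / l_g` (m^-1): the geometric factor such that the
#' diffusive flux across the sheath is `C_M * D * delta_c`.
#'
#' @inheritParams filtration_coefficient
#' @return Diffusion membrane coefficient(s) in m^-1.
#' @examples
#' membrane_diffusion_coefficient(0.00588, gap_geometry(h_es_um = 1, l_g_um = 1))
#' @export
membrane_diffusion_coefficient <- function(phi_g, gap = gap_geometry()) {
  check_phi(phi_g)
  gap$alpha * phi_g / gap$l_g_m
}

check_phi <- function(phi_g) {
  if (any(phi_g < 0 | phi_g >= 1)) abort("`phi_g` must lie in [0, 1).")
  invisible(phi_g)
}

#' Transmembrane fluxes across a vessel segment's sheath
#'
#' Diffusive flux `F_D = C_M * D * delta_c` (per unit area) and volumetric
#' filtration rate `Q = S * L_p * delta_p`, together with the diffusion
#' capacity `S * C_M * D` and filtration capacity `S * L_p`.
#'
#' @param C_M Diffusion membrane coefficient (m^-1).
#' @param L_p Filtration coefficient (m Pa^-1 s^-1).
#' @param S Sheath surface area (m^2); for a tubular segment
#'   `S = 2 pi r_v l_v`.
#' @param D Free diffusion coefficient (m^2/s).
#' @param delta_c Concentration drop across the sheath (mol m^-3).
#' @param delta_p Pressure drop across the sheath (Pa).
#' @return A one-row tibble: `F_D` (mol m^-2 s^-1), `Q` (m^3 s^-1),
#'   `diffusion_capacity` (m^3 s^-1... i.e. `S * C_M * D`, m^3/s per unit
#'   concentration), `filtration_capacity` (`S * L_p`, m^3 Pa^-1 s^-1).
#' @export
transmembrane_fluxes <- function(C_M, L_p, S, D = 1e-9, delta_c = 0,
                                 delta_p = 0) {
  if (any(S < 0)) abort("`S` must be non-negative.")
  tibble(
    F_D = C_M * D * delta_c,
    Q = S * L_p * delta_p,
    diffusion_capacity = S * C_M * D,
    filtration_capacity = S * L_p
  )
}

#' Renkin hindrance factor for a narrow gap
#'
#' Classical steric-exclusion and restricted-diffusion correction for a
#' solute of hydrodynamic diameter a fraction `lambda` of the gap width:
#' `alpha = (1 - lambda)^2 (1 - 2.104 lambda + 2.09 lambda^3 - 0.95
#' lambda^5)`, clamped to `[0, 1]`. `alpha = 1` for point solutes and 0
#' for solutes as large as the gap.
#'
#' @param lambda_ratio Solute diameter / gap width, in `[0, 1]`,
#'   vectorized.
#' @param coefficients Polynomial coefficients `(c1, c3, c5)` of the
#'   mobility factor, exposed for sensitivity analyses.
#' @return Hindrance factor(s) in `[0, 1]`.
#' @examples
#' renkin_hindrance(0.1)  # ~0.641
#' @export
renkin_hindrance <- function(lambda_ratio,
                             coefficients = c(2.104, 2.09, 0.95)) {
  if (any(lambda_ratio < 0 | lambda_ratio > 1)) {
    abort("`lambda_ratio` must lie in [0, 1].")
  }
  l <- lambda_ratio
  a <- (1 - l)^2 *
    (1 - coefficients[1] * l + coefficients[2] * l^3 - coefficients[3] * l^5)
  pmin(pmax(a, 0), 1)
}

#' Gap Peclet number
#'
#' `Pe_g = delta_p * d_g^2 / (12 mu alpha D)`: ratio of advective to
#' diffusive transport through an inter-endfoot gap, using the gap path
#' length as the characteristic length (it cancels between the
#' parallel-plate velocity and the diffusion time). Values well below 1
#' mean diffusion-dominated exchange.
#'
#' @param delta_p Pressure drop across the sheath (Pa), vectorized.
#' @param gap A [gap_geometry()] (uses `d_g` and `alpha`; `alpha` > 0).
#' @param fluid A [fluid_properties()] (`D` > 0).
#' @return Peclet number(s), dimensionless.
#' @examples
#' peclet_number(100)  # ~4.8e-3 for 20 nm gaps and D = 1e-9
#' @export
peclet_number <- function(delta_p, gap = gap_geometry(),
                          fluid = fluid_properties()) {
  stopifnot(inherits(gap, "gap_geometry"), inherits(fluid, "fluid_properties"))
  if (gap$alpha <= 0) abort("`alpha` must be positive for a Peclet number.")
  delta_p * gap$d_g_m^2 / (12 * fluid$mu * gap$alpha * fluid$D)
}

#' Sheath geometry from the vessel lumen radius
#'
#' Structural relations linking the lumen radius `r_v` (excluding
#' perivascular structures) to the endfoot sheath geometry:
#' * sheath thickness `h_ES = 1 + 0.15 (r_v - 3)` um, clamped below at
#'   1 um so small capillaries stay within the observed 1-2.5 um in-vivo
#'   range;
#' * gap path length `l_g = 1.5 * h_ES`;
#' * outer sheath radius `r_o = 1.3 r_v + 1.5` for `r_v >= 3` um (a
#'   smooth-muscle/pericyte layer of thickness ~`h_ES` appears between
#'   endothelium and sheath on larger vessels) and
#'   `r_o = 1.15 r_v + 0.95` below; both include a 0.4 um
#'   endothelium-plus-basement-membrane allowance. The jump at
#'   `r_v = 3` um is a genuine anatomical discontinuity and is not
#'   smoothed.
#'
#' @param r_v Lumen radius (um), vectorized, > 0.
#' @return A tibble: `r_v`, `h_es_um`, `l_g_um`, `r_o`.
#' @examples
#' sheath_geometry_from_lumen(c(2, 3, 10))
#' @export
sheath_geometry_from_lumen <- function(r_v) {
  if (any(r_v <= 0)) abort("`r_v` must be positive.")
  h_es <- pmax(1, 1 + 0.15 * (r_v - 3))
  tibble(
    r_v = r_v,
    h_es_um = h_es,
    l_g_um = 1.5 * h_es,
    r_o = ifelse(r_v >= 3, 1.3 * r_v + 1.5, 1.15 * r_v + 0.95)
  )
}

#' Transport-coefficient table over lumen radii
#'
#' Convenience sweep: for each lumen radius, derives the sheath geometry,
#' evaluates the gap-fraction fit of the requested vessel kind at `r_o`,
#' and computes `L_p` and `C_M`.
#'
#' @param r_v Lumen radii (um).
#' @param vessel_kind `"arterial"` or `"venous"` fit for `phi_g(r_o)`.
#' @param d_g_nm Gap width (nm).
#' @param mu Viscosity (Pa s).
#' @param alpha Hindrance factor.
#' @param extrapolate Passed to [eval_gap_fraction()].
#' @return A tibble: `r_v`, `r_o`, `h_es_um`, `l_g_um`, `phi_g`, `L_p`,
#'   `C_M`.
#' @export
vessel_coefficient_table <- function(r_v, vessel_kind = c("arterial", "venous"),
                                     d_g_nm = 20, mu = 0.7e-3, alpha = 1,
                                     extrapolate = FALSE) {
  vessel_kind <- match.arg(vessel_kind)
  geo <- sheath_geometry_from_lumen(r_v)
  fit <- gap_fraction_fit(vessel_kind)
  phi <- eval_gap_fraction(geo$r_o, fit, extrapolate = extrapolate)
  lp <- cm <- numeric(nrow(geo))
  for (i in seq_len(nrow(geo))) {
    g <- gap_geometry(d_g_nm = d_g_nm, h_es_um = geo$h_es_um[i],
                      l_g_um = geo$l_g_um[i], alpha = alpha)
    lp[i] <- filtration_coefficient(phi[i], g, fluid_properties(mu = mu))
    cm[i] <- membrane_diffusion_coefficient(phi[i], g)
  }
  mutate(geo, phi_g = phi, L_p = lp, C_M = cm)
}
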