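#' Map transport coefficients onto network segments
#'
#' For every segment: outer sheath radius and gap geometry from the lumen
#' radius ([sheath_geometry_from_lumen()]), gap area fraction from the
#' exponential radius fit of the segment's pressure label (arterial
#' segments use the arterial fit, venous the venous fit; capillaries use
#' the fit of their pressure label), then `L_p`, `C_M` and the outer
#' (sheath) surface area `S = 2 pi r_o l_v`.
#'
#' @param net A `vascular_network`.
#' @param labels A [classify_segments()] table.
#' @param d_g_nm Gap width (nm).
#' @param mu Water viscosity for `L_p` (Pa s).
#' @param alpha Hindrance factor for `C_M`.
#' @param arterial_fit,venous_fit [gap_fraction_fit()]s to evaluate.
#' @return A tibble: `segment`, `from`, `to`, `r_v`, `length`, `label`,
#'   `category`, `pressure`, `r_o`, `h_es_um`, `l_g_um`, `phi_g`, `L_p`
#'   (m Pa^-1 s^-1), `C_M` (m^-1), `S` (m^2), `S_lumen` (m^2).
#' @export
network_coefficients <- function(net, labels, d_g_nm = 20, mu = 0.7e-3,
                                 alpha = 1,
                                 arterial_fit = gap_fraction_fit("arterial"),
                                 venous_fit = gap_fraction_fit("venous")) {
  stopifnot(inherits(net, "vascular_network"))
  segs <- net$segments %>%
    left_join(labels[, c("segment", "label", "category", "pressure")],
              by = "segment")
  geo <- sheath_geometry_from_lumen(segs$r_v)
  phi <- ifelse(
    segs$label == "arterial",
    eval_gap_fraction(geo$r_o, arterial_fit, extrapolate = TRUE),
    eval_gap_fraction(geo$r_o, venous_fit, extrapolate = TRUE)
  )
  lg_m <- geo$l_g_um * 1e-6
  d_m <- d_g_nm * 1e-9
  segs %>%
    mutate(
      r_o = geo$r_o, h_es_um = geo$h_es_um, l_g_um = geo$l_g_um,
      phi_g = phi,
      L_p = phi * d_m^2 / (12 * mu * lg_m),
      C_M = alpha * phi / lg_m,
      S = 2 * pi * (geo$r_o * 1e-6) * (.data$length * 1e-6),
      S_lumen = 2 * pi * (.data$r_v * 1e-6) * (.data$length * 1e-6)
    )
}

#' Depth-layer aggregation of transport capacity
#'
#' Splits the network into 6 vertically stacked analysis layers (layer 0
#' nearest the cortical surface; 200 um thick, 100 um for layer 5) and
#' aggregates, per layer and vessel category (A/V/C): total sheath
#' surface `sum(S)`, filtration capacity `sum(S * L_p)`, diffusion
#' capacity `sum(S * C_M)` and surface-area-weighted means of `r_v`,
#' `r_o`, `L_p`, `C_M`. Segments are assigned to layers by the depth of
#' their midpoint. Empty layer/category combinations are kept with zero
#' surface and `NA` averages.
#'
#' @param net A `vascular_network`.
#' @param coeffs A [network_coefficients()] table.
#' @param layer_breaks_um Depth breaks (um); default
#'   `c(0, 200, 400, 600, 800, 1000, 1100)`.
#' @return A list: `layers` (per layer x category tibble), `network`
#'   (per-category and overall totals with surface-weighted means),
#'   class `layer_summary`.
#' @export
summarize_layers <- function(net, coeffs,
                             layer_breaks_um = c(0, 200, 400, 600, 800,
                                                 1000, 1100)) {
  stopifnot(inherits(net, "vascular_network"))
  pos <- net$nodes %>% select("node", "z")
  seg_depth <- coeffs %>%
    left_join(pos, by = c(from = "node")) %>%
    left_join(pos, by = c(to = "node"), suffix = c("_a", "_b")) %>%
    mutate(depth = (.data$z_a + .data$z_b) / 2)
  if (any(seg_depth$depth < min(layer_breaks_um) |
            seg_depth$depth > max(layer_breaks_um))) {
    abort("segments outside the depth range of `layer_breaks_um`.")
  }
  nlay <- length(layer_breaks_um) - 1
  seg_depth <- seg_depth %>%
    mutate(layer = pmin(
      findInterval(.data$depth, layer_breaks_um, rightmost.closed = TRUE) - 1,
      nlay - 1
    ))

  grid <- tidyr::expand_grid(layer = 0:(nlay - 1), category = c("A", "V", "C"))
  layers <- seg_depth %>%
    group_by(.data$layer, .data$category) %>%
    summarise(
      n_segments = dplyr::n(),
      surface_m2 = sum(.data$S),
      filtration_capacity = sum(.data$S * .data$L_p),
      diffusion_capacity = sum(.data$S * .data$C_M),
      mean_r_v = sum(.data$S * .data$r_v) / sum(.data$S),
      mean_r_o = sum(.data$S * .data$r_o) / sum(.data$S),
      mean_L_p = sum(.data$S * .data$L_p) / sum(.data$S),
      mean_C_M = sum(.data$S * .data$C_M) / sum(.data$S),
      .groups = "drop"
    ) %>%
    dplyr::right_join(grid, by = c("layer", "category")) %>%
    mutate(
      n_segments = tidyr::replace_na(.data$n_segments, 0L),
      surface_m2 = tidyr::replace_na(.data$surface_m2, 0),
      filtration_capacity = tidyr::replace_na(.data$filtration_capacity, 0),
      diffusion_capacity = tidyr::replace_na(.data$diffusion_capacity, 0),
      depth_from_um = layer_breaks_um[.data$layer + 1],
      depth_to_um = layer_breaks_um[.data$layer + 2]
    ) %>%
    arrange(.data$layer, .data$category)

  network <- seg_depth %>%
    group_by(.data$category) %>%
    summarise(
      n_segments = dplyr::n(),
      surface_m2 = sum(.data$S),
      filtration_capacity = sum(.data$S * .data$L_p),
      diffusion_capacity = sum(.data$S * .data$C_M),
      mean_L_p = sum(.data$S * .data$L_p) / sum(.data$S),
      mean_C_M = sum(.data$S * .data$C_M) / sum(.data$S),
      .groups = "drop"
    ) %>%
    bind_rows(
      seg_depth %>% summarise(
        category = "all", n_segments = dplyr::n(), surface_m2 = sum(.data$S),
        filtration_capacity = sum(.data$S * .data$L_p),
        diffusion_capacity = sum(.data$S * .data$C_M),
        mean_L_p = sum(.data$S * .data$L_p) / sum(.data$S),
        mean_C_M = sum(.data$S * .data$C_M) / sum(.data$S)
      )
    )

  structure(list(layers = layers, network = network,
                 layer_breaks_um = layer_breaks_um),
            class = "layer_summary")
}

#' @export
print.layer_summary <- function(x, ...) {
  cat("<layer_summary>\n")
  print(x$network)
  invisible(x)
}

#' @describeIn summarize_layers Per-layer tibble.
#' @param x A `layer_summary`.
#' @param ... Unused.
#' @export
tidy.layer_summary <- function(x, ...) x$layers

#' Whole-network geometric summary
#'
#' Cylindrical-segment totals in the style of a network characterization
#' table: per-category and total sheath surface area, bounding-box
#' volume, outer and lumen vessel volume fractions (`zeta`, `zeta_L`) and
#' surface-to-volume ratios (outer and lumen).
#'
#' @param net A `vascular_network`.
#' @param coeffs A [network_coefficients()] table.
#' @return A one-row tibble with fields `S_C`, `S_A`, `S_V`, `S_total`
#'   (m^2), `volume_m3`, `zeta`, `zeta_L`, `S_over_V`, `S_lumen_over_V`
#'   (m^2/m^3).
#' @export
network_summary <- function(net, coeffs) {
  V <- network_volume(net) * 1e-18 # um^3 -> m^3
  vol_outer <- sum(pi * (coeffs$r_o * 1e-6)^2 * coeffs$length * 1e-6)
  vol_lumen <- sum(pi * (coeffs$r_v * 1e-6)^2 * coeffs$length * 1e-6)
  s_cat <- function(cat) sum(coeffs$S[coeffs$category == cat])
  tibble(
    S_C = s_cat("C"), S_A = s_cat("A"), S_V = s_cat("V"),
    S_total = sum(coeffs$S),
    S_lumen_total = sum(coeffs$S_lumen),
    volume_m3 = V,
    zeta = vol_outer / V,
    zeta_L = vol_lumen / V,
    S_over_V = sum(coeffs$S) / V,
    S_lumen_over_V = sum(coeffs$S_lumen) / V
  )
}

#' Endfoot counts around network vessels
#'
#' Divides each segment's sheath surface by the mean endfoot area at its
#' outer radius (arterial segments use the arterial area relation, venous
#' and capillary segments the relation of their pressure label) and sums
#' per category. With an astrocyte density, also reports endfoot
#' processes per astrocyte in the sampled tissue block.
#'
#' @param net A `vascular_network`.
#' @param coeffs A [network_coefficients()] table.
#' @param arterial_relation,venous_relation Corrected [area_relation()]s.
#' @param astrocyte_density_mm3 Astrocytes per mm^3 (optional; must be
#'   positive when supplied).
#' @return A list: `by_category` tibble (`category`, `n_endfeet`,
#'   `density_per_mm2`), `total_endfeet`, and (when density given)
#'   `n_astrocytes`, `endfeet_per_astrocyte`.
#' @export
endfoot_counts <- function(net, coeffs,
                           arterial_relation = area_relation("arterial"),
                           venous_relation = area_relation("venous"),
                           astrocyte_density_mm3 = NULL) {
  A_um2 <- ifelse(
    coeffs$label == "arterial",
    mean_endfoot_area(coeffs$r_o, arterial_relation, extrapolate = TRUE),
    mean_endfoot_area(coeffs$r_o, venous_relation, extrapolate = TRUE)
  )
  n_seg <- coeffs$S / (A_um2 * 1e-12)
  by_cat <- tibble(category = coeffs$category, n = n_seg, S = coeffs$S) %>%
    group_by(.data$category) %>%
    summarise(n_endfeet = sum(.data$n),
              density_per_mm2 = sum(.data$n) / (sum(.data$S) * 1e6),
              .groups = "drop")
  out <- list(by_category = by_cat, total_endfeet = sum(n_seg))
  if (!is.null(astrocyte_density_mm3)) {
    if (astrocyte_density_mm3 <= 0) abort("`astrocyte_density_mm3` must be positive.")
    V_mm3 <- network_volume(net) * 1e-9 # um^3 -> mm^3
    out$n_astrocytes <- astrocyte_density_mm3 * V_mm3
    out$endfeet_per_astrocyte <- out$total_endfeet / out$n_astrocytes
  }
  out
}
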