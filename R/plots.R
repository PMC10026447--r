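#' Plot an endfoot tessellation
#'
#' Draws the periodic Voronoi cells on the unrolled vessel surface,
#' optionally with their generator points.
#'
#' @param object An `endfoot_tessellation` (built with polygons).
#' @param show_generators Overlay generator points.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.endfoot_tessellation <- function(object, show_generators = TRUE,
                                          ...) {
  if (is.null(object$polygons)) abort("tessellation was built with `keep_polygons = FALSE`.")
  df <- purrr::imap_dfr(object$polygons, function(m, i) {
    tibble(cell = i, u = m[, "u"], z = m[, "z"])
  })
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$u, y = .data$z,
                                        group = .data$cell)) +
    ggplot2::geom_polygon(fill = "grey92", colour = "grey25",
                          linewidth = 0.3) +
    ggplot2::coord_fixed(xlim = c(0, object$domain$width),
                         ylim = c(0, object$domain$L)) +
    ggplot2::labs(
      x = "circumferential position u (µm)",
      y = "axial position z (µm)",
      title = sprintf("Endfoot tessellation, r_o = %.3g µm",
                      object$domain$r_o)
    ) +
    ggplot2::theme_minimal()
  if (show_generators) {
    p <- p + ggplot2::geom_point(
      data = object$cells, ggplot2::aes(x = .data$u, y = .data$z),
      inherit.aes = FALSE, size = 0.6, colour = "firebrick"
    )
  }
  p
}

#' Plot simulated gap fractions against the exponential fit
#'
#' @param samples Output of [simulate_gap_fraction_profile()].
#' @param fit Optional [gap_fraction_fit()] curve(s) to overlay; defaults
#'   to the packaged calibration of each vessel kind present.
#' @return A ggplot object.
#' @export
plot_gap_fraction_profile <- function(samples, fit = NULL) {
  kinds <- unique(samples$vessel_kind)
  fits <- if (is.null(fit)) lapply(kinds, gap_fraction_fit) else list(fit)
  curve_df <- purrr::map_dfr(fits, function(f) {
    r <- seq(f$valid_radius_range[1], f$valid_radius_range[2],
             length.out = 100)
    tibble(vessel_kind = f$vessel_kind, r_o = r,
           phi_g = eval_gap_fraction(r, f))
  })
  ggplot2::ggplot(samples, ggplot2::aes(x = .data$r_o, y = .data$phi_g,
                                        colour = .data$vessel_kind)) +
    ggplot2::geom_point(alpha = 0.25, size = 0.7) +
    ggplot2::geom_line(data = curve_df, linewidth = 0.8) +
    ggplot2::labs(x = "outer sheath radius r_o (µm)",
                  y = "gap area fraction φ_g",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot layer-resolved transport capacity
#'
#' @param object A [summarize_layers()] result.
#' @param ... Unused.
#' @return A ggplot object (filtration capacity per layer and category).
#' @export
autoplot.layer_summary <- function(object, ...) {
  df <- object$layers %>%
    mutate(depth_mid = (.data$depth_from_um + .data$depth_to_um) / 2)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$depth_mid,
                                   y = .data$filtration_capacity,
                                   colour = .data$category)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "cortical depth (µm)",
                  y = "filtration capacity Σ S·L_p (m³ Pa⁻¹ s⁻¹)",
                  colour = "category") +
    ggplot2::theme_minimal()
}
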