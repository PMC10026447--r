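#' Apparent blood viscosity in microvessels
#'
#' Empirical diameter- and hematocrit-dependent apparent viscosity laws
#' for blood flowing in narrow tubes, with the tube diameter rescaled by
#' `(rbc_reference_volume / rbc_volume)^(1/3)` to transfer the (human red
#' blood cell) parameterization to other species (default: mouse cells of
#' 55 fL against a 92 fL human reference).
#'
#' * `"invivo"` (default): the in-vivo formulation including the
#'   endothelial surface layer correction `(D / (D - 1.1))^2`;
#' * `"invitro"`: the in-vitro tube-flow law (no wall correction; exactly
#'   1 at zero hematocrit);
#' * `"constant"`: returns `constant_viscosity_pa_s / plasma_viscosity`
#'   as relative viscosity regardless of diameter.
#'
#' @param diameter_um Lumen diameter (um), vectorized, > 0.
#' @param hematocrit Discharge (tube) hematocrit in `[0, 1)`; default
#'   0.45.
#' @param law `"invivo"`, `"invitro"` or `"constant"`.
#' @param rbc_volume_fl Red-blood-cell volume of the modelled species
#'   (fL).
#' @param rbc_reference_volume_fl Reference cell volume of the law's
#'   calibration (fL).
#' @param plasma_viscosity_pa_s Plasma viscosity (Pa s) used to convert
#'   relative to absolute viscosity.
#' @param constant_viscosity_pa_s Absolute viscosity for the fallback law.
#' @param relative Return relative (plasma-normalized) viscosity instead
#'   of absolute Pa s.
#' @return Apparent viscosity (Pa s, or relative if `relative = TRUE`).
#' @examples
#' apparent_viscosity(6, law = "invivo")
#' apparent_viscosity(6, hematocrit = 0, law = "invitro", relative = TRUE)  # 1
#' @export
apparent_viscosity <- function(diameter_um, hematocrit = 0.45,
                               law = c("invivo", "invitro", "constant"),
                               rbc_volume_fl = 55,
                               rbc_reference_volume_fl = 92,
                               plasma_viscosity_pa_s = 1.2e-3,
                               constant_viscosity_pa_s = 1.2e-3,
                               relative = FALSE) {
  law <- match.arg(law)
  if (any(diameter_um <= 0)) abort("`diameter_um` must be positive.")
  if (hematocrit < 0 || hematocrit >= 1) abort("`hematocrit` must lie in [0, 1).")

  if (law == "constant") {
    mu_rel <- rep(constant_viscosity_pa_s / plasma_viscosity_pa_s,
                  length(diameter_um))
  } else {
    D <- diameter_um * (rbc_reference_volume_fl / rbc_volume_fl)^(1 / 3)
    C <- (0.8 + exp(-0.075 * D)) * (-1 + 1 / (1 + 1e-11 * D^12)) +
      1 / (1 + 1e-11 * D^12)
    fH <- if (hematocrit == 0) 0 else
      ((1 - hematocrit)^C - 1) / ((1 - 0.45)^C - 1)
    if (law == "invitro") {
      mu45 <- 220 * exp(-1.3 * D) + 3.2 - 2.44 * exp(-0.06 * D^0.645)
      mu_rel <- 1 + (mu45 - 1) * fH
    } else {
      mu45 <- 6 * exp(-0.085 * D) + 3.2 - 2.44 * exp(-0.06 * D^0.645)
      wall <- (D / (D - 1.1))^2
      mu_rel <- (1 + (mu45 - 1) * fH * wall) * wall
    }
  }
  if (relative) mu_rel else mu_rel * plasma_viscosity_pa_s
}

#' Solve Poiseuille pressures on a vascular network
#'
#' Assembles the nodal linear system of a Poiseuille-type network flow
#' (segment conductance `g = pi r_v^4 / (8 mu_app l_v)` in SI units,
#' filtration across the vessel wall neglected), applies the network's
#' pressure boundary conditions and solves for nodal pressures. Mass is
#' conserved at every interior node.
#'
#' @param net A `vascular_network` with at least two pressure boundary
#'   nodes (`pressure_bc` set on `nodes`).
#' @param viscosity_law Passed to [apparent_viscosity()].
#' @param hematocrit Discharge hematocrit for the viscosity law.
#' @param ... Further arguments for [apparent_viscosity()].
#' @return A `flow_solution`: list with `node_pressures` (tibble `node`,
#'   `pressure`), `segments` (tibble `segment`, `from`, `to`, `pressure`
#'   = segment mean, `flow` m^3/s signed from->to, `mu_app`,
#'   `conductance`), `max_imbalance` (relative mass defect at interior
#'   nodes), `boundary` (the BCs used).
#' @export
solve_pressures <- function(net, viscosity_law = "invivo", hematocrit = 0.45,
                            ...) {
  stopifnot(inherits(net, "vascular_network"))
  nodes <- net$nodes
  segs <- net$segments
  bc <- !is.na(nodes$pressure_bc)
  if (sum(bc) < 2) abort("need >= 2 nodes with pressure boundary conditions.")

  g_comp <- igraph::graph_from_data_frame(
    segs[, c("from", "to")], directed = FALSE,
    vertices = data.frame(name = nodes$node)
  )
  if (!igraph::is_connected(g_comp)) abort("network is disconnected; cannot solve.")

  mu_app <- apparent_viscosity(2 * segs$r_v, hematocrit = hematocrit,
                               law = viscosity_law, ...)
  cond <- pi * (segs$r_v * 1e-6)^4 / (8 * mu_app * segs$length * 1e-6)

  id <- match(c(segs$from, segs$to), nodes$node)
  i_from <- id[seq_len(nrow(segs))]
  i_to <- id[-seq_len(nrow(segs))]
  nn <- nrow(nodes)
  lap <- Matrix::sparseMatrix(
    i = c(i_from, i_to, i_from, i_to),
    j = c(i_to, i_from, i_from, i_to),
    x = c(-cond, -cond, cond, cond),
    dims = c(nn, nn)
  )

  p <- rep(NA_real_, nn)
  p[bc] <- nodes$pressure_bc[bc]
  free <- which(!bc)
  if (length(free) > 0) {
    rhs <- -(lap[free, bc, drop = FALSE] %*% p[bc])
    p[free] <- as.numeric(Matrix::solve(lap[free, free, drop = FALSE], rhs))
  }

  flow <- cond * (p[i_from] - p[i_to])
  imb <- as.numeric(lap %*% p)
  scale <- sum(abs(flow)) / 2 + .Machine$double.eps
  max_imbalance <- if (length(free) > 0) max(abs(imb[free])) / scale else 0

  structure(
    list(
      node_pressures = tibble(node = nodes$node, pressure = p),
      segments = tibble(
        segment = segs$segment, from = segs$from, to = segs$to,
        pressure = (p[i_from] + p[i_to]) / 2,
        flow = flow, mu_app = mu_app, conductance = cond
      ),
      max_imbalance = max_imbalance,
      boundary = nodes[bc, c("node", "kind", "pressure_bc")]
    ),
    class = "flow_solution"
  )
}

#' @export
print.flow_solution <- function(x, ...) {
  cat(sprintf(
    "<flow_solution> %d segments; pressure range [%.4g, %.4g] Pa; max interior imbalance %.2e\n",
    nrow(x$segments), min(x$node_pressures$pressure),
    max(x$node_pressures$pressure), x$max_imbalance
  ))
  invisible(x)
}

#' Classify segments into arterial and venous vessels
#'
#' A segment is arterial if its pressure (mean of its two node pressures)
#' strictly exceeds the unweighted mean pressure of all small segments
#' (`r_v <= 4.5` um), and venous otherwise. Capillaries are additionally
#' tagged as the reporting category for `r_v < 3` um; larger vessels take
#' their pressure label as category.
#'
#' @param net A `vascular_network`.
#' @param flow A [solve_pressures()] solution for `net`.
#' @param small_radius_um Radius cut for the reference pressure (4.5 um).
#' @param capillary_radius_um Radius cut for the capillary category
#'   (3 um).
#' @return A tibble: `segment`, `r_v`, `pressure`, `label`
#'   (arterial/venous), `category` (A/V/C).
#' @export
classify_segments <- function(net, flow, small_radius_um = 4.5,
                              capillary_radius_um = 3.0) {
  stopifnot(inherits(net, "vascular_network"), inherits(flow, "flow_solution"))
  segs <- net$segments %>%
    left_join(flow$segments[, c("segment", "pressure")], by = "segment")
  small <- segs$r_v <= small_radius_um
  if (!any(small)) abort("no segments with r_v <= small_radius_um to set the pressure threshold.")
  threshold <- mean(segs$pressure[small])
  label <- ifelse(segs$pressure > threshold, "arterial", "venous")
  tibble(
    segment = segs$segment, r_v = segs$r_v, pressure = segs$pressure,
    label = label,
    category = dplyr::case_when(
      segs$r_v < capillary_radius_um ~ "C",
      label == "arterial" ~ "A",
      TRUE ~ "V"
    ),
    pressure_threshold = threshold
  )
}
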