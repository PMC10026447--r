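#' Generate a synthetic cortical microvascular network
#'
#' Builds a labelled synthetic stand-in for a mouse-cortex microvascular
#' network: penetrating arterioles and venules descend from the cortical
#' surface (z = 0) through the full depth extent, tapering from their
#' surface radius towards 3 um, and are coupled into a jittered
#' capillary lattice (lumen radii 1.5-2.9 um) spanning the tissue block.
#' Arteriole top nodes are tagged as pressure inlets and venule top nodes
#' as outlets. The construction targets a capillary-dominated surface
#' area and a surface-to-volume ratio of order 1e4 m^2/m^3, the scale of
#' real cortical networks. The network is deterministic per seed.
#'
#' @param depth_um Depth extent of the block (default 1100 um).
#' @param lateral_um Lateral (x, y) extent (default 400 um).
#' @param capillary_spacing_um Capillary lattice spacing (default 75 um).
#' @param n_arterioles,n_venules Number of penetrating trees of each kind.
#' @param arteriole_top_radius_um,venule_top_radius_um Lumen radii at the
#'   surface; they taper linearly to 3 um at the bottom.
#' @param capillary_radius_range_um Range of capillary lumen radii.
#' @param edge_keep_fraction Fraction of lattice edges kept (pruning
#'   randomizes the mesh; connectivity is verified and re-tried).
#' @param inlet_pressure_pa,outlet_pressure_pa Boundary pressures.
#' @param jitter_fraction Node position jitter as a fraction of spacing.
#' @param seed Integer seed.
#'
#' @return A `vascular_network`: list with `nodes` (tibble: `node`, `x`,
#'   `y`, `z`, `kind` in interior/inlet/outlet, `pressure_bc`),
#'   `segments` (tibble: `segment`, `from`, `to`, `r_v`, `length`,
#'   `vessel_class` in penetrating_arteriole/penetrating_venule/capillary)
#'   and `metadata` (units, provenance = "synthetic", parameters).
#' @examples
#' net <- generate_synthetic_network(seed = 1)
#' nrow(net$segments)
#' @export
generate_synthetic_network <- function(depth_um = 1100, lateral_um = 400,
                                       capillary_spacing_um = 75,
                                       n_arterioles = 2, n_venules = 2,
                                       arteriole_top_radius_um = 10,
                                       venule_top_radius_um = 12,
                                       capillary_radius_range_um = c(1.5, 2.9),
                                       edge_keep_fraction = 0.8,
                                       inlet_pressure_pa = 8000,
                                       outlet_pressure_pa = 2000,
                                       jitter_fraction = 0.2,
                                       seed = 1) {
  set.seed(seed)
  s <- capillary_spacing_um
  nx <- max(2, round(lateral_um / s) + 1)
  nz <- max(3, round(depth_um / s) + 1)
  xs <- seq(0, lateral_um, length.out = nx)
  zs <- seq(s / 2, depth_um - s / 2, length.out = nz)

  lattice <- tidyr::expand_grid(ix = seq_len(nx), iy = seq_len(nx),
                                iz = seq_len(nz)) %>%
    mutate(
      x = xs[.data$ix] + stats::runif(n(), -1, 1) * jitter_fraction * s,
      y = xs[.data$iy] + stats::runif(n(), -1, 1) * jitter_fraction * s,
      z = zs[.data$iz] + stats::runif(n(), -1, 1) * jitter_fraction * s,
      node = dplyr::row_number()
    )
  idx <- function(ix, iy, iz) (ix - 1) * nx * nz + (iy - 1) * nz + iz
  stopifnot(all(lattice$node == idx(lattice$ix, lattice$iy, lattice$iz)))

  lattice_edges <- bind_rows(
    lattice %>% filter(.data$ix < nx) %>%
      mutate(to = idx(.data$ix + 1, .data$iy, .data$iz)),
    lattice %>% filter(.data$iy < nx) %>%
      mutate(to = idx(.data$ix, .data$iy + 1, .data$iz)),
    lattice %>% filter(.data$iz < nz) %>%
      mutate(to = idx(.data$ix, .data$iy, .data$iz + 1))
  ) %>%
    select(from = "node", "to")

  # penetrating trees: vertical chains of nodes at tree-specific (x, y)
  tree_xy <- tibble(
    kind = c(rep("penetrating_arteriole", n_arterioles),
             rep("penetrating_venule", n_venules)),
    x = lateral_um * stats::runif(n_arterioles + n_venules, 0.15, 0.85),
    y = lateral_um * stats::runif(n_arterioles + n_venules, 0.15, 0.85),
    r_top = c(rep(arteriole_top_radius_um, n_arterioles),
              rep(venule_top_radius_um, n_venules))
  )

  next_id <- nrow(lattice)
  pen_nodes <- list(); pen_segments <- list(); couplings <- list()
  for (t in seq_len(nrow(tree_xy))) {
    zs_pen <- c(0, zs)
    ids <- next_id + seq_along(zs_pen)
    next_id <- max(ids)
    r_pen <- tree_xy$r_top[t] - (tree_xy$r_top[t] - 3) * zs_pen / depth_um
    pen_nodes[[t]] <- tibble(
      node = ids, x = tree_xy$x[t], y = tree_xy$y[t], z = zs_pen,
      kind = c(if (tree_xy$kind[t] == "penetrating_arteriole") "inlet" else "outlet",
               rep("interior", length(zs_pen) - 1))
    )
    pen_segments[[t]] <- tibble(
      from = ids[-length(ids)], to = ids[-1],
      r_v = (r_pen[-length(r_pen)] + r_pen[-1]) / 2,
      vessel_class = tree_xy$kind[t]
    )
    # couple each penetrating node (below the surface) to its nearest
    # lattice node with a pre/post-capillary branch
    for (k in seq(2, length(ids), by = 2)) {
      d2 <- (lattice$x - tree_xy$x[t])^2 + (lattice$y - tree_xy$y[t])^2 +
        (lattice$z - zs_pen[k])^2
      couplings[[length(couplings) + 1]] <- tibble(
        from = ids[k], to = lattice$node[which.min(d2)],
        r_v = 2.8, vessel_class = "capillary"
      )
    }
  }
  pen_nodes <- bind_rows(pen_nodes)
  pen_segments <- bind_rows(pen_segments)
  couplings <- bind_rows(couplings)

  # prune lattice edges, retrying until the full network stays connected
  nodes <- bind_rows(
    lattice %>% mutate(kind = "interior") %>%
      select("node", "x", "y", "z", "kind"),
    pen_nodes
  )
  must_edges <- bind_rows(pen_segments %>% select("from", "to"),
                          couplings %>% select("from", "to"))
  kept <- NULL
  for (try in 1:25) {
    keep <- stats::runif(nrow(lattice_edges)) < edge_keep_fraction
    cand <- lattice_edges[keep, ]
    g <- igraph::graph_from_data_frame(
      bind_rows(cand, must_edges), directed = FALSE,
      vertices = data.frame(name = nodes$node)
    )
    if (igraph::is_connected(g)) { kept <- cand; break }
  }
  if (is.null(kept)) abort("could not generate a connected capillary mesh; raise `edge_keep_fraction`.")

  cap_segments <- kept %>%
    mutate(r_v = stats::runif(n(), capillary_radius_range_um[1],
                              capillary_radius_range_um[2]),
           vessel_class = "capillary")

  segments <- bind_rows(pen_segments, couplings, cap_segments) %>%
    mutate(segment = dplyr::row_number(), .before = 1)

  pos <- nodes %>% select("node", "x", "y", "z")
  segments <- segments %>%
    left_join(pos, by = c(from = "node")) %>%
    left_join(pos, by = c(to = "node"), suffix = c("_a", "_b")) %>%
    mutate(length = sqrt((.data$x_b - .data$x_a)^2 +
                           (.data$y_b - .data$y_a)^2 +
                           (.data$z_b - .data$z_a)^2)) %>%
    select("segment", "from", "to", "r_v", "length", "vessel_class")

  nodes <- nodes %>%
    mutate(pressure_bc = dplyr::case_when(
      .data$kind == "inlet" ~ inlet_pressure_pa,
      .data$kind == "outlet" ~ outlet_pressure_pa,
      TRUE ~ NA_real_
    ))

  new_vascular_network(
    nodes, segments,
    metadata = list(
      units = list(length = "um", radius = "um", pressure = "Pa"),
      provenance = "synthetic",
      depth_um = depth_um, lateral_um = lateral_um, seed = seed
    )
  )
}

new_vascular_network <- function(nodes, segments, metadata = list()) {
  stopifnot(all(segments$r_v > 0), all(segments$length > 0))
  structure(list(nodes = nodes, segments = segments, metadata = metadata),
            class = "vascular_network")
}

#' @export
print.vascular_network <- function(x, ...) {
  cat(sprintf(
    "<vascular_network> %d nodes, %d segments (%s); depth %.0f-%.0f um\n",
    nrow(x$nodes), nrow(x$segments),
    x$metadata$provenance %||% "unknown provenance",
    min(x$nodes$z), max(x$nodes$z)
  ))
  invisible(x)
}

#' Bounding-box volume of a network
#'
#' @param net A `vascular_network`.
#' @return Volume in um^3 of the axis-aligned node bounding box.
#' @export
network_volume <- function(net) {
  stopifnot(inherits(net, "vascular_network"))
  with(net$nodes, prod(max(x) - min(x), max(y) - min(y), max(z) - min(z)))
}

#' Simplify network polylines (Douglas-Peucker)
#'
#' Reduces each segment's polyline with the Douglas-Peucker algorithm
#' using the local lumen radius as the distance tolerance; endpoints are
#' always preserved and the graph topology is untouched. Segment lengths
#' are recomputed as the simplified polyline arclength. Idempotent.
#' Segments without polylines pass through unchanged.
#'
#' @param net A `vascular_network` whose `segments` may carry a
#'   `polyline` list-column of n x 3 coordinate matrices.
#' @return The network with simplified polylines.
#' @export
simplify_network <- function(net) {
  stopifnot(inherits(net, "vascular_network"))
  if (!"polyline" %in% names(net$segments)) return(net)
  segs <- net$segments
  for (i in seq_len(nrow(segs))) {
    pl <- segs$polyline[[i]]
    if (is.null(pl) || nrow(pl) <= 2) next
    keep <- douglas_peucker_keep(pl, tol = segs$r_v[i])
    segs$polyline[[i]] <- pl[keep, , drop = FALSE]
    segs$length[i] <- polyline_length(pl[keep, , drop = FALSE])
  }
  net$segments <- segs
  net
}

polyline_length <- function(m) {
  if (nrow(m) < 2) return(0)
  sum(sqrt(rowSums((m[-1, , drop = FALSE] - m[-nrow(m), , drop = FALSE])^2)))
}

douglas_peucker_keep <- function(m, tol) {
  n <- nrow(m)
  keep <- rep(FALSE, n)
  keep[c(1, n)] <- TRUE
  recurse <- function(i0, i1) {
    if (i1 - i0 < 2) return(invisible())
    a <- m[i0, ]; b <- m[i1, ]
    ab <- b - a
    ab2 <- sum(ab^2)
    d <- vapply(seq(i0 + 1, i1 - 1), function(k) {
      ap <- m[k, ] - a
      t <- if (ab2 > 0) sum(ap * ab) / ab2 else 0
      t <- min(max(t, 0), 1)
      sqrt(sum((ap - t * ab)^2))
    }, numeric(1))
    kmax <- which.max(d)
    if (d[kmax] > tol) {
      ksplit <- i0 + kmax
      keep[ksplit] <<- TRUE
      recurse(i0, ksplit)
      recurse(ksplit, i1)
    }
  }
  recurse(1, n)
  keep
}
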