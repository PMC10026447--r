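#' Read and write the network CSV dialect
#'
#' A network is persisted as two CSV files plus optional JSON metadata:
#' * `<stem>_nodes.csv`: `node`, `x_um`, `y_um`, `z_um`, `kind`
#'   (interior/inlet/outlet), `pressure_bc_pa`;
#' * `<stem>_segments.csv`: `segment`, `node_a`, `node_b`, `r_v_um`,
#'   `length_um`, `vessel_class`;
#' * `<stem>_meta.json`: units and provenance.
#'
#' The loader validates that the declared length unit is micrometres and
#' that radii and lengths are positive.
#'
#' @param net A `vascular_network`.
#' @param stem Path stem (without suffix) for the three files.
#' @return `write_network()` returns `stem` invisibly; `read_network()`
#'   returns a `vascular_network`.
#' @export
write_network <- function(net, stem) {
  stopifnot(inherits(net, "vascular_network"))
  readr::write_csv(
    net$nodes %>%
      select(node = "node", x_um = "x", y_um = "y", z_um = "z",
             kind = "kind", pressure_bc_pa = "pressure_bc"),
    paste0(stem, "_nodes.csv")
  )
  readr::write_csv(
    net$segments %>%
      select(segment = "segment", node_a = "from", node_b = "to",
             r_v_um = "r_v", length_um = "length",
             vessel_class = "vessel_class"),
    paste0(stem, "_segments.csv")
  )
  meta <- net$metadata
  meta$units <- meta$units %||% list(length = "um", radius = "um",
                                     pressure = "Pa")
  jsonlite::write_json(meta, paste0(stem, "_meta.json"), auto_unbox = TRUE)
  invisible(stem)
}

#' @rdname write_network
#' @export
read_network <- function(stem) {
  nodes_path <- paste0(stem, "_nodes.csv")
  segs_path <- paste0(stem, "_segments.csv")
  meta_path <- paste0(stem, "_meta.json")
  if (!file.exists(nodes_path) || !file.exists(segs_path)) {
    abort("expected `<stem>_nodes.csv` and `<stem>_segments.csv`.")
  }
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else {
    list(units = list(length = "um"), provenance = "unknown")
  }
  if (!identical(meta$units$length %||% "um", "um")) {
    abort("network length unit must be micrometres ('um').")
  }
  nodes <- readr::read_csv(nodes_path, show_col_types = FALSE) %>%
    select(node = "node", x = "x_um", y = "y_um", z = "z_um",
           kind = "kind", pressure_bc = "pressure_bc_pa")
  segs <- readr::read_csv(segs_path, show_col_types = FALSE) %>%
    select(segment = "segment", from = "node_a", to = "node_b",
           r_v = "r_v_um", length = "length_um",
           vessel_class = "vessel_class")
  if (any(segs$r_v <= 0) || any(segs$length <= 0)) {
    abort("segment radii and lengths must be positive.")
  }
  new_vascular_network(nodes, segs, metadata = meta)
}

#' Export per-segment results as tidy CSV
#'
#' @param coeffs A [network_coefficients()] table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_segment_results <- function(coeffs, path) {
  readr::write_csv(
    coeffs %>%
      select("segment", "r_v", "r_o", "label", "category",
             pressure_pa = "pressure", "phi_g", "L_p", "C_M", S_m2 = "S"),
    path
  )
  invisible(path)
}
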