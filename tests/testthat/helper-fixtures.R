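# Shared fixtures built in code at test time.

# Generators on a regular triangular lattice (hexagonal Voronoi cells) with
# cell area A, commensurate with the periodic domain.
hex_lattice_points <- function(A = 50, nx = 10, ny = 10) {
  a <- sqrt(2 * A / sqrt(3))
  dy <- a * sqrt(3) / 2
  stopifnot(ny %% 2 == 0)
  grid <- expand.grid(i = 0:(nx - 1), j = 0:(ny - 1))
  W <- nx * a
  list(
    points = tibble::tibble(
      u = (grid$i * a + (grid$j %% 2) * a / 2) %% W,
      z = grid$j * dy
    ),
    domain = surface_domain(W / (2 * pi), L = ny * dy)
  )
}

# Minimal hand-built network: a chain of `n` equal small-radius segments
# from an inlet to an outlet.
chain_network <- function(n = 10, r_v = 2, seg_len = 100,
                          p_in = 100, p_out = 0) {
  nodes <- tibble::tibble(
    node = seq_len(n + 1),
    x = 0, y = 0, z = (seq_len(n + 1) - 1) * seg_len,
    kind = c("inlet", rep("interior", n - 1), "outlet"),
    pressure_bc = c(p_in, rep(NA_real_, n - 1), p_out)
  )
  segments <- tibble::tibble(
    segment = seq_len(n), from = seq_len(n), to = seq_len(n) + 1,
    r_v = r_v, length = seg_len, vessel_class = "capillary"
  )
  endfeet:::new_vascular_network(nodes, segments,
                                 metadata = list(provenance = "synthetic"))
}

# Symmetric Y: inlet node 1 splits at node 2 into two identical branches
# ending at outlets 3 and 4.
y_network <- function(r_v = 3, seg_len = 100, p_in = 100, p_out = 0) {
  nodes <- tibble::tibble(
    node = 1:4,
    x = c(0, 0, -50, 50), y = 0, z = c(0, seg_len, 2 * seg_len, 2 * seg_len),
    kind = c("inlet", "interior", "outlet", "outlet"),
    pressure_bc = c(p_in, NA, p_out, p_out)
  )
  segments <- tibble::tibble(
    segment = 1:3, from = c(1, 2, 2), to = c(2, 3, 4),
    r_v = r_v, length = seg_len, vessel_class = "capillary"
  )
  endfeet:::new_vascular_network(nodes, segments,
                                 metadata = list(provenance = "synthetic"))
}
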