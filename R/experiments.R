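#' Configuration-driven experiment runner
#'
#' Reproduces the package's computational experiments end to end, writing
#' tidy CSV tables plus a JSON manifest (config, seed, versions) to an
#' output directory. Identical config and seed give identical tables.
#'
#' Experiments:
#' * `"fig4"` — reference-vessel ensembles: capillary (r_o = 2.9 um,
#'   A = 50 um^2), venule (15, 110) and arteriole (15, 490); writes
#'   `fig4_summary.csv` (mean phi_g, gaps/ring, phi_perp per vessel) and
#'   `fig4_realizations.csv`.
#' * `"fig5_fig6"` — gap-fraction sweep over radii for arterial and
#'   venous relations with exponential refits; writes
#'   `gap_fraction_samples.csv` and `gap_fraction_fits.csv`.
#' * `"projection_table"` — measured-to-true area correction table;
#'   writes `area_correction.csv`.
#' * `"network"` — synthetic network, pressure solve, classification,
#'   coefficient mapping, layer summary; writes `segments.csv`,
#'   `layers.csv`, `network_summary.csv`.
#'
#' @param experiment One of the names above.
#' @param config Named list of parameter overrides (see Details of each
#'   experiment's underlying functions), or a path to a YAML file.
#' @param seed Integer seed.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a named list of the written file paths.
#' @examples
#' \dontrun{
#' run_experiment("fig4", config = list(n_realizations = 10), seed = 1,
#'                out_dir = tempfile())
#' }
#' @export
run_experiment <- function(experiment, config = list(), seed = 1,
                           out_dir = ".") {
  experiments <- c("fig4", "fig5_fig6", "projection_table", "network")
  if (!is.character(experiment) || length(experiment) != 1 ||
        !experiment %in% experiments) {
    abort(sprintf("unknown experiment %s; valid names: %s",
                  deparse(substitute(experiment)),
                  paste(experiments, collapse = ", ")))
  }
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  cfg <- function(name, default) config[[name]] %||% default
  paths <- list()
  w <- function(x, name) {
    p <- file.path(out_dir, name)
    readr::write_csv(x, p)
    paths[[name]] <<- p
  }

  if (experiment == "fig4") {
    vessels <- tibble(
      vessel = c("capillary", "venule", "arteriole"),
      r_o = c(2.9, 15, 15),
      mean_area = c(50, 110, 490)
    )
    n_real <- cfg("n_realizations", 200)
    d_g <- cfg("d_g_um", 0.02)
    sims <- purrr::pmap(vessels, function(vessel, r_o, mean_area) {
      sim <- simulate_sheath(r_o, mean_area, d_g = d_g,
                             n_realizations = n_real,
                             seed = seed + which(vessels$vessel == vessel) * 1000)
      mutate(as_tibble(sim), vessel = vessel)
    })
    w(bind_rows(sims), "fig4_realizations.csv")
    w(
      bind_rows(sims) %>%
        group_by(.data$vessel) %>%
        summarise(r_o_um = .data$r_o_um[1],
                  mean_area_um2 = mean(.data$mean_area_um2),
                  phi_g = mean(.data$phi_g), phi_perp = mean(.data$phi_perp),
                  gaps_per_ring = mean(.data$gaps_per_ring),
                  .groups = "drop"),
      "fig4_summary.csv"
    )
  } else if (experiment == "fig5_fig6") {
    n_per <- cfg("n_per_radius", 20)
    n_radii <- cfg("n_radii", 10)
    samples <- purrr::map2_dfr(
      c("arterial", "venous"), c(seed, seed + 500000),
      function(kind, s) {
        fit0 <- gap_fraction_fit(kind)
        radii <- seq(fit0$valid_radius_range[1], fit0$valid_radius_range[2],
                     length.out = n_radii)
        simulate_gap_fraction_profile(kind, radii = radii,
                                      n_per_radius = n_per, seed = s,
                                      d_g = cfg("d_g_um", 0.02))
      }
    )
    w(samples, "gap_fraction_samples.csv")
    fits <- purrr::map_dfr(c("arterial", "venous"), function(kind) {
      tidy(fit_gap_fraction_model(samples[samples$vessel_kind == kind, ], kind))
    })
    w(fits, "gap_fraction_fits.csv")
  } else if (experiment == "projection_table") {
    tab <- build_area_correction(
      r_o_grid = cfg("r_o_grid", c(2, 2.9, 4, 6, 8, 10, 12, 15, 20)),
      a_true_grid = cfg("a_true_grid", NULL),
      n_realizations = cfg("n_realizations", 50),
      seed = seed
    )
    w(as_tibble(tab), "area_correction.csv")
  } else if (experiment == "network") {
    net <- generate_synthetic_network(seed = seed)
    flow <- solve_pressures(net,
                            viscosity_law = cfg("viscosity_law", "invivo"),
                            hematocrit = cfg("hematocrit", 0.45))
    labels <- classify_segments(net, flow)
    coeffs <- network_coefficients(net, labels,
                                   d_g_nm = cfg("d_g_nm", 20),
                                   mu = cfg("mu_pa_s", 0.7e-3))
    lay <- summarize_layers(net, coeffs)
    w(coeffs %>%
        select("segment", "r_v", "r_o", "label", "category",
               pressure_pa = "pressure", "phi_g", "L_p", "C_M", S_m2 = "S"),
      "segments.csv")
    w(lay$layers, "layers.csv")
    w(network_summary(net, coeffs), "network_summary.csv")
  }

  manifest <- list(
    experiment = experiment, seed = seed, config = config,
    package_version = as.character(utils::packageVersion("endfeet")),
    r_version = R.version.string,
    files = names(paths)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  paths$manifest <- file.path(out_dir, "manifest.json")
  invisible(paths)
}
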