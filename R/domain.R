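#' Unrolled vessel-surface domain
#'
#' The outer surface of the endfoot sheath around a vessel is modelled as a
#' cylinder of radius `r_o` and axial length `L`, unrolled into a flat
#' rectangle of width `2 * pi * r_o` (circumference) and height `L`. Both
#' directions are treated as periodic: circumferentially the rectangle wraps
#' around the vessel, and axial periodicity removes boundary bias from edge
#' statistics.
#'
#' When `L` is `NULL` it is chosen so that the expected number of endfoot
#' cells at mean cell area `mean_area` is `n_cells_target` (default 500),
#' i.e. `L = n_cells_target * mean_area / (2 * pi * r_o)`. This bounds the
#' Monte-Carlo error of per-realization gap-fraction estimates at roughly
#' the percent level.
#'
#' @param r_o Outer endfoot-sheath radius in micrometres (> 0).
#' @param L Axial length in micrometres (> 0), or `NULL` to derive it from
#'   `mean_area`.
#' @param mean_area Mean endfoot cell area in square micrometres; required
#'   when `L` is `NULL`.
#' @param n_cells_target Expected cell count used to derive `L`.
#'
#' @return An object of class `surface_domain`: a list with fields `r_o`,
#'   `L`, `width` (`2 * pi * r_o`) and `area` (`width * L`), all in
#'   micrometre units.
#' @examples
#' surface_domain(r_o = 2.9, mean_area = 50)
#' @export
surface_domain <- function(r_o, L = NULL, mean_area = NULL,
                           n_cells_target = 500) {
  if (!is.numeric(r_o) || length(r_o) != 1 || !is.finite(r_o) || r_o <= 0) {
    abort("`r_o` must be a single positive number (micrometres).")
  }
  if (is.null(L)) {
    if (is.null(mean_area) || mean_area <= 0) {
      abort("supply `L`, or a positive `mean_area` from which to derive it.")
    }
    L <- n_cells_target * mean_area / (2 * pi * r_o)
  }
  if (!is.numeric(L) || length(L) != 1 || !is.finite(L) || L <= 0) {
    abort("`L` must be a single positive number (micrometres).")
  }
  structure(
    list(r_o = r_o, L = L, width = 2 * pi * r_o, area = 2 * pi * r_o * L),
    class = "surface_domain"
  )
}

#' @export
print.surface_domain <- function(x, ...) {
  cat(sprintf(
    "<surface_domain> r_o = %.4g um, L = %.4g um, width = %.4g um, area = %.6g um^2\n",
    x$r_o, x$L, x$width, x$area
  ))
  invisible(x)
}

is_surface_domain <- function(x) inherits(x, "surface_domain")
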