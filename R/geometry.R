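#' Lateral-plus-caps surface area of a cylindrical enterocyte
#'
#' Caco-2 cells grown on bicameral inserts are approximated as cylinders of
#' height `h_c` and diameter `d_c`; the absorptive surface is taken as the
#' lateral area plus the two circular caps,
#' \eqn{A_E = 2\pi (d_c/2) h_c + 2\pi (d_c/2)^2}.
#'
#' @param h_c Cell height in micrometres.
#' @param d_c Cell diameter in micrometres.
#' @return Surface area in square micrometres.
#' @examples
#' enterocyte_area(29.6, 6.2) # ~636.94 um^2 for a differentiated Caco-2 cell
#' @export
enterocyte_area <- function(h_c, d_c) {
  if (any(h_c < 0) || any(d_c < 0)) {
    stop("`h_c` and `d_c` must be non-negative", call. = FALSE)
  }
  r <- d_c / 2
  2 * pi * r * h_c + 2 * pi * r^2
}

#' Cell-culture geometry for an insert-grown Caco-2 monolayer
#'
#' Bundles the measured culture dimensions and volumes together with the
#' derived quantities used by the uptake models: the enterocyte surface area
#' `A_E`, the volume `V_V` of DMT1-bearing vesicles capable of iron release,
#' and the volume correction factor `gamma = V_V / V_cb` that scales vesicular
#' iron release into the pooled intracellular-basolateral compartment.
#'
#' Defaults describe the reference Caco-2 insert culture: 29.6 um cell height,
#' 6.2 um diameter, vesicle volume density 0.04 um^3 per um^2 of cell surface,
#' 200 uL apical medium, 1000 uL combined cellular + basolateral volume, and a
#' release fraction of 0.01 (1% of vesicles competent for iron release, the
#' lower bound of the plausible 1-5% range and the value consistent with
#' V_V = 2.5e-10 uL).
#'
#' @param h_c Cell height (um).
#' @param d_c Cell diameter (um).
#' @param R_V Vesicle volume per unit cell surface area (um^3/um^2).
#' @param V_a Apical medium volume (uL).
#' @param V_cb Combined cellular and basolateral volume (uL).
#' @param V_m Monolayer volume (uL); carried for completeness, unused by the
#'   model equations.
#' @param release_fraction Fraction of vesicles capable of iron release,
#'   in \[0, 0.05\].
#' @return An object of class `cell_geometry`: a list with the stored fields
#'   plus derived `A_E` (um^2), `V_V` (uL) and `gamma` (dimensionless).
#' @examples
#' geom <- cell_geometry()
#' geom$A_E   # 636.94 um^2
#' geom$V_V   # 2.5e-10 uL
#' @export
cell_geometry <- function(h_c = 29.6, d_c = 6.2, R_V = 0.04,
                          V_a = 200, V_cb = 1000, V_m = 1.67,
                          release_fraction = 0.01) {
  stored <- c(h_c = h_c, d_c = d_c, R_V = R_V, V_a = V_a,
              V_cb = V_cb, V_m = V_m)
  if (any(!is.finite(stored)) || any(stored <= 0)) {
    stop("all geometry quantities must be strictly positive and finite",
         call. = FALSE)
  }
  if (!is.finite(release_fraction) || release_fraction < 0 ||
      release_fraction > 0.05) {
    stop("`release_fraction` must lie in [0, 0.05]", call. = FALSE)
  }
  geom <- list(h_c = h_c, d_c = d_c, R_V = R_V, V_a = V_a, V_cb = V_cb,
               V_m = V_m, release_fraction = release_fraction)
  geom$A_E <- enterocyte_area(h_c, d_c)
  geom$V_V <- vesicle_volume_raw(release_fraction, R_V, geom$A_E)
  geom$gamma <- geom$V_V / V_cb
  structure(geom, class = "cell_geometry")
}

# um^3 -> uL conversion: 1 um^3 = 1e-9 uL
vesicle_volume_raw <- function(release_fraction, R_V, A_E) {
  release_fraction * R_V * A_E * 1e-9
}

#' Volume of iron-releasing DMT1 vesicles
#'
#' `V_V = release_fraction * R_V * A_E`, converted from cubic micrometres to
#' microlitres. Only the release-competent fraction of the vesicular
#' compartment contributes to intracellular iron delivery.
#'
#' @param geometry A [cell_geometry()] object.
#' @return Volume in microlitres.
#' @export
vesicle_volume <- function(geometry) {
  stopifnot(inherits(geometry, "cell_geometry"))
  geometry$V_V
}

#' Volume correction factor for vesicular iron release
#'
#' The dimensionless factor `gamma = V_V / V_cb` scaling the maximum vesicular
#' release rate into the pooled intracellular-basolateral compartment.
#'
#' @param geometry A [cell_geometry()] object.
#' @return Dimensionless ratio.
#' @export
volume_correction_factor <- function(geometry) {
  stopifnot(inherits(geometry, "cell_geometry"))
  if (geometry$V_cb <= 0) stop("`V_cb` must be positive", call. = FALSE)
  geometry$V_V / geometry$V_cb
}

#' @export
print.cell_geometry <- function(x, ...) {
  cat("<cell_geometry>\n")
  cat(sprintf("  cell: h_c = %g um, d_c = %g um (A_E = %.2f um^2)\n",
              x$h_c, x$d_c, x$A_E))
  cat(sprintf("  volumes: V_a = %g uL, V_cb = %g uL, V_m = %g uL\n",
              x$V_a, x$V_cb, x$V_m))
  cat(sprintf("  vesicles: R_V = %g um^3/um^2, release fraction = %g\n",
              x$R_V, x$release_fraction))
  cat(sprintf("  derived: V_V = %.3e uL, gamma = %.3e\n", x$V_V, x$gamma))
  invisible(x)
}

#' @export
tidy.cell_geometry <- function(x, ...) {
  tibble::tibble(
    term = c("h_c", "d_c", "R_V", "V_a", "V_cb", "V_m",
             "release_fraction", "A_E", "V_V", "gamma"),
    value = c(x$h_c, x$d_c, x$R_V, x$V_a, x$V_cb, x$V_m,
              x$release_fraction, x$A_E, x$V_V, x$gamma),
    unit = c("um", "um", "um^3/um^2", "uL", "uL", "uL",
             "", "um^2", "uL", "")
  )
}
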