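#' Microwell / droplet geometry
#'
#' Builds the geometric quantities the kinetic model needs: the droplet
#' volume `V` (the droplet is assumed to fill the cylindrical well, so
#' `V = pi (d/2)^2 h`) and the dextran-PEG interface area `A`. Two interface
#' models are available:
#' \describe{
#'   \item{`disc_at_mouth`}{a flat circular interface spanning the well
#'     mouth, `A = pi (d/2)^2`. With this choice `A/V = 1/h`, so the
#'     diffusive loss rate depends on well depth only.}
#'   \item{`spherical_cap`}{a spherical cap whose base is the well mouth and
#'     which meets the mouth at `contact_angle` (radians, measured from the
#'     mouth plane): `A = 2 pi R_m^2 / (1 + cos(theta))` with `R_m = d/2`.
#'     Reduces to the flat disc as `theta -> 0`; appropriate when the
#'     droplet bulges out of (or recedes into) the well.}
#' }
#'
#' @param diameter Well (and droplet) diameter, meters.
#' @param depth Well depth `h`, meters.
#' @param interface_thickness Thickness `w` of the dextran-PEG interfacial
#'   region, meters. Default 4e-8 m (40 nm).
#' @param interface_model `"disc_at_mouth"` (default) or `"spherical_cap"`.
#' @param contact_angle Cap contact angle in radians, used only by
#'   `"spherical_cap"`. Default `pi / 6`.
#' @return An object of class `well_geometry` with fields `diameter`,
#'   `depth`, `interface_thickness`, `interface_model`, `interface_area`
#'   (m^2) and `volume` (m^3).
#' @examples
#' g <- make_well_geometry(50e-6, 100e-6)
#' g$volume          # 1.9635e-13 m^3
#' g$interface_area  # 1.9635e-9 m^2
#' @export
make_well_geometry <- function(diameter, depth,
                               interface_thickness = 4e-8,
                               interface_model = c("disc_at_mouth",
                                                   "spherical_cap"),
                               contact_angle = pi / 6) {
  interface_model <- match.arg(interface_model)
  for (nm in c("diameter", "depth", "interface_thickness")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0)
      stop(sprintf("`%s` must be a single positive number (meters)", nm))
  }
  r_mouth <- diameter / 2
  area <- switch(interface_model,
    disc_at_mouth = pi * r_mouth^2,
    spherical_cap = {
      if (!is.finite(contact_angle) || contact_angle < 0 ||
          contact_angle >= pi)
        stop("`contact_angle` must be in [0, pi) radians")
      2 * pi * r_mouth^2 / (1 + cos(contact_angle))
    })
  structure(
    list(diameter = diameter, depth = depth,
         interface_thickness = interface_thickness,
         interface_model = interface_model,
         interface_area = area,
         volume = pi * r_mouth^2 * depth),
    class = "well_geometry")
}

#' @export
print.well_geometry <- function(x, ...) {
  cat(sprintf(
    "<well_geometry> d = %.3g um, h = %.3g um, w = %.3g nm (%s)\n",
    x$diameter * 1e6, x$depth * 1e6, x$interface_thickness * 1e9,
    x$interface_model))
  cat(sprintf("  V = %.4g m^3, A = %.4g m^2\n", x$volume, x$interface_area))
  invisible(x)
}
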