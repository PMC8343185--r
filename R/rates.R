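#' Stokes-Einstein diffusion coefficient of the unbound Y-motif
#'
#' `D = kT / (6 pi eta r)` for a monodisperse sphere of hydrodynamic radius
#' `r` in a medium of viscosity `eta`.
#'
#' @param phys A [physical_params()] object.
#' @param motif A [motif_spec()] object.
#' @return Diffusion coefficient in m^2/s.
#' @examples
#' diffusion_coefficient(physical_params(), motif_spec())  # ~4.37e-12
#' @export
diffusion_coefficient <- function(phys, motif) {
  stopifnot(inherits(phys, "physical_params"), inherits(motif, "motif_spec"))
  phys$boltzmann_constant * phys$temperature /
    (6 * pi * phys$viscosity * motif$hydrodynamic_radius)
}

#' Smoluchowski collision rate for Brownian monodisperse spheres
#'
#' `alpha = 8kT / (3 eta)`, the diffusion-limited pairwise collision rate
#' kernel. Independent of particle size for equal-sized spheres.
#'
#' @inheritParams diffusion_coefficient
#' @return Collision rate in m^3/s.
#' @export
collision_rate <- function(phys) {
  stopifnot(inherits(phys, "physical_params"))
  8 * phys$boltzmann_constant * phys$temperature / (3 * phys$viscosity)
}

#' Lumped rate constants of the well-mixed droplet model
#'
#' Combines the transport coefficients with the well geometry into the two
#' coefficients of the kinetic model
#' `dN_u/dt = -a N_u - b N_u^2`:
#' \describe{
#'   \item{`loss_rate_a`}{`a = D A / (V w)`, first-order loss of unbound
#'     motifs by Fick diffusion through the interfacial layer of thickness
#'     `w` and area `A`. Units 1/s.}
#'   \item{`coalescence_rate_b`}{`b = alpha / (2V) = 4kT / (3 eta V)`,
#'     second-order Smoluchowski coalescence in a compartment of volume `V`.
#'     Units 1/(s count).}
#' }
#'
#' @inheritParams diffusion_coefficient
#' @param geom A [make_well_geometry()] object.
#' @return An object of class `rate_constants` with fields
#'   `diffusion_coefficient`, `collision_rate`, `loss_rate_a`,
#'   `coalescence_rate_b`.
#' @examples
#' rc <- rate_constants(physical_params(), motif_spec(),
#'                      make_well_geometry(50e-6, 100e-6))
#' rc$loss_rate_a        # ~1.091 /s
#' rc$coalescence_rate_b # ~2.79e-6 /(s count)
#' @export
rate_constants <- function(phys, motif, geom) {
  stopifnot(inherits(geom, "well_geometry"))
  D <- diffusion_coefficient(phys, motif)
  alpha <- collision_rate(phys)
  structure(
    list(diffusion_coefficient = D,
         collision_rate = alpha,
         loss_rate_a = D * geom$interface_area /
           (geom$volume * geom$interface_thickness),
         coalescence_rate_b = alpha / (2 * geom$volume)),
    class = "rate_constants")
}

## Bare (a, b) pair for callers that bypass the physical parametrisation,
## e.g. the closed-form oracles and randomized property tests.
#' Rate constants from bare coefficients
#'
#' Wraps an explicit `(a, b)` pair as a `rate_constants` object, for use
#' with [solve_kinetics()] when the coefficients are given directly rather
#' than derived from physical parameters.
#'
#' @param a First-order diffusive loss rate, 1/s.
#' @param b Second-order coalescence rate, 1/(s count).
#' @return A `rate_constants` object (transport fields set to `NA`).
#' @export
rate_constants_ab <- function(a, b) {
  if (!is.numeric(a) || a < 0 || !is.numeric(b) || b < 0)
    stop("`a` and `b` must be non-negative")
  structure(
    list(diffusion_coefficient = NA_real_, collision_rate = NA_real_,
         loss_rate_a = a, coalescence_rate_b = b),
    class = "rate_constants")
}
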