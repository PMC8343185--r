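# Shared fixtures: the reference 50-um well condition and small scene specs.

ref_geometry <- function() make_well_geometry(50e-6, 100e-6)

ref_rates <- function() {
  rate_constants(physical_params(), motif_spec(), ref_geometry())
}

ref_N0 <- function(conc = 8e-6) {
  gelwell:::conc_to_count(conc, ref_geometry()$volume)
}

# A small, fast scene: 0.6 mm field on a 150-um pitch -> 4 x 4 wells.
small_scene_spec <- function(seed = 1L, ...) {
  args <- list(field_size = 0.6e-3, lattice_pitch = 150e-6,
               well_diameter = 100e-6, seed = seed)
  override <- list(...)
  args[names(override)] <- override
  do.call(array_spec, args)
}

# Uniform thresholds halfway between the intensity levels of a spec.
midpoint_thresholds <- function(spec) {
  lv <- spec$intensities
  c(dex = (lv$dex_bg + lv$dex_fg) / 2,
    dna = (lv$dna_droplet + lv$dna_particle) / 2)
}

# Largest time at which the closed-form unbound count still exceeds
# `floor_count`; the continuum ODE is only meaningful above ~1 molecule.
time_to_count <- function(a, b, N0, floor_count = 1) {
  if (N0 <= floor_count) return(0)
  f <- function(t) closed_form_unbound(a, b, N0, t) - floor_count
  upper <- 1 / (a + b * N0)
  while (f(upper) > 0) upper <- upper * 2
  stats::uniroot(f, c(0, upper), tol = 1e-12)$root
}
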