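#' Gel particle radius from the gelled motif count
#'
#' The aggregate is a sphere of gel with internal motif concentration
#' `rho_g`, so `(4 pi r^3 / 3) rho_g = N_g` fixes the uncompacted radius;
#' crowding agents and spermine then shrink it by the compaction factor
#' `lambda`:
#' \deqn{r_g = \frac{1}{\lambda}\left(\frac{3 N_g}{4\pi\rho_g}\right)^{1/3},}
#' with `rho_g` converted from mol/L to counts/m^3 via Avogadro's number.
#'
#' @param N_g Gelled motif count (>= 0, vectorised).
#' @param gel A [gel_params()] object.
#' @return Radius in meters (0 when `N_g = 0`).
#' @examples
#' gel_radius(9.46e8, gel_params()) * 1e6  # ~6 um
#' @export
gel_radius <- function(N_g, gel = gel_params()) {
  stopifnot(inherits(gel, "gel_params"))
  if (any(N_g < 0)) stop("`N_g` must be >= 0")
  rho_count <- gel$gel_motif_concentration * 1000 * .NA  # counts / m^3
  (3 * N_g / (4 * pi * rho_count))^(1 / 3) / gel$compaction_factor
}

#' Sweep the model over concentrations and well geometries
#'
#' Runs the annealing model for every (initial concentration, well) pair
#' and tabulates the lumped rates, the initial and final motif counts, and
#' the predicted particle radius. This is the model's concentration-by-well
#' prediction surface.
#'
#' @param concentrations Initial per-motif concentrations, mol/L.
#' @param wells A list of [make_well_geometry()] objects.
#' @param phys,motif,gel Parameter objects; see [physical_params()],
#'   [motif_spec()], [gel_params()]. `motif$initial_concentration` is
#'   ignored in favour of `concentrations`.
#' @param schedule An [annealing_schedule()]; default a single round run to
#'   quasi-steady state.
#' @param rel_tol Solver relative tolerance.
#' @return A data.frame with one row per (concentration, well) and columns
#'   `concentration_M`, `well_diameter_m`, `a_per_s`, `b_per_s_count`,
#'   `N0`, `Ng_final`, `r_g_m`.
#' @export
sweep_model <- function(concentrations, wells,
                        phys = physical_params(), motif = motif_spec(),
                        gel = gel_params(),
                        schedule = annealing_schedule(n_rounds = 1),
                        rel_tol = 1e-9) {
  if (length(concentrations) == 0 || length(wells) == 0)
    stop("`concentrations` and `wells` must be non-empty")
  if (inherits(wells, "well_geometry")) wells <- list(wells)
  rows <- list()
  for (geom in wells) {
    rc <- rate_constants(phys, motif, geom)
    for (conc in concentrations) {
      N0 <- conc_to_count(conc, geom$volume)
      traj <- run_annealing(rc, N0, schedule, rel_tol = rel_tol)
      ng <- traj$N_g[nrow(traj)]
      rows[[length(rows) + 1]] <- data.frame(
        concentration_M = conc,
        well_diameter_m = geom$diameter,
        a_per_s = rc$loss_rate_a,
        b_per_s_count = rc$coalescence_rate_b,
        N0 = N0,
        Ng_final = ng,
        r_g_m = gel_radius(ng, gel))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
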