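# gelwell

Kinetic modelling and image quantification for DNA nanostar hydrogel
particles grown inside dextran/PEG aqueous two-phase (ATPS) droplets
confined in microwell arrays.

**Who it is for.** Experimentalists and modellers working on
DNA-nanostructure self-assembly in compartmentalised ATPS: the package
predicts how large a hydrogel particle a given well geometry and DNA
concentration will produce, and quantifies droplet and particle size
distributions from two-channel fluorescence images of microwell arrays.

## The model

Unbound Y-motifs (three-arm DNA nanostars, count `N_u`) in a dextran
droplet of volume `V = A·h` either escape by diffusion across the
dextran–PEG interface (area `A`, thickness `w`) or coalesce irreversibly
into a single aggregate (count `N_g`):

    dN_u/dt = −a·N_u − b·N_u²,   dN_g/dt = b·N_u²

    a = D·A/(V·w),  D = kT/(6πηr)       (Stokes–Einstein + Fick)
    b = 4kT/(3ηV)                        (Smoluchowski kernel α = 8kT/3η)

The aggregate is a sphere of gel with internal motif concentration
`ρ_g`, compacted by a factor `λ`:

    r_g = (1/λ)·(3·N_g / (4π·ρ_g))^(1/3)

The Riccati equation has a closed form, used as an independent oracle for
the numerical integrator, with the asymptote
`N_g(∞) = N0 − (a/b)·ln(1 + b·N0/a)`. Annealing rounds (heat →
dissociate → cool → re-gel) are modelled by resetting `N_u ← N_u + N_g`
at round boundaries; motifs lost to the PEG phase never return.

The package also includes:

* a wetting classifier for particle position at the interface
  (`particle_location()`): interface iff `|γ_p,PEG − γ_p,dex| < γ_dex,PEG`;
* a seeded two-channel synthetic confocal scene generator with ground
  truth (`array_spec()`, `generate_truth()`, `render_channels()`,
  `write_dataset()`);
* an image quantification pipeline — global threshold, connected
  components, ≥1 µm² area filter, `r = sqrt(A/π)` — with truth matching
  (`segment()`, `measure()`, `analyze_scene()`, `match_to_truth()`).

## Worked example

```r
library(gelwell)

geom <- make_well_geometry(50e-6, 100e-6)        # 50 um well, 100 um deep
rc   <- rate_constants(physical_params(), motif_spec(), geom)
N0   <- 8e-6 * 1000 * geom$volume * 6.02214076e23  # 8 uM of motifs
c(a = rc$loss_rate_a, b = rc$coalescence_rate_b, N0 = N0)
#>            a            b           N0
#> 1.091361e+00 2.793884e-06 9.459557e+08

traj <- run_annealing(rc, N0, annealing_schedule(n_rounds = 1))
gel_radius(traj$N_g[nrow(traj)]) * 1e6
#> [1] 5.977659
```

`a ≈ 1.09 s⁻¹` is the diffusive escape rate, `b·N0 ≈ 2.6×10³ s⁻¹` the
initial coalescence rate — coalescence wins, ~99.7% of the motifs gel,
and the predicted particle radius is **≈ 6.0 µm**, inside the 4.8–6.0 µm
range observed for such wells. Sweep concentrations and well sizes with
`sweep_model()`; compare predictions against measured distributions with
`compare_report()`.

Synthetic benchmark + quantification:

```r
spec  <- scene_preset("microwell_50um", seed = 2)
scene <- render_scene(spec)
out   <- analyze_scene(scene$dex, scene$dna,
                       dex_threshold = 0.4, dna_threshold = 0.485)
out$summary$particles_per_well
#> [1] 1.009259
```

— 324 droplets and 327 particles detected, exactly matching the
generated ground truth.

A command-line wrapper over the same functions lives at
`inst/cli/gelwell.R` (`simulate | generate | analyze | wetting | report`).

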