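---
title: "Methods: kinetics of DNA hydrogel particle growth in microwell ATPS droplets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kinetics of DNA hydrogel particle growth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gelwell)
```

## The system

Three-arm DNA nanostars (Y-motifs) with complementary sticky ends are
dissolved in the dextran-rich droplet of a dextran/PEG aqueous two-phase
system (ATPS). Each droplet sits in a cylindrical microwell and is
surrounded by the PEG-rich continuous phase. During thermal annealing the
motifs cross-link into a single hydrogel particle per droplet. Two
processes compete for the unbound motifs:

* **diffusive escape** across the dextran-PEG interface into the PEG
  phase, from which they never return, and
* **coalescence** into the growing aggregate, which is too large to cross
  the interface.

The final particle size is set by which process wins, which is why it
depends on both the DNA concentration and the well geometry.

## The kinetic model

The droplet is a well-mixed compartment of volume $V = A h$ (a cylinder of
depth $h$ whose mouth of area $A$ is the interface). The interfacial
region is a layer of thickness $w$; Fick's law across it gives a
first-order loss of unbound motifs, and the Smoluchowski coagulation
kernel for Brownian monodisperse spheres, $\alpha = 8kT/(3\eta)$, gives a
second-order coalescence term:

$$\frac{dN_u}{dt} = -a N_u - b N_u^2, \qquad
  \frac{dN_g}{dt} = b N_u^2,$$

with

$$a = \frac{D A}{V w}, \qquad
  D = \frac{kT}{6\pi\eta r}, \qquad
  b = \frac{\alpha}{2V} = \frac{4kT}{3\eta V},$$

where $N_u$ is the unbound motif count ($N_u(0) = c_u V$), $N_g$ the
gelled count, $r$ the motif hydrodynamic radius and $\eta$ the
dextran-phase viscosity. The model is isothermal: $\eta$ and $D$ are
evaluated at ambient temperature and held fixed, and binding is
irreversible within a round. We additionally track
$dN_\mathrm{lost}/dt = a N_u$, so $N_u + N_g + N_\mathrm{lost} = N_u(0)$
is an exact invariant that every solved trajectory is tested against.

The final particle radius follows from the gel's internal motif
concentration $\rho_g$ and the compaction factor $\lambda$ (crowding
agents and spermine shrink the network):

$$\frac{4\pi r_g^3}{3}\rho_g = N_g
  \quad\Longrightarrow\quad
  r_g = \frac{1}{\lambda}\left(\frac{3 N_g}{4\pi\rho_g}\right)^{1/3}.$$

### Closed-form oracle

The $N_u$ equation is a Riccati equation with constant coefficients and
admits the closed form

$$N_u(t) = \frac{a N_0 e^{-at}}{a + b N_0 (1 - e^{-at})},
  \qquad
  N_g(\infty) = N_0 - \frac{a}{b}\ln\!\left(1 + \frac{b N_0}{a}\right),$$

with the limits $N_0 e^{-at}$ (pure diffusion) and the Smoluchowski
hyperbola $N_0/(1 + b N_0 t)$ (pure coalescence). Before being trusted as
test oracles these expressions are themselves verified independently in
the test suite: the trajectory formula by substituting a central finite
difference into the ODE, and the $t\to\infty$ limit by numerical
quadrature of $b N_u(t)^2$ over the closed-form trajectory. The adaptive
integrator (`deSolve::lsoda`) is then required to reproduce both.

### Default parameters

| symbol | meaning | default | units |
|---|---|---|---|
| $T$ | temperature | 298 | K |
| $\eta$ | dextran-phase viscosity | $10^{-2}$ | Pa s |
| $r$ | motif hydrodynamic radius | 5 | nm |
| $w$ | interfacial-layer thickness | 40 | nm |
| $\rho_g$ | motif concentration in the gel | 14 | uM |
| $\lambda$ | compaction factor | 5 | — |
| $c_u$ | per-motif concentration | 1–8 | uM |

Notes on three of these. The motif radius is quoted in the source
literature without units; 5 nm is the only physically sensible reading for
a nanostar with ~20-bp arms, and it is exposed as a parameter rather than
hard-coded. The interfacial thickness appears both as $w$ in the flux
derivation and as a 40-nm length estimate; the package treats them as the
same quantity. The interface area $A$ is genuinely under-determined for
wells whose droplets do not fill the mouth, so two interface models are
provided: `disc_at_mouth` (flat interface spanning the mouth, the default,
for which $A/V = 1/h$ exactly) and `spherical_cap` (a cap meeting the
mouth at a configurable contact angle, for bulging or receded droplets).
Under the flat-disc model $a$ and $b N_0$ are independent of well
diameter at fixed concentration, so any diameter dependence of the
predicted radius comes purely through $V$; the cap model is the lever for
exploring geometry effects beyond that. No claim is made about which
choice matches any particular experiment.

### Worked numbers

For the 50-um-diameter, 100-um-deep well at 8 uM:

```{r}
geom <- make_well_geometry(50e-6, 100e-6)
rc <- rate_constants(physical_params(), motif_spec(), geom)
N0 <- 8e-6 * 1000 * geom$volume * 6.02214076e23
c(a = rc$loss_rate_a, b = rc$coalescence_rate_b, N0 = N0)
traj <- run_annealing(rc, N0, annealing_schedule(n_rounds = 1))
gel_radius(traj$N_g[nrow(traj)]) * 1e6  # um
```

About 99.7% of the motifs gel ($bN_0/a \approx 2.4\times 10^3$), giving a
particle of roughly 6 um — coalescence dominates in small wells at high
concentration.

### Annealing rounds

Each heating step fully dissociates the aggregate; `run_annealing()`
models a round as an isothermal integration at ambient followed by the
reset $N_u \leftarrow N_u + N_g$, $N_g \leftarrow 0$. Motifs already in
the PEG phase never return, so the gelled fraction decreases
monotonically with the number of rounds. By default each round is
integrated to quasi-steady state, defined by
$|dN_g/dt|\, t / N_0 < 10^{-6}$ with a doubling time horizon: the
gelation transient (tens of seconds at most for realistic parameters) is
much faster than the minutes-long cooling interval, so "to completion" is
the right default; a fixed `round_seconds` mode exists for protocols
where it is not. The exponential `cooling_profile()` (time constant
$\tau = 30$ s by default; $\tau$ is not pinned by any measurement we
reproduce, only the exponential form is) describes the device
temperature but deliberately does not feed back into the rate constants
— the isothermal approximation is part of the model, not a shortcut.

### Numerical choices

* `lsoda` with `rel_tol = 1e-9` and `abs_tol = 1e-3` counts: the
  absolute floor is far below one molecule, so depletion endpoints are
  resolved, while the stiff-capable switching handles $a + bN_0$
  spanning many orders of magnitude.
* The continuum ODE stops being meaningful below one molecule. Accuracy
  requirements (the $10^{-6}$ relative agreement with the closed form)
  are therefore imposed on the portion of the trajectory with
  $N_u \ge 1$ count; in the sub-molecular tail only non-negativity and
  conservation are enforced. Tests that probe the oracle agreement run
  the solver at tightened tolerances (`1e-11`/`1e-8`) because the
  default absolute tolerance is itself of the order of the permitted
  error near the one-count floor.
* $N_0 = 0$ short-circuits to the zero trajectory without invoking the
  solver.

## Wetting classification

A particle sits at the dextran-PEG interface iff
$|\gamma_{p,\mathrm{PEG}} - \gamma_{p,\mathrm{dex}}| <
\gamma_{\mathrm{dex,PEG}}$: replacing dextran-PEG interface by particle
surface must lower the energy. The two complementary engulfment branches
follow standard wetting energetics; equality is classified as engulfed
because the interface condition is strict. This is a pure classifier —
no contact-angle geometry, no map from polymer composition to tensions.

## The synthetic-image generator

`generate_truth()` + `render_channels()` emulate the confocal data the
quantification pipeline is designed for: a 1.8 mm x 1.8 mm field at
3.5 um/pixel (fixed to a 514 x 514 grid — 1800/3.5 = 514.3, within half a
pixel of the stated resolution), a centred square lattice of wells, one
bright dextran-channel disc per droplet, a dim droplet-wide DNA
background for the unbound fraction, bright DNA-channel particle discs,
and optional Poisson shot noise plus Gaussian read noise. Pixel-centre
convention throughout: physical position = (index − 0.5) x pixel size,
indices counted row-major from the top-left.

Discs are rendered as projected circles with a linear one-pixel
anti-aliasing ramp; the summed coverage of a disc is verified in tests
against 10x-supersampled brute-force rasterisation. Particles are 2D
discs, not shaded spheres, because the pipeline measures projected areas.

Default scene statistics are chosen once, to be realistic for the imaging
conditions emulated, and are exposed in `array_spec()`:

* occupancy $P(0..2) = (0.02, 0.93, 0.05)$ — near-one particles per well
  with a small excess;
* `microwell_50um` preset: droplet radius $\mathcal N(25, 1)$ um (tight,
  tracking the well), particle radius $\mathcal N(5.4, 0.6)$ um;
* `microwell_100um` preset: droplet radius $\mathcal N(40, 5)$ um
  (droplets 70–90 um across, smaller than the well and more variable),
  particle radius $\mathcal N(7, 1.5)$ um;
* rim placement: particle centres sit exactly on the droplet rim circle
  (interfacial accumulation); `center` models the single coalesced
  aggregate; `uniform` serves bulk-like scenes.

What the generator does **not** emulate: optical point-spread functions
and confocal sectioning, photobleaching, intensity cross-talk between
channels, convective motion, or well-to-well illumination gradients.
Passing the recovery tests therefore demonstrates the correctness of the
measurement chain (thresholding, labelling, unit conversion, statistics)
on geometrically faithful scenes — it does not validate threshold choice
against real microscope noise or PSF blur.

## The quantification pipeline

`segment()` applies a single global threshold (pixels at the threshold
count as foreground) and labels connected components; `measure()`
converts pixel counts to physical areas, drops components below
1 um^2 (the floor that keeps single-pixel noise out of the statistics —
note that at 3.5 um/pixel one pixel is 12.25 um^2, so the floor only
bites on finer-sampled images, and it is implemented in physical units
for exactly that reason), and reports centroids and the projected-circle
radius $r = \sqrt{A/\pi}$. The same radius formula serves both channels:
a microwell-shaped droplet and a spherical particle both present a
circular cross-section in a single confocal plane.

Deliberate conventions, each configurable:

* default threshold: Otsu on the channel histogram (a "uniform
  threshold" constrains only that it is global; Otsu is the standard
  automatic choice), with explicit per-channel overrides for bit-exact
  runs — the end-to-end recovery tests use fixed midpoint thresholds,
  uniform across all scenes;
* per-channel thresholds rather than one shared mask, recorded in the
  output;
* 8-connectivity by default (the ImageJ Analyze-Particles convention),
  4-connectivity available; labels are deterministic, ordered by each
  component's first pixel in raster order;
* holes inside components are not filled;
* `summarize_records()` uses the sample (n−1) standard deviation, and
  `particles_per_well()` is the plain detected-count ratio.

`match_to_truth()` (greedy globally-nearest centroid matching, order
invariant) supports the recovery benchmarks: on noiseless full-size
scenes detected counts must equal the truth exactly and the mean radius
must land within one pixel; at a particle-to-background contrast of five
noise standard deviations the matched mean radius must still land within
one pixel. The test suite runs 20 full-size scenes (ten per microwell
preset, plus noisy variants) — enough fields for stable count and radius
statistics while keeping the default run fast.

## Known limitations

* Single-aggregate, monodisperse-kernel coalescence: no polydisperse
  Smoluchowski size spectrum, no spatial structure inside the droplet.
* No re-entry of escaped motifs in later rounds; the PEG phase is a
  perfect sink.
* No temperature dependence inside a round; hybridisation thermodynamics
  are entirely absent.
* The experimentally observed per-well statistics of real devices (e.g.
  occupancy slightly above one at high DNA concentration) are emulated
  structurally by the generator's occupancy distribution, not derived
  from the kinetics.
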