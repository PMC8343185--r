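## Seeded evaluation that leaves the caller's RNG stream untouched.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## Normal draws truncated to (lo, hi]; resamples, then clamps as a last
## resort so pathological (mean, sd) pairs cannot loop forever.
rnorm_trunc <- function(n, mean, sd, lo = 0, hi = Inf) {
  x <- stats::rnorm(n, mean, sd)
  for (i in 1:20) {
    bad <- x <= lo | x > hi
    if (!any(bad)) break
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  pmin(pmax(x, lo + 1e-12), hi)
}

#' Synthetic microwell-array scene specification
#'
#' Describes one two-channel confocal field of a microwell array: a square
#' lattice of wells, one bright dextran-channel droplet disc per well, 0+
#' bright DNA-channel hydrogel particles per well, a diffuse unbound-DNA
#' background inside each droplet, and sensor noise. Defaults emulate the
#' imaging setup the quantification pipeline targets: a 1.8 mm x 1.8 mm
#' field at 3.5 um/pixel.
#'
#' @param field_size Side of the square field, meters. Default 1.8e-3.
#' @param pixel_size Pixel pitch, meters. Default 3.5e-6.
#' @param lattice_pitch Well lattice pitch, meters. Default 150e-6.
#' @param well_diameter Nominal well diameter, meters. Default 100e-6.
#' @param droplet_radius `c(mean, sd)` of the droplet disc radius, meters.
#' @param particle_count_probs Named numeric vector of per-well particle
#'   count probabilities; names are the counts (`"0"`, `"1"`, ...). Must
#'   sum to 1. Default `c("0" = 0.02, "1" = 0.93, "2" = 0.05)`, emulating
#'   near-one occupancy with a small excess.
#' @param particle_radius `c(mean, sd)` of the particle radius, meters.
#' @param particle_placement `"rim"` (particle centre on the droplet rim
#'   circle, emulating interfacial accumulation), `"center"` (droplet
#'   centre, the convection-driven single-aggregate case), or `"uniform"`
#'   (uniform inside the droplet disc, for bulk-like scenes).
#' @param intensities Named list of channel levels in `[0, 1]`: `dex_bg`,
#'   `dex_fg` (droplet disc), `dna_bg` (outside droplets), `dna_droplet`
#'   (diffuse unbound DNA inside droplets), `dna_particle`.
#' @param noise_sd Gaussian read-noise standard deviation (intensity
#'   units). 0 disables.
#' @param shot_noise Add Poisson shot noise before read noise?
#' @param shot_scale Photons per intensity unit for the shot-noise model.
#' @param seed Integer root seed; every stochastic step derives its stream
#'   from it, so a spec renders identically every time.
#' @return An object of class `array_spec`.
#' @export
array_spec <- function(field_size = 1.8e-3,
                       pixel_size = 3.5e-6,
                       lattice_pitch = 150e-6,
                       well_diameter = 100e-6,
                       droplet_radius = c(40e-6, 5e-6),
                       particle_count_probs = c("0" = 0.02, "1" = 0.93,
                                                "2" = 0.05),
                       particle_radius = c(7e-6, 1.5e-6),
                       particle_placement = c("rim", "center", "uniform"),
                       intensities = list(dex_bg = 0.05, dex_fg = 0.75,
                                          dna_bg = 0.02, dna_droplet = 0.12,
                                          dna_particle = 0.85),
                       noise_sd = 0, shot_noise = FALSE, shot_scale = 1e3,
                       seed = 1L) {
  particle_placement <- match.arg(particle_placement)
  if (pixel_size <= 0 || field_size <= 0 || lattice_pitch <= 0 ||
      well_diameter <= 0)
    stop("all dimensions must be positive")
  if (pixel_size >= well_diameter)
    stop("`pixel_size` must be smaller than `well_diameter`")
  if (lattice_pitch < well_diameter)
    stop("`lattice_pitch` must be >= `well_diameter`")
  if (is.null(names(particle_count_probs)) ||
      anyNA(suppressWarnings(as.integer(names(particle_count_probs)))))
    stop("`particle_count_probs` must be named by integer counts")
  if (abs(sum(particle_count_probs) - 1) > 1e-8)
    stop("`particle_count_probs` must sum to 1")
  if (any(particle_count_probs < 0))
    stop("`particle_count_probs` must be non-negative")
  if (any(droplet_radius <= 0) || any(particle_radius[1] <= 0))
    stop("radius distribution parameters must be positive")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  need <- c("dex_bg", "dex_fg", "dna_bg", "dna_droplet", "dna_particle")
  if (!all(need %in% names(intensities)))
    stop("`intensities` must name: ", paste(need, collapse = ", "))
  structure(
    list(field_size = field_size, pixel_size = pixel_size,
         lattice_pitch = lattice_pitch, well_diameter = well_diameter,
         droplet_radius = droplet_radius,
         particle_count_probs = particle_count_probs,
         particle_radius = particle_radius,
         particle_placement = particle_placement,
         intensities = intensities,
         noise_sd = noise_sd, shot_noise = shot_noise,
         shot_scale = shot_scale, seed = as.integer(seed)),
    class = "array_spec")
}

#' Sample the ground truth of a synthetic scene
#'
#' Places wells on a square lattice clipped to the field (lattice centred
#' in the field), samples one droplet disc per well, then samples particle
#' counts, radii and positions. Deterministic for a fixed `spec$seed`.
#'
#' Placement rules: with `"rim"` the particle centre lies exactly on the
#' droplet rim circle at a random angle (angles within a well are
#' re-sampled until neighbouring particles do not touch); `"center"` puts a
#' single aggregate at the droplet centre; `"uniform"` scatters centres
#' uniformly over the droplet disc. Droplet radii are truncated so
#' neighbouring droplets can never merge; particle radii so a rim particle
#' stays inside its lattice cell.
#'
#' @param spec An [array_spec()].
#' @return An object of class `gelwell_truth`: a list with data.frames
#'   `wells` (`well_id, cx_m, cy_m, droplet_r_m, n_particles`) and
#'   `particles` (`particle_id, well_id, px_m, py_m, particle_r_m`), plus
#'   the generating `spec`.
#' @export
generate_truth <- function(spec) {
  stopifnot(inherits(spec, "array_spec"))
  n_side <- floor(spec$field_size / spec$lattice_pitch)
  if (n_side < 1) stop("field too small for one lattice cell")
  offset <- (spec$field_size - n_side * spec$lattice_pitch) / 2 +
    spec$lattice_pitch / 2
  centers <- offset + (seq_len(n_side) - 1) * spec$lattice_pitch
  wells <- expand.grid(cx_m = centers, cy_m = centers,
                       KEEP.OUT.ATTRS = FALSE)
  ## raster order: row by row (y), then x
  wells <- wells[order(wells$cy_m, wells$cx_m), ]
  n_wells <- nrow(wells)
  wells$well_id <- seq_len(n_wells)

  max_dr <- spec$lattice_pitch / 2 - spec$pixel_size
  wells$droplet_r_m <- with_seed(spec$seed, {
    rnorm_trunc(n_wells, spec$droplet_radius[1], spec$droplet_radius[2],
                lo = 2 * spec$pixel_size, hi = max_dr)
  })

  counts <- with_seed(spec$seed + 1L, {
    ks <- as.integer(names(spec$particle_count_probs))
    sample(ks, n_wells, replace = TRUE, prob = spec$particle_count_probs)
  })
  wells$n_particles <- counts

  n_part <- sum(counts)
  particles <- data.frame(
    particle_id = seq_len(n_part),
    well_id = rep(wells$well_id, counts),
    px_m = numeric(n_part), py_m = numeric(n_part),
    particle_r_m = numeric(n_part))

  if (n_part > 0) {
    dr <- wells$droplet_r_m[match(particles$well_id, wells$well_id)]
    max_pr <- switch(spec$particle_placement,
      rim     = spec$lattice_pitch / 2 - dr - spec$pixel_size,
      center  = pmin(dr, spec$lattice_pitch / 2) - spec$pixel_size,
      uniform = dr / 2)
    particles$particle_r_m <- with_seed(spec$seed + 2L, {
      rnorm_trunc(n_part, spec$particle_radius[1], spec$particle_radius[2],
                  lo = spec$pixel_size / 2, hi = pmax(max_pr, spec$pixel_size))
    })
    cx <- wells$cx_m[match(particles$well_id, wells$well_id)]
    cy <- wells$cy_m[match(particles$well_id, wells$well_id)]
    with_seed(spec$seed + 3L, {
      if (spec$particle_placement == "center") {
        particles$px_m <- cx
        particles$py_m <- cy
      } else if (spec$particle_placement == "uniform") {
        rad <- pmax(dr - particles$particle_r_m, 0) * sqrt(stats::runif(n_part))
        th <- stats::runif(n_part, 0, 2 * pi)
        particles$px_m <- cx + rad * cos(th)
        particles$py_m <- cy + rad * sin(th)
      } else {  # rim
        for (w in wells$well_id[counts > 0]) {
          idx <- which(particles$well_id == w)
          rw <- dr[idx[1]]
          th <- stats::runif(length(idx), 0, 2 * pi)
          ## keep same-well rim particles from touching (chord > r_i + r_j)
          if (length(idx) > 1) {
            for (try in 1:50) {
              chord <- 2 * rw * sin(abs(outer(th, th, "-")) / 2)
              need <- outer(particles$particle_r_m[idx],
                            particles$particle_r_m[idx], "+") +
                2 * spec$pixel_size
              diag(chord) <- Inf
              if (all(chord > need)) break
              th <- stats::runif(length(idx), 0, 2 * pi)
              if (try == 50)  # deterministic fallback: spread evenly
                th <- 2 * pi * (seq_along(idx) - 1) / length(idx)
            }
          }
          particles$px_m[idx] <- cx[idx] + rw * cos(th)
          particles$py_m[idx] <- cy[idx] + rw * sin(th)
        }
      }
    })
  }

  structure(list(wells = wells[, c("well_id", "cx_m", "cy_m",
                                   "droplet_r_m", "n_particles")],
                 particles = particles, spec = spec),
            class = "gelwell_truth")
}

## Composite an anti-aliased disc onto image `img` (matrix, row = y).
## Coverage ramps linearly over one pixel around the rim, so the summed
## coverage approximates the true disc area to sub-pixel accuracy.
composite_disc <- function(img, cx, cy, radius, level, pixel_size) {
  n_row <- nrow(img); n_col <- ncol(img)
  half <- (radius + pixel_size) / pixel_size
  ci <- cy / pixel_size + 0.5  # fractional row index of the centre
  cj <- cx / pixel_size + 0.5
  rows <- max(1, floor(ci - half)):min(n_row, ceiling(ci + half))
  cols <- max(1, floor(cj - half)):min(n_col, ceiling(cj + half))
  if (length(rows) == 0 || length(cols) == 0) return(img)
  ## pixel-centre physical coordinates: (index - 0.5) * pixel_size
  yy <- (rows - 0.5) * pixel_size
  xx <- (cols - 0.5) * pixel_size
  d <- sqrt(outer((yy - cy)^2, (xx - cx)^2, "+"))
  cov <- pmin(1, pmax(0, (radius - d) / pixel_size + 0.5))
  img[rows, cols] <- img[rows, cols] * (1 - cov) + level * cov
  img
}

#' Render the two fluorescence channels of a scene
#'
#' Rasterises the ground truth into two grayscale images on a
#' `round(field_size / pixel_size)` square grid (514 x 514 at defaults).
#' The dextran channel is background plus one bright disc per droplet; the
#' DNA channel is background, a dim droplet-wide level for unbound DNA,
#' and a bright disc per hydrogel particle. Discs are anti-aliased with
#' linear sub-pixel edge coverage. No noise is added here; see
#' [add_noise()].
#'
#' @param truth A [generate_truth()] result.
#' @param spec The generating [array_spec()] (defaults to `truth$spec`).
#' @return A list with matrices `dex` and `dna` (rows = image y, columns =
#'   image x, intensities in `[0, 1]`).
#' @export
render_channels <- function(truth, spec = truth$spec) {
  stopifnot(inherits(truth, "gelwell_truth"))
  n_px <- round(spec$field_size / spec$pixel_size)
  lv <- spec$intensities
  dex <- matrix(lv$dex_bg, n_px, n_px)
  dna <- matrix(lv$dna_bg, n_px, n_px)
  for (i in seq_len(nrow(truth$wells))) {
    w <- truth$wells[i, ]
    dex <- composite_disc(dex, w$cx_m, w$cy_m, w$droplet_r_m,
                          lv$dex_fg, spec$pixel_size)
    dna <- composite_disc(dna, w$cx_m, w$cy_m, w$droplet_r_m,
                          lv$dna_droplet, spec$pixel_size)
  }
  for (i in seq_len(nrow(truth$particles))) {
    p <- truth$particles[i, ]
    dna <- composite_disc(dna, p$px_m, p$py_m, p$particle_r_m,
                          lv$dna_particle, spec$pixel_size)
  }
  list(dex = dex, dna = dna)
}

#' Add sensor noise to a rendered channel
#'
#' Optional Poisson shot noise (at `shot_scale` photons per intensity
#' unit) followed by seeded Gaussian read noise, clipped at zero.
#' Identical `(spec$seed, stream)` pairs give identical output.
#'
#' @param image Numeric matrix from [render_channels()].
#' @param spec The [array_spec()] holding `noise_sd`, `shot_noise`,
#'   `shot_scale` and the root seed.
#' @param stream Integer stream offset so different channels of one scene
#'   receive independent noise.
#' @return The noisy image matrix.
#' @export
add_noise <- function(image, spec, stream = 0L) {
  stopifnot(is.matrix(image), inherits(spec, "array_spec"))
  if (spec$noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (!spec$shot_noise && spec$noise_sd == 0) return(image)
  with_seed(spec$seed + 100L + stream, {
    out <- image
    if (spec$shot_noise)
      out <- matrix(stats::rpois(length(out), out * spec$shot_scale) /
                      spec$shot_scale, nrow(out), ncol(out))
    if (spec$noise_sd > 0)
      out <- out + matrix(stats::rnorm(length(out), 0, spec$noise_sd),
                          nrow(out), ncol(out))
    pmax(out, 0)
  })
}

#' Generate, render and degrade a full scene
#'
#' Convenience wrapper chaining [generate_truth()], [render_channels()]
#' and [add_noise()] (dextran channel on noise stream 1, DNA on stream 2).
#'
#' @param spec An [array_spec()].
#' @return A list with `truth`, `dex`, `dna`.
#' @export
render_scene <- function(spec) {
  truth <- generate_truth(spec)
  ch <- render_channels(truth, spec)
  list(truth = truth,
       dex = add_noise(ch$dex, spec, stream = 1L),
       dna = add_noise(ch$dna, spec, stream = 2L))
}

#' Scene presets for the benchmark conditions
#'
#' Parameter bundles emulating the three qualitative imaging conditions the
#' pipeline is built around:
#' \describe{
#'   \item{`microwell_50um`}{50-um wells on a 100-um pitch: tight droplet
#'     size distribution tracking the well, near-one particle occupancy at
#'     the rim, particle radii ~N(5.4, 0.6) um.}
#'   \item{`microwell_100um`}{100-um wells on a 150-um pitch: droplets
#'     smaller than the well (radius ~N(40, 5) um, i.e. 70-90 um
#'     diameters), rim-bound particles ~N(7, 1.5) um.}
#'   \item{`single_phase`}{no droplet structure (dextran everywhere):
#'     many small particles (~N(1.5, 0.4) um) scattered uniformly, with a
#'     high diffuse DNA background.}
#'   \item{`two_phase_bulk`}{bulk two-phase emulsion: polydisperse
#'     droplets and polydisperse particles (~N(5, 2.5) um), 1-3 per
#'     droplet.}
#' }
#'
#' @param name Preset name.
#' @param seed Root seed passed to [array_spec()].
#' @return An [array_spec()].
#' @export
scene_preset <- function(name = c("microwell_50um", "microwell_100um",
                                  "single_phase", "two_phase_bulk"),
                         seed = 1L) {
  name <- match.arg(name)
  switch(name,
    microwell_50um = array_spec(
      lattice_pitch = 100e-6, well_diameter = 50e-6,
      droplet_radius = c(25e-6, 1e-6),
      particle_radius = c(5.4e-6, 0.6e-6),
      particle_placement = "rim", seed = seed),
    microwell_100um = array_spec(
      lattice_pitch = 150e-6, well_diameter = 100e-6,
      droplet_radius = c(40e-6, 5e-6),
      particle_radius = c(7e-6, 1.5e-6),
      particle_placement = "rim", seed = seed),
    single_phase = array_spec(
      lattice_pitch = 150e-6, well_diameter = 149e-6,
      droplet_radius = c(70e-6, 2e-6),
      particle_count_probs = c("3" = 0.2, "4" = 0.3, "5" = 0.3, "6" = 0.2),
      particle_radius = c(1.5e-6, 0.4e-6),
      particle_placement = "uniform",
      intensities = list(dex_bg = 0.3, dex_fg = 0.6, dna_bg = 0.05,
                         dna_droplet = 0.35, dna_particle = 0.85),
      seed = seed),
    two_phase_bulk = array_spec(
      lattice_pitch = 150e-6, well_diameter = 100e-6,
      droplet_radius = c(35e-6, 10e-6),
      particle_count_probs = c("1" = 0.4, "2" = 0.4, "3" = 0.2),
      particle_radius = c(5e-6, 2.5e-6),
      particle_placement = "uniform", seed = seed))
}
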