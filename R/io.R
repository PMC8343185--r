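#' Write a synthetic scene to disk
#'
#' Writes one 16-bit grayscale TIFF per channel (`<prefix>_dex.tif`,
#' `<prefix>_dna.tif`), the ground truth as CSV (`<prefix>_truth.csv`, one
#' row per particle, wells without particles carried with empty particle
#' fields) and the generating spec as JSON (`<prefix>_spec.json`).
#' Intensities are clipped to `[0, 1]` and quantised to 16 bits; output is
#' byte-stable for identical inputs.
#'
#' Truth CSV columns:
#' `well_id,cx_um,cy_um,droplet_r_um,particle_id,px_um,py_um,particle_r_um`
#' (coordinates and radii in micrometers).
#'
#' @param channels List with matrices `dex` and `dna` (see
#'   [render_channels()]).
#' @param truth A [generate_truth()] result.
#' @param path_prefix Output path prefix.
#' @return Invisibly, the four file paths written.
#' @export
write_dataset <- function(channels, truth, path_prefix) {
  stopifnot(inherits(truth, "gelwell_truth"),
            is.matrix(channels$dex), is.matrix(channels$dna))
  dir <- dirname(path_prefix)
  if (!dir.exists(dir))
    stop("output directory does not exist: ", dir)
  paths <- paste0(path_prefix, c("_dex.tif", "_dna.tif",
                                 "_truth.csv", "_spec.json"))
  tiff::writeTIFF(pmin(pmax(channels$dex, 0), 1), paths[1],
                  bits.per.sample = 16, compression = "none")
  tiff::writeTIFF(pmin(pmax(channels$dna, 0), 1), paths[2],
                  bits.per.sample = 16, compression = "none")

  wells <- truth$wells
  parts <- truth$particles
  tab <- merge(wells[, c("well_id", "cx_m", "cy_m", "droplet_r_m")],
               parts, by = "well_id", all.x = TRUE, sort = TRUE)
  out <- data.frame(
    well_id = tab$well_id,
    cx_um = tab$cx_m * 1e6, cy_um = tab$cy_m * 1e6,
    droplet_r_um = tab$droplet_r_m * 1e6,
    particle_id = tab$particle_id,
    px_um = tab$px_m * 1e6, py_um = tab$py_m * 1e6,
    particle_r_um = tab$particle_r_m * 1e6)
  out <- out[order(out$well_id, out$particle_id), ]
  utils::write.csv(out, paths[3], row.names = FALSE, na = "")

  sp <- unclass(truth$spec)
  ## named atomic vectors serialise as bare arrays; keep the count keys
  sp$particle_count_probs <- as.list(sp$particle_count_probs)
  jsonlite::write_json(sp, paths[4], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Read a scene written by [write_dataset()]
#'
#' @param path_prefix The prefix used at write time.
#' @return A list with `dex`, `dna` (matrices), `truth` (a
#'   `gelwell_truth`) and `spec` (an [array_spec()]).
#' @export
read_dataset <- function(path_prefix) {
  paths <- paste0(path_prefix, c("_dex.tif", "_dna.tif",
                                 "_truth.csv", "_spec.json"))
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("missing dataset files: ", paste(missing, collapse = ", "))
  dex <- tiff::readTIFF(paths[1])
  dna <- tiff::readTIFF(paths[2])
  tab <- utils::read.csv(paths[3])

  wells <- unique(tab[, c("well_id", "cx_um", "cy_um", "droplet_r_um")])
  wells <- data.frame(well_id = wells$well_id,
                      cx_m = wells$cx_um * 1e-6,
                      cy_m = wells$cy_um * 1e-6,
                      droplet_r_m = wells$droplet_r_um * 1e-6)
  keep <- !is.na(tab$particle_id)
  particles <- data.frame(
    particle_id = tab$particle_id[keep],
    well_id = tab$well_id[keep],
    px_m = tab$px_um[keep] * 1e-6,
    py_m = tab$py_um[keep] * 1e-6,
    particle_r_m = tab$particle_r_um[keep] * 1e-6)
  particles <- particles[order(particles$particle_id), ]
  rownames(particles) <- rownames(wells) <- NULL
  wells$n_particles <- as.integer(
    tabulate(particles$well_id, nbins = max(wells$well_id)))[wells$well_id]

  sp <- jsonlite::read_json(paths[4], simplifyVector = TRUE)
  spec <- array_spec(
    field_size = sp$field_size, pixel_size = sp$pixel_size,
    lattice_pitch = sp$lattice_pitch, well_diameter = sp$well_diameter,
    droplet_radius = sp$droplet_radius,
    particle_count_probs = unlist(sp$particle_count_probs),
    particle_radius = sp$particle_radius,
    particle_placement = sp$particle_placement,
    intensities = as.list(sp$intensities),
    noise_sd = sp$noise_sd, shot_noise = sp$shot_noise,
    shot_scale = sp$shot_scale, seed = sp$seed)

  truth <- structure(list(wells = wells, particles = particles,
                          spec = spec),
                     class = "gelwell_truth")
  list(dex = dex, dna = dna, truth = truth, spec = spec)
}
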