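#' Global Otsu threshold of a grayscale image
#'
#' Computes the between-class-variance-maximising threshold on a 256-bin
#' histogram of intensities clipped to `[0, 1]`.
#'
#' @param image Numeric matrix.
#' @return The threshold intensity.
#' @export
auto_threshold <- function(image) {
  stopifnot(is.matrix(image), length(image) > 0)
  EBImage::otsu(EBImage::Image(pmin(pmax(image, 0), 1)),
                range = c(0, 1), levels = 256)
}

#' Threshold and label an image
#'
#' Foreground is every pixel with intensity `>= threshold` (ties count as
#' foreground); connected foreground components are labelled `1..n` in
#' deterministic raster order (components ordered by their first pixel,
#' scanning rows top to bottom and columns left to right).
#'
#' Labelling uses 4-connected flood fill; for `connectivity = 8` (the
#' ImageJ Analyze-Particles convention, the default) components touching
#' diagonally are then merged via graph components.
#'
#' @param image Numeric matrix (rows = image y).
#' @param threshold Intensity threshold, or `NULL` for [auto_threshold()].
#' @param connectivity 4 or 8.
#' @return Integer label matrix of the same dimensions (0 = background),
#'   with the threshold used in attribute `"threshold"`.
#' @export
segment <- function(image, threshold = NULL, connectivity = c(8, 4)) {
  if (!is.matrix(image) || length(image) == 0)
    stop("`image` must be a non-empty numeric matrix")
  connectivity <- match.arg(as.character(connectivity[1]), c("8", "4"))
  if (is.null(threshold)) threshold <- auto_threshold(image)
  if (!is.finite(threshold)) stop("`threshold` must be finite")
  mask <- image >= threshold
  labels <- matrix(as.integer(EBImage::bwlabel(mask * 1L)),
                   nrow(image), ncol(image))
  n_lab <- max(labels)
  if (connectivity == "8" && n_lab > 1) {
    nr <- nrow(labels); nc <- ncol(labels)
    ## diagonal neighbour pairs with two distinct positive labels
    dr <- cbind(as.vector(labels[-nr, -nc]), as.vector(labels[-1, -1]))
    dl <- cbind(as.vector(labels[-nr, -1]), as.vector(labels[-1, -nc]))
    edges <- rbind(dr, dl)
    edges <- edges[edges[, 1] > 0 & edges[, 2] > 0 &
                     edges[, 1] != edges[, 2], , drop = FALSE]
    if (nrow(edges) > 0) {
      g <- igraph::make_graph(as.vector(t(edges)), n = n_lab,
                              directed = FALSE)
      map <- igraph::components(g)$membership
      labels[labels > 0] <- map[labels[labels > 0]]
    }
  }
  ## deterministic relabel: order components by first pixel in row-major
  ## raster order (top row first, then left to right)
  pos <- which(labels > 0)
  if (length(pos)) {
    row <- (pos - 1) %% nrow(labels) + 1
    col <- (pos - 1) %/% nrow(labels) + 1
    raster_key <- (row - 1) * ncol(labels) + col
    lab <- labels[pos]
    first <- tapply(raster_key, lab, min)
    new_id <- integer(max(lab))
    new_id[as.integer(names(first))] <- rank(first, ties.method = "first")
    labels[pos] <- new_id[lab]
  }
  attr(labels, "threshold") <- threshold
  labels
}

#' Measure labelled components
#'
#' One record per connected component: pixel count, physical area,
#' projected-circle equivalent radius and centroid (unweighted mean of
#' pixel centres). Components smaller than `min_area` are dropped — the
#' sub-square-micrometre filter that keeps single-pixel noise out of the
#' particle statistics.
#'
#' @param labels Integer label matrix from [segment()].
#' @param pixel_size_um Pixel pitch in micrometers.
#' @param min_area Minimum area in um^2 (default 1); components with
#'   `area < min_area` are excluded.
#' @param channel Optional channel tag (`"dextran"` or `"dna"`) carried
#'   into the records.
#' @return A data.frame with columns `channel`, `label`, `pixel_count`,
#'   `area_um2`, `radius_um`, `cx_um`, `cy_um`, ordered by label.
#' @export
measure <- function(labels, pixel_size_um, min_area = 1,
                    channel = NA_character_) {
  stopifnot(is.matrix(labels), pixel_size_um > 0)
  pos <- which(labels > 0)
  empty <- data.frame(channel = character(), label = integer(),
                      pixel_count = integer(), area_um2 = numeric(),
                      radius_um = numeric(), cx_um = numeric(),
                      cy_um = numeric())
  if (length(pos) == 0) return(empty)
  lab <- labels[pos]
  row <- (pos - 1) %% nrow(labels) + 1
  col <- (pos - 1) %/% nrow(labels) + 1
  counts <- tabulate(lab)
  ids <- which(counts > 0)
  ## pixel-centre convention: physical = (index - 0.5) * pixel_size
  cx <- tapply((col - 0.5) * pixel_size_um, lab, mean)[as.character(ids)]
  cy <- tapply((row - 0.5) * pixel_size_um, lab, mean)[as.character(ids)]
  area <- counts[ids] * pixel_size_um^2
  rec <- data.frame(channel = channel, label = ids,
                    pixel_count = counts[ids], area_um2 = area,
                    radius_um = radius_from_area(area),
                    cx_um = as.numeric(cx), cy_um = as.numeric(cy))
  rec <- rec[rec$area_um2 >= min_area, , drop = FALSE]
  rownames(rec) <- NULL
  rec
}

#' Equivalent radius of a projected object
#'
#' `r = sqrt(area / pi)`: the radius of the circle with the measured
#' projected area. The same formula serves both object classes — a
#' cylinder-shaped droplet and a spherical particle both present a
#' circular cross-section in a single confocal plane.
#'
#' @param area Area(s) in um^2 (>= 0).
#' @param mode Only `"projected_circle"` is defined.
#' @return Radius in um.
#' @export
radius_from_area <- function(area, mode = "projected_circle") {
  mode <- match.arg(mode)
  if (any(!is.finite(area)) || any(area < 0))
    stop("`area` must be finite and >= 0")
  sqrt(area / pi)
}

#' Particles per well
#'
#' The per-image occupancy statistic: number of detected DNA hydrogel
#' particles divided by number of detected dextran droplets.
#'
#' @param dna_records,dextran_records Record tables from [measure()].
#' @return A single ratio.
#' @export
particles_per_well <- function(dna_records, dextran_records) {
  if (nrow(dextran_records) == 0)
    stop("no dextran droplets detected; particles-per-well is undefined")
  nrow(dna_records) / nrow(dextran_records)
}

#' Distribution statistics of a record table
#'
#' @param records A [measure()] table.
#' @return A list with `n`, `mean_radius` and `sd_radius` (um; sample
#'   standard deviation, `NA` when undefined).
#' @export
summarize_records <- function(records) {
  n <- nrow(records)
  list(n = n,
       mean_radius = if (n > 0) mean(records$radius_um) else NA_real_,
       sd_radius = if (n > 1) stats::sd(records$radius_um) else NA_real_)
}

#' Match detections to ground truth
#'
#' Greedy nearest-centroid matching: repeatedly pair the globally closest
#' unmatched (detection, truth) centroids while their distance is below
#' `max_dist_um`. Invariant to the ordering of the input records.
#'
#' @param records A [measure()] table.
#' @param truth A [generate_truth()] result.
#' @param channel `"dna"` matches against truth particles, `"dextran"`
#'   against truth droplets.
#' @param max_dist_um Maximum centroid distance for a match.
#' @return A list with `n_detected`, `n_truth`, `n_matched`, `precision`,
#'   `recall`, `mean_abs_radius_error_um`, and a `matches` data.frame
#'   (`record_label`, `truth_id`, `dist_um`, `radius_error_um`).
#' @export
match_to_truth <- function(records, truth, channel = c("dna", "dextran"),
                           max_dist_um = 10) {
  stopifnot(inherits(truth, "gelwell_truth"))
  channel <- match.arg(channel)
  if (channel == "dna") {
    tx <- truth$particles$px_m * 1e6
    ty <- truth$particles$py_m * 1e6
    tr <- truth$particles$particle_r_m * 1e6
    tid <- truth$particles$particle_id
  } else {
    tx <- truth$wells$cx_m * 1e6
    ty <- truth$wells$cy_m * 1e6
    tr <- truth$wells$droplet_r_m * 1e6
    tid <- truth$wells$well_id
  }
  n_rec <- nrow(records); n_tru <- length(tx)
  matches <- data.frame(record_label = integer(), truth_id = integer(),
                        dist_um = numeric(), radius_error_um = numeric())
  if (n_rec > 0 && n_tru > 0) {
    d <- sqrt(outer(records$cx_um, tx, "-")^2 +
                outer(records$cy_um, ty, "-")^2)
    repeat {
      m <- which.min(d)
      if (length(m) == 0 || d[m] > max_dist_um) break
      i <- (m - 1) %% n_rec + 1
      j <- (m - 1) %/% n_rec + 1
      matches[nrow(matches) + 1, ] <- list(records$label[i], tid[j], d[m],
                                           records$radius_um[i] - tr[j])
      d[i, ] <- Inf
      d[, j] <- Inf
      if (all(!is.finite(d))) break
    }
  }
  list(n_detected = n_rec, n_truth = n_tru, n_matched = nrow(matches),
       precision = if (n_rec > 0) nrow(matches) / n_rec else NA_real_,
       recall = if (n_tru > 0) nrow(matches) / n_tru else 0,
       mean_abs_radius_error_um =
         if (nrow(matches) > 0) mean(abs(matches$radius_error_um))
         else NA_real_,
       matches = matches)
}

#' Quantify a two-channel scene
#'
#' Full pipeline over one field: channel-specific thresholding,
#' labelling, area filtering, per-channel statistics and the
#' particles-per-well ratio.
#'
#' @param dex,dna Channel matrices.
#' @param pixel_size_um Pixel pitch in micrometers. Default 3.5.
#' @param dex_threshold,dna_threshold Explicit uniform thresholds, or
#'   `NULL` for per-channel Otsu.
#' @param min_area Area filter in um^2 (default 1).
#' @param connectivity 4 or 8 (default 8).
#' @return A list with `records` (both channels, row-bound), `droplets`,
#'   `particles` (per-channel tables), `summary` (per-channel stats plus
#'   `particles_per_well`) and `thresholds`.
#' @export
analyze_scene <- function(dex, dna, pixel_size_um = 3.5,
                          dex_threshold = NULL, dna_threshold = NULL,
                          min_area = 1, connectivity = 8) {
  lab_dex <- segment(dex, dex_threshold, connectivity)
  lab_dna <- segment(dna, dna_threshold, connectivity)
  droplets <- measure(lab_dex, pixel_size_um, min_area, channel = "dextran")
  particles <- measure(lab_dna, pixel_size_um, min_area, channel = "dna")
  list(records = rbind(droplets, particles),
       droplets = droplets, particles = particles,
       summary = list(
         dextran = summarize_records(droplets),
         dna = summarize_records(particles),
         particles_per_well =
           if (nrow(droplets) > 0) particles_per_well(particles, droplets)
           else NA_real_),
       thresholds = c(dextran = attr(lab_dex, "threshold"),
                      dna = attr(lab_dna, "threshold")))
}
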