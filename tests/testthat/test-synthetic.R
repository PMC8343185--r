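test_that("wells tile the field on a centred square lattice", {
  spec <- array_spec(field_size = 1.8e-3, lattice_pitch = 150e-6)
  truth <- generate_truth(spec)
  expect_equal(nrow(truth$wells), 144)  # floor(1800/150)^2
  expect_true(all(truth$wells$cx_m > 0 & truth$wells$cx_m < 1.8e-3))

  # degenerate spec: pitch must accommodate the well
  expect_error(array_spec(lattice_pitch = 80e-6, well_diameter = 100e-6),
               "lattice_pitch")
})

test_that("ground truth is deterministic in the seed and respects the
           occupancy distribution", {
  spec <- small_scene_spec(seed = 5L)
  t1 <- generate_truth(spec)
  t2 <- generate_truth(spec)
  expect_identical(t1$wells, t2$wells)
  expect_identical(t1$particles, t2$particles)
  t3 <- generate_truth(small_scene_spec(seed = 6L))
  expect_false(identical(t1$wells$droplet_r_m, t3$wells$droplet_r_m))

  # a point-mass occupancy of one gives exactly one particle per well
  one <- generate_truth(small_scene_spec(
    particle_count_probs = c("1" = 1)))
  expect_equal(nrow(one$particles), nrow(one$wells))
  expect_equal(one$wells$n_particles, rep(1L, nrow(one$wells)))

  # counts column always matches the particle list
  counts <- table(factor(t1$particles$well_id,
                         levels = t1$wells$well_id))
  expect_equal(as.integer(counts), t1$wells$n_particles)
})

test_that("rim placement puts particle centres on the droplet rim circle,
           centre placement at the droplet centre", {
  rim <- generate_truth(small_scene_spec(particle_placement = "rim"))
  w <- rim$wells[match(rim$particles$well_id, rim$wells$well_id), ]
  d <- sqrt((rim$particles$px_m - w$cx_m)^2 +
              (rim$particles$py_m - w$cy_m)^2)
  expect_equal(d, w$droplet_r_m, tolerance = 1e-12)

  ctr <- generate_truth(small_scene_spec(particle_placement = "center"))
  w <- ctr$wells[match(ctr$particles$well_id, ctr$wells$well_id), ]
  expect_equal(ctr$particles$px_m, w$cx_m)
  expect_equal(ctr$particles$py_m, w$cy_m)

  uni <- generate_truth(small_scene_spec(particle_placement = "uniform"))
  w <- uni$wells[match(uni$particles$well_id, uni$wells$well_id), ]
  d <- sqrt((uni$particles$px_m - w$cx_m)^2 +
              (uni$particles$py_m - w$cy_m)^2)
  expect_true(all(d <= w$droplet_r_m))
})

test_that("anti-aliased disc coverage matches 10x supersampled
           rasterisation", {
  px <- 3.5e-6
  for (r_um in c(7, 3.5, 12.25)) {
    r <- r_um * 1e-6
    img <- gelwell:::composite_disc(matrix(0, 40, 40),
                                    cx = 70e-6, cy = 70e-6,
                                    radius = r, level = 1, pixel_size = px)
    # brute-force oracle: 10x10 subsamples per pixel
    sub <- (seq_len(400) - 0.5) * px / 10
    inside <- outer((sub - 70e-6)^2, (sub - 70e-6)^2, "+") < r^2
    oracle_px <- sum(inside) / 100
    expect_lt(abs(sum(img) - oracle_px), 4)
    expect_lt(abs(sum(img) - pi * (r / px)^2), 4)
  }
})

test_that("rendering levels: particle-free wells peak at the droplet
           background and the signal is linear in intensity", {
  spec <- small_scene_spec(particle_count_probs = c("0" = 1))
  ch <- render_channels(generate_truth(spec))
  expect_equal(max(ch$dna), spec$intensities$dna_droplet)
  expect_equal(max(ch$dex), spec$intensities$dex_fg)

  # with zero backgrounds, doubling the particle level doubles the total
  base_int <- list(dex_bg = 0, dex_fg = 0.4, dna_bg = 0,
                   dna_droplet = 0, dna_particle = 0.4)
  dbl_int <- modifyList(base_int, list(dna_particle = 0.8, dex_fg = 0.8))
  s1 <- small_scene_spec(intensities = base_int)
  s2 <- small_scene_spec(intensities = dbl_int)
  truth <- generate_truth(s1)
  c1 <- render_channels(truth, s1)
  c2 <- render_channels(truth, s2)
  expect_equal(sum(c2$dna), 2 * sum(c1$dna))
  expect_equal(sum(c2$dex), 2 * sum(c1$dex))
})

test_that("sensor noise is seeded, optional and calibrated", {
  spec <- small_scene_spec(noise_sd = 0)
  img <- matrix(0.5, 150, 150)
  expect_identical(add_noise(img, spec), img)  # sd = 0 is the identity

  spec <- small_scene_spec(noise_sd = 0.05)
  n1 <- add_noise(img, spec)
  n2 <- add_noise(img, spec)
  expect_identical(n1, n2)  # same seed, same stream
  expect_false(identical(n1, add_noise(img, spec, stream = 1L)))

  # empirical sd on a flat region far from the clipping floor
  expect_equal(sd(n1 - img), 0.05, tolerance = 0.05)
  expect_true(all(add_noise(matrix(0.01, 100, 100), spec) >= 0))
})

test_that("datasets round-trip through TIFF + CSV + JSON byte-stably", {
  spec <- small_scene_spec(noise_sd = 0.02)
  scene <- render_scene(spec)
  dir <- withr::local_tempdir()
  prefix <- file.path(dir, "scene")
  ch <- list(dex = scene$dex, dna = scene$dna)
  paths <- write_dataset(ch, scene$truth, prefix)
  expect_true(all(file.exists(paths)))

  back <- read_dataset(prefix)
  # channels come back within one 16-bit quantisation step
  expect_equal(dim(back$dex), dim(ch$dex))
  expect_lt(max(abs(back$dex - pmin(pmax(ch$dex, 0), 1))), 1.01 / 65535)
  expect_lt(max(abs(back$dna - pmin(pmax(ch$dna, 0), 1))), 1.01 / 65535)
  # truth tables survive the micrometre round trip
  expect_equal(back$truth$wells$droplet_r_m, scene$truth$wells$droplet_r_m)
  expect_equal(back$truth$particles$px_m, scene$truth$particles$px_m)
  expect_equal(back$spec$seed, spec$seed)

  # byte stability: writing the same scene twice gives identical files
  prefix2 <- file.path(dir, "scene2")
  write_dataset(ch, scene$truth, prefix2)
  for (ext in c("_dex.tif", "_dna.tif", "_truth.csv", "_spec.json"))
    expect_identical(readBin(paste0(prefix, ext), "raw", 1e7),
                     readBin(paste0(prefix2, ext), "raw", 1e7))

  expect_error(write_dataset(ch, scene$truth,
                             file.path(dir, "no_such_dir", "x")),
               "directory")
})

test_that("scene presets encode the three imaging conditions
           structurally", {
  s50 <- scene_preset("microwell_50um")
  s100 <- scene_preset("microwell_100um")
  sp <- scene_preset("single_phase")
  bulk <- scene_preset("two_phase_bulk")

  # microwell presets: near-one occupancy, rim-bound particles
  for (s in list(s50, s100)) {
    mean_count <- sum(as.integer(names(s$particle_count_probs)) *
                        s$particle_count_probs)
    expect_equal(mean_count, 1, tolerance = 0.05)
    expect_equal(s$particle_placement, "rim")
  }
  # droplet radius spread (CV) is tighter in 50-um wells
  expect_lt(s50$droplet_radius[2] / s50$droplet_radius[1],
            s100$droplet_radius[2] / s100$droplet_radius[1])

  # single phase: many small particles, high diffuse DNA background
  mean_sp <- sum(as.integer(names(sp$particle_count_probs)) *
                   sp$particle_count_probs)
  expect_gt(mean_sp, 2)
  expect_lt(sp$particle_radius[1], s50$particle_radius[1])
  expect_gt(sp$intensities$dna_droplet, s50$intensities$dna_droplet)

  # bulk two-phase: polydisperse particles
  expect_gt(bulk$particle_radius[2] / bulk$particle_radius[1],
            s50$particle_radius[2] / s50$particle_radius[1])
})
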