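em <- test_endmembers()

test_that("zero cell density yields an empty scene on a clean background", {
  cfg <- small_scene_config(1, cell_density = c(follicle = 0, t_zone = 0,
                                                stroma = 0, other = 0),
                            noise_sd_frac = 0)
  sc <- generate_scene(cfg, em)
  expect_equal(nrow(sc$truth$cells), 0)
  expect_true(all(sc$truth$abundance == 0))
  expect_true(all(sc$cube$data == cfg$I0))
})

test_that("ground-truth class counts concentrate at the configured fractions", {
  # ~1000 follicle cells with bright fraction 0.8: the observed count must
  # fall in the central 99% binomial interval
  cfg <- scene_config(image_shape = c(600, 600), n_follicles = 1,
                      follicle_radius_px = 200, include_t_zone = FALSE,
                      other_strip_px = 0,
                      cell_density = c(follicle = 8, stroma = 0.5, other = 0),
                      bright_frac = c(follicle = 0.8, stroma = 0.3, other = 0),
                      seed = 9)
  sc <- generate_scene(cfg, em)
  fol <- sc$truth$cells[sc$truth$cells$region == "follicle", ]
  n <- nrow(fol)
  expect_gte(n, 800)
  k <- sum(fol$tet_class == "bright")
  expect_gte(k, qbinom(0.005, n, 0.8))
  expect_lte(k, qbinom(0.995, n, 0.8))
})

test_that("identical config and seed give bit-identical scenes", {
  s1 <- generate_scene(small_scene_config(4), em)
  s2 <- generate_scene(small_scene_config(4), em)
  expect_identical(s1$truth$cells, s2$truth$cells)
  expect_identical(s1$cube$data, s2$cube$data)
  expect_identical(s1$truth$region_mask$labels, s2$truth$region_mask$labels)
})

test_that("brightfield rendering follows the Beer-Lambert closed form", {
  # single pixel, one endmember s = (0.5, 1.0), a = 1, I0 = 255
  emx <- endmember_set("s", c(500, 600), rbind(c(0.5, 1)))
  cfg <- scene_config(image_shape = c(16, 16), n_follicles = 0,
                      other_strip_px = 0, noise_sd_frac = 0, I0 = 255,
                      channels = c(nuclear = "s", lineage = "s", tetraspanin = "s"))
  truth <- list(abundance = array(0, c(16, 16, 1), dimnames = list(NULL, NULL, "s")),
                region_mask = region_mask(matrix(3L, 16, 16)))
  truth$abundance[1, 1, 1] <- 1
  cube <- render_cube(truth, emx, cfg)
  expect_equal(cube$data[1, 1, ], 255 * 10^(-c(0.5, 1)), tolerance = 1e-12)
  # zero absorbance elsewhere -> white reference in every band
  expect_true(all(cube$data[2, , ] == 255))
})

test_that("fluorescence rendering is exactly linear with autofluorescence", {
  emx <- endmember_set(c("f1", "f2"), c(500, 600, 700),
                       rbind(c(1, 0.5, 0), c(0, 0.5, 1)), mode = "fluorescence")
  cfg <- scene_config(image_shape = c(16, 16), n_follicles = 0,
                      other_strip_px = 0, noise_sd_frac = 0,
                      mode = "fluorescence", af_amplitude = 2,
                      channels = c(nuclear = "f1", lineage = "f1", tetraspanin = "f2"))
  ab <- array(0, c(16, 16, 2), dimnames = list(NULL, NULL, c("f1", "f2")))
  ab[3, 4, ] <- c(2, 3)
  truth <- list(abundance = ab, region_mask = region_mask(matrix(3L, 16, 16)))
  cube <- render_cube(truth, emx, cfg)
  af <- 2 * spectracyte:::autofluorescence_spectrum(emx$wavelengths_nm)
  expect_equal(cube$data[3, 4, ],
               2 * emx$spectra[1, ] + 3 * emx$spectra[2, ] + af,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("mode mismatch between endmembers and config is an error", {
  cfg <- small_scene_config(1, mode = "fluorescence")
  expect_error(generate_scene(cfg, em), "mode mismatch")
})

test_that("excessive cell density fails with a clear message", {
  cfg <- small_scene_config(1, cell_density = c(follicle = 500, t_zone = 1,
                                                stroma = 1, other = 1))
  expect_error(generate_scene(cfg, em), "density too high")
})

test_that("ground truth is internally consistent", {
  sc <- generate_scene(small_scene_config(6), em)
  cells <- sc$truth$cells
  H <- nrow(sc$truth$region_mask$labels); W <- ncol(sc$truth$region_mask$labels)
  expect_true(all(cells$y >= 0.5 & cells$y <= H + 0.5))
  expect_true(all(cells$x >= 0.5 & cells$x <= W + 0.5))
  expect_identical(spectracyte:::region_at(sc$truth$region_mask, cells$y, cells$x),
                   cells$region)
  expect_true(all(sc$truth$abundance >= 0))
  expect_true(all(table(cells$region)[c("follicle", "stroma")] > 0))
})

test_that("nucleus overlap stays within the configured bound", {
  sc <- generate_scene(small_scene_config(8), em)
  cells <- sc$truth$cells
  d <- as.matrix(dist(cells[, c("y", "x")]))
  rsum <- outer(cells$radius, cells$radius, "+")
  sep <- d / rsum
  diag(sep) <- Inf
  expect_gte(min(sep), 1 - small_scene_config(8)$max_overlap_frac - 1e-9)
})
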