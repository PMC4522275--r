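em <- test_endmembers()

# a 10x10 brightfield cube whose two designated pixels carry the given OD
# spectra and everything else is blank
two_pixel_cube <- function(od1, od2, I0 = 255) {
  B <- length(od1)
  wl <- seq(500, 500 + 10 * (B - 1), by = 10)
  arr <- array(I0, c(10, 10, B))
  arr[1, 1, ] <- I0 * 10^(-od1)
  arr[2, 2, ] <- I0 * 10^(-od2)
  multispectral_cube(arr, wl, "brightfield", I0 = I0)
}

test_that("a constant foreground spectrum peak-normalizes as expected", {
  cube <- two_pixel_cube(c(0.2, 0.8), c(0.2, 0.8))
  lib <- build_library(list(stain = cube))
  expect_equal(unname(lib$endmembers$spectra["stain", ]), c(0.25, 1),
               tolerance = 1e-10)
})

test_that("foreground spectra are averaged before normalization", {
  cube <- two_pixel_cube(c(0.2, 0.8), c(0.3, 0.7))
  lib <- build_library(list(stain = cube))
  # mean (0.25, 0.75) -> peak-normalized (1/3, 1)
  expect_equal(unname(lib$endmembers$spectra["stain", ]), c(1 / 3, 1),
               tolerance = 1e-10)
  expect_equal(lib$meta$stain$n_foreground, 2)
})

test_that("an all-blank cube gives an empty-foreground error naming the stain", {
  blank <- multispectral_cube(array(255, c(5, 5, 2)), c(500, 600),
                              "brightfield", I0 = 255)
  expect_error(build_library(list(nuc = blank)), "empty foreground.*nuc")
})

test_that("mismatched wavelengths across single-stain cubes are rejected", {
  c1 <- two_pixel_cube(c(0.2, 0.8), c(0.2, 0.8))
  c2 <- c1; c2$wavelengths_nm <- c(400, 450)
  expect_error(build_library(list(a = c1, b = c2)), "wavelength")
})

test_that("libraries built from rendered single stains recover the spectra", {
  for (k in seq_along(em$names)) {
    od <- array(0, c(12, 12, 3))
    set.seed(40 + k)
    fg <- matrix(runif(144) < 0.3, 12, 12)
    od_k <- matrix(0, 12, 12); od_k[fg] <- runif(sum(fg), 0.3, 1)
    od[, , k] <- od_k
    cube <- cube_from_od(od, em)
    lib <- build_library(stats::setNames(list(cube), em$names[k]))
    cosim <- sum(lib$endmembers$spectra[1, ] * em$spectra[k, ]) /
      sqrt(sum(lib$endmembers$spectra[1, ]^2) * sum(em$spectra[k, ]^2))
    expect_gt(cosim, 0.9999)
  }
})

test_that("autofluorescence estimation is the masked per-band mean", {
  arr <- array(0, c(4, 4, 3))
  arr[1, 1, ] <- c(4, 4, 4); arr[2, 2, ] <- c(6, 6, 6)
  cube <- multispectral_cube(arr, c(500, 600, 700), "fluorescence")
  mask <- matrix(FALSE, 4, 4); mask[1, 1] <- TRUE; mask[2, 2] <- TRUE
  expect_equal(unname(estimate_autofluorescence(cube, mask)), c(5, 5, 5))
  const <- mask; const[3, 3] <- TRUE
  arr2 <- array(5, c(4, 4, 3))
  cube2 <- multispectral_cube(arr2, c(500, 600, 700), "fluorescence")
  expect_equal(unname(estimate_autofluorescence(cube2, const)), c(5, 5, 5))
  expect_error(estimate_autofluorescence(cube, matrix(FALSE, 4, 4)),
               "empty tissue mask")
  bf <- multispectral_cube(arr, c(500, 600, 700), "brightfield", I0 = 255)
  expect_error(estimate_autofluorescence(bf, mask), "fluorescence")
})

test_that("autofluorescence subtraction clamps at zero and renormalizes", {
  mk_lib <- function(raw) {
    structure(list(
      endmembers = endmember_set(rownames(raw), c(500, 600), raw,
                                 mode = "fluorescence"),
      raw_spectra = raw, autofluorescence = NULL, meta = list()),
      class = "spectral_library")
  }
  lib <- mk_lib(rbind(f = c(10, 8)))
  out <- subtract_autofluorescence(lib, c(2, 3))
  expect_equal(unname(out$endmembers$spectra["f", ]), c(1, 0.625))
  lib2 <- mk_lib(rbind(f = c(1, 8)))
  out2 <- subtract_autofluorescence(lib2, c(2, 3))
  expect_equal(unname(out2$endmembers$spectra["f", ]), c(0, 1))
  # af = 0 is the identity
  out3 <- subtract_autofluorescence(lib, c(0, 0))
  expect_equal(out3$endmembers$spectra, lib$endmembers$spectra)
  expect_true(all(out$endmembers$spectra >= 0))
  expect_error(subtract_autofluorescence(lib2, c(5, 9)), "annihilates.*f")
})

test_that("the condition report quantifies endmember separability", {
  ortho <- endmember_set(c("a", "b"), c(500, 600), rbind(c(1, 0), c(0, 1)))
  rep1 <- library_condition_report(ortho)
  expect_equal(rep1$angles_deg["a", "b"], 90)
  expect_equal(rep1$condition_number, 1)
  expect_equal(nrow(rep1$flagged_pairs), 0)

  ident <- endmember_set(c("a", "b"), c(500, 600), rbind(c(1, 0.5), c(1, 0.5)))
  rep2 <- library_condition_report(ident)
  expect_lt(rep2$angles_deg["a", "b"], 1e-3)
  expect_true(!is.finite(rep2$condition_number) || rep2$condition_number > 1e12)
  expect_equal(nrow(rep2$flagged_pairs), 1)

  # constructed pair at exactly 5 degrees (rotation in the plane)
  th <- 5 * pi / 180
  pair <- endmember_set(c("a", "b"), c(500, 600),
                        rbind(c(1, 0), c(cos(th), sin(th))))
  rep3 <- library_condition_report(pair)
  expect_equal(rep3$angles_deg["a", "b"], 5, tolerance = 0.01 / 5)
})

test_that("library CSV serialization round-trips", {
  od <- array(0, c(12, 12, 3))
  od[, , 1] <- matrix(runif(144, 0.2, 1), 12, 12)
  cube <- cube_from_od(od, em)
  lib <- build_library(stats::setNames(list(cube), em$names[1]))
  path <- file.path(tempdir(), "lib_test.csv")
  write_spectral_library(lib, path)
  back <- read_spectral_library(path)
  expect_equal(back$endmembers$spectra, lib$endmembers$spectra,
               tolerance = 1e-12)
  expect_equal(back$endmembers$wavelengths_nm, lib$endmembers$wavelengths_nm)
  expect_equal(back$endmembers$mode, "brightfield")
})
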