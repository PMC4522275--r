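em <- test_endmembers()

test_that("optical density conversion is exact at its anchor points", {
  cube <- multispectral_cube(array(c(25.5, 255, 0, 255), c(2, 2, 1)), 550,
                             "brightfield", I0 = 255)
  od <- to_optical_density(cube)
  expect_equal(od$data[1, 1, 1], 1)
  expect_equal(od$data[2, 1, 1], 0)
  expect_equal(od$data[1, 2, 1], 3)   # clamp at od_max
  expect_error(to_optical_density(cube, I0 = -1), "I0")
})

test_that("unmix_pixel reproduces the worked examples", {
  expect_equal(unname(unmix_pixel(c(0.3, 0.7), rbind(c(1, 0), c(0, 1)))),
               c(0.3, 0.7), tolerance = 1e-12)
  S <- rbind(c(1, 0.5), c(0.2, 1))
  a <- unmix_pixel(c(0.42, 0.30), S)
  expect_equal(unname(a), c(0.4, 0.1), tolerance = 1e-9)
  # substitution check: consistent system reconstructs exactly
  expect_equal(drop(t(S) %*% a), c(0.42, 0.30), tolerance = 1e-9)
  # unconstrained optimum has a negative coefficient; NNLS clamps
  S2 <- rbind(c(1, 1), c(1, 0))
  a2 <- unmix_pixel(c(0, 0.5), S2)
  expect_equal(unname(a2), c(0.25, 0), tolerance = 1e-9)
  expect_error(unmix_pixel(c(NA, 1), S2), "non-finite")
})

test_that("NNLS never does worse than the brute-force grid oracle", {
  set.seed(71)
  for (i in 1:25) {
    S <- matrix(runif(2 * 6), 2, 6)
    S <- S / apply(S, 1, max)
    a_true <- round(runif(2, 0, 0.9), 3)
    x <- drop(t(S) %*% a_true) + rnorm(6, 0, 0.02)
    sol <- nnls_solve(t(S), x)
    oracle <- grid_nnls_sse(S, x)
    expect_lte(sol$resid^2, oracle$sse + 1e-6)
  }
})

test_that("nnls_solve agrees with an independent active-set implementation", {
  skip_if_not_installed("pracma")
  set.seed(5)
  for (i in 1:40) {
    K <- sample(2:5, 1)
    A <- matrix(runif(8 * K), 8, K)
    b <- runif(8, -0.2, 1)
    mine <- nnls_solve(A, b)
    ref <- pracma::lsqnonneg(A, b)
    expect_equal(mine$coef, ref$x, tolerance = 1e-8)
  }
})

test_that("noise-free cubes unmix back to the exact ground truth", {
  cfg <- small_scene_config(3, noise_sd_frac = 0)
  sc <- generate_scene(cfg, em)
  od <- to_optical_density(sc$cube)
  ab <- unmix_cube(od, em)
  err <- max(abs(ab$coefficients -
                 sc$truth$abundance[, , dimnames(ab$coefficients)[[3]]]))
  expect_lt(err, 1e-6)
  expect_true(all(ab$coefficients >= 0))
})

test_that("an all-background OD cube unmixes to zero abundances", {
  od <- structure(list(data = array(0, c(8, 8, 16)),
                       wavelengths_nm = em$wavelengths_nm, I0 = rep(255, 16),
                       od_max = 3, image_id = NULL), class = "od_cube")
  ab <- unmix_cube(od, em)
  expect_true(all(ab$coefficients == 0))
  expect_true(all(ab$residual == 0))
})

test_that("abundance RMSE under noise stays within the least-squares bound", {
  cfg <- small_scene_config(3, noise_sd_frac = 0.01)
  sc <- generate_scene(cfg, em)
  od <- to_optical_density(sc$cube)
  ab <- unmix_cube(od, em)
  truth <- sc$truth$abundance[, , dimnames(ab$coefficients)[[3]]]
  rmse <- sqrt(mean((ab$coefficients - truth)^2))
  # error propagation: OD noise sd ~= sd_I / (I ln 10); the LS abundance
  # covariance is sigma_od^2 (S S^T)^{-1}, bounded by its largest eigenvalue
  sd_I <- 0.01 * cfg$I0
  I_typ <- stats::median(sc$cube$data)
  sigma_od <- sd_I / (I_typ * log(10))
  G_inv <- solve(em$spectra %*% t(em$spectra))
  bound <- sigma_od * sqrt(max(eigen(G_inv, only.values = TRUE)$values))
  expect_lt(rmse, 5 * bound)
})

test_that("consistent-case solutions scale with the spectrum", {
  S <- em$spectra
  a0 <- c(0.3, 0.1, 0.5)
  x <- drop(t(S) %*% a0)
  for (cc in c(0.5, 2, 7)) {
    expect_equal(unname(unmix_pixel(cc * x, S)), cc * a0, tolerance = 1e-8)
  }
})

test_that("residuals behave like an orthogonal-projection distance", {
  S <- rbind(a = c(1, 0, 0), b = c(0, 1, 0))
  x <- c(0, 0, 0.7)                    # orthogonal to both endmembers
  sol <- nnls_solve(t(S), x)
  expect_equal(sol$coef, c(0, 0))
  expect_equal(sol$resid, 0.7)
})

test_that("reconstruction residuals are recomputed and monotone in noise", {
  run_mean <- function(nsd) {
    cfg <- small_scene_config(12, noise_sd_frac = nsd)
    sc <- generate_scene(cfg, em)
    od <- to_optical_density(sc$cube)
    ab <- unmix_cube(od, em)
    rr <- reconstruction_residual(ab, od)
    expect_equal(rr$residual, ab$residual, tolerance = 1e-9)
    rr$mean
  }
  exact <- run_mean(0)
  expect_lt(exact, 1e-9)
  m1 <- run_mean(0.01); m2 <- run_mean(0.02)
  expect_gt(m2, m1)
})

test_that("near-collinear libraries trigger the conditioning warning", {
  bad <- generate_endmember_set(16, c("r1", "r2"),
                                similar_pair = list("r1", "r2", 2), seed = 1)
  od <- structure(list(data = array(0.1, c(4, 4, 16)),
                       wavelengths_nm = bad$wavelengths_nm, I0 = rep(255, 16),
                       od_max = 3, image_id = NULL), class = "od_cube")
  expect_warning(unmix_cube(od, bad), "near-collinear")
})

test_that("input contract violations fail early", {
  od <- structure(list(data = array(0.1, c(4, 4, 16)),
                       wavelengths_nm = em$wavelengths_nm + 5,
                       I0 = rep(255, 16), od_max = 3, image_id = NULL),
                  class = "od_cube")
  expect_error(unmix_cube(od, em), "wavelengths")
  raw <- multispectral_cube(array(100, c(4, 4, 16)), em$wavelengths_nm,
                            "brightfield", I0 = 255)
  expect_error(unmix_cube(raw, em), "to_optical_density")
})
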