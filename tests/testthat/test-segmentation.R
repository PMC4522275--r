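em <- test_endmembers()

disk_map <- function(centers, radius, value = 1, shape = c(64, 64)) {
  m <- matrix(0, shape[1], shape[2])
  yy <- matrix(seq_len(shape[1]), shape[1], shape[2])
  xx <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  for (k in seq_len(nrow(centers))) {
    m[(yy - centers[k, 1])^2 + (xx - centers[k, 2])^2 <= radius^2] <- value
  }
  m
}

test_that("an empty nuclear map yields zero cells", {
  seg <- segment_nuclei(matrix(0, 32, 32))
  expect_equal(nrow(seg$cells), 0)
  expect_true(all(seg$labels == 0))
  expect_error(segment_nuclei(matrix(c(NA, 1), 2, 2)), "non-finite")
})

test_that("disjoint disks are each recovered with accurate centroids", {
  centers <- rbind(c(12, 12), c(12, 40), c(40, 12), c(40, 40), c(26, 26))
  seg <- segment_nuclei(disk_map(centers, 6))
  expect_equal(nrow(seg$cells), 5)
  for (k in 1:5) {
    d <- sqrt((seg$cells$y - centers[k, 1])^2 + (seg$cells$x - centers[k, 2])^2)
    expect_lt(min(d), 1)
  }
})

test_that("overlapping disks are split by the watershed", {
  seg <- segment_nuclei(disk_map(rbind(c(30, 26), c(30, 35)), 6))
  expect_equal(nrow(seg$cells), 2)
})

test_that("the area filter removes specks and merged blobs", {
  m <- disk_map(rbind(c(16, 16)), 6)
  m[40, 40] <- 1                       # 1-px speck
  seg <- segment_nuclei(m, min_area = 12, max_area = 400)
  expect_equal(nrow(seg$cells), 1)
})

test_that("uniform tiles report their constants and blank tiles zeros", {
  A <- array(0, c(32, 32, 3), dimnames = list(NULL, NULL, em$names))
  A[1:16, , 1] <- 0.3; A[1:16, , 2] <- 0.1
  ab <- structure(list(coefficients = A, residual = matrix(0, 32, 32),
                       wavelengths_nm = em$wavelengths_nm,
                       mode = "brightfield", library = em),
                  class = "abundance_map")
  f <- extract_tile_features(ab, NULL, tile_size = 16, smooth_tiles = 0)
  top <- f[f$y0 == 1 & f$x0 == 1, ]
  expect_equal(top$mean_warp_red, 0.3)
  expect_equal(top$mean_true_blue, 0.1)
  expect_equal(top$tissue_fraction, 1)
  bottom <- f[f$y0 == 17 & f$x0 == 1, ]
  expect_equal(bottom$mean_warp_red, 0)
  expect_equal(bottom$tissue_fraction, 0)
  expect_equal(bottom$cell_density, 0)
})

test_that("tile cell density and mean area come from centroids", {
  A <- array(0.2, c(100, 100, 3), dimnames = list(NULL, NULL, em$names))
  ab <- structure(list(coefficients = A, residual = matrix(0, 100, 100),
                       wavelengths_nm = em$wavelengths_nm,
                       mode = "brightfield", library = em),
                  class = "abundance_map")
  cells <- structure(list(
    labels = matrix(0L, 100, 100),
    cells = data.frame(cell_id = 1:4, y = c(10, 20, 30, 40),
                       x = c(10, 20, 30, 40), area = rep(25, 4),
                       eq_radius = sqrt(25 / pi))), class = "cell_label_map")
  f <- extract_tile_features(ab, cells, tile_size = 100, smooth_tiles = 0)
  expect_equal(f$cell_density, 0.4)
  expect_equal(f$mean_cell_area, 25)
})

test_that("training requires at least two classes and is deterministic", {
  feats <- data.frame(f1 = c(0, 0.1, 0.9, 1.0))
  attr(feats, "feature_names") <- "f1"
  expect_error(train_tissue_classifier(feats, rep("a", 4)), "2 region classes")
  m1 <- train_tissue_classifier(feats, c("a", "a", "b", "b"))
  m2 <- train_tissue_classifier(feats, c("a", "a", "b", "b"))
  expect_identical(m1, m2)
  # disjoint supports classify the training set perfectly
  expect_equal(predict(m1, feats), c("a", "a", "b", "b"))
})

test_that("tile classification honours priors, ties and background rule", {
  feats <- data.frame(f1 = c(rep(0, 5), rep(1, 5)))
  attr(feats, "feature_names") <- "f1"
  model <- train_tissue_classifier(feats, c(rep("follicle", 5), rep("stroma", 5)))
  nd <- data.frame(f1 = c(0.02, 0.97), tissue_fraction = c(1, 1),
                   y0 = c(1, 1), y1 = c(8, 8), x0 = c(1, 9), x1 = c(8, 16))
  expect_equal(predict(model, nd), c("follicle", "stroma"))
  # exact tie goes to the higher-priority region (follicle)
  expect_equal(predict(model, data.frame(f1 = 0.5)), "follicle")
  # classification is permutation-invariant over tiles
  set.seed(1)
  nd2 <- data.frame(f1 = runif(20))
  perm <- sample(20)
  expect_equal(predict(model, nd2)[perm], predict(model, nd2[perm, , drop = FALSE]))
  # all-background image
  ndb <- data.frame(f1 = c(0.1, 0.9), tissue_fraction = c(0, 0),
                    y0 = c(1, 1), y1 = c(8, 8), x0 = c(1, 9), x1 = c(8, 16))
  attr(ndb, "tile_grid") <- c(1, 2)
  rm <- classify_tissue(model, ndb, c(8, 16))
  expect_true(all(rm$labels == match("background", rm$levels)))
})

test_that("tissue fraction counts pixels above the summed-OD threshold", {
  mk_ab <- function(total) {
    A <- array(0, c(10, 10, 1), dimnames = list(NULL, NULL, "x"))
    A[, , 1] <- total
    structure(list(coefficients = A, residual = matrix(0, 10, 10)),
              class = "abundance_map")
  }
  expect_equal(compute_tissue_fraction(mk_ab(matrix(0, 10, 10))), 0)
  m <- matrix(0, 10, 10); m[1:9] <- 1
  expect_equal(compute_tissue_fraction(mk_ab(m)), 0.09)
  chk <- matrix(c(1, 0), 10, 10)
  expect_equal(compute_tissue_fraction(mk_ab(chk)), 0.5)
})
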