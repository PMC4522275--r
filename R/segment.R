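#' Segment nuclei from the nuclear-channel abundance map
#'
#' Gaussian smoothing, global Otsu (or fixed) thresholding, Euclidean
#' distance transform, and watershed splitting of touching nuclei, followed
#' by an area filter. Deterministic.
#'
#' @param nuclear_abundance Non-negative `H x W` matrix (nuclear-channel
#'   abundances, OD units).
#' @param smooth_sigma Gaussian smoothing sigma in px.
#' @param threshold_method `"otsu"` or a fixed numeric threshold.
#' @param min_area,max_area Area filter in px^2.
#' @param min_peak_distance Watershed neighbourhood radius (px) used when
#'   deciding whether two distance-transform peaks are distinct seeds.
#' @param watershed_tolerance Minimum depth (in distance-map units)
#'   separating two objects before they are split.
#' @return Object of class `cell_label_map`: `labels` (`H x W` integer
#'   matrix, 0 background, 1..N cells) and `cells` (data frame with
#'   `cell_id`, `y`, `x` centroid, `area`, `eq_radius`).
#' @export
segment_nuclei <- function(nuclear_abundance, smooth_sigma = 0.8,
                           threshold_method = "otsu",
                           min_area = 12, max_area = 400,
                           min_peak_distance = 1, watershed_tolerance = 0.1) {
  m <- as.matrix(nuclear_abundance)
  if (!all(is.finite(m))) stop("non-finite values in nuclear abundance map")
  stopifnot(smooth_sigma > 0, min_area > 0, max_area >= min_area,
            min_peak_distance >= 1)
  if (max(m) <= 0) return(empty_label_map(dim(m)))

  img <- EBImage::Image(m / max(m))
  sm <- EBImage::gblur(img, sigma = smooth_sigma)
  thr <- if (identical(threshold_method, "otsu")) {
    EBImage::otsu(sm, range = c(0, 1))
  } else {
    as.numeric(threshold_method) / max(m)
  }
  bin <- sm > thr
  if (!any(bin)) return(empty_label_map(dim(m)))
  dm <- EBImage::distmap(bin)
  lab <- EBImage::watershed(dm, tolerance = watershed_tolerance,
                            ext = as.integer(min_peak_distance))
  lab <- EBImage::imageData(lab)

  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= min_area & areas <= max_area)
  if (length(keep) == 0) return(empty_label_map(dim(m)))
  remap <- integer(length(areas))
  remap[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(m), ncol(m))
  nz <- lab > 0
  out[nz] <- remap[lab[nz]]

  idx <- which(out > 0)
  lv <- out[idx]
  yy <- ((idx - 1) %% nrow(m)) + 1
  xx <- ((idx - 1) %/% nrow(m)) + 1
  area <- as.numeric(tabulate(lv, nbins = length(keep)))
  cells <- data.frame(
    cell_id = seq_along(keep),
    y = as.numeric(tapply(yy, lv, mean)),
    x = as.numeric(tapply(xx, lv, mean)),
    area = area,
    eq_radius = sqrt(area / pi)
  )
  structure(list(labels = out, cells = cells), class = "cell_label_map")
}

empty_label_map <- function(d) {
  structure(list(labels = matrix(0L, d[1], d[2]),
                 cells = data.frame(cell_id = integer(0), y = numeric(0),
                                    x = numeric(0), area = numeric(0),
                                    eq_radius = numeric(0))),
            class = "cell_label_map")
}

#' @export
print.cell_label_map <- function(x, ...) {
  cat(sprintf("Cell label map: %d cells on %d x %d px\n",
              nrow(x$cells), nrow(x$labels), ncol(x$labels)))
  invisible(x)
}

#' Per-tile features for tissue classification
#'
#' Cuts the image into `tile_size` x `tile_size` tiles (edge tiles
#' truncated) and computes, per tile: mean abundance per endmember,
#' nucleus density (cells per 1000 px^2, by centroid), mean nucleus area,
#' and the fraction of pixels whose summed abundance exceeds the tissue
#' threshold. Because a single tile holds only a handful of cells, raw
#' tile features are dominated by sampling noise; with
#' `smooth_tiles > 0` each feature is box-averaged over the
#' `(2s+1) x (2s+1)` tile neighbourhood (edge-truncated), which sharpens
#' region composition estimates at a small cost in boundary resolution.
#' When `channel_map` is given, per-nucleus marker ratios
#' (`lineage_ratio`, `tet_ratio` = marker mean over nuclear mean) are
#' added; these factor out local cell density.
#'
#' @param abundances An `abundance_map`.
#' @param cells A `cell_label_map` for the same image.
#' @param tile_size Tile edge in px (default 8).
#' @param tissue_od_threshold Summed-abundance cutoff defining a tissue
#'   pixel (default 0.05).
#' @param smooth_tiles Neighbourhood radius, in tiles, of the feature
#'   box smoothing (default 3; 0 disables).
#' @param channel_map Optional role-to-endmember map enabling the ratio
#'   features.
#' @return Data frame with tile bounds (`y0`, `y1`, `x0`, `x1`) and the
#'   feature columns; feature names in `attr(, "feature_names")`.
#' @export
extract_tile_features <- function(abundances, cells, tile_size = 8,
                                  tissue_od_threshold = 0.05,
                                  smooth_tiles = 3, channel_map = NULL) {
  stopifnot(inherits(abundances, "abundance_map"), tile_size >= 4)
  A <- abundances$coefficients
  H <- dim(A)[1]; W <- dim(A)[2]; K <- dim(A)[3]
  emn <- dimnames(A)[[3]]
  total <- rowSums(matrix(A, H * W, K))
  total <- matrix(total, H, W)

  ty <- seq(1, H, by = tile_size)
  tx <- seq(1, W, by = tile_size)
  out <- list()
  r <- 0L
  for (y0 in ty) for (x0 in tx) {
    r <- r + 1L
    y1 <- min(H, y0 + tile_size - 1); x1 <- min(W, x0 + tile_size - 1)
    px_area <- (y1 - y0 + 1) * (x1 - x0 + 1)
    feats <- vapply(seq_len(K), function(k) mean(A[y0:y1, x0:x1, k]), numeric(1))
    names(feats) <- paste0("mean_", emn)
    if (!is.null(cells) && nrow(cells$cells) > 0) {
      sel <- cells$cells$y >= y0 - 0.5 & cells$cells$y < y1 + 0.5 &
        cells$cells$x >= x0 - 0.5 & cells$cells$x < x1 + 0.5
      ncell <- sum(sel)
      marea <- if (ncell > 0) mean(cells$cells$area[sel]) else 0
    } else { ncell <- 0; marea <- 0 }
    out[[r]] <- c(y0 = y0, y1 = y1, x0 = x0, x1 = x1, feats,
                  cell_density = 1000 * ncell / px_area,
                  mean_cell_area = marea,
                  tissue_fraction = mean(total[y0:y1, x0:x1] > tissue_od_threshold))
  }
  df <- as.data.frame(do.call(rbind, out))
  fn <- c(paste0("mean_", emn), "cell_density", "mean_cell_area",
          "tissue_fraction")
  nty <- length(ty); ntx <- length(tx)
  smooth_feat <- function(v) {
    if (smooth_tiles <= 0) return(v)
    as.vector(t(box_mean(matrix(v, nty, ntx, byrow = TRUE), smooth_tiles)))
  }
  for (cc in fn) df[[cc]] <- smooth_feat(df[[cc]])
  if (!is.null(channel_map)) {
    nucf <- paste0("mean_", channel_map[["nuclear"]])
    df$lineage_ratio <- df[[paste0("mean_", channel_map[["lineage"]])]] /
      (df[[nucf]] + 0.02)
    df$tet_ratio <- df[[paste0("mean_", channel_map[["tetraspanin"]])]] /
      (df[[nucf]] + 0.02)
    fn <- c(fn, "lineage_ratio", "tet_ratio")
    # composition features: fraction of cells in the window whose
    # membrane-ring OD clears a global two-class (Otsu) cut per marker
    cc <- cells$cells
    ncell <- if (is.null(cells)) 0L else nrow(cc)
    tile_of <- function(y, x) {
      ti <- pmin(pmax(ceiling(y / tile_size), 1), nty)
      tj <- pmin(pmax(ceiling(x / tile_size), 1), ntx)
      (ti - 1L) * ntx + tj
    }
    cnt <- cnt_lin <- cnt_tet <- numeric(nrow(df))
    if (ncell > 0) {
      ods <- cell_ring_ods(cells, abundances, channel_map)
      lin_cut <- otsu_cut(ods$lineage)
      tet_cut <- otsu_cut(ods$tetraspanin)
      ti <- tile_of(cc$y, cc$x)
      cnt <- tabulate(ti, nbins = nrow(df))
      cnt_lin <- tabulate(ti[ods$lineage >= lin_cut], nbins = nrow(df))
      cnt_tet <- tabulate(ti[ods$tetraspanin >= tet_cut], nbins = nrow(df))
    }
    df$frac_lin_pos <- smooth_feat(cnt_lin) / pmax(smooth_feat(cnt), 1e-9)
    df$frac_tet_bright <- smooth_feat(cnt_tet) / pmax(smooth_feat(cnt), 1e-9)
    fn <- c(fn, "frac_lin_pos", "frac_tet_bright")
  }
  attr(df, "feature_names") <- fn
  attr(df, "tile_size") <- tile_size
  attr(df, "tile_grid") <- c(nty, ntx)
  df
}

# Quick per-cell membrane-ring medians (distance (r, r+2] around the
# centroid), used only for tile composition features.
cell_ring_ods <- function(cells, abundances, channel_map) {
  A <- abundances$coefficients
  H <- dim(A)[1]; W <- dim(A)[2]
  vl <- A[, , channel_map[["lineage"]]]
  vt <- A[, , channel_map[["tetraspanin"]]]
  cc <- cells$cells
  n <- nrow(cc)
  lin <- tet <- numeric(n)
  for (i in seq_len(n)) {
    r <- cc$eq_radius[i]
    rr <- r + 2
    i0 <- max(1, floor(cc$y[i] - rr)); i1 <- min(H, ceiling(cc$y[i] + rr))
    j0 <- max(1, floor(cc$x[i] - rr)); j1 <- min(W, ceiling(cc$x[i] + rr))
    d <- sqrt(outer((i0:i1 - cc$y[i])^2, (j0:j1 - cc$x[i])^2, "+"))
    ring <- d > r & d <= rr
    if (any(ring)) {
      lin[i] <- stats::median(vl[i0:i1, j0:j1][ring])
      tet[i] <- stats::median(vt[i0:i1, j0:j1][ring])
    }
  }
  list(lineage = lin, tetraspanin = tet)
}

# Otsu threshold on a numeric vector (256-bin histogram); splits a
# bimodal per-cell OD distribution into negative/positive classes.
otsu_cut <- function(x, nbins = 256) {
  if (length(x) < 2 || max(x) <= min(x)) return(Inf)
  br <- seq(min(x), max(x), length.out = nbins + 1)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins)
  w1 <- cumsum(h); w2 <- sum(h) - w1
  mids <- (br[-1] + br[-length(br)]) / 2
  m1 <- cumsum(h * mids) / pmax(w1, 1e-12)
  m2 <- (sum(h * mids) - cumsum(h * mids)) / pmax(w2, 1e-12)
  between <- w1 * w2 * (m1 - m2)^2
  between[c(1, nbins)] <- -Inf
  mids[which.max(between)]
}

# Edge-truncated box mean over a (2r+1)^2 neighbourhood of a matrix.
box_mean <- function(M, r) {
  nr <- nrow(M); nc <- ncol(M)
  out <- matrix(0, nr, nc)
  cnt <- matrix(0, nr, nc)
  for (dy in -r:r) for (dx in -r:r) {
    ys <- max(1, 1 + dy):min(nr, nr + dy)
    yd <- max(1, 1 - dy):min(nr, nr - dy)
    xs <- max(1, 1 + dx):min(nc, nc + dx)
    xd <- max(1, 1 - dx):min(nc, nc - dx)
    out[yd, xd] <- out[yd, xd] + M[ys, xs]
    cnt[yd, xd] <- cnt[yd, xd] + 1
  }
  out / cnt
}

# Majority ground-truth region label per tile; used to build training sets.
tile_labels_from_mask <- function(features, mask) {
  vapply(seq_len(nrow(features)), function(r) {
    sub <- mask$labels[features$y0[r]:features$y1[r],
                       features$x0[r]:features$x1[r]]
    mask$levels[which.max(tabulate(sub, nbins = length(mask$levels)))]
  }, character(1))
}

#' Train a Gaussian tissue-region classifier on labeled tiles
#'
#' Gaussian class-conditional model with class priors from tile
#' frequencies. With `covariance = "pooled"` (default) the classes share
#' a ridge-regularized pooled covariance (linear discriminant analysis),
#' which handles the strong correlation among tile features; with
#' `"diagonal"` a per-feature-variance naive Bayes model is fit instead.
#' Deterministic.
#'
#' @param features Tile feature data frame from [extract_tile_features()]
#'   (rows pooled across training images), or a plain data frame holding
#'   the feature columns.
#' @param labels Character vector of region labels, one per tile row.
#' @param covariance `"pooled"` or `"diagonal"`.
#' @param ridge_frac Ridge added to the (co)variance, as a fraction of
#'   each feature's pooled variance (default 1e-3).
#' @return Object of class `tissue_classifier`: `classes`,
#'   `feature_names`, `means`, `log_priors`, `covariance`, and either
#'   `cov_inv` (pooled) or `vars` (diagonal); plus `tile_size`.
#' @export
train_tissue_classifier <- function(features, labels,
                                    covariance = c("pooled", "diagonal"),
                                    ridge_frac = 1e-3) {
  covariance <- match.arg(covariance)
  fn <- attr(features, "feature_names") %||%
    setdiff(colnames(features), c("y0", "y1", "x0", "x1"))
  X <- as.matrix(features[, fn, drop = FALSE])
  labels <- as.character(labels)
  stopifnot(nrow(X) == length(labels))
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("need at least 2 region classes to train")
  pooled_var <- apply(X, 2, stats::var)
  pooled_var[!is.finite(pooled_var) | pooled_var <= 0] <- 1e-12
  means <- matrix(NA_real_, length(classes), length(fn),
                  dimnames = list(classes, fn))
  for (cl in classes) {
    sel <- labels == cl
    if (!any(sel)) stop("class with zero tiles: ", cl)
    means[cl, ] <- colMeans(X[sel, , drop = FALSE])
  }
  pri <- table(factor(labels, levels = classes))
  out <- list(classes = classes, feature_names = fn, means = means,
              log_priors = log(as.numeric(pri) / sum(pri)),
              covariance = covariance,
              tile_size = attr(features, "tile_size") %||% NA_integer_)
  if (covariance == "pooled") {
    Xc <- X - means[labels, , drop = FALSE]
    Sig <- crossprod(Xc) / max(1, nrow(X) - length(classes))
    Sig <- Sig + diag(ridge_frac * pooled_var + 1e-12, length(fn))
    out$cov_inv <- solve(Sig)
  } else {
    vars <- matrix(NA_real_, length(classes), length(fn),
                   dimnames = list(classes, fn))
    floorv <- ridge_frac * pooled_var + 1e-12
    for (cl in classes) {
      v <- apply(X[labels == cl, , drop = FALSE], 2, stats::var)
      v[!is.finite(v)] <- 0
      vars[cl, ] <- pmax(v, floorv)
    }
    out$vars <- vars
  }
  structure(out, class = "tissue_classifier")
}

#' @export
print.tissue_classifier <- function(x, ...) {
  cat("Gaussian tissue classifier:", paste(x$classes, collapse = ", "),
      "\n  features:", paste(x$feature_names, collapse = ", "), "\n")
  invisible(x)
}

#' @export
predict.tissue_classifier <- function(object, newdata, ...) {
  fn <- object$feature_names
  if (!all(fn %in% colnames(newdata)))
    stop("feature mismatch: missing ", paste(setdiff(fn, colnames(newdata)), collapse = ", "))
  X <- as.matrix(newdata[, fn, drop = FALSE])
  n <- nrow(X)
  ll <- matrix(NA_real_, n, length(object$classes),
               dimnames = list(NULL, object$classes))
  for (i in seq_along(object$classes)) {
    mu <- object$means[i, ]
    if (object$covariance == "pooled") {
      # linear discriminant: x' S^-1 mu - mu' S^-1 mu / 2 + log prior
      w <- object$cov_inv %*% mu
      ll[, i] <- object$log_priors[i] + X %*% w - 0.5 * drop(mu %*% w)
    } else {
      v <- object$vars[i, ]
      ll[, i] <- object$log_priors[i] -
        0.5 * rowSums(sweep(sweep(X, 2, mu)^2, 2, v, "/")) -
        0.5 * sum(log(2 * pi * v))
    }
  }
  # argmax with ties broken by canonical region priority
  pri <- match(object$classes, REGION_LEVELS)
  pri[is.na(pri)] <- length(REGION_LEVELS) + seq_len(sum(is.na(pri)))
  cls <- apply(ll, 1, function(z) {
    top <- which(z >= max(z) - 1e-9)
    object$classes[top[order(pri[top])[1]]]
  })
  cls
}

#' Classify tissue into regions from tile features
#'
#' Per-tile argmax posterior under the Gaussian model (ties broken by the
#' canonical region priority follicle > t_zone > stroma > other),
#' rasterized back to a per-pixel [region_mask]. Tiles whose
#' above-tissue-threshold fraction is below `background_cutoff` are
#' labeled background. With `smooth_labels > 0` the per-tile labels are
#' majority-smoothed over the tile neighbourhood, removing isolated
#' misclassified tiles inside coherent regions.
#'
#' @param model A [train_tissue_classifier()] fit.
#' @param features Tile features of the image to classify.
#' @param image_shape `c(H, W)` of the image.
#' @param background_cutoff Minimum tile tissue fraction to count as
#'   tissue (default 0.05).
#' @param smooth_labels Majority-smoothing radius in tiles (default 2;
#'   0 disables).
#' @return A [region_mask].
#' @export
classify_tissue <- function(model, features, image_shape,
                            background_cutoff = 0.05, smooth_labels = 2) {
  stopifnot(inherits(model, "tissue_classifier"))
  cls <- predict(model, features)
  cls[features$tissue_fraction < background_cutoff] <- "background"
  code <- match(cls, REGION_LEVELS)
  grid <- attr(features, "tile_grid")
  if (smooth_labels > 0 && !is.null(grid)) {
    pm <- matrix(code, grid[1], grid[2], byrow = TRUE)
    sm <- pm
    r <- smooth_labels
    for (i in seq_len(grid[1])) for (j in seq_len(grid[2])) {
      nb <- pm[max(1, i - r):min(grid[1], i + r),
               max(1, j - r):min(grid[2], j + r)]
      tb <- tabulate(nb, nbins = length(REGION_LEVELS))
      # majority; ties resolved by canonical priority (lowest code wins)
      sm[i, j] <- which.max(tb)
    }
    code <- as.vector(t(sm))
  }
  lab <- matrix(match("background", REGION_LEVELS), image_shape[1], image_shape[2])
  for (r in seq_len(nrow(features))) {
    lab[features$y0[r]:features$y1[r], features$x0[r]:features$x1[r]] <- code[r]
  }
  region_mask(lab)
}

#' Fraction of image area covered by tissue
#'
#' The fraction of pixels whose summed abundance (or summed OD, for an
#' `od_cube`) exceeds the tissue threshold; the quantity behind the
#' image-level QC rule that discards fields of view with less than 10
#' percent tissue.
#'
#' @param x An `abundance_map` or `od_cube`.
#' @param tissue_od_threshold Summed-signal cutoff (default 0.05).
#' @return Fraction in `[0, 1]`.
#' @export
compute_tissue_fraction <- function(x, tissue_od_threshold = 0.05) {
  stopifnot(tissue_od_threshold > 0)
  total <- if (inherits(x, "abundance_map")) {
    d <- dim(x$coefficients)
    rowSums(matrix(x$coefficients, d[1] * d[2], d[3]))
  } else if (inherits(x, "od_cube")) {
    d <- dim(x$data)
    rowSums(matrix(x$data, d[1] * d[2], d[3]))
  } else stop("x must be an abundance_map or od_cube")
  mean(total > tissue_od_threshold)
}
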