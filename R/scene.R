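#' Region mask
#'
#' Per-pixel tissue-region labels. Regions follow lymphoid-organ anatomy:
#' B-cell follicles, T-cell zones, stroma (red pulp / lamina propria),
#' "other" (non-immune tissue such as vessels and collagen, used as the
#' negative-control compartment) and background (no tissue).
#'
#' @param labels Integer `H x W` matrix of indices into `levels`.
#' @param levels Character vector of region names (default the canonical
#'   five-level set).
#' @return Object of class `region_mask` with `labels`, `levels` and
#'   per-region `pixel_counts`.
#' @export
region_mask <- function(labels, levels = REGION_LEVELS) {
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  stopifnot(all(labels >= 1), all(labels <= length(levels)))
  counts <- tabulate(labels, nbins = length(levels))
  names(counts) <- levels
  structure(list(labels = labels, levels = levels, pixel_counts = counts),
            class = "region_mask")
}

#' @export
print.region_mask <- function(x, ...) {
  cat("Region mask", paste(dim(x$labels), collapse = " x "), "px\n")
  print(x$pixel_counts)
  invisible(x)
}

# Region name at (possibly fractional) pixel coordinates.
region_at <- function(mask, y, x) {
  i <- pmin(pmax(round(y), 1), nrow(mask$labels))
  j <- pmin(pmax(round(x), 1), ncol(mask$labels))
  mask$levels[mask$labels[cbind(i, j)]]
}

#' Scene configuration for the synthetic tissue generator
#'
#' Bundles every knob of the synthetic lymphoid-tissue forward model:
#' geometry of the region layout, per-region cell densities and class
#' fractions, the log-normal per-cell optical-density distributions of the
#' three chromogen channels, the optical rendering parameters and the seed.
#' Defaults emulate a densely cellular secondary lymphoid section:
#' follicles rich in bright lineage-positive cells, T-zone annuli, stroma
#' with mixed composition, and a non-immune "other" strip that serves as
#' the negative-control region for threshold derivation.
#'
#' OD level distributions are given as `c(median, sdlog)` of a log-normal.
#' Densities are cells per 1000 px^2; fractions are probabilities in
#' `[0, 1]`.
#'
#' @param image_shape `c(H, W)` in pixels.
#' @param n_follicles Number of follicle disks (0 gives a bone-marrow-like
#'   scene without region structure).
#' @param follicle_radius_px Follicle radius.
#' @param include_t_zone Give each follicle an adjacent T-zone disk (the
#'   white-pulp arrangement: T-cell zones flanking the follicles)?
#' @param t_zone_radius_px Radius of that disk (default: the follicle
#'   radius).
#' @param other_strip_px Width of the left-edge non-immune control strip
#'   (0 disables it).
#' @param cell_density Named vector, cells per 1000 px^2 per region.
#' @param lineage_pos_frac Named vector, probability a cell is
#'   lineage-marker positive, per region.
#' @param bright_frac Named vector, probability a cell is tetraspanin
#'   bright, per region.
#' @param nucleus_radius_median_px,nucleus_radius_sdlog Log-normal nucleus
#'   radius.
#' @param max_overlap_frac Maximum allowed nucleus overlap, as a fraction
#'   of the summed radii (centers at least `(1 - f) * (r1 + r2)` apart).
#' @param membrane_width_px Width of the membrane annulus carrying lineage
#'   and tetraspanin chromogen.
#' @param od_tet_dim,od_tet_bright,od_tet_background,od_lineage_pos,od_lineage_neg,od_nuclear
#'   `c(median, sdlog)` log-normal OD level distributions. The background
#'   distribution applies to non-immune cells in the "other" region and is
#'   deliberately more dispersed than the homogeneous dim lymphocyte mode.
#' @param noise_sd_frac Gaussian intensity noise sd as a fraction of `I0`.
#' @param poisson_noise Also apply Poisson resampling of intensities?
#' @param af_amplitude Autofluorescence amplitude (fluorescence mode).
#' @param I0 White reference intensity (brightfield).
#' @param mode Acquisition mode to render.
#' @param channels Named map from roles (`nuclear`, `lineage`,
#'   `tetraspanin`) to endmember names.
#' @param background_margin_px Width of a background (no tissue) border.
#' @param image_id Identifier stamped on the rendered cube.
#' @param seed Integer seed; the whole scene is a pure function of
#'   (config, seed).
#' @return Object of class `scene_config`.
#' @export
scene_config <- function(image_shape = c(512, 512),
                         n_follicles = 3,
                         follicle_radius_px = 60,
                         include_t_zone = TRUE,
                         t_zone_radius_px = NULL,
                         other_strip_px = 64,
                         cell_density = c(follicle = 8, t_zone = 7, stroma = 5, other = 4),
                         lineage_pos_frac = c(follicle = 0.85, t_zone = 0.80, stroma = 0.35, other = 0),
                         bright_frac = c(follicle = 0.90, t_zone = 0.35, stroma = 0.45, other = 0),
                         nucleus_radius_median_px = 4,
                         nucleus_radius_sdlog = 0.12,
                         max_overlap_frac = 0.10,
                         membrane_width_px = 2,
                         od_tet_dim = c(median = 0.035, sdlog = 0.18),
                         od_tet_bright = c(median = 0.35, sdlog = 0.25),
                         od_tet_background = c(median = 0.04, sdlog = 0.30),
                         od_lineage_pos = c(median = 0.45, sdlog = 0.25),
                         od_lineage_neg = c(median = 0.02, sdlog = 0.30),
                         od_nuclear = c(median = 0.50, sdlog = 0.20),
                         noise_sd_frac = 0.01,
                         poisson_noise = FALSE,
                         af_amplitude = 0,
                         I0 = 255,
                         mode = c("brightfield", "fluorescence"),
                         channels = c(nuclear = "nuclear_red",
                                      lineage = "warp_red",
                                      tetraspanin = "true_blue"),
                         background_margin_px = 0,
                         image_id = "scene",
                         seed = 1) {
  mode <- match.arg(mode)
  t_zone_radius_px <- t_zone_radius_px %||% follicle_radius_px
  fr <- c(lineage_pos_frac, bright_frac)
  stopifnot(
    length(image_shape) == 2, all(image_shape >= 16),
    n_follicles >= 0, follicle_radius_px > 0, t_zone_radius_px > 0,
    all(cell_density >= 0), all(fr >= 0), all(fr <= 1),
    max_overlap_frac >= 0, max_overlap_frac < 1,
    nucleus_radius_median_px > 0, membrane_width_px >= 0,
    noise_sd_frac >= 0, af_amplitude >= 0, I0 > 0,
    all(c("nuclear", "lineage", "tetraspanin") %in% names(channels))
  )
  for (d in list(od_tet_dim, od_tet_bright, od_tet_background,
                 od_lineage_pos, od_lineage_neg, od_nuclear)) {
    stopifnot(length(d) == 2, d[1] > 0, d[2] >= 0)
  }
  cfg <- as.list(environment())
  structure(cfg, class = "scene_config")
}

#' @export
print.scene_config <- function(x, ...) {
  cat(sprintf("Scene config: %d x %d px, %d follicles, mode %s, seed %d\n",
              x$image_shape[1], x$image_shape[2], x$n_follicles, x$mode,
              as.integer(x$seed)))
  invisible(x)
}

rlnorm_med <- function(n, dist) {
  stats::rlnorm(n, meanlog = log(dist[[1]]), sdlog = dist[[2]])
}

# Build the region label matrix for a config; consumes RNG (follicle centers).
build_region_layout <- function(config) {
  H <- config$image_shape[1]; W <- config$image_shape[2]
  lv <- REGION_LEVELS
  lab <- matrix(match("stroma", lv), H, W)
  m <- config$background_margin_px
  if (m > 0) {
    bg <- match("background", lv)
    lab[c(seq_len(m), (H - m + 1):H), ] <- bg
    lab[, c(seq_len(m), (W - m + 1):W)] <- bg
  }
  if (config$other_strip_px > 0) {
    j0 <- m + 1; j1 <- min(W, m + config$other_strip_px)
    lab[(m + 1):(H - m), j0:j1] <- match("other", lv)
  }
  centers <- NULL
  if (config$n_follicles > 0) {
    Rf <- config$follicle_radius_px
    Rt <- if (config$include_t_zone) config$t_zone_radius_px else 0
    xlo <- m + config$other_strip_px
    in_bounds <- function(cy, cx, r) {
      cy - r >= m + 1 && cy + r <= H - m && cx - r >= xlo + 1 && cx + r <= W - m
    }
    if (xlo + 2 * Rf + 4 > W - m || m + 2 * Rf + 4 > H - m)
      stop("image too small for the requested follicle geometry")
    # each complex = follicle disk + tangent T-zone disk; placed jointly
    placed <- matrix(numeric(0), 0, 5)  # fy fx ty tx (t NA when no t zone)
    tries <- 0L
    while (nrow(placed) < config$n_follicles && tries < 500L * config$n_follicles) {
      tries <- tries + 1L
      fy <- stats::runif(1, m + Rf + 2, H - m - Rf - 2)
      fx <- stats::runif(1, xlo + Rf + 2, W - m - Rf - 2)
      if (config$include_t_zone) {
        ang <- stats::runif(1, 0, 2 * pi)
        dd <- 0.95 * (Rf + Rt)
        ty <- fy + dd * sin(ang); tx <- fx + dd * cos(ang)
        if (!in_bounds(ty, tx, Rt)) next
      } else { ty <- NA_real_; tx <- NA_real_ }
      ok <- TRUE
      if (nrow(placed) > 0) {
        for (k in seq_len(nrow(placed))) {
          pts_new <- rbind(c(fy, fx, Rf), if (config$include_t_zone) c(ty, tx, Rt))
          pts_old <- rbind(placed[k, 1:2], if (config$include_t_zone) placed[k, 3:4])
          rads_old <- c(Rf, if (config$include_t_zone) Rt)
          for (a in seq_len(nrow(pts_new))) for (b in seq_len(nrow(pts_old))) {
            if (sqrt(sum((pts_new[a, 1:2] - pts_old[b, ])^2)) <
                pts_new[a, 3] + rads_old[b] + 4) ok <- FALSE
          }
        }
      }
      if (ok) placed <- rbind(placed, c(fy, fx, ty, tx, tries))
    }
    if (nrow(placed) < config$n_follicles)
      stop("could not place ", config$n_follicles, " non-overlapping follicles")
    yy <- matrix(seq_len(H), H, W)
    xx <- matrix(seq_len(W), H, W, byrow = TRUE)
    for (k in seq_len(nrow(placed))) {
      if (config$include_t_zone) {
        d2t <- (yy - placed[k, 3])^2 + (xx - placed[k, 4])^2
        lab[d2t <= Rt^2 & lab == match("stroma", lv)] <- match("t_zone", lv)
      }
      d2 <- (yy - placed[k, 1])^2 + (xx - placed[k, 2])^2
      lab[d2 <= Rf^2] <- match("follicle", lv)
    }
    centers <- placed[, 1:2, drop = FALSE]
  }
  list(mask = region_mask(lab, lv), follicle_centers = centers)
}

# Place disk nuclei region by region with a grid-accelerated overlap check.
# Consumes RNG. Errors when the requested density cannot be met.
place_cells <- function(config, mask) {
  H <- nrow(mask$labels); W <- ncol(mask$labels)
  gs <- max(8, ceiling(4 * config$nucleus_radius_median_px))
  ngy <- ceiling(H / gs); ngx <- ceiling(W / gs)
  grid <- vector("list", ngy * ngx)
  ys <- xs <- rs <- numeric(0)
  regs <- character(0)
  gcell_yx <- function(y, x) {
    gy <- min(max(ceiling(y / gs), 1L), ngy)
    gx <- min(max(ceiling(x / gs), 1L), ngx)
    c(gy, gx)
  }

  for (reg in setdiff(mask$levels, "background")) {
    dens <- if (reg %in% names(config$cell_density)) config$cell_density[[reg]] else 0
    if (is.na(dens) || dens <= 0) next
    pix <- which(mask$labels == match(reg, mask$levels))
    if (length(pix) == 0) next
    n_target <- round(dens * length(pix) / 1000)
    if (n_target == 0) next
    placed <- 0L
    attempts <- 0L
    max_attempts <- 60L * n_target
    while (placed < n_target && attempts < max_attempts) {
      attempts <- attempts + 1L
      p <- pix[sample.int(length(pix), 1)]
      y <- ((p - 1) %% H) + 1 + stats::runif(1, -0.5, 0.5)
      x <- ((p - 1) %/% H) + 1 + stats::runif(1, -0.5, 0.5)
      r <- rlnorm_med(1, c(config$nucleus_radius_median_px, config$nucleus_radius_sdlog))
      g0 <- gcell_yx(y, x); gy <- g0[1]; gx <- g0[2]
      ok <- TRUE
      for (dy in -1:1) for (dx in -1:1) {
        if (!ok) next
        gy2 <- gy + dy; gx2 <- gx + dx
        if (gy2 < 1 || gy2 > ngy || gx2 < 1 || gx2 > ngx) next
        nb <- grid[[(gx2 - 1L) * ngy + gy2]]
        for (i in nb) {
          if (sqrt((ys[i] - y)^2 + (xs[i] - x)^2) <
              (1 - config$max_overlap_frac) * (rs[i] + r)) { ok <- FALSE; break }
        }
      }
      if (!ok) next
      ys <- c(ys, y); xs <- c(xs, x); rs <- c(rs, r); regs <- c(regs, reg)
      idx <- length(ys)
      g <- (gx - 1L) * ngy + gy
      grid[[g]] <- c(grid[[g]], idx)
      placed <- placed + 1L
    }
    if (placed < n_target) {
      stop(sprintf(
        "cell density too high: placed %d of %d cells in region '%s' after %d attempts",
        placed, n_target, reg, attempts))
    }
  }

  n <- length(ys)
  if (n == 0) {
    return(data.frame(cell_id = integer(0), y = numeric(0), x = numeric(0),
                      radius = numeric(0), region = character(0),
                      lineage_class = character(0), tet_class = character(0),
                      od_lineage = numeric(0), od_tet = numeric(0),
                      od_nuclear = numeric(0)))
  }
  lin_p <- config$lineage_pos_frac[regs]
  bri_p <- config$bright_frac[regs]
  lin_p[is.na(lin_p)] <- 0; bri_p[is.na(bri_p)] <- 0
  lineage <- ifelse(stats::runif(n) < lin_p, "pos", "neg")
  tet <- ifelse(stats::runif(n) < bri_p, "bright", "dim")

  od_lin <- numeric(n); od_tet <- numeric(n)
  pos <- lineage == "pos"
  od_lin[pos] <- rlnorm_med(sum(pos), config$od_lineage_pos)
  od_lin[!pos] <- rlnorm_med(sum(!pos), config$od_lineage_neg)
  ctrl <- regs == "other"
  # non-immune control cells: background-level tetraspanin staining
  od_tet[ctrl] <- rlnorm_med(sum(ctrl), config$od_tet_background)
  bb <- !ctrl & tet == "bright"
  dd <- !ctrl & tet == "dim"
  od_tet[bb] <- rlnorm_med(sum(bb), config$od_tet_bright)
  od_tet[dd] <- rlnorm_med(sum(dd), config$od_tet_dim)
  tet[ctrl] <- "dim"
  od_nuc <- rlnorm_med(n, config$od_nuclear)

  data.frame(cell_id = seq_len(n), y = ys, x = xs, radius = rs, region = regs,
             lineage_class = lineage, tet_class = tet,
             od_lineage = od_lin, od_tet = od_tet, od_nuclear = od_nuc)
}

# Rasterize per-cell OD levels into true H x W x K abundance maps:
# nuclear chromogen on the disk, membrane chromogens (lineage and
# tetraspanin) on an annulus, co-depositing additively.
rasterize_abundance <- function(cells, config, endmember_names) {
  H <- config$image_shape[1]; W <- config$image_shape[2]
  K <- length(endmember_names)
  maps <- array(0, c(H, W, K), dimnames = list(NULL, NULL, endmember_names))
  k_nuc <- match(config$channels[["nuclear"]], endmember_names)
  k_lin <- match(config$channels[["lineage"]], endmember_names)
  k_tet <- match(config$channels[["tetraspanin"]], endmember_names)
  if (any(is.na(c(k_nuc, k_lin, k_tet))))
    stop("channel map names endmembers absent from the endmember set")
  mw <- config$membrane_width_px
  for (i in seq_len(nrow(cells))) {
    y0 <- cells$y[i]; x0 <- cells$x[i]; r <- cells$radius[i]
    rr <- r + mw
    i0 <- max(1, floor(y0 - rr)); i1 <- min(H, ceiling(y0 + rr))
    j0 <- max(1, floor(x0 - rr)); j1 <- min(W, ceiling(x0 + rr))
    ii <- i0:i1; jj <- j0:j1
    d <- sqrt(outer((ii - y0)^2, (jj - x0)^2, "+"))
    disk <- d <= r
    ann <- d > r & d <= rr
    maps[ii, jj, k_nuc][disk] <- maps[ii, jj, k_nuc][disk] + cells$od_nuclear[i]
    if (any(ann)) {
      maps[ii, jj, k_lin][ann] <- maps[ii, jj, k_lin][ann] + cells$od_lineage[i]
      maps[ii, jj, k_tet][ann] <- maps[ii, jj, k_tet][ann] + cells$od_tet[i]
    }
  }
  maps
}

#' Render a multispectral cube from ground-truth abundances
#'
#' The forward optical model. Brightfield (Beer-Lambert):
#' `I(x, b) = I0 * 10^(-sum_k a_k(x) s_k(b)) + noise`, clipped to
#' `[0, I0]`. Fluorescence (additive):
#' `I(x, b) = sum_k a_k(x) s_k(b) + AF(b) * af_mask(x) + noise`, clipped
#' at 0. Noise is Gaussian with sd `noise_sd_frac * I0` (brightfield) or
#' `noise_sd_frac * max signal` (fluorescence), optionally preceded by
#' Poisson resampling.
#'
#' @param truth A `ground_truth` object (see [generate_scene()]), or any
#'   list with `abundance` (H x W x K, dimnames on the third margin) and
#'   `region_mask`.
#' @param endmembers The [endmember_set] to render with; its mode must
#'   match the config's.
#' @param config The [scene_config].
#' @param seed Seed for the noise draw; `NULL` uses the current RNG stream
#'   (as when called from [generate_scene()]).
#' @return A [multispectral_cube].
#' @export
render_cube <- function(truth, endmembers, config, seed = NULL) {
  stopifnot(inherits(endmembers, "endmember_set"))
  if (endmembers$mode != config$mode)
    stop(sprintf("mode mismatch: endmembers are %s, config is %s",
                 endmembers$mode, config$mode))
  A <- truth$abundance
  H <- dim(A)[1]; W <- dim(A)[2]; K <- dim(A)[3]
  stopifnot(K == length(endmembers$names))
  # align channel order with the endmember set
  ord <- match(endmembers$names, dimnames(A)[[3]])
  if (any(is.na(ord))) stop("abundance channels do not match endmember names")
  Af <- matrix(A[, , ord], H * W, K)
  S <- endmembers$spectra
  B <- ncol(S)

  with_seed(seed, {
    if (config$mode == "brightfield") {
      I <- config$I0 * 10^(-(Af %*% S))
      if (config$poisson_noise) I[] <- stats::rpois(length(I), pmax(I, 0))
      if (config$noise_sd_frac > 0)
        I <- I + stats::rnorm(length(I), 0, config$noise_sd_frac * config$I0)
      I[I < 0] <- 0
      I[I > config$I0] <- config$I0
      cube <- multispectral_cube(array(I, c(H, W, B)), endmembers$wavelengths_nm,
                                 "brightfield", I0 = config$I0,
                                 image_id = config$image_id)
    } else {
      I <- Af %*% S
      if (config$af_amplitude > 0) {
        af <- autofluorescence_spectrum(endmembers$wavelengths_nm)
        tissue <- as.numeric(truth$region_mask$labels !=
                               match("background", truth$region_mask$levels))
        I <- I + config$af_amplitude * outer(tissue, af)
      }
      peak <- max(I, 1e-12)
      if (config$poisson_noise) I[] <- stats::rpois(length(I), pmax(I, 0))
      if (config$noise_sd_frac > 0)
        I <- I + stats::rnorm(length(I), 0, config$noise_sd_frac * peak)
      I[I < 0] <- 0
      cube <- multispectral_cube(array(I, c(H, W, B)), endmembers$wavelengths_nm,
                                 "fluorescence", image_id = config$image_id)
    }
    cube
  })
}

# Broad smooth endogenous-tissue emission shape, peak-normalized.
autofluorescence_spectrum <- function(wavelengths_nm) {
  s <- exp(-0.5 * ((wavelengths_nm - 520) / 90)^2)
  s / max(s)
}

#' Generate a synthetic multispectral tissue scene with ground truth
#'
#' Lays out tissue regions (follicles, optional T-zone annuli, a non-immune
#' control strip, stroma), places disk nuclei at the configured per-region
#' densities with bounded overlap, assigns each cell a lineage class and a
#' dim/bright tetraspanin class by the region's probabilities, draws
#' per-cell chromogen OD levels from the configured log-normals,
#' rasterizes true abundance maps (nuclear chromogen on the disk, membrane
#' markers on an annulus) and renders the multispectral cube through
#' [render_cube()]. Identical `(config, seed)` give bit-identical output.
#'
#' @param config A [scene_config].
#' @param endmembers An [endmember_set] whose names cover the config's
#'   `channels` map.
#' @return List of class `synthetic_scene` with `truth` (class
#'   `ground_truth`: `region_mask`, `cells` data frame, `abundance` array,
#'   `channels`, `follicle_centers`) and `cube` (a [multispectral_cube]).
#' @export
#' @examples
#' em <- default_endmembers()
#' sc <- generate_scene(scene_config(image_shape = c(96, 96), n_follicles = 1,
#'   follicle_radius_px = 24, t_zone_width_px = 8, other_strip_px = 16,
#'   seed = 7), em)
#' nrow(sc$truth$cells)
generate_scene <- function(config, endmembers) {
  stopifnot(inherits(config, "scene_config"), inherits(endmembers, "endmember_set"))
  if (!all(config$channels %in% endmembers$names))
    stop("endmember set lacks channels: ",
         paste(setdiff(config$channels, endmembers$names), collapse = ", "))
  with_seed(config$seed, {
    layout <- build_region_layout(config)
    cells <- place_cells(config, layout$mask)
    abundance <- rasterize_abundance(cells, config, endmembers$names)
    truth <- structure(list(
      region_mask = layout$mask,
      cells = cells,
      abundance = abundance,
      channels = config$channels,
      follicle_centers = layout$follicle_centers
    ), class = "ground_truth")
    cube <- render_cube(truth, endmembers, config, seed = NULL)
    structure(list(truth = truth, cube = cube, config = config),
              class = "synthetic_scene")
  })
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("Synthetic scene '%s': %d cells\n", x$config$image_id,
              nrow(x$truth$cells)))
  print(x$truth$region_mask)
  invisible(x)
}
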