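#' Endmember set
#'
#' Container for the pure spectral signatures (endmembers) of the chromogens
#' or fluorophores in a staining panel: a `K x B` matrix with one
#' peak-normalized spectrum per row, the band center wavelengths, and the
#' acquisition mode.
#'
#' @param names Character vector of endmember identifiers.
#' @param wavelengths_nm Strictly increasing numeric vector of band centers.
#' @param spectra `K x B` non-negative matrix; each row is peak-normalized
#'   to maximum 1 (done here if not already).
#' @param mode `"brightfield"` (chromogens, Beer-Lambert optics) or
#'   `"fluorescence"` (additive emission).
#' @return An object of class `endmember_set` with fields `names`,
#'   `wavelengths_nm`, `spectra`, `mode` and `pairwise_angles_deg`.
#' @export
endmember_set <- function(names, wavelengths_nm, spectra, mode = c("brightfield", "fluorescence")) {
  mode <- match.arg(mode)
  spectra <- as.matrix(spectra)
  stopifnot(
    length(names) == nrow(spectra),
    length(wavelengths_nm) == ncol(spectra),
    all(diff(wavelengths_nm) > 0),
    ncol(spectra) >= nrow(spectra),
    all(spectra >= 0), all(is.finite(spectra))
  )
  rownames(spectra) <- names
  colnames(spectra) <- wavelengths_nm
  spectra <- peak_normalize(spectra)
  structure(list(
    names = as.character(names),
    wavelengths_nm = as.numeric(wavelengths_nm),
    spectra = spectra,
    mode = mode,
    pairwise_angles_deg = pairwise_angles(spectra)
  ), class = "endmember_set")
}

#' @export
print.endmember_set <- function(x, ...) {
  cat(sprintf("Endmember set (%s): %d endmembers x %d bands (%g-%g nm)\n",
              x$mode, length(x$names), length(x$wavelengths_nm),
              min(x$wavelengths_nm), max(x$wavelengths_nm)))
  K <- length(x$names)
  if (K > 1) {
    ang <- x$pairwise_angles_deg
    pairs <- which(upper.tri(ang), arr.ind = TRUE)
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1]; j <- pairs[r, 2]
      cat(sprintf("  angle(%s, %s) = %.2f deg\n", x$names[i], x$names[j], ang[i, j]))
    }
  }
  invisible(x)
}

# Smooth non-negative base spectrum: main Gaussian bump plus a smaller
# shoulder, evaluated on the band grid.
gaussian_spectrum <- function(wl, center, width, shoulder_frac = 0.3) {
  s <- exp(-0.5 * ((wl - center) / width)^2) +
    shoulder_frac * exp(-0.5 * ((wl - center - 1.3 * width) / (1.4 * width))^2)
  s / max(s)
}

#' Generate a synthetic endmember set with controlled spectral angles
#'
#' Builds smooth (sum-of-Gaussians) peak-normalized spectra on an evenly
#' spaced band grid. All pairwise spectral angles are at least
#' `min_pair_angle_deg`, except an optional designated pair that is driven
#' to a requested (typically small) angle — emulating panels where two
#' chromogens, like the two red stains Warp Red and Nuclear Red, are nearly
#' collinear and stress the unmixing.
#'
#' @param n_bands Number of spectral bands (`>= length(names)`).
#' @param names Endmember identifiers.
#' @param min_pair_angle_deg Minimum angle, degrees in (0, 90], required
#'   between all pairs other than `similar_pair`.
#' @param similar_pair Optional `list(name_a, name_b, angle_deg)` (or a
#'   length-3 vector): the pair whose angle is driven to `angle_deg`
#'   (within 0.5 degrees; in practice much closer).
#' @param seed Integer seed for the small jitter on peak positions.
#' @param wl_range Wavelength range in nm, default 420-720.
#' @param mode Acquisition mode of the set.
#' @return An [endmember_set].
#' @export
#' @examples
#' em <- generate_endmember_set(16, c("warp_red", "true_blue", "nuclear_red"),
#'   similar_pair = list("warp_red", "nuclear_red", 8), seed = 1)
#' em$pairwise_angles_deg["warp_red", "nuclear_red"] # ~8
generate_endmember_set <- function(n_bands, names, min_pair_angle_deg = 20,
                                   similar_pair = NULL, seed = 1,
                                   wl_range = c(420, 720),
                                   mode = c("brightfield", "fluorescence")) {
  mode <- match.arg(mode)
  K <- length(names)
  stopifnot(n_bands >= K, K >= 1,
            min_pair_angle_deg > 0, min_pair_angle_deg <= 90)
  if (!is.null(similar_pair)) {
    similar_pair <- as.list(similar_pair)
    stopifnot(length(similar_pair) == 3)
    ang_req <- as.numeric(similar_pair[[3]])
    stopifnot(ang_req > 0, ang_req <= 90,
              all(c(similar_pair[[1]], similar_pair[[2]]) %in% names))
  }
  wl <- seq(wl_range[1], wl_range[2], length.out = n_bands)
  span <- diff(wl_range)

  S <- with_seed(seed, {
    centers <- wl_range[1] + span * (seq_len(K) - 0.5) / K +
      stats::runif(K, -0.02, 0.02) * span
    width <- span / (2.2 * K)
    t(vapply(centers, function(cc) gaussian_spectrum(wl, cc, width),
             numeric(n_bands)))
  })
  rownames(S) <- names

  if (!is.null(similar_pair)) {
    ia <- match(similar_pair[[1]], names)
    ib <- match(similar_pair[[2]], names)
    a <- S[ia, ]; c0 <- S[ib, ]
    base_angle <- spectral_angle_deg(a, c0)
    if (base_angle < ang_req) {
      stop(sprintf(
        "requested similar-pair angle %.2f deg infeasible: base spectra are only %.2f deg apart",
        ang_req, base_angle))
    }
    # mixing b(t) = (1-t) a + t c moves the angle monotonically from 0 to
    # base_angle while staying non-negative; bisect on t
    f <- function(t) spectral_angle_deg(a, (1 - t) * a + t * c0) - ang_req
    t_star <- stats::uniroot(f, c(1e-12, 1), tol = 1e-12)$root
    S[ib, ] <- (1 - t_star) * a + t_star * c0
  }

  em <- endmember_set(names, wl, S, mode)

  ang <- em$pairwise_angles_deg
  if (K > 1) {
    chk <- matrix(TRUE, K, K); diag(chk) <- FALSE
    if (!is.null(similar_pair)) {
      ia <- match(similar_pair[[1]], names); ib <- match(similar_pair[[2]], names)
      chk[ia, ib] <- chk[ib, ia] <- FALSE
      if (abs(ang[ia, ib] - ang_req) > 0.5) {
        stop(sprintf("similar pair achieved %.3f deg, requested %.3f deg",
                     ang[ia, ib], ang_req))
      }
    }
    bad <- which(chk & ang < min_pair_angle_deg, arr.ind = TRUE)
    bad <- bad[bad[, 1] < bad[, 2], , drop = FALSE]
    if (nrow(bad) > 0) {
      msg <- paste(sprintf("%s-%s: %.2f deg", names[bad[, 1]], names[bad[, 2]],
                           ang[cbind(bad[, 1], bad[, 2])]), collapse = "; ")
      stop("angle constraints infeasible for n_bands=", n_bands,
           "; achieved angles: ", msg)
    }
  }
  em
}

#' Default three-chromogen panel
#'
#' The standard simulated panel: a Warp-Red-like lineage chromogen, a
#' True-Blue-like tetraspanin chromogen and a Nuclear-Red-like counterstain,
#' on 16 bands over 420-720 nm, with the two red chromogens at a
#' deliberately small 8-degree spectral angle.
#'
#' @param n_bands Number of bands (default 16).
#' @param red_pair_angle_deg Angle between the two red chromogens (default 8).
#' @param seed Seed passed to [generate_endmember_set()].
#' @return An [endmember_set] with endmembers `warp_red`, `true_blue`,
#'   `nuclear_red`.
#' @export
default_endmembers <- function(n_bands = 16, red_pair_angle_deg = 8, seed = 101) {
  generate_endmember_set(
    n_bands, c("warp_red", "true_blue", "nuclear_red"),
    min_pair_angle_deg = 20,
    similar_pair = list("warp_red", "nuclear_red", red_pair_angle_deg),
    seed = seed
  )
}
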