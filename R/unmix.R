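#' Unmix one pixel spectrum into non-negative endmember abundances
#'
#' Solves `argmin_{a >= 0} ||t(S) a - spectrum||_2` by non-negative least
#' squares ([nnls_solve()]). Because library endmembers are peak-normalized,
#' a brightfield coefficient equals the chromogen's OD contribution at its
#' peak band — the per-marker "optical density" used downstream.
#'
#' @param spectrum Length-B pixel spectrum (OD for brightfield,
#'   AF-corrected intensity for fluorescence).
#' @param endmembers `K x B` matrix of peak-normalized endmember spectra,
#'   an [endmember_set], or a `spectral_library`.
#' @return Named length-K non-negative coefficient vector.
#' @export
#' @examples
#' S <- rbind(e1 = c(1, 0), e2 = c(0, 1))
#' unmix_pixel(c(0.3, 0.7), S) # c(0.3, 0.7)
unmix_pixel <- function(spectrum, endmembers) {
  S <- endmember_matrix(endmembers)
  spectrum <- as.numeric(spectrum)
  if (!all(is.finite(spectrum))) stop("non-finite values in pixel spectrum")
  stopifnot(length(spectrum) == ncol(S), ncol(S) >= nrow(S))
  a <- nnls_solve(t(S), spectrum)$coef
  names(a) <- rownames(S)
  a
}

endmember_matrix <- function(x) {
  if (inherits(x, "spectral_library")) x <- x$endmembers
  if (inherits(x, "endmember_set")) return(x$spectra)
  as.matrix(x)
}

#' Unmix a whole cube against a spectral library
#'
#' Applies non-negative least squares to every pixel. Brightfield input
#' must already be OD-converted (an `od_cube`); fluorescence cubes are
#' unmixed on raw (AF-corrected) intensities. Pixels whose unconstrained
#' least-squares solution is already non-negative are solved in one
#' vectorized normal-equations pass; the remainder go through the
#' active-set solver, which yields the identical minimizer on the easy
#' pixels and the exact constrained one elsewhere. Warns when the library
#' carries near-collinear endmembers (see [library_condition_report()]).
#'
#' @param x An `od_cube` (brightfield) or fluorescence
#'   [multispectral_cube].
#' @param library A `spectral_library` or [endmember_set].
#' @return Object of class `abundance_map`: `coefficients`
#'   (H x W x K, named on the third margin), `residual` (H x W Euclidean
#'   reconstruction residuals), `wavelengths_nm`, `mode`, `library`.
#' @export
unmix_cube <- function(x, library) {
  em <- if (inherits(library, "spectral_library")) library$endmembers else library
  stopifnot(inherits(em, "endmember_set"))
  if (inherits(x, "multispectral_cube")) {
    if (x$mode == "brightfield")
      stop("convert brightfield cubes with to_optical_density() before unmixing")
    if (em$mode != "fluorescence")
      stop("fluorescence cube unmixed against a ", em$mode, " library")
  } else if (!inherits(x, "od_cube")) {
    stop("x must be an od_cube or a fluorescence multispectral_cube")
  }
  if (!isTRUE(all.equal(x$wavelengths_nm, em$wavelengths_nm)))
    stop("wavelengths of image and library do not match")

  crep <- library_condition_report(em)
  if (nrow(crep$flagged_pairs) > 0) {
    warning(sprintf(
      "near-collinear endmembers (angle < %g deg): %s — abundance estimates may be noise-amplified",
      crep$warn_angle_deg,
      paste(sprintf("%s/%s (%.2f)", crep$flagged_pairs$name_a,
                    crep$flagged_pairs$name_b, crep$flagged_pairs$angle_deg),
            collapse = ", ")))
  }

  d <- dim(x$data)
  H <- d[1]; W <- d[2]; B <- d[3]
  S <- em$spectra                       # K x B
  K <- nrow(S)
  X <- t(matrix(x$data, H * W, B))      # B x N
  if (!all(is.finite(X))) stop("non-finite values in input cube")

  G <- S %*% t(S)
  C <- S %*% X
  A <- solve(G, C)                      # unconstrained LS, K x N
  bad <- which(colSums(A < -1e-12) > 0)
  if (length(bad)) {
    A[, bad] <- nnls_batch(G, C[, bad, drop = FALSE],
                           colSums(X[, bad, drop = FALSE]^2), t(S),
                           X[, bad, drop = FALSE])
  }
  A[A < 0] <- 0
  E <- t(S) %*% A - X
  resid <- sqrt(colSums(E^2))

  structure(list(
    coefficients = array(t(A), c(H, W, K), dimnames = list(NULL, NULL, em$names)),
    residual = matrix(resid, H, W),
    wavelengths_nm = em$wavelengths_nm,
    mode = em$mode,
    library = library
  ), class = "abundance_map")
}

# Exact NNLS for many pixels at once by enumerating support subsets
# (valid because the NNLS optimum solves unconstrained LS on its support,
# so it is the feasible subset solution of minimal SSE). Vectorized over
# pixels for small K; falls back to per-pixel active set for K > 10.
nnls_batch <- function(G, C, xx, At, X) {
  K <- nrow(G)
  n <- ncol(C)
  if (K > 10) {
    A <- matrix(0, K, n)
    for (p in seq_len(n)) A[, p] <- nnls_solve(At, X[, p])$coef
    return(A)
  }
  best_sse <- xx                        # empty support: a = 0
  A <- matrix(0, K, n)
  subsets <- lapply(seq_len(2^K - 1), function(m) which(bitwAnd(m, 2^(seq_len(K) - 1)) > 0))
  for (P in subsets) {
    GP <- G[P, P, drop = FALSE]
    AP <- tryCatch(solve(GP, C[P, , drop = FALSE]), error = function(e) NULL)
    if (is.null(AP)) next
    feas <- colSums(AP < -1e-12) == 0
    sse <- xx - colSums(AP * C[P, , drop = FALSE])
    upd <- feas & sse < best_sse - 1e-12
    if (any(upd)) {
      best_sse[upd] <- sse[upd]
      A[, upd] <- 0
      A[P, upd] <- AP[, upd]
    }
  }
  A
}

#' @export
print.abundance_map <- function(x, ...) {
  d <- dim(x$coefficients)
  cat(sprintf("Abundance map: %d x %d px, %d endmembers (%s); mean residual %.3g\n",
              d[1], d[2], d[3], paste(dimnames(x$coefficients)[[3]], collapse = ", "),
              mean(x$residual)))
  invisible(x)
}

#' Summarize reconstruction residuals of an unmixing result
#'
#' Recomputes `||t(S) a - spectrum||_2` per pixel independently of the
#' values stored in the abundance map and summarizes them over tissue
#' pixels (or all pixels).
#'
#' @param abundances An `abundance_map`.
#' @param odcube The `od_cube` (or fluorescence cube) it was computed from.
#' @param tissue_mask Optional logical matrix restricting the summary.
#' @return List with `mean`, `p95`, `max` and the `residual` matrix.
#' @export
reconstruction_residual <- function(abundances, odcube, tissue_mask = NULL) {
  stopifnot(inherits(abundances, "abundance_map"))
  S <- endmember_matrix(abundances$library)
  d <- dim(odcube$data)
  stopifnot(all(dim(abundances$coefficients)[1:2] == d[1:2]))
  A <- t(matrix(abundances$coefficients, d[1] * d[2], nrow(S)))
  X <- t(matrix(odcube$data, d[1] * d[2], d[3]))
  r <- sqrt(colSums((t(S) %*% A - X)^2))
  keep <- if (is.null(tissue_mask)) rep(TRUE, length(r)) else as.logical(tissue_mask)
  rs <- r[keep]
  list(mean = mean(rs), p95 = stats::quantile(rs, 0.95, names = FALSE),
       max = max(rs), residual = matrix(r, d[1], d[2]))
}
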