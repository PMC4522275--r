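#' Build a spectral library from single-stain cubes
#'
#' For each single-stain image, foreground pixels are those whose total
#' signal (summed OD across bands in brightfield, summed intensity in
#' fluorescence) exceeds the `foreground_quantile` of that image; the
#' endmember is the mean foreground spectrum, peak-normalized to 1.
#' Brightfield cubes are converted to optical density first, so brightfield
#' endmembers are absorbance spectra.
#'
#' @param single_stain_cubes Named list of [multispectral_cube] objects,
#'   one per stain; names become endmember names.
#' @param mode Acquisition mode; all cubes must match.
#' @param foreground_quantile Quantile of total signal above which a pixel
#'   counts as foreground (default 0.90).
#' @param od_max OD ceiling for the brightfield conversion.
#' @return Object of class `spectral_library`: `endmembers` (an
#'   [endmember_set]), `raw_spectra` (pre-normalization mean spectra),
#'   `autofluorescence` (NULL until set), and per-stain `meta`
#'   (foreground pixel count and threshold).
#' @export
build_library <- function(single_stain_cubes,
                          mode = c("brightfield", "fluorescence"),
                          foreground_quantile = 0.90, od_max = 3) {
  mode <- match.arg(mode)
  stopifnot(length(single_stain_cubes) >= 1,
            !is.null(names(single_stain_cubes)),
            all(nzchar(names(single_stain_cubes))))
  wl <- single_stain_cubes[[1]]$wavelengths_nm
  raw <- matrix(NA_real_, length(single_stain_cubes), length(wl),
                dimnames = list(names(single_stain_cubes), wl))
  meta <- list()
  for (nm in names(single_stain_cubes)) {
    cube <- single_stain_cubes[[nm]]
    stopifnot(inherits(cube, "multispectral_cube"))
    if (!isTRUE(all.equal(cube$wavelengths_nm, wl)))
      stop("mismatched wavelengths across single-stain cubes (", nm, ")")
    if (cube$mode != mode) stop("cube '", nm, "' is not in ", mode, " mode")
    sig <- if (mode == "brightfield") to_optical_density(cube, od_max = od_max)$data else cube$data
    d <- dim(sig)
    X <- matrix(sig, d[1] * d[2], d[3])
    total <- rowSums(X)
    thr <- stats::quantile(total, foreground_quantile, names = FALSE)
    fg <- total > thr
    if (!any(fg)) stop("empty foreground after thresholding for stain '", nm, "'")
    raw[nm, ] <- colMeans(X[fg, , drop = FALSE])
    meta[[nm]] <- list(n_foreground = sum(fg), foreground_threshold = thr,
                       foreground_quantile = foreground_quantile)
  }
  structure(list(
    endmembers = endmember_set(rownames(raw), wl, raw, mode),
    raw_spectra = raw,
    autofluorescence = NULL,
    meta = meta
  ), class = "spectral_library")
}

#' @export
print.spectral_library <- function(x, ...) {
  cat("Spectral library\n")
  print(x$endmembers)
  if (!is.null(x$autofluorescence)) cat("  autofluorescence spectrum attached\n")
  invisible(x)
}

#' Estimate a tissue autofluorescence spectrum
#'
#' Per-band mean intensity of an unstained fluorescence image over the
#' tissue mask — the endogenous emission to subtract from each
#' fluorophore's library spectrum before unmixing.
#'
#' @param unstained_cube A fluorescence [multispectral_cube] of unstained
#'   tissue.
#' @param tissue_mask Logical `H x W` matrix; must select at least one
#'   pixel.
#' @return Numeric length-B vector (raw intensity units).
#' @export
estimate_autofluorescence <- function(unstained_cube, tissue_mask) {
  stopifnot(inherits(unstained_cube, "multispectral_cube"))
  if (unstained_cube$mode != "fluorescence")
    stop("autofluorescence is estimated from fluorescence images")
  tissue_mask <- as.logical(tissue_mask)
  d <- dim(unstained_cube$data)
  stopifnot(length(tissue_mask) == d[1] * d[2])
  if (!any(tissue_mask)) stop("empty tissue mask")
  X <- matrix(unstained_cube$data, d[1] * d[2], d[3])
  af <- colMeans(X[tissue_mask, , drop = FALSE])
  names(af) <- unstained_cube$wavelengths_nm
  af
}

#' Subtract autofluorescence from a fluorescence library
#'
#' Subtracts the autofluorescence spectrum from each raw (pre-normalized)
#' endmember spectrum, clamps at zero per band, and re-peak-normalizes.
#' The spectrum is retained in the library so it can optionally be used as
#' an extra unmixing endmember instead.
#'
#' @param library A fluorescence [build_library()] result.
#' @param af Length-B non-negative autofluorescence spectrum.
#' @return The corrected `spectral_library` (with `autofluorescence` set).
#' @export
subtract_autofluorescence <- function(library, af) {
  stopifnot(inherits(library, "spectral_library"))
  if (library$endmembers$mode != "fluorescence")
    stop("autofluorescence subtraction applies to fluorescence libraries only")
  af <- as.numeric(af)
  stopifnot(length(af) == length(library$endmembers$wavelengths_nm), all(af >= 0))
  raw <- pmax(sweep(library$raw_spectra, 2, af, "-"), 0)
  dead <- apply(raw, 1, max) <= 0
  if (any(dead)) {
    stop("autofluorescence subtraction annihilates the spectrum of ",
         paste(rownames(raw)[dead], collapse = ", "))
  }
  library$raw_spectra <- raw
  library$endmembers <- endmember_set(rownames(raw),
                                      library$endmembers$wavelengths_nm,
                                      raw, "fluorescence")
  library$autofluorescence <- af
  library
}

#' Report how well-conditioned a library is for unmixing
#'
#' Pairwise spectral angles, the 2-norm condition number of the endmember
#' matrix, and flags for pairs closer than a warning threshold — the
#' quantitative check on how separable near-collinear chromogens (like two
#' red stains) are.
#'
#' @param library A `spectral_library` or [endmember_set].
#' @param warn_angle_deg Pairs below this angle are flagged (default 3).
#' @return List with `angles_deg` (K x K), `condition_number`, and
#'   `flagged_pairs` (data frame of name_a, name_b, angle_deg).
#' @export
library_condition_report <- function(library, warn_angle_deg = 3) {
  em <- if (inherits(library, "spectral_library")) library$endmembers else library
  stopifnot(inherits(em, "endmember_set"))
  S <- em$spectra
  ang <- em$pairwise_angles_deg
  sv <- svd(t(S))$d
  cond <- if (min(sv) <= max(sv) * .Machine$double.eps) Inf else max(sv) / min(sv)
  flagged <- data.frame(name_a = character(0), name_b = character(0),
                        angle_deg = numeric(0))
  K <- nrow(S)
  if (K > 1) {
    for (i in seq_len(K - 1)) for (j in (i + 1):K) {
      if (ang[i, j] < warn_angle_deg) {
        flagged <- rbind(flagged, data.frame(name_a = em$names[i],
                                             name_b = em$names[j],
                                             angle_deg = ang[i, j]))
      }
    }
  }
  list(angles_deg = ang, condition_number = cond, flagged_pairs = flagged,
       warn_angle_deg = warn_angle_deg)
}

#' Write / read a spectral library as CSV plus JSON sidecar
#'
#' CSV rows are endmembers (plus an `autofluorescence` row when present),
#' columns are wavelengths; metadata (mode, foreground selection, raw peak
#' values) goes to `<path>.json`.
#'
#' @param library A `spectral_library`.
#' @param path CSV path.
#' @return `write_spectral_library` returns `path` invisibly;
#'   `read_spectral_library` returns the `spectral_library`.
#' @export
write_spectral_library <- function(library, path) {
  stopifnot(inherits(library, "spectral_library"))
  em <- library$endmembers
  M <- em$spectra
  if (!is.null(library$autofluorescence))
    M <- rbind(M, autofluorescence = library$autofluorescence)
  df <- data.frame(name = rownames(M), M, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  side <- list(mode = em$mode, wavelengths_nm = em$wavelengths_nm,
               raw_peak = apply(library$raw_spectra, 1, max),
               meta = library$meta)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_spectral_library
#' @export
read_spectral_library <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  M <- as.matrix(df[, -1, drop = FALSE])
  rownames(M) <- df$name
  af <- NULL
  if ("autofluorescence" %in% rownames(M)) {
    af <- M["autofluorescence", ]
    M <- M[setdiff(rownames(M), "autofluorescence"), , drop = FALSE]
  }
  raw <- M
  if (!is.null(side$raw_peak)) {
    pk <- unlist(side$raw_peak)[rownames(M)]
    pk[is.na(pk)] <- 1
    raw <- M * pk
  }
  structure(list(
    endmembers = endmember_set(rownames(M), side$wavelengths_nm, M, side$mode),
    raw_spectra = raw,
    autofluorescence = af,
    meta = side$meta
  ), class = "spectral_library")
}

# Coerce an endmember_set into a bare library (used by the pipeline when
# the true endmembers are supplied directly instead of single-stain cubes).
as_spectral_library <- function(endmembers) {
  stopifnot(inherits(endmembers, "endmember_set"))
  structure(list(endmembers = endmembers, raw_spectra = endmembers$spectra,
                 autofluorescence = NULL, meta = list()),
            class = "spectral_library")
}
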