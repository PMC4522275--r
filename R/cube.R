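#' Multispectral image cube
#'
#' An `H x W x B` stack of non-negative intensities, one plane per spectral
#' band, with band wavelengths and the acquisition mode. Brightfield cubes
#' carry the white reference `I0` (blank-field intensity) used for optical
#' density conversion.
#'
#' @param data Numeric `H x W x B` array of intensities (`>= 0`).
#' @param wavelengths_nm Strictly increasing band centers, length `B`.
#' @param mode `"brightfield"` or `"fluorescence"`.
#' @param I0 White reference: positive scalar or length-B vector
#'   (brightfield only; brightfield intensities must not exceed `I0` by
#'   more than 0.1 percent).
#' @param image_id Optional identifier carried through the pipeline.
#' @param pixel_size_um Optional physical pixel size.
#' @return Object of class `multispectral_cube`.
#' @export
multispectral_cube <- function(data, wavelengths_nm,
                               mode = c("brightfield", "fluorescence"),
                               I0 = NULL, image_id = NULL, pixel_size_um = NULL) {
  mode <- match.arg(mode)
  data <- as.array(data)
  stopifnot(length(dim(data)) == 3,
            dim(data)[3] == length(wavelengths_nm),
            all(diff(wavelengths_nm) > 0),
            all(is.finite(data)), all(data >= 0))
  if (mode == "brightfield") {
    if (is.null(I0)) stop("brightfield cubes require a white reference I0")
    stopifnot(all(I0 > 0), length(I0) %in% c(1L, dim(data)[3]))
    I0max <- if (length(I0) == 1) rep(I0, dim(data)[3]) else I0
    for (b in seq_len(dim(data)[3])) {
      if (max(data[, , b]) > I0max[b] * 1.001)
        stop("brightfield intensities exceed the white reference I0 in band ", b)
    }
  }
  structure(list(
    data = data, wavelengths_nm = as.numeric(wavelengths_nm), mode = mode,
    I0 = I0, image_id = image_id, pixel_size_um = pixel_size_um
  ), class = "multispectral_cube")
}

#' @export
print.multispectral_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Multispectral cube%s: %d x %d px, %d bands (%g-%g nm), %s%s\n",
              if (is.null(x$image_id)) "" else paste0(" '", x$image_id, "'"),
              d[1], d[2], d[3], min(x$wavelengths_nm), max(x$wavelengths_nm),
              x$mode,
              if (x$mode == "brightfield") sprintf(", I0 = %g", x$I0[1]) else ""))
  invisible(x)
}

#' Convert brightfield intensities to optical density
#'
#' Beer-Lambert conversion `OD(x, b) = -log10(max(I, eps) / I0)`, clamped to
#' `[0, od_max]`, with `eps = I0 * 10^-od_max` so zero-intensity pixels map
#' to the OD ceiling. Optical density is linear in chromogen amount, which
#' is what makes per-pixel unmixing a linear problem in brightfield.
#'
#' @param cube A brightfield [multispectral_cube].
#' @param I0 White reference (scalar or per-band); defaults to the cube's.
#' @param od_max OD ceiling, default 3 (transmittance 1/1000).
#' @return Object of class `od_cube`: fields `data` (H x W x B absorbances),
#'   `wavelengths_nm`, `I0`, `od_max`, `image_id`.
#' @export
#' @examples
#' cube <- multispectral_cube(array(25.5, c(1, 1, 1)), 550, "brightfield", I0 = 255)
#' to_optical_density(cube)$data[1, 1, 1] # 1
to_optical_density <- function(cube, I0 = NULL, od_max = 3) {
  stopifnot(inherits(cube, "multispectral_cube"))
  if (cube$mode != "brightfield")
    stop("optical density is defined for brightfield cubes only")
  I0 <- I0 %||% cube$I0
  if (is.null(I0) || any(I0 <= 0)) stop("I0 must be positive")
  B <- dim(cube$data)[3]
  I0v <- if (length(I0) == 1) rep(as.numeric(I0), B) else as.numeric(I0)
  stopifnot(length(I0v) == B, od_max > 0)
  od <- cube$data
  for (b in seq_len(B)) {
    eps <- I0v[b] * 10^(-od_max)
    od[, , b] <- -log10(pmax(cube$data[, , b], eps) / I0v[b])
  }
  od[od < 0] <- 0
  od[od > od_max] <- od_max
  structure(list(data = od, wavelengths_nm = cube$wavelengths_nm,
                 I0 = I0v, od_max = od_max, image_id = cube$image_id),
            class = "od_cube")
}

#' @export
print.od_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("OD cube%s: %d x %d px, %d bands, od_max = %g\n",
              if (is.null(x$image_id)) "" else paste0(" '", x$image_id, "'"),
              d[1], d[2], d[3], x$od_max))
  invisible(x)
}
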