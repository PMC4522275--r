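# 32-bit TIFF storage grid. The writer truncates sample * (2^32 - 1) to
# a uint32 code, with double-rounding jitter at exact grid points, so we
# encode each code at its half-step midpoint (k + 0.5) / M — truncation
# then lands exactly on k — and snap to the grid with round() on read.
# Quantization error is 2^-32 of the scale; the grid round-trips exactly.
M32 <- 4294967295
enc32 <- function(x) {
  k <- pmin(pmax(round(x * M32), 0), M32)
  ifelse(k == M32, 1, (k + 0.5) / M32)
}
# the reader scales 32-bit samples by 2^32 (16-bit ones by 2^16 - 1)
dec32 <- function(p) pmin(round(p * 4294967296), M32) / M32

#' Write / read a multispectral cube as multi-page TIFF
#'
#' One 32-bit page per band plus a JSON sidecar (`<path>.json`) holding
#' wavelengths, mode, `I0`, image id and the storage scale. Samples are
#' stored as `value / scale` with a power-of-two scale at 32-bit
#' precision (quantization `2^-32` of the scale, finer than single
#' precision over most of the range); data already on the storage grid —
#' in particular anything previously read back — round-trips
#' bit-identically.
#'
#' @param cube A [multispectral_cube].
#' @param path Output TIFF path.
#' @return `write_cube` returns `path` invisibly; `read_cube` the cube.
#' @export
write_cube <- function(cube, path) {
  stopifnot(inherits(cube, "multispectral_cube"))
  d <- dim(cube$data)
  mx <- max(cube$data, 1)
  scale <- 2^ceiling(log2(mx))
  pages <- lapply(seq_len(d[3]), function(b) matrix(enc32(cube$data[, , b] / scale),
                                                    d[1], d[2]))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  side <- list(wavelengths_nm = cube$wavelengths_nm, mode = cube$mode,
               I0 = cube$I0, image_id = cube$image_id,
               pixel_size_um = cube$pixel_size_um, scale = scale)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_cube
#' @export
read_cube <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  side_path <- paste0(path, ".json")
  if (!file.exists(side_path))
    stop("missing metadata sidecar: ", side_path)
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  if (is.null(side$wavelengths_nm))
    stop("sidecar lacks band wavelengths: ", side_path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  dims <- vapply(pages, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("inconsistent page shapes in ", path)
  if (length(pages) != length(side$wavelengths_nm))
    stop(sprintf("%d TIFF pages but %d declared wavelengths in %s",
                 length(pages), length(side$wavelengths_nm), path))
  scale <- side$scale %||% 1
  arr <- array(0, c(dims[1, 1], dims[2, 1], length(pages)))
  for (b in seq_along(pages)) arr[, , b] <- dec32(pages[[b]]) * scale
  multispectral_cube(arr, side$wavelengths_nm, side$mode, I0 = side$I0,
                     image_id = side$image_id,
                     pixel_size_um = side$pixel_size_um)
}

# uint16 label TIFF with an optional JSON sidecar carrying level names.
write_label_tiff <- function(labels, path, levels = NULL) {
  labels <- as.matrix(labels)
  if (max(labels) > 65535) stop("more than 65535 labels")
  enc <- ifelse(labels == 65535, 1, (labels + 0.5) / 65535)
  tiff::writeTIFF(matrix(enc, nrow(labels), ncol(labels)), path,
                  bits.per.sample = 16L, compression = "none")
  if (!is.null(levels)) {
    jsonlite::write_json(list(levels = levels), paste0(path, ".json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

read_label_tiff <- function(path) {
  m <- round(tiff::readTIFF(path) * 65535)
  storage.mode(m) <- "integer"
  side_path <- paste0(path, ".json")
  levels <- if (file.exists(side_path)) {
    unlist(jsonlite::read_json(side_path, simplifyVector = TRUE)$levels)
  } else NULL
  list(labels = m, levels = levels)
}

#' Write / read a region mask as integer TIFF
#'
#' @param mask A [region_mask].
#' @param path Output TIFF path.
#' @return `write_region_mask` returns `path` invisibly; `read_region_mask`
#'   the [region_mask].
#' @export
write_region_mask <- function(mask, path) {
  stopifnot(inherits(mask, "region_mask"))
  write_label_tiff(mask$labels, path, levels = mask$levels)
}

#' @rdname write_region_mask
#' @export
read_region_mask <- function(path) {
  x <- read_label_tiff(path)
  region_mask(x$labels, x$levels %||% REGION_LEVELS)
}

#' Write an abundance map as multi-page 32-bit TIFF
#'
#' One page per endmember plus a final residual page, with a JSON sidecar
#' naming the pages and recording the storage scale.
#'
#' @param abundances An `abundance_map`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_abundance_map <- function(abundances, path) {
  stopifnot(inherits(abundances, "abundance_map"))
  A <- abundances$coefficients
  d <- dim(A)
  mx <- max(A, abundances$residual, 1)
  scale <- 2^ceiling(log2(mx))
  pages <- c(lapply(seq_len(d[3]), function(k)
    matrix(enc32(A[, , k] / scale), d[1], d[2])),
    list(matrix(enc32(abundances$residual / scale), d[1], d[2])))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  jsonlite::write_json(
    list(pages = c(dimnames(A)[[3]], "residual"), scale = scale,
         mode = abundances$mode, wavelengths_nm = abundances$wavelengths_nm),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Save a synthetic scene to disk
#'
#' Writes the rendered cube (TIFF + sidecar), the ground-truth cell table
#' (CSV), the ground-truth region mask (integer TIFF) and the scene
#' configuration (plain-text key-value file, seed included) into a
#' directory.
#'
#' @param scene A [generate_scene()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_scene <- function(scene, dir) {
  stopifnot(inherits(scene, "synthetic_scene"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_cube(scene$cube, file.path(dir, "cube.tiff"))
  write_region_mask(scene$truth$region_mask, file.path(dir, "region_mask.tiff"))
  cells <- scene$truth$cells
  utils::write.csv(
    cells[, c("cell_id", "y", "x", "radius", "region", "lineage_class",
              "tet_class", "od_lineage", "od_tet", "od_nuclear")],
    file.path(dir, "cells_truth.csv"), row.names = FALSE)
  write_scene_config(scene$config, file.path(dir, "config.txt"))
  invisible(dir)
}

#' Write a scene configuration as a plain-text key-value file
#'
#' Scalars as `key = value`, vectors comma-joined (named vectors as
#' `name:value` pairs); diff-able and language-neutral.
#'
#' @param config A [scene_config].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scene_config <- function(config, path) {
  fmt <- function(v) {
    if (is.null(v)) return("")
    if (!is.null(names(v)) && any(nzchar(names(v)))) {
      paste(sprintf("%s:%s", names(v), as.character(v)), collapse = ",")
    } else paste(as.character(v), collapse = ",")
  }
  keys <- setdiff(names(config), "")
  writeLines(sprintf("%s = %s", keys,
                     vapply(config[keys], fmt, character(1))), path)
  invisible(path)
}

#' Write / read pipeline cell records as CSV
#'
#' @param records Cell records data frame.
#' @param path CSV path.
#' @return `write_cell_records` returns `path` invisibly;
#'   `read_cell_records` the data frame.
#' @export
write_cell_records <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cell_records
#' @export
read_cell_records <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
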