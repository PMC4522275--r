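# Shared fixtures, built in code at test time.

test_endmembers <- function() default_endmembers()

# A small but fully featured scene configuration (one follicle complex,
# control strip) that keeps per-test runtime low.
small_scene_config <- function(seed, ..., image_id = paste0("scene", seed)) {
  scene_config(image_shape = c(192, 192), n_follicles = 1,
               follicle_radius_px = 40, other_strip_px = 32,
               seed = seed, image_id = image_id, ...)
}

# Build a brightfield cube directly from a per-pixel OD array and an
# endmember set (noise-free forward model); handy for library tests.
cube_from_od <- function(od_by_channel, endmembers, I0 = 255) {
  H <- dim(od_by_channel)[1]; W <- dim(od_by_channel)[2]
  A <- matrix(od_by_channel, H * W, dim(od_by_channel)[3])
  I <- I0 * 10^(-(A %*% endmembers$spectra))
  multispectral_cube(array(I, c(H, W, ncol(endmembers$spectra))),
                     endmembers$wavelengths_nm, "brightfield", I0 = I0)
}
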