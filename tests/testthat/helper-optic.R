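# Small-field parameter sets so unit tests stay fast; the acceptance tests
# use the package defaults where the check is about default behaviour.

fast_params <- function(...) {
  args <- list(field_shape = c(96L, 96L), cell_radius = 22,
               spot_radius = 3, cluster_angle = pi / 4)
  user <- list(...)
  args[names(user)] <- user
  do.call(optic_params, args)
}

noise_free <- function(..., blur = TRUE) {
  args <- list(psf_sigma = if (blur) 2 else 0, poisson = FALSE,
               gaussian_read_sd = 0)
  user <- list(...)
  args[names(user)] <- user
  do.call(fast_params, args)
}

disk <- function(shape, center, radius) {
  rows <- matrix(seq_len(shape[1]) - 1, shape[1], shape[2])
  cols <- matrix(seq_len(shape[2]) - 1, shape[1], shape[2], byrow = TRUE)
  (rows - center[1])^2 + (cols - center[2])^2 <= radius^2
}

# Fixture from the worked boundary example: a uniform cell ROI at 71
# counts and an adjacent cluster ROI whose brightest pixel is 142 counts.
boundary_fixture <- function() {
  poi <- matrix(0, 64, 64)
  roi1 <- matrix(FALSE, 64, 64); roi1[10:50, 10:40] <- TRUE
  poi[roi1] <- 71
  roi2 <- matrix(FALSE, 64, 64); roi2[28:32, 42:46] <- TRUE
  poi[roi2] <- 71
  poi[30, 44] <- 142
  list(poi = poi, roi1 = roi1, roi2 = roi2)
}
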