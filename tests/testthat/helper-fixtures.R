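# Shared fixtures and small independent oracles used across test files.

# Digitised ball mask: voxel centres within `radius` of the grid centre.
ball_mask <- function(radius, pitch, n, label = "sphere") {
  ax <- (seq_len(n) - 0.5) * pitch - n * pitch / 2
  d2 <- outer(outer(ax^2, ax^2, "+"), ax^2, "+")
  region_mask(d2 <= radius^2, label, rep(pitch, 3))
}

# Digitised axis-aligned ellipsoid mask (semi-axes a, b, c).
ellipsoid_mask <- function(semi, pitch, n, label = "ellipsoid") {
  ax <- (seq_len(n) - 0.5) * pitch - n * pitch / 2
  d2 <- outer(outer(ax^2 / semi[1]^2, ax^2 / semi[2]^2, "+"),
              ax^2 / semi[3]^2, "+")
  region_mask(d2 <= 1, label, rep(pitch, 3))
}

# Closed-form surface area of a prolate spheroid with polar semi-axis a
# and equatorial semi-axis b (a > b).
prolate_area <- function(a, b) {
  e <- sqrt(1 - b^2 / a^2)
  2 * pi * b^2 * (1 + a / (b * e) * asin(e))
}

# Exhaustive per-voxel window classification: the brute-force oracle for
# segment_by_ri, written as plain loops over every voxel.
brute_force_segment <- function(grid, ranges) {
  out <- list(whole = array(FALSE, dim(grid)),
              midpiece = array(FALSE, dim(grid)),
              nucleus = array(FALSE, dim(grid)))
  d <- dim(grid)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    v <- grid[i, j, k]
    for (r in names(out)) {
      w <- ranges[[r]]
      if (v >= w[1] && v < w[2]) out[[r]][i, j, k] <- TRUE
    }
  }
  out
}

# Average segmented window volumes over sub-voxel placements of a phantom,
# the voxel-count oracle used for volume-recovery checks.
jittered_window_volume <- function(spec, region, voxel_size, grid_shape,
                                   n_rep = 12) {
  ext_phys <- grid_shape * voxel_size
  ext <- spermHT:::phantom_extent(spec)
  a <- spec$nucleus_semiaxes[1]
  vols <- replicate(n_rep, {
    ctr <- c((ext_phys[1] - ext["x"]) / 2 + a, ext_phys[2] / 2,
             ext_phys[3] / 2) + runif(3, -0.5, 0.5) * voxel_size
    masks <- segment_cell(render_tomogram(spec, voxel_size, grid_shape,
                                          center = ctr))
    mask_volume(masks[[region]])
  })
  mean(vols)
}
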