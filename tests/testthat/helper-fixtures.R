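# build a particle_table from terse per-particle rows
ptab <- function(..., pixel_size = 1) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r) {
    as.data.frame(utils::modifyList(
      list(tomogram_id = "t1", particle_id = NA_integer_,
           x = 0, y = 0, z = 0, rot = 0, tilt = 0, psi = 0,
           state_label = "unassigned", population_label = "unassigned"),
      r), stringsAsFactors = FALSE)
  }))
  if (anyNA(df$particle_id))
    df$particle_id <- stats::ave(seq_len(nrow(df)), df$tomogram_id,
                                 FUN = seq_along)
  particle_table(df, pixel_size = pixel_size)
}

# minimal STAR file writer for read tests (columns given as named vectors)
write_star_fixture <- function(path, cols) {
  lines <- c("data_particles", "", "loop_",
             sprintf("_%s #%d", names(cols), seq_along(cols)))
  n <- length(cols[[1]])
  if (n > 0) {
    mat <- vapply(cols, function(x) as.character(x), character(n))
    if (n == 1L) mat <- matrix(mat, nrow = 1L)
    lines <- c(lines, apply(mat, 1L, paste, collapse = " "))
  }
  writeLines(lines, path, useBytes = TRUE)
  path
}

# direction mask whose TRUE region is the set of voxels containing `points`
planted_mask <- function(points, direction, geometry = histogram_geometry(),
                         dilation = 0) {
  vox <- array(FALSE, dim = rep(geometry$n_voxels, 3))
  if (!is.matrix(points)) points <- matrix(points, ncol = 3, byrow = FALSE)
  ix <- polysomix:::bin_axis(points[, 1], geometry)
  iy <- polysomix:::bin_axis(points[, 2], geometry)
  iz <- polysomix:::bin_axis(points[, 3], geometry)
  vox[cbind(ix, iy, iz)] <- TRUE
  if (dilation > 0) vox <- polysomix:::dilate_mask(vox, dilation)
  polysomix:::new_direction_mask(geometry, vox, direction, "planted")
}

# key strings for edge comparison
edge_keys <- function(edges) {
  paste(edges$tomogram_id, edges$trailing_id, edges$leading_id, sep = "|")
}

small_scene_config <- function(seed = 5, n_tomograms = 4, ...) {
  scene_config(n_tomograms = n_tomograms, seed = seed, vesicle_radius = 4000,
               membrane_density = 60, ...)
}
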