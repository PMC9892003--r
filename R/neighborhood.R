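#' Neighbour-search parameters
#'
#' Each ribosome contributes distance vectors to its `n_neighbors` closest
#' neighbours within the same tomogram, excluding neighbours further than
#' `max_distance` (defaults: 4 neighbours within 100 Angstrom).
#'
#' @param n_neighbors Maximum neighbours retained per focal particle.
#' @param max_distance Distance cutoff in Angstrom (ties at exactly the
#'   cutoff are included).
#' @return A `neighbor_params` list.
#' @export
neighbor_params <- function(n_neighbors = 4, max_distance = 100) {
  stopifnot(n_neighbors >= 1, max_distance > 0)
  structure(list(n_neighbors = as.integer(n_neighbors),
                 max_distance = max_distance),
            class = "neighbor_params")
}

#' Histogram geometry
#'
#' Regular cubic grid on which neighbour vectors are binned, centred on the
#' focal particle: `half_extent_voxels` voxels on each side of the central
#' voxel, i.e. `2 * half_extent_voxels + 1` voxels per axis with edges at odd
#' multiples of `voxel_size / 2`, so the focal particle sits at the centre of
#' the central voxel. The default (15 A voxels, half extent 7) spans
#' +/- 112.5 A and covers the 100 A neighbour cutoff.
#'
#' @param voxel_size Voxel edge length in Angstrom.
#' @param half_extent_voxels Number of voxels on each side of the centre.
#' @return A `histogram_geometry` list with derived fields `n_voxels` (per
#'   axis) and `centers` (voxel-centre coordinates along one axis).
#' @export
histogram_geometry <- function(voxel_size = 15, half_extent_voxels = 7) {
  stopifnot(voxel_size > 0, half_extent_voxels >= 1)
  n <- 2L * as.integer(half_extent_voxels) + 1L
  structure(list(voxel_size = voxel_size,
                 half_extent_voxels = as.integer(half_extent_voxels),
                 n_voxels = n,
                 centers = (seq_len(n) - half_extent_voxels - 1) * voxel_size),
            class = "histogram_geometry")
}

geometry_covers <- function(geometry, max_distance) {
  geometry$voxel_size * geometry$half_extent_voxels >= max_distance
}

#' Bin coordinates on the histogram grid
#'
#' Returns 1-based voxel indices along one axis; coordinates outside the grid
#' give NA.
#'
#' @param x Coordinates in Angstrom (focal frame).
#' @param geometry A [histogram_geometry()].
#' @return Integer vector of voxel indices.
#' @keywords internal
bin_axis <- function(x, geometry) {
  i <- floor(x / geometry$voxel_size + 0.5) + geometry$half_extent_voxels + 1L
  i[i < 1L | i > geometry$n_voxels] <- NA_integer_
  as.integer(i)
}

#' Find the nearest neighbours of every particle
#'
#' For each focal ribosome, retains the up-to-`n_neighbors` closest other
#' particles in the same tomogram with centre distance `<= max_distance`, and
#' expresses the focal-to-neighbour vector in the focal particle's reference
#' frame (see [to_particle_frame()]). The search spans all particles in the
#' tomogram regardless of label. Ties for the n-th nearest are broken by
#' ascending `particle_id`.
#'
#' @param table A [particle_table()].
#' @param params A [neighbor_params()].
#' @return A data.frame of class `neighbor_sets` with columns `tomogram_id`,
#'   `focal_id`, `neighbor_id`, `vx`, `vy`, `vz` (focal-frame vector,
#'   Angstrom) and `distance`, sorted by tomogram, focal and ascending
#'   distance.
#' @export
find_neighbors <- function(table, params = neighbor_params()) {
  stopifnot(inherits(table, "particle_table"), nrow(table) > 0)
  out <- vector("list", 0)
  for (sub in split_by_tomogram(table)) {
    n <- nrow(sub)
    if (n < 2) next
    X <- as.matrix(sub[, c("x", "y", "z")])
    D <- as.matrix(stats::dist(X))
    res <- vector("list", n)
    for (i in seq_len(n)) {
      d <- D[i, ]
      cand <- setdiff(which(d <= params$max_distance), i)
      if (!length(cand)) next
      ord <- cand[order(d[cand], sub$particle_id[cand])]
      keep <- ord[seq_len(min(params$n_neighbors, length(ord)))]
      v <- to_particle_frame(sub[i, ], X[keep, , drop = FALSE])
      res[[i]] <- data.frame(
        tomogram_id = sub$tomogram_id[i],
        focal_id = sub$particle_id[i],
        neighbor_id = sub$particle_id[keep],
        vx = v[, 1], vy = v[, 2], vz = v[, 3],
        distance = d[keep],
        stringsAsFactors = FALSE)
    }
    out[[length(out) + 1L]] <- do.call(rbind, res)
  }
  if (!length(out)) {
    ns <- data.frame(tomogram_id = character(0), focal_id = integer(0),
                     neighbor_id = integer(0), vx = numeric(0), vy = numeric(0),
                     vz = numeric(0), distance = numeric(0))
  } else {
    ns <- do.call(rbind, out)
    ns <- ns[order(ns$tomogram_id, ns$focal_id, ns$distance, ns$neighbor_id), ]
    rownames(ns) <- NULL
  }
  structure(ns, params = params, class = c("neighbor_sets", "data.frame"))
}

#' Accumulate a neighbour-probability histogram
#'
#' Bins the focal-frame neighbour vectors on the regular grid and divides the
#' per-voxel counts by the total number of analysed neighbours, giving the
#' probability of finding a neighbouring particle in each voxel. Probabilities
#' sum to 1 whenever at least one neighbour was analysed and the grid covers
#' the cutoff.
#'
#' @param neighbor_sets A [find_neighbors()] result (possibly subset).
#' @param geometry A [histogram_geometry()].
#' @param population_tag Label recording which focal population the histogram
#'   describes.
#' @return A `probability_histogram`: list with `geometry`, integer array
#'   `counts`, `total_neighbors` and real array `probabilities`.
#' @export
accumulate_histogram <- function(neighbor_sets, geometry = histogram_geometry(),
                                 population_tag = "all") {
  nv <- geometry$n_voxels
  counts <- array(0L, dim = c(nv, nv, nv))
  total <- nrow(neighbor_sets)
  if (total > 0) {
    ix <- bin_axis(neighbor_sets$vx, geometry)
    iy <- bin_axis(neighbor_sets$vy, geometry)
    iz <- bin_axis(neighbor_sets$vz, geometry)
    if (anyNA(ix) || anyNA(iy) || anyNA(iz))
      stop("neighbour vector outside histogram grid; enlarge half_extent_voxels")
    lin <- (iz - 1L) * nv * nv + (iy - 1L) * nv + ix
    tab <- tabulate(lin, nbins = nv^3)
    counts[] <- tab
  }
  probs <- if (total > 0) counts / total else array(0, dim = dim(counts))
  structure(list(geometry = geometry, counts = counts,
                 total_neighbors = total, probabilities = probs,
                 population_tag = population_tag,
                 empty = total == 0L),
            class = "probability_histogram")
}

#' Project a probability histogram onto the xy plane
#'
#' Sums the 3D probabilities over z; for membrane-bound ribosomes the xy
#' plane corresponds to the ER membrane, so the projection shows the density
#' of neighbours around the ribosome in the membrane plane. Total mass is
#' conserved.
#'
#' @param hist A `probability_histogram`.
#' @return 2D numeric matrix (x index by y index).
#' @export
project_xy <- function(hist) {
  stopifnot(inherits(hist, "probability_histogram"))
  apply(hist$probabilities, c(1, 2), sum)
}

#' Per-group neighbour histograms
#'
#' Builds one probability histogram per group of focal particles. Grouping
#' applies to the focal particle only: the neighbours entering each histogram
#' are whatever particles are nearby, regardless of their own labels.
#'
#' @param table A [particle_table()].
#' @param neighbor_sets A [find_neighbors()] result for `table`.
#' @param geometry A [histogram_geometry()].
#' @param group_by `"state_label"`, `"population_label"` or `"compartment"`
#'   (membrane / soluble dichotomy via [particle_compartment()]).
#' @return Named list of `probability_histogram` objects; groups with no
#'   focal particles or no retained neighbours are flagged with `empty = TRUE`
#'   and a warning.
#' @export
subgroup_histograms <- function(table, neighbor_sets,
                                geometry = histogram_geometry(),
                                group_by = c("compartment", "state_label",
                                             "population_label")) {
  group_by <- match.arg(group_by)
  g <- if (group_by == "compartment") particle_compartment(table)
       else table[[group_by]]
  key_tab <- paste(table$tomogram_id, table$particle_id, sep = "\r")
  key_ns <- paste(neighbor_sets$tomogram_id, neighbor_sets$focal_id, sep = "\r")
  focal_group <- g[match(key_ns, key_tab)]
  out <- list()
  for (grp in unique(g)) {
    sub <- neighbor_sets[!is.na(focal_group) & focal_group == grp, , drop = FALSE]
    h <- accumulate_histogram(sub, geometry, population_tag = grp)
    if (h$empty)
      warning("group '", grp, "' has no analysed neighbours; empty histogram")
    out[[grp]] <- h
  }
  out
}

#' Export a histogram as a table of non-zero voxels
#'
#' @param hist A `probability_histogram`.
#' @return data.frame with voxel-centre coordinates (Angstrom), count and
#'   probability for every non-zero voxel.
#' @export
histogram_to_df <- function(hist) {
  idx <- which(hist$counts > 0, arr.ind = TRUE)
  ctr <- hist$geometry$centers
  data.frame(x = ctr[idx[, 1]], y = ctr[idx[, 2]], z = ctr[idx[, 3]],
             count = hist$counts[idx], probability = hist$probabilities[idx])
}

#' Write a 3D grid as an MRC volume
#'
#' Minimal MRC2014 writer (mode 2, 32-bit float, little endian) recording the
#' voxel size in the cell dimensions, for inspection of histograms and masks
#' in standard cryo-EM viewers.
#'
#' @param grid 3D numeric array.
#' @param voxel_size Voxel edge length in Angstrom.
#' @param path Output path.
#' @export
write_mrc <- function(grid, voxel_size, path) {
  stopifnot(length(dim(grid)) == 3)
  d <- dim(grid)
  con <- file(path, open = "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d)                                   # nx ny nz
  wi(2)                                   # mode 2: float32
  wi(c(0, 0, 0))                          # nxstart
  wi(d)                                   # mx my mz
  wf(d * voxel_size)                      # cell dimensions (A)
  wf(c(90, 90, 90))                       # cell angles
  wi(c(1, 2, 3))                          # axis order
  wf(c(min(grid), max(grid), mean(grid))) # dmin dmax dmean
  wi(c(0, 0))                             # ispg, nsymbt
  wi(rep(0, 25))                          # extra
  wf(c(0, 0, 0))                          # origin
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(stats::sd(as.numeric(grid)))         # rms
  wi(0)                                   # nlabl
  writeBin(raw(800), con)                 # labels
  wf(as.numeric(grid))
  invisible(path)
}
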