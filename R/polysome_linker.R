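#' Mask-building parameters
#'
#' Probability thresholds used to binarize the neighbour histograms before
#' extracting trailing/leading clusters: 0.0005 for the membrane-bound
#' population and 0.0003 for soluble ribosomes, both masks dilated by two
#' voxels.
#'
#' @param threshold_membrane Probability threshold for the membrane histogram.
#' @param threshold_soluble Probability threshold for the soluble histogram.
#' @param dilation_voxels Radius (in voxels) of the ball structuring element.
#' @return A `mask_params` list.
#' @export
mask_params <- function(threshold_membrane = 5e-4, threshold_soluble = 3e-4,
                        dilation_voxels = 2) {
  stopifnot(threshold_membrane > 0, threshold_membrane < 1,
            threshold_soluble > 0, threshold_soluble < 1,
            dilation_voxels >= 0)
  structure(list(threshold_membrane = threshold_membrane,
                 threshold_soluble = threshold_soluble,
                 dilation_voxels = as.integer(dilation_voxels)),
            class = "mask_params")
}

## ---- 3D morphology on small grids ----

#' Label connected components (26-connectivity) in a 3D logical array
#'
#' @param bw Logical 3D array.
#' @return Integer array of the same shape; 0 = background, components
#'   numbered from 1.
#' @keywords internal
label_components <- function(bw) {
  d <- dim(bw)
  labels <- array(0L, dim = d)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  todo <- which(bw, arr.ind = TRUE)
  lab <- 0L
  for (r in seq_len(nrow(todo))) {
    p <- todo[r, ]
    if (labels[p[1], p[2], p[3]] != 0L) next
    lab <- lab + 1L
    queue <- matrix(p, nrow = 1)
    labels[p[1], p[2], p[3]] <- lab
    while (nrow(queue) > 0) {
      q <- queue[1, ]
      queue <- queue[-1, , drop = FALSE]
      nb <- sweep(offs, 2, q, "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
            nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      for (k in seq_len(nrow(nb))) {
        i <- nb[k, 1]; j <- nb[k, 2]; l <- nb[k, 3]
        if (bw[i, j, l] && labels[i, j, l] == 0L) {
          labels[i, j, l] <- lab
          queue <- rbind(queue, nb[k, , drop = FALSE])
        }
      }
    }
  }
  labels
}

#' Dilate a 3D logical array with a discrete ball
#'
#' @param bw Logical 3D array.
#' @param radius Ball radius in voxels (offsets with squared norm
#'   `<= radius^2`).
#' @return Dilated logical array (same shape).
#' @keywords internal
dilate_mask <- function(bw, radius) {
  if (radius <= 0) return(bw)
  d <- dim(bw)
  r <- as.integer(radius)
  offs <- as.matrix(expand.grid(dx = -r:r, dy = -r:r, dz = -r:r))
  offs <- offs[rowSums(offs^2) <= radius^2, , drop = FALSE]
  out <- array(FALSE, dim = d)
  src <- which(bw, arr.ind = TRUE)
  if (nrow(src) == 0) return(out)
  for (k in seq_len(nrow(offs))) {
    nb <- sweep(src, 2, offs[k, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
          nb[, 3] >= 1 & nb[, 3] <= d[3]
    out[nb[ok, , drop = FALSE]] <- TRUE
  }
  out
}

new_direction_mask <- function(geometry, voxels, direction, provenance) {
  structure(list(geometry = geometry, voxels = voxels,
                 direction = direction, provenance = provenance),
            class = "direction_mask")
}

mask_one_population <- function(hist, threshold, reference_directions,
                                dilation, tag) {
  geom <- hist$geometry
  nv <- geom$n_voxels
  bw <- hist$probabilities > threshold
  per_dir <- lapply(reference_directions, function(v) array(FALSE, dim = dim(bw)))
  if (!any(bw)) return(per_dir)
  labels <- label_components(bw)
  refs <- lapply(reference_directions, function(v) v / sqrt(sum(v^2)))
  ctr <- geom$centers
  for (lab in seq_len(max(labels))) {
    idx <- which(labels == lab, arr.ind = TRUE)
    w <- hist$probabilities[idx]
    cen <- c(sum(ctr[idx[, 1]] * w), sum(ctr[idx[, 2]] * w),
             sum(ctr[idx[, 3]] * w)) / sum(w)
    if (sum(cen^2) == 0)
      stop("component ", lab, " of ", tag, " histogram is centred on the ",
           "focal particle; cannot assign a direction")
    cen <- cen / sqrt(sum(cen^2))
    ang <- vapply(refs, function(r)
      acos(max(-1, min(1, sum(cen * r)))) * 180 / pi, numeric(1))
    ord <- order(ang)
    if (length(ang) > 1 && abs(ang[ord[1]] - ang[ord[2]]) < 5)
      stop("ambiguous direction for component ", lab, " of ", tag,
           " histogram: angles ", paste(sprintf("%.1f", ang), collapse = "/"),
           " deg to the reference directions differ by < 5 deg")
    dir <- names(refs)[ord[1]]
    per_dir[[dir]] <- per_dir[[dir]] | (labels == lab)
  }
  lapply(per_dir, dilate_mask, radius = dilation)
}

#' Build trailing and leading direction masks
#'
#' Thresholds the membrane and soluble neighbour histograms (different
#' probability thresholds), extracts 26-connected supra-threshold clusters,
#' assigns each cluster to the direction (trailing or leading) whose
#' reference unit vector is closest in angle to the cluster's
#' probability-weighted centroid, dilates each directional mask with a
#' discrete ball, and finally unions the membrane and soluble masks per
#' direction into dataset-wide trailing and leading masks.
#'
#' @param hist_membrane,hist_soluble `probability_histogram` objects sharing
#'   a geometry.
#' @param params A [mask_params()].
#' @param reference_directions Named list with unit 3-vectors `trailing` and
#'   `leading` (particle-frame directions of the expected neighbour hotspots;
#'   supplied from configuration or, for synthetic scenes, from the planted
#'   offsets).
#' @return List with `direction_mask` elements `trailing` and `leading`.
#' @export
build_direction_masks <- function(hist_membrane, hist_soluble,
                                  params = mask_params(),
                                  reference_directions) {
  stopifnot(inherits(hist_membrane, "probability_histogram"),
            inherits(hist_soluble, "probability_histogram"))
  if (!identical(hist_membrane$geometry$n_voxels, hist_soluble$geometry$n_voxels) ||
      hist_membrane$geometry$voxel_size != hist_soluble$geometry$voxel_size)
    stop("membrane and soluble histograms must share a geometry")
  if (!all(c("trailing", "leading") %in% names(reference_directions)))
    stop("reference_directions must name 'trailing' and 'leading' unit vectors")
  refs <- reference_directions[c("trailing", "leading")]
  mem <- mask_one_population(hist_membrane, params$threshold_membrane, refs,
                             params$dilation_voxels, "membrane")
  sol <- mask_one_population(hist_soluble, params$threshold_soluble, refs,
                             params$dilation_voxels, "soluble")
  if (!any(mem$trailing | mem$leading | sol$trailing | sol$leading))
    warning("no voxel above threshold in either histogram; masks are empty")
  geom <- hist_membrane$geometry
  prov <- sprintf("thresholds %g (membrane) / %g (soluble), dilation %d voxels",
                  params$threshold_membrane, params$threshold_soluble,
                  params$dilation_voxels)
  list(trailing = new_direction_mask(geom, mem$trailing | sol$trailing,
                                     "trailing", prov),
       leading = new_direction_mask(geom, mem$leading | sol$leading,
                                    "leading", prov))
}

#' Test whether focal-frame vectors fall inside a direction mask
#'
#' Vectors are binned with the histogram registration (no interpolation) and
#' looked up in the mask; vectors outside the grid are not in the mask.
#'
#' @param mask A `direction_mask`.
#' @param v Matrix of vectors (one per row, Angstrom) or a single 3-vector.
#' @return Logical vector.
#' @export
vector_in_mask <- function(mask, v) {
  if (!is.matrix(v)) v <- matrix(v, nrow = 1)
  ix <- bin_axis(v[, 1], mask$geometry)
  iy <- bin_axis(v[, 2], mask$geometry)
  iz <- bin_axis(v[, 3], mask$geometry)
  out <- logical(nrow(v))
  ok <- !(is.na(ix) | is.na(iy) | is.na(iz))
  out[ok] <- mask$voxels[cbind(ix[ok], iy[ok], iz[ok])]
  out
}

#' Confirm reciprocal polysome links
#'
#' A neighbour j is a confirmed trailing neighbour of focal i iff the vector
#' from i to j (in i's frame) falls in the trailing mask AND the vector from
#' j to i (in j's frame) falls in the leading mask — the inverse calculation.
#' Each confirmed pair yields a directed edge trailing -> leading
#' (j -> i). If several neighbours of a particle pass the same directional
#' test, the nearest by Euclidean distance is kept (ties by particle id), so
#' that each particle ends up with at most one upstream and one downstream
#' partner. The result is independent of the iteration order over focal
#' particles.
#'
#' The reciprocal vector is taken from the neighbour sets themselves: if i is
#' not among j's retained neighbours the pair cannot be confirmed.
#'
#' @param neighbor_sets A [find_neighbors()] result.
#' @param trailing_mask,leading_mask `direction_mask` objects sharing the
#'   geometry used for the histograms.
#' @return A `polysome_links` object: list with `edges` (data.frame
#'   `tomogram_id`, `trailing_id`, `leading_id`, `distance`), `members`
#'   (data.frame of particles participating in at least one edge) and
#'   `chains` (NULL until [assemble_chains()] is run).
#' @export
confirm_links <- function(neighbor_sets, trailing_mask, leading_mask) {
  ns <- as.data.frame(neighbor_sets)
  empty <- data.frame(tomogram_id = character(0), trailing_id = integer(0),
                      leading_id = integer(0), distance = numeric(0))
  if (nrow(ns) == 0)
    return(structure(list(edges = empty, members = empty[0, 1:2],
                          chains = NULL), class = "polysome_links"))
  V <- as.matrix(ns[, c("vx", "vy", "vz")])
  in_trail <- vector_in_mask(trailing_mask, V)
  in_lead <- vector_in_mask(leading_mask, V)
  key <- paste(ns$tomogram_id, ns$focal_id, ns$neighbor_id, sep = "\r")
  rev_key <- paste(ns$tomogram_id, ns$neighbor_id, ns$focal_id, sep = "\r")
  rev_row <- match(rev_key, key)
  # row (i, j): j trailing neighbour of i needs v(i->j) in trailing
  # and v(j->i) in leading
  ok <- in_trail & !is.na(rev_row) & in_lead[rev_row]
  cand <- data.frame(tomogram_id = ns$tomogram_id[ok],
                     trailing_id = ns$neighbor_id[ok],
                     leading_id = ns$focal_id[ok],
                     distance = ns$distance[ok],
                     stringsAsFactors = FALSE)
  cand <- cand[order(cand$distance, cand$tomogram_id, cand$trailing_id,
                     cand$leading_id), , drop = FALSE]
  src_used <- character(0)
  tgt_used <- character(0)
  keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    s <- paste(cand$tomogram_id[r], cand$trailing_id[r], sep = "\r")
    t <- paste(cand$tomogram_id[r], cand$leading_id[r], sep = "\r")
    if (!(s %in% src_used) && !(t %in% tgt_used)) {
      keep[r] <- TRUE
      src_used <- c(src_used, s)
      tgt_used <- c(tgt_used, t)
    }
  }
  edges <- cand[keep, , drop = FALSE]
  rownames(edges) <- NULL
  members <- unique(rbind(
    data.frame(tomogram_id = edges$tomogram_id, particle_id = edges$trailing_id,
               stringsAsFactors = FALSE),
    data.frame(tomogram_id = edges$tomogram_id, particle_id = edges$leading_id,
               stringsAsFactors = FALSE)))
  members <- members[order(members$tomogram_id, members$particle_id), , drop = FALSE]
  rownames(members) <- NULL
  structure(list(edges = edges, members = members, chains = NULL),
            class = "polysome_links")
}

#' Assemble polysome chains from confirmed links
#'
#' Chains are the maximal directed trailing -> leading paths of the edge set.
#' Cycles (possible on closed vesicle geodesics) are broken at their
#' largest-distance edge with a warning.
#'
#' @param links A `polysome_links` object from [confirm_links()].
#' @return The same object with `chains` populated: a list of data.frames,
#'   each with the ordered `tomogram_id`, `particle_id` of one chain
#'   (trailing end first).
#' @export
assemble_chains <- function(links) {
  stopifnot(inherits(links, "polysome_links"))
  e <- links$edges
  if (nrow(e) == 0) {
    links$chains <- list()
    return(links)
  }
  skey <- paste(e$tomogram_id, e$trailing_id, sep = "\r")
  tkey <- paste(e$tomogram_id, e$leading_id, sep = "\r")
  if (anyDuplicated(skey) || anyDuplicated(tkey))
    stop("internal error: edge multiplicity invariant violated")
  drop <- logical(nrow(e))
  # break cycles: repeatedly drop the longest edge of any remaining cycle
  repeat {
    act <- which(!drop)
    starts <- act[!(skey[act] %in% tkey[act])]
    reach <- logical(nrow(e))
    for (r in starts) {
      cur <- r
      while (!is.na(cur)) {
        reach[cur] <- TRUE
        cur <- act[match(tkey[cur], skey[act])]
      }
    }
    cyc <- act[!reach[act]]
    if (!length(cyc)) break
    worst <- cyc[which.max(e$distance[cyc])]
    drop[worst] <- TRUE
    warning("cycle detected; broken at edge ", e$trailing_id[worst], " -> ",
            e$leading_id[worst], " (distance ",
            sprintf("%.1f", e$distance[worst]), " A) in tomogram ",
            e$tomogram_id[worst])
  }
  act <- which(!drop)
  starts <- act[!(skey[act] %in% tkey[act])]
  chains <- list()
  for (r in starts) {
    ids <- c(e$trailing_id[r], e$leading_id[r])
    tom <- e$tomogram_id[r]
    cur <- act[match(tkey[r], skey[act])]
    while (!is.na(cur)) {
      ids <- c(ids, e$leading_id[cur])
      cur <- act[match(tkey[cur], skey[act])]
    }
    chains[[length(chains) + 1L]] <-
      data.frame(tomogram_id = tom, particle_id = ids, stringsAsFactors = FALSE)
  }
  links$chains <- chains
  links
}

#' Per-tomogram event frequencies
#'
#' For each tomogram and group, the fraction of its particles that are
#' associated in polysomes (participate in at least one confirmed link in
#' either direction). For example, a tomogram with 7 ribosomes of one state
#' of which 6 are polysome members has frequency 6/7 = 0.86.
#'
#' @param table A [particle_table()].
#' @param links A `polysome_links` object.
#' @param group_by Grouping column: `"state_label"`, `"population_label"` or
#'   `"compartment"`.
#' @return data.frame with `tomogram_id`, `group`, `n_total`,
#'   `n_in_polysome`, `frequency`; groups absent from a tomogram are omitted.
#' @export
per_tomogram_frequencies <- function(table, links, group_by = "state_label") {
  g <- if (group_by == "compartment") particle_compartment(table)
       else table[[group_by]]
  mkey <- paste(links$members$tomogram_id, links$members$particle_id, sep = "\r")
  member <- paste(table$tomogram_id, table$particle_id, sep = "\r") %in% mkey
  agg <- stats::aggregate(
    cbind(n_total = rep(1L, nrow(table)), n_in_polysome = as.integer(member)),
    by = list(tomogram_id = table$tomogram_id, group = g), FUN = sum)
  agg$frequency <- agg$n_in_polysome / agg$n_total
  agg <- agg[order(agg$tomogram_id, agg$group), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}
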