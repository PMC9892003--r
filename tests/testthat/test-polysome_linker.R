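# histogram with the given counts planted at focal-frame points
planted_hist <- function(points, counts, geometry = histogram_geometry(),
                         total = sum(counts)) {
  ns <- data.frame(tomogram_id = "t", focal_id = 1L, neighbor_id = 2L,
                   vx = rep(points[, 1], counts),
                   vy = rep(points[, 2], counts),
                   vz = rep(points[, 3], counts), distance = 1)
  accumulate_histogram(ns, geometry)
}

refs_y <- list(trailing = c(0, 1, 0), leading = c(0, -1, 0))

test_that("sub-threshold histograms give empty masks with a warning", {
  pts <- matrix(c(0, 60, 0), 1)
  h <- planted_hist(pts, 1)
  h$probabilities[] <- h$probabilities * 1e-4   # push below both thresholds
  expect_warning(m <- build_direction_masks(h, h, mask_params(), refs_y),
                 "empty")
  expect_false(any(m$trailing$voxels))
  expect_false(any(m$leading$voxels))
})

test_that("clusters are split by direction and dilation is monotone", {
  pts <- rbind(c(0, 60, 0), c(0, -60, 0))
  h <- planted_hist(pts, c(600, 400))
  sol <- planted_hist(pts, c(1, 1)); sol$probabilities[] <- 0; sol$counts[] <- 0L
  m0 <- build_direction_masks(h, sol, mask_params(dilation_voxels = 0), refs_y)
  m2 <- build_direction_masks(h, sol, mask_params(dilation_voxels = 2), refs_y)
  geom <- h$geometry
  expect_true(vector_in_mask(m0$trailing, c(0, 60, 0)))
  expect_false(vector_in_mask(m0$trailing, c(0, -60, 0)))
  expect_true(vector_in_mask(m0$leading, c(0, -60, 0)))
  # dilation grows masks by set inclusion
  expect_true(all(m2$trailing$voxels[m0$trailing$voxels]))
  expect_true(all(m2$leading$voxels[m0$leading$voxels]))
  expect_gt(sum(m2$trailing$voxels), sum(m0$trailing$voxels))
  # two-voxel dilation reaches 30 A from the cluster
  expect_true(vector_in_mask(m2$trailing, c(0, 90, 0)))
  expect_false(vector_in_mask(m0$trailing, c(0, 90, 0)))
})

test_that("membrane and soluble masks are combined per direction", {
  mem <- planted_hist(rbind(c(0, 60, 0)), 1000)
  sol <- planted_hist(rbind(c(0, -60, 0)), 1000)
  m <- build_direction_masks(mem, sol, mask_params(dilation_voxels = 0),
                             refs_y)
  expect_true(vector_in_mask(m$trailing, c(0, 60, 0)))    # from membrane
  expect_true(vector_in_mask(m$leading, c(0, -60, 0)))    # from soluble
})

test_that("a direction-ambiguous cluster raises an error naming it", {
  h <- planted_hist(rbind(c(60, 0, 0)), 1000)   # orthogonal to both refs
  sol <- planted_hist(rbind(c(0, -60, 0)), 1)
  sol$probabilities[] <- 0
  expect_error(build_direction_masks(h, sol, mask_params(), refs_y),
               "ambiguous direction for component 1")
})

test_that("links require the reciprocal mask condition", {
  tmask <- planted_mask(c(60, 0, 0), "trailing", dilation = 1)
  lmask <- planted_mask(c(-60, 0, 0), "leading", dilation = 1)
  both <- data.frame(
    tomogram_id = "t", focal_id = c(1L, 2L), neighbor_id = c(2L, 1L),
    vx = c(60, -60), vy = 0, vz = 0, distance = 60)
  lk <- confirm_links(both, tmask, lmask)
  expect_identical(nrow(lk$edges), 1L)
  expect_identical(lk$edges$trailing_id, 2L)   # neighbour seen trailing
  expect_identical(lk$edges$leading_id, 1L)
  expect_identical(nrow(lk$members), 2L)

  # forward condition only: neighbour's reciprocal vector misses the mask
  fwd <- both; fwd$vx[2] <- 30
  expect_identical(nrow(confirm_links(fwd, tmask, lmask)$edges), 0L)

  # missing reciprocal row: no edge
  expect_identical(nrow(confirm_links(both[1, ], tmask, lmask)$edges), 0L)
})

test_that("a planted 5-ribosome chain with sub-voxel jitter is fully recovered", {
  set.seed(55)
  xs <- 60 * (0:4) + runif(5, -6, 6)
  rows <- lapply(seq_along(xs), function(i)
    list(x = xs[i], y = runif(1, -6, 6), z = runif(1, -6, 6)))
  tab <- do.call(ptab, rows)
  ns <- find_neighbors(tab)
  tmask <- planted_mask(c(-60, 0, 0), "trailing", dilation = 2)
  lmask <- planted_mask(c(60, 0, 0), "leading", dilation = 2)
  lk <- confirm_links(ns, tmask, lmask)
  expect_identical(nrow(lk$edges), 4L)
  expect_setequal(edge_keys(lk$edges),
                  paste("t1", 1:4, 2:5, sep = "|"))
  lk <- assemble_chains(lk)
  expect_identical(length(lk$chains), 1L)
  expect_identical(lk$chains[[1]]$particle_id, 1:5)
})

test_that("confirm_links is invariant to iteration order and independently re-checkable", {
  cfg <- small_scene_config(seed = 57, n_tomograms = 3)
  sc <- generate_scene(cfg)
  ns <- find_neighbors(sc$table)
  tmask <- planted_mask(matrix(cfg$trailing_offset, 1), "trailing",
                        dilation = 2)
  lmask <- planted_mask(matrix(cfg$leading_offset, 1), "leading",
                        dilation = 2)
  lk <- confirm_links(ns, tmask, lmask)
  rev_ns <- ns[rev(seq_len(nrow(ns))), ]
  lk_rev <- confirm_links(rev_ns, tmask, lmask)
  expect_setequal(edge_keys(lk$edges), edge_keys(lk_rev$edges))
  expect_gt(nrow(lk$edges), 0L)
  # every emitted edge satisfies both mask conditions when re-checked
  key <- paste(ns$tomogram_id, ns$focal_id, ns$neighbor_id)
  for (r in seq_len(nrow(lk$edges))) {
    fwd <- ns[match(paste(lk$edges$tomogram_id[r], lk$edges$leading_id[r],
                          lk$edges$trailing_id[r]), key), ]
    bwd <- ns[match(paste(lk$edges$tomogram_id[r], lk$edges$trailing_id[r],
                          lk$edges$leading_id[r]), key), ]
    expect_true(vector_in_mask(tmask, c(fwd$vx, fwd$vy, fwd$vz)))
    expect_true(vector_in_mask(lmask, c(bwd$vx, bwd$vy, bwd$vz)))
  }
  # multiplicity invariant: at most one upstream and one downstream partner
  expect_false(anyDuplicated(paste(lk$edges$tomogram_id,
                                   lk$edges$trailing_id)) > 0)
  expect_false(anyDuplicated(paste(lk$edges$tomogram_id,
                                   lk$edges$leading_id)) > 0)
})

test_that("chain assembly walks paths and breaks cycles at the longest edge", {
  links <- structure(list(
    edges = data.frame(tomogram_id = "t",
                       trailing_id = c(1L, 2L), leading_id = c(2L, 3L),
                       distance = c(60, 60)),
    members = data.frame(tomogram_id = "t", particle_id = 1:3),
    chains = NULL), class = "polysome_links")
  out <- assemble_chains(links)
  expect_identical(length(out$chains), 1L)
  expect_identical(out$chains[[1]]$particle_id, 1:3)

  empty <- structure(list(edges = links$edges[0, ],
                          members = links$members[0, ], chains = NULL),
                     class = "polysome_links")
  expect_identical(length(assemble_chains(empty)$chains), 0L)

  cyc <- links
  cyc$edges <- rbind(links$edges,
                     data.frame(tomogram_id = "t", trailing_id = 3L,
                                leading_id = 1L, distance = 72))
  expect_warning(out2 <- assemble_chains(cyc), "cycle")
  expect_identical(length(out2$chains), 1L)
  expect_identical(out2$chains[[1]]$particle_id, 1:3)  # longest edge dropped
})

test_that("per-tomogram frequencies match the worked 6-of-7 example", {
  rows <- c(lapply(1:7 * 200, function(x) list(x = x, state_label = "pre+")),
            lapply(1:5 * 200, function(x)
              list(x = x, y = 1000, state_label = "NR-H",
                   tomogram_id = "t2")))
  tab <- do.call(ptab, rows)
  links <- structure(list(
    edges = data.frame(tomogram_id = "t1", trailing_id = 1:3,
                       leading_id = 4:6, distance = 60),
    members = data.frame(tomogram_id = "t1", particle_id = 1:6),
    chains = NULL), class = "polysome_links")
  fr <- per_tomogram_frequencies(tab, links, "state_label")
  f1 <- fr$frequency[fr$tomogram_id == "t1" & fr$group == "pre+"]
  expect_equal(round(f1, 2), 0.86)          # 6 of 7 in polysomes
  expect_equal(fr$frequency[fr$tomogram_id == "t2" & fr$group == "NR-H"], 0)
  all_in <- links
  all_in$members <- data.frame(tomogram_id = "t1", particle_id = 1:7)
  fr2 <- per_tomogram_frequencies(tab, all_in, "state_label")
  expect_equal(fr2$frequency[fr2$tomogram_id == "t1"], 1)
})
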