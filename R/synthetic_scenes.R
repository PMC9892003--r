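#' Default synthetic state catalog
#'
#' Ribosome states planted by the scene generator, with their base abundance
#' and the typical-tomogram probability of being associated in a polysome.
#' The catalog echoes the qualitative structure of ER-bound ribosome fields:
#' elongating states (the dominant classical pre+ intermediate, decoding,
#' post) are polysome-enriched while the two hibernating classes (NR-H, R-H)
#' are strongly depleted. The numbers are synthetic stand-ins, not measured
#' values.
#'
#' @return data.frame with `state_label`, `base_probability`,
#'   `in_polysome_probability`.
#' @export
default_state_catalog <- function() {
  data.frame(
    state_label = c("pre+", "decoding", "post", "NR-H", "R-H"),
    base_probability = c(0.33, 0.15, 0.17, 0.20, 0.15),
    in_polysome_probability = c(0.70, 0.70, 0.65, 0.10, 0.10),
    stringsAsFactors = FALSE)
}

#' Default synthetic translocon-population mix for membrane particles
#' @return Named numeric vector of fractions.
#' @export
default_population_catalog <- function() {
  c("SEC61-TRAP-OSTA" = 0.69, "SEC61-TRAP" = 0.16,
    "multipass" = 0.10, "multipass-TRAP" = 0.05)
}

#' Synthetic-scene configuration
#'
#' Parameters of the vesicle scenes the generator emulates: per tomogram one
#' spherical ER-derived vesicle carrying membrane-bound ribosomes (particle
#' z axis along the outward normal, so the particle xy plane is the membrane
#' plane), a subset of which are strung into polysome chains that step along
#' the membrane by the planted trailing/leading offset vectors; hibernating
#' and other monosomes sit on the membrane without links; a residual soluble
#' pool occupies the vesicle interior with random orientations. Per-tomogram
#' polysome propensity varies through a logit-scale Gaussian random effect.
#'
#' Offsets are expressed in the particle frame (Angstrom); both must have
#' equal magnitude below the 100 A neighbour cutoff. `min_separation` is a
#' hard-core exclusion distance approximating ribosome excluded volume.
#'
#' @param n_tomograms Number of tomograms (vesicles).
#' @param seed Integer seed; expanded into per-tomogram substreams.
#' @param vesicle_radius Sphere radius, Angstrom.
#' @param membrane_density Membrane-bound ribosomes per square micrometre of
#'   membrane.
#' @param soluble_fraction Fraction of all particles that are soluble.
#' @param state_catalog See [default_state_catalog()].
#' @param population_catalog Membrane population mix.
#' @param trailing_offset,leading_offset Planted particle-frame offsets of
#'   the upstream/downstream neighbour (Angstrom).
#' @param chain_continuation Geometric continuation probability of chain
#'   growth beyond the minimum length of 2.
#' @param max_chain_length Chain length cap.
#' @param positional_jitter_sd,angular_jitter_sd Gaussian jitter applied last
#'   (Angstrom / degrees).
#' @param tomogram_effect_sd Logit-scale SD of the per-tomogram random
#'   effect on polysome propensity.
#' @param min_separation Hard-core distance between any two particles,
#'   Angstrom.
#' @param soluble_min_separation Hard-core distance among soluble particles
#'   (kept above the neighbour cutoff so the residual soluble pool is
#'   monosomal).
#' @return A `scene_config` list.
#' @export
scene_config <- function(n_tomograms = 20, seed = 1,
                         vesicle_radius = 10000, membrane_density = 120,
                         soluble_fraction = 0.15,
                         state_catalog = default_state_catalog(),
                         population_catalog = default_population_catalog(),
                         trailing_offset = c(75, 30, 0),
                         leading_offset = 80.777 * c(cos(210 * pi / 180),
                                                     sin(210 * pi / 180), 0),
                         chain_continuation = 0.55,
                         max_chain_length = 12,
                         positional_jitter_sd = 5, angular_jitter_sd = 3,
                         tomogram_effect_sd = 0.5,
                         min_separation = 70, soluble_min_separation = 110) {
  stopifnot(n_tomograms >= 1, vesicle_radius > 0, membrane_density > 0,
            soluble_fraction >= 0, soluble_fraction < 1,
            chain_continuation >= 0, chain_continuation < 1)
  if (abs(sum(state_catalog$base_probability) - 1) > 1e-8)
    stop("state base probabilities must sum to 1")
  mt <- sqrt(sum(trailing_offset^2)); ml <- sqrt(sum(leading_offset^2))
  if (mt > 100 || ml > 100)
    stop("planted offsets must lie inside the 100 A neighbour cutoff")
  if (abs(mt - ml) > 1)
    stop("trailing and leading offsets must have equal magnitude")
  if (min_separation >= min(mt, ml))
    stop("min_separation must be below the offset magnitude")
  structure(list(n_tomograms = as.integer(n_tomograms), seed = as.integer(seed),
                 vesicle_radius = vesicle_radius,
                 membrane_density = membrane_density,
                 soluble_fraction = soluble_fraction,
                 state_catalog = state_catalog,
                 population_catalog = population_catalog,
                 trailing_offset = trailing_offset,
                 leading_offset = leading_offset,
                 chain_continuation = chain_continuation,
                 max_chain_length = as.integer(max_chain_length),
                 positional_jitter_sd = positional_jitter_sd,
                 angular_jitter_sd = angular_jitter_sd,
                 tomogram_effect_sd = tomogram_effect_sd,
                 min_separation = min_separation,
                 soluble_min_separation = soluble_min_separation),
            class = "scene_config")
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

unit3 <- function(v) v / sqrt(sum(v^2))

# orthonormal tangent basis at unit normal n
tangent_basis <- function(n) {
  e <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  a <- unit3(cross3(n, e))
  b <- cross3(n, a)
  list(a = a, b = b)
}

# frame matrix (rows x, y, z) for normal n and in-plane x-axis angle phi
membrane_frame <- function(n, phi) {
  tb <- tangent_basis(n)
  xhat <- cos(phi) * tb$a + sin(phi) * tb$b
  yhat <- cross3(n, xhat)
  rbind(xhat, yhat, n, deparse.level = 0)
}

# rotation by `deg` degrees about arbitrary unit axis (Rodrigues)
axis_angle <- function(axis, deg) {
  th <- deg * pi / 180
  K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

min_dist_ok <- function(placed, k, p, min_sep) {
  if (k == 0) return(TRUE)
  d2 <- (placed[seq_len(k), 1] - p[1])^2 + (placed[seq_len(k), 2] - p[2])^2 +
    (placed[seq_len(k), 3] - p[3])^2
  all(d2 >= min_sep^2)
}

random_sphere_point <- function() {
  z <- stats::runif(1, -1, 1)
  phi <- stats::runif(1, 0, 2 * pi)
  r <- sqrt(1 - z^2)
  c(r * cos(phi), r * sin(phi), z)
}

generate_tomogram <- function(cfg, tom_id, u_t) {
  R <- cfg$vesicle_radius
  center <- rep(2 * R, 3)
  area_um2 <- 4 * pi * (R / 1e4)^2
  n_mem <- max(2L, round(cfg$membrane_density * area_um2))
  cat_tab <- cfg$state_catalog
  states <- sample(cat_tab$state_label, n_mem, replace = TRUE,
                   prob = cat_tab$base_probability)
  p_in <- stats::plogis(
    stats::qlogis(cat_tab$in_polysome_probability[
      match(states, cat_tab$state_label)]) + u_t)
  member <- stats::runif(n_mem) < p_in
  # string members into chains of geometric length >= 2
  midx <- which(member)
  midx <- midx[sample.int(length(midx))]
  chains <- list()
  while (length(midx) >= 2) {
    L <- min(2 + stats::rgeom(1, 1 - cfg$chain_continuation),
             cfg$max_chain_length, length(midx))
    if (length(midx) - L == 1) L <- L + 1   # avoid orphan member
    chains[[length(chains) + 1L]] <- midx[seq_len(L)]
    midx <- midx[-seq_len(L)]
  }
  if (length(midx) == 1) member[midx] <- FALSE
  pos <- matrix(NA_real_, n_mem, 3)
  frames <- vector("list", n_mem)
  normals <- matrix(NA_real_, n_mem, 3)
  placed_order <- integer(0)
  k <- 0L
  fails <- 0L
  place <- function(idx, p, M, n) {
    k <<- k + 1L
    pos[idx, ] <<- p
    frames[[idx]] <<- M
    normals[idx, ] <<- n
    placed_order <<- c(placed_order, idx)
  }
  tau <- atan2(cfg$trailing_offset[2], cfg$trailing_offset[1])
  edges <- list()
  dropped <- integer(0)
  for (ch in chains) {
    # seed the chain on the sphere
    ok <- FALSE
    for (try in 1:200) {
      n0 <- random_sphere_point()
      p0 <- center + R * n0
      if (min_dist_ok(pos[placed_order, , drop = FALSE], k, p0,
                      cfg$min_separation)) { ok <- TRUE; break }
      fails <- fails + 1L
      if (fails > 1e4) stop("placement rejection failed 10^4 times; ",
                            "lower membrane_density or min_separation")
    }
    if (!ok) { dropped <- c(dropped, ch); next }
    M <- membrane_frame(n0, stats::runif(1, 0, 2 * pi))
    place(ch[1], p0, M, n0)
    prev <- ch[1]
    placed_in_chain <- 1L
    for (m in ch[-1]) {
      p_prev <- pos[prev, ]
      raw <- p_prev + as.numeric(t(frames[[prev]]) %*% cfg$leading_offset)
      nn <- unit3(raw - center)
      p_new <- center + R * nn
      if (!min_dist_ok(pos[placed_order, , drop = FALSE], k, p_new,
                       cfg$min_separation)) { dropped <- c(dropped, m); next }
      # azimuth so that the previous member sits at the trailing offset
      d <- p_prev - p_new
      tb <- tangent_basis(nn)
      dt <- d - sum(d * nn) * nn
      alpha <- atan2(sum(dt * tb$b), sum(dt * tb$a))
      Mn <- membrane_frame(nn, alpha - tau)
      place(m, p_new, Mn, nn)
      edges[[length(edges) + 1L]] <- c(prev, m)
      prev <- m
      placed_in_chain <- placed_in_chain + 1L
    }
    if (placed_in_chain < 2) { member[ch[1]] <- FALSE }
  }
  # chain members that could not be placed become membrane monosomes
  member[dropped] <- FALSE
  monos <- setdiff(seq_len(n_mem), placed_order)
  for (i in monos) {
    ok <- FALSE
    for (try in 1:200) {
      n0 <- random_sphere_point()
      p0 <- center + R * n0
      if (min_dist_ok(pos[placed_order, , drop = FALSE], k, p0,
                      cfg$min_separation)) { ok <- TRUE; break }
      fails <- fails + 1L
      if (fails > 1e4) stop("placement rejection failed 10^4 times; ",
                            "lower membrane_density or min_separation")
    }
    if (!ok) stop("placement rejection failed; lower membrane_density")
    place(i, p0, membrane_frame(n0, stats::runif(1, 0, 2 * pi)), n0)
  }
  populations <- sample(names(cfg$population_catalog), n_mem, replace = TRUE,
                        prob = cfg$population_catalog)
  # soluble pool in the vesicle interior
  n_sol <- round(cfg$soluble_fraction / (1 - cfg$soluble_fraction) * n_mem)
  sol_pos <- matrix(NA_real_, n_sol, 3)
  sol_eul <- matrix(NA_real_, n_sol, 3)
  ks <- 0L
  rmax <- max(R - 150, R / 2)
  while (ks < n_sol) {
    p0 <- center + rmax * stats::runif(1)^(1 / 3) * random_sphere_point()
    if (!min_dist_ok(sol_pos, ks, p0, cfg$soluble_min_separation)) {
      fails <- fails + 1L
      if (fails > 1e4) stop("soluble placement rejection failed")
      next
    }
    ks <- ks + 1L
    sol_pos[ks, ] <- p0
    sol_eul[ks, ] <- c(stats::runif(1, -180, 180),
                       acos(stats::runif(1, -1, 1)) * 180 / pi,
                       stats::runif(1, -180, 180))
  }
  sol_states <- if (n_sol > 0)
    sample(cat_tab$state_label, n_sol, replace = TRUE,
           prob = cat_tab$base_probability) else character(0)
  # truth is recorded before jitter
  edge_df <- if (length(edges)) {
    em <- do.call(rbind, edges)
    data.frame(tomogram_id = tom_id, trailing_id = em[, 1],
               leading_id = em[, 2], stringsAsFactors = FALSE)
  } else {
    data.frame(tomogram_id = character(0), trailing_id = integer(0),
               leading_id = integer(0))
  }
  # jitter positions and orientations
  pos_j <- pos + matrix(stats::rnorm(3 * n_mem, 0, cfg$positional_jitter_sd),
                        n_mem, 3)
  eul <- matrix(NA_real_, n_mem, 3)
  for (i in seq_len(n_mem)) {
    Rj <- axis_angle(random_sphere_point(),
                     stats::rnorm(1, 0, cfg$angular_jitter_sd))
    eul[i, ] <- rotation_to_euler(frames[[i]] %*% t(Rj))
  }
  if (n_sol > 0)
    sol_pos <- sol_pos + matrix(stats::rnorm(3 * n_sol, 0,
                                             cfg$positional_jitter_sd),
                                n_sol, 3)
  df <- data.frame(
    tomogram_id = tom_id,
    particle_id = c(seq_len(n_mem), n_mem + seq_len(n_sol)),
    x = c(pos_j[, 1], sol_pos[, 1]),
    y = c(pos_j[, 2], sol_pos[, 2]),
    z = c(pos_j[, 3], sol_pos[, 3]),
    rot = c(eul[, 1], sol_eul[, 1]),
    tilt = c(eul[, 2], sol_eul[, 2]),
    psi = c(eul[, 3], sol_eul[, 3]),
    state_label = c(states, sol_states),
    population_label = c(populations, rep("soluble-EBP1", n_sol)),
    stringsAsFactors = FALSE)
  truth <- list(
    edges = edge_df,
    membership = data.frame(tomogram_id = tom_id,
                            particle_id = c(seq_len(n_mem),
                                            n_mem + seq_len(n_sol)),
                            in_polysome = c(member, rep(FALSE, n_sol)),
                            stringsAsFactors = FALSE),
    normals = normals,
    tomogram_effect = u_t)
  list(table = df, truth = truth)
}

#' Generate a synthetic particle scene
#'
#' Draws `n_tomograms` vesicle scenes under the configured conditions and
#' returns the pooled particle table together with the ground truth recorded
#' before jitter (true trailing -> leading edges, per-particle polysome
#' membership, per-particle membrane normals and the realized per-tomogram
#' random effects). A fixed seed yields an identical table; the seed is
#' expanded into independent per-tomogram substreams.
#'
#' @param config A [scene_config()].
#' @return List with `table` (a [particle_table()]) and `truth`.
#' @export
generate_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  set.seed(config$seed)
  sub_seeds <- sample.int(2^31 - 2, config$n_tomograms)
  u <- stats::rnorm(config$n_tomograms, 0, config$tomogram_effect_sd)
  tabs <- vector("list", config$n_tomograms)
  truths <- vector("list", config$n_tomograms)
  for (t in seq_len(config$n_tomograms)) {
    set.seed(sub_seeds[t])
    res <- generate_tomogram(config, sprintf("tomo_%03d", t), u[t])
    tabs[[t]] <- res$table
    truths[[t]] <- res$truth
  }
  table <- particle_table(do.call(rbind, tabs), pixel_size = 1,
                          provenance = sprintf("synthetic scene, seed %d",
                                               config$seed))
  truth <- list(
    edges = do.call(rbind, lapply(truths, `[[`, "edges")),
    membership = do.call(rbind, lapply(truths, `[[`, "membership")),
    normals = lapply(truths, `[[`, "normals"),
    tomogram_effects = u,
    config = config)
  rownames(truth$edges) <- rownames(truth$membership) <- NULL
  list(table = table, truth = truth)
}

#' Generate association observations directly from the logistic model
#'
#' Bypasses the geometry: draws per-tomogram random intercepts
#' u_t ~ N(0, tomogram_effect_sd), assigns each ribosome a state from the
#' catalog's base abundances, and draws the binary in-polysome outcome from
#' plogis(qlogis(p_state) + u_t) — exactly the model the association fit
#' assumes. Used to validate estimation (recovery, CI coverage, null
#' calibration) independently of the spatial pipeline.
#'
#' @param config A [scene_config()]; uses `n_tomograms`, `seed`,
#'   `tomogram_effect_sd` and the state catalog.
#' @param n_per_tomogram Ribosomes per tomogram.
#' @return data.frame with `tomogram_id`, `state`, `outcome`
#'   ("in-polysome"/"none"); attribute `truth` carries the realized random
#'   effects and the true per-state probabilities.
#' @export
generate_association_dataset <- function(config, n_per_tomogram = 50) {
  stopifnot(inherits(config, "scene_config"))
  set.seed(config$seed)
  cat_tab <- config$state_catalog
  u <- stats::rnorm(config$n_tomograms, 0, config$tomogram_effect_sd)
  out <- vector("list", config$n_tomograms)
  for (t in seq_len(config$n_tomograms)) {
    st <- sample(cat_tab$state_label, n_per_tomogram, replace = TRUE,
                 prob = cat_tab$base_probability)
    p <- stats::plogis(stats::qlogis(
      cat_tab$in_polysome_probability[match(st, cat_tab$state_label)]) + u[t])
    out[[t]] <- data.frame(
      tomogram_id = sprintf("tomo_%03d", t), state = st,
      outcome = ifelse(stats::runif(n_per_tomogram) < p, "in-polysome", "none"),
      stringsAsFactors = FALSE)
  }
  obs <- do.call(rbind, out)
  rownames(obs) <- NULL
  attr(obs, "truth") <- list(tomogram_effects = u,
                             in_polysome_probability =
                               stats::setNames(cat_tab$in_polysome_probability,
                                               cat_tab$state_label))
  obs
}
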