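#' Pipeline configuration
#'
#' Bundles every stage's parameters into one serializable object. Input is
#' either a STAR particle table (`input_star`) or a synthetic scene
#' (`scene`); reference directions default to the scene's planted offsets
#' when a scene is generated and must be supplied explicitly for real data.
#'
#' @param output_dir Directory for stage outputs and the run manifest.
#' @param input_star Optional STAR file path (alternative to `scene`).
#' @param scene Optional [scene_config()].
#' @param neighbor A [neighbor_params()].
#' @param geometry A [histogram_geometry()].
#' @param masks A [mask_params()].
#' @param reference_directions Named list of unit vectors `trailing`,
#'   `leading`; NULL to take them from the scene config.
#' @param masks_file Optional path to externally supplied masks (as written
#'   by a previous run's `masks.json`); skips mask building.
#' @param model A [model_config()].
#' @param column_map,pixel_size Passed to [read_particle_table()] for
#'   `input_star`.
#' @param seed Integer seed for every stochastic component of the run.
#' @param log_level `"info"` or `"quiet"`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(output_dir, input_star = NULL, scene = NULL,
                            neighbor = neighbor_params(),
                            geometry = histogram_geometry(),
                            masks = mask_params(),
                            reference_directions = NULL,
                            masks_file = NULL,
                            model = model_config(),
                            column_map = default_column_map(), pixel_size = 1,
                            seed = 1, log_level = c("info", "quiet")) {
  if (is.null(input_star) && is.null(scene))
    stop("either input_star or a scene config is required")
  if (is.null(reference_directions) && is.null(scene))
    stop("reference_directions must be supplied for real data")
  structure(list(output_dir = output_dir, input_star = input_star,
                 scene = scene, neighbor = neighbor, geometry = geometry,
                 masks = masks, reference_directions = reference_directions,
                 masks_file = masks_file, model = model,
                 column_map = column_map, pixel_size = pixel_size,
                 seed = as.integer(seed), log_level = match.arg(log_level)),
            class = "pipeline_config")
}

plog <- function(config, ...) {
  if (config$log_level == "quiet") return(invisible(NULL))
  msg <- paste0("[", format(Sys.time(), "%H:%M:%S"), "] ", ...)
  message(msg)
  lf <- file.path(config$output_dir, "pipeline.log")
  cat(msg, "\n", file = lf, append = TRUE)
  invisible(NULL)
}

serialize_config <- function(config) {
  x <- unclass(config)
  x$scene <- if (!is.null(x$scene)) unclass(x$scene)
  x$neighbor <- unclass(x$neighbor)
  x$geometry <- unclass(x$geometry)
  x$masks <- unclass(x$masks)
  x$model <- unclass(x$model)
  x
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

mask_to_json <- function(masks, path) {
  enc <- lapply(masks, function(m) {
    list(direction = m$direction,
         voxel_size = m$geometry$voxel_size,
         half_extent_voxels = m$geometry$half_extent_voxels,
         provenance = m$provenance,
         true_voxels = which(m$voxels) - 1L)
  })
  jsonlite::write_json(enc, path, auto_unbox = TRUE, digits = NA)
  path
}

#' Read direction masks written by a pipeline run
#'
#' @param path Path to a `masks.json` file.
#' @return List with `direction_mask` elements `trailing` and `leading`.
#' @export
read_masks_json <- function(path) {
  enc <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(enc, function(m) {
    geom <- histogram_geometry(m$voxel_size, m$half_extent_voxels)
    vox <- array(FALSE, dim = rep(geom$n_voxels, 3))
    vox[unlist(m$true_voxels) + 1L] <- TRUE
    new_direction_mask(geom, vox, m$direction, m$provenance)
  })
}

#' Run the full polysome-analysis pipeline
#'
#' Executes the stages end to end — particle input, neighbour search,
#' per-population histograms, direction masks, reciprocal link confirmation,
#' chain assembly, per-tomogram frequencies, the association model and the
#' fold-increase table — writing every intermediate artifact into the output
#' directory plus a JSON manifest with content hashes. Identical config and
#' seed yield identical manifest hashes.
#'
#' @param config A [pipeline_config()].
#' @return The run manifest (named list of stage outputs with md5 hashes),
#'   invisibly; also written to `manifest.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  outputs <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      partial <- file.path(config$output_dir, "manifest_partial.json")
      jsonlite::write_json(
        list(failed_stage = name, error = conditionMessage(e),
             outputs = as.list(outputs)),
        partial, auto_unbox = TRUE)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  emit <- function(name, path) outputs[[name]] <<- path
  jsonlite::write_json(serialize_config(config),
                       file.path(config$output_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  ## 1. particles
  part <- stage("particles", {
    if (!is.null(config$input_star)) {
      plog(config, "reading particles from ", config$input_star)
      list(table = read_particle_table(config$input_star, config$column_map,
                                       config$pixel_size), truth = NULL)
    } else {
      sc <- config$scene
      sc$seed <- config$seed
      plog(config, "simulating scene: ", sc$n_tomograms, " tomogram(s)")
      res <- generate_scene(sc)
      list(table = res$table, truth = res$truth)
    }
  })
  table <- part$table
  truth <- part$truth
  star_path <- file.path(config$output_dir, "particles.star")
  write_particle_table(table, star_path)
  emit("particles", star_path)
  if (!is.null(truth)) {
    emit("ground_truth", write_tsv(truth$edges,
                                   file.path(config$output_dir,
                                             "ground_truth_edges.tsv")))
  }

  ## 2. neighbours
  ns <- stage("neighbors", find_neighbors(table, config$neighbor))
  plog(config, nrow(ns), " neighbour vectors retained")
  emit("neighbors", write_tsv(as.data.frame(ns),
                              file.path(config$output_dir, "neighbors.tsv")))

  ## 3. histograms per compartment
  hists <- stage("histograms", suppressWarnings(
    subgroup_histograms(table, ns, config$geometry, "compartment")))
  if (is.null(hists$membrane))
    stop("pipeline stage 'histograms' failed: no membrane-bound particles")
  if (is.null(hists$soluble))
    hists$soluble <- accumulate_histogram(ns[0, ], config$geometry, "soluble")
  for (tag in names(hists)) {
    p <- file.path(config$output_dir, paste0("histogram_", tag, ".csv"))
    utils::write.csv(histogram_to_df(hists[[tag]]), p, row.names = FALSE)
    emit(paste0("histogram_", tag), p)
  }
  proj <- project_xy(hists$membrane)
  pp <- file.path(config$output_dir, "projection_membrane_xy.csv")
  utils::write.csv(proj, pp, row.names = FALSE)
  emit("projection_xy", pp)

  ## 4. masks
  masks <- stage("masks", {
    if (!is.null(config$masks_file)) {
      plog(config, "using externally supplied masks: ", config$masks_file)
      read_masks_json(config$masks_file)
    } else {
      refs <- config$reference_directions
      if (is.null(refs))
        refs <- list(trailing = unit3(config$scene$trailing_offset),
                     leading = unit3(config$scene$leading_offset))
      build_direction_masks(hists$membrane, hists$soluble, config$masks, refs)
    }
  })
  mp <- file.path(config$output_dir, "masks.json")
  emit("masks", mask_to_json(masks, mp))

  ## 5. links, 6. chains
  links <- stage("links", confirm_links(ns, masks$trailing, masks$leading))
  plog(config, nrow(links$edges), " confirmed trailing->leading links")
  emit("links", write_tsv(links$edges,
                          file.path(config$output_dir, "links.tsv")))
  links <- stage("chains", assemble_chains(links))
  ch <- if (length(links$chains))
    do.call(rbind, lapply(seq_along(links$chains), function(i)
      cbind(chain = i, links$chains[[i]], position = seq_len(nrow(links$chains[[i]])))))
  else data.frame(chain = integer(0), tomogram_id = character(0),
                  particle_id = integer(0), position = integer(0))
  emit("chains", write_tsv(ch, file.path(config$output_dir, "chains.tsv")))

  ## 7. per-tomogram frequencies
  freqs <- stage("frequencies",
                 per_tomogram_frequencies(table, links, "state_label"))
  emit("frequencies", write_tsv(freqs,
                                file.path(config$output_dir,
                                          "frequencies.tsv")))

  ## 8. association model + contrasts
  fit <- stage("model", {
    obs <- association_observations(table, links, "membership")
    fit_association_model(obs, config$model)
  })
  assoc <- fit$predicted_probabilities
  if (!is.null(fit$contrasts))
    assoc <- merge(assoc,
                   fit$contrasts[, c("state_a", "state_b", "outcome", "p_raw",
                                     "p_adjusted")],
                   by.x = c("state", "outcome"),
                   by.y = c("state_a", "outcome"), all.x = TRUE)
  emit("association", write_tsv(assoc,
                                file.path(config$output_dir,
                                          "association.tsv")))

  ## 9. fold increase over random association
  fold <- stage("fold_increase", {
    member_frac <- nrow(links$members) / nrow(table)
    ab <- c("in-polysome" = member_frac, "none" = 1 - member_frac)
    fold_increase(fit, ab)
  })
  emit("fold_increase", write_tsv(fold,
                                  file.path(config$output_dir,
                                            "fold_increase.tsv")))

  manifest <- lapply(outputs, function(p)
    list(path = basename(p), md5 = unname(tools::md5sum(p))))
  jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE)
  plog(config, "pipeline complete: ", length(outputs), " stage outputs")
  invisible(list(manifest = manifest, table = table, neighbors = ns,
                 histograms = hists, masks = masks, links = links,
                 frequencies = freqs, fit = fit, fold = fold, truth = truth))
}
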