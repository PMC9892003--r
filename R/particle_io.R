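#' Controlled vocabularies for particle annotations
#'
#' Ribosome functional-state classes and ER translocon / soluble population
#' classes used to annotate particles. The state vocabulary covers the ten
#' intermediates routinely resolved by deep subtomogram classification of
#' ER-associated ribosomes: unrotated elongation states (decoding, pre+, pre),
#' rotated states (rotated-1, rotated-2), translocation, post, the two
#' hibernating classes (non-rotated NR-H and rotated R-H) and a catch-all
#' "unassigned". Populations distinguish translocon variants bound at the
#' ribosomal exit tunnel plus soluble and unidentified particles.
#'
#' Both vocabularies are defaults; every reader accepts a custom character
#' vector. "unassigned" is always appended as the sentinel for labels that do
#' not map.
#'
#' @return Character vector of allowed labels.
#' @export
default_state_vocabulary <- function() {
  c("decoding", "pre+", "pre", "rotated-1", "rotated-2",
    "translocation", "post", "NR-H", "R-H", "unassigned")
}

#' @rdname default_state_vocabulary
#' @export
default_population_vocabulary <- function() {
  c("SEC61-TRAP-OSTA", "SEC61-TRAP", "multipass", "multipass-TRAP",
    "soluble-EBP1", "unidentified", "unassigned")
}

#' Default STAR column mapping
#'
#' Maps particle-table fields to the metadata column names commonly emitted by
#' subtomogram-alignment software. Required fields: `tomogram_id`, `x`, `y`,
#' `z`, `rot`, `tilt`, `psi`. Optional: `particle_id` (defaults to the row
#' index within each tomogram), `origin_x/y/z` (refinement origin shifts in
#' voxels, treated as zero when absent) and the two label columns (defaulting
#' to "unassigned" when absent).
#'
#' @return Named list mapping field names to STAR column names.
#' @export
default_column_map <- function() {
  list(
    tomogram_id      = "rlnMicrographName",
    particle_id      = "polyParticleId",
    x                = "rlnCoordinateX",
    y                = "rlnCoordinateY",
    z                = "rlnCoordinateZ",
    origin_x         = "rlnOriginX",
    origin_y         = "rlnOriginY",
    origin_z         = "rlnOriginZ",
    rot              = "rlnAngleRot",
    tilt             = "rlnAngleTilt",
    psi              = "rlnAnglePsi",
    state_label      = "polyState",
    population_label = "polyPopulation"
  )
}

wrap180 <- function(a) ((a + 180) %% 360) - 180

#' Canonicalize ZYZ Euler angles
#'
#' Accepts rot, psi in \[-180, 360) and any tilt, and returns the equivalent
#' triple with rot, psi in \[-180, 180) and tilt in \[0, 180\]. A negative
#' tilt is folded using the ZYZ identity
#' Rz(psi) Ry(-t) Rz(rot) = Rz(psi+180) Ry(t) Rz(rot+180).
#'
#' @param rot,tilt,psi Euler angles in degrees (vectorized).
#' @return List with components `rot`, `tilt`, `psi`.
#' @export
canonicalize_euler <- function(rot, tilt, psi) {
  stopifnot(is.finite(rot), is.finite(tilt), is.finite(psi))
  t0 <- tilt %% 360
  neg <- t0 > 180
  t0[neg] <- 360 - t0[neg]
  rot[neg] <- rot[neg] + 180
  psi[neg] <- psi[neg] + 180
  list(rot = wrap180(rot), tilt = t0, psi = wrap180(psi))
}

## ---- minimal STAR (single data block, single loop) ----

read_star_block <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  i <- 1L
  n <- length(lines)
  while (i <= n && !startsWith(lines[i], "data_")) i <- i + 1L
  if (i > n) stop("STAR format error: no data_ block found in '", path, "'")
  i <- i + 1L
  while (i <= n && lines[i] != "loop_") {
    if (startsWith(lines[i], "data_"))
      stop("STAR format error: data block without loop_ in '", path, "'")
    i <- i + 1L
  }
  if (i > n) stop("STAR format error: no loop_ found in '", path, "'")
  i <- i + 1L
  cols <- character(0)
  while (i <= n && startsWith(lines[i], "_")) {
    cols <- c(cols, sub("^_([^ \t]+).*$", "\\1", lines[i]))
    i <- i + 1L
  }
  if (length(cols) == 0L) stop("STAR format error: loop_ without column labels")
  rows <- list()
  r <- 0L
  while (i <= n && nzchar(lines[i]) && !startsWith(lines[i], "data_")) {
    tok <- strsplit(lines[i], "[ \t]+")[[1]]
    if (length(tok) != length(cols))
      stop("STAR format error: row ", r + 1L, " has ", length(tok),
           " fields, expected ", length(cols))
    r <- r + 1L
    rows[[r]] <- tok
    i <- i + 1L
  }
  if (r == 0L) {
    df <- as.data.frame(matrix(character(0), nrow = 0, ncol = length(cols)),
                        stringsAsFactors = FALSE)
  } else {
    df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  }
  names(df) <- cols
  df
}

write_star_block <- function(df, path, block = "particles") {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c("", paste0("data_", block), "", "loop_"), con)
  writeLines(sprintf("_%s #%d", names(df), seq_along(df)), con)
  if (nrow(df) > 0) {
    mat <- vapply(df, as.character, character(nrow(df)))
    if (nrow(df) == 1L) mat <- matrix(mat, nrow = 1L)
    writeLines(apply(mat, 1L, paste, collapse = "\t"), con)
  }
  writeLines("", con)
  invisible(NULL)
}

## ---- particle table ----

#' Construct a particle table
#'
#' A particle table is a `data.frame` (class `particle_table`) with one row
#' per ribosome and columns `tomogram_id` (character), `particle_id` (integer,
#' unique within tomogram), `x`, `y`, `z` (positions in Angstrom, tomogram
#' frame), `rot`, `tilt`, `psi` (canonicalized ZYZ Euler angles in degrees)
#' and the categorical `state_label` and `population_label`. Positions are
#' always stored in Angstrom so that downstream distance thresholds (100 A
#' neighbour cutoff, 15 A histogram voxels) apply directly.
#'
#' @param df data.frame carrying the columns above (labels may be missing).
#' @param pixel_size Angstrom per voxel of the source tomogram (recorded for
#'   provenance; positions are already in Angstrom).
#' @param provenance Free-text source description.
#' @param state_vocabulary,population_vocabulary Closed label vocabularies.
#' @return A `particle_table`.
#' @export
particle_table <- function(df, pixel_size = 1, provenance = "constructed",
                           state_vocabulary = default_state_vocabulary(),
                           population_vocabulary = default_population_vocabulary()) {
  required <- c("tomogram_id", "particle_id", "x", "y", "z", "rot", "tilt", "psi")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("particle table lacks columns: ", paste(missing_cols, collapse = ", "))
  df$tomogram_id <- as.character(df$tomogram_id)
  df$particle_id <- as.integer(df$particle_id)
  for (cc in c("x", "y", "z", "rot", "tilt", "psi")) df[[cc]] <- as.numeric(df[[cc]])
  if (!all(is.finite(as.matrix(df[, c("x", "y", "z")]))))
    stop("non-finite particle position")
  eu <- canonicalize_euler(df$rot, df$tilt, df$psi)
  df$rot <- eu$rot; df$tilt <- eu$tilt; df$psi <- eu$psi
  if (is.null(df$state_label)) df$state_label <- "unassigned"
  if (is.null(df$population_label)) df$population_label <- "unassigned"
  df$state_label <- as.character(df$state_label)
  df$population_label <- as.character(df$population_label)
  key <- paste(df$tomogram_id, df$particle_id, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicated (tomogram_id, particle_id) pair")
  rownames(df) <- NULL
  structure(df,
            pixel_size = pixel_size,
            provenance = provenance,
            state_vocabulary = unique(c(state_vocabulary, "unassigned")),
            population_vocabulary = unique(c(population_vocabulary, "unassigned")),
            class = c("particle_table", "data.frame"))
}

map_labels <- function(x, vocabulary, strict, what) {
  unknown <- !(x %in% vocabulary)
  if (any(unknown)) {
    if (strict)
      stop("unknown ", what, " label(s): ",
           paste(unique(x[unknown]), collapse = ", "))
    x[unknown] <- "unassigned"
  }
  x
}

numeric_column <- function(raw, col) {
  out <- suppressWarnings(as.numeric(raw))
  bad <- which(!is.finite(out))
  if (length(bad))
    stop("non-numeric value in column '", col, "' at row ", bad[1])
  out
}

#' Read a particle table from a STAR file
#'
#' Parses the first `data_` block (one `loop_`) of a STAR-format particle
#' metadata file and standardizes it: positions are converted to Angstrom as
#' `(coordinate - origin_shift) * pixel_size` (origin shifts, in voxels, are
#' taken as zero when no origin columns are mapped or present), Euler angles
#' are canonicalized, and labels are passed through the closed vocabularies
#' (unknown labels become `"unassigned"` unless `strict = TRUE`).
#'
#' @param path STAR file path.
#' @param column_map Mapping of particle-table fields to STAR column names;
#'   see [default_column_map()].
#' @param pixel_size Angstrom per voxel used to scale coordinates.
#' @param strict Error on labels outside the vocabulary instead of mapping
#'   them to `"unassigned"`.
#' @param state_vocabulary,population_vocabulary Label vocabularies.
#' @return A [particle_table()].
#' @export
read_particle_table <- function(path, column_map = default_column_map(),
                                pixel_size = 1, strict = FALSE,
                                state_vocabulary = default_state_vocabulary(),
                                population_vocabulary = default_population_vocabulary()) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read_star_block(path)
  cm <- utils::modifyList(default_column_map(), column_map)
  required <- c("tomogram_id", "x", "y", "z", "rot", "tilt", "psi")
  for (f in required) {
    if (!(cm[[f]] %in% names(raw)))
      stop("STAR format error: missing mapped column '", cm[[f]],
           "' (field ", f, ")")
  }
  n <- nrow(raw)
  get_num <- function(field) numeric_column(raw[[cm[[field]]]], cm[[field]])
  opt_num <- function(field) {
    col <- cm[[field]]
    if (!is.null(col) && col %in% names(raw)) numeric_column(raw[[col]], col)
    else rep(0, n)
  }
  x <- (get_num("x") - opt_num("origin_x")) * pixel_size
  y <- (get_num("y") - opt_num("origin_y")) * pixel_size
  z <- (get_num("z") - opt_num("origin_z")) * pixel_size
  tom <- as.character(raw[[cm$tomogram_id]])
  pid_col <- cm$particle_id
  if (!is.null(pid_col) && pid_col %in% names(raw)) {
    pid <- as.integer(numeric_column(raw[[pid_col]], pid_col))
  } else {
    pid <- stats::ave(seq_len(n), tom, FUN = seq_along)
  }
  lab <- function(field, vocab) {
    col <- cm[[field]]
    if (!is.null(col) && col %in% names(raw))
      map_labels(as.character(raw[[col]]), vocab, strict, field)
    else rep("unassigned", n)
  }
  df <- data.frame(
    tomogram_id = tom, particle_id = pid,
    x = x, y = y, z = z,
    rot = get_num("rot"), tilt = get_num("tilt"), psi = get_num("psi"),
    state_label = lab("state_label", unique(c(state_vocabulary, "unassigned"))),
    population_label = lab("population_label",
                           unique(c(population_vocabulary, "unassigned"))),
    stringsAsFactors = FALSE)
  particle_table(df, pixel_size = pixel_size,
                 provenance = paste0("read from ", path),
                 state_vocabulary = state_vocabulary,
                 population_vocabulary = population_vocabulary)
}

#' Write a particle table to a STAR file
#'
#' Positions are written in Angstrom (pixel size 1), so that
#' `read_particle_table(path)` round-trips positions to well below 1e-6 A and
#' all labels exactly.
#'
#' @param table A [particle_table()].
#' @param path Output path.
#' @export
write_particle_table <- function(table, path) {
  stopifnot(inherits(table, "particle_table"))
  fmt <- function(v) sprintf("%.9f", v)
  df <- data.frame(
    rlnMicrographName = table$tomogram_id,
    polyParticleId    = table$particle_id,
    rlnCoordinateX    = fmt(table$x),
    rlnCoordinateY    = fmt(table$y),
    rlnCoordinateZ    = fmt(table$z),
    rlnAngleRot       = fmt(table$rot),
    rlnAngleTilt      = fmt(table$tilt),
    rlnAnglePsi       = fmt(table$psi),
    polyState         = table$state_label,
    polyPopulation    = table$population_label,
    stringsAsFactors  = FALSE)
  write_star_block(df, path)
  invisible(path)
}

#' Split a particle table by tomogram
#'
#' @param table A [particle_table()].
#' @return Named list of per-tomogram subsets (plain data.frames).
#' @export
split_by_tomogram <- function(table) {
  split(as.data.frame(table), table$tomogram_id)
}

#' Compartment (membrane / soluble) of each particle
#'
#' Derives the membrane-versus-soluble dichotomy from the population label:
#' populations whose name starts with "soluble" are soluble, "unidentified"
#' and "unassigned" map to "unidentified", everything else (the translocon
#' variants) is membrane-bound.
#'
#' @param table A [particle_table()].
#' @param soluble_populations Populations counted as soluble.
#' @return Character vector, one of "membrane", "soluble", "unidentified".
#' @export
particle_compartment <- function(table,
                                 soluble_populations = c("soluble-EBP1", "soluble")) {
  pop <- table$population_label
  out <- rep("membrane", length(pop))
  out[pop %in% soluble_populations | startsWith(pop, "soluble")] <- "soluble"
  out[pop %in% c("unidentified", "unassigned")] <- "unidentified"
  out
}

#' @export
print.particle_table <- function(x, ...) {
  cat(sprintf("particle_table: %d particles in %d tomogram(s)\n",
              nrow(x), length(unique(x$tomogram_id))))
  cat(sprintf("  pixel size %.4g A; provenance: %s\n",
              attr(x, "pixel_size"), attr(x, "provenance")))
  NextMethod()
}
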