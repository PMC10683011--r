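#' Write snapshots as extended XYZ
#'
#' One frame per snapshot, in extended-XYZ layout: a bead count line, a
#' comment line carrying `Lattice=...` and a `Properties=` descriptor
#' (`species:S:1:pos:R:3:vel:R:3:mol:I:1`), then one line per bead.
#'
#' @param frames A `dpd_snapshot` or list of them.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(frames, path) {
  frames <- as_frames(frames)
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in frames) {
    n <- nrow(fr$positions)
    writeLines(as.character(n), con)
    lat <- sprintf("%g 0 0 0 %g 0 0 0 %g", fr$box, fr$box, fr$box)
    writeLines(sprintf(
      'Lattice="%s" Properties=species:S:1:pos:R:3:vel:R:3:mol:I:1', lat), con)
    writeLines(sprintf("%s %.10g %.10g %.10g %.10g %.10g %.10g %d",
                       fr$species,
                       fr$positions[, 1], fr$positions[, 2], fr$positions[, 3],
                       fr$velocities[, 1], fr$velocities[, 2],
                       fr$velocities[, 3], fr$molecule_id), con)
  }
  invisible(path)
}

#' Read an extended XYZ trajectory
#'
#' Counterpart of [write_xyz()].  Bonds are not carried by the format;
#' the returned snapshots have empty bond lists.
#'
#' @param path File written by [write_xyz()].
#' @return A list of `dpd_snapshot`s.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    n <- as.integer(lines[i])
    if (is.na(n)) abort_validation("malformed XYZ: expected a bead count")
    comment <- lines[i + 1L]
    m <- regmatches(comment, regexec('Lattice="([^"]+)"', comment))[[1]]
    if (length(m) < 2) abort_validation("malformed XYZ: missing Lattice")
    lat <- as.numeric(strsplit(m[2], "\\s+")[[1]])
    box <- lat[1]
    body <- lines[i + 1L + seq_len(n)]
    parts <- strsplit(trimws(body), "\\s+")
    species <- vapply(parts, `[[`, character(1), 1)
    num <- t(vapply(parts, function(p) as.numeric(p[2:8]), numeric(7)))
    frames[[length(frames) + 1L]] <- snapshot(
      box, num[, 1:3, drop = FALSE], num[, 4:6, drop = FALSE], species,
      as.integer(num[, 7]))
    i <- i + 2L + n
  }
  frames
}

#' Write an RDF profile, coordination table or thermo log as TSV
#'
#' @param x An `rdf_profile`, `coordination_table` or `dpd_run`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_tsv_result <- function(x, path) {
  df <- if (inherits(x, "dpd_run")) x$thermo else tibble::as_tibble(x)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a system configuration from YAML
#'
#' Recognised keys: `box_edge`, `bead_density`, `polymer_fraction`,
#' `blocks` (list of `species`/`count` pairs), `seed`.
#'
#' @param path YAML file path (or a pre-parsed list).
#' @return A [system_config()].
#' @export
read_system_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  blocks <- if (is.null(cfg$blocks)) mcm_blocks() else
    dplyr::bind_rows(lapply(cfg$blocks, tibble::as_tibble))
  system_config(
    box_edge = cfg$box_edge,
    bead_density = cfg$bead_density %||% 3,
    polymer_fraction = cfg$polymer_fraction %||% 0.05,
    chain = build_chain(blocks),
    seed = cfg$seed %||% 1L
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
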