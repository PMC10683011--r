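as_frames <- function(frames) {
  if (inherits(frames, "dpd_snapshot")) return(list(frames))
  if (inherits(frames, "dpd_run")) {
    if (length(frames$frames) > 0) return(frames$frames)
    return(list(frames$snapshot))
  }
  if (is.list(frames) && length(frames) > 0 &&
      all(vapply(frames, inherits, logical(1), "dpd_snapshot"))) {
    return(frames)
  }
  abort_validation(
    "`frames` must be a dpd_snapshot, a dpd_run, or a list of snapshots")
}

#' Block-resolved pair-correlation profile
#'
#' Computes the density-weighted pair correlation \eqn{\rho_i g(r)}
#' between a reference species and a target species (or group of target
#' species treated as one): for every reference bead, target beads in
#' the spherical shell `[r, r + delta_r)` are counted under the minimum
#' image convention, divided by the shell volume \eqn{4\pi r^2\Delta r},
#' and averaged over reference beads and frames.  For a uniformly
#' distributed target the profile tends to the bulk number density
#' \eqn{\rho_i} of the target at large `r`.
#'
#' @param frames A `dpd_snapshot`, a `dpd_run` (its stored frames, or
#'   final snapshot if none), or a list of snapshots.
#' @param ref_species Reference species label (e.g. `"Proline"`).
#' @param target_species Target species label(s); several labels are
#'   pooled into one target group.
#' @param delta_r Bin width (reduced length); default 0.05.
#' @param r_max Profile range; default `min(6, box/2 - delta_r)`.  Must
#'   not exceed half the box edge (minimum-image validity).
#' @return An `rdf_profile`: tibble with columns `r` (bin centers) and
#'   `rho_g`, carrying `ref_species`, `target_species`, `delta_r`,
#'   `n_frames` and `box` as attributes.
#' @export
pair_correlation <- function(frames, ref_species, target_species,
                             delta_r = 0.05, r_max = NULL) {
  frames <- as_frames(frames)
  stopifnot_scalar_number(delta_r, "delta_r", positive = TRUE)
  box <- frames[[1]]$box
  if (is.null(r_max)) r_max <- min(6, box / 2 - delta_r)
  if (r_max > box / 2 + 1e-12) {
    abort_validation(sprintf(
      "r_max = %g exceeds box/2 = %g: minimum-image convention invalid",
      r_max, box / 2))
  }
  if (r_max <= delta_r) abort_validation("`r_max` must exceed `delta_r`")

  nbin <- ceiling(r_max / delta_r)
  acc <- numeric(nbin)
  for (fr in frames) {
    ref_idx <- which(fr$species %in% ref_species)
    if (length(ref_idx) == 0) {
      abort_validation(paste0("reference species absent from frame: ",
                              paste(ref_species, collapse = ",")))
    }
    tgt_idx <- which(fr$species %in% target_species)
    counts <- rdf_counts_cpp(fr$positions, fr$box, ref_idx - 1L,
                             tgt_idx - 1L, delta_r, nbin)
    acc <- acc + counts / length(ref_idx)
  }
  r_centers <- (seq_len(nbin) - 0.5) * delta_r
  shell_vol <- 4 * pi * r_centers^2 * delta_r
  out <- tibble::tibble(r = r_centers, rho_g = acc / length(frames) / shell_vol)
  structure(out,
            ref_species = ref_species, target_species = target_species,
            delta_r = delta_r, n_frames = length(frames), box = box,
            class = c("rdf_profile", class(out)))
}

#' Coordination number from a pair-correlation profile
#'
#' Integrates the density-weighted profile over the coordination sphere:
#' \eqn{Z = \sum_k \rho_i g(r_k)\, 4\pi r_k^2\, \Delta r} over bins below
#' `r_cut`; the bin straddling `r_cut` enters pro-rata.
#'
#' @param profile An `rdf_profile`.
#' @param r_cut Integration upper bound (reduced length); default 3.45,
#'   the first-peak position of the Proline-L pair in the assembled
#'   micelle.
#' @return The coordination number `Z` (scalar).
#' @export
coordination_number <- function(profile, r_cut = 3.45) {
  stopifnot(inherits(profile, "rdf_profile"))
  if (nrow(profile) == 0) abort_validation("empty profile")
  dr <- attr(profile, "delta_r")
  if (r_cut > max(profile$r) + dr / 2 + 1e-12) {
    abort_validation("`r_cut` exceeds the range of the profile")
  }
  lower <- profile$r - dr / 2
  upper <- profile$r + dr / 2
  frac <- pmin(pmax((r_cut - lower) / dr, 0), 1)
  sum(profile$rho_g * 4 * pi * profile$r^2 * dr * frac)
}

#' Position of the first maximum of a profile
#'
#' Used to self-calibrate the coordination sphere on scaled-down boxes:
#' the coordination cutoff is taken at the first peak of the
#' Proline-L profile.
#'
#' @param profile An `rdf_profile`.
#' @return The `r` of the global maximum of `rho_g`.
#' @export
first_peak <- function(profile) {
  stopifnot(inherits(profile, "rdf_profile"))
  profile$r[which.max(profile$rho_g)]
}

#' Coordination table of a reference species against several targets
#'
#' @inheritParams pair_correlation
#' @param r_cut Coordination cutoff passed to [coordination_number()].
#' @return A `coordination_table`: tibble with columns `target` and `Z`,
#'   carrying `ref_species` and `r_cut` as attributes.
#' @export
coordination_table <- function(frames, ref_species, target_species,
                               delta_r = 0.05, r_cut = 3.45, r_max = NULL) {
  frames <- as_frames(frames)
  if (is.null(r_max)) {
    r_max <- min(max(6, r_cut + delta_r), frames[[1]]$box / 2 - delta_r)
  }
  z <- vapply(target_species, function(tg) {
    coordination_number(
      pair_correlation(frames, ref_species, tg, delta_r, r_max), r_cut)
  }, numeric(1))
  out <- tibble::tibble(target = target_species, Z = unname(z))
  structure(out, ref_species = ref_species, r_cut = r_cut,
            class = c("coordination_table", class(out)))
}

#' Direct time-averaged neighbour count
#'
#' Counts target beads within `r_cut` of each reference bead directly
#' (no binning), averaged over reference beads and frames.  Serves as an
#' integration-free cross-check of [coordination_number()].
#'
#' @inheritParams pair_correlation
#' @param r_cut Counting radius.
#' @return Mean neighbour count (scalar).
#' @export
direct_coordination <- function(frames, ref_species, target_species, r_cut) {
  frames <- as_frames(frames)
  vals <- vapply(frames, function(fr) {
    ref_idx <- which(fr$species %in% ref_species)
    tgt_idx <- which(fr$species %in% target_species)
    if (length(ref_idx) == 0) {
      abort_validation("reference species absent from frame")
    }
    counts <- rdf_counts_cpp(fr$positions, fr$box, ref_idx - 1L,
                             tgt_idx - 1L, r_cut, 1L)
    sum(counts) / length(ref_idx)
  }, numeric(1))
  mean(vals)
}

#' Plot pair-correlation profiles
#'
#' @param object An `rdf_profile`.
#' @param ... Further `rdf_profile`s to overlay.
#' @return A ggplot of \eqn{\rho_i g(r)} vs `r`, one line per profile.
#' @export
autoplot.rdf_profile <- function(object, ...) {
  profiles <- c(list(object), list(...))
  df <- purrr::map_dfr(profiles, function(p) {
    tibble::tibble(
      r = p$r, rho_g = p$rho_g,
      pair = paste0(paste(attr(p, "ref_species"), collapse = "+"), "-",
                    paste(attr(p, "target_species"), collapse = "+")))
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$r, .data$rho_g,
                                   colour = .data$pair)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "r (r_c)", y = expression(rho[i] * g(r)),
                  colour = "pair")
}

#' Compartment identification by contact clustering
#'
#' Single-linkage clustering of the selected species' beads: beads
#' closer than `contact_cutoff` (minimum image) are linked, and clusters
#' are the connected components of the resulting contact graph.
#' Interfacial contacts are tallied per species pair.
#'
#' @param snapshot A `dpd_snapshot`.
#' @param contact_cutoff Linkage distance (reduced length); default 1.
#' @param species_subset Species to cluster; default all non-water.
#' @return A `compartment_report`: list with `clusters` (tibble:
#'   `cluster`, `size`, and one count column per species) and `contacts`
#'   (tibble: `species_i`, `species_j`, `n`).
#' @export
identify_compartments <- function(snapshot, contact_cutoff = 1,
                                  species_subset = NULL) {
  stopifnot(inherits(snapshot, "dpd_snapshot"))
  stopifnot_scalar_number(contact_cutoff, "contact_cutoff", positive = TRUE)
  if (is.null(species_subset)) {
    species_subset <- setdiff(unique(snapshot$species), "W")
  }
  idx <- which(snapshot$species %in% species_subset)
  if (length(idx) == 0) abort_validation("species subset selects no beads")

  pairs <- contact_pairs_cpp(snapshot$positions, snapshot$box, idx - 1L,
                             contact_cutoff)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (nrow(pairs) > 0) g <- igraph::add_edges(g, t(pairs + 1L))
  comp <- igraph::components(g)

  sp <- snapshot$species[idx]
  cl_df <- tibble::tibble(cluster = comp$membership, species = sp)
  clusters <- cl_df |>
    dplyr::count(.data$cluster, .data$species) |>
    tidyr::pivot_wider(names_from = "species", values_from = "n",
                       values_fill = 0L) |>
    dplyr::mutate(size = rowSums(dplyr::pick(-"cluster"))) |>
    dplyr::relocate("cluster", "size") |>
    dplyr::arrange(dplyr::desc(.data$size))

  contacts <- if (nrow(pairs) > 0) {
    tibble::tibble(
      species_i = pmin(sp[pairs[, 1] + 1L], sp[pairs[, 2] + 1L]),
      species_j = pmax(sp[pairs[, 1] + 1L], sp[pairs[, 2] + 1L])
    ) |> dplyr::count(.data$species_i, .data$species_j, name = "n")
  } else {
    tibble::tibble(species_i = character(), species_j = character(),
                   n = integer())
  }
  structure(list(clusters = clusters, contacts = contacts,
                 contact_cutoff = contact_cutoff,
                 n_beads = length(idx)),
            class = "compartment_report")
}

#' @export
print.compartment_report <- function(x, ...) {
  cat("<compartment_report> ", nrow(x$clusters), " cluster(s) over ",
      x$n_beads, " beads at cutoff ", x$contact_cutoff, "\n", sep = "")
  print(x$clusters, n = 5)
  invisible(x)
}

#' Core-shell burial metric
#'
#' Quantifies hydrophobic burial of the fluorophilic core: the fraction
#' of core-species beads with more shell-species contacts than solvent
#' contacts within the cutoff.  Values near 1 indicate the core is
#' covered by the shell species rather than exposed to water.
#'
#' @param snapshot A `dpd_snapshot`.
#' @param core,shell,solvent Species labels; defaults `"F"`, `"L"`, `"W"`.
#' @param cutoff Contact distance; default 1.
#' @return Fraction in `[0, 1]`.
#' @export
core_shell_metric <- function(snapshot, core = "F", shell = "L",
                              solvent = "W", cutoff = 1) {
  core_idx <- which(snapshot$species == core)
  if (length(core_idx) == 0) abort_validation("no core beads in snapshot")
  n_shell <- per_ref_neighbour_count(snapshot, core_idx, shell, cutoff)
  n_solv <- per_ref_neighbour_count(snapshot, core_idx, solvent, cutoff)
  mean(n_shell > n_solv)
}

# Per-reference-bead neighbour counts (R helper; small selections only).
per_ref_neighbour_count <- function(snapshot, ref_idx, target_species,
                                    cutoff) {
  tgt <- which(snapshot$species %in% target_species)
  pos <- snapshot$positions
  box <- snapshot$box
  vapply(ref_idx, function(i) {
    d <- sweep(pos[tgt, , drop = FALSE], 2, pos[i, ])
    d <- d - box * round(d / box)
    r2 <- rowSums(d^2)
    sum(r2 <= cutoff^2 & r2 > 0)
  }, numeric(1))
}
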