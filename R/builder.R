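#' Build a linear multiblock bead-spring chain topology
#'
#' Concatenates block runs into a bead sequence and connects consecutive
#' beads with harmonic springs.  The default multicompartment-micelle
#' chain is the scaled-down amphiphile H12-L3-Proline7-F3 (hydrophilic
#' ethylene-oxide shell block, lipophilic styrene, catalyst block,
#' fluorophilic pentafluorostyrene): 25 beads, 24 bonds.
#'
#' @param blocks Data frame with columns `species` and `count`, one row
#'   per block, in chain order.
#' @return A `chain_topology`: list with `sequence` (character vector,
#'   one label per bead) and `bonds` (integer matrix, two 1-based bead
#'   indices per row).  Custom (e.g. grafted) topologies can be built by
#'   supplying `bonds` directly to [chain_topology()].
#' @export
#' @examples
#' ch <- build_chain(mcm_blocks())
#' length(ch$sequence) # 25
build_chain <- function(blocks) {
  blocks <- as.data.frame(blocks)
  if (nrow(blocks) == 0) abort_validation("`blocks` must contain at least one block")
  if (!all(c("species", "count") %in% names(blocks))) {
    abort_validation("`blocks` needs `species` and `count` columns")
  }
  if (any(blocks$count < 1) || any(blocks$count != round(blocks$count))) {
    abort_validation("block counts must be integers >= 1")
  }
  sequence <- rep(as.character(blocks$species), times = blocks$count)
  n <- length(sequence)
  bonds <- if (n > 1) cbind(seq_len(n - 1), seq(2, n)) else
    matrix(integer(0), 0, 2)
  chain_topology(sequence, bonds)
}

#' @rdname build_chain
#' @param sequence Character vector of per-bead species labels.
#' @param bonds Two-column integer matrix of 1-based bead index pairs.
#' @export
chain_topology <- function(sequence, bonds) {
  sequence <- as.character(sequence)
  n <- length(sequence)
  bonds <- matrix(as.integer(bonds), ncol = 2)
  if (nrow(bonds) > 0) {
    if (any(bonds < 1) || any(bonds > n)) {
      abort_validation("bonds reference bead indices outside the chain")
    }
    if (any(bonds[, 1] == bonds[, 2])) abort_validation("self-bonds are not allowed")
    key <- paste(pmin(bonds[, 1], bonds[, 2]), pmax(bonds[, 1], bonds[, 2]))
    if (anyDuplicated(key)) abort_validation("duplicate bonds are not allowed")
  }
  structure(list(sequence = sequence, bonds = bonds), class = "chain_topology")
}

#' Default block table of the micelle-forming amphiphile
#'
#' @return A tibble of blocks for the 25-bead chain H12-L3-Proline7-F3.
#' @export
mcm_blocks <- function() {
  tibble::tibble(
    species = c("H", "L", "Proline", "F"),
    count = c(12L, 3L, 7L, 3L)
  )
}

round_half_up <- function(x) floor(x + 0.5)

# Evaluate `code` under a locally seeded RNG, restoring the caller's
# RNG state afterwards so builders never perturb the global stream.
with_local_seed <- function(seed, code) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE))
    get(".Random.seed", envir = env) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE))
        rm(".Random.seed", envir = env)
    } else assign(".Random.seed", old, envir = env)
  })
  set.seed(seed)
  force(code)
}

#' System configuration for the builder
#'
#' @param box_edge Cubic box edge (reduced length, units of `r_c`).
#' @param bead_density Beads per \eqn{r_c^3}; default 3.
#' @param polymer_fraction Fraction of beads belonging to polymer chains;
#'   default 0.05 (the 5% polymer / 95% water composition).
#' @param chain A `chain_topology`; default the H12-L3-Proline7-F3 chain.
#' @param seed Integer RNG seed.
#' @return A list of class `system_config`.
#' @export
system_config <- function(box_edge, bead_density = 3, polymer_fraction = 0.05,
                          chain = build_chain(mcm_blocks()), seed = 1L) {
  box_edge <- as.numeric(box_edge)
  bead_density <- as.numeric(bead_density)
  polymer_fraction <- as.numeric(polymer_fraction)
  stopifnot_scalar_number(box_edge, "box_edge", positive = TRUE)
  stopifnot_scalar_number(bead_density, "bead_density", positive = TRUE)
  stopifnot_scalar_number(polymer_fraction, "polymer_fraction")
  if (polymer_fraction < 0 || polymer_fraction > 1) {
    abort_validation("`polymer_fraction` must be in [0, 1]")
  }
  stopifnot(inherits(chain, "chain_topology"))
  structure(
    list(box_edge = box_edge, bead_density = bead_density,
         polymer_fraction = polymer_fraction, chain = chain,
         seed = as.integer(seed)),
    class = "system_config"
  )
}

#' Construct a snapshot object
#'
#' A snapshot is the full per-bead state of a periodic system: positions
#' (wrapped into `[0, box)`), velocities, species labels and molecule
#' ids (each water bead is its own molecule).
#'
#' @param box Cubic box edge (reduced).
#' @param positions,velocities Numeric `n x 3` matrices.
#' @param species Character vector of per-bead labels.
#' @param molecule_id Integer vector of per-bead molecule ids.
#' @param bonds Two-column integer matrix of 1-based global bead indices
#'   (may have zero rows).
#' @return An object of class `dpd_snapshot`.
#' @export
snapshot <- function(box, positions, velocities, species, molecule_id,
                     bonds = matrix(integer(0), 0, 2)) {
  positions <- as.matrix(positions)
  velocities <- as.matrix(velocities)
  n <- nrow(positions)
  if (!all(dim(positions) == c(n, 3)) || !all(dim(velocities) == c(n, 3))) {
    abort_validation("positions and velocities must be n x 3 matrices")
  }
  if (length(species) != n || length(molecule_id) != n) {
    abort_validation("species and molecule_id must match the bead count")
  }
  positions <- positions %% box
  structure(
    list(box = box, positions = positions, velocities = velocities,
         species = as.character(species),
         molecule_id = as.integer(molecule_id),
         bonds = matrix(as.integer(bonds), ncol = 2)),
    class = "dpd_snapshot"
  )
}

#' @export
print.dpd_snapshot <- function(x, ...) {
  cat("<dpd_snapshot> ", nrow(x$positions), " beads in box ", x$box, "^3\n",
      sep = "")
  print(table(x$species))
  invisible(x)
}

#' Coerce a snapshot to a tibble
#'
#' @param x A `dpd_snapshot`.
#' @param ... Unused.
#' @return A tibble with one row per bead: `species`, `molecule_id`,
#'   `x`, `y`, `z`, `vx`, `vy`, `vz`.
#' @export
as_tibble.dpd_snapshot <- function(x, ...) {
  pos <- x$positions
  vel <- x$velocities
  tibble::tibble(
    species = x$species, molecule_id = x$molecule_id,
    x = pos[, 1], y = pos[, 2], z = pos[, 3],
    vx = vel[, 1], vy = vel[, 2], vz = vel[, 3]
  )
}

maxwell_velocities <- function(n) {
  if (n == 0) return(matrix(0, 0, 3))
  v <- matrix(stats::rnorm(3 * n), n, 3)   # kT = 1, m = 1
  sweep(v, 2, colMeans(v))                 # zero total momentum
}

# Random-walk chain with bond length ~0.7 r_c; candidates folding straight
# back onto bead i-2 are re-drawn (soft self-avoidance, overlap is fine for
# soft DPD potentials).
place_chain <- function(n_beads, box, bond_len = 0.7) {
  pos <- matrix(0, n_beads, 3)
  pos[1, ] <- stats::runif(3, 0, box)
  for (k in seq_len(n_beads - 1L)) {
    for (try in 1:10) {
      d <- stats::rnorm(3)
      d <- d / sqrt(sum(d^2)) * bond_len
      cand <- pos[k, ] + d
      if (k == 1L) break
      prev <- cand - pos[k - 1L, ]
      if (sqrt(sum(prev^2)) > 0.5 * bond_len) break
    }
    pos[k + 1L, ] <- cand
  }
  pos %% box
}

#' Build an initial periodic configuration
#'
#' Realises a `system_config`: the bead budget is
#' `round(bead_density * box_edge^3)` (round half up), the chain count is
#' `round(polymer_fraction * total / chain_length)`, residual beads are
#' water.  Chains are placed as soft self-avoiding random walks with bond
#' length 0.7 `r_c`; water beads uniformly at random; velocities are
#' drawn from the Maxwell distribution at \eqn{k_BT = 1} and shifted to
#' zero net momentum.  Identical config + seed gives a bit-identical
#' snapshot.
#'
#' @param cfg A [system_config()].
#' @return A `dpd_snapshot` with global bond list attached.
#' @export
#' @examples
#' cfg <- system_config(box_edge = 10, seed = 42)
#' snap <- build_system(cfg)
#' table(snap$species)["W"] # 2850
build_system <- function(cfg) {
  stopifnot(inherits(cfg, "system_config"))
  n_total <- round_half_up(cfg$bead_density * cfg$box_edge^3)
  chain_len <- length(cfg$chain$sequence)
  budget <- cfg$polymer_fraction * n_total
  n_chain <- if (cfg$polymer_fraction > 0) {
    if (chain_len > budget) {
      abort_validation(sprintf(
        "chain of %d beads exceeds the polymer budget of %.1f beads",
        chain_len, budget))
    }
    round_half_up(budget / chain_len)
  } else 0L
  n_poly <- n_chain * chain_len
  n_water <- n_total - n_poly

  with_local_seed(cfg$seed, {
    pos <- matrix(0, n_total, 3)
    species <- character(n_total)
    mol <- integer(n_total)
    bonds <- matrix(integer(0), 0, 2)
    at <- 0L
    if (n_chain > 0) {
      bond_rows <- vector("list", n_chain)
      for (c_id in seq_len(n_chain)) {
        idx <- at + seq_len(chain_len)
        pos[idx, ] <- place_chain(chain_len, cfg$box_edge)
        species[idx] <- cfg$chain$sequence
        mol[idx] <- c_id
        if (nrow(cfg$chain$bonds) > 0) bond_rows[[c_id]] <- cfg$chain$bonds + at
        at <- at + chain_len
      }
      bonds <- do.call(rbind, bond_rows)
      if (is.null(bonds)) bonds <- matrix(integer(0), 0, 2)
    }
    if (n_water > 0) {
      idx <- at + seq_len(n_water)
      pos[idx, ] <- matrix(stats::runif(3 * n_water, 0, cfg$box_edge),
                           n_water, 3)
      species[idx] <- "W"
      mol[idx] <- n_chain + seq_len(n_water)
    }
    snapshot(cfg$box_edge, pos, maxwell_velocities(n_total), species, mol,
             bonds)
  })
}

#' Small deterministic test systems
#'
#' Convenience generators for validation work:
#' * `pure_fluid` — a single species at the requested density,
#' * `binary_blend` — two species at 50:50 (counts differ by at most 1),
#' * `single_chain` — one polymer chain in dilute water,
#' * `lattice` — beads on a simple cubic grid (zero velocities), whose
#'   neighbour shells are known analytically.
#'
#' @param kind One of `"pure_fluid"`, `"binary_blend"`, `"single_chain"`,
#'   `"lattice"`.
#' @param box_edge Box edge (for `lattice` this is `spacing * cells`).
#' @param bead_density Beads per \eqn{r_c^3} (ignored for `lattice`).
#' @param species Species label(s); `binary_blend` needs two.
#' @param chain Chain topology for `single_chain`.
#' @param spacing,cells Lattice spacing and cells per edge.
#' @param seed RNG seed.
#' @return A `dpd_snapshot`.
#' @export
build_fixture <- function(kind = c("pure_fluid", "binary_blend",
                                   "single_chain", "lattice"),
                          box_edge = 6, bead_density = 3,
                          species = "W", chain = build_chain(mcm_blocks()),
                          spacing = 1, cells = 5, seed = 1L) {
  kind <- tryCatch(match.arg(kind),
                   error = function(e) abort_validation(
                     paste0("unknown fixture kind: ", kind[1])))
  switch(kind,
    pure_fluid = with_local_seed(seed, {
      n <- round_half_up(bead_density * box_edge^3)
      snapshot(box_edge, matrix(stats::runif(3 * n, 0, box_edge), n, 3),
               maxwell_velocities(n), rep(species[1], n), seq_len(n))
    }),
    binary_blend = with_local_seed(seed, {
      if (length(species) < 2) species <- c("A", "B")
      n <- round_half_up(bead_density * box_edge^3)
      n1 <- ceiling(n / 2)
      sp <- c(rep(species[1], n1), rep(species[2], n - n1))
      snapshot(box_edge, matrix(stats::runif(3 * n, 0, box_edge), n, 3),
               maxwell_velocities(n), sp, seq_len(n))
    }),
    single_chain = with_local_seed(seed, {
      n <- round_half_up(bead_density * box_edge^3)
      cl <- length(chain$sequence)
      if (cl > n) abort_validation("chain does not fit the bead budget")
      pos <- rbind(place_chain(cl, box_edge),
                   matrix(stats::runif(3 * (n - cl), 0, box_edge), n - cl, 3))
      snapshot(box_edge, pos, maxwell_velocities(n),
               c(chain$sequence, rep("W", n - cl)),
               c(rep(1L, cl), 1L + seq_len(n - cl)),
               bonds = chain$bonds)
    }),
    lattice = {
      g <- seq(0, cells - 1) * spacing
      pos <- as.matrix(expand.grid(x = g, y = g, z = g))
      n <- nrow(pos)
      snapshot(cells * spacing, pos, matrix(0, n, 3), rep(species[1], n),
               seq_len(n))
    }
  )
}
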