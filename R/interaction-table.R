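#' Construct a DPD interaction table
#'
#' An interaction table bundles the pairwise Flory-Huggins \eqn{\chi}
#' matrix, the corresponding soft-repulsion matrix \eqn{a_{ij}}, and the
#' shared thermostat parameters (dissipative coefficient \eqn{\gamma},
#' random-force amplitude \eqn{\sigma}, cutoff \eqn{r_c}).  The
#' fluctuation-dissipation relation \eqn{\sigma^2 = 2\gamma k_BT} is
#' enforced at construction (reduced units, \eqn{k_BT = 1}).
#'
#' @param species Character vector of bead species labels.
#' @param chi Symmetric numeric matrix of \eqn{\chi} parameters with zero
#'   diagonal, in the order of `species`.
#' @param gamma Dissipative coefficient (reduced); default 4.5.
#' @param sigma Random-force amplitude (reduced); default `sqrt(2 * gamma)`
#'   so that the thermostat targets \eqn{k_BT = 1}.
#' @param r_c Interaction cutoff (reduced length); default 1.
#' @param baseline Like-species repulsion \eqn{a_{ii}}; default 25
#'   (the Groot-Warren value for bead density 3).
#' @param slope Slope of the \eqn{\chi \to a} map; default 3.27.
#'
#' @return An object of class `interaction_table`: a list with elements
#'   `species`, `chi`, `a`, `gamma`, `sigma`, `r_c`.
#' @export
#' @examples
#' it <- interaction_table(c("A", "B"), matrix(c(0, 2, 2, 0), 2))
#' it$a
interaction_table <- function(species, chi, gamma = 4.5, sigma = sqrt(2 * gamma),
                              r_c = 1, baseline = 25, slope = 3.27) {
  species <- as.character(species)
  ns <- length(species)
  if (ns < 1L || anyDuplicated(species)) {
    abort_validation("`species` must be a non-empty vector of unique labels")
  }
  chi <- as.matrix(chi)
  if (!is.numeric(chi) || nrow(chi) != ns || ncol(chi) != ns) {
    abort_validation("`chi` must be a numeric matrix matching `species`")
  }
  if (max(abs(chi - t(chi))) > 1e-12) {
    abort_validation("`chi` must be symmetric")
  }
  if (max(abs(diag(chi))) > 1e-12) {
    abort_validation("`chi` must have a zero diagonal")
  }
  stopifnot_scalar_number(gamma, "gamma", positive = TRUE)
  stopifnot_scalar_number(sigma, "sigma", positive = TRUE)
  stopifnot_scalar_number(r_c, "r_c", positive = TRUE)
  if (abs(sigma^2 - 2 * gamma) > 1e-9) {
    abort_validation(sprintf(
      "fluctuation-dissipation violated: sigma^2 = %g but 2*gamma*kT = %g",
      sigma^2, 2 * gamma
    ))
  }
  a <- repulsion_from_chi(chi, baseline = baseline, slope = slope)
  dimnames(chi) <- dimnames(a) <- list(species, species)
  structure(
    list(species = species, chi = chi, a = a,
         gamma = gamma, sigma = sigma, r_c = r_c),
    class = "interaction_table"
  )
}

#' @export
print.interaction_table <- function(x, ...) {
  cat("<interaction_table> ", length(x$species), " species: ",
      paste(x$species, collapse = ", "), "\n", sep = "")
  cat("gamma = ", x$gamma, ", sigma = ", x$sigma, ", r_c = ", x$r_c, "\n",
      sep = "")
  cat("chi:\n")
  print(round(x$chi, 4))
  invisible(x)
}

#' Tidy an interaction table into long pair format
#'
#' @param x An `interaction_table`.
#' @param ... Unused.
#' @return A tibble with one row per unordered species pair (including
#'   like pairs) and columns `species_i`, `species_j`, `chi`, `a`.
#' @export
tidy.interaction_table <- function(x, ...) {
  ns <- length(x$species)
  idx <- which(upper.tri(x$chi, diag = TRUE), arr.ind = TRUE)
  tibble::tibble(
    species_i = x$species[idx[, 1]],
    species_j = x$species[idx[, 2]],
    chi = x$chi[idx],
    a = x$a[idx]
  )
}

#' Map Flory-Huggins chi parameters onto DPD repulsions
#'
#' Applies the Groot-Warren linear relation for bead density
#' \eqn{\rho = 3}: \eqn{a_{ij} = 25 + 3.27\,\chi_{ij}} (reduced units).
#' Only the density-3 line is supported; the mapping is not extrapolated
#' to other densities.
#'
#' @param chi Numeric scalar, vector or matrix of \eqn{\chi} values.
#' @param baseline Like-species repulsion; default 25.
#' @param slope Linear coefficient; default 3.27.
#' @param density Bead density the mapping is valid for; must be 3.
#' @return Repulsion parameter(s) of the same shape as `chi`.
#' @export
#' @examples
#' repulsion_from_chi(0.963) # 28.149
repulsion_from_chi <- function(chi, baseline = 25, slope = 3.27, density = 3) {
  if (!isTRUE(all.equal(density, 3))) {
    abort_validation(
      "the chi -> a mapping is calibrated for bead density 3 only")
  }
  if (!is.numeric(chi)) abort_validation("`chi` must be numeric")
  a <- baseline + slope * chi
  if (any(a < 0)) {
    abort_validation(sprintf(
      "chi = %g maps to a negative repulsion; chi must exceed %g",
      min(chi), -baseline / slope
    ))
  }
  a
}

#' Reference chi-parameter table for the micelle nanoreactor system
#'
#' Returns the packaged quantum-chemistry-derived Flory-Huggins
#' \eqn{\chi} matrix for the five bead species of the amphiphilic
#' bottlebrush copolymer system: `L` (lipophilic styrene), `H`
#' (hydrophilic ethylene oxide), `F` (fluorophilic pentafluorostyrene),
#' `Proline` (the L-proline catalyst block) and `W` (water).  The
#' repulsion matrix is filled via [repulsion_from_chi()].
#'
#' @param ... Passed on to [interaction_table()] (e.g. `gamma`).
#' @return An `interaction_table` for species L, H, F, Proline, W.
#' @export
#' @examples
#' it <- mcm_chi_table()
#' it$chi["H", "L"] # 1.462, the most immiscible pair
mcm_chi_table <- function(...) {
  path <- system.file("extdata", "chi_table_mcm.csv", package = "dpdmicelle",
                      mustWork = TRUE)
  read_chi_csv(path, ...)
}

#' Read / write a chi matrix as CSV
#'
#' The on-disk format is a header row of species labels followed by a
#' symmetric numeric body (first column = species label).
#'
#' @param path File path.
#' @param ... Passed on to [interaction_table()].
#' @return `read_chi_csv()` returns an `interaction_table`;
#'   `write_chi_csv()` returns `path` invisibly.
#' @export
read_chi_csv <- function(path, ...) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  species <- as.character(df[[1]])
  chi <- as.matrix(df[, -1, drop = FALSE])
  if (!identical(colnames(chi), species)) {
    abort_validation("chi CSV header labels must match its row labels")
  }
  storage.mode(chi) <- "double"
  interaction_table(species, chi, ...)
}

#' @rdname read_chi_csv
#' @param table An `interaction_table`.
#' @export
write_chi_csv <- function(table, path) {
  stopifnot(inherits(table, "interaction_table"))
  df <- data.frame(species = table$species, table$chi, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
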