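#' Thermodynamic context for chi-parameter estimation
#'
#' Holds the reference volume and temperature used to normalise mixing
#' energies into dimensionless Flory-Huggins \eqn{\chi} parameters.
#'
#' @param temperature Absolute temperature in K; default 298.15.
#' @param v_ref Reference volume in \eqn{\mbox{\AA}^3}.
#' @param gas_constant Gas constant in units consistent with the
#'   interaction energies; default kcal/(mol K).
#' @return A list of class `thermo_context`.
#' @export
thermo_context <- function(temperature = 298.15, v_ref = 100,
                           gas_constant = 1.987204258e-3) {
  stopifnot_scalar_number(temperature, "temperature", positive = TRUE)
  stopifnot_scalar_number(v_ref, "v_ref", positive = TRUE)
  stopifnot_scalar_number(gas_constant, "gas_constant", positive = TRUE)
  structure(
    list(temperature = temperature, v_ref = v_ref,
         gas_constant = gas_constant),
    class = "thermo_context"
  )
}

validate_mixing_records <- function(records) {
  needed <- c("species_i", "species_j", "Z", "V_A3", "E_kcal_mol", "n")
  missing <- setdiff(needed, names(records))
  if (length(missing) > 0) {
    abort_validation(paste0("mixing records lack column(s): ",
                            paste(missing, collapse = ", ")))
  }
  if (any(records$Z < 0)) abort_validation("coordination numbers Z must be >= 0")
  if (any(records$V_A3 <= 0)) abort_validation("pair volumes V_A3 must be > 0")
  if (any(records$n < 1)) abort_validation("monomer counts n must be >= 1")
  invisible(records)
}

# Volume-normalised pair energy density for one directed record row.
pair_energy_density <- function(row) {
  row$Z * row$E_kcal_mol / row$V_A3
}

find_record <- function(records, si, sj, what) {
  hit <- records[records$species_i == si & records$species_j == sj, , drop = FALSE]
  if (nrow(hit) == 0) {
    abort_config(sprintf("missing %s mixing record for pair %s-%s", what, si, sj))
  }
  hit[1, , drop = FALSE]
}

#' Mixing energy density of an A-B pair from pairwise statistics
#'
#' Combines directed pair records (coordination number \eqn{Z_{ij}},
#' combined Connolly-surface pair volume \eqn{V_{ij}}, mean interaction
#' energy \eqn{E_{ij}}, monomer count \eqn{n}) into a mixing energy per
#' unit volume using a Blends-style combining rule: the volume-normalised
#' unlike-pair energy densities \eqn{Z_{ij}E_{ij}/V_{ij}}, averaged over
#' the two directions, minus the average of the two like-pair terms,
#' scaled by \eqn{1/n}:
#' \deqn{\Delta E^{mix}_{AB} = \frac{1}{n}\left[
#'   \frac{1}{2}\left(\frac{Z_{AB}E_{AB}}{V_{AB}} +
#'                    \frac{Z_{BA}E_{BA}}{V_{BA}}\right) -
#'   \frac{1}{2}\left(\frac{Z_{AA}E_{AA}}{V_{AA}} +
#'                    \frac{Z_{BB}E_{BB}}{V_{BB}}\right)\right]}
#' The result is an energy density (kcal/mol per \eqn{\mbox{\AA}^3});
#' it vanishes when unlike-pair energetics equal the mean of the
#' like-pair energetics under the same volume normalisation, and is
#' linear in the energy fields.  The combining rule can be swapped via
#' `rule` without touching callers.
#'
#' @param records Data frame of directed mixing records with columns
#'   `species_i`, `species_j`, `Z`, `V_A3`, `E_kcal_mol`, `n`; must
#'   contain rows for AB, BA, AA and BB.
#' @param species_a,species_b The two species labels.
#' @param rule Combining rule; a function taking the four single-row
#'   record data frames (ab, ba, aa, bb) and returning an energy density.
#' @return Mixing energy density \eqn{\Delta E^{mix}_{AB}} (scalar).
#' @export
#' @examples
#' rec <- tibble::tibble(
#'   species_i = c("A", "B", "A", "B"), species_j = c("B", "A", "A", "B"),
#'   Z = 6, V_A3 = 100, E_kcal_mol = c(-1, -1, -2, -2), n = 1
#' )
#' mixing_energy(rec, "A", "B") # 0.06 kcal/mol/A^3
mixing_energy <- function(records, species_a, species_b, rule = NULL) {
  records <- validate_mixing_records(as.data.frame(records))
  ab <- find_record(records, species_a, species_b, "unlike")
  ba <- find_record(records, species_b, species_a, "unlike")
  aa <- find_record(records, species_a, species_a, "like")
  bb <- find_record(records, species_b, species_b, "like")
  if (is.null(rule)) {
    rule <- function(ab, ba, aa, bb) {
      n <- ab$n
      unlike <- (pair_energy_density(ab) + pair_energy_density(ba)) / 2
      like <- (pair_energy_density(aa) + pair_energy_density(bb)) / 2
      (unlike - like) / n
    }
  }
  rule(ab, ba, aa, bb)
}

#' Flory-Huggins chi from a mixing energy density
#'
#' Standard Flory-Huggins normalisation:
#' \eqn{\chi_{AB} = V_{ref}\,\Delta E^{mix}_{AB} / (RT)}.
#'
#' @param delta_e_mix Mixing energy density (energy per volume, units
#'   consistent with `ctx`).
#' @param ctx A [thermo_context()].
#' @return Dimensionless \eqn{\chi}; its sign follows `delta_e_mix`.
#' @export
chi_from_mixing <- function(delta_e_mix, ctx = thermo_context()) {
  stopifnot(inherits(ctx, "thermo_context"))
  ctx$v_ref * delta_e_mix / (ctx$gas_constant * ctx$temperature)
}

#' Build a chi table from a table of directed mixing records
#'
#' Convenience wrapper: applies [mixing_energy()] and [chi_from_mixing()]
#' to every unordered species pair present in `records` and assembles an
#' [interaction_table()].
#'
#' @inheritParams mixing_energy
#' @param ctx A [thermo_context()].
#' @param ... Passed on to [interaction_table()].
#' @return An `interaction_table`.
#' @export
chi_table_from_records <- function(records, ctx = thermo_context(), ...) {
  records <- validate_mixing_records(as.data.frame(records))
  species <- unique(c(records$species_i, records$species_j))
  ns <- length(species)
  chi <- matrix(0, ns, ns, dimnames = list(species, species))
  if (ns > 1) {
    for (i in seq_len(ns - 1)) {
      for (j in seq(i + 1, ns)) {
        de <- mixing_energy(records, species[i], species[j])
        chi[i, j] <- chi[j, i] <- chi_from_mixing(de, ctx)
      }
    }
  }
  interaction_table(species, chi, ...)
}

#' Read directed mixing records from CSV
#'
#' Expected columns: `species_i`, `species_j`, `Z`, `V_A3`, `E_kcal_mol`,
#' `n`.
#'
#' @param path File path.
#' @return A tibble of mixing records.
#' @export
read_mixing_records <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_mixing_records(df)
  tibble::as_tibble(df)
}
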