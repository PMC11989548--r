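#' Wavenumber-to-energy conversion factor (kcal/mol per cm^-1)
#'
#' A photon of wavenumber 1 cm^-1 carries an energy of h*c per molecule;
#' scaled by Avogadro's number and expressed in thermochemical kilocalories
#' this is 2.85914e-3 kcal/mol.  The constant is hard-coded here and
#' re-derived from CODATA values by [derive_conversion_factor()]; the two
#' must agree to six significant figures.
#'
#' @format A length-one numeric.
#' @export
KCAL_PER_WAVENUMBER <- 2.85914e-3

#' Derive the wavenumber-to-energy conversion factor from physical constants
#'
#' Computes N_A * h * c for a wavenumber of 1 cm^-1 and expresses the result
#' in kcal/mol, using the CODATA (SI 2019 exact) values of Planck's constant,
#' the speed of light and Avogadro's number, and the thermochemical calorie
#' (1 cal = 4.184 J).
#'
#' @param per_molecule Logical; if `TRUE` return the per-molecule energy in
#'   kcal (the molar value divided by Avogadro's number).
#' @return Conversion factor in kcal/mol per cm^-1 (or kcal per molecule per
#'   cm^-1 when `per_molecule = TRUE`).
#' @examples
#' derive_conversion_factor()        # ~2.85914e-3
#' 1 / derive_conversion_factor()    # ~349.75 cm^-1 per kcal/mol
#' @export
derive_conversion_factor <- function(per_molecule = FALSE) {
  planck <- 6.62607015e-34        # J s (exact)
  c_cm <- 2.99792458e10           # cm/s (exact)
  avogadro <- 6.02214076e23       # 1/mol (exact)
  joule_per_kcal <- 4184          # thermochemical
  molar <- planck * c_cm * avogadro / joule_per_kcal
  if (per_molecule) molar / avogadro else molar
}

#' Convert an FTIR wavenumber to a molar bond energy
#'
#' Photon energy is directly proportional to wavenumber (E = h c W), so
#' higher-wavenumber vibrational bands correspond to higher bond energies.
#'
#' @param wavenumber Non-negative wavenumber(s) in cm^-1.
#' @return Energy in kcal/mol (vectorized).
#' @examples
#' wavenumber_to_energy(1744)  # aldehyde C=O stretch, ~4.99 kcal/mol
#' wavenumber_to_energy(976)   # phosphate stretch, ~2.79 kcal/mol
#' @export
wavenumber_to_energy <- function(wavenumber) {
  if (!is.numeric(wavenumber) || any(!is.finite(wavenumber))) {
    stop("`wavenumber` must be finite numeric", call. = FALSE)
  }
  if (any(wavenumber < 0)) {
    stop("`wavenumber` must be non-negative (cm^-1)", call. = FALSE)
  }
  KCAL_PER_WAVENUMBER * wavenumber
}

# Characteristic coronary-artery absorption bands: wavenumber (cm^-1),
# functional-group assignment, and molar bond energy as printed in the
# clinical FTIR literature (energies truncated to 3 significant figures).
.band_table <- function() {
  data.frame(
    wavenumber_cm1 = c(1744, 1685, 1657, 1631, 1541, 1511, 1163, 1113, 976),
    assignment = c(
      "Aldehydes (CHO) - peroxidation product",
      "beta-sheet, anti-parallel",
      "Amide I alpha-helix",
      "Amide I, random coil, beta-sheet parallel",
      "Amide II, alpha-helix",
      "beta-sheet, parallel",
      "PO2- of phospholipids",
      "vC-O-C, Glycosylation (AGEs)",
      "vPO4(3-)"
    ),
    energy_kcal_mol = c(4.98, 4.82, 4.74, 4.66, 4.4, 4.32, 3.32, 3.18, 2.79),
    stringsAsFactors = FALSE
  )
}

#' Registry of characteristic FTIR bands of atherosclerotic coronary arteries
#'
#' Returns the nine characteristic absorption bands used by the model:
#' the aldehyde (CHO) stretch at 1744 cm^-1 that tracks malondialdehyde
#' (MDA), the protein amide bands, the phospholipid and glycosylation
#' bands, and the phosphate stretch at 976 cm^-1 that tracks
#' hydroxyapatite-like mineralization.  Energies are the published values;
#' each is reproduced within 0.01 kcal/mol by
#' [wavenumber_to_energy()] (the published table truncates rather than
#' rounds).
#'
#' @return A data frame with columns `wavenumber_cm1`, `assignment`,
#'   `energy_kcal_mol`.
#' @seealso [band_lookup()], [write_band_registry()]
#' @export
band_registry <- function() .band_table()

#' Look up one FTIR band by wavenumber
#'
#' @param wavenumber Exact wavenumber in cm^-1 of a registry band.
#' @return A one-row data frame (`wavenumber_cm1`, `assignment`,
#'   `energy_kcal_mol`).
#' @examples
#' band_lookup(1113)
#' @export
band_lookup <- function(wavenumber) {
  reg <- band_registry()
  hit <- which(reg$wavenumber_cm1 == wavenumber)
  if (length(hit) == 0L) {
    stop("no registry band at ", wavenumber, " cm^-1", call. = FALSE)
  }
  reg[hit, , drop = FALSE]
}

#' Write the band registry to CSV
#'
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_band_registry <- function(path) {
  utils::write.csv(band_registry(), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Construct a Morse bond description
#'
#' @param dissociation_energy Bond dissociation energy D (> 0, energy units).
#' @param force_constant Stretching force constant k (> 0).
#' @param equilibrium_length Equilibrium bond length r0 (> 0).
#' @return An object of class `morse_bond`.
#' @export
morse_bond <- function(dissociation_energy, force_constant, equilibrium_length) {
  vals <- c(D = dissociation_energy, k = force_constant, r0 = equilibrium_length)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("morse_bond parameters must all be strictly positive", call. = FALSE)
  }
  structure(
    list(
      dissociation_energy = dissociation_energy,
      force_constant = force_constant,
      equilibrium_length = equilibrium_length
    ),
    class = "morse_bond"
  )
}

#' Morse potential energy of a stretched bond
#'
#' Evaluates the anharmonic Morse well
#' \deqn{E(r) = D (1 - e^{-a (r - r_0)})^2, \qquad a = \sqrt{k / (2D)},}
#' where D is the bond dissociation energy, k the stretching force constant
#' and r0 the equilibrium bond length.  The energy is zero at r = r0 and
#' tends to D as the bond is pulled apart.
#'
#' @param bond A [morse_bond()] object.
#' @param r Interatomic distance(s), same length unit as `equilibrium_length`;
#'   must be non-negative.
#' @return Energy (vectorized over `r`), in the unit of
#'   `dissociation_energy`.
#' @examples
#' b <- morse_bond(100, 50, 1)
#' morse_energy(b, 1)      # 0 at the bottom of the well
#' morse_energy(b, 1.1)    # ~0.2379
#' @export
morse_energy <- function(bond, r) {
  stopifnot(inherits(bond, "morse_bond"))
  if (any(!is.finite(r)) || any(r < 0)) {
    stop("`r` must be non-negative and finite", call. = FALSE)
  }
  a <- sqrt(bond$force_constant / (2 * bond$dissociation_energy))
  bond$dissociation_energy * (1 - exp(-a * (r - bond$equilibrium_length)))^2
}
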